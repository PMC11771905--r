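#' Extract key regulators from a decomposition tree
#'
#' Key regulators are the genes that persist from the root of the
#' hierarchical decomposition down to a terminal triangle (G(3,3)) motif.
#' Because the community partitions are nested, every member of a motif
#' leaf has an ancestor community at every level, so the set of key
#' regulators is exactly the union of the motif-leaf members and their
#' count is 3 times the number of motif leaves.
#'
#' @param tree a [recursive_decompose()] tree.
#' @return data.frame with one row per regulator: `gene`, `leaf_label`,
#'   `partner1`, `partner2` (the other two genes of its motif).
#' @export
extract_key_regulators <- function(tree) {
  stopifnot(inherits(tree, "decomposition_tree"))
  if (length(tree$motif_leaves) == 0)
    return(data.frame(gene = character(0), leaf_label = character(0),
                      partner1 = character(0), partner2 = character(0),
                      stringsAsFactors = FALSE))
  rows <- lapply(tree$motif_leaves, function(leaf) {
    mem <- sort(leaf$members)
    data.frame(gene = mem,
               leaf_label = leaf$label,
               partner1 = vapply(mem, function(g) setdiff(mem, g)[1], ""),
               partner2 = vapply(mem, function(g) setdiff(mem, g)[2], ""),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Topological summary of the key regulators
#'
#' Joins each regulator with its node metrics from the primary network and
#' flags low-degree bridge nodes: regulators whose own degree is at most
#' `bridge_k_max` while some motif partner has degree at least `hub_k_min`.
#' The default thresholds are report heuristics for highlighting the
#' low-degree-next-to-hub pattern and are fully configurable.
#'
#' @param records output of [extract_key_regulators()].
#' @param metrics output of [node_metrics()] on the primary network.
#' @param bridge_k_max maximum degree of a "low degree" regulator.
#'   Default 11.
#' @param hub_k_min minimum partner degree that counts as a hub.
#'   Default 17.
#' @return data.frame with columns `gene`, `leaf_label`, `partner1`,
#'   `partner2`, `k`, `C_B`, `C_C`, `C`, `low_degree_bridge` (full
#'   precision; round for reports with [write_regulator_table()]).
#' @export
regulator_summary <- function(records, metrics, bridge_k_max = 11,
                              hub_k_min = 17) {
  idx <- match(records$gene, metrics$node)
  if (anyNA(idx))
    stop("no metrics for gene(s): ",
         paste(records$gene[is.na(idx)], collapse = ", "))
  k_of <- stats::setNames(metrics$k, metrics$node)
  out <- cbind(records,
               k = metrics$k[idx],
               C_B = metrics$C_B[idx],
               C_C = metrics$C_C[idx],
               C = metrics$C[idx])
  out$low_degree_bridge <- out$k <= bridge_k_max &
    pmax(k_of[records$partner1], k_of[records$partner2]) >= hub_k_min
  out$low_degree_bridge <- unname(out$low_degree_bridge)
  rownames(out) <- NULL
  out
}

#' Write the key-regulator table as TSV (centralities rounded to 4 decimals)
#'
#' @param summary output of [regulator_summary()].
#' @param path output path.
#' @param digits decimal places for `C_B`, `C_C`, `C`. Default 4.
#' @return The table as written, invisibly.
#' @export
write_regulator_table <- function(summary, path, digits = 4) {
  out <- summary
  for (col in intersect(c("C_B", "C_C", "C"), names(out)))
    out[[col]] <- round(out[[col]], digits)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(out)
}
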