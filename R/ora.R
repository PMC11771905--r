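#' Gene-set collection
#'
#' @param sets named list; each element a list with `description` (string)
#'   and `genes` (character vector), or simply a character vector of genes.
#' @param universe background gene symbols; defaults to the union of all
#'   set members. Members outside the universe are dropped (count reported
#'   via message); empty sets are dropped with a warning.
#' @return A `gene_set_collection`: list with `sets` and `universe`.
#' @export
gene_set_collection <- function(sets, universe = NULL) {
  sets <- lapply(sets, function(s) {
    if (is.character(s)) list(description = "", genes = unique(s))
    else list(description = s$description %||% "",
              genes = unique(s$genes))
  })
  if (is.null(universe))
    universe <- unique(unlist(lapply(sets, `[[`, "genes")))
  universe <- unique(as.character(universe))
  dropped <- 0L
  sets <- lapply(sets, function(s) {
    keep <- s$genes %in% universe
    dropped <<- dropped + sum(!keep)
    s$genes <- s$genes[keep]
    s
  })
  if (dropped > 0)
    message(sprintf("dropped %d set member(s) outside the universe", dropped))
  empty <- vapply(sets, function(s) length(s$genes) == 0, TRUE)
  if (any(empty)) {
    warning(sprintf("dropping %d empty set(s)", sum(empty)))
    sets <- sets[!empty]
  }
  structure(list(sets = sets, universe = universe),
            class = "gene_set_collection")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a GMT gene-set file
#'
#' Tab-separated lines: set name, description, then member symbols.
#' Duplicate members within a set are collapsed.
#'
#' @param path GMT file path.
#' @param universe optional background; see [gene_set_collection()].
#' @return A `gene_set_collection`.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop(sprintf("GMT line %d has fewer than 3 fields", i))
    sets[[fields[1]]] <- list(description = fields[2],
                              genes = unique(fields[-(1:2)]))
  }
  gene_set_collection(sets, universe = universe)
}

#' Write a collection to GMT
#'
#' @param collection a `gene_set_collection`.
#' @param path output path.
#' @return Invisibly, the collection.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    s <- collection$sets[[nm]]
    paste(c(nm, s$description, s$genes), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(collection)
}

#' Hypergeometric over-representation analysis
#'
#' For each set, with universe size `N`, set size `K`, query size `n` and
#' overlap `k`, the enrichment p-value is the hypergeometric upper tail
#' `P[X >= k]` and the fold enrichment is `(k/n) / (K/N)`. P-values are
#' BH-adjusted across the sets of the collection and results are sorted by
#' p-value.
#'
#' @param query character vector of gene symbols; members outside the
#'   universe are dropped with a warning.
#' @param collection a [gene_set_collection()].
#' @return data.frame with columns `set_name`, `description`, `overlap_k`,
#'   `query_n`, `set_K`, `universe_N`, `fold_enrichment`, `p_value`, `fdr`,
#'   `genes` (overlap, comma-joined), sorted by `p_value`.
#' @export
hypergeom_ora <- function(query, collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  N <- length(collection$universe)
  if (N == 0) stop("empty universe")
  query <- unique(as.character(query))
  outside <- setdiff(query, collection$universe)
  if (length(outside)) {
    warning(sprintf("dropping %d query gene(s) outside the universe",
                    length(outside)))
    query <- setdiff(query, outside)
  }
  n <- length(query)
  if (n == 0) stop("empty query")
  rows <- lapply(names(collection$sets), function(nm) {
    s <- collection$sets[[nm]]
    K <- length(s$genes)
    hit <- intersect(query, s$genes)
    k <- length(hit)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = nm, description = s$description,
               overlap_k = k, query_n = n, set_K = K, universe_N = N,
               fold_enrichment = (k / n) / (K / N),
               p_value = p,
               genes = paste(sort(hit), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p_value)
  out <- out[order(out$p_value, out$set_name), ]
  rownames(out) <- NULL
  out[, c("set_name", "description", "overlap_k", "query_n", "set_K",
          "universe_N", "fold_enrichment", "p_value", "fdr", "genes")]
}
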