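#' Read a scored gene-gene interaction table
#'
#' Two TSV dialects are supported. `string_tsv` is the STRING export format
#' with columns `protein1`, `protein2`, `combined_score`, where the combined
#' score is an integer on a 0-1000 scale and is divided by 1000. `plain_tsv`
#' expects columns `protein_a`, `protein_b`, `combined_score` with scores
#' already in \[0, 1\]. Duplicate A-B / B-A rows are collapsed keeping the
#' maximum score; self-pairs are dropped with a warning.
#'
#' @param path TSV file path.
#' @param dialect `"string_tsv"` or `"plain_tsv"`.
#' @return A data.frame (`interaction_table`) with columns `protein_a`,
#'   `protein_b`, `combined_score`.
#' @export
read_interactions <- function(path, dialect = c("string_tsv", "plain_tsv")) {
  dialect <- match.arg(dialect)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, sep = "")
  cols <- if (dialect == "string_tsv")
    c("protein1", "protein2", "combined_score") else
    c("protein_a", "protein_b", "combined_score")
  miss <- setdiff(cols, names(df))
  if (length(miss)) stop("missing column: ", paste(miss, collapse = ", "))
  tab <- data.frame(protein_a = as.character(df[[cols[1]]]),
                    protein_b = as.character(df[[cols[2]]]),
                    combined_score = as.numeric(df[[cols[3]]]),
                    stringsAsFactors = FALSE)
  if (dialect == "string_tsv") tab$combined_score <- tab$combined_score / 1000
  interaction_table(tab)
}

#' Construct a validated interaction table
#'
#' @param tab data.frame with columns `protein_a`, `protein_b`,
#'   `combined_score` (scores in \[0, 1\]).
#' @return The cleaned `interaction_table` data.frame.
#' @export
interaction_table <- function(tab) {
  need <- c("protein_a", "protein_b", "combined_score")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing column: ", paste(miss, collapse = ", "))
  if (any(tab$combined_score < 0 | tab$combined_score > 1, na.rm = TRUE))
    stop("combined_score outside [0, 1] after normalization")
  self <- tab$protein_a == tab$protein_b
  if (any(self)) {
    warning(sprintf("dropping %d self-pair(s)", sum(self)))
    tab <- tab[!self, , drop = FALSE]
  }
  if (nrow(tab)) {
    a <- pmin(tab$protein_a, tab$protein_b)
    b <- pmax(tab$protein_a, tab$protein_b)
    key <- paste(a, b, sep = "\r")
    score <- tapply(tab$combined_score, key, max)
    parts <- strsplit(names(score), "\r", fixed = TRUE)
    tab <- data.frame(protein_a = vapply(parts, `[`, "", 1),
                      protein_b = vapply(parts, `[`, "", 2),
                      combined_score = unname(score),
                      stringsAsFactors = FALSE)
    rownames(tab) <- NULL
  }
  class(tab) <- c("interaction_table", "data.frame")
  tab
}

#' Build the interaction network over a gene whitelist
#'
#' Keeps edges whose combined score is strictly greater than `score_min` and
#' whose both endpoints belong to `node_whitelist` (typically the DEG
#' symbols). Whitelist genes left without any retained edge are excluded
#' from the graph (their count is reported via a message).
#'
#' @param table an [interaction_table()].
#' @param node_whitelist character vector of gene symbols to keep.
#' @param score_min strict lower score threshold. Default 0.4.
#' @return An undirected simple [igraph::graph] with an `score` edge
#'   attribute.
#' @export
build_network <- function(table, node_whitelist, score_min = 0.4) {
  if (length(node_whitelist) == 0) stop("empty node whitelist")
  keep <- table$combined_score > score_min &
    table$protein_a %in% node_whitelist &
    table$protein_b %in% node_whitelist
  edges <- table[keep, , drop = FALSE]
  if (nrow(edges) == 0) stop("no edges above threshold")
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$protein_a, to = edges$protein_b,
               score = edges$combined_score),
    directed = FALSE)
  g <- igraph::simplify(g, edge.attr.comb = list(score = "max"))
  isolated <- setdiff(node_whitelist, igraph::V(g)$name)
  message(sprintf("network: %d nodes, %d edges; %d whitelist gene(s) isolated/unmatched",
                  igraph::vcount(g), igraph::ecount(g), length(isolated)))
  g
}

#' Connected components as node-name sets
#'
#' @param graph an undirected igraph graph.
#' @return List of character vectors of node names, sorted by decreasing
#'   component size.
#' @export
connected_components <- function(graph) {
  comp <- igraph::components(graph)
  sets <- split(igraph::V(graph)$name, comp$membership)
  sets[order(-vapply(sets, length, 1L),
             vapply(sets, min, ""))]
}

#' Write / read a network edge list as TSV (`a<TAB>b<TAB>score`)
#'
#' @param graph an igraph graph with an optional `score` edge attribute.
#' @param path output (or input) path.
#' @return `write_network` invisibly returns the graph; `read_network`
#'   returns an igraph graph.
#' @export
write_network <- function(graph, path) {
  el <- igraph::as_data_frame(graph, what = "edges")
  if (is.null(el$score)) el$score <- 1
  utils::write.table(el[, c("from", "to", "score")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE,
                     col.names = c("protein_a", "protein_b", "combined_score"))
  invisible(graph)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  tab <- read_interactions(path, dialect = "plain_tsv")
  build_network(tab, unique(c(tab$protein_a, tab$protein_b)), score_min = -1)
}
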