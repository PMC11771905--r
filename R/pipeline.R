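pipeline_defaults <- function() {
  list(
    expression = NULL,      # path to expression TSV, or expression_matrix
    groups = NULL,          # path to sample-group TSV (with expression path)
    scale = "log2",
    pseudocount = 1,
    interactions = NULL,    # path to interaction TSV, or interaction_table
    dialect = "plain_tsv",
    lfc_min = 1.0,
    p_max = 0.05,
    padj_max = 0.05,
    test = "moderated",
    score_min = 0.4,
    n_boot = 2500,
    seed = 1,
    max_level = NULL,
    scope = "local",
    refine = "none",
    gmt = NULL,             # optional path to GMT collection
    query = "keyreg",       # ORA query: "keyreg" or "deg"
    bridge_k_max = 11,
    hub_k_min = 17,
    out_dir = NULL          # where stage TSV/JSON outputs are written
  )
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage %s failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full key-regulator pipeline
#'
#' Executes the stage chain deg -> network -> topology -> power-law fits ->
#' community decomposition -> key regulators -> (optional) enrichment with a
#' single config, and returns a consolidated report. With `out_dir` set,
#' each stage's table is written as TSV/JSON and md5-checksummed into the
#' report; reruns with the same config and seed are byte-identical (the
#' report carries no timestamps).
#'
#' @param config named list overriding the defaults (see
#'   `keyregnet:::pipeline_defaults()`); unknown keys are rejected.
#'   Required: `expression` (path or [expression_matrix()]) with `groups`
#'   when a path, and `interactions` (path or [interaction_table()]).
#' @return A `pipeline_report` list: `config`, `deg` (counts + table),
#'   `network` (size), `topology`, `fits`, `classification`, `tree`
#'   summary, `key_regulators`, `enrichment` (or NULL), `warnings`,
#'   `checksums`.
#' @export
run_pipeline <- function(config = list()) {
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  warn_log <- character(0)
  withCallingHandlers({

  set.seed(cfg$seed)

  expr <- run_stage("deg_screen", {
    if (inherits(cfg$expression, "expression_matrix")) cfg$expression
    else {
      if (is.null(cfg$expression) || is.null(cfg$groups))
        stop("expression matrix and groups are required")
      read_expression(cfg$expression, cfg$groups, scale = cfg$scale,
                      pseudocount = cfg$pseudocount)
    }
  })
  deg_tab <- run_stage("deg_screen",
    screen_degs(expr, lfc_min = cfg$lfc_min, p_max = cfg$p_max,
                padj_max = cfg$padj_max, test = cfg$test))
  degs <- deg_tab$gene[deg_tab$direction != "none"]

  itab <- run_stage("network_build", {
    if (inherits(cfg$interactions, "interaction_table")) cfg$interactions
    else {
      if (is.null(cfg$interactions)) stop("interaction table is required")
      read_interactions(cfg$interactions, dialect = cfg$dialect)
    }
  })
  net <- run_stage("network_build",
    suppressMessages(build_network(itab, degs, score_min = cfg$score_min)))

  metrics <- run_stage("topology_metrics", node_metrics(net))
  profile <- run_stage("topology_metrics", degree_profile(metrics))

  fits <- run_stage("powerlaw_fit",
    fit_topology(metrics, profile, n_boot = cfg$n_boot, seed = cfg$seed))
  classification <- run_stage("powerlaw_fit", classify_network(fits))

  tree <- run_stage("community_decomposition",
    recursive_decompose(net, max_level = cfg$max_level,
                        scope = cfg$scope, refine = cfg$refine))

  records <- run_stage("key_regulators", extract_key_regulators(tree))
  keyreg <- run_stage("key_regulators",
    if (nrow(records)) regulator_summary(records, metrics,
                                         bridge_k_max = cfg$bridge_k_max,
                                         hub_k_min = cfg$hub_k_min)
    else records)

  enrichment <- NULL
  if (!is.null(cfg$gmt)) {
    query <- if (cfg$query == "deg") degs else unique(records$gene)
    if (length(query) == 0) {
      message("enrichment skipped: empty query gene set")
    } else {
      enrichment <- run_stage("enrichment_ora", {
        collection <- read_gmt(cfg$gmt, universe = igraph::V(net)$name)
        hypergeom_ora(query, collection)
      })
    }
  }

  exponents <- vapply(fits[c("pk", "ck", "cnk", "cbk", "cck", "cek")],
                      function(f) f$exponent, 0)
  signs <- vapply(fits[c("pk", "ck", "cnk", "cbk", "cck", "cek")],
                  function(f) f$sign, "")

  # config echoed for provenance; in-memory inputs summarized as strings so
  # the report stays JSON-serializable and deterministic
  cfg_echo <- cfg[order(names(cfg))]
  if (inherits(cfg_echo$expression, "expression_matrix"))
    cfg_echo$expression <- sprintf(
      "<expression_matrix %d genes x %d samples>",
      nrow(cfg$expression$values), ncol(cfg$expression$values))
  if (inherits(cfg_echo$interactions, "interaction_table"))
    cfg_echo$interactions <- sprintf("<interaction_table %d rows>",
                                     nrow(cfg$interactions))
  report <- list(
    config = cfg_echo,
    deg = list(n_tested = nrow(deg_tab),
               n_deg = length(degs),
               counts = as.list(attr(deg_tab, "counts"))),
    network = list(nodes = igraph::vcount(net),
                   edges = igraph::ecount(net),
                   components = length(connected_components(net))),
    fits = list(exponents = as.list(exponents),
                exponent_signs = as.list(signs),
                degree_clauset = fits$degree_clauset[
                  c("exponent", "xmin", "ks_D", "boot_p", "n_tail")]),
    classification = classification[c("scale_free", "hierarchy", "mixing")],
    tree = list(levels = tree$max_level,
                motif_leaves = length(tree$motif_leaves),
                key_regulators = nrow(keyreg),
                motif_table = label_paths(tree)),
    key_regulators = keyreg,
    enrichment = enrichment,
    warnings = NULL, checksums = NULL)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(degs = file.path(cfg$out_dir, "degs.tsv"),
               network = file.path(cfg$out_dir, "network.tsv"),
               metrics = file.path(cfg$out_dir, "metrics.tsv"),
               profile = file.path(cfg$out_dir, "profile.tsv"),
               motifs = file.path(cfg$out_dir, "motifs.tsv"),
               keyreg = file.path(cfg$out_dir, "keyreg.tsv"))
    write_deg_table(deg_tab, paths["degs"])
    write_network(net, paths["network"])
    utils::write.table(metrics, paths["metrics"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(profile, paths["profile"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(label_paths(tree), paths["motifs"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_regulator_table(keyreg, paths["keyreg"])
    if (!is.null(enrichment)) {
      paths["enrichment"] <- file.path(cfg$out_dir, "enrichment.tsv")
      utils::write.table(enrichment, paths["enrichment"], sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    report$checksums <- as.list(tools::md5sum(unname(paths)))
    names(report$checksums) <- names(paths)
  }
  report$warnings <- warn_log
  structure(report, class = "pipeline_report")

  }, warning = function(w) {
    warn_log <<- c(warn_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf(
    "pipeline_report: %d/%d DEGs (up %d, down %d); network %d nodes / %d edges; tree depth %d, %d motif leaves, %d key regulators\n",
    x$deg$n_deg, x$deg$n_tested, x$deg$counts$up, x$deg$counts$down,
    x$network$nodes, x$network$edges, x$tree$levels, x$tree$motif_leaves,
    x$tree$key_regulators))
  cat(sprintf("classification: scale_free = %s, hierarchy = %s, mixing = %s\n",
              x$classification$scale_free, x$classification$hierarchy,
              x$classification$mixing))
  invisible(x)
}

#' Serialize a pipeline report to JSON
#'
#' Deterministic (no timestamps), so identical configs and seeds produce
#' byte-identical files.
#'
#' @param report a [run_pipeline()] report.
#' @param path output JSON path.
#' @return Invisibly, the path.
#' @export
write_report <- function(report, path) {
  out <- unclass(report)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
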