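#' Per-gene log2 fold change (case minus control)
#'
#' On the log2 scale the fold change is the difference of group means, which
#' equals the log2 ratio of geometric means on the linear scale.
#'
#' @param x an [expression_matrix()].
#' @return Named numeric vector of log2 fold changes, one per gene.
#' @export
log2_fold_change <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  ctrl <- x$groups == "control"
  case <- x$groups == "case"
  if (!any(ctrl) || !any(case)) stop("empty group")
  rowMeans(x$values[, case, drop = FALSE]) -
    rowMeans(x$values[, ctrl, drop = FALSE])
}

# Newton inversion of the trigamma function (solve trigamma(x) = y), as used
# when moment-matching the prior degrees of freedom of the variance model.
trigamma_inverse <- function(y) {
  out <- y
  lo <- y < 1e-6
  hi <- y > 1e7
  out[lo] <- 1 / y[lo]
  out[hi] <- 1 / sqrt(y[hi])
  mid <- !lo & !hi
  if (any(mid)) {
    x <- 0.5 + 1 / y[mid]
    for (i in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / y[mid]) / psigamma(x, deriv = 2)
      x <- x + dif
      if (max(-dif / x) < 1e-10) break
    }
    out[mid] <- x
  }
  out
}

# Moment-matching estimate of the variance prior (d0, s0^2): the log sample
# variances are matched to the log-F distribution they follow under the
# hierarchical model, giving d0 from an inverted trigamma and s0^2 from the
# mean. Genes with zero sample variance are excluded from estimation.
estimate_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (!any(ok)) stop("degenerate variance")
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.na(evar) || evar <= 0) {
    list(d0 = Inf, s0_2 = exp(emean))
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    list(d0 = d0, s0_2 = exp(emean + digamma(d0 / 2) - log(d0 / 2)))
  }
}

#' Moderated two-sample t-test per gene
#'
#' Gene-wise pooled variances are shrunk toward a common prior variance by
#' empirical Bayes: the posterior variance is `(d0*s0^2 + d*s^2) / (d0 + d)`
#' with the prior degrees of freedom `d0` and prior variance `s0^2` estimated
#' by moment matching on the distribution of log gene variances. Two-sided
#' p-values come from a t distribution on `d + d0` degrees of freedom.
#' `test = "ordinary"` disables shrinkage (`d0 = 0`), giving the classical
#' pooled-variance two-sample t-test.
#'
#' @param x an [expression_matrix()] with at least 2 samples per group.
#' @param test `"moderated"` (default) or `"ordinary"`.
#' @return A data.frame with columns `gene`, `t`, `p`; attributes `d0` and
#'   `s0_2` carry the estimated prior.
#' @export
moderated_t <- function(x, test = c("moderated", "ordinary")) {
  test <- match.arg(test)
  stopifnot(inherits(x, "expression_matrix"))
  ctrl <- x$values[, x$groups == "control", drop = FALSE]
  case <- x$values[, x$groups == "case", drop = FALSE]
  n1 <- ncol(ctrl); n2 <- ncol(case)
  if (n1 < 2 || n2 < 2) stop("need at least 2 samples per group")
  df <- n1 + n2 - 2
  m1 <- rowMeans(ctrl); m2 <- rowMeans(case)
  ss1 <- rowSums((ctrl - m1)^2)
  ss2 <- rowSums((case - m2)^2)
  s2 <- (ss1 + ss2) / df
  if (all(s2 == 0)) stop("degenerate variance")
  diff <- m2 - m1
  if (test == "moderated") {
    prior <- estimate_variance_prior(s2, df)
    d0 <- prior$d0; s0_2 <- prior$s0_2
    s2_post <- if (is.infinite(d0)) rep(s0_2, length(s2)) else
      (d0 * s0_2 + df * s2) / (d0 + df)
    df_total <- df + d0
  } else {
    d0 <- 0; s0_2 <- NA_real_
    s2_post <- s2
    df_total <- df
  }
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t <- ifelse(se > 0, diff / se, ifelse(diff == 0, 0, Inf * sign(diff)))
  p <- 2 * stats::pt(-abs(t), df = df_total)
  structure(data.frame(gene = rownames(x$values), t = t, p = p,
                       row.names = NULL, stringsAsFactors = FALSE),
            d0 = d0, s0_2 = s0_2, df_total = df_total)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validated wrapper over [stats::p.adjust()] with `method = "BH"`:
#' adjusted values are clipped at 1 and returned in the input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("p-values must be numeric")
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Filter a DEG table at the screening thresholds
#'
#' Retains records with `|log2fc| >= lfc_min` AND `p < p_max` AND
#' `padj <= padj_max` (note the mixed strictness: non-strict on the fold
#' change and adjusted p, strict on the raw p). Passing records are
#' directed `up` (log2fc > 0) or `down` (log2fc < 0).
#'
#' @param table data.frame with columns `gene`, `log2fc`, `p`, `padj` (and
#'   optionally `t`).
#' @param lfc_min minimum absolute log2 fold change. Default 1.
#' @param p_max exclusive upper bound on the raw p-value. Default 0.05.
#' @param padj_max inclusive upper bound on the BH-adjusted p. Default 0.05.
#' @return The retained rows with a `direction` column; attribute `counts`
#'   holds the up/down tally.
#' @export
filter_degs <- function(table, lfc_min = 1.0, p_max = 0.05, padj_max = 0.05) {
  need <- c("gene", "log2fc", "p", "padj")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (nrow(table) == 0) {
    out <- cbind(table, direction = character(0))
    attr(out, "counts") <- c(up = 0L, down = 0L)
    return(out)
  }
  pass <- abs(table$log2fc) >= lfc_min & table$p < p_max & table$padj <= padj_max
  out <- table[pass, , drop = FALSE]
  out$direction <- ifelse(out$log2fc > 0, "up", "down")
  rownames(out) <- NULL
  attr(out, "counts") <- c(up = sum(out$direction == "up"),
                           down = sum(out$direction == "down"))
  out
}

#' Screen differentially expressed genes
#'
#' Full DEG stage: log2 fold changes, (moderated) t-test, BH adjustment, and
#' threshold filtering. Every gene is reported; the `direction` column is
#' `up`/`down` for genes passing all three filters and `none` otherwise.
#'
#' @inheritParams moderated_t
#' @inheritParams filter_degs
#' @return A data.frame with columns `gene`, `log2fc`, `t`, `p`, `padj`,
#'   `direction`; attribute `counts` gives the up/down tally among passers.
#' @export
screen_degs <- function(x, lfc_min = 1.0, p_max = 0.05, padj_max = 0.05,
                        test = c("moderated", "ordinary")) {
  test <- match.arg(test)
  lfc <- log2_fold_change(x)
  tt <- moderated_t(x, test = test)
  tab <- data.frame(gene = tt$gene, log2fc = unname(lfc[tt$gene]),
                    t = tt$t, p = tt$p, padj = bh_adjust(tt$p),
                    stringsAsFactors = FALSE)
  kept <- filter_degs(tab, lfc_min, p_max, padj_max)
  tab$direction <- "none"
  tab$direction[match(kept$gene, tab$gene)] <- kept$direction
  attr(tab, "counts") <- attr(kept, "counts")
  tab
}

#' Write / read a DEG table as TSV
#'
#' @param table a DEG table from [screen_degs()].
#' @param path output (or input) TSV path.
#' @return `write_deg_table` returns the table invisibly; `read_deg_table`
#'   returns the data.frame.
#' @export
write_deg_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(table)
}

#' @rdname write_deg_table
#' @export
read_deg_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
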