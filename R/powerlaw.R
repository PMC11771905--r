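#' Fit a power law by the Clauset maximum-likelihood procedure
#'
#' The lower cutoff `xmin` is chosen to minimize the Kolmogorov-Smirnov
#' distance between the tail empirical CDF and the fitted power law
#' (candidates are the unique observed values; ties broken toward the
#' smallest `xmin`). The exponent is fitted by maximum likelihood: the
#' continuous closed form `1 + n / sum(log(x/xmin))`, or numerical
#' maximization of the zeta likelihood in the discrete case. The
#' goodness-of-fit p-value is the fraction of `n_boot` semi-parametric
#' bootstrap resamples (body resampled empirically, tail drawn from the
#' fitted model) whose refitted KS distance exceeds the observed one.
#'
#' @param values positive numeric observations (e.g. node degrees).
#' @param discrete logical; `NULL` (default) auto-detects integer-valued
#'   input.
#' @param xmin fixed lower cutoff, or `NULL` (default) to scan.
#' @param n_boot number of bootstrap resamples for the goodness-of-fit test
#'   (0 = skip). The conventional run uses 2500.
#' @param seed optional integer seed applied via [set.seed()] so the
#'   bootstrap is reproducible.
#' @return A `powerlaw_fit` object: list with `exponent` (magnitude),
#'   `sign` (`"decaying"`), `xmin`, `ks_D`, `boot_p`, `n_tail`, `method`.
#' @export
fit_clauset <- function(values, discrete = NULL, xmin = NULL, n_boot = 0,
                        seed = NULL) {
  values <- as.numeric(values)
  if (any(!is.finite(values)) || any(values <= 0))
    stop("values must be positive and finite")
  if (is.null(xmin) && length(values) < 10)
    stop("need at least 10 observations to scan xmin")
  if (is.null(discrete)) discrete <- all(values == round(values))
  if (!is.null(seed)) set.seed(seed)
  fit <- cpp_fit_powerlaw(values, discrete, if (is.null(xmin)) NA_real_ else
    as.numeric(xmin), as.integer(n_boot))
  structure(list(exponent = fit$alpha, sign = "decaying", xmin = fit$xmin,
                 ks_D = fit$ks_D, boot_p = fit$boot_p, n_tail = fit$n_tail,
                 method = "clauset_mle", discrete = discrete),
            class = "powerlaw_fit")
}

#' Log-log least-squares slope of a degree profile
#'
#' Ordinary least squares of `log(y)` on `log(x)`. The fitted slope keeps
#' its sign: a negative slope is a decaying `k^-b` form, a positive slope a
#' growing `k^+b` form. Non-positive `y` bins are dropped with a warning.
#'
#' @param profile_x degrees (positive).
#' @param profile_y per-degree means (non-negative; zeros dropped).
#' @return A `powerlaw_fit` with `method = "loglog_ols"`; `exponent` is the
#'   slope magnitude, `slope` the signed slope, plus `intercept` and
#'   `r_squared`.
#' @export
loglog_slope <- function(profile_x, profile_y) {
  stopifnot(length(profile_x) == length(profile_y))
  ok <- profile_x > 0 & profile_y > 0
  if (any(!ok)) warning(sprintf("dropping %d non-positive bin(s)", sum(!ok)))
  x <- log(profile_x[ok]); y <- log(profile_y[ok])
  if (length(x) < 3) stop("fewer than 3 usable points")
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  structure(list(exponent = abs(slope),
                 sign = if (slope < 0) "decaying" else
                   if (slope > 0) "growing" else "flat",
                 slope = slope, intercept = unname(stats::coef(fit)[1]),
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 xmin = min(profile_x[ok]), ks_D = NA_real_,
                 boot_p = NA_real_, n_tail = length(x),
                 method = "loglog_ols"),
            class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("powerlaw_fit [%s]: exponent %.4f (%s), xmin %g, n_tail %d",
              x$method, x$exponent, x$sign, x$xmin, x$n_tail))
  if (!is.na(x$ks_D)) cat(sprintf(", KS D %.4f", x$ks_D))
  if (!is.na(x$boot_p)) cat(sprintf(", boot p %.4f", x$boot_p))
  cat("\n")
  invisible(x)
}

#' Fit all six topological power laws of a network
#'
#' The degree distribution gets the full Clauset treatment (MLE + KS xmin
#' scan + bootstrap goodness-of-fit on the raw degrees); the five per-degree
#' profiles — clustering `C(k)`, neighbourhood connectivity `C_N(k)`,
#' betweenness `C_B(k)`, closeness `C_C(k)`, eigenvector `C_E(k)` — and the
#' `P(k)` profile are fitted by log-log least squares.
#'
#' @param metrics output of [node_metrics()].
#' @param profile output of [degree_profile()] (recomputed when `NULL`).
#' @param n_boot bootstrap resamples for the degree-distribution fit.
#' @param seed seed for the bootstrap.
#' @return Named list of fits: `degree_clauset` plus log-log fits `pk`,
#'   `ck`, `cnk`, `cbk`, `cck`, `cek`.
#' @export
fit_topology <- function(metrics, profile = NULL, n_boot = 2500, seed = NULL) {
  if (is.null(profile)) profile <- degree_profile(metrics)
  degs <- metrics$k[metrics$k > 0]
  fits <- list(
    degree_clauset = fit_clauset(degs, discrete = TRUE, n_boot = n_boot,
                                 seed = seed),
    pk  = suppressWarnings(loglog_slope(profile$k, profile$p_k)),
    ck  = suppressWarnings(loglog_slope(profile$k, profile$C)),
    cnk = suppressWarnings(loglog_slope(profile$k, profile$C_N)),
    cbk = suppressWarnings(loglog_slope(profile$k, profile$C_B)),
    cck = suppressWarnings(loglog_slope(profile$k, profile$C_C)),
    cek = suppressWarnings(loglog_slope(profile$k, profile$C_E)))
  fits
}

#' Classify a network from its six power-law fits
#'
#' Hierarchy: `weak` when the `C(k)` exponent is decaying with magnitude
#' below 1 and the `C_N(k)` exponent is growing with magnitude at most 0.5;
#' `strong` when `C(k)` decays with magnitude at least 1; `none` otherwise.
#' Mixing follows the sign of the `C_N(k)` exponent (growing = assortative,
#' decaying = disassortative, flat = neutral). The scale-free call is the
#' Clauset bootstrap decision on the degree distribution: plausible when the
#' bootstrap p exceeds 0.1 (and, when recorded, the KS distance is at most
#' 0.35).
#'
#' @param fits named list as returned by [fit_topology()], or any list with
#'   elements `ck`, `cnk` (powerlaw_fit) and optionally `degree_clauset`.
#' @return A `network_classification` list: `scale_free` (logical or NA),
#'   `hierarchy`, `mixing`, and a human-readable `trace`.
#' @export
classify_network <- function(fits) {
  ck <- fits$ck; cnk <- fits$cnk
  if (is.null(ck) || is.null(cnk)) stop("fits must include ck and cnk")
  trace <- character(0)
  hierarchy <- "none"
  if (ck$sign == "decaying" && ck$exponent >= 1) {
    hierarchy <- "strong"
    trace <- c(trace, sprintf("C(k) decays with |beta| = %.3f >= 1", ck$exponent))
  } else if (ck$sign == "decaying" && ck$exponent < 1 &&
             cnk$sign == "growing" && cnk$exponent <= 0.5 && cnk$exponent > 0) {
    hierarchy <- "weak"
    trace <- c(trace, sprintf(
      "C(k) decays with |beta| = %.3f < 1 and C_N(k) grows with phi = %.3f in (0, 0.5]",
      ck$exponent, cnk$exponent))
  } else {
    trace <- c(trace, "C(k)/C_N(k) exponents outside hierarchical bounds")
  }
  mixing <- switch(cnk$sign, growing = "assortative",
                   decaying = "disassortative", "neutral")
  trace <- c(trace, sprintf("C_N(k) %s => %s mixing", cnk$sign, mixing))
  scale_free <- NA
  if (!is.null(fits$degree_clauset) && !is.na(fits$degree_clauset$boot_p)) {
    dc <- fits$degree_clauset
    scale_free <- dc$boot_p > 0.1 && (is.na(dc$ks_D) || dc$ks_D <= 0.35)
    trace <- c(trace, sprintf(
      "degree distribution: boot p = %.3f (> 0.1 required), KS D = %.3f (<= 0.35 required) => scale_free = %s",
      dc$boot_p, dc$ks_D, scale_free))
  } else {
    trace <- c(trace, "no bootstrap fit of the degree distribution supplied")
  }
  structure(list(scale_free = scale_free, hierarchy = hierarchy,
                 mixing = mixing, trace = trace),
            class = "network_classification")
}

#' @export
print.network_classification <- function(x, ...) {
  cat(sprintf("network classification: scale_free = %s, hierarchy = %s, mixing = %s\n",
              x$scale_free, x$hierarchy, x$mixing))
  for (t in x$trace) cat(" -", t, "\n")
  invisible(x)
}
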