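test_that("continuous MLE matches the closed form", {
  f <- fit_clauset(c(1, exp(1)), xmin = 1)
  expect_equal(f$exponent, 3.0, tolerance = 1e-12) # 1 + 2/1
  set.seed(61)
  x <- sample_powerlaw(200, 2.2, 1.5)
  f2 <- fit_clauset(x, discrete = FALSE, xmin = 1.5)
  expect_equal(f2$exponent, 1 + length(x) / sum(log(x / 1.5)),
               tolerance = 1e-12)
})

test_that("discrete MLE agrees with a brute-force grid search", {
  x <- sample_powerlaw(500, 2.5, 1, discrete = TRUE, seed = 63)
  f <- fit_clauset(x, discrete = TRUE, xmin = 1)
  grid <- seq(1.01, 5, by = 1e-3)
  nll <- vapply(grid, function(a)
    length(x) * log(keyregnet:::cpp_hurwitz_zeta(a, 1)) + a * sum(log(x)), 0)
  expect_equal(f$exponent, grid[which.min(nll)], tolerance = 1e-3)
})

test_that("Hurwitz zeta agrees with direct summation", {
  for (s in c(1.5, 2.5, 4)) for (q in c(1, 2, 7)) {
    direct <- sum((q:(q + 2e5))^(-s)) +
      (q + 2e5 + 0.5)^(1 - s) / (s - 1) # crude tail closure
    expect_equal(keyregnet:::cpp_hurwitz_zeta(s, q), direct,
                 tolerance = 1e-6)
  }
})

test_that("exponent is recovered on discrete synthetic draws", {
  x <- sample_powerlaw(5000, 2.5, 1, discrete = TRUE, seed = 65)
  f <- fit_clauset(x, discrete = TRUE)
  expect_lt(abs(f$exponent - 2.5), 0.1)
  expect_lte(f$xmin, 3)
  expect_equal(f$n_tail, sum(x >= f$xmin))
})

test_that("bootstrap p is seed-reproducible and seed-stable", {
  x <- sample_powerlaw(2000, 2.5, 1, discrete = TRUE, seed = 67)
  f1 <- fit_clauset(x, discrete = TRUE, n_boot = 2500, seed = 7)
  f2 <- fit_clauset(x, discrete = TRUE, n_boot = 2500, seed = 7)
  expect_identical(f1$boot_p, f2$boot_p)
  f3 <- fit_clauset(x, discrete = TRUE, n_boot = 2500, seed = 8)
  expect_lt(abs(f1$boot_p - f3$boot_p), 0.03)
})

test_that("goodness-of-fit p is roughly uniform under the fitted model", {
  ps <- vapply(1:20, function(s) {
    x <- sample_powerlaw(1000, 2.5, 1, discrete = TRUE, seed = 500 + s)
    fit_clauset(x, discrete = TRUE, n_boot = 200, seed = 600 + s)$boot_p
  }, 0)
  expect_gte(sum(ps > 0.1), 15)
})

test_that("degenerate inputs error", {
  expect_error(fit_clauset(rep(2, 50), discrete = TRUE, xmin = 2),
               "log-spread|tail")
  expect_error(fit_clauset(c(1, 2, 3)), "at least 10")
  expect_error(fit_clauset(c(-1, rep(2, 20))), "positive")
})

test_that("log-log OLS recovers exact and noisy slopes", {
  x <- c(1, 2, 4, 8)
  f <- loglog_slope(x, x^-0.5)
  expect_equal(f$slope, -0.5, tolerance = 1e-12)
  expect_equal(f$exponent, 0.5, tolerance = 1e-12)
  expect_equal(f$sign, "decaying")
  expect_equal(f$r_squared, 1, tolerance = 1e-12)

  fc <- loglog_slope(1:10, rep(3, 10))
  expect_lt(abs(fc$slope), 1e-12)

  set.seed(71)
  xx <- 1:40
  yy <- 2 * xx^1.008 * exp(rnorm(40, 0, 0.01))
  fn <- loglog_slope(xx, yy)
  expect_lt(abs(fn$slope - 1.008), 0.05)
  expect_equal(fn$sign, "growing")

  expect_warning(fz <- loglog_slope(c(1, 2, 3, 4), c(1, 0, 2, 3)), "bin")
  expect_equal(fz$n_tail, 3)
  expect_error(suppressWarnings(loglog_slope(c(1, 2), c(1, 1))), "3 usable")
})

mkfit <- function(exponent, sign) {
  structure(list(exponent = exponent, sign = sign, xmin = 1,
                 ks_D = NA_real_, boot_p = NA_real_, n_tail = 10,
                 method = "loglog_ols"),
            class = "powerlaw_fit")
}

test_that("exponent signs drive the weak/strong hierarchy and mixing calls", {
  fits <- list(pk = mkfit(0.294, "decaying"), ck = mkfit(0.165, "decaying"),
               cnk = mkfit(0.122, "growing"), cbk = mkfit(0.302, "growing"),
               cck = mkfit(0.095, "growing"), cek = mkfit(1.008, "growing"))
  cl <- classify_network(fits)
  expect_equal(cl$hierarchy, "weak")
  expect_equal(cl$mixing, "assortative")

  fits$ck <- mkfit(1.2, "decaying")
  expect_equal(classify_network(fits)$hierarchy, "strong")

  fits$ck <- mkfit(0.165, "decaying")
  fits$cnk <- mkfit(0.3, "decaying")
  cl3 <- classify_network(fits)
  expect_equal(cl3$mixing, "disassortative")
  expect_equal(cl3$hierarchy, "none")
})

test_that("the scale-free call follows the bootstrap decision thresholds", {
  base <- list(pk = mkfit(0.3, "decaying"), ck = mkfit(0.2, "decaying"),
               cnk = mkfit(0.1, "growing"))
  dc <- structure(list(exponent = 2.4, sign = "decaying", xmin = 1,
                       ks_D = 0.02, boot_p = 0.4, n_tail = 100,
                       method = "clauset_mle"), class = "powerlaw_fit")
  cl <- classify_network(c(base, list(degree_clauset = dc)))
  expect_true(cl$scale_free)
  dc$boot_p <- 0.05
  expect_false(classify_network(c(base, list(degree_clauset = dc)))$scale_free)
  dc$boot_p <- 0.4; dc$ks_D <- 0.5
  expect_false(classify_network(c(base, list(degree_clauset = dc)))$scale_free)
  expect_true(is.na(classify_network(base)$scale_free))
})
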