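test_that("log2 fold change is the difference of group means on log2 scale", {
  ex <- toy_expression(case_mean = c(8, 5), ctrl_mean = c(6, 5))
  lfc <- log2_fold_change(ex)
  expect_equal(unname(lfc["g1"]), 2.0)
  expect_equal(unname(lfc["g2"]), 0.0)
})

test_that("linear-scale input reduces to the log2 ratio of values", {
  vals <- matrix(c(50, 200), 1, 2,
                 dimnames = list("g1", c("s1", "s2")))
  ex <- expression_matrix(vals, c("control", "case"), scale = "linear",
                          pseudocount = 0)
  expect_equal(unname(log2_fold_change(ex)), log2(200 / 50))
})

test_that("expression matrix validates groups and drops incomplete genes", {
  vals <- matrix(rnorm(6), 2, 3,
                 dimnames = list(c("a", "b"), c("s1", "s2", "s3")))
  expect_error(expression_matrix(vals, c("control", "control", "control")),
               "empty group")
  expect_error(expression_matrix(vals, c("control", "case")), "one entry")
  vals[1, 2] <- NA
  expect_warning(ex <- expression_matrix(vals, c("control", "case", "case")),
                 "missing")
  expect_equal(rownames(ex$values), "b")
})

test_that("ordinary test equals the pooled-variance t-test oracle", {
  set.seed(11)
  ex <- toy_expression(case_mean = rnorm(30, 7), ctrl_mean = rnorm(30, 7),
                       n_per_group = 4, sd = 0.5, seed = 12)
  res <- moderated_t(ex, test = "ordinary")
  for (i in seq_len(nrow(res))) {
    g <- res$gene[i]
    ora <- pooled_t_oracle(ex$values[g, ex$groups == "control"],
                           ex$values[g, ex$groups == "case"])
    expect_equal(res$t[i], ora$t, tolerance = 1e-12)
    expect_equal(res$p[i], ora$p, tolerance = 1e-12)
  }
})

test_that("hand-computed two-sample case: control (1,2,3) vs case (4,5,6)", {
  vals <- rbind(g1 = c(1, 2, 3, 4, 5, 6),
                g2 = c(2, 3, 4, 3, 4, 5)) # filler so variance prior exists
  colnames(vals) <- sprintf("s%d", 1:6)
  ex <- expression_matrix(vals, rep(c("control", "case"), each = 3))
  res <- moderated_t(ex, test = "ordinary")
  expect_equal(res$t[1], 3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_lt(res$p[1], 0.05)
})

test_that("a gene with identical case and control vectors gives t = 0, p = 1", {
  set.seed(3)
  vals <- matrix(rnorm(40 * 6, 7, 0.4), 40, 6,
                 dimnames = list(sprintf("g%d", 1:40), sprintf("s%d", 1:6)))
  vals[1, ] <- rep(c(5, 6, 7), 2)
  ex <- expression_matrix(vals, rep(c("control", "case"), each = 3))
  res <- moderated_t(ex)
  expect_equal(res$t[1], 0)
  expect_equal(res$p[1], 1)
})

test_that("moderated t matches the limma empirical-Bayes pipeline", {
  skip_if_not_installed("limma")
  set.seed(21)
  n <- 300
  ex <- toy_expression(case_mean = rnorm(n, 7, 1), ctrl_mean = rnorm(n, 7, 1),
                       n_per_group = 4, sd = 0.4, seed = 22)
  res <- moderated_t(ex)
  design <- cbind(1, ex$groups == "case")
  fit <- limma::eBayes(limma::lmFit(ex$values, design))
  # same moment-matching idea, slightly different finite-sample estimator of
  # the prior df inside limma: agreement to ~1%, not bit-compatibility
  expect_equal(res$t, unname(fit$t[, 2]), tolerance = 1e-2)
  expect_equal(attr(res, "d0"), unname(fit$df.prior), tolerance = 5e-2)
})

test_that("degenerate all-zero variance errors", {
  vals <- matrix(1, 5, 4, dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  ex <- expression_matrix(vals, c("control", "control", "case", "case"))
  expect_error(moderated_t(ex), "degenerate variance")
})

test_that("BH adjustment matches the step-up ladder oracle", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  set.seed(5)
  for (rep in 1:20) {
    p <- runif(sample(1:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-15)
    expect_true(all(adj >= p))                    # BH can only raise
    expect_true(all(diff(adj[order(p)]) >= -1e-15)) # monotone in ranks
  }
  expect_equal(bh_adjust(rep(0.2, 6)), rep(0.2, 6)) # constant ladder fixed point
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(-0.1)), "\\[0, 1\\]")
})

test_that("DEG filtering applies the >=, <, <= threshold strictness", {
  out <- filter_degs(toy_deg_table())
  expect_equal(nrow(out), 2)
  expect_equal(out$gene, c("g1", "g2"))
  expect_equal(unname(attr(out, "counts")), c(1, 1))
  expect_equal(out$direction, c("up", "down"))
  # boundary semantics: lfc exactly at threshold passes, p exactly at
  # threshold fails, padj exactly at threshold passes
  rec <- data.frame(gene = "x", log2fc = 1.0, p = 0.05, padj = 0.05)
  expect_equal(nrow(filter_degs(rec)), 0)
  rec$p <- 0.049
  expect_equal(nrow(filter_degs(rec)), 1)
})

test_that("DEG filtering is permutation-invariant and handles empty input", {
  tab <- toy_deg_table()
  set.seed(9)
  shuffled <- tab[sample(nrow(tab)), ]
  a <- filter_degs(tab); b <- filter_degs(shuffled)
  expect_setequal(a$gene, b$gene)
  expect_equal(attr(a, "counts"), attr(b, "counts"))
  empty <- filter_degs(tab[0, ])
  expect_equal(nrow(empty), 0)
  expect_equal(unname(attr(empty, "counts")), c(0L, 0L))
})

test_that("planted strong effects are recovered with few false positives", {
  # variance prior df = 20 keeps gene sigmas near 0.3, the regime in which
  # a 2-unit log2 effect at n = 10/group is fully detectable
  for (seed in c(101, 102, 103)) {
    sim <- gen_expression(n_genes = 500, n_per_group = 10, n_deg = 50,
                          effect_lfc = 2, var_prior_df = 20, seed = seed)
    res <- screen_degs(sim$matrix)
    called <- res$gene[res$direction != "none"]
    planted <- sim$truth$gene[sim$truth$is_deg]
    expect_true(all(planted %in% called))
    null_pass <- length(setdiff(called, planted))
    expect_lte(null_pass, 0.05 * (500 - 50) + 5)
  }
})
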