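test_that("a complete matrix passes through MinProb untouched", {
  qm <- two_group_matrix(rep(20, 10), rep(20, 10), seed = 2)
  expect_identical(minprob_impute(qm, seed = 1), qm)
})

test_that("MinProb is deterministic under seed and leaves observed cells", {
  qm <- two_group_matrix(rep(20, 30), rep(20, 30), seed = 3)
  qm$values[cbind(sample(30, 12), sample(6, 12, replace = TRUE))] <- NA
  i1 <- minprob_impute(qm, seed = 7)
  i2 <- minprob_impute(qm, seed = 7)
  expect_identical(i1, i2)
  obs <- !is.na(qm$values)
  expect_identical(i1$values[obs], qm$values[obs])
  expect_false(anyNA(i1$values))
  i3 <- minprob_impute(qm, seed = 8)
  expect_false(identical(i1$values, i3$values))
})

test_that("imputed values land in the low tail of the observed distribution", {
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    vals <- matrix(rnorm(600, 20, 1), 100, 6,
                   dimnames = list(sprintf("P%03d", 1:100),
                                   c(paste0("a_", 1:3), paste0("b_", 1:3))))
    miss <- matrix(runif(600) < 0.3, 100, 6)
    # keep >= 3 observed per sample
    vals[miss] <- NA
    qm <- qm_fixture(vals)
    imp <- minprob_impute(qm, seed = s)
    mean(imp$values[miss]) <
      quantile(vals[!miss], 0.1, names = FALSE)
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("samples with under three observations are refused by name", {
  vals <- matrix(rnorm(12, 20), 4, 3,
                 dimnames = list(paste0("P", 1:4),
                                 c("a_1", "a_2", "b_1")))
  vals[1:2, 2] <- NA
  qm <- quant_matrix(vals, design_from_names(colnames(vals)))
  expect_error(minprob_impute(qm, seed = 1), "a_2")
})

test_that("identical group means give t = 0, p = 1", {
  vals <- matrix(c(1, 2, 3, 1, 2, 3,
                   5, 6, 7, 5, 6, 7), 2, 6, byrow = TRUE,
                 dimnames = list(c("P1", "P2"),
                                 c(paste0("a_", 1:3), paste0("b_", 1:3))))
  res <- moderated_t_test(qm_fixture(vals), "a", "b")
  expect_equal(res$t, c(0, 0))
  expect_equal(res$p, c(1, 1))
  expect_equal(res$log2fc, c(0, 0))
})

test_that("with a zero prior the moderated t equals the classical t-test", {
  set.seed(9)
  qm <- two_group_matrix(rnorm(50, 20, 2), rnorm(50, 20, 2), sd = 0.5,
                         seed = 9)
  res <- moderated_t_test(qm, "a", "b", d0 = 0, s02 = 1)
  p_classic <- vapply(seq_len(50), function(i)
    stats::t.test(qm$values[i, 1:3], qm$values[i, 4:6],
                  var.equal = TRUE)$p.value, 0)
  expect_equal(res$p, p_classic, tolerance = 1e-10)
})

test_that("moderated t is calibrated on pure-null data", {
  set.seed(101)
  vals <- matrix(rnorm(6000), 1000, 6,
                 dimnames = list(sprintf("P%04d", 1:1000),
                                 c(paste0("a_", 1:3), paste0("b_", 1:3))))
  res <- moderated_t_test(qm_fixture(vals), "a", "b")
  frac <- mean(res$p < 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("the estimated prior agrees with the limma empirical-Bayes fit", {
  skip_if_not_installed("limma")
  set.seed(33)
  vals <- matrix(rnorm(1200, 20, sqrt(rchisq(200, 3))), 200, 6,
                 dimnames = list(sprintf("P%03d", 1:200),
                                 c(paste0("a_", 1:3), paste0("b_", 1:3))))
  qm <- qm_fixture(vals)
  res <- moderated_t_test(qm, "a", "b")
  fit <- limma::lmFit(vals, stats::model.matrix(
    ~ rep(c(1, 0), each = 3)))
  fit <- limma::eBayes(fit)
  expect_equal(attr(res, "d0"), fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(res, "s02"), fit$s2.prior, tolerance = 1e-6)
  expect_equal(res$p, fit$p.value[, 2], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("p-values are shift-invariant; swapping groups negates the FC", {
  qm <- two_group_matrix(rnorm(40, 21, 1), rnorm(40, 20, 1), seed = 12)
  res <- moderated_t_test(qm, "a", "b")
  shifted <- qm
  shifted$values <- shifted$values + 3.7
  res_s <- moderated_t_test(shifted, "a", "b")
  expect_equal(res$p, res_s$p)
  res_swap <- moderated_t_test(qm, "b", "a")
  expect_equal(res_swap$p, res$p)
  expect_equal(res_swap$log2fc, -res$log2fc)
})

test_that("BH adjustment matches hand-derived and brute-force step-up values", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(0.005, 0.01, 0.03, 0.04)),
               c(0.02, 0.02, 0.04, 0.04))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(6)
  grid <- seq(0.01, 1, by = 0.01)
  for (i in 1:200) {
    p <- sample(grid, sample(1:6, 1), replace = TRUE)
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("a complete matrix makes every stability iteration identical", {
  qm <- two_group_matrix(c(rep(24, 5), rep(20, 45)), rep(20, 50),
                         sd = 0.3, seed = 15)
  res <- stability_dea(qm, "a", "b", n_iter = 5, seed = 1)
  expect_true(all(res$stability_fraction %in% c(0, 1)))
  # equals a single-pass analysis
  single <- moderated_t_test(qm, "a", "b")
  single$p_adj <- bh_adjust(single$p)
  pass <- single$p_adj < 0.05 & abs(single$log2fc) > log2(1.5)
  expect_equal(res$stability_fraction, as.numeric(pass))
  expect_equal(res$median_log2fc, single$log2fc)
})

test_that("stability analysis is reproducible and respects the row filter", {
  qm <- two_group_matrix(rnorm(40, 21), rnorm(40, 20), seed = 18)
  qm$values[1, 1:6] <- c(NA, 20, 21, NA, 20, 21)  # no complete condition
  qm$values[2, 4] <- NA                           # complete in condition a
  r1 <- stability_dea(qm, "a", "b", n_iter = 20, seed = 5)
  r2 <- stability_dea(qm, "a", "b", n_iter = 20, seed = 5)
  expect_identical(r1, r2)
  expect_false("P001" %in% r1$id)
  expect_true("P002" %in% r1$id)
  expect_error(stability_dea(qm, "a", "b", n_iter = 0), "n_iter")
})

test_that("the flagged set shrinks as the stability threshold rises", {
  set.seed(44)
  qm <- two_group_matrix(c(rnorm(10, 23), rnorm(90, 20)),
                         rnorm(100, 20), sd = 0.5, seed = 44)
  qm$values[matrix(runif(600) < 0.15, 100, 6) & qm$values < 20] <- NA
  res20 <- stability_dea(qm, "a", "b", n_iter = 50, stability = 0.2,
                         seed = 9)
  res80 <- stability_dea(qm, "a", "b", n_iter = 50, stability = 0.8,
                         seed = 9)
  res95 <- stability_dea(qm, "a", "b", n_iter = 50, stability = 0.95,
                         seed = 9)
  expect_true(all(res80$id[res80$significant] %in%
                    res20$id[res20$significant]))
  expect_true(all(res95$id[res95$significant] %in%
                    res80$id[res80$significant]))
})

test_that("the IQR outlier test returns only sign-inverting outliers", {
  flat <- setNames(rep(0, 9), paste0("P", 1:9))
  expect_equal(nrow(iqr_outlier_test(flat, flat)), 0L)

  fwd <- setNames(c(rep(0, 20), 5), c(paste0("P", 1:20), "HIT"))
  rev <- setNames(c(rep(0, 20), -5), c(paste0("P", 1:20), "HIT"))
  res <- iqr_outlier_test(fwd, rev)
  expect_equal(res$id, "HIT")
  expect_equal(res$direction, "up")

  # exceeding the threshold in one run only is not significant
  rev_null <- setNames(rep(0, 21), names(rev))
  expect_equal(nrow(iqr_outlier_test(fwd, rev_null)), 0L)

  # down-regulation is the mirror image
  res_dn <- iqr_outlier_test(-fwd, -rev)
  expect_equal(res_dn$id, "HIT")
  expect_equal(res_dn$direction, "down")

  # unpaired proteins are excluded but tallied
  fwd2 <- c(fwd, LONELY = 9)
  res2 <- iqr_outlier_test(fwd2, rev)
  expect_equal(res2$id, "HIT")
  expect_equal(attr(res2, "n_unpaired"), 1L)
})
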