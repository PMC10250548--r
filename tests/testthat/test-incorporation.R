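test_that("co-occurring modification states are summed per replicate", {
  pep <- pep_table(
    pep_row("ATK", "Thr->bES", c(mix_1 = 3, mix_2 = 4, mix_3 = 5)),
    pep_row("ATK", "Acetyl (Protein N-term),Thr->bES",
            c(mix_1 = 7, mix_2 = NA, mix_3 = 1)),
    pep_row("ATK", "Thr->Thr5", c(mix_1 = 40, mix_2 = 40, mix_3 = 40)),
    pep_row("ATK", "Unmodified", c(mix_1 = 20, mix_2 = 20, mix_3 = 20)))
  mset <- select_matched_peptides(pep)
  expect_equal(mset$groups$bES["ATK", ], c(mix_1 = 10, mix_2 = 4, mix_3 = 6))
  expect_equal(unname(mset$provenance$bES["ATK"]), 2L)
  expect_equal(mset$intersection, "ATK")
})

test_that("multi-threonine and threonine-free peptides are excluded", {
  pep <- pep_table(
    pep_row("ATTK", "Thr->bES", c(mix_1 = 3, mix_2 = 4)),
    pep_row("AGGK", "Unmodified", c(mix_1 = 3, mix_2 = 4)),
    pep_row("ATK", "Thr->bES", c(mix_1 = 3, mix_2 = 4)))
  mset <- select_matched_peptides(pep)
  expect_equal(rownames(mset$groups$bES), "ATK")
  expect_equal(nrow(mset$groups$Thr0), 0L)
})

test_that("the >=2-replicate rule gates group membership", {
  pep <- pep_table(
    pep_row("ATK", "Thr->bES", c(mix_1 = 3, mix_2 = NA, mix_3 = NA)),
    pep_row("GTK", "Thr->bES", c(mix_1 = 3, mix_2 = 4, mix_3 = NA)))
  mset <- select_matched_peptides(pep)
  expect_equal(rownames(mset$groups$bES), "GTK")
  one_rep <- pep_table(pep_row("ATK", "Thr->bES", c(mix_1 = 3)))
  expect_error(select_matched_peptides(one_rep), ">= 2 replicates")
})

test_that("the three-group intersection is enumerated correctly", {
  # 10 peptides; exactly 4 present (>=2 reps) in all three groups
  mk <- function(s, groups) {
    do.call(rbind, lapply(groups, function(g)
      pep_row(s, c(Thr0 = "Unmodified", Thr5 = "Thr->Thr5",
                   bES = "Thr->bES")[[g]],
              c(mix_1 = 10, mix_2 = 12, mix_3 = NA))))
  }
  all3 <- c("ATKA", "CTKC", "DTKD", "ETKE")
  pep <- do.call(rbind, c(
    lapply(all3, mk, groups = c("Thr0", "Thr5", "bES")),
    lapply(c("FTKF", "GTKG", "HTKH"), mk, groups = c("Thr0", "Thr5")),
    lapply(c("ITKI", "KTKA"), mk, groups = "bES"),
    list(mk("LTKL", "Thr5"))))
  attr(pep, "samples") <- c("mix_1", "mix_2", "mix_3")
  mset <- select_matched_peptides(pep)
  expect_setequal(mset$intersection, all3)
})

test_that("a single clean pair gives the analytic f and one-in-N", {
  pep <- pep_table(
    pep_row("ATK", "Thr->bES", c(mix_1 = 1, mix_2 = 1, mix_3 = 1)),
    pep_row("ATK", "Thr->Thr5", c(mix_1 = 39, mix_2 = 39, mix_3 = 39)),
    pep_row("ATK", "Unmodified", c(mix_1 = 5, mix_2 = 5, mix_3 = 5)))
  est <- estimate_incorporation(select_matched_peptides(pep), seed = 1)
  expect_equal(est$f, 0.025)
  expect_equal(est$one_in_n, 40)
  expect_equal(est$n_peptides, 1L)
})

test_that("f and N are invariant to a global intensity rescaling", {
  base <- pep_table(
    pep_row("ATK", "Thr->bES", c(mix_1 = 1, mix_2 = 1.2, mix_3 = 0.9)),
    pep_row("ATK", "Thr->Thr5", c(mix_1 = 39, mix_2 = 41, mix_3 = 38)),
    pep_row("ATK", "Unmodified", c(mix_1 = 5, mix_2 = 5, mix_3 = 5)),
    pep_row("GTK", "Thr->bES", c(mix_1 = 2, mix_2 = 2, mix_3 = 2)),
    pep_row("GTK", "Thr->Thr5", c(mix_1 = 78, mix_2 = 78, mix_3 = 78)),
    pep_row("GTK", "Unmodified", c(mix_1 = 9, mix_2 = 9, mix_3 = 9)))
  scaled <- base
  for (col in grep("^Intensity ", names(scaled), value = TRUE))
    scaled[[col]] <- scaled[[col]] * 1e3
  attr(scaled, "samples") <- attr(base, "samples")
  e1 <- estimate_incorporation(select_matched_peptides(base), seed = 1)
  e2 <- estimate_incorporation(select_matched_peptides(scaled), seed = 1)
  expect_equal(e1$f, e2$f)
  expect_equal(e1$one_in_n, e2$one_in_n)
})

test_that("swapping analog and heavy labels maps f to 1 - f", {
  cfg <- sim_config(n_proteins = 80, peptides_per_protein = c(1, 1),
                    incorporation_p = 0.1, missing_curve = NULL,
                    multi_thr_fraction = 0, thr_free_fraction = 0,
                    seed = 17)
  sim <- simulate_incorporation_dataset(cfg)
  f_fwd <- estimate_incorporation(
    select_matched_peptides(sim$peptides), seed = 1)$f
  f_swp <- estimate_incorporation(
    select_matched_peptides(sim$peptides, thr5_tag = "Thr->bES",
                            bes_tag = "Thr->Thr5"), seed = 1)$f
  expect_equal(f_swp, 1 - f_fwd, tolerance = 1e-10)
})

test_that("an empty intersection is an explicit error, not N = Inf", {
  pep <- pep_table(
    pep_row("ATK", "Thr->bES", c(mix_1 = 3, mix_2 = 4)),
    pep_row("GTK", "Thr->Thr5", c(mix_1 = 3, mix_2 = 4)))
  expect_error(estimate_incorporation(select_matched_peptides(pep)),
               "no matched peptides")
})

test_that("the estimator recovers the true substitution probability", {
  for (p_true in c(0.01, 0.025, 0.1)) {
    f_hat <- vapply(1:20, function(s) {
      cfg <- sim_config(n_proteins = 150, peptides_per_protein = c(1, 1),
                        incorporation_p = p_true, replicate_cv = 0.2,
                        missing_curve = NULL, multi_thr_fraction = 0,
                        thr_free_fraction = 0, seed = 1000 + s)
      sim <- simulate_incorporation_dataset(cfg)
      estimate_incorporation(select_matched_peptides(sim$peptides),
                             seed = s)$f
    }, 0)
    expect_lt(abs(mean(f_hat) - p_true) / p_true, 0.10)
  }
})

test_that("with left-censoring the incorporation estimate is biased upward", {
  # censoring removes mostly low analog intensities; imputation pulls
  # them back near the detection floor, which sits above the smallest
  # true analog signals, so f is overestimated. The direction is
  # documented here, not hidden.
  f_hat <- vapply(1:10, function(s) {
    cfg <- sim_config(n_proteins = 150, peptides_per_protein = c(1, 1),
                      incorporation_p = 0.025, replicate_cv = 0.2,
                      base_log2_mu = 23, base_log2_sigma = 1.5,
                      missing_curve = c(midpoint = 18.5, slope = 1.2),
                      multi_thr_fraction = 0, thr_free_fraction = 0,
                      seed = 2000 + s)
    sim <- simulate_incorporation_dataset(cfg)
    estimate_incorporation(select_matched_peptides(sim$peptides),
                           seed = s)$f
  }, 0)
  expect_gt(mean(f_hat), 0.025)
})

test_that("labeling efficiency is a guarded one-decimal percentage", {
  expect_equal(labeling_efficiency(142, 10000), 1.4)
  expect_equal(labeling_efficiency(0, 10), 0)
  expect_equal(labeling_efficiency(7, 200), 3.5)
  expect_error(labeling_efficiency(1, 0), "n_total")
  expect_error(labeling_efficiency(5, 3), "n_modified")
})
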