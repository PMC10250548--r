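#' Configuration for the synthetic-data generators
#'
#' Bundles and validates the knobs shared by the three simulators. The
#' defaults describe a typical label-free LC-MS/MS experiment: log-normal
#' protein abundances spanning several orders of magnitude, three
#' biological replicates with ~20% coefficient of variation, and
#' intensity-dependent left-censoring following a logistic detection
#' curve (the standard surrogate for the instrument detection limit).
#'
#' @param n_proteins number of simulated proteins.
#' @param peptides_per_protein integer range `c(lo, hi)`; each protein
#'   contributes a uniform number of peptides in this range.
#' @param incorporation_p true per-threonine analog substitution
#'   probability, in (0, 1). The default 1/40 reflects the incorporation
#'   rate regime of an efficient threonine analog.
#' @param base_log2_mu,base_log2_sigma mean and s.d. of latent log2
#'   abundances (log-normal intensities).
#' @param replicate_cv coefficient of variation of multiplicative
#'   replicate noise on the raw intensity scale.
#' @param n_replicates replicates per condition (or per time window).
#' @param nsp_fraction fraction of proteins that are true newly
#'   synthesized proteins in [simulate_nsp_experiment()].
#' @param background_fraction fraction of proteins that are background
#'   binders (equal expected intensity in treated and control).
#' @param nsp_log2fc enrichment of a true NSP over control, in log2
#'   units, for NSPs that are not structurally absent from the control.
#' @param nsp_absent_fraction fraction of true NSPs fully absent from the
#'   control condition (structural missingness, not censoring).
#' @param de_effects optional data frame with columns `n`, `log2fc` for
#'   spiked differential effects in [simulate_timecourse()] designs.
#' @param missing_curve `c(midpoint, slope)` of the logistic detection
#'   model: a cell with latent log2 intensity x is *observed* with
#'   probability `plogis(slope * (x - midpoint))`. `NULL` disables
#'   censoring.
#' @param lys8_fraction probability that a simulated peptide carries the
#'   heavy-lysine label in the time-course peptide table.
#' @param thr0_level expected intensity of the unmodified-threonine form
#'   relative to the latent peptide abundance (pre-existing protein
#'   carried through the labeling window).
#' @param multi_thr_fraction,thr_free_fraction fractions of peptides with
#'   two threonines / no threonine, emitted to exercise the selection
#'   filters of [select_matched_peptides()].
#' @param extra_mod_fraction fraction of analog-form peptide rows split
#'   into two co-occurring modification states (e.g. with and without
#'   acetylation) to exercise intensity summation.
#' @param seed integer seed; a fixed seed gives byte-identical output.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 200,
                       peptides_per_protein = c(1L, 3L),
                       incorporation_p = 1 / 40,
                       base_log2_mu = 23, base_log2_sigma = 2,
                       replicate_cv = 0.2,
                       n_replicates = 3L,
                       nsp_fraction = 0.2,
                       background_fraction = 0.3,
                       nsp_log2fc = 5,
                       nsp_absent_fraction = 0.5,
                       de_effects = NULL,
                       missing_curve = c(midpoint = 16, slope = 1),
                       lys8_fraction = 0.95,
                       thr0_level = 0.5,
                       multi_thr_fraction = 0.1,
                       thr_free_fraction = 0.1,
                       extra_mod_fraction = 0.15,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot_cfg <- function(ok, msg)
    if (!isTRUE(ok)) stop("configuration error: ", msg, call. = FALSE)
  stopifnot_cfg(n_proteins >= 1, "n_proteins must be >= 1")
  stopifnot_cfg(length(peptides_per_protein) == 2 &&
                  all(peptides_per_protein >= 1) &&
                  peptides_per_protein[1] <= peptides_per_protein[2],
                "peptides_per_protein must be an increasing range >= 1")
  for (p in c("incorporation_p", "lys8_fraction", "nsp_fraction",
              "background_fraction", "nsp_absent_fraction",
              "multi_thr_fraction", "thr_free_fraction",
              "extra_mod_fraction"))
    stopifnot_cfg(cfg[[p]] >= 0 && cfg[[p]] <= 1,
                  paste(p, "must be in [0, 1]"))
  stopifnot_cfg(incorporation_p > 0 && incorporation_p < 1,
                "incorporation_p must be in (0, 1)")
  stopifnot_cfg(base_log2_sigma > 0, "base_log2_sigma must be > 0")
  stopifnot_cfg(replicate_cv >= 0, "replicate_cv must be >= 0")
  stopifnot_cfg(n_replicates >= 1, "n_replicates must be >= 1")
  stopifnot_cfg(is.null(missing_curve) || length(missing_curve) == 2,
                "missing_curve must be NULL or c(midpoint, slope)")
  stopifnot_cfg(nsp_fraction + background_fraction <= 1,
                "nsp_fraction + background_fraction must be <= 1")
  cfg$n_replicates <- as.integer(n_replicates)
  class(cfg) <- "sim_config"
  cfg
}

# log2-scale s.d. equivalent to a raw-scale CV under log-normal noise
cv_to_sdlog2 <- function(cv) sqrt(log(1 + cv^2)) / log(2)

# apply logistic left-censoring; returns values with NA where censored.
# When a collector environment is given, the latent values of censored
# and observed cells are appended to it (ground-truth bookkeeping).
censor_values <- function(log2_int, curve, collector = NULL) {
  present <- !is.na(log2_int)  # structurally absent cells stay absent
  if (is.null(curve)) {
    if (!is.null(collector))
      collector$observed <- c(collector$observed, log2_int[present])
    return(log2_int)
  }
  p_obs <- stats::plogis(curve[[2]] * (log2_int - curve[[1]]))
  miss <- present & (stats::runif(length(log2_int)) > p_obs)
  if (!is.null(collector)) {
    collector$censored <- c(collector$censored, log2_int[miss])
    collector$observed <- c(collector$observed,
                            log2_int[present & !miss])
  }
  log2_int[miss] <- NA_real_
  log2_int
}

# random tryptic-looking peptide with exactly n_thr threonines
random_peptide <- function(n, n_thr) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "L", "M",
          "N", "P", "Q", "S", "V", "W", "Y")
  len <- sample(8:14, n, replace = TRUE)
  vapply(seq_len(n), function(i) {
    body <- sample(aa, len[i], replace = TRUE)
    if (n_thr[i] > 0) {
      pos <- sample(len[i], n_thr[i])
      body[pos] <- "T"
    }
    paste0(paste(body, collapse = ""), sample(c("K", "R"), 1))
  }, "")
}

#' Simulate a matched-pair incorporation-rate dataset
#'
#' Emulates the double-labeling experiment used to measure how often a
#' threonine analog replaces threonine: cells are grown with both the
#' analog (`bES`) and heavy threonine (`Thr5`), so every single-threonine
#' peptide with latent abundance A appears as a heavy form with expected
#' intensity A(1-p) and an analog form with expected intensity Ap, where
#' p is the per-threonine substitution probability. Unmodified (`Thr0`)
#' forms, multi-threonine and threonine-free peptides, co-occurring
#' modification states, replicate noise and logistic left-censoring are
#' added so every selection filter downstream is exercised.
#'
#' @param cfg a [sim_config()]; `n_proteins` and `peptides_per_protein`
#'   set the peptide count, `incorporation_p` the true p.
#' @return list with `peptides` (a table in the [read_peptide_table()]
#'   layout, one condition named `"mix"`), and `truth` (list with
#'   `incorporation_p`, per-peptide latent log2 abundance, and the
#'   peptide class: single/multi/free).
#' @export
simulate_incorporation_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    n_pep <- sum(sample(seq(cfg$peptides_per_protein[1],
                            cfg$peptides_per_protein[2]),
                        cfg$n_proteins, replace = TRUE))
    u <- stats::runif(n_pep)
    klass <- ifelse(u < cfg$multi_thr_fraction, "multi",
                    ifelse(u < cfg$multi_thr_fraction +
                             cfg$thr_free_fraction, "free", "single"))
    n_thr <- c(single = 1L, multi = 2L, free = 0L)[klass]
    seqs <- random_peptide(n_pep, n_thr)
    # a few collisions are possible; force uniqueness
    while (anyDuplicated(seqs)) {
      d <- duplicated(seqs)
      seqs[d] <- random_peptide(sum(d), n_thr[d])
    }
    prot <- paste0("PROT", rep(seq_len(cfg$n_proteins),
                               length.out = n_pep))
    a <- stats::rnorm(n_pep, cfg$base_log2_mu, cfg$base_log2_sigma)
    p <- cfg$incorporation_p
    reps <- seq_len(cfg$n_replicates)
    samples <- paste0("mix_", reps)
    sd2 <- cv_to_sdlog2(cfg$replicate_cv)

    rows <- list()
    emit <- function(i, mods, frac_log2) {
      ints <- a[i] + frac_log2 + stats::rnorm(length(reps), 0, sd2)
      ints <- censor_values(ints, cfg$missing_curve)
      row <- data.frame(Sequence = seqs[i], Modifications = mods,
                        Proteins = prot[i], Charge = 2L,
                        stringsAsFactors = FALSE)
      for (r in reps)
        row[[paste0("Intensity mix_", r)]] <- 2^ints[r]
      rows[[length(rows) + 1L]] <<- row
    }
    for (i in seq_len(n_pep)) {
      k <- n_thr[i]
      if (k == 0L) {
        emit(i, "Unmodified", 0)
        next
      }
      # heavy form: all k Thr sites heavy; analog form: >=1 site analog.
      # For k = 1 the expected split is exactly (1-p) vs p.
      emit(i, "Thr->Thr5", k * log2(1 - p))
      f_bes <- 1 - (1 - p)^k
      if (stats::runif(1) < cfg$extra_mod_fraction) {
        s <- stats::runif(1, 0.2, 0.8)
        emit(i, "Thr->bES", log2(f_bes * s))
        emit(i, "Acetyl (Protein N-term),Thr->bES", log2(f_bes * (1 - s)))
      } else {
        emit(i, "Thr->bES", log2(f_bes))
      }
      emit(i, "Unmodified", log2(cfg$thr0_level))
    }
    peptides <- do.call(rbind, rows)
    attr(peptides, "samples") <- samples
    list(peptides = peptides,
         truth = list(incorporation_p = p,
                      latent_log2 = stats::setNames(a, seqs),
                      peptide_class = stats::setNames(klass, seqs)))
  })
}

#' Simulate a nascent-proteome enrichment experiment
#'
#' Emulates an NSP pull-down with an untreated control: true NSPs are
#' abundant in the treated condition and absent or strongly depleted in
#' the control, background binders (non-specific bead/resin binders)
#' have equal expected intensity in both conditions, and the remaining
#' proteins appear only in the control. Left-censoring is applied on top
#' of the structural design.
#'
#' @param cfg a [sim_config()]; `nsp_fraction`, `background_fraction`,
#'   `nsp_log2fc` and `nsp_absent_fraction` shape the design.
#' @param treated,control condition labels used in the sample names.
#' @return list with `matrix` (a [quant_matrix()]) and `truth` (list
#'   with `nsp_ids`, `background_ids`, `control_only_ids`).
#' @export
simulate_nsp_experiment <- function(cfg = sim_config(),
                                    treated = "treated",
                                    control = "control") {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_proteins
    ids <- sprintf("PROT%04d", seq_len(n))
    n_nsp <- round(cfg$nsp_fraction * n)
    n_bg <- round(cfg$background_fraction * n)
    nsp_ids <- ids[seq_len(n_nsp)]
    bg_ids <- ids[n_nsp + seq_len(n_bg)]
    rest_ids <- setdiff(ids, c(nsp_ids, bg_ids))
    mu <- stats::rnorm(n, cfg$base_log2_mu, cfg$base_log2_sigma)
    names(mu) <- ids
    reps <- seq_len(cfg$n_replicates)
    sd2 <- cv_to_sdlog2(cfg$replicate_cv)
    samples <- c(paste0(treated, "_", reps), paste0(control, "_", reps))
    vals <- matrix(NA_real_, n, length(samples),
                   dimnames = list(ids, samples))
    tcol <- seq_along(reps)
    ccol <- length(reps) + seq_along(reps)
    absent <- stats::setNames(rep(FALSE, n), ids)
    absent[nsp_ids] <- stats::runif(n_nsp) < cfg$nsp_absent_fraction
    coll <- new.env()
    coll$censored <- numeric(0)
    coll$observed <- numeric(0)
    for (id in ids) {
      mt <- mu[id]          # treated mean
      mc <- mu[id]          # control mean
      if (id %in% nsp_ids) mc <- mu[id] - cfg$nsp_log2fc
      if (id %in% rest_ids) mt <- -Inf   # control-only protein
      if (absent[id]) mc <- -Inf
      vt <- if (is.finite(mt))
        mt + stats::rnorm(length(reps), 0, sd2) else rep(NA_real_, length(reps))
      vc <- if (is.finite(mc))
        mc + stats::rnorm(length(reps), 0, sd2) else rep(NA_real_, length(reps))
      vals[id, tcol] <- censor_values(vt, cfg$missing_curve, coll)
      vals[id, ccol] <- censor_values(vc, cfg$missing_curve, coll)
    }
    qm <- quant_matrix(vals, design_from_names(samples))
    list(matrix = qm,
         truth = list(nsp_ids = nsp_ids, background_ids = bg_ids,
                      control_only_ids = rest_ids,
                      absent_in_control = names(absent)[absent],
                      censored_latent = coll$censored,
                      observed_latent = coll$observed))
  })
}

#' Simulate a pulse-labeling time course
#'
#' Emulates a pulse-labeling design in which cells are exposed to the
#' analog plus heavy lysine during consecutive time windows after a
#' stimulus: each protein follows a per-window log2 mean profile, with
#' replicate noise and optional left-censoring; a companion peptide
#' table assigns each peptide the heavy-lysine label with probability
#' `lys8_fraction`, emulating the specificity of the enrichment.
#'
#' @param cfg a [sim_config()].
#' @param profiles numeric matrix protein x window of latent log2 means;
#'   an `NA` entry makes the protein structurally absent from that
#'   window. Rownames are protein ids; colnames the ordered window
#'   labels (first = steady state).
#' @param condition condition label used in sample names.
#' @param peptides_per_protein peptides per protein in the companion
#'   peptide table.
#' @return list with `matrix` (a [quant_matrix()] whose design carries
#'   the windows), `peptides` (companion table with `Lys8`/`Lys0`
#'   modification states), and `truth` (list with `profiles` and
#'   `lys8_labels`).
#' @export
simulate_timecourse <- function(cfg = sim_config(), profiles,
                                condition = "cells",
                                peptides_per_protein = 2L) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.matrix(profiles) || is.null(rownames(profiles)) ||
      is.null(colnames(profiles)))
    stop("`profiles` must be a protein x window matrix with dimnames")
  if (ncol(profiles) < 2) stop("need >= 2 time windows")
  with_seed(cfg$seed, {
    wins <- colnames(profiles)
    ids <- rownames(profiles)
    reps <- seq_len(cfg$n_replicates)
    sd2 <- cv_to_sdlog2(cfg$replicate_cv)
    samples <- as.vector(t(outer(wins, reps, function(w, r)
      paste0(condition, "@", w, "_", r))))
    vals <- matrix(NA_real_, length(ids), length(samples),
                   dimnames = list(ids, samples))
    for (i in seq_along(ids)) for (w in seq_along(wins)) {
      m <- profiles[i, w]
      if (is.na(m)) next
      v <- m + stats::rnorm(length(reps), 0, sd2)
      cols <- (w - 1L) * length(reps) + seq_along(reps)
      vals[i, cols] <- censor_values(v, cfg$missing_curve)
    }
    qm <- quant_matrix(vals, design_from_names(samples,
                                               window_levels = wins))
    n_pep <- length(ids) * peptides_per_protein
    seqs <- random_peptide(n_pep, rep(1L, n_pep))
    while (anyDuplicated(seqs))
      seqs[duplicated(seqs)] <- random_peptide(sum(duplicated(seqs)), 1L)
    heavy <- stats::runif(n_pep) < cfg$lys8_fraction
    peptides <- data.frame(
      Sequence = seqs,
      Modifications = ifelse(heavy, "Lys8", "Lys0"),
      Proteins = rep(ids, each = peptides_per_protein),
      Charge = 2L, stringsAsFactors = FALSE)
    base <- stats::rnorm(n_pep, cfg$base_log2_mu, cfg$base_log2_sigma)
    for (r in reps)
      peptides[[paste0("Intensity ", condition, "_", r)]] <-
        2^(base + stats::rnorm(n_pep, 0, sd2))
    attr(peptides, "samples") <- paste0(condition, "_", reps)
    list(matrix = qm, peptides = peptides,
         truth = list(profiles = profiles,
                      lys8_labels = stats::setNames(heavy, seqs)))
  })
}
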