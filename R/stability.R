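#' Left-censored (MinProb) imputation
#'
#' Missing LC-MS intensities are concentrated at low abundances because
#' of the detection limit (missing-not-at-random, left-censored).
#' MinProb imputes each missing cell of a sample with an independent
#' draw from a Gaussian centered at a low quantile of that sample's
#' observed log2 intensities, i.e. from the "minimum-probability" region
#' where censored values are expected to lie.
#'
#' The center is the `q`-quantile (default 0.01) of the sample's
#' observed values; the spread is `tune_sigma` times the median, over
#' rows, of the per-row observed standard deviation. Observed cells are
#' never touched.
#'
#' @param qm a [quant_matrix()].
#' @param q low quantile defining the censoring center, in (0, 0.5).
#' @param tune_sigma multiplier on the imputation s.d.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return a complete [quant_matrix()] (no `NA` cells).
#' @export
minprob_impute <- function(qm, q = 0.01, tune_sigma = 1.0, seed = NULL) {
  stopifnot(inherits(qm, "quant_matrix"))
  if (q <= 0 || q >= 0.5) stop("q must be in (0, 0.5)")
  if (tune_sigma <= 0) stop("tune_sigma must be > 0")
  vals <- qm$values
  n_obs <- colSums(!is.na(vals))
  if (any(n_obs < 3))
    stop("sample(s) with fewer than 3 observed values: ",
         paste(colnames(vals)[n_obs < 3], collapse = ", "))
  if (!anyNA(vals)) return(qm)
  row_sd <- apply(vals, 1L, stats::sd, na.rm = TRUE)
  sigma <- tune_sigma * stats::median(row_sd[!is.na(row_sd) & row_sd > 0])
  if (!is.finite(sigma) || sigma <= 0)
    stop("cannot derive an imputation s.d.: no row with >= 2 observed ",
         "values and positive spread")
  with_seed(seed, {
    for (j in seq_len(ncol(vals))) {
      miss <- which(is.na(vals[, j]))
      if (!length(miss)) next
      center <- stats::quantile(vals[, j], probs = q, na.rm = TRUE,
                                names = FALSE)
      vals[miss, j] <- stats::rnorm(length(miss), center, sigma)
    }
    quant_matrix(vals, qm$design)
  })
}

# Inverse of trigamma, by Newton iteration on 1/trigamma (limma-style
# parameterisation); used by the moment-matching prior estimator.
trigamma_inverse <- function(x) {
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-8) break
  }
  y
}

# Moment-matching estimate of the variance prior (d0, s0^2) from
# per-row sample variances s2 with df degrees of freedom each, via the
# distribution of log(s2): Var[log s2] = trigamma(df/2) + trigamma(d0/2),
# E[log s2] = log(s0^2) + digamma(df/2) - log(df/2)
#                       - digamma(d0/2) + log(d0/2).
estimate_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (!any(ok))
    stop("prior estimation error: zero variance in every row")
  z <- log(s2[ok])
  e_z <- mean(z)
  v_z <- if (sum(ok) > 1) stats::var(z) else 0
  resid_v <- v_z - trigamma(df / 2)
  if (is.na(resid_v) || resid_v <= 0) {
    d0 <- Inf
    s02 <- exp(e_z - digamma(df / 2) + log(df / 2))
  } else {
    d0 <- 2 * trigamma_inverse(resid_v)
    s02 <- exp(e_z - digamma(df / 2) + log(df / 2) +
                 digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s02 = s02)
}

#' Empirical-Bayes moderated two-sample t-test
#'
#' A two-sample equal-variance t-test whose per-row variance is shrunk
#' toward a prior estimated across all rows: the posterior variance is
#' `(d0*s0^2 + dg*sg^2) / (d0 + dg)` where `sg^2` is the row's pooled
#' sample variance with `dg` degrees of freedom, and the prior `(d0,
#' s0^2)` is obtained by moment-matching on the log sample variances.
#' The t-statistic is referred to a t distribution with `d0 + dg`
#' degrees of freedom (two-sided). With `d0 = 0` the test reduces
#' exactly to the classical equal-variance t-test.
#'
#' @param qm a complete [quant_matrix()] (no missing cells; impute
#'   first, e.g. with [minprob_impute()]).
#' @param group_a,group_b condition labels; `log2FC = mean_a - mean_b`.
#' @param d0,s02 optional fixed prior; both `NULL` (the default) means
#'   the prior is estimated from the data.
#' @return data frame with one row per protein: `id`, `log2fc`, `t`,
#'   `p`, `df`, plus the prior as attributes `d0` and `s02`.
#' @export
moderated_t_test <- function(qm, group_a, group_b,
                             d0 = NULL, s02 = NULL) {
  stopifnot(inherits(qm, "quant_matrix"))
  check_condition(qm, group_a)
  check_condition(qm, group_b)
  if (anyNA(qm$values))
    stop("matrix has missing cells; impute before testing")
  a <- qm$values[, sample_cols(qm, group_a), drop = FALSE]
  b <- qm$values[, sample_cols(qm, group_b), drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  if (na < 2 || nb < 2) stop("each group needs >= 2 replicates")
  dg <- na + nb - 2
  mean_a <- rowMeans(a); mean_b <- rowMeans(b)
  ss_a <- rowSums((a - mean_a)^2)
  ss_b <- rowSums((b - mean_b)^2)
  s2 <- (ss_a + ss_b) / dg
  if (is.null(d0) != is.null(s02))
    stop("supply both d0 and s02, or neither")
  if (is.null(d0)) {
    prior <- estimate_variance_prior(s2, dg)
    d0 <- prior$d0; s02 <- prior$s02
  }
  if (d0 < 0) stop("prior df d0 must be >= 0")
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2))
             else (d0 * s02 + dg * s2) / (d0 + dg)
  se <- sqrt(s2_post * (1 / na + 1 / nb))
  tt <- (mean_a - mean_b) / se
  df_total <- d0 + dg
  p <- 2 * stats::pt(abs(tt), df = df_total, lower.tail = FALSE)
  out <- data.frame(id = rownames(qm$values),
                    log2fc = mean_a - mean_b,
                    t = tt, p = p, df = df_total,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "d0") <- d0
  attr(out, "s02") <- s02
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjusted p-values with enforced
#' monotonicity, returned in the input order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Imputation-stability differential enrichment analysis
#'
#' Left-censored imputation injects randomness into every test, so a
#' single imputation round can flag proteins whose significance depends
#' on the imputed draws. This wrapper repeats the full pipeline —
#' MinProb imputation, moderated t-test, BH adjustment — `n_iter` times
#' with independent imputation substreams and calls a protein
#' differentially enriched only if it passes the significance criterion
#' (`p.adj < alpha` and fold change > `fc`) in more than `stability`
#' (default 80%) of the iterations.
#'
#' Only proteins detected in all replicates of at least one of the two
#' conditions are considered; the rest are dropped before testing.
#'
#' @param qm a [quant_matrix()] (may contain missing cells).
#' @param group_a,group_b condition labels.
#' @param n_iter number of imputation iterations (>= 1; 1000 mirrors a
#'   full analysis, smaller values are useful for exploration).
#' @param fc fold-change threshold on the raw scale (1.5 means
#'   |log2FC| > log2 1.5).
#' @param alpha significance level on BH-adjusted p-values.
#' @param stability required fraction of passing iterations, in (0, 1].
#' @param q,tune_sigma MinProb parameters, see [minprob_impute()].
#' @param seed master seed; per-iteration substreams are derived from it.
#' @return data frame with one row per tested protein: `id`,
#'   `median_log2fc`, `mean_log2fc`, `median_p_adj`, `stability_fraction`
#'   (share of iterations passing the criterion) and `significant`
#'   (`stability_fraction > stability`).
#' @export
stability_dea <- function(qm, group_a, group_b, n_iter = 1000L,
                          fc = 1.5, alpha = 0.05, stability = 0.8,
                          q = 0.01, tune_sigma = 1.0, seed = 1L) {
  stopifnot(inherits(qm, "quant_matrix"))
  if (n_iter < 1) stop("n_iter must be >= 1")
  if (fc <= 0 || alpha <= 0) stop("thresholds must be positive")
  check_condition(qm, group_a)
  check_condition(qm, group_b)
  ca <- sample_cols(qm, group_a)
  cb <- sample_cols(qm, group_b)
  keep_rows <- rowSums(!is.na(qm$values[, ca, drop = FALSE])) ==
                 length(ca) |
               rowSums(!is.na(qm$values[, cb, drop = FALSE])) ==
                 length(cb)
  if (!any(keep_rows))
    stop("no protein detected in all replicates of either condition")
  sub <- quant_matrix(qm$values[keep_rows, c(ca, cb), drop = FALSE],
                      qm$design[c(ca, cb), , drop = FALSE])
  lfc_thr <- log2(fc)
  n_row <- nrow(sub$values)
  seeds <- substream_seeds(seed, n_iter)
  lfc_mat <- matrix(NA_real_, n_row, n_iter)
  padj_mat <- matrix(NA_real_, n_row, n_iter)
  pass_mat <- matrix(FALSE, n_row, n_iter)
  for (it in seq_len(n_iter)) {
    imp <- minprob_impute(sub, q = q, tune_sigma = tune_sigma,
                          seed = seeds[it])
    res <- moderated_t_test(imp, group_a, group_b)
    padj <- bh_adjust(res$p)
    lfc_mat[, it] <- res$log2fc
    padj_mat[, it] <- padj
    pass_mat[, it] <- padj < alpha & abs(res$log2fc) > lfc_thr
  }
  frac <- rowMeans(pass_mat)
  data.frame(id = rownames(sub$values),
             median_log2fc = apply(lfc_mat, 1L, stats::median),
             mean_log2fc = rowMeans(lfc_mat),
             median_p_adj = apply(padj_mat, 1L, stats::median),
             stability_fraction = frac,
             significant = frac > stability,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Forward/reverse IQR outlier test for label-swap designs
#'
#' In a chemical-labeling duplicate design the two conditions swap
#' labels between a forward and a reverse run, so a true abundance
#' change inverts the sign of its log ratio between runs while labeling
#' artifacts keep it. Per run, outlier thresholds are set at
#' `Q3 + 1.5 IQR` and `Q1 - 1.5 IQR` of that run's log-ratio
#' distribution (quartiles by the linear-interpolation convention,
#' `stats::quantile` type 7). A protein is significant only if it
#' exceeds the upper threshold in one run and the lower threshold in
#' the other.
#'
#' Ratios are stored in label order (e.g. medium/light); the reverse
#' run's biological contrast is therefore the negative of the forward
#' run's, which is why opposite-side exceedance is required.
#'
#' @param forward_ratios,reverse_ratios named numeric vectors of per-
#'   protein log2 ratios from the forward and reverse runs.
#' @return data frame with columns `id` and `direction` (`"up"` if the
#'   protein is high in the forward run's heavy label); proteins present
#'   in only one run are excluded and counted in attribute `n_unpaired`;
#'   the per-run thresholds are attached as attribute `thresholds`.
#' @export
iqr_outlier_test <- function(forward_ratios, reverse_ratios) {
  if (!length(forward_ratios) || !length(reverse_ratios))
    stop("both runs must be non-empty")
  if (is.null(names(forward_ratios)) || is.null(names(reverse_ratios)))
    stop("ratio vectors must be named by protein id")
  shared <- intersect(names(forward_ratios), names(reverse_ratios))
  n_unpaired <- (length(forward_ratios) - length(shared)) +
                (length(reverse_ratios) - length(shared))
  thr <- function(x) {
    qs <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
    iqr <- qs[2] - qs[1]
    c(lo = qs[1] - 1.5 * iqr, hi = qs[2] + 1.5 * iqr)
  }
  tf <- thr(forward_ratios)
  tr <- thr(reverse_ratios)
  f <- forward_ratios[shared]
  r <- reverse_ratios[shared]
  up <- f > tf["hi"] & r < tr["lo"]
  down <- f < tf["lo"] & r > tr["hi"]
  out <- data.frame(id = c(shared[up], shared[down]),
                    direction = c(rep("up", sum(up)),
                                  rep("down", sum(down))),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_unpaired") <- n_unpaired
  attr(out, "thresholds") <- list(forward = tf, reverse = tr)
  out
}
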