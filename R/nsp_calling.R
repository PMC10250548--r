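#' Identify background binders in an enrichment experiment
#'
#' Proteins that bind the enrichment resin non-specifically appear in
#' the untreated control at intensities comparable to the treated
#' condition. Every protein detected in the control is tested for
#' enrichment in the treated condition (moderated t-test on
#' MinProb-imputed log2 intensities, BH-adjusted); those that fail the
#' enrichment criterion (FC > `fc` and p.adj < `alpha`) are background
#' binders and should be removed from all downstream comparisons.
#' A protein entirely absent from the control can never be classified
#' as background.
#'
#' @param qm a [quant_matrix()].
#' @param treated,control condition labels (each with >= 2 replicates).
#' @param fc,alpha enrichment thresholds (raw-scale fold change and
#'   BH-adjusted significance level).
#' @param q,tune_sigma MinProb parameters (see [minprob_impute()]).
#' @param seed seed for the imputation draw.
#' @return character vector of background protein ids.
#' @export
identify_background <- function(qm, treated, control, fc = 1.5,
                                alpha = 0.05, q = 0.01,
                                tune_sigma = 1.0, seed = 1L) {
  stopifnot(inherits(qm, "quant_matrix"))
  check_condition(qm, treated)
  check_condition(qm, control)
  if (fc <= 0 || alpha <= 0) stop("thresholds must be positive")
  ccols <- sample_cols(qm, control)
  tcols <- sample_cols(qm, treated)
  if (length(ccols) < 2 || length(tcols) < 2)
    stop("both conditions need >= 2 replicates")
  in_control <- rowSums(!is.na(qm$values[, ccols, drop = FALSE])) > 0
  if (!any(in_control)) return(character(0))
  sub <- quant_matrix(qm$values[, c(tcols, ccols), drop = FALSE],
                      qm$design[c(tcols, ccols), , drop = FALSE])
  imp <- minprob_impute(sub, q = q, tune_sigma = tune_sigma, seed = seed)
  res <- moderated_t_test(imp, treated, control)
  res <- res[in_control, , drop = FALSE]
  res$p_adj <- bh_adjust(res$p)
  enriched <- res$log2fc > log2(fc) & res$p_adj < alpha
  res$id[!enriched]
}

#' Call newly synthesized proteins against an untreated control
#'
#' A protein is a candidate NSP if it is detected (non-missing) in all
#' replicates of the treated condition and is not a background binder.
#' A candidate is called NSP if it is either absent from every control
#' replicate (evidence `"absent-in-control"`) or significantly enriched
#' over the control (moderated t-test on MinProb-imputed log2 values,
#' FC > `fc`, BH p.adj < `alpha`; evidence `"enriched"`). All other
#' proteins are labeled `"background"`, `"not-identified"` (not seen in
#' every treated replicate) or `"identified-not-enriched"`.
#'
#' @param qm a [quant_matrix()].
#' @param treated,control condition labels.
#' @param background character vector of background ids, as returned by
#'   [identify_background()] on the same matrix.
#' @param fc,alpha enrichment thresholds.
#' @param q,tune_sigma MinProb parameters.
#' @param seed seed for the imputation draw.
#' @return data frame with one row per protein: `id`, `status`
#'   (`"NSP"`, `"background"`, `"not-identified"`,
#'   `"identified-not-enriched"`), `evidence` (`"absent-in-control"`,
#'   `"enriched"`, or `NA`), `log2fc`, `p`, `p_adj` (`NA` where no
#'   enrichment test was run).
#' @export
call_nsps <- function(qm, treated, control, background = character(0),
                      fc = 1.5, alpha = 0.05, q = 0.01,
                      tune_sigma = 1.0, seed = 1L) {
  stopifnot(inherits(qm, "quant_matrix"))
  check_condition(qm, treated)
  check_condition(qm, control)
  if (fc <= 0 || alpha <= 0) stop("thresholds must be positive")
  ids <- rownames(qm$values)
  tcols <- sample_cols(qm, treated)
  ccols <- sample_cols(qm, control)
  all_treated <- rowSums(!is.na(qm$values[, tcols, drop = FALSE])) ==
    length(tcols)
  none_control <- rowSums(!is.na(qm$values[, ccols, drop = FALSE])) == 0
  out <- data.frame(id = ids, status = NA_character_,
                    evidence = NA_character_, log2fc = NA_real_,
                    p = NA_real_, p_adj = NA_real_,
                    row.names = NULL, stringsAsFactors = FALSE)
  is_bg <- ids %in% background
  candidate <- all_treated & !is_bg
  test_me <- candidate & !none_control
  if (any(test_me)) {
    sub <- quant_matrix(qm$values[, c(tcols, ccols), drop = FALSE],
                        qm$design[c(tcols, ccols), , drop = FALSE])
    imp <- minprob_impute(sub, q = q, tune_sigma = tune_sigma,
                          seed = seed)
    res <- moderated_t_test(imp, treated, control)
    res <- res[test_me, , drop = FALSE]
    res$p_adj <- bh_adjust(res$p)
    idx <- match(res$id, out$id)
    out$log2fc[idx] <- res$log2fc
    out$p[idx] <- res$p
    out$p_adj[idx] <- res$p_adj
  }
  enriched <- !is.na(out$p_adj) & out$log2fc > log2(fc) &
    out$p_adj < alpha
  out$status[is_bg] <- "background"
  out$status[!is_bg & !all_treated] <- "not-identified"
  nsp_absent <- candidate & none_control
  nsp_enr <- candidate & !none_control & enriched
  out$status[nsp_absent | nsp_enr] <- "NSP"
  out$evidence[nsp_absent] <- "absent-in-control"
  out$evidence[nsp_enr] <- "enriched"
  out$status[is.na(out$status)] <- "identified-not-enriched"
  out
}

#' Replicate reproducibility of protein detection
#'
#' Over the union of proteins detected in at least one replicate,
#' the fraction detected in every replicate and the fraction detected
#' in at least two.
#'
#' @param detection logical matrix (proteins x replicates), `TRUE` =
#'   detected; or a numeric matrix where non-`NA` means detected.
#' @return named numeric vector `c(all_replicates =, at_least_two =)`
#'   in percent, one decimal.
#' @export
replicate_reproducibility <- function(detection) {
  if (is.numeric(detection)) detection <- !is.na(detection)
  if (!is.matrix(detection) || ncol(detection) < 2)
    stop("need a detection matrix with >= 2 replicates")
  k <- rowSums(detection)
  union_n <- sum(k > 0)
  if (union_n == 0) stop("no protein detected in any replicate")
  c(all_replicates = round(100 * sum(k == ncol(detection)) / union_n, 1L),
    at_least_two = round(100 * sum(k >= 2) / union_n, 1L))
}

#' Overlap between two protein sets as percentages of their union
#'
#' @param a,b character vectors of ids (at least one non-empty).
#' @return named numeric vector `c(shared =, a_only =, b_only =)` in
#'   percent of the union, one decimal.
#' @examples
#' set_overlap(c("P1", "P2", "P3"), c("P2", "P3", "P4"))
#' @export
set_overlap <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- union(a, b)
  if (!length(u)) stop("both sets are empty")
  c(shared = round(100 * length(intersect(a, b)) / length(u), 1L),
    a_only = round(100 * length(setdiff(a, b)) / length(u), 1L),
    b_only = round(100 * length(setdiff(b, a)) / length(u), 1L))
}
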