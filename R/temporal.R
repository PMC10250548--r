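#' Heavy-label specificity of an enriched peptide population
#'
#' In a pulse-labeling design every newly synthesized peptide should
#' carry the heavy-lysine label, so the fraction of enriched peptides
#' carrying it measures how specifically the enrichment captures
#' nascent protein.
#'
#' @param peptides data frame in the [read_peptide_table()] layout.
#' @param heavy_label substring of the `Modifications` field marking
#'   the heavy label (default `"Lys8"`).
#' @return percentage of peptides carrying the label, one decimal.
#' @export
label_specificity <- function(peptides, heavy_label = "Lys8") {
  if (!nrow(peptides)) stop("empty peptide list")
  hit <- grepl(heavy_label, peptides$Modifications, fixed = TRUE)
  round(100 * mean(hit), 1L)
}

#' Detection dynamics across pulse-labeling time windows
#'
#' A protein is *detected* in a window when it is present in all
#' replicates of that window (the all-replicates rule; set
#' `rule = "any"` for the permissive variant). Relative to the first
#' window (steady state), the summary counts proteins detected at
#' steady state (`n_steady`), those among them undetected in the first
#' post-stimulation window (`n_lost`), and those lost proteins detected
#' again in any later window (`n_regained`).
#'
#' @param qm a [quant_matrix()] whose design carries >= 2 ordered time
#'   windows, the first being the steady state.
#' @param rule `"all"` (default) or `"any"` replicates per window.
#' @return object of class `presence_dynamics`: list with `detected`
#'   (logical protein x window matrix), and counts `n_total` (proteins
#'   detected in >= 1 window), `n_steady`, `n_lost`, `n_regained`.
#' @export
presence_dynamics <- function(qm, rule = c("all", "any")) {
  stopifnot(inherits(qm, "quant_matrix"))
  rule <- match.arg(rule)
  wins <- window_levels(qm)
  if (length(wins) < 2)
    stop("need >= 2 time windows; the design has ", length(wins))
  det <- vapply(wins, function(w) {
    cols <- which(!is.na(qm$design$window) & qm$design$window == w)
    obs <- !is.na(qm$values[, cols, drop = FALSE])
    if (rule == "all") rowSums(obs) == length(cols) else rowSums(obs) > 0
  }, logical(nrow(qm$values)))
  dimnames(det) <- list(rownames(qm$values), wins)
  steady <- det[, 1L]
  lost <- steady & !det[, 2L]
  regained <- lost & if (ncol(det) > 2)
    rowSums(det[, -(1:2), drop = FALSE]) > 0 else FALSE
  structure(list(detected = det,
                 n_total = sum(rowSums(det) > 0),
                 n_steady = sum(steady),
                 n_lost = sum(lost),
                 n_regained = sum(regained)),
            class = "presence_dynamics")
}

#' @export
print.presence_dynamics <- function(x, ...) {
  cat(sprintf(
    "presence_dynamics: %d detected, %d at steady state, %d lost after stimulation, %d regained later\n",
    x$n_total, x$n_steady, x$n_lost, x$n_regained))
  invisible(x)
}

#' Per-protein z-scored time-window profiles
#'
#' For each complete row, replicate intensities are averaged per window
#' and the window means standardized per protein:
#' `z = (x - mean(x)) / sd(x)` with the sample (n-1) standard
#' deviation. Rows with zero spread cannot be standardized and are
#' flagged rather than silently dropped.
#'
#' @param qm a [quant_matrix()] with windows; rows must be complete
#'   (impute or subset first).
#' @param level `"window"` (default, z over window replicate-means, the
#'   heatmap granularity) or `"replicate"` (z over individual
#'   replicates).
#' @return list with `z` (protein x window — or x sample — matrix of
#'   z-scores, `NA` rows where flagged) and `flagged` (ids of
#'   zero-spread rows).
#' @export
zscore_profiles <- function(qm, level = c("window", "replicate")) {
  stopifnot(inherits(qm, "quant_matrix"))
  level <- match.arg(level)
  if (anyNA(qm$values))
    stop("rows must be complete across all windows and replicates")
  wins <- window_levels(qm)
  if (level == "window") {
    if (length(wins) < 2) stop("need >= 2 time windows")
    x <- vapply(wins, function(w) {
      cols <- which(!is.na(qm$design$window) & qm$design$window == w)
      rowMeans(qm$values[, cols, drop = FALSE])
    }, numeric(nrow(qm$values)))
    dimnames(x) <- list(rownames(qm$values), wins)
  } else {
    x <- qm$values
  }
  mu <- rowMeans(x)
  sdev <- apply(x, 1L, stats::sd)
  flagged <- rownames(x)[sdev == 0]
  z <- (x - mu) / sdev
  z[sdev == 0, ] <- NA_real_
  list(z = z, flagged = flagged)
}

#' One-way ANOVA across time windows for one protein
#'
#' Fixed-effects one-way ANOVA of a protein's replicate log2
#' intensities across time windows, followed by Bonferroni-corrected
#' pairwise two-sample t-tests between consecutive windows (each raw
#' p-value multiplied by the number of comparisons, capped at 1).
#'
#' @param qm a [quant_matrix()] with >= 2 windows and >= 2 replicates
#'   per window; the protein's data must be complete.
#' @param protein row id.
#' @return list with `F`, `p`, `df` (c(between, within)), and
#'   `pairwise` (data frame: `window_a`, `window_b`, `p`,
#'   `p_bonferroni`).
#' @export
profile_anova <- function(qm, protein) {
  stopifnot(inherits(qm, "quant_matrix"))
  if (!protein %in% rownames(qm$values))
    stop("unknown protein id: ", protein)
  wins <- window_levels(qm)
  if (length(wins) < 2) stop("need >= 2 time windows")
  cols <- which(!is.na(qm$design$window))
  y <- qm$values[protein, cols]
  if (anyNA(y))
    stop("protein ", protein, " has missing values; ANOVA assumes ",
         "complete data")
  g <- factor(qm$design$window[cols], levels = wins)
  if (any(table(g) < 2)) stop("need >= 2 replicates per window")
  if (length(unique(y)) == 1L) {
    # degenerate flat profile: no evidence of change by convention
    pw <- data.frame(window_a = wins[-length(wins)],
                     window_b = wins[-1L], p = 1, p_bonferroni = 1,
                     stringsAsFactors = FALSE)
    return(list(F = 0, p = 1,
                df = c(between = length(wins) - 1L,
                       within = length(y) - length(wins)),
                pairwise = pw))
  }
  fit <- stats::aov(y ~ g)
  tab <- summary(fit)[[1L]]
  n_cmp <- length(wins) - 1L
  pw <- data.frame(window_a = wins[-length(wins)],
                   window_b = wins[-1L],
                   p = NA_real_, p_bonferroni = NA_real_,
                   stringsAsFactors = FALSE)
  for (i in seq_len(n_cmp)) {
    pa <- stats::t.test(y[g == wins[i]], y[g == wins[i + 1L]],
                        var.equal = TRUE)$p.value
    pw$p[i] <- pa
    pw$p_bonferroni[i] <- min(1, pa * n_cmp)
  }
  list(F = tab[["F value"]][1L], p = tab[["Pr(>F)"]][1L],
       df = c(between = tab[["Df"]][1L], within = tab[["Df"]][2L]),
       pairwise = pw)
}
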