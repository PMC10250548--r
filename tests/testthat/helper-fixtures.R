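# Shared fixture builders and independent oracles. Fixtures are built
# in code so the suite carries no data files.

# quant_matrix from a plain matrix of log2 values (NA = missing)
qm_fixture <- function(vals, window_levels = NULL) {
  quant_matrix(vals, design_from_names(colnames(vals), window_levels))
}

# two-condition matrix: n rows, 3 + 3 replicates, given group means
two_group_matrix <- function(mean_a, mean_b, sd = 0.3, n_rep = 3,
                             ids = sprintf("P%03d", seq_along(mean_a)),
                             seed = 1) {
  set.seed(seed)
  n <- length(mean_a)
  vals <- cbind(
    matrix(rnorm(n * n_rep, mean_a, sd), n, n_rep),
    matrix(rnorm(n * n_rep, mean_b, sd), n, n_rep))
  dimnames(vals) <- list(ids, c(paste0("a_", seq_len(n_rep)),
                                paste0("b_", seq_len(n_rep))))
  qm_fixture(vals)
}

# peptide-table row in the read_peptide_table() layout
pep_row <- function(sequence, mods, intensities, protein = "P1") {
  row <- data.frame(Sequence = sequence, Modifications = mods,
                    Proteins = protein, Charge = 2L,
                    stringsAsFactors = FALSE)
  for (nm in names(intensities)) row[[paste0("Intensity ", nm)]] <-
      intensities[[nm]]
  row
}

pep_table <- function(...) {
  df <- do.call(rbind, list(...))
  attr(df, "samples") <- sub("^Intensity ", "",
                             grep("^Intensity ", names(df), value = TRUE))
  df
}

# Brute-force Benjamini-Hochberg oracle: the adjusted p-value of
# hypothesis i is the smallest significance level (among the finitely
# many candidate levels n*p_(k)/k) at which the step-up procedure
# rejects i. Independent of any step-up shortcut formula. The step-up
# comparison carries an absolute 1e-9 guard because at a candidate
# level the defining inequality holds with equality, which floating-
# point division can break by one ulp.
bh_oracle <- function(p) {
  n <- length(p)
  ps <- sort(p)
  cand <- sort(unique(pmin(1, n * ps / seq_len(n))))
  vapply(p, function(pi) {
    for (a in cand) {
      k <- which(ps <= a * seq_len(n) / n + 1e-9)
      k <- if (length(k)) max(k) else 0L
      if (k > 0 && pi <= ps[k]) return(a)
    }
    1
  }, 0)
}
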