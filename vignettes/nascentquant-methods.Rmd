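---
title: "Models and methods behind nascentquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nascentquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nascentquant)
```

# The experimental setting

Metabolic labeling with a clickable threonine analog marks proteins
synthesized during a labeling window: the analog is incorporated at a
small fraction of threonine positions, labeled proteins are enriched by
click chemistry, and the enriched fraction is quantified by label-free
LC-MS/MS. Two stable-isotope channels support the design: heavy
threonine (Thr₅) co-fed with the analog makes the incorporation rate
measurable from matched peptide pairs, and heavy lysine (Lys₈) fed only
during a pulse window marks peptides translated inside that window.
This package implements the downstream statistics of such experiments;
everything upstream of the quantification tables (spectral search,
protein inference, LFQ) is consumed, not reproduced.

# Incorporation rate from matched peptide pairs

For a peptide with a single threonine and latent abundance $A$, the
heavy form has expected intensity $A(1-p)$ and the analog form $Ap$,
where $p$ is the per-site substitution probability. The estimator:

1. keeps peptides with exactly one threonine (so the modification state
   is unambiguous);
2. sums intensities per replicate over co-occurring modification states
   (e.g. with and without N-terminal acetylation) so each peptide has
   one value per group;
3. requires detection in at least two replicates for group membership
   and keeps the intersection of peptides present in all three groups
   (unmodified, heavy, analog);
4. MinProb-imputes remaining missing replicate values, averages
   replicates per group on the **linear** intensity scale, and forms
   $r_i = I_{\text{analog},i} / I_{\text{heavy},i}$.

The substitution fraction is summarized as
$f = \operatorname{mean}_i\, r_i/(1+r_i)$ and reported as one-in-$N$
with $N = 1/f$. This summary is bounded in $(0,1)$, robust to an
occasional large $r_i$, and asymptotically equal to the naive
mean-ratio reading $1/\operatorname{mean}(r_i)$ when $r$ is small; both
summaries are reported because either reading of "pairwise ratios were
averaged" is defensible, and on clean simulated data they agree to
within a few percent. Swapping the analog and heavy labels maps
$f \mapsto 1-f$, and both $f$ and $N$ are invariant to rescaling all
intensities.

Under left-censoring the estimate of $f$ is biased **upward**: the
three-group intersection preferentially drops peptides whose analog
form (the weak one, $\approx A p$) fell below the detection limit, so
the surviving peptides carry larger-than-average ratios. The test suite
asserts this direction rather than hiding it; analyses of heavily
censored data should treat the incorporation rate as an upper bound on
$p$.

# Missing values: the censoring model and MinProb

Non-detection in LC-MS is concentrated at low intensities. The
simulator and the imputer share one view of this mechanism:

* **Generator.** A cell with latent log2 intensity $x$ is observed with
  probability $\operatorname{logit}^{-1}(s\,(x-m))$ — a logistic
  detection curve with midpoint $m$ (default 16 on the log2 scale,
  i.e. well below the default abundance mean of 23) and slope $s$
  (default 1). Logistic censoring is the standard surrogate for an
  instrument detection limit and is the regime MinProb-style imputation
  presumes. Structural absence (a protein truly not present) is
  distinct from censoring and recorded separately in the ground truth.
* **Imputer.** `minprob_impute()` replaces each missing cell of a
  sample with a draw from a Gaussian centered at the $q$-quantile
  (default $q = 0.01$) of that sample's observed log2 values, with
  standard deviation `tune_sigma` (default 1.0) times the median
  per-row observed standard deviation. These are the conventional
  defaults of the MinProb method. A sample with fewer than three
  observed values has no meaningful low quantile and is refused by
  name.

# The moderated t-test and its prior

Per-row variance estimates from three replicates are noisy; the
moderated t-test shrinks them toward a prior shared across rows.
With pooled row variance $s_g^2$ on $d_g$ degrees of freedom, the
posterior variance is

$$\tilde s^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},$$

and $t = \Delta\bar x / (\tilde s\sqrt{1/n_a + 1/n_b})$ is referred to
a $t$ distribution on $d_0 + d_g$ degrees of freedom (two-sided). The
prior $(d_0, s_0^2)$ is estimated by moment-matching on
$z = \log s_g^2$: under the scaled-F model
$\operatorname{Var}(z) = \psi_1(d_g/2) + \psi_1(d_0/2)$, solved with a
Newton inverse of the trigamma function, and $s_0^2$ follows from the
mean of $z$. This is the classical empirical-Bayes fit (the test suite
cross-checks $d_0$, $s_0^2$ and the p-values against limma's
implementation); exact marginal likelihood would differ negligibly at
these scales. When the observed log-variance spread is no larger than
the sampling noise ($\operatorname{Var}(z) \le \psi_1(d_g/2)$), the
prior degrees of freedom are infinite and every row uses the common
variance. With $d_0 = 0$ the test reduces exactly to the classical
equal-variance t-test, which the suite verifies to $10^{-10}$.

Fold-change thresholds are always stated on the raw intensity scale:
FC > 1.5 means $|\log_2 \text{FC}| > \log_2 1.5$. Log base 2 is applied
exactly once, at read time.

# Imputation-stability differential enrichment

Because imputation is stochastic, a single round can flag proteins
whose significance rides on the imputed draws. `stability_dea()`
repeats the full round — fresh MinProb imputation, moderated t, BH —
`n_iter` times (1000 in a full analysis; tests and the acceptance
script use 200, which already stabilizes the pass fraction to a few
percent) and flags a protein only if it satisfies
`p.adj < 0.05 ∧ FC > 1.5` in more than 80% of iterations. Only proteins
detected in all replicates of at least one condition enter the
analysis. Per-protein medians *and* means of the per-iteration fold
changes and adjusted p-values are reported, but the flag depends only
on the per-iteration criterion — the summaries are descriptive, since
no single summary is canonical. Iteration substreams derive from one
master seed, so results are byte-reproducible and the flagged set is
monotone non-increasing in the stability threshold.

# Forward/reverse IQR outlier test

In a label-swap (dimethyl-style) duplicate design, ratios are stored in
label order, so a true biological change inverts its sign between the
forward and reverse runs while label-specific artifacts keep it.
Outlier thresholds are computed per run as $Q_3 + 1.5\,\mathrm{IQR}$
and $Q_1 - 1.5\,\mathrm{IQR}$ of that run's log-ratio distribution,
with quartiles by the linear-interpolation convention
(`stats::quantile` type 7). A protein is significant only when it
exceeds the upper threshold in one run and the lower threshold in the
other; proteins quantified in a single run are excluded and tallied.

# NSP calling

Identification is operationalized as a non-missing LFQ value (search-
engine FDR control happens upstream). Background binders are identified
**first** — every protein detected in the control is tested for
enrichment, and non-enriched ones are removed — and candidacy
(detection in all treated replicates) is evaluated on what remains;
the order matters only for proteins that would fail both rules, and
removing background first matches the analysis style of subtracting a
bead-binder list before any comparison. "Absent in the untreated
condition" is read strictly as missing in *every* control replicate;
the permissive reading is one argument away. Raising the fold-change
threshold can only shrink the NSP set.

# Time-course analytics

The presence-dynamics counts use the all-replicates detection rule per
window (detected = present in all replicates of that window), applied
uniformly to the steady-state, lost and regained definitions; "regained"
means detected in at least one window after the first post-stimulation
window. The permissive any-replicate rule is available because the
strict rule is only stated for heatmap-grade data. Z-score profiles are
computed on window replicate-means (heatmap granularity) with the
sample (n−1) standard deviation; constant rows are flagged, not
silently dropped. A flat profile yields $F = 0,\ p = 1$ by convention
(the 0/0 F-statistic of an all-equal response carries no evidence of
change). With two windows the ANOVA reduces to the squared t-test, and
on null data its p-values are uniform — both verified in the suite.

# The simulators: what they do and do not emulate

The generators emulate exactly what the downstream statistics are
sensitive to: log-normal abundances (log2 mean 23, s.d. 2 — the
dynamic-range regime of a typical LFQ run), multiplicative replicate
noise at 20% CV, per-threonine substitution at a configurable $p$
(default 1/40), heavy-label assignment at 95%, structural designs
(true NSPs, background binders, control-only proteins; per-window
profiles), and logistic left-censoring. Defaults were fixed once, as
study-realistic values, and are not tuned per analysis.

They deliberately do **not** emulate chromatography, ionization
efficiency, isotope envelopes, peptide-level shared-intensity effects,
or search-engine identification error. Consequently, passing tests
demonstrate correctness of the statistical procedures under the stated
missingness and noise model — not robustness to every pathology of real
LC-MS data. Dataset-scale published counts (thousands of NSPs, the
exact 124-peptide intersection) depend on the deposited raw data and
are out of reach of a desk-scale simulation; the pipeline's recovery
properties are what the suite checks (e.g. one-in-N within ±15% of a
true 1/40.8 at 150 peptides and 20% CV).

# Numerical and degenerate-case choices

* Intensity 0, empty cells and `NaN` in input tables all mean
  non-detection; written tables use 0, matching the upstream
  convention. Numeric round-trips are bit-exact (17 significant
  digits).
* Monoisotopic mass deltas are derived from the elemental composition
  and the standard atomic/isotopic mass table, never entered as
  literals. The heavy-threonine substitution (four ¹³C, one ¹⁵N)
  computes to +5.0105 Da; search configurations sometimes quote
  +5.0145 Da, a ~0.004 Da discrepancy that is surfaced as-is in
  `built_in_mods()` rather than reconciled.
* Nonstandard residues (U, X, B, Z) are excluded from both numerator
  and denominator of content statistics. The mean residue content is
  the unweighted per-protein mean ("average content of identified
  proteins"); the length-weighted variant is an option.
* BH adjustment delegates to `stats::p.adjust`; its step-up behavior is
  property-tested against an independent brute-force oracle on short
  p-value grids.
* Replicate averaging for the incorporation ratio happens on the linear
  scale (intensities are averaged, then divided), not on the log scale.
* Seeds: every stochastic entry point takes a seed, runs under a local
  RNG state, and restores the caller's state; multi-stage procedures
  split one master seed into substreams so stages can be re-run
  independently.

# Known limitations

* The incorporation estimator assumes the analog and heavy forms of a
  peptide ionize identically; a systematic ionization difference would
  bias $f$ multiplicatively and is indistinguishable from a different
  $p$ without standards.
* MinProb imputation is single-valued per cell per iteration; the
  stability wrapper quantifies imputation sensitivity but not model
  uncertainty about the censoring mechanism itself.
* The moderated t assumes equal variances between the two groups per
  protein (pooled $s_g^2$), as its reference implementations do.
* `profile_anova()` requires complete data by design; imputing a time
  course before ANOVA is possible but conflates imputation noise with
  temporal signal, so it is left to the caller's judgment.
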