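# Monoisotopic masses (Da) of the elements and named heavy isotopes
# used in peptide modification arithmetic.
MONOISOTOPIC_MASS <- c(
  H = 1.007825032, C = 12.000000000, N = 14.003074005,
  O = 15.994914620, S = 31.972071174, P = 30.973761998,
  `2H` = 2.014101778, `13C` = 13.003354835, `15N` = 15.000108899
)

#' Define a residue modification by its elemental composition delta
#'
#' A modification is a named residue substitution described by the
#' signed change in elemental composition it causes; its monoisotopic
#' mass delta is derived from the standard atomic mass table, never
#' entered by hand. Heavy-isotope swaps are expressed by removing the
#' light element and adding the heavy isotope (e.g. `c("13C" = 4,
#' C = -4)` for four carbon-13 substitutions).
#'
#' @param name modification name.
#' @param target single-letter code of the residue the modification
#'   applies to.
#' @param delta named numeric vector, element/isotope symbol -> signed
#'   atom count. Symbols must be in the built-in mass table.
#' @return object of class `modification_spec` with fields `name`,
#'   `target`, `delta`, `monoisotopic` (Da).
#' @examples
#' mod_spec("Thr->bES", "T", c(C = 1, H = -2))
#' @export
mod_spec <- function(name, target, delta) {
  if (length(delta) && is.null(names(delta)))
    stop("`delta` must be a named vector of atom counts")
  unknown <- setdiff(names(delta), names(MONOISOTOPIC_MASS))
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  structure(list(name = name, target = target, delta = delta,
                 monoisotopic = mod_mass_delta(delta)),
            class = "modification_spec")
}

#' Monoisotopic mass delta of an elemental composition change
#'
#' Signed sum of atom counts times monoisotopic masses. Additive:
#' the delta of a combined change is the sum of its parts.
#'
#' @param delta a `modification_spec` or a named numeric vector,
#'   element/isotope symbol -> signed atom count.
#' @return mass delta in Da.
#' @examples
#' mod_mass_delta(c(C = 1, H = -2))   # threonine -> analog, +9.9843
#' mod_mass_delta(c(O = 1))           # Met oxidation, +15.9949
#' @export
mod_mass_delta <- function(delta) {
  if (inherits(delta, "modification_spec")) return(delta$monoisotopic)
  if (!length(delta)) return(0)
  if (is.null(names(delta)))
    stop("`delta` must be a named vector of atom counts")
  unknown <- setdiff(names(delta), names(MONOISOTOPIC_MASS))
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  sum(delta * MONOISOTOPIC_MASS[names(delta)])
}

#' Built-in modification table
#'
#' Named residue substitutions used in analog-labeling searches. Note
#' that the derived heavy-threonine delta (four 13C plus one 15N,
#' +5.0105 Da) differs by ~0.004 Da from the +5.0145 Da sometimes
#' quoted in search configurations; the elemental arithmetic is
#' reported as computed.
#'
#' @return named list of [mod_spec()] objects: `Thr->bES`,
#'   `Thr->Thr5`, `Lys->Lys8`, `Oxidation (M)`.
#' @export
built_in_mods <- function() {
  list(
    `Thr->bES` = mod_spec("Thr->bES", "T", c(C = 1, H = -2)),
    `Thr->Thr5` = mod_spec("Thr->Thr5", "T",
                           c(`13C` = 4, C = -4, `15N` = 1, N = -1)),
    `Lys->Lys8` = mod_spec("Lys->Lys8", "K",
                           c(`13C` = 6, C = -6, `15N` = 2, N = -2)),
    `Oxidation (M)` = mod_spec("Oxidation (M)", "M", c(O = 1))
  )
}

STANDARD_AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Residue content of one protein sequence
#'
#' Percentage of a protein's residues equal to `residue`. Nonstandard
#' letters (U, X, B, Z, ...) are excluded from both numerator and
#' denominator.
#'
#' @param sequence amino-acid string (non-empty).
#' @param residue single-letter residue code.
#' @return percentage in [0, 100].
#' @examples
#' residue_content("MKTAYIAKQR", "T")  # 10
#' @export
residue_content <- function(sequence, residue) {
  if (!nchar(sequence)) stop("empty sequence")
  chars <- strsplit(toupper(sequence), "")[[1]]
  std <- chars[chars %in% STANDARD_AA]
  if (!length(std)) stop("sequence has no standard residues")
  100 * sum(std == toupper(residue)) / length(std)
}

#' Composition summary of a protein set
#'
#' Per-protein residue fractions and their unweighted mean over a
#' proteome or a subset of it, the percentage of proteins lacking the
#' residue, and — for methionine only — the percentage of proteins
#' whose single methionine is the N-terminal one (relevant because an
#' N-terminal methionine may be post-translationally removed, leaving
#' the protein invisible to methionine-directed labeling).
#'
#' @param proteome named character vector, id -> sequence (e.g. from
#'   [read_fasta()]).
#' @param residue single-letter residue code.
#' @param subset optional character vector of ids to restrict to.
#' @param weighted if `TRUE`, the mean is length-weighted (equivalent to
#'   the residue frequency of the concatenated sequences) instead of
#'   the default unweighted per-protein mean.
#' @return object of class `content_summary`: list with `per_protein`
#'   (named percentages), `mean_pct`, `lacking_pct`,
#'   `single_nterm_met_pct` (`NA` unless `residue == "M"`), `n`,
#'   `residue`.
#' @export
content_summary <- function(proteome, residue, subset = NULL,
                            weighted = FALSE) {
  if (!length(proteome)) stop("empty proteome")
  if (is.null(names(proteome))) stop("proteome must be named by id")
  if (!is.null(subset)) {
    missing_ids <- setdiff(subset, names(proteome))
    if (length(missing_ids))
      stop("subset id(s) not in proteome: ",
           paste(missing_ids, collapse = ", "))
    proteome <- proteome[subset]
  }
  residue <- toupper(residue)
  per <- vapply(proteome, residue_content, 0, residue = residue)
  mean_pct <- if (weighted) {
    chars <- strsplit(toupper(paste(proteome, collapse = "")), "")[[1]]
    std <- chars[chars %in% STANDARD_AA]
    100 * sum(std == residue) / length(std)
  } else mean(per)
  single_nterm <- NA_real_
  if (residue == "M") {
    hit <- vapply(proteome, function(s) {
      chars <- strsplit(toupper(s), "")[[1]]
      sum(chars == "M") == 1L && chars[1L] == "M"
    }, TRUE)
    single_nterm <- 100 * mean(hit)
  }
  structure(list(per_protein = per,
                 mean_pct = mean_pct,
                 lacking_pct = 100 * mean(per == 0),
                 single_nterm_met_pct = single_nterm,
                 n = length(proteome), residue = residue),
            class = "content_summary")
}

#' @export
print.content_summary <- function(x, ...) {
  cat(sprintf(
    "content_summary (%s, n = %d): mean %.2f%%, lacking %.1f%%",
    x$residue, x$n, x$mean_pct, x$lacking_pct))
  if (!is.na(x$single_nterm_met_pct))
    cat(sprintf(", single N-terminal Met %.1f%%",
                x$single_nterm_met_pct))
  cat("\n")
  invisible(x)
}
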