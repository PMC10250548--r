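#' Read a search-engine peptide quantification table
#'
#' Reads a tab-separated modification-specific peptide table of the kind
#' emitted by MaxQuant (`modificationSpecificPeptides`). Each row is one
#' (sequence, modification-state) combination with one intensity column
#' per sample. An intensity of 0, an empty cell, or `NaN` means the
#' peptide was not detected in that sample and is stored as `NA` —
#' search engines emit 0 for non-detection.
#'
#' @param path path to a TSV file.
#' @param dialect table schema; `"peptides"` requires columns `Sequence`,
#'   `Modifications` and at least one `Intensity <sample>` column
#'   (`Proteins` and `Charge` are carried through when present).
#' @return data frame with columns `Sequence`, `Modifications`,
#'   `Proteins`, `Charge` and one numeric `Intensity <sample>` column per
#'   sample (`NA` = missing). The sample ids are attached as
#'   `attr(, "samples")`.
#' @export
read_peptide_table <- function(path, dialect = "peptides") {
  dialect <- match.arg(dialect, "peptides")
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  for (col in c("Sequence", "Modifications"))
    if (!col %in% names(df))
      stop("schema error: mandatory column '", col, "' is missing")
  int_cols <- grep("^Intensity ", names(df), value = TRUE)
  if (!length(int_cols))
    stop("schema error: no 'Intensity <sample>' columns found")
  for (col in int_cols) {
    raw <- trimws(df[[col]])
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & raw != "" & raw != "NaN" & is.na(num))
    if (length(bad))
      stop("parse error in column '", col, "', row ", bad[1L],
           ": cannot read '", raw[bad[1L]], "' as a number")
    num[!is.na(num) & num == 0] <- NA_real_
    df[[col]] <- num
  }
  if (!"Proteins" %in% names(df)) df$Proteins <- NA_character_
  df$Charge <- if ("Charge" %in% names(df))
    as.integer(df$Charge) else NA_integer_
  df$Sequence <- toupper(df$Sequence)
  ok <- grepl("^[ACDEFGHIKLMNPQRSTVWY]*$", df$Sequence)
  if (!all(ok))
    stop("non-standard residue in sequence at row ", which(!ok)[1L])
  attr(df, "samples") <- sub("^Intensity ", "", int_cols)
  df
}

#' Read a protein-level LFQ matrix with its experiment design
#'
#' Reads a tab-separated protein table (`proteinGroups` style) whose
#' quantification columns are named `LFQ intensity <sample>`. Sample
#' names must follow the `<condition>[@<window>]_<replicate>` convention
#' (see [design_from_names()]); the design is inferred from them. Raw
#' intensities are log2-transformed exactly once; zeros and blanks
#' become `NA`.
#'
#' @param path path to a TSV file with an id column (`Majority protein
#'   IDs`, or the first column as fallback) and `LFQ intensity *` columns.
#' @param window_levels optional explicit ordering of time-window labels.
#' @return a [quant_matrix()].
#' @export
read_protein_matrix <- function(path, window_levels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  lfq <- grep("^LFQ intensity ", names(df), value = TRUE)
  if (!length(lfq))
    stop("schema error: no 'LFQ intensity <sample>' columns found")
  id_col <- if ("Majority protein IDs" %in% names(df))
    "Majority protein IDs" else names(df)[1L]
  ids <- df[[id_col]]
  if (anyDuplicated(ids))
    stop("duplicate row id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- vapply(lfq, function(col) {
    num <- suppressWarnings(as.numeric(df[[col]]))
    num[!is.na(num) & num == 0] <- NA_real_
    num
  }, numeric(nrow(df)))
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(ids, sub("^LFQ intensity ", "", lfq)))
  if (any(vals[!is.na(vals)] < 0)) stop("negative raw intensity")
  vals <- log2(vals)
  quant_matrix(vals, design_from_names(colnames(vals), window_levels))
}

#' Read a proteome FASTA into a named sequence vector
#'
#' Ids are taken from the first whitespace-delimited header token; for
#' UniProt-style `db|ACCESSION|NAME` headers the accession is extracted.
#' Sequences are uppercased and trailing stop characters (`*`) stripped.
#'
#' @param path path to a FASTA file.
#' @return named character vector, id -> amino-acid sequence.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e)
                    stop("FASTA format error in ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  if (!length(set)) stop("FASTA format error: no sequences in ", path)
  ids <- vapply(strsplit(names(set), "[ \t]"), `[`, "", 1L)
  piped <- grepl("^[^|]+\\|[^|]+\\|", ids)
  ids[piped] <- vapply(strsplit(ids[piped], "|", fixed = TRUE),
                       `[`, "", 2L)
  seqs <- toupper(as.character(set))
  seqs <- sub("\\*+$", "", seqs)
  names(seqs) <- ids
  seqs
}

#' Write a results data frame as TSV
#'
#' Numeric columns are written with 17 significant digits so that
#' reading the table back reproduces every finite value bit-identically;
#' missing values are written as empty cells.
#'
#' @param df data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) {
      s <- sprintf("%.17g", out[[j]])
      s[is.na(out[[j]])] <- NA_character_
      out[[j]] <- s
    }
  utils::write.table(out, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}

#' Write a quant_matrix as a protein-level LFQ table
#'
#' Inverse of [read_protein_matrix()]: values are de-logged to the raw
#' intensity scale and missing cells written as 0, the non-detection
#' code of the upstream search engine.
#'
#' @param qm a [quant_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_protein_matrix <- function(qm, path) {
  raw <- 2^qm$values
  raw[is.na(raw)] <- 0
  df <- data.frame(`Majority protein IDs` = rownames(qm$values),
                   check.names = FALSE, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(raw)))
    df[[paste("LFQ intensity", colnames(raw)[j])]] <- raw[, j]
  write_results_table(df, path)
}

#' Write a peptide data frame as an Intensity-column TSV
#'
#' @param peptides data frame as returned by [read_peptide_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peptide_table <- function(peptides, path) {
  out <- peptides
  int_cols <- grep("^Intensity ", names(out), value = TRUE)
  for (col in int_cols) {
    v <- out[[col]]
    v[is.na(v)] <- 0
    out[[col]] <- v
  }
  write_results_table(out, path)
}
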