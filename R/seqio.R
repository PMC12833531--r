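#' Read a multi-record nucleotide FASTA file
#'
#' Parses a FASTA file (DNA or RNA alphabet, any case) into a data.frame of
#' raw sequence records, order preserved.  Residues are returned exactly as
#' read apart from removal of line breaks and whitespace; use
#' [normalizeToRna()] / [validateCds()] to obtain the canonical form.
#'
#' @param path path to an existing FASTA file.
#' @return data.frame with columns `id` (first header token), `description`
#'   (remainder of the header, possibly `""`) and `residues`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">a demo", "AUG", "UAA"), fa)
#' readFasta(fa)
#' @export
readFasta <- function(path) {
  if (!file.exists(path))
    stop("FASTA file not found: ", path)
  lines <- readLines(path)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) && !startsWith(trimws(lines[nonblank[1L]]), ">"))
    stop("malformed FASTA: sequence data before any header at line ",
         nonblank[1L])
  xs <- Biostrings::readBStringSet(path)
  if (length(xs) == 0L)
    stop("malformed FASTA: no records in ", path)
  headers <- names(xs)
  id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  residues <- gsub("[[:space:]]", "", as.character(xs))
  if (any(!nzchar(residues))) {
    empty <- which(!nzchar(residues))[1L]
    stop("malformed FASTA: empty record '", id[empty], "'")
  }
  data.frame(id = unname(id), description = unname(description),
             residues = unname(residues), stringsAsFactors = FALSE)
}

#' Normalize a nucleotide string to the canonical RNA alphabet
#'
#' Uppercases and transliterates T to U; all other IUPAC nucleotide codes
#' pass through unchanged (ambiguity codes are dealt with at validation
#' time).  Idempotent.
#'
#' @param residues a single nucleotide string (DNA or RNA, any case).
#' @return the normalized RNA string.
#' @examples
#' normalizeToRna("atgtttc")   # "AUGUUUC"
#' @export
normalizeToRna <- function(residues) {
  stopifnot(is.character(residues), length(residues) == 1L)
  out <- chartr("t", "u", toupper(residues))
  out <- chartr("T", "U", out)
  chars <- strsplit(out, "")[[1]]
  bad <- which(!chars %in% .IUPAC_RNA)
  if (length(bad))
    stop("non-IUPAC nucleotide character '", chars[bad[1L]],
         "' at position ", bad[1L])
  out
}

#' Validate a coding sequence into its canonical frame-anchored form
#'
#' Enforces the codon frame (length divisible by 3) and normalizes the
#' alphabet.  A missing AUG start or terminal stop codon is recorded as a
#' warning, never an error, since therapeutic constructs are frequently
#' supplied as CDS fragments.  Ambiguity codes are an error in strict mode;
#' otherwise they are recorded as warnings and any scan window containing
#' one is skipped downstream.
#'
#' @param residues nucleotide string, or a one-row record as returned by
#'   [readFasta()].
#' @param id sequence identifier; ignored when `residues` is a record.
#' @param strict reject ambiguity codes outright (default `FALSE`).
#' @param cdsStartOffset number of 5' nucleotides (e.g. a UTR) to discard
#'   before frame anchoring; default 0 assumes the input is exactly the CDS.
#' @return a [ValidatedCds-class] object.
#' @examples
#' validateCds("AUGUUUCUGAUAAGGUAA", id = "toy")
#' @export
validateCds <- function(residues, id = "cds", strict = FALSE,
                        cdsStartOffset = 0L) {
  if (is.data.frame(residues)) {
    stopifnot(nrow(residues) == 1L)
    id <- residues$id
    residues <- residues$residues
  }
  rna <- normalizeToRna(residues)
  if (cdsStartOffset > 0L) {
    if (cdsStartOffset >= nchar(rna))
      stop("cdsStartOffset (", cdsStartOffset,
           ") is not smaller than the sequence length (", nchar(rna), ")")
    rna <- substr(rna, cdsStartOffset + 1L, nchar(rna))
  }
  n <- nchar(rna)
  if (n %% 3L != 0L)
    stop("frame error: CDS length ", n, " is not divisible by 3",
         " (sequence '", id, "')")
  warnings <- character()
  chars <- strsplit(rna, "")[[1]]
  amb <- which(!chars %in% c("A", "C", "G", "U"))
  if (length(amb)) {
    if (strict)
      stop("ambiguity code '", chars[amb[1L]], "' at position ", amb[1L],
           " (strict mode)")
    warnings <- c(warnings,
                  paste0("ambiguity codes at position(s) ",
                         paste(amb, collapse = ",")))
  }
  if (substr(rna, 1L, 3L) != "AUG")
    warnings <- c(warnings, "no AUG start codon")
  if (!substr(rna, n - 2L, n) %in% c("UAA", "UAG", "UGA"))
    warnings <- c(warnings, "no terminal stop codon")
  new("ValidatedCds", id = id, rna = rna, nCodons = as.integer(n %/% 3L),
      warnings = warnings)
}

## ---- site / product report serialization -----------------------------------

# user-facing column order; positions are 1-based in files, as everywhere in R
.SITE_COLS <- c("cds_id", "codon", "nt_start", "motif", "slipped_base")
.PRODUCT_COLS <- c("cds_id", "codon", "nt_start", "motif",
                   "chimeric_peptide", "native_prefix_aa", "tail_peptide",
                   "tail_len_aa", "stop_in_shifted_frame", "classification")

.reportCols <- function(df) {
  if (all(.PRODUCT_COLS %in% names(df))) .PRODUCT_COLS
  else if (all(.SITE_COLS %in% names(df))) .SITE_COLS
  else stop("not a site or product report: columns ",
            paste(names(df), collapse = ", "))
}

#' Write a site or product report to TSV or JSON
#'
#' Columns are emitted in a fixed, deterministic order; all positions are
#' 1-based.  The JSON form round-trips losslessly through
#' [readReport()].
#'
#' @param report data.frame from [scanSlipperySites()] or
#'   [predictFrameshiftProducts()] (an empty report yields a header-only
#'   TSV / empty JSON array).
#' @param path output file path.
#' @param format `"tsv"` (default) or `"json"`.
#' @return `path`, invisibly.
#' @export
writeReport <- function(report, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  cols <- .reportCols(report)
  report <- report[, cols, drop = FALSE]
  if (format == "tsv") {
    utils::write.table(report, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  } else {
    jsonlite::write_json(report, path, dataframe = "rows",
                         auto_unbox = FALSE, digits = NA)
  }
  invisible(path)
}

#' Read back a report written by [writeReport()]
#'
#' @param path file path.
#' @param format `"tsv"` or `"json"`; inferred from the extension when
#'   missing.
#' @return the report data.frame.
#' @export
readReport <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
              else "tsv"
  if (format == "tsv") {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE,
                            colClasses = NA, comment.char = "")
  } else {
    df <- as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE),
                        stringsAsFactors = FALSE)
  }
  if (nrow(df) == 0L) return(df)
  for (col in c("codon", "nt_start", "native_prefix_aa", "tail_len_aa"))
    if (col %in% names(df)) df[[col]] <- as.integer(df[[col]])
  if ("stop_in_shifted_frame" %in% names(df))
    df$stop_in_shifted_frame <- as.logical(df$stop_in_shifted_frame)
  if ("tail_peptide" %in% names(df)) {
    df$tail_peptide <- as.character(df$tail_peptide)
    df$tail_peptide[is.na(df$tail_peptide)] <- ""
  }
  df
}
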