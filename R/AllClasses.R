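#' @import methods
NULL

# IUPAC nucleotide one-letter codes in the RNA alphabet (T already mapped to U)
.IUPAC_RNA <- c("A", "C", "G", "U",
                "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")

#' ValidatedCds: a frame-anchored coding sequence
#'
#' Canonical representation of a coding sequence consumed by the scanner,
#' the frameshift emulator and the recoder: uppercase RNA alphabet, length
#' divisible by 3, codon `c` occupying nucleotide positions `3c - 2` to `3c`
#' (1-based).  Ambiguity codes are tolerated (with warnings) unless the
#' sequence was validated in strict mode.
#'
#' @slot id single character, sequence identifier (FASTA header token).
#' @slot rna single character string over the IUPAC RNA alphabet.
#' @slot nCodons integer, number of codons; `nchar(rna) == 3 * nCodons`.
#' @slot warnings character vector of validation warnings (missing start
#'   codon, missing terminal stop, ambiguity codes).
#'
#' @seealso [validateCds()], [scanSlipperySites()]
#' @exportClass ValidatedCds
setClass("ValidatedCds",
  representation(
    id       = "character",
    rna      = "character",
    nCodons  = "integer",
    warnings = "character"
  )
)

setValidity("ValidatedCds", function(object) {
  msg <- character()
  if (length(object@id) != 1L || !nzchar(object@id))
    msg <- c(msg, "'id' must be a single non-empty string")
  if (length(object@rna) != 1L || !nzchar(object@rna))
    msg <- c(msg, "'rna' must be a single non-empty string")
  if (length(object@nCodons) != 1L ||
      nchar(object@rna) != 3L * object@nCodons)
    msg <- c(msg, "'rna' length must equal 3 * nCodons")
  bad <- setdiff(unique(strsplit(object@rna, "")[[1]]), .IUPAC_RNA)
  if (length(bad))
    msg <- c(msg, paste0("non-IUPAC characters in rna: ",
                         paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' FrameshiftVariant: a +1-slip-emulating single-deletion variant
#'
#' The sequence obtained from a parent CDS by deleting the slipped base
#' (4th nucleotide of a slippery motif).  Everything downstream of the
#' slippery codon is thereby placed in the parent's +1 reading frame, so
#' ordinary frame-0 translation of the variant yields the chimeric
#' frameshift product.
#'
#' @slot parentId id of the parent [ValidatedCds-class].
#' @slot ntStart 1-based position of the motif's first nucleotide in the
#'   parent.
#' @slot motif the matched motif, one of `"UUUU"`, `"UUUC"`, `"AAAG"`.
#' @slot rna variant sequence; `nchar` equals parent length minus one.
#'
#' @seealso [buildFrameshiftVariant()], [predictFrameshiftProduct()]
#' @exportClass FrameshiftVariant
setClass("FrameshiftVariant",
  representation(
    parentId = "character",
    ntStart  = "integer",
    motif    = "character",
    rna      = "character"
  )
)

setValidity("FrameshiftVariant", function(object) {
  msg <- character()
  if (!object@motif %in% c("UUUU", "UUUC", "AAAG"))
    msg <- c(msg, "'motif' must be one of UUUU, UUUC, AAAG")
  if (length(object@ntStart) != 1L || object@ntStart < 1L ||
      (object@ntStart - 1L) %% 3L != 0L)
    msg <- c(msg, "'ntStart' must be 1-based and codon-aligned")
  if (length(msg)) msg else TRUE
})

#' RecodedCds: a synonymously recoded coding sequence
#'
#' Result of [recodeAll()]: the parent CDS with every slippery codon
#' wobble-edited (UUU to UUC, AAA to AAG) so that no slippery motif
#' remains, while the encoded protein is unchanged residue-for-residue.
#'
#' @slot parentId id of the parent CDS.
#' @slot rna recoded sequence, same length as the parent.
#' @slot edits data.frame with columns `nt_pos` (1-based), `old_base`,
#'   `new_base`, one row per substitution.
#' @slot residualSites data.frame of sites still present after the final
#'   round (empty on convergence), in the format of [scanSlipperySites()].
#' @slot converged logical, `TRUE` when the final rescan found no sites.
#' @slot nRounds integer, scan/recode rounds performed.
#'
#' @seealso [recodeAll()], [recodeSite()]
#' @exportClass RecodedCds
setClass("RecodedCds",
  representation(
    parentId      = "character",
    rna           = "character",
    edits         = "data.frame",
    residualSites = "data.frame",
    converged     = "logical",
    nRounds       = "integer"
  )
)

## ---- accessors -------------------------------------------------------------

#' @describeIn ValidatedCds-class sequence identifier
#' @param x a `ValidatedCds`
#' @export
cdsId <- function(x) x@id

#' @describeIn ValidatedCds-class RNA sequence as a character string
#' @export
cdsRna <- function(x) x@rna

#' @describeIn ValidatedCds-class number of codons
#' @export
nCodons <- function(x) x@nCodons

#' @describeIn ValidatedCds-class validation warnings
#' @export
cdsWarnings <- function(x) x@warnings

#' @describeIn FrameshiftVariant-class variant RNA sequence
#' @param x a `FrameshiftVariant`
#' @export
variantRna <- function(x) x@rna

#' @describeIn RecodedCds-class recoded RNA sequence
#' @param x a `RecodedCds`
#' @export
recodedRna <- function(x) x@rna

#' @describeIn RecodedCds-class edit log (1-based positions)
#' @export
recodeEdits <- function(x) x@edits

#' @describeIn RecodedCds-class sites remaining after recoding
#' @export
residualSites <- function(x) x@residualSites

## ---- show ------------------------------------------------------------------

.clip <- function(s, n = 54L) {
  if (nchar(s) <= n) s else paste0(substr(s, 1L, n), "...")
}

setMethod("show", "ValidatedCds", function(object) {
  cat("ValidatedCds '", object@id, "': ", object@nCodons, " codons (",
      nchar(object@rna), " nt)\n  ", .clip(object@rna), "\n", sep = "")
  if (length(object@warnings))
    cat("  warnings: ", paste(object@warnings, collapse = "; "), "\n",
        sep = "")
})

setMethod("show", "FrameshiftVariant", function(object) {
  cat("FrameshiftVariant of '", object@parentId, "' (motif ", object@motif,
      " at nt ", object@ntStart, "): ", nchar(object@rna), " nt\n  ",
      .clip(object@rna), "\n", sep = "")
})

setMethod("show", "RecodedCds", function(object) {
  cat("RecodedCds of '", object@parentId, "': ", nrow(object@edits),
      " edit(s) in ", object@nRounds, " round(s); ",
      if (object@converged) "converged" else
        paste0(nrow(object@residualSites), " residual site(s)"),
      "\n  ", .clip(object@rna), "\n", sep = "")
})
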