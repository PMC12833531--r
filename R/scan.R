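#' Slippery motifs scanned by the pipeline
#'
#' The +1 frameshift-prone motif set: UUUX (X = U or C) and AAAG.  The first
#' three bases are the ribosome's decoded codon (Phe UUU or Lys AAA); the
#' 4th base is the one the ribosome slips past.
#'
#' @return named character vector mapping motif to its slipped base.
#' @examples
#' slipperyMotifs()
#' @export
slipperyMotifs <- function() {
  c(UUUU = "U", UUUC = "C", AAAG = "G")
}

.emptySites <- function() {
  data.frame(cds_id = character(), codon = integer(), nt_start = integer(),
             motif = character(), slipped_base = character(),
             stringsAsFactors = FALSE)
}

#' Scan a validated CDS for codon-aligned slippery sites
#'
#' Reports every position at which one of the slippery motifs (UUUU, UUUC,
#' AAAG) begins exactly on a codon boundary, i.e. its first three bases form
#' a complete in-frame codon.  Overlapping and adjacent matches are all
#' reported (a poly-U run can yield a site at each codon boundary it
#' covers).  Windows containing ambiguity codes never match and are thereby
#' skipped.
#'
#' @param cds a [ValidatedCds-class].
#' @return data.frame with one row per site, sorted by position, columns
#'   `cds_id`, `codon` (1-based codon number), `nt_start` (1-based position
#'   of the motif's first base; `nt_start == 3 * codon - 2`), `motif`,
#'   `slipped_base`.
#' @examples
#' cds <- validateCds("AUGUUUCUGAUAAGGUAA", id = "toy")
#' scanSlipperySites(cds)   # one UUUC site at nt_start 4
#' @export
scanSlipperySites <- function(cds) {
  stopifnot(is(cds, "ValidatedCds"))
  rna <- cds@rna
  n <- nchar(rna)
  starts <- seq.int(1L, by = 3L, length.out = cds@nCodons)
  starts <- starts[starts + 3L <= n]          # motif needs a 4th base
  if (!length(starts)) return(.emptySites())
  windows <- substring(rna, starts, starts + 3L)
  motifs <- slipperyMotifs()
  hit <- windows %in% names(motifs)
  if (!any(hit)) return(.emptySites())
  starts <- starts[hit]
  windows <- windows[hit]
  data.frame(
    cds_id = cds@id,
    codon = as.integer((starts - 1L) %/% 3L + 1L),
    nt_start = as.integer(starts),
    motif = windows,
    slipped_base = unname(motifs[windows]),
    stringsAsFactors = FALSE
  )
}
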