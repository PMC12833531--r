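#' Synonymously recode one slippery site
#'
#' Edits the wobble (3rd) base of the slippery codon: UUU becomes UUC
#' (Phe preserved) for the UUUU/UUUC motifs, AAA becomes AAG (Lys
#' preserved) for AAAG.  Exactly one base changes, the encoded protein is
#' untouched, and the edited window (UUCU, UUCC or AAGG) can no longer
#' match any slippery motif.
#'
#' @param cds a [ValidatedCds-class].
#' @param site one row from [scanSlipperySites()] on `cds`.
#' @return the edited RNA string (same length as the parent).
#' @examples
#' cds <- validateCds("AUGUUUCUGAUAAGGUAA", id = "toy")
#' recodeSite(cds, scanSlipperySites(cds)[1, ])  # "AUGUUCCUGAUAAGGUAA"
#' @export
recodeSite <- function(cds, site) {
  site <- .checkSite(cds, site)
  p <- as.integer(site$nt_start)
  newBase <- switch(substr(site$motif, 1L, 3L), UUU = "C", AAA = "G",
                    stop("unrecognized motif ", site$motif))
  rna <- cds@rna
  substr(rna, p + 2L, p + 2L) <- newBase    # wobble base of slippery codon
  rna
}

#' Remove all slippery sites by iterative synonymous recoding
#'
#' Iterates scan, recode every found site, rescan, until no sites remain or
#' `maxRounds` is exhausted.  Because the edited codons (UUC, AAG) cannot
#' seed a new motif and edits never touch a neighbouring site's window,
#' convergence is typically reached in one round; any residual sites are
#' reported, never raised.  The encoded protein is preserved exactly at
#' every round.
#'
#' @param cds a [ValidatedCds-class].
#' @param maxRounds maximum scan/recode rounds (default 5).
#' @return a [RecodedCds-class] carrying the recoded sequence, the edit log
#'   (1-based positions) and any residual sites.
#' @examples
#' cds <- validateCds("AUGUUUCUGAUAAGGUAA", id = "toy")
#' recodeAll(cds)
#' @export
recodeAll <- function(cds, maxRounds = 5L) {
  stopifnot(is(cds, "ValidatedCds"), maxRounds >= 1L)
  current <- cds
  edits <- data.frame(nt_pos = integer(), old_base = character(),
                      new_base = character(), stringsAsFactors = FALSE)
  rounds <- 0L
  sites <- scanSlipperySites(current)
  while (nrow(sites) > 0L && rounds < maxRounds) {
    rounds <- rounds + 1L
    for (i in seq_len(nrow(sites))) {
      pos <- sites$nt_start[i] + 2L
      old <- substr(current@rna, pos, pos)
      rna <- recodeSite(current, sites[i, ])
      edits <- rbind(edits, data.frame(
        nt_pos = pos, old_base = old, new_base = substr(rna, pos, pos),
        stringsAsFactors = FALSE))
      current <- new("ValidatedCds", id = cds@id, rna = rna,
                     nCodons = cds@nCodons, warnings = cds@warnings)
    }
    sites <- scanSlipperySites(current)
  }
  new("RecodedCds", parentId = cds@id, rna = current@rna, edits = edits,
      residualSites = sites, converged = nrow(sites) == 0L,
      nRounds = rounds)
}
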