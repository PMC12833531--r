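#' Translate an RNA string with the standard genetic code
#'
#' Codon-by-codon translation from position 1, halting at the first stop
#' codon (not included in the peptide) or at the last complete codon; a
#' trailing 1-2 nt remainder is ignored.  The codon table is the standard
#' genetic code (NCBI table 1), appropriate for human therapeutic mRNA.
#'
#' @param rna string over `{A,C,G,U}` (ambiguity codes inside a translated
#'   codon are an error).
#' @return list with `peptide` (amino-acid string, possibly `""`) and
#'   `stopFound` (logical).
#' @examples
#' translateRna("AUGUUUUGA")   # $peptide "MF", $stopFound TRUE
#' @export
translateRna <- function(rna) {
  stopifnot(is.character(rna), length(rna) == 1L)
  nc <- nchar(rna) %/% 3L
  if (nc == 0L) return(list(peptide = "", stopFound = FALSE))
  starts <- seq.int(1L, by = 3L, length.out = nc)
  codons <- substring(rna, starts, starts + 2L)
  aa <- unname(Biostrings::RNA_GENETIC_CODE[codons])
  firstStop <- match("*", aa)
  end <- if (is.na(firstStop)) nc else firstStop - 1L
  if (end > 0L && anyNA(aa[seq_len(end)])) {
    bad <- which(is.na(aa[seq_len(end)]))[1L]
    stop("cannot translate codon '", codons[bad], "' at nt position ",
         starts[bad], " (ambiguity code)")
  }
  list(peptide = paste(aa[seq_len(end)], collapse = ""),
       stopFound = !is.na(firstStop))
}

.checkSite <- function(cds, site) {
  stopifnot(is(cds, "ValidatedCds"))
  if (is.data.frame(site)) {
    stopifnot(nrow(site) == 1L)
    site <- as.list(site)
  }
  p <- as.integer(site$nt_start)
  window <- substr(cds@rna, p, p + 3L)
  if ((p - 1L) %% 3L != 0L || !identical(window, site$motif))
    stop("site integrity error: motif ", site$motif,
         " not found codon-aligned at nt ", p, " of '", cds@id,
         "' (window '", window, "')")
  site
}

#' Build the +1-frameshift-emulating variant for one site
#'
#' Deletes the single slipped nucleotide (the X of UUUX or the G of AAAG,
#' i.e. the 4th base of the motif) from the parent CDS.  Downstream of the
#' slippery codon the variant's frame-0 translation then equals the
#' parent's +1-frame translation, which is exactly the chimeric product a
#' +1 ribosomal slip would produce.
#'
#' @param cds the parent [ValidatedCds-class].
#' @param site one row of the data.frame returned by [scanSlipperySites()]
#'   on `cds`.
#' @return a [FrameshiftVariant-class] (length = parent length - 1).
#' @examples
#' cds <- validateCds("AUGUUUCUGAUAAGGUAA", id = "toy")
#' site <- scanSlipperySites(cds)[1, ]
#' variantRna(buildFrameshiftVariant(cds, site))  # "AUGUUUUGAUAAGGUAA"
#' @export
buildFrameshiftVariant <- function(cds, site) {
  site <- .checkSite(cds, site)
  p <- as.integer(site$nt_start)
  del <- p + 3L                       # the slipped base
  rna <- paste0(substr(cds@rna, 1L, del - 1L),
                substr(cds@rna, del + 1L, nchar(cds@rna)))
  new("FrameshiftVariant", parentId = cds@id, ntStart = p,
      motif = site$motif, rna = rna)
}

#' Predict the chimeric protein product of a +1 slip at one site
#'
#' Builds the single-deletion variant, translates it from the start, and
#' decomposes the resulting chimeric peptide into the native prefix (all
#' codons up to and including the slippery codon, identical to the parent
#' protein) and the shifted tail (residues read in the +1 frame up to the
#' first stop).  The product is classified by tail length:
#' `null_product` (tail of 0 aa -- the slip runs straight into a stop),
#' `short_tail` (shorter than `minTailAa`), or `long_tail`.
#'
#' @param cds the parent [ValidatedCds-class].
#' @param site one row from [scanSlipperySites()].
#' @param minTailAa minimum shifted-tail length (amino acids) for a product
#'   to be considered a potentially functional polypeptide; default 20.
#' @return one-row data.frame with columns `cds_id`, `codon`, `nt_start`,
#'   `motif`, `chimeric_peptide`, `native_prefix_aa`, `tail_peptide`,
#'   `tail_len_aa`, `stop_in_shifted_frame`, `classification`.
#' @examples
#' cds <- validateCds("AUGUUUCUGAUAAGGUAA", id = "toy")
#' site <- scanSlipperySites(cds)[1, ]
#' predictFrameshiftProduct(cds, site)   # peptide "MF", null_product
#' @export
predictFrameshiftProduct <- function(cds, site, minTailAa = 20L) {
  stopifnot(minTailAa >= 0L)
  if (is.data.frame(site)) site <- as.list(site[1L, ])
  variant <- buildFrameshiftVariant(cds, site)
  tr <- translateRna(variant@rna)
  prefixAa <- as.integer(site$codon)       # codons 1..codon incl. slippery
  chim <- tr$peptide
  tailLen <- max(0L, nchar(chim) - prefixAa)
  tail <- if (tailLen > 0L)
    substr(chim, nchar(chim) - tailLen + 1L, nchar(chim)) else ""
  classification <- if (tailLen == 0L) "null_product"
    else if (tailLen < minTailAa) "short_tail"
    else "long_tail"
  data.frame(
    cds_id = cds@id, codon = prefixAa, nt_start = as.integer(site$nt_start),
    motif = site$motif, chimeric_peptide = chim,
    native_prefix_aa = prefixAa, tail_peptide = tail,
    tail_len_aa = tailLen, stop_in_shifted_frame = tr$stopFound,
    classification = classification, stringsAsFactors = FALSE
  )
}

.emptyProducts <- function() {
  data.frame(cds_id = character(), codon = integer(), nt_start = integer(),
             motif = character(), chimeric_peptide = character(),
             native_prefix_aa = integer(), tail_peptide = character(),
             tail_len_aa = integer(), stop_in_shifted_frame = logical(),
             classification = character(), stringsAsFactors = FALSE)
}

#' Predict products for every detected site of a CDS
#'
#' @param cds a [ValidatedCds-class].
#' @param sites data.frame from [scanSlipperySites()]; scanned afresh when
#'   missing.
#' @inheritParams predictFrameshiftProduct
#' @return data.frame with one row per site (see
#'   [predictFrameshiftProduct()]), empty when the CDS is clean.
#' @export
predictFrameshiftProducts <- function(cds, sites = scanSlipperySites(cds),
                                      minTailAa = 20L) {
  if (nrow(sites) == 0L) return(.emptyProducts())
  do.call(rbind, lapply(seq_len(nrow(sites)), function(i)
    predictFrameshiftProduct(cds, sites[i, ], minTailAa = minTailAa)))
}

#' Export putative frameshift peptides as a FASTA file
#'
#' One entry per product; the header encodes parent id, 1-based site
#' position, motif and classification, and the sequence is the chimeric
#' peptide -- directly usable as a BLASTx/BLASTp query set for external
#' cross-reactivity screening.
#'
#' @param products data.frame from [predictFrameshiftProducts()].
#' @param path output FASTA path (an empty product set produces an empty
#'   file and a warning).
#' @return `path`, invisibly.
#' @export
exportPutativePeptides <- function(products, path) {
  if (nrow(products) == 0L) {
    file.create(path)
    warning("no frameshift products to export; wrote empty file ", path)
    return(invisible(path))
  }
  keep <- nzchar(products$chimeric_peptide)
  if (!all(keep))
    warning(sum(!keep), " product(s) with empty peptide skipped")
  products <- products[keep, , drop = FALSE]
  aa <- Biostrings::AAStringSet(products$chimeric_peptide)
  names(aa) <- sprintf("%s|site%d|%s|%s", products$cds_id,
                       products$nt_start, products$motif,
                       products$classification)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}
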