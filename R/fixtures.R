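# run expr with a locally seeded RNG, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

.STOP_CODONS <- c("UAA", "UAG", "UGA")

# all 61 sense codons with sampling weights at a target GC fraction
.senseCodonWeights <- function(gcFraction) {
  stopifnot(gcFraction >= 0, gcFraction <= 1)
  bases <- c("A", "C", "G", "U")
  pBase <- c(A = (1 - gcFraction) / 2, C = gcFraction / 2,
             G = gcFraction / 2, U = (1 - gcFraction) / 2)
  grid <- expand.grid(b1 = bases, b2 = bases, b3 = bases,
                      stringsAsFactors = FALSE)
  codons <- paste0(grid$b1, grid$b2, grid$b3)
  w <- pBase[grid$b1] * pBase[grid$b2] * pBase[grid$b3]
  keep <- !codons %in% .STOP_CODONS
  stats::setNames(w[keep] / sum(w[keep]), codons[keep])
}

.sampleSense <- function(n, weights) {
  sample(names(weights), n, replace = TRUE, prob = weights)
}

#' Brute-force slippery-site oracle
#'
#' Independent reference scanner used to validate [scanSlipperySites()]: a
#' literal regex sliding-window pass over every position of the raw string
#' (implemented without sharing any code with the production scanner),
#' keeping a match at 1-based position `p` only when `p %% 3 == 1`, i.e.
#' when the motif starts on a codon boundary.
#'
#' @param rna RNA string (need not be a validated CDS).
#' @param id sequence id to put in the `cds_id` column.
#' @return data.frame in the format of [scanSlipperySites()].
#' @examples
#' oracleScan("UUUUUUU")   # sites at nt 1 and 4
#' @export
oracleScan <- function(rna, id = "seq") {
  stopifnot(is.character(rna), length(rna) == 1L)
  m <- gregexpr("(?=(UUU[UC]|AAAG))", rna, perl = TRUE)[[1]]
  hits <- integer(0)
  if (m[1L] != -1L) hits <- as.integer(m)
  hits <- hits[(hits - 1L) %% 3L == 0L]
  if (!length(hits)) return(.emptySites())
  motif <- substring(rna, hits, hits + 3L)
  data.frame(cds_id = id, codon = (hits - 1L) %/% 3L + 1L,
             nt_start = hits, motif = motif,
             slipped_base = substring(motif, 4L, 4L),
             stringsAsFactors = FALSE)
}

#' Random coding sequence (slippery sites allowed)
#'
#' Draws `nCodons` codons -- AUG start, random sense codons weighted toward
#' the requested GC fraction, random terminal stop -- without removing any
#' slippery motif that arises by chance.  Used for stress-testing the
#' scanner against the oracle; use [generateCleanCds()] for motif-free
#' backgrounds.
#'
#' @param nCodons number of codons (>= 3).
#' @param gcFraction target GC content of the random background in
#'   `[0, 1]`; default 0.5.
#' @param seed integer seed for reproducibility (`NULL` leaves the RNG
#'   state alone).
#' @param id sequence id.
#' @return a [ValidatedCds-class].
#' @export
randomCds <- function(nCodons, gcFraction = 0.5, seed = NULL, id = "random") {
  stopifnot(nCodons >= 3L)
  .withSeed(seed, {
    w <- .senseCodonWeights(gcFraction)
    body <- .sampleSense(nCodons - 2L, w)
    rna <- paste0("AUG", paste(body, collapse = ""),
                  sample(.STOP_CODONS, 1L))
    new("ValidatedCds", id = id, rna = rna, nCodons = as.integer(nCodons),
        warnings = character())
  })
}

#' Generate a slippery-site-free random CDS
#'
#' Draws a random CDS and then resamples every codon at which the oracle
#' still finds a slippery motif, rescanning after each pass, until the
#' sequence is verifiably clean.  Deterministic for a fixed seed.
#'
#' @inheritParams randomCds
#' @param maxIter resampling passes before giving up (practically never
#'   reached; a pass removes almost all remaining motifs).
#' @return a [ValidatedCds-class] with `oracleScan()` provably empty.
#' @examples
#' cds <- generateCleanCds(50, seed = 1)
#' nrow(oracleScan(cdsRna(cds)))   # 0
#' @export
generateCleanCds <- function(nCodons, gcFraction = 0.5, seed = NULL,
                             id = "clean", maxIter = 50L) {
  stopifnot(nCodons >= 3L)
  .withSeed(seed, {
    w <- .senseCodonWeights(gcFraction)
    codons <- c("AUG", .sampleSense(nCodons - 2L, w),
                sample(.STOP_CODONS, 1L))
    for (iter in seq_len(maxIter)) {
      rna <- paste(codons, collapse = "")
      sites <- oracleScan(rna)
      if (nrow(sites) == 0L)
        return(new("ValidatedCds", id = id, rna = rna,
                   nCodons = as.integer(nCodons), warnings = character()))
      # resample the slippery codon of each remaining site (never the
      # fixed AUG start; UUU/AAA cannot be the terminal stop)
      idx <- unique(pmax(sites$codon, 2L))
      codons[idx] <- .sampleSense(length(idx), w)
    }
    stop("failed to generate a clean CDS after ", maxIter,
         " resampling passes (nCodons=", nCodons,
         ", gcFraction=", gcFraction, ")")
  })
}

#' Plant slippery motifs at known codon positions
#'
#' For each `(codonIndex, motif)` pair, writes the motif's first three
#' bases into codon `codonIndex` and its 4th base into the first position
#' of the following codon.  Planted codon indices must be at least 2 apart
#' (adjacent planting windows share the junction base) and leave room for
#' the following codon.  If setting the junction base would turn the
#' following codon into a premature stop, its remaining two bases are
#' resampled to a sense codon.  The result is verified against the oracle:
#' detected sites must equal planted sites exactly, otherwise the
#' background is regenerated with a fresh seed (accidental junction motifs
#' are rare but possible).
#'
#' @param cds a clean [ValidatedCds-class] from [generateCleanCds()], or
#'   `NULL` to generate one.
#' @param planted data.frame with columns `codon` (1-based codon number,
#'   `2 <= codon <= nCodons - 1`) and `motif`.
#' @param seed seed used for stop-avoidance resampling and background
#'   regeneration.
#' @param maxAttempts background regenerations allowed before erroring.
#' @param ... passed to [generateCleanCds()] when `cds` is `NULL`.
#' @return a [ValidatedCds-class] whose detected sites are exactly the
#'   planted ones.
#' @examples
#' cds <- plantSites(planted = data.frame(codon = 3, motif = "UUUC"),
#'                   seed = 1, nCodons = 30)
#' scanSlipperySites(cds)
#' @export
plantSites <- function(cds = NULL, planted, seed = NULL,
                       maxAttempts = 20L, ...) {
  stopifnot(is.data.frame(planted),
            all(c("codon", "motif") %in% names(planted)))
  planted$codon <- as.integer(planted$codon)
  planted$motif <- as.character(planted$motif)
  if (!all(planted$motif %in% names(slipperyMotifs())))
    stop("unknown motif(s): ",
         paste(setdiff(planted$motif, names(slipperyMotifs())),
               collapse = ", "))
  if (anyDuplicated(planted$codon))
    stop("planted codon indices must be distinct")
  cs <- sort(planted$codon)
  if (length(cs) > 1L && any(diff(cs) < 2L))
    stop("planting windows overlap: codon indices must be >= 2 apart")

  .withSeed(seed, {
    for (attempt in seq_len(maxAttempts)) {
      base <- if (is.null(cds) || attempt > 1L)
        generateCleanCds(...) else cds
      if (any(planted$codon < 2L | planted$codon > base@nCodons - 1L))
        stop("planted codon indices must lie in [2, nCodons - 1]")
      codons <- substring(base@rna,
                          seq.int(1L, by = 3L, length.out = base@nCodons),
                          seq.int(3L, by = 3L, length.out = base@nCodons))
      w <- .senseCodonWeights(0.5)
      for (i in seq_len(nrow(planted))) {
        ci <- planted$codon[i]
        motif <- planted$motif[i]
        codons[ci] <- substr(motif, 1L, 3L)
        nxt <- paste0(substr(motif, 4L, 4L), substr(codons[ci + 1L], 2L, 3L))
        while (nxt %in% .STOP_CODONS) {
          tail2 <- substr(.sampleSense(1L, w), 2L, 3L)
          nxt <- paste0(substr(motif, 4L, 4L), tail2)
        }
        codons[ci + 1L] <- nxt
      }
      rna <- paste(codons, collapse = "")
      found <- oracleScan(rna, id = base@id)
      ok <- nrow(found) == nrow(planted) &&
        setequal(paste(found$codon, found$motif),
                 paste(planted$codon, planted$motif))
      if (ok) {
        warn <- character()
        n <- nchar(rna)
        if (!substr(rna, n - 2L, n) %in% .STOP_CODONS)
          warn <- "no terminal stop codon"
        return(new("ValidatedCds", id = base@id, rna = rna,
                   nCodons = base@nCodons, warnings = warn))
      }
      if (!is.null(cds) && attempt == 1L && maxAttempts > 1L &&
          length(list(...)) == 0L)
        stop("planting into the supplied CDS created accidental sites; ",
             "pass generation arguments (e.g. nCodons) to allow ",
             "regeneration, or supply a different background")
    }
    stop("could not realize the planted-site specification in ",
         maxAttempts, " attempts")
  })
}
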