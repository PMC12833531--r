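test_that("translateRna halts at the first stop and drops remainders", {
  expect_equal(translateRna("AUGUUUUGA"),
               list(peptide = "MF", stopFound = TRUE))
  expect_equal(translateRna("AUGUUU"),
               list(peptide = "MF", stopFound = FALSE))
  expect_equal(translateRna("AUGUUUCU"),
               list(peptide = "MF", stopFound = FALSE))
  expect_equal(translateRna("UAAAUG"),
               list(peptide = "", stopFound = TRUE))
  expect_error(translateRna("AUGNNNUAA"), "position 4")
  # ambiguity after the first stop is never reached
  expect_equal(translateRna("AUGUAANNN")$peptide, "M")
})

test_that("translateRna agrees with Biostrings translation", {
  for (seed in 1:20) {
    cds <- randomCds(80, gcFraction = 0.4, seed = seed)
    expect_identical(translateRna(cdsRna(cds))$peptide,
                     biostringsTranslate(cdsRna(cds)))
  }
})

test_that("buildFrameshiftVariant deletes exactly the slipped base", {
  cds <- toyCds()
  site <- scanSlipperySites(cds)[1, ]
  v <- buildFrameshiftVariant(cds, site)
  expect_identical(variantRna(v), "AUGUUUUGAUAAGGUAA")
  expect_equal(nchar(variantRna(v)), nchar(cdsRna(cds)) - 1L)

  k <- validateCds("AUGAAAGGGUAA", id = "k")
  vk <- buildFrameshiftVariant(k, scanSlipperySites(k)[1, ])
  expect_identical(variantRna(vk), "AUGAAAGGUAA")

  # a site that does not match the sequence is an integrity error
  bogus <- data.frame(cds_id = "toy", codon = 1L, nt_start = 1L,
                      motif = "AAAG", slipped_base = "G")
  expect_error(buildFrameshiftVariant(cds, bogus), "integrity")
})

test_that("predictFrameshiftProduct decomposes and classifies the chimera", {
  p <- predictFrameshiftProduct(toyCds(), scanSlipperySites(toyCds())[1, ])
  expect_equal(p$chimeric_peptide, "MF")
  expect_equal(p$native_prefix_aa, 2L)
  expect_equal(p$tail_len_aa, 0L)
  expect_equal(p$tail_peptide, "")
  expect_true(p$stop_in_shifted_frame)
  expect_equal(p$classification, "null_product")

  k <- validateCds("AUGAAAGGGUAA", id = "k")
  pk <- predictFrameshiftProduct(k, scanSlipperySites(k)[1, ])
  expect_equal(pk$chimeric_peptide, "MKG")
  expect_equal(pk$tail_len_aa, 1L)
  expect_false(pk$stop_in_shifted_frame)
  expect_equal(pk$classification, "short_tail")
})

test_that("classification moves monotonically toward null as the
          threshold rises, and never the reverse", {
  ranks <- c(null_product = 0L, short_tail = 1L, long_tail = 2L)
  for (seed in 1:10) {
    cds <- plantSites(planted = data.frame(codon = c(5, 20),
                                           motif = c("UUUU", "AAAG")),
                      seed = seed, nCodons = 120, id = "m")
    sites <- scanSlipperySites(cds)
    prev <- NULL
    for (thr in c(0L, 1L, 5L, 20L, 1000L)) {
      cls <- ranks[predictFrameshiftProducts(cds, sites, thr)$classification]
      if (!is.null(prev)) expect_true(all(cls <= prev))
      prev <- cls
    }
  }
})

test_that("product count equals site count and no upstream site appears", {
  for (seed in 1:10) {
    n <- sample(40:150, 1)
    cds <- randomCds(n, gcFraction = 0.35, seed = seed)
    sites <- scanSlipperySites(cds)
    prods <- predictFrameshiftProducts(cds, sites)
    expect_equal(nrow(prods), nrow(sites))
    for (i in seq_len(nrow(sites))) {
      v <- buildFrameshiftVariant(cds, sites[i, ])
      upstream <- oracleScan(substr(variantRna(v), 1L, sites$nt_start[i] - 1L))
      parentUp <- oracleScan(substr(cdsRna(cds), 1L, sites$nt_start[i] - 1L))
      expect_equal(upstream$nt_start, parentUp$nt_start)
      expect_equal(upstream$motif, parentUp$motif)
    }
  }
})

test_that("exportPutativePeptides writes BLAST-ready FASTA", {
  prods <- predictFrameshiftProducts(toyCds())
  path <- tempfile(fileext = ".fasta")
  exportPutativePeptides(prods, path)
  lines <- readLines(path)
  expect_equal(lines[1], ">toy|site4|UUUC|null_product")
  expect_equal(lines[2], "MF")

  expect_warning(exportPutativePeptides(prods[0, ], path), "empty file")
  expect_equal(file.size(path), 0)
})
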