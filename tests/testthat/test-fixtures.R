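test_that("oracleScan applies the literal frame-filtered window rule", {
  expect_equal(oracleScan("UUUU")$nt_start, 1L)
  expect_equal(nrow(oracleScan("AUUUU")), 0L)       # off-frame match rejected
  expect_equal(oracleScan("UUUUUU")$nt_start, 1L)   # window at 4 incomplete
  expect_equal(oracleScan("UUUUUUU")$nt_start, c(1L, 4L))
  expect_equal(oracleScan("AUGAAAGUAA")$motif, "AAAG")
  expect_equal(nrow(oracleScan("ACGUACGU")), 0L)
})

test_that("generators are seed-deterministic", {
  a <- generateCleanCds(100, gcFraction = 0.4, seed = 1)
  b <- generateCleanCds(100, gcFraction = 0.4, seed = 1)
  expect_identical(cdsRna(a), cdsRna(b))
  expect_false(identical(cdsRna(a),
                         cdsRna(generateCleanCds(100, gcFraction = 0.4,
                                                 seed = 2))))
  expect_identical(cdsRna(randomCds(50, seed = 9)),
                   cdsRna(randomCds(50, seed = 9)))
})

test_that("clean sequences are motif-free, well-formed and GC-controlled", {
  for (gc in c(0.3, 0.5, 0.7)) {
    cds <- generateCleanCds(400, gcFraction = gc, seed = round(100 * gc))
    rna <- cdsRna(cds)
    expect_equal(nchar(rna), 1200L)
    expect_equal(nrow(oracleScan(rna)), 0L)
    expect_identical(substr(rna, 1, 3), "AUG")
    expect_true(substr(rna, 1198, 1200) %in% c("UAA", "UAG", "UGA"))
    gcObs <- mean(strsplit(rna, "")[[1]] %in% c("G", "C"))
    expect_lt(abs(gcObs - gc), 0.08)
  }
})

test_that("planted sites are recovered exactly, including boundaries", {
  # single site
  one <- plantSites(planted = data.frame(codon = 3, motif = "UUUC"),
                    seed = 1, nCodons = 30)
  expect_equal(scanSlipperySites(one)$nt_start, 7L)

  # k disjoint sites
  planted <- data.frame(codon = c(2, 10, 25, 40, 55),
                        motif = c("UUUU", "UUUC", "AAAG", "UUUU", "AAAG"))
  five <- plantSites(planted = planted, seed = 2, nCodons = 60)
  hit <- scanSlipperySites(five)
  expect_equal(hit$codon, planted$codon)
  expect_equal(hit$motif, planted$motif)

  # last allowed codon index: nCodons - 1 (the motif's 4th base lands in
  # the final codon)
  last <- plantSites(planted = data.frame(codon = 29, motif = "AAAG"),
                     seed = 3, nCodons = 30)
  expect_equal(scanSlipperySites(last)$nt_start, 3L * 29L - 2L)
})

test_that("invalid planting specifications are rejected", {
  expect_error(plantSites(planted = data.frame(codon = c(5, 6),
                                               motif = c("UUUU", "UUUU")),
                          seed = 1, nCodons = 30),
               "overlap")
  expect_error(plantSites(planted = data.frame(codon = 5, motif = "GGGG"),
                          seed = 1, nCodons = 30),
               "unknown motif")
  expect_error(plantSites(planted = data.frame(codon = 29, motif = "UUUU"),
                          seed = 1, nCodons = 29),
               "nCodons - 1")
})

test_that("production scanner and oracle agree on adversarial fixtures", {
  set.seed(42)
  for (i in 1:50) {
    cds <- randomCds(sample(50:400, 1),
                     gcFraction = sample(c(0.25, 0.5, 0.7), 1),
                     seed = sample.int(1e6, 1), id = "adv")
    a <- scanSlipperySites(cds)
    b <- oracleScan(cdsRna(cds), id = "adv")
    expect_identical(a, b)
  }
})
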