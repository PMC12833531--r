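# standard planted fixture used by the validation suite: clean random
# background of 100-400 codons at mixed GC, 1-10 planted sites >= 2 codons
# apart; returns the CDS together with its ground-truth site table
makePlantedFixture <- function(seed) {
  set.seed(seed)
  nCodons <- sample(100:400, 1)
  gc <- sample(c(0.3, 0.5, 0.7), 1)
  k <- sample(1:10, 1)
  codons <- sort(sample(seq(2L, nCodons - 1L, by = 2L), k))
  planted <- data.frame(codon = codons,
                        motif = sample(names(slipperyMotifs()), k,
                                       replace = TRUE))
  cds <- plantSites(planted = planted, seed = seed + 1L,
                    nCodons = nCodons, gcFraction = gc,
                    id = paste0("fixture", seed))
  list(cds = cds, planted = planted)
}
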