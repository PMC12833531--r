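# hand-checkable toy CDS: AUG UUU CUG AUA AGG UAA -> protein MFLIR,
# one UUUC slippery site anchored on codon 2 (nt 4-7)
toyCds <- function() validateCds("AUGUUUCUGAUAAGGUAA", id = "toy")

writeFastaText <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}

# translation truncated at the first stop, via Biostrings -- independent of
# the package's own codon walk
biostringsTranslate <- function(rna) {
  full <- as.character(Biostrings::translate(
    Biostrings::RNAString(substr(rna, 1L, 3L * (nchar(rna) %/% 3L)))))
  sub("\\*.*$", "", full)
}
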