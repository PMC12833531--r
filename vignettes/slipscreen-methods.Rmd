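---
title: "Screening therapeutic mRNA for +1 frameshift slippery sites"
author: "slipscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening therapeutic mRNA for +1 frameshift slippery sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slipscreen)
```

## Background and model

Therapeutic mRNAs — CAR constructs for transient T-cell engineering among
them — are commonly synthesized with N1-methylpseudouridine in place of
uridine. The modified base stabilizes the transcript and blunts innate
immune sensing, but it also makes the ribosome measurably more prone to
**+1 frameshifting** at *slippery sequences*: short runs where the P-site
tRNA can re-pair after the ribosome slips one nucleotide forward. A slip
places everything downstream in the +1 frame, so the cell produces a
chimeric protein — the native N-terminus up to the slip site, fused to an
unintended C-terminal peptide read in the wrong frame until the first stop
codon. For an mRNA drug this is an off-target protein that must be screened
for before use.

`slipscreen` implements that screen as a deterministic sequence-analysis
pipeline over a coding sequence (CDS) $s_1 s_2 \dots s_{3n}$ of $n$ codons:

1. **Detection.** Report every codon-aligned occurrence of a slippery
   motif. The motif set is UUU**X** with X ∈ {U, C}, plus AAA**G**: the
   first three bases are the codon the ribosome is decoding (Phe UUU or
   Lys AAA), the 4th base is the one it slips past. A window starting at
   nucleotide $p$ (1-based) is a site iff $p \equiv 1 \pmod 3$ — the motif
   is anchored on a codon — and $s_p s_{p+1} s_{p+2} s_{p+3}$ is in the
   motif set. Codon alignment is the central interpretive choice: +1
   slippage happens on the decoded UUU/AAA codon, so a 4-mer that is not
   anchored on a codon cannot be "in frame". Every matching window is
   reported independently, so a poly-U run yields a site at each codon
   boundary it covers.

2. **Emulation.** For each site, the +1 slip is emulated by *deleting* the
   slipped 4th base. Deletion — not substitution — is what places all
   downstream sequence in the +1 frame; ordinary frame-0 translation of
   the variant is then exactly the chimeric product of a slip at that
   site. Each site gets its own single-deletion variant: a ribosome slips
   once per event, so multi-site combinations are not modeled.

3. **Product prediction.** The variant is translated with the standard
   genetic code (NCBI table 1 — the sequences are human therapeutic
   constructs; no alternative codes are supported), halting at the first
   stop codon. The chimeric peptide decomposes into the *native prefix*
   (codons 1 … slip codon, identical to the parent protein) and the
   *shifted tail* read in the +1 frame.

4. **Classification.** Whether a chimeric product is a biologically
   meaningful polypeptide is not decidable from the sequence alone; the
   package uses the shifted-tail length as a deterministic, testable
   proxy. With threshold `minTailAa` (default **20 aa** — below the length
   of the shortest structured protein domains and of typical MHC-relevant
   antigenic stretches): `null_product` (tail of 0 aa, the slip runs
   straight into a stop), `short_tail` (< `minTailAa`), `long_tail`
   (≥ `minTailAa`). The definitive cross-reactivity call is delegated to
   external homology screening: `exportPutativePeptides()` writes every
   chimeric peptide as a BLASTx/BLASTp-ready FASTA. Classification is
   monotone in the threshold — raising `minTailAa` can only move a product
   toward `null_product`, never the reverse.

5. **Mitigation.** `recodeAll()` removes sites by synonymous recoding of
   the slippery codon's wobble base: UUU → UUC (Phe) for UUUU/UUUC, AAA →
   AAG (Lys) for AAAG. The wobble base is targeted because the genetic
   code guarantees synonymy there, whereas the 4th (downstream-codon)
   base is generally not synonymously editable. The edited windows
   (UUCU, UUCC, AAGG) match no motif, and an edit can touch no other
   site's window, so a single scan/recode round converges in practice;
   the implementation nevertheless iterates scan → recode → rescan (up to
   `maxRounds`, default 5) and reports any residual sites rather than
   assuming convergence.

## Frame anchoring and input conventions

"In frame" is meaningless without a frame anchor, so inputs are treated as
exact CDSs: length must be divisible by 3 (an error otherwise), while a
missing AUG start or terminal stop is only a warning — constructs are
frequently supplied as CDS fragments. A full transcript with UTRs can be
supplied with `cdsStartOffset` (the `--cds-start-offset` flag), which
discards the 5′ leader before anchoring.

All coordinates in reports, edit logs and FASTA headers are **1-based and
fully closed**, matching both R convention and what practitioners expect in
sequence tooling; the same 1-based convention is used internally (R's
native indexing), so there is no translation layer to get wrong.

Alphabet handling: input may be DNA or RNA, any case; everything is
normalized to uppercase RNA (T → U) first, and scanning/recoding are
invariant under that transliteration. IUPAC ambiguity codes are an error in
`strict` mode; by default they are recorded as warnings, and since a window
containing an ambiguity character can never equal a motif, such windows are
skipped — appropriate because a synthesized construct sequence is fully
specified, so ambiguity codes indicate an upstream data problem, not
biology.

## The synthetic-fixture generator and the oracle

The package is validated entirely on synthetic data it generates itself:

* `randomCds()` draws codons independently — fixed AUG start, body sampled
  uniformly over the 61 sense codons weighted toward a target GC fraction
  (each base position G/C with probability `gcFraction`), random terminal
  stop. Defaults: `gcFraction = 0.5`; validation sweeps 0.3/0.5/0.7 to
  cover AU-rich backgrounds (motif-dense, the hard case) through GC-rich
  ones.
* `generateCleanCds()` produces a verifiably motif-free background:
  after the initial draw, every codon at which the oracle still finds a
  site is resampled and the sequence rescanned, iterating until clean.
  Cleaning is local to the offending codons (a whole-sequence redraw
  would essentially never terminate on long AU-rich sequences, where
  dozens of motifs arise by chance) and the result is still
  oracle-verified and seed-deterministic.
* `plantSites()` writes motifs at chosen codons — codon $c$ takes the
  motif's first three bases, the first base of codon $c+1$ its 4th.
  Planted codons must be ≥ 2 apart (adjacent planting windows share the
  junction base) and within $[2, n-1]$. If the junction base would turn
  codon $c+1$ into a premature stop, that codon's remaining two bases are
  resampled to a sense codon, keeping chimeric-product decomposition well
  defined on fixtures. Planting is verified against the oracle —
  detected sites must equal planted sites exactly — and on the rare
  accidental junction motif the background is regenerated rather than
  repaired, so the planted set remains the exact truth set.
* `oracleScan()` is the independent referee: a literal regex
  sliding-window pass over every position with a frame filter, sharing no
  code with the production scanner. Wherever a reference scanner would be
  wanted, the oracle is it; the production scanner is never compared
  against itself.

What the fixtures do **not** emulate: human codon-usage bias, UTRs,
secondary structure, and the chemistry of modified bases. Passing tests
therefore demonstrate that the algorithms are correct on fully specified
CDSs, not that any particular real construct is safe — the screen's
biological significance still rests on the external homology step.

## Validation strategy and problem sizes

The test suite and `scripts/acceptance.R` recompute, from scratch:

* **Oracle equivalence** on 1,000 random CDSs of 100–2,000 codons at GC
  0.3/0.5/0.7 — exact set equality of (position, motif) pairs.
* **Planted-site recovery** on 200 fixtures with 1–10 planted sites each.
* **Frame-emulation identity**: for every detected site, frame-0
  translation of the variant downstream of the slip equals +1-frame
  translation of the parent, codon for codon to the first stop.
* **Prefix conservation**: every chimeric peptide begins with the parent
  protein's own prefix through the slippery codon.
* **Recoding soundness**: residue-exact protein identity and convergence
  with zero residual sites across the fixture set.
* A fully hand-checkable worked example (below).

These sizes exercise the scanner well past typical construct length
(a CAR CDS is ≈ 500 codons) while keeping the whole suite fast.

## Worked example

`AUG UUU CUG AUA AGG UAA` encodes MFLIR. The UUUC window at nucleotides
4–7 is anchored on codon 2:

```{r toy}
cds <- validateCds("AUGUUUCUGAUAAGGUAA", id = "toy")
scanSlipperySites(cds)
variantRna(buildFrameshiftVariant(cds, scanSlipperySites(cds)[1, ]))
predictFrameshiftProduct(cds, scanSlipperySites(cds)[1, ])
recodedRna(recodeAll(cds))
```

Deleting the slipped C gives `AUGUUUUGA…`: UGA immediately follows the
slippery codon, the chimeric product is just MF with an empty tail
(`null_product`), and recoding UUU → UUC removes the site without touching
the protein.

The package ships a CAR-scale demonstration input,
`inst/extdata/synthetic_car_cds.fasta` — a **synthetic stand-in**
(490 codons, GC 0.55, two planted sites) generated by `plantSites()` to
mirror the screening scenario of a real construct whose two candidate
sites both fail to yield a long-tail product. It is not a real therapeutic
sequence.

## Known limitations

* The scan is exactly UUUU/UUUC/AAAG; near-miss motifs (e.g. AAAA/AAAC)
  are deliberately out of scope.
* No modeling of frameshift probability or kinetics — every site is
  reported as a candidate, with no ranking.
* −1 frameshifting, spliced transcripts and ORF discovery in genomic
  sequence are out of scope.
* The length-threshold classification is a proxy; cross-reactivity must
  be established by the external homology search on the exported
  peptides.
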