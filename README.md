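# slipscreen

Quality-control toolkit for therapeutic mRNA coding sequences:
detection of **+1 ribosomal frameshift slippery sites**, prediction of the
chimeric protein a slip would produce, and synonymous recoding to remove
the sites.

N1-methylpseudouridine — the modified base used in most mRNA therapeutics,
including mRNA-encoded CAR constructs — promotes +1 ribosomal
frameshifting at slippery sequences. A slip produces an off-target
chimeric protein: the native N-terminus up to the slip site fused to a
peptide read in the +1 frame. `slipscreen` is for anyone designing or
QC-ing such constructs who needs to find these sites, see what each one
could produce, export the putative peptides for homology screening
(BLASTx), and engineer the sites away.

## Method

For a CDS $s_1 \dots s_{3n}$ ($n$ codons), a **slippery site** is a window
$s_p s_{p+1} s_{p+2} s_{p+3} \in \{\mathrm{UUUU},\ \mathrm{UUUC},\
\mathrm{AAAG}\}$ with $p \equiv 1 \pmod 3$ (1-based): the motif's first
three bases form the in-frame Phe/Lys codon the ribosome decodes, the 4th
is the base it slips past. Per site, the +1 slip is emulated by deleting
that 4th base; frame-0 translation of the variant (standard genetic code,
halt at first stop) yields the chimeric product, decomposed into the
native prefix and the +1-frame tail and classified by tail length
(`null_product` / `short_tail` / `long_tail`, threshold `minTailAa` = 20).
Mitigation recodes the slippery codon's wobble base (UUU→UUC, AAA→AAG),
which provably preserves the protein and leaves no matching window.
An independent brute-force oracle and a planted-site fixture generator
make every step verifiable without external data. Details:
`vignettes/slipscreen-methods.Rmd`.

## Worked example

```r
library(slipscreen)
cds <- validateCds("AUGUUUCUGAUAAGGUAA", id = "toy")   # MFLIR
scanSlipperySites(cds)
#>   cds_id codon nt_start motif slipped_base
#> 1    toy     2        4  UUUC            C
site <- scanSlipperySites(cds)[1, ]
variantRna(buildFrameshiftVariant(cds, site))
#> [1] "AUGUUUUGAUAAGGUAA"
predictFrameshiftProduct(cds, site)
#>   cds_id codon nt_start motif chimeric_peptide native_prefix_aa tail_peptide
#> 1    toy     2        4  UUUC               MF                2
#>   tail_len_aa stop_in_shifted_frame classification
#> 1           0                  TRUE    null_product
recodedRna(recodeAll(cds))
#> [1] "AUGUUCCUGAUAAGGUAA"
```

One UUUC site sits on codon 2 (nucleotides 4–7, 1-based). Deleting the
slipped C puts a UGA stop right behind the slippery codon: the chimeric
product is just MF with an empty +1 tail — a `null_product`, no off-target
protein. Recoding UUU→UUC removes the site; the protein MFLIR is unchanged.

The same pipeline on the bundled CAR-scale demonstration construct (a
*synthetic* stand-in with two planted sites,
`inst/extdata/synthetic_car_cds.fasta`):

```sh
Rscript inst/scripts/slipscreen.R shift \
  --input inst/extdata/synthetic_car_cds.fasta --out results/
#> 2 frameshift product(s) predicted (0 long_tail)
```

Two candidate sites, both with short +1 tails (12 aa and 3 aa), neither
classified as a potentially functional product; `putative_peptides.fasta`
holds the two chimeric peptides ready for BLASTx screening.

The command-line front end (`inst/scripts/slipscreen.R`) also provides
`scan`, `recode` and `simulate` subcommands with `--format tsv|json`,
`--min-tail-aa`, `--strict`, `--cds-start-offset` and `--seed`; sites are
findings, not failures, so only operational errors exit nonzero.

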