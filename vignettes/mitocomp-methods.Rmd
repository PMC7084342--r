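---
title: "Methods: comparative mitogenome statistics in mitocomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative mitogenome statistics in mitocomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocomp)
```

mitocomp implements the comparative statistics that descriptive
mitogenome papers report for newly sequenced vertebrate mitochondria:
structural accounting of the annotated feature map, compositional
skews, codon usage, and pairwise divergence of the protein-coding
genes. This vignette records the models, conventions and design
decisions behind each stage, and what the packaged tests do and do not
demonstrate.

## The feature map and its statistics

A mitogenome is modelled as an ordered, stranded feature map over a
circular molecule, with 1-based inclusive coordinates (the GenBank
convention; a gene's size is `end − start + 1`). The typical vertebrate
complement is 13 protein-coding genes, 22 tRNAs (with duplicated Leu
and Ser isoacceptors), 2 rRNAs and the control region; most features
sit on the heavy (H) strand, with ND6 and eight tRNAs on the light (L)
strand.

Spacings between consecutive features are signed:
`downstream.start − upstream.end − 1`, so positive values are
intergenic spacers, negative values overlaps, and zero abutting genes.
Three conventions matter and are fixed here:

* **The origin-spanning pair is included.** On a circular molecule the
  (last, first) adjacency gets spacing
  `(length − last.end) + (first.start − 1)`. In the packaged *Gerres*
  tables this is always zero (the control region runs to the last
  base), so printed tallies are unaffected, but the adjacency exists
  and closes the tiling identity
  `Σ sizes + Σ spacers − Σ overlaps = genome length`.
* **Nested features are excluded.** A feature fully contained in
  another has no meaningful consecutive-pair spacing; it is dropped
  from the adjacency profile with a warning rather than contaminating
  the spacer/overlap census.
* **The O_L spacer** is reported as the spacing of the
  tRNA-Asn → tRNA-Cys adjacency, its canonical location in bony
  fishes; a non-positive spacing is reported with an explicit
  "no O_L spacer" flag rather than silently clamped.

### The packaged Gerres tables

The three fixture TSVs transcribe the published annotation tables of
*G. filamentosus*, *G. erythrourus* and *G. decacanthus*. Two printed
cells are internally inconsistent and were repaired to the unique
values consistent with the rest of their table: the *G. filamentosus*
tRNA-Ser(GCT) position (printed with a lost separator; transcribed
11867..11934, which matches the printed 68 bp size and both flanking
spacings) and the *G. decacanthus* ND2 end (printed 5239; transcribed
5240, which matches the printed 1047 bp size and the printed zero
spacing to tRNA-Trp). The *G. erythrourus* table is transcribed
verbatim even though its overlap entries (2 sites, 14 bp) disagree with
the running text ("three … 15 bp") — the tables, not the prose, are the
machine-checkable source, and the discrepancy is left visible rather
than guessed away. The same applies to that genome's spacer count: the
printed column contains 16 positive entries summing to the printed
157 bp total, not 15.

## Composition and skew

Base counts are case-insensitive, treat U as T, and exclude ambiguity
codes from the denominator (tallying them separately), so fractions
always sum to 1. Skews follow the standard definitions
AT-skew = (A−T)/(A+T) and GC-skew = (G−C)/(G+C); a zero denominator
yields a missing value, never 0, since "no AT bases" and "balanced AT"
are different facts.

Per-gene skews are computed on the **coding-strand** sequence: L-strand
genes are reverse-complemented before counting. This is the convention
under which ND6 — the lone L-strand protein gene — stands out with a
positive GC-skew against the negative skews of the other twelve, the
strand effect these analyses are designed to expose. The whole-genome
row is computed on the H strand. The convention is stated in outputs
rather than configurable silently.

Codon-position composition assigns base *i* of each coding gene to
position `((i − 1) mod 3) + 1` independently per gene, so genes ending
in incomplete stop codons (a bare T contributes one extra
first-position base; TA one first- and one second-position base)
produce the characteristically unequal position totals seen in
published composition tables. Percentages in reports are rounded
half-even to two decimals.

## Codon usage

The genetic code defaults to NCBI translation table 2 (vertebrate
mitochondrial: AGA/AGG are stops, ATA is Met, TGA is Trp), obtained
from Biostrings and carried as data so alternative tables can be
configured. Terminal codon classification reads the length residue:
`len mod 3 = 0` with a terminal stop codon, `= 2` ending TA, `= 1`
ending T — the two incomplete forms completed by polyadenylation in
vivo.

Codon counting pools complete codons across genes, discards and tallies
incomplete trailing codons, and by default excludes terminal complete
stop codons (`drop_terminal_stop = TRUE`); whether published RSCU
figures include stops is usually unstated, so the flag is exposed and
the default documented. Internal stop codons warn but do not fail —
mitochondrial annotations and reading frames legitimately disagree at
overlap boundaries. ND6 is included on its coding strand. RSCU follows
`k·x_c / X_F` within each synonymous family; an unused family is
reported as missing, not zero.

## Divergence

p-distances are computed over aligned in-frame pairs with
complete-codon deletion: any codon column containing a gap or ambiguity
in either sequence is dropped from **all** partitions (all sites,
positions 1+2 pooled, position 3 — the pooling used in the figures this
reproduces; per-position counts are recoverable from the site tallies).

Ka/Ks uses Nei–Gojobori (1986) counting with equal-weight pathway
averaging and Jukes–Cantor correction. The source study names no
method, so the era's common default (as in MEGA/DnaSP) was chosen; the
method is recorded in every result (`method = "NG86+JC"`), and the
published per-gene Ka/Ks means are treated as indicative only, never
asserted. Numerical conventions:

* Site counts: per position, mutations to stop codons are excluded and
  the synonymous fraction renormalized over the remaining mutants; a
  position with no legal mutant counts as fully nonsynonymous. This
  keeps `s + n = 3` exactly for all 60 non-stop codons.
* Differences: codons differing at *d* positions average over the *d*!
  substitution orderings; orderings passing through a stop codon are
  excluded with weight renormalization (MEGA-style). If every ordering
  is illegal, per-position direct classification is used and flagged.
* `S`/`N` are averaged over the two sequences; `Sd`/`Nd` summed over
  codon pairs; `Ks = JC(Sd/S)`, `Ka = JC(Nd/N)`; ω is undefined (with
  explicit flags) at `Ks = 0` or when either class saturates at
  `p ≥ 3/4`.
* The 64×64 difference grid and the site table are precomputed once
  per genetic code and cached, making genome-scale Ka/Ks a table
  lookup.

Alignment itself is out of scope (published pipelines use MUSCLE or
similar): `pairwise_gene_matrix()` accepts pre-aligned input and
otherwise requires equal-length gene sequences. With
`trim_terminal = TRUE` it drops each gene's start codon and incomplete
tail, and drops the final codon only when it is a stop in **every**
genome — a joint rule that keeps sequences aligned when an overlap has
overwritten one genome's stop.

## The synthetic generator

The generator exists so that every stage has a ground truth. It tiles a
circular genome from a gene-order template — by default the 38-feature
vertebrate order with the sizes, strands, spacings and terminal codons
of the packaged *G. filamentosus* table, so structural statistics of
default output equal the published ones exactly — and plants sequences:
protein-coding genes as start codon + i.i.d. biased codons + (possibly
incomplete) stop, everything else i.i.d. from a background composition
(default A 0.27, T 0.27, G 0.17, C 0.29, the H-strand composition
typical of fish mitogenomes). All randomness flows from one seeded
stream per generation call; identical seeds give identical files.

Where adjacent features overlap, the downstream feature's bases
overwrite the shared positions during assembly, as a single molecule
demands; the truth record keeps the planted per-feature sequences, and
exact sequence-recovery tests therefore use gap-only layouts.

`evolve_cds()` applies exactly the planted numbers of synonymous and
nonsynonymous single-base changes, at most one per codon, never
creating stops, and returns a replayable ledger. In this low-divergence
mode NG86 recovers `Sd`/`Nd` exactly — the basis of the exact Ka = 0
test for purely synonymous plans. For the recovery experiment the
planted ω is defined on the estimator's own scale:
`n_nonsyn = ω · n_syn · N/S` with `N`, `S` the ancestor's NG86 site
counts, so `(Nd/N)/(Sd/S) = ω` by construction and the residual error
of the estimate reflects counting and Jukes–Cantor behaviour, not the
plan.

What the generator does **not** emulate: indels, rate heterogeneity
along genes, multiple hits per codon, tRNA secondary structure,
realistic spacer sequence content, or phylogenetic structure among
genomes. Green tests on generated data therefore validate the
arithmetic and the conventions, not the biological realism of any
particular inference on real genomes.

## Problem sizes and tolerances

The test suite and the acceptance script run at sizes chosen to make
sampling error negligible relative to the asserted tolerances:
compositional sampling checks at 10,000 bases against 4–5σ binomial
bounds; codon-bias recovery at 5,000 codons; the NG86 oracle comparison
exhaustively over all 3,600 ordered non-stop codon pairs at 1e−12; the
tiling-identity property over 100 random layouts; and ω recovery over
10 seeded replicates of 2,000-codon pairs at planted ω ∈ {0.1, 0.5}
with a ±20% band — at those sizes the estimator's deviation is
typically under 5%, dominated by the slight differential inflation of
the Jukes–Cantor correction across the two substitution classes.

## Known limitations

* The GenBank reader covers the flat-file subset the package writes
  (typed features, complement locations, ORIGIN): enough to round-trip
  its own records and read straightforward mitogenome submissions, not
  a general parser for joins, fuzzy coordinates or rich qualifiers.
* Ka/Ks is counting-based; no maximum-likelihood codon models, no
  transition/transversion weighting (that would be NG86's later
  modified forms).
* Circular-coordinate support extends to origin-wrapping features in
  extraction, but the default template places no feature across the
  origin, matching the deposited annotations.
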