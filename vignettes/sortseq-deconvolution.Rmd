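---
title: "Deconvolving sorted surface-display libraries from long-read amplicons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvolving sorted surface-display libraries from long-read amplicons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gatecall)
library(dplyr)
```

## The screening problem

Combinatorial Golden Gate assembly can put every promoter of a modular yeast
toolkit in front of every signal peptide of a small panel, fused to a coding
sequence of interest, an anchoring cassette and epitope tags, and integrate
the whole library into yeast. Staining the displayed protein with a
fluorophore-conjugated antibody turns surface-display strength into a FACS
observable: the library is sorted into low, medium and high fluorescence
gates, each sorted pool is amplified with a dual-barcoded primer pair
(forward barcode = which ORF library, reverse barcode = which gate), and the
pools are sequenced on a nanopore flow cell as 2-3 kb amplicons. The
genotype of every read — which promoter, which signal peptide, which CDS —
is then recovered informatically, giving per-gate genotype abundance tables
from which promoter/signal-peptide combinations with the desired expression
and secretion behaviour are read off.

`gatecall` implements this entire analysis natively, plus a ground-truthed
simulator of the wet half (sorting and sequencing), so that the
deconvolution pipeline can be validated end to end against a known truth.

## The part grammar and design space

A construct is one part per slot, in fixed order:
promoter (part 2) - signal peptide + 3xFLAG (3a) - CDS (3b) - CBM fusion
module (modified 4a) - terminator cassette with or without the Aga2 anchor
(modified 4b). Parts carry 4-nt assembly overhangs; adjacent parts must
share their junction overhang, and the assembled sequence counts each shared
junction once (scarless assembly), so the assembled length is the part-length
sum minus 4 per junction.

The demonstration registry holds 20 promoters (`pYTK009`-`pYTK028`) in
three strength classes and 4 signal peptides (`MF`, `STA1`, `SUC2`, `AMY`),
giving the 80-construct design space per ORF library:

```{r design-space}
reg <- demo_registry()
designs <- enumerate_design_space(reg, cds = "ELP2")
nrow(designs)
```

Elastin-like polypeptide CDS parts are built from the repeat formula: one
ELP1 unit is the 100-aa block
(VPGVG)~5~-(VPGAG)~2~-(VPGGG)~3~-(VPGVG)~5~-(VPGAG)~2~-(VPGGG)~3~, repeated
`n_units` times (`build_elp()`); DNA-level fixtures use one fixed codon per
amino acid so that sequences are deterministic (codon optimisation is out of
scope). All other fixture sequences are synthetic random DNA under a fixed
seed — real toolkit sequences are not redistributed — with lengths chosen so
that full barcoded amplicons span roughly 2.2-3.3 kb, the regime the 2-kb
full-amplicon filter expects.

## The synthetic sort-seq generator

The generator is the package's model of the experiment, with three layers:

* **Fluorescence.** Each genotype's log10 fluorescence mean is looked up
  from a (promoter strength class, signal peptide) table plus a small
  seeded per-genotype offset (sd 0.1, clamped to 3 sd so class ordering is
  preserved); cells draw log10 fluorescence from a normal with shared
  sd `sigma = 0.3`. The default table spans 2.25-4.8 on a scale where
  background is ~2 and the brightest display is ~5, with strong promoters +
  MF at the top and weak promoters near background for every signal peptide
  — the qualitative pattern a display screen of a secretable protein shows.
* **Gating.** Thresholds `t_low = 2.7 < t_mid = 3.2 < t_high = 4.2` define
  low `(-Inf, 2.7)`, an intentionally excluded band `[2.7, 3.2)`, medium
  `[3.2, 4.2)` and high `[4.2, Inf)`; intervals are left-closed and excluded
  cells are discarded, mirroring the sorting strategy that separates low
  from medium expression by a dead band. The defaults sit inside the
  printed 1e2-1e5 fluorescence span; the instrument's actual gate positions
  are only available graphically, so these are package choices.
* **Reads.** A read is forward barcode + amplicon + reverse barcode with
  per-base substitution/insertion/deletion noise (defaults 0.03/0.02/0.03,
  ~8% total — nanopore-like), reverse-complemented with probability 0.5.
  With probability `truncation_prob` the template lacks its CDS (keeping one
  junction copy, so it is shorter by `CDS length - 4`): this is the
  "false-high" species, a clone whose strong fluorescence comes from
  displaying a partial protein. `chimera_prob` concatenates a second
  barcoded amplicon to test the double-marker discard rule. Quality strings
  are a constant placeholder; nothing downstream is quality-aware.

What the generator does **not** model: basecaller signal-level error
structure (homopolymer bias, strand asymmetry), PCR amplification bias,
cell-growth dynamics between sorting and sequencing, and barcode-primer
synthesis errors. Passing tests therefore demonstrate correctness of the
deconvolution logic under idealised independent errors, not performance on
any particular flow-cell chemistry.

Barcodes are 24 nt, designed by rejection sampling so that every pair —
including reverse complements — is at least 8 edits apart, which keeps
crosstalk far below the matcher's acceptance distance.

## Deconvolution

**Demultiplexing.** Each barcode is matched by best infix (semi-global)
alignment under unit-cost edit distance within a 150-nt window at the read
head (forward barcodes) and tail (reverse barcodes), in both read
orientations. A read is assigned iff exactly one forward and one reverse
barcode match within `max_dist = 4` (about len/6 for 24-nt barcodes); two
matches of a role make the read `ambiguous`, a missing one `no_fwd`/`no_rev`.
Ties prefer the smaller distance, then the smaller start coordinate. At the
default error rates this yields ~95% recall and >99.9% purity on the
fixture barcode set; the package treats assignment loss as the price of the
full-amplicon rule, never rescuing single-barcode reads.

**Length filter.** "At least 2 kb" is read inclusively: a 2,000-nt read is
kept, a 1,999-nt read is not.

**Orientation.** The CBM fusion-module sequence marks the 3' end of every
sense-strand amplicon. The marker is aligned against each read and its
reverse complement; the strand carrying the sense marker is kept, so
oriented reads place the marker near their 3' end. Reads without an
acceptable marker hit (identity >= 0.8 over >= 50% of the marker) are
`no_marker`; a second disjoint sense hit flags `chimeric`. A tie between
strands resolves to plus with a warning. Orientation precedes annotation,
and marker presence is required for genotype calling but not for the pool
assignment counts themselves.

**Annotation.** Every grammar part is locally aligned to the oriented read
(match +2, mismatch -3, gap open -4, gap extend -2; a gap of length L costs
`open + (L-1) * extend`). The implementation seeds each part with shared
11-mers, estimates the alignment diagonal from their median offset, and runs
a banded (±100) affine Gotoh pass with traceback; an exact substring
occurrence short-circuits the DP, which makes noise-free data essentially
free. When the marker position is known, each slot is searched only in the
window the grammar implies, which cuts runtime several-fold without changing
results on grammar-conformant reads. Hits need identity >= 0.8 and coverage
>= 0.8 of the part; promoter hits flush with the read's 5' barcode junction
are allowed down to coverage 0.5, because the PCR primer can clip 5'-terminal
promoters — these carry a `clipped` flag. Overlapping hits of the same slot
(e.g. a 2-unit ELP inside a 4-unit ELP read) resolve toward the higher
score, then the longer alignment. Hits export to GFF3 (1-based inclusive
coordinates; internally everything is 0-based half-open) and round-trip
through the package's reader.

**Calling.** Slots are filled by registry role, never by similarity. A
`full` call needs one promoter, one signal peptide, one CDS and one 4a hit
in left-to-right order (junction-sharing neighbours may overlap by up to
12 nt); promoter + signal peptide + 4a without a CDS is `truncated_no_cds`
— the false-high signature; two accepted hits in a slot or an order
violation is `ambiguous`; ambiguity is never rescued by abundance priors.

**Quantification.** Only `full` calls are counted. The abundance matrix is
promoters x signal peptides in fixed registry order, with fractions over
the pool's full calls — the denominator used throughout, since only
full-amplicon reads enter the analysis. Gate profiles summarise a genotype
across the three gates of one ORF library as
`score = (f_medium + 2 f_high) / (f_low + f_medium + f_high)`, a 0-2 scalar
that is invariant to per-gate depth. The weights (0, 1, 2) are a package
convention to make recovery testable as a single rank correlation; the
underlying screen ranks combinations by inspection of the heatmaps.

## Validation strategy and problem sizes

The test suite validates each stage against independent oracles: the infix
matcher against brute-force edit distance over all substrings
(`utils::adist`), the aligner against a quadratic-time pure-R affine DP, the
sorter against closed-form normal-CDF band probabilities, and the whole
pipeline against the simulator's hidden truth. Problem sizes were chosen to
keep the default test run comfortable on a laptop while leaving narrow
Monte-Carlo bands: 9 pools x 500 noise-free reads for the end-to-end
identity check, ~2,000 noisy reads for caller accuracy and abundance
calibration, 1,000 reads/gate for the rank-score recovery (observed
Spearman ~0.97 against true fluorescence means), and 1e5 cells for the
gate-fraction convergence test.

Two evaluation choices deserve note. Caller accuracy is measured over reads
that reach the caller: at the spec-level demux operating point (~95%
recall) charging barcode-failure losses to the caller would conflate two
stages whose contracts are tested separately. And the 2-kb filter is not
applied when evaluating truncation detection, because CDS-less templates
are deliberately ~600 nt shorter and would be censored by the filter before
the caller could classify them — on real data this means the false-high
class is detected primarily through its length signature, with the caller's
`truncated_no_cds` status confirming the missing CDS on reads that pass a
lower length floor.

## Numerical and degenerate-input conventions

* `sigma = 0` is allowed in `sort_cells()` as the degenerate noise-free
  limit; gate intervals are left-closed, so a cell exactly on `t_mid` sorts
  into medium.
* Compositions must sum to 1 within 1e-9; abundance fractions sum to 1
  within 1e-9 whenever a pool has any full call, and an empty pool returns
  an all-zero matrix with a warning rather than an error.
* Top-genotype ties break lexicographically by promoter id then signal
  peptide id, making rankings stable and pure functions of the matrix.
* One user-facing seed expands into independent per-stage seeds, so a whole
  run is byte-reproducible while stages remain individually rerunnable.

## Limitations

The aligner's banded heuristic assumes the true alignment stays within
±100 diagonals of the k-mer median offset — ample for ~8% independent
errors, but long tandem repeats with unit length below the band could in
principle confuse the diagonal estimate. The sandwich of fixed windows
around the marker assumes grammar-conformant reads; structurally aberrant
reads that are neither chimeric nor truncated may annotate partially and
fall out as `partial`/`ambiguous`, which is the conservative outcome. The
fluorescence model is a single log-normal per genotype: it does not model
the bimodal display distributions real libraries can show, nor
antibody-saturation ceilings.
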