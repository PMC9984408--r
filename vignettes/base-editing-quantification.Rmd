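---
title: "Quantifying base-editing outcomes from amplicon sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying base-editing outcomes from amplicon sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beamplicon)
```

## The measurement problem

CRISPR base editors — adenine base editors (ABEs, A•T→G•C), cytosine base
editors (CBEs, C•G→T•A), and dual editors carrying both deaminases — are
characterized by deep sequencing of PCR amplicons spanning the target locus.
Each amplicon read is one sampled allele from the edited cell population. The
quantities of interest are:

* the **per-position conversion efficiency**: at every protospacer position
  whose reference base is editable (A for A-to-G, C for C-to-T), the fraction
  of indel-free reads carrying the converted base;
* the **editing window**: which positions are converted efficiently, usually
  summarised for position ranges such as 2–9 (canonical) versus 10–15
  (PAM-proximal);
* the **indel frequency**: the fraction of aligned reads with an insertion or
  deletion near the nick site, the unwanted by-product;
* for dual editors, the **allele-level outcome composition**: reads carrying
  only A-to-G, only C-to-T, both on the same allele ("simultaneous"
  conversion, the dual-editor headline statistic), other substitutions,
  indels, or no edit;
* for the guide-independent RNA off-target mode of deaminase editors, the
  number and editing fraction of A-to-I (or C-to-U) transcript variants that
  survive a control-based filtering chain.

Positions are numbered 1 (PAM-distal 5' end of the protospacer) to L
(PAM-proximal, typically 20), with the PAM immediately 3' of position L and
not numbered. The numbering is strand-invariant: for a protospacer found on
the minus strand of the amplicon, observed bases are complemented into
protospacer orientation before counting, so "A8" means the same thing
whichever strand the guide targets.

## Read processing and alignment

Reads first lose their library adapters (`trim_adapters()`): the constant
forward primer-tail and the reverse complement of the backward one, matched
exactly or as an end-anchored partial overlap of at least 8 nt (configurable).
Exact matching with no mismatch tolerance keeps trimming deterministic;
adapters are constant PCR primer sequences, so errors in them are rare and a
missed trim only costs the read its alignment score, not its correctness.

Each read is then aligned to the full amplicon with a semi-global affine-gap
aligner (`align_read()`, compiled): the read is global, the amplicon local, so
reference overhangs are free. The default scoring is match +2, mismatch −1,
gap open −6, gap extend −1; a gap of length k costs `gap_open + k *
gap_extend`. These values make a single base conversion (one mismatch, −3
relative to match) much cheaper than a gap (−9 for length 1), which is what a
substitution-dominated outcome spectrum needs. Traceback ties prefer
match/mismatch over deletion over insertion and the leftmost best end column,
so alignments are fully deterministic. Pairs involving N score as mismatches;
N calls are tallied separately and excluded from both numerator and
denominator of efficiencies.

Quality control (`qc_params()`) drops reads with mean Phred below 20, reads
shorter than the protospacer, reads whose alignment scores below 60% of the
maximum attainable (`match × read length`), and reads whose alignment does not
span the protospacer. These thresholds are explicit, configurable defaults;
dropped reads are counted as "unusable", never as indels.

## Denominators and the indel window

Substitution counts use **indel-free reads only** (the CRISPResso-style
convention): a read with an insertion or deletion overlapping the
quantification window is excluded from the per-position base counts and
counted once in `n_indel`. Indel frequency is `n_indel / n_aligned` over all
aligned reads. Keeping the two denominators separate prevents gap columns
from deflating conversion rates and matches how substitution and indel panels
are reported separately in editor characterization studies.

The indel quantification window is the protospacer ± 5 nt (`indel_pad`,
configurable). A deletion overlaps the window when a deleted reference base
lies inside it; an insertion when its anchor point touches the window,
inclusive of both edges. One caveat is inherent to alignment rather than to
this choice: an indel inside a repeat run that crosses the window boundary is
placed leftmost by the aligner and can normalise to just outside the window.
The ± 5 padding absorbs shifts up to five bases; validation fixtures with
exact truth-table comparisons therefore use interior indels.

## Allele classes

`allele_table()` tallies each aligned read's protospacer-window sequence
(protospacer orientation, `-` for deleted bases) into distinct alleles.
`classify_alleles()` partitions reads into six mutually exclusive classes:
`indel`, `simultaneous` (≥1 A-to-G at a scored A position *and* ≥1 C-to-T at
a scored C position on the same allele), `only_a2g`, `only_c2t`, `unedited`,
and `other_subst`. By default every reference A and C in the protospacer is
scored; restricted windows can be passed instead. Whole-protospacer scoring
is the most inclusive reading of "simultaneous A/C conversion" as a single
per-site number; because it is a parameter, window-restricted definitions are
one argument away. Indel-carrying alleles stay in the denominator (they are
reads from the population and can never be "simultaneous"), so
`simultaneous_fraction()` is simultaneous reads over all classified reads.

The "number of mutant allele types" statistic counts distinct non-reference
alleles above a minimum frequency floor, 0.1% of reads by default. Without a
floor the statistic grows roughly linearly with sequencing depth because
every error singleton mints a new "allele"; the floor is configurable and 0
disables it.

## Comparison statistics

`compare_editors()` reports, per position, each editor's cross-site mean of
per-site replicate means, the fold change `mean(Y)/mean(X)` (undefined, and
reported `NA`, where `mean(X)` is 0), and a two-tailed two-sample t-test on
the per-site means. Per window, per-site window means are compared across
editors with the two-sided **paired Wilcoxon signed-rank test**: a "paired
rank-sum" comparison of site-paired values is the signed-rank test, and that
is the reading implemented here. `signed_rank_test()` drops zero differences
(all-zero input is degenerate with p = 1), computes the exact null by
convolution over the 2^n sign assignments for n ≤ 25 — ranks are doubled so
tied, half-integer ranks convolve on an integer lattice, making the exact
path valid under ties — and switches to a normal approximation with
continuity and tie correction beyond. The exact two-sided p is
`min(1, 2·min(P(W ≤ w), P(W ≥ w)))`. No multiple-testing correction is
applied anywhere; reports state this.

## RNA off-target filtering

The RNA stage consumes per-sample variant tables (TSV, or VCF via vcfR) from
an upstream aligner/caller; calling itself is out of scope. The chain in
`rna_pipeline()` is:

1. **Control confidence** (`control_confidence_filter()`): keep an
   overexpression variant only if the control covers the locus with depth
   strictly greater than the 90th percentile of coverages across all
   overexpression variants, and the control reference-allele fraction is at
   least 0.99. The percentile is the type-7 linear-interpolation sample
   percentile (`percentile()`), fixed for determinism. The comparison of
   *control* depth against the *overexpression* coverage distribution is
   implemented literally as stated; it acts as a depth-matching gate that
   only trusts absence-of-variant calls made on well-covered control loci.
2. **Background subtraction**: loci retained from the GFP control
   (`gfp_background_filter()`: depth ≥ 10 and at least one alternate read)
   are removed, matched by (contig, position, ref, alt) — the most specific
   key available in a variant table.
3. **Alt-read requirement and labeling**: retained loci need at least one
   alternate read; `label_edit_type()` then applies the strand-aware rules —
   A→G on a plus-strand gene or T→C on a minus-strand gene is A-to-I, C→T on
   plus or G→A on minus is C-to-U, everything else (including unknown
   strand) is `other`.

All three filters are monotone — tightening any threshold can only shrink the
retained set — and the pipeline is invariant to input row order; both
properties are tested.

## The simulator and what passing tests mean

`simulate_reads()` draws reads from an explicit generative model
(`editing_model()`): per-position conversion probabilities `p_edit`, a
co-editing coupling `rho`, a per-read indel rate with a small-size indel
distribution placed uniformly in the protospacer ± 5 window, a uniform
per-base substitution error overlay with constant Phred qualities, and
optional adapter attachment. The coupling is a two-component mixture chosen
for its closed-form marginals: with probability `rho` one shared uniform draw
drives all positions (position i edits iff U < p_i), otherwise positions edit
independently. Marginals are exactly `p_i` for any `rho`; the co-edit
probability of two positions is `p_i·p_j` at `rho = 0` and `min(p_i, p_j)` at
`rho = 1`. These two laws are the quantitative anchors the allele statistics
are validated against.

`simulate_rna_tables()` plants A-to-I loci in an overexpression table, adds
heterozygous germline-like loci shared with the control (caught by the
consensus filter) and background editing loci shared with a GFP control
(caught by subtraction). Control depths (Poisson mean 300) sit well above
overexpression depths (mean 50) so a clean control passes the coverage gate;
editing fractions are uniform on 0.05–0.6 — mid-range values typical of
reported RNA off-target fractions.

Default validation sizes are 5,000 reads for estimator-recovery and
co-editing checks (binomial 3·SD bounds), 1,000 random read/reference pairs
for the alignment oracle, and 100-row variant tables over 20 seeds for the
RNA filter oracle; these sizes make all statistical bounds comfortably tight
while keeping the whole suite fast on a laptop.

What passing does **not** show: the simulator draws uniform, quality-blind
errors, at most one indel per read, no PCR duplicates or chimeras, no
quality degradation along the read, and single (pre-merged) reads only. Real
amplicon libraries violate all of these mildly. The pipeline's counting
logic is exercised exhaustively, but error-model-sensitive settings (the
allele-type frequency floor most of all) should be tuned on real data.

## Determinism

Every stochastic component takes an explicit seed, restores the caller's RNG
state, and is byte-stable: the same model and seed give identical FASTQ
bytes, and `run_pipeline()` reruns are hash-identical file for file (no
timestamps are written). This is tested end to end.

## Known limitations

* No paired-end merging, demultiplexing, or UMI handling; input reads are
  single or pre-merged.
* No base-quality-aware probabilistic calling; a base is what the aligner
  column says it is.
* Indel normalisation at window edges (above).
* The aligner is designed for amplicon-scale references (tens to hundreds of
  nt), not genomes.
* RNA filtering consumes variant tables; it cannot rescue upstream calling
  artifacts.
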