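---
title: "Counting telomere-like ATAC-seq reads as a condensation biomarker: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting telomere-like ATAC-seq reads as a condensation biomarker: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teloatac)
```

## The measurement and its interpretation

ATAC-seq uses the Tn5 transposase to fragment and tag accessible chromatin.
A small fraction of the resulting reads consists of tandem telomere repeats
— `TTAGGG` on the G-rich strand, `CCCTAA` on its complement. `teloatac`
counts these reads and normalises by depth:

$$\mathrm{nTA} = \frac{\text{telomere-like reads}}{\text{total reads}},
\qquad \mathrm{RPM} = \mathrm{nTA} \times 10^6.$$

Two facts shape the interpretation. First, the telomere proper is largely
protected from Tn5 transposition, so the motif-bearing reads are mostly
subtelomeric; nTA is therefore **not** a telomere-length estimate. Second,
the repeat compartments that produce these reads are constitutively compact,
so their *relative* read share moves with the condensation state of the rest
of the genome: global condensation raises nTA, global opening lowers it.
nTA is used here as a per-library or per-cell chromatin-condensation
biomarker.

## Read classification

A read is **telomere-like** when it carries at least `min_consecutive`
strictly tandem (zero-gap) copies of the canonical motif on either strand.
The default threshold of three consecutive hexamers is the conventional
operating point for calling short reads telomeric; it suppresses chance
single-motif hits (a random 50-mer contains a given hexamer somewhere with
probability about 1%, but three tandem copies are vanishingly unlikely).
Design choices worth stating:

* *Tandem means tandem.* Runs are measured per strand and never merged
  across strands or across gaps; any non-matching character, including `N`,
  terminates a run. This is the strictest reading of "consecutive motifs"
  and avoids inflating counts from low-quality bases.
* *Equivalent fast path.* A run of at least $k$ copies exists exactly when
  the $6k$-mer `motif`$^k$ occurs as a substring, so large simulations can
  classify with a fixed-substring search; the equivalence of the two routes
  is property-tested against a brute-force oracle.
* *Variant repeats* (`T**GGG` minus the canonical motif) are counted as
  non-overlapping occurrences without a run threshold, since no such
  threshold is conventional for variants; a run-threshold mode exists in
  the configuration for sensitivity analyses.
* *Fragments versus reads.* In paired mode a fragment counts once if either
  mate qualifies and the denominator is fragments; in single-end mode both
  are reads. The mode is recorded in the output.

Per-cell tables tally total and telomere-like reads by barcode; records
without a barcode accumulate in a reserved row excluded from ranking. For
display, `rank_transform()` maps nTA to average ranks rescaled by
$(r-1)/(n-1)$, sending ties to their mean rank and a constant vector to 0.5.

## Reorientation and motif logos

Telomere-like fragments are sequenced from either strand. To build a
per-base motif matrix, pairs are first brought into a common-strand
representation (reverse complement the raw second read), then flipped —
both mates reverse complemented and swapped — whenever read 1's G fraction
falls below 0.5. The G fraction is assessed over the whole read by default;
the assessment window is configurable because the original procedure's
window is not standardised. On telomere-like pairs the operation is
idempotent. Stacked reads (truncated or `N`-padded to a common length)
yield column-normalised base frequencies; `N` can be excluded from the
denominator when padding should not dilute the signal.

## Tn5 insert detection and target-site duplication

Non-fragmenting 95-bp cargo oligos, terminated by the 19-bp mosaic-end
sequences, mark Tn5 insertion points in long reads without breaking the
molecule. Detection is seed-and-verify: seeds of `seed_length` (default
20 bp) from both cargo termini are matched in both orientations, and each
candidate is verified over the full cargo at up to `max_mismatch_fraction`
(default 0.1) mismatches. Seeds tolerate mismatches at the same rate as the
verification — with exact seeds a single sequencing error near a terminus
would hide the insert, capping recall near 60% at a 5% error rate, whereas
mismatch-tolerant seeds keep recall at the verification ceiling
($P[\mathrm{Bin}(95, 0.05) \le 9] \approx 0.98$). Overlapping candidates
resolve to the lowest-mismatch, leftmost event; multiple non-overlapping
inserts per read are allowed because transposome pairs occasionally act in
tandem.

The **target-site duplication** is measured with the standard definition:
the largest $d \le d_\max$ (default 15) such that the last $d$ bases of the
left flank equal the first $d$ bases of the right flank. Wild-type Tn5 is
reported to duplicate 9 bp of its target; a constructed 9-bp duplication is
recovered exactly on clean reads, and unrelated flanks measure 0 (with the
usual $4^{-d}$ chance of spurious short matches). Insertion-context
matrices and telomere-proximity histograms are computed in the
insert-removed (host) frame, with cargo bases masked so motifs inside the
insert never count; the same masking underlies `nta_by_insert_status()`,
which contrasts nTA over all reads with the insert-bearing subset — the
comparison that exposes the telomere proper's protection from transposition.

## Nanopore telomere reads and the subtelomere boundary

Telomere-capture nanopore reads start at the chromosome end on the C-rich
strand. Processing trims the ligation adapter (`CCCTCCGATA`) only when it
matches at position 0 (exact by default; a mismatch allowance is exposed),
flags reads whose trimmed length is under 8 kb rather than dropping them,
and walks the repeat tract: starting at position 0, the scanner repeatedly
accepts the next `TAACCC` beginning within 0–18 bp of the cursor and jumps
past it; where no match follows, the cursor is the subtelomere start, and
the telomere length equals that coordinate. The 18-bp window is treated as
inclusive so that a full three-hexamer interruption (three variant repeats)
is tolerated; a pure tract of $k$ repeats followed by anything else yields
exactly $6k$.

## The read-origin model

Because telomere-like reads cannot be placed by alignment, a small
convolutional regressor infers the approximate origin of a 50-bp sequence
as a distance from the telomere. Training windows are labelled
$\log_{10}(1+d)$: 0 within the telomere proper, the distance past the
boundary for subtelomeric windows, and fixed artificial pseudo-distances
for chromatin ($10^7$) and centromere ($5\times10^7$) windows — values
chosen to sit far above any real subtelomeric distance while remaining
distinct from each other; both are configurable. $\log_{10}(1+d)$ resolves
the $d=0$ case that a bare log cannot. Every window's reverse complement is
added with the same label.

The architecture is deliberately small to limit overfitting: one-hot
`ATCGN` input (5 channels), two unpadded convolutions of kernel width 6
(matching the repeat hexamer) with 20 filters each and ReLU, and a dense
layer to one scalar — 3841 parameters, mean-squared-error loss on the log
distance. The optimiser is Adam (batch size 64, learning rate $10^{-3}$ by
default) since the original training settings are not standardised; all
settings are recorded in the saved model artifact. Data are split 80/20
into train and test; the default 200 epochs is generous (about half
suffices), and training is bit-reproducible under a seed. The forward pass,
backpropagation and optimiser are implemented in base R matrix algebra (an
im2col formulation), which at these sizes trains in minutes on one CPU.

Predictions are binned to classes at the midpoints between class label
values in log space, with telomere-proper predictions merged into the
subtelomere bin. The bins are defined by the classes present in the
training data. On a separable two-class set (pure repeat windows versus
random 50-mers) the model reaches per-class recall above 0.9 and beats the
constant predictor by two orders of magnitude in MSE. A known limitation:
distinguishing chromatin from a single-monomer centromere at desk scale
plateaus around 0.86 recall for chromatin, because random 50-mers share
centromeric hexamers by chance; at the full training sizes the method
targets (a million windows), this margin improves, but the class boundary
between two arbitrary pseudo-distances should be read qualitatively.

## Correlation statistics

Per-cell nTA is correlated with feature tables (motif activities, gene
scores) by Spearman's method — Pearson correlation of average ranks — with
two-sided p-values and Benjamini–Hochberg adjusted values reported side by
side (the adjustment is provided even where raw p-values are the
convention). For the grouped ranking, correlations are computed within each
cell group (cell type × batch), keeping only groups with more than 1000
cells to reduce noise, and aggregated per feature into the mean, variance
and mean/variance ratio across groups. Ranking by the mean favours strong
global correlates but is confounded by G/C-rich motifs whose correlation
with nTA is inflated by sequence composition; those motifs are inconsistent
across groups, so the mean/variance ratio demotes them. The ratio is
implemented literally as mean divided by variance (not standard deviation).
Zero variance across groups produces a signed infinite ratio, which orders
above every finite ratio of the same sign — the natural limit of "perfectly
consistent". Pearson correlation is available behind a flag since the
choice of correlation for grouped rankings is not settled.

## The simulators: what they emulate, and what they do not

`make_genome()` builds arms that run telomere → subtelomere → chromatin →
centromere from the chromosome end:

* telomere proper: pure tandem `TTAGGG` (default 300 copies, 1.8 kb);
* subtelomere (default 2 kb): blocks of 3–10 tandem hexamers, each
  canonical with probability `1 - tvr_rate` (default `tvr_rate = 0.5`),
  separated by 20–50 bp random spacers. Spacers are G-free so that every
  `T**GGG` in the compartment is an intentional repeat — this makes
  zero-variant genomes (`tvr_rate = 0`) exactly variant-free and keeps the
  fraction of subtelomeric fragments that classify as telomere-like a
  controlled function of the block parameters;
* chromatin proper (default 50 kb): uniform random sequence;
* centromere: tandem copies of one random 171-bp monomer.

These defaults are one plausible rendering of a degenerate human
subtelomere at desk scale; real subtelomeres carry segmental duplications,
satellite families and far longer variant gradients that this model does
not attempt.

`simulate_atac_reads()` samples fragment starts proportionally to
per-compartment accessibility weights. The telomere proper's default weight
is 0.01 — near zero, encoding its protection from transposition — and the
condensation parameter $c$ divides the chromatin weight by $1 + c$, which
makes expected nTA strictly increasing in $c$: the module's key
monotonicity property, verified at 50,000 fragments per state. Fragment
starts reserve one read length inside the source compartment and fragments
are clipped at the compartment end, so each fragment's truth label is exact
for both mates; the cost is that boundary-spanning fragments are not
generated. Per-barcode condensation parameters allow per-cell ground truth.

`simulate_longreads_with_inserts()` shears the genome uniformly and places
a Poisson number of cargo insertions per read, accepting candidate
positions with probability proportional to the underlying compartment's
insertion weight (telomere proper 0 by default); a configurable
duplication length reproduces the staggered-cut signature.
`simulate_nanopore_telomere_reads()` emits adapter + `TAACCC`$^k$ + a 25-bp
motif-free spacer + the reverse-complemented subtelomere + chromatin
filler, with read lengths straddling the 8-kb filter. The spacer guarantees
that the boundary scan terminates at exactly $6k$ on noise-free reads —
real reads have no such guarantee, and on them the detected boundary
extends into subtelomeric repeat blocks by construction of the scan rule.
None of the simulators models instrument-specific error profiles,
GC-coverage bias, PCR duplication or barcode errors; passing tests on them
demonstrates the correctness of the computations, not performance on real
libraries.

## Numerical and interface conventions

Coordinates are 0-based half-open throughout. Classification, counting and
correlation are deterministic; every stochastic function takes an explicit
seed and restores the caller's RNG state. Undefined quantities are `NA`,
never silent zeros: nTA at zero depth, Spearman correlation of a constant
vector, insert-only nTA without inserts. Cell tables serialise as TSV with
the fixed header `barcode, total, telomere_like, nta, rank_nta` (nta at six
significant digits, the no-barcode row with an empty barcode field);
configurations and library summaries as flat key/value files; models as
self-describing JSON. Problem sizes in the test suite (hundreds of reads to
tens of thousands of fragments, training sets of a few thousand windows)
were chosen so the full suite documents the methods at interactive speed;
all scale linearly if larger runs are wanted.
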