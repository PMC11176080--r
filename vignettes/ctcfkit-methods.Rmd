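---
title: "Methods: motif-anchored chromatin analysis around CTCF sites"
author: "ctcfkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motif-anchored chromatin analysis around CTCF sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctcfkit)
```

## Scope and model of the data

ctcfkit quantifies what happens around CTCF motifs in chromatin: how
accessible the DNA is (ATAC-seq), how strongly CTCF and its cofactors
are bound (ChIP-seq, CUT&RUN), how nucleosomes are spaced around the
motif (MNase-seq), what single molecules look like at base resolution
(GpC-methyltransferase footprinting, SMF), which DNA sequence features
predict changes in binding when a chromatin remodeler is removed (a
convolutional network on 150-bp windows), and how contact insulation at
these sites changes (Hi-C pileups). All sequencing inputs are consumed
downstream of alignment, as fragment tables — (chrom, start, end,
strand) records in 0-based half-open coordinates — so the package is
agnostic to the upstream aligner. Contact data are consumed as binned
symmetric matrices.

Every analysis stage has a matching generator in the synthetic-data
module that plants a known ground truth. The package's tests are
organized around *recovery*: the phasogram must recover a planted
nucleosome repeat length, bound-site calling must recover planted
enrichment, the network must recover planted sequence determinants, the
insulation statistic must recover a planted boundary strength.

## Anchored profiles and their normalizations

Profiles are matrices of sites by positions in a window (default 2 kb,
relative positions −1000..+999) centered on the oriented motif. The
center of a motif match `[start, end)` is `start + floor(width/2)`; for
minus-strand motifs the position axis is reversed so +x always points
3' of the motif. Fragments enter a profile either at their midpoint
(`start + floor(length/2)`, the half-insert shift used for MNase
dyad-centered signal; the right-of-center base for even lengths), at
their strand-aware 5' end, or once per covered base. Overlapping
anchors are counted independently, matching per-site profile
semantics.

Three normalizations are provided, mirroring common practice for the
respective assays: counts scaled by library size and multiplied by 100
(ATAC display scale); counts scaled by library size, divided by the
number of sites, and multiplied by 1000 (ChIP metaprofiles); and the
median scheme for MNase, in which each co-analyzed sample's profile is
divided by its own median and multiplied by the median of sample
medians, giving all samples a common median while preserving shape.
The multiplicative constants are display scalings; the provenance tag
on every profile records the scheme applied. Smoothing is a centered
running mean (21 bp for ATAC/ChIP/MNase metaprofiles, 51 bp for
CUT&RUN) whose window truncates at the profile edges, so constants are
preserved exactly.

Fixed-width window counts (default 250 bp) assign fragments by their
midpoint and report `log2(n + 8)` where `n` is the count scaled to the
median library size of the co-analyzed samples; the pseudocount of 8
damps noise at low counts, and enrichment over a control is the
difference of two such values. Depth matching across samples is done by
subsampling every sample, without replacement and seeded, to the
smallest library.

## Enrichment and bound-site calling

The central score is

$$e_i = \log_2 \frac{n_i/N_i \cdot \mathrm{median}(N) + 8}
                    {n_j/N_j \cdot \mathrm{median}(N) + 8},$$

with window counts $n$, library sizes $N$, and the median library size
taken over the samples co-loaded in one analysis (recorded in the
model object when fixed). The same formula scores IP-versus-input
enrichment and mutant-versus-wild-type changes. A motif is called
bound when its IP-over-input enrichment in a 251-bp window centered on
the motif is at least 1.0 in log2 units (twofold); the threshold is
inclusive. The 251-bp window is `center − 125 .. center + 126`
(0-based half-open) and fragments are assigned by midpoint — the
overlap rule is a documented package choice, as is the motif-center
convention.

PWM scanning converts a JASPAR-format frequency matrix to log2 odds
against a uniform background with a flat pseudo-probability of 0.01
per cell, scans both strands, and resolves overlapping same-strand
hits by keeping the higher score. The default reporting threshold is
80 percent of the maximal attainable score; no canonical motif
threshold is claimed, and the shipped 19-column and 9-column matrices
are synthetic placeholders (labeled as such in `inst/extdata/`), never
stand-ins for the canonical CTCF matrices — users supply real
matrices where needed.

## Phasograms and the nucleosome repeat length

The phasogram counts, per chromosome and strand, pairs of fragment
5'-start positions at each distance 1..3000 bp, then pools by
summation. The implementation computes this as an FFT autocorrelation
of per-position start counts, which is exact (integer counts) and
scales with genome span; the test suite holds it to an all-pairs
brute force. Fragment 5' starts, not midpoints, are used — the
convention of the phasogram literature.

NRL estimation smooths the phasogram (running mean, 31 bp), detrends
by subtracting a wide running mean (301 bp), takes local maxima above
zero with at least 100 bp mutual separation inside the fit range
(100–3000 bp), and regresses peak position on peak index by ordinary
least squares; the slope is the NRL, reported with its standard error
and R². These defaults were chosen once to resolve repeat lengths in
the 150–250 bp range and are configurable; exact numerical parity
with any particular published implementation is not claimed — the
contract is planted-truth recovery, which the tests check at ±3 bp
(200 anchors × 50 cells, 10 bp dyad jitter) along with recovery of a
planted 10-bp difference between two conditions.

Fragment-length-stratified profiles split fragments into contiguous
length bins, sum each bin's midpoint profile over anchors, and
standardize each bin to mean 0, s.d. 1; empty or constant bins stay
at zero rather than NaN.

## Single-molecule footprints

Cytosines are classified by trinucleotide context, strand-aware:
GCH is an informative GpC (the exogenous methyltransferase
substrate), HCG an endogenous CpG, and the overlap contexts GCG and
CCG are ambiguous and excluded from both sets. The footprint at a
position is 1 minus the methylation rate over informative calls;
missing calls never enter denominators, and positions under the
coverage floor are missing, not zero. Replicate profiles are averaged
with the per-replicate values and their s.d. retained; with equal
molecule counts the mean of replicate means equals the pooled mean.
Calls from both strands are pooled per position by default (a
per-strand mode exists, since the convention varies). Molecules can
be ordered and partitioned by mean methylation in a site window, with
ties broken by molecule id for determinism.

## Site classes

Response clustering uses Lloyd's k-means with k-means++ seeding and
the best of 25 restarts by total within-cluster sum of squares, on
unscaled log2 fold changes (they are already commensurate; a z-score
option exists). Cluster labels are permutation-unstable in any
k-means, so clusters are relabeled in decreasing order of mean
accessibility change, making the numbering reproducible across seeds.
An elbow scan reports WCSS across k without making an automatic
choice.

Persistent-binding sites are those whose linear binding fold change
`2^ΔChIP` lies in the closed interval [0.8, 1.2] — "less than ±20
percent variation" read on the linear scale, with the log-scale
asymmetry accepted as-is; a relative tolerance of 1e-9 on the
endpoints absorbs the one-ulp error of the log/exp round trip so
boundary fold changes stay included. The persistent set is split into
4 groups by accessibility-change quantile (group 1 = least loss);
quantiles rather than fixed cut-points are a package choice, made
configurable because either reading is defensible. Chromatin-state
annotation first streamlines raw labels through a merge map (e.g.
strong/weak enhancers into Enhancer, heterochromatin into
RepressedChromatin), then assigns each site the highest-priority
overlapping state in the order ActivePromoter, BivalentChromatin,
Enhancer, RepressedChromatin, Insulator; no overlap means Intergenic.

## The sequence model

The network maps one-hot encoded 150-bp windows centered on bound
motifs (oriented, N as an all-zero column) to a scalar binding
change. The architecture is fixed: four 1-D convolutions with 128,
128, 128 and 64 filters of sizes 5, 3, 5 and 3, each followed by ReLU
and max-pooling of width 2; then dense ReLU layers of 128 and 64
units with dropout 0.4 after each; then one linear unit. Convolutions
are same-padded, so the length trace is 150 → 75 → 37 → 18 → 9 and
the flattened feature size is 576. Training minimizes mean squared
error with Adam (learning rate 0.001 — a frozen package default, as
are the other Adam constants — batch size 64), holds out 20 percent
of the training set for validation, and stops early on validation
loss with patience 15, restoring the best weights; the epoch cap is
100. Sites on the holdout chromosomes (default chr16–chr19; the
synthetic runs hold out two of eight simulated chromosomes) are never
seen in training or validation and form the test set.

The forward/backward pass is implemented in compiled code with the
whole minibatch stacked into a single im2col GEMM per layer, in
single precision — the customary deep-learning precision; parameters
and gradients cross the interface as doubles, and all randomness
(splits, shuffling, dropout, initialization) flows from R's seeded
RNG, so training is run-to-run reproducible on a given platform.
Analytic gradients are tested against finite differences through the
full network.

Attribution uses expected gradients over dinucleotide-preserving
shuffled references (default 100 per sequence): the input gradient is
integrated along the straight path from each reference to the input
(midpoint rule, 16 points by default; the acceptance runs use 8,
which keeps the completeness error of the piecewise-linear network
well under 5 percent) and `(input − reference) · ∫grad` is averaged
over references. In-silico mutagenesis — prediction of the original
minus the mean over the three substitutions per position — is always
available as the model-agnostic oracle, and the test suite requires
the two to correlate. Dinucleotide shuffles sample uniform random
Euler paths through the dinucleotide multigraph (random final-exit
edges accepted when they form an arborescence into the terminal
vertex, remaining edges permuted), which preserves the dinucleotide
count multiset exactly; uniformity is tested against exhaustive
enumeration on a 10-mer. The contribution weight matrix averages, per
base and position, the contribution scores of the bases actually
present in the aligned sequences; signed scores are averaged (an
absolute-value mode is a trivial variant the tests do not rely on),
and cells for bases never observed at a position are missing.

In the synthetic study condition the label is
`Δ = 0.5·standardize(M1 score) + 0.8·1[M2] + Normal(0, 0.3)` over
5000 sites with half the sites carrying M2 — generative R² ≈ 0.8, so
an ideal predictor reaches r ≈ 0.9 and the acceptance bound of 0.69
corresponds to recovering most of the available signal. M1 instances
are sampled per-column from the PWM so motif scores vary; M2 is
planted as its consensus because it enters the generative model as a
binary presence indicator. The planted M2 starts 21 bp 3' of the M1
center in motif orientation, and the attribution mass check asks that
at least 60 percent of absolute CWM mass fall inside the M1 window
(±9 bp) plus the M2 window (+21..+29 bp).

## Hi-C pileups and insulation

Observed/expected normalization divides each (weight-balanced) entry
by the expected value at its genomic distance. By default the
expected is the empirical mean of the diagonal; a known analytic
decay can be supplied instead. The distinction matters for
calibration: planted boundary depletion contaminates empirical
diagonal means, so the quadrant statistic on a noiseless planted
matrix equals the planted strength *exactly* only when the
generator's analytic decay is used as the expected — the calibration
tests therefore use it, and at 10-kb resolution with three boundaries
per 200 bins the empirical-expected statistic lands ~13 percent low,
a bias that shrinks with boundary sparsity (a single boundary in 400
bins recovers within 2 percent).

Local pileups average O/E submatrices in a ±300-kb window (pad)
around anchor bins, flipping both axes for minus-strand anchors;
distal pileups average anchor-pair rectangles at ±100 kb. Missing
cells are excluded from per-cell means with counts retained, and
anchors whose window leaves the matrix are skipped and counted — no
statistic silently includes out-of-range bins. The quadrant
insulation strength of a pileup is the mean of the upper-left and
lower-right quadrants over the mean of the upper-right and
lower-left — contacts that do not cross the central bin over those
that do — ignoring cells within two diagonals of the main diagonal
(the short-range artifact mask) and excluding the central row and
column from every quadrant (the central-bin treatment is a documented
package choice). Quadrant means pool cells of the averaged pileup
(statistic of the mean), one of two defensible orders.

The diamond insulation track is, per bin, the mean balanced contact
in the w × w square straddling the bin (w = window/resolution,
default 100 kb at 10 kb), reported as log2 over the chromosome-wide
mean; local minima are boundary candidates scored by prominence, and
the default strength threshold is Li's iterative minimum
cross-entropy threshold on the candidate strengths — a
reimplementation choice, not claimed parity with any external
thresholding. Note that the diamond fully crosses a boundary at both
flanking bins, so the minimum legitimately sits on either. TAD
intervals pair consecutive boundaries and drop candidates longer than
1.5 Mb (exactly 1.5 Mb is kept). Pileup ratios divide elementwise
with missing propagation; the insulation strength of a ratio window
and the ratio of insulation strengths agree only approximately, so
both are reported.

## The synthetic generators

All generators are driven by one `synthetic_config()`; the seed fully
determines every output (each generator draws from its own derived
stream and restores the caller's RNG state). Defaults describe the
desk-scale study condition: 42 percent GC i.i.d. background (no
repeat structure — sufficient for motif and profile testing, one of
the stated limitations below), 19-bp M1 and 9-bp M2 placeholder
motifs, M2 offset +21, NRL 182 bp with 10 bp dyad jitter, 10
nucleosomes per array side, 50 cells, read depth 10^6, 8-fold IP
enrichment, a 30-bp footprint with accessible/protected methylation
probabilities 0.8/0.1, 10-kb Hi-C bins with decay exponent −1 and
twofold boundary depletion. Site placement uses a jittered grid with
a minimum gap, which keeps placement linear-time and collision-free;
a genome too short for the requested sites is an explicit capacity
error.

Two bookkeeping details deserve note. First, nucleosomal fragments
emit one ~Normal(147, 10) fragment per dyad with Bernoulli(0.5)
strands — strand balance matters for the phasogram, phase does not.
Second, the IP generator draws *exactly* `read_depth` fragments from
a density that is 1/bp outside and F/bp inside the 251-bp windows of
bound sites. Because the enrichment score normalizes by library
size, the measured bound-site enrichment then has the closed form
`log2(F·L/Z)` with `Z = L + n_bound(F−1)w`: planting enrichment
necessarily dilutes the background share of the IP library. With 600
sites in a 1-Mb genome this shrinks measured log2 enrichment from 3
to ~2.35 (still far above the twofold calling threshold — recall and
false positive rate are unaffected), while a small planted mass
fraction (50 bound sites per Mb) keeps the measurement within 0.2 of
log2 F, which is the condition the recovery test uses. The Poisson
Hi-C sampler has a `noiseless` switch that emits expected values for
the exact analytic tests, and every matrix carries its analytic
decay as an attribute.

## What passing tests do and do not show

The generators emulate the *statistical* structure the analyses key
on: planted motifs with graded scores, phased arrays, uniform
backgrounds, binomial methylation, Poisson contacts with block
depletion. They do not emulate mappability, GC or fragment-length
bias, repeat sequence, PCR duplication, chromatin-state
heterogeneity, inter-chromosomal contacts, or realistic read
qualities (no FASTQ). Recovery on synthetic data therefore
demonstrates the correctness of the implementations and estimators
under their own model assumptions — not performance on real
libraries, and no real-data headline number is claimed or
reproduced. Problem sizes in the tests (10^6-fragment libraries, 200
anchors × 50 cells, 5000 training sites, 200-bin contact matrices)
were chosen as the smallest sizes at which the stated tolerances are
comfortably identifiable.

## Numerical and degenerate-input choices

Running means truncate at edges (constants are fixed points). The
phasogram FFT rounds to integers, exactness being guaranteed by the
all-pairs oracle tests. Median normalization refuses degenerate
all-zero profiles. Zero-coverage footprint positions are missing,
never zero. Insulation with an empty quadrant after masking is an
error, not an NA. k-means++ duplicate centers are jittered by 1e-9
so Lloyd's algorithm accepts them; duplicated points collapse to a
zero-WCSS cluster. Fragment tables reject `end ≤ start` with the
offending line number. Depth-0 simulation yields empty, flagged
tables rather than errors. The CNN trains on all-constant labels but
flags zero label variance in its report.
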