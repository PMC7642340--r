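---
title: "Molecular tagging with nanopore-read DNA barcodes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular tagging with nanopore-read DNA barcodes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models behind each stage of the `molbit`
pipeline, the parameters that matter and why their defaults were chosen,
the numerical conventions, and the boundaries of what the synthetic
experiments can and cannot demonstrate.

## The system in one paragraph

A molecular tag is a mixture of DNA strands. Each strand ("molbit") is a
unique 40-nt barcode joined to a fixed spacer; a 96-bit binary word is
written by including or omitting each of 96 molbits from the mixture.
Reading a tag is a short nanopore sequencing run: every read's raw
current trace is classified to a molbit identity, per-molbit read counts
are accumulated, rescaled, binarized at a swept threshold, and decoded
to the nearest codeword of a random linear error-correcting code whose
32-bit message is the user's payload.

## Squiggle model

`simulate_squiggle()` is a k-mer lookup simulator: as the strand
translocates, the current level is determined by the k-mer occupying the
pore, so a sequence of length L produces L − k + 1 *event levels*, each
held for a dwell and optionally perturbed by Gaussian noise at the
k-mer's level standard deviation.

Parameters and defaults:

* `k = 6`, `samples_per_base = 10` — typical of current nanopore
  chemistries; both configurable, and any pore model table (TSV of
  `kmer`, `level_mean`, `level_stdv`) can be loaded with
  `read_pore_model()`. `synthetic_pore_model()` draws level means
  uniformly in 60–120 pA and standard deviations in 1–3 pA, the working
  range of common pores.
* `dwell_model` — `"fixed"` holds every event for exactly
  `samples_per_base` samples and is used wherever a deterministic
  squiggle is needed (the design optimizer compares noiseless
  fixed-dwell event levels); `"geometric"` draws dwells as
  1 + Geometric with mean `samples_per_base`, emulating stochastic
  enzyme stepping, and is the realistic condition paired with noisy
  simulation. Cumulative dwell jitter is what makes classification
  non-trivial: the barcode's position and length in the raw signal vary
  considerably from read to read.

This simulator is a deliberate simplification: it has no convolutional
response blending adjacent k-mers, no slow baseline drift, no adapter or
stall prefix, and no event-level outliers. Absolute DTW distances
between its squiggles are therefore on a different scale from any
simulator with a different response model, which is why the design
stage's separability numbers are meaningful only relative to one
another.

### Preprocessing

Classification consumes signals normalized by
`preprocess_signal()` = MAD rescale → stall trim → truncate:

* **MAD rescale**: `(x − median(x)) / (1.4826 · MAD(x))`. The constant
  1.4826 makes the MAD a consistent estimator of the standard deviation
  under normality, giving a robust z-score insensitive to per-read
  offset and gain. A constant signal has MAD 0 and is rejected as
  degenerate rather than silently producing NaNs.
* **Stall trim**: real reads begin with a variable-length low-variance
  stall. After an unconditional `fixed_skip` (default 200 samples), the
  leading samples are dropped until a rolling window (default 50
  samples) has standard deviation above `stall_sd_fraction` (default
  0.2) of the global SD. The rolling-SD heuristic and its defaults are
  this package's own choice — they are exposed in
  `preprocess_config()` — and the fallback contract guarantees a
  nonempty result even for an all-stall signal. Purely synthetic
  barcode-only squiggles have no stall, so the desk-scale configurations
  below set `fixed_skip = 0`.
* **Truncate** to the first `truncate_to` samples (default 3000, of
  which a real barcode occupies roughly the first tenth). Shorter
  signals are kept unpadded here; fixed-length zero padding is applied
  by the classifier, keeping preprocessing lossless.

## Barcode design

`init_barcodes()` + `evolve_barcodes()` implement an evolutionary search
for a set of sequences whose *squiggles* are mutually far apart under
dynamic time warping.

**Distance.** `dtw_distance()` is classic DTW (steps (i−1,j), (i,j−1),
(i−1,j−1); local cost |a−b|) on z-normalized event-level vectors, with
the accumulated cost divided by the optimal warping path length so that
sequences of different lengths are comparable. Ties between predecessors
are broken deterministically (diagonal, then vertical, then horizontal),
which pins down the path length when several optimal paths exist.
Z-normalization is skipped for signals of length < 2 or zero spread. DTW
is a symmetric premetric — d(x,x) = 0, d(x,y) = d(y,x) ≥ 0 — but
violates the triangle inequality, so no test asserts it.

**Constraints.** Independent constraints apply to one sequence: GC in
[0.30, 0.70]; folding energy ≥ −8 kcal/mol; no forbidden motif;
homopolymers ≤ 5 (A/T) and ≤ 4 (C/G). The BsaI recognition site is
excluded on *both* strands (GGTCTC and GAGACC) because the enzyme acts
on double-stranded DNA during Golden Gate assembly; a config option can
restrict this to one strand. Dependent constraints relate a candidate to
the rest of the set: pairwise local Smith–Waterman score ≤ 15 under
(+1, −1, −8), and pairwise DTW at least a floor.

**Folding proxy.** `fold_energy_proxy()` scans all hairpins with a
perfect Watson–Crick stem (≥ 4 bp) and loop ≥ 3 nt, scoring stems with
nearest-neighbor stack free energies (SantaLucia 2004 DNA/DNA, 37 °C)
plus a loop-length penalty, and returns the most stable value (0 if no
hairpin exists). Ignoring bulges, internal loops and multiloops makes it
an upper bound on the stability a full thermodynamic folder would
report, i.e. conservative in the safe direction for a ≥ −8 kcal/mol
constraint on 40-mers. The `backend` argument accepts any replacement
function, so an external thermodynamic tool can be plugged in.

**The acceptance rule.** Each round visits the sequences in a fresh
random order; each sequence gets up to 100 mutation attempts (two
adjacent bases, each redrawn from the three alternatives). A mutation is
kept only if the mutant (a) passes the independent constraints, (b)
stays ≤ 15 SW against every other barcode, (c) stays at or above the DTW
floor against every other squiggle, and (d) *strictly* improves both the
minimum and the mean DTW between itself and all others ("improve" is
read row-wise — the mutated sequence's own row of the distance matrix —
and strictly, so neutral drift cycles are impossible). Because a
sequence's row minimum can only rise, the global minimum DTW is
non-decreasing across rounds, which every run asserts.

Two values the procedure needs are not prescribed anywhere and are fixed
as follows: the DTW floor defaults to the initial set's global minimum
(so evolution never makes any pair worse than the starting set), and
termination is declared when accepted mutations have touched at most two
distinct sequences for 3 consecutive rounds — the optimization
"bouncing" between a final pair — or after `max_rounds` (default 50;
desk-scale runs use ~10, which already shows substantial improvement).

**Initialization.** `"random"` rejection-samples constraint-satisfying
sequences one at a time; `"warm_start"` draws a 10× candidate pool,
simulates all squiggles, and greedily grows a max–min-DTW subset from
the most distant SW-compatible pair. Warm starting raises the initial
minimum DTW in expectation (asserted over paired seeds) and simply gives
evolution a head start.

`partition_sets()` splits a designed set into equal groups for training
data acquisition, placing the most crowded barcodes first and assigning
each to the group maximizing its minimum within-group DTW, so easily
confused barcodes are sequenced in different runs.

## Raw-signal classifier

`train_classifier()` fits the architecture fixed by
`classifier_config()`: five blocks of (1-D convolution → ReLU →
average pooling → batch normalization), two fully connected layers
with 50% dropout, and a softmax output. The network, its Adam optimizer
with cosine learning-rate decay (to 10% of the initial rate), and
inference are implemented in compiled code inside the package;
every source of randomness (initialization, shuffling, dropout) draws
from R's RNG, so a seed makes training bit-reproducible.

Layer shapes are tunable because no single set fits all input lengths.
The default (channels 16/32/64/128/256, kernel 9, pool 3, FC 512/256)
suits 3000-sample inputs typical of real reads. The desk-scale
configuration used throughout the tests — 400-sample inputs, channels
16/32/64/64/64, kernel 7, pool 2, FC 128/64, batch 16, learning rate
3·10⁻³, 5 epochs — matches barcode-only synthetic squiggles
(~350 samples at 10 samples/base) and trains in well under a minute on
one CPU. Inputs shorter than `input_length` are zero-padded after
normalization; a prediction whose softmax maximum falls below
`confidence_threshold = 0.9` is reported unclassified (there is no junk
class — low confidence is the only rejection mechanism).

Training data come either from the simulator or, for real runs, from
`label_read_by_alignment()`: each barcode and its reverse complement is
aligned semilocally (barcode end-to-end, free end gaps on the read)
against the basecalled read, and the best barcode wins if it scores
≥ 15; exact ties are discarded. `build_training_dataset()` caps each
class at 6000 reads and splits 85/15 stratified by class.

On the seeded desk-scale problem — 16 evolved barcodes, 300 noisy
geometric-dwell reads per class, 5 epochs — validation accuracy exceeds
0.90 (the acceptance suite computes it; typical values are ~0.93–0.96).
A model trained purely on noiseless fixed-dwell squiggles classifies
noisy fixed-dwell reads essentially perfectly, confirming that Gaussian
level noise alone is easy; dwell jitter is the hard part.

## Error-correcting tag codec

Messages are `k = 32` bits (e.g. four ASCII characters); codewords are
`n = 96` bits, one per molbit: `codeword = message × G` over GF(2).

**Generator construction.** `make_generator_matrix()` rejection-samples
uniform k×n binary matrices of full rank and accepts the first for which
an information-set low-weight search finds no nonzero codeword of weight
below `required_min_distance = 19`. A code with minimum distance d
uniquely corrects ⌊(d−1)/2⌋ errors, so 19 is the smallest distance that
*guarantees* correction of t = 9 errors; the minimum pairwise tag
distance is sometimes quoted as "at least 18", which corrects 9 errors
only non-uniquely, and the parameter is exposed for users who want that
reading. For a random [96,32] code the expected number of nonzero
codewords of weight ≤ 18 is ≈ 0.95, so acceptance succeeds after ~2.6
candidates on average and construction takes well under a second. A
matrix verified by a 100,000-iteration search ships with the package.

**Minimum-weight search.** For k ≤ 20 all 2^k codewords are enumerated
(Gray-code walk), giving the exact minimum distance and the oracle
against which the stochastic search is tested. Otherwise the
information-set search repeatedly Gaussian-eliminates G to systematic
form on a random column set and records the weights of all rows and row
pairs; the result is an upper bound on the true minimum that detects
low-weight codewords quickly (a weight-18 codeword intersects a random
32-column information set in ≤ 2 positions often enough that 10⁵
iterations miss it with negligible probability).

**Decoding.** `decode_nearest()` enumerates all codewords when k ≤ 24;
for k = 32 it uses information-set decoding: sample k columns forming an
invertible submatrix, re-encode the message implied by the received bits
on those columns, and accept as soon as a codeword within distance t is
found. With e ≤ 9 errors in 96 positions, a random 32-column set avoids
all errors with probability ≈ 2%, so the default 2000–3000 iterations
make the miss probability astronomically small; a decoding at distance
≤ t is provably unique given the verified distance. The switch point
k = 24 and the iteration counts are implementation choices, exposed as
arguments.

**Threshold sweep.** `decode_tag()` scales counts (optionally), then
binarizes them at every midpoint between consecutive distinct scaled
counts, decodes each binarization, and returns the minimum-distance
decoding within radius t (ties go to the lowest threshold). Thresholds
outside the observed count range are deliberately *not* swept: a
threshold above the maximum count binarizes to the all-zero word, which
is itself a codeword at distance 0 and would preempt every true decoding
under minimum-distance selection. A count vector with fewer than two
distinct values therefore cannot be binarized and fails — including the
all-zero counts of an empty run.

**Count rescaling.** Per-molbit counts vary tens-fold but consistently
across runs. `fit_scaling_vector()` normalizes each calibration run over
its present molbits, averages per-molbit relative abundance across runs,
and returns reciprocal factors (mean 1). Scaling by accurate factors
flattens the dispersion, widening the gap between the lowest present
molbit and the misassignment background — the paired acceptance check
verifies that fitted rescaling never increases the optimal-threshold bit
error count on high-dispersion synthetic runs.

**Length channel.** `classify_by_length()` bins reads by raw signal
length at 9800 samples; the boundary itself is called "short" (the tie
rule is a documented convention — observed median lengths for the two
spacer classes, ~5800 and ~17000 samples, sit far from the cutoff).

**Failure probability.** `estimate_error_probability()` offers
`P(Binomial(n, p) > t)` — an upper bound on decoding *failure*, since
more than t errors may still decode correctly — and a Monte-Carlo
estimator that flips bits on random codewords and decodes. No closed
form for the exact incorrect-decoding chance is claimed; on a small
[12,4] code the Monte-Carlo estimate is tested against exact
error-pattern enumeration.

## Synthetic sequencing runs

`simulate_run()`/`simulate_counts()` generate the statistical structure
the decoder has to survive:

* **Abundance dispersion**: each present molbit carries a static
  log-normal(0, σ = 0.67) factor. Over 96 molbits this puts the median
  max/min spread near 25× (order statistics of 96 log-normal draws),
  the tens-fold regime reported for real runs; the distributional check
  in the test suite asserts the median ratio lies in [15, 40]. The
  log-normal family was chosen once, for positivity and a heavy right
  tail; the true generative mechanism (library prep vs pore bias) is
  unidentified, so the factor is modeled as static per molbit, which is
  exactly the consistency that count rescaling exploits.
* **Background**: each read is misassigned to a uniformly random molbit
  with probability 0.005, producing the nonzero counts observed for
  absent molbits. Flowcell carry-over contamination is not modeled
  beyond this rate.
* **Timing**: reads arrive as a Poisson process at 10,000 reads/min.
  `decode_time_curve()` subsamples the reads available by each time
  point (10 repetitions), decodes, and records distance and correctness
  — minimum decoding distance falls as reads accumulate until the tag
  decodes exactly, and `remap_tag()` reassigns molbit labels within a
  tag (1-positions to 1-positions) to simulate new tags from one run.

What the generator does **not** emulate: adapter/stall signal structure,
baseline drift, channel-to-channel variation, read truncation, real pore
models, or basecalling errors in the labeling path. Passing the
synthetic end-to-end checks therefore demonstrates the correctness and
calibration of the *algorithms* — the design optimizer's monotonicity,
the classifier's ability to absorb dwell warping at realistic noise, the
codec's guaranteed radius under realistic count dispersion — not the
accuracy figures achievable on real nanopore data, which depend on the
deposited runs and trained weights and are out of scope here.

## Desk-scale problem sizes

The test and acceptance suites run everything at sizes chosen to
exercise the full pipeline in minutes on one CPU: 16-barcode designs
(~10 evolution rounds), 300 reads per class for classifier training
(5 epochs), 500-trial decoding experiments per error weight, 20-seed
end-to-end runs of ~2000–2500 reads, and 100,000-iteration code
searches. All are the package's own choices and are trivially scaled up
through the corresponding config objects.

## Known limitations

* The folding proxy scores only perfect single hairpins; sequences with
  strong bulged structures may pass the constraint that a full
  partition-function folder would flag.
* DTW distances are simulator-relative; absolute separability values
  from other squiggle models are not comparable.
* Information-set decoding is Las-Vegas: its iteration budget bounds the
  failure probability but a pathological budget (a handful of
  iterations) can miss a correctable codeword.
* The classifier handles reverse-orientation reads only implicitly: the
  simulator emits barcode-first reads, and a real reverse read would be
  rejected by the confidence threshold rather than recognized. The
  labeling path does search both orientations.
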