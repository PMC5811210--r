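---
title: "Methods: time-resolved decoding, RSA, and model-based MEG-fMRI fusion"
author: "repdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-resolved decoding, RSA, and model-based MEG-fMRI fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

When a person categorizes a visual object, the task they are performing —
judging its color, its tilt, whether it is man-made, whether it is large —
shapes how the object is processed. Magnetoencephalography (MEG) resolves
*when* task and object information are present in neural activity; fMRI
resolves *where*. `repdyn` implements the full analysis chain that connects
the two: time-resolved multivariate decoding of task and object category,
temporal generalization analysis, time-resolved representational similarity
analysis (RSA), and model-based MEG-fMRI fusion via commonality analysis,
together with the nonparametric cluster and bootstrap inference that such
analyses require.

The experimental design the package models is factorial: 4 tasks (two
perceptual: Color, Tilt; two conceptual: Content, Size) crossed with 8
object categories, 5 exemplars, 2 outline colors and 2 tilts. Each of the
160 unique stimuli appears once per task, giving 640 experimental trials,
plus 80 catch trials, in 20 runs of 36. A trial lasts 5 s: the task cue
appears at 0 ms, the object stimulus at 2000 ms, and the response-mapping
screen at 3500 ms; epochs span −100 to 5000 ms.

No public recordings accompany this design, so the package ships a
first-class synthetic-data module with known ground truth. Every downstream
claim the package makes is validated against that ground truth.

# The synthetic-data generator

`generate_design()` produces the randomized trial table;
`generate_subject_epochs()` turns it into a trials × channels × time array:

* a **task pattern** — a standard-normal spatial vector per task, switched
  on at `task_onset_ms` after cue onset (default 100 ms),
* an **object pattern** per category, switched on at `object_onset_ms`
  after stimulus onset (default 80 ms),
* amplitude envelopes, by default boxcars with a short sigmoidal edge
  (`edge_ms = 5` ms), any nonnegative function accepted,
* a **task-type gain** multiplying the object pattern during conceptual
  tasks from `tasktype_gain_onset_ms` (default 1, i.e. off) — this emulates
  a late change in the *strength* of object representations without any
  change in their geometry,
* white Gaussian sensor noise (`noise_sd`, default 1).

Default amplitudes (0.06 in noise-SD units per unit pattern norm) were
chosen once so that, after supertrial averaging, group-level decoding is
clearly above chance without saturating — comparable in character to
event-related MEG decoding curves. The defaults are the study conditions
for all calibration and recovery tests and are not tuned per test.

The default scale is 10 subjects, 64 channels and 300 Hz generation; the
`paper` preset of `pipeline_config()` switches to 17 subjects, 272 channels
and 1200 Hz. Validating the mathematics does not require the full-scale
array.

What the generator deliberately does **not** emulate: realistic MEG noise
spectra (1/f, alpha), sensor covariance, head geometry or forward models,
eye blinks or other artifacts, trial-to-trial latency jitter. Passing tests
therefore demonstrate that the *analysis chain* is correct and calibrated
for exchangeable Gaussian noise — not that real recordings would yield any
particular result.

`generate_fmri_patterns()` synthesizes ROI condition-pattern matrices (32
conditions × units). Each task and each category receives a basis pattern;
basis patterns are distinct non-constant columns of a seeded, row-permuted,
sign-flipped Hadamard matrix, hence exactly orthogonal, zero-mean, ±1
vectors. With weights $w_t, w_o$ and unit noise $\sigma$, two conditions
sharing only a task correlate at $w_t^2 / (w_t^2 + w_o^2 + \sigma^2)$, and
in the noise-free case the induced 1 − Pearson dissimilarity structure is
*exactly* tied where the binary model matrices say it should be — which is
what makes rank-correlation recovery tests exact rather than approximate.
`n_units` must be a power of two for this construction (default 256).

# Preprocessing

The chain is fixed: filter → spatial PCA → low-variance component removal →
baseline normalization → temporal smoothing → downsampling. Each stage is a
pure function of its inputs and configuration.

**Filtering.** A zero-phase band-pass (2nd-order Butterworth high-pass at
0.1 Hz, 4th-order low-pass at 300 Hz by default) plus 2nd-order Butterworth
band-stops (±2 Hz) at the line frequency and harmonics. On 5.1 s epochs a
0.1 Hz IIR high-pass settles more slowly than the epoch lasts: a
forward-backward (`filtfilt`) pass leaves edge transients that span the
whole epoch, boost in-band tones by tens of percent, and induce strong
long-range anticorrelation in white noise. `filter_epochs()` therefore
applies the cascade's *squared magnitude response* in the frequency domain
to the mirror-extended epoch. This is exactly zero-phase, transient-free,
matches the forward-backward gain |H(f)|², removes DC to machine precision,
and passes a 10 Hz tone to within 10⁻⁶.

**Spatial PCA.** Channels are decorrelated by an eigendecomposition of the
channel covariance over all trials' samples. The rotation is purely
spatial: an impulse at sample *k* stays at sample *k*. Component sign is
fixed (largest-magnitude loading positive) for reproducibility.

**Component removal.** The largest suffix of ascending-variance components
whose summed variance is ≤ 1% of the total is removed, unless that suffix
exceeds 50% of the components, in which case exactly ⌊n/2⌋ are removed —
on a 272-component recording whose low-variance tail is broad this cap
yields 136 retained components. The 1% rule is read as a cumulative-suffix
rule; with near-equal variances nothing is removable.

**Baseline normalization.** Per component, the mean and SD over the
baseline window pooled across trials (pooled rather than per-trial, for
stability; recorded in provenance) are subtracted/divided out. Task
analyses use −100…0 ms (pre-cue); object-category analyses use 1900…2000 ms
(pre-stimulus). Decoding functions check the recorded window against the
decoded factor and refuse mismatches. A zero-SD component is an error.

**Smoothing and downsampling.** Gaussian kernel with half duration at half
maximum 15 ms (FWHM 30 ms, σ = 15/√(2 ln 2) ≈ 12.74 ms), truncated at ±4σ,
unit-sum, reflection at edges; then every (rate ratio)-th sample is kept,
starting at the epoch start. The ratio must be an integer: 1200 → 120 Hz
gives 612 samples from a 6120-sample epoch. Because 300 Hz does not divide
by 120, the desk preset downsamples to 100 Hz instead. Since the
normalization is a per-component affine map and the kernel is unit-sum and
purely temporal, normalization and smoothing commute; the pipeline exploits
this to smooth once and derive both baseline branches.

# Time-resolved decoding

At every time point and for every unordered pair of classes, a linear
maximum-margin classifier (C = 1) is trained on **supertrials** — averages
of 10 same-class trials drawn without replacement; leftovers are unused for
that draw and re-randomized on the next iteration. One supertrial per class
is held out, and performance is scored by **ordering accuracy**: 100 if the
held-out pair is ranked correctly by decision value, 0 if reversed, 50 on a
tie. For one sample per class this equals the two-sample area under the ROC
curve and is independent of the classifier's bias term. Accuracies are
averaged over pairs (28 for 8 categories, 6 for 4 tasks; chance 50%) and
over `n_iterations` re-partitions (500 at paper scale; 20 in the desk
preset; the separate chance-calibration check uses 50). Per-iteration RNG
streams derive from (seed, iteration), so iterations are reproducible and
order-independent.

The solver is an L2-regularized hinge-loss dual coordinate-descent SVM
written in C++ and batched so that all class pairs at a time point share
one Gram matrix; held-out decision values are read off the same Gram
matrix. The bias enters as a regularized constant feature — ordering
accuracy cannot be affected by this convention. The solver is cross-checked
against libsvm (`e1071`) in the test suite. The positive class of each pair
is the lexicographically first label.

`temporal_generalization()` evaluates each trained classifier at every
testing time with the same held-out supertrials, yielding a train × test
accuracy matrix whose diagonal reproduces `decode_timecourse()` exactly
under matched seeds. `cross_tasktype_object_decode()` trains object
classifiers within one task type (perceptual vs conceptual) and tests on
held-out supertrials of the same or the other type, averaged over both
directions: equal within- and between-type accuracy indicates a change of
representational strength, not geometry.

# RSA and model-based fusion

For each of the 32 task × category conditions, trials are averaged into a
condition pattern per time point; RDMs are 1 − Pearson correlation between
condition patterns, and RDVs their 496-entry lower triangles (column-major,
diagonal excluded). The condition ordering is fixed task-major and embedded
in every artifact; all cross-modal operations verify ordering equality.
Binary model RDMs put 0 where two conditions share the factor level and 1
elsewhere: the task model's lower triangle has 112 zeros, the category
model's 48. The two models are non-orthogonal, which is exactly why the
fusion regression partials each out of the other.

Fusion correlates the group-average MEG RDV at each time point with an
ROI's (group-average) fMRI RDV by squared Spearman correlation — the
coefficient of determination R² of one rank-transformed RDV explaining the
other. Commonality analysis then splits that shared variance. With X the
MEG RDV at time t, Y an ROI's fMRI RDV, A the task model and B the category
model:

$$C_{X_t,(Y,A)} = R^2_{X_t,(Y.B)} - R^2_{X_t,(Y.A,B)}$$

where $Y.B$ denotes the ranks of Y residualized on the ranks of B (least
squares, with intercept), and $R^2$ is a squared semi-partial Spearman
correlation. Commonalities can slightly exceed the total R² or dip slightly
negative (suppression, numerical error); they are deliberately not clipped.
Ranks use average-tie ranking — with binary model RDVs the ties are massive,
so the tie policy materially matters and is fixed. Rank-then-residualize
order is used (the literal reading of a semi-partial *Spearman*
correlation). By default the models are partialled out of the fMRI side
(MEG is the target); `target = "fmri"` swaps the roles, a mode provided for
comparison without any claim of equality. If a residual has (near-)zero
variance the corresponding R² is defined as 0 with a warning.

# Statistics

**1D cluster test.** Per-subject curves minus chance are sign-flipped: all
2ⁿ assignments when 2ⁿ ≤ `max_exhaustive` (131,072 at n = 17), otherwise a
without-replacement sample of `n_perm` assignments, identity always
included — so the observed data is one member of the ensemble and p-values
can never be 0. The cluster-inducing threshold is the empirical 95th
percentile (smallest value with ≥ 95% of the distribution at or below it)
of the permutation t-values at each time point; clusters are maximal
supra-threshold runs; a cluster is significant when the share of
permutations whose maximum cluster size reaches it is at most α — the exact
permutation reading of "at the 95th percentile of the max-cluster-size
null". (For discrete cluster extents, taking a literal order-statistic
threshold can place the cutoff on a large probability atom and reject far
too often; the p-value form is the one that controls the family-wise error,
and is what "equivalent to p < 0.05, one-sided" describes.) One-sided
throughout; the statistic is cluster extent in samples, not mass.

The suite calibrates the family-wise error of this test on null studies of
17 subjects whose curves carry the temporal autocorrelation the package's
own smoothing kernel imposes (σ ≈ 1.5 samples at 120 Hz). That matters:
decoding curves are never temporally white, and on white noise the
cluster-extent null degenerates to singleton clusters, making extent-based
inference vacuously conservative regardless of implementation.

**2D cluster test.** The same logic with 4-connected (edge-adjacent)
components on the train × test grid; diagonally touching points are
separate clusters. Permutations are sampled without replacement; asking for
more than 2ⁿ is an error.

**Fusion randomization test.** The null permutes the rows and columns of
the group-average MEG RDM jointly (one condition relabelling applied to
every time point) and re-runs fusion. Implementation note: a joint
row/column permutation induces a fixed index permutation of the RDV, and
rank transforms commute with index permutation, so the whole null ensemble
reduces to indexed matrix products against fixed residualized fMRI vectors
— mathematically identical to re-running fusion per permutation, and
asserted against the direct route in the tests. Per-ROI, per-time
thresholds are the null 95th percentiles; maximum cluster sizes are pooled
across ROIs to correct for multiple comparisons.

**Bootstrap latency CIs.** Subjects are resampled with replacement
(100,000 draws for decoding, 5,000 for fusion at paper scale; 10,000/1,000
in the desk preset); each draw's statistic is the argmax latency of the
resampled average curve in a window (earliest maximum on ties, flagged if
the window is flat), a difference of argmaxes, or — for onsets, which the
underlying analyses never define formally — the earliest time the average
curve exceeds a configurable criterion. The CI is the 2.5/97.5 percentile
(order statistics, so endpoints lie on the time grid; at bin width Δ the
interval is conservative by up to 2Δ). Fusion-mode draws average the
resampled subjects' MEG RDM series and re-run fusion before taking the
latency.

# Pipeline

`pipeline_config()` holds every stage's parameters in one nested document
(JSON round-trip, unknown keys rejected before compute); all stage seeds
derive deterministically from the global seed, so a configuration fully
determines every output, and re-running reproduces identical file
checksums. `run_pipeline()` executes simulate → preprocess → decode →
cross-decode → temporal generalization → RSA → fusion → cluster statistics
→ bootstrap CIs, writing CSV/JSON artifacts plus a checksum bundle and run
log; `read_bundle()` verifies checksums on load. The desk preset completes
on one CPU in well under the 15-minute target (about 12 minutes), with
problem sizes chosen as: 10 subjects, 64 channels, 300 Hz → 100 Hz, 20
decoding iterations (10 for cross-decoding and generalization,
`time_step = 5` on the generalization grid), 2,000/1,000 permutations and
10,000/1,000 bootstrap draws.

Catch trials are generated (they are part of the design) but excluded from
every analysis; nothing in the underlying procedure suggests they were
analyzed. Epochs are serialized as RDS when requested; tables, RDMs,
configurations and results as CSV/JSON.

# Known limitations

* The generator's noise is white; calibration under realistic (1/f,
  spatially correlated) noise is not demonstrated.
* The frequency-domain zero-phase filter is the right tool for epoched
  data, but its response differs at the margins from a forward-backward
  IIR pass on continuous recordings.
* Onset estimates use a criterion-crossing definition; cluster-onset
  recovery depends on SNR and the ±4σ smoothing leakage (~50 ms at the
  default kernel), which biases detected onsets early at very high SNR.
* ROI patterns are synthesized with exactly orthogonal bases; real
  condition patterns are anything but orthogonal, so fusion recovery rates
  here are upper bounds on what matched real data would give.
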