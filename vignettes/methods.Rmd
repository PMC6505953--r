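---
title: "Methods: inverted encoding of spatial working memory from oscillatory EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inverted encoding of spatial working memory from oscillatory EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ctfiem` implements a complete analysis chain for tracking spatial
representations held in working memory through the scalp topography of
band-limited EEG power: spectral estimation, an inverted encoding model
(IEM) with cross-validation, selectivity statistics with cluster-based
permutation inference, a simulated-switching null for multi-item storage,
mixture models of continuous-report behavior, and a synthetic-data
generator that makes every stage testable without any recorded data.
This vignette explains the model, the choices that were genuinely open,
and what the package's validation does and does not establish.

## The encoding model and its assumptions

The model assumes that band power at each electrode is a *linear,
time-point-wise* mixture of `k` spatially tuned channels (default
`k = 8`, matching an 8-bin position design), and that a channel's
response falls off with angular distance `d` from its preferred location
as a half sinusoid raised to a power:

$$R(d) = \cos(d/2)^{25}.$$

The exponent (default 25) controls tuning width; the value at one bin
width (45°) is ≈ 0.138, so neighboring channels overlap only modestly.
Training estimates the electrodes × channels weight matrix by ordinary
least squares from bin-averaged power; testing inverts the mapping on
held-out bin averages. Both closed forms
($\hat W = B_1C_1^\top(C_1C_1^\top)^{-1}$,
$\hat C_2 = (\hat W^\top \hat W)^{-1}\hat W^\top B_2$) define the
*value*; the implementation solves the least-squares problems by QR
factorization and refuses rank-deficient systems with an explicit error
rather than falling back to a pseudo-inverse silently. Degenerate
configurations (fewer electrodes than channels) are rejected at
configuration time.

Two modeling decisions were open and are worth stating:

* **Training predictions use bin centers.** The training measurements
  are per-bin averages, so the predicted channel response for a bin-`b`
  measurement is the basis evaluated at `b`'s center, not at the mean of
  the within-bin jittered angles. Exact angles are used only by the
  generator (and by the behavioral analyses, where they matter).
* **Channel offsets** are reported on the grid −135°…180° in 45° steps,
  defined as (channel center − probed bin center) mod 360 mapped to
  (−180°, 180°]; 180° is its own fold partner.

## Cross-validation regimes

Trials are partitioned into 3 sets with equal per-bin counts per set
(excess trials left out, re-randomized over iterations so all trials
contribute); two sets train, one tests, rotating through all folds.
`run_iem()` offers three regimes:

* `condition_neutral` — per-bin counts additionally equated *across*
  conditions and training data combined across conditions before
  averaging. One encoding model per fold serves every condition's test
  set, so condition differences in reconstructed selectivity are
  attributable to the test data alone. This is the regime for comparing
  conditions, and the one the simulation harness uses.
* `within_condition` — train and test inside one condition; appropriate
  when asking *which* frequencies or times carry information in each
  condition separately, not for comparing selectivity across conditions.
* `cross_training` — train on one-item data, test two-item data; used
  for the inter-item distance profiles and the switching comparison.

Iteration count is a knob: 50 is conventional for single-band analyses,
10 for frequency sweeps and for the simulations (where partitions have
no excess trials and iterations only smooth partition noise).

## CTF slope

Selectivity is the OLS slope of the folded profile (offsets ±45, ±90,
±135 averaged pairwise) against the unit-spaced ranks of decreasing
distance, *not* against degrees. This makes the statistic scale-free
with respect to the offset grid; its magnitude therefore depends on the
convention, and values are comparable only within it. A noiseless
exponent-25 profile gives slope ≈ 0.2138 (the package's exactness tests
pin this against an independent regression oracle); realistic band-power
CTFs are an order of magnitude lower.

## Cluster-based permutation inference

Pointwise one-sample t statistics (against zero) are thresholded at the
one-sided 0.05 critical value recomputed from the sample size
(t = 1.703 at n = 28); contiguous supra-threshold runs (1-D adjacency in
time; 4-connectivity in time × frequency, 8 available) form clusters
scored by summed t. The null distribution of the maximum cluster mass
comes from re-running the IEM with position labels permuted within every
training and test set; observed clusters beating the 95th percentile are
significant — a one-tailed test with family-wise error control.
Zero-variance points are treated as sub-threshold rather than producing
infinite t. The suite calibrates the whole procedure: under a pure null
the family-wise error rate over 500 runs must sit inside the binomial
95% band around 0.05.

## The switching null

The switching account holds that only one of two remembered items is
neurally active at any moment. `simulate_switching()` builds the
corresponding null from one-item data by randomizing the position labels
of a fraction (default 50%) of trials, fresh on every IEM iteration.
Two choices deserve explanation:

* **Scrambling enters at the reconstruction stage; the encoding model is
  trained on veridical labels.** The switching hypothesis leaves the
  encoding itself intact — what varies is which item drives it — so the
  null perturbs the test-stage labels, not the model. There is also a
  sharp technical reason: because the least-squares inversion undoes any
  label mixing it was trained on (the mixing operator commutes with the
  circulant basis), scrambling the training labels as well largely
  *cancels*, and the "null" would reproduce the full one-item CTF.
  With test-stage scrambling the expectation is exact: the switching CTF
  is `fraction × flat + (1 − fraction) × CTF`, so its slope is
  `(1 − fraction)` times the one-item slope — the property the tests
  assert at fraction 0.5.
* **Labels are randomized by permutation within each partition set**, not
  by iid redrawing over bins. Permutation preserves every set's per-bin
  trial counts; iid redrawing unbalances them, and the resulting
  ratio-estimator bias inflates the switching slope by roughly the
  inverse per-bin count (~1.6% under the default design), enough to
  break the strict-alternation equivalence below at n = 28. Uniform
  redrawing (over all bins, or over the 7 non-true bins) remains
  available via `redraw=`.

`switching_study()` validates the comparison against ground truth with a
common one-item-trained model and both the two-item data and the
switching null entering as test sets only (reconstruction is linear in
the test data, so the two reconstructions differ only in what they are
asked to reconstruct — the same logic as condition-neutral training).
Under a strict-alternation truth the two-item and switching slopes are
statistically indistinguishable; under concurrent storage at 75%
per-item amplitude the two-item slope wins essentially always at n = 28.

## Spectral estimation

Band-limited instantaneous power is obtained by zero-phase
(forward–backward) FIR filtering (Hamming window, order
`3 × floor(rate / low-cutoff)`, the conventional heuristic for two-way
FIR filtering of EEG), followed by the analytic signal via the Hilbert
transform and squaring of the complex magnitude. The analytic-signal
construction is implemented in-package via the FFT (no installed R
package provides it). Downsampling (default 20 ms) is pure decimation
*after* power computation, so retained values are an exact subsequence
of the full-rate power. Samples within one filter length of the epoch
edges are flagged in metadata and should not be interpreted; note that
with the order heuristic above, bands below ~8 Hz on short (2–3 s)
epochs are almost entirely edge, and that the heuristic makes
high-frequency bands of a 1-Hz sweep effectively much wider than 1 Hz —
a property of the legacy design the package reproduces deliberately, and
the reason the white-noise calibration test predicts each band's power
from its own filter's frequency response rather than expecting equal
power across bands.

## The synthetic generator

The generator is first-class, tested code: it defines the study
conditions under which everything else is validated. Defaults are the
canonical ones — 28 subjects, 576 trials per condition, 30 electrodes,
8 channels with exponent 25, channel weights drawn uniformly from
[0, 1] (one weight matrix per subject, shared across conditions),
additive two-item responses, i.i.d. Gaussian electrode noise of SD 1 —
with two standard variants: extra two-item noise (SD 2) and two-item
amplitude scaled by 0.9. Position bins are exactly counterbalanced (each
of the 64 ordered two-item bin pairs occurs `n/64` times), jitter within
a bin is uniform over its 45° wedge (the maximum-entropy choice
consistent with covering all 360°), and the two items' exact positions
are kept at least 4.6° apart by joint rejection sampling (a
configuration knob approximating the physical non-overlap constraint of
two small stimuli on an invisible ring; the analyses are insensitive to
its exact value). `generate_timecourse_dataset()` embeds tuning inside a
stated time window only, giving the time-resolved pipeline and the
cluster test exact ground truth.

What the generator does *not* emulate: continuous raw EEG (it produces
power-like values directly, since the simulations have no time
dimension), 1/f spectra, artifacts, eye movements, temporally correlated
noise, or across-electrode noise correlations. Passing tests therefore
establish the *internal* validity of the machinery — exactness on
noiseless data, calibration under the generator's noise model, and
correct behavior of the comparisons under known ground truth — not that
real recordings satisfy the model's assumptions. Real epoched data enter
through the plain-text containers (`read_epoched_power()`, long-format
CSV plus JSON sidecar; trial metadata as CSV) and flow through the same
pipeline via `run_pipeline()`.

## Behavioral mixture models

Continuous-report errors (signed degrees, wrapped to (−180°, 180°] with
the boundary mapping to +180°) are fit by maximum likelihood with a
two-component mixture (von Mises centered on the target plus a uniform
guess component) or three components (adding a von Mises centered on the
unprobed item's location — swaps — sharing the target's dispersion).
Optimization is multi-start bound-constrained L-BFGS over log
concentration and stick-breaking logits of the weights (which enforces
`p_guess + p_swap ≤ 1`); non-convergence is flagged on the returned
object, not thrown. Dispersion is reported as circular s.d. converted
from the concentration through the mean-resultant-length relation, with
an asymptotic Bessel expansion above κ = 10⁴ and an s.d. floor of 0.5°
so degenerate samples keep a finite likelihood. The estimator is the
MLE throughout. Recovery is validated by generating from the same
mixture (the generative twin `generate_behavioral_errors()` records each
trial's true component) and requiring all three parameters back within
±15% at n = 5,000.

## Numerical and performance choices

The 10,000-sample simulation studies run through a compiled
(RcppArmadillo) implementation of the condition-neutral IEM hot path,
with a xoshiro256++ RNG and ziggurat normal sampler. Correctness is
enforced two ways: the deterministic core must agree with the R
reference path to ~1e-12 on shared inputs and partitions, and the
sampler's RNG and study-level statistics are tested against analytic
moments and the R engine. Per-sample seeds are derived in R from the
study seed, so results are reproducible given the seed (R and C++ paths
are distributionally, not bitwise, equivalent). The R path remains the
implementation of record for every regime the compiled path does not
cover (time courses, sweeps, non-8-channel bases).

Problem sizes in the shipped tests were chosen to keep the default suite
in the minutes range while leaving tolerances honest: desk-scale studies
use 1,000 samples (binomial 95% band [3.5%, 6.6%] around the 5% rate),
the cluster calibration uses 500 runs × 400 permutations, switching
Monte Carlos use 40–100 samples, and mixture recovery uses 20 seeds at
n = 5,000. The full 10,000-sample studies live in
`scripts/acceptance.R`.

## Known limitations

* The slope statistic's magnitude is convention-dependent (rank x-axis);
  only comparisons within the convention are meaningful.
* The two planned window comparisons (delay 250–1250 ms, late 800–1250
  ms) are reported with raw p values; no multiplicity correction is
  applied across them.
* Condition-neutral partitioning equates per-bin counts to the *minimum*
  across conditions and bins, discarding excess trials per iteration by
  design; with severely unbalanced real data this can be wasteful.
* The spectral stage offers FIR + Hilbert only (no wavelets or
  multitapers), no artifact handling, and no baseline correction beyond
  a pass-through for already-baselined input.
* Real-data effect sizes cannot be validated without recorded EEG; the
  package's guarantees on that front are interface-level (the file
  containers and pipeline run end-to-end on externally supplied data).
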