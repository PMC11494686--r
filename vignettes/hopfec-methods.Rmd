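---
title: "Models and methods: RMSSD activation and generative effective connectivity for block-design episodic-memory fMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hopfec)
```

This vignette is the package's own account of its models, parameter
choices, numerical conventions and limitations. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## The experimental design being modelled

Each acquisition is 550 s of task inside a 696-sample scan at
TR = 0.8 s (556.8 s; the trailing 6.8 s are prompt-time padding and
belong to no analysis phase). The task template is fixed: 10 s of
fixation, then three cycles of

* an 80-s *encoding* (storage) block — eight 10-s trials, each a 5-s
  image followed by a 5-s blank;
* a 10-s counting-backwards baseline;
* an 80-s *retrieval* (recall) block of eight trials;
* a second 10-s baseline.

That gives 24 encoding and 24 retrieval trials per acquisition and a
paradigm fundamental of 0.1 Hz (10-s trials). Three tasks
(object-location, reward-location, word-pair) share the template. The
text calls both the within-acquisition cycles and the acquisitions
"runs"; the package models one acquisition per task containing three
cycles, because 550 s ≈ 696 × 0.8 s and the block counts fit a single
scan. "Averaging across runs" is therefore implemented as averaging the
three congruent 180-s cycles (`average_cycles()`).

**Sample/event alignment.** 10-s blocks are 12.5 samples at TR 0.8 s,
so event boundaries fall between samples. The package assigns a sample
to an event iff its acquisition midpoint `(i - 0.5) * TR` lies in
`[onset, onset + duration)`. This is deterministic, makes each cycle an
exact 225-sample segment, and gives the encoding phase exactly 100
samples per cycle. The storage mask is `encoding_image ∪
encoding_blank` (the recall mask likewise): the 0.1-Hz rise-and-fall
that the activation measure targets spans the blank half of every
trial.

## Parcellation

All tables and matrices are framed by an ordered region scheme with
every label present once per hemisphere (`load_parcellation()`). The
packaged default is the 360-region HCP-MMP cortical atlas, stored as a
plain TSV in the standard Glasser 1–180 label order per hemisphere.
(Published figures sometimes use the HCPex re-ordering of the same
labels; ordering is presentation only — every operation here is
label-keyed — and any ordering can be supplied as a metadata table.)
`reduced_scheme()` subsets the atlas while preserving left/right
pairing, so laterality stays defined at desk scale. The five a-priori
ROI sets (`memory_roi_sets()`) are the ventromedial "scene" stream
(VMV1-3, VVC, PHA1-3), the lateral temporal semantic system (STGa,
STSda, STSdp, STSvp, TGd, TGv, PSL), Broca's area (44, 45, 47l), the
orbitofrontal/vmPFC/pregenual-cingulate reward system (d32, p24, pOFC,
s32, 10d, 10pp, 11l, a10p, OFC, p10p), and intraparietal LIPv, MIP,
VIP.

## Activation: preprocessing and RMSSD

Per region and acquisition the chain is fixed as: within-region
averaging (when vertex data are supplied) → linear detrend →
Butterworth band-pass → cycle averaging → phase masking → RMSSD. The
band-pass is second-order and applied forward–backward (zero phase):
RMSSD is computed on segments whose timing must not shift, and the test
suite checks that a band-centred sinusoid's cross-correlation peak
stays at lag 0.

Two bands are used, both configurable:

* **activation band, 0.05–0.15 Hz** — "close to 0.1 Hz" realised as a
  symmetric band around the paradigm fundamental;
* **FC band, 0.008–0.08 Hz** — the conventional slow band for BOLD
  functional connectivity.

`RMSSD(x) = sqrt(mean(diff(x)^2))` is nonnegative and scale-
equivariant; for a narrowband signal it is proportional to the signal
SD (the suite asserts r > 0.7 between regional RMSSD and regional SD on
the default synthetic cohort — a strong-positive property, not a
reproduction of any real-data value). Laterality is plain R − L per
paired label; the cohort grand-mean activation is reported alongside
because figures conventionally plot R − L around that baseline.

## The coupled Hopf model

Each region j has a two-dimensional state near a Hopf bifurcation:

$$\dot x_j = (a - x_j^2 - y_j^2)x_j - \omega y_j
  + G\sum_i C_{ji}(x_i - x_j) + \sigma\eta,$$

with the symmetric equation for $y_j$. `C` is oriented column → row:
`C[j, i]` couples region i *into* region j. Defaults: a = −0.02 (noise-
driven fluctuations just below the bifurcation, the standard operating
point for resting/task BOLD modelling), f = 0.05 Hz (centre of the slow
band), G = 1, σ = 0.01, integration step dt = 0.1 s with Euler–Maruyama
and a discarded 60-s burn-in, subsampled every TR/dt = 8 steps (TR/dt
must be an integer). For a > 0 the noiseless node settles on a limit
cycle of radius √a; the suite checks √0.04 = 0.2 within 2% at
dt = 0.01. At the working step dt = 0.1 the explicit Euler scheme
carries a known radius bias of order dt·ω²/2 (≈ 6% at f = 0.05 Hz) —
irrelevant to GEC fitting, where the same discretisation sits on both
sides of the comparison, but worth remembering if absolute amplitudes
matter.

The integrator is compiled (Rcpp) because it sits inside the GEC
fitting loop; it draws noise from R's RNG, so every simulation is
reproducible from `set.seed()`-style integer seeds, and it aborts with
the offending step index if a trajectory diverges.

## Synthetic cohorts with known ground truth

`cohort_spec()` fixes the study conditions: 23 participants × 3 tasks ×
one 696-sample acquisition. Ground-truth coupling is drawn by
`make_ground_truth_network()` (edge probability `density`, half-normal
magnitudes scaled by `strength_scale = 0.1`, clipped to the same
[0, 0.2] range the estimator uses, zero diagonal). Defaults chosen
where no value was prescribed: edge density 0.3 (sparse but
well-connected at desk scale), per-subject multiplicative log-normal
jitter with SD 0.1 on both effect gains and coupling entries (mild,
realistic between-subject heterogeneity).

Task effects are injected as a 5-s image boxcar convolved with a
canonical double-gamma HRF (peak ≈ 5–6 s, undershoot ≈ 16 s, 1:6
ratio), scaled by `base_amplitude × gain × jitter` and added only to
the targeted ROI / task / phase / hemisphere. `base_amplitude = 0.05`
is about one SD of the background Hopf fluctuation at the default noise
level, i.e. a clearly detectable but not overwhelming response. The
Hopf background itself is left unconvolved, mirroring the common
practice of fitting Hopf dynamics directly to band-limited BOLD. The
default effect structure mirrors the qualitative findings the analyses
are meant to detect: scene-stream and intraparietal responses in both
location tasks (storage and recall), semantic and left-lateralised
Broca responses in word-pair storage, and reward-system responses in
reward-location storage.

What the generator does *not* emulate: scanner drift and physiological
noise spectra, spatial autocorrelation between neighbouring parcels,
HRF variability across regions and subjects, and motion artefacts.
Passing tests therefore demonstrate the pipeline's correctness and the
estimator's recoverability under the stated generative model — not
robustness to every artefact of real BOLD.

## GEC fitting

`fit_gec()` starts from C = 0 and iterates: simulate the Hopf model at
the current C (freshly seeded from `(seed, iteration)`), compute the
simulated FC and τ-lagged FC, and update

$$C_{ij} \leftarrow C_{ij} + \epsilon\,[(FC^{emp} - FC^{sim})_{ij}
  + (FC_\tau^{emp} - FC_\tau^{sim})_{ji}]$$

for i ≠ j, clipping into [0, 0.2]. The error `MSE(FC) + MSE(FC_τ)` is
tracked per iteration and the C with minimum error is returned; fitting
stops after `patience` iterations without improvement. τ = 2 s becomes
`lag_samples = round-half-away-from-zero(τ/TR) = 3` (2.4 s) — integer
lags only, no fractional-lag interpolation.

Three numerical choices were genuinely open and were settled by
ground-truth recovery experiments (reproduced in the test suite):

* **Lag-term orientation.** The lagged difference enters *transposed*:
  the entry driving `C[i, j]` (coupling j → i) is the lag statistic in
  which j leads i. With the transposed term the 10-region benchmark
  (density 0.3) recovers the true pattern at r ≈ 0.86 and clearly
  beats the transposed ground truth (r ≈ 0.47); with the untransposed
  pairing the fit cannot distinguish the two orientations (both
  ≈ 0.64).
* **Step size and schedule.** ε = 0.02, `max_iter` = 200,
  `patience` = 30, per-iteration simulation length 2784 samples (4
  acquisitions). Much smaller steps or shorter simulations leave the
  fit far from convergence before the (noisy) error plateau trips the
  early stop. All are config-exposed.
* **Filtering inside the fit.** The simulated series is passed through
  the same band attached to the empirical FC, so model and data are
  compared like for like. For recovery experiments on synthetic Hopf
  data the connectivity is computed *unfiltered* (`band = NULL`): the
  model's output is already band-limited, and narrowband filtering
  makes the series quasi-sinusoidal, which destroys most of the
  lead–lag information the τ-lagged FC carries (recovery drops from
  ≈ 0.86 to ≈ 0.68 with the 0.008–0.08 Hz band). Real BOLD keeps the
  slow band, which there serves to remove out-of-band noise.

Couplings are constrained nonnegative with cap 0.2, matching the
reporting range of the field's EC heat maps. Estimation is at group
level by default: per-participant FC and lagged-FC matrices are
Fisher-z averaged and one fit is run on the averages — the same
construction the split-half reliability uses. EC matrices are
conventionally reported per hemisphere (`hemisphere = "L"` in the
pipeline default); full-cortex fits are a config switch.

**Directionality reversal.** For fMRI with τ on the order of seconds,
fitted directed influences are interpreted in the reversed direction;
`reverse_for_fmri = TRUE` transposes the returned matrix and flags it
(`reverse_directionality()` is an exact involution). Recovery
experiments validate against the ground truth with reversal *off*:
synthetic Hopf output has no haemodynamic inversion to undo, so the
unreversed estimate is the one comparable to `C_true`.

`split_half_reliability()` splits n participants ⌊n/2⌋ / ⌈n/2⌉ (23 →
11 / 12), runs the group fit per half under the same configuration
(hence a common orientation), and correlates the vectorised
off-diagonal entries. With zero between-participant variability the two
halves agree up to fitting-simulation noise; the suite requires
r > 0.95 there using converged settings.

## Statistics

ROI contrasts are paired t-tests across participants on per-participant
ROI means (unweighted over the ROI's regions, both hemispheres unless
scoped — the Broca contrasts are left-scoped, following the
lateralisation of the language findings the battery encodes). The
packaged battery holds nine pre-specified contrasts; significance is
the a-priori two-tailed α = 0.02 with *no* further multiplicity
correction — the design's stated policy, with α configurable.
Degenerate inputs follow fixed conventions: zero-variance nonzero
differences give t = ±∞, p = 0; identical vectors give t = 0, p = 1.
The suite verifies the statistic digit-for-digit against the closed
form, and calibration on null cohorts: over 200 replicate batteries the
false-positive counts (pooled and per contrast) must lie within the
central 95% binomial acceptance region of α.

## Problem sizes used in validation

All validation runs at desk scale, chosen so the full suite runs in a
few minutes: 10–12-region schemes for estimator recovery (23
participants for the headline recovery, 2-participant groups across 5
seeds for the data-length comparison, where empirical noise — not
fitting noise — limits recovery), a 72-region ROI-complete scheme for
activation, laterality and battery tests, and 200-replicate null
batteries for calibration. The acceptance script fits a 12-region,
23-participant cohort with the default configuration and reports the
maximum coupling entry of the group estimate.

## Known limitations

* The update rule is a heuristic fixed-point scheme, not a gradient of
  an explicit likelihood; convergence is monitored, not guaranteed.
* Parameter recovery is demonstrated for the model family that
  generated the data; with real BOLD the Hopf model is itself an
  approximation, and recovery quality cannot be asserted from these
  experiments.
* Homogeneous node parameters (a, ω) are assumed by default;
  per-region values are accepted but no fitting of them is provided.
* No anatomical prior restricts which couplings may update, and
  couplings are nonnegative by construction — inhibitory effective
  interactions are outside the model's expressive range.
* The synthetic haemodynamic response uses one canonical HRF for all
  regions and subjects.
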