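---
title: "Methods: synthetic glottal area waveforms and frame-rate stability analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic glottal area waveforms and frame-rate stability analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`gawsense` studies how objective measures of vocal-fold vibration, computed
from the glottal area waveform (GAW) of laryngeal high-speed videoendoscopy,
depend on the camera's recording frame rate. Because no public recordings
accompany this kind of experiment, the package's evidence comes from a
synthetic cohort with known ground truth: every claim the test suite makes
is a closed-loop statement — program a kinematic property, push it through
decimation and analysis, and check what comes back. This vignette documents
the generative model, the landmark and estimator conventions, the
statistical procedure, and the places where a genuine design choice had to
be made.

## The kinematic GAW model

A synthetic recording is a sequence of glottal cycles. Cycle $i$ has period
$T_i$ and peak area $A_i$; within a cycle the area is

* a **closed floor** at $g = \text{gap\_fraction} \cdot \text{peak\_area\_px}$,
  modelling the posterior glottal chink that keeps a healthy female glottis
  from closing completely (so the waveform never returns to zero);
* an **opening limb** rising from the floor to $A_i$ as a quarter-sine,
  over a fraction $\text{SQ}/(1+\text{SQ})$ of the open phase;
* a **closing limb** falling back as a quarter-cosine over the remaining
  $1/(1+\text{SQ})$.

The open phase occupies `open_quotient` of the period. The limbs join the
peak with zero slope (a smooth maximum, as a real GAW has) but leave the
floor with finite slope. That second property is deliberate: a limb that
is tangent to the floor (for example a raised cosine) spends ~6% of its
duration below a 1%-of-range closure threshold, which would bias every
threshold-based phase landmark by far more than the quantization the
package is trying to measure. With quarter-sine limbs the crossing bias is
~0.6% of a limb and landmark recovery is limited by frame quantization, as
it should be.

**Perturbation.** Cycle-to-cycle variability uses i.i.d. Gaussian draws on
log-period and on dB-amplitude, rescaled so that the *realized* mean
absolute difference between consecutive cycles matches the request exactly
(in dB) or to first order (periods): `jitter_ms` is the mean
$|T_{i+1}-T_i|$ in milliseconds and `shimmer_db` the mean
$|20\log_{10}(A_{i+1}/A_i)|$. The generator's own per-cycle bookkeeping
(realized periods, amplitudes, peak times, jitter, shimmer) is stored as a
ground-truth attribute and is what recovery tests compare against.

**Left/right halves and phase asymmetry.** Each half waveform is half the
pulse, time-shifted by $\pm\,\text{phase\_asym}\cdot T_i/2$, so the phase
asymmetry PA of the pair is exactly `phase_asym`. The total is defined as
the *sum of the shifted halves*; additive Gaussian noise (`noise_sd`, in
pixels of total area) is split equally between the halves. Both choices
make `left + right == total` an exact identity rather than an
approximation. One consequence is recorded in the ground truth: the total
waveform's open phase is the *union* of two shifted open windows, exactly
$|\text{PA}|\cdot T$ longer than each half's, so the effective open and
speed quotients of the total (`oq_total`, `sq_total`) differ slightly from
the per-half programmed values; measurements on the total are compared to
the effective truths.

**Defaults.** The defaults describe sustained phonation of a vocally
healthy adult female as the study conditions require: F0 = 176 Hz
(cohort draws use 176 ± 11 Hz), 15 000 fps master rate, 106 cycles,
open quotient 0.9, speed quotient 1.25, gap fraction 0.06 (cohort
0.05–0.07), phase asymmetry −0.02, jitter 0.3 ms, shimmer 0.2 dB, peak area
6000 px, noise 10 px. With these values the analysed parameters land where
healthy-female HSV studies put them (OQ near unity under a zero closure
threshold, mJT ≈ 0.3 ms, mSH ≈ 0.2 dB, SH ≈ 0.3%, GGI ≈ 0.06, HNR ≈ 15 dB).

**What the generator does not emulate:** mucosal-wave propagation,
vertical-phase effects, camera optics and illumination, segmentation errors
on real tissue, voice breaks or onset/offset transients. Passing tests
therefore demonstrate correctness of the *measurement pipeline* under
controlled kinematics, not robustness to clinical image material.

## Imaging round trip

`render_frames()` draws each frame as a dark vertical ellipse of fixed
length-to-width aspect on a bright background. Pixels are filled in order
of increasing elliptical radius, so the dark-pixel count equals the rounded
target area *exactly* — the rendering contract is testable to the pixel.
`segment_frame()` recovers the area as the largest dark 4-connected
component (run-merge union-find labelling) at or below an intensity
threshold, inside an optional ROI; `extract_gaw()` splits left from right
along the principal axis of the time-union mask. The union-mask axis (not
per-frame axes) keeps the split defined when the glottis closes; pixels
exactly on the axis alternate by row parity so a symmetric glottis splits
evenly.

## Frame-rate emulation

A slower camera captures a subset of instants; it does not low-pass the
scene. `decimate_gaw()` therefore assigns output frame $j$ (0-based) the
master frame $\lfloor j \cdot f_\text{master}/f_\text{target}\rfloor$ —
sample-and-hold, no interpolation, areas stay integer-valued. Non-divisor
targets (e.g. 15 → 14 kfps) are allowed through the same floor map.

One artifact of the floor map is worth knowing: for non-divisor targets the
stride between selected master frames alternates (e.g. 1 and 2 master
frames near the master rate), so the steepest *single-step* area drop —
MADR — rescaled to pixels per second is inflated by up to the stride ratio.
On divisor rates (uniform subsampling) MADR × fps is rate-invariant to
within slope curvature, and the package's property tests check it there. A
real constant-interval camera would not show the non-divisor artifact; an
emulation from a fixed master recording cannot avoid it.

## Cycle landmarks

Cycle boundaries are successive *opening instants*. Detection is two-pass:
upward crossings of the mid level (baseline + half the global range) are
noise-robust candidates; each is refined to the frame after the last frame
at or below the closure level
$c = \text{baseline} + \text{closure\_threshold\_rel}\cdot(\text{cycle-local max} - \text{baseline})$
within the preceding half period. A small numeric tolerance
($10^{-9}$ of the dynamic range) guards the comparison against floating-point
noise in the floor. If no sub-level frame exists — typical for noisy data
under the zero threshold — the mid-level crossing stands. Boundaries at
opening instants, rather than minimum-to-minimum, stay well defined when a
glottal gap leaves no unique minimum.

Within a cycle (half-open $[t_\text{start}, t_\text{end})$, frame $k$ at
time $k/f_s$, 0-based):

* **closed** frames have area strictly below $c$ — so with the default
  `closure_threshold_rel = 0` nothing is ever closed and OQ = 1, the
  behaviour of real gapped waveforms under a baseline-only closure
  criterion. The conventions 0.01 and 0.05 reproduce the 1%- and
  5%-of-maximum criteria used in the clinical literature; recovery tests
  use 0.01, since the zero threshold by construction reports OQ = 1
  regardless of the programmed geometry.
* **opening** runs from the cycle start to the earliest peak frame and
  *includes the partial frame during which the waveform crossed* $c$. This
  half-sample convention is deliberate: counting only whole supra-threshold
  frames undercounts opening by ~0.8 frames on average while closing
  overcounts by ~0.3, biasing SQ low by more than a frame-rate study can
  tolerate. Sub-frame interpolation of landmarks is intentionally out of
  scope, and the open duration is capped at the period.
* **closing** runs from the peak frame to the first closed frame after it,
  or to the cycle end if the cycle never closes. Peak ties break to the
  earliest frame.

Partial first and last cycles are discarded; the analysis window keeps the
first 106 complete cycles (the conventional minimum of ~100 cycles for
perturbation measures, with headroom). At 15 kfps and F0 ≈ 176 Hz that is
~85 samples per cycle; at 1 kfps only ~5.7, where ratio landmarks such as
SQ carry a structural quantization bias of ~0.3 — the package documents
this rather than hiding it, because it is precisely the effect a frame-rate
sensitivity analysis is about.

## Parameter estimators

All quotient and perturbation parameters are computed per cycle and then
averaged, which makes exclusion of degenerate cycles well defined: cycles
with zero closing duration leave RQ/SQ/ASQ/SI (with a warning), pairs with
zero dynamic range leave AP/mSH, and a fully excluded parameter becomes an
explicit `NA` with a reason code in the `undefined` column — never a silent
zero. `compute_gaw_parameters()` never aborts a sweep; failures propagate
as sentinels.

Amplitude measures treat the area waveform as the amplitude and use
$20\log_{10}$ scaling. SH normalizes mean shimmer by the mean dB dynamic
range *re 1 pixel*; this follows the definition of shimmer as a ratio of
dB quantities literally, and makes SH depend on pixel calibration — users
comparing across image resolutions should prefer mSH.

Spectral measures use the mean-removed, Hann-windowed analysis window,
zero-padded to at least 4× its length. Harmonic bands are
$k F_0 \pm 0.12 F_0$ (the width accommodates the harmonic broadening that
~5% jitter produces over a 106-cycle window; configurable). HI and HNR use
the exact partition $E_\text{harm} + E_\text{noise} = E_\text{total}$ over
positive-frequency bins (DC excluded); HNR is capped at ±120 dB when one
side vanishes. NNE estimates the noise *inside* each harmonic band from the
flanking non-harmonic bins of the same inter-harmonic stretch and adds it
to the out-of-band energy, so a pure-noise signal scores ≈ 0 dB and a
noiseless periodic signal is strongly negative. SPF is
$10\log_{10}(\text{GM}/\text{AM})$ of the power coefficients, zero
coefficients excluded; it is ≤ 0 by the AM–GM inequality.

## The stability procedure

For each parameter the sweep table (recordings × rates) is screened for
normality (Shapiro–Wilk and Lilliefors; constant samples count as
non-normal by convention) and tested with the Friedman test, recordings as
blocks. Only a significant Friedman test (α = 0.05) releases the parameter
to pairwise Wilcoxon signed-rank tests over all rate pairs — 105 pairs for
15 rates — at the Bonferroni-corrected level α/(n_rates − 1) = 0.05/14 ≈
0.0036, reflecting that each rate takes part in 14 comparisons. Zero
differences are discarded before testing (a pair with all-zero differences
is non-significant by convention); exact p-values are used for n ≤ 25
without ties, the normal approximation above.

Two practical notes. First, the exact two-sided signed-rank test with $n$
blocks cannot produce a p-value below $2/2^n$; at the corrected level
0.0036 the procedure needs at least 10 recordings to be able to reject at
all, and the default cohort of 20 gives a floor of ~2 × 10⁻⁶. Second,
because the Friedman gate fails ~5% of the time under the null, i.i.d.
data are classified rate-independent (Group 1) in ≥ 90% of seeded
replicates — a calibration the test suite checks.

Rates are then merged greedily left to right into maximal runs containing
no internally significant pair. A run is marked *gray* when neither
boundary step to its neighbours is significant while the neighbours differ
from each other — a bridge between two plateaus; gray status is reported
but does not affect classification. Group labels: **1** — one run spans
all rates; **2** — the final run reaches the top rate and spans ≥ 4 rates;
**3** — some earlier run spans ≥ 4 rates; **4** — no run longer than 3
rates. The ≥ 4 cutoff makes a parameter that is only stable over the top
two or three rates count as highly rate-dependent, which matches how such
parameters behave everywhere else in the grid.

Greedy merging is one of several defensible conventions; it produces
contiguous, non-overlapping intervals and is monotone in the sense that
adding a significant pair never grows the leading interval nor reduces the
interval count (it *can* re-cut an earlier run so that a later run extends
further — an inherent property of greedy partitions).

## Problem sizes and runtime choices

The package's own experiments use the full study geometry — 20 recordings
× 15 rates × 106 cycles at 15 kfps (≈ 9 000 frames per master recording,
300 analysed samples) — for the acceptance script and the end-to-end test,
which complete in a few minutes on one core. Unit tests use shorter
recordings (6–40 cycles) and the imaging round trip uses a 64 × 32 px
canvas at 3 kfps, sizes chosen so each test isolates one property while
the suite stays fast. Null-calibration checks use 100 seeded replicates of
the 20 × 15 design; the Friedman uniformity check uses 200.

## Known limitations

* The kinematic model has a single pulse shape; it cannot represent double
  peaks, alternate-cycle subharmonics or voice breaks.
* SH's 1-pixel dB reference ties it to image calibration (see above).
* MADR's per-second rescaling is only meaningful at divisor rates of the
  master (emulation artifact, see above).
* The zero-threshold OQ is exactly 1 by construction on gapped waveforms;
  its Group-1 stability is a property of the convention as much as of the
  signal — which is, in itself, the methodological point.
* Group labels for borderline parameters can move between adjacent groups
  across cohort seeds; the construction-invariant (OQ, PA) and
  quantization-bound (AMQ, MADR) parameters are seed-stable.
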