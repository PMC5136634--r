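# gawsense

Frame-rate sensitivity analysis for glottal area waveform (GAW) parameters
from laryngeal high-speed videoendoscopy (HSV).

## The problem

HSV films the vibrating vocal folds at kilohertz frame rates; segmenting the
glottis (the dark opening between the folds) in every frame yields the
glottal area waveform — glottal area in pixels versus time. Clinical
voice assessment summarises the GAW with objective parameters: phase-duration
quotients of the oscillation cycle (open quotient OQ = Open/T, closing
quotient CQ = Closing/T, speed quotient SQ = Opening/Closing, asymmetry
quotient ASQ = SQ/(SQ+1), speed index SI = (SQ−1)/(SQ+1), rate quotient
RQ = (Closed+Opening)/Closing), amplitude dynamics (maximum area declination
rate MADR, amplitude quotient AMQ = dynamic range/MADR, glottal gap index
GGI = min(GA)/max(GA), phase asymmetry PA = (t_M(left) − t_M(right))/T),
cycle-to-cycle perturbation (jitter mJT/JT, shimmer mSH/SH, amplitude
periodicity AP, amplitude variability index AVI) and spectral noise measures
(HI, HNR, NNE, SPF).

Every one of these is computed from frame-quantized landmarks, so the
camera's recording rate is a hidden experimental variable: a parameter value
measured at 4 kfps need not equal the value at 15 kfps. `gawsense` provides
a complete, reproducible pipeline for quantifying that dependence:

1. **Synthetic ground truth** (`kinematic_params()`, `generate_gaw()`,
   `synthetic_cohort()`): GAWs with programmed F0, open/speed quotient,
   glottal gap, left–right phase asymmetry, jitter, shimmer and noise —
   emulating sustained phonation of a healthy adult female (F0 ≈ 176 ± 11 Hz,
   106 cycles at a 15 kfps master rate).
2. **Imaging plumbing** (`render_frames()`, `segment_frame()`,
   `extract_gaw()`): endoscopy-like frame stacks and threshold/largest-
   component glottis segmentation with a principal-axis left/right split,
   so the pipeline is exercisable end to end from images.
3. **Camera emulation** (`rate_sweep_plan()`, `decimate_gaw()`,
   `build_sweep()`): stepwise frame-rate reduction from 15 down to 1 kfps by
   nearest-preceding-frame decimation.
4. **Cycle analysis and parameters** (`detect_cycles()`, `estimate_f0()`,
   `compute_gaw_parameters()`, `sweep_parameters()`): phase landmarks per
   cycle and the twenty parameters above, per recording and rate.
5. **Stability statistics** (`build_stability_report()` with
   `normality_check()`, `friedman_across_rates()`, `pairwise_wilcoxon()`,
   `merge_stable_intervals()`, `classify_group()`): a Friedman test across
   rates (recordings as blocks) gates pairwise Wilcoxon signed-rank tests at
   the Bonferroni-corrected level α = 0.05/14 ≈ 0.0036; rates that never
   differ significantly are merged into stable intervals and each parameter
   is classified into a four-group taxonomy — Group 1: rate-independent;
   Group 2: stable from some rate up to the top rate; Group 3: stable only
   in an interior range; Group 4: no stable stretch longer than 3 rates.

Results are tibbles throughout; fitted reports support `tidy()`, `glance()`
and `autoplot()`.

## Worked example

A single synthetic recording, analysed at its master rate:

```r
library(gawsense)
kp  <- kinematic_params(f0_hz = 176, n_cycles = 106, seed = 1)
gaw <- generate_gaw(kp)
cycles <- detect_cycles(gaw, closure_threshold_rel = 0.01)
round(estimate_f0(cycles), 1)
#> [1] 174.9
params <- compute_gaw_parameters(gaw, cycles)
round(params[, c("OQ","SQ","GGI","PA","mJT","JT","mSH","SH","HNR","NNE")], 3)
#>      OQ    SQ   GGI     PA   mJT    JT   mSH    SH    HNR     NNE
#> 1 0.928 1.235 0.058 -0.019 0.307 5.365 0.213 0.283 14.105 -13.111
```

The open quotient is near unity (a small posterior gap keeps the glottis
from closing), SQ ≈ 1.24 means opening takes a quarter longer than closing,
jitter ≈ 0.3 ms and shimmer ≈ 0.2 dB are at healthy sustained-phonation
levels, and HNR ≈ 14 dB quantifies how much of the waveform's spectral
energy is harmonic.

A full sensitivity experiment — 20 recordings × 15 rates (60 cycles each
here; runs in about a minute):

```r
recs   <- lapply(synthetic_cohort(20, seed = 7, n_cycles = 60), generate_gaw)
tbl    <- sweep_parameters(build_sweep(recs, rate_sweep_plan()))
report <- build_stability_report(tbl)
glance(report)
#>   n_parameters n_group1 n_group2 n_group3 n_group4 n_rates alpha_corrected
#> 1           20        2        5        8        5      15     0.003571429
tidy(report)[tidy(report)$parameter %in% c("OQ","PA","mJT","AMQ"),
             c("parameter","group","stable_from")]
#>   parameter group stable_from
#> 1       AMQ     4       15000
#> 2        OQ     1        1000
#> 3        PA     1        1000
#> 4       mJT     2       11000
```

OQ and PA are rate-independent (Group 1). Mean jitter is quantization-
limited: its merged intervals show 0.60 ms at 1 kfps falling to 0.29 ms in
the stable high-rate interval (Group 2), and AMQ — dynamic range divided by
a per-frame closing velocity — changes at nearly every rate (Group 4).
`autoplot(report)` draws the merged-interval table; `plot_parameter_sweep(tbl)`
shows per-rate means and spreads.

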