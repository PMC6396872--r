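# menisq

Quantitative T2* relaxometry for short-T2* fibrocartilage — the human
meniscus in particular — from multi-echo gradient-echo magnitude images.

Healthy meniscus is dominated by short T2*/T2 components, so it appears
dark on conventional clinical sequences; (ultra)short-TE multi-echo
acquisitions make its signal decay measurable. Two questions then arise
per voxel and per region: *how fast* does the signal decay (the T2* map),
and *how many water pools* does the decay reveal — one (monoexponential)
or two (biexponential, conventionally read as collagen-bound vs free
water)? Because the highly ordered circumferential collagen fibers retain
residual dipolar coupling, the answer also depends strongly on the
fiber-to-field angle (the magic-angle effect). `menisq` implements this
full analysis as a tested, reproducible pipeline, together with a
synthetic phantom generator so that every stage can be validated without
scanner data.

## Models and statistics

Signal at echo time TE (ms) is modeled as either

- monoexponential (3 parameters): `S(TE) = A1 * exp(-TE/T2*) + eps`
- biexponential (5 parameters):
  `S(TE) = B1 * exp(-TE/T2*s) + B2 * exp(-TE/T2*l) + eps`

fitted by bounded Levenberg–Marquardt least squares (`minpack.lm`), with
T2*s ∈ [0, 20] ms, T2*l ∈ [0, 200] ms, nonnegative amplitudes, free
offset, and starting values T2* = 10 ms (mono) and 2 ms / 15 ms (bi). The
short-fraction map is `Fs = 100 * B1 / (B1 + B2)`.

The nested models are compared per voxel (and per ROI-averaged decay) by

- the small-sample corrected Akaike criterion
  `AICc = 2k + n*log(SSE/n) + 2k(k+1)/(n-k-1)` (lower wins), and
- the nested F-test
  `F = ((SSE_mono - SSE_bi)/SSE_bi) * (v_bi/(v_mono - v_bi))`,
  `v = n - k`, with p from the F(2, n−5) distribution at alpha = 0.05,

yielding binary decay-type maps (0 = mono, 1 = bi) per criterion.

The phantom's orientation model adds dipolar relaxation to each rate:
`R2*(theta) = R2*,iso + C * (3*cos^2(theta) - 1)^2`, which vanishes at the
magic angle (~54.7°) and reproduces the ordering
T2*(55°) > T2*(90°) > T2*(0°).

## Worked example

Simulate the demo meniscus phantom (triangular body, 0.2 mm laminar rim,
strongly anisotropic tendon-like band with a two-pool decay) at fiber
angle 0° and first-echo SNR 35, then run the voxel-wise and ROI-averaged
analyses:

```r
library(menisq)

spec <- meniscus_demo_spec(seed = 42, fiber_angle_deg = 0)
syn  <- synthesize_echo_series(spec, te_schedule_12())
syn$series
#> echo series: 40 x 32 x 6 voxels, 12 echoes (TE 0.82-23.6 ms)

mask      <- mask_foreground(syn$series, threshold_factor = 5)
maps_mono <- fit_volume(syn$series, mask = mask, model = "mono")
maps_bi   <- fit_volume(syn$series, mask = mask, model = "bi")
sel       <- select_voxels(maps_mono, maps_bi, alpha = 0.05)

tendon <- syn$truth$label_map == 3
mean(maps_mono$t2star_ms[tendon], na.rm = TRUE)   # 2.49 ms at 0 degrees
biexp_percentage(sel, "ftest", tendon)            # 4.0 % of voxels

roi <- roi_fit_and_select(syn$series, roi = tendon)
roi$summary[, c("t2s_mean", "t2l_mean", "fs_mean", "pct_bi_ftest")]
#>   t2s_mean t2l_mean fs_mean pct_bi_ftest
#> 1     1.47     3.59   40.07          100
```

Voxel-wise, only 4% of the tendon-like voxels are flagged biexponential —
at SNR 35 the F-test simply cannot resolve two closely spaced components.
Averaging the ~88 ROI voxels per slice raises the SNR roughly
sqrt(88) ≈ 9-fold, and every slice is then flagged biexponential by both
criteria, with the short/long T2* pair resolved at about 1.5 / 3.6 ms.
That voxel-level-mono / ROI-level-bi contrast is the pipeline's central
SNR mechanism.

`run_pipeline(config)` chains all stages (optional simulation, masking,
both fits, selection, ROI tables) from a YAML/list config and writes
NIfTI maps, CSV summaries, and a JSON provenance record; the CLI wrapper
exposes the same stages as `simulate | fit | select | roi | run`
subcommands.

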