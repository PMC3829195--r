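# vsdcontext

Analysis of long-range contextual interactions in mesoscopic
voltage-sensitive dye imaging (VSDI) of visual cortex.

When two natural-movie patches are presented through distant apertures
(separated by 2.5 FWHM, beyond classical receptive field sizes), each
drives its own spot of cortical activity. This package quantifies how
the distant patch — the *context* — modulates the local response, and
whether the modulation is specific to coherent context (both patches
from the same movie, preserving natural spatio-temporal correlations)
as opposed to incoherent context (patches from different movies). It is
aimed at researchers analyzing widefield optical-imaging experiments
with this two-patch design, and at anyone who wants a fully synthetic,
ground-truth-controlled replica of the analysis.

## What it computes

1. **Preprocessing** — raw trial stacks to evoked ΔF/F in two steps:
   divisive normalization of each pixel by its prestimulus mean (per
   trial), then subtraction of the trial-averaged blank signal and
   division by it. Heartbeat-locked artifacts shared with blank trials
   cancel exactly; results are averaged across trials.
2. **Spatial-profile modelling** — each condition's time-averaged map
   (initial 750 ms) is fitted with a superposition of two rotated 2-D
   Gaussians,

   G(x, y) = A·exp(−[(x−μx)²/2σx² + (y−μy)²/2σy² + ρ(x−μx)(y−μy)]),

   all 12 parameters estimated simultaneously by bounded nonlinear
   least squares, centers constrained near the two known spot
   locations. The second Gaussian in single conditions estimates the
   *indirect* activation at the unstimulated site.
3. **Contextual metrics** — per (location × movie) comparison cell,
   from fitted peaks A: total facilitation 100(A_coh − A_dir)/A_dir;
   superadditive component 100(A_coh − A_dir − A_ind)/A_dir; linear
   component (their difference, = 100·A_ind/A_dir); specificity
   100(A_coh − A_incoh)/A_incoh; plus joint (√(σx·σy)) and per-axis
   spread changes. Aggregated with percentile-bootstrap CIs (1000
   reps, α = 0.05), Wilcoxon sign-rank, sign and paired-t tests.
4. **Time-course analysis** — top-5th-percentile ROIs from the single
   conditions, ROI-mean traces at 200 Hz, per-bin sign-rank tests,
   difference traces, and cross-location correlations r_single,
   r_coherent, r_incoherent.
5. **Synthetic generator** — trial stacks with two Gaussian spots,
   temporally correlated drives, multiplicative paired-condition
   facilitation, heartbeat artifact, illumination gain field and trial
   noise, with exported ground truth for recovery tests.
6. **EVO I/O** — reader/writer for the deposited MAT-format evoked
   datasets (`[space, time, condition]`, ten documented conditions).

## Worked example

Simulate one experiment at the calibrated study conditions (coherent
gain 1.45, incoherent gain 1.2, indirect leak 3%, 30 trials) on a
scaled-down grid, run the full pipeline, and read off the metrics:

```r
library(vsdcontext)

cfg <- synth_config(ys = 32, xs = 64, stim_ms = 1000, n_trials = 30, seed = 7)
res <- contextual_analysis(list(cfg), n_boot = 1000, seed = 42)
print(res$facilitation, digits = 3)
#>                metric estimate ci_lo ci_hi n p_signrank p_signtest  p_ttest
#> 1       total_fac_pct    46.46 44.18 49.34 4      0.125      0.125 6.84e-05
#> 2        superadd_pct    40.69 37.70 44.51 4      0.125      0.125 2.39e-04
#> 3          linear_pct     5.77  4.17  7.75 4      0.125      0.125 1.38e-02
#> 4     specificity_pct    20.65 19.11 22.06 4      0.125      0.125 1.77e-04
#> 5 incoh_vs_direct_pct    21.43 18.61 24.58 4      0.125      0.125 1.44e-03
```

The recovered total facilitation (~46%, CI [44, 49]) matches the
injected 45% (gain 1.45); about 41 points of it are superadditive and
~21% is the specific advantage of coherent over incoherent context
(injected: 100·(1.45−1.2)/1.2 = 20.8). With a single experiment there
are only 4 comparison cells, so the sign-based tests bottom out at
p = 0.125; CIs and t-tests already resolve the effects.

The fitted spatial model for the coherent condition:

```r
print(res$fits[[1]][["A1B1"]])
#> <two_spot_fit> r_fit = 0.927 (converged)
#>   spot A: A=0.000335 mu=(32.6,7.6) sigma=(2.99,3.61) rho=-0.00334
#>   spot B: A=0.000334 mu=(32.5,25.4) sigma=(3.00,3.61) rho=0.00369
```

Both peaks recover the injected 1.45 × 2.3e-4 = 3.34e-4 ΔF/F, and the
spread along the context axis (σy ≈ 3.6) shows the injected widening of
the generative σ = 3. Time-course correlations between the two
locations, per movie:

```r
ev <- res$evoked[[1]]
rois <- lapply(1:2, function(m)
  define_roi(time_average(ev, paste0("A", m)), time_average(ev, paste0("B", m))))
timecourse_correlations(ev, rois)
#>   movie r_single r_coherent r_incoherent
#> 1     1     0.67       0.85        0.094
#> 2     2     0.32       0.73       -0.281
```

Coherent presentation entrains the two locations (r_coherent well
above r_single); incoherent pairs, driven by independent movies, hover
near zero.

## Documentation

The methods vignette (`vignettes/vsdcontext-methods.Rmd`) describes
the preprocessing model, the constrained fitting procedure and its
numerical choices, the metric definitions, what the synthetic
generator does and does not emulate, and known limitations.
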