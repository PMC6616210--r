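# usmikb

Quantitative analysis of **ultrasound molecular imaging (USMI)** with
VEGFR2-targeted microbubbles: per-voxel pharmacokinetic estimation of the
microbubble **binding rate constant k<sub>b</sub>**, the semi-quantitative
late-enhancement (LE) and differential-targeted-enhancement (dTE) readouts,
and the complete longitudinal case-control statistics used to judge early
response to anti-angiogenic therapy in preclinical tumor studies. A
synthetic 4-D cohort generator makes the whole chain testable without any
animal data.

Intended users: imaging scientists and pharmacokinetic modelers working
with destruction-replenishment contrast ultrasound who want a reproducible,
scriptable alternative to scanner-vendor quantification tools.

## The model

The total targeted-contrast concentration in a voxel is free transport plus
accumulated binding (the first-pass binding, FPB, model):

- free phase, modified local density random walk (mLDRW):

      C_f(t) = α √(κ / 2π(t−t₀)) · exp( −κ (t−t₀−μ)² / 2(t−t₀) ),  t > t₀

- bound phase, well-mixed compartment fed at rate k_b (negligible
  unbinding during the first pass):

      C_t(t) = C_f(t) + k_b ∫₀ᵗ C_f(τ) dτ   →   k_b · α  as t → ∞

Parameters: α (wash-in area), μ (mean transit time, s), t₀ (theoretical
injection time, s), κ = v²/D (local dispersion, 1/s), k_b (binding rate,
fitted in 1/s, reported in 1/min). The running integral is evaluated by an
exact closed form in normal CDFs — no quadrature through the t₀
singularity — and the fit uses an analytic Jacobian. Per-voxel estimates
are aggregated per tumor as plane medians, then the mean of plane medians.

## Worked example

Fit one synthetic wash-in (ground truth: α = 2·10⁵, μ = 25 s, t₀ = 10 s,
κ = 0.5 1/s, k_b = 0.01 1/s = 0.6 1/min), from 8-bit gray levels:

```r
library(usmikb)
y <- fpb_concentration(0:299, fpb_params(2e5, 25, 10, 0.5, 0.01))$value
x <- tic(0:299, compress_gray(y, quantize = TRUE), t_flash = 240)
fit <- fit_fpb(x)   # first 60 s only
tidy(fit)
#>   term    estimate unit
#> 1 alpha 200606.    intensity*s
#> 2 mu        24.8   s
#> 3 t0        10.2   s
#> 4 kappa      0.486 1/s
#> 5 k_b        0.587 1/min
```

All five parameters come back within a few percent of truth from a single
quantized voxel curve (the ~2 % wobble is the 8-bit quantization floor;
unquantized curves recover to < 0.5 %).

A full virtual study — 17 mice, days 0/1/3/7/10, treated responders with a
programmed k_b decline — runs end to end in under a minute at desk scale:

```r
study <- run_pipeline(synthetic_design(), seed = 1, grid = c(8, 8, 2))
dplyr::filter(study$report$day_tests,
              parameter == "k_b", group == "responder_treated")
#>   group             parameter omnibus_p  day   p_raw   p_adj
#> 1 responder_treated k_b          0.0045    1 0.00794 0.00794
#> 2 responder_treated k_b          0.0045    3 0.00794 0.00794
#> 3 responder_treated k_b          0.0045    7 0.00794 0.00794
#> 4 responder_treated k_b          0.0045   10 0.00794 0.00794
```

The day-1 contrast is significant after Benjamini-Hochberg adjustment
(0.0079 is the exact-enumeration floor for 5-vs-5 samples), while no
control or non-responder group reaches significance — the early-prediction
signature of the binding-rate biomarker. The fold-change classification
table (`study$report$classification`) calls every treated mouse correctly
from k_b at the 0.7 cutoff in this run; the synthetic LE/dTE readouts, being
log-compressed gray levels, have fold changes compressed toward 1 and are
deliberately poor under the default modest effect sizes (see the methods
vignette, `vignettes/fpb-methods.Rmd`).

Published confusion counts can be replayed into the five performance
metrics at any time:

```r
replay_classification(tibble::tibble(
  parameter = "k_b", TP = 16, FP = 2, FN = 4, TN = 18))
#>   parameter TP FP FN TN sensitivity specificity accuracy  ppv  npv
#> 1 k_b       16  2  4 18        80.0        90.0     85.0 88.9 81.8
```

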