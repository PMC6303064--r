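# t1relax

Quantitative T1 relaxation mapping from a single ordinary 3D T1-weighted
spoiled gradient-echo acquisition (3DT1TFE/SPGR), for neuroimaging analysts
who want absolute, longitudinally comparable tissue values — in particular
for tracking chronic T1-hypointense MS lesions ("black holes") and gray
matter — without acquiring a dedicated relaxometry sequence.

## The method

T1-weighted intensities have no absolute scale, so the package converts
them into T1 relaxation times (ms). The steady-state SPGR magnitude signal
is

    S = k (1 − E) sin θ / (1 − E cos θ),   E = exp(−TR / T1)

with TR the repetition time, θ the flip angle, and k a lumped scanner
constant (receiver gain, proton density, coil sensitivity). k is calibrated
per scan by constraining the equation to reference tissues with literature
T1 values — normal-appearing white matter (810 ms at 3T) and
normal-appearing gray matter (1350 ms, conventionally Heschl gyrus) — via
least squares in signal space, `k = Σ Sᵢfᵢ / Σ fᵢ²` where `fᵢ` is the
unit-k forward signal. Every voxel is then inverted in closed form:

    u = S / (k sin θ),   E = (1 − u) / (1 − u cos θ),   T1 = −TR / log E

Voxels outside the invertible range (background zeros, saturated signal)
are flagged invalid, never clamped. Defaults mirror a 3T protocol with
TR = 8 ms, TE = 3.6 ms, flip = 15°.

The package also ships a digital brain phantom (nested-ellipsoid WM/GM/CSF
geometry plus spherical WM lesions, known per-class T1, Gaussian/Rician
noise) for validation, a two-timepoint cohort simulator, and the paired-t /
Spearman / OLS analysis plan of longitudinal atrophy studies.

## Worked example

```r
library(t1relax)

# a 64^3 phantom with 5 WM lesions, Rician noise at SNR 40 on the WM signal
ph <- generate_phantom(phantom_spec(shape = c(64, 64, 64), lesion_count = 5, seed = 7))
wm_sig <- forward_signal(810, ph$spec$params, ph$spec$k_true)
noisy <- add_noise(ph$signal, snr = 40, reference = wm_sig, model = "rician", seed = 8)

fit <- derive_t1_map(noisy,
                     wm_mask = ph$labels == 3, gm_mask = ph$labels == 2,
                     brain_mask = ph$labels > 0)
fit
#> T1 relaxation map: 64 x 64 x 64 voxels
#>   scanner constant k = 100.049 (refs: NAWM, NAGM)
#>   valid voxels: 93312 (35.6% of grid)

roi_t1_stats(fit, ph$labels, labels = c("1"="csf","2"="gm","3"="wm","4"="lesion"))
#>    label n_voxels mean_t1_ms  sd_t1_ms pct_invalid
#> 1    csf      848  4009.7571 442.19131           0
#> 2     gm    60744  1351.7282  60.18575           0
#> 3     wm    31011   810.8052  26.03552           0
#> 4 lesion      709  1042.0174  38.60619           0
```

The calibrated k recovers the generating constant (100) to 0.05%, and the
class mean T1s land within a few ms of the ground truth (CSF 4000, GM 1350,
WM 810, lesion 1040 ms) despite the noise; `pct_invalid = 0` confirms no
voxel fell outside the invertible range inside the brain.

Longitudinal statistics on a simulated cohort (negative PBVC = volume
loss):

```r
co <- simulate_cohort(20, seed = 7)
paired_t_test(co$gm_baseline, co$gm_followup)
#> Paired t-test (n = 20): mean diff = -2.077e+04 (decrease), t = -12.467, p = 1.357e-10

regress_pbvc(co, c("age", "disease_duration", "t2_lesion_volume"),
             multivariate = TRUE)[[1]]
#> OLS: pbvc ~ age + disease_duration + t2_lesion_volume  (n = 20, R^2 = 0.307)
#>              name coefficient    ci_low  ci_high p_value
#>               age    -0.06830 -0.125300 -0.01130 0.02184
#>  disease_duration    -0.01264 -0.132800  0.10750 0.82640
#>  t2_lesion_volume     0.02228 -0.008487  0.05305 0.14430
```

The simulated gray-matter decline is detected by the paired test, and the
configured age effect on brain volume loss (−0.062 %/yr) is recovered with
a significant coefficient while the null covariates are not.

A thin command-line wrapper lives at `inst/cli/t1relax` with subcommands
`derive`, `phantom`, `cohort-sim`, `stats` and `roistats`; `run_pipeline()`
executes the derive → ROI-statistics workflow from a YAML/JSON config and
writes a reproducibility manifest. See `vignettes/t1-mapping.Rmd` for the
full methods account.

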