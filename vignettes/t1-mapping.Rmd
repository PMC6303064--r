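---
title: "Quantitative T1 mapping from a single T1-weighted acquisition: model, calibration and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative T1 mapping from a single T1-weighted acquisition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t1relax)
```

## The problem

Chronic T1-hypointense lesions ("black holes") in multiple sclerosis mark
severe tissue damage, but ordinary T1-weighted images carry no absolute
intensity scale: the shade of gray of a lesion depends on receiver gain,
coil loading and sequence settings, so longitudinal comparisons of
hypointensity are unreliable. A quantitative alternative is to convert the
T1-weighted image into a map of the T1 relaxation time itself (in ms), a
physical tissue property that increases with edema, demyelination and
axonal loss. `t1relax` implements such a conversion for 3D T1-weighted
spoiled gradient-echo acquisitions (3DT1TFE/SPGR), requiring only the scan
that was already acquired plus two reference-tissue ROIs.

## Signal model

For an ideally spoiled gradient-recalled echo with repetition time $TR$,
flip angle $\theta$ and echo time $TE \ll T_2$, the steady-state magnitude
signal is

$$ S \;=\; k\,\frac{(1 - E)\,\sin\theta}{1 - E\cos\theta},
   \qquad E = e^{-TR/T_1}, $$

where $k$ is a lumped scanner constant (receiver gain, proton density,
coil sensitivity). For fixed $TR$, $\theta$ and $k$, $S$ is strictly
decreasing in $T_1$ over $0<\theta\le 90^\circ$, so the relation is
invertible in closed form: with $u = S/(k\sin\theta)$,

$$ E = \frac{1-u}{1-u\cos\theta}, \qquad T_1 = -\,\frac{TR}{\log E}. $$

`forward_signal()` and `invert_signal()` implement the two directions.
Because $TE \ll T_2$ no $T_2^*$ term is modelled, and $TE$ is carried in
`seq_params()` purely as provenance. The default acquisition constants are
$TR = 8$ ms, $TE = 3.6$ ms, $\theta = 15^\circ$, a typical 3T 3DT1TFE
protocol at 1 mm isotropic resolution.

## Calibration of the scanner constant

$k$ cannot be known a priori; it is estimated by constraining the signal
equation to reference tissues with well-established literature T1 values:
normal-appearing white matter (NAWM, 810 ms at 3T) and normal-appearing
gray matter (NAGM, 1350 ms), the latter conventionally sampled in the
Heschl gyrus because it is not known to be affected in MS. Given the mean
ROI intensity $S_i$ of each reference and the unit-$k$ forward signal
$f_i$, `calibrate_k()` minimises $\sum_i (S_i - k f_i)^2$, giving the
closed form

$$ \hat k = \frac{\sum_i S_i f_i}{\sum_i f_i^2}. $$

Two references over-determine the single unknown; we chose a joint
least-squares fit in signal space (rather than per-tissue fits averaged
afterwards) because it is deterministic, symmetric in the references, and
leaves per-reference residuals as a diagnostic: a large residual signals a
violation of the single-$k$ assumption, most plausibly proton-density or
coil-sensitivity differences between WM and GM. That bias is not
corrected — it is measurable with the phantom's `proton_density` dial (see
below). With a single reference the fit is exact and the residual is zero.

Calibration is scale-equivariant: multiplying all intensities by $c$
multiplies $\hat k$ by exactly $c$ and leaves every derived T1 unchanged,
which is what makes maps from different sessions of the same protocol
nominally comparable without intensity normalisation.

## Voxel-wise mapping and invalid voxels

`derive_t1_map()` measures the reference means under user-supplied WM/GM
masks, calibrates $k$, and inverts every voxel inside an optional brain
mask. The closed form is undefined for $u \ge 1$ (intensities at or above
the model maximum $k\sin\theta$), for $E \le 0$, and for $E \ge 1$
(zero or saturated signal, e.g. background). Such voxels are recorded as
`NA` and excluded through the validity mask rather than clamped to a
boundary value: clamping would silently bias ROI means, whereas an
explicit invalid fraction (`pct_invalid` in `roi_t1_stats()`) is visible
in every summary. On disk the sentinel is NaN, always paired with the
saved validity mask.

Masks are interpreted as value > 0.5 after coercion to double, so
probabilistic segmentations can be passed directly. Masks must be
voxel-aligned with the image; no resampling or registration is in scope,
and input volumes are assumed bias-field corrected upstream. ROI SDs use
the sample ($n-1$) denominator.

## The digital phantom

`generate_phantom()` builds a deliberately simple 3-D phantom: a
gray-matter ellipsoidal shell around a white-matter interior with a small
central CSF core, plus non-overlapping spherical lesions placed entirely
inside white matter. Anatomical realism is a non-goal — the mapping is
voxel-wise, so correctness is exercised by tissue contrast, not geometry.
Default class T1s are the calibration references themselves (WM 810 ms,
GM 1350 ms), a chronic-lesion class at 1040 ms (typical of the black-hole
T1 range), and CSF at 4000 ms, a standard 3T literature value. The
noiseless signal is the forward model times a per-class proton-density
factor, defaulting to 1 everywhere to match the single-$k$ model; setting
it away from 1 exists specifically to quantify the bias that assumption
introduces (the test suite demonstrates a 0.9 GM proton density shifts
the recovered GM T1 by tens of ms).

`add_noise()` adds Gaussian noise of SD $\sigma = \text{reference}/SNR$,
or Rician noise — the modulus of the signal plus complex Gaussian noise —
which is the correct model for magnitude MRI and is positively biased at
low SNR (the noise floor). The SNR reference intensity must be stated by
the caller; the package convention for phantoms is the noiseless WM-class
signal, recorded in output metadata. All randomness is locally seeded:
a seed is mandatory and the caller's RNG state is restored.

What passing phantom tests show: the calibration/inversion chain is
mathematically exact (noiseless recovery to < 1e-6 ms) and robust to
magnitude noise at realistic SNR (class means within 2% at SNR 40 over
ten seeds, ROIs of at least 500 voxels). What they do not show: behaviour
under partial-volume mixing, B1 inhomogeneity, imperfect spoiling, motion
or residual bias fields — none of which the phantom models.

## The cohort simulator and statistics

`simulate_cohort()` emulates a two-timepoint longitudinal MS cohort
(default n = 20 over 36.6 months): per-subject gray matter, white matter,
thalamus and corpus-callosum volumes, T2 lesion volume, GM and lesion ROI
T1 means, and demographic covariates. Default percent changes are
GM −2.24, WM −0.335, thalamus −3.599, corpus callosum −5.262, stable T2
lesion volume, and upward (non-significant) T1 drifts of +6.06% (GM) and
+2.64% (lesions); baseline means and dispersions match a natalizumab-
treated relapsing-remitting cohort (GM 798,025 mm³, WM 643,248 mm³,
thalamus 10,671 mm³, corpus callosum 1,751 mm³, GM T1 1240 ms, lesion T1
1042 ms). PBVC is composed as a 0.55/0.45 gray/white mix of the realised
compartment changes plus a linear age effect (−0.062 percent per year,
centred at 40 y) and residual noise, so gray-matter change correlates
with PBVC and a configured age effect is recoverable by regression. The
package fixes the PBVC sign convention as negative = volume loss,
removing the ambiguity between "change" and "loss magnitude" phrasings.

The analysis plan mirrors longitudinal atrophy studies:
`paired_t_test()` (classic paired t, two-sided), `spearman_rho()`
(average ranks for ties, p by the t approximation) and `regress_pbvc()`
(OLS with intercept; univariate mode fits each covariate separately,
multivariate jointly; factor covariates such as race are coded with the
largest category as reference, since a single reported "race" coefficient
does not pin down a coding). Zero-variance differences and constant
vectors return explicit degenerate flags instead of NaN. Two-sided tests
throughout and no multiple-testing correction, matching the analysis
plans this module emulates. No automated normality gate is applied — Q-Q
screening has no crisp decision rule — and the CLI report says so.

## Numerical choices and degenerate inputs

* Flip angles are accepted in degrees at every interface and converted
  internally.
* T1 is reported in ms throughout; volumes in mm³, T2 lesion volume in
  cm³, changes in percent.
* Inversion validity is decided by the exact conditions $0 < E < 1$ and
  $S > 0$; no epsilon tolerances are applied, so a voxel at exactly the
  saturation intensity is invalid rather than mapped to an enormous T1.
* `calibrate_k()` rejects degenerate references whose unit-$k$ forward
  signal is zero, and an empty reference list is a usage error.
* Lesion placement retries up to 200 attempts per requested lesion and
  then raises an explicit placement error rather than silently dropping
  lesions.
* Problem sizes in the validation suite: noiseless recovery and the
  noisy-recovery gate run on 64³ phantoms (the noisy gate over ten
  seeds at SNR 40); statistical routines are cross-checked against
  independent textbook-formula oracles on 100 random vectors.

## Known limitations

The single global $k$ ignores proton-density and receive-field
differences between tissues; the residuals and the phantom's
proton-density dial expose, but do not correct, the resulting bias.
Variable-flip-angle fitting, B1 correction, phase/complex data, DICOM
ingestion, registration between timepoints and lesion segmentation are
all out of scope: lesion and reference masks are user input, and the
Heschl-gyrus NAGM convention is documented rather than enforced. Whether
intensities were normalised across timepoints upstream is an assumption
the per-scan calibration makes harmless only to the extent the protocol
was truly unchanged.
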