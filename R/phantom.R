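# All stochastic code in this file draws from a locally scoped RNG stream:
# the caller's .Random.seed is saved and restored, and a seed is mandatory.

with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number", call. = FALSE)
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  code
}

#' Specification of a synthetic brain phantom
#'
#' Describes a simple 3-D digital brain phantom: nested ellipsoids forming a
#' gray-matter shell around a white-matter interior with a central
#' CSF (ventricle-like) core, plus optional spherical lesions embedded in the
#' white matter. Each tissue class carries a ground-truth T1 and a
#' proton-density factor. Default T1s are the calibration literature values
#' for WM (810 ms) and GM (1350 ms), a chronic-lesion class at 1040 ms
#' (typical of T1-hypointense "black holes"), and CSF at 4000 ms. Proton
#' density defaults to 1 for every class, matching the single-k signal
#' model; setting per-class values away from 1 exists specifically to
#' measure the bias that assumption introduces.
#'
#' @param shape Integer grid dimensions, length 3.
#' @param t1_ms Named per-class T1 in ms: `csf`, `gm`, `wm`, `lesion`.
#' @param proton_density Named per-class proton-density factor, same names.
#' @param lesion_count Number of spherical WM lesions (>= 0).
#' @param lesion_radius_range Lesion radius range in voxels, length 2.
#' @param k_true Scanner constant used by the forward model.
#' @param params A [seq_params] object for the forward model.
#' @param seed RNG seed (mandatory; lesion placement is stochastic).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 64),
                         t1_ms = c(csf = 4000, gm = 1350, wm = 810,
                                   lesion = 1040),
                         proton_density = c(csf = 1, gm = 1, wm = 1,
                                            lesion = 1),
                         lesion_count = 5,
                         lesion_radius_range = c(2, 4),
                         k_true = 100,
                         params = seq_params(),
                         seed) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 8L))
    stop("'shape' must be three dimensions, each >= 8", call. = FALSE)
  cls <- c("csf", "gm", "wm", "lesion")
  if (!all(cls %in% names(t1_ms)) || any(t1_ms <= 0))
    stop("'t1_ms' must name positive csf/gm/wm/lesion values", call. = FALSE)
  if (!all(cls %in% names(proton_density)) || any(proton_density <= 0))
    stop("'proton_density' must name positive csf/gm/wm/lesion values",
         call. = FALSE)
  if (lesion_count < 0) stop("'lesion_count' must be >= 0", call. = FALSE)
  if (length(lesion_radius_range) != 2L || any(lesion_radius_range <= 0) ||
      lesion_radius_range[1] > lesion_radius_range[2])
    stop("'lesion_radius_range' must be an increasing positive pair",
         call. = FALSE)
  if (k_true <= 0) stop("'k_true' must be positive", call. = FALSE)
  stopifnot_params(params)
  structure(list(shape = shape, t1_ms = t1_ms[cls],
                 proton_density = proton_density[cls],
                 lesion_count = as.integer(lesion_count),
                 lesion_radius_range = lesion_radius_range,
                 k_true = k_true, params = params, seed = seed),
            class = "phantom_spec")
}

# Integer codes for the label grid.
PHANTOM_LABELS <- c(background = 0L, csf = 1L, gm = 2L, wm = 3L, lesion = 4L)

#' Generate a synthetic brain phantom
#'
#' Realises a [phantom_spec]: builds the nested-ellipsoid label grid, places
#' the requested number of non-overlapping spherical lesions entirely inside
#' white matter, assigns ground-truth T1 per class, and synthesises the
#' noiseless signal volume as
#' `proton_density * forward_signal(t1_truth, params, k_true)`.
#' Deterministic given the spec's seed.
#'
#' @param spec A [phantom_spec].
#' @return An object of class `phantom` with elements `labels` (integer
#'   3-D grid: 0 background, 1 CSF, 2 GM, 3 WM, 4 lesion), `t1_truth`
#'   (ms; `NA` in background), `signal` (noiseless magnitude grid), and
#'   `spec`.
#' @examples
#' ph <- generate_phantom(phantom_spec(shape = c(24, 24, 24),
#'                                     lesion_count = 1, seed = 7))
#' table(ph$labels)
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec"))
    stop("'spec' must be a phantom_spec", call. = FALSE)
  d <- spec$shape
  # normalised coordinates in [-1, 1] per axis
  nx <- (seq_len(d[1]) - (d[1] + 1) / 2) / (d[1] / 2)
  ny <- (seq_len(d[2]) - (d[2] + 1) / 2) / (d[2] / 2)
  nz <- (seq_len(d[3]) - (d[3] + 1) / 2) / (d[3] / 2)
  X <- array(rep(nx, times = d[2] * d[3]), d)
  Y <- array(rep(rep(ny, each = d[1]), times = d[3]), d)
  Z <- array(rep(nz, each = d[1] * d[2]), d)
  in_ellipsoid <- function(ax) (X / ax[1])^2 + (Y / ax[2])^2 + (Z / ax[3])^2 <= 1

  labels <- array(PHANTOM_LABELS[["background"]], d)
  labels[in_ellipsoid(c(0.88, 0.92, 0.84))] <- PHANTOM_LABELS[["gm"]]
  labels[in_ellipsoid(c(0.62, 0.66, 0.58))] <- PHANTOM_LABELS[["wm"]]
  labels[in_ellipsoid(c(0.16, 0.28, 0.14))] <- PHANTOM_LABELS[["csf"]]

  if (spec$lesion_count > 0) {
    labels <- with_seed(spec$seed,
                        place_lesions(labels, spec$lesion_count,
                                      spec$lesion_radius_range))
  }

  t1 <- array(NA_real_, d)
  pd <- array(0, d)
  for (cls in c("csf", "gm", "wm", "lesion")) {
    sel <- labels == PHANTOM_LABELS[[cls]]
    t1[sel] <- spec$t1_ms[[cls]]
    pd[sel] <- spec$proton_density[[cls]]
  }
  signal <- array(0, d)
  inside <- labels > 0L
  signal[inside] <- pd[inside] *
    forward_signal(t1[inside], spec$params, spec$k_true)

  structure(list(labels = labels, t1_truth = t1, signal = signal,
                 spec = spec),
            class = "phantom")
}

place_lesions <- function(labels, count, radius_range) {
  d <- dim(labels)
  wm_idx <- which(labels == PHANTOM_LABELS[["wm"]])
  max_attempts <- 200L * count
  placed <- 0L
  attempts <- 0L
  while (placed < count) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop(sprintf("could not place %d lesions after %d attempts",
                   count, max_attempts), call. = FALSE)
    r <- stats::runif(1, radius_range[1], radius_range[2])
    centre <- arrayInd(sample(wm_idx, 1L), d)[1, ]
    rc <- ceiling(r)
    lo <- centre - rc; hi <- centre + rc
    if (any(lo < 1L) || any(hi > d)) next
    xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
    cube <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
    dist2 <- (cube[, 1] - centre[1])^2 + (cube[, 2] - centre[2])^2 +
      (cube[, 3] - centre[3])^2
    ball <- cube[dist2 <= r^2, , drop = FALSE]
    vals <- labels[ball]
    if (!all(vals == PHANTOM_LABELS[["wm"]])) next  # stay inside pure WM
    labels[ball] <- PHANTOM_LABELS[["lesion"]]
    placed <- placed + 1L
  }
  labels
}

#' @export
print.phantom <- function(x, ...) {
  d <- dim(x$labels)
  counts <- table(factor(x$labels, levels = PHANTOM_LABELS,
                         labels = names(PHANTOM_LABELS)))
  cat(sprintf("Digital brain phantom: %d x %d x %d voxels (seed %s)\n",
              d[1], d[2], d[3], format(x$spec$seed)))
  print(counts)
  invisible(x)
}

#' Add measurement noise to a magnitude signal volume
#'
#' Gaussian noise adds `N(0, sigma)` with `sigma = reference / snr`. Rician
#' noise — the distribution of magnitude MRI data under complex Gaussian
#' noise — takes the modulus of `(signal + N(0, sigma)) + i N(0, sigma)`;
#' it is strictly non-negative and positively biased at low SNR (the noise
#' floor). The reference intensity defining the SNR must be stated
#' explicitly; for phantoms the convention is the noiseless WM-class signal.
#'
#' @param volume A numeric array of magnitude intensities.
#' @param snr Signal-to-noise ratio on `reference`; positive.
#' @param reference Reference intensity defining the SNR (e.g. the noiseless
#'   white-matter signal); positive.
#' @param model `"gaussian"` or `"rician"`.
#' @param seed RNG seed (mandatory).
#' @return A numeric array of the same shape, with attributes `snr`,
#'   `snr_reference` and `noise_model` recording the simulation conditions.
#' @export
add_noise <- function(volume, snr, reference, model = c("rician", "gaussian"),
                      seed) {
  model <- match.arg(model)
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  if (!is.numeric(snr) || length(snr) != 1L || snr <= 0)
    stop("'snr' must be a single positive number", call. = FALSE)
  if (!is.numeric(reference) || length(reference) != 1L || reference <= 0)
    stop("'reference' must be a single positive number", call. = FALSE)
  sigma <- reference / snr
  n <- length(volume)
  out <- with_seed(seed, {
    if (model == "gaussian") {
      volume + stats::rnorm(n, 0, sigma)
    } else {
      sqrt((volume + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
    }
  })
  dim(out) <- dim(volume)
  attr(out, "snr") <- snr
  attr(out, "snr_reference") <- reference
  attr(out, "noise_model") <- model
  out
}

#' Default longitudinal effect configuration for the cohort simulator
#'
#' Percent changes between baseline and follow-up per compartment, the
#' between-timepoint noise on those changes, and the linear effect of age on
#' percent brain volume change (PBVC). Defaults emulate a two-timepoint
#' natalizumab-treated relapsing-remitting MS cohort over ~36.6 months:
#' gray matter declines (-2.24%), white matter is essentially stable
#' (-0.335%), the thalamus atrophies (-3.6%) while the corpus callosum
#' change does not reach significance, T2 lesion volume is stable, and ROI
#' T1 values drift upward without significance. PBVC follows the
#' negative-equals-loss sign convention, so the default age slope is
#' negative: older subjects lose more volume.
#'
#' @param change_pct Named percent changes (follow-up vs baseline).
#' @param change_sd_pct Named between-subject SDs of those percent changes.
#' @param pbvc_age_slope PBVC percent per year of age (centred at 40 y).
#' @param pbvc_sd Residual SD of PBVC, percent.
#' @return A list understood by [simulate_cohort].
#' @export
cohort_effects <- function(change_pct = c(gm = -2.24, wm = -0.335,
                                          thalamus = -3.599,
                                          corpus_callosum = -5.262,
                                          t2_lesion_volume = 0,
                                          gm_t1 = 6.06, lesion_t1 = 2.64),
                           change_sd_pct = c(gm = 1.0, wm = 1.0,
                                             thalamus = 1.5,
                                             corpus_callosum = 3.0,
                                             t2_lesion_volume = 5,
                                             gm_t1 = 5, lesion_t1 = 8),
                           pbvc_age_slope = -0.062,
                           pbvc_sd = 0.8) {
  list(change_pct = change_pct, change_sd_pct = change_sd_pct,
       pbvc_age_slope = pbvc_age_slope, pbvc_sd = pbvc_sd)
}

# Baseline population parameters (means / SDs) for the simulated cohort.
COHORT_BASELINE <- list(
  gm = c(mean = 798024.63, sd = 69694),            # mm^3
  wm = c(mean = 643247.52, sd = 58277),            # mm^3
  thalamus = c(mean = 10670.98, sd = 1618.9),      # mm^3
  corpus_callosum = c(mean = 1751.24, sd = 625.8), # mm^3
  gm_t1 = c(mean = 1240.46, sd = 56.44),           # ms
  lesion_t1 = c(mean = 1041.52, sd = 125.82)       # ms
)

#' Simulate a two-timepoint longitudinal cohort
#'
#' Generates per-subject demographic covariates, compartment volumes, T2
#' lesion volume and ROI T1 means at baseline and follow-up, applying the
#' configured multiplicative changes plus between-timepoint noise.
#' PBVC (percent brain volume change, negative = loss) is composed as a
#' gray/white weighted mix of the compartment changes plus a linear age
#' effect centred at 40 years and residual noise, so that gray-matter change
#' correlates with PBVC and a configured age effect is recoverable by
#' regression.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param effects Effect configuration from [cohort_effects].
#' @param interval_months Scan interval in months.
#' @param seed RNG seed (mandatory).
#' @return A data.frame, one row per subject: `subject_id`, `age` (years),
#'   `race`, `disease_duration` (years), `treatment_duration` (months),
#'   `treatment_possession` (percent), `t2_lesion_volume` (baseline, cm^3)
#'   and `t2_lesion_volume_followup`, `pbvc` (percent, negative = loss),
#'   `<compartment>_baseline` / `<compartment>_followup` volumes (mm^3) for
#'   gm, wm, thalamus and corpus_callosum, and `gm_t1_` / `lesion_t1_`
#'   baseline and follow-up means (ms).
#' @examples
#' head(simulate_cohort(6, seed = 1))
#' @export
simulate_cohort <- function(n_subjects = 20, effects = cohort_effects(),
                            interval_months = 36.6, seed) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  if (!is.numeric(n_subjects) || n_subjects < 2)
    stop("'n_subjects' must be at least 2", call. = FALSE)
  n <- as.integer(n_subjects)
  ch <- effects$change_pct
  sdp <- effects$change_sd_pct
  with_seed(seed, {
    age <- pmin(pmax(round(stats::rnorm(n, 38.5, 8)), 18), 65)
    race <- sample(c("Caucasian", "African-American", "Hispanic"), n,
                   replace = TRUE, prob = c(0.50, 0.45, 0.05))
    disease_duration <- pmin(pmax(stats::rlnorm(n, log(9), 0.55), 1), 35)
    treatment_duration <- pmin(pmax(stats::rlnorm(n, log(32.5), 0.30), 24), 68)
    treatment_possession <- pmin(
      100 * treatment_duration / (disease_duration * 12), 100)
    t2lv <- stats::rlnorm(n, log(7.42), 1.0)

    base <- lapply(COHORT_BASELINE, function(p) {
      pmax(stats::rnorm(n, p[["mean"]], p[["sd"]]), 0.1 * p[["mean"]])
    })
    realised <- lapply(names(ch), function(nm) {
      ch[[nm]] + stats::rnorm(n, 0, sdp[[nm]])
    })
    names(realised) <- names(ch)

    follow <- list(
      gm = base$gm * (1 + realised$gm / 100),
      wm = base$wm * (1 + realised$wm / 100),
      thalamus = base$thalamus * (1 + realised$thalamus / 100),
      corpus_callosum = base$corpus_callosum *
        (1 + realised$corpus_callosum / 100),
      gm_t1 = base$gm_t1 * (1 + realised$gm_t1 / 100),
      lesion_t1 = base$lesion_t1 * (1 + realised$lesion_t1 / 100)
    )
    t2lv_follow <- t2lv * (1 + realised$t2_lesion_volume / 100)

    pbvc <- 0.55 * realised$gm + 0.45 * realised$wm +
      effects$pbvc_age_slope * (age - 40) +
      stats::rnorm(n, 0, effects$pbvc_sd)

    data.frame(
      subject_id = sprintf("S%03d", seq_len(n)),
      age = age,
      race = race,
      disease_duration = disease_duration,
      treatment_duration = treatment_duration,
      treatment_possession = treatment_possession,
      t2_lesion_volume = t2lv,
      t2_lesion_volume_followup = t2lv_follow,
      pbvc = pbvc,
      gm_baseline = base$gm, gm_followup = follow$gm,
      wm_baseline = base$wm, wm_followup = follow$wm,
      thalamus_baseline = base$thalamus,
      thalamus_followup = follow$thalamus,
      corpus_callosum_baseline = base$corpus_callosum,
      corpus_callosum_followup = follow$corpus_callosum,
      gm_t1_baseline = base$gm_t1, gm_t1_followup = follow$gm_t1,
      lesion_t1_baseline = base$lesion_t1,
      lesion_t1_followup = follow$lesion_t1,
      interval_months = interval_months,
      stringsAsFactors = FALSE
    )
  })
}
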