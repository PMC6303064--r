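test_that("phantom geometry and determinism contracts hold", {
  spec <- phantom_spec(shape = c(32, 32, 32), lesion_count = 0, seed = 3)
  ph <- generate_phantom(spec)

  # without lesions: exactly background + CSF/GM/WM
  expect_setequal(unique(as.vector(ph$labels)), c(0L, 1L, 2L, 3L))
  # label counts account for every voxel
  expect_equal(sum(table(ph$labels)), prod(spec$shape))
  # t1_truth has no values absent from the spec
  expect_setequal(unique(ph$t1_truth[!is.na(ph$t1_truth)]),
                  unname(spec$t1_ms[c("csf", "gm", "wm")]))
  expect_true(all(is.na(ph$t1_truth[ph$labels == 0L])))
  expect_true(all(ph$signal >= 0))

  # bit-identical regeneration from the same spec
  ph2 <- generate_phantom(spec)
  expect_identical(ph$labels, ph2$labels)
  expect_identical(ph$signal, ph2$signal)

  with_lesions <- generate_phantom(phantom_spec(shape = c(32, 32, 32),
                                                lesion_count = 3, seed = 3))
  expect_true(sum(with_lesions$labels == 4L) > 0)
  # lesions are carved strictly out of white matter
  changed <- with_lesions$labels != ph$labels
  expect_true(all(ph$labels[changed] == 3L))
})

test_that("phantom signal equals an independent forward-model evaluation", {
  spec <- phantom_spec(shape = c(24, 24, 24), lesion_count = 2,
                       k_true = 100, seed = 8)
  ph <- generate_phantom(spec)
  cls_t1 <- c(NA, spec$t1_ms[["csf"]], spec$t1_ms[["gm"]],
              spec$t1_ms[["wm"]], spec$t1_ms[["lesion"]])
  for (lab in 1:4) {
    sel <- which(ph$labels == lab)
    expect_gt(length(sel), 0)
    want <- oracle_forward(cls_t1[lab + 1], 8, 15, 100)
    expect_true(all(abs(ph$signal[sel] - want) < 1e-12))
  }
  expect_true(all(ph$signal[ph$labels == 0L] == 0))
})

test_that("per-class proton density scales the signal and biases the fit", {
  spec <- phantom_spec(shape = c(24, 24, 24), lesion_count = 0,
                       proton_density = c(csf = 1, gm = 0.9, wm = 1,
                                          lesion = 1),
                       seed = 5)
  ph <- generate_phantom(spec)
  gm_sig <- unique(ph$signal[ph$labels == 2L])
  expect_equal(gm_sig, 0.9 * oracle_forward(1350, 8, 15, spec$k_true),
               tolerance = 1e-12)
  # the single-k model then mis-states GM T1 (documented bias, not silent)
  masks <- phantom_class_masks(ph)
  fit <- derive_t1_map(ph$signal, wm_mask = masks$wm, gm_mask = masks$gm,
                       brain_mask = ph$labels > 0)
  st <- roi_t1_stats(fit, masks$gm)
  expect_gt(abs(st$mean_t1_ms - 1350), 10)
})

test_that("lesion placement failure is an explicit error", {
  # a tiny phantom cannot host a huge lesion entirely inside white matter
  spec <- phantom_spec(shape = c(16, 16, 16), lesion_count = 2,
                       lesion_radius_range = c(10, 12), seed = 1)
  expect_error(generate_phantom(spec), "could not place")
})

test_that("noise models behave in their limits", {
  ph <- small_phantom(shape = c(16, 16, 16), lesion_count = 0, seed = 2)
  ref <- oracle_forward(810, 8, 15, ph$spec$k_true)

  # vanishing noise: output identical to input
  quiet <- add_noise(ph$signal, snr = 1e12, reference = ref,
                     model = "rician", seed = 1)
  rel <- abs(quiet - ph$signal)[ph$labels > 0] /
    ph$signal[ph$labels > 0]
  expect_lt(max(rel), 1e-6)

  # Rician floor: zero-signal region acquires a strictly positive mean
  zero <- array(0, c(24, 24, 24))
  noisy0 <- add_noise(zero, snr = 10, reference = 1, model = "rician",
                      seed = 3)
  expect_true(all(noisy0 >= 0))
  expect_gt(mean(noisy0), 0.1 / 10)

  # determinism per seed
  a <- add_noise(ph$signal, 20, ref, "rician", seed = 9)
  b <- add_noise(ph$signal, 20, ref, "rician", seed = 9)
  expect_identical(a, b)
  expect_error(add_noise(ph$signal, 20, ref, "poisson", seed = 1))
})

test_that("Rician mean at SNR 2 matches a Monte-Carlo oracle", {
  nu <- 1                       # constant true signal
  sigma <- nu / 2               # SNR = 2
  vol <- array(nu, c(40, 40, 40))
  noisy <- add_noise(vol, snr = 2, reference = nu, model = "rician",
                     seed = 12)
  # independent Monte-Carlo estimate of the Rician mean (1e6 draws)
  set.seed(99)
  mc <- sqrt((nu + rnorm(1e6, 0, sigma))^2 + rnorm(1e6, 0, sigma)^2)
  se <- sd(mc) / sqrt(length(mc)) + sd(noisy) / sqrt(length(noisy))
  expect_lt(abs(mean(noisy) - mean(mc)), 3 * se)
})

test_that("cohort simulator honours configured effects", {
  # zero effects, zero noise: follow-up equals baseline everywhere
  eff0 <- cohort_effects(
    change_pct = c(gm = 0, wm = 0, thalamus = 0, corpus_callosum = 0,
                   t2_lesion_volume = 0, gm_t1 = 0, lesion_t1 = 0),
    change_sd_pct = c(gm = 0, wm = 0, thalamus = 0, corpus_callosum = 0,
                      t2_lesion_volume = 0, gm_t1 = 0, lesion_t1 = 0),
    pbvc_age_slope = 0, pbvc_sd = 0)
  co0 <- simulate_cohort(10, effects = eff0, seed = 21)
  for (comp in c("gm", "wm", "thalamus", "corpus_callosum", "gm_t1",
                 "lesion_t1")) {
    expect_identical(co0[[paste0(comp, "_baseline")]],
                     co0[[paste0(comp, "_followup")]])
  }
  expect_identical(co0$t2_lesion_volume, co0$t2_lesion_volume_followup)
  expect_true(all(co0$pbvc == 0))

  # configured GM decline with zero noise reproduces the exact percent change
  eff <- eff0
  eff$change_pct[["gm"]] <- -2.24
  co <- simulate_cohort(12, effects = eff, seed = 21)
  pc <- percent_change(co$gm_baseline, co$gm_followup)
  expect_equal(pc, rep(-2.24, 12), tolerance = 1e-10)

  # with noise, the mean realised change sits within 4 SE of the target
  co_n <- simulate_cohort(200, seed = 33)
  pc_n <- percent_change(co_n$gm_baseline, co_n$gm_followup)
  se <- sd(pc_n) / sqrt(length(pc_n))
  expect_lt(abs(mean(pc_n) + 2.24), 4 * se)

  # determinism and basic record sanity
  expect_identical(simulate_cohort(8, seed = 5), simulate_cohort(8, seed = 5))
  expect_true(all(co_n$gm_baseline > 0 & co_n$treatment_possession <= 100))
  expect_error(simulate_cohort(1, seed = 1), "at least 2")
})
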