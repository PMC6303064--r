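# Mask handling: masks may arrive as logical, integer labels or probabilistic
# floats; binary interpretation is value > 0.5 after coercion to double.

as_voxels <- function(x, arg = "volume") {
  if (inherits(x, "image_volume")) x <- x$voxels
  if (!is.array(x) || length(dim(x)) != 3L)
    stop(sprintf("'%s' must be a 3-D array or image_volume", arg), call. = FALSE)
  x
}

as_binary_mask <- function(mask, ref_dim, arg = "mask") {
  m <- as_voxels(mask, arg)
  if (!identical(dim(m), ref_dim))
    stop(sprintf("'%s' shape %s does not match volume shape %s", arg,
                 paste(dim(m), collapse = "x"),
                 paste(ref_dim, collapse = "x")), call. = FALSE)
  storage.mode(m) <- "double"
  m > 0.5
}

#' Mean magnitude intensity under a region-of-interest mask
#'
#' @param volume A 3-D numeric array or [image_volume].
#' @param mask A binary mask of the same shape (values > 0.5 are inside).
#' @return The arithmetic mean of the intensities under the mask.
#' @export
mean_roi_signal <- function(volume, mask) {
  vox <- as_voxels(volume)
  m <- as_binary_mask(mask, dim(vox))
  if (!any(m))
    stop("mask selects no voxels", call. = FALSE)
  mean(vox[m])
}

#' Derive a T1 relaxation map from a T1-weighted volume
#'
#' The central fit of the package. Reference tissue intensities are measured
#' under the supplied white- and gray-matter masks, the scanner constant k is
#' calibrated against the literature reference T1s, and every voxel inside
#' the brain mask (the whole grid when absent) is inverted through the
#' closed-form spoiled gradient-echo relation. Voxels whose intensity falls
#' outside the invertible range — background zeros, saturated or super-model
#' intensities — are marked invalid (`NA` in the map), never clamped.
#'
#' Because k is calibrated per scan, the derived map is invariant to a global
#' rescaling of the input intensities.
#'
#' @param volume A 3-D numeric array or [image_volume] of magnitude
#'   intensities.
#' @param params A [seq_params] object; defaults to the 3DT1TFE protocol
#'   TR = 8 ms, TE = 3.6 ms, flip = 15 degrees.
#' @param wm_mask,gm_mask Binary reference masks (normal-appearing white
#'   matter; normal-appearing gray matter, conventionally Heschl gyrus).
#'   Must be non-empty and disjoint.
#' @param brain_mask Optional binary mask restricting the fit; voxels outside
#'   it are invalid in the result.
#' @param ref_t1_ms Named numeric vector with elements `wm` and `gm`:
#'   literature reference T1s in ms. Defaults to 810 (WM) and 1350 (GM).
#' @return An object of class `t1map` with elements `t1` (3-D array, ms, `NA`
#'   where invalid), `valid` (logical 3-D array), `calibration`
#'   (a `t1_calibration`), `params`, and `spacing`/`affine` when the input
#'   was an [image_volume].
#' @examples
#' ph <- generate_phantom(phantom_spec(shape = c(24, 24, 24), seed = 1))
#' fit <- derive_t1_map(ph$signal,
#'                      wm_mask = ph$labels == 3, gm_mask = ph$labels == 2,
#'                      brain_mask = ph$labels > 0)
#' coef(fit)
#' @export
derive_t1_map <- function(volume, params = seq_params(),
                          wm_mask, gm_mask, brain_mask = NULL,
                          ref_t1_ms = c(wm = 810, gm = 1350)) {
  stopifnot_params(params)
  vox <- as_voxels(volume)
  if (any(!is.finite(vox)) || any(vox < 0))
    stop("'volume' intensities must be finite and non-negative", call. = FALSE)
  if (!all(c("wm", "gm") %in% names(ref_t1_ms)))
    stop("'ref_t1_ms' needs named elements 'wm' and 'gm'", call. = FALSE)
  wm <- as_binary_mask(wm_mask, dim(vox), "wm_mask")
  gm <- as_binary_mask(gm_mask, dim(vox), "gm_mask")
  if (!any(wm)) stop("'wm_mask' selects no voxels", call. = FALSE)
  if (!any(gm)) stop("'gm_mask' selects no voxels", call. = FALSE)
  if (any(wm & gm))
    stop("'wm_mask' and 'gm_mask' overlap; reference ROIs must be disjoint",
         call. = FALSE)
  brain <- if (is.null(brain_mask)) {
    array(TRUE, dim(vox))
  } else {
    as_binary_mask(brain_mask, dim(vox), "brain_mask")
  }

  refs <- list(
    tissue_reference("NAWM", unname(ref_t1_ms["wm"]), mean(vox[wm])),
    tissue_reference("NAGM", unname(ref_t1_ms["gm"]), mean(vox[gm]))
  )
  calib <- calibrate_k(refs, params)

  t1 <- array(NA_real_, dim(vox))
  t1[brain] <- invert_signal(vox[brain], params, calib$k)
  valid <- brain & !is.na(t1)

  out <- list(t1 = t1, valid = valid, calibration = calib, params = params,
              ref_t1_ms = ref_t1_ms, call = match.call())
  if (inherits(volume, "image_volume")) {
    out$spacing <- volume$spacing
    out$affine <- volume$affine
  }
  class(out) <- "t1map"
  out
}

#' @export
print.t1map <- function(x, ...) {
  d <- dim(x$t1)
  cat(sprintf("T1 relaxation map: %d x %d x %d voxels\n", d[1], d[2], d[3]))
  cat(sprintf("  scanner constant k = %.6g (refs: %s)\n",
              x$calibration$k,
              paste(x$calibration$references_used, collapse = ", ")))
  cat(sprintf("  valid voxels: %d (%.1f%% of grid)\n",
              sum(x$valid), 100 * mean(x$valid)))
  invisible(x)
}

#' @export
summary.t1map <- function(object, ...) {
  v <- object$t1[object$valid]
  s <- list(
    dim = dim(object$t1),
    k = object$calibration$k,
    residuals = object$calibration$residuals,
    n_valid = sum(object$valid),
    pct_valid = 100 * mean(object$valid),
    t1_quantiles = if (length(v)) stats::quantile(v, c(0, .25, .5, .75, 1))
                   else NULL,
    params = object$params
  )
  class(s) <- "summary.t1map"
  s
}

#' @export
print.summary.t1map <- function(x, ...) {
  cat(sprintf("T1 relaxation map, %s voxels; TR = %g ms, flip = %g deg\n",
              paste(x$dim, collapse = " x "), x$params$tr_ms,
              x$params$flip_deg))
  cat(sprintf("Calibrated k = %.6g; calibration residuals (signal units):\n",
              x$k))
  print(signif(x$residuals, 4))
  cat(sprintf("Valid voxels: %d (%.1f%%)\n", x$n_valid, x$pct_valid))
  if (!is.null(x$t1_quantiles)) {
    cat("T1 (ms) over valid voxels:\n")
    print(round(x$t1_quantiles, 1))
  }
  invisible(x)
}

#' @export
coef.t1map <- function(object, ...) coef(object$calibration)

#' @export
residuals.t1map <- function(object, ...) object$calibration$residuals

#' Display an axial slice of a T1 map
#'
#' @param x A `t1map` object.
#' @param slice Axial (third-axis) slice index; defaults to the middle slice.
#' @param ... Passed to [graphics::image].
#' @export
plot.t1map <- function(x, slice = NULL, ...) {
  d <- dim(x$t1)
  if (is.null(slice)) slice <- ceiling(d[3] / 2)
  sl <- x$t1[, , slice]
  graphics::image(seq_len(d[1]), seq_len(d[2]), sl,
                  col = grDevices::gray.colors(128), asp = 1,
                  xlab = "x (voxels)", ylab = "y (voxels)",
                  main = sprintf("T1 map (ms), slice %d", slice), ...)
  invisible(x)
}

#' ROI-level T1 statistics from a fitted map
#'
#' Summarises T1 over each label of a region mask. Statistics use valid
#' voxels only; the invalid fraction is reported per ROI, and an ROI whose
#' voxels all failed inversion yields an explicit record with `NA` mean/SD
#' rather than propagating NaN arithmetic. SD uses the sample (n-1)
#' denominator.
#'
#' @param t1map A `t1map` object from [derive_t1_map].
#' @param mask A binary or integer-label mask of the same shape; each
#'   distinct non-zero label becomes one row.
#' @param labels Optional named character vector mapping label values to ROI
#'   names.
#' @return A data.frame with columns `label`, `n_voxels`, `mean_t1_ms`,
#'   `sd_t1_ms`, `pct_invalid`.
#' @export
roi_t1_stats <- function(t1map, mask, labels = NULL) {
  if (!inherits(t1map, "t1map"))
    stop("'t1map' must come from derive_t1_map()", call. = FALSE)
  m <- as_voxels(mask, "mask")
  if (!identical(dim(m), dim(t1map$t1)))
    stop("'mask' shape does not match the T1 map", call. = FALSE)
  if (is.logical(m)) m <- m * 1L
  vals <- sort(unique(as.vector(m[m != 0])))
  if (length(vals) == 0L)
    stop("mask selects no voxels", call. = FALSE)
  rows <- lapply(vals, function(v) {
    inside <- m == v
    n <- sum(inside)
    good <- inside & t1map$valid
    ngood <- sum(good)
    lbl <- if (!is.null(labels) && as.character(v) %in% names(labels))
      labels[[as.character(v)]] else as.character(v)
    data.frame(
      label = lbl,
      n_voxels = n,
      mean_t1_ms = if (ngood > 0) mean(t1map$t1[good]) else NA_real_,
      sd_t1_ms = if (ngood > 1) stats::sd(t1map$t1[good])
                 else if (ngood == 1) 0 else NA_real_,
      pct_invalid = (n - ngood) / n,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
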