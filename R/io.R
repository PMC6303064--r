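#' Construct an in-memory image volume
#'
#' A light container for a 3-D magnitude image: the voxel grid, the voxel
#' spacing in mm and the voxel-to-world affine. Voxel indices are 0-based in
#' voxel space; world coordinates are obtained only through the affine.
#' NIfTI stores scale through the quaternion/pixdim pair, so the affine's
#' column norms should agree with `spacing` (the default affine is built
#' that way).
#'
#' @param voxels 3-D numeric array, non-negative; `NaN` is tolerated as the
#'   invalid-voxel sentinel of on-disk T1 maps.
#' @param spacing Voxel size per axis in mm, length 3, positive.
#' @param affine 4x4 voxel-to-world matrix; defaults to `diag(spacing)` with
#'   zero origin.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(voxels, spacing = c(1, 1, 1), affine = NULL) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("'voxels' must be a 3-D array", call. = FALSE)
  if (any(is.infinite(voxels)) || any(voxels < 0, na.rm = TRUE))
    stop("'voxels' must be non-negative and free of infinities", call. = FALSE)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("'spacing' must be three positive values", call. = FALSE)
  if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
  }
  if (!is.matrix(affine) || !identical(dim(affine), c(4L, 4L)))
    stop("'affine' must be a 4x4 matrix", call. = FALSE)
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 affine = unname(affine)),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("Image volume: %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(format(x$spacing), collapse = " x ")))
  invisible(x)
}

#' Read a 3-D NIfTI-1 volume
#'
#' Accepts plain `.nii` and gzipped `.nii.gz` files; only 3-D volumes are
#' supported (time series and multi-channel data are rejected explicitly).
#'
#' @param path Path to a NIfTI-1 file.
#' @return An [image_volume].
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop(sprintf("unsupported dimensionality: %d-D volume (only 3-D supported)",
                 length(d)), call. = FALSE)
  aff <- RNifti::xform(img)
  image_volume(array(as.numeric(img), d),
               spacing = RNifti::pixdim(img),
               affine = matrix(as.numeric(aff), 4, 4))
}

#' Write a 3-D volume as NIfTI-1
#'
#' Float data are stored as 64-bit doubles so that write-then-read round
#' trips are bit-identical; integer arrays (e.g. label grids) are stored as
#' 32-bit integers. Compression is chosen from the file extension
#' (`.nii.gz` vs `.nii`).
#'
#' @param volume An [image_volume] or a bare 3-D array.
#' @param path Output path.
#' @param spacing,affine Used only when `volume` is a bare array.
#' @return The path, invisibly.
#' @export
write_volume <- function(volume, path, spacing = c(1, 1, 1), affine = NULL) {
  if (inherits(volume, "image_volume")) {
    vox <- volume$voxels
    spacing <- volume$spacing
    affine <- volume$affine
  } else {
    vox <- volume
  }
  if (!is.array(vox) || length(dim(vox)) != 3L)
    stop("'volume' must be a 3-D array or image_volume", call. = FALSE)
  if (is.logical(vox)) storage.mode(vox) <- "integer"
  as_int <- is.integer(vox)
  if (!as_int) storage.mode(vox) <- "double"
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  img <- RNifti::asNifti(vox)
  RNifti::pixdim(img) <- spacing
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = if (as_int) "int32" else "double")
  invisible(path)
}

#' Read a run configuration from YAML or JSON
#'
#' Recognised keys mirror the derive pipeline: `tr_ms`, `te_ms`, `flip_deg`
#' (defaults 8, 3.6, 15 — the 3DT1TFE protocol), `references` (list with
#' `wm`/`gm` entries holding `t1_ms`, defaults 810/1350), input paths
#' (`image`, `wm_mask`, `gm_mask`, `brain_mask`, `roi_mask`), `out_dir`,
#' and `seed`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config must be .yaml, .yml or .json", call. = FALSE)
  }
  cfg
}

config_params <- function(config) {
  seq_params(tr_ms = config$tr_ms %||% 8,
             te_ms = config$te_ms %||% 3.6,
             flip_deg = config$flip_deg %||% 15)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the derive -> ROI-statistics pipeline
#'
#' Executes the full mapping workflow described by a configuration list (or
#' a YAML/JSON path): read the T1-weighted volume and reference masks,
#' derive the T1 map, write the map and validity mask, compute ROI
#' statistics for an optional label mask, and record a reproducibility
#' manifest (inputs, seed, calibrated k, MD5 hashes of every output).
#'
#' @param config A list (see [read_run_config]) or a path to a config file.
#' @return The manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  for (key in c("image", "wm_mask", "gm_mask", "out_dir")) {
    if (is.null(config[[key]]))
      stop("config is missing required key '", key, "'", call. = FALSE)
  }
  for (key in c("image", "wm_mask", "gm_mask",
                intersect(c("brain_mask", "roi_mask"), names(config)))) {
    if (!file.exists(config[[key]]))
      stop("input for '", key, "' not found: ", config[[key]], call. = FALSE)
  }
  params <- config_params(config)
  refs <- config$references %||% list()
  ref_t1 <- c(wm = refs$wm$t1_ms %||% 810, gm = refs$gm$t1_ms %||% 1350)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  vol <- read_volume(config$image)
  wm <- read_volume(config$wm_mask)
  gm <- read_volume(config$gm_mask)
  brain <- if (!is.null(config$brain_mask)) read_volume(config$brain_mask)
  fit <- derive_t1_map(vol, params, wm_mask = wm, gm_mask = gm,
                       brain_mask = brain, ref_t1_ms = ref_t1)

  map_path <- file.path(config$out_dir, "t1_map.nii.gz")
  valid_path <- file.path(config$out_dir, "valid_mask.nii.gz")
  t1_out <- fit$t1                 # invalid-voxel sentinel is NaN on disk
  t1_out[!fit$valid] <- NaN
  write_volume(t1_out, map_path, spacing = vol$spacing, affine = vol$affine)
  write_volume(fit$valid, valid_path, spacing = vol$spacing,
               affine = vol$affine)

  outputs <- c(t1_map = map_path, valid_mask = valid_path)
  stats_tbl <- NULL
  if (!is.null(config$roi_mask)) {
    roi <- read_volume(config$roi_mask)
    stats_tbl <- roi_t1_stats(fit, roi$voxels)
    stats_path <- file.path(config$out_dir, "roi_stats.csv")
    write_roi_stats(stats_tbl, stats_path)
    outputs <- c(outputs, roi_stats = stats_path)
  }

  manifest <- list(
    package = "t1relax",
    version = as.character(utils::packageVersion("t1relax")),
    seed = config$seed %||% NA,
    inputs = config[intersect(c("image", "wm_mask", "gm_mask", "brain_mask",
                                "roi_mask"), names(config))],
    sequence = list(tr_ms = params$tr_ms, te_ms = params$te_ms,
                    flip_deg = params$flip_deg),
    reference_t1_ms = as.list(ref_t1),
    k = fit$calibration$k,
    calibration_residuals = as.list(fit$calibration$residuals),
    n_valid_voxels = sum(fit$valid),
    outputs = as.list(outputs),
    output_md5 = as.list(tools::md5sum(unname(outputs)))
  )
  if (!is.null(stats_tbl)) {
    manifest$roi_stats <- stats_tbl
  }
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "rows",
                       na = "null")
  invisible(manifest)
}

#' Write ROI statistics as CSV
#'
#' Fixed dialect: comma separator, `.` decimal, UTF-8, header row. Units are
#' in the column names (`mean_t1_ms`, `sd_t1_ms`); `pct_invalid` is a
#' fraction in \[0, 1\].
#'
#' @param stats A data.frame from [roi_t1_stats].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_roi_stats <- function(stats, path) {
  utils::write.csv(stats, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
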