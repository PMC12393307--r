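# Readers/writers for the standard interchange formats: 4D NIfTI volumes
# (via RNifti), 3-column onset files, whitespace-delimited 6-column motion
# tables, single-column outlier flags, YAML configuration.

#' Read a 4D BOLD NIfTI file
#'
#' @param path Path to a `.nii`/`.nii.gz` file.
#' @return A `bold_series` (list: `data` 4D array, `tr` s, `voxel_size`
#'   mm, `slice_order`). Errors name the offending header field: a 3D
#'   file raises a dimensionality error, a missing or non-positive TR is
#'   rejected rather than silently defaulted.
#' @export
read_bold <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  # validate against the raw on-disk header (readNifti normalises degenerate
  # pixdim entries, which would silently default a missing TR)
  hdr <- RNifti::niftiHeader(path)
  pd <- hdr$pixdim[-1]                     # drop the qfac slot, pixdim[0]
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L)
    stop(sprintf("expected a 4D volume, got %dD (header field 'dim')",
                 length(d)))
  if (length(pd) < 4L || !is.finite(pd[4]) || pd[4] <= 0)
    stop("missing or non-positive repetition time (header field 'pixdim[4]')")
  if (any(!is.finite(pd[1:3])) || any(abs(pd[1:3]) <= 0))
    stop("non-positive voxel size (header field 'pixdim[1:3]')")
  structure(list(data = array(as.numeric(img), d), tr = pd[4],
                 voxel_size = abs(pd[1:3]), slice_order = seq_len(d[3])),
            class = "bold_series")
}

#' Write a 4D BOLD series as NIfTI
#'
#' Stores the voxel sizes and the TR in the header's `pixdim` field so
#' [read_bold()] round-trips losslessly.
#'
#' @param series A `bold_series`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_bold <- function(series, path) {
  .check_series(series)
  img <- RNifti::asNifti(series$data)
  RNifti::pixdim(img) <- c(series$voxel_size, series$tr)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Write / read a 3D volume (maps, labels, masks) as NIfTI
#' @param volume 3D numeric/integer/logical array.
#' @param path Output path.
#' @param voxel_size Voxel sizes in mm.
#' @return The path, invisibly (writer); the array (reader).
#' @export
write_volume <- function(volume, path, voxel_size = c(0.8, 0.8, 0.8)) {
  stopifnot(is.array(volume), length(dim(volume)) == 3L)
  img <- RNifti::asNifti(array(as.numeric(volume), dim(volume)))
  RNifti::pixdim(img) <- voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("expected a 3D volume")
  array(as.numeric(img), dim(img))
}

#' Write / read stimulus onsets as a 3-column text file
#'
#' Columns: onset (s), duration (s), weight — one row per block.
#'
#' @param paradigm A [make_paradigm()] object.
#' @param path File path.
#' @return The path, invisibly (writer); for the reader, a data.frame
#'   with `onset`, `duration`, `weight`.
#' @export
write_onsets <- function(paradigm, path) {
  stopifnot(inherits(paradigm, "paradigm"))
  df <- data.frame(onset = paradigm$onsets,
                   duration = paradigm$block_duration, weight = 1)
  utils::write.table(df, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_onsets
#' @export
read_onsets <- function(path) {
  df <- utils::read.table(path, col.names = c("onset", "duration", "weight"))
  if (ncol(df) != 3L) stop("onset file must have 3 columns")
  df
}

#' Write / read a motion-parameter table
#'
#' Whitespace-delimited, six columns per volume: roll, pitch, yaw
#' (degrees) and x/y/z displacement (mm).
#'
#' @param motion A [motion_trace()].
#' @param path File path.
#' @return The path, invisibly (writer); a `motion_trace` (reader).
#' @export
write_motion <- function(motion, path) {
  stopifnot(is.data.frame(motion))
  utils::write.table(motion[, c("roll", "pitch", "yaw", "dx", "dy", "dz")],
                     path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_motion
#' @export
read_motion <- function(path) {
  m <- as.matrix(utils::read.table(path))
  if (ncol(m) != 6L) stop("motion table must have 6 columns")
  motion_trace(translations_mm = m[, 4:6], rotations_deg = m[, 1:3])
}

#' Write outlier flags as single-column text (one row per volume, 0/1)
#' @param flags Logical per-volume vector.
#' @param path File path.
#' @export
write_outlier_flags <- function(flags, path) {
  utils::write.table(as.integer(flags), path, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' All thresholds default to the study's stated values: 0.02 Hz
#' high-pass cutoff, 0.8 mm trial-censoring threshold, z > 3.1
#' activation threshold, 3 equivolume depth bins, 7 columns per slice,
#' top-40th-centile column selection, 0.16 x 0.16 x 0.8 mm analysis
#' grid, 26.6 s on/off blocks at TR 2.66 s.
#'
#' @param seed Integer seed for the run.
#' @return A nested list of class `pipeline_config`.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    groups = c("preterm", "early_term", "late_term", "adult"),
    paradigm = list(n_blocks = 7L, block_s = 26.6, rest_s = 26.6, tr = 2.66),
    ribbon = list(shape = c(10L, 10L, 2L), voxel_size = c(0.8, 0.8, 0.8),
                  geometry = "annulus", inner = 4, outer = 6),
    generator = list(noise_sd = 0.2, baseline = 1000,
                     drift = list(linear = 0.5, cosine = 0.3),
                     depth_amplitudes = list(
                       preterm = c(3.0, 1.5, 1.0),
                       early_term = c(3.0, 1.5, 1.0),
                       late_term = c(3.0, 1.5, 1.0),
                       adult = c(2.5, 2.0, 1.5))),
    preprocess = list(cutoff_hz = 0.02, censor_mm = 0.8, denoise = "none",
                      slice_timing = TRUE),
    glm = list(z_thresh = 3.1, prewhiten = FALSE),
    laminar = list(n_bins = 3L, n_columns = 7L, centile = 40,
                   target_voxel = c(0.16, 0.16, 0.8),
                   resample_mode = "nearest")
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Fields present in the file override [default_config()] defaults;
#' basic validity (positive thresholds) is checked.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(unclass(default_config()), user)
  stopifnot(cfg$preprocess$cutoff_hz > 0, cfg$preprocess$censor_mm > 0,
            cfg$glm$z_thresh > 0, cfg$laminar$n_bins >= 1,
            cfg$laminar$n_columns >= 1,
            cfg$laminar$centile > 0, cfg$laminar$centile <= 100)
  class(cfg) <- "pipeline_config"
  cfg
}
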