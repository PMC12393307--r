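# Minimal preprocessing chain for 4D BOLD data. Stage order mirrors common
# practice for laminar acquisitions: slice-timing interpolation, an optional
# denoising hook, motion handling, confound regression, high-pass filtering.
# All operators take and return a `bold_series` (list: data 4D array, tr,
# voxel_size, slice_order).

.check_series <- function(series) {
  stopifnot(is.list(series), is.array(series$data),
            length(dim(series$data)) == 4L, dim(series$data)[4] >= 2L,
            is.numeric(series$tr), series$tr > 0)
  invisible(series)
}

# time x voxel matrix view and back
.as_tv <- function(series) {
  d <- dim(series$data)
  t(matrix(series$data, prod(d[1:3]), d[4]))
}
.from_tv <- function(series, m) {
  series$data <- array(t(m), dim(series$data))
  series
}

#' Slice-timing correction
#'
#' Linearly interpolates each slice's timeseries to the acquisition time
#' of the middle slice of each volume. Slice k (in acquisition order) is
#' assumed acquired at `(pos_k - 1) / n_slices * TR` after the volume
#' start.
#'
#' @param series A `bold_series`.
#' @param slice_order Integer vector: acquisition order of slices
#'   (`slice_order[i]` is the i-th slice acquired). Must be a permutation
#'   of the slice indices.
#' @return Corrected `bold_series`.
#' @export
slice_time_correct <- function(series, slice_order = NULL) {
  .check_series(series)
  d <- dim(series$data)
  nz <- d[3]; nt <- d[4]
  if (is.null(slice_order)) slice_order <- series$slice_order
  if (is.null(slice_order)) slice_order <- seq_len(nz)
  if (!setequal(slice_order, seq_len(nz)))
    stop("'slice_order' must be a permutation of the slice indices")
  # acquisition-time offset of each slice within the volume
  pos <- match(seq_len(nz), slice_order)          # rank in acquisition order
  t_off <- (pos - 1) / nz * series$tr
  mid <- t_off[slice_order[ceiling(nz / 2)]]      # middle acquired slice
  t_vol <- (seq_len(nt) - 1) * series$tr
  for (k in seq_len(nz)) {
    shift <- t_off[k] - mid
    if (abs(shift) < 1e-12) next
    sl <- matrix(series$data[, , k, ], d[1] * d[2], nt)
    sl <- t(apply(sl, 1, function(ts)
      stats::approx(t_vol, ts, xout = t_vol - shift, rule = 2)$y))
    series$data[, , k, ] <- array(sl, c(d[1], d[2], nt))
  }
  series
}

#' Denoising hook
#'
#' Pass-through hook at the position where thermal-noise denoising (for
#' example a low-rank PCA method applied to magnitude data) would run.
#' `method = "none"` (default) returns the input unchanged;
#' `method = "tpca"` applies a simple temporal-PCA soft threshold that
#' discards components with singular values below
#' `keep_sd * median singular value`.
#'
#' @param series A `bold_series`.
#' @param method `"none"` or `"tpca"`.
#' @param keep_sd Threshold multiplier for `"tpca"`.
#' @return A `bold_series`.
#' @export
denoise_hook <- function(series, method = c("none", "tpca"), keep_sd = 1.2) {
  method <- match.arg(method)
  .check_series(series)
  if (method == "none") return(series)
  m <- .as_tv(series)
  mu <- colMeans(m)
  sv <- svd(sweep(m, 2, mu))
  keep <- sv$d >= keep_sd * stats::median(sv$d)
  keep[1] <- TRUE
  rec <- sv$u[, keep, drop = FALSE] %*%
    (sv$d[keep] * t(sv$v[, keep, drop = FALSE]))
  .from_tv(series, sweep(rec, 2, mu, `+`))
}

#' Translation-only motion correction
#'
#' Estimates an integer-voxel in-plane translation of every volume
#' relative to a reference volume by exhaustive search over a small shift
#' window (maximising correlation), and resamples each volume back
#' (nearest-voxel). A stand-in for full rigid-body registration, adequate
#' for the generator's translation-only motion.
#'
#' @param series A `bold_series`.
#' @param reference_index Reference volume (default 1).
#' @param max_shift_vox Search radius in voxels per in-plane axis.
#' @return List with `series` (corrected) and `motion` (a
#'   [motion_trace()] of the estimated translations in mm).
#' @export
register_translation <- function(series, reference_index = 1L,
                                 max_shift_vox = 2L) {
  .check_series(series)
  d <- dim(series$data)
  nt <- d[4]
  if (reference_index < 1 || reference_index > nt)
    stop("'reference_index' outside the acquisition")
  ref <- series$data[, , , reference_index]
  shifts <- expand.grid(dx = -max_shift_vox:max_shift_vox,
                        dy = -max_shift_vox:max_shift_vox)
  est <- matrix(0, nt, 3)
  for (j in seq_len(nt)) {
    vol <- series$data[, , , j, drop = FALSE]
    dim(vol) <- d[1:3]
    best <- c(0L, 0L); best_cor <- -Inf
    for (s in seq_len(nrow(shifts))) {
      cand <- .shift_volume(vol, -shifts$dx[s], -shifts$dy[s])
      cc <- stats::cor(as.vector(cand), as.vector(ref))
      if (is.finite(cc) && cc > best_cor) {
        best_cor <- cc; best <- c(shifts$dx[s], shifts$dy[s])
      }
    }
    if (any(best != 0)) {
      series$data[, , , j] <- .shift_volume(vol, -best[1], -best[2])
      est[j, 1:2] <- best * series$voxel_size[1:2]
    }
  }
  est <- sweep(est, 2, est[reference_index, ])
  list(series = series, motion = motion_trace(est))
}

#' High-pass filter for low-frequency drift removal
#'
#' Removes signal components below `cutoff_hz`; the temporal mean is
#' preserved. Two kernels are available. The default, `"gaussian"`, is a
#' Gaussian-weighted running-line filter (local weighted linear fit with
#' temporal sd equal to half the cutoff period, subtracted from the
#' data): its gentle roll-off removes drift while passing a 26.6 s
#' on/off block design (fundamental 0.0188 Hz) almost untouched even at
#' the 0.02 Hz cutoff. `"dct"` regresses out the discrete-cosine basis
#' functions below the cutoff — a sharp projection that also removes
#' task power at frequencies just under the cutoff, so it suits designs
#' whose fundamental lies well above it.
#'
#' @param series A `bold_series`.
#' @param cutoff_hz Cutoff frequency in Hz (default 0.02). Must be below
#'   Nyquist, `1 / (2 * TR)`.
#' @param method `"gaussian"` (running line) or `"dct"` (cosine-basis
#'   projection).
#' @return Filtered `bold_series`.
#' @export
highpass <- function(series, cutoff_hz = 0.02,
                     method = c("gaussian", "dct")) {
  method <- match.arg(method)
  .check_series(series)
  nt <- dim(series$data)[4]
  nyq <- 1 / (2 * series$tr)
  if (cutoff_hz >= nyq)
    stop(sprintf("cutoff %.3f Hz is not below Nyquist %.3f Hz", cutoff_hz, nyq))
  m <- .as_tv(series)
  mu <- colMeans(m)
  if (method == "gaussian") {
    S <- hp_smoother(nt, series$tr, cutoff_hz)
    filt <- m - S %*% m
  } else {
    X <- dct_basis(nt, series$tr, cutoff_hz)
    if (is.null(X)) return(series)
    filt <- as.matrix(stats::lm.fit(X, sweep(m, 2, mu))$residuals)
  }
  .from_tv(series, sweep(filt, 2, mu - colMeans(filt), `+`))
}

#' Running-line smoother matrix for drift estimation
#'
#' Returns the `n x n` matrix `S` whose rows give, for each timepoint,
#' the Gaussian-weighted local linear fit evaluated there (temporal sd =
#' `1 / (2 * cutoff_hz)` seconds). `S %*% y` is the drift estimate;
#' `y - S %*% y` the high-passed signal. Polynomials up to degree 1 are
#' reproduced exactly, so linear drift is removed completely, including
#' at the run edges.
#'
#' @param n_volumes Number of timepoints.
#' @param tr Repetition time (s).
#' @param cutoff_hz Cutoff frequency (Hz).
#' @return An `n x n` smoother matrix.
#' @export
hp_smoother <- function(n_volumes, tr, cutoff_hz) {
  t <- (seq_len(n_volumes) - 1) * tr
  sigma <- 1 / (2 * cutoff_hz)
  S <- matrix(0, n_volumes, n_volumes)
  for (i in seq_len(n_volumes)) {
    w <- exp(-((t - t[i])^2) / (2 * sigma^2))
    X <- cbind(1, t - t[i])
    WX <- w * X
    # weighted least squares evaluated at t[i]: e1' (X'WX)^-1 X'W
    S[i, ] <- solve(crossprod(X, WX), t(WX))[1, ]
  }
  S
}

#' Discrete-cosine drift basis
#'
#' DCT-II basis columns `cos(pi * (2t + 1) * k / (2T))` for the
#' frequencies `k / (2 * T * TR)` strictly below `cutoff_hz`, `k >= 1`.
#'
#' @param n_volumes Number of timepoints.
#' @param tr Repetition time (s).
#' @param cutoff_hz Cutoff frequency (Hz).
#' @return Matrix with one column per retained basis function, or `NULL`
#'   if none fall below the cutoff.
#' @export
dct_basis <- function(n_volumes, tr, cutoff_hz) {
  k_max <- floor(2 * n_volumes * tr * cutoff_hz)
  if (k_max < 1) return(NULL)
  t <- seq_len(n_volumes) - 1
  X <- vapply(seq_len(k_max),
              function(k) cos(pi * (2 * t + 1) * k / (2 * n_volumes)),
              numeric(n_volumes))
  matrix(X, n_volumes, k_max)
}

#' Regress confound timecourses out of a 4D series
#'
#' Voxelwise least-squares projection removing the span of the confound
#' columns (after centring them, so the voxel temporal mean is retained).
#' Collinear columns are dropped with a warning.
#'
#' @param series A `bold_series`.
#' @param regressors Numeric matrix, volumes x confounds (e.g. the six
#'   motion parameters).
#' @return Residual `bold_series`.
#' @export
regress_confounds <- function(series, regressors) {
  .check_series(series)
  regressors <- as.matrix(regressors)
  nt <- dim(series$data)[4]
  if (nrow(regressors) != nt)
    stop("confound rows must equal the number of volumes")
  X <- scale(regressors, center = TRUE, scale = FALSE)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    warning(sprintf("dropping %d collinear confound column(s)",
                    ncol(X) - qrX$rank))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  }
  if (ncol(X) == 0L || all(abs(X) < 1e-12)) return(series)
  m <- .as_tv(series)
  mu <- colMeans(m)
  resid <- as.matrix(stats::lm.fit(X, sweep(m, 2, mu))$residuals)
  .from_tv(series, sweep(resid, 2, mu, `+`))
}

#' RMS-based motion-outlier detection
#'
#' Computes each volume's root-mean-square intensity difference to the
#' reference volume and flags volumes whose RMS exceeds the boxplot upper
#' fence (75th percentile + `fence * IQR`) of the RMS distribution.
#'
#' @param series A `bold_series`.
#' @param reference_index Reference volume (default 1, never flagged).
#' @param fence IQR multiplier of the boxplot rule (default 1.5).
#' @return List with `flags` (logical per volume), `rms` (per-volume RMS),
#'   and `threshold`.
#' @export
detect_outliers <- function(series, reference_index = 1L, fence = 1.5) {
  .check_series(series)
  d <- dim(series$data)
  if (reference_index < 1 || reference_index > d[4])
    stop("'reference_index' outside the acquisition")
  m <- matrix(series$data, prod(d[1:3]), d[4])
  ref <- m[, reference_index]
  rms <- sqrt(colMeans((m - ref)^2))
  q <- stats::quantile(rms, c(0.25, 0.75), names = FALSE)
  thr <- q[2] + fence * (q[2] - q[1])
  flags <- rms > thr
  flags[reference_index] <- FALSE
  list(flags = flags, rms = rms, threshold = thr)
}

#' Censor trials by head displacement
#'
#' A trial is dropped when any of its volumes has scalar displacement
#' (relative to the reference volume) strictly greater than
#' `threshold_mm`. The default 0.8 mm equals one acquisition voxel.
#'
#' @param motion A [motion_trace()] (or data.frame with a
#'   `displacement_mm` column), one row per volume.
#' @param paradigm A [make_paradigm()] object.
#' @param threshold_mm Displacement threshold in mm (> 0; default 0.8).
#' @return Logical vector, `TRUE` for kept trials.
#' @export
censor_trials <- function(motion, paradigm, threshold_mm = 0.8) {
  stopifnot(is.data.frame(motion), !is.null(motion$displacement_mm),
            inherits(paradigm, "paradigm"))
  if (threshold_mm <= 0) stop("'threshold_mm' must be > 0")
  win <- trial_windows(paradigm)
  if (max(win) > nrow(motion))
    stop("paradigm extends beyond the motion trace")
  apply(win, 1, function(idx)
    all(motion$displacement_mm[idx] <= threshold_mm))
}

#' Run the preprocessing chain
#'
#' Applies, in order: slice-timing correction, the denoising hook,
#' translation-only motion correction (or ingestion of a known motion
#' trace), confound regression of the motion parameters, and high-pass
#' filtering.
#'
#' @param series A `bold_series`.
#' @param known_motion Optional [motion_trace()] from the generator; when
#'   supplied, registration is skipped and these parameters are used for
#'   confound regression and censoring.
#' @param cutoff_hz High-pass cutoff (Hz).
#' @param denoise Denoising hook method.
#' @param slice_timing Apply slice-timing correction.
#' @return List with `series` (preprocessed), `motion` (trace used) and
#'   `outliers` (from [detect_outliers()], computed before filtering).
#' @export
preprocess_bold <- function(series, known_motion = NULL, cutoff_hz = 0.02,
                            denoise = "none", slice_timing = TRUE,
                            hp_method = "gaussian") {
  .check_series(series)
  if (slice_timing) series <- slice_time_correct(series)
  series <- denoise_hook(series, method = denoise)
  if (is.null(known_motion)) {
    reg <- register_translation(series)
    series <- reg$series
    motion <- reg$motion
  } else {
    motion <- known_motion
  }
  outliers <- detect_outliers(series)
  mot_cols <- as.matrix(motion[, c("roll", "pitch", "yaw", "dx", "dy", "dz")])
  if (any(apply(mot_cols, 2, stats::sd) > 0))
    series <- suppressWarnings(regress_confounds(series, mot_cols))
  series <- highpass(series, cutoff_hz, method = hp_method)
  list(series = series, motion = motion, outliers = outliers)
}
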