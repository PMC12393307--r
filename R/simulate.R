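# Forward model: 4D BOLD signal over a cortical ribbon. Grey-matter voxels
# respond with a depth-dependent peak percent signal change scaled by the
# age-group block response; white matter and exterior carry baseline
# intensity only. Drift, Gaussian thermal noise and discrete head-motion
# translations are added on top. Everything the generator used is recorded
# in the ground-truth object so recovery can be tested.

#' Ground-truth record for a simulated dataset
#'
#' @param depth_amplitudes Peak percent signal change at the
#'   superficial/middle/deep depth-bin centres (length-3, in the order
#'   superficial, middle, deep). Neonatal default 3.0/1.5/1.0 %.
#' @param response_model A [make_response_model()] object.
#' @param noise_sd Thermal noise standard deviation, in percent of
#'   baseline signal.
#' @param drift List with `linear` (percent drift over the whole run) and
#'   `cosine` (amplitude in percent of a half-cosine across the run).
#' @param motion_events List of events, each `list(volume =, dx_mm =,
#'   dy_mm =)`: from `volume` onwards the head is displaced by the given
#'   in-plane translation (displacements are absolute w.r.t. volume 1).
#' @param baseline Baseline grey-matter intensity (arbitrary units).
#' @param profile Depth-amplitude profile over volume-normalized depth:
#'   `"step"` (default; each equivolume depth third carries its bin
#'   amplitude, so the per-bin ground truth equals the anchor) or
#'   `"linear"` (piecewise-linear between bin-centre anchors).
#' @param seed Integer seed recorded (and used by [simulate_bold()]).
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(depth_amplitudes = c(3.0, 1.5, 1.0),
                         response_model = make_response_model("preterm"),
                         noise_sd = 0.2,
                         drift = list(linear = 0.5, cosine = 0.3),
                         motion_events = list(),
                         baseline = 1000, profile = c("step", "linear"),
                         seed = 1L) {
  profile <- match.arg(profile)
  stopifnot(length(depth_amplitudes) == 3L, all(is.finite(depth_amplitudes)),
            inherits(response_model, "response_model"),
            noise_sd >= 0, baseline > 0)
  structure(list(depth_amplitudes = depth_amplitudes,
                 response_model = response_model,
                 noise_sd = noise_sd, drift = drift,
                 motion_events = motion_events,
                 baseline = baseline, profile = profile,
                 seed = as.integer(seed)),
            class = "ground_truth")
}

# depth-amplitude profile over volume-normalized depth: "step" assigns each
# equivolume depth third its bin amplitude (the per-bin ground truth is then
# exactly the anchor); "linear" interpolates between the bin-centre anchors
# (normalized depths 1/6, 1/2, 5/6), clamped outside
.depth_amplitude <- function(depth, depth_amplitudes, profile = "step") {
  if (profile == "step") {
    idx <- pmin(pmax(findInterval(depth, c(1, 2) / 3) + 1L, 1L), 3L)
    depth_amplitudes[idx]
  } else {
    stats::approx(c(1, 3, 5) / 6, depth_amplitudes, xout = depth,
                  rule = 2)$y
  }
}

# integer-voxel in-plane translation with edge replication
.shift_volume <- function(vol, dx, dy) {
  if (dx == 0 && dy == 0) return(vol)
  d <- dim(vol)
  ix <- pmin(pmax(seq_len(d[1]) - dx, 1L), d[1])
  iy <- pmin(pmax(seq_len(d[2]) - dy, 1L), d[2])
  vol[ix, iy, , drop = FALSE]
}

#' Simulate a 4D BOLD acquisition over a cortical ribbon
#'
#' Grey-matter signal at volume time t is
#' `baseline * (1 + PSC(depth) * shape(t) / 100)` where `PSC(depth)` is
#' the piecewise-linear interpolation of the ground-truth depth
#' amplitudes at the voxel's normalized depth and `shape` is the run
#' timecourse of the age-group block response. White matter is simulated
#' at 80 % and exterior at 10 % of baseline intensity. Low-frequency
#' drift (linear + half-cosine) and i.i.d. Gaussian noise are added, and
#' motion events translate the sampled grid (nearest-voxel). The
#' generator is deterministic under the ground-truth seed.
#'
#' @param ribbon A [make_ribbon()] object.
#' @param paradigm A [make_paradigm()] object.
#' @param truth A [ground_truth()] object (its `response_model` supplies
#'   the response shape).
#' @return A list with `series` (a `bold_series`: `data` 4D array, `tr`,
#'   `voxel_size`), `truth`, and `motion` (a per-volume motion trace,
#'   see [motion_trace()]).
#' @examples
#' rb <- make_ribbon(c(16, 16, 1), thickness = 2)
#' sim <- simulate_bold(rb, make_paradigm(2), ground_truth(noise_sd = 0))
#' dim(sim$series$data)
#' @export
simulate_bold <- function(ribbon, paradigm, truth = ground_truth()) {
  stopifnot(inherits(ribbon, "cortical_ribbon"), inherits(paradigm, "paradigm"),
            inherits(truth, "ground_truth"))
  lab <- ribbon$label_volume
  d <- dim(lab)
  nt <- paradigm$n_volumes
  times <- paradigm_times(paradigm)

  # static anatomy
  base_vol <- array(truth$baseline * 0.1, d)
  base_vol[lab == LBL_WM] <- truth$baseline * 0.8
  base_vol[lab == LBL_RIBBON] <- truth$baseline

  gm <- which(lab == LBL_RIBBON)
  amp <- .depth_amplitude(ribbon$normalized_depth[gm], truth$depth_amplitudes,
                          truth$profile %||% "step")
  task <- response_timecourse(paradigm, truth$response_model, times)

  # per-volume absolute displacement from motion events
  dxy <- matrix(0, nt, 2)
  for (ev in truth$motion_events) {
    v <- ev$volume
    if (v < 1 || v > nt) stop("motion event volume outside the acquisition")
    dx <- if (is.null(ev$dx_mm)) 0 else ev$dx_mm
    dy <- if (is.null(ev$dy_mm)) 0 else ev$dy_mm
    upto <- if (is.null(ev$until)) nt else min(ev$until, nt)
    dxy[v:upto, 1] <- dx
    dxy[v:upto, 2] <- dy
  }

  drift_lin <- truth$drift$linear
  drift_cos <- truth$drift$cosine
  frac <- if (nt > 1) (seq_len(nt) - 1) / (nt - 1) else 0
  drift_t <- truth$baseline / 100 *
    (drift_lin * frac + drift_cos * cos(pi * frac))

  set.seed(truth$seed)
  data <- array(0, c(d, nt))
  sd_abs <- truth$baseline * truth$noise_sd / 100
  for (j in seq_len(nt)) {
    vol <- base_vol
    vol[gm] <- truth$baseline * (1 + amp * task[j] / 100)
    dx_vox <- as.integer(round(dxy[j, 1] / ribbon$voxel_size[1]))
    dy_vox <- as.integer(round(dxy[j, 2] / ribbon$voxel_size[2]))
    vol <- .shift_volume(vol, dx_vox, dy_vox)
    vol <- vol + drift_t[j]
    if (sd_abs > 0) vol <- vol + array(stats::rnorm(prod(d), 0, sd_abs), d)
    data[, , , j] <- vol
  }

  series <- structure(list(data = data, tr = paradigm$tr,
                           voxel_size = ribbon$voxel_size,
                           slice_order = seq_len(d[3])),
                      class = "bold_series")
  motion <- motion_trace(translations_mm = cbind(dxy, 0))
  list(series = series, truth = truth, motion = motion)
}

#' Per-volume head-motion trace
#'
#' Six motion parameters per volume (roll/pitch/yaw in degrees and x/y/z
#' translation in mm, relative to the reference volume) plus the scalar
#' displacement used for censoring: the Euclidean norm of the three
#' translations (optionally adding rotation displacement at a 50 mm
#' radius).
#'
#' @param translations_mm Numeric matrix, volumes x 3 (mm).
#' @param rotations_deg Numeric matrix, volumes x 3 (degrees); default
#'   zero.
#' @param include_rotation Add `radius_mm * rotation angle (rad)` per axis
#'   to the displacement norm. Off by default.
#' @param radius_mm Head radius for the rotation-to-displacement
#'   conversion.
#' @return An object of class `motion_trace`: data.frame with columns
#'   `roll`, `pitch`, `yaw`, `dx`, `dy`, `dz`, `displacement_mm`.
#' @export
motion_trace <- function(translations_mm, rotations_deg = NULL,
                         include_rotation = FALSE, radius_mm = 50) {
  translations_mm <- as.matrix(translations_mm)
  stopifnot(ncol(translations_mm) == 3L)
  n <- nrow(translations_mm)
  if (is.null(rotations_deg)) rotations_deg <- matrix(0, n, 3)
  rotations_deg <- as.matrix(rotations_deg)
  stopifnot(nrow(rotations_deg) == n, ncol(rotations_deg) == 3L)
  disp <- sqrt(rowSums(translations_mm^2))
  if (include_rotation)
    disp <- disp + radius_mm * rowSums(abs(rotations_deg)) * pi / 180
  out <- data.frame(roll = rotations_deg[, 1], pitch = rotations_deg[, 2],
                    yaw = rotations_deg[, 3],
                    dx = translations_mm[, 1], dy = translations_mm[, 2],
                    dz = translations_mm[, 3],
                    displacement_mm = disp)
  class(out) <- c("motion_trace", "data.frame")
  out
}

#' Simulate depth-binned trial signals directly
#'
#' Lightweight generator for the statistics modules: produces raw trial
#' signal matrices (trials x timepoints x 3 depth bins) as the forward
#' model evaluated at the depth-bin centres plus i.i.d. Gaussian noise,
#' bypassing image space. Useful for calibration and power studies where
#' the full 4D pipeline is not the object under test.
#'
#' @param response A [make_response_model()] object.
#' @param depth_amplitudes Length-3 peak PSC per bin
#'   (superficial, middle, deep).
#' @param n_trials Number of trials.
#' @param noise_sd Noise sd in percent of baseline, applied to the
#'   bin-mean signal.
#' @param tr Repetition time (s); trials span `n_timepoints` TRs.
#' @param n_timepoints Timepoints per trial (default 20 = 10 on + 10 off).
#' @param baseline Baseline intensity.
#' @return Array `n_trials x n_timepoints x 3` of raw signal.
#' @export
simulate_trials <- function(response, depth_amplitudes = c(3.0, 1.5, 1.0),
                            n_trials = 7, noise_sd = 0.2, tr = 2.66,
                            n_timepoints = 20, baseline = 1000) {
  stopifnot(inherits(response, "response_model"), length(depth_amplitudes) == 3L)
  t <- (seq_len(n_timepoints) - 1) * tr
  s <- sample_response(response, t)
  clean <- outer(s, depth_amplitudes)       # timepoints x 3
  out <- array(0, c(n_trials, n_timepoints, 3))
  sd_abs <- baseline * noise_sd / 100
  for (i in seq_len(n_trials)) {
    out[i, , ] <- baseline * (1 + clean / 100) +
      matrix(stats::rnorm(n_timepoints * 3, 0, sd_abs), n_timepoints)
  }
  out
}
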