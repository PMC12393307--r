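# Age-group-specific BOLD response shapes for a single 26.6 s stimulation
# block. Shapes are sums of gamma-shaped components (plus a smoothed plateau
# and a negative post-stimulus component where needed), normalised to unit
# peak. Only the landmark times (onset delay, peak times, undershoot time,
# return to baseline) are constrained by the developmental literature; the
# functional form is a modelling choice.

AGE_GROUPS <- c("preterm", "early_term", "late_term", "adult")

# gamma bump with unit peak: mode at `peak`, rising from `onset`
.gamma_bump <- function(t, onset, peak, shape) {
  x <- t - onset
  sc <- (peak - onset) / (shape - 1)
  g <- ifelse(x > 0, stats::dgamma(x, shape = shape, scale = sc), 0)
  pk <- stats::dgamma(peak - onset, shape = shape, scale = sc)
  if (pk > 0) g / pk else g * 0
}

# smoothed plateau: logistic rise after the first peak, logistic fall after
# stimulus offset
.plateau <- function(t, onset, rise_t, fall_t, rise_tau = 1.5, fall_tau = 2.5) {
  p <- stats::plogis((t - rise_t) / rise_tau) *
    stats::plogis((fall_t - t) / fall_tau)
  p[t < onset] <- 0
  p
}

.default_shape_params <- function(age_group, block_s = 26.6) {
  switch(age_group,
    preterm = list(
      onset = 5, peak_times = c(13, 27), peak_shapes = c(6, 18),
      second_peak_frac = 0.75, plateau_frac = 0, undershoot_frac = 0,
      undershoot_time = NA_real_, return_time = 43, peak_amp = 1),
    early_term = list(
      onset = 4, peak_times = 13, peak_shapes = 6,
      second_peak_frac = 0, plateau_frac = 0.6, undershoot_frac = -0.12,
      undershoot_time = 32, return_time = 45, peak_amp = 1),
    late_term = list(
      onset = 3.5, peak_times = 13, peak_shapes = 6,
      second_peak_frac = 0, plateau_frac = 0.6, undershoot_frac = -0.17,
      undershoot_time = 32, return_time = 45, peak_amp = 1),
    adult = list(
      onset = 1, peak_times = 8, peak_shapes = 5,
      second_peak_frac = 0, plateau_frac = 0.6, undershoot_frac = -0.2,
      undershoot_time = 31, return_time = 42, peak_amp = 1),
    stop(sprintf("unknown age group '%s'", age_group)))
}

#' Age-group-specific block response model
#'
#' Returns the normalised BOLD response shape to one stimulation block for
#' the requested age group, on a fine time grid. Defaults encode the
#' developmental landmarks: preterm responses rise ~5 s after onset with a
#' biphasic profile peaking near 13 s and 27 s and return to baseline by
#' ~43 s; early- and late-term responses show a single 13 s peak followed
#' by a plateau and a small post-stimulus undershoot (deepest, about
#' -0.17 of peak, in the late-term group); adult responses rise within
#' 0--2 s, peak near 8 s, plateau, and undershoot near 32 s.
#'
#' @param age_group One of `"preterm"`, `"early_term"`, `"late_term"`,
#'   `"adult"`.
#' @param shape_params Named list of overrides for the group defaults
#'   (`onset`, `peak_times`, `peak_shapes`, `second_peak_frac`,
#'   `plateau_frac`, `undershoot_frac`, `undershoot_time`, `return_time`,
#'   `peak_amp`).
#' @param block_s Stimulus block duration in seconds.
#' @param duration Length of the modelled response in seconds (default two
#'   block phases, 53.2 s).
#' @param dt Time-grid step in seconds.
#' @return An object of class `response_model`: list with `age_group`,
#'   `time_grid` (s), `amplitude` (unit peak), `shape_params`, `block_s`.
#' @examples
#' rm <- make_response_model("preterm")
#' rm$time_grid[which.max(rm$amplitude)]  # ~13 s
#' @export
make_response_model <- function(age_group, shape_params = list(),
                                block_s = 26.6, duration = 2 * 26.6,
                                dt = 0.05) {
  if (!is.character(age_group) || length(age_group) != 1L ||
      !(age_group %in% AGE_GROUPS))
    stop(sprintf("unknown age group; must be one of %s",
                 paste(AGE_GROUPS, collapse = ", ")))
  p <- utils::modifyList(.default_shape_params(age_group, block_s),
                         shape_params)
  t <- seq(0, duration, by = dt)
  s <- p$peak_amp * .gamma_bump(t, p$onset, p$peak_times[1], p$peak_shapes[1])
  if (length(p$peak_times) > 1L && p$second_peak_frac != 0)
    s <- s + p$peak_amp * p$second_peak_frac *
      .gamma_bump(t, p$onset, p$peak_times[2], p$peak_shapes[2])
  if (p$plateau_frac != 0)
    s <- s + p$peak_amp * p$plateau_frac *
      .plateau(t, p$onset, rise_t = p$peak_times[1] + 5, fall_t = block_s + 1,
               rise_tau = 1, fall_tau = 1.5)
  if (p$undershoot_frac != 0 && is.finite(p$undershoot_time)) {
    # undershoot develops after stimulus offset and resolves by return_time
    s <- s + p$peak_amp * p$undershoot_frac *
      .gamma_bump(t, block_s, p$undershoot_time, 5)
  }
  s[t < p$onset] <- 0
  mx <- max(s)
  if (mx > 0) s <- s / mx
  structure(list(age_group = age_group, time_grid = t, amplitude = s,
                 shape_params = p, block_s = block_s),
            class = "response_model")
}

#' @export
print.response_model <- function(x, ...) {
  cat(sprintf("Response model (%s): peak at %.1f s, min %.2f at %.1f s, %d samples\n",
              x$age_group, x$time_grid[which.max(x$amplitude)],
              min(x$amplitude), x$time_grid[which.min(x$amplitude)],
              length(x$time_grid)))
  invisible(x)
}

#' Sample a response model at arbitrary times
#'
#' Linear interpolation of the block response on its time grid; zero
#' outside the modelled interval.
#'
#' @param response A [make_response_model()] object (or any list with
#'   `time_grid` and `amplitude`).
#' @param times Times in seconds (relative to block onset).
#' @return Response values at `times`.
#' @export
sample_response <- function(response, times) {
  stopifnot(!is.null(response$time_grid), !is.null(response$amplitude))
  out <- stats::approx(response$time_grid, response$amplitude, xout = times,
                       rule = 1)$y
  out[is.na(out)] <- 0
  out
}

#' Superimpose block responses over a paradigm
#'
#' The run-level task timecourse: the block response placed at every
#' stimulus onset (the convolution of the onset impulse train with the
#' block response).
#'
#' @param paradigm A [make_paradigm()] object.
#' @param response A [make_response_model()] object.
#' @param times Optional sample times (defaults to the paradigm's volume
#'   acquisition times).
#' @return Numeric vector of task response values at `times`.
#' @export
response_timecourse <- function(paradigm, response, times = NULL) {
  stopifnot(inherits(paradigm, "paradigm"))
  if (is.null(times)) times <- paradigm_times(paradigm)
  out <- numeric(length(times))
  for (o in paradigm$onsets)
    out <- out + sample_response(response, times - o)
  out
}
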