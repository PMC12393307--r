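#' Block-design stimulation paradigm
#'
#' Builds an on/off block paradigm with a leading rest period: each block
#' of `block_s` seconds of stimulation is followed by `rest_s` seconds of
#' rest, after an initial rest of `rest_s`. With the default 26.6 s
#' blocks at TR 2.66 s each phase spans exactly 10 volumes, so a trial
#' (one block plus the following rest) covers 20 TRs.
#'
#' @param n_blocks Number of stimulation blocks (>= 1).
#' @param block_s Block (stimulus-on) duration in seconds.
#' @param rest_s Rest duration in seconds (also the leading rest).
#' @param tr Repetition time in seconds. Block and rest durations must be
#'   integer multiples of `tr`.
#' @return An object of class `paradigm`: list with `onsets` (s),
#'   `block_duration`, `rest_duration`, `tr`, `n_volumes`.
#' @examples
#' p <- make_paradigm(7)
#' p$n_volumes  # 10 leading-rest volumes + 7 * 20 task volumes
#' @export
make_paradigm <- function(n_blocks, block_s = 26.6, rest_s = 26.6, tr = 2.66) {
  stopifnot(is.numeric(n_blocks), length(n_blocks) == 1L)
  if (n_blocks < 1) stop("'n_blocks' must be >= 1")
  if (block_s <= 0 || rest_s <= 0 || tr <= 0)
    stop("durations and TR must be positive")
  bv <- block_s / tr; rv <- rest_s / tr
  if (abs(bv - round(bv)) > 1e-6 || abs(rv - round(rv)) > 1e-6)
    stop("block and rest durations must be integer multiples of TR")
  onsets <- rest_s + (seq_len(n_blocks) - 1) * (block_s + rest_s)
  n_volumes <- as.integer(round(rv + n_blocks * (bv + rv)))
  structure(list(onsets = onsets, block_duration = block_s,
                 rest_duration = rest_s, tr = tr, n_volumes = n_volumes),
            class = "paradigm")
}

#' @export
print.paradigm <- function(x, ...) {
  cat(sprintf("Paradigm: %d blocks of %g s on / %g s off, TR %g s, %d volumes\n",
              length(x$onsets), x$block_duration, x$rest_duration, x$tr,
              x$n_volumes))
  invisible(x)
}

#' Volume acquisition times of a paradigm
#' @param paradigm A [make_paradigm()] object.
#' @return Times in seconds, one per volume (volume j acquired at (j-1)*TR).
#' @export
paradigm_times <- function(paradigm) {
  stopifnot(inherits(paradigm, "paradigm"))
  (seq_len(paradigm$n_volumes) - 1) * paradigm$tr
}

#' Per-volume stimulus boxcar
#' @param paradigm A [make_paradigm()] object.
#' @return Numeric vector, 1 during stimulation volumes (half-open
#'   \[onset, onset + block) intervals), else 0.
#' @export
paradigm_boxcar <- function(paradigm) {
  t <- paradigm_times(paradigm)
  on <- rep(0, length(t))
  for (o in paradigm$onsets)
    on[t >= o - 1e-9 & t < o + paradigm$block_duration - 1e-9] <- 1
  on
}

#' Trial volume windows
#'
#' Volume indices covering each trial: the stimulus-on block plus the
#' following rest (for the default paradigm, 10 + 10 = 20 TRs).
#'
#' @param paradigm A [make_paradigm()] object.
#' @return Integer matrix, one row per trial, `n_trial_volumes` columns.
#' @export
trial_windows <- function(paradigm) {
  stopifnot(inherits(paradigm, "paradigm"))
  len <- as.integer(round((paradigm$block_duration + paradigm$rest_duration) /
                            paradigm$tr))
  starts <- as.integer(round(paradigm$onsets / paradigm$tr)) + 1L
  t(vapply(starts, function(s) seq.int(s, s + len - 1L), integer(len)))
}
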