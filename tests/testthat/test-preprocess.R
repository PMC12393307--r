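make_series <- function(data, tr = 2.66, vox = c(0.8, 0.8, 0.8)) {
  structure(list(data = data, tr = tr, voxel_size = vox,
                 slice_order = seq_len(dim(data)[3])),
            class = "bold_series")
}

test_that("slice-timing interpolation shifts series to the middle slice time", {
  nt <- 30
  # constant series unchanged
  s <- make_series(array(7, c(2, 2, 5, nt)))
  expect_equal(slice_time_correct(s)$data, s$data)
  # middle slice (3rd of 5, sequential order) unchanged even for ramps
  ramp <- array(0, c(1, 1, 5, nt))
  for (k in 1:5) ramp[1, 1, k, ] <- seq_len(nt) * k
  sr <- make_series(ramp)
  out <- slice_time_correct(sr)
  expect_equal(out$data[1, 1, 3, ], ramp[1, 1, 3, ])
  # linear-in-time voxel: interior values land at t + shift by closed form
  tr <- 2.66
  shift_k5 <- (5 - 3) / 5 * tr       # slice 5 acquired 2/5 TR after middle
  t_vol <- (seq_len(nt) - 1) * tr
  expected <- 5 * (pmin(pmax(t_vol - shift_k5, 0), max(t_vol)) / tr + 1)
  expect_equal(out$data[1, 1, 5, 2:(nt - 1)], expected[2:(nt - 1)])
  expect_error(slice_time_correct(sr, slice_order = c(1, 1, 2, 3, 4)),
               "permutation")
})

test_that("high-pass removes drift and preserves task-band signal and the mean", {
  nt <- 150; tr <- 2.66
  t <- (seq_len(nt) - 1) * tr
  mk <- function(y) make_series(array(rep(y, each = 1), c(1, 1, 1, nt)), tr)
  # constant series unchanged
  expect_equal(highpass(mk(rep(5, nt)))$data[1, 1, 1, ], rep(5, nt))
  # pure linear drift: residual amplitude < 5 % of input
  drift <- 10 * t / max(t)
  hp <- highpass(mk(drift))$data[1, 1, 1, ]
  expect_lt(diff(range(hp)), 0.05 * diff(range(drift)))
  # 0.1 Hz sinusoid (well above cutoff) preserved within 5 % away from the
  # run edges (the local fit has wider transition bands at the boundaries)
  sine <- sin(2 * pi * 0.1 * t)
  hps <- highpass(mk(sine))$data[1, 1, 1, ]
  expect_lt(max(abs(hps - sine)[10:140]), 0.05)
  # the block-design fundamental (0.0188 Hz) survives the 0.02 Hz filter
  block <- sin(2 * pi * t / 53.2)
  hpb <- highpass(mk(block))$data[1, 1, 1, ]
  expect_gt(stats::sd(hpb) / stats::sd(block), 0.9)
  # mean preserved
  y <- drift + sine + 3
  expect_equal(mean(highpass(mk(y))$data), mean(y))
  # approximate idempotence
  once <- highpass(mk(y))
  twice <- highpass(once)
  expect_lt(max(abs(twice$data - once$data)), 0.05 * diff(range(y)))
  expect_error(highpass(mk(y), cutoff_hz = 0.2), "Nyquist")
})

test_that("dct high-pass variant projects out sub-cutoff cosines", {
  nt <- 150; tr <- 2.66
  t <- (seq_len(nt) - 1) * tr
  mk <- function(y) make_series(array(y, c(1, 1, 1, nt)), tr)
  drift <- 4 * t / max(t)
  hp <- highpass(mk(drift), method = "dct")$data[1, 1, 1, ]
  expect_lt(diff(range(hp)), 0.05 * diff(range(drift)))
  X <- dct_basis(nt, tr, 0.02)
  expect_true(all(seq_len(ncol(X)) / (2 * nt * tr) < 0.02 + 1e-12))
  # projection is idempotent
  hp2 <- highpass(highpass(mk(drift), method = "dct"), method = "dct")
  expect_equal(hp2$data, highpass(mk(drift), method = "dct")$data,
               tolerance = 1e-8)
})

test_that("confound regression is an exact projection", {
  nt <- 60
  set.seed(3)
  motion <- stats::rnorm(nt)
  # series equal to a regressor is annihilated (up to its mean)
  s <- make_series(array(rep(motion, each = 4), c(2, 2, 1, nt)))
  out <- regress_confounds(s, cbind(motion))
  expect_lt(stats::sd(out$data[1, 1, 1, ]), 1e-10)
  # series orthogonal to the (centred) regressor unchanged
  sig <- sin(2 * pi * seq_len(nt) / 10)
  mc <- motion - mean(motion)
  sig <- sig - sum(sig * mc) / sum(mc^2) * mc
  s2 <- make_series(array(rep(sig, each = 1), c(1, 1, 1, nt)))
  expect_equal(regress_confounds(s2, cbind(motion))$data, s2$data)
  # signal + 0.7 * motion: recovered signal correlates > 0.99 with truth
  s3 <- make_series(array(sig + 0.7 * motion, c(1, 1, 1, nt)))
  rec <- regress_confounds(s3, cbind(motion))$data[1, 1, 1, ]
  expect_gt(stats::cor(rec, sig), 0.99)
  # projection idempotent
  again <- regress_confounds(regress_confounds(s3, cbind(motion)),
                             cbind(motion))
  expect_equal(again$data, regress_confounds(s3, cbind(motion))$data,
               tolerance = 1e-10)
  # collinear columns dropped with a warning
  expect_warning(regress_confounds(s3, cbind(motion, motion)), "collinear")
})

test_that("RMS outlier detection flags an injected spike and spares the reference", {
  nt <- 40
  set.seed(12)
  data <- array(stats::rnorm(4 * 4 * 2 * nt, 100, 1), c(4, 4, 2, nt))
  s <- make_series(data)
  res0 <- detect_outliers(make_series(array(50, c(2, 2, 1, 10))))
  expect_false(any(res0$flags))            # identical volumes: none flagged
  s$data[, , , 17] <- s$data[, , , 17] + 50
  res <- detect_outliers(s)
  expect_true(res$flags[17])
  expect_equal(which(res$flags), 17L)
  expect_false(res$flags[1])               # reference has RMS 0
  expect_equal(res$rms[1], 0)
})

test_that("trial censoring applies the 0.8 mm rule with strict inequality", {
  p <- make_paradigm(5)
  n <- p$n_volumes
  zero <- motion_trace(matrix(0, n, 3))
  expect_true(all(censor_trials(zero, p)))
  # 1.0 mm displacement during trial 3 only
  win <- trial_windows(p)
  tr3 <- matrix(0, n, 3); tr3[win[3, 5], 1] <- 1.0
  kept <- censor_trials(motion_trace(tr3), p)
  expect_equal(which(!kept), 3L)
  # exactly 0.8 mm is retained
  tr3[win[3, 5], 1] <- 0.8
  expect_true(all(censor_trials(motion_trace(tr3), p)))
  expect_error(censor_trials(zero[1:10, ], p), "beyond the motion trace")
  expect_error(censor_trials(zero, p, threshold_mm = 0), "threshold_mm")
})

test_that("translation registration undoes injected integer-voxel motion", {
  # curved geometry so in-plane shifts are identifiable from image structure
  rb <- fixture_annulus(inner = 3, outer = 5.5, voxel = 0.8, nz = 1L)
  p <- fixture_paradigm(1L)
  truth <- ground_truth(noise_sd = 0.1, drift = list(linear = 0, cosine = 0),
                        motion_events = list(list(volume = 10L, dx_mm = 0.8,
                                                  until = 14L)), seed = 2L)
  sim <- simulate_bold(rb, p, truth)
  reg <- register_translation(sim$series)
  expect_equal(reg$motion$dx[10:14], rep(0.8, 5), tolerance = 1e-9)
  expect_equal(reg$motion$dx[1:9], rep(0, 9))
})
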