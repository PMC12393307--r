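test_that("flat slab ribbon has the constructed geometry", {
  rb <- fixture_slab()
  lab <- rb$label_volume
  # 2 mm thickness at 0.8 mm voxels: 2-3 voxels deep per tangential position
  per_col <- colSums(matrix(lab[, , 1] == 1L, dim(lab)[1]))
  depth_count <- rowSums(matrix(lab[, , 1] == 1L, dim(lab)[1]))
  expect_true(all(depth_count %in% 2:3))
  dep <- rb$normalized_depth[lab == 1L]
  expect_true(all(dep >= 0 & dep < 1))
  expect_error(make_ribbon(c(20, 16, 1), thickness = 0.4),
               "under two voxels")
})

test_that("annulus ribbon area matches the analytic quarter-annulus area", {
  rb <- fixture_annulus(inner = 10, outer = 12, voxel = 0.4, nz = 1L)
  n_gm <- sum(rb$label_volume == 1L)
  area_vox <- n_gm * 0.4^2
  area_true <- pi * (12^2 - 10^2) / 4
  expect_lt(abs(area_vox - area_true) / area_true, 0.05)
})

test_that("distance-transform depth agrees with the analytic annulus depth", {
  rb <- fixture_annulus(inner = 4, outer = 6, voxel = 0.2, nz = 1L)
  gm <- rb$label_volume == 1L
  dep_dt <- depth_from_labels(rb$label_volume)
  # compare as geometric depth: analytic geometric depth = (b - r)/(b - a)
  d <- dim(rb$label_volume)
  xc <- (seq_len(d[1]) - 0.5) * 0.2
  yc <- (seq_len(d[2]) - 0.5) * 0.2
  rr <- sqrt(outer(xc^2, yc^2, `+`))
  geo <- array((6 - rr) / 2, d)
  err <- abs(dep_dt[gm] - geo[gm])
  # interior voxels within ~half a voxel of the analytic depth scale
  expect_lt(stats::median(err), 0.2 / 2 / 2)
  # monotone in radius: rank correlation with analytic depth near 1
  expect_gt(stats::cor(dep_dt[gm], geo[gm], method = "spearman"), 0.98)
})

test_that("paradigm phases span exactly 10 volumes at the default timing", {
  p <- make_paradigm(7)
  expect_equal(p$block_duration / p$tr, 10)
  expect_equal(p$rest_duration / p$tr, 10)
  expect_equal(p$n_volumes, 10 + 7 * 20)
  expect_equal(p$onsets[1], 26.6)
  expect_equal(diff(p$onsets), rep(53.2, 6))
  expect_equal(make_paradigm(1)$n_volumes, 30)
  # 12-block maximum: 240 task volumes plus the leading rest
  expect_equal(make_paradigm(12)$n_volumes, 240 + 10)
  expect_error(make_paradigm(0), "n_blocks")
  expect_error(make_paradigm(3, block_s = -1), "positive")
  expect_error(make_paradigm(3, block_s = 27), "integer multiples")
})

test_that("response models reproduce the developmental landmarks", {
  pre <- make_response_model("preterm")
  t <- pre$time_grid; s <- pre$amplitude
  expect_equal(max(s), 1)
  expect_true(all(s[t < pre$shape_params$onset] == 0))
  expect_lt(abs(t[which.max(s)] - 13), 1)
  # second, later peak: a local maximum near 27 s
  locmax <- t[which(diff(sign(diff(s))) == -2) + 1]
  expect_true(any(abs(locmax - 27) <= 2))
  # return to baseline by ~43 s
  expect_lt(abs(s[which.min(abs(t - 43))]), 0.05)

  ad <- make_response_model("adult")
  ta <- ad$time_grid; sa <- ad$amplitude
  expect_lt(abs(ta[which.max(sa)] - 8), 1)
  post <- ta > ad$block_s
  expect_lt(abs(ta[post][which.min(sa[post])] - 32), 2)
  expect_lt(min(sa), 0)  # post-stimulus undershoot present

  for (g in c("early_term", "late_term")) {
    r <- make_response_model(g)
    expect_lt(abs(r$time_grid[which.max(r$amplitude)] - 13), 1)
    expect_lt(min(r$amplitude), 0)
  }
  # late-term undershoot deeper than early-term
  expect_lt(min(make_response_model("late_term")$amplitude),
            min(make_response_model("early_term")$amplitude))

  flat <- make_response_model("preterm", shape_params = list(peak_amp = 0))
  expect_true(all(flat$amplitude == 0))
  expect_error(make_response_model("toddler"), "unknown age group")
})

test_that("zero-noise simulation recovers the depth amplitudes exactly", {
  rb <- fixture_annulus(inner = 2, outer = 4, voxel = 0.2, nz = 1L)
  p <- fixture_paradigm(2L)
  tr_mod <- make_response_model("preterm")
  truth <- ground_truth(depth_amplitudes = c(3.0, 1.5, 1.0),
                        response_model = tr_mod, noise_sd = 0,
                        drift = list(linear = 0, cosine = 0))
  sim <- simulate_bold(rb, p, truth)
  bins <- equivolume_bins(rb, 3)
  trials <- extract_trials(sim$series, p, bins)
  psc <- trials_to_psc(trials, "neonate")
  peaks <- apply(psc, 3, max)
  # forward model is exact at zero noise up to the response sampled at TR
  s_pk <- max(sample_response(tr_mod, (0:19) * 2.66))
  expect_equal(peaks, c(3.0, 1.5, 1.0) * s_pk, tolerance = 0.02)
})

test_that("simulation is deterministic under seed and decorrelated across seeds", {
  rb <- fixture_slab(1L)
  p <- fixture_paradigm(1L)
  a <- simulate_bold(rb, p, ground_truth(seed = 5L))
  b <- simulate_bold(rb, p, ground_truth(seed = 5L))
  expect_identical(a$series$data, b$series$data)
  c2 <- simulate_bold(rb, p, ground_truth(seed = 6L))
  clean <- simulate_bold(rb, p, ground_truth(seed = 5L, noise_sd = 0))
  noise_a <- as.vector(a$series$data - clean$series$data)
  noise_c <- as.vector(c2$series$data - clean$series$data)
  expect_lt(abs(stats::cor(noise_a, noise_c)), 0.05)
})

test_that("noise-only runs are stationary after drift removal", {
  rb <- fixture_slab(1L)
  p <- fixture_paradigm(3L)
  truth <- ground_truth(depth_amplitudes = c(0, 0, 0), noise_sd = 0.5,
                        drift = list(linear = 2, cosine = 1), seed = 9L)
  sim <- simulate_bold(rb, p, truth)
  filt <- highpass(sim$series, 0.02)
  gm_mean <- apply(filt$data, 4, function(v) mean(v[rb$label_volume == 1L]))
  # no remaining trend: regression slope indistinguishable from zero
  tt <- seq_along(gm_mean)
  fit <- stats::lm(gm_mean ~ tt)
  expect_gt(summary(fit)$coefficients[2, 4], 0.01)
})

test_that("motion events displace the sampled grid and are recorded", {
  rb <- fixture_slab(1L)
  p <- fixture_paradigm(1L)
  # displacement along the depth axis, where the slab has structure
  truth <- ground_truth(noise_sd = 0, drift = list(linear = 0, cosine = 0),
                        motion_events = list(list(volume = 5L, dy_mm = 1.6,
                                                  until = 8L)))
  sim <- simulate_bold(rb, p, truth)
  expect_equal(sim$motion$displacement_mm[5:8], rep(1.6, 4))
  expect_equal(sim$motion$displacement_mm[1:4], rep(0, 4))
  expect_false(identical(sim$series$data[, , , 5], sim$series$data[, , , 4]))
  # shifted volume equals the unshifted one displaced by 2 voxels
  expect_equal(sim$series$data[, 3:16, , 5], sim$series$data[, 1:14, , 4])
})
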