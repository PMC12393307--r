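test_that("upsampling preserves labels as blocks and intensities as constants", {
  lab <- array(sample(0:2, 6 * 4 * 1, replace = TRUE), c(6, 4, 1))
  up <- upsample_volume(lab, c(0.8, 0.8, 0.8), c(0.16, 0.16, 0.8), "nearest")
  expect_equal(dim(up), c(30, 20, 1))
  # each source voxel becomes a 5x5 block
  expect_equal(up[cbind(rep(1:30, 20), rep(1:20, each = 30), 1)],
               lab[cbind(rep(ceiling(1:30 / 5), 20),
                         rep(ceiling(1:20 / 5), each = 30), 1)])
  # label area ratios preserved exactly (checkerboard included)
  chk <- array(0L, c(4, 4, 1)); chk[, , 1] <- (outer(1:4, 1:4, `+`) %% 2)
  upc <- upsample_volume(chk, c(0.8, 0.8, 0.8), c(0.16, 0.16, 0.8), "nearest")
  expect_equal(mean(upc), mean(chk))
  # constant intensity stays constant under linear interpolation
  con <- array(3.7, c(5, 5, 2))
  expect_true(all(upsample_volume(con, c(0.8, 0.8, 0.8),
                                  c(0.16, 0.16, 0.8)) == 3.7))
  # a linear ramp stays linear (interior)
  ramp <- array(rep(1:8, times = 4), c(8, 4, 1))
  upr <- upsample_volume(ramp, c(0.8, 0.8, 0.8), c(0.4, 0.4, 0.8), "linear")
  expect_equal(diff(upr[3:14, 1, 1]), rep(0.5, 11))
  expect_error(upsample_volume(con, c(0.8, 0.8, 0.8), c(0.3, 0.3, 0.8)),
               "integer factor")
  expect_error(upsample_volume(con, c(0.8, 0.8, 0.8), c(-1, 0.16, 0.8)),
               "positive")
})

test_that("equivolume bins are equal-thickness thirds on a flat slab", {
  rb <- make_ribbon(c(30, 40, 1), voxel_size = c(0.2, 0.2, 0.8),
                    thickness = 3)
  bins <- equivolume_bins(rb, 3)
  lab <- bins$bin_volume[, , 1]
  dep <- rb$normalized_depth[, , 1]
  for (b in 1:3) {
    dd <- dep[!is.na(lab) & lab == b]
    expect_lt(max(dd) - min(dd), 1 / 3 + 0.2 / 3)
  }
  # bin volumes equal within one voxel row
  counts <- table(lab)
  expect_lt(diff(range(counts)), 30 + 1)
  # single bin is the identity
  one <- equivolume_bins(rb, 1)
  expect_equal(sum(one$bin_volume == 1, na.rm = TRUE),
               sum(rb$label_volume == 1))
})

test_that("equivolume boundaries on an annulus match the closed form", {
  # randomised analytic annuli: discrete boundaries vs equal-area radii
  set.seed(17)
  for (i in 1:5) {
    a <- runif(1, 1.5, 3); b <- a + runif(1, 0.8, 1.5)
    n_bins <- sample(2:4, 1)
    vox <- 0.16
    n <- ceiling((b + 2 * vox) / vox)
    rb <- make_ribbon(c(n, n, 1), voxel_size = c(vox, vox, 0.8),
                      geometry = "annulus", inner = a, outer = b)
    bins <- equivolume_bins(rb, n_bins)
    d <- dim(rb$label_volume)
    xc <- (seq_len(d[1]) - 0.5) * vox
    yc <- (seq_len(d[2]) - 0.5) * vox
    rr <- sqrt(outer(xc^2, yc^2, `+`))
    for (k in seq_len(n_bins - 1)) {
      r_true <- sqrt(b^2 - k * (b^2 - a^2) / n_bins)  # outer bin = bin 1
      inner_bin <- bins$bin_volume[, , 1] == k
      r_min_k <- min(rr[which(inner_bin)])
      expect_lt(abs(r_min_k - r_true), vox)
    }
  }
})

test_that("column segmentation partitions the ROI into equal tangential spans", {
  rb <- fixture_annulus(inner = 4, outer = 6, voxel = 0.2, nz = 1L)
  cols <- segment_columns(rb, 7)
  cl <- cols$column_volume[, , 1]
  expect_equal(sort(unique(cl[!is.na(cl)])), 1:7)
  # each angular sector spans ~90/7 degrees
  tg <- rb$tangential[, , 1]
  for (cc in 1:7) {
    span <- range(tg[!is.na(cl) & cl == cc])
    expect_lt(diff(span), 90 / 7 + 2)
  }
  # every column crosses all depth bins
  bins <- equivolume_bins(rb, 3)
  bl <- bins$bin_volume[, , 1]
  for (cc in 1:7)
    expect_setequal(unique(bl[!is.na(cl) & cl == cc]), 1:3)
  # single column is the whole slice ROI
  c1 <- segment_columns(rb, 1)
  expect_equal(sum(c1$column_volume == 1, na.rm = TRUE),
               sum(rb$label_volume == 1))
})

test_that("21 tangential positions split deterministically into 7 columns of 3", {
  rb <- make_ribbon(c(21, 8, 1), voxel_size = c(0.8, 0.8, 0.8), thickness = 2)
  cols <- segment_columns(rb, 7)
  cl <- cols$column_volume[, , 1]
  per_col <- table(apply(cl, 1, function(r) unique(r[!is.na(r)])))
  expect_equal(unname(c(per_col)), rep(3L, 7))
  expect_error(segment_columns(rb, 30), "tangential extent")
})

test_that("column selection keeps the top centile by deep-bin signal with ties", {
  # curved ribbon: depth varies continuously so every column holds all bins
  rb <- fixture_annulus(inner = 4, outer = 6, voxel = 0.2, nz = 1L)
  bins <- equivolume_bins(rb, 3)
  cols <- segment_columns(rb, 7)
  # paint a psc map whose deep-bin column means are 0.1 ... 0.7
  psc <- array(0, dim(rb$label_volume))
  cl <- cols$column_volume
  for (cc in 1:7) psc[!is.na(cl) & cl == cc] <- cc / 10
  sel <- select_columns(psc, bins, cols, centile = 40)
  expect_equal(which(sel$kept), 5:7)          # ceiling(0.4 * 7) = 3 columns
  expect_equal(sum(sel$kept), 3L)
  # selected ROI spans all depth bins
  expect_setequal(unique(bins$bin_volume[sel$mask]), 1:3)
  # ties at the threshold kept: equal map keeps everything
  sel_eq <- select_columns(array(1, dim(psc)), bins, cols, centile = 40)
  expect_true(all(sel_eq$kept))
  # centile 100 keeps everything
  expect_true(all(select_columns(psc, bins, cols, centile = 100)$kept))
  # invariance under monotone rescaling
  sel2 <- select_columns(exp(2 * psc), bins, cols, centile = 40)
  expect_equal(sel2$kept, sel$kept)
  expect_error(select_columns(psc, bins, cols, centile = 0), "centile")
})
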