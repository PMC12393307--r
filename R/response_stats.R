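# Depth-resolved trial statistics: extraction of per-trial depth-bin
# timeseries, percent-signal-change baseline conventions, group trial
# averages, maximum-PSC depth ratios, and the rank-based group comparison
# (Kruskal-Wallis with Dunn post-hoc tests, Bonferroni-adjusted).

#' Extract per-trial depth-bin timeseries
#'
#' For every trial (stimulus block plus the following rest), averages the
#' raw signal over each depth bin's final-ROI voxels at each of the
#' trial's TRs.
#'
#' @param series A `bold_series` on the same grid as the labels.
#' @param paradigm A [make_paradigm()] object.
#' @param depth_labels A [equivolume_bins()] object.
#' @param roi Logical array: the final ROI (e.g. from
#'   [select_columns()]); default: all labelled voxels.
#' @return Array `trials x timepoints x n_bins` of raw signal (class
#'   `trial_matrix`, with attribute `tr`).
#' @export
extract_trials <- function(series, paradigm, depth_labels, roi = NULL) {
  .check_series(series)
  stopifnot(inherits(paradigm, "paradigm"),
            inherits(depth_labels, "depth_bin_labels"))
  bin <- depth_labels$bin_volume
  stopifnot(identical(dim(series$data)[1:3], dim(bin)))
  if (is.null(roi)) roi <- !is.na(bin)
  win <- trial_windows(paradigm)
  if (max(win) > dim(series$data)[4])
    stop("paradigm extends beyond the series")
  nb <- depth_labels$n_bins
  idx_by_bin <- lapply(seq_len(nb), function(b) which(roi & !is.na(bin) & bin == b))
  if (any(vapply(idx_by_bin, length, integer(1)) == 0L))
    stop("a depth bin has no ROI voxels")
  nvox <- prod(dim(series$data)[1:3])
  out <- array(NA_real_, c(nrow(win), ncol(win), nb))
  for (i in seq_len(nrow(win))) for (j in seq_len(ncol(win))) {
    voladdr <- (win[i, j] - 1L) * nvox
    for (b in seq_len(nb))
      out[i, j, b] <- mean(series$data[voladdr + idx_by_bin[[b]]])
  }
  structure(out, tr = paradigm$tr, class = c("trial_matrix", "array"))
}

#' Percent signal change with age-specific baseline conventions
#'
#' Converts a raw trial timeseries (20 timepoints for the default
#' paradigm) to percent signal change. The neonate convention takes the
#' baseline as the mean of the first stimulus-on TR and the last
#' stimulus-off TR of the trial; the adult convention uses the mean of
#' the last two stimulus-off TRs. A `"prestim"` mode (mean of the first
#' TR only, which precedes any response under a delayed-onset shape) is
#' provided for sensitivity analysis.
#'
#' @param trial_row Numeric vector of raw signal over one trial.
#' @param mode `"neonate"`, `"adult"`, or `"prestim"`.
#' @return Percent-signal-change vector of the same length.
#' @export
baseline_psc <- function(trial_row, mode = c("neonate", "adult", "prestim")) {
  mode <- match.arg(mode)
  n <- length(trial_row)
  stopifnot(n >= 2L)
  base <- switch(mode,
                 neonate = mean(trial_row[c(1L, n)]),
                 adult = mean(trial_row[c(n - 1L, n)]),
                 prestim = trial_row[1L])
  if (!is.finite(base) || base <= 0) stop("non-positive baseline")
  100 * (trial_row - base) / base
}

#' Convert a trial matrix to percent signal change
#'
#' Applies [baseline_psc()] to every trial and depth bin.
#'
#' @param trials A `trial_matrix` (trials x timepoints x bins) of raw
#'   signal.
#' @param mode Baseline convention, see [baseline_psc()].
#' @return A `trial_matrix` in percent-signal-change units.
#' @export
trials_to_psc <- function(trials, mode = "neonate") {
  stopifnot(length(dim(trials)) == 3L)
  out <- trials
  for (i in seq_len(dim(trials)[1])) for (b in seq_len(dim(trials)[3]))
    out[i, , b] <- baseline_psc(trials[i, , b], mode)
  out
}

#' Group trial-average response
#'
#' Pointwise mean and standard error of the mean over kept trials, per
#' timepoint and depth bin, within each group.
#'
#' @param trials A `trial_matrix` (in PSC units), trials x timepoints x
#'   bins.
#' @param group Character/factor label per trial (default: one group).
#' @param kept Logical per trial (default: all kept).
#' @param tr Repetition time used for the time column (defaults to the
#'   matrix attribute, else 2.66).
#' @return A data.frame with columns `group`, `time_s`, `depth_bin`,
#'   `mean`, `sem`, `n`.
#' @export
trial_average <- function(trials, group = NULL, kept = NULL, tr = NULL) {
  stopifnot(length(dim(trials)) == 3L)
  nt <- dim(trials)[1]
  group <- group %||% rep("all", nt)
  kept <- kept %||% rep(TRUE, nt)
  tr <- tr %||% (attr(trials, "tr") %||% 2.66)
  stopifnot(length(group) == nt, length(kept) == nt)
  res <- list()
  for (g in unique(group)) {
    sel <- which(group == g & kept)
    if (length(sel) == 0L) {
      warning(sprintf("group '%s' has no kept trials; omitted", g))
      next
    }
    sub <- trials[sel, , , drop = FALSE]
    mu <- apply(sub, c(2, 3), mean)
    sem <- apply(sub, c(2, 3), function(x)
      if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0)
    res[[length(res) + 1L]] <- data.frame(
      group = g,
      time_s = rep((seq_len(dim(trials)[2]) - 1) * tr, dim(trials)[3]),
      depth_bin = rep(seq_len(dim(trials)[3]), each = dim(trials)[2]),
      mean = as.vector(mu), sem = as.vector(sem), n = length(sel))
  }
  do.call(rbind, res)
}

#' Per-trial maximum-PSC depth ratios
#'
#' For each kept trial, takes the maximum percent signal change over the
#' trial's timepoints in each depth bin (model-free peak estimate) and
#' forms the three pairwise ratios superficial:middle, superficial:deep
#' and middle:deep. Ratios with a non-positive denominator are `NA` and
#' flagged.
#'
#' @param trials A `trial_matrix` in PSC units with 3 depth bins (bin 1
#'   superficial, 3 deep).
#' @param group Label per trial.
#' @param kept Logical per trial.
#' @return A data.frame of class `depth_ratio_table`: one row per kept
#'   trial with `max_superficial`, `max_middle`, `max_deep`,
#'   `sup_mid`, `sup_deep`, `mid_deep`, `group`, `defined`.
#' @export
depth_ratios <- function(trials, group = NULL, kept = NULL) {
  stopifnot(length(dim(trials)) == 3L, dim(trials)[3] == 3L)
  nt <- dim(trials)[1]
  group <- group %||% rep("all", nt)
  kept <- kept %||% rep(TRUE, nt)
  sel <- which(kept)
  mx <- t(vapply(sel, function(i) apply(trials[i, , ], 2, max), numeric(3)))
  ratio <- function(a, b) ifelse(b > 0, a / b, NA_real_)
  out <- data.frame(max_superficial = mx[, 1], max_middle = mx[, 2],
                    max_deep = mx[, 3],
                    sup_mid = ratio(mx[, 1], mx[, 2]),
                    sup_deep = ratio(mx[, 1], mx[, 3]),
                    mid_deep = ratio(mx[, 2], mx[, 3]),
                    group = group[sel])
  out$defined <- !is.na(out$sup_mid) & !is.na(out$sup_deep) &
    !is.na(out$mid_deep)
  class(out) <- c("depth_ratio_table", "data.frame")
  out
}

#' Kruskal-Wallis test with Dunn post-hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square p-value on k - 1
#' degrees of freedom (via [stats::kruskal.test()]), followed by Dunn's
#' pairwise z tests on the mean ranks with the tie-corrected variance and
#' Bonferroni adjustment (each pairwise p multiplied by the number of
#' pairs, capped at 1).
#'
#' @param values Numeric vector of observations.
#' @param group Group label per observation (>= 2 non-empty groups).
#' @return An object of class `rank_test_result`: list with `H`, `df`,
#'   `p`, `pairwise` (data.frame: group1, group2, z, p, p_adj) and
#'   `n_pairs`.
#' @examples
#' kruskal_dunn(c(1, 2, 3, 4, 5, 6), rep(c("a", "b", "c"), each = 2))
#' @export
kruskal_dunn <- function(values, group) {
  ok <- is.finite(values)
  values <- values[ok]; group <- factor(group[ok])
  if (nlevels(group) < 2L || any(table(group) == 0L))
    stop("need at least two non-empty groups")
  if (length(unique(values)) == 1L) {
    # degenerate: a single tied value carries no rank information
    lv <- levels(group)
    pairs <- utils::combn(lv, 2)
    pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                     z = 0, p = 1, p_adj = 1)
    return(structure(list(H = 0, df = nlevels(group) - 1L, p = 1,
                          pairwise = pw, n_pairs = ncol(pairs)),
                     class = "rank_test_result"))
  }
  kw <- stats::kruskal.test(values, group)
  N <- length(values)
  rk <- rank(values)
  mean_rank <- tapply(rk, group, mean)
  n_g <- tapply(rk, group, length)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  lv <- levels(group)
  pairs <- utils::combn(lv, 2)
  n_pairs <- ncol(pairs)
  pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                   z = NA_real_, p = NA_real_, p_adj = NA_real_)
  for (j in seq_len(n_pairs)) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n_g[g1] + 1 / n_g[g2]))
    z <- (mean_rank[g1] - mean_rank[g2]) / se
    p <- 2 * stats::pnorm(-abs(z))
    pw$z[j] <- z
    pw$p[j] <- p
    pw$p_adj[j] <- min(1, p * n_pairs)
  }
  structure(list(H = unname(kw$statistic), df = unname(kw$parameter),
                 p = kw$p.value, pairwise = pw, n_pairs = n_pairs),
            class = "rank_test_result")
}

#' @export
print.rank_test_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H(%d) = %.2f, p = %.3g\n", x$df, x$H, x$p))
  cat("Dunn post-hoc (Bonferroni-adjusted):\n")
  print(format(x$pairwise, digits = 3), row.names = FALSE)
  invisible(x)
}
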