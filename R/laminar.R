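# Cortical-depth machinery: in-plane upsampling, equivolume depth binning,
# tangential column segmentation, and deep-depth-driven column selection.
# Depth bin 1 is the most superficial (pial side); the deepest bin borders
# the white matter.

#' In-plane upsampling of a volume
#'
#' Resamples a 3D volume (or one volume of a 4D series) to a finer
#' in-plane grid whose voxel size divides the source size by an integer
#' factor. Label volumes use nearest-neighbour (block replication, so
#' area ratios are preserved exactly); intensity volumes use separable
#' linear interpolation at the target voxel centres with edge clamping.
#'
#' @param volume 3D numeric array.
#' @param voxel_size Source voxel sizes, mm (length 3).
#' @param target_voxel Target voxel sizes, mm (length 3); the third axis
#'   is typically left unchanged (e.g. 0.8 -> 0.16 x 0.16 x 0.8).
#' @param method `"linear"` or `"nearest"`.
#' @return The upsampled array.
#' @export
upsample_volume <- function(volume, voxel_size, target_voxel,
                            method = c("linear", "nearest")) {
  method <- match.arg(method)
  stopifnot(is.array(volume), length(dim(volume)) == 3L,
            length(voxel_size) == 3L, length(target_voxel) == 3L)
  if (any(target_voxel <= 0)) stop("'target_voxel' must be positive")
  f <- voxel_size / target_voxel
  if (any(abs(f - round(f)) > 1e-6) || any(f < 1 - 1e-9))
    stop("target voxel size must divide the source size by an integer factor")
  f <- as.integer(round(f))
  d <- dim(volume)
  dn <- d * f
  if (method == "nearest") {
    out <- volume[rep(seq_len(d[1]), each = f[1]),
                  rep(seq_len(d[2]), each = f[2]),
                  rep(seq_len(d[3]), each = f[3]), drop = FALSE]
    dim(out) <- dn
    return(out)
  }
  # linear: fractional source-index coordinate of each target centre,
  # clamped to the source centre range
  idx <- function(n_new, fk) {
    pos <- ((seq_len(n_new) - 0.5) / fk) + 0.5
    pmin(pmax(pos, 1), n_new / fk)
  }
  interp_axis <- function(arr, axis, fk) {
    if (fk == 1L) return(arr)
    da <- dim(arr)
    pos <- idx(da[axis] * fk, fk)
    lo <- pmax(floor(pos), 1); hi <- pmin(lo + 1, da[axis])
    w <- pos - lo
    pick <- function(i) {
      ind <- rep(list(quote(expr = )), 3); ind[[axis]] <- i
      do.call(`[`, c(list(arr), ind, list(drop = FALSE)))
    }
    a_lo <- pick(lo); a_hi <- pick(hi)
    if (axis == 1L) W <- array(w, dim(a_lo))
    if (axis == 2L) W <- aperm(array(w, dim(a_lo)[c(2, 1, 3)]), c(2, 1, 3))
    if (axis == 3L) W <- aperm(array(w, dim(a_lo)[c(3, 1, 2)]), c(2, 3, 1))
    a_lo * (1 - W) + a_hi * W
  }
  out <- volume
  for (ax in 1:3) out <- interp_axis(out, ax, f[ax])
  out
}

#' Refine a cortical ribbon to a finer grid
#'
#' Labels are regenerated from the ribbon's analytic boundary
#' descriptors at the target resolution (mirroring manual ROI refinement
#' after resampling); when no analytic geometry is stored, labels are
#' nearest-neighbour upsampled and the depth field recomputed with
#' [depth_from_labels()].
#'
#' @param ribbon A [make_ribbon()] object.
#' @param target_voxel Target voxel sizes, mm.
#' @return A refined `cortical_ribbon`.
#' @export
upsample_ribbon <- function(ribbon, target_voxel = c(0.16, 0.16, 0.8)) {
  stopifnot(inherits(ribbon, "cortical_ribbon"))
  f <- ribbon$voxel_size / target_voxel
  if (any(abs(f - round(f)) > 1e-6))
    stop("target voxel size must divide the source size by an integer factor")
  f <- as.integer(round(f))
  shape <- dim(ribbon$label_volume) * f
  gp <- ribbon$geometry_params
  if (identical(gp$type, "flat")) {
    make_ribbon(shape, target_voxel, thickness = ribbon$thickness,
                geometry = "flat", margin = gp$pial_y)
  } else if (identical(gp$type, "annulus")) {
    make_ribbon(shape, target_voxel, geometry = "annulus",
                inner = gp$inner, outer = gp$outer)
  } else {
    lab <- upsample_volume(ribbon$label_volume, ribbon$voxel_size,
                           target_voxel, method = "nearest")
    dep <- depth_from_labels(lab)
    structure(list(label_volume = lab, voxel_size = target_voxel,
                   thickness = ribbon$thickness, geometry_params = gp,
                   normalized_depth = dep, tangential = NULL),
              class = "cortical_ribbon")
  }
}

#' Equivolume depth bins
#'
#' Partitions the ribbon ROI into `n_bins` cortical depth bins of equal
#' volume per slice: ROI voxels are sorted by normalized depth and split
#' into equal voxel-count groups (voxel count times voxel volume = bin
#' volume). On curved geometry this reproduces the equivolume principle
#' (each bin occupies the same tissue volume despite unequal thickness);
#' on a flat slab it reduces to equal-thickness bins.
#'
#' @param ribbon A [make_ribbon()] object.
#' @param n_bins Number of depth bins (default 3; bin 1 = most
#'   superficial).
#' @param roi Optional logical array restricting the ROI (default: the
#'   whole grey-matter ribbon).
#' @param depth Optional depth array overriding the ribbon's
#'   `normalized_depth` (e.g. from [depth_from_labels()]).
#' @return An object of class `depth_bin_labels`: list with `bin_volume`
#'   (integer array, `NA` outside the ROI), `n_bins`, `normalized_depth`,
#'   and `boundaries` (per-slice depth thresholds between bins).
#' @export
equivolume_bins <- function(ribbon, n_bins = 3L, roi = NULL, depth = NULL) {
  stopifnot(inherits(ribbon, "cortical_ribbon"), n_bins >= 1L)
  lab <- ribbon$label_volume
  dep <- depth %||% ribbon$normalized_depth
  if (is.null(roi)) roi <- lab == LBL_RIBBON
  stopifnot(identical(dim(roi), dim(lab)))
  bin <- array(NA_integer_, dim(lab))
  nz <- dim(lab)[3]
  boundaries <- vector("list", nz)
  for (k in seq_len(nz)) {
    sel <- which(roi[, , k] & lab[, , k] == LBL_RIBBON)
    if (length(sel) == 0L) next
    dk <- dep[, , k][sel]
    if (anyNA(dk)) stop("ROI voxels without a depth value")
    ord <- order(dk)
    n <- length(sel)
    cuts <- round(seq_len(n_bins - 1L) * n / n_bins)
    ids <- integer(n)
    ids[ord] <- findInterval(seq_len(n) - 0.5, cuts) + 1L
    slice_bin <- matrix(NA_integer_, dim(lab)[1], dim(lab)[2])
    slice_bin[sel] <- ids
    bin[, , k] <- slice_bin
    boundaries[[k]] <- if (n_bins > 1L)
      vapply(cuts, function(cc) mean(dk[ord][c(cc, min(cc + 1L, n))]),
             numeric(1)) else numeric(0)
  }
  if (all(is.na(bin))) stop("empty ROI: no ribbon voxels selected")
  structure(list(bin_volume = bin, n_bins = as.integer(n_bins),
                 normalized_depth = dep, boundaries = boundaries),
            class = "depth_bin_labels")
}

#' Tangential column segmentation
#'
#' Splits each slice's ROI into `n_columns` contiguous columns of equal
#' tangential extent (equal spans of the ribbon's tangential boundary
#' coordinate: the x position for a flat slab, the angle for an annulus),
#' so each column crosses all depth bins.
#'
#' @param ribbon A [make_ribbon()] object with analytic geometry.
#' @param n_columns Columns per slice (default 7).
#' @param roi Optional logical array restricting the ROI.
#' @return An object of class `column_labels`: list with `column_volume`
#'   (integer array, `NA` outside the ROI) and `n_columns`.
#' @export
segment_columns <- function(ribbon, n_columns = 7L, roi = NULL) {
  stopifnot(inherits(ribbon, "cortical_ribbon"), n_columns >= 1L)
  if (is.null(ribbon$tangential))
    stop("ribbon has no tangential coordinate; analytic geometry required")
  lab <- ribbon$label_volume
  if (is.null(roi)) roi <- lab == LBL_RIBBON
  col <- array(NA_integer_, dim(lab))
  nz <- dim(lab)[3]
  for (k in seq_len(nz)) {
    sel <- which(roi[, , k] & lab[, , k] == LBL_RIBBON)
    if (length(sel) == 0L) next
    tg <- ribbon$tangential[, , k][sel]
    if (length(unique(tg)) < n_columns)
      stop("ROI tangential extent is smaller than the number of columns")
    rng <- range(tg)
    breaks <- seq(rng[1], rng[2], length.out = n_columns + 1L)
    ids <- findInterval(tg, breaks, rightmost.closed = TRUE)
    ids <- pmin(pmax(ids, 1L), n_columns)
    slice_col <- matrix(NA_integer_, dim(lab)[1], dim(lab)[2])
    slice_col[sel] <- ids
    col[, , k] <- slice_col
  }
  structure(list(column_volume = col, n_columns = as.integer(n_columns)),
            class = "column_labels")
}

#' Select columns by deep-depth percent signal change
#'
#' For every column (per slice), averages the percent-signal-change map
#' over the column's deepest-bin voxels; columns in the top `centile`
#' percent of that distribution (k = ceiling(centile/100 * n columns),
#' ties at the threshold kept) form the final ROI, taken across all
#' depth bins. Ranking on the deep bin counteracts the superficial (pial)
#' bias of the BOLD signal.
#'
#' @param psc_map Numeric array of percent signal change on the same grid
#'   as the labels.
#' @param depth_labels A [equivolume_bins()] object.
#' @param column_labels A [segment_columns()] object.
#' @param centile Percentage of columns to keep (default 40, in (0, 100\]).
#' @return List with `mask` (logical array: the final ROI), `kept`
#'   (logical per column unit), and `column_psc` (data.frame: slice,
#'   column, deep-bin mean psc, kept).
#' @export
select_columns <- function(psc_map, depth_labels, column_labels,
                           centile = 40) {
  stopifnot(inherits(depth_labels, "depth_bin_labels"),
            inherits(column_labels, "column_labels"),
            identical(dim(psc_map), dim(depth_labels$bin_volume)))
  if (centile <= 0 || centile > 100) stop("'centile' must be in (0, 100]")
  bin <- depth_labels$bin_volume
  col <- column_labels$column_volume
  deep <- depth_labels$n_bins
  nz <- dim(bin)[3]
  units <- list()
  for (k in seq_len(nz)) {
    ck <- col[, , k]; bk <- bin[, , k]; pk <- psc_map[, , k]
    present <- sort(unique(ck[!is.na(ck)]))
    for (cc in present) {
      vox <- !is.na(ck) & ck == cc & !is.na(bk) & bk == deep
      units[[length(units) + 1L]] <- data.frame(
        slice = k, column = cc,
        deep_psc = if (any(vox)) mean(pk[vox], na.rm = TRUE) else NA_real_)
    }
  }
  if (length(units) == 0L) stop("no columns found")
  tab <- do.call(rbind, units)
  vals <- tab$deep_psc
  kcount <- as.integer(ceiling(centile / 100 * nrow(tab)))
  thr <- sort(vals, decreasing = TRUE)[kcount]
  tab$kept <- !is.na(vals) & vals >= thr - 1e-12
  mask <- array(FALSE, dim(bin))
  for (i in which(tab$kept)) {
    k <- tab$slice[i]
    sel <- !is.na(col[, , k]) & col[, , k] == tab$column[i]
    m <- mask[, , k]; m[sel] <- TRUE; mask[, , k] <- m
  }
  list(mask = mask, kept = tab$kept, column_psc = tab)
}
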