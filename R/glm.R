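# Block-design GLM activation mapping. The task regressor is the stimulus
# onset train convolved with an age-group response basis (the block response
# from `make_response_model()`, or any kernel with `time_grid`/`amplitude`),
# fitted voxelwise by OLS with optional AR(1) prewhitening; t statistics are
# mapped through the normal quantile to z.

#' Build a GLM design matrix
#'
#' The task column is the superposition of the response basis at every
#' stimulus onset, sampled at the volume acquisition times (for a
#' delta-like basis this reduces to the stimulus boxcar). Confound
#' columns, one-hot outlier columns, and an intercept are appended.
#'
#' @param paradigm A [make_paradigm()] object.
#' @param response A [make_response_model()] object (or a list with
#'   `time_grid` and `amplitude`) describing the response to one block.
#' @param confounds Optional matrix of per-volume confounds.
#' @param outlier_flags Optional logical per-volume vector; each flagged
#'   volume contributes a one-hot scrubbing column.
#' @return An object of class `design_matrix`: list with `X` (volumes x
#'   columns, named), `task_col` (index), `scaling` (peak-to-peak height
#'   of the task column) and `tr`.
#' @export
build_design <- function(paradigm, response, confounds = NULL,
                         outlier_flags = NULL) {
  stopifnot(inherits(paradigm, "paradigm"))
  task <- response_timecourse(paradigm, response)
  nt <- paradigm$n_volumes
  X <- cbind(task = task, intercept = rep(1, nt))
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    if (nrow(confounds) != nt)
      stop("confound rows must equal the number of volumes")
    colnames(confounds) <- colnames(confounds) %||%
      paste0("confound", seq_len(ncol(confounds)))
    X <- cbind(X, confounds)
  }
  if (!is.null(outlier_flags)) {
    stopifnot(length(outlier_flags) == nt)
    for (j in which(outlier_flags)) {
      one <- numeric(nt); one[j] <- 1
      X <- cbind(X, one)
      colnames(X)[ncol(X)] <- paste0("outlier_vol", j)
    }
  }
  structure(list(X = X, task_col = 1L,
                 scaling = diff(range(task)), tr = paradigm$tr),
            class = "design_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# t -> z through log-scale tail probabilities (stable far into the tails)
.t_to_z <- function(tval, df) {
  z <- ifelse(tval >= 0,
              stats::qnorm(stats::pt(tval, df, lower.tail = FALSE,
                                     log.p = TRUE),
                           lower.tail = FALSE, log.p = TRUE),
              stats::qnorm(stats::pt(tval, df, lower.tail = TRUE,
                                     log.p = TRUE),
                           lower.tail = TRUE, log.p = TRUE))
  pmin(pmax(z, -40), 40)
}

#' Fit a voxelwise GLM
#'
#' Ordinary least squares per voxel; with `prewhiten = TRUE` a global
#' AR(1) coefficient is estimated from the residual lag-1 autocorrelation
#' and both data and design are transformed (Cochrane--Orcutt) before
#' refitting. The task-effect t statistic is converted to a z statistic
#' through the normal quantile, capped at |z| = 40.
#'
#' @param series A `bold_series`, or a volumes x voxels numeric matrix.
#' @param design A [build_design()] object.
#' @param prewhiten Logical.
#' @return An object of class `glm_result`: list with `beta` (task effect
#'   per voxel), `z` (z statistic), `se`, `dof`, `ar_coeff`, `mean_map`
#'   (voxel temporal means of the input), `dims` (spatial dims when the
#'   input was 4D) and `design`.
#' @export
fit_glm <- function(series, design, prewhiten = FALSE) {
  stopifnot(inherits(design, "design_matrix"))
  dims <- NULL
  if (is.list(series) && inherits(series, "bold_series")) {
    dims <- dim(series$data)[1:3]
    Y <- .as_tv(series)
  } else {
    Y <- as.matrix(series)
  }
  X <- design$X
  if (nrow(Y) != nrow(X)) stop("volumes in data and design differ")
  dof <- nrow(X) - qr(X)$rank
  if (dof <= 0) stop("non-positive residual degrees of freedom")
  mean_map <- colMeans(Y)

  fit_once <- function(X, Y) {
    qrX <- qr(X)
    beta_all <- qr.coef(qrX, Y)
    res <- qr.resid(qrX, Y)
    sigma2 <- colSums(res^2) / dof
    XtXinv <- chol2inv(qr.R(qrX))
    list(beta = beta_all[design$task_col, ],
         se = sqrt(sigma2 * XtXinv[design$task_col, design$task_col]),
         res = res)
  }

  f <- fit_once(X, Y)
  rho <- NA_real_
  if (prewhiten) {
    r <- f$res
    num <- sum(colSums(r[-1, , drop = FALSE] * r[-nrow(r), , drop = FALSE]))
    den <- sum(colSums(r^2))
    rho <- if (den > 0) num / den else 0
    rho <- max(min(rho, 0.97), -0.97)
    n <- nrow(Y)
    Yw <- Y[-1, , drop = FALSE] - rho * Y[-n, , drop = FALSE]
    Xw <- X[-1, , drop = FALSE] - rho * X[-n, , drop = FALSE]
    dof <- nrow(Xw) - qr(Xw)$rank
    if (dof <= 0) stop("non-positive residual degrees of freedom")
    design_w <- design; design_w$X <- Xw
    f <- local({
      qrX <- qr(Xw)
      beta_all <- qr.coef(qrX, Yw)
      res <- qr.resid(qrX, Yw)
      sigma2 <- colSums(res^2) / dof
      XtXinv <- chol2inv(qr.R(qrX))
      list(beta = beta_all[design$task_col, ],
           se = sqrt(sigma2 * XtXinv[design$task_col, design$task_col]),
           res = res)
    })
  }
  tval <- ifelse(f$se > 0, f$beta / f$se, sign(f$beta) * Inf)
  structure(list(beta = unname(f$beta), z = unname(.t_to_z(tval, dof)),
                 se = unname(f$se), dof = dof, ar_coeff = rho,
                 mean_map = unname(mean_map), dims = dims, design = design),
            class = "glm_result")
}

#' Threshold a z map
#'
#' @param z_map Numeric vector or array of z statistics.
#' @param z_thresh Threshold; voxels with `z > z_thresh` (strictly) are
#'   active.
#' @return Logical mask of the same shape.
#' @export
threshold_map <- function(z_map, z_thresh = 3.1) {
  z_map > z_thresh
}

#' Convert GLM effect sizes to percent signal change
#'
#' `psc = 100 * beta * scaling / mean` where `scaling` is the
#' peak-to-peak height of the task regressor and `mean` the voxel
#' temporal mean; voxels with non-positive mean are returned as `NA`.
#'
#' @param glm_result A [fit_glm()] object.
#' @param design Optional design (defaults to the one stored in the fit).
#' @param mean_map Optional voxel means (defaults to those of the fitted
#'   data).
#' @return Numeric vector of percent signal change per voxel.
#' @export
to_percent_signal_change <- function(glm_result, design = NULL,
                                     mean_map = NULL) {
  stopifnot(inherits(glm_result, "glm_result"))
  design <- design %||% glm_result$design
  mean_map <- mean_map %||% glm_result$mean_map
  psc <- 100 * glm_result$beta * design$scaling / mean_map
  psc[!is.finite(psc) | mean_map <= 0] <- NA_real_
  psc
}
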