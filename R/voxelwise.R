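## Voxelwise GLMs for age (GLM1) and age-by-sex (GLM2) effects with the
## other two parameter maps as voxelwise covariates, plus Monte-Carlo
## cluster-extent correction of the resulting T fields.

#' Build the voxelwise design
#'
#' GLM1 models `Y ~ intercept + age + sex + race + ICV + gm_density + Z`
#' and tests the age coefficient; GLM2 adds the age-by-sex product and
#' tests it. `gm_density` and the two non-response parameter maps `Z` are
#' voxelwise columns appended at fit time; this function assembles the
#' subject-level part, records the voxelwise column names and the contrast.
#'
#' @param cohort `data.frame` with `age`, `sex`, and optionally `race`
#'   (one-hot encoded, reference level `"White"` when present) and `icv`.
#' @param model `"glm1"` (age effect) or `"glm2"` (age-by-sex interaction).
#' @param voxel_covariates names of the voxelwise covariate maps that will
#'   be supplied to [fit_glm_voxelwise()] (e.g.
#'   `c("gm_density", "cbf", "att")`).
#' @return A `vox_design` object: `fixed` (n x p matrix), `voxel_covariates`,
#'   `contrast` (column name tested).
#' @export
build_design <- function(cohort, model = c("glm1", "glm2"),
                         voxel_covariates = character(0)) {
  model <- match.arg(model)
  n <- nrow(cohort)
  sex01 <- as.numeric(cohort$sex == "M")
  X <- cbind(`(Intercept)` = rep(1, n), age = cohort$age, sex = sex01)
  if (model == "glm2") X <- cbind(X, `age:sex` = cohort$age * sex01)
  if ("race" %in% names(cohort)) {
    lev <- unique(as.character(cohort$race))
    lev <- c(intersect("White", lev), sort(setdiff(lev, "White")))
    race <- factor(cohort$race, levels = lev)
    if (nlevels(race) > 1L) {
      dm <- stats::model.matrix(~race)[, -1, drop = FALSE]
      colnames(dm) <- paste0("race", lev[-1])
      X <- cbind(X, dm)
    }
  }
  if ("icv" %in% names(cohort)) X <- cbind(X, icv = cohort$icv)
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient subject-level design (constant or collinear ",
         "columns)", call. = FALSE)
  structure(list(fixed = X, voxel_covariates = voxel_covariates,
                 contrast = if (model == "glm1") "age" else "age:sex",
                 model = model),
            class = "vox_design")
}

#' Voxelwise ordinary least squares with a t contrast
#'
#' Per voxel, fits `Y = X beta + e` where `X` is the subject-level design
#' augmented with the voxelwise covariate columns, and computes
#' \eqn{T = c'\hat\beta / \sqrt{c'(X'X)^{-1}c\,s^2}} with
#' `df = n - rank(X)` for the design's contrast column.
#'
#' @param response n x V matrix of the response map values (one row per
#'   subject, one column per in-mask voxel).
#' @param design a [build_design()] object.
#' @param voxel_data named list of n x V matrices, one per entry of
#'   `design$voxel_covariates`.
#' @return list with `t` (length-V T values), `beta` (contrast
#'   coefficients), `sigma2`, `df`, and `flags` (voxels with missing
#'   covariates or rank-deficient voxelwise designs are flagged and
#'   returned as `NA`).
#' @export
fit_glm_voxelwise <- function(response, design, voxel_data = list()) {
  stopifnot(inherits(design, "vox_design"))
  X0 <- design$fixed
  n <- nrow(X0)
  V <- ncol(response)
  missing_vc <- setdiff(design$voxel_covariates, names(voxel_data))
  if (length(missing_vc))
    stop("voxel_data lacks: ", paste(missing_vc, collapse = ", "),
         call. = FALSE)
  ci_name <- design$contrast
  tval <- beta <- sig2 <- rep(NA_real_, V)
  flags <- integer(V)
  dfres <- n - ncol(X0) - length(design$voxel_covariates)

  if (!length(design$voxel_covariates)) {
    ok <- colSums(!is.finite(response)) == 0
    qr0 <- qr(X0)
    ci <- which(colnames(X0) == ci_name)
    XtXinv_c <- chol2inv(qr.R(qr0))[ci, ci]
    B <- qr.coef(qr0, response[, ok, drop = FALSE])
    res <- response[, ok, drop = FALSE] - X0 %*% B
    s2 <- colSums(res^2) / dfres
    tval[ok] <- B[ci, ] / sqrt(XtXinv_c * s2)
    beta[ok] <- B[ci, ]
    sig2[ok] <- s2
    flags[!ok] <- dpasl_flags[["missing"]]
    return(list(t = tval, beta = beta, sigma2 = sig2, df = dfres,
                flags = flags))
  }

  for (v in seq_len(V)) {
    y <- response[, v]
    Xv <- cbind(X0, vapply(design$voxel_covariates,
                           function(nm) voxel_data[[nm]][, v], numeric(n)))
    if (any(!is.finite(y)) || any(!is.finite(Xv))) {
      flags[v] <- dpasl_flags[["missing"]]
      next
    }
    qv <- qr(Xv)
    if (qv$rank < ncol(Xv)) {
      flags[v] <- dpasl_flags[["missing"]]
      next
    }
    ci <- which(colnames(Xv) == ci_name)
    b <- qr.coef(qv, y)
    res <- y - Xv %*% b
    df <- n - ncol(Xv)
    s2 <- sum(res^2) / df
    covc <- chol2inv(qr.R(qv))[ci, ci]
    tval[v] <- b[ci] / sqrt(covc * s2)
    beta[v] <- b[ci]
    sig2[v] <- s2
  }
  list(t = tval, beta = beta, sigma2 = sig2, df = dfres, flags = flags)
}

## separable Gaussian convolution along each axis (kernel renormalized at
## the array edges)
.gauss_smooth <- function(arr, sigma) {
  d <- dim(arr)
  sigma <- rep_len(sigma, length(d))
  out <- arr
  for (ax in seq_along(d)) {
    s <- sigma[ax]
    if (s <= 0) next
    half <- max(1L, ceiling(3 * s))
    kern <- stats::dnorm(seq(-half, half), sd = s)
    n <- d[ax]
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- (i - half):(i + half)
      keep <- j >= 1 & j <= n
      K[i, j[keep]] <- kern[keep] / sum(kern[keep])
    }
    perm <- c(ax, setdiff(seq_along(d), ax))
    m <- matrix(aperm(out, perm), nrow = n)
    m <- K %*% m
    out <- aperm(array(m, dim = d[perm]), order(perm))
  }
  out
}

## exact per-voxel SD of .gauss_smooth applied to unit white noise
.gauss_smooth_sd <- function(dims, sigma) {
  sigma <- rep_len(sigma, length(dims))
  v <- array(1, dims)
  for (ax in seq_along(dims)) {
    s <- sigma[ax]
    if (s <= 0) next
    half <- max(1L, ceiling(3 * s))
    kern <- stats::dnorm(seq(-half, half), sd = s)
    n <- dims[ax]
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- (i - half):(i + half)
      keep <- j >= 1 & j <= n
      K[i, j[keep]] <- kern[keep] / sum(kern[keep])
    }
    K2 <- K^2
    perm <- c(ax, setdiff(seq_along(dims), ax))
    m <- matrix(aperm(v, perm), nrow = n)
    m <- K2 %*% m
    v <- aperm(array(m, dim = dims[perm]), order(perm))
  }
  sqrt(v)
}

#' Spatial smoothness of residual maps
#'
#' Gaussian-field smoothness estimated from the variance of spatial first
#' differences of the standardized residuals: with neighbor correlation
#' `r = 1 - s^2/2`, the equivalent Gaussian kernel has
#' `sigma^2 = -delta^2 / (4 log r)` and `FWHM = 2.3548 sigma`. The estimate
#' is floored at the voxel size (a sampled field cannot resolve smoothness
#' below its grid).
#'
#' @param residuals 4-D array (x, y, z, subject) of model residuals.
#' @param mask 3-D logical mask.
#' @param voxdim voxel size per axis, mm.
#' @return list with `fwhm` (per axis, mm) and `fwhm_iso` (their mean).
#' @export
estimate_smoothness <- function(residuals, mask = NULL, voxdim = c(1, 1, 1)) {
  d <- dim(residuals)
  if (length(d) != 4L) stop("residuals must be 4-D", call. = FALSE)
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  voxdim <- rep_len(voxdim, 3)
  sds <- apply(residuals, 1:3, stats::sd)
  if (all(sds[mask] == 0, na.rm = TRUE))
    stop("constant residual field: smoothness undefined", call. = FALSE)
  std <- sweep(residuals, 1:3, sds, "/")
  std[!is.finite(std)] <- NA_real_
  fwhm <- numeric(3)
  for (ax in 1:3) {
    n <- d[ax]
    idx_lo <- lapply(c(d[1:3], d[4]), seq_len)
    idx_hi <- idx_lo
    idx_lo[[ax]] <- seq_len(n - 1L)
    idx_hi[[ax]] <- 2:n
    lo_arr <- do.call(`[`, c(list(std), idx_lo, list(drop = FALSE)))
    hi_arr <- do.call(`[`, c(list(std), idx_hi, list(drop = FALSE)))
    mlo <- do.call(`[`, c(list(mask), idx_lo[1:3], list(drop = FALSE)))
    mhi <- do.call(`[`, c(list(mask), idx_hi[1:3], list(drop = FALSE)))
    ok <- array(mlo & mhi, dim = dim(lo_arr))
    # normalize by the empirical second moment of the standardized
    # residuals: sample-SD standardization inflates both the difference
    # variance and the voxel variance by the same small-sample factor
    s2 <- mean((hi_arr[ok] - lo_arr[ok])^2, na.rm = TRUE) /
      mean(c(lo_arr[ok]^2, hi_arr[ok]^2), na.rm = TRUE)
    r <- 1 - s2 / 2
    f <- if (is.finite(r) && r > 0 && r < 1)
      2.3548 * sqrt(-voxdim[ax]^2 / (4 * log(r))) else 0
    fwhm[ax] <- max(f, voxdim[ax])
  }
  list(fwhm = fwhm, fwhm_iso = mean(fwhm))
}

#' Label connected components of a logical volume
#'
#' Iterative flood fill under face (6), edge (18) or corner (26)
#' connectivity.
#'
#' @param x 3-D logical array.
#' @param connectivity 6, 18 or 26.
#' @return integer array of component labels (0 = background), labels
#'   assigned in raster-scan discovery order.
#' @export
label_components <- function(x, connectivity = 6) {
  d <- dim(x)
  stopifnot(length(d) == 3L, connectivity %in% c(6, 18, 26))
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(abs(offs))
  offs <- switch(as.character(connectivity),
                 "6" = offs[nz == 1, , drop = FALSE],
                 "18" = offs[nz >= 1 & nz <= 2, , drop = FALSE],
                 "26" = offs[nz >= 1, , drop = FALSE])
  labels <- array(0L, d)
  x[is.na(x)] <- FALSE
  todo <- which(x)
  lab <- 0L
  nxy <- d[1] * d[2]
  for (start in todo) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    stack <- start
    labels[start] <- lab
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      z <- (v - 1L) %/% nxy + 1L
      rem <- (v - 1L) %% nxy
      yy <- rem %/% d[1] + 1L
      xx <- rem %% d[1] + 1L
      nb_x <- xx + offs[, 1]; nb_y <- yy + offs[, 2]; nb_z <- z + offs[, 3]
      ok <- nb_x >= 1 & nb_x <= d[1] & nb_y >= 1 & nb_y <= d[2] &
        nb_z >= 1 & nb_z <= d[3]
      nb <- (nb_z[ok] - 1L) * nxy + (nb_y[ok] - 1L) * d[1] + nb_x[ok]
      nb <- nb[x[nb] & labels[nb] == 0L]
      if (length(nb)) {
        labels[nb] <- lab
        stack <- c(stack, nb)
      }
    }
  }
  labels
}

#' Monte-Carlo cluster-size threshold
#'
#' Simulates null Gaussian random fields at the estimated smoothness,
#' standardizes them exactly, thresholds two-sided at the Student-t
#' equivalent quantile, and records the maximum suprathreshold cluster size
#' per iteration. The cluster-extent threshold controlling the family-wise
#' error at level `alpha` is the `1 - alpha` quantile of those maxima.
#'
#' @param shape grid dimensions.
#' @param mask optional 3-D logical mask.
#' @param fwhm smoothness, mm (scalar or per axis).
#' @param t_threshold voxelwise |T| threshold.
#' @param df degrees of freedom of the T field.
#' @param n_iter Monte-Carlo iterations (warning below 200).
#' @param seed RNG seed (the result is deterministic given the seed).
#' @param alpha family-wise error level; `alpha >= 1` returns 0.
#' @param connectivity cluster connectivity (6, 18 or 26).
#' @param voxdim voxel size, mm.
#' @return list with `k_threshold` (voxels; clusters must exceed it),
#'   `max_sizes`, and the simulation settings.
#' @export
cluster_null <- function(shape, mask = NULL, fwhm, t_threshold, df,
                         n_iter = 1000, seed = 1, alpha = 0.05,
                         connectivity = 6, voxdim = c(1, 1, 1)) {
  if (n_iter < 200)
    warning("n_iter < 200: cluster threshold will be unstable")
  if (alpha >= 1)
    return(list(k_threshold = 0, max_sizes = integer(0), alpha = alpha,
                fwhm = fwhm, t_threshold = t_threshold, n_iter = n_iter))
  if (is.null(mask)) mask <- array(TRUE, shape)
  voxdim <- rep_len(voxdim, 3)
  sigma <- rep_len(fwhm, 3) / 2.3548 / voxdim
  z_thr <- -stats::qnorm(stats::pt(-abs(t_threshold), df))
  sd_map <- if (any(sigma > 0)) .gauss_smooth_sd(shape, sigma) else NULL
  max_sizes <- with_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      field <- array(stats::rnorm(prod(shape)), shape)
      if (any(sigma > 0)) field <- .gauss_smooth(field, sigma) / sd_map
      mx <- 0L
      for (sgn in c(1, -1)) {
        supra <- (sgn * field > z_thr) & mask
        if (any(supra)) {
          labs <- label_components(supra, connectivity)
          mx <- max(mx, max(tabulate(labs[labs > 0L])))
        }
      }
      mx
    }, integer(1))
  })
  k <- as.numeric(stats::quantile(max_sizes, 1 - alpha, type = 1))
  list(k_threshold = k, max_sizes = max_sizes, alpha = alpha, fwhm = fwhm,
       t_threshold = t_threshold, n_iter = n_iter, df = df, seed = seed)
}

#' Named cluster-threshold presets
#'
#' The published lifespan analysis reported clusters of more than 501
#' voxels at |T| > 1.97 (age effects) and |T| > 1.90 (age-by-sex
#' interactions). These presets reproduce those fixed thresholds; the
#' default analysis path instead recomputes the cluster-extent threshold
#' from the data's own smoothness via [cluster_null()], since a fixed
#' extent is only valid at the smoothness of the data that produced it.
#'
#' @param name `"paper-fig4"` or `"paper-fig5"`.
#' @return list with `t_threshold` and `k_threshold`.
#' @export
cluster_preset <- function(name = c("paper-fig4", "paper-fig5")) {
  name <- match.arg(name)
  switch(name,
         "paper-fig4" = list(t_threshold = 1.97, k_threshold = 501),
         "paper-fig5" = list(t_threshold = 1.90, k_threshold = 501))
}

#' Threshold a T map into significant clusters
#'
#' Positive and negative suprathreshold voxels are labeled separately;
#' clusters whose size exceeds `k_threshold` are reported.
#'
#' @param t_map 3-D T-value array (`NA` outside the mask).
#' @param t_threshold voxelwise |T| threshold.
#' @param k_threshold cluster-extent threshold (strictly exceeded).
#' @param connectivity 6, 18 or 26.
#' @return A `cluster_report`: `clusters` data.frame (`sign`, `size`,
#'   `peak_t`, `peak_x/y/z`), the thresholds, and `cluster_mask` (integer
#'   array labeling surviving clusters, sorted by decreasing size).
#' @export
threshold_clusters <- function(t_map, t_threshold, k_threshold,
                               connectivity = 6) {
  d <- dim(t_map)
  out <- list()
  cl_mask <- array(0L, d)
  nxt <- 0L
  for (sgn in c(1, -1)) {
    supra <- !is.na(t_map) & (sgn * t_map > t_threshold)
    if (!any(supra)) next
    labs <- label_components(supra, connectivity)
    sizes <- tabulate(labs[labs > 0L])
    for (l in which(sizes > k_threshold)) {
      vox <- which(labs == l)
      tv <- t_map[vox]
      pk <- vox[which.max(abs(tv))]
      pkc <- arrayInd(pk, d)
      out[[length(out) + 1]] <- data.frame(
        sign = if (sgn > 0) "positive" else "negative",
        size = sizes[l], peak_t = tv[which.max(abs(tv))],
        peak_x = pkc[1], peak_y = pkc[2], peak_z = pkc[3])
    }
  }
  clusters <- if (length(out)) do.call(rbind, out) else
    data.frame(sign = character(0), size = integer(0),
               peak_t = numeric(0), peak_x = integer(0),
               peak_y = integer(0), peak_z = integer(0))
  if (nrow(clusters)) {
    clusters <- clusters[order(-clusters$size, clusters$sign), ]
    rownames(clusters) <- NULL
    for (i in seq_len(nrow(clusters))) {
      sgn <- if (clusters$sign[i] == "positive") 1 else -1
      supra <- !is.na(t_map) & (sgn * t_map > t_threshold)
      labs <- label_components(supra, connectivity)
      pk <- (clusters$peak_z[i] - 1L) * d[1] * d[2] +
        (clusters$peak_y[i] - 1L) * d[1] + clusters$peak_x[i]
      nxt <- nxt + 1L
      cl_mask[labs == labs[pk]] <- nxt
    }
  }
  structure(list(clusters = clusters, t_threshold = t_threshold,
                 k_threshold = k_threshold, connectivity = connectivity,
                 cluster_mask = cl_mask),
            class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("Cluster report: |T| > %.3g, extent > %g (%d-connectivity)\n",
              x$t_threshold, x$k_threshold, x$connectivity))
  if (nrow(x$clusters)) print(x$clusters, row.names = FALSE)
  else cat("  no surviving clusters\n")
  invisible(x)
}
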