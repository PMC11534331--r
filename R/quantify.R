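## Voxelwise quantification: 4-D DP-pCASL series -> ATT / CBF / kw maps.

#' Assemble a DP-pCASL acquisition series
#'
#' @param conditions list of per-condition entries, each a list with
#'   `pld` (s), `b` (s/mm2) and `volumes`, a 4-D array
#'   (x, y, z, 2*repeats) of interleaved control/label volumes.
#' @param m0 3-D equilibrium-magnetization volume on the same grid.
#' @param mask optional 3-D logical mask; defaults to finite, positive M0.
#' @param interleave `"control-first"` (default) or `"label-first"`.
#' @return An `asl_series` object.
#' @export
asl_series <- function(conditions, m0, mask = NULL,
                       interleave = c("control-first", "label-first")) {
  interleave <- match.arg(interleave)
  dims <- dim(m0)
  if (length(dims) != 3L) stop("m0 must be a 3-D array", call. = FALSE)
  for (cond in conditions) {
    if (!all(c("pld", "b", "volumes") %in% names(cond)))
      stop("each condition needs pld, b and volumes", call. = FALSE)
    dv <- dim(cond$volumes)
    if (length(dv) != 4L || !all(dv[1:3] == dims))
      stop("all conditions must share the M0 grid", call. = FALSE)
    if (dv[4] %% 2L != 0L)
      stop("volumes must hold control/label pairs (even 4th dim)",
           call. = FALSE)
    if (dv[4] < 4L)
      stop("at least 2 repeats per condition are required", call. = FALSE)
  }
  if (is.null(mask)) mask <- is.finite(m0) & m0 > 0
  if (!all(dim(mask) == dims)) stop("mask grid mismatch", call. = FALSE)
  mask <- mask & is.finite(m0) & m0 > 0
  structure(list(conditions = conditions, m0 = m0, mask = mask,
                 interleave = interleave),
            class = "asl_series")
}

#' @export
print.asl_series <- function(x, ...) {
  cat(sprintf("DP-pCASL series: %s grid, %d conditions (%s)\n",
              paste(dim(x$m0), collapse = "x"), length(x$conditions),
              x$interleave))
  for (cond in x$conditions)
    cat(sprintf("  PLD %.2g s, b = %g s/mm2, %d repeats\n",
                cond$pld, cond$b, dim(cond$volumes)[4] / 2))
  invisible(x)
}

#' Control-label differencing
#'
#' Pairs control and label volumes per condition, forms the per-pair
#' difference normalized by M0, and averages over repeats.
#'
#' @param series an [asl_series()].
#' @return list with one element per condition: `pld`, `b`, `mean`
#'   (3-D repeat-mean normalized difference), `stack` (4-D per-repeat
#'   differences) and `flags` (3-D integer; masked/invalid-M0 voxels are
#'   flagged missing, not NaN-propagated).
#' @export
compute_diff <- function(series) {
  stopifnot(inherits(series, "asl_series"))
  m0 <- series$m0
  bad_m0 <- !series$mask
  lapply(series$conditions, function(cond) {
    nrep <- dim(cond$volumes)[4] / 2
    ctrl_idx <- seq(1L, by = 2L, length.out = nrep)
    lab_idx <- ctrl_idx + 1L
    if (series$interleave == "label-first") {
      tmp <- ctrl_idx; ctrl_idx <- lab_idx; lab_idx <- tmp
    }
    stack <- cond$volumes[, , , ctrl_idx, drop = FALSE] -
      cond$volumes[, , , lab_idx, drop = FALSE]
    stack <- sweep(stack, 1:3, m0, "/")
    stack[is.infinite(stack) | is.nan(stack)] <- NA_real_
    mean_map <- apply(stack, 1:3, mean)
    flags <- array(0L, dim(m0))
    flags[bad_m0 | !is.finite(mean_map)] <- dpasl_flags[["missing"]]
    mean_map[bad_m0] <- NA_real_
    list(pld = cond$pld, b = cond$b, mean = mean_map, stack = stack,
         flags = flags)
  })
}

#' Physiological-noise reduction by principal component analysis
#'
#' Removes the repeat-mean difference signal, decomposes the residual
#' repeat-by-voxel matrix by SVD, and strips the leading (highest-variance)
#' components — the structured, physiological-noise-like part of the
#' residual — until at most `retain_fraction` of the residual variance
#' remains; the repeat mean is then restored. Because the residual has zero
#' mean over repeats in every voxel and every principal component inherits
#' that property, the repeat-mean signal is preserved exactly.
#' `retain_fraction = 1` removes nothing.
#'
#' @param stack 4-D per-repeat difference array (x, y, z, repeat).
#' @param retain_fraction fraction of residual variance retained, in (0, 1].
#' @param mask optional 3-D logical mask of voxels entering the
#'   decomposition (others pass through untouched).
#' @return denoised stack with the same dimensions.
#' @export
pca_denoise <- function(stack, retain_fraction = 0.8, mask = NULL) {
  if (!is.numeric(retain_fraction) || length(retain_fraction) != 1L ||
      retain_fraction <= 0 || retain_fraction > 1)
    stop("retain_fraction must lie in (0, 1]", call. = FALSE)
  d <- dim(stack)
  nrep <- d[4]
  if (nrep < 3L) stop("pca_denoise needs at least 3 repeats", call. = FALSE)
  if (retain_fraction == 1) return(stack)
  vox <- if (is.null(mask)) rep(TRUE, prod(d[1:3])) else as.vector(mask)
  X <- matrix(aperm(stack, c(4, 1, 2, 3)), nrow = nrep)   # repeat x voxel
  usable <- vox & colSums(!is.finite(X)) == 0
  Xu <- X[, usable, drop = FALSE]
  mu <- colMeans(Xu)
  R <- sweep(Xu, 2, mu)
  sv <- svd(R, nu = nrep, nv = 0)
  ev <- sv$d^2
  tot <- sum(ev)
  # smallest number of leading components whose removal leaves at most
  # retain_fraction of the residual variance
  m <- 0L
  while (m < length(ev) && (tot - sum(ev[seq_len(m)])) / tot >
         retain_fraction + 1e-12) m <- m + 1L
  if (m > 0L) {
    U <- sv$u[, seq_len(m), drop = FALSE]
    R <- R - U %*% (t(U) %*% R)
  }
  X[, usable] <- sweep(R, 2, mu, "+")
  aperm(array(X, dim = c(nrep, d[1:3])), c(2, 3, 4, 1))
}

## pick the diff entry for a given (pld, b) condition
.find_cond <- function(diffs, pld, b) {
  for (d in diffs)
    if (isTRUE(all.equal(d$pld, pld)) && isTRUE(all.equal(d$b, b))) return(d)
  stop(sprintf("condition PLD=%g, b=%g not present in the series", pld, b),
       call. = FALSE)
}

#' Transit-time map from the early-delay condition pair
#'
#' Voxelwise crushed/uncrushed ratio, clamped into (0, 1], inverted through
#' [feast_invert_att()].
#'
#' @param diff_uncrushed,diff_crushed 3-D repeat-mean normalized difference
#'   maps at the early PLD, b = 0 and the low crusher b-value.
#' @param proto an [asl_protocol()].
#' @param pld early post-labeling delay, seconds.
#' @return list with `att` (3-D, ms) and `flags` (3-D integer).
#' @export
map_att <- function(diff_uncrushed, diff_crushed, proto = asl_protocol(),
                    pld = min(proto$plds)) {
  if (!all(dim(diff_uncrushed) == dim(diff_crushed)))
    stop("maps must share a grid", call. = FALSE)
  dims <- dim(diff_uncrushed)
  r <- as.vector(diff_crushed) / as.vector(diff_uncrushed)
  r[!is.finite(r) | as.vector(diff_uncrushed) <= 0] <- NA_real_
  att <- feast_invert_att(r, proto, pld)
  list(att = array(as.numeric(att), dims),
       flags = array(attr(att, "flags"), dims))
}

#' CBF map from the late-delay uncrushed condition
#'
#' @param diff_uncrushed 3-D repeat-mean normalized difference map at the
#'   late PLD, b = 0.
#' @param att_map 3-D transit-time map, ms (att-aware mode).
#' @inheritParams buxton_invert_cbf
#' @return list with `cbf` (3-D, ml/100g/min) and `flags`.
#' @export
map_cbf <- function(diff_uncrushed, att_map = NULL, proto = asl_protocol(),
                    pld = max(proto$plds),
                    mode = c("att-aware", "white-paper")) {
  mode <- match.arg(mode)
  dims <- dim(diff_uncrushed)
  cbf <- buxton_invert_cbf(as.vector(diff_uncrushed),
                           if (is.null(att_map)) NULL else as.vector(att_map),
                           proto, pld, mode)
  list(cbf = array(as.numeric(cbf), dims),
       flags = array(attr(cbf, "flags"), dims))
}

#' kw map from the late-delay condition pair
#'
#' Forms the voxelwise tissue-fraction ratio A = crushed/uncrushed, clamps
#' it into `[0, 1)`, optionally denoises the ratio map by edge-preserving
#' total-variation minimization, and inverts it through [spa_invert_kw()].
#'
#' @param diff_uncrushed,diff_crushed 3-D repeat-mean normalized difference
#'   maps at the late PLD, b = 0 and the high crusher b-value.
#' @param att_map 3-D transit-time map, ms.
#' @param r1t_map optional 3-D tissue relaxation-rate map, 1/s.
#' @param proto an [asl_protocol()].
#' @param pld late post-labeling delay, seconds.
#' @param reg_weight total-variation weight applied to the ratio map before
#'   inversion; 0 (default) disables regularization.
#' @param kw_max upper inversion bound, 1/min.
#' @return list with `kw` (3-D, 1/min), `a_ratio` (the possibly regularized
#'   ratio map) and `flags`.
#' @export
map_kw <- function(diff_uncrushed, diff_crushed, att_map, r1t_map = NULL,
                   proto = asl_protocol(), pld = max(proto$plds),
                   reg_weight = 0, kw_max = 1000) {
  if (reg_weight < 0) stop("reg_weight must be >= 0", call. = FALSE)
  dims <- dim(diff_uncrushed)
  flags <- array(0L, dims)
  A <- diff_crushed / diff_uncrushed
  bad <- !is.finite(A) | diff_uncrushed <= 0
  A[bad] <- NA_real_
  flags[bad] <- bitwOr(flags[bad], dpasl_flags[["missing"]])
  lo <- !bad & A < 0
  A[lo] <- 0
  flags[lo] <- bitwOr(flags[lo], dpasl_flags[["clamp_lo"]])
  hi <- !bad & A >= 1
  A[hi] <- 1 - 1e-9
  flags[hi] <- bitwOr(flags[hi], dpasl_flags[["clamp_hi"]])
  if (reg_weight > 0)
    A <- tv_regularize(A, reg_weight, mask = !bad)
  kw <- spa_invert_kw(as.vector(A), as.vector(att_map),
                      if (is.null(r1t_map)) NULL else as.vector(r1t_map),
                      proto, pld, kw_max)
  flags <- array(bitwOr(as.vector(flags), attr(kw, "flags")), dims)
  list(kw = array(as.numeric(kw), dims), a_ratio = A, flags = flags)
}

#' Full quantification of a DP-pCASL series
#'
#' Differencing (optionally PCA-denoised), transit-time mapping from the
#' early-delay pair, CBF from the late-delay uncrushed signal and kw from
#' the late-delay ratio.
#'
#' @param series an [asl_series()].
#' @param proto an [asl_protocol()].
#' @param pca_retain residual variance fraction kept by [pca_denoise()];
#'   1 disables denoising.
#' @param reg_weight TV weight for the kw ratio map (0 = voxelwise).
#' @param cbf_mode CBF inversion mode, see [buxton_invert_cbf()].
#' @param r1t_map optional tissue relaxation-rate map, 1/s.
#' @param kw_max upper kw search bound, 1/min.
#' @return A `parameter_maps` object: 3-D `cbf`, `att`, `kw`, integer
#'   `flags`, logical `mask`, plus clamp/saturation counts in `$log`.
#' @export
quantify_series <- function(series, proto = asl_protocol(),
                            pca_retain = 1, reg_weight = 0,
                            cbf_mode = c("att-aware", "white-paper"),
                            r1t_map = NULL, kw_max = 1000) {
  cbf_mode <- match.arg(cbf_mode)
  stopifnot(inherits(series, "asl_series"))
  diffs <- compute_diff(series)
  if (pca_retain < 1) {
    diffs <- lapply(diffs, function(d) {
      d$stack <- pca_denoise(d$stack, pca_retain, series$mask)
      d$mean <- apply(d$stack, 1:3, mean)
      d$mean[!series$mask] <- NA_real_
      d
    })
  }
  pld_e <- min(proto$plds); pld_l <- max(proto$plds)
  b_e <- proto$b_values[[which.min(proto$plds)]]
  b_l <- proto$b_values[[which.max(proto$plds)]]

  att <- map_att(.find_cond(diffs, pld_e, b_e[1])$mean,
                 .find_cond(diffs, pld_e, b_e[2])$mean, proto, pld_e)
  cbf <- map_cbf(.find_cond(diffs, pld_l, b_l[1])$mean, att$att, proto,
                 pld_l, cbf_mode)
  kw <- map_kw(.find_cond(diffs, pld_l, b_l[1])$mean,
               .find_cond(diffs, pld_l, b_l[2])$mean, att$att, r1t_map,
               proto, pld_l, reg_weight, kw_max)

  flags <- bitwOr(bitwOr(att$flags, cbf$flags), kw$flags)
  out_mask <- series$mask & !has_flag(flags, "missing")
  att$att[!out_mask] <- NA_real_
  cbf$cbf[!out_mask] <- NA_real_
  kw$kw[!out_mask] <- NA_real_
  flags[!series$mask] <- bitwOr(flags[!series$mask],
                                dpasl_flags[["missing"]])
  log <- c(
    n_missing = sum(has_flag(flags, "missing")),
    n_clamp_lo = sum(has_flag(flags, "clamp_lo")),
    n_clamp_hi = sum(has_flag(flags, "clamp_hi")),
    n_saturated = sum(has_flag(flags, "saturated")),
    n_clipped = sum(has_flag(flags, "clipped"))
  )
  structure(list(cbf = cbf$cbf, att = att$att, kw = kw$kw,
                 flags = array(flags, dim(series$m0)), mask = out_mask,
                 log = log),
            class = "parameter_maps")
}

#' @export
print.parameter_maps <- function(x, ...) {
  cat(sprintf("DP-pCASL parameter maps (%s grid, %d voxels in mask)\n",
              paste(dim(x$cbf), collapse = "x"), sum(x$mask)))
  fm <- function(v, u) sprintf("median %.3g %s", stats::median(v[x$mask]), u)
  cat("  CBF:", fm(x$cbf, "ml/100g/min"), "\n")
  cat("  ATT:", fm(x$att, "ms"), "\n")
  cat("  kw :", fm(x$kw, "1/min"), "\n")
  cat("  events:", paste(names(x$log), x$log, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}
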