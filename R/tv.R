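## Edge-preserving total-variation denoising of parameter / ratio maps:
## minimize 0.5*||u - f||^2 + weight * TV(u), with anisotropic TV (l1 norm
## of forward differences, Neumann boundaries), restricted to a mask.
## Solved by the Chambolle-Pock primal-dual scheme; the data term keeps the
## iteration unconditionally convergent and the spatial mean of the input
## is preserved (the discrete divergence sums to zero).

## forward differences along axis `ax`; differences across the mask edge
## (or the array edge) are zero
.fdiff <- function(u, ax, valid) {
  d <- array(0, dim(u))
  n <- dim(u)[ax]
  if (n < 2L) return(d)
  idx <- lapply(dim(u), seq_len)
  lo <- hi <- idx
  lo[[ax]] <- seq_len(n - 1L)
  hi[[ax]] <- 2:n
  d_lo <- do.call(`[`, c(list(u), hi, list(drop = FALSE))) -
    do.call(`[`, c(list(u), lo, list(drop = FALSE)))
  ok <- do.call(`[`, c(list(valid), hi, list(drop = FALSE))) &
    do.call(`[`, c(list(valid), lo, list(drop = FALSE)))
  d_lo[!ok] <- 0
  do.call(`[<-`, c(list(d), lo, list(d_lo)))
}

## negative adjoint of .fdiff (discrete divergence contribution of axis ax)
.fdiv <- function(p, ax) {
  d <- array(0, dim(p))
  n <- dim(p)[ax]
  idx <- lapply(dim(p), seq_len)
  lo <- hi <- idx
  lo[[ax]] <- seq_len(n - 1L)
  hi[[ax]] <- 2:n
  pl <- do.call(`[`, c(list(p), lo, list(drop = FALSE)))
  d <- do.call(`[<-`, c(list(d), lo, list(pl)))
  shifted <- array(0, dim(p))
  shifted <- do.call(`[<-`, c(list(shifted), hi, list(pl)))
  d - shifted
}

## total variation of a field on the mask
.tv_value <- function(u, valid) {
  nd <- length(dim(u))
  s <- 0
  for (ax in seq_len(nd)) s <- s + sum(abs(.fdiff(u, ax, valid)))
  s
}

#' Total-variation regularization of a scalar field
#'
#' Minimizes \eqn{\frac12\|u-f\|^2 + w\,TV(u)} over the mask with
#' anisotropic first-order total variation and Neumann boundaries, by a
#' primal-dual iteration. `weight = 0` returns the input unchanged; the
#' output total variation never exceeds the input's; constant fields are
#' fixed points for any weight; the in-mask spatial mean is preserved.
#'
#' @param field numeric array (1-, 2- or 3-D). `NA`s outside the mask are
#'   tolerated and passed through.
#' @param weight regularization weight `w >= 0`, in the units of `field`.
#' @param mask optional logical array; defaults to finite voxels.
#' @param max_iter iteration cap; a warning is issued (and the last iterate
#'   returned) if the relative change has not fallen below `tol` by then.
#' @param tol relative-change stopping tolerance.
#' @return the denoised field (same dimensions; untouched outside the mask).
#' @export
tv_regularize <- function(field, weight, mask = NULL, max_iter = 400,
                          tol = 1e-7) {
  if (!is.numeric(weight) || length(weight) != 1L || weight < 0)
    stop("weight must be a single value >= 0", call. = FALSE)
  f <- field
  if (is.null(dim(f))) f <- array(f, length(f))
  if (is.null(mask)) mask <- is.finite(f)
  if (is.null(dim(mask))) mask <- array(mask, dim(f))
  if (weight == 0 || sum(mask) == 0) return(field)
  nd <- length(dim(f))
  f0 <- f
  f[!mask] <- 0

  L2 <- 4 * nd
  sigma <- tau <- 1 / sqrt(L2)
  u <- f
  ubar <- f
  p <- rep(list(array(0, dim(f))), nd)
  conv <- FALSE
  for (it in seq_len(max_iter)) {
    for (ax in seq_len(nd)) {
      p[[ax]] <- pmin(pmax(p[[ax]] + sigma * .fdiff(ubar, ax, mask),
                           -weight), weight)
    }
    div <- array(0, dim(f))
    for (ax in seq_len(nd)) div <- div + .fdiv(p[[ax]], ax)
    u_new <- (u + tau * div + tau * f) / (1 + tau)
    u_new[!mask] <- 0
    delta <- sqrt(sum((u_new - u)^2)) / max(sqrt(sum(u^2)), 1e-12)
    ubar <- 2 * u_new - u
    u <- u_new
    if (delta < tol) { conv <- TRUE; break }
  }
  if (!conv)
    warning("tv_regularize did not converge within max_iter; ",
            "returning last iterate")
  out <- f0
  out[mask] <- u[mask]
  if (length(dim(field)) == 0L || is.null(dim(field))) out <- as.vector(out)
  out
}
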