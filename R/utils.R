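#' Quality flag bits used in parameter maps
#'
#' Voxelwise quantification never drops voxels silently: every clamp,
#' clip or saturation leaves a bit in the integer flag volume.
#'
#' @format Named integer vector with bits:
#' \describe{
#'   \item{missing}{1 — voxel masked out or input not finite}
#'   \item{clamp_lo}{2 — a ratio was clamped up into its valid domain}
#'   \item{clamp_hi}{4 — a ratio was clamped down into its valid domain}
#'   \item{saturated}{8 — inversion hit the upper search bound}
#'   \item{clipped}{16 — a negative estimate was clipped to zero}
#' }
#' @export
dpasl_flags <- c(
  missing   = 1L,
  clamp_lo  = 2L,
  clamp_hi  = 4L,
  saturated = 8L,
  clipped   = 16L
)

#' Test flag bits
#'
#' @param flags integer vector/array of flag bitfields
#' @param which name from [dpasl_flags]
#' @return logical of the same shape
#' @export
has_flag <- function(flags, which) {
  bit <- dpasl_flags[[which]]
  bitwAnd(as.integer(flags), bit) != 0L
}

## evaluate `expr` under a temporary RNG state seeded with `seed`,
## restoring the caller's RNG afterwards
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

## round half away from zero to `digits` decimals (base round() is
## round-half-even, which does not reproduce conventional reporting)
round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## x/y with 0 where y is 0 or not finite
safe_div <- function(x, y) {
  out <- x / y
  out[!is.finite(out)] <- NA_real_
  out
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}
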