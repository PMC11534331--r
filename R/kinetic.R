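## Kinetic forward and inverse models for DP-pCASL.
##
## Conventions (package-wide): ATT is milliseconds and kw is 1/min at every
## exported interface; internally time is seconds, rates are 1/s, and the
## delivered flux is cbf/(6000*lambda) in 1/s. Signals are fractions of M0.

## (exp(-a*v) - exp(-b*v)) / (b - a), with its limit v*exp(-a*v) as b -> a
.dexp <- function(a, b, v) {
  d <- b - a
  out <- ifelse(abs(d) > 1e-9 * pmax(abs(a), abs(b), 1),
                (exp(-a * v) - exp(-b * v)) / d,
                v * exp(-a * v))
  out
}

## Two-compartment single-pass components at measurement time t = pld + tau.
## Capillary label is delivered at rate F*c(t) (c(t) the arterial input,
## 2*alpha*exp(-delta*R1b) during the bolus), relaxes with R1b and drains
## into tissue at k = kw/60 1/s; tissue label relaxes with R1t.
## Closed-form piecewise solution; kw = 0 reduces to the single-compartment
## model with blood T1.
.spa_components <- function(cbf, att_ms, kw_min, proto, pld, r1t = NULL) {
  if (any(pld < 0)) stop("pld must be nonnegative", call. = FALSE)
  n <- max(length(cbf), length(att_ms), length(kw_min), length(pld),
           length(r1t %||% 1))
  cbf <- rep_len(as.numeric(cbf), n)
  att <- rep_len(as.numeric(att_ms), n) / 1000
  k <- rep_len(as.numeric(kw_min), n) / 60
  pld <- rep_len(as.numeric(pld), n)
  tau <- proto$label_dur
  r1b <- 1 / proto$t1_blood
  r1t <- rep_len(if (is.null(r1t)) 1 / proto$t1_tissue else as.numeric(r1t), n)

  t_meas <- pld + tau
  Fs <- cbf / (6000 * proto$lambda_part)
  a <- r1b + k
  I <- 2 * proto$label_eff * Fs * exp(-att * r1b)

  u <- pmin(pmax(t_meas - att, 0), tau)       # delivered bolus duration
  v <- pmax(t_meas - att - tau, 0)            # post-bolus decay time

  cap1 <- I / a * (1 - exp(-a * u))
  tis1 <- (k * I / a) * ((1 - exp(-r1t * u)) / r1t - .dexp(a, r1t, u))

  cap <- cap1 * exp(-a * v)
  tis <- tis1 * exp(-r1t * v) + k * cap1 * .dexp(a, r1t, v)

  none <- u <= 0                              # label not yet arrived
  cap[none] <- 0
  tis[none] <- 0
  list(cap = cap, tis = tis)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Single-compartment pCASL forward model
#'
#' Difference signal (fraction of M0) predicted by the single-compartment
#' continuous-labeling model in which the label relaxes with the blood T1
#' throughout: zero before arrival, rising during bolus delivery, then
#' decaying. Continuous in both measurement time and transit time.
#'
#' @param physio a [physio_state()] (vectors recycle).
#' @param proto an [asl_protocol()].
#' @param pld post-labeling delay, seconds.
#' @return difference signal as fraction of M0, same length as `physio`.
#' @export
buxton_forward <- function(physio, proto = asl_protocol(), pld) {
  s <- .spa_components(physio$cbf, physio$att, 0, proto, pld)
  s$cap
}

#' Invert the single-compartment model for CBF
#'
#' @param dM difference signal, fraction of M0. Non-finite values propagate
#'   as missing voxels.
#' @param att transit time, ms (used in `"att-aware"` mode only).
#' @param proto an [asl_protocol()].
#' @param pld post-labeling delay, seconds.
#' @param mode `"att-aware"` inverts [buxton_forward()] exactly at the given
#'   transit time; `"white-paper"` uses the consensus closed form
#'   \eqn{6000 \lambda \Delta M e^{PLD/T1b} / (2 \alpha T1b (1-e^{-\tau/T1b}))},
#'   which ignores the transit time (the two agree whenever PLD >= ATT).
#' @return CBF in ml/100g/min, clipped at zero; an integer `"flags"`
#'   attribute records clip/missing events (see [dpasl_flags]).
#' @export
buxton_invert_cbf <- function(dM, att = NULL, proto = asl_protocol(),
                              pld = max(proto$plds),
                              mode = c("att-aware", "white-paper")) {
  mode <- match.arg(mode)
  dM <- as.numeric(dM)
  n <- length(dM)
  flags <- integer(n)
  if (mode == "white-paper") {
    denom <- 2 * proto$label_eff * proto$t1_blood *
      (1 - exp(-proto$label_dur / proto$t1_blood))
    unit <- denom * exp(-pld / proto$t1_blood) / (6000 * proto$lambda_part)
    unit <- rep_len(unit, n)
  } else {
    if (is.null(att)) stop("att is required in att-aware mode", call. = FALSE)
    unit <- buxton_forward(physio_state(1, att, 0), proto, pld)
    unit <- rep_len(unit, n)
  }
  cbf <- dM / unit
  bad <- !is.finite(cbf)
  flags[bad] <- bitwOr(flags[bad], dpasl_flags[["missing"]])
  cbf[bad] <- NA_real_
  neg <- !bad & cbf < 0
  flags[neg] <- bitwOr(flags[neg], dpasl_flags[["clipped"]])
  cbf[neg] <- 0
  structure(cbf, flags = flags)
}

#' Two-compartment single-pass forward model
#'
#' Capillary and tissue label fractions at readout. The capillary
#' compartment is filled by arterial delivery and drained by water exchange
#' at rate kw; the tissue compartment is fed by that exchange and relaxes
#' with the tissue T1.
#'
#' @inheritParams buxton_forward
#' @param r1t optional tissue relaxation rate 1/s (default `1/proto$t1_tissue`;
#'   may be a per-voxel vector).
#' @return A `compartment_signal` list with elements `dM_cap`, `dM_tis`,
#'   `dM_total`, all fractions of M0.
#' @export
spa_forward <- function(physio, proto = asl_protocol(), pld, r1t = NULL) {
  s <- .spa_components(physio$cbf, physio$att, physio$kw, proto, pld, r1t)
  structure(list(dM_cap = s$cap, dM_tis = s$tis,
                 dM_total = s$cap + s$tis),
            class = "compartment_signal")
}

#' Tissue fraction of the labeled signal
#'
#' The diffusion-weighted ratio on which kw quantification rests:
#' \eqn{A = \Delta M_{tis} / (\Delta M_{cap} + \Delta M_{tis})}, equal to the
#' crushed/uncrushed signal ratio under the assumption that the high-b
#' acquisition crushes capillary label completely. `A` is independent of CBF
#' and strictly increasing in kw.
#'
#' @inheritParams spa_forward
#' @return dimensionless ratio in `[0, 1]`; missing where the total signal
#'   is zero.
#' @export
spa_ratio <- function(physio, proto = asl_protocol(), pld, r1t = NULL) {
  s <- spa_forward(physio, proto, pld, r1t)
  out <- s$dM_tis / s$dM_total
  out[!is.finite(out)] <- NA_real_
  out
}

## ratio as a function of kw/att only (cbf cancels); used by the inverter
.ratio_kw <- function(kw_min, att_ms, proto, pld, r1t = NULL) {
  s <- .spa_components(50, att_ms, kw_min, proto, pld, r1t)
  tot <- s$cap + s$tis
  out <- s$tis / tot
  out[!is.finite(out)] <- NA_real_
  out
}

#' Invert the tissue-fraction ratio for kw
#'
#' Monotone bracketing and bisection of [spa_ratio()] in kw over
#' `[0, kw_max]`, to a ratio tolerance of 1e-8.
#'
#' @param A observed tissue fraction (crushed/uncrushed ratio), in `[0, 1)`.
#' @param att transit time, ms (vector recycles against `A`).
#' @param r1t optional tissue relaxation rate, 1/s.
#' @param proto an [asl_protocol()].
#' @param pld post-labeling delay, seconds.
#' @param kw_max upper search bound, 1/min.
#' @return kw in 1/min with a `"flags"` attribute: values of `A` below the
#'   ratio at kw = 0 return 0 (flag `clamp_lo`); values at or above the
#'   ratio at `kw_max` return `kw_max` (flag `saturated`); non-finite `A`
#'   propagates as missing.
#' @export
spa_invert_kw <- function(A, att, r1t = NULL, proto = asl_protocol(),
                          pld = max(proto$plds), kw_max = 1000) {
  n <- max(length(A), length(att))
  A <- rep_len(as.numeric(A), n)
  att <- rep_len(as.numeric(att), n)
  if (!is.null(r1t)) r1t <- rep_len(as.numeric(r1t), n)
  flags <- integer(n)
  kw <- rep(NA_real_, n)

  bad <- !is.finite(A) | !is.finite(att)
  flags[bad] <- bitwOr(flags[bad], dpasl_flags[["missing"]])

  A0 <- .ratio_kw(0, att, proto, pld, r1t)      # = 0 wherever defined
  Amax <- .ratio_kw(kw_max, att, proto, pld, r1t)
  lo_idx <- !bad & A <= A0
  kw[lo_idx] <- 0
  flags[lo_idx & A < A0] <- bitwOr(flags[lo_idx & A < A0],
                                   dpasl_flags[["clamp_lo"]])
  hi_idx <- !bad & A >= Amax
  kw[hi_idx] <- kw_max
  flags[hi_idx] <- bitwOr(flags[hi_idx], dpasl_flags[["saturated"]])

  todo <- !bad & !lo_idx & !hi_idx
  if (any(todo)) {
    lo <- rep(0, sum(todo))
    hi <- rep(kw_max, sum(todo))
    Att <- att[todo]
    Rt <- if (is.null(r1t)) NULL else r1t[todo]
    target <- A[todo]
    for (i in 1:52) {
      mid <- (lo + hi) / 2
      fm <- .ratio_kw(mid, Att, proto, pld, Rt)
      up <- fm < target
      lo[up] <- mid[up]
      hi[!up] <- mid[!up]
      if (max(abs(fm - target)) <= 1e-8 && max(hi - lo) < 1e-6) break
    }
    kw[todo] <- (lo + hi) / 2
  }
  structure(kw, flags = flags)
}

#' Crushed/uncrushed early-delay signal ratio (flow-encoding ATT model)
#'
#' The crushed early-delay signal reflects label that has arrived in tissue
#' by the transit time `att`, while the uncrushed reference is modelled as
#' the same signal at the earliest resolvable arrival (`proto$att_floor`).
#' The ratio is 1 at the floor and strictly decreasing in `att`.
#'
#' @param att transit time, ms, within
#'   `[att_floor*1000, (label_dur+pld)*1000)`.
#' @param proto an [asl_protocol()].
#' @param pld early post-labeling delay, seconds.
#' @return dimensionless ratio in `(0, 1]`.
#' @export
feast_ratio <- function(att, proto = asl_protocol(), pld = min(proto$plds)) {
  lo <- proto$att_floor * 1000
  hi <- (proto$label_dur + pld) * 1000
  if (any(is.finite(att) & (att < lo | att >= hi)))
    stop(sprintf("att outside [%g, %g) ms", lo, hi), call. = FALSE)
  num <- buxton_forward(physio_state(1, att, 0), proto, pld)
  den <- buxton_forward(physio_state(1, rep(lo, length(att)), 0), proto, pld)
  num / den
}

## per-(proto, pld) lookup cache for the ATT inversion
.feast_cache <- new.env(parent = emptyenv())

.feast_table <- function(proto, pld) {
  key <- paste(proto$att_floor, proto$label_dur, proto$t1_blood, pld,
               sep = "|")
  tab <- .feast_cache[[key]]
  if (is.null(tab)) {
    lo <- proto$att_floor * 1000
    hi <- (proto$label_dur + pld) * 1000 - 1
    att_grid <- seq(lo, hi, by = 1)
    r_grid <- feast_ratio(att_grid, proto, pld)
    tab <- list(att = att_grid, r = r_grid)
    .feast_cache[[key]] <- tab
  }
  tab
}

#' Invert the early-delay signal ratio for ATT
#'
#' Monotone inversion of [feast_ratio()] through a precomputed 1-ms lookup
#' table with linear interpolation.
#'
#' @param r crushed/uncrushed ratio, in `(0, 1]`. `r > 1` clamps to the
#'   transit-time floor (flag `clamp_lo`); `r` below the smallest tabled
#'   ratio clamps to the longest resolvable transit time (flag `clamp_hi`);
#'   `r <= 0` or non-finite is missing.
#' @param proto an [asl_protocol()].
#' @param pld early post-labeling delay, seconds.
#' @return ATT in ms with a `"flags"` attribute.
#' @export
feast_invert_att <- function(r, proto = asl_protocol(),
                             pld = min(proto$plds)) {
  tab <- .feast_table(proto, pld)
  r <- as.numeric(r)
  n <- length(r)
  flags <- integer(n)
  att <- rep(NA_real_, n)

  bad <- !is.finite(r) | r <= 0
  flags[bad] <- bitwOr(flags[bad], dpasl_flags[["missing"]])

  high <- !bad & r >= 1
  att[high] <- tab$att[1]
  flags[high & r > 1] <- bitwOr(flags[high & r > 1],
                                dpasl_flags[["clamp_lo"]])

  low <- !bad & r <= min(tab$r)
  att[low] <- tab$att[length(tab$att)]
  flags[low] <- bitwOr(flags[low], dpasl_flags[["clamp_hi"]])

  mid <- !bad & !high & !low
  if (any(mid)) {
    # ratio grid is strictly decreasing in att; interpolate on reversed axis
    att[mid] <- stats::approx(x = rev(tab$r), y = rev(tab$att),
                              xout = r[mid], ties = "ordered")$y
  }
  structure(att, flags = flags)
}

#' Sensitivity of kw to a transit-time shift
#'
#' Re-inverts the tissue-fraction ratio after shifting the assumed transit
#' time, quantifying how much an unmodelled ATT difference (e.g. the ~60 ms
#' sex difference in transit time) would move the kw estimate.
#'
#' @inheritParams spa_invert_kw
#' @param att_shift shift added to `att`, ms.
#' @return kw (1/min) recomputed at `att + att_shift`, with flags as in
#'   [spa_invert_kw()].
#' @export
kw_att_sensitivity <- function(A, att, att_shift, r1t = NULL,
                               proto = asl_protocol(),
                               pld = max(proto$plds), kw_max = 1000) {
  shifted <- att + att_shift
  hi <- (proto$label_dur + pld) * 1000
  if (any(is.finite(shifted) & (shifted < 0 | shifted >= hi)))
    stop("shifted att outside the valid transit-time range", call. = FALSE)
  spa_invert_kw(A, shifted, r1t, proto, pld, kw_max)
}
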