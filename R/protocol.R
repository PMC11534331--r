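#' DP-pCASL acquisition protocol
#'
#' Container for the labeling and readout constants of a diffusion-prepared
#' pCASL acquisition. Defaults describe the two-delay protocol used
#' throughout this package: labeling duration 1.5 s; an early delay
#' (PLD = 0.9 s) acquired at b = 0 and 14 s/mm2 for transit-time mapping,
#' and a late delay (PLD = 1.8 s) at b = 0 and 50 s/mm2 for perfusion and
#' water-exchange mapping.
#'
#' @param label_dur labeling duration tau, seconds.
#' @param plds post-labeling delays, seconds (one per diffusion-weighted
#'   condition pair).
#' @param b_values list of length `length(plds)`; each element the
#'   (uncrushed, crushed) b-value pair in s/mm2, strictly increasing.
#' @param label_eff labeling efficiency alpha in (0, 1]. The default 0.72
#'   is the product of a nominal pCASL inversion efficiency 0.85 and a
#'   background-suppression factor 0.85; it scales CBF only, not ATT or kw.
#' @param t1_blood longitudinal relaxation time of arterial blood, seconds.
#' @param t1_tissue longitudinal relaxation time of tissue water, seconds
#'   (overridable per voxel in the quantification functions).
#' @param lambda_part blood-brain partition coefficient, ml/g.
#' @param att_floor minimum resolvable arterial transit time, seconds; also
#'   the assumed arrival time of the uncrushed early-delay reference signal.
#'
#' @return An object of class `asl_protocol`.
#' @examples
#' proto <- asl_protocol()
#' proto$plds
#' @export
asl_protocol <- function(label_dur = 1.5,
                         plds = c(0.9, 1.8),
                         b_values = list(c(0, 14), c(0, 50)),
                         label_eff = 0.72,
                         t1_blood = 1.65,
                         t1_tissue = 1.2,
                         lambda_part = 0.9,
                         att_floor = 0.5) {
  stopifnot_scalar(label_dur, "label_dur", positive = TRUE)
  stopifnot_scalar(label_eff, "label_eff")
  stopifnot_scalar(t1_blood, "t1_blood", positive = TRUE)
  stopifnot_scalar(t1_tissue, "t1_tissue", positive = TRUE)
  stopifnot_scalar(lambda_part, "lambda_part", positive = TRUE)
  stopifnot_scalar(att_floor, "att_floor", positive = TRUE)
  if (label_eff <= 0 || label_eff > 1)
    stop("label_eff must lie in (0, 1]", call. = FALSE)
  if (!is.numeric(plds) || any(!is.finite(plds)) || any(plds <= 0))
    stop("all PLDs must be positive and finite", call. = FALSE)
  if (!is.list(b_values) || length(b_values) != length(plds))
    stop("b_values must be a list with one pair per PLD", call. = FALSE)
  for (bv in b_values) {
    if (length(bv) != 2L || any(bv < 0) || diff(bv) <= 0)
      stop("each b-value pair must be nonnegative and strictly increasing",
           call. = FALSE)
  }
  structure(
    list(label_dur = label_dur, plds = plds, b_values = b_values,
         label_eff = label_eff, t1_blood = t1_blood, t1_tissue = t1_tissue,
         lambda_part = lambda_part, att_floor = att_floor),
    class = "asl_protocol"
  )
}

#' @export
print.asl_protocol <- function(x, ...) {
  cat("DP-pCASL acquisition protocol\n")
  cat(sprintf("  labeling duration : %.3g s\n", x$label_dur))
  for (i in seq_along(x$plds))
    cat(sprintf("  PLD %.2g s, b = %s s/mm2\n", x$plds[i],
                paste(x$b_values[[i]], collapse = "/")))
  cat(sprintf("  alpha = %.3g, T1b = %.3g s, T1t = %.3g s, lambda = %.3g ml/g\n",
              x$label_eff, x$t1_blood, x$t1_tissue, x$lambda_part))
  cat(sprintf("  ATT floor = %.3g s\n", x$att_floor))
  invisible(x)
}

#' Read / write a protocol descriptor file
#'
#' Protocol descriptors are plain YAML with keys `label_dur`, `plds`,
#' `b_values`, `label_eff`, `t1_blood`, `t1_tissue`, `lambda`, `att_floor`.
#' A protocol written by [write_protocol()] reads back identical.
#'
#' @param path file path.
#' @return [read_protocol()] returns an `asl_protocol`;
#'   [write_protocol()] returns `path` invisibly.
#' @export
read_protocol <- function(path) {
  y <- yaml::read_yaml(path)
  asl_protocol(
    label_dur = y$label_dur,
    plds = as.numeric(y$plds),
    b_values = lapply(y$b_values, as.numeric),
    label_eff = y$label_eff,
    t1_blood = y$t1_blood,
    t1_tissue = y$t1_tissue,
    lambda_part = y$lambda,
    att_floor = y$att_floor
  )
}

#' @param proto an `asl_protocol`.
#' @rdname read_protocol
#' @export
write_protocol <- function(proto, path) {
  stopifnot(inherits(proto, "asl_protocol"))
  yaml::write_yaml(
    list(label_dur = proto$label_dur,
         plds = as.list(proto$plds),
         b_values = lapply(proto$b_values, as.list),
         label_eff = proto$label_eff,
         t1_blood = proto$t1_blood,
         t1_tissue = proto$t1_tissue,
         lambda = proto$lambda_part,
         att_floor = proto$att_floor),
    path, precision = 15
  )
  invisible(path)
}

#' Physiological state of a voxel or subject
#'
#' Bundles the three parameters the DP-pCASL forward models depend on.
#'
#' @param cbf cerebral blood flow, ml/100g/min (>= 0).
#' @param att arterial transit time, milliseconds.
#' @param kw blood-brain-barrier water-exchange rate, 1/min (>= 0).
#' @param proto protocol used to validate the transit-time range; `NULL`
#'   skips the range check.
#' @return A `physio_state` list. Fields recycle to a common length, so a
#'   state can describe a whole vector of voxels.
#' @export
physio_state <- function(cbf, att, kw, proto = NULL) {
  n <- max(length(cbf), length(att), length(kw))
  cbf <- rep_len(as.numeric(cbf), n)
  att <- rep_len(as.numeric(att), n)
  kw <- rep_len(as.numeric(kw), n)
  ok <- is.finite(cbf) & is.finite(att) & is.finite(kw)
  if (any(cbf[ok] < 0)) stop("cbf must be >= 0", call. = FALSE)
  if (any(kw[ok] < 0)) stop("kw must be >= 0", call. = FALSE)
  if (!is.null(proto)) {
    lo <- proto$att_floor * 1000
    hi <- (proto$label_dur + max(proto$plds)) * 1000
    if (any(att[ok] < lo - 1e-9 | att[ok] > hi + 1e-9))
      stop(sprintf("att must lie in [%g, %g] ms", lo, hi), call. = FALSE)
  }
  structure(list(cbf = cbf, att = att, kw = kw), class = "physio_state")
}
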