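## Synthetic cohorts and phantom acquisitions with the statistical
## structure the analysis assumes: piecewise-linear lifespan trajectories
## per sex calibrated so that age-group expectations reproduce published
## whole-brain group means, plus forward-simulated DP-pCASL signals for
## end-to-end recovery tests. All generators are pure functions of
## (preset, seed).

## integer ages are discrete-uniform within each group; bin moments of the
## hinge pieces have exact closed (finite-sum) forms
.bin_ages <- function(edges) {
  lapply(seq_len(length(edges) - 1), function(i) edges[i]:(edges[i + 1] - 1))
}

## solve (level-at-knee, pre-slope, post-slope) so that the discrete-uniform
## bin expectations of c + s_pre*min(a-K,0) + s_post*max(a-K,0) equal the
## three group targets
.calibrate_piecewise <- function(knee, targets, edges = default_age_bins()) {
  stopifnot(length(targets) == length(edges) - 1)
  ages <- .bin_ages(edges)
  A <- t(vapply(ages, function(a)
    c(1, mean(pmin(a - knee, 0)), mean(pmax(a - knee, 0))), numeric(3)))
  sol <- solve(A, targets)
  list(knee = knee, level = sol[1], slope_pre = sol[2], slope_post = sol[3])
}

.piecewise_value <- function(age, par) {
  par$level + par$slope_pre * pmin(age - par$knee, 0) +
    par$slope_post * pmax(age - par$knee, 0)
}

## residual SD per bin: the printed group SD minus the variance contributed
## by the age trajectory within the bin (floored at 40% of the printed SD
## so a miscalibrated trajectory can never silence the noise)
.residual_sd <- function(par, sd_targets, edges) {
  ages <- .bin_ages(edges)
  vapply(seq_along(ages), function(i) {
    vtraj <- stats::var(.piecewise_value(ages[[i]], par)) *
      (length(ages[[i]]) - 1) / length(ages[[i]])
    sqrt(max(sd_targets[i]^2 - vtraj, (0.4 * sd_targets[i])^2))
  }, numeric(1))
}

#' Study-demographics synthetic preset
#'
#' Encodes the lifespan study structure the generators emulate: 186
#' subjects (89 male / 97 female; race White 65, Latinx 27, African
#' American 47, Asian 47 with the published per-sex split), age groups
#' 8-35 / 36-61 / 62-92 with 56 / 55 / 75 subjects (sex allocation 31/25,
#' 28/27, 30/45), and per-sex piecewise-linear whole-brain trajectories of
#' kw (knee 62 y), CBF (knee 22 y) and ATT (knee 36 y) solved so that every
#' age-group x sex expectation equals the published group mean; residual
#' SDs are calibrated to the published group SDs.
#'
#' @return A `study_preset` object.
#' @export
study_preset <- function() {
  edges <- default_age_bins()
  demo <- list(
    n_total = 186,
    bins = edges,
    group_n = c(56, 55, 75),
    sex_by_group = list(M = c(31, 28, 30), F = c(25, 27, 45)),
    race_by_sex = list(
      M = c(White = 29, Latinx = 11, AfricanAmerican = 21, Asian = 28),
      F = c(White = 36, Latinx = 16, AfricanAmerican = 26, Asian = 19)),
    icv = list(M = c(mean = 1450, sd = 110), F = c(mean = 1300, sd = 100)),
    gm_density = c(mean = 0.55, sd = 0.05))

  targets <- list(
    kw = list(knee = 62,
              M = list(mean = c(120.7, 117.5, 97.9),
                       sd = c(17.4, 26.5, 31.4)),
              F = list(mean = c(121.7, 118.9, 114.8),
                       sd = c(18.2, 14.0, 23.7))),
    cbf = list(knee = 22,
               M = list(mean = c(51.5, 43.9, 31.9),
                        sd = c(11.9, 10.7, 8.5)),
               F = list(mean = c(60.5, 51.2, 39.6),
                        sd = c(10.7, 11.7, 10.3))),
    att = list(knee = 36,
               M = list(mean = c(1325.8, 1383.9, 1526.7),
                        sd = c(157.7, 199.6, 117.4)),
               F = list(mean = c(1220.2, 1334.4, 1468.1),
                        sd = c(134.2, 155.4, 166.9))))

  features <- lapply(targets, function(tg) {
    sexes <- lapply(c(M = "M", F = "F"), function(s) {
      par <- .calibrate_piecewise(tg$knee, tg[[s]]$mean, edges)
      par$resid_sd <- .residual_sd(par, tg[[s]]$sd, edges)
      par$targets <- tg[[s]]$mean
      par
    })
    sexes
  })
  preset <- structure(list(demographics = demo, features = features,
                           units = c(kw = "1/min", cbf = "ml/100g/min",
                                     att = "ms"),
                           region = "whole-brain"),
                      class = "study_preset")
  validate_preset(preset)
  preset
}

#' Gray-matter kw preset
#'
#' Same demographic structure as [study_preset()], but kw follows the
#' published gray-matter trajectory: flat at 121.2 1/min (the young-group
#' whole-brain level) until the knee at 62 years, declining at 0.82 1/min
#' per year thereafter in both sexes (no gray-matter sex difference), with
#' a residual SD of 20 1/min — the spread that reproduces the published
#' confidence-interval width of the post-knee slope at this design.
#'
#' @return A `study_preset` with gray-matter kw trajectory parameters and
#'   `$generating` recording the true knee and post-knee slope.
#' @export
gm_kw_preset <- function() {
  preset <- study_preset()
  par <- list(knee = 62, level = 121.2, slope_pre = 0, slope_post = -0.82,
              resid_sd = rep(20, 3), targets = NULL)
  preset$features$kw <- list(M = par, F = par)
  preset$region <- "GM"
  preset$generating <- c(knee = 62, slope_post = -0.82)
  preset
}

#' Validate a synthetic preset
#'
#' Checks the demographic marginals (group sizes sum to the total, per-sex
#' allocations sum to the sex totals, race counts match the sex totals) and
#' that each calibrated trajectory reproduces its group-mean targets to
#' within 0.5%.
#'
#' @param preset a `study_preset`.
#' @return `TRUE` invisibly; error on inconsistency.
#' @export
validate_preset <- function(preset) {
  d <- preset$demographics
  if (sum(d$group_n) != d$n_total)
    stop("group sizes do not sum to n_total", call. = FALSE)
  sx <- vapply(d$sex_by_group, sum, numeric(1))
  if (!all(sx == c(M = sum(d$race_by_sex$M), F = sum(d$race_by_sex$F))))
    stop("sex allocations do not match race marginals", call. = FALSE)
  if (!all(d$sex_by_group$M + d$sex_by_group$F == d$group_n))
    stop("per-group sex allocations do not sum to group sizes",
         call. = FALSE)
  ages <- .bin_ages(d$bins)
  for (f in names(preset$features)) for (s in c("M", "F")) {
    par <- preset$features[[f]][[s]]
    if (is.null(par$targets)) next
    got <- vapply(ages, function(a) mean(.piecewise_value(a, par)),
                  numeric(1))
    rel <- abs(got - par$targets) / abs(par$targets)
    if (any(rel > 0.005))
      stop(sprintf("calibration of %s (%s) misses its targets", f, s),
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Expected feature value on the preset trajectory
#'
#' Continuous piecewise-linear mean trajectory with the preset's knee and
#' sex-specific slopes.
#'
#' @param age age in years (vector).
#' @param sex `"M"` or `"F"` (recycled).
#' @param feature `"kw"`, `"cbf"` or `"att"`.
#' @param preset a [study_preset()].
#' @return expected value in the feature's units.
#' @export
trajectory_mean <- function(age, sex, feature, preset = study_preset()) {
  stopifnot(feature %in% names(preset$features))
  n <- max(length(age), length(sex))
  age <- rep_len(age, n)
  sex <- rep_len(sex, n)
  out <- numeric(n)
  for (s in c("M", "F")) {
    sel <- sex == s
    if (any(sel))
      out[sel] <- .piecewise_value(age[sel], preset$features[[feature]][[s]])
  }
  out
}

#' Generate a synthetic cohort
#'
#' Ages are integer years, uniform within each age group at the preset's
#' group-by-sex allocation; sex and race hit the preset counts exactly;
#' each feature is its trajectory mean plus Gaussian residual noise with
#' the bin-calibrated SD. Output is byte-identical for equal seeds.
#'
#' @param preset a [study_preset()].
#' @param seed integer seed.
#' @return cohort `data.frame` (`subject_id`, `age`, `sex`, `race`, `icv`,
#'   `gm_density`, `kw`, `cbf`, `att`) with `units` and `truth` attributes;
#'   `truth` holds the per-subject trajectory means.
#' @export
generate_cohort <- function(preset = study_preset(), seed = 1) {
  validate_preset(preset)
  d <- preset$demographics
  edges <- d$bins
  with_seed(seed, {
    rows <- list()
    for (s in c("M", "F")) {
      for (g in seq_along(d$group_n)) {
        ng <- d$sex_by_group[[s]][g]
        if (ng == 0) next
        ages <- sample(edges[g]:(edges[g + 1] - 1), ng, replace = TRUE)
        rows[[length(rows) + 1]] <- data.frame(age = ages, sex = s,
                                               group = g)
      }
    }
    coh <- do.call(rbind, rows)
    coh$race <- NA_character_
    coh$icv <- NA_real_
    for (s in c("M", "F")) {
      idx <- which(coh$sex == s)
      race_pool <- rep(names(d$race_by_sex[[s]]), d$race_by_sex[[s]])
      coh$race[idx] <- sample(race_pool)
      coh$icv[idx] <- stats::rnorm(length(idx), d$icv[[s]]["mean"],
                                   d$icv[[s]]["sd"])
    }
    coh$gm_density <- pmin(pmax(
      stats::rnorm(nrow(coh), d$gm_density["mean"], d$gm_density["sd"]),
      0.3), 0.8)
    truth <- data.frame(row.names = seq_len(nrow(coh)))
    for (f in names(preset$features)) {
      mu <- trajectory_mean(coh$age, coh$sex, f, preset)
      sd_bin <- vapply(seq_len(nrow(coh)), function(i)
        preset$features[[f]][[coh$sex[i]]]$resid_sd[coh$group[i]],
        numeric(1))
      val <- mu + stats::rnorm(nrow(coh)) * sd_bin
      val <- pmax(val, 0)
      coh[[f]] <- val
      truth[[paste0(f, "_mean")]] <- mu
    }
    # keep transit times inside the resolvable window of the default protocol
    coh$att <- pmin(pmax(coh$att, 600), 2250)
    coh$group <- NULL
    coh <- cbind(subject_id = sprintf("S%03d", seq_len(nrow(coh))), coh)
    attr(coh, "units") <- c(subject_id = "", age = "years", sex = "",
                            race = "", icv = "ml", gm_density = "",
                            preset$units)
    attr(coh, "truth") <- truth
    attr(coh, "region") <- preset$region
    coh
  })
}

#' Generate smooth parameter fields for one subject
#'
#' Gaussian random fields centered on the subject's true parameter values
#' over a toy two-region atlas (left/right split). The spatial perturbation
#' is mean-centered within each region, so region means equal the truth
#' exactly; `smoothness = 0` gives i.i.d. voxel noise.
#'
#' @param truth named list/vector with elements `kw`, `cbf`, `att`; each a
#'   scalar (both regions) or a length-2 per-region value.
#' @param shape 3-D grid dimensions.
#' @param smoothness Gaussian smoothing sigma of the perturbation, voxels.
#' @param spatial_cv coefficient of variation of the spatial perturbation.
#' @param seed integer seed.
#' @return list with `maps` (named list of 3-D arrays), `atlas`, `mask`,
#'   `truth`.
#' @export
generate_parameter_maps <- function(truth, shape = c(16, 16, 16),
                                    smoothness = 2, spatial_cv = 0.05,
                                    seed = 1) {
  stopifnot(all(c("kw", "cbf", "att") %in% names(truth)))
  atlas <- array(2L, shape)
  atlas[seq_len(floor(shape[1] / 2)), , ] <- 1L
  mask <- array(TRUE, shape)
  maps <- with_seed(seed, {
    lapply(c(kw = "kw", cbf = "cbf", att = "att"), function(f) {
      tv <- rep_len(as.numeric(truth[[f]]), 2)
      base <- array(tv[atlas], shape)
      if (spatial_cv > 0) {
        pert <- array(stats::rnorm(prod(shape)), shape)
        if (smoothness > 0) {
          pert <- .gauss_smooth(pert, smoothness)
          pert <- pert / stats::sd(pert)
        }
        for (lab in 1:2)
          pert[atlas == lab] <- pert[atlas == lab] -
            mean(pert[atlas == lab])
        base <- base * (1 + spatial_cv * pert)
      }
      base
    })
  })
  maps$kw <- pmax(maps$kw, 0)
  maps$cbf <- pmax(maps$cbf, 0)
  maps$att <- pmin(pmax(maps$att, 550), 2300)
  list(maps = maps, atlas = atlas, mask = mask, truth = truth)
}

#' Forward-simulate a DP-pCASL acquisition
#'
#' Synthesizes control/label repeats for every (PLD, b) condition of the
#' protocol from the parameter fields: the uncrushed signals follow the
#' single-compartment model (the early-delay uncrushed reference at the
#' protocol's transit-time floor, matching the quantification assumption),
#' the early crushed signal carries the transit-time dependence, and the
#' late crushed signal is the tissue fraction of the uncrushed one. Repeat
#' counts default to 15 (early PLD) and 20 (late PLD) per condition.
#' Gaussian noise is added per repeat volume.
#'
#' @param maps named list of 3-D `kw` (1/min), `cbf` (ml/100g/min), `att`
#'   (ms) fields.
#' @param proto an [asl_protocol()].
#' @param noise_sd per-repeat noise SD as a fraction of M0; ignored when
#'   `noise_rel` is given.
#' @param noise_rel per-repeat noise SD relative to the in-mask mean
#'   uncrushed difference signal of the same PLD (e.g. 0.02 for the "2%
#'   noise" study condition).
#' @param n_repeats repeats per condition, one entry per PLD.
#' @param m0_value equilibrium signal level (arbitrary units).
#' @param mask optional 3-D logical mask.
#' @param seed integer seed.
#' @return an [asl_series()].
#' @export
generate_dp_pcasl_signals <- function(maps, proto = asl_protocol(),
                                      noise_sd = 0, noise_rel = NULL,
                                      n_repeats = c(15, 20),
                                      m0_value = 100, mask = NULL,
                                      seed = 1) {
  shape <- dim(maps$cbf)
  if (is.null(mask)) mask <- array(TRUE, shape)
  n_repeats <- rep_len(n_repeats, length(proto$plds))
  m0 <- array(m0_value, shape)
  r1t <- 1 / proto$t1_tissue
  pld_early <- which.min(proto$plds)

  conds <- list()
  with_seed(seed, {
    for (i in seq_along(proto$plds)) {
      pld <- proto$plds[i]
      uncrushed <- if (i == pld_early)
        buxton_forward(physio_state(as.vector(maps$cbf),
                                    proto$att_floor * 1000, 0), proto, pld)
      else
        buxton_forward(physio_state(as.vector(maps$cbf),
                                    as.vector(maps$att), 0), proto, pld)
      crushed <- if (i == pld_early)
        buxton_forward(physio_state(as.vector(maps$cbf),
                                    as.vector(maps$att), 0), proto, pld)
      else
        uncrushed * .ratio_kw(as.vector(maps$kw), as.vector(maps$att),
                              proto, pld, r1t)
      sd_eff <- if (!is.null(noise_rel))
        noise_rel * mean(abs(uncrushed[as.vector(mask)])) else noise_sd
      for (bi in 1:2) {
        dM <- array(if (bi == 1) uncrushed else crushed, shape)
        nrep <- n_repeats[i]
        vols <- array(0, c(shape, 2L * nrep))
        for (r in seq_len(nrep)) {
          noise_c <- array(stats::rnorm(prod(shape), 0, sd_eff), shape)
          noise_l <- array(stats::rnorm(prod(shape), 0, sd_eff), shape)
          vols[, , , 2L * r - 1L] <- m0 * (1 + dM / 2 + noise_c)
          vols[, , , 2L * r] <- m0 * (1 - dM / 2 + noise_l)
        }
        conds[[length(conds) + 1]] <- list(pld = pld,
                                           b = proto$b_values[[i]][bi],
                                           volumes = vols)
      }
    }
  })
  asl_series(conds, m0, mask, interleave = "control-first")
}
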