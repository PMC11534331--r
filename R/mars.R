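## Adaptive hinge-spline ("hockey stick") regression of ROI features on
## age with optional sex main effect and sex-by-age interactions: greedy
## forward selection of reflected hinge pairs, backward pruning by GCV,
## OLS refit with segment slopes and confidence intervals, and k-fold
## cross-validated R^2 on mutually exclusive folds.

#' Hinge ("hockey stick") basis function
#'
#' @param x input (years).
#' @param knot knot location (years).
#' @param direction `"+"` for `max(0, x - knot)`, `"-"` for
#'   `max(0, knot - x)`.
#' @return numeric vector.
#' @export
hinge <- function(x, knot, direction = c("+", "-")) {
  direction <- match.arg(direction)
  if (direction == "+") pmax(0, x - knot) else pmax(0, knot - x)
}

#' Generalized cross-validation score
#'
#' \eqn{GCV = (RSS/n) / (1 - C/n)^2} with effective complexity
#' \eqn{C = M + d (M - 1) / 2}, `M` the number of model columns including
#' the intercept and `d` the complexity penalty per knot.
#'
#' @param rss residual sum of squares.
#' @param n number of observations.
#' @param n_terms `M`, model size including the intercept.
#' @param d complexity penalty (default 3).
#' @return the GCV score; error if `C >= n`.
#' @export
gcv_score <- function(rss, n, n_terms, d = 3) {
  C <- n_terms + d * (n_terms - 1) / 2
  if (C >= n) stop("effective complexity C >= n; model too large",
                   call. = FALSE)
  (rss / n) / (1 - C / n)^2
}

#' Configuration of the hinge-spline fit
#'
#' @param max_terms maximum model size including the intercept.
#' @param gcv_penalty complexity penalty `d` of [gcv_score()].
#' @param min_knot_spacing minimum number of observations strictly on each
#'   side of a candidate knot.
#' @param cv_folds folds for the cross-validated R^2.
#' @param cv_seed seed controlling the fold assignment (the fit is
#'   deterministic given this seed).
#' @param candidate_vars any of `"age"`, `"sex"`, `"age_sex"`; `"age_sex"`
#'   allows products of the sex indicator with age basis functions
#'   (interaction depth 2).
#' @param refit_race include race (when present in the data) as an additive
#'   covariate in the final OLS refit.
#' @return A `mars_config` list.
#' @export
mars_config <- function(max_terms = 8, gcv_penalty = 3,
                        min_knot_spacing = 5, cv_folds = 10, cv_seed = 1,
                        candidate_vars = c("age", "sex", "age_sex"),
                        refit_race = TRUE) {
  if (max_terms < 2) stop("max_terms must be >= 2", call. = FALSE)
  if (cv_folds < 2) stop("cv_folds must be >= 2", call. = FALSE)
  candidate_vars <- match.arg(candidate_vars,
                              c("age", "sex", "age_sex"), several.ok = TRUE)
  structure(list(max_terms = max_terms, gcv_penalty = gcv_penalty,
                 min_knot_spacing = min_knot_spacing, cv_folds = cv_folds,
                 cv_seed = cv_seed, candidate_vars = candidate_vars,
                 refit_race = refit_race),
            class = "mars_config")
}

## ---- internal term machinery -------------------------------------------

## a term is list(var, knot (NA = linear), dir ("+"/"-"/""), with_sex)
.term_label <- function(tm) {
  base <- if (tm$var == "sex") "sex"
  else if (is.na(tm$knot)) "age"
  else sprintf("h(%s, %g)", tm$dir, tm$knot)
  if (isTRUE(tm$with_sex) && tm$var != "sex") paste0("sex:", base) else base
}

.term_col <- function(tm, age, sex01) {
  col <- if (tm$var == "sex") sex01
  else if (is.na(tm$knot)) age
  else hinge(age, tm$knot, tm$dir)
  if (isTRUE(tm$with_sex) && tm$var != "sex") col <- col * sex01
  col
}

.basis_matrix <- function(terms, age, sex01) {
  if (!length(terms))
    return(matrix(numeric(0), nrow = length(age), ncol = 0))
  cols <- vapply(terms, .term_col, numeric(length(age)),
                 age = age, sex01 = sex01)
  colnames(cols) <- vapply(terms, .term_label, character(1))
  cols
}

.candidate_knots <- function(age, min_spacing) {
  u <- sort(unique(age))
  keep <- vapply(u, function(k)
    sum(age < k) >= min_spacing && sum(age > k) >= min_spacing, logical(1))
  u[keep]
}

## RSS of the pivoted least-squares fit; valid under rank deficiency (the
## residuals are the projection onto the achieved column space). Reflected
## hinge pairs at two knots are always collinear with the intercept
## (h+ - h- is linear in age), so candidate bases are routinely deficient
## and the redundant member is dropped at add time.
.rss_of <- function(X, y) {
  sum(.lm.fit(X, y)$residuals^2)
}

.has_term <- function(terms, tm) {
  any(vapply(terms, function(t)
    identical(.term_label(t), .term_label(tm)), logical(1)))
}

## ---- fitting ------------------------------------------------------------

#' Adaptive hinge-spline trajectory fit
#'
#' Fits `response ~ age (+ sex + sex-by-age)` with reflected hinge pairs at
#' data-driven knots: a greedy forward pass adds the basis unit (hinge pair,
#' linear age, sex indicator, or sex-by-age product) that most reduces the
#' residual sum of squares, a backward pass deletes terms while the GCV
#' improves, and the surviving basis is refit by ordinary least squares
#' (optionally with race as an additive covariate). Model generalization is
#' summarized by a k-fold cross-validated R^2 computed on mutually
#' exclusive folds.
#'
#' @param data cohort `data.frame` with columns `age` (years), `sex`
#'   (`"M"`/`"F"`, coded M = 1 internally), optionally `race`, and the
#'   response column.
#' @param response name of the feature column to model.
#' @param config a [mars_config()].
#' @return An object of class `mars_fit` with `print`, `summary`, `coef`,
#'   `predict`, `plot`, `residuals` and `fitted` methods. Key fields:
#'   `terms` (selected basis), `gcv`, `cv_r2`, `knots`, `segments`
#'   (per-segment slopes with 95% CIs, see [refit_slopes()]) and `refit`
#'   (the underlying `lm` refit).
#' @examples
#' coh <- generate_cohort(gm_kw_preset(), seed = 1)
#' fit <- mars_fit(coh, "kw")
#' fit
#' @export
mars_fit <- function(data, response, config = mars_config()) {
  keep <- is.finite(data[[response]]) & is.finite(data$age)
  if ("sex" %in% names(data)) keep <- keep & !is.na(data$sex)
  data <- data[keep, , drop = FALSE]
  n <- nrow(data)
  if (n < 20) stop("need at least 20 complete rows", call. = FALSE)
  y <- data[[response]]
  age <- data$age
  sex01 <- if ("sex" %in% names(data))
    as.numeric(data$sex == "M") else rep(0, n)
  use_sex <- "sex" %in% config$candidate_vars &&
    length(unique(sex01)) > 1L
  use_int <- "age_sex" %in% config$candidate_vars && use_sex
  knots <- .candidate_knots(age, config$min_knot_spacing)

  terms <- list()
  tss <- sum((y - mean(y))^2)
  rss <- tss
  dropped <- character(0)

  repeat {
    M <- 1L + length(terms)
    if (M >= config$max_terms) break
    budget <- config$max_terms - M
    cands <- list()
    if ("age" %in% config$candidate_vars) {
      lin <- list(var = "age", knot = NA_real_, dir = "", with_sex = FALSE)
      if (!.has_term(terms, lin)) cands <- c(cands, list(list(lin)))
      if (budget >= 2) for (k in knots) {
        pair <- list(
          list(var = "age", knot = k, dir = "+", with_sex = FALSE),
          list(var = "age", knot = k, dir = "-", with_sex = FALSE))
        if (!.has_term(terms, pair[[1]]))
          cands <- c(cands, list(pair))
      }
    }
    if (use_sex) {
      sx <- list(var = "sex", knot = NA_real_, dir = "", with_sex = FALSE)
      if (!.has_term(terms, sx)) cands <- c(cands, list(list(sx)))
      sex_in <- .has_term(terms, sx)
      if (use_int && sex_in) {
        slin <- list(var = "age", knot = NA_real_, dir = "",
                     with_sex = TRUE)
        if (!.has_term(terms, slin)) cands <- c(cands, list(list(slin)))
        if (budget >= 2) for (k in knots) {
          pair <- list(
            list(var = "age", knot = k, dir = "+", with_sex = TRUE),
            list(var = "age", knot = k, dir = "-", with_sex = TRUE))
          if (!.has_term(terms, pair[[1]]))
            cands <- c(cands, list(pair))
        }
      }
    }
    cands <- Filter(function(u) length(u) <= budget, cands)
    if (!length(cands)) break
    base_cols <- .basis_matrix(terms, age, sex01)
    rss_new <- vapply(cands, function(unit) {
      X <- cbind(1, base_cols, .basis_matrix(unit, age, sex01))
      .rss_of(X, y)
    }, numeric(1))
    if (all(!is.finite(rss_new))) break
    # ties (within float noise) go to the earliest — hence simplest — unit
    best <- which(rss_new <= min(rss_new, na.rm = TRUE) +
                    1e-10 * max(tss, 1))[1]
    if (!(rss - rss_new[best] > 1e-12 * max(tss, 1))) break
    # add the unit's terms one by one, dropping any that leave the basis
    # rank-deficient
    for (tm in cands[[best]]) {
      Xtry <- cbind(1, .basis_matrix(c(terms, list(tm)), age, sex01))
      if (qr(Xtry)$rank == ncol(Xtry)) terms <- c(terms, list(tm))
      else dropped <- c(dropped, .term_label(tm))
    }
    rss <- rss_new[best]
    if (rss <= 1e-12 * max(tss, 1)) break
  }

  ## backward pruning: greedily delete terms while GCV improves
  gcv_of <- function(terms) {
    X <- cbind(1, .basis_matrix(terms, age, sex01))
    r <- .rss_of(X, y)
    if (!is.finite(r)) return(Inf)
    gcv_score(r, n, ncol(X), config$gcv_penalty)
  }
  current_gcv <- gcv_of(terms)
  repeat {
    if (!length(terms)) break
    del_gcv <- vapply(seq_along(terms), function(i)
      gcv_of(terms[-i]), numeric(1))
    best <- which.min(del_gcv)
    if (del_gcv[best] <= current_gcv) {
      dropped <- c(dropped, .term_label(terms[[best]]))
      terms <- terms[-best]
      current_gcv <- del_gcv[best]
    } else break
  }

  ## final OLS refit (optionally with race as additive covariate)
  B <- .basis_matrix(terms, age, sex01)
  refit_df <- data.frame(.y = y)
  if (ncol(B)) {
    bn <- paste0(".b", seq_len(ncol(B)))
    refit_df[bn] <- as.data.frame(B)
  } else bn <- character(0)
  use_race <- isTRUE(config$refit_race) && "race" %in% names(data) &&
    length(unique(data$race)) > 1L
  if (use_race) refit_df$race <- factor(data$race)
  fml <- stats::as.formula(paste(".y ~",
    paste(c("1", bn, if (use_race) "race"), collapse = " + ")))
  refit <- stats::lm(fml, data = refit_df)

  folds <- with_seed(config$cv_seed,
                     sample(rep_len(seq_len(config$cv_folds), n)))
  press <- 0
  Xfull <- cbind(`(Intercept)` = 1, B,
                 if (use_race) stats::model.matrix(~race, refit_df)[, -1,
                                                                    drop = FALSE])
  for (fd in seq_len(config$cv_folds)) {
    tr <- folds != fd
    ft <- .lm.fit(Xfull[tr, , drop = FALSE], y[tr])
    beta <- ft$coefficients
    beta[is.na(beta)] <- 0
    pred <- drop(Xfull[!tr, , drop = FALSE] %*% beta)
    press <- press + sum((y[!tr] - pred)^2)
  }
  cv_r2 <- 1 - press / tss

  obj <- structure(list(
    terms = terms, refit = refit, basis_names = bn, use_race = use_race,
    gcv = current_gcv, cv_r2 = cv_r2,
    knots = sort(unique(stats::na.omit(vapply(terms, `[[`, numeric(1),
                                              "knot")))),
    response = response, n = n, age_range = range(age),
    sex_levels = if (use_sex) c("F", "M") else NULL,
    dropped = dropped, config = config,
    data = data, call = match.call()), class = "mars_fit")
  obj$segments <- refit_slopes(obj)
  obj
}

#' Segment slopes with confidence intervals from the refit model
#'
#' The knots of a fitted hinge model partition the observed age range into
#' segments; within each segment (and for each sex when sex-by-age terms
#' are present) the fitted trajectory is linear with slope equal to the
#' signed sum of the active hinge coefficients. Each slope is a linear
#' contrast of the refit OLS coefficients, so its standard error comes from
#' the refit covariance matrix.
#'
#' @param object a [mars_fit()] object.
#' @param level confidence level.
#' @return `data.frame` with columns `age_lo`, `age_hi`, `sex`, `slope`,
#'   `se`, `ci_lo`, `ci_hi` (feature units per year).
#' @export
refit_slopes <- function(object, level = 0.95) {
  stopifnot(inherits(object, "mars_fit"))
  edges <- c(object$age_range[1], object$knots, object$age_range[2])
  edges <- unique(edges)
  beta <- stats::coef(object$refit)
  V <- stats::vcov(object$refit)
  sexes <- if (!is.null(object$sex_levels) &&
               any(vapply(object$terms, function(t)
                 isTRUE(t$with_sex) && t$var == "age", logical(1))))
    c(F = 0, M = 1) else c(both = NA)
  df <- stats::df.residual(object$refit)
  tcrit <- stats::qt(1 - (1 - level) / 2, df)
  out <- list()
  for (si in seq_along(sexes)) {
    sx <- sexes[si]
    sxv <- if (is.na(sx)) 1 else sx     # multiplier for sex-modulated terms
    for (seg in seq_len(length(edges) - 1)) {
      mid <- (edges[seg] + edges[seg + 1]) / 2
      contrast <- stats::setNames(numeric(length(beta)), names(beta))
      for (i in seq_along(object$terms)) {
        tm <- object$terms[[i]]
        if (tm$var != "age") next
        deriv <- if (is.na(tm$knot)) 1
        else if (tm$dir == "+") as.numeric(mid > tm$knot)
        else -as.numeric(mid < tm$knot)
        if (isTRUE(tm$with_sex)) deriv <- deriv * (if (is.na(sx)) 1 else sx)
        contrast[object$basis_names[i]] <-
          contrast[object$basis_names[i]] + deriv
      }
      slope <- sum(contrast * beta, na.rm = TRUE)
      keepc <- names(beta)[!is.na(beta)]
      se <- sqrt(drop(t(contrast[keepc]) %*% V[keepc, keepc] %*%
                        contrast[keepc]))
      out[[length(out) + 1]] <- data.frame(
        age_lo = edges[seg], age_hi = edges[seg + 1],
        sex = names(sexes)[si], slope = slope, se = se,
        ci_lo = slope - tcrit * se, ci_hi = slope + tcrit * se)
    }
  }
  do.call(rbind, out)
}

## ---- methods ------------------------------------------------------------

#' @export
print.mars_fit <- function(x, ...) {
  cat(sprintf("Hinge-spline trajectory fit: %s ~ age%s (n = %d)\n",
              x$response,
              if (!is.null(x$sex_levels)) " + sex" else "", x$n))
  if (length(x$terms)) {
    cat("  basis:",
        paste(vapply(x$terms, .term_label, character(1)), collapse = ", "),
        "\n")
  } else cat("  basis: intercept only\n")
  cat(sprintf("  GCV = %.4g, %d-fold CV R^2 = %.3f\n", x$gcv,
              x$config$cv_folds, x$cv_r2))
  if (length(x$knots))
    cat("  knots (years):", paste(x$knots, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.mars_fit <- function(object, ...) {
  print(object)
  cat("\nSegment slopes (", object$response, " per year):\n", sep = "")
  print(format(object$segments, digits = 3), row.names = FALSE)
  invisible(object)
}

#' @export
coef.mars_fit <- function(object, ...) {
  beta <- stats::coef(object$refit)
  lbl <- c("(Intercept)",
           vapply(object$terms, .term_label, character(1)))
  idx <- c("(Intercept)", object$basis_names)
  stats::setNames(beta[idx], lbl)
}

#' @export
fitted.mars_fit <- function(object, ...) stats::fitted(object$refit)

#' @export
residuals.mars_fit <- function(object, ...) stats::residuals(object$refit)

#' @param newdata `data.frame` with `age`, and `sex`/`race` when the model
#'   uses them (race defaults to the refit reference level).
#' @rdname mars_fit
#' @export
predict.mars_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::fitted(object$refit))
  age <- newdata$age
  sex01 <- if ("sex" %in% names(newdata))
    as.numeric(newdata$sex == "M") else rep(0, length(age))
  B <- .basis_matrix(object$terms, age, sex01)
  nd <- data.frame(row.names = seq_along(age))
  if (length(object$basis_names)) nd[object$basis_names] <- as.data.frame(B)
  if (object$use_race) {
    lev <- levels(object$refit$model$race)
    race <- if ("race" %in% names(newdata)) newdata$race
    else rep(lev[1], length(age))
    nd$race <- factor(race, levels = lev)
  }
  unname(stats::predict(object$refit, nd))
}

#' @export
plot.mars_fit <- function(x, ...) {
  dat <- x$data
  ages <- seq(x$age_range[1], x$age_range[2], length.out = 200)
  cols <- c(F = "#c0392b", M = "#2e6da4")
  sexes <- x$sex_levels %||% "F"
  plot(dat$age, dat[[x$response]], col = cols[as.character(dat$sex)],
       pch = ifelse(dat$sex == "M", 8, 1), xlab = "age (years)",
       ylab = x$response, ...)
  for (s in sexes) {
    nd <- data.frame(age = ages, sex = s)
    graphics::lines(ages, predict(x, nd), col = cols[s], lwd = 2)
  }
  if (length(x$knots))
    graphics::abline(v = x$knots, lty = 3, col = "grey50")
  invisible(x)
}

#' Regional association of kw with CBF or ATT within age strata
#'
#' Ordinary least squares of one regional feature on another with sex as a
#' covariate, fit separately within age strata, with a two-sided t test on
#' the predictor coefficient.
#'
#' @param cohort cohort `data.frame`.
#' @param y response column name (e.g. a regional kw).
#' @param x predictor column name (e.g. the regional CBF or ATT).
#' @param covariate covariate column (default `"sex"`).
#' @param strata list of `(lo, hi)` age intervals, half-open `[lo, hi)`.
#' @param level confidence level.
#' @return `data.frame`: one row per stratum with `n`, `estimate`, `se`,
#'   `ci_lo`, `ci_hi`, `t`, `p`.
#' @export
regional_association <- function(cohort, y, x, covariate = "sex",
                                 strata = list(c(8, 62), c(62, 93)),
                                 level = 0.95) {
  out <- lapply(strata, function(st) {
    sub <- cohort[cohort$age >= st[1] & cohort$age < st[2], , drop = FALSE]
    sub <- sub[is.finite(sub[[y]]) & is.finite(sub[[x]]), , drop = FALSE]
    X <- cbind(1, sub[[x]],
               if (covariate %in% names(sub)) {
                 cv <- sub[[covariate]]
                 if (is.numeric(cv)) cv else as.numeric(factor(cv)) - 1
               })
    if (qr(X)$rank < ncol(X))
      stop("collinear design in stratum [", st[1], ", ", st[2], ")",
           call. = FALSE)
    fml <- stats::as.formula(paste(y, "~", x,
                                   if (covariate %in% names(sub))
                                     paste("+", covariate) else ""))
    fit <- stats::lm(fml, data = sub)
    sm <- summary(fit)$coefficients
    est <- sm[x, "Estimate"]; se <- sm[x, "Std. Error"]
    tcrit <- stats::qt(1 - (1 - level) / 2, stats::df.residual(fit))
    data.frame(age_lo = st[1], age_hi = st[2], n = nrow(sub),
               estimate = est, se = se,
               ci_lo = est - tcrit * se, ci_hi = est + tcrit * se,
               t = sm[x, "t value"], p = sm[x, "Pr(>|t|)"])
  })
  do.call(rbind, out)
}

#' Serialize / restore a fitted trajectory model as JSON
#'
#' @param object a [mars_fit()].
#' @param path output path.
#' @return [write_mars_json()] returns `path` invisibly.
#' @export
write_mars_json <- function(object, path) {
  stopifnot(inherits(object, "mars_fit"))
  payload <- list(
    response = object$response,
    n = object$n,
    terms = lapply(object$terms, function(tm)
      list(label = .term_label(tm), var = tm$var,
           knot = if (is.na(tm$knot)) NULL else tm$knot,
           direction = tm$dir, with_sex = isTRUE(tm$with_sex))),
    coefficients = as.list(coef(object)),
    gcv = object$gcv, cv_r2 = object$cv_r2,
    knots = object$knots,
    segments = object$segments)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
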