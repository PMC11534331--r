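# Hinge-spline trajectory regression: basis arithmetic, GCV, selection
# against an exhaustive oracle, refit slope contrasts against a matrix
# oracle, and the stratified regional associations.

test_that("hinge basis and GCV arithmetic", {
  expect_equal(hinge(62, 62, "+"), 0)
  expect_equal(hinge(70, 62, "+"), 8)
  x <- c(40, 55, 62, 71, 90)
  expect_equal(hinge(x, 62, "+") + hinge(x, 62, "-"), abs(x - 62))

  expect_equal(gcv_score(10, 100, 1, 3), (10 / 100) / (1 - 1 / 100)^2)
  # hand-evaluated: C = 5 + 3*(5-1)/2 = 11
  expect_equal(gcv_score(10, 100, 5, 3), 0.1 / (1 - 11 / 100)^2)
  expect_error(gcv_score(10, 8, 5, 3), "C >= n")
})

test_that("noiseless linear data yields a knotless exact fit", {
  d <- data.frame(age = rep(10:80, length.out = 100),
                  sex = rep(c("M", "F"), 50))
  d$y <- 2 * d$age + 1
  fit <- suppressWarnings(mars_fit(d, "y",
                                   mars_config(refit_race = FALSE)))
  expect_length(fit$knots, 0)
  expect_equal(unique(fit$segments$slope), 2, tolerance = 1e-10)
  expect_equal(fit$cv_r2, 1, tolerance = 1e-10)
})

test_that("noiseless piecewise data recovers its knot and slope exactly", {
  age <- rep(seq(8, 92, by = 2), 3)
  d <- data.frame(age = age, sex = "F",
                  y = 121 - 0.82 * pmax(0, age - 62))
  fit <- suppressWarnings(
    mars_fit(d, "y", mars_config(candidate_vars = "age",
                                 refit_race = FALSE)))
  expect_equal(fit$knots, 62)
  seg <- oldest_segment(fit)
  expect_equal(seg$slope, -0.82, tolerance = 1e-8)
})

test_that("selection matches exhaustive enumeration over <=2-knot models
          on small instances", {
  # greedy forward/backward selection is not globally optimal for
  # arbitrary data; on instances whose kinks sit at candidate knots with
  # modest noise it should coincide with the exhaustive optimum
  age <- sort(rep(seq(10, 90, by = 8), length.out = 25))
  n <- 25
  cfg <- mars_config(candidate_vars = "age", refit_race = FALSE,
                     min_knot_spacing = 6)
  knots <- dpasl:::.candidate_knots(age, cfg$min_knot_spacing)
  expect_lte(length(knots), 8)

  exhaustive_best <- function(y) {
    pool <- list(list(kind = "lin"))
    for (k in knots)
      pool <- c(pool, list(list(kind = "h+", k = k),
                           list(kind = "h-", k = k)))
    col_of <- function(tm) switch(tm$kind, lin = age,
                                  `h+` = pmax(0, age - tm$k),
                                  `h-` = pmax(0, tm$k - age))
    best <- gcv_score(sum((y - mean(y))^2), n, 1, cfg$gcv_penalty)
    for (size in 1:(cfg$max_terms - 1)) {
      for (sub in utils::combn(seq_along(pool), size, simplify = FALSE)) {
        ks <- unique(unlist(lapply(pool[sub], function(t) t$k)))
        if (length(ks) > 2) next
        X <- cbind(1, vapply(pool[sub], col_of, numeric(n)))
        if (qr(X)$rank < ncol(X)) next
        rss <- sum(.lm.fit(X, y)$residuals^2)
        best <- min(best, gcv_score(rss, n, ncol(X), cfg$gcv_penalty))
      }
    }
    best
  }

  fixtures <- list(
    one_kink = list(mu = function(a) 100 - 0.9 * pmax(0, a - 58), sd = 1),
    two_kinks = list(mu = function(a) 100 - 0.5 * pmax(0, a - 34) -
                       1.2 * pmax(0, a - 66), sd = 0.6))
  for (fx in fixtures) {
    set.seed(1)
    y <- fx$mu(age) + rnorm(n, 0, fx$sd)
    fit <- mars_fit(data.frame(age = age, sex = "F", y = y), "y", cfg)
    expect_equal(fit$gcv, exhaustive_best(y), tolerance = 1e-10)
  }
})

test_that("backward pruning never leaves a worse GCV than the
          intercept-only model, and the fit is seed-deterministic", {
  coh <- generate_cohort(gm_kw_preset(), seed = 5)
  fit <- mars_fit(coh, "kw")
  g0 <- gcv_score(sum((coh$kw - mean(coh$kw))^2), nrow(coh), 1, 3)
  expect_lte(fit$gcv, g0)
  fit2 <- mars_fit(coh, "kw")
  expect_identical(fit$cv_r2, fit2$cv_r2)
  expect_identical(coef(fit), coef(fit2))
})

test_that("segment-slope contrasts match a brute-force covariance oracle", {
  set.seed(4)
  age <- rep(c(12, 25, 33, 41, 50, 58, 66, 74, 81, 90), 2)
  n <- length(age)
  y <- 110 - 0.5 * pmax(0, age - 58) + rnorm(n, 0, 2)
  d <- data.frame(age = age, sex = "F", y = y)
  fit <- mars_fit(d, "y", mars_config(candidate_vars = "age",
                                      refit_race = FALSE,
                                      min_knot_spacing = 3))
  # brute-force oracle, valid for whatever basis was selected: rebuild the
  # design from hinge() definitions, form the OLS covariance sandwich, and
  # express the oldest-segment slope as a finite difference of basis rows
  basis_row <- function(a) {
    c(1, vapply(fit$terms, function(tm) {
      if (is.na(tm$knot)) a else hinge(a, tm$knot, tm$dir)
    }, numeric(1)))
  }
  X <- cbind(1, vapply(fit$terms, function(tm) {
    if (is.na(tm$knot)) age else hinge(age, tm$knot, tm$dir)
  }, numeric(n)))
  b <- solve(crossprod(X), crossprod(X, y))
  s2 <- sum((y - X %*% b)^2) / (n - ncol(X))
  Vb <- s2 * solve(crossprod(X))
  lo <- if (length(fit$knots)) max(fit$knots) else min(age)
  a1 <- lo + 0.25 * (max(age) - lo)
  a2 <- lo + 0.75 * (max(age) - lo)
  L <- (basis_row(a2) - basis_row(a1)) / (a2 - a1)
  seg <- oldest_segment(fit)
  expect_equal(seg$slope, drop(L %*% b), tolerance = 1e-8)
  expect_equal(seg$se, sqrt(drop(t(L) %*% Vb %*% L)), tolerance = 1e-8)
})

test_that("degenerate responses: constant y gives zero slopes with
          zero-width intervals; linear-truth CI covers the truth", {
  d <- data.frame(age = rep(seq(10, 90, 5), 2), sex = "M", y = 3.3)
  fit <- suppressWarnings(mars_fit(d, "y",
                                   mars_config(refit_race = FALSE)))
  expect_true(all(fit$segments$slope == 0))
  expect_true(all(fit$segments$ci_hi - fit$segments$ci_lo < 1e-10))

  set.seed(8)
  d2 <- data.frame(age = rep(seq(8, 92, 2), 3), sex = "F")
  d2$y <- 50 - 0.4 * d2$age + rnorm(nrow(d2), 0, 2)
  fit2 <- mars_fit(d2, "y", mars_config(refit_race = FALSE))
  seg <- oldest_segment(fit2)
  expect_true(seg$ci_lo <= -0.4 && -0.4 <= seg$ci_hi)
})

test_that("sex interactions: sex-specific post-knee slopes are recovered
          on a noiseless two-slope fixture", {
  age <- rep(seq(8, 92, by = 1), 2)
  sex <- rep(c("M", "F"), each = length(age) / 2)
  y <- 120 + ifelse(sex == "M", -1.2, -0.3) * pmax(0, age - 62)
  d <- data.frame(age = age, sex = sex, y = y)
  fit <- suppressWarnings(mars_fit(d, "y",
                                   mars_config(refit_race = FALSE)))
  seg <- fit$segments
  old <- seg[seg$age_hi == max(seg$age_hi), ]
  expect_setequal(old$sex, c("F", "M"))
  expect_equal(old$slope[old$sex == "M"], -1.2, tolerance = 1e-6)
  expect_equal(old$slope[old$sex == "F"], -0.3, tolerance = 1e-6)
})

test_that("stratified regional association: planted slopes are covered,
          null predictors give uniform p values, collinearity errors", {
  # planted slope -0.5, known sigma: CI coverage over seeded replicates
  covered <- with_seed(1, {
    vapply(1:100, function(i) {
      n <- 200
      coh <- data.frame(age = sample(8:92, n, TRUE),
                        sex = sample(c("M", "F"), n, TRUE))
      coh$cbf <- rnorm(n, 50, 10)
      coh$kw <- 120 - 0.5 * coh$cbf + 5 * (coh$sex == "M") + rnorm(n, 0, 8)
      res <- regional_association(coh, "kw", "cbf",
                                  strata = list(c(8, 93)))
      res$ci_lo <= -0.5 && -0.5 <= res$ci_hi
    }, logical(1))
  })
  expect_gte(mean(covered), 0.93)

  pvals <- with_seed(2, {
    vapply(1:60, function(i) {
      n <- 120
      coh <- data.frame(age = sample(8:92, n, TRUE),
                        sex = sample(c("M", "F"), n, TRUE))
      coh$att <- rnorm(n, 1300, 150)
      coh$kw <- rnorm(n, 110, 20)          # independent of att
      regional_association(coh, "kw", "att", strata = list(c(8, 93)))$p
    }, numeric(1))
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
  expect_lte(mean(pvals < 0.05), 0.15)

  coh <- data.frame(age = rep(30, 30), sex = rep(c("M", "F"), 15))
  coh$x <- as.numeric(coh$sex == "M")      # perfectly collinear with sex
  coh$kw <- rnorm(30)
  expect_error(regional_association(coh, "kw", "x",
                                    strata = list(c(8, 93))), "collinear")
})

test_that("fitted models serialize to JSON and predict on new data", {
  coh <- generate_cohort(gm_kw_preset(), seed = 9)
  fit <- mars_fit(coh, "kw")
  path <- tempfile(fileext = ".json")
  write_mars_json(fit, path)
  js <- jsonlite::read_json(path)
  expect_equal(js$response, "kw")
  expect_equal(js$cv_r2, fit$cv_r2, tolerance = 1e-12)

  nd <- data.frame(age = c(30, 70), sex = c("F", "M"))
  pr <- predict(fit, nd)
  expect_length(pr, 2)
  expect_true(all(is.finite(pr)))
})
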