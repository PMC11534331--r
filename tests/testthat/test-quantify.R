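# Differencing, PCA noise reduction, map-level inversions, TV
# regularization, and the end-to-end noise-free identity.

proto <- asl_protocol()

make_series <- function(dM_by_cond, nrep = 6, m0val = 100, noise = 0,
                        seed = 1) {
  shape <- dim(dM_by_cond[[1]]$dM)
  m0 <- array(m0val, shape)
  conds <- with_seed(seed, lapply(dM_by_cond, function(cd) {
    vols <- array(0, c(shape, 2 * nrep))
    for (r in seq_len(nrep)) {
      vols[, , , 2 * r - 1] <- m0 * (1 + cd$dM / 2) +
        array(stats::rnorm(prod(shape), 0, noise * m0val), shape)
      vols[, , , 2 * r] <- m0 * (1 - cd$dM / 2) +
        array(stats::rnorm(prod(shape), 0, noise * m0val), shape)
    }
    list(pld = cd$pld, b = cd$b, volumes = vols)
  }))
  asl_series(conds, m0)
}

test_that("differencing: control == label gives zero; known offsets give
          the arithmetic mean; zero M0 is flagged missing, not NaN", {
  shape <- c(4, 4, 2)
  dM <- array(0, shape)
  ser <- make_series(list(list(pld = 1.8, b = 0, dM = dM)))
  d <- compute_diff(ser)[[1]]
  expect_equal(max(abs(d$mean)), 0)

  # per-pair offsets vary by repeat: the mean map must equal their mean
  m0 <- array(50, shape)
  offsets <- c(0.002, 0.004, 0.009, 0.001)
  vols <- array(0, c(shape, 8))
  for (r in 1:4) {
    vols[, , , 2 * r - 1] <- m0 * (1 + offsets[r])
    vols[, , , 2 * r] <- m0
  }
  m0[2, 3, 1] <- 0
  ser2 <- asl_series(list(list(pld = 1.8, b = 0, volumes = vols)), m0)
  d2 <- compute_diff(ser2)[[1]]
  expect_equal(d2$mean[1, 1, 1], mean(offsets), tolerance = 1e-12)
  expect_true(is.na(d2$mean[2, 3, 1]))
  expect_true(has_flag(d2$flags[2, 3, 1], "missing"))
  expect_false(any(is.nan(d2$mean)))

  vols_odd <- array(1, c(shape, 5))
  expect_error(asl_series(list(list(pld = 1.8, b = 0, volumes = vols_odd)),
                          m0), "pairs")
})

test_that("label-first interleave flips the sign convention", {
  shape <- c(3, 3, 2)
  dM <- array(0.01, shape)
  ser <- make_series(list(list(pld = 1.8, b = 0, dM = dM)))
  d_cf <- compute_diff(ser)[[1]]$mean
  ser$interleave <- "label-first"
  d_lf <- compute_diff(ser)[[1]]$mean
  expect_equal(d_lf, -d_cf)
})

test_that("PCA denoising strips a dominant artifact component, is the
          identity at retain_fraction 1, and always preserves the
          repeat mean", {
  shape <- c(5, 5, 2)
  nrep <- 10
  nvox <- prod(shape)
  mean_map <- array(0.01, shape)
  set.seed(11)
  v <- rnorm(nvox); v <- v / sqrt(sum(v^2))
  a <- rnorm(nrep, 0, 0.05); a <- a - mean(a)    # zero-mean repeat loading
  noise <- array(rnorm(nvox * nrep, 0, 1e-4), c(shape, nrep))
  stack <- noise
  for (r in seq_len(nrep))
    stack[, , , r] <- stack[, , , r] + mean_map + a[r] * array(v, shape)

  expect_identical(pca_denoise(stack, 1), stack)
  expect_error(pca_denoise(stack, 0), "retain_fraction")

  den <- pca_denoise(stack, 0.8)
  # repeat mean untouched
  expect_lt(max(abs(apply(den, 1:3, mean) - apply(stack, 1:3, mean))),
            1e-10)
  # artifact energy: projection of the residual onto the artifact pattern
  energy <- function(s) {
    R <- matrix(aperm(sweep(s, 1:3, apply(s, 1:3, mean)), c(4, 1, 2, 3)),
                nrow = nrep)
    sum((R %*% v)^2)
  }
  expect_lt(energy(den), 0.1 * energy(stack))

  white <- array(rnorm(nvox * nrep), c(shape, nrep))
  dw <- pca_denoise(white, 0.5)
  expect_equal(apply(dw, 1:3, mean), apply(white, 1:3, mean),
               tolerance = 1e-12)
})

test_that("ATT map: unit ratio hits the floor; noise-free fields recover
          within 1 ms; 2% ratio noise keeps the median within 25 ms", {
  truth <- array(seq(1000, 2200, length.out = 64), c(4, 4, 4))
  unc <- array(buxton_forward(physio_state(1, 500, 0), proto, 0.9),
               dim(truth))
  cru <- array(buxton_forward(physio_state(1, as.vector(truth), 0),
                              proto, 0.9), dim(truth))
  m <- map_att(unc, cru, proto, 0.9)
  expect_lt(max(abs(m$att - truth)), 1)

  ones <- array(1, c(3, 3, 1))
  m1 <- map_att(ones, ones, proto, 0.9)
  expect_true(all(m1$att == 500))

  # Monte-Carlo: 100 voxels at 1400 ms, 2% Gaussian noise on both maps
  set.seed(42)
  tr <- array(1400, c(10, 10, 1))
  unc2 <- array(buxton_forward(physio_state(1, 500, 0), proto, 0.9),
                dim(tr))
  cru2 <- array(buxton_forward(physio_state(1, 1400, 0), proto, 0.9),
                dim(tr))
  sd2 <- 0.02 * mean(unc2)
  mn <- map_att(unc2 + array(rnorm(100, 0, sd2), dim(tr)),
                cru2 + array(rnorm(100, 0, sd2), dim(tr)), proto, 0.9)
  expect_lt(abs(median(mn$att) - 1400), 25)

  neg <- map_att(array(-1, c(2, 2, 1)), array(0.5, c(2, 2, 1)), proto, 0.9)
  expect_true(all(is.na(neg$att)))
  expect_true(all(has_flag(neg$flags, "missing")))
})

test_that("CBF map: zero difference gives zero flow; noise-free round trip
          is exact; the two modes differ by the arrival factor only", {
  truth <- array(seq(20, 90, length.out = 27), c(3, 3, 3))
  att <- array(1200, dim(truth))
  dm <- array(buxton_forward(physio_state(as.vector(truth), 1200, 0),
                             proto, 1.8), dim(truth))
  m <- map_cbf(dm, att, proto, 1.8)
  expect_lt(max(abs(m$cbf - truth)), 1e-6)
  expect_true(all(map_cbf(array(0, c(2, 2, 1)), array(1200, c(2, 2, 1)),
                          proto, 1.8)$cbf == 0))

  # with att > pld the bolus is partial: the att-aware estimate equals the
  # closed-form estimate times the analytic arrival factor
  att_long <- 2000
  dml <- buxton_forward(physio_state(55, att_long, 0), proto, 1.8)
  aware <- as.numeric(buxton_invert_cbf(dml, att_long, proto, 1.8))
  wp <- as.numeric(buxton_invert_cbf(dml, proto = proto, pld = 1.8,
                                     mode = "white-paper"))
  unit_aware <- buxton_forward(physio_state(1, att_long, 0), proto, 1.8)
  unit_wp <- 2 * proto$label_eff * proto$t1_blood *
    (1 - exp(-proto$label_dur / proto$t1_blood)) *
    exp(-1.8 / proto$t1_blood) / (6000 * proto$lambda_part)
  expect_equal(aware / wp, unit_wp / unit_aware, tolerance = 1e-12)
  expect_equal(aware, 55, tolerance = 1e-9)
})

test_that("kw map: zero ratio gives zero exchange; noise-free round trip
          within 0.05/min; TV regularization lowers the phantom RMSE", {
  shape <- c(8, 8, 2)
  kw_truth <- array(80, shape)
  kw_truth[5:8, , ] <- 140                       # piecewise-constant phantom
  att <- array(1300, shape)
  unc <- array(buxton_forward(physio_state(50, 1300, 0), proto, 1.8),
               shape)
  A_true <- array(spa_ratio(physio_state(50, as.vector(att),
                                         as.vector(kw_truth)), proto, 1.8),
                  shape)
  cru <- unc * A_true
  m0k <- map_kw(unc, cru, att, proto = proto, pld = 1.8)
  expect_lt(max(abs(m0k$kw - kw_truth)), 0.05)

  zz <- map_kw(unc, array(0, shape), att, proto = proto, pld = 1.8)
  expect_true(all(zz$kw == 0))

  set.seed(7)
  noise <- function() array(rnorm(prod(shape), 0, 0.03 * mean(unc)), shape)
  unc_n <- unc + noise(); cru_n <- cru + noise()
  plain <- map_kw(unc_n, cru_n, att, proto = proto, pld = 1.8)
  regd <- map_kw(unc_n, cru_n, att, proto = proto, pld = 1.8,
                 reg_weight = 0.03)
  rmse <- function(k) sqrt(mean((k - kw_truth)^2))
  expect_lt(rmse(regd$kw), rmse(plain$kw))
})

test_that("TV regularization: identity at zero weight, fixed point on
          constants, exact on the 1-D dual-QP oracle, mean preserved", {
  set.seed(3)
  f <- c(rep(0, 12), rep(1, 12)) + rnorm(24, 0, 0.1)
  f1 <- array(f, length(f))
  expect_identical(tv_regularize(f1, 0), f1)
  cst <- array(4.2, c(3, 4, 2))
  expect_equal(tv_regularize(cst, 2), cst)

  u <- tv_regularize(f1, 0.3, max_iter = 20000, tol = 1e-12)
  expect_lt(max(abs(u - tv1d_qp_oracle(f, 0.3))), 1e-4)
  expect_lte(sum(abs(diff(as.vector(u)))), sum(abs(diff(f))))
  expect_lt(abs(mean(u) - mean(f)) / abs(mean(f)), 1e-6)

  expect_warning(tv_regularize(f1, 0.3, max_iter = 2), "converge")
  expect_error(tv_regularize(f1, -1), "weight")
})

test_that("end-to-end noise-free identity over heterogeneous truth fields,
          with masked voxels never finite", {
  pm <- generate_parameter_maps(
    list(kw = c(95, 130), cbf = c(35, 60), att = c(1250, 1600)),
    shape = c(10, 10, 4), smoothness = 1.5, spatial_cv = 0.06, seed = 21)
  mask <- array(TRUE, c(10, 10, 4)); mask[1, 1, 1] <- FALSE
  ser <- generate_dp_pcasl_signals(pm$maps, proto, noise_sd = 0,
                                   mask = mask, seed = 4)
  ser$m0[2, 1, 1] <- 0                    # invalid M0 voxel
  ser$mask[2, 1, 1] <- FALSE
  q <- quantify_series(ser, proto)
  inm <- q$mask
  expect_lt(max(abs(q$cbf - pm$maps$cbf)[inm]), 1e-3)
  expect_lt(max(abs(q$att - pm$maps$att)[inm]), 1)
  expect_lt(max(abs(q$kw - pm$maps$kw)[inm]), 0.1)
  expect_true(all(is.na(q$cbf[!inm]) & is.na(q$att[!inm]) &
                    is.na(q$kw[!inm])))
  expect_true(all(has_flag(q$flags[!ser$mask], "missing")))
  expect_equal(unname(q$log["n_missing"]), 2)
})

test_that("parameter maps survive a NIfTI round trip", {
  pm <- generate_parameter_maps(
    list(kw = 100, cbf = 50, att = 1400), shape = c(6, 6, 3),
    smoothness = 1, spatial_cv = 0.05, seed = 5)
  ser <- generate_dp_pcasl_signals(pm$maps, proto, noise_sd = 0, seed = 5)
  q <- quantify_series(ser, proto)
  dir <- tempfile()
  write_parameter_maps(q, dir)
  q2 <- read_parameter_maps(dir)
  expect_equal(q2$kw, q$kw, tolerance = 1e-6)
  expect_equal(q2$att, q$att, tolerance = 1e-6)
  expect_identical(q2$flags, q$flags)
})
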