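# Independent numerical oracles used across the suite.

# Two-compartment delivery/exchange/relaxation system integrated with
# deSolve's classical 4th-order Runge-Kutta, piecewise over the bolus
# breakpoints so the integrator never steps across a discontinuity.
# Independent of the package's closed-form solution.
ode_compartments <- function(cbf, att_ms, kw_min, pld,
                             proto = asl_protocol(), r1t = NULL,
                             steps = 800) {
  tau <- proto$label_dur
  r1b <- 1 / proto$t1_blood
  if (is.null(r1t)) r1t <- 1 / proto$t1_tissue
  delta <- att_ms / 1000
  k <- kw_min / 60
  Fs <- cbf / (6000 * proto$lambda_part)
  inflow <- 2 * proto$label_eff * Fs * exp(-delta * r1b)
  t_end <- pld + tau
  rhs <- function(t, y, parms) {
    inp <- if (parms$on) inflow else 0
    list(c(inp - (r1b + k) * y[1], k * y[1] - r1t * y[2]))
  }
  y <- c(0, 0)
  breaks <- sort(unique(pmin(pmax(c(0, delta, delta + tau, t_end), 0),
                             t_end)))
  for (i in seq_len(length(breaks) - 1)) {
    t0 <- breaks[i]; t1 <- breaks[i + 1]
    if (t1 <= t0) next
    on <- t0 >= delta - 1e-12 && t1 <= delta + tau + 1e-12
    sol <- deSolve::ode(y, seq(t0, t1, length.out = steps),
                        rhs, list(on = on), method = "rk4")
    y <- as.numeric(sol[nrow(sol), 2:3])
  }
  list(cap = y[1], tis = y[2], total = sum(y))
}

# scalar bisection inversion of feast_ratio, independent of the package's
# lookup-table path
bisect_att <- function(r, proto = asl_protocol(), pld = 0.9, tol = 1e-4) {
  lo <- proto$att_floor * 1000
  hi <- (proto$label_dur + pld) * 1000 - 1
  f <- function(a) feast_ratio(a, proto, pld) - r
  if (f(lo) < 0) return(lo)
  if (f(hi) > 0) return(hi)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# naive recursive flood fill (reference for label_components)
flood_fill_sizes <- function(x, connectivity = 6) {
  d <- dim(x)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nz <- rowSums(abs(offs))
  offs <- switch(as.character(connectivity),
                 "6" = offs[nz == 1, , drop = FALSE],
                 "18" = offs[nz >= 1 & nz <= 2, , drop = FALSE],
                 "26" = offs[nz >= 1, , drop = FALSE])
  seen <- array(FALSE, d)
  sizes <- integer(0)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!x[i, j, k] || seen[i, j, k]) next
    queue <- matrix(c(i, j, k), ncol = 3)
    seen[i, j, k] <- TRUE
    size <- 0L
    while (nrow(queue)) {
      cur <- queue[1, , drop = FALSE]
      queue <- queue[-1, , drop = FALSE]
      size <- size + 1L
      for (o in seq_len(nrow(offs))) {
        nb <- cur + offs[o, ]
        if (any(nb < 1) || any(nb > d)) next
        if (x[nb[1], nb[2], nb[3]] && !seen[nb[1], nb[2], nb[3]]) {
          seen[nb[1], nb[2], nb[3]] <- TRUE
          queue <- rbind(queue, nb)
        }
      }
    }
    sizes <- c(sizes, size)
  }
  sizes
}

# exact 1-D TV-L2 solution through the dual box-constrained QP,
# solved by L-BFGS-B (independent of the primal-dual implementation)
tv1d_qp_oracle <- function(f, w) {
  n <- length(f)
  D <- diff(diag(n))
  obj <- function(p) { r <- f - drop(t(D) %*% p); 0.5 * sum(r^2) }
  gr <- function(p) { r <- f - drop(t(D) %*% p); -drop(D %*% r) }
  o <- stats::optim(rep(0, n - 1), obj, gr, method = "L-BFGS-B",
                    lower = -w, upper = w,
                    control = list(maxit = 5000, factr = 10))
  f - drop(t(D) %*% o$par)
}

# small helper: oldest-age-segment slope row of a mars fit
oldest_segment <- function(fit) {
  seg <- fit$segments
  seg <- seg[seg$age_hi == max(seg$age_hi), ]
  seg[nrow(seg), ]
}
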