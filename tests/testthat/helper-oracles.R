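# Independent oracles used across the suite. These deliberately re-derive
# everything from first principles (plain formulas, quadrature, ODE
# integration, exhaustive enumeration) so they share no code path with the
# package internals they check.

# mLDRW density written out directly from the closed form
oracle_mldrw <- function(t, alpha, mu, t0, kappa) {
  s <- pmax(t - t0, .Machine$double.eps)
  out <- alpha * sqrt(kappa / (2 * pi * s)) *
    exp(-kappa * (s - mu)^2 / (2 * s))
  out[t <= t0] <- 0
  out
}

# adaptive quadrature of the running integral of the mLDRW bolus
oracle_cumfree <- function(t, alpha, mu, t0, kappa) {
  sapply(t, function(tt) {
    if (tt <= t0) return(0)
    stats::integrate(oracle_mldrw, lower = t0, upper = tt, alpha = alpha,
                     mu = mu, t0 = t0, kappa = kappa,
                     rel.tol = 1e-10, abs.tol = 1e-12)$value
  })
}

# total-concentration oracle: integrate the bound-compartment ODE
# dCb/dt = k_b * C_f(t) driven by the mLDRW bolus, then add the free term
oracle_fpb_ode <- function(times, alpha, mu, t0, kappa, k_b) {
  rhs <- function(t, state, parms) {
    list(k_b * oracle_mldrw(t, alpha, mu, t0, kappa))
  }
  grid <- sort(unique(c(0, times)))
  sol <- deSolve::lsoda(c(Cb = 0), grid, rhs, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
  cb <- sol[match(times, sol[, "time"]), "Cb"]
  oracle_mldrw(times, alpha, mu, t0, kappa) + cb
}

# exact two-sided rank-sum p-value by enumeration of all group assignments
oracle_rank_sum_p <- function(x, y) {
  pooled <- c(x, y)
  m <- length(x)
  u_of <- function(idx) {
    xs <- pooled[idx]; ys <- pooled[-idx]
    sum(outer(xs, ys, ">"))
  }
  u_obs <- sum(outer(x, y, ">"))
  us <- apply(utils::combn(length(pooled), m), 2, u_of)
  p_lo <- mean(us <= u_obs)
  p_hi <- mean(us >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# exact two-sided signed-rank p-value by enumeration of all sign patterns
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(signs %*% r)
  min(1, 2 * min(mean(vs <= v_obs), mean(vs >= v_obs)))
}

# central finite-difference Jacobian of the FPB model
oracle_fd_jacobian <- function(times, par, h = 1e-6) {
  f <- function(p) usmikb:::fpb_value(times, p[1], p[2], p[3], p[4], p[5])
  J <- matrix(0, length(times), length(par))
  for (j in seq_along(par)) {
    step <- h * max(abs(par[j]), 1)
    up <- par; up[j] <- up[j] + step
    dn <- par; dn[j] <- dn[j] - step
    J[, j] <- (f(up) - f(dn)) / (2 * step)
  }
  J
}

# build a clean (optionally speckled) TIC from known FPB parameters
make_tic <- function(alpha = 2e5, mu = 25, t0 = 10, kappa = 0.5,
                     k_b = 0.01, t_flash = 240, duration = 300,
                     snr_db = NULL, quantize = FALSE, seed = NULL) {
  tt <- seq(0, duration - 1)
  y <- usmikb:::fpb_value(tt, alpha, mu, t0, kappa, k_b)
  if (!is.null(snr_db)) {
    if (!is.null(seed)) set.seed(seed)
    shape <- 10^(snr_db / 10)
    y <- y * rgamma(length(y), shape, shape)
  }
  tic(tt, compress_gray(y, quantize = quantize), t_flash = t_flash)
}
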