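test_that("TIC smoothing has unit DC gain and suppresses speckle", {
  tt <- 0:299
  flat <- tic(tt, rep(50, 300), t_flash = 240)
  expect_equal(smooth_tic(flat)$linear, flat$linear)

  # kernel mass: an impulse spreads but sums to 1
  imp <- c(rep(0, 20), 1, rep(0, 20))
  expect_equal(sum(usmikb:::moving_average(imp, 5)), 1)

  clean <- usmikb:::fpb_value(tt, 2e5, 25, 10, 0.5, 0.01)
  set.seed(21)
  noisy <- clean * rgamma(300, 100, 100)
  x <- tic(tt, compress_gray(noisy), t_flash = 240)
  rms <- function(v) sqrt(mean(v^2))
  expect_gt(rms(noisy - clean) / rms(smooth_tic(x)$linear - clean), 2)

  expect_error(smooth_tic(tic(0:3, rep(1, 4), t_flash = 2)),
               class = "usmikb_invalid_input")
})

test_that("R^2 follows the 1 - SS_res/SS_tot definition", {
  obs <- c(3, 1, 4, 1, 5, 9, 2, 6)
  expect_equal(r_squared(obs, obs), 1)
  expect_equal(r_squared(obs, rep(mean(obs), 8)), 0)
  fitted <- obs + c(0.5, -0.2, 0.1, 0, -0.4, 0.2, 0.3, -0.1)
  expect_equal(r_squared(obs, fitted),
               1 - sum((obs - fitted)^2) / sum((obs - mean(obs))^2))
  expect_warning(expect_true(is.na(r_squared(rep(2, 5), 1:5))))
})

test_that("analytic model Jacobian matches finite differences", {
  tt <- seq(0, 60, 1)
  for (par in list(c(100, 25, 10, 0.5, 0.01),
                   c(5e4, 15, 3, 2, 0.05),
                   c(1e3, 40, 0, 0.1, 0))) {
    J <- usmikb:::fpb_jacobian(tt, par[1], par[2], par[3], par[4], par[5])
    Jfd <- oracle_fd_jacobian(tt, par)
    scale <- pmax(abs(Jfd), max(abs(Jfd)) * 1e-6)
    expect_lt(max(abs(J - Jfd) / scale), 1e-4)
  }
})

test_that("noiseless TICs are recovered essentially exactly", {
  x <- make_tic(alpha = 2e5, mu = 25, t0 = 10, kappa = 0.5, k_b = 0.01)
  fit <- fit_fpb(x)
  expect_true(fit$converged)
  truth <- c(2e5, 25, 10, 0.5, 0.01)
  est <- with(fit$params, c(alpha, mu, t0, kappa, k_b))
  expect_lt(max(abs(est - truth) / truth), 0.005)
  expect_gt(fit$r_squared, 0.9999)
  expect_equal(tidy(fit)$estimate[tidy(fit)$term == "k_b"],
               fit$params$k_b * 60)

  # null binding stays at (numerically) zero
  x0 <- make_tic(k_b = 0)
  expect_lt(fit_fpb(x0)$params$k_b, 1e-4)
})

test_that("random in-bounds ground truths are recovered without noise", {
  set.seed(31)
  n_ok <- 0
  n_sets <- 50
  for (i in seq_len(n_sets)) {
    truth <- c(alpha = 10^runif(1, 4, 6), mu = runif(1, 10, 40),
               t0 = runif(1, 2, 20), kappa = runif(1, 0.2, 2),
               k_b = runif(1, 0.002, 0.05))
    x <- make_tic(truth[1], truth[2], truth[3], truth[4], truth[5])
    fit <- fit_fpb(x)
    if (fit$converged &&
        abs(fit$params$k_b - truth[5]) / truth[5] < 0.01) n_ok <- n_ok + 1
  }
  expect_gte(n_ok / n_sets, 0.95)
})

test_that("fitted amplitude scales with the TIC; shape parameters do not", {
  tt <- 0:299
  y <- usmikb:::fpb_value(tt, 1e5, 22, 8, 0.7, 0.015)
  f1 <- fit_fpb(tic(tt, compress_gray(y), t_flash = 240))
  f2 <- fit_fpb(tic(tt, compress_gray(4 * y), t_flash = 240))
  expect_equal(unname(f2$params$alpha / f1$params$alpha), 4,
               tolerance = 1e-3)
  for (nm in c("mu", "t0", "kappa", "k_b")) {
    expect_equal(unname(f2$params[[nm]]), unname(f1$params[[nm]]),
                 tolerance = 1e-3)
  }
})

test_that("the fit never sees post-burst samples and handles bad input", {
  x <- make_tic()
  fit <- fit_fpb(x, window = 60)
  expect_true(all(fit$data$time <= 60))
  expect_true(max(fit$data$time) < attr(x, "t_flash"))

  expect_error(fit_fpb(x, window = 250), class = "usmikb_invalid_input")

  flat <- tic(0:299, rep(40, 300), t_flash = 240)
  dfit <- fit_fpb(flat)
  expect_false(dfit$converged)
  expect_null(dfit$params)
  expect_match(dfit$message, "degenerate")

  short <- tic(seq(0, 290, by = 10), rep(c(1, 5), 15)[1:30], t_flash = 240)
  expect_error(fit_fpb(short, window = 60), class = "usmikb_invalid_input")
})

test_that("speckle noise leaves the binding-rate estimate usable", {
  set.seed(41)
  errs <- replicate(30, {
    x <- make_tic(snr_db = 20, quantize = TRUE)
    fit <- fit_fpb(x)
    abs(fit$params$k_b - 0.01) / 0.01
  })
  expect_lt(median(errs), 0.15)
})
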