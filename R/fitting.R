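#' Low-pass filter a TIC
#'
#' Zero-phase moving average of the linearized intensity (default 5 samples
#' at 1 Hz), with edge replication so the filter has exactly unit DC gain
#' everywhere: a constant curve passes through unchanged. Used for display
#' and for the fit initialization heuristics; the least-squares fit itself
#' runs on the raw linearized samples unless asked otherwise.
#'
#' @param tic A [tic()] object with >= 5 samples.
#' @param width Filter width in samples (odd; even values are rounded up).
#' @return The TIC with its `linear` column replaced by the filtered curve
#'   and `gray` recomputed to match.
#' @export
smooth_tic <- function(tic, width = 5) {
  if (nrow(tic) < 5L) {
    abort("TIC too short to filter (need >= 5 samples).",
          class = "usmikb_invalid_input")
  }
  sm <- moving_average(tic$linear, width)
  tic$linear <- sm
  tic$gray <- compress_gray(sm, attr(tic, "dynamic_range", exact = TRUE))
  tic
}

# centred (zero-phase) moving average with edge replication; kernel mass 1
moving_average <- function(x, width) {
  width <- as.integer(width)
  if (width %% 2L == 0L) width <- width + 1L
  if (width <= 1L) return(x)
  half <- (width - 1L) %/% 2L
  n <- length(x)
  padded <- c(rep(x[1L], half), x, rep(x[n], half))
  as.numeric(stats::filter(padded, rep(1 / width, width), sides = 2))[
    (half + 1L):(half + n)]
}

#' Coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot` of a fitted curve against observations.
#'
#' @param observed,fitted Equal-length numeric vectors (>= 2 samples).
#' @return Scalar R^2 (<= 1); `NA` with a warning when the observations are
#'   constant, where R^2 is undefined.
#' @export
r_squared <- function(observed, fitted) {
  if (length(observed) != length(fitted) || length(observed) < 2L) {
    abort("`observed` and `fitted` must have equal length >= 2.",
          class = "usmikb_invalid_input")
  }
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    warn("R^2 undefined for a constant observed curve; returning NA.")
    return(NA_real_)
  }
  1 - sum((observed - fitted)^2) / ss_tot
}

#' Control settings for FPB fitting
#'
#' @param maxiter Maximum optimizer iterations, default 400.
#' @param ftol,ptol Relative cost / step convergence tolerances, default 1e-8.
#' @param smooth_width Moving-average width used by the initialization
#'   heuristics, default 5 samples.
#' @return A list of settings for [fit_fpb()].
#' @export
fpb_fit_control <- function(maxiter = 400, ftol = 1e-8, ptol = 1e-8,
                            smooth_width = 5) {
  list(maxiter = maxiter, ftol = ftol, ptol = ptol,
       smooth_width = smooth_width)
}

#' Fit the first-pass binding model to one TIC
#'
#' Estimates `{alpha, mu, t0, kappa, k_b}` by bounded nonlinear least
#' squares (Levenberg-Marquardt with box constraints and the analytic model
#' Jacobian) on the linearized intensity of the first `window` seconds of
#' the wash-in — the first pass only, so recirculation and the destructive
#' burst never enter the fit.
#'
#' Bounds: `alpha` in (0, 10 x curve area\], `mu` in \[1, 120\] s, `t0` in
#' \[0, first-peak time\], `kappa` in \[1e-3, 1e3\] 1/s, `k_b` in \[0, 1\]
#' 1/s. Starting values come from the smoothed curve: `t0` where it first
#' exceeds 5 % of its maximum, `mu` from peak time minus `t0`, `alpha` from
#' the trapezoidal area, `kappa = 1`, `k_b` from the end-of-window level
#' over `alpha`.
#'
#' @param tic A [tic()] object.
#' @param window Fit window length (s), default 60; must end before
#'   `t_flash` and contain >= 20 samples.
#' @param presmooth Fit the low-pass filtered curve instead of the raw one?
#'   Default `FALSE`.
#' @param multi_start Also try 3 randomly perturbed starting points and keep
#'   the best sum of squares? Default `FALSE`.
#' @param seed Optional seed for the multi-start perturbations.
#' @param control A [fpb_fit_control()] list.
#' @return An object of class `fpb_fit`: fields `params` ([fpb_params()] or
#'   `NULL` when degenerate), `r_squared`, `converged`, `n_samples`,
#'   `residual_norm`, and the fitted curve in `$data`. Optimizer failure is
#'   reported via `converged = FALSE`, never an error. [tidy()] and
#'   [glance()] methods give broom-style summaries (`k_b` tidied in 1/min).
#' @examples
#' p <- fpb_params(alpha = 2e5, mu = 25, t0 = 10, kappa = 0.5, k_b = 0.01)
#' y <- fpb_concentration(0:299, p)$value
#' x <- tic(0:299, compress_gray(y), t_flash = 240)
#' fit <- fit_fpb(x)
#' tidy(fit)
#' @export
fit_fpb <- function(tic, window = 60, presmooth = FALSE, multi_start = FALSE,
                    seed = NULL, control = fpb_fit_control()) {
  tf <- t_flash_of(tic)
  if (window > tf) {
    abort("Fit window overlaps the destructive burst.",
          class = "usmikb_invalid_input")
  }
  sel <- tic$time <= window
  t_fit <- tic$time[sel]
  y <- if (presmooth) smooth_tic(tic, control$smooth_width)$linear[sel]
       else tic$linear[sel]
  n <- length(y)
  if (n < 20L) {
    abort("Need >= 20 samples inside the fit window.",
          class = "usmikb_invalid_input")
  }
  core <- fpb_fit_core(t_fit, y, control, multi_start = multi_start,
                       seed = seed)
  if (is.null(core$par)) {
    return(new_fpb_fit(NULL, NA_real_, FALSE, n, NA_real_, t_fit, y,
                       fitted = rep(NA_real_, n), message = core$message))
  }
  p <- core$par
  params <- fpb_params(alpha = p[1], mu = p[2], t0 = p[3], kappa = p[4],
                       k_b = p[5])
  fitted <- fpb_value(t_fit, p[1], p[2], p[3], p[4], p[5])
  new_fpb_fit(params, r_squared(y, fitted), core$converged, n,
              sqrt(core$deviance), t_fit, y, fitted, message = core$message)
}

# shared fitting core: bounded Levenberg-Marquardt on one linearized curve.
# Returns list(par, converged, deviance, message); par = NULL when the curve
# is degenerate or the optimizer fails outright.
fpb_fit_core <- function(t_fit, y, control = fpb_fit_control(),
                         multi_start = FALSE, seed = NULL) {
  n <- length(y)
  if (diff(range(y)) == 0) {
    return(list(par = NULL, converged = FALSE, deviance = NA_real_,
                message = "degenerate TIC: all samples equal"))
  }
  ys <- moving_average(y, control$smooth_width)
  peak_t <- t_fit[which.max(ys)]
  t0_init <- t_fit[which(ys > 0.05 * max(ys))[1L]]
  if (!is.finite(t0_init) || t0_init >= peak_t) t0_init <- max(peak_t - 1, 0)
  area <- sum(diff(t_fit) * (head(y, -1) + tail(y, -1)) / 2)
  lower <- c(alpha = area * 1e-6, mu = 1, t0 = 0, kappa = 1e-3, k_b = 0)
  upper <- c(alpha = 10 * area, mu = 120, t0 = max(peak_t, 1e-3),
             kappa = 1e3, k_b = 1)
  init <- c(alpha = area, mu = max(peak_t - t0_init, 1), t0 = t0_init,
            kappa = 1, k_b = min(max(y[n] / area, 0), 1))
  init <- pmin(pmax(init, lower), upper)

  starts <- list(init)
  if (multi_start) {
    starts <- c(starts, with_seed(seed, lapply(1:3, function(i) {
      p <- init * exp(rnorm(5, 0, c(0.3, 0.3, 0, 0.5, 0.3)))
      p["t0"] <- init["t0"] * runif(1, 0.5, 1.5)
      pmin(pmax(p, lower), upper)
    })))
  }

  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = st, lower = lower, upper = upper,
        fn = function(p) y - fpb_value(t_fit, p[1], p[2], p[3], p[4], p[5]),
        jac = function(p) -fpb_jacobian(t_fit, p[1], p[2], p[3], p[4], p[5]),
        control = minpack.lm::nls.lm.control(
          maxiter = control$maxiter, ftol = control$ftol,
          ptol = control$ptol)),
      error = function(e) NULL)
    if (!is.null(fit) &&
        (is.null(best) || fit$deviance < best$deviance)) best <- fit
  }
  if (is.null(best)) {
    return(list(par = NULL, converged = FALSE, deviance = NA_real_,
                message = "optimizer failed"))
  }
  list(par = best$par, converged = best$info %in% 1:4,
       deviance = best$deviance, message = best$message)
}

new_fpb_fit <- function(params, r2, converged, n, residual_norm,
                        time, observed, fitted, message = "") {
  structure(list(params = params, r_squared = r2, converged = converged,
                 n_samples = n, residual_norm = residual_norm,
                 data = tibble(time = time, observed = observed,
                               fitted = fitted),
                 message = message),
            class = "fpb_fit")
}

#' @export
print.fpb_fit <- function(x, ...) {
  cat("<fpb_fit> ", if (x$converged) "converged" else "NOT converged",
      sprintf(" (n = %d, R^2 = %.3f)\n", x$n_samples, x$r_squared))
  if (!is.null(x$params)) print(x$params)
  invisible(x)
}

#' @rdname fit_fpb
#' @param x An `fpb_fit` object.
#' @param ... Unused.
#' @method tidy fpb_fit
#' @export
tidy.fpb_fit <- function(x, ...) {
  if (is.null(x$params)) {
    return(tibble(term = character(), estimate = numeric(),
                  unit = character()))
  }
  p <- x$params
  tibble(term = c("alpha", "mu", "t0", "kappa", "k_b"),
         estimate = c(p$alpha, p$mu, p$t0, p$kappa, p$k_b * 60),
         unit = c("intensity*s", "s", "s", "1/s", "1/min"))
}

#' @rdname fit_fpb
#' @method glance fpb_fit
#' @export
glance.fpb_fit <- function(x, ...) {
  tibble(r_squared = x$r_squared, converged = x$converged,
         n_samples = x$n_samples, residual_norm = x$residual_norm)
}

# evaluate expr with a temporary RNG state when seed is given
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv())) set.seed(NULL)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
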