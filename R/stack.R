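# gray matrix (in-mask voxels x time) + voxel coordinates from a 4-D stack
mask_curves <- function(stack, mask) {
  d <- dim(stack)
  if (length(d) != 4L || !all(dim(mask) == d[1:3])) {
    abort("`stack` must be 4-D (x, y, plane, time) with a matching mask.",
          class = "usmikb_invalid_input")
  }
  nt <- d[4]
  idx <- which(mask)
  flat <- matrix(stack, nrow = prod(d[1:3]), ncol = nt)
  coords <- which(mask, arr.ind = TRUE)
  list(gray = flat[idx, , drop = FALSE],
       coords = tibble(x = coords[, 1], y = coords[, 2],
                       plane = coords[, 3]))
}

#' Semi-quantitative readouts for every tumor voxel
#'
#' Computes late enhancement (gray level nearest `t_flash - 40` s) and
#' differential targeted enhancement (mean pre-burst minus mean post-burst
#' gray level) for each in-mask voxel of a 4-D acquisition, using the same
#' window rules as [late_enhancement()] and
#' [differential_targeted_enhancement()].
#'
#' @param stack 4-D gray-level array (x, y, plane, time).
#' @param mask 3-D logical/0-1 array marking the tumor.
#' @param protocol An [acquisition_protocol()].
#' @return A tibble with one row per in-mask voxel: `x`, `y`, `plane`,
#'   `LE`, `dTE`.
#' @export
quantify_stack <- function(stack, mask, protocol = acquisition_protocol()) {
  mc <- mask_curves(stack, mask)
  times <- protocol_times(protocol)
  tf <- protocol$t_flash
  keep <- !(times >= tf & times <= tf + protocol$burst_duration)
  le_target <- tf - 40
  kept_idx <- which(keep)
  le_col <- kept_idx[which.min(abs(times[kept_idx] - le_target))]
  pre <- keep & times > tf - 130 & times < tf - 30
  post <- keep & times > tf + 30
  if (!any(pre) || !any(post)) {
    abort("Protocol leaves an empty dTE window.",
          class = "usmikb_invalid_input")
  }
  mc$coords %>%
    mutate(LE = mc$gray[, le_col],
           dTE = rowMeans(mc$gray[, pre, drop = FALSE]) -
             rowMeans(mc$gray[, post, drop = FALSE]))
}

#' Fit the FPB model to every tumor voxel
#'
#' Linearizes each in-mask voxel curve and fits the first-pass binding
#' model to the first `window` seconds (see [fit_fpb()] for the bounds and
#' initialization). Optimizer failures are flagged per voxel, never raised.
#'
#' @inheritParams quantify_stack
#' @param window Fit window (s), default 60.
#' @param multi_start,seed,control Passed to the fitting core; see
#'   [fit_fpb()].
#' @return A tibble with one row per in-mask voxel: coordinates, `alpha`,
#'   `mu`, `t0`, `kappa`, `k_b` (1/min), `r_squared`, `converged`.
#' @export
fit_stack <- function(stack, mask, protocol = acquisition_protocol(),
                      window = 60, multi_start = FALSE, seed = NULL,
                      control = fpb_fit_control()) {
  mc <- mask_curves(stack, mask)
  times <- protocol_times(protocol)
  if (window > protocol$t_flash) {
    abort("Fit window overlaps the destructive burst.",
          class = "usmikb_invalid_input")
  }
  sel <- times <= window
  t_fit <- times[sel]
  lin <- linearize(mc$gray[, sel, drop = FALSE], protocol$dynamic_range)
  nv <- nrow(lin)
  est <- matrix(NA_real_, nv, 6L,
                dimnames = list(NULL, c("alpha", "mu", "t0", "kappa",
                                        "k_b", "r_squared")))
  converged <- logical(nv)
  for (i in seq_len(nv)) {
    y <- lin[i, ]
    core <- fpb_fit_core(t_fit, y, control, multi_start = multi_start,
                         seed = if (is.null(seed)) NULL else seed + i)
    converged[i] <- core$converged
    if (!is.null(core$par)) {
      p <- core$par
      fitted <- fpb_value(t_fit, p[1], p[2], p[3], p[4], p[5])
      ss_tot <- sum((y - mean(y))^2)
      est[i, ] <- c(p[1], p[2], p[3], p[4], p[5] * 60,
                    if (ss_tot > 0) 1 - sum((y - fitted)^2) / ss_tot
                    else NA_real_)
    }
  }
  dplyr::bind_cols(mc$coords, as_tibble(est), tibble(converged = converged))
}

#' Whole-tumor summary of one acquisition
#'
#' Aggregates the per-voxel maps into one value per parameter using the
#' robust plane-median / volume-mean rule of [aggregate_parameter_map()].
#'
#' @param voxels A per-voxel tibble from [quantify_stack()] and/or
#'   [fit_stack()] (joined on the voxel coordinates), containing a `plane`
#'   column.
#' @param parameters Which columns to aggregate, default the USMI readouts
#'   present.
#' @return A one-row tibble with the volume-mean of each parameter and
#'   `prop_converged` when a `converged` column is present.
#' @export
summarize_acquisition <- function(voxels,
                                  parameters = intersect(
                                    c("k_b", "dTE", "LE"), names(voxels))) {
  out <- purrr::map(parameters, function(p) {
    volume_mean(aggregate_parameter_map(voxels, !!rlang::sym(p), plane))
  })
  res <- as_tibble(setNames(out, parameters))
  if ("converged" %in% names(voxels)) {
    res$prop_converged <- mean(voxels$converged)
  }
  res
}
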