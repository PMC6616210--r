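#' Construct a time-intensity curve
#'
#' A time-intensity curve (TIC) is the per-voxel contrast signal sampled over
#' an acquisition: log-compressed gray levels (0-255) on a ~1 Hz time base,
#' with the time of the high-MI destructive burst (`t_flash`) and the display
#' dynamic range recorded alongside. The linearized amplitude, used for
#' pharmacokinetic fitting, is derived with [linearize()].
#'
#' @param time Sample times (s), strictly increasing.
#' @param gray Gray levels in \[0, 255\] (need not be integer).
#' @param t_flash Burst time (s); must lie strictly inside the time span.
#' @param dynamic_range Display dynamic range (dB), default 52.
#' @param burst_duration Duration of the destructive burst (s), default 2.
#'   Samples inside `[t_flash, t_flash + burst_duration]` are saturated by
#'   the burst and are excluded from every analysis window.
#' @return A tibble of class `usmi_tic` with columns `time`, `gray`,
#'   `linear`, and attributes `t_flash`, `dynamic_range`, `burst_duration`.
#' @examples
#' tt <- 0:299
#' tic(tt, pmin(255, 30 + tt / 3), t_flash = 240)
#' @export
tic <- function(time, gray, t_flash, dynamic_range = 52, burst_duration = 2) {
  if (length(time) != length(gray)) {
    abort("`time` and `gray` must have the same length.",
          class = "usmikb_invalid_input")
  }
  if (any(diff(time) <= 0)) {
    abort("`time` must be strictly increasing.",
          class = "usmikb_invalid_input")
  }
  check_gray(gray)
  if (t_flash <= min(time) || t_flash >= max(time)) {
    abort("`t_flash` must lie strictly inside the sampled time span.",
          class = "usmikb_invalid_input")
  }
  out <- tibble(time = as.numeric(time), gray = as.numeric(gray),
                linear = linearize(gray, dynamic_range))
  structure(out, t_flash = t_flash, dynamic_range = dynamic_range,
            burst_duration = burst_duration,
            class = c("usmi_tic", class(out)))
}

check_gray <- function(gray) {
  if (!is.numeric(gray) || anyNA(gray) || any(gray < 0 | gray > 255)) {
    abort("Gray levels must be numeric in [0, 255].",
          class = "usmikb_invalid_input")
  }
  invisible(gray)
}

t_flash_of <- function(x) attr(x, "t_flash", exact = TRUE)
burst_duration_of <- function(x) {
  bd <- attr(x, "burst_duration", exact = TRUE)
  if (is.null(bd)) 2 else bd
}

# logical index of samples unaffected by the destructive burst
non_burst <- function(tic) {
  tf <- t_flash_of(tic)
  !(tic$time >= tf & tic$time <= tf + burst_duration_of(tic))
}

#' Linearize log-compressed gray levels
#'
#' Inverts the scanner's log compression to recover an amplitude
#' proportional to acoustic power (the accepted proxy for microbubble
#' concentration): `p = 10^((g / 255) * DR / 10)`. Gray 0 maps to 1
#' (the relative floor) and gray 255 to `10^(DR/10)`.
#'
#' @param gray Gray levels in \[0, 255\].
#' @param dynamic_range Dynamic range (dB), default 52.
#' @return Linear-power values, same length as `gray`.
#' @seealso [compress_gray()] for the exact inverse.
#' @export
linearize <- function(gray, dynamic_range = 52) {
  check_gray(gray)
  if (dynamic_range <= 0) {
    abort("`dynamic_range` must be positive.", class = "usmikb_invalid_input")
  }
  10^((gray / 255) * dynamic_range / 10)
}

#' Log-compress linear power to gray levels
#'
#' Exact inverse of [linearize()]: `g = 255 * 10*log10(p) / DR`, clamped to
#' \[0, 255\]. With `quantize = TRUE` (the display convention, used by the
#' synthetic stack generator) the result is rounded to integer gray levels.
#'
#' @param linear Linear-power values (>= 0; values below 1 clamp to gray 0).
#' @param dynamic_range Dynamic range (dB), default 52.
#' @param quantize Round to integer gray levels? Default `FALSE`.
#' @return Gray levels in \[0, 255\].
#' @export
compress_gray <- function(linear, dynamic_range = 52, quantize = FALSE) {
  if (any(linear < 0)) {
    abort("`linear` must be non-negative.", class = "usmikb_invalid_input")
  }
  g <- 255 * (10 * log10(pmax(linear, 1))) / dynamic_range
  g <- pmin(pmax(g, 0), 255)
  if (quantize) g <- round(g)
  g
}

#' Late enhancement of a TIC
#'
#' The late enhancement (LE) is the gray level at the empirically chosen
#' time `t_flash - offset` (default offset 40 s), late enough after
#' injection that the signal is dominated by bound microbubbles. The sample
#' nearest to the requested time is returned (no interpolation: at ~1 Hz
#' sub-sample interpolation adds nothing); an optional centred averaging
#' window is available.
#'
#' @param tic A [tic()] object.
#' @param offset Seconds before `t_flash` at which LE is read, default 40.
#' @param window Full width (s) of an optional averaging window around the
#'   target time; default 0 (single nearest sample).
#' @return LE in gray levels (scalar).
#' @export
late_enhancement <- function(tic, offset = 40, window = 0) {
  tf <- t_flash_of(tic)
  target <- tf - offset
  if (target < min(tic$time) || target > max(tic$time)) {
    abort("LE time point falls outside the sampled span.",
          class = "usmikb_invalid_input")
  }
  keep <- non_burst(tic)
  if (window > 0) {
    sel <- keep & abs(tic$time - target) <= window / 2
    if (!any(sel)) {
      abort("LE averaging window contains no samples.",
            class = "usmikb_invalid_input")
    }
    return(mean(tic$gray[sel]))
  }
  idx <- which(keep)
  tic$gray[idx[which.min(abs(tic$time[idx] - target))]]
}

#' Differential targeted enhancement of a TIC
#'
#' The differential targeted enhancement (dTE) isolates the bound-microbubble
#' signal by destroying the bubbles with a high-MI burst: it is the mean
#' gray level in the pre-burst window `(t_flash - 130, t_flash - 30)` minus
#' the mean gray level after `t_flash + 30` (replenished free bubbles only).
#' Positive dTE therefore indicates bound contrast. Burst-contaminated
#' samples are never included.
#'
#' @param tic A [tic()] object.
#' @param pre_window Offsets (s) before `t_flash` delimiting the pre-burst
#'   window, default `c(130, 30)`.
#' @param post_offset Seconds after `t_flash` at which the post-burst window
#'   opens, default 30 (extends to the end of the acquisition).
#' @return dTE in gray levels (scalar).
#' @export
differential_targeted_enhancement <- function(tic, pre_window = c(130, 30),
                                              post_offset = 30) {
  tf <- t_flash_of(tic)
  keep <- non_burst(tic)
  pre <- keep & tic$time > tf - pre_window[1] & tic$time < tf - pre_window[2]
  post <- keep & tic$time > tf + post_offset
  if (!any(pre) || !any(post)) {
    abort("Pre- or post-burst dTE window contains no samples.",
          class = "usmikb_invalid_input")
  }
  mean(tic$gray[pre]) - mean(tic$gray[post])
}

#' Ellipsoidal tumor volume from caliper dimensions
#'
#' `V = pi/6 * L * W * H`, the standard ellipsoid approximation from the
#' greatest longitudinal, transverse and anteroposterior dimensions.
#'
#' @param L,W,H Dimensions in mm, >= 0.
#' @return Volume in mm^3 (vectorised).
#' @export
tumor_volume <- function(L, W, H) {
  if (any(c(L, W, H) < 0)) {
    abort("Tumor dimensions must be non-negative.",
          class = "usmikb_invalid_input")
  }
  pi / 6 * L * W * H
}

#' Aggregate a per-voxel parameter map over imaging planes
#'
#' Voxelwise pharmacokinetic estimates are not Gaussian within a plane, so a
#' whole-tumor value is formed robustly: the median of each 2-D plane's
#' finite voxel values, then the arithmetic mean of the plane medians.
#'
#' @param data A data frame with one row per voxel.
#' @param value Column of voxel values (tidy-eval).
#' @param plane Column identifying the 2-D plane (tidy-eval).
#' @return A tibble of class `volume_summary` with columns `plane`,
#'   `n_voxels`, `plane_median`, and the whole-volume mean retrievable with
#'   [volume_mean()].
#' @examples
#' df <- data.frame(plane = rep(1:2, each = 3), v = c(1, 2, 3, 3, 4, 5))
#' s <- aggregate_parameter_map(df, v, plane)
#' volume_mean(s)
#' @export
aggregate_parameter_map <- function(data, value, plane) {
  df <- tibble(plane = dplyr::pull(data, {{ plane }}),
               value = dplyr::pull(data, {{ value }}))
  if (nrow(df) == 0L) {
    abort("No voxel values supplied.", class = "usmikb_invalid_input")
  }
  out <- df %>%
    group_by(plane) %>%
    summarise(n_voxels = sum(is.finite(.data$value)),
              plane_median = median(.data$value[is.finite(.data$value)]),
              .groups = "drop")
  dropped <- out$n_voxels == 0L
  if (any(dropped)) {
    warn(sprintf("%d plane(s) with no finite voxel values excluded.",
                 sum(dropped)))
    out <- out[!dropped, , drop = FALSE]
  }
  if (nrow(out) == 0L) {
    abort("Every plane was empty; nothing to aggregate.",
          class = "usmikb_invalid_input")
  }
  structure(out, volume_mean = mean(out$plane_median),
            class = c("volume_summary", class(out)))
}

#' Whole-volume mean of a plane-median summary
#'
#' @param summary A `volume_summary` from [aggregate_parameter_map()].
#' @return The mean of the plane medians (scalar).
#' @export
volume_mean <- function(summary) {
  attr(summary, "volume_mean", exact = TRUE)
}
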