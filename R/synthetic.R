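#' Acquisition protocol description
#'
#' Timing and display settings of a destruction-replenishment USMI
#' acquisition: ~1 Hz volumetric frames for ~5 minutes, a 2-s high-MI
#' destructive burst at ~4 minutes, 52 dB log-compression dynamic range.
#'
#' @param frame_rate Frames per second, default 1.
#' @param duration Total acquisition length (s), default 300.
#' @param t_flash Burst time (s), default 240.
#' @param burst_duration Burst length (s), default 2.
#' @param dynamic_range Log-compression dynamic range (dB), default 52.
#' @return A named list of class `acquisition_protocol`.
#' @export
acquisition_protocol <- function(frame_rate = 1, duration = 300,
                                 t_flash = 240, burst_duration = 2,
                                 dynamic_range = 52) {
  if (frame_rate <= 0 || t_flash + burst_duration >= duration) {
    abort("Invalid protocol: need frame_rate > 0 and burst before the end.",
          class = "usmikb_invalid_input")
  }
  structure(list(frame_rate = frame_rate, duration = duration,
                 t_flash = t_flash, burst_duration = burst_duration,
                 dynamic_range = dynamic_range),
            class = "acquisition_protocol")
}

protocol_times <- function(protocol) {
  seq(0, protocol$duration - 1 / protocol$frame_rate,
      by = 1 / protocol$frame_rate)
}

#' Design of a synthetic USMI study
#'
#' Describes the virtual cohort emulating a longitudinal antiangiogenic
#' case-control study: two tumor models (responder / non-responder), a
#' treated and a control arm, imaging at days 0/1/3/7/10, and a programmed
#' treatment effect — a multiplicative decline of the binding rate constant
#' in treated responders only, mild upward drift everywhere else. All
#' kinetic magnitudes, heterogeneity and noise levels are configurable; the
#' methods vignette documents the rationale for each default.
#'
#' @param n_treated_responders,n_treated_nonresponders Treated group sizes
#'   (defaults 5 and 5).
#' @param n_control_responders,n_control_nonresponders Control group sizes
#'   (defaults 4 and 3).
#' @param days Imaging days, default `c(0, 1, 3, 7, 10)`.
#' @param protocol An [acquisition_protocol()].
#' @param grid Voxels per plane and number of planes, default
#'   `c(32, 32, 6)`.
#' @param kb_median Median baseline binding rate (1/min), default 0.6.
#' @param kb_gcv Geometric CV of the baseline binding rate across mice,
#'   default 0.3.
#' @param effect Treated-responder multiplicative k_b schedule at the
#'   post-baseline days, default `c(0.45, 0.40, 0.35, 0.35)`.
#' @param drift_range Uniform range of the per-day multiplicative drift in
#'   all other groups, default `c(1.0, 1.2)`.
#' @param voxel_gcv Geometric CV of voxel heterogeneity around the
#'   mouse-day mean (applies to amplitude and binding rate), default 0.4.
#' @param snr_db Target multiplicative speckle SNR (dB), default 20.
#' @param noise_floor Mean additive noise floor (linear-power units),
#'   default 5.
#' @param alpha_median,alpha_gcv Median and geometric CV of the perfusion
#'   amplitude `alpha` across mice (linear-power * s), defaults 2e5 / 0.3.
#' @param alpha_day_gcv Day-to-day acquisition variability of `alpha`
#'   (injection/gain differences), default 0.1.
#' @param mu_range,t0_range Uniform ranges of per-mouse mean transit time
#'   and appearance time (s), defaults `c(20, 30)` and `c(8, 15)`.
#' @param kappa_median,kappa_gcv Median / geometric CV of the dispersion
#'   parameter (1/s), defaults 0.6 / 0.2.
#' @param repl_fraction Post-burst free-phase replenishment amplitude as a
#'   fraction of `alpha`, default 0.3.
#' @param repl_mu Mean transit time of the replenishment bolus (s), default
#'   5 (refill is fast relative to the systemic bolus).
#' @param repl_kappa Dispersion parameter of the replenishment bolus (1/s),
#'   default 2 (a compact refill front, so the post-burst dTE window sees
#'   only free-bubble steady signal).
#' @param recirculation Add a delayed, attenuated second bolus pass to
#'   stress-test the first-minute fitting window? Default `FALSE`.
#' @param growth_responder_treated,growth_other Per-day fractional growth of
#'   tumor caliper dimensions, defaults 0.005 and 0.025.
#' @param histology_rho Target population correlation between ground truth
#'   and simulated ex-vivo markers, default 0.7.
#' @param n_fov Fields of view averaged per histology slide, default 5.
#' @return A named list of class `synthetic_design`.
#' @export
synthetic_design <- function(n_treated_responders = 5,
                             n_treated_nonresponders = 5,
                             n_control_responders = 4,
                             n_control_nonresponders = 3,
                             days = c(0, 1, 3, 7, 10),
                             protocol = acquisition_protocol(),
                             grid = c(32, 32, 6),
                             kb_median = 0.6, kb_gcv = 0.3,
                             effect = c(0.45, 0.40, 0.35, 0.35),
                             drift_range = c(1.0, 1.2),
                             voxel_gcv = 0.4,
                             snr_db = 20, noise_floor = 5,
                             alpha_median = 2e5, alpha_gcv = 0.3,
                             alpha_day_gcv = 0.1,
                             mu_range = c(20, 30), t0_range = c(8, 15),
                             kappa_median = 0.6, kappa_gcv = 0.2,
                             repl_fraction = 0.3, repl_mu = 5, repl_kappa = 2,
                             recirculation = FALSE,
                             growth_responder_treated = 0.005,
                             growth_other = 0.025,
                             histology_rho = 0.7, n_fov = 5) {
  sizes <- c(n_treated_responders, n_treated_nonresponders,
             n_control_responders, n_control_nonresponders)
  if (any(sizes < 1)) {
    abort("All group sizes must be >= 1.", class = "usmikb_invalid_input")
  }
  if (any(effect <= 0) || snr_db <= 0) {
    abort("Effect multipliers and SNR must be positive.",
          class = "usmikb_invalid_input")
  }
  if (length(effect) != length(days) - 1L) {
    abort("`effect` needs one multiplier per post-baseline day.",
          class = "usmikb_invalid_input")
  }
  structure(as.list(environment()), class = "synthetic_design")
}

# deterministic stage/child seed fan-out from a single study seed
child_seed <- function(seed, tag) {
  codes <- utf8ToInt(tag)
  h <- sum(codes * seq_along(codes))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

gcv_sdlog <- function(gcv) log(1 + gcv)

#' Generate a virtual cohort with ground truth
#'
#' Draws per-mouse kinetic latents (baseline binding rate, perfusion
#' amplitude, transit time, appearance time, dispersion) and rolls them
#' forward over the imaging days: treated responders receive the programmed
#' k_b decline schedule, every other group a mild upward drift. Tumor
#' caliper dimensions grow daily (faster off-treatment). Regenerating with
#' the same seed reproduces the cohort bit-identically.
#'
#' @param design A [synthetic_design()].
#' @param seed Integer seed for the whole study.
#' @return A list of class `usmi_cohort`: `metadata` (one row per mouse per
#'   day: ids, labels, caliper dimensions, burst time), `ground_truth`
#'   (per mouse-day true kinetic parameters; `k_b` in 1/min), `latents`
#'   (per-mouse draws), plus the design and seed.
#' @export
generate_cohort <- function(design, seed = 1) {
  stopifnot(inherits(design, "synthetic_design"))
  groups <- tibble(
    model = rep(c("responder", "nonresponder", "responder", "nonresponder"),
                times = c(design$n_treated_responders,
                          design$n_treated_nonresponders,
                          design$n_control_responders,
                          design$n_control_nonresponders)),
    arm = rep(c("treated", "treated", "control", "control"),
              times = c(design$n_treated_responders,
                        design$n_treated_nonresponders,
                        design$n_control_responders,
                        design$n_control_nonresponders)))
  n <- nrow(groups)
  latents <- with_seed(child_seed(seed, "cohort"), {
    groups %>% mutate(
      mouse_id = sprintf("m%02d_%s%s", seq_len(n),
                         substr(.data$model, 1, 1), substr(.data$arm, 1, 1)),
      kb0 = rlnorm(n, log(design$kb_median), gcv_sdlog(design$kb_gcv)),
      alpha0 = rlnorm(n, log(design$alpha_median),
                      gcv_sdlog(design$alpha_gcv)),
      mu = runif(n, design$mu_range[1], design$mu_range[2]),
      t0 = runif(n, design$t0_range[1], design$t0_range[2]),
      kappa = rlnorm(n, log(design$kappa_median),
                     gcv_sdlog(design$kappa_gcv)),
      L0 = runif(n, 6, 9), W0 = runif(n, 5, 8), H0 = runif(n, 4, 7))
  })

  post_days <- design$days[-1]
  per_day <- with_seed(child_seed(seed, "days"), {
    purrr::pmap_dfr(latents, function(mouse_id, model, arm, kb0, alpha0, mu,
                                      t0, kappa, L0, W0, H0, ...) {
      is_rt <- model == "responder" && arm == "treated"
      mult <- c(1, if (is_rt) design$effect
                   else runif(length(post_days), design$drift_range[1],
                              design$drift_range[2]))
      g <- if (is_rt) design$growth_responder_treated else design$growth_other
      alpha_day <- alpha0 * rlnorm(length(design$days), 0,
                                   gcv_sdlog(design$alpha_day_gcv))
      tibble(mouse_id = mouse_id, model = model, arm = arm,
             day = design$days,
             k_b = kb0 * mult, alpha = alpha_day,
             mu = mu, t0 = t0, kappa = kappa,
             L_mm = L0 * (1 + g)^design$days,
             W_mm = W0 * (1 + g)^design$days,
             H_mm = H0 * (1 + g)^design$days)
    })
  })
  per_day <- mutate(per_day,
                    bound_signal = (.data$k_b / 60) * .data$alpha)
  metadata <- per_day %>%
    select("mouse_id", "model", "arm", "day",
           "L_mm", "W_mm", "H_mm") %>%
    mutate(t_flash_s = design$protocol$t_flash)
  structure(list(metadata = metadata, ground_truth = per_day,
                 latents = latents, design = design, seed = seed),
            class = "usmi_cohort")
}

#' @export
print.usmi_cohort <- function(x, ...) {
  cat(sprintf("<usmi_cohort> %d mice, %d mouse-days (seed %d)\n",
              nrow(x$latents), nrow(x$metadata), x$seed))
  invisible(x)
}

# ellipsoidal tumor mask centred on the grid
tumor_mask <- function(grid) {
  nx <- grid[1]; ny <- grid[2]; np <- grid[3]
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2; cz <- (np + 1) / 2
  rx <- 0.42 * nx; ry <- 0.42 * ny; rz <- max(0.55 * np, 0.75)
  arr <- array(FALSE, dim = grid)
  for (z in seq_len(np)) {
    for (y in seq_len(ny)) {
      for (x in seq_len(nx)) {
        arr[x, y, z] <- ((x - cx) / rx)^2 + ((y - cy) / ry)^2 +
          ((z - cz) / rz)^2 <= 1
      }
    }
  }
  arr
}

#' Simulate one 4-D USMI acquisition
#'
#' Builds the gray-level stack (x, y, plane, time) for one mouse-day from
#' the cohort ground truth. Inside the ellipsoidal tumor mask each voxel
#' follows the first-pass binding model with voxel-heterogeneous amplitude
#' and binding rate; during the destructive burst the signal drops to the
#' noise floor; afterwards only a fast, reduced-amplitude free-phase
#' replenishment bolus remains (bound bubbles destroyed), which is what the
#' dTE readout exploits. Multiplicative gamma speckle and an additive floor
#' are applied in the linear domain before 52-dB log compression to integer
#' gray levels.
#'
#' @param cohort A [generate_cohort()] result.
#' @param mouse_id,day Which acquisition to simulate.
#' @param noise Apply speckle and the additive floor? Default `TRUE`;
#'   `FALSE` gives the noiseless forward model (quantization only).
#' @param grid Optional grid override, default the design's.
#' @return A list of class `usmi_stack`: `stack` (gray-level array), `mask`
#'   (logical array), `times`, `t_flash`, `protocol`, and `voxel_truth`
#'   (per in-mask voxel true `alpha` and `k_b` in 1/min).
#' @export
generate_stack <- function(cohort, mouse_id, day, noise = TRUE,
                           grid = NULL) {
  stopifnot(inherits(cohort, "usmi_cohort"))
  design <- cohort$design
  if (is.null(grid)) grid <- design$grid
  gt <- cohort$ground_truth
  row <- gt[gt$mouse_id == mouse_id & gt$day == day, ]
  if (nrow(row) != 1L) {
    abort(sprintf("No ground truth for %s day %s.", mouse_id, day),
          class = "usmikb_invalid_input")
  }
  protocol <- design$protocol
  times <- protocol_times(protocol)
  tf <- protocol$t_flash
  mask <- tumor_mask(grid)
  nv <- sum(mask)

  with_seed(child_seed(cohort$seed, paste("stack", mouse_id, day)), {
    alpha_v <- row$alpha * rlnorm(nv, 0, gcv_sdlog(design$voxel_gcv))
    kb_v <- (row$k_b / 60) * rlnorm(nv, 0, gcv_sdlog(design$voxel_gcv))

    pre <- times < tf
    burst <- times >= tf & times <= tf + protocol$burst_duration
    post <- times > tf + protocol$burst_duration

    kern_f <- mldrw_value(times, 1, row$mu, row$t0, row$kappa)
    kern_F <- cumfree_value(times, 1, row$mu, row$t0, row$kappa)
    if (isTRUE(design$recirculation)) {
      # delayed, attenuated echo of the bolus (second pass)
      kern_f <- kern_f + 0.15 * mldrw_value(times, 1, row$mu,
                                            row$t0 + 18, row$kappa)
    }
    kern_repl <- mldrw_value(times, 1, design$repl_mu,
                             tf + protocol$burst_duration,
                             design$repl_kappa)

    # voxels x time linear-power signal
    sig <- outer(alpha_v, kern_f) +
      outer(kb_v * alpha_v, kern_F)
    sig[, burst] <- 0
    sig[, post] <- outer(design$repl_fraction * alpha_v,
                         kern_repl[post])
    if (noise) {
      shape <- 10^(design$snr_db / 10)
      sig <- sig * matrix(rgamma(length(sig), shape, shape), nrow = nv) +
        matrix(rexp(length(sig), 1 / design$noise_floor), nrow = nv)
    }
    gray_v <- compress_gray(sig, protocol$dynamic_range, quantize = TRUE)

    nt <- length(times)
    stack <- array(0, dim = c(grid, nt))
    if (noise) {
      bg <- compress_gray(
        matrix(rexp(prod(grid) * nt, 1 / design$noise_floor),
               nrow = prod(grid)),
        protocol$dynamic_range, quantize = TRUE)
      stack <- array(bg, dim = c(grid, nt))
    }
    idx <- which(mask)
    for (j in seq_len(nt)) {
      frame <- array(stack[, , , j], dim = grid)
      frame[idx] <- gray_v[, j]
      stack[, , , j] <- frame
    }
    coords <- which(mask, arr.ind = TRUE)
    structure(list(stack = stack, mask = mask, times = times, t_flash = tf,
                   protocol = protocol,
                   voxel_truth = tibble(x = coords[, 1], y = coords[, 2],
                                        plane = coords[, 3],
                                        alpha = alpha_v, k_b = kb_v * 60)),
              class = "usmi_stack")
  })
}

#' Simulate correlated ex-vivo histology
#'
#' Emulates immunofluorescence quantification on the excised day-10 tumors:
#' the VEGFR2 expression score tracks the true final-day binding rate and
#' the percentage blood-vessel area tracks the true perfusion amplitude,
#' each measured as the mean of `n_fov` noisy fields of view. The
#' field-of-view noise is calibrated so the population correlation with the
#' ground-truth latent is approximately `histology_rho` after averaging.
#'
#' @param cohort A [generate_cohort()] result.
#' @return A tibble: `mouse_id`, `vegfr2_expression` (arbitrary units),
#'   `vessel_area_pct`.
#' @export
generate_histology <- function(cohort) {
  stopifnot(inherits(cohort, "usmi_cohort"))
  design <- cohort$design
  gt <- cohort$ground_truth
  final_day <- max(design$days)
  last <- gt[gt$day == final_day, ]
  with_seed(child_seed(cohort$seed, "histology"), {
    rho <- design$histology_rho
    n_fov <- design$n_fov
    noisy_mean <- function(latent) {
      sd_mean <- sd(latent) * sqrt(1 / rho^2 - 1)
      sapply(latent, function(v) {
        mean(v + rnorm(n_fov, 0, sd_mean * sqrt(n_fov)))
      })
    }
    vegfr2 <- noisy_mean(last$k_b)                     # a.u., a = 1 per 1/min
    vessel <- noisy_mean(8 * last$alpha / design$alpha_median)  # ~8 % typical
    tibble(mouse_id = last$mouse_id,
           vegfr2_expression = pmax(vegfr2, 0),
           vessel_area_pct = pmin(pmax(vessel, 0), 100))
  })
}

#' Write a synthetic study to disk
#'
#' Materializes a cohort as the on-disk layout the pipeline readers expect:
#' per mouse-day NIfTI stacks and tumor masks, a metadata CSV, a histology
#' CSV and a ground-truth JSON. Stacks round-trip bit-exactly through
#' [read_dataset()].
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @param grid Optional grid override for the stacks.
#' @param noise Passed to [generate_stack()].
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(cohort, dir, grid = NULL, noise = TRUE) {
  stopifnot(inherits(cohort, "usmi_cohort"))
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) {
    abort(sprintf("Cannot create fixture directory '%s'.", dir),
          class = "usmikb_io_error")
  }
  readr::write_csv(cohort$metadata, file.path(dir, "metadata.csv"))
  readr::write_csv(generate_histology(cohort),
                   file.path(dir, "histology.csv"))
  jsonlite::write_json(cohort$ground_truth,
                       file.path(dir, "ground_truth.json"),
                       digits = NA)
  purrr::pwalk(distinct(cohort$metadata, .data$mouse_id, .data$day),
               function(mouse_id, day) {
    sim <- generate_stack(cohort, mouse_id, day, noise = noise, grid = grid)
    base <- sprintf("%s_day%02d", mouse_id, day)
    RNifti::writeNifti(RNifti::asNifti(sim$stack),
                       file.path(dir, paste0(base, "_stack.nii.gz")),
                       datatype = "uint8")
    RNifti::writeNifti(RNifti::asNifti(sim$mask * 1L),
                       file.path(dir, paste0(base, "_mask.nii.gz")),
                       datatype = "uint8")
  })
  invisible(dir)
}

#' Read a study directory
#'
#' Loads the metadata and histology tables of a study written by
#' [write_fixture()] (or laid out the same way by other tooling) and indexes
#' the per-acquisition NIfTI stacks for lazy loading with [read_stack()].
#'
#' @param dir Study directory.
#' @return A list of class `usmi_dataset`: `metadata`, `histology` (or
#'   `NULL`), `dir`.
#' @export
read_dataset <- function(dir) {
  meta_path <- file.path(dir, "metadata.csv")
  if (!file.exists(meta_path)) {
    abort(sprintf("No metadata.csv in '%s'.", dir), class = "usmikb_io_error")
  }
  metadata <- readr::read_csv(meta_path, show_col_types = FALSE)
  hist_path <- file.path(dir, "histology.csv")
  histology <- if (file.exists(hist_path)) {
    readr::read_csv(hist_path, show_col_types = FALSE)
  }
  structure(list(metadata = metadata, histology = histology, dir = dir),
            class = "usmi_dataset")
}

#' @rdname read_dataset
#' @param dataset A `usmi_dataset`.
#' @param mouse_id,day Which acquisition to load.
#' @return `read_stack()`: a list with `stack` and `mask` arrays.
#' @export
read_stack <- function(dataset, mouse_id, day) {
  base <- file.path(dataset$dir, sprintf("%s_day%02d", mouse_id, day))
  stack_path <- paste0(base, "_stack.nii.gz")
  mask_path <- paste0(base, "_mask.nii.gz")
  if (!file.exists(stack_path) || !file.exists(mask_path)) {
    abort(sprintf("Missing stack or mask for %s day %s under '%s'.",
                  mouse_id, day, dataset$dir),
          class = "usmikb_io_error")
  }
  s <- RNifti::readNifti(stack_path)
  m <- RNifti::readNifti(mask_path)
  list(stack = array(as.numeric(s), dim = dim(s)),
       mask = array(as.numeric(m) > 0, dim = dim(m)))
}
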