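#' Run the full USMI study pipeline
#'
#' One reproducible pass over a whole longitudinal study: simulate (or
#' load) every acquisition, quantify the semi-quantitative readouts, fit
#' the first-pass binding model per voxel, aggregate to one value per
#' mouse-day, and run the complete case-control statistical battery. A
#' single seed fans out deterministically to every stage (stage-name keyed
#' child seeds), so the same call reproduces byte-identical tables.
#'
#' @param design A [synthetic_design()] (ignored when `input` is given).
#' @param seed Integer study seed.
#' @param input Optional directory written by [write_fixture()]; when given
#'   the acquisitions are read from disk instead of simulated in memory.
#' @param grid Optional grid override for simulated stacks (e.g.
#'   `c(8, 8, 2)` for a desk-scale run).
#' @param parameters USMI readouts to compute, subset of
#'   `c("k_b", "dTE", "LE")`; tumor volume is always carried along.
#' @param window Fit window (s), default 60.
#' @param cutoff Fold-change classification cutoff, default 0.7.
#' @param multi_start Use multi-start fitting? Default `FALSE`.
#' @param out_dir Optional directory to write the observation table and the
#'   four study tables as CSV (each prefixed with a config-hash comment).
#' @param quiet Suppress progress messages? Default `TRUE`.
#' @return A list of class `usmi_study`: `observations` (one row per mouse
#'   per day), `report` (a [longitudinal_report()]), `histology`, `cohort`
#'   (when simulated), and `provenance` (seed, config hash, version).
#' @export
run_pipeline <- function(design = synthetic_design(), seed = 1,
                         input = NULL, grid = NULL,
                         parameters = c("k_b", "dTE", "LE"),
                         window = 60, cutoff = 0.7, multi_start = FALSE,
                         out_dir = NULL, quiet = TRUE) {
  parameters <- match.arg(parameters, several.ok = TRUE)
  cohort <- NULL
  if (is.null(input)) {
    cohort <- generate_cohort(design, seed = seed)
    metadata <- cohort$metadata
    histology <- generate_histology(cohort)
    protocol <- design$protocol
  } else {
    dataset <- read_dataset(input)
    metadata <- dataset$metadata
    histology <- dataset$histology
    first <- read_stack(dataset, metadata$mouse_id[1], metadata$day[1])
    protocol <- acquisition_protocol(t_flash = metadata$t_flash_s[1],
                                     duration = dim(first$stack)[4])
  }
  if (nrow(metadata) == 0L) {
    abort("Empty dataset.", class = "usmikb_invalid_input")
  }

  acq <- distinct(metadata, .data$mouse_id, .data$day)
  obs_rows <- purrr::pmap_dfr(acq, function(mouse_id, day) {
    arrays <- tryCatch({
      if (is.null(input)) {
        sim <- generate_stack(cohort, mouse_id, day, grid = grid)
        list(stack = sim$stack, mask = sim$mask)
      } else {
        read_stack(dataset, mouse_id, day)
      }
    }, error = function(e) {
      warn(sprintf("Skipping %s day %s: %s", mouse_id, day,
                   conditionMessage(e)))
      NULL
    })
    if (is.null(arrays)) return(tibble())
    if (!quiet) message(sprintf("processed %s day %s", mouse_id, day))
    voxels <- NULL
    if (any(c("dTE", "LE") %in% parameters)) {
      voxels <- quantify_stack(arrays$stack, arrays$mask, protocol)
    }
    if ("k_b" %in% parameters) {
      fitted <- fit_stack(arrays$stack, arrays$mask, protocol,
                          window = window, multi_start = multi_start,
                          seed = if (multi_start)
                            child_seed(seed, paste("fit", mouse_id, day))
                          else NULL)
      voxels <- if (is.null(voxels)) fitted else {
        left_join(voxels, fitted, by = c("x", "y", "plane"))
      }
    }
    mutate(summarize_acquisition(voxels, parameters),
           mouse_id = mouse_id, day = day, .before = 1)
  })

  observations <- metadata %>%
    mutate(volume = tumor_volume(.data$L_mm, .data$W_mm, .data$H_mm)) %>%
    select("mouse_id", "model", "arm", "day", "volume") %>%
    left_join(obs_rows, by = c("mouse_id", "day"))

  report <- longitudinal_report(
    observations, histology = histology,
    parameters = c(parameters, "volume"), cutoff = cutoff)

  provenance <- list(
    seed = seed,
    config_hash = rlang::hash(list(design = unclass(design), seed = seed,
                                   parameters = parameters, window = window,
                                   cutoff = cutoff, grid = grid,
                                   multi_start = multi_start)),
    package = as.character(utils::packageVersion("usmikb")))
  study <- structure(list(observations = observations, report = report,
                          histology = histology, cohort = cohort,
                          provenance = provenance),
                     class = "usmi_study")
  if (!is.null(out_dir)) write_study(study, out_dir)
  study
}

#' @export
print.usmi_study <- function(x, ...) {
  cat(sprintf("<usmi_study> %d observations (seed %d, config %s)\n",
              nrow(x$observations), x$provenance$seed,
              x$provenance$config_hash))
  print(x$report)
  invisible(x)
}

write_study <- function(study, out_dir) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok) {
    abort(sprintf("Cannot create output directory '%s'.", out_dir),
          class = "usmikb_io_error")
  }
  header <- sprintf("# config_hash: %s", study$provenance$config_hash)
  dump <- function(df, name) {
    if (is.null(df)) return(invisible())
    path <- file.path(out_dir, paste0(name, ".csv"))
    writeLines(header, path)
    suppressWarnings(readr::write_csv(df, path, append = TRUE,
                                      col_names = TRUE))
  }
  dump(study$observations, "observations")
  dump(study$report$day_tests, "day_tests")
  dump(study$report$fold_change_tests, "fold_change_tests")
  dump(study$report$classification, "classification")
  dump(study$report$correlations, "correlations")
  jsonlite::write_json(study$provenance,
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE)
  invisible(out_dir)
}

#' Validate a study directory
#'
#' Report-only consistency checks of an on-disk study: metadata present
#' with the expected columns, every mouse imaged at baseline, burst time
#' inside the acquisition, stack/mask pairs present with matching geometry,
#' gray levels within 0-255.
#'
#' @param dir Study directory.
#' @return A tibble with columns `check`, `pass`, `detail`; never errors.
#' @export
validate_inputs <- function(dir) {
  checks <- list()
  add <- function(check, pass, detail = "") {
    checks[[length(checks) + 1L]] <<- tibble(check = check, pass = pass,
                                             detail = detail)
  }
  meta_path <- file.path(dir, "metadata.csv")
  if (!file.exists(meta_path)) {
    add("metadata_present", FALSE, "metadata.csv not found")
    return(bind_rows(checks))
  }
  add("metadata_present", TRUE)
  metadata <- readr::read_csv(meta_path, show_col_types = FALSE)
  need <- c("mouse_id", "model", "arm", "day", "L_mm", "W_mm", "H_mm",
            "t_flash_s")
  missing_cols <- setdiff(need, names(metadata))
  add("metadata_columns", length(missing_cols) == 0L,
      paste(missing_cols, collapse = ", "))
  if (length(missing_cols) > 0L) return(bind_rows(checks))

  no_base <- setdiff(metadata$mouse_id, metadata$mouse_id[metadata$day == 0])
  add("baseline_present", length(no_base) == 0L,
      if (length(no_base)) paste("missing day 0:",
                                 paste(no_base, collapse = ", ")) else "")

  for (i in seq_len(nrow(distinct(metadata, .data$mouse_id, .data$day)))) {
    row <- distinct(metadata, .data$mouse_id, .data$day)[i, ]
    base <- file.path(dir, sprintf("%s_day%02d", row$mouse_id, row$day))
    sp <- paste0(base, "_stack.nii.gz"); mp <- paste0(base, "_mask.nii.gz")
    tag <- sprintf("%s_day%02d", row$mouse_id, row$day)
    if (!file.exists(sp) || !file.exists(mp)) {
      add(paste0("stack_present:", tag), FALSE, "missing stack or mask")
      next
    }
    s <- RNifti::readNifti(sp); m <- RNifti::readNifti(mp)
    geom_ok <- length(dim(s)) == 4L && length(dim(m)) == 3L &&
      all(dim(m) == dim(s)[1:3])
    add(paste0("geometry:", tag), geom_ok,
        if (!geom_ok) sprintf("stack %s vs mask %s",
                              paste(dim(s), collapse = "x"),
                              paste(dim(m), collapse = "x")) else "")
    rng_ok <- min(s) >= 0 && max(s) <= 255
    add(paste0("gray_range:", tag), rng_ok,
        if (!rng_ok) sprintf("range [%g, %g]", min(s), max(s)) else "")
    tf <- metadata$t_flash_s[metadata$mouse_id == row$mouse_id &
                               metadata$day == row$day][1]
    add(paste0("t_flash:", tag),
        is.finite(tf) && tf > 0 && tf < dim(s)[4],
        sprintf("t_flash = %g with %d frames", tf, dim(s)[4]))
  }
  bind_rows(checks)
}
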