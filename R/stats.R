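#' Kruskal-Wallis test across day groups
#'
#' Tie-corrected Kruskal-Wallis rank test that a USMI parameter has the same
#' distribution across imaging days (or any grouping). When every value is
#' identical the statistic is 0 and p = 1 (the tie correction degenerates).
#'
#' @param data A data frame.
#' @param value Value column (tidy-eval).
#' @param group Grouping column (tidy-eval).
#' @return A one-row tibble with `statistic` (H), `df`, `p_value`.
#' @export
kruskal_wallis <- function(data, value, group) {
  v <- dplyr::pull(data, {{ value }})
  g <- factor(dplyr::pull(data, {{ group }}))
  if (nlevels(g) < 2L || any(!is.finite(v))) {
    abort("Need >= 2 groups of finite values.",
          class = "usmikb_invalid_input")
  }
  if (length(unique(v)) == 1L) {
    return(tibble(statistic = 0, df = nlevels(g) - 1L, p_value = 1))
  }
  kt <- kruskal.test(v, g)
  tibble(statistic = unname(kt$statistic), df = unname(kt$parameter),
         p_value = kt$p.value)
}

#' Wilcoxon-Mann-Whitney two-sample rank-sum test
#'
#' Two-sided rank-sum test. With combined n <= 10 and no ties the p-value is
#' computed by exact enumeration of the rank assignments; otherwise the
#' normal approximation with continuity and tie correction is used. The
#' branch taken is reported in the `method` column so every call is
#' reproducible at the small group sizes of longitudinal mouse studies.
#'
#' @param x,y Non-empty numeric samples.
#' @param exact Force the exact (`TRUE`) or approximate (`FALSE`) branch;
#'   default `NULL` applies the size/tie rule above.
#' @return A one-row tibble with `statistic` (Mann-Whitney U of `x`),
#'   `p_value`, `method` ("exact" or "normal-approx").
#' @export
rank_sum_test <- function(x, y, exact = NULL) {
  if (length(x) == 0L || length(y) == 0L) {
    abort("Both samples must be non-empty.", class = "usmikb_invalid_input")
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  if (is.null(exact)) exact <- (length(x) + length(y) <= 10L) && !ties
  if (exact && ties) {
    abort("Exact rank-sum p-values are unavailable with ties.",
          class = "usmikb_invalid_input")
  }
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  tibble(statistic = unname(wt$statistic), p_value = min(wt$p.value, 1),
         method = if (exact) "exact" else "normal-approx")
}

#' Wilcoxon signed-rank test on paired differences
#'
#' Two-sided one-sample signed-rank test of symmetric-about-zero
#' differences. Exact sign enumeration for n <= 12 non-zero untied
#' differences, normal approximation beyond.
#'
#' @param differences Numeric vector with at least one non-zero value.
#' @param exact As in [rank_sum_test()].
#' @return A one-row tibble with `statistic` (V), `p_value`, `method`.
#' @export
signed_rank_test <- function(differences, exact = NULL) {
  d <- differences[differences != 0]
  if (length(d) == 0L) {
    abort("All differences are zero; the signed-rank test is undefined.",
          class = "usmikb_invalid_input")
  }
  ties <- anyDuplicated(abs(d)) > 0L
  if (is.null(exact)) exact <- length(d) <= 12L && !ties
  wt <- suppressWarnings(wilcox.test(d, exact = exact, correct = TRUE))
  tibble(statistic = unname(wt$statistic), p_value = min(wt$p.value, 1),
         method = if (exact) "exact" else "normal-approx")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' False-discovery-rate adjustment of a family of p-values: `p * m / rank`
#' with step-up monotone enforcement, capped at 1, returned in the input
#' order.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    abort("p-values must lie in [0, 1].", class = "usmikb_invalid_input")
  }
  p.adjust(pvalues, method = "BH")
}

#' Per-mouse fold changes relative to baseline
#'
#' Normalizes each parameter at each post-baseline day by the same mouse's
#' day-0 value. Mice with a missing or zero baseline for a parameter are
#' excluded from that parameter with a warning.
#'
#' @param observations A data frame with columns `mouse_id`, `day`, and the
#'   parameter columns, one row per mouse per day (day 0 = baseline).
#' @param parameters Character vector of parameter columns to normalize.
#' @return A long tibble: `mouse_id`, any retained label columns (`model`,
#'   `arm`), `parameter`, `day`, `value`, `baseline`, `fold_change`, for
#'   post-baseline days only.
#' @export
fold_changes <- function(observations,
                         parameters = intersect(
                           c("k_b", "dTE", "LE", "volume"),
                           names(observations))) {
  labels <- intersect(c("model", "arm"), names(observations))
  long <- observations %>%
    select(dplyr::all_of(c("mouse_id", "day", labels, parameters))) %>%
    tidyr::pivot_longer(dplyr::all_of(parameters), names_to = "parameter",
                        values_to = "value")
  base <- long %>%
    filter(.data$day == 0) %>%
    select("mouse_id", "parameter", baseline = "value")
  out <- long %>%
    filter(.data$day != 0) %>%
    left_join(base, by = c("mouse_id", "parameter"))
  bad <- !is.finite(out$baseline) | out$baseline == 0
  if (any(bad)) {
    drop <- unique(out$mouse_id[bad])
    warn(sprintf(
      "Excluding mouse/parameter pairs with missing or zero baseline: %s",
      paste(drop, collapse = ", ")))
    out <- out[!bad, , drop = FALSE]
  }
  out %>% mutate(fold_change = .data$value / .data$baseline)
}

#' Classify therapeutic response from fold changes
#'
#' Each post-baseline observation is called a predicted responder when its
#' fold change is strictly below the cutoff (default 0.7; a value exactly at
#' the cutoff is conservatively called non-response). Counts are accumulated
#' over all supplied observations against the true labels.
#'
#' @param data A data frame of pooled post-baseline fold changes.
#' @param truth Logical column (or expression): `TRUE` for a true responder.
#' @param fold Fold-change column, default `fold_change`.
#' @param cutoff Decision threshold, default 0.7.
#' @return A `confusion_matrix` object (fields `TP`, `FP`, `FN`, `TN`).
#' @export
classify_response <- function(data, truth, fold = fold_change, cutoff = 0.7) {
  fc <- dplyr::pull(data, {{ fold }})
  lab <- dplyr::pull(dplyr::mutate(data, ..truth = {{ truth }}), "..truth")
  if (anyNA(lab) || anyNA(fc)) {
    abort("Every observation needs a fold change and a truth label.",
          class = "usmikb_invalid_input")
  }
  pred <- fc < cutoff
  confusion_matrix(TP = sum(pred & lab), FP = sum(pred & !lab),
                   FN = sum(!pred & lab), TN = sum(!pred & !lab))
}

#' Confusion matrix
#'
#' @param TP,FP,FN,TN Non-negative counts.
#' @return A `confusion_matrix` object.
#' @export
confusion_matrix <- function(TP, FP, FN, TN) {
  counts <- c(TP = TP, FP = FP, FN = FN, TN = TN)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("Confusion counts must be non-negative integers.",
          class = "usmikb_invalid_input")
  }
  structure(as.list(counts), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> TP=%d FP=%d FN=%d TN=%d (n=%d)\n",
              x$TP, x$FP, x$FN, x$TN, x$TP + x$FP + x$FN + x$TN))
  invisible(x)
}

#' Classification performance metrics
#'
#' Sensitivity, specificity, accuracy, positive and negative predictive
#' value of a confusion matrix, in percent reported to one decimal. A metric
#' whose denominator is zero is returned as `NA` (undefined).
#'
#' @param cm A [confusion_matrix()].
#' @return A one-row tibble: counts plus `sensitivity`, `specificity`,
#'   `accuracy`, `ppv`, `npv` (percent, 1 decimal).
#' @examples
#' classification_metrics(confusion_matrix(16, 2, 4, 18))
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  pct <- function(num, den) if (den == 0) NA_real_ else round(100 * num / den, 1)
  total <- cm$TP + cm$FP + cm$FN + cm$TN
  tibble(TP = cm$TP, FP = cm$FP, FN = cm$FN, TN = cm$TN,
         sensitivity = pct(cm$TP, cm$TP + cm$FN),
         specificity = pct(cm$TN, cm$TN + cm$FP),
         accuracy = pct(cm$TP + cm$TN, total),
         ppv = pct(cm$TP, cm$TP + cm$FP),
         npv = pct(cm$TN, cm$TN + cm$FN))
}

#' Pearson and Spearman correlation with p-values
#'
#' Pearson correlation on raw values and Spearman correlation on average
#' ranks, both with two-sided p-values from the t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` on n - 2 degrees of freedom.
#'
#' @param x,y Finite numeric vectors, n >= 3.
#' @return A one-row tibble: `pearson_rho`, `p_pearson`, `spearman_rho`,
#'   `p_spearman`, `n`. Zero variance in either input yields `NA`
#'   correlations with a warning.
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L ||
      !all(is.finite(x), is.finite(y))) {
    abort("Need equal-length finite vectors with n >= 3.",
          class = "usmikb_invalid_input")
  }
  n <- length(x)
  if (sd(x) == 0 || sd(y) == 0) {
    warn("Zero variance: correlation undefined, returning NA.")
    return(tibble(pearson_rho = NA_real_, p_pearson = NA_real_,
                  spearman_rho = NA_real_, p_spearman = NA_real_, n = n))
  }
  t_p <- function(rho) {
    if (abs(rho) >= 1) return(0)
    2 * pt(-abs(rho * sqrt((n - 2) / (1 - rho^2))), n - 2)
  }
  rp <- cor(x, y)
  rs <- cor(rank(x), rank(y))
  tibble(pearson_rho = rp, p_pearson = t_p(rp),
         spearman_rho = rs, p_spearman = t_p(rs), n = n)
}

#' Full longitudinal case-control analysis
#'
#' Reproduces the study's statistical battery on a cohort observation table:
#'
#' * per group x parameter: Kruskal-Wallis across days, then BH-adjusted
#'   day-vs-baseline rank-sum post hocs (family = the four post-baseline
#'   days within one group x parameter);
#' * per parameter x day: BH-adjusted rank-sum comparison of fold changes
#'   between treated responders and treated non-responders (family = the
#'   four days within one parameter);
#' * per parameter: fold-change responder classification at the cutoff over
#'   all pooled post-baseline treated observations, with the five
#'   performance metrics;
#' * optionally, Pearson/Spearman correlation of each parameter (days 7 and
#'   10 pooled) with ex-vivo histology markers.
#'
#' @param observations One row per mouse per day: `mouse_id`, `model`
#'   ("responder"/"nonresponder"), `arm` ("treated"/"control"), `day`, and
#'   parameter columns. Mice lacking a day-0 row are dropped with a warning.
#' @param histology Optional per-mouse table with `mouse_id` and marker
#'   columns (e.g. `vegfr2_expression`, `vessel_area_pct`).
#' @param parameters Parameter columns to analyse.
#' @param cutoff Fold-change classification cutoff, default 0.7.
#' @param day_test "kruskal" (default) or "anova" (with Tukey HSD post hocs)
#'   for the within-group day effect.
#' @param fold_change_test "rank_sum" (default; between treated groups) or
#'   "signed_rank" (one-sample test of the treated-responder fold changes
#'   against 1).
#' @return A `usmi_report`: list of tibbles `day_tests`, `fold_change_tests`,
#'   `classification`, and `correlations` (when histology is given), plus
#'   the `fold_changes` table and the settings used.
#' @export
longitudinal_report <- function(observations, histology = NULL,
                                parameters = intersect(
                                  c("k_b", "dTE", "LE", "volume"),
                                  names(observations)),
                                cutoff = 0.7,
                                day_test = c("kruskal", "anova"),
                                fold_change_test = c("rank_sum",
                                                     "signed_rank")) {
  day_test <- match.arg(day_test)
  fold_change_test <- match.arg(fold_change_test)
  obs <- as_tibble(observations)
  need <- c("mouse_id", "model", "arm", "day", parameters)
  missing_cols <- setdiff(need, names(obs))
  if (length(missing_cols) > 0L) {
    abort(paste("Missing observation columns:",
                paste(missing_cols, collapse = ", ")),
          class = "usmikb_invalid_input")
  }
  no_baseline <- setdiff(obs$mouse_id, obs$mouse_id[obs$day == 0])
  if (length(no_baseline) > 0L) {
    warn(sprintf("Dropping mice without day-0 data: %s",
                 paste(no_baseline, collapse = ", ")))
    obs <- filter(obs, !.data$mouse_id %in% no_baseline)
  }
  if (nrow(obs) == 0L) {
    abort("No observations left to analyse.", class = "usmikb_invalid_input")
  }
  obs <- mutate(obs, group = paste(.data$model, .data$arm, sep = "_"))
  post_days <- sort(setdiff(unique(obs$day), 0))

  day_tests <- day_vs_baseline_tests(obs, parameters, post_days, day_test)
  fc <- suppressWarnings(fold_changes(obs, parameters))
  fc_tests <- fold_change_group_tests(fc, parameters, post_days,
                                      fold_change_test)
  classification <- purrr::map_dfr(
    setdiff(parameters, "volume"), function(p) {
      pooled <- filter(fc, .data$parameter == p, .data$arm == "treated")
      if (nrow(pooled) == 0L) return(tibble())
      cm <- classify_response(pooled, truth = .data$model == "responder",
                              cutoff = cutoff)
      mutate(classification_metrics(cm), parameter = p, .before = 1)
    })

  correlations <- NULL
  if (!is.null(histology)) {
    markers <- setdiff(names(histology), "mouse_id")
    pooled <- obs %>%
      filter(.data$day %in% c(7, 10)) %>%
      left_join(as_tibble(histology), by = "mouse_id")
    correlations <- purrr::map_dfr(parameters, function(p) {
      purrr::map_dfr(markers, function(m) {
        ok <- is.finite(pooled[[p]]) & is.finite(pooled[[m]])
        if (sum(ok) < 3L) return(tibble())
        mutate(correlate(pooled[[p]][ok], pooled[[m]][ok]),
               parameter = p, marker = m, .before = 1)
      })
    })
  }

  structure(list(day_tests = day_tests, fold_change_tests = fc_tests,
                 classification = classification,
                 correlations = correlations, fold_changes = fc,
                 settings = list(cutoff = cutoff, day_test = day_test,
                                 fold_change_test = fold_change_test,
                                 parameters = parameters)),
            class = "usmi_report")
}

day_vs_baseline_tests <- function(obs, parameters, post_days, day_test) {
  grid <- tidyr::expand_grid(group = unique(obs$group),
                             parameter = parameters)
  purrr::pmap_dfr(grid, function(group, parameter) {
    g <- obs[obs$group == group, c("day", parameter)]
    names(g)[2] <- "value"
    g <- filter(g, is.finite(.data$value))
    if (length(unique(g$day)) < 2L) return(tibble())
    omni_p <- if (day_test == "kruskal") {
      kruskal_wallis(g, value, day)$p_value
    } else {
      summary(aov(value ~ factor(day), data = g))[[1]][["Pr(>F)"]][1]
    }
    base <- g$value[g$day == 0]
    per_day <- purrr::map_dfr(post_days, function(d) {
      v <- g$value[g$day == d]
      if (length(v) == 0L || length(base) == 0L) {
        return(tibble(day = d, p_raw = NA_real_))
      }
      p <- if (day_test == "kruskal") {
        rank_sum_test(v, base)$p_value
      } else {
        fit <- aov(value ~ factor(day),
                   data = filter(g, .data$day %in% c(0, d)))
        TukeyHSD(fit)[[1]][1, "p adj"]
      }
      tibble(day = d, p_raw = p)
    })
    ok <- !is.na(per_day$p_raw)
    per_day$p_adj <- NA_real_
    per_day$p_adj[ok] <- bh_adjust(per_day$p_raw[ok])
    mutate(per_day, group = group, parameter = parameter,
           omnibus_p = omni_p, .before = 1)
  })
}

fold_change_group_tests <- function(fc, parameters, post_days, test) {
  treated <- filter(fc, .data$arm == "treated")
  purrr::map_dfr(parameters, function(p) {
    per_day <- purrr::map_dfr(post_days, function(d) {
      sub <- filter(treated, .data$parameter == p, .data$day == d)
      r <- sub$fold_change[sub$model == "responder"]
      nr <- sub$fold_change[sub$model == "nonresponder"]
      pv <- if (test == "rank_sum") {
        if (length(r) == 0L || length(nr) == 0L) NA_real_
        else rank_sum_test(r, nr)$p_value
      } else {
        if (length(r) == 0L || all(r == 1)) NA_real_
        else signed_rank_test(r - 1)$p_value
      }
      tibble(day = d, p_raw = pv)
    })
    ok <- !is.na(per_day$p_raw)
    per_day$p_adj <- NA_real_
    per_day$p_adj[ok] <- bh_adjust(per_day$p_raw[ok])
    mutate(per_day, parameter = p, .before = 1)
  })
}

#' @export
print.usmi_report <- function(x, ...) {
  cat("<usmi_report>\n\n-- Day-vs-baseline tests (BH-adjusted) --\n")
  print(x$day_tests, n = 20)
  cat("\n-- Responder vs non-responder fold-change tests --\n")
  print(x$fold_change_tests, n = 20)
  cat("\n-- Fold-change classification (cutoff ",
      x$settings$cutoff, ") --\n", sep = "")
  print(x$classification)
  if (!is.null(x$correlations)) {
    cat("\n-- Ex-vivo correlations (days 7/10 pooled) --\n")
    print(x$correlations)
  }
  invisible(x)
}

#' Classification metrics from printed confusion counts
#'
#' Replay mode: given a table of per-parameter confusion counts, recompute
#' the five performance metrics. Useful for auditing published
#' classification tables.
#'
#' @param counts A data frame with columns `parameter`, `TP`, `FP`, `FN`,
#'   `TN`.
#' @return A tibble, one row per parameter, with counts and metrics.
#' @export
replay_classification <- function(counts) {
  purrr::pmap_dfr(counts, function(parameter, TP, FP, FN, TN, ...) {
    mutate(classification_metrics(confusion_matrix(TP, FP, FN, TN)),
           parameter = parameter, .before = 1)
  })
}
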