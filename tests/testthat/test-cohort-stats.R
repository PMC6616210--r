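test_that("Kruskal-Wallis handles ties, identity and permutation invariance", {
  same <- data.frame(v = rep(c(1, 2, 3), 2), g = rep(1:2, each = 3))
  expect_equal(kruskal_wallis(same, v, g)$statistic, 0)

  # hand rank computation: groups {1,2}, {10,11}, {20,21}, no ties
  # H = 12/(N(N+1)) * sum n_i (Rbar_i - (N+1)/2)^2 with N = 6
  df <- data.frame(v = c(1, 2, 10, 11, 20, 21), g = rep(1:3, each = 2))
  rbar <- c(1.5, 3.5, 5.5)
  h_hand <- 12 / (6 * 7) * sum(2 * (rbar - 3.5)^2)
  expect_equal(kruskal_wallis(df, v, g)$statistic, h_hand)

  const <- data.frame(v = rep(7, 6), g = rep(1:3, each = 2))
  expect_equal(kruskal_wallis(const, v, g)$p_value, 1)

  perm <- df; perm$g <- c(3, 3, 1, 1, 2, 2)
  expect_equal(kruskal_wallis(perm, v, g)$statistic,
               kruskal_wallis(df, v, g)$statistic)
})

test_that("exact rank-sum p-values equal full enumeration (n <= 8)", {
  expect_equal(rank_sum_test(c(1, 2), c(3, 4))$p_value, 2 / 6,
               tolerance = 1e-12)
  expect_equal(rank_sum_test(1:5, 6:10)$p_value, 2 / 252, tolerance = 1e-12)

  set.seed(51)
  for (m in 2:4) {
    for (k in 2:(8 - m)) {
      vals <- sample(100, m + k)  # distinct values, no ties
      x <- vals[1:m]; y <- vals[-(1:m)]
      res <- rank_sum_test(x, y)
      expect_equal(res$method, "exact")
      expect_equal(res$p_value, oracle_rank_sum_p(x, y), tolerance = 1e-12)
    }
  }

  # identical multisets fall back to the approximation and give p = 1
  res <- rank_sum_test(c(1, 2), c(1, 2))
  expect_equal(res$method, "normal-approx")
  expect_equal(res$p_value, 1)
  expect_error(rank_sum_test(numeric(0), 1:3),
               class = "usmikb_invalid_input")
})

test_that("signed-rank p-values equal sign enumeration", {
  expect_equal(signed_rank_test(c(1, 2, 3, 4, 5))$p_value, 2 / 32,
               tolerance = 1e-12)
  expect_equal(signed_rank_test(c(-2, 2, -5, 5))$p_value, 1)

  set.seed(52)
  d <- c(-3.2, 1.1, 4.7, -0.4, 2.9, 6.3, -1.8)
  expect_equal(signed_rank_test(d)$p_value, oracle_signed_rank_p(d),
               tolerance = 1e-12)
  expect_error(signed_rank_test(c(0, 0)), class = "usmikb_invalid_input")
})

test_that("BH adjustment is the step-up procedure", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(rep(1, 4)), rep(1, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "usmikb_invalid_input")

  set.seed(53)
  p <- runif(10)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  ord <- order(p)
  expect_true(all(diff(adj[ord]) >= -1e-15))
})

test_that("fold changes are ratios to each mouse's baseline", {
  obs <- tibble::tibble(
    mouse_id = rep(c("a", "b"), each = 3),
    model = "responder", arm = "treated",
    day = rep(c(0, 1, 3), 2),
    k_b = c(10, 10, 7, 2, 1, 4))
  fc <- fold_changes(obs)
  expect_equal(fc$fold_change[fc$mouse_id == "a"], c(1, 0.7))
  expect_equal(fc$fold_change[fc$mouse_id == "b"], c(0.5, 2))

  obs$k_b[obs$mouse_id == "b" & obs$day == 0] <- 0
  expect_warning(fc2 <- fold_changes(obs), "baseline")
  expect_false("b" %in% fc2$mouse_id)
})

test_that("response classification counts match a brute-force tally", {
  df <- tibble::tibble(
    fold_change = c(0.5, 1.2, 0.69, 0.7, 0.3, 0.71, 0.2, 0.9),
    responder = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  cm <- classify_response(df, truth = responder)
  # manual count at strict < 0.7: predictions T F T F T F T F
  expect_equal(cm$TP, 2); expect_equal(cm$FN, 2)
  expect_equal(cm$FP, 2); expect_equal(cm$TN, 2)

  one <- classify_response(
    tibble::tibble(fold_change = 0.5, responder = TRUE), truth = responder)
  expect_equal(one$TP, 1)
  miss <- classify_response(
    tibble::tibble(fold_change = 1.2, responder = TRUE), truth = responder)
  expect_equal(miss$FN, 1)
})

test_that("classification metrics reproduce the published study table", {
  kb <- classification_metrics(confusion_matrix(16, 2, 4, 18))
  expect_equal(unlist(kb[c("sensitivity", "specificity", "accuracy",
                           "ppv", "npv")], use.names = FALSE),
               c(80.0, 90.0, 85.0, 88.9, 81.8))
  dte <- classification_metrics(confusion_matrix(20, 1, 0, 19))
  expect_equal(unlist(dte[c("sensitivity", "specificity", "accuracy",
                            "ppv", "npv")], use.names = FALSE),
               c(100.0, 95.0, 97.5, 95.2, 100.0))
  le <- classification_metrics(confusion_matrix(19, 4, 1, 16))
  expect_equal(unlist(le[c("sensitivity", "specificity", "accuracy",
                           "ppv", "npv")], use.names = FALSE),
               c(95.0, 80.0, 87.5, 82.6, 94.1))

  nodeg <- classification_metrics(confusion_matrix(0, 0, 3, 5))
  expect_true(is.na(nodeg$ppv))
})

test_that("correlation identities hold and match the direct formulas", {
  x <- 1:10
  lin <- correlate(x, 2 * x + 1)
  expect_equal(lin$pearson_rho, 1)
  expect_equal(lin$spearman_rho, 1)

  mono <- correlate(x, -exp(x / 3))
  expect_equal(mono$spearman_rho, -1)

  set.seed(54)
  a <- rnorm(10); b <- 0.6 * a + rnorm(10)
  got <- correlate(a, b)
  r_hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(got$pearson_rho, r_hand, tolerance = 1e-12)
  expect_equal(got$spearman_rho, cor(rank(a), rank(b)), tolerance = 1e-12)
  # Spearman = Pearson on ranks, and Pearson p agrees with cor.test
  expect_equal(got$spearman_rho,
               correlate(rank(a), rank(b))$pearson_rho, tolerance = 1e-12)
  expect_equal(got$p_pearson, cor.test(a, b)$p.value, tolerance = 1e-10)

  expect_warning(flat <- correlate(rep(1, 5), 1:5), "variance")
  expect_true(is.na(flat$pearson_rho))
})

test_that("longitudinal report handles degenerate cohorts cleanly", {
  tiny <- tibble::tibble(
    mouse_id = rep(c("r1", "n1"), each = 2),
    model = rep(c("responder", "nonresponder"), each = 2),
    arm = "treated",
    day = rep(c(0, 1), 2),
    k_b = c(1, 0.4, 1, 1.1))
  rep1 <- suppressWarnings(longitudinal_report(tiny, parameters = "k_b"))
  expect_s3_class(rep1$day_tests, "tbl_df")
  expect_true(all(rep1$fold_change_tests$p_raw >= 0, na.rm = TRUE))

  # missing baseline drops the mouse with a warning
  nob <- tiny[tiny$mouse_id != "r1" | tiny$day != 0, ]
  expect_warning(longitudinal_report(nob, parameters = "k_b"),
                 "day-0")
  expect_error(longitudinal_report(tiny[0, ], parameters = "k_b"),
               class = "usmikb_invalid_input")
})
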