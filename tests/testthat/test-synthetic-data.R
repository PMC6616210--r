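small_design <- function(...) {
  synthetic_design(n_treated_responders = 2, n_treated_nonresponders = 2,
                   n_control_responders = 1, n_control_nonresponders = 1,
                   grid = c(8, 8, 2), ...)
}

test_that("the default design reproduces the study layout deterministically", {
  co <- generate_cohort(synthetic_design(), seed = 7)
  expect_equal(nrow(co$latents), 17)
  expect_equal(nrow(co$metadata), 85)
  expect_equal(sort(unique(co$metadata$day)), c(0, 1, 3, 7, 10))
  counts <- dplyr::count(co$latents, model, arm)
  expect_equal(counts$n[counts$model == "responder" &
                          counts$arm == "treated"], 5)
  expect_equal(counts$n[counts$model == "nonresponder" &
                          counts$arm == "control"], 3)

  co2 <- generate_cohort(synthetic_design(), seed = 7)
  expect_identical(co$metadata, co2$metadata)
  expect_identical(co$ground_truth, co2$ground_truth)
  co3 <- generate_cohort(synthetic_design(), seed = 8)
  expect_false(identical(co$ground_truth$k_b, co3$ground_truth$k_b))
})

test_that("only treated responders carry a programmed binding-rate decline", {
  for (seed in 1:10) {
    gt <- generate_cohort(synthetic_design(), seed = seed)$ground_truth
    base <- gt[gt$day == 0, c("mouse_id", "k_b")]
    names(base)[2] <- "kb0"
    fc <- merge(gt[gt$day != 0, ], base, by = "mouse_id")
    fc$ratio <- fc$k_b / fc$kb0
    rt <- fc$model == "responder" & fc$arm == "treated"
    expect_true(all(abs(fc$ratio[rt & fc$day == 1] - 0.45) < 1e-12))
    expect_true(all(abs(fc$ratio[rt & fc$day == 10] - 0.35) < 1e-12))
    expect_true(all(fc$ratio[!rt] >= 1 - 1e-12))
    expect_true(all(fc$ratio[!rt] <= 1.2 + 1e-12))
  }
})

test_that("noise-free stacks equal the forward model up to quantization", {
  co <- generate_cohort(small_design(), seed = 3)
  id <- co$metadata$mouse_id[1]
  sim <- generate_stack(co, id, 0, noise = FALSE)
  gt <- co$ground_truth
  row <- gt[gt$mouse_id == id & gt$day == 0, ]
  times <- sim$times
  v <- sim$voxel_truth[5, ]
  curve <- usmikb:::fpb_value(times, v$alpha, row$mu, row$t0, row$kappa,
                              v$k_b / 60)
  pre <- times < sim$t_flash
  expect_equal(sim$stack[v$x, v$y, v$plane, pre],
               compress_gray(curve[pre], quantize = TRUE))
  # burst frames collapse to the floor
  burst <- times >= sim$t_flash & times <= sim$t_flash + 2
  expect_true(all(sim$stack[v$x, v$y, v$plane, burst] == 0))
})

test_that("dTE on a noise-free stack recovers the bound-signal contrast", {
  co <- generate_cohort(small_design(), seed = 4)
  id <- co$metadata$mouse_id[1]
  sim <- generate_stack(co, id, 0, noise = FALSE)
  q <- quantify_stack(sim$stack, sim$mask, co$design$protocol)
  q <- dplyr::inner_join(q, sim$voxel_truth, by = c("x", "y", "plane"))
  predicted <- compress_gray(q$k_b / 60 * q$alpha, quantize = FALSE)
  rel <- abs(q$dTE - predicted) / predicted
  expect_lt(median(rel), 0.1)
})

test_that("fitting a noise-free stack recovers voxel binding rates", {
  co <- generate_cohort(small_design(), seed = 5)
  id <- co$metadata$mouse_id[1]
  sim <- generate_stack(co, id, 0, noise = FALSE)
  fits <- fit_stack(sim$stack, sim$mask, co$design$protocol)
  joined <- dplyr::inner_join(fits, sim$voxel_truth,
                              by = c("x", "y", "plane"),
                              suffix = c("_est", "_true"))
  # accuracy here is limited by 8-bit gray-level quantization (~2.4 %
  # multiplicative error per sample); unquantized curves recover < 0.5 %
  rel <- abs(joined$k_b_est - joined$k_b_true) / joined$k_b_true
  expect_lt(median(rel), 0.02)
  expect_lt(unname(quantile(rel, 0.9)), 0.05)
  expect_gt(mean(fits$converged), 0.95)
})

test_that("histology markers correlate with ground truth as designed", {
  exact <- generate_cohort(synthetic_design(histology_rho = 1), seed = 6)
  h <- generate_histology(exact)
  truth <- exact$ground_truth
  last <- truth[truth$day == 10, ]
  expect_equal(cor(h$vegfr2_expression, last$k_b), 1, tolerance = 1e-12)

  rhos <- sapply(1:50, function(s) {
    co <- generate_cohort(synthetic_design(), seed = s)
    hh <- generate_histology(co)
    lt <- co$ground_truth[co$ground_truth$day == 10, ]
    cor(hh$vegfr2_expression, lt$k_b)
  })
  expect_lt(abs(mean(rhos) - 0.7), 0.1)
})

test_that("fixtures round-trip through the readers bit-exactly", {
  dir <- withr::local_tempdir()
  design <- synthetic_design(n_treated_responders = 1,
                             n_treated_nonresponders = 1,
                             n_control_responders = 1,
                             n_control_nonresponders = 1,
                             days = c(0, 1), effect = 0.45,
                             grid = c(8, 8, 2))
  co <- generate_cohort(design, seed = 9)
  write_fixture(co, dir)
  ds <- read_dataset(dir)
  expect_equal(as.data.frame(ds$metadata), as.data.frame(co$metadata))

  id <- co$metadata$mouse_id[2]
  sim <- generate_stack(co, id, 1)
  back <- read_stack(ds, id, 1)
  expect_identical(as.numeric(back$stack), as.numeric(sim$stack))
  expect_identical(back$mask, sim$mask)

  # tiny fixture stays small on disk
  size <- sum(file.info(list.files(dir, full.names = TRUE))$size)
  expect_lt(size, 5e6)
})
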