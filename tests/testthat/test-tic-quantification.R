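test_that("linearization follows the 52-dB convention and round-trips", {
  expect_equal(linearize(0), 1)
  expect_equal(linearize(255, 52), 10^5.2)
  set.seed(3)
  g <- runif(100, 0, 255)
  expect_equal(linearize(compress_gray(linearize(g))), linearize(g),
               tolerance = 1e-9)
  expect_error(linearize(-1), class = "usmikb_invalid_input")
  expect_error(linearize(256), class = "usmikb_invalid_input")
})

test_that("late enhancement reads the sample nearest t_flash - 40 s", {
  tt <- 0:299
  expect_equal(late_enhancement(tic(tt, rep(37, 300), t_flash = 240)), 37)

  g <- rep(10, 300); g[tt == 200] <- 123
  expect_equal(late_enhancement(tic(tt, g, t_flash = 240)), 123)

  # plateau of a synthetic binding curve is read back within quantization
  plateau_gl <- compress_gray(2e5 * 0.01)
  x <- make_tic(quantize = TRUE)
  expect_lt(abs(late_enhancement(x) - plateau_gl), 1)

  expect_error(late_enhancement(tic(0:99, rep(1, 100), t_flash = 90),
                                offset = 95),
               class = "usmikb_invalid_input")
})

test_that("dTE is pre-burst minus post-burst mean gray level", {
  tt <- 0:299
  expect_equal(
    differential_targeted_enhancement(tic(tt, rep(8, 300), t_flash = 240)),
    0)

  g <- ifelse(tt < 240, 10, 4)
  expect_equal(
    differential_targeted_enhancement(tic(tt, g, t_flash = 240)), 6)

  # linear in the gray levels
  x1 <- tic(tt, g / 2, t_flash = 240)
  expect_equal(differential_targeted_enhancement(x1), 3)

  expect_error(
    differential_targeted_enhancement(tic(0:59, rep(1, 60), t_flash = 50)),
    class = "usmikb_invalid_input")
})

test_that("burst-contaminated frames are excluded from every readout", {
  tt <- 0:299
  g <- rep(10, 300)
  g[tt >= 240 & tt <= 242] <- 255  # saturated burst frames
  x <- tic(tt, g, t_flash = 240)
  expect_equal(differential_targeted_enhancement(x), 0)
  expect_equal(late_enhancement(x), 10)
})

test_that("tumor volume uses the pi/6 ellipsoid formula", {
  expect_equal(tumor_volume(1, 1, 1), pi / 6)
  expect_equal(tumor_volume(0, 5, 5), 0)
  expect_equal(tumor_volume(6, 6, 6), 36 * pi)
  expect_error(tumor_volume(-1, 1, 1), class = "usmikb_invalid_input")
})

test_that("parameter maps aggregate as plane medians then volume mean", {
  one <- data.frame(plane = c(1, 1, 1), v = c(1, 2, 3))
  s1 <- aggregate_parameter_map(one, v, plane)
  expect_equal(s1$plane_median, 2)
  expect_equal(volume_mean(s1), 2)

  two <- data.frame(plane = rep(1:2, each = 3), v = c(1, 2, 3, 3, 4, 5))
  expect_equal(volume_mean(aggregate_parameter_map(two, v, plane)), 3)

  # robust to outlier voxels
  out <- data.frame(plane = 1, v = c(1, 2, 1000))
  expect_equal(volume_mean(aggregate_parameter_map(out, v, plane)), 2)

  # permutation invariance within planes
  set.seed(5)
  big <- data.frame(plane = rep(1:3, each = 20), v = rnorm(60))
  shuf <- big[sample(nrow(big)), ]
  expect_equal(volume_mean(aggregate_parameter_map(shuf, v, plane)),
               volume_mean(aggregate_parameter_map(big, v, plane)))

  # NaN-only planes are dropped with a warning; all-empty errors
  nanplane <- data.frame(plane = rep(1:2, each = 2), v = c(1, 3, NaN, NaN))
  expect_warning(s <- aggregate_parameter_map(nanplane, v, plane),
                 "excluded")
  expect_equal(volume_mean(s), 2)
  allnan <- data.frame(plane = 1, v = c(NaN, NA))
  expect_warning(expect_error(aggregate_parameter_map(allnan, v, plane),
                              class = "usmikb_invalid_input"))
})
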