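test_that("assembled populations show the predicted dual-color fraction", {
  # two-copy fraction d with equimolar labels: dual fraction 2*d*r*g
  cx <- assemble_complexes(1e5, copy_number_model(d = 0.44), label_model(),
                           seed = 11)
  expect_lt(abs(mean(cx$color_class == "dual") - 0.22),
            binom_3se(0.22, 1e5))

  # one copy can never be two colors
  cx0 <- assemble_complexes(1e4, copy_number_model(d = 0),
                            label_model(r = 0.7), seed = 12)
  expect_identical(sum(cx0$color_class == "dual"), 0L)
  expect_true(all(is.na(cx0$color_second)))

  # all-two-copy population against the pair-enumeration oracle
  p_dual <- dual_prob_enumerated(0.3)
  expect_equal(p_dual, 2 * 0.3 * 0.7)
  cx1 <- assemble_complexes(1e5, copy_number_model(d = 1),
                            label_model(r = 0.3), seed = 13)
  expect_lt(abs(mean(cx1$color_class == "dual") - p_dual),
            binom_3se(p_dual, 1e5))
})

test_that("seeded generation is bit-identical and seeds matter", {
  a <- assemble_complexes(500, copy_number_model(d = 0.5), label_model(),
                          seed = 42)
  b <- assemble_complexes(500, copy_number_model(d = 0.5), label_model(),
                          seed = 42)
  c <- assemble_complexes(500, copy_number_model(d = 0.5), label_model(),
                          seed = 43)
  expect_identical(a, b)
  expect_false(identical(a$color_class, c$color_class))

  fd1 <- simulate_field(field_config(1, 50, 50, 0.02),
                        copy_number_model(d = 0.4), label_model(),
                        motility_params(), seed = 7)
  fd2 <- simulate_field(field_config(1, 50, 50, 0.02),
                        copy_number_model(d = 0.4), label_model(),
                        motility_params(), seed = 7)
  expect_identical(fd1$trajectories, fd2$trajectories)
})

test_that("noiseless runs are exactly affine and end where the length ends", {
  cx <- data.frame(complex_id = 1L, n_copies = 1L, color_first = "color1",
                   color_second = NA_character_, color_class = "color1",
                   n_dynein = 1L, stringsAsFactors = FALSE)
  p <- motility_params(localization_sd = 0)
  tr <- mrnpmotility:::traj_from_kinetics(cx, v = 0.5, len = 2, params = p)
  expect_equal(tr$position_um, 0.5 * tr$time_s)
  expect_equal(max(tr$time_s), 4.0)
  expect_equal(nrow(tr), 21L)
})

test_that("run lengths are detection-truncated exponentials", {
  p <- motility_params(runlen_mean_one = 7.2, runlen_mean_two = 7.2,
                       min_detectable_runlen = 0.5)
  cx <- assemble_complexes(1e4, copy_number_model(d = 0), label_model(),
                           seed = 21)
  trj <- withr::with_seed(22, mrnpmotility:::simulate_runs_bulk(cx, p))
  len <- attr(trj, "true_length")
  # memoryless: mean of (length - x0) equals mean - x0
  expect_lt(abs(mean(len - 0.5) - 6.7), 3 * 6.7 / sqrt(1e4))
  # and the excess is exponential with that scale
  ks <- ks.test(len - 0.5, "pexp", rate = 1 / 6.7)
  expect_gt(ks$p.value, 0.01)
  expect_true(all(len >= 0.5))
})

test_that("speeds follow the motor-number class, truncated at zero", {
  # two-motor class set to the dual-colored condition (0.63 +/- 0.26 um/s)
  p <- motility_params(speed_mean_two = 0.63, speed_sd_two = 0.26)
  cx <- assemble_complexes(1e4, copy_number_model(d = 1), label_model(),
                           p_two_dynein = 1, seed = 31)
  expect_true(all(cx$n_dynein == 2L))
  trj <- withr::with_seed(32, mrnpmotility:::simulate_runs_bulk(cx, p))
  v <- attr(trj, "true_speed")
  oracle <- truncnorm_mean(0.63, 0.26)      # analytic truncated-normal mean
  expect_lt(abs(mean(v) - oracle), 3 * 0.26 / sqrt(1e4))
  expect_lt(abs(mean(v) - 0.63), 0.02)
  expect_true(all(v > 0))
})

test_that("field landing counts are Poisson in the configured rate", {
  expect_identical(
    nrow(simulate_field(field_config(1, 100, 100, 0),
                        copy_number_model(d = 0.5), label_model(),
                        motility_params(), seed = 1)$complexes),
    0L)

  # lambda = 100: mean count over 200 seeds within 3 SE of the Poisson mean
  counts <- vapply(1:200, function(s) {
    nrow(simulate_field(field_config(1, 100, 100, 0.01),
                        copy_number_model(d = 0.5), label_model(),
                        motility_params(runlen_mean_one = 0.8,
                                        runlen_mean_two = 0.8),
                        seed = s)$complexes)
  }, numeric(1))
  expect_lt(abs(mean(counts) - 100), 3 * sqrt(100 / 200))

  # doubling concentration doubles the expected count (single large field)
  n1 <- nrow(simulate_field(field_config(1, 100, 100, 1),
                            copy_number_model(d = 0.5), label_model(),
                            motility_params(runlen_mean_one = 0.8,
                                            runlen_mean_two = 0.8),
                            seed = 5)$complexes)
  n2 <- nrow(simulate_field(field_config(2, 100, 100, 1),
                            copy_number_model(d = 0.5), label_model(),
                            motility_params(runlen_mean_one = 0.8,
                                            runlen_mean_two = 0.8),
                            seed = 6)$complexes)
  expect_lt(abs(n1 - 1e4), 3 * sqrt(1e4))
  expect_lt(abs(n2 - 2e4), 3 * sqrt(2e4))
})

test_that("kymographs quantize trajectories onto pixel traces", {
  tr <- make_noiseless_traj(v = 0.5, len = 4, dt = 0.2)
  img <- render_kymograph(tr, pixel_size = 0.1066)
  occ <- apply(unclass(img), 2, function(col) which(col > 0) - 1L)
  expect_equal(occ, floor(0.5 * 0.2 * (seq_along(occ) - 1) / 0.1066))

  expect_warning(img0 <- render_kymograph(tr[0, ]), "empty")
  expect_true(all(unclass(img0) == 0))
  expect_true(attr(img0, "empty"))

  # two speeds give two monotone traces whose slopes recompute correctly
  tr2 <- rbind(make_noiseless_traj(0.3, 3, id = 1L),
               make_noiseless_traj(0.8, 8, id = 2L))
  img2 <- render_kymograph(tr2, pixel_size = 0.1066)
  for (v in c(0.3, 0.8)) {
    one <- render_kymograph(make_noiseless_traj(v, 10), pixel_size = 0.1066)
    occ <- apply(unclass(one), 2, function(col) which(col > 0)[1] - 1L)
    slope <- coef(lm(occ ~ seq_along(occ)))[2] * 0.1066 / 0.2
    expect_lt(abs(slope - v), 0.05)
  }
  expect_gte(max(unclass(img2)), 1)
})
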