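test_that("speed is the least-squares slope of position on time", {
  tr <- make_noiseless_traj(0.5, 2)
  expect_identical(estimate_speed(tr), 0.5)

  flat <- tr
  flat$position_um <- 1.3
  expect_identical(estimate_speed(flat), 0)

  expect_error(estimate_speed(tr[1:2, ]), ">= 3 samples")

  # noisy track: slope within the closed-form OLS error band
  v <- 0.42; sd_loc <- 0.03; n <- 50; dt <- 0.2
  tt <- seq(0, n - 1) * dt
  noisy <- withr::with_seed(101, {
    tr <- make_noiseless_traj(v, v * (n - 1) * dt + 1e-9, dt)
    tr$position_um <- tr$position_um + rnorm(nrow(tr), 0, sd_loc)
    tr
  })
  se_slope <- sd_loc / sqrt(sum((tt - mean(tt))^2))   # exact OLS slope SE
  est <- estimate_speed(noisy)
  expect_lt(abs(est - v), 3 * se_slope)
  expect_lt(abs(est - v), 0.02)
})

test_that("run length is the net start-to-end displacement", {
  tr <- make_noiseless_traj(0.5, 2)
  expect_identical(measure_run_length(tr), 2.0)
  expect_error(measure_run_length(tr[1, ]), ">= 2 samples")

  p <- motility_params(runlen_mean_one = 7.2, runlen_mean_two = 7.2,
                       localization_sd = 0)
  cx <- assemble_complexes(2000, copy_number_model(d = 0), label_model(),
                           seed = 41)
  trj <- withr::with_seed(42, mrnpmotility:::simulate_runs_bulk(cx, p))
  runs <- summarize_runs(trj)
  # measured net displacement tracks the generator's true lengths: the only
  # systematic loss is sub-frame quantization, under half a frame's travel
  truth <- attr(trj, "true_length")
  expect_lt(abs(mean(runs$run_length_um) - mean(truth)),
            3 * sd(truth) / sqrt(length(truth)) + 0.42 * 0.2)
})

test_that("color classification needs both channels within the radius", {
  one <- make_noiseless_traj(0.5, 2, channel = "color2")
  expect_identical(classify_color(one), "color2")

  both <- rbind(make_noiseless_traj(0.5, 2, channel = "color1"),
                make_noiseless_traj(0.5, 2, channel = "color2"))
  expect_identical(classify_color(both), "dual")

  shifted <- make_noiseless_traj(0.5, 2, channel = "color2")
  shifted$position_um <- shifted$position_um + 0.5
  apart <- rbind(make_noiseless_traj(0.5, 2, channel = "color1"), shifted)
  cls <- classify_color(apart)
  expect_false(identical(as.character(cls), "dual"))
  expect_true(attr(cls, "split"))
})

test_that("run frequency is runs per (uM x um x s)", {
  expect_equal(run_frequency(100, 1, 100, 100)$value, 0.01)
  expect_equal(run_frequency(0, 1, 100, 100)$value, 0)
  f1 <- run_frequency(50, 2, 100, 100)$value
  f2 <- run_frequency(50, 2, 100, 200)$value
  expect_equal(f2, f1 / 2)
  expect_error(run_frequency(10, 0, 100, 100), "conc")
})

test_that("run filtering applies both thresholds and reports counts", {
  runs <- data.frame(complex_id = 1:5, speed_um_s = 0.5,
                     run_length_um = c(0.2, 0.6, 1.0, 3.0, 7.0),
                     duration_s = 2, color_class = "color1",
                     n_frames = c(5L, 10L, 10L, 20L, 40L),
                     stringsAsFactors = FALSE)
  expect_identical(nrow(suppressMessages(filter_runs(runs))), 5L)
  kept <- suppressMessages(filter_runs(runs, min_length = 0.5))
  expect_identical(nrow(kept), 4L)
  expect_identical(attr(kept, "n_before"), 5L)
  expect_warning(suppressMessages(filter_runs(runs, min_frames = 100)),
                 "all runs removed")
})

test_that("bulk run summaries agree with the per-trajectory operations", {
  fd <- simulate_field(field_config(1, 100, 100, 0.02),
                       copy_number_model(d = 0.5), label_model(),
                       motility_params(), seed = 55)
  runs <- summarize_runs(fd)
  expect_gt(nrow(runs), 100)
  tr <- fd$trajectories
  for (id in runs$complex_id[seq(1, nrow(runs), by = 7)]) {
    t1 <- tr[tr$complex_id == id, ]
    ch1 <- t1[t1$channel == t1$channel[1], ]
    row <- runs[runs$complex_id == id, ]
    expect_equal(row$speed_um_s, estimate_speed(ch1))
    expect_equal(row$run_length_um, measure_run_length(ch1))
    expect_identical(row$color_class, as.character(classify_color(t1)))
    expect_equal(row$duration_s, (row$n_frames - 1) * 0.2)
  }
})

test_that("noiseless simulated data are recovered exactly", {
  p <- motility_params(localization_sd = 0)
  fd <- simulate_field(field_config(1, 100, 100, 0.01),
                       copy_number_model(d = 0.5), label_model(),
                       p, seed = 66)
  runs <- summarize_runs(fd)
  truth_v <- attr(fd$trajectories, "true_speed")
  kept <- match(runs$complex_id, fd$complexes$complex_id)
  expect_equal(runs$speed_um_s, truth_v[kept], tolerance = 1e-12)
  expect_identical(runs$color_class, fd$complexes$color_class[kept])
})
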