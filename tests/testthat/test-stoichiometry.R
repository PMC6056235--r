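test_that("the forward model reproduces the enumeration of color pairs", {
  all_one <- predict_observed(copy_number_model(d = 0), label_model())
  expect_equal(c(all_one$f1, all_one$f2, all_one$f12), c(0.5, 0.5, 0))

  all_two <- predict_observed(copy_number_model(d = 1), label_model())
  expect_equal(c(all_two$f1, all_two$f2, all_two$f12), c(0.25, 0.25, 0.5))

  expect_equal(predict_observed(copy_number_model(d = 0.44),
                                label_model())$f12, 0.22)

  # fractions sum to one identically across the whole grid
  for (d in seq(0, 1, by = 0.1)) {
    for (r in seq(0.1, 0.9, by = 0.1)) {
      ob <- predict_observed(copy_number_model(d = d), label_model(r = r))
      expect_equal(ob$f1 + ob$f2 + ob$f12, 1)
      expect_equal(ob$f12, 2 * d * r * (1 - r))
    }
  }
})

test_that("copy-number correction inverts the dual observable", {
  expect_equal(correct_copy_number(observed_fractions(f12 = 0.22),
                                   label_model())$d, 0.44)
  expect_equal(correct_copy_number(observed_fractions(f12 = 0.055),
                                   label_model())$d, 0.11)
  est0 <- correct_copy_number(observed_fractions(f12 = 0), label_model())
  expect_equal(est0$d, 0)
  expect_equal(est0$s, 1)

  # uneven labels: d = f12 / (2 r g), confirmed by forward simulation
  est <- correct_copy_number(observed_fractions(f12 = 0.3),
                             label_model(r = 0.4))
  expect_equal(est$d, 0.625)
  cx <- assemble_complexes(1e5, copy_number_model(d = 0.625),
                           label_model(r = 0.4), seed = 301)
  f12_sim <- mean(cx$color_class == "dual")
  expect_lt(abs(f12_sim - 0.3), binom_3se(0.3, 1e5))
})

test_that("round trip through the forward model is exact on a grid", {
  for (d in seq(0, 1, by = 0.1)) {
    for (r in seq(0.1, 0.9, by = 0.1)) {
      ob <- predict_observed(copy_number_model(d = d), label_model(r = r))
      est <- correct_copy_number(ob, label_model(r = r))
      expect_equal(est$d, d, tolerance = 1e-12)
    }
  }
})

test_that("estimates outside [0,1] are clipped and flagged", {
  est <- correct_copy_number(observed_fractions(f12 = 0.6), label_model())
  expect_true(est$clipped)
  expect_equal(est$d, 1)
  expect_equal(est$d_raw, 1.2)
  expect_error(correct_copy_number(observed_fractions(f12 = 0.1),
                                   label_model(r = 1)),
               "strictly inside")
})

test_that("bootstrap intervals cover the true two-copy fraction", {
  d_true <- 0.44
  ob_true <- predict_observed(copy_number_model(d = d_true), label_model())
  p <- c(ob_true$f1, ob_true$f2, ob_true$f12)
  covered <- withr::with_seed(311, {
    vapply(1:200, function(i) {
      cnt <- as.vector(rmultinom(1, 300, p))
      obs <- observed_fractions_from_counts(cnt[1], cnt[2], cnt[3])
      est <- correct_copy_number(obs, label_model(), n_boot = 2000)
      est$ci_low <= d_true && d_true <= est$ci_high
    }, logical(1))
  })
  expect_gte(mean(covered), 0.90)   # nominal 95%, 3 binomial SE below
})

test_that("consistency report flags data the one-label model cannot explain", {
  ob <- predict_observed(copy_number_model(d = 0.3), label_model(r = 0.4))
  chk <- consistency_check(ob, label_model(r = 0.4))
  expect_true(chk$pass)
  expect_equal(chk$residual_f1, 0, tolerance = 1e-12)
  expect_equal(chk$sum_deviation, 0, tolerance = 1e-12)

  bad <- observed_fractions(f12 = 0.05, f1 = 0.9, f2 = 0.05)
  chk2 <- consistency_check(bad, label_model())
  expect_false(chk2$pass)
  expect_equal(chk2$d_implied, 0.1)
  expect_gt(abs(chk2$residual_f1), 0.1)

  # fractions summing to 0.8: unlabeled complexes suspected
  part <- observed_fractions(f12 = 0.1, f1 = 0.4, f2 = 0.3)
  chk3 <- consistency_check(part, label_model())
  expect_false(chk3$pass)
  expect_lt(chk3$sum_deviation, -0.05)
})
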