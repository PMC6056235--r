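# Figure-condition fixtures: each entry regenerates a synthetic dataset with
# the published fit parameters of one experimental condition, plus the
# expected values a recovery test should see. Speeds are truncated-at-zero
# Gaussians; run lengths are detection-truncated exponentials.

rtnorm_pos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= 0)
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= 0]
  }
  x
}

rmix_pos <- function(n, means, sds, weights = c(0.5, 0.5)) {
  comp <- sample.int(length(means), n, replace = TRUE, prob = weights)
  rtnorm_pos(n, means[comp], sds[comp])
}

rrunlen <- function(n, mean, x0 = 0.5) {
  x0 + stats::rexp(n, rate = 1 / (mean - x0))
}

fixture_registry <- list(
  fig5_DDBE_K10 = list(
    note = "fully reconstituted mRNP: unimodal speeds, exponential run lengths",
    generate = function() {
      list(speeds = rtnorm_pos(505, 0.42, 0.22),
           run_lengths = rrunlen(142, 7.2))
    },
    expected = list(speed_k = 1, speed_mean = 0.42, speed_sd = 0.22,
                    n_speeds = 505, runlen_mean = 7.2, n_runlen = 142,
                    runlen_x0 = 0.5)
  ),
  fig5_DDBCC1 = list(
    note = "minimal activated complex: unimodal speeds",
    generate = function() {
      list(speeds = rtnorm_pos(516, 0.43, 0.26),
           run_lengths = rrunlen(66, 5.3))
    },
    expected = list(speed_k = 1, speed_mean = 0.43, speed_sd = 0.26,
                    n_speeds = 516, runlen_mean = 5.3, n_runlen = 66,
                    runlen_x0 = 0.5)
  ),
  fig6_egl_two_color = list(
    note = "two-color adaptor: single- vs dual-colored motile complexes",
    generate = function() {
      list(speeds_single = rtnorm_pos(81, 0.38, 0.20),
           speeds_dual = rmix_pos(62, c(0.27, 0.73), c(0.10, 0.16)),
           runlen_single = rrunlen(81, 6.4),
           runlen_dual = rrunlen(62, 12.1))
    },
    expected = list(d = 0.867, speed_k_single = 1, speed_k_dual = 2,
                    speed_means_dual = c(0.27, 0.73),
                    runlen_mean_single = 6.4, runlen_mean_dual = 12.1,
                    runlen_x0 = 0.5)
  ),
  fig7_two_dynein = list(
    note = "two-color motor counting: 22% dual-colored spots imply 44% two-motor",
    generate = function() {
      cx <- assemble_complexes(1245, copy_number_model(d = 0.44),
                               label_model(), link_dynein = TRUE)
      list(complexes = cx,
           speeds_dual = rtnorm_pos(40, 0.63, 0.26),
           speeds_single = rmix_pos(44, c(0.40, 0.74), c(0.14, 0.13)),
           runlen_dual = rrunlen(40, 8.9),
           runlen_single = rrunlen(44, 5.8))
    },
    expected = list(d = 0.44, f12 = 0.22, r = 0.5,
                    speed_mean_dual = 0.63,
                    speed_means_single = c(0.40, 0.74),
                    runlen_mean_dual = 8.9, runlen_mean_single = 5.8,
                    runlen_percent_longer = 53, speed_percent_faster = 58,
                    runlen_x0 = 0.5)
  ),
  fig9_two_mrna = list(
    note = "two-color mRNA counting: 5.5% dual implies 11% two-mRNA",
    generate = function() {
      cx <- assemble_complexes(187, copy_number_model(d = 0.11),
                               label_model())
      list(complexes = cx,
           speeds = rmix_pos(187, c(0.36, 0.62), c(0.09, 0.38)),
           run_lengths = rrunlen(67, 5.5))
    },
    expected = list(d = 0.11, f12 = 0.055, r = 0.5, n_runs = 187,
                    speed_means = c(0.36, 0.62), runlen_mean = 5.5,
                    runlen_x0 = 0.5)
  ),
  fig10_eglzip = list(
    note = "zippered adaptor fragment: bimodal speeds without mRNA",
    generate = function() {
      list(speeds = rmix_pos(633, c(0.43, 0.95), c(0.21, 0.15)),
           run_lengths = rrunlen(84, 7.6))
    },
    expected = list(speed_k = 2, speed_means = c(0.43, 0.95),
                    speed_sds = c(0.21, 0.15), n_speeds = 633,
                    runlen_mean = 7.6, runlen_x0 = 0.5)
  )
)

#' Generate a registered figure-condition fixture
#'
#' Each fixture regenerates, from its published fit parameters, a synthetic
#' dataset matching one experimental condition (sample sizes, class means
#' and SDs, characteristic run lengths, copy-number fractions), together
#' with the expected values a parameter-recovery test should compare
#' against. Population mixture weights, where a condition is bimodal, are
#' 0.5/0.5.
#'
#' @param name Fixture name; call with no arguments (or an unknown name) to
#'   see the registered set in the error message.
#' @param seed Optional RNG seed.
#' @return A list with `name`, `note`, `data` (named numeric vectors and/or
#'   complex tables) and `expected` (the generating parameters).
#' @examples
#' fx <- generate_fixture("fig10_eglzip", seed = 1)
#' length(fx$data$speeds)   # 633
#' @export
generate_fixture <- function(name, seed = NULL) {
  if (missing(name) || !name %in% names(fixture_registry)) {
    stop("unknown fixture", if (!missing(name)) paste0(" '", name, "'"),
         "; registered fixtures: ",
         paste(names(fixture_registry), collapse = ", "), call. = FALSE)
  }
  fx <- fixture_registry[[name]]
  data <- with_seed_if(seed, fx$generate())
  list(name = name, note = fx$note, data = data, expected = fx$expected,
       seed = seed)
}

#' List registered figure fixtures
#'
#' @return Character vector of fixture names.
#' @export
list_fixtures <- function() names(fixture_registry)
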