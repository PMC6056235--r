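#' Observed color fractions of a two-color experiment
#'
#' Container for the observables of a two-color subunit-counting experiment:
#' the fractions of spots showing only color 1, only color 2, or both.
#' Under the model (every copy labeled, one or two copies per complex) the
#' three fractions sum to one.
#'
#' @param f1 Fraction of spots showing only color 1.
#' @param f2 Fraction showing only color 2.
#' @param f12 Fraction showing both colors.
#' @param n_total Optional total spot count, enabling bootstrap confidence
#'   intervals downstream.
#' @return An object of class `observed_fractions`.
#' @examples
#' observed_fractions(f12 = 0.22, f1 = 0.39, f2 = 0.39, n_total = 1245)
#' @export
observed_fractions <- function(f12, f1 = NA_real_, f2 = NA_real_,
                               n_total = NULL) {
  check_fraction(f12, "f12")
  if (!is.na(f1)) check_fraction(f1, "f1")
  if (!is.na(f2)) check_fraction(f2, "f2")
  if (!is.null(n_total)) check_count(n_total, "n_total")
  if (!is.na(f1) && !is.na(f2) && f1 + f2 + f12 > 1 + 1e-6) {
    stop("f1 + f2 + f12 must not exceed 1", call. = FALSE)
  }
  structure(list(f1 = f1, f2 = f2, f12 = f12, n_total = n_total),
            class = "observed_fractions")
}

#' Observed color fractions from category counts
#'
#' @param n1,n2,n12 Counts of color1-only, color2-only and dual spots.
#' @return An `observed_fractions` object with `n_total = n1 + n2 + n12`.
#' @export
observed_fractions_from_counts <- function(n1, n2, n12) {
  check_count(n1, "n1"); check_count(n2, "n2"); check_count(n12, "n12")
  n <- n1 + n2 + n12
  if (n == 0) stop("no spots counted", call. = FALSE)
  observed_fractions(f12 = n12 / n, f1 = n1 / n, f2 = n2 / n, n_total = n)
}

#' Predict observed color fractions from the copy-number model
#'
#' The forward model of the two-color experiment. A one-copy complex shows
#' color 1 with probability `r`; a two-copy complex shows only color 1 when
#' both copies drew color 1 (`r^2`), and both colors when the copies differ
#' (`2 r g`). Hence
#' \deqn{f_1 = s r + d r^2, \quad f_2 = s g + d g^2, \quad f_{12} = 2 d r g,}
#' which sum to one identically.
#'
#' @param copy_model A [copy_number_model()].
#' @param label_model A [label_model()].
#' @return An `observed_fractions` object.
#' @examples
#' predict_observed(copy_number_model(d = 0.44), label_model())  # f12 = 0.22
#' @export
predict_observed <- function(copy_model, label_model) {
  stopifnot(inherits(copy_model, "copy_number_model"),
            inherits(label_model, "label_model"))
  s <- copy_model$s; d <- copy_model$d
  r <- label_model$r; g <- label_model$g
  observed_fractions(f12 = 2 * d * r * g,
                     f1 = s * r + d * r^2,
                     f2 = s * g + d * g^2)
}

#' Correct observed dual-color fractions for same-color two-copy complexes
#'
#' Single-colored spots are a mixture of one-copy complexes and two-copy
#' complexes whose copies happen to carry the same color, so the raw
#' dual-color fraction underestimates the two-copy fraction. Inverting the
#' forward model on the dual observable gives
#' \deqn{d = f_{12} / (2 r g), \qquad s = 1 - d.}
#' With equimolar labels (`r = g = 0.5`) this doubles the dual fraction:
#' 22\% dual implies 44\% two-copy complexes. Estimates outside `[0, 1]`
#' (possible under sampling noise) are clipped and flagged. When `n_total`
#' is available a category-multinomial bootstrap supplies a percentile
#' confidence interval for `d`.
#'
#' @param obs An [observed_fractions()] object.
#' @param label_model A [label_model()] with `r`, `g` strictly inside (0, 1).
#' @param n_boot Bootstrap resamples (default 10000); used only when
#'   `obs$n_total` and `f1`, `f2` are available.
#' @param conf Confidence level (default 0.95).
#' @param seed Optional RNG seed for the bootstrap.
#' @return An object of class `stoich_estimate`: `d`, `s`, `clipped`,
#'   `ci_low`, `ci_high` (NA without counts), `n_total`, plus the inputs.
#' @examples
#' est <- correct_copy_number(observed_fractions(f12 = 0.22), label_model())
#' est$d  # 0.44
#' @export
correct_copy_number <- function(obs, label_model, n_boot = 10000,
                                conf = 0.95, seed = NULL) {
  stopifnot(inherits(obs, "observed_fractions"),
            inherits(label_model, "label_model"))
  r <- label_model$r; g <- label_model$g
  if (r <= 0 || r >= 1) {
    stop("label fractions must be strictly inside (0, 1): ",
         "dual observations are impossible when r or g is 0", call. = FALSE)
  }
  d_raw <- obs$f12 / (2 * r * g)
  clipped <- d_raw > 1 || d_raw < 0
  d <- min(max(d_raw, 0), 1)
  ci <- c(NA_real_, NA_real_)
  if (!is.null(obs$n_total) && !is.na(obs$f1) && !is.na(obs$f2)) {
    counts <- round(obs$n_total * c(obs$f1, obs$f2, obs$f12))
    ci <- with_seed_if(seed, {
      res <- stats::rmultinom(n_boot, sum(counts), counts / sum(counts))
      d_b <- pmin(pmax(res[3, ] / colSums(res) / (2 * r * g), 0), 1)
      stats::quantile(d_b, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                      names = FALSE)
    })
  }
  structure(list(d = d, s = 1 - d, d_raw = d_raw, clipped = clipped,
                 ci_low = ci[1], ci_high = ci[2], conf = conf,
                 n_total = obs$n_total, obs = obs,
                 label_model = label_model),
            class = "stoich_estimate")
}

#' @export
print.stoich_estimate <- function(x, ...) {
  cat(sprintf("Copy-number estimate: %.1f%% two-copy, %.1f%% one-copy\n",
              100 * x$d, 100 * x$s))
  if (!is.na(x$ci_low)) {
    cat(sprintf("  %d%% bootstrap CI for two-copy fraction: [%.1f%%, %.1f%%] (n = %d)\n",
                round(100 * x$conf), 100 * x$ci_low, 100 * x$ci_high,
                x$n_total))
  }
  if (x$clipped) {
    cat(sprintf("  note: raw estimate %.3f outside [0, 1], clipped (model-inconsistent)\n",
                x$d_raw))
  }
  invisible(x)
}

#' Check observed fractions against the copy-number model
#'
#' The correction uses only the dual-color observable, which leaves the two
#' single-color observables free to disagree with the model — as they will
#' if, for example, a fraction of copies carries no label at all. This
#' report plugs the dual-implied `d` back into the forward model and
#' returns the residuals of `f1` and `f2`, together with the deviation of
#' the fraction sum from one.
#'
#' @param obs An [observed_fractions()] object with all three fractions.
#' @param label_model A [label_model()].
#' @param tol Pass/fail tolerance on each residual (default 0.02).
#' @return An object of class `stoich_consistency`: `d_implied`,
#'   `residual_f1`, `residual_f2`, `sum_deviation`, `pass`.
#' @export
consistency_check <- function(obs, label_model, tol = 0.02) {
  stopifnot(inherits(obs, "observed_fractions"),
            inherits(label_model, "label_model"))
  if (is.na(obs$f1) || is.na(obs$f2)) {
    stop("consistency_check needs f1 and f2", call. = FALSE)
  }
  est <- correct_copy_number(observed_fractions(f12 = obs$f12, f1 = obs$f1,
                                                f2 = obs$f2),
                             label_model)
  pred <- predict_observed(copy_number_model(d = est$d), label_model)
  res1 <- obs$f1 - pred$f1
  res2 <- obs$f2 - pred$f2
  sum_dev <- obs$f1 + obs$f2 + obs$f12 - 1
  pass <- abs(res1) <= tol && abs(res2) <= tol && abs(sum_dev) <= tol &&
    !est$clipped
  structure(list(d_implied = est$d, residual_f1 = res1, residual_f2 = res2,
                 sum_deviation = sum_dev, tol = tol, pass = pass),
            class = "stoich_consistency")
}

#' @export
print.stoich_consistency <- function(x, ...) {
  cat(sprintf("Consistency: %s (implied d = %.3f)\n",
              if (x$pass) "PASS" else "FAIL", x$d_implied))
  cat(sprintf("  residual f1 %+.4f, f2 %+.4f; fraction sum deviates %+.4f (tol %.3g)\n",
              x$residual_f1, x$residual_f2, x$sum_deviation, x$tol))
  if (abs(x$sum_deviation) > x$tol) {
    cat("  fractions do not sum to 1: unlabeled complexes suspected\n")
  }
  invisible(x)
}
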