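#' Fit a one- or two-component Gaussian mixture to speeds
#'
#' Single-molecule speed histograms are unimodal when one motor-number class
#' dominates and bimodal when one- and two-motor complexes coexist. This
#' fits each candidate component count by maximum likelihood (closed form
#' for k = 1; expectation-maximization with k-means initialization and
#' random restarts for k = 2) and selects k by the Bayesian information
#' criterion. Components are always reported in increasing mean order, so
#' the fit is invariant to label switching.
#'
#' @param speeds Numeric vector of speeds (um/s), `n >= 10`.
#' @param k_candidates Component counts to consider, a subset of `c(1, 2)`.
#' @param n_restarts EM restarts per k (default 10).
#' @param max_iter Maximum EM iterations (default 500).
#' @param tol Convergence threshold on the relative log-likelihood change
#'   (default 1e-8).
#' @param seed Optional RNG seed controlling initialization, for exact
#'   reproducibility.
#' @return An object of class `speed_mixture_fit`: `k`, `weights`, `means`,
#'   `sds`, `log_likelihood`, `bic` (named per candidate k), `n`,
#'   `converged`.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(300, 0.4, 0.15), rnorm(300, 0.95, 0.15))
#' fit_speed_mixture(x, seed = 1)
#' @export
fit_speed_mixture <- function(speeds, k_candidates = c(1, 2),
                              n_restarts = 10, max_iter = 500,
                              tol = 1e-8, seed = NULL) {
  speeds <- as.numeric(speeds)
  if (anyNA(speeds)) stop("speeds contain NA", call. = FALSE)
  n <- length(speeds)
  if (n < 10) stop("need at least 10 speeds (got ", n, ")", call. = FALSE)
  if (stats::var(speeds) == 0) {
    stop("degenerate data: speeds have zero variance", call. = FALSE)
  }
  if (!all(k_candidates %in% c(1, 2))) {
    stop("k_candidates must be a subset of {1, 2}", call. = FALSE)
  }

  with_seed_if(seed, {
    fits <- lapply(sort(k_candidates), function(k) {
      if (k == 1) fit_gauss1(speeds) else
        fit_gauss2_em(speeds, n_restarts, max_iter, tol)
    })
    bics <- vapply(fits, `[[`, numeric(1), "bic")
    names(bics) <- paste0("k", sort(k_candidates))
    best <- fits[[which.min(bics)]]
    structure(list(k = best$k, weights = best$weights, means = best$means,
                   sds = best$sds, log_likelihood = best$loglik,
                   bic = bics, n = n, converged = best$converged),
              class = "speed_mixture_fit")
  })
}

fit_gauss1 <- function(x) {
  n <- length(x)
  m <- mean(x)
  s <- sqrt(sum((x - m)^2) / n)           # MLE variance
  ll <- sum(stats::dnorm(x, m, s, log = TRUE))
  list(k = 1L, weights = 1, means = m, sds = s, loglik = ll,
       bic = -2 * ll + 2 * log(n), converged = TRUE)
}

fit_gauss2_em <- function(x, n_restarts, max_iter, tol) {
  n <- length(x)
  sd_floor <- 1e-4 * stats::sd(x)         # guard against variance collapse
  best <- NULL
  for (r in seq_len(n_restarts)) {
    km <- suppressWarnings(stats::kmeans(x, centers = 2, nstart = 1))
    w <- as.numeric(table(factor(km$cluster, levels = 1:2))) / n
    mu <- as.numeric(km$centers)
    sg <- vapply(1:2, function(j) {
      xx <- x[km$cluster == j]
      max(stats::sd(c(xx, xx)), sd_floor, na.rm = TRUE)
    }, numeric(1))
    sg[!is.finite(sg) | sg <= 0] <- stats::sd(x)
    # jitter after the first restart so restarts actually differ
    if (r > 1) {
      mu <- mu + stats::rnorm(2, 0, 0.1 * stats::sd(x))
      sg <- sg * exp(stats::rnorm(2, 0, 0.2))
    }
    fit <- em_2gauss(x, w, mu, sg, max_iter, tol, sd_floor)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  ord <- order(best$means)
  list(k = 2L, weights = best$weights[ord], means = best$means[ord],
       sds = best$sds[ord], loglik = best$loglik,
       bic = -2 * best$loglik + 5 * log(n), converged = best$converged)
}

em_2gauss <- function(x, w, mu, sg, max_iter, tol, sd_floor) {
  n <- length(x)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(x, mu[1], sg[1])
    d2 <- w[2] * stats::dnorm(x, mu[2], sg[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    g1 <- d1 / tot
    ll <- sum(log(tot))
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * abs(ll)) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
    n1 <- sum(g1)
    n2 <- n - n1
    if (n1 < 1e-8 || n2 < 1e-8) break     # a component died
    w <- c(n1, n2) / n
    mu <- c(sum(g1 * x) / n1, sum((1 - g1) * x) / n2)
    sg <- c(sqrt(sum(g1 * (x - mu[1])^2) / n1),
            sqrt(sum((1 - g1) * (x - mu[2])^2) / n2))
    sg <- pmax(sg, sd_floor)
  }
  list(weights = w, means = mu, sds = sg, loglik = ll_old,
       converged = converged)
}

#' @export
print.speed_mixture_fit <- function(x, ...) {
  cat("Gaussian mixture fit (k =", x$k, "selected by BIC)\n")
  for (j in seq_len(x$k)) {
    cat(sprintf("  component %d: %.3f +/- %.3f um/s (weight %.2f)\n",
                j, x$means[j], x$sds[j], x$weights[j]))
  }
  cat(sprintf("  logLik %.2f, n = %d; BIC: %s\n", x$log_likelihood, x$n,
              paste(names(x$bic), round(x$bic, 1), collapse = ", ")))
  if (!x$converged) cat("  note: EM stopped before convergence\n")
  invisible(x)
}

#' @export
coef.speed_mixture_fit <- function(object, ...) {
  k <- object$k
  stats::setNames(c(object$weights, object$means, object$sds),
                  c(paste0("weight", seq_len(k)), paste0("mean", seq_len(k)),
                    paste0("sd", seq_len(k))))
}

#' @export
logLik.speed_mixture_fit <- function(object, ...) {
  structure(object$log_likelihood, df = if (object$k == 1) 2 else 5,
            nobs = object$n, class = "logLik")
}

#' Draw speeds from a fitted mixture
#'
#' @param object A `speed_mixture_fit`.
#' @param nsim Number of draws.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @return Numeric vector of simulated speeds (um/s).
#' @export
simulate.speed_mixture_fit <- function(object, nsim = 1, seed = NULL, ...) {
  with_seed_if(seed, {
    comp <- sample.int(object$k, nsim, replace = TRUE, prob = object$weights)
    stats::rnorm(nsim, object$means[comp], object$sds[comp])
  })
}

#' @export
plot.speed_mixture_fit <- function(x, speeds = NULL, breaks = 20, ...) {
  xs <- seq(max(0, min(x$means - 4 * x$sds)), max(x$means + 4 * x$sds),
            length.out = 400)
  dens <- rowSums(vapply(seq_len(x$k), function(j) {
    x$weights[j] * stats::dnorm(xs, x$means[j], x$sds[j])
  }, numeric(length(xs))))
  if (!is.null(speeds)) {
    graphics::hist(speeds, breaks = breaks, freq = FALSE,
                   xlab = "speed (um/s)", main = "Speed distribution", ...)
    graphics::lines(xs, dens, lwd = 2)
  } else {
    graphics::plot(xs, dens, type = "l", lwd = 2, xlab = "speed (um/s)",
                   ylab = "density", main = "Fitted mixture", ...)
  }
  invisible(x)
}

#' Fit a truncated-exponential run-length distribution
#'
#' Run lengths of processive motors are exponential, but runs shorter than a
#' detection threshold `x0` are not scored. Under the memoryless property
#' the observable lengths satisfy `length - x0 ~ Exp(mean - x0)`, so the
#' maximum-likelihood characteristic run length is `x0 + mean(length - x0)`
#' with standard error `(mean - x0) / sqrt(n)`. A least-squares fit of the
#' empirical cumulative distribution is reported alongside as a cross-check
#' (`mean_cdf`), approximating fits done on binned histograms.
#'
#' @param lengths Numeric vector of run lengths (um), all `>= x0`.
#' @param x0 Truncation (minimum detectable run length, um); default 0.
#' @return An object of class `runlength_fit`: `mean`, `se`, `mean_cdf`,
#'   `x0`, `n`.
#' @examples
#' fit_run_lengths(c(1, 2, 3))   # mean 2, se 2/sqrt(3)
#' @export
fit_run_lengths <- function(lengths, x0 = 0) {
  lengths <- as.numeric(lengths)
  check_number(x0, "x0")
  if (x0 < 0) stop("x0 must be >= 0", call. = FALSE)
  n <- length(lengths)
  if (n < 2) stop("need at least 2 run lengths", call. = FALSE)
  n_below <- sum(lengths < x0)
  if (n_below > 0) {
    stop(n_below, " run length(s) fall below the truncation x0 = ", x0,
         call. = FALSE)
  }
  theta <- mean(lengths - x0)
  if (theta <= 0) stop("degenerate run lengths: all equal to x0", call. = FALSE)
  # least-squares on the empirical CDF as an independent route to theta
  srt <- sort(lengths)
  ecdf_y <- (seq_len(n) - 0.5) / n
  obj <- function(th) sum((ecdf_y - (1 - exp(-(srt - x0) / th)))^2)
  theta_cdf <- stats::optimize(obj, c(theta / 10, theta * 10))$minimum
  structure(list(mean = x0 + theta, se = theta / sqrt(n),
                 mean_cdf = x0 + theta_cdf, x0 = x0, n = n),
            class = "runlength_fit")
}

#' @export
print.runlength_fit <- function(x, ...) {
  cat(sprintf(
    "Run-length fit: %.2f +/- %.2f um (MLE, n = %d, x0 = %.2f um; CDF-LS %.2f um)\n",
    x$mean, x$se, x$n, x$x0, x$mean_cdf))
  invisible(x)
}

#' @export
coef.runlength_fit <- function(object, ...) {
  c(mean = object$mean, se = object$se)
}

#' Compare two speed samples (Welch t-test)
#'
#' Two-sided Welch two-sample t-test, the comparison used for speed
#' distributions between conditions. The report also carries the ratio of
#' sample means and its rounded percent difference (see
#' [percent_difference()]).
#'
#' @param a,b Numeric speed vectors, each `n >= 3`.
#' @return An object of class `run_comparison` with `statistic`, `p_value`,
#'   `test_name`, `n_a`, `n_b`, `mean_a`, `mean_b`, `ratio`, `percent_diff`.
#' @export
compare_speeds <- function(a, b) {
  check_sample_pair(a, b)
  tt <- stats::t.test(a, b, var.equal = FALSE)
  comparison_result(unname(tt$statistic), tt$p.value, "t-test", a, b)
}

#' Compare two run-length samples (Kolmogorov-Smirnov)
#'
#' Two-sample two-sided Kolmogorov-Smirnov test, the standard comparison for
#' run-length distributions whose shape (not just mean) is of interest.
#'
#' @inheritParams compare_speeds
#' @return An object of class `run_comparison`; `statistic` is the KS D.
#' @export
compare_run_lengths <- function(a, b) {
  check_sample_pair(a, b)
  ks <- suppressWarnings(stats::ks.test(a, b))
  comparison_result(unname(ks$statistic), ks$p.value, "KS", a, b)
}

check_sample_pair <- function(a, b) {
  if (length(a) < 3 || length(b) < 3) {
    stop("both samples need n >= 3 (got ", length(a), " and ", length(b), ")",
         call. = FALSE)
  }
  if (anyNA(a) || anyNA(b)) stop("samples contain NA", call. = FALSE)
  invisible(NULL)
}

comparison_result <- function(stat, p, test, a, b) {
  rr <- percent_difference(mean(a), mean(b))
  structure(list(statistic = stat, p_value = p, test_name = test,
                 n_a = length(a), n_b = length(b),
                 mean_a = mean(a), mean_b = mean(b),
                 ratio = rr$ratio, percent_diff = rr$percent_diff),
            class = "run_comparison")
}

#' Percent difference between two summary values
#'
#' The convention used when reporting one condition as "X% faster" or
#' "X% longer" than another: `ratio = a / b` and `percent_diff =
#' round(100 * (ratio - 1))`, rounded to a whole percent.
#'
#' @param a,b Summary values (e.g. fitted means); `b` is the reference.
#' @return A list with `ratio` and integer `percent_diff`.
#' @examples
#' percent_difference(8.9, 5.8)$percent_diff    # 53: 53% longer
#' percent_difference(0.63, 0.40)$percent_diff  # 58: 58% faster
#' @export
percent_difference <- function(a, b) {
  check_positive(b, "b")
  check_number(a, "a")
  ratio <- a / b
  # half away from zero, with a guard digit so ratios like 0.63/0.40 (57.5%
  # up to representation error) round the way they are quoted
  pct <- signif(100 * (ratio - 1), 12)
  list(ratio = ratio,
       percent_diff = as.integer(sign(pct) * floor(abs(pct) + 0.5)))
}

#' @export
print.run_comparison <- function(x, ...) {
  cat(sprintf("%s comparison: statistic %.4g, p = %.4g (n = %d vs %d)\n",
              x$test_name, x$statistic, x$p_value, x$n_a, x$n_b))
  cat(sprintf("  means %.3g vs %.3g; ratio %.3f (%+d%%)\n",
              x$mean_a, x$mean_b, x$ratio, x$percent_diff))
  invisible(x)
}
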