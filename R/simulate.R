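#' Assemble a population of labeled complexes
#'
#' Draws `n` complexes: each carries two copies of the labeled subunit with
#' probability `copy_model$d` (otherwise one), and each copy is independently
#' color 1 with probability `label_model$r`. When the labeled subunit is the
#' motor itself (`link_dynein = TRUE`) the motor count equals the copy count;
#' otherwise motor number is drawn independently with probability
#' `p_two_dynein` of two motors.
#'
#' @param n Number of complexes to draw.
#' @param copy_model A [copy_number_model()].
#' @param label_model A [label_model()].
#' @param p_two_dynein Probability that a complex carries two dynein motors
#'   when motor count is independent of the label (default 0.5).
#' @param link_dynein If `TRUE`, `n_dynein` is set equal to `n_copies`
#'   (appropriate when the labeled subunit is dynein).
#' @param seed Optional RNG seed; a fixed seed gives a bit-identical table.
#' @return A data frame of class `labeled_complexes` with columns
#'   `complex_id`, `n_copies`, `color_first`, `color_second` (`NA` for
#'   one-copy complexes), `color_class` (`"color1"`, `"color2"` or `"dual"`),
#'   and `n_dynein`.
#' @examples
#' cx <- assemble_complexes(1000, copy_number_model(d = 0.44),
#'                          label_model(), seed = 1)
#' mean(cx$color_class == "dual")   # about 2 * d * r * g = 0.22
#' @export
assemble_complexes <- function(n, copy_model, label_model,
                               p_two_dynein = 0.5, link_dynein = FALSE,
                               seed = NULL) {
  check_count(n, "n")
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  stopifnot(inherits(copy_model, "copy_number_model"),
            inherits(label_model, "label_model"))
  check_fraction(p_two_dynein, "p_two_dynein")

  with_seed_if(seed, {
    n_copies <- 1L + stats::rbinom(n, 1L, copy_model$d)
    first  <- ifelse(stats::runif(n) < label_model$r, "color1", "color2")
    second <- ifelse(stats::runif(n) < label_model$r, "color1", "color2")
    second[n_copies == 1L] <- NA_character_
    n_dynein <- if (link_dynein) {
      n_copies
    } else {
      1L + stats::rbinom(n, 1L, p_two_dynein)
    }
    cls <- ifelse(is.na(second) | first == second, first, "dual")
    out <- data.frame(complex_id = seq_len(n),
                      n_copies = n_copies,
                      color_first = first,
                      color_second = second,
                      color_class = cls,
                      n_dynein = n_dynein,
                      stringsAsFactors = FALSE)
    class(out) <- c("labeled_complexes", "data.frame")
    attr(out, "copy_model") <- copy_model
    attr(out, "label_model") <- label_model
    attr(out, "seed") <- seed
    out
  })
}

# channels present on one complex, derived from its copy colors
complex_channels <- function(color_first, color_second) {
  chans <- unique(stats::na.omit(c(color_first, color_second)))
  if ("dual" %in% chans) stop("invalid color label")
  chans
}

#' Simulate one processive run
#'
#' Draws the run's true speed from the Gaussian of its motor-number class
#' (redrawn while non-positive), its true length from the class exponential
#' (`length - min_detectable_runlen ~ Exp(mean - min_detectable_runlen)`),
#' then samples positions `p(t_k) = v t_k + eps_k` every `frame_interval`
#' until the run length is covered, with i.i.d. Gaussian localization error.
#' Every label color on the complex reports the same positions, mirroring a
#' rigid complex imaged in two channels.
#'
#' @param complex One row of an [assemble_complexes()] table (or a list with
#'   `complex_id`, `n_dynein`, `color_first`, `color_second`).
#' @param params A [motility_params()].
#' @param seed Optional RNG seed.
#' @return A data frame of class `trajectory` with columns `complex_id`,
#'   `channel`, `frame`, `time_s`, `position_um`; attributes record the true
#'   speed and length.
#' @export
simulate_run <- function(complex, params, seed = NULL) {
  stopifnot(inherits(params, "motility_params"))
  two <- complex$n_dynein == 2L
  mu <- if (two) params$speed_mean_two else params$speed_mean_one
  sg <- if (two) params$speed_sd_two else params$speed_sd_one
  lm0 <- if (two) params$runlen_mean_two else params$runlen_mean_one
  x0 <- params$min_detectable_runlen

  with_seed_if(seed, {
    v <- stats::rnorm(1, mu, sg)
    while (v <= 0) v <- stats::rnorm(1, mu, sg)
    len <- x0 + stats::rexp(1, rate = 1 / (lm0 - x0))
    traj_from_kinetics(complex, v, len, params)
  })
}

# Deterministic part of run synthesis: frame times, noise, channel replication.
# Kept separate so simulate_field can draw kinetics in bulk.
traj_from_kinetics <- function(complex, v, len, params) {
  dt <- params$frame_interval
  k_max <- floor(len / (v * dt) + 1e-9)
  tt <- seq(0, k_max) * dt
  pos <- v * tt
  if (params$localization_sd > 0) {
    pos <- pos + stats::rnorm(length(pos), 0, params$localization_sd)
  }
  chans <- complex_channels(complex$color_first, complex$color_second)
  out <- data.frame(
    complex_id = complex$complex_id,
    channel = rep(chans, each = length(tt)),
    frame = rep(seq_along(tt) - 1L, times = length(chans)),
    time_s = rep(tt, times = length(chans)),
    position_um = rep(pos, times = length(chans)),
    stringsAsFactors = FALSE)
  class(out) <- c("trajectory", "data.frame")
  attr(out, "true_speed") <- v
  attr(out, "true_length") <- len
  out
}

#' Simulate a whole imaging field
#'
#' Landing events are homogeneous Poisson in time with expected count
#' `landing_rate_coeff * dynein_conc * mt_total_length * duration`; each
#' landing produces one complex drawn from the copy/label models and one
#' processive run via the kinetics of [simulate_run()]. Runs are emitted
#' pre-segmented; truncation at microtubule ends is not modeled.
#'
#' @param field A [field_config()].
#' @param copy_model A [copy_number_model()].
#' @param label_model A [label_model()].
#' @param params A [motility_params()].
#' @param p_two_dynein,link_dynein Passed to [assemble_complexes()].
#' @param seed Optional RNG seed; overrides `field$seed` when given.
#' @return An object of class `field_dataset`: a list with `trajectories`
#'   (one long data frame), `complexes` (the generating complex table), and
#'   `config` (all generating parameters, for downstream normalization).
#' @export
simulate_field <- function(field, copy_model, label_model, params,
                           p_two_dynein = 0.5, link_dynein = FALSE,
                           seed = NULL) {
  stopifnot(inherits(field, "field_config"))
  if (is.null(seed)) seed <- field$seed
  lambda <- field$landing_rate_coeff * field$dynein_conc *
    field$mt_total_length * field$duration

  with_seed_if(seed, {
    n_runs <- stats::rpois(1, lambda)
    cx <- if (n_runs > 0) {
      assemble_complexes(n_runs, copy_model, label_model,
                         p_two_dynein = p_two_dynein,
                         link_dynein = link_dynein)
    } else {
      empty_complexes()
    }
    trajs <- simulate_runs_bulk(cx, params)
    structure(list(trajectories = trajs,
                   complexes = cx,
                   config = list(field = field, copy_model = copy_model,
                                 label_model = label_model, params = params,
                                 p_two_dynein = p_two_dynein,
                                 link_dynein = link_dynein, seed = seed)),
              class = "field_dataset")
  })
}

empty_complexes <- function() {
  out <- data.frame(complex_id = integer(0), n_copies = integer(0),
                    color_first = character(0), color_second = character(0),
                    color_class = character(0), n_dynein = integer(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("labeled_complexes", "data.frame")
  out
}

# Vectorized run synthesis for a whole complex table. Draws all speeds and
# lengths at once, then expands frames with rep(); avoids per-run overhead at
# n ~ 1e5.
simulate_runs_bulk <- function(cx, params) {
  n <- nrow(cx)
  if (n == 0) {
    out <- data.frame(complex_id = integer(0), channel = character(0),
                      frame = integer(0), time_s = numeric(0),
                      position_um = numeric(0), stringsAsFactors = FALSE)
    return(out)
  }
  two <- cx$n_dynein == 2L
  mu <- ifelse(two, params$speed_mean_two, params$speed_mean_one)
  sg <- ifelse(two, params$speed_sd_two, params$speed_sd_one)
  lm0 <- ifelse(two, params$runlen_mean_two, params$runlen_mean_one)
  x0 <- params$min_detectable_runlen
  dt <- params$frame_interval

  v <- stats::rnorm(n, mu, sg)
  bad <- which(v <= 0)
  while (length(bad) > 0) {
    v[bad] <- stats::rnorm(length(bad), mu[bad], sg[bad])
    bad <- bad[v[bad] <= 0]
  }
  len <- x0 + stats::rexp(n, rate = 1 / (lm0 - x0))

  n_frames <- floor(len / (v * dt) + 1e-9) + 1L
  idx <- rep.int(seq_len(n), n_frames)
  frame <- sequence(n_frames) - 1L
  tt <- frame * dt
  pos <- v[idx] * tt
  if (params$localization_sd > 0) {
    pos <- pos + stats::rnorm(length(pos), 0, params$localization_sd)
  }
  # duplicate the noisy track into each channel the complex is labeled in
  base <- data.frame(complex_id = cx$complex_id[idx],
                     channel = cx$color_first[idx],
                     frame = frame,
                     time_s = tt,
                     position_um = pos,
                     stringsAsFactors = FALSE)
  dual_row <- cx$color_class[idx] == "dual"
  if (any(dual_row)) {
    ch2 <- base[dual_row, ]
    base$channel[dual_row] <- "color1"
    ch2$channel <- "color2"
    base <- rbind(base, ch2)
    base <- base[order(base$complex_id, base$channel, base$frame), ]
    rownames(base) <- NULL
  }
  out <- base
  attr(out, "true_speed") <- v
  attr(out, "true_length") <- len
  out
}

#' @export
print.field_dataset <- function(x, ...) {
  cat("Field dataset:", nrow(x$complexes), "runs,",
      nrow(x$trajectories), "trajectory samples\n")
  print(x$config$field)
  invisible(x)
}

#' Render a kymograph from trajectories
#'
#' Quantizes each trajectory sample to a position pixel and a frame and
#' accumulates unit intensity, producing the position-vs-time image a TIRF
#' acquisition of the same field would summarize to. Intended for visual QC,
#' not for re-detection.
#'
#' @param trajs A trajectory data frame (`complex_id`, `channel`, `frame`,
#'   `time_s`, `position_um`) or a `field_dataset`.
#' @param pixel_size Pixel size (um); default 0.1066 um/pixel.
#' @param channel Optional channel to restrict to.
#' @return An integer matrix (position pixel x frame) of class `kymograph`,
#'   all-zero `1 x 1` with attribute `empty = TRUE` for an empty dataset.
#' @export
render_kymograph <- function(trajs, pixel_size = 0.1066, channel = NULL) {
  check_positive(pixel_size, "pixel_size")
  if (inherits(trajs, "field_dataset")) trajs <- trajs$trajectories
  if (!is.null(channel)) trajs <- trajs[trajs$channel == channel, ]
  if (nrow(trajs) == 0) {
    img <- matrix(0L, 1, 1)
    class(img) <- c("kymograph", class(img))
    attr(img, "empty") <- TRUE
    warning("empty dataset: returning an all-zero kymograph", call. = FALSE)
    return(img)
  }
  px <- floor(trajs$position_um / pixel_size)
  px <- px - min(px)
  fr <- trajs$frame - min(trajs$frame)
  img <- matrix(0L, nrow = max(px) + 1L, ncol = max(fr) + 1L)
  tab <- table(px, fr)
  img[cbind(as.integer(rownames(tab))[row(tab)] + 1L,
            as.integer(colnames(tab))[col(tab)] + 1L)] <- as.integer(tab)
  class(img) <- c("kymograph", class(img))
  attr(img, "pixel_size") <- pixel_size
  attr(img, "empty") <- FALSE
  img
}

#' @export
plot.kymograph <- function(x, ...) {
  graphics::image(t(unclass(x)), col = grDevices::grey.colors(32, 1, 0),
                  axes = FALSE,
                  xlab = "frame", ylab = "position pixel", ...)
  invisible(x)
}
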