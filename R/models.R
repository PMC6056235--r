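#' Copy-number model for a dimeric adaptor site
#'
#' Describes a population of complexes in which each complex carries either
#' one or two copies of a labeled subunit (adaptor, motor, or mRNA).
#' `s` is the fraction of one-copy complexes and `d` the fraction of two-copy
#' complexes; the two must sum to one.
#'
#' @param d Fraction of complexes carrying two labeled copies, in `[0, 1]`.
#' @param s Fraction carrying one copy. Defaults to `1 - d`.
#' @return An object of class `copy_number_model` with elements `s` and `d`.
#' @examples
#' copy_number_model(d = 0.44)
#' @export
copy_number_model <- function(d, s = 1 - d) {
  check_fraction(d, "d")
  check_fraction(s, "s")
  if (abs(s + d - 1) > 1e-8) {
    stop("copy-number fractions must satisfy s + d = 1 (got s = ", s,
         ", d = ", d, ")", call. = FALSE)
  }
  structure(list(s = s, d = d), class = "copy_number_model")
}

#' Two-color labeling model
#'
#' Each labeled copy is independently color 1 with probability `r` or
#' color 2 with probability `g = 1 - r`, reflecting a preparation that mixes
#' two spectrally distinct labels (e.g. 488 nm and 647 nm fluorophores) at
#' fractions `r` and `g`.
#'
#' @param r Fraction of copies carrying color 1, in `[0, 1]`.
#' @param g Fraction carrying color 2. Defaults to `1 - r`.
#' @return An object of class `label_model` with elements `r` and `g`.
#' @examples
#' label_model()          # equimolar labels, r = g = 0.5
#' label_model(r = 0.3)
#' @export
label_model <- function(r = 0.5, g = 1 - r) {
  check_fraction(r, "r")
  check_fraction(g, "g")
  if (abs(r + g - 1) > 1e-8) {
    stop("label_model fractions must satisfy r + g = 1 (got r = ", r,
         ", g = ", g, ")", call. = FALSE)
  }
  structure(list(r = r, g = g), class = "label_model")
}

#' Motility parameters of the one- and two-dynein classes
#'
#' Class-conditional kinetic parameters used by the run simulator. Speeds are
#' Gaussian within each motor-number class (truncated at zero when sampled);
#' run lengths are exponential with a class-specific characteristic length.
#' `runlen_mean_*` follows the convention of the exponential fit: it is the
#' characteristic run length including the detection offset, so sampled
#' lengths satisfy `length - min_detectable_runlen ~ Exp(mean -
#' min_detectable_runlen)`.
#'
#' Defaults are the speed classes of single- vs two-motor complexes
#' (0.40 +/- 0.14 and 0.74 +/- 0.13 um/s) and their characteristic run
#' lengths (5.8 and 8.9 um).
#'
#' @param speed_mean_one,speed_sd_one Speed mean and SD (um/s), one-dynein class.
#' @param speed_mean_two,speed_sd_two Speed mean and SD (um/s), two-dynein class.
#' @param runlen_mean_one,runlen_mean_two Characteristic run lengths (um).
#' @param min_detectable_runlen Shortest scoreable run (um); default 0.5 um,
#'   about five camera pixels.
#' @param frame_interval Sampling interval (s); default 0.2 s.
#' @param localization_sd Gaussian localization noise SD (um); default
#'   0.03 um, typical for quantum-dot tracking.
#' @return An object of class `motility_params`.
#' @export
motility_params <- function(speed_mean_one = 0.40, speed_sd_one = 0.14,
                            speed_mean_two = 0.74, speed_sd_two = 0.13,
                            runlen_mean_one = 5.8, runlen_mean_two = 8.9,
                            min_detectable_runlen = 0.5,
                            frame_interval = 0.2,
                            localization_sd = 0.03) {
  p <- list(speed_mean_one = speed_mean_one, speed_sd_one = speed_sd_one,
            speed_mean_two = speed_mean_two, speed_sd_two = speed_sd_two,
            runlen_mean_one = runlen_mean_one, runlen_mean_two = runlen_mean_two,
            min_detectable_runlen = min_detectable_runlen,
            frame_interval = frame_interval,
            localization_sd = localization_sd)
  for (nm in setdiff(names(p), "localization_sd")) {
    check_positive(p[[nm]], nm)
  }
  check_number(p$localization_sd, "localization_sd")
  if (p$localization_sd < 0) {
    stop("localization_sd must be >= 0", call. = FALSE)
  }
  for (nm in c("runlen_mean_one", "runlen_mean_two")) {
    if (p[[nm]] <= p$min_detectable_runlen) {
      stop(nm, " must exceed min_detectable_runlen", call. = FALSE)
    }
  }
  structure(p, class = "motility_params")
}

#' Field configuration for a whole-field simulation
#'
#' Describes one imaging field: motor concentration, total microtubule
#' length, acquisition duration, and the landing-rate coefficient. The
#' expected number of runs is `landing_rate_coeff * dynein_conc *
#' mt_total_length * duration` and actual counts are Poisson.
#'
#' @param dynein_conc Dynein concentration (uM).
#' @param mt_total_length Total microtubule length in the field (um).
#' @param duration Observation time (s).
#' @param landing_rate_coeff Runs per (uM motor x um microtubule x s).
#' @param seed Optional RNG seed recorded with the field.
#' @return An object of class `field_config`.
#' @export
field_config <- function(dynein_conc, mt_total_length, duration,
                         landing_rate_coeff, seed = NULL) {
  check_positive(dynein_conc, "dynein_conc")
  check_positive(mt_total_length, "mt_total_length")
  check_positive(duration, "duration")
  check_number(landing_rate_coeff, "landing_rate_coeff")
  if (landing_rate_coeff < 0) {
    stop("landing_rate_coeff must be >= 0", call. = FALSE)
  }
  structure(list(dynein_conc = dynein_conc,
                 mt_total_length = mt_total_length,
                 duration = duration,
                 landing_rate_coeff = landing_rate_coeff,
                 seed = seed),
            class = "field_config")
}

#' @export
print.copy_number_model <- function(x, ...) {
  cat("Copy-number model: s =", x$s, "(one copy), d =", x$d, "(two copies)\n")
  invisible(x)
}

#' @export
print.label_model <- function(x, ...) {
  cat("Label model: r =", x$r, "(color 1), g =", x$g, "(color 2)\n")
  invisible(x)
}

#' @export
print.motility_params <- function(x, ...) {
  cat("Motility parameters\n")
  cat(sprintf("  one-dynein:  speed %.2f +/- %.2f um/s, run length %.1f um\n",
              x$speed_mean_one, x$speed_sd_one, x$runlen_mean_one))
  cat(sprintf("  two-dynein:  speed %.2f +/- %.2f um/s, run length %.1f um\n",
              x$speed_mean_two, x$speed_sd_two, x$runlen_mean_two))
  cat(sprintf("  detection >= %.2f um, frame %.1f s, localization SD %.3f um\n",
              x$min_detectable_runlen, x$frame_interval, x$localization_sd))
  invisible(x)
}

#' @export
print.field_config <- function(x, ...) {
  cat(sprintf(
    "Field: %.3g uM dynein, %.3g um MT, %.3g s; landing coeff %.3g -> E[runs] = %.3g\n",
    x$dynein_conc, x$mt_total_length, x$duration, x$landing_rate_coeff,
    x$landing_rate_coeff * x$dynein_conc * x$mt_total_length * x$duration))
  invisible(x)
}
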