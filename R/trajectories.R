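#' Estimate speed from a tracked run
#'
#' Speed is the magnitude of the ordinary-least-squares slope of position
#' against time over the whole run. Fitting the slope over all frames, rather
#' than dividing net displacement by duration, damps the influence of
#' localization error at the two endpoints.
#'
#' @param traj A trajectory data frame with `time_s` and `position_um`
#'   columns (one complex, one channel).
#' @return Speed in um/s.
#' @export
estimate_speed <- function(traj) {
  tp <- one_channel(traj)
  if (nrow(tp) < 3) {
    stop("estimate_speed needs >= 3 samples (got ", nrow(tp), ")",
         call. = FALSE)
  }
  tt <- tp$time_s
  pp <- tp$position_um
  abs(sum((tt - mean(tt)) * (pp - mean(pp))) / sum((tt - mean(tt))^2))
}

#' Measure run length from a tracked run
#'
#' Run length is the net start-to-end displacement; pauses within the run
#' are not excised.
#'
#' @inheritParams estimate_speed
#' @return Run length in um.
#' @export
measure_run_length <- function(traj) {
  tp <- one_channel(traj)
  if (nrow(tp) < 2) {
    stop("measure_run_length needs >= 2 samples (got ", nrow(tp), ")",
         call. = FALSE)
  }
  abs(tp$position_um[nrow(tp)] - tp$position_um[1])
}

# pick a single channel's samples, ordered in time
one_channel <- function(traj) {
  if (inherits(traj, "field_dataset")) {
    stop("pass a single trajectory, not a field_dataset", call. = FALSE)
  }
  if (!is.null(traj$channel) && length(unique(traj$channel)) > 1) {
    traj <- traj[traj$channel == traj$channel[1], ]
  }
  traj[order(traj$time_s), , drop = FALSE]
}

#' Classify a trajectory's color class
#'
#' A run is `dual` when both channels are present and their median
#' inter-channel distance at shared frames is within `radius`; otherwise it
#' takes the class of its single present channel. Co-moving but spatially
#' separate channels (median distance beyond `radius`) are flagged as two
#' coincident single-color runs.
#'
#' @inheritParams estimate_speed
#' @param radius Colocalization radius (um); default one camera pixel,
#'   0.1066 um.
#' @return A character scalar: `"color1"`, `"color2"` or `"dual"`. If both
#'   channels exist but never colocalize, the value carries attribute
#'   `split = TRUE` and names the channels present.
#' @export
classify_color <- function(traj, radius = 0.1066) {
  check_positive(radius, "radius")
  chans <- unique(traj$channel)
  if (length(chans) == 0) stop("trajectory has no channel", call. = FALSE)
  if (length(chans) == 1) return(chans)
  a <- traj[traj$channel == chans[1], c("frame", "position_um")]
  b <- traj[traj$channel == chans[2], c("frame", "position_um")]
  m <- merge(a, b, by = "frame")
  med <- stats::median(abs(m$position_um.x - m$position_um.y))
  if (is.na(med) || med > radius) {
    out <- structure("split", split = TRUE, channels = sort(chans))
    return(out)
  }
  "dual"
}

#' Normalized run frequency
#'
#' The total number of runs divided by motor concentration, total
#' microtubule length and observation time, the standard normalization that
#' makes landing rates comparable across fields and preparations.
#'
#' @param n_runs Number of runs counted.
#' @param conc Motor concentration (uM).
#' @param mt_length Total microtubule length (um).
#' @param duration Observation time (s).
#' @return An object of class `run_frequency` with `value` in runs per
#'   (uM x um x s), the raw count, and the normalizers.
#' @examples
#' run_frequency(100, conc = 1, mt_length = 100, duration = 100)  # 0.01
#' @export
run_frequency <- function(n_runs, conc, mt_length, duration) {
  check_count(n_runs, "n_runs")
  check_positive(conc, "conc")
  check_positive(mt_length, "mt_length")
  check_positive(duration, "duration")
  structure(list(value = n_runs / (conc * mt_length * duration),
                 n_runs = n_runs,
                 normalizers = c(conc = conc, mt_length = mt_length,
                                 duration = duration)),
            class = "run_frequency")
}

#' @export
print.run_frequency <- function(x, ...) {
  cat(sprintf("Run frequency: %.4g runs / (uM x um x s)  [%d runs]\n",
              x$value, x$n_runs))
  invisible(x)
}

#' Reduce a trajectory table to per-run records
#'
#' Applies [estimate_speed()], [measure_run_length()] and [classify_color()]
#' to every complex in a trajectory table, producing the per-run table that
#' the fitting and stoichiometry stages consume. Runs with fewer than three
#' frames are dropped and counted in the `rejected` attribute.
#'
#' @param trajs A trajectory data frame or `field_dataset`.
#' @param radius Colocalization radius (um) for [classify_color()].
#' @return A data frame of class `run_records` with columns `complex_id`,
#'   `speed_um_s`, `run_length_um`, `duration_s`, `color_class`, `n_frames`.
#' @export
summarize_runs <- function(trajs, radius = 0.1066) {
  if (inherits(trajs, "field_dataset")) trajs <- trajs$trajectories
  if (nrow(trajs) == 0) return(empty_run_records())
  trajs <- trajs[order(trajs$complex_id, trajs$channel, trajs$time_s), ]

  # grouped sufficient statistics per (complex, channel): the OLS slope and
  # endpoints only need sums, so the whole table reduces with rowsum()
  key <- paste(trajs$complex_id, trajs$channel, sep = "\r")
  ukey <- !duplicated(key)
  sums <- rowsum(cbind(n = 1, t = trajs$time_s, p = trajs$position_um,
                       tt = trajs$time_s^2, tp = trajs$time_s *
                         trajs$position_um),
                 key, reorder = FALSE)
  first_pos <- trajs$position_um[ukey]
  last_pos <- trajs$position_um[rev(nrow(trajs) + 1 -
                                      which(!duplicated(rev(key))))]
  first_t <- trajs$time_s[ukey]
  last_t <- trajs$time_s[rev(nrow(trajs) + 1 - which(!duplicated(rev(key))))]
  grp_id <- trajs$complex_id[ukey]
  grp_chan <- trajs$channel[ukey]

  n <- sums[, "n"]
  sxx <- sums[, "tt"] - sums[, "t"]^2 / n
  sxy <- sums[, "tp"] - sums[, "t"] * sums[, "p"] / n
  speed <- abs(sxy / sxx)

  # reference channel = first channel of each complex
  ref <- !duplicated(grp_id)
  n_chan <- as.vector(table(factor(grp_id, levels = unique(grp_id))))

  # colocalization distance for two-channel complexes, at shared frames
  cls <- grp_chan[ref]
  two <- which(n_chan == 2L)
  if (length(two) > 0) {
    two_ids <- unique(grp_id)[two]
    sub <- trajs[trajs$complex_id %in% two_ids, ]
    fkey <- paste(sub$complex_id, sub$frame, sep = "\r")
    shared <- fkey %in% fkey[duplicated(fkey)]
    sub <- sub[shared, ]
    # rows alternate channels within each (complex, frame) after reordering
    sub <- sub[order(sub$complex_id, sub$frame, sub$channel), ]
    odd <- seq(1, nrow(sub), by = 2)
    dist <- abs(sub$position_um[odd] - sub$position_um[odd + 1])
    med <- tapply(dist, sub$complex_id[odd], stats::median)
    coloc <- med[as.character(two_ids)] <= radius
    coloc[is.na(coloc)] <- FALSE
    cls[two] <- ifelse(coloc, "dual", "split")
  }

  keep <- n[ref] >= 3
  out <- data.frame(complex_id = grp_id[ref][keep],
                    speed_um_s = speed[ref][keep],
                    run_length_um = abs(last_pos[ref] - first_pos[ref])[keep],
                    duration_s = (last_t[ref] - first_t[ref])[keep],
                    color_class = cls[keep],
                    n_frames = as.integer(n[ref][keep]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("run_records", "data.frame")
  attr(out, "rejected") <- sum(!keep)
  out
}

empty_run_records <- function() {
  out <- data.frame(complex_id = integer(0), speed_um_s = numeric(0),
                    run_length_um = numeric(0), duration_s = numeric(0),
                    color_class = character(0), n_frames = integer(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("run_records", "data.frame")
  out
}

#' Filter run records by length and frame count
#'
#' @param runs A `run_records` table.
#' @param min_length Minimum run length (um).
#' @param min_frames Minimum number of frames.
#' @return The surviving rows; attributes `n_before` / `n_after` record the
#'   filtering. A message reports the counts; an empty result warns.
#' @export
filter_runs <- function(runs, min_length = 0, min_frames = 0) {
  if (min_length < 0 || min_frames < 0) {
    stop("filter thresholds must be >= 0", call. = FALSE)
  }
  keep <- runs$run_length_um >= min_length & runs$n_frames >= min_frames
  out <- runs[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_before") <- nrow(runs)
  attr(out, "n_after") <- nrow(out)
  message(sprintf("filter_runs: %d of %d runs retained", nrow(out), nrow(runs)))
  if (nrow(out) == 0 && nrow(runs) > 0) {
    warning("all runs removed by filter", call. = FALSE)
  }
  out
}
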