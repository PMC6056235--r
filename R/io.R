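# Plain-text interchange: trajectory tables and run tables as CSV, reports
# and manifests as JSON, configs as YAML or JSON.

#' Write / read trajectory tables
#'
#' Trajectories travel as CSV with the fixed header
#' `complex_id,channel,frame,time_s,position_um`. An optional JSON sidecar
#' (`<file>.json`) records the generating configuration and seed so any
#' dataset can be regenerated bit-identically.
#'
#' @param trajs A trajectory data frame or `field_dataset`.
#' @param file Output CSV path.
#' @param sidecar Write the JSON sidecar when metadata is available
#'   (default TRUE).
#' @return `file`, invisibly.
#' @export
write_trajectories <- function(trajs, file, sidecar = TRUE) {
  meta <- NULL
  if (inherits(trajs, "field_dataset")) {
    meta <- trajs$config
    trajs <- trajs$trajectories
  }
  utils::write.csv(trajs[, c("complex_id", "channel", "frame", "time_s",
                             "position_um")],
                   file, row.names = FALSE, quote = FALSE)
  if (sidecar && !is.null(meta)) {
    jsonlite::write_json(config_to_list(meta), paste0(file, ".json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(file)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(file) {
  out <- utils::read.csv(file, stringsAsFactors = FALSE,
                         colClasses = c(complex_id = "integer",
                                        channel = "character",
                                        frame = "integer",
                                        time_s = "numeric",
                                        position_um = "numeric"))
  need <- c("complex_id", "channel", "frame", "time_s", "position_um")
  if (!all(need %in% names(out))) {
    stop("trajectory CSV must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  }
  out
}

#' Write / read per-run tables
#'
#' Run records travel as CSV with header
#' `complex_id,speed_um_s,run_length_um,duration_s,color_class,n_frames`.
#'
#' @param runs A `run_records` data frame.
#' @param file CSV path.
#' @return `file` (write) or the table (read), invisibly for write.
#' @export
write_runs <- function(runs, file) {
  utils::write.csv(runs[, c("complex_id", "speed_um_s", "run_length_um",
                            "duration_s", "color_class", "n_frames")],
                   file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_runs
#' @export
read_runs <- function(file) {
  out <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("complex_id", "speed_um_s", "run_length_um", "duration_s",
            "color_class", "n_frames")
  if (!all(need %in% names(out))) {
    stop("runs CSV must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  }
  class(out) <- c("run_records", "data.frame")
  out
}

#' Read colocalization category counts
#'
#' Accepts a two-column CSV (`category,count` with categories
#' `color1`, `color2`, `dual`) or a JSON object with those keys.
#'
#' @param file Path to CSV or JSON counts.
#' @return An [observed_fractions()] object.
#' @export
read_color_counts <- function(file) {
  if (grepl("\\.json$", file, ignore.case = TRUE)) {
    x <- jsonlite::read_json(file, simplifyVector = TRUE)
    cnt <- c(color1 = x$color1, color2 = x$color2, dual = x$dual)
  } else {
    tab <- utils::read.csv(file, stringsAsFactors = FALSE)
    if (!all(c("category", "count") %in% names(tab))) {
      stop("counts CSV must have columns category,count", call. = FALSE)
    }
    cnt <- stats::setNames(tab$count, tab$category)[c("color1", "color2",
                                                      "dual")]
  }
  if (anyNA(cnt)) {
    stop("counts must include categories color1, color2, dual", call. = FALSE)
  }
  observed_fractions_from_counts(cnt[["color1"]], cnt[["color2"]],
                                 cnt[["dual"]])
}

#' Read a pipeline configuration (YAML or JSON)
#'
#' @param file Path; format chosen by extension (`.yaml`/`.yml` or `.json`).
#' @return A named list.
#' @export
read_config <- function(file) {
  if (!file.exists(file)) stop("config file not found: ", file, call. = FALSE)
  if (grepl("\\.json$", file, ignore.case = TRUE)) {
    jsonlite::read_json(file, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(file)
  }
}

# serialize nested config objects (S3 lists) to plain lists for JSON
config_to_list <- function(x) {
  if (is.list(x)) {
    lapply(unclass(x), config_to_list)
  } else {
    x
  }
}
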