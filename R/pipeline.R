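#' Run the simulate / analyze / fit / stoichiometry pipeline
#'
#' Executes the requested stages in order and writes all outputs plus a
#' manifest (configuration, seed, package version) into `out_dir`, so that
#' the manifest alone suffices to reproduce every file bit-identically.
#'
#' Configuration is a nested list (or a YAML/JSON file path) with optional
#' blocks:
#' \describe{
#'   \item{simulate}{`field` (dynein_conc, mt_total_length, duration,
#'     landing_rate_coeff), `copy_model` (d), `label_model` (r),
#'     `params` (overrides for [motility_params()]), `p_two_dynein`,
#'     `link_dynein`.}
#'   \item{analyze}{`radius`, `min_length`, `min_frames`; requires
#'     simulated trajectories or `trajectories` (a CSV path).}
#'   \item{fit}{`speeds` (`k_candidates`), `run_lengths` (`x0`).}
#'   \item{stoich}{`r`; counts are taken from the analyzed color classes or
#'     from `counts` (a CSV/JSON path).}
#' }
#'
#' @param config A named list or path to a YAML/JSON config file.
#' @param seed Integer seed for the whole run; overrides `config$seed`.
#' @param out_dir Output directory (created if needed); overrides
#'   `config$out_dir`.
#' @return Invisibly, a list with the in-memory results of each stage and
#'   `files`, the paths written.
#' @export
run_pipeline <- function(config, seed = NULL, out_dir = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- read_config(config)
  }
  if (!is.list(config)) stop("config must be a list or file path", call. = FALSE)
  if (is.null(seed)) seed <- config$seed
  if (is.null(seed)) stop("a seed is required (config$seed or seed =)",
                          call. = FALSE)
  if (is.null(out_dir)) out_dir <- config$out_dir
  if (is.null(out_dir)) stop("an output directory is required", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  results <- list(files = character(0))
  seeds <- split_seed(seed, 4)

  if (!is.null(config$simulate)) {
    results$dataset <- pipeline_simulate(config$simulate, seeds[[1]])
    f <- file.path(out_dir, "trajectories.csv")
    write_trajectories(results$dataset, f)
    results$files <- c(results$files, f, paste0(f, ".json"))
  }

  if (!is.null(config$analyze)) {
    cfg <- config$analyze
    trajs <- if (!is.null(cfg$trajectories)) {
      read_trajectories(cfg$trajectories)
    } else if (!is.null(results$dataset)) {
      results$dataset
    } else {
      stop("analyze: no trajectories available (run simulate or give ",
           "analyze$trajectories)", call. = FALSE)
    }
    runs <- summarize_runs(trajs, radius = cfg$radius %||% 0.1066)
    runs <- suppressMessages(
      filter_runs(runs, min_length = cfg$min_length %||% 0,
                  min_frames = cfg$min_frames %||% 0))
    results$runs <- runs
    f <- file.path(out_dir, "runs.csv")
    write_runs(runs, f)
    results$files <- c(results$files, f)
    if (!is.null(results$dataset)) {
      fc <- results$dataset$config$field
      freq <- run_frequency(nrow(runs), fc$dynein_conc, fc$mt_total_length,
                            fc$duration)
      results$frequency <- freq
      f <- file.path(out_dir, "run_frequency.json")
      jsonlite::write_json(unclass(freq), f, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
      results$files <- c(results$files, f)
    }
  }

  if (!is.null(config$fit)) {
    if (is.null(results$runs)) {
      stop("fit: no run table available (run analyze first)", call. = FALSE)
    }
    cfg <- config$fit
    rep <- list()
    if (!is.null(cfg$speeds)) {
      k_cand <- cfg$speeds$k_candidates %||% c(1, 2)
      fit <- fit_speed_mixture(results$runs$speed_um_s,
                               k_candidates = k_cand, seed = seeds[[2]])
      results$speed_fit <- fit
      rep$speeds <- list(k = fit$k, weights = fit$weights, means = fit$means,
                         sds = fit$sds, log_likelihood = fit$log_likelihood,
                         bic = as.list(fit$bic), n = fit$n)
    }
    if (!is.null(cfg$run_lengths)) {
      x0 <- cfg$run_lengths$x0 %||% 0
      lens <- results$runs$run_length_um
      # measured lengths can fall below the detection cutoff through
      # localization noise and frame quantization; the truncated fit is
      # only defined above x0, so shorter runs are dropped here
      if (any(lens < x0)) {
        message(sprintf("fit: dropping %d run(s) shorter than x0 = %g um",
                        sum(lens < x0), x0))
        lens <- lens[lens >= x0]
      }
      fit <- fit_run_lengths(lens, x0 = x0)
      results$runlength_fit <- fit
      rep$run_lengths <- unclass(fit)
    }
    f <- file.path(out_dir, "fits.json")
    jsonlite::write_json(rep, f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    results$files <- c(results$files, f)
  }

  if (!is.null(config$stoich)) {
    cfg <- config$stoich
    obs <- if (!is.null(cfg$counts)) {
      read_color_counts(cfg$counts)
    } else if (!is.null(results$runs)) {
      cls <- results$runs$color_class
      observed_fractions_from_counts(sum(cls == "color1"),
                                     sum(cls == "color2"),
                                     sum(cls == "dual"))
    } else {
      stop("stoich: no counts available (run analyze or give stoich$counts)",
           call. = FALSE)
    }
    lm <- pipeline_label_model(cfg)
    est <- correct_copy_number(obs, lm, seed = seeds[[3]])
    results$stoich <- est
    rep <- list(d = est$d, s = est$s, d_raw = est$d_raw,
                clipped = est$clipped, ci_low = est$ci_low,
                ci_high = est$ci_high, n_total = est$n_total,
                observed = unclass(est$obs))
    if (!is.na(obs$f1) && !is.na(obs$f2)) {
      chk <- consistency_check(obs, lm)
      rep$consistency <- unclass(chk)
    }
    f <- file.path(out_dir, "stoichiometry.json")
    jsonlite::write_json(rep, f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    results$files <- c(results$files, f)
  }

  manifest <- list(config = config_to_list(config), seed = seed,
                   package = "mrnpmotility",
                   version = as.character(utils::packageVersion("mrnpmotility")))
  f <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, f, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  results$files <- c(results$files, f)
  invisible(results)
}

pipeline_simulate <- function(cfg, seed) {
  for (nm in c("field", "copy_model")) {
    if (is.null(cfg[[nm]])) {
      stop("simulate config is missing the '", nm, "' block", call. = FALSE)
    }
  }
  field <- do.call(field_config, cfg$field)
  copy_model <- tryCatch(do.call(copy_number_model, cfg$copy_model),
                         error = function(e) {
                           stop("copy_model: ", conditionMessage(e),
                                call. = FALSE)
                         })
  lm <- pipeline_label_model(cfg$label_model %||% list())
  params <- do.call(motility_params, cfg$params %||% list())
  simulate_field(field, copy_model, lm, params,
                 p_two_dynein = cfg$p_two_dynein %||% 0.5,
                 link_dynein = isTRUE(cfg$link_dynein),
                 seed = seed)
}

pipeline_label_model <- function(cfg) {
  args <- cfg[intersect(names(cfg), c("r", "g"))]
  tryCatch(do.call(label_model, args),
           error = function(e) {
             stop("label_model: ", conditionMessage(e), call. = FALSE)
           })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
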