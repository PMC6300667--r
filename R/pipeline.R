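# End-to-end pipeline driver and command-line interface.

#' Pipeline configuration
#'
#' Collects every numeric analysis parameter at its reference default:
#' 2.5 SD despike threshold, 0.01-0.1 Hz band, 21.6 s initial drop, 4 mm
#' FWHM smoothing, FDR q = 0.05, 500 split-half iterations, 1000
#' permutations, ISC labeling threshold 0.15, and a single global seed
#' from which all stage substreams derive.
#'
#' @param output_dir directory for results.
#' @param simulate generate inputs with the synthetic-data module.
#' @param stages character subset of
#'   `c("simulate", "preprocess", "connectivity", "netstruct", "isc", "taskglm")`.
#' @param seed global integer seed.
#' @param n_subjects,n_subjects_movie subject counts.
#' @param despike_sd,band_low,band_high,drop_seconds,fwhm_mm preprocessing
#'   parameters.
#' @param fdr_q FDR level.
#' @param split_half_iterations,n_permutations resampling sizes.
#' @param isc_threshold ISC labeling threshold.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir = "pulvicor-results",
                            simulate = TRUE,
                            stages = c("simulate", "preprocess", "connectivity",
                                       "netstruct", "isc", "taskglm"),
                            seed = 1L,
                            n_subjects = 13,
                            n_subjects_movie = 11,
                            despike_sd = 2.5,
                            band_low = 0.01, band_high = 0.1,
                            drop_seconds = 21.6,
                            fwhm_mm = 4,
                            fdr_q = 0.05,
                            split_half_iterations = 500,
                            n_permutations = 1000,
                            isc_threshold = 0.15) {
  structure(as.list(environment()), class = "pipeline_config")
}

.pipeline_keys <- function() names(formals(pipeline_config))

#' Run the full analysis pipeline
#'
#' Executes the requested stages in order on simulated (or previously
#' written) inputs and writes TSV/JSON outputs plus a resolved-config
#' snapshot into `config$output_dir`. Rerunning from the snapshot and the
#' same seed reproduces every numeric table bit for bit.
#'
#' @param config a [pipeline_config()] (or named list of its keys).
#' @return invisibly, a list of in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cfg <- config
  unknown <- setdiff(names(cfg), .pipeline_keys())
  if (length(unknown)) stop("run_pipeline: unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  write_config(cfg, file.path(cfg$output_dir, "config_snapshot.txt"))
  res <- list()
  stage <- function(name, expr) {
    if (!(name %in% cfg$stages)) return(NULL)
    pv_log("stage: ", name)
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  rest <- stage("simulate", {
    if (!cfg$simulate) stop("non-simulated input requires precomputed datasets")
    generate_resting_dataset(sim_config(n_subjects = cfg$n_subjects,
                                        seed = cfg$seed))
  })
  res$rest <- rest
  pp <- if (is.null(rest)) NULL else stage("preprocess", {
    preprocess_dataset(rest, drop_seconds = cfg$drop_seconds,
                       despike_sd = cfg$despike_sd,
                       band = c(cfg$band_low, cfg$band_high),
                       fwhm_mm = cfg$fwhm_mm)
  })
  if (is.null(pp)) pp <- rest
  res$preprocessed <- pp
  conn <- if (is.null(pp)) NULL else stage("connectivity", {
    cm <- connectivity_analysis(pp)
    rel <- split_half_reliability(cm[[1]]$subject_maps,
                                  iterations = cfg$split_half_iterations,
                                  seed = cfg$seed)
    write_tsv_table(
      data.frame(iteration = seq_along(rel$per_iteration), r = rel$per_iteration),
      file.path(cfg$output_dir, "split_half_reliability.tsv"))
    attr(cm, "reliability") <- rel
    cm
  })
  res$connectivity <- conn
  net <- if (is.null(conn)) NULL else stage("netstruct", {
    ns <- network_structure(conn, p_threshold = cfg$fdr_q)
    write_tsv_table(ns$map_similarity, file.path(cfg$output_dir, "map_similarity.tsv"))
    write_tsv_table(ns$peaks, file.path(cfg$output_dir, "peaks.tsv"))
    jsonlite::write_json(
      list(clusters = as.list(ns$clusters$labels),
           n_clusters = ns$clusters$n_clusters,
           modularity = ns$clusters$modularity),
      file.path(cfg$output_dir, "netstruct.json"), auto_unbox = TRUE, digits = NA)
    ns
  })
  res$netstruct <- net
  isc <- stage("isc", {
    movie <- generate_movie_dataset(sim_config(seed = cfg$seed),
                                    n_subjects = cfg$n_subjects_movie)
    ia <- isc_analysis(movie, threshold = cfg$isc_threshold)
    summ <- data.frame(
      region = names(ia),
      mean_intact = vapply(ia, `[[`, numeric(1), "mean_intact"),
      mean_scrambled = vapply(ia, `[[`, numeric(1), "mean_scrambled"),
      difference = vapply(ia, `[[`, numeric(1), "difference"))
    write_tsv_table(summ, file.path(cfg$output_dir, "isc_summary.tsv"))
    ia
  })
  res$isc <- isc
  glm <- stage("taskglm", {
    lat <- generate_laterality_dataset(sim_config(n_subjects = 5,
                                                  tr_seconds = 2.0,
                                                  n_timepoints = 208,
                                                  seed = cfg$seed))
    ti <- tuning_indices(lat)
    summ <- data.frame(
      compartment = lat$compartment,
      laterality = rowMeans(ti$laterality),
      attention = rowMeans(ti$attention))
    write_tsv_table(summ, file.path(cfg$output_dir, "tuning_indices.tsv"))
    list(dataset = lat, indices = ti)
  })
  res$taskglm <- glm
  pv_log("pipeline complete: ", cfg$output_dir)
  invisible(res)
}

#' Command-line entry point
#'
#' Thin wrapper so the pipeline can be driven from a shell:
#' `pulvicor.R <subcommand> [--config FILE] [--out DIR] [--seed N]` with
#' subcommands `simulate`, `preprocess`, `taskglm`, `isc`, `connectivity`,
#' `netstruct`, `all`.
#'
#' @param args character vector (default `commandArgs(trailingOnly = TRUE)`).
#' @return invisibly, the pipeline result.
#' @export
pulvicor_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  sub <- if (length(args)) args[1] else "all"
  valid <- c("simulate", "preprocess", "taskglm", "isc", "connectivity",
             "netstruct", "all")
  if (!(sub %in% valid)) {
    stop("usage: pulvicor.R <", paste(valid, collapse = "|"),
         "> [--config FILE] [--out DIR] [--seed N]")
  }
  rest_args <- args[-1]
  getopt <- function(flag, default = NULL) {
    i <- which(rest_args == flag)
    if (length(i) && i < length(rest_args)) rest_args[i + 1] else default
  }
  overrides <- list()
  cfile <- getopt("--config")
  if (!is.null(cfile)) overrides <- read_config(cfile, known = .pipeline_keys())
  out <- getopt("--out")
  if (!is.null(out)) overrides$output_dir <- out
  seed <- getopt("--seed")
  if (!is.null(seed)) overrides$seed <- as.integer(seed)
  cfg <- do.call(pipeline_config, overrides)
  upto <- function(...) c("simulate", ...)
  cfg$stages <- switch(sub,
    all = cfg$stages,
    simulate = "simulate",
    preprocess = upto("preprocess"),
    connectivity = upto("preprocess", "connectivity"),
    netstruct = upto("preprocess", "connectivity", "netstruct"),
    isc = "isc",
    taskglm = "taskglm")
  run_pipeline(cfg)
}
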