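# Run configuration and the end-to-end pipeline: synthesize a cohort,
# exclude artifact trials, compute trace statistics, classify percepts and
# rank glomerular activation, writing tidy CSV/JSON reports plus a manifest.

#' Default run configuration
#'
#' @return Nested list of class `run_config` with all stage parameters:
#'   `seed`, `cohort` (arguments of [cohort_spec()] minus the seed),
#'   `analysis` (baseline/pre windows, SNR threshold, percept boundaries,
#'   artifact-exclusion settings) and `classifier` (top-k list, number of
#'   label shuffles).
#' @export
default_run_config <- function() {
  structure(list(
    seed = 1L,
    log_level = "info",
    cohort = list(n_mice = 9, cohort = "naive",
                  ladder = c(3e-5, 1e-4, 3e-3, 1e-2, 0.1, 1, 3, 10),
                  n_glomeruli = 12, n_trials = 3, frame_hz = 42,
                  stim_s = 3, pre_s = 5, post_s = 7, noise_sd = 0.03,
                  artifact_prob = 0),
    analysis = list(baseline_s = 5, pre_s = 3, snr_threshold = 5,
                    weak_max = 0.01, strong_min = 0.3,
                    require_successor = TRUE,
                    artifact = list(z = 2, frac = 0.8, min_dur_s = 0.5)),
    classifier = list(top_k = c(1, 2, 3), n_shuffles = 0)),
    class = "run_config")
}

check_known_keys <- function(x, template, path = "") {
  extra <- setdiff(names(x), names(template))
  if (length(extra))
    stop("unknown configuration key: ", paste0(path, extra[1]))
  for (nm in names(x)) {
    if (is.list(template[[nm]]) && !is.null(names(template[[nm]])) &&
        length(names(template[[nm]])) > 0) {
      if (!is.list(x[[nm]]))
        stop("configuration key ", path, nm, " must be a mapping")
      check_known_keys(x[[nm]], template[[nm]], paste0(path, nm, "."))
    }
  }
  invisible(TRUE)
}

#' Load a run configuration
#'
#' Reads a YAML or JSON configuration file, validates it against the known
#' schema (unknown keys are rejected by name) and fills every omitted field
#' with its default. An empty file yields the full default configuration.
#'
#' @param path File path (`.yaml`/`.yml`/`.json`).
#' @return A `run_config` list.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  defaults <- default_run_config()
  check_known_keys(user, defaults)
  cfg <- modifyList(defaults, user)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "run_config"
  cfg
}

#' Save a run configuration
#'
#' @param config A `run_config`.
#' @param path Output path (`.yaml` or `.json`).
#' @return `path`, invisibly.
#' @export
save_run_config <- function(config, path) {
  x <- unclass(config)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  else yaml::write_yaml(x, path)
  invisible(path)
}

log_msg <- function(level, cfg, ...) {
  levels <- c(debug = 1, info = 2, warn = 3)
  if (levels[[level]] >= levels[[cfg$log_level %||% "info"]])
    message(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " [", level, "] ", ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full synthetic-cohort analysis pipeline
#'
#' Executes synthesize -> exclude artifact trials -> trace statistics ->
#' percept classification -> activation ranking, writing an AI/SNR/amplitude
#' table, a classifier report, a rank table, the configuration used and a
#' manifest (with the MD5 of the configuration) into `out_dir`. Identical
#' configuration and seed give identical outputs.
#'
#' @param config A `run_config` (or path to one).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with the computed objects (`stats`,
#'   `classifier`, `ranks`, `excluded`, `manifest`).
#' @export
run_pipeline <- function(config = default_run_config(), out_dir) {
  if (is.character(config)) config <- load_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg("info", config, "stage synth: generating ", config$cohort$cohort,
          " cohort (seed ", config$seed, ")")
  spec <- do.call(cohort_spec, c(config$cohort, list(seed = config$seed)))
  tables <- tryCatch(generate_cohort(spec),
                     error = function(e) stop("stage synth failed (seed ",
                                              config$seed, "): ",
                                              conditionMessage(e)))
  gt <- attr(tables, "ground_truth")

  log_msg("info", config, "stage analyze: artifact exclusion + trial statistics")
  an <- config$analysis
  excluded <- exclude_artifact_trials(tables, spec, an)
  keep_rows <- !interaction(tables$mouse, tables$concentration, tables$trial) %in%
    interaction(excluded$mouse, excluded$concentration, excluded$trial)[excluded$excluded]
  kept <- tables[keep_rows, ]
  attr(kept, "ground_truth") <- gt
  stats <- cohort_trial_stats(kept, onset_s = spec$pre_s, stim_s = spec$stim_s,
                              baseline_s = an$baseline_s, pre_s = an$pre_s)

  log_msg("info", config, "stage classify: per-mouse percept decoding")
  dataset <- generate_percept_dataset(spec, tables = kept)
  reports <- lapply(dataset$per_mouse, function(m)
    fit_percept_classifier(m$x, m$labels, top_k = config$classifier$top_k))
  f1 <- vapply(reports, `[[`, numeric(1), "f1")

  ranks <- rank_table(kept, spec, reports, an)

  cfg_path <- file.path(out_dir, "config.yaml")
  save_run_config(config, cfg_path)
  stats_path <- file.path(out_dir, "trial_stats.csv")
  write.csv(stats, stats_path, row.names = FALSE)
  ranks_path <- file.path(out_dir, "rank_table.csv")
  write.csv(ranks, ranks_path, row.names = FALSE)
  report <- list(
    per_mouse_f1 = unname(f1), mean_f1 = mean(f1),
    top_k = lapply(reports, `[[`, "top_k"),
    weights = lapply(reports, function(r) as.list(r$weights)),
    excluded_trials = sum(excluded$excluded))
  report_path <- file.path(out_dir, "classifier_report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  manifest <- list(config_hash = cfg_hash, seed = config$seed,
                   inputs = list(config = basename(cfg_path)),
                   outputs = basename(c(stats_path, ranks_path, report_path)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_msg("info", config, "pipeline complete: ", out_dir)
  invisible(list(stats = stats, classifier = reports, ranks = ranks,
                 excluded = excluded, manifest = manifest))
}

# Per-trial artifact exclusion over a cohort table.
exclude_artifact_trials <- function(tables, spec, an) {
  trials <- unique(tables[, c("mouse", "concentration", "trial")])
  trials$excluded <- FALSE
  for (k in seq_len(nrow(trials))) {
    sel <- tables$mouse == trials$mouse[k] &
      tables$concentration == trials$concentration[k] &
      tables$trial == trials$trial[k]
    d <- tables[sel, ]
    traces <- lapply(split(seq_len(nrow(d)), d$glomerulus), function(ix)
      dff(d$F[ix], d$frame_time_s[ix], spec$pre_s,
          baseline_s = min(an$baseline_s, spec$pre_s)))
    t_s <- d$frame_time_s[d$glomerulus == d$glomerulus[1]]
    trials$excluded[k] <- breathing_artifact(
      traces, t_s, spec$pre_s, pre_s = an$pre_s, z = an$artifact$z,
      frac = an$artifact$frac, min_dur_s = an$artifact$min_dur_s)
  }
  trials
}

# Activation rank of the top-weight (primary) glomerulus per mouse and
# concentration, averaged across trials.
rank_table <- function(tables, spec, reports, an) {
  out <- list()
  for (mi in names(reports)) {
    prim <- which.max(reports[[mi]]$weights)
    d_m <- tables[tables$mouse == as.numeric(mi), ]
    for (conc in unique(d_m$concentration)) {
      rk <- c()
      for (tr in unique(d_m$trial[d_m$concentration == conc])) {
        d <- d_m[d_m$concentration == conc & d_m$trial == tr, ]
        traces <- lapply(split(seq_len(nrow(d)), d$glomerulus), function(ix)
          dff(d$F[ix], d$frame_time_s[ix], spec$pre_s,
              baseline_s = min(an$baseline_s, spec$pre_s)))
        t_s <- d$frame_time_s[d$glomerulus == d$glomerulus[1]]
        ra <- rank_activation(traces, t_s,
                              c(spec$pre_s, spec$pre_s + spec$stim_s),
                              pre_s = an$pre_s,
                              threshold = an$snr_threshold)
        rk <- c(rk, ra$rank[as.numeric(ra$glomerulus) == prim])
      }
      out[[length(out) + 1]] <- tibble::tibble(
        mouse = as.numeric(mi), concentration = conc,
        primary_glomerulus = unname(prim),
        mean_rank = mean_rank(rk), n_trials = sum(!is.na(rk)))
    }
  }
  do.call(rbind, out)
}
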