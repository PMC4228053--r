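#' Write / read a cohort as plain-text interchange files
#'
#' Serialises a cohort to a directory: `rasters.csv` (block, unit_id,
#' condition, stim, trial, spike_time_s), `erg.csv` (b-wave measurements
#' with condition, contrast, trial), `ground_truth.json` (unit parameters
#' and planted flags), and `config.yaml`. `read_cohort()` reconstructs an
#' analysis-ready cohort (the stimulus battery is re-rendered from the
#' config, which is exact because rendering is config-deterministic).
#'
#' @param cohort a [make_cohort] result.
#' @param dir output directory (created if missing).
#' @return `write_cohort()` the directory invisibly; `read_cohort()` a
#'   `"cohort"` object.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$spikes, file.path(dir, "rasters.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$erg, file.path(dir, "erg.csv"), row.names = FALSE)
  gt <- cohort$units
  jsonlite::write_json(
    list(seed = cohort$seed,
         affected = gt$affected, responsive = gt$responsive,
         is_ds = gt$is_ds, movie_animal = cohort$movie_animal,
         units = lapply(gt$units, unclass)),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  cfg <- unclass(cohort$config)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @param dir directory written by [write_cohort].
#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  cfg <- do.call(cohort_config, yaml::read_yaml(file.path(dir, "config.yaml")))
  spikes <- utils::read.csv(file.path(dir, "rasters.csv"),
                            stringsAsFactors = FALSE)
  erg <- utils::read.csv(file.path(dir, "erg.csv"), stringsAsFactors = FALSE)
  gt_raw <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  gt <- list(seed = gt_raw$seed,
             affected = unlist(gt_raw$affected),
             responsive = unlist(gt_raw$responsive),
             is_ds = unlist(gt_raw$is_ds),
             movie_animal = unlist(gt_raw$movie_animal))
  units <- lapply(gt_raw$units, function(u) {
    u <- lapply(u, function(fld) {
      v <- unlist(fld)
      if (!is.null(names(fld)) && any(nzchar(names(fld))))
        names(v) <- names(fld)
      v
    })
    class(u) <- "unit_spec"
    u
  })
  stimuli <- cohort_stimuli(cfg)
  structure(list(config = cfg, seed = gt$seed,
                 units = list(units = units, affected = gt$affected,
                              responsive = gt$responsive, is_ds = gt$is_ds),
                 spikes = spikes, groups = rebuild_groups(spikes),
                 stim_meta = NULL, erg = erg,
                 movie_animal = gt$movie_animal, stimuli = stimuli),
            class = "cohort")
}

# FNV-1a 32-bit hash over a serialized object (pipeline provenance tag)
fnv1a_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)  # keep in integer range
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

#' Run the full design-simulate-analyze-report pipeline
#'
#' Executes the stimulus design (daylight / mel-low metamer quartet), cohort
#' simulation, the analysis battery and the condition-comparison report,
#' optionally writing every artifact (tagged with the seed and a config
#' hash) to an output directory. Rerunning with the same config and seed is
#' bit-identical.
#'
#' @param config a [cohort_config].
#' @param seed integer seed for all randomness.
#' @param out_dir optional output directory; when `NULL` nothing is written.
#' @param design run the spectral metamer design stage (skipped if the
#'   required templates are not of interest).
#' @return List of class `"pipeline_result"`: `design` (metamer solution),
#'   `cohort`, `analysis`, `report`, `seed`, `config_hash`.
#' @export
run_pipeline <- function(config = cohort_config(), seed = 1, out_dir = NULL,
                         design = TRUE) {
  if (config$n_units < 1) stop("run_pipeline: config with 0 units")
  hash <- fnv1a_hash(unclass(config))
  des <- NULL
  if (design) {
    tp <- mouse_templates()[c("SWS", "melanopsin", "rod", "LWS_human")]
    pr <- default_led_primaries()
    des <- design_daylight_mellow(pr, tp, daylight_flux_profile(pr, tp))
  }
  cohort <- make_cohort(config, seed = seed)
  analysis <- analyze_cohort(cohort)
  report <- compare_conditions(analysis)
  out <- structure(list(design = des, cohort = cohort, analysis = analysis,
                        report = report, seed = seed, config_hash = hash),
                   class = "pipeline_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_cohort(cohort, file.path(out_dir, "cohort"))
    meta <- list(seed = seed, config_hash = hash)
    jsonlite::write_json(
      c(meta, list(
        tests = report$tests,
        sf_classification = as.list(report$sf_classification),
        ds_prevalence = report$ds_prevalence,
        frac_larger_in_mellow = report$frac_larger_in_mellow)),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "rows")
    utils::write.csv(analysis$flash, file.path(out_dir, "flash_metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(analysis$sf, file.path(out_dir, "sf_metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(analysis$tfds, file.path(out_dir, "tfds_metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(analysis$pairs, file.path(out_dir, "pair_metrics.csv"),
                     row.names = FALSE)
    if (!is.null(des))
      jsonlite::write_json(
        list(seed = seed, config_hash = hash,
             weights = des$weights,
             log10_fluxes = log10(des$fluxes),
             cone_contrasts = des$cone_contrasts,
             feasible = des$feasible),
        file.path(out_dir, "design.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> seed %d, config %s\n", x$seed,
              x$config_hash))
  print(x$report)
  invisible(x)
}

#' Preset configurations for test fixtures
#'
#' `"tiny"` (a few units, few trials) runs the full battery in seconds and
#' is used by the test suite; `"desk"` is the package default; `"study"`
#' mirrors the sampling of the modelled recordings: 272 simulated units of
#' which 161 planted flash-responsive, 200 flash repeats, 50 movie repeats
#' and 28 within-animal movie pairs.
#'
#' @param scale one of `"tiny"`, `"desk"`, `"study"`.
#' @return A [cohort_config].
#' @export
make_fixtures <- function(scale = c("tiny", "desk", "study")) {
  scale <- match.arg(scale)
  switch(scale,
    tiny = cohort_config(
      n_units = 8L, movie_units_per_animal = c(3L, 2L),
      n_flash_trials = 30L, n_grating_trials = 6L, n_drift_trials = 6L,
      n_movie_trials = 10L, movie_duration = 10,
      sf_grid = c(0.0175, 0.035, 0.07, 0.28),
      tf_grid = c(0.2, 1), n_erg_trials = 3L),
    desk = cohort_config(),
    study = cohort_config(
      n_units = 272L, n_responsive = 161L,
      n_flash_trials = 200L, n_grating_trials = 20L,
      n_drift_trials = 10L, n_movie_trials = 50L))
}
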