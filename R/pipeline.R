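#' Simulate a cohort (pipeline front end)
#'
#' Thin wrapper over [generate_cohort()] that optionally writes the
#' raw-sample and trial tables plus a JSON snapshot of the configuration
#' next to them.
#'
#' @inheritParams generate_cohort
#' @return The [generate_cohort()] result.
#' @export
cit_simulate <- function(config = study_config(),
                         params = generative_params(),
                         effects = familiarity_effects(),
                         layout = face_layout(), seed = NULL, dir = NULL) {
  res <- generate_cohort(config, params, effects, layout, seed, dir)
  if (!is.null(dir)) {
    snap <- list(seed = seed,
                 config = unclass(config[setdiff(names(config), "screen")]),
                 effects = unclass(effects),
                 package_version = as.character(utils::packageVersion("gazecit")))
    jsonlite::write_json(snap, file.path(dir, "config_snapshot.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(res)
}

#' Analyze raw gaze data end to end
#'
#' Runs the full analysis chain on a raw-sample table: I-DT fixation
#' detection, interest-area assignment, per-trial markers, trial
#' exclusions, and the detection-efficiency fit ([cit_detect()]).
#'
#' @param samples Raw-sample table (dialect of [generate_cohort()], or
#'   read from its `raw_samples.csv`).
#' @param trials Trial table with responses.
#' @param layout A [face_layout()].
#' @param min_duration,max_dispersion,max_gap I-DT thresholds, see
#'   [detect_fixations()].
#' @param markers Marker columns to analyse.
#' @param n_reps,n_boot,seed,predicted Passed to [cit_detect()].
#' @return List of class `"cit_analysis"`: `fixations`, `markers`
#'   (retained), `exclusions`, and `fit` (a `"cit_detection"`).
#' @export
cit_analyze <- function(samples, trials, layout = face_layout(),
                        min_duration = 80, max_dispersion = 100,
                        max_gap = 75,
                        markers = names(predicted_directions()),
                        n_reps = 1000, n_boot = 1000, seed = NULL,
                        predicted = predicted_directions()) {
  fixations <- detect_fixations_cohort(samples, min_duration,
                                       max_dispersion, max_gap)
  marker_tab <- compute_marker_table(fixations, trials, layout)
  flt <- filter_trials(trials, marker_tab)
  fit <- cit_detect(flt$retained, markers, n_reps, n_boot, seed, predicted)
  structure(list(fixations = fixations, markers = flt$retained,
                 exclusions = flt$exclusions, fit = fit),
            class = "cit_analysis")
}

#' @export
print.cit_analysis <- function(x, ...) {
  cat(sprintf("CIT analysis: %d fixations, %d retained trials, %d excluded\n",
              nrow(x$fixations), nrow(x$markers), nrow(x$exclusions)))
  if (nrow(x$exclusions))
    print(table(x$exclusions$reason))
  print(x$fit, ...)
  invisible(x)
}

#' Run the full pipeline from simulation to report
#'
#' Generates a seeded synthetic cohort and analyses it end to end. A full
#' run is a pure function of `(config, params, effects, seed)`.
#'
#' @inheritParams cit_simulate
#' @inheritParams cit_analyze
#' @param dir Optional output directory; when given, the cohort tables,
#'   fixation/marker/exclusion tables and the results JSON are written
#'   there.
#' @return List with `cohort` and `analysis`.
#' @export
run_cit_pipeline <- function(config = study_config(),
                             params = generative_params(),
                             effects = familiarity_effects(),
                             layout = face_layout(),
                             min_duration = 80, max_dispersion = 100,
                             max_gap = 75,
                             markers = names(predicted_directions()),
                             n_reps = 1000, n_boot = 1000, seed = NULL,
                             dir = NULL) {
  cohort <- cit_simulate(config, params, effects, layout,
                         seed = derive_seed(seed, 11L), dir = dir)
  analysis <- cit_analyze(cohort$samples, cohort$trials, layout,
                          min_duration, max_dispersion, max_gap, markers,
                          n_reps, n_boot, seed = derive_seed(seed, 12L))
  if (!is.null(dir)) {
    write.csv(analysis$fixations, file.path(dir, "fixations.csv"),
              row.names = FALSE)
    write.csv(analysis$markers, file.path(dir, "markers.csv"),
              row.names = FALSE)
    write.csv(analysis$exclusions, file.path(dir, "exclusions.csv"),
              row.names = FALSE)
    cit_write_results(analysis$fit, file.path(dir, "results.json"))
  }
  list(cohort = cohort, analysis = analysis)
}

#' Write a detection fit as a JSON report
#'
#' Serialises the per-condition, per-marker results (d, AUC, CIs,
#' direction percentages) together with the run's provenance (reps,
#' bootstrap size, seed, package version).
#'
#' @param fit A `"cit_detection"` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
cit_write_results <- function(fit, path) {
  if (!inherits(fit, "cit_detection"))
    stop_bad_arg("fit", "must be a cit_detection object")
  r <- fit$results
  by_cond <- lapply(split(r, r$condition), function(rc) {
    setNames(lapply(seq_len(nrow(rc)), function(i) list(
      d = rc$d[i], d_ci = c(rc$d_lo[i], rc$d_hi[i]),
      auc = rc$auc[i], auc_ci = c(rc$auc_lo[i], rc$auc_hi[i]),
      pct_direction = rc$pct_direction[i])), rc$marker)
  })
  out <- list(results = by_cond,
              n_reps = fit$n_reps, n_boot = fit$n_boot,
              seed = fit$seed,
              package_version = as.character(utils::packageVersion("gazecit")))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
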