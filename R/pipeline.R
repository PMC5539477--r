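#' Default run configuration
#'
#' All protocol constants in one overridable list: sampling rates (ECG
#' 256 Hz, accelerometer 128 Hz), window lengths (2-s IMU windows, 60-s
#' minutes), cohort size (13), the session schedule, recognition
#' scenarios/classifiers, EE model specs and the 5% selection threshold.
#' The list round-trips losslessly through its JSON file form.
#'
#' @param ... named overrides.
#' @return A `run_config` list.
#' @export
default_config <- function(...) {
  cfg <- list(
    n_subjects = 13L,
    ecg_fs = 256, accel_fs = 128,
    imu_window_s = 2, minute_s = 60,
    schedule = default_schedule(include_rest = TRUE),
    scenarios = c(1L, 3L),
    classifier = "lda",
    k_grid = 1:8,
    alpha = 0.05,
    ee_models = ee_model_specs(),
    seed = 1L,
    feature_level = TRUE)
  utils::modifyList(cfg, list(...))
}

#' @rdname default_config
#' @param config a `run_config`.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname default_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$schedule <- as.data.frame(cfg$schedule)
  cfg$ee_models <- as.data.frame(cfg$ee_models)
  cfg
}

#' Write a simulated cohort as delimited text plus a JSON manifest
#'
#' One CSV per subject-activity block for the accelerometer
#' (`time_s, ax, ay, az`), one for the RR ground truth
#' (`peak_time_s, rr_ms`), optionally one for the ECG waveform
#' (`time_s, value`); a cohort-level `labels.csv`
#' (`subject_id, minute_index, activity, ee_kcal_per_min`) and
#' `manifest.json` (subjects, files, anthropometrics, seed).
#'
#' @param cohort a `cohort`.
#' @param dir output directory (created).
#' @return The manifest, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = cohort$seed,
                   schedule = cohort$schedule,
                   subjects = list())
  for (sub in cohort$subjects) {
    sid <- sub$profile$subject_id
    files <- list()
    for (b in seq_along(sub$blocks)) {
      blk <- sub$blocks[[b]]
      stem <- sprintf("%s_%02d_%s", sid, b, blk$activity)
      acc_f <- file.path(dir, paste0(stem, "_accel.csv"))
      utils::write.csv(data.frame(time_s = blk$accel$time, ax = blk$accel$ax,
                                  ay = blk$accel$ay, az = blk$accel$az),
                       acc_f, row.names = FALSE)
      rr_f <- file.path(dir, paste0(stem, "_rr.csv"))
      utils::write.csv(data.frame(peak_time_s = blk$rr$t, rr_ms = blk$rr$rr_ms),
                       rr_f, row.names = FALSE)
      entry <- list(activity = blk$activity, accel = basename(acc_f),
                    rr = basename(rr_f))
      if (!is.null(blk$ecg)) {
        ecg_f <- file.path(dir, paste0(stem, "_ecg.csv"))
        utils::write.csv(data.frame(time_s = blk$ecg$time, value = blk$ecg$ecg),
                         ecg_f, row.names = FALSE)
        entry$ecg <- basename(ecg_f)
      }
      files[[length(files) + 1L]] <- entry
    }
    manifest$subjects[[sid]] <- list(height = sub$profile$height,
                                     weight = sub$profile$weight,
                                     blocks = files)
  }
  utils::write.csv(cohort$labels, file.path(dir, "labels.csv"), row.names = FALSE)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(manifest)
}

#' Validate a written cohort directory
#'
#' Schema and sanity checks: manifest and labels present, label vocabulary
#' within the six activities, referenced files exist, accelerometer and RR
#' timestamps strictly increasing, RR intervals within the physiological
#' band.  Hard errors and warnings are itemized separately.
#'
#' @param dir cohort directory.
#' @return List with `errors` and `warnings` (character vectors).
#' @export
validate_dataset <- function(dir) {
  errors <- character(0); warns <- character(0)
  man_f <- file.path(dir, "manifest.json")
  lab_f <- file.path(dir, "labels.csv")
  if (!file.exists(man_f)) return(list(errors = "manifest.json missing", warnings = warns))
  if (!file.exists(lab_f)) errors <- c(errors, "labels.csv missing")
  man <- jsonlite::read_json(man_f, simplifyVector = TRUE)
  if (file.exists(lab_f)) {
    lab <- utils::read.csv(lab_f, stringsAsFactors = FALSE)
    need <- c("subject_id", "minute_index", "activity", "ee_kcal_per_min")
    miss <- setdiff(need, names(lab))
    if (length(miss)) errors <- c(errors, paste("labels.csv missing columns:",
                                                paste(miss, collapse = ", ")))
    bad <- setdiff(unique(lab$activity), activity_labels())
    if (length(bad))
      errors <- c(errors, paste("labels.csv has unknown activity label(s):",
                                paste(bad, collapse = ", ")))
  }
  for (sid in names(man$subjects)) {
    blocks <- man$subjects[[sid]]$blocks
    files <- unlist(blocks[intersect(names(blocks), c("accel", "rr", "ecg"))])
    for (f in files) {
      path <- file.path(dir, f)
      if (!file.exists(path)) { errors <- c(errors, paste("missing file:", f)); next }
      d <- utils::read.csv(path, nrows = 5000)
      tcol <- intersect(c("time_s", "peak_time_s"), names(d))[1]
      if (is.na(tcol)) { errors <- c(errors, paste(f, "has no time column")); next }
      nm <- which(diff(d[[tcol]]) <= 0)
      if (length(nm))
        errors <- c(errors, sprintf("%s: non-monotone timestamps at row %d", f, nm[1] + 1L))
      if ("rr_ms" %in% names(d) && any(d$rr_ms < 300 | d$rr_ms > 2000))
        warns <- c(warns, paste(f, "has RR intervals outside 300-2000 ms"))
    }
  }
  list(errors = errors, warnings = warns)
}

#' Run the full analysis end to end
#'
#' Simulate (feature-level by default, signal-level when
#' `config$feature_level` is FALSE) -> recognition scenarios -> EE model
#' comparison -> two-way ANOVA, reproducibly from `config$seed`.
#'
#' @param config a `run_config` (see [default_config()]).
#' @return List with `minutes`, `recognition` (one `evaluation_report`
#'   per scenario), `ee` (`ee_report`), `anova`, `config`.
#' @export
run_pipeline <- function(config = default_config()) {
  minutes <- if (isTRUE(config$feature_level)) {
    simulate_feature_cohort(config$n_subjects, schedule = config$schedule,
                            seed = config$seed)
  } else {
    cohort <- generate_cohort(config$n_subjects, schedule = config$schedule,
                              seed = config$seed, accel_fs = config$accel_fs,
                              ecg_fs = config$ecg_fs)
    cohort_minutes(cohort)
  }
  recognition <- lapply(config$scenarios, function(sc)
    run_loso(minutes, scenario = sc, classifier = config$classifier,
             k_grid = config$k_grid))
  names(recognition) <- paste0("scenario_", config$scenarios)
  ee <- run_ee_cv(minutes, specs = config$ee_models, alpha = config$alpha)
  cells <- ee$rmse[!is.na(ee$rmse$rmse), ]
  anova <- anova_2x2(cells$rmse, cells$data_type, cells$model_type)
  list(minutes = minutes, recognition = recognition, ee = ee,
       anova = anova, config = config)
}
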