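#' Write / read a session recording
#'
#' Recordings are persisted as single-file RDS archives holding the per-sensor
#' frame matrices plus all acquisition metadata (fps, sampling rate, sensor
#' ids, room height, seed, optional subject label). The write -> read round
#' trip is bit-exact.
#'
#' @param recording A [session_recording()].
#' @param path Destination file (conventionally `.rds`).
#' @return `write_recording` invisibly returns `path`; `read_recording`
#'   returns the [session_recording()].
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "uwb_recording"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(unclass(recording), path)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop_input("no such recording file: ", path)
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop_input("not a readable recording file: ",
                                                 path, " (", conditionMessage(e), ")"))
  required <- c("frames", "fps", "sampling_rate", "sensor_ids", "room_height",
                "stage")
  missing <- setdiff(required, names(obj))
  if (length(missing) > 0)
    stop_input("recording file is missing field(s): ",
               paste(missing, collapse = ", "))
  subj <- obj$subject
  if (!is.null(subj) && !inherits(subj, "uwb_subject"))
    subj <- structure(subj, class = "uwb_subject")
  session_recording(obj$frames, fps = obj$fps,
                    sampling_rate = obj$sampling_rate, subject = subj,
                    seed = obj$seed, room_height = obj$room_height,
                    stage = obj$stage)
}

#' Write / read a cohort reference table
#'
#' One CSV row per subject with the seven anthropometric parameters
#' (comma-separated, UTF-8, header row).
#'
#' @param cohort List of [subject_profile()]s (or a [cohort_table()] frame).
#' @param path CSV path.
#' @return `write_cohort` invisibly returns `path`; `read_cohort` returns a
#'   list of [subject_profile()]s.
#' @export
write_cohort <- function(cohort, path) {
  df <- if (is.data.frame(cohort)) cohort else cohort_table(cohort)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i)
    subject_profile(df$height[i], df$weight[i], df$muscle_pct[i],
                    df$skeletal_muscle_pct[i], df$body_water_pct[i],
                    df$body_fat_pct[i], id = df$id[i]))
}

#' Generate the bundled test fixture set
#'
#' A tiny, fully synthetic dataset: 4 subjects x 2 repetitions of 5-second
#' acquisitions, one empty-room calibration recording, and the cohort CSV.
#' Regeneration is bit-identical for a fixed seed.
#'
#' @param dir Output directory.
#' @param seed Integer seed.
#' @param calibration_s Length of the empty-room recording in seconds.
#' @return Invisibly, a list with the cohort, recording paths and the
#'   calibration path.
#' @export
make_fixtures <- function(dir, seed = 1L, calibration_s = 30) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  geometry <- room_geometry(); pulse <- pulse_model()
  cohort <- sample_population(4, seed = seed)
  write_cohort(cohort, file.path(dir, "cohort.csv"))
  paths <- character(0)
  for (s in seq_along(cohort)) {
    for (rep in 1:2) {
      acq_seed <- child_seed(seed, "acq", s, rep)
      rec <- simulate_session(cohort[[s]], geometry, pulse,
                              scene = subject_scene(cohort[[s]], geometry,
                                                    pulse,
                                                    position_jitter_m = 0.03,
                                                    seed = acq_seed),
                              seed = acq_seed)
      p <- file.path(dir, sprintf("%s_rep%d.rds", cohort[[s]]$id, rep))
      write_recording(rec, p)
      paths <- c(paths, p)
    }
  }
  calib <- simulate_empty_room(geometry, pulse, duration_s = calibration_s,
                               seed = child_seed(seed, "calib"))
  calib_path <- file.path(dir, "empty_room.rds")
  write_recording(calib, calib_path)
  invisible(list(cohort = cohort, recordings = paths,
                 calibration = calib_path))
}

#' Pipeline configuration
#'
#' Resolvable parameters for every stage of the end-to-end pipeline, with the
#' protocol defaults. Unknown keys are rejected; the object round-trips
#' losslessly through JSON.
#'
#' @param n_subjects,reps Cohort size and repetitions per subject.
#' @param duration_s,fps Acquisition length and frame rate.
#' @param calibration_s Empty-room calibration length (seconds).
#' @param alpha Background-subtraction forgetting factor.
#' @param beta CFAR false-alarm constant.
#' @param colormap Imaging colormap.
#' @param parameters Anthropometric parameters to train networks for.
#' @param depth,n_filters,fc_out CNN architecture.
#' @param learning_rate,minibatch,epochs Training hyperparameters.
#' @param train_frac,split_mode Train/validation split settings.
#' @param seed Master seed.
#' @param out_dir Output directory for artifacts.
#' @return An object of class `uwb_config`.
#' @export
pipeline_config <- function(n_subjects = 6L, reps = 2L, duration_s = 5,
                            fps = 20, calibration_s = 30, alpha = 0.95,
                            beta = 3, colormap = "jet",
                            parameters = "weight", depth = 3L,
                            n_filters = 16L, fc_out = 256L,
                            learning_rate = 0.001, minibatch = 8L,
                            epochs = 30L, train_frac = 0.75,
                            split_mode = "subject", seed = 1L,
                            out_dir = tempfile("uwbanthro_")) {
  cfg <- as.list(environment())
  structure(cfg, class = "uwb_config")
}

#' @rdname pipeline_config
#' @param path JSON file path.
#' @param config A `uwb_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "uwb_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0)
    stop_input("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Run the full pipeline on a synthetic cohort
#'
#' simulate -> preprocess -> (height estimation + imaging) -> train ->
#' predict -> evaluate, writing every artifact under `config$out_dir`:
#' `cohort.csv`, `height.csv`, `predictions.csv` and `report.csv` (one row
#' per requested parameter plus the signal-processing height row). Fully
#' seeded and reproducible.
#'
#' @param config A [pipeline_config()].
#' @param verbose Emit per-stage progress messages.
#' @return Invisibly, a list with the report data.frame and artifact paths.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = FALSE) {
  stopifnot(inherits(config, "uwb_config"))
  say <- function(...) if (verbose) message(sprintf("[uwbanthro] %s", sprintf(...)))
  t0 <- Sys.time()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  geometry <- room_geometry(); pulse <- pulse_model()
  say("stage=simulate seed=%d subjects=%d reps=%d", config$seed,
      config$n_subjects, config$reps)
  cohort <- sample_population(config$n_subjects, seed = config$seed)
  write_cohort(cohort, file.path(config$out_dir, "cohort.csv"))

  calib <- simulate_empty_room(geometry, pulse,
                               duration_s = config$calibration_s,
                               fps = config$fps,
                               seed = child_seed(config$seed, "calib"))
  calib_res <- subtract_background(calib, alpha = config$alpha)
  threshold <- calibrate_threshold(calibration_buffer(calib_res, "ceiling"),
                                   beta = config$beta)

  say("stage=preprocess+height alpha=%g beta=%g", config$alpha, config$beta)
  heights <- data.frame(id = character(0), estimate = numeric(0),
                        reference = numeric(0))
  sets <- list()
  for (s in seq_along(cohort)) {
    for (rep in seq_len(config$reps)) {
      acq_seed <- child_seed(config$seed, "acq", s, rep)
      rec <- simulate_session(cohort[[s]], geometry, pulse,
                              scene = subject_scene(cohort[[s]], geometry,
                                                    pulse,
                                                    position_jitter_m = 0.03,
                                                    seed = acq_seed),
                              duration_s = config$duration_s,
                              fps = config$fps, seed = acq_seed)
      res <- subtract_background(rec, alpha = config$alpha)
      if (rep == 1L) {  # one data point per subject for height
        h <- estimate_height(res, threshold)
        heights <- rbind(heights,
                         data.frame(id = cohort[[s]]$id, estimate = h$height,
                                    reference = cohort[[s]]$height))
      }
      sets[[length(sets) + 1L]] <-
        fusion_image_set(res, colormap = config$colormap,
                         id = sprintf("%s_rep%d", cohort[[s]]$id, rep))
    }
  }
  write.csv(heights, file.path(config$out_dir, "height.csv"),
            row.names = FALSE)
  report <- data.frame()
  if (nrow(heights) >= 2)
    report <- as.data.frame(evaluate_height_cohort(heights$estimate,
                                                   heights$reference))

  units <- c(height = "cm", weight = "kg", bmi = "kg/m2", muscle_pct = "%",
             skeletal_muscle_pct = "%", body_water_pct = "%",
             body_fat_pct = "%")
  preds_all <- data.frame()
  for (par in config$parameters) {
    say("stage=train parameter=%s epochs=%d", par, config$epochs)
    ds <- labeled_dataset(sets, parameter = par)
    sp <- split_dataset(ds, config$train_frac,
                        seed = child_seed(config$seed, "split"),
                        mode = config$split_mode)
    fit <- fusion_cnn(sp$train,
                      network_spec(depth = config$depth,
                                   n_filters = config$n_filters,
                                   fc_out = config$fc_out),
                      train_hyper(config$learning_rate, config$minibatch,
                                  config$epochs,
                                  seed = child_seed(config$seed, "train", par)))
    pred <- predict(fit, sp$val)
    preds_all <- rbind(preds_all,
                       data.frame(parameter = par, id = sp$val$ids,
                                  estimate = pred, reference = sp$val$y))
    rep_row <- as.data.frame(agreement_report(pred, sp$val$y, parameter = par,
                                              units = unname(units[par])))
    rep_row$parameter <- paste0(par, "_cnn")
    report <- rbind(report, rep_row)
  }
  write.csv(preds_all, file.path(config$out_dir, "predictions.csv"),
            row.names = FALSE)
  report_path <- file.path(config$out_dir, "report.csv")
  write.csv(report, report_path, row.names = FALSE)
  say("done in %.1f s; report at %s", as.numeric(Sys.time() - t0, units = "secs"),
      report_path)
  invisible(list(report = report, heights = heights, predictions = preds_all,
                 out_dir = config$out_dir))
}
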