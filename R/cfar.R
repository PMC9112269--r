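#' Calibration buffer of empty-room envelope frames
#'
#' Extracts the stack `H[k]` of background-subtracted, envelope-detected
#' frames from an empty-room recording for one sensor; its per-bin statistics
#' calibrate the CA-CFAR threshold.
#'
#' @param recording A residual [session_recording()] of the empty room (run
#'   [subtract_background()] first), or one already holding envelopes.
#' @param sensor Sensor id (default "ceiling").
#' @return A matrix of class `uwb_calibration` (`N_c` rows x `n_bins`
#'   columns, all values >= 0).
#' @export
calibration_buffer <- function(recording, sensor = "ceiling") {
  stopifnot(inherits(recording, "uwb_recording"))
  if (!sensor %in% recording$sensor_ids)
    stop_input("sensor '", sensor, "' not present in recording")
  if (recording$stage != "residuals")
    stop_input("run subtract_background() before building a calibration buffer")
  H <- envelope(recording$frames[[sensor]])
  structure(H, class = c("uwb_calibration", "matrix", "array"))
}

#' Calibrate the CA-CFAR detection threshold
#'
#' Per-bin threshold from `N_c` empty-room envelope frames. The default
#' `standard` convention is `T[k] = mu[k] + beta * sigma[k]` with `mu` the
#' per-bin mean and `sigma` the per-bin sample standard deviation (ddof 1);
#' the `literal` convention `T[k] = beta * mu[k] + sigma[k]` swaps the roles
#' of the two statistics and is retained for sensitivity checks.
#'
#' @param buffer Matrix of `N_c >= 2` envelope frames (rows) by bins
#'   (columns); see [calibration_buffer()].
#' @param beta False-alarm constant (default 3).
#' @param convention `"standard"` or `"literal"`.
#' @return An object of class `uwb_threshold` with fields `T`, `mu`, `sigma`,
#'   `beta`, `convention`, `n_frames`.
#' @export
#' @examples
#' H <- rbind(c(1, 1), c(2, 2), c(3, 3))
#' calibrate_threshold(H, beta = 2)$T  # 2 + 2*1 = 4 at both bins
calibrate_threshold <- function(buffer, beta = 3,
                                convention = c("standard", "literal")) {
  convention <- match.arg(convention)
  H <- unclass(buffer)
  if (!is.matrix(H)) stop_input("calibration buffer must be a matrix")
  if (nrow(H) < 2L)
    stop_input("calibration needs N_c >= 2 frames (std undefined for ", nrow(H), ")")
  if (any(H < 0)) stop_input("envelope frames must be nonnegative")
  mu <- colMeans(H)
  sigma <- apply(H, 2, sd)
  Tk <- if (convention == "standard") mu + beta * sigma else beta * mu + sigma
  structure(list(T = Tk, mu = mu, sigma = sigma, beta = beta,
                 convention = convention, n_frames = nrow(H)),
            class = "uwb_threshold")
}

#' @export
print.uwb_threshold <- function(x, ...) {
  cat(sprintf("CA-CFAR threshold (%s): %d bins, beta = %g, N_c = %d frames\n",
              x$convention, length(x$T), x$beta, x$n_frames))
  invisible(x)
}

#' First threshold crossing in an envelope frame
#'
#' Returns the smallest fast-time bin `k` (0-based) opening a run of at least
#' `min_run` consecutive bins whose envelope strictly exceeds the threshold,
#' or `NA` if no such run exists (no detection is a value, not an error).
#'
#' @param env Envelope frame (nonnegative numeric vector).
#' @param threshold A `uwb_threshold` or a numeric per-bin threshold vector.
#' @param min_run Minimum run length in bins (default 2).
#' @return 0-based bin index, or `NA_integer_`.
#' @export
detect_first_crossing <- function(env, threshold, min_run = 2L) {
  Tk <- if (inherits(threshold, "uwb_threshold")) threshold$T else threshold
  if (length(env) != length(Tk))
    stop_input("envelope and threshold lengths differ")
  if (min_run < 1L) stop_input("min_run must be >= 1")
  over <- env > Tk
  if (min_run > length(over)) return(NA_integer_)
  run <- over
  if (min_run > 1L)
    for (j in seq_len(min_run - 1L))
      run <- run & c(over[-seq_len(j)], rep(FALSE, j))
  i <- which(run)
  if (length(i) == 0L) NA_integer_ else as.integer(i[1] - 1L)
}

#' Height estimate container
#' @keywords internal
#' @noRd
height_estimate <- function(height_cm, detected_bin, detected_range,
                            per_frame, room_height) {
  if (!(height_cm > 0 && height_cm < room_height * 100))
    stop_input("estimated height ", round(height_cm, 1),
               " cm violates 0 < height < room height; degenerate detection")
  structure(list(height = height_cm, detected_bin = detected_bin,
                 detected_range = detected_range, per_frame = per_frame,
                 room_height = room_height),
            class = "uwb_height")
}

#' @export
print.uwb_height <- function(x, ...) {
  cat(sprintf("Estimated height: %.1f cm (range %.3f m, bin %d; %d/%d frames detected)\n",
              x$height, x$detected_range, x$detected_bin,
              sum(!is.na(x$per_frame$bin)), nrow(x$per_frame)))
  invisible(x)
}

#' Estimate standing height from the ceiling sensor
#'
#' For every frame of the residual recording, the envelope is compared with
#' the calibrated CA-CFAR threshold; the first crossing marks the leading
#' edge of the head echo and is refined to the envelope peak within the next
#' `refine_bins` bins (threshold detectors fire on the rising edge of the
#' pulse, a few bins before its centre; the refinement window is kept below
#' the head-shoulder separation so the shoulder echo cannot capture it).
#' Ranges are aggregated over frames and the height follows from the known
#' ceiling height: `height = room_height - range`.
#'
#' @param recording A residual [session_recording()] containing the ceiling
#'   sensor (run [subtract_background()] first).
#' @param threshold A calibrated [calibrate_threshold()] object for that
#'   sensor.
#' @param ceiling_sensor Sensor id (default "ceiling").
#' @param room_height Ceiling height in metres; defaults to the recording's.
#' @param aggregator `"median"` or `"mode"` over per-frame detected bins.
#' @param min_run Run length passed to [detect_first_crossing()].
#' @param refine_bins Peak-refinement window after the first crossing.
#' @param floor_frac Per-frame relative threshold floor: the effective
#'   threshold is at least `floor_frac` times that frame's envelope peak.
#'   Guards the degenerate zero-variance calibration (noise-free empty room),
#'   where the CFAR threshold collapses to zero and numerical leakage of the
#'   FFT-based envelope would otherwise fire far ahead of the echo.
#' @param max_missing Fail if more than this fraction of frames has no
#'   detection (default 0.5).
#' @return An object of class `uwb_height`.
#' @export
estimate_height <- function(recording, threshold, ceiling_sensor = "ceiling",
                            room_height = NULL,
                            aggregator = c("median", "mode"),
                            min_run = 2L, refine_bins = 36L,
                            floor_frac = 0.05, max_missing = 0.5) {
  stopifnot(inherits(recording, "uwb_recording"),
            inherits(threshold, "uwb_threshold"))
  aggregator <- match.arg(aggregator)
  if (!ceiling_sensor %in% recording$sensor_ids)
    stop_input("ceiling sensor '", ceiling_sensor, "' not in recording")
  if (recording$stage != "residuals")
    stop_input("run subtract_background() before estimating height")
  if (is.null(room_height)) room_height <- recording$room_height
  X <- recording$frames[[ceiling_sensor]]
  if (ncol(X) != length(threshold$T))
    stop_input("threshold was calibrated for a different bin count")
  dr <- range_resolution(recording$sampling_rate)
  E <- envelope(X)
  n <- nrow(E)
  bins <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    Tk <- pmax(threshold$T, floor_frac * max(E[i, ]))
    d <- detect_first_crossing(E[i, ], Tk, min_run = min_run)
    if (!is.na(d)) {
      j <- d + 1L  # R column of bin d
      win <- j:min(ncol(E), j + refine_bins)
      bins[i] <- d + (which.max(E[i, win]) - 1L)
    }
  }
  n_det <- sum(!is.na(bins))
  if (n_det < (1 - max_missing) * n)
    stop_input("insufficient detections: only ", n_det, " of ", n,
               " frames crossed the threshold")
  agg_bin <- if (aggregator == "median") median(bins, na.rm = TRUE)
  else as.integer(names(which.max(table(bins))))
  rng <- agg_bin * dr
  if (rng > room_height)
    stop_input("aggregated range ", round(rng, 2),
               " m exceeds the room height; degenerate detection")
  per_frame <- data.frame(frame = seq_len(n), bin = bins, range = bins * dr)
  height_estimate((room_height - rng) * 100, as.integer(round(agg_bin)), rng,
                  per_frame, room_height)
}

#' Cohort-level agreement of height estimates
#'
#' Convenience wrapper bundling the agreement statistics (RMSE, MAE,
#' ICC(2,1), Pearson r^2) for paired height estimates and references, one
#' data point per subject.
#'
#' @param estimates Numeric vector of estimated heights (cm).
#' @param references Numeric vector of reference heights (cm).
#' @return An [agreement_report()] for parameter "height".
#' @export
evaluate_height_cohort <- function(estimates, references) {
  agreement_report(estimates, references, parameter = "height", units = "cm")
}
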