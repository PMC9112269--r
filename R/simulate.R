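#' Session recording container
#'
#' One acquisition: per-sensor matrices of shape `(n_frames, n_bins)` sampled
#' at `fps` frames per second, plus acquisition metadata. Row `n` holds frame
#' `n`; column `j` holds fast-time bin `k = j - 1` (0-based, so that range
#' equals `k * range_resolution(sampling_rate)`).
#'
#' @param frames Named list of numeric matrices, one per sensor, identical
#'   dimensions, all values finite.
#' @param fps Frames per second.
#' @param sampling_rate Receiver sampling rate (samples/s).
#' @param subject Optional true [subject_profile()] label.
#' @param seed Seed the recording was generated with (or NA).
#' @param room_height Room height in metres (for height estimation).
#' @param stage Either "raw" or "residuals".
#' @return An object of class `uwb_recording`.
#' @export
session_recording <- function(frames, fps = 20, sampling_rate = 23.328e9,
                              subject = NULL, seed = NA_integer_,
                              room_height = 2.5, stage = "raw") {
  if (!is.list(frames) || length(frames) == 0L)
    stop_input("`frames` must be a nonempty named list of matrices")
  dims <- lapply(frames, dim)
  d0 <- dims[[1]]
  for (d in dims)
    if (!identical(d, d0)) stop_input("all sensors must share n_frames and n_bins")
  for (m in frames)
    if (!all(is.finite(m))) stop_input("all frame values must be finite")
  structure(list(frames = frames, fps = fps, n_frames = d0[1], n_bins = d0[2],
                 sampling_rate = sampling_rate,
                 sensor_ids = names(frames), subject = subject, seed = seed,
                 room_height = room_height, stage = stage),
            class = "uwb_recording")
}

#' @export
print.uwb_recording <- function(x, ...) {
  cat(sprintf("IR-UWB recording (%s): %d sensors [%s], %d frames x %d bins @ %g fps\n",
              x$stage, length(x$frames), paste(x$sensor_ids, collapse = ", "),
              x$n_frames, x$n_bins, x$fps))
  if (!is.null(x$subject)) print(x$subject)
  invisible(x)
}

# Core of the received-signal model: for every sensor and frame, the frame is
# the superposition of delayed, scaled pulse templates over all paths, plus
# the static clutter profile, plus white Gaussian noise. Breathing moves each
# path's delay sinusoidally, scaled by the path's breath_gain.
simulate_frames <- function(scene, pulse, n_frames, fps, seed) {
  dr <- range_resolution(pulse$sampling_rate)
  n_bins <- scene$n_bins
  k <- seq_len(n_bins) - 1
  t_n <- (seq_len(n_frames) - 1) / fps
  br <- scene$breathing
  breath_bins <- (br$amplitude_mm / 1000) / dr  # delay excursion, bins
  out <- list()
  for (s in names(scene$paths)) {
    M <- matrix(0, n_frames, n_bins)
    if (!is.null(scene$clutter))
      M <- M + matrix(scene$clutter[[s]], n_frames, n_bins, byrow = TRUE)
    p <- scene$paths[[s]]
    if (nrow(p) > 0) {
      for (m in seq_len(nrow(p))) {
        tau <- p$delay[m] + p$breath_gain[m] * breath_bins *
          sin(2 * pi * br$rate_hz * t_n + br$phase)
        for (n in seq_len(n_frames))
          M[n, ] <- M[n, ] + p$amplitude[m] * pulse$template(k - tau[n])
      }
    }
    if (scene$noise_sd > 0)
      M <- M + with_seed(child_seed(seed, "noise", s),
                         matrix(rnorm(n_frames * n_bins, 0, scene$noise_sd),
                                n_frames, n_bins))
    out[[s]] <- M
  }
  out
}

#' Simulate one radar acquisition of a standing subject
#'
#' Generates a [session_recording()] from the received-signal model: each
#' frame is a sum of delayed, amplitude-scaled pulse templates over the
#' scene's scattering paths, plus static clutter and white Gaussian noise,
#' with breathing modulating path delays sinusoidally. Bit-identical for a
#' fixed seed.
#'
#' @param subject A [subject_profile()] (label; also used to build the scene
#'   when `scene` is NULL).
#' @param geometry A [room_geometry()].
#' @param pulse A [pulse_model()].
#' @param scene A [scatter_scene()]; defaults to [subject_scene()] of the
#'   subject.
#' @param duration_s Acquisition length in seconds (default 5).
#' @param fps Frame rate (default 20), so `n_frames = round(fps * duration_s)`.
#' @param seed Integer seed.
#' @return A [session_recording()] with `stage = "raw"`.
#' @export
#' @examples
#' subj <- subject_profile(164, 62.2, 39.2, 22.7, 30.6, 17.9)
#' rec <- simulate_session(subj, seed = 1)
#' dim(rec$frames$ceiling)  # 100 x 400
simulate_session <- function(subject, geometry = room_geometry(),
                             pulse = pulse_model(), scene = NULL,
                             duration_s = 5, fps = 20, seed = 1) {
  if (duration_s <= 0) stop_input("duration_s must be > 0")
  if (is.null(scene))
    scene <- subject_scene(subject, geometry, pulse, seed = seed)
  n_frames <- round(fps * duration_s)
  frames <- simulate_frames(scene, pulse, n_frames, fps, seed)
  session_recording(frames, fps = fps, sampling_rate = pulse$sampling_rate,
                    subject = subject, seed = seed,
                    room_height = geometry$height, stage = "raw")
}

#' Simulate the empty measurement room
#'
#' As [simulate_session()] but with no target in the scene; used to calibrate
#' the CFAR detection threshold from noise-and-clutter-only statistics.
#'
#' @inheritParams simulate_session
#' @param scene A target-free scene; defaults to [empty_room_scene()].
#' @param duration_s Calibration length in seconds (default 300, i.e. 5
#'   minutes = 6000 frames at 20 fps).
#' @return A [session_recording()] with no subject label.
#' @export
simulate_empty_room <- function(geometry = room_geometry(),
                                pulse = pulse_model(), scene = NULL,
                                duration_s = 300, fps = 20, seed = 1) {
  if (duration_s <= 0) stop_input("duration_s must be > 0")
  if (is.null(scene)) scene <- empty_room_scene(geometry, pulse)
  n_frames <- round(fps * duration_s)
  frames <- simulate_frames(scene, pulse, n_frames, fps, seed)
  session_recording(frames, fps = fps, sampling_rate = pulse$sampling_rate,
                    subject = NULL, seed = seed,
                    room_height = geometry$height, stage = "raw")
}
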