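#' IR-UWB pulse model
#'
#' Describes the transmitted impulse as a Gaussian-modulated cosine sampled at
#' the receiver rate. The template is carried as a continuous function of the
#' (possibly fractional) fast-time bin offset, so echoes can be placed at
#' sub-bin delays exactly. The envelope standard deviation is matched to the
#' stated bandwidth through the Gaussian FWHM relation
#' \eqn{\sigma_f = B / 2\sqrt{2\log 2}}, \eqn{\sigma_t = 1/(2\pi\sigma_f)}.
#'
#' @param center_frequency Carrier frequency in Hz (default 8.748 GHz).
#' @param bandwidth -3 dB bandwidth in Hz (default 1.5 GHz).
#' @param sampling_rate Receiver sampling rate in samples/s (default
#'   23.328 GS/s, giving a 6.4 mm range bin).
#' @param support_sigmas Half-support of the discretised template, in units of
#'   the envelope sigma.
#'
#' @return An object of class `uwb_pulse`: a list with the stated fields plus
#'   `sigma_bins` (envelope sigma in bins), `support` (half-support in bins)
#'   and `template`, a vectorised function of the bin offset.
#' @export
#' @examples
#' p <- pulse_model()
#' p$template(0)        # peak amplitude 1
#' range_resolution(p$sampling_rate)  # ~6.4 mm
pulse_model <- function(center_frequency = 8.748e9, bandwidth = 1.5e9,
                        sampling_rate = 23.328e9, support_sigmas = 4) {
  if (sampling_rate <= 0) stop_input("`sampling_rate` must be > 0")
  if (center_frequency <= 0 || bandwidth <= 0)
    stop_input("`center_frequency` and `bandwidth` must be > 0")
  sigma_f <- bandwidth / (2 * sqrt(2 * log(2)))
  sigma_t <- 1 / (2 * pi * sigma_f)
  sigma_bins <- sigma_t * sampling_rate
  f_norm <- center_frequency / sampling_rate  # carrier cycles per bin
  template <- function(u) exp(-u^2 / (2 * sigma_bins^2)) * cos(2 * pi * f_norm * u)
  support <- ceiling(support_sigmas * sigma_bins)
  # invariant: template energy > 0
  u <- seq(-support, support, by = 1)
  if (sum(template(u)^2) <= 0) stop_input("pulse template has zero energy")
  structure(list(center_frequency = center_frequency, bandwidth = bandwidth,
                 sampling_rate = sampling_rate, sigma_bins = sigma_bins,
                 support = support, template = template),
            class = "uwb_pulse")
}

#' @export
print.uwb_pulse <- function(x, ...) {
  cat("IR-UWB pulse: fc =", x$center_frequency / 1e9, "GHz, B =",
      x$bandwidth / 1e9, "GHz, fs =", x$sampling_rate / 1e9,
      "GS/s, envelope sigma =", round(x$sigma_bins, 2), "bins\n")
  invisible(x)
}

#' Room and sensor geometry
#'
#' Default layout mirrors the measurement room: 3 m x 3 m floor, 2.5 m
#' ceiling, one sensor at the ceiling centre and two on opposite walls 1 m
#' above the floor, with the subject standing at the room centre.
#'
#' @param width,depth,height Room dimensions in metres.
#' @param sensor_positions Named list of 3D coordinates (metres). All sensors
#'   must lie inside the room volume.
#' @return An object of class `uwb_geometry`.
#' @export
room_geometry <- function(width = 3, depth = 3, height = 2.5,
                          sensor_positions = NULL) {
  if (width <= 0 || depth <= 0 || height <= 0)
    stop_input("room dimensions must be positive")
  if (is.null(sensor_positions)) {
    sensor_positions <- list(
      ceiling = c(width / 2, depth / 2, height),
      wall_1  = c(0, depth / 2, 1.0),
      wall_2  = c(width, depth / 2, 1.0))
  }
  for (nm in names(sensor_positions)) {
    p <- sensor_positions[[nm]]
    if (length(p) != 3L) stop_input("sensor position must be a 3-vector: ", nm)
    if (any(p < -1e-9) || p[1] > width + 1e-9 || p[2] > depth + 1e-9 ||
        p[3] > height + 1e-9)
      stop_input("sensor '", nm, "' lies outside the room volume")
  }
  structure(list(width = width, depth = depth, height = height,
                 sensor_positions = sensor_positions),
            class = "uwb_geometry")
}

#' @export
print.uwb_geometry <- function(x, ...) {
  cat("Room", x$width, "x", x$depth, "x", x$height, "m;",
      length(x$sensor_positions), "sensors:",
      paste(names(x$sensor_positions), collapse = ", "), "\n")
  invisible(x)
}

#' Range resolution of the sampled radar
#'
#' One fast-time bin spans `c / (2 * sampling_rate)` metres of range
#' (round-trip propagation at the speed of light).
#'
#' @param sampling_rate Receiver sampling rate in samples/s.
#' @return Metres per range bin. At 23.328 GS/s this is 6.4 mm.
#' @export
range_resolution <- function(sampling_rate) {
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0)
    stop_input("`sampling_rate` must be a single positive number")
  .C_LIGHT / (2 * sampling_rate)
}
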