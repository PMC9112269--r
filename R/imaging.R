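#' Extract the CNN training buffer for one sensor
#'
#' Deterministic crop of the residual recording: the first
#' `round(fps * window_s)` frames by the first `n_bins_out` fast-time bins
#' (default 100 x 400, i.e. 5 s at 20 fps over ~2.4 m of range).
#'
#' @param recording A residual [session_recording()].
#' @param sensor Sensor id.
#' @param window_s Window length in seconds (default 5).
#' @param n_bins_out Number of bins kept (default 400).
#' @return A numeric matrix of class `uwb_buffer` with attribute `sensor`.
#' @export
build_buffer <- function(recording, sensor, window_s = 5, n_bins_out = 400L) {
  stopifnot(inherits(recording, "uwb_recording"))
  if (!sensor %in% recording$sensor_ids)
    stop_input("sensor '", sensor, "' not present in recording")
  n_frames <- round(recording$fps * window_s)
  if (recording$n_frames < n_frames)
    stop_input("recording too short: ", recording$n_frames, " frames, need ",
               n_frames)
  if (recording$n_bins < n_bins_out)
    stop_input("recording has ", recording$n_bins, " bins, need ", n_bins_out)
  M <- recording$frames[[sensor]][seq_len(n_frames), seq_len(n_bins_out),
                                  drop = FALSE]
  structure(M, sensor = sensor, class = c("uwb_buffer", "matrix", "array"))
}

round_half_up <- function(x) floor(x + 0.5)

#' Jointly rescale three sensor buffers to 8-bit
#'
#' The three buffers are stacked and mapped linearly to `[0, 255]` with a
#' single global minimum and maximum (so cross-sensor amplitude ratios are
#' preserved), rounding half-up to integers. A constant stack (max == min)
#' maps to all zeros. With `per_sensor = TRUE` each buffer is normalised on
#' its own.
#'
#' @param buffers List of three equally shaped numeric matrices.
#' @param per_sensor Normalise each buffer independently (default FALSE).
#' @return List of three integer matrices with values in `[0, 255]`.
#' @export
stack_and_rescale <- function(buffers, per_sensor = FALSE) {
  if (length(buffers) != 3L) stop_input("expected exactly 3 buffers")
  d <- dim(buffers[[1]])
  for (b in buffers) {
    if (!identical(dim(b), d)) stop_input("buffers must share a common shape")
    if (any(is.na(b)) || any(!is.finite(b))) stop_input("buffers must be finite")
  }
  scale_one <- function(b, lo, hi) {
    if (hi == lo) return(matrix(0L, d[1], d[2]))
    m <- round_half_up((b - lo) / (hi - lo) * 255)
    matrix(as.integer(m), d[1], d[2])
  }
  if (per_sensor) {
    lapply(buffers, function(b) scale_one(b, min(b), max(b)))
  } else {
    lo <- min(vapply(buffers, min, 0))
    hi <- max(vapply(buffers, max, 0))
    lapply(buffers, scale_one, lo = lo, hi = hi)
  }
}

#' 256-entry colormap lookup table
#'
#' `"gray"` maps value v to (v, v, v); `"jet"` is the classic blue-cyan-
#' yellow-red map built from piecewise-linear ramps.
#'
#' @param name Colormap name: `"jet"` or `"gray"`.
#' @return Integer matrix 256 x 3 (R, G, B in `[0, 255]`), row `v + 1` is the
#'   colour of value `v`.
#' @export
colormap_table <- function(name = c("jet", "gray")) {
  name <- match.arg(name)
  v <- 0:255
  if (name == "gray") return(cbind(R = v, G = v, B = v))
  # classic jet: piecewise-linear ramps on [0, 1]
  x <- v / 255
  ramp <- function(x) pmin(pmax(x, 0), 1)
  r <- ramp(1.5 - abs(4 * x - 3))
  g <- ramp(1.5 - abs(4 * x - 2))
  b <- ramp(1.5 - abs(4 * x - 1))
  cbind(R = as.integer(round_half_up(255 * r)),
        G = as.integer(round_half_up(255 * g)),
        B = as.integer(round_half_up(255 * b)))
}

#' Map an 8-bit matrix to an RGB image through a colormap
#'
#' @param m8 Integer matrix with values in `[0, 255]`.
#' @param colormap Colormap name accepted by [colormap_table()].
#' @return Integer array `(nrow, ncol, 3)` with channels in `[0, 255]`.
#' @export
colorize <- function(m8, colormap = "jet") {
  if (any(m8 < 0) || any(m8 > 255)) stop_input("values must be in [0, 255]")
  tab <- colormap_table(colormap)
  out <- array(0L, c(nrow(m8), ncol(m8), 3L))
  for (ch in 1:3) out[, , ch] <- matrix(tab[m8 + 1L, ch], nrow(m8), ncol(m8))
  out
}

# bilinear resample of a single channel to (h_out, w_out); output pixel i maps
# to source coordinate (i-1) * (H-1)/(h_out-1) + 1 (corner-aligned grid)
resize_channel <- function(M, h_out, w_out) {
  H <- nrow(M); W <- ncol(M)
  src_i <- if (h_out == 1L) rep(1, 1) else (seq_len(h_out) - 1) * (H - 1) / (h_out - 1) + 1
  src_j <- if (w_out == 1L) rep(1, 1) else (seq_len(w_out) - 1) * (W - 1) / (w_out - 1) + 1
  i0 <- pmin(floor(src_i), H - 1L); i0[H == 1] <- 1
  j0 <- pmin(floor(src_j), W - 1L); j0[W == 1] <- 1
  if (H == 1L) { i0 <- rep(1L, h_out); di <- rep(0, h_out) } else di <- src_i - i0
  if (W == 1L) { j0 <- rep(1L, w_out); dj <- rep(0, w_out) } else dj <- src_j - j0
  i1 <- pmin(i0 + 1L, H); j1 <- pmin(j0 + 1L, W)
  A <- M[i0, j0, drop = FALSE]; B <- M[i0, j1, drop = FALSE]
  C <- M[i1, j0, drop = FALSE]; D <- M[i1, j1, drop = FALSE]
  wi <- matrix(di, h_out, w_out); wj <- matrix(dj, h_out, w_out, byrow = TRUE)
  A * (1 - wi) * (1 - wj) + B * (1 - wi) * wj + C * wi * (1 - wj) + D * wi * wj
}

#' Resize an RGB image to the CNN input shape
#'
#' Corner-aligned bilinear interpolation to `(227, 227, 3)` (or any requested
#' size), with channel values rounded half-up back to integers in `[0, 255]`.
#'
#' @param image Integer or numeric array `(H, W, 3)`.
#' @param size Output height and width (default `c(227, 227)`).
#' @return Integer array `(size[1], size[2], 3)`.
#' @export
resize_to_input <- function(image, size = c(227L, 227L)) {
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L || d[1] < 1L || d[2] < 1L)
    stop_input("`image` must be a nonempty (H, W, 3) array")
  out <- array(0L, c(size[1], size[2], 3L))
  for (ch in 1:3) {
    r <- resize_channel(image[, , ch], size[1], size[2])
    out[, , ch] <- matrix(as.integer(round_half_up(pmin(pmax(r, 0), 255))),
                          size[1], size[2])
  }
  out
}

#' Build the three-sensor fusion image set for one acquisition
#'
#' Full imaging path of one 5-second acquisition: per-sensor 100 x 400
#' residual buffers, joint 8-bit rescaling across the three sensors, colormap
#' conversion to RGB, and bilinear resize to `(227, 227, 3)`. Entirely
#' deterministic: identical recordings give byte-identical tensors.
#'
#' @param recording A residual [session_recording()] with three sensors.
#' @param colormap Colormap name (default "jet").
#' @param window_s Window length (default 5 s).
#' @param per_sensor Per-sensor instead of joint rescaling.
#' @param size CNN input height/width (default `c(227, 227)`).
#' @param id Acquisition identifier.
#' @return An object of class `uwb_imageset`: list with `images` (list of
#'   three `(size, size, 3)` integer arrays), `label` (the recording's
#'   subject, if any) and `id`.
#' @export
fusion_image_set <- function(recording, colormap = "jet", window_s = 5,
                             per_sensor = FALSE, size = c(227L, 227L),
                             id = NA_character_) {
  stopifnot(inherits(recording, "uwb_recording"))
  if (length(recording$sensor_ids) != 3L)
    stop_input("fusion imaging expects exactly 3 sensors")
  bufs <- lapply(recording$sensor_ids, function(s)
    build_buffer(recording, s, window_s = window_s))
  m8 <- stack_and_rescale(bufs, per_sensor = per_sensor)
  imgs <- lapply(m8, function(m) resize_to_input(colorize(m, colormap), size))
  names(imgs) <- recording$sensor_ids
  structure(list(images = imgs, label = recording$subject, id = id),
            class = "uwb_imageset")
}

#' @export
print.uwb_imageset <- function(x, ...) {
  d <- dim(x$images[[1]])
  cat(sprintf("Fusion image set %s: %d images of %d x %d x %d%s\n", x$id,
              length(x$images), d[1], d[2], d[3],
              if (!is.null(x$label)) paste0(", labeled (", x$label$id, ")") else ""))
  invisible(x)
}

#' Write a fusion image set to PNG files
#'
#' Lossless PNG per sensor plus a JSON label sidecar; the numeric pipeline
#' never re-reads JPEGs, keeping the tensors deterministic.
#'
#' @param imageset A [fusion_image_set()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_imageset <- function(imageset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (s in names(imageset$images)) {
    p <- file.path(dir, paste0(s, ".png"))
    png::writePNG(imageset$images[[s]] / 255, p)
    paths <- c(paths, p)
  }
  lab <- file.path(dir, "label.json")
  meta <- list(id = imageset$id)
  if (!is.null(imageset$label))
    meta$label <- unclass(imageset$label)
  jsonlite::write_json(meta, lab, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, lab))
}
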