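#' Exponential clutter (background) state
#'
#' Running estimate of the static background, updated each frame as
#' `C_n = alpha * C_{n-1} + (1 - alpha) * x_n`.
#'
#' @param C Per-bin clutter estimate.
#' @param alpha Forgetting factor in `[0, 1]` (default 0.95).
#' @param frame_count Number of frames absorbed so far.
#' @return An object of class `uwb_clutter_state`.
#' @export
clutter_state <- function(C, alpha = 0.95, frame_count = 0L) {
  if (alpha < 0 || alpha > 1) stop_input("alpha must be in [0, 1]")
  structure(list(C = as.numeric(C), alpha = alpha,
                 frame_count = as.integer(frame_count)),
            class = "uwb_clutter_state")
}

#' One step of exponential background subtraction
#'
#' Literal update order: the clutter estimate is first refreshed with the
#' incoming frame, then subtracted, so the residual is
#' `y_n = x_n - C_n = alpha * (x_n - C_{n-1})`.
#'
#' @param state A [clutter_state()].
#' @param frame Per-bin amplitude vector, same length as `state$C`.
#' @return List with elements `state` (updated) and `residual`.
#' @export
#' @examples
#' st <- clutter_state(rep(0, 4), alpha = 0.95)
#' update_clutter(st, rep(1, 4))$residual  # 0.95 everywhere
update_clutter <- function(state, frame) {
  stopifnot(inherits(state, "uwb_clutter_state"))
  if (length(frame) != length(state$C))
    stop_input("frame length (", length(frame), ") does not match state (",
               length(state$C), ")")
  C_new <- state$alpha * state$C + (1 - state$alpha) * frame
  list(state = clutter_state(C_new, state$alpha, state$frame_count + 1L),
       residual = frame - C_new)
}

#' Remove static clutter from a recording
#'
#' Applies the exponential background filter independently per sensor. With
#' the default literal order the residual is `y_n = x_n - C_n` where `C_n` has
#' already absorbed `x_n`; the `legacy` order subtracts before updating
#' (`y_n = x_n - C_{n-1}`), which differs by a factor `alpha` on step inputs.
#' The filter is initialised with the first frame (`init = "first_frame"`), so
#' a fully static scene yields exactly zero residuals, or with zeros.
#'
#' @param recording A [session_recording()].
#' @param alpha Forgetting factor (default 0.95).
#' @param init `"first_frame"` or `"zero"`.
#' @param order `"literal"` (update then subtract) or `"legacy"`.
#' @return A [session_recording()] of residuals (`stage = "residuals"`).
#' @export
subtract_background <- function(recording, alpha = 0.95,
                                init = c("first_frame", "zero"),
                                order = c("literal", "legacy")) {
  if (!inherits(recording, "uwb_recording") || length(recording$frames) == 0L)
    stop_input("`recording` must be a nonempty session recording")
  if (recording$n_frames < 1L) stop_input("recording has no frames")
  init <- match.arg(init)
  order <- match.arg(order)
  res <- lapply(recording$frames, function(X) {
    C0 <- if (init == "first_frame") X[1, ] else numeric(ncol(X))
    # recursive filter per bin: C_n = alpha C_{n-1} + (1-alpha) x_n
    C <- stats::filter((1 - alpha) * X, alpha, method = "recursive",
                       init = matrix(C0, 1))
    C <- matrix(as.numeric(C), nrow(X), ncol(X))
    if (order == "literal") X - C
    else {
      C_prev <- rbind(C0, C[-nrow(C), , drop = FALSE])
      dimnames(C_prev) <- NULL
      X - C_prev
    }
  })
  out <- recording
  out$frames <- res
  out$stage <- "residuals"
  out
}

#' Hilbert envelope of residual frames
#'
#' Magnitude of the analytic signal along the range (fast-time) axis,
#' computed by zeroing the negative-frequency half of the spectrum. Accepts a
#' single frame (vector) or a `(n_frames, n_bins)` matrix, in which case each
#' row is transformed independently.
#'
#' @param y Numeric vector or matrix of residuals; must be finite.
#' @return Nonnegative envelope of the same shape.
#' @export
#' @examples
#' k <- 0:255
#' env <- envelope(3 * cos(2 * pi * 0.2 * k))
#' summary(env[50:200])  # ~3 at interior bins
envelope <- function(y) {
  if (any(!is.finite(y))) stop_input("envelope input contains non-finite values")
  one <- is.null(dim(y))
  Y <- if (one) matrix(y, nrow = 1) else y
  N <- ncol(Y)
  # analytic-signal weights: keep DC (and Nyquist) once, double positive freqs
  h <- numeric(N)
  if (N %% 2 == 0) {
    h[c(1, N / 2 + 1)] <- 1
    h[2:(N / 2)] <- 2
  } else {
    h[1] <- 1
    if (N > 1) h[2:((N + 1) / 2)] <- 2
  }
  Yf <- mvfft(t(Y)) * h
  A <- mvfft(Yf, inverse = TRUE) / N
  E <- t(Mod(A))
  if (one) as.numeric(E) else E
}
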