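check_pairs <- function(est, ref, min_n = 1L) {
  if (length(est) != length(ref))
    stop_input("`est` and `ref` must have equal length")
  if (length(est) < min_n)
    stop_input("need at least ", min_n, " pairs")
  if (any(!is.finite(est)) || any(!is.finite(ref)))
    stop_input("inputs must be finite")
  invisible(TRUE)
}

#' Root-mean-square error
#' @param est,ref Paired numeric vectors.
#' @return `sqrt(mean((est - ref)^2))`.
#' @export
rmse <- function(est, ref) {
  check_pairs(est, ref)
  sqrt(mean((est - ref)^2))
}

#' Mean absolute error
#' @param est,ref Paired numeric vectors.
#' @return `mean(abs(est - ref))`.
#' @export
mae <- function(est, ref) {
  check_pairs(est, ref)
  mean(abs(est - ref))
}

#' Squared Pearson correlation
#' @param est,ref Paired numeric vectors of length >= 2 with nonzero variance.
#' @return Squared Pearson correlation coefficient, in `[0, 1]`.
#' @export
pearson_r2 <- function(est, ref) {
  check_pairs(est, ref, min_n = 2L)
  if (sd(est) == 0 || sd(ref) == 0)
    stop_input("Pearson correlation undefined: zero variance")
  cor(est, ref)^2
}

#' Intraclass correlation coefficient, ICC(2,1) absolute agreement
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC for a
#' method-comparison design with two raters (estimate vs reference). From the
#' ANOVA mean squares of the n x 2 table (MSR between subjects, MSC between
#' raters, MSE residual):
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)` with `k = 2`.
#' Absolute agreement penalises systematic offsets between the methods.
#'
#' @param est,ref Paired numeric vectors, n >= 2.
#' @return ICC in `[-1, 1]`.
#' @export
icc <- function(est, ref) {
  check_pairs(est, ref, min_n = 2L)
  n <- length(est)
  k <- 2
  Y <- cbind(est, ref)
  g <- mean(Y)
  if (all(Y == Y[1])) stop_input("ICC undefined: all values identical")
  ss_total <- sum((Y - g)^2)
  ss_rows <- k * sum((rowMeans(Y) - g)^2)     # between subjects
  ss_cols <- n * sum((colMeans(Y) - g)^2)     # between raters
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' Agreement report between estimates and references
#'
#' Bundles RMSE, MAE, ICC(2,1) and Pearson r^2 for one anthropometric
#' parameter, mirroring a one-row method-comparison summary.
#'
#' @param est,ref Paired numeric vectors, n >= 2.
#' @param parameter Parameter name (e.g. "weight").
#' @param units Measurement units (e.g. "kg").
#' @return An object of class `uwb_agreement` with fields `rmse`, `mae`,
#'   `icc`, `r2`, `n`, `parameter`, `units`.
#' @export
#' @examples
#' agreement_report(c(160, 170, 181), c(161, 171, 179), "height", "cm")
agreement_report <- function(est, ref, parameter = "parameter", units = "") {
  check_pairs(est, ref, min_n = 2L)
  structure(list(rmse = rmse(est, ref), mae = mae(est, ref),
                 icc = icc(est, ref), r2 = pearson_r2(est, ref),
                 n = length(est), parameter = parameter, units = units),
            class = "uwb_agreement")
}

#' @export
print.uwb_agreement <- function(x, ...) {
  cat(sprintf("%s%s (n = %d): RMSE %.3f | MAE %.3f | ICC %.3f | r2 %.3f\n",
              x$parameter, if (nzchar(x$units)) paste0(" [", x$units, "]") else "",
              x$n, x$rmse, x$mae, x$icc, x$r2))
  invisible(x)
}

#' @export
as.data.frame.uwb_agreement <- function(x, ...) {
  data.frame(parameter = x$parameter, units = x$units, rmse = x$rmse,
             mae = x$mae, icc = x$icc, r2 = x$r2, n = x$n)
}
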