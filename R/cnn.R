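#' Network architecture specification
#'
#' Per-branch stack of `depth` hidden blocks (3x3 valid convolution -> ReLU ->
#' 2x2 average pooling, stride 2), one stack per sensor with unshared weights;
#' the flattened branch outputs are concatenated (the CAT layer), followed by
#' one fully connected ReLU layer of width `fc_out` and a single-unit linear
#' regression head.
#'
#' @param depth Hidden conv blocks per branch (default 3).
#' @param n_filters Filters per conv layer (default 16).
#' @param filter_size Convolution kernel size; fixed at 3.
#' @param fc_out Width of the fully connected layer (default 256).
#' @param n_branches Number of sensor branches (default 3).
#' @return An object of class `uwb_netspec`.
#' @export
network_spec <- function(depth = 3L, n_filters = 16L, filter_size = 3L,
                         fc_out = 256L, n_branches = 3L) {
  if (depth < 1L) stop_input("depth must be >= 1")
  if (filter_size != 3L) stop_input("filter_size is fixed at 3")
  if (n_filters < 1L || fc_out < 1L || n_branches < 1L)
    stop_input("n_filters, fc_out and n_branches must be positive")
  structure(list(depth = as.integer(depth), n_filters = as.integer(n_filters),
                 filter_size = 3L, fc_out = as.integer(fc_out),
                 n_branches = as.integer(n_branches)),
            class = "uwb_netspec")
}

#' Training hyperparameters
#'
#' Defaults: learning rate 0.001, minibatch 8, 60 epochs, MSE loss, Adam
#' optimiser. Targets are z-scored internally during training and restored at
#' prediction.
#'
#' @param learning_rate Adam step size.
#' @param minibatch Minibatch size; a final partial batch is trained on as-is.
#' @param epochs Number of passes over the training set.
#' @param seed Seed controlling weight initialisation and shuffling.
#' @return An object of class `uwb_hyper`.
#' @export
train_hyper <- function(learning_rate = 0.001, minibatch = 8L, epochs = 60L,
                        seed = 1L) {
  if (learning_rate < 0) stop_input("learning_rate must be >= 0")
  if (minibatch < 1L || epochs < 1L) stop_input("minibatch and epochs must be >= 1")
  structure(list(learning_rate = learning_rate, minibatch = as.integer(minibatch),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "uwb_hyper")
}

# spatial size of each branch block and the flattened feature length
conv_shapes <- function(spec, input_shape) {
  h <- input_shape[1]; w <- input_shape[2]
  hs <- ws <- integer(spec$depth)
  for (l in seq_len(spec$depth)) {
    h <- h - 2L; w <- w - 2L
    if (h < 1L || w < 1L) stop_input("input too small for depth ", spec$depth,
                                     " (pooled size < 1)")
    h <- h %/% 2L; w <- w %/% 2L
    if (h < 1L || w < 1L) stop_input("input too small for depth ", spec$depth,
                                     " (pooled size < 1)")
    hs[l] <- h; ws[l] <- w
  }
  list(hs = hs, ws = ws,
       branch_dim = hs[spec$depth] * ws[spec$depth] * spec$n_filters)
}

#' Number of learnable parameters of a network
#' @param spec A [network_spec()].
#' @param input_shape Per-branch input shape `c(H, W, C)`.
#' @return Total count of weights and biases.
#' @export
count_parameters <- function(spec, input_shape = c(227L, 227L, 3L)) {
  sh <- conv_shapes(spec, input_shape)
  n <- 0
  c_in <- input_shape[3]
  for (l in seq_len(spec$depth)) {
    n <- n + (9 * c_in * spec$n_filters + spec$n_filters)
    c_in <- spec$n_filters
  }
  n <- n * spec$n_branches
  D <- sh$branch_dim * spec$n_branches
  n + (D * spec$fc_out + spec$fc_out) + (spec$fc_out + 1)
}

#' Initialise network weights
#'
#' Seeded He-style initialisation: conv kernels `N(0, sqrt(2 / fan_in))` with
#' `fan_in = 9 * C_in`, fully connected layers likewise; biases zero. Branch
#' weights are drawn independently (not shared across sensors).
#'
#' @param spec A [network_spec()].
#' @param input_shape Per-branch input shape `c(H, W, C)`.
#' @param seed Integer seed.
#' @return A named list of weight arrays, the format consumed by the trainer.
#' @export
build_network <- function(spec, input_shape = c(227L, 227L, 3L), seed = 1L) {
  sh <- conv_shapes(spec, input_shape)
  with_seed(seed, {
    conv_w <- conv_b <- vector("list", spec$n_branches)
    for (b in seq_len(spec$n_branches)) {
      ws <- bs <- vector("list", spec$depth)
      c_in <- input_shape[3]
      for (l in seq_len(spec$depth)) {
        fan_in <- 9 * c_in
        ws[[l]] <- matrix(rnorm(fan_in * spec$n_filters, 0, sqrt(2 / fan_in)),
                          fan_in, spec$n_filters)
        bs[[l]] <- numeric(spec$n_filters)
        c_in <- spec$n_filters
      }
      conv_w[[b]] <- ws; conv_b[[b]] <- bs
    }
    D <- sh$branch_dim * spec$n_branches
    list(conv_w = conv_w, conv_b = conv_b,
         fc_w = matrix(rnorm(D * spec$fc_out, 0, sqrt(2 / D)), D, spec$fc_out),
         fc_b = numeric(spec$fc_out),
         out_w = rnorm(spec$fc_out, 0, sqrt(1 / spec$fc_out)),
         out_b = 0)
  })
}

#' Labelled image dataset for CNN regression
#'
#' @param x Integer array `(H, W, 3, n_branches, N)` of 8-bit images, or a
#'   list of [fusion_image_set()] objects (then `y`/`subject_ids` may be
#'   derived from their labels).
#' @param y Numeric targets of length N (taken from labels when `x` is a list
#'   of image sets and `y` is NULL).
#' @param parameter Name of the regressed parameter.
#' @param subject_ids Subject id per item (used for leakage-safe splitting).
#' @param ids Optional acquisition ids.
#' @return An object of class `uwb_dataset`.
#' @export
labeled_dataset <- function(x, y = NULL, parameter = "weight",
                            subject_ids = NULL, ids = NULL) {
  if (is.list(x) && !is.array(x)) {
    sets <- x
    if (!all(vapply(sets, inherits, TRUE, "uwb_imageset")))
      stop_input("`x` must be an array or a list of fusion image sets")
    d <- dim(sets[[1]]$images[[1]])
    nb <- length(sets[[1]]$images)
    x <- array(0L, c(d, nb, length(sets)))
    for (n in seq_along(sets))
      for (b in seq_len(nb)) x[, , , b, n] <- sets[[n]]$images[[b]]
    if (is.null(y))
      y <- vapply(sets, function(s) {
        if (is.null(s$label)) stop_input("image set ", s$id, " is unlabeled")
        s$label[[parameter]]
      }, 0)
    if (is.null(subject_ids))
      subject_ids <- vapply(sets, function(s)
        if (is.null(s$label)) NA_character_ else s$label$id, "")
    if (is.null(ids)) ids <- vapply(sets, function(s) s$id, "")
  }
  d <- dim(x)
  if (length(d) != 5L) stop_input("`x` must have dims (H, W, 3, branches, N)")
  N <- d[5]
  if (N < 1L) stop_input("dataset must be nonempty")
  if (length(y) != N) stop_input("`y` must have one target per item")
  if (any(!is.finite(y))) stop_input("targets must be finite")
  if (is.null(subject_ids)) subject_ids <- as.character(seq_len(N))
  if (length(subject_ids) != N) stop_input("`subject_ids` must have length N")
  if (is.null(ids)) ids <- as.character(seq_len(N))
  storage.mode(x) <- "integer"
  structure(list(x = x, y = as.numeric(y), parameter = parameter,
                 subject_ids = as.character(subject_ids), ids = ids),
            class = "uwb_dataset")
}

#' @export
print.uwb_dataset <- function(x, ...) {
  d <- dim(x$x)
  cat(sprintf("Labelled dataset: %d items (%s), %d x %d x %d images, %d branches, %d subjects\n",
              d[5], x$parameter, d[1], d[2], d[3], d[4],
              length(unique(x$subject_ids))))
  invisible(x)
}

#' Subset a labelled dataset
#' @param dataset A [labeled_dataset()].
#' @param idx Integer item indices.
#' @return The subsetted `uwb_dataset`.
#' @export
subset_dataset <- function(dataset, idx) {
  labeled_dataset(dataset$x[, , , , idx, drop = FALSE], dataset$y[idx],
                  dataset$parameter, dataset$subject_ids[idx],
                  dataset$ids[idx])
}

#' Train/validation split
#'
#' `"acquisition"` mode splits the items at random (the protocol's 75/25 split
#' of 360 acquisitions, which can place repetitions of a subject on both
#' sides); `"subject"` mode (the leakage-safe default) keeps all repetitions
#' of a subject on the same side.
#'
#' @param dataset A [labeled_dataset()].
#' @param train_frac Fraction assigned to training, in (0, 1) (default 0.75).
#' @param seed Integer seed.
#' @param mode `"subject"` or `"acquisition"`.
#' @return List with `train` and `val` datasets (disjoint, exhaustive).
#' @export
split_dataset <- function(dataset, train_frac = 0.75, seed = 1L,
                          mode = c("subject", "acquisition")) {
  mode <- match.arg(mode)
  if (train_frac <= 0 || train_frac >= 1)
    stop_input("train_frac must be in (0, 1)")
  N <- length(dataset$y)
  idx_train <- with_seed(seed, {
    if (mode == "acquisition") {
      sort(sample(N, round(train_frac * N)))
    } else {
      subj <- unique(dataset$subject_ids)
      tr <- sample(subj, round(train_frac * length(subj)))
      which(dataset$subject_ids %in% tr)
    }
  })
  list(train = subset_dataset(dataset, idx_train),
       val = subset_dataset(dataset, setdiff(seq_len(N), idx_train)))
}

#' Fit the three-branch late-fusion CNN regressor
#'
#' Trains one network for one anthropometric parameter by minibatch Adam on
#' the mean-squared error of z-scored targets. The fit is a pure function of
#' the dataset, the architecture, and the hyperparameters (including their
#' seed).
#'
#' @param dataset Training [labeled_dataset()].
#' @param spec A [network_spec()].
#' @param hyper A [train_hyper()].
#' @param init_weights Optional [build_network()] list to start from (warm
#'   start); defaults to a fresh seeded initialisation.
#' @return An object of class `fusion_cnn` with components `spec`, `hyper`,
#'   `weights`, `target_center`, `target_scale`, `history` (per-epoch training
#'   loss, normalised and in target units), `parameter`, `input_shape`, and
#'   the training fit (`fitted_values`, `train_y`).
#' @seealso [predict.fusion_cnn()], [split_dataset()], [sweep_architectures()]
#' @export
#' @examples
#' \dontrun{
#' sets <- lapply(recs, fusion_image_set)   # residual recordings
#' ds <- labeled_dataset(sets, parameter = "weight")
#' sp <- split_dataset(ds, 0.75, seed = 1)
#' fit <- fusion_cnn(sp$train, network_spec(), train_hyper(epochs = 20))
#' pred <- predict(fit, sp$val)
#' agreement_report(pred, sp$val$y, "weight", "kg")
#' }
fusion_cnn <- function(dataset, spec = network_spec(), hyper = train_hyper(),
                       init_weights = NULL) {
  stopifnot(inherits(dataset, "uwb_dataset"), inherits(spec, "uwb_netspec"),
            inherits(hyper, "uwb_hyper"))
  d <- dim(dataset$x)
  input_shape <- d[1:3]
  if (d[4] != spec$n_branches)
    stop_input("dataset has ", d[4], " branches but spec expects ",
               spec$n_branches)
  N <- d[5]
  center <- mean(dataset$y)
  scale <- sd(dataset$y)
  if (!is.finite(scale) || scale == 0) scale <- 1
  y_norm <- (dataset$y - center) / scale
  if (is.null(init_weights))
    init_weights <- build_network(spec, input_shape, seed = hyper$seed)
  perm <- with_seed(child_seed(hyper$seed, "perm"),
                    vapply(seq_len(hyper$epochs), function(e) sample.int(N),
                           integer(N)))
  res <- cnn_train(dataset$x, dim(dataset$x), y_norm, unclass(spec),
                   init_weights, perm, hyper$learning_rate, hyper$minibatch,
                   0.9, 0.999, 1e-8)
  # canonical R shapes (the trainer returns 1 x n bias matrices)
  res$weights$conv_b <- lapply(res$weights$conv_b,
                               function(bl) lapply(bl, as.numeric))
  res$weights$fc_b <- as.numeric(res$weights$fc_b)
  res$weights$out_w <- as.numeric(res$weights$out_w)
  res$weights$out_b <- as.numeric(res$weights$out_b)
  fitted_norm <- cnn_forward(dataset$x, dim(dataset$x), res$weights,
                             unclass(spec), seq_len(N))
  history <- data.frame(epoch = seq_len(hyper$epochs),
                        mse = res$history,
                        rmse = sqrt(res$history) * scale)
  structure(list(spec = spec, hyper = hyper, weights = res$weights,
                 target_center = center, target_scale = scale,
                 history = history, parameter = dataset$parameter,
                 input_shape = input_shape, n_train = N,
                 fitted_values = fitted_norm * scale + center,
                 train_y = dataset$y, call = match.call()),
            class = "fusion_cnn")
}

#' @export
print.fusion_cnn <- function(x, ...) {
  cat(sprintf("Late-fusion CNN for '%s': %d branches, depth %d, %d filters, fc %d (%s parameters)\n",
              x$parameter, x$spec$n_branches, x$spec$depth, x$spec$n_filters,
              x$spec$fc_out,
              format(count_parameters(x$spec, x$input_shape), big.mark = ",")))
  cat(sprintf("Trained %d epochs on %d items; final training RMSE %.3f (target SD %.3f)\n",
              x$hyper$epochs, x$n_train, tail(x$history$rmse, 1),
              x$target_scale))
  invisible(x)
}

#' @export
summary.fusion_cnn <- function(object, ...) {
  cat("Call: "); print(object$call)
  print(object)
  cat("\nTraining loss (normalised MSE) by epoch:\n")
  print(summary(object$history$mse))
  cat("\nTraining-set agreement:\n")
  print(agreement_report(object$fitted_values, object$train_y,
                         object$parameter))
  invisible(object)
}

#' Predict anthropometric values for new image sets
#'
#' @param object A fitted [fusion_cnn()].
#' @param newdata A [labeled_dataset()], a list of [fusion_image_set()]s, or a
#'   single image set; image shapes must match the training input.
#' @param ... Unused.
#' @return Numeric vector of predictions in target units.
#' @export
predict.fusion_cnn <- function(object, newdata, ...) {
  if (inherits(newdata, "uwb_imageset")) newdata <- list(newdata)
  if (!inherits(newdata, "uwb_dataset"))
    newdata <- labeled_dataset(newdata, y = rep(0, length(newdata)),
                               parameter = object$parameter)
  d <- dim(newdata$x)
  if (!identical(as.integer(d[1:3]), as.integer(object$input_shape)) ||
      d[4] != object$spec$n_branches)
    stop_input("newdata image shape does not match the trained network")
  out <- cnn_forward(newdata$x, d, object$weights, unclass(object$spec),
                     seq_len(d[5]))
  as.numeric(out) * object$target_scale + object$target_center
}

#' @export
fitted.fusion_cnn <- function(object, ...) object$fitted_values

#' @export
residuals.fusion_cnn <- function(object, ...) object$train_y - object$fitted_values

#' @export
coef.fusion_cnn <- function(object, ...) object$weights

#' Plot the training history of a fitted fusion CNN
#' @param x A [fusion_cnn()] fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.fusion_cnn <- function(x, ...) {
  plot(x$history$epoch, x$history$rmse, type = "l", xlab = "epoch",
       ylab = sprintf("training RMSE (%s)", x$parameter), ...)
  invisible(x)
}

#' Architecture sweep over depth, filter count and FC width
#'
#' Trains one network per grid cell on a common train/validation split and
#' reports the validation RMSE, mirroring a depth x filters x FC-width
#' accuracy comparison.
#'
#' @param dataset A [labeled_dataset()].
#' @param depths,filters,fc_widths Grid values.
#' @param hyper A [train_hyper()] applied to every cell.
#' @param train_frac,seed,mode Passed to [split_dataset()].
#' @return A data.frame with columns `depth`, `filters`, `fc_out`,
#'   `val_rmse`, and `error` (NA unless the cell failed).
#' @export
sweep_architectures <- function(dataset, depths = c(2L, 3L, 4L),
                                filters = c(16L, 32L, 64L, 128L),
                                fc_widths = c(256L, 512L, 1024L),
                                hyper = train_hyper(), train_frac = 0.75,
                                seed = 1L, mode = "subject") {
  grid <- expand.grid(depth = depths, filters = filters, fc_out = fc_widths)
  if (nrow(grid) == 0L) stop_input("sweep grid is empty")
  sp <- split_dataset(dataset, train_frac, seed, mode)
  grid$val_rmse <- NA_real_
  grid$error <- NA_character_
  for (i in seq_len(nrow(grid))) {
    cell <- sprintf("depth=%d/filters=%d/fc=%d", grid$depth[i],
                    grid$filters[i], grid$fc_out[i])
    res <- tryCatch({
      fit <- fusion_cnn(sp$train,
                        network_spec(depth = grid$depth[i],
                                     n_filters = grid$filters[i],
                                     fc_out = grid$fc_out[i]),
                        hyper)
      rmse(predict(fit, sp$val), sp$val$y)
    }, error = function(e) {
      warning("sweep cell ", cell, " failed: ", conditionMessage(e),
              call. = FALSE)
      NA_real_
    })
    grid$val_rmse[i] <- res
    if (is.na(res)) grid$error[i] <- cell
  }
  grid
}
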