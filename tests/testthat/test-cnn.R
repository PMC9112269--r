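test_that("network bookkeeping: shapes, parameter counts, invalid specs", {
  # hand count for a 1-branch toy: depth 1, 1 filter, input 20 x 24 x 3
  # conv: 9*3*1 + 1 = 28; flatten: 9*11*1 = 99; fc 4: 99*4 + 4; head: 4 + 1
  spec <- network_spec(depth = 1, n_filters = 1, fc_out = 4, n_branches = 1)
  expect_equal(count_parameters(spec, c(20L, 24L, 3L)),
               28 + (99 * 4 + 4) + (4 + 1))
  w <- build_network(spec, c(20L, 24L, 3L), seed = 1)
  expect_equal(length(unlist(w)), count_parameters(spec, c(20L, 24L, 3L)))

  # three branches, depth 3 (the default architecture)
  spec3 <- network_spec()
  expect_identical(spec3$depth, 3L)
  w3 <- build_network(spec3, c(227L, 227L, 3L), seed = 1)
  expect_equal(length(unlist(w3)), count_parameters(spec3))

  expect_error(network_spec(depth = 0), "depth")
  expect_error(network_spec(filter_size = 5), "fixed at 3")
  expect_error(count_parameters(network_spec(depth = 4), c(20L, 20L, 3L)),
               "too small")
})

test_that("a forward pass yields one finite scalar per item", {
  ds <- small_dataset(n = 5)
  fit <- fusion_cnn(ds, network_spec(depth = 2, n_filters = 4, fc_out = 8),
                    train_hyper(epochs = 2L, seed = 1))
  pred <- predict(fit, ds)
  expect_length(pred, 5L)
  expect_true(all(is.finite(pred)))
  # duplicated input gives identical outputs
  dup <- subset_dataset(ds, c(2L, 2L))
  p2 <- predict(fit, dup)
  # BLAS kernels may round identically-valued rows differently by position,
  # so agreement is to float precision rather than bitwise
  expect_equal(p2[1], p2[2], tolerance = 1e-6)
})

test_that("splits are disjoint, exhaustive, seeded, and leakage-safe", {
  ds <- small_dataset(n = 360, H = 6L, W = 6L, seed = 2)
  ds$subject_ids <- rep(sprintf("S%02d", 1:45), each = 8)

  sp <- split_dataset(ds, 0.75, seed = 4, mode = "acquisition")
  expect_identical(length(sp$train$y), 270L)
  expect_identical(length(sp$val$y), 90L)
  expect_identical(sort(c(sp$train$ids, sp$val$ids)), sort(ds$ids))

  sps <- split_dataset(ds, 0.75, seed = 4, mode = "subject")
  expect_length(intersect(unique(sps$train$subject_ids),
                          unique(sps$val$subject_ids)), 0L)
  expect_identical(length(sps$train$y) + length(sps$val$y), 360L)

  sp2 <- split_dataset(ds, 0.75, seed = 4, mode = "acquisition")
  expect_identical(sp$train$ids, sp2$train$ids)

  expect_error(split_dataset(ds, 1.2), "train_frac")
})

test_that("training is a pure function of its seed; lr = 0 is a null update", {
  ds <- small_dataset(n = 6)
  spec <- network_spec(depth = 2, n_filters = 4, fc_out = 8)
  w0 <- build_network(spec, c(12L, 14L, 3L), seed = 7)

  null_fit <- fusion_cnn(ds, spec, train_hyper(0, 6L, 3L, seed = 3),
                         init_weights = w0)
  expect_equal(coef(null_fit), w0, tolerance = 1e-6)
  expect_equal(null_fit$history$mse[1], null_fit$history$mse[3],
               tolerance = 1e-8)

  hy <- train_hyper(0.003, 3L, 10L, seed = 3)
  f1 <- fusion_cnn(ds, spec, hy)
  f2 <- fusion_cnn(ds, spec, hy)
  expect_identical(f1$history, f2$history)
  expect_identical(coef(f1), coef(f2))
})

test_that("backpropagation matches central finite differences when linear", {
  # all conv/fc biases shifted up so every ReLU stays active: the network is
  # locally linear and finite differences are exact up to float noise
  spec <- network_spec(depth = 2, n_filters = 4, fc_out = 8)
  ds <- small_dataset(n = 6, H = 16L, W = 18L, seed = 42)
  y_norm <- (ds$y - mean(ds$y)) / sd(ds$y)
  w <- build_network(spec, c(16L, 18L, 3L), seed = 5)
  for (b in 1:3) for (l in 1:2) w$conv_b[[b]][[l]] <- w$conv_b[[b]][[l]] + 3
  w$fc_b <- w$fc_b + 5
  perm <- matrix(1:6, 6, 1)
  # float-rounded baseline, then one Adam step with huge eps extracts lr/eps
  # times the raw gradient of the full-batch MSE
  wf <- uwbanthro:::cnn_train(ds$x, dim(ds$x), y_norm, unclass(spec), w,
                              perm, 0, 6L, 0.9, 0.999, 1e-8)$weights
  res <- uwbanthro:::cnn_train(ds$x, dim(ds$x), y_norm, unclass(spec), w,
                               perm, 1e6, 6L, 0.9, 0.999, 1e9)$weights
  loss <- function(wx) {
    f <- uwbanthro:::cnn_forward(ds$x, dim(ds$x), wx, unclass(spec), 1:6)
    mean((f - y_norm)^2)
  }
  fd_vs_analytic <- function(get, set) {
    ga <- (get(wf) - get(res)) * 1e3
    h <- 2e-3
    fd <- (loss(set(wf, h)) - loss(set(wf, -h))) / (2 * h)
    c(ga, fd)
  }
  checks <- list(
    conv1 = fd_vs_analytic(function(w) w$conv_w[[1]][[1]][8, 2],
                           function(w, h) { w$conv_w[[1]][[1]][8, 2] <- w$conv_w[[1]][[1]][8, 2] + h; w }),
    conv2 = fd_vs_analytic(function(w) w$conv_w[[2]][[2]][13, 3],
                           function(w, h) { w$conv_w[[2]][[2]][13, 3] <- w$conv_w[[2]][[2]][13, 3] + h; w }),
    conv_b = fd_vs_analytic(function(w) w$conv_b[[3]][[1]][2],
                            function(w, h) { w$conv_b[[3]][[1]][2] <- w$conv_b[[3]][[1]][2] + h; w }),
    fc = fd_vs_analytic(function(w) w$fc_w[5, 3],
                        function(w, h) { w$fc_w[5, 3] <- w$fc_w[5, 3] + h; w }),
    out = fd_vs_analytic(function(w) w$out_w[2],
                         function(w, h) { w$out_w[2] <- w$out_w[2] + h; w }))
  for (nm in names(checks)) {
    ga <- checks[[nm]][1]; fd <- checks[[nm]][2]
    expect_lt(abs(ga - fd), 0.02 * max(abs(fd), 0.05))
  }
})

test_that("training reduces the loss on a learnable synthetic problem", {
  ds <- signal_dataset(n = 40, seed = 11)
  fit <- fusion_cnn(ds, network_spec(depth = 2, n_filters = 8, fc_out = 16),
                    train_hyper(0.001, 8L, 12L, seed = 12))
  expect_lt(tail(fit$history$mse, 1), fit$history$mse[1])
  expect_identical(nrow(fit$history), 12L)
})

test_that("the network can overfit 16 items (capacity check)", {
  ds <- signal_dataset(n = 16, H = 32L, W = 32L, seed = 13)
  fit <- fusion_cnn(ds, network_spec(depth = 2, n_filters = 8, fc_out = 32),
                    train_hyper(0.003, 8L, 200L, seed = 14))
  train_rmse <- rmse(fitted(fit), ds$y)
  expect_lt(train_rmse, 0.05 * sd(ds$y))
})

test_that("target normalisation round-trips and feeds prediction", {
  ds <- small_dataset(n = 8, y = rnorm(8, 70, 12))
  fit <- fusion_cnn(ds, network_spec(depth = 2, n_filters = 4, fc_out = 8),
                    train_hyper(epochs = 2L, seed = 5))
  expect_equal(fit$target_center, mean(ds$y))
  expect_equal(fit$target_scale, sd(ds$y))
  z <- (ds$y - fit$target_center) / fit$target_scale
  expect_equal(z * fit$target_scale + fit$target_center, ds$y, tolerance = 1e-6)
  expect_equal(residuals(fit), ds$y - fitted(fit), tolerance = 1e-12)
})

test_that("branches are wired to sensors: permuting sensors changes output", {
  ds <- small_dataset(n = 4, seed = 20)
  fit <- fusion_cnn(ds, network_spec(depth = 2, n_filters = 4, fc_out = 8),
                    train_hyper(epochs = 3L, seed = 6))
  permuted <- ds
  permuted$x <- ds$x[, , , c(2, 1, 3), , drop = FALSE]
  p0 <- predict(fit, ds)
  p1 <- predict(fit, permuted)
  # per-branch weights are unshared, so branch-to-sensor assignment matters
  expect_false(isTRUE(all.equal(p0, p1)))
})

test_that("a 1-cell sweep equals a direct train-and-evaluate", {
  ds <- small_dataset(n = 24, H = 10L, W = 10L, seed = 30)
  ds$subject_ids <- rep(sprintf("P%d", 1:8), each = 3)
  hy <- train_hyper(0.001, 8L, 2L, seed = 31)
  tab <- sweep_architectures(ds, depths = 2L, filters = 4L, fc_widths = 16L,
                             hyper = hy, seed = 32, mode = "subject")
  expect_identical(nrow(tab), 1L)
  sp <- split_dataset(ds, 0.75, seed = 32, mode = "subject")
  fit <- fusion_cnn(sp$train, network_spec(depth = 2, n_filters = 4,
                                           fc_out = 16), hy)
  expect_equal(tab$val_rmse[1], rmse(predict(fit, sp$val), sp$val$y),
               tolerance = 1e-12)

  # row count equals the grid size
  tab2 <- sweep_architectures(ds, depths = c(1L, 2L), filters = c(2L, 4L),
                              fc_widths = 8L, hyper = hy, seed = 32)
  expect_identical(nrow(tab2), 4L)
  expect_true(all(is.finite(tab2$val_rmse)))
})
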