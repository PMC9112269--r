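# shared fixtures, all generated in code

ref_subject <- function(id = "S001") {
  subject_profile(164, 62.2, 39.2, 22.7, 30.6, 17.9, id = id)
}

# single-path scene with everything else switched off
one_path_scene <- function(delay, amplitude, breath_gain = 0, n_bins = 400,
                           noise_sd = 0, amplitude_mm = 0) {
  scatter_scene(
    list(ceiling = data.frame(delay = delay, amplitude = amplitude,
                              breath_gain = breath_gain)),
    noise_sd = noise_sd,
    breathing = list(rate_hz = 0.3, amplitude_mm = amplitude_mm, phase = 0),
    n_bins = n_bins)
}

# random small labelled dataset for CNN unit tests
small_dataset <- function(n = 6L, H = 12L, W = 14L, n_branches = 3L,
                          seed = 42L, y = NULL) {
  withr::with_seed(seed, {
    x <- array(sample(0:255, H * W * 3 * n_branches * n, replace = TRUE),
               c(H, W, 3L, n_branches, n))
    if (is.null(y)) y <- rnorm(n)
    labeled_dataset(x, y, "weight")
  })
}

# small images whose mean brightness encodes the target; learnable by design
signal_dataset <- function(n = 16L, H = 24L, W = 24L, seed = 7L,
                           subject_ids = NULL) {
  withr::with_seed(seed, {
    y <- runif(n, -1, 1)
    x <- array(0L, c(H, W, 3L, 3L, n))
    for (i in seq_len(n)) {
      base <- 128 + 80 * y[i]
      for (b in 1:3)
        x[, , , b, i] <- pmin(255L, pmax(0L, as.integer(
          round(base + rnorm(H * W * 3, 0, 12)))))
    }
    labeled_dataset(x, y, "weight", subject_ids = subject_ids)
  })
}
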