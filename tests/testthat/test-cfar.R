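test_that("range resolution follows c / (2 fs)", {
  dr <- range_resolution(23.328e9)
  expect_equal(dr, 299792458 / (2 * 23.328e9), tolerance = 1e-15)
  expect_equal(round(dr * 1000, 1), 6.4)              # the 6.4 mm bin
  expect_equal(range_resolution(299792458 / 2), 1.0)  # unit case
  expect_equal(range_resolution(2 * 23.328e9), dr / 2)
  expect_error(range_resolution(0), "positive")
})

test_that("threshold calibration matches hand-computed mean/std statistics", {
  # identical frames: zero variance, standard threshold is the mean
  H <- rbind(c(1, 4), c(1, 4), c(1, 4))
  for (beta in c(0, 1, 5))
    expect_equal(calibrate_threshold(H, beta = beta)$T, c(1, 4))

  # beta = 0 reduces to the per-bin mean
  H2 <- rbind(c(1, 0), c(2, 2), c(3, 1))
  expect_equal(calibrate_threshold(H2, beta = 0)$T, colMeans(H2))

  # 3 frames {1,2,3}, beta 2: T = 2 + 2 * 1 (sample std, ddof 1)
  th <- calibrate_threshold(matrix(c(1, 2, 3), ncol = 1), beta = 2)
  expect_equal(th$T, 4)
  expect_equal(th$mu, 2)
  expect_equal(th$sigma, 1)

  # the literal symbol assignment swaps the roles: T = beta * mean + std
  expect_equal(calibrate_threshold(matrix(c(1, 2, 3), ncol = 1), beta = 2,
                                   convention = "literal")$T, 2 * 2 + 1)

  expect_error(calibrate_threshold(matrix(1, 1, 4)), "N_c >= 2")
})

test_that("first-crossing detection agrees with a brute-force scan", {
  # constructed cases
  expect_identical(detect_first_crossing(rep(0.1, 50), rep(1, 50)), NA_integer_)
  env <- rep(0, 200); env[121:126] <- 5   # bins 120..125 (0-based)
  expect_identical(detect_first_crossing(env, rep(1, 200), min_run = 2), 120L)

  brute <- function(env, Tk, min_run) {
    for (k in 0:(length(env) - min_run))
      if (all(env[(k + 1):(k + min_run)] > Tk[(k + 1):(k + min_run)]))
        return(as.integer(k))
    NA_integer_
  }
  withr::with_seed(99, {
    for (case in 1:200) {
      n <- sample(5:40, 1)
      env <- runif(n)
      Tk <- runif(n, 0.2, 0.8)
      mr <- sample(1:3, 1)
      expect_identical(detect_first_crossing(env, Tk, mr), brute(env, Tk, mr),
                       info = sprintf("case %d", case))
    }
  })
})

test_that("false-alarm fraction is non-increasing in beta on noise-only data", {
  g <- room_geometry(); p <- pulse_model()
  calib <- simulate_empty_room(g, p, duration_s = 20, seed = 5)
  H <- calibration_buffer(subtract_background(calib), "ceiling")
  probe <- simulate_empty_room(g, p, duration_s = 2, seed = 6)
  E <- envelope(subtract_background(probe)$frames$ceiling)
  fracs <- vapply(c(0, 0.5, 1, 2, 3, 4, 5), function(beta) {
    Tk <- calibrate_threshold(H, beta = beta)$T
    mean(sweep(E, 2, Tk) > 0)
  }, 0)
  expect_true(all(diff(fracs) <= 0))
  expect_lt(fracs[length(fracs)], 0.01)
})

test_that("height follows the ceiling-range arithmetic", {
  # synthetic residual whose envelope crosses at a known bin
  p <- pulse_model()
  dr <- range_resolution(p$sampling_rate)
  X <- matrix(0, 10, 400)
  X[, 122] <- 3    # bin 121 (0-based) spike in every frame
  X[, 123] <- 2.5
  rec <- session_recording(list(ceiling = X), stage = "residuals")
  th <- calibrate_threshold(matrix(0.01, 4, 400), beta = 3)
  h <- estimate_height(rec, th)
  expect_identical(h$detected_bin, 121L)
  expect_equal(h$height, (2.5 - 121 * dr) * 100, tolerance = 1e-9)
  # 0.78 m of range in a 2.5 m room is 172 cm of height
  expect_equal((2.5 - 0.78) * 100, 172)
})

test_that("degenerate detections are rejected with diagnostics", {
  # an echo whose range reaches the floor (>= room height) must be rejected
  p <- pulse_model()
  X <- matrix(5 * p$template(0:399 - 200), 10, 400, byrow = TRUE)
  rec <- session_recording(list(ceiling = X), stage = "residuals")
  th <- calibrate_threshold(matrix(0.01, 4, 400), beta = 3)
  expect_error(estimate_height(rec, th, room_height = 1.0),
               "exceeds the room height|violates")

  Xq <- matrix(0, 10, 400); Xq[1:3, 122:130] <- 5  # detections in 3/10 frames
  recq <- session_recording(list(ceiling = Xq), stage = "residuals")
  expect_error(estimate_height(recq, th), "insufficient detections: only 3 of 10")
})

test_that("detection shifts are translation-consistent (noiseless)", {
  g <- room_geometry(); p <- pulse_model()
  th <- calibrate_threshold(matrix(0, 4, 400) + 1e-9, beta = 3)
  detect_at <- function(delay) {
    sc <- one_path_scene(delay, 2, breath_gain = 1, amplitude_mm = 4)
    res <- subtract_background(simulate_session(ref_subject(), g, p,
                                                scene = sc, seed = 21))
    estimate_height(res, th)$detected_bin
  }
  base <- detect_at(140)
  for (d in c(5, 17, 60))
    expect_identical(detect_at(140 + d), base + as.integer(d))
})

test_that("with default noise a cohort's heights are recovered to ~2 cm", {
  g <- room_geometry(); p <- pulse_model()
  calib <- subtract_background(simulate_empty_room(g, p, duration_s = 30,
                                                   seed = 71))
  th <- calibrate_threshold(calibration_buffer(calib, "ceiling"), beta = 3)
  cohort <- sample_population(10, seed = 72)
  est <- vapply(seq_along(cohort), function(i) {
    res <- subtract_background(
      simulate_session(cohort[[i]], g, p, seed = 100 + i))
    estimate_height(res, th)$height
  }, 0)
  refs <- cohort_table(cohort)$height
  expect_lte(rmse(est, refs), 2)
})

test_that("evaluate_height_cohort composes the agreement statistics", {
  est <- c(160.2, 171.5, 158.8, 183.1)
  ref <- c(161.0, 170.0, 160.0, 182.0)
  rep_ <- evaluate_height_cohort(est, ref)
  expect_s3_class(rep_, "uwb_agreement")
  expect_identical(rep_$parameter, "height")
  expect_equal(rep_$rmse, rmse(est, ref))
  expect_equal(evaluate_height_cohort(c(1, 2), c(1, 2))$rmse, 0)
  expect_error(evaluate_height_cohort(1:3, 1:2), "equal length")
  expect_error(evaluate_height_cohort(numeric(0), numeric(0)), "at least")
})
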