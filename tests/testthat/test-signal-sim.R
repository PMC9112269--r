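test_that("cohort sampling respects size, seed and the population medians", {
  expect_identical(sample_population(0, seed = 1), list())

  big <- sample_population(1000, seed = 7)
  tab <- cohort_table(big)
  # large cohorts center on the study population's median height
  expect_lt(abs(median(tab$height) - 164.00), 2)
  # BMI is definitional, never sampled
  expect_equal(tab$bmi, tab$weight / (tab$height / 100)^2, tolerance = 1e-9)
  # joint plausibility of the composition percentages
  expect_true(all(tab$body_water_pct + tab$body_fat_pct <= 100))
  expect_true(all(tab$height > 100 & tab$height < 220))
  expect_true(all(tab$weight > 20 & tab$weight < 200))

  # pure function of the seed
  expect_identical(sample_population(20, seed = 5), sample_population(20, seed = 5))
  expect_false(identical(cohort_table(sample_population(20, seed = 5)),
                         cohort_table(sample_population(20, seed = 6))))

  expect_error(population_defaults(height = c(164, -1)), "sd > 0")
})

test_that("scattering scale is the Mosteller surface area: monotone and exact", {
  s60 <- subject_profile(170, 60, 40, 23, 31, 18)
  s90 <- subject_profile(170, 90, 40, 23, 31, 18)
  expect_gt(body_scattering(s90)[["ceiling"]], body_scattering(s60)[["ceiling"]])
  expect_identical(body_scattering(s60), body_scattering(s60))
  # ratio equals the closed-form area ratio, evaluated independently
  s35 <- subject_profile(170, 35, 40, 23, 31, 18)
  s70 <- subject_profile(170, 70, 40, 23, 31, 18)
  expect_equal(body_scattering(s70)[["wall_1"]] / body_scattering(s35)[["wall_1"]],
               sqrt(170 * 70 / 3600) / sqrt(170 * 35 / 3600), tolerance = 1e-12)
})

test_that("a single noiseless path reproduces the pulse superposition exactly", {
  p <- pulse_model()
  rec <- simulate_session(ref_subject(), scene = one_path_scene(50, 2),
                          pulse = p, seed = 1)
  k <- 0:399
  expected <- 2 * p$template(k - 50)
  for (n in c(1, 37, 100))
    expect_identical(rec$frames$ceiling[n, ], expected)
})

test_that("frame counts follow fps and duration; output is seed-deterministic", {
  rec <- simulate_session(ref_subject(), seed = 3, duration_s = 5, fps = 20)
  expect_identical(dim(rec$frames$ceiling), c(100L, 400L))
  expect_length(rec$frames, 3L)

  rec2 <- simulate_session(ref_subject(), seed = 3, duration_s = 5, fps = 20)
  expect_identical(rec$frames, rec2$frames)
  rec3 <- simulate_session(ref_subject(), seed = 4)
  expect_false(identical(rec$frames, rec3$frames))
})

test_that("the received-signal model is linear in path amplitudes", {
  p <- pulse_model()
  sc1 <- one_path_scene(c(50, 120), c(1.5, 0.7), breath_gain = c(1, 0.3),
                        amplitude_mm = 5)
  sc2 <- sc1
  sc2$paths$ceiling$amplitude <- 2 * sc2$paths$ceiling$amplitude
  r1 <- simulate_session(ref_subject(), scene = sc1, pulse = p, seed = 9)
  r2 <- simulate_session(ref_subject(), scene = sc2, pulse = p, seed = 9)
  # equality is exact except in the subnormal underflow tail of the pulse
  expect_equal(2 * r1$frames$ceiling, r2$frames$ceiling, tolerance = 1e-14)
})

test_that("geometry violations are rejected", {
  tall <- subject_profile(219, 80, 40, 23, 31, 18)
  expect_error(simulate_session(tall, room_geometry(height = 2.0)),
               "taller than the room")
  expect_error(room_geometry(sensor_positions = list(bad = c(5, 1, 1))),
               "outside the room")
  expect_error(one_path_scene(500, 1), "outside")
})

test_that("empty-room recordings carry clutter plus noise only", {
  g <- room_geometry(); p <- pulse_model()
  # zero noise: every frame is exactly the static clutter profile
  sc <- empty_room_scene(g, p, noise_sd = 0)
  rec <- simulate_empty_room(g, p, scene = sc, duration_s = 2, seed = 1)
  for (s in rec$sensor_ids)
    for (n in c(1, 40))
      expect_identical(rec$frames[[s]][n, ], sc$clutter[[s]])

  # 5 minutes at 20 fps is 6000 frames (small bin count keeps this cheap)
  sc16 <- empty_room_scene(g, p, n_bins = 16, no_clutter = TRUE, noise_sd = 0)
  rec5 <- simulate_empty_room(g, p, scene = sc16, duration_s = 300, seed = 1)
  expect_identical(rec5$n_frames, 6000L)

  # CLT: the per-bin mean over frames approaches the clutter value
  scn <- empty_room_scene(g, p, n_bins = 64, noise_sd = 0.5)
  recn <- simulate_empty_room(g, p, scene = scn, duration_s = 60, seed = 2)
  n_frames <- recn$n_frames
  dev <- abs(colMeans(recn$frames$ceiling) - scn$clutter$ceiling[1:64])
  expect_true(all(dev < 3 * 0.5 / sqrt(n_frames) * 3))  # 3-sigma with slack
})

test_that("breathing makes the target dominate residual energy", {
  g <- room_geometry(); p <- pulse_model()
  subj <- ref_subject()
  scn <- subject_scene(subj, g, p, noise_sd = 0,
                       breathing = list(rate_hz = 0.3, amplitude_mm = 2,
                                        phase = 0.4))
  res <- subtract_background(simulate_session(subj, g, p, scene = scn, seed = 4))
  en <- colSums(res$frames$ceiling^2)
  target_bins <- round(range(scn$paths$ceiling$delay)) + c(-30, 30)
  target_en <- max(en[target_bins[1]:target_bins[2]])
  clutter_bins <- setdiff(seq_len(400), (target_bins[1] - 40):(target_bins[2] + 40))
  expect_gt(target_en, 10 * max(en[clutter_bins]))
})
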