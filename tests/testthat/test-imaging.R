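test_that("buffers are deterministic 100 x 400 crops", {
  rec <- simulate_session(ref_subject(), seed = 2)
  res <- subtract_background(rec)
  buf <- build_buffer(res, "ceiling")
  expect_identical(dim(buf), c(100L, 400L))
  expect_identical(unclass(buf)[3, 7], res$frames$ceiling[3, 7])
  expect_identical(matrix(buf, 100, 400),
                   res$frames$ceiling[1:100, 1:400])

  short <- simulate_session(ref_subject(), duration_s = 4, seed = 2)
  expect_error(build_buffer(subtract_background(short), "ceiling"),
               "too short")
  expect_error(build_buffer(res, "nope"), "not present")
})

test_that("joint 8-bit rescaling follows the documented linear map", {
  b1 <- matrix(c(-2, 2), 2, 2)   # stack min -2
  b2 <- matrix(c(0, 6), 2, 2)    # stack max 6
  b3 <- matrix(1, 2, 2)
  out <- stack_and_rescale(list(b1, b2, b3))
  expect_identical(out[[1]][1, 1], 0L)     # -2 -> 0
  expect_identical(out[[2]][2, 1], 255L)   # 6 -> 255
  expect_identical(out[[1]][2, 1], 128L)   # midpoint 2 -> 127.5, half-up
  expect_true(all(vapply(out, function(m) all(m >= 0 & m <= 255), TRUE)))

  # a constant stack maps to zeros by policy
  const <- lapply(1:3, function(i) matrix(4.2, 3, 3))
  expect_true(all(vapply(stack_and_rescale(const),
                         function(m) all(m == 0L), TRUE)))

  # invariance under a common affine change (a > 0)
  bufs <- withr::with_seed(4, lapply(1:3, function(i) matrix(rnorm(12), 3, 4)))
  shifted <- lapply(bufs, function(b) 3.7 * b - 11)
  expect_identical(stack_and_rescale(bufs), stack_and_rescale(shifted))

  bad <- bufs; bad[[2]][1, 1] <- NaN
  expect_error(stack_and_rescale(bad), "finite")
})

test_that("colormap lookup is an exact per-pixel table indexing", {
  m8 <- matrix(as.integer(c(0, 128, 255, 40)), 2, 2)
  gr <- colorize(m8, "gray")
  for (ch in 1:3) expect_identical(gr[, , ch], m8)

  zero <- colorize(matrix(0L, 2, 3), "jet")
  tab <- colormap_table("jet")
  for (ch in 1:3) expect_true(all(zero[, , ch] == tab[1, ch]))

  # brute-force oracle over every pixel
  withr::with_seed(10, {
    m <- matrix(sample(0:255, 35, replace = TRUE), 5, 7)
    img <- colorize(m, "jet")
    for (i in 1:5) for (j in 1:7)
      expect_identical(img[i, j, ], unname(tab[m[i, j] + 1, ]))
  })

  expect_error(colorize(matrix(300L, 1, 1)), "\\[0, 255\\]")
  expect_error(colormap_table("sunset"))
})

test_that("bilinear resize hits the CNN input contract", {
  img <- array(as.integer(seq_len(100 * 400 * 3) %% 256), c(100, 400, 3))
  out <- resize_to_input(img)
  expect_identical(dim(out), c(227L, 227L, 3L))
  expect_true(all(out >= 0 & out <= 255))

  # constant images are invariant under interpolation
  const <- array(97L, c(227, 227, 3))
  expect_identical(resize_to_input(const), const)

  # upscaling a 2x2 checkerboard stays within the convex hull of the sources
  cb <- array(0L, c(2, 2, 3)); cb[1, 2, ] <- 200L; cb[2, 1, ] <- 200L
  up <- resize_to_input(cb, size = c(5L, 5L))
  expect_true(all(up >= 0 & up <= 200))
  expect_true(all(up[3, 3, ] > 0 & up[3, 3, ] < 200))  # interior is blended

  expect_error(resize_to_input(array(1, c(0, 3, 3))), "nonempty")
})

test_that("the full imaging path is byte-deterministic and well-shaped", {
  res <- subtract_background(simulate_session(ref_subject(), seed = 12))
  set1 <- fusion_image_set(res, id = "a1")
  set2 <- fusion_image_set(res, id = "a1")
  expect_identical(set1$images, set2$images)
  expect_length(set1$images, 3L)
  for (im in set1$images) {
    expect_identical(dim(im), c(227L, 227L, 3L))
    expect_true(all(im >= 0 & im <= 255))
  }
  expect_identical(set1$label$height, 164)

  # per-sensor normalisation is the documented alternative, not the default
  ps <- fusion_image_set(res, per_sensor = TRUE, id = "a1")
  expect_false(identical(ps$images, set1$images))

  # PNG export writes three lossless images plus the label sidecar
  d <- withr::local_tempdir()
  files <- write_imageset(set1, d)
  expect_length(list.files(d, pattern = "png$"), 3L)
  back <- png::readPNG(file.path(d, "ceiling.png"))
  expect_identical(as.integer(round(back * 255)),
                   as.integer(set1$images$ceiling))
})
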