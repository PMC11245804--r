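# Image export: rescale, linear VOI windowing, policies, resize/pad.

test_that("rescale transform is the elementwise linear map", {
  raw <- matrix(c(0L, 512L, 1024L, 2048L), 2, 2)
  expect_equal(rescale_pixels(raw, 1, 0), raw)            # identity
  expect_equal(rescale_pixels(matrix(1024L), 1, -1024)[1, 1], 0)
  expect_equal(rescale_pixels(raw, 2, 0), 2 * raw)        # linearity
  expect_error(rescale_pixels(raw, NA, 0), "not eligible")
})

test_that("windowing follows the linear VOI closed form with half-up rounding", {
  c0 <- 2048; w0 <- 4096
  expect_equal(window_to_8bit(matrix(-1e6), c0, w0)[1, 1], 0L)
  expect_equal(window_to_8bit(matrix(1e6), c0, w0)[1, 1], 255L)
  # x = center - 0.5 maps to the window midpoint 127.5 -> 128 half-up
  expect_equal(window_to_8bit(matrix(c0 - 0.5), c0, w0)[1, 1], 128L)
  # hand-computed interior pixels of the closed form
  xs <- c(500, 1000, 3000)
  manual <- as.integer(floor((((xs - (c0 - 0.5)) / (w0 - 1) + 0.5) * 255) + 0.5))
  expect_equal(as.vector(window_to_8bit(matrix(xs, 1), c0, w0)), manual)
  # constant input inside the window stays constant
  out <- window_to_8bit(matrix(1500, 3, 3), c0, w0)
  expect_equal(length(unique(as.vector(out))), 1L)
  expect_error(window_to_8bit(matrix(1), c0, 1), "not eligible")
  # photometric inversion flips the scale
  expect_equal(window_to_8bit(matrix(1e6), c0, w0, invert = TRUE)[1, 1], 0L)
})

test_that("value and shape policies reject degenerate images", {
  expect_false(value_policy(matrix(0L, 4, 4)))     # all black
  expect_false(value_policy(matrix(255L, 4, 4)))   # all white
  expect_true(value_policy(matrix(c(0L, 1L), 2, 2)))
  expect_false(shape_policy(1:16384))              # 1-D vector
  expect_true(shape_policy(matrix(0L, 512, 512)))
  expect_false(shape_policy(matrix(integer(0), 0, 128)))
})

test_that("resize preserves aspect ratio with centred zero padding", {
  img <- matrix(100L, 200, 100)
  out <- resize_pad(img, side = 128)
  expect_equal(dim(out$pixels), c(128, 128))
  expect_equal(unname(out$pad_box), c(0, 0, 32, 32))  # 128x64 content
  expect_true(all(out$pixels[, 1:32] == 0))
  expect_true(all(out$pixels[, 97:128] == 0))
  expect_true(all(out$pixels[, 33:96] > 0))

  same <- matrix(7L, 128, 128)
  expect_identical(resize_pad(same)$pixels, same)     # identity
  up <- resize_pad(matrix(c(0L, 50L, 100L, 200L), 64, 64), side = 128)
  expect_equal(unname(up$pad_box), rep(0L, 4))        # upscale, no padding
  # odd remainder lands bottom/right
  odd <- resize_pad(matrix(10L, 128, 127), side = 128)
  expect_equal(unname(odd$pad_box[c("left", "right")]), c(0L, 1L))
})

test_that("batch export enforces eligibility, policies and invariants", {
  ds <- small_dataset()
  exp <- export_images(ds, side = 64)
  expect_true(all(exp$manifest$kept))
  expect_equal(ncol(exp$images), 64^2)
  expect_true(all(exp$images >= 0 & exp$images <= 255))
  # no exported image is single-valued
  expect_true(all(apply(exp$images, 1, function(r) length(unique(r)) > 1)))

  # records failing eligibility are dropped with the reason recorded
  ds2 <- ds
  ds2$tags[[1]]$WindowWidth <- NULL
  ds2$tags[[2]]$WindowWidth <- 1      # width <= 1
  ds2$pixels[[3]] <- matrix(5L, 20, 20)
  ds2$pixels[[3]][] <- 5L             # constant after window -> value policy
  exp2 <- export_images(ds2, side = 64)
  m <- exp2$manifest
  expect_false(m$kept[1]); expect_false(m$eligible[1])
  expect_false(m$kept[2]); expect_false(m$eligible[2])
  expect_false(m$kept[3]); expect_false(m$value_ok[3])
  expect_true(all(m$kept[-(1:3)]))

  # determinism and idempotence: identity window on an exported image
  ex <- matrix(exp$images[1, ], 64, 64)
  again <- window_to_8bit(rescale_pixels(ex, 1, 0), 128, 256)
  expect_identical(again, matrix(as.integer(ex), 64, 64))
  expect_identical(resize_pad(again, 64)$pixels, matrix(as.integer(ex), 64, 64))
})
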