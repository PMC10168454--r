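test_that("image8 enforces its invariants", {
  expect_error(image8(matrix(0.5, 8, 8)), "integers")
  expect_error(image8(matrix(-1L, 8, 8)), "0, 255")
  expect_error(image8(matrix(300L, 8, 8)), "0, 255")
  expect_error(image8(matrix(0L, 4, 8)), "8x8")
  m <- matrix(NA_real_, 8, 8); m[] <- 1; m[3, 2] <- NaN
  expect_error(image8(m), "index 11")
  img <- image8(matrix(7L, 8, 8), id = "seven")
  expect_identical(img_id(img), "seven")
  expect_identical(dim(img), c(8L, 8L))
})

test_that("window_to_8bit maps the window edges and centre correctly", {
  win <- window_spec(level = 2048, width = 4096)
  raw <- matrix(2048, 8, 8)
  raw[1, 1] <- 0        # at WL - WW/2: lower clamp
  raw[1, 2] <- -500     # below: still 0
  raw[1, 3] <- 4096     # at WL + WW/2: upper clamp
  raw[1, 4] <- 9000     # above: still 255
  out <- window_to_8bit(raw, win)
  expect_equal(out[1, 1], 0)
  expect_equal(out[1, 2], 0)
  expect_equal(out[1, 3], 255)
  expect_equal(out[1, 4], 255)
  expect_equal(out[2, 2], 128)  # round(255 * 0.5), half away from zero
  expect_identical(dim(out), dim(raw))
})

test_that("window_to_8bit is monotone in the raw intensity", {
  for (s in 1:5) {
    win <- withr::with_seed(s, window_spec(runif(1, -100, 3000),
                                           runif(1, 1, 5000)))
    x <- sort(withr::with_seed(s, runif(64, -2000, 6000)))
    out <- window_to_8bit(matrix(x, 8, 8), win)
    expect_true(all(diff(as.vector(as.matrix(out))) >= 0))
  }
})

test_that("window_to_8bit rejects non-finite input, naming the index", {
  raw <- matrix(1, 8, 8); raw[5, 1] <- Inf
  expect_error(window_to_8bit(raw, window_spec(0, 1)), "index 5")
})

test_that("window_from_range recovers the full dynamic range", {
  raw <- matrix(seq(100, 612, length.out = 64), 8, 8)
  win <- window_from_range(raw)
  expect_equal(win$level, 356)
  expect_equal(win$width, 512)
  out <- window_to_8bit(raw, win)
  expect_equal(min(out), 0)
  expect_equal(max(out), 255)
  # constant input degenerates gracefully
  expect_equal(window_from_range(matrix(5, 8, 8))$width, 1)
})

test_that("inverted (bright = air) acquisitions can be windowed", {
  raw <- matrix(seq(0, 630, by = 10), 8, 8)
  win <- window_from_range(raw)
  straight <- window_to_8bit(raw, win)
  inverted <- window_to_8bit(raw, win, invert = TRUE)
  expect_equal(as.matrix(inverted), 255 - as.matrix(straight))
})

test_that("resize is the identity at the native side and on constants", {
  img <- rand_img(16, seed = 3)
  expect_identical(as.matrix(resize_image(img, 16)), as.matrix(img))
  const <- image8(matrix(77L, 32, 32), id = "c")
  for (side in c(8, 16, 31, 64)) {
    out <- resize_image(const, side)
    expect_true(all(as.matrix(out) == 77))
    expect_identical(dim(out), c(as.integer(side), as.integer(side)))
  }
  expect_error(resize_image(img, 4), ">= 8")
})

test_that("resize agrees with an independent bilinear oracle", {
  for (s in 1:5) {
    img <- rand_img(16, seed = s)
    for (side in c(8, 11, 24)) {
      ref <- reference_bilinear(as.matrix(img), side)
      got <- as.matrix(resize_image(img, side))
      want <- pmin(pmax(round_half_away(ref), 0), 255)
      if (side == 8) {
        # dyadic scale: interpolation weights are exact, so quantised
        # outputs match bit for bit
        expect_identical(got, matrix(as.integer(want), side, side))
      } else {
        # non-dyadic weights differ by floating-point association order;
        # interpolated values agree to 1e-9 and quantised values to 1 level
        expect_lte(max(abs(got - want)), 1)
        expect_equal(max(abs(adadetect:::bilinear_resample(
          as.matrix(img), side, side) - ref)), 0, tolerance = 1e-9)
      }
    }
  }
  # checkerboard downsample stays in range with the right dimensions
  cb <- image8(matrix(rep(c(0L, 255L), 128), 16, 16), id = "cb")
  small <- resize_image(cb, 8)
  expect_identical(dim(small), c(8L, 8L))
  expect_true(all(as.matrix(small) >= 0 & as.matrix(small) <= 255))
})

test_that("PNG write-then-read round-trips bit-identically", {
  img <- rand_img(16, seed = 9, id = "roundtrip")
  f <- withr::local_tempfile(fileext = ".png")
  write_image_png(img, f)
  back <- read_image_png(f, id = "roundtrip")
  expect_identical(as.matrix(back), as.matrix(img))
  expect_identical(img_id(back), "roundtrip")
})

test_that("read_image_png averages colour channels and names ids from files", {
  f <- withr::local_tempfile(fileext = ".png")
  g <- withr::local_tempfile(fileext = ".png")
  m <- matrix(runif(64), 8, 8)
  png::writePNG(array(rep(m, 3), dim = c(8, 8, 3)), f)  # equal channels
  png::writePNG(m, g)                                   # same data, gray
  got <- read_image_png(f)
  expect_identical(as.matrix(got), as.matrix(read_image_png(g)))
  expect_identical(img_id(got), sub("\\.png$", "", basename(f)))
})

test_that("read_image_png rejects missing files and 16-bit depth", {
  expect_error(read_image_png("does-not-exist.png"), "no such file")
  f <- withr::local_tempfile(fileext = ".png")
  write_png16(f)
  expect_error(read_image_png(f), "bit depth 16")
})
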