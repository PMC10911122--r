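test_that("grayscale conversion handles 1-, 3- and 4-channel rasters", {
  m <- matrix(sample(0:255, 12), 3, 4)
  expect_equal(unclass(to_grayscale(m)), matrix(as.integer(m), 3, 4),
                   ignore_attr = TRUE)
  arr1 <- array(m, dim = c(3, 4, 1))
  expect_equal(as.vector(to_grayscale(arr1)), as.vector(m))

  # equal channels pass through; pure red follows the Rec.601 weight
  rgb <- array(0, dim = c(1, 1, 3))
  rgb[1, 1, ] <- c(100, 100, 100)
  expect_equal(as.vector(to_grayscale(rgb)), 100)
  rgb[1, 1, ] <- c(255, 0, 0)
  expect_equal(as.vector(to_grayscale(rgb)), 76)

  rgba <- array(0, dim = c(2, 2, 4))
  rgba[, , 1:3] <- 50
  rgba[, , 4] <- 255   # alpha ignored
  expect_true(all(to_grayscale(rgba) == 50))

  bad <- array(300, dim = c(1, 1, 3))
  expect_error(to_grayscale(bad), "unsupported")
})

test_that("normalization maps extremes to [0, T] and rounds half away from zero", {
  img <- gray_image(matrix(c(10L, 110L, 210L), 1, 3))
  out <- normalize_image(img, T = 255)
  expect_equal(as.vector(out), c(0, 128, 255))  # midpoint 127.5 -> 128

  full <- gray_image(matrix(0:255, 16, 16))
  expect_equal(as.vector(normalize_image(full)), 0:255)

  expect_error(normalize_image(gray_image(matrix(5L, 2, 2))), "degenerate")
})

test_that("normalization is idempotent and order-preserving", {
  set.seed(42)
  for (i in 1:5) {
    img <- gray_image(matrix(sample(20:180, 60, replace = TRUE), 6, 10))
    once <- normalize_image(img)
    twice <- normalize_image(once)
    expect_identical(unclass(once), unclass(twice))
    o <- order(as.vector(img))
    expect_true(all(diff(as.vector(once)[o]) >= 0))
  }
})

test_that("global min-max normalization uses the supplied extremes", {
  img <- gray_image(matrix(c(50L, 100L), 1, 2))
  out <- normalize_image(img, T = 255, f_min = 0, f_max = 200)
  expect_equal(as.vector(out), c(64, 128))  # 255*50/200 = 63.75 -> 64
})

test_that("polygon rasterization follows the even-odd pixel-center rule", {
  sq <- roi_polygon(rbind(c(-0.5, -0.5), c(1.5, -0.5), c(1.5, 1.5),
                          c(-0.5, 1.5)))
  mask <- rasterize_roi(sq, 4, 4)
  expect_equal(sum(mask), 4)
  expect_true(all(mask[1:2, 1:2]))

  whole <- roi_polygon(rbind(c(-1, -1), c(4, -1), c(4, 4), c(-1, 4)))
  expect_true(all(rasterize_roi(whole, 4, 4)))

  flat <- roi_polygon(rbind(c(0, 0), c(1, 1), c(2, 2)))
  expect_error(rasterize_roi(flat, 4, 4), "empty mask")

  outside <- roi_polygon(rbind(c(10, 10), c(12, 10), c(12, 12)))
  expect_error(rasterize_roi(outside, 4, 4), "empty mask")
})

test_that("rasterized area of a square converges to its geometric area", {
  for (n in c(8, 32, 128)) {
    # square covering the central quarter of an n x n image
    a <- n / 4 - 0.5; b <- 3 * n / 4 - 0.5
    sq <- roi_polygon(rbind(c(a, a), c(b, a), c(b, b), c(a, b)))
    got <- sum(rasterize_roi(sq, n, n))
    expect_equal(got / (b - a)^2, 1, tolerance = 4 / n)
  }
})

test_that("sample extraction is row-major and length matches mask popcount", {
  img <- gray_image(matrix(1:4, 2, 2, byrow = TRUE))
  all_mask <- structure(matrix(TRUE, 2, 2), class = c("roi_mask", "matrix"))
  expect_equal(extract_sample(img, all_mask)$values, 1:4)
  diag_mask <- structure(diag(2) == 1, class = c("roi_mask", "matrix"))
  expect_equal(extract_sample(img, diag_mask)$values, c(1L, 4L))

  empty <- structure(matrix(FALSE, 2, 2), class = c("roi_mask", "matrix"))
  expect_error(extract_sample(img, empty), "empty mask")
  big <- gray_image(matrix(0L, 3, 3))
  expect_error(extract_sample(big, all_mask), "dimensions")

  set.seed(7)
  for (i in 1:5) {
    m <- matrix(runif(35) < 0.5, 5, 7)
    m[1, 1] <- TRUE
    msk <- structure(m, class = c("roi_mask", "matrix"))
    im <- gray_image(matrix(sample(0:255, 35, TRUE), 5, 7))
    expect_length(extract_sample(im, msk)$values, sum(m))
  }
})

test_that("PNG round-trip preserves 8-bit images and ROI JSON round-trips", {
  set.seed(11)
  img <- gray_image(matrix(sample(0:255, 80, TRUE), 8, 10))
  path <- withr::local_tempfile(fileext = ".png")
  write_gray_png(img, path)
  back <- read_gray_image(path)
  expect_equal(unclass(back), unclass(img), ignore_attr = TRUE)

  poly <- roi_polygon(rbind(c(0.5, 1.25), c(7, 0), c(6.5, 7.75)))
  jpath <- withr::local_tempfile(fileext = ".json")
  write_roi_json(poly, jpath)
  expect_equal(read_roi_json(jpath)$vertices, poly$vertices)
})
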