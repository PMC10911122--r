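# Image I/O, grayscale conversion, normalization, polygonal ROI masking.

#' Round half away from zero
#'
#' Rounds to the nearest integer with exact halves going away from zero,
#' the convention used by most bitmap-analysis software (base `round()`
#' rounds halves to even).
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @keywords internal
round_half_away <- function(x) {
  trunc(abs(x) + 0.5) * sign(x)
}

#' Construct a grayscale image
#'
#' A `gray_image` is an integer intensity matrix (rows = image rows, columns
#' = image columns) with values in `[0, L]`. `L = 255` corresponds to 8-bit
#' B-mode ultrasonograms, 0 absolute black and 255 absolute white.
#'
#' @param pixels numeric matrix of integer-valued intensities.
#' @param L maximum representable intensity (default 255).
#' @return a `gray_image`: an integer matrix with attribute `L`.
#' @export
gray_image <- function(pixels, L = 255L) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    stop("image must have at least one row and one column")
  }
  if (anyNA(pixels)) stop("image contains missing values")
  if (any(pixels != round(pixels))) stop("intensities must be integers")
  if (any(pixels < 0) || any(pixels > L)) {
    stop("intensities must lie in [0, ", L, "]")
  }
  storage.mode(pixels) <- "integer"
  structure(pixels, L = as.integer(L), class = c("gray_image", "matrix"))
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d, L = %d, range [%d, %d]>\n",
              nrow(x), ncol(x), attr(x, "L"), min(x), max(x)))
  invisible(x)
}

img_L <- function(img) {
  L <- attr(img, "L")
  if (is.null(L)) 255L else as.integer(L)
}

#' Convert a multi-channel raster to grayscale
#'
#' Single-channel input passes through unchanged. 3- and 4-channel input is
#' converted with Rec.601 luma weights (0.299 R + 0.587 G + 0.114 B), alpha
#' ignored, rounded half away from zero.
#'
#' @param raster a matrix (already grayscale) or an `h x w x c` array with
#'   `c` in 1, 3, 4; integer values in `[0, 255]`.
#' @return a [gray_image].
#' @export
to_grayscale <- function(raster) {
  if (is.matrix(raster)) return(gray_image(raster))
  if (!is.array(raster) || length(dim(raster)) != 3L) {
    stop("unsupported raster: expected a matrix or h x w x c array")
  }
  ch <- dim(raster)[3]
  chan <- function(k) matrix(raster[, , k], dim(raster)[1], dim(raster)[2])
  if (ch == 1L) return(gray_image(chan(1L)))
  if (!ch %in% c(3L, 4L)) {
    stop("unsupported channel count: ", ch, " (expected 1, 3 or 4)")
  }
  if (any(raster < 0) || any(raster > 255) || any(raster != round(raster))) {
    stop("unsupported format: channels must be 8-bit integers in [0, 255]")
  }
  luma <- 0.299 * chan(1L) + 0.587 * chan(2L) + 0.114 * chan(3L)
  gray_image(round_half_away(luma))
}

#' Read an 8-bit PNG or TIFF image as grayscale
#'
#' Multi-channel images are converted via [to_grayscale()]. Inputs with a
#' bit depth other than 8 per channel are rejected.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @return a [gray_image].
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    raw <- png::readPNG(path, info = TRUE)
    info <- attr(raw, "info")
    if (!is.null(info$bit.depth) && info$bit.depth != 8L) {
      stop("unsupported format: PNG bit depth ", info$bit.depth,
           " (8 required)")
    }
    vals <- round(raw * 255)
  } else if (ext %in% c("tif", "tiff")) {
    raw <- tiff::readTIFF(path, info = TRUE)
    bps <- attr(raw, "bits.per.sample")
    if (!is.null(bps) && any(bps != 8L)) {
      stop("unsupported format: TIFF bit depth ", paste(bps, collapse = ","),
           " (8 required)")
    }
    vals <- round(raw * 255)
  } else {
    stop("unsupported image format: .", ext, " (PNG or TIFF expected)")
  }
  attributes(vals) <- attributes(vals)["dim"]
  to_grayscale(vals)
}

#' Write a grayscale image as PNG
#'
#' @param img a [gray_image].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gray_png <- function(img, path) {
  L <- img_L(img)
  png::writePNG(unclass(img) / L, path)
  invisible(path)
}

#' Affine min-max normalization of a grayscale image
#'
#' Rescales intensities with `G_i = T * (f_i - f_min) / (f_max - f_min)`,
#' where `f_min`/`f_max` default to the per-image extremes, so the darkest
#' pixel maps to 0 and the brightest to `T`. Results are rounded half away
#' from zero and clamped to `[0, T]`. Supplying `f_min`/`f_max` (e.g.,
#' cohort-wide extremes) gives global scaling instead.
#'
#' Idempotent: a second pass with the same `T` is the identity, since after
#' the first pass the extremes are already 0 and `T`.
#'
#' @param img a [gray_image] with at least two distinct intensities.
#' @param T target ceiling (default 255).
#' @param f_min,f_max optional explicit input extremes for global scaling.
#' @return a [gray_image] with `L = T`.
#' @export
normalize_image <- function(img, T = 255L, f_min = NULL, f_max = NULL) {
  if (T < 1) stop("T must be >= 1")
  fmin <- if (is.null(f_min)) min(img) else f_min
  fmax <- if (is.null(f_max)) max(img) else f_max
  if (fmax <= fmin) {
    stop("degenerate image: f_max must exceed f_min (constant image?)")
  }
  g <- T * (unclass(img) - fmin) / (fmax - fmin)
  g <- pmin(pmax(round_half_away(g), 0), T)
  gray_image(g, L = as.integer(T))
}

#' Construct a polygonal region of interest
#'
#' Vertices are `(x, y)` pairs in pixel units, 0-based, with `x` the column
#' index and `y` the row index; the pixel at matrix position `(r, c)` has
#' its center at `(x = c - 1, y = r - 1)`.
#'
#' @param vertices an `n x 2` numeric matrix (or coercible) of `(x, y)`
#'   vertex coordinates, `n >= 3`, in drawing order.
#' @return an `roi_polygon`.
#' @export
roi_polygon <- function(vertices) {
  v <- as.matrix(vertices)
  if (ncol(v) != 2L) stop("vertices must be an n x 2 (x, y) matrix")
  if (nrow(v) < 3L) stop("a polygon needs at least 3 vertices")
  if (!all(is.finite(v))) stop("vertex coordinates must be finite")
  storage.mode(v) <- "double"
  colnames(v) <- c("x", "y")
  structure(list(vertices = v), class = "roi_polygon")
}

#' Read a polygonal ROI from JSON
#'
#' Expected dialect: `{"vertices": [[x, y], ...]}`.
#'
#' @param path path to a JSON file.
#' @return an [roi_polygon].
#' @export
read_roi_json <- function(path) {
  if (!file.exists(path)) stop("ROI file not found: ", path)
  obj <- jsonlite::fromJSON(path)
  if (is.null(obj$vertices)) stop("ROI JSON lacks a 'vertices' field")
  roi_polygon(obj$vertices)
}

#' Write a polygonal ROI to JSON
#'
#' @param poly an [roi_polygon].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_roi_json <- function(poly, path) {
  jsonlite::write_json(
    list(vertices = unname(poly$vertices)), path,
    digits = NA, auto_unbox = FALSE
  )
  invisible(path)
}

#' Rasterize a polygonal ROI to a boolean mask
#'
#' A pixel belongs to the mask iff its center satisfies the even-odd
#' (crossing-number) rule for the polygon. Centers lying exactly on an edge
#' are resolved by a consistent half-open rule — left/top edges inclusive —
#' implemented by testing the point nudged by +1e-7 in both coordinates.
#'
#' @param poly an [roi_polygon].
#' @param width,height image dimensions in pixels.
#' @return an `roi_mask`: a logical `height x width` matrix.
#' @export
rasterize_roi <- function(poly, width, height) {
  v <- poly$vertices
  n <- nrow(v)
  eps <- 1e-7
  px <- rep(seq_len(width) - 1L, each = height) + eps   # column-major grid
  py <- rep(seq_len(height) - 1L, times = width) + eps
  inside <- rep(FALSE, width * height)
  j <- n
  for (i in seq_len(n)) {
    x1 <- v[i, 1L]; y1 <- v[i, 2L]
    x2 <- v[j, 1L]; y2 <- v[j, 2L]
    crosses <- (y1 > py) != (y2 > py)
    if (any(crosses)) {
      xint <- x1 + (py[crosses] - y1) * (x2 - x1) / (y2 - y1)
      flip <- which(crosses)[px[crosses] < xint]
      inside[flip] <- !inside[flip]
    }
    j <- i
  }
  mask <- matrix(inside, nrow = height, ncol = width)
  if (!any(mask)) {
    stop("empty mask: polygon covers no pixel centers in the image")
  }
  structure(mask, class = c("roi_mask", "matrix"))
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask %d x %d, %d pixels inside>\n",
              nrow(x), ncol(x), sum(x)))
  invisible(x)
}

#' Extract the ROI pixel sample from an image
#'
#' Returns the intensities of all masked pixels in row-major order (scanning
#' each image row left to right, top row first).
#'
#' @param img a [gray_image].
#' @param mask an `roi_mask` with matching dimensions.
#' @param subject_id identifier attached to the sample (default `NA`).
#' @return a [pixel_sample].
#' @export
extract_sample <- function(img, mask, subject_id = NA_character_) {
  if (nrow(img) != nrow(mask) || ncol(img) != ncol(mask)) {
    stop("image and mask dimensions differ")
  }
  if (!any(mask)) stop("empty mask")
  vals <- t(unclass(img))[t(unclass(mask))]
  pixel_sample(vals, subject_id = subject_id, L = img_L(img))
}
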