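# First-order echotexture statistics: whole-ROI summaries, echointensity
# (EI) band statistics, and range means.

#' Construct a pixel sample
#'
#' The multiset of ROI pixel intensities for one subject — the atom every
#' statistic in the package is computed from.
#'
#' @param values integer intensities in `[0, L]`; nonempty.
#' @param subject_id subject identifier.
#' @param L intensity ceiling (default 255).
#' @return a `pixel_sample`: list with `subject_id`, `values`, `L`.
#' @export
pixel_sample <- function(values, subject_id = NA_character_, L = 255L) {
  values <- as.vector(values)
  if (length(values) == 0L) stop("empty pixel sample")
  if (anyNA(values)) stop("pixel sample contains missing values")
  if (any(values != round(values)) || any(values < 0) || any(values > L)) {
    stop("pixel values must be integers in [0, ", L, "]")
  }
  structure(
    list(subject_id = as.character(subject_id),
         values = as.integer(values), L = as.integer(L)),
    class = "pixel_sample"
  )
}

#' @export
print.pixel_sample <- function(x, ...) {
  cat(sprintf("<pixel_sample '%s': %d pixels in [%d, %d], L = %d>\n",
              x$subject_id, length(x$values), min(x$values), max(x$values),
              x$L))
  invisible(x)
}

as_pixel_values <- function(sample) {
  if (inherits(sample, "pixel_sample")) sample$values else as.integer(sample)
}

#' Population or sample standard deviation
#'
#' Bitmap-analysis software conventionally reports the population form
#' (denominator n); `type = "sample"` gives the n-1 form.
#'
#' @param x numeric vector.
#' @param type `"population"` (default) or `"sample"`.
#' @return standard deviation; 0 for a single value under `"population"`.
#' @keywords internal
sd_of <- function(x, type = c("population", "sample")) {
  type <- match.arg(type)
  n <- length(x)
  if (type == "population") {
    if (n == 1L) return(0)
    sqrt(sum((x - mean(x))^2) / n)
  } else {
    stats::sd(x)
  }
}

#' Whole-ROI first-order statistics
#'
#' Mean (NPV), standard deviation (heterogeneity), min, max and pixel count
#' of the full sample.
#'
#' @param sample a [pixel_sample] or integer vector.
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return one-row data.frame with `mean`, `sd`, `min`, `max`, `n`.
#' @export
whole_roi_stats <- function(sample, sd_type = "population") {
  v <- as_pixel_values(sample)
  if (length(v) == 0L) stop("empty pixel sample")
  data.frame(mean = mean(v), sd = sd_of(v, sd_type),
             min = min(v), max = max(v), n = length(v))
}

#' Construct an echointensity band specification
#'
#' An ordered list of inclusive integer intensity intervals `[lo, hi]`,
#' non-overlapping and sorted.
#'
#' @param lo,hi integer vectors of equal length with `0 <= lo <= hi <= L`.
#' @param L intensity ceiling (default 255).
#' @return a `band_spec`: data.frame with columns `lo`, `hi`.
#' @export
band_spec <- function(lo, hi, L = 255L) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (length(lo) != length(hi) || length(lo) == 0L) {
    stop("lo and hi must be nonempty vectors of equal length")
  }
  if (any(lo > hi)) stop("each band needs lo <= hi")
  if (any(lo < 0L) || any(hi > L)) stop("bands must lie within [0, ", L, "]")
  o <- order(lo)
  lo <- lo[o]; hi <- hi[o]
  if (length(lo) > 1L && any(lo[-1L] <= hi[-length(hi)])) {
    stop("bands must not overlap")
  }
  structure(data.frame(lo = lo, hi = hi),
            L = as.integer(L), class = c("band_spec", "data.frame"))
}

#' The 50-unit echointensity band preset
#'
#' Bands 0-50, 51-100, 101-150, 151-200, 201-255: an exhaustive partition
#' of the 8-bit intensity scale.
#'
#' @return a [band_spec].
#' @export
bands50 <- function() {
  band_spec(lo = c(0L, 51L, 101L, 151L, 201L),
            hi = c(50L, 100L, 150L, 200L, 255L))
}

#' The 25-unit echointensity band preset
#'
#' Bands 0-25, 26-50, 51-75, 76-100, 101-125, 126-150, 151-175, 176-200,
#' 201-225, 226-250, 251-255.
#'
#' @return a [band_spec].
#' @export
bands25 <- function() {
  band_spec(lo = c(0L, 26L, 51L, 76L, 101L, 126L, 151L, 176L, 201L, 226L, 251L),
            hi = c(25L, 50L, 75L, 100L, 125L, 150L, 175L, 200L, 225L, 250L, 255L))
}

#' Per-band first-order statistics of a pixel sample
#'
#' For each band: pixel count, EI% (percentage of the sample falling in the
#' band), NPV (mean of in-band intensities) and SD (heterogeneity). Bands
#' containing no pixels report `NA` (not zero) for NPV and SD; a single
#' in-band pixel has SD 0 under the population convention.
#'
#' @param sample a [pixel_sample] or integer vector.
#' @param spec a [band_spec].
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return data.frame with columns `band_lo`, `band_hi`, `n_pixels`,
#'   `ei_percent`, `npv`, `sd`.
#' @export
band_stats <- function(sample, spec, sd_type = "population") {
  v <- as_pixel_values(sample)
  if (length(v) == 0L) stop("empty pixel sample")
  stopifnot(inherits(spec, "band_spec"))
  n_total <- length(v)
  out <- lapply(seq_len(nrow(spec)), function(b) {
    inb <- v[v >= spec$lo[b] & v <= spec$hi[b]]
    nb <- length(inb)
    data.frame(
      band_lo = spec$lo[b], band_hi = spec$hi[b], n_pixels = nb,
      ei_percent = 100 * nb / n_total,
      npv = if (nb > 0L) mean(inb) else NA_real_,
      sd = if (nb > 0L) sd_of(inb, sd_type) else NA_real_
    )
  })
  do.call(rbind, out)
}

#' Mean intensity within a range
#'
#' Mean of sample values `v` with `lo <= v <= hi`; `NA` if the range
#' captures no pixel.
#'
#' @param sample a [pixel_sample] or integer vector.
#' @param lo,hi inclusive intensity bounds, `lo <= hi`.
#' @return scalar mean or `NA`.
#' @export
range_mean <- function(sample, lo, hi) {
  if (lo > hi) stop("lo must not exceed hi")
  v <- as_pixel_values(sample)
  inr <- v[v >= lo & v <= hi]
  if (length(inr) == 0L) NA_real_ else mean(inr)
}

#' Band statistics for a whole cohort
#'
#' One row per subject x band; empty bands propagate `NA` cells.
#'
#' @param cohort a [subject_cohort].
#' @param spec a [band_spec].
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return data.frame with columns `subject_id`, `group`, `band_lo`,
#'   `band_hi`, `n_pixels`, `ei_percent`, `npv`, `sd`.
#' @export
cohort_band_table <- function(cohort, spec, sd_type = "population") {
  stopifnot(inherits(cohort, "subject_cohort"))
  rows <- lapply(seq_along(cohort$subject_id), function(i) {
    bs <- band_stats(cohort$samples[[i]], spec, sd_type)
    cbind(data.frame(subject_id = cohort$subject_id[i],
                     group = cohort$group[i]),
          bs)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
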