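# Exhaustive contiguous intensity-range search: for each candidate range
# [lo, hi] the per-subject mean of in-range pixels is correlated with an
# external per-subject measurement; the range maximizing |r| is selected.
# Prefix tables over the intensity histogram make each range mean O(1), so
# the full search over all (L+1)(L+2)/2 ranges is O(L^2 * subjects).

#' Range admissibility constraints
#'
#' A range is evaluated for a subject only if the subject has at least
#' `min_pixels_per_subject` pixels in it; subjects below the floor are
#' excluded pairwise (or, in strict mode, the range is skipped entirely),
#' and a range is skipped if fewer than 3 subjects remain.
#'
#' @param min_pixels_per_subject minimum in-range pixels per subject
#'   (default 1).
#' @param min_width minimum range width in intensity units (default 1).
#' @param strict if TRUE, a range is admissible only when every subject
#'   meets the pixel floor (default FALSE: pairwise exclusion).
#' @return a `range_constraints` list.
#' @export
range_constraints <- function(min_pixels_per_subject = 1L, min_width = 1L,
                              strict = FALSE) {
  if (min_pixels_per_subject < 1L) stop("min_pixels_per_subject must be >= 1")
  if (min_width < 1L) stop("min_width must be >= 1")
  structure(list(min_pixels_per_subject = as.integer(min_pixels_per_subject),
                 min_width = as.integer(min_width),
                 strict = isTRUE(strict)),
            class = "range_constraints")
}

#' Enumerate all contiguous intensity ranges
#'
#' All integer intervals `0 <= lo <= hi <= L` with width `hi - lo + 1 >=
#' min_width`, ordered by `(lo, hi)`. With `min_width = 1` there are
#' `(L+1)(L+2)/2` of them (32,896 for L = 255).
#'
#' @param L intensity ceiling (>= 1).
#' @param min_width minimum width (default 1).
#' @return data.frame with columns `lo`, `hi`.
#' @export
enumerate_ranges <- function(L, min_width = 1L) {
  if (L < 1L) stop("L must be >= 1")
  lo <- rep.int(0:L, (L + 1L):1L)
  hi <- unlist(lapply(0:L, function(l) l:L), use.names = FALSE)
  keep <- (hi - lo + 1L) >= min_width
  data.frame(lo = lo[keep], hi = hi[keep])
}

#' Per-subject prefix tables over the intensity histogram
#'
#' For each subject, cumulative pixel counts, intensity sums and sums of
#' squares indexed by intensity, so that for any range `[lo, hi]` the
#' in-range count, sum (hence mean) and sum of squares are table
#' differences.
#'
#' @param cohort a [subject_cohort].
#' @return a `prefix_tables` list: `subject_id`, `L`, and per-subject
#'   cumulative vectors `count`, `sum`, `sumsq` of length `L + 2` (index
#'   `v + 2` holds the cumulative total over intensities `<= v`).
#' @export
build_prefix_tables <- function(cohort) {
  stopifnot(inherits(cohort, "subject_cohort"))
  L <- cohort$L
  vals <- 0:L
  per <- lapply(cohort$samples, function(v) {
    cnt <- tabulate(v + 1L, nbins = L + 1L)
    list(count = c(0, cumsum(cnt)),
         sum = c(0, cumsum(cnt * vals)),
         sumsq = c(0, cumsum(cnt * vals^2)))
  })
  structure(list(subject_id = cohort$subject_id, L = L, tables = per),
            class = "prefix_tables")
}

#' Query prefix tables for one range
#'
#' @param tables a `prefix_tables` object from [build_prefix_tables()].
#' @param lo,hi inclusive intensity bounds.
#' @return data.frame with `subject_id`, `n`, `sum`, `mean`, `sd`
#'   (population SD of in-range intensities; `mean`/`sd` are `NA` when the
#'   subject has no in-range pixel).
#' @export
query_range <- function(tables, lo, hi) {
  stopifnot(inherits(tables, "prefix_tables"))
  if (lo > hi) stop("lo must not exceed hi")
  i1 <- lo + 1L; i2 <- hi + 2L
  rows <- lapply(tables$tables, function(tb) {
    n <- tb$count[i2] - tb$count[i1]
    s <- tb$sum[i2] - tb$sum[i1]
    s2 <- tb$sumsq[i2] - tb$sumsq[i1]
    m <- if (n > 0) s / n else NA_real_
    sdv <- if (n > 0) sqrt(pmax(s2 / n - m^2, 0)) else NA_real_
    data.frame(n = n, sum = s, mean = m, sd = sdv)
  })
  out <- do.call(rbind, rows)
  cbind(data.frame(subject_id = tables$subject_id), out)
}

# Internal vectorized search engine shared by search_best_range() and the
# permutation test. Precomputes, for every enumerated range, the in-range
# pixel count and mean per subject, then evaluates the Pearson r of all
# ranges against one or many output vectors in a single pass.
range_engine <- function(cohort, constraints = range_constraints()) {
  tables <- build_prefix_tables(cohort)
  L <- cohort$L
  ranges <- enumerate_ranges(L, constraints$min_width)
  i1 <- ranges$lo + 1L
  i2 <- ranges$hi + 2L
  n_ranges_total <- nrow(ranges)
  nsub <- length(cohort$subject_id)

  N <- matrix(0, nrow(ranges), nsub)
  SUM <- matrix(0, nrow(ranges), nsub)
  for (s in seq_len(nsub)) {
    tb <- tables$tables[[s]]
    N[, s] <- tb$count[i2] - tb$count[i1]
    SUM[, s] <- tb$sum[i2] - tb$sum[i1]
  }
  A <- N >= constraints$min_pixels_per_subject
  if (constraints$strict) A[rowSums(A) < nsub, ] <- FALSE
  n_inc <- rowSums(A)
  M0 <- matrix(0, nrow(ranges), nsub)
  M0[A] <- SUM[A] / N[A]
  Sx <- rowSums(M0)
  Sxx <- rowSums(M0^2)
  denx <- n_inc * Sxx - Sx^2
  # keep only admissible ranges with >= 3 included subjects and nonzero
  # between-subject variance of range means (up to fp noise)
  keep <- which(n_inc >= 3L & denx > 1e-9 * pmax(Sxx, 1))
  ranges <- ranges[keep, , drop = FALSE]
  N <- N[keep, , drop = FALSE]
  A <- A[keep, , drop = FALSE]
  M0 <- M0[keep, , drop = FALSE]
  n_inc <- n_inc[keep]
  Sx <- Sx[keep]
  denx <- denx[keep]
  Ad <- A + 0  # double copy: avoids logical coercion in every %*%

  r_for <- function(Y) {
    Y <- as.matrix(Y)
    Sy <- Ad %*% Y
    Syy <- Ad %*% Y^2
    Sxy <- M0 %*% Y
    num <- n_inc * Sxy - Sx * Sy
    deny <- n_inc * Syy - Sy^2
    r <- num / sqrt(denx * deny)
    r[deny <= 1e-9 * pmax(Syy, 1)] <- NA_real_
    r
  }

  list(ranges = ranges, N = N, A = A, means = ifelse(A, M0, NA_real_),
       n_included = n_inc, n_ranges_total = n_ranges_total,
       tables = tables, r_for = r_for)
}

#' Search all contiguous intensity ranges for the strongest correlation
#'
#' Evaluates every admissible range `[lo, hi]` (see [range_constraints()]):
#' per-subject in-range mean pixel values are correlated (Pearson) with the
#' subjects' values of `marker`, and the range with the largest |r| is
#' returned. The selection objective is the correlation magnitude, since a
#' strong negative correlation is as informative as a positive one. Ties in
#' |r| (within `tie_tol`) are broken by smaller width, then smaller `lo`,
#' and the full tie set is reported.
#'
#' @param cohort a [subject_cohort] (>= 3 subjects with a value for
#'   `marker`; marker non-constant).
#' @param marker name of an output variable in `cohort$markers`.
#' @param constraints a [range_constraints] object.
#' @param tie_tol absolute tolerance on |r| for tie detection (default 1e-9).
#' @return a `range_search_result`: list with `marker`, `lo`, `hi`, `r`,
#'   `p_naive`, `per_subject` (data.frame subject_id, group, marker value,
#'   in-range n, mean, ei_percent, sd), `per_subject_means` (named vector,
#'   `NA` for excluded subjects), `n_subjects_used`, `n_ranges_evaluated`,
#'   `ties` (data.frame lo, hi, width, r), and `constraints`.
#' @export
search_best_range <- function(cohort, marker,
                              constraints = range_constraints(),
                              tie_tol = 1e-9) {
  stopifnot(inherits(cohort, "subject_cohort"))
  y <- cohort$markers[[marker]]
  if (is.null(y)) stop("unknown marker: ", marker)
  keep <- !is.na(y)
  if (sum(keep) < 3L) stop("fewer than 3 subjects with a value for ", marker)
  if (!all(keep)) {
    cohort <- subject_cohort(cohort$samples[keep], cohort$group[keep],
                             cohort$markers[keep, , drop = FALSE],
                             L = cohort$L)
    y <- y[keep]
  }
  if (stats::var(y) == 0) stop("constant marker: correlation undefined")

  eng <- range_engine(cohort, constraints)
  if (nrow(eng$ranges) == 0L) stop("no admissible range for marker ", marker)
  r <- pmin(pmax(as.vector(eng$r_for(y)), -1), 1)
  ok <- !is.na(r)
  if (!any(ok)) stop("no admissible range for marker ", marker)
  best_abs <- max(abs(r[ok]))
  tie_idx <- which(ok & abs(r) >= best_abs - tie_tol)
  ties <- data.frame(lo = eng$ranges$lo[tie_idx], hi = eng$ranges$hi[tie_idx],
                     r = r[tie_idx])
  ties$width <- ties$hi - ties$lo + 1L
  ties <- ties[order(ties$width, ties$lo), c("lo", "hi", "width", "r")]
  rownames(ties) <- NULL
  win <- tie_idx[order(eng$ranges$hi[tie_idx] - eng$ranges$lo[tie_idx],
                       eng$ranges$lo[tie_idx])][1L]
  lo <- eng$ranges$lo[win]; hi <- eng$ranges$hi[win]

  means <- eng$means[win, ]
  inc <- !is.na(means)
  cr <- pearson(means[inc], y[inc])
  qr <- query_range(eng$tables, lo, hi)
  per_subject <- data.frame(
    subject_id = cohort$subject_id, group = cohort$group, marker = y,
    n_in_range = qr$n,
    mean = ifelse(inc, means, NA_real_),
    ei_percent = 100 * qr$n / lengths(cohort$samples),
    sd = qr$sd
  )
  names(means) <- cohort$subject_id
  structure(
    list(marker = marker, lo = lo, hi = hi, r = cr$r,
         p_naive = cr$p_two_tailed,
         per_subject = per_subject, per_subject_means = means,
         n_subjects_used = sum(inc),
         n_ranges_evaluated = sum(ok), n_ranges_total = eng$n_ranges_total,
         ties = ties, constraints = constraints),
    class = "range_search_result"
  )
}

#' @export
print.range_search_result <- function(x, ...) {
  cat(sprintf(
    "Selected range [%d, %d] for '%s': r = %.4f, naive p = %.3g (n = %d)\n",
    x$lo, x$hi, x$marker, x$r, x$p_naive, x$n_subjects_used))
  cat(sprintf("%d of %d ranges evaluated; %d tie(s)\n",
              x$n_ranges_evaluated, x$n_ranges_total, nrow(x$ties)))
  invisible(x)
}

#' Greedy search for a scattered intensity set
#'
#' Exhaustive search over arbitrary subsets of intensities is infeasible
#' (2^(L+1) subsets), so a greedy forward selection is used. A singleton
#' set has a constant per-subject mean (the intensity itself), so its
#' correlation is undefined; the search therefore starts from the best
#' *pair* of intensities by |r| (found exhaustively over all pairs), then
#' repeatedly adds the intensity whose inclusion most increases |r|
#' (per-subject means recomputed over the union), until no addition
#' improves |r| by more than `tol` or `max_set_size` is reached. Ties are
#' broken toward the lower intensity; the greedy trace is returned so the
#' heuristic is auditable.
#'
#' @param cohort a [subject_cohort].
#' @param marker output-variable name.
#' @param constraints a [range_constraints]; the pixel floor applies to the
#'   union of selected intensities.
#' @param max_set_size maximum number of intensities (default 16).
#' @param tol minimum |r| improvement to continue (default 1e-9).
#' @return a `scattered_set_result`: list with `marker`, `intensities`
#'   (sorted), `r`, `p_naive`, `per_subject_means`, `trace` (data.frame
#'   step, intensity, r).
#' @export
search_scattered_set <- function(cohort, marker,
                                 constraints = range_constraints(),
                                 max_set_size = 16L, tol = 1e-9) {
  stopifnot(inherits(cohort, "subject_cohort"))
  y <- cohort$markers[[marker]]
  if (is.null(y)) stop("unknown marker: ", marker)
  if (stats::var(y, na.rm = TRUE) == 0) stop("constant marker")
  L <- cohort$L
  nsub <- length(cohort$subject_id)
  vals <- 0:L
  # per-intensity pixel counts and intensity sums, subjects x (L+1)
  CNT <- t(vapply(cohort$samples,
                  function(v) tabulate(v + 1L, nbins = L + 1L),
                  integer(L + 1L)))
  SUMV <- sweep(CNT, 2L, vals, `*`)

  abs_r_of <- function(count_mat, sum_mat) {
    # one column per candidate; returns |r| with NA for inadmissible columns
    A <- count_mat >= constraints$min_pixels_per_subject
    if (constraints$strict) A[, colSums(A) < nsub] <- FALSE
    n_inc <- colSums(A)
    M0 <- matrix(0, nsub, ncol(count_mat))
    M0[A] <- sum_mat[A] / count_mat[A]
    Sx <- colSums(M0); Sxx <- colSums(M0^2)
    Sy <- crossprod(A, y); Syy <- crossprod(A, y^2)
    Sxy <- crossprod(M0, y)
    denx <- n_inc * Sxx - Sx^2
    deny <- as.vector(n_inc * Syy - Sy^2)
    num <- as.vector(n_inc * Sxy - Sx * Sy)
    r <- num / sqrt(pmax(denx, 0) * pmax(deny, 0))
    r[n_inc < 3L | denx <= 1e-9 * pmax(Sxx, 1) |
        deny <= 1e-9 * pmax(as.vector(Syy), 1)] <- NA_real_
    abs(pmin(pmax(r, -1), 1))
  }

  if (max_set_size < 2L) stop("max_set_size must be at least 2")
  # step 1: exhaustive best pair (singleton means are constant)
  iv <- rep.int(0:(L - 1L), L:1L)
  iw <- unlist(lapply(0:(L - 1L), function(v) (v + 1L):L),
               use.names = FALSE)
  ar_pair <- abs_r_of(CNT[, iv + 1L, drop = FALSE] +
                        CNT[, iw + 1L, drop = FALSE],
                      SUMV[, iv + 1L, drop = FALSE] +
                        SUMV[, iw + 1L, drop = FALSE])
  if (all(is.na(ar_pair))) stop("no admissible intensity set for ", marker)
  kp <- which.max(ifelse(is.na(ar_pair), -Inf, ar_pair))
  selected <- c(iv[kp], iw[kp])
  cur_cnt <- CNT[, iv[kp] + 1L, drop = FALSE] +
    CNT[, iw[kp] + 1L, drop = FALSE]
  cur_sum <- SUMV[, iv[kp] + 1L, drop = FALSE] +
    SUMV[, iw[kp] + 1L, drop = FALSE]
  best_r <- ar_pair[kp]
  trace <- data.frame(step = c(1L, 1L), intensity = selected,
                      r = rep(best_r, 2L))
  repeat {
    if (length(selected) >= max_set_size) break
    cand <- setdiff(0:L, selected)
    ar <- abs_r_of(CNT[, cand + 1L, drop = FALSE] + as.vector(cur_cnt),
                   SUMV[, cand + 1L, drop = FALSE] + as.vector(cur_sum))
    if (all(is.na(ar))) break
    k <- which.max(ifelse(is.na(ar), -Inf, ar))  # ties -> lower intensity
    if (!(ar[k] > best_r + tol)) break
    v <- cand[k]
    selected <- c(selected, v)
    cur_cnt <- cur_cnt + CNT[, v + 1L, drop = FALSE]
    cur_sum <- cur_sum + SUMV[, v + 1L, drop = FALSE]
    best_r <- ar[k]
    trace <- rbind(trace,
                   data.frame(step = length(selected) - 1L, intensity = v,
                              r = ar[k]))
  }

  A <- as.vector(cur_cnt) >= constraints$min_pixels_per_subject
  means <- ifelse(A, as.vector(cur_sum) / as.vector(cur_cnt), NA_real_)
  names(means) <- cohort$subject_id
  cr <- pearson(means[A], y[A])
  structure(
    list(marker = marker, intensities = sort(selected), r = cr$r,
         p_naive = cr$p_two_tailed, per_subject_means = means,
         trace = trace),
    class = "scattered_set_result"
  )
}

#' @export
print.scattered_set_result <- function(x, ...) {
  cat(sprintf(
    "Scattered set {%s} for '%s': r = %.4f, naive p = %.3g (%d steps)\n",
    paste(x$intensities, collapse = ", "), x$marker, x$r, x$p_naive,
    nrow(x$trace)))
  invisible(x)
}

#' Threshold map of an intensity range
#'
#' Marks the spatial locations of the masked pixels whose intensity lies in
#' `[lo, hi]` — the spatial counterpart of the range statistics.
#'
#' @param img a [gray_image].
#' @param mask an `roi_mask` of matching dimensions.
#' @param lo,hi inclusive intensity bounds, `lo <= hi`.
#' @return a `threshold_map`: list with `overlay` (logical matrix, TRUE at
#'   in-range masked pixels), `coords` (data.frame `x`, `y`, `value`;
#'   0-based x = column, y = row), `lo`, `hi`, `n_marked`.
#' @export
threshold_map <- function(img, mask, lo, hi) {
  if (lo > hi) stop("lo must not exceed hi")
  if (nrow(img) != nrow(mask) || ncol(img) != ncol(mask)) {
    stop("image and mask dimensions differ")
  }
  if (!any(mask)) stop("empty mask")
  overlay <- unclass(mask) & unclass(img) >= lo & unclass(img) <= hi
  idx <- which(overlay, arr.ind = TRUE)
  coords <- data.frame(x = idx[, "col"] - 1L, y = idx[, "row"] - 1L,
                       value = unclass(img)[idx])
  coords <- coords[order(coords$y, coords$x), ]
  rownames(coords) <- NULL
  structure(list(overlay = overlay, coords = coords, lo = lo, hi = hi,
                 n_marked = nrow(coords)),
            class = "threshold_map")
}

#' Write a threshold-map overlay as PNG
#'
#' The grayscale image is rendered with in-range masked pixels highlighted
#' in red.
#'
#' @param img a [gray_image].
#' @param map a `threshold_map` from [threshold_map()].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_threshold_png <- function(img, map, path) {
  L <- img_L(img)
  g <- unclass(img) / L
  rgb <- array(rep(g, 3L), dim = c(nrow(img), ncol(img), 3L))
  m <- map$overlay
  rgb[, , 1L][m] <- 1
  rgb[, , 2L][m] <- 0
  rgb[, , 3L][m] <- 0
  png::writePNG(rgb, path)
  invisible(path)
}
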