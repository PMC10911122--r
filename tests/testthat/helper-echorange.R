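# Shared fixtures and independent oracles for the test suite.

# random cohort of integer pixel samples with an unrelated marker
make_test_cohort <- function(seed, n_subjects = 10, n_pixels = 500, L = 31,
                             n_markers = 1) {
  set.seed(seed)
  samples <- lapply(seq_len(n_subjects), function(i) {
    sample(0:L, n_pixels, replace = TRUE,
           prob = stats::dgamma(0:L, shape = 2, scale = L / 6) + 1e-3)
  })
  names(samples) <- sprintf("s%02d", seq_len(n_subjects))
  markers <- as.data.frame(stats::setNames(
    lapply(seq_len(n_markers), function(k) stats::rnorm(n_subjects)),
    paste0("m", seq_len(n_markers))))
  subject_cohort(samples, rep(c("a", "b"), length.out = n_subjects),
                 markers, L = L)
}

# brute-force range search: recomputes every range mean from scratch;
# independent of the prefix-table engine
brute_search <- function(cohort, marker, constraints = range_constraints(),
                         tie_tol = 1e-9) {
  y0 <- cohort$markers[[marker]]
  L <- cohort$L
  rows <- list()
  for (lo in 0:L) for (hi in lo:L) {
    if (hi - lo + 1 < constraints$min_width) next
    means <- vapply(cohort$samples, function(v) {
      x <- v[v >= lo & v <= hi]
      if (length(x) >= constraints$min_pixels_per_subject) mean(x)
      else NA_real_
    }, numeric(1))
    inc <- !is.na(means)
    if (constraints$strict && !all(inc)) next
    if (sum(inc) < 3) next
    x <- means[inc]; y <- y0[inc]
    if (stats::var(x) == 0 || stats::var(y) == 0) next
    rows[[length(rows) + 1]] <- c(lo, hi, stats::cor(x, y))
  }
  m <- do.call(rbind, rows)
  best_abs <- max(abs(m[, 3]))
  t <- m[abs(m[, 3]) >= best_abs - tie_tol, , drop = FALSE]
  o <- order(t[, 2] - t[, 1], t[, 1])
  list(lo = t[o[1], 1], hi = t[o[1], 2], r = t[o[1], 3])
}

# Jaccard overlap of two inclusive integer intervals
jaccard_range <- function(a, b) {
  inter <- max(0, min(a[2], b[2]) - max(a[1], b[1]) + 1)
  inter / ((a[2] - a[1] + 1) + (b[2] - b[1] + 1) - inter)
}

# constraints recommended for recovery analyses: every subject must support
# the range with enough pixels for a stable mean
recovery_constraints <- function() {
  range_constraints(min_pixels_per_subject = 25, strict = TRUE)
}
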