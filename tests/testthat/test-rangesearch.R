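test_that("range enumeration is complete, ordered and width-filtered", {
  r255 <- enumerate_ranges(255)
  expect_equal(nrow(r255), 32896)  # 256 * 257 / 2
  expect_true(all(r255$lo <= r255$hi))
  expect_true(!is.unsorted(r255$lo))

  r1 <- enumerate_ranges(1)
  expect_equal(r1, data.frame(lo = c(0L, 0L, 1L), hi = c(0L, 1L, 1L)))

  expect_equal(nrow(enumerate_ranges(255, min_width = 256)), 1)
  expect_equal(unlist(enumerate_ranges(255, min_width = 256)),
               c(lo = 0L, hi = 255L))
})

test_that("prefix tables answer range queries exactly", {
  samples <- list(a = c(3L, 3L, 7L), b = c(0L, 5L, 9L), c = c(1L, 1L, 1L))
  co <- subject_cohort(samples, c("g1", "g1", "g2"),
                       data.frame(m = c(1, 2, 3)), L = 9L)
  tb <- build_prefix_tables(co)

  q <- query_range(tb, 0, 3)
  expect_equal(q$n[1], 2)
  expect_equal(q$sum[1], 6)
  expect_equal(q$mean[1], 3)

  q <- query_range(tb, 0, 9)
  expect_equal(q$n, lengths(samples), ignore_attr = TRUE)
  expect_equal(q$mean, sapply(samples, mean), ignore_attr = TRUE)

  q <- query_range(tb, 4, 6)
  expect_equal(q$n[1], 0)
  expect_true(is.na(q$mean[1]))
  expect_equal(q$n[2], 1)
  expect_equal(q$mean[2], 5)
})

test_that("search matches the planted perfect-correlation range", {
  # marker equals each subject's mean over [3, 7] exactly, so that range
  # attains r = 1; brute force confirms the selected optimum
  set.seed(12)
  samples <- lapply(1:10, function(i) sample(0:9, 120, replace = TRUE))
  names(samples) <- paste0("s", 1:10)
  mk <- sapply(samples, function(v) mean(v[v >= 3 & v <= 7]))
  co <- subject_cohort(samples, rep(c("sham", "surgery"), 5),
                       data.frame(m = mk), L = 9L)
  res <- search_best_range(co, "m")
  bf <- brute_search(co, "m")
  expect_equal(c(res$lo, res$hi), c(bf$lo, bf$hi))
  expect_equal(c(res$lo, res$hi), c(3, 7))
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_equal(res$r, bf$r, tolerance = 1e-12)
  # the reported r is exactly pearson() on the per-subject means
  pm <- res$per_subject_means
  expect_equal(res$r, pearson(pm[!is.na(pm)], mk[!is.na(pm)])$r)
})

test_that("a single admissible range is returned regardless of its r", {
  # every subject's pixels sit at 0 and L only, and the per-subject floor
  # equals the sample size, so [0, L] is the only admissible range
  set.seed(5)
  samples <- lapply(1:5, function(i) {
    c(rep(0L, 10 + i), rep(9L, 20 - i))
  })
  names(samples) <- paste0("s", 1:5)
  co <- subject_cohort(samples, rep(c("a", "b"), length.out = 5),
                       data.frame(m = rnorm(5)), L = 9L)
  res <- search_best_range(co, "m",
                           range_constraints(min_pixels_per_subject = 30))
  expect_equal(c(res$lo, res$hi), c(0, 9))
  expect_equal(res$n_ranges_evaluated, 1)

  expect_error(
    search_best_range(co, "m",
                      range_constraints(min_pixels_per_subject = 31)),
    "no admissible range")
  co2 <- subject_cohort(samples, rep(c("a", "b"), length.out = 5),
                        data.frame(m = rep(1, 5)), L = 9L)
  expect_error(search_best_range(co2, "m"), "constant marker")
})

test_that("prefix-table search equals brute-force recomputation across seeds", {
  for (seed in 1:6) {
    co <- make_test_cohort(seed, n_subjects = 8, n_pixels = 200, L = 15)
    res <- search_best_range(co, "m1")
    bf <- brute_search(co, "m1")
    expect_equal(c(res$lo, res$hi), c(bf$lo, bf$hi),
                 info = paste("seed", seed))
    expect_equal(res$r, bf$r, tolerance = 1e-12)
  }
  # and under strict admissibility with a pixel floor
  for (seed in 7:9) {
    co <- make_test_cohort(seed, n_subjects = 8, n_pixels = 200, L = 15)
    cn <- range_constraints(min_pixels_per_subject = 5, strict = TRUE)
    res <- search_best_range(co, "m1", cn)
    bf <- brute_search(co, "m1", cn)
    expect_equal(c(res$lo, res$hi), c(bf$lo, bf$hi))
    expect_equal(res$r, bf$r, tolerance = 1e-12)
  }
})

test_that("per-subject range means stay within the selected bounds", {
  for (seed in 1:4) {
    co <- make_test_cohort(seed, n_subjects = 6, n_pixels = 150, L = 31)
    res <- search_best_range(co, "m1")
    pm <- res$per_subject_means
    expect_true(all(pm[!is.na(pm)] >= res$lo & pm[!is.na(pm)] <= res$hi))
  }
})

test_that("search is deterministic, including the tie list", {
  co <- make_test_cohort(77, n_subjects = 8, n_pixels = 100, L = 15)
  a <- search_best_range(co, "m1")
  b <- search_best_range(co, "m1")
  expect_identical(a[c("lo", "hi", "r", "p_naive", "ties")],
                   b[c("lo", "hi", "r", "p_naive", "ties")])
  expect_equal(a$per_subject_means, b$per_subject_means)
})

test_that("scattered-set search recovers a planted two-intensity signal", {
  # marker equals each subject's mean over the union {40, 90}; exhaustive
  # pair search (the greedy first step) must find it
  set.seed(60)
  samples <- lapply(1:10, function(i) {
    n40 <- sample(30:90, 1)
    c(rep(40L, n40), rep(90L, 120 - n40),
      sample(setdiff(0:99, c(40L, 90L)), 200, replace = TRUE))
  })
  names(samples) <- paste0("s", 1:10)
  mk <- sapply(samples, function(v) mean(v[v %in% c(40L, 90L)]))
  co <- subject_cohort(samples, rep(c("a", "b"), 5), data.frame(m = mk),
                       L = 99L)
  res <- search_scattered_set(co, "m", max_set_size = 4)
  expect_true(all(c(40, 90) %in% res$intensities))
  expect_equal(res$r, 1, tolerance = 1e-9)

  # oracle: exhaustive search over all 2-element subsets
  best <- c(-1, NA, NA)
  for (v in 0:98) for (w in (v + 1):99) {
    means <- sapply(samples, function(px) {
      x <- px[px == v | px == w]
      if (length(x) >= 1) mean(x) else NA_real_
    })
    inc <- !is.na(means)
    if (sum(inc) < 3 || var(means[inc]) == 0) next
    rr <- abs(cor(means[inc], mk[inc]))
    if (!is.na(rr) && rr > best[1]) best <- c(rr, v, w)
  }
  expect_equal(best[2:3], c(40, 90))
  expect_equal(sort(res$trace$intensity[res$trace$step == 1]), c(40, 90))

  co_const <- subject_cohort(samples, rep(c("a", "b"), 5),
                             data.frame(m = rep(1, 10)), L = 99L)
  expect_error(search_scattered_set(co_const, "m"), "constant marker")
})

test_that("threshold maps mark exactly the in-range masked pixels", {
  img <- gray_image(matrix(1:9, 3, 3, byrow = TRUE), L = 255L)
  mask <- structure(matrix(TRUE, 3, 3), class = c("roi_mask", "matrix"))
  tm <- threshold_map(img, mask, 4, 6)
  expect_equal(tm$n_marked, 3)
  expect_equal(sort(tm$coords$value), 4:6)

  full <- threshold_map(img, mask, 0, 255)
  expect_equal(full$overlay, unclass(mask), ignore_attr = TRUE)

  none <- threshold_map(img, mask, 200, 210)
  expect_equal(none$n_marked, 0)

  co <- subject_cohort(list(s1 = as.vector(t(unclass(img))),
                            s2 = 1:9, s3 = 2:10),
                       c("a", "b", "a"),
                       data.frame(m = c(1, 2, 3)), L = 255L)
  tb <- build_prefix_tables(co)
  expect_equal(threshold_map(img, mask, 4, 6)$n_marked,
               query_range(tb, 4, 6)$n[1])
})
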