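test_that("pearson handles perfect correlation and degenerate input", {
  expect_equal(pearson(c(1, 2, 3), c(2, 4, 6))$r, 1)
  expect_equal(pearson(c(1, 2, 3), c(2, 4, 6))$p_two_tailed, 0)
  expect_equal(pearson(c(1, 2, 3), c(3, 2, 1))$r, -1)
  expect_error(pearson(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson(1:4, 1:3), "equal length")
  expect_error(pearson(1:2, 2:1), "at least 3")
})

test_that("pearson p for r = 0.94 at n = 12 matches a t-density integration", {
  # independent oracle: numerically integrate the t(n-2) density tail
  t_tail <- function(t, df) {
    dens <- function(x) {
      gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
        (1 + x^2 / df)^(-(df + 1) / 2)
    }
    stats::integrate(dens, t, Inf, rel.tol = 1e-12)$value
  }
  r <- 0.94; n <- 12
  oracle_p <- 2 * t_tail(r * sqrt(n - 2) / sqrt(1 - r^2), n - 2)
  expect_equal(oracle_p, 5.5e-6, tolerance = 0.05)

  # construct a sample whose correlation is exactly 0.94, then compare the
  # implementation's p against the oracle to 3 significant figures
  set.seed(8)
  x <- rnorm(n)
  e <- resid(lm(rnorm(n) ~ x))
  xs <- scale(x)[, 1]
  es <- e / sqrt(sum(e^2) / (n - 1))
  y <- r * xs + sqrt(1 - r^2) * es
  cr <- pearson(x, y)
  expect_equal(cr$r, r, tolerance = 1e-12)
  expect_equal(cr$p_two_tailed, oracle_p, tolerance = 1e-3)
})

test_that("pearson is affine-invariant and p decreases in |r|", {
  set.seed(4)
  x <- rnorm(10); y <- rnorm(10)
  base <- pearson(x, y)
  expect_equal(pearson(3 * x + 7, y)$r, base$r)
  expect_equal(pearson(x, -2 * y + 1)$r, -base$r)
  expect_equal(pearson(x, x)$r, 1)

  n <- 12
  rs <- c(0.1, 0.3, 0.5, 0.7, 0.9, 0.99)
  ps <- sapply(rs, function(r) 2 * pt(-r * sqrt(n - 2) / sqrt(1 - r^2),
                                      n - 2))
  expect_true(all(diff(ps) < 0))
})

test_that("Student t-test matches hand-computed pooled-variance results", {
  same <- student_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_two_tailed, 1)

  expect_error(student_t_test(rep(0, 4), rep(1, 4)), "zero pooled variance")

  a <- c(1, 2, 3, 4); b <- c(3, 4, 5, 6)
  got <- student_t_test(a, b)
  # independent hand computation of the pooled-variance statistic
  sp2 <- (3 * var(a) + 3 * var(b)) / 6
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  p_hand <- 2 * pt(-abs(t_hand), df = 6)
  expect_equal(got$t_statistic, t_hand, tolerance = 1e-12)
  expect_equal(got$t_statistic, -2.19089023, tolerance = 1e-6)
  expect_equal(got$p_two_tailed, p_hand, tolerance = 1e-12)
  expect_equal(got$p_two_tailed, 0.0709, tolerance = 2e-3)
  expect_equal(got$df, 6)
  expect_equal(got$sem_a, sd(a) / 2)
})

test_that("SEM is the sample SD over sqrt(n)", {
  expect_equal(sem(c(5, 5, 5)), 0)
  expect_equal(sem(c(0, 2)), 1)
  expect_equal(sem(c(1, 2, 3, 4)), sqrt(5 / 3) / 2)
  expect_equal(sem(c(1, 2, 3, 4)), 0.6455, tolerance = 1e-4)
  expect_error(sem(3), "at least 2")
})

test_that("permutation test reaches its lower bound for an unmatchable maximum", {
  # marker exactly equals each subject's full-range mean: observed |r| = 1;
  # with 8 distinct subjects no permutation of a generic marker is collinear
  set.seed(31)
  samples <- lapply(1:8, function(i) sample(0:15, 50, replace = TRUE))
  names(samples) <- paste0("s", 1:8)
  mu <- sapply(samples, mean)
  co <- subject_cohort(samples, rep(c("a", "b"), 4), data.frame(M = mu),
                       L = 15L)
  pt <- max_r_permutation_test(co, "M", range_constraints(), n_perm = 99,
                               seed = 2)
  expect_equal(pt$observed_abs_r, 1, tolerance = 1e-12)
  expect_equal(pt$p_fwe, 1 / 100)

  co2 <- subject_cohort(samples, rep(c("a", "b"), 4),
                        data.frame(M = rep(2, 8)), L = 15L)
  expect_error(max_r_permutation_test(co2, "M", n_perm = 99, seed = 1),
               "constant marker")
})

test_that("permutation p-values are approximately uniform on null cohorts", {
  set.seed(90)
  ps <- sapply(1:120, function(i) {
    samples <- lapply(1:8, function(s) sample(0:15, 120, replace = TRUE))
    names(samples) <- paste0("s", 1:8)
    co <- subject_cohort(samples, rep(c("a", "b"), 4),
                         data.frame(M = rnorm(8)), L = 15L)
    max_r_permutation_test(co, "M", n_perm = 99, seed = i)$p_fwe
  })
  # p lives on the grid k/100; smear each value across its own cell so the
  # KS statistic compares a genuinely continuous sample against U(0, 1)
  smeared <- ps - runif(length(ps)) / 100
  expect_gt(stats::ks.test(smeared, "punif")$p.value, 0.01)
})
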