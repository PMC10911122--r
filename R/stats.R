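# Statistical kernels: Pearson product-moment correlation, pooled-variance
# Student t-test, SEM, and the permutation test for a searched maximum |r|.

#' Pearson product-moment correlation with two-tailed p
#'
#' `r` is the standard product-moment coefficient; the p-value comes from
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` referred to a t distribution with
#' `n - 2` degrees of freedom, two-tailed. Perfect correlation (|r| = 1)
#' reports p = 0.
#'
#' @param x,y numeric vectors of equal length `n >= 3`, each with nonzero
#'   variance.
#' @return a `correlation_result`: list with `r`, `p_two_tailed`, `n`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed; drop pairs first")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("undefined correlation: zero variance")
  }
  r <- stats::cor(x, y)
  r <- max(-1, min(1, r))
  p <- if (abs(r) >= 1) 0 else {
    tval <- r * sqrt(n - 2) / sqrt(1 - r^2)
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  structure(list(r = r, p_two_tailed = p, n = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.4f, p (two-tailed) = %.3g, n = %d\n",
              x$r, x$p_two_tailed, x$n))
  invisible(x)
}

#' Two-sample Student t-test (pooled variance)
#'
#' Classical two-sided Student t with `n_a + n_b - 2` degrees of freedom and
#' pooled variance; per-group means and SEMs are reported alongside. Welch's
#' unequal-variance form is available with `welch = TRUE`.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param welch use the Welch correction instead of pooling (default FALSE).
#' @return a `group_comparison`: list with `mean_a`, `mean_b`, `sem_a`,
#'   `sem_b`, `t_statistic`, `p_two_tailed`, `df`, `n_a`, `n_b`.
#' @export
student_t_test <- function(a, b, welch = FALSE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) stop("each group needs n >= 2")
  if (!welch && stats::var(a) == 0 && stats::var(b) == 0) {
    stop("degenerate test: zero pooled variance")
  }
  tt <- stats::t.test(a, b, var.equal = !welch)
  structure(
    list(mean_a = mean(a), mean_b = mean(b),
         sem_a = sem(a), sem_b = sem(b),
         t_statistic = unname(tt$statistic),
         p_two_tailed = tt$p.value, df = unname(tt$parameter),
         n_a = length(a), n_b = length(b)),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "group A: %.4g +/- %.4g (n=%d); group B: %.4g +/- %.4g (n=%d)\n",
    x$mean_a, x$sem_a, x$n_a, x$mean_b, x$sem_b, x$n_b))
  cat(sprintf("Student t = %.4f (df %g), p (two-tailed) = %.3g\n",
              x$t_statistic, x$df, x$p_two_tailed))
  invisible(x)
}

#' Standard error of the mean
#'
#' Sample standard deviation (n-1 denominator) divided by `sqrt(n)`.
#'
#' @param values numeric vector, length >= 2.
#' @return scalar SEM.
#' @export
sem <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2L) stop("SEM needs at least 2 values")
  stats::sd(values) / sqrt(n)
}

#' Permutation test for the searched maximum correlation
#'
#' The naive Pearson p of a range selected by maximizing |r| over tens of
#' thousands of candidate ranges is anti-conservative. This test permutes
#' the output variable across subjects, reruns the full range search on each
#' permutation, and reports the family-wise
#' `p = (1 + #\{max |r|_perm >= max |r|_obs\}) / (n_perm + 1)`.
#'
#' @param cohort a [subject_cohort].
#' @param marker marker (output-variable) name in `cohort$markers`.
#' @param constraints a [range_constraints] object.
#' @param n_perm number of permutations (>= 99; default 999).
#' @param seed integer seed for the permutation stream.
#' @return list with `p_fwe`, `observed_abs_r`, `perm_abs_r` (vector),
#'   `n_perm`.
#' @export
max_r_permutation_test <- function(cohort, marker,
                                   constraints = range_constraints(),
                                   n_perm = 999L, seed = 1L) {
  stopifnot(inherits(cohort, "subject_cohort"))
  if (n_perm < 99L) stop("n_perm must be at least 99")
  n <- length(cohort$subject_id)
  if (n < 3L) stop("fewer than 3 subjects")
  y <- cohort$markers[[marker]]
  if (is.null(y)) stop("unknown marker: ", marker)
  if (stats::var(y) == 0) stop("undefined correlation: constant marker")

  eng <- range_engine(cohort, constraints)
  if (nrow(eng$ranges) == 0L) stop("no admissible range for marker ", marker)
  obs <- suppressWarnings(max(abs(eng$r_for(y)), na.rm = TRUE))
  if (!is.finite(obs)) stop("no admissible range for marker ", marker)

  set.seed(seed)
  yperm <- replicate(n_perm, sample(y))
  perm_max <- suppressWarnings(
    apply(abs(eng$r_for(yperm)), 2L, max, na.rm = TRUE)
  )
  p <- (1 + sum(perm_max >= obs)) / (n_perm + 1)
  list(p_fwe = p, observed_abs_r = obs, perm_abs_r = perm_max,
       n_perm = as.integer(n_perm))
}
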