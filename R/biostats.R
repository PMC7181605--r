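# Validation and association statistics for morphometric fibrosis scores:
# one-way random-effects single-rater ICC with F-based confidence bounds,
# Fisher-z Pearson intervals, paired location tests, simple least squares,
# and the simulators needed to exercise them.

#' Assemble a paired-ratings table
#'
#' @param values n x k numeric matrix (subjects x raters/repeats), no
#'   missing cells.
#' @param subject_ids optional subject identifiers.
#' @return A `paired_ratings` object.
#' @export
paired_ratings <- function(values, subject_ids = NULL) {
  values <- as.matrix(values)
  if (nrow(values) < 3L || ncol(values) < 2L)
    fq_error("fq_precondition_error", "need n >= 3 subjects and k >= 2 ratings")
  if (anyNA(values))
    fq_error("fq_precondition_error",
             "missing cells not allowed; drop incomplete subjects upstream")
  if (is.null(subject_ids)) subject_ids <- paste0("S", seq_len(nrow(values)))
  structure(list(subject_ids = as.character(subject_ids),
                 values = unname(values)),
            class = "paired_ratings")
}

#' One-way random-effects single-rater ICC with F-based 95% CI
#'
#' ICC(1,1): each subject's k ratings share only a subject effect. The
#' estimate is `(MSB - MSW) / (MSB + (k-1) MSW)` from the one-way ANOVA
#' decomposition; confidence bounds come from the F statistic
#' `F = MSB/MSW` with `df1 = n-1`, `df2 = n(k-1)`:
#' `F_L = F / qF(1-a/2; df1, df2)`, `F_U = F * qF(1-a/2; df2, df1)`, each
#' mapped through `rho = (F* - 1)/(F* + k - 1)`. The p-value is the upper
#' F tail under `rho = 0`.
#'
#' @param ratings a [paired_ratings()] (or n x k matrix).
#' @param alpha two-sided confidence level complement (default 0.05).
#' @return An `icc_result` with estimate, ci bounds, F statistic, dfs,
#'   p-value, n, k.
#' @export
icc_oneway <- function(ratings, alpha = 0.05) {
  if (!inherits(ratings, "paired_ratings")) ratings <- paired_ratings(ratings)
  x <- ratings$values
  n <- nrow(x); k <- ncol(x)
  grand <- mean(x)
  row_means <- rowMeans(x)
  ssb <- k * sum((row_means - grand)^2)
  ssw <- sum((x - row_means)^2)
  df1 <- n - 1L; df2 <- n * (k - 1L)
  msb <- ssb / df1; msw <- ssw / df2
  if (msb <= 0 && msw <= 0)
    fq_error("fq_degenerate_error", "zero total variance: ICC undefined")
  est <- (msb - msw) / (msb + (k - 1) * msw)
  if (msw == 0) {
    ci <- c(1, 1); f <- Inf; p <- 0
  } else {
    f <- msb / msw
    b <- icc_f_bounds(f, n, k, alpha)
    ci <- b; p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  }
  structure(list(estimate = est, ci_lower = ci[1], ci_upper = ci[2],
                 model = "oneway_random_single", f_stat = f,
                 df1 = df1, df2 = df2, p_value = p, n = n, k = k,
                 alpha = alpha),
            class = "icc_result")
}

icc_f_bounds <- function(f, n, k, alpha) {
  df1 <- n - 1; df2 <- n * (k - 1)
  fl <- f / stats::qf(1 - alpha / 2, df1, df2)
  fu <- f * stats::qf(1 - alpha / 2, df2, df1)
  c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(1,1) = %.3f, %d%% CI [%.3f, %.3f], F(%d,%d) = %.2f, p = %.3g, n = %d, k = %d\n",
              x$estimate, round(100 * (1 - x$alpha)), x$ci_lower, x$ci_upper,
              x$df1, x$df2, x$f_stat, x$p_value, x$n, x$k))
  invisible(x)
}

#' Reconstruct the F-based ICC confidence interval from a point estimate
#'
#' Inverts the one-way ICC estimate to its F statistic,
#' `F = (1 + (k-1) icc) / (1 - icc)`, and applies the same F bounds as
#' [icc_oneway()]. This reconstructs a published interval from the printed
#' estimate and sample size alone, without the raw ratings.
#'
#' @param icc point estimate, in `(-1/(k-1), 1)`.
#' @param n number of subjects; `k` number of raters/repeats.
#' @param alpha confidence level complement.
#' @return Numeric `c(ci_lower, ci_upper)`.
#' @export
icc_ci_from_estimate <- function(icc, n, k = 2, alpha = 0.05) {
  stopifnot(n >= 3, k >= 2)
  if (icc >= 1) return(c(1, 1))
  if (icc <= -1 / (k - 1))
    fq_error("fq_precondition_error", "icc must exceed -1/(k-1)")
  f <- (1 + (k - 1) * icc) / (1 - icc)
  icc_f_bounds(f, n, k, alpha)
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' @param x,y numeric vectors of equal length, n >= 4.
#' @param alpha confidence level complement.
#' @return A `correlation_result` with r, ci bounds, n and the t-test
#'   p-value.
#' @export
pearson_ci <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y))
    fq_error("fq_precondition_error", "x and y must have equal length")
  n <- length(x)
  if (n < 4L) fq_error("fq_precondition_error", "need n >= 4")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    fq_error("fq_degenerate_error", "zero variance: correlation undefined")
  r <- stats::cor(x, y)
  ci <- if (abs(r) < 1) pearson_ci_from_estimate(r, n, alpha) else c(r, r)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  p <- if (abs(r) < 1) 2 * stats::pt(abs(tt), n - 2, lower.tail = FALSE) else 0
  structure(list(r = r, ci_lower = ci[1], ci_upper = ci[2], n = n,
                 p_value = p, alpha = alpha),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f, %d%% CI [%.3f, %.3f], p = %.3g, n = %d\n",
              x$r, round(100 * (1 - x$alpha)), x$ci_lower, x$ci_upper,
              x$p_value, x$n))
  invisible(x)
}

#' Fisher-z confidence interval from a correlation point estimate
#'
#' `tanh(atanh(r) +/- z_{1-a/2} / sqrt(n - 3))`.
#'
#' @param r correlation estimate, `|r| < 1`.
#' @param n sample size, n >= 4.
#' @param alpha confidence level complement.
#' @return Numeric `c(ci_lower, ci_upper)`.
#' @export
pearson_ci_from_estimate <- function(r, n, alpha = 0.05) {
  stopifnot(n >= 4)
  if (abs(r) >= 1) return(c(r, r))
  z <- atanh(r)
  half <- stats::qnorm(1 - alpha / 2) / sqrt(n - 3)
  tanh(c(z - half, z + half))
}

#' Simulate paired ratings with a known true ICC
#'
#' `value[i, j] = s_i + e_ij` with `s_i ~ N(0, true_icc)` and
#' `e_ij ~ N(0, 1 - true_icc)`, so the population one-way ICC equals
#' `true_icc`.
#'
#' @param true_icc in `[0, 1)`.
#' @param n subjects; `k` ratings per subject.
#' @param seed RNG seed.
#' @return A [paired_ratings()].
#' @export
simulate_paired_ratings <- function(true_icc, n, k = 2, seed = 1L) {
  stopifnot(true_icc >= 0, true_icc < 1, n >= 3, k >= 2)
  with_seed(seed, {
    s <- stats::rnorm(n, 0, sqrt(true_icc))
    e <- matrix(stats::rnorm(n * k, 0, sqrt(1 - true_icc)), n, k)
    paired_ratings(s + e)
  })
}

#' Simulate grouped values from printed per-group summaries
#'
#' Draws `n_g` values from `Normal(mean_g, sd_g)` for each group; used to
#' reconstruct statistics that are fully determined by published group
#' summaries (counts, means, SDs per ordinal grade).
#'
#' @param groups data frame with columns `label`, `n`, `mean`, `sd`.
#' @param seed RNG seed.
#' @return List with `values` and `labels` vectors.
#' @export
simulate_grouped <- function(groups, seed = 1L) {
  groups <- as.data.frame(groups)
  stopifnot(nrow(groups) >= 1, all(c("label", "n", "mean", "sd") %in% names(groups)),
            all(groups$n >= 1), all(groups$sd >= 0))
  with_seed(seed, {
    values <- unlist(lapply(seq_len(nrow(groups)), function(i)
      stats::rnorm(groups$n[i], groups$mean[i], groups$sd[i])))
    labels <- rep(groups$label, groups$n)
    list(values = values, labels = labels)
  })
}

#' The printed per-ci-grade mIF summaries of the validation cohort
#'
#' Group sizes, means and SDs of the morphometric fibrosis score within
#' each Banff ci grade for the 151 evaluable biopsies (grades 0-3).
#'
#' @return Data frame with columns label, n, mean, sd.
#' @export
ci_grade_groups <- function() {
  data.frame(label = 0:3, n = c(40L, 82L, 18L, 11L),
             mean = c(8.3, 10.7, 17.1, 20.1), sd = c(2.4, 3.6, 6.4, 8.0))
}

#' Paired Wilcoxon signed-rank and paired t tests
#'
#' Zero differences are dropped before the signed-rank test (Wilcoxon
#' convention); the exact null distribution is used for n <= 25 untied
#' differences and the normal approximation with continuity correction
#' above. If every difference is zero both p-values are 1 and the result
#' is flagged degenerate.
#'
#' @param before,after numeric vectors of equal length.
#' @return List with `p_wilcoxon`, `p_paired_t`, `n_nonzero`, `degenerate`.
#' @export
paired_location_test <- function(before, after) {
  if (length(before) != length(after))
    fq_error("fq_precondition_error", "before/after must have equal length")
  d <- after - before
  nz <- d[d != 0]
  if (length(nz) == 0L)
    return(list(p_wilcoxon = 1, p_paired_t = 1, n_nonzero = 0L,
                degenerate = TRUE))
  if (length(nz) < 5L)
    fq_error("fq_precondition_error",
             "need >= 5 non-zero differences for the signed-rank test")
  pw <- suppressWarnings(stats::wilcox.test(
    nz, mu = 0, exact = length(nz) <= 25 && !any(duplicated(abs(nz))),
    correct = TRUE)$p.value)
  pt_ <- if (stats::sd(d) == 0) 0 else stats::t.test(d, mu = 0)$p.value
  list(p_wilcoxon = pw, p_paired_t = pt_, n_nonzero = length(nz),
       degenerate = FALSE)
}

#' Simple least-squares regression of y on x
#'
#' @param x,y numeric vectors, n >= 3, `var(x) > 0`.
#' @return A `regression_result` with intercept, slope, r_squared, slope
#'   p-value and n.
#' @export
ols_simple <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    fq_error("fq_precondition_error", "need equal-length x, y with n >= 3")
  if (stats::sd(x) == 0)
    fq_error("fq_degenerate_error", "constant x: fit undefined")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  structure(list(intercept = unname(stats::coef(fit)[1]),
                 slope = unname(stats::coef(fit)[2]),
                 r_squared = sm$r.squared,
                 p_value = unname(sm$coefficients["x", "Pr(>|t|)"]),
                 n = length(x)),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("y = %.4g + %.4g x, R^2 = %.4f, p = %.3g, n = %d\n",
              x$intercept, x$slope, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' Per-group n, mean and sample SD
#'
#' @param values numeric vector; `labels` parallel ordinal labels.
#' @return Data frame (label ascending) with n, mean, sd and a `degenerate`
#'   flag where sd is undefined (n = 1) or zero.
#' @export
group_summary <- function(values, labels) {
  if (length(values) != length(labels))
    fq_error("fq_precondition_error", "values and labels must have equal length")
  labs <- sort(unique(labels))
  out <- do.call(rbind, lapply(labs, function(l) {
    v <- values[labels == l]
    s <- if (length(v) > 1) stats::sd(v) else NA_real_
    data.frame(label = l, n = length(v), mean = mean(v), sd = s,
               degenerate = is.na(s) || s == 0)
  }))
  rownames(out) <- NULL
  out
}
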