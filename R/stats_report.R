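#' Percent error of an estimate relative to a reference
#'
#' @param estimate,reference Scalars (or equal-length vectors);
#'   `reference` must be nonzero.
#' @param absolute Return the absolute percent error.
#' @return `100 * (estimate - reference) / reference`, optionally in
#'   absolute value.
#' @export
percent_error <- function(estimate, reference, absolute = FALSE) {
  if (any(reference == 0))
    stop("percent error undefined for a zero reference", call. = FALSE)
  pe <- 100 * (estimate - reference) / reference
  if (absolute) abs(pe) else pe
}

#' Paired test of averaged-pattern vs mean-of-costs estimates
#'
#' Paired t-test of the per-trial method-2 (averaged gait pattern) against
#' method-3 (mean of per-stride costs) estimates, with the mean percent
#' difference and its standard error in the conventional mean +/- s.e.
#' reporting style.
#'
#' @param method2_costs,method3_costs Equal-length numeric vectors
#'   (>= 3 pairs), one entry per trial.
#' @return A list: `t`, `df`, `p_value` (two-sided), `mean_diff`,
#'   `se_diff`, `mean_percent_diff`, `se_percent_diff`.
#' @export
paired_method_test <- function(method2_costs, method3_costs) {
  if (length(method2_costs) != length(method3_costs))
    stop("paired vectors must have equal length", call. = FALSE)
  if (length(method2_costs) < 3L)
    stop("need at least 3 pairs", call. = FALSE)
  d <- method2_costs - method3_costs
  if (stats::sd(d) == 0)
    stop("degenerate pairs: all differences identical, t undefined",
         call. = FALSE)
  ht <- stats::t.test(method2_costs, method3_costs, paired = TRUE)
  pd <- percent_error(method2_costs, method3_costs)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value,
       mean_diff = mean(d), se_diff = stats::sd(d) / sqrt(length(d)),
       mean_percent_diff = mean(pd),
       se_percent_diff = stats::sd(pd) / sqrt(length(pd)))
}

#' Regress percent error on walking speed
#'
#' Pooled ordinary least squares of per-trial percent error on trial
#' speed, testing for a speed dependence of the estimation error.
#'
#' @param speeds Numeric vector of trial speeds (m/s); at least 2 distinct
#'   values are required for the slope to be identified.
#' @param errors Percent errors, same length.
#' @return A list: `slope` (percent per m/s), `intercept`, `p_value`
#'   (two-sided, for the slope), `r_squared`.
#' @export
regress_error_on_speed <- function(speeds, errors) {
  if (length(speeds) != length(errors))
    stop("speeds and errors must have equal length", call. = FALSE)
  if (length(unique(speeds)) < 2L)
    stop("need at least 2 distinct speeds to fit a slope", call. = FALSE)
  fit <- stats::lm(errors ~ speeds)
  sm <- suppressWarnings(summary(fit))   # zero-residual fits warn
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       p_value = if (nrow(sm$coefficients) > 1L &&
                     ncol(sm$coefficients) >= 4L)
         sm$coefficients[2L, 4L] else NA_real_,
       r_squared = sm$r.squared)
}

#' Jensen gap of a convex function over a point set
#'
#' For a convex function `f`, `f(mean(p)) <= mean(f(p))`; the gap
#' `mean(f(p)) - f(mean(p))` is the averaging bias that makes the
#' averaged-pattern cost underestimate the mean of per-stride costs.
#'
#' @param f A scalar function, vectorized or not.
#' @param p Numeric vector of input points (>= 2).
#' @return A list: `f_of_mean`, `mean_of_f`, `gap` (`>= 0` for convex
#'   `f`, 0 for affine `f`).
#' @export
jensen_gap <- function(f, p) {
  if (length(p) < 2L) stop("need at least 2 points", call. = FALSE)
  fp <- vapply(p, function(x) f(x), numeric(1))
  f_of_mean <- f(mean(p))
  list(f_of_mean = f_of_mean, mean_of_f = mean(fp),
       gap = mean(fp) - f_of_mean)
}

#' Variance of the N-stride mean cost as a function of N
#'
#' Empirically checks that averaging per-stride costs over N independent
#' strides shrinks the variance of the estimate like 1/N: for each N it
#' draws `n_resamples` independent N-stride sets from the generator,
#' computes the mean cost (the method-3 estimator) for each set, and
#' reports the variance of those means across resamples, together with the
#' slope of log-variance against log-N.
#'
#' @param config A [synthetic_gait_config()].
#' @param cost_model A cost model for [stride_cost()].
#' @param N_grid Stride counts (>= 3 values, including 1).
#' @param n_resamples Resamples per N (default 2000).
#' @param seed Integer seed.
#' @return A list: `table` (data.frame `N`, `variance`), `means` (named
#'   list of the resampled N-stride mean costs, one vector per N), and
#'   `loglog_slope` (OLS slope of `log(variance)` on `log(N)`; -1 for
#'   ideal 1/N scaling).
#' @export
variance_scaling_experiment <- function(config, cost_model,
                                        N_grid = c(1, 2, 5, 10, 20),
                                        n_resamples = 2000, seed = 1) {
  if (length(N_grid) < 3L || !1 %in% N_grid)
    stop("N_grid must contain at least 3 values including 1", call. = FALSE)
  means <- lapply(seq_along(N_grid), function(i) {
    N <- N_grid[[i]]
    costs <- draw_stride_costs(config, cost_model, N * n_resamples,
                               seed = (seed + 104729L * i) %% 2147483647L)
    colMeans(matrix(costs, nrow = N))
  })
  names(means) <- paste0("N", N_grid)
  vars <- vapply(means, stats::var, numeric(1))
  fit <- stats::lm(log(vars) ~ log(N_grid))
  list(table = data.frame(N = N_grid, variance = unname(vars)),
       means = means,
       loglog_slope = unname(stats::coef(fit)[2L]))
}

#' Bootstrap confidence interval for a variance ratio
#'
#' CI for `var(x) / var(y)` by resampling both vectors with replacement.
#'
#' @param x,y Numeric vectors.
#' @param n_boot Bootstrap replicates (default 2000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed.
#' @return Numeric vector `c(lower, upper)`.
#' @export
bootstrap_var_ratio_ci <- function(x, y, n_boot = 2000, level = 0.95,
                                   seed = 1) {
  set.seed(seed)
  r <- vapply(seq_len(n_boot), function(b) {
    stats::var(sample(x, replace = TRUE)) /
      stats::var(sample(y, replace = TRUE))
  }, numeric(1))
  unname(stats::quantile(r, c((1 - level) / 2, 1 - (1 - level) / 2)))
}
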