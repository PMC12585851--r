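#' Resample a stride onto the 0-100% gait-cycle grid
#'
#' Maps a stride's time axis to gait-cycle fraction (0 at the opening heel
#' strike, 1 at the closing one) and linearly interpolates every channel
#' onto a uniform fraction grid. The stride's real duration is retained so
#' the normalized stride can be mapped back to time.
#'
#' @param stride A `stride_series` from [segment_strides()].
#' @param n_grid Number of grid points including both endpoints (default
#'   101, i.e. 0, 1, ..., 100% of the cycle).
#' @return An object of class `"normalized_stride"`: `grid` (fractions in
#'   \[0, 1\]), `channels` (named list of [signal_channel()]s whose samples
#'   live on the grid), `duration` (s), `side`.
#' @export
time_normalize <- function(stride, n_grid = 101) {
  stopifnot(inherits(stride, "stride_series"))
  if (!is.numeric(n_grid) || n_grid < 2)
    stop("n_grid must be at least 2", call. = FALSE)
  n_grid <- as.integer(n_grid)
  grid <- seq(0, 1, length.out = n_grid)
  n <- length(stride$channels[[1L]]$samples)
  frac <- seq(0, 1, length.out = n)
  chans <- lapply(stride$channels, function(ch) {
    y <- stats::approx(frac, ch$samples, xout = grid)$y
    signal_channel(ch$name, y, kind = ch$kind, units = ch$units)
  })
  structure(list(grid = grid, channels = chans, duration = stride$duration,
                 side = stride$side),
            class = "normalized_stride")
}

#' @export
print.normalized_stride <- function(x, ...) {
  cat(sprintf("<normalized_stride> %d grid points, duration %.3f s\n",
              length(x$grid), x$duration))
  invisible(x)
}

#' Average time-normalized strides into one gait pattern
#'
#' Builds the averaged gait pattern: channel values are pointwise
#' arithmetic means at each gait-cycle fraction, and the pattern is mapped
#' to the mean stride period. This is the stride used by the
#' averaged-pattern estimator (method 2 of [estimate_methods()]).
#'
#' @param normalized List of [time_normalize()]d strides (>= 2) sharing the
#'   same grid and channel names.
#' @return An object of class `c("averaged_stride", "normalized_stride")`
#'   with an extra field `n_members`; its `duration` is the mean of the
#'   member durations.
#' @export
average_gait_pattern <- function(normalized) {
  if (length(normalized) < 2L)
    stop("need at least 2 strides to average", call. = FALSE)
  g0 <- normalized[[1L]]$grid
  nm0 <- names(normalized[[1L]]$channels)
  for (s in normalized[-1L]) {
    if (length(s$grid) != length(g0) || max(abs(s$grid - g0)) > 1e-12)
      stop("strides must share the same gait-cycle grid", call. = FALSE)
    if (!identical(names(s$channels), nm0))
      stop("strides must share the same channel set", call. = FALSE)
  }
  chans <- lapply(nm0, function(nm) {
    mat <- vapply(normalized, function(s) s$channels[[nm]]$samples,
                  numeric(length(g0)))
    tmpl <- normalized[[1L]]$channels[[nm]]
    signal_channel(nm, rowMeans(mat), kind = tmpl$kind, units = tmpl$units)
  })
  names(chans) <- nm0
  structure(list(grid = g0, channels = chans,
                 duration = mean(vapply(normalized, `[[`, numeric(1),
                                        "duration")),
                 side = normalized[[1L]]$side,
                 n_members = length(normalized)),
            class = c("averaged_stride", "normalized_stride"))
}

#' Map a normalized stride back to the time domain
#'
#' Converts a normalized (or averaged) stride into a `stride_series`. With
#' `sampling_rate = NULL` the gait-cycle grid itself becomes the (uniform)
#' time base, scaled by the stride duration; otherwise the channels are
#' resampled at the requested rate over the stride duration.
#'
#' @param norm A `normalized_stride` or `averaged_stride`.
#' @param sampling_rate Target rate in Hz, or `NULL` to reuse the grid.
#' @return A `stride_series`.
#' @export
remap_stride <- function(norm, sampling_rate = NULL) {
  stopifnot(inherits(norm, "normalized_stride"))
  if (is.null(sampling_rate)) {
    fs <- (length(norm$grid) - 1) / norm$duration
    chans <- norm$channels
  } else {
    fs <- sampling_rate
    n <- floor(norm$duration * fs + 1e-9) + 1L
    frac <- seq(0, by = 1 / fs, length.out = n) / norm$duration
    chans <- lapply(norm$channels, function(ch) {
      y <- stats::approx(norm$grid, ch$samples, xout = pmin(frac, 1))$y
      signal_channel(ch$name, y, kind = ch$kind, units = ch$units)
    })
  }
  structure(list(channels = chans, t_start = 0,
                 duration = (length(chans[[1L]]$samples) - 1) / fs,
                 sampling_rate = fs,
                 side = if (is.null(norm$side)) "left" else norm$side),
            class = "stride_series")
}

#' Compare the three cost-averaging methods on one trial's strides
#'
#' Computes the three estimators of a trial's effort rate:
#' \describe{
#'   \item{method 1}{the cost of a single, uniformly drawn stride;}
#'   \item{method 2}{the cost of the averaged gait pattern (strides
#'     time-normalized, averaged pointwise, mapped to the mean stride
#'     period) — equivalent to zeroing out the stride-to-stride
#'     variability;}
#'   \item{method 3}{the arithmetic mean of the per-stride costs, the
#'     reference that fully retains the variability.}
#' }
#' Percent errors of methods 1 and 2 are reported relative to method 3.
#' All three estimators are evaluated on the common gait-cycle grid
#' representation so that differences between them reflect stride-to-stride
#' variability rather than discretization.
#'
#' @param strides List of >= 2 `stride_series`.
#' @param cost_model A cost model (see [torque_cost_model()],
#'   [muscle_cost_model()]), mapping one stride to a scalar effort rate.
#' @param rng_seed Integer seed for the method-1 stride draw.
#' @param n_grid Gait-cycle grid size (default 101).
#' @param duration_weighted If `TRUE`, method 3 weights per-stride cost
#'   rates by stride duration (time-weighted mean rate); default `FALSE`,
#'   the plain arithmetic mean of per-stride rates.
#' @return An object of class `"method_comparison"`: `per_stride_costs`,
#'   `method1_index` (1-based chosen stride), `method1_cost`,
#'   `method2_cost`, `method3_cost`, `percent_error_m1`,
#'   `abs_percent_error_m1`, `percent_error_m2`.
#' @export
estimate_methods <- function(strides, cost_model, rng_seed = NULL,
                             n_grid = 101, duration_weighted = FALSE) {
  if (length(strides) < 2L)
    stop("need at least 2 strides", call. = FALSE)
  normalized <- lapply(strides, time_normalize, n_grid = n_grid)
  per_stride <- vapply(seq_along(normalized), function(i) {
    cost <- try(stride_cost(cost_model, remap_stride(normalized[[i]])),
                silent = TRUE)
    if (inherits(cost, "try-error"))
      stop("cost model failed on stride ", i, ": ",
           attr(cost, "condition")$message, call. = FALSE)
    cost
  }, numeric(1))
  avg <- average_gait_pattern(normalized)
  method2 <- stride_cost(cost_model, remap_stride(avg))
  method3 <- if (duration_weighted) {
    w <- vapply(strides, `[[`, numeric(1), "duration")
    sum(w * per_stride) / sum(w)
  } else mean(per_stride)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  i1 <- sample.int(length(strides), 1L)
  method1 <- per_stride[[i1]]
  pe <- function(est) 100 * (est - method3) / method3
  structure(list(per_stride_costs = per_stride,
                 method1_index = i1,
                 method1_cost = method1,
                 method2_cost = method2,
                 method3_cost = method3,
                 percent_error_m1 = pe(method1),
                 abs_percent_error_m1 = abs(pe(method1)),
                 percent_error_m2 = pe(method2)),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat("<method_comparison>\n")
  cat(sprintf("  per-stride costs: %s\n",
              paste(formatC(x$per_stride_costs, digits = 5), collapse = ", ")))
  cat(sprintf("  method 1 (random stride %d): %.6g  (%+.3f%%)\n",
              x$method1_index, x$method1_cost, x$percent_error_m1))
  cat(sprintf("  method 2 (averaged pattern): %.6g  (%+.3f%%)\n",
              x$method2_cost, x$percent_error_m2))
  cat(sprintf("  method 3 (mean of costs):    %.6g  (reference)\n",
              x$method3_cost))
  invisible(x)
}
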