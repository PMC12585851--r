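#' Zero-phase Butterworth low-pass filter
#'
#' Filters a channel with a Butterworth low-pass applied forward and
#' backward (`signal::filtfilt`), giving zero phase lag so that event times
#' derived from the filtered signal are unbiased. The default 6 Hz cutoff is
#' the conventional choice for walking kinematics and ground reaction
#' forces; order 4 applied in both directions gives an effective order-8
#' magnitude response.
#'
#' @param channel A [signal_channel()].
#' @param cutoff Cutoff frequency in Hz (must be below the Nyquist
#'   frequency `sampling_rate / 2`).
#' @param sampling_rate Sampling rate of the channel in Hz.
#' @param order Butterworth order of each pass (default 4).
#' @param zero_phase Apply forward-backward (`TRUE`, default) or a single
#'   causal pass.
#' @return A filtered [signal_channel()] of equal length.
#' @export
lowpass_filter <- function(channel, cutoff = 6, sampling_rate, order = 4,
                           zero_phase = TRUE) {
  stopifnot(inherits(channel, "signal_channel"))
  nyq <- sampling_rate / 2
  if (cutoff >= nyq)
    stop(sprintf("cutoff %g Hz must be below Nyquist %g Hz", cutoff, nyq),
         call. = FALSE)
  x <- channel$samples
  if (length(x) <= 3L * order)
    stop(sprintf("signal too short to filter: %d samples <= 3 x order %d",
                 length(x), order), call. = FALSE)
  bf <- signal::butter(order, cutoff / nyq, type = "low")
  y <- if (zero_phase) signal::filtfilt(bf, x) else
    as.numeric(signal::filter(bf, x))
  signal_channel(channel$name, y, kind = channel$kind, units = channel$units)
}

#' Filter all angle and GRF channels of a trial
#'
#' Applies [lowpass_filter()] to every channel of kind `angle`, `moment`,
#' or `grf_force` in a trial, leaving the others untouched. Joint moments
#' are included because they enter the effort models on the same footing as
#' the measured signals they derive from.
#'
#' @inheritParams lowpass_filter
#' @param trial A [gait_trial()].
#' @param kinds Channel kinds to filter.
#' @return The trial with filtered channels.
#' @export
filter_trial <- function(trial, cutoff = 6, order = 4,
                         kinds = c("angle", "moment", "grf_force")) {
  trial$channels <- lapply(trial$channels, function(ch) {
    if (ch$kind %in% kinds)
      lowpass_filter(ch, cutoff, trial$sampling_rate, order)
    else ch
  })
  trial
}

#' Detect heel strikes from a vertical ground reaction force
#'
#' A heel strike is an upward crossing of the force threshold: the first
#' sample at or above `threshold` after at least one sample below it.
#' Crossings closer than `min_gap` to the previous accepted event are
#' rejected (debouncing), which suppresses double-crossings caused by noise
#' near the threshold.
#'
#' @param vertical_grf A [signal_channel()] of kind `"grf_force"` holding
#'   the vertical force in N.
#' @param sampling_rate Sampling rate in Hz.
#' @param threshold Force threshold in N (default 30).
#' @param min_gap Minimum spacing between events in s (default 0.4, a lower
#'   bound on plausible stride periods).
#' @param side Which foot the channel belongs to (`"left"` or `"right"`).
#' @return An object of class `"gait_events"`: a list with
#'   `heel_strike_times` (s, strictly increasing, possibly empty),
#'   `heel_strike_index` (1-based sample indices), and `side`.
#' @export
detect_heel_strikes <- function(vertical_grf, sampling_rate, threshold = 30,
                                min_gap = 0.4, side = "left") {
  stopifnot(inherits(vertical_grf, "signal_channel"))
  if (vertical_grf$kind != "grf_force")
    stop("heel-strike detection needs a 'grf_force' channel, got '",
         vertical_grf$kind, "'", call. = FALSE)
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  side <- match.arg(side, c("left", "right"))
  x <- vertical_grf$samples
  above <- x >= threshold
  # upward crossings: below at i-1, at/above at i
  idx <- which(!above[-length(above)] & above[-1L]) + 1L
  keep <- integer(0)
  last_t <- -Inf
  for (i in idx) {
    t_i <- (i - 1L) / sampling_rate
    if (t_i - last_t >= min_gap) {
      keep <- c(keep, i)
      last_t <- t_i
    }
  }
  structure(list(heel_strike_times = (keep - 1L) / sampling_rate,
                 heel_strike_index = keep, side = side),
            class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("<gait_events> %d %s heel strikes\n",
              length(x$heel_strike_times), x$side))
  invisible(x)
}

#' Zero ground reaction forces during swing
#'
#' During swing the foot is airborne and measured forces are treadmill
#' noise; wherever the vertical force is below `threshold`, every GRF
#' component in `grf_channels` (including the vertical itself) is set to
#' exactly 0.
#'
#' @param grf_channels List of [signal_channel()]s for one foot; must
#'   include the channel named by `vertical`.
#' @param vertical Name of the vertical component within `grf_channels`.
#' @param threshold Swing threshold in N (default 30).
#' @return The list of channels with swing samples zeroed.
#' @export
zero_swing_grf <- function(grf_channels, vertical, threshold = 30) {
  names(grf_channels) <- vapply(grf_channels, `[[`, character(1), "name")
  if (!vertical %in% names(grf_channels))
    stop("vertical channel '", vertical, "' not found", call. = FALSE)
  swing <- grf_channels[[vertical]]$samples < threshold
  lapply(grf_channels, function(ch) {
    ch$samples[swing] <- 0
    ch
  })
}

#' Segment a trial into consecutive strides
#'
#' A stride spans one heel strike to the next of the same foot. Stride k
#' contains the samples from event k through event k+1 inclusive, so
#' consecutive strides share their boundary sample and the stride duration
#' is the heel-strike spacing.
#'
#' @param trial A [gait_trial()].
#' @param events A `gait_events` object with at least `n_strides + 1` heel
#'   strikes.
#' @param n_strides Number of consecutive strides to return (default 5).
#' @param start_index 0-based index of the first heel strike to use, or
#'   `"random"` to draw it uniformly from the valid starts.
#' @param seed Optional integer seed used only when `start_index =
#'   "random"`.
#' @return List of `n_strides` objects of class `"stride_series"`, each with
#'   `channels` (named list of [signal_channel()]s), `t_start` (s),
#'   `duration` (s), `sampling_rate`, and `side`.
#' @export
segment_strides <- function(trial, events, n_strides = 5,
                            start_index = "random", seed = NULL) {
  n_ev <- length(events$heel_strike_index)
  if (n_ev < n_strides + 1L)
    stop(sprintf(
      "need %d heel strikes for %d strides but only %d were detected",
      n_strides + 1L, n_strides, n_ev), call. = FALSE)
  n_starts <- n_ev - n_strides
  if (identical(start_index, "random")) {
    if (!is.null(seed)) set.seed(seed)
    start_index <- sample.int(n_starts, 1L) - 1L
  }
  if (start_index < 0 || start_index > n_starts - 1L)
    stop("start_index out of range [0, ", n_starts - 1L, "]", call. = FALSE)
  fs <- trial$sampling_rate
  lapply(seq_len(n_strides), function(k) {
    i0 <- events$heel_strike_index[[start_index + k]]
    i1 <- events$heel_strike_index[[start_index + k + 1L]]
    chans <- lapply(trial$channels, function(ch) {
      signal_channel(ch$name, ch$samples[i0:i1], kind = ch$kind,
                     units = ch$units)
    })
    structure(list(channels = chans, t_start = (i0 - 1L) / fs,
                   duration = (i1 - i0) / fs, sampling_rate = fs,
                   side = events$side),
              class = "stride_series")
  })
}

#' @export
print.stride_series <- function(x, ...) {
  cat(sprintf("<stride_series> %s, %.3f s @ %g Hz, %d channels\n",
              x$side, x$duration, x$sampling_rate, length(x$channels)))
  invisible(x)
}

#' Sample times of a stride, relative to its start
#' @param stride A `stride_series`.
#' @return Numeric vector of times in s from 0 to `duration`.
#' @export
stride_time <- function(stride) {
  n <- length(stride$channels[[1L]]$samples)
  seq(0, stride$duration, length.out = n)
}
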