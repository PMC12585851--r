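#' Default channel templates for the synthetic gait generator
#'
#' Low-order Fourier templates (at most 6 harmonics) with textbook-shaped
#' waveforms: sinusoid-like joint angles, smooth joint moments, a
#' double-bump vertical ground reaction force that is exactly 0 N during
#' the swing window (38% of the cycle), and an S-shaped
#' braking/propulsion fore-aft force. The values are illustrative shapes,
#' not participant data. Angle/moment templates are
#' `offset + sum_k(cos_k cos(2 pi k phi) + sin_k sin(2 pi k phi))`; GRF
#' templates are defined over the stance fraction of the cycle.
#'
#' @param weight Nominal vertical-force scale in N (default 700,
#'   approximately body weight of a 72 kg adult).
#' @param stance_fraction Fraction of the gait cycle spent in stance
#'   (default 0.62).
#' @return Named list of template definitions.
#' @export
default_gait_templates <- function(weight = 700, stance_fraction = 0.62) {
  fourier <- function(kind, offset, cos, sin)
    list(type = "fourier", kind = kind, offset = offset, cos = cos, sin = sin)
  list(
    ankle_angle_r = fourier("angle", -5, c(2, -6, 1), c(10, 4, -1)),
    knee_angle_r  = fourier("angle", 25, c(-20, 8, 2), c(5, -10, 1)),
    hip_angle_r   = fourier("angle", 10, c(18, 2, 0), c(8, -2, 0)),
    ankle_moment_r = fourier("moment", 30, c(-35, 10, -3), c(20, 15, -2)),
    knee_moment_r  = fourier("moment", 5, c(15, -8, 2), c(-12, 6, 1)),
    hip_moment_r   = fourier("moment", -5, c(20, 5, -2), c(25, -5, 0)),
    grf_vy_r = list(type = "grf_vertical", kind = "grf_force",
                    weight = weight, stance_fraction = stance_fraction),
    grf_vx_r = list(type = "grf_foreaft", kind = "grf_force",
                    weight = weight, stance_fraction = stance_fraction)
  )
}

# Evaluate one template at gait-cycle fractions phi in [0, 1) with a
# multiplicative amplitude factor on the time-varying part (offsets are
# preserved; GRF templates have zero offset so swing stays at 0 N).
eval_template <- function(tmpl, phi, amp = 1) {
  if (tmpl$type == "fourier") {
    y <- 0
    for (k in seq_along(tmpl$cos))
      y <- y + tmpl$cos[[k]] * cos(2 * pi * k * phi) +
        tmpl$sin[[k]] * sin(2 * pi * k * phi)
    return(tmpl$offset + amp * y)
  }
  sf <- tmpl$stance_fraction
  u <- phi / sf
  stance <- phi < sf
  if (tmpl$type == "grf_vertical") {
    y <- ifelse(stance, tmpl$weight * (sin(pi * u) + 0.25 * sin(3 * pi * u)),
                0)
    return(amp * pmax(y, 0))
  }
  if (tmpl$type == "grf_foreaft") {
    y <- ifelse(stance, -0.15 * tmpl$weight * sin(2 * pi * u), 0)
    return(amp * y)
  }
  stop("unknown template type: ", tmpl$type, call. = FALSE)
}

#' Configuration for the synthetic gait generator
#'
#' Describes the statistical structure of a treadmill-style multi-stride
#' recording: quasi-periodic strides around a base period, per-stride
#' amplitude scaling, stride-period jitter, and additive measurement noise
#' per channel kind. The defaults emulate normal treadmill walking sampled
#' at 100 Hz with a 1.1 s stride period; variability defaults (5% amplitude
#' CV, 0.02 s period SD, modest sensor noise) are typical of steady
#' treadmill gait.
#'
#' @param n_strides Number of complete strides the trial must contain
#'   (default 5). The generated recording carries `n_strides + 1`
#'   heel-strike events so that exactly `n_strides` strides can be
#'   segmented.
#' @param base_period Nominal stride period in s (default 1.1).
#' @param sampling_rate Sampling rate in Hz (default 100).
#' @param speed Belt-speed label in m/s (metadata only).
#' @param sigma_amplitude Fractional SD of the per-stride amplitude factor.
#' @param sigma_period SD of the stride period in s.
#' @param sigma_meas Named numeric vector of additive measurement-noise SDs
#'   by channel kind (`angle` in deg, `moment` in N·m, `grf_force` in N).
#' @param templates Channel templates, see [default_gait_templates()].
#' @param seed Integer seed; the generator is fully reproducible from
#'   `(config, seed)`.
#' @return An object of class `"synthetic_gait_config"`.
#' @export
synthetic_gait_config <- function(n_strides = 5, base_period = 1.1,
                                  sampling_rate = 100, speed = 1.0,
                                  sigma_amplitude = 0.05,
                                  sigma_period = 0.02,
                                  sigma_meas = c(angle = 0.25, moment = 0.5,
                                                 grf_force = 2),
                                  templates = default_gait_templates(),
                                  seed = 1) {
  stopifnot(n_strides >= 1, base_period > 0, sampling_rate > 0,
            sigma_amplitude >= 0, sigma_period >= 0, all(sigma_meas >= 0))
  structure(list(n_strides = as.integer(n_strides),
                 base_period = base_period, sampling_rate = sampling_rate,
                 speed = speed, sigma_amplitude = sigma_amplitude,
                 sigma_period = sigma_period, sigma_meas = sigma_meas,
                 templates = templates, seed = as.integer(seed)),
            class = "synthetic_gait_config")
}

# Draw stride periods and amplitude factors; periods <= 0.2 s are redrawn.
draw_stride_params <- function(config, n) {
  periods <- config$base_period + stats::rnorm(n, 0, config$sigma_period)
  n_redraw <- 0L
  while (any(bad <- periods <= 0.2)) {
    n_redraw <- n_redraw + sum(bad)
    periods[bad] <- config$base_period +
      stats::rnorm(sum(bad), 0, config$sigma_period)
  }
  if (n_redraw > 0L)
    message("redrew ", n_redraw, " stride period(s) <= 0.2 s")
  amps <- 1 + stats::rnorm(n, 0, config$sigma_amplitude)
  list(periods = periods, amps = amps)
}

# Time (s from stride onset) at which the scaled vertical GRF template
# rises through `threshold`, solved on the continuous template.
grf_crossing_offset <- function(tmpl, period, amp, threshold = 30) {
  f <- function(phi) eval_template(tmpl, phi, amp) - threshold
  peak_phi <- 0.25 * tmpl$stance_fraction
  stats::uniroot(f, c(1e-9, peak_phi), tol = 1e-12)$root * period
}

#' Generate a synthetic multi-stride gait trial
#'
#' Concatenates `n_strides + 1` stride repetitions. Repetition k has period
#' `base_period + delta_k` (`delta ~ N(0, sigma_period)`, redrawn if the
#' period would fall at or below 0.2 s) and channel amplitudes scaled by
#' `1 + gamma_k` (`gamma ~ N(0, sigma_amplitude)`) on the time-varying part
#' of each template; i.i.d. Gaussian measurement noise is then added per
#' sample. The vertical GRF rises through 30 N exactly once per stride
#' repetition, and the exact continuous-time crossing instants are returned
#' as ground truth.
#'
#' The recording opens with a short swing-phase lead-in (the last 30% of a
#' nominal cycle) so that the first heel strike is preceded by
#' below-threshold samples and is detectable even after filtering.
#'
#' @param config A [synthetic_gait_config()].
#' @return A list with elements `trial` (a [gait_trial()]) and `truth`, the
#'   generator ground truth: `heel_strike_times` (`n_strides + 1` values,
#'   s), `stride_durations` (`n_strides` values, s), `periods` and
#'   `amplitude_factors` (one per repetition).
#' @export
generate_gait_trial <- function(config) {
  stopifnot(inherits(config, "synthetic_gait_config"))
  set.seed(config$seed)
  n_rep <- config$n_strides + 1L
  par <- draw_stride_params(config, n_rep)
  lead_frac <- 0.3                      # inside the swing window (> 0.62)
  lead <- lead_frac * config$base_period
  bounds <- lead + c(0, cumsum(par$periods))
  fs <- config$sampling_rate
  n_samp <- floor(bounds[[n_rep + 1L]] * fs) + 1L
  tt <- (seq_len(n_samp) - 1L) / fs
  rep_idx <- pmin(findInterval(tt, bounds, rightmost.closed = TRUE), n_rep)
  phi <- (tt - bounds[pmax(rep_idx, 1L)]) / par$periods[pmax(rep_idx, 1L)]
  in_lead <- rep_idx == 0L
  phi[in_lead] <- 1 - lead_frac + tt[in_lead] / config$base_period
  rep_idx[in_lead] <- 1L                # lead-in uses stride 1's amplitude
  phi <- pmin(pmax(phi, 0), 1 - 1e-12)

  chans <- lapply(names(config$templates), function(nm) {
    tmpl <- config$templates[[nm]]
    y <- eval_template(tmpl, phi, par$amps[rep_idx])
    sd_meas <- config$sigma_meas[tmpl$kind]
    if (!is.na(sd_meas) && sd_meas > 0)
      y <- y + stats::rnorm(length(y), 0, sd_meas)
    signal_channel(nm, y, kind = tmpl$kind)
  })
  trial <- gait_trial(chans, sampling_rate = fs, participant_id = "synthetic",
                      belt_speed = config$speed)

  vy <- config$templates[[which(vapply(config$templates, function(t)
    t$type == "grf_vertical", logical(1)))[[1L]]]]
  hs <- vapply(seq_len(n_rep), function(k) {
    bounds[[k]] + grf_crossing_offset(vy, par$periods[[k]], par$amps[[k]])
  }, numeric(1))
  list(trial = trial,
       truth = list(heel_strike_times = hs,
                    stride_durations = diff(hs),
                    periods = par$periods,
                    amplitude_factors = par$amps))
}

#' Generate synthetic muscle-state trajectories, one stride at a time
#'
#' Emits smooth periodic muscle states for `n_muscles` muscles over
#' `config$n_strides` strides, using the same per-stride period and
#' amplitude perturbation machinery as [generate_gait_trial()]. Muscle `i`
#' has a periodic activation burst centred at cycle fraction
#' `(i - 1) / n_muscles` (clamped to \[0, 1\]), a normalized fibre length
#' oscillating around 1, a fibre velocity equal to the analytic time
#' derivative of the length, and an active force
#' `max_isometric_force x activation x force-length factor`. No
#' measurement noise is added: these stand in for the output of a muscle
#' control solution, not for raw sensor data.
#'
#' @param config A [synthetic_gait_config()].
#' @param n_muscles Number of muscles (default 4).
#' @param activation_peak Peak activation of each burst (default 0.6).
#' @param burst_width Width parameter of the periodic activation bump
#'   (default 0.15, in cycle-fraction units).
#' @param length_excursion Half-amplitude of the fibre-length oscillation
#'   (default 0.05 optimal lengths).
#' @param max_isometric_force Force scale in N (default 1000).
#' @return List of `config$n_strides` `stride_series`, each with channels
#'   `m<i>_activation`, `m<i>_excitation`, `m<i>_fiber_length`,
#'   `m<i>_fiber_velocity`, `m<i>_active_force`.
#' @export
generate_muscle_states <- function(config, n_muscles = 4,
                                   activation_peak = 0.6,
                                   burst_width = 0.15,
                                   length_excursion = 0.05,
                                   max_isometric_force = 1000) {
  stopifnot(inherits(config, "synthetic_gait_config"), n_muscles >= 1)
  set.seed(config$seed)
  par <- draw_stride_params(config, config$n_strides)
  fs <- config$sampling_rate
  centers <- (seq_len(n_muscles) - 1) / n_muscles
  lapply(seq_len(config$n_strides), function(k) {
    T_k <- par$periods[[k]]
    amp <- par$amps[[k]]
    n <- floor(T_k * fs) + 1L
    phi <- (seq_len(n) - 1L) / fs / T_k
    chans <- list()
    for (i in seq_len(n_muscles)) {
      # periodic bump, peak 1 at phi = center, smooth across the wrap
      bump <- exp((cos(2 * pi * (phi - centers[[i]])) - 1) / burst_width)
      act <- pmin(pmax(activation_peak * amp * bump, 0), 1)
      len <- 1 + length_excursion * amp * sin(2 * pi * (phi - centers[[i]]))
      vel <- length_excursion * amp * 2 * pi *
        cos(2 * pi * (phi - centers[[i]])) / T_k
      frc <- max_isometric_force * act * force_length_factor(len)
      pre <- paste0("m", i, "_")
      chans <- c(chans, list(
        signal_channel(paste0(pre, "activation"), act, kind = "other",
                       units = ""),
        signal_channel(paste0(pre, "excitation"), act, kind = "other",
                       units = ""),
        signal_channel(paste0(pre, "fiber_length"), len, kind = "other",
                       units = "l_opt"),
        signal_channel(paste0(pre, "fiber_velocity"), vel, kind = "other",
                       units = "l_opt/s"),
        signal_channel(paste0(pre, "active_force"), frc, kind = "other",
                       units = "N")))
    }
    names(chans) <- vapply(chans, `[[`, character(1), "name")
    structure(list(channels = chans, t_start = if (k == 1L) 0 else
      sum(par$periods[seq_len(k - 1L)]),
      duration = (n - 1L) / fs, sampling_rate = fs, side = "left"),
      class = "stride_series")
  })
}

#' Draw independent single-stride costs from the generator
#'
#' Fast path for resampling experiments: draws `n` independent strides
#' (each one template repetition with its own period and amplitude draw,
#' plus measurement noise), evaluates the cost model on each, and returns
#' the per-stride costs without assembling full trials.
#'
#' @param config A [synthetic_gait_config()].
#' @param cost_model A cost model for [stride_cost()].
#' @param n Number of strides to draw.
#' @param seed Integer seed.
#' @return Numeric vector of `n` per-stride effort rates.
#' @export
draw_stride_costs <- function(config, cost_model, n, seed = 1) {
  set.seed(seed)
  par <- draw_stride_params(config, n)
  fs <- config$sampling_rate
  vapply(seq_len(n), function(k) {
    T_k <- par$periods[[k]]
    nk <- floor(T_k * fs) + 1L
    phi <- pmin((seq_len(nk) - 1L) / fs / T_k, 1 - 1e-12)
    chans <- lapply(names(config$templates), function(nm) {
      tmpl <- config$templates[[nm]]
      y <- eval_template(tmpl, phi, par$amps[[k]])
      sd_meas <- config$sigma_meas[tmpl$kind]
      if (!is.na(sd_meas) && sd_meas > 0)
        y <- y + stats::rnorm(length(y), 0, sd_meas)
      signal_channel(nm, y, kind = tmpl$kind)
    })
    names(chans) <- names(config$templates)
    stride <- structure(list(channels = chans, t_start = 0,
                             duration = (nk - 1L) / fs, sampling_rate = fs,
                             side = "left"),
                        class = "stride_series")
    stride_cost(cost_model, stride)
  }, numeric(1))
}
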