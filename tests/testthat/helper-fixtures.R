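# Build a stride_series from per-channel sample vectors at a given rate.
make_stride <- function(channels, sampling_rate = 100, side = "left") {
  chans <- lapply(names(channels), function(nm)
    signal_channel(nm, channels[[nm]]))
  names(chans) <- names(channels)
  n <- length(channels[[1L]])
  structure(list(channels = chans, t_start = 0,
                 duration = (n - 1) / sampling_rate,
                 sampling_rate = sampling_rate, side = side),
            class = "stride_series")
}

# A stride with one constant single-joint moment channel of given value.
const_torque_stride <- function(tau, n = 101, sampling_rate = 100) {
  make_stride(list(ankle_moment_r = rep(tau, n)), sampling_rate)
}

# Noise-free synthetic config shorthand.
quiet_config <- function(...) {
  synthetic_gait_config(sigma_amplitude = 0, sigma_period = 0,
                        sigma_meas = c(angle = 0, moment = 0,
                                       grf_force = 0), ...)
}

# Segment a generated trial using its own detected events.
segment_generated <- function(gen, n_strides = 5, start_index = 0) {
  ev <- detect_heel_strikes(gen$trial$channels$grf_vy_r,
                            gen$trial$sampling_rate)
  segment_strides(gen$trial, ev, n_strides = n_strides,
                  start_index = start_index)
}
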