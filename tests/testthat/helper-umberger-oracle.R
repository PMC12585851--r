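# Independent scalar implementation of the muscle heat-rate model, written
# directly from the published coefficient tables (activation/maintenance
# base 128 f + 25 W/kg split 40/60, exponents 0.6 and 2, shortening
# coefficients 100/vmax_slow and 153/vmax_fast with vmax_slow = vmax/2.5
# and slow-twitch velocity saturation, lengthening coefficient 4 x the
# slow-twitch shortening coefficient scaled by A^1, Gaussian force-length
# factor with width 0.45 applied above optimal length). Scalar branches
# only; kept deliberately separate in style from the package code.
oracle_heat_rates <- function(a, u, l, v, force,
                              f_fast = 0.5, vmax = 12, lopt = 0.1,
                              mass = 0.1, S = 1.5, clamp = TRUE,
                              basal = FALSE) {
  if (u > a) A <- u else A <- (u + a) / 2
  if (l > 1) fl <- exp(-(l - 1)^2 / 0.45) else fl <- 1

  base <- 128 * f_fast + 25
  h_act <- 0.4 * base * A^0.6
  h_mnt <- 0.6 * base * A^0.6 * fl
  if (basal) h_mnt <- h_mnt + 1.2

  vmax_slow <- vmax / 2.5
  if (v <= 0) {
    v_slow <- v
    if (v_slow < -vmax_slow) v_slow <- -vmax_slow
    h_sl <- -((100 / vmax_slow) * (1 - f_fast) * v_slow +
                (153 / vmax) * f_fast * v) * A^2
  } else {
    h_sl <- 4 * (100 / vmax_slow) * v * A
  }
  h_sl <- h_sl * fl

  w <- -force * v * lopt
  hA <- h_act * S * mass
  hM <- h_mnt * S * mass
  hSL <- h_sl * S * mass
  tot <- w + hA + hM + hSL
  if (clamp && tot < 0) tot <- 0
  c(w_dot = w, hA_dot = hA, hM_dot = hM, hSL_dot = hSL, total = tot)
}
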