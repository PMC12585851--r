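#' Cost of one stride under a cost model
#'
#' Generic mapping from one stride's signals to a scalar effort rate
#' (energy per unit time, averaged over the stride). Methods exist for
#' [torque_cost_model()] and [muscle_cost_model()].
#'
#' @param model A cost model object.
#' @param stride A `stride_series`.
#' @param ... Passed to methods.
#' @return Scalar effort rate.
#' @export
stride_cost <- function(model, stride, ...) UseMethod("stride_cost")

# ---- torque-squared model --------------------------------------------------

#' Torque-squared effort model
#'
#' The simple convex effort measure: squared joint moments, summed over
#' joints and averaged over the stride,
#' \deqn{\dot E = \frac{1}{T}\int_0^T \sum_j a_j \tau_j(t)^2 \, dt,}
#' with per-joint coefficients \eqn{a_j} (all 1 by default, the
#' illustrative convention). The quadratic integrand makes this cost
#' strictly convex in the torque trajectory, which is what drives the
#' averaged-pattern underestimation.
#'
#' @param joint_names Names of the moment channels to include, or `NULL`
#'   (default) to use every channel of kind `"moment"` in the stride.
#' @param a Per-joint coefficients, recycled to the number of joints; all
#'   must be >= 0.
#' @return An object of class `c("torque_cost_model", "cost_model")`.
#' @export
torque_cost_model <- function(joint_names = NULL, a = 1) {
  if (any(a < 0)) stop("coefficients a must be non-negative", call. = FALSE)
  structure(list(joint_names = joint_names, a = a),
            class = c("torque_cost_model", "cost_model"))
}

#' Torque-squared cost of a stride
#'
#' Evaluates the time-averaged sum of squared joint moments by trapezoidal
#' quadrature on the sampled torques.
#'
#' @param stride A `stride_series` containing one moment channel per joint.
#' @param model A [torque_cost_model()].
#' @return Scalar effort rate in (N·m)^2 (per unit of the coefficients).
#' @export
torque_squared_cost <- function(stride, model = torque_cost_model()) {
  joints <- model$joint_names
  if (is.null(joints)) {
    kinds <- vapply(stride$channels, `[[`, character(1), "kind")
    joints <- names(stride$channels)[kinds == "moment"]
    if (!length(joints))
      stop("stride has no moment channels", call. = FALSE)
  }
  a <- rep_len(model$a, length(joints))
  tt <- stride_time(stride)
  integrand <- 0
  for (j in seq_along(joints)) {
    ch <- stride$channels[[joints[[j]]]]
    if (is.null(ch))
      stop("missing joint moment channel '", joints[[j]], "'", call. = FALSE)
    integrand <- integrand + a[[j]] * ch$samples^2
  }
  pracma::trapz(tt, integrand) / stride$duration
}

#' @export
stride_cost.torque_cost_model <- function(model, stride, ...) {
  torque_squared_cost(stride, model)
}

# ---- muscle heat-rate model ------------------------------------------------

#' Muscle parameters for the heat-rate energetics model
#'
#' Parameters of one muscle for [umberger_heat_rates()]. Defaults are
#' generic values for a mixed-fibre lower-limb muscle; the maximum
#' shortening velocity is that of the fast-twitch fibres (slow-twitch
#' fibres are taken 2.5-fold slower, the published ratio).
#'
#' @param name Muscle label.
#' @param muscle_mass Muscle mass in kg.
#' @param fast_twitch_fraction Fraction of fast-twitch fibres in \[0, 1\].
#' @param max_shortening_velocity Maximum shortening velocity in optimal
#'   fibre lengths per second (fast-twitch value; default 12).
#' @param optimal_fiber_length Optimal fibre length in m.
#' @param max_isometric_force Maximum isometric force in N.
#' @param aerobic_scale Scaling of the heat-rate terms for primarily
#'   aerobic activity (default 1.5; 1.0 for primarily anaerobic bouts).
#' @param clamp_total_nonnegative Clamp the summed rate at zero (default
#'   `TRUE`): a muscle cannot store free energy from negative work.
#' @param include_basal Add a basal rate of 1.2 W per kg muscle mass to the
#'   maintenance term (default `FALSE`).
#' @return An object of class `"muscle_params"`.
#' @export
muscle_params <- function(name = "muscle", muscle_mass = 0.1,
                          fast_twitch_fraction = 0.5,
                          max_shortening_velocity = 12,
                          optimal_fiber_length = 0.1,
                          max_isometric_force = 1000,
                          aerobic_scale = 1.5,
                          clamp_total_nonnegative = TRUE,
                          include_basal = FALSE) {
  stopifnot(muscle_mass > 0, max_shortening_velocity > 0,
            optimal_fiber_length > 0, max_isometric_force > 0,
            aerobic_scale > 0)
  if (fast_twitch_fraction < 0 || fast_twitch_fraction > 1)
    stop("fast_twitch_fraction must lie in [0, 1]", call. = FALSE)
  structure(list(name = name, muscle_mass = muscle_mass,
                 fast_twitch_fraction = fast_twitch_fraction,
                 max_shortening_velocity = max_shortening_velocity,
                 optimal_fiber_length = optimal_fiber_length,
                 max_isometric_force = max_isometric_force,
                 aerobic_scale = aerobic_scale,
                 clamp_total_nonnegative = clamp_total_nonnegative,
                 include_basal = include_basal),
            class = "muscle_params")
}

#' Muscle state at one or more instants
#'
#' All fields may be vectors of a common length (a trajectory). Velocity is
#' in optimal fibre lengths per second, negative while shortening.
#'
#' @param activation,excitation Activation and neural excitation in
#'   \[0, 1\]; `excitation` defaults to `activation`.
#' @param fiber_length Normalized fibre length (1 = optimal).
#' @param fiber_velocity Normalized fibre velocity (optimal lengths / s;
#'   negative = shortening).
#' @param active_force Active fibre force in N.
#' @return An object of class `"muscle_state"`.
#' @export
muscle_state <- function(activation, excitation = activation,
                         fiber_length = 1, fiber_velocity = 0,
                         active_force = 0) {
  n <- max(length(activation), length(excitation), length(fiber_length),
           length(fiber_velocity), length(active_force))
  st <- list(activation = rep_len(activation, n),
             excitation = rep_len(excitation, n),
             fiber_length = rep_len(fiber_length, n),
             fiber_velocity = rep_len(fiber_velocity, n),
             active_force = rep_len(active_force, n))
  bad <- !vapply(st, function(v) all(is.finite(v)), logical(1))
  if (any(bad))
    stop("non-finite muscle state field(s): ",
         paste(names(st)[bad], collapse = ", "), call. = FALSE)
  if (any(st$activation < 0 | st$activation > 1) ||
      any(st$excitation < 0 | st$excitation > 1))
    stop("activation and excitation must lie in [0, 1]", call. = FALSE)
  structure(st, class = "muscle_state")
}

# Normalized active force-length curve (Gaussian, width parameter 0.45).
force_length_factor <- function(l) exp(-(l - 1)^2 / 0.45)

#' Muscle heat and work rates
#'
#' Decomposes a muscle's instantaneous energy rate into mechanical fibre
#' work rate plus activation, maintenance, and shortening/lengthening heat
#' rates, following the published heat-rate formulation for mixed
#' fast/slow-twitch muscle:
#' \itemize{
#'   \item an effective activation level `A` equal to the excitation `u`
#'     while `u > a` and to `(u + a)/2` otherwise, entering the
#'     activation/maintenance terms as `A^0.6` and the shortening heat as
#'     `A^2` (lengthening heat scales with `A` itself);
#'   \item a combined activation-maintenance base rate `128 f + 25` W per
#'     kg muscle (with `f` the fast-twitch fraction), split 40% activation
#'     / 60% maintenance, the maintenance share modulated by the
#'     force-length factor at fibre lengths above optimal;
#'   \item shortening heat coefficients `100 / vmax_slow` (slow twitch,
#'     with `vmax_slow = vmax/2.5`; the slow-twitch velocity saturates at
#'     `vmax_slow`) and `153 / vmax` (fast twitch); lengthening heat
#'     coefficient four times the slow-twitch shortening coefficient;
#'   \item fibre work rate `-(active force) x (fibre velocity in m/s)`,
#'     positive while shortening.
#' }
#' Heat terms are multiplied by `aerobic_scale` and the muscle mass; the
#' total is the sum of the four components, optionally clamped at zero.
#'
#' @param state A [muscle_state()] (fields may be trajectories).
#' @param params A [muscle_params()].
#' @return An object of class `"heat_rates"`: `w_dot`, `hA_dot`, `hM_dot`,
#'   `hSL_dot`, `total`, all in W (vectors if the state was a trajectory).
#' @export
umberger_heat_rates <- function(state, params) {
  stopifnot(inherits(state, "muscle_state"), inherits(params, "muscle_params"))
  a <- state$activation; u <- state$excitation
  l <- state$fiber_length; v <- state$fiber_velocity
  f <- params$fast_twitch_fraction
  S <- params$aerobic_scale
  m <- params$muscle_mass
  A <- ifelse(u > a, u, (u + a) / 2)
  A_am <- A^0.6
  fl <- ifelse(l > 1, force_length_factor(l), 1)

  h_am_base <- 128 * f + 25                       # W / kg muscle
  hA <- 0.4 * h_am_base * A_am * S * m
  hM <- (0.6 * h_am_base * A_am * fl +
           if (params$include_basal) 1.2 else 0) * S * m

  vmax <- params$max_shortening_velocity
  vmax_st <- vmax / 2.5
  alpha_st <- 100 / vmax_st
  alpha_ft <- 153 / vmax
  v_st <- pmax(v, -vmax_st)                       # slow-twitch saturation
  h_sl_short <- -(alpha_st * (1 - f) * v_st + alpha_ft * f * v) * A^2
  h_sl_len <- 4 * alpha_st * v * A
  hSL <- ifelse(v <= 0, h_sl_short, h_sl_len) * fl * S * m

  w <- -state$active_force * v * params$optimal_fiber_length
  total_raw <- w + hA + hM + hSL
  total <- if (params$clamp_total_nonnegative) pmax(total_raw, 0) else
    total_raw
  structure(list(w_dot = w, hA_dot = hA, hM_dot = hM, hSL_dot = hSL,
                 total = total), class = "heat_rates")
}

#' Integrate muscle energy rates over one stride
#'
#' Sums the total rates across muscles at each sample, integrates over the
#' stride by trapezoidal quadrature, and divides by the stride duration to
#' give a mean rate; optionally divides by body mass for W/kg reporting.
#'
#' @param rates A numeric matrix (samples x muscles) of total rates in W,
#'   or a list of equal-length numeric vectors, one per muscle.
#' @param T_stride Stride duration in s.
#' @param body_mass Body mass in kg, or `NULL` for whole-body W.
#' @return Scalar mean metabolic rate (W, or W/kg if `body_mass` given).
#' @export
integrate_cost_rate <- function(rates, T_stride, body_mass = NULL) {
  if (is.list(rates)) {
    n <- unique(vapply(rates, length, integer(1)))
    if (length(n) != 1L)
      stop("muscle rate series have mismatched lengths: ",
           paste(vapply(rates, length, integer(1)), collapse = ", "),
           call. = FALSE)
    rates <- do.call(cbind, rates)
  }
  total <- rowSums(as.matrix(rates))
  tt <- seq(0, T_stride, length.out = length(total))
  out <- pracma::trapz(tt, total) / T_stride
  if (!is.null(body_mass)) out <- out / body_mass
  out
}

#' Muscle heat-rate cost model for stride comparisons
#'
#' Wraps [umberger_heat_rates()] into a cost model usable with
#' [estimate_methods()]. For each muscle `m` the stride must carry state
#' channels named `<m>_activation`, `<m>_fiber_length`,
#' `<m>_fiber_velocity`, and optionally `<m>_excitation` (defaults to the
#' activation) and `<m>_active_force` (defaults to
#' `max_isometric_force x activation x force-length factor`), as produced
#' by [generate_muscle_states()].
#'
#' @param muscles List of [muscle_params()] with distinct names.
#' @param body_mass Body mass in kg for W/kg reporting, or `NULL`.
#' @return An object of class `c("muscle_cost_model", "cost_model")`.
#' @export
muscle_cost_model <- function(muscles, body_mass = NULL) {
  if (inherits(muscles, "muscle_params")) muscles <- list(muscles)
  stopifnot(all(vapply(muscles, inherits, logical(1), "muscle_params")))
  names(muscles) <- vapply(muscles, `[[`, character(1), "name")
  structure(list(muscles = muscles, body_mass = body_mass),
            class = c("muscle_cost_model", "cost_model"))
}

#' @export
stride_cost.muscle_cost_model <- function(model, stride, ...) {
  get_ch <- function(nm) {
    ch <- stride$channels[[nm]]
    if (is.null(ch)) NULL else ch$samples
  }
  rates <- lapply(model$muscles, function(mp) {
    act <- get_ch(paste0(mp$name, "_activation"))
    if (is.null(act))
      stop("missing state channel '", mp$name, "_activation'", call. = FALSE)
    len <- get_ch(paste0(mp$name, "_fiber_length"))
    vel <- get_ch(paste0(mp$name, "_fiber_velocity"))
    if (is.null(len) || is.null(vel))
      stop("missing fibre length/velocity channels for '", mp$name, "'",
           call. = FALSE)
    exc <- get_ch(paste0(mp$name, "_excitation"))
    if (is.null(exc)) exc <- act
    frc <- get_ch(paste0(mp$name, "_active_force"))
    if (is.null(frc))
      frc <- mp$max_isometric_force * act * force_length_factor(len)
    st <- muscle_state(pmin(pmax(act, 0), 1), pmin(pmax(exc, 0), 1),
                       len, vel, frc)
    umberger_heat_rates(st, mp)$total
  })
  integrate_cost_rate(rates, stride$duration, model$body_mass)
}

#' Read cost-model parameters from a YAML or JSON config file
#'
#' The config carries either a `torque` block (`joint_names`, `a`) or a
#' `muscles` list of [muscle_params()] fields (plus an optional top-level
#' `body_mass`), and is turned into the corresponding cost model.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A cost model object.
#' @export
read_model_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE,
                        simplifyDataFrame = FALSE)
  else yaml::read_yaml(path)
  if (!is.null(cfg$torque)) {
    return(torque_cost_model(joint_names = cfg$torque$joint_names,
                             a = if (is.null(cfg$torque$a)) 1 else
                               cfg$torque$a))
  }
  if (!is.null(cfg$muscles)) {
    ms <- lapply(cfg$muscles, function(m) do.call(muscle_params, m))
    return(muscle_cost_model(ms, body_mass = cfg$body_mass))
  }
  stop("config must contain a 'torque' or 'muscles' block", call. = FALSE)
}
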