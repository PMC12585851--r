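#' @section Model:
#' The walker is the minimal point-mass, massless-leg compass model in
#' nondimensional units (mass, gravity and leg length all 1): stance is an
#' inverted pendulum `theta'' = sin(theta)` with `theta` the stance-leg
#' angle from vertical (negative behind, positive ahead), and the
#' step-to-step transition is an impulsive push-off `P` along the trailing
#' leg followed immediately by a heel-strike impulse that removes the
#' velocity component along the new leg. With inter-leg angle `2 alpha`
#' (step length `s = 2 sin(alpha)`), the pre- to post-transition speed map
#' is `v+ = v- cos(2 alpha) + P sin(2 alpha)`, push-off work is `P^2 / 2`,
#' and the heel-strike loss is `(v- sin(2 alpha) - P cos(2 alpha))^2 / 2`.
#' @name pendulum-model
#' @keywords internal
NULL

# cached Gauss-Legendre nodes on [-1, 1]
.walker_env <- new.env(parent = emptyenv())
gl_nodes <- function(n = 40) {
  key <- paste0("gl", n)
  if (is.null(.walker_env[[key]]))
    .walker_env[[key]] <- pracma::gaussLegendre(n, -1, 1)
  .walker_env[[key]]
}

# Stance duration from theta = -a0 to theta = +a1 given mid-stance speed,
# via the conserved energy thetadot(theta) = sqrt(v_ms^2 + 2(1 - cos theta))
# and fixed-order Gauss-Legendre quadrature of dt = dtheta / thetadot.
stance_duration <- function(v_ms, a0, a1, n_nodes = 40) {
  gl <- gl_nodes(n_nodes)
  half_span <- (a0 + a1) / 2
  th <- half_span * gl$x + (a1 - a0) / 2
  sum(gl$w / sqrt(v_ms^2 + 2 * (1 - cos(th)))) * half_span
}

#' Walker configuration
#'
#' Parameters of the feedback-controlled inverted-pendulum walker. All
#' quantities are nondimensional (lengths in leg lengths, speeds in
#' `sqrt(g l)`, time in `sqrt(l / g)`, impulses per unit mass, energies in
#' `m g l`). The swing cost per step is `c_sw * (1 / T_step)^q`; the
#' default coefficient is calibrated so that the energy-optimal gait at
#' speed 0.4 has a human-like step length of 0.6 leg lengths. Controller
#' gains left `NULL` are computed at setup as the minimum-norm pair that
#' deadbeats the linearized mid-stance-speed deviation in one step.
#'
#' @param target_speed Mean forward speed of the nominal gait.
#' @param swing_cost_coef,swing_cost_exponent Swing cost `c_sw` and
#'   exponent `q` (defaults 0.0176555362 and 3).
#' @param k_P,k_s Push-off and step-length feedback gains per unit sensed
#'   speed deviation, or `NULL` for the deadbeat defaults.
#' @param sigma_sense SD of Gaussian sensory noise added to the sensed
#'   mid-stance speed.
#' @param sigma_P,sigma_s SDs of Gaussian motor noise added to the
#'   commanded push-off impulse and step length.
#' @param n_steps Number of steps to simulate (default 2000).
#' @param seed Integer seed for the noise stream.
#' @param s_bounds Admissible step-length interval; commands outside it are
#'   clipped and counted.
#' @return An object of class `"walker_params"`.
#' @export
walker_params <- function(target_speed = 0.4,
                          swing_cost_coef = 0.0176555362,
                          swing_cost_exponent = 3,
                          k_P = NULL, k_s = NULL,
                          sigma_sense = 0, sigma_P = 0, sigma_s = 0,
                          n_steps = 2000, seed = 1,
                          s_bounds = c(0.05, 1.95)) {
  stopifnot(target_speed > 0, swing_cost_coef >= 0,
            sigma_sense >= 0, sigma_P >= 0, sigma_s >= 0, n_steps >= 1)
  structure(list(target_speed = target_speed,
                 swing_cost_coef = swing_cost_coef,
                 swing_cost_exponent = swing_cost_exponent,
                 k_P = k_P, k_s = k_s,
                 sigma_sense = sigma_sense, sigma_P = sigma_P,
                 sigma_s = sigma_s,
                 n_steps = as.integer(n_steps), seed = as.integer(seed),
                 s_bounds = s_bounds,
                 nominal = NULL),
            class = "walker_params")
}

#' Integrate one stance phase of the inverted pendulum
#'
#' Integrates `theta'' = sin(theta)` from `(theta0, thetadot0)` until the
#' stance angle reaches `theta_trigger` (the inter-leg trigger for the next
#' heel strike), using `deSolve::lsodar` with event (root) detection. The
#' mid-stance (`theta = 0`) speed is reported from the detected crossing;
#' a fall is flagged if the angular speed reaches zero before the trigger.
#'
#' @param theta0,thetadot0 Initial angle (rad) and angular speed
#'   (`thetadot0 > 0`, forward progress).
#' @param theta_trigger Terminal stance angle (rad, `> theta0`).
#' @param rtol,atol Integration tolerances.
#' @return A list: `trajectory` (data.frame `time`, `theta`, `thetadot`),
#'   `mid_stance_speed` (`NA` if `theta0 > 0`), `duration`, `fell`.
#' @export
integrate_stance <- function(theta0, thetadot0, theta_trigger,
                             rtol = 1e-10, atol = 1e-12) {
  stopifnot(thetadot0 > 0, theta_trigger > theta0)
  deriv <- function(t, y, p) list(c(y[2], sin(y[1])))
  run_until <- function(y0, rootfun, t_max = 50) {
    out <- deSolve::lsodar(y = y0, times = seq(0, t_max, by = 0.01),
                           func = deriv, rootfunc = rootfun,
                           rtol = rtol, atol = atol)
    out
  }
  v_ms <- NA_real_
  traj <- NULL
  t_off <- 0
  y <- c(theta0, thetadot0)
  if (theta0 < 0) {
    out <- run_until(y, function(t, y, p) c(y[1], y[2]))
    if (nrow(out) < 1L || is.null(attr(out, "troot")))
      stop("stance integration failed before mid-stance", call. = FALSE)
    traj <- out
    y <- as.numeric(out[nrow(out), 2:3])
    t_off <- out[nrow(out), 1]
    if (abs(y[2]) < 1e-9 || y[1] < -1e-9) {     # speed hit zero first
      tr <- as.data.frame(traj)
      names(tr) <- c("time", "theta", "thetadot")
      return(list(trajectory = tr, mid_stance_speed = NA_real_,
                  duration = t_off, fell = TRUE))
    }
    v_ms <- y[2]
  } else if (theta0 == 0) v_ms <- thetadot0
  out <- run_until(y, function(t, y, p) c(y[1] - theta_trigger, y[2]))
  out[, 1] <- out[, 1] + t_off
  traj <- if (is.null(traj)) out else rbind(traj, out[-1L, , drop = FALSE])
  yf <- as.numeric(out[nrow(out), 2:3])
  fell <- abs(yf[1] - theta_trigger) > 1e-6
  tr <- as.data.frame(traj)
  names(tr) <- c("time", "theta", "thetadot")
  list(trajectory = tr, mid_stance_speed = unname(v_ms),
       duration = unname(out[nrow(out), 1]), fell = fell)
}

#' Apply an impulsive step-to-step transition
#'
#' Push-off impulse `P` along the trailing leg, applied just before heel
#' strike, followed by the heel-strike impulse along the new leg.
#'
#' @param v_minus Pre-transition speed (perpendicular to the trailing leg),
#'   `> 0`.
#' @param alpha Half the inter-leg angle (rad).
#' @param P Push-off impulse, `>= 0`.
#' @return A list: `v_plus` (post-transition speed), `pushoff_work`
#'   (`P^2 / 2`), `heelstrike_loss`.
#' @export
apply_step_transition <- function(v_minus, alpha, P) {
  stopifnot(v_minus > 0, P >= 0)
  two_a <- 2 * alpha
  v_plus <- v_minus * cos(two_a) + P * sin(two_a)
  list(v_plus = v_plus,
       pushoff_work = P^2 / 2,
       heelstrike_loss = (v_minus * sin(two_a) - P * cos(two_a))^2 / 2)
}

#' Find the energy-optimal nominal gait at a target speed
#'
#' Minimizes the per-time cost (push-off work plus swing cost per step,
#' divided by step time) over period-1 periodic gaits of the noise-free
#' walker, subject to mean forward speed equal to `target_speed` (met to
#' 1e-6 by the inner root solve). Periodicity fixes the push-off at
#' `P = v- tan(alpha)`, which returns the walker to the same mid-stance
#' speed every step, so the search is one-dimensional in step length.
#'
#' @param target_speed Mean forward speed (step length / step time).
#' @param params A [walker_params()] (supplies the swing cost).
#' @param s_range Step-length search interval.
#' @return A list: `s_star`, `P_star`, `alpha_star`, `v_ms_star` (the
#'   nominal mid-stance speed, also the controller set point),
#'   `v_minus_star`, `T_step`, `baseline_cost_rate`.
#' @export
find_nominal_gait <- function(target_speed = 0.4,
                              params = walker_params(target_speed),
                              s_range = c(0.05, 1.5)) {
  c_sw <- params$swing_cost_coef
  q <- params$swing_cost_exponent
  solve_vms <- function(s) {
    a <- asin(s / 2)
    T_req <- s / target_speed
    stats::uniroot(function(vm) stance_duration(vm, a, a) - T_req,
                   c(1e-8, 50), tol = 1e-13)$root
  }
  rate <- function(s) {
    a <- asin(s / 2)
    vm <- solve_vms(s)
    v_minus <- sqrt(vm^2 + 2 * (1 - cos(a)))
    P <- v_minus * tan(a)
    T_req <- s / target_speed
    (P^2 / 2 + c_sw * T_req^(-q)) / T_req
  }
  opt <- stats::optimize(rate, s_range, tol = 1e-9)
  s_star <- opt$minimum
  a_star <- asin(s_star / 2)
  vm_star <- solve_vms(s_star)
  v_minus <- sqrt(vm_star^2 + 2 * (1 - cos(a_star)))
  list(s_star = s_star, P_star = v_minus * tan(a_star),
       alpha_star = a_star, v_ms_star = vm_star, v_minus_star = v_minus,
       T_step = s_star / target_speed, baseline_cost_rate = opt$objective)
}

# One-step mid-stance-speed map of the noise-free closed loop, used for
# gain design: current mid-stance speed -> next mid-stance speed.
stride_map <- function(v_ms, nom, k_P, k_s, s_bounds) {
  dv <- v_ms - nom$v_ms_star
  P <- max(nom$P_star + k_P * dv, 0)
  s <- min(max(nom$s_star + k_s * dv, s_bounds[1]), s_bounds[2])
  a <- asin(s / 2)
  v_minus <- sqrt(v_ms^2 + 2 * (1 - cos(a)))
  v_plus <- v_minus * cos(2 * a) + P * sin(2 * a)
  vms2 <- v_plus^2 - 2 * (1 - cos(a))
  if (vms2 <= 0) return(NA_real_)
  sqrt(vms2)
}

#' Prepare a walker for simulation
#'
#' Solves the nominal gait for `params$target_speed` and, if gains were not
#' given, computes the deadbeat defaults: with partial derivatives
#' `F_v, F_P, F_s` of the one-step mid-stance-speed map (by central finite
#' differences at the nominal gait), the minimum-norm gain pair solving
#' `F_v + F_P k_P + F_s k_s = 0` is used, which drives a linearized speed
#' deviation to zero in a single step.
#'
#' @param params A [walker_params()].
#' @return `params` with `nominal`, `k_P`, `k_s` filled in.
#' @export
setup_walker <- function(params) {
  stopifnot(inherits(params, "walker_params"))
  nom <- find_nominal_gait(params$target_speed, params)
  if (is.null(params$k_P) || is.null(params$k_s)) {
    h <- 1e-6
    step_from <- function(v, P_off = 0, s_off = 0) {
      P <- nom$P_star + P_off
      s <- nom$s_star + s_off
      a <- asin(s / 2)
      v_minus <- sqrt(v^2 + 2 * (1 - cos(a)))
      v_plus <- v_minus * cos(2 * a) + P * sin(2 * a)
      sqrt(v_plus^2 - 2 * (1 - cos(a)))
    }
    F_v <- (step_from(nom$v_ms_star + h) - step_from(nom$v_ms_star - h)) /
      (2 * h)
    F_P <- (step_from(nom$v_ms_star, P_off = h) -
              step_from(nom$v_ms_star, P_off = -h)) / (2 * h)
    F_s <- (step_from(nom$v_ms_star, s_off = h) -
              step_from(nom$v_ms_star, s_off = -h)) / (2 * h)
    denom <- F_P^2 + F_s^2
    params$k_P <- -F_v * F_P / denom
    params$k_s <- -F_v * F_s / denom
  }
  params$nominal <- nom
  params
}

#' Feedback control law for one step
#'
#' Computes the commanded push-off impulse and step length from the sensed
#' mid-stance speed: nominal command plus gain times the sensed speed
#' deviation, plus Gaussian motor noise. The sensed speed itself is the
#' true mid-stance speed plus Gaussian sensory noise. Noise values are
#' drawn from the current RNG stream (seed it before calling).
#'
#' @param v_ms True mid-stance speed.
#' @param params A set-up [walker_params()] (see [setup_walker()]).
#' @return A list: `v_hat` (sensed speed), `P_command`, `s_command`
#'   (after clipping to `params$s_bounds`), `clipped` (flag).
#' @export
control_law <- function(v_ms, params) {
  nom <- params$nominal
  if (is.null(nom)) stop("walker not set up; call setup_walker()",
                         call. = FALSE)
  v_hat <- v_ms + params$sigma_sense * stats::rnorm(1)
  dv <- v_hat - nom$v_ms_star
  P <- nom$P_star + params$k_P * dv + params$sigma_P * stats::rnorm(1)
  s <- nom$s_star + params$k_s * dv + params$sigma_s * stats::rnorm(1)
  s_cl <- min(max(s, params$s_bounds[1]), params$s_bounds[2])
  list(v_hat = v_hat, P_command = max(P, 0), s_command = s_cl,
       clipped = (s != s_cl))
}

#' Simulate a noisy walk
#'
#' Runs `params$n_steps` steps of the feedback-controlled walker from the
#' nominal gait, with seeded Gaussian sensory and motor noise (three draws
#' per step in a fixed order, so identical seeds give identical runs).
#' Stance speeds are propagated through the conserved pendulum energy and
#' stance durations by fixed-order Gauss-Legendre quadrature, which agree
#' with direct integration of the stance ODE to near machine precision.
#' A step on which the walker fails to pass mid-stance (or moves backward
#' after the transition) is a fall: it is recorded, the walker is reset to
#' the nominal state, and the run continues.
#'
#' @param params A [walker_params()]; set up automatically if needed.
#' @return An object of class `"walk_sim_result"`: `steps` (data.frame of
#'   per-step records: `v_ms`, `v_hat`, `P`, `s`, `step_duration`,
#'   `pushoff_work`, `heelstrike_loss`, `swing_cost`, `step_cost`, `fell`),
#'   `mean_cost_rate` (total cost / total time over completed steps),
#'   `sd_step_cost`, `baseline_cost_rate` (deterministic no-noise rate),
#'   `normalized_mean`, `normalized_sd` (mean and SD as multiples of the
#'   baseline), `n_falls`, `n_clipped`.
#' @export
simulate_walk <- function(params) {
  if (is.null(params$nominal)) params <- setup_walker(params)
  nom <- params$nominal
  n <- params$n_steps
  set.seed(params$seed)
  z <- matrix(stats::rnorm(3L * n), ncol = 3L)   # sense, P, s per step
  c_sw <- params$swing_cost_coef
  q <- params$swing_cost_exponent
  v_ms <- numeric(n); v_hat <- numeric(n); P_r <- numeric(n)
  s_r <- numeric(n); dur <- numeric(n); po_w <- numeric(n)
  hs_l <- numeric(n); sw_c <- numeric(n); fell <- logical(n)
  n_clipped <- 0L
  alpha_prev <- nom$alpha_star
  v_plus <- nom$v_minus_star     # nominal gait is periodic: v+ = v-
  for (i in seq_len(n)) {
    vms2 <- v_plus^2 - 2 * (1 - cos(alpha_prev))
    if (vms2 <= 0) {             # cannot pass mid-stance: fall, reset
      fell[i] <- TRUE
      v_ms[i] <- NA_real_; v_hat[i] <- NA_real_
      P_r[i] <- NA_real_; s_r[i] <- NA_real_; dur[i] <- NA_real_
      po_w[i] <- NA_real_; hs_l[i] <- NA_real_; sw_c[i] <- NA_real_
      alpha_prev <- nom$alpha_star
      v_plus <- nom$v_minus_star
      next
    }
    v <- sqrt(vms2)
    vh <- v + params$sigma_sense * z[i, 1L]
    dv <- vh - nom$v_ms_star
    P <- max(nom$P_star + params$k_P * dv + params$sigma_P * z[i, 2L], 0)
    s <- nom$s_star + params$k_s * dv + params$sigma_s * z[i, 3L]
    s_cl <- min(max(s, params$s_bounds[1]), params$s_bounds[2])
    if (s_cl != s) n_clipped <- n_clipped + 1L
    a_next <- asin(s_cl / 2)
    v_minus <- sqrt(vms2 + 2 * (1 - cos(a_next)))
    T_i <- stance_duration(v, alpha_prev, a_next)
    tr <- apply_step_transition(v_minus, a_next, P)
    v_ms[i] <- v; v_hat[i] <- vh; P_r[i] <- P; s_r[i] <- s_cl
    dur[i] <- T_i; po_w[i] <- tr$pushoff_work; hs_l[i] <- tr$heelstrike_loss
    sw_c[i] <- c_sw * T_i^(-q)
    if (tr$v_plus <= 0) {        # walker knocked backward: fall, reset
      fell[i] <- TRUE
      alpha_prev <- nom$alpha_star
      v_plus <- nom$v_minus_star
    } else {
      alpha_prev <- a_next
      v_plus <- tr$v_plus
    }
  }
  step_cost <- po_w + sw_c
  ok <- !is.na(step_cost) & !fell
  mean_rate <- sum(step_cost[ok]) / sum(dur[ok])
  structure(list(
    steps = data.frame(v_ms = v_ms, v_hat = v_hat, P = P_r, s = s_r,
                       step_duration = dur, pushoff_work = po_w,
                       heelstrike_loss = hs_l, swing_cost = sw_c,
                       step_cost = step_cost, fell = fell),
    mean_cost_rate = mean_rate,
    sd_step_cost = stats::sd(step_cost[ok]),
    baseline_cost_rate = nom$baseline_cost_rate,
    normalized_mean = mean_rate / nom$baseline_cost_rate,
    normalized_sd = stats::sd(step_cost[ok]) /
      (nom$baseline_cost_rate * nom$T_step),
    n_falls = sum(fell), n_clipped = n_clipped,
    params = params), class = "walk_sim_result")
}

#' @export
print.walk_sim_result <- function(x, ...) {
  cat(sprintf(
    "<walk_sim_result> %d steps, mean cost rate %.6g (x%.4f baseline), %d falls\n",
    nrow(x$steps), x$mean_cost_rate, x$normalized_mean, x$n_falls))
  invisible(x)
}

#' Sweep noise level and measure the cost of variability
#'
#' Runs [simulate_walk()] at each noise SD in `noise_grid` (which must
#' include 0), in either motor mode (noise on push-off and foot placement,
#' `sigma_P = sigma_s = sigma`) or sensory mode (noise on the sensed
#' mid-stance speed). Each level uses a fresh sub-seed derived from `seed`.
#' Mean cost rate and per-step cost SD are normalized by the deterministic
#' zero-noise baseline.
#'
#' @param params A [walker_params()].
#' @param noise_grid Noise SDs, including 0.
#' @param mode `"motor"` or `"sensory"`.
#' @return A data.frame with columns `mode`, `sigma`, `mean_cost_rate`,
#'   `sd_step_cost`, `normalized_mean`, `normalized_sd`, `n_falls`.
#' @export
noise_sweep <- function(params = walker_params(),
                        noise_grid = c(0, 0.005, 0.01, 0.02, 0.04),
                        mode = c("motor", "sensory")) {
  mode <- match.arg(mode)
  if (!any(noise_grid == 0))
    stop("noise_grid must include 0 (the baseline)", call. = FALSE)
  if (is.null(params$nominal)) params <- setup_walker(params)
  rows <- lapply(seq_along(noise_grid), function(i) {
    sg <- noise_grid[[i]]
    p <- params
    if (mode == "motor") {
      p$sigma_P <- sg; p$sigma_s <- sg; p$sigma_sense <- 0
    } else {
      p$sigma_sense <- sg; p$sigma_P <- 0; p$sigma_s <- 0
    }
    p$seed <- (params$seed + 7919L * i) %% 2147483647L
    r <- simulate_walk(p)
    data.frame(mode = mode, sigma = sg, mean_cost_rate = r$mean_cost_rate,
               sd_step_cost = r$sd_step_cost,
               normalized_mean = r$normalized_mean,
               normalized_sd = r$normalized_sd, n_falls = r$n_falls)
  })
  do.call(rbind, rows)
}
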