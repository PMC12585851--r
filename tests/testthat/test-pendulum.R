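test_that("stance integration conserves pendulum energy and finds mid-stance", {
  st <- integrate_stance(-0.3, 0.6, 0.3)
  E <- 0.5 * st$trajectory$thetadot^2 + cos(st$trajectory$theta)
  expect_lt(max(abs(E - E[1])), 1e-8)
  expect_false(st$fell)
  # closed-form mid-stance speed from the conserved energy
  v_closed <- sqrt(0.6^2 - 2 * (1 - cos(0.3)))
  expect_equal(st$mid_stance_speed, v_closed, tolerance = 1e-8)

  # starting at mid-stance reports the initial speed
  st0 <- integrate_stance(0, 0.4, 0.3)
  expect_equal(st0$mid_stance_speed, 0.4)

  # too slow to pass mid-stance: flagged as a fall
  stf <- integrate_stance(-0.3, 0.05, 0.3)
  expect_true(stf$fell)
})

test_that("quadrature stance durations agree with the integrated ODE", {
  st <- integrate_stance(-0.25, 0.55, 0.35, rtol = 1e-12, atol = 1e-13)
  v_ms <- sqrt(0.55^2 - 2 * (1 - cos(0.25)))
  expect_equal(stridecost:::stance_duration(v_ms, 0.25, 0.35), st$duration,
               tolerance = 1e-8)
})

test_that("transition algebra matches the vector-projection closed forms", {
  # no push-off: pure heel-strike projection
  for (v in c(0.3, 0.5)) for (al in c(0.2, 0.35)) {
    tr <- apply_step_transition(v, al, 0)
    expect_equal(tr$v_plus, v * cos(2 * al), tolerance = 1e-12)
    expect_equal(tr$heelstrike_loss, 0.5 * v^2 * sin(2 * al)^2,
                 tolerance = 1e-12)
  }
  # collinear legs, no push-off: nothing happens
  tr0 <- apply_step_transition(0.4, 0, 0)
  expect_equal(tr0$v_plus, 0.4)
  expect_equal(tr0$heelstrike_loss, 0)
  # steady gait: P = v tan(alpha) preserves speed, work balances loss
  v <- 0.45; al <- 0.3
  tr <- apply_step_transition(v, al, v * tan(al))
  expect_equal(tr$v_plus, v, tolerance = 1e-12)
  expect_equal(tr$pushoff_work, tr$heelstrike_loss, tolerance = 1e-12)
  # energy bookkeeping: KE+ = KE- + work - loss
  set.seed(5)
  for (i in 1:20) {
    v <- runif(1, 0.2, 0.8); al <- runif(1, 0.1, 0.5); P <- runif(1, 0, 0.4)
    tr <- apply_step_transition(v, al, P)
    expect_equal(0.5 * tr$v_plus^2,
                 0.5 * v^2 + tr$pushoff_work - tr$heelstrike_loss,
                 tolerance = 1e-10)
  }
})

test_that("nominal gait is a periodic local optimum at the target speed", {
  p <- setup_walker(walker_params(target_speed = 0.4, n_steps = 50, seed = 2))
  nom <- p$nominal
  # speed constraint met
  expect_equal(nom$s_star / nom$T_step, 0.4, tolerance = 1e-6)
  # fixed point: 50 noise-free steps with constant per-step cost
  r <- simulate_walk(p)
  expect_lte(diff(range(r$steps$step_cost)), 1e-8)
  expect_equal(r$normalized_mean, 1, tolerance = 1e-8)
  # perturbing step length (re-solving the periodic gait at the same
  # speed) never lowers the cost rate
  rate_at <- function(s) {
    a <- asin(s / 2)
    T_req <- s / 0.4
    vm <- uniroot(function(v) stridecost:::stance_duration(v, a, a) - T_req,
                  c(1e-8, 50), tol = 1e-13)$root
    v_minus <- sqrt(vm^2 + 2 * (1 - cos(a)))
    P <- v_minus * tan(a)
    (P^2 / 2 + p$swing_cost_coef * T_req^(-p$swing_cost_exponent)) / T_req
  }
  expect_gte(rate_at(nom$s_star * 1.1), nom$baseline_cost_rate - 1e-12)
  expect_gte(rate_at(nom$s_star * 0.9), nom$baseline_cost_rate - 1e-12)
  # re-solving from a different search interval agrees
  nom2 <- find_nominal_gait(0.4, p, s_range = c(0.2, 1.2))
  expect_equal(nom2$baseline_cost_rate, nom$baseline_cost_rate,
               tolerance = 1e-6)
  expect_equal(nom2$s_star, nom$s_star, tolerance = 1e-4)
})

test_that("control law returns nominal commands at the set point", {
  p <- setup_walker(walker_params())
  set.seed(1)
  cl <- control_law(p$nominal$v_ms_star, p)
  expect_equal(cl$P_command, p$nominal$P_star)
  expect_equal(cl$s_command, p$nominal$s_star)
  expect_false(cl$clipped)
  # open loop: zero gains ignore the sensed speed
  p0 <- p; p0$k_P <- 0; p0$k_s <- 0
  cl2 <- control_law(p$nominal$v_ms_star + 0.1, p0)
  expect_equal(cl2$P_command, p$nominal$P_star)
})

test_that("default gains deadbeat the linearized stride map", {
  p <- setup_walker(walker_params())
  f <- function(v) stridecost:::stride_map(v, p$nominal, p$k_P, p$k_s,
                                           p$s_bounds)
  h <- 1e-5
  slope <- (f(p$nominal$v_ms_star + h) - f(p$nominal$v_ms_star - h)) / (2 * h)
  expect_lt(abs(slope), 1e-3)     # spectral radius ~ 0 << 1
  # an injected deviation decays rapidly
  v1 <- f(p$nominal$v_ms_star + 0.02)
  expect_lt(abs(v1 - p$nominal$v_ms_star), 0.002)
  v2 <- f(v1)
  expect_lt(abs(v2 - p$nominal$v_ms_star), abs(v1 - p$nominal$v_ms_star))
})

test_that("noise-free walking is deterministic; seeds reproduce runs", {
  p <- setup_walker(walker_params(n_steps = 50, seed = 7))
  r <- simulate_walk(p)
  expect_lte(r$sd_step_cost, 1e-8)
  expect_equal(r$n_falls, 0L)
  # all step records identical
  expect_true(all(vapply(r$steps, function(col) length(unique(col)) == 1L,
                         logical(1))))
  p2 <- p; p2$sigma_P <- 0.01; p2$sigma_s <- 0.01; p2$n_steps <- 200L
  ra <- simulate_walk(p2)
  rb <- simulate_walk(p2)
  expect_identical(ra$steps, rb$steps)
  expect_identical(ra$mean_cost_rate, rb$mean_cost_rate)
})

test_that("small motor noise raises cost above the baseline across seeds", {
  p <- setup_walker(walker_params(n_steps = 2000))
  for (s in 1:10) {
    p$seed <- 300L + s
    p$sigma_P <- 0.01; p$sigma_s <- 0.01
    r <- simulate_walk(p)
    expect_gt(r$mean_cost_rate, r$baseline_cost_rate)
  }
})

test_that("noise sweeps normalize the zero-noise row to (1, 0)", {
  p <- setup_walker(walker_params(n_steps = 300, seed = 17))
  sw <- noise_sweep(p, noise_grid = c(0, 0.01, 0.03), mode = "motor")
  expect_equal(sw$normalized_mean[sw$sigma == 0], 1, tolerance = 1e-8)
  expect_lte(sw$normalized_sd[sw$sigma == 0], 1e-8)
  expect_error(noise_sweep(p, noise_grid = c(0.01, 0.02)), "include 0")
})
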