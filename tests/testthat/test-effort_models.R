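test_that("torque-squared cost matches closed forms", {
  z <- const_torque_stride(0)
  expect_equal(torque_squared_cost(z), 0)

  expect_equal(torque_squared_cost(const_torque_stride(2)), 4,
               tolerance = 1e-12)

  # tau(t) = sin(2 pi t / T): time-average of sin^2 is 1/2
  t <- seq(0, 1, by = 0.01)
  s <- make_stride(list(ankle_moment_r = sin(2 * pi * t)))
  expect_equal(torque_squared_cost(s), 0.5, tolerance = 1e-6)

  # multiple joints with coefficients
  s2 <- make_stride(list(ankle_moment_r = rep(1, 101),
                         knee_moment_r = rep(2, 101)))
  m <- torque_cost_model(c("ankle_moment_r", "knee_moment_r"), a = c(1, 3))
  expect_equal(torque_squared_cost(s2, m), 1 + 3 * 4, tolerance = 1e-12)
  expect_error(
    torque_squared_cost(s, torque_cost_model("hip_moment_r")),
    "hip_moment_r")
})

test_that("torque cost is sign-invariant, quadratic in scale, convex", {
  set.seed(7)
  tau <- rnorm(120, 0, 40)
  base <- torque_squared_cost(make_stride(list(x_moment = tau)))
  expect_equal(torque_squared_cost(make_stride(list(x_moment = -tau))), base,
               tolerance = 1e-12)
  expect_equal(torque_squared_cost(make_stride(list(x_moment = 3 * tau))),
               9 * base, tolerance = 1e-10)
  # convexity: cost of pointwise mean <= mean of costs, random pairs
  for (i in 1:20) {
    a <- rnorm(90, 0, 30); b <- rnorm(90, 0, 30)
    ca <- torque_squared_cost(make_stride(list(x_moment = a)))
    cb <- torque_squared_cost(make_stride(list(x_moment = b)))
    cm <- torque_squared_cost(make_stride(list(x_moment = (a + b) / 2)))
    expect_lte(cm, (ca + cb) / 2 + 1e-12)
  }
  # equality only for identical trajectories
  a <- rnorm(90)
  ca <- torque_squared_cost(make_stride(list(x_moment = a)))
  expect_equal(torque_squared_cost(make_stride(list(x_moment = a))), ca)
})

test_that("inactive muscle liberates no energy; total is the component sum", {
  p <- muscle_params(clamp_total_nonnegative = FALSE)
  hr0 <- umberger_heat_rates(muscle_state(0, 0, 1, 0, 0), p)
  expect_equal(unlist(hr0[c("w_dot", "hA_dot", "hM_dot", "hSL_dot", "total")]),
               c(w_dot = 0, hA_dot = 0, hM_dot = 0, hSL_dot = 0, total = 0))

  set.seed(12)
  st <- muscle_state(runif(50), runif(50), runif(50, 0.7, 1.4),
                     runif(50, -10, 5), runif(50, 0, 1500))
  hr <- umberger_heat_rates(st, p)
  expect_equal(hr$total, hr$w_dot + hr$hA_dot + hr$hM_dot + hr$hSL_dot,
               tolerance = 1e-12)
  # clamped variant never goes negative
  hr_cl <- umberger_heat_rates(st, muscle_params())
  expect_true(all(hr_cl$total >= 0))
})

test_that("heat rates match the independent oracle over a state grid", {
  set.seed(99)
  n <- 200
  a <- runif(n); u <- runif(n)
  l <- runif(n, 0.7, 1.4); v <- runif(n, -10, 5)
  frc <- runif(n, 0, 1500)
  for (clamp in c(TRUE, FALSE)) {
    p <- muscle_params(fast_twitch_fraction = 0.35, muscle_mass = 0.2,
                       aerobic_scale = 1.5, clamp_total_nonnegative = clamp)
    got <- umberger_heat_rates(muscle_state(a, u, l, v, frc), p)
    for (i in seq_len(n)) {
      want <- oracle_heat_rates(a[i], u[i], l[i], v[i], frc[i],
                                f_fast = 0.35, vmax = 12, lopt = 0.1,
                                mass = 0.2, S = 1.5, clamp = clamp)
      for (comp in names(want)) {
        expect_lt(abs(got[[comp]][i] - want[[comp]]),
                  1e-8 * max(abs(want[[comp]]), 1e-9))
      }
    }
  }
  # isometric spot value against the oracle
  p0 <- muscle_params()
  iso <- umberger_heat_rates(muscle_state(0.5, 0.5, 1, 0, 0), p0)
  want_iso <- oracle_heat_rates(0.5, 0.5, 1, 0, 0)
  expect_equal(iso$total, unname(want_iso["total"]), tolerance = 1e-8)
})

test_that("heat components are non-negative and continuous across v = 0", {
  p <- muscle_params(clamp_total_nonnegative = FALSE)
  set.seed(3)
  st <- muscle_state(runif(100), runif(100), runif(100, 0.6, 1.5),
                     runif(100, -12, 8), 0)
  hr <- umberger_heat_rates(st, p)
  expect_true(all(hr$hA_dot >= 0))
  expect_true(all(hr$hM_dot >= 0))
  expect_true(all(hr$hSL_dot >= 0))
  eps <- 1e-9
  left <- umberger_heat_rates(muscle_state(0.6, 0.6, 1.1, -eps, 100), p)
  right <- umberger_heat_rates(muscle_state(0.6, 0.6, 1.1, eps, 100), p)
  expect_lt(abs(left$total - right$total), 1e-5)
})

test_that("rate integration averages over time and sums across muscles", {
  expect_equal(integrate_cost_rate(list(rep(10, 50)), 1.2), 10)
  expect_equal(integrate_cost_rate(list(rep(10, 50), rep(5, 50)), 0.9), 15)
  tri <- c(seq(0, 10, length.out = 51), seq(10, 0, length.out = 51)[-1])
  expect_equal(integrate_cost_rate(list(tri), 1.0), 5, tolerance = 1e-9)
  expect_equal(integrate_cost_rate(list(rep(10, 50)), 1, body_mass = 70),
               10 / 70)
  expect_error(integrate_cost_rate(list(rep(1, 10), rep(1, 11)), 1),
               "mismatch")
})

test_that("muscle cost model evaluates generated state strides", {
  cfg <- synthetic_gait_config(seed = 77)
  ms <- generate_muscle_states(cfg, n_muscles = 2)
  model <- muscle_cost_model(list(muscle_params("m1"), muscle_params("m2")))
  cost <- stride_cost(model, ms[[1L]])
  expect_gt(cost, 0)
  # missing muscle channels are reported by name
  m3 <- muscle_cost_model(muscle_params("m9"))
  expect_error(stride_cost(m3, ms[[1L]]), "m9_activation")
})

test_that("model config files build the right cost models", {
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("torque:", "  joint_names: [ankle_moment_r]", "  a: [2.0]"),
             yml)
  m <- read_model_config(yml)
  expect_s3_class(m, "torque_cost_model")
  expect_equal(torque_squared_cost(const_torque_stride(1), m), 2,
               tolerance = 1e-12)

  js <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(
    body_mass = 70,
    muscles = list(list(name = "m1", muscle_mass = 0.3))),
    auto_unbox = TRUE), js)
  mm <- read_model_config(js)
  expect_s3_class(mm, "muscle_cost_model")
  expect_equal(mm$body_mass, 70)
  expect_equal(mm$muscles$m1$muscle_mass, 0.3)
})
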