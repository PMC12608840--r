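# Beam-equilibrium interface-pressure model.

test_that("a centred CoM gives a uniform restoring-force profile", {
  p <- beam_model_params(40, 50, com_y = 20)
  ys <- seq(0, 40, by = 5)
  expect_equal(restoring_force(p, ys), rep(50 * 9.80665 / 40, length(ys)))
})

test_that("force and torque equilibrium hold for random parameter draws", {
  set.seed(31)
  for (i in 1:1000) {
    L <- runif(1, 30, 55)
    m <- runif(1, 40, 110)
    com_y <- runif(1, 0.05 * L, 0.6 * L)
    p <- beam_model_params(L, m, com_y)
    # trapezoid quadrature is exact for an affine integrand's force
    # integral; the torque integrand is quadratic, so use Simpson weights
    ys <- seq(0, L, length.out = 2001)
    f <- restoring_force(p, ys)
    h <- ys[2] - ys[1]
    simpson <- function(v) {
      h / 3 * (v[1] + v[length(v)] +
                 4 * sum(v[seq(2, length(v) - 1, by = 2)]) +
                 2 * sum(v[seq(3, length(v) - 2, by = 2)]))
    }
    expect_equal(simpson(f), m * 9.80665, tolerance = 1e-9)
    expect_equal(simpson(f * ys), com_y * m * 9.80665, tolerance = 1e-9)
  }
})

test_that("the closed form matches the 2x2 linear solve of the
          equilibrium system", {
  L <- 40; m <- 50; com_y <- 12; g <- 9.80665
  # solve integral_0^L (a y + b) dy = m g ; integral (a y + b) y dy = CoM m g
  A <- matrix(c(L^2 / 2, L, L^3 / 3, L^2 / 2), 2, 2, byrow = TRUE)
  ab <- solve(A, c(m * g, com_y * m * g))
  p <- beam_model_params(L, m, com_y)
  expect_equal(restoring_force(p, 0), ab[2], tolerance = 1e-12)
  expect_equal(restoring_force(p, L), ab[1] * L + ab[2], tolerance = 1e-12)
})

test_that("evaluation outside the beam is a domain error", {
  p <- beam_model_params(40, 50, 12)
  expect_error(restoring_force(p, -1), "outside")
  expect_error(restoring_force(p, 41), "outside")
})

test_that("proportional pressure is 1 at no lean and matches the
          restoring-force ratio", {
  p <- beam_model_params(40, 50, com_y = 10, com_y0 = 10, y_eval = 0)
  expect_identical(proportional_pressure(p, 0), 1)
  # worked value at y = 0: 1 + 3/(3*10 - 2*40) * 1 = 0.94
  expect_equal(proportional_pressure(p, 1), 0.94)

  # restoring-force ratio oracle at arbitrary y_eval
  set.seed(37)
  for (i in 1:200) {
    L <- runif(1, 30, 55)
    com_y0 <- runif(1, 0.1 * L, 0.6 * L)
    y <- runif(1, 0, 0.45 * L)
    delta <- runif(1, 0, 2)
    pp <- beam_model_params(L, 60, com_y0, com_y0, y_eval = y)
    got <- proportional_pressure(pp, delta)
    want <- restoring_force(pp, y, com_y = com_y0 + delta) /
      restoring_force(pp, y, com_y = com_y0)
    expect_equal(got, max(0, want), tolerance = 1e-9)
  }
})

test_that("the hip-position reduction of the proportional-pressure slope
          holds exactly", {
  set.seed(41)
  for (i in 1:1000) {
    L <- runif(1, 30, 55)
    com_y0 <- runif(1, 0.05 * L, 0.64 * L)
    expect_equal(sipcop:::prop_pressure_slope(L, com_y0, 0),
                 3 / (3 * com_y0 - 2 * L), tolerance = 1e-12)
  }
})

test_that("proportional pressure is monotone nonincreasing and clipped at
          zero", {
  p <- beam_model_params(40, 50, 10, 10, y_eval = 0)
  deltas <- seq(0, 40, by = 0.5)
  vals <- proportional_pressure(p, deltas)
  expect_true(all(diff(vals) <= 0))
  expect_true(all(vals >= 0))
  expect_equal(proportional_pressure(p, 30), 0) # 1 - 0.06*30 < 0, clipped
})

test_that("theoretical slope: worked value, sign, and steepening with
          shorter legs", {
  a <- test_anthro(L = 40, com_y0 = 10, y_it = 0)
  expect_equal(theoretical_slope(a), -0.06)
  # finite-difference oracle on proportional_pressure
  p <- beam_model_params(40, a$body_mass, 10, 10, 0)
  h <- 1e-6
  fd <- (proportional_pressure(p, h) - proportional_pressure(p, 0)) / h
  expect_equal(theoretical_slope(a), fd, tolerance = 1e-6)

  set.seed(43)
  for (i in 1:100) {
    b <- random_anthro()
    expect_lt(theoretical_slope(b), 0)
  }
  s_long <- theoretical_slope(test_anthro(L = 46, com_y0 = 10, y_it = 0))
  s_short <- theoretical_slope(test_anthro(L = 38, com_y0 = 10, y_it = 0))
  expect_gt(abs(s_short), abs(s_long))
})

test_that("the sine coefficient is |T| t_m and matches the kinematics", {
  a <- test_anthro(trunk_z = 40, t_m = 0.5)
  expect_equal(theoretical_sine_coefficient(a), 20)
  expect_equal(theoretical_sine_coefficient(a),
               cop_magnitude_forward(a, pi / 2))
  # b sin(theta) reproduces the full-kinematics forward CoP_y change
  g <- test_geom()
  b <- theoretical_sine_coefficient(a)
  cop0 <- cop_from_com(body_com(a, lean_pose(0, 0)), g)
  for (th in deg2rad(c(5, 15, 25, 35, 45))) {
    cop1 <- cop_from_com(body_com(a, lean_pose(th, 0)), g)
    expect_equal(b * sin(th), cop1[2] - cop0[2], tolerance = 1e-9)
  }
})
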