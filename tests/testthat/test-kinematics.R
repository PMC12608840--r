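# Three-segment lean kinematics: rotations, CoP projection, closed forms.

# independent oracle: explicit 4x4 homogeneous transforms
hom_rot_x <- function(theta) {
  rbind(c(1, 0, 0, 0),
        c(0, cos(theta), sin(theta), 0),
        c(0, -sin(theta), cos(theta), 0),
        c(0, 0, 0, 1))
}
hom_rot_y_about <- function(phi, axis_point) {
  T1 <- diag(4); T1[1:3, 4] <- -axis_point
  T2 <- diag(4); T2[1:3, 4] <- axis_point
  R <- rbind(c(cos(phi), 0, -sin(phi), 0),
             c(0, 1, 0, 0),
             c(sin(phi), 0, cos(phi), 0),
             c(0, 0, 0, 1))
  T2 %*% R %*% T1
}
oracle_com <- function(anthro, theta, phi) {
  A <- hom_rot_y_about(phi, c(-anthro$hip_half_width, 0, 0))
  tr <- A %*% hom_rot_x(theta) %*% c(anthro$trunk_com, 1)
  lg <- A %*% c(anthro$upper_leg_com, 1)
  (tr[1:3] * anthro$trunk_mass_fraction +
      lg[1:3] * anthro$upper_leg_mass_fraction)
}

test_that("upright pose returns the weighted segment CoMs unchanged", {
  a <- test_anthro()
  expect_equal(body_com(a, lean_pose(0, 0)),
               a$trunk_com * a$trunk_mass_fraction +
                 a$upper_leg_com * a$upper_leg_mass_fraction)
})

test_that("a pure forward lean keeps the CoM at midline", {
  a <- test_anthro()
  for (th in c(0.1, 0.4, 1.0)) {
    expect_equal(body_com(a, lean_pose(th, 0))[1],
                 body_com(a, lean_pose(0, 0))[1])
  }
})

test_that("combined lean matches an independent homogeneous-matrix
          composition", {
  a <- test_anthro()
  expect_equal(body_com(a, lean_pose(deg2rad(20), deg2rad(15))),
               oracle_com(a, deg2rad(20), deg2rad(15)),
               tolerance = 1e-12)
  set.seed(11)
  for (i in 1:50) {
    b <- random_anthro()
    th <- runif(1, 0, 1.2)
    ph <- runif(1, 0, 1.2)
    expect_equal(body_com(b, lean_pose(th, ph)), oracle_com(b, th, ph),
                 tolerance = 1e-12)
  }
})

test_that("rotations are isometries of the segment vectors", {
  set.seed(3)
  for (i in 1:50) {
    a <- random_anthro()
    th <- runif(1, 0, 1.5)
    ph <- runif(1, 0, 1.5)
    # forward rotation preserves |T|
    tr <- sipcop:::rot_forward(a$trunk_com, th)
    expect_equal(sqrt(sum(tr^2)), sqrt(sum(a$trunk_com^2)),
                 tolerance = 1e-12)
    # lateral rotation preserves distance from its axis point
    ax <- c(-a$hip_half_width, 0, 0)
    lg <- sipcop:::rot_leftward(a$upper_leg_com, ph, a$hip_half_width)
    expect_equal(sqrt(sum((lg - ax)^2)),
                 sqrt(sum((a$upper_leg_com - ax)^2)), tolerance = 1e-12)
  }
})

test_that("CoP projection passes x through and offsets y", {
  g <- seat_geometry(body_origin_offset_y = 3)
  expect_equal(cop_from_com(c(0, 0, 30), g), c(0, 3))
  # left-right mirror symmetry
  com <- c(-4, 7, 30)
  mirrored <- com * c(-1, 1, 1)
  expect_equal(cop_from_com(mirrored, g)[1], -cop_from_com(com, g)[1])
})

test_that("the upright CoP sits at midline, slightly behind seat centre", {
  a <- test_anthro()
  cop <- cop_from_com(body_com(a, lean_pose(0, 0)), test_geom())
  expect_equal(cop[1], 0)
  expect_lt(cop[2], 0)
  expect_gt(cop[2], -test_geom()$depth_cm / 2)
})

test_that("forward closed form: endpoints and full-kinematics agreement", {
  a <- test_anthro()
  expect_equal(cop_magnitude_forward(a, 0), 0)
  expect_equal(cop_magnitude_forward(a, pi / 2),
               sqrt(sum(a$trunk_com^2)) * a$trunk_mass_fraction)
  g <- test_geom()
  th <- deg2rad(30)
  cop0 <- cop_from_com(body_com(a, lean_pose(0, 0)), g)
  cop1 <- cop_from_com(body_com(a, lean_pose(th, 0)), g)
  expect_equal(cop_magnitude_forward(a, th), sqrt(sum((cop1 - cop0)^2)),
               tolerance = 1e-12)
})

test_that("combined closed form reduces to the forward form at phi = 0", {
  set.seed(19)
  for (i in 1:1000) {
    a <- random_anthro()
    th <- runif(1, 0, pi / 2 * 0.99)
    expect_equal(cop_magnitude_combined(a, th, 0),
                 cop_magnitude_forward(a, th), tolerance = 1e-9)
  }
})

test_that("combined closed form matches the full kinematic pipeline and
          mirrors in phi", {
  g <- test_geom()
  set.seed(23)
  for (i in 1:200) {
    a <- test_anthro(trunk_z = runif(1, 35, 50), leg_y = runif(1, 15, 25),
                     t_m = runif(1, 0.5, 0.65), u_m = runif(1, 0.15, 0.25),
                     r = runif(1, 7, 11))
    th <- runif(1, 0, 1.2)
    ph <- runif(1, 0, 1.2)
    cop0 <- cop_from_com(body_com(a, lean_pose(0, 0)), g)
    cop1 <- cop_from_com(body_com(a, lean_pose(th, ph)), g)
    expect_equal(cop_magnitude_combined(a, th, ph),
                 sqrt(sum((cop1 - cop0)^2)), tolerance = 1e-9)
    expect_equal(cop_magnitude_combined(a, th, -ph),
                 cop_magnitude_combined(a, th, ph))
    expect_equal(cop_magnitude_combined(a, 0, 0), 0)
  }
})

test_that("forward CoP magnitude is nondecreasing in theta", {
  a <- test_anthro()
  th <- seq(0, pi / 2, length.out = 200)
  expect_true(all(diff(cop_magnitude_forward(a, th)) >= 0))
})

test_that("pose validation rejects out-of-range angles", {
  expect_error(lean_pose(pi / 2, 0), "theta")
  expect_error(lean_pose(0, -pi / 2), "phi")
})
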