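# Synthetic trial generator: corner forces, mat rendering, trials, cohorts.

test_that("corner forces: centred, edge, and round-trip inverse", {
  g <- test_geom()
  expect_equal(corner_forces_from_cop(400, c(0, 0), g),
               c(f_bl_n = 100, f_br_n = 100, f_fl_n = 100, f_fr_n = 100))
  edge <- corner_forces_from_cop(400, c(g$width_cm / 2, 0), g)
  expect_equal(unname(edge[c("f_bl_n", "f_fl_n")]), c(0, 0))
  expect_equal(unname(edge[c("f_br_n", "f_fr_n")]), c(200, 200))

  set.seed(47)
  for (i in 1:100) {
    cop <- c(runif(1, -19.9, 19.9), runif(1, -19.9, 19.9))
    ff <- corner_forces_from_cop(runif(1, 100, 900), cop, g)
    expect_true(all(ff >= 0))
    back <- cop_from_forces(as.data.frame(as.list(ff)), g)
    expect_equal(c(back$cop_x, back$cop_y), cop, tolerance = 1e-9)
  }
  expect_error(corner_forces_from_cop(400, c(25, 0), g), "outside")
})

test_that("mat frames render IT blocks, respect the ambient floor, and
          are seed-deterministic", {
  centers <- list(left = c(10, 6), right = c(10, 11))
  f1 <- render_mat_frame(1, 1, 60, centers, noise_sd = 0, ambient = 4)
  expect_equal(unique(as.vector(f1[10:11, 6:7])), 60)
  expect_equal(unique(as.vector(f1[10:11, 11:12])), 60)
  expect_equal(f1[1, 1], 4)

  f2 <- render_mat_frame(1, 0, 60, centers, noise_sd = 0, ambient = 4)
  expect_equal(unique(as.vector(f2[10:11, 11:12])), 4) # offloaded: ambient

  set.seed(5); fa <- render_mat_frame(1, 1, 60, centers, 1.5)
  set.seed(5); fb <- render_mat_frame(1, 1, 60, centers, 1.5)
  expect_identical(fa, fb)
  expect_true(all(fa >= 0))

  expect_error(render_mat_frame(1, 1, 60,
                                list(left = c(16, 6), right = c(10, 11))),
               "edge")
})

test_that("noiseless forward trials land on the closed-form CoP magnitude
          and are deterministic", {
  cfg <- noiseless_config()
  cond <- trial_condition("forward", "own", "backrest", 1, "P01")
  tr <- simulate_trial(cfg, cond)
  expect_equal(tr$truth$final_cop_mag,
               cop_magnitude_forward(cfg$anthro, deg2rad(40)),
               tolerance = 1e-9)
  expect_identical(tr, simulate_trial(cfg, cond))
  # a different repetition gets different noise but identical kinematics
  tr2 <- simulate_trial(simulation_config(test_anthro(), seed = 2),
                        cond)
  tr3 <- simulate_trial(simulation_config(test_anthro(), seed = 2),
                        trial_condition("forward", "own", "backrest", 2,
                                        "P01"))
  expect_false(identical(tr2$loadcell$f_bl_n, tr3$loadcell$f_bl_n))
})

test_that("corner forces conserve the modelled seat-borne weight at every
          sample", {
  cfg <- noiseless_config()
  tr <- simulate_trial(cfg, trial_condition("left"))
  total <- rowSums(tr$loadcell[, c("f_bl_n", "f_br_n", "f_fl_n",
                                   "f_fr_n")])
  expected <- tr$truth$seat_weight_n + tr$truth$cushion_mat_weight_n
  expect_equal(total, rep(expected, nrow(tr$loadcell)), tolerance = 1e-9)
})

test_that("trajectories steeper than the model domain are rejected", {
  expect_error(simulation_config(test_anthro(), max_angle_deg = 95),
               "max_angle_deg")
})

test_that("stream sample rates match their nominal values", {
  cfg <- noiseless_config()
  tr <- simulate_trial(cfg, trial_condition("forward"))
  expect_equal(median(diff(tr$loadcell$t_s)), 1 / 125)
  expect_equal(median(diff(tr$imu$t_s[tr$imu$sensor == "sternum"])),
               1 / 100)
  expect_equal(median(diff(tr$mat$t_s)), 1 / 15, tolerance = 1e-9)
})

test_that("cohorts have the expected size, varying slopes, and are
          seed-reproducible", {
  co <- make_cohort(n_participants = 3, seed = 9, repetitions = 3)
  expect_length(co$trials, 3 * 3 * 3) # participants x directions x reps
  expect_equal(nrow(co$ground_truth), 3)
  expect_gt(sd(co$ground_truth$forward_slope), 0)

  co2 <- make_cohort(n_participants = 3, seed = 9, repetitions = 3)
  expect_identical(co$ground_truth, co2$ground_truth)
  expect_identical(co$trials[[1]], co2$trials[[1]])
  expect_identical(co$trials[[length(co$trials)]],
                   co2$trials[[length(co2$trials)]])

  expect_error(make_cohort(n_participants = 1), "at least 2")
})
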