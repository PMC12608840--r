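# Shared fixtures: a fixed test anthropometry (vertical trunk CoM,
# y-aligned upper-leg CoM, so the closed-form CoP magnitudes apply), the
# study seat geometry, and cached cohorts reused across test files.

test_anthro <- function(trunk_z = 42, leg_y = 20, t_m = 0.58, u_m = 0.22,
                        L = 42, r = 9, y_it = 1.5, com_y0 = 12, mass = 75) {
  anthropometry(
    trunk_com = c(0, 0, trunk_z), upper_leg_com = c(0, leg_y, 0),
    trunk_mass_fraction = t_m, upper_leg_mass_fraction = u_m,
    upper_leg_length = L, hip_half_width = r, it_offset = y_it,
    upright_com_y = com_y0, body_mass = mass
  )
}

test_geom <- function() seat_geometry()

noiseless_config <- function(anthro = test_anthro(), ...) {
  simulation_config(anthro, loadcell_noise_sd_n = 0, mat_noise_sd = 0,
                    imu_noise_sd_deg = 0, mat_jitter_frac = 0, ...)
}

test_region <- function() it_region(c(10L, 6L), c(10L, 11L))

# random draw of a valid anthropometry (used by property tests)
random_anthro <- function() {
  L <- runif(1, 35, 50)
  anthropometry(
    trunk_com = c(0, 0, runif(1, 35, 50)),
    upper_leg_com = c(0, runif(1, 15, 25), 0),
    trunk_mass_fraction = runif(1, 0.5, 0.65),
    upper_leg_mass_fraction = runif(1, 0.15, 0.25),
    upper_leg_length = L,
    hip_half_width = runif(1, 7, 11),
    it_offset = runif(1, 0, L / 2 * 0.9),
    upright_com_y = runif(1, 5, 2 * L / 3 * 0.95),
    body_mass = runif(1, 45, 115)
  )
}

# cached noisy study cohort (default simulator conditions), shared by the
# model-selection and recovery tests so it is simulated once per run
.fixture_cache <- new.env(parent = emptyenv())

study_cohort <- function() {
  if (is.null(.fixture_cache$cohort)) {
    .fixture_cache$cohort <- make_cohort(n_participants = 10, seed = 101)
  }
  .fixture_cache$cohort
}

study_processed <- function() {
  if (is.null(.fixture_cache$processed)) {
    .fixture_cache$processed <- process_cohort(study_cohort())
  }
  .fixture_cache$processed
}

study_lmm_fits <- function() {
  if (is.null(.fixture_cache$fits)) {
    design <- build_lmm_design(study_processed()$samples)
    fits <- lapply(LMM_STRUCTURES[1:3],
                   function(s) fit_sip_lmm(design, s))
    names(fits) <- LMM_STRUCTURES[1:3]
    .fixture_cache$fits <- fits
  }
  .fixture_cache$fits
}

# minimal synthetic normalized series for direct pipeline-rule tests
fake_normalized_series <- function(prop, cop_mag = seq_along(prop) - 1,
                                   direction = "forward") {
  n <- length(prop)
  samples <- data.frame(
    t_s = (seq_len(n) - 1) / 15,
    cop_x = 0, cop_y = cop_mag, force_n = 500,
    sternum_pitch = 0, sternum_roll = 0, pelvis_pitch = 0, pelvis_roll = 0,
    femur_l_pitch = 0, femur_l_roll = 0, femur_r_pitch = 0,
    femur_r_roll = 0,
    lc_gap_s = 0, imu_gap_s = 0,
    prop_left = prop, prop_right = prop, prop_mean = prop,
    cop_dx = 0, cop_dy = cop_mag, cop_mag = cop_mag,
    cop_angle_deg = 90, excluded = FALSE
  )
  out <- structure(
    list(samples = samples, mat_frames = matrix(prop, n, 256),
         condition = trial_condition(direction), stage = "normalized"),
    class = "sip_cop_series"
  )
  attr(out, "peak_index") <- 1L
  attr(out, "peak_time") <- 0
  attr(out, "norm_constant") <- 1
  attr(out, "norm_rel_se") <- 0
  out
}
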