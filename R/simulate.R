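#' A trial condition label
#'
#' Identifies one pressure-redistribution manoeuvre: lean direction, cushion,
#' starting position, repetition number, and participant.
#'
#' @param direction one of `"forward"`, `"left"`, `"right"`.
#' @param cushion one of `"air"`, `"foam"`, `"own"`.
#' @param start_position one of `"backrest"`, `"situp"`.
#' @param repetition integer 1-3.
#' @param participant_id character label.
#' @return object of class `trial_condition`.
#' @export
trial_condition <- function(direction, cushion = "own",
                            start_position = "backrest", repetition = 1L,
                            participant_id = "P01") {
  direction <- match.arg(direction, DIRECTIONS)
  cushion <- match.arg(cushion, CUSHIONS)
  start_position <- match.arg(start_position, START_POSITIONS)
  stop_if_not(is_number(repetition) && repetition >= 1 && repetition <= 3,
              "repetition must be 1, 2 or 3")
  stop_if_not(is.character(participant_id) && length(participant_id) == 1L,
              "participant_id must be a single string")
  structure(
    list(direction = direction, cushion = cushion,
         start_position = start_position, repetition = as.integer(repetition),
         participant_id = participant_id),
    class = "trial_condition"
  )
}

condition_label <- function(cond) {
  paste(cond$participant_id, cond$cushion, cond$start_position,
        cond$direction, cond$repetition, sep = "_")
}

#' Configuration of the synthetic trial simulator
#'
#' Holds the forward model's parameters: the participant's anthropometry and
#' the seat geometry; the lean trajectory (maximum angle, ramp and hold
#' durations); sensor sample rates and noise standard deviations; the
#' pressure-mat rendering parameters; and the lateral-lean response
#' parameters. The interface-pressure model is only derived for forward
#' leans, so lateral trials impose the forward-lean slope scaled by
#' `lateral_multiplier` (>= 1) on the offloaded side, consistent with
#' sideways leans producing steeper SIP-CoP responses. Lateral trials ramp
#' the forward angle together with the lateral angle
#' (`theta = lateral_forward_ratio * phi`), since sideways manoeuvres
#' typically incorporate some forward lean.
#'
#' The underlying pose trajectory is piecewise-constant on the nominal
#' pressure-mat frame grid (one posture per 1/15 s): all sensor streams
#' observe the identical pose at timestamps that the nearest-neighbour
#' alignment later pairs, which makes noiseless end-to-end recovery exact.
#'
#' No sensor noise magnitudes are reported for the instruments emulated
#' here; the defaults below are this package's choices and can be varied
#' freely.
#'
#' @param anthro an [anthropometry()].
#' @param geom a [seat_geometry()].
#' @param max_angle_deg peak lean angle, degrees.
#' @param ramp_s,hold_s,still_s,backrest_s,tare_s phase durations, s: lean
#'   ramp, hold at peak, still upright sitting, backrest-to-upright
#'   transition (backrest starts only), and pre-transfer taring.
#' @param loadcell_rate_hz,imu_rate_hz,mat_rate_hz nominal sample rates.
#' @param loadcell_noise_sd_n additive load-cell noise SD, N.
#' @param mat_noise_sd additive per-cell mat noise SD, pressure units.
#' @param imu_noise_sd_deg additive IMU angle noise SD, degrees.
#' @param mat_jitter_frac mat timestamp jitter as a fraction of the frame
#'   period (uniform positive delays, emulating acquisition slowdowns).
#' @param lateral_multiplier slope multiplier (>= 1) on the offloaded side
#'   during lateral leans.
#' @param lateral_forward_ratio theta/phi ratio during lateral leans.
#' @param loaded_side_gain fraction of the offloaded-side pressure change
#'   that loads the opposite IT (pressure rises on the lean side).
#' @param baseline_peak upright IT-block cell pressure, mat units.
#' @param ambient background mat cell pressure, mat units; also the floor an
#'   IT block cannot fall below (residual tissue contact).
#' @param it_centers list with `left` and `right`, each `c(row, col)`
#'   (1-based top-left corner of the 2x2 IT cell block; row 1 = back of the
#'   seat, col 1 = user's left).
#' @param cushion_mat_weight_n weight of cushion plus mat on the load cells,
#'   N, removed later by taring.
#' @param knee_bias_cm additive forward CoP bias at full lean emulating
#'   weight transfer through the knees (default off).
#' @param backrest_pitch_drop_deg sternum pitch deficit at the backrest,
#'   degrees.
#' @param backrest_prop proportional IT pressure at the backrest.
#' @param backrest_cop_shift_cm rearward CoP offset at the backrest, cm.
#' @param sternum_gain,pelvis_gain,femur_gain pitch gains of the IMU
#'   channels relative to the trunk lean angle.
#' @param seed integer; fixes all randomness of trials simulated from this
#'   configuration.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(anthro,
                              geom = seat_geometry(),
                              max_angle_deg = 40,
                              ramp_s = 6, hold_s = 1.5, still_s = 1,
                              backrest_s = 2, tare_s = 1,
                              loadcell_rate_hz = 125, imu_rate_hz = 100,
                              mat_rate_hz = 15,
                              loadcell_noise_sd_n = 0.5,
                              mat_noise_sd = 1.5,
                              imu_noise_sd_deg = 0.3,
                              mat_jitter_frac = 0.05,
                              lateral_multiplier = 1.4,
                              lateral_forward_ratio = 0.5,
                              loaded_side_gain = 0.3,
                              baseline_peak = 60, ambient = 4,
                              it_centers = list(left = c(10L, 6L),
                                                right = c(10L, 11L)),
                              cushion_mat_weight_n = 30,
                              knee_bias_cm = 0,
                              backrest_pitch_drop_deg = 15,
                              backrest_prop = 0.85,
                              backrest_cop_shift_cm = 3,
                              sternum_gain = 1, pelvis_gain = 0.6,
                              femur_gain = 0.25,
                              seed = 1L) {
  stop_if_not(inherits(anthro, "anthropometry"), "need an anthropometry")
  stop_if_not(inherits(geom, "seat_geometry"), "need a seat_geometry")
  stop_if_not(is_number(max_angle_deg) && max_angle_deg > 0 &&
                max_angle_deg < 90, "max_angle_deg must be in (0, 90)")
  for (nm in c("ramp_s", "hold_s", "still_s", "backrest_s", "tare_s")) {
    stop_if_not(is_number(get(nm)) && get(nm) >= 0,
                paste(nm, "must be nonnegative"))
  }
  stop_if_not(ramp_s > 0, "ramp_s must be positive")
  for (nm in c("loadcell_noise_sd_n", "mat_noise_sd", "imu_noise_sd_deg")) {
    stop_if_not(is_number(get(nm)) && get(nm) >= 0,
                paste(nm, "must be a nonnegative SD"))
  }
  stop_if_not(is_number(mat_jitter_frac) && mat_jitter_frac >= 0 &&
                mat_jitter_frac < 0.5,
              "mat_jitter_frac must be in [0, 0.5)")
  stop_if_not(is_number(lateral_multiplier) && lateral_multiplier >= 1,
              "lateral_multiplier must be >= 1")
  stop_if_not(is_number(lateral_forward_ratio) && lateral_forward_ratio >= 0,
              "lateral_forward_ratio must be >= 0")
  stop_if_not(is_number(loaded_side_gain) && loaded_side_gain >= 0,
              "loaded_side_gain must be >= 0")
  stop_if_not(is_number(baseline_peak) && baseline_peak > 0 &&
                is_number(ambient) && ambient >= 0 &&
                ambient < baseline_peak,
              "need 0 <= ambient < baseline_peak")
  stop_if_not(is_number(backrest_prop) && backrest_prop > 0 &&
                backrest_prop < 1, "backrest_prop must be in (0, 1)")
  cfg <- list(
    anthro = anthro, geom = geom, max_angle_deg = max_angle_deg,
    ramp_s = ramp_s, hold_s = hold_s, still_s = still_s,
    backrest_s = backrest_s, tare_s = tare_s,
    loadcell_rate_hz = loadcell_rate_hz, imu_rate_hz = imu_rate_hz,
    mat_rate_hz = mat_rate_hz,
    loadcell_noise_sd_n = loadcell_noise_sd_n,
    mat_noise_sd = mat_noise_sd, imu_noise_sd_deg = imu_noise_sd_deg,
    mat_jitter_frac = mat_jitter_frac,
    lateral_multiplier = lateral_multiplier,
    lateral_forward_ratio = lateral_forward_ratio,
    loaded_side_gain = loaded_side_gain,
    baseline_peak = baseline_peak, ambient = ambient,
    it_centers = it_centers,
    cushion_mat_weight_n = cushion_mat_weight_n,
    knee_bias_cm = knee_bias_cm,
    backrest_pitch_drop_deg = backrest_pitch_drop_deg,
    backrest_prop = backrest_prop,
    backrest_cop_shift_cm = backrest_cop_shift_cm,
    sternum_gain = sternum_gain, pelvis_gain = pelvis_gain,
    femur_gain = femur_gain,
    seed = as.integer(seed)
  )
  structure(cfg, class = "simulation_config")
}

#' Distribute a seat load over the four corner load cells
#'
#' Bilinear (separable) distribution: with `u` the rightward and `v` the
#' forward fractional position of the CoP inside the load-cell rectangle,
#' the corner forces are `F (1-u)(1-v)`, `F u (1-v)`, `F (1-u) v`, `F u v`
#' for back-left, back-right, front-left, front-right. This is the unique
#' separable nonnegative scheme whose corner-force CoP (see
#' [cop_from_forces()]) reproduces the input CoP exactly, and it is additive
#' over superimposed loads.
#'
#' @param total_force total vertical load, N, `> 0`.
#' @param cop CoP 2-vector `(x, y)`, cm, seat frame; must lie inside the
#'   load-cell rectangle.
#' @param geom a [seat_geometry()].
#' @return named numeric vector `f_bl_n`, `f_br_n`, `f_fl_n`, `f_fr_n`.
#' @export
corner_forces_from_cop <- function(total_force, cop, geom) {
  stop_if_not(is_number(total_force) && total_force > 0,
              "total_force must be > 0")
  stop_if_not(is.numeric(cop) && length(cop) == 2L, "cop must be a 2-vector")
  stop_if_not(inherits(geom, "seat_geometry"), "need a seat_geometry")
  w <- geom$width_cm
  d <- geom$depth_cm
  eps <- 1e-9
  stop_if_not(abs(cop[1]) <= w / 2 + eps && abs(cop[2]) <= d / 2 + eps,
              "cop outside the seat rectangle")
  u <- min(max(cop[1] / w + 0.5, 0), 1)
  v <- min(max(cop[2] / d + 0.5, 0), 1)
  c(f_bl_n = total_force * (1 - u) * (1 - v),
    f_br_n = total_force * u * (1 - v),
    f_fl_n = total_force * (1 - u) * v,
    f_fr_n = total_force * u * v)
}

#' Render one synthetic 16 x 16 pressure-mat frame
#'
#' Places a 2 x 2 high-pressure block at each ischial-tuberosity centre,
#' scaled by the side's proportional pressure but never below the ambient
#' level (residual tissue contact), over a uniform ambient background, then
#' adds Gaussian noise (from the caller's RNG state) and clips at zero.
#'
#' @param prop_left,prop_right proportional pressures, `>= 0`.
#' @param baseline_peak upright block cell value, mat units.
#' @param it_centers list with `left`, `right`: `c(row, col)` top-left
#'   corners of the 2 x 2 blocks (1-based; must fit inside the grid).
#' @param noise_sd additive noise SD, mat units.
#' @param ambient background level, mat units.
#' @return 16 x 16 numeric matrix (row 1 = back of seat, col 1 = user's
#'   left).
#' @export
render_mat_frame <- function(prop_left, prop_right, baseline_peak,
                             it_centers, noise_sd = 0, ambient = 4) {
  stop_if_not(is_number(prop_left) && prop_left >= 0 &&
                is_number(prop_right) && prop_right >= 0,
              "proportions must be nonnegative")
  for (side in c("left", "right")) {
    ctr <- it_centers[[side]]
    stop_if_not(length(ctr) == 2L && all(ctr >= 1) && all(ctr <= 15),
                "IT centre too close to the grid edge for a 2x2 block")
  }
  grid <- matrix(ambient, 16, 16)
  bl <- it_centers$left
  br <- it_centers$right
  grid[bl[1]:(bl[1] + 1), bl[2]:(bl[2] + 1)] <-
    max(ambient, baseline_peak * prop_left)
  grid[br[1]:(br[1] + 1), br[2]:(br[2] + 1)] <-
    max(ambient, baseline_peak * prop_right)
  if (noise_sd > 0) {
    grid <- grid + matrix(stats::rnorm(256, 0, noise_sd), 16, 16)
  }
  pmax(grid, 0)
}

## Pose/pressure state at one instant of the manoeuvre, before sensor
## sampling. Returns per-time-point vectors; `t` is time from stream start.
trajectory_state <- function(cfg, cond, t) {
  anthro <- cfg$anthro
  bk <- if (cond$start_position == "backrest") cfg$backrest_s else 0
  t_still_end <- bk + cfg$still_s
  t_ramp_end <- t_still_end + cfg$ramp_s
  max_angle <- deg2rad(cfg$max_angle_deg)

  ## lean progress lambda in [0, max_angle]; backrest factor fb in [0, 1]
  lam <- ifelse(t < t_still_end, 0,
                ifelse(t < t_ramp_end,
                       max_angle * (t - t_still_end) / cfg$ramp_s,
                       max_angle))
  fb <- if (bk > 0) pmax(0, 1 - t / bk) else rep(0, length(t))

  theta <- switch(cond$direction,
                  forward = lam,
                  left = cfg$lateral_forward_ratio * lam,
                  right = cfg$lateral_forward_ratio * lam)
  phi <- switch(cond$direction,
                forward = rep(0, length(t)),
                left = lam,
                right = -lam)

  cop_up <- cop_from_com(body_com(anthro, lean_pose(0, 0)), cfg$geom)
  n <- length(t)
  cop_x <- numeric(n)
  cop_y <- numeric(n)
  for (i in seq_len(n)) {
    cop <- cop_from_com(body_com(anthro, lean_pose(theta[i], phi[i])),
                        cfg$geom)
    cop_x[i] <- cop[1]
    cop_y[i] <- cop[2]
  }
  ## backrest transition: CoP sits behind upright and slides forward
  cop_y <- cop_y - cfg$backrest_cop_shift_cm * fb
  if (cfg$knee_bias_cm != 0) {
    cop_y <- cop_y + cfg$knee_bias_cm * lam / max_angle
  }
  cop_mag <- sqrt((cop_x - cop_up[1])^2 + (cop_y - cop_up[2])^2)

  s <- theoretical_slope(anthro)
  s_lat <- s * cfg$lateral_multiplier
  upright_p <- function(mag, slope) pmax(0, 1 + slope * mag)
  p_left <- switch(cond$direction,
                   forward = upright_p(cop_mag, s),
                   left = pmax(0, 1 - cfg$loaded_side_gain * s_lat * cop_mag),
                   right = upright_p(cop_mag, s_lat))
  p_right <- switch(cond$direction,
                    forward = upright_p(cop_mag, s),
                    left = upright_p(cop_mag, s_lat),
                    right = pmax(0, 1 - cfg$loaded_side_gain * s_lat *
                                   cop_mag))
  ## backrest phase: reduced, equal IT pressure ramping up to upright
  pb <- cfg$backrest_prop + (1 - cfg$backrest_prop) * (1 - fb)
  in_bk <- t < bk
  p_left[in_bk] <- pb[in_bk]
  p_right[in_bk] <- pb[in_bk]

  theta_deg <- rad2deg(theta)
  phi_deg <- rad2deg(phi)
  drop <- cfg$backrest_pitch_drop_deg * fb
  list(
    t = t, theta = theta, phi = phi,
    cop_x = cop_x, cop_y = cop_y, cop_mag = cop_mag,
    p_left = p_left, p_right = p_right,
    sternum_pitch = 90 + cfg$sternum_gain * (theta_deg - drop),
    pelvis_pitch = 90 + cfg$pelvis_gain * (theta_deg - drop),
    femur_l_pitch = 90 + cfg$femur_gain * theta_deg - 0.3 * phi_deg,
    femur_r_pitch = 90 + cfg$femur_gain * theta_deg + 0.3 * phi_deg,
    sternum_roll = phi_deg,
    pelvis_roll = 0.8 * phi_deg,
    femur_l_roll = 0.1 * phi_deg,
    femur_r_roll = 0.1 * phi_deg,
    upright_cop = cop_up
  )
}

## Deterministic per-trial seed derived from the config seed and the
## condition label, kept below 2^31.
trial_seed <- function(cfg, cond) {
  h <- sum(utf8ToInt(condition_label(cond)) *
             seq_along(utf8ToInt(condition_label(cond))))
  (cfg$seed + 7919 * (h %% 262143L)) %% (.Machine$integer.max - 1L) + 1L
}

#' Simulate one pressure-redistribution trial
#'
#' Composes the lean kinematics and the beam pressure model forward into
#' the three raw sensor streams: corner load cells at 125 Hz, a 16 x 16
#' pressure mat at a nominal 15 Hz (with optional positive timestamp
#' jitter), and four IMU pitch/roll channels at 100 Hz, plus pre-transfer
#' tare frames. A noiseless run is exactly consistent with the closed
#' forms: the final CoP magnitude of a forward trial equals
#' [cop_magnitude_forward()] at the peak angle, and the proportional IT
#' pressure follows the [theoretical_slope()] line (scaled by the lateral
#' multiplier on the offloaded side of sideways trials).
#'
#' @param cfg a [simulation_config()].
#' @param cond a [trial_condition()].
#' @param seed optional integer overriding the seed derived from
#'   `cfg$seed` and the condition.
#' @return object of class `pr_trial`: list with `condition`, `loadcell`
#'   (`t_s`, `f_bl_n`, `f_br_n`, `f_fl_n`, `f_fr_n`), `mat` (`t_s` plus
#'   `p_<row>_<col>` columns, row-major, 0-based names), `imu` (`t_s`,
#'   `sensor`, `pitch_deg`, `roll_deg`), `tare` (pre-transfer load-cell
#'   frames, negative timestamps), and a `truth` list with the generating
#'   quantities used by recovery tests.
#' @export
simulate_trial <- function(cfg, cond, seed = NULL) {
  stop_if_not(inherits(cfg, "simulation_config"), "need a simulation_config")
  stop_if_not(inherits(cond, "trial_condition"), "need a trial_condition")
  stop_if_not(deg2rad(cfg$max_angle_deg) < pi / 2,
              "trajectory exceeds pi/2")
  if (is.null(seed)) seed <- trial_seed(cfg, cond)

  bk <- if (cond$start_position == "backrest") cfg$backrest_s else 0
  t_total <- bk + cfg$still_s + cfg$ramp_s + cfg$hold_s
  t_mat_period <- 1 / cfg$mat_rate_hz

  ## pose is piecewise-constant on the nominal mat grid
  k_max <- floor(t_total / t_mat_period) - 1L
  state_t <- (0:k_max) * t_mat_period
  st <- trajectory_state(cfg, cond, state_t)
  state_at <- function(t) pmin(pmax(round(t / t_mat_period), 0), k_max) + 1L

  anthro <- cfg$anthro
  seat_weight <- (anthro$trunk_mass_fraction +
                    anthro$upper_leg_mass_fraction) *
    anthro$body_mass * GRAVITY

  local_seed(seed, {
    ## --- load cells ---
    t_lc <- seq(0, t_total, by = 1 / cfg$loadcell_rate_hz)
    idx <- state_at(t_lc)
    n_lc <- length(t_lc)
    corners <- matrix(0, n_lc, 4)
    cushion <- corner_forces_from_cop(cfg$cushion_mat_weight_n, c(0, 0),
                                      cfg$geom)
    for (i in seq_len(n_lc)) {
      k <- idx[i]
      corners[i, ] <- corner_forces_from_cop(
        seat_weight, c(st$cop_x[k], st$cop_y[k]), cfg$geom) + cushion
    }
    if (cfg$loadcell_noise_sd_n > 0) {
      corners <- corners + matrix(stats::rnorm(4 * n_lc, 0,
                                               cfg$loadcell_noise_sd_n),
                                  n_lc, 4)
    }
    loadcell <- data.frame(t_s = t_lc, f_bl_n = corners[, 1],
                           f_br_n = corners[, 2], f_fl_n = corners[, 3],
                           f_fr_n = corners[, 4])

    ## --- tare frames (pre-transfer: cushion + mat only) ---
    t_tare <- seq(-cfg$tare_s, -1 / cfg$loadcell_rate_hz,
                  by = 1 / cfg$loadcell_rate_hz)
    n_tare <- length(t_tare)
    tare_m <- matrix(rep(cushion, each = n_tare), n_tare, 4)
    if (cfg$loadcell_noise_sd_n > 0) {
      tare_m <- tare_m + matrix(stats::rnorm(4 * n_tare, 0,
                                             cfg$loadcell_noise_sd_n),
                                n_tare, 4)
    }
    tare <- data.frame(t_s = t_tare, f_bl_n = tare_m[, 1],
                       f_br_n = tare_m[, 2], f_fl_n = tare_m[, 3],
                       f_fr_n = tare_m[, 4])

    ## --- pressure mat ---
    t_mat <- state_t
    if (cfg$mat_jitter_frac > 0) {
      t_mat <- t_mat + stats::runif(length(t_mat), 0,
                                    cfg$mat_jitter_frac * t_mat_period)
    }
    frames <- matrix(0, length(t_mat), 256)
    for (k in seq_along(t_mat)) {
      fr <- render_mat_frame(st$p_left[k], st$p_right[k],
                             cfg$baseline_peak, cfg$it_centers,
                             cfg$mat_noise_sd, cfg$ambient)
      frames[k, ] <- as.vector(t(fr)) # row-major
    }
    mat <- data.frame(t_s = t_mat, frames)
    names(mat) <- c("t_s", mat_column_names())

    ## --- IMUs ---
    t_imu <- seq(0, t_total, by = 1 / cfg$imu_rate_hz)
    ki <- state_at(t_imu)
    imu <- do.call(rbind, lapply(IMU_SENSORS, function(sensor) {
      pitch <- switch(sensor,
                      sternum = st$sternum_pitch, pelvis = st$pelvis_pitch,
                      femur_l = st$femur_l_pitch, femur_r = st$femur_r_pitch)
      roll <- switch(sensor,
                     sternum = st$sternum_roll, pelvis = st$pelvis_roll,
                     femur_l = st$femur_l_roll, femur_r = st$femur_r_roll)
      data.frame(t_s = t_imu, sensor = sensor,
                 pitch_deg = pitch[ki], roll_deg = roll[ki])
    }))
    if (cfg$imu_noise_sd_deg > 0) {
      imu$pitch_deg <- imu$pitch_deg +
        stats::rnorm(nrow(imu), 0, cfg$imu_noise_sd_deg)
      imu$roll_deg <- imu$roll_deg +
        stats::rnorm(nrow(imu), 0, cfg$imu_noise_sd_deg)
    }

    s <- theoretical_slope(anthro)
    truth <- list(
      forward_slope = s,
      lateral_slope = s * cfg$lateral_multiplier,
      sine_b = theoretical_sine_coefficient(anthro),
      final_cop_mag = st$cop_mag[k_max + 1L],
      seat_weight_n = seat_weight,
      cushion_mat_weight_n = cfg$cushion_mat_weight_n,
      upright_cop = st$upright_cop,
      seed = seed
    )
    structure(
      list(condition = cond, loadcell = loadcell, mat = mat, imu = imu,
           tare = tare, truth = truth),
      class = "pr_trial"
    )
  })
}

mat_column_names <- function() {
  rows <- rep(0:15, each = 16)
  cols <- rep(0:15, times = 16)
  paste0("p_", rows, "_", cols)
}

#' Extract pressure-mat frames as a numeric matrix
#'
#' @param mat the `mat` data frame of a `pr_trial` (column `t_s` plus 256
#'   cell columns).
#' @return list with `t_s` and `frames`, an `n x 256` matrix (row-major
#'   cells; cell `(r, c)` 1-based is column `(r-1)*16 + c`).
#' @keywords internal
mat_as_matrix <- function(mat) {
  cols <- mat_column_names()
  stop_if_not(all(cols %in% names(mat)), "missing mat cell columns")
  list(t_s = mat$t_s, frames = as.matrix(mat[, cols]))
}

#' Simulate a synthetic cohort of pressure-redistribution trials
#'
#' Draws per-participant anthropometry uniformly from stated ranges, then
#' simulates every combination of direction, cushion, start position and
#' repetition for each participant. The ground-truth table records each
#' participant's generating slopes and sine coefficient for recovery tests.
#'
#' @param n_participants number of participants (>= 2).
#' @param seed integer; fixes the cohort draw and every trial's noise.
#' @param directions,cushions,start_positions,repetitions condition grid.
#' @param ranges named list of `c(min, max)` anthropometry ranges with
#'   elements `body_mass`, `trunk_com_z`, `upper_leg_com_y`,
#'   `trunk_mass_fraction`, `upper_leg_mass_fraction`, `upper_leg_length`,
#'   `hip_half_width`, `it_offset`, `upright_com_y`.
#' @param ... further arguments passed to [simulation_config()] (noise SDs,
#'   trajectory, multipliers, ...).
#' @return object of class `pr_cohort`: list with `trials` (list of
#'   `pr_trial`), `ground_truth` (one row per participant), `configs`
#'   (per-participant [simulation_config()]s), and `seed`.
#' @export
make_cohort <- function(n_participants = 10, seed = 1L,
                        directions = DIRECTIONS,
                        cushions = "own",
                        start_positions = "backrest",
                        repetitions = 3,
                        ranges = cohort_default_ranges(),
                        ...) {
  stop_if_not(is_number(n_participants) && n_participants >= 2,
              "need at least 2 participants")
  directions <- match.arg(directions, DIRECTIONS, several.ok = TRUE)
  cushions <- match.arg(cushions, CUSHIONS, several.ok = TRUE)
  start_positions <- match.arg(start_positions, START_POSITIONS,
                               several.ok = TRUE)
  n <- as.integer(n_participants)

  draws <- local_seed(seed, {
    lapply(seq_len(n), function(i) {
      lapply(ranges, function(rg) stats::runif(1, rg[1], rg[2]))
    })
  })
  n_trials_pp <- length(directions) * length(cushions) *
    length(start_positions) * repetitions
  seeds <- child_seeds(seed + 1L, n * n_trials_pp)

  trials <- list()
  configs <- list()
  gt <- list()
  trial_i <- 0L
  extra_args <- list(...)
  for (i in seq_len(n)) {
    d <- draws[[i]]
    pid <- sprintf("P%02d", i)
    anthro <- anthropometry(
      trunk_com = c(0, 0, d$trunk_com_z),
      upper_leg_com = c(0, d$upper_leg_com_y, 0),
      trunk_mass_fraction = d$trunk_mass_fraction,
      upper_leg_mass_fraction = d$upper_leg_mass_fraction,
      upper_leg_length = d$upper_leg_length,
      hip_half_width = d$hip_half_width,
      it_offset = d$it_offset,
      upright_com_y = d$upright_com_y,
      body_mass = d$body_mass
    )
    args <- extra_args
    ## per-participant lateral response unless the caller fixed one
    if (!is.null(d$lateral_multiplier) &&
        !("lateral_multiplier" %in% names(args))) {
      args$lateral_multiplier <- d$lateral_multiplier
    }
    cfg <- do.call(simulation_config,
                   c(list(anthro = anthro, seed = seed), args))
    configs[[pid]] <- cfg
    gt[[pid]] <- data.frame(
      participant_id = pid,
      forward_slope = theoretical_slope(anthro),
      lateral_slope = theoretical_slope(anthro) * cfg$lateral_multiplier,
      sine_b = theoretical_sine_coefficient(anthro),
      body_mass = d$body_mass,
      trunk_com_z = d$trunk_com_z,
      upper_leg_com_y = d$upper_leg_com_y,
      trunk_mass_fraction = d$trunk_mass_fraction,
      upper_leg_mass_fraction = d$upper_leg_mass_fraction,
      upper_leg_length = d$upper_leg_length,
      hip_half_width = d$hip_half_width,
      it_offset = d$it_offset,
      upright_com_y = d$upright_com_y
    )
    for (cushion in cushions) {
      for (startp in start_positions) {
        for (direction in directions) {
          for (rep_i in seq_len(repetitions)) {
            trial_i <- trial_i + 1L
            cond <- trial_condition(direction, cushion, startp, rep_i, pid)
            trials[[condition_label(cond)]] <-
              simulate_trial(cfg, cond, seed = seeds[trial_i])
          }
        }
      }
    }
  }
  structure(
    list(trials = trials, ground_truth = do.call(rbind, gt),
         configs = configs, seed = as.integer(seed)),
    class = "pr_cohort"
  )
}

#' Default anthropometry ranges for the synthetic cohort
#'
#' Uniform ranges spanning adult seated anthropometry: body mass 50-110 kg,
#' trunk CoM height 38-48 cm, upper-leg CoM 18-24 cm ahead of the hip,
#' trunk mass fraction 0.54-0.62 (head included), upper-leg fraction
#' 0.18-0.24, upper-leg length 38-46 cm, hip half-width 8-10 cm, IT
#' evaluation offset 0-3 cm, upright CoM 10-16 cm ahead of the hip, and a
#' lateral slope multiplier of 1.25-1.55 (individuals differ in how much
#' forward lean their sideways manoeuvres carry). These produce theoretical
#' forward slopes of roughly -0.05 to -0.08 per cm and sine coefficients of
#' roughly 20-30 cm.
#'
#' @return named list of `c(min, max)` ranges.
#' @export
cohort_default_ranges <- function() {
  list(
    body_mass = c(50, 110),
    trunk_com_z = c(38, 48),
    upper_leg_com_y = c(18, 24),
    trunk_mass_fraction = c(0.54, 0.62),
    upper_leg_mass_fraction = c(0.18, 0.24),
    upper_leg_length = c(38, 46),
    hip_half_width = c(8, 10),
    it_offset = c(0, 3),
    upright_com_y = c(10, 16),
    lateral_multiplier = c(1.25, 1.55)
  )
}
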