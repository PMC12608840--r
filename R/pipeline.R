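#' Centre of pressure from four corner load-cell forces
#'
#' For load cells at the corners of a `w x d` rectangle,
#' `CoP_x = w (F_FR + F_BR - F_FL - F_BL) / (2 sum F)` and
#' `CoP_y = d (F_FL + F_FR - F_BL - F_BR) / (2 sum F)`; equivalently the
#' force-weighted centroid of the four corner coordinates.
#'
#' @param forces data frame (or one-row list) with columns `f_bl_n`,
#'   `f_br_n`, `f_fl_n`, `f_fr_n`; vectorized over rows.
#' @param geom a [seat_geometry()].
#' @return data frame with `cop_x`, `cop_y` (cm, seat frame) and `force_n`
#'   (total force).
#' @export
cop_from_forces <- function(forces, geom) {
  stop_if_not(inherits(geom, "seat_geometry"), "need a seat_geometry")
  need <- c("f_bl_n", "f_br_n", "f_fl_n", "f_fr_n")
  stop_if_not(all(need %in% names(forces)),
              "forces needs columns f_bl_n, f_br_n, f_fl_n, f_fr_n")
  total <- forces$f_bl_n + forces$f_br_n + forces$f_fl_n + forces$f_fr_n
  stop_if_not(all(total > 0),
              "nonpositive force sum (pre-transfer or sensor fault)")
  data.frame(
    cop_x = geom$width_cm * (forces$f_fr_n + forces$f_br_n -
                               forces$f_fl_n - forces$f_bl_n) / (2 * total),
    cop_y = geom$depth_cm * (forces$f_fl_n + forces$f_fr_n -
                               forces$f_bl_n - forces$f_br_n) / (2 * total),
    force_n = total
  )
}

#' Subtract the cushion-and-mat tare from a load-cell series
#'
#' The per-channel mean of the pre-transfer tare frames is subtracted from
#' every sample, so the load cells measure participant weight only.
#'
#' @param series load-cell data frame with channels `f_bl_n` ... `f_fr_n`.
#' @param tare_frames data frame of pre-transfer samples, same channels.
#' @return the tared series.
#' @export
tare_load_cells <- function(series, tare_frames) {
  chans <- c("f_bl_n", "f_br_n", "f_fl_n", "f_fr_n")
  stop_if_not(all(chans %in% names(series)), "series missing force channels")
  stop_if_not(is.data.frame(tare_frames) && nrow(tare_frames) >= 1,
              "need at least one tare frame")
  stop_if_not(all(chans %in% names(tare_frames)),
              "tare frames missing force channels")
  for (ch in chans) series[[ch]] <- series[[ch]] - mean(tare_frames[[ch]])
  series
}

## Index of the nearest value in sorted vector `haystack` for each needle.
nearest_index <- function(needles, haystack) {
  lo <- findInterval(needles, haystack, all.inside = TRUE)
  hi <- pmin(lo + 1L, length(haystack))
  ifelse(abs(needles - haystack[lo]) <= abs(haystack[hi] - needles), lo, hi)
}

#' Align the three sensor streams on the pressure-mat timestamps
#'
#' The mat has the lowest rate, so each mat frame is paired with the
#' nearest-in-time load-cell and IMU samples. Mat frames with no partner
#' within `max_gap_s` in every stream are dropped with a warning. Load-cell
#' forces are tared before the CoP is computed. The initial zeros (first
#' `zero_window_s` of data) are recorded as attributes; the definitive
#' re-basing happens in [normalize_and_rezero()].
#'
#' @param trial a `pr_trial` (or any list with `loadcell`, `mat`, `imu`,
#'   `tare`, `condition` of the same shapes).
#' @param geom a [seat_geometry()].
#' @param max_gap_s maximum pairing gap, s.
#' @param zero_window_s initial zeroing window, s.
#' @return object of class `sip_cop_series`: list with `samples` (one row
#'   per kept mat frame: `t_s`, `cop_x`, `cop_y`, `force_n`, pitch/roll per
#'   sensor, `lc_gap_s`, `imu_gap_s`), `mat_frames` (n x 256 matrix),
#'   `condition`, and `stage = "aligned"`.
#' @export
align_streams <- function(trial, geom, max_gap_s = 0.02,
                          zero_window_s = 0.5) {
  mat <- mat_as_matrix(trial$mat)
  t_mat <- mat$t_s
  stop_if_not(all(diff(t_mat) > 0), "mat timestamps must be increasing")
  lc <- tare_load_cells(trial$loadcell, trial$tare)
  t_lc <- lc$t_s
  stop_if_not(max(t_lc) >= min(t_mat) && min(t_lc) <= max(t_mat),
              "streams do not overlap")

  i_lc <- nearest_index(t_mat, t_lc)
  lc_gap <- abs(t_mat - t_lc[i_lc])

  imu <- trial$imu
  imu_wide <- list()
  imu_gap <- rep(0, length(t_mat))
  for (sensor in IMU_SENSORS) {
    sub <- imu[imu$sensor == sensor, , drop = FALSE]
    stop_if_not(nrow(sub) > 0, paste("missing IMU sensor", sensor))
    ii <- nearest_index(t_mat, sub$t_s)
    imu_gap <- pmax(imu_gap, abs(t_mat - sub$t_s[ii]))
    imu_wide[[paste0(sensor, "_pitch")]] <- sub$pitch_deg[ii]
    imu_wide[[paste0(sensor, "_roll")]] <- sub$roll_deg[ii]
  }

  keep <- lc_gap <= max_gap_s & imu_gap <= max_gap_s
  if (!all(keep)) {
    warning(sprintf("dropped %d mat frame(s) with pairing gap > %g s",
                    sum(!keep), max_gap_s), call. = FALSE)
  }
  cop <- cop_from_forces(lc[i_lc, , drop = FALSE], geom)
  samples <- data.frame(
    t_s = t_mat, cop_x = cop$cop_x, cop_y = cop$cop_y,
    force_n = cop$force_n, as.data.frame(imu_wide),
    lc_gap_s = lc_gap, imu_gap_s = imu_gap
  )[keep, , drop = FALSE]
  rownames(samples) <- NULL

  out <- structure(
    list(samples = samples, mat_frames = mat$frames[keep, , drop = FALSE],
         condition = trial$condition, stage = "aligned"),
    class = "sip_cop_series"
  )
  in_window <- samples$t_s <= samples$t_s[1] + zero_window_s
  attr(out, "initial_zeros") <- colMeans(samples[in_window, , drop = FALSE])
  out
}

## cell columns (row-major index into the 256-cell frame) of a 2x2 block
block_cells <- function(row, col) {
  rows <- c(row, row, row + 1L, row + 1L)
  cols <- c(col, col + 1L, col, col + 1L)
  (rows - 1L) * 16L + cols
}

#' An ischial-tuberosity cell region
#'
#' Two disjoint 2 x 2 blocks of mat cells, one per IT, the left block
#' strictly left (lower column) of the right block.
#'
#' @param left,right `c(row, col)` 1-based top-left corners.
#' @return object of class `it_region`.
#' @export
it_region <- function(left, right) {
  for (b in list(left, right)) {
    stop_if_not(length(b) == 2L && all(b >= 1) && all(b <= 15),
                "block corner must allow a 2x2 block inside the 16x16 grid")
  }
  stop_if_not(left[2] + 1L < right[2],
              "left block must lie strictly left of the right block")
  structure(
    list(left = as.integer(left), right = as.integer(right),
         left_cells = block_cells(left[1], left[2]),
         right_cells = block_cells(right[1], right[2])),
    class = "it_region"
  )
}

## best 2x2 window (by summed mean pressure) within a column range,
## exhaustive over all window positions
best_block <- function(mean_frame, col_range, tie_tol, persistence = NULL) {
  grid <- expand.grid(row = 1:15, col = seq(col_range[1], col_range[2] - 1L))
  sums <- vapply(seq_len(nrow(grid)), function(i) {
    sum(mean_frame[block_cells(grid$row[i], grid$col[i])])
  }, numeric(1))
  best_sum <- max(sums)
  cand_i <- which(sums >= best_sum - tie_tol * max(best_sum, 1e-12))
  if (length(cand_i) > 1L && !is.null(persistence)) {
    scores <- vapply(cand_i, function(i) {
      persistence(block_cells(grid$row[i], grid$col[i]))
    }, numeric(1))
    cand_i <- cand_i[scores == max(scores)]
  }
  ## stable tie-break: lowest (row, col)
  cand_i <- cand_i[order(grid$row[cand_i], grid$col[cand_i])]
  c(grid$row[cand_i[1]], grid$col[cand_i[1]])
}

#' Select the ischial-tuberosity cell regions
#'
#' For each half of the seat (left and right of the grid midline), finds
#' the 2 x 2 cell block maximizing the summed mean pressure over the static
#' sitting frames, by exhaustive window search. If several blocks tie
#' within `tie_tol` (relative), the persistence criterion decides: the
#' block whose cells stay above half their maximum for the longest time
#' during the first forward-lean trial; remaining ties go to the lowest
#' `(row, col)`.
#'
#' @param static_frames `n x 256` matrix of mat frames (row-major cells)
#'   from static sitting, or a `sip_cop_series` whose `mat_frames` are used.
#' @param forward_frames optional `n x 256` matrix from a forward-lean
#'   trial for the persistence fallback.
#' @param tie_tol relative tie tolerance.
#' @return an [it_region()].
#' @export
select_it_regions <- function(static_frames, forward_frames = NULL,
                              tie_tol = 0.02) {
  if (inherits(static_frames, "sip_cop_series")) {
    static_frames <- static_frames$mat_frames
  }
  stop_if_not(is.matrix(static_frames) && ncol(static_frames) == 256,
              "static_frames must be an n x 256 matrix")
  stop_if_not(nrow(static_frames) >= 1, "need at least one static frame")
  mean_frame <- colMeans(static_frames)
  left_cols <- seq(1L, 128L)  # grid cols 1..8, any row
  col_sum <- function(cols_range) {
    idx <- which(((seq_len(256) - 1L) %% 16L + 1L) >= cols_range[1] &
                   ((seq_len(256) - 1L) %% 16L + 1L) <= cols_range[2])
    sum(mean_frame[idx])
  }
  stop_if_not(col_sum(c(1L, 8L)) > 0, "all-zero left half-grid")
  stop_if_not(col_sum(c(9L, 16L)) > 0, "all-zero right half-grid")

  persistence <- NULL
  if (!is.null(forward_frames)) {
    if (inherits(forward_frames, "sip_cop_series")) {
      forward_frames <- forward_frames$mat_frames
    }
    persistence <- function(cells) {
      trace <- rowMeans(forward_frames[, cells, drop = FALSE])
      sum(trace >= max(trace) / 2)
    }
  }
  left <- best_block(mean_frame, c(1L, 8L), tie_tol, persistence)
  right <- best_block(mean_frame, c(9L, 16L), tie_tol, persistence)
  it_region(left, right)
}

#' Normalize pressures and re-zero the series at peak mean IT pressure
#'
#' Computes each side's IT pressure as the mean of its four region cells,
#' finds the sample where the mean pressure over both ITs peaks (on a
#' lightly smoothed trace so a single noisy cell does not pick the peak;
#' the peak should occur at upright sitting), divides all pressures by that
#' maximum mean pressure, and re-bases the CoP origin and the angle zeros
#' at the peak-time sample. Samples before the peak are flagged `excluded`.
#' For trials that start upright the peak is the first sample and re-zeroing
#' reduces to zeroing at the start. The operation is idempotent.
#'
#' @param series a `sip_cop_series` from [align_streams()].
#' @param region an [it_region()].
#' @param smooth_window_s width of the moving-average window used only to
#'   locate the peak, s.
#' @return the series with `stage = "normalized"`; `samples` gains
#'   `prop_left`, `prop_right`, `prop_mean`, `cop_dx`, `cop_dy`, `cop_mag`,
#'   `cop_angle_deg`, zeroed `*_pitch`/`*_roll` channels, and `excluded`.
#'   Attributes: `peak_index`, `peak_time`, `norm_constant`,
#'   `norm_rel_se` (relative standard error of the normalization constant).
#' @export
normalize_and_rezero <- function(series, region, smooth_window_s = 0.5) {
  stop_if_not(inherits(series, "sip_cop_series"), "need a sip_cop_series")
  stop_if_not(inherits(region, "it_region"), "need an it_region")
  s <- series$samples
  stop_if_not(nrow(s) >= 1, "empty series")
  frames <- series$mat_frames
  raw_left <- rowMeans(frames[, region$left_cells, drop = FALSE])
  raw_right <- rowMeans(frames[, region$right_cells, drop = FALSE])
  raw_mean <- (raw_left + raw_right) / 2

  ## moving-average smoothing: locates the peak and supplies the
  ## normalization constant, so a single noisy sample defines neither
  dt <- if (nrow(s) > 1) stats::median(diff(s$t_s)) else smooth_window_s
  w <- max(1L, min(nrow(s), round(smooth_window_s / dt)))
  half <- (w - 1L) %/% 2L
  if (w > 1L) {
    sm <- stats::filter(raw_mean, rep(1 / w, w), sides = 2)
    sm <- as.numeric(sm)
    sm[is.na(sm)] <- -Inf # edge samples never win over interior ones
    if (all(!is.finite(sm))) sm <- raw_mean
  } else {
    sm <- raw_mean
  }
  k <- which.max(sm)
  win <- seq(max(1L, k - half), min(nrow(s), k + half))
  norm_const <- mean(raw_mean[win])
  stop_if_not(norm_const > 0, "zero maximum mean IT pressure")

  ## relative SE of the normalization constant: per-sample noise of the
  ## mean-IT trace (from first differences), reduced by the averaging
  ## window that defined the constant
  noise_sd <- if (nrow(s) > 3) stats::sd(diff(raw_mean)) / sqrt(2) else 0
  norm_rel_se <- noise_sd / sqrt(length(win)) / norm_const

  s$prop_left <- raw_left / norm_const
  s$prop_right <- raw_right / norm_const
  s$prop_mean <- raw_mean / norm_const
  s$cop_dx <- s$cop_x - s$cop_x[k]
  s$cop_dy <- s$cop_y - s$cop_y[k]
  s$cop_mag <- sqrt(s$cop_dx^2 + s$cop_dy^2)
  s$cop_angle_deg <- rad2deg(atan2(s$cop_dy, s$cop_dx))
  for (ch in c(paste0(IMU_SENSORS, "_pitch"), paste0(IMU_SENSORS, "_roll"))) {
    s[[ch]] <- s[[ch]] - s[[ch]][k]
  }
  s$excluded <- seq_len(nrow(s)) < k

  out <- series
  out$samples <- s
  out$stage <- "normalized"
  attr(out, "initial_zeros") <- attr(series, "initial_zeros")
  attr(out, "peak_index") <- k
  attr(out, "peak_time") <- s$t_s[k]
  attr(out, "norm_constant") <- norm_const
  attr(out, "norm_rel_se") <- norm_rel_se
  out
}

## proportional-pressure trace the analysis tracks for a lean direction:
## both ITs for forward leans, the offloaded IT for sideways leans
tracked_proportion <- function(samples, direction,
                               target = c("auto", "mean", "left", "right")) {
  target <- match.arg(target)
  if (target == "auto") {
    target <- switch(direction, forward = "mean", left = "right",
                     right = "left")
  }
  switch(target,
         mean = samples$prop_mean,
         left = samples$prop_left,
         right = samples$prop_right)
}

#' Truncate a normalized series to the first 95% of the SIP reduction
#'
#' Starting at the re-zero (peak-pressure) sample, keeps samples up to and
#' including the first one where the tracked proportional pressure reaches
#' `p_min + (1 - keep_fraction) * (1 - p_min)`, i.e. has completed
#' `keep_fraction` of its total reduction; the nonlinear plateau beyond is
#' dropped. The tracked pressure is the mean of both ITs for forward leans
#' and the offloaded side's for sideways leans (configurable).
#'
#' @param series a normalized `sip_cop_series`.
#' @param keep_fraction fraction of the SIP reduction to keep.
#' @param target tracked-pressure override (`"mean"`, `"left"`, `"right"`).
#' @return the truncated series (`stage = "truncated"`); `samples` gains
#'   `prop_tracked` and is a contiguous block starting at the re-zero
#'   sample.
#' @export
truncate_to_95 <- function(series, keep_fraction = 0.95, target = "auto") {
  stop_if_not(inherits(series, "sip_cop_series") &&
                identical(series$stage, "normalized"),
              "need a normalized sip_cop_series")
  stop_if_not(is_number(keep_fraction) && keep_fraction > 0 &&
                keep_fraction <= 1, "keep_fraction must be in (0, 1]")
  k <- attr(series, "peak_index")
  s <- series$samples[seq(k, nrow(series$samples)), , drop = FALSE]
  p <- tracked_proportion(s, series$condition$direction, target)
  p_min <- min(p)
  if (p_min >= 1) {
    stop("no SIP reduction in trial; excluded", call. = FALSE)
  }
  cutoff <- p_min + (1 - keep_fraction) * (1 - p_min)
  end <- which(p <= cutoff)[1]
  s <- s[seq_len(end), , drop = FALSE]
  s$prop_tracked <- p[seq_len(end)]
  rownames(s) <- NULL
  out <- series
  out$samples <- s
  out$mat_frames <- series$mat_frames[seq(k, k + end - 1L), , drop = FALSE]
  out$stage <- "truncated"
  for (a in c("peak_index", "peak_time", "norm_constant", "norm_rel_se")) {
    attr(out, a) <- attr(series, a)
  }
  attr(out, "peak_index") <- 1L
  out
}

#' Fit the SIP-CoP regression line
#'
#' Ordinary least squares of the tracked proportional pressure on the CoP
#' magnitude, pooling the samples of the supplied series (typically the
#' three repetitions of one participant-condition). The reported slope
#' standard error includes the propagated uncertainty of the shared
#' max-pressure normalization constant (all of a trial's pressures are
#' divided by one noisy estimate, which scales the slope), added in
#' quadrature to the OLS standard error.
#'
#' @param series a truncated `sip_cop_series`, or a list of them to pool.
#' @param condition optional condition label attached to the result.
#' @return object of class `sip_regression`: list with `slope`,
#'   `intercept`, `r_squared`, `n_samples`, `slope_se`, `condition`.
#' @export
fit_sip_cop_line <- function(series, condition = NULL) {
  if (inherits(series, "sip_cop_series")) series <- list(series)
  stop_if_not(length(series) >= 1 &&
                all(vapply(series, inherits, logical(1), "sip_cop_series")),
              "need one or more sip_cop_series")
  stop_if_not(all(vapply(series, function(x)
    identical(x$stage, "truncated"), logical(1))),
    "series must be truncated (see truncate_to_95)")
  xs <- unlist(lapply(series, function(x) x$samples$cop_mag))
  ys <- unlist(lapply(series, function(x) x$samples$prop_tracked))
  stop_if_not(length(xs) >= 3, "need at least 3 pooled samples")
  stop_if_not(stats::var(xs) > 0, "zero CoP variance")
  fit <- stats::lm(ys ~ xs)
  co <- summary(fit)$coefficients
  slope <- co["xs", "Estimate"]
  ols_se <- co["xs", "Std. Error"]
  ## normalization-constant uncertainty, averaged over the pooled trials
  rel <- vapply(series, function(x) {
    v <- attr(x, "norm_rel_se")
    if (is.null(v) || !is.finite(v)) 0 else v
  }, numeric(1))
  norm_se <- abs(slope) * sqrt(mean(rel^2))
  if (is.null(condition)) condition <- series[[1]]$condition
  structure(
    list(slope = slope, intercept = co["(Intercept)", "Estimate"],
         r_squared = summary(fit)$r.squared,
         n_samples = length(xs),
         slope_se = sqrt(ols_se^2 + norm_se^2),
         condition = condition),
    class = "sip_regression"
  )
}

#' @export
print.sip_regression <- function(x, ...) {
  cat(sprintf(
    "SIP-CoP regression: slope %.4f /cm (SE %.4f), intercept %.4f, R^2 %.4f, n %d\n",
    x$slope, x$slope_se, x$intercept, x$r_squared, x$n_samples))
  invisible(x)
}

#' Fit the sine relation between CoP and sternum pitch
#'
#' Least-squares fit of `delta CoP_y = b * sin(delta sternum pitch)` on the
#' post-re-zero samples, using only the first `keep_fraction` of them (by
#' sample count), since the extreme end of a lean can wrap the sensor range
#' or plateau.
#'
#' @param series a normalized or truncated `sip_cop_series`.
#' @param keep_fraction fraction of post-re-zero samples used.
#' @return list with `b` (cm), `r_squared`, `n_samples`, class `sine_fit`.
#' @export
fit_sine <- function(series, keep_fraction = 0.90) {
  stop_if_not(inherits(series, "sip_cop_series") &&
                series$stage %in% c("normalized", "truncated"),
              "need a normalized sip_cop_series")
  k <- attr(series, "peak_index")
  s <- series$samples[seq(k, nrow(series$samples)), , drop = FALSE]
  n_keep <- max(3L, floor(nrow(s) * keep_fraction))
  stop_if_not(nrow(s) >= 3, "need at least 3 samples")
  s <- s[seq_len(min(n_keep, nrow(s))), , drop = FALSE]
  sn <- sin(deg2rad(s$sternum_pitch))
  stop_if_not(sum(sn^2) > 0, "degenerate: all zeroed pitch angles are zero")
  b <- sum(s$cop_dy * sn) / sum(sn^2)
  ss_res <- sum((s$cop_dy - b * sn)^2)
  ss_tot <- sum((s$cop_dy - mean(s$cop_dy))^2)
  structure(
    list(b = b,
         r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
         n_samples = nrow(s)),
    class = "sine_fit"
  )
}

#' CoP-magnitude threshold for a target SIP reduction
#'
#' Divides the target proportional reduction by the magnitude of the
#' SIP-CoP slope: the CoP displacement needed to offload that proportion.
#'
#' @param slope SIP-CoP slope, per cm; must be negative.
#' @param target_reduction proportional reduction in `[0, 1]`.
#' @return threshold CoP magnitude, cm.
#' @examples
#' cop_threshold(-0.0730, 0.90) # 12.33 cm
#' @export
cop_threshold <- function(slope, target_reduction) {
  stop_if_not(is_number(slope) && slope < 0, "slope must be negative")
  stop_if_not(is_number(target_reduction) && target_reduction >= 0 &&
                target_reduction <= 1,
              "target_reduction must be in [0, 1]")
  target_reduction / abs(slope)
}

#' Bland-Altman agreement analysis
#'
#' For paired measurements (e.g. fitted vs theoretical slopes) computes the
#' per-pair differences and means, the mean and SD of the differences, and
#' the limits of agreement `mean +/- loa_multiplier * SD`.
#'
#' @param fitted,theoretical numeric vectors of equal length (>= 2 pairs).
#' @param loa_multiplier limits-of-agreement multiplier.
#' @return object of class `bland_altman`: list with `mean_diff`,
#'   `sd_diff`, `loa_lower`, `loa_upper`, and a `pairs` data frame
#'   (`mean`, `diff`).
#' @export
bland_altman <- function(fitted, theoretical, loa_multiplier = 1.96) {
  stop_if_not(is.numeric(fitted) && is.numeric(theoretical) &&
                length(fitted) == length(theoretical),
              "fitted and theoretical must be numeric vectors of equal length")
  stop_if_not(length(fitted) >= 2, "need at least 2 pairs")
  d <- fitted - theoretical
  m <- (fitted + theoretical) / 2
  md <- mean(d)
  sdd <- stats::sd(d)
  structure(
    list(mean_diff = md, sd_diff = sdd,
         loa_lower = md - loa_multiplier * sdd,
         loa_upper = md + loa_multiplier * sdd,
         loa_multiplier = loa_multiplier,
         pairs = data.frame(mean = m, diff = d)),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: mean diff %.4f, SD %.4f, LoA [%.4f, %.4f]\n",
              x$mean_diff, x$sd_diff, x$loa_lower, x$loa_upper))
  invisible(x)
}

#' Process one trial through the pipeline
#'
#' Convenience wrapper: align, normalize/re-zero against the given IT
#' region, truncate to the first part of the SIP reduction.
#'
#' @param trial a `pr_trial`.
#' @param geom a [seat_geometry()].
#' @param region an [it_region()].
#' @param keep_fraction see [truncate_to_95()].
#' @param ... passed to [align_streams()].
#' @return a truncated `sip_cop_series`.
#' @export
process_trial <- function(trial, geom, region, keep_fraction = 0.95, ...) {
  series <- align_streams(trial, geom, ...)
  series <- normalize_and_rezero(series, region)
  truncate_to_95(series, keep_fraction)
}

#' Process a synthetic cohort into per-condition regressions
#'
#' For each participant, selects the IT region from the first forward
#' trial's frames around its pressure peak, processes every trial, pools
#' repetitions within each participant x cushion x start x direction cell,
#' and fits the SIP-CoP regression and (for forward leans) the sine
#' relation. Trials with no SIP reduction are excluded and listed.
#'
#' @param cohort a `pr_cohort` from [make_cohort()], or a plain list of
#'   `pr_trial`s.
#' @param geom a [seat_geometry()]; defaults to the cohort's.
#' @param keep_fraction see [truncate_to_95()].
#' @return list with `regressions` (data frame: participant, cushion,
#'   start_position, direction, slope, slope_se, intercept, r2, n),
#'   `sine_fits` (participant-level, forward trials pooled per condition),
#'   `samples` (pooled per-sample rows for mixed modelling: participant,
#'   cushion, start_position, direction, cop_mag, prop_pressure),
#'   `exclusions` (character vector of excluded trial labels), and
#'   `regions` (per participant).
#' @export
process_cohort <- function(cohort, geom = NULL, keep_fraction = 0.95) {
  trials <- if (inherits(cohort, "pr_cohort")) cohort$trials else cohort
  stop_if_not(length(trials) >= 1, "no trials")
  if (is.null(geom)) {
    geom <- if (inherits(cohort, "pr_cohort")) {
      cohort$configs[[1]]$geom
    } else {
      seat_geometry()
    }
  }
  conds <- lapply(trials, `[[`, "condition")
  pids <- vapply(conds, `[[`, character(1), "participant_id")

  regions <- list()
  results <- list()
  sines <- list()
  samples <- list()
  exclusions <- character(0)

  for (pid in unique(pids)) {
    p_trials <- trials[pids == pid]
    p_conds <- conds[pids == pid]
    ## IT region: frames around the peak total pressure of the first
    ## forward trial (static sitting surrogate)
    fwd <- which(vapply(p_conds, `[[`, character(1), "direction") ==
                   "forward")
    ref_idx <- if (length(fwd) > 0) fwd[1] else 1L
    ref_aligned <- align_streams(p_trials[[ref_idx]], geom)
    tot <- rowSums(ref_aligned$mat_frames)
    pk <- which.max(tot)
    win <- seq(max(1, pk - 3), min(length(tot), pk + 3))
    region <- select_it_regions(
      ref_aligned$mat_frames[win, , drop = FALSE],
      forward_frames = ref_aligned$mat_frames)
    regions[[pid]] <- region

    processed <- list()
    for (label in names(p_trials)) {
      processed[[label]] <- tryCatch(
        process_trial(p_trials[[label]], geom, region, keep_fraction),
        error = function(e) {
          exclusions <<- c(exclusions, paste0(label, ": ",
                                              conditionMessage(e)))
          NULL
        })
    }
    processed <- Filter(Negate(is.null), processed)
    if (length(processed) == 0) next

    key <- vapply(processed, function(x) {
      cn <- x$condition
      paste(cn$cushion, cn$start_position, cn$direction, sep = "|")
    }, character(1))
    for (kk in unique(key)) {
      grp <- processed[key == kk]
      cn <- grp[[1]]$condition
      reg <- tryCatch(fit_sip_cop_line(grp), error = function(e) {
        exclusions <<- c(exclusions, paste0(pid, " ", kk, ": ",
                                            conditionMessage(e)))
        NULL
      })
      if (!is.null(reg)) {
        results[[paste(pid, kk)]] <- data.frame(
          participant = pid, cushion = cn$cushion,
          start_position = cn$start_position, direction = cn$direction,
          slope = reg$slope, slope_se = reg$slope_se,
          intercept = reg$intercept, r2 = reg$r_squared,
          n = reg$n_samples)
      }
      if (cn$direction == "forward") {
        bs <- vapply(grp, function(x) fit_sine(x)$b, numeric(1))
        r2s <- vapply(grp, function(x) fit_sine(x)$r_squared, numeric(1))
        sines[[paste(pid, kk)]] <- data.frame(
          participant = pid, cushion = cn$cushion,
          start_position = cn$start_position,
          b = mean(bs), r_squared = mean(r2s), n_trials = length(bs))
      }
      for (g in grp) {
        samples[[length(samples) + 1L]] <- data.frame(
          participant = pid, cushion = cn$cushion,
          start_position = cn$start_position, direction = cn$direction,
          cop_mag = g$samples$cop_mag,
          prop_pressure = g$samples$prop_tracked)
      }
    }
  }
  list(
    regressions = if (length(results)) {
      r <- do.call(rbind, results); rownames(r) <- NULL; r
    } else NULL,
    sine_fits = if (length(sines)) {
      r <- do.call(rbind, sines); rownames(r) <- NULL; r
    } else NULL,
    samples = if (length(samples)) {
      r <- do.call(rbind, samples); rownames(r) <- NULL; r
    } else NULL,
    exclusions = exclusions,
    regions = regions
  )
}
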