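# Bed-mat segment mass estimation and anthropometry containers.

make_frame <- function(fill, landmarks = c(1L, 17L, 33L, 45L, 57L, 65L)) {
  bed_mat_frame(fill, landmarks)
}

test_that("a single loaded band carries the whole mass", {
  m <- matrix(0, 64, 27)
  m[45:56, 10:18] <- 2.5 # upper-torso band only
  seg <- estimate_segment_masses(make_frame(m))
  expect_equal(sum(seg$mass_kg), attr(seg, "total_mass_kg"))
  expect_equal(seg$mass_kg[seg$segment == "upper_torso"],
               sum(m) / 9.80665)
  expect_equal(sum(seg$mass_kg[seg$segment != "upper_torso"]), 0)
})

test_that("two equal uniform bands split the mass and centre on their
          midpoints", {
  m <- matrix(0, 64, 27)
  m[17:32, 5:20] <- 1.0   # upper-leg band, rows 17..32
  m[33:44, 5:20] <- 16 / 12 # lower-torso band, rows 33..44, equal total
  seg <- estimate_segment_masses(make_frame(m))

  # brute-force cell-by-cell oracle
  pitch <- 2.86
  oracle <- function(rows) {
    w <- rowSums(m)[rows]
    c(mass = sum(w) / 9.80665,
      com = sum(w * (rows - 1) * pitch) / sum(w))
  }
  leg <- oracle(17:32)
  torso <- oracle(33:44)
  expect_equal(seg$mass_kg[seg$segment == "upper_leg"], leg[["mass"]])
  expect_equal(seg$mass_kg[seg$segment == "lower_torso"], torso[["mass"]])
  expect_equal(seg$mass_kg[seg$segment == "upper_leg"],
               seg$mass_kg[seg$segment == "lower_torso"])
  expect_equal(seg$com_grid_cm[seg$segment == "upper_leg"], leg[["com"]])
  expect_equal(seg$com_grid_cm[seg$segment == "lower_torso"],
               torso[["com"]])
  # uniform bands centre on the band midpoint
  expect_equal(leg[["com"]], mean((17:32 - 1) * pitch))
  # fractions 0.5 / 0.5 of the loaded mass
  fr <- mass_fractions(seg)
  expect_equal(fr$trunk_mass_fraction, 0.5)
  expect_equal(fr$upper_leg_mass_fraction, 0.5)
})

test_that("degenerate and invalid frames are rejected", {
  expect_error(estimate_segment_masses(make_frame(matrix(0, 64, 27))),
               "zero")
  expect_error(bed_mat_frame(matrix(1, 64, 27),
                             c(1L, 17L, 17L, 45L, 57L, 65L)),
               "increasing")
  expect_error(bed_mat_frame(matrix(1, 64, 27),
                             c(1L, 17L, 33L, 45L, 57L, 80L)),
               "within the grid")
  expect_error(bed_mat_frame(matrix(-1, 64, 27),
                             c(1L, 17L, 33L, 45L, 57L, 65L)),
               "nonnegative")
})

test_that("mass is conserved and CoMs shift exactly with the pattern", {
  set.seed(7)
  for (i in 1:20) {
    m <- matrix(rexp(64 * 27, rate = 2), 64, 27)
    seg <- estimate_segment_masses(make_frame(m))
    expect_equal(sum(seg$mass_kg) * 9.80665, sum(m), tolerance = 1e-9)
    # every segment CoM lies within its row band
    lm_rows <- c(1L, 17L, 33L, 45L, 57L, 65L)
    for (j in 1:5) {
      lo <- (lm_rows[j] - 1) * 2.86
      hi <- (lm_rows[j + 1] - 2) * 2.86
      expect_gte(seg$com_grid_cm[j], lo)
      expect_lte(seg$com_grid_cm[j], hi)
    }
  }

  # translation equivariance: shift pattern and landmarks by k rows
  k <- 3L
  m <- matrix(0, 64, 27)
  m[10:40, 8:20] <- runif(31 * 13)
  shifted <- matrix(0, 64, 27)
  shifted[(10:40) + k, 8:20] <- m[10:40, 8:20]
  base_lm <- c(5L, 15L, 30L, 42L, 50L, 60L)
  seg0 <- estimate_segment_masses(bed_mat_frame(m, base_lm))
  seg1 <- estimate_segment_masses(bed_mat_frame(shifted, base_lm + k))
  expect_equal(seg1$com_grid_cm, seg0$com_grid_cm + k * 2.86)
  expect_equal(seg1$com_body_cm, seg0$com_body_cm)
  expect_equal(seg1$mass_kg, seg0$mass_kg)
})

test_that("anthropometry validates its invariants and round-trips CSV", {
  expect_error(test_anthro(t_m = 0.7, u_m = 0.4), "sum to at most 1")
  expect_error(test_anthro(y_it = 25), "it_offset")
  expect_error(test_anthro(com_y0 = 30), "upright_com_y")
  expect_error(test_anthro(L = -1), "upper_leg_length")

  a <- test_anthro()
  path <- withr::local_tempfile(fileext = ".csv")
  write_anthropometry(a, path)
  b <- read_anthropometry(path)
  expect_equal(unclass(a), unclass(b), tolerance = 1e-12)
})

test_that("bed-mat CSV reader reconstructs the grid", {
  m <- matrix(0, 64, 27)
  m[20:30, 10:15] <- 3
  idx <- which(m > 0, arr.ind = TRUE)
  d <- data.frame(row = idx[, 1], col = idx[, 2], force_N = m[idx])
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(d, path, row.names = FALSE)
  fr <- read_bed_mat(path, c(1L, 17L, 33L, 45L, 57L, 65L))
  expect_equal(fr$forces, m)
})
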