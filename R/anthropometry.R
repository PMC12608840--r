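#' Body-model parameters for a seated individual
#'
#' Bundles the segment parameters of the three-segment seated lean model:
#' the trunk and upper-leg centre-of-mass vectors in the body frame (origin
#' at the trunk/upper-leg hinge near the sacrum; x left-right with left
#' negative, y back-front with forward positive, z up), the segment mass
#' fractions, the upper-leg length, the hip half-width (distance from the
#' midline to the femur about which lateral leans pivot), the position along
#' y at which ischial-tuberosity pressure is evaluated, and the upright
#' centre of mass along y used by the beam pressure model. Lower legs are
#' footrest-supported and carry no seat load, so no lower-leg vector is
#' stored.
#'
#' @param trunk_com 3-vector, cm: trunk CoM in the body frame when upright.
#' @param upper_leg_com 3-vector, cm: upper-leg CoM in the body frame.
#' @param trunk_mass_fraction fraction of body mass in the trunk segment
#'   (head included; see the methods vignette).
#' @param upper_leg_mass_fraction fraction of body mass in the upper legs.
#' @param upper_leg_length cm, hip to knee.
#' @param hip_half_width cm, midline to femur axis.
#' @param it_offset cm, position along y (from the hip hinge) where IT
#'   pressure is evaluated; must lie in `[0, upper_leg_length/2)`.
#' @param upright_com_y cm, upright CoM of the seat-borne mass along y, as
#'   measured (e.g. from a supine pressure-mat frame); must be below
#'   2/3 of the upper-leg length for the theoretical SIP-CoP slope to be
#'   finite and negative.
#' @param body_mass kg.
#' @return an object of class `anthropometry`.
#' @examples
#' a <- anthropometry(
#'   trunk_com = c(0, 0, 40), upper_leg_com = c(0, 20, 0),
#'   trunk_mass_fraction = 0.58, upper_leg_mass_fraction = 0.22,
#'   upper_leg_length = 40, hip_half_width = 9, it_offset = 0,
#'   upright_com_y = 12, body_mass = 75
#' )
#' theoretical_slope(a)
#' @export
anthropometry <- function(trunk_com, upper_leg_com,
                          trunk_mass_fraction, upper_leg_mass_fraction,
                          upper_leg_length, hip_half_width,
                          it_offset = 0, upright_com_y, body_mass) {
  stop_if_not(is.numeric(trunk_com) && length(trunk_com) == 3L,
              "trunk_com must be a numeric 3-vector")
  stop_if_not(is.numeric(upper_leg_com) && length(upper_leg_com) == 3L,
              "upper_leg_com must be a numeric 3-vector")
  stop_if_not(is_number(trunk_mass_fraction) && trunk_mass_fraction > 0 &&
                trunk_mass_fraction < 1,
              "trunk_mass_fraction must be in (0, 1)")
  stop_if_not(is_number(upper_leg_mass_fraction) &&
                upper_leg_mass_fraction > 0 && upper_leg_mass_fraction < 1,
              "upper_leg_mass_fraction must be in (0, 1)")
  stop_if_not(trunk_mass_fraction + upper_leg_mass_fraction <= 1,
              "mass fractions must sum to at most 1")
  stop_if_not(is_number(upper_leg_length) && upper_leg_length > 0,
              "upper_leg_length must be positive")
  stop_if_not(is_number(hip_half_width) && hip_half_width >= 0,
              "hip_half_width must be nonnegative")
  stop_if_not(is_number(it_offset) && it_offset >= 0 &&
                it_offset < upper_leg_length / 2,
              "it_offset must lie in [0, upper_leg_length/2)")
  stop_if_not(is_number(upright_com_y) && upright_com_y >= 0 &&
                upright_com_y < 2 * upper_leg_length / 3,
              "upright_com_y must lie in [0, 2*upper_leg_length/3)")
  stop_if_not(is_number(body_mass) && body_mass > 0,
              "body_mass must be positive")
  structure(
    list(
      trunk_com = as.numeric(trunk_com),
      upper_leg_com = as.numeric(upper_leg_com),
      trunk_mass_fraction = trunk_mass_fraction,
      upper_leg_mass_fraction = upper_leg_mass_fraction,
      upper_leg_length = upper_leg_length,
      hip_half_width = hip_half_width,
      it_offset = it_offset,
      upright_com_y = upright_com_y,
      body_mass = body_mass
    ),
    class = "anthropometry"
  )
}

#' @export
print.anthropometry <- function(x, ...) {
  cat("Anthropometry (body frame, cm / kg)\n")
  cat(sprintf("  trunk CoM  (%.1f, %.1f, %.1f)  mass fraction %.3f\n",
              x$trunk_com[1], x$trunk_com[2], x$trunk_com[3],
              x$trunk_mass_fraction))
  cat(sprintf("  upper-leg CoM (%.1f, %.1f, %.1f)  mass fraction %.3f\n",
              x$upper_leg_com[1], x$upper_leg_com[2], x$upper_leg_com[3],
              x$upper_leg_mass_fraction))
  cat(sprintf("  upper-leg length %.1f, hip half-width %.1f, IT offset %.1f\n",
              x$upper_leg_length, x$hip_half_width, x$it_offset))
  cat(sprintf("  upright CoM_y %.1f, body mass %.1f\n",
              x$upright_com_y, x$body_mass))
  invisible(x)
}

#' Read anthropometry from a flat key-value CSV
#'
#' The file has columns `key,value` with keys `trunk_com_x/_y/_z`,
#' `upper_leg_com_x/_y/_z`, `trunk_mass_fraction`, `upper_leg_mass_fraction`,
#' `upper_leg_length`, `hip_half_width`, `it_offset`, `upright_com_y`,
#' `body_mass`.
#'
#' @param path file path.
#' @return an [anthropometry()] object.
#' @export
read_anthropometry <- function(path) {
  kv <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  stop_if_not(all(c("key", "value") %in% names(kv)),
              "anthropometry file must have columns key,value")
  v <- stats::setNames(as.numeric(kv$value), kv$key)
  need <- c("trunk_com_x", "trunk_com_y", "trunk_com_z",
            "upper_leg_com_x", "upper_leg_com_y", "upper_leg_com_z",
            "trunk_mass_fraction", "upper_leg_mass_fraction",
            "upper_leg_length", "hip_half_width", "it_offset",
            "upright_com_y", "body_mass")
  missing <- setdiff(need, names(v))
  stop_if_not(length(missing) == 0L,
              paste("missing anthropometry keys:",
                    paste(missing, collapse = ", ")))
  anthropometry(
    trunk_com = v[c("trunk_com_x", "trunk_com_y", "trunk_com_z")],
    upper_leg_com = v[c("upper_leg_com_x", "upper_leg_com_y",
                        "upper_leg_com_z")],
    trunk_mass_fraction = v[["trunk_mass_fraction"]],
    upper_leg_mass_fraction = v[["upper_leg_mass_fraction"]],
    upper_leg_length = v[["upper_leg_length"]],
    hip_half_width = v[["hip_half_width"]],
    it_offset = v[["it_offset"]],
    upright_com_y = v[["upright_com_y"]],
    body_mass = v[["body_mass"]]
  )
}

#' Write anthropometry to a flat key-value CSV
#'
#' @param anthro an [anthropometry()] object.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_anthropometry <- function(anthro, path) {
  stop_if_not(inherits(anthro, "anthropometry"), "need an anthropometry object")
  kv <- data.frame(
    key = c("trunk_com_x", "trunk_com_y", "trunk_com_z",
            "upper_leg_com_x", "upper_leg_com_y", "upper_leg_com_z",
            "trunk_mass_fraction", "upper_leg_mass_fraction",
            "upper_leg_length", "hip_half_width", "it_offset",
            "upright_com_y", "body_mass"),
    value = c(anthro$trunk_com, anthro$upper_leg_com,
              anthro$trunk_mass_fraction, anthro$upper_leg_mass_fraction,
              anthro$upper_leg_length, anthro$hip_half_width,
              anthro$it_offset, anthro$upright_com_y, anthro$body_mass)
  )
  utils::write.csv(kv, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## Segment order on the supine bed mat, feet (row 1) to head.
BED_SEGMENTS <- c("lower_leg", "upper_leg", "lower_torso", "upper_torso",
                  "head")

#' A supine bed-mat pressure frame with segment landmarks
#'
#' One frame from a 27 x 64 bed-sized pressure mat (cell pitch 2.86 cm in
#' both directions), taken while the participant lies supine, plus the row
#' indices of the body landmarks that delimit the five measured segments
#' (lower legs, upper legs, lower torso, upper torso, head). Rows run from
#' the feet (row 1) toward the head. Segment bands are half-open: a landmark
#' row starts the next segment.
#'
#' @param forces numeric matrix of cell forces in newtons, all `>= 0`.
#'   Default dimensions 27 x 64 (rows x columns of the mat as stored here:
#'   64 rows along the body is transposed on input if needed); any
#'   `n_rows >= 6` works, rows along the body axis.
#' @param landmark_rows strictly increasing integer vector of 6 row indices:
#'   start of the lower-leg band (calcaneus), mid patella, anterior superior
#'   iliac spine (ASIS), xyphoid process, sternal clavicular joint, and the
#'   row just past the vertex (end of the head band, exclusive).
#' @param cell_pitch_cm centre-to-centre cell spacing, cm.
#' @return object of class `bed_mat_frame`.
#' @export
bed_mat_frame <- function(forces, landmark_rows, cell_pitch_cm = 2.86) {
  forces <- as.matrix(forces)
  stop_if_not(is.numeric(forces) && all(is.finite(forces)),
              "forces must be finite numeric")
  stop_if_not(all(forces >= 0), "cell forces must be nonnegative")
  landmark_rows <- as.integer(landmark_rows)
  stop_if_not(length(landmark_rows) == 6L,
              "need 6 landmark rows (5 segment bands)")
  stop_if_not(all(diff(landmark_rows) > 0),
              "landmark rows must be strictly increasing")
  stop_if_not(landmark_rows[1] >= 1L &&
                landmark_rows[6] <= nrow(forces) + 1L,
              "landmark rows must lie within the grid")
  structure(
    list(forces = forces, landmark_rows = landmark_rows,
         cell_pitch_cm = cell_pitch_cm),
    class = "bed_mat_frame"
  )
}

#' Read a bed-mat frame from a long-format CSV
#'
#' Expects columns `row,col,force_N`; cells absent from the file are zero.
#' Landmarks are supplied separately (they come from tape-measure
#' measurements, not from the mat).
#'
#' @param path CSV path.
#' @param landmark_rows see [bed_mat_frame()].
#' @param n_rows,n_cols grid dimensions.
#' @param cell_pitch_cm cell spacing, cm.
#' @return a [bed_mat_frame()].
#' @export
read_bed_mat <- function(path, landmark_rows, n_rows = 64, n_cols = 27,
                         cell_pitch_cm = 2.86) {
  d <- utils::read.csv(path, comment.char = "#")
  stop_if_not(all(c("row", "col", "force_N") %in% names(d)),
              "bed-mat CSV must have columns row,col,force_N")
  m <- matrix(0, n_rows, n_cols)
  stop_if_not(all(d$row >= 1 & d$row <= n_rows & d$col >= 1 &
                    d$col <= n_cols), "cell index outside grid")
  m[cbind(d$row, d$col)] <- d$force_N
  bed_mat_frame(m, landmark_rows, cell_pitch_cm)
}

#' Estimate segment masses and centres of mass from a supine frame
#'
#' Sums cell forces within each landmark-delimited row band to obtain the
#' segment weight (mass = weight / g) and takes the force-weighted centroid
#' of the band's rows as the segment centre of mass. Positions are reported
#' in cm from the grid origin (row 1 = 0 cm) and, additionally, relative to
#' the ASIS landmark row (the body-frame reference used by the lean model).
#'
#' @param frame a [bed_mat_frame()].
#' @param g gravitational acceleration, m/s^2.
#' @return data frame with one row per segment: `segment`, `mass_kg`,
#'   `com_grid_cm` (force-weighted centroid from the grid origin),
#'   `com_body_cm` (centroid minus the ASIS row position). Attribute
#'   `total_mass_kg` holds the whole-frame mass.
#' @export
estimate_segment_masses <- function(frame, g = GRAVITY) {
  stop_if_not(inherits(frame, "bed_mat_frame"), "need a bed_mat_frame")
  forces <- frame$forces
  total <- sum(forces)
  stop_if_not(total > 0, "degenerate input: total frame force is zero")
  lm_rows <- frame$landmark_rows
  pitch <- frame$cell_pitch_cm
  row_force <- rowSums(forces)
  row_pos <- (seq_len(nrow(forces)) - 1L) * pitch
  asis_pos <- (lm_rows[3] - 1L) * pitch
  out <- lapply(seq_along(BED_SEGMENTS), function(i) {
    rows <- seq.int(lm_rows[i], lm_rows[i + 1] - 1L)
    w <- row_force[rows]
    seg_force <- sum(w)
    com <- if (seg_force > 0) sum(w * row_pos[rows]) / seg_force else NA_real_
    data.frame(segment = BED_SEGMENTS[i],
               mass_kg = seg_force / g,
               com_grid_cm = com,
               com_body_cm = com - asis_pos)
  })
  res <- do.call(rbind, out)
  attr(res, "total_mass_kg") <- total / g
  res
}

#' Trunk and upper-leg mass fractions from bed-mat segment masses
#'
#' The lean model folds the head into the trunk fraction (both ride on the
#' trunk segment when leaning) and excludes the lower legs (footrest
#' supported). Fractions are of the whole-frame mass.
#'
#' @param segments output of [estimate_segment_masses()].
#' @return list with `trunk_mass_fraction` and `upper_leg_mass_fraction`.
#' @export
mass_fractions <- function(segments) {
  stop_if_not(is.data.frame(segments) && all(c("segment", "mass_kg") %in%
                                               names(segments)),
              "need the data frame returned by estimate_segment_masses()")
  total <- sum(segments$mass_kg)
  stop_if_not(total > 0, "zero total mass")
  trunk <- sum(segments$mass_kg[segments$segment %in%
                                  c("lower_torso", "upper_torso", "head")])
  legs <- segments$mass_kg[segments$segment == "upper_leg"]
  list(trunk_mass_fraction = trunk / total,
       upper_leg_mass_fraction = legs / total)
}
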