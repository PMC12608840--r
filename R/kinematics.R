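#' A lean pose
#'
#' Forward-lean angle `theta` and leftward-lean angle `phi`, radians.
#' `theta >= 0` tips the trunk forward; `phi >= 0` tips trunk and upper legs
#' leftward about the left femur. A negative `phi` denotes a rightward lean,
#' modelled as the mirror image of the leftward lean (pivot at the right
#' femur).
#'
#' @param theta forward-lean angle, rad; `|theta| < pi/2`.
#' @param phi leftward-lean angle, rad; `|phi| < pi/2`.
#' @return object of class `lean_pose`.
#' @export
lean_pose <- function(theta = 0, phi = 0) {
  stop_if_not(is_number(theta) && abs(theta) < pi / 2,
              "theta must satisfy |theta| < pi/2")
  stop_if_not(is_number(phi) && abs(phi) < pi / 2,
              "phi must satisfy |phi| < pi/2")
  structure(list(theta = theta, phi = phi), class = "lean_pose")
}

#' Seat-pan geometry
#'
#' Width and depth are measured between the corner load cells. The body
#' origin (the trunk/upper-leg hinge, near the sacrum) sits behind the seat
#' centre; `body_origin_offset_y` is the signed y-offset added to body-frame
#' y-coordinates to express them in the seat frame (origin at the seat
#' centre). It equals minus (half the seat depth minus half the trunk
#' depth), i.e. is negative for a user seated against the backrest. The dump
#' angle (rearward seat tilt) is carried as metadata; the CoP projection is
#' computed in the seat-pan plane.
#'
#' @param width_cm,depth_cm seat dimensions between load cells, cm.
#' @param dump_angle_deg rearward seat-pan tilt, degrees.
#' @param body_origin_offset_y signed offset, cm.
#' @return object of class `seat_geometry`.
#' @export
seat_geometry <- function(width_cm = 40, depth_cm = 40, dump_angle_deg = 8,
                          body_origin_offset_y = -10) {
  stop_if_not(is_number(width_cm) && width_cm > 0, "width_cm must be > 0")
  stop_if_not(is_number(depth_cm) && depth_cm > 0, "depth_cm must be > 0")
  stop_if_not(is_number(dump_angle_deg), "dump_angle_deg must be a number")
  stop_if_not(is_number(body_origin_offset_y),
              "body_origin_offset_y must be a number")
  structure(
    list(width_cm = width_cm, depth_cm = depth_cm,
         dump_angle_deg = dump_angle_deg,
         body_origin_offset_y = body_origin_offset_y),
    class = "seat_geometry"
  )
}

## Forward rotation about the x-axis: a vertical vector (0,0,1) maps to
## (0, sin(theta), cos(theta)); leaning forward moves mass toward +y.
rot_forward <- function(v, theta) {
  c(v[1],
    v[2] * cos(theta) + v[3] * sin(theta),
    -v[2] * sin(theta) + v[3] * cos(theta))
}

## Leftward rotation about the axis parallel to y passing through
## (-r, 0, 0): points above the axis move toward -x.
rot_leftward <- function(v, phi, r) {
  rel <- c(v[1] + r, v[2], v[3])
  c(rel[1] * cos(phi) - rel[3] * sin(phi) - r,
    rel[2],
    rel[1] * sin(phi) + rel[3] * cos(phi))
}

#' Body centre of mass for a forward and leftward lean
#'
#' The seat-borne CoM is the mass-fraction-weighted sum of the trunk and
#' upper-leg CoM vectors. A forward lean rotates only the trunk term about
#' the x-axis through `theta`; a leftward lean rotates both terms about the
#' axis parallel to y through the left femur at `(-r, 0, 0)` through `phi`.
#' Rightward leans (`phi < 0`) are the x-mirror of the corresponding
#' leftward lean.
#'
#' @param anthro an [anthropometry()] object.
#' @param pose a [lean_pose()] (or a list with `theta` and `phi` in rad).
#' @return CoM 3-vector, cm, body frame.
#' @export
body_com <- function(anthro, pose) {
  stop_if_not(inherits(anthro, "anthropometry"), "need an anthropometry")
  if (!inherits(pose, "lean_pose")) pose <- lean_pose(pose$theta, pose$phi)
  if (pose$phi < 0) {
    mirrored <- body_com(anthro, lean_pose(pose$theta, -pose$phi))
    return(c(-mirrored[1], mirrored[2], mirrored[3]))
  }
  r <- anthro$hip_half_width
  trunk <- rot_leftward(rot_forward(anthro$trunk_com, pose$theta),
                        pose$phi, r)
  legs <- rot_leftward(anthro$upper_leg_com, pose$phi, r)
  trunk * anthro$trunk_mass_fraction + legs * anthro$upper_leg_mass_fraction
}

#' Project a centre of mass onto the seat plane
#'
#' On level ground the CoP is directly below the CoM: the x-coordinate
#' passes through unchanged and y is shifted by the body-origin offset of
#' the seat geometry.
#'
#' @param com CoM 3-vector, cm, body frame.
#' @param geom a [seat_geometry()].
#' @return CoP 2-vector `(x, y)`, cm, seat frame (origin at seat centre).
#' @export
cop_from_com <- function(com, geom) {
  stop_if_not(is.numeric(com) && length(com) == 3L, "com must be a 3-vector")
  stop_if_not(inherits(geom, "seat_geometry"), "need a seat_geometry")
  c(com[1], com[2] + geom$body_origin_offset_y)
}

#' Closed-form CoP magnitude for a pure forward lean
#'
#' Under the assumption that the trunk CoM vector is vertical when upright,
#' the CoP displacement of a forward lean through `theta` has magnitude
#' `|T| * t_m * sin(theta)`.
#'
#' @param anthro an [anthropometry()].
#' @param theta forward-lean angle, rad, in `[0, pi/2]`.
#' @return CoP displacement magnitude, cm.
#' @export
cop_magnitude_forward <- function(anthro, theta) {
  stop_if_not(inherits(anthro, "anthropometry"), "need an anthropometry")
  stop_if_not(is.numeric(theta) && all(is.finite(theta)) &&
                all(theta >= 0 & theta <= pi / 2),
              "theta must lie in [0, pi/2]")
  sqrt(sum(anthro$trunk_com^2)) * anthro$trunk_mass_fraction * sin(theta)
}

#' Closed-form CoP magnitude for a combined forward and leftward lean
#'
#' Assumes the trunk CoM vector is vertical and the upper-leg CoM vector
#' lies along y when upright. The forward component contributes
#' `|T| t_m sin(theta)` along y; the lateral pivot about the femur shifts
#' both segments toward the lean side, contributing
#' `r (t_m + u_m)(1 - cos(phi)) + |T| t_m cos(theta) sin(phi)` along x.
#' Reduces to [cop_magnitude_forward()] at `phi = 0`, is symmetric under
#' `phi -> -phi` (x mirror), and agrees exactly with the displacement
#' computed through [body_com()] and [cop_from_com()].
#'
#' @param anthro an [anthropometry()].
#' @param theta forward-lean angle, rad, in `[0, pi/2)`.
#' @param phi leftward-lean angle, rad, in `(-pi/2, pi/2)`.
#' @return CoP displacement magnitude, cm.
#' @export
cop_magnitude_combined <- function(anthro, theta, phi) {
  stop_if_not(inherits(anthro, "anthropometry"), "need an anthropometry")
  stop_if_not(is.numeric(theta) && all(theta >= 0 & theta < pi / 2),
              "theta must lie in [0, pi/2)")
  stop_if_not(is.numeric(phi) && all(abs(phi) < pi / 2),
              "phi must lie in (-pi/2, pi/2)")
  t_mag <- sqrt(sum(anthro$trunk_com^2))
  t_m <- anthro$trunk_mass_fraction
  u_m <- anthro$upper_leg_mass_fraction
  r <- anthro$hip_half_width
  dy <- t_mag * t_m * sin(theta)
  dx <- r * (t_m + u_m) * (1 - cos(phi)) +
    t_mag * t_m * cos(theta) * sin(abs(phi))
  sqrt(dy^2 + dx^2)
}
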