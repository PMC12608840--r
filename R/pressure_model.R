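#' Parameters of the uniform-elasticity beam pressure model
#'
#' The torso and upper legs are treated as rigid blocks resting on a surface
#' of uniform elasticity; the restoring-force density `f(y)` along the
#' upper-leg axis is affine (`f = a y + b`) and is pinned down by force and
#' torque equilibrium: the integral of `f` over `[0, L]` equals `m g`, and
#' the first moment equals `CoM_y m g`.
#'
#' @param upper_leg_length `L`, cm.
#' @param mass `m`, kg: total mass of the torso + upper-leg system.
#' @param com_y current CoM position along y, cm.
#' @param com_y0 upright CoM position along y, cm; must be `< 2L/3` so the
#'   proportional-pressure slope at the hip is finite and negative.
#' @param y_eval position along y where IT pressure is evaluated, cm, in
#'   `[0, L]`.
#' @return object of class `beam_model_params`.
#' @export
beam_model_params <- function(upper_leg_length, mass, com_y,
                              com_y0 = com_y, y_eval = 0) {
  stop_if_not(is_number(upper_leg_length) && upper_leg_length > 0,
              "upper_leg_length must be > 0")
  stop_if_not(is_number(mass) && mass > 0, "mass must be > 0")
  stop_if_not(is_number(com_y), "com_y must be a number")
  stop_if_not(is_number(com_y0) && com_y0 < 2 * upper_leg_length / 3,
              "com_y0 must be < 2L/3")
  stop_if_not(is_number(y_eval) && y_eval >= 0 &&
                y_eval <= upper_leg_length,
              "y_eval must lie in [0, L]")
  structure(
    list(upper_leg_length = upper_leg_length, mass = mass,
         com_y = com_y, com_y0 = com_y0, y_eval = y_eval),
    class = "beam_model_params"
  )
}

#' Restoring-force density along the upper leg under static equilibrium
#'
#' Evaluates the affine force profile
#' `f(y) = -2 g m ((3 CoM_y - 2L)/L^2 - 3 (2 CoM_y - L) y / L^3)`,
#' the unique linear profile satisfying force and torque equilibrium.
#' When `CoM_y = L/2` the load is symmetric and the profile is uniform,
#' `f = m g / L`.
#'
#' @param params a [beam_model_params()].
#' @param y evaluation position(s) along y, cm, each in `[0, L]`.
#' @param com_y optional CoM override, cm (defaults to `params$com_y`).
#' @param g gravitational acceleration, m/s^2.
#' @return force density in N/cm (mass in kg, lengths in cm).
#' @export
restoring_force <- function(params, y, com_y = params$com_y, g = GRAVITY) {
  stop_if_not(inherits(params, "beam_model_params"),
              "need beam_model_params")
  L <- params$upper_leg_length
  stop_if_not(is.numeric(y) && all(is.finite(y)),
              "y must be finite numeric")
  stop_if_not(all(y >= 0 & y <= L), "y outside [0, L]")
  m <- params$mass
  -2 * g * m * ((3 * com_y - 2 * L) / L^2 -
                  3 * (2 * com_y - L) * y / L^3)
}

## Slope of proportional pressure in delta_com_y at evaluation point y:
## 3 (L - 2y) / (3 CoMy0 (L - 2y) - L (2L - 3y)).
prop_pressure_slope <- function(L, com_y0, y) {
  denom <- 3 * com_y0 * (L - 2 * y) - L * (2 * L - 3 * y)
  if (abs(denom) < sqrt(.Machine$double.eps) * L^2) {
    stop("singular configuration: proportional-pressure denominator is zero",
         call. = FALSE)
  }
  3 * (L - 2 * y) / denom
}

#' Proportional IT pressure as a function of forward CoM shift
#'
#' Ratio of the restoring-force density at `y_eval` after the CoM has moved
#' forward by `delta_com_y` to its value at the upright CoM `com_y0`:
#' `p(delta) = 1 + 3 (L - 2y) / (3 CoMy0 (L - 2y) - L (2L - 3y)) * delta`,
#' clipped at zero (contact pressure cannot be negative). At `y = 0` this
#' reduces to `1 + 3 / (3 CoMy0 - 2L) * delta`.
#'
#' @param params a [beam_model_params()]; `com_y0` and `y_eval` are used.
#' @param delta_com_y forward CoM shift(s), cm, `>= 0`.
#' @return proportional pressure, unitless, 1 at `delta = 0`.
#' @export
proportional_pressure <- function(params, delta_com_y) {
  stop_if_not(inherits(params, "beam_model_params"),
              "need beam_model_params")
  stop_if_not(is.numeric(delta_com_y) && all(delta_com_y >= 0),
              "delta_com_y must be nonnegative")
  s <- prop_pressure_slope(params$upper_leg_length, params$com_y0,
                           params$y_eval)
  pmax(0, 1 + s * delta_com_y)
}

#' Theoretical SIP-CoP slope for an individual
#'
#' The coefficient of the CoM shift in the proportional-pressure relation,
#' evaluated at the individual's IT position: the expected change in
#' proportional SIP per centimetre of forward CoP displacement. Negative
#' under the model invariants; steeper when the upright CoM sits further
#' forward, the IT position is closer to the hip, or the upper leg is
#' shorter.
#'
#' @param anthro an [anthropometry()].
#' @return slope, proportional SIP per cm (negative).
#' @export
theoretical_slope <- function(anthro) {
  stop_if_not(inherits(anthro, "anthropometry"), "need an anthropometry")
  prop_pressure_slope(anthro$upper_leg_length, anthro$upright_com_y,
                      anthro$it_offset)
}

#' Theoretical sine coefficient relating CoP magnitude to trunk pitch
#'
#' Under the vertical-trunk assumption the forward-lean CoP magnitude is
#' `b sin(theta)` with `b = |T| t_m`; this is the value of
#' [cop_magnitude_forward()] at `theta = pi/2`.
#'
#' @param anthro an [anthropometry()].
#' @return `b`, cm.
#' @export
theoretical_sine_coefficient <- function(anthro) {
  stop_if_not(inherits(anthro, "anthropometry"), "need an anthropometry")
  sqrt(sum(anthro$trunk_com^2)) * anthro$trunk_mass_fraction
}
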