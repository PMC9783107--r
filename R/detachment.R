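#' Stokes drag with near-wall and slip corrections
#'
#' Drag force on a small sphere in creeping flow,
#' \deqn{F_D = \frac{1}{2} C_D \rho V^2 \frac{\pi d_p^2}{4}\frac{f}{C_u},
#'   \qquad C_D = \frac{24}{Re_p},\qquad Re_p = \frac{d_p \rho V}{\mu},}
#' which collapses algebraically to \eqn{3\pi\mu d_p V f / C_u}. The
#' `V_rel = 0` case is handled symbolically (zero force, no division).
#'
#' @param dp Particle diameter (m). Vectorized with `V_rel`.
#' @param V_rel Relative (slip) speed (m/s), non-negative.
#' @param fluid [fluid_properties()].
#' @param f Near-wall drag correction factor (1 in free flight, 1.7 for a
#'   particle resting on the wall).
#' @param Cu Cunningham slip correction.
#' @return Drag force (N).
#' @export
stokes_drag <- function(dp, V_rel, fluid = fluid_properties(), f = 1, Cu = 1) {
  if (any(dp < 0) || any(V_rel < 0))
    stop("dp and V_rel must be non-negative", call. = FALSE)
  3 * pi * fluid$mu * dp * V_rel * f / Cu
}

#' Fluid speed seen by a wall-resting particle in the viscous sublayer
#'
#' Linear law of the wall evaluated at the particle centre height
#' \eqn{d_p/2}:
#' \deqn{V = \frac{\rho\, d_p\, (u^*)^2}{2 \mu}.}
#'
#' @param dp Particle diameter (m).
#' @param u_star Wall friction velocity (m/s).
#' @param fluid [fluid_properties()].
#' @return Fluid speed at the particle centre (m/s).
#' @export
sublayer_velocity <- function(dp, u_star, fluid = fluid_properties()) {
  if (any(dp < 0) || any(u_star < 0))
    stop("dp and u_star must be non-negative", call. = FALSE)
  fluid$rho * dp * u_star^2 / (2 * fluid$mu)
}

#' Wall shear drag force on a deposited particle
#'
#' Composition of the corrected Stokes drag with the sublayer velocity at
#' the particle centre; with the default near-wall correction f = 1.7 and
#' Cu = 1 this is
#' \deqn{F_D = 5.1\,\frac{\pi}{2}\, d_p^2\, \rho\, (u^*)^2,}
#' the coefficient 5.1 arising as 3 f.
#'
#' @inheritParams sublayer_velocity
#' @param f Near-wall drag correction factor.
#' @param Cu Cunningham slip correction.
#' @return Drag force (N).
#' @export
wall_drag_force <- function(dp, u_star, fluid = fluid_properties(),
                            f = 1.7, Cu = 1) {
  (3 * f / Cu) * (pi / 2) * dp^2 * fluid$rho * u_star^2
}

#' Rolling detachment criterion
#'
#' A stuck particle detaches by rolling when the drag moment about the edge
#' of the contact exceeds the adhesion moment:
#' \deqn{F_D\, \frac{d_p}{2} \ge F_{st}\, a.}
#' Lift force and normal flattening are neglected (both are small for
#' elastic micron-scale contacts). The boundary is inclusive.
#'
#' @param FD Wall drag force on the stuck particle (N).
#' @param dp Particle diameter (m).
#' @param Fst Adhesion force (N).
#' @param a Contact radius (m).
#' @return Logical: `TRUE` if the rolling condition is met.
#' @export
rolling_check <- function(FD, dp, Fst, a) {
  FD * (dp / 2) >= Fst * a
}

#' Sliding detachment criterion
#'
#' A stuck particle detaches by sliding when the drag force overcomes static
#' friction against the adhesion load:
#' \deqn{F_D \ge k_s F_{st}.}
#'
#' @param FD Wall drag force (N).
#' @param ks Static friction coefficient.
#' @param Fst Adhesion force (N).
#' @return Logical: `TRUE` if the sliding condition is met.
#' @export
sliding_check <- function(FD, ks, Fst) {
  FD >= ks * Fst
}

#' Critical wall shear velocity for rolling detachment
#'
#' The friction velocity at which the drag moment balances the adhesion
#' moment. The default `"force_balance"` variant is the exact root of
#' \eqn{F_D(u^*)\,d_p/2 = F_{st}\,a} with the near-wall drag law, i.e.
#' \deqn{u_R^* = \sqrt{\frac{3 (3\pi/2)^{1/3}}{3f}\;
#'   \frac{1}{\rho}\left(\frac{1}{K_C}\right)^{1/3}
#'   \left(\frac{W_A}{d_p}\right)^{4/3}},}
#' whose bracket matches the published closed-form expression to within a
#' coefficient of about 0.986 (at f = 1.7). The `"as_printed"` variant
#' returns that literal closed-form bracket without the square root; it has
#' units m^2/s^2 and is retained for audit only.
#'
#' @param dp Particle diameter (m). Vectorized.
#' @param mat [material_parameters()].
#' @param fluid [fluid_properties()].
#' @param variant `"force_balance"` (default, m/s) or `"as_printed"`
#'   (literal expression, m^2/s^2, audit only).
#' @return Critical wall shear velocity (m/s) for the default variant.
#' @export
critical_shear_rolling <- function(dp, mat = material_parameters(),
                                   fluid = fluid_properties(),
                                   variant = c("force_balance", "as_printed")) {
  variant <- match.arg(variant)
  if (any(dp <= 0)) stop("particle diameter dp must be > 0", call. = FALSE)
  KC <- composite_young(mat)
  if (variant == "as_printed") {
    return((1 / fluid$rho) * (1 / KC)^(1 / 3) * (mat$WA / dp)^(4 / 3))
  }
  Fst <- adhesion_force(dp, mat)
  a <- contact_radius(dp, mat)
  # u* root of (3f/Cu)(pi/2) dp^2 rho u*^2 * dp/2 = Fst * a
  coef <- (3 * mat$f / mat$Cu) * (pi / 2) * fluid$rho
  sqrt(Fst * a / (coef * dp^3 / 2))
}

#' Critical wall shear velocity for sliding detachment
#'
#' The friction velocity at which the wall drag force balances the static
#' friction resistance. The default `"force_balance"` variant is the exact
#' root of \eqn{F_D(u^*) = k_s F_{st}}:
#' \deqn{u_S^* = \sqrt{\frac{3\,k_s\,W_A}{2\cdot 3f\,\rho\, d_p}}.}
#' The `"as_printed"` variant returns the literal published expression
#' \eqn{0.5\,k_s W_A/(\rho_p d_p)} (particle density, no square root,
#' units m^2/s^2), kept for audit: the force balance implies the fluid
#' density, and the two disagree in general.
#'
#' @inheritParams critical_shear_rolling
#' @return Critical wall shear velocity (m/s) for the default variant.
#' @export
critical_shear_sliding <- function(dp, mat = material_parameters(),
                                   fluid = fluid_properties(),
                                   variant = c("force_balance", "as_printed")) {
  variant <- match.arg(variant)
  if (any(dp <= 0)) stop("particle diameter dp must be > 0", call. = FALSE)
  if (variant == "as_printed") {
    return(0.5 * mat$ks * mat$WA / (mat$rho_p * dp))
  }
  Fst <- adhesion_force(dp, mat)
  coef <- (3 * mat$f / mat$Cu) * (pi / 2) * fluid$rho
  sqrt(mat$ks * Fst / (coef * dp^2))
}

#' Detachment assessment for one stuck particle
#'
#' Evaluates the full rolling/sliding force system for a deposited particle
#' exposed to a local wall friction velocity: wall drag force, drag and
#' adhesion moments, sliding resistance, and the two critical wall shear
#' velocities. Rolling takes precedence when both criteria hold (rolling is
#' the more likely detachment mode for spherical particles); both raw flags
#' are stored.
#'
#' @param dp Particle diameter (m), scalar.
#' @param u_star Local wall friction velocity (m/s), non-negative.
#' @param mat [material_parameters()].
#' @param fluid [fluid_properties()].
#' @return A list of class `detachment_assessment` with fields `dp`,
#'   `u_star`, `FD`, `drag_moment`, `adhesion_moment`, `sliding_resistance`,
#'   `uR_star`, `uS_star`, `rolling`, `sliding` and
#'   `outcome` (one of `"remain_stuck"`, `"detach_rolling"`,
#'   `"detach_sliding"`).
#' @examples
#' detachment_decision(2e-6, 0.5)
#' @export
detachment_decision <- function(dp, u_star, mat = material_parameters(),
                                fluid = fluid_properties()) {
  if (u_star < 0) stop("u_star must be >= 0", call. = FALSE)
  Fst <- adhesion_force(dp, mat)
  a <- contact_radius(dp, mat)
  FD <- wall_drag_force(dp, u_star, fluid, f = mat$f, Cu = mat$Cu)
  roll <- rolling_check(FD, dp, Fst, a)
  slide <- sliding_check(FD, mat$ks, Fst)
  outcome <- if (roll) "detach_rolling" else if (slide) "detach_sliding" else "remain_stuck"
  structure(
    list(dp = dp, u_star = u_star, FD = FD,
         drag_moment = FD * dp / 2,
         adhesion_moment = Fst * a,
         sliding_resistance = mat$ks * Fst,
         uR_star = critical_shear_rolling(dp, mat, fluid),
         uS_star = critical_shear_sliding(dp, mat, fluid),
         rolling = roll, sliding = slide, outcome = outcome),
    class = "detachment_assessment"
  )
}

#' Physics table over a diameter grid
#'
#' Tabulates the adhesion/detachment quantities over a particle-diameter
#' grid: adhesion force, capture velocity, contact radius, composite
#' modulus and both critical wall shear velocities.
#'
#' @param dp_min,dp_max Diameter range (m).
#' @param n Number of grid points (log-spaced).
#' @param mat,fluid Material and fluid parameter sets.
#' @param variant Variant passed to the critical shear velocity functions.
#' @return A data.frame with columns `dp`, `Fst`, `vcr`, `a`, `KC`,
#'   `uR_star`, `uS_star`.
#' @export
physics_table <- function(dp_min = 0.5e-6, dp_max = 5e-6, n = 25,
                          mat = material_parameters(),
                          fluid = fluid_properties(),
                          variant = "force_balance") {
  dp <- exp(seq(log(dp_min), log(dp_max), length.out = n))
  k <- compliances(mat)
  E_cap <- elbatsh_parameter(k[["k1"]], k[["k2"]], mat$rho_p)
  data.frame(
    dp = dp,
    Fst = adhesion_force(dp, mat),
    vcr = capture_velocity(dp, E_cap),
    a = contact_radius(dp, mat),
    KC = composite_young(mat),
    uR_star = critical_shear_rolling(dp, mat, fluid, variant),
    uS_star = critical_shear_sliding(dp, mat, fluid, variant)
  )
}
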