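#' Van der Waals adhesion (sticking) force
#'
#' For a dry particle--wall contact the adhesion force is proportional to the
#' work of adhesion and the particle diameter,
#' \deqn{F_{st} = \tfrac{3}{4}\,\pi\, W_A\, d_p.}
#'
#' @param dp Particle diameter (m), strictly positive. Vectorized.
#' @param mat [material_parameters()].
#' @return Adhesion force (N).
#' @examples
#' adhesion_force(1e-6, material_parameters())
#' @export
adhesion_force <- function(dp, mat = material_parameters()) {
  if (any(dp <= 0)) stop("particle diameter dp must be > 0", call. = FALSE)
  0.75 * pi * mat$WA * dp
}

#' Contact compliances of the surface and the particle
#'
#' \deqn{k_1 = \frac{1-\nu_s^2}{\pi E_s}, \qquad k_2 = \frac{1-\nu_p^2}{\pi E_p}.}
#'
#' @param mat [material_parameters()].
#' @return Named numeric vector `c(k1 = , k2 = )` (1/Pa).
#' @export
compliances <- function(mat = material_parameters()) {
  c(k1 = (1 - mat$nu_s^2) / (pi * mat$Es),
    k2 = (1 - mat$nu_p^2) / (pi * mat$Ep))
}

#' El-Batsh capture parameter
#'
#' Composite material parameter entering the capture-velocity power law,
#' \deqn{E = 0.51\left[\frac{5\pi^2 (k_1 + k_2)}{4\,\rho_p^{3/2}}\right]^{2/5}.}
#' Treated as the SI composite that makes [capture_velocity()] return m/s
#' when the diameter is in metres.
#'
#' @param k1,k2 Contact compliances (1/Pa), see [compliances()].
#' @param rho_p Particle density (kg/m^3).
#' @return The capture parameter (SI composite units).
#' @export
elbatsh_parameter <- function(k1, k2, rho_p) {
  if (any(c(k1, k2, rho_p) <= 0))
    stop("k1, k2 and rho_p must be strictly positive", call. = FALSE)
  0.51 * (5 * pi^2 * (k1 + k2) / (4 * rho_p^1.5))^(2 / 5)
}

#' Capture velocity (Dahneke sticking criterion threshold)
#'
#' The normal impact speed below which an impacting particle adheres instead
#' of rebounding,
#' \deqn{v_{cr} = \left(\frac{2E}{d_p}\right)^{10/7}.}
#' Strictly decreasing in diameter: larger particles are easier to bounce.
#'
#' @param dp Particle diameter (m), strictly positive. Vectorized.
#' @param E_cap Capture parameter from [elbatsh_parameter()].
#' @return Capture velocity (m/s).
#' @examples
#' k <- compliances()
#' E <- elbatsh_parameter(k[["k1"]], k[["k2"]], 1230)
#' capture_velocity(5e-6, E)
#' @export
capture_velocity <- function(dp, E_cap) {
  if (any(dp <= 0)) stop("particle diameter dp must be > 0", call. = FALSE)
  (2 * E_cap / dp)^(10 / 7)
}

#' Composite Young's modulus of the particle--wall contact
#'
#' \deqn{K_C = \frac{4}{3}\left[\frac{1-\nu_s^2}{E_s} +
#'   \frac{1-\nu_p^2}{E_p}\right]^{-1}.}
#' Symmetric under swapping particle and surface materials.
#'
#' @inheritParams adhesion_force
#' @return Composite modulus (Pa).
#' @export
composite_young <- function(mat = material_parameters()) {
  (4 / 3) / ((1 - mat$nu_s^2) / mat$Es + (1 - mat$nu_p^2) / mat$Ep)
}

#' Contact deformation radius along the surface
#'
#' Lateral extent of the adhesive contact flattening (the moment arm of the
#' adhesion force in the rolling balance),
#' \deqn{a = \left[\frac{3\pi}{2}\frac{W_A d_p^2}{K_C}\right]^{1/3}.}
#' Scales as \eqn{d_p^{2/3}} and stays far below the diameter for micron
#' particles, which justifies neglecting the normal flattening.
#'
#' @inheritParams adhesion_force
#' @return Contact radius (m).
#' @export
contact_radius <- function(dp, mat = material_parameters()) {
  if (any(dp <= 0)) stop("particle diameter dp must be > 0", call. = FALSE)
  ((3 * pi / 2) * mat$WA * dp^2 / composite_young(mat))^(1 / 3)
}

#' All adhesion-derived quantities for one diameter
#'
#' Convenience bundle evaluating the adhesion force, compliances, capture
#' parameter, composite modulus, contact radius and capture velocity for a
#' single particle diameter.
#'
#' @inheritParams adhesion_force
#' @return A list of class `adhesion_derived` with fields `dp`, `Fst`, `k1`,
#'   `k2`, `E_cap`, `KC`, `a`, `vcr`.
#' @export
adhesion_derived <- function(dp, mat = material_parameters()) {
  k <- compliances(mat)
  E_cap <- elbatsh_parameter(k[["k1"]], k[["k2"]], mat$rho_p)
  structure(
    list(dp = dp,
         Fst = adhesion_force(dp, mat),
         k1 = k[["k1"]], k2 = k[["k2"]],
         E_cap = E_cap,
         KC = composite_young(mat),
         a = contact_radius(dp, mat),
         vcr = capture_velocity(dp, E_cap)),
    class = "adhesion_derived"
  )
}

#' Stick-or-bounce decision on wall impact
#'
#' A particle whose normal impact speed is below the capture velocity
#' adheres; above it, it rebounds. The measure-zero tie `vn == vcr` is
#' resolved as a stick.
#'
#' @param vn Normal impact speed (m/s), non-negative. Vectorized.
#' @param vcr Capture velocity (m/s).
#' @return Character vector, `"stick"` or `"bounce"`.
#' @export
sticking_decision <- function(vn, vcr) {
  if (any(vn < 0)) stop("normal impact speed vn must be >= 0", call. = FALSE)
  ifelse(vn <= vcr, "stick", "bounce")
}

#' Rebound velocity after a wall bounce
#'
#' Scales the normal velocity component by `-e_n` (reversal with restitution
#' loss) and the tangential component by `e_t`.
#'
#' @param v_in Incoming velocity vector (m/s), length 3, approaching the wall
#'   (`sum(v_in * n) < 0`).
#' @param n Unit inward wall normal.
#' @param cor [restitution_pair()].
#' @return Outgoing velocity vector (m/s); its normal component is >= 0
#'   (directed away from the wall).
#' @examples
#' bounce_velocity(c(-1, 0, 2), c(1, 0, 0), restitution_pair(0.5, 0.5))
#' @export
bounce_velocity <- function(v_in, n, cor) {
  if (abs(sum(n^2) - 1) > 1e-9) stop("wall normal must be a unit vector", call. = FALSE)
  vn <- sum(v_in * n)
  if (vn >= 0)
    stop("bounce_velocity requires a wall-approaching velocity (v_in . n < 0)",
         call. = FALSE)
  v_t <- v_in - vn * n
  cor$e_t * v_t + (-cor$e_n * vn) * n
}
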