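#' Particle/surface mechanical and adhesion constants
#'
#' Bundles the material constants that govern microparticle sticking and
#' detachment: Young's moduli and Poisson ratios of the particle and of the
#' wall surface, the work of adhesion of the (dry, van der Waals) contact,
#' the static friction coefficient, the near-wall drag correction factor,
#' the Cunningham slip correction and the particle material density.
#'
#' The default values are the silicon-on-silicon / polymer-particle profile
#' used throughout the package (see [default_materials()]).
#'
#' @param Es Surface Young's modulus (Pa).
#' @param Ep Particle Young's modulus (Pa).
#' @param nu_s Surface Poisson ratio (dimensionless, in `[0, 0.5)`).
#' @param nu_p Particle Poisson ratio (dimensionless, in `[0, 0.5)`).
#' @param WA Work of adhesion of the particle--surface contact (J/m^2).
#' @param ks Static friction coefficient (dimensionless, in `(0, 2]`).
#' @param f Near-wall drag correction factor (dimensionless, >= 1).
#' @param Cu Cunningham slip correction factor (dimensionless, >= 1).
#' @param rho_p Particle material density (kg/m^3).
#' @return An object of class `material_parameters` (a named list).
#' @examples
#' mat <- material_parameters()
#' mat$WA
#' @export
material_parameters <- function(Es = 4.1e9, Ep = 1e9, nu_s = 0.35, nu_p = 0.4,
                                WA = 0.039, ks = 0.5, f = 1.7, Cu = 1,
                                rho_p = 1230) {
  stopifnot(
    is.numeric(Es), is.numeric(Ep), is.numeric(WA), is.numeric(rho_p),
    length(Es) == 1L, length(Ep) == 1L
  )
  if (Es <= 0 || Ep <= 0 || WA <= 0 || rho_p <= 0)
    stop("Es, Ep, WA and rho_p must be strictly positive", call. = FALSE)
  if (Cu < 1) stop("Cunningham correction Cu must be >= 1", call. = FALSE)
  if (ks <= 0 || ks > 2) stop("static friction ks must lie in (0, 2]", call. = FALSE)
  if (f < 1) stop("near-wall drag correction f must be >= 1", call. = FALSE)
  if (nu_s < 0 || nu_s >= 0.5 || nu_p < 0 || nu_p >= 0.5)
    stop("Poisson ratios must lie in [0, 0.5)", call. = FALSE)
  structure(
    list(Es = Es, Ep = Ep, nu_s = nu_s, nu_p = nu_p, WA = WA,
         ks = ks, f = f, Cu = Cu, rho_p = rho_p),
    class = "material_parameters"
  )
}

#' Fluid (carrier air) properties
#'
#' @param rho Fluid density (kg/m^3). Default is air at 1013.25 hPa, 15 C.
#' @param mu Dynamic viscosity (Pa s).
#' @param rho_M Mixture density (kg/m^3); defaults to `rho` under the dilute
#'   one-way-coupling assumption.
#' @return An object of class `fluid_properties`.
#' @examples
#' fluid_properties()$mu
#' @export
fluid_properties <- function(rho = 1.225, mu = 1.7894e-5, rho_M = rho) {
  if (rho <= 0 || mu <= 0 || rho_M <= 0)
    stop("rho, mu and rho_M must be strictly positive", call. = FALSE)
  structure(list(rho = rho, mu = mu, rho_M = rho_M),
            class = "fluid_properties")
}

#' Default material and fluid profile
#'
#' Reads the profile shipped with the package
#' (`extdata/materials/default_silicon.yaml`): a silicon-like inhaler wall
#' (Es = 4.1e9 Pa, nu_s = 0.35), a polymeric drug microparticle
#' (Ep = 1e9 Pa, nu_p = 0.4, rho_p = 1230 kg/m^3), work of adhesion
#' WA = 0.039 J/m^2 for the dry van der Waals contact, static friction
#' ks = 0.5, near-wall drag correction f = 1.7 and Cu = 1, with ambient air
#' as the carrier.
#'
#' @return A list with components `material` ([material_parameters()]) and
#'   `fluid` ([fluid_properties()]).
#' @export
default_materials <- function() {
  path <- system.file("extdata", "materials", "default_silicon.yaml",
                      package = "dpitrack", mustWork = TRUE)
  read_material_profile(path)
}

#' Read a material/fluid profile from a YAML file
#'
#' The file must contain a `material` mapping (fields of
#' [material_parameters()]) and may contain a `fluid` mapping (fields of
#' [fluid_properties()]); missing fluid fields fall back to ambient air.
#'
#' @param path Path to the YAML profile.
#' @return A list with components `material` and `fluid`.
#' @export
read_material_profile <- function(path) {
  prof <- yaml::read_yaml(path)
  if (is.null(prof$material))
    stop("profile has no 'material' section: ", path, call. = FALSE)
  mat <- do.call(material_parameters, prof$material)
  fl <- if (is.null(prof$fluid)) fluid_properties()
        else do.call(fluid_properties, prof$fluid)
  list(material = mat, fluid = fl)
}

#' Normal/tangential restitution coefficient pair
#'
#' @param e_n Normal coefficient of restitution, in `(0, 1]`.
#' @param e_t Tangential coefficient of restitution, in `(0, 1]`.
#' @return An object of class `restitution_pair`.
#' @examples
#' restitution_pair(0.75, 0.75)
#' @export
restitution_pair <- function(e_n, e_t) {
  if (e_n <= 0 || e_n > 1 || e_t <= 0 || e_t > 1)
    stop("restitution coefficients must lie in (0, 1]", call. = FALSE)
  structure(list(e_n = e_n, e_t = e_t), class = "restitution_pair")
}

#' @export
print.material_parameters <- function(x, ...) {
  cat("Material parameters (particle-wall contact)\n")
  for (nm in names(x)) cat(sprintf("  %-6s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' @export
print.fluid_properties <- function(x, ...) {
  cat(sprintf("Fluid: rho = %g kg/m^3, mu = %g Pa s, rho_M = %g kg/m^3\n",
              x$rho, x$mu, x$rho_M))
  invisible(x)
}
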