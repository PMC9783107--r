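#' Construct a flow-field object
#'
#' A flow field is a steady velocity-query contract: `velocity(points)`
#' returns an n x 3 matrix of fluid velocities (m/s) for an n x 3 matrix of
#' positions (m), together with near-wall sampling metadata (`ds`, the
#' first-sample wall offset) and the calibrated operating point. Analytic
#' surrogates are built with [make_analytic_field()]; gridded fields are
#' read with [load_gridded_field()]; this constructor also accepts any
#' user-supplied velocity function (e.g. a plane Couette profile for
#' verification).
#'
#' @param velocity Function mapping an n x 3 position matrix to an n x 3
#'   velocity matrix.
#' @param kind Field kind label.
#' @param ds First-sample wall offset for shear evaluation (m).
#' @param flow_rate_lpm Calibrated volumetric flow rate (L/min), or `NA`.
#' @param pressure_drop_pa Nominal operating pressure drop (Pa).
#' @param geom Optional [build_default_geometry()] domain.
#' @param params Kind-specific parameter list.
#' @param cpp_spec Internal descriptor consumed by the compiled tracker
#'   (`NULL` for fields that only support R-side queries).
#' @return An object of class `flow_field`.
#' @export
flow_field <- function(velocity, kind = "custom", ds = 50e-6,
                       flow_rate_lpm = NA_real_, pressure_drop_pa = 2800,
                       geom = NULL, params = list(), cpp_spec = NULL) {
  stopifnot(is.function(velocity), ds > 0)
  structure(
    list(velocity = velocity, kind = kind, ds = ds,
         flow_rate_lpm = flow_rate_lpm, pressure_drop_pa = pressure_drop_pa,
         geom = geom, params = params, cpp_spec = cpp_spec),
    class = "flow_field"
  )
}

#' Evaluate a flow field
#' @param field A [flow_field()].
#' @param points Length-3 vector or n x 3 matrix of positions (m).
#' @return n x 3 matrix of velocities (m/s).
#' @export
field_velocity <- function(field, points) {
  p <- if (is.matrix(points)) points else matrix(points, ncol = 3)
  v <- field$velocity(p)
  if (any(!is.finite(v))) stop("flow field returned non-finite velocity",
                               call. = FALSE)
  v
}

#' Analytic surrogate flow fields
#'
#' Builds a steady analytic stand-in for the solved device flow at the
#' given operating point. All kinds conserve the volumetric flow rate
#' through every cross-section, so the integrated outlet flux matches the
#' configured flow rate by construction.
#'
#' * `pipe_poiseuille`: purely axial parabolic profile in each region,
#'   \eqn{u_z(r) = 2 Q / (\pi R^2) (1 - r^2/R^2)} with the local region
#'   radius `R`.
#' * `chamber_swirl`: adds a solid-body azimuthal swirl
#'   \eqn{u_\theta = S\, \bar u_z(z)\, r/R} in the capsule and central
#'   chambers (mimicking tangential inlet ports), tapering linearly to zero
#'   across the grid zone.
#' * `grid_jet_composite`: additionally accelerates the axial flow through
#'   open screen cells by `1/open_fraction` (jets through the grid) and
#'   stagnates it over the bars, within the grid zone.
#'
#' @param kind One of `"pipe_poiseuille"`, `"chamber_swirl"`,
#'   `"grid_jet_composite"`.
#' @param geom A [build_default_geometry()].
#' @param flow_rate Volumetric flow rate (L/min). Default 60 L/min, the
#'   peak inspiratory operating point set by a 2800 Pa pressure drop.
#' @param swirl_strength Swirl number `S`: azimuthal wall speed in units of
#'   the local mean axial speed.
#' @param pressure_drop Nominal pressure drop (Pa), metadata.
#' @param ds Wall offset for shear sampling (m).
#' @return A [flow_field()].
#' @examples
#' geom <- build_default_geometry()
#' fld <- make_analytic_field("chamber_swirl", geom)
#' field_velocity(fld, c(0, 0, 0.03))
#' @export
make_analytic_field <- function(kind = c("pipe_poiseuille", "chamber_swirl",
                                         "grid_jet_composite"),
                                geom = build_default_geometry(),
                                flow_rate = 60, swirl_strength = 1,
                                pressure_drop = 2800, ds = 50e-6) {
  kind <- match.arg(kind)
  if (flow_rate <= 0) stop("flow_rate must be > 0", call. = FALSE)
  Q <- flow_rate / 60000                      # L/min -> m^3/s
  S <- if (kind == "pipe_poiseuille") 0 else swirl_strength
  jet <- kind == "grid_jet_composite"
  zb <- geom$z_breaks
  rad <- geom$regions$radius
  scr <- geom$screen
  vel <- function(p) {
    z <- pmin(pmax(p[, 3], zb[1]), zb[5])
    idx <- pmin(findInterval(z, zb, rightmost.closed = TRUE,
                             all.inside = TRUE), 4L)
    R <- rad[idx]
    r2 <- p[, 1]^2 + p[, 2]^2
    um <- Q / (pi * R^2)
    uz <- 2 * um * pmax(0, 1 - r2 / R^2)
    if (jet) {
      in_grid <- z > zb[3] & z <= zb[4]
      if (any(in_grid)) {
        open <- screen_open(geom, p[in_grid, 1], p[in_grid, 2])
        uz[in_grid] <- uz[in_grid] * ifelse(open, 1 / scr$open_fraction, 0)
      }
    }
    ux <- uy <- numeric(nrow(p))
    if (S > 0) {
      g <- ifelse(z <= zb[3], 1,
                  ifelse(z >= zb[4], 0, (zb[4] - z) / (zb[4] - zb[3])))
      omega_r <- S * um * sqrt(r2) / R * g    # u_theta at radius r
      r <- sqrt(r2)
      nz <- r > 0
      ux[nz] <- -omega_r[nz] * p[nz, 2] / r[nz]
      uy[nz] <-  omega_r[nz] * p[nz, 1] / r[nz]
    }
    cbind(ux, uy, uz, deparse.level = 0)
  }
  cpp_spec <- list(
    kind = switch(kind, pipe_poiseuille = 1L, chamber_swirl = 2L,
                  grid_jet_composite = 3L),
    Q = Q, S = S,
    zb = zb, rad = rad,
    screen_z = scr$z, screen_pitch = scr$pitch,
    screen_hw = scr$open_halfwidth, open_fraction = scr$open_fraction
  )
  flow_field(vel, kind = kind, ds = ds, flow_rate_lpm = flow_rate,
             pressure_drop_pa = pressure_drop, geom = geom,
             params = list(swirl_strength = S), cpp_spec = cpp_spec)
}

#' Integrated outlet flux of a field
#'
#' Numerically integrates the axial velocity over the outlet surface
#' (area-uniform polar quadrature). Used to verify flow-rate calibration.
#'
#' @param field A [flow_field()] with an attached geometry.
#' @param n_r,n_theta Quadrature resolution.
#' @return Volumetric flux (L/min).
#' @export
outlet_flux <- function(field, n_r = 200, n_theta = 32) {
  geom <- field$geom
  if (is.null(geom)) stop("field has no attached geometry", call. = FALSE)
  R <- geom$outlet$radius
  z <- geom$outlet$z - 1e-9                 # just inside the outlet plane
  r <- R * sqrt((seq_len(n_r) - 0.5) / n_r) # uniform in area
  th <- 2 * pi * (seq_len(n_theta) - 0.5) / n_theta
  gr <- expand.grid(r = r, th = th)
  pts <- cbind(gr$r * cos(gr$th), gr$r * sin(gr$th), z)
  uz <- field_velocity(field, pts)[, 3]
  mean(uz) * pi * R^2 * 60000
}

#' Wall friction velocity from the first-grid-point relation
#'
#' \deqn{u^* = \frac{\mu\, y^+}{\rho_M\, d_s},}
#' where `ds` is the wall distance of the first sample point and `y+` the
#' dimensionless wall distance there.
#'
#' @param y_plus Dimensionless wall distance (>= 0).
#' @param ds First sample point wall distance (m), > 0.
#' @param fluid [fluid_properties()] (uses the mixture density `rho_M`).
#' @return Wall friction velocity (m/s).
#' @export
wall_friction_velocity <- function(y_plus, ds, fluid = fluid_properties()) {
  if (any(ds <= 0)) stop("ds must be > 0", call. = FALSE)
  if (any(y_plus < 0)) stop("y_plus must be >= 0", call. = FALSE)
  fluid$mu * y_plus / (fluid$rho_M * ds)
}

#' Sample the wall friction velocity from a flow field
#'
#' Samples the tangential fluid speed at offset `ds` along the inward
#' normal from a wall point and converts it through the linear viscous
#' sublayer gradient: \eqn{u^* = \sqrt{\mu |u_t| / (\rho\, d_s)}}. The
#' returned `y_plus` is back-computed so the first-grid-point identity of
#' [wall_friction_velocity()] holds exactly for the stored triple.
#'
#' @param field A [flow_field()].
#' @param wall_point Length-3 wall position (m).
#' @param normal Unit inward wall normal.
#' @param fluid [fluid_properties()].
#' @param ds Sampling offset (m); defaults to the field's `ds`.
#' @return A list of class `wall_shear_sample` with fields `u_star`,
#'   `y_plus`, `ds`.
#' @export
friction_velocity_from_field <- function(field, wall_point, normal,
                                         fluid = fluid_properties(),
                                         ds = field$ds) {
  if (abs(sum(normal^2) - 1) > 1e-9)
    stop("normal must be a unit vector", call. = FALSE)
  p <- wall_point + ds * normal
  u <- drop(field_velocity(field, p))
  u_t <- u - sum(u * normal) * normal
  u_star <- sqrt(fluid$mu * sqrt(sum(u_t^2)) / (fluid$rho_M * ds))
  structure(list(u_star = u_star,
                 y_plus = fluid$rho_M * u_star * ds / fluid$mu,
                 ds = ds),
            class = "wall_shear_sample")
}
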