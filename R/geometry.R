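#' Build the idealized inhaler geometry
#'
#' Constructs an axisymmetric surrogate of a capsule-based dry powder
#' inhaler as a stack of four cylindrical regions (bottom to top): capsule
#' chamber, central chamber, grid zone and mouthpiece, with a perforated
#' screen at the grid-zone entrance and the outlet at the top of the
#' mouthpiece. The dispersion chamber is the union of the capsule and
#' central chambers. The screen is modeled as a plane with a periodic
#' open mask (crossed bar strips) of the given open-area fraction.
#'
#' Default dimensions: the outlet radius is sized so that 60 L/min gives a
#' mean outlet speed of about 12 m/s, and the powder release plane sits
#' 12.5 mm above the device bottom (the capsule position), spanning a
#' capsule-sized disk at the axis.
#'
#' @param capsule_radius,capsule_height Capsule chamber radius/height (m).
#' @param central_height Central chamber height (m); its radius equals the
#'   capsule chamber radius.
#' @param grid_radius,grid_height Grid zone radius/height (m).
#' @param mouth_radius,mouth_height Mouthpiece radius/height (m).
#' @param screen_pitch Period of the screen bar lattice (m).
#' @param open_fraction Open-area fraction of the screen, in (0, 1).
#' @param release_height Height of the particle release plane (m).
#' @param release_radius Radius of the release disk (m).
#' @param n_inlets Number of tangential inlet ports (metadata only).
#' @return An object of class `surrogate_geometry`.
#' @examples
#' geom <- build_default_geometry()
#' geom$regions
#' @export
build_default_geometry <- function(capsule_radius = 0.010,
                                   capsule_height = 0.025,
                                   central_height = 0.015,
                                   grid_radius = 0.007,
                                   grid_height = 0.004,
                                   mouth_radius = 0.00515,
                                   mouth_height = 0.026,
                                   screen_pitch = 5e-4,
                                   open_fraction = 0.815,
                                   release_height = 0.0125,
                                   release_radius = 0.00315,
                                   n_inlets = 2) {
  dims <- c(capsule_radius, capsule_height, central_height, grid_radius,
            grid_height, mouth_radius, mouth_height, screen_pitch,
            release_height, release_radius)
  if (any(!is.finite(dims)) || any(dims <= 0))
    stop("all geometry dimensions must be finite and strictly positive",
         call. = FALSE)
  if (open_fraction <= 0 || open_fraction >= 1)
    stop("open_fraction must lie in (0, 1)", call. = FALSE)
  if (release_height >= capsule_height)
    stop("release plane must lie inside the capsule chamber", call. = FALSE)
  if (release_radius > capsule_radius)
    stop("release disk wider than the capsule chamber", call. = FALSE)
  if (grid_radius > capsule_radius || mouth_radius > grid_radius)
    stop("regions must narrow toward the mouthpiece", call. = FALSE)
  z0 <- 0
  z1 <- capsule_height
  z2 <- z1 + central_height
  z3 <- z2 + grid_height
  z4 <- z3 + mouth_height
  regions <- data.frame(
    name = c("capsule_chamber", "central_chamber", "grid_zone", "mouthpiece"),
    z_lo = c(z0, z1, z2, z3),
    z_hi = c(z1, z2, z3, z4),
    radius = c(capsule_radius, capsule_radius, grid_radius, mouth_radius),
    stringsAsFactors = FALSE
  )
  structure(
    list(regions = regions,
         z_breaks = c(z0, z1, z2, z3, z4),
         screen = list(z = z2, pitch = screen_pitch,
                       open_fraction = open_fraction,
                       open_halfwidth = sqrt(open_fraction) / 2),
         release = list(z = release_height, radius = release_radius),
         outlet = list(z = z4, radius = mouth_radius),
         inlets = list(n = n_inlets, region = "capsule_chamber",
                       z = 0.3 * capsule_height)),
    class = "surrogate_geometry"
  )
}

#' @export
print.surrogate_geometry <- function(x, ...) {
  cat("Surrogate inhaler geometry (axisymmetric region stack)\n")
  print(x$regions, row.names = FALSE)
  cat(sprintf("screen at z = %g m, pitch %g m, open fraction %g\n",
              x$screen$z, x$screen$pitch, x$screen$open_fraction))
  cat(sprintf("release plane z = %g m (disk radius %g m); outlet z = %g m\n",
              x$release$z, x$release$radius, x$outlet$z))
  invisible(x)
}

#' Region names of the surrogate geometry
#' @param geom A [build_default_geometry()] object.
#' @return Character vector of region names, bottom to top.
#' @export
region_names <- function(geom) geom$regions$name

#' Wall radius of the geometry at a given height
#' @param geom A `surrogate_geometry`.
#' @param z Height(s) (m), inside `[0, top]`. Boundaries belong to the lower
#'   region.
#' @return Radius (m).
#' @export
radius_at <- function(geom, z) {
  idx <- .region_index(geom, z)
  geom$regions$radius[idx]
}

.region_index <- function(geom, z) {
  zb <- geom$z_breaks
  if (any(z < zb[1] - 1e-12) || any(z > zb[5] + 1e-12))
    stop("height outside the domain", call. = FALSE)
  idx <- findInterval(pmin(pmax(z, zb[1]), zb[5]), zb,
                      rightmost.closed = TRUE, all.inside = TRUE)
  pmin(idx, 4L)
}

#' Region label of an interior point
#'
#' @param geom A `surrogate_geometry`.
#' @param point Numeric length-3 position (m), or an n x 3 matrix.
#' @return Region label(s); errors if the point lies outside the domain.
#' @export
region_of <- function(geom, point) {
  p <- if (is.matrix(point)) point else matrix(point, ncol = 3)
  idx <- .region_index(geom, p[, 3])
  r <- sqrt(p[, 1]^2 + p[, 2]^2)
  if (any(r > geom$regions$radius[idx] + 1e-12))
    stop("point outside the domain (beyond the wall radius)", call. = FALSE)
  geom$regions$name[idx]
}

#' Is a screen location open?
#'
#' The screen mask is a periodic square lattice: a location is open when
#' both lattice coordinates fall in the centered open window of relative
#' width `sqrt(open_fraction)`, giving crossed bar strips with total open
#' area `open_fraction`.
#'
#' @param geom A `surrogate_geometry`.
#' @param x,y In-plane coordinates (m). Vectorized.
#' @return Logical: `TRUE` where the screen is open.
#' @export
screen_open <- function(geom, x, y) {
  hw <- geom$screen$open_halfwidth
  px <- (x / geom$screen$pitch) %% 1
  py <- (y / geom$screen$pitch) %% 1
  (abs(px - 0.5) < hw) & (abs(py - 0.5) < hw)
}

#' First wall intersection of a straight path segment
#'
#' Finds the earliest boundary crossing of the segment `p0 -> p1`
#' (`p0` interior), classifying the surface that is hit: lateral wall,
#' region shoulder, bottom plate, screen bar, or the outlet plane.
#' Passing through an open screen cell or through a widening region
#' transition is not an event.
#'
#' @param geom A `surrogate_geometry`.
#' @param p0,p1 Numeric length-3 segment endpoints (m).
#' @return `NULL` if the segment stays interior, otherwise a list of class
#'   `wall_hit` with fields `point`, `normal` (unit, inward), `region`,
#'   `kind` (one of `"wall"`, `"grid_bar"`, `"outlet"`, `"inlet"`) and
#'   `t` (fractional position along the segment).
#' @export
intersect_path <- function(geom, p0, p1) {
  stopifnot(length(p0) == 3, length(p1) == 3)
  d <- p1 - p0
  if (sum(d^2) == 0) return(NULL)
  zb <- geom$z_breaks
  rad <- geom$regions$radius
  t_a <- 0
  reg <- .region_index(geom, p0[3])
  eps <- 1e-12
  for (iter in 1:8) {
    # earliest z-plane crossing after t_a
    t_zb <- 1
    plane <- 0L  # 0 none, 1..5 index into zb
    if (abs(d[3]) > 0) {
      for (k in seq_along(zb)) {
        tk <- (zb[k] - p0[3]) / d[3]
        if (tk > t_a + eps && tk <= 1 && tk < t_zb - eps) {
          t_zb <- tk; plane <- k
        }
      }
    }
    # radial crossing within (t_a, t_zb] against the current region radius
    R <- rad[reg]
    aa <- d[1]^2 + d[2]^2
    t_rad <- Inf
    if (aa > 0) {
      bb <- 2 * (p0[1] * d[1] + p0[2] * d[2])
      cc <- p0[1]^2 + p0[2]^2 - R^2
      disc <- bb^2 - 4 * aa * cc
      if (disc >= 0) {
        tr <- (-bb + sqrt(disc)) / (2 * aa)  # outward crossing root
        if (tr > t_a + eps && tr <= min(t_zb, 1)) t_rad <- tr
      }
    }
    if (is.finite(t_rad)) {
      hp <- p0 + t_rad * d
      rr <- sqrt(hp[1]^2 + hp[2]^2)
      n <- c(-hp[1] / rr, -hp[2] / rr, 0)
      return(.wall_hit(hp, n, geom$regions$name[reg], "wall", t_rad))
    }
    if (plane == 0L) return(NULL)
    hp <- p0 + t_zb * d
    going_up <- d[3] > 0
    if (plane == 1L) {           # bottom plate
      return(.wall_hit(hp, c(0, 0, 1), "capsule_chamber", "wall", t_zb))
    }
    if (plane == 5L) {           # outlet plane: particle leaves the device
      return(.wall_hit(hp, c(0, 0, -1), "mouthpiece", "outlet", t_zb))
    }
    r_hit <- sqrt(hp[1]^2 + hp[2]^2)
    nxt <- if (going_up) reg + 1L else reg - 1L
    # shoulder: narrowing transition blocks the annulus r > radius[nxt]
    if (rad[nxt] < rad[reg] - eps && r_hit > rad[nxt]) {
      nrm <- c(0, 0, if (going_up) -1 else 1)
      return(.wall_hit(hp, nrm, geom$regions$name[reg], "wall", t_zb))
    }
    if (abs(zb[plane] - geom$screen$z) < eps) {   # screen plane
      if (!screen_open(geom, hp[1], hp[2])) {
        nrm <- c(0, 0, if (going_up) -1 else 1)
        reg_lab <- if (going_up) "grid_zone" else geom$regions$name[reg]
        return(.wall_hit(hp, nrm, reg_lab, "grid_bar", t_zb))
      }
    }
    t_a <- t_zb
    reg <- nxt
  }
  NULL
}

.wall_hit <- function(point, normal, region, kind, t) {
  structure(list(point = point, normal = normal, region = region,
                 kind = kind, t = t),
            class = "wall_hit")
}
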