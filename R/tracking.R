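#' Simulation configuration
#'
#' Bundles the injection protocol and tracking policy. The defaults
#' reproduce the reference protocol: 500 particles released from a
#' capsule-height plane 12.5 mm above the device bottom, initial velocity
#' equal to the local fluid velocity, at the 60 L/min operating point, with
#' particle sizes drawn from a lognormal distribution truncated to the
#' respirable 0.5--5 um window.
#'
#' @param n_particles Number of injected particles (>= 1).
#' @param seed Integer seed controlling the injection (and hence the whole
#'   run: tracking itself is deterministic).
#' @param cor [restitution_pair()] applied at bouncing impacts.
#' @param size_dist Size distribution: `list(type = "lognormal", median =,
#'   gsd =, range = c(lo, hi))`, `list(type = "uniform", lo =, hi =)` or
#'   `list(type = "fixed", dp =)`. Diameters in metres.
#' @param release_height Release plane height (m).
#' @param flow_rate Volumetric flow rate (L/min).
#' @param field_kind Analytic surrogate kind, see [make_analytic_field()].
#' @param swirl_strength Swirl number of the surrogate field.
#' @param dt_tau_factor Time step as a fraction of the particle relaxation
#'   time (default 1/10).
#' @param dt_floor Lower bound on the step (s); sub-relaxation dynamics of
#'   the smallest particles are resolved exactly by the exponential
#'   integrator, so the floor only bounds the advective error.
#' @param dt_cross_len Maximum free-flight distance per step (m).
#' @param dt_max Upper bound on the step (s).
#' @param max_time Maximum transit time before a particle is declared
#'   timed out (s).
#' @param max_impacts Wall-impact cap per particle (guards against
#'   pathological bounce loops).
#' @param ds Wall offset for friction-velocity sampling (m).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_particles = 500, seed = 1,
                              cor = restitution_pair(0.75, 0.75),
                              size_dist = list(type = "lognormal",
                                               median = 2e-6, gsd = 1.8,
                                               range = c(0.5e-6, 5e-6)),
                              release_height = 12.5e-3,
                              flow_rate = 60,
                              field_kind = "chamber_swirl",
                              swirl_strength = 1,
                              dt_tau_factor = 0.1,
                              dt_floor = 2e-6,
                              dt_cross_len = 5e-4,
                              dt_max = 5e-5,
                              max_time = 0.25,
                              max_impacts = 10000,
                              ds = 50e-6) {
  if (n_particles < 1) stop("n_particles must be >= 1", call. = FALSE)
  if (!inherits(cor, "restitution_pair")) cor <- do.call(restitution_pair, cor)
  structure(
    list(n_particles = as.integer(n_particles), seed = as.integer(seed),
         cor = cor, size_dist = size_dist,
         release_height = release_height, flow_rate = flow_rate,
         field_kind = field_kind, swirl_strength = swirl_strength,
         dt_tau_factor = dt_tau_factor, dt_floor = dt_floor,
         dt_cross_len = dt_cross_len, dt_max = dt_max,
         max_time = max_time, max_impacts = as.integer(max_impacts),
         ds = ds),
    class = "simulation_config"
  )
}

#' Particle momentum relaxation time
#'
#' \deqn{\tau_p = \frac{\rho_p d_p^2 C_u}{18 \mu}.}
#'
#' @param dp Particle diameter (m).
#' @param mat [material_parameters()].
#' @param fluid [fluid_properties()].
#' @return Relaxation time (s).
#' @export
relaxation_time <- function(dp, mat = material_parameters(),
                            fluid = fluid_properties()) {
  mat$rho_p * dp^2 * mat$Cu / (18 * fluid$mu)
}

# inverse-CDF draw per particle: one uniform per diameter, no rejection
.quantile_diameter <- function(u, size_dist) {
  sd <- size_dist
  switch(sd$type,
    fixed = rep(sd$dp, length(u)),
    uniform = sd$lo + u * (sd$hi - sd$lo),
    lognormal = {
      ml <- log(sd$median); sl <- log(sd$gsd)
      plo <- stats::plnorm(sd$range[1], ml, sl)
      phi <- stats::plnorm(sd$range[2], ml, sl)
      stats::qlnorm(plo + u * (phi - plo), ml, sl)
    },
    stop("unknown size distribution type: ", sd$type, call. = FALSE)
  )
}

#' Inject particles on the release plane
#'
#' Places `n_particles` uniformly at random on the release disk (the
#' capsule cross-section), draws diameters from the configured size
#' distribution, and sets each initial velocity equal to the local fluid
#' velocity (zero initial slip). Reproducible per seed.
#'
#' @param config [simulation_config()].
#' @param geom [build_default_geometry()].
#' @param field [flow_field()].
#' @return A data.frame with columns `id`, `dp`, `x`, `y`, `z`,
#'   `vx`, `vy`, `vz`.
#' @export
inject_particles <- function(config, geom, field) {
  if (config$release_height <= 0 ||
      config$release_height >= geom$z_breaks[2])
    stop("release plane lies outside the capsule chamber", call. = FALSE)
  set.seed(config$seed)
  n <- config$n_particles
  # Latin-hypercube draw over (area fraction, azimuth, size quantile):
  # every particle is marginally uniform on the release disk and follows
  # the configured size distribution, while the ensemble is stratified so
  # that deposition estimates converge with n (the discrete-phase analogue
  # of deterministic surface-injection seeding)
  u <- vapply(1:3, function(k) (sample.int(n) - stats::runif(n)) / n,
              numeric(n))
  u <- matrix(u, ncol = 3)
  r <- geom$release$radius * sqrt(u[, 1])
  th <- 2 * pi * u[, 2]
  dp <- .quantile_diameter(u[, 3], config$size_dist)
  pos <- cbind(r * cos(th), r * sin(th), config$release_height)
  v <- field_velocity(field, pos)
  data.frame(id = seq_len(n), dp = dp,
             x = pos[, 1], y = pos[, 2], z = pos[, 3],
             vx = v[, 1], vy = v[, 2], vz = v[, 3])
}

#' Advance one particle by one drag step (reference integrator)
#'
#' Exact one-step update of the linear Stokes-drag equation of motion
#' \eqn{\dot v = (u_f - v)/\tau_p} for a locally constant fluid velocity:
#' \deqn{v' = u_f + (v - u_f) e^{-\Delta t/\tau_p},\qquad
#'   x' = x + u_f \Delta t + (v - u_f)\,\tau_p (1 - e^{-\Delta t/\tau_p}).}
#' Free-flight drag carries no near-wall correction (f = 1); the
#' correction applies only to the detachment assessment of deposited
#' particles.
#'
#' @param particle List with fields `x` (position), `v` (velocity), `dp`.
#' @param field [flow_field()].
#' @param fluid [fluid_properties()].
#' @param mat [material_parameters()] (for `rho_p` and `Cu`).
#' @param dt Time step (s), > 0.
#' @return The updated particle list.
#' @export
step_particle <- function(particle, field, fluid = fluid_properties(),
                          mat = material_parameters(), dt) {
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  u <- drop(field_velocity(field, particle$x))
  tau <- relaxation_time(particle$dp, mat, fluid)
  e <- exp(-dt / tau)
  v_new <- u + (particle$v - u) * e
  x_new <- particle$x + u * dt + (particle$v - u) * tau * (1 - e)
  particle$x <- x_new
  particle$v <- v_new
  particle
}

.geom_cpp <- function(geom) {
  list(zb = geom$z_breaks, rad = geom$regions$radius,
       screen_z = geom$screen$z, screen_pitch = geom$screen$pitch,
       screen_hw = geom$screen$open_halfwidth)
}

.status_labels <- c("in_flow", "stuck", "emitted", "in_domain_timeout")
.kind_labels <- c("wall", "grid_bar", "outlet")
.detach_labels <- c("remain_stuck", "detach_rolling", "detach_sliding")

#' Run a full particle-tracking simulation
#'
#' Injects particles, integrates their trajectories through the steady
#' flow field with the compiled tracker, detects wall impacts, applies the
#' stick/bounce capture-velocity criterion and, for each deposited
#' particle, evaluates the rolling/sliding detachment assessment once at
#' the stuck point (the flow is steady, so a single evaluation suffices).
#' Detached particles re-enter tracking from rest at the wall.
#'
#' @param config [simulation_config()].
#' @param geom [build_default_geometry()]; defaults to the standard
#'   surrogate.
#' @param field A [flow_field()] with a compiled-tracker descriptor
#'   (analytic or gridded); by default built from the config.
#' @param mat,fluid Material and fluid parameter sets.
#' @return An object of class `dpi_run`: a list with `states` (final
#'   particle states), `impacts` (one row per wall impact), `detach` (one
#'   assessment row per stick event), plus the inputs and the injected
#'   particle table.
#' @examples
#' \donttest{
#' run <- run_simulation(simulation_config(n_particles = 50, seed = 7))
#' table(run$states$status)
#' }
#' @export
run_simulation <- function(config = simulation_config(),
                           geom = build_default_geometry(),
                           field = NULL,
                           mat = material_parameters(),
                           fluid = fluid_properties()) {
  if (is.null(field)) {
    field <- make_analytic_field(config$field_kind, geom,
                                 flow_rate = config$flow_rate,
                                 swirl_strength = config$swirl_strength,
                                 ds = config$ds)
  }
  if (is.null(field$cpp_spec))
    stop("this flow field supports only R-side queries, not tracking",
         call. = FALSE)
  injected <- inject_particles(config, geom, field)
  k <- compliances(mat)
  phys <- list(mu = fluid$mu, rho = fluid$rho, rho_M = fluid$rho_M,
               rho_p = mat$rho_p, Cu = mat$Cu, f = mat$f, ks = mat$ks,
               WA = mat$WA, KC = composite_young(mat),
               E_cap = elbatsh_parameter(k[["k1"]], k[["k2"]], mat$rho_p),
               e_n = config$cor$e_n, e_t = config$cor$e_t, ds = config$ds)
  control <- list(dt_tau_factor = config$dt_tau_factor,
                  dt_floor = config$dt_floor,
                  dt_cross_len = config$dt_cross_len,
                  dt_max = config$dt_max, max_time = config$max_time,
                  max_impacts = config$max_impacts)
  raw <- cpp_track(as.matrix(injected), field$cpp_spec, .geom_cpp(geom),
                   phys, control)
  st <- as.data.frame(raw$states)
  states <- data.frame(
    id = injected$id, dp = injected$dp,
    x = st$x, y = st$y, z = st$z, vx = st$vx, vy = st$vy, vz = st$vz,
    time = st$time,
    status = .status_labels[st$status + 1L],
    stuck_region = ifelse(st$region > 0, region_names(geom)[st$region],
                          NA_character_),
    n_impacts = st$n_impacts,
    stringsAsFactors = FALSE
  )
  impacts <- as.data.frame(raw$impacts)
  if (nrow(impacts)) {
    impacts$region <- region_names(geom)[impacts$region]
    impacts$kind <- .kind_labels[impacts$kind]
    impacts$outcome <- c("stick", "bounce")[impacts$outcome]
  }
  detach <- as.data.frame(raw$detach)
  if (nrow(detach)) {
    detach$region <- region_names(geom)[detach$region]
    detach$outcome <- .detach_labels[detach$outcome + 1L]
  }
  structure(
    list(states = states, impacts = impacts, detach = detach,
         injected = injected, config = config, geom = geom, field = field,
         mat = mat, fluid = fluid),
    class = "dpi_run"
  )
}

#' @export
print.dpi_run <- function(x, ...) {
  n <- nrow(x$states)
  tab <- table(factor(x$states$status, levels = .status_labels))
  cat(sprintf("Particle tracking run: %d particles (seed %d)\n",
              n, x$config$seed))
  for (s in names(tab))
    cat(sprintf("  %-18s %4d (%.1f%%)\n", s, tab[[s]], 100 * tab[[s]] / n))
  cat(sprintf("  impacts: %d; detachment events: %d\n",
              nrow(x$impacts),
              sum(x$detach$outcome != "remain_stuck")))
  invisible(x)
}
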