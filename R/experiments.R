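#' Region-wise deposition report
#'
#' Summarizes a completed run: deposited counts and percentages (of the
#' injected total) per region, the derived dispersion chamber
#' (capsule + central), emitted and timed-out percentages, total
#' deposition, and the fine particle fraction (share of injected particles
#' that were emitted with a diameter below the cutoff; the cutoff is a
#' configurable convention, not a fixed constant of the method).
#'
#' @param run A [run_simulation()] result, or its `states` data.frame.
#' @param geom Geometry (taken from the run when available).
#' @param fpf_cutoff FPF diameter cutoff (m).
#' @return An object of class `deposition_report`.
#' @export
deposition_report <- function(run, geom = NULL, fpf_cutoff = 5e-6) {
  states <- if (inherits(run, "dpi_run")) run$states else run
  if (is.null(geom)) geom <- if (inherits(run, "dpi_run")) run$geom
                             else build_default_geometry()
  n <- nrow(states)
  regions <- region_names(geom)
  stuck <- states[states$status == "stuck", , drop = FALSE]
  counts <- vapply(regions, function(r) sum(stuck$stuck_region == r),
                   integer(1))
  pct <- 100 * counts / n
  emitted <- sum(states$status == "emitted")
  timeout <- sum(states$status == "in_domain_timeout")
  fpf <- 100 * sum(states$status == "emitted" & states$dp < fpf_cutoff) / n
  structure(
    list(n_injected = n,
         region_counts = counts,
         region_pct = pct,
         dispersion_chamber_pct = pct[["capsule_chamber"]] +
                                  pct[["central_chamber"]],
         total_deposition_pct = sum(pct),
         emitted_pct = 100 * emitted / n,
         timeout_pct = 100 * timeout / n,
         fpf_pct = fpf,
         fpf_cutoff = fpf_cutoff),
    class = "deposition_report"
  )
}

#' @export
print.deposition_report <- function(x, ...) {
  cat(sprintf("Deposition report (%d injected)\n", x$n_injected))
  for (r in names(x$region_pct))
    cat(sprintf("  %-16s %5.1f%% (%d)\n", r, x$region_pct[[r]],
                x$region_counts[[r]]))
  cat(sprintf("  dispersion chamber %.1f%%\n", x$dispersion_chamber_pct))
  cat(sprintf("  total deposition %.1f%%, emitted %.1f%%, timeout %.1f%%\n",
              x$total_deposition_pct, x$emitted_pct, x$timeout_pct))
  cat(sprintf("  FPF (dp < %g um) %.1f%%\n", x$fpf_cutoff * 1e6, x$fpf_pct))
  invisible(x)
}

#' Restitution-coefficient sweep
#'
#' Runs one simulation per combination of normal and tangential
#' restitution coefficients with identical seed and injection across
#' cells, and aggregates the deposition reports. The default grid is the
#' 4 x 4 set normal `{0.20, 0.25, 0.50, 0.75}` x tangential
#' `{0.25, 0.50, 0.75, 0.80}`; the wider candidate set
#' `{0.2, 0.25, 0.5, 0.75, 0.85}` squared is available by passing those
#' values.
#'
#' @param base_config [simulation_config()] whose `cor` field is swept.
#' @param e_n,e_t Normal / tangential restitution values to cross.
#' @param geom,mat,fluid Passed to [run_simulation()].
#' @return An object of class `sweep_result`: list with `grid` (a
#'   data.frame, one row per cell, with deposition and detachment-count
#'   columns) and `reports` (the per-cell [deposition_report()]s).
#' @export
cor_sweep <- function(base_config = simulation_config(),
                      e_n = c(0.20, 0.25, 0.50, 0.75),
                      e_t = c(0.25, 0.50, 0.75, 0.80),
                      geom = build_default_geometry(),
                      mat = material_parameters(),
                      fluid = fluid_properties()) {
  cells <- expand.grid(e_n = e_n, e_t = e_t, KEEP.OUT.ATTRS = FALSE)
  field <- make_analytic_field(base_config$field_kind, geom,
                               flow_rate = base_config$flow_rate,
                               swirl_strength = base_config$swirl_strength,
                               ds = base_config$ds)
  reports <- vector("list", nrow(cells))
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cfg <- base_config
    cfg$cor <- restitution_pair(cells$e_n[i], cells$e_t[i])
    run <- run_simulation(cfg, geom, field, mat, fluid)
    rep <- deposition_report(run)
    reports[[i]] <- rep
    rows[[i]] <- data.frame(
      e_n = cells$e_n[i], e_t = cells$e_t[i],
      total_deposition_pct = rep$total_deposition_pct,
      emitted_pct = rep$emitted_pct,
      timeout_pct = rep$timeout_pct,
      dispersion_chamber_pct = rep$dispersion_chamber_pct,
      grid_zone_pct = rep$region_pct[["grid_zone"]],
      mouthpiece_pct = rep$region_pct[["mouthpiece"]],
      n_detach_rolling = sum(run$detach$outcome == "detach_rolling"),
      n_detach_sliding = sum(run$detach$outcome == "detach_sliding")
    )
  }
  grid <- do.call(rbind, rows)
  structure(list(grid = grid, reports = reports,
                 seed = base_config$seed,
                 n_particles = base_config$n_particles),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("Restitution sweep: %d cells, %d particles each (seed %d)\n",
              nrow(x$grid), x$n_particles, x$seed))
  print(x$grid, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Particle-count independence check
#'
#' Re-runs the same configuration with different injected particle counts
#' and compares total deposition percentages; the model should behave
#' identically across counts. Each count is estimated as the mean over
#' `n_replicates` independent injections (seeds `seed, seed + 1, ...`):
#' replication separates finite-sample injection noise, which scales as
#' \eqn{1/\sqrt{n}} and dominates at the smallest count, from a genuine
#' dependence of the model on the particle count, which is what the check
#' is after. `n_replicates = 1` recovers the raw single-run comparison.
#'
#' @param config [simulation_config()].
#' @param counts Particle counts to compare (at least two).
#' @param tolerance_pp Flagging threshold for the maximum pairwise
#'   difference of the per-count estimates, in percentage points.
#' @param n_replicates Injections averaged per count.
#' @param geom,mat,fluid Passed to [run_simulation()].
#' @return A list with the comparison `table` (count, mean and replicate
#'   spread of total deposition), the maximum pairwise difference
#'   `max_diff_pp` and the logical flag `within_tolerance`.
#' @export
particle_count_independence <- function(config = simulation_config(),
                                        counts = c(100, 500, 5000),
                                        tolerance_pp = 3,
                                        n_replicates = 12,
                                        geom = build_default_geometry(),
                                        mat = material_parameters(),
                                        fluid = fluid_properties()) {
  if (length(counts) < 2)
    stop("particle-count independence needs at least two counts",
         call. = FALSE)
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  field <- make_analytic_field(config$field_kind, geom,
                               flow_rate = config$flow_rate,
                               swirl_strength = config$swirl_strength,
                               ds = config$ds)
  est <- lapply(counts, function(nn) {
    reps <- vapply(seq_len(n_replicates) - 1L, function(k) {
      cfg <- config
      cfg$n_particles <- as.integer(nn)
      cfg$seed <- config$seed + k
      deposition_report(run_simulation(cfg, geom, field, mat, fluid)
                        )$total_deposition_pct
    }, numeric(1))
    c(mean = mean(reps), sd = stats::sd(reps))
  })
  dep <- vapply(est, `[[`, numeric(1), "mean")
  tab <- data.frame(n_particles = counts,
                    total_deposition_pct = dep,
                    replicate_sd = vapply(est, `[[`, numeric(1), "sd"))
  max_diff <- max(abs(outer(dep, dep, "-")))
  list(table = tab, max_diff_pp = max_diff,
       within_tolerance = max_diff <= tolerance_pp,
       tolerance_pp = tolerance_pp, n_replicates = n_replicates)
}

#' Per-particle physics diagnostics tables
#'
#' Builds the diagnostic tables behind the standard deposited-particle
#' plots: drag vs adhesion moments per stuck particle, normal impact
#' velocity vs capture velocity (per stuck particle, vs impact height, and
#' vs diameter), and wall friction velocity vs the critical wall shear
#' velocities.
#'
#' @param run A [run_simulation()] result.
#' @return A list of data.frames: `moments`, `velocities`, `velocities_z`,
#'   `velocities_dp`, `shear`. Empty logs yield empty tables with a
#'   warning.
#' @export
diagnostics_tables <- function(run) {
  stopifnot(inherits(run, "dpi_run"))
  det <- run$detach
  imp <- run$impacts
  if (!nrow(det) && !nrow(imp))
    warning("run produced no wall events; diagnostics tables are empty")
  stuck_det <- det
  sticks <- imp[imp$outcome == "stick", , drop = FALSE]
  dp_of <- run$injected$dp[match(sticks$id, run$injected$id)]
  list(
    moments = data.frame(id = stuck_det$id,
                         drag_moment = stuck_det$drag_moment,
                         adhesion_moment = stuck_det$adhesion_moment),
    velocities = data.frame(id = sticks$id, vn = sticks$vn,
                            vcr = sticks$vcr),
    velocities_z = data.frame(id = imp$id, z = imp$z, vn = imp$vn,
                              vcr = imp$vcr, outcome = imp$outcome),
    velocities_dp = data.frame(id = sticks$id, dp = dp_of, vn = sticks$vn,
                               vcr = sticks$vcr),
    shear = data.frame(id = stuck_det$id, u_star = stuck_det$u_star,
                       uR_star = stuck_det$uR_star,
                       uS_star = stuck_det$uS_star,
                       outcome = stuck_det$outcome)
  )
}

#' Write run outputs as CSV/JSON files
#'
#' Writes the event logs (`stick.csv`, `impact.csv`,
#' `detach_rolling.csv`, `detach_sliding.csv`), the machine-readable
#' deposition report (`report.json`) and the diagnostics tables to a
#' directory.
#'
#' @param run A [run_simulation()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_outputs <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  imp <- run$impacts
  det <- run$detach
  utils::write.csv(imp[imp$outcome == "stick", , drop = FALSE],
                   file.path(dir, "stick.csv"), row.names = FALSE)
  utils::write.csv(imp, file.path(dir, "impact.csv"), row.names = FALSE)
  utils::write.csv(det[det$outcome == "detach_rolling", , drop = FALSE],
                   file.path(dir, "detach_rolling.csv"), row.names = FALSE)
  utils::write.csv(det[det$outcome == "detach_sliding", , drop = FALSE],
                   file.path(dir, "detach_sliding.csv"), row.names = FALSE)
  rep <- deposition_report(run)
  jsonlite::write_json(unclass(rep), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  diags <- diagnostics_tables(run)
  for (nm in names(diags))
    utils::write.csv(diags[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  invisible(dir)
}
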