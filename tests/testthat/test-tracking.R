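test_that("injection is reproducible, zero-slip, and respects the size window", {
  geom <- build_default_geometry()
  fld <- make_analytic_field("chamber_swirl", geom)
  cfg <- simulation_config(n_particles = 500, seed = 123)
  a <- inject_particles(cfg, geom, fld)
  b <- inject_particles(cfg, geom, fld)
  expect_identical(a, b)                           # bit-identical per seed
  expect_equal(nrow(a), 500)
  expect_equal(simulation_config()$n_particles, 500L)
  # initial velocity equals the local fluid velocity: zero initial slip
  v_fluid <- field_velocity(fld, as.matrix(a[, c("x", "y", "z")]))
  expect_equal(as.matrix(a[, c("vx", "vy", "vz")]), v_fluid,
               ignore_attr = TRUE)
  # release plane and disk
  expect_true(all(a$z == cfg$release_height))
  expect_true(all(a$x^2 + a$y^2 <= geom$release$radius^2))
  # truncated lognormal sizes stay in the respirable window
  expect_true(all(a$dp >= 0.5e-6 & a$dp <= 5e-6))
  expect_gt(median(a$dp), 1e-6)
  c2 <- simulation_config(n_particles = 500, seed = 124)
  expect_false(identical(inject_particles(c2, geom, fld)$x, a$x))
  expect_error(inject_particles(simulation_config(release_height = 0.1),
                                geom, fld), "release plane")
})

test_that("momentum relaxation time matches the Stokes formula", {
  expect_equal(relaxation_time(5e-6, mat0, fluid0), 9.546962e-5,
               tolerance = 1e-6)
  expect_equal(relaxation_time(0.5e-6) / relaxation_time(5e-6), 0.01)
})

test_that("reference integrator: zero slip advects exactly, still fluid relaxes exponentially", {
  u <- c(0.4, -0.2, 1.5)
  fld <- uniform_field(u)
  p <- list(x = c(0, 0, 0), v = u, dp = 2e-6)
  for (i in 1:25) p <- step_particle(p, fld, fluid0, mat0, dt = 1e-5)
  expect_equal(p$x, u * 25e-5, tolerance = 1e-12)   # zero slip is a fixed point
  expect_equal(p$v, u)
  # velocity decay in still fluid matches exp(-t/tau) (exact integrator)
  tau <- relaxation_time(5e-6, mat0, fluid0)
  q <- list(x = c(0, 0, 0), v = c(1, 0, 0), dp = 5e-6)
  still <- uniform_field(c(0, 0, 0))
  for (i in 1:10) q <- step_particle(q, still, fluid0, mat0, dt = tau / 10)
  expect_equal(q$v[1], exp(-1), tolerance = 1e-9)
  expect_lt(abs(q$v[1] - exp(-1)) / exp(-1), 0.01)  # stated accuracy bound
  expect_error(step_particle(q, still, fluid0, mat0, dt = 0), "dt")
})

test_that("compiled integrator reproduces the analytic velocity decay", {
  # still fluid as a gridded zero field spanning the chamber
  xs <- seq(-0.01, 0.01, length.out = 3)
  zs <- seq(0, 0.07, length.out = 3)
  still <- sample_field_to_grid(uniform_field(c(0, 0, 0)), xs, xs, zs)
  tau <- relaxation_time(3e-6, mat0, fluid0)
  Tend <- 5 * tau
  k <- compliances(mat0)
  phys <- list(mu = fluid0$mu, rho = fluid0$rho, rho_M = fluid0$rho_M,
               rho_p = mat0$rho_p, Cu = mat0$Cu, f = mat0$f, ks = mat0$ks,
               WA = mat0$WA, KC = composite_young(mat0),
               E_cap = elbatsh_parameter(k[["k1"]], k[["k2"]], mat0$rho_p),
               e_n = 0.75, e_t = 0.75, ds = 5e-5)
  control <- list(dt_tau_factor = 0.1, dt_floor = 1e-9, dt_cross_len = 5e-4,
                  dt_max = 5e-5, max_time = Tend, max_impacts = 10L)
  init <- matrix(c(1, 3e-6, 0, 0, 0.01, 1e-4, 0, 0), nrow = 1)
  out <- dpitrack:::cpp_track(init, still$cpp_spec,
                              dpitrack:::.geom_cpp(build_default_geometry()),
                              phys, control)
  expect_equal(out$states$vx[1], 1e-4 * exp(-5), tolerance = 1e-6)
  expect_equal(out$states$status[1], 3L)           # timed out in still fluid
})

test_that("particle bookkeeping is conserved and terminal states are coherent", {
  for (s in c(1, 9)) {
    run <- small_run(n = 120, seed = s)
    st <- run$states
    expect_equal(nrow(st), 120)
    expect_true(all(st$status %in% c("stuck", "emitted",
                                     "in_domain_timeout")))
    counts <- table(factor(st$status, levels = c("stuck", "emitted",
                                                 "in_domain_timeout")))
    expect_equal(sum(counts), 120)
    stuck <- st[st$status == "stuck", ]
    expect_true(all(!is.na(stuck$stuck_region)))
    expect_true(all(stuck$stuck_region %in% region_names(run$geom)))
    emitted <- st[st$status == "emitted", ]
    expect_equal(emitted$z, rep(run$geom$outlet$z, nrow(emitted)),
                 tolerance = 1e-9)
    # one detachment assessment per stick event
    expect_equal(nrow(run$detach),
                 sum(run$impacts$outcome == "stick"))
  }
})

test_that("identical config and seed give identical event logs", {
  r1 <- small_run(n = 100, seed = 4)
  r2 <- small_run(n = 100, seed = 4)
  expect_identical(r1$states, r2$states)
  expect_identical(r1$impacts, r2$impacts)
  expect_identical(r1$detach, r2$detach)
})

test_that("compiled wall physics agrees with the R reference functions on the event logs", {
  run <- small_run(n = 150, seed = 8)
  imp <- run$impacts
  expect_gt(nrow(imp), 0)
  dp_imp <- run$injected$dp[match(imp$id, run$injected$id)]
  k <- compliances(run$mat)
  E0 <- elbatsh_parameter(k[["k1"]], k[["k2"]], run$mat$rho_p)
  # capture velocity recomputed by the R route
  expect_equal(imp$vcr, capture_velocity(dp_imp, E0), tolerance = 1e-12)
  # stick/bounce outcomes match the R decision rule
  expect_equal(imp$outcome, sticking_decision(imp$vn, imp$vcr))
  det <- run$detach
  dp_det <- run$injected$dp[match(det$id, run$injected$id)]
  expect_equal(det$uR_star,
               critical_shear_rolling(dp_det, run$mat, run$fluid),
               tolerance = 1e-12)
  expect_equal(det$uS_star,
               critical_shear_sliding(dp_det, run$mat, run$fluid),
               tolerance = 1e-12)
  expect_equal(det$FD,
               wall_drag_force(dp_det, det$u_star, run$fluid,
                               run$mat$f, run$mat$Cu),
               tolerance = 1e-12)
  # outcome equals the scalar reference decision at the sampled u*
  ref <- vapply(seq_len(nrow(det)), function(i)
    detachment_decision(dp_det[i], det$u_star[i], run$mat,
                        run$fluid)$outcome, character(1))
  expect_equal(det$outcome, ref)
})

test_that("a zero-flow field strands every particle inside the device", {
  xs <- seq(-0.011, 0.011, length.out = 3)
  zs <- seq(0, 0.071, length.out = 3)
  still <- sample_field_to_grid(uniform_field(c(0, 0, 0)), xs, xs, zs)
  cfg <- simulation_config(n_particles = 30, seed = 2, max_time = 0.01)
  run <- run_simulation(cfg, field = still)
  expect_true(all(run$states$status != "emitted"))
})
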