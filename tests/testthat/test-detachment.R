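# bisection oracles: roots of the raw moment/force balances, independent of
# the closed forms under test
oracle_uR <- function(dp, mat = mat0, fluid = fluid0) {
  stats::uniroot(function(u)
    wall_drag_force(dp, u, fluid, mat$f, mat$Cu) * dp / 2 -
      adhesion_force(dp, mat) * contact_radius(dp, mat),
    c(1e-6, 1e4), tol = 1e-12)$root
}
oracle_uS <- function(dp, mat = mat0, fluid = fluid0) {
  stats::uniroot(function(u)
    wall_drag_force(dp, u, fluid, mat$f, mat$Cu) - mat$ks * adhesion_force(dp, mat),
    c(1e-6, 1e4), tol = 1e-12)$root
}

test_that("free-flight drag is Stokes drag, linear in slip speed and diameter", {
  expect_equal(stokes_drag(2e-6, 0, fluid0), 0)
  expect_equal(stokes_drag(2e-6, 3, fluid0) / stokes_drag(2e-6, 1, fluid0), 3)
  expect_equal(stokes_drag(4e-6, 1, fluid0) / stokes_drag(2e-6, 1, fluid0), 2)
  expect_equal(stokes_drag(1e-6, 1, fluid0, f = 1.7, Cu = 1) /
                 stokes_drag(1e-6, 1, fluid0), 1.7)
  expect_error(stokes_drag(1e-6, -1, fluid0), "non-negative")
})

test_that("sublayer velocity is quadratic in the friction velocity", {
  expect_equal(sublayer_velocity(2e-6, 0, fluid0), 0)
  expect_equal(sublayer_velocity(2e-6, 2, fluid0) /
                 sublayer_velocity(2e-6, 1, fluid0), 4)
})

test_that("wall drag equals the sublayer/Stokes composition to machine precision", {
  dp <- seq(0.5e-6, 5e-6, length.out = 20)
  us <- seq(0.1, 5, length.out = 20)
  for (d in dp) {
    direct <- wall_drag_force(d, us, fluid0, f = 1.7, Cu = 1)
    composed <- stokes_drag(d, sublayer_velocity(d, us, fluid0), fluid0,
                            f = 1.7, Cu = 1)
    expect_lt(max(abs(direct - composed) / composed), 1e-9)
  }
  # the printed coefficient 5.1 is 3 f at f = 1.7
  expect_equal(wall_drag_force(1e-6, 1, fluid0) /
                 ((pi / 2) * (1e-6)^2 * fluid0$rho), 5.1)
})

test_that("rolling and sliding criteria are inclusive at the balance point", {
  expect_false(rolling_check(0, 1e-6, 1e-8, 5e-8))
  expect_false(sliding_check(0, 0.5, 1e-8))
  Fst <- adhesion_force(2e-6, mat0); a <- contact_radius(2e-6, mat0)
  FD_bal <- Fst * a / (2e-6 / 2)
  expect_true(rolling_check(FD_bal, 2e-6, Fst, a))            # exact tie
  expect_false(rolling_check(FD_bal * (1 - 1e-9), 2e-6, Fst, a))
  expect_true(sliding_check(0.5 * Fst, 0.5, Fst))
  expect_false(sliding_check(0.5 * Fst * (1 - 1e-9), 0.5, Fst))
})

test_that("closed-form critical shear velocities match the bisection roots within 2%", {
  dp <- exp(seq(log(0.1e-6), log(10e-6), length.out = 25))
  uR <- critical_shear_rolling(dp, mat0, fluid0)
  uS <- critical_shear_sliding(dp, mat0, fluid0)
  for (i in seq_along(dp)) {
    expect_lt(abs(uR[i] - oracle_uR(dp[i])) / oracle_uR(dp[i]), 0.02)
    expect_lt(abs(uS[i] - oracle_uS(dp[i])) / oracle_uS(dp[i]), 0.02)
  }
  # frozen oracle roots
  expect_equal(critical_shear_rolling(1e-6), 31.376855, tolerance = 1e-5)
  expect_equal(critical_shear_rolling(5e-6), 10.730733, tolerance = 1e-5)
  expect_equal(critical_shear_sliding(5e-6), 30.600238, tolerance = 1e-5)
})

test_that("sliding root satisfies its defining balance exactly and scales as dp^-1/2", {
  dp <- c(0.5, 1, 2, 5) * 1e-6
  uS <- critical_shear_sliding(dp, mat0, fluid0)
  expect_equal(wall_drag_force(dp, uS, fluid0, mat0$f, mat0$Cu),
               mat0$ks * adhesion_force(dp, mat0))
  expect_equal(uS[2] / uS[4], sqrt(5), tolerance = 1e-12)
})

test_that("as-printed audit variants return the literal published expressions", {
  dp <- 2e-6
  KC <- composite_young(mat0)
  expect_equal(critical_shear_rolling(dp, mat0, fluid0, "as_printed"),
               (1 / fluid0$rho) * (1 / KC)^(1 / 3) * (mat0$WA / dp)^(4 / 3))
  expect_equal(critical_shear_sliding(dp, mat0, fluid0, "as_printed"),
               0.5 * mat0$ks * mat0$WA / (mat0$rho_p * dp))
  # the force-balance rolling form reproduces the printed bracket up to a
  # coefficient of about 0.986 (in the squared velocity)
  ratio <- critical_shear_rolling(dp, mat0, fluid0)^2 /
    critical_shear_rolling(dp, mat0, fluid0, "as_printed")
  expect_equal(ratio, 3 * (3 * pi / 2)^(1 / 3) / 5.1, tolerance = 1e-12)
  expect_equal(ratio, 0.986, tolerance = 1e-3)
  expect_error(critical_shear_rolling(dp, mat0, fluid0, "nonsense"))
})

test_that("monotonicity: thresholds fall and adhesion grows with diameter", {
  dp <- exp(seq(log(0.1e-6), log(10e-6), length.out = 60))
  k <- compliances(mat0)
  E0 <- elbatsh_parameter(k[["k1"]], k[["k2"]], mat0$rho_p)
  expect_true(all(diff(capture_velocity(dp, E0)) < 0))
  expect_true(all(diff(critical_shear_rolling(dp, mat0, fluid0)) < 0))
  expect_true(all(diff(critical_shear_sliding(dp, mat0, fluid0)) < 0))
  expect_true(all(diff(adhesion_force(dp, mat0)) > 0))
  expect_true(all(diff(contact_radius(dp, mat0)) > 0))
})

test_that("detachment decision is consistent with the critical-shear comparison", {
  expect_equal(detachment_decision(2e-6, 0)$outcome, "remain_stuck")
  # realistic near-wall shear cannot detach micron particles
  for (dp in c(0.5, 1, 2.5, 5) * 1e-6)
    for (us in c(0.05, 0.3, 1))
      expect_equal(detachment_decision(dp, us, mat0, fluid0)$outcome,
                   "remain_stuck")
  # outcome flips exactly at the rolling threshold (rolling precedes
  # sliding: uR* < uS* for these materials)
  for (dp in c(0.8, 2, 4) * 1e-6) {
    uR <- critical_shear_rolling(dp, mat0, fluid0)
    uS <- critical_shear_sliding(dp, mat0, fluid0)
    expect_lt(uR, uS)
    below <- detachment_decision(dp, uR * (1 - 1e-9), mat0, fluid0)
    above <- detachment_decision(dp, uR * (1 + 1e-9), mat0, fluid0)
    expect_equal(below$outcome, "remain_stuck")
    expect_equal(above$outcome, "detach_rolling")
    expect_lt(below$drag_moment, below$adhesion_moment)
    expect_gte(above$drag_moment, above$adhesion_moment)
    # far above both thresholds the sliding flag is set too, but rolling
    # keeps precedence
    both <- detachment_decision(dp, uS * 1.01, mat0, fluid0)
    expect_true(both$rolling && both$sliding)
    expect_equal(both$outcome, "detach_rolling")
  }
  expect_error(detachment_decision(1e-6, -0.1), "u_star")
})

test_that("the physics table spans the diameter grid coherently", {
  tab <- physics_table(0.5e-6, 5e-6, n = 12)
  expect_equal(nrow(tab), 12)
  expect_equal(tab$dp[1], 0.5e-6)
  expect_equal(tab$dp[12], 5e-6)
  expect_true(all(diff(tab$vcr) < 0))
  expect_true(all(tab$uR_star < tab$uS_star))
  expect_equal(tab$Fst, adhesion_force(tab$dp, mat0))
})
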