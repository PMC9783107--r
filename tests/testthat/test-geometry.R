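geomT <- build_default_geometry()

test_that("default geometry is valid and ordered bottom to top", {
  expect_equal(region_names(geomT),
               c("capsule_chamber", "central_chamber", "grid_zone",
                 "mouthpiece"))
  reg <- geomT$regions
  # regions partition the axis without gaps or overlaps
  expect_equal(reg$z_lo[-1], reg$z_hi[-4])
  expect_equal(reg$z_lo[1], 0)
  expect_equal(geomT$release$z, 12.5e-3)
  expect_true(geomT$release$z > reg$z_lo[1] && geomT$release$z < reg$z_hi[1])
  expect_error(build_default_geometry(capsule_height = 0.010),
               "release plane")
  expect_error(build_default_geometry(grid_radius = -1), "positive")
  expect_error(build_default_geometry(open_fraction = 1.2), "open_fraction")
  expect_error(build_default_geometry(mouth_radius = 0.008),
               "narrow")
})

test_that("points are assigned to the correct region", {
  expect_equal(region_of(geomT, c(0, 0, geomT$release$z)), "capsule_chamber")
  expect_equal(region_of(geomT, c(0.001, 0.001, 0.03)), "central_chamber")
  expect_equal(region_of(geomT, c(0, 0.002, geomT$screen$z + 1e-4)),
               "grid_zone")
  expect_equal(region_of(geomT, c(0, 0, 0.06)), "mouthpiece")
  expect_error(region_of(geomT, c(0, 0, 1)), "outside")
  expect_error(region_of(geomT, c(0.02, 0, 0.05)), "outside")
  expect_equal(radius_at(geomT, 0.01), 0.010)
  expect_equal(radius_at(geomT, 0.06), 0.00515)
})

test_that("screen mask has the configured open-area fraction", {
  set.seed(3)
  x <- runif(2e5, -0.004, 0.004); y <- runif(2e5, -0.004, 0.004)
  frac <- mean(screen_open(geomT, x, y))
  expect_lt(abs(frac - geomT$screen$open_fraction), 0.01)
  # mask is periodic with the pitch
  p <- geomT$screen$pitch
  expect_equal(screen_open(geomT, x[1:100], y[1:100]),
               screen_open(geomT, x[1:100] + 3 * p, y[1:100] - 2 * p))
})

test_that("path intersection classifies walls, shoulders, bars, and the outlet", {
  # purely interior step
  expect_null(intersect_path(geomT, c(0, 0, 0.01), c(0.001, 0, 0.012)))
  # radial step through the capsule wall: inward radial normal
  hit <- intersect_path(geomT, c(0, 0, 0.01), c(0.02, 0, 0.01))
  expect_s3_class(hit, "wall_hit")
  expect_equal(hit$kind, "wall")
  expect_equal(hit$region, "capsule_chamber")
  expect_equal(hit$point, c(0.010, 0, 0.01))
  expect_equal(hit$normal, c(-1, 0, 0))
  # downward step to the bottom plate
  bot <- intersect_path(geomT, c(0.002, 0, 0.005), c(0.002, 0, -0.005))
  expect_equal(bot$normal, c(0, 0, 1))
  # upward through an open screen cell: no event below the mouthpiece wall
  pc <- geomT$screen$pitch / 2
  thr <- intersect_path(geomT, c(pc, pc, 0.039), c(pc, pc, 0.041))
  expect_null(thr)
  # upward into a bar (lattice line x = 0 is closed)
  bar <- intersect_path(geomT, c(0, 0, 0.039), c(0, 0, 0.041))
  expect_equal(bar$kind, "grid_bar")
  expect_equal(bar$region, "grid_zone")
  expect_equal(bar$normal, c(0, 0, -1))
  expect_equal(bar$point[3], geomT$screen$z)
  # shoulder: upward at r = 8 mm is blocked by the grid-zone annulus
  sh <- intersect_path(geomT, c(0.008, 0, 0.039), c(0.008, 0, 0.041))
  expect_equal(sh$kind, "wall")
  expect_equal(sh$normal, c(0, 0, -1))
  expect_equal(sh$region, "central_chamber")
  # outlet crossing is an emission surface, not a wall
  out <- intersect_path(geomT, c(pc, pc, 0.069), c(pc, pc, 0.071))
  expect_equal(out$kind, "outlet")
  # degenerate zero-length segment
  expect_null(intersect_path(geomT, c(0, 0, 0.01), c(0, 0, 0.01)))
})

test_that("random interior rays always terminate on a classified boundary", {
  set.seed(17)
  n <- 2e4
  zb <- geomT$z_breaks
  z <- runif(n, 1e-4, zb[5] - 1e-4)
  Rz <- radius_at(geomT, z)
  r <- 0.98 * Rz * sqrt(runif(n)); th <- runif(n, 0, 2 * pi)
  p0 <- cbind(r * cos(th), r * sin(th), z)
  dir <- matrix(rnorm(3 * n), ncol = 3)
  dir <- dir / sqrt(rowSums(dir^2))
  L <- 0.2                                 # longer than any domain chord
  kinds <- character(n)
  unit_ok <- inward_ok <- logical(n)
  for (i in seq_len(n)) {
    h <- intersect_path(geomT, p0[i, ], p0[i, ] + L * dir[i, ])
    if (is.null(h)) next                   # leaves kinds[i] == "" -> flagged
    kinds[i] <- h$kind
    unit_ok[i] <- abs(sum(h$normal^2) - 1) < 1e-9
    # normals point back into the domain: a small inward step is interior
    inward_ok[i] <- !inherits(try(region_of(geomT, h$point + 1e-7 * h$normal),
                                  silent = TRUE), "try-error")
  }
  expect_true(all(kinds %in% c("wall", "grid_bar", "outlet")))
  expect_true(all(unit_ok))
  expect_true(all(inward_ok))
  expect_true(all(c("wall", "outlet") %in% kinds))
})

test_that("compiled and R-side intersection agree on random segments", {
  set.seed(29)
  gcpp <- dpitrack:::.geom_cpp(geomT)
  agree <- logical(500)
  for (i in 1:500) {
    z <- runif(1, 1e-4, geomT$z_breaks[5] - 1e-4)
    r <- 0.98 * radius_at(geomT, z) * sqrt(runif(1)); th <- runif(1, 0, 2 * pi)
    p0 <- c(r * cos(th), r * sin(th), z)
    p1 <- p0 + runif(1, 1e-4, 0.05) * {
      d <- rnorm(3); d / sqrt(sum(d^2))
    }
    hR <- intersect_path(geomT, p0, p1)
    hC <- dpitrack:::cpp_intersect_path(p0, p1, gcpp)
    agree[i] <- if (is.null(hR)) !hC$any else {
      hC$any &&
        abs(hC$t - hR$t) < 1e-9 &&
        max(abs(hC$point - hR$point)) < 1e-9 &&
        max(abs(hC$normal - hR$normal)) < 1e-9 &&
        region_names(geomT)[hC$region] == hR$region &&
        c("wall", "grid_bar", "outlet")[hC$kind] == hR$kind
    }
  }
  expect_true(all(agree))
})
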