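test_that("mean divergence recovers 2k for a linear radial field", {
  f <- make_field(n = 64, k = 0.05)
  expect_equal(mean_divergence(f), 0.10, tolerance = 1e-3)
})

test_that("mean divergence vanishes for rigid translations and rotations", {
  expect_lt(abs(mean_divergence(make_field(n = 64, const = c(0.3, -0.2)))),
            1e-9)
  expect_lt(abs(mean_divergence(make_field(n = 64, omega = 0.04))), 1e-9)
})

test_that("divergence is invariant to adding a constant field", {
  f1 <- make_field(n = 48, k = 0.03)
  f2 <- make_field(n = 48, k = 0.03, const = c(0.5, -0.1))
  expect_equal(mean_divergence(f1), mean_divergence(f2), tolerance = 1e-12)
})

test_that("divergence estimator converges at second order on smooth fields", {
  # u = (sin x cos y, -cos x sin y): div = 0 analytically? no:
  # d/dx sin(x)cos(y) + d/dy (x cos y) ... use u = (x^2, y^2): div = 2x+2y
  err_at <- function(n) {
    g <- make_grid(n)
    f <- displacement_field(data.frame(
      g, ux_mm = g$x_mm^2, uy_mm = g$y_mm^2, mask = disk_mask(g)))
    dm <- divergence_map(f)
    max(abs(dm$divergence - 2 * (dm$x_mm + dm$y_mm)))
  }
  e32 <- err_at(32); e64 <- err_at(64)
  # quadratic fields are differenced exactly by central stencils; the
  # one-sided boundary cells dominate the max error and shrink ~ h
  expect_lt(e64, 0.6 * e32)

  # interior cells (full central stencils) are exact for quadratics
  g <- make_grid(48)
  f <- displacement_field(data.frame(
    g, ux_mm = g$x_mm^2, uy_mm = g$y_mm^2, mask = disk_mask(g, 0.7)))
  dm <- divergence_map(f)
  interior <- dm$x_mm^2 + dm$y_mm^2 < 0.6^2
  expect_lt(max(abs(dm$divergence[interior] -
                      2 * (dm$x_mm + dm$y_mm)[interior])), 1e-10)
})

test_that("gridding reproduces affine fields exactly", {
  pts <- scatter_from_function(200, function(x, y) {
    list(0.1 + 0 * x, -0.2 + 0 * y)
  })
  f <- grid_interpolate(pts, nx = 32, ny = 32)
  expect_lt(max(abs(f$ux_mm[f$mask] - 0.1)), 1e-10)
  expect_lt(max(abs(f$uy_mm[f$mask] + 0.2)), 1e-10)

  pts2 <- scatter_from_function(300, function(x, y) {
    list(0.05 * x, 0.05 * y)
  }, seed = 2)
  f2 <- grid_interpolate(pts2, nx = 32, ny = 32)
  expect_lt(max(abs(f2$ux_mm[f2$mask] - 0.05 * f2$x_mm[f2$mask])), 1e-10)
  expect_equal(mean_divergence(f2), 0.10, tolerance = 1e-6)
})

test_that("gridding error on a smooth field shrinks with point density", {
  fun <- function(x, y) list(0.05 * sin(2 * x) * cos(y),
                             0.05 * cos(x) * sin(2 * y))
  err <- vapply(c(200, 1600), function(np) {
    pts <- scatter_from_function(np, fun, seed = 3)
    f <- grid_interpolate(pts, nx = 24, ny = 24, k = 10)
    m <- f$mask
    tru <- fun(f$x_mm[m], f$y_mm[m])
    sqrt(mean((f$ux_mm[m] - tru[[1]])^2 + (f$uy_mm[m] - tru[[2]])^2))
  }, numeric(1))
  expect_lt(err[2], err[1])
  # 8x the points ~ 1/8 the squared spacing: expect at least ~4x drop
  expect_lt(err[2], err[1] / 2)
})

test_that("gridding never extrapolates outside the convex hull", {
  set.seed(4)
  th <- runif(60, 0, 2 * pi)
  r <- sqrt(runif(60)) * 0.5
  pts <- tibble::tibble(x_mm = r * cos(th), y_mm = r * sin(th),
                        ux_mm = 0.1, uy_mm = 0)
  f <- grid_interpolate(pts, nx = 40, ny = 40)
  outside <- !f$mask
  expect_true(all(is.na(f$ux_mm[outside])))
})

test_that("degenerate point sets are rejected", {
  expect_error(grid_interpolate(tibble::tibble(
    x_mm = 1:2, y_mm = c(0, 0), ux_mm = 0, uy_mm = 0)), "3")
  expect_error(grid_interpolate(tibble::tibble(
    x_mm = 1:10, y_mm = 2 * (1:10), ux_mm = 0, uy_mm = 0)), "collinear")
})

test_that("strain components match closed forms", {
  f <- make_field(n = 48, k = 0.03)
  sc <- strain_components(f)
  expect_equal(max(abs(sc$eps_xx - 0.03)), 0, tolerance = 1e-10)
  expect_equal(max(abs(sc$eps_yy - 0.03)), 0, tolerance = 1e-10)
  expect_equal(max(abs(sc$principal_max - 0.03)), 0, tolerance = 1e-10)
  expect_equal(longitudinal_strain(f), 3, tolerance = 1e-8)

  # small rigid rotation: principal strains vanish to first order
  fr <- make_field(n = 48, omega = 1e-5)
  scr <- strain_components(fr)
  expect_lt(max(abs(scr$principal_max)), 1e-8)
})

test_that("strain rate series finds peak rate and force at peak", {
  # linear strain ramp 0 -> 10% over 1 s: constant rate 10 %/s
  ts <- seq(0, 1, by = 0.1)
  fields <- lapply(ts, function(t) {
    make_field(n = 24, k = 0.10 * t / 2, timestamp = t) # strain k*100 pct
  })
  force <- tibble::tibble(t_s = ts, fz_N = 5 * ts)
  out <- strain_rate_series(fields, force)
  expect_equal(out$series$strain_pct[11], 5, tolerance = 1e-6)
  expect_equal(max(abs(out$series$strain_rate_pct_s - 5)), 0,
               tolerance = 1e-6)
  expect_equal(out$peak_rate_pct_s, 5, tolerance = 1e-6)
  expect_true(out$force_at_peak_N >= 0 && out$force_at_peak_N <= 5)

  expect_error(strain_rate_series(fields[1]), "2 frames")
  bad <- fields
  attr(bad[[2]], "timestamp") <- -1
  expect_error(strain_rate_series(bad, force), "increasing")
})

test_that("sigmoidal strain profile peak rate matches analytic derivative", {
  # strain(t) = S / (1 + exp(-(t - t0)/tau)): peak rate S/(4 tau) at t0
  S <- 8; t0 <- 0.5; tau <- 0.12
  ts <- seq(0, 1, by = 0.02)
  fields <- lapply(ts, function(t) {
    k <- (S / 100) / (1 + exp(-(t - t0) / tau))
    make_field(n = 24, k = k, timestamp = t)
  })
  out <- strain_rate_series(fields)
  expect_equal(out$peak_rate_pct_s, S / (4 * tau), tolerance = 0.05)
  expect_equal(out$t_peak_s, t0, tolerance = 0.05)
})

test_that("strain energy matches the uniform biaxial closed form", {
  expect_identical(strain_energy(make_field(n = 32, k = 0)), 0)
  f <- make_field(n = 64, k = 0.02, mask_radius = 0.9)
  E <- 0.1; nu <- 0.4; t <- 1.5
  A <- sum(f$mask) * attr(f, "dx") * attr(f, "dy")
  # uniform biaxial strain eps: U = E eps^2 A t / (1 - nu)
  expected <- E * 0.02^2 * A * t / (1 - nu)
  got <- strain_energy(f, modulus_mpa = E, thickness_mm = t, poisson = nu)
  # boundary cells miss full stencils; compare within a few percent
  expect_equal(got, expected, tolerance = 0.05)
  # quadratic scaling
  f2 <- make_field(n = 64, k = 0.04, mask_radius = 0.9)
  expect_equal(strain_energy(f2, E, t, nu) / got, 4, tolerance = 1e-6)
  expect_error(strain_energy(f, modulus_mpa = -1), "physical")
})

test_that("global displacement flags trials beyond the 0.3 mm rule", {
  f_move <- make_field(n = 24, const = c(0.4, 0))
  g1 <- global_displacement(f_move)
  expect_true(g1$excluded)
  expect_equal(g1$magnitude_mm, 0.4, tolerance = 1e-12)

  f_keep <- make_field(n = 24, const = c(0.29, 0))
  expect_false(global_displacement(f_keep)$excluded)

  f_rad <- make_field(n = 25, k = 0.05)  # odd n: symmetric about 0
  g3 <- global_displacement(f_rad)
  expect_lt(g3$magnitude_mm, 1e-9)
  expect_false(g3$excluded)
})

test_that("displacement_field validates its inputs", {
  g <- make_grid(8)
  expect_error(displacement_field(
    data.frame(g[-1, ], ux_mm = 0, uy_mm = 0, mask = TRUE)), "incomplete")
  expect_error(displacement_field(
    data.frame(g, ux_mm = 0, uy_mm = 0, mask = FALSE)), "mask")
  expect_error(displacement_field(
    data.frame(g, ux_mm = NA_real_, uy_mm = 0, mask = TRUE)), "finite")
})
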