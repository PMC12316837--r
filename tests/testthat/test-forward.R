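# Forward-solver validation against closed forms and the analytic cylinder
# series.

med <- background_medium()

test_that("incident field matches the line-source definition and decays in a lossy medium", {
  kb <- wavenumbers(med, 1e9)$kb
  tx <- c(0.075, 0)
  pts <- rbind(c(0.01, 0.02), c(0.01, -0.02), c(-0.03, 0.005))
  E <- incident_field(tx, pts, kb)
  # mirror-symmetric points see identical fields
  expect_equal(E[1], E[2], tolerance = 1e-13)
  # definition at a probe point
  d <- sqrt(sum((pts[3, ] - tx)^2))
  expect_equal(E[3], (1i / 4) * zhankel1(0, kb * d), tolerance = 1e-13)
  # strictly decaying magnitude with distance along a ray
  dd <- seq(0.01, 0.12, by = 0.005)
  ray <- cbind(0.075 - dd, 0)
  expect_true(all(diff(Mod(incident_field(tx, ray, kb))) < 0))
  expect_error(incident_field(tx, rbind(tx), kb), "source location")
})

test_that("self-cell integral matches numerical quadrature of G over the equivalent disc", {
  g <- grid_spec(4, 0.002)
  kb <- wavenumbers(med, 1.5e9)$kb
  a <- g$cell_size / sqrt(pi)
  closed <- (1i / (2 * kb^2)) * (pi * kb * a * zhankel1(1, kb * a) + 2i)
  # 2*pi int_0^a (i/4) H0(kb r) r dr, real and imaginary parts separately
  fre <- function(r) Re((1i / 4) * zhankel1(0, kb * r) * 2 * pi * r)
  fim <- function(r) Im((1i / 4) * zhankel1(0, kb * r) * 2 * pi * r)
  quad <- integrate(fre, 0, a, rel.tol = 1e-10)$value +
    1i * integrate(fim, 0, a, rel.tol = 1e-10)$value
  expect_lt(Mod(closed - quad) / Mod(quad), 1e-6)
})

test_that("zero contrast gives the incident field and exactly zero scattered data", {
  g <- grid_spec(12, 0.002)
  freqs <- frequency_grid(2, 1e9, 2e9)
  ant <- antenna_array(6, 0.075)
  dmap <- cylinder_dielectric_map(g, freqs, med, R = 0.008,
                                  eps_r_cyl = 20, sigma_cyl = 0.6)
  sol <- solve_total_field(dmap, 1e9, ant)
  kb <- wavenumbers(med, 1e9)$kb
  expect_equal(sol$E[, 1], incident_field(ant$positions[1, ], g, kb),
               tolerance = 1e-14)
  sim <- simulate_multistatic(dmap, ant)
  expect_true(all(sim$Es == 0))
})

test_that("a single contrast cell reproduces the one-term Born sum", {
  g <- grid_spec(8, 0.002)
  freqs <- frequency_grid(1, 1e9, 1e9)
  ant <- antenna_array(4, 0.075)
  n <- g$n
  eps_r <- array(med$eps_rb, c(n, n, 1)); sigma <- array(med$sigma_b, c(n, n, 1))
  eps_r[4, 5, 1] <- 22
  dmap <- new_dielectric_map(g, freqs, med, eps_r, sigma)
  sol <- solve_total_field(dmap, 1e9, ant)
  sim <- scattered_at_receivers(sol)
  cell <- which(sol$chi != 0)
  expect_length(cell, 1)
  Crx <- cell_green_matrix(ant$positions, g, sol$kb)
  pred <- sol$k0^2 * sol$chi[cell] * outer(Crx[, cell], sol$E[cell, ])
  expect_equal(sim, pred, tolerance = 1e-12)
})

test_that("MoM receiver data and internal fields match the cylinder series within 2%", {
  g <- grid_spec(24, 0.002)
  freqs <- frequency_grid(2, 1e9, 2e9)
  ant <- antenna_array(8, 0.075)
  dmap <- cylinder_dielectric_map(g, freqs, med, R = 0.012,
                                  eps_r_cyl = 30, sigma_cyl = 1.0)
  cache <- forward_cache(g, ant, freqs, med)
  sim <- simulate_multistatic(dmap, ant, cache)
  for (j in 1:2) {
    f <- freqs$frequencies[j]
    eps_c <- 30 + 1i * 1.0 / (2 * pi * f * 8.8541878128e-12)
    ref <- cylinder_scattered_series(0.012, eps_c, med, f, ant)
    err <- sqrt(sum(Mod(sim$Es[, , j] - ref)^2) / sum(Mod(ref)^2))
    expect_lt(err, 0.02)
  }
  f <- 1e9
  sol <- solve_total_field(dmap, f, ant, cache)
  eps_c <- 30 + 1i * 1.0 / (2 * pi * f * 8.8541878128e-12)
  Eref <- cylinder_total_series(0.012, eps_c, med, f, g$coords,
                                ant$positions[1, ])
  expect_lt(sqrt(sum(Mod(sol$E[, 1] - Eref)^2) / sum(Mod(Eref)^2)), 0.02)
})

test_that("multi-static matrices are reciprocal to solver precision", {
  g <- grid_spec(16, 0.002)
  freqs <- frequency_grid(2, 0.5e9, 2e9)
  ant <- antenna_array(8, 0.075)
  ph <- breast_phantom(grid = g, freqs = freqs, breast_radius = 0.014,
                       skin_thickness = 0.002, tumor_center = c(0.006, 0),
                       tumor_radius = 0.003)
  sim <- simulate_multistatic(ph$dielectric, ant)
  for (j in 1:2) {
    m <- sim$Es[, , j]
    expect_lt(max(Mod(m - t(m))) / max(Mod(m)), 1e-8)
  }
})

test_that("full-scale acquisition geometry yields a 16 x 16 x 16 complex array", {
  g <- grid_spec(10, 0.002)
  freqs <- frequency_grid(16, 0.5e9, 2e9)
  ant <- antenna_array(16, 0.075)
  dmap <- cylinder_dielectric_map(g, freqs, med, R = 0.006,
                                  eps_r_cyl = 25, sigma_cyl = 0.8)
  sim <- simulate_multistatic(dmap, ant)
  expect_identical(dim(sim$Es), c(16L, 16L, 16L))
  expect_true(all(is.finite(Re(sim$Es)) & is.finite(Im(sim$Es))))
  expect_identical(length(freqs$frequencies), 16L)
  expect_equal(range(freqs$frequencies), c(0.5e9, 2e9))
  expect_equal(diff(freqs$frequencies), rep(1.5e9 / 15, 15))
})

test_that("rotating phantom and array together permutes the matrix exactly", {
  # 4 antennas (90 degree spacing): the grid and a centred cylinder are both
  # invariant under the rotation, so E_s[i, j] == E_s[i+1, j+1] cyclically.
  g <- grid_spec(16, 0.002)
  freqs <- frequency_grid(1, 1e9, 1e9)
  ant <- antenna_array(4, 0.075)
  dmap <- cylinder_dielectric_map(g, freqs, med, R = 0.009,
                                  eps_r_cyl = 28, sigma_cyl = 0.9)
  m <- simulate_multistatic(dmap, ant)$Es[, , 1]
  perm <- c(2, 3, 4, 1)
  expect_equal(m[perm, perm], m, tolerance = 1e-8)
})

test_that("scattering is linear in the contrast in the Born limit", {
  g <- grid_spec(12, 0.002)
  freqs <- frequency_grid(1, 1e9, 1e9)
  ant <- antenna_array(4, 0.075)
  born_pred <- NULL
  prev_dev <- Inf
  for (s in c(1, 0.1, 0.01)) {
    dmap <- cylinder_dielectric_map(g, freqs, med, R = 0.008,
                                    eps_r_cyl = 20 + 10 * s,
                                    sigma_cyl = 0.6 + 0.4 * s)
    sol <- solve_total_field(dmap, 1e9, ant)
    Es <- scattered_at_receivers(sol) / s
    if (is.null(born_pred)) {
      # Born prediction with the unit-scale contrast shape
      kb <- sol$kb
      Einc <- vapply(1:4, function(t)
        incident_field(ant$positions[t, ], g, kb), complex(g$n^2))
      Crx <- cell_green_matrix(ant$positions, g, kb)
      chi1 <- sol$chi / s    # contrast shape, linear in s by construction
      born_pred <- sol$k0^2 * (Crx %*% (chi1 * Einc))
    }
    dev <- max(Mod(Es - born_pred)) / max(Mod(born_pred))
    expect_lt(dev, prev_dev)   # deviation shrinks as s -> 0
    prev_dev <- dev
  }
  expect_lt(prev_dev, 5e-3)
})

test_that("halving the cell size reduces the cylinder-test error", {
  freqs <- frequency_grid(1, 1e9, 1e9)
  ant <- antenna_array(4, 0.075)
  f <- 1e9
  eps_c <- 28 + 1i * 0.9 / (2 * pi * f * 8.8541878128e-12)
  ref <- cylinder_scattered_series(0.010, eps_c, med, f, ant)
  errs <- vapply(c(0.004, 0.002), function(h) {
    g <- grid_spec(round(0.048 / h), h)
    dmap <- cylinder_dielectric_map(g, freqs, med, R = 0.010,
                                    eps_r_cyl = 28, sigma_cyl = 0.9)
    sim <- simulate_multistatic(dmap, ant)
    sqrt(sum(Mod(sim$Es[, , 1] - ref)^2) / sum(Mod(ref)^2))
  }, numeric(1))
  expect_lt(errs[2], errs[1])
})
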