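test_that("linear coupling reproduces the per-degree coefficients exactly", {
  m <- thermo_model("linear")
  d <- delta_dp(m, eps_r = 20, sigma = 0.6, dT = 1)
  expect_equal(d$delta_eps_r, -20 * 0.0025 * 1)   # -0.05
  expect_equal(d$delta_sigma, 0.6 * 0.0125 * 1)   # +0.0075
  z <- delta_dp(m, 20, 0.6, 0)
  expect_identical(c(z$delta_eps_r, z$delta_sigma), c(0, 0))
})

test_that("quadratic family is endpoint-anchored to the linear model", {
  lin <- thermo_model("linear")
  for (a in c(0.25, 0.5, 1)) {
    quad <- thermo_model("quadratic", a = a)
    for (dT in c(0, 24)) {
      dl <- delta_dp(lin, 35, 1.2, dT)
      dq <- delta_dp(quad, 35, 1.2, dT)
      expect_equal(dq$delta_eps_r, dl$delta_eps_r, tolerance = 1e-12)
      expect_equal(dq$delta_sigma, dl$delta_sigma, tolerance = 1e-12)
    }
    # strictly between the endpoints the quadratic lies below the linear rise
    dmid_l <- delta_dp(lin, 35, 1.2, 12)$delta_sigma
    dmid_q <- delta_dp(quad, 35, 1.2, 12)$delta_sigma
    expect_lt(dmid_q, dmid_l)
  }
})

test_that("DP changes are strictly monotone in the temperature rise", {
  dT <- seq(0, 24, by = 0.5)
  for (m in list(thermo_model("linear"), thermo_model("quadratic", a = 0.7))) {
    d <- delta_dp(m, rep(30, length(dT)), rep(0.9, length(dT)), dT)
    expect_true(all(diff(abs(d$delta_eps_r)) > 0))
    expect_true(all(diff(d$delta_sigma) > 0))
  }
})

test_that("temperature rises outside the validity range are clamped with a warning", {
  m <- thermo_model("linear")
  expect_warning(d <- delta_dp(m, 20, 0.6, 30), "clamped")
  expect_equal(d$delta_sigma, 0.6 * 0.0125 * 24)
  expect_error(delta_dp(m, -1, 0.6, 5), "negative")
})

test_that("forward map then inversion recovers the rise to machine precision", {
  m <- thermo_model("linear")
  eps <- c(10, 25, 50); sig <- c(0.2, 0.9, 1.5); dT <- c(3, 11.5, 24)
  d <- delta_dp(m, eps, sig, dT)
  inv_s <- temperature_from_dp(delta_sigma = d$delta_sigma, sigma = sig,
                               model = m, channel = "sigma")
  inv_e <- temperature_from_dp(delta_eps_r = d$delta_eps_r, eps_r = eps,
                               model = m, channel = "eps")
  expect_equal(inv_s$dT, dT, tolerance = 1e-12)
  expect_equal(inv_e$dT, dT, tolerance = 1e-12)
  # the worked inverse: delta_sigma 0.075 on sigma_ref 0.6 is a 10 degC rise
  one <- temperature_from_dp(delta_sigma = 0.075, sigma = 0.6, model = m)
  expect_equal(one$dT, 10)
})

test_that("near-zero reference DPs are flagged invalid, not NaN", {
  m <- thermo_model("linear")
  r <- temperature_from_dp(delta_eps_r = c(0, -0.5), eps_r = c(1e-9, 20),
                           model = m, channel = "eps")
  expect_false(r$valid[1])
  expect_true(is.na(r$dT[1]))
  expect_true(r$valid[2])
  expect_false(any(is.nan(r$dT)))
})

test_that("heated map equals the cold map at baseline and scales tissue under uniform rise", {
  ph <- breast_phantom(grid = grid_spec(24, 0.002), freqs = frequency_grid(2),
                       breast_radius = 0.021, skin_thickness = 0.002,
                       tumor_center = c(0.0096, 0), tumor_radius = 0.0036)
  base <- structure(list(grid = ph$tissue$grid,
                         T = matrix(37, 24, 24), baseline_T = 37),
                    class = "temperature_field")
  hot0 <- heated_dielectric_map(ph$dielectric, base, tissue = ph$tissue)
  expect_identical(hot0$eps_r, ph$dielectric$eps_r)

  Tu <- matrix(47, 24, 24)
  uni <- structure(list(grid = ph$tissue$grid, T = Tu, baseline_T = 37),
                   class = "temperature_field")
  hot <- heated_dielectric_map(ph$dielectric, uni, tissue = ph$tissue)
  tiss <- breast_mask(ph$tissue)
  for (j in 1:2) {
    e0 <- ph$dielectric$eps_r[, , j]; e1 <- hot$eps_r[, , j]
    s0 <- ph$dielectric$sigma[, , j]; s1 <- hot$sigma[, , j]
    expect_equal(e1[tiss], e0[tiss] * (1 - 0.025), tolerance = 1e-12)
    expect_equal(s1[tiss], s0[tiss] * (1 + 0.125), tolerance = 1e-12)
    # coupling-medium cells never modified
    expect_identical(e1[!tiss], e0[!tiss])
    expect_identical(s1[!tiss], s0[!tiss])
  }
})
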