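# Regularised inversion building blocks and the Born-iterative baseline.

rand_system <- function(seed, m = 24, n = 10) {
  rng <- hotspotmon:::local_rng(seed)
  M <- matrix(complex(real = rng$rnorm(m * n), imaginary = rng$rnorm(m * n)),
              m, n)
  x <- complex(real = rng$rnorm(n), imaginary = rng$rnorm(n))
  list(M = M, x = x, d = M %*% x)
}

test_that("Tikhonov tends to the least-squares solution as lambda -> 0", {
  s <- rand_system(1)
  got <- regularized_solve(s$M, s$d, inverse_config("tr", lambda = 1e-10))
  expect_equal(got$x, s$x, tolerance = 1e-6)
})

test_that("full-rank TSVD equals the pseudo-inverse and converged CGLS", {
  s <- rand_system(2)
  tsvd <- regularized_solve(s$M, s$d, inverse_config("tsvd", trunc = 10))
  cgls <- regularized_solve(s$M, s$d,
                            inverse_config("cgls", noise_level = 1e-10,
                                           cg_iters = 500))
  expect_equal(tsvd$x, s$x, tolerance = 1e-8)
  expect_equal(cgls$x, s$x, tolerance = 1e-6)
})

test_that("discrepancy-principle Tikhonov meets the target residual", {
  s <- rand_system(3, m = 40, n = 30)
  delta <- 0.1 * sqrt(sum(Mod(s$d)^2))
  got <- regularized_solve(s$M, s$d, inverse_config("tr", noise_level = delta))
  resid <- sqrt(sum(Mod(s$M %*% got$x - s$d)^2))
  expect_lt(resid, delta * 1.05)
  expect_gt(resid, delta * 0.5)   # regularisation actually active
})

test_that("FISTA recovers the support of a sparse solution", {
  rng <- hotspotmon:::local_rng(4)
  m <- 40; n <- 60
  M <- matrix(complex(real = rng$rnorm(m * n), imaginary = rng$rnorm(m * n)),
              m, n) / sqrt(m)
  x0 <- complex(n)
  act <- c(7, 19, 33, 48, 55)
  x0[act] <- complex(real = rng$rnorm(5, 0, 2), imaginary = rng$rnorm(5, 0, 2))
  d <- M %*% x0
  got <- regularized_solve(M, d, inverse_config("fista", fista_iters = 400,
                                                fista_weight = 0.02))
  top <- order(Mod(got$x), decreasing = TRUE)[1:5]
  expect_setequal(top, act)
})

test_that("the Born operator predicts weak-perturbation data to first order", {
  pl <- small_pipeline()
  ds <- pl$dataset
  dmap <- ds$phantom$dielectric
  cache <- forward_cache(dmap$grid, ds$antennas, dmap$freqs, dmap$medium)
  cold_sim <- simulate_multistatic(dmap, ds$antennas, cache)
  bo <- born_operator(dmap, ds$antennas, cache, ds$thermo)
  # uniform small rise on the tissue
  errs <- vapply(c(2, 0.2), function(dTmax) {
    fld <- structure(list(grid = dmap$grid,
                          T = 37 + dTmax * (breast_mask(ds$phantom$tissue)),
                          baseline_T = 37), class = "temperature_field")
    hmap <- heated_dielectric_map(dmap, fld, ds$thermo,
                                  tissue = ds$phantom$tissue)
    d_true <- as.vector(simulate_multistatic(hmap, ds$antennas, cache)$Es -
                          cold_sim$Es)
    j <- bo$ref_freq
    dchi <- as.vector(dp_at_frequency(hmap, dmap$freqs$frequencies[j]) -
                        dp_at_frequency(dmap, dmap$freqs$frequencies[j]))
    d_pred <- as.vector(bo$M %*% dchi)
    sqrt(sum(Mod(d_pred - d_true)^2) / sum(Mod(d_true)^2))
  }, numeric(1))
  expect_lt(errs[2], errs[1])        # error shrinks with the perturbation
  expect_lt(errs[2], 0.02)
  # zero contrast change predicts zero data
  expect_true(all(bo$M %*% complex(ncol(bo$M)) == 0))
})

test_that("zero differential data yields a zero temperature estimate", {
  pl <- small_pipeline()
  ds <- pl$dataset
  dmap <- ds$phantom$dielectric
  z <- array(0i, dim(ds$cold$Es))
  fit <- bim_invert(z, dmap, ds$antennas, inverse_config("tr"))
  expect_true(all(fit$delta_T == 0))
  expect_true(all(!fit$hotspot))
})

test_that("BIM localises a strong heating region and the residual improves", {
  pl <- small_pipeline()
  ds <- pl$dataset
  dmap <- ds$phantom$dielectric
  cache <- forward_cache(dmap$grid, ds$antennas, dmap$freqs, dmap$medium)
  cold_sim <- simulate_multistatic(dmap, ds$antennas, cache)
  # strong heating centred on the (high-DP) tumor, noise-free data
  cfgs <- scenario_config(n_regions_range = 1, peak_range = c(22, 22),
                          p_tumor = 1)
  fld <- sample_scenario(ds$phantom$tissue, cfgs, seed = 8)
  hmap <- heated_dielectric_map(dmap, fld, ds$thermo,
                                tissue = ds$phantom$tissue)
  d <- simulate_multistatic(hmap, ds$antennas, cache)$Es - cold_sim$Es
  fit <- bim_invert(d, dmap, ds$antennas,
                    inverse_config("tr", noise_level = 1e-8 *
                                     sqrt(sum(Mod(d)^2))),
                    thermo = ds$thermo, cache = cache, cold_sim = cold_sim)
  expect_gt(max(fit$delta_T), 5)
  truth <- build_label(fld)
  cc <- confusion_counts(fit$hotspot, truth)
  expect_gt(dice_score(cc), 0.3)
  expect_lt(min(fit$residuals), 0.5)
})
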