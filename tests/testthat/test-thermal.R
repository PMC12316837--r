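fixture_tissue <- function() {
  breast_phantom(grid = grid_spec(24, 0.002), freqs = frequency_grid(2),
                 breast_radius = 0.021, skin_thickness = 0.002,
                 tumor_center = c(0.0096, 0), tumor_radius = 0.0036,
                 seed = 3)$tissue
}

test_that("degenerate region count gives a uniform baseline field", {
  ts <- fixture_tissue()
  fld <- sample_scenario(ts, scenario_config(n_regions_range = 0), seed = 5)
  expect_true(all(fld$T == 37))
})

test_that("temperature rise is capped at the configured maximum for any seed", {
  ts <- fixture_tissue()
  cfg <- scenario_config()
  for (s in 1:25) {
    fld <- sample_scenario(ts, cfg, seed = s)
    expect_true(all(fld$T >= fld$baseline_T))
    expect_lte(max(fld$T) - fld$baseline_T, 24)
  }
})

test_that("unsmoothed single-region field follows the layered profile exactly", {
  ts <- fixture_tissue()
  cfg <- scenario_config(n_regions_range = 1, peak_range = c(10, 10),
                         p_tumor = 1, smooth_sigma_cells = 0)
  fld <- sample_scenario(ts, cfg, seed = 11)
  # peak at the tumor-centre cell
  g <- ts$grid
  d <- sqrt((g$coords[, 1] - ts$tumor_center[1])^2 +
              (g$coords[, 2] - ts$tumor_center[2])^2)
  centre <- which.min(d)
  expect_equal(as.vector(fld$T)[centre], 37 + 10)
  # baseline beyond the outermost layer
  outer_r <- max(fld$regions[[1]]$radii)
  far <- d > outer_r
  expect_true(all(fld$T[matrix(far, g$n, g$n)] == 37))
  # radial monotonicity before smoothing (within tissue support)
  ord <- order(d)
  dT <- (as.vector(fld$T) - 37)[ord]
  on_tissue <- as.vector(breast_mask(ts))[ord]
  expect_true(all(diff(dT[on_tissue & (d[ord] <= outer_r)]) <= 1e-12))
})

test_that("smoothing bounds the discrete Laplacian of the field inside the tissue", {
  ts <- fixture_tissue()
  # the coupling bath is temperature-controlled, so the field is pinned to
  # baseline outside the breast; smoothness is claimed (and measured) on
  # stencils lying fully inside the tissue
  interior <- breast_mask(ts)
  n <- nrow(interior)
  core <- matrix(FALSE, n, n)
  i <- 2:(n - 1)
  core[i, i] <- interior[i, i] & interior[i - 1, i] & interior[i + 1, i] &
    interior[i, i - 1] & interior[i, i + 1]
  lap_max <- function(T) {
    L <- matrix(0, n, n)
    L[i, i] <- 4 * T[i, i] - T[i - 1, i] - T[i + 1, i] - T[i, i - 1] - T[i, i + 1]
    max(abs(L[core]))
  }
  cfg_raw <- scenario_config(n_regions_range = 2, peak_range = c(24, 24),
                             smooth_sigma_cells = 0)
  cfg_sm <- scenario_config(n_regions_range = 2, peak_range = c(24, 24),
                            smooth_sigma_cells = 1)
  for (s in 1:10) {
    raw <- lap_max(sample_scenario(ts, cfg_raw, seed = s)$T)
    sm <- lap_max(sample_scenario(ts, cfg_sm, seed = s)$T)
    expect_lt(sm, raw)
    # a 1-cell Gaussian kernel caps the second difference of a step of
    # height S at ~0.45 S; with steps up to 24 degC the limit is 12
    expect_lt(sm, 12)
  }
})

test_that("tumor-heated fraction matches the configured probability", {
  ts <- fixture_tissue()
  cfg <- scenario_config(p_tumor = 0.5)
  heated <- vapply(1:1000, function(s)
    sample_scenario(ts, cfg, seed = s)$tumor_heated, logical(1))
  p_hat <- mean(heated)
  band <- 3 * sqrt(0.5 * 0.5 / 1000)
  expect_gt(p_hat, 0.5 - band)
  expect_lt(p_hat, 0.5 + band)
})

test_that("scenarios are reproducible from their seed", {
  ts <- fixture_tissue()
  a <- sample_scenario(ts, seed = 42)
  b <- sample_scenario(ts, seed = 42)
  expect_identical(a$T, b$T)
})

test_that("temperature maps round-trip through the text format", {
  ts <- fixture_tissue()
  fld <- sample_scenario(ts, seed = 2)
  path <- withr::local_tempfile(fileext = ".txt")
  export_temperature_map(fld, path)
  back <- import_temperature_map(path, ts$grid)
  expect_equal(back$T, fld$T, tolerance = 1e-12)
})

test_that("imported constant-37 map yields no hotspots downstream", {
  g <- grid_spec(10, 0.002)
  path <- withr::local_tempfile(fileext = ".txt")
  write.table(matrix(37, 10, 10), path, row.names = FALSE, col.names = FALSE)
  fld <- import_temperature_map(path, g)
  expect_true(all(fld$T == 37))
  expect_identical(sum(fld$T > 40), 0L)
})

test_that("nearest-neighbour resampling matches an explicit oracle", {
  g <- grid_spec(5, 0.002)
  src <- matrix(seq_len(100), 10, 10)
  path <- withr::local_tempfile(fileext = ".txt")
  write.table(src / 100 + 37, path, row.names = FALSE, col.names = FALSE)
  fld <- import_temperature_map(path, g)
  # oracle: each 5-grid centre (i-0.5)/5 against 10-grid centres (j-0.5)/10
  idx <- vapply((seq_len(5) - 0.5) / 5, function(tc)
    which.min(abs((seq_len(10) - 0.5) / 10 - tc)), integer(1))
  expect_equal(fld$T, (src / 100 + 37)[idx, idx], tolerance = 1e-12)
})

test_that("invalid temperature maps are rejected", {
  g <- grid_spec(4, 0.002)
  p1 <- withr::local_tempfile(fileext = ".txt")
  write.table(matrix(c(NA, rep(37, 15)), 4, 4), p1,
              row.names = FALSE, col.names = FALSE)
  expect_error(import_temperature_map(p1, g), "non-finite")
  p2 <- withr::local_tempfile(fileext = ".txt")
  write.table(matrix(c(150, rep(37, 15)), 4, 4), p2,
              row.names = FALSE, col.names = FALSE)
  expect_error(import_temperature_map(p2, g), "0-100")
})
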