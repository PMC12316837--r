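# Scale presets binding all modules into the acquisition/training pipeline.
#
# Three presets share one structure and differ only in problem size:
#   full    - the full-scale configuration (50x50 grid of 2 mm cells,
#             16 antennas, 16 frequencies, 50,000 scenarios, 40 epochs);
#             multi-day on a single CPU, provided for completeness.
#   desk    - a single-CPU reduction (24x24 grid of 2 mm cells, 4 antennas,
#             4 frequencies, 2,000 scenarios, 15 epochs) preserving every
#             structural element of the pipeline.
#   fixture - a seconds-scale smoke configuration for tests and examples.
# The phantom shrinks with the domain (breast and tumor scaled
# proportionally); the antenna ring, coupling medium, thermal statistics,
# thermo-dielectric coefficients and SNR are identical across presets.

#' Pipeline configuration presets
#'
#' @param scale `"full"`, `"desk"` or `"fixture"`.
#' @param seed global seed; every random stage derives its stream from it.
#' @return nested configuration list of class `run_config`.
#' @export
preset_config <- function(scale = c("desk", "fixture", "full"), seed = 1L) {
  scale <- match.arg(scale)
  base <- list(
    scale = scale, seed = as.integer(seed),
    medium = list(eps_rb = 20, sigma_b = 0.6),
    antenna_radius = 0.075,
    cell_size = 0.002,
    snr_train = 40,
    thermo = list(kind = "linear", a = 0),
    scen = list(),             # scenario_config() defaults
    splits = c(0.70, 0.15, 0.15)
  )
  dims <- switch(scale,
    full = list(n_grid = 50L, n_antennas = 16L, n_freqs = 16L,
                 n_samples = 50000L, epochs = 40L, base_filters = NA,
                 breast_radius = 0.045, skin = 0.002,
                 tumor_center = c(0.020, 0), tumor_radius = 0.0075,
                 n_blobs = 3L),
    desk = list(n_grid = 24L, n_antennas = 4L, n_freqs = 4L,
                n_samples = 2000L, epochs = 15L, base_filters = 16,
                breast_radius = 0.021, skin = 0.002,
                tumor_center = c(0.0096, 0), tumor_radius = 0.0036,
                n_blobs = 2L),
    fixture = list(n_grid = 24L, n_antennas = 4L, n_freqs = 2L,
                   n_samples = 50L, epochs = 3L, base_filters = 8,
                   tumor_center = c(0.0096, 0), tumor_radius = 0.0036,
                   breast_radius = 0.021, skin = 0.002, n_blobs = 2L))
  structure(c(base, dims), class = "run_config")
}

#' Materialise the geometry and phantom of a configuration
#'
#' @param config a [preset_config()].
#' @return list with `grid`, `antennas`, `freqs`, `medium`, `phantom`,
#'   `thermo`, `scen`.
#' @export
build_problem <- function(config) {
  grid <- grid_spec(config$n_grid, config$cell_size)
  freqs <- frequency_grid(config$n_freqs)
  medium <- background_medium(config$medium$eps_rb, config$medium$sigma_b)
  antennas <- antenna_array(config$n_antennas, config$antenna_radius)
  phantom <- breast_phantom(grid = grid, freqs = freqs, medium = medium,
                            breast_radius = config$breast_radius,
                            skin_thickness = config$skin,
                            tumor_center = config$tumor_center,
                            tumor_radius = config$tumor_radius,
                            n_fibro_blobs = config$n_blobs,
                            seed = derive_seed(config$seed, 1))
  thermo <- thermo_model(config$thermo$kind, a = config$thermo$a)
  scen <- do.call(scenario_config, config$scen)
  list(grid = grid, antennas = antennas, freqs = freqs, medium = medium,
       phantom = phantom, thermo = thermo, scen = scen)
}

#' Run the full pipeline for a configuration
#'
#' Generates the dataset, trains the network and evaluates the held-out
#' test split at the training SNR. The heavy stages can be reused by
#' passing previous results.
#'
#' @param config a [preset_config()].
#' @param dataset optionally, a previously generated dataset.
#' @param fit optionally, a previously trained model.
#' @param verbose print progress.
#' @return list with `problem`, `dataset`, `fit`, `eval`.
#' @export
run_pipeline <- function(config, dataset = NULL, fit = NULL, verbose = FALSE) {
  pb <- build_problem(config)
  if (is.null(dataset)) {
    dataset <- generate_dataset(pb$phantom, pb$antennas, pb$thermo, pb$scen,
                                n = config$n_samples,
                                snr_train = config$snr_train,
                                seed = derive_seed(config$seed, 2),
                                splits = config$splits, verbose = verbose)
  }
  if (is.null(fit)) {
    arch <- if (config$scale == "full") fullscale_architecture()
    else design_architecture(config$n_antennas, config$n_grid,
                             base_filters = config$base_filters)
    fit <- hotspot_cnn(dataset, architecture = arch,
                       control = train_control(epochs = config$epochs,
                                               seed = derive_seed(config$seed, 3),
                                               verbose = verbose))
  }
  ev <- evaluate_hotspots(fit, dataset, split = "test",
                          snr_test = config$snr_train)
  list(problem = pb, dataset = dataset, fit = fit, eval = ev)
}
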