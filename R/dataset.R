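# Dataset assembly: differential-field input tensors and hotspot labels.
#
# For every scenario the cold (reference) scattered field is simulated once
# and reused; the hot field is simulated from the heated dielectric map.
# Hot and cold data are noised independently at SNR_train, subtracted, and
# the complex difference is unpacked into real/imaginary channel pairs per
# frequency (third-axis length 2 x n_freq). Labels threshold the true
# temperature at 40 degC (strictly greater; exact equality is not a
# hotspot).

HOTSPOT_T <- 40

#' Differential input tensor from hot and cold measurements
#'
#' `Delta E = E_s^hot - E_s^cold`, unpacked so channel `2k-1` is the real
#' and channel `2k` the imaginary part at frequency `k`.
#'
#' @param hot,cold `scatter_data` objects on identical geometry.
#' @return real array `n_rx x n_tx x 2 n_freq`.
#' @export
build_input <- function(hot, cold) {
  if (!all(dim(hot$Es) == dim(cold$Es)) ||
      !isTRUE(all.equal(hot$freqs$frequencies, cold$freqs$frequencies)))
    stop("hot and cold measurements have mismatching geometry")
  d <- dim(hot$Es)
  dE <- hot$Es - cold$Es
  out <- array(0, c(d[1], d[2], 2 * d[3]))
  for (j in seq_len(d[3])) {
    out[, , 2 * j - 1] <- Re(dE[, , j])
    out[, , 2 * j] <- Im(dE[, , j])
  }
  out
}

#' Hotspot label image from a temperature field
#'
#' @param field a `temperature_field`.
#' @param threshold danger threshold in degC.
#' @return logical matrix, `TRUE` where `T > threshold`.
#' @export
build_label <- function(field, threshold = HOTSPOT_T) {
  field$T > threshold
}

#' Generate a labelled hotspot dataset
#'
#' Runs the full acquisition chain: random heating scenario -> hot
#' dielectric map -> multi-static multi-frequency forward solve ->
#' clean hot/cold scattered fields, plus the true temperature field, label
#' image and danger status per scenario. Noise is applied lazily (see
#' [noised_tensors()]) so the same dataset can be re-noised at any test
#' SNR. Fully reproducible from `seed`.
#'
#' @param phantom a [breast_phantom()].
#' @param antennas an [antenna_array()].
#' @param thermo a [thermo_model()] used to map temperature to DPs.
#' @param scen a [scenario_config()].
#' @param n number of scenarios.
#' @param snr_train training SNR in dB.
#' @param seed integer seed.
#' @param splits train/validation/test fractions (validation and test
#'   counts are rounded; training takes the remainder).
#' @param cache optional [forward_cache]; built once if omitted.
#' @param verbose print progress.
#' @return object of class `hotspot_dataset`.
#' @export
generate_dataset <- function(phantom, antennas, thermo = thermo_model(),
                             scen = scenario_config(), n = 100,
                             snr_train = 40, seed = 1L,
                             splits = c(0.70, 0.15, 0.15),
                             cache = NULL, verbose = FALSE) {
  stopifnot(n >= 1, length(splits) == 3, abs(sum(splits) - 1) < 1e-9)
  grid <- phantom$tissue$grid
  freqs <- phantom$dielectric$freqs
  if (is.null(cache))
    cache <- forward_cache(grid, antennas, freqs, phantom$dielectric$medium)
  cold <- simulate_multistatic(phantom$dielectric, antennas, cache)
  nrx <- antennas$n; nf <- freqs$n
  hot <- array(0i, c(nrx, nrx, nf, n))
  Tarr <- array(0, c(grid$n, grid$n, n))
  labels <- array(FALSE, c(grid$n, grid$n, n))
  tumor_heated <- danger_truth <- logical(n)
  tmask <- tumor_mask(phantom$tissue)
  for (i in seq_len(n)) {
    field <- sample_scenario(phantom$tissue, scen, seed = derive_seed(seed, 1e6 + i))
    hmap <- heated_dielectric_map(phantom$dielectric, field, thermo,
                                  tissue = phantom$tissue)
    sim <- simulate_multistatic(hmap, antennas, cache)
    hot[, , , i] <- sim$Es
    Tarr[, , i] <- field$T
    lab <- build_label(field)
    labels[, , i] <- lab
    tumor_heated[i] <- isTRUE(field$tumor_heated)
    danger_truth[i] <- danger_status(lab, tmask)
    if (verbose && i %% 100 == 0) message("  scenario ", i, "/", n)
  }
  n_val <- round(splits[2] * n); n_test <- round(splits[3] * n)
  n_train <- n - n_val - n_test
  idx <- seq_len(n)
  ds <- structure(list(
    phantom = phantom, antennas = antennas, thermo = thermo, scen = scen,
    cold = cold, hot = hot, T = Tarr, labels = labels,
    tumor_heated = tumor_heated, danger_truth = danger_truth,
    splits = list(train = idx[seq_len(n_train)],
                  val = idx[n_train + seq_len(n_val)],
                  test = idx[n_train + n_val + seq_len(n_test)]),
    snr_train = snr_train, seed = seed), class = "hotspot_dataset")
  Xt <- noised_tensors(ds, ds$splits$train, snr_train, noise_tag = 0L)
  ds$norm_sd <- stats::sd(Xt$X)
  ds
}

#' @export
print.hotspot_dataset <- function(x, ...) {
  d <- dim(x$hot)
  cat(sprintf("<hotspot_dataset> %d scenarios (%d/%d/%d train/val/test)\n",
              d[4], length(x$splits$train), length(x$splits$val),
              length(x$splits$test)))
  cat(sprintf("  input %d x %d x %d, labels %d x %d, SNR_train %g dB\n",
              d[1], d[2], 2 * d[3], dim(x$labels)[1], dim(x$labels)[2],
              x$snr_train))
  cat(sprintf("  hotspot pixel prevalence %.3f, danger-positive fraction %.3f\n",
              mean(x$labels), mean(x$danger_truth)))
  invisible(x)
}

#' Noised input tensors for a set of scenarios
#'
#' Applies independent AWGN draws to the clean hot and cold fields of each
#' selected scenario (per-frequency scope) at the requested SNR, builds the
#' differential tensors and stacks them `[H, W, N, C]` alongside the label
#' stack `[H, W, N]`. Noise seeds derive from the dataset seed, the
#' scenario id and `noise_tag`, so training (tag 0) and any evaluation
#' re-noising (other tags) use disjoint, reproducible streams.
#'
#' @param ds a `hotspot_dataset`.
#' @param idx scenario indices.
#' @param snr_db SNR in dB (`Inf` for noise-free).
#' @param noise_tag integer stream tag.
#' @return list with `X` (inputs), `Y` (labels), `idx`.
#' @export
noised_tensors <- function(ds, idx, snr_db, noise_tag = 0L) {
  d <- dim(ds$hot)
  H <- d[1]; W <- d[2]; nf <- d[3]
  X <- array(0, c(H, W, length(idx), 2 * nf))
  for (j in seq_along(idx)) {
    i <- idx[j]
    hot_i <- ds$cold
    hot_i$Es <- ds$hot[, , , i, drop = FALSE]
    dim(hot_i$Es) <- d[1:3]
    hot_n <- add_awgn(hot_i, snr_db,
                      seed = derive_seed(ds$seed, 4e6 + 16 * i + 2 * noise_tag))
    cold_n <- add_awgn(ds$cold, snr_db,
                       seed = derive_seed(ds$seed, 4e6 + 16 * i + 2 * noise_tag + 1))
    X[, , j, ] <- build_input(hot_n, cold_n)
  }
  list(X = X, Y = ds$labels[, , idx, drop = FALSE], idx = idx)
}
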