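# Experiment sweeps: test-SNR robustness, decision-threshold trade-off and
# thermo-dielectric model mismatch.

#' Test-SNR sweep
#'
#' Evaluates a fitted model on one split across a grid of test SNRs
#' (training noise level fixed). Performance is expected to rise with the
#' test SNR and plateau near the training SNR.
#'
#' @param fit a fitted `hotspot_cnn`.
#' @param ds the `hotspot_dataset`.
#' @param snrs numeric vector of test SNRs in dB.
#' @param split dataset split.
#' @param alpha decision threshold.
#' @return data.frame with one row per SNR.
#' @export
snr_sweep <- function(fit, ds, snrs = c(20, 25, 30, 35, 40, 45, 50),
                      split = "test", alpha = 0.5) {
  rows <- lapply(snrs, function(s) {
    ev <- evaluate_hotspots(fit, ds, split = split, snr_test = s,
                            alpha = alpha)
    data.frame(snr_test = s, mean_s_acc = ev$mean_s_acc,
               pixel_accuracy = ev$pixel_accuracy,
               mean_s_dice = ev$mean_s_dice,
               danger_accuracy = ev$danger_accuracy)
  })
  do.call(rbind, rows)
}

#' Decision-threshold sweep for a fitted model
#'
#' Computes the mean accuracy / danger-accuracy trade-off over a threshold
#' grid from one set of probability maps.
#'
#' @inheritParams snr_sweep
#' @param alphas threshold grid.
#' @param snr_test evaluation SNR in dB.
#' @return data.frame (see [threshold_sweep()]).
#' @export
alpha_sweep <- function(fit, ds, alphas = seq(0.1, 0.9, 0.1), split = "test",
                        snr_test = ds$snr_train) {
  ev <- evaluate_hotspots(fit, ds, split = split, snr_test = snr_test,
                          return_probs = TRUE)
  te_idx <- ds$splits[[split]]
  threshold_sweep(attr(ev, "probs"), ds$labels[, , te_idx, drop = FALSE],
                  tumor_mask(ds$phantom$tissue), alphas)
}

# Re-simulate the hot fields of selected scenarios under a different
# thermo-dielectric model (the stored temperature fields are reused).
regenerate_hot <- function(ds, thermo2, idx, cache = NULL, verbose = FALSE) {
  dmap <- ds$phantom$dielectric
  if (is.null(cache))
    cache <- forward_cache(dmap$grid, ds$antennas, dmap$freqs, dmap$medium)
  out <- ds
  out$thermo <- thermo2
  for (i in idx) {
    fld <- structure(list(grid = dmap$grid, T = ds$T[, , i], baseline_T = 37),
                     class = "temperature_field")
    hmap <- heated_dielectric_map(dmap, fld, thermo2,
                                  tissue = ds$phantom$tissue)
    out$hot[, , , i] <- simulate_multistatic(hmap, ds$antennas, cache)$Es
    if (verbose && i %% 50 == 0) message("  re-simulated ", i)
  }
  out
}

#' Thermo-dielectric mismatch sweep
#'
#' The model mismatch study: the network was trained under the linear
#' coupling model, but the test data are regenerated under the quadratic
#' family at increasing nonlinearity degrees `a` (at `a = 0` the data are
#' unchanged).
#'
#' @inheritParams snr_sweep
#' @param a_grid nonlinearity degrees in `[0, 1]`.
#' @param snr_test evaluation SNR in dB.
#' @param cache optional [forward_cache].
#' @return data.frame with one row per degree.
#' @export
mismatch_sweep <- function(fit, ds, a_grid = c(0, 0.5, 1), split = "test",
                           snr_test = ds$snr_train, cache = NULL) {
  idx <- ds$splits[[split]]
  dmap <- ds$phantom$dielectric
  if (is.null(cache))
    cache <- forward_cache(dmap$grid, ds$antennas, dmap$freqs, dmap$medium)
  rows <- lapply(a_grid, function(a) {
    ds2 <- if (a == 0) ds
    else regenerate_hot(ds, thermo_model("quadratic", a = a), idx, cache)
    ev <- evaluate_hotspots(fit, ds2, split = split, snr_test = snr_test)
    data.frame(a = a, mean_s_acc = ev$mean_s_acc,
               pixel_accuracy = ev$pixel_accuracy,
               mean_s_dice = ev$mean_s_dice,
               danger_accuracy = ev$danger_accuracy)
  })
  do.call(rbind, rows)
}
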