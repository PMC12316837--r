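# Additive white Gaussian noise on scattered-field arrays.
#
# SNR is defined as 10 log10(P_Es / P_Noise) with powers taken as mean
# squared moduli. The default scope is per frequency: the scattered-field
# power varies strongly over 0.5-2 GHz, and a global scope would over-noise
# the high-frequency slices. Noise is circularly symmetric complex Gaussian
# (power split equally between real and imaginary parts); hot and cold
# measurements are always noised with independent draws.

#' Add white Gaussian noise at a target SNR
#'
#' @param sd a `scatter_data` object.
#' @param snr_db target signal-to-noise ratio in dB; `Inf` returns the data
#'   unchanged.
#' @param scope `"per_frequency"` (default) or `"global"`: the slice over
#'   which signal power is measured and the SNR imposed.
#' @param seed integer seed for the noise draw.
#' @return a `scatter_data` with noise added.
#' @export
add_awgn <- function(sd, snr_db, scope = c("per_frequency", "global"),
                     seed = 1L) {
  scope <- match.arg(scope)
  stopifnot(inherits(sd, "scatter_data"), !is.na(snr_db))
  if (is.infinite(snr_db) && snr_db > 0) return(sd)
  rng <- local_rng(seed)
  Es <- sd$Es
  dm <- dim(Es)
  noise_for <- function(slice_pow, n) {
    if (slice_pow <= 0) stop("zero signal power: SNR is undefined")
    s <- sqrt(slice_pow * 10^(-snr_db / 10) / 2)
    complex(real = rng$rnorm(n, 0, s), imaginary = rng$rnorm(n, 0, s))
  }
  if (scope == "global") {
    Es <- Es + noise_for(mean(Mod(Es)^2), length(Es))
  } else {
    for (j in seq_len(dm[3])) {
      sl <- Es[, , j]
      Es[, , j] <- sl + noise_for(mean(Mod(sl)^2), length(sl))
    }
  }
  out <- sd
  out$Es <- Es
  out
}

#' Measure the empirical SNR between clean and noisy data
#'
#' `10 log10(||clean||^2 / ||noisy - clean||^2)` per scope. Identical arrays
#' give `Inf`.
#'
#' @param clean,noisy `scatter_data` objects of matching shape.
#' @param scope `"per_frequency"` (vector result) or `"global"` (scalar).
#' @return SNR in dB.
#' @export
measure_snr <- function(clean, noisy, scope = c("per_frequency", "global")) {
  scope <- match.arg(scope)
  if (!all(dim(clean$Es) == dim(noisy$Es))) stop("shape mismatch")
  ratio <- function(cl, no) {
    np <- sum(Mod(no - cl)^2)
    if (np == 0) return(Inf)
    10 * log10(sum(Mod(cl)^2) / np)
  }
  if (scope == "global") return(ratio(clean$Es, noisy$Es))
  vapply(seq_len(dim(clean$Es)[3]),
         function(j) ratio(clean$Es[, , j], noisy$Es[, , j]), numeric(1))
}
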