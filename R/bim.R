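# Born-iterative inversion baseline with pluggable regularisers.
#
# The comparator estimates the temperature-rise map from the differential
# data: at each outer iteration the data equation is linearised about the
# current dielectric estimate (total fields re-solved with the MoM), the
# resulting linear system is inverted with one of four classical
# regularisers (Tikhonov, truncated SVD, CGLS, FISTA), the complex
# contrast change is converted to a temperature rise through the linear
# thermo-dielectric inverse, and the dielectric estimate is updated.
#
# Frequency stacking: the unknown is the contrast change at a reference
# frequency (mid-band); columns of the other frequency blocks are scaled
# by the thermo-dielectric ratio g_f / g_ref, where g_f is the derivative
# of the complex contrast with respect to temperature. This makes the
# multi-frequency system consistent for any temperature field under the
# linear coupling model.

#' Inversion configuration for the BIM baseline
#'
#' @param regularizer `"tr"`, `"tsvd"`, `"cgls"` or `"fista"`.
#' @param outer_iterations Born iterations (>= 1).
#' @param stop_tol stop when the relative data residual improves by less
#'   than this between iterations.
#' @param noise_level absolute data-noise norm for the discrepancy
#'   principle; `NULL` defaults to `0.05 ||d||`.
#' @param lambda explicit Tikhonov parameter (overrides discrepancy).
#' @param trunc explicit TSVD truncation index.
#' @param cg_iters CGLS iteration cap.
#' @param fista_iters FISTA iteration count.
#' @param fista_weight explicit L1 weight; `NULL` scales from the data.
#' @param channel thermo-dielectric channel for the temperature inverse.
#' @param dT_max cap on the estimated rise (degC).
#' @return list of class `inverse_config`.
#' @export
inverse_config <- function(regularizer = c("tr", "tsvd", "cgls", "fista"),
                           outer_iterations = 5, stop_tol = 1e-3,
                           noise_level = NULL, lambda = NULL, trunc = NULL,
                           cg_iters = 200, fista_iters = 100,
                           fista_weight = NULL,
                           channel = c("sigma", "eps"), dT_max = 24) {
  regularizer <- match.arg(regularizer)
  channel <- match.arg(channel)
  stopifnot(outer_iterations >= 1)
  structure(list(regularizer = regularizer,
                 outer_iterations = outer_iterations, stop_tol = stop_tol,
                 noise_level = noise_level, lambda = lambda, trunc = trunc,
                 cg_iters = cg_iters, fista_iters = fista_iters,
                 fista_weight = fista_weight, channel = channel,
                 dT_max = dT_max), class = "inverse_config")
}

# dchi/dT at every cell for one frequency slice of a dielectric map.
thermo_sensitivity <- function(dmap, j, thermo) {
  w <- dmap$freqs$omega[j]
  -thermo$alpha_eps * dmap$eps_r[, , j] +
    1i * thermo$alpha_sigma * dmap$sigma[, , j] / (w * EPS0)
}

#' Linearised (distorted-Born) operator about a dielectric estimate
#'
#' Maps a per-cell complex contrast change at the reference frequency to
#' the stacked multi-static multi-frequency differential data. The
#' linearisation is the exact Frechet derivative of the discretised
#' forward model about the current estimate: the receive-side Green's
#' function of the inhomogeneous estimate equals, by reciprocity, the
#' total field solved with the receiver acting as the source, so the
#' operator column for cell `n` is
#' `k0^2 kappa E_n^(rx) E_n^(tx)` with `kappa` the equivalent-circle cell
#' integration constant. Cells with zero field contribute zero columns.
#'
#' @param dmap_cur current dielectric estimate.
#' @param antennas an [antenna_array()] (transmit and receive).
#' @param cache a [forward_cache] for the geometry.
#' @param thermo the linear [thermo_model()] fixing the frequency scaling.
#' @param ref_freq reference frequency index (default mid-band).
#' @return list with `M` (`(n_rx n_tx n_freq) x n_cells` complex matrix,
#'   rows ordered receiver-fastest) and `ref_freq`.
#' @export
born_operator <- function(dmap_cur, antennas, cache, thermo = thermo_model(),
                          ref_freq = NULL) {
  freqs <- dmap_cur$freqs
  if (is.null(ref_freq)) ref_freq <- ceiling(freqs$n / 2)
  nrx <- antennas$n
  ncell <- dmap_cur$grid$n^2
  a <- dmap_cur$grid$cell_size / sqrt(pi)
  g_ref <- as.vector(thermo_sensitivity(dmap_cur, ref_freq, thermo))
  blocks <- vector("list", freqs$n)
  for (j in seq_len(freqs$n)) {
    sol <- solve_total_field(dmap_cur, freqs$frequencies[j], antennas, cache)
    kappa <- (2 * pi * a / sol$kb) * zbesselJ(1, sol$kb * a)
    gratio <- as.vector(thermo_sensitivity(dmap_cur, j, thermo)) / g_ref
    w <- sol$k0^2 * kappa * gratio
    Mi <- matrix(0i, nrx * nrx, ncell)
    for (t in seq_len(nrx)) {
      Mi[(t - 1) * nrx + seq_len(nrx), ] <- t(sol$E * (w * sol$E[, t]))
    }
    blocks[[j]] <- Mi
  }
  list(M = do.call(rbind, blocks), ref_freq = ref_freq)
}

# complex conjugate transpose product
chprod <- function(M, v) crossprod(Conj(M), v)

#' Regularised solution of the linearised system
#'
#' Textbook implementations selected by the configuration: Tikhonov
#' (penalised least squares, parameter by the discrepancy principle),
#' truncated SVD (smallest truncation meeting the discrepancy), CGLS
#' (iteration-count regularisation, discrepancy stopping) and FISTA
#' (L1-penalised proximal gradient with complex soft thresholding).
#'
#' @param M complex system matrix.
#' @param d complex data vector.
#' @param config an [inverse_config()].
#' @return list with the estimate `x` and diagnostic `info`.
#' @export
regularized_solve <- function(M, d, config) {
  delta <- config$noise_level %||% (0.05 * sqrt(sum(Mod(d)^2)))
  if (config$regularizer %in% c("tr", "tsvd")) {
    sv <- svd(M)
    utd <- chprod(sv$u, d)
    perp2 <- sum(Mod(d)^2) - sum(Mod(utd)^2)
    if (config$regularizer == "tr") {
      resid_of <- function(lam)
        sqrt(max(0, sum((lam^2 / (sv$d^2 + lam^2))^2 * Mod(utd)^2) + perp2))
      lam <- config$lambda
      if (is.null(lam)) {
        lo <- 1e-8 * sv$d[1]; hi <- 10 * sv$d[1]
        if (resid_of(lo) >= delta) lam <- lo
        else {
          for (it in 1:80) {
            mid <- sqrt(lo * hi)
            if (resid_of(mid) < delta) lo <- mid else hi <- mid
          }
          lam <- sqrt(lo * hi)
        }
      }
      x <- sv$v %*% (sv$d / (sv$d^2 + lam^2) * utd)
      info <- list(lambda = lam, residual = resid_of(lam))
    } else {
      r2 <- rev(cumsum(rev(Mod(utd)^2)))      # residual^2 of rank k-1 keeps
      resid_k <- sqrt(pmax(0, c(r2[-1], 0) + perp2))  # after keeping k comps
      k <- config$trunc %||% {
        meets <- which(resid_k <= delta)
        if (length(meets)) min(meets) else length(sv$d)
      }
      k <- min(k, sum(sv$d > sv$d[1] * 1e-12))
      x <- sv$v[, seq_len(k), drop = FALSE] %*%
        (utd[seq_len(k)] / sv$d[seq_len(k)])
      info <- list(trunc = k, residual = resid_k[k])
    }
  } else if (config$regularizer == "cgls") {
    x <- complex(ncol(M))
    r <- d
    s <- chprod(M, r)
    p <- s
    norms2 <- sum(Mod(s)^2)
    hist <- numeric(0)
    for (it in seq_len(config$cg_iters)) {
      q <- M %*% p
      alpha <- norms2 / sum(Mod(q)^2)
      x <- x + alpha * p
      r <- r - alpha * q
      hist <- c(hist, sqrt(sum(Mod(r)^2)))
      if (hist[it] <= delta) break
      s <- chprod(M, r)
      ns2 <- sum(Mod(s)^2)
      p <- s + (ns2 / norms2) * p
      norms2 <- ns2
    }
    info <- list(iterations = length(hist), residual = utils::tail(hist, 1))
  } else {  # fista
    L <- svd(M, nu = 0, nv = 0)$d[1]^2
    atb <- chprod(M, d)
    lam <- config$fista_weight %||% (0.1 * max(Mod(atb)))
    soft <- function(z, thr) {
      m <- Mod(z)
      ifelse(m > thr, z * (m - thr) / pmax(m, 1e-300), 0i)
    }
    x <- z <- complex(ncol(M))
    tk <- 1
    for (it in seq_len(config$fista_iters)) {
      grad <- chprod(M, M %*% z) - atb
      xn <- soft(z - grad / L, lam / L)
      tn <- (1 + sqrt(1 + 4 * tk^2)) / 2
      z <- xn + ((tk - 1) / tn) * (xn - x)
      x <- xn; tk <- tn
    }
    info <- list(weight = lam,
                 residual = sqrt(sum(Mod(M %*% x - d)^2)))
  }
  list(x = as.vector(x), info = info)
}

#' Born-iterative temperature inversion
#'
#' Iterates linearise -> regularised solve -> temperature conversion ->
#' dielectric update, starting from the cold reference map, and thresholds
#' the final temperature estimate at 40 degC.
#'
#' @param d_diff differential data, complex array `n_rx x n_tx x n_freq`
#'   (hot minus cold measurements).
#' @param dmap_cold the known cold (reference) dielectric map.
#' @param antennas an [antenna_array()].
#' @param config an [inverse_config()].
#' @param thermo the linear [thermo_model()].
#' @param cache optional [forward_cache].
#' @param cold_sim optional precomputed clean cold simulation
#'   (`scatter_data`) reused for residual tracking.
#' @param baseline_T baseline temperature, degC.
#' @return object of class `bim_fit`: `delta_T` matrix, logical `hotspot`
#'   image, relative `residuals` per iteration, and the configuration.
#' @export
bim_invert <- function(d_diff, dmap_cold, antennas, config = inverse_config(),
                       thermo = thermo_model(), cache = NULL,
                       cold_sim = NULL, baseline_T = 37) {
  freqs <- dmap_cold$freqs
  if (is.null(cache))
    cache <- forward_cache(dmap_cold$grid, antennas, freqs, dmap_cold$medium)
  if (is.null(cold_sim))
    cold_sim <- simulate_multistatic(dmap_cold, antennas, cache)
  d <- as.vector(d_diff)
  dnorm <- sqrt(sum(Mod(d)^2))
  n <- dmap_cold$grid$n
  if (dnorm == 0) {
    return(structure(list(delta_T = matrix(0, n, n),
                          hotspot = matrix(FALSE, n, n),
                          residuals = numeric(0), config = config,
                          converged = TRUE), class = "bim_fit"))
  }
  dmap_cur <- dmap_cold
  best <- list(res = Inf, dT = matrix(0, n, n))
  residuals <- numeric(0)
  for (it in seq_len(config$outer_iterations)) {
    bo <- born_operator(dmap_cur, antennas, cache, thermo)
    sol <- regularized_solve(bo$M, d, config)
    j <- bo$ref_freq
    delta_sigma <- Im(sol$x) * freqs$omega[j] * EPS0
    delta_eps <- Re(sol$x)
    inv <- temperature_from_dp(delta_eps_r = delta_eps,
                               delta_sigma = delta_sigma,
                               eps_r = as.vector(dmap_cold$eps_r[, , j]),
                               sigma = as.vector(dmap_cold$sigma[, , j]),
                               model = thermo, channel = config$channel)
    dT <- inv$dT
    dT[!inv$valid | is.na(dT)] <- 0
    dT <- matrix(pmin(pmax(dT, 0), config$dT_max), n, n)
    field <- structure(list(grid = dmap_cold$grid, T = baseline_T + dT,
                            baseline_T = baseline_T),
                       class = "temperature_field")
    dmap_cur <- heated_dielectric_map(dmap_cold, field, thermo)
    sim <- simulate_multistatic(dmap_cur, antennas, cache)
    res <- sqrt(sum(Mod(as.vector(sim$Es - cold_sim$Es) - d)^2)) / dnorm
    residuals <- c(residuals, res)
    if (res < best$res) best <- list(res = res, dT = dT)
    if (it > 1 && (residuals[it - 1] - res) < config$stop_tol) break
  }
  structure(list(delta_T = best$dT,
                 hotspot = (baseline_T + best$dT) > HOTSPOT_T,
                 residuals = residuals, config = config,
                 converged = best$res < Inf && which.min(residuals) == length(residuals)),
            class = "bim_fit")
}

#' @export
print.bim_fit <- function(x, ...) {
  cat(sprintf("<bim_fit> %s, %d iteration(s), final relative residual %.3g\n",
              x$config$regularizer, length(x$residuals),
              if (length(x$residuals)) min(x$residuals) else NA_real_))
  cat(sprintf("  max estimated rise %.2f degC, %d hotspot pixel(s)\n",
              max(x$delta_T), sum(x$hotspot)))
  invisible(x)
}

#' Evaluate the BIM baseline over dataset scenarios
#'
#' Runs [bim_invert()] on the noised differential data of the selected
#' scenarios (same noising machinery as the network evaluation) and scores
#' the resulting hotspot images. The discrepancy noise level is derived
#' from the known evaluation SNR.
#'
#' @param ds a `hotspot_dataset`.
#' @param config an [inverse_config()].
#' @param idx scenario indices (default: the test split).
#' @param snr_test evaluation SNR in dB.
#' @param noise_tag evaluation noise stream tag (match the network
#'   evaluation for identical measurement noise).
#' @param cache optional [forward_cache].
#' @return a `metrics_report`.
#' @export
evaluate_bim <- function(ds, config = inverse_config(),
                         idx = ds$splits$test, snr_test = ds$snr_train,
                         noise_tag = 1L, cache = NULL) {
  dmap <- ds$phantom$dielectric
  if (is.null(cache))
    cache <- forward_cache(dmap$grid, ds$antennas, dmap$freqs, dmap$medium)
  cold_sim <- simulate_multistatic(dmap, ds$antennas, cache)
  # expected noise norm on the differential data at the known SNR
  d3 <- dim(ds$cold$Es)
  pf <- vapply(seq_len(d3[3]), function(j) mean(Mod(ds$cold$Es[, , j])^2),
               numeric(1))
  if (is.finite(snr_test)) {
    config$noise_level <- sqrt(sum(2 * d3[1] * d3[2] * pf * 10^(-snr_test / 10)))
  } else config$noise_level <- config$noise_level %||% 1e-12
  n <- dmap$grid$n
  preds <- array(FALSE, c(n, n, length(idx)))
  for (jj in seq_along(idx)) {
    i <- idx[jj]
    hot_i <- ds$cold
    hot_i$Es <- ds$hot[, , , i, drop = FALSE]
    dim(hot_i$Es) <- d3
    hot_n <- add_awgn(hot_i, snr_test,
                      seed = derive_seed(ds$seed, 4e6 + 16 * i + 2 * noise_tag))
    cold_n <- add_awgn(ds$cold, snr_test,
                       seed = derive_seed(ds$seed, 4e6 + 16 * i + 2 * noise_tag + 1))
    fit <- bim_invert(hot_n$Es - cold_n$Es, dmap, ds$antennas, config,
                      thermo = ds$thermo, cache = cache, cold_sim = cold_sim)
    preds[, , jj] <- fit$hotspot
  }
  rep <- score_images(preds, ds$labels[, , idx, drop = FALSE],
                      tumor_mask(ds$phantom$tissue))
  rep$regularizer <- config$regularizer
  rep$snr_test <- snr_test
  rep
}
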