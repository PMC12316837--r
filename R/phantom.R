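# Synthetic 2-D breast phantom: tissue-class map plus frequency-resolved
# dielectric maps (the cold/reference state).
#
# Tissue classes: 0 = coupling medium (background), 1 = skin, 2 = fat,
# 3 = fibroglandular, 4 = tumor. The layout (skin ring, fat bulk, seeded
# fibroglandular blobs, circular tumor inclusion) is a parametric stand-in
# for a patient-specific MRI-derived map: structurally comparable (low-DP
# fat against high-DP fibroglandular tissue), not anatomically exact.

TISSUE_LEVELS <- c(background = 0L, skin = 1L, fat = 2L,
                   fibroglandular = 3L, tumor = 4L)

#' Default single-pole Debye parameters per tissue class
#'
#' `eps_r(f) = eps_inf + deps / (1 + (omega tau)^2)` and
#' `sigma(f) = sigma_s + eps0 deps omega^2 tau / (1 + (omega tau)^2)`.
#' Magnitudes follow the published wideband breast-tissue dielectric
#' literature (low-permittivity adipose vs. high-permittivity
#' fibroglandular tissue, tumor slightly above fibroglandular); they are
#' documented substitutes, not fits to a specific patient.
#'
#' @return data.frame with one row per tissue class.
#' @export
tissue_debye_defaults <- function() {
  data.frame(
    class = c("skin", "fat", "fibroglandular", "tumor"),
    eps_inf = c(4.0, 2.5, 6.1, 6.8),
    deps = c(33.0, 3.0, 44.0, 50.0),
    tau = c(7.23e-12, 13.0e-12, 10.0e-12, 10.5e-12),
    sigma_s = c(1.1, 0.05, 0.8, 1.0)
  )
}

debye_eval <- function(p, f) {
  w <- 2 * pi * f
  wt2 <- (w * p$tau)^2
  list(eps_r = p$eps_inf + p$deps / (1 + wt2),
       sigma = p$sigma_s + EPS0 * p$deps * w^2 * p$tau / (1 + wt2))
}

#' Build the synthetic breast phantom
#'
#' Constructs the tissue-class map (skin ring, fat bulk, fibroglandular
#' blobs, circular tumor) and evaluates the cold-state dielectric maps on
#' the frequency grid. Deterministic given the arguments (blob placement is
#' driven by `seed` only).
#'
#' @param grid a [grid_spec()].
#' @param freqs a [frequency_grid()].
#' @param medium a [background_medium()]; used for background cells.
#' @param breast_radius outer breast radius in m.
#' @param skin_thickness skin ring thickness in m.
#' @param tumor_center length-2 numeric, tumor centre (x, y) in m.
#' @param tumor_radius tumor radius in m (0 for no tumor).
#' @param n_fibro_blobs number of fibroglandular discs to scatter.
#' @param dp_mode `"debye"` (dispersive, default) or `"constant"`.
#' @param dp_table Debye table as [tissue_debye_defaults()], or for
#'   `"constant"` mode a data.frame with columns `class`, `eps_r`, `sigma`.
#' @param seed integer seed for blob placement.
#' @return list of class `breast_phantom` with elements `tissue` (a
#'   `tissue_map`: integer matrix of classes plus geometry metadata) and
#'   `dielectric` (a `dielectric_map`: `eps_r` and `sigma` arrays of shape
#'   `n x n x n_freq`).
#' @export
breast_phantom <- function(grid = grid_spec(), freqs = frequency_grid(),
                           medium = background_medium(),
                           breast_radius = 0.045, skin_thickness = 0.002,
                           tumor_center = c(0.020, 0), tumor_radius = 0.0075,
                           n_fibro_blobs = 3, dp_mode = c("debye", "constant"),
                           dp_table = NULL, seed = 1L) {
  dp_mode <- match.arg(dp_mode)
  stopifnot(breast_radius > 0, skin_thickness >= 0, tumor_radius >= 0)
  inner <- breast_radius - skin_thickness
  if (tumor_radius > 0 &&
      sqrt(sum(tumor_center^2)) + tumor_radius > inner) {
    stop("tumor disc extends outside the breast interior (|center| + radius > ",
         signif(inner, 3), " m)")
  }
  n <- grid$n
  r2 <- grid$coords[, 1]^2 + grid$coords[, 2]^2
  cls <- integer(n * n)                       # background
  cls[r2 <= breast_radius^2] <- TISSUE_LEVELS[["skin"]]
  cls[r2 <= inner^2] <- TISSUE_LEVELS[["fat"]]
  if (n_fibro_blobs > 0) {
    rng <- local_rng(seed)
    for (b in seq_len(n_fibro_blobs)) {
      ang <- rng$runif(1, 0, 2 * pi)
      rad <- rng$runif(1, 0, 0.5 * inner)
      ctr <- c(rad * cos(ang), rad * sin(ang))
      br <- rng$runif(1, 0.15, 0.30) * breast_radius
      d2 <- (grid$coords[, 1] - ctr[1])^2 + (grid$coords[, 2] - ctr[2])^2
      cls[d2 <= br^2 & cls == TISSUE_LEVELS[["fat"]]] <-
        TISSUE_LEVELS[["fibroglandular"]]
    }
  }
  if (tumor_radius > 0) {
    d2 <- (grid$coords[, 1] - tumor_center[1])^2 +
      (grid$coords[, 2] - tumor_center[2])^2
    cls[d2 <= tumor_radius^2] <- TISSUE_LEVELS[["tumor"]]
  }
  cls_mat <- matrix(cls, n, n)
  tissue <- structure(list(grid = grid, classes = cls_mat,
                           tumor_center = tumor_center,
                           tumor_radius = tumor_radius,
                           breast_radius = breast_radius,
                           skin_thickness = skin_thickness),
                      class = "tissue_map")
  dielectric <- tissue_dielectric(tissue, freqs, medium, dp_mode, dp_table)
  structure(list(tissue = tissue, dielectric = dielectric),
            class = "breast_phantom")
}

# Evaluate per-class DPs on the frequency grid.
tissue_dielectric <- function(tissue, freqs, medium, dp_mode = "debye",
                              dp_table = NULL) {
  n <- tissue$grid$n
  nf <- freqs$n
  eps_r <- array(medium$eps_rb, dim = c(n, n, nf))
  sigma <- array(medium$sigma_b, dim = c(n, n, nf))
  if (dp_mode == "debye") {
    tab <- if (is.null(dp_table)) tissue_debye_defaults() else dp_table
    for (k in seq_len(nrow(tab))) {
      id <- TISSUE_LEVELS[[tab$class[k]]]
      sel <- tissue$classes == id
      if (!any(sel)) next
      for (j in seq_len(nf)) {
        dp <- debye_eval(tab[k, ], freqs$frequencies[j])
        eps_r[, , j][sel] <- dp$eps_r
        sigma[, , j][sel] <- dp$sigma
      }
    }
  } else {
    stopifnot(!is.null(dp_table), all(c("class", "eps_r", "sigma") %in%
                                        names(dp_table)))
    for (k in seq_len(nrow(dp_table))) {
      id <- TISSUE_LEVELS[[dp_table$class[k]]]
      sel <- tissue$classes == id
      for (j in seq_len(nf)) {
        eps_r[, , j][sel] <- dp_table$eps_r[k]
        sigma[, , j][sel] <- dp_table$sigma[k]
      }
    }
  }
  new_dielectric_map(tissue$grid, freqs, medium, eps_r, sigma)
}

new_dielectric_map <- function(grid, freqs, medium, eps_r, sigma) {
  stopifnot(all(dim(eps_r) == c(grid$n, grid$n, freqs$n)),
            all(dim(sigma) == dim(eps_r)))
  if (!all(is.finite(eps_r)) || !all(is.finite(sigma)))
    stop("dielectric map contains non-finite values")
  if (any(eps_r < 1)) stop("relative permittivity below 1")
  if (any(sigma < 0)) stop("negative conductivity")
  structure(list(grid = grid, freqs = freqs, medium = medium,
                 eps_r = eps_r, sigma = sigma),
            class = "dielectric_map")
}

#' @export
print.breast_phantom <- function(x, ...) {
  tab <- table(factor(x$tissue$classes, levels = TISSUE_LEVELS,
                      labels = names(TISSUE_LEVELS)))
  cat(sprintf("<breast_phantom> %d x %d grid, %d frequencies\n",
              x$tissue$grid$n, x$tissue$grid$n, x$dielectric$freqs$n))
  print(tab)
  invisible(x)
}

freq_index <- function(freqs, f) {
  if (f <= 0) stop("frequency must be positive")
  j <- which(abs(freqs$frequencies - f) <= 1e-6 * f)
  if (length(j) != 1) stop("frequency ", f, " Hz is not on the frequency grid")
  j
}

#' Complex relative permittivity at one frequency
#'
#' `eps_c = eps_r + i sigma / (omega eps0)` per cell (`e^{-i omega t}`
#' convention; the loss term has a non-negative imaginary part for passive
#' media).
#'
#' @param dmap a `dielectric_map`.
#' @param f frequency in Hz; must lie on the map's frequency grid.
#' @return complex matrix `n x n`.
#' @export
dp_at_frequency <- function(dmap, f) {
  j <- freq_index(dmap$freqs, f)
  dmap$eps_r[, , j] + 1i * dmap$sigma[, , j] / (2 * pi * f * EPS0)
}

#' Contrast function at one frequency
#'
#' Per-cell difference between the complex relative permittivity and that of
#' the coupling medium. Exactly zero on background cells.
#'
#' @inheritParams dp_at_frequency
#' @return complex matrix `n x n`.
#' @export
contrast_at_frequency <- function(dmap, f) {
  dp_at_frequency(dmap, f) - background_eps_c(dmap$medium, f)
}

#' Tumor mask
#'
#' @param tissue a `tissue_map`.
#' @return logical matrix, `TRUE` on tumor cells.
#' @export
tumor_mask <- function(tissue) tissue$classes == TISSUE_LEVELS[["tumor"]]

#' Breast-interior mask (all tissue cells, background excluded)
#'
#' @param tissue a `tissue_map`.
#' @return logical matrix.
#' @export
breast_mask <- function(tissue) tissue$classes != TISSUE_LEVELS[["background"]]

#' Save / load a phantom
#'
#' The phantom container is a documented JSON file holding grid metadata,
#' the tissue-class map and the per-frequency `eps_r`/`sigma` arrays at full
#' numeric precision; the round trip is lossless.
#'
#' @param phantom a `breast_phantom`.
#' @param path file path.
#' @return `save_phantom` returns `path` invisibly; `load_phantom` returns a
#'   `breast_phantom`.
#' @export
save_phantom <- function(phantom, path) {
  d <- phantom$dielectric
  obj <- list(
    format = "hotspotmon-phantom", version = 1L,
    grid = list(n = d$grid$n, cell_size = d$grid$cell_size),
    frequencies = d$freqs$frequencies,
    medium = list(eps_rb = d$medium$eps_rb, sigma_b = d$medium$sigma_b),
    tissue = list(classes = as.vector(phantom$tissue$classes),
                  tumor_center = phantom$tissue$tumor_center,
                  tumor_radius = phantom$tissue$tumor_radius,
                  breast_radius = phantom$tissue$breast_radius,
                  skin_thickness = phantom$tissue$skin_thickness),
    eps_r = as.vector(d$eps_r), sigma = as.vector(d$sigma)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_phantom
#' @export
load_phantom <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "hotspotmon-phantom"))
    stop("not a hotspotmon phantom container: ", path)
  grid <- grid_spec(obj$grid$n, obj$grid$cell_size)
  f <- obj$frequencies
  freqs <- structure(list(n = length(f), frequencies = f, omega = 2 * pi * f),
                     class = "frequency_grid")
  medium <- background_medium(obj$medium$eps_rb, obj$medium$sigma_b)
  n <- grid$n; nf <- freqs$n
  if (length(obj$eps_r) != n * n * nf || length(obj$sigma) != n * n * nf)
    stop("shape mismatch between grid metadata and dielectric arrays")
  eps_r <- array(obj$eps_r, dim = c(n, n, nf))
  sigma <- array(obj$sigma, dim = c(n, n, nf))
  dielectric <- new_dielectric_map(grid, freqs, medium, eps_r, sigma)
  tissue <- structure(list(grid = grid,
                           classes = matrix(as.integer(obj$tissue$classes), n, n),
                           tumor_center = obj$tissue$tumor_center,
                           tumor_radius = obj$tissue$tumor_radius,
                           breast_radius = obj$tissue$breast_radius,
                           skin_thickness = obj$tissue$skin_thickness),
                      class = "tissue_map")
  structure(list(tissue = tissue, dielectric = dielectric),
            class = "breast_phantom")
}
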