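# Random heating-scenario generator.
#
# Emulates the temperature fields arising in microwave hyperthermia: one to
# a few heating regions with layered (concentric-annulus) profiles whose
# temperature decreases away from the focal point, combined by per-cell
# maximum, then Gaussian-smoothed so the field varies smoothly, and clamped
# to baseline + delta_T_max. The tumor is heated with a configurable
# probability; remaining region centres fall uniformly on the breast
# interior.

#' Heating-scenario configuration
#'
#' Distributions driving [sample_scenario()]. Defaults: 1-3 heating regions
#' (uniform), peak temperature rise uniform on (0, 24) degC, 2-5 annular
#' layers of width 4-12 mm (scaled to the domain extent), tumor heated with
#' probability 0.5, Gaussian smoothing with a one-cell kernel, baseline
#' body temperature 37 degC, rise capped at 24 degC.
#'
#' @param n_regions_range integer vector of admissible region counts
#'   (sampled uniformly); may include 0.
#' @param peak_range numeric length 2, range of the peak temperature rise
#'   in degC.
#' @param n_layers_range integer vector of admissible layer counts.
#' @param layer_width_frac numeric length 2, annulus width range as a
#'   fraction of the domain extent.
#' @param p_tumor probability that one region is centred on the tumor.
#' @param smooth_sigma_cells Gaussian smoothing kernel width in cells
#'   (0 disables smoothing).
#' @param baseline_T baseline temperature in degC.
#' @param delta_T_max cap on the temperature rise in degC.
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(n_regions_range = 1:3, peak_range = c(0, 24),
                            n_layers_range = 2:5,
                            layer_width_frac = c(0.04, 0.12),
                            p_tumor = 0.5, smooth_sigma_cells = 1,
                            baseline_T = 37, delta_T_max = 24) {
  stopifnot(delta_T_max > 0, p_tumor >= 0, p_tumor <= 1,
            all(n_regions_range >= 0), all(n_layers_range >= 1),
            peak_range[2] >= peak_range[1], peak_range[1] >= 0)
  structure(list(n_regions_range = n_regions_range, peak_range = peak_range,
                 n_layers_range = n_layers_range,
                 layer_width_frac = layer_width_frac, p_tumor = p_tumor,
                 smooth_sigma_cells = smooth_sigma_cells,
                 baseline_T = baseline_T, delta_T_max = delta_T_max),
            class = "scenario_config")
}

# Layered radial profile: delta_T at distance d from the centre, with
# per-layer constant values decreasing linearly from `peak` to zero beyond
# the outermost layer.
layered_profile <- function(d, peak, radii) {
  nl <- length(radii)
  lev <- peak * (1 - (seq_len(nl) - 1) / nl)
  out <- numeric(length(d))
  layer <- findInterval(d, radii, left.open = TRUE) + 1L   # 1..nl inside
  inside <- layer <= nl
  out[inside] <- lev[layer[inside]]
  out
}

# Separable Gaussian smoothing with edge renormalisation.
gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-half):half)^2 / (2 * sigma^2))
  k <- k / sum(k)
  smooth1 <- function(x) {   # along rows of a matrix (columns fixed)
    n <- nrow(x)
    out <- matrix(0, n, ncol(x))
    wt <- numeric(n)
    for (o in (-half):half) {
      src <- (1 + max(0, o)):(n + min(0, o))
      dst <- src - o
      w <- k[o + half + 1]
      out[dst, ] <- out[dst, ] + w * x[src, ]
      wt[dst] <- wt[dst] + w
    }
    out / wt
  }
  t(smooth1(t(smooth1(m))))
}

#' Sample one random heating scenario
#'
#' Draws the number of heating regions, their centres (the tumor centre with
#' probability `p_tumor`, otherwise uniform over breast-interior cells),
#' layered radial profiles, combines regions by per-cell maximum, smooths,
#' clamps the rise to `delta_T_max`, and confines heating to tissue cells
#' (the coupling liquid is temperature-controlled). Reproducible from
#' `seed`.
#'
#' @param tissue a `tissue_map` (from [breast_phantom()]).
#' @param config a [scenario_config()].
#' @param seed integer seed.
#' @return object of class `temperature_field`: list with `T` (degC matrix),
#'   `baseline_T`, `tumor_heated` flag, region metadata and `seed`.
#' @export
sample_scenario <- function(tissue, config = scenario_config(), seed = 1L) {
  grid <- tissue$grid
  interior <- which(breast_mask(tissue))
  if (length(interior) == 0) stop("breast interior is empty")
  rng <- local_rng(seed)
  n_regions <- if (length(config$n_regions_range) == 1) config$n_regions_range
  else config$n_regions_range[rng$sample(seq_along(config$n_regions_range), 1)]
  dT <- matrix(0, grid$n, grid$n)
  tumor_heated <- FALSE
  regions <- list()
  if (n_regions > 0) {
    tumor_heated <- tissue$tumor_radius > 0 && rng$runif(1) < config$p_tumor
    for (ri in seq_len(n_regions)) {
      if (ri == 1 && tumor_heated) ctr <- tissue$tumor_center
      else {
        cell <- interior[rng$sample(length(interior), 1)]
        ctr <- grid$coords[cell, ]
      }
      peak <- rng$runif(1, config$peak_range[1], config$peak_range[2])
      nl <- if (length(config$n_layers_range) == 1) config$n_layers_range
      else config$n_layers_range[rng$sample(seq_along(config$n_layers_range), 1)]
      widths <- rng$runif(nl, config$layer_width_frac[1] * grid$extent,
                          config$layer_width_frac[2] * grid$extent)
      radii <- cumsum(widths)
      d <- sqrt((grid$coords[, 1] - ctr[1])^2 + (grid$coords[, 2] - ctr[2])^2)
      prof <- layered_profile(d, peak, radii)
      dT <- pmax(dT, matrix(prof, grid$n, grid$n))
      regions[[ri]] <- list(center = ctr, peak = peak, radii = radii)
    }
  }
  dT <- gaussian_smooth(dT, config$smooth_sigma_cells)
  dT <- pmin(dT, config$delta_T_max)
  dT[!breast_mask(tissue)] <- 0
  structure(list(grid = grid, T = config$baseline_T + dT,
                 baseline_T = config$baseline_T, tumor_heated = tumor_heated,
                 regions = regions, seed = seed),
            class = "temperature_field")
}

#' @export
print.temperature_field <- function(x, ...) {
  cat(sprintf("<temperature_field> %d x %d, baseline %.1f degC, max rise %.2f degC, %d region(s)%s\n",
              x$grid$n, x$grid$n, x$baseline_T, max(x$T) - x$baseline_T,
              length(x$regions), if (isTRUE(x$tumor_heated)) ", tumor heated" else ""))
  invisible(x)
}

#' Import / export a temperature map
#'
#' Plain whitespace-delimited matrix of temperatures in degC. On import the
#' map is validated (finite, within 0-100 degC) and resampled to the target
#' grid by nearest neighbour if the source resolution differs (both grids
#' are taken to span the same physical domain).
#'
#' @param path file path.
#' @param grid target [grid_spec()].
#' @param baseline_T baseline recorded on the returned field, degC.
#' @return `import_temperature_map` returns a `temperature_field`;
#'   `export_temperature_map` returns `path` invisibly.
#' @export
import_temperature_map <- function(path, grid, baseline_T = 37) {
  m <- as.matrix(utils::read.table(path))
  dimnames(m) <- NULL
  if (!all(is.finite(m))) stop("temperature map contains non-finite entries")
  if (any(m < 0) || any(m > 100))
    stop("temperatures outside the plausible 0-100 degC range")
  if (nrow(m) != ncol(m)) stop("temperature map must be square")
  if (nrow(m) != grid$n) {
    src <- nrow(m)
    src_centers <- (seq_len(src) - 0.5) / src
    tgt_centers <- (seq_len(grid$n) - 0.5) / grid$n
    idx <- vapply(tgt_centers,
                  function(tc) which.min(abs(src_centers - tc)), integer(1))
    m <- m[idx, idx, drop = FALSE]
  }
  structure(list(grid = grid, T = m, baseline_T = baseline_T,
                 tumor_heated = NA, regions = list(), seed = NA_integer_),
            class = "temperature_field")
}

#' @rdname import_temperature_map
#' @param field a `temperature_field`.
#' @export
export_temperature_map <- function(field, path) {
  utils::write.table(format(field$T, digits = 17), path,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
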