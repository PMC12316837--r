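# Problem geometry: computation domain grid, antenna ring, frequency grid,
# coupling medium.

EPS0 <- 8.8541878128e-12   # F/m
MU0 <- 4e-7 * pi           # H/m
C0 <- 299792458            # m/s

#' Computation-domain grid
#'
#' Square cell grid for the 2-D imaging domain. The default (50 cells of
#' 2 mm) gives a 10 cm x 10 cm domain. Coordinates: x to the right, y up,
#' origin at the domain centre; cell `[row, col]` = `[1, 1]` is the top-left
#' corner. Arrays over the grid are stored `[row, col]` and flattened
#' column-major (R's native order).
#'
#' @param n number of cells per axis.
#' @param cell_size cell edge length in metres.
#' @return object of class `grid_spec` with cell-centre coordinates: `xs`
#'   (per column, ascending), `ys` (per row, descending), and `coords`, an
#'   `n^2 x 2` matrix of `(x, y)` in flattened order.
#' @export
grid_spec <- function(n = 50, cell_size = 0.002) {
  stopifnot(n >= 1, cell_size > 0)
  half <- (n - 1) / 2 * cell_size
  xs <- -half + (seq_len(n) - 1) * cell_size
  ys <- half - (seq_len(n) - 1) * cell_size
  coords <- cbind(x = rep(xs, each = n), y = rep(ys, times = n))
  structure(list(n = as.integer(n), cell_size = cell_size,
                 extent = n * cell_size, xs = xs, ys = ys, coords = coords),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells of %.3g mm (%.3g cm domain)\n",
              x$n, x$n, 1000 * x$cell_size, 100 * x$extent))
  invisible(x)
}

#' Circular antenna array
#'
#' Transmit/receive antennas equally spaced on a circle around the domain,
#' modelled as unit-amplitude 2-D line sources. Antenna 1 sits on the
#' positive x axis; ordering is counter-clockwise.
#'
#' @param n number of antennas.
#' @param radius circle radius in metres.
#' @return object of class `antenna_array` with `angles` (radians) and
#'   `positions` (`n x 2` matrix of `(x, y)` in metres).
#' @export
antenna_array <- function(n = 16, radius = 0.075) {
  stopifnot(n >= 2, radius > 0)
  angles <- 2 * pi * (seq_len(n) - 1) / n
  structure(list(n = as.integer(n), radius = radius, angles = angles,
                 positions = cbind(x = radius * cos(angles),
                                   y = radius * sin(angles))),
            class = "antenna_array")
}

#' @export
print.antenna_array <- function(x, ...) {
  cat(sprintf("<antenna_array> %d line sources on a %.1f mm circle\n",
              x$n, 1000 * x$radius))
  invisible(x)
}

#' Measurement frequency grid
#'
#' Linearly spaced frequencies; the default covers 0.5-2 GHz with 16 points.
#'
#' @param n number of frequencies.
#' @param fmin,fmax band edges in Hz.
#' @return object of class `frequency_grid` with `frequencies` (Hz) and
#'   `omega` (rad/s).
#' @export
frequency_grid <- function(n = 16, fmin = 0.5e9, fmax = 2e9) {
  stopifnot(n >= 1, fmin > 0, fmax >= fmin)
  f <- if (n == 1) fmin else seq(fmin, fmax, length.out = n)
  structure(list(n = as.integer(n), frequencies = f, omega = 2 * pi * f),
            class = "frequency_grid")
}

#' Coupling (background) medium
#'
#' Homogeneous matching medium surrounding the breast. Default relative
#' permittivity 20 and effective conductivity 0.6 S/m.
#'
#' @param eps_rb relative permittivity (dimensionless).
#' @param sigma_b effective conductivity in S/m.
#' @return object of class `background_medium`.
#' @export
background_medium <- function(eps_rb = 20, sigma_b = 0.6) {
  stopifnot(eps_rb >= 1, sigma_b >= 0)
  structure(list(eps_rb = eps_rb, sigma_b = sigma_b),
            class = "background_medium")
}

# Complex relative permittivity of the background at frequency f (Hz),
# e^{-i omega t} convention: eps_c = eps_r + i sigma / (omega eps0).
background_eps_c <- function(medium, f) {
  stopifnot(f > 0)
  medium$eps_rb + 1i * medium$sigma_b / (2 * pi * f * EPS0)
}

#' Background and free-space wavenumbers
#'
#' `k_b = (omega/c) sqrt(eps_rb + i sigma_b/(omega eps0))`, principal branch,
#' so that `Im(k_b) >= 0` (decaying outgoing waves under the `e^{-i omega t}`
#' convention); `k_0 = omega/c`.
#'
#' @param medium a [background_medium()].
#' @param f frequency in Hz.
#' @return list with `k0` (free space, rad/m) and `kb` (complex, rad/m).
#' @export
wavenumbers <- function(medium, f) {
  stopifnot(f > 0)
  k0 <- 2 * pi * f / C0
  list(k0 = k0, kb = k0 * sqrt(background_eps_c(medium, f)))
}
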