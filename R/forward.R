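# 2-D TM method-of-moments forward scattering solver.
#
# Domain integral equation E = E_inc + k0^2 \int_D G chi E, discretised on
# the cell grid with Richmond-style equivalent-area circular cells: each
# square cell of side h is replaced by the disc of equal area (radius
# a = h/sqrt(pi)), for which the integral of the 2-D Green's function
# G = (i/4) H0^(1)(kb |r - r'|) has a closed form:
#   observation outside the cell:  (i pi a / (2 kb)) J1(kb a) H0^(1)(kb rho)
#   observation at the cell centre: (i/(2 kb^2)) (pi kb a H1^(1)(kb a) + 2i)
# One dense factorisation per (map, frequency) serves all transmitters.

pair_dist <- function(P, Q) {
  dx <- outer(P[, 1], Q[, 1], "-")
  dy <- outer(P[, 2], Q[, 2], "-")
  sqrt(dx * dx + dy * dy)
}

#' Cell-integrated Green's function matrix
#'
#' Matrix of `\int_cell G(r_obs, r') dA'` over equivalent-circle cells, for
#' a set of observation points. Uses the closed-form off-centre and
#' self-cell integrals.
#'
#' @param points `m x 2` matrix of observation coordinates (m).
#' @param grid a [grid_spec()].
#' @param kb complex background wavenumber (rad/m).
#' @return `m x n_cells` complex matrix.
#' @export
cell_green_matrix <- function(points, grid, kb) {
  a <- grid$cell_size / sqrt(pi)
  R <- pair_dist(points, grid$coords)
  isself <- R < grid$cell_size * 1e-9
  out <- matrix(0i, nrow(R), ncol(R))
  if (any(!isself)) {
    out[!isself] <- (1i * pi * a / (2 * kb)) * zbesselJ(1, kb * a) *
      zhankel1(0, kb * R[!isself])
  }
  if (any(isself)) {
    out[isself] <- (1i / (2 * kb^2)) * (pi * kb * a * zhankel1(1, kb * a) + 2i)
  }
  out
}

#' Incident field of one line-source transmitter
#'
#' Unit-amplitude 2-D line source: `E_inc(r) = (i/4) H0^(1)(kb |r - r_t|)`,
#' the same normalisation as the Green's function.
#'
#' @param tx_pos length-2 transmitter coordinates (m), outside the domain.
#' @param points `m x 2` matrix of evaluation points, or a [grid_spec()]
#'   (all cell centres).
#' @param kb complex background wavenumber.
#' @return complex vector of field values.
#' @export
incident_field <- function(tx_pos, points, kb) {
  if (inherits(points, "grid_spec")) points <- points$coords
  d <- sqrt((points[, 1] - tx_pos[1])^2 + (points[, 2] - tx_pos[2])^2)
  if (any(d == 0)) stop("incident field evaluated at the source location")
  (1i / 4) * zhankel1(0, kb * d)
}

#' Precompute per-frequency geometry factors
#'
#' Builds the cell-integrated Green's matrices (domain and receiver), the
#' incident fields and the wavenumbers for every frequency. The cache
#' depends only on the geometry and the coupling medium, so it can be
#' reused across dielectric maps (e.g. over all scenarios of a dataset).
#'
#' @param grid a [grid_spec()].
#' @param antennas an [antenna_array()].
#' @param freqs a [frequency_grid()].
#' @param medium a [background_medium()].
#' @return object of class `forward_cache`.
#' @export
forward_cache <- function(grid, antennas, freqs, medium) {
  per_freq <- lapply(seq_len(freqs$n), function(j) {
    f <- freqs$frequencies[j]
    k <- wavenumbers(medium, f)
    C <- cell_green_matrix(grid$coords, grid, k$kb)
    Crx <- cell_green_matrix(antennas$positions, grid, k$kb)
    Einc <- vapply(seq_len(antennas$n), function(t)
      incident_field(antennas$positions[t, ], grid, k$kb),
      complex(grid$n^2))
    list(f = f, k0 = k$k0, kb = k$kb, C = C, Crx = Crx, Einc = Einc)
  })
  structure(list(grid = grid, antennas = antennas, freqs = freqs,
                 medium = medium, per_freq = per_freq),
            class = "forward_cache")
}

#' Solve the total field in the domain at one frequency
#'
#' Assembles `A = I - k0^2 C diag(chi)` and solves `A E = E_inc` for all
#' transmitters with one dense factorisation. With zero contrast the system
#' is the identity and `E` equals the incident field exactly.
#'
#' @param dmap a `dielectric_map`.
#' @param f frequency in Hz (on the map's grid).
#' @param antennas an [antenna_array()].
#' @param cache optional [forward_cache] for the geometry (built on the
#'   fly if omitted).
#' @return list with `E` (`n_cells x n_tx` complex), `chi` (contrast
#'   vector), `k0`, `kb`.
#' @export
solve_total_field <- function(dmap, f, antennas, cache = NULL) {
  j <- freq_index(dmap$freqs, f)
  pf <- if (is.null(cache)) {
    fg <- structure(list(n = 1L, frequencies = f, omega = 2 * pi * f),
                    class = "frequency_grid")
    forward_cache(dmap$grid, antennas, fg, dmap$medium)$per_freq[[1]]
  } else cache$per_freq[[j]]
  chi <- as.vector(contrast_at_frequency(dmap, f))
  ncell <- length(chi)
  if (all(chi == 0)) {
    E <- pf$Einc
  } else {
    A <- (-pf$k0^2) * pf$C * rep(chi, each = ncell)
    diag(A) <- diag(A) + 1
    E <- solve(A, pf$Einc)
  }
  list(E = E, chi = chi, k0 = pf$k0, kb = pf$kb, Crx = pf$Crx)
}

#' Scattered field at the receivers
#'
#' Discretised data equation: `E_s(r_r) = k0^2 sum_n C_rx[r, n] chi_n E_n`,
#' with the same cell-integral rule as the system matrix.
#'
#' @param sol result of [solve_total_field()].
#' @return `n_rx x n_tx` complex matrix.
#' @export
scattered_at_receivers <- function(sol) {
  sol$k0^2 * (sol$Crx %*% (sol$chi * sol$E))
}

#' Multi-static multi-frequency scattered-field simulation
#'
#' Full `n_rx x n_tx` matrix per frequency (monostatic diagonal included by
#' default; `mask_monostatic = TRUE` zeroes it).
#'
#' @param dmap a `dielectric_map`.
#' @param antennas an [antenna_array()].
#' @param cache optional [forward_cache].
#' @param mask_monostatic zero the transmit == receive entries.
#' @return object of class `scatter_data`: complex array
#'   `n_rx x n_tx x n_freq` in `$Es` plus geometry metadata.
#' @export
simulate_multistatic <- function(dmap, antennas, cache = NULL,
                                 mask_monostatic = FALSE) {
  freqs <- dmap$freqs
  if (is.null(cache)) cache <- forward_cache(dmap$grid, antennas, freqs,
                                             dmap$medium)
  Es <- array(0i, dim = c(antennas$n, antennas$n, freqs$n))
  for (j in seq_len(freqs$n)) {
    sol <- solve_total_field(dmap, freqs$frequencies[j], antennas, cache)
    Es[, , j] <- scattered_at_receivers(sol)
  }
  if (mask_monostatic)
    for (j in seq_len(freqs$n)) diag(Es[, , j]) <- 0i
  structure(list(Es = Es, freqs = freqs, antennas = antennas,
                 grid = dmap$grid, medium = dmap$medium),
            class = "scatter_data")
}

#' @export
print.scatter_data <- function(x, ...) {
  cat(sprintf("<scatter_data> %d rx x %d tx x %d frequencies (%.2g-%.2g GHz)\n",
              dim(x$Es)[1], dim(x$Es)[2], dim(x$Es)[3],
              min(x$freqs$frequencies) / 1e9, max(x$freqs$frequencies) / 1e9))
  invisible(x)
}

# ---- analytic validation: homogeneous circular cylinder --------------------

# Eigenfunction-series solution for a homogeneous dielectric cylinder of
# radius R centred at the origin in the lossy background, illuminated by a
# unit line source. Independent of the MoM path; used to validate it.
cylinder_series_coeffs <- function(R, eps_c_cyl, medium, f, nmax) {
  k <- wavenumbers(medium, f)
  k1 <- k$k0 * sqrt(eps_c_cyl)
  a <- b <- complex(nmax + 1)
  for (n in 0:nmax) {
    jb <- zbesselJ(n, k$kb * R); jbp <- zbesselJprime(n, k$kb * R)
    hb <- zhankel1(n, k$kb * R); hbp <- zhankel1prime(n, k$kb * R)
    j1 <- zbesselJ(n, k1 * R); j1p <- zbesselJprime(n, k1 * R)
    # continuity of E and dE/dr, solved in closed form (the raw 2x2 system
    # is badly scaled at high order: J_n underflows while H_n grows)
    a[n + 1] <- -(jb * k1 * j1p - k$kb * jbp * j1) /
      (hb * k1 * j1p - k$kb * hbp * j1)
    b[n + 1] <- (jb + a[n + 1] * hb) / j1
  }
  list(a = a, b = b, kb = k$kb, k1 = k1)
}

#' Analytic cylinder scattering (series oracle)
#'
#' Scattered field of a homogeneous dielectric cylinder centred at the
#' origin, for line-source transmitters, via the classical eigenfunction
#' series. Serves as an independent reference for the MoM solver.
#'
#' @param R cylinder radius (m).
#' @param eps_c_cyl complex relative permittivity of the cylinder.
#' @param medium a [background_medium()].
#' @param f frequency (Hz).
#' @param antennas an [antenna_array()] (transmitters and receivers).
#' @param nmax series order (default from `|kb| R`).
#' @return `n_rx x n_tx` complex matrix of scattered fields.
#' @export
cylinder_scattered_series <- function(R, eps_c_cyl, medium, f, antennas,
                                      nmax = NULL) {
  if (is.null(nmax)) nmax <- max(10, ceiling(Mod(wavenumbers(medium, f)$kb) * R) + 15)
  cs <- cylinder_series_coeffs(R, eps_c_cyl, medium, f, nmax)
  pos <- antennas$positions
  r <- sqrt(rowSums(pos^2)); phi <- atan2(pos[, 2], pos[, 1])
  Hn <- vapply(0:nmax, function(n) zhankel1(n, cs$kb * r), complex(antennas$n))
  Es <- matrix(0i, antennas$n, antennas$n)
  for (n in 0:nmax) {
    w <- if (n == 0) 1 else 2
    Es <- Es + w * cs$a[n + 1] * outer(Hn[, n + 1], Hn[, n + 1]) *
      cos(n * outer(phi, phi, "-"))
  }
  (1i / 4) * Es
}

#' @rdname cylinder_scattered_series
#' @param points `m x 2` evaluation points (inside or outside the cylinder,
#'   inside the source circle).
#' @param tx_pos transmitter coordinates.
#' @return for `cylinder_total_series`: complex vector of total fields.
#' @export
cylinder_total_series <- function(R, eps_c_cyl, medium, f, points, tx_pos,
                                  nmax = NULL) {
  if (is.null(nmax)) nmax <- max(10, ceiling(Mod(wavenumbers(medium, f)$kb) * R) + 15)
  cs <- cylinder_series_coeffs(R, eps_c_cyl, medium, f, nmax)
  r <- sqrt(rowSums(points^2)); phi <- atan2(points[, 2], points[, 1])
  rt <- sqrt(sum(tx_pos^2)); phit <- atan2(tx_pos[2], tx_pos[1])
  stopifnot(all(r < rt))
  inside <- r < R
  E <- complex(nrow(points))
  for (n in 0:nmax) {
    w <- if (n == 0) 1 else 2
    Ht <- zhankel1(n, cs$kb * rt)
    rad <- complex(nrow(points))
    if (any(!inside)) {
      rad[!inside] <- zbesselJ(n, cs$kb * r[!inside]) +
        cs$a[n + 1] * zhankel1(n, cs$kb * r[!inside])
    }
    if (any(inside)) rad[inside] <- cs$b[n + 1] * zbesselJ(n, cs$k1 * r[inside])
    E <- E + w * rad * Ht * cos(n * (phi - phit))
  }
  (1i / 4) * E
}

#' Homogeneous-cylinder dielectric map
#'
#' Builds a `dielectric_map` for a centred homogeneous cylinder in the
#' coupling medium, optionally area-weighting boundary cells (16 x 16
#' sub-sampling) so the discretised cylinder converges to the true disc.
#'
#' @param grid,freqs,medium geometry objects.
#' @param R cylinder radius (m).
#' @param eps_r_cyl,sigma_cyl cylinder DPs (frequency-independent).
#' @param antialias area-weight boundary cells (default `TRUE`).
#' @return a `dielectric_map`.
#' @export
cylinder_dielectric_map <- function(grid, freqs, medium, R, eps_r_cyl,
                                    sigma_cyl, antialias = TRUE) {
  d <- sqrt(rowSums(grid$coords^2))
  frac <- as.numeric(d <= R)
  if (antialias) {
    h <- grid$cell_size
    edge <- which(abs(d - R) <= h)
    if (length(edge)) {
      ss <- (seq_len(16) - 0.5) / 16 - 0.5
      offs <- as.matrix(expand.grid(ss * h, ss * h))
      for (i in edge) {
        pts <- sweep(offs, 2, grid$coords[i, ], "+")
        frac[i] <- mean(rowSums(pts^2) <= R^2)
      }
    }
  }
  nf <- freqs$n
  eps_r <- array(medium$eps_rb + frac * (eps_r_cyl - medium$eps_rb),
                 dim = c(grid$n, grid$n, nf))
  sigma <- array(medium$sigma_b + frac * (sigma_cyl - medium$sigma_b),
                 dim = c(grid$n, grid$n, nf))
  new_dielectric_map(grid, freqs, medium, eps_r, sigma)
}
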