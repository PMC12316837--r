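# Cylinder functions of complex argument.
#
# The lossy coupling medium makes the background wavenumber complex, so every
# Green's-function evaluation needs Bessel/Hankel functions at complex z with
# Im(z) >= 0.  Base R only covers real arguments; the implementations below
# use the ascending power series for |z| <= 12 and the large-argument Hankel
# asymptotic expansion beyond, which covers the argument range reached by the
# 0.5-2 GHz geometry (|z| < ~40) at better than 1e-9 relative accuracy.

ZB_SERIES_CUT <- 12

#' Bessel function of the first kind, complex argument
#'
#' Power-series evaluation of \eqn{J_n(z)} for complex \eqn{z}. Intended for
#' moderate arguments (\eqn{|z| \lesssim 20}); beyond that, cancellation in
#' the alternating series erodes accuracy.
#'
#' @param n non-negative integer order.
#' @param z complex (or numeric) vector.
#' @return complex vector of \eqn{J_n(z)}.
#' @export
zbesselJ <- function(n, z) {
  stopifnot(length(n) == 1, n >= 0, n == round(n))
  z <- as.complex(z)
  out <- complex(length.out = length(z))
  # series is accurate for small |z|, and for n approaching |z| (the leading
  # term dominates and cancellation is mild); otherwise use the asymptotic
  # expansions of H^(1), H^(2) and recurse upward.
  small <- Mod(z) <= ZB_SERIES_CUT | n >= 0.9 * Mod(z)
  if (any(small)) out[small] <- zbesselJ_series(n, z[small])
  if (any(!small)) out[!small] <- zbesselJ_large(n, z[!small])
  out
}

zbesselJ_series <- function(n, z) {
  half <- z / 2
  term <- half^n / factorial(n)
  s <- term
  zz <- -half * half
  for (k in 1:400) {
    term <- term * zz / (k * (n + k))
    s <- s + term
    if (all(Mod(term) <= 1e-17 * (Mod(s) + 1e-300))) break
  }
  s
}

# dJ_n/dz
zbesselJprime <- function(n, z) {
  if (n == 0) return(-zbesselJ(1, z))
  (zbesselJ(n - 1, z) - zbesselJ(n + 1, z)) / 2
}

# Y0, Y1 by their ascending series (log branch: principal).
zbesselY0_series <- function(z) {
  z <- as.complex(z)
  euler <- 0.57721566490153286
  j0 <- zbesselJ(0, z)
  q <- z * z / 4
  term <- rep(1 + 0i, length(z))
  s <- 0 * z
  hk <- 0
  for (k in 1:400) {
    term <- term * q / (k * k)
    hk <- hk + 1 / k
    add <- (-1)^(k + 1) * hk * term
    s <- s + add
    if (all(Mod(add) <= 1e-17 * (Mod(s) + 1e-300))) break
  }
  (2 / pi) * ((log(z / 2) + euler) * j0 + s)
}

zbesselY1_series <- function(z) {
  z <- as.complex(z)
  euler <- 0.57721566490153286
  j1 <- zbesselJ(1, z)
  q <- z * z / 4
  # sum_k (-1)^k (H_k + H_{k+1}) (z/2)^{2k+1} / (k! (k+1)!)
  term <- z / 2                       # k = 0 term basis: (z/2)^{1} / (0! 1!)
  hk <- 0; hk1 <- 1
  s <- term * (hk + hk1)
  sgn <- 1
  for (k in 1:400) {
    term <- term * q / (k * (k + 1))
    hk <- hk + 1 / k
    hk1 <- hk1 + 1 / (k + 1)
    sgn <- -sgn
    add <- sgn * (hk + hk1) * term
    s <- s + add
    if (all(Mod(add) <= 1e-17 * (Mod(s) + 1e-300))) break
  }
  (2 / pi) * (log(z / 2) + euler) * j1 - 2 / (pi * z) - s / pi
}

# J_n for |z| > series cutoff: J = (H^(1) + H^(2))/2 at orders 0, 1 from the
# asymptotic expansions, then upward recurrence (stable while n < |z|).
zbesselJ_large <- function(n, z) {
  jm <- (zhankel1_asym(0, z) + zhankel2_asym(0, z)) / 2
  if (n == 0) return(jm)
  j <- (zhankel1_asym(1, z) + zhankel2_asym(1, z)) / 2
  if (n == 1) return(j)
  for (m in 1:(n - 1)) {
    jp <- (2 * m / z) * j - jm
    jm <- j; j <- jp
  }
  j
}

# Asymptotic Hankel expansion, nu in {0,1}, valid |z| >= ~10.
zhankel1_asym <- function(nu, z) {
  z <- as.complex(z)
  mu <- 4 * nu^2
  term <- rep(1 + 0i, length(z))
  s <- term
  iz <- 1i / z
  for (k in 1:22) {
    term <- term * (mu - (2 * k - 1)^2) / (8 * k) * iz
    s <- s + term
  }
  sqrt(2 / (pi * z)) * exp(1i * (z - nu * pi / 2 - pi / 4)) * s
}

zhankel2_asym <- function(nu, z) {
  z <- as.complex(z)
  mu <- 4 * nu^2
  term <- rep(1 + 0i, length(z))
  s <- term
  iz <- -1i / z
  for (k in 1:22) {
    term <- term * (mu - (2 * k - 1)^2) / (8 * k) * iz
    s <- s + term
  }
  sqrt(2 / (pi * z)) * exp(-1i * (z - nu * pi / 2 - pi / 4)) * s
}

#' Hankel function of the first kind, complex argument
#'
#' \eqn{H_n^{(1)}(z) = J_n(z) + i Y_n(z)} for complex \eqn{z} with
#' \eqn{Im(z) \ge 0}. Orders 0 and 1 are computed directly (series below
#' \eqn{|z| = 12}, asymptotic expansion above); higher orders follow from the
#' upward recurrence, which is stable for Hankel functions.
#'
#' @param n non-negative integer order.
#' @param z complex (or numeric) vector; zero is not allowed.
#' @return complex vector of \eqn{H_n^{(1)}(z)}.
#' @export
zhankel1 <- function(n, z) {
  stopifnot(length(n) == 1, n >= 0, n == round(n))
  z <- as.complex(z)
  if (any(Mod(z) == 0)) stop("zhankel1: argument must be nonzero")
  h01 <- function(nu, z) {
    out <- complex(length.out = length(z))
    small <- Mod(z) <= ZB_SERIES_CUT
    if (any(small)) {
      zs <- z[small]
      ys <- if (nu == 0) zbesselY0_series(zs) else zbesselY1_series(zs)
      out[small] <- zbesselJ(nu, zs) + 1i * ys
    }
    if (any(!small)) out[!small] <- zhankel1_asym(nu, z[!small])
    out
  }
  if (n <= 1) return(h01(n, z))
  hm <- h01(0, z); h <- h01(1, z)
  for (m in 1:(n - 1)) {
    hp <- (2 * m / z) * h - hm
    hm <- h; h <- hp
  }
  h
}

# dH_n^{(1)}/dz
zhankel1prime <- function(n, z) {
  if (n == 0) return(-zhankel1(1, z))
  (zhankel1(n - 1, z) - zhankel1(n + 1, z)) / 2
}
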