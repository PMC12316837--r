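# Thermo-dielectric coupling: temperature change -> dielectric change.
#
# Linear model: relative permittivity falls by 0.25% and effective
# conductivity rises by 1.25% per degC of temperature rise,
#   delta_eps_r = -eps_r * 0.0025 * dT,   delta_sigma = sigma * 0.0125 * dT.
# The quadratic family replaces dT by an effective rise
#   dT_eff = (1 - a) dT + a dT^2 / dT_ref,
# an endpoint-anchored blend: for every nonlinearity degree `a` in [0, 1]
# the quadratic model agrees with the linear one at dT = 0 and at
# dT = dT_ref (24 degC, the largest rise in the data). The coefficients are
# applied frequency-independently; frequency enters only through the
# reference DPs.

ALPHA_EPS <- 0.0025    # fractional permittivity decrease per degC
ALPHA_SIGMA <- 0.0125  # fractional conductivity increase per degC

#' Thermo-dielectric model
#'
#' @param kind `"linear"` or `"quadratic"`.
#' @param a nonlinearity degree in `[0, 1]`; 0 reduces the quadratic family
#'   to the linear model.
#' @param alpha_eps,alpha_sigma fractional DP change per degC.
#' @param dT_ref anchoring endpoint of the quadratic family, degC; also the
#'   upper end of the validity range.
#' @return list of class `thermo_model`.
#' @export
thermo_model <- function(kind = c("linear", "quadratic"), a = 0,
                         alpha_eps = ALPHA_EPS, alpha_sigma = ALPHA_SIGMA,
                         dT_ref = 24) {
  kind <- match.arg(kind)
  stopifnot(a >= 0, a <= 1, dT_ref > 0, alpha_eps > 0, alpha_sigma > 0)
  if (kind == "linear") a <- 0
  if (kind == "quadratic" && a == 0) kind <- "linear"
  structure(list(kind = kind, a = a, alpha_eps = alpha_eps,
                 alpha_sigma = alpha_sigma, dT_ref = dT_ref),
            class = "thermo_model")
}

effective_dT <- function(model, dT) {
  out_of_range <- dT < 0 | dT > model$dT_ref
  if (any(out_of_range)) {
    warning("temperature rise outside [0, ", model$dT_ref,
            "] degC clamped to the model's validity range")
    dT <- pmin(pmax(dT, 0), model$dT_ref)
  }
  (1 - model$a) * dT + model$a * dT^2 / model$dT_ref
}

#' Dielectric-property change for a temperature rise
#'
#' @param model a [thermo_model()].
#' @param eps_r,sigma reference (cold) DP values; scalars, vectors or
#'   matrices (recycled against `dT`).
#' @param dT temperature rise in degC; values outside the validity range
#'   are clamped with a warning.
#' @return list with `delta_eps_r` and `delta_sigma` of the common shape.
#' @export
delta_dp <- function(model, eps_r, sigma, dT) {
  if (any(eps_r < 0) || any(sigma < 0)) stop("negative reference DPs")
  dTe <- effective_dT(model, dT)
  list(delta_eps_r = -eps_r * model$alpha_eps * dTe,
       delta_sigma = sigma * model$alpha_sigma * dTe)
}

#' Hot-state dielectric map for a temperature field
#'
#' Applies [delta_dp()] per cell and per frequency. Background cells are
#' never modified: heating is confined to tissue.
#'
#' @param dmap cold `dielectric_map`.
#' @param field a `temperature_field` on the same grid.
#' @param model a [thermo_model()].
#' @param tissue optional `tissue_map` providing the background mask; when
#'   omitted, cells whose rise is zero are unchanged anyway.
#' @return hot `dielectric_map`.
#' @export
heated_dielectric_map <- function(dmap, field, model = thermo_model(),
                                  tissue = NULL) {
  if (!identical(dim(field$T), c(dmap$grid$n, dmap$grid$n)) &&
      !all(dim(field$T) == dmap$grid$n))
    stop("temperature grid does not match the dielectric map grid")
  dT <- field$T - field$baseline_T
  if (!is.null(tissue)) dT[!breast_mask(tissue)] <- 0
  dTe <- effective_dT(model, dT)
  nf <- dmap$freqs$n
  scale_eps <- 1 - model$alpha_eps * dTe
  scale_sig <- 1 + model$alpha_sigma * dTe
  eps_r <- dmap$eps_r * array(scale_eps, dim = dim(dmap$eps_r))
  sigma <- dmap$sigma * array(scale_sig, dim = dim(dmap$sigma))
  new_dielectric_map(dmap$grid, dmap$freqs, dmap$medium, eps_r, sigma)
}

#' Temperature rise from dielectric change (linear model inverse)
#'
#' Inverts the linear coupling per cell: `dT = -delta_eps_r/(alpha_eps
#' eps_r)` from the permittivity channel or `dT = delta_sigma/(alpha_sigma
#' sigma)` from the conductivity channel (the stronger effect, the
#' default). Cells whose reference DP is near zero are flagged invalid
#' (`NA` rise, `valid = FALSE`) rather than propagating infinities.
#'
#' @param delta_eps_r,delta_sigma observed DP changes (either may be
#'   `NULL` if the other channel is used).
#' @param eps_r,sigma reference (cold) DPs.
#' @param model a linear [thermo_model()].
#' @param channel `"sigma"`, `"eps"`, or `"mean"` (average of the two).
#' @param ref_tol references with magnitude below `ref_tol` are invalid.
#' @return list with `dT` (same shape, `NA` where invalid) and `valid`
#'   (logical).
#' @export
temperature_from_dp <- function(delta_eps_r = NULL, delta_sigma = NULL,
                                eps_r = NULL, sigma = NULL,
                                model = thermo_model(),
                                channel = c("sigma", "eps", "mean"),
                                ref_tol = 1e-6) {
  channel <- match.arg(channel)
  if (model$kind != "linear")
    stop("temperature inversion is defined for the linear model")
  inv_one <- function(delta, ref, alpha, sign) {
    valid <- is.finite(ref) & abs(ref) > ref_tol
    dT <- rep(NA_real_, length(ref))
    dT[valid] <- sign * delta[valid] / (alpha * ref[valid])
    list(dT = dT, valid = valid)
  }
  pick <- function(need_e, need_s) {
    if (need_e && (is.null(delta_eps_r) || is.null(eps_r)))
      stop("permittivity channel requested but delta_eps_r/eps_r missing")
    if (need_s && (is.null(delta_sigma) || is.null(sigma)))
      stop("conductivity channel requested but delta_sigma/sigma missing")
  }
  shape <- dim(delta_sigma %||% delta_eps_r)
  if (channel == "sigma") {
    pick(FALSE, TRUE)
    r <- inv_one(delta_sigma, sigma, model$alpha_sigma, +1)
  } else if (channel == "eps") {
    pick(TRUE, FALSE)
    r <- inv_one(delta_eps_r, eps_r, model$alpha_eps, -1)
  } else {
    pick(TRUE, TRUE)
    re <- inv_one(delta_eps_r, eps_r, model$alpha_eps, -1)
    rs <- inv_one(delta_sigma, sigma, model$alpha_sigma, +1)
    valid <- re$valid | rs$valid
    dT <- rowMeans(cbind(re$dT, rs$dT), na.rm = TRUE)
    dT[!valid] <- NA_real_
    r <- list(dT = dT, valid = valid)
  }
  if (!is.null(shape)) {
    dim(r$dT) <- shape
    dim(r$valid) <- shape
  }
  r
}
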