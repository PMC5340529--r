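# Demographic kernels of the two-season model. The exported functions
# validate their domains; the dot-prefixed versions are the unchecked,
# vectorized forms used inside the quadrature (they clamp z into the trait
# domain, where the distributions place negligible mass anyway).

.fec <- function(z, X0, Y1, p) {
  (p$phi1 + (p$phi2 * z)^4) *
    exp(-(p$phi3 + p$phi4 * z^4) * (X0 + p$phi5 * Y1 + p$phi6 * X0 * Y1))
}

.surv_raw <- function(z, Y0, L1, L2, p) {
  num <- 1 - z * (p$ups1 * L1 + p$ups2 * L2)
  inner <- if (identical(p$exp_parse, "exp_zv4")) {
    Y0 + p$ups3 * Y0 * z * exp(z * p$ups4)
  } else {
    Y0 + p$ups3 * Y0 * z * exp(z) * p$ups4
  }
  num / (1 + (z * inner / p$ups6)^p$ups5)
}

.surv <- function(z, Y0, L1, L2, p) {
  pmin(pmax(.surv_raw(z, Y0, L1, L2, p), 0), 1)
}

.check_z <- function(z, p) {
  if (!all(is.finite(z)))
    stop("body size z must be finite", call. = FALSE)
  if (any(z < p$zmin | z > p$zmax))
    stop(sprintf("body size z outside trait domain [%g, %g]", p$zmin, p$zmax),
         call. = FALSE)
  invisible(z)
}

#' Per-capita fecundity as a function of body size and density
#'
#' Evaluates
#' `f(z) = (phi1 + (phi2 z)^4) * exp(-(phi3 + phi4 z^4) (X0 + phi5 Y1 + phi6 X0 Y1))`:
#' fecundity rises steeply with body size `z` but is discounted by a density
#' load combining the current breeding-season-start abundance `X0`, the
#' previous generation's non-breeding-season-start abundance `Y1`
#' (a carry-over effect) and their interaction. Larger flies suffer a
#' stronger density discount (the `phi4 z^4` term), which is the fecundity
#' side of the seasonal fitness trade-off.
#'
#' @param z Body size (mg), within `[zmin, zmax]`; vectorized.
#' @param X0 Abundance at the current breeding-season start (>= 0).
#' @param Y1 Abundance at the previous non-breeding-season start (>= 0).
#' @param params An [model_params()] object.
#' @return Per-capita fecundity (offspring per individual), finite and >= 0.
#' @examples
#' p <- model_params()
#' fecundity_kernel(0, 0, 0, p)    # phi1 = 1.5
#' fecundity_kernel(0.5, 0, 0, p)  # 1.5 + (2.8 * 0.5)^4
#' @export
fecundity_kernel <- function(z, X0, Y1, params) {
  .check_z(z, params)
  if (!is.finite(X0) || X0 < 0 || !is.finite(Y1) || Y1 < 0)
    stop("abundances must be finite and >= 0", call. = FALSE)
  .fec(z, X0, Y1, params)
}

#' Non-breeding survival probability as a function of body size and density
#'
#' Evaluates the survival kernel
#' `s(z) = [1 - z (ups1 (X1+Y1) + ups2 (X2+Y2))] /
#'         [1 + (z (Y0 + ups3 Y0 z exp(z) ups4) / ups6)^ups5]`,
#' clamped to `[0, 1]`. The numerator is a delayed-density penalty (abundances
#' one and two generations back), the denominator a sharply nonlinear
#' interaction between current non-breeding density `Y0` and body size: at
#' high density large flies survive poorly, which is the viability side of
#' the seasonal trade-off. Lags are read from `state`: `Y0 = state$Y[1]`,
#' `X1 + Y1 = state$X[2] + state$Y[2]`, `X2 + Y2 = state$X[3] + state$Y[3]`
#' (the state as emitted by [breeding_update()], i.e. at the
#' non-breeding-season start).
#'
#' When the raw expression leaves `[0, 1]` (the numerator can go negative at
#' extreme size-density combinations) the value is clamped and the result
#' carries a `"clamped"` attribute with the number of clamped evaluations.
#'
#' @param z Body size (mg), within `[zmin, zmax]`; vectorized.
#' @param state A [pop_state()] at the non-breeding-season start.
#' @param params An [model_params()] object.
#' @return Survival probability in `[0, 1]`.
#' @examples
#' p <- model_params()
#' st <- pop_state(rep(0, 3), rep(0, 3), 0.3, 0.3, 0.3, 0.3)
#' survival_kernel(0.3, st, p) # 1 at zero density
#' @export
survival_kernel <- function(z, state, params) {
  .check_z(z, params)
  validate_pop_state(state)
  Y0 <- state$Y[1]
  L1 <- state$X[2] + state$Y[2]
  L2 <- state$X[3] + state$Y[3]
  raw <- .surv_raw(z, Y0, L1, L2, params)
  out <- pmin(pmax(raw, 0), 1)
  n_clamped <- sum(raw < 0 | raw > 1)
  if (n_clamped > 0) attr(out, "clamped") <- n_clamped
  out
}

#' Mean environmental effect of density on body size
#'
#' The average environmental deviation (mg) added to phenotypes after
#' development or residence at abundance `N`: `e(N) = -lam * N`, a linear
#' size deficit. With `lam = lamX` this is the developmental effect of
#' breeding-season density; with `lam = lamY` the (stronger) weight loss
#' driven by non-breeding-season density.
#'
#' @param N Abundance (>= 0); vectorized.
#' @param lam Non-negative slope (mg per individual).
#' @return `-lam * N` (<= 0).
#' @examples
#' env_effect_mean(400, 0.00025) # -0.1 mg
#' @export
env_effect_mean <- function(N, lam) {
  if (!all(is.finite(N)) || any(N < 0))
    stop("N must be finite and >= 0", call. = FALSE)
  if (!is.finite(lam) || lam < 0)
    stop("lam must be finite and >= 0", call. = FALSE)
  -lam * N
}
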