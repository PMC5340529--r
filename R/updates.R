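# Season-to-season integral updates. Quadrature is composite Simpson on
# uniform grids (trapezoid when the node count is even); the integrands are
# smooth on the closed trait domain, so n_grid = 201 resolves every quantity
# far below 1e-6 relative.

# The model's integrals are truncated to the trait domain by construction
# and every update normalizes by the truncated mass, so tail truncation is
# part of the model's definition. This guard only refuses to proceed when
# the majority of a distribution's mass leaves the domain (a runaway mean),
# which is never silent; the trait means themselves are separately required
# to stay inside [zmin, zmax].
.MASS_TOL <- 0.5

.quad_w <- function(n) {
  if (n %% 2 == 1) {
    w <- rep(c(2, 4), length.out = n)
    w[c(1, n)] <- 1
    w / 3
  } else {
    w <- rep(1, n)
    w[c(1, n)] <- 0.5
    w
  }
}

# Mean of g(z) over z ~ N(mu, var) truncated to the trait domain.
.mean_over_phenotype <- function(g, mu, var, p) {
  sdv <- sqrt(var)
  lost <- 1 - (stats::pnorm(p$zmax, mu, sdv) - stats::pnorm(p$zmin, mu, sdv))
  if (lost > .MASS_TOL)
    stop(sprintf(paste0("phenotype distribution (mean %.4g, sd %.4g) places ",
                        "%.3g of its mass outside the trait domain [%g, %g]"),
                 mu, sdv, lost, p$zmin, p$zmax), call. = FALSE)
  z <- seq(p$zmin, p$zmax, length.out = p$n_grid)
  w <- .quad_w(p$n_grid)
  d <- stats::dnorm(z, mu, sdv)
  sum(w * d * g(z)) / sum(w * d)
}

# Selection-weighted mean breeding value. The double integral runs over
# breeding value x in [zmin, zmax] and environmental deviation y in
# [zmin - x, zmax - x]; substituting the phenotype u = x + y turns the
# x-dependent inner limits into a fixed rectangle (x, u) in [zmin, zmax]^2
# with the smooth integrand N(x; b_mean, VA) N(u - x; e_mean, VE) kernel(u),
# which composite Simpson resolves to high order.
.selection_weighted_bv <- function(kernel, b_mean, e_mean, p) {
  if (p$VA == 0) return(b_mean)
  sdx <- sqrt(p$VA)
  sdy <- sqrt(p$VE)
  lost <- 1 - (stats::pnorm(p$zmax, b_mean, sdx) - stats::pnorm(p$zmin, b_mean, sdx))
  if (lost > .MASS_TOL)
    stop(sprintf(paste0("breeding-value distribution (mean %.4g, sd %.4g) places ",
                        "%.3g of its mass outside the trait domain [%g, %g]"),
                 b_mean, sdx, lost, p$zmin, p$zmax), call. = FALSE)
  x <- seq(p$zmin, p$zmax, length.out = p$n_grid)
  u <- x
  w <- .quad_w(p$n_grid)
  dx <- stats::dnorm(x, b_mean, sdx)
  Dy <- stats::dnorm(outer(u, x, "-"), e_mean, sdy) # [u, x]
  Ku <- kernel(u)
  W <- Dy * outer(w * Ku, w * dx)
  tot <- sum(W)
  if (!is.finite(tot) || tot <= 0)
    stop("selection-weighted quadrature mass vanished", call. = FALSE)
  sum(t(W) * x) / tot
}

# Mean phenotype as the domain-truncated mean of breeding value plus
# environmental deviation (the phenotype integrals are truncated to the
# trait domain just like every other integral of the model; away from the
# domain edges this is b_mean + e_mean to quadrature accuracy).
.phenotype_mean <- function(b_mean, e_mean, p) {
  if (p$VA == 0) {
    z <- seq(p$zmin, p$zmax, length.out = p$n_grid)
    w <- .quad_w(p$n_grid)
    d <- stats::dnorm(z, b_mean + e_mean, sqrt(p$VE))
    return(sum(w * d * z) / sum(w * d))
  }
  sdx <- sqrt(p$VA)
  sdy <- sqrt(p$VE)
  x <- seq(p$zmin, p$zmax, length.out = p$n_grid)
  y <- seq(e_mean - 8 * sdy, e_mean + 8 * sdy, length.out = p$n_grid)
  w <- .quad_w(p$n_grid)
  W <- outer(w * stats::dnorm(x, b_mean, sdx), w * stats::dnorm(y, e_mean, sdy))
  Z <- pmin(pmax(outer(x, y, "+"), p$zmin), p$zmax)
  sum(W * Z) / sum(W)
}

.check_trait_mean <- function(m, p, what) {
  if (!is.finite(m) || m < p$zmin || m > p$zmax)
    stop(sprintf("%s (%.4g) left the trait domain [%g, %g]", what, m, p$zmin, p$zmax),
         call. = FALSE)
  m
}

#' Breeding-season update: reproduction and fecundity selection
#'
#' Projects the state across one breeding season. The new non-breeding-start
#' abundance is the current breeding-start abundance times the mean per-capita
#' fecundity over the phenotype distribution `N(p_mean_X, VA + VE)`; the new
#' mean breeding value is the fecundity-weighted mean of the parental
#' breeding-value distribution (offspring inherit the selection-weighted
#' parental mean; variances are held constant); the new mean phenotype adds
#' the developmental environmental effect of breeding density,
#' `eX(X0) = -lamX * X0`. With a size-independent fecundity the mean breeding
#' value is conserved exactly; with fecundity increasing in size it rises
#' (fecundity selection for large flies).
#'
#' @param state A [pop_state()] whose `Y` lags have not yet been shifted for
#'   the current generation (so `state$Y[1]` is the previous generation's
#'   non-breeding-season start).
#' @param params An [model_params()] object.
#' @param fecundity_fn Optional replacement kernel, a function of `z` only
#'   (used by scenario variants and tests); defaults to the model kernel at
#'   the state's densities.
#' @return The updated `pop_state`: `Y` shifted with the new non-breeding
#'   start in slot 1, `b_mean_Y` and `p_mean_Y` replaced.
#' @seealso [nonbreeding_update()], [run_scenario()]
#' @export
breeding_update <- function(state, params, fecundity_fn = NULL) {
  validate_pop_state(state)
  X0 <- state$X[1]
  Y1 <- state$Y[1]
  if (X0 <= 0)
    stop("breeding_update requires X0 > 0 (population extinct)", call. = FALSE)
  fk <- if (is.null(fecundity_fn)) function(z) .fec(z, X0, Y1, params) else fecundity_fn
  fbar <- .mean_over_phenotype(fk, state$p_mean_X, params$VA + params$VE, params)
  Y0_new <- X0 * fbar
  b_new <- .selection_weighted_bv(fk, state$b_mean_X,
                                  state$p_mean_X - state$b_mean_X, params)
  p_new <- .phenotype_mean(b_new, env_effect_mean(X0, params$lamX), params)
  .check_trait_mean(b_new, params, "mean breeding value after breeding update")
  .check_trait_mean(p_new, params, "mean phenotype after breeding update")
  out <- state
  out$Y <- c(Y0_new, state$Y[1], state$Y[2])
  out$b_mean_Y <- b_new
  out$p_mean_Y <- p_new
  out
}

#' Non-breeding-season update: survival and viability selection
#'
#' Projects the state across one non-breeding season. The new breeding-start
#' abundance is the current non-breeding-start abundance times the mean
#' survival over the phenotype distribution `N(p_mean_Y, VA + VE)`; the new
#' mean breeding value is the survival-weighted mean of the breeding-value
#' distribution; the new mean phenotype adds the non-breeding environmental
#' effect `eY(Y0) = -lamY * Y0` (density-driven weight loss). With a
#' size-independent survival the mean breeding value is conserved exactly;
#' with survival decreasing in size it falls (viability selection for small
#' flies).
#'
#' @param state A [pop_state()] as emitted by [breeding_update()] (its `Y[1]`
#'   is the current non-breeding-season start).
#' @param params An [model_params()] object.
#' @param survival_fn Optional replacement kernel, a function of `z` only;
#'   defaults to the model kernel at the state's densities.
#' @param uniform_phenotype If `TRUE`, survival is evaluated once at the mean
#'   phenotype and applied to every individual, so no viability selection
#'   occurs and the mean breeding value is conserved exactly (the
#'   no-viability-selection and stop-selection rules).
#' @return The updated `pop_state`: `X` shifted with the new breeding start in
#'   slot 1, `b_mean_X` and `p_mean_X` replaced.
#' @export
nonbreeding_update <- function(state, params, survival_fn = NULL,
                               uniform_phenotype = FALSE) {
  validate_pop_state(state)
  Y0 <- state$Y[1]
  if (Y0 <= 0)
    stop("nonbreeding_update requires Y0 > 0 (population extinct)", call. = FALSE)
  L1 <- state$X[2] + state$Y[2]
  L2 <- state$X[3] + state$Y[3]
  sk <- if (is.null(survival_fn)) function(z) .surv(z, Y0, L1, L2, params) else survival_fn
  if (uniform_phenotype) {
    z0 <- min(max(state$p_mean_Y, params$zmin), params$zmax)
    sbar <- sk(z0)
    b_new <- state$b_mean_Y
  } else {
    sbar <- .mean_over_phenotype(sk, state$p_mean_Y, params$VA + params$VE, params)
    b_new <- .selection_weighted_bv(sk, state$b_mean_Y,
                                    state$p_mean_Y - state$b_mean_Y, params)
  }
  X0_new <- Y0 * sbar
  p_new <- .phenotype_mean(b_new, env_effect_mean(Y0, params$lamY), params)
  .check_trait_mean(b_new, params, "mean breeding value after non-breeding update")
  .check_trait_mean(p_new, params, "mean phenotype after non-breeding update")
  out <- state
  out$X <- c(X0_new, state$X[1], state$X[2])
  out$b_mean_X <- b_new
  out$p_mean_X <- p_new
  out
}
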