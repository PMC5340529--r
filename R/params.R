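#' Model parameters for the seasonal eco-evolutionary IPM
#'
#' Bundles every constant of the two-season integral projection model: the
#' six fecundity constants `phi1..phi6`, the six survival constants
#' `ups1..ups6`, the environmental-effect slopes `lamX` and `lamY` (mg of body
#' size lost per individual of density), the additive genetic and
#' environmental variances `VA` and `VE` (mg^2), the trait-domain bounds
#' `zmin`/`zmax` (mg) and the number of quadrature nodes per axis `n_grid`.
#'
#' The defaults are the calibrated values of the model: at zero density a
#' small fly produces `phi1 = 1.5` offspring, fecundity rises with the fourth
#' power of size scaled by `phi2`, and declines exponentially with a density
#' load made of current breeding density, the previous non-breeding density
#' (carry-over, `phi5`) and their interaction (`phi6`). Non-breeding survival
#' is penalized linearly in size times lagged density (`ups1`, `ups2`: one and
#' two generations back) and divided by a sharply nonlinear current-density
#' by size term shaped by `ups3..ups6`.
#'
#' @param phi1,phi2,phi3,phi4,phi5,phi6 Fecundity constants.
#' @param ups1,ups2,ups3,ups4,ups5,ups6 Survival constants.
#' @param lamX Environmental-effect slope of breeding-season density
#'   (mg per individual); sets the mean developmental size deficit of a cohort
#'   reared at breeding density N via eX(N) = -lamX * N.
#' @param lamY Environmental-effect slope of non-breeding-season density
#'   (mg per individual); sets the mean size deficit after a non-breeding
#'   season spent at density N via eY(N) = -lamY * N.
#' @param VA Additive genetic variance for body size (mg^2).
#' @param VE Environmental variance for body size (mg^2).
#' @param zmin,zmax Trait-domain bounds (mg) for all quadrature.
#' @param n_grid Number of quadrature nodes per axis (>= 3).
#' @param exp_parse Which reading of the survival interaction term to use:
#'   `"exp_z"` (default) multiplies `exp(z)` by `ups4`; `"exp_zv4"` uses
#'   `exp(z * ups4)`. The printed form of the model is typographically
#'   ambiguous here; both readings are retained and give the same qualitative
#'   dynamics.
#'
#' @return An object of class `ipm_params` (a named list).
#' @seealso [heritability()], [read_model_params()], [su_params()]
#' @examples
#' p <- model_params()
#' heritability(p) # 0.3
#' @export
model_params <- function(phi1 = 1.5, phi2 = 2.8, phi3 = 0.00007, phi4 = 0.04588,
                         phi5 = 1, phi6 = 0.001,
                         ups1 = 0.005, ups2 = 0.0026, ups3 = 0.7, ups4 = 0.7,
                         ups5 = 6, ups6 = 350,
                         lamX = 0.00001, lamY = 0.00025,
                         VA = 0.003, VE = 0.007,
                         zmin = 0, zmax = 1, n_grid = 201,
                         exp_parse = c("exp_z", "exp_zv4")) {
  p <- list(phi1 = phi1, phi2 = phi2, phi3 = phi3, phi4 = phi4,
            phi5 = phi5, phi6 = phi6,
            ups1 = ups1, ups2 = ups2, ups3 = ups3, ups4 = ups4,
            ups5 = ups5, ups6 = ups6,
            lamX = lamX, lamY = lamY, VA = VA, VE = VE,
            zmin = zmin, zmax = zmax, n_grid = as.integer(n_grid),
            exp_parse = match.arg(exp_parse))
  validate_model_params(p)
  structure(p, class = "ipm_params")
}

validate_model_params <- function(p) {
  num <- p[setdiff(names(p), "exp_parse")]
  if (!all(vapply(num, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                  logical(1)))) {
    stop("all model parameters must be finite numeric scalars", call. = FALSE)
  }
  if (p$VA < 0) stop("VA must be >= 0", call. = FALSE)
  if (p$VE <= 0) stop("VE must be > 0", call. = FALSE)
  if (p$zmin >= p$zmax) stop("zmin must be < zmax", call. = FALSE)
  if (p$n_grid < 3) stop("n_grid must be >= 3", call. = FALSE)
  h2 <- p$VA / (p$VA + p$VE)
  if (h2 < 0 || h2 > 1) stop("heritability VA/(VA+VE) must lie in [0,1]", call. = FALSE)
  invisible(p)
}

#' Narrow-sense heritability implied by the model variances
#'
#' @param params An [model_params()] object.
#' @return `VA / (VA + VE)`.
#' @export
heritability <- function(params) params$VA / (params$VA + params$VE)

#' @export
print.ipm_params <- function(x, ...) {
  cat("Seasonal IPM parameters\n")
  cat(sprintf("  fecundity phi1..phi6: %s\n",
              paste(signif(unlist(x[paste0("phi", 1:6)]), 5), collapse = ", ")))
  cat(sprintf("  survival  ups1..ups6: %s\n",
              paste(signif(unlist(x[paste0("ups", 1:6)]), 5), collapse = ", ")))
  cat(sprintf("  env slopes lamX = %g, lamY = %g mg/indiv\n", x$lamX, x$lamY))
  cat(sprintf("  VA = %g, VE = %g mg^2 (h2 = %.3g)\n", x$VA, x$VE, heritability(x)))
  cat(sprintf("  trait domain [%g, %g] mg, %d quadrature nodes\n",
              x$zmin, x$zmax, x$n_grid))
  invisible(x)
}

#' Read / write model parameters as a flat YAML file
#'
#' The file is a flat key-value mapping with keys named exactly
#' `phi1..phi6`, `ups1..ups6`, `lamX`, `lamY`, `VA`, `VE`, `zmin`, `zmax`,
#' `n_grid` (and optionally `exp_parse`). The packaged default file is at
#' `system.file("extdata", "default_params.yaml", package = "seasipm")`.
#'
#' @param path File path.
#' @return `read_model_params()` returns an `ipm_params` object;
#'   `write_model_params()` returns `path` invisibly.
#' @export
read_model_params <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(model_params, vals)
}

#' @rdname read_model_params
#' @param params An `ipm_params` object.
#' @export
write_model_params <- function(params, path) {
  vals <- unclass(params)
  vals$n_grid <- as.integer(vals$n_grid)
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' Parameters of the logistic non-breeding survival function
#'
#' The stop-selection survival rule is `Su(N) = 1 / (1 + (N / v)^w)`, where
#' `N` is abundance at the start of the non-breeding season, `v` is the
#' half-survival abundance (`Su(v) = 0.5`) and `w` is a dimensionless shape
#' exponent. The defaults are the values fitted to the long-term control
#' populations (v = 375.22 individuals, w = 1.83).
#'
#' @param v Half-survival abundance (individuals, > 0).
#' @param w Shape exponent (> 0).
#' @return An object of class `su_params`.
#' @seealso [logistic_survival()], [fit_logistic_survival()]
#' @export
su_params <- function(v = 375.22, w = 1.83) {
  if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
    stop("v must be a positive finite scalar", call. = FALSE)
  if (!is.numeric(w) || length(w) != 1 || !is.finite(w) || w <= 0)
    stop("w must be a positive finite scalar", call. = FALSE)
  structure(list(v = v, w = w), class = "su_params")
}
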