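# Viability-selection and density-dependence statistics: standardized
# selection differentials, Welch tests, nonlinear logistic survival fits and
# the mixed-model regressions of selection and of lagged density dependence.

#' Standardized linear selection differential for one population-generation
#'
#' Weights are standardized to mean zero and unit variance against the pooled
#' before + after distribution of the population-generation (so S is in
#' within-generation phenotypic standard deviations, the conventional unit of
#' a linear selection differential); S is the standardized mean after the
#' non-breeding season minus the standardized mean before. With `pool =
#' "global"` the standardization instead uses a caller-supplied mean and sd
#' (e.g. of the whole experiment).
#'
#' @param weight Numeric vector of female dry weights (mg, > 0).
#' @param stage Character/factor vector, `"before"` or `"after"` the
#'   non-breeding season, same length as `weight`; at least 2 weights per
#'   stage.
#' @param pool `"within"` (default) or `"global"`.
#' @param center,scale Mean and sd used when `pool = "global"`.
#' @return The selection differential S (standardized units).
#' @examples
#' selection_differential(c(1, 2, 3, 1, 2, 3),
#'                        rep(c("before", "after"), each = 3)) # 0
#' @export
selection_differential <- function(weight, stage, pool = c("within", "global"),
                                   center = NULL, scale = NULL) {
  pool <- match.arg(pool)
  stage <- as.character(stage)
  if (length(weight) != length(stage))
    stop("weight and stage must have equal length", call. = FALSE)
  if (!all(stage %in% c("before", "after")))
    stop("stage must be 'before' or 'after'", call. = FALSE)
  nb <- sum(stage == "before")
  na <- sum(stage == "after")
  if (nb < 2 || na < 2)
    stop("need at least 2 weights in each stage", call. = FALSE)
  if (pool == "within") {
    center <- mean(weight)
    scale <- stats::sd(weight)
  } else if (is.null(center) || is.null(scale)) {
    stop("pool = 'global' requires center and scale", call. = FALSE)
  }
  if (scale == 0) return(0)
  z <- (weight - center) / scale
  mean(z[stage == "after"]) - mean(z[stage == "before"])
}

#' Welch two-sample t test on dry weights
#'
#' `t = (mean(after) - mean(before)) / sqrt(s2a/na + s2b/nb)` with
#' Welch-Satterthwaite degrees of freedom and a two-sided p value.
#'
#' @param before,after Numeric vectors (>= 2 values each; at least one group
#'   with positive variance).
#' @return List with `t`, `df`, `p`.
#' @export
welch_t <- function(before, after) {
  nb <- length(before); na <- length(after)
  if (nb < 2 || na < 2) stop("need >= 2 values per group", call. = FALSE)
  vb <- stats::var(before); va <- stats::var(after)
  if (vb == 0 && va == 0)
    stop("both groups have zero variance", call. = FALSE)
  se2 <- va / na + vb / nb
  t <- (mean(after) - mean(before)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Fit the logistic non-breeding survival function
#'
#' Nonlinear least squares of observed survival fractions on
#' `Su(N) = 1 / (1 + (N / v)^w)` via `stats::nls`, returning
#' point estimates and standard errors for the half-survival abundance `v`
#' and shape exponent `w`.
#'
#' @param data Data frame with columns `N` (non-breeding-start abundance),
#'   `survivors` and `total` (or a precomputed `survival` fraction). Needs at
#'   least 3 distinct values of `N`; `survivors` must not exceed `total`.
#' @param start Optional named list of starting values `v`, `w`.
#' @return Object of class `logistic_survival_fit`: list with `v`, `w`,
#'   `se_v`, `se_w`, `converged` and the underlying `nls` fit.
#' @examples
#' N <- seq(50, 700, by = 50)
#' d <- data.frame(N = N, survivors = round(1000 / (1 + (N / 375.22)^1.83)),
#'                 total = 1000)
#' fit_logistic_survival(d)$v
#' @export
fit_logistic_survival <- function(data, start = NULL) {
  if (!("survival" %in% names(data))) {
    if (!all(c("N", "survivors", "total") %in% names(data)))
      stop("data needs columns N, survivors, total (or N, survival)", call. = FALSE)
    if (any(data$survivors > data$total))
      stop("survivors exceed total", call. = FALSE)
    data$survival <- data$survivors / data$total
  }
  if (any(data$survival > 1 | data$survival < 0))
    stop("survival fractions must lie in [0, 1]", call. = FALSE)
  if (length(unique(data$N)) < 3)
    stop("need at least 3 distinct abundances", call. = FALSE)
  if (is.null(start)) {
    i <- which.min(abs(data$survival - 0.5))
    v0 <- max(data$N[i], 1)
    start <- list(v = v0, w = 2)
  }
  fit <- stats::nls(survival ~ 1 / (1 + (N / v)^w), data = data, start = start,
                    control = stats::nls.control(maxiter = 500, scaleOffset = 1,
                                                 tol = 1e-9))
  sm <- summary(fit)
  est <- sm$coefficients
  structure(list(v = est["v", "Estimate"], w = est["w", "Estimate"],
                 se_v = est["v", "Std. Error"], se_w = est["w", "Std. Error"],
                 converged = fit$convInfo$isConv, fit = fit),
            class = "logistic_survival_fit")
}

#' @export
print.logistic_survival_fit <- function(x, ...) {
  cat(sprintf("Logistic survival fit: v = %.2f (se %.3g), w = %.3f (se %.3g)%s\n",
              x$v, x$se_v, x$w, x$se_w,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

# Coefficient table from an lmerTest (Satterthwaite) or lm summary.
.coef_table <- function(fit) {
  sm <- summary(fit)$coefficients
  if (ncol(sm) == 4) { # lm: no df column
    df <- stats::df.residual(fit)
    out <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                      df = df, t = sm[, 3], p = sm[, 4])
  } else {
    out <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                      se = sm[, "Std. Error"], df = sm[, "df"],
                      t = sm[, "t value"], p = sm[, "Pr(>|t|)"])
  }
  rownames(out) <- NULL
  out
}

# Nakagawa-style marginal / conditional variance explained for a
# random-intercept lmer fit.
.r2_lmm <- function(fit) {
  var_f <- stats::var(as.numeric(stats::model.matrix(fit) %*% lme4::fixef(fit)))
  vc <- lme4::VarCorr(fit)
  var_r <- sum(vapply(vc, function(m) m[1, 1], numeric(1)))
  var_e <- attr(vc, "sc")^2
  tot <- var_f + var_r + var_e
  c(R2m = var_f / tot, R2c = (var_f + var_r) / tot)
}

#' Selection differential as a function of non-breeding density
#'
#' Linear mixed model with the per-population-generation selection
#' differential `S` as response, abundance at the non-breeding-season start
#' (`N_nb`) as fixed effect and population as random intercept; a
#' significantly negative slope is the diagnostic of density-dependent
#' viability selection. p values use the Satterthwaite approximation. With a
#' single population (or if the mixed fit is singular) the model collapses to
#' ordinary least squares with a warning.
#'
#' @param records Data frame with columns `population`, `S`, `N_nb`
#'   (>= 10 rows).
#' @return List with `coefficients` (term/estimate/se/df/t/p), `R2m`, `R2c`
#'   and the fitted `model`.
#' @export
fit_selection_density_model <- function(records) {
  stopifnot(all(c("population", "S", "N_nb") %in% names(records)))
  if (nrow(records) < 10)
    stop("need at least 10 selection records", call. = FALSE)
  if (length(unique(records$population)) < 2) {
    warning("single population: falling back to ordinary least squares")
    fit <- stats::lm(S ~ N_nb, data = records)
    return(list(coefficients = .coef_table(fit), R2m = summary(fit)$r.squared,
                R2c = summary(fit)$r.squared, model = fit))
  }
  fit <- tryCatch(lmerTest::lmer(S ~ N_nb + (1 | population), data = records),
                  error = function(e) NULL)
  if (is.null(fit) || lme4::isSingular(fit)) {
    message("degenerate mixed fit (singular or zero random-intercept variance); refitting as OLS")
    ols <- stats::lm(S ~ N_nb, data = records)
    return(list(coefficients = .coef_table(ols), R2m = summary(ols)$r.squared,
                R2c = summary(ols)$r.squared, model = ols))
  }
  r2 <- .r2_lmm(fit)
  list(coefficients = .coef_table(fit), R2m = unname(r2["R2m"]),
       R2c = unname(r2["R2c"]), model = fit)
}

# Standardize a predictor to mean 0, sd 1.
.std <- function(x) (x - mean(x)) / stats::sd(x)

# Log-transform a rate, offsetting exact zeros by half the smallest
# positive value.
.log_rate <- function(x) {
  if (any(x < 0)) stop("negative rates", call. = FALSE)
  if (any(x == 0)) {
    off <- min(x[x > 0]) / 2
    x[x == 0] <- off
  }
  log(x)
}

#' Lagged density-dependence models for fecundity and survival
#'
#' Reconstructs per-population per-generation fecundity (breeding-season end
#' count over start count) and non-breeding survival (non-breeding end over
#' start) from a long abundance table, then fits two linear mixed models with
#' population as random intercept, log-transformed responses and
#' standardized predictors:
#' \itemize{
#'   \item fecundity ~ B + NB + B:NB, where B is the current
#'     breeding-season-start abundance and NB the previous generation's
#'     non-breeding-season-start abundance (carry-over);
#'   \item survival ~ NB + B1 + NB1 + B2 + NB2, current non-breeding density
#'     plus the four season-start abundances one and two generations back.
#' }
#' Significant lag coefficients in the survival model are the signature of
#' delayed density dependence.
#'
#' @param abundance Data frame with columns `population`, `generation`,
#'   `season` (`"breeding"`/`"nonbreeding"`), `boundary` (`"start"`/`"end"`)
#'   and `count`. Needs >= 3 generations for the two-generation lags.
#' @return List with `fecundity` and `survival` coefficient tables
#'   (term/estimate/se/df/t/p), their `R2` summaries, and the model frames.
#' @export
fit_delayed_density_models <- function(abundance) {
  need <- c("population", "generation", "season", "boundary", "count")
  stopifnot(all(need %in% names(abundance)))
  abundance$key <- paste(abundance$season, abundance$boundary, sep = "_")
  wide <- stats::reshape(abundance[, c("population", "generation", "key", "count")],
                         idvar = c("population", "generation"),
                         timevar = "key", direction = "wide", v.names = "count")
  names(wide) <- sub("^count\\.", "", names(wide))
  need_cols <- c("breeding_start", "breeding_end", "nonbreeding_start",
                 "nonbreeding_end")
  if (!all(need_cols %in% names(wide)))
    stop("abundance table must cover both seasons at start and end", call. = FALSE)
  wide <- wide[order(wide$population, wide$generation), ]
  if (max(table(wide$population)) < 3)
    stop("need at least 3 generations per population for two-generation lags",
         call. = FALSE)

  wide <- do.call(rbind, lapply(split(wide, wide$population), function(d) {
    d <- d[order(d$generation), ]
    d$NB_prev <- c(NA, utils::head(d$nonbreeding_start, -1))
    d$B1 <- c(NA, utils::head(d$breeding_start, -1))
    d$NB1 <- d$NB_prev
    d$B2 <- c(NA, NA, utils::head(d$breeding_start, -2))
    d$NB2 <- c(NA, NA, utils::head(d$nonbreeding_start, -2))
    d
  }))
  rownames(wide) <- NULL

  fec <- wide[stats::complete.cases(wide[, c("breeding_start", "breeding_end",
                                             "NB_prev")]) &
                wide$breeding_start > 0, ]
  fec$resp <- .log_rate(fec$breeding_end / fec$breeding_start)
  fec$B <- .std(fec$breeding_start)
  fec$NB <- .std(fec$NB_prev)

  sur <- wide[stats::complete.cases(wide[, c("nonbreeding_start", "nonbreeding_end",
                                             "B1", "NB1", "B2", "NB2")]) &
                wide$nonbreeding_start > 0, ]
  sur$resp <- .log_rate(sur$nonbreeding_end / sur$nonbreeding_start)
  sur$NB <- .std(sur$nonbreeding_start)
  for (cc in c("B1", "NB1", "B2", "NB2")) sur[[cc]] <- .std(sur[[cc]])

  fit_one <- function(formula_lmm, formula_ols, data) {
    if (length(unique(data$population)) < 2) {
      warning("single population: falling back to ordinary least squares")
      fit <- stats::lm(formula_ols, data = data)
      return(list(coefficients = .coef_table(fit),
                  R2 = c(R2m = summary(fit)$r.squared,
                         R2c = summary(fit)$r.squared), model = fit))
    }
    fit <- tryCatch(lmerTest::lmer(formula_lmm, data = data),
                    error = function(e) NULL)
    if (is.null(fit) || lme4::isSingular(fit)) {
      message("degenerate mixed fit (singular or zero random-intercept variance); refitting as OLS")
      fit2 <- stats::lm(formula_ols, data = data)
      return(list(coefficients = .coef_table(fit2),
                  R2 = c(R2m = summary(fit2)$r.squared,
                         R2c = summary(fit2)$r.squared), model = fit2))
    }
    list(coefficients = .coef_table(fit), R2 = .r2_lmm(fit), model = fit)
  }

  f <- fit_one(resp ~ B * NB + (1 | population), resp ~ B * NB, fec)
  s <- fit_one(resp ~ NB + B1 + NB1 + B2 + NB2 + (1 | population),
               resp ~ NB + B1 + NB1 + B2 + NB2, sur)
  list(fecundity = f$coefficients, survival = s$coefficients,
       fecundity_R2 = f$R2, survival_R2 = s$R2,
       fecundity_model = f$model, survival_model = s$model,
       fecundity_data = fec, survival_data = sur)
}

#' Per-population-generation selection records from weight samples
#'
#' Builds the [fit_selection_density_model()] input from a long weight table
#' and a survival table: one selection differential per population-generation
#' with both stages sampled (>= 2 weights each), paired with the abundance at
#' the non-breeding-season start.
#'
#' @param weights Data frame with columns `population`, `generation`, `stage`
#'   (`"before"`/`"after"`), `weight_mg`.
#' @param survival Data frame with columns `population`, `generation`, `N`
#'   (non-breeding-start abundance).
#' @return Data frame with columns `population`, `generation`, `S`, `N_nb`.
#' @export
selection_records <- function(weights, survival) {
  stopifnot(all(c("population", "generation", "stage", "weight_mg") %in%
                  names(weights)),
            all(c("population", "generation", "N") %in% names(survival)))
  keys <- unique(weights[, c("population", "generation")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    w <- weights[weights$population == keys$population[i] &
                   weights$generation == keys$generation[i], ]
    if (sum(w$stage == "before") < 2 || sum(w$stage == "after") < 2) return(NULL)
    nrow_s <- survival$population == keys$population[i] &
      survival$generation == keys$generation[i]
    if (!any(nrow_s)) return(NULL)
    data.frame(population = keys$population[i], generation = keys$generation[i],
               S = selection_differential(w$weight_mg, w$stage),
               N_nb = survival$N[which(nrow_s)[1]])
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(out) <- NULL
  out
}
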