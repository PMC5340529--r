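# Individual-based generator of experiment-shaped data: replicate fly
# populations cycled between a breeding and a non-breeding season, with
# female dry weights subsampled before and after the non-breeding season.
# The demographic rules reuse the IPM kernels so that the generated data
# carry the statistical structure the analyses assume.

#' Configuration of a synthetic seasonal fly experiment
#'
#' @param n_populations Number of replicate populations (default 45).
#' @param n_generations Number of generations (default 58).
#' @param n_initial Founding adults per population (default 10, sex ratio
#'   1:1).
#' @param trait_mean Mean founding breeding value (mg, default 0.36 to match
#'   the calibrated model state).
#' @param params An [model_params()] object; supplies the fecundity and
#'   survival kernels, VA, VE and the environmental-effect slopes.
#' @param su An [su_params()] object; the logistic survival rule used when
#'   viability selection is off.
#' @param viability_selection If `TRUE` (default) non-breeding survival is
#'   the size-and-density kernel applied per individual; if `FALSE` survivor
#'   numbers follow [logistic_survival()] of current density and survivors
#'   are drawn without regard to size (the stop-selection treatment).
#' @param weigh_fraction Fraction of the population whose females are dried
#'   and weighed at each stage (default 0.05).
#' @param weight_resolution Weighing resolution in mg (default 0.001).
#' @param survival_noise `"binomial"` (default): survivor counts under the
#'   logistic rule are Binomial(N, Su(N)); `"deterministic"`:
#'   `round(Su(N) * N)`.
#' @param seed Integer seed consumed at the start of a generation run.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(n_populations = 45, n_generations = 58,
                              n_initial = 10, trait_mean = 0.36,
                              params = model_params(), su = su_params(),
                              viability_selection = TRUE,
                              weigh_fraction = 0.05, weight_resolution = 0.001,
                              survival_noise = c("binomial", "deterministic"),
                              seed = 1L) {
  stopifnot(n_populations >= 1, n_generations >= 1, n_initial >= 2,
            weigh_fraction > 0, weigh_fraction <= 1, weight_resolution > 0)
  structure(list(n_populations = as.integer(n_populations),
                 n_generations = as.integer(n_generations),
                 n_initial = as.integer(n_initial), trait_mean = trait_mean,
                 params = params, su = su,
                 viability_selection = isTRUE(viability_selection),
                 weigh_fraction = weigh_fraction,
                 weight_resolution = weight_resolution,
                 survival_noise = match.arg(survival_noise),
                 seed = seed),
            class = "experiment_config")
}

# One breeding season for a data frame of adults (columns bv, phen, sex).
# Each female produces Poisson(2 * f(z_female)) offspring and each offspring's
# sire is drawn from the males with probability proportional to f(z_male)
# (size-dependent siring success), so the per-capita output of every
# individual scales with its own fecundity kernel and the selection response
# on breeding values is the full cov(bv, f)/fbar of the one-sex kernel - a
# random sire would dilute it by half. Offspring breeding value = mid-parent
# + N(0, VA/2) segregation deviate; phenotype = breeding value +
# N(eX(X0), VE); both are truncated into the trait domain (a fly cannot have
# a non-positive dry weight). Returns the offspring data frame with a
# `midparent_phen` column for heritability checks.
.breed <- function(adults, X0, Y1, p) {
  females <- adults[adults$sex == "F", , drop = FALSE]
  males <- adults[adults$sex == "M", , drop = FALSE]
  if (nrow(females) == 0 || nrow(males) == 0) return(NULL)
  fphen <- pmin(pmax(females$phen, p$zmin), p$zmax)
  mphen <- pmin(pmax(males$phen, p$zmin), p$zmax)
  n_off <- stats::rpois(nrow(females), 2 * .fec(fphen, X0, Y1, p))
  tot <- sum(n_off)
  if (tot == 0) return(NULL)
  sire_w <- .fec(mphen, X0, Y1, p)
  if (sum(sire_w) <= 0) sire_w <- rep(1, nrow(males))
  sire <- sample.int(nrow(males), tot, replace = TRUE, prob = sire_w)
  mother <- rep(seq_len(nrow(females)), n_off)
  mid_bv <- (females$bv[mother] + males$bv[sire]) / 2
  mid_phen <- (females$phen[mother] + males$phen[sire]) / 2
  bv <- mid_bv + stats::rnorm(tot, 0, sqrt(p$VA / 2))
  phen <- bv + stats::rnorm(tot, env_effect_mean(X0, p$lamX), sqrt(p$VE))
  data.frame(bv = pmin(pmax(bv, p$zmin), p$zmax),
             phen = pmin(pmax(phen, p$zmin), p$zmax),
             sex = ifelse(stats::runif(tot) < 0.5, "F", "M"),
             midparent_phen = mid_phen)
}

# Weigh a without-replacement female subsample, rounded to resolution.
.weigh <- function(pop, gen, stage, flies, frac, res, shift = 0) {
  females <- flies[flies$sex == "F", , drop = FALSE]
  n <- min(nrow(females), max(0L, round(frac * nrow(flies))))
  if (n == 0) return(NULL)
  idx <- sample.int(nrow(females), n)
  w <- round((females$phen[idx] + shift) / res) * res
  data.frame(population = pop, generation = gen, stage = stage,
             weight_mg = pmax(w, res))
}

#' Generate a synthetic seasonal fly experiment
#'
#' Simulates `n_populations` replicate populations for `n_generations`
#' generations of a breeding season (density-dependent, size-dependent
#' Poisson reproduction with additive-genetic inheritance) followed by a
#' non-breeding season (density- and size-dependent Bernoulli survival when
#' viability selection is on; logistic density-only survivor counts drawn
#' without regard to size when it is off). Female dry weights are recorded
#' for a `weigh_fraction` subsample at the start and end of each non-breeding
#' season, rounded to `weight_resolution` mg; weights recorded after a
#' food-limited (selection-on) non-breeding season include the density-driven
#' weight loss `eY(N) = -lamY * N`.
#'
#' Runs are fully reproducible under `config$seed`. If every population goes
#' extinct the partial tables are returned with attribute `truncated = TRUE`
#' and a warning.
#'
#' @param config An [experiment_config()].
#' @return List of class `fly_experiment` with data frames
#'   \describe{
#'     \item{`abundance`}{`population`, `generation`, `season`, `boundary`,
#'       `count` — both seasons at start and end.}
#'     \item{`weights`}{`population`, `generation`, `stage`, `weight_mg`.}
#'     \item{`survival`}{`population`, `generation`, `N` (non-breeding
#'       start), `survivors`.}
#'   }
#' @examples
#' cfg <- experiment_config(n_populations = 2, n_generations = 5, seed = 42)
#' ex <- generate_experiment(cfg)
#' head(ex$abundance)
#' @export
generate_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  p <- config$params
  if (!is.null(config$seed)) set.seed(config$seed)
  ab <- list(); wt <- list(); sv <- list()
  k <- 0L
  for (pop in seq_len(config$n_populations)) {
    nf <- ceiling(config$n_initial / 2)
    nm <- config$n_initial - nf
    bv <- stats::rnorm(config$n_initial, config$trait_mean, sqrt(p$VA))
    adults <- data.frame(bv = bv,
                         phen = bv + stats::rnorm(config$n_initial, 0, sqrt(p$VE)),
                         sex = rep(c("F", "M"), c(nf, nm)))
    Y1 <- 0; lagB1 <- 0; lagNB1 <- 0; lagB2 <- 0; lagNB2 <- 0
    for (gen in seq_len(config$n_generations)) {
      X0 <- nrow(adults)
      k <- k + 1L
      ab[[k]] <- data.frame(population = pop, generation = gen,
                            season = "breeding", boundary = "start", count = X0)
      offspring <- .breed(adults, X0, Y1, p)
      N <- if (is.null(offspring)) 0L else nrow(offspring)
      k <- k + 1L
      ab[[k]] <- data.frame(population = pop, generation = gen,
                            season = "breeding", boundary = "end", count = N)
      k <- k + 1L
      ab[[k]] <- data.frame(population = pop, generation = gen,
                            season = "nonbreeding", boundary = "start", count = N)
      if (N == 0) break
      w <- .weigh(pop, gen, "before", offspring, config$weigh_fraction,
                  config$weight_resolution)
      if (!is.null(w)) wt[[length(wt) + 1L]] <- w
      if (config$viability_selection) {
        zp <- pmin(pmax(offspring$phen, p$zmin), p$zmax)
        pr <- .surv(zp, N, lagB1 + lagNB1, lagB2 + lagNB2, p)
        alive <- stats::runif(N) < pr
        shift <- env_effect_mean(N, p$lamY)
      } else {
        su_frac <- logistic_survival(N, config$su)
        n_surv <- if (config$survival_noise == "binomial") {
          stats::rbinom(1, N, su_frac)
        } else {
          round(su_frac * N)
        }
        alive <- rep(FALSE, N)
        if (n_surv > 0) alive[sample.int(N, n_surv)] <- TRUE
        shift <- 0
      }
      survivors <- offspring[alive, , drop = FALSE]
      k <- k + 1L
      ab[[k]] <- data.frame(population = pop, generation = gen,
                            season = "nonbreeding", boundary = "end",
                            count = nrow(survivors))
      sv[[length(sv) + 1L]] <- data.frame(population = pop, generation = gen,
                                          N = N, survivors = nrow(survivors))
      if (nrow(survivors) > 0) {
        w <- .weigh(pop, gen, "after", survivors, config$weigh_fraction,
                    config$weight_resolution, shift = shift)
        if (!is.null(w)) wt[[length(wt) + 1L]] <- w
      }
      if (nrow(survivors) == 0) break
      lagB2 <- lagB1; lagNB2 <- lagNB1
      lagB1 <- X0; lagNB1 <- N
      Y1 <- N
      adults <- survivors[, c("bv", "phen", "sex")]
    }
  }
  abundance <- do.call(rbind, ab)
  weights <- do.call(rbind, wt)
  survival <- do.call(rbind, sv)
  rownames(abundance) <- rownames(weights) <- rownames(survival) <- NULL
  full_len <- config$n_populations * config$n_generations
  truncated <- nrow(survival) < full_len ||
    any(survival$survivors == 0)
  if (truncated && all(tapply(survival$survivors, survival$population,
                              function(x) utils::tail(x, 1)) == 0))
    warning("all populations went extinct; returning partial tables")
  structure(list(abundance = abundance, weights = weights, survival = survival),
            class = "fly_experiment", truncated = truncated)
}

#' Emulate the stop-selection experiment
#'
#' Identical breeding mechanics to [generate_experiment()], but non-breeding
#' survivor numbers follow the logistic density-only rule [logistic_survival()]
#' and survivors are drawn uniformly at random without regard to body size:
#' no viability selection, no density-driven weight loss, and no lagged
#' density effects on survival, by construction.
#'
#' @param config An [experiment_config()]; its `viability_selection` field is
#'   forced to `FALSE`.
#' @return Same table list as [generate_experiment()].
#' @export
emulate_stop_selection <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  config$viability_selection <- FALSE
  generate_experiment(config)
}
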