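#' Logistic density-dependent non-breeding survival
#'
#' The size-independent survival rule of the stop-selection regime:
#' `Su(N) = 1 / (1 + (N / v)^w)`. `Su(0) = 1`, `Su(v) = 0.5` exactly, and the
#' function is strictly decreasing in `N`.
#'
#' @param N Abundance at the non-breeding-season start (>= 0); vectorized.
#' @param su An [su_params()] object.
#' @return Survival fraction in `(0, 1]`.
#' @examples
#' logistic_survival(375.22, su_params()) # 0.5
#' @export
logistic_survival <- function(N, su) {
  if (!inherits(su, "su_params")) su <- do.call(su_params, as.list(su)[c("v", "w")])
  if (!all(is.finite(N)) || any(N < 0))
    stop("N must be finite and >= 0", call. = FALSE)
  1 / (1 + (N / su$v)^su$w)
}

#' Define a simulation scenario
#'
#' The five scenario variants of the model:
#' \describe{
#'   \item{`full`}{all terms active: fecundity and viability selection, direct
#'     and delayed density dependence.}
#'   \item{`stop_selection`}{full rules up to `switch_generation`, then
#'     survival becomes the logistic [logistic_survival()] of current density
#'     applied with every individual assigned the mean phenotype (no viability
#'     selection, no survival lags) and the carry-over parameters `phi5`,
#'     `phi6` are reduced by 25\%.}
#'   \item{`no_viability`}{survival is evaluated at the mean phenotype
#'     (size-independent) but keeps its delayed density terms; fecundity
#'     selection is retained.}
#'   \item{`no_delay`}{`ups1 = ups2 = phi5 = phi6 = 0`: no delayed density
#'     dependence or carry-over, viability selection retained.}
#'   \item{`low_h2`}{`VA` rescaled so that the heritability equals `h2`
#'     (default 1e-5) with the total phenotypic variance `VA + VE` held
#'     fixed; all else as `full`.}
#' }
#'
#' @param name One of `"full"`, `"stop_selection"`, `"no_viability"`,
#'   `"no_delay"`, `"low_h2"`.
#' @param n_generations Number of generations to simulate (>= 1).
#' @param switch_generation Generation after which stop-selection rules apply
#'   (required for `stop_selection`; must be < `n_generations`).
#' @param initial_state A [pop_state()]; defaults to the packaged
#'   [calibrated_initial_state()].
#' @param h2 Target heritability for `low_h2`.
#' @param seed Optional integer, stored for provenance (the engine is
#'   deterministic, so it is never consumed).
#' @return An object of class `ipm_scenario`.
#' @export
scenario <- function(name = c("full", "stop_selection", "no_viability",
                              "no_delay", "low_h2"),
                     n_generations = 40, switch_generation = NULL,
                     initial_state = calibrated_initial_state(),
                     h2 = 1e-5, seed = NULL) {
  name <- match.arg(name)
  if (!is.numeric(n_generations) || n_generations < 1)
    stop("n_generations must be >= 1", call. = FALSE)
  if (name == "stop_selection") {
    if (is.null(switch_generation))
      stop("stop_selection requires switch_generation", call. = FALSE)
    if (switch_generation >= n_generations)
      stop("switch_generation must be < n_generations", call. = FALSE)
  }
  validate_pop_state(initial_state)
  structure(list(name = name, n_generations = as.integer(n_generations),
                 switch_generation = if (is.null(switch_generation)) NULL
                                     else as.integer(switch_generation),
                 initial_state = initial_state, h2 = h2, seed = seed),
            class = "ipm_scenario")
}

.scenario_params <- function(scn, params) {
  p <- params
  if (scn$name == "no_delay") {
    p$ups1 <- 0; p$ups2 <- 0; p$phi5 <- 0; p$phi6 <- 0
  }
  if (scn$name == "low_h2") {
    VP <- p$VA + p$VE
    p$VA <- scn$h2 * VP
    p$VE <- VP - p$VA
  }
  p
}

#' Run a multi-generation scenario
#'
#' Alternates [breeding_update()] and [nonbreeding_update()] under the rules
#' of the scenario, recording one row per generation: the breeding-season
#' start (`X0`, `b_mean_X`, `p_mean_X`) and the non-breeding-season start
#' (`Y0`, `b_mean_Y`, `p_mean_Y`). The run terminates as soon as a
#' season-start abundance drops below one individual; the trajectory then
#' carries `crashed = TRUE` and the crash generation (the earlier season of a
#' generation wins ties). The engine is fully deterministic: identical inputs
#' give bit-identical trajectories.
#'
#' @param scn An [scenario()] object.
#' @param params An [model_params()] object.
#' @param su An [su_params()] object (used only by the stop-selection phase).
#' @return A `data.frame` of class `ipm_trajectory` with columns
#'   `generation`, `X0`, `Y0`, `b_mean_X`, `b_mean_Y`, `p_mean_X`, `p_mean_Y`
#'   and attributes `crashed`, `crash_generation`, `scenario` and
#'   `clamp_events` (generations in which the raw survival expression was
#'   clamped into `[0, 1]`).
#' @examples
#' traj <- run_scenario(scenario("no_viability"), model_params())
#' attr(traj, "crash_generation") # 10
#' @export
run_scenario <- function(scn, params = model_params(), su = su_params()) {
  stopifnot(inherits(scn, "ipm_scenario"))
  p <- .scenario_params(scn, params)
  st <- scn$initial_state
  n <- scn$n_generations
  rows <- vector("list", n)
  crash <- NA_integer_
  clamp_gens <- integer(0)
  for (g in seq_len(n)) {
    if (st$X[1] < 1) {
      rows[[g]] <- data.frame(generation = g, X0 = st$X[1], Y0 = NA_real_,
                              b_mean_X = st$b_mean_X, b_mean_Y = NA_real_,
                              p_mean_X = st$p_mean_X, p_mean_Y = NA_real_)
      crash <- g
      break
    }
    stop_phase <- scn$name == "stop_selection" && !is.null(scn$switch_generation) &&
      g > scn$switch_generation
    pg <- p
    if (stop_phase) {
      pg$phi5 <- 0.75 * p$phi5
      pg$phi6 <- 0.75 * p$phi6
    }
    X0_entry <- st$X[1]
    bX_entry <- st$b_mean_X
    pX_entry <- st$p_mean_X
    st <- breeding_update(st, pg)
    rows[[g]] <- data.frame(generation = g, X0 = X0_entry, Y0 = st$Y[1],
                            b_mean_X = bX_entry, b_mean_Y = st$b_mean_Y,
                            p_mean_X = pX_entry, p_mean_Y = st$p_mean_Y)
    if (st$Y[1] < 1) {
      crash <- g
      break
    }
    if (stop_phase) {
      Y0 <- st$Y[1]
      st <- nonbreeding_update(st, pg,
                               survival_fn = function(z) logistic_survival(Y0, su),
                               uniform_phenotype = TRUE)
    } else if (scn$name == "no_viability") {
      st <- nonbreeding_update(st, pg, uniform_phenotype = TRUE)
    } else {
      raw <- .surv_raw(seq(pg$zmin, pg$zmax, length.out = pg$n_grid),
                       st$Y[1], st$X[2] + st$Y[2], st$X[3] + st$Y[3], pg)
      if (any(raw < 0 | raw > 1)) clamp_gens <- c(clamp_gens, g)
      st <- nonbreeding_update(st, pg)
    }
    if (!all(is.finite(c(st$X[1], st$b_mean_X, st$p_mean_X))))
      stop(sprintf("non-finite state at generation %d (non-breeding season)", g),
           call. = FALSE)
  }
  traj <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(traj) <- NULL
  structure(traj,
            class = c("ipm_trajectory", "data.frame"),
            crashed = !is.na(crash),
            crash_generation = crash,
            scenario = scn$name,
            clamp_events = clamp_gens)
}

#' Locate a population crash in a trajectory
#'
#' @param traj An `ipm_trajectory` (or any data frame with `generation`,
#'   `X0`, `Y0` columns).
#' @return The first generation at which either season-start abundance is
#'   below 1 (the breeding season, coming first, wins ties), or
#'   `NA_integer_` if the population never crashes.
#' @export
detect_crash <- function(traj) {
  if (nrow(traj) == 0) stop("empty trajectory", call. = FALSE)
  bad <- (!is.na(traj$X0) & traj$X0 < 1) | (!is.na(traj$Y0) & traj$Y0 < 1)
  if (!any(bad)) return(NA_integer_)
  as.integer(traj$generation[which(bad)[1]])
}

#' @export
print.ipm_trajectory <- function(x, ...) {
  cat(sprintf("IPM trajectory: scenario '%s', %d generation(s)\n",
              attr(x, "scenario"), nrow(x)))
  if (isTRUE(attr(x, "crashed")))
    cat(sprintf("  population crashed (size < 1) at generation %d\n",
                attr(x, "crash_generation")))
  ce <- attr(x, "clamp_events")
  if (length(ce))
    cat(sprintf("  survival clamped into [0,1] in %d generation(s)\n", length(ce)))
  print.data.frame(utils::head(as.data.frame(x), 8), ...)
  if (nrow(x) > 8) cat(sprintf("  ... %d more rows\n", nrow(x) - 8))
  invisible(x)
}
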