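# Documentation of multigenerational cycles: burn-in exclusion, linear
# detrending, autocorrelation, and a formal oscillatory-decay classifier.

#' Remove burn-in and a linear trend from a seasonal series
#'
#' Drops the first `burn_in` generations (to avoid transients caused by the
#' initial population size) and subtracts the fitted values of an ordinary
#' least-squares regression of the remaining values on their time index. The
#' output has mean ~0 and zero OLS slope on its index.
#'
#' @param values Numeric series (abundance or trait mean per step), no
#'   missing values.
#' @param burn_in Number of generations to drop from the front (default 3).
#' @param steps_per_generation 1 for one value per generation (model series),
#'   2 for interleaved breeding/non-breeding experimental series.
#' @return Numeric vector of detrended residuals, length
#'   `length(values) - burn_in * steps_per_generation`.
#' @export
detrend_series <- function(values, burn_in = 3, steps_per_generation = 1) {
  if (anyNA(values)) stop("series contains missing values", call. = FALSE)
  drop <- burn_in * steps_per_generation
  if (length(values) <= drop + 2)
    stop(sprintf("series too short: %d values, %d dropped as burn-in",
                 length(values), drop), call. = FALSE)
  x <- values[-seq_len(drop)]
  idx <- seq_along(x)
  unname(stats::resid(stats::lm(x ~ idx)))
}

#' Sample autocorrelation function with a white-noise confidence bound
#'
#' Standard biased-normalized sample ACF (autocovariances divided by `n`,
#' then by the lag-0 autocovariance, which keeps every estimate in
#' `[-1, 1]`), with the usual two-sided white-noise bound `1.96 / sqrt(n)`.
#'
#' @param values A (detrended) numeric series.
#' @param max_lag Largest lag; defaults to `min(floor(n/2) - 1, 20)` and must
#'   be below `n/2`.
#' @return An object of class `acf_result`: list with `lags` (0..max_lag),
#'   `rho`, `conf` and `n`.
#' @export
autocorrelation <- function(values, max_lag = NULL) {
  n <- length(values)
  if (n < 8) stop("need at least 8 values for ACF estimation", call. = FALSE)
  if (stats::var(values) == 0)
    stop("zero-variance series: ACF undefined", call. = FALSE)
  if (is.null(max_lag)) max_lag <- min(floor(n / 2) - 1, 20)
  if (max_lag >= n / 2) stop("max_lag must be < length/2", call. = FALSE)
  rho <- as.numeric(stats::acf(values, lag.max = max_lag, plot = FALSE,
                               demean = TRUE)$acf)
  structure(list(lags = 0:max_lag, rho = rho, conf = 1.96 / sqrt(n), n = n),
            class = "acf_result")
}

#' Classify a correlogram as cycling or not
#'
#' A series is classified as cycling when its ACF shows an oscillatory decay
#' to zero: some lag with a significantly negative autocorrelation (below
#' `-conf`) followed at a larger lag by a significantly positive one (above
#' `+conf`). The period estimate is the lag of the first significant positive
#' peak after the first significant trough; ties break toward the smaller
#' lag. Monotone positive decay (e.g. an AR(1) with positive coefficient) and
#' white noise are classified as non-cycling.
#'
#' @param acf An [autocorrelation()] result.
#' @return List with `cycling` (logical) and `period_estimate` (steps, or
#'   `NA` when not cycling).
#' @export
classify_cycling <- function(acf) {
  stopifnot(inherits(acf, "acf_result"))
  lags <- acf$lags[-1]
  rho <- acf$rho[-1]
  trough <- lags[rho < -acf$conf]
  sig_pos <- lags[rho > acf$conf]
  if (length(trough)) {
    after <- sig_pos[sig_pos > trough[1]]
    if (length(after)) {
      # the period is the first significant positive *peak*: a local maximum
      # of the correlogram (edge lags count as peaks on their open side)
      full <- acf$rho
      is_peak <- vapply(after, function(k) {
        i <- k + 1L # rho is indexed from lag 0
        left <- i == 2L || full[i] >= full[i - 1L]
        right <- i == length(full) || full[i] >= full[i + 1L]
        left && right
      }, logical(1))
      period <- if (any(is_peak)) after[which(is_peak)[1]] else after[1]
      return(list(cycling = TRUE, period_estimate = period))
    }
  }
  list(cycling = FALSE, period_estimate = NA_integer_)
}

#' Full cycle-documentation pipeline for one series
#'
#' Convenience wrapper: burn-in removal and detrending via
#' [detrend_series()], ACF via [autocorrelation()], classification via
#' [classify_cycling()].
#'
#' @inheritParams detrend_series
#' @inheritParams autocorrelation
#' @return List with `detrended`, `acf`, `cycling`, `period_estimate`.
#' @examples
#' traj <- run_scenario(scenario("full", n_generations = 40))
#' cycle_stats(traj$X0)$cycling
#' @export
cycle_stats <- function(values, burn_in = 3, steps_per_generation = 1,
                        max_lag = NULL) {
  d <- detrend_series(values, burn_in, steps_per_generation)
  a <- autocorrelation(d, max_lag)
  cls <- classify_cycling(a)
  list(detrended = d, acf = a,
       cycling = cls$cycling, period_estimate = cls$period_estimate)
}
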