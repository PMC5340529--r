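# Shared fixtures: parameter sets and population states used across files.

p_default <- model_params()

# Drop trajectory bookkeeping attributes so value-level comparisons between
# scenarios are possible.
strip_traj <- function(tr) {
  d <- as.data.frame(tr)
  attributes(d) <- attributes(d)[c("names", "row.names", "class")]
  rownames(d) <- NULL
  d
}

# A state in the cycling regime (the calibrated starting point).
state_calibrated <- function() {
  pop_state(X = rep(94, 3), Y = rep(94, 3),
            b_mean_X = 0.36, b_mean_Y = 0.36,
            p_mean_X = 0.36, p_mean_Y = 0.36)
}

# Assorted mid-trajectory states for oracle comparisons.
oracle_states <- list(
  pop_state(X = c(94, 94, 94), Y = c(180, 94, 94), 0.36, 0.365, 0.36, 0.362),
  pop_state(X = c(50, 100, 80), Y = c(120, 90, 150), 0.30, 0.31, 0.28, 0.30),
  pop_state(X = c(30, 40, 90), Y = c(60, 110, 70), 0.26, 0.27, 0.24, 0.26),
  pop_state(X = c(110, 60, 45), Y = c(200, 130, 80), 0.33, 0.34, 0.31, 0.33),
  pop_state(X = c(70, 85, 100), Y = c(90, 160, 140), 0.29, 0.30, 0.27, 0.29)
)

# Monte-Carlo oracles. The model's integrals are truncated to the trait
# domain, so samples falling outside it are rejected: the abundance update
# averages the kernel over phenotypes z ~ N(p_mean, VA + VE) restricted to
# [zmin, zmax]; the breeding-value update weights breeding values x by
# kernel(x + y) over the joint (x, y) distribution restricted to x and
# x + y inside the domain.
mc_season <- function(kernel, b_mean, p_mean, params, n, seed) {
  set.seed(seed)
  z1 <- rnorm(n, p_mean, sqrt(params$VA + params$VE))
  z1 <- z1[z1 >= params$zmin & z1 <= params$zmax]
  r <- kernel(z1)
  x <- rnorm(n, b_mean, sqrt(params$VA))
  y <- rnorm(n, p_mean - b_mean, sqrt(params$VE))
  keep <- x >= params$zmin & x <= params$zmax &
    (x + y) >= params$zmin & (x + y) <= params$zmax
  x <- x[keep]
  wk <- kernel(x + y[keep])
  mu_b <- sum(wk * x) / sum(wk)
  list(rate = mean(r), rate_se = sd(r) / sqrt(length(r)),
       b = mu_b, b_se = sqrt(sum((wk * (x - mu_b))^2)) / sum(wk))
}

mc_nonbreeding <- function(state, params, n = 1e6, seed = 1) {
  kern <- function(z) seasipm:::.surv(z, state$Y[1], state$X[2] + state$Y[2],
                                      state$X[3] + state$Y[3], params)
  mc <- mc_season(kern, state$b_mean_Y, state$p_mean_Y, params, n, seed)
  list(X0 = state$Y[1] * mc$rate, X0_se = state$Y[1] * mc$rate_se,
       b = mc$b, b_se = mc$b_se)
}

mc_breeding <- function(state, params, n = 1e6, seed = 1) {
  kern <- function(z) seasipm:::.fec(z, state$X[1], state$Y[1], params)
  mc <- mc_season(kern, state$b_mean_X, state$p_mean_X, params, n, seed)
  list(Y0 = state$X[1] * mc$rate, Y0_se = state$X[1] * mc$rate_se,
       b = mc$b, b_se = mc$b_se)
}
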