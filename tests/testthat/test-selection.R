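test_that("selection differential: definition, null case and affine invariance", {
  set.seed(21)
  w_before <- rnorm(40, 0.38, 0.04)
  w_after <- rnorm(25, 0.28, 0.04)
  w <- c(w_before, w_after)
  stage <- rep(c("before", "after"), c(40, 25))
  S <- selection_differential(w, stage)
  # hand recomputation on the pooled standardization
  z <- (w - mean(w)) / sd(w)
  expect_equal(S, mean(z[stage == "after"]) - mean(z[stage == "before"]))
  # the differential is the after-mean minus before-mean in pooled sd units,
  # e.g. standardized stage means of 0.577 and -0.566 give S = -1.143
  expect_equal(round(-0.566 - 0.577, 3), -1.143)
  expect_lt(S, 0)

  # identical stages: no selection
  expect_equal(selection_differential(c(1, 2, 3, 1, 2, 3),
                                      rep(c("before", "after"), each = 3)), 0)
  # invariant to affine rescaling of the raw weights
  expect_equal(selection_differential(1000 * w + 3, stage), S, tolerance = 1e-12)
  expect_error(selection_differential(w_before, rep("before", 40)), "each stage")
})

test_that("Welch t statistic, df and p match hand computation and stats::t.test", {
  # t is signed as mean(after) - mean(before): a weight decline across the
  # non-breeding season gives a negative statistic
  res <- welch_t(before = c(2, 3, 4), after = c(1, 2, 3))
  expect_equal(res$t, -1 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(res$t, -1.2247, tolerance = 1e-4)
  expect_equal(res$df, 4, tolerance = 1e-12)

  same <- welch_t(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  set.seed(33)
  for (i in 1:20) {
    a <- rnorm(5 + i, sd = runif(1, 0.5, 2))
    b <- rnorm(8 + i, sd = runif(1, 0.5, 2))
    ours <- welch_t(b, a)
    ref <- t.test(a, b)
    expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-12)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  }
  # equal sizes and variances: Welch equals the pooled-variance test
  a <- c(1, 2, 3, 4); b <- a + 1
  expect_equal(welch_t(b, a)$t,
               unname(t.test(a, b, var.equal = TRUE)$statistic),
               tolerance = 1e-9)
  expect_error(welch_t(c(1, 1, 1), c(2)), "2 values")
  expect_error(welch_t(c(1, 1, 1), c(2, 2, 2)), "zero variance")
})

test_that("logistic survival fit recovers noiseless parameters and is scale-consistent", {
  su <- su_params(v = 375.22, w = 1.83)
  N <- seq(50, 700, by = 50)
  d <- data.frame(N = N, survival = logistic_survival(N, su))
  fit <- fit_logistic_survival(d)
  expect_true(fit$converged)
  expect_equal(fit$v, su$v, tolerance = 1e-6)
  expect_equal(fit$w, su$w, tolerance = 1e-6)
  # fitted curve passes through 0.5 at N = v
  expect_equal(logistic_survival(fit$v, su_params(fit$v, fit$w)), 0.5)
  # multiplying all N by c multiplies v-hat by c and leaves w-hat unchanged
  d2 <- data.frame(N = 3 * N, survival = d$survival)
  fit2 <- fit_logistic_survival(d2)
  expect_equal(fit2$v, 3 * fit$v, tolerance = 1e-6)
  expect_equal(fit2$w, fit$w, tolerance = 1e-6)

  expect_error(fit_logistic_survival(data.frame(N = c(1, 2), survival = c(1, 0.5))),
               "3 distinct")
  expect_error(fit_logistic_survival(data.frame(N = 1:5, survivors = 6:10,
                                                total = rep(8, 5))),
               "exceed")
})

test_that("logistic fit recovers truth from binomial survivor counts within 3 se", {
  su <- su_params()
  set.seed(55)
  N <- rep(round(seq(30, 650, length.out = 45)), times = 10)
  d <- data.frame(N = N, total = N,
                  survivors = rbinom(length(N), N, logistic_survival(N, su)))
  fit <- fit_logistic_survival(d)
  expect_true(fit$converged)
  expect_lt(abs(fit$v - su$v), 3 * fit$se_v)
  expect_lt(abs(fit$w - su$w), 3 * fit$se_w)
})

test_that("selection-on-density mixed model recovers a built-in slope", {
  set.seed(77)
  n_pop <- 25; n_gen <- 38
  pop <- rep(seq_len(n_pop), each = n_gen)
  N_nb <- runif(n_pop * n_gen, 50, 400)
  pop_eff <- rnorm(n_pop, 0, 0.05)[pop]
  S <- -0.18 - 0.004 * N_nb + pop_eff + rnorm(n_pop * n_gen, 0, 0.15)
  rec <- data.frame(population = pop, S = S, N_nb = N_nb)
  m <- fit_selection_density_model(rec)
  slope <- m$coefficients[m$coefficients$term == "N_nb", ]
  expect_lt(abs(slope$estimate - (-0.004)), 3 * slope$se)
  expect_lt(slope$p, 0.05)
  expect_true(m$R2c >= m$R2m)
})

test_that("selection-on-density model is null-calibrated and degenerates sensibly", {
  # S independent of density: slope non-significant in >= 90% of seeds
  hits <- vapply(1:10, function(s) {
    set.seed(400 + s)
    pop <- rep(1:10, each = 20)
    rec <- data.frame(population = pop,
                      S = rnorm(200, -0.2, 0.1) + rnorm(10, 0, 0.05)[pop],
                      N_nb = runif(200, 50, 400))
    m <- fit_selection_density_model(rec)
    m$coefficients$p[m$coefficients$term == "N_nb"] < 0.05
  }, logical(1))
  expect_gte(mean(!hits), 0.9)

  # all records identical S: slope exactly 0
  rec0 <- data.frame(population = rep(1:5, each = 4), S = -0.3,
                     N_nb = rep(c(100, 200, 300, 400), 5))
  m0 <- suppressMessages(suppressWarnings(fit_selection_density_model(rec0)))
  expect_equal(m0$coefficients$estimate[m0$coefficients$term == "N_nb"], 0)

  # single population: ordinary regression with a warning
  rec1 <- data.frame(population = 1, S = rnorm(20), N_nb = runif(20, 10, 100))
  expect_warning(fit_selection_density_model(rec1), "single population")
})

test_that("delayed-density models recover generator truth and standardize predictors", {
  # synthetic abundance tables with a known negative current-NB effect on
  # survival and no lag effects; fecundity with known B effect
  make_tables <- function(seed) {
    set.seed(seed)
    rows <- list(); k <- 0
    for (pop in 1:15) {
      for (gen in 1:25) {
        # exogenous breeding density each generation so that lagged densities
        # carry no signal by construction
        B <- round(runif(1, 60, 250))
        fec <- exp(0.45 - 0.003 * B + rnorm(1, 0, 0.05))
        NB <- max(round(B * fec), 1)
        surv <- min(exp(-0.2 - 0.0015 * NB + rnorm(1, 0, 0.05)), 1)
        B_next <- max(round(NB * surv), 2)
        rows[[k + 1]] <- data.frame(population = pop, generation = gen,
                                    season = "breeding",
                                    boundary = c("start", "end"),
                                    count = c(B, NB))
        rows[[k + 2]] <- data.frame(population = pop, generation = gen,
                                    season = "nonbreeding",
                                    boundary = c("start", "end"),
                                    count = c(NB, B_next))
        k <- k + 2
      }
    }
    do.call(rbind, rows)
  }
  ab <- make_tables(91)
  res <- suppressMessages(fit_delayed_density_models(ab))

  # predictors standardized to mean 0, sd 1
  for (cc in c("NB", "B1", "NB1", "B2", "NB2")) {
    expect_lt(abs(mean(res$survival_data[[cc]])), 1e-10)
    expect_equal(sd(res$survival_data[[cc]]), 1)
  }

  # current-density effect on survival recovered (on the standardized scale)
  sNB <- res$survival[res$survival$term == "NB", ]
  truth <- -0.0015 * sd(res$survival_data$nonbreeding_start)
  expect_lt(abs(sNB$estimate - truth), 3 * sNB$se)
  expect_lt(sNB$p, 0.001)

  # fecundity B effect negative and significant
  fB <- res$fecundity[res$fecundity$term == "B", ]
  expect_lt(fB$estimate, 0)
  expect_lt(fB$p, 0.001)

  # no built-in lag effects: all four lag terms jointly non-significant at
  # the 1% level in >= 90% of seeds
  hits <- vapply(1:10, function(s) {
    r <- suppressMessages(fit_delayed_density_models(make_tables(500 + s)))
    any(r$survival$p[r$survival$term %in% c("B1", "NB1", "B2", "NB2")] < 0.01)
  }, logical(1))
  expect_gte(mean(!hits), 0.9)

  expect_error(fit_delayed_density_models(ab[ab$generation <= 2, ]),
               "3 generations")
})
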