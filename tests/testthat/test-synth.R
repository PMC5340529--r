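test_that("experiment tables are schema-complete and reproducible under a seed", {
  cfg <- experiment_config(n_populations = 3, n_generations = 8, seed = 12)
  ex1 <- generate_experiment(cfg)
  ex2 <- generate_experiment(cfg)
  expect_identical(ex1, ex2)
  expect_named(ex1, c("abundance", "weights", "survival"))
  expect_named(ex1$abundance, c("population", "generation", "season",
                                "boundary", "count"))
  expect_named(ex1$weights, c("population", "generation", "stage", "weight_mg"))
  expect_named(ex1$survival, c("population", "generation", "N", "survivors"))
  expect_true(all(ex1$weights$weight_mg > 0))
  expect_true(all(ex1$survival$survivors <= ex1$survival$N))
  # weights respect the microbalance resolution
  expect_equal(ex1$weights$weight_mg, round(ex1$weights$weight_mg, 3))
})

test_that("stop-selection emulation: no selection differential, logistic survivor counts", {
  cfg <- experiment_config(n_populations = 12, n_generations = 20, seed = 5)
  ex <- emulate_stop_selection(cfg)
  rec <- selection_records(ex$weights, ex$survival)
  # mean S within 3 standard errors of zero
  se <- sd(rec$S) / sqrt(nrow(rec))
  expect_lt(abs(mean(rec$S)), 3 * se)

  # survivor fraction near the configured half-survival abundance is ~0.5
  near_v <- ex$survival[abs(ex$survival$N - cfg$su$v) < 100, ]
  expect_gt(nrow(near_v), 5)
  frac <- sum(near_v$survivors) / sum(near_v$N)
  expect_lt(abs(frac - logistic_survival(mean(near_v$N), cfg$su)),
            3 * sqrt(0.25 / sum(near_v$N)) + 0.02)

  # deterministic survivor rule: count = round(Su(N) * N), and survivor
  # counts equal N wherever Su rounds to 1
  cfg_d <- experiment_config(n_populations = 4, n_generations = 10, seed = 6,
                             survival_noise = "deterministic")
  exd <- emulate_stop_selection(cfg_d)
  expect_equal(exd$survival$survivors,
               round(logistic_survival(exd$survival$N, cfg_d$su) * exd$survival$N))
  low <- exd$survival[logistic_survival(exd$survival$N, cfg_d$su) > 0.995, ]
  if (nrow(low) > 0) expect_equal(low$survivors, low$N)
})

test_that("uniform survivor sampling leaves the breeding-value mean unchanged", {
  cfg <- experiment_config(n_populations = 10, n_generations = 12, seed = 9)
  ex <- emulate_stop_selection(cfg)
  # S-on-density slope is null by construction
  rec <- selection_records(ex$weights, ex$survival)
  m <- suppressMessages(suppressWarnings(fit_selection_density_model(rec)))
  expect_gt(m$coefficients$p[m$coefficients$term == "N_nb"], 0.05)
})

test_that("viability selection on: negative S, density-dependent selection slope", {
  cfg <- experiment_config(n_populations = 15, n_generations = 25, seed = 3)
  ex <- generate_experiment(cfg)
  rec <- selection_records(ex$weights, ex$survival)
  expect_lt(mean(rec$S), 0)
  m <- fit_selection_density_model(rec)
  slope <- m$coefficients[m$coefficients$term == "N_nb", ]
  expect_lt(slope$estimate, 0)
  expect_lt(slope$p, 0.05)
})

test_that("stop-selection survival shows no lagged density dependence", {
  hits <- vapply(1:5, function(s) {
    cfg <- experiment_config(n_populations = 12, n_generations = 20,
                             seed = 700 + s)
    ex <- emulate_stop_selection(cfg)
    r <- suppressMessages(fit_delayed_density_models(ex$abundance))
    any(r$survival$p[r$survival$term %in% c("B1", "NB1", "B2", "NB2")] < 0.05)
  }, logical(1))
  expect_gte(mean(!hits), 0.8)
})

test_that("realized heritability matches VA/(VA+VE) in the breeding mechanics", {
  p <- p_default
  set.seed(42)
  n <- 4000
  bv <- rnorm(n, 0.36, sqrt(p$VA))
  adults <- data.frame(bv = bv, phen = bv + rnorm(n, 0, sqrt(p$VE)),
                       sex = rep(c("F", "M"), n / 2))
  off <- seasipm:::.breed(adults, X0 = 5, Y1 = 0, p) # low density: ~no selection
  fit <- lm(off$phen ~ off$midparent_phen)
  h2_hat <- coef(fit)[2]
  se <- summary(fit)$coefficients[2, 2]
  expect_lt(abs(h2_hat - heritability(p)), 3 * se)
})

test_that("calibration realism: survival in 0.6-0.8 and weights in 0.2-0.4 mg", {
  cfg <- experiment_config(n_populations = 12, n_generations = 58, seed = 7)
  ex <- generate_experiment(cfg)
  expect_gt(mean(ex$survival$survivors / ex$survival$N), 0.6)
  expect_lt(mean(ex$survival$survivors / ex$survival$N), 0.8)
  expect_gt(mean(ex$weights$weight_mg), 0.2)
  expect_lt(mean(ex$weights$weight_mg), 0.4)
})

test_that("pipeline closure: generated tables feed every analysis unchanged", {
  cfg <- experiment_config(n_populations = 10, n_generations = 18, seed = 13)
  ex <- generate_experiment(cfg)
  # selection stats
  rec <- selection_records(ex$weights, ex$survival)
  expect_true(nrow(rec) >= 10)
  expect_s3_class(fit_selection_density_model(rec)$coefficients, "data.frame")
  # delayed-density models
  dd <- suppressMessages(fit_delayed_density_models(ex$abundance))
  expect_true(all(c("NB", "B1", "NB1", "B2", "NB2") %in% dd$survival$term))
  # cycle stats on the replicate-mean abundance series
  nb <- ex$abundance[ex$abundance$season == "nonbreeding" &
                       ex$abundance$boundary == "start", ]
  series <- aggregate(count ~ generation, nb, mean)$count
  cs <- cycle_stats(series)
  expect_type(cs$cycling, "logical")
  # Welch test on the pooled weights runs
  wt <- welch_t(ex$weights$weight_mg[ex$weights$stage == "before"],
                ex$weights$weight_mg[ex$weights$stage == "after"])
  expect_true(is.finite(wt$p))
})
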