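test_that("selection-free limits: constant kernels conserve the mean breeding value", {
  # at the domain centre the truncation is symmetric, so conservation under a
  # constant kernel is exact to quadrature tolerance
  st <- pop_state(rep(94, 3), rep(94, 3), 0.5, 0.5, 0.5, 0.5)
  up <- breeding_update(st, p_default, fecundity_fn = function(z) rep(2, length(z)))
  expect_equal(up$Y[1], 2 * st$X[1], tolerance = 1e-8)
  expect_equal(up$b_mean_Y, st$b_mean_X, tolerance = 1e-8)

  # survival forced to 1: X0 = Y0, b conserved (the selection-free limit)
  dn <- nonbreeding_update(st, p_default, survival_fn = function(z) z^0)
  expect_equal(dn$X[1], st$Y[1], tolerance = 1e-8)
  expect_equal(dn$b_mean_X, st$b_mean_Y, tolerance = 1e-8)

  # off-centre, the domain truncation leaves only a tail-mass-sized residue
  stc <- state_calibrated()
  upc <- breeding_update(stc, p_default, fecundity_fn = function(z) rep(2, length(z)))
  expect_equal(upc$Y[1], 2 * stc$X[1], tolerance = 1e-8)
  expect_equal(upc$b_mean_Y, stc$b_mean_X, tolerance = 1e-4)

  # and the kernel itself is 1 when every density is zero (all ups = 0)
  p0 <- model_params(ups1 = 0, ups2 = 0, ups3 = 0)
  zero_state <- pop_state(c(10, 0, 0), c(0, 0, 0), 0.3, 0.3, 0.3, 0.3)
  expect_equal(survival_kernel(0.4, zero_state, p0), 1)
})

test_that("opposing selection: breeding raises and non-breeding lowers the mean breeding value", {
  st <- state_calibrated()
  up <- breeding_update(st, p_default)
  expect_gt(up$b_mean_Y, st$b_mean_X)
  # crowded non-breeding season: viability selection for small size
  crowded <- pop_state(c(94, 94, 94), c(250, 120, 100), 0.36, 0.365, 0.36, 0.362)
  dn <- nonbreeding_update(crowded, p_default)
  expect_lt(dn$b_mean_X, crowded$b_mean_Y)
  # and the abundance update is a survivorship: X0 <= Y0
  expect_lte(dn$X[1], crowded$Y[1])
})

test_that("updates agree with an individual-based Monte-Carlo oracle on 5 states", {
  for (i in seq_along(oracle_states)) {
    st <- oracle_states[[i]]
    mc <- mc_nonbreeding(st, p_default, n = 1e6, seed = 100 + i)
    dn <- nonbreeding_update(st, p_default)
    expect_lt(abs(dn$X[1] - mc$X0), 3 * mc$X0_se)
    expect_lt(abs(dn$b_mean_X - mc$b), 3 * mc$b_se)

    mcb <- mc_breeding(st, p_default, n = 1e6, seed = 200 + i)
    up <- breeding_update(st, p_default)
    expect_lt(abs(up$Y[1] - mcb$Y0), 3 * mcb$Y0_se)
    expect_lt(abs(up$b_mean_Y - mcb$b), 3 * mcb$b_se)
  }
})

test_that("doubling the quadrature grid changes nothing beyond 1e-6 relative", {
  p1 <- model_params(n_grid = 201)
  p2 <- model_params(n_grid = 401)
  st <- oracle_states[[2]]
  u1 <- breeding_update(st, p1); u2 <- breeding_update(st, p2)
  d1 <- nonbreeding_update(st, p1); d2 <- nonbreeding_update(st, p2)
  rel <- function(a, b) abs(a - b) / pmax(abs(b), 1e-12)
  expect_lt(rel(u1$Y[1], u2$Y[1]), 1e-6)
  expect_lt(rel(u1$b_mean_Y, u2$b_mean_Y), 1e-6)
  expect_lt(rel(u1$p_mean_Y, u2$p_mean_Y), 1e-6)
  expect_lt(rel(d1$X[1], d2$X[1]), 1e-6)
  expect_lt(rel(d1$b_mean_X, d2$b_mean_X), 1e-6)
  expect_lt(rel(d1$p_mean_X, d2$p_mean_X), 1e-6)
})

test_that("updates refuse extinct populations and runaway trait distributions", {
  st <- state_calibrated()
  st$X[1] <- 0
  expect_error(breeding_update(st, p_default), "extinct")
  st2 <- state_calibrated()
  st2$Y[1] <- 0
  expect_error(nonbreeding_update(st2, p_default), "extinct")
  # a distribution centred far outside the domain is an error, never silent
  st3 <- pop_state(rep(94, 3), rep(94, 3), 0.36, 0.36, -0.9, 0.36)
  expect_error(breeding_update(st3, p_default), "mass outside")
})

test_that("lag bookkeeping: updates shift their own season's lag vector", {
  st <- state_calibrated()
  up <- breeding_update(st, p_default)
  expect_equal(up$Y[2:3], st$Y[1:2]) # old Y0 becomes Y1
  expect_equal(up$X, st$X)           # X untouched by the breeding season
  dn <- nonbreeding_update(up, p_default)
  expect_equal(dn$X[2:3], up$X[1:2])
  expect_equal(dn$Y, up$Y)
})
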