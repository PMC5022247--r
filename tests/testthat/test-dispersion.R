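test_that("moment estimates match the mean-variance relation and clamp at zero", {
  # constant normalized counts: variance 0 < mean -> clamped to 0
  flat <- toy_counts(rep(4, 8), 2, 4)
  expect_equal(unname(mom_dispersion(flat, rep(1, 4))), c(0, 0))

  # exactly Poisson moments: counts (0, 1) have m = v = 1/2
  pois <- toy_counts(c(0, 0, 1, 1), 2, 2)
  expect_equal(unname(mom_dispersion(pois, rep(1, 2))), c(0, 0))

  # constructed vector with normalized mean 10 and variance 110 -> phi = 1
  x <- toy_counts(c(13, 0, 1, 7, 4), 1, 5)
  expect_equal(unname(mom_dispersion(x, rep(0.5, 5))), 1.0)

  # all-zero gene gets dispersion 0; single sample errors
  z <- toy_counts(c(0, 5, 0, 9), 2, 2)
  expect_equal(unname(mom_dispersion(z, rep(1, 2)))[1], 0)
  expect_error(mom_dispersion(z[, 1, drop = FALSE], 1), "two samples")
})

test_that("the shrinkage weight follows the variance-ratio formula with its conventions", {
  expect_equal(shrinkage_weight(c(1, 2, 3), 2), 0.5)
  # zero cross-gene variance with an off-target xi: no shrinkage
  expect_equal(shrinkage_weight(c(2, 2, 2), 5), 0)
  # all estimates equal the target: 0/0 resolved as full shrinkage
  expect_equal(shrinkage_weight(c(2, 2, 2), 2), 1)
  # clamped to at most 1
  expect_lte(shrinkage_weight(c(1, 2, 3), 1.9), 1)
  expect_error(shrinkage_weight(c(1, 2), 1), "at least 3")
})

test_that("target selection: mean strategy, degenerate inputs, and the grid search", {
  expect_equal(select_xi(c(1, 2, 3), "mean"), 2)
  expect_equal(select_xi(c(7, 7, 7), "mean"), 7)
  expect_equal(select_xi(c(7, 7, 7), "grid"), 7)
  expect_error(select_xi(c(1, 2, NaN)), "finite")

  # the 100-point grid agrees with a 10x finer brute-force search
  set.seed(42)
  for (rep in 1:5) {
    phi <- rexp(30, 0.5)
    coarse <- select_xi(phi, "grid")
    fine_grid <- seq(min(phi), max(phi), length.out = 1000L)
    obj <- vapply(fine_grid, function(xi) {
      mean((shrinkage_weight(phi, xi) * (xi - phi))^2)
    }, numeric(1))
    step <- diff(range(phi)) / 99
    expect_lte(abs(coarse - fine_grid[which.min(obj)]), step + 1e-12)
  }
})

test_that("shrunk dispersions are an exact convex combination lying between estimate and target", {
  set.seed(7)
  for (rep in 1:10) {
    sim <- simulate_counts(sim_config(G = 40, n = 10, de_prop = 0.2, sigma = 1,
                                      phi = rexp(1, 0.5), seed = rep))
    s <- size_factors(sim$train$counts)
    fit <- shrink_dispersion(sim$train$counts, s)
    expect_identical(fit$phi_hat,
                     fit$delta * fit$xi + (1 - fit$delta) * fit$phi_initial)
    expect_true(all(fit$phi_hat >= pmin(fit$phi_initial, fit$xi) - 1e-15))
    expect_true(all(fit$phi_hat <= pmax(fit$phi_initial, fit$xi) + 1e-15))
    expect_true(all(fit$phi_hat >= 0))
    # contraction toward the mean target
    expect_lte(stats::var(fit$phi_hat), stats::var(fit$phi_initial))
  }
  # manual composition at the worked example
  delta <- shrinkage_weight(c(1, 2, 3), 2)
  expect_equal(delta * 2 + (1 - delta) * c(1, 2, 3), c(1.5, 2, 2.5))
  # delta = 0 leaves the initial estimates untouched
  d0 <- shrinkage_weight(c(2, 2, 2), 9)
  expect_identical(d0 * 9 + (1 - d0) * c(2, 2, 2), c(2, 2, 2))
})

test_that("recovery bias of the shrunk median falls as samples accumulate", {
  bias <- vapply(c(8, 20, 50, 100), function(n) {
    sim <- simulate_counts(sim_config(G = 200, n = n, de_prop = 0, sigma = 0,
                                      phi = 20, seed = 1))
    s <- size_factors(sim$train$counts)
    abs(stats::median(shrink_dispersion(sim$train$counts, s)$phi_hat) - 20)
  }, numeric(1))
  expect_true(all(diff(bias) < 0))
})

test_that("within-class moments ignore class mean differences that pooled moments absorb", {
  sim <- simulate_counts(sim_config(G = 100, n = 20, de_prop = 1, sigma = 3,
                                    phi = 0.5, seed = 3))
  s <- size_factors(sim$train$counts)
  pooled <- mom_dispersion(sim$train$counts, s)
  within <- mom_dispersion(sim$train$counts, s, labels = sim$train$y)
  # with every gene differentially expressed, pooling inflates the estimates
  expect_gt(stats::median(pooled), stats::median(within))
  expect_error(mom_dispersion(sim$train$counts, s,
                              labels = factor(c("a", rep("b", 19)))),
               "two samples per class")
})
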