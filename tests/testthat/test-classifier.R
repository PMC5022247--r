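test_that("plug-in estimates: totals, smoothed class effects, empirical priors", {
  # one sample per class with equal size factors: a balanced gene gets d = 1
  m <- toy_counts(c(5, 2, 1, 5, 2, 1), 3, 2)
  fit <- nblda_fit(m, factor(c("A", "B")))
  expect_equal(unname(fit$lambda), c(10, 4, 2))
  expect_equal(fit$sf, c(0.5, 0.5))
  expect_equal(unname(fit$d["A", "g1"]), 1)  # (5 + 1) / (0.5 * 10 + 1)

  # smoothing keeps effects positive when a class never expresses a gene
  z <- toy_counts(c(0, 3, 2, 0, 4, 1, 9, 2, 5, 8, 1, 7), 3, 4)
  fz <- nblda_fit(z, factor(c("A", "A", "B", "B")))
  expect_true(all(fz$d > 0))

  # priors are class frequencies
  set.seed(1)
  f <- nblda_fit(toy_counts(rpois(12, 5) + 1, 3, 4),
                 factor(c("A", "A", "A", "B")))
  expect_equal(f$pi, c(0.75, 0.25))
  expect_error(nblda_fit(m, factor(c("A", "B", "B"))), "length")
})

test_that("discriminant scores match independent scalar evaluations", {
  m1 <- manual_model(lambda = 10, d = matrix(2, 1, 1, dimnames = list("A", "g1")),
                     pi = 1, phi = 0.5)
  expect_equal(unname(nblda_score(m1, c(g1 = 4), 1)),
               4 * (log(2) - log(11)) - 2 * log(11))

  m2 <- manual_model(lambda = 10, d = matrix(1.5, 1, 1, dimnames = list("A", "g1")),
                     pi = 1, phi = 0)
  expect_equal(unname(plda_score(m2, c(g1 = 10), 1)), 10 * log(1.5) - 15)

  expect_error(nblda_score(m1, c(g1 = 4), -1), "positive")
  bad <- m1; bad$d[] <- -2
  expect_error(nblda_score(bad, c(g1 = 4), 1), "strictly positive")
})

test_that("zero dispersion reproduces the Poisson score exactly; the gap vanishes with phi", {
  for (seed in 1:5) {
    model <- random_model(seed, G = 20, K = 3)
    x <- rpois(20, 8)
    model$phi[] <- 0
    expect_equal(nblda_score(model, x, 0.7), plda_score(model, x, 0.7))

    gaps <- vapply(c(1e-2, 1e-4, 1e-6), function(phi) {
      model$phi[] <- phi
      max(abs(nblda_score(model, x, 0.7) - plda_score(model, x, 0.7)))
    }, numeric(1))
    expect_true(all(diff(gaps) < 0))
  }
})

test_that("identical classes tie and the tie goes to the first class", {
  model <- random_model(1, G = 10, K = 3)
  model$d[2, ] <- model$d[1, ]
  model$d[3, ] <- model$d[1, ]
  model$pi <- rep(1 / 3, 3)
  x <- rpois(10, 5)
  sc <- nblda_score(model, x, 1)
  expect_equal(max(sc) - min(sc), 0)
  expect_equal(unname(which.max(sc)), 1L)

  sim <- simulate_counts(sim_config(G = 10, n = 6, de_prop = 0, sigma = 0,
                                    phi = 0.2, seed = 3))
  model$gene_ids <- rownames(sim$test$counts)
  names(model$lambda) <- names(model$phi) <- colnames(model$d) <- model$gene_ids
  expect_identical(as.character(predict(model, sim$test$counts)),
                   rep("c1", 6))
})

test_that("softmax of the score agrees with brute-force Bayes posteriors", {
  # certifies that the constant dropped from the log-posterior is class-independent
  worst <- 0
  for (seed in 1:40) {
    model <- random_model(seed, G = sample(3:10, 1), K = sample(2:4, 1))
    set.seed(seed + 1000)
    x <- pmin(rpois(length(model$gene_ids), 10), 50)
    s_star <- runif(1, 0.3, 2)
    sc <- nblda_score(model, x, s_star)
    soft <- exp(sc - max(sc)); soft <- soft / sum(soft)
    oracle <- brute_force_posterior(model, x, s_star)
    worst <- max(worst, max(abs(soft - oracle)))
  }
  expect_lt(worst, 1e-8)
})

test_that("predictions: posterior normalization, degenerate K = 1, gene permutation invariance", {
  sim <- simulate_counts(sim_config(G = 40, n = 12, de_prop = 0.4, sigma = 2,
                                    phi = 1, seed = 9))
  fit <- nblda_fit(sim$train$counts, sim$train$y)
  post <- predict(fit, sim$test$counts, type = "posterior")
  expect_true(all(abs(rowSums(post) - 1) < 1e-12))

  # permuting genes consistently in training and test changes nothing
  perm <- sample(nrow(sim$train$counts))
  fitp <- nblda_fit(sim$train$counts[perm, ], sim$train$y)
  expect_equal(predict(fitp, sim$test$counts[perm, ], type = "posterior"),
               post)

  one <- suppressWarnings(nblda_fit(sim$train$counts, factor(rep("only", 12))))
  p1 <- predict(one, sim$test$counts, type = "all")
  expect_identical(as.character(p1$class), rep("only", 12))
  expect_true(all(p1$posterior == 1))

  expect_error(predict(fit, sim$test$counts[-1, ]), "genes")
})
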