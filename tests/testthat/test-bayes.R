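test_that("closed-form log marginal matches the quadrature oracle", {
  set.seed(101)
  for (rep in 1:20) {
    J <- sample(c(3L, 6L), 1L)
    n <- sample(c(2L, 5L), 1L)
    y <- random_cpg(n, J)
    ms <- generic_models(J)
    prior <- prior_config(b0 = runif(1, 0.3, 0.7),
                          g = exp(runif(1, log(0.1), log(100))))
    for (mod in ms$models) {
      closed <- log_marginal_likelihood(y, mod, prior)
      oracle <- oracle_log_marginal(y, mod, prior)
      expect_equal(closed, oracle, tolerance = 1e-6)
    }
  }
})

test_that("the null model wins on equal-mean, tiny-noise data (Occam penalty)", {
  ms <- generic_models(6)
  # at moderate-to-large g the parsimony penalty (P/2) log(1+g) dominates
  # the gain from fitting noise and the null model wins deterministically
  set.seed(7)
  prior <- prior_config(0.5, 100)
  y <- matrix(0.5 + rnorm(3 * 6, sd = 1e-3), 3, 6,
              dimnames = list(NULL, paste0("ct", 1:6)))
  lml_null <- log_marginal_likelihood(y, ms$models[["Null"]], prior)
  lml_sat <- log_marginal_likelihood(y, ms$models[["All"]], prior)
  expect_gt(lml_null, lml_sat)
  expect_equal(lml_null, oracle_log_marginal(y, ms$models[["Null"]], prior),
               tolerance = 1e-6)
  expect_equal(lml_sat, oracle_log_marginal(y, ms$models[["All"]], prior),
               tolerance = 1e-6)
  # at g = 1 the penalty is weak and the ordering is only typical, not sure
  set.seed(8)
  pr1 <- prior_config(0.5, 1)
  wins <- mean(replicate(300, {
    y <- matrix(0.5 + rnorm(18, sd = 1e-3), 3, 6,
                dimnames = list(NULL, paste0("ct", 1:6)))
    log_marginal_likelihood(y, ms$models[["Null"]], pr1) >
      log_marginal_likelihood(y, ms$models[["All"]], pr1)
  }))
  expect_gt(wins, 0.55)
})

test_that("the marginal is invariant under joint translation of y and b0", {
  set.seed(11)
  y <- random_cpg(3, 4)
  mod <- generic_models(4)$models[["ct1"]]
  a <- log_marginal_likelihood(y, mod, prior_config(0.5, 2))
  b <- log_marginal_likelihood(y + 0.17, mod, prior_config(0.5 + 0.17, 2))
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("improper and degenerate marginals are rejected", {
  y2 <- random_cpg(1, 2)
  y2 <- rbind(y2, y2)[1:1, , drop = FALSE]  # n*J = 2 <= P = 2
  expect_error(
    log_marginal_likelihood(y2, candidate_model("All", list("ct1", "ct2")),
                            prior_config(0.5, 1)),
    "improper marginal")
  flat <- matrix(0.5, 3, 2, dimnames = list(NULL, c("ct1", "ct2")))
  expect_error(
    log_marginal_likelihood(flat, candidate_model("Null", list(c("ct1", "ct2"))),
                            prior_config(0.5, 1)),
    "degenerate")
})

test_that("posterior model probabilities normalise correctly", {
  expect_equal(posterior_model_probabilities(c(3, 3), c(0.5, 0.5)),
               c(0.5, 0.5))
  expect_equal(posterior_model_probabilities(c(0, -log(3)), c(0.5, 0.5)),
               c(0.75, 0.25))
  expect_equal(posterior_model_probabilities(0, 1), 1)
  # invariance under adding a constant; extreme magnitudes don't overflow
  p1 <- posterior_model_probabilities(c(-9990, -10000, -10005),
                                      rep(1 / 3, 3))
  p2 <- posterior_model_probabilities(c(10, 0, -5), rep(1 / 3, 3))
  expect_equal(p1, p2, tolerance = 1e-12)
  expect_equal(sum(p1), 1, tolerance = 1e-10)
  expect_error(posterior_model_probabilities(c(-Inf, -Inf), c(0.5, 0.5)),
               "-Inf")
})

test_that("posterior mean of mu shrinks partition sample means toward b0", {
  y <- rbind(c(0.2, 0.8), c(0.2, 0.8))
  colnames(y) <- c("A", "B")
  mod <- candidate_model("All", list("A", "B"))
  expect_equal(posterior_mu(y, mod, prior_config(0.5, 1)), c(0.35, 0.65))
  # g -> infinity: no shrinkage
  expect_equal(posterior_mu(y, mod, prior_config(0.5, 1e12)), c(0.2, 0.8),
               tolerance = 1e-9)
  # data at b0: posterior mean b0 everywhere
  flat <- matrix(0.5, 2, 2, dimnames = list(NULL, c("A", "B")))
  expect_equal(posterior_mu(flat, mod, prior_config(0.5, 3)), c(0.5, 0.5))
})

test_that("posterior sigma2 matches the quadrature oracle and scales", {
  set.seed(21)
  y <- random_cpg(3, 6)
  ms <- generic_models(6)
  prior <- prior_config(0.5, 1)
  for (mod in ms$models) {
    expect_equal(posterior_sigma2(y, mod, prior),
                 oracle_posterior_sigma2(y, mod, prior), tolerance = 1e-8)
  }
  # doubling deviations about b0 multiplies the estimate by exactly 4
  y2 <- 0.5 + 2 * (y - 0.5)
  mod <- ms$models[["Null"]]
  expect_equal(posterior_sigma2(y2, mod, prior),
               4 * posterior_sigma2(y, mod, prior), tolerance = 1e-12)
  # near-noiseless data: prior-dominated but strictly positive
  yq <- matrix(0.5 + 1e-9 * rnorm(18), 3, 6,
               dimnames = list(NULL, paste0("ct", 1:6)))
  expect_gt(posterior_sigma2(yq, mod, prior), 0)
})

test_that("fit_models returns coherent per-probe posteriors", {
  set.seed(31)
  means <- matrix(runif(40 * 6, 0.3, 0.7), 40, 6,
                  dimnames = list(NULL, sort(blood_cell_types())))
  ds <- beta_tensor(means, n = 4, sigma = 0.03)
  ms <- blood_cell_models()
  fit <- fit_models(ds, ms, g = 2)
  expect_s3_class(fit, "meth_fit")
  expect_equal(unname(rowSums(fit$posterior_probs)), rep(1, 40),
               tolerance = 1e-10)
  expect_true(all(fit$sigma2_hat > 0))
  # tidy/glance round out the surface
  td <- tidy(fit)
  expect_equal(nrow(td), 40 * 12)
  expect_equal(glance(fit)$g, 2)
  # a random probe agrees with the single-CpG functions
  k <- 17
  y <- matrix(ds$beta[k, , ], 4, 6, dimnames = list(NULL, ds$cell_types))
  prior <- prior_config(fit$b0, 2)
  expect_equal(fit$log_marginal[k, "Pan_T"],
               log_marginal_likelihood(y, ms$models[["Pan_T"]], prior),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(unname(fit$mu_hat[["Myeloid"]][k, ]),
               unname(posterior_mu(y, ms$models[["Myeloid"]], prior)),
               tolerance = 1e-10)
  expect_equal(fit$sigma2_hat[k, "All"],
               posterior_sigma2(y, ms$models[["All"]], prior),
               tolerance = 1e-10, ignore_attr = TRUE)
})
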