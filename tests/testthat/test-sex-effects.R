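forge_pair <- function(mu_f, mu_m, s2_f, s2_m, g_f, g_m, n_f, n_m,
                       models, probes) {
  mk <- function(mu, s2, g, n, sex) {
    M <- length(models$models)
    structure(
      list(probes = probes, cell_types = models$cell_types, sex = sex,
           n_s = n, models = models, b0 = 0.5, g = g,
           log_marginal = matrix(0, length(probes), M,
                                 dimnames = list(probes,
                                                 names(models$models))),
           posterior_probs = matrix(1 / M, length(probes), M,
                                    dimnames = list(probes,
                                                    names(models$models))),
           mu_hat = mu, sigma2_hat = s2, em = NULL),
      class = "meth_fit")
  }
  list(f = mk(mu_f, s2_f, g_f, n_f, "F"), m = mk(mu_m, s2_m, g_m, n_m, "M"))
}

nk_model_set <- function() {
  ct <- sort(blood_cell_types())
  model_set(list(
    candidate_model("CD56_NK", list("CD56_NK", setdiff(ct, "CD56_NK")),
                    cell_types = ct, reference = 2L)))
}

test_that("declaration follows the normal-CDF probability of |diff| >= delta", {
  # engineered: F - M difference 0.2 in the NK partition, total sd 0.03
  ms <- nk_model_set()
  mu_f <- list(CD56_NK = matrix(c(0.70, 0.50), 1, 2,
                                dimnames = list("cg1", NULL)))
  mu_m <- list(CD56_NK = matrix(c(0.50, 0.50), 1, 2,
                                dimnames = list("cg1", NULL)))
  # choose sigma2 so that each sex contributes var 0.03^2/2 to partition 1:
  # var_s = s2 * w_s / (n_s * c_p); with g=1 (w=1/2), n=5, c=1: s2 = 2*var
  v_each <- 0.03^2 / 2
  s2 <- matrix(2 * v_each * 5, 1, 1, dimnames = list("cg1", "CD56_NK"))
  pair <- forge_pair(mu_f, mu_m, s2, s2, 1, 1, 5, 5, ms, "cg1")
  out <- sex_effect_posterior(pair$f, pair$m, "CD56_NK")
  expect_equal(out$posterior_mean, 0.2, tolerance = 1e-12)
  expect_equal(out$posterior_sd, 0.03, tolerance = 1e-12)
  want <- pnorm((0.2 - 0.1) / 0.03) + pnorm((-0.1 - 0.2) / 0.03)
  expect_equal(out$prob_effect, want, tolerance = 1e-12)
  expect_true(out$declared)

  # identical posterior means: probability bounded by 2(1 - Phi(delta/sd))
  pair0 <- forge_pair(mu_f, mu_f, s2, s2, 1, 1, 5, 5, ms, "cg1")
  out0 <- sex_effect_posterior(pair0$f, pair0$m, "CD56_NK")
  expect_lte(out0$prob_effect - 2 * (1 - pnorm(0.1 / out0$posterior_sd)),
             1e-12)
  expect_false(out0$declared)

  # delta = 0: probability 1 for any nondegenerate posterior
  outd0 <- sex_effect_posterior(pair$f, pair$m, "CD56_NK", delta = 0)
  expect_equal(outd0$prob_effect, 1)
})

test_that("the declaration rule matches direct CDF computation on random draws", {
  set.seed(55)
  for (rep in 1:100) {
    mean_d <- runif(1, -0.4, 0.4)
    sd_d <- runif(1, 0.005, 0.1)
    delta <- 0.10
    p <- prob_abs_diff_at_least(mean_d, sd_d, delta)
    direct <- (1 - pnorm((delta - mean_d) / sd_d)) +
      pnorm((-delta - mean_d) / sd_d)
    # absolute comparison: the naive 1 - pnorm form cancels for tiny tails
    expect_lt(abs(p - direct), 1e-12)
    expect_identical(p > 0.95, direct > 0.95)
  }
})

test_that("swapping sexes negates the mean and preserves the declaration", {
  set.seed(60)
  sim <- simulate_dataset(sim_config(
    K = 150, seed = 60, sigma = 0.02,
    sex_shift = list(delta = 0.2, prob = 0.3)))
  fit_f <- fit_models(sim$F, sim$models)
  fit_m <- fit_models(sim$M, sim$models)
  a <- sex_effect_posterior(fit_f, fit_m, "CD56_NK")
  b <- sex_effect_posterior(fit_m, fit_f, "CD56_NK")
  expect_equal(a$posterior_mean, -b$posterior_mean, tolerance = 1e-12)
  expect_equal(a$prob_effect, b$prob_effect, tolerance = 1e-12)
  expect_equal(a$declared, b$declared)
})

test_that("partition mismatch across sexes is rejected", {
  ms_f <- nk_model_set()
  ct <- sort(blood_cell_types())
  ms_m <- model_set(list(
    candidate_model("CD56_NK", list("CD4_T", setdiff(ct, "CD4_T")),
                    cell_types = ct, reference = 2L)))
  mu <- list(CD56_NK = matrix(0.5, 1, 2, dimnames = list("cg1", NULL)))
  s2 <- matrix(0.01, 1, 1, dimnames = list("cg1", "CD56_NK"))
  pair <- forge_pair(mu, mu, s2, s2, 1, 1, 5, 5, ms_f, "cg1")
  bad_m <- pair$m
  bad_m$models <- ms_m
  expect_error(sex_effect_posterior(pair$f, bad_m, "CD56_NK"),
               "partition mismatch")
})

test_that("simulated sex shifts are detected with high sensitivity", {
  sim <- simulate_dataset(sim_config(
    K = 400, seed = 91, sigma = 0.02,
    sex_shift = list(delta = 0.25, prob = 0.15)))
  fit_f <- fit_models(sim$F, sim$models)
  fit_m <- fit_models(sim$M, sim$models)
  # evaluate per generating model over its own probes (common panel stand-in)
  truth <- sim$truth$probes
  res <- purrr::map_dfr(unique(truth$model), function(m) {
    pr <- truth$probe_id[truth$model == m]
    sex_effect_posterior(fit_f, fit_m, m, probes = pr)
  })
  rec <- recovery_report(sim$truth, fit_f, sex_effects = res)
  expect_gt(rec$sex_effect$sensitivity, 0.8)
  expect_gt(rec$sex_effect$specificity, 0.95)
})
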