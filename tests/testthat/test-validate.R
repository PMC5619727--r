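training_row <- function(probe, partition, mean, sd = 0.02,
                         state = if (mean < 0) "hypomethylated"
                                 else "hypermethylated") {
  tibble::tibble(probe_id = probe, partition = partition,
                 posterior_mean = mean, posterior_sd = sd,
                 ci_low = mean - qnorm(0.975) * sd,
                 ci_high = mean + qnorm(0.975) * sd, state = state)
}

# validation dataset with exact cell-type means (sigma ~ 0)
exact_validation <- function(means, n = 3) {
  K <- nrow(means); J <- ncol(means)
  beta <- aperm(array(means, dim = c(K, J, n)), c(1, 3, 2))
  dimnames(beta) <- list(rownames(means), paste0("v", seq_len(n)),
                         colnames(means))
  meth_dataset(beta, sex = "F")
}

test_that("a validation difference at the training mean is covered and concordant", {
  ct <- c("B", "Mono", "T")
  model <- candidate_model("B", list("B", c("Mono", "T")),
                           cell_types = ct, reference = 2L)
  means <- matrix(c(0.7, 0.5, 0.5), 1, 3, dimnames = list("cg1", ct))
  training <- training_row("cg1", "B", 0.2)
  rep <- validate_panel(training, exact_validation(means), model)
  expect_equal(rep$per_probe$validation_difference, 0.2)
  expect_true(rep$per_probe$covered)
  expect_true(rep$per_probe$state_concordant)
  expect_equal(rep$summary$pct_covered, 100)
})

test_that("a sign flip outside the CI is neither covered nor concordant", {
  ct <- c("B", "Mono", "T")
  model <- candidate_model("B", list("B", c("Mono", "T")),
                           cell_types = ct, reference = 2L)
  means <- matrix(c(0.45, 0.5, 0.5), 1, 3, dimnames = list("cg1", ct))
  training <- training_row("cg1", "B", 0.15, sd = 0.012)  # CI ~ (0.126, 0.174)
  rep <- validate_panel(training, exact_validation(means), model)
  expect_equal(rep$per_probe$validation_difference, -0.05)
  expect_false(rep$per_probe$covered)
  expect_false(rep$per_probe$state_concordant)
})

test_that("missing validation cell types are handled by marginalisation", {
  ct <- sort(blood_cell_types())
  model <- blood_cell_models()$models[["Pan_T"]]
  # validation data carry only B, CD4, CD8 (no myeloid, no NK)
  vmeans <- matrix(c(0.5, 0.62, 0.38), 1, 3,
                   dimnames = list("cg1", c("CD19_B", "CD4_T", "CD8_T")))
  # an extra subject axis is required; reference partition reduces to CD19_B
  training <- dplyr::bind_rows(training_row("cg1", "CD4_T", 0.12),
                               training_row("cg1", "CD8_T", -0.12))
  rep <- validate_panel(training, exact_validation(vmeans), model)
  expect_equal(sort(rep$per_probe$validation_difference), c(-0.12, 0.12))
  expect_true(all(rep$per_probe$covered))
  # joint row present for the two-partition model
  expect_true("joint" %in% rep$summary$partition)
  joint <- rep$summary[rep$summary$partition == "joint", ]
  expect_lte(joint$pct_covered, min(rep$summary$pct_covered))
})

test_that("empty overlap warns and returns an empty report", {
  ct <- c("A", "B")
  model <- candidate_model("A", list("A", "B"), cell_types = ct,
                           reference = 2L)
  means <- matrix(0.5, 1, 2, dimnames = list("other", ct))
  training <- training_row("cg1", "A", 0.1)
  expect_warning(rep <- validate_panel(training, exact_validation(means),
                                       model),
                 "no overlapping probes")
  expect_equal(nrow(rep$per_probe), 0L)
})

test_that("joint Pan-T coverage never exceeds either per-partition rate", {
  set.seed(12)
  mix <- setNames(rep(0, 12), names(blood_cell_models()$models))
  mix["Pan_T"] <- 1
  sim <- simulate_dataset(sim_config(K = 120, seed = 12, model_mixture = mix))
  fit <- fit_models(sim$F, sim$models)
  training <- differential_posterior(fit, "Pan_T")
  # fresh draw from the same truth as 'validation'
  val <- simulate_dataset(sim_config(K = 120, seed = 13, model_mixture = mix))
  rep <- validate_panel(training, val$F, sim$models$models[["Pan_T"]])
  joint <- rep$summary$pct_covered[rep$summary$partition == "joint"]
  expect_lte(joint, min(rep$summary$pct_covered[rep$summary$partition !=
                                                  "joint"]))
})

test_that("feature cross-tabulation tallies percentages over the vocabulary", {
  ann <- tibble::tibble(
    probe_id = paste0("cg", 1:5),
    feature = c("Body", "Body", "TSS200", "Intergenic", "5'UTR"))
  out <- cross_tabulate_features(paste0("cg", 1:4), ann)
  expect_equal(sum(out$percent), 100, tolerance = 0.01)
  expect_equal(out$percent[out$feature == "Body"], 50)
  expect_equal(out$percent[out$feature == "TSS200"], 25)
  expect_equal(out$percent[out$feature == "Intergenic"], 25)
  # all same feature
  out1 <- cross_tabulate_features(c("cg1", "cg2"), ann)
  expect_equal(out1$percent[out1$feature == "Body"], 100)
  # empty panel
  expect_warning(out0 <- cross_tabulate_features(character(), ann), "empty")
  expect_equal(nrow(out0), 0L)
  # unannotated probes reported
  expect_warning(out2 <- cross_tabulate_features(c("cg1", "ghost"), ann),
                 "unannotated")
  expect_equal(attr(out2, "n_unannotated"), 1L)
  expect_equal(sum(out2$percent), 100)
})
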