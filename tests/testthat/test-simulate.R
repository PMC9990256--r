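test_that("synthetic templates are closed, deterministic and heavy-tailed", {
  tpl <- synthetic_template(500, seed = 1)
  expect_lt(abs(sum(tpl$proportions) - 1), 1e-12)
  expect_identical(tpl, synthetic_template(500, seed = 1))
  expect_false(identical(tpl$proportions,
                         synthetic_template(500, seed = 2)$proportions))
  flat <- synthetic_template(50, seed = 3, lognormal_sigma = 0)
  expect_equal(flat$proportions, rep(1 / 50, 50))
  expect_error(synthetic_template(5, seed = 1), "at least 10")
})

test_that("scenario validation guards impossible settings", {
  expect_error(simulation_scenario(10, effect_size = 0.5, seed = 1))
  expect_error(simulation_scenario(10, 2, n_template_taxa = 50,
                                   n_true_positive = 100, seed = 1))
  tpl <- synthetic_template(100, seed = 1)
  sc <- simulation_scenario(5, 2, depth = 100, n_template_taxa = 500,
                            n_true_positive = 10, seed = 1)
  expect_error(simulate_case_control(tpl, sc), "only has")
})

test_that("raw samples total the configured depth and labels are balanced", {
  tpl <- synthetic_template(300, seed = 4)
  sc <- simulation_scenario(n_per_group = 20, effect_size = 2, depth = 500,
                            n_template_taxa = 300, n_true_positive = 30,
                            seed = 9)
  ds <- simulate_case_control(tpl, sc)
  expect_true(all(rowSums(ds$table$values) == 500))
  expect_equal(as.vector(table(ds$labels)), c(20, 20))
  expect_length(ds$true_positive_taxa, 30)
  expect_false(ds$postprocessed)
})

test_that("identical scenario and seed reproduce the dataset exactly", {
  tpl <- synthetic_template(200, seed = 5)
  sc <- simulation_scenario(10, 5, depth = 300, n_template_taxa = 200,
                            n_true_positive = 20, seed = 77)
  expect_identical(simulate_case_control(tpl, sc),
                   simulate_case_control(tpl, sc))
})

test_that("post-processing removes taxa below 5% prevalence, keeps 5% exactly,
           and leaves no entry below the pseudocount", {
  counts <- matrix(0, 100, 3)
  counts[1:4, 1] <- 1          # 4% prevalence -> removed
  counts[1:5, 2] <- 1          # exactly 5% -> kept
  counts[, 3] <- 7             # fully prevalent
  ds <- structure(list(
    table = composition_table(counts, taxon_ids = c("rare", "edge", "common")),
    labels = factor(rep(c("control", "case"), 50)),
    true_positive_taxa = character(0),
    scenario = list(prevalence_filter = 0.05, pseudocount = 1),
    postprocessed = FALSE), class = "sim_dataset")
  out <- benchmark_postprocess(ds)
  expect_setequal(out$table$taxon_ids, c("edge", "common"))
  expect_gte(min(out$table$values), 1)
  expect_true(out$postprocessed)
})

test_that("fully prevalent data only gains the pseudocount", {
  counts <- matrix(5, 10, 3)
  ds <- structure(list(
    table = composition_table(counts),
    labels = factor(rep(c("a", "b"), 5)), true_positive_taxa = character(0),
    scenario = list(prevalence_filter = 0.05, pseudocount = 1),
    postprocessed = FALSE), class = "sim_dataset")
  expect_equal(unname(benchmark_postprocess(ds)$table$values),
               matrix(6, 10, 3))
})

test_that("toy signal generators are deterministic with sensible shapes", {
  sim <- simulate_logcontrast_data(n = 40, n_taxa = 6, effect = 2, seed = 2)
  expect_identical(sim,
                   simulate_logcontrast_data(n = 40, n_taxa = 6, effect = 2,
                                             seed = 2))
  expect_equal(dim(sim$table$values), c(40, 6))
  expect_true(all(sim$table$values > 0))
  expect_equal(levels(sim$y), c("control", "case"))

  lsim <- simulate_trajectory_data(n_per_group = 5, n_taxa = 5, n_times = 4,
                                   seed = 3)
  expect_equal(length(unique(lsim$table$subject_ids)), 10)
  expect_equal(nrow(lsim$table$values), 40)
  expect_named(lsim$y)
})
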