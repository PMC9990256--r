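test_that("intercept-only covariate offsets reduce to closed forms", {
  y_num <- c(1, 2, 3, 6)
  off <- covariate_offset(y_num, NULL, family = "gaussian")
  expect_equal(off$offset, rep(3, 4))

  y_bin <- c(0, 0, 1, 1, 1, 1)
  offb <- covariate_offset(y_bin, NULL, family = "binomial")
  expect_equal(offb$offset, rep(qlogis(4 / 6), 6), tolerance = 1e-8)
})

test_that("a binary covariate gives group-wise logit offsets", {
  g <- rep(c(0, 1), each = 10)
  y <- c(rbinom(0, 1, 0), rep(c(0, 1), c(8, 2)), rep(c(0, 1), c(3, 7)))
  off <- covariate_offset(y, data.frame(g = g), family = "binomial")
  expect_equal(unique(round(off$offset[g == 0], 8)), round(qlogis(0.2), 8))
  expect_equal(unique(round(off$offset[g == 1], 8)), round(qlogis(0.7), 8))
})

test_that("collinear covariates are rejected by name", {
  y <- rnorm(20)
  cov <- data.frame(a = 1:20, b = 2 * (1:20))
  expect_error(covariate_offset(y, cov, family = "gaussian"), "\\bb\\b")
})

test_that("full shrinkage at the top of the lambda grid gives the null model", {
  sim <- simulate_logcontrast_data(n = 50, n_taxa = 6, effect = 1,
                                   family = "gaussian", seed = 5)
  design <- pairwise_logratios(to_log(sim$table))
  fit <- fit_logratio_glmnet(design, sim$y, nfolds = 5, seed = 1)
  expect_equal(sum(abs(fit$glmnet$beta[, 1])), 0)
  expect_equal(unname(fit$glmnet$a0[1]), mean(sim$y), tolerance = 1e-8)

  # with an offset, the top-of-grid intercept matches the offset-adjusted null
  off <- rnorm(50)
  fit_o <- fit_logratio_glmnet(design, sim$y, nfolds = 5, seed = 1,
                               offset = off)
  expect_equal(sum(abs(fit_o$glmnet$beta[, 1])), 0)
  expect_equal(unname(fit_o$glmnet$a0[1]), mean(sim$y - off), tolerance = 1e-8)
})

test_that("a planted gaussian log-contrast puts the true pair on top", {
  sim <- simulate_logcontrast_data(n = 100, n_taxa = 5, effect = 2,
                                   family = "gaussian", noise_sd = 0.1,
                                   seed = 8)
  design <- pairwise_logratios(to_log(sim$table))
  fit <- fit_logratio_glmnet(design, sim$y, nfolds = 5, seed = 2)
  beta <- fit$glmnet$beta[, fit$index_min]
  top <- which.max(abs(beta))
  expect_equal(unname(c(fit$pairs$j[top], fit$pairs$k[top])), c(1, 2))
  # independent single-column least-squares oracle agrees on the best column
  rss <- apply(design$matrix, 2, function(col)
    sum(stats::lm.fit(cbind(1, col), sim$y)$residuals^2))
  expect_equal(unname(which.min(rss)), unname(top))
})

test_that("defaults and selection rules are as documented", {
  sim <- simulate_logcontrast_data(n = 60, n_taxa = 6, effect = 2, seed = 3)
  design <- pairwise_logratios(to_log(sim$table))
  fit <- fit_logratio_glmnet(design, sim$y, nfolds = 5, seed = 3)
  expect_equal(fit$alpha, 0.9)
  expect_gte(fit$lambda_1se, fit$lambda_min)
  expect_true(all(fit$cv_sd >= 0))
  expect_true(all(diff(fit$lambda) < 0))
})

test_that("sparsity along the path grows as lambda shrinks (allowing ties and
           single-variable transient exits)", {
  for (s in c(4, 9)) {
    sim <- simulate_logcontrast_data(n = 60, n_taxa = 10, effect = 1.5,
                                     family = "gaussian", seed = s)
    design <- pairwise_logratios(to_log(sim$table))
    fit <- fit_logratio_glmnet(design, sim$y, nfolds = 5, seed = s)
    expect_equal(unname(fit$nzero[1]), 0)
    expect_true(all(diff(fit$nzero) >= -1))
    expect_gt(fit$nzero[length(fit$nzero)], 0)
  }
})

test_that("degenerate fitting inputs are rejected", {
  sim <- simulate_logcontrast_data(n = 30, n_taxa = 5, effect = 1, seed = 1)
  design <- pairwise_logratios(to_log(sim$table))
  expect_error(fit_logratio_glmnet(design, rep(1, 30), nfolds = 5, seed = 1),
               "constant|2 distinct")
  expect_error(fit_logratio_glmnet(design, sim$y, nfolds = 2, seed = 1),
               "at least 3")
  expect_error(fit_logratio_glmnet(design, sim$y, nfolds = 16, seed = 1),
               "per fold|nfolds")
})

test_that("binary outcome coding follows factor levels and is overridable", {
  y <- factor(c("case", "control", "case", "control"),
              levels = c("control", "case"))
  enc <- codasig:::encode_outcome(y)
  expect_equal(enc$y, c(1, 0, 1, 0))
  enc2 <- codasig:::encode_outcome(c("a", "b", "a", "b"))
  expect_equal(enc2$y, c(0, 1, 0, 1))        # lexicographic: second label = 1
  enc3 <- codasig:::encode_outcome(c("a", "b", "a", "b"), case_level = "a")
  expect_equal(enc3$y, c(1, 0, 1, 0))
  expect_equal(codasig:::encode_outcome(c(1.5, 2.5, 3.5))$family, "gaussian")
})
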