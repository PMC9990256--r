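test_that("longitudinal tables reject duplicate (subject, time) records", {
  vals <- matrix(1, 3, 2)
  expect_error(longitudinal_table(vals, sample_ids = c("a", "b", "c"),
                                  subject_ids = c("S1", "S1", "S1"),
                                  times = c(0, 1, 1)),
               "duplicate")
})

test_that("filtering drops out-of-window observations, short subjects, rare taxa", {
  lt <- make_qualify_table(n_qualifying = 7)
  # add a subject with a single in-window observation: must be removed
  vals <- rbind(lt$values, c(1, 1, 1))
  ids <- c(lt$sample_ids, "lone_1")
  lt2 <- longitudinal_table(vals, sample_ids = ids,
                            taxon_ids = lt$taxon_ids,
                            subject_ids = c(lt$subject_ids, "LONE"),
                            times = c(lt$times, 10))
  flt <- filter_longitudinal(lt2, window = c(0, 30))
  expect_false("LONE" %in% flt$subject_ids)
  # taxon qualifying in 7 of 10 subjects survives ceil(0.7 * 10) = 7
  expect_true("qual" %in% flt$taxon_ids)
  # qualifying in only 6 subjects -> removed
  flt6 <- filter_longitudinal(make_qualify_table(n_qualifying = 6),
                              window = c(0, 30))
  expect_false("qual" %in% flt6$taxon_ids)
})

test_that("filtering already-clean data is the identity", {
  lt <- make_qualify_table(n_qualifying = 10)
  expect_identical(filter_longitudinal(lt, window = c(0, 30)), lt)
})

test_that("window observations outside the window are dropped before counting", {
  lt <- make_qualify_table(n_qualifying = 10)
  flt <- filter_longitudinal(lt, window = c(0, 20))
  expect_true(all(flt$times <= 20))
  expect_equal(length(unique(flt$subject_ids)), 10)
})

test_that("trajectory integration matches simple closed forms", {
  expect_equal(integrate_log_trajectory(c(0, 10), c(3, 3), 0, 10), 30)
  expect_equal(integrate_log_trajectory(c(0, 2), c(0, 2), 0, 2), 2)
  # partial coverage: observed only on [0, 1], window twice as long
  expect_equal(integrate_log_trajectory(c(0, 1), c(1, 1), 0, 2), 2)
  expect_error(integrate_log_trajectory(c(5, 6), c(1, 1), 0, 2), "cover")
  expect_error(integrate_log_trajectory(c(0, 0, 1), c(1, 1, 1), 0, 1),
               "strictly increasing")
})

test_that("trapezoid integrals match a fine-grid Riemann oracle", {
  for (s in 1:10) {
    pts <- withr::with_seed(s, {
      tt <- sort(runif(sample(3:8, 1), 0, 10))
      list(t = tt, v = rnorm(length(tt), 0, 2))
    })
    l1 <- pts$t[1]; l2 <- pts$t[length(pts$t)]
    grid <- seq(l1, l2, length.out = 1e5)
    yy <- approx(pts$t, pts$v, xout = grid)$y
    h <- (l2 - l1) / (length(grid) - 1)
    oracle <- h * (sum(yy) - (yy[1] + yy[length(yy)]) / 2)
    got <- integrate_log_trajectory(pts$t, pts$v, l1, l2)
    expect_equal(got, oracle, tolerance = 1e-6)
  }
})

test_that("per-taxon integral matrix has closed-form values", {
  lt <- make_qualify_table(n_qualifying = 10)
  loglt <- to_log(impute_zeros(lt, 0))
  # taxon 'ref' is constant 2 -> integral log(2) * window length
  ts <- taxon_integral_matrix(loglt, c(0, 30))
  expect_equal(dim(ts$integrals), c(10, 3))
  expect_equal(unname(ts$integrals[, "ref"]), rep(log(2) * 30, 10))
  # doubling all abundances shifts every integral by log(2) * window length
  lt2 <- lt; lt2$values <- lt$values * 2
  ts2 <- taxon_integral_matrix(to_log(impute_zeros(lt2, 0)), c(0, 30))
  expect_equal(ts2$integrals, ts$integrals + log(2) * 30)
})

test_that("pairwise summaries obey exact linearity and antisymmetry", {
  lsim <- simulate_trajectory_data(n_per_group = 5, seed = 21)
  loglt <- to_log(impute_zeros(lsim$table, 0))
  ts <- taxon_integral_matrix(loglt, c(0, 90))
  d <- pairwise_summaries(ts)
  for (c in seq_len(ncol(d$matrix))) {
    j <- d$pairs$j[c]; k <- d$pairs$k[c]
    expect_identical(d$matrix[, c], ts$integrals[, j] - ts$integrals[, k])
    expect_identical(-(ts$integrals[, k] - ts$integrals[, j]),
                     ts$integrals[, j] - ts$integrals[, k])
  }
  # a pair with identical trajectories summarizes to zero
  lt_eq <- make_qualify_table(10)
  lt_eq$values[, "other"] <- lt_eq$values[, "ref"]
  ts_eq <- taxon_integral_matrix(to_log(impute_zeros(lt_eq, 0)), c(0, 30))
  expect_equal(unname(pairwise_summaries(ts_eq)$matrix[, 1]), rep(0, 10))
})

test_that("a trajectory strictly above another has a positive summary", {
  # taxon 'other' (3) strictly above 'ref' (2): s(ref, other) < 0, s flipped > 0
  lt <- make_qualify_table(10)
  ts <- taxon_integral_matrix(to_log(impute_zeros(lt, 0)), c(0, 30))
  s_ref_other <- pairwise_summaries(ts)$matrix[, 1]  # pair (ref, other)
  expect_true(all(s_ref_other < 0))
  expect_true(all(ts$integrals[, "other"] - ts$integrals[, "ref"] > 0))
})

test_that("pairwise summary equals direct integration of the log-ratio", {
  lsim <- simulate_trajectory_data(n_per_group = 4, seed = 31)
  loglt <- to_log(impute_zeros(lsim$table, 0))
  ts <- taxon_integral_matrix(loglt, c(0, 90))
  d <- pairwise_summaries(ts)
  subj <- ts$subject_ids[1]
  idx <- which(loglt$subject_ids == subj)
  ord <- idx[order(loglt$times[idx])]
  direct <- integrate_log_trajectory(loglt$times[ord],
                                     loglt$values[ord, 1] - loglt$values[ord, 2],
                                     0, 90)
  expect_equal(unname(d$matrix[1, 1]), direct, tolerance = 1e-9)
})

test_that("subject scores equal the integral of the signature trajectory", {
  lsim <- simulate_trajectory_data(n_per_group = 10, effect = 2, seed = 41)
  res <- coda_signature_longitudinal(lsim$table, lsim$y, window = c(0, 90),
                                     nfolds = 5, seed = 6)
  loglt <- res$log_table
  for (i in seq_along(res$integrals$subject_ids)) {
    subj <- res$integrals$subject_ids[i]
    idx <- which(loglt$subject_ids == subj)
    ord <- idx[order(loglt$times[idx])]
    curve <- drop(loglt$values[ord, , drop = FALSE] %*% res$theta)
    got <- integrate_log_trajectory(loglt$times[ord], curve, 0, 90)
    expect_equal(got, unname(res$scores[i]), tolerance = 1e-9)
  }
})

test_that("signature trajectories are constant for constant compositions and
           reject grids outside the window", {
  lsim <- simulate_trajectory_data(n_per_group = 10, effect = 2, seed = 43)
  res <- coda_signature_longitudinal(lsim$table, lsim$y, window = c(0, 90),
                                     nfolds = 5, seed = 7)
  expect_error(signature_trajectory(res, grid = c(-5, 10)), "window")
  tr <- signature_trajectory(res, grid = seq(0, 90, by = 10))
  expect_equal(dim(tr$curves), c(length(res$integrals$subject_ids), 10))
  expect_equal(nrow(tr$group_means), 2)
  # group mean is the pointwise mean of its class
  grp <- as.character(res$y)
  cls <- rownames(tr$group_means)[1]
  expect_equal(tr$group_means[cls, ],
               colMeans(tr$curves[grp == cls, , drop = FALSE], na.rm = TRUE))

  # constant composition over time -> constant curve, invariant to scaling
  lt <- make_qualify_table(10)
  sig <- manual_signature(c(ref = 1, other = -1, qual = 0))
  loglt <- to_log(impute_zeros(lt, 0))
  curve <- drop(loglt$values[1:4, ] %*% sig$theta)
  expect_equal(curve, rep(log(2 / 3), 4), ignore_attr = TRUE)
})

test_that("outcomes must be available for every retained subject", {
  lsim <- simulate_trajectory_data(n_per_group = 6, seed = 51)
  y <- lsim$y
  names(y)[1] <- "missing_subject"
  expect_error(coda_signature_longitudinal(lsim$table, y, window = c(0, 90),
                                           nfolds = 3, seed = 1),
               "missing for subjects")
})
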