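# Small in-code fixtures shared across test files.

rand_table <- function(n, K, seed, sparse = FALSE) {
  withr::with_seed(seed, {
    m <- matrix(exp(rnorm(n * K)), n, K)
    if (sparse) m[matrix(runif(n * K) < 0.3, n, K)] <- 0
  })
  composition_table(m)
}

# A quickly fitted signature on planted-signal data; family alternates with
# the seed so both GLM families are exercised in property loops.
fit_random_signature <- function(seed) {
  fam <- if (seed %% 2 == 0) "gaussian" else "binomial"
  sim <- simulate_logcontrast_data(n = 60, n_taxa = 6, effect = 2,
                                   family = fam, seed = seed)
  res <- coda_signature(sim$table, sim$y, pseudocount = 0, nfolds = 5,
                        seed = seed)
  list(res = res, table = sim$table)
}

# Minimal hand-built signature object for score arithmetic tests.
manual_signature <- function(theta, taxon_ids = names(theta)) {
  structure(list(theta = stats::setNames(theta, taxon_ids),
                 intercept = 0, taxon_ids = taxon_ids,
                 selected_taxa = taxon_ids[theta != 0],
                 group_positive = taxon_ids[theta > 0],
                 group_negative = taxon_ids[theta < 0],
                 family = "gaussian", metric = "mse"),
            class = "coda_signature")
}

# Brute-force AUC by exhaustive concordant-pair counting (test oracle).
auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Ten-subject longitudinal toy: taxon "qual" has >= 3 nonzero observations
# for exactly `n_qualifying` subjects, taxon "ref" qualifies everywhere.
make_qualify_table <- function(n_qualifying, n_subjects = 10, n_obs = 4) {
  m <- n_subjects * n_obs
  subj <- rep(sprintf("S%02d", seq_len(n_subjects)), each = n_obs)
  times <- rep(seq(0, 30, length.out = n_obs), n_subjects)
  qual <- rep(1, m)
  for (s in seq_len(n_subjects)) {
    if (s > n_qualifying) qual[(s - 1) * n_obs + seq_len(n_obs)] <- c(1, 0, 0, 0)
  }
  vals <- cbind(ref = rep(2, m), other = rep(3, m), qual = qual)
  longitudinal_table(vals, sample_ids = paste0(subj, "_", seq_len(m)),
                     taxon_ids = colnames(vals), subject_ids = subj,
                     times = times)
}
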