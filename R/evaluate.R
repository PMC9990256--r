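#' Seeded, class-stratified k-fold assignment
#'
#' Partitions samples into k folds so that within each outcome class the
#' per-fold counts differ by at most one; with balanced classes and a fold
#' count dividing the class sizes, every fold has exactly the same number
#' of cases and controls. The same assignment can be reused across methods
#' so they are compared on identical train/test splits.
#'
#' @param labels Class labels (two or more classes; each class needs at
#'   least k members).
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return Integer vector of fold labels in `1..k`, with attribute `seed`.
#' @export
stratified_kfold <- function(labels, k = 5, seed) {
  labels <- as.character(labels)
  tab <- table(labels)
  if (any(tab < k))
    stop("class '", names(tab)[which.min(tab)], "' has fewer than k = ", k,
         " members")
  fold <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in names(tab)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  structure(fold, seed = seed)
}

#' Area under the ROC curve (midrank Mann-Whitney)
#'
#' The probability that a random case scores above a random control, with
#' ties counted one half — computed from midranks, equivalent to exhaustive
#' concordant-pair counting.
#'
#' @param scores Numeric scores (higher = more case-like).
#' @param labels Binary labels; anything coercible to two classes, the
#'   second sorted level (or 1) being the case.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' auc_score(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.75
auc_score <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length")
  if (anyNA(scores) || anyNA(labels)) stop("missing values in scores or labels")
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  y <- encode_outcome(labels, family = "binomial")$y
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Built-in per-taxon test for the DA baseline: two-sample Wilcoxon rank test
# on relative abundances (normal approximation; robust to the zero ties).
rank_test_per_taxon <- function(abundance, labels) {
  y <- encode_outcome(labels, family = "binomial")$y
  suppressWarnings(stats::wilcox.test(abundance[y == 1], abundance[y == 0],
                                      exact = FALSE)$p.value)
}

#' Differential-abundance baseline classifier
#'
#' The benchmark's baseline for DA-style methods: run a per-taxon test on
#' the training data, select taxa with Benjamini-Hochberg adjusted p-value
#' below `alpha`, fit a logistic regression on the relative abundances of
#' the selected taxa (with a tiny ridge stabilizer so complete separation
#' stays finite), and score the test samples. With zero selections the
#' classifier is constant (test AUC 0.5).
#'
#' @param train A `composition_table` of training samples.
#' @param train_labels Binary labels for the training samples.
#' @param test A `composition_table` of test samples (same taxa).
#' @param per_taxon_test Function `(abundance, labels) -> p-value` applied
#'   to each taxon's relative abundances; defaults to a two-sample
#'   Wilcoxon rank test. Plug in any external DA method here.
#' @param alpha BH-adjusted significance threshold (default 0.05).
#' @return List with `scores` (test linear predictors), `selected_taxa`,
#'   and `p_adjusted` (named, all taxa).
#' @export
da_baseline <- function(train, train_labels, test,
                        per_taxon_test = rank_test_per_taxon, alpha = 0.05) {
  stopifnot(inherits(train, "composition_table"),
            inherits(test, "composition_table"))
  if (!identical(train$taxon_ids, test$taxon_ids))
    stop("train and test tables must share taxa")
  rel_train <- relative_abundance(train)$values
  rel_test <- relative_abundance(test)$values
  p <- apply(rel_train, 2L, per_taxon_test, labels = train_labels)
  p_adj <- stats::p.adjust(p, method = "BH")
  names(p_adj) <- train$taxon_ids
  sel <- which(p_adj < alpha)
  if (length(sel) == 0L)
    return(list(scores = rep(0, nrow(rel_test)),
                selected_taxa = character(0), p_adjusted = p_adj))
  y <- encode_outcome(train_labels, family = "binomial")$y
  x_tr <- rel_train[, sel, drop = FALSE]
  x_te <- rel_test[, sel, drop = FALSE]
  if (length(sel) == 1L) {          # glmnet needs >= 2 columns
    x_tr <- cbind(x_tr, 0)
    x_te <- cbind(x_te, 0)
  }
  fit <- glmnet::glmnet(x_tr, y, family = "binomial", alpha = 0,
                        lambda = 1e-8, standardize = FALSE)
  scores <- drop(stats::predict(fit, x_te, s = 1e-8, type = "link"))
  list(scores = scores, selected_taxa = train$taxon_ids[sel],
       p_adjusted = p_adj)
}

#' Method adapter: log-ratio signature
#'
#' Wraps [coda_signature()] as a benchmark method: trained on the training
#' fold (internal cross-validation included), it returns a scorer that
#' applies the collapsed signature to the log-transformed test fold.
#'
#' @param alpha,nfolds,lambda_rule Passed to [coda_signature()]; the
#'   benchmark default is 5 internal folds.
#' @return A function `(train_table, train_labels, seed) -> list(score =
#'   function(test_table), n_selected)`.
#' @export
method_signature <- function(alpha = 0.9, nfolds = 5,
                             lambda_rule = "lambda.1se") {
  function(train_table, train_labels, seed) {
    res <- coda_signature(train_table, train_labels, pseudocount = 0,
                          alpha = alpha, nfolds = nfolds,
                          lambda_rule = lambda_rule, seed = seed)
    list(score = function(test_table)
           signature_score(res, to_log(test_table)),
         n_selected = length(res$selected_taxa))
  }
}

#' Method adapter: DA-selection + logistic baseline
#'
#' @param per_taxon_test,alpha Passed to [da_baseline()].
#' @return A method adapter (see [method_signature()]).
#' @export
method_da <- function(per_taxon_test = rank_test_per_taxon, alpha = 0.05) {
  function(train_table, train_labels, seed) {
    trained <- NULL
    list(score = function(test_table) {
           trained <<- da_baseline(train_table, train_labels, test_table,
                                   per_taxon_test, alpha)
           trained$scores
         },
         n_selected_fn = function() length(trained$selected_taxa))
  }
}

#' Run the simulation benchmark
#'
#' For each scenario and replicate: simulate a case-control dataset from
#' the template, post-process it (prevalence filter + pseudocount), assign
#' shared stratified folds, and for every fold train each method on the
#' training samples and compute the held-out AUC. All methods within a
#' replicate see identical fold assignments. A method failure on a fold is
#' recorded as `NA` with a warning, not an error.
#'
#' @param template A `sim_template`.
#' @param scenarios List of `sim_scenario` objects (their `seed` fields are
#'   combined with `seed` and the replicate number).
#' @param methods Named list of method adapters (see [method_signature()]).
#' @param replicates Simulated datasets per scenario (default 10).
#' @param k Outer CV folds (default 5).
#' @param seed Integer base seed.
#' @return Data frame with one row per scenario x replicate x fold x
#'   method: `effect_size`, `n_per_group`, `replicate`, `fold`, `method`,
#'   `auc`, `n_selected`.
#' @export
run_benchmark <- function(template, scenarios, methods, replicates = 10,
                          k = 5, seed) {
  if (inherits(scenarios, "sim_scenario")) scenarios <- list(scenarios)
  stopifnot(length(methods) > 0, !is.null(names(methods)))
  out <- list()
  for (sc_i in seq_along(scenarios)) {
    sc <- scenarios[[sc_i]]
    for (r in seq_len(replicates)) {
      rep_seed <- (seed + 7919L * sc_i + 104729L * r) %% 2147483647L
      sc_r <- sc
      sc_r$seed <- rep_seed
      ds <- benchmark_postprocess(simulate_case_control(template, sc_r))
      folds <- stratified_kfold(ds$labels, k = k, seed = rep_seed)
      for (f in seq_len(k)) {
        tr <- folds != f
        train_tab <- subset_samples(ds$table, which(tr))
        test_tab <- subset_samples(ds$table, which(!tr))
        for (mname in names(methods)) {
          row <- data.frame(effect_size = sc$effect_size,
                            n_per_group = sc$n_per_group,
                            replicate = r, fold = f, method = mname,
                            auc = NA_real_, n_selected = NA_real_)
          res <- tryCatch({
            trained <- methods[[mname]](train_tab, ds$labels[tr],
                                        seed = rep_seed + f)
            scores <- trained$score(test_tab)
            nsel <- if (!is.null(trained[["n_selected"]])) trained[["n_selected"]]
                    else if (!is.null(trained[["n_selected_fn"]])) trained[["n_selected_fn"]]()
                    else NA_real_
            list(auc = auc_score(scores, ds$labels[!tr]), n_selected = nsel)
          }, error = function(e) {
            warning("method '", mname, "' failed on replicate ", r,
                    ", fold ", f, ": ", conditionMessage(e), call. = FALSE)
            NULL
          })
          if (!is.null(res)) {
            row$auc <- res$auc
            row$n_selected <- res$n_selected
          }
          out[[length(out) + 1L]] <- row
        }
      }
    }
  }
  do.call(rbind, out)
}

#' Aggregate benchmark results per scenario and method
#'
#' @param results Data frame from [run_benchmark()].
#' @return Data frame with `effect_size`, `n_per_group`, `method`,
#'   `mean_auc`, `sd_auc` (sd of per-replicate mean AUCs), and
#'   `mean_n_selected`.
#' @export
aggregate_benchmark <- function(results) {
  key <- interaction(results$effect_size, results$n_per_group,
                     results$method, drop = TRUE)
  agg <- lapply(split(results, key), function(d) {
    per_rep <- tapply(d$auc, d$replicate, mean, na.rm = TRUE)
    data.frame(effect_size = d$effect_size[1L],
               n_per_group = d$n_per_group[1L], method = d$method[1L],
               mean_auc = mean(d$auc, na.rm = TRUE),
               sd_auc = stats::sd(per_rep),
               mean_n_selected = mean(d$n_selected, na.rm = TRUE))
  })
  res <- do.call(rbind, agg)
  rownames(res) <- NULL
  res[order(res$method, res$n_per_group, res$effect_size), ]
}
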