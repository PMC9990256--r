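# Outcome handling: binary factors keep their level order (second level =
# "case" = 1); other label types are sorted lexicographically with the second
# label coded 1. Override with case_level. Numeric outcomes with > 2 distinct
# values dispatch to the gaussian family.
encode_outcome <- function(y, family = NULL, case_level = NULL) {
  if (anyNA(y)) stop("outcome contains missing values")
  fac_levels <- if (is.factor(y)) levels(droplevels(y)) else NULL
  if (is.factor(y)) y <- as.character(y)
  u <- if (!is.null(fac_levels)) fac_levels else sort(unique(y))
  if (is.null(family))
    family <- if (is.numeric(y) && length(u) > 2L) "gaussian" else "binomial"
  family <- match.arg(family, c("binomial", "gaussian"))
  if (family == "gaussian") {
    if (!is.numeric(y)) stop("gaussian family requires a numeric outcome")
    if (length(u) < 2L) stop("outcome is constant")
    return(list(y = as.numeric(y), family = family, levels = NULL))
  }
  if (length(u) != 2L)
    stop(sprintf("binary outcome must have exactly 2 distinct values, found %d",
                 length(u)))
  levs <- as.character(u)
  if (!is.null(case_level)) {
    if (!case_level %in% levs) stop("case_level not found among outcome values")
    levs <- c(setdiff(levs, case_level), case_level)
  }
  list(y = as.numeric(as.character(y) == levs[2L]), family = family,
       levels = levs)
}

#' Fit covariates ahead of the penalized model
#'
#' Non-compositional covariates are modelled against the outcome with an
#' ordinary (unpenalized) GLM first; the fitted linear predictors are then
#' held fixed as an offset in the penalized log-ratio fit, so the signature
#' captures only microbial structure beyond the covariates.
#'
#' @param y Outcome vector (binary or continuous).
#' @param covariates Matrix or data frame of covariates (n rows), or `NULL`
#'   for an intercept-only fit.
#' @param family `"binomial"`, `"gaussian"`, or `NULL` to auto-detect from
#'   the outcome.
#' @param case_level For binary outcomes, the label to code as 1.
#' @return Object of class `covariate_offset`: per-sample linear predictors
#'   (`offset`), the `family`, and the underlying `glm` coefficients.
#' @export
covariate_offset <- function(y, covariates = NULL, family = NULL,
                             case_level = NULL) {
  enc <- encode_outcome(y, family, case_level)
  fam <- if (enc$family == "binomial") stats::binomial() else stats::gaussian()
  if (is.null(covariates) || NCOL(covariates) == 0L) {
    fit <- stats::glm(enc$y ~ 1, family = fam)
  } else {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != length(enc$y))
      stop("covariates must have one row per sample")
    mm <- stats::model.matrix(~ ., data = covariates)
    qr_ <- qr(mm)
    if (qr_$rank < ncol(mm)) {
      dropped <- colnames(mm)[qr_$pivot[(qr_$rank + 1L):ncol(mm)]]
      stop("covariates are rank deficient; collinear columns: ",
           paste(dropped, collapse = ", "))
    }
    dat <- cbind(.y = enc$y, covariates)
    fit <- stats::glm(.y ~ ., data = dat, family = fam)
  }
  structure(list(offset = as.numeric(stats::predict(fit, type = "link")),
                 family = enc$family, coefficients = stats::coef(fit)),
            class = "covariate_offset")
}

#' Cross-validated elastic-net fit on a log-ratio design
#'
#' Fits the all-pairs log-ratio model under an elastic-net penalty over an
#' automatically generated decreasing lambda grid, and evaluates each lambda
#' by k-fold cross-validation: held-out AUC for binary outcomes (to be
#' maximized) or held-out mean squared error for continuous outcomes (to be
#' minimized). Folds are class-stratified and seeded, so the assignment is
#' reproducible. `lambda_min` is the lambda with the best cross-validated
#' performance; `lambda_1se` is the largest lambda whose performance is
#' within one standard error of the best (the default selection rule, which
#' favours sparser signatures).
#'
#' @param design A `logratio_design` (pairwise log-ratios, or pairwise
#'   trajectory-integral summaries for longitudinal data).
#' @param y Outcome vector (one per design row).
#' @param family `"binomial"`, `"gaussian"`, or `NULL` to auto-detect.
#' @param alpha Elastic-net mixing parameter in `[0, 1]`; default 0.9
#'   (close to lasso, with a small ridge component for stability among
#'   correlated log-ratios).
#' @param nfolds Number of CV folds (>= 3). Default 10.
#' @param offset Optional `covariate_offset` (or numeric vector of linear
#'   predictors) held fixed, unpenalized, during fitting.
#' @param seed Integer seed controlling the fold assignment.
#' @param nlambda Length of the lambda grid (default 100).
#' @param case_level For binary outcomes, the label coded as 1.
#' @return Object of class `penalized_fit` with the coefficient path, the
#'   lambda grid, per-lambda CV mean/sd/se, `lambda_min`, `lambda_1se`, the
#'   per-lambda count of nonzero pairs, and bookkeeping (folds, seed, pair
#'   index).
#' @export
fit_logratio_glmnet <- function(design, y, family = NULL, alpha = 0.9,
                                nfolds = 10, offset = NULL, seed,
                                nlambda = 100, case_level = NULL) {
  stopifnot(inherits(design, "logratio_design"))
  x <- design$matrix
  n <- nrow(x)
  if (ncol(x) < 2L)
    stop("need at least 3 taxa (2 log-ratio columns) to fit the penalized model")
  if (nfolds < 3L) stop("nfolds must be at least 3")
  if (n < 2L * nfolds) stop("need at least 2 samples per fold")
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  enc <- encode_outcome(y, family, case_level)
  if (length(enc$y) != n) stop("outcome length does not match design rows")
  off <- NULL
  if (!is.null(offset))
    off <- if (inherits(offset, "covariate_offset")) offset$offset else as.numeric(offset)
  if (!is.null(off) && length(off) != n)
    stop("offset length does not match design rows")

  lmr <- if (n > ncol(x)) 1e-3 else 1e-2
  full <- glmnet::glmnet(x, enc$y, family = enc$family, alpha = alpha,
                         nlambda = nlambda, lambda.min.ratio = lmr,
                         offset = off, standardize = TRUE)
  lambda <- full$lambda

  if (enc$family == "binomial") {
    if (min(table(enc$y)) < nfolds)
      stop("each outcome class needs at least nfolds members for stratified CV")
    foldid <- stratified_kfold(enc$y, k = nfolds, seed = seed)
  } else {
    foldid <- withr::with_seed(seed, sample(rep_len(seq_len(nfolds), n)))
  }

  cvm <- matrix(NA_real_, nfolds, length(lambda))
  for (f in seq_len(nfolds)) {
    tr <- foldid != f
    fit_f <- glmnet::glmnet(x[tr, , drop = FALSE], enc$y[tr],
                            family = enc$family, alpha = alpha,
                            lambda = lambda, offset = off[tr],
                            standardize = TRUE)
    pred <- stats::predict(fit_f, x[!tr, , drop = FALSE], s = lambda,
                           newoffset = off[!tr], type = "link")
    if (enc$family == "binomial") {
      cvm[f, ] <- apply(pred, 2L, auc_score, labels = enc$y[!tr])
    } else {
      cvm[f, ] <- colMeans((enc$y[!tr] - pred)^2)
    }
  }
  cv_mean <- colMeans(cvm)
  cv_sd <- apply(cvm, 2L, stats::sd)
  cv_se <- cv_sd / sqrt(nfolds)

  if (enc$family == "binomial") {
    idx_min <- min(which(cv_mean >= max(cv_mean) - 1e-12))
    idx_1se <- min(which(cv_mean >= cv_mean[idx_min] - cv_se[idx_min]))
  } else {
    idx_min <- min(which(cv_mean <= min(cv_mean) + 1e-12))
    idx_1se <- min(which(cv_mean <= cv_mean[idx_min] + cv_se[idx_min]))
  }

  structure(list(
    glmnet = full, alpha = alpha, lambda = lambda,
    cv_mean = cv_mean, cv_sd = cv_sd, cv_se = cv_se,
    nzero = full$df,
    lambda_min = lambda[idx_min], lambda_1se = lambda[idx_1se],
    index_min = idx_min, index_1se = idx_1se,
    metric = if (enc$family == "binomial") "auc" else "mse",
    family = enc$family, outcome_levels = enc$levels,
    offset = off, offset_used = !is.null(off),
    foldid = foldid, nfolds = nfolds, seed = seed,
    pairs = design$pairs, taxon_ids = design$taxon_ids
  ), class = "penalized_fit")
}

#' @export
print.penalized_fit <- function(x, ...) {
  cat(sprintf("<penalized_fit> %s family, alpha = %g, %d lambdas, %d-fold CV (seed %s)\n",
              x$family, x$alpha, length(x$lambda), x$nfolds, format(x$seed)))
  cat(sprintf("  lambda_min = %.4g (%s %.3f), lambda_1se = %.4g (%s %.3f, %d pairs)\n",
              x$lambda_min, x$metric, x$cv_mean[x$index_min],
              x$lambda_1se, x$metric, x$cv_mean[x$index_1se],
              x$nzero[x$index_1se]))
  invisible(x)
}

#' Collapse selected log-ratio pairs to a zero-sum signature
#'
#' Rewrites the fitted pairwise model as a log-contrast over single taxa:
#' `theta_j` is the sum of the coefficients of pairs where taxon j is the
#' numerator minus those where it is the denominator. The thetas sum to
#' zero by construction, so the signature is invariant to rescaling any
#' sample. Taxa with positive theta form group G1, negative theta group G2.
#'
#' @param fit A `penalized_fit`.
#' @param design Optional `logratio_design`; when supplied its pair index
#'   must match the one stored in the fit.
#' @param lambda_rule `"lambda.1se"` (default, sparser) or `"lambda.min"`.
#' @return Object of class `coda_signature`: named `theta` (length K,
#'   summing to zero), `intercept`, `selected_taxa`, `group_positive` (G1),
#'   `group_negative` (G2), the nonzero pairwise `beta`, and the CV metric
#'   at the chosen lambda.
#' @export
collapse_signature <- function(fit, design = NULL,
                               lambda_rule = c("lambda.1se", "lambda.min")) {
  stopifnot(inherits(fit, "penalized_fit"))
  lambda_rule <- match.arg(lambda_rule)
  if (!is.null(design)) {
    stopifnot(inherits(design, "logratio_design"))
    if (!identical(design$pairs, fit$pairs) ||
        !identical(design$taxon_ids, fit$taxon_ids))
      stop("design does not match the one the fit was built from")
  }
  idx <- if (lambda_rule == "lambda.1se") fit$index_1se else fit$index_min
  beta <- as.numeric(fit$glmnet$beta[, idx])
  K <- length(fit$taxon_ids)
  theta <- theta_from_beta(beta, fit$pairs, K)
  theta[abs(theta) < 1e-12] <- 0   # guard against solver noise
  names(theta) <- fit$taxon_ids
  sel <- fit$taxon_ids[theta != 0]
  nz <- which(beta != 0)
  beta_nz <- beta[nz]
  names(beta_nz) <- paste(fit$taxon_ids[fit$pairs$j[nz]],
                          fit$taxon_ids[fit$pairs$k[nz]], sep = "/")
  structure(list(
    theta = theta, intercept = unname(fit$glmnet$a0[idx]),
    selected_taxa = sel,
    group_positive = fit$taxon_ids[theta > 0],
    group_negative = fit$taxon_ids[theta < 0],
    taxon_ids = fit$taxon_ids, beta = beta_nz,
    n_pairs_selected = length(nz),
    lambda = fit$lambda[idx], lambda_rule = lambda_rule,
    family = fit$family, outcome_levels = fit$outcome_levels,
    metric = fit$metric,
    cv_metric_mean = fit$cv_mean[idx], cv_metric_se = fit$cv_se[idx]
  ), class = "coda_signature")
}

#' Score samples with a signature
#'
#' The signature score of a sample is the log-contrast
#' `M_i = sum_j theta_j * log(X_ij)` (no intercept). Because the thetas sum
#' to zero, the score is unchanged when a sample's composition is rescaled
#' by any positive constant, and it equals the pairwise form
#' `sum beta_jk * log(X_ij / X_ik)`.
#'
#' @param sig A `coda_signature`.
#' @param logx A `log_abundance_table` over the same taxa (same order).
#' @return Numeric vector of per-sample scores.
#' @export
signature_score <- function(sig, logx) {
  stopifnot(inherits(sig, "coda_signature"),
            inherits(logx, "log_abundance_table"))
  if (!identical(logx$taxon_ids, sig$taxon_ids))
    stop("taxa of the log-abundance table do not match the signature")
  drop(logx$values %*% sig$theta)
}

#' Identify a microbial signature from a cross-sectional study
#'
#' End-to-end pipeline: pseudocount zero replacement, log transform, the
#' all-pairs log-ratio design, optional covariate offset, cross-validated
#' elastic-net fit, collapse to a zero-sum log-contrast, and scoring. The
#' apparent metric (AUC for binary outcomes, squared correlation for
#' continuous ones) evaluates the signature on the training data itself;
#' the cross-validated metric at the chosen lambda is the honest estimate.
#'
#' @param table A `composition_table` (counts or proportions).
#' @param y Outcome vector, one per sample.
#' @param covariates Optional matrix/data frame of non-compositional
#'   covariates, modelled first and held as an offset.
#' @param pseudocount Added to all entries before the log transform
#'   (default 1); use 0 only for strictly positive tables.
#' @param alpha,nfolds,seed,case_level Passed to [fit_logratio_glmnet()].
#' @param lambda_rule `"lambda.1se"` (default) or `"lambda.min"`.
#' @param family `"binomial"`, `"gaussian"`, or `NULL` to auto-detect.
#' @return A `coda_signature` augmented with per-sample `scores`, the
#'   outcome `y`, `apparent_metric`, and the underlying `fit`.
#' @export
#' @examples
#' sim <- simulate_logcontrast_data(n = 80, n_taxa = 8, effect = 3, seed = 1)
#' res <- coda_signature(sim$table, sim$y, nfolds = 5, seed = 1)
#' res$selected_taxa
coda_signature <- function(table, y, covariates = NULL, pseudocount = 1,
                           alpha = 0.9, nfolds = 10,
                           lambda_rule = c("lambda.1se", "lambda.min"),
                           seed, family = NULL, case_level = NULL) {
  stopifnot(inherits(table, "composition_table"))
  lambda_rule <- match.arg(lambda_rule)
  enc <- encode_outcome(y, family, case_level)
  logx <- to_log(impute_zeros(table, pseudocount))
  design <- pairwise_logratios(logx)
  off <- if (!is.null(covariates))
    covariate_offset(y, covariates, enc$family, case_level) else NULL
  fit <- fit_logratio_glmnet(design, y, family = enc$family, alpha = alpha,
                             nfolds = nfolds, offset = off, seed = seed,
                             case_level = case_level)
  sig <- collapse_signature(fit, design, lambda_rule)
  sig$scores <- signature_score(sig, logx)
  eta <- sig$intercept + sig$scores + (fit$offset %||% 0)
  sig$apparent_metric <- if (enc$family == "binomial") {
    auc_score(eta, enc$y)
  } else if (stats::sd(eta) > 0) {
    stats::cor(eta, enc$y)^2
  } else 0
  sig$y <- y
  sig$fit <- fit
  sig$pseudocount <- pseudocount
  sig$seed <- seed
  sig
}

#' @export
print.coda_signature <- function(x, ...) {
  cat(sprintf("<coda_signature> %s outcome, %d taxa selected (%d pairs), rule %s\n",
              x$family, length(x$selected_taxa), x$n_pairs_selected,
              x$lambda_rule))
  if (length(x$group_positive))
    cat("  G1 (+):", paste(x$group_positive, collapse = ", "), "\n")
  if (length(x$group_negative))
    cat("  G2 (-):", paste(x$group_negative, collapse = ", "), "\n")
  metric <- toupper(x$metric)
  if (!is.null(x$apparent_metric))
    cat(sprintf("  apparent %s = %.3f\n",
                if (x$family == "binomial") "AUC" else "R^2",
                x$apparent_metric))
  cat(sprintf("  cv %s = %.3f (se %.4f) at lambda = %.4g\n",
              metric, x$cv_metric_mean, x$cv_metric_se, x$lambda))
  invisible(x)
}
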