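#' Construct a longitudinal composition table
#'
#' A composition table whose samples additionally carry a subject identifier
#' and an observation time, so each subject contributes a trajectory of
#' compositions.
#'
#' @inheritParams composition_table
#' @param subject_ids Character vector, one subject label per sample.
#' @param times Numeric vector of observation times, one per sample.
#'   `(subject, time)` pairs must be unique (duplicate records are an error;
#'   resolve them upstream rather than silently averaging).
#' @return Object of class `longitudinal_table` (a `composition_table` with
#'   `subject_ids` and `times`).
#' @export
longitudinal_table <- function(values, sample_ids = NULL, taxon_ids = NULL,
                               subject_ids, times) {
  tab <- composition_table(values, sample_ids, taxon_ids)
  subject_ids <- as.character(subject_ids)
  times <- as.numeric(times)
  if (length(subject_ids) != nrow(tab$values) ||
      length(times) != nrow(tab$values))
    stop("subject_ids and times must have one entry per sample")
  if (anyNA(times) || any(!is.finite(times)))
    stop("observation times must be finite")
  key <- paste(subject_ids, times)
  if (anyDuplicated(key))
    stop("duplicate (subject, time) record: ", key[duplicated(key)][1L])
  tab$subject_ids <- subject_ids
  tab$times <- times
  class(tab) <- c("longitudinal_table", class(tab))
  tab
}

#' @export
print.longitudinal_table <- function(x, ...) {
  cat(sprintf("<longitudinal_table> %d observations, %d subjects, %d taxa, time %g..%g\n",
              nrow(x$values), length(unique(x$subject_ids)), ncol(x$values),
              min(x$times), max(x$times)))
  invisible(x)
}

#' Filter a longitudinal table for trajectory analysis
#'
#' Applies, in order: (1) drop observations outside the time window;
#' (2) drop subjects with fewer than `min_obs_per_subject` in-window
#' observations (a single time point gives no trajectory); (3) drop taxa
#' for which fewer than `ceiling(min_subject_fraction * retained subjects)`
#' subjects have at least `min_nonzero_obs` nonzero observations. The
#' nonzero rule is evaluated on the raw table, so run this before any
#' pseudocount imputation.
#'
#' @param lt A `longitudinal_table` (raw counts or proportions).
#' @param min_obs_per_subject Minimum in-window observations per subject
#'   (default 2).
#' @param min_nonzero_obs Minimum nonzero observations for a subject to
#'   count towards a taxon (default 3).
#' @param min_subject_fraction Fraction of retained subjects that must meet
#'   `min_nonzero_obs` for a taxon to be kept (default 0.7).
#' @param window Numeric `c(l1, l2)` with `l1 < l2`.
#' @return The filtered `longitudinal_table`.
#' @export
filter_longitudinal <- function(lt, min_obs_per_subject = 2,
                                min_nonzero_obs = 3,
                                min_subject_fraction = 0.7, window) {
  stopifnot(inherits(lt, "longitudinal_table"))
  window <- check_window(window)
  keep_obs <- lt$times >= window[1L] & lt$times <= window[2L]
  if (!any(keep_obs))
    stop("no observations fall inside the window [", window[1L], ", ",
         window[2L], "]")
  lt <- subset_samples(lt, which(keep_obs))
  obs_per_subject <- table(lt$subject_ids)
  keep_subj <- names(obs_per_subject)[obs_per_subject >= min_obs_per_subject]
  if (length(keep_subj) == 0L)
    stop("all subjects have fewer than ", min_obs_per_subject,
         " in-window observations")
  lt <- subset_samples(lt, which(lt$subject_ids %in% keep_subj))
  m <- length(unique(lt$subject_ids))
  need <- ceiling(min_subject_fraction * m)
  qualifying <- vapply(seq_len(ncol(lt$values)), function(j) {
    nz_per_subj <- tapply(lt$values[, j] != 0, lt$subject_ids, sum)
    sum(nz_per_subj >= min_nonzero_obs)
  }, integer(1))
  keep_tax <- qualifying >= need
  if (!any(keep_tax))
    stop("no taxon has at least ", min_nonzero_obs,
         " nonzero observations in ", need, " of ", m, " subjects")
  if (sum(keep_tax) < 2L)
    stop("fewer than 2 taxa survive the nonzero-observation rule")
  subset_taxa(lt, which(keep_tax))
}

check_window <- function(window) {
  if (length(window) != 2L || !is.numeric(window) || window[1L] >= window[2L])
    stop("window must be numeric c(l1, l2) with l1 < l2")
  as.numeric(window)
}

#' Integrate a piecewise-linear trajectory over a window
#'
#' Computes the integral of the linear interpolant of `(times, values)`
#' over `[l1, l2]` by the trapezoid rule, with interpolated values inserted
#' at the window endpoints. There is no extrapolation beyond the first and
#' last observation: when the observations only partially cover the window
#' the integral over the covered sub-interval is rescaled by
#' `(l2 - l1) / covered length`, keeping summaries comparable across
#' subjects without inventing data.
#'
#' @param times Strictly increasing observation times.
#' @param values Trajectory values at `times`.
#' @param l1,l2 Window bounds, `l1 < l2`.
#' @return The (rescaled) integral, a single number.
#' @export
#' @examples
#' integrate_log_trajectory(c(0, 2), c(0, 2), 0, 2)  # triangle, area 2
integrate_log_trajectory <- function(times, values, l1, l2) {
  check_window(c(l1, l2))
  if (length(times) != length(values))
    stop("times and values must have equal length")
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing")
  a <- max(l1, times[1L])
  b <- min(l2, times[length(times)])
  if (!(a < b))
    stop("observations do not cover any part of the window")
  inside <- times > a & times < b
  if (length(times) < 2L)
    stop("need at least 2 observations to form a trajectory")
  tt <- c(a, times[inside], b)
  vv <- c(stats::approx(times, values, xout = a)$y, values[inside],
          stats::approx(times, values, xout = b)$y)
  integral <- sum(diff(tt) * (vv[-1L] + vv[-length(vv)]) / 2)
  integral * (l2 - l1) / (b - a)
}

#' Per-taxon trajectory integrals
#'
#' For each subject and taxon, integrates the log-abundance trajectory over
#' the window. Only K integrals per subject are needed: by linearity, the
#' integral of any pairwise log-ratio trajectory is the difference of the
#' two per-taxon integrals (see [pairwise_summaries()]), so the K(K-1)/2
#' pairwise summaries come for free.
#'
#' @param loglt A `longitudinal_table` on the natural-log scale (apply
#'   [impute_zeros()] and [to_log()] first), already filtered so every
#'   subject has >= 2 in-window observations.
#' @param window Numeric `c(l1, l2)`.
#' @return Object of class `trajectory_summary`: `integrals` (subjects x
#'   taxa matrix), `subject_ids`, `taxon_ids`, `window`.
#' @export
taxon_integral_matrix <- function(loglt, window) {
  stopifnot(inherits(loglt, "longitudinal_table"),
            inherits(loglt, "log_abundance_table"))
  window <- check_window(window)
  subjects <- unique(loglt$subject_ids)
  K <- ncol(loglt$values)
  integrals <- matrix(NA_real_, length(subjects), K,
                      dimnames = list(subjects, loglt$taxon_ids))
  for (s in seq_along(subjects)) {
    idx <- which(loglt$subject_ids == subjects[s])
    ord <- idx[order(loglt$times[idx])]
    tt <- loglt$times[ord]
    for (j in seq_len(K))
      integrals[s, j] <- integrate_log_trajectory(tt, loglt$values[ord, j],
                                                  window[1L], window[2L])
  }
  structure(list(integrals = integrals, subject_ids = subjects,
                 taxon_ids = loglt$taxon_ids, window = window),
            class = "trajectory_summary")
}

#' Pairwise log-ratio trajectory summaries
#'
#' The summary `s_i(j, k)` of the log-ratio trajectory of taxa j and k for
#' subject i is the integral of that trajectory over the window, computed
#' exactly as the difference of the two per-taxon integrals. Positive
#' values mean taxon j's trajectory lies above taxon k's.
#'
#' @param ts A `trajectory_summary` from [taxon_integral_matrix()].
#' @return A `logratio_design` whose matrix holds the pairwise summaries
#'   (subjects as rows), directly usable by [fit_logratio_glmnet()].
#' @export
pairwise_summaries <- function(ts) {
  stopifnot(inherits(ts, "trajectory_summary"))
  K <- ncol(ts$integrals)
  pairs <- pair_index(K)
  m <- ts$integrals[, pairs$j, drop = FALSE] - ts$integrals[, pairs$k, drop = FALSE]
  colnames(m) <- paste(ts$taxon_ids[pairs$j], ts$taxon_ids[pairs$k], sep = "/")
  structure(list(matrix = m, pairs = pairs, taxon_ids = ts$taxon_ids),
            class = "logratio_design")
}

#' Identify a dynamic microbial signature from a longitudinal study
#'
#' Pipeline: filter subjects and taxa with enough longitudinal information
#' (on the raw table, so the nonzero-observation rule is meaningful), add
#' the pseudocount, log-transform, compute per-taxon trajectory integrals
#' over the window, form all pairwise summaries, fit the cross-validated
#' elastic net, and collapse to a zero-sum signature. The per-subject score
#' `M_i = sum_j theta_j * I_ij` equals the integral of the subject's
#' log-contrast trajectory over the window.
#'
#' @param lt A `longitudinal_table` (raw counts or proportions).
#' @param y Outcome, one value per subject, named by subject id (or a
#'   vector aligned to `unique(lt$subject_ids)`).
#' @param covariates Optional subject-level covariates (rows named by
#'   subject id, or aligned as for `y`).
#' @param window Numeric `c(l1, l2)`: the integration window (required).
#' @param min_obs_per_subject,min_nonzero_obs,min_subject_fraction Passed
#'   to [filter_longitudinal()].
#' @inheritParams coda_signature
#' @return A `coda_signature` augmented with per-subject `scores`, the
#'   (aligned) outcome `y`, `apparent_metric`, the `fit`, the filtered
#'   log-scale table (`log_table`), the `trajectory_summary` (`integrals`)
#'   and the `window`.
#' @export
coda_signature_longitudinal <- function(lt, y, covariates = NULL, window,
                                        pseudocount = 1, alpha = 0.9,
                                        nfolds = 10,
                                        lambda_rule = c("lambda.1se", "lambda.min"),
                                        seed, family = NULL, case_level = NULL,
                                        min_obs_per_subject = 2,
                                        min_nonzero_obs = 3,
                                        min_subject_fraction = 0.7) {
  stopifnot(inherits(lt, "longitudinal_table"))
  lambda_rule <- match.arg(lambda_rule)
  window <- check_window(window)
  flt <- filter_longitudinal(lt, min_obs_per_subject, min_nonzero_obs,
                             min_subject_fraction, window)
  loglt <- to_log(impute_zeros(flt, pseudocount))
  ts <- taxon_integral_matrix(loglt, window)
  design <- pairwise_summaries(ts)

  y_sub <- align_by_subject(y, ts$subject_ids, "outcome")
  cov_sub <- NULL
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    cov_sub <- covariates[match_subjects(rownames(covariates), ts$subject_ids,
                                         "covariates"), , drop = FALSE]
  }
  enc <- encode_outcome(y_sub, family, case_level)
  off <- if (!is.null(cov_sub))
    covariate_offset(y_sub, cov_sub, enc$family, case_level) else NULL
  fit <- fit_logratio_glmnet(design, y_sub, family = enc$family,
                             alpha = alpha, nfolds = nfolds, offset = off,
                             seed = seed, case_level = case_level)
  sig <- collapse_signature(fit, design, lambda_rule)
  sig$scores <- drop(ts$integrals %*% sig$theta)
  eta <- sig$intercept + sig$scores + (fit$offset %||% 0)
  sig$apparent_metric <- if (enc$family == "binomial") {
    auc_score(eta, enc$y)
  } else if (stats::sd(eta) > 0) stats::cor(eta, enc$y)^2 else 0
  sig$y <- y_sub
  sig$fit <- fit
  sig$log_table <- loglt
  sig$integrals <- ts
  sig$window <- window
  sig$pseudocount <- pseudocount
  sig$seed <- seed
  sig
}

align_by_subject <- function(y, subjects, what) {
  if (!is.null(names(y))) {
    y[match_subjects(names(y), subjects, what)]
  } else {
    if (length(y) != length(subjects))
      stop(what, " must be named by subject id or have one value per retained subject")
    y
  }
}

match_subjects <- function(have, want, what) {
  idx <- match(want, have)
  if (anyNA(idx))
    stop(what, " missing for subjects: ",
         paste(want[is.na(idx)], collapse = ", "))
  idx
}

#' Per-subject signature trajectories
#'
#' Evaluates each subject's log-contrast curve
#' `curve_i(t) = sum_j theta_j * log(X_ij(t))` (linear interpolation between
#' observations, no extrapolation) on a time grid inside the window, plus
#' the pointwise per-group mean curves for binary outcomes. The trapezoid
#' integral of a subject's curve over the window (with the same partial-
#' coverage rescaling as [integrate_log_trajectory()]) equals the subject's
#' signature score.
#'
#' @param object A `coda_signature` returned by
#'   [coda_signature_longitudinal()].
#' @param grid Time points inside the fitted window (default: 100 equally
#'   spaced points spanning it).
#' @return Object of class `signature_trajectories`: `grid`, `curves`
#'   (subjects x grid, `NA` outside a subject's observed span),
#'   `subject_ids`, the per-subject outcome `y`, and `group_means` (a
#'   groups x grid matrix) when the outcome is binary.
#' @export
signature_trajectory <- function(object, grid = NULL) {
  stopifnot(inherits(object, "coda_signature"))
  if (is.null(object$log_table))
    stop("signature_trajectory() needs a signature fitted with coda_signature_longitudinal()")
  window <- object$window
  if (is.null(grid))
    grid <- seq(window[1L], window[2L], length.out = 100L)
  if (any(grid < window[1L]) || any(grid > window[2L]))
    stop("grid points must lie inside the fitted window [", window[1L], ", ",
         window[2L], "]")
  loglt <- object$log_table
  subjects <- object$integrals$subject_ids
  curves <- matrix(NA_real_, length(subjects), length(grid),
                   dimnames = list(subjects, NULL))
  for (s in seq_along(subjects)) {
    idx <- which(loglt$subject_ids == subjects[s])
    ord <- idx[order(loglt$times[idx])]
    tt <- loglt$times[ord]
    contrast <- drop(loglt$values[ord, , drop = FALSE] %*% object$theta)
    inside <- grid >= tt[1L] & grid <= tt[length(tt)]
    if (any(inside))
      curves[s, inside] <- stats::approx(tt, contrast, xout = grid[inside])$y
  }
  out <- list(grid = grid, curves = curves, subject_ids = subjects,
              y = object$y, window = window)
  if (object$family == "binomial") {
    groups <- split(seq_along(subjects), as.character(object$y))
    out$group_means <- do.call(rbind, lapply(groups, function(i)
      colMeans(curves[i, , drop = FALSE], na.rm = TRUE)))
  }
  structure(out, class = "signature_trajectories")
}
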