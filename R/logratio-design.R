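#' Index of all taxon pairs
#'
#' Lexicographically ordered pairs (j, k) with 1 <= j < k <= K, one per
#' column of the all-pairs log-ratio design.
#'
#' @param K Number of taxa (>= 2).
#' @return Data frame with integer columns `j` and `k`, K(K-1)/2 rows.
#' @export
pair_index <- function(K) {
  K <- as.integer(K)
  if (K < 2L) stop("need at least 2 taxa to form pairs")
  data.frame(j = rep.int(seq_len(K - 1L), times = (K - 1L):1L),
             k = sequence((K - 1L):1L, from = 2:K))
}

#' Build the all-pairs log-ratio design matrix
#'
#' Column (j, k) of the design is `log(X_j) - log(X_k)`, i.e. the log-ratio
#' of taxa j and k, for every pair with j < k. The design therefore has
#' K(K-1)/2 columns for K taxa.
#'
#' @param logx A `log_abundance_table` (see [to_log()]).
#' @return An object of class `logratio_design`: list with `matrix`
#'   (n x K(K-1)/2, columns named "taxonA/taxonB"), `pairs` (see
#'   [pair_index()]) and `taxon_ids`.
#' @export
pairwise_logratios <- function(logx) {
  stopifnot(inherits(logx, "log_abundance_table"))
  K <- ncol(logx$values)
  pairs <- pair_index(K)
  m <- logx$values[, pairs$j, drop = FALSE] - logx$values[, pairs$k, drop = FALSE]
  colnames(m) <- paste(logx$taxon_ids[pairs$j], logx$taxon_ids[pairs$k], sep = "/")
  structure(list(matrix = m, pairs = pairs, taxon_ids = logx$taxon_ids),
            class = "logratio_design")
}

#' @export
print.logratio_design <- function(x, ...) {
  cat(sprintf("<logratio_design> %d samples x %d pairs (%d taxa)\n",
              nrow(x$matrix), ncol(x$matrix), length(x$taxon_ids)))
  invisible(x)
}

# Collapse pairwise coefficients beta_jk to per-taxon theta_j:
# theta_j = sum_{k > j} beta_jk - sum_{k < j} beta_kj.
# The construction guarantees sum(theta) == 0 up to float accumulation.
theta_from_beta <- function(beta, pairs, K) {
  theta <- numeric(K)
  nz <- which(beta != 0)
  for (c in nz) {
    theta[pairs$j[c]] <- theta[pairs$j[c]] + beta[c]
    theta[pairs$k[c]] <- theta[pairs$k[c]] - beta[c]
  }
  theta
}
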