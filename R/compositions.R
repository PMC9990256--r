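#' Construct a composition table
#'
#' A composition table holds a samples-by-taxa matrix of non-negative
#' abundances, either raw read counts or proportions. Only the relative
#' information in each row is meaningful: all downstream modelling is
#' invariant to rescaling a sample by a positive constant.
#'
#' @param values Numeric matrix, samples in rows, taxa in columns. All
#'   entries must be non-negative and finite.
#' @param sample_ids Character vector of unique sample labels. Defaults to
#'   `rownames(values)` (or `sample_1 ...` when absent).
#' @param taxon_ids Character vector of unique taxon labels. Defaults to
#'   `colnames(values)` (or `taxon_1 ...` when absent).
#'
#' @return An object of class `composition_table` with fields `values`
#'   (dimnamed matrix), `sample_ids` and `taxon_ids`.
#' @export
#' @examples
#' x <- composition_table(matrix(c(0, 5, 2, 0), 2, 2))
#' impute_zeros(x)
composition_table <- function(values, sample_ids = NULL, taxon_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L || ncol(values) < 2L)
    stop("a composition table needs at least 1 sample and 2 taxa")
  if (anyNA(values) || any(!is.finite(values)))
    stop("abundance values must be finite and non-missing")
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative abundance at sample %d, taxon %d", bad[1L], bad[2L]))
  }
  if (is.null(sample_ids))
    sample_ids <- rownames(values) %||% paste0("sample_", seq_len(nrow(values)))
  if (is.null(taxon_ids))
    taxon_ids <- colnames(values) %||% paste0("taxon_", seq_len(ncol(values)))
  sample_ids <- as.character(sample_ids)
  taxon_ids <- as.character(taxon_ids)
  if (length(sample_ids) != nrow(values) || anyDuplicated(sample_ids))
    stop("sample_ids must be unique and match the number of rows")
  if (length(taxon_ids) != ncol(values) || anyDuplicated(taxon_ids))
    stop("taxon_ids must be unique and match the number of columns")
  dimnames(values) <- list(sample_ids, taxon_ids)
  structure(list(values = values, sample_ids = sample_ids,
                 taxon_ids = taxon_ids),
            class = "composition_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.composition_table <- function(x, ...) {
  cat(sprintf("<composition_table> %d samples x %d taxa\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  zeros: %d (%.1f%%)\n", sum(x$values == 0),
              100 * mean(x$values == 0)))
  invisible(x)
}

#' Number of samples / taxa in a table
#' @param x A `composition_table` (or subclass).
#' @return Integer count.
#' @export
n_samples <- function(x) nrow(x$values)

#' @rdname n_samples
#' @export
n_taxa <- function(x) ncol(x$values)

#' Replace zeros by adding a pseudocount
#'
#' Adds `pseudocount` to every entry of the table (the simple additive
#' zero-replacement used throughout the package; applied to all entries so
#' that within-column comparability is preserved). With a strictly positive
#' table a pseudocount of 0 is allowed and returns the table unchanged.
#'
#' @param table A `composition_table` (longitudinal tables are handled too,
#'   their subject/time annotations are preserved).
#' @param pseudocount Non-negative value added to every entry; must be > 0
#'   whenever the table contains zeros. Default 1 (one read count).
#'
#' @return A strictly positive table of the same class.
#' @export
impute_zeros <- function(table, pseudocount = 1) {
  stopifnot(inherits(table, "composition_table"))
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount < 0)
    stop("pseudocount must be a single non-negative number")
  if (pseudocount == 0) {
    if (any(table$values == 0)) {
      bad <- which(table$values == 0, arr.ind = TRUE)[1L, ]
      stop(sprintf(
        "zero abundance present (e.g. sample '%s', taxon '%s'); use a positive pseudocount",
        table$sample_ids[bad[1L]], table$taxon_ids[bad[2L]]))
    }
    return(table)
  }
  table$values <- table$values + pseudocount
  table
}

#' Natural-log transform a strictly positive table
#'
#' @param table A strictly positive `composition_table` (run
#'   [impute_zeros()] first if the table contains zeros).
#' @return An object of class `log_abundance_table` (same fields, values on
#'   the natural-log scale). Longitudinal annotations are preserved.
#' @export
to_log <- function(table) {
  stopifnot(inherits(table, "composition_table"))
  if (any(table$values <= 0))
    stop("table contains zero or negative entries; apply impute_zeros() before to_log()")
  table$values <- log(table$values)
  class(table) <- c("log_abundance_table", setdiff(class(table), "composition_table"))
  table
}

#' @export
print.log_abundance_table <- function(x, ...) {
  cat(sprintf("<log_abundance_table> %d samples x %d taxa\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Close each sample to relative abundances
#'
#' Divides each row by its total so rows sum to one.
#'
#' @param table A `composition_table` whose row sums are all positive.
#' @return A `composition_table` of proportions.
#' @export
relative_abundance <- function(table) {
  stopifnot(inherits(table, "composition_table"))
  rs <- rowSums(table$values)
  if (any(rs <= 0))
    stop(sprintf("sample '%s' has zero total abundance",
                 table$sample_ids[which(rs <= 0)[1L]]))
  table$values <- table$values / rs
  table
}

# Row-subset a composition table (keeps longitudinal annotations in step).
subset_samples <- function(table, idx) {
  table$values <- table$values[idx, , drop = FALSE]
  table$sample_ids <- table$sample_ids[idx]
  if (!is.null(table$subject_ids)) table$subject_ids <- table$subject_ids[idx]
  if (!is.null(table$times)) table$times <- table$times[idx]
  table
}

# Column-subset a composition table.
subset_taxa <- function(table, idx) {
  table$values <- table$values[, idx, drop = FALSE]
  table$taxon_ids <- colnames(table$values)
  table
}
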