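delim_for <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

read_delim_frame <- function(path) {
  utils::read.table(path, header = TRUE, sep = delim_for(path),
                    check.names = FALSE, stringsAsFactors = FALSE,
                    comment.char = "", quote = "\"")
}

#' Read a taxa abundance table from delimited text
#'
#' TSV or CSV (chosen by extension), first column holding sample ids and
#' remaining columns one taxon each; with `transpose = TRUE` the file holds
#' taxa in rows and samples in columns instead.
#'
#' @param path File path.
#' @param transpose Set `TRUE` when the file is taxa x samples.
#' @return A validated `composition_table`.
#' @export
read_abundance_table <- function(path, transpose = FALSE) {
  df <- read_delim_frame(path)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate identifiers in first column: ",
         ids[duplicated(ids)][1L])
  m <- df[, -1L, drop = FALSE]
  bad_col <- which(!vapply(m, is.numeric, logical(1)))
  if (length(bad_col))
    stop("non-numeric abundance column: ", colnames(m)[bad_col[1L]])
  m <- as.matrix(m)
  rownames(m) <- ids
  if (transpose) m <- t(m)
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative abundance for sample '%s', taxon '%s'",
                 rownames(m)[bad[1L]], colnames(m)[bad[2L]]))
  }
  composition_table(m)
}

#' Write an abundance table as delimited text
#'
#' Values are serialized at 17 significant digits, so a read/write round
#' trip reproduces doubles exactly.
#'
#' @param table A `composition_table`.
#' @param path Output path (`.csv` for comma-separated, else tab).
#' @export
write_abundance_table <- function(table, path) {
  stopifnot(inherits(table, "composition_table"))
  chr <- matrix(sprintf("%.17g", table$values), nrow(table$values))
  df <- data.frame(sample_id = table$sample_ids, chr, check.names = FALSE)
  colnames(df) <- c("sample_id", table$taxon_ids)
  utils::write.table(df, path, sep = delim_for(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a longitudinal abundance table
#'
#' Delimited text with reserved columns `sample_id`, `subject_id`, `time`,
#' followed by one column per taxon.
#'
#' @param path File path.
#' @return A validated `longitudinal_table`.
#' @export
read_longitudinal_table <- function(path) {
  df <- read_delim_frame(path)
  need <- c("sample_id", "subject_id", "time")
  if (!all(need %in% colnames(df)))
    stop("longitudinal file must contain columns: ",
         paste(need, collapse = ", "))
  taxa_cols <- setdiff(colnames(df), need)
  m <- as.matrix(df[, taxa_cols, drop = FALSE])
  longitudinal_table(m, sample_ids = as.character(df$sample_id),
                     taxon_ids = taxa_cols,
                     subject_ids = as.character(df$subject_id),
                     times = as.numeric(df$time))
}

#' Read and align sample metadata
#'
#' Reads a delimited metadata table keyed by its first column (sample id,
#' or subject id for longitudinal studies), aligns it to the requested ids
#' (erroring on missing keys), and extracts the outcome and covariates. A
#' numeric outcome with more than two distinct values dispatches to the
#' gaussian family; two distinct values to binomial.
#'
#' @param path File path.
#' @param ids Character vector of sample/subject ids to align to.
#' @param outcome Name of the outcome column.
#' @param covariates Character vector of covariate column names (optional).
#' @return List with `y` (named, aligned), `covariates` (aligned data
#'   frame or `NULL`), and `family` (`"binomial"` or `"gaussian"`).
#' @export
read_metadata <- function(path, ids, outcome, covariates = character(0)) {
  df <- read_delim_frame(path)
  keys <- as.character(df[[1L]])
  if (anyDuplicated(keys))
    stop("duplicate keys in metadata: ", keys[duplicated(keys)][1L])
  idx <- match(ids, keys)
  if (anyNA(idx))
    stop("metadata missing for: ", paste(ids[is.na(idx)], collapse = ", "))
  missing_cols <- setdiff(c(outcome, covariates), colnames(df))
  if (length(missing_cols))
    stop("metadata lacks column(s): ", paste(missing_cols, collapse = ", "))
  y <- df[[outcome]][idx]
  names(y) <- ids
  fam <- if (is.numeric(y) && length(unique(y)) > 2L) "gaussian" else "binomial"
  if (fam == "binomial" && length(unique(y)) != 2L)
    stop("outcome '", outcome, "' has ", length(unique(y)),
         " distinct non-numeric values; a binary outcome needs exactly 2")
  cov <- NULL
  if (length(covariates)) {
    cov <- df[idx, covariates, drop = FALSE]
    rownames(cov) <- ids
  }
  list(y = y, covariates = cov, family = fam)
}

#' Export a signature as TSV
#'
#' Writes the selected taxa with their zero-sum coefficients and balance
#' group (`G1` positive, `G2` negative), sorted by coefficient.
#'
#' @param sig A `coda_signature`.
#' @param path Output path.
#' @export
write_signature <- function(sig, path) {
  stopifnot(inherits(sig, "coda_signature"))
  sel <- sig$theta[sig$theta != 0]
  df <- data.frame(taxon_id = names(sel), theta = sprintf("%.17g", sel),
                   group = ifelse(sel > 0, "G1", "G2"))
  df <- df[order(-sel), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export per-sample signature scores as TSV
#'
#' @param sig A `coda_signature` carrying `scores` (as returned by
#'   [coda_signature()] or [coda_signature_longitudinal()]).
#' @param path Output path.
#' @export
write_scores <- function(sig, path) {
  stopifnot(inherits(sig, "coda_signature"))
  if (is.null(sig$scores)) stop("signature carries no scores")
  df <- data.frame(id = names(sig$scores) %||% seq_along(sig$scores),
                   score = sprintf("%.17g", sig$scores),
                   outcome = as.character(sig$y))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
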