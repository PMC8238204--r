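#' Read an expression matrix from TSV
#'
#' Patients in rows (first column = patient id), measured proteins in the
#' header.
#'
#' @param path TSV path
#' @return numeric matrix with patient row names and protein column names
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  storage.mode(m) <- "double"
  if (anyNA(m)) stop(sprintf("'%s' contains missing expression values", path))
  m
}

#' Write an expression or feature matrix to TSV
#'
#' @param m numeric matrix with row and column names
#' @param path output path
#' @param id_column name of the first (row id) column
#' @return `path`, invisibly
#' @export
write_matrix_tsv <- function(m, path, id_column = "patient_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a survival table from TSV
#'
#' Expects columns `patient_id`, `time`, `event`.
#'
#' @param path TSV path
#' @return a [survival_data()]
#' @export
read_survival_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("patient_id", "time", "event")
  if (!all(need %in% names(df))) {
    stop(sprintf("'%s' must have columns %s", path, paste(need, collapse = ", ")))
  }
  survival_data(df$time, df$event, df$patient_id)
}

#' Write a survival table to TSV
#'
#' @param surv a [survival_data()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_survival_tsv <- function(surv, path) {
  utils::write.table(surv, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
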