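#' Read / write a numeric matrix as tab-separated text
#'
#' Square or rectangular numeric matrices (FC matrices, time series) stored
#' with a header row of column names; row order is meaningful.
#'
#' @param m Numeric matrix.
#' @param path File path.
#' @return `read_matrix_tsv()` returns a numeric matrix.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- as.data.frame(m)
  if (is.null(colnames(m))) names(df) <- sprintf("c%03d", seq_len(ncol(m)))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  as.matrix(x)
}
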