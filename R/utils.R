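#' @keywords internal
"_PACKAGE"

# Shared TSV helpers: every on-disk table is tab-separated with a header line.

read_tsv_file <- function(path, ...) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, ...)
}

write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# Matrix <-> TSV with the row-id in a named first column.
write_matrix_tsv <- function(mat, path, id_col = "id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write_tsv_file(df, path)
}

read_matrix_tsv <- function(path) {
  df <- read_tsv_file(path)
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- df[[1]]
  mat
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
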