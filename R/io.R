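#' Write a labelled matrix as TSV with a JSON sidecar
#'
#' Matrices (FC, lagged FC, EC) are stored as delimited text with row and
#' column label headers; the sidecar records the reading orientation
#' ("column->row"), the reversed flag, band, lag and a config digest, so
#' a matrix file is self-describing.
#'
#' @param mat Numeric matrix with dimnames.
#' @param path TSV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @param meta Named list of metadata stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(mat, path, meta = list()) {
  if (is.null(rownames(mat))) rownames(mat) <- paste0("r", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- paste0("c", seq_len(ncol(mat)))
  con <- file(path, "w")
  writeLines(paste(c("label", colnames(mat)), collapse = "\t"), con)
  for (i in seq_len(nrow(mat)))
    writeLines(paste(c(rownames(mat)[i],
                       formatC(mat[i, ], format = "g", digits = 15)),
                     collapse = "\t"), con)
  close(con)
  meta$orientation <- if (is.null(meta$orientation)) "column->row"
                      else meta$orientation
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a labelled matrix TSV written by [write_matrix_tsv()]
#'
#' @param path TSV path.
#' @param labels Optional label order; the matrix is reindexed (rows and
#'   columns) to match, and unknown/missing labels are an error.
#' @return List with `values` (matrix) and `meta` (sidecar list, or NULL).
#' @export
read_matrix_tsv <- function(path, labels = NULL) {
  d <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  rn <- as.character(d[[1]])
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- rn
  if (!is.null(labels)) {
    if (!setequal(labels, rownames(m)) || !setequal(labels, colnames(m)))
      stop("matrix labels in ", path, " do not match the requested labels")
    m <- m[labels, labels, drop = FALSE]
  }
  sc <- paste0(path, ".json")
  meta <- if (file.exists(sc))
    jsonlite::read_json(sc, simplifyVector = TRUE) else NULL
  list(values = m, meta = meta)
}
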