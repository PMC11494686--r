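# Deterministic sub-seed derivation: mixes a base seed with integer tags
# (participant, task index, iteration ...) into a 32-bit-safe seed.
derive_seed <- function(seed, ...) {
  s <- as.double(seed) %% 2147483647
  for (k in c(...)) s <- (s * 69069 + as.double(k) * 2654435761) %% 2147483647
  as.integer(s)
}

# md5 digest of an arbitrary R object via its serialized text form
# (base tools::md5sum works on files only).
object_digest <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = 12,
                              force = TRUE), f)
  unname(tools::md5sum(f))
}

file_digest <- function(path) unname(tools::md5sum(path))

# Fixed-format numeric TSV writer: deterministic bytes for identical input.
write_numeric_tsv <- function(mat, path, col_labels = colnames(mat)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(col_labels, collapse = "\t"), con)
  body <- apply(mat, 1, function(r)
    paste(formatC(r, format = "g", digits = 12), collapse = "\t"))
  writeLines(body, con)
  invisible(path)
}

read_numeric_tsv <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  as.matrix(d)
}
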