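## Internal helpers: deterministic RNG streams, TSV i/o, validation.

#' Derive a reproducible sub-stream seed from a master seed and string keys
#'
#' Results must be invariant to gene order and to parallel scheduling, so every
#' unit of randomised work (one gene, one pipeline stage) draws from its own
#' stream whose seed depends only on the master seed and a stable string key.
#' A 31-multiplier rolling hash over the key is folded with the master seed
#' modulo 2^31 - 1, keeping the result a valid 32-bit seed.
#'
#' @param seed master integer seed
#' @param ... character/numeric key components identifying the work unit
#' @return an integer between 0 and 2^31 - 2
#' @keywords internal
stream_seed <- function(seed, ...) {
  key <- paste(vapply(list(...), as.character, ""), collapse = "\r")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer((h + (as.numeric(seed) %% 2147483647) * 48271) %% 2147483647)
}

#' Evaluate code under a temporary RNG seed, restoring the caller's RNG state
#' @keywords internal
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

#' Write a numeric matrix as TSV with an `id` first column
#' @param mat numeric matrix with row and column names
#' @param path output path
#' @return `path`, invisibly
#' @export
write_expression_tsv <- function(mat, path) {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression TSV (first column ids) back into a matrix
#' @param path input path
#' @return numeric matrix, row names from the first column
#' @export
read_expression_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write / read a plain data frame as TSV
#' @param df data frame
#' @param path file path
#' @return `path` (write) or the data frame (read)
#' @export
write_table_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
             stringsAsFactors = FALSE)
}
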