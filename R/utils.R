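# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @keywords internal
read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, ...)
}

# stop() with a machine-readable condition class so callers can test on it
stop_starr <- function(class, msg, call. = FALSE) {
  cond <- structure(
    class = c(class, "starrscore_error", "error", "condition"),
    list(message = msg, call = NULL)
  )
  stop(cond)
}

is_nt <- function(x) x %in% c("A", "C", "G", "T")

# split character vector of sequences into an nchar x n matrix of bases
seq_to_mat <- function(x) {
  stopifnot(length(unique(nchar(x))) <= 1)
  matrix(unlist(strsplit(x, "", fixed = TRUE)), nrow = nchar(x[1]))
}
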