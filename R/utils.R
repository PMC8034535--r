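# Internal helpers shared across modules.

#' Signal a structured pipeline error
#'
#' All validation failures carry a machine-readable `code` so the CLI can map
#' them to exit codes (2 = validation, 3 = data, 4 = internal).
#'
#' @param code short machine-readable error code string.
#' @param message human-readable message.
#' @param class condition class; one of `"mv_validation_error"`,
#'   `"mv_data_error"`, `"mv_internal_error"`.
#' @keywords internal
mv_stop <- function(code, message, class = "mv_validation_error") {
  cond <- structure(
    class = c(class, "mv_error", "error", "condition"),
    list(message = sprintf("[%s] %s", code, message), call = sys.call(-1),
         code = code)
  )
  stop(cond)
}

mv_warn <- function(message) {
  warning(message, call. = FALSE)
}

# Locale-independent ordering (C collation) so outputs are byte-identical
# across platforms.
radix_order <- function(...) order(..., method = "radix")

radix_sort <- function(x) x[radix_order(x)]

# Collapse a character set into a stable ";"-separated field for TSV output.
collapse_set <- function(x) {
  if (length(x) == 0L || all(is.na(x))) return("")
  paste(radix_sort(unique(x[!is.na(x)])), collapse = ";")
}

split_set <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, ";", fixed = TRUE)[[1L]]
}

# Deterministic 31-bit substream seed derived from a master seed and a label
# index; keeps per-interval draws independent of iteration order.
derive_seed <- function(master, index) {
  s <- (as.double(master) %% 2147483647) * 48271 + as.double(index) * 16807
  as.integer(s %% 2147483629 + 1)
}

# Polynomial string hash (31-bit) so per-interval RNG substreams follow the
# interval's label, not its position in the input.
string_hash <- function(x) {
  h <- 0
  for (cp in utf8ToInt(x)) h <- (h * 31 + cp) %% 2147483647
  h
}

# Fixed-format TSV writers/readers: no quoting, "\n" line endings, integers
# printed without scientific notation, so identical inputs give identical bytes.
write_tsv <- function(df, path) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (j in seq_along(df)) {
    if (is.list(df[[j]])) df[[j]] <- vapply(df[[j]], collapse_set, character(1))
    if (is.double(df[[j]])) df[[j]] <- format(df[[j]], scientific = FALSE, trim = TRUE)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, eol = "\n")
  invisible(path)
}

read_tsv <- function(path, colClasses = NA) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = colClasses, na.strings = "NA")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x, min = 1) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= min && x == floor(x)
}
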