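#' @keywords internal
"_PACKAGE"

## Classed conditions so callers (and the CLI) can distinguish user errors
## from programming errors.
abort_regulink <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "regulink_error")))
}

#' Normalize gene symbols
#'
#' Uppercases and strips surrounding whitespace. No alias mapping is
#' attempted: evidence sources are matched on plain HGNC-style symbols.
#'
#' @param x Character vector of gene symbols.
#' @return Character vector of normalized symbols.
#' @export
normalize_symbols <- function(x) {
  toupper(trimws(as.character(x)))
}

## Clamp p-values into (0, 1]. Exact zeros are clamped to the smallest
## positive double with a warning; values outside [0, 1] are an error.
check_pvalues <- function(p, what = "p-value") {
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    abort_regulink(
      sprintf("%s values must lie in (0, 1]", what),
      "regulink_validation_error"
    )
  }
  if (any(p == 0)) {
    warning(sprintf(
      "%d %s value(s) of exactly 0 clamped to %.3g",
      sum(p == 0), what, .Machine$double.xmin
    ), call. = FALSE)
    p[p == 0] <- .Machine$double.xmin
  }
  p
}

## Deterministic per-stream seed derivation: a single fixture seed plus a
## stream name yields an independent, reproducible substream seed, so adding
## a new output never perturbs existing ones. Kept strictly below 2^31 - 1.
stream_seed <- function(seed, stream) {
  h <- 0
  for (ch in utf8ToInt(stream)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer((abs(as.numeric(seed)) + h * 97) %% 2147483647)
}

## Tab-separated read with a required header; returns a data.frame of
## character columns (callers coerce what they need).
read_tsv_strict <- function(path) {
  if (!file.exists(path)) {
    abort_regulink(sprintf("file not found: %s", path), "regulink_io_error")
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character",
                          check.names = FALSE, comment.char = "",
                          quote = "", stringsAsFactors = FALSE)
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

## Resolve a schema mapping (canonical name -> file column name) against a
## header, erroring with the name of the first missing mapped column.
resolve_schema <- function(header, schema, required) {
  for (canon in required) {
    col <- schema[[canon]]
    if (is.null(col) || !col %in% header) {
      abort_regulink(
        sprintf("required column '%s' (mapped from '%s') missing from header",
                if (is.null(col)) canon else col, canon),
        "regulink_schema_error"
      )
    }
  }
  schema
}

parse_numeric_column <- function(x, colname) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x) & nzchar(trimws(x)))
  if (length(bad)) {
    abort_regulink(
      sprintf("non-numeric value '%s' in column '%s' at data row %d",
              x[bad[1]], colname, bad[1]),
      "regulink_parse_error"
    )
  }
  out
}
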