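## Evidence I/O: read, validate, and harmonize heterogeneous TF-target
## evidence tables into one canonical in-memory model. Sources fall into
## five classes: chip (ChIP-seq derived), knockdown (perturbation log2FC),
## curated (literature, activation/repression mode), motif (binding-site
## predictions), coexpression.

SOURCE_CLASSES <- c("chip", "knockdown", "curated", "motif", "coexpression")

#' Default column-name schema for evidence tables
#'
#' Maps canonical field names to the column names expected in input files.
#' Override individual entries to read files with other headers.
#'
#' @return Named character vector (canonical name -> file column name).
#' @export
default_schema <- function() {
  c(tf = "tf", target = "target", log2fc = "log2FC",
    mode = "mode", score = "score", pvalue = "p_value")
}

#' Construct a harmonized evidence source table
#'
#' A `source_table` holds the TF-target edges contributed by one evidence
#' source. Symbols are uppercased, and duplicate (tf, target) pairs are
#' collapsed: knockdown sources keep the row with the largest absolute
#' log2 fold-change (the most informative perturbation), all other classes
#' keep the first occurrence.
#'
#' @param edges Data frame with columns `tf`, `target` and optionally
#'   `log2fc`, `mode`, `score`, `pvalue`.
#' @param source_id Identifier for the source (e.g. `"htftarget"`).
#' @param source_class One of `"chip"`, `"knockdown"`, `"curated"`,
#'   `"motif"`, `"coexpression"`.
#' @return An object of class `source_table` with elements `source_id`,
#'   `source_class` and `edges` (one row per distinct TF-target pair).
#' @export
source_table <- function(edges, source_id, source_class) {
  source_class <- match.arg(source_class, SOURCE_CLASSES)
  stopifnot(is.data.frame(edges))
  for (col in c("tf", "target")) {
    if (!col %in% names(edges)) {
      abort_regulink(sprintf("edges lack column '%s'", col),
                     "regulink_schema_error")
    }
  }
  tf <- normalize_symbols(edges$tf)
  target <- normalize_symbols(edges$target)
  if (any(!nzchar(tf)) || any(!nzchar(target))) {
    abort_regulink("empty gene symbol in evidence table",
                   "regulink_validation_error")
  }
  out <- data.frame(
    tf = tf, target = target, source = rep(source_id, length(tf)),
    log2fc = if ("log2fc" %in% names(edges)) as.numeric(edges$log2fc) else
      rep(NA_real_, length(tf)),
    mode = if ("mode" %in% names(edges)) as.character(edges$mode) else
      rep(NA_character_, length(tf)),
    score = if ("score" %in% names(edges)) as.numeric(edges$score) else
      rep(NA_real_, length(tf)),
    pvalue = if ("pvalue" %in% names(edges)) as.numeric(edges$pvalue) else
      rep(NA_real_, length(tf)),
    stringsAsFactors = FALSE
  )
  if (source_class == "knockdown" && anyNA(out$log2fc)) {
    abort_regulink("knockdown source requires a log2fc value on every edge",
                   "regulink_validation_error")
  }
  if (source_class != "knockdown") out$log2fc <- rep(NA_real_, nrow(out))
  if (source_class != "curated") {
    out$mode <- rep(NA_character_, nrow(out))
  } else {
    out$mode[is.na(out$mode) | !out$mode %in%
               c("activation", "repression")] <- "unknown"
  }
  present <- !is.na(out$pvalue)
  if (any(present)) out$pvalue[present] <- check_pvalues(out$pvalue[present])

  ## deduplicate (tf, target) pairs
  key <- paste(out$tf, out$target, sep = "\r")
  if (source_class == "knockdown") {
    ord <- order(key, -abs(out$log2fc))
    out <- out[ord, , drop = FALSE]
    key <- key[ord]
  }
  out <- out[!duplicated(key), , drop = FALSE]
  out <- out[order(out$tf, out$target), , drop = FALSE]
  rownames(out) <- NULL

  structure(
    list(source_id = source_id, source_class = source_class, edges = out),
    class = "source_table"
  )
}

#' @export
print.source_table <- function(x, ...) {
  cat(sprintf("<source_table> %s (class: %s): %d edges, %d TFs, %d targets\n",
              x$source_id, x$source_class, nrow(x$edges),
              length(unique(x$edges$tf)), length(unique(x$edges$target))))
  invisible(x)
}

#' Read a TF-target evidence table from a tab-separated file
#'
#' Reads one evidence source, applies the column schema, normalizes gene
#' symbols and collapses duplicate pairs (see [source_table()]).
#'
#' @param path Path to a tab-separated file with a header row.
#' @param source_id Identifier to assign to the source.
#' @param source_class Evidence class, one of `"chip"`, `"knockdown"`,
#'   `"curated"`, `"motif"`, `"coexpression"`.
#' @param schema Named character vector mapping canonical names
#'   (`tf`, `target`, `log2fc`, `mode`, `score`, `pvalue`) to file column
#'   names; defaults to [default_schema()].
#' @return A [source_table()].
#' @export
read_source_table <- function(path, source_id, source_class,
                              schema = default_schema()) {
  source_class <- match.arg(source_class, SOURCE_CLASSES)
  df <- read_tsv_strict(path)
  if (nrow(df) == 0) {
    abort_regulink(sprintf("evidence table is empty: %s", path),
                   "regulink_empty_error")
  }
  full <- default_schema()
  full[names(schema)] <- schema
  required <- c("tf", "target", if (source_class == "knockdown") "log2fc")
  resolve_schema(names(df), as.list(full), required)

  edges <- data.frame(tf = df[[full[["tf"]]]],
                      target = df[[full[["target"]]]],
                      stringsAsFactors = FALSE)
  for (opt in c("log2fc", "score", "pvalue")) {
    col <- full[[opt]]
    if (col %in% names(df)) {
      edges[[opt]] <- parse_numeric_column(df[[col]], col)
    }
  }
  if ("mode" %in% names(full) && full[["mode"]] %in% names(df)) {
    edges$mode <- df[[full[["mode"]]]]
  }
  source_table(edges, source_id, source_class)
}

#' Write a source table to a tab-separated file
#'
#' @param table A [source_table()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_source_table <- function(table, path) {
  stopifnot(inherits(table, "source_table"))
  write_tsv(table$edges, path)
}

#' Construct a differential-expression (DEG) table
#'
#' Normalizes symbols and resolves duplicate genes by keeping the row with
#' the smallest p-value.
#'
#' @param df Data frame with columns `gene`, `log2fc`, `pvalue`.
#' @return Object of class `deg_table` (a data frame, one row per gene).
#' @export
deg_table <- function(df) {
  stopifnot(is.data.frame(df))
  for (col in c("gene", "log2fc", "pvalue")) {
    if (!col %in% names(df)) {
      abort_regulink(sprintf("DEG table lacks column '%s'", col),
                     "regulink_schema_error")
    }
  }
  out <- data.frame(
    gene = normalize_symbols(df$gene),
    log2fc = as.numeric(df$log2fc),
    pvalue = as.numeric(df$pvalue),
    stringsAsFactors = FALSE
  )
  out$pvalue <- check_pvalues(out$pvalue)
  out <- out[order(out$gene, out$pvalue), , drop = FALSE]
  out <- out[!duplicated(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("deg_table", "data.frame")
  out
}

#' Read a differential-expression table
#'
#' @param path Tab-separated file with a header.
#' @param schema Named character vector mapping `gene`, `log2fc`, `pvalue`
#'   to file column names (defaults: `gene`, `log2FC`, `p_value`).
#' @return A [deg_table()].
#' @export
read_deg_table <- function(path,
                           schema = c(gene = "gene", log2fc = "log2FC",
                                      pvalue = "p_value")) {
  df <- read_tsv_strict(path)
  full <- c(gene = "gene", log2fc = "log2FC", pvalue = "p_value")
  full[names(schema)] <- schema
  resolve_schema(names(df), as.list(full), c("gene", "log2fc", "pvalue"))
  deg_table(data.frame(
    gene = df[[full[["gene"]]]],
    log2fc = parse_numeric_column(df[[full[["log2fc"]]]], full[["log2fc"]]),
    pvalue = parse_numeric_column(df[[full[["pvalue"]]]], full[["pvalue"]]),
    stringsAsFactors = FALSE
  ))
}

#' Write a DEG table
#'
#' Columns are written under the default schema names (`gene`, `log2FC`,
#' `p_value`) so [read_deg_table()] round-trips without a schema override.
#'
#' @param deg A [deg_table()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_deg_table <- function(deg, path) {
  write_tsv(data.frame(gene = deg$gene, log2FC = deg$log2fc,
                       p_value = deg$pvalue, stringsAsFactors = FALSE),
            path)
}

#' Write a gene set to a plain-text file
#'
#' One symbol per line, sorted; [read_gene_set()] round-trips exactly.
#'
#' @param genes Character vector of gene symbols.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gene_set <- function(genes, path) {
  genes <- sort(unique(normalize_symbols(genes)))
  genes <- genes[nzchar(genes)]
  ok <- tryCatch({
    writeLines(genes, path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) {
    abort_regulink(sprintf("cannot write gene set to %s", path),
                   "regulink_io_error")
  }
  invisible(path)
}

#' Read a gene set written by [write_gene_set()]
#' @param path Input path.
#' @return Sorted character vector of symbols.
#' @export
read_gene_set <- function(path) {
  if (!file.exists(path)) {
    abort_regulink(sprintf("file not found: %s", path), "regulink_io_error")
  }
  lines <- readLines(path)
  sort(unique(normalize_symbols(lines[nzchar(trimws(lines))])))
}
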