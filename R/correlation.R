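## Expression-correlation engine: TF-gene correlations within annotated
## cohorts, correlation-derived gene sets used as intersectable evidence,
## and pan-tissue correlation of a single TF-target pair.

#' Construct an annotated expression matrix
#'
#' @param values Numeric genes x samples matrix of log-scale expression,
#'   with gene symbols as row names and sample identifiers as column names.
#' @param annotations Data frame with one row per sample and columns
#'   `sample`, `cohort`, and optionally `tissue` and `is_tumor` (logical).
#' @return Object of class `expression_matrix` with elements `values` and
#'   `annotations` (rows aligned to the matrix columns).
#' @export
expression_matrix <- function(values, annotations) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort_regulink("expression matrix needs gene row names and sample column names",
                   "regulink_validation_error")
  }
  rownames(values) <- normalize_symbols(rownames(values))
  if (anyDuplicated(rownames(values))) {
    abort_regulink("duplicate gene symbols in expression matrix",
                   "regulink_validation_error")
  }
  stopifnot(is.data.frame(annotations))
  for (col in c("sample", "cohort")) {
    if (!col %in% names(annotations)) {
      abort_regulink(sprintf("sample annotations lack column '%s'", col),
                     "regulink_schema_error")
    }
  }
  if (!"tissue" %in% names(annotations)) annotations$tissue <- annotations$cohort
  if (!"is_tumor" %in% names(annotations)) annotations$is_tumor <- FALSE
  annotations$is_tumor <- as.logical(annotations$is_tumor)
  idx <- match(colnames(values), annotations$sample)
  if (anyNA(idx)) {
    abort_regulink("every sample column must have an annotation row",
                   "regulink_validation_error")
  }
  annotations <- annotations[idx, , drop = FALSE]
  rownames(annotations) <- NULL
  structure(list(values = values, annotations = annotations),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples, %d cohort(s)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$annotations$cohort))))
  invisible(x)
}

#' Read an expression matrix and its sample annotations from TSV
#'
#' @param path Genes-in-rows TSV whose first column holds gene symbols and
#'   whose header holds sample identifiers.
#' @param annot_path Sample-annotation TSV with columns `sample`, `cohort`
#'   and optionally `tissue`, `is_tumor`.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, annot_path) {
  df <- read_tsv_strict(path)
  genes <- df[[1]]
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- genes
  ann <- read_tsv_strict(annot_path)
  if ("is_tumor" %in% names(ann)) {
    ann$is_tumor <- toupper(ann$is_tumor) %in% c("TRUE", "T", "1", "YES")
  }
  expression_matrix(vals, ann)
}

#' Write an expression matrix and annotations to TSV
#' @param expr An [expression_matrix()].
#' @param path,annot_path Output paths for the matrix and annotations.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, annot_path) {
  df <- data.frame(gene = rownames(expr$values), expr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
  write_tsv(expr$annotations, annot_path)
  invisible(path)
}

#' Correlation between two expression vectors
#'
#' Pearson's product-moment correlation (or Spearman's rank correlation,
#' i.e. Pearson on average ranks) with a two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#' Missing values are removed pairwise. Perfect correlations (|r| = 1)
#' report the p-value clamp floor (`.Machine$double.xmin`) rather than 0.
#'
#' @param x,y Numeric vectors of equal length.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List with elements `r`, `pvalue`, `n`, `method`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) {
    abort_regulink("x and y must have equal length",
                   "regulink_validation_error")
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3) {
    abort_regulink(sprintf("need at least 3 complete pairs (have %d)", n),
                   "regulink_insufficient_data")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort_regulink("zero variance in one of the vectors",
                   "regulink_degenerate_input")
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = method, exact = FALSE,
                    alternative = "two.sided")
  )
  r <- max(-1, min(1, unname(ct$estimate)))
  if (abs(r) >= 1 - 1e-15) {
    p <- .Machine$double.xmin
  } else {
    p <- min(max(ct$p.value, .Machine$double.xmin), 1)
  }
  list(r = r, pvalue = p, n = n, method = method)
}

cohort_submatrix <- function(expr, cohort, tumor_only = FALSE) {
  ann <- expr$annotations
  keep <- ann$cohort == cohort
  if (tumor_only) keep <- keep & ann$is_tumor
  expr$values[, keep, drop = FALSE]
}

#' Genes correlated with a TF in one cohort
#'
#' The correlation-derived gene set used as an extra intersectable evidence
#' channel (the cor_TCGA / cor_GTEx pattern): all genes whose expression
#' correlation with the TF in the chosen cohort clears `r_threshold` under
#' the chosen sign rule.
#'
#' @param expr An [expression_matrix()].
#' @param tf TF gene symbol (must be a row of `expr`).
#' @param cohort Cohort label.
#' @param method `"pearson"` or `"spearman"`.
#' @param r_threshold Correlation-coefficient threshold (default 0.3).
#' @param signed Sign rule: `"abs"` (default) keeps genes with
#'   \eqn{|r| \ge} threshold, `"positive"` requires \eqn{r \ge} threshold,
#'   `"negative"` requires \eqn{r \le -}threshold.
#' @param tumor_only Restrict to tumor-labelled samples.
#' @return Sorted character vector of gene symbols (the TF excluded).
#' @export
correlated_gene_set <- function(expr, tf, cohort,
                                method = c("pearson", "spearman"),
                                r_threshold = 0.3,
                                signed = c("abs", "positive", "negative"),
                                tumor_only = FALSE) {
  method <- match.arg(method)
  signed <- match.arg(signed)
  tf <- normalize_symbols(tf)
  if (!tf %in% rownames(expr$values)) {
    abort_regulink(sprintf("gene '%s' not in expression matrix", tf),
                   "regulink_unknown_gene")
  }
  if (!cohort %in% expr$annotations$cohort) {
    abort_regulink(sprintf("cohort '%s' not in annotations", cohort),
                   "regulink_unknown_gene")
  }
  vals <- cohort_submatrix(expr, cohort, tumor_only)
  if (ncol(vals) < 3) {
    abort_regulink("fewer than 3 samples in cohort",
                   "regulink_insufficient_data")
  }
  x <- vals[tf, ]
  r <- suppressWarnings(as.vector(
    stats::cor(x, t(vals), method = method, use = "pairwise.complete.obs")
  ))
  names(r) <- rownames(vals)
  r <- r[names(r) != tf & !is.na(r)]
  keep <- switch(signed,
                 abs = abs(r) >= r_threshold,
                 positive = r >= r_threshold,
                 negative = r <= -r_threshold)
  sort(names(r)[keep])
}

#' Pan-tissue correlation of a TF-target pair
#'
#' Correlates the expression of a TF and a candidate target within every
#' cohort and flags cohorts passing the coefficient and p-value thresholds.
#' All cohorts with at least 3 usable samples are reported, pass or fail.
#'
#' @param expr An [expression_matrix()].
#' @param tf,target Gene symbols (rows of `expr`).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param r_threshold Coefficient threshold for the significance flag
#'   (absolute value; default 0.3).
#' @param p_threshold P-value threshold (default 0.05).
#' @param tumor_only Restrict every cohort to tumor-labelled samples.
#' @param adjust Apply Benjamini-Hochberg correction across cohorts before
#'   flagging (default `FALSE`: the plain per-cohort p-value is used).
#' @return Data frame of class `correlation_result` with columns `tf`,
#'   `gene`, `cohort`, `r`, `pvalue`, (optionally `padj`,) `n`, `method`,
#'   `significant`.
#' @export
pan_tissue_correlation <- function(expr, tf, target,
                                   method = c("pearson", "spearman"),
                                   r_threshold = 0.3, p_threshold = 0.05,
                                   tumor_only = FALSE, adjust = FALSE) {
  method <- match.arg(method)
  tf <- normalize_symbols(tf)
  target <- normalize_symbols(target)
  for (g in unique(c(tf, target))) {
    if (!g %in% rownames(expr$values)) {
      abort_regulink(sprintf("gene '%s' not in expression matrix", g),
                     "regulink_unknown_gene")
    }
  }
  cohorts <- unique(expr$annotations$cohort)
  rows <- list()
  for (co in cohorts) {
    vals <- cohort_submatrix(expr, co, tumor_only)
    if (ncol(vals) < 3) next
    if (tf == target) {
      res <- list(r = 1, pvalue = .Machine$double.xmin, n = ncol(vals),
                  method = method)
    } else {
      res <- tryCatch(correlate(vals[tf, ], vals[target, ], method),
                      regulink_error = function(e) NULL)
      if (is.null(res)) next
    }
    rows[[co]] <- data.frame(tf = tf, gene = target, cohort = co,
                             r = res$r, pvalue = res$pvalue, n = res$n,
                             method = method, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(tf = character(), gene = character(), cohort = character(),
               r = numeric(), pvalue = numeric(), n = integer(),
               method = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  p_flag <- out$pvalue
  if (adjust && nrow(out)) {
    out$padj <- stats::p.adjust(out$pvalue, method = "BH")
    p_flag <- out$padj
  }
  out$significant <- abs(out$r) >= r_threshold & p_flag < p_threshold
  class(out) <- c("correlation_result", "data.frame")
  out
}

#' Write pan-tissue correlation results to TSV
#' @param res A `correlation_result` data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_correlation_results <- function(res, path) {
  write_tsv(as.data.frame(res), path)
}

#' Export scatter-plot data for a TF-target pair
#'
#' Two expression columns per sample for one cohort, ready for external
#' plotting.
#'
#' @param expr An [expression_matrix()].
#' @param tf,target Gene symbols.
#' @param cohort Cohort label.
#' @param tumor_only Restrict to tumor samples.
#' @return Data frame with columns `sample`, `cohort`, `tf_expr`,
#'   `target_expr`.
#' @export
scatter_data <- function(expr, tf, target, cohort, tumor_only = FALSE) {
  tf <- normalize_symbols(tf)
  target <- normalize_symbols(target)
  vals <- cohort_submatrix(expr, cohort, tumor_only)
  data.frame(sample = colnames(vals), cohort = cohort,
             tf_expr = vals[tf, ], target_expr = vals[target, ],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Precompute a TF-versus-all-genes correlation cache for one cohort
#'
#' Mirrors a precomputed-database design: one row per gene with `r`,
#' `pvalue` and `n`, written (optionally) as a tab-separated table.
#'
#' @param expr An [expression_matrix()].
#' @param tf TF gene symbol.
#' @param cohort Cohort label.
#' @param method `"pearson"` or `"spearman"`.
#' @param path Optional output TSV path.
#' @return Data frame with columns `tf`, `gene`, `cohort`, `r`, `pvalue`,
#'   `n`.
#' @export
correlation_cache <- function(expr, tf, cohort,
                              method = c("pearson", "spearman"),
                              path = NULL) {
  method <- match.arg(method)
  tf <- normalize_symbols(tf)
  vals <- cohort_submatrix(expr, cohort)
  genes <- setdiff(rownames(vals), tf)
  rows <- lapply(genes, function(g) {
    res <- tryCatch(correlate(vals[tf, ], vals[g, ], method),
                    regulink_error = function(e) NULL)
    if (is.null(res)) return(NULL)
    data.frame(tf = tf, gene = g, cohort = cohort, r = res$r,
               pvalue = res$pvalue, n = res$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  if (!is.null(path)) write_tsv(out, path)
  out
}
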