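## Bidirectional prediction by configurable intersection of per-source gene
## sets: targets of a TF, or upstream regulators of a gene, with knockdown
## log2FC filtering, optional correlation-derived sets, and Venn-region
## accounting.

#' Construct a prediction query
#'
#' @param query_symbol TF symbol (direction `"targets_of_tf"`) or target
#'   gene symbol (direction `"regulators_of_gene"`).
#' @param direction `"targets_of_tf"` or `"regulators_of_gene"`.
#' @param sources Character vector of source identifiers to draw evidence
#'   sets from.
#' @param knocktf_lfc_threshold Minimum `|log2fc|` for edges from knockdown
#'   sources (default 0.5).
#' @param knocktf_down_only Keep only knockdown edges with `log2fc < 0`
#'   (target falls when the TF is perturbed; activation-consistent).
#' @param correlation_sets Named list of extra gene sets (e.g.
#'   correlation-derived `cor_TCGA` / `cor_GTEx` sets) that participate in
#'   the intersection like ordinary sources.
#' @param intersect_over Names of the sets to intersect; default all
#'   (`sources` plus `names(correlation_sets)`).
#' @param min_support `NULL` (default) for strict intersection over
#'   `intersect_over`, or an integer k for a k-of-n consensus.
#' @return Object of class `prediction_query`.
#' @export
prediction_query <- function(query_symbol,
                             direction = c("targets_of_tf",
                                           "regulators_of_gene"),
                             sources = character(),
                             knocktf_lfc_threshold = 0.5,
                             knocktf_down_only = FALSE,
                             correlation_sets = list(),
                             intersect_over = NULL,
                             min_support = NULL) {
  direction <- match.arg(direction)
  if (knocktf_lfc_threshold < 0) {
    abort_regulink("knocktf_lfc_threshold must be non-negative",
                   "regulink_validation_error")
  }
  all_names <- c(sources, names(correlation_sets))
  if (is.null(intersect_over)) intersect_over <- all_names
  if (length(setdiff(intersect_over, all_names))) {
    abort_regulink(
      sprintf("intersect_over names not declared: %s",
              paste(setdiff(intersect_over, all_names), collapse = ", ")),
      "regulink_config_error"
    )
  }
  structure(
    list(query_symbol = normalize_symbols(query_symbol),
         direction = direction, sources = sources,
         knocktf_lfc_threshold = knocktf_lfc_threshold,
         knocktf_down_only = knocktf_down_only,
         correlation_sets = lapply(correlation_sets, function(s)
           sort(unique(normalize_symbols(s)))),
         intersect_over = intersect_over,
         min_support = min_support),
    class = "prediction_query"
  )
}

#' Gene set contributed by one evidence source for a query
#'
#' For direction `"targets_of_tf"` returns the targets of the query TF; for
#' `"regulators_of_gene"` the TFs pointing at the query gene. Knockdown
#' sources are filtered by `|log2fc| >= knocktf_lfc_threshold`, and, when
#' `knocktf_down_only`, additionally by `log2fc < 0`.
#'
#' @param table A [source_table()].
#' @param query A [prediction_query()].
#' @return Sorted character vector of gene symbols (possibly empty; an
#'   unknown query symbol yields the empty set with a message).
#' @export
source_gene_set <- function(table, query) {
  stopifnot(inherits(table, "source_table"),
            inherits(query, "prediction_query"))
  e <- table$edges
  if (table$source_class == "knockdown") {
    keep <- abs(e$log2fc) >= query$knocktf_lfc_threshold
    if (query$knocktf_down_only) keep <- keep & e$log2fc < 0
    e <- e[keep, , drop = FALSE]
  }
  out <- if (query$direction == "targets_of_tf") {
    e$target[e$tf == query$query_symbol]
  } else {
    e$tf[e$target == query$query_symbol]
  }
  if (!length(out) &&
      !(query$query_symbol %in% (if (query$direction == "targets_of_tf")
        table$edges$tf else table$edges$target))) {
    message(sprintf("source '%s': query '%s' not present; empty set",
                    table$source_id, query$query_symbol))
  }
  sort(unique(out))
}

#' Intersect named gene sets with Venn-region accounting
#'
#' @param per_set Named list of character gene sets.
#' @param intersect_over Names of the sets to intersect (default all).
#' @param min_support `NULL` for strict intersection, or an integer k: keep
#'   genes present in at least k of the `intersect_over` sets.
#' @return Object of class `prediction_result`: `per_set` (all sets,
#'   sorted), `intersection`, `region_counts` (one count per non-empty
#'   subset of `intersect_over`, keys like `"A&B"`; regions partition the
#'   union), `support_counts` (over all sets), `intersect_over`,
#'   `empty_sets` (names of selected sets that contributed nothing).
#' @export
intersect_gene_sets <- function(per_set, intersect_over = names(per_set),
                                min_support = NULL) {
  if (is.null(names(per_set)) || any(!nzchar(names(per_set)))) {
    abort_regulink("per_set must be a named list", "regulink_config_error")
  }
  if (!length(intersect_over)) {
    abort_regulink("intersect_over must be non-empty",
                   "regulink_config_error")
  }
  if (length(setdiff(intersect_over, names(per_set)))) {
    abort_regulink(
      sprintf("unknown set name(s) in intersect_over: %s",
              paste(setdiff(intersect_over, names(per_set)),
                    collapse = ", ")),
      "regulink_config_error"
    )
  }
  per_set <- lapply(per_set, function(s) sort(unique(normalize_symbols(s))))

  all_genes <- sort(unique(unlist(per_set, use.names = FALSE)))
  membership_all <- vapply(per_set, function(s) all_genes %in% s,
                           logical(length(all_genes)))
  if (length(all_genes) == 1) {
    membership_all <- matrix(membership_all, nrow = 1,
                             dimnames = list(NULL, names(per_set)))
  }
  support_counts <- if (length(all_genes)) {
    stats::setNames(as.integer(rowSums(membership_all)), all_genes)
  } else {
    stats::setNames(integer(0), character(0))
  }

  sel <- membership_all[, intersect_over, drop = FALSE]
  in_union <- if (length(all_genes)) rowSums(sel) > 0 else logical(0)
  sel_support <- if (length(all_genes)) rowSums(sel) else integer(0)

  k <- if (is.null(min_support)) length(intersect_over) else min_support
  if (k < 1 || k > length(intersect_over)) {
    abort_regulink("min_support out of range", "regulink_config_error")
  }
  intersection <- all_genes[sel_support >= k]

  ## every non-empty subset of intersect_over gets a (possibly zero) count
  n <- length(intersect_over)
  region_counts <- integer(0)
  for (mask in seq_len(2^n - 1)) {
    bits <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
    key <- paste(intersect_over[bits], collapse = "&")
    if (length(all_genes)) {
      in_region <- rowSums(sel[, bits, drop = FALSE]) == sum(bits) &
        sel_support == sum(bits)
      region_counts[key] <- sum(in_region)
    } else {
      region_counts[key] <- 0L
    }
  }

  structure(
    list(per_set = per_set, intersection = intersection,
         region_counts = region_counts, support_counts = support_counts,
         intersect_over = intersect_over, min_support = min_support,
         empty_sets = names(per_set)[lengths(per_set) == 0]),
    class = "prediction_result"
  )
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("<prediction_result> %d set(s), intersecting over %d\n",
              length(x$per_set), length(x$intersect_over)))
  for (nm in names(x$per_set)) {
    cat(sprintf("  %-18s %5d gene(s)%s\n", nm, length(x$per_set[[nm]]),
                if (nm %in% x$intersect_over) "  [intersected]" else ""))
  }
  cat(sprintf("  intersection: %d gene(s)\n", length(x$intersection)))
  if (length(x$empty_sets)) {
    cat(sprintf("  empty set(s): %s\n", paste(x$empty_sets, collapse = ", ")))
  }
  invisible(x)
}

#' Run a bidirectional prediction query over evidence sources
#'
#' Builds one gene set per selected source via [source_gene_set()], appends
#' the query's correlation sets verbatim as additional named sets, and
#' intersects over `intersect_over` (strict by default).
#'
#' @param query A [prediction_query()].
#' @param sources Named list of [source_table()] objects; must cover
#'   `query$sources`.
#' @return A `prediction_result` (see [intersect_gene_sets()]).
#' @export
predict_regulation <- function(query, sources) {
  stopifnot(inherits(query, "prediction_query"))
  missing <- setdiff(query$sources, names(sources))
  if (length(missing)) {
    abort_regulink(sprintf("source table(s) not loaded: %s",
                           paste(missing, collapse = ", ")),
                   "regulink_config_error")
  }
  per_set <- lapply(stats::setNames(query$sources, query$sources),
                    function(id) source_gene_set(sources[[id]], query))
  per_set <- c(per_set, query$correlation_sets)
  intersect_gene_sets(per_set, query$intersect_over, query$min_support)
}

#' Predict the target genes of a TF
#'
#' Convenience wrapper around [prediction_query()] + [predict_regulation()].
#'
#' @param tf TF gene symbol.
#' @param sources Named list of [source_table()] objects.
#' @param ... Passed to [prediction_query()] (`knocktf_lfc_threshold`,
#'   `correlation_sets`, `intersect_over`, ...).
#' @return A `prediction_result`.
#' @export
predict_targets <- function(tf, sources, ...) {
  q <- prediction_query(tf, "targets_of_tf", sources = names(sources), ...)
  predict_regulation(q, sources)
}

#' Predict the upstream TFs of a target gene
#'
#' @param gene Target gene symbol.
#' @param sources Named list of [source_table()] objects.
#' @param ... Passed to [prediction_query()] (`knocktf_down_only` is
#'   meaningful here).
#' @return A `prediction_result`.
#' @export
predict_regulators <- function(gene, sources, ...) {
  q <- prediction_query(gene, "regulators_of_gene",
                        sources = names(sources), ...)
  predict_regulation(q, sources)
}

#' Venn or petal summary of a prediction result
#'
#' Up to 5 intersected sets yield a Venn region table; 6-7 sets yield a
#' petal (flower-plot) summary of per-set sizes around the common core.
#'
#' @param result A `prediction_result`.
#' @return Object of class `venn_summary`: `type` (`"venn"` or `"petal"`),
#'   `regions` (data frame `region`, `count`; Venn only), `set_sizes`,
#'   `core_size`.
#' @export
venn_summary <- function(result) {
  stopifnot(inherits(result, "prediction_result"))
  n <- length(result$intersect_over)
  if (n < 1 || n > 7) {
    abort_regulink("venn_summary supports 1-7 sets",
                   "regulink_unsupported")
  }
  sizes <- lengths(result$per_set[result$intersect_over])
  core <- length(intersect_gene_sets(result$per_set,
                                     result$intersect_over)$intersection)
  if (n <= 5) {
    regions <- data.frame(region = names(result$region_counts),
                          count = as.integer(result$region_counts),
                          stringsAsFactors = FALSE)
    structure(list(type = "venn", regions = regions, set_sizes = sizes,
                   core_size = core), class = "venn_summary")
  } else {
    structure(list(type = "petal", regions = NULL, set_sizes = sizes,
                   core_size = core), class = "venn_summary")
  }
}

#' @export
print.venn_summary <- function(x, ...) {
  cat(sprintf("<venn_summary> type: %s, core: %d\n", x$type, x$core_size))
  if (x$type == "venn") {
    nz <- x$regions[x$regions$count > 0, , drop = FALSE]
    for (i in seq_len(nrow(nz))) {
      cat(sprintf("  %-40s %d\n", nz$region[i], nz$count[i]))
    }
  } else {
    for (nm in names(x$set_sizes)) {
      cat(sprintf("  %-18s %d\n", nm, x$set_sizes[[nm]]))
    }
  }
  invisible(x)
}

#' Plot a Venn/petal summary
#'
#' Basic base-graphics rendering: proportional circles with region counts
#' for 2-3 sets, a region barplot for 4-5 sets, and a flower layout of
#' per-set sizes around the common core for 6-7 sets.
#'
#' @param x A `venn_summary`.
#' @param ... Ignored.
#' @return `x`, invisibly.
#' @export
plot.venn_summary <- function(x, ...) {
  op <- graphics::par(mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  n <- length(x$set_sizes)
  if (x$type == "venn" && n <= 3) {
    centers <- switch(as.character(n),
                      "1" = matrix(c(0, 0), 1),
                      "2" = rbind(c(-0.45, 0), c(0.45, 0)),
                      "3" = rbind(c(-0.45, -0.3), c(0.45, -0.3), c(0, 0.5)))
    graphics::plot(NA, xlim = c(-1.6, 1.6), ylim = c(-1.5, 1.5),
                   axes = FALSE, xlab = "", ylab = "",
                   main = "Set intersections", asp = 1)
    for (i in seq_len(n)) {
      graphics::symbols(centers[i, 1], centers[i, 2], circles = 0.8,
                        inches = FALSE, add = TRUE,
                        fg = i + 1)
      graphics::text(centers[i, 1] * 1.9, centers[i, 2] * 1.9,
                     sprintf("%s (%d)", names(x$set_sizes)[i],
                             x$set_sizes[[i]]), col = i + 1)
    }
    graphics::text(0, -1.4,
                   sprintf("core: %d", x$core_size))
  } else if (x$type == "venn") {
    nz <- x$regions[x$regions$count > 0, , drop = FALSE]
    graphics::par(mar = c(9, 4, 2, 1))
    graphics::barplot(nz$count, names.arg = nz$region, las = 2,
                      main = "Venn region counts", ylab = "genes")
  } else {
    k <- length(x$set_sizes)
    theta <- seq(0, 2 * pi, length.out = k + 1)[-(k + 1)]
    graphics::plot(NA, xlim = c(-2, 2), ylim = c(-2, 2), axes = FALSE,
                   xlab = "", ylab = "", main = "Per-set sizes (petal)",
                   asp = 1)
    for (i in seq_len(k)) {
      graphics::symbols(cos(theta[i]), sin(theta[i]), circles = 0.6,
                        inches = FALSE, add = TRUE, fg = i + 1)
      graphics::text(1.6 * cos(theta[i]), 1.6 * sin(theta[i]),
                     sprintf("%s\n%d", names(x$set_sizes)[i],
                             x$set_sizes[[i]]), col = i + 1, cex = 0.8)
    }
    graphics::text(0, 0, sprintf("core\n%d", x$core_size))
  }
  invisible(x)
}

#' Write a prediction result to a directory of TSV files
#'
#' Writes one gene-set file per source, the intersection, and the
#' Venn-region count table.
#'
#' @param result A `prediction_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_prediction_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(result$per_set)) {
    write_gene_set(result$per_set[[nm]],
                   file.path(dir, paste0("set_", nm, ".txt")))
  }
  write_gene_set(result$intersection, file.path(dir, "intersection.txt"))
  write_tsv(data.frame(region = names(result$region_counts),
                       count = as.integer(result$region_counts),
                       stringsAsFactors = FALSE),
            file.path(dir, "region_counts.tsv"))
  invisible(dir)
}
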