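## Motif evidence channel: JASPAR PFM parsing, log-odds scoring of
## TSS-upstream promoter windows, and exact hit p-values from the null
## distribution of the score under the background model.

DNA_BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix (PWM)
#'
#' Wraps a 4 x L count matrix (rows A, C, G, T) together with a background
#' nucleotide distribution and a pseudocount. The pseudocount is distributed
#' across bases proportionally to the background when converting counts to
#' probabilities, so zero counts never produce infinite log-odds when
#' `pseudocount > 0`.
#'
#' @param counts Numeric 4 x L matrix of non-negative counts; rows may be
#'   named A/C/G/T (reordered if so) or are taken in that order.
#' @param motif_id Motif identifier (e.g. a JASPAR accession).
#' @param tf_name TF gene symbol associated with the motif (uppercased).
#' @param background Length-4 vector of positive base probabilities
#'   (A, C, G, T) summing to 1; default uniform.
#' @param pseudocount Non-negative total pseudocount per column; default 0.1.
#' @return Object of class `pwm`.
#' @export
pwm <- function(counts, motif_id = "motif", tf_name = motif_id,
                background = rep(0.25, 4), pseudocount = 0.1) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) {
    abort_regulink("PWM counts must have 4 rows (A, C, G, T)",
                   "regulink_format_error")
  }
  if (!is.null(rownames(counts)) &&
      setequal(rownames(counts), DNA_BASES)) {
    counts <- counts[DNA_BASES, , drop = FALSE]
  }
  rownames(counts) <- DNA_BASES
  if (any(!is.finite(counts)) || any(counts < 0)) {
    abort_regulink("PWM counts must be finite and non-negative",
                   "regulink_validation_error")
  }
  if (length(background) != 4 || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-12) {
    abort_regulink(
      "background must be 4 positive probabilities summing to 1",
      "regulink_validation_error"
    )
  }
  if (pseudocount < 0) {
    abort_regulink("pseudocount must be non-negative",
                   "regulink_validation_error")
  }
  if (any(colSums(counts) + pseudocount <= 0)) {
    abort_regulink("every PWM column must have positive total count after pseudocount",
                   "regulink_validation_error")
  }
  structure(
    list(motif_id = motif_id, tf_name = toupper(tf_name),
         counts = counts, background = as.numeric(background),
         pseudocount = pseudocount),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s (%s), length %d\n",
              x$motif_id, x$tf_name, ncol(x$counts)))
  invisible(x)
}

motif_length <- function(pwm) ncol(pwm$counts)

#' Consensus sequence of a PWM (highest count per column, ties to the
#' first base in A, C, G, T order).
#' @param x A [pwm()].
#' @return Character scalar.
#' @export
pwm_consensus <- function(x) {
  paste(DNA_BASES[apply(x$counts, 2, which.max)], collapse = "")
}

#' Read motifs from a JASPAR-format PFM file
#'
#' Parses the plain-text JASPAR format: a `>ID NAME` header followed by four
#' count rows, either bare numbers or `A [ 1 2 3 ]` style with base labels
#' and brackets.
#'
#' @param path Path to the JASPAR file.
#' @param background,pseudocount Passed to [pwm()] for every record.
#' @return Named list of [pwm()] objects in file order (names = motif ids).
#' @export
read_jaspar <- function(path, background = rep(0.25, 4), pseudocount = 0.1) {
  if (!file.exists(path)) {
    abort_regulink(sprintf("file not found: %s", path), "regulink_io_error")
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (length(starts) == 0) {
    abort_regulink("no JASPAR records found (missing '>' headers)",
                   "regulink_format_error")
  }
  ends <- c(starts[-1] - 1, length(lines))
  out <- list()
  for (i in seq_along(starts)) {
    block <- lines[starts[i]:ends[i]]
    header <- sub("^>\\s*", "", block[1])
    fields <- strsplit(trimws(header), "\\s+")[[1]]
    motif_id <- fields[1]
    tf_name <- if (length(fields) >= 2) {
      paste(fields[-1], collapse = "_")
    } else {
      motif_id
    }
    rows <- block[-1]
    if (length(rows) != 4) {
      abort_regulink(
        sprintf("record %s has %d count rows; expected 4", motif_id,
                length(rows)),
        "regulink_format_error"
      )
    }
    counts <- vector("list", 4)
    labels <- character(4)
    for (k in seq_len(4)) {
      row <- gsub("[][]", " ", rows[k])
      toks <- strsplit(trimws(row), "\\s+")[[1]]
      if (toupper(toks[1]) %in% DNA_BASES) {
        labels[k] <- toupper(toks[1])
        toks <- toks[-1]
      }
      vals <- suppressWarnings(as.numeric(toks))
      if (anyNA(vals)) {
        abort_regulink(
          sprintf("non-numeric count in record %s row %d", motif_id, k),
          "regulink_parse_error"
        )
      }
      counts[[k]] <- vals
    }
    if (length(unique(lengths(counts))) != 1) {
      abort_regulink(
        sprintf("record %s has count rows of unequal length", motif_id),
        "regulink_format_error"
      )
    }
    mat <- do.call(rbind, counts)
    if (all(nzchar(labels))) rownames(mat) <- labels
    out[[motif_id]] <- pwm(mat, motif_id = motif_id, tf_name = tf_name,
                           background = background,
                           pseudocount = pseudocount)
  }
  out
}

#' Write motifs to a JASPAR-format PFM file
#' @param pwms List of [pwm()] objects.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_jaspar <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(sprintf(">%s %s", p$motif_id, p$tf_name), con)
    for (b in DNA_BASES) {
      writeLines(sprintf("%s [ %s ]", b,
                         paste(format(p$counts[b, ], trim = TRUE),
                               collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Log-odds scoring matrix of a PWM
#'
#' Entry `[b, j]` is
#' `log2((counts[b, j] + pseudocount * background[b]) / colsum_j / background[b])`
#' where `colsum_j` is the pseudocount-adjusted column total, i.e. the log2
#' likelihood ratio of base `b` at position `j` under the motif versus the
#' background.
#'
#' @param x A [pwm()].
#' @return 4 x L numeric matrix (rows A, C, G, T), in log2 units.
#' @export
log_odds <- function(x) {
  stopifnot(inherits(x, "pwm"))
  adj <- x$counts + x$pseudocount * matrix(x$background, 4, ncol(x$counts))
  freq <- sweep(adj, 2, colSums(adj), "/")
  log2(freq / x$background)
}

#' Null distribution of the log-odds score under the background model
#'
#' Computes the distribution of the score of a random L-mer whose bases are
#' drawn i.i.d. from the background, by position-wise convolution. While the
#' number of distinct attainable score sums stays below `max_exact`, the
#' convolution is carried out on the exact score values; longer motifs fall
#' back to a discretized grid of at least `grid` bins spanning the
#' attainable score range, with p-values then read conservatively from the
#' bin containing the query score.
#'
#' @param lom 4 x L log-odds matrix from [log_odds()].
#' @param background Length-4 base probability vector.
#' @param grid Number of discretization bins for the grid fallback
#'   (minimum 1000; default 10000).
#' @param max_exact State-count cap for the exact convolution.
#' @return Object of class `score_distribution` with sorted `support`,
#'   `prob`, and a query tolerance; use [tail_prob()] to evaluate
#'   `P(score >= s)`.
#' @export
score_null_distribution <- function(lom, background = rep(0.25, 4),
                                    grid = 10000L, max_exact = 100000L) {
  lom <- as.matrix(lom)
  stopifnot(nrow(lom) == 4)
  if (grid < 1000) {
    abort_regulink("grid must be at least 1000 bins",
                   "regulink_validation_error")
  }
  L <- ncol(lom)

  ## exact convolution over distinct score sums
  support <- 0
  prob <- 1
  exact <- TRUE
  for (j in seq_len(L)) {
    ns <- as.vector(outer(support, lom[, j], "+"))
    np <- as.vector(outer(prob, background))
    o <- order(ns)
    ns <- ns[o]
    np <- np[o]
    d <- diff(ns)
    d[is.na(d)] <- 0  # -Inf minus -Inf (possible at pseudocount 0)
    grp <- cumsum(c(TRUE, d > 1e-9))
    support <- ns[!duplicated(grp)]
    prob <- as.vector(rowsum(np, grp))
    if (length(support) > max_exact) {
      exact <- FALSE
      break
    }
  }

  if (!exact) {
    mins <- apply(lom, 2, min)
    smin <- sum(mins)
    smax <- sum(apply(lom, 2, max))
    unit <- (smax - smin) / grid
    if (unit <= 0) {  # degenerate: single attainable score
      return(structure(list(support = smin, prob = 1, tol = 1e-9,
                            method = "exact"),
                       class = "score_distribution"))
    }
    k <- round(sweep(lom, 2, mins) / unit)  # 4 x L non-negative integers
    pv <- 1
    offset <- 0  # score of index 1 in pv is smin + offset * unit (offset=0)
    for (j in seq_len(L)) {
      newlen <- length(pv) + max(k[, j])
      acc <- numeric(newlen)
      for (b in 1:4) {
        idx <- seq_along(pv) + k[b, j]
        acc[idx] <- acc[idx] + pv * background[b]
      }
      pv <- acc
    }
    support <- smin + unit * (seq_along(pv) - 1)
    keep <- pv > 0
    return(structure(
      list(support = support[keep], prob = pv[keep],
           tol = unit * L / 2 + 1e-12, method = "grid"),
      class = "score_distribution"
    ))
  }

  structure(list(support = support, prob = prob, tol = 1e-9,
                 method = "exact"),
            class = "score_distribution")
}

#' @export
print.score_distribution <- function(x, ...) {
  cat(sprintf("<score_distribution> %s, %d support points, range [%.3f, %.3f]\n",
              x$method, length(x$support), min(x$support), max(x$support)))
  invisible(x)
}

#' Tail probability P(score >= s) of a score null distribution
#'
#' @param dist A `score_distribution` from [score_null_distribution()].
#' @param s Numeric vector of query scores.
#' @return Numeric vector of tail probabilities in `[0, 1]`; conservative
#'   (never smaller than the exact value beyond the distribution's stated
#'   discretization tolerance).
#' @export
tail_prob <- function(dist, s) {
  stopifnot(inherits(dist, "score_distribution"))
  tails <- rev(cumsum(rev(dist$prob)))
  vapply(s, function(si) {
    idx <- findInterval(si - dist$tol, dist$support, left.open = TRUE) + 1
    if (idx > length(dist$support)) 0 else min(tails[idx], 1)
  }, numeric(1))
}

## integer codes 1..4 for A,C,G,T; NA for N
encode_dna <- function(seq_chr, record_name) {
  chars <- strsplit(seq_chr, "")[[1]]
  bad <- setdiff(unique(chars), c(DNA_BASES, "N"))
  if (length(bad)) {
    abort_regulink(
      sprintf("record '%s' contains non-ACGTN character(s): %s",
              record_name, paste(bad, collapse = ", ")),
      "regulink_validation_error"
    )
  }
  match(chars, DNA_BASES)
}

## score every offset of an encoded sequence; windows containing N give NA
score_offsets <- function(code, lom) {
  L <- ncol(lom)
  W <- length(code)
  n_off <- W - L + 1
  if (n_off < 1) return(numeric(0))
  sc <- numeric(n_off)
  for (j in seq_len(L)) {
    sc <- sc + lom[cbind(code[j:(n_off + j - 1)], j)]
  }
  sc
}

#' Scan promoter sequences for motif occurrences
#'
#' Scores both strands of every promoter window at every offset with the
#' log-odds matrix of each PWM, assigns each position an exact p-value
#' (probability that a random background L-mer scores at least as high) and
#' keeps positions with `pvalue < p_threshold`. Reverse-strand scores are
#' computed on the reverse complement; reported offsets are always 0-based
#' starts of the matching window on the input (forward) sequence. No
#' per-promoter multiple-testing correction is applied: a TF-gene edge is
#' emitted whenever at least one sub-threshold hit exists.
#'
#' @param pwms A [pwm()], or a list of them (as from [read_jaspar()]).
#' @param promoters Path to a promoter FASTA file (records named by gene
#'   symbol; typically TSS-upstream windows) or a
#'   [Biostrings::DNAStringSet].
#' @param p_threshold Hit p-value threshold in (0, 1); default `1e-4`.
#' @param source_id Source identifier for the resulting table.
#' @return A [source_table()] of class `"motif"`; its `edges` carry the best
#'   hit score and smallest p-value per TF-gene pair, and component `hits`
#'   is a data frame of all individual hits (`motif_id`, `tf`, `gene`,
#'   `offset`, `strand`, `score`, `pvalue`).
#' @export
scan_promoters <- function(pwms, promoters, p_threshold = 1e-4,
                           source_id = "motif_scan") {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  stopifnot(all(vapply(pwms, inherits, logical(1), "pwm")))
  if (!(p_threshold > 0 && p_threshold < 1)) {
    abort_regulink("p_threshold must lie in (0, 1)",
                   "regulink_validation_error")
  }
  if (is.character(promoters)) {
    promoters <- Biostrings::readDNAStringSet(promoters)
  }
  stopifnot(inherits(promoters, "DNAStringSet"))
  genes <- normalize_symbols(sub("\\s.*$", "", names(promoters)))

  seq_chr <- as.character(promoters)
  hits <- list()
  n_skipped <- 0L
  for (p in pwms) {
    lom <- log_odds(p)
    L <- ncol(lom)
    dist <- score_null_distribution(lom, p$background)
    tails <- rev(cumsum(rev(dist$prob)))
    pass <- which(tails < p_threshold)
    s_min <- if (length(pass)) dist$support[min(pass)] else Inf

    for (i in seq_along(seq_chr)) {
      code <- encode_dna(seq_chr[i], names(promoters)[i])
      W <- length(code)
      if (W < L) next
      for (strand in c("+", "-")) {
        cc <- if (strand == "+") code else rev(5L - code)
        sc <- score_offsets(cc, lom)
        n_na <- sum(is.na(sc))
        if (n_na > 0) n_skipped <- n_skipped + n_na
        hit_off <- which(!is.na(sc) & sc >= s_min - dist$tol)
        if (!length(hit_off)) next
        pv <- tail_prob(dist, sc[hit_off])
        keep <- pv < p_threshold
        if (!any(keep)) next
        off0 <- hit_off[keep] - 1L  # 0-based on scanned strand
        offsets <- if (strand == "+") off0 else (W - L - off0)
        hits[[length(hits) + 1]] <- data.frame(
          motif_id = p$motif_id, tf = p$tf_name, gene = genes[i],
          offset = offsets, strand = strand,
          score = sc[hit_off][keep], pvalue = pmax(pv[keep], .Machine$double.xmin),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (n_skipped > 0) {
    message(sprintf("scan_promoters: %d window(s) containing N skipped",
                    n_skipped))
  }
  hits <- if (length(hits)) do.call(rbind, hits) else
    data.frame(motif_id = character(), tf = character(), gene = character(),
               offset = integer(), strand = character(), score = numeric(),
               pvalue = numeric(), stringsAsFactors = FALSE)
  hits <- hits[order(hits$tf, hits$gene, hits$offset, hits$strand), ,
               drop = FALSE]
  rownames(hits) <- NULL

  if (nrow(hits)) {
    best <- do.call(rbind, lapply(
      split(hits, paste(hits$tf, hits$gene, sep = "\r")),
      function(h) data.frame(tf = h$tf[1], target = h$gene[1],
                             score = max(h$score), pvalue = min(h$pvalue),
                             stringsAsFactors = FALSE)
    ))
  } else {
    best <- data.frame(tf = character(), target = character(),
                       score = numeric(), pvalue = numeric(),
                       stringsAsFactors = FALSE)
  }
  st <- source_table(best, source_id, "motif")
  st$hits <- hits
  st
}

#' Write motif hits as TSV or BED6
#'
#' @param scan A motif [source_table()] from [scan_promoters()].
#' @param path Output path.
#' @param format `"tsv"` (full hit table) or `"bed"` (BED6: chrom = gene,
#'   name = motif id, score = `round(100 * score)`, strand).
#' @param motif_lengths Named integer vector of motif lengths (required for
#'   BED end coordinates); taken from hit score context if supplied.
#' @return The path, invisibly.
#' @export
write_motif_hits <- function(scan, path, format = c("tsv", "bed"),
                             motif_lengths = NULL) {
  format <- match.arg(format)
  hits <- scan$hits
  if (format == "tsv") {
    return(write_tsv(hits, path))
  }
  if (is.null(motif_lengths)) {
    abort_regulink("motif_lengths required for BED output",
                   "regulink_validation_error")
  }
  len <- motif_lengths[hits$motif_id]
  bed <- data.frame(chrom = hits$gene, start = hits$offset,
                    end = hits$offset + as.integer(len),
                    name = hits$motif_id,
                    score = round(100 * hits$score),
                    strand = hits$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
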