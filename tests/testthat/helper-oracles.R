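## Independent oracles used across the suite. Each re-derives the expected
## quantity from first principles (enumeration, direct formulas, naive set
## arithmetic) without touching the implementation path it checks.

## Tail probabilities of the log-odds score by exhaustive enumeration of
## all 4^L words under the background model.
enum_tails <- function(lom, background, scores) {
  L <- ncol(lom)
  words <- as.matrix(expand.grid(rep(list(1:4), L)))
  ws <- rowSums(vapply(seq_len(L), function(j) lom[words[, j], j],
                       numeric(nrow(words))))
  wp <- exp(rowSums(vapply(seq_len(L), function(j)
    log(background[words[, j]]), numeric(nrow(words)))))
  vapply(scores, function(s) sum(wp[ws >= s - 1e-9]), numeric(1))
}

## distinct achievable word scores of a log-odds matrix
enum_scores <- function(lom) {
  L <- ncol(lom)
  words <- as.matrix(expand.grid(rep(list(1:4), L)))
  sort(unique(rowSums(vapply(seq_len(L), function(j) lom[words[, j], j],
                             numeric(nrow(words))))))
}

## Product-moment correlation and t-based two-sided p, straight from the
## formulas (Spearman = the same on average ranks).
direct_cor <- function(x, y, method = "pearson") {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (method == "spearman") {
    x <- rank(x)
    y <- rank(y)
  }
  n <- length(x)
  dx <- x - mean(x)
  dy <- y - mean(y)
  r <- sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
  tval <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, pvalue = 2 * stats::pt(-abs(tval), n - 2), n = n)
}

## Naive set arithmetic: strict intersection, support counts over all
## sets, and per-region counts over the selected sets.
naive_set_summary <- function(sets, over) {
  sets <- lapply(sets, unique)
  inter <- Reduce(intersect, sets[over])
  support <- table(unlist(lapply(sets, unique), use.names = FALSE))
  union_sel <- Reduce(union, sets[over])
  n <- length(over)
  regions <- integer(0)
  for (mask in seq_len(2^n - 1)) {
    bits <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
    inside <- over[bits]
    outside <- over[!bits]
    members <- Reduce(intersect, sets[inside])
    for (o in outside) members <- setdiff(members, sets[[o]])
    regions[paste(inside, collapse = "&")] <- length(members)
  }
  list(intersection = sort(inter), support = support, regions = regions,
       union_size = length(union_sel))
}

## small evidence table builders
chip_table <- function(tf, targets, source_id = "chip_src") {
  source_table(data.frame(tf = tf, target = targets,
                          stringsAsFactors = FALSE),
               source_id, "chip")
}

knockdown_table <- function(tf, targets, log2fc,
                            source_id = "knocktf") {
  source_table(data.frame(tf = tf, target = targets, log2fc = log2fc,
                          stringsAsFactors = FALSE),
               source_id, "knockdown")
}

write_evidence_file <- function(rows, path) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  path
}

random_gene_sets <- function(n_sets, universe, size) {
  sets <- lapply(seq_len(n_sets), function(i)
    sample(universe, min(size, length(universe))))
  names(sets) <- paste0("SET", seq_len(n_sets))
  sets
}
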