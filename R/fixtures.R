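## Seeded synthetic-fixture generator: schema-identical evidence tables,
## JASPAR motif files, promoter FASTA with planted binding sites,
## expression matrices with planted TF-gene correlations, and DEG tables
## embedding a planted regulatory network. One integer seed drives one
## named pseudo-random stream per output, so adding an output never
## perturbs the others, and every ground truth is recorded in a manifest.

#' Default evidence sources emulated by the fixture generator
#'
#' Two ChIP-seq-style sources, one knockdown source, one curated source and
#' one further ChIP source, mirroring the mix of evidence classes found in
#' public TF-target compendia.
#'
#' @format Data frame with columns `id` and `class`.
#' @export
DEFAULT_FIXTURE_SOURCES <- data.frame(
  id = c("htftarget", "chip_atlas", "knocktf", "trrust", "encode"),
  class = c("chip", "chip", "knockdown", "curated", "chip"),
  stringsAsFactors = FALSE
)

#' Specify a synthetic fixture
#'
#' Declares the universes (TFs, genes, cohorts, samples), the evidence
#' sources to emulate, and the planted ground truth (edges, expression
#' correlations, motif sites, differential expression). The seed fully
#' determines every generated byte.
#'
#' @param seed Integer master seed.
#' @param n_tfs,n_genes Sizes of the TF and gene universes (symbols
#'   `TF01..` and `G0001..`).
#' @param n_cohorts,n_samples_per_cohort Cohort structure of the expression
#'   fixture (labels `COHORT1..`; within each cohort, alternate samples are
#'   labelled tumor).
#' @param sources Data frame (`id`, `class`) of evidence sources to
#'   generate; default emulates two ChIP sources, one knockdown, one
#'   curated, one more ChIP.
#' @param planted_edges Data frame (`tf`, `target`, `sources`) where
#'   `sources` is a comma-separated subset of source ids the edge must
#'   appear in.
#' @param decoy_rate Decoy density per source in `[0, 1)`: each source
#'   receives `round(decoy_rate * n_genes)` uniformly drawn decoy edges
#'   that never collide with any planted pair.
#' @param planted_correlations Data frame (`tf`, `gene`, `cohort`, `rho`,
#'   optionally `group` in all/tumor/normal) of pairs to generate from a
#'   bivariate normal with the requested correlation; the optional group
#'   restricts the planted signal to tumor or normal samples (the rest stay
#'   independent).
#' @param planted_motifs Data frame (`motif_id`, `gene`, `offset`,
#'   `strand`) of consensus sites to write into promoter windows.
#' @param motifs Optional data frame (`motif_id`, `tf_name`, `length`)
#'   describing the motifs to synthesize; defaults to strong 8-bp motifs,
#'   one per distinct `motif_id` in `planted_motifs`, named after `TF01`,
#'   `TF02`, ... in order.
#' @param de_spec Data frame (`gene`, `log2fc`, `pvalue`) of planted DEG
#'   rows.
#' @param n_filler_genes DEG rows added below any reasonable DEG threshold
#'   (`|log2fc| < 0.5`, `p > 0.2`); default 500.
#' @param n_promoter_decoys Promoters generated for genes without planted
#'   sites (default 20).
#' @param promoter_window Promoter window length in bp (default 2000, the
#'   TSS-upstream window size).
#' @param background Background base probabilities (A, C, G, T) for
#'   promoter sequence generation and motif models.
#' @return Object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_tfs = 50L, n_genes = 2000L,
                         n_cohorts = 5L, n_samples_per_cohort = 200L,
                         sources = DEFAULT_FIXTURE_SOURCES,
                         planted_edges = NULL, decoy_rate = 0.25,
                         planted_correlations = NULL,
                         planted_motifs = NULL, motifs = NULL,
                         de_spec = NULL, n_filler_genes = 500L,
                         n_promoter_decoys = 20L,
                         promoter_window = 2000L,
                         background = rep(0.25, 4)) {
  if (decoy_rate < 0 || decoy_rate >= 1) {
    abort_regulink("decoy_rate must lie in [0, 1)", "regulink_spec_error")
  }
  tfs <- sprintf("TF%0*d", max(2, nchar(n_tfs)), seq_len(n_tfs))
  genes <- sprintf("G%0*d", max(4, nchar(n_genes)), seq_len(n_genes))
  cohorts <- paste0("COHORT", seq_len(n_cohorts))
  universe <- c(tfs, genes)

  check_symbols <- function(x, what) {
    bad <- setdiff(normalize_symbols(x), universe)
    if (length(bad)) {
      abort_regulink(
        sprintf("%s reference symbol(s) outside the declared universe: %s",
                what, paste(utils::head(bad, 5), collapse = ", ")),
        "regulink_spec_error"
      )
    }
  }
  if (!is.null(planted_edges)) {
    check_symbols(planted_edges$tf, "planted_edges")
    check_symbols(planted_edges$target, "planted_edges")
    listed <- unique(unlist(strsplit(planted_edges$sources, ",")))
    if (length(setdiff(trimws(listed), sources$id))) {
      abort_regulink("planted_edges name undeclared source id(s)",
                     "regulink_spec_error")
    }
  }
  if (!is.null(planted_correlations)) {
    check_symbols(planted_correlations$tf, "planted_correlations")
    check_symbols(planted_correlations$gene, "planted_correlations")
    if (any(abs(planted_correlations$rho) >= 1)) {
      abort_regulink("planted rho must lie strictly inside (-1, 1)",
                     "regulink_spec_error")
    }
    if (is.null(planted_correlations$group)) {
      planted_correlations$group <- "all"
    }
    if (length(setdiff(planted_correlations$group,
                       c("all", "tumor", "normal")))) {
      abort_regulink("planted correlation group must be all/tumor/normal",
                     "regulink_spec_error")
    }
    if (length(setdiff(planted_correlations$cohort, cohorts))) {
      abort_regulink("planted correlation names an undeclared cohort",
                     "regulink_spec_error")
    }
  }
  if (!is.null(de_spec)) check_symbols(de_spec$gene, "de_spec")
  if (!is.null(planted_motifs)) {
    check_symbols(planted_motifs$gene, "planted_motifs")
    if (any(!planted_motifs$strand %in% c("+", "-"))) {
      abort_regulink("planted motif strand must be '+' or '-'",
                     "regulink_spec_error")
    }
  }

  structure(
    list(seed = as.integer(seed), n_tfs = n_tfs, n_genes = n_genes,
         n_cohorts = n_cohorts,
         n_samples_per_cohort = n_samples_per_cohort,
         tfs = tfs, genes = genes, cohorts = cohorts,
         sources = sources, planted_edges = planted_edges,
         decoy_rate = decoy_rate,
         planted_correlations = planted_correlations,
         planted_motifs = planted_motifs, motifs = motifs,
         de_spec = de_spec, n_filler_genes = n_filler_genes,
         n_promoter_decoys = n_promoter_decoys,
         promoter_window = promoter_window,
         background = background),
    class = "fixture_spec"
  )
}

#' @export
print.fixture_spec <- function(x, ...) {
  cat(sprintf(
    "<fixture_spec> seed %d: %d TFs, %d genes, %d cohort(s) x %d sample(s)\n",
    x$seed, x$n_tfs, x$n_genes, x$n_cohorts, x$n_samples_per_cohort))
  invisible(x)
}

## planted (tf, target) pairs as linear indices into the tf x gene grid
planted_pair_index <- function(spec) {
  if (is.null(spec$planted_edges)) return(integer(0))
  ti <- match(normalize_symbols(spec$planted_edges$tf), spec$tfs)
  gi <- match(normalize_symbols(spec$planted_edges$target), spec$genes)
  ## planted targets may themselves be TFs; those pairs cannot collide with
  ## decoys (drawn over the gene universe) and are ignored here
  ok <- !is.na(ti) & !is.na(gi)
  (ti[ok] - 1L) * spec$n_genes + gi[ok]
}

#' Generate synthetic evidence source tables
#'
#' Each planted edge appears in exactly its listed sources; decoy edges are
#' drawn uniformly over the TF x gene grid, never colliding with planted
#' pairs. Knockdown sources carry log2 fold-changes: planted edges get a
#' negative value of magnitude in `[0.8, 2.5]` (a clear, activation-
#' consistent knockdown response), decoys get `Uniform(-2, 2)`.
#'
#' @param spec A [fixture_spec()].
#' @param dir Optional directory; when given, one `evidence_<id>.tsv` per
#'   source is written with the default schema column names.
#' @return List with `tables` (named list of [source_table()]), `manifest`
#'   (planted and decoy ground truth), and `paths` when `dir` is given.
#' @export
make_evidence <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  n_decoys <- round(spec$decoy_rate * spec$n_genes)
  n_pairs <- spec$n_tfs * spec$n_genes
  planted_idx <- planted_pair_index(spec)
  if (n_decoys > n_pairs - length(planted_idx)) {
    abort_regulink("universe too small for the requested decoys",
                   "regulink_capacity_error")
  }

  planted_by_source <- function(id) {
    pe <- spec$planted_edges
    if (is.null(pe)) {
      return(data.frame(tf = character(), target = character(),
                        stringsAsFactors = FALSE))
    }
    in_src <- vapply(strsplit(pe$sources, ","), function(s)
      id %in% trimws(s), logical(1))
    data.frame(tf = normalize_symbols(pe$tf[in_src]),
               target = normalize_symbols(pe$target[in_src]),
               stringsAsFactors = FALSE)
  }

  tables <- list()
  decoy_manifest <- list()
  for (i in seq_len(nrow(spec$sources))) {
    id <- spec$sources$id[i]
    cls <- spec$sources$class[i]
    set.seed(stream_seed(spec$seed, paste0("evidence:", id)))

    planted <- planted_by_source(id)
    decoys <- data.frame(tf = character(), target = character(),
                         stringsAsFactors = FALSE)
    if (n_decoys > 0) {
      idx <- integer(0)
      while (length(idx) < n_decoys) {
        cand <- sample.int(n_pairs, n_decoys - length(idx) + 10L,
                           replace = TRUE)
        cand <- setdiff(unique(cand), c(planted_idx, idx))
        idx <- c(idx, cand)
      }
      idx <- idx[seq_len(n_decoys)]
      decoys <- data.frame(
        tf = spec$tfs[(idx - 1L) %/% spec$n_genes + 1L],
        target = spec$genes[(idx - 1L) %% spec$n_genes + 1L],
        stringsAsFactors = FALSE
      )
    }
    edges <- rbind(planted, decoys)
    n_p <- nrow(planted)
    n_all <- nrow(edges)
    if (cls == "knockdown") {
      edges$log2fc <- c(-stats::runif(n_p, 0.8, 2.5),
                        stats::runif(n_all - n_p, -2, 2))
    }
    if (cls == "curated") {
      edges$mode <- sample(c("activation", "repression", "unknown"),
                           n_all, replace = TRUE, prob = c(0.5, 0.3, 0.2))
    }
    if (cls %in% c("chip", "motif")) {
      edges$score <- round(stats::runif(n_all, 1, 100), 3)
      edges$pvalue <- signif(stats::runif(n_all, 1e-6, 0.05), 4)
    }
    tables[[id]] <- source_table(edges, id, cls)
    decoy_manifest[[id]] <- decoys
  }

  out <- list(
    tables = tables,
    manifest = list(planted_edges = spec$planted_edges,
                    decoys = decoy_manifest,
                    n_decoys_per_source = n_decoys)
  )
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- character(0)
    for (id in names(tables)) {
      e <- tables[[id]]$edges
      raw <- data.frame(tf = e$tf, target = e$target, log2FC = e$log2fc,
                        mode = e$mode, score = e$score, p_value = e$pvalue,
                        stringsAsFactors = FALSE)
      p <- file.path(dir, paste0("evidence_", id, ".tsv"))
      write_tsv(raw, p)
      paths[id] <- p
    }
    out$paths <- paths
  }
  out
}

#' Generate a synthetic expression matrix with planted correlations
#'
#' Every gene gets an independent baseline (mean `Uniform(2, 10)`, unit
#' residual standard deviation, log-expression scale). Each planted
#' (tf, gene, cohort, rho) pair is rebuilt from a bivariate normal so that
#' the gene's values in the chosen cohort (optionally only its tumor or
#' normal samples) have population correlation `rho` with the TF; all
#' unplanted pairs are independent.
#'
#' @param spec A [fixture_spec()].
#' @return An [expression_matrix()] over `c(tfs, genes)` with cohort and
#'   alternating tumor/normal annotations.
#' @export
make_expression <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(stream_seed(spec$seed, "expression"))
  rows <- c(spec$tfs, spec$genes)
  n_samples <- spec$n_cohorts * spec$n_samples_per_cohort
  samples <- sprintf("S%05d", seq_len(n_samples))
  ann <- data.frame(
    sample = samples,
    cohort = rep(spec$cohorts, each = spec$n_samples_per_cohort),
    tissue = rep(paste0("TISSUE", seq_len(spec$n_cohorts)),
                 each = spec$n_samples_per_cohort),
    is_tumor = rep(rep(c(TRUE, FALSE),
                       length.out = spec$n_samples_per_cohort),
                   times = spec$n_cohorts),
    stringsAsFactors = FALSE
  )
  mu <- stats::runif(length(rows), 2, 10)
  vals <- matrix(stats::rnorm(length(rows) * n_samples), length(rows),
                 n_samples, dimnames = list(rows, samples)) + mu

  pc <- spec$planted_correlations
  if (!is.null(pc)) {
    for (i in seq_len(nrow(pc))) {
      tf <- normalize_symbols(pc$tf[i])
      gene <- normalize_symbols(pc$gene[i])
      rho <- pc$rho[i]
      cols <- ann$cohort == pc$cohort[i]
      if (pc$group[i] == "tumor") cols <- cols & ann$is_tumor
      if (pc$group[i] == "normal") cols <- cols & !ann$is_tumor
      if (tf == gene) next  # self-pair: r = 1 by construction
      z <- as.numeric(scale(vals[tf, cols]))
      vals[gene, cols] <- mu[match(gene, rows)] +
        rho * z + sqrt(1 - rho^2) * stats::rnorm(sum(cols))
    }
  }
  expression_matrix(round(vals, 6), ann)
}

default_fixture_motifs <- function(spec) {
  ids <- unique(spec$planted_motifs$motif_id)
  ## length 10 so the consensus p-value (4^-10 under a uniform background)
  ## clears even a 1e-6 scan threshold
  data.frame(motif_id = ids,
             tf_name = spec$tfs[seq_along(ids)],
             length = 10L, stringsAsFactors = FALSE)
}

#' Generate promoter sequences and motif models with planted sites
#'
#' Builds one strong PWM per motif (dominant base count 97 against 1s, so
#' the consensus is unambiguous), then writes i.i.d. background promoter
#' windows for every gene carrying a planted site plus
#' `spec$n_promoter_decoys` site-free genes, embedding the motif consensus
#' (or its reverse complement on the minus strand) at each planted offset.
#'
#' @param spec A [fixture_spec()] with `planted_motifs`.
#' @param dir Optional directory; writes `promoters.fa` and
#'   `motifs.jaspar` when given.
#' @return List with `promoters` ([Biostrings::DNAStringSet]), `pwms`
#'   (list of [pwm()]), `manifest` (planted sites), and `paths` when `dir`
#'   is given.
#' @export
make_promoters <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (is.null(spec$planted_motifs)) {
    abort_regulink("fixture spec has no planted_motifs",
                   "regulink_spec_error")
  }
  set.seed(stream_seed(spec$seed, "promoters"))
  motifs <- if (is.null(spec$motifs)) default_fixture_motifs(spec) else
    spec$motifs
  W <- spec$promoter_window

  pwms <- list()
  for (i in seq_len(nrow(motifs))) {
    L <- motifs$length[i]
    dominant <- sample.int(4, L, replace = TRUE)
    counts <- matrix(1, 4, L, dimnames = list(DNA_BASES, NULL))
    counts[cbind(dominant, seq_len(L))] <- 97
    pwms[[motifs$motif_id[i]]] <- pwm(
      counts, motif_id = motifs$motif_id[i],
      tf_name = motifs$tf_name[i], background = spec$background
    )
  }

  pm <- spec$planted_motifs
  pm$gene <- normalize_symbols(pm$gene)
  lens <- vapply(pwms[pm$motif_id], motif_length, integer(1))
  if (any(pm$offset < 0 | pm$offset + lens > W)) {
    abort_regulink("planted motif offset outside the promoter window",
                   "regulink_spec_error")
  }
  for (g in unique(pm$gene)) {  # reject overlapping plants within a gene
    sub <- pm[pm$gene == g, , drop = FALSE]
    if (nrow(sub) > 1) {
      o <- order(sub$offset)
      starts <- sub$offset[o]
      ends <- starts + lens[pm$gene == g][o]
      if (any(starts[-1] < ends[-length(ends)])) {
        abort_regulink(sprintf("overlapping planted sites in gene %s", g),
                       "regulink_spec_error")
      }
    }
  }

  decoy_pool <- setdiff(spec$genes, pm$gene)
  n_decoy <- min(spec$n_promoter_decoys, length(decoy_pool))
  promoter_genes <- c(sort(unique(pm$gene)),
                      sort(sample(decoy_pool, n_decoy)))
  seqs <- character(length(promoter_genes))
  for (i in seq_along(promoter_genes)) {
    g <- promoter_genes[i]
    chars <- sample(DNA_BASES, W, replace = TRUE, prob = spec$background)
    sub <- pm[pm$gene == g, , drop = FALSE]
    for (k in seq_len(nrow(sub))) {
      cons <- pwm_consensus(pwms[[sub$motif_id[k]]])
      if (sub$strand[k] == "-") {
        cons <- as.character(
          Biostrings::reverseComplement(Biostrings::DNAString(cons))
        )
      }
      at <- sub$offset[k] + seq_len(nchar(cons))
      chars[at] <- strsplit(cons, "")[[1]]
    }
    seqs[i] <- paste(chars, collapse = "")
  }
  promoters <- Biostrings::DNAStringSet(stats::setNames(seqs,
                                                        promoter_genes))
  out <- list(promoters = promoters, pwms = pwms,
              manifest = list(planted_motifs = pm,
                              motif_tf = stats::setNames(motifs$tf_name,
                                                         motifs$motif_id)))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    fa <- file.path(dir, "promoters.fa")
    jp <- file.path(dir, "motifs.jaspar")
    Biostrings::writeXStringSet(promoters, fa)
    write_jaspar(pwms, jp)
    out$paths <- c(promoters = fa, motifs = jp)
  }
  out
}

#' Generate a synthetic DEG table
#'
#' Exactly the `de_spec` rows, plus `n_filler_genes` filler genes whose
#' `|log2fc| < 0.5` and `p > 0.2` keep them below any customary DEG
#' threshold.
#'
#' @param spec A [fixture_spec()].
#' @return A [deg_table()].
#' @export
make_degs <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(stream_seed(spec$seed, "degs"))
  de <- spec$de_spec
  if (is.null(de)) {
    de <- data.frame(gene = character(), log2fc = numeric(),
                     pvalue = numeric(), stringsAsFactors = FALSE)
  }
  pool <- setdiff(c(spec$tfs, spec$genes), normalize_symbols(de$gene))
  n_fill <- min(spec$n_filler_genes, length(pool))
  filler <- data.frame(
    gene = sort(sample(pool, n_fill)),
    log2fc = round(stats::runif(n_fill, -0.45, 0.45), 4),
    pvalue = round(stats::runif(n_fill, 0.25, 0.95), 4),
    stringsAsFactors = FALSE
  )
  deg_table(rbind(de[, c("gene", "log2fc", "pvalue")], filler))
}

#' Write a complete fixture set to a directory
#'
#' Generates and writes every artifact the other modules read: evidence
#' TSVs, expression matrix + annotations, promoters FASTA + JASPAR motifs
#' (when planted), a DEG table, and a `manifest.yaml` recording the planted
#' ground truth. Byte-identical across runs for a fixed spec.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_fixtures <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)

  ev <- make_evidence(spec, dir)
  paths <- c(paths, ev$paths)

  expr <- make_expression(spec)
  write_expression(expr, file.path(dir, "expression.tsv"),
                   file.path(dir, "annotations.tsv"))
  paths <- c(paths, expression = file.path(dir, "expression.tsv"),
             annotations = file.path(dir, "annotations.tsv"))

  if (!is.null(spec$planted_motifs)) {
    pr <- make_promoters(spec, dir)
    paths <- c(paths, pr$paths)
  }

  degs <- make_degs(spec)
  write_deg_table(degs, file.path(dir, "degs.tsv"))
  paths <- c(paths, degs = file.path(dir, "degs.tsv"))

  manifest <- list(
    seed = spec$seed,
    universe = list(n_tfs = spec$n_tfs, n_genes = spec$n_genes,
                    cohorts = spec$cohorts),
    sources = stats::setNames(as.list(spec$sources$class),
                              spec$sources$id),
    planted_edges = if (is.null(spec$planted_edges)) list() else
      apply(spec$planted_edges, 1, as.list),
    planted_correlations = if (is.null(spec$planted_correlations)) list()
      else apply(spec$planted_correlations, 1, as.list),
    planted_motifs = if (is.null(spec$planted_motifs)) list() else
      apply(spec$planted_motifs, 1, as.list),
    de_spec = if (is.null(spec$de_spec)) list() else
      apply(spec$de_spec, 1, as.list)
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  paths <- c(paths, manifest = file.path(dir, "manifest.yaml"))
  invisible(paths)
}
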