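test_that("JASPAR records parse into PWMs with header names and counts preserved", {
  f <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(c(
    ">MA0001.1 stat3",
    "A [ 10 0 ]",
    "C [ 0 10 ]",
    "G [ 0 0 ]",
    "T [ 0 0 ]",
    ">MA0002.1 FOXM1",
    "5 5 5",
    "1 1 1",
    "2 2 2",
    "2 2 2",
    ">MA0003.1 YY1",
    "A [ 1 2 ]",
    "C [ 3 4 ]",
    "G [ 5 6 ]",
    "T [ 7 8 ]"
  ), f)
  pwms <- read_jaspar(f)
  expect_length(pwms, 3)
  expect_identical(names(pwms), c("MA0001.1", "MA0002.1", "MA0003.1"))
  expect_equal(ncol(pwms[["MA0001.1"]]$counts), 2)
  expect_equal(pwms[["MA0001.1"]]$tf_name, "STAT3")
  expect_equal(unname(pwms[["MA0003.1"]]$counts[, 1]), c(1, 3, 5, 7))
  expect_equal(unname(pwms[["MA0002.1"]]$counts["A", ]), c(5, 5, 5))

  ## write/read round-trip preserves counts
  f2 <- withr::local_tempfile(fileext = ".jaspar")
  write_jaspar(pwms, f2)
  pwms2 <- read_jaspar(f2)
  expect_equal(lapply(pwms2, `[[`, "counts"),
               lapply(pwms, `[[`, "counts"))
})

test_that("malformed JASPAR records raise format and parse errors", {
  f <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(c(">M1 X", "A [ 1 2 ]", "C [ 3 ]", "G [ 5 6 ]", "T [ 7 8 ]"),
             f)
  expect_error(read_jaspar(f), class = "regulink_format_error")
  writeLines(c(">M1 X", "A [ 1 z ]", "C [ 3 4 ]", "G [ 5 6 ]",
               "T [ 7 8 ]"), f)
  expect_error(read_jaspar(f), class = "regulink_parse_error")
})

test_that("log-odds matrix follows the pseudocount-adjusted formula", {
  flat <- pwm(matrix(1, 4, 3), pseudocount = 0)
  expect_equal(log_odds(flat), matrix(0, 4, 3,
                                      dimnames = list(c("A", "C", "G", "T"),
                                                      NULL)))
  pure <- pwm(matrix(c(1, 0, 0, 0), 4, 1), pseudocount = 0)
  expect_equal(unname(log_odds(pure)["A", 1]), 2)  # log2(4)

  set.seed(11)
  cnt <- matrix(runif(4 * 5, 0, 30), 4, 5)
  bg <- c(0.3, 0.2, 0.2, 0.3)
  p <- pwm(cnt, background = bg, pseudocount = 0.1)
  lom <- log_odds(p)
  ## independent re-evaluation of the stated formula
  for (j in 1:5) {
    adj <- cnt[, j] + 0.1 * bg
    expect_equal(unname(lom[, j]), log2(adj / sum(adj) / bg),
                 tolerance = 1e-12)
  }
})

test_that("score null distribution is exact for short motifs", {
  ## L = 1, uniform background: four distinct scores, each mass 1/4
  p1 <- pwm(matrix(c(5, 3, 2, 1), 4, 1))
  d1 <- score_null_distribution(log_odds(p1), p1$background)
  expect_equal(sum(d1$prob), 1, tolerance = 1e-9)
  expect_equal(unname(d1$prob), rep(0.25, 4))

  ## unique-consensus PWM: P(score >= max) = 4^-L
  cons <- pwm(matrix(c(90, 2, 3, 5, 2, 90, 3, 5, 5, 3, 90, 2), 4, 3))
  d3 <- score_null_distribution(log_odds(cons), cons$background)
  expect_equal(tail_prob(d3, max(d3$support)), 4^-3, tolerance = 1e-12)

  ## random PWMs vs exhaustive enumeration
  set.seed(202)
  for (i in 1:5) {
    L <- sample(2:6, 1)
    cnt <- matrix(runif(4 * L, 0, 20), 4, L)
    bg <- if (i %% 2) rep(0.25, 4) else c(0.2, 0.3, 0.3, 0.2)
    pw <- pwm(cnt, background = bg)
    lom <- log_odds(pw)
    d <- score_null_distribution(lom, bg)
    expect_equal(sum(d$prob), 1, tolerance = 1e-9)
    s <- enum_scores(lom)
    expect_equal(tail_prob(d, s), enum_tails(lom, bg, s),
                 tolerance = 1e-6)
    ## tail is non-increasing in the score
    expect_true(all(diff(tail_prob(d, s)) <= 1e-12))
  }
})

test_that("grid fallback stays close to truth for long motifs", {
  set.seed(203)
  L <- 14
  cnt <- matrix(runif(4 * L, 0, 50), 4, L)
  pw <- pwm(cnt)
  lom <- log_odds(pw)
  d <- score_null_distribution(lom, pw$background, max_exact = 500L)
  expect_identical(d$method, "grid")
  expect_equal(sum(d$prob), 1, tolerance = 1e-9)
  ## compare against the exact convolution at a few quantiles
  d_exact <- score_null_distribution(lom, pw$background)
  qs <- stats::quantile(d_exact$support, c(0.5, 0.9, 0.99))
  expect_equal(tail_prob(d, qs), tail_prob(d_exact, qs),
               tolerance = 5e-3)
})

test_that("planted consensus sites are recovered at the exact offset and strand", {
  spec <- fixture_spec(
    seed = 31, n_tfs = 5, n_genes = 30,
    planted_motifs = data.frame(
      motif_id = c("M1", "M1", "M2"),
      gene = c("G0001", "G0002", "G0003"),
      offset = c(100L, 1500L, 0L),
      strand = c("+", "-", "+"), stringsAsFactors = FALSE),
    n_promoter_decoys = 3
  )
  pr <- make_promoters(spec)
  st <- scan_promoters(pr$pwms, pr$promoters, p_threshold = 1e-4)
  hits <- st$hits
  for (i in seq_len(nrow(spec$planted_motifs))) {
    pl <- spec$planted_motifs[i, ]
    match_hit <- hits[hits$motif_id == pl$motif_id &
                        hits$gene == pl$gene &
                        hits$offset == pl$offset, ]
    expect_equal(nrow(match_hit), 1)
    expect_equal(match_hit$strand, pl$strand)
  }
  ## every planted TF-gene pair is an edge (near-consensus background
  ## words may add edges at the permissive 1e-4 threshold)
  expect_true(all(c("TF01 G0001", "TF01 G0002", "TF02 G0003") %in%
                    paste(st$edges$tf, st$edges$target)))
  ## at 1e-6 only perfect consensus words score: edges are exactly planted
  strict <- scan_promoters(pr$pwms, pr$promoters, p_threshold = 1e-6)
  expect_setequal(paste(strict$edges$tf, strict$edges$target),
                  c("TF01 G0001", "TF01 G0002", "TF02 G0003"))
})

test_that("a motif that cannot match the sequence yields no hits", {
  cnt <- matrix(1, 4, 6)
  cnt[1, ] <- 0  # zero A counts at every column
  pw <- pwm(cnt, pseudocount = 0.01)
  all_a <- Biostrings::DNAStringSet(c(PROM1 = strrep("A", 200)))
  st <- scan_promoters(pw, all_a, p_threshold = 1e-4)
  expect_equal(nrow(st$hits), 0)
  expect_equal(nrow(st$edges), 0)
})

test_that("palindromic motifs hit both strands at the same positions", {
  ## consensus ACGT is its own reverse complement
  cnt <- matrix(1, 4, 4)
  cnt[cbind(1:4, 1:4)] <- 60
  pw <- pwm(cnt, motif_id = "PAL", tf_name = "PAL")
  set.seed(99)
  seq <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
               collapse = "")
  seq <- paste0(substr(seq, 1, 100), "ACGT", substr(seq, 105, 500))
  st <- scan_promoters(pw, Biostrings::DNAStringSet(c(P = seq)),
                       p_threshold = 1e-2)
  plus <- st$hits[st$hits$strand == "+", ]
  minus <- st$hits[st$hits$strand == "-", ]
  expect_gt(nrow(plus), 0)
  expect_setequal(plus$offset, minus$offset)
  expect_equal(sort(plus$score), sort(minus$score))
})

test_that("scanning the reverse complement swaps strands and maps offsets", {
  spec <- fixture_spec(
    seed = 41, n_tfs = 2, n_genes = 10,
    planted_motifs = data.frame(motif_id = "M1", gene = "G0001",
                                offset = 700L, strand = "+",
                                stringsAsFactors = FALSE),
    n_promoter_decoys = 2
  )
  pr <- make_promoters(spec)
  st_fwd <- scan_promoters(pr$pwms, pr$promoters, p_threshold = 1e-3)
  st_rev <- scan_promoters(pr$pwms,
                           Biostrings::reverseComplement(pr$promoters),
                           p_threshold = 1e-3)
  W <- spec$promoter_window
  L <- ncol(pr$pwms[[1]]$counts)
  mapped <- st_rev$hits
  mapped$offset <- W - L - mapped$offset
  mapped$strand <- ifelse(mapped$strand == "+", "-", "+")
  key <- function(h) sort(paste(h$motif_id, h$gene, h$offset, h$strand,
                                round(h$score, 9)))
  expect_identical(key(mapped), key(st_fwd$hits))
})

test_that("lowering the p-value threshold never adds hits", {
  spec <- fixture_spec(
    seed = 51, n_tfs = 2, n_genes = 10,
    planted_motifs = data.frame(motif_id = "M1", gene = "G0001",
                                offset = 50L, strand = "+",
                                stringsAsFactors = FALSE),
    n_promoter_decoys = 4
  )
  pr <- make_promoters(spec)
  loose <- scan_promoters(pr$pwms, pr$promoters, p_threshold = 1e-3)
  strict <- scan_promoters(pr$pwms, pr$promoters, p_threshold = 1e-5)
  key <- function(h) paste(h$motif_id, h$gene, h$offset, h$strand)
  expect_true(all(key(strict$hits) %in% key(loose$hits)))
})

test_that("N windows are skipped with a message and foreign characters error", {
  pw <- pwm(matrix(c(60, 1, 1, 1), 4, 4), motif_id = "M",
            tf_name = "TFX")
  withN <- Biostrings::DNAStringSet(c(G1 = "AAAANAAAAAAA"))
  expect_message(scan_promoters(pw, withN, p_threshold = 0.9),
                 "skipped")
  ## DNAStringSet itself rejects most foreign letters; ambiguity codes
  ## (IUPAC) pass construction but are rejected by the scanner
  amb <- Biostrings::DNAStringSet(c(BADREC = "AACGTRYAACGT"))
  expect_error(scan_promoters(pw, amb, p_threshold = 0.9),
               "BADREC", class = "regulink_validation_error")
})

test_that("motif hits export as TSV and BED6", {
  spec <- fixture_spec(
    seed = 61, n_tfs = 2, n_genes = 10,
    planted_motifs = data.frame(motif_id = "M1", gene = "G0001",
                                offset = 10L, strand = "+",
                                stringsAsFactors = FALSE),
    n_promoter_decoys = 0
  )
  pr <- make_promoters(spec)
  st <- scan_promoters(pr$pwms, pr$promoters, p_threshold = 1e-4)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_motif_hits(st, f)
  back <- utils::read.delim(f)
  expect_equal(nrow(back), nrow(st$hits))
  b <- withr::local_tempfile(fileext = ".bed")
  write_motif_hits(st, b, format = "bed",
                   motif_lengths = c(M1 = 10L))
  bed <- utils::read.delim(b, header = FALSE)
  expect_equal(bed$V3 - bed$V2, rep(10L, nrow(bed)))
})
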