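test_that("planted edges appear in exactly their listed sources", {
  spec <- fixture_spec(
    seed = 5, n_tfs = 5, n_genes = 50,
    planted_edges = data.frame(
      tf = "TF01", target = c("G0001", "G0002"),
      sources = c("htftarget,knocktf", "trrust"),
      stringsAsFactors = FALSE),
    decoy_rate = 0
  )
  ev <- make_evidence(spec)
  has_edge <- function(id, tf, tg) {
    any(ev$tables[[id]]$edges$tf == tf & ev$tables[[id]]$edges$target == tg)
  }
  expect_true(has_edge("htftarget", "TF01", "G0001"))
  expect_true(has_edge("knocktf", "TF01", "G0001"))
  expect_false(has_edge("trrust", "TF01", "G0001"))
  expect_true(has_edge("trrust", "TF01", "G0002"))
  expect_false(has_edge("htftarget", "TF01", "G0002"))
})

test_that("strict intersection of generated sources recovers the planted targets", {
  targets <- sprintf("G%04d", 1:50)
  spec <- fixture_spec(
    seed = 6, n_tfs = 50, n_genes = 2000,
    planted_edges = data.frame(
      tf = "TF01", target = targets,
      sources = paste(DEFAULT_FIXTURE_SOURCES$id, collapse = ","),
      stringsAsFactors = FALSE),
    decoy_rate = 0.25
  )
  ev <- make_evidence(spec)
  expect_equal(ev$manifest$n_decoys_per_source, 500)
  ## brute-force intersection over the generated tables
  per_source <- lapply(ev$tables, function(s)
    s$edges$target[s$edges$tf == "TF01"])
  inter <- Reduce(intersect, per_source)
  expect_setequal(inter, targets)
})

test_that("decoys never collide with planted pairs", {
  spec <- fixture_spec(
    seed = 7, n_tfs = 3, n_genes = 30,
    planted_edges = data.frame(tf = "TF01", target = "G0001",
                               sources = "htftarget",
                               stringsAsFactors = FALSE),
    decoy_rate = 0.5
  )
  ev <- make_evidence(spec)
  for (id in names(ev$manifest$decoys)) {
    d <- ev$manifest$decoys[[id]]
    expect_false(any(d$tf == "TF01" & d$target == "G0001"))
  }
})

test_that("the decoy capacity check fires when the universe is too small", {
  spec <- fixture_spec(
    seed = 8, n_tfs = 1, n_genes = 3, decoy_rate = 0.9,
    planted_edges = data.frame(tf = "TF01", target = "G0001",
                               sources = "htftarget",
                               stringsAsFactors = FALSE)
  )
  ## 3 decoys requested against 3 pairs of which 1 is planted
  expect_error(make_evidence(spec), class = "regulink_capacity_error")
})

test_that("expression fixtures carry the planted correlation structure", {
  spec <- fixture_spec(
    seed = 9, n_tfs = 2, n_genes = 4, n_cohorts = 2,
    n_samples_per_cohort = 500,
    planted_correlations = data.frame(
      tf = "TF01", gene = c("G0001", "G0002"), cohort = "COHORT1",
      rho = c(0.6, 0), stringsAsFactors = FALSE)
  )
  expr <- make_expression(spec)
  cols <- expr$annotations$cohort == "COHORT1"
  r_planted <- correlate(expr$values["TF01", cols],
                         expr$values["G0001", cols])$r
  expect_lt(abs(r_planted - 0.6), 0.1)
  r_null <- correlate(expr$values["TF01", cols],
                      expr$values["G0002", cols])$r
  expect_lt(abs(r_null), 0.3)
  ## self-correlation is exactly 1
  expect_equal(correlate(expr$values["TF01", cols],
                         expr$values["TF01", cols])$r, 1)
  expect_error(
    fixture_spec(seed = 9, n_tfs = 1, n_genes = 1,
                 planted_correlations = data.frame(
                   tf = "TF01", gene = "G0001", cohort = "COHORT1",
                   rho = 1.2)),
    class = "regulink_spec_error"
  )
})

test_that("promoter fixtures embed consensus sites and nothing else scores", {
  spec <- fixture_spec(
    seed = 10, n_tfs = 2, n_genes = 20,
    planted_motifs = data.frame(motif_id = "M1", gene = "G0001",
                                offset = 100L, strand = "+",
                                stringsAsFactors = FALSE),
    n_promoter_decoys = 5
  )
  pr <- make_promoters(spec)
  st <- scan_promoters(pr$pwms, pr$promoters, p_threshold = 1e-6)
  ## with this seed the only sub-1e-6 hit is the planted site
  expect_equal(nrow(st$hits), 1)
  expect_equal(st$hits$gene, "G0001")
  expect_equal(st$hits$offset, 100L)

  ## a reverse-strand plant is reported on the minus strand
  spec_m <- fixture_spec(
    seed = 10, n_tfs = 2, n_genes = 20,
    planted_motifs = data.frame(motif_id = "M1", gene = "G0002",
                                offset = 40L, strand = "-",
                                stringsAsFactors = FALSE),
    n_promoter_decoys = 0
  )
  pr_m <- make_promoters(spec_m)
  st_m <- scan_promoters(pr_m$pwms, pr_m$promoters, p_threshold = 1e-4)
  pl <- st_m$hits[st_m$hits$offset == 40L, ]
  expect_equal(pl$strand, "-")

  ## overlapping plants and out-of-window offsets are spec errors
  expect_error(make_promoters(fixture_spec(
    seed = 10, n_tfs = 2, n_genes = 20,
    planted_motifs = data.frame(motif_id = c("M1", "M1"),
                                gene = "G0001", offset = c(10L, 12L),
                                strand = "+", stringsAsFactors = FALSE))),
    class = "regulink_spec_error")
  expect_error(make_promoters(fixture_spec(
    seed = 10, n_tfs = 2, n_genes = 20,
    planted_motifs = data.frame(motif_id = "M1", gene = "G0001",
                                offset = 1999L, strand = "+",
                                stringsAsFactors = FALSE))),
    class = "regulink_spec_error")
})

test_that("DEG fixtures contain exactly the planted rows plus sub-threshold filler", {
  de <- data.frame(gene = c("TF01", "G0001", "G0002"),
                   log2fc = c(2, -1.5, 1.2), pvalue = c(0.001, 0.01, 0.04))
  spec <- fixture_spec(seed = 13, n_tfs = 3, n_genes = 200, de_spec = de,
                       n_filler_genes = 150)
  deg <- make_degs(spec)
  expect_equal(nrow(deg), 153)
  expect_setequal(filter_degs(deg, 1, 0.05), c("TF01", "G0001", "G0002"))

  empty <- make_degs(fixture_spec(seed = 13, n_tfs = 3, n_genes = 20,
                                  n_filler_genes = 0))
  expect_equal(nrow(empty), 0)
})

test_that("fixture generation is byte-identical under a fixed seed", {
  spec <- fixture_spec(
    seed = 42, n_tfs = 5, n_genes = 60, n_cohorts = 2,
    n_samples_per_cohort = 20,
    planted_edges = data.frame(tf = "TF01", target = "G0001",
                               sources = "htftarget",
                               stringsAsFactors = FALSE),
    planted_motifs = data.frame(motif_id = "M1", gene = "G0001",
                                offset = 100L, strand = "+",
                                stringsAsFactors = FALSE),
    decoy_rate = 0.3, n_filler_genes = 20, n_promoter_decoys = 2
  )
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_fixtures(spec, d1)
  write_fixtures(spec, d2)
  files <- list.files(d1)
  expect_identical(files, list.files(d2))
  for (f in files) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
  ## manifest records the planted truth
  man <- yaml::read_yaml(file.path(d1, "manifest.yaml"))
  expect_equal(man$seed, 42)
  expect_equal(man$planted_edges[[1]]$tf, "TF01")
})
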