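test_that("hypergeometric enrichment equals exhaustive enumeration", {
  # N <= 30: direct summation of the counting formula
  cases <- list(c(k = 3, K = 10, N = 30, n = 5), c(k = 2, K = 4, N = 20, n = 6),
                c(k = 5, K = 8, N = 25, n = 10), c(k = 1, K = 3, N = 12, n = 4))
  for (cs in cases) {
    universe <- sprintf("g%02d", seq_len(cs["N"]))
    term_genes <- universe[seq_len(cs["K"])]
    cluster <- c(term_genes[seq_len(cs["k"])],
                 setdiff(universe, term_genes)[seq_len(cs["n"] - cs["k"])])
    ann <- data.frame(term_id = "T1", gene = term_genes)
    res <- enrich_terms(cluster, ann, universe)
    expect_equal(res$p, hyper_tail_enum(cs["k"], cs["K"], cs["N"], cs["n"]),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("degenerate enrichment cases give p = 1", {
  universe <- sprintf("g%02d", 1:20)
  ann <- data.frame(term_id = "ALL", gene = universe)
  # cluster = term = universe
  expect_equal(enrich_terms(universe, ann, universe)$p, 1)
  # k = 0: no term member in the cluster
  ann2 <- data.frame(term_id = "T", gene = universe[1:5])
  expect_equal(enrich_terms(universe[6:10], ann2, universe)$p, 1)
  # a term disjoint from the universe is skipped
  ann3 <- data.frame(term_id = "OUT", gene = c("zz1", "zz2"))
  expect_identical(nrow(enrich_terms(universe[1:3], ann3, universe)), 0L)
  # Bonferroni never exceeds 1 and scales with the number of terms
  ann4 <- rbind(ann2, data.frame(term_id = "T2", gene = universe[6:9]))
  res <- enrich_terms(universe[1:5], ann4, universe)
  expect_equal(res$p_adj, pmin(1, res$p * 2))
})

test_that("GTA reproduces hand-computed means and sample SDs", {
  # sample SD (n-1): sd(c(-13.9, -10.5)) = 2.404, not the population 1.7
  g <- compute_gta(c(-13.9, -10.5))
  expect_equal(g$gta_value, -12.2)
  expect_equal(g$gta_sd, sd(c(-13.9, -10.5)))
  expect_equal(round(g$gta_sd, 1), 2.4)
  expect_equal(g$gta_score, abs(g$gta_value) - g$gta_sd)
  set.seed(41)
  for (i in 1:10) {
    v <- rnorm(5, 0, 4)
    g <- compute_gta(v)
    expect_equal(g$gta_value, sum(v) / 5, tolerance = 1e-12)
    expect_equal(g$gta_sd, sqrt(sum((v - mean(v))^2) / 4), tolerance = 1e-12)
  }
})

test_that("GTA degenerate inputs behave as specified", {
  one <- compute_gta(5)
  expect_true(is.na(one$gta_sd) && !one$significant)
  zeros <- compute_gta(rep(0, 4))
  expect_equal(zeros$gta_value, 0)
  expect_false(zeros$significant)
  # identical values v: GTA v, SD 0, score |v|
  same <- compute_gta(rep(-6, 3))
  expect_equal(same$gta_sd, 0)
  expect_equal(same$gta_score, 6)
  expect_true(same$significant)
})

test_that("adding a gene at the term mean never decreases the GTA score", {
  set.seed(42)
  for (i in 1:20) {
    v <- rnorm(sample(2:8, 1), sample(-5:5, 1), 2)
    expect_gte(compute_gta(c(v, mean(v)))$gta_score,
               compute_gta(v)$gta_score - 1e-12)
  }
})

test_that("gta_scan flags planted terms and drops unscored genes", {
  run <- shared_run()
  gta <- run$gta
  planted <- run$bundle$truth$planted_terms
  resp <- gta[gta$medium == "respiratory", ]
  expect_true(all(planted %in% resp$term_id[resp$significant]))
  # genes absent from the interaction table are dropped before n is counted
  ann <- rbind(run$bundle$go,
               data.frame(term_id = "GO:0000001", gene = "NOT_A_STRAIN"))
  g2 <- gta_scan(run$scores, ann, "respiratory")
  expect_identical(g2$n[g2$term_id == "GO:0000001"],
                   gta[gta$medium == "respiratory" &
                         gta$term_id == "GO:0000001", "n"])
  # a term straddling zero with big SD is not significant despite |mean| > 2
  straddle <- compute_gta(c(8, -3.5))
  expect_gt(abs(straddle$gta_value), 2)
  expect_false(straddle$significant)
})

test_that("unplanted terms rarely reach a GTA score above 2", {
  run <- shared_run()
  gta <- run$gta
  unplanted <- !(gta$term_id %in% run$bundle$truth$planted_terms)
  fp <- gta$significant[unplanted]
  expect_lte(mean(fp), 0.05)
})

test_that("term heatmap matrices contain exactly the scored members", {
  run <- shared_run()
  pm0 <- select_profiles(run$scores, threshold = 0)
  tid <- run$bundle$truth$planted_terms[1]
  hm <- term_heatmap_matrix(tid, run$bundle$go, pm0)
  members <- unique(run$bundle$go$gene[run$bundle$go$term_id == tid])
  expect_setequal(rownames(hm), intersect(members, rownames(pm0)))
  # ordering equals a direct dendrogram computation on the same features
  feats <- pm0[rownames(hm), seq_len(4), drop = FALSE]
  ord <- order_for_heatmap(pm0[intersect(members, rownames(pm0)), 1:4])
  expect_identical(rownames(hm),
                   rownames(pm0[intersect(members, rownames(pm0)), ])[ord])
})

test_that("annotation files round-trip through the parsers", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("term_id\tgene", "GO:1\tYFG1", "GO:1\tYFG2", "GO:2\tYFG3"),
             tsv)
  ann <- read_go_annotations(tsv)
  expect_identical(nrow(ann), 3L)
  gaf <- tempfile(fileext = ".gaf")
  writeLines(c("!gaf-version: 2.1",
               paste("SGD", "S001", "YFG1", "", "GO:1", "PMID:1", "IDA",
                     "", "P", "", "", "gene", "taxon:4932", "20200101",
                     "SGD", sep = "\t"),
               paste("SGD", "S002", "YFG2", "", "GO:2", "PMID:1", "IDA",
                     "", "P", "", "", "gene", "taxon:4932", "20200101",
                     "SGD", sep = "\t")), gaf)
  ag <- read_go_annotations(gaf, format = "gaf")
  expect_identical(ag$term_id, c("GO:1", "GO:2"))
  expect_identical(ag$gene, c("YFG1", "YFG2"))
  obo <- tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.4", "", "[Term]", "id: GO:child",
               "is_a: GO:parent ! some name", "", "[Term]", "id: GO:parent",
               "is_a: GO:root", "", "[Typedef]", "id: part_of"), obo)
  isa <- read_obo_isa(obo)
  expect_identical(isa$term_id, c("GO:child", "GO:parent"))
  expect_identical(isa$parent_id, c("GO:parent", "GO:root"))
  prop <- propagate_annotations(
    data.frame(term_id = "GO:child", gene = "YFG1"), isa)
  expect_setequal(prop$term_id, c("GO:child", "GO:parent", "GO:root"))
})
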