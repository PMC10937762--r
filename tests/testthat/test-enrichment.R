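ranked_from <- function(genes, scores) {
  rank_by_log2fc(data.frame(gene = genes, log2FC = scores))
}

test_that("ranking sorts descending with deterministic tie-breaks and dedup", {
  r <- ranked_from(c("a", "b", "c"), c(2, -1, 0))
  expect_equal(r$gene, c("a", "c", "b"))
  expect_warning(
    r2 <- rank_by_log2fc(data.frame(gene = c("a", "a", "b"),
                                    log2FC = c(1, -3, 0))),
    "duplicate")
  expect_equal(r2$score[r2$gene == "a"], -3)
  # ties in score break lexicographically by gene id
  r3 <- ranked_from(c("z", "m", "a"), c(1, 1, 1))
  expect_equal(r3$gene, c("a", "m", "z"))
  expect_error(rank_by_log2fc(data.frame(gene = character(0),
                                         log2FC = numeric(0))), "empty")
})

test_that("five-gene worked examples give ES of exactly +1 and -1", {
  r <- ranked_from(paste0("g", 1:5), c(3, 2, 1, -1, -2))
  expect_identical(enrichment_score(r, gene_set("top", "g1"))$es, 1)
  expect_identical(enrichment_score(r, gene_set("bottom", "g5"))$es, -1)
})

test_that("running sum ends at zero and ES lies in [-1, 1]", {
  set.seed(10)
  for (rep in 1:20) {
    N <- sample(10:50, 1)
    r <- ranked_from(sprintf("g%03d", 1:N), rnorm(N))
    k <- sample(1:(N - 1), 1)
    sc <- enrichment_score(r, gene_set("s", sample(r$gene, k)))
    expect_lt(abs(sc$running_sum[N]), 1e-12)
    expect_lte(abs(sc$es), 1)
  }
})

test_that("negating scores and reversing the list negates ES", {
  set.seed(20)
  for (rep in 1:10) {
    N <- 30
    scores <- rnorm(N)
    genes <- sprintf("g%03d", 1:N)
    members <- sample(genes, 6)
    es1 <- enrichment_score(ranked_from(genes, scores),
                            gene_set("s", members))$es
    es2 <- enrichment_score(ranked_from(genes, -scores),
                            gene_set("s", members))$es
    expect_equal(es2, -es1, tolerance = 1e-12)
  }
})

test_that("ES agrees with the naive oracle and with an external reference", {
  set.seed(30)
  for (rep in 1:200) {
    N <- sample(5:50, 1)
    scores <- rnorm(N)
    r <- ranked_from(sprintf("g%03d", 1:N), scores)
    k <- sample(1:(N - 1), 1)
    members <- sample(r$gene, k)
    es <- enrichment_score(r, gene_set("s", members))$es
    expect_equal(es, oracle_es(r$score, r$gene %in% members),
                 tolerance = 1e-12)
  }
  # independent reference implementation (fgsea's statistic, same weights)
  set.seed(31)
  for (rep in 1:25) {
    N <- 40
    r <- ranked_from(sprintf("g%03d", 1:N), rnorm(N))
    members <- sample(r$gene, 8)
    stats_v <- stats::setNames(r$score, r$gene)
    ref <- fgsea::calcGseaStat(stats_v, selectedStats = which(r$gene %in%
                                                                members),
                               gseaParam = 1)
    expect_equal(enrichment_score(r, gene_set("s", members))$es, ref,
                 tolerance = 1e-10)
  }
})

test_that("fast hit-position ES path equals the running-sum path", {
  set.seed(40)
  for (rep in 1:50) {
    N <- sample(20:200, 1)
    r <- ranked_from(sprintf("g%04d", 1:N), rnorm(N))
    k <- sample(1:15, 1)
    idx <- sort(sample.int(N, k))
    members <- r$gene[idx]
    expect_equal(stingquant:::es_from_hits(r$score, idx),
                 enrichment_score(r, gene_set("s", members))$es,
                 tolerance = 1e-12)
  }
})

test_that("degenerate gene sets are rejected", {
  r <- ranked_from(paste0("g", 1:6), c(3, 2, 1, 0, -1, -2))
  expect_error(enrichment_score(r, gene_set("none", c("x", "y"))),
               "disjoint")
  expect_error(enrichment_score(r, gene_set("zero", "g4")), "N_R = 0")
  expect_error(enrichment_score(r, gene_set("all", paste0("g", 1:6))),
               "whole universe")
})

test_that("empirical p is floored when ES tops its matching-sign null", {
  set.seed(50)
  pos_null <- runif(999, 0, 0.5)
  nm <- normalize_es(0.99, pos_null)
  expect_equal(nm$p_emp, 1 / 1000)   # all 999 draws share the sign
  expect_equal(sign(nm$nes), 1)
  nm2 <- normalize_es(-0.99, -pos_null)
  expect_equal(nm2$p_emp, 1 / 1000)
  expect_equal(sign(nm2$nes), -1)
  # mixed-sign null: the floor is 1/(matching-sign draws + 1)
  mixed <- c(runif(499, 0, 0.5), runif(500, -0.5, 0))
  expect_equal(normalize_es(0.99, mixed)$p_emp, 1 / 500)
  # no matching-sign draws at all: flagged
  expect_true(normalize_es(0.9, -pos_null)$flag)
})

test_that("permutation p-values are calibrated under exchangeable scores", {
  dep <- de_preset(planted_shift = 0, n_genes = 4000L, seed = 7L)
  ranked <- rank_by_log2fc(generate_de_table(dep))
  ctl <- random_geneset_control(ranked, size = 30L, n_sets = 200L,
                                n_perm = 500L, seed = 7L)
  expect_lt(abs(ctl$fraction_significant - 0.05), 0.03)
})

test_that("the planted STING panel is detected while random sets are not", {
  dep <- de_preset(planted_shift = 1.0, null_sd = 0.3, seed = 9L)
  de <- generate_de_table(dep)
  ranked <- rank_by_log2fc(de)
  res <- gsea_preranked(ranked, sting_panel(), n_perm = 500L, seed = 9L)
  expect_lt(res$p_emp, 0.05)
  expect_gt(res$es, 0)
  expect_gt(res$nes, 1)
  ctl <- random_geneset_control(ranked, size = 30L, n_sets = 100L,
                                n_perm = 500L, seed = 9L)
  expect_lte(ctl$fraction_significant, 0.1)
  # target genes rank above the universe median
  med_rank <- median(which(ranked$gene %in% dep$target_set$members))
  expect_lt(med_rank, nrow(ranked) / 2)
})

test_that("GMT files round-trip and the shipped panel has 25 genes", {
  panel <- sting_panel()
  expect_length(panel$members, 25L)
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(list(panel, gene_set("other", c("A", "B"))), path)
  back <- read_gene_sets(path)
  expect_equal(back[[1]]$members, panel$members)
  expect_equal(back[["other"]]$members, c("A", "B"))
})
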