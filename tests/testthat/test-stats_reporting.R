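test_that("pooled t-test reproduces the closed-form worked example", {
  cmp <- student_t_two_tailed(c(1, 2, 3), c(2, 3, 4))
  expect_equal(cmp$t_stat, -1.224745, tolerance = 1e-6)
  expect_equal(cmp$df, 4)
  expect_equal(cmp$p_two_tailed, 0.2878641, tolerance = 1e-6)
  expect_equal(cmp$stars, "ns")
})

test_that("identical groups give t = 0, p = 1; swapping groups negates t", {
  cmp <- student_t_two_tailed(c(1, 2, 3), c(1, 2, 3))
  expect_equal(cmp$t_stat, 0)
  expect_equal(cmp$p_two_tailed, 1)
  set.seed(3)
  x <- rnorm(7); y <- rnorm(5, 1)
  a <- student_t_two_tailed(x, y)
  b <- student_t_two_tailed(y, x)
  expect_equal(a$t_stat, -b$t_stat)
  expect_equal(a$p_two_tailed, b$p_two_tailed)
})

test_that("t matches an independent pooled-formula implementation to 1e-8", {
  set.seed(17)
  for (rep in 1:25) {
    n1 <- sample(3:12, 1); n2 <- sample(3:12, 1)
    x <- rnorm(n1, 5, 2); y <- rnorm(n2, 6, 3)
    cmp <- student_t_two_tailed(x, y)
    sp <- sqrt(((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2))
    t_ref <- (mean(x) - mean(y)) / (sp * sqrt(1 / n1 + 1 / n2))
    p_ref <- 2 * pt(-abs(t_ref), n1 + n2 - 2)
    expect_equal(cmp$t_stat, t_ref, tolerance = 1e-8)
    expect_equal(cmp$p_two_tailed, p_ref, tolerance = 1e-8)
    expect_equal(cmp$df, n1 + n2 - 2)
  }
})

test_that("zero variance in both groups with equal means is p = 1, flagged", {
  expect_warning(cmp <- student_t_two_tailed(c(2, 2, 2), c(2, 2)),
                 "zero variance")
  expect_equal(cmp$p_two_tailed, 1)
  expect_true(cmp$degenerate)
})

test_that("fold change: exact ratios and a planted end-to-end recovery input", {
  expect_equal(fold_change(c(3, 4, 5), c(3, 4, 5), seed = 1)$ratio, 1)
  fc <- fold_change(c(5, 5, 5), c(1, 1, 1), seed = 1)
  expect_equal(fc$ratio, 5)
  expect_error(fold_change(c(1, 2), c(0, 0)), "pseudo-count")
})

test_that("bootstrap fold-change CI coverage is near nominal at 90%", {
  set.seed(8)
  cover <- 0; n_sim <- 500
  for (s in 1:n_sim) {
    d <- rnorm(20, 10, 2); c_ <- rnorm(20, 5, 1.5)
    fc <- fold_change(d, c_, n_boot = 400, conf = 0.90, seed = s)
    if (fc$ci[1] <= 2 && 2 <= fc$ci[2]) cover <- cover + 1
  }
  expect_gt(cover / n_sim, 0.85)
  expect_lt(cover / n_sim, 0.95)
})

test_that("ddCt worked examples are forced by the 2^(-ddCt) definition", {
  rec <- data.frame(
    sample = c("v1", "v1", "t1", "t1"),
    gene = c("STING1", "TBP", "STING1", "TBP"),
    Cq = c(26, 20, 25, 20),
    condition = c("vehicle", "vehicle", "treated", "treated"))
  out <- ddct_fold_change(rec)
  tr <- out[out$condition == "treated", ]
  expect_equal(tr$fold_change, 2)
  expect_equal(tr$log2FC, 1)
  expect_equal(out$fold_change[out$condition == "vehicle"], 1)
})

test_that("treated identical to vehicle gives fold 1", {
  rec <- data.frame(sample = rep(c("v1", "t1"), each = 2),
                    gene = rep(c("IL6", "GAPDH"), 2),
                    Cq = c(28, 21, 28, 21),
                    condition = rep(c("vehicle", "treated"), each = 2))
  out <- ddct_fold_change(rec)
  expect_equal(out$fold_change, c(1, 1))
})

test_that("ddCt matches an independent spreadsheet-style recomputation", {
  set.seed(23)
  genes <- c("IL6", "TNF", "CXCL10")
  samples <- paste0("s", 1:8)
  cond <- rep(c("vehicle", "treated"), each = 4)
  rec <- do.call(rbind, lapply(seq_along(samples), function(i) {
    data.frame(sample = samples[i], gene = c(genes, "TBP"),
               Cq = c(runif(3, 22, 30), runif(1, 18, 21)),
               condition = cond[i])
  }))
  out <- ddct_fold_change(rec, reference_genes = "TBP")
  for (g in genes) {
    dct <- sapply(samples, function(s) {
      rec$Cq[rec$sample == s & rec$gene == g] -
        rec$Cq[rec$sample == s & rec$gene == "TBP"]
    })
    ddct <- mean(dct[cond == "treated"]) - mean(dct[cond == "vehicle"])
    expect_equal(out$fold_change[out$gene == g & out$condition == "treated"],
                 2^(-ddct), tolerance = 1e-10)
  }
})

test_that("ddCt validates vehicle presence and reference coverage", {
  rec <- data.frame(sample = "s1", gene = "IL6", Cq = 25,
                    condition = "treated")
  expect_error(ddct_fold_change(rec), "vehicle")
  rec2 <- data.frame(sample = c("s1", "s2"), gene = c("IL6", "IL6"),
                     Cq = c(25, 24), condition = c("vehicle", "treated"))
  expect_error(ddct_fold_change(rec2), "reference")
})

test_that("significance stars map exactly to the printed thresholds", {
  expect_equal(p_stars(c(0.049, 0.051, 0.009, 0.0009, 0.00009, NA)),
               c("*", "ns", "**", "***", "****", NA))
})

test_that("report generation is pure: identical inputs give identical bytes", {
  cmp <- student_t_two_tailed(c(4, 5, 6), c(1, 2, 3),
                              labels = c("disease", "control"))
  vals <- list(disease = c(4, 5, 6), control = c(1, 2, 3))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  df1 <- build_report(list(layerV = cmp), list(layerV = vals), d1,
                      meta = list(seed = 1))
  df2 <- build_report(list(layerV = cmp), list(layerV = vals), d2,
                      meta = list(seed = 1))
  expect_equal(nrow(df1), 1L)
  expect_equal(df1$stars, "*")
  expect_identical(unname(tools::md5sum(file.path(d1, "comparisons.csv"))),
                   unname(tools::md5sum(file.path(d2, "comparisons.csv"))))
  expect_true(file.exists(file.path(d1, "run_metadata.json")))
})
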