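test_that("single-pixel dilation matches closed forms and the brute-force oracle", {
  m <- matrix(FALSE, 41, 41); m[21, 21] <- TRUE
  d8 <- dilate_mask(m, 10, connectivity = 8)
  expect_equal(sum(d8), 441L)            # 21 x 21 Chebyshev ball
  expect_equal(sum(d8 & !m), 440L)       # ring
  d4 <- dilate_mask(m, 10, connectivity = 4)
  expect_equal(sum(d4), 2 * 10 * 11 + 1) # L1 ball, 2r(r+1)+1 = 221
  expect_equal(sum(d4 & !m), 220L)
  expect_identical(d8, oracle_dilate(m, 10, 8))
  expect_identical(d4, oracle_dilate(m, 10, 4))
})

test_that("dilation: identity at 0, semigroup property, oracle on random masks", {
  set.seed(5)
  for (rep in 1:6) {
    m <- matrix(runif(18 * 22) < 0.12, 18, 22)
    expect_identical(dilate_mask(m, 0L), m > 0)
    for (conn in c(8L, 4L)) {
      expect_identical(dilate_mask(m, 5L, conn), oracle_dilate(m, 5, conn))
      expect_identical(dilate_mask(m, 5L, conn),
                       dilate_mask(dilate_mask(m, 2L, conn), 3L, conn))
    }
  }
  expect_error(dilate_mask(matrix(TRUE, 2, 2), -1), "non-negative")
})

test_that("ring area is non-decreasing in iterations", {
  set.seed(9)
  m <- matrix(runif(30 * 30) < 0.05, 30, 30)
  areas <- vapply(0:8, function(it) sum(dilate_mask(m, it) & !m), numeric(1))
  expect_true(all(diff(areas) >= 0))
})

test_that("uniform ring intensities give exact integrated/mean measurements", {
  h <- 64
  nuc <- matrix(0, h, h)
  nuc[stingquant:::annulus_indices(h, h, 32, 32, 6)] <- 3000
  st <- channel_stack(list(nucleus_dye = nuc,
                           sting = matrix(5, h, h)))
  ct <- assemble_cells(segment_nuclei(nuc), NULL, st,
                       layer_bands = list(all = c(0, 1)))
  ring <- measure_perinuclear(ct, 1, st)
  expect_gt(ring$area_px, 0)
  expect_equal(ring$integrated, 5 * ring$area_px)
  expect_equal(ring$mean, 5)
  expect_false(ring$clipped)
})

test_that("a fully perinuclear-biased cell concentrates its STING in the ring", {
  p <- imaging_preset(field_shape = c(160L, 160L),
                      layer_bands = list(all = c(0.1, 0.9)),
                      cells_per_layer = c(all = 1L),
                      positive_fraction = data.frame(
                        group = "g", layer = "all", marker = "sting",
                        fraction = 1, stringsAsFactors = FALSE),
                      perinuclear_bias = 1,
                      noise = list(gaussian_sd = 0, poisson_scale = 0,
                                   background = 0),
                      seed = 2L, name = "bias1")
  fld <- generate_field(p, "g", 1)
  ct <- quantify_field(fld$stack, layer_bands = p$layer_bands)
  ring <- measure_perinuclear(ct, 1, fld$stack)
  total <- sum(fld$stack$channels$sting)
  expect_gte(ring$integrated / total, 0.9)
})

test_that("a planted-negative cell has near-zero stained ring area", {
  p <- imaging_preset(field_shape = c(160L, 160L),
                      layer_bands = list(all = c(0.1, 0.9)),
                      cells_per_layer = c(all = 4L),
                      seed = 6L, name = "neg")  # sting fraction defaults to 0
  fld <- generate_field(p, "g", 1)
  ct <- quantify_field(fld$stack, layer_bands = p$layer_bands)
  for (k in seq_len(nrow(ct$cells))) {
    ring <- measure_perinuclear(ct, k, fld$stack)
    expect_lte(ring$stained_area_px / ring$area_px, 0.25)
  }
})

test_that("compartment measurements are additive and match a per-pixel loop", {
  set.seed(31)
  for (rep in 1:5) {
    h <- 32
    img <- matrix(runif(h * h, 0, 100), h, h)
    nuc_idx <- stingquant:::annulus_indices(h, h, 16, 16, 5)
    cyt_idx <- stingquant:::annulus_indices(h, h, 16, 16, 10, 5)
    ct <- structure(list(
      masks = list(list(nuclear = nuc_idx, perinuclear = integer(0),
                        cytoplasm = cyt_idx)),
      pixel_size_um = 0.5, background = list(sting = 50)),
      class = "CellTable")
    st <- channel_stack(list(nucleus_dye = img, sting = img))
    ct$background$nucleus_dye <- 50
    mn <- measure_compartment(ct, 1, st, "sting", "nuclear")
    mc <- measure_compartment(ct, 1, st, "sting", "cytoplasmic")
    # brute-force loop
    s_nuc <- 0
    for (i in nuc_idx) s_nuc <- s_nuc + img[i]
    expect_equal(mn$integrated, s_nuc)
    expect_equal(mn$mean, s_nuc / length(nuc_idx))
    expect_equal(mn$area_um2, length(nuc_idx) * 0.25)
    # additivity over disjoint compartments
    expect_equal(mn$integrated + mc$integrated,
                 sum(img[c(nuc_idx, cyt_idx)]))
  }
})

test_that("control-based calling has the closed-form false-positive rate", {
  set.seed(12)
  ref <- rnorm(20000, 100, 10)
  cells <- data.frame(perinuclear_sting_mean = rnorm(40000, 100, 10))
  pol <- positivity_policy("control_mean_plus_k_sd", k = 2, reference = ref)
  called <- call_positive(cells, pol)
  fpr <- mean(called$pos_sting)
  expect_lt(abs(fpr - pnorm(-2)), 0.005)  # P(Z > 2) ~ 2.28%
  thr <- attr(called, "positivity_thresholds")$pos_sting
  expect_lt(abs(thr[["threshold"]] - (mean(ref) + 2 * sd(ref))), 1e-9)
})

test_that("fixed threshold 0 flags all strictly positive measurements", {
  cells <- data.frame(perinuclear_sting_mean = c(0.5, 2, 100))
  pol <- positivity_policy("fixed", threshold = 0)
  expect_true(all(call_positive(cells, pol)$pos_sting))
})

test_that("positivity policies validate their inputs", {
  expect_error(positivity_policy("control_mean_plus_k_sd"), "reference")
  expect_error(positivity_policy("fixed"), "threshold")
  expect_error(positivity_policy(k = -1, reference = 1:5), "positive")
  cells <- data.frame(other_col = 1:3)
  expect_error(call_positive(cells, positivity_policy("fixed", threshold = 1)),
               "measurement column not found")
})

test_that("positivity counts are non-increasing in the threshold multiplier k", {
  set.seed(44)
  ref <- rnorm(500, 100, 20)
  cells <- data.frame(perinuclear_sting_mean = rnorm(2000, 130, 30))
  counts <- vapply(c(0.5, 1, 2, 3), function(k)
    sum(call_positive(cells, positivity_policy("control_mean_plus_k_sd",
                                               k = k,
                                               reference = ref))$pos_sting),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("per-cell positivity accuracy reaches 0.9 on a planted cohort", {
  p <- get_preset("fig1b_c9_layerV", seed = 29)
  cohort <- quantify_imaging_cohort(p, c(disease = 1L, control = 1L),
                                    fields_per_section = 3L)
  cohort <- call_cohort_positivity(cohort)
  cells <- cohort$cells
  acc_n <- 0L; acc_ok <- 0L
  for (fid in unique(cells$field_id)) {
    cc <- cells[cells$field_id == fid, ]
    tt <- cohort$truth[cohort$truth$field_id == fid, ]
    mt <- match_to_truth(cc, tt)
    ok <- mt$dist < 5
    acc_n <- acc_n + sum(ok)
    acc_ok <- acc_ok + sum(cc$pos_sting[ok] == tt$pos_sting[mt$idx[ok]])
  }
  expect_gte(acc_n, 250L)
  expect_gte(acc_ok / acc_n, 0.9)
})

test_that("dual-positive counting is the conjunction of flags", {
  cells <- data.frame(pos_effector = c(TRUE, TRUE, FALSE),
                      pos_sting = c(TRUE, FALSE, TRUE))
  expect_equal(count_dual_positive(cells), 1L)
  set.seed(2)
  for (rep in 1:10) {
    cc <- data.frame(pos_effector = runif(50) < 0.4,
                     pos_sting = runif(50) < 0.3)
    expect_lte(count_dual_positive(cc),
               min(sum(cc$pos_effector), sum(cc$pos_sting)))
  }
  expect_error(count_dual_positive(data.frame(pos_sting = TRUE)), "flags")
})

test_that("planted dual-positive fraction is recovered on the knockdown preset", {
  res <- run_cohort_analysis("fig6_shTDP43", seed = 19,
                             group_sizes = c(disease = 2L, control = 2L),
                             fields_per_section = 3L,
                             markers = c("sting", "effector"))
  cells <- res$cohort$cells
  dis <- cells[cells$group == "disease" & cells$is_neuron, ]
  frac <- mean(dis$pos_sting & dis$pos_effector)
  n <- nrow(dis)
  expect_gte(n, 200L)
  half <- 2.576 * sqrt(0.35 * 0.65 / n)
  expect_lt(abs(frac - 0.35), half + 0.02)  # binomial 99% CI + calling slack
  # control wells stay near their planted 5% dual rate
  ctl <- cells[cells$group == "control" & cells$is_neuron, ]
  expect_lt(mean(ctl$pos_sting & ctl$pos_effector), 0.12)
})
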