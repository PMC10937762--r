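make_disk_channel <- function(h, w, centers, r, value = 3000, bg = 0) {
  m <- matrix(bg, h, w)
  for (i in seq_len(nrow(centers))) {
    idx <- stingquant:::annulus_indices(h, w, centers[i, 1], centers[i, 2], r)
    m[idx] <- value
  }
  m
}

test_that("two separated disks segment into two labels at planted centres", {
  centers <- rbind(c(40, 40), c(40, 90))
  ch <- make_disk_channel(128, 128, centers, r = 8)
  lm <- segment_nuclei(ch)
  expect_equal(max(lm$labels), 2L)
  for (k in 1:2) {
    idx <- which(lm$labels == k, arr.ind = TRUE)
    cen <- colMeans(idx)
    d <- sqrt(rowSums((t(t(centers) - cen))^2))
    expect_lt(min(d), 1)
  }
})

test_that("blank channel yields an empty mask with a warning", {
  expect_warning(lm <- segment_nuclei(matrix(0, 64, 64)), "blank")
  expect_equal(max(lm$labels), 0L)
})

test_that("watershed splits two overlapping nuclei", {
  # centres 12 px apart with radius 8: ~30% overlap
  centers <- rbind(c(40, 40), c(40, 52))
  ch <- make_disk_channel(96, 96, centers, r = 8)
  lm <- segment_nuclei(ch)
  expect_equal(max(lm$labels), 2L)
})

test_that("labels are consecutive and segmentation is deterministic", {
  p <- tiny_preset(seed = 21L)
  ch <- generate_field(p, "g", 1)$stack$channels$nucleus_dye
  l1 <- segment_nuclei(ch)$labels
  l2 <- segment_nuclei(ch)$labels
  expect_identical(l1, l2)
  expect_identical(sort(unique(as.integer(l1))), 0:max(l1))
})

test_that("neuron mask covers planted neuronal pixels; degenerate channels", {
  p <- tiny_preset(seed = 8L, n_cells = 8L)
  fld <- generate_field(p, "g", 1)
  mask <- define_neuron_mask(fld$stack$channels$neuron_marker)
  truth <- fld$truth
  planted <- unlist(lapply(seq_len(nrow(truth)), function(i)
    stingquant:::annulus_indices(192, 192, truth$y[i] + 1, truth$x[i] + 1,
                                 truth$nucleus_radius[i] + 9,
                                 truth$nucleus_radius[i] + 1)))
  expect_gte(mean(mask[planted]), 0.95)
  expect_false(any(define_neuron_mask(matrix(0, 32, 32))))
  expect_true(all(define_neuron_mask(matrix(65535, 32, 32))))
  expect_error(define_neuron_mask(matrix(1, 4, 4), policy = "magic"))
})

test_that("single nucleus in one annulus gets exactly the annulus as cytoplasm", {
  h <- 96
  nuc_ch <- make_disk_channel(h, h, rbind(c(48, 48)), r = 7)
  ann_idx <- stingquant:::annulus_indices(h, h, 48, 48, 16, 7)
  neuron <- matrix(FALSE, h, h); neuron[ann_idx] <- TRUE
  lm <- segment_nuclei(nuc_ch)
  st <- channel_stack(list(nucleus_dye = nuc_ch), pixel_size_um = 0.5)
  ct <- assemble_cells(lm, neuron, st, layer_bands = list(all = c(0, 1)))
  expect_equal(nrow(ct$cells), 1L)
  # cytoplasm = annulus pixels outside the (smoothed) segmented nucleus
  expected <- setdiff(ann_idx, which(lm$labels > 0))
  expect_setequal(ct$masks[[1]]$cytoplasm, expected)
  expect_true(ct$cells$is_neuron[1])
})

test_that("shared-bridge cytoplasm splits by the geodesic nearest rule (oracle)", {
  h <- 40; w <- 70
  nuclei <- matrix(0L, h, w)
  nuclei[stingquant:::annulus_indices(h, w, 20, 15, 5)] <- 1L
  nuclei[stingquant:::annulus_indices(h, w, 20, 55, 5)] <- 2L
  allowed <- matrix(FALSE, h, w)
  allowed[17:23, 8:62] <- TRUE           # bridge joining the two somata
  allowed[nuclei > 0] <- FALSE
  got <- propagate_labels(nuclei, allowed, max_dist_px = 60)$labels
  want <- oracle_geodesic_labels(nuclei, allowed)
  expect_identical(got[allowed], want[allowed])
  # equidistant column ties break to the lower label
  mid <- got[17:23, 35]
  expect_true(all(mid[mid > 0] == 1L))
})

test_that("cytoplasm regions are disjoint and confined to neuron mask minus nuclei", {
  p <- tiny_preset(seed = 13L, n_cells = 8L)
  fld <- generate_field(p, "g", 2)
  ct <- quantify_field(fld$stack, layer_bands = p$layer_bands,
                       compute_cytoplasm = TRUE)
  all_cyto <- unlist(lapply(ct$masks, `[[`, "cytoplasm"))
  expect_equal(anyDuplicated(all_cyto), 0L)
  nuc_all <- unlist(lapply(ct$masks, `[[`, "nuclear"))
  expect_length(intersect(all_cyto, nuc_all), 0L)
  nmask <- define_neuron_mask(fld$stack$channels$neuron_marker)
  expect_true(all(nmask[all_cyto]))
})

test_that("a nucleus without neuron-marker overlap is excluded from neuron counts", {
  h <- 96
  nuc_ch <- make_disk_channel(h, h, rbind(c(30, 30), c(65, 65)), r = 7)
  ann_idx <- stingquant:::annulus_indices(h, h, 30, 30, 16, 7)
  neuron <- matrix(FALSE, h, h); neuron[ann_idx] <- TRUE
  st <- channel_stack(list(nucleus_dye = nuc_ch))
  ct <- assemble_cells(segment_nuclei(nuc_ch), neuron, st,
                       layer_bands = list(all = c(0, 1)))
  expect_equal(sum(ct$cells$is_neuron), 1L)
  s <- summarize_field(ct$cells)
  expect_equal(s$n_neurons, 1L)
})

test_that("nucleus detection recall and precision reach 0.95 on a noisy cohort", {
  p <- get_preset("fig1b_c9_layerV", seed = 17)
  tp <- 0L; n_truth <- 0L; n_seg <- 0L
  for (i in 1:10) {
    fld <- generate_field(p, "disease", i)
    ct <- quantify_field(fld$stack, layer_bands = p$layer_bands,
                         compute_cytoplasm = FALSE)
    mt <- match_to_truth(ct$cells, fld$truth)
    hit <- mt$dist < 5 & !duplicated(mt$idx)
    tp <- tp + sum(hit)
    n_truth <- n_truth + nrow(fld$truth)
    n_seg <- n_seg + nrow(ct$cells)
  }
  expect_gte(n_truth, 500L)
  expect_gte(tp / n_truth, 0.95)   # recall
  expect_gte(tp / n_seg, 0.95)     # precision
})
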