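# Independent brute-force oracles used across tests. These deliberately share
# no code with the package implementations they check.

# Binary dilation by explicit per-pixel neighbourhood scan, one iteration at a
# time.
oracle_dilate <- function(mask, iterations, connectivity = 8) {
  m <- mask > 0
  h <- nrow(m); w <- ncol(m)
  for (it in seq_len(iterations)) {
    out <- m
    for (r in 1:h) for (c_ in 1:w) {
      if (m[r, c_]) next
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        if (connectivity == 4 && abs(dr) + abs(dc) != 1) next
        rr <- r + dr; cc <- c_ + dc
        if (rr >= 1 && rr <= h && cc >= 1 && cc <= w && m[rr, cc]) {
          out[r, c_] <- TRUE
        }
      }
    }
    m <- out
  }
  m
}

# Geodesic nearest-source labelling by Dijkstra over the pixel graph with
# chamfer 3-4 weights, ties resolved to the lower label.
oracle_geodesic_labels <- function(nuclei, allowed, max_dist_px = 1e6) {
  h <- nrow(nuclei); w <- ncol(nuclei)
  trav <- allowed | nuclei > 0
  D <- matrix(Inf, h, w); L <- matrix(0L, h, w)
  D[nuclei > 0] <- 0; L[nuclei > 0] <- nuclei[nuclei > 0]
  done <- matrix(FALSE, h, w)
  repeat {
    idx <- which(!done & is.finite(D))
    if (!length(idx)) break
    i <- idx[which.min(D[idx] * 1000 + L[idx])]  # min dist, then min label
    done[i] <- TRUE
    rc <- arrayInd(i, c(h, w))
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- rc[1] + dr; cc <- rc[2] + dc
      if (rr < 1 || rr > h || cc < 1 || cc > w || !trav[rr, cc]) next
      nd <- D[i] + if (abs(dr) + abs(dc) == 2) 4 else 3
      if (nd < D[rr, cc] || (nd == D[rr, cc] && L[i] < L[rr, cc])) {
        D[rr, cc] <- nd; L[rr, cc] <- L[i]
        done[rr, cc] <- FALSE
      }
    }
  }
  L[!allowed] <- 0L
  L[D > max_dist_px * 3] <- 0L
  L
}

# Naive two-pass preranked enrichment score: build the full running sum by
# explicit loop over ranks.
oracle_es <- function(scores, in_set, p = 1) {
  N <- length(scores)
  NR <- sum(abs(scores[in_set])^p)
  miss <- 1 / (N - sum(in_set))
  rs <- numeric(N)
  run <- 0
  for (i in 1:N) {
    run <- run + if (in_set[i]) abs(scores[i])^p / NR else -miss
    rs[i] <- run
  }
  i_max <- which.max(rs); i_min <- which.min(rs)
  top <- rs[i_max]; bot <- min(rs[i_min], 0)
  if (abs(top + bot) < 1e-12) 0 else if (top > -bot) top else bot
}

# Tiny quiet imaging preset for fast structural tests.
tiny_preset <- function(seed = 1L, n_cells = 6L, noise = TRUE, ...) {
  imaging_preset(
    field_shape = c(192L, 192L),
    layer_bands = list("II/III" = c(0.05, 0.45), "V" = c(0.55, 0.95)),
    cells_per_layer = c("II/III" = ceiling(n_cells / 2),
                        "V" = floor(n_cells / 2)),
    noise = if (noise) list(gaussian_sd = 30, poisson_scale = 1,
                            background = 100)
    else list(gaussian_sd = 0, poisson_scale = 0, background = 0),
    seed = seed, name = "tiny", ...)
}

# Match segmented cells to planted truth rows by nearest centroid; returns the
# truth row index per segmented cell and the distances.
match_to_truth <- function(cells, truth) {
  if (nrow(cells) == 0L || nrow(truth) == 0L)
    return(list(idx = integer(0), dist = numeric(0)))
  d2 <- outer(cells$x, truth$x, "-")^2 + outer(cells$y, truth$y, "-")^2
  idx <- apply(d2, 1, which.min)
  list(idx = idx, dist = sqrt(d2[cbind(seq_len(nrow(cells)), idx)]))
}
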