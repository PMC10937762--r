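#' Segment nuclei from the nuclear-dye channel
#'
#' Minimal standard pipeline: Gaussian smoothing, Otsu threshold, hole
#' filling, distance-transform watershed to split touching nuclei, then a
#' size gate. All parameters are exposed; the defaults suit the synthetic
#' cohorts (nuclei of radius ~5-10 px).
#'
#' @param nucleus_channel 2-D numeric matrix.
#' @param min_area_px,max_area_px size gate in pixels; objects outside are
#'   dropped.
#' @param smooth_sigma Gaussian smoothing sigma (px).
#' @param watershed_tolerance tolerance passed to the watershed split.
#' @return A `LabelMask`: list with `labels` (integer matrix, 0 = background,
#'   consecutive positive labels) and `provenance`.
#' @export
segment_nuclei <- function(nucleus_channel, min_area_px = 30L,
                           max_area_px = 2500L, smooth_sigma = 1.5,
                           watershed_tolerance = 1) {
  stopifnot(is.matrix(nucleus_channel))
  rng <- range(nucleus_channel)
  if (rng[1] == rng[2]) {
    warning("blank nucleus channel: returning empty mask")
    return(structure(list(labels = matrix(0L, nrow(nucleus_channel),
                                          ncol(nucleus_channel)),
                          provenance = "segment_nuclei(blank)"),
                     class = "LabelMask"))
  }
  x <- (nucleus_channel - rng[1]) / (rng[2] - rng[1])
  if (smooth_sigma > 0) x <- gaussian_blur(x, smooth_sigma)
  img <- EBImage::Image(pmin(pmax(x, 0), 1))
  bw <- img > EBImage::otsu(img)
  bw <- EBImage::fillHull(bw)
  dm <- EBImage::distmap(bw)
  labels <- EBImage::imageData(EBImage::watershed(dm,
                                                  tolerance = watershed_tolerance))
  labels <- relabel_size_gate(labels, min_area_px, max_area_px)
  structure(list(labels = labels,
                 provenance = sprintf(
                   "segment_nuclei(sigma=%g, otsu, watershed tol=%g, area=[%d,%d])",
                   smooth_sigma, watershed_tolerance, min_area_px,
                   max_area_px)),
            class = "LabelMask")
}

# Drop objects outside the size gate and relabel 1..K in raster order of the
# objects' first pixel (deterministic).
relabel_size_gate <- function(labels, min_area_px, max_area_px) {
  labels <- matrix(as.integer(labels), nrow(labels))
  if (max(labels) == 0L) return(labels)
  areas <- tabulate(labels)
  keep <- which(areas >= min_area_px & areas <= max_area_px)
  map <- integer(max(labels))
  nz <- which(labels > 0L)
  first_px <- nz[!duplicated(labels[nz])]        # raster-order first pixel
  first_of <- integer(max(labels))
  first_of[labels[first_px]] <- first_px
  map[keep[order(first_of[keep])]] <- seq_along(keep)
  out <- matrix(0L, nrow(labels), ncol(labels))
  nz <- labels > 0L
  out[nz] <- map[labels[nz]]
  out
}

#' Threshold the pan-neuronal marker channel into a neuron mask
#'
#' @param neuron_channel 2-D numeric matrix (TUJ1/HuC-HuD analogue).
#' @param policy `"otsu"` (default) or `"quantile"` (foreground above the
#'   given quantile).
#' @param quantile cut for the quantile policy.
#' @return Logical matrix; `attr(, "policy")` records the policy used.
#' @export
define_neuron_mask <- function(neuron_channel, policy = c("otsu", "quantile"),
                               quantile = 0.75) {
  stopifnot(is.matrix(neuron_channel))
  policy <- match.arg(policy)
  rng <- range(neuron_channel)
  if (rng[1] == rng[2]) {
    mask <- matrix(neuron_channel > 0, nrow(neuron_channel))
  } else if (policy == "otsu") {
    x <- (neuron_channel - rng[1]) / (rng[2] - rng[1])
    mask <- matrix(x > EBImage::otsu(EBImage::Image(x)),
                   nrow(neuron_channel))
  } else {
    mask <- neuron_channel > stats::quantile(neuron_channel, quantile)
  }
  attr(mask, "policy") <- policy
  mask
}

#' Geodesic nearest-nucleus cytoplasm assignment (chamfer propagation)
#'
#' Assigns each pixel of `allowed` (typically the neuron mask minus nuclei) to
#' its geodesically nearest nucleus, where distance is measured by chamfer
#' 3-4 weights (3 per orthogonal step, 4 per diagonal step) along paths
#' confined to `allowed` plus the nuclei. Ties go to the lower nucleus label.
#'
#' @param nuclei integer label matrix (sources, distance 0).
#' @param allowed logical matrix of traversable pixels.
#' @param max_dist_px maximum Euclidean-equivalent distance (chamfer units /
#'   3) a pixel may lie from its nucleus.
#' @return List with `labels` (integer matrix; assignment over `allowed`,
#'   nuclei pixels keep their own label) and `dist` (chamfer distance / 3).
#' @export
propagate_labels <- function(nuclei, allowed, max_dist_px = 30) {
  stopifnot(is.matrix(nuclei), is.matrix(allowed),
            all(dim(nuclei) == dim(allowed)))
  h <- nrow(nuclei); w <- ncol(nuclei)
  big <- .Machine$integer.max %/% 2L
  D <- matrix(big, h, w)
  L <- matrix(0L, h, w)
  src <- nuclei > 0L
  D[src] <- 0L; L[src] <- nuclei[src]
  trav <- allowed | src
  max_chamfer <- ceiling(max_dist_px * 3)
  steps <- list(c(-1, 0, 3L), c(1, 0, 3L), c(0, -1, 3L), c(0, 1, 3L),
                c(-1, -1, 4L), c(-1, 1, 4L), c(1, -1, 4L), c(1, 1, 4L))
  repeat {
    changed <- FALSE
    for (s in steps) {
      cd <- shift_mat(D, s[1], s[2], big) + s[3]
      cl <- shift_mat(L, s[1], s[2], 0L)
      upd <- trav & cl > 0L & cd <= max_chamfer &
        (cd < D | (cd == D & cl < L))
      if (any(upd)) {
        D[upd] <- cd[upd]; L[upd] <- cl[upd]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  L[!trav] <- 0L
  list(labels = L, dist = D / 3)
}

#' Assemble per-cell records from a segmented field
#'
#' For every nucleus this builds the three measurement compartments and the
#' per-compartment, per-channel measurements:
#'
#' * nuclear mask — the nucleus label itself;
#' * perinuclear mask — the nucleus dilated `ring_iterations` times with a
#'   3 x 3 (8-connectivity) structuring element, minus all nuclei (ring);
#' * cytoplasm mask — neuron-mask pixels outside all nuclei assigned to their
#'   geodesically nearest nucleus (ties to the lower label) within
#'   `max_radius_um` of it.
#'
#' A cell is a neuron (`is_neuron`) iff at least half of its perinuclear ring
#' overlaps the neuron mask. Layer labels come from y-band geometry when
#' `layer_bands` is given (marker-based assignment is applied downstream via
#' positivity calling on the `layer_marker` channel); otherwise cells are
#' `unassigned` (with a warning).
#'
#' @param nuclei a `LabelMask` from [segment_nuclei()].
#' @param neuron_mask logical matrix from [define_neuron_mask()], or `NULL`
#'   to treat the whole field as neuronal.
#' @param stack the `ChannelStack` measured (2-D; see [project_z()]).
#' @param layer_bands named list of y-fraction intervals, or `NULL`.
#' @param ring_iterations dilation iterations for the perinuclear ring
#'   (default 10, the protocol value).
#' @param connectivity 8 (3 x 3 square element) or 4 (cross).
#' @param max_radius_um cytoplasm assignment radius.
#' @param compute_cytoplasm set `FALSE` to skip cytoplasm propagation when
#'   only nuclear/perinuclear readouts are needed.
#' @return A `CellTable`: list with `cells` (data.frame, one row per cell,
#'   measurement columns named `<compartment>_<role>_<stat>`), `masks`
#'   (per-cell linear pixel indices per compartment), `pixel_size_um`, and
#'   `background` (per-channel pixel-level background thresholds).
#' @export
assemble_cells <- function(nuclei, neuron_mask, stack, layer_bands = NULL,
                           ring_iterations = 10L, connectivity = 8L,
                           max_radius_um = 15, compute_cytoplasm = TRUE) {
  stopifnot(inherits(nuclei, "LabelMask"), inherits(stack, "ChannelStack"))
  labels <- nuclei$labels
  h <- nrow(labels); w <- ncol(labels)
  px <- stack$pixel_size_um
  n_cells <- max(labels)
  chans <- stack$channels
  if (any(vapply(chans, function(x) length(dim(x)) == 3L, logical(1))))
    stop("assemble_cells requires a 2-D stack; project first (project_z)")
  if (is.null(neuron_mask)) neuron_mask <- matrix(TRUE, h, w)
  bg <- lapply(chans, background_level)

  cyto_lab <- NULL
  if (compute_cytoplasm && n_cells > 0) {
    allowed <- neuron_mask & labels == 0L
    cyto_lab <- propagate_labels(labels, allowed,
                                 max_dist_px = max_radius_um / px)$labels
    cyto_lab[labels > 0L] <- 0L
  }

  if (is.null(layer_bands) && n_cells > 0)
    warning("no layer information supplied; layer_label set to 'unassigned'")

  any_nucleus <- labels > 0L
  nz <- which(labels > 0L)
  idx_by_label <- split(nz, labels[nz])
  rows <- vector("list", n_cells)
  masks <- vector("list", n_cells)
  for (k in seq_len(n_cells)) {
    idx_nuc <- idx_by_label[[as.character(k)]]
    rc <- arrayInd(idx_nuc, dim(labels))
    cen_r <- mean(rc[, 1]); cen_c <- mean(rc[, 2])
    # perinuclear ring on a cropped window (pad by the dilation radius)
    pad <- ring_iterations + 1L
    r0 <- max(1L, min(rc[, 1]) - pad); r1 <- min(h, max(rc[, 1]) + pad)
    c0 <- max(1L, min(rc[, 2]) - pad); c1 <- min(w, max(rc[, 2]) + pad)
    sub_nuc <- labels[r0:r1, c0:c1] == k
    sub_dil <- dilate_mask(sub_nuc, iterations = ring_iterations,
                           connectivity = connectivity)
    sub_ring <- sub_dil & !any_nucleus[r0:r1, c0:c1]
    ring_rc <- which(sub_ring, arr.ind = TRUE)
    idx_ring <- (ring_rc[, 1] + r0 - 1L) +
      (ring_rc[, 2] + c0 - 2L) * h
    idx_cyto <- if (!is.null(cyto_lab)) which(cyto_lab == k) else integer(0)
    frac_neuron <- if (length(idx_ring)) mean(neuron_mask[idx_ring]) else 0
    layer <- "unassigned"
    if (!is.null(layer_bands)) {
      yfrac <- (cen_r - 0.5) / h
      for (lay in names(layer_bands)) {
        b <- layer_bands[[lay]]
        if (yfrac >= b[1] && yfrac <= b[2]) { layer <- lay; break }
      }
    }
    meas <- list()
    for (role in names(chans)) {
      ch <- chans[[role]]
      for (cmp in c("nuclear", "perinuclear", "cytoplasmic")) {
        idx <- switch(cmp, nuclear = idx_nuc, perinuclear = idx_ring,
                      cytoplasmic = idx_cyto)
        v <- ch[idx]
        a <- length(idx)
        meas[[paste(cmp, role, "area_px", sep = "_")]] <- a
        meas[[paste(cmp, role, "integrated", sep = "_")]] <- sum(v)
        meas[[paste(cmp, role, "mean", sep = "_")]] <-
          if (a > 0) sum(v) / a else NA_real_
        meas[[paste(cmp, role, "stained_area_px", sep = "_")]] <-
          sum(v > bg[[role]])
      }
    }
    rows[[k]] <- c(list(cell_label = k, x = cen_c - 1, y = cen_r - 1,
                        nuclear_area_um2 = length(idx_nuc) * px^2,
                        layer_label = layer,
                        is_neuron = frac_neuron >= 0.5,
                        ring_clipped = length(idx_ring) == 0L),
                   meas)
    masks[[k]] <- list(nuclear = idx_nuc, perinuclear = idx_ring,
                       cytoplasm = idx_cyto)
  }
  cells <- if (n_cells > 0)
    do.call(rbind, lapply(rows, function(r) as.data.frame(r,
                                                          stringsAsFactors = FALSE)))
  else empty_cell_table_df()
  structure(list(cells = cells, masks = masks, pixel_size_um = px,
                 background = bg,
                 params = list(ring_iterations = ring_iterations,
                               connectivity = connectivity,
                               max_radius_um = max_radius_um)),
            class = "CellTable")
}

empty_cell_table_df <- function() {
  data.frame(cell_label = integer(0), x = numeric(0), y = numeric(0),
             nuclear_area_um2 = numeric(0), layer_label = character(0),
             is_neuron = logical(0), ring_clipped = logical(0),
             stringsAsFactors = FALSE)
}

#' @export
print.CellTable <- function(x, ...) {
  cat(sprintf("<CellTable> %d cell(s), ring %d iterations (%d-connectivity)\n",
              nrow(x$cells), x$params$ring_iterations,
              x$params$connectivity))
  invisible(x)
}
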