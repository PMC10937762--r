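#' Define a synthetic imaging preset
#'
#' An `ImagingPreset` fully specifies a synthetic fluorescence cohort: field
#' geometry, cortical layer bands, per-layer cell counts (optionally
#' group-specific, to plant neuron-loss contrasts), planted positive fractions
#' per (group, layer, marker), the intensity model, perinuclear signal bias,
#' and the noise/PSF forward model. Identical (preset, seed) pairs reproduce
#' identical images.
#'
#' @param field_shape integer `c(H, W)` in pixels.
#' @param pixel_size_um physical pixel size (um).
#' @param layer_bands named list of `c(lo, hi)` y-fraction intervals, e.g.
#'   `list("II/III" = c(0.05, 0.45), "V" = c(0.55, 0.95))`. Bands must be
#'   disjoint and lie within `[0, 1]`.
#' @param cells_per_layer either a named integer vector (cells per field per
#'   layer, all groups) or a named list `group -> named vector` for
#'   group-specific densities (planted neuron loss).
#' @param positive_fraction data.frame with columns `group`, `layer`,
#'   `marker`, `fraction`; unlisted combinations default per marker:
#'   `layer_marker` is 1 in layer "V" and 0 elsewhere, other markers 0.
#' @param dual_fraction optional data.frame (`group`, `layer`, `fraction`)
#'   forcing a planted fraction of cells jointly positive for `sting` and
#'   `effector` (bounded by both marginals).
#' @param intensity_model named list `marker -> c(negative_mean,
#'   positive_mean, sd)` in arbitrary 16-bit fluorescence units.
#' @param nucleus_radius_px `c(mean, sd)` of nucleus radius in pixels.
#' @param peri_width_px,distal_width_px widths of the perinuclear and distal
#'   cytoplasm annuli (px).
#' @param perinuclear_bias fraction of a positive cell's STING signal placed
#'   in the perinuclear annulus (the rest goes to the distal cytoplasm).
#' @param noise list `gaussian_sd`, `poisson_scale`, `background`.
#' @param psf_sigma_px Gaussian PSF sigma (px); 0 disables blurring.
#' @param n_z number of z-planes (planes are replicated with independent
#'   noise; quantification projects them).
#' @param layer_marker_localization `"nuclear"` (CTIP2-like) or
#'   `"cytoplasmic"` (CRYM-like).
#' @param seed integer master seed for the preset.
#' @param name preset name.
#' @return An object of class `ImagingPreset`.
#' @export
imaging_preset <- function(field_shape = c(1024L, 1024L),
                           pixel_size_um = 0.5,
                           layer_bands = list("II/III" = c(0.05, 0.45),
                                              "V" = c(0.55, 0.95)),
                           cells_per_layer = c("II/III" = 25L, "V" = 25L),
                           positive_fraction = NULL,
                           dual_fraction = NULL,
                           intensity_model = default_intensity_model(),
                           nucleus_radius_px = c(7, 0.8),
                           peri_width_px = 4,
                           distal_width_px = 6,
                           perinuclear_bias = 0.8,
                           noise = list(gaussian_sd = 40, poisson_scale = 1,
                                        background = 100),
                           psf_sigma_px = 1,
                           n_z = 1L,
                           layer_marker_localization = c("nuclear", "cytoplasmic"),
                           seed = 1L,
                           name = "custom") {
  layer_marker_localization <- match.arg(layer_marker_localization)
  stopifnot(length(field_shape) == 2L, all(field_shape >= 32),
            perinuclear_bias >= 0, perinuclear_bias <= 1,
            nucleus_radius_px[1] > 0)
  bands <- do.call(rbind, layer_bands)
  if (any(bands < 0) || any(bands > 1) || any(bands[, 1] >= bands[, 2]))
    stop("layer bands must be sub-intervals of [0, 1]")
  if (length(layer_bands) > 1L) {
    o <- order(bands[, 1])
    if (any(bands[o, 1][-1] < bands[o, 2][-nrow(bands)]))
      stop("layer bands must be disjoint")
  }
  if (!is.null(positive_fraction)) {
    stopifnot(is.data.frame(positive_fraction),
              all(c("group", "layer", "marker", "fraction") %in%
                    names(positive_fraction)),
              all(positive_fraction$fraction >= 0),
              all(positive_fraction$fraction <= 1))
  }
  for (m in names(intensity_model)) {
    im <- intensity_model[[m]]
    if (im[2] <= im[1])
      stop("positive_mean must exceed negative_mean for marker ", m)
  }
  structure(list(field_shape = as.integer(field_shape),
                 pixel_size_um = pixel_size_um, layer_bands = layer_bands,
                 cells_per_layer = cells_per_layer,
                 positive_fraction = positive_fraction,
                 dual_fraction = dual_fraction,
                 intensity_model = intensity_model,
                 nucleus_radius_px = nucleus_radius_px,
                 peri_width_px = peri_width_px,
                 distal_width_px = distal_width_px,
                 perinuclear_bias = perinuclear_bias, noise = noise,
                 psf_sigma_px = psf_sigma_px, n_z = as.integer(n_z),
                 layer_marker_localization = layer_marker_localization,
                 seed = as.integer(seed), name = name),
            class = "ImagingPreset")
}

#' Default synthetic intensity model
#'
#' The source measurements come from stained tissue whose intensity
#' distributions are not published; these per-marker
#' `(negative_mean, positive_mean, sd)` values are synthetic free parameters,
#' chosen to give the clear positive/negative separation typical of a
#' well-stained confocal field.
#'
#' Negative (unstained) cells sit at the image background: a marker-negative
#' neuron shows no specific signal, so its `negative_mean` is 0 and only the
#' shared background/noise floor remains. The per-cell brightness spread `sd`
#' applies at `positive_mean` and scales with the drawn mean (a constant
#' coefficient of variation), the usual behaviour of staining intensity.
#'
#' @return Named list of `c(negative_mean, positive_mean, sd)` per marker.
#' @export
default_intensity_model <- function() {
  list(nucleus_dye   = c(1500, 3000, 300),
       neuron_marker = c(0,    2500, 300),
       sting         = c(0,    3000, 400),
       effector      = c(0,    2500, 300),
       layer_marker  = c(0,    3000, 300))
}

lookup_fraction <- function(preset, group, layer, marker) {
  pf <- preset$positive_fraction
  if (!is.null(pf)) {
    hit <- pf$group == group & pf$layer == layer & pf$marker == marker
    if (any(hit)) return(pf$fraction[which(hit)[1]])
  }
  if (marker == "layer_marker") return(if (layer == "V") 1 else 0)
  0
}

lookup_counts <- function(preset, group) {
  cpl <- preset$cells_per_layer
  if (is.list(cpl)) {
    if (!group %in% names(cpl))
      stop("no cells_per_layer entry for group ", group)
    cpl <- cpl[[group]]
  }
  cpl
}

place_cells <- function(h, w, band, n, min_dist, margin, max_tries = 200L) {
  if (n == 0L) return(cbind(row = numeric(0), col = numeric(0)))
  # inset 2 px from the band edges so centroid jitter from the PSF cannot
  # push a cell's measured centre across a band boundary
  lo <- max(margin, ceiling(band[1] * h) + 2)
  hi <- min(h - margin, floor(band[2] * h) - 2)
  if (hi <= lo) stop("placement error: layer band too thin for cell radius")
  rows <- numeric(0); cols <- numeric(0)
  tries <- 0L
  while (length(rows) < n) {
    tries <- tries + 1L
    if (tries > max_tries * n)
      stop(sprintf(paste0("placement error: could not place %d cells in band ",
                          "[%.2f, %.2f] without overlap after %d attempts"),
                   n, band[1], band[2], tries))
    r <- stats::runif(1, lo, hi)
    c_ <- stats::runif(1, margin, w - margin)
    if (length(rows) == 0L ||
        min((rows - r)^2 + (cols - c_)^2) >= min_dist^2) {
      rows <- c(rows, r); cols <- c(cols, c_)
    }
  }
  cbind(row = round(rows), col = round(cols))
}

#' Generate one synthetic imaging field with its planted ground truth
#'
#' Cells are rendered as a nucleus disk plus a cytoplasm annulus split into a
#' perinuclear and a distal zone. For STING-positive cells the planted
#' `perinuclear_bias` fraction of the cell's total STING signal is placed in
#' the perinuclear zone, emulating the perinuclear relocalisation of activated
#' STING; negative cells carry uniform low-level signal. The effector channel
#' (p-IRF3 / p-NF-kB / gH2AX analogue) is nuclear; the layer marker is nuclear
#' (CTIP2-like) or cytoplasmic (CRYM-like). Channels are blurred by a Gaussian
#' PSF, then carry Poisson shot noise and Gaussian read noise.
#'
#' @param preset an [imaging_preset()].
#' @param group_label group the field belongs to (selects planted fractions).
#' @param field_index non-negative integer; together with the preset seed it
#'   determines the field's RNG stream.
#' @return A list with elements `stack` (a `ChannelStack`) and `truth` (a
#'   data.frame, one row per planted cell: id, centroid, layer, radius,
#'   per-marker true positivity and true mean intensity).
#' @export
generate_field <- function(preset, group_label, field_index = 1L) {
  stopifnot(inherits(preset, "ImagingPreset"), field_index >= 0)
  seed <- derive_seed(preset$seed,
                      sprintf("%s|%s|field%06d", preset$name, group_label,
                              as.integer(field_index)))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  h <- preset$field_shape[1]; w <- preset$field_shape[2]
  counts <- lookup_counts(preset, group_label)
  r_mu <- preset$nucleus_radius_px[1]; r_sd <- preset$nucleus_radius_px[2]
  r_outer_max <- r_mu + 3 * r_sd + 1 + preset$peri_width_px +
    preset$distal_width_px
  margin <- ceiling(r_outer_max) + 2
  min_dist <- 2 * r_outer_max + 2

  rows <- numeric(0); cols <- numeric(0); layers <- character(0)
  for (layer in names(preset$layer_bands)) {
    n <- if (layer %in% names(counts)) counts[[layer]] else 0L
    pos <- place_cells(h, w, preset$layer_bands[[layer]], n, min_dist, margin)
    rows <- c(rows, pos[, "row"]); cols <- c(cols, pos[, "col"])
    layers <- c(layers, rep(layer, nrow(pos)))
  }
  n_cells <- length(rows)
  field_id <- sprintf("%s_%s_f%04d", preset$name, gsub("[^A-Za-z0-9]", "",
                                                       group_label),
                      as.integer(field_index))

  radii <- pmax(3, stats::rnorm(n_cells, r_mu, r_sd))
  # planted positivity flags
  pos_flags <- matrix(FALSE, n_cells, 3,
                      dimnames = list(NULL, c("sting", "effector",
                                              "layer_marker")))
  for (i in seq_len(n_cells)) {
    lay <- layers[i]
    f_s <- lookup_fraction(preset, group_label, lay, "sting")
    f_e <- lookup_fraction(preset, group_label, lay, "effector")
    f_l <- lookup_fraction(preset, group_label, lay, "layer_marker")
    f_d <- 0
    df <- preset$dual_fraction
    if (!is.null(df)) {
      hit <- df$group == group_label & df$layer == lay
      if (any(hit)) f_d <- min(df$fraction[which(hit)[1]], f_s, f_e)
    }
    u <- stats::runif(1)
    # joint draw preserving marginals f_s, f_e with planted overlap f_d
    if (u < f_d) {
      pos_flags[i, "sting"] <- TRUE; pos_flags[i, "effector"] <- TRUE
    } else if (u < f_s) {
      pos_flags[i, "sting"] <- TRUE
    } else if (u < f_s + (f_e - f_d)) {
      pos_flags[i, "effector"] <- TRUE
    }
    pos_flags[i, "layer_marker"] <- stats::runif(1) < f_l
  }

  im <- preset$intensity_model
  true_mean <- matrix(0, n_cells, length(CHANNEL_ROLES),
                      dimnames = list(NULL, CHANNEL_ROLES))
  peri_w <- preset$peri_width_px; dist_w <- preset$distal_width_px

  draw_level <- function(role, positive) {
    p <- im[[role]]
    mu <- if (positive) p[2] else p[1]
    max(0, stats::rnorm(1, mu, p[3] * mu / p[2]))  # constant CV
  }

  # accumulate (index, value) pairs per channel; cells never overlap, so a
  # single vectorised add per channel renders the whole field
  acc <- lapply(CHANNEL_ROLES, function(r) list(idx = list(), val = list()))
  names(acc) <- CHANNEL_ROLES
  put <- function(role, idx, value) {
    a <- acc[[role]]
    a$idx[[length(a$idx) + 1L]] <- idx
    a$val[[length(a$val) + 1L]] <- rep(value, length(idx))
    acc[[role]] <<- a
  }

  for (i in seq_len(n_cells)) {
    r <- radii[i]; row <- rows[i]; col <- cols[i]
    # the perinuclear (ER) zone starts 1 px off the nuclear envelope, so
    # PSF leakage into the nucleus stays small
    r_peri <- r + 1 + peri_w; r_out <- r + 1 + peri_w + dist_w
    idx_nuc <- annulus_indices(h, w, row, col, r)
    idx_cyt <- annulus_indices(h, w, row, col, r_out, r)
    # nuclear dye: every nucleus stains
    lv <- draw_level("nucleus_dye", TRUE)
    true_mean[i, "nucleus_dye"] <- lv
    put("nucleus_dye", idx_nuc, lv)
    # pan-neuronal marker: whole cytoplasm annulus
    lv <- draw_level("neuron_marker", TRUE)
    true_mean[i, "neuron_marker"] <- lv
    put("neuron_marker", idx_cyt, lv)
    # STING: perinuclear-biased when positive
    sting_pos <- pos_flags[i, "sting"]
    lv <- draw_level("sting", sting_pos)
    true_mean[i, "sting"] <- lv
    if (sting_pos) {
      idx_p <- annulus_indices(h, w, row, col, r_peri, r + 1)
      idx_d <- annulus_indices(h, w, row, col, r_out, r_peri)
      a_c <- length(idx_p) + length(idx_d)
      bias <- preset$perinuclear_bias
      put("sting", idx_p, lv * bias * a_c / length(idx_p))
      if (bias < 1 && length(idx_d) > 0)
        put("sting", idx_d, lv * (1 - bias) * a_c / length(idx_d))
    } else {
      put("sting", idx_cyt, lv)
    }
    # effector: nuclear
    lv <- draw_level("effector", pos_flags[i, "effector"])
    true_mean[i, "effector"] <- lv
    put("effector", idx_nuc, lv)
    # layer marker
    lv <- draw_level("layer_marker", pos_flags[i, "layer_marker"])
    true_mean[i, "layer_marker"] <- lv
    put("layer_marker",
        if (preset$layer_marker_localization == "nuclear") idx_nuc else
          idx_cyt, lv)
  }
  chans <- lapply(acc, function(a) {
    m <- matrix(0, h, w)
    idx <- unlist(a$idx, use.names = FALSE)
    if (length(idx)) m[idx] <- m[idx] + unlist(a$val, use.names = FALSE)
    m
  })

  ns <- preset$noise
  render_plane <- function(m) {
    m <- m + ns$background
    if (preset$psf_sigma_px > 0)
      m <- gaussian_blur(m, preset$psf_sigma_px)
    if (!is.null(ns$poisson_scale) && ns$poisson_scale > 0) {
      lam <- pmax(m, 0) / ns$poisson_scale
      m <- matrix(stats::rpois(length(lam), lam), nrow(m)) * ns$poisson_scale
    }
    if (ns$gaussian_sd > 0)
      m <- m + stats::rnorm(length(m), 0, ns$gaussian_sd)
    matrix(pmin(pmax(round(m), 0), 65535), nrow(m))
  }
  channels <- lapply(chans, function(m) {
    if (preset$n_z == 1L) render_plane(m) else
      array(unlist(lapply(seq_len(preset$n_z), function(z) render_plane(m))),
            dim = c(h, w, preset$n_z))
  })

  truth <- data.frame(
    cell_id = sprintf("%s_c%04d", field_id, seq_len(n_cells)),
    field_id = rep(field_id, n_cells),
    group = rep(group_label, n_cells),
    x = cols - 1, y = rows - 1,          # 0-based pixel-centre coordinates
    layer = layers,
    nucleus_radius = radii,
    pos_sting = pos_flags[, "sting"],
    pos_effector = pos_flags[, "effector"],
    pos_layer_marker = pos_flags[, "layer_marker"],
    mean_sting = true_mean[, "sting"],
    mean_effector = true_mean[, "effector"],
    mean_layer_marker = true_mean[, "layer_marker"],
    stringsAsFactors = FALSE
  )

  list(stack = channel_stack(channels, pixel_size_um = preset$pixel_size_um,
                             acquisition = list(preset = preset$name,
                                                group = group_label,
                                                field_index = field_index,
                                                seed = seed)),
       truth = truth)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed",
                                                       envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Write a synthetic cohort to disk
#'
#' Generates `fields_per_section` fields per section for each group, writing
#' one multi-page TIFF (+ YAML sidecar) and one ground-truth CSV per field,
#' plus a manifest CSV listing every file with its MD5 checksum. Deterministic
#' under a fixed preset seed.
#'
#' @param preset an [imaging_preset()].
#' @param group_sizes named integer vector, group -> number of sections.
#' @param fields_per_section fields imaged per section (the emulated protocol
#'   takes 15-25 fields per well; default 20).
#' @param out_dir output directory.
#' @param overwrite refuse to write into an existing non-empty directory
#'   unless `TRUE`.
#' @return Invisibly, the manifest data.frame.
#' @export
generate_cohort <- function(preset, group_sizes, fields_per_section = 20L,
                            out_dir, overwrite = FALSE) {
  stopifnot(length(group_sizes) >= 1L, !is.null(names(group_sizes)))
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !overwrite)
    stop("output directory ", out_dir,
         " exists and is non-empty; use overwrite = TRUE")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (group in names(group_sizes)) {
    for (section in seq_len(group_sizes[[group]])) {
      for (f in seq_len(fields_per_section)) {
        idx <- (section - 1L) * fields_per_section + f
        fld <- generate_field(preset, group, idx)
        base <- sprintf("%s_s%02d_f%04d", gsub("[^A-Za-z0-9]", "", group),
                        section, idx)
        tif <- file.path(out_dir, paste0(base, ".tif"))
        csv <- file.path(out_dir, paste0(base, "_truth.csv"))
        write_stack(fld$stack, tif)
        utils::write.csv(fld$truth, csv, row.names = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          group = group, section = section, field_index = idx,
          image = basename(tif), truth = basename(csv),
          image_md5 = unname(tools::md5sum(tif)),
          truth_md5 = unname(tools::md5sum(csv)),
          stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Define a synthetic differential-expression preset
#'
#' Emulates the output of a two-group RNA-seq differential-expression fit
#' (gene, log2 fold change, adjusted p), with a concordant shift planted in a
#' designated gene set against an exchangeable Normal background.
#'
#' @param n_genes universe size.
#' @param target_set a [gene_set()] whose members receive the planted shift;
#'   defaults to the 25-gene STING pathway panel shipped with the package.
#' @param planted_shift mean log2FC added to target-set genes; 0 gives fully
#'   exchangeable genes.
#' @param null_sd standard deviation of the background log2FC.
#' @param seed integer seed.
#' @return An object of class `DePreset`.
#' @export
de_preset <- function(n_genes = 15000L, target_set = sting_panel(),
                      planted_shift = 1.0, null_sd = 0.3, seed = 1L) {
  stopifnot(n_genes > length(target_set$members), null_sd > 0)
  structure(list(n_genes = as.integer(n_genes), target_set = target_set,
                 planted_shift = planted_shift, null_sd = null_sd,
                 seed = as.integer(seed)), class = "DePreset")
}

#' Generate a synthetic differential-expression table
#'
#' Background genes draw `log2FC ~ Normal(0, null_sd)`; target-set genes get
#' `planted_shift` added. Adjusted p-values are Benjamini-Hochberg on
#' two-sided z-tests with the known null sd (plumbing for the downstream
#' `padj < 0.05` convention, not a model fit).
#'
#' @param preset a [de_preset()].
#' @param universe optional character vector of gene ids; must contain the
#'   target set. By default the target genes are embedded in a synthetic
#'   universe of `n_genes` ids.
#' @return data.frame with columns `gene`, `log2FC`, `pvalue`, `padj`,
#'   `in_target`.
#' @export
generate_de_table <- function(preset, universe = NULL) {
  stopifnot(inherits(preset, "DePreset"))
  tgt <- preset$target_set$members
  if (is.null(universe)) {
    filler <- sprintf("GENE%05d", seq_len(preset$n_genes))
    universe <- c(tgt, setdiff(filler, tgt)[seq_len(preset$n_genes -
                                                      length(tgt))])
  } else {
    missing <- setdiff(tgt, universe)
    if (length(missing))
      stop("target set genes missing from universe: ",
           paste(missing, collapse = ", "))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(preset$seed, "de_table"))
  lfc <- stats::rnorm(length(universe), 0, preset$null_sd)
  in_target <- universe %in% tgt
  lfc[in_target] <- lfc[in_target] + preset$planted_shift
  p <- 2 * stats::pnorm(-abs(lfc) / preset$null_sd)
  data.frame(gene = universe, log2FC = lfc, pvalue = p,
             padj = stats::p.adjust(p, method = "BH"),
             in_target = in_target, stringsAsFactors = FALSE)
}
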