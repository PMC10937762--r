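#' Named imaging presets for the planted study contrasts
#'
#' Each preset plants one of the effect sizes reported for the corresponding
#' experimental comparison, at desk scale:
#'
#' * `fig1b_c9_layerV` — human motor cortex, repeat-expansion disease vs
#'   control: layer-V STING-positive fraction 0.25 vs 0.05 (five-fold), layer
#'   II/III 0.03 in both groups (no planted difference).
#' * `fig1g_sals`, `fig1g_c9`, `fig1g_fals` — ventral-horn spinal motor
#'   neurons: STING-positive fraction ratios of four-, five- and three-fold
#'   (0.40/0.50/0.30 over a 0.10 control base rate; the base rate is a
#'   synthetic choice sized so the planted ratio is resolvable at the small
#'   per-group section counts of the emulated comparison).
#' * `fig2b_mouse` — mouse motor cortex neuron loss: layer-V cell density
#'   22/field (control) vs 14/field (disease), a 36.4% reduction; layer
#'   II/III density equal in both groups. The layer marker is nuclear
#'   (CTIP2-like).
#' * `fig2d_mouse_layerV` — layer-V-focused fields; 18.9% of layer-marker-
#'   positive cells in the disease group are perinuclear-STING-positive
#'   (2% in controls).
#' * `fig6_shTDP43` — culture wells; planted dual gH2AX+/STING+ fractions
#'   0.35 (knockdown) vs 0.05 (scramble). The source figure prints no
#'   percentages, so these are synthetic choices giving its qualitative
#'   contrast.
#'
#' Fields are 512 x 512 px at 0.5 um/px (a cropped confocal field); base-rate
#' and intensity parameters are synthetic (see the methods vignette).
#'
#' @param name preset name; unknown names raise an error listing the catalog.
#' @param seed master seed stamped into the preset.
#' @return An [imaging_preset()].
#' @export
get_preset <- function(name, seed = 1L) {
  cat_ <- preset_catalog(seed)
  if (!name %in% names(cat_))
    stop("unknown preset '", name, "'; available presets: ",
         paste(names(cat_), collapse = ", "))
  cat_[[name]]
}

#' @rdname get_preset
#' @export
preset_catalog <- function(seed = 1L) {
  pf <- function(...) {
    df <- data.frame(matrix(unlist(list(...)), ncol = 4, byrow = TRUE),
                     stringsAsFactors = FALSE)
    names(df) <- c("group", "layer", "marker", "fraction")
    df$fraction <- as.numeric(df$fraction)
    df
  }
  shape <- c(512L, 512L)
  smn_bands <- list(ventral_horn = c(0.08, 0.92))
  list(
    fig1b_c9_layerV = imaging_preset(
      field_shape = shape,
      cells_per_layer = c("II/III" = 25L, "V" = 25L),
      positive_fraction = pf(
        c("disease", "V", "sting", 0.25),
        c("disease", "II/III", "sting", 0.03),
        c("control", "V", "sting", 0.05),
        c("control", "II/III", "sting", 0.03)),
      seed = seed, name = "fig1b_c9_layerV"),
    fig1g_sals = imaging_preset(
      field_shape = shape, layer_bands = smn_bands,
      cells_per_layer = c(ventral_horn = 30L),
      positive_fraction = pf(
        c("disease", "ventral_horn", "sting", 0.40),
        c("control", "ventral_horn", "sting", 0.10)),
      seed = seed, name = "fig1g_sals"),
    fig1g_c9 = imaging_preset(
      field_shape = shape, layer_bands = smn_bands,
      cells_per_layer = c(ventral_horn = 30L),
      positive_fraction = pf(
        c("disease", "ventral_horn", "sting", 0.50),
        c("control", "ventral_horn", "sting", 0.10)),
      seed = seed, name = "fig1g_c9"),
    fig1g_fals = imaging_preset(
      field_shape = shape, layer_bands = smn_bands,
      cells_per_layer = c(ventral_horn = 30L),
      positive_fraction = pf(
        c("disease", "ventral_horn", "sting", 0.30),
        c("control", "ventral_horn", "sting", 0.10)),
      seed = seed, name = "fig1g_fals"),
    fig2b_mouse = imaging_preset(
      field_shape = shape,
      cells_per_layer = list(
        control = c("II/III" = 20L, "V" = 22L),
        disease = c("II/III" = 20L, "V" = 14L)),
      positive_fraction = pf(
        c("disease", "V", "sting", 0.189),
        c("control", "V", "sting", 0.02),
        c("disease", "II/III", "sting", 0.02),
        c("control", "II/III", "sting", 0.02)),
      seed = seed, name = "fig2b_mouse"),
    fig2d_mouse_layerV = imaging_preset(
      field_shape = shape,
      layer_bands = list(V = c(0.05, 0.95)),
      cells_per_layer = c(V = 60L),
      positive_fraction = pf(
        c("disease", "V", "sting", 0.189),
        c("control", "V", "sting", 0.02),
        c("disease", "V", "layer_marker", 0.8),
        c("control", "V", "layer_marker", 0.8)),
      seed = seed, name = "fig2d_mouse_layerV"),
    fig6_shTDP43 = imaging_preset(
      field_shape = shape,
      layer_bands = list(culture = c(0.05, 0.95)),
      cells_per_layer = c(culture = 50L),
      positive_fraction = pf(
        c("disease", "culture", "sting", 0.40),
        c("disease", "culture", "effector", 0.45),
        c("control", "culture", "sting", 0.08),
        c("control", "culture", "effector", 0.10)),
      dual_fraction = data.frame(
        group = c("disease", "control"), layer = "culture",
        fraction = c(0.35, 0.05), stringsAsFactors = FALSE),
      seed = seed, name = "fig6_shTDP43")
  )
}

# Section counts matching each emulated comparison (disease first).
#' Default group sizes (sections/mice/wells per group) for each preset
#' @param name preset name.
#' @return Named integer vector `c(disease = ..., control = ...)`.
#' @export
preset_group_sizes <- function(name) {
  switch(name,
         fig1b_c9_layerV = c(disease = 8L, control = 6L),
         fig1g_sals = c(disease = 13L, control = 6L),
         fig1g_c9 = c(disease = 6L, control = 6L),
         fig1g_fals = c(disease = 4L, control = 3L),
         fig2b_mouse = c(disease = 5L, control = 4L),
         fig2d_mouse_layerV = c(disease = 5L, control = 4L),
         fig6_shTDP43 = c(disease = 6L, control = 6L),
         stop("unknown preset '", name, "'"))
}

#' Planted effect sizes per preset (for recovery tests)
#'
#' @param name preset name.
#' @return Named numeric vector describing the planted contrast.
#' @export
preset_planted <- function(name) {
  switch(name,
         fig1b_c9_layerV = c(layerV_ratio = 0.25 / 0.05),
         fig1g_sals = c(smn_ratio = 0.40 / 0.10),
         fig1g_c9 = c(smn_ratio = 0.50 / 0.10),
         fig1g_fals = c(smn_ratio = 0.30 / 0.10),
         fig2b_mouse = c(layerV_reduction_pct = 100 * (1 - 14 / 22)),
         fig2d_mouse_layerV = c(dual_fraction_pct = 18.9),
         fig6_shTDP43 = c(dual_fraction_disease = 0.35,
                          dual_fraction_control = 0.05),
         stop("unknown preset '", name, "'"))
}
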