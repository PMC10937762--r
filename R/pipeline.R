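#' Quantify one imaging field
#'
#' Projects the stack if needed, segments nuclei, thresholds the neuron mask
#' and assembles per-cell records.
#'
#' @param stack a `ChannelStack`.
#' @param layer_bands named y-fraction bands, or `NULL`.
#' @param ring_iterations,connectivity perinuclear ring parameters.
#' @param max_radius_um cytoplasm assignment radius.
#' @param compute_cytoplasm compute cytoplasm masks (slower; off for
#'   count-based cohort runs).
#' @param projection z-projection method when the stack is 3-D.
#' @param min_area_px,max_area_px nucleus size gate.
#' @return A `CellTable`.
#' @export
quantify_field <- function(stack, layer_bands = NULL, ring_iterations = 10L,
                           connectivity = 8L, max_radius_um = 15,
                           compute_cytoplasm = TRUE, projection = "max",
                           min_area_px = 30L, max_area_px = 2500L) {
  if (any(vapply(stack$channels, function(x) length(dim(x)) == 3L,
                 logical(1))))
    stack <- project_z(stack, projection)
  nuclei <- segment_nuclei(stack$channels$nucleus_dye,
                           min_area_px = min_area_px,
                           max_area_px = max_area_px)
  nmask <- if (!is.null(stack$channels$neuron_marker))
    define_neuron_mask(stack$channels$neuron_marker) else NULL
  assemble_cells(nuclei, nmask, stack, layer_bands = layer_bands,
                 ring_iterations = ring_iterations,
                 connectivity = connectivity, max_radius_um = max_radius_um,
                 compute_cytoplasm = compute_cytoplasm)
}

#' Generate and quantify a synthetic cohort in memory
#'
#' Streams over groups, sections and fields: each field is generated,
#' quantified, and reduced to its per-cell measurement rows (masks are
#' dropped), so memory stays flat in cohort size.
#'
#' @param preset an [imaging_preset()].
#' @param group_sizes named vector, group -> number of sections.
#' @param fields_per_section fields per section.
#' @param ring_iterations,connectivity ring parameters.
#' @param compute_cytoplasm forwarded to [quantify_field()].
#' @return List: `cells` (per-cell rows with `group`, `section`, `field_id`),
#'   `truth` (concatenated planted truth), `preset`, `group_sizes`.
#' @export
quantify_imaging_cohort <- function(preset, group_sizes,
                                    fields_per_section = 20L,
                                    ring_iterations = 10L,
                                    connectivity = 8L,
                                    compute_cytoplasm = FALSE) {
  cells_l <- list(); truth_l <- list()
  for (group in names(group_sizes)) {
    for (section in seq_len(group_sizes[[group]])) {
      for (f in seq_len(fields_per_section)) {
        idx <- (section - 1L) * fields_per_section + f
        fld <- generate_field(preset, group, idx)
        ct <- quantify_field(fld$stack, layer_bands = preset$layer_bands,
                             ring_iterations = ring_iterations,
                             connectivity = connectivity,
                             compute_cytoplasm = compute_cytoplasm)
        cc <- ct$cells
        if (nrow(cc)) {
          cc$group <- group; cc$section <- section
          cc$field_id <- fld$truth$field_id[1] %||%
            sprintf("%s_%s_f%04d", preset$name, group, idx)
          cells_l[[length(cells_l) + 1L]] <- cc
        }
        truth_l[[length(truth_l) + 1L]] <- fld$truth
      }
    }
  }
  list(cells = do.call(rbind, cells_l), truth = do.call(rbind, truth_l),
       preset = preset, group_sizes = group_sizes,
       fields_per_section = fields_per_section)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

#' Call cohort-level positivity and assign layers
#'
#' Applies the positivity machinery at cohort scope: the layer marker is
#' called by a global Otsu split (its planted mixture is strongly bimodal)
#' when `layer_by = "marker"`; STING (and optionally the effector) is called
#' against the control group's measurement distribution
#' (`mean + k * sd`), falling back to a global Otsu split when no control
#' group is present (single-group cohorts).
#'
#' @param cohort result of [quantify_imaging_cohort()].
#' @param layer_by `"band"` (keep geometric labels) or `"marker"`.
#' @param markers marker roles to call (subset of `c("sting", "effector")`).
#' @param control_group control group label (reference distribution).
#' @param k threshold multiplier for the control-based policy.
#' @return The cohort list with `cells` flagged, plus `thresholds`.
#' @export
call_cohort_positivity <- function(cohort, layer_by = c("band", "marker"),
                                   markers = "sting",
                                   control_group = "control", k = 2) {
  layer_by <- match.arg(layer_by)
  cells <- cohort$cells
  thresholds <- list()
  if (layer_by == "marker") {
    loc <- cohort$preset$layer_marker_localization %||% "nuclear"
    cmp <- if (loc == "nuclear") "nuclear" else "cytoplasmic"
    pol <- positivity_policy("otsu_global", compartment = cmp,
                             role = "layer_marker", stat = "mean")
    cells <- call_positive(cells, pol)
    cells <- assign_layer_by_marker(cells)
    thresholds$layer_marker <-
      attr(cells, "positivity_thresholds")$pos_layer_marker
  }
  for (mk in markers) {
    cmp <- if (mk == "sting") "perinuclear" else "nuclear"
    col <- paste(cmp, mk, "mean", sep = "_")
    ref <- cells[[col]][cells$group == control_group & cells$is_neuron]
    pol <- if (length(ref) >= 2L)
      positivity_policy("control_mean_plus_k_sd", k = k, reference = ref,
                        compartment = cmp, role = mk, stat = "mean")
    else
      positivity_policy("otsu_global", compartment = cmp, role = mk,
                        stat = "mean")
    cells <- call_positive(cells, pol)
    thresholds[[mk]] <- attr(cells, "positivity_thresholds")[[paste0("pos_",
                                                                     mk)]]
  }
  cohort$cells <- cells
  cohort$thresholds <- thresholds
  cohort
}

#' Per-field and per-unit summary tables for a called cohort
#'
#' Fields are summarised with [summarize_field()]; sections (the unit of
#' analysis: one value per well/section/mouse, as in the emulated boxplots)
#' aggregate fields by the mean.
#'
#' @param cohort a cohort with positivity flags (see
#'   [call_cohort_positivity()]).
#' @param layerV_label deep-layer label in `layer_label`.
#' @return List: `fields` (one row per field), `units` (one row per
#'   (group, section): mean over that section's fields of every count).
#' @export
cohort_summary_tables <- function(cohort, layerV_label = "V") {
  cells <- cohort$cells
  key <- interaction(cells$group, cells$section, cells$field_id, drop = TRUE)
  fields <- do.call(rbind, lapply(split(cells, key), function(cc)
    summarize_field(cc, field_id = cc$field_id[1], group_label = cc$group[1],
                    section_id = cc$section[1],
                    layerV_label = layerV_label)))
  rownames(fields) <- NULL
  num_cols <- setdiff(names(fields)[vapply(fields, is.numeric, logical(1))],
                      "section")
  units <- stats::aggregate(fields[num_cols],
                            by = list(group = fields$group,
                                      section = fields$section),
                            FUN = mean)
  list(fields = fields, units = units)
}

#' End-to-end cohort analysis for a named preset
#'
#' Convenience wrapper running simulate -> quantify -> call -> summarise for
#' one named preset at its default study design (group sizes from
#' [preset_group_sizes()]), returning the tables the reports and recovery
#' checks are built from.
#'
#' @param preset_name catalog name (see [preset_catalog()]).
#' @param seed master seed.
#' @param fields_per_section fields per section; `NULL` uses the preset's
#'   design default.
#' @param group_sizes named vector; `NULL` uses the design default. Supplying
#'   only a disease entry analyses a single-group cohort.
#' @param layer_by `NULL` picks the preset's natural mode (marker for the
#'   mouse CTIP2 presets, band geometry otherwise).
#' @param markers marker roles to call.
#' @param k control-policy threshold multiplier.
#' @return List: `cohort` (with flagged cells), `fields`, `units`.
#' @export
run_cohort_analysis <- function(preset_name, seed = 1L,
                                fields_per_section = NULL,
                                group_sizes = NULL, layer_by = NULL,
                                markers = "sting", k = 2) {
  preset <- get_preset(preset_name, seed = seed)
  if (is.null(group_sizes)) group_sizes <- preset_group_sizes(preset_name)
  if (is.null(fields_per_section))
    fields_per_section <- switch(preset_name, fig1b_c9_layerV = 20L,
                                 fig2d_mouse_layerV = 8L, fig6_shTDP43 = 5L,
                                 fig2b_mouse = 6L, 8L)
  if (is.null(layer_by))
    layer_by <- if (preset_name %in% c("fig2b_mouse", "fig2d_mouse_layerV"))
      "marker" else "band"
  cohort <- quantify_imaging_cohort(preset, group_sizes,
                                    fields_per_section = fields_per_section)
  cohort <- call_cohort_positivity(cohort, layer_by = layer_by,
                                   markers = markers, k = k)
  layerV <- if (layer_by == "band" &&
                !"V" %in% names(preset$layer_bands))
    names(preset$layer_bands)[1] else "V"
  tabs <- cohort_summary_tables(cohort, layerV_label = layerV)
  c(list(cohort = cohort), tabs)
}

#' Disease-vs-control comparison of a per-unit count column
#'
#' @param units per-unit table from [cohort_summary_tables()].
#' @param column count column to compare.
#' @param disease,control group labels.
#' @param seed bootstrap seed for the fold-change CI.
#' @return List: `comparison` (a `GroupComparison`), `fold` (ratio + CI),
#'   `values` (per-group unit values).
#' @export
compare_units <- function(units, column, disease = "disease",
                          control = "control", seed = 1L) {
  x <- units[[column]][units$group == disease]
  y <- units[[column]][units$group == control]
  list(comparison = student_t_two_tailed(x, y, labels = c(disease, control)),
       fold = fold_change(x, y, seed = seed),
       values = stats::setNames(list(x, y), c(disease, control)))
}

#' Pooled dual-positivity fraction
#'
#' Percentage of cells positive for `among` that are also positive for `of`
#' (e.g. the share of CTIP2-analogue-positive neurons with perinuclear STING),
#' pooled over all cells of a group.
#'
#' @param cells flagged per-cell table.
#' @param group group label, or `NULL` for all cells.
#' @param among,of positivity flag columns (without the `pos_` prefix).
#' @param neurons_only restrict to `is_neuron` cells.
#' @return List: `fraction_pct`, `n_among`, `n_dual`.
#' @export
pooled_dual_fraction <- function(cells, group = NULL, among = "layer_marker",
                                 of = "sting", neurons_only = TRUE) {
  if (!is.null(group)) cells <- cells[cells$group == group, , drop = FALSE]
  if (neurons_only) cells <- cells[cells$is_neuron, , drop = FALSE]
  ca <- paste0("pos_", among); co <- paste0("pos_", of)
  base <- cells[[ca]]
  n_among <- sum(base)
  n_dual <- sum(base & cells[[co]])
  list(fraction_pct = 100 * n_dual / n_among, n_among = n_among,
       n_dual = n_dual)
}

#' Run the staged pipeline with on-disk artifacts
#'
#' Single entry point wiring simulate -> quantify -> report (imaging) and
#' enrich (expression) with reproducible configuration: every stage writes
#' its artifacts under `config$out_dir`, a stage whose output already exists
#' is skipped (resume semantics), and the config echo (with its hash and
#' seed) is written alongside the results.
#'
#' @param config list with elements `preset` (catalog name), `seed`,
#'   `out_dir`, and optionally `fields_per_section`, `group_sizes`,
#'   `layer_by`, `markers`, `k`, `n_perm`, `alpha`, `planted_shift`,
#'   `ring_iterations`; or a path to a YAML file with those keys.
#' @param stages character vector among `simulate`, `quantify`, `report`,
#'   `enrich`.
#' @return Invisibly, a list of stage outputs.
#' @export
run_pipeline <- function(config, stages = c("simulate", "quantify",
                                            "report")) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$out_dir))
  known <- c("simulate", "quantify", "report", "enrich")
  bad <- setdiff(stages, known)
  if (length(bad))
    stop("invalid stage name(s): ", paste(bad, collapse = ", "),
         "; known stages: ", paste(known, collapse = ", "))
  config$seed <- config$seed %||% 1L
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_file <- tempfile()
  hashed <- config[setdiff(names(config), "out_dir")]  # location-independent
  saveRDS(hashed[order(names(hashed))], cfg_file)
  config_hash <- unname(tools::md5sum(cfg_file))
  unlink(cfg_file)
  out <- list(config_hash = config_hash)
  yaml::write_yaml(c(config, list(config_hash = config_hash)),
                   file.path(config$out_dir, "config_echo.yaml"))

  img_dir <- file.path(config$out_dir, "images")
  cells_csv <- file.path(config$out_dir, "cells.csv")
  if ("simulate" %in% stages) {
    if (!file.exists(file.path(img_dir, "manifest.csv"))) {
      preset <- get_preset(config$preset, seed = config$seed)
      gs <- unlist(config$group_sizes) %||%
        preset_group_sizes(config$preset)
      generate_cohort(preset, gs,
                      fields_per_section = config$fields_per_section %||% 2L,
                      out_dir = img_dir, overwrite = TRUE)
    }
    out$images <- img_dir
  }
  if ("quantify" %in% stages) {
    if (!file.exists(file.path(img_dir, "manifest.csv")))
      stop("missing upstream artifact: ", file.path(img_dir, "manifest.csv"),
           "; run the simulate stage first")
    if (!file.exists(cells_csv)) {
      preset <- get_preset(config$preset, seed = config$seed)
      man <- utils::read.csv(file.path(img_dir, "manifest.csv"))
      cells_l <- list()
      for (i in seq_len(nrow(man))) {
        stack <- read_stack(file.path(img_dir, man$image[i]))
        ct <- quantify_field(stack, layer_bands = preset$layer_bands,
                             ring_iterations = config$ring_iterations %||% 10L,
                             compute_cytoplasm = FALSE)
        cc <- ct$cells
        if (nrow(cc)) {
          cc$group <- man$group[i]; cc$section <- man$section[i]
          cc$field_id <- tools::file_path_sans_ext(man$image[i])
          cells_l[[length(cells_l) + 1L]] <- cc
        }
      }
      utils::write.csv(do.call(rbind, cells_l), cells_csv,
                       row.names = FALSE)
    }
    out$cells <- cells_csv
  }
  if ("report" %in% stages) {
    if (!file.exists(cells_csv))
      stop("missing upstream artifact: ", cells_csv,
           "; run the quantify stage first")
    preset <- get_preset(config$preset, seed = config$seed)
    cohort <- list(cells = utils::read.csv(cells_csv,
                                           stringsAsFactors = FALSE),
                   preset = preset)
    cohort <- call_cohort_positivity(
      cohort, layer_by = config$layer_by %||% "band",
      markers = config$markers %||% "sting", k = config$k %||% 2)
    tabs <- cohort_summary_tables(cohort)
    cmp_col <- intersect(c("n_sting_pos_V", "n_sting_pos_total"),
                         names(tabs$units))[1]
    cmp <- compare_units(tabs$units, cmp_col, seed = config$seed)
    rep_df <- build_report(
      stats::setNames(list(cmp$comparison), cmp_col),
      unit_values = stats::setNames(list(cmp$values), cmp_col),
      out_dir = file.path(config$out_dir, "report"),
      meta = list(seed = config$seed, config_hash = config_hash,
                  preset = config$preset))
    utils::write.csv(tabs$units,
                     file.path(config$out_dir, "report", "units.csv"),
                     row.names = FALSE)
    out$report <- rep_df
  }
  if ("enrich" %in% stages) {
    dep <- de_preset(planted_shift = config$planted_shift %||% 1.0,
                     seed = config$seed)
    de <- generate_de_table(dep)
    ranked <- rank_by_log2fc(de)
    res <- gsea_preranked(ranked, dep$target_set,
                          n_perm = config$n_perm %||% 1000L,
                          seed = config$seed)
    ctrl <- random_geneset_control(ranked, size = 30L,
                                   n_sets = config$n_random_sets %||% 50L,
                                   n_perm = config$n_perm %||% 1000L,
                                   alpha = config$alpha %||% 0.05,
                                   seed = config$seed)
    jsonlite::write_json(
      list(panel = list(set = res$set_name, es = res$es, nes = res$nes,
                        p_emp = res$p_emp, n_perm = res$n_perm),
           random_control = list(
             fraction_significant = ctrl$fraction_significant,
             n_sets = ctrl$n_sets, alpha = ctrl$alpha),
           seed = config$seed, config_hash = config_hash),
      file.path(config$out_dir, "enrichment.json"), auto_unbox = TRUE,
      pretty = TRUE, digits = NA)
    out$enrichment <- res
  }
  invisible(out)
}
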