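#' Iterative binary dilation (ImageJ-style)
#'
#' Dilates a binary mask `iterations` times with a 3 x 3 square structuring
#' element (8-connectivity, the ImageJ binary-dilation default) or a cross
#' (4-connectivity), clipping at the image border. This is the primitive
#' behind the perinuclear ring: the protocol dilates the nuclear mask 10
#' iterations and measures STING inside the dilated region.
#'
#' @param mask logical (or 0/1) matrix.
#' @param iterations non-negative integer; 0 returns the input unchanged.
#' @param connectivity 8 or 4.
#' @return Logical matrix of the same shape.
#' @export
dilate_mask <- function(mask, iterations = 10L, connectivity = 8L) {
  stopifnot(is.matrix(mask))
  if (iterations < 0) stop("iterations must be non-negative")
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  m <- mask > 0
  if (iterations == 0L) return(m)
  shifts <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8L)
    shifts <- c(shifts, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
  for (i in seq_len(iterations)) {
    out <- m
    for (s in shifts) out <- out | shift_mat(m, s[1], s[2], FALSE)
    m <- out
  }
  m
}

#' Perinuclear ring measurement for one cell
#'
#' Measures the STING (or any) channel within the cell's perinuclear ring:
#' stained area (pixels above the per-image background threshold), integrated
#' intensity (raw sum) and mean. A nucleus whose ring is fully clipped at the
#' border yields a zero-area flagged result rather than an error.
#'
#' @param cell_table a `CellTable` from [assemble_cells()].
#' @param cell_label cell to measure.
#' @param stack the measured `ChannelStack`.
#' @param role channel role (default `"sting"`).
#' @return List: `area_px` (ring size), `stained_area_px`, `integrated`,
#'   `mean`, `clipped`.
#' @export
measure_perinuclear <- function(cell_table, cell_label, stack,
                                role = "sting") {
  stopifnot(inherits(cell_table, "CellTable"))
  idx <- cell_table$masks[[cell_label]]$perinuclear
  ch <- stack$channels[[role]]
  if (is.null(ch)) stop("unknown channel role: ", role)
  v <- ch[idx]
  list(area_px = length(idx),
       stained_area_px = sum(v > cell_table$background[[role]]),
       integrated = sum(v),
       mean = if (length(idx)) sum(v) / length(idx) else NA_real_,
       clipped = length(idx) == 0L)
}

#' Compartment measurement for one cell
#'
#' Exact pixel sums over the requested compartment mask; no interpolation.
#'
#' @inheritParams measure_perinuclear
#' @param compartment `"nuclear"`, `"cytoplasmic"` or `"perinuclear"`.
#' @return List: `area_px`, `area_um2`, `integrated`, `mean`,
#'   `stained_area_px`.
#' @export
measure_compartment <- function(cell_table, cell_label, stack, role,
                                compartment = c("nuclear", "cytoplasmic",
                                                "perinuclear")) {
  stopifnot(inherits(cell_table, "CellTable"))
  compartment <- match.arg(compartment)
  ch <- stack$channels[[role]]
  if (is.null(ch)) stop("unknown channel role: ", role)
  idx <- cell_table$masks[[cell_label]][[switch(compartment,
                                                nuclear = "nuclear",
                                                cytoplasmic = "cytoplasm",
                                                perinuclear = "perinuclear")]]
  v <- ch[idx]
  a <- length(idx)
  list(area_px = a, area_um2 = a * cell_table$pixel_size_um^2,
       integrated = sum(v), mean = if (a) sum(v) / a else NA_real_,
       stained_area_px = sum(v > cell_table$background[[role]]))
}

#' Define a positivity-calling policy
#'
#' The source study reports positive/negative neurons without stating the
#' cut; positivity here is an explicit, logged policy on a per-cell
#' measurement:
#'
#' * `control_mean_plus_k_sd` — threshold at `mean + k * sd` of a reference
#'   (control-group) measurement distribution (default `k = 2`);
#' * `otsu_global` — Otsu split of the pooled per-cell measurements (for
#'   single-group cohorts with a bimodal readout);
#' * `robust_mad` — `median + k * MAD` of the pooled measurements;
#' * `fixed` — explicit threshold.
#'
#' @param method policy name.
#' @param k multiplier for sd/MAD-based policies (must be positive).
#' @param reference numeric vector of reference measurements
#'   (`control_mean_plus_k_sd` only).
#' @param threshold fixed threshold (`fixed` only).
#' @param compartment,role,stat the measurement the flag is computed from,
#'   e.g. perinuclear sting mean.
#' @return A `PositivityPolicy`.
#' @export
positivity_policy <- function(method = c("control_mean_plus_k_sd",
                                         "otsu_global", "robust_mad",
                                         "fixed"),
                              k = 2, reference = NULL, threshold = NULL,
                              compartment = "perinuclear", role = "sting",
                              stat = "mean") {
  method <- match.arg(method)
  if (k <= 0) stop("k must be positive")
  if (method == "control_mean_plus_k_sd" &&
      (is.null(reference) || length(reference) < 2L))
    stop("control-based policy requires a non-empty reference distribution")
  if (method == "fixed" && is.null(threshold))
    stop("fixed policy requires a threshold")
  structure(list(method = method, k = k, reference = reference,
                 threshold = threshold, compartment = compartment,
                 role = role, stat = stat), class = "PositivityPolicy")
}

policy_threshold <- function(policy, values) {
  switch(policy$method,
         control_mean_plus_k_sd =
           mean(policy$reference) + policy$k * stats::sd(policy$reference),
         otsu_global = otsu_vector(values),
         robust_mad = stats::median(values) +
           policy$k * stats::mad(values),
         fixed = policy$threshold)
}

measure_column <- function(policy) {
  paste(policy$compartment, policy$role, policy$stat, sep = "_")
}

#' Call marker positivity on a per-cell table
#'
#' Adds a logical `pos_<role>` column: measurement strictly above the policy
#' threshold. The threshold actually applied is recorded in
#' `attr(, "positivity_thresholds")`, so every call is auditable. Calling is
#' deterministic given the policy.
#'
#' @param cells data.frame of per-cell measurements (the `cells` slot of a
#'   `CellTable`, or a cohort-level concatenation of them).
#' @param policy a [positivity_policy()].
#' @param flag_name name of the flag column; defaults to `pos_<role>`.
#' @return `cells` with the flag column added.
#' @export
call_positive <- function(cells, policy, flag_name = NULL) {
  stopifnot(is.data.frame(cells), inherits(policy, "PositivityPolicy"))
  col <- measure_column(policy)
  if (!col %in% names(cells)) stop("measurement column not found: ", col)
  thr <- policy_threshold(policy, cells[[col]])
  if (is.null(flag_name)) flag_name <- paste0("pos_", policy$role)
  cells[[flag_name]] <- !is.na(cells[[col]]) & cells[[col]] > thr
  log_ <- attr(cells, "positivity_thresholds")
  if (is.null(log_)) log_ <- list()
  log_[[flag_name]] <- c(threshold = thr)
  attr(cells, "positivity_thresholds") <- log_
  cells
}

#' Assign the layer label from layer-marker positivity
#'
#' The emulated studies identify deep-layer (layer V) neurons either by
#' anatomical position or by a marker (nuclear CTIP2 in mouse, cytoplasmic
#' CRYM in human). This replaces band-geometry labels with a marker-based
#' call: marker-positive cells get `positive_label`, the rest
#' `negative_label`.
#'
#' @param cells per-cell data.frame with a `pos_layer_marker` flag (see
#'   [call_positive()]).
#' @param positive_label,negative_label labels to assign.
#' @return `cells` with `layer_label` replaced.
#' @export
assign_layer_by_marker <- function(cells, positive_label = "V",
                                   negative_label = "other") {
  if (!"pos_layer_marker" %in% names(cells))
    stop("call_positive() for the layer marker first")
  cells$layer_label <- ifelse(cells$pos_layer_marker, positive_label,
                              negative_label)
  cells
}

#' Count cells positive for both of two markers
#'
#' @param cells per-cell data.frame with `pos_<marker>` flags.
#' @param marker_a,marker_b marker roles.
#' @return Integer count of cells with both flags set.
#' @export
count_dual_positive <- function(cells, marker_a = "effector",
                                marker_b = "sting") {
  ca <- paste0("pos_", marker_a); cb <- paste0("pos_", marker_b)
  if (!all(c(ca, cb) %in% names(cells)))
    stop("positivity flags missing; call call_positive() for both markers")
  sum(cells[[ca]] & cells[[cb]])
}

#' Summarise one field's cells into counts
#'
#' @param cells per-cell data.frame for one field (neurons and non-neurons;
#'   counts are over `is_neuron` cells).
#' @param field_id,group_label,section_id bookkeeping labels.
#' @param layerV_label label of the deep layer in `layer_label`.
#' @return One-row data.frame: `n_neurons`, per-layer STING-positive counts
#'   (`n_sting_pos_<layer>`), `n_layerV_neurons`, `n_dual_positive` (when
#'   both flags exist), `fraction_layerV_sting_positive`.
#' @export
summarize_field <- function(cells, field_id = NA, group_label = NA,
                            section_id = NA, layerV_label = "V") {
  neurons <- cells[cells$is_neuron, , drop = FALSE]
  out <- data.frame(field_id = field_id, group = group_label,
                    section = section_id, n_neurons = nrow(neurons),
                    stringsAsFactors = FALSE)
  layers <- unique(neurons$layer_label)
  if ("pos_sting" %in% names(neurons)) {
    for (lay in layers) {
      nm <- paste0("n_sting_pos_", gsub("[^A-Za-z0-9]", "_", lay))
      out[[nm]] <- sum(neurons$pos_sting[neurons$layer_label == lay])
    }
    out$n_sting_pos_total <- sum(neurons$pos_sting)
  }
  nV <- sum(neurons$layer_label == layerV_label)
  out$n_layerV_neurons <- nV
  if ("pos_sting" %in% names(neurons)) {
    out$fraction_layerV_sting_positive <- if (nV > 0)
      sum(neurons$pos_sting[neurons$layer_label == layerV_label]) / nV
    else NA_real_
  }
  if (all(c("pos_sting", "pos_effector") %in% names(neurons)))
    out$n_dual_positive <- count_dual_positive(neurons, "effector", "sting")
  out
}
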