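#' Unpaired two-tailed Student's t comparison of two groups
#'
#' Pooled-variance Student's t (df = n1 + n2 - 2), the test used for every
#' group comparison in the emulated figures; a Welch variant is available
#' behind a flag. Units are wells/sections/mice, one value each. Two groups
#' with zero variance and equal means return t = 0, p = 1 with a flag.
#'
#' @param x,y numeric vectors (n >= 2 each).
#' @param labels length-2 character vector naming the groups.
#' @param var_equal pooled variance (default, Student) or Welch when `FALSE`.
#' @return A `GroupComparison`: list with group labels, ns, means, sems,
#'   `fold_change` (mean(x)/mean(y), `NA` when mean(y) == 0), `t_stat`,
#'   `df`, `p_two_tailed`, `stars`, `degenerate` flag.
#' @export
student_t_two_tailed <- function(x, y, labels = c("x", "y"),
                                 var_equal = TRUE) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  degenerate <- stats::sd(x) == 0 && stats::sd(y) == 0
  if (degenerate && mean(x) == mean(y)) {
    t_stat <- 0; df <- length(x) + length(y) - 2L; p <- 1
    warning("zero variance in both groups with equal means; p = 1 by convention")
  } else if (degenerate) {
    t_stat <- Inf * sign(mean(x) - mean(y))
    df <- length(x) + length(y) - 2L; p <- 0
  } else {
    tt <- stats::t.test(x, y, var.equal = var_equal)
    t_stat <- unname(tt$statistic); df <- unname(tt$parameter)
    p <- tt$p.value
  }
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  structure(list(groups = labels, n = c(length(x), length(y)),
                 means = c(mean(x), mean(y)), sems = c(sem(x), sem(y)),
                 fold_change = if (mean(y) != 0) mean(x) / mean(y) else NA_real_,
                 t_stat = t_stat, df = df, p_two_tailed = p,
                 stars = p_stars(p), var_equal = var_equal,
                 degenerate = degenerate),
            class = "GroupComparison")
}

#' @export
print.GroupComparison <- function(x, ...) {
  cat(sprintf("<GroupComparison> %s (n=%d) vs %s (n=%d): means %.3g vs %.3g, fold %.3g, t=%.4g (df=%g), p=%.4g %s\n",
              x$groups[1], x$n[1], x$groups[2], x$n[2], x$means[1],
              x$means[2], x$fold_change, x$t_stat, x$df, x$p_two_tailed,
              x$stars))
  invisible(x)
}

#' Fold change between group means with a bootstrap CI
#'
#' Ratio of group means (disease over control), the effect measure behind the
#' reported "x-fold increase" statements. The CI is a seeded basic
#' (reflected) bootstrap over units on the log-ratio scale, back-transformed
#' — ratio statistics are closer to symmetric on the log scale, which keeps
#' coverage near nominal at small unit counts.
#'
#' @param disease,control per-unit values (counts per section/well/mouse).
#' @param n_boot bootstrap replicates.
#' @param conf confidence level.
#' @param seed integer seed.
#' @return List: `ratio`, `ci` (length 2), `n_boot`, `conf`.
#' @export
fold_change <- function(disease, control, n_boot = 2000L, conf = 0.95,
                        seed = 1L) {
  if (mean(control) <= 0)
    stop("control mean is not positive; consider a pseudo-count on counts")
  ratio <- mean(disease) / mean(control)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, "fold_change_boot"))
  bs <- vapply(seq_len(n_boot), function(i) {
    d <- sample(disease, replace = TRUE)
    c_ <- sample(control, replace = TRUE)
    if (mean(d) > 0 && mean(c_) > 0) log(mean(d) / mean(c_)) else NA_real_
  }, numeric(1))
  a <- (1 - conf) / 2
  q <- stats::quantile(bs, c(1 - a, a), na.rm = TRUE)  # reflected
  list(ratio = ratio, ci = unname(exp(2 * log(ratio) - q)),
       n_boot = n_boot, conf = conf)
}

#' Delta-delta-Ct relative expression from qPCR Cq tables
#'
#' Standard relative quantification: `dCt = Cq_target - Cq_reference` per
#' sample, `ddCt = mean(dCt_treated) - mean(dCt_vehicle)`, fold change
#' `2^(-ddCt)` over the vehicle condition. The reference per sample is a
#' single housekeeping gene (TBP/HPRT/GAPDH-style) or the mean Cq of several
#' (equivalent to a geometric-mean expression reference).
#'
#' @param records data.frame with columns `sample`, `gene`, `Cq`,
#'   `condition`; all `Cq > 0`.
#' @param target_genes genes to quantify; defaults to all non-reference
#'   genes.
#' @param reference_genes housekeeping gene(s); every sample must carry at
#'   least one of them.
#' @param vehicle label of the baseline condition.
#' @return data.frame per (gene, condition): `ddCt`, `fold_change`,
#'   `log2FC`, with vehicle rows at fold 1 by construction.
#' @export
ddct_fold_change <- function(records, target_genes = NULL,
                             reference_genes = c("TBP", "HPRT", "GAPDH"),
                             vehicle = "vehicle") {
  stopifnot(is.data.frame(records),
            all(c("sample", "gene", "Cq", "condition") %in% names(records)),
            all(records$Cq > 0))
  if (!vehicle %in% records$condition)
    stop("vehicle condition '", vehicle, "' absent from records")
  if (is.null(target_genes))
    target_genes <- setdiff(unique(records$gene), reference_genes)
  ref <- records[records$gene %in% reference_genes, ]
  if (nrow(ref) == 0L) stop("no reference-gene rows found")
  ref_cq <- tapply(ref$Cq, ref$sample, mean)
  miss <- setdiff(unique(records$sample), names(ref_cq))
  if (length(miss))
    stop("samples missing a reference gene: ", paste(miss, collapse = ", "))
  out <- list()
  for (g in target_genes) {
    sub <- records[records$gene == g, ]
    dct <- sub$Cq - ref_cq[sub$sample]
    mean_v <- mean(dct[sub$condition == vehicle])
    for (cond in unique(sub$condition)) {
      ddct <- mean(dct[sub$condition == cond]) - mean_v
      out[[length(out) + 1L]] <- data.frame(
        gene = g, condition = cond, ddCt = ddct,
        fold_change = 2^(-ddct), log2FC = -ddct, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Build a cohort comparison report
#'
#' Writes a comparisons CSV (one row per comparison: means, sems, fold
#' change, t, df, p, stars), a boxplot-style summary figure, and a run
#' metadata JSON (seed, parameter echo), mirroring the mean +/- s.e.m.
#' boxplot presentation of the emulated figures. Output bytes are a pure
#' function of inputs and seed.
#'
#' @param comparisons named list of `GroupComparison` objects.
#' @param unit_values optional named list (same names) of named lists
#'   `group -> per-unit values`, used for the plot.
#' @param out_dir output directory (created).
#' @param meta extra metadata stored in the JSON.
#' @return Invisibly, the comparisons data.frame.
#' @export
build_report <- function(comparisons, unit_values = NULL, out_dir,
                         meta = list()) {
  stopifnot(length(comparisons) >= 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  df <- do.call(rbind, lapply(names(comparisons), function(nm) {
    cp <- comparisons[[nm]]
    data.frame(comparison = nm, group1 = cp$groups[1], group2 = cp$groups[2],
               n1 = cp$n[1], n2 = cp$n[2], mean1 = cp$means[1],
               mean2 = cp$means[2], sem1 = cp$sems[1], sem2 = cp$sems[2],
               fold_change = cp$fold_change, t_stat = cp$t_stat, df = cp$df,
               p_two_tailed = cp$p_two_tailed, stars = cp$stars,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, file.path(out_dir, "comparisons.csv"),
                   row.names = FALSE)
  if (!is.null(unit_values)) {
    long <- do.call(rbind, lapply(names(unit_values), function(nm) {
      do.call(rbind, lapply(names(unit_values[[nm]]), function(g)
        data.frame(comparison = nm, group = g,
                   value = unit_values[[nm]][[g]],
                   stringsAsFactors = FALSE)))
    }))
    p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$group,
                                            y = .data$value)) +
      ggplot2::geom_boxplot(outlier.shape = NA) +
      ggplot2::geom_jitter(width = 0.15, height = 0, size = 1.5) +
      ggplot2::facet_wrap(~comparison, scales = "free_y") +
      ggplot2::labs(x = NULL, y = "per-unit value") +
      ggplot2::theme_bw()
    ggplot2::ggsave(file.path(out_dir, "comparisons.pdf"), p,
                    width = 2.2 * length(unique(long$comparison)) + 2,
                    height = 4, limitsize = FALSE)
  }
  jsonlite::write_json(c(list(generated_by = "stingquant::build_report",
                              n_comparisons = nrow(df)), meta),
                       file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(df)
}
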