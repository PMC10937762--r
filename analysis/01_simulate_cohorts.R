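#!/usr/bin/env Rscript
# Simulate the synthetic study materials used by the downstream analyses:
# a small on-disk imaging cohort (TIFFs + ground truth + manifest) for the
# mouse layer-V loss comparison, and differential-expression tables with and
# without a planted STING-pathway shift.
#
# Outputs under results/01_simulate/.

suppressMessages(library(stingquant))

seed <- 101L
out <- "results/01_simulate"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

# A deliberately small on-disk cohort (1 section per group, 2 fields each):
# the full-size analyses stream fields in memory instead of writing TIFFs.
preset <- get_preset("fig2b_mouse", seed = seed)
manifest <- generate_cohort(preset, c(disease = 1L, control = 1L),
                            fields_per_section = 2L,
                            out_dir = file.path(out, "cohort_fig2b_demo"),
                            overwrite = TRUE)
cat(sprintf("wrote %d fields (TIFF + truth CSV) to %s\n", nrow(manifest),
            file.path(out, "cohort_fig2b_demo")))

# DE tables: a null (exchangeable) table and one with the planted pathway
# shift (log2FC +1.0 on the 25-gene panel over a N(0, 0.3) background).
for (shift in c(0, 1)) {
  dep <- de_preset(planted_shift = shift, seed = seed)
  de <- generate_de_table(dep)
  f <- file.path(out, sprintf("de_table_shift%g.tsv", shift))
  write.table(de, f, sep = "\t", row.names = FALSE, quote = FALSE)
  cat(sprintf("DE table (shift %g): %d genes, %d in panel, %d at padj<0.05 -> %s\n",
              shift, nrow(de), sum(de$in_target), sum(de$padj < 0.05), f))
}
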