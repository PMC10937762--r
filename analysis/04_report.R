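#!/usr/bin/env Rscript
# Cohort-level report for the human motor-cortex comparison: layer-resolved
# STING-positive neuron counts (deep layer V vs superficial II/III), group
# comparison by unpaired two-tailed Student's t on per-section means, fold
# change with bootstrap CI, and the boxplot-style summary figure.
#
# Writes results under results/04_report/.

suppressMessages(library(stingquant))

seed <- 101L
out <- "results/04_report"

res <- run_cohort_analysis("fig1b_c9_layerV", seed = seed)
cmpV <- compare_units(res$units, "n_sting_pos_V", seed = seed)
cmp23 <- compare_units(res$units, "n_sting_pos_II_III", seed = seed)

rep_df <- build_report(
  list(layerV_sting_pos = cmpV$comparison,
       layerII_III_sting_pos = cmp23$comparison),
  unit_values = list(layerV_sting_pos = cmpV$values,
                     layerII_III_sting_pos = cmp23$values),
  out_dir = out, meta = list(seed = seed, preset = "fig1b_c9_layerV"))
write.csv(res$units, file.path(out, "units.csv"), row.names = FALSE)

cat(sprintf("layer V:    fold %.2f (planted %.0f), 95%% CI [%.2f, %.2f], p=%.2g %s\n",
            cmpV$fold$ratio, unname(preset_planted("fig1b_c9_layerV")),
            cmpV$fold$ci[1], cmpV$fold$ci[2],
            cmpV$comparison$p_two_tailed, cmpV$comparison$stars))
cat(sprintf("layer II/III: fold %.2f, p=%.2g %s (no planted difference)\n",
            cmp23$fold$ratio, cmp23$comparison$p_two_tailed,
            cmp23$comparison$stars))
cat("wrote", file.path(out, "comparisons.csv"), "and summary figure\n")
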