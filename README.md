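# stingquant

Quantification of neuronal STING activation for ALS/FTD models: per-neuron
immunofluorescence measurement with a perinuclear-ring readout, layer-resolved
positive-neuron counting and fold-change statistics, and preranked gene-set
enrichment of a cGAS–STING pathway panel with a random-gene-set negative
control — all backed by a synthetic-data generator that plants known effect
sizes so the whole pipeline is testable without tissue or sequencing data.

## The scientific problem

STING (stimulator of interferon genes) is an ER-resident innate-immune
adaptor: cytosolic double-stranded DNA sensed by cGAS produces cGAMP, which
activates the canonical STING–TBK1–IRF3 arm, while nuclear DNA damage drives
the non-canonical NF-κB arm. When activated, STING relocalises to a
perinuclear compartment. In ALS/FTD this activation is reported selectively
in the vulnerable neuron classes — deep layer V cortical motor neurons and
spinal motor neurons — and not in spared layer II/III neurons. Substantiating
such claims requires a chain of quantitative steps this package makes
explicit and reproducible, for imaging scientists and computational
biologists who want to audit, reuse or extend them.

## The measurement core

**Perinuclear ring.** Each DAPI-segmented nucleus is dilated 10 iterations
with a 3×3 structuring element (ImageJ convention); STING stained area,
integrated intensity (Σ pixel values) and mean are measured in the ring
(dilated mask minus nuclei). A single-pixel nucleus dilates to a 21×21
square: ring area 440 (8-connectivity) or 220 (4-connectivity) — the
geometry is oracle-tested.

**Positive-neuron calling.** A neuron is STING-positive when its ring mean
exceeds an explicit, logged threshold: control-group mean + 2 sd by default,
or a global Otsu split for single-group cohorts. Counts aggregate cells →
fields → sections (one value per section/well/mouse), and groups are
compared by unpaired two-tailed Student's t (pooled variance); fold change is
the ratio of group means with a seeded bootstrap CI.

**Preranked enrichment.** Genes ranked by log2 fold change; the enrichment
score is the weighted Kolmogorov–Smirnov running sum
(`P_hit(i) = Σ_{g∈S, rank≤i} |s_g|/N_R`, `P_miss(i) = Σ_{g∉S, rank≤i}
1/(N−N_h)`, ES = signed extremum of `P_hit − P_miss`), with a gene-sampling
permutation null, `NES = ES / mean(|null ES| of matching sign)`, and the
empirical p as the matching-sign tail probability. A 25-gene cGAS–STING
panel ships as a clearly-labelled synthetic stand-in (replaceable via any
GMT file), and `random_geneset_control()` reproduces the negative control:
random gene sets stay at the nominal false-positive rate while the planted
panel is significant.

**ΔΔCt.** `ΔCt = Cq_target − Cq_reference`, `fold = 2^(−ΔΔCt)` over vehicle,
with TBP/HPRT/GAPDH-style reference genes.

## Worked example

Recover the planted layer-V contrast of the human motor-cortex cohort
(8 disease vs 6 control sections, 20 fields each, ~50 neurons per field):

```r
library(stingquant)

res  <- run_cohort_analysis("fig1b_c9_layerV", seed = 101)
cmpV <- compare_units(res$units, "n_sting_pos_V",      seed = 101)
cmp23 <- compare_units(res$units, "n_sting_pos_II_III", seed = 101)

cmpV$fold$ratio   # 4.88  — planted five-fold layer-V contrast
cmpV$fold$ci      # [4.41, 5.46]
cmpV$comparison   # t test on per-section means: p = 2.1e-12, "****"
cmp23$comparison  # layer II/III: p = 0.44, "ns" — no planted difference
```

The same run in script form is `analysis/04_report.R`, which prints

```
layer V:    fold 4.88 (planted 5), 95% CI [4.41, 5.46], p=2.1e-12 ****
layer II/III: fold 0.89, p=0.44 ns (no planted difference)
```

meaning: the full pipeline (simulate → segment → ring → call → count →
compare) returns the planted five-fold layer-V increase within its CI and
finds nothing in the spared superficial layer. The other drivers cover the
mouse comparisons (`analysis/02_quantify_imaging.R`: 36.4% layer-V neuron
loss vs 36.4% planted; 18.8% perinuclear-STING fraction among layer-marker-
positive neurons vs 18.9% planted) and enrichment
(`analysis/03_enrichment.R`: panel ES 0.92, NES 3.1, p ≈ 1e-3 on planted
data; 5.5–6% of random 30-gene sets significant at α = 0.05).

## Package layout

* `R/` — generator (`imaging_preset`, `generate_field`, `generate_de_table`),
  imaging I/O (`read_stack`, `project_z`), segmentation (`segment_nuclei`,
  `assemble_cells`), quantification (`dilate_mask`, `measure_perinuclear`,
  `call_positive`, `summarize_field`), enrichment (`enrichment_score`,
  `gsea_preranked`, `random_geneset_control`), statistics
  (`student_t_two_tailed`, `fold_change`, `ddct_fold_change`,
  `build_report`), and the staged `run_pipeline`.
* `analysis/` — numbered narrative drivers writing `results/`.
* `vignettes/stingquant-methods.Rmd` — the model, parameter and design
  documentation.
* `tests/testthat/` — unit, property and recovery tests with brute-force
  oracles.
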