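#!/usr/bin/env Rscript
# Spatial intra-tumoural heterogeneity: classify each selected variant as
# core-only / margin-only / shared, summarise exclusivity per patient, per
# gene and cohort-wide, and compare core vs margin exclusivity with an
# unpaired t-test.

suppressMessages({library(ctdnaITH); library(dplyr)})

tables <- read_cohort("results/cohort")
res <- run_cohort_analysis(tables)

classes <- bind_rows(lapply(names(res$patients), function(id) {
  left_join(res$patients[[id]]$classes,
            res$patients[[id]]$decisions[c("chrom", "pos", "ref", "alt",
                                           "gene")],
            by = c("chrom", "pos", "ref", "alt")) |>
    mutate(patient_id = id, .before = 1)
}))
write_results(list(spatial_classes = classes,
                   heterogeneity_per_patient = res$heterogeneity,
                   heterogeneity_cohort = res$cohort_heterogeneity,
                   gene_heterogeneity = res$gene_summary),
              "results")

het <- res$heterogeneity
all_rows <- het[het$annotation_filter == "all", ]
cos_rows <- het[het$annotation_filter == "cosmic_subset", ]
cat(sprintf("cohort heterogeneity rate (all variants): %.1f%% (range %.1f-%.1f%%)\n",
            100 * mean(all_rows$heterogeneity_rate),
            100 * min(all_rows$heterogeneity_rate),
            100 * max(all_rows$heterogeneity_rate)))
cat(sprintf("cohort heterogeneity rate (COSMIC subset): %.1f%%\n",
            100 * mean(cos_rows$heterogeneity_rate, na.rm = TRUE)))

tt <- compare_exclusivity(all_rows$prop_core_only, all_rows$prop_margin_only)
cat(sprintf("core vs margin exclusivity: %.1f%% vs %.1f%%, t = %.2f, p = %.3g\n",
            100 * mean(all_rows$prop_core_only),
            100 * mean(all_rows$prop_margin_only), tt$statistic, tt$p_value))
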