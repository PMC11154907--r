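#!/usr/bin/env Rscript
# Baseline ctDNA vs tumour concordance over the 9-gene plasma panel
# restricted to HNSCC COSMIC variants: detection rates over all and
# high-frequency (VAF > 5%) tumour variants, sub-site exclusivity of the
# detected variants, and the ctDNA-only fraction.

suppressMessages({library(ctdnaITH); library(dplyr)})

tables <- read_cohort("results/cohort")
res <- run_cohort_analysis(tables)

venns <- bind_rows(lapply(names(res$patients), function(id) {
  mutate(venn_counts(res$patients[[id]]$presence, tables[[id]]$variants),
         patient_id = id, .before = 1)
}))
write_results(list(concordance_per_patient = res$concordance,
                   concordance_cohort = res$cohort_concordance,
                   venn_counts = venns),
              "results")

co <- res$cohort_concordance
cat(sprintf("ctDNA detected %.1f%% of tumour variants (range %.1f-%.1f%%)\n",
            100 * co$mean_detection_rate_all,
            100 * co$min_detection_rate_all,
            100 * co$max_detection_rate_all))
cat(sprintf("ctDNA detected %.1f%% of high-frequency variants (range %.1f-%.1f%%)\n",
            100 * co$mean_detection_rate_highfreq,
            100 * co$min_detection_rate_highfreq,
            100 * co$max_detection_rate_highfreq))
cat(sprintf("of detected variants, %.1f%% were exclusive to one sub-site\n",
            100 * co$mean_exclusivity_among_detected))
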