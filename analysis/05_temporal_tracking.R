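#!/usr/bin/env Rscript
# Temporal tracking in the recurrence patients: baseline vs acquired
# labels, serial plasma VAF trajectories (persistence / loss /
# re-emergence), and molecular lead time ahead of clinical recurrence.

suppressMessages({library(ctdnaITH); library(dplyr)})

tables <- read_cohort("results/cohort")
res <- run_cohort_analysis(tables)

write_results(list(temporal_labels = res$labels,
                   trajectories = res$trajectories,
                   recurrence_calls = res$recurrence_calls),
              "results")

cat("label counts in recurrence patients:\n")
print(table(res$labels$patient_id, res$labels$label))

traj1 <- distinct(res$trajectories,
                  patient_id, chrom, pos, ref, alt, re_emerged)
cat("variants with dormancy-then-re-emergence pattern:",
    sum(traj1$re_emerged), "\n")

for (i in seq_len(nrow(res$recurrence_calls))) {
  r <- res$recurrence_calls[i, ]
  cat(sprintf("patient %s: molecular detection day %s, clinical recurrence day %s, lead time %s days\n",
              r$patient_id, r$detection_day, r$clinical_recurrence_day,
              r$lead_time_days))
}
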