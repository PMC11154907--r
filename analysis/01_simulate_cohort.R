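#!/usr/bin/env Rscript
# Generate the study cohort: 9 patients with PBMC, tumour core/margin and
# baseline plasma; the first 2 patients additionally carry serial
# post-treatment plasma (timepoints B-D) with a regrowing resistant clone
# and acquired variants. Writes pipeline-ready VCFs and sheets.

suppressMessages(library(ctdnaITH))

outdir <- "results/cohort"
cfg <- sim_config(seed = 1L)
cohort <- simulate_cohort(cfg, outdir = outdir, force = TRUE)

cat("simulated", cfg$n_patients, "patients ->", outdir, "\n")
cat("  variants per patient:",
    paste(vapply(cohort$tables, function(t) nrow(t$variants), integer(1)),
          collapse = ", "), "\n")
cat("  recurrence patients:", cfg$n_recurrence,
    "| resistant clones:",
    paste(na.omit(cohort$resistant_clones), collapse = ", "), "\n")
cat("  HNSCC COSMIC ids:", length(cohort$cosmic_ids), "\n")
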