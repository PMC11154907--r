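test_that("identical configs reproduce identical cohorts, files included", {
  cfg <- sim_config(n_patients = 2, n_recurrence = 1, seed = 99)
  d1 <- tempfile(); d2 <- tempfile()
  simulate_cohort(cfg, outdir = d1)
  simulate_cohort(cfg, outdir = d2)
  files <- sort(dir(d1))
  expect_setequal(files, sort(dir(d2)))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  expect_error(simulate_cohort(cfg, outdir = d1), "not empty")
  expect_silent(simulate_cohort(cfg, outdir = d1, force = TRUE))
})

test_that("cohort outputs are mutually consistent and reader-compatible", {
  cfg <- sim_config(n_patients = 3, n_recurrence = 1, seed = 12)
  dir <- tempfile()
  co <- simulate_cohort(cfg, outdir = dir)
  expect_length(dir(dir, pattern = "\\.vcf$"), 3)
  sheet <- read_sample_sheet(file.path(dir, "samples.tsv"))
  expect_equal(sum(sheet$role == "PBMC"), 3)

  # truth consistency: every table variant has truth rows for every sample
  for (id in names(co$tables)) {
    tab <- co$tables[[id]]
    tr <- co$truth[co$truth$patient_id == id, ]
    expect_setequal(paste(tr$chrom, tr$pos, tr$ref, tr$alt),
                    paste(tab$variants$chrom, tab$variants$pos,
                          tab$variants$ref, tab$variants$alt))
    expect_equal(nrow(tr), nrow(tab$variants) * nrow(tab$samples))
  }

  # files round-trip through the io layer to the in-memory tables
  tabs <- read_cohort(dir)
  for (id in names(tabs)) {
    expect_equal(tabs[[id]]$variants, co$tables[[id]]$variants)
    expect_equal(tabs[[id]]$calls[, c("depth", "alt_reads")],
                 co$tables[[id]]$calls[, c("depth", "alt_reads")])
  }
})

test_that("expected VAFs follow the purity/CCF and shedding formulas", {
  # purity 1, truncal CCF 1: expected tumour VAF 0.5; deep sequencing makes
  # the sample mean land within 3 binomial standard errors
  cfg <- sim_config(n_patients = 1, n_recurrence = 0, n_truncal = 1000L,
                    n_core_private = 0L, n_margin_private = 0L,
                    n_germline = 0L, n_chip = 0L, tumour_purity = 1,
                    mean_depth_tumour = 500, seed = 4)
  co <- simulate_cohort(cfg)
  calls <- co$tables[[1]]$calls
  core <- calls[calls$role == "CORE", ]
  se <- sqrt(0.5 * 0.5 / sum(core$depth))
  expect_lt(abs(sum(core$alt_reads) / sum(core$depth) - 0.5), 3 * se)

  tr <- co$truth
  expect_true(all(tr$true_vaf[tr$sample_name == paste0("PT01_CORE")] == 0.5))
  # plasma A truth for truncal variants: 0.5 * shed * mean CCF
  pa <- tr$true_vaf[grepl("PLASMA_A", tr$sample_name)]
  expect_true(all(abs(pa - 0.5 * cfg$shed_fraction * 1) < 1e-12))
})

test_that("shedding fraction 0 silences all somatic plasma reads", {
  cfg <- sim_config(n_patients = 2, n_recurrence = 0, shed_fraction = 0,
                    n_germline = 0L, n_chip = 0L, seed = 31)
  co <- simulate_cohort(cfg)
  for (tab in co$tables) {
    pl <- tab$calls[tab$calls$role == "PLASMA", ]
    expect_true(all(pl$alt_reads == 0))
  }
})

test_that("private clones are confined to their sub-site in truth and mostly in data", {
  cfg <- sim_config(n_patients = 1, n_recurrence = 0, seed = 77)
  co <- simulate_cohort(cfg)
  tr <- co$truth[co$truth$patient_id == "PT01", ]
  cp <- tr[tr$class == "SOMATIC_CORE_PRIVATE", ]
  expect_true(all(cp$true_vaf[cp$sample_name == "PT01_MARGIN"] == 0))
  expect_true(all(cp$true_vaf[cp$sample_name == "PT01_CORE"] > 0))
  tv <- tr[tr$class == "SOMATIC_TRUNCAL", ]
  expect_true(all(tv$true_vaf[tv$sample_name %in%
                                c("PT01_CORE", "PT01_MARGIN")] > 0))
  g <- tr[tr$class == "GERMLINE", ]
  expect_true(all(g$true_vaf %in% c(0.5, 1.0)))
  ch <- tr[tr$class == "CHIP", ]
  expect_true(all(ch$true_vaf[ch$sample_name %in%
                                c("PT01_CORE", "PT01_MARGIN")] == 0))
})

test_that("serial plasma honours the recurrence scenario construction", {
  # no resistant clone, no acquired variants: post-treatment somatic silence
  cfg <- sim_config(n_patients = 1, n_recurrence = 1,
                    resistant_clone = FALSE, n_acquired = 0L,
                    n_germline = 0L, n_chip = 0L, seed = 8)
  co <- simulate_cohort(cfg)
  tab <- co$tables[[1]]
  post <- tab$calls[tab$calls$role == "PLASMA" &
                      tab$calls$timepoint %in% c("B", "C", "D"), ]
  expect_true(all(post$alt_reads == 0))

  # multipliers (0, 0, 1): the resistant clone is detectable only at D
  cfg2 <- sim_config(n_patients = 1, n_recurrence = 1,
                     regrowth_multipliers = c(B = 0, C = 0, D = 20),
                     n_acquired = 0L, n_germline = 0L, n_chip = 0L,
                     shed_fraction = 0.05, seed = 15)
  co2 <- simulate_cohort(cfg2)
  tr2 <- co2$truth[co2$truth$patient_id == "PT01", ]
  bc <- tr2[grepl("PLASMA_[BC]", tr2$sample_name), ]
  expect_true(all(bc$true_vaf == 0))
  dd <- tr2[grepl("PLASMA_D", tr2$sample_name), ]
  expect_true(any(dd$true_vaf > 0))

  # acquired variants appear from the onset timepoint onward
  cfg3 <- sim_config(n_patients = 1, n_recurrence = 1, n_acquired = 4L,
                     acquired_onset = "C", resistant_clone = FALSE,
                     seed = 5)
  co3 <- simulate_cohort(cfg3)
  tr3 <- co3$truth[co3$truth$class == "ACQUIRED", ]
  expect_true(all(tr3$true_vaf[grepl("PLASMA_B|PLASMA_A|CORE|MARGIN|PBMC",
                                     tr3$sample_name)] == 0))
  expect_true(all(tr3$true_vaf[grepl("PLASMA_[CD]", tr3$sample_name)] > 0))
  expect_error(
    simulate_patient(sim_config(n_truncal = 0L, n_core_private = 0L,
                                n_margin_private = 0L), "X",
                     recurrence = TRUE),
    "somatic")
})

test_that("two-step serial extension matches the one-shot recurrence contract", {
  cfg <- sim_config(n_patients = 1, n_recurrence = 0, seed = 42)
  set.seed(1)
  base <- simulate_patient(cfg, "PTX", recurrence = FALSE)
  ext <- simulate_serial_plasma(cfg, base)
  expect_setequal(ext$table$samples$timepoint[ext$table$samples$role == "PLASMA"],
                  c("A", "B", "C", "D"))
  expect_gte(nrow(ext$table$variants), nrow(base$table$variants))
  # acquired variants exist post-extension and are absent pre-extension
  expect_true(any(ext$truth$class == "ACQUIRED"))
  expect_false(any(base$truth$class == "ACQUIRED"))
  # every variant still has a call for every sample
  expect_equal(nrow(ext$table$calls),
               nrow(ext$table$variants) * nrow(ext$table$samples))
})
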