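test_that("threshold invariants are validated", {
  expect_error(filter_thresholds(germline_af_max = 1.2), "\\[0, 1\\]")
  expect_error(filter_thresholds(lowcov_af_min = 0.05), "must exceed")
  expect_error(filter_thresholds(min_supporting_reads = -1), "non-negative")
  th <- filter_thresholds()
  expect_equal(th$germline_af_max, 0.10)
  expect_equal(th$final_vaf_min, 0.001)
})

test_that("filter config YAML round-trips and rejects unknown fields", {
  th <- filter_thresholds(high_freq_vaf = 0.1)
  path <- tempfile(fileext = ".yaml")
  write_filter_config(th, path)
  expect_equal(read_filter_config(path), th)
  yaml::write_yaml(list(nonsense = 1), path)
  expect_error(read_filter_config(path), "unknown filter config")
})

# one variant per scenario, spanning each rule of the cascade
cascade_case <- function(pbmc_depth, pbmc_alt, core_depth, core_alt,
                         cosmic = FALSE) {
  calls <- dplyr::bind_rows(
    vcall("chr1", 100, "PBMC", pbmc_depth, pbmc_alt),
    vcall("chr1", 100, "CORE", core_depth, core_alt))
  tab <- mk_table(calls, cosmic_keys = if (cosmic) "chr1 100 A T")
  apply_filter_cascade(tab)$outcome
}

test_that("cascade reproduces the published rule set on worked examples", {
  # well-covered PBMC at 15% VAF: germline, unless COSMIC-rescued
  expect_equal(cascade_case(30, 5, 50, 20), "REMOVED_GERMLINE")  # 5/30 > 10%
  expect_equal(cascade_case(30, 5, 50, 20, cosmic = TRUE), "RESCUED_COSMIC")
  # low-coverage PBMC rescued by >20% VAF with >= 10 supporting reads
  expect_equal(cascade_case(10, 0, 48, 12), "RETAINED")          # 25%, 12 reads
  # same VAF but only 6 supporting reads: untestable germline
  expect_equal(cascade_case(10, 0, 24, 6), "REMOVED_LOWCOV_PBMC")
  # fewer than 4 supporting reads anywhere: no evidence
  expect_equal(cascade_case(30, 0, 60, 3), "REMOVED_LOW_SUPPORT")
  # boundary: exactly 10% PBMC VAF is not germline (strict >)
  expect_equal(cascade_case(20, 2, 50, 20), "RETAINED")
  # boundary: exactly 20% non-PBMC VAF does not rescue low PBMC coverage
  expect_equal(cascade_case(19, 0, 50, 10), "REMOVED_LOWCOV_PBMC")
  expect_error(
    apply_filter_cascade(mk_table(vcall("chr1", 1, "CORE", 10, 5),
                                  samples = default_samples()[-1, ])),
    "no PBMC")
})

test_that("alternative germline-restore reading only differs for R1 removals", {
  # germline-flagged variant with strong non-PBMC support is restored under
  # the alternative reading (and then faces the remaining rules)
  calls <- dplyr::bind_rows(
    vcall("chr1", 100, "PBMC", 30, 5),
    vcall("chr1", 100, "CORE", 50, 20))
  tab <- mk_table(calls)
  expect_equal(apply_filter_cascade(tab)$outcome, "REMOVED_GERMLINE")
  expect_equal(
    apply_filter_cascade(tab, germline_rescue_by_reads = TRUE)$outcome,
    "RETAINED")
  # with < 4 supporting reads it stays germline under both readings
  calls2 <- dplyr::bind_rows(
    vcall("chr1", 100, "PBMC", 30, 5),
    vcall("chr1", 100, "CORE", 50, 3))
  tab2 <- mk_table(calls2)
  expect_equal(
    apply_filter_cascade(tab2, germline_rescue_by_reads = TRUE)$outcome,
    "REMOVED_GERMLINE")
})

test_that("cascade outcomes match the brute-force oracle on randomized records", {
  tab <- random_cascade_table(2000, seed = 11)
  dec <- apply_filter_cascade(tab)
  calls <- tab$calls
  expected <- vapply(seq_len(nrow(dec)), function(i) {
    vc <- calls[calls$pos == dec$pos[i], ]
    pb <- vc[vc$role == "PBMC", ]
    ot <- vc[vc$role != "PBMC", ]
    oracle_filter_one(pb$depth, pb$alt_reads, ot$depth, ot$alt_reads,
                      dec$in_hnscc_cosmic_subset[i])
  }, character(1))
  expect_identical(dec$outcome, expected)
  # partition: every variant gets exactly one outcome
  expect_equal(sum(table(dec$outcome)), nrow(tab$variants))
})

test_that("cascade is idempotent on the retained subset", {
  tab <- random_cascade_table(500, seed = 3)
  dec <- apply_filter_cascade(tab)
  kept <- dec[dec$outcome == "RETAINED", c("chrom", "pos", "ref", "alt")]
  sub_calls <- dplyr::semi_join(tab$calls, kept,
                                by = c("chrom", "pos", "ref", "alt"))
  sub <- mk_table(sub_calls[, c("chrom", "pos", "ref", "alt", "sample_name",
                                "depth", "alt_reads")])
  dec2 <- apply_filter_cascade(sub)
  expect_true(all(dec2$outcome == "RETAINED"))
})

test_that("retention is monotone in the germline threshold, presence in the VAF floor", {
  tab <- random_cascade_table(800, seed = 5)
  kept_at <- function(af) {
    sum(apply_filter_cascade(tab, filter_thresholds(germline_af_max = af))$outcome
        %in% c("RETAINED", "RESCUED_COSMIC"))
  }
  counts <- vapply(c(0.05, 0.10, 0.15, 0.19), kept_at, numeric(1))
  expect_true(all(diff(counts) >= 0))

  dec <- apply_filter_cascade(tab)
  present_at <- function(v) {
    sum(build_presence_matrix(tab, dec,
                              filter_thresholds(final_vaf_min = v))$present)
  }
  pres <- vapply(c(0.0005, 0.001, 0.01, 0.1), present_at, numeric(1))
  expect_true(all(diff(pres) <= 0))
})

test_that("presence needs candidacy plus >=1 read at or above the 0.1% floor", {
  calls <- dplyr::bind_rows(
    vcall("chr1", 1, "PBMC", 30, 0), vcall("chr1", 1, "CORE", 1000, 1),
    vcall("chr1", 2, "PBMC", 30, 0), vcall("chr1", 2, "CORE", 2000, 1),
    vcall("chr1", 2, "MARGIN", 100, 30),
    vcall("chr1", 3, "PBMC", 30, 15), vcall("chr1", 3, "CORE", 100, 50))
  # give variant 1 enough support elsewhere to survive R2
  calls <- dplyr::bind_rows(calls, vcall("chr1", 1, "MARGIN", 100, 20))
  tab <- mk_table(calls)
  dec <- apply_filter_cascade(tab)
  pres <- build_presence_matrix(tab, dec)
  get <- function(pos, sample) pres$present[pres$pos == pos &
                                              pres$sample_name == sample]
  expect_true(get(1, "CORE"))    # vaf exactly 0.001: floor is inclusive
  expect_false(get(2, "CORE"))   # vaf 0.0005: below the floor
  expect_false(get(3, "CORE"))   # removed as germline: absent everywhere
  # PBMC never appears in the presence matrix
  expect_false(any(pres$role == "PBMC"))
})
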