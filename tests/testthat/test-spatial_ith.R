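# presence fixtures built directly (bypassing the filter) via prow()

simple_presence <- function() {
  dplyr::bind_rows(
    prow(1, "CORE", "CORE", TRUE), prow(1, "MARGIN", "MARGIN", FALSE),
    prow(2, "CORE", "CORE", TRUE), prow(2, "MARGIN", "MARGIN", TRUE),
    prow(3, "CORE", "CORE", FALSE), prow(3, "MARGIN", "MARGIN", TRUE),
    prow(4, "CORE", "CORE", FALSE), prow(4, "MARGIN", "MARGIN", FALSE),
    prow(4, "PLASMA_A", "PLASMA", TRUE, timepoint = "A")
  )
}

test_that("variants classify by sub-site exclusivity; plasma-only stays out of tumour", {
  cl <- classify_spatial(simple_presence())
  got <- setNames(cl$spatial_class, cl$pos)
  expect_equal(got[["1"]], "CORE_ONLY")
  expect_equal(got[["2"]], "SHARED")
  expect_equal(got[["3"]], "MARGIN_ONLY")
  expect_equal(got[["4"]], "NOT_IN_TUMOUR")

  no_margin <- simple_presence() |> dplyr::filter(role != "MARGIN")
  expect_error(classify_spatial(no_margin, "P9"), "P9 has no MARGIN")
})

test_that("heterogeneity proportions partition tumour-present variants", {
  # 10 variants: 4 core-only, 3 margin-only, 3 shared
  pres <- dplyr::bind_rows(lapply(1:10, function(i) {
    dplyr::bind_rows(
      prow(i, "CORE", "CORE", i <= 4 || i > 7),
      prow(i, "MARGIN", "MARGIN", i > 4))
  }))
  s <- heterogeneity_summary(classify_spatial(pres))
  expect_equal(s$n_variants, 10L)
  expect_equal(s$prop_core_only, 0.4)
  expect_equal(s$prop_margin_only, 0.3)
  expect_equal(s$prop_shared, 0.3)
  expect_equal(s$heterogeneity_rate, 0.7)
  expect_equal(s$prop_core_only + s$prop_margin_only + s$prop_shared, 1)

  all_shared <- dplyr::bind_rows(prow(1, "CORE", "CORE", TRUE),
                                 prow(1, "MARGIN", "MARGIN", TRUE))
  expect_equal(heterogeneity_summary(classify_spatial(all_shared))$heterogeneity_rate, 0)

  # no tumour-present variants: undefined, not zero
  empty <- dplyr::bind_rows(prow(1, "CORE", "CORE", FALSE),
                            prow(1, "MARGIN", "MARGIN", FALSE))
  s0 <- heterogeneity_summary(classify_spatial(empty))
  expect_equal(s0$n_variants, 0L)
  expect_true(is.na(s0$heterogeneity_rate))
})

test_that("swapping core and margin labels swaps proportions, keeps the rate", {
  pres <- simple_presence()
  swapped <- pres |>
    dplyr::mutate(role = dplyr::recode(role, CORE = "MARGIN", MARGIN = "CORE"))
  a <- heterogeneity_summary(classify_spatial(pres))
  b <- heterogeneity_summary(classify_spatial(swapped))
  expect_equal(a$prop_core_only, b$prop_margin_only)
  expect_equal(a$prop_margin_only, b$prop_core_only)
  expect_equal(a$heterogeneity_rate, b$heterogeneity_rate)
})

test_that("cohort summary is the unweighted mean over patients with range", {
  per <- tibble::tibble(
    n_variants = c(10L, 4L), prop_core_only = c(0.4, 0.5),
    prop_margin_only = c(0.3, 0.25), prop_shared = c(0.3, 0.25),
    heterogeneity_rate = c(0.7, 0.75))
  co <- cohort_heterogeneity(per)
  expect_equal(co$mean_heterogeneity_rate, 0.725)
  expect_equal(co$min_heterogeneity_rate, 0.7)
  expect_equal(co$max_heterogeneity_rate, 0.75)
  # undefined patients are excluded, not averaged as zero
  co2 <- cohort_heterogeneity(dplyr::bind_rows(
    per, tibble::tibble(n_variants = 0L, prop_core_only = NA_real_,
                        prop_margin_only = NA_real_, prop_shared = NA_real_,
                        heterogeneity_rate = NA_real_)))
  expect_equal(co2$n_patients, 2L)
  expect_equal(co2$mean_heterogeneity_rate, 0.725)
})

test_that("gene-level means match brute-force recomputation on a random cohort", {
  set.seed(21)
  genes <- c("TP53", "FAT1", "NOTCH1")
  mk_patient <- function() {
    n <- 6
    tibble::tibble(
      chrom = "chr1", pos = 1:n, ref = "A", alt = "T",
      gene = sample(genes, n, replace = TRUE),
      spatial_class = sample(c("CORE_ONLY", "MARGIN_ONLY", "SHARED",
                               "NOT_IN_TUMOUR"), n, replace = TRUE))
  }
  cohort <- list(p1 = mk_patient(), p2 = mk_patient(), p3 = mk_patient())
  got <- gene_level_summary(cohort, gene_panel = c(genes, "PTEN"))

  for (g in genes) {
    per_patient <- c()
    for (p in cohort) {
      rows <- p[p$gene == g & p$spatial_class != "NOT_IN_TUMOUR", ]
      if (nrow(rows) > 0) {
        per_patient <- c(per_patient,
                         mean(rows$spatial_class != "SHARED"))
      }
    }
    row <- got[got$gene == g, ]
    if (length(per_patient) == 0) {
      expect_equal(row$n_patients, 0L)
    } else {
      expect_equal(row$n_patients, length(per_patient))
      expect_equal(row$mean_exclusivity, mean(per_patient))
    }
  }
  # gene absent cohort-wide still gets a row with undefined mean
  pten <- got[got$gene == "PTEN", ]
  expect_equal(pten$n_patients, 0L)
  expect_true(is.na(pten$mean_exclusivity))
})

test_that("high-frequency subset uses a strict 5% cut within tumour-present variants", {
  pres <- dplyr::bind_rows(
    prow(1, "CORE", "CORE", TRUE, vaf = 0.06),
    prow(1, "MARGIN", "MARGIN", FALSE, vaf = 0),
    prow(2, "CORE", "CORE", TRUE, vaf = 0.05),
    prow(2, "MARGIN", "MARGIN", TRUE, vaf = 0.04),
    prow(3, "CORE", "CORE", TRUE, vaf = 0.02),
    prow(3, "MARGIN", "MARGIN", TRUE, vaf = 0.07),
    prow(4, "PLASMA_A", "PLASMA", TRUE, vaf = 0.5, timepoint = "A"))
  hf <- high_frequency_subset(pres)
  expect_equal(sort(hf$pos), c(1L, 3L))           # strict > 0.05
  tumour_present <- classify_spatial(pres)
  tp <- tumour_present$pos[tumour_present$spatial_class != "NOT_IN_TUMOUR"]
  expect_true(all(hf$pos %in% tp))                # subset of tumour-present
})

test_that("exclusivity comparison matches the closed-form Student t-test", {
  expect_equal(compare_exclusivity(c(0.2, 0.6), c(0.2, 0.6))$p_value, 1)
  expect_equal(compare_exclusivity(c(0.2, 0.6), c(0.2, 0.6))$statistic, 0)
  expect_lt(compare_exclusivity(c(0, 0, 0), c(1, 1, 1))$p_value, 0.001)
  expect_error(compare_exclusivity(0.5, c(0.2, 0.3)), "at least 2")

  set.seed(8)
  a <- runif(6); b <- runif(9)
  got <- compare_exclusivity(a, b)
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  df <- length(a) + length(b) - 2
  expect_equal(got$statistic, tstat)
  expect_equal(got$p_value, 2 * pt(-abs(tstat), df))
  # Welch flag switches to unequal-variance df
  expect_equal(compare_exclusivity(a, b, welch = TRUE)$df,
               unname(t.test(a, b)$parameter))
})
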