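# Concordance between baseline plasma (ctDNA) variants and tumour sub-site
# variants: detection rates over all and high-frequency tumour variants, the
# sub-site exclusivity of detected variants, and the ctDNA-only fraction.

#' Per-patient ctDNA/tumour concordance
#'
#' The tumour set is the union of variants present in the core or margin;
#' the plasma set is the variants present in the baseline plasma sample.
#' Because the plasma assay is a targeted panel, the variant universe is
#' restricted by default to the panel genes (tumour variants the assay
#' cannot see are excluded from denominators) and to COSMIC-annotated
#' variants of the HNSCC subset. Rates with zero denominators are reported
#' as NA, never 0.
#'
#' @param presence Output of [build_presence_matrix()].
#' @param classes Output of [classify_spatial()].
#' @param highfreq Output of [high_frequency_subset()].
#' @param variants Variant annotation tibble (key columns, `gene`,
#'   `in_hnscc_cosmic_subset`).
#' @param patient_id Patient identifier carried into the output.
#' @param baseline_timepoint Plasma timepoint defining the ctDNA set
#'   (default `"A"`).
#' @param cosmic_only Restrict the universe to the HNSCC COSMIC subset
#'   (default TRUE).
#' @param panel_genes Genes visible to the plasma assay; `NULL` disables the
#'   panel restriction. Default the 9-gene plasma panel.
#' @return One-row tibble: `patient_id`, `n_tumour`, `n_tumour_highfreq`,
#'   `n_plasma`, `n_overlap`, `detection_rate_all`,
#'   `detection_rate_highfreq`, `exclusivity_among_detected`,
#'   `plasma_only_fraction`; or NULL (with a warning) when the patient has
#'   no baseline plasma sample.
#' @export
concordance <- function(presence, classes, highfreq, variants,
                        patient_id = "?", baseline_timepoint = "A",
                        cosmic_only = TRUE,
                        panel_genes = plasma_panel_genes()) {
  has_baseline <- any(presence$role == "PLASMA" &
                        !is.na(presence$timepoint) &
                        presence$timepoint == baseline_timepoint)
  if (!has_baseline) {
    warning("patient ", patient_id, " has no baseline plasma sample; skipped")
    return(NULL)
  }

  universe <- variants[KEY_COLS]
  if (!is.null(panel_genes)) {
    universe <- variants[variants$gene %in% panel_genes, KEY_COLS]
  }
  if (cosmic_only) {
    universe <- dplyr::semi_join(
      universe, variants[variants$in_hnscc_cosmic_subset, KEY_COLS],
      by = KEY_COLS)
  }

  tumour <- classes |>
    dplyr::filter(.data$spatial_class != "NOT_IN_TUMOUR") |>
    dplyr::semi_join(universe, by = KEY_COLS)
  plasma <- presence |>
    dplyr::filter(.data$role == "PLASMA", !is.na(.data$timepoint),
                  .data$timepoint == baseline_timepoint, .data$present) |>
    dplyr::distinct(dplyr::across(dplyr::all_of(KEY_COLS))) |>
    dplyr::semi_join(universe, by = KEY_COLS)
  hf <- dplyr::semi_join(highfreq, universe, by = KEY_COLS)

  overlap <- dplyr::semi_join(tumour, plasma, by = KEY_COLS)
  hf_overlap <- dplyr::semi_join(hf, plasma, by = KEY_COLS)
  n_tumour <- nrow(tumour)
  n_hf <- nrow(hf)
  n_plasma <- nrow(plasma)
  n_overlap <- nrow(overlap)

  rate <- function(num, den) if (den > 0) num / den else NA_real_
  tibble::tibble(
    patient_id = patient_id,
    n_tumour = n_tumour, n_tumour_highfreq = n_hf, n_plasma = n_plasma,
    n_overlap = n_overlap,
    detection_rate_all = rate(n_overlap, n_tumour),
    detection_rate_highfreq = rate(nrow(hf_overlap), n_hf),
    exclusivity_among_detected = rate(
      sum(overlap$spatial_class %in% c("CORE_ONLY", "MARGIN_ONLY")),
      n_overlap),
    plasma_only_fraction = rate(n_plasma - n_overlap, n_plasma)
  )
}

#' Cohort concordance summary
#'
#' Unweighted mean and min--max range of each rate over patients with
#' defined values; undefined (NA) rates are excluded from the means.
#' Optionally adds leave-one-out means of `detection_rate_highfreq`, to
#' quantify the influence of outlier patients.
#'
#' @param per_patient Row-bound per-patient [concordance()] summaries.
#' @param leave_one_out Also compute leave-one-out means (default FALSE).
#' @return One-row tibble of means and ranges; with `leave_one_out`, a
#'   list with the summary and a per-left-out-patient tibble.
#' @export
cohort_concordance <- function(per_patient, leave_one_out = FALSE) {
  rates <- c("detection_rate_all", "detection_rate_highfreq",
             "exclusivity_among_detected", "plasma_only_fraction")
  out <- tibble::tibble(n_patients = nrow(per_patient))
  for (r in rates) {
    v <- per_patient[[r]]
    v <- v[!is.na(v)]
    out[[paste0("mean_", r)]] <- if (length(v)) mean(v) else NA_real_
    out[[paste0("min_", r)]] <- if (length(v)) min(v) else NA_real_
    out[[paste0("max_", r)]] <- if (length(v)) max(v) else NA_real_
  }
  if (!leave_one_out) return(out)
  loo <- lapply(seq_len(nrow(per_patient)), function(i) {
    v <- per_patient$detection_rate_highfreq[-i]
    tibble::tibble(left_out = per_patient$patient_id[i],
                   mean_detection_rate_highfreq = mean(v, na.rm = TRUE))
  })
  list(summary = out, leave_one_out = dplyr::bind_rows(loo))
}

#' Venn region counts for core/margin/baseline-plasma membership
#'
#' Counts of variants in each of the 7 non-empty regions of the
#' core/margin/plasma Venn diagram, over the same restricted universe as
#' [concordance()].
#'
#' @inheritParams concordance
#' @return Tibble with columns `region` and `n`.
#' @export
venn_counts <- function(presence, variants, baseline_timepoint = "A",
                        cosmic_only = TRUE,
                        panel_genes = plasma_panel_genes()) {
  universe <- variants[KEY_COLS]
  if (!is.null(panel_genes)) {
    universe <- variants[variants$gene %in% panel_genes, KEY_COLS]
  }
  if (cosmic_only) {
    universe <- dplyr::semi_join(
      universe, variants[variants$in_hnscc_cosmic_subset, KEY_COLS],
      by = KEY_COLS)
  }
  mem <- presence |>
    dplyr::semi_join(universe, by = KEY_COLS) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(KEY_COLS))) |>
    dplyr::summarise(
      core = any(.data$present[.data$role == "CORE"]),
      margin = any(.data$present[.data$role == "MARGIN"]),
      plasma = any(.data$present[.data$role == "PLASMA" &
                                   !is.na(.data$timepoint) &
                                   .data$timepoint == baseline_timepoint]),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$core | .data$margin | .data$plasma)
  lab <- function(c, m, p) {
    paste0(ifelse(c, "core", ""), ifelse(m, "+margin", ""),
           ifelse(p, "+plasma", ""))
  }
  regions <- expand.grid(core = c(TRUE, FALSE), margin = c(TRUE, FALSE),
                         plasma = c(TRUE, FALSE))
  regions <- regions[rowSums(regions) > 0, ]
  tibble::tibble(
    region = sub("^\\+", "", mapply(lab, regions$core, regions$margin,
                                    regions$plasma)),
    n = mapply(function(c, m, p) {
      sum(mem$core == c & mem$margin == m & mem$plasma == p)
    }, regions$core, regions$margin, regions$plasma)
  )
}
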