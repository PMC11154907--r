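# Spatial intra-tumoural heterogeneity: classify variants by tumour sub-site
# exclusivity (core vs advancing margin) and summarise exclusivity
# proportions at variant, gene, patient and cohort level.

SPATIAL_CLASSES <- c("CORE_ONLY", "MARGIN_ONLY", "SHARED", "NOT_IN_TUMOUR")

#' Classify variants by tumour sub-site exclusivity
#'
#' A variant present in the core but not the margin is `CORE_ONLY`
#' (symmetrically `MARGIN_ONLY`); present in both, `SHARED`; present in
#' neither sub-site (e.g. plasma-only), `NOT_IN_TUMOUR`. Classification
#' uses the presence matrix restricted to the CORE and MARGIN samples only.
#'
#' @param presence Output of [build_presence_matrix()]; the patient must
#'   have both a CORE and a MARGIN sample.
#' @param patient_id Used in error messages.
#' @return Tibble: key columns plus `spatial_class`.
#' @export
classify_spatial <- function(presence, patient_id = "?") {
  for (site in c("CORE", "MARGIN")) {
    if (!site %in% presence$role) {
      stop("patient ", patient_id, " has no ", site, " sample")
    }
  }
  wide <- presence |>
    dplyr::filter(.data$role %in% c("CORE", "MARGIN")) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(KEY_COLS))) |>
    dplyr::summarise(
      in_core = any(.data$present[.data$role == "CORE"]),
      in_margin = any(.data$present[.data$role == "MARGIN"]),
      .groups = "drop"
    )
  all_keys <- dplyr::distinct(presence[KEY_COLS])
  dplyr::left_join(all_keys, wide, by = KEY_COLS) |>
    dplyr::mutate(
      in_core = !is.na(.data$in_core) & .data$in_core,
      in_margin = !is.na(.data$in_margin) & .data$in_margin,
      spatial_class = dplyr::case_when(
        .data$in_core & .data$in_margin ~ "SHARED",
        .data$in_core ~ "CORE_ONLY",
        .data$in_margin ~ "MARGIN_ONLY",
        TRUE ~ "NOT_IN_TUMOUR"
      )
    ) |>
    dplyr::select(dplyr::all_of(c(KEY_COLS, "spatial_class")))
}

#' Per-patient heterogeneity summary
#'
#' Proportions of tumour-present variants exclusive to the core, exclusive
#' to the margin, or shared; the heterogeneity rate is the exclusive
#' fraction (1 - shared). Variants not present in either sub-site are
#' excluded from all denominators. With no tumour-present variant in scope
#' the proportions are undefined (NA), never 0.
#'
#' @param classes Output of [classify_spatial()].
#' @param variants Optional variant annotation tibble (key columns plus
#'   `gene`, `in_hnscc_cosmic_subset`), required for
#'   `annotation_filter = "cosmic_subset"`.
#' @param annotation_filter `"all"` or `"cosmic_subset"` (restrict to
#'   variants flagged in the HNSCC COSMIC subset).
#' @return One-row tibble: `n_variants`, `prop_core_only`,
#'   `prop_margin_only`, `prop_shared`, `heterogeneity_rate`.
#' @export
heterogeneity_summary <- function(classes, variants = NULL,
                                  annotation_filter = c("all",
                                                        "cosmic_subset")) {
  annotation_filter <- match.arg(annotation_filter)
  if (annotation_filter == "cosmic_subset") {
    if (is.null(variants)) {
      stop("annotation_filter = 'cosmic_subset' needs the variants table")
    }
    keep <- variants[variants$in_hnscc_cosmic_subset, KEY_COLS]
    classes <- dplyr::semi_join(classes, keep, by = KEY_COLS)
  }
  tum <- classes$spatial_class[classes$spatial_class != "NOT_IN_TUMOUR"]
  n <- length(tum)
  if (n == 0) {
    return(tibble::tibble(n_variants = 0L, prop_core_only = NA_real_,
                          prop_margin_only = NA_real_,
                          prop_shared = NA_real_,
                          heterogeneity_rate = NA_real_))
  }
  tibble::tibble(
    n_variants = n,
    prop_core_only = mean(tum == "CORE_ONLY"),
    prop_margin_only = mean(tum == "MARGIN_ONLY"),
    prop_shared = mean(tum == "SHARED"),
    heterogeneity_rate = mean(tum != "SHARED")
  )
}

#' Cohort-level heterogeneity summary
#'
#' Cohort values are unweighted means over per-patient proportions (not
#' pooled over variants), with min--max ranges, mirroring how multi-patient
#' exclusivity is conventionally reported. Patients with undefined
#' proportions (no tumour-present variants in scope) are excluded.
#'
#' @param per_patient Tibble with one [heterogeneity_summary()] row per
#'   patient (a `patient_id` column is allowed and ignored).
#' @return One-row tibble of means and ranges.
#' @export
cohort_heterogeneity <- function(per_patient) {
  ok <- per_patient[!is.na(per_patient$heterogeneity_rate), ]
  if (nrow(ok) == 0) {
    return(tibble::tibble(n_patients = 0L, mean_heterogeneity_rate = NA_real_,
                          min_heterogeneity_rate = NA_real_,
                          max_heterogeneity_rate = NA_real_,
                          mean_prop_core_only = NA_real_,
                          mean_prop_margin_only = NA_real_,
                          mean_prop_shared = NA_real_))
  }
  tibble::tibble(
    n_patients = nrow(ok),
    mean_heterogeneity_rate = mean(ok$heterogeneity_rate),
    min_heterogeneity_rate = min(ok$heterogeneity_rate),
    max_heterogeneity_rate = max(ok$heterogeneity_rate),
    mean_prop_core_only = mean(ok$prop_core_only),
    mean_prop_margin_only = mean(ok$prop_margin_only),
    mean_prop_shared = mean(ok$prop_shared)
  )
}

#' Per-gene heterogeneity across patients
#'
#' For each gene in the panel, the exclusivity proportion is computed per
#' patient over that gene's tumour-present variants; the gene summary is the
#' unweighted mean over patients with at least one such variant. Genes with
#' no variants cohort-wide are emitted with `n_patients = 0` and undefined
#' mean.
#'
#' @param patient_classes Named list (by patient id) of tibbles joining
#'   [classify_spatial()] output with the `gene` column.
#' @param gene_panel Character vector of genes to report (default the
#'   19-gene TCGA HNSCC panel).
#' @return Tibble: `gene`, `n_patients`, `mean_exclusivity`,
#'   `min_exclusivity`, `max_exclusivity`.
#' @export
gene_level_summary <- function(patient_classes,
                               gene_panel = hnscc_gene_panel()$gene) {
  per <- dplyr::bind_rows(patient_classes, .id = "patient_id") |>
    dplyr::filter(.data$spatial_class != "NOT_IN_TUMOUR",
                  .data$gene %in% gene_panel) |>
    dplyr::group_by(.data$patient_id, .data$gene) |>
    dplyr::summarise(
      exclusivity = mean(.data$spatial_class != "SHARED"),
      .groups = "drop"
    )
  out <- per |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      n_patients = dplyr::n(),
      mean_exclusivity = mean(.data$exclusivity),
      min_exclusivity = min(.data$exclusivity),
      max_exclusivity = max(.data$exclusivity),
      .groups = "drop"
    )
  tibble::tibble(gene = gene_panel) |>
    dplyr::left_join(out, by = "gene") |>
    dplyr::mutate(n_patients = ifelse(is.na(.data$n_patients), 0L,
                                      .data$n_patients))
}

#' High-frequency tumour variants
#'
#' Tumour-present variants whose VAF strictly exceeds `high_freq_vaf`
#' (default 5%) in at least one of the core/margin samples -- a crude proxy
#' for clonal (driver) status in the absence of formal clonality analysis.
#'
#' @param presence Output of [build_presence_matrix()].
#' @param thresholds A [filter_thresholds()] object.
#' @return Tibble of variant keys.
#' @export
high_frequency_subset <- function(presence,
                                  thresholds = filter_thresholds()) {
  tumour_present <- presence |>
    dplyr::filter(.data$role %in% c("CORE", "MARGIN"), .data$present) |>
    dplyr::distinct(dplyr::across(dplyr::all_of(KEY_COLS)))
  hf <- presence |>
    dplyr::filter(.data$role %in% c("CORE", "MARGIN"), .data$present,
                  !is.na(.data$vaf), .data$vaf > thresholds$high_freq_vaf) |>
    dplyr::distinct(dplyr::across(dplyr::all_of(KEY_COLS)))
  dplyr::semi_join(hf, tumour_present, by = KEY_COLS)
}

#' Compare exclusivity proportions between two groups
#'
#' Two-sample unpaired Student t-test (equal variance) on per-patient
#' proportions, two-sided; Welch's correction available via `welch = TRUE`.
#'
#' @param group_a,group_b Numeric vectors of per-patient proportions, each
#'   of length >= 2.
#' @param welch Use Welch's unequal-variance t-test instead of Student's.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
compare_exclusivity <- function(group_a, group_b, welch = FALSE) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least 2 values")
  }
  # degenerate zero-variance groups (t.test refuses them): complete
  # separation gives p = 0, identical constants give p = 1
  if (stats::var(group_a) + stats::var(group_b) < .Machine$double.eps) {
    delta <- mean(group_a) - mean(group_b)
    df <- length(group_a) + length(group_b) - 2
    if (abs(delta) < .Machine$double.eps) {
      return(list(statistic = 0, df = df, p_value = 1))
    }
    return(list(statistic = sign(delta) * Inf, df = df, p_value = 0))
  }
  ht <- stats::t.test(group_a, group_b, var.equal = !welch,
                      alternative = "two.sided")
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}
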