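# End-to-end orchestration: filter -> presence -> spatial -> concordance ->
# temporal, per patient and across the cohort. The analysis/ scripts and
# the acceptance script are thin drivers over these two functions.

#' Run the full analysis for one patient
#'
#' @param table A [patient_variant_table()] with annotation attached.
#' @param thresholds A [filter_thresholds()] object.
#' @param cosmic_only,panel_genes Passed to [concordance()].
#' @param qualifying Passed to [molecular_recurrence()].
#' @return List: `decisions`, `presence`, `classes`, `highfreq`,
#'   `heterogeneity` (all-variant and COSMIC-subset rows), `concordance`,
#'   `labels`, `trajectories`, `recurrence` (the last three NULL when the
#'   patient has no post-treatment plasma).
#' @export
run_patient_analysis <- function(table, thresholds = filter_thresholds(),
                                 cosmic_only = TRUE,
                                 panel_genes = plasma_panel_genes(),
                                 qualifying = "cosmic_subset") {
  decisions <- apply_filter_cascade(table, thresholds)
  presence <- build_presence_matrix(table, decisions, thresholds)
  classes <- classify_spatial(presence, table$patient_id)
  highfreq <- high_frequency_subset(presence, thresholds)

  het <- dplyr::bind_rows(
    heterogeneity_summary(classes) |>
      dplyr::mutate(annotation_filter = "all"),
    heterogeneity_summary(classes, table$variants, "cosmic_subset") |>
      dplyr::mutate(annotation_filter = "cosmic_subset")
  ) |>
    dplyr::mutate(patient_id = table$patient_id, .before = 1)

  conc <- suppressWarnings(
    concordance(presence, classes, highfreq, table$variants,
                patient_id = table$patient_id, cosmic_only = cosmic_only,
                panel_genes = panel_genes))

  has_post <- any(presence$role == "PLASMA" & !is.na(presence$timepoint) &
                    presence$timepoint %in% POST_TREATMENT_TIMEPOINTS)
  labels <- trajectories <- recurrence <- NULL
  if (has_post) {
    labels <- label_variants(presence, classes)
    trajectories <- build_trajectories(presence, labels, table$variants)
    rec_day <- unique(stats::na.omit(table$samples$recurrence_day))
    recurrence <- molecular_recurrence(
      trajectories,
      if (length(rec_day) == 1) rec_day else NA_integer_,
      patient_id = table$patient_id, qualifying = qualifying)
  }

  list(decisions = decisions, presence = presence, classes = classes,
       highfreq = highfreq, heterogeneity = het, concordance = conc,
       labels = labels, trajectories = trajectories,
       recurrence = recurrence)
}

#' Run the full analysis across a cohort
#'
#' @param tables Named list of annotated [patient_variant_table()] objects.
#' @inheritParams run_patient_analysis
#' @return List of cohort-level tables: per-patient results (`patients`),
#'   `heterogeneity` (per patient), `cohort_heterogeneity` (all-variant and
#'   COSMIC-subset rows), `gene_summary`, `concordance` (per patient),
#'   `cohort_concordance`, `labels`, `trajectories`, `recurrence_calls`.
#' @export
run_cohort_analysis <- function(tables, thresholds = filter_thresholds(),
                                cosmic_only = TRUE,
                                panel_genes = plasma_panel_genes(),
                                qualifying = "cosmic_subset") {
  res <- lapply(tables, run_patient_analysis, thresholds = thresholds,
                cosmic_only = cosmic_only, panel_genes = panel_genes,
                qualifying = qualifying)

  het <- dplyr::bind_rows(lapply(res, function(r) r$heterogeneity))
  cohort_het <- dplyr::bind_rows(
    cohort_heterogeneity(het[het$annotation_filter == "all", ]) |>
      dplyr::mutate(annotation_filter = "all", .before = 1),
    cohort_heterogeneity(het[het$annotation_filter == "cosmic_subset", ]) |>
      dplyr::mutate(annotation_filter = "cosmic_subset", .before = 1)
  )

  gene_classes <- lapply(res, function(r) {
    dplyr::left_join(r$classes,
                     r$decisions[c(KEY_COLS, "gene")], by = KEY_COLS)
  })
  names(gene_classes) <- names(res)
  gene_summary <- gene_level_summary(gene_classes)

  conc <- dplyr::bind_rows(lapply(res, function(r) r$concordance))
  cohort_conc <- if (nrow(conc) > 0) cohort_concordance(conc) else NULL

  labels <- dplyr::bind_rows(lapply(names(res), function(id) {
    if (is.null(res[[id]]$labels)) return(NULL)
    dplyr::mutate(res[[id]]$labels, patient_id = id, .before = 1)
  }))
  traj <- dplyr::bind_rows(lapply(names(res), function(id) {
    if (is.null(res[[id]]$trajectories)) return(NULL)
    dplyr::mutate(res[[id]]$trajectories, patient_id = id, .before = 1)
  }))
  rec <- dplyr::bind_rows(lapply(res, function(r) r$recurrence))

  list(patients = res, heterogeneity = het,
       cohort_heterogeneity = cohort_het, gene_summary = gene_summary,
       concordance = conc, cohort_concordance = cohort_conc,
       labels = labels, trajectories = traj, recurrence_calls = rec)
}

#' Load a simulated or real cohort from files
#'
#' Reads every `*.vcf` under `dir` together with `samples.tsv`,
#' `annotation.tsv` and `cosmic_hnscc.txt` (the layout written by
#' [simulate_cohort()]) and returns annotated per-patient variant tables.
#'
#' @param dir Directory holding the cohort files.
#' @return Named list of [patient_variant_table()] objects.
#' @export
read_cohort <- function(dir) {
  sheet <- read_sample_sheet(file.path(dir, "samples.tsv"))
  ann <- read_annotation_table(file.path(dir, "annotation.tsv"))
  cosmic <- read_cosmic_list(file.path(dir, "cosmic_hnscc.txt"))
  vcfs <- sort(list.files(dir, pattern = "\\.vcf$", full.names = TRUE))
  tables <- lapply(vcfs, function(p) {
    annotate_variants(read_multisample_vcf(p, sheet), ann, cosmic)
  })
  names(tables) <- vapply(tables, function(t) t$patient_id, character(1))
  tables
}
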