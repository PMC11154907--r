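# Temporal tracking across serial plasma timepoints: baseline vs acquired
# variant labels, per-variant VAF trajectories (persistence, loss,
# re-emergence), and molecular lead time relative to clinical recurrence.

POST_TREATMENT_TIMEPOINTS <- c("B", "C", "D")

#' Label variants as baseline or acquired
#'
#' A variant present in the resected primary tumour (core or margin) is
#' `BASELINE`; a variant absent from both tumour sub-sites but present in at
#' least one post-treatment plasma sample (timepoints B--D) is `ACQUIRED`.
#' The two labels are disjoint by construction. Variants present only in
#' baseline plasma (timepoint A) receive neither label and are reported as
#' `PLASMA_A_ONLY`; such a variant's origin cannot be assigned under the
#' study design. Acquisition is defined against the primary tumour only, so
#' by default a variant present at A and again post-treatment but never in
#' tumour is still `ACQUIRED`; `strict_acquired` additionally requires
#' absence at A.
#'
#' @param presence Output of [build_presence_matrix()].
#' @param classes Output of [classify_spatial()].
#' @param strict_acquired Require absence at baseline plasma too (default
#'   FALSE).
#' @return Tibble: key columns plus `label` (`BASELINE`, `ACQUIRED` or
#'   `PLASMA_A_ONLY`), covering every variant present in at least one
#'   non-PBMC sample. Warns when the patient has no post-treatment plasma
#'   sample (labelling is then restricted to BASELINE).
#' @export
label_variants <- function(presence, classes, strict_acquired = FALSE) {
  has_post <- any(presence$role == "PLASMA" & !is.na(presence$timepoint) &
                    presence$timepoint %in% POST_TREATMENT_TIMEPOINTS)
  if (!has_post) {
    warning("no post-treatment plasma sample; only BASELINE labels possible")
  }
  status <- presence |>
    dplyr::group_by(dplyr::across(dplyr::all_of(KEY_COLS))) |>
    dplyr::summarise(
      in_plasma_a = any(.data$present[.data$role == "PLASMA" &
                                        !is.na(.data$timepoint) &
                                        .data$timepoint == "A"]),
      in_post = any(.data$present[.data$role == "PLASMA" &
                                    !is.na(.data$timepoint) &
                                    .data$timepoint %in%
                                      POST_TREATMENT_TIMEPOINTS]),
      anywhere = any(.data$present),
      .groups = "drop"
    ) |>
    dplyr::left_join(classes, by = KEY_COLS) |>
    dplyr::filter(.data$anywhere)
  tumour_present <- status$spatial_class %in% c("CORE_ONLY", "MARGIN_ONLY",
                                                "SHARED")
  acquired <- !tumour_present & status$in_post &
    (!strict_acquired | !status$in_plasma_a)
  status$label <- dplyr::case_when(
    tumour_present ~ "BASELINE",
    acquired ~ "ACQUIRED",
    TRUE ~ "PLASMA_A_ONLY"
  )
  status[c(KEY_COLS, "label")]
}

#' Build per-variant plasma VAF trajectories
#'
#' One row per labelled variant per plasma timepoint, with presence, VAF and
#' collection day, plus per-variant pattern flags: `persisted` (present at
#' two consecutive sampled timepoints), `lost` (present then absent at a
#' later sampled timepoint) and `re_emerged` (present, absent, then present
#' again -- the dormant-clone pattern), and `first_detection_day` (earliest
#' post-treatment day the variant was seen).
#'
#' @param presence Output of [build_presence_matrix()].
#' @param labels Output of [label_variants()].
#' @param variants Variant annotation tibble (for `gene`/COSMIC columns).
#' @return Long tibble: key, `gene`, `in_hnscc_cosmic_subset`, `label`,
#'   `timepoint`, `collection_day`, `present`, `vaf`, pattern flags and
#'   `first_detection_day` (NA when never seen post-treatment).
#' @export
build_trajectories <- function(presence, labels, variants) {
  plasma <- presence |>
    dplyr::filter(.data$role == "PLASMA", !is.na(.data$timepoint)) |>
    dplyr::inner_join(labels, by = KEY_COLS) |>
    dplyr::left_join(
      variants[c(KEY_COLS, "gene", "in_hnscc_cosmic_subset")],
      by = KEY_COLS) |>
    dplyr::arrange(.data$chrom, .data$pos, .data$ref, .data$alt,
                   .data$collection_day)
  patt <- plasma |>
    dplyr::group_by(dplyr::across(dplyr::all_of(KEY_COLS))) |>
    dplyr::summarise(
      persisted = any(.data$present[-dplyr::n()] &
                        .data$present[-1]),
      lost = any(cumsum(.data$present) > 0 & !.data$present),
      re_emerged = {
        p <- .data$present
        runs <- rle(p)$values
        sum(runs) >= 2  # present, absent, present again
      },
      first_detection_day = {
        post <- .data$present &
          .data$timepoint %in% POST_TREATMENT_TIMEPOINTS
        if (any(post)) min(.data$collection_day[post]) else NA_integer_
      },
      .groups = "drop"
    )
  plasma |>
    dplyr::select(dplyr::all_of(c(KEY_COLS, "gene",
                                  "in_hnscc_cosmic_subset", "label",
                                  "timepoint", "collection_day", "present",
                                  "vaf"))) |>
    dplyr::mutate(vaf = ifelse(.data$present, .data$vaf, NA_real_)) |>
    dplyr::left_join(patt, by = KEY_COLS)
}

#' Molecular recurrence call and lead time
#'
#' The molecular detection day is the earliest post-treatment plasma
#' collection day at which at least one qualifying variant (BASELINE or
#' ACQUIRED; by default restricted to the HNSCC COSMIC subset, since
#' recurrence tracking follows oncogenic variants) is present. Lead time is
#' the number of days molecular detection precedes clinical recurrence.
#' Baseline plasma (timepoint A) never triggers molecular recurrence.
#'
#' @param trajectories Output of [build_trajectories()].
#' @param clinical_recurrence_day Day of clinical recurrence relative to
#'   treatment completion (integer), or NA if unknown.
#' @param patient_id Carried into the output.
#' @param qualifying `"cosmic_subset"` (default) or `"all"`.
#' @return One-row tibble: `patient_id`, `detection_day`,
#'   `clinical_recurrence_day`, `lead_time_days`. `detection_day` is NA when
#'   no qualifying variant is ever detected post-treatment; `lead_time_days`
#'   is NA when there is no detection on or before the clinical recurrence
#'   day.
#' @export
molecular_recurrence <- function(trajectories, clinical_recurrence_day,
                                 patient_id = "?",
                                 qualifying = c("cosmic_subset", "all")) {
  qualifying <- match.arg(qualifying)
  qual <- trajectories |>
    dplyr::filter(.data$label %in% c("BASELINE", "ACQUIRED"),
                  .data$timepoint %in% POST_TREATMENT_TIMEPOINTS,
                  .data$present)
  if (qualifying == "cosmic_subset") {
    qual <- qual[qual$in_hnscc_cosmic_subset, ]
  }
  detection_day <- if (nrow(qual) > 0) min(qual$collection_day) else
    NA_integer_
  lead <- if (!is.na(detection_day) && !is.na(clinical_recurrence_day) &&
              detection_day <= clinical_recurrence_day) {
    as.integer(clinical_recurrence_day - detection_day)
  } else {
    NA_integer_
  }
  tibble::tibble(patient_id = patient_id,
                 detection_day = as.integer(detection_day),
                 clinical_recurrence_day =
                   as.integer(clinical_recurrence_day),
                 lead_time_days = lead)
}
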