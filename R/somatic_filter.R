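# Per-patient somatic variant selection: germline/CHIP subtraction against
# the matched PBMC sample, minimum-evidence and low-coverage-PBMC rules, and
# COSMIC HNSCC driver rescue, with a complete per-variant audit trail.

FILTER_OUTCOMES <- c("RETAINED", "REMOVED_GERMLINE", "REMOVED_LOW_SUPPORT",
                     "REMOVED_LOWCOV_PBMC", "RESCUED_COSMIC")

#' Thresholds for the somatic selection cascade
#'
#' Defaults follow the study's published criteria: a variant is called
#' germline when the PBMC control shows alternate allele frequency >10% at
#' 20-fold or greater coverage; candidate somatic variants need 4 or more
#' supporting reads in at least one non-PBMC sample; sites with below
#' 20-fold PBMC coverage are kept only when some non-PBMC sample shows VAF
#' >20% with 10 or more supporting reads; and a universal VAF floor of 0.1%
#' defines per-sample presence in tumour and plasma. The 5% threshold marks
#' "high frequency" variants used as a crude clonality proxy.
#'
#' @param germline_af_max PBMC VAF above which (strictly) a well-covered
#'   variant is germline. Default 0.10.
#' @param germline_min_depth PBMC depth at/above which the germline rule is
#'   trustworthy. Default 20.
#' @param min_supporting_reads Minimum alt reads required in at least one
#'   non-PBMC sample. Default 4.
#' @param lowcov_af_min Non-PBMC VAF that must be exceeded (strictly) to keep
#'   a variant whose PBMC coverage is inadequate. Default 0.20.
#' @param lowcov_min_reads Alt reads required alongside `lowcov_af_min` in
#'   the same sample. Default 10.
#' @param final_vaf_min Per-sample presence floor on VAF (inclusive),
#'   applied to tumour and plasma samples. Default 0.001.
#' @param high_freq_vaf VAF above which (strictly) a tumour variant counts
#'   as high frequency. Default 0.05.
#' @return A list of class `filter_thresholds`.
#' @export
filter_thresholds <- function(germline_af_max = 0.10,
                              germline_min_depth = 20L,
                              min_supporting_reads = 4L,
                              lowcov_af_min = 0.20,
                              lowcov_min_reads = 10L,
                              final_vaf_min = 0.001,
                              high_freq_vaf = 0.05) {
  th <- list(germline_af_max = germline_af_max,
             germline_min_depth = as.integer(germline_min_depth),
             min_supporting_reads = as.integer(min_supporting_reads),
             lowcov_af_min = lowcov_af_min,
             lowcov_min_reads = as.integer(lowcov_min_reads),
             final_vaf_min = final_vaf_min,
             high_freq_vaf = high_freq_vaf)
  fracs <- c(th$germline_af_max, th$lowcov_af_min, th$final_vaf_min,
             th$high_freq_vaf)
  if (any(fracs < 0 | fracs > 1)) {
    stop("frequency thresholds must lie in [0, 1]")
  }
  if (th$lowcov_af_min <= th$germline_af_max) {
    stop("lowcov_af_min must exceed germline_af_max")
  }
  counts <- c(th$germline_min_depth, th$min_supporting_reads,
              th$lowcov_min_reads)
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("read-count thresholds must be non-negative integers")
  }
  structure(th, class = "filter_thresholds")
}

#' Read / write filter thresholds as a YAML config
#'
#' @param path YAML file holding any subset of the [filter_thresholds()]
#'   fields; unlisted fields keep their defaults.
#' @export
read_filter_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(filter_thresholds))
  extra <- setdiff(names(vals), known)
  if (length(extra) > 0) {
    stop("unknown filter config field(s): ", paste(extra, collapse = ", "))
  }
  do.call(filter_thresholds, vals)
}

#' @rdname read_filter_config
#' @param thresholds A [filter_thresholds()] object.
#' @export
write_filter_config <- function(thresholds, path) {
  yaml::write_yaml(unclass(thresholds), path)
  invisible(path)
}

#' Apply the somatic selection cascade to one patient
#'
#' Every variant is evaluated in a fixed rule order:
#'
#' * **R1** (germline removal): PBMC depth >= `germline_min_depth` and PBMC
#'   VAF strictly > `germline_af_max` removes the variant as germline/CHIP.
#' * **R2** (minimum evidence): otherwise, a variant with fewer than
#'   `min_supporting_reads` alt reads in every non-PBMC sample is removed.
#'   PBMC reads never count as support -- rescuing on germline evidence
#'   would defeat the subtraction.
#' * **R3** (untestable germline): otherwise, a variant whose PBMC coverage
#'   is below `germline_min_depth` is removed unless some non-PBMC sample
#'   shows VAF strictly > `lowcov_af_min` with >= `lowcov_min_reads` alt
#'   reads.
#' * **R4** (COSMIC rescue): a variant removed by R1--R3 whose annotation is
#'   in the HNSCC COSMIC subset is restored to candidacy (`RESCUED_COSMIC`).
#'   Rescue restores candidacy only; the per-sample presence floor still
#'   applies (see [build_presence_matrix()]).
#'
#' `rule_trace` records each rule evaluated with its boolean result, e.g.
#' `"R1=F;R2=T;R4=F"`; rules after the first firing removal rule are not
#' evaluated (R4 is evaluated whenever a removal fired).
#'
#' @param table A [patient_variant_table()] including a PBMC sample.
#' @param thresholds A [filter_thresholds()] object.
#' @param germline_rescue_by_reads Alternative reading of the evidence rule
#'   in which variants removed as germline (R1) are restored when some
#'   non-PBMC sample carries `min_supporting_reads` alt reads, instead of
#'   that requirement gating all variants. Off by default; the default
#'   reading is the only one under which the cascade yields a somatic rather
#'   than germline-dominated set.
#' @return A tibble with one row per variant: the key, `outcome`,
#'   `rule_trace`, and the PBMC / best-non-PBMC evidence used.
#' @export
apply_filter_cascade <- function(table, thresholds = filter_thresholds(),
                                 germline_rescue_by_reads = FALSE) {
  stopifnot(inherits(thresholds, "filter_thresholds"))
  calls <- table$calls
  if (!any(calls$role == "PBMC") && nrow(table$variants) > 0) {
    stop("patient ", table$patient_id, " has no PBMC sample")
  }
  if (!"PBMC" %in% table$samples$role) {
    stop("patient ", table$patient_id, " has no PBMC sample")
  }

  pbmc <- calls[calls$role == "PBMC", ] |>
    dplyr::transmute(dplyr::across(dplyr::all_of(KEY_COLS)),
                     pbmc_depth = .data$depth,
                     pbmc_vaf = .data$vaf)
  other <- calls[calls$role != "PBMC", ] |>
    dplyr::group_by(dplyr::across(dplyr::all_of(KEY_COLS))) |>
    dplyr::summarise(
      max_alt_reads = if (dplyr::n() > 0) max(.data$alt_reads) else 0L,
      max_vaf = suppressWarnings(max(c(.data$vaf, 0), na.rm = TRUE)),
      lowcov_rescue = any(!is.na(.data$vaf) &
                            .data$vaf > thresholds$lowcov_af_min &
                            .data$alt_reads >= thresholds$lowcov_min_reads),
      .groups = "drop"
    )

  d <- table$variants |>
    dplyr::left_join(pbmc, by = KEY_COLS) |>
    dplyr::left_join(other, by = KEY_COLS)
  d$max_alt_reads[is.na(d$max_alt_reads)] <- 0L
  d$max_vaf[is.na(d$max_vaf)] <- 0
  d$lowcov_rescue[is.na(d$lowcov_rescue)] <- FALSE

  r1 <- d$pbmc_depth >= thresholds$germline_min_depth &
    !is.na(d$pbmc_vaf) & d$pbmc_vaf > thresholds$germline_af_max
  r2 <- d$max_alt_reads < thresholds$min_supporting_reads
  r3 <- d$pbmc_depth < thresholds$germline_min_depth & !d$lowcov_rescue

  n <- nrow(d)
  outcome <- character(n)
  trace <- character(n)
  for (i in seq_len(n)) {
    tr <- c(R1 = r1[i])
    if (r1[i] && germline_rescue_by_reads) {
      # alternative reading: R1-removed variants restored by read support
      tr <- c(tr, R1b = !r2[i])
      if (!r2[i]) tr["R1"] <- FALSE  # restored: continue the cascade
    }
    fired <- ""
    if (isTRUE(tr[["R1"]]) &&
        !(germline_rescue_by_reads && isTRUE(tr["R1b"]))) {
      fired <- "REMOVED_GERMLINE"
    } else {
      tr <- c(tr, R2 = r2[i])
      if (r2[i]) {
        fired <- "REMOVED_LOW_SUPPORT"
      } else {
        tr <- c(tr, R3 = r3[i])
        if (r3[i]) fired <- "REMOVED_LOWCOV_PBMC"
      }
    }
    if (fired != "") {
      rescued <- isTRUE(d$in_hnscc_cosmic_subset[i])
      tr <- c(tr, R4 = rescued)
      outcome[i] <- if (rescued) "RESCUED_COSMIC" else fired
    } else {
      outcome[i] <- "RETAINED"
    }
    trace[i] <- paste(names(tr), ifelse(tr, "T", "F"),
                      sep = "=", collapse = ";")
  }

  tibble::tibble(
    d[c(KEY_COLS, "gene", "cosmic_id", "in_hnscc_cosmic_subset")],
    outcome = outcome, rule_trace = trace,
    pbmc_depth = d$pbmc_depth, pbmc_vaf = d$pbmc_vaf,
    max_alt_reads = d$max_alt_reads, max_nonpbmc_vaf = d$max_vaf
  )
}

#' Per-sample presence of selected variants
#'
#' A variant is present in a tumour or plasma sample when it survived the
#' cascade (`RETAINED` or `RESCUED_COSMIC`) and the sample shows at least
#' one alt read at non-zero depth with VAF at or above the presence floor
#' (`final_vaf_min`, default 0.1%, inclusive). PBMC samples are excluded --
#' the presence floor applies to tumour and plasma only.
#'
#' @param table A [patient_variant_table()].
#' @param decisions Output of [apply_filter_cascade()].
#' @param thresholds A [filter_thresholds()] object.
#' @return Tibble: key columns, `sample_name`, `role`, `timepoint`,
#'   `collection_day`, `vaf`, `present`.
#' @export
build_presence_matrix <- function(table, decisions,
                                  thresholds = filter_thresholds()) {
  kept <- decisions[decisions$outcome %in% c("RETAINED", "RESCUED_COSMIC"),
                    KEY_COLS]
  kept$kept <- TRUE
  table$calls[table$calls$role != "PBMC", ] |>
    dplyr::left_join(kept, by = KEY_COLS) |>
    dplyr::mutate(
      present = !is.na(.data$kept) & .data$alt_reads >= 1L &
        .data$depth >= 1L & !is.na(.data$vaf) &
        .data$vaf >= thresholds$final_vaf_min
    ) |>
    dplyr::select(dplyr::all_of(c(KEY_COLS, "sample_name", "role",
                                  "timepoint", "collection_day", "depth",
                                  "alt_reads", "vaf", "present")))
}
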