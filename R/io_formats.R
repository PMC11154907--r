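# Reading and writing the pipeline's external formats: multi-sample VCF,
# sample sheet, annotation table, COSMIC id list, and result tables.
#
# Conventions (fixed throughout the package):
#  * coordinates are 1-based, VCF convention; input is assumed normalized and
#    keys are never left-renormalized beyond multi-allelic splitting
#  * VAF is always recomputed as alt_reads/depth; frequency fields in the VCF
#    are ignored (avoids dialect drift between callers)
#  * depth 0 means "absent, untestable": vaf is NA and the call can never be
#    scored present downstream
#  * the sample sheet is the single source of role/timepoint truth; VCF
#    sample names carry no semantics

KEY_COLS <- c("chrom", "pos", "ref", "alt")
SAMPLE_ROLES <- c("PBMC", "CORE", "MARGIN", "PLASMA")
PLASMA_TIMEPOINTS <- c("A", "B", "C", "D")

#' Read and validate a sample sheet
#'
#' The sample sheet maps VCF sample names to their biological role and, for
#' plasma samples, their serial timepoint. One row per sequenced sample.
#'
#' @param path Path to a tab-separated file with header columns
#'   `patient_id`, `sample_name`, `role` (one of PBMC, CORE, MARGIN, PLASMA),
#'   `timepoint` (A--D for plasma, empty otherwise; A is the baseline sample
#'   drawn at resection), `collection_day` (integer days relative to
#'   completion of primary treatment, negative allowed pre-treatment) and
#'   `recurrence_day` (day of clinical recurrence, empty if none).
#' @return A tibble with those columns, types enforced.
#' @export
read_sample_sheet <- function(path) {
  sheet <- readr::read_tsv(
    path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      sample_name = readr::col_character(),
      role = readr::col_character(),
      timepoint = readr::col_character(),
      collection_day = readr::col_integer(),
      recurrence_day = readr::col_integer()
    ),
    na = c("", "NA")
  )
  validate_sample_sheet(sheet)
}

#' @rdname read_sample_sheet
#' @param sheet A data frame shaped like the sample-sheet TSV.
#' @export
validate_sample_sheet <- function(sheet) {
  sheet <- tibble::as_tibble(sheet)
  required <- c("patient_id", "sample_name", "role", "timepoint",
                "collection_day", "recurrence_day")
  missing <- setdiff(required, names(sheet))
  if (length(missing) > 0) {
    stop("sample sheet is missing columns: ", paste(missing, collapse = ", "))
  }
  bad_role <- setdiff(unique(sheet$role), SAMPLE_ROLES)
  if (length(bad_role) > 0) {
    stop("unknown sample role(s): ", paste(bad_role, collapse = ", "))
  }
  if (anyDuplicated(sheet$sample_name) > 0) {
    stop("duplicate sample_name in sample sheet")
  }
  bad_tp <- sheet$role == "PLASMA" &
    (is.na(sheet$timepoint) | !sheet$timepoint %in% PLASMA_TIMEPOINTS)
  if (any(bad_tp)) {
    stop("plasma samples must carry a timepoint in A-D: ",
         paste(sheet$sample_name[bad_tp], collapse = ", "))
  }
  for (pid in unique(sheet$patient_id)) {
    ps <- sheet[sheet$patient_id == pid, ]
    if (sum(ps$role == "PBMC") != 1) {
      stop("patient ", pid, " must have exactly one PBMC sample")
    }
    if (sum(ps$role == "CORE") > 1 || sum(ps$role == "MARGIN") > 1) {
      stop("patient ", pid, " has more than one CORE or MARGIN sample")
    }
    pl <- ps[ps$role == "PLASMA", ]
    if (anyDuplicated(pl$timepoint) > 0) {
      stop("patient ", pid, " has duplicate plasma timepoints")
    }
    if (nrow(pl) > 1) {
      ord <- order(match(pl$timepoint, PLASMA_TIMEPOINTS))
      if (is.unsorted(pl$collection_day[ord], strictly = TRUE)) {
        stop("patient ", pid,
             ": plasma timepoint order A<B<C<D must match collection_day order")
      }
    }
  }
  sheet
}

#' Construct a per-patient variant table
#'
#' The central container for one patient's calls: an ordered set of variant
#' keys (chrom, pos, ref, alt) with annotation, and one read-evidence entry
#' (depth, alt_reads, vaf) per variant per sequenced sample. Every variant
#' carries a call for every sample; a sample not covering a site carries
#' depth 0 (vaf NA).
#'
#' @param patient_id Patient identifier.
#' @param variants Tibble with columns `chrom`, `pos`, `ref`, `alt` and
#'   optionally `gene`, `cosmic_id`, `in_hnscc_cosmic_subset`.
#' @param calls Tibble with the key columns plus `sample_name`, `depth`,
#'   `alt_reads` (`vaf` is recomputed).
#' @param samples Sample-sheet rows for this patient.
#' @return An object of class `patient_variant_table`.
#' @export
patient_variant_table <- function(patient_id, variants, calls, samples) {
  variants <- tibble::as_tibble(variants)
  if (!"gene" %in% names(variants)) variants$gene <- ""
  if (!"cosmic_id" %in% names(variants)) variants$cosmic_id <- ""
  if (!"in_hnscc_cosmic_subset" %in% names(variants)) {
    variants$in_hnscc_cosmic_subset <- FALSE
  }
  variants$gene[is.na(variants$gene)] <- ""
  variants$cosmic_id[is.na(variants$cosmic_id)] <- ""
  variants <- variants[c(KEY_COLS, "gene", "cosmic_id",
                         "in_hnscc_cosmic_subset")] |>
    dplyr::arrange(.data$chrom, .data$pos, .data$ref, .data$alt)
  if (anyDuplicated(variants[KEY_COLS]) > 0) {
    stop("duplicate variant keys for patient ", patient_id)
  }
  if (any(variants$pos < 1)) stop("variant positions must be >= 1")
  if (any(variants$ref == variants$alt)) stop("ref and alt alleles must differ")

  samples <- tibble::as_tibble(samples)
  calls <- tibble::as_tibble(calls)
  # complete the grid: a variant with no entry for some sample gets depth 0
  grid <- tidyr::crossing(variants[KEY_COLS],
                          sample_name = samples$sample_name)
  calls <- dplyr::left_join(grid, calls[c(KEY_COLS, "sample_name", "depth",
                                          "alt_reads")],
                            by = c(KEY_COLS, "sample_name")) |>
    dplyr::mutate(
      depth = ifelse(is.na(.data$depth), 0L, as.integer(.data$depth)),
      alt_reads = ifelse(is.na(.data$alt_reads), 0L,
                         as.integer(.data$alt_reads))
    )
  if (any(calls$alt_reads > calls$depth)) {
    stop("alt_reads exceeds depth for patient ", patient_id)
  }
  calls$vaf <- ifelse(calls$depth > 0, calls$alt_reads / calls$depth, NA_real_)
  calls <- dplyr::left_join(
    calls, samples[c("sample_name", "role", "timepoint", "collection_day")],
    by = "sample_name"
  ) |>
    dplyr::arrange(.data$chrom, .data$pos, .data$ref, .data$alt,
                   .data$sample_name)

  structure(
    list(patient_id = patient_id, variants = variants, calls = calls,
         samples = samples),
    class = "patient_variant_table"
  )
}

#' @export
print.patient_variant_table <- function(x, ...) {
  cat("<patient_variant_table> patient", x$patient_id, "-",
      nrow(x$variants), "variants x", nrow(x$samples), "samples\n")
  invisible(x)
}

#' Read a per-patient multi-sample VCF into a variant table
#'
#' Parses a VCF 4.x file covering all of one patient's samples (PBMC, tumour
#' core/margin, plasma timepoints). Multi-allelic records are split into one
#' row per alternate allele. Depth and alt-supporting read counts are taken
#' from the per-sample FORMAT fields; VAF is recomputed from the counts and
#' any frequency field in the file is ignored. Missing genotype entries
#' become depth-0 calls.
#'
#' @param path Path to the VCF file.
#' @param sample_sheet Validated sample sheet; every VCF sample name must
#'   resolve to exactly one row, all belonging to a single patient.
#' @param dp_tag FORMAT tag holding total read depth (default `"DP"`).
#' @param ad_tag FORMAT tag holding allele-supporting read counts (default
#'   `"AD"`); either a comma list `ref,alt1[,alt2...]` or a bare alt count.
#' @return A [patient_variant_table()].
#' @export
read_multisample_vcf <- function(path, sample_sheet, dp_tag = "DP",
                                 ad_tag = "AD") {
  sample_sheet <- validate_sample_sheet(sample_sheet)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  vcf_samples <- colnames(vcf@gt)[-1]
  unknown <- setdiff(vcf_samples, sample_sheet$sample_name)
  if (length(unknown) > 0) {
    stop("VCF sample(s) not in sample sheet: ", paste(unknown, collapse = ", "))
  }
  rows <- sample_sheet[match(vcf_samples, sample_sheet$sample_name), ]
  pid <- unique(rows$patient_id)
  if (length(pid) != 1) {
    stop("VCF mixes samples from patients: ", paste(pid, collapse = ", "))
  }
  samples <- sample_sheet[sample_sheet$patient_id == pid, ]

  n_rec <- nrow(vcf@fix)
  if (n_rec == 0) {
    empty <- tibble::tibble(chrom = character(), pos = integer(),
                            ref = character(), alt = character())
    return(patient_variant_table(pid, empty,
                                 cbind(empty, tibble::tibble(
                                   sample_name = character(),
                                   depth = integer(), alt_reads = integer())),
                                 samples))
  }

  fix <- vcfR::getFIX(vcf)
  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  if (anyNA(pos)) {
    stop("malformed VCF record (non-integer POS) at record ",
         which(is.na(pos))[1])
  }
  dp <- vcfR::extract.gt(vcf, element = dp_tag, as.numeric = TRUE)
  ad <- vcfR::extract.gt(vcf, element = ad_tag)
  if (is.null(dim(dp))) dp <- matrix(dp, nrow = n_rec)
  if (is.null(dim(ad))) ad <- matrix(ad, nrow = n_rec)

  recs <- vector("list", n_rec)
  for (i in seq_len(n_rec)) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    per_alt <- vector("list", length(alts))
    for (j in seq_along(alts)) {
      depth_i <- dp[i, ]
      depth_i[is.na(depth_i)] <- 0
      ad_i <- ad[i, ]
      alt_ct <- vapply(ad_i, function(x) {
        if (is.na(x) || x == ".") return(0)
        parts <- strsplit(x, ",", fixed = TRUE)[[1]]
        val <- if (length(parts) > 1) parts[j + 1L] else parts[1L]
        out <- suppressWarnings(as.numeric(val))
        if (is.na(out)) {
          stop("malformed ", ad_tag, " field '", x, "' at record ", i)
        }
        out
      }, numeric(1), USE.NAMES = FALSE)
      per_alt[[j]] <- tibble::tibble(
        chrom = unname(fix[i, "CHROM"]), pos = pos[i],
        ref = unname(fix[i, "REF"]), alt = unname(alts[j]),
        sample_name = vcf_samples,
        depth = as.integer(depth_i), alt_reads = as.integer(alt_ct)
      )
    }
    recs[[i]] <- dplyr::bind_rows(per_alt)
  }
  calls <- dplyr::bind_rows(recs)
  variants <- dplyr::distinct(calls[KEY_COLS])
  patient_variant_table(pid, variants, calls, samples)
}

#' Read a variant annotation table
#'
#' @param path Tab-separated file with header columns `chrom`, `pos`, `ref`,
#'   `alt`, `gene`, `cosmic_id` (empty cosmic_id allowed). Keys are
#'   normalized identically to VCF reading (1-based, one alt per row).
#' @return A tibble keyed by (chrom, pos, ref, alt); duplicate keys with
#'   conflicting gene raise an error, identical duplicates are collapsed.
#' @export
read_annotation_table <- function(path) {
  ann <- readr::read_tsv(
    path,
    col_types = readr::cols(
      chrom = readr::col_character(), pos = readr::col_integer(),
      ref = readr::col_character(), alt = readr::col_character(),
      gene = readr::col_character(), cosmic_id = readr::col_character()
    ),
    na = c("", "NA")
  )
  ann$gene[is.na(ann$gene)] <- ""
  ann$cosmic_id[is.na(ann$cosmic_id)] <- ""
  ann <- dplyr::distinct(ann)
  dups <- ann |> dplyr::count(dplyr::across(dplyr::all_of(KEY_COLS))) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dups) > 0) {
    stop("conflicting annotation for variant ", dups$chrom[1], ":",
         dups$pos[1], " ", dups$ref[1], ">", dups$alt[1])
  }
  ann
}

#' Read a COSMIC id list
#'
#' @param path Plain-text file, one COSMIC identifier per line (the HNSCC /
#'   upper-aerodigestive-tract subset used for driver rescue).
#' @return Character vector of ids.
#' @export
read_cosmic_list <- function(path) {
  ids <- trimws(readLines(path, warn = FALSE))
  ids[nzchar(ids)]
}

#' Attach annotation and the COSMIC HNSCC flag to a variant table
#'
#' Variants absent from the annotation table keep empty annotation.
#'
#' @param table A [patient_variant_table()].
#' @param annotation Tibble from [read_annotation_table()].
#' @param cosmic_ids Character vector from [read_cosmic_list()].
#' @return The table with `gene`, `cosmic_id` and `in_hnscc_cosmic_subset`
#'   filled in.
#' @export
annotate_variants <- function(table, annotation, cosmic_ids = character()) {
  v <- table$variants[KEY_COLS] |>
    dplyr::left_join(annotation, by = KEY_COLS) |>
    dplyr::mutate(
      gene = ifelse(is.na(.data$gene), "", .data$gene),
      cosmic_id = ifelse(is.na(.data$cosmic_id), "", .data$cosmic_id),
      in_hnscc_cosmic_subset = nzchar(.data$cosmic_id) &
        .data$cosmic_id %in% cosmic_ids
    )
  table$variants <- v
  table
}

#' Write the per-patient variant table to its documented TSV form
#'
#' One long row per (variant, sample): key, annotation, depth, alt reads,
#' vaf. Deterministic row order (chrom, pos, ref, alt, sample_name);
#' re-reading reproduces identical keys and calls.
#'
#' @param table A [patient_variant_table()].
#' @param path Output TSV path.
#' @export
write_patient_table <- function(table, path) {
  out <- dplyr::left_join(table$calls, table$variants, by = KEY_COLS) |>
    dplyr::transmute(
      patient_id = table$patient_id,
      .data$chrom, .data$pos, .data$ref, .data$alt, .data$gene,
      .data$cosmic_id, .data$in_hnscc_cosmic_subset,
      .data$sample_name, .data$depth, .data$alt_reads,
      vaf = .data$vaf
    ) |>
    dplyr::arrange(.data$chrom, .data$pos, .data$ref, .data$alt,
                   .data$sample_name)
  readr::write_tsv(out, path, na = "NA")
  invisible(path)
}

#' @rdname write_patient_table
#' @param sample_sheet Sample sheet covering the patient in the file.
#' @export
read_patient_table <- function(path, sample_sheet) {
  long <- readr::read_tsv(
    path,
    col_types = readr::cols(
      patient_id = readr::col_character(), chrom = readr::col_character(),
      pos = readr::col_integer(), ref = readr::col_character(),
      alt = readr::col_character(), gene = readr::col_character(),
      cosmic_id = readr::col_character(),
      in_hnscc_cosmic_subset = readr::col_logical(),
      sample_name = readr::col_character(), depth = readr::col_integer(),
      alt_reads = readr::col_integer(), vaf = readr::col_double()
    ),
    na = "NA"
  )
  long$gene[is.na(long$gene)] <- ""
  long$cosmic_id[is.na(long$cosmic_id)] <- ""
  pid <- unique(long$patient_id)
  if (length(pid) != 1) stop("file holds more than one patient")
  samples <- sample_sheet[sample_sheet$patient_id == pid, ]
  variants <- dplyr::distinct(
    long[c(KEY_COLS, "gene", "cosmic_id", "in_hnscc_cosmic_subset")]
  )
  patient_variant_table(pid, variants,
                        long[c(KEY_COLS, "sample_name", "depth", "alt_reads")],
                        samples)
}

#' Write analysis result tables
#'
#' Writes each result tibble as a TSV under `outdir`, with deterministic row
#' order (variant-keyed tables are sorted by chrom, pos, ref, alt). Rerunning
#' on identical input yields byte-identical files.
#'
#' @param results Named list of data frames.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(results, outdir) {
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(outdir)) stop("cannot create directory ", outdir)
  }
  paths <- character(0)
  for (nm in names(results)) {
    df <- tibble::as_tibble(results[[nm]])
    sort_cols <- intersect(c("patient_id", KEY_COLS, "sample_name",
                             "timepoint", "gene"), names(df))
    if (length(sort_cols) > 0) {
      df <- dplyr::arrange(df, dplyr::across(dplyr::all_of(sort_cols)))
    }
    p <- file.path(outdir, paste0(nm, ".tsv"))
    readr::write_tsv(df, p, na = "NA")
    paths <- c(paths, p)
  }
  invisible(paths)
}
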