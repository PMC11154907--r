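# Forward simulation of clonal tumours with plasma shedding: spatially
# structured clones (truncal + one private subclone per sub-site), germline
# and CHIP background, Poisson depths with binomial allele sampling, a
# targeted plasma panel, and post-treatment clone dynamics (regrowth of a
# resistant clone, acquired variants). Emits pipeline-ready tables/VCFs and
# a ground-truth table for parameter-recovery tests.

SIM_CLASSES <- c("GERMLINE", "CHIP", "SOMATIC_TRUNCAL",
                 "SOMATIC_CORE_PRIVATE", "SOMATIC_MARGIN_PRIVATE", "ACQUIRED")

#' Simulation configuration
#'
#' Defaults encode the study conditions the analysis assumes: 9 patients of
#' whom 2 have serial post-treatment plasma, mean read depths of 59x for
#' tumour/PBMC and 84x for plasma, a truncal clone at CCF 1 shared by both
#' tumour sub-sites plus one private subclone per sub-site (CCF ~
#' Uniform(0.1, 0.5)), and serial plasma timepoints at roughly 6 weeks, 3
#' months and 12 months after treatment completion. Tumour purity (0.6) and
#' the plasma shedding fraction (0.05) are conventional placeholder values,
#' not derived from any measurement.
#'
#' @param n_patients Number of patients in the cohort.
#' @param n_recurrence Number of patients (the first ones) given serial
#'   post-treatment plasma and a recurrence scenario.
#' @param n_truncal,n_core_private,n_margin_private Somatic variants per
#'   patient on the truncal, core-private and margin-private clones. The
#'   defaults give a true site-exclusivity fraction of 0.7 (14/20).
#' @param truncal_ccf Cancer cell fraction of the truncal clone (1.0).
#' @param ccf_min,ccf_max Range of the per-site private subclone CCFs.
#' @param tumour_purity Tumour cell fraction of the tissue samples, in
#'   (0, 1].
#' @param mean_depth_tumour,mean_depth_plasma,mean_depth_pbmc Poisson mean
#'   read depths.
#' @param shed_fraction Linear scalar mapping mean clone CCF to plasma VAF,
#'   in \[0, 1\].
#' @param n_germline Germline heterozygous/homozygous variants per patient.
#' @param hom_fraction Fraction of germline variants that are homozygous
#'   (true VAF 1.0 rather than 0.5).
#' @param n_chip CHIP variants per patient (present in PBMC and plasma only,
#'   VAF ~ Uniform over `chip_vaf_range`).
#' @param chip_vaf_range Length-2 numeric range of CHIP VAFs.
#' @param cosmic_fraction Fraction of somatic (truncal/private) variants
#'   given an HNSCC-subset COSMIC id.
#' @param resistant_clone In recurrence patients, regrow one randomly chosen
#'   clone post-treatment (its plasma VAF follows
#'   `regrowth_multipliers` x its baseline plasma VAF).
#' @param regrowth_multipliers Named numeric multipliers for timepoints B,
#'   C, D; zeros give dormancy-then-re-emergence patterns.
#' @param n_acquired Acquired variants per recurrence patient (absent from
#'   tumour and baseline, appearing in plasma from `acquired_onset`).
#' @param acquired_onset Timepoint ("B", "C" or "D") at which acquired
#'   variants appear.
#' @param acquired_vaf_range Length-2 numeric range of acquired-variant
#'   plasma VAFs.
#' @param acquired_cosmic Give acquired variants an HNSCC-subset COSMIC id
#'   (default TRUE; recurrence tracking follows oncogenic variants).
#' @param timepoint_days Named integer collection days (relative to
#'   treatment completion) for plasma timepoints A--D; tissue and PBMC
#'   samples share day A (resection, pre-treatment, hence negative).
#' @param recurrence_day Clinical recurrence day for recurrence patients.
#' @param gene_panel Gene interval tibble as [hnscc_gene_panel()].
#' @param plasma_genes Genes covered by the targeted plasma assay; plasma
#'   depth is 0 outside them.
#' @param seed Integer seed; identical configs reproduce identical cohorts.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 9L, n_recurrence = 2L,
                       n_truncal = 6L, n_core_private = 7L,
                       n_margin_private = 7L,
                       truncal_ccf = 1.0, ccf_min = 0.1, ccf_max = 0.5,
                       tumour_purity = 0.6,
                       mean_depth_tumour = 59, mean_depth_plasma = 84,
                       mean_depth_pbmc = 59,
                       shed_fraction = 0.05,
                       n_germline = 30L, hom_fraction = 0.1,
                       n_chip = 5L, chip_vaf_range = c(0.01, 0.1),
                       cosmic_fraction = 0.3,
                       resistant_clone = TRUE,
                       regrowth_multipliers = c(B = 1, C = 4, D = 20),
                       n_acquired = 5L, acquired_onset = "B",
                       acquired_vaf_range = c(0.02, 0.15),
                       acquired_cosmic = TRUE,
                       timepoint_days = c(A = -75L, B = 42L, C = 90L,
                                          D = 365L),
                       recurrence_day = 102L,
                       gene_panel = hnscc_gene_panel(),
                       plasma_genes = plasma_panel_genes(),
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_patients >= 1, cfg$n_recurrence >= 0,
            cfg$n_recurrence <= cfg$n_patients,
            cfg$tumour_purity > 0, cfg$tumour_purity <= 1,
            cfg$shed_fraction >= 0, cfg$shed_fraction <= 1,
            cfg$ccf_min > 0, cfg$ccf_max <= 1, cfg$ccf_min <= cfg$ccf_max,
            cfg$mean_depth_tumour > 0, cfg$mean_depth_plasma > 0,
            cfg$mean_depth_pbmc > 0,
            cfg$cosmic_fraction >= 0, cfg$cosmic_fraction <= 1,
            cfg$hom_fraction >= 0, cfg$hom_fraction <= 1,
            nrow(cfg$gene_panel) > 0,
            cfg$acquired_onset %in% c("B", "C", "D"),
            all(c("A", "B", "C", "D") %in% names(cfg$timepoint_days)))
  structure(cfg, class = "sim_config")
}

# place k variants in a gene's nominal interval with unique positions
place_variants <- function(gene_row, k) {
  pos <- sample(seq(gene_row$start, gene_row$end), k)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, k, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1),
                USE.NAMES = FALSE)
  tibble::tibble(chrom = gene_row$chrom, pos = as.integer(pos),
                 ref = ref, alt = alt, gene = gene_row$gene)
}

# draw variant keys for a class: genes uniform over a panel, positions
# unique within each gene's interval
draw_variants <- function(n, panel, class) {
  if (n == 0) {
    return(tibble::tibble(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          gene = character(), class = character()))
  }
  genes <- sample(panel$gene, n, replace = TRUE)
  out <- lapply(unique(genes), function(g) {
    place_variants(panel[panel$gene == g, ], sum(genes == g))
  })
  dplyr::bind_rows(out) |> dplyr::mutate(class = class)
}

synthetic_cosmic_id <- function(gene, pos) paste0("COSV_", gene, "_", pos)

#' Simulate one patient's baseline samples
#'
#' Generates the patient's variant ground truth and read counts for PBMC,
#' tumour core, tumour margin and baseline plasma (timepoint A). True
#' tumour VAF of a somatic variant in a sub-site is
#' `0.5 * purity * CCF(clone in that sub-site)`; true baseline plasma VAF is
#' `0.5 * shed_fraction * mean(CCF_core, CCF_margin)`. Germline variants
#' have true VAF 0.5 or 1.0 in every sample; CHIP variants a low VAF in
#' PBMC and plasma only. Depths are Poisson (0 for plasma outside the
#' targeted panel), alt reads Binomial(depth, true VAF). Randomness comes
#' from the current R RNG state; callers seed it (see [simulate_cohort()]).
#'
#' @param config A [sim_config()].
#' @param patient_id Patient identifier string.
#' @param recurrence Simulate serial post-treatment plasma (timepoints B--D)
#'   with the configured recurrence scenario.
#' @return List with `table` (a [patient_variant_table()]), `truth` (long
#'   tibble: key, gene, class, cosmic flag, sample_name, true_vaf) and
#'   `resistant_clone` (NA or one of "TRUNCAL", "CORE", "MARGIN").
#' @export
simulate_patient <- function(config, patient_id, recurrence = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  ccf_core <- stats::runif(1, config$ccf_min, config$ccf_max)
  ccf_margin <- stats::runif(1, config$ccf_min, config$ccf_max)

  v <- dplyr::bind_rows(
    draw_variants(config$n_germline, config$gene_panel, "GERMLINE"),
    draw_variants(config$n_chip,
                  config$gene_panel[config$gene_panel$gene %in%
                                      config$plasma_genes, ], "CHIP"),
    draw_variants(config$n_truncal, config$gene_panel, "SOMATIC_TRUNCAL"),
    draw_variants(config$n_core_private, config$gene_panel,
                  "SOMATIC_CORE_PRIVATE"),
    draw_variants(config$n_margin_private, config$gene_panel,
                  "SOMATIC_MARGIN_PRIVATE"),
    if (recurrence) {
      draw_variants(config$n_acquired,
                    config$gene_panel[config$gene_panel$gene %in%
                                        config$plasma_genes, ], "ACQUIRED")
    }
  )
  # duplicate keys across classes are astronomically unlikely but would
  # violate the table contract; drop any repeat
  v <- dplyr::distinct(v, dplyr::across(dplyr::all_of(KEY_COLS)),
                       .keep_all = TRUE)
  n <- nrow(v)

  somatic <- v$class %in% c("SOMATIC_TRUNCAL", "SOMATIC_CORE_PRIVATE",
                            "SOMATIC_MARGIN_PRIVATE")
  v$cosmic <- FALSE
  v$cosmic[somatic] <- stats::runif(sum(somatic)) < config$cosmic_fraction
  v$cosmic[v$class == "ACQUIRED"] <- config$acquired_cosmic

  germ_hom <- stats::runif(n) < config$hom_fraction
  germ_vaf <- ifelse(germ_hom, 1.0, 0.5)
  chip_vaf <- stats::runif(n, config$chip_vaf_range[1],
                           config$chip_vaf_range[2])
  acq_vaf <- stats::runif(n, config$acquired_vaf_range[1],
                          config$acquired_vaf_range[2])

  ccf_site <- function(site) {
    dplyr::case_when(
      v$class == "SOMATIC_TRUNCAL" ~ config$truncal_ccf,
      v$class == "SOMATIC_CORE_PRIVATE" & site == "CORE" ~ ccf_core,
      v$class == "SOMATIC_MARGIN_PRIVATE" & site == "MARGIN" ~ ccf_margin,
      TRUE ~ 0
    )
  }
  mean_ccf <- (ccf_site("CORE") + ccf_site("MARGIN")) / 2

  true_vaf <- list(
    PBMC = ifelse(v$class == "GERMLINE", germ_vaf,
                  ifelse(v$class == "CHIP", chip_vaf, 0)),
    CORE = ifelse(v$class == "GERMLINE", germ_vaf,
                  0.5 * config$tumour_purity * ccf_site("CORE")),
    MARGIN = ifelse(v$class == "GERMLINE", germ_vaf,
                    0.5 * config$tumour_purity * ccf_site("MARGIN")),
    PLASMA_A = ifelse(v$class == "GERMLINE", germ_vaf,
                      ifelse(v$class == "CHIP", chip_vaf,
                             0.5 * config$shed_fraction * mean_ccf))
  )

  resistant <- NA_character_
  if (recurrence) {
    if (!any(somatic)) stop("recurrence scenario needs somatic variants")
    if (config$resistant_clone) {
      resistant <- sample(c("TRUNCAL", "CORE", "MARGIN"), 1)
    }
    serial <- simulate_serial_plasma_vafs(
      config, v$class, true_vaf$PLASMA_A, germ_vaf, chip_vaf, acq_vaf,
      resistant)
    true_vaf <- c(true_vaf, serial)
  }

  day_a <- unname(config$timepoint_days["A"])
  samples <- tibble::tibble(
    patient_id = patient_id,
    sample_name = paste0(patient_id, "_", names(true_vaf)),
    role = ifelse(grepl("^PLASMA", names(true_vaf)), "PLASMA",
                  names(true_vaf)),
    timepoint = ifelse(grepl("^PLASMA", names(true_vaf)),
                       sub("PLASMA_", "", names(true_vaf)), NA_character_),
    collection_day = as.integer(ifelse(
      grepl("^PLASMA", names(true_vaf)),
      config$timepoint_days[sub("PLASMA_", "", names(true_vaf))], day_a)),
    recurrence_day = if (recurrence) as.integer(config$recurrence_day) else
      NA_integer_
  )

  mean_depth <- c(PBMC = config$mean_depth_pbmc,
                  CORE = config$mean_depth_tumour,
                  MARGIN = config$mean_depth_tumour)
  calls <- lapply(names(true_vaf), function(sn) {
    is_plasma <- grepl("^PLASMA", sn)
    md <- if (is_plasma) config$mean_depth_plasma else mean_depth[[sn]]
    depth <- stats::rpois(n, md)
    if (is_plasma) depth[!v$gene %in% config$plasma_genes] <- 0L
    alt_counts <- stats::rbinom(n, depth, pmin(true_vaf[[sn]], 1))
    out <- v[KEY_COLS]
    out$sample_name <- paste0(patient_id, "_", sn)
    out$depth <- as.integer(depth)
    out$alt_reads <- as.integer(alt_counts)
    out
  })

  variants <- v[KEY_COLS] |>
    dplyr::mutate(
      gene = v$gene,
      cosmic_id = ifelse(v$cosmic, synthetic_cosmic_id(v$gene, v$pos), ""),
      in_hnscc_cosmic_subset = v$cosmic
    )
  table <- patient_variant_table(patient_id, variants,
                                 dplyr::bind_rows(calls), samples)

  truth <- dplyr::bind_rows(lapply(names(true_vaf), function(sn) {
    tibble::tibble(patient_id = patient_id, v[KEY_COLS], gene = v$gene,
                   class = v$class, in_hnscc_cosmic_subset = v$cosmic,
                   sample_name = paste0(patient_id, "_", sn),
                   true_vaf = true_vaf[[sn]])
  }))
  list(table = table, truth = truth, resistant_clone = resistant)
}

# per-variant true plasma VAFs for timepoints B-D under the recurrence
# scenario: non-resistant somatic clones fall to 0, the resistant clone
# follows the regrowth multipliers, germline/CHIP persist, acquired
# variants appear from the onset timepoint
simulate_serial_plasma_vafs <- function(config, class, plasma_a_vaf,
                                        germ_vaf, chip_vaf, acq_vaf,
                                        resistant) {
  resistant_class <- switch(
    ifelse(is.na(resistant), "NONE", resistant),
    TRUNCAL = "SOMATIC_TRUNCAL", CORE = "SOMATIC_CORE_PRIVATE",
    MARGIN = "SOMATIC_MARGIN_PRIVATE", NONE = "")
  onset_idx <- match(config$acquired_onset, c("B", "C", "D"))
  out <- list()
  for (i in seq_along(c("B", "C", "D"))) {
    tp <- c("B", "C", "D")[i]
    mult <- unname(config$regrowth_multipliers[tp])
    vaf <- dplyr::case_when(
      class == "GERMLINE" ~ germ_vaf,
      class == "CHIP" ~ chip_vaf,
      class == resistant_class ~ pmin(plasma_a_vaf * mult, 1),
      class == "ACQUIRED" & i >= onset_idx ~ acq_vaf,
      TRUE ~ 0
    )
    out[[paste0("PLASMA_", tp)]] <- vaf
  }
  out
}

#' Extend a baseline patient simulation with serial post-treatment plasma
#'
#' Takes the output of [simulate_patient()] (baseline only) and adds plasma
#' samples B--D under the configured recurrence scenario: somatic clones
#' other than the resistant one disappear from plasma, the resistant clone
#' follows the per-timepoint regrowth multipliers (zeros give
#' dormancy-then-re-emergence), and acquired variants appear from the onset
#' timepoint. New acquired variants get depth-0 calls backfilled in the
#' baseline samples by the table contract.
#'
#' @param config A [sim_config()].
#' @param sim Output of `simulate_patient(config, id, recurrence = FALSE)`.
#' @return A list shaped like [simulate_patient()] output with the serial
#'   plasma samples included.
#' @export
simulate_serial_plasma <- function(config, sim) {
  base <- sim$table
  truth_a <- sim$truth[sim$truth$sample_name ==
                         paste0(base$patient_id, "_PLASMA_A"), ]
  if (nrow(truth_a) == 0) stop("baseline simulation has no plasma A sample")
  somatic <- truth_a$class %in% c("SOMATIC_TRUNCAL", "SOMATIC_CORE_PRIVATE",
                                  "SOMATIC_MARGIN_PRIVATE")
  if (!any(somatic)) stop("recurrence scenario needs somatic variants")

  resistant <- NA_character_
  if (config$resistant_clone) {
    resistant <- sample(c("TRUNCAL", "CORE", "MARGIN"), 1)
  }
  acq <- draw_variants(config$n_acquired,
                       config$gene_panel[config$gene_panel$gene %in%
                                           config$plasma_genes, ],
                       "ACQUIRED")
  acq <- dplyr::anti_join(acq, truth_a[KEY_COLS], by = KEY_COLS)
  n_old <- nrow(truth_a)
  class_all <- c(truth_a$class, acq$class)
  plasma_a_all <- c(truth_a$true_vaf, rep(0, nrow(acq)))
  # germline/CHIP plasma VAFs persist at their baseline values
  germ_all <- ifelse(class_all == "GERMLINE", plasma_a_all, 0)
  chip_all <- ifelse(class_all == "CHIP", plasma_a_all, 0)
  acq_all <- c(rep(0, n_old),
               stats::runif(nrow(acq), config$acquired_vaf_range[1],
                            config$acquired_vaf_range[2]))
  serial <- simulate_serial_plasma_vafs(config, class_all, plasma_a_all,
                                        germ_all, chip_all, acq_all,
                                        resistant)

  keys <- dplyr::bind_rows(truth_a[c(KEY_COLS, "gene")], acq[c(KEY_COLS,
                                                               "gene")])
  cosmic <- c(truth_a$in_hnscc_cosmic_subset,
              rep(config$acquired_cosmic, nrow(acq)))
  pid <- base$patient_id
  new_samples <- tibble::tibble(
    patient_id = pid,
    sample_name = paste0(pid, "_PLASMA_", c("B", "C", "D")),
    role = "PLASMA", timepoint = c("B", "C", "D"),
    collection_day = as.integer(config$timepoint_days[c("B", "C", "D")]),
    recurrence_day = as.integer(config$recurrence_day)
  )
  new_calls <- dplyr::bind_rows(lapply(names(serial), function(sn) {
    depth <- stats::rpois(nrow(keys), config$mean_depth_plasma)
    depth[!keys$gene %in% config$plasma_genes] <- 0L
    alt_counts <- stats::rbinom(nrow(keys), depth, pmin(serial[[sn]], 1))
    out <- keys[KEY_COLS]
    out$sample_name <- paste0(pid, "_", sn)
    out$depth <- as.integer(depth)
    out$alt_reads <- as.integer(alt_counts)
    out
  }))

  variants <- dplyr::bind_rows(
    base$variants,
    acq[KEY_COLS] |> dplyr::mutate(
      gene = acq$gene,
      cosmic_id = ifelse(config$acquired_cosmic,
                         synthetic_cosmic_id(acq$gene, acq$pos), ""),
      in_hnscc_cosmic_subset = config$acquired_cosmic)
  )
  samples <- dplyr::bind_rows(
    base$samples |> dplyr::mutate(recurrence_day =
                                    as.integer(config$recurrence_day)),
    new_samples)
  calls <- dplyr::bind_rows(
    base$calls[c(KEY_COLS, "sample_name", "depth", "alt_reads")], new_calls)
  table <- patient_variant_table(pid, variants, calls, samples)

  new_truth <- dplyr::bind_rows(lapply(names(serial), function(sn) {
    tibble::tibble(patient_id = pid, keys[KEY_COLS], gene = keys$gene,
                   class = class_all, in_hnscc_cosmic_subset = cosmic,
                   sample_name = paste0(pid, "_", sn),
                   true_vaf = serial[[sn]])
  }))
  acq_base_truth <- if (nrow(acq) > 0) {
    dplyr::bind_rows(lapply(c("PBMC", "CORE", "MARGIN", "PLASMA_A"),
                            function(sn) {
      tibble::tibble(patient_id = pid, acq[KEY_COLS], gene = acq$gene,
                     class = "ACQUIRED",
                     in_hnscc_cosmic_subset = config$acquired_cosmic,
                     sample_name = paste0(pid, "_", sn), true_vaf = 0)
    }))
  }
  list(table = table,
       truth = dplyr::bind_rows(sim$truth, acq_base_truth, new_truth),
       resistant_clone = resistant)
}

#' Simulate a full cohort, optionally writing pipeline-ready files
#'
#' Seeds the RNG from `config$seed` and simulates `n_patients` patients (the
#' first `n_recurrence` with serial post-treatment plasma and a recurrence
#' scenario). With `outdir`, writes one VCF per patient plus `samples.tsv`,
#' `annotation.tsv`, `cosmic_hnscc.txt` and `truth.tsv`, all readable by the
#' package's readers without modification; identical configs (including
#' seed) produce byte-identical files.
#'
#' @param config A [sim_config()].
#' @param outdir Optional output directory.
#' @param force Overwrite into a non-empty `outdir`.
#' @return Invisibly, a list: `tables` (named list of
#'   [patient_variant_table()], annotation attached), `truth`,
#'   `sample_sheet`, `annotation`, `cosmic_ids`, `resistant_clones`.
#' @export
simulate_cohort <- function(config = sim_config(), outdir = NULL,
                            force = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(outdir) && dir.exists(outdir) &&
      length(dir(outdir)) > 0 && !force) {
    stop("output directory ", outdir, " is not empty (use force = TRUE)")
  }
  set.seed(config$seed)
  sims <- vector("list", config$n_patients)
  ids <- sprintf("PT%02d", seq_len(config$n_patients))
  for (i in seq_len(config$n_patients)) {
    sims[[i]] <- simulate_patient(config, ids[i],
                                  recurrence = i <= config$n_recurrence)
  }
  names(sims) <- ids

  annotation <- dplyr::bind_rows(lapply(sims, function(s) {
    s$table$variants[c(KEY_COLS, "gene", "cosmic_id")]
  })) |>
    dplyr::distinct(dplyr::across(dplyr::all_of(KEY_COLS)),
                    .keep_all = TRUE) |>
    dplyr::arrange(.data$chrom, .data$pos, .data$ref, .data$alt)
  cosmic_ids <- sort(unique(unlist(lapply(sims, function(s) {
    s$table$variants$cosmic_id[s$table$variants$in_hnscc_cosmic_subset]
  }))))
  sample_sheet <- dplyr::bind_rows(lapply(sims, function(s) s$table$samples))
  truth <- dplyr::bind_rows(lapply(sims, function(s) s$truth))
  out <- list(
    tables = lapply(sims, function(s) s$table),
    truth = truth, sample_sheet = sample_sheet, annotation = annotation,
    cosmic_ids = cosmic_ids,
    resistant_clones = vapply(sims, function(s) s$resistant_clone,
                              character(1))
  )

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (id in ids) {
      write_patient_vcf(out$tables[[id]],
                        file.path(outdir, paste0(id, ".vcf")))
    }
    readr::write_tsv(sample_sheet, file.path(outdir, "samples.tsv"),
                     na = "")
    readr::write_tsv(annotation, file.path(outdir, "annotation.tsv"),
                     na = "")
    writeLines(cosmic_ids, file.path(outdir, "cosmic_hnscc.txt"))
    readr::write_tsv(
      dplyr::arrange(truth, .data$patient_id, .data$chrom, .data$pos,
                     .data$ref, .data$alt, .data$sample_name),
      file.path(outdir, "truth.tsv"), na = "NA")
  }
  invisible(out)
}

#' Write a patient variant table as a multi-sample VCF
#'
#' Emits a minimal VCF 4.2 file with per-sample `GT:DP:AD` fields
#' (`AD` as `ref_count,alt_count`), one biallelic record per variant,
#' readable back via [read_multisample_vcf()].
#'
#' @param table A [patient_variant_table()].
#' @param path Output path.
#' @export
write_patient_vcf <- function(table, path) {
  samples <- table$samples$sample_name
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=ctdnaITH_simulator",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,Description=",
           "\"Allelic depths (ref,alt)\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  v <- table$variants
  calls <- table$calls
  lines <- character(nrow(v))
  for (i in seq_len(nrow(v))) {
    vc <- calls[calls$chrom == v$chrom[i] & calls$pos == v$pos[i] &
                  calls$ref == v$ref[i] & calls$alt == v$alt[i], ]
    vc <- vc[match(samples, vc$sample_name), ]
    gt <- sprintf("./.:%d:%d,%d", vc$depth, vc$depth - vc$alt_reads,
                  vc$alt_reads)
    lines[i] <- paste(c(v$chrom[i], v$pos[i], ".", v$ref[i], v$alt[i], ".",
                        "PASS", ".", "GT:DP:AD", gt), collapse = "\t")
  }
  writeLines(c(header, lines), path)
  invisible(path)
}
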