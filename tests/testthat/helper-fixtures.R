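# In-code fixtures: tiny patient tables, presence matrices and VCF text
# built programmatically, so tests carry no binary data.

default_samples <- function(patient_id = "P1", plasma = c("A", "B", "C"),
                            recurrence_day = NA_integer_) {
  days <- c(A = -75L, B = 42L, C = 90L, D = 365L)
  tibble::tibble(
    patient_id = patient_id,
    sample_name = c("PBMC", "CORE", "MARGIN", paste0("PLASMA_", plasma)),
    role = c("PBMC", "CORE", "MARGIN", rep("PLASMA", length(plasma))),
    timepoint = c(NA, NA, NA, plasma),
    collection_day = c(-75L, -75L, -75L, unname(days[plasma])),
    recurrence_day = recurrence_day
  )
}

# calls: tibble(chrom, pos, ref, alt, sample_name, depth, alt_reads);
# omitted (variant, sample) pairs become depth-0 calls
mk_table <- function(calls, patient_id = "P1", samples = NULL,
                     cosmic_keys = NULL, genes = NULL) {
  if (is.null(samples)) samples <- default_samples(patient_id)
  variants <- dplyr::distinct(calls[, c("chrom", "pos", "ref", "alt")])
  if (!is.null(genes)) {
    variants$gene <- genes[seq_len(nrow(variants))]
  }
  if (!is.null(cosmic_keys)) {
    id <- paste(variants$chrom, variants$pos, variants$ref, variants$alt)
    variants$cosmic_id <- ifelse(id %in% cosmic_keys, paste0("COSV", id), "")
    variants$in_hnscc_cosmic_subset <- id %in% cosmic_keys
  }
  patient_variant_table(patient_id, variants, calls, samples)
}

# shorthand for one variant row across samples:
# vcall("chr1", 100, sample = "CORE", depth = 50, alt = 10)
vcall <- function(chrom, pos, sample, depth, alt, ref = "A", altbase = "T") {
  n_alt <- as.integer(alt)   # the `alt` column below would shadow the arg
  tibble::tibble(chrom = chrom, pos = as.integer(pos), ref = ref,
                 alt = altbase, sample_name = sample,
                 depth = as.integer(depth), alt_reads = n_alt)
}

# presence matrix row built directly, bypassing the filter
prow <- function(pos, sample, role, present, vaf = 0.1, timepoint = NA,
                 day = 0L, chrom = "chr1", ref = "A", alt = "T") {
  tibble::tibble(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
                 sample_name = sample, role = role,
                 timepoint = as.character(timepoint),
                 collection_day = as.integer(day),
                 depth = 100L, alt_reads = as.integer(round(vaf * 100)),
                 vaf = vaf, present = present)
}

write_test_vcf <- function(lines, path = tempfile(fileext = ".vcf"),
                           samples = c("S_PBMC", "S_CORE")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(header, lines), path)
  path
}

test_sheet <- function(samples = c("S_PBMC", "S_CORE"),
                       roles = c("PBMC", "CORE"),
                       patient_id = "S") {
  tibble::tibble(
    patient_id = patient_id, sample_name = samples, role = roles,
    timepoint = ifelse(roles == "PLASMA", "A", NA_character_),
    collection_day = ifelse(roles == "PLASMA", 0L, -10L),
    recurrence_day = NA_integer_
  )
}

# randomized cascade input whose depths and VAFs straddle every rule
# boundary (20x PBMC coverage, 10%/20% VAF, 4/10 supporting reads)
random_cascade_table <- function(n, seed) {
  set.seed(seed)
  depth <- function(k) sample(0:40, k, replace = TRUE)
  mk <- function(sample, k) {
    d <- depth(k)
    a <- vapply(d, function(di) {
      if (di == 0) 0L else as.integer(min(di, stats::rbinom(
        1, di, sample(c(0, 0.05, 0.08, 0.1, 0.12, 0.2, 0.25, 0.5), 1))))
    }, integer(1))
    tibble::tibble(chrom = "chr1", pos = seq_len(k), ref = "A", alt = "T",
                   sample_name = sample, depth = d, alt_reads = a)
  }
  calls <- dplyr::bind_rows(mk("PBMC", n), mk("CORE", n), mk("MARGIN", n),
                            mk("PLASMA_A", n))
  cosmic <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.2, 0.8))
  mk_table(calls, cosmic_keys = paste("chr1", which(cosmic), "A", "T"))
}
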