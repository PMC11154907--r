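# Independent brute-force evaluator of the somatic selection rules, written
# directly from their prose definition one variant at a time. Used as the
# oracle against the vectorised cascade; kept deliberately naive.

oracle_filter_one <- function(pbmc_depth, pbmc_alt, other_depth, other_alt,
                              cosmic, th = filter_thresholds()) {
  pbmc_vaf <- if (pbmc_depth > 0) pbmc_alt / pbmc_depth else NA_real_
  other_vaf <- ifelse(other_depth > 0, other_alt / other_depth, NA_real_)
  removed <- ""
  if (pbmc_depth >= th$germline_min_depth && !is.na(pbmc_vaf) &&
      pbmc_vaf > th$germline_af_max) {
    removed <- "REMOVED_GERMLINE"
  } else if (length(other_alt) == 0 ||
             max(other_alt) < th$min_supporting_reads) {
    removed <- "REMOVED_LOW_SUPPORT"
  } else if (pbmc_depth < th$germline_min_depth &&
             !any(!is.na(other_vaf) & other_vaf > th$lowcov_af_min &
                    other_alt >= th$lowcov_min_reads)) {
    removed <- "REMOVED_LOWCOV_PBMC"
  }
  if (removed == "") "RETAINED" else if (cosmic) "RESCUED_COSMIC" else removed
}
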