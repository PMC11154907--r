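---
title: "Models and design choices behind the ctdnaITH pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices behind the ctdnaITH pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctdnaITH)
```

## What the pipeline computes

ctdnaITH analyses per-patient multi-sample variant calls from an HNSCC
study design with four sample roles: a PBMC germline control, two tumour
sub-sites (core and advancing margin, sampled at resection), and serial
plasma cell-free DNA at up to four timepoints (A at resection, B/C/D at
roughly 6 weeks, 3 months and 12 months after treatment completion). Four
quantities are derived: a per-variant somatic/germline decision with audit
trail, the spatial exclusivity of somatic variants between the two tumour
sub-sites, the concordance of baseline ctDNA with the tumour variant sets,
and baseline-vs-acquired dynamics across post-treatment plasma.

## The somatic selection cascade

Variant selection is rule-based, per patient, in a fixed order:

* **R1 — germline removal.** PBMC depth ≥ 20 and PBMC VAF > 10% marks a
  variant germline (or CHIP). Both cuts mirror their published wording:
  the VAF cut is strict (">10%"), the coverage cut inclusive ("at least
  20-fold").
* **R2 — minimum evidence.** A surviving variant needs ≥ 4 alt-supporting
  reads in at least one non-PBMC sample. The source phrasing ("variants in
  this selection were initially restored if 4 or more supporting reads
  were detected") is ambiguous about whether the *removed* set is restored
  or the *kept* set is gated; we implement the gate, because restoring
  removed germline variants on read support alone would re-admit
  essentially every germline variant (they have abundant support in tumour
  samples too) and the cascade would no longer yield a somatic set. The
  alternative reading remains available via
  `apply_filter_cascade(..., germline_rescue_by_reads = TRUE)`.
* **R3 — untestable germline.** When PBMC coverage is below 20×, germline
  status cannot be excluded; the variant is kept only with strong somatic
  evidence (some non-PBMC sample at VAF > 20% with ≥ 10 reads).
* **R4 — COSMIC rescue.** Any removed variant carrying a COSMIC id from
  the upper-aerodigestive-tract (HNSCC) subset is restored to candidacy.
  Rescue restores candidacy, not presence: the 0.1% floor below still
  applies per sample, keeping the floor universal.

PBMC reads never count toward R2/R3 support — rescuing on germline
evidence would defeat the subtraction. After selection, a variant is
*present* in a tumour or plasma sample iff it has ≥ 1 alt read at non-zero
depth with VAF ≥ 0.1% (inclusive). A depth-0 call is treated as "absent,
untestable" everywhere, since its VAF is undefined. Whether the 0.1% floor
also applies to PBMC is unstated in the source; we apply it to tumour and
plasma only, following its wording ("in both tumour and plasma samples").

All thresholds live in `filter_thresholds()` (YAML-configurable via
`read_filter_config()`); defaults are the published values.

## Spatial heterogeneity

A tumour-present variant is core-only, margin-only, or shared; the
heterogeneity (ITH) rate is the exclusive fraction. Choices worth noting:

* Plasma-only variants are excluded from every spatial denominator.
* Cohort summaries are unweighted means over per-patient proportions with
  min–max ranges, not variant-pooled proportions — matching how
  multi-patient exclusivity is conventionally reported ("mean … (range
  …)"). Both conventions differ when patients contribute unequal variant
  counts; the per-patient mean is primary throughout.
* Per-gene summaries average per-patient exclusivity over patients with at
  least one tumour-present variant in that gene; patients without such
  variants are excluded from that gene's mean rather than counted as zero.
* Undefined proportions (no tumour-present variants in scope) propagate as
  `NA`, never as 0.
* The group comparison is a two-sided unpaired Student t-test (equal
  variance), since the source specifies an "unpaired t-test" with no
  variance caveat; Welch's correction is available via `welch = TRUE`.
  Zero-variance degenerate inputs (identical constant groups, complete
  separation) are answered with p = 1 and p = 0 respectively rather than
  an error.
* The "high frequency" set uses a strict VAF > 5% cut in at least one
  sub-site — an arbitrary but conventional proxy for clonal status in the
  absence of formal clonality analysis, which this package deliberately
  does not attempt.

## ctDNA concordance

The tumour set is the union of core- and margin-present variants; the
plasma set is baseline (timepoint A) presence. Because the plasma assay is
a targeted 9-gene panel (*TP53, NOTCH1, PIK3CA, KMT2D, CDKN2A, CASP8,
NSD1, FAT1, FBXW7*), tumour variants outside those genes are invisible to
it and are excluded from denominators by default (`panel_genes = NULL`
disables this); the universe is further restricted to HNSCC COSMIC
variants by default (`cosmic_only = FALSE` disables). Rates with zero
denominators are `NA` and are excluded from cohort means. Leave-one-out
cohort means are available to quantify outlier influence.

## Temporal tracking

*Baseline* means present in the resected primary tumour (either sub-site);
*acquired* means absent from both sub-sites but present in ≥ 1
post-treatment plasma sample (B–D). Acquisition is defined against the
primary tumour only, so baseline-plasma membership does not block it; a
strict mode additionally requiring absence at A exists
(`strict_acquired = TRUE`). Variants seen only in baseline plasma get
neither label and are reported as `PLASMA_A_ONLY` — their origin (missed
spatial heterogeneity vs blood-derived background) cannot be resolved by a
two-site design. Molecular recurrence is the earliest post-treatment
collection day with ≥ 1 qualifying variant present; timepoint A never
triggers it. Qualifying variants default to the HNSCC COSMIC subset, since
recurrence tracking follows oncogenic variants. All days are integers
relative to treatment completion, taken from the sample sheet; no calendar
parsing is attempted.

## The simulator: what it emulates, and what it does not

`simulate_cohort()` generates cohorts with the statistical structure the
analysis assumes:

* **Clonal geometry.** One truncal clone at CCF 1.0 present in both
  sub-sites, plus exactly one private subclone per sub-site with CCF ~
  Uniform(0.1, 0.5). The default 6 truncal + 7 + 7 private variants give a
  true site-exclusivity fraction of 0.7. General multi-region clone trees
  are out of scope.
* **Read model.** True sub-site VAF = 0.5 × purity × CCF; depths are
  Poisson (59× tumour/PBMC, 84× plasma, matching the study's reported
  means), alt reads Binomial(depth, VAF) — the minimal model under which
  the VAF thresholds have calibratable sampling error.
* **Plasma.** Baseline plasma VAF = 0.5 × shed_fraction × mean sub-site
  CCF, a simple linear shedding scalar: the analysis only needs ordering
  and monotonicity in tumour burden, not a biophysical shedding model.
  Plasma depth is 0 outside the 9 panel genes, emulating the targeted
  assay.
* **Background.** Germline variants at true VAF 0.5/1.0 in every sample;
  CHIP variants at VAF ~ Uniform(0.01, 0.1) in PBMC and plasma only, so
  the germline/CHIP subtraction path is exercised.
* **Post-treatment dynamics.** Non-resistant clones vanish from plasma
  after treatment; one randomly chosen resistant clone follows
  per-timepoint regrowth multipliers (zeros give
  dormancy-then-re-emergence); acquired variants appear from a
  configurable onset timepoint at VAF ~ Uniform(0.02, 0.15). Acquired
  variants carry HNSCC COSMIC ids by default, matching how post-treatment
  surveillance tracks oncogenic variants.
* **Placement.** Variant positions are drawn uniformly within nominal
  per-gene intervals (approximate hg38 starts, synthetic widths); no
  reference genome or sequence context is simulated.

Purity (0.6) and shedding fraction (0.05) are conventional placeholder
values — the study reports neither — and are *not* derived from data.

Features of real data the simulator does not model: sequencing error and
UMI consensus artefacts, copy-number alterations (so true VAFs never
exceed the diploid heterozygous expectation), unsampled spatial clones
shedding into plasma, and fragment-level ctDNA features. Two consequences
matter for interpreting green tests. First, the simulated ctDNA-only
fraction is structurally near zero (plasma sheds only from the two sampled
sub-sites and CHIP variants are non-COSMIC), whereas real cohorts report
large ctDNA-only fractions attributed to unsampled heterogeneity — passing
recovery tests therefore says nothing about that phenomenon. Second,
absence of false positives means detection-rate recovery here bounds only
sensitivity behaviour, not specificity.

## Numerical and testing choices

* Problem sizes: recovery tests use 50-patient cohorts (20 for the
  temporal suite) at the default depths, and depth 500 where the test
  isolates estimator bias from sampling noise; these sizes give binomial
  standard errors well inside the asserted tolerances.
* Determinism: all randomness flows from the single config seed through
  R's RNG in a fixed patient/sample order, so identical configs reproduce
  byte-identical cohort files and result tables.
* The filter cascade is validated against an independently written
  brute-force evaluator (one variant at a time, straight from the prose
  rules) on randomized records straddling every rule boundary.
* Ties/boundaries follow the wording: strict for ">10%", ">20%", ">5%";
  inclusive for "4 or more", "10 or more", "at least 20-fold", and the
  0.1% floor.
* Known limitations: per-variant rule evaluation is an R loop (adequate at
  panel scale, not exome-cohort scale); indels are accepted by the format
  contract but untested beyond SNVs; and multi-allelic records are split
  but never left-normalized — input is assumed normalized upstream.
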