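# ctdnaITH

Downstream analysis of multi-region tumour and serial plasma sequencing in
head and neck squamous cell carcinoma (HNSCC), for researchers quantifying
how spatial intra-tumoural heterogeneity (ITH) shows up in circulating
tumour DNA (ctDNA) and how serial liquid biopsies track disease after
treatment.

The pipeline starts from called, annotated variants (one multi-sample VCF
per patient covering a PBMC germline control, tumour core, tumour advancing
margin, and 1–4 plasma timepoints) and runs four stages:

1. **Somatic selection** (`apply_filter_cascade`): per patient, variants are
   removed as germline/CHIP when the PBMC control shows alternate allele
   frequency > 10% at ≥ 20× coverage; candidates need ≥ 4 supporting reads
   in some non-PBMC sample; sites with < 20× PBMC coverage are kept only
   with a non-PBMC sample at VAF > 20% and ≥ 10 reads; variants removed by
   any rule are restored if they carry a known HNSCC COSMIC id. A universal
   presence floor of VAF ≥ 0.1% then applies per tumour/plasma sample.
   Every variant keeps a full audit trail of the rules evaluated.
2. **Spatial ITH** (`classify_spatial`, `heterogeneity_summary`): each
   selected variant is core-only, margin-only, shared, or not-in-tumour;
   the heterogeneity rate is the fraction of tumour-present variants
   exclusive to one sub-site, summarised per gene, per patient, and as
   unweighted cohort means with ranges. Core vs margin exclusivity is
   compared with an unpaired Student t-test (`compare_exclusivity`).
3. **ctDNA concordance** (`concordance`): over the 9-gene targeted plasma
   panel and the HNSCC COSMIC subset, the fraction of tumour variants
   detected in baseline plasma — over all tumour variants and over
   high-frequency ones (tumour VAF > 5%, a crude clonality proxy) — plus
   the sub-site exclusivity of detected variants and the ctDNA-only
   fraction.
4. **Temporal tracking** (`label_variants`, `molecular_recurrence`):
   variants present in the resected tumour are *baseline*; variants absent
   from both sub-sites but seen in post-treatment plasma are *acquired*.
   Serial VAF trajectories flag persistence, loss and re-emergence, and the
   earliest variant-positive post-treatment sample defines the molecular
   lead time over clinical recurrence.

Because the underlying patient-level sequencing data are not public, the
package ships a forward simulator (`sim_config`, `simulate_cohort`) of
clonal tumours — truncal clone shared by both sub-sites, one private
subclone per sub-site, germline/CHIP background, Poisson depths (59× tumour,
84× plasma) with binomial allele sampling, linear plasma shedding, and
post-treatment clone dynamics — that emits pipeline-ready VCFs plus a
ground-truth table, so every stage is testable by parameter recovery.

## Worked example

The `analysis/` scripts run the whole study on a simulated cohort:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_filter_variants.R
Rscript analysis/03_spatial_heterogeneity.R
Rscript analysis/04_ctdna_concordance.R
Rscript analysis/05_temporal_tracking.R
```

which prints, among other things:

```
filter outcomes across 9 patients:
   REMOVED_GERMLINE REMOVED_LOW_SUPPORT      RESCUED_COSMIC            RETAINED
                275                  47                  18                 165
cohort heterogeneity rate (all variants): 63.9% (range 60.0-70.0%)
ctDNA detected 44.3% of tumour variants (range 0.0-100.0%)
patient PT01: molecular detection day 42, clinical recurrence day 102, lead time 60 days
```

Reading: of 505 simulated variants, the cascade removed 275 as germline and
47 for lack of read support, rescued 18 via HNSCC COSMIC ids, and retained
165 as somatic candidates. At 59× tumour depth the estimated cohort
heterogeneity rate is 63.9% against a configured true site-exclusivity of
70% — low-CCF private variants drop below the evidence threshold, which is
exactly the depth-driven bias the simulator exists to expose. Baseline
plasma detected 44.3% of panel-covered COSMIC tumour variants, and in both
recurrence patients the first variant-positive post-treatment sample (day
42) preceded clinical recurrence (day 102) by 60 days. Result tables land
under `results/`.

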