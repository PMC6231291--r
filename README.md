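# tcrrecon

Quantitative analysis of T cell receptor (TCR) repertoires during immune
reconstitution after haematopoietic stem cell transplantation — the
analysis layer that turns UMI-corrected clonotype tables (AIRR
rearrangement TSV or Decombinator-style frequency files) into clinically
interpretable summaries.

For clinicians and analysts monitoring post-transplant T cell recovery,
the package provides:

* **Diversity metrics** — the Gini coefficient of the clone-size Lorenz
  curve, *G* = Σᵢ (2i − n − 1) x₍ᵢ₎ / (n Σ xᵢ) over ascending counts
  (0 = completely equal, → 1 = oligoclonal), and Shannon entropy
  *H* = −Σᵢ pᵢ log₂ pᵢ in bits, plus top-k clonotype fractions.
* **Minimum representative subsampling depth** — replicate rarefaction
  (default 30 subsamples per 1% depth step, multivariate hypergeometric,
  seeded) of the normalized Gini coefficient; depths where the decline
  gradient exceeds 1.1 (10% steeper than linear) are grouped into runs of
  consecutive percents, and the lowest run's largest percent + 1 marks
  the sample's representativeness floor. A cohort-level optimizer then
  picks the common depth that maximizes the number of samples whose
  [floor, total] interval contains it.
* **Virtual spectratypes** — per-TRBV-family CDR3 nucleotide-length
  histograms with peak counts and a Gaussian-shape score, classified into
  the clinical groups Abnormal / Almost_normal / Normal.
* **Clonotype dynamics** — longitudinal tracking of each timepoint's top
  clonotypes with persistence flags, and exact-match annotation against
  VDJdb-format tables summarized as per-species *antigen binding
  potential*.
* **A synthetic-repertoire simulator** — heavy-tailed clone-size
  distributions spanning control-cord-like to clonally expanded
  repertoires, per-family length models (Gaussian vs spiked), calibration
  to a target Gini, and longitudinal series with persistent clones — so
  the whole pipeline is testable without patient data.

See `vignette("tcr-reconstitution-methods")` for the underlying models,
conventions and design decisions.

## Worked example

The package ships a miniature simulated cohort (1200 reads per sample):
one patient sampled at months 1 and 12 post-transplant and a cord-blood
control, plus a small synthetic VDJdb-style annotation table.

```r
library(tcrrecon)

path <- function(f) system.file("extdata", f, package = "tcrrecon")
m1   <- read_clonotype_table(path("patient1_month1_airr.tsv"), "airr",
                             sample_id = "patient1_m1",
                             patient_id = "patient1", month_post_tx = 1)
m12  <- read_clonotype_table(path("patient1_month12_airr.tsv"), "airr",
                             sample_id = "patient1_m12",
                             patient_id = "patient1", month_post_tx = 12)
cord <- read_clonotype_table(path("cord_control_airr.tsv"), "airr",
                             sample_id = "cord_control",
                             group = "control_cord")

diversity_summary(m1)
#> <diversity_summary> patient1_m1
#>   Gini 0.4526   Shannon 5.108 bits   richness 63   reads 1200
#>   top-20 clonotypes: 63.9% of reads
diversity_summary(cord)
#> <diversity_summary> cord_control
#>   Gini 0.3113   Shannon 8.171 bits   richness 338   reads 1200
#>   top-20 clonotypes: 14.7% of reads
```

The month-1 sample is strongly oligoclonal — half the inequality scale,
with 20 clonotypes holding 64% of all reads — while the control spreads
its reads across 338 clonotypes. (At this miniature depth the control's
Gini sits above the ~0.2 seen in full-size control repertoires purely
through sampling noise; diversity comparisons are depth-bound, which is
exactly why the subsampling-depth machinery exists.)

```r
cfg    <- rarefaction_config(master_seed = 1)          # 30 replicates, 1..100%
curves <- lapply(list(m1, m12, cord), rarefaction_curve, config = cfg)
depths <- lapply(curves, minimum_representative_depth, config = cfg)
depths[[1]]
#> <min_depth_result> patient1_m1
#>   qualifying runs: 1-8; 10-10; 13-14; 17-17; 29-29; 33-33; 36-36; 47-47; 51-51; 69-69
#>   minimum representative depth: 9% = 108 of 1200 reads
cohort_common_depth(depths)
#> <cohort_depth_result> common depth 1200 reads; 3 sample(s) included
```

Steep normalized-Gini decline below 9% of reads marks where this sample
stops being representative; all three samples' intervals admit the full
1200 reads, so nothing needs excluding.

```r
classify_spectratype(cdr3_length_distribution(m1))
#> <spectratype_profile> patient1_m1: 19 V families, 11 length bins
#>   classification: Abnormal (median peaks 3.0, Gaussian fraction 0.42)

db <- read_vdjdb_table(path("vdjdb_synthetic.tsv"))
annotate_vdjdb(m1, db)
#> <annotation_result> patient1_m1 (policy cdr3_aa+v): 3 hit(s)
#>   CMV: binding potential 0.1400 (14.00% of reads)
#>   EBV: binding potential 0.1400 (14.00% of reads)
#>   HIV-1: binding potential 0.1342 (13.42% of reads)

tr <- track_clonotypes(list(m1, m12), n = 5)
head(tr[, c("month", "frequency", "persistent")], 2)
#>   month  frequency persistent
#> 1     1 0.12416667       TRUE
#> 2    12 0.01666667       TRUE
```

A clone holding 12.4% of the month-1 repertoire persists to month 12 at
1.7% — the contraction of an early expansion as the repertoire
diversifies. `run_cohort_analysis(cohort_config(...))` chains all stages
and writes one TSV per product plus a `run.log`; the thin CLI wrapper in
`inst/scripts/tcrrecon.R` exposes the same operations per-file
(`diversity`, `mindepth`, `subsample`, `spectratype`, `annotate`,
`simulate`).

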