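---
title: "Methods: quantitative TCR repertoire analysis for immune reconstitution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative TCR repertoire analysis for immune reconstitution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrrecon)
```

## The problem

After haematopoietic stem cell transplantation — in particular cord blood
transplantation in children — the T cell compartment rebuilds itself from a
small, often clonally skewed starting pool. Clinically this recovery has
long been monitored by CDR3 spectratyping: per-V-beta-family length
profiles whose multi-peak Gaussian shape indicates a polyclonal repertoire
and whose collapse into a few spikes indicates oligoclonality. Deep
sequencing of TCR rearrangements replaces those length profiles with full
clonotype tables — every (V gene, J gene, CDR3 nucleotide junction)
rearrangement with a UMI-corrected molecule count — and so admits proper
quantitative summaries: inequality and entropy of the clone-size
distribution, principled subsampling, clone-level tracking over time, and
database annotation.

`tcrrecon` implements that analysis layer. It consumes clonotype tables
(AIRR rearrangement TSV or Decombinator-style frequency files), not raw
reads; demultiplexing, UMI correction and V/J assignment are upstream
tools' jobs.

## Data model

A *clonotype* is keyed by `(v_call, j_call, cdr3_nt)` — nucleotide-level
identity, since that is what a UMI-corrected read distinguishes; for the
Decombinator dialect, which carries deletion counts and an insert instead
of the full junction, the deletions join the key. Duplicate keys are
merged by summing counts, zero-count rows are dropped with a warning, and
negative or fractional counts are an error. Frequencies are computed over
reads (`count / total_reads`), not over unique clonotypes, so the most
abundant 20 clonotypes can be read directly as a percentage of all
molecules. Amino-acid junctions, where present and in frame, must equal
the translation of the nucleotide junction; out-of-frame rearrangements
simply have no `cdr3_aa` and are retained (they still carry diversity
information; amino-acid-level operations skip them and say so).

## Diversity metrics

Two statistics summarize a clone-size vector $x_1,\dots,x_n$ with
$p_i = x_i / \sum_j x_j$:

* **Gini coefficient** — twice the area between the 45° line and the
  Lorenz curve of cumulative clone share versus cumulative read share,
  computed with the discrete estimator
  $G = \sum_i (2i - n - 1)\,x_{(i)} \big/ (n \sum_i x_i)$ over ascending
  counts. No small-sample correction (no $n/(n-1)$ factor) is applied:
  the uncorrected form is the literal Lorenz-area definition and returns
  exactly 0 for completely equal counts, which is the anchor case for the
  scale (0 = completely equal, values toward 1 = oligoclonal).
* **Shannon entropy** — $H = -\sum_i p_i \log_2 p_i$, reported in bits
  everywhere. Base 2 is fixed by convention here so that a repertoire of
  $2^k$ equal clonotypes scores exactly $k$ bits.

A monoclonal sample returns 0 for both with a `degenerate` attribute:
inequality *between* clonotypes is undefined for one clonotype, and the
flag keeps a 0 from being misread as "maximally even". Both metrics are
permutation- and scale-invariant, and the test suite checks them against
an independent trapezoid Lorenz-area oracle and direct summation (plus
`vegan`'s entropy as an external cross-check).

## Minimum representative subsampling depth

Comparing diversity across samples of different depth requires rarefying
to a common depth — but rarefying too deep destroys the signal it is
meant to preserve. The package therefore estimates, per sample, the
smallest depth at which the sample remains representative:

1. For each percent $p = 1,\dots,100$ of the sample's reads, draw
   `replicates` (default 30) independent subsamples *without replacement*
   (multivariate hypergeometric draws from the read population — each
   clonotype contributes `count` indistinguishable reads), compute Gini
   and Shannon, normalize to the full-depth values, and record the
   replicate mean and standard error. At 100% the subsample is the sample
   itself, so the normalized means are exactly 1 with zero SE.
2. Compute the gradient of the mean normalized Gini decline. Several
   conventions are deliberately pinned down here because they are easy to
   get inconsistently wrong: depth is expressed as a *fraction* in
   $[0,1]$, the finite difference is the forward difference on the 1%
   grid, $(g(p{+}1) - g(p))/0.01$, and the decline is traversed toward
   low depth. On this scale a perfectly linear depreciation from $(0,0)$
   to $(1,1)$ has gradient exactly 1, so the default threshold 1.1 reads
   as "at least 10% steeper than linear" — steep enough to ignore minor
   replicate noise.
3. Percents whose gradient exceeds the threshold are grouped into maximal
   runs of consecutive integers. The run containing the smallest percents
   is taken to mark the regime where low-frequency clonotypes collapse
   into the top clones, and the minimum representative percent is that
   run's largest member **plus one** — a qualifying run ending at 20%
   yields 21%. If no gradient qualifies, the sample is representative at
   any depth and the floor is 1%: the algorithm only ever *raises* the
   floor on evidence of distortion.
4. Percents convert to reads by the ceiling, so the chosen depth never
   falls below the floor; the result is capped at the sample's own total.

A genuine empirical subtlety, found while validating the package and
worth knowing when reading curves: the mean *normalized* Gini is not
weakly monotone over the whole depth range. Between roughly 60% and 100%
depth the subsampled Gini carries a small upward bias (dropping rare
singletons first makes the remaining distribution look slightly *more*
unequal), so the normalized curve can overshoot 1 by about 1% before the
true decline takes over at lower depths. The tests assert strict decline
only in the low-depth regime and bound the overshoot; the depth algorithm
is unaffected, since it reacts to large positive gradients, which the
flat overshoot region does not produce.

Samples whose full-depth Gini or Shannon is 0 cannot be normalized; their
curves are flagged degenerate and the depth algorithm refuses them
explicitly rather than emitting a misleading floor.

### Cohort common depth

Across a cohort, each sample contributes an inclusion interval
`[min_depth_reads, total_reads]`. The common depth is the read count $D$
contained in the largest number of intervals. Because the inclusion count
only changes at interval endpoints, the search is restricted to the
endpoint set (verified against exhaustive integer search in the tests);
ties are broken toward the **largest** $D$, which retains the most reads
per included sample at equal inclusion. The optimizer works in absolute
reads, not percents, since a common depth must be a single read count.
Samples whose totals fall below the chosen depth are excluded from
rarefied comparisons rather than analyzed at full depth — the optimizer
already traded their inclusion away, and silently mixing depths would
reintroduce exactly the bias the procedure exists to remove.

### Reproducibility

Every replicate draw derives its own child seed from the master seed and
the (percent, replicate) indices through a fixed integer hash, so curves
are bit-identical across runs and independent of evaluation order, and
the C++ sampling kernel uses R's own RNG stream under that seed.

## Virtual spectratypes

The spectratype analogue is reconstructed directly from sequence: the
histogram of nucleotide junction lengths weighted by read frequency,
overall and per TRBV family (family = IMGT label truncated before the
gene-member/allele suffix, e.g. `TRBV5-1*01` → `TRBV5`). Nucleotide
rather than amino-acid lengths are used because classical spectratyping
resolves nucleotides; in-frame repertoires then show the familiar 3-nt
comb. A *peak* is a length bin holding more than a configurable floor
(default 1%) of its family's mass.

Gaussian shape is scored as $1 - \mathrm{L1}/2$ between the normalized
histogram and a Gaussian fitted by the histogram's own frequency-weighted
mean and SD, discretized on the histogram's length lattice (lattice step
= gcd of the observed spacings, so 3-nt combs are compared comb-to-comb
instead of being penalized for their gaps). The score is bounded in
$[0,1]$, 1 for identical shapes, 0 for disjoint ones; a single-length
family has no shape and scores 0 with a degeneracy flag. A shape
distance was preferred over a formal normality test because the clinical
judgement is about profile shape, not sampling significance, and a
bounded score can be thresholded.

Classification into the three clinical groups uses the two classical
spectratype criteria — median peaks per family and the fraction of
families with approximately Gaussian profiles:

* **Normal**: median peaks ≥ 8 *and* Gaussian-family fraction ≥ 0.75;
* **Abnormal**: median peaks ≤ 5 *or* Gaussian fraction ≤ 0.4;
* **Almost_normal**: everything between.

All five cut-offs are configuration with these defaults; the ≥ 8 peaks
convention follows common clinical spectratyping practice, but no
published fixed cut-offs exist for the NGS reconstruction, so the
defaults are explicit package choices, marked as such, and every analysis
records them. Comparisons are inclusive (a profile exactly at the Normal
thresholds is Normal). Histograms are weighted by read abundance by
default (`weight = "clonotypes"` is available) because the fluorescence
intensity that classical spectratyping integrates is abundance-weighted.

Note that the classifier needs reasonably deep tables: with only a few
clonotypes per family the length histograms are spikes whatever the
underlying repertoire, and the verdict will honestly be Abnormal. The
bundled miniature example data (1200 reads per sample) show exactly that
behaviour for the control sample.

## Clonotype dynamics and annotation

Top clonotypes are ranked by count with a deterministic lexicographic
tie-break on `(cdr3_nt, v_call, j_call)`. Longitudinal tracking takes the
union of each timepoint's top-n clonotypes and reports each tracked
clonotype's frequency at *every* timepoint where it is detected at all,
including timepoints where it sits far outside the top-n; persistence
(detection at ≥ 2 timepoints) requires exact nucleotide identity. Input
order is irrelevant — samples are re-ordered by month.

Annotation matches amino-acid CDR3s exactly against a VDJdb-format table.
The default policy also requires V gene-family agreement, the common
convention for beta-chain matching, which suppresses spurious "public"
hits; the permissive CDR3-only policy is available and is the mode in
which implausible annotations (e.g. HIV-1-annotated sequences in
seronegative patients) surface — a useful caution, not a bug. Results
are reported as per-species **antigen binding potential** — the summed
frequency of distinct matching clonotypes, each counted once per species
however many of that species' epitopes it matches, contributing its full
frequency to every species it matches. The term "specificity" is
deliberately avoided: exact CDR3 matches are evidence of binding
*potential*, heavily confounded by cross-reactivity and alpha-chain
pairing.

## The synthetic-repertoire generator

The simulator exists so every stage is testable without patient data. Its
generative model: expected clone sizes for a baseline of `richness`
clones are drawn from a geometric or lognormal distribution; a small set
of expanded clones holds fixed repertoire fractions; `total_reads` reads
are drawn multinomially over the expected frequencies (fixing the read
total exactly, matching fixed-depth table semantics, rather than
per-clone Poisson); each clone receives a V family and J gene from weight
vectors and a random in-frame junction (conserved C…F flanks, no stop
codons) whose length follows the family's model — Gaussian over codon
counts for polyclonal profiles, fixed spikes for oligoclonal ones.
Expanded clones are distinct from baseline clones by construction, giving
unambiguous ground truth for tracking tests.

Defaults describe a control-cord-like beta repertoire: geometric clone
sizes with success probability 0.9 (closed-form Gini
$(1-q)/(2-q) \approx 0.09$ before sampling noise), richness 6000, 150,000
reads. Observed counts add multinomial noise of roughly
$1/\sqrt{\pi \lambda}$ Gini at $\lambda$ reads per clone, so the
*observed* defaults land near Gini 0.18 and Shannon 12.5 bits — inside
the control band (Gini below 0.2, Shannon above 12 bits) with realistic
headroom rather than unrealistically even. Post-transplant samples are
emulated with fewer baseline clones, heavier baseline tails, expanded
clones and spiked length models.

`calibrate_to_target_gini()` bisects the total expansion mass until the
mean observed Gini over a set of seeds hits a target. Sampling noise sets
a floor: targets at or below the floor return zero expansion mass when
the floor is within tolerance, and error with the achievable bracket
otherwise — one cannot simulate *below* the noise floor by removing
expansions.

`simulate_reconstitution_series()` produces one sample per month with
baseline richness and expansion mass following a monotone linear schedule
from an initial oligoclonal state to a final diverse one, and expanded
clones carried between consecutive months with a configurable persistence
probability; carried identities are recorded as ground truth. Categorical
settings (length models, gene weights) follow the initial parameters
throughout — the schedule interpolates the quantities that define the
diversity trajectory, not the family composition.

What the generator does **not** emulate — and therefore what passing
tests do not establish about real data: PCR amplification bias and
sequencing error (counts are exact multinomial draws), V-family-specific
length differences, biologically realistic V(D)J junction statistics
(junctions are uniform random codons), public clones shared between
individuals, out-of-frame rearrangements, and any coupling between clone
size and CDR3 identity. Tests against simulated data validate the
*analysis machinery*; claims about patient cohorts still require patient
data.

## Numerical choices and degenerate inputs

* Depth for percent $p$ on the rarefaction grid is
  `max(1, round(p/100 × total))` reads; the final percent-to-depth
  conversion for the representativeness floor uses the ceiling.
* Subsampling at full depth returns the input object unchanged (exact
  identity, zero cost); depth beyond the total is an error — no
  extrapolation, by design (no Chao-style estimators).
* Replicate SE is $\mathrm{sd}/\sqrt{R}$; with one replicate it is `NA`
  rather than a fabricated 0.
* Ties everywhere break deterministically (lexicographic for clonotypes,
  largest-depth for the cohort optimizer), so all outputs are stable
  across platforms and reruns.
* Monoclonal and single-bin degeneracies carry explicit flags instead of
  silently returning boundary values.

## Problem sizes used in validation

The shipped test-suite and acceptance checks run on simulated material
sized for quick iteration while keeping every estimate well inside its
statistical tolerance: diversity oracles on 1000 random vectors;
hypergeometric law on $10^5$ draws from a 4-read toy; depth-selection
against brute force on 1000 synthetic curves; cohort optimization against
exhaustive search on 200 random cohorts; Gini calibration at $10^5$ reads
averaged over 10 seeds; classifier recovery over 200 seeded draws at
60,000 reads; and a byte-identity rerun of the full pipeline on a
three-sample cohort of 4000-read repertoires. Those sizes are package
choices balancing resolution against iteration speed; all of them can be
scaled up by the corresponding arguments.

## Known limitations

* The Decombinator frequency dialect lacks the full junction sequence, so
  spectratype reconstruction and database annotation require AIRR-style
  junction-bearing input.
* Spectratype classification thresholds are explicit conventions, not
  values validated against clinical spectratype panels.
* Binding-potential annotation is exact-match only (no TCRdist-style
  similarity, no alpha/beta pairing inference).
* Group-level statistics (diversity vs GvHD grade, vs spectratype class,
  …) are intentionally not computed in-package; the reports are tidy
  tables meant to feed standard statistical tools.
```{r example, eval = FALSE}
# one-command cohort analysis on simulated data
samples <- lapply(1:3, function(i)
  simulate_repertoire(
    simulation_params(baseline_richness = 500 * i, total_reads = 4000,
                      n_expanded = 4L,
                      expansion_fractions = rep(0.3 / (2 * i), 4),
                      seed = i),
    sample_id = paste0("s", i), patient_id = "P1", month_post_tx = c(1, 6, 12)[i]))
res <- run_cohort_analysis(
  cohort_config(samples = samples, out_dir = tempdir(), master_seed = 1))
res$cohort_depth
```
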