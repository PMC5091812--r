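---
title: "Screening low-biomass metagenomes for contamination and batch effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening low-biomass metagenomes for contamination and batch effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmascreen)
```

## The problem

Plasma contains vanishingly little microbial nucleic acid. When such a
specimen is amplified and shotgun-sequenced, three technical signals compete
with — and usually dwarf — any biological one:

* **reagent contamination**: DNA/RNA present in extraction kits, water and
  plasticware, which dominates precisely when input biomass is low;
* **batch effects**: every extraction/library/sequencing occasion leaves its
  own multiplicative fingerprint on taxon abundances;
* **spurious classifications**: at a handful of reads per taxon, a few
  mis-aligned single mates are enough to "detect" a pathogen.

`plasmascreen` packages the analysis stack needed to recognise all three:
tag-aware read QC for Sol-B primed random-amplified libraries, taxon count
profiling normalised by filtered reads, presence-overlap screening against
plasma-free negative extraction controls, per-taxon regression of counts on
study group *and* sequencing batch, and a paired-read concordance audit for
low-abundance calls. Because the interesting claims are statistical, the
package also ships a synthetic-data generator that plants known defects and
effects, so every stage can be validated against truth labels.

## Read quality control

Libraries built from tagged random nonamers (the 18-nt Sol-B primer
`GTTTCCCACTGGAGGATA` flanking an N9) carry characteristic artefacts. The QC
stack applies, in order:

1. **DUST low-complexity filtering.** For windows of up to 64 bases the score
   is $\sum_t c_t(c_t-1)/2 \,/\, (w-3)$ over the ACGT 3-mer counts $c_t$,
   rescaled to 0–100 so a mononucleotide run scores 100; the read score is
   the maximum over windows (start every 32 bases, final window anchored at
   the 3' end). Reads scoring above 7 are removed. This is the windowed,
   rescaled convention of read-QC tools, not the unscaled score of the
   original DUST publication; window, step and threshold are configurable.
2. **Pair dereplication.** A pair duplicating an earlier pair exactly, or
   equalling its reverse complement with mates swapped (the same fragment
   read from the opposite strand), is removed; first occurrence wins.
3. **B-tail trimming.** BpmI digestion leaves a 5' fragment of the Sol-B
   primer on some reads. The longest read prefix matching a primer suffix is
   trimmed, allowing `min(1, floor(len/10))` mismatches. The length-scaled
   allowance matters: a flat one-mismatch rule would "match" every read at
   prefix length one and trim unconditionally, so short tails must match
   exactly. A consequence of any mismatch tolerance is occasional over-trim
   of a read whose start coincides with a primer suffix by chance; at 100 bp
   reads this costs a few bases, never a read.
4. **The six bespoke rules.** Failed Illumina chastity flag (CASAVA ≥ 1.8
   header field, `Y` = failed, absent = pass); a single-base run of more
   than 20 bases; any `N`; fewer than 2/3 of the first $\lfloor L/2 \rfloor$
   bases at Q ≥ 30 (strict inequality); the full Sol-B 18-mer still present;
   length under 70 bp. A pair is dropped when either mate fails — orphan
   retention would complicate the paired-read audit downstream — and the
   removal is attributed to the first failing rule in that order.
5. **Single-read dereplication.** A second, pair-blind exact-sequence pass
   (mates pooled in pair order). To keep the attrition report
   pair-consistent (`filtered_read_count` = 2 × surviving pairs), the
   surviving mate of a removed read is dropped with it.

Two consequences of the stage order are worth knowing. A 21-base homopolymer
run scores ≈ 9 in a 64-base window, above the DUST threshold of 7, so
homopolymer reads are removed as low-complexity before the homopolymer rule
ever sees them; the rule still matters for configurations with a higher DUST
threshold. And because trimming precedes the length rule, a read whose
post-trim length drops under 70 bp is removed as too short.

The surviving read count is the **filtered-read denominator** used for
normalisation: read counts divided by it (× 10^6 by default, i.e. counts per
million filtered reads). CPM is the conventional scale; the regression below
never uses normalised values, only raw counts with the denominator as an
exposure offset, so the scale choice affects no test statistic.

## Contamination screening

A taxon is "present" in a sample when its raw count reaches a threshold
(default 1 read — the weakest, most inclusive criterion; raising it can only
shrink the overlap, and the threshold is exposed as an argument). The screen
reports how many of the taxa observed anywhere are present in at least one
plasma-free negative control, pooling all negatives. On data simulated with
28 taxa of which 20 are reagent contaminants, the screen reports 71.4%
overlap; the per-taxon flags combine negative-control presence with an
editable catalog of commonly reported kit contaminants
(`extdata/known_contaminants.txt`).

```{r overlap}
sim <- simulate_counts(sim_config(seed = 5, n_taxa = 28, n_contaminant_taxa = 20))
negcontrol_overlap(sim$matrix)
```

## Group versus batch regression

For each sufficiently prevalent taxon the package fits

$$\log E[y_{st}] = \log d_s + \beta_0 + \beta_{group(s)} + \beta_{batch(s)}$$

on **raw** counts $y_{st}$ with the filtered-read denominator $d_s$ as
exposure offset, on study samples only (controls excluded, re-sequenced
duplicates removed by a seeded draw). Joint factor significance uses
quasi-likelihood F tests comparing nested fits; per-level Wald contrasts
(t statistics) probe which level drives a significant factor. P-values are
Bonferroni-corrected over the taxa actually tested, and each taxon is
classified `group_only` / `batch_only` / `both` / `neither`; group-significant
taxa that are also contaminant-flagged are annotated as likely
contamination/batch artefacts.

Numerical choices that required a decision:

* **Family.** The default working family is quasi-likelihood with log link
  and variance $\phi\mu^2$ (constant coefficient of variation). Two measured
  facts drove this. First, only a quadratic-variance family has scale-free
  estimating equations, making every p-value exactly invariant when a
  sample's counts and denominator are multiplied together by a constant —
  the behaviour one wants when libraries differ a hundred-fold in depth.
  Second, on negative-binomially overdispersed counts (dispersion 0.3) the
  quasi-Poisson alternative rejected at ~11% at nominal 5% in our
  simulations, while the quadratic family held 5% at moderate abundance and
  was conservative below it. `"quasi-poisson"` remains available.
* **Deviance at zero.** The gamma-type unit deviance is undefined at
  $y = 0$, and the patch in `stats::quasi` (`log(1/\mu)`) depends on the
  absolute scale of $\mu$, which would break the invariance above. The
  package uses the ratio-form deviance
  $-2[\log(y/\mu) - (y-\mu)/\mu]$ with zero counts contributing zero,
  which depends on $y/\mu$ only. Fits use a tight IRLS tolerance
  (`epsilon = 1e-12`) so the invariance holds to numerical precision.
* **Prevalence filter.** Taxa are tested only if non-zero in at least 5
  samples (`min_samples_present`). A taxon observed as a few singleton reads
  cannot support a six-parameter model: such fits are quasi-separated, and in
  null simulations every false group call came from taxa present in ≤ 4 of
  74 samples. Filtering low-prevalence features before per-feature modelling
  is standard in differential-abundance practice.
* **Degenerate fits.** A perfectly fitted taxon (dispersion numerically
  zero, e.g. constant counts with equal offsets) carries no evidence: its
  p-values are 1. Non-convergent taxa are reported with `NA` p-values. A
  factor with one observed level is dropped with a warning.
* **References.** Healthy and batch 1; Bonferroni $m$ = taxa tested in the
  analysis at hand (ranks/kingdoms analysed separately each get their own
  $m$).

## Paired-read validation

A low-abundance call is audited by counting reads assigned to the taxon,
read pairs with *both* mates assigned, samples contributing, and (given a
second, independent assignment table) reads confirmed by both classifiers.
The verdict is "unsupported" when concordant pairs are at or below one per
study sample **and** the confirmation fraction is below 0.1. The thresholds
are explicit configuration: the qualitative judgment they encode is that tens
of discordant single-mate reads spread over a hundred samples, with
single-digit cross-classifier confirmation, are classifier noise rather than
organism presence. On the canonical fixture (47 reads, 5 concordant pairs,
1 confirmed read, 102 samples) the verdict is "unsupported".

```{r audit}
fx <- plant_audit_fixture("Borrelia", n_reads = 47, n_concordant = 5,
                          n_confirmed = 1, n_samples = 16)
concordance_report(pair_concordance(fx$assignments, "Borrelia", fx$confirm),
                   n_samples_total = 102)
```

## Cohort tables

Demographic comparisons use Fisher's exact test in the Freeman–Halton sense
(sum of margin-consistent tables no more probable than the observed one, the
two-sided convention for r×c tables) for categorical variables, and the
Wilcoxon rank-sum test (exact when the smaller sample has ≤ 25 observations
and there are no ties, tie-corrected normal approximation otherwise) for
continuous ones. Exact enumeration is guarded to tables of ≤ 200
observations; cohort tables are far smaller. The packaged demographics table
(4 groups, sex and ethnicity) reproduces its published p-values exactly.

## The synthetic-data generator

The generator is first-class, tested code; its defaults are the study design
the package targets: 25 CFS + 25 healthy + 13 ADCLS + 11 SLE samples, 7
plasma-free negative controls, 1 positive control, 3 batches (stratified
within group so group and batch stay estimable), 20 re-sequenced libraries
linked by `replicate_of`, 100 bp read pairs.

*Counts* follow $E[y_{st}] = d_s(1-h)\,a_t\,b_{t,batch(s)}\,g_{t,group(s)}$
with log-normal library sizes (desk-scale mean 50,000 pairs — the targeted
study's 16.9M mean is emulated only in the deep-sequencing calibration test),
host fraction $h = 0.98$, log-normal baseline abundances $a_t$, and
negative-binomial noise (dispersion 0.3, matching the overdispersion the
regression assumes at moderate abundance). Contaminant taxa are the only
taxa with non-zero expectation in negative controls. Planted batch effects
multiply batch 3 by `batch_effect_fold` (default 10) for a chosen number of
taxa; planted group effects multiply CFS. Effect taxa are drawn from the
upper half of baseline abundance — a planted fold change on a taxon expected
at 0.1 reads per sample is unidentifiable at desk scale and would make
"sensitivity" a property of the abundance draw, not of the method — and
group-effect taxa are drawn within the batch-effect set, mirroring the
empirical situation where apparent group signals ride on batch/reagent
structure.

*Reads* are clean uniform-random sequence (Q35–40) unless planted with
exactly one defect per pair, drawn multinomially from `defect_rates`
(single-defect planting keeps truth attribution unambiguous). Duplicate
pairs copy an earlier clean pair so that "first occurrence kept" matches the
truth labels; a duplicate drawn before any clean source exists is demoted to
clean, which is why duplicate prevalence is bounded above but not below by
its nominal rate.

What the generator does **not** emulate: real genome sequence (reads are
random, so classification itself cannot be tested), alignment and database
errors, adapter read-through (inputs are assumed adapter-trimmed), chimeras,
or depth-dependent classifier sensitivity. Passing tests therefore show that
the *filtering, accounting and statistics* behave as specified on data whose
generative model is known — not that any particular classifier is accurate
on real plasma.

## Figures

Heatmaps cluster `log1p` of normalised abundances with Euclidean distance
and average linkage (neither is canonical; both are stated so the dendrogram
is reproducible), annotated by group and batch. PCA uses centred, unit-scaled
`log1p` normalised abundances, with component signs fixed so the
largest-magnitude loading is positive, and joins re-sequenced pairs with
dashed lines. Zero-variance taxa are dropped; an all-constant matrix yields
all-zero coordinates rather than an error.

## Validation scales and limitations

The shipped tests validate: exact QC/truth agreement and per-rule attrition
on 10,000 planted pairs; DUST against an independent brute-force scorer on
1,000 random sequences (agreement to 1e-9); dereplication against planted
duplicates; batch-effect recovery (fold 10, batch 3) with sensitivity ≥ 0.9
and group-factor family-wise error ≤ 0.05 across 100 replicates of 500 taxa
× 74 samples; offset invariance to 1e-6; the 71.4% overlap fixture; and
pair-concordance equality with brute-force mate pairing on 1,000 fixtures.
These problem sizes keep the full suite in the minutes range; the same code
paths run unchanged at larger scale.

Known limitations: the quadratic-variance family is conservative for taxa
near the detection floor (those taxa are also the ones the prevalence filter
removes); the overlap screen is presence/absence only, by design — no
frequency-based decontamination model is provided; and verdict thresholds in
the paired-read audit encode a qualitative judgment, not a calibrated error
rate.
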