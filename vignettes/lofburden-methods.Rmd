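---
title: "Methods: stringent-LoF burden and gene-level odds ratios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stringent-LoF burden and gene-level odds ratios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Rare loss-of-function (LoF) variants in autism-associated and
LoF-constrained genes are carried by a few per mille to a few per cent of
individuals. Estimating a per-gene case-control odds ratio is complicated by
two features of the data: the undiagnosed group is one to two orders of
magnitude larger than the diagnosed group, and the definition of a "rare"
variant (a singleton) depends on the size of the group it is counted in. A
naive 2x2 OR computed on the raw groups therefore mixes two different
rarity definitions and two very different sampling depths. The estimator
implemented here equalizes the groups by design: the undiagnosed carrier
count is averaged over repeated sub-samples of the undiagnosed pool, each
of exactly the diagnosed group's size, with singletons re-selected within
each group.

This vignette records the modelling choices, parameter conventions and
numerical decisions, in the order of the pipeline.

## Variant stringency cascade

`classify_variants()` labels each variant `S_LOF`, `S_SYN` or `OTHER` with
its failed filters. All thresholds keep their printed strictness and are
exercised one by one in the test suite:

* **Genotype QC** — call rate > 0.9 (strict), genotype quality >= 30
  (inclusive), depth > 20 (strict), allelic fraction >= 0.25, and <= 0.75
  for autosomal variants only. A missing metric fails with reason
  `missing_metric`.
* **Frequency** — default `strict` mode requires absence from the reference
  population and in-sample allele frequency <= 1%. A `maf` mode (reference
  MAF <= 1%) is exposed because both definitions are defensible for
  replication against other cohorts; the strict mode is the default because
  the carrier-level results it produces are the ones the rest of the
  pipeline is built around.
* **Recurrent genes** — a nine-gene blocklist (`MUC4`, `MUC12`, `HLA-A`,
  `HLA-B`, `HYDIN`, `TTN`, `PAX5`, `OR2T10`, `MYH4`) of loci recurrently
  called mutated across unrelated families, a known artifact signature.
* **Annotation confidence** — only high-confidence LoF annotations without
  auxiliary flags survive.
* **Brain exon expression** — per exon, the maximum pext (proportion
  expressed across transcripts) over 13 brain tissues must exceed 0.10
  strictly. The maximum is taken over available tissues; only an exon with
  all 13 missing fails (`missing_pext`). The maximum is robust to missing
  components, which is why partial tissue panels are tolerated.
* **Protein truncation** — `1 - cds_position / cds_length` must exceed 0.10
  strictly. CDS coordinates are 1-based and inclusive.
* **Splice mapping** — a splice-site variant sits outside the CDS, so its
  record carries the CDS coordinate of the closest coding base plus an
  explicit intronic offset (`splice_offset_bp`). Offsets up to 3 bp
  (inclusive: "+/-3 bp" most naturally includes the bound) map the variant
  to the adjacent exon with the boundary as effective position; larger
  offsets yield `unmapped_splice`. The offset field exists because exons
  tile `[1, cds_length]`, leaving no CDS coordinate free to encode an
  off-exon position.
* **MNV phase** — an S-LoF candidate is dropped only when an *in-phase*
  variant within the vicinity window (default 2 bp, one codon) changes the
  joint consequence away from LoF, e.g. a same-codon SNV rescuing a
  stop-gain to missense. Out-of-phase or distant partners never drop it;
  unknown phase retains the candidate with a warning, which is the
  conservative choice for carrier counts.

S-SYN applies the same QC, frequency, recurrent-gene, exon-expression and
truncation filters to synonymous variants; annotation confidence and phase
rescue are LoF-specific. Whether the truncation-position rule should apply
identically to synonymous variants is not fully determined by the method's
description; it is applied identically here, which makes S-SYN a strict
positional negative control.

## Gene-level autism OR

For a gene with `k_d` diagnosed carriers among `n` diagnosed individuals
and an averaged `k_u` undiagnosed carriers among a matched group of size
`n`:

```
OR = (k_d * (n - k_u)) / (k_u * (n - k_d))
```

Conventions, each of which is tested:

* `k_u` is the mean over `n_iterations` (default 100) sub-samples, used
  **unrounded**.
* Both denominators use the matched size `n`; equalizing the group sizes is
  the entire point of the sub-sampling.
* Singleton selection (`per_group_singletons`, the default) recomputes
  within-group allele counts inside the diagnosed group and inside every
  sub-sample; `prefiltered_only` trusts the upstream rarity filter. The
  default re-applies the rule because within-group allele counts are the
  rarity definition that matches the matched-size design.
* `OR = +Inf` iff there are diagnosed carriers and no undiagnosed carriers;
  `OR = NA` (undefined) iff there are no diagnosed carriers. Undefined
  genes are excluded from summaries and from OR-based stratification.
* When the undiagnosed pool already equals the diagnosed size, every
  sub-sample is the whole pool and the estimator reduces exactly to the
  direct OR (tested as an identity).

The **bootstrap empirical P** relabels the pooled cohort: each replicate
draws a pseudo-diagnosed set of size `n` without replacement, labels the
rest undiagnosed and reruns the same estimator (the sub-sampling is rerun
inside each replicate; a `single_pass` option exists for very large
designs). One set of replicates is shared by all genes, as a single
relabeling of the cohort determines every gene's bootstrap OR
simultaneously. `M` counts replicates with OR >= observed (ties count), and

```
P = (M + 1) / (N + 1),   95% CI = P +/- 1.96 * sqrt(P (1 - P) / (N + 1))
```

with significance declared when the CI's upper bound is strictly below
0.05. Infinite ORs are replaced by the highest finite OR of the gene set
("highest measurable") before correlation or module summaries; a set with
no finite OR raises an error rather than inventing a cap.

### Calibration and its limits

Under a null cohort in which the undiagnosed pool is substantially larger
than the diagnosed group — the regime the method is designed for — the
averaged `k_u` takes near-continuous values, ties between bootstrap and
observed ORs are rare, and the empirical P is uniform: with a 10x pool,
200 null genes and 800 bootstraps the suite's calibration test obtains a
Kolmogorov-Smirnov p of ~0.78.

When the pool size *equals* the diagnosed size, the sub-sample is always
the whole pool, `k_u` stays integer, the OR support is coarse, and the
tie-counting `>=` rule makes the empirical P conservative (its mean rises
to ~0.56 at carrier frequency 0.005 and n = 2,000). Monte-Carlo evaluation
of the marginal law puts its sup-deviation from uniform at ~0.113, which is
essentially the KS critical value (0.115) for 200 genes at alpha = 0.01:
a uniformity test of this degenerate design sits on the rejection boundary
and can land on either side depending on the draw. The package implements
the printed tie rule as is; no randomized tie-breaking is applied.

## Burden statistics

* **Carrier proportion CI** — normal approximation
  `p +/- 1.96 sqrt(p(1-p)/n)`, clamped to [0, 1]. This convention
  reproduces the standard cohort-scale reporting exactly at two-decimal
  rounding of the percentage (e.g. 523/13,091 -> 4.0%, CI 3.66-4.33%;
  1,090/188,856 -> 0.58%, CI 0.54-0.61%). Note 223/19,488 computes to
  1.14% even though such figures are sometimes reported as 1.13% with the
  matching CI 0.99-1.29%; the package reports the computed value.
* **Fisher exact** — two-sided by the probability-mass rule (sum of
  conditional hypergeometric probabilities no larger than the observed
  table's), which is `stats::fisher.test`'s convention; stated explicitly
  because two-sided conventions differ. The reported OR is the sample
  cross-product ratio, not the conditional MLE. The test suite checks both
  against exhaustive enumeration on all small tables.
* **Mann-Whitney U** — exact when the smaller sample has <= 8 observations
  and no ties; otherwise a tie-corrected, continuity-corrected normal
  approximation. The approximation's worst-case deviation from enumeration
  at n = 8 per group is 0.011 (enumerated); the continuity correction is
  kept because it halves that bound.
* **OR-expression correlation** — restricted to genes with at least one
  diagnosed carrier, capped ORs, expression values strictly above 1.
  Kendall tau-b is the default; Pearson in log10 space of both variables is
  exposed as `pearson_log10` because both conventions are in circulation
  for this analysis, and they answer slightly different questions (rank
  association vs log-linear association).
* **Module summaries** — per-module mean capped OR in descending order and
  a Mann-Whitney contrast of genes found exclusively in neuron/interneuron
  modules versus genes also assigned to other cell types.
* Bonferroni is applied per family (variant type x gene set) and BH-FDR per
  covariate within three outcome families: (1) diagnosis, trait scores and
  factors; (2) developmental milestones; (3) socioeconomic and fluid
  intelligence outcomes. Neither adjustment can lower a p value below raw.

## Association models

The regression engine fits three families with one term convention:

* binary logistic for diagnosis (a two-level ordinal logistic and a binary
  logistic coincide, so the binary fit is used and documented as such);
* ordinary least squares for continuous traits, with continuous predictors
  **and** outcomes z-scored ("standardized beta") while binary carrier
  indicators stay unstandardized so their coefficients read per carrier;
* proportional-odds (MASS::polr) for ordinal bands (income, qualification),
  reported as cumulative ORs.

Sex is coded 0 = male, 1 = female throughout (the coding is a free
convention; it only flips the sign of the sex term). Carrier indicators are
split at gene OR 10 — a gene at exactly 10 falls in the low stratum,
infinite ORs in the high stratum, undefined ORs in neither. The Townsend
deprivation index is reversed (negated) before modelling so that higher
material deprivation carries a negative sign; reversal flips fitted
coefficients exactly. Complete or quasi-complete separation in logistic
fits is detected (fitted probabilities at machine bounds or |coef| > 15 on
standardized predictors) and flagged in `glance()` rather than silently
penalized. Participation ORs are plain 2x2 sample ORs of response against
carrier status with Woolf log-OR confidence intervals; zero cells keep the
raw point estimate (0 when no carrier responded) and use the
Haldane-Anscombe 0.5 correction for the interval and p value.

## The synthetic-data generator

`simulate_cohort()`, `simulate_gene_panel()`, `simulate_variants()`,
`simulate_genotype_metrics()`, `simulate_phenotypes()`,
`simulate_expression()` and `simulate_modules()` emulate the *structure*
the analysis assumes:

* family-based ascertainment with always-undiagnosed parents, a 4:1 default
  male:female ratio among diagnosed individuals, standard-normal PGS with a
  0.2 SD diagnosed-group shift (a free parameter of the generator — no
  published value exists for it) and standard-normal ancestry PCs;
* per-gene carrier draws independent across genes (the gene-level OR treats
  genes marginally), one variant per carrier per gene by default (carrier
  status is binary downstream), with ground-truth carriers generated to
  pass every stringency filter and decoy variants violating exactly one
  filter each, so classifier recovery is exact by construction;
* genotype metrics that pass QC by default, with per-threshold failure
  fractions for boundary tests;
* phenotypes from one shared linear predictor. Continuous traits use
  Gaussian noise. Ordinal income/qualification bands threshold a latent
  with **logistic** errors so the proportional-odds fit recovers the latent
  coefficient on its own scale; IQ bins threshold a Gaussian latent because
  they are analyzed as a continuous outcome by linear regression. The
  Townsend analog is generated as the negated predictor plus noise so its
  raw orientation is "larger = more deprived". Questionnaire response is
  Bernoulli with a carrier odds multiplier applied uniformly.
* expression values are log-normal over a gene x region (R1-R4) x period
  (P1-P8) grid with the early-fetal R4 cell absent (mirroring the missing
  donor in the reference resource whose shape this emulates).

What the generator does **not** emulate: linkage disequilibrium or
haplotype structure, pedigree transmission beyond role labels, sequencing
reads, PGS construction from SNPs (the score is drawn directly, since its
construction is out of scope), genuine phenotype covariance structure or
participation mechanisms beyond a single odds multiplier. Passing
recovery tests therefore demonstrates the estimators' correctness under
the stated sampling model, not robustness to the correlation structure of
real cohorts.

## Problem sizes in the tests

Monte-Carlo checks run at deliberately scaled sizes chosen for stable
verdicts: null calibration with 200 genes and 800-2,000 bootstraps;
estimator consistency with 5,000 vs 50,000 individuals over 50 seeds
(median within 25% of the analytic OR 8.03 for carrier frequencies 0.004
vs 0.0005); regression recovery at n = 100,000 (continuous beta -0.37
within +/-0.05; ordinal latent beta -0.5 within +/-0.1) and participation
recovery at n = 150,000 (OR 0.8 within +/-0.05, with a 10% carrier
frequency giving that tolerance a ~3 SE margin). Generator frequencies in
the recovery designs were fixed from these power considerations before the
tests were run.

## Known limitations

* The empirical P is conservative whenever the OR support is coarse (few
  carriers, or a pool no larger than the diagnosed group); see the
  calibration section.
* The proportional-odds assumption is not tested automatically.
* X-chromosome dosage is not modelled; autosomal restriction is expected to
  be enforced by the input gene list.
* The capped OR depends on the composition of the gene set it is capped
  within; correlation results should only be compared within one capping
  set.
* No re-annotation is performed: consequence classes, confidence flags and
  pext values are consumed as given.
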