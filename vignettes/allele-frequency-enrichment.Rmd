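---
title: "Population enrichment of vitamin D-associated alleles and composite risk scores"
author: "vdfreq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population enrichment of vitamin D-associated alleles and composite risk scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vdfreq)
```

## The scientific problem

Mean serum 25-hydroxy-vitamin-D (25(OH)D3) concentration differs
substantially between ancestry groups, and the differences persist even at
matched latitude, which points at a genetic component. Genome-wide
association studies have identified hundreds of SNPs associated with
25(OH)D3 concentration (in and around *GC*, *NADSYN1*/*DHCR7*, *CYP2R1*,
*CYP24A1* and many other loci). vdfreq asks, for each such SNP and each
population: is the concentration-raising ("effect") allele significantly
enriched or depleted in that population relative to a pooled global
reference panel — and do the population-level totals of these alleles,
summarized as a composite genetic risk score, track the observed
concentration differences better than latitude does?

The pipeline has five stages, each exposed as ordinary functions and
composable through `runPipeline()` / `runStage()`:

1. **curate** — parse a GWAS-catalog association export, deduplicate SNPs,
   and harmonize effect alleles against the genotype panel.
2. **freqs** — effect-allele frequencies (EAFs) per population group from
   VCF genotypes, plus published frequencies for cohorts external to the
   panel (e.g. a national reference database), converted back to integer
   allele counts.
3. **enrich** — the signed log10 Fisher statistic per SNP and population,
   the SNP-by-population matrix, SNP classification, and hierarchical
   clustering of populations.
4. **grs** — composite genetic risk scores per individual and cohort, with
   a two-phase frequency-concordance SNP filter.
5. **associate** — ordinary least-squares fits relating population score,
   concentration, and latitude.

## The signed enrichment statistic

For SNP $i$ and population $P$ with $k_P$ effect alleles out of $n_P$, and
a background pool with $k_B$ of $n_B$, the 2x2 table
$\{(k_P, n_P-k_P), (k_B, n_B-k_B)\}$ is tested with a two-sided Fisher
exact test. The statistic carried into the heatmap matrix is

$$ S_{iP} = \mathrm{sign}(\hat p_P - \hat p_B)\,\cdot\,|\log_{10} p_{iP}|, $$

positive when the effect allele is enriched in $P$, negative when
depleted, zero on an exact frequency tie.

Two implementation points matter:

* **Log-space evaluation.** With thousands of alleles per group, $p$ can
  fall far below the smallest representable double (`4.9e-324`); a naive
  implementation reports 0 and the log-statistic overflows to infinity or
  saturates. `fisherTestLog10()` accumulates hypergeometric point
  probabilities as log-gamma terms combined by log-sum-exp, so
  $\log_{10} p$ is finite and accurate at any magnitude. (Published tables
  of this kind often show a repeated ceiling value near 312 — the signature
  of double-precision underflow at $-\log_{10}(\,\approx 5\times
  10^{-313})$ in a linear-space computation. No saturation cap is applied
  here; recomputed magnitudes beyond that ceiling are reported as they
  are.)
* **Two-sidedness.** The two-sided $p$ sums all point probabilities no
  larger than the observed one, with the customary relative tolerance of
  $10^{-7}$ so that floating-point noise cannot exclude exactly tied
  tables; this matches the convention of `fisher.test`. The test suite
  checks the implementation against exhaustive hypergeometric enumeration
  for every table with both group sizes up to 30.

**Background choice.** By default each population is tested against the
pooled global panel as given (`background_mode = "inclusive"`). A cohort
external to the panel — such as the Korean reference cohort against the
1000 Genomes pool, which contains no Korean samples — is naturally
disjoint from its background. For panel superpopulations the inclusive
default keeps the background identical across columns; a
`"complement"` mode that subtracts the tested group's counts first is
available for users who prefer strictly disjoint comparisons.

**Classification.** Per population, SNPs partition into enriched
($p < \alpha$, $S > 0$), depleted ($p < \alpha$, $S < 0$) and comparable
($p \ge \alpha$), with $\alpha = 0.05$ and no multiple-testing correction
by default (Bonferroni and Benjamini-Hochberg are options); an "extreme"
subset collects SNPs with $|S|$ above a threshold, 100 by default.

**Counts from published frequencies.** When only a published frequency
$\hat p$ and sample count $n$ are available, allele counts are
reconstructed as $k = \mathrm{round}(\hat p \cdot 2n)$, rounding half away
from zero. The rounding rule is stated because exact-test p-values at
extreme counts are sensitive to a one-allele change.

## Clustering populations

Population columns are clustered agglomeratively on their signed
enrichment profiles. The default distance is $1 - r$ (Pearson correlation
between columns) with complete linkage. Correlation distance is
deliberate: $|S|$ scales with sample size, so cohorts of very different
size (a 1722-individual national cohort vs 347-sample panel groups) live
on very different magnitude scales, and a Euclidean metric separates them
by sample size before any biology. Correlation distance compares the
*pattern* of enrichment and depletion across SNPs — what the heatmap
visualizes — and on the packaged reference table it recovers the expected
continental structure ({EUR, AMR, SAS} vs {AFR, EAS, KOR}) under every
linkage, which Euclidean distance does not. Euclidean distance remains
available via `metric = "euclidean"`.

## The composite genetic risk score

For one individual with effect-allele dosages $X_i \in \{0,1,2\}$ over $I$
catalog SNPs,

$$ \mathrm{GRS} = \frac{\sum_{i=1}^I X_i}{2I} \in [0, 1], $$

1 for a homozygous carrier of every effect allele, 0 for a carrier of
none, and 0.5 in expectation under uniformly random dosages. The score is
deliberately unweighted: per-allele effect sizes estimated in one ancestry
transfer poorly to others, so a composite count is the more defensible
cross-population summary. For a cohort with complete genotypes the mean
score equals the mean of the per-SNP population EAFs exactly — the
frequency form `expectedGrsFromEaf()` used for cohorts known only through
published frequencies.

Missing dosages are imputed as their Hardy-Weinberg expectation $2\hat
p$ from the individual's own population, keeping the denominator at $2I$;
a strict mode refuses missing data instead.

**Two-phase concordance filter.** When a cohort provides both full-sample
frequencies and an individually genotyped second phase, SNPs whose two
frequencies differ by more than 0.10 are excluded from scoring
(`phaseConcordanceFilter()`). The threshold is an absolute frequency
difference and the inequality is strict — a difference of exactly 0.10 is
retained; "more than 10%" is read on the frequency scale, the common usage
for allele frequencies.

## Association with concentration and latitude

`differenceAnalysis()` forms, relative to a reference population (EUR by
default, configurable), the between-population differences in mean
concentration, mean score, and latitude, and fits the concentration
difference on each of the other two by ordinary least squares. Comparing
the two $R^2$ values asks whether concentration differences track genetics
or geography. The U-shaped relation between score and native-population
concentration is modeled as an OLS quadratic (`quadraticFit()`); no
specific functional form is claimed beyond curvature.

## What the simulator generates — and what it does not

`simulateAlleleFrequencies()` implements the Balding-Nichols model:
ancestral frequencies $p_0 \sim U(0.05, 0.95)$ and population frequencies

$$ p_{pop} \sim \mathrm{Beta}\!\left(p_0\frac{1-F}{F},\;
   (1-p_0)\frac{1-F}{F}\right), \qquad
   \mathrm{Var}(p_{pop}) = F\,p_0(1-p_0), $$

with $F$ an $F_{ST}$-like drift parameter per population, optionally with
a clade level in between (a shared intermediate frequency per clade) to
give clustering something to recover. The default configuration mirrors
the study design the package targets: five continental groups at the
published 1000 Genomes phase 3 sizes (AFR 661, AMR 347, EAS 504, EUR 503,
SAS 489), an external cohort of 1722, I = 320 SNPs, and drift parameters
of 0.07-0.15, the range typical of human continental differentiation.
Genotypes are Binomial(2, $p_{pop}$) (Hardy-Weinberg), phenotypes are
$\beta_0 + \beta_{grs}\cdot\mathrm{GRS} + \beta_{lat}\cdot\mathrm{lat} +
\varepsilon$ with Gaussian noise (defaults $\beta_0 = 25$ ng/mL,
$\beta_{grs} = 30$ ng/mL per score unit, $\beta_{lat} = -0.15$ ng/mL per
degree, $\sigma = 1$ ng/mL — chosen once to put simulated concentrations
in the observed 15-30 ng/mL range with genetic and latitude effects of a
few ng/mL each). All randomness flows from one root seed through fixed
per-stage substreams (frequencies / genotypes / phenotypes / subsampling),
so any stage can be regenerated independently and byte-identically.

The simulator does **not** generate linkage disequilibrium, selection,
admixture, or any demographic history beyond the two-level clade tree, and
its phenotype model is exactly the linear model the association stage
fits. Passing tests therefore demonstrate correctness of the computations
and recoverability of planted structure — not that real data satisfy the
model's assumptions.

`emitFixtures()` writes simulated data in the very formats the pipeline
reads (VCF with GT, sample-map TSV, frequency-table TSV, GWAS-catalog
dialect TSV with planted duplicate rows and an unstated "?" risk allele,
phenotype TSV), so fixtures and real downloads are interchangeable and
every parser is exercised round-trip.

## Numerical and design choices, collected

* Fisher two-sided rule: sum of point probabilities $\le p_{obs}(1 +
  10^{-7})$; log-gamma + log-sum-exp evaluation; degenerate margins give
  $p = 1$.
* Counts from frequencies round half away from zero.
* Duplicate catalog entries: first occurrence in file order wins
  (deterministic, auditable).
* Strand handling: exact allele match preferred, reverse complement
  accepted otherwise, strand-ambiguous A/T and C/G SNPs only on exact
  match (flagged); unresolvable records are dropped loudly, never kept
  silently. Entries without a stated risk allele fall back to the panel
  minor allele, recorded as such per record.
* Missing genotypes shrink the frequency denominator; at scoring time they
  are imputed as $2\hat p$ (default) or refused (strict).
* Clustering: correlation distance, complete linkage, deterministic leaf
  order; missing cells imputed as 0 with a warning.
* Degenerate fits: constant response gives $R^2 = 0$ with a warning;
  constant predictor is an error.
* In the parameter-recovery checks, slope coverage uses the analytic
  standard error computed from the generator's known noise sd, for which
  the $\pm 2$ SE band has exact 95.4% normal coverage (an estimated SE
  would make the band a t-interval with lower coverage).

## Problem sizes in the test suite

The suite runs entirely on generated data and the packaged 29-SNP
reference table: the exhaustive Fisher sweep covers all ~245,000 tables
with both group sizes up to 30; score identities use 100 seeds of 20 SNPs
by 90 samples; parameter recovery uses 200 replicates of 20 populations by
50 SNPs; clustering recovery uses 100 replicates of 6 populations (two
clades of drift 0.2 between, 0.02 within) by 50 SNPs at 500 individuals
per population; the uniform-dosage score check uses 320 SNPs by 2000
individuals. These sizes keep the full suite under a minute while leaving
every statistical bound a comfortable margin.

## Known limitations

* Frequencies reconstructed from 2-3 printed decimals carry rounding error
  that exact tests amplify at extreme counts; recomputed $|\log_{10} p|$
  near such values should be read with a percent-level tolerance.
* The pipeline treats SNPs as independent (no LD pruning); the composite
  score and enrichment counts inherit whatever correlation structure the
  input catalog has.
* Effect alleles from a GWAS catalog are imperfectly curated upstream;
  the minor-allele fallback is the standard but imperfect remedy, and
  each record carries its resolution provenance so downstream users can
  filter on it.
* Cross-population transfer of GWAS associations is assumed, as in the
  underlying study design; nothing in the statistics corrects for
  ancestry-specific effect heterogeneity.
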