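---
title: "Finding onset-modifier loci in multiplex families: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding onset-modifier loci in multiplex families: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(onsetmod)
```

## The problem

A modifier locus changes a clinical feature of a disease — here the age at
first onset (AAO) — without changing susceptibility to the disease itself.
Detecting modifiers with a case-only design is attractive in familial
disease: affected relatives share much of their genetic background, and
families can be ranked by how early the disease strikes their affected
members. `onsetmod` implements the full chain of such a design: extreme
sampling on family-mean onset, a covariate-adjusted logistic genome scan
contrasting the two tails, replication in co-affected siblings, an ordinal
trend across four onset strata, a weighted multi-SNP genetic risk score
(GRS), and two susceptibility-side tests (family-based transmission and
matched case–control) whose *nullness* at a candidate is what marks it as a
modifier rather than a risk locus.

## The generative model behind the test bed

No public cohort accompanies this design, so the package carries a
first-class synthetic-data module whose defaults define the study
conditions everything else is tested under.

For affected sibling $i$ in family $f$ with minor-allele dosages $g_{ij}$:

$$\mathrm{AAO}_i = \mu + \sum_j \beta_j g_{ij} + a_f + \varepsilon_i,
\qquad a_f \sim N(0, \sigma_F^2),\ \varepsilon_i \sim N(0, \sigma_E^2),$$

floored at 7 years. Defaults: $\mu = 23.7$ years (the kind of mean onset
seen in early-adult psychotic illness), $\sigma_F = 4$, $\sigma_E = 7$
years. The family effect creates the within-family onset correlation that
makes ranking families by mean sibling AAO meaningful; the split between
$\sigma_F$ and $\sigma_E$ is a placeholder in the absence of a published
variance decomposition, and modifier effects add their own variance on top.
Current age adds an illness duration drawn Uniform(5, 20) years, which
induces the strong age–AAO correlation (r ≈ 0.5) typical of prevalent
samples — and is why the scan deliberately omits age as a covariate.

Genotypes: ancestral minor-allele frequencies are Uniform on a configurable
interval (default 0.05–0.5); founders draw binomially; offspring arise by
gene dropping (each parent transmits a random allele), so Mendelian
consistency is guaranteed by construction and is asserted, not assumed, in
tests. Optional two-subpopulation structure uses Balding–Nichols Beta
frequencies at a given fst; `prop_pop2` of families come from the second
subpopulation. Affection is ascertainment-defined (all sampled siblings are
affected). A configurable susceptibility marker reweights transmissions to
affected offspring by a per-allele relative risk — it exists purely to give
the family-based test a non-null test bed, since a pure onset modifier
must look null there.

What the generator does **not** emulate: linkage disequilibrium beyond the
hand-built candidate cliques, genotyping-intensity artefacts, batch
effects, X-linked markers, and assortative or non-random mating. Tests
passing on these cohorts therefore validate the statistical machinery and
the design's internal logic, not robustness to every failure mode of real
array data.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| sample/marker call rate | > 0.98 | fraction | standard array QC retention rule (strict >) |
| MAF filter | > 0.05 | frequency | rare markers are underpowered and HWE-unstable at n ≈ 190 |
| HWE exact p | > 0.001 | p-value | two-sided exact test, computed on one member per family to avoid relatedness distortion |
| kinship flag | φ̂ > 0.354 | — | duplicate/MZ bound of the KING-robust estimator (midpoint of 0.5 and 0.25 on the log₂ scale); the pair member with the lower call rate is dropped |
| ancestry outlier | z > 5 | SD | leave-one-out z on any of 4 MDS components; leave-one-out keeps the outlier itself from inflating the SD it is tested against |
| suggestive / genome-wide | 10⁻⁴ / 7.2 × 10⁻⁸ | p | screening vs declaration thresholds (strict <) |
| LD collapse | r² > 0.8 within 500 kb | — | "same signal" rule; each clique keeps its smallest-p member |
| Bonferroni | 0.05/m | p | m = candidates carried into confirmation (14 in the standard fixture ⇒ 0.0036) |
| matching | 5:1, 5-year bins | — | frequency matching on sex × age bin by largest-remainder quotas |

## Numerical and algorithmic choices

**Logistic fits** use iteratively reweighted least squares
(`stats::glm.fit`, deviance tolerance 10⁻¹⁴). Complete or quasi-separation
is detected as any |β| > 15 on the log-odds scale or non-convergence; such
fits report missing p-values rather than astronomical ones. Wald p-values
come from the observed-information standard errors; on a 2×2 layout they
agree with the closed-form cross-product odds-ratio z-test to high relative
precision, which the suite asserts.

**MDS adjustment rule.** Any of the four MDS components whose between-tail
two-sample t-test has p < 0.05 enters the scan as a covariate; if none
does, the scan runs unadjusted and says so. This makes the printed
"adjust one of the four components" behaviour reproducible without a
per-dataset manual choice.

**Permutation empirical p.** Group labels are permuted and the dosage
term's Wald |z| refit each time; $\hat p = (1 + \#\{z_b \ge z_{obs}\})/(1 +
B)$ with adaptive stopping once 10 exceedances accrue (the relative error
of $\hat p$ is then already bounded). For n ≤ 8 all label assignments are
enumerated and the estimate is exact. A non-converged observed fit yields a
missing empirical p by design.

**Exact tests.** The Hardy–Weinberg test sums conditional probabilities of
heterozygote counts no more probable than the observed one (computed in log
space; equal-probability ties included with a 10⁻¹² relative guard). The
Mann–Whitney test enumerates all group assignments when n₁ + n₂ ≤ 12 and
otherwise uses the normal approximation with midranks, tie-corrected
variance and continuity correction. Fisher's exact test and Welch's t-test
for the descriptive table come from base R.

**Ordinal trend.** The four onset groups are ordered latest < later <
earlier < earliest — earliest highest — so a trend odds ratio above 1 means
the minor allele pushes onset earlier, matching the sign of the two-group
OR. The proportional-odds model is fit by `MASS::polr`; with only two
represented levels the cumulative-logit model *is* binary logistic
regression, and the implementation dispatches accordingly (the two routes
agree to 10⁻⁶, which is tested). The proportional-odds assumption itself is
not tested: one trend OR per marker is the design's contract.

**GRS.** Weights are natural-log odds ratios frozen from the learning set;
applying a profile never refits. A missing dosage is imputed by its
learning-set mean dosage 2·MAF so scores remain comparable across
missingness patterns; an all-major-homozygote sample scores exactly 0.
Scores are reported raw (unstandardised).

**FBAT.** For each affected, genotyped offspring with both parents
genotyped, the offspring dosage is compared with its Mendelian expectation
given the parental pair; contributions sum over offspring (independent
given parents) and $z = (S - E[S])/\sqrt{\mathrm{Var}[S]}$. Families with a
missing parental genotype are excluded and counted — a deliberate
simplification relative to sufficient-statistic conditioning on partially
typed parents, flagged in the output. On heterozygote-by-homozygote matings
with one affected child this statistic reduces algebraically to the
classical TDT, which the suite checks.

**Matching.** Per-stratum control quotas are largest-remainder roundings of
ratio × case count, so quotas sum exactly to ratio × n(cases) and no
stratum deviates from proportionality by more than one control; sampling
within strata is without replacement and seeded. Deficient strata abort
with a named shortfall rather than silently under-matching.

**Power.** The analytic two-group power uses the 1-df additive trend test:
genotype frequencies under HWE, baseline penetrance solved from the
prevalence of early onset among patients, group-specific genotype
distributions by Bayes, null variance at the pooled mixture, alternative
variance group-specific. The significance level is a free parameter
(default 0.05) because the design's printed 0.7–0.9 range does not pin it.
A vectorised Monte-Carlo companion agrees with the closed form within ±0.01
at 10⁵ replicates.

**Determinism.** Identical (config, seed) reproduce cohorts and pipeline
artifacts byte for byte. The pipeline derives per-stage seeds from one root
seed by fixed offsets so stages can be re-run in isolation; changing the
root seed with fixed data perturbs only the stochastic columns.

## Fixture design

Two standard fixtures are shipped as code, not data. The **proband QC
fixture** plants, among 190 extreme-tail probands, two samples at 90% call
rate, one near-duplicate of another proband (1% discordance, half miscalls
and half no-calls so the copy's call rate sits just below its source's and
kinship removal resolves the pair deterministically), and two samples
redrawn from an fst = 0.1 subpopulation. Its default panel is 20 000
markers: ancestry outliers at that divergence need a dense identity-by-state
panel to clear the z > 5 rule reliably, mirroring how real array QC leans
on hundreds of thousands of SNPs. The **candidate fixture** plants 17
markers with a strong tail contrast (MAF 0.50 vs 0.10), three of them
within 300 bp in near-perfect LD, among null background markers, plus a
replication-round genotype set in which exactly one collapsed-set survivor
has a sub-0.98 call rate — so the accounting 17 → 15 → 14 is reproduced by
computation under any seed.

## Problem sizes used in the tests

The suite runs the scan's type-I error on ≥ 10⁴ null marker-tests (four
cohorts of 190 probands × 2500 markers), the planted-modifier recovery and
modifier-vs-susceptibility contrast on five replicates of 557 families, the
GRS-trend calibration on 1000 permutations of 200 scores, and the power
cross-check at 10⁵ Monte-Carlo replicates. These sizes keep the whole suite
under a couple of minutes on one core while leaving binomial error bands
tight enough to be meaningful; they are desk-scale stand-ins for the
hundreds of thousands of markers a real array carries.

## Known limitations

- The FBAT implementation conditions only on fully typed parental pairs;
  families with untyped parents are dropped rather than recovered through
  sufficient statistics.
- No batch-effect checking or adjustment; no X-chromosome handling; no
  sex-consistency QC (autosomes only).
- LD is modelled only as hand-planted cliques; the collapse rule is greedy
  and windowed, which matches practice but is not a haplotype model.
- The GRS uses exactly the candidate set with log-OR weights — no p-value
  thresholding sweep, shrinkage, or cross-validation.
- The ordinal model assumes proportional odds without testing it.
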