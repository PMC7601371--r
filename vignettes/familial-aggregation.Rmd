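---
title: "Familial aggregation testing in pedigree cohorts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Familial aggregation testing in pedigree cohorts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(echagg)
```

## The scientific problem

Endemic congenital hypothyroidism (endemic CH) affected severely
iodine-deficient populations in two clinical forms: a myxedematous
phenotype (persistent hypothyroidism, stunted growth, myxedema) and a
neurological phenotype (spasticity, deaf-mutism, profound intellectual
deficiency without persistent frank hypothyroidism). Although iodine
deficiency is the established causal factor, cases were not obviously
spread at random across households. The question this package addresses
is statistical: given a family survey — pedigrees plus a clinical
phenotype per living subject — do cases aggregate within families more
than random affection at the population prevalence would produce?

The package was built around a 1979–1980 survey of one village cohort:
62 family units, 468 clinically phenotyped living subjects, 46 cases
(~10%). Affection is analysed for three categories: *myxedematous*
(severe, moderate or unknown-grade myxedema, plus the mixed form),
*neurological* (neurological and deaf-mute forms) and *combined* (either).
Under each category every individual is `affected`, `control` or
`unphenotyped`; deceased subjects and subjects never phenotyped are
`unphenotyped` everywhere and excluded from every count, prevalence
denominator and resampling pool, while an alive subject carrying only the
*other* category's phenotype counts as a control (this keeps the
denominator at 468 for every category, matching the published prevalence
arithmetic of 46/468 and 44/468).

## Data model

A cohort is a validated pedigree forest: ids are opaque strings, founder
parents are `NA` (written as `"0"` in PED files), both parents are
recorded or neither, parent references must resolve with compatible
sexes, and the parent graph must be acyclic. Multi-generation and
polygamous structures are decomposed into *nuclear families* (one
father–mother couple and their shared offspring); a father with w wives
heads w nuclear families. Sibship size counts **living** offspring only.
Sex is recorded and reported descriptively but no test uses it; vital
status matters only through the phenotyped/unphenotyped distinction.

I/O uses the 6-column PED dialect plus a TSV sidecar
(`id phenotype alive age goitre`, missing token `NA`). The PED affection
column is written (2/1/0 under the combined category) for
interoperability with other pedigree tools but ignored on input; the
sidecar is authoritative.

## The tests

Let φ(i,j) be the Malécot kinship coefficient, computed by the standard
pedigree recursion (parents processed before children):
φ(i,i) = (1 + φ(f_i, m_i))/2, φ(i,j) = (φ(f_i, j) + φ(m_i, j))/2,
founders pairwise unrelated. The implementation is checked in the test
suite against closed forms (self 0.5, parent–offspring and full sibs
0.25, first cousins 0.0625) and against an independent gene-dropping
simulation on pedigrees of up to 20 members.

With π the prevalence, n_f / k_f the phenotyped / affected counts of
family f, and A = Σ k_f cases among N phenotyped subjects:

* **Binomial probability (per family).** p_f = P(X ≥ k_f),
  X ~ Binomial(n_f, π), exact tail sum. The family unit is the
  *recorded* family — parents included, all wives' offspring pooled —
  and the BH multiplicity is the 62 recorded families. Both conventions
  are pinned by the published arithmetic: the reported
  p = 1.62 × 10⁻⁴ for the flagged families is exactly
  P(X ≥ 5 | n = 7, π = 46/468), and its adjusted value
  5.04 × 10⁻³ is p × 62/2.
* **Kinship sum (per case).** s_i = Σ_{j affected, j≠i} φ(i,j). Each of
  B null draws resamples A ids uniformly without replacement from the N
  phenotyped subjects and records every sampled id's kinship sum with
  the rest of the draw; the default pools all B·A sums into one null
  (p_i = (1 + #{pooled ≥ s_i})/(1 + B·A)). The published per-case
  p-value convention is not fully recoverable; a per-draw-maximum
  variant is available via `null = "per_draw_max"`, and the pooled
  default reproduces the published values to within their order of
  magnitude on the reconstructed cohort. Exact replication is not
  claimed.
* **Genealogical index of familiality.** 10⁵ × mean φ over unordered
  case pairs; same resampling null; per-family variant restricts both
  the cases and the resampling pool to one family. When the
  family-restricted null collapses to a point mass (e.g. every
  phenotyped member affected) the result is flagged `degenerate` with no
  p-value, mirroring the behaviour reported for the two fully affected
  families.
* **Probability of familial clustering.** Under random allocation the
  per-family case counts follow a multivariate hypergeometric law; the
  statistic is the observed configuration's probability mass and the
  p-value is the total mass of configurations no more probable. The
  p-value is estimated by Monte-Carlo (sequential-conditioning
  hypergeometric draws, vectorised across replicates); masses below the
  Monte-Carlo resolution are reported as bounds, not as exact values —
  the original analysis evidently used an exact computation for its
  smallest value, which is out of scope here.

**Monte-Carlo conventions.** p = (k+1)/(B+1) (pooled: (k+1)/(B·A+1));
ties between a null statistic and the observed one count as exceedances
(conservative); zero exceedances set `p_is_bound = TRUE`, representing
"p < 1/B". Default B = 10⁶ mirrors the original analysis; the bundled
quick profile (`run_config(B = 1e5)`) is the desk-scale default, and the
test suite demonstrates at B = 10⁵ that sampled p-values sit inside the
99% binomial envelope of exhaustively enumerated limits on small cohorts.
All samplers take an explicit seed; identical inputs and seed give
identical results.

**Multiplicity.** BH step-up (via `stats::p.adjust`), applied per test
type and per category across that test's units (62 families for the
family tests, the affected individuals for the kinship sum test). The
p ∈ (0,1] domain is enforced; bounds participate with their bound value.

## Sibship-level analysis and model probabilities

`sibship_table()` tabulates, per sibship size s, the family count F_s,
the affected-family count A_s, observed cases O_s and expected cases
E_s = F_s · s · π. The χ² statistic Σ (O_s − E_s)²/E_s is referred to a
chi-squared law with S − 1 degrees of freedom — deliberately *not*
reducing df for the estimated π, to match the published df = 8 over nine
cells; cells are the sizes actually present, with no small-cell pooling,
for the same reason. π defaults to the cohort's observed affected /
phenotyped ratio (46/468 on the reference cohort) rather than the
rounded 10%.

`recessive_model_prob(n, k)` gives exact Binomial(n, 1/4) upper tails
for offspring of two carriers: (1/4)⁵ ≈ 0.001 for five affected of
five, 1/64 ≈ 0.016 for at least four of five — small enough to argue
against a simple mono-allelic recessive transmission for the two fully
affected families.

Descriptive comparisons (`cohort_summary()`) use Fisher's exact test
(two-sided mass-summation convention, `stats::fisher.test`) for 2×2
counts and the two-sided Mann–Whitney test for ages. Age strata are
<5, 5–18, ≥18 years with 18 in the upper stratum.

## The reference cohort reconstruction

The original field data were never deposited, so `reference_cohort()`
rebuilds a cohort that satisfies every published constraint
deterministically:

* 89 nuclear families with F_s = (19, 15, 19, 11, 10, 4, 6, 3, 2) for
  s = 1..9 (308 offspring), A_s = (1, 5, 6, 4, 4, 1, 3, 1, 1),
  O_s = (1, 5, 9, 4, 13, 3, 8, 2, 1);
* 62 family units: 45 monogamous, 12 bigamous, 5 polygamous (4 wives
  each); 468 phenotyped alive subjects, 46 cases = 44 myxedematous + 2
  neurological, with the published myxedematous subtype totals
  (20 severe, 17 moderate, 3 unknown grade, 4 mixed) and sex margins
  (24/22 affected, 185/237 control males/females);
* families A and B reproduced to their published pedigree detail: two
  healthy parents each, eight offspring each, five alive and affected
  (A: all myxedematous, ages 5–25, with three deceased siblings
  reported affected; B: eldest a neurological female, ages 6–30, three
  deceased of unknown status), goitre grades as described;
* the four never-phenotyped living subjects, excluded from every
  statistic.

Below those constraints the published record does not determine the
data, and the reconstruction fixes the remainder by rule: per-size case
splits (size 3: 2/2/2/1/1/1; size 5: 5/5/2/1; size 7: 4/3/1 — the
4-affected/3-healthy sibship reported to drive the residual cohort
signal; size 6: 3; size 8: 2; other sizes: singletons); every affected
sibship in its own monogamous unit; unaffected sibships filling the
remaining units largest-first; the second neurological case placed as
the size-9 sibship's single (deaf-mute) case; ages only where published
bounds exist. The 160 non-offspring subjects are the 151 parents plus 9
unaffected founder relatives attached to otherwise-unaffected monogamous
units — kept without pedigree links so the nuclear-family decomposition
stays at exactly the published 89 sibships; their only analytic effect
is enlarging the phenotyped pool to 468, and a test verifies the
per-family counts are insensitive to their removal. The acceptance
checks were chosen to be insensitive to the allocation rule, and the
test suite re-runs the headline scenario count under an alternative
same-totals allocation to demonstrate that.

Two published values are deliberately **not** reproduced: the
myxedematous binomial p for family A (9.31 × 10⁻⁵) is not
P(X ≥ 5 | n = 7, π = 44/468) = 1.31 × 10⁻⁴ under any convention we
could pin down, and the reconstructed 2%-prevalence scenario count is 8
rather than 9 significant families (allocation-dependent). Both are
documented rather than tuned for.

## Synthetic cohorts

`generate_cohort()` draws family units with the surveyed structure
probabilities (45/62, 12/62, 5/62 for 1/2/4 wives), sibship sizes from
the empirical size distribution (F_s/89), and offspring affection by one
of three mechanisms:

* `null_iid` — independent Bernoulli(π) per offspring, π = 46/468 by
  default: the random-distribution hypothesis the tests calibrate
  against. The test suite verifies family-wise type-I control of the
  BH-corrected binomial test over 300 such cohorts.
* `beta_binomial` — a per-sibship affection probability drawn from a
  Beta with mean π and intra-class correlation ρ (default 0.2, a
  moderate familial correlation; shape parameters π(1−ρ)/ρ and
  (1−π)(1−ρ)/ρ), offspring conditionally independent: a generic
  family-environment/polygenic aggregation mechanism for power studies.
* `recessive` — parental recessive-allele counts drawn at allele
  frequency q (default 0.15, putting carrier×carrier couples at the few-
  percent scale), Mendelian transmission, offspring affected iff
  homozygous; parents never express the phenotype. Parental genotypes
  are attached to the result for verification.

The generator emulates the features the tests rely on — family
structure, sibship sizes, prevalence, within-family correlation — and
deliberately not demographic realism: everyone is alive, ages and goitre
are missing, sexes alternate. Passing tests on synthetic cohorts
therefore say nothing about mortality patterns, age confounding or
phenotype misclassification in real data.

## Numerical choices and degenerate inputs

* Exact binomial/hypergeometric tails come from `pbinom`/`fisher.test`;
  the recessive tails are summed directly so that upper and lower tails
  partition to 1 exactly at sibship sizes.
* Tie comparisons in Monte-Carlo nulls use a 10⁻¹² absolute tolerance on
  kinship statistics (sums of dyadic rationals) and 10⁻⁹ on log-scale
  clustering masses.
* A χ² cell with E = 0 is an input error; O = E cells contribute 0 but
  still count toward df.
* Families with fewer than two affected members are not testable by the
  kinship-based family tests and are rejected with an informative error;
  the driver simply skips them.
* Degenerate family-restricted nulls (point mass) yield `degenerate =
  TRUE` and `p = NA` rather than a misleading p-value.

## Problem sizes

The bundled test-suite and quick-profile sizes are chosen for
desk-scale runs: B = 10⁵ for Monte-Carlo agreement checks (99% binomial
envelopes against enumerated limits), 300 replicates for the type-I
study, 10⁵–2×10⁵ gene drops for kinship verification. The statistical
conditions themselves (cohort structure, prevalence, mechanisms) are
the surveyed ones throughout; only B and replicate counts scale.

## Known limitations

* The reconstruction is faithful to published totals but not to the
  unpublished microdata; per-individual Monte-Carlo p-values on it are
  convention- and reconstruction-dependent (documented above).
* The clustering test is Monte-Carlo only; p-values far below 1/B are
  reported as bounds.
* No inbreeding-loop optimisations; kinship is O(n²) memory, fine for
  cohorts of hundreds, not for biobanks.
* Ascertainment (the village was surveyed *because* it was severely
  affected) is outside the model: the tests condition on the observed
  case count and say nothing about absolute prevalence.
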