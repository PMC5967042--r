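---
title: "Methods: burden scoring, population contrasts, and the synthetic cohort"
author: "grburden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: burden scoring, population contrasts, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grburden)
```

# The model

## Score

The package scores each individual for the cumulative burden of
trait-lowering alleles over an annotated variant panel. With
effect-allele counts $c_{ij} \in \{0,1,2\}$ and positive per-allele
effect sizes $\beta_i$ (in standard deviations of the trait per
allele), the burden over a subset of $N$ variants is

$$\mathrm{GRB}_j \;=\; N\,\frac{\sum_i c_{ij}\beta_i}{\sum_i \beta_i}.$$

The rescaling constant $N$ is a deliberate design choice. The
literature describes the score only as a weighted allele count
"rescaled by the sum of the effect sizes", which fixes the ratio but
not the constant in front of it. Multiplying by $N$ places the score
on the allele-count scale $[0, 2N]$ — for a 59-variant panel, 0 to 118
— which matches the magnitude of published group means (low 60s) and
makes the weighted and unweighted scores directly comparable. Any
other constant rescales all group differences by the same factor and
leaves every significance test unchanged; `compute_grb()` exposes it
as `scale_constant` for users who need a different convention.

Assumptions baked into the score: additivity of allele effects, no
linkage between the panel variants (each contributes independently),
and effect sizes transportable across the populations being compared.
The last assumption is the strongest one; the package computes the
score identically in every group and leaves its justification to the
analyst's panel selection.

## Genotype orientation

Dosages are counts of the annotated *effect* allele, not the VCF ALT.
`extract_dosages()` matches variants by chromosome and position
(rsIDs are used for labelling only — ID columns are unreliable),
compares alleles literally to REF/ALT, and flips the ALT count to
$2 - \text{ALT count}$ when the effect allele is the reference. No
strand flipping or palindromic-SNP resolution is attempted: the
intended workflow is a single harmonized genotype source, and any
record whose allele pair does not match is excluded and reported
rather than guessed at. Multi-allelic records are decomposed per ALT
allele and used only if REF plus one ALT equals the annotated pair.
Missing genotypes stay missing (`NA`), never silently zero.

## Missing-data policy

Scores renormalize weights per individual: both sums in the formula
run over that individual's observed variants while $N$ stays the full
subset size. This is equivalent to imputing each missing genotype with
the individual's own weighted mean dosage, is exact for complete data
(the intended reference cohort has complete genotypes), and avoids the
downward bias of treating missing as zero. An individual with no
observed genotypes in a subset gets a missing score.

# Group statistics

* **Mean comparisons** use Welch's unequal-variance two-sample t-test.
  The source analysis says only "t-test"; Welch is the safer default
  for the unequal group sizes (347–661) and unequal variances seen in
  practice, and a pooled-variance option is kept behind
  `var_equal = TRUE` for sensitivity. Confidence intervals use the
  Welch degrees of freedom, two-sided $\alpha = 0.05$.
* **Rare classification** folds frequencies: a variant is rare in a
  group iff $\min(\mathrm{RAF}, 1-\mathrm{RAF}) < 0.05$ *within that
  group*, making the call invariant to which allele is labelled the
  effect allele. Group-vs-reference contrasts use the two-sided Fisher
  exact test, appropriate for the small counts involved.
* **The selection test** deliberately uses *unfolded* RAF tails
  ($<0.05$ vs $>0.95$, or the $<0.5$ vs $\ge 0.5$ half-split): the
  question is whether the *trait-lowering* allele specifically is
  pushed rare. Because tail counts are tiny (often under 10), equality
  of tail proportions is tested with an exact binomial sign
  construction restricted to the tail variants rather than a
  chi-squared approximation. The exact test is conservative: its
  type-I error is at most the nominal 5%.
* **Fixation** follows the operational definition RAF $\ge 0.99$, and
  a variant is reported only when it is still polymorphic
  (RAF $< 0.99$) in the reference group — fixation everywhere carries
  no contrast.
* **No multiplicity correction** is applied anywhere; all p-values
  are nominal, matching the descriptive, table-style reporting the
  package reproduces. Users scanning many panels should adjust
  externally.

Boundary conventions worth knowing: the deleteriousness split sends
median-valued CADD scores to the *benign* side (`cadd <= threshold`),
which is what reproduces a 30/29 split of a 59-variant panel at median
2.8; histogram bins on $[0,1]$ are right-open except the last, so a
frequency of exactly 1 lands in the top bin; and in half-split mode a
RAF of exactly 0.5 counts as common.

# The synthetic cohort

`simulate_cohort()` exists so the full pipeline — file parsing,
orientation, scoring, every group statistic — runs and is tested with
no external data. Its stated world:

| parameter | default | rationale |
|---|---|---|
| variants | 59 unlinked biallelic SNPs | the size of the motivating panel |
| populations | AFR 661, AMR 347, EAS 504, EUR 503, SAS 489 | reference-cohort sample sizes |
| $F_{ST}$ | 0.1 per population | typical continental-scale human differentiation (≈0.08–0.12) |
| ancestral RAF | Uniform(0.05, 0.95) | common variants, as expected for GWAS index SNPs |
| effect sizes | Uniform(0.01, 0.09) s.d./allele | the range of published per-allele birthweight effects |
| P(effect allele ancestral) | 33/59 | the panel's ancestral/derived composition |
| CADD phred | Exponential(rate 0.25) | non-negative, right-skewed, median ≈ 2.8 — the panel's median |

Population frequencies follow the Balding–Nichols model: for ancestral
frequency $p$ and differentiation $F$, the population RAF is
$\mathrm{Beta}\!\big(p\tfrac{1-F}{F},\,(1-p)\tfrac{1-F}{F}\big)$, with
mean $p$ and variance $F\,p(1-p)$ — the minimal standard model with a
controllable $F_{ST}$. Genotypes are Binomial(2, RAF): exact
Hardy–Weinberg proportions within populations. The VCF writer places
the effect allele as ALT for a random half of the variants and as REF
for the rest, so round-tripping exercises both orientation branches.
Monomorphic draws are retained on purpose to feed the fixation and
rare-variant edge cases.

What the generator does **not** emulate — and therefore what a green
test does not establish: linkage disequilibrium between variants,
admixture or any demographic history beyond a star-shaped
differentiation, genotype error or uncertainty, missingness patterns,
sex-linked variation, and any real relationship between CADD, allele
age and frequency. Green synthetic tests establish that the
*computations* are correct under the stated model, not that the
scientific conclusions transfer to any real cohort.

The truth file records the drawn per-population RAFs and the analytic
expectation $E[\mathrm{GRB}] = N \sum_i 2 p_{ik}\beta_i / \sum_i
\beta_i$; parameter-recovery tests compare pipeline estimates against
this *conditional* expectation (given the drawn frequencies), so the
only residual randomness is binomial genotype sampling and a
3-standard-error criterion has ≈99.7% coverage.

# Numerical and testing choices

* Score-range validation allows a relative $10^{-8}$ overshoot of
  $[0, 2N]$: the rescaling arithmetic can land an ulp outside.
* All TSV output formats numbers through a fixed `%g` with 10
  significant digits, making reruns byte-identical across platforms;
  determinism is asserted at the md5 level in the tests.
* The Welch test, Fisher exact test and exact binomial test are
  delegated to `stats::`; the test suite verifies each against an
  independent oracle (the textbook Welch formula, exhaustive
  hypergeometric enumeration, the closed-form binomial tail) so the
  implementation and its check never share code.
* Exhaustive Fisher verification over *all* tables with margins ≤ 80
  is computationally out of reach (~10⁷ tests); the suite enumerates
  all tables with total $n \le 14$ exhaustively and samples 300 larger
  tables with margins up to 80.
* Calibration simulations are scaled to the test budget and say so in
  comments: null calibration of the group comparison uses 200 seeds
  (band: 3 binomial standard errors around 5%), selection-test
  calibration uses 2000 replicates, parameter recovery 200 seeds.
* Degenerate paired contrasts (zero-variance differences) return
  p = 1 when the scores are identical and `NA` for a nonzero constant
  offset, where the t-statistic is undefined.
* Kernel density estimation falls back to a fixed bandwidth of 0.05
  when the default bandwidth selector fails (constant frequencies).

# Known limitations

* No LD pruning, clumping or p-value thresholding: the package scores
  the panel it is given.
* Effect sizes are taken at face value from the annotation; no
  shrinkage, no standard errors, no meta-analytic machinery.
* The selection test is a coarse frequency-tail contrast, not a formal
  selection scan (no iHS, XP-EHH or $F_{ST}$ outlier machinery).
* Annotation inputs (ancestral state, CADD) are consumed, never
  computed: polarization and deleteriousness scoring belong to
  upstream pipelines.
* Reproduction of the published reference-cohort tables requires the
  external genotype download and the published annotation supplement;
  the corresponding acceptance test documents the expected numbers and
  tolerances and activates only when those inputs are supplied.
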