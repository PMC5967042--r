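# grburden

Population comparison of polygenic risk burden from VCF genotypes.

`grburden` is an R package for asking a simple population-genetics
question about a panel of trait-associated variants: **do some
populations carry a systematically heavier burden of the
trait-lowering alleles than others, and does the burden's allele
frequency spectrum show signs of selection?** The motivating use case
is the panel of 59 autosomal SNPs associated with lower birthweight,
scored across the 26 populations / 5 super-populations of the 1000
Genomes Project, but the machinery is generic: any annotation table of
effect alleles with positive effect sizes, any VCF cohort, any grouping
panel.

It is aimed at statistical-genetics analysts who want the whole
pipeline — genotype orientation, scoring, group statistics, frequency
spectrum — as tested, reusable functions rather than a one-off script.

## The score and the statistics

For individual *j* and a subset of *N* variants with effect-allele
counts *c<sub>ij</sub>* ∈ {0, 1, 2} and per-allele effect sizes
*β<sub>i</sub>* > 0, the genetic risk burden is the weighted allele
count rescaled by the sum of the effect sizes:

```
GRB_j = N * ( Σ_i c_ij β_i ) / ( Σ_i β_i )        ∈ [0, 2N]
```

so the score lives on the allele-count scale (an unweighted variant,
`compute_unweighted_grb()`, is exactly Σ c<sub>ij</sub>). Group-level
analyses on top of the score and the per-group risk-allele frequencies
(RAF):

| analysis | function | statistic |
|---|---|---|
| burden vs reference group | `compare_grb_groups()` | Welch t, 95% CI of mean difference |
| RAF per group per variant | `compute_group_raf()` | Σ dosage / (2 × non-missing n) |
| rare-variant proportions | `classify_rare()` | folded MAF < 0.05; Fisher exact vs reference |
| fixed alleles | `detect_fixed()` | RAF ≥ 0.99 outside, < 0.99 in reference |
| purifying-selection check | `selection_test()` | exact binomial on RAF < 0.05 vs > 0.95 tails |
| deleterious vs benign strata | `within_group_strata_contrast()` | paired t within group |
| frequency spectrum | `frequency_spectrum()` | histogram + Gaussian-kernel density |

Variant strata (`stratify_variants()`) follow the panel annotation:
ancestral vs derived effect alleles, and deleterious (CADD phred >
threshold, default the panel median) vs benign (≤ threshold).

A Balding–Nichols simulator (`simulation_config()`,
`simulate_cohort()`) generates multi-population cohorts — VCF, sample
panel, annotation table and ground truth — with Hardy–Weinberg
genotypes and controllable between-population differentiation
(population RAF ~ Beta(p(1−F)/F, (1−p)(1−F)/F) around an ancestral
frequency p), so every stage is testable with no downloads.

## Worked example

Simulate the default synthetic world (five super-populations with 1000
Genomes sample sizes, 59 variants, FST = 0.1) and run all comparisons:

```r
library(grburden)
cfg   <- simulation_config(seed = 42)
paths <- simulate_cohort(cfg, "readme_demo")
rc    <- run_config(paths$vcf, paths$panel, paths$annotations,
                    "readme_demo/out", reference = "EUR")
res   <- run_compare(rc)
subset(res$tables$grb_comparison, subset_label == "all")
```

```
  subset_label n_variants group   n  mean    sd mean_diff  ci_low ci_high   p_value
1          all         59   EUR 503 69.41 4.636     0.000      NA      NA        NA
2          all         59   SAS 489 72.32 4.833     2.914  2.3237   3.504 2.937e-21
3          all         59   AMR 347 71.21 5.029     1.801  1.1330   2.468 1.587e-07
4          all         59   AFR 661 70.45 5.231     1.043  0.4739   1.612 3.372e-04
5          all         59   EAS 504 67.23 4.553    -2.182 -2.7501  -1.613 1.099e-13
```

Read: with this seed, simulated SAS carries on average ~2.9 more
trait-lowering alleles (on the 0–118 scale of 59 variants) than the
EUR reference, with a Welch 95% CI of 2.32–3.50. The rare-allele and
selection summaries from the same run:

```r
res$tables$rare_proportions
```
```
  group n_rare n_total proportion fisher_p
1   AFR      7      59      0.119    0.789
2   AMR     13      59      0.220    0.479
3   EAS     15      59      0.254    0.253
4   EUR      9      59      0.153       NA
5   SAS      8      59      0.136    1.000
```
```r
subset(res$tables$selection_test, mode == "tails")
```
```
   mode group n_rare n_common_reciprocal p_value conclusion
1 tails   AFR      2                   5  0.4531  no_excess
...
```

No group shows an excess of rare risk alleles over the reciprocal
common tail — as expected, since the simulator's ground truth contains
no selection. All tables are also written as TSV under
`readme_demo/out/` together with a JSON manifest (input checksums,
parameters, stratum sizes).

## Command line

```sh
Rscript inst/cli/grburden.R simulate --outdir demo --seed 42
Rscript inst/cli/grburden.R all --vcf demo/cohort.vcf \
    --panel demo/cohort.panel --annotations demo/annotations.tsv \
    --outdir demo/out --reference EUR
```

Subcommands `simulate`, `score`, `compare`, `all`; parameters can also
come from a JSON file via `--config`, with flags taking precedence.
Exit codes: 0 success, 2 configuration error, 3 input-format error,
4 analysis error.

## Real-data recipe

To score the real reference cohort: download the 1000 Genomes Phase 3
VCFs and the `integrated_call_samples` panel from the project site,
subset the VCFs to your annotation's positions (e.g.
`bcftools view -R positions.tsv`), and point `run_config()` at the
merged VCF, the panel and your annotation TSV (columns `rsid`,
`chrom`, `pos`, `effect_allele`, `other_allele`, `beta`,
`allele_state`, `cadd_phred`). No download helper is included.
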