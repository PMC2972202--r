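# rarestep

Data-driven aggregation tests for rare genetic variants.

## The problem

Individually testing rare variants (minor allele frequency below ~1%)
against a phenotype is hopeless at realistic sample sizes: each variant is
carried by a handful of people, so per-variant effect estimates are
unstable and uninformative.  Burden (collapsing) tests trade per-variant
resolution for power by aggregating many rare variants in a region into a
single per-individual score — but they force strong *a priori* choices:
which variants belong in the group, in which direction each acts, and with
what weight.  Functional-prediction algorithms that could inform these
choices disagree with each other much of the time.

`rarestep` implements a family of score tests over weighted, signed,
selected combinations of variants, and two data-driven ways of choosing
the combination: maximising over many candidate groupings
(allele-frequency thresholds, functional annotation groups, or both) and a
greedy **step-up** search that builds the best aggregated group
analytically, with no prior information at all.  Because every one of
these choices is made from the data, inference is by permutation of the
phenotype with the *entire* procedure recomputed in each permutation.

## The model

For dosages \(G_{ij}\) (minor-allele count of individual *i* at variant
*j*) each candidate model assigns every variant a multiplicative weight
\(w_j s_j \gamma_j\):

* \(w_j > 0\) — a continuous weight: constant, or the Madsen–Browning
  inverse standard deviation \(w_j = 1/\sqrt{n\,q_j(1-q_j)}\) with
  \(q_j = (m_j+1)/(2n_{ref}+2)\) estimated with pseudocounts in the
  controls (all subjects for a continuous trait);
* \(s_j \in \{+1,-1\}\) — the effect direction, fixed at +1 or estimated
  from the case/control frequency difference (trait–dosage covariance for
  continuous traits);
* \(\gamma_j \in \{0,1\}\) — inclusion: a hard MAF threshold, every
  observed MAF threshold, functional-annotation groups, or the step-up
  selection.

The aggregated score \(S_i = \sum_j w_j s_j \gamma_j G_{ij}\) is tested
with the score statistic

\[ T \;=\; \frac{\big(\sum_i (Y_i - \bar Y)\,S_i\big)^2}
               {\hat\sigma^2_Y \sum_i (S_i - \bar S)^2},
   \qquad \hat\sigma^2_Y = \tfrac1n \sum_i (Y_i - \bar Y)^2, \]

which is chi-squared with 1 df under the null for a single prespecified
model, and identical to the Rao score test of logistic (or linear)
regression of \(Y\) on \(S\).  For a set \(M\) of candidate models the
final statistic is \(T = \max_{m \in M} T_m\), and its p-value is the
add-one Monte-Carlo permutation p-value
\(p = (1 + \#\{b: T_b \ge T_{obs}\})/(B+1)\), with signs, weights and the
model search all re-estimated inside each permutation.  A CMC
(combined multivariate and collapsing) logistic-regression comparator
with an asymptotic chi-squared p-value is included.

The package also ships the simulation machinery to study these tests:
synthetic haplotype pools with a rare-heavy frequency spectrum and three
partially concordant functional-annotation algorithms, five generative
disease-model scenarios (fixed threshold, random threshold, continuous
penetrance, rare-plus-common, mixed deleterious/protective), logistic
intercept calibration to a target population prevalence, ascertained
case-control and quantitative-trait samplers, and a replicate-level
type-I-error / power driver.

## Worked example

Simulate one "gene" (a 40-variant haplotype pool), generate a
case-control study in which the 8 rare deleterious variants carry an odds
ratio of 3, and test with the signed step-up procedure and a fixed
0.01-threshold burden test:

```r
library(rarestep)

pool <- generate_haplotype_pool(p = 40, H = 100, concordance = 0.6, seed = 503)
cfg  <- scenario_config(scenario = 1, effect = 3, cutoff = 0.01,
                        n_cases = 1000, n_controls = 1000)
set.seed(7)
beta  <- scenario_betas(pool, cfg)            # log OR 3 on 8 rare functional variants
model <- disease_model(pool, beta, prevalence = 0.01)
dat   <- sample_case_control(pool, model, 1000, 1000)

summary(rare_burden_test(dat$genotypes, dat$phenotypes, method = "step",
                         signed = TRUE, B = 999, seed = 1))
#> 	Rare-variant aggregation association test
#>
#> method: C,s=±,step   (n = 2000 individuals, 40 variants, dichotomous trait)
#> statistic = 93.915, p-value = 0.001 (999 permutations)
#> best model: C,s=±,step
#> variants in the selected model:
#>   v17, v24, v35, v39, v21, v14, v37

rare_burden_test(dat$genotypes, dat$phenotypes, method = "cast",
                 cutoff = 0.01, B = 999, seed = 2)
#> method: C,s=1,MAF<=0.01   (n = 2000 individuals, 40 variants, dichotomous trait)
#> statistic = 54.549, p-value = 0.001 (999 permutations)
```

The step-up search recovered five of the eight causal variants (v14, v21,
v24, v35, v39 — the others are too rare to be seen in this sample)
plus two passengers, and both procedures reject decisively: p = 0.001 is
the smallest value 999 permutations can produce.  Real data come in
through `read_genotypes()` (TSV dosage matrix or biallelic VCF),
`read_phenotypes()` and `read_annotations()`.

Power studies run through the same machinery:

```r
res <- run_power_study(pools = list(pool),
                       scenarios = scenario_config(5, effect = 4, deleterious_fraction = 0.5,
                                                   n_cases = 1000, n_controls = 1000),
                       methods = list(burden_method("cutoff", signed = TRUE),
                                      burden_method("cutoff", signed = FALSE)),
                       n_sims = 100, B = 199, seed = 405)
```

A thin command-line front end wraps these functions:

```sh
Rscript inst/cli/rarecomb.R makepool --variants 40 --haplotypes 100 --seed 1 --out pool.json
Rscript inst/cli/rarecomb.R simulate --pool pool.json --scenario 1 --or 3 --out-prefix sim
Rscript inst/cli/rarecomb.R test --geno sim_geno.tsv --pheno sim_pheno.tsv \
        --method step --signed --permutations 999 --seed 1 --out result.tsv
```

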