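---
title: "Aggregation tests for rare variants: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aggregation tests for rare variants: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rarestep)
```

## The testing framework

The package tests the association between a region's rare variants and a
phenotype $Y_i$ (dichotomous 0/1 or continuous) through a per-individual
aggregated score
$$S_i = \sum_{j=1}^p w_j\, s_j\, \gamma_j\, G_{ij},$$
where $G_{ij} \in \{0,1,2\}$ is the minor-allele dosage.  The three
multiplicative components factor the modelling choices every burden-style
test must make:

* **Weight $w_j > 0$.**  `constant_weights()` gives the plain dosage-sum
  burden (a dosage analogue of the cohort allelic sums test);
  `madsen_browning_weights()` upweights rarer variants by the inverse
  standard deviation of the dosage under a control-estimated allele
  frequency, $w_j = 1/\sqrt{n q_j (1-q_j)}$ with
  $q_j = (m_j+1)/(2 n_{ref}+2)$.  The $+1$ pseudocounts in numerator and
  denominator keep weights finite for variants absent from the reference
  group.  $n_{ref}$ is the number of controls for a dichotomous trait and
  the full sample for a continuous one; $n$ is always the full sample.
* **Sign $s_j \in \{\pm 1\}$.**  Either all $+1$ ("all variants
  deleterious"), or estimated: $+1$ when the minor allele is more
  frequent in cases than controls, $-1$ when less (continuous traits use
  the sign of the trait–dosage covariance).  The extracted sources for
  this convention are ambiguous, so the package fixes the convention that
  $s_j = +1$ means risk-increasing; since the statistic squares the
  aggregate, only relative signs matter.  Exact ties get $+1$, so a
  signed test with no directional information collapses onto the
  unsigned test.  Dichotomous ties are detected in integer arithmetic
  (cross-multiplied allele counts), never by comparing floats.
* **Inclusion $\gamma_j \in \{0,1\}$.**  A hard MAF threshold
  ($0 < \text{maf} \le c$, boundary inclusive so a threshold taken from
  an observed MAF includes its own variant), the family of all observed
  MAF thresholds, functional-annotation groups crossed with thresholds,
  or the step-up selection below.  Monomorphic variants are always
  excluded: they carry no information and would make MAF-indexed model
  families ill-defined.

Sample MAFs are computed from the full sample (cases plus controls), the
convention of the variable-threshold literature; control-only frequencies
appear only inside the Madsen–Browning weight, where the estimator is
defined that way.

### The score statistic

Each candidate model is scored with
$$T = \frac{\left(\sum_i (Y_i - \bar Y) S_i\right)^2}
           {\hat\sigma^2_Y \sum_i (S_i - \bar S)^2},
  \qquad \hat\sigma^2_Y = \frac1n \sum_i (Y_i - \bar Y)^2 .$$
With the maximum-likelihood (1/n) variance this is exactly the Rao score
test of a generalised linear regression of $Y$ on $S$ — logistic for a
dichotomous trait, linear for a continuous one — and is asymptotically
$\chi^2_1$ under the null.  The test suite verifies the logistic identity
against an independently coded likelihood-based oracle to $10^{-10}$ and
the $\chi^2_1$ calibration by simulation.  Degenerate inputs (constant
$S$, e.g. an empty model, or constant $Y$) score 0 rather than erroring,
so maximisation over families containing empty groupings stays well
defined.  The statistic is invariant to affine rescaling of $S$, hence to
any permutation-constant rescaling of the weights.

For a family $M$ of candidate models the reported statistic is
$T = \max_{m \in M} T_m$ with first-in-set-order tie-breaking, so results
are deterministic given the family's construction order.

### Step-up selection

`step_up()` searches for the best single aggregated group directly: the
univariate statistic is computed for every polymorphic variant (with the
chosen weight and sign model applied marginally, estimated once from the
full data rather than re-estimated per subset); the best variant seeds
the group; then the variant whose addition gives the largest statistic is
appended as long as the statistic strictly increases.  A plateau (the
best addition equalling the current statistic) terminates the search, and
ties among candidate additions break towards the lowest variant index for
determinism.  The search costs at most $O(p^2)$ statistic evaluations.

Internally all of this runs on a precomputed centred cross-product matrix
$C_{jk} = \sum_i (G_{ij}-\bar G_j)(G_{ik}-\bar G_k)$: for coefficients
$a_j = w_j s_j \gamma_j$ the statistic is
$(\sum_j a_j u_j)^2 / (\hat\sigma^2_Y\, a^\top C a)$ with
$u_j = \sum_i (Y_i - \bar Y) G_{ij}$, and the greedy loop maintains
running group sums so each candidate evaluation is $O(1)$.  Because
column scaling commutes with centring, $C$ is computed once per dataset
and reused across all permutations; only the $O(np)$ vector $u$, the
signs and the weights are phenotype-dependent.  The suite checks the
incremental path against a plain re-implementation built on the direct
aggregate-score formula, and against exhaustive best-subset search (with
which it must coincide for $p \le 2$ and which it can never exceed).

### Permutation inference

Every data-adaptive choice — signs, control-frequency weights, the model
search, the step-up path — biases the maximised statistic upward, so
p-values come from permuting the phenotype vector (equivalently the
individuals, preserving the genotype LD structure) and re-running the
*entire* procedure each time.  The add-one estimator
$p = (1+\#\{T_b \ge T_{obs}\})/(B+1)$ is used: it is never zero and gives
a valid (super-uniform) test at any $B$.  The suite includes a negative
control demonstrating why full re-computation matters: freezing the
observed-data signs across permutations inflates the null rejection rate
at $\alpha = 0.05$ roughly twenty-fold, while the full procedure stays at
the nominal level.  An optional adaptive rule stops after 10 exceedances
(configurable) and reports $p$ from the permutations seen — the exact
stopping rule is the package's own choice, as only the idea of early
stopping is established.

Default $B = 199$ makes $(B+1)\alpha$ an integer at $\alpha = 0.05$, so
rejection at $p \le \alpha$ is exactly attainable; larger studies would
use 999 or more.  The CMC comparator (collapsed any-rare-variant
indicator plus one dosage term per common variant, likelihood-ratio
tested against the intercept-only logistic model) instead uses its
asymptotic $\chi^2$ p-value, the usual practice because multivariate
logistic refits inside permutations are prohibitively slow; separated or
non-converged fits return `NA` with a warning and are excluded from power
tallies.

## The simulator

`generate_haplotype_pool()` emulates the kind of deep-sequenced
candidate-gene data such studies draw on: a pool of $H$ haplotypes (default
100) over $p$ variants (default 40) with random-simplex frequencies.
Individuals are two independent haplotype draws (Hardy–Weinberg random
mating); drawing whole haplotypes preserves LD between variants sharing
haplotypes.  Defaults and their rationale:

* **Spectrum.**  85% of variants target a population MAF log-uniform on
  $[5\times10^{-4}, 0.01]$ and the rest log-uniform on $[0.01, 0.35]$,
  matching the rare-heavy spectra reported for deeply sequenced coding
  regions (roughly 85% of discovered SNVs below the rare cutoff).  Each
  variant's carrier haplotypes are chosen by scanning all haplotypes in
  random order and keeping any that still fits under the target mass, so
  the realised MAF tracks the target and carriers scatter across
  haplotypes.  (An earlier prefix-based rule silently parked most rare
  variants on the single rarest haplotype, in perfect mutual LD, which
  both distorted the spectrum and starved disease models of causal
  burden.)
* **Annotations.**  30% of variants are nonsynonymous; 40% of those are
  latently deleterious; nonsynonymous variants carry a deleteriousness
  score in $[0,1]$ (0 = most damaging, like a tolerance index:
  deleterious variants score below 0.05).  Three annotation algorithms
  each report the latent state with accuracy
  $a = (1+\sqrt{2\kappa-1})/2$, giving expected pairwise agreement
  $\kappa$ (default 0.6, the "limited concordance" regime reported for
  SIFT/PMUT/PolyPhen-style tools; $\kappa = 1$ makes them unanimous).
  Pools are drawn conditional on every algorithm calling at least one
  rare variant deleterious, mirroring study designs that drop genes with
  no putatively damaging variant; `require_functional = FALSE` disables
  the conditioning.
* **Not emulated:** sequencing or genotyping error, missing genotypes,
  population structure, multi-allelic sites, and realistic gene-specific
  LD beyond haplotype sharing.  Tests passing on these pools therefore
  speak to the statistical procedure, not to robustness against data
  artefacts.

### Disease scenarios

`scenario_betas()` implements five generative effect models, with every
per-variant magnitude capped at $\log(\text{OR})$ so no allele
contributes more than the nominal odds ratio:

1. **Fixed threshold** — $\beta_j = \log(\text{OR})$ for functional
   variants with MAF $\le c$;
2. **Random threshold** — $c$ redrawn each replicate uniformly from the
   pool's distinct MAFs below 0.05 (a draw below every functional
   variant's MAF yields a legitimate null replicate);
3. **Continuous penetrance** — $\beta_j \propto (1 - \text{score}_j)$
   over nonsynonymous variants;
4. **Rare plus common** — decay $k_j = \lambda/(\lambda+\text{maf}_j)$
   rescaled to 1 at the rarest functional variant.  The decay's exact
   functional form is the package's own choice; it satisfies the
   qualitative requirements (small $\lambda$: rare variants strong,
   common ones negligible; large $\lambda$: effects even out);
5. **Mixed direction** — rare functional variants split so that a
   fraction $f$ of their total MAF is deleterious ($+\log\text{OR}$) and
   the rest protective ($-\log\text{OR}$).  The split takes a
   random-order prefix whose cumulative MAF lands closest to
   $f \times$ total, which is exact at $f \in \{0, 1\}$ (so $f = 1$
   degenerates to scenario 1).  Study arms use $f = 0.5$ and $0.8$.

For dichotomous traits `calibrate_intercept()` solves
$E_G[\operatorname{expit}(\beta_0 + G\beta)] = K$ for the intercept, with
the expectation exact over all $H^2$ haplotype pairs whenever that is
enumerable ($\le 10^6$ pairs; the root is then found to
$|P - K| \le 10^{-6}$) and Monte-Carlo otherwise.  The prevalence target
defaults to $K = 0.01$.  Case-control samples are rejection-sampled from
the unascertained population; a budget guard errors when the expected
number of rejections is unreasonable rather than spinning.  Sampled
genotype matrices keep the pool's allele orientation (sample MAFs are
reported as $\min(\hat q, 1-\hat q)$), because flipping a column inside
an ascertained sample would silently change which allele a weight or
threshold refers to.  Continuous traits are
$Y_i \sim N(\sum_j \beta_j G_{ij}, 1)$ with per-dosage mean shifts in
place of log odds ratios.

## Study-level checks and problem sizes

The acceptance checks re-derive the framework's calibration claims at
sizes chosen to finish in minutes on a single core:

* **Type-I error**: 3 pools × 300 null replicates (250 cases / 250
  controls — a scaled-down version of the 1000/1000 design; effects all
  zero) × 199 permutations of the signed step-up test; the rejection
  rate at $\alpha = 0.05$ must fall in the exact binomial 99% interval
  around 0.05 at 900 replicates, roughly $[0.031, 0.073]$.
* **Prevalence calibration**: after calibrating under scenario 1 with
  OR 2, the Monte-Carlo prevalence of $10^6$ unascertained individuals
  must lie within $\pm 0.001$ of 0.01.
* **$\chi^2_1$ calibration**: 10,000 null replicates of the
  fixed-single-model statistic (a 2000-individual continuous-trait
  design) must have mean in $[0.95, 1.05]$ and Kolmogorov–Smirnov
  distance to $\chi^2_1$ below 0.02.
* **Properties**: step-up versus exhaustive subset search;
  super-uniformity of permutation p-values; the frozen-signs negative
  control; the likelihood-oracle identity; the signed-versus-unsigned
  power ordering under the mixed-direction scenario (OR 4, 50/50 split,
  1000/1000, 3 pools × 100 replicates, fixed-threshold tests,
  CI-separated); and byte-identical outputs across two seeded runs.

The power driver `run_power_study()` re-seeds each replicate from the
master seed and a counter, so any replicate is reproducible in
isolation, and pools replicates across haplotype pools exactly as a
multi-gene study averages power across genes.

## Limitations

* No covariate adjustment (stratification or residual-based workflows
  would be the natural extensions) and no handling of missing genotypes
  — missingness is rejected rather than imputed, because silent
  imputation changes the statistic.
* Asymptotic p-values are available only for the CMC comparator;
  everything data-adaptive is permutation-only by design.
* The step-up search is greedy: it can stop short of the best subset
  (it provably cannot exceed it), and a step-down variant is deliberately
  not offered.
* VCF input is a convenience reader restricted to biallelic sites with a
  GT field.
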