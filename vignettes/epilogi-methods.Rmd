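---
title: "Greedy multi-signature variant selection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Greedy multi-signature variant selection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epilogi)
```

## The selection model

GWAS panels are extreme "large p, small n" problems: thousands to
millions of variant dosages, hundreds to thousands of samples, heavy
local correlation from linkage disequilibrium (LD). The package
implements forward selection in the generalized Orthogonal Matching
Pursuit family. Writing $S$ for the current selected set, each
iteration:

1. fits the working model on $S$ — ordinary least squares for a
   continuous outcome, maximum-likelihood logistic regression for a
   binary one, always with an intercept;
2. computes its residuals $r$ — raw residuals $y - \hat y$ for OLS,
   signed deviance residuals
   $d_i = \mathrm{sign}(y_i - \hat p_i)\sqrt{-2[y_i\ln\hat p_i + (1-y_i)\ln(1-\hat p_i)]}$
   for the logistic model;
3. scans all remaining variants for the one maximizing
   $|\mathrm{cor}(x_j, r)|$ — the variant carrying the most information
   about what the current model gets wrong;
4. accepts it iff the likelihood-ratio statistic
   $D = 2(\ell_{S \cup \{j\}} - \ell_S)$ is significant against
   $\chi^2_1$ at level $\alpha$ (one coefficient is added per step, so
   one degree of freedom).

Selection stops at the first rejection, at candidate exhaustion, or at
the `max_features` cap (default 50, a practical bound for very wide
panels). The ordered accepted set is the **reference signature**.

The statistic is also reported on a delta-BIC scale,
$\Delta\mathrm{BIC} = D + \ln n$, under which significance levels map
to sample-size-dependent thresholds via
`pvalue_to_dbic(alpha, n) = qchisq(1 - alpha, 1) + log(n)`; at
$n = 1177$ the levels $10^{-6}$ and $0.8$ correspond to 31.00 and
7.13. The chi-squared p-value on $D$ is the operative accept/reject
rule; the delta-BIC value is bookkeeping on a scale practitioners
recognize.

### Why residual correlation scales

The scan is a single pass over the variant columns: cost linear in the
number of variants and independent of how many variants were *not*
selected beyond that pass. The scan is chunked — each chunk keeps its
best candidate, then the global best is taken. Chunking is purely an
execution detail: per-column sums are accumulated in a fixed order
(`colSums`, not a blocked matrix product), so the scan result and hence
the whole path are bit-identical for every chunk size and chunk order.
Ties are broken to the lowest column index, making the algorithm fully
deterministic.

### The threshold grid and path prefixes

Model search evaluates selection across a grid of significance levels
(default `threshold_grid()`: 10 points log-spaced between $10^{-6}$
and 0.8). A key structural fact keeps this cheap: the greedy path at a
stricter $\alpha$ is exactly the prefix of a looser-$\alpha$ path up to
the first step whose p-value exceeds the stricter level — earlier
accepted steps do not depend on the threshold, and selection halts at
the first rejection. `truncate_path()` exploits this; the test suite
verifies it against direct re-runs.

### Collinearity

A candidate whose dosage column is numerically collinear with the
current design (residual variance below $10^{-10}$ after projection)
cannot enter the model; it is skipped, recorded on the path object, and
remains available to the equivalence stage — an exact duplicate of a
selected variant is the archetypal equivalent substitute.

## Statistically equivalent substitutes

Two variants $R$ (selected) and $C$ (candidate) are *informationally
equivalent* with respect to the iteration residuals $r$ when both
conditional independencies hold:
$\mathrm{Ind}(R; r \mid C)$ and $\mathrm{Ind}(r; C \mid R)$.
Under linearity each test is a partial correlation: residualize both
arguments on the conditioning variable, Fisher-z-transform the
correlation of the residuals, and refer
$\mathrm{atanh}(\hat\rho)\sqrt{n - 4}$ to a standard normal.
Independence is *accepted* when the p-value exceeds `alpha_eq`
(default 0.05). Degenerate conditioning — a variant fully explained by
the conditioning column, as with exact duplicates — returns
$\rho = 0, p = 1$, so exact duplicates are always detected for any
`alpha_eq` below 1.

Two design points deserve emphasis:

* **Which residuals?** For the variant selected at step $k$, the
  residuals are those of the model on the first $k - 1$ selected
  variants, *excluding* $R$. If $R$ were included, OLS residuals would
  be orthogonal to $R$ by construction and both tests would be vacuous;
  the exclusive reading is the only informative one, and it matches the
  intuition "at the moment $R$ was chosen, $C$ would have served".
* **Detection is statistics, not matching.** The two tests each spend
  `alpha_eq` of type-I error under true equivalence, so even a perfect
  (non-duplicate) substitute is accepted in roughly
  $1 - 2\,\alpha_{eq}$ of datasets, and a highly correlated but
  genuinely distinguishable proxy — say LD $r \approx 0.9$ at
  $n = 1000$ — is *correctly* rejected, because its unique variation
  carries detectable signal. The test suite's equivalence fixtures are
  built with this in mind (near-duplicates one genotyping error apart).

Candidates are prescreened by residual correlation
(`|cor(C, r)| >= prescreen_fraction * |cor(R, r)|`, default fraction
0.5) purely to bound cost; prescreening can only drop candidates that
would anyway fail the full tests at practically relevant settings, and
the suite checks that screened results are a subset of unscreened ones.
Classes are computed only against the reference signature — no
recursion into substituted signatures. The number of distinct
signatures is $\prod_k (1 + |\text{class}_k|)$;
`enumerate_signatures()` lists them deterministically (reference first,
then single substitutions in path order, then pairs, ...).

## The phenotype simulator

Real GWAS matrices cannot ship with a package; the simulator provides
genotypes with the features that matter for selection benchmarks and a
known causal truth.

* **Genotypes.** Per-variant allele frequency uniform on `maf_range`
  (default [0.05, 0.5]); two haplotypes per sample from a stationary
  AR(1) latent-Gaussian process with adjacent-variant correlation
  `ld_rho` (default 0.2), thresholded at the frequency quantile; dosage
  is the haplotype sum. This produces valid 0/1/2 dosages, the intended
  frequencies, and LD that decays geometrically with distance.
* **Causal positions.** `gaussian` mode samples causal indices with
  Normal-density weights around a random anchor; `gamma` mode walks
  from the anchor with Gamma(2) gaps, wrapped and deduplicated. Both
  produce positionally clustered causal sets (scale `position_spread`,
  default 0.02 of the panel length) as real causal loci cluster within
  regions.
* **Phenotype.** Effects $\beta \sim N(0, 1)$ per causal variant
  (the simplest zero-mean choice; any continuous zero-mean law would
  do, and the drawn effects are recorded in the truth object);
  genetic value $g = X_c\beta$ on centred dosages; noise variance
  $\mathrm{var}(g)(1 - h^2)/h^2$ calibrated against the *realized*
  genetic variance so the genetic component explains a fraction $h^2$
  in-sample. $h^2 = 1$ yields a deterministic phenotype, $h^2 = 0$
  pure noise.

Presets pin the benchmark conditions: `scenario_I` (Gaussian positions,
20 causal variants, $h^2 = 0.7$) and `scalability` (the same with
gamma positions), both at 1307 samples by 5000 variants by default —
desk-scale stand-ins for panels two orders of magnitude wider.

What the simulator does **not** emulate: population structure and
relatedness, dominance/epistasis, missingness mechanisms, allele-
frequency/effect-size coupling. Passing recovery tests on simulated
data therefore says the algorithm works under clean polygenic
additivity with local LD — not that it is robust to confounding.

## Evaluation and the univariate baseline

`tpr_fdr()` implements recovery metrics: TPR is the fraction of causal
variants recovered, FDR the fraction of the selection that is
non-causal (0 for an empty selection, avoiding 0/0).
`tpr_fdr_with_equivalents()` widens the selection with all equivalence
class members first — a causal variant found only as a substitute still
counts. `univariate_gwas_select()` is the standard-practice baseline:
per-variant marginal tests (slope t-test for continuous outcomes, a
score test for logistic regression for binary ones) against the
genome-wide threshold $5\times10^{-8}$, no LD clumping. Its
characteristic failure modes — selecting both members of a duplicated
pair, missing variants that only matter jointly — are what the greedy
selector is designed to avoid, and the suite contrasts them directly.

## Configuration search and honest performance estimation

`run_automl()` wraps selection in a small model-search harness. A
configuration is (selection threshold, equivalence threshold, cap,
imputation mode, model family + hyper-parameters); the default grid
crosses the 10 thresholds with three model settings (ridge at two
penalties, random forest), gated by task. Cross-validation (default
10-fold, folds shared across configurations for paired comparison) runs
the *entire* pipeline inside each fold — imputation statistics and
selection are computed on the training part only, so no information
leaks from held-out samples into the selection.

Because many configurations are tried, the raw cross-validated score of
the winner is optimistic (winner's curse). The bootstrap-bias-corrected
estimate removes this: for each of `B` (default 500) bootstrap draws of
sample indices, the configuration winning on the pooled in-bag
out-of-fold predictions is scored on the out-of-bag samples; the
corrected estimate is the mean of those out-of-bag scores, the 95%
interval their 2.5/97.5 percentiles. No samples are lost to estimation:
the final model is refit on all data with the winning configuration,
and its reference signature plus equivalence classes are attached to
the report.

## Numerical choices

* Probability clipping at $\varepsilon = 10^{-10}$ in logistic
  log-likelihoods and deviance residuals; logistic fits capped at 100
  IRLS iterations with a ridge-stabilized fallback (flagged on the
  fit) for separable data.
* RSS floored at $10^{-300}$ in the Gaussian profile log-likelihood; a
  perfect fit terminates selection via the zero-variance-residual check
  before the floor matters.
* Collinearity tolerance $10^{-10}$ on partial variance; scan
  zero-variance tolerance $10^{-12}$.
* All ties (scan maxima, bootstrap winners, imputation modes) break to
  the lowest index/value for determinism.
* Single-predictor ridge configurations fall back to an unpenalized
  `lm`/`glm` fit (the ridge backend requires two or more columns); with
  one predictor the penalty is immaterial at the default settings.

## Problem sizes

The shipped tests run recovery at 1307 samples by 5000 variants over
20 replicates, null-selection control at 300 by 1000 over 200
replicates, and the heritability-ceiling check at 20000 samples with
20 causal variants among 100 — sizes chosen so the full suite completes
in minutes on one core while keeping every statistical assertion
comfortably powered. The reproduction script uses 20000 samples by
1000 variants, averaged over 10 replicates.

## Known limitations

* Linear/logistic working models only; purely additive genetics.
* Equivalence is pairwise against the reference signature; no search
  for equivalent sets of different cardinality, and no full
  multiple-Markov-boundary machinery.
* No population-structure correction; on structured cohorts the
  selector will pick up stratification signal like any unadjusted
  method.
* The univariate baseline deliberately omits LD clumping and
  permutation thresholds; it represents the plain textbook pipeline.

## A worked example

```{r example, eval = FALSE}
set.seed(1)
sim <- simulate_gwas(scenario_preset("scenario_I"), seed = 1)
path <- epilogi_select(sim$genotypes, sim$phenotype, alpha = 1e-4)
tpr_fdr(selected_variants(path), sim$truth$causal_indices)
sg <- find_equivalents(sim$genotypes, path, sim$phenotype)
enumerate_signatures(sg, limit = 5)
```
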