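---
title: "Gene-level FDR control for grouped eQTL tests: models and methods"
author: "groupfdr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-level FDR control for grouped eQTL tests: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The testing problem

A cis-eQTL study asks, for each of $N$ genes, whether any of the $m_i$ SNPs
local to gene $i$ is associated with its expression. The natural unit of
discovery is the gene (the "eGene" question): the gene-level null
$H_{0i}$ is the intersection of the $m_i$ SNP-level nulls. groupfdr
controls the false discovery rate across these $N$ grouped hypotheses.

Two structural facts make eQTL data special. First, when a gene has an
eQTL, conditional analyses support a single dominant local signal, so we
model exactly one causal SNP per alternative gene, uniformly placed among
its $m_i$ SNPs (randomizing SNP order enforces the uniformity assumption
when in doubt). Second, effect sizes vary across genes, which we capture
with a random effect rather than a fixed alternative.

## The two-group random-effects model

Let $Y_i$ be the (covariate-residualized, standardized) expression vector
of gene $i$ and $X^{(i)}$ its $m_i \times n$ genotype matrix, treated as
fixed. With prior null probability $\pi_0$,

$$\lambda_i = P(H_{0i} \mid Y_i, X^{(i)}) =
\frac{\pi_0 f_0(Y_i)}{\pi_0 f_0(Y_i) + (1 - \pi_0)\,
\frac{1}{m_i}\sum_{j=1}^{m_i} f_1(Y_i \mid X^{(i)}_j)},$$

the gene's local false discovery rate (lfdr). The genotype marginal
cancels from this ratio, so no model of SNP dependence is needed. Under
the null $f_0 = N_n(0, I)$; given causal SNP $j$ and effect $\beta$
(the expression-genotype correlation),
$f_1(\cdot \mid X_j, \beta) = N_n(\beta X_j, (1 - \beta^2) I)$, which
keeps the unconditional variance of $Y_i$ equal to one. Across genes the
effect is random on the variance-stabilized Fisher scale:
$t = \sqrt{n-3}\,\mathrm{atanh}(\beta) \sim N(0, \sigma^2)$. The two
hyperparameters $(\pi_0, \sigma)$ are estimated from all genes jointly —
an empirical-Bayes step — and plugged into $\lambda_i$.

Given lfdr values, **adaptive thresholding** sorts them ascending and
rejects the largest prefix whose running mean is at most the target
$\alpha$; the running mean is exactly the estimated FDR of the rejected
set, which is what makes the rule calibrated when the lfdr values are
consistently estimated posterior probabilities.

## Full-data fit: EM with adaptive Gauss-Hermite quadrature

`reg_fdr()` maximizes the composite likelihood
$\prod_i \{\pi_0 f_0(Y_i) + (1-\pi_0) \frac{1}{m_i}\sum_j f_1(Y_i\mid X_j)\}$
("composite" because genes are treated as independent given genotypes;
the estimates remain consistent under dependence). The marginal
$f_1(Y_i \mid X_j)$ has no closed form; substituting
$\beta = \tanh(t/\sqrt{n-3})$ turns it into a Gaussian-prior integral in
$t$, evaluated by Gauss-Hermite quadrature (41 nodes by default,
configurable via `quad_order`).

One numerical point matters: on the $t$ scale the correlation likelihood
is approximately $N(\hat z, 1)$ with $\hat z$ the observed Fisher-scaled
correlation, while the prior is $N(0, \sigma^2)$. Nodes placed under the
prior alone miss the likelihood peak as soon as $\sigma$ is a few times
the unit likelihood width, so the rule is *adaptive*: nodes are centered
at the Gaussian-product mode $\hat z \sigma^2/(1+\sigma^2)$ and scaled by
$\sigma/\sqrt{1+\sigma^2}$. The tests verify agreement with a dense
trapezoid rule on the $\beta$ scale to better than $10^{-6}$ relative
error across $\sigma$ from 0.5 to 6, and 41 vs 81 nodes agree to better
than $10^{-7}$.

The EM treats three latent quantities per gene: the null indicator, the
causal index $j$, and the effect $t$ itself. The E-step computes the
posterior null probability (the current lfdr), causal responsibilities
$\propto f_1(Y_i \mid X_j)$, and $E[t^2 \mid \text{data}, j]$, all from
one quadrature pass. The M-step is then closed form:
$\pi_0 \leftarrow$ mean posterior null probability and
$\sigma^2 \leftarrow$ responsibility-weighted mean of $E[t^2]$ — the
standard variance-component update. Each iteration is an exact EM step;
the composite log-likelihood trace is asserted non-decreasing at every
iteration, with a slack of $10^{-6}(1 + |\ell|)$ reflecting the
quadrature noise floor rather than the textbook zero. Iteration stops
when the change falls below `tol` (default $10^{-6}$) or would dip below
the noise floor. The default initialization is a warm start from the
summary-statistic fit below; tests confirm the EM fixed point matches a
direct two-parameter maximization of the same objective.

## Summary-statistic fit: the z-scale pseudo-likelihood

`zreg_fdr()` needs only the Fisher-scaled z-statistics
$z_j^{(i)} = \sqrt{n-3}\,\mathrm{atanh}(r_j^{(i)})$ — or, because the
model is symmetric, only $|z|$ (or SNP-level p-values). Under the null
each $z$ is approximately $N(0,1)$; a causal statistic is $N(\mu, 1)$
with $\mu \sim N(0, \sigma^2)$, hence marginally $N(0, 1 + \sigma^2)$,
giving the closed-form density ratio
$p_1(z)/p_0(z) = (1+\sigma^2)^{-1/2} \exp\{z^2\sigma^2 / 2(1+\sigma^2)\}$.

If the non-causal statistics, given the causal one, are distributed as
under the null (true for Markov serial dependence with null-identical
kernels, in particular for independence), the conditional factor cancels
from the likelihood ratio to the all-null model, leaving the
pseudo-likelihood
$\prod_i \{\pi_0 + (1-\pi_0)\frac{1}{m_i}\sum_k p_1(z_k^{(i)})/p_0(z_k^{(i)})\}$
and the gene-level lfdr with the same average-of-ratios form. When that
conditional assumption fails (e.g. LD makes inter-statistic correlation
depend on the effect), the fit degrades gracefully into an approximate
maximum-likelihood method; the paired-dataset checks in the test suite
quantify how closely it still tracks the full-data fit.

Maximization uses a quasi-Newton search with analytic gradients on
transformed coordinates (logit $\pi_0$, log $\sigma$), inside the box
$\pi_0 \in [10^{-6}, 1-10^{-6}]$, $\sigma \in [10^{-4}, 50]$. The
objective has a flat ridge along small $\sigma$ (where $\pi_0$ loses
identifiability), so three starts are used: $(0.5, 1)$, $(0.5, 3)$, and a
method-of-moments start that reads $\pi_0$ off the fraction of $|z| > 2$
in excess of the null rate and $\sigma^2$ off the excess second moment.
The best converged optimum wins; convergence tolerance is $10^{-9}$
relative on the objective. The inner accumulation is grouped log-sum-exp
in compiled code, so arbitrarily large $|z|$ cannot overflow.

**Degenerate data.** When the fitted mixture improves on the all-null
model by less than 2 log-likelihood units (the value of its two free
parameters), the whole ridge $\{\sigma = 0\} \cup \{\pi_0 = 1\}$ is the
effective optimum and the reported estimate would be arbitrary. Both
fitting routes then report the canonical corner — $\pi_0$ at its upper
box bound, $\sigma$ at its lower bound — with a warning, so "no signal"
is always represented the same way.

## Decision procedures and baselines

`fdr_reject()` implements adaptive thresholding (stable sort, ties by
original index; the maximality of the rejected prefix is asserted in the
tests). The baselines mirror common eGene practice: per-gene Bonferroni
(`bonferroni_gene_p()`) and Simes (`simes_gene_p()`) combiners;
permutation min-p p-values (`permutation_minp()`) with one shared
permutation stream across genes (valid because genes are judged
marginally, and much faster; p-values use the $(1 + \#\{\cdot\})/(B+1)$
convention and cannot be zero); and Storey q-values
(`storey_qvalue()`) with fixed $\lambda = 0.5$ — the smoother variant is
out of scope. `calibrated_alpha()` bisects the nominal level until the
mean realized false discovery proportion across replicate simulations
matches a target, reusing one simulated ensemble across bisection steps.

## What the generators emulate

`simulate_zstats()` produces the serial-correlation study design: null
genes carry a stationary AR(1) chain of standard normal statistics with
lag-1 correlation $\rho$; an alternative gene plants $z_k \sim N(\mu, 1)$,
$\mu \sim N(0, \sigma^2)$, at a uniform causal position and extends both
ways with the null kernel $z_{j\pm1} \mid z_j \sim N(\rho z_j, 1-\rho^2)$.
This makes the pseudo-likelihood's conditional assumption hold *exactly*,
so it isolates estimator behaviour from assumption violations. Defaults
are the study conditions the method targets: $N = 10{,}000$ genes,
$n = 200$ samples (carried for interface consistency; the z-scale design
never uses it), $\pi_0 = 0.2$, and $m = 30$ SNPs per gene. The per-gene
SNP count is not dictated by the design, so 30 is a package choice in the
realistic cis-window range; a `m = c(lo, hi)` sampler is available, and
the replicate studies are insensitive to the choice at $\sigma \ge 2$.
The Bernoulli indicator is parameterized so that $\pi_0$ is the
probability a gene is *null*, matching the estimand.

`simulate_genotypes()` is a synthetic stand-in for real genotype
matrices: two latent Gaussian AR(1) haplotypes per gene, thresholded at a
per-SNP allele-frequency quantile (MAF uniform on `maf_range`, default
(0.05, 0.5]) and summed, giving Hardy-Weinberg dosages with LD decaying
in $\rho^{|j-j'|}$. Monomorphic SNPs are redrawn (breaking their LD with
neighbours — rare and documented). It does not attempt recombination
maps, realistic allele-frequency spectra, or population structure, so
passing tests say nothing about those features of real cohorts.
`simulate_expression()` applies the three-step scheme: Bernoulli null
indicator, uniform causal SNP, Fisher-scale effect
$t \sim N(0, \sigma^2)$, then $Y_i \sim N(\beta x_k, 1 - \beta^2)$
elementwise — unconditional unit variance by construction.

## Numerical and design choices

* **Standardization.** Expression and genotype rows are residualized,
  then z-scored with the population ($1/n$) convention, making the null
  exactly $N_n(0, I)$ and $\beta$ a correlation. Correlations are
  scale-invariant, so this matters for the full-data density, not for
  the z-statistics.
* **Degrees of freedom.** The $\sqrt{n-3}$ scaling is used uniformly and
  $n$ is not reduced for removed covariates; with many covariates and
  small $n$ the null variance is slightly underestimated (documented
  small-sample caveat).
* **Dropped data.** Monomorphic SNPs and constant expression rows are
  dropped with warnings (a gene only when all its SNPs go); missing
  genotypes are mean-imputed per SNP, logged. Perfect correlations
  ($|r| = 1$) have no finite Fisher statistic and the SNP is dropped.
* **Ties.** The lfdr sort is stable with ties broken by original index;
  since the criterion is a prefix mean, tied genes at the boundary enter
  only while the criterion holds.
* **Seeds.** Every randomized routine takes a single seed; replicate
  studies derive per-replicate sub-seeds once up front, so results do not
  depend on evaluation order or worker count.

## Problem sizes used in the shipped studies

The replicate studies run at the published design scale of
$N = 10{,}000$ genes and $m = 30$, with 200 replicates per cell in the
test suite and 100 in the acceptance script (the reference study used
1,000; Monte-Carlo SEs are computed from our own replicates so
comparisons stay calibrated). The paired full-data/summary comparison
uses 100 datasets of $N = 1{,}000$ genes at $n = 83$ — the full-data EM
dominates the cost, and these sizes give estimator correlations with
standard errors well below the margins being tested. Power comparisons
use $N$ of a few hundred genes and a few hundred permutations, enough to
order the methods at $\sigma \ge 3$ where the gaps are wide.

## Known limitations

* One causal SNP per gene is a working simplification; secondary signals
  exist in large studies and are not modeled.
* The uniform causal prior over SNPs is assumed, not estimated; a
  weighted prior would be a straightforward extension but is out of
  scope.
* The summary-statistic fit can be mildly anti-conservative at moderate
  signal ($\sigma \approx 2$) — visible in the replicate studies — and
  noticeably at $\sigma \le 1$, where the two mixture components are
  barely separable; this is a property of the two-group model itself,
  not of the approximation. `calibrated_alpha()` provides the adjusted
  variant for fair power comparisons.
* lfdr values ignore gene-gene correlation; the composite-likelihood
  argument protects the hyperparameter estimates, not the per-gene
  posteriors, under strong co-expression.
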