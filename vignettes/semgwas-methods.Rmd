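---
title: "Multi-trait multi-locus SEM: model, estimation and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-trait multi-locus SEM: model, estimation and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(semgwas)
```

This vignette is the package's account of its science: the model and its
assumptions, the construction algorithm, the numerical conventions that a
reader would otherwise have to reverse-engineer from the code, and the
places where the design was genuinely open and a choice had to be made.
It states no empirical result that the test suite does not itself compute.

## 1. Model

Traits in association panels come in correlated blocks; the model explains
each block by a latent factor and lets SNPs act either on factors
(pleiotropic effects, shared by all the factor's traits) or on individual
traits (single-trait effects):

$$
\begin{aligned}
\eta &= B\eta + \Pi \tilde g + \varepsilon, &\varepsilon &\sim N(0, \Theta_\varepsilon),\\
p &= \Lambda\eta + K \tilde y + \delta, &\delta &\sim N(0, \Theta_\delta),
\end{aligned}
$$

with diagonal error covariances, an acyclic $B$, and the column rule that
every SNP occupies exactly one cell of $\Pi$ or $K$ (a SNP influences one
variable; its downstream effects propagate through $B$ and $\Lambda$, which
is what makes direct and indirect effects separable). Traits are
standardised, so there are no intercepts.

**Ordinal variables.** Ordinal traits and all SNP codes $\{0,1,2\}$ are
modelled as discretisations of hidden standard-normal variables through
ordered thresholds $t_k = \Phi^{-1}(\sum_{i\le k} f_i)$, where $f_i$ are the
observed category proportions; a value in category $k$ constrains its hidden
variable to $(t_{k-1}, t_k]$. All covariances involving ordinal variables
are estimated on that latent scale — Pearson for continuous pairs,
polyserial for mixed pairs, polychoric for ordinal pairs — and the resulting
*hybrid matrix* is what every likelihood in the package consumes. Because a
polychoric matrix need not be positive semi-definite, a PSD-repaired copy
(eigenvalue clipping at $10^{-6}$) is produced alongside, and the Frobenius
norm of the repair is recorded.

**Likelihood.** The sample covariance $S$ of the observed variables is
scored against the model-implied covariance $\Sigma(\phi)$ through the
Wishart density of $W = (n-1)S$ with $n-1$ degrees of freedom and scale
$\Sigma$, i.e. the parametrisation with $E[S] = \Sigma$. (The alternative
scale $\Sigma/(n-1)$ would make the density *increase* under inflation of a
mismatched $\Sigma$, which contradicts what a fit criterion must do; the
convention is fixed package-wide so log-likelihoods are comparable across
runs.) The implied covariance follows the standard
LISREL-with-exogenous-covariates algebra; with $A = (I-B)^{-1}$:

$$
\mathrm{Cov}(\eta) = A(\Pi\Sigma_{gg}\Pi^\top + \Theta_\varepsilon)A^\top,
\qquad
\mathrm{Cov}(p) = \Lambda\,\mathrm{Cov}(\eta)\,\Lambda^\top
  + \Lambda\,\mathrm{Cov}(\eta,\tilde y)K^\top + \cdots + \Theta_\delta .
$$

This algebra is *validated*, not assumed: the test suite checks it against
the Monte-Carlo covariance of $2\times10^5$ draws from the generative
equations (2% relative Frobenius tolerance) on ten model configurations.

## 2. Automatic construction

1. **Factor count** — parallel analysis: eigenvalues of the observed trait
   correlation matrix against the 95th percentile of eigenvalues from 500
   column-permuted datasets; the count is the number of *leading*
   eigenvalues above their null quantile.
2. **Attribution** — ML factor analysis with varimax rotation; a trait joins
   a factor when its absolute standardised loading exceeds 0.5 (strictly),
   ties to the largest |loading|; factors keeping fewer than two traits and
   unattributed traits are dropped from the model entirely.
3. **Identification** — one loading per factor (the first attributed trait)
   is anchored at 1; the factor's variance stays free. Beware the
   2-indicator corner: an *isolated* two-trait factor has four parameters
   against three moments and is under-identified until a structural edge or
   a SNP ties it to the rest of the model; its Wald tests are meaningless on
   that ridge. Three indicators per factor is the minimum for stand-alone
   identification.
4. **Structural search** — greedy forward selection over directed factor
   pairs: a candidate edge must keep $B$ acyclic and leave *every* free
   $\Lambda$ and $B$ entry significant at $p < 0.05$ (two-sided Wald from
   the observed information); the admissible candidate with the highest
   fitted log-likelihood is added; the search stops when the best gain is
   $\le 10^{-4}$ log-units. Two facts temper expectations here. The
   log-likelihood trace is non-decreasing by construction. And edge
   *orientation* is not identifiable: reversing an edge (or a whole chain)
   yields a Markov-equivalent model with an identical maximum likelihood, so
   what the search recovers reliably is the skeleton plus any
   orientation-forcing structures, with ties broken by scan order.

## 3. SNP selection

With $B$ and $\Lambda$ frozen at their construction ML values, candidates
are attached greedily — factors first, in breadth-first DAG order
(name-ordered tie-breaks), then traits; SNPs already fixed in $\Pi$ are
excluded from trait candidacy. Scoring a candidate: its single coefficient
is fitted by ML over the full observed covariance (error variances stay
free — they must re-absorb the variance the SNP explains; $B$ and $\Lambda$
stay frozen), and the candidate's *full-covariance Wishart log-density
gain* over the same model with the coefficient pinned at zero is the
ranking and stopping statistic. Densities are comparable across candidates
because every SNP has unit variance on the latent-normal scale, and the
gain is the likelihood-ratio improvement attributable to the SNP alone.

Why not the phenotype-block density? With error variances free, the fitted
phenotype-block implied covariance is the same whether the SNP is causal or
null — the explained variance merely moves from $\Theta_\varepsilon$ into
$\Pi\Sigma_{gg}\Pi^\top$ — so that block carries no ranking information;
the signal lives in the SNP–trait cross-covariances. The phenotype-block
density is still computed and written to the selection log.

Stopping and redundancy (the quantities that shape how many SNPs a model
absorbs): stop when the best gain falls below `gain_min` (default 2.0
log-units, an AIC-style penalty for one parameter) or when `max_snps` per
variable (default 15) is reached; after each addition, candidates whose
genotype-code correlation with the added SNP exceeds 0.9 in absolute value
are removed — this is why the selected sets contain no correlated SNP
pairs. Candidates are re-scored after every addition (a cheap 1-D
pre-ranking with variances held, then a full fit of the winner;
`rescore = FALSE` switches to a single initial ranking). Note that
uncapped factor-level selection can absorb trait-specific SNPs before the
trait stage sees them — their factor-level gains are smaller but can clear
the threshold; `max_snps` is the lever if that matters.

## 4. Bayesian estimation

All retained coefficients (everything except anchors) and both error
covariances are sampled by a six-step Gibbs sweep: augmented data for
ordinal traits and SNP codes, then $\eta$, then $\Theta_\varepsilon$, rows
of $[B, \Pi]$, $\Theta_\delta$, rows of $[\Lambda, K]$. Conjugate families
throughout: truncated normals for augmented data, multivariate normals for
$\eta$ (all samples share the conditional covariance, so the draw is one
vectorised matrix operation) and for coefficient rows, inverse-gamma for
variances.

**Priors.** Coefficient priors are $N(\text{construction value}, 1)$ — the
frozen ML estimates act as prior information — and variance priors are
IG(2, 1). Chains initialise at $N(\text{prior mean}, 0.1)$ (0.1 read as a
variance) for coefficients and IG(2, 1) draws for variances, with per-chain
seeds derived from one master seed. Burn-in discards the first 500 of 2000
iterations by default. Thresholds are fixed at their empirical estimates
and never sampled.

**Augmentation schemes.** `gibbs_control(augmentation = )` offers two:

- `"conditional"` (default): augmented variables are drawn from their exact
  truncated-normal full conditionals given the current parameters and
  factors. This is a correct Gibbs sampler for the joint model; on the
  2-factor/6-trait/6-SNP recovery benchmark all parameters land within 3
  posterior SDs of truth.
- `"marginal"`: augmented variables are drawn from truncated standard
  normals given only the observed category, independently of the
  parameters. This simpler scheme redraws the SNP's latent value with its
  full within-category variance every sweep, which attenuates SNP
  coefficients by the categorisation $R^2$ (about 0.8 for a balanced
  3-category SNP) and inflates $\Theta_\varepsilon$ correspondingly;
  measured on the same benchmark, about 1 parameter in 6 drifts beyond 3
  posterior SDs. It is retained because it is the scheme a reader of the
  method's original description would implement.

**Diagnostics.** Gelman–Rubin $\hat R$ (classic between/within variant) and
a spectral-density effective sample size (AR-fit estimator of the spectrum
at zero, the estimator used by the standard MCMC diagnostic packages),
summed over chains. Posterior summaries pool chains: mean, sd, 5%/95%
quantiles.

## 5. Prediction and validation

Prediction maps each observed SNP code to the conditional mean of its
latent variable given the category (a truncated-normal mean; missing codes
map to 0), then $\hat\eta = (I-B)^{-1}\Pi\tilde g$ and
$\hat p = \Lambda\hat\eta + K\tilde y$. Observing 3-category codes rather
than latent dosages caps the attainable correlation at the square root of
the mean categorisation $R^2$ (about 0.9 even for a noiseless model) — the
test suite asserts this derived ceiling rather than a higher constant.

Cross-validation uses a seeded equal-size partition; *everything* —
thresholds, the hybrid matrix, measurement, structure, SNP selection,
sampling — is re-estimated per training fold, and metrics are computed on
the pooled held-out predictions (pooling, rather than averaging per-fold
correlations, is the reading adopted for "across all test sets"). Metrics:
Pearson $r$; the coefficient of determination reported as $r^2$ (the
squared-correlation convention that published $r$/$r^2$ pairs follow, not
$1 - \mathrm{SSE}/\mathrm{SST}$); NRMSE = RMSE / sd(observed).

Positional concordance across the per-fold models uses a sliding window
(500 kb, step 100 kb; 0-based half-open windows on a per-chromosome start
grid at multiples of the step) counting models with at least one SNP per
window, and a permutation test against external hits whose null circularly
shifts hit positions per chromosome — circular shifting preserves local hit
clustering, which a uniform scatter would destroy.

## 6. The synthetic world

The generator draws loadings with magnitudes in $[0.6, 0.9]$ (sign negative
with probability 0.25 — real trait blocks mix orientations), sets error
variances so factor and trait variances are close to 1 (so true loadings
are comparable to standardised estimates), attaches SNPs with the requested
effects, and simulates genotypes at Hardy–Weinberg proportions from
latent-normal dosages with allele frequencies in $[0.15, 0.85]$ —
comfortably inside the MAF filter band. Loci are independent by default; an
optional within-chromosome AR(1) mode (`ld_rho`) creates correlated loci to
exercise the redundancy filter. Missingness defaults to 0 and is capped in
practice by the call-rate filter at 10%.

What a green test does establish: the estimators recover the generative
truth of *this* world — threshold-normal ordinal data, HWE, no population
structure, linear effects. What it does not: robustness to kinship,
stratification, non-normal latent distributions, or LD beyond AR(1); none
of these are modelled, and the package makes no claims about them.

## 7. Data preparation conventions

MAF uses $p = \text{mean(code)}/2$ over non-missing calls and retains SNPs
with $\min(p, 1-p)$ strictly above 0.03 and call rate strictly above 0.90.
Log transforms are natural-log (the base washes out under z-scoring) and
refuse non-positive values; z-scores use the population-sd convention.
Missing data: correlations are pairwise-complete; within cross-validation,
thresholds come from training data only. Category merge maps are applied
before threshold estimation; merge maps are a no-op on re-application only
when they are identity on their own range.

## 8. Known limitations

- Edge orientation in the structural part is decided by scan order within a
  Markov equivalence class; interpret directions with caution.
- Isolated 2-indicator factors are under-identified in zero models (see
  §2); the significance filter can stall the structural search there.
- The greedy selection's gain threshold of 2.0 admits occasional null SNPs
  with gains just above threshold (best-of-many selection bias); the
  threshold trades power for parsimony and is configurable.
- ML fitting uses dense numerical gradients; it is intended for the
  panel-scale models the method targets (tens of traits, hundreds of
  candidate SNPs per fit), not genome-wide dense scans.
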