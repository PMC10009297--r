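---
title: "Estimating and comparing psychometric networks with resilnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and comparing psychometric networks with resilnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resilnet)
```

## The model

resilnet analyses multi-group ordinal survey data — here, resilience
questionnaires in which two item communities measure complementary domains:
an intrapersonal community of skills and strengths (items `R1, R2, ...`) and
a social-ecological community of relational and contextual resources
(items `A1, A2, ...`) — as Gaussian graphical models (GGMs). In a GGM the
nodes are items, and an edge between items $i$ and $j$ carries the partial
correlation $\omega_{ij}$ between them given all other items; a missing edge
means conditional independence. The saturated network is obtained from the
inverse of the item correlation matrix $R$: with $K = R^{-1}$,

$$\omega_{ij} = -\frac{\kappa_{ij}}{\sqrt{\kappa_{ii}\kappa_{jj}}}.$$

### Pruning instead of regularization

Dense saturated networks are hard to read and carry many spurious edges.
Rather than lasso-style shrinkage, resilnet sparsifies by *recursive
significance pruning*: each edge of the saturated network is tested with the
Fisher-z statistic $z = \operatorname{atanh}(\omega_{ij})\sqrt{n - k - 3}$,
where $k = p - 2$ is the size of the conditioning set; all edges with
$p \ge \alpha$ (default $\alpha = .05$) are removed *simultaneously*; the
constrained model is refit by maximum likelihood; the implied partials of
the refit model are retested; and the cycle repeats until a round removes
nothing. Pruned edges are never re-added, which makes the retained edge set
monotone over rounds. Simultaneous (rather than one-at-a-time) removal is
the natural reading of "re-evaluate after pruning" semantics and keeps the
procedure inexpensive; in our simulations it controls the false-positive
edge rate near or below $\alpha$ (the empty-graph retention rate at
$n = 1000$ is about 4–5%).

The constrained refit is classical covariance selection: find $\Sigma$ that
matches the sample matrix $S$ on the diagonal and every retained pair while
$(\Sigma^{-1})_{ij} = 0$ on pruned pairs. We solve it with the regression
form of iterative proportional fitting — cycle over variables, each time
solving the regression of one variable on its free partners within the
current $\Sigma$ — iterated until the largest change in any entry of
$\Sigma$ is below $10^{-8}$ (cap: 1000 sweeps). The sweep kernel is written
in C++ because the permutation and bootstrap procedures below re-run the
entire pipeline thousands of times. A test verifies the fit against a
brute-force quasi-Newton optimizer of the constrained Gaussian likelihood
on all single-edge patterns of 3–5-node fixtures.

Model quality is summarised with SEM-style indices computed from the
discrepancy $F = \ln|\Sigma| + \mathrm{tr}(S\Sigma^{-1}) - \ln|S| - p$ and
$T = (n-1)F$: RMSEA, CFI and TLI against the diagonal-covariance baseline,
and $\mathrm{BIC} = -2\ell + q\ln n$ with $q$ counting the $p$ variances
plus retained edges (data are standardized, so means are excluded).

### Centrality

Expected influence (EI) is the signed sum of a node's edge weights — the
appropriate "importance" measure when edges can be negative, since absolute
strength would reward antagonistic ties. Bridge EI restricts the sum to
edges crossing into the other community. Because the two communities have
unequal sizes (10 vs 17 items by default), each node's bridge EI is
normalized by the size of the *other* community; this is our fixed,
documented convention — other software may scale differently, so absolute
bridge-EI values are comparable within, not across, toolchains. Global EI
is the sum of node EI (equivalently twice the sum of all edge weights), and
global bridge EI the sum of normalized node bridge EI.

### Comparing group networks

Three complementary tests are provided, all re-running the *full* pruning
pipeline on every resample so the null distributions reflect the entire
procedure, not just reweighting:

* **Structure test.** The observed statistic is the symmetric
  Kullback–Leibler divergence between the two groups' pruned-model-implied
  covariances,
  $\mathrm{KL}_s = \tfrac12\{\mathrm{tr}(\Sigma_b^{-1}\Sigma_a)
  + \mathrm{tr}(\Sigma_a^{-1}\Sigma_b)\} - p$. Its reference distribution
  is a plug-in posterior predictive: fit the pooled data, simulate paired
  Gaussian datasets of the original group sizes from the pooled fit,
  re-estimate both implied covariances, and record their divergence. We use
  the plug-in predictive rather than full posterior sampling of the
  precision matrix: it removes prior-specification ambiguity while keeping
  the same logic (does the observed divergence exceed what a common model
  would generate?), at the cost of ignoring pooled-estimation uncertainty —
  in calibration runs the test is approximately exact (null rejection
  ~4% at the 5% level).
* **Global permutation tests.** Differences in global EI and global bridge
  EI are tested by shuffling group labels over the pooled respondents
  (keeping group sizes), re-estimating both networks per shuffle, and
  comparing $|\Delta|$ to its permutation distribution, with
  $p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + B)$ — so $p$ honours the
  floor $1/(B+1)$.
* **Edge- and node-level tests.** From the same permutation stream (one
  pass records all statistics, which also makes the pair's results
  internally consistent), element-wise tests of $|w_a - w_b|$ over the
  union of edges retained in either group, and of node EI and bridge-EI
  differences. Difference counts are reported at uncorrected $p < .05$ —
  the convention for these element-wise summaries — with Holm-adjusted
  p-values alongside.

Comparisons canonicalize the two groups by sorting labels, so results are
invariant to argument order.

### Stability and variability

Case-drop bootstrapping re-estimates the network after deleting
$\lfloor 0.25\,n \rfloor$ randomly chosen respondents (without replacement)
per replicate, 1000 times by default; the per-edge inclusion proportion and
the mean inclusion of the full-sample edges summarise robustness. The
variability network condenses $k$ group networks into one graph whose edge
weights are the sample standard deviation (denominator $k-1$, conventional
at small $k$) of each edge across groups, with pruned edges contributing 0
— so presence/absence variation counts as variability — and node weights
the SD of node EI.

## Synthetic data with known truth

Because real survey microdata of this kind are typically proprietary, the
generator is a first-class module. It emulates:

* **two item communities** (defaults 10 + 17 items) with planted positive
  within-community partial correlations, a configurable number of bridges,
  and optionally negative bridges — matching the empirical pattern that
  negative edges, when they occur, appear between domains;
* **ordinal responding**: latent vectors are drawn from the Gaussian with
  covariance equal to the standardized inverse of the true precision
  matrix, then cut at thresholds $\Phi^{-1}(0.15, 0.40, 0.70, 0.90)$ into
  five categories — a mildly right-shifted agreement distribution typical
  of protective-factor scales (a 17-item, 1–5 scale spans 17–85, matching
  the published score ranges); thresholds are configurable per group;
* **straight-liners**: a configurable fraction of rows overwritten with one
  constant category drawn uniformly per respondent, modelling disengaged
  responding as a data-quality artifact independent of the latent process;
* **demographics**: integer ages uniform on 16–29 (so the 20–29 analysis
  subset exercises the age filter) and a binary sex label at 52% female.

Construction of the truth: the precision matrix starts with unit diagonal
and $-\rho_{ij}$ off-diagonal (so its partials are exactly the requested
$\rho$); if not positive definite, a ridge is added to the diagonal
(doubling from 0.05, at most 20 attempts) and the matrix rescaled so the
latent covariance has unit diagonal — rescaling changes neither support nor
partials. Default edge magnitudes are uniform on [0.1, 0.35], the range
typical of pruned psychometric networks; recovery studies use
[0.15, 0.35] so every planted edge is detectable at $n = 2000$.

What the generator does **not** emulate: item-specific threshold variation,
local dependence beyond the GGM, differential item functioning across
groups, and missing data (the target surveys forced complete responses).
Passing tests therefore demonstrate correctness of the estimation machinery
under the latent-Gaussian ordinal model, not robustness to measurement
non-invariance.

## Cleaning and screening

`clean_survey()` reproduces the standard intake: drop respondents giving
one identical answer across *all* items of the combined measures (per-scale
straight-lining is not exclusion-worthy — a constant subscale can be a
valid response), subset to a closed integer age interval (default 20–29),
compute Cronbach's $\alpha$ per community ($n-1$ variance denominator
throughout), and screen for redundant item pairs: pairs with $|r| \ge .7$
whose correlation profiles with every third item are statistically
indistinguishable (fewer than 20% of Hittner back-transformed-average-z
comparisons significant at $\alpha = .05$) are flagged as topological
overlap. Raw Pearson correlations are the default input — the choice is
recorded in the report; a polychoric option (two-step ML with quadrature
for the bivariate normal rectangle probabilities) is available behind the
`method` flag of `estimate_correlations()` for users who prefer the latent
scale, at substantially higher cost on 27 items.

## Numerical choices and edge cases

* Edge tests use the closed-form Fisher z on (implied) partials rather than
  ML standard errors: reproducible and fast; the two agree to first order.
* `alpha = 1` prunes nothing (the saturated model, df = 0, RMSEA = 0,
  CFI = 1); TLI is reported as 1 with a note when df = 0.
* Near-singular correlation inputs are repaired to the nearest PSD matrix
  by eigenvalue clipping at $10^{-8}$, with a warning.
* Resampling failures (singular resample, non-convergence) are skipped and
  counted; more than 1% failed permutations or 5% failed bootstrap
  replicates aborts with diagnostics.
* Tie-breaks in the top-varying-edges ranking are lexicographic by node
  pair, making reports byte-reproducible.
* Every stochastic stage takes an explicit seed; the pipeline derives
  per-stage seeds from the master seed with a fixed counter scheme
  (`derive_seed()`), so stages can be reproduced in isolation.

## Study sizes used in the validation suite

The test suite validates the pipeline at sizes chosen to give stable Monte
Carlo estimates on a single core: edge recovery over 20 replicates of a
27-node network at $n = 2000$ (sensitivity $\ge .90$, false-positive rate
$\le .10$); null calibration of the global permutation test over 200
replicates of 200 permutations at $n = 400$ per group, and of the structure
test over 100 replicates of 200 predictive draws (both within a 2–9%
rejection band at the 5% level); power against a 10-edge difference of 0.2
at $n = 500$ per group over 50 replicates ($\ge 80\%$ joint detection);
and bootstrap stability over 200 case-drop replicates at $n = 2000$
(inclusion $\ge .90$ for edges with $|w| \ge .25$; $\le 9\%$ for absent
edges). Production analyses should use the defaults (5000 permutations,
1000 predictive draws, 1000 bootstraps).

## Known limitations

* Pearson correlations on 1–5 ordinal scores attenuate partial correlations
  by roughly 10% at these thresholds; pruning decisions are slightly
  conservative as a result. The polychoric option removes the bias at
  higher computational cost.
* The bridge-EI normalization convention (divide by the other community's
  size) is fixed but not universal; compare absolute values only within
  this package.
* The plug-in predictive ignores uncertainty in the pooled fit; at very
  small samples the structure test may become conservative.
* Fit-index scaling uses the $(n-1)$ multiplier for $T$; packages using $n$
  will differ negligibly at survey sample sizes.

## A worked example

```{r example, eval = FALSE}
spec_a <- true_network_spec(seed = 1, weight_range = c(0.15, 0.35))
study <- generate_study(list(
  group_spec("brazil", spec_a, 700, straightliner_rate = 0.05),
  group_spec("vietnam", true_network_spec(seed = 2,
                                          weight_range = c(0.15, 0.35)),
             700, straightliner_rate = 0.05)), seed = 42)

cfg <- pipeline_config(study, output_dir = "report",
                       n_permutations = 1000, n_ppc_draws = 500,
                       n_boot = 500, seed = 42)
bundle <- run_pipeline(cfg)
print(bundle)
bundle$comparisons$brazil_vs_vietnam
```
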