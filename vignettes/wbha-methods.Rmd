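---
title: "Covariate-weighted FDR control for GWAS: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Covariate-weighted FDR control for GWAS: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wbha)
library(dplyr)
```

## The multiple-testing problem this package addresses

A genome-wide association scan tests m markers (often 10^4 to 10^6) for
association with a phenotype, and the markers most worth finding — rare
variants with strong effects — are precisely the ones with the least
individual power: a variant with minor allele frequency (MAF) 0.02 carries
far less information per sample than one at MAF 0.35. Unweighted false
discovery rate (FDR) procedures such as Benjamini–Hochberg (BH) treat all
hypotheses symmetrically and consequently under-detect the rare end of the
spectrum.

The wBHa procedure implemented here attacks this with *p-value weights*
that are an explicit function of an informative covariate $x_i$
(typically the observed MAF):

$$w(x_i, a) = \frac{m}{\sum_{j=1}^{m} x_j^{-a}} \; x_i^{-a},
\qquad \sum_i w(x_i, a) = m,$$

followed by the weighted BH step-up on $p_i / w_i$. The exponent $a \ge 0$
tunes how aggressively small covariate values are prioritized: $a = 0$
recovers plain BH, $a = 1$ is the classical fixed-weight wBH comparator,
and large $a$ concentrates virtually all weight on the smallest covariate
values. The free parameter is chosen *from the data* by maximizing the
number of rejections over the grid $a = 0, 0.1, \dots, 10$, stabilized by
bagging: K bootstrap subsamples of $m/K$ hypotheses are scored
independently and the final exponent is the mean of the per-round winners.

## The procedures

* `bh_stepup(p, alpha)` — reject the k smallest p-values,
  $k = \max\{i : p_{(i)} \le i\alpha/m\}$. Step-up semantics imply that
  every p-value tied with $p_{(k)}$ is rejected (the tied values satisfy
  their own thresholds), so no extra tie rule is needed.
* `weighted_bh(p, w, alpha)` — BH on $p_i/w_i$ with $\sum w_i = m$.
  Weighted p-values are not capped at 1 (the step-up comparison handles
  values above 1 naturally) and a zero weight maps to an infinite weighted
  p-value, i.e. "never reject". Zero weights cannot arise from
  `covariate_weights()` but are accepted defensively for user-supplied
  weight vectors.
* `storey_pi0(p)` / `qvalue_procedure(p, alpha)` — the adaptive
  comparator: $\hat\pi_0(\lambda) = \#\{p_i > \lambda\}/(m(1-\lambda))$ on
  the grid $\lambda = 0.05, 0.10, \dots, 0.95$, smoothed by a natural
  cubic spline with 3 effective degrees of freedom and read off at
  $\lambda = 0.95$, clipped to (0, 1]. These grid and spline settings are
  the conventional choices for this estimator; with fewer than 20
  p-values the spline is unsupported and the estimate falls back to the
  conservative $\hat\pi_0 = 1$ with a warning. BH is then run at
  $\alpha/\hat\pi_0$.
* `wbha(data, ...)` — the full adaptive procedure described below.

Numerical policy: weights are computed in log space (a log-sum-exp
normalization), so exponents at the top of the grid never overflow even
when the covariate spans several orders of magnitude; step-up comparisons
use plain `<=` with no epsilon.

## Exponent selection in detail

Each bagging round draws `sample_size = max(1, floor(m/K))` hypotheses
with replacement — p-value and covariate drawn jointly — and treats the
subsample as a self-contained testing problem: weights are renormalized to
sum to the subsample size before the weighted step-up. (The alternative,
carrying full-sample weights into the subsample, leaves the subsample
weight sum random; renormalizing is the reading consistent with "apply the
weighted procedure to the sampled set".) Final weights are always built on
the full m hypotheses at the selected exponent.

The winner of a round is the exponent maximizing the rejection count, with
ties resolved by a cascade:

1. Collect the sorted tied maximizers A and split them into runs wherever
   the gap between consecutive values exceeds the grid step.
2. One run → its maximum. One strictly longest run → its maximum.
3. Tied-longest runs → the run "closest to 1", measured as the smallest
   endpoint distance $\min(|a_{\min}-1|, |a_{\max}-1|)$; a residual tie
   goes to the run with the larger maximum. Run length is counted in grid
   points, which on a constant-step grid is equivalent to the span.

The closest-to-1 metric is our choice; the tie rule names the target
value but not the distance. Duplicated values are removed before
tie-breaking (they cannot arise from the grid loop; defensive only).

**Rounds with no rejections anywhere.** With sparse signal the bootstrap
subsamples are small (m/K = 80 in the reference setting) and most contain
no causal marker and reject nothing at *any* exponent. Such a round is
uninformative about $a$: its count vector is identically zero, and reading
it as a full-grid tie would return the top of the grid, pushing the bagged
average toward exponents where the weights collapse onto the handful of
rarest markers and the procedure loses essentially all power — the
opposite of the adaptive behavior the optimizer exists to provide. We
therefore score a zero-count round as the neutral exponent 0 (unit
weights): absence of evidence for weighting shrinks the procedure toward
plain BH. A practical consequence worth knowing: when the covariate is
uninformative, wBHa drifts toward BH and pays only a small power penalty,
which is exactly the robustness one wants from an adaptive weighting
scheme. The full-grid-tie rule still applies verbatim whenever at least
one hypothesis is rejected (e.g. a constant covariate yields $a_k = 10$
in every signal-bearing round — inconsequential, since constant
covariates give unit weights at every exponent).

The final exponent is the arithmetic mean of the K round winners and is
deliberately *not* re-snapped to the grid. Round k seeds its bootstrap
draw with `seed + k`, so enlarging K extends the earlier rounds instead of
reshuffling them.

## The simulator

`simulate_study()` emulates a single-cohort GWAS:

* **Genotypes.** Latent $m$-dimensional Gaussians with block-diagonal
  equicorrelation (blocks of `block_size = 10`, correlation `rho`) mimic
  linkage disequilibrium. Blocks are generated by the one-factor
  construction $\sqrt{\rho}\,Z_{block} + \sqrt{1-\rho}\,Z_i$ at O(nm)
  cost. Each latent value is discretized at the quantiles $\Phi^{-1}(p^2)$
  and $\Phi^{-1}(1-(1-p)^2)$ so the genotypes 2/1/0 hit the Hardy–Weinberg
  frequencies $(p^2,\, 2p(1-p),\, (1-p)^2)$ for MAF p. (The two cut
  points are the only pair consistent with Hardy–Weinberg; thresholding at
  $\Phi^{-1}((1-p)^2)$ instead would give $P(G=0) = 1-(1-p)^2$.)
* **MAFs and causal structure.** Null MAFs are U[0.01, 0.5]; the m1
  causal markers split into four groups — rare U[0.01, 0.05], medium-rare
  U[0.05, 0.15], medium U[0.15, 0.25], common U[0.30, 0.40] — of size
  ⌊m1/4⌋ each with the remainder added to the common group. Causal
  positions are uniform over markers, so under correlation several causal
  variants may share a block; the evaluation handles that through
  clustering rather than by constraining placement.
* **Effects.** Scenario 1 (the motivating regime): rare variants get the
  largest effects — quantitative (4, 3, 2, 1), binary (log 2.2, log 1.8,
  log 1.5, log 1.3) from rare to common. Scenario 2 reverses the vectors;
  scenario 3 is flat (2, resp. log 1.5).
* **Traits.** Quantitative: $Y = G\beta + \varepsilon$, with
  $\sigma^2 = (1-R^2)\sum_i (s_i - \bar s)^2 / (R^2(n-2))$ for the genetic
  score $s = G\beta$ — the value that calibrates the realized coefficient
  of determination to `r_squared` (default 0.2). If every effect is zero
  the score has no variance and $\sigma^2 = 1$ is used with a warning.
  Binary: logistic $P(Y=1) = \mathrm{expit}(\beta_0 + G\beta)$ with
  $\beta_0$ solved by root-finding so the mean case probability over the
  realized genotypes is exactly 0.5 (balanced design).
* **Plug-in genotypes.** A user matrix (0/1/2 coding) replaces the
  simulated genotypes: observed MAFs are computed from it, markers are
  binned at the MAF cutoffs 0.05 / 0.15 / 0.30, and causal markers are
  drawn per bin with the same quotient/remainder sizes — the
  semi-simulation mechanism for real genotype panels.

What the generator does *not* emulate: realistic LD maps and
recombination, population structure, genotyping error and missingness.
Passing tests therefore demonstrate correct operating characteristics
under idealized equicorrelated LD and clean genotypes, not performance on
any particular cohort.

## Association scans

`scan_quantitative()` fits per-marker simple linear regressions (two-sided
t-test on the slope, vectorized through the closed-form least-squares
solution); `scan_binary()` fits per-marker logistic regressions (Wald
test, iteration-capped). Monomorphic markers, separated or non-converged
logistic fits are reported conservatively as p = 1 with a warning. No
covariate adjustment or genomic control is applied — the simulations
contain no confounding. The observed MAF (folded allele frequency) is
returned as the `covariate` column, ready for the weighted procedures; in
the evaluation harness a folded MAF of exactly 0 (monomorphic marker) is
floored at 1e-4 to keep the weight function defined.

## Evaluation harness

`run_study()` loops simulate → scan → adjust → count. Per replicate r it
uses seed `seed + r`, so any replicate can be regenerated in isolation.
Metrics follow the standard confusion decomposition with the false
discovery proportion FP/max(R, 1); power is TP/m1 overall and
TP_g/m1_g within each MAF group, each reported with its Monte-Carlo
standard error (sample SD / √replicates).

Under correlation the marker-level definition of a true positive is
ambiguous (one causal variant can light up its whole LD block), so for
`rho > 0` overall power and FDR are counted on *clusters*: connected
components of the graph joining marker pairs with empirical |r| ≥ 0.8
(Pearson, on the 0/1/2 codes). A cluster is causal if it contains a causal
marker, rejected if any member is rejected; a causal cluster with no
rejected member counts as a false negative, a clean cluster with no
rejection as a true negative. Clustering is restricted to the simulator's
declared blocks (markers in different blocks are independent by
construction), keeping the cost linear in m; for user data without block
structure the full correlation matrix is scanned. Subgroup powers are
always counted at marker granularity, because MAF groups are defined per
causal marker and a cluster has no unique group.

The covariate fed to the weighted procedures can be the observed MAF
(rare-variant prioritization), 1/MAF (common-variant prioritization), or
an independent U(0, 1) draw (the uninformative-covariate robustness
check).

## Problem sizes used by the shipped checks

The package's replication studies run the reference protocol — scenario 1,
quantitative trait, n = 2000, m = 8000, m1 = 25, rho = 0, R² = 0.2,
nominal FDR 5% — at 100 replicates, with the bagged optimizer at its
defaults (grid 0–10 by 0.1, K = 100). One hundred replicates estimate a
mean FDP with a Monte-Carlo standard error near 0.005 at this rejection
density, tight enough to detect a violated 5% level; unit tests use
smaller configurations (m up to a few hundred, n up to 20 000 for the
calibration checks) chosen so each property is measured with at least a
4-standard-error margin.

## Known limitations

* The weight family is a single-covariate power function; multi-covariate
  or non-monotone weighting is out of scope, as is continuous optimization
  of the exponent (the grid is part of the procedure's definition).
* FDR control of the *adaptive* procedure is inherited empirically, not
  proven: the exponent is data-chosen, and only the fixed-weight wBH has
  the theoretical guarantee. The replication studies verify control at the
  reference conditions.
* Cluster-based counting restores interpretability under correlation but
  makes power values incomparable across different rho (the number of
  units changes).
* The q-value comparator estimates a global $\hat\pi_0$; covariate-dependent
  null proportions (FDR regression and relatives) are deliberately not
  implemented here.
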