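---
title: "Testing differential expression relative to a fold-change threshold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing differential expression relative to a fold-change threshold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldthresh)
```

## The problem

Digital counting platforms such as NanoString nCounter measure the RNA
abundance of a few hundred genes as barcode counts per lane, with 6--12
biological replicates per condition and no technical replicates. In
screening applications where each discovery triggers expensive follow-up
work, the question of interest is not "is this gene's expression different
between mutant and control?" but "is its fold change *significantly larger
than a threshold* the biology makes meaningful?". The popular shortcut --
require a significant t-test *and* an observed fold change above a cut-off
-- ignores the error variance of the fold-change estimate and gives no
statistical guarantee about the threshold. `foldthresh` tests the threshold
question directly.

## Normalization model

Raw counts are corrected for lane-level technical variation in three steps:

1. **Positive-control scaling.** Each lane is multiplied by
   (mean over lanes of the per-lane geometric mean of the positive spikes)
   / (this lane's geometric mean of the positive spikes). The target --
   the across-lane arithmetic mean of geometric means -- preserves the
   overall count scale; any fixed target gives the same downstream M
   values, since per-lane ratios are unchanged.
2. **Reference-gene scaling.** The same construction using a set of
   housekeeping genes (typically five), applied to the step-1 output. This
   corrects for differing RNA input amounts.
3. **Background correction.** Each lane's background, the mean plus twice
   the standard deviation of that lane's negative-control counts (after
   step 2), is subtracted. Background is per lane, not pooled across a
   cartridge: lane-specific background is the standard digital-counting
   convention and nothing in the design forces pooling.

Values below 1 are then fixed to 1. The floor is a background sentinel: all
downstream modelling is on log2 counts, and 1 maps to 0. A zero or negative
count among positive controls or reference genes aborts normalization
rather than being patched with a pseudocount -- it indicates a failed lane.

Two consequences worth knowing. First, renormalizing an already-normalized
matrix is *not* an exact no-op under these conventions: the second pass
rescales all lanes by one common factor (the product of the mean and the
mean reciprocal of the residual lane factors, 1 only when the lanes were
already exchangeable), and the background floor interacts with
subtraction. Between-lane ratios -- hence all M values -- are unaffected,
which is what the tests consume; the test suite checks exactly that
invariance rather than a literal idempotence.

A gene is **informative** when the median of its normalized counts over the
control lanes is at least 100 (boundary inclusive). Only informative genes
are tested.

## Gene-wise linear model

For gene $g$ with log2 normalized counts $y_g$ over $l$ lanes,
$E[y_g] = X\psi_g$ with design matrix $X$ and contrast
$\beta_g = C^T\psi_g$; for the two-group design the contrast is the log2
fold change $M_g = \bar y_{g2} - \bar y_{g1}$ exactly. Least squares gives
$\hat\beta_g$, residual variance $s_g^2$ on $df = l - \mathrm{rank}(X)$
degrees of freedom, the contrast scale $z = C^T(X^TX)^{-1}C$ (e.g.
$1/6 + 1/6 = 1/3$ for 6 vs 6), and $t_g = \hat\beta_g/(s_g\sqrt z)$.

The moderated statistic replaces $s_g^2$ by the posterior blend
$\tilde s_g^2 = (d_0 s_0^2 + df\, s_g^2)/(d_0 + df)$ with $df + d_0$
degrees of freedom. The prior $(d_0, s_0^2)$ is estimated by method of
moments on $\log s^2$ (digamma/trigamma matching, with a Newton iteration
for the trigamma inverse). When the observed variances show no excess
spread beyond chi-square sampling noise, $d_0 = \infty$ and the pooled
value is the geometric mean of the variances, so constant inputs pass
through unchanged; $d_0 = 0$ reproduces the classical statistics exactly.
The test suite cross-checks the fit against `limma::squeezeVar`.

**Degenerate genes.** A gene with zero residual variance has no evidence
scale; the classical convention here is $t = 0$, $p = 1$ (never called DE).
Real count data essentially never produce this; the convention is explicit
rather than inherited.

## Threshold tests

With threshold $\tau \ge 1$, the composite null is
$|M_g| \le \log_2\tau$. The p-value bound is evaluated at the
hardest-to-reject null point $M_0 = \min(\log_2\tau, |\hat M|)$, with
$\delta = M_0/(s\sqrt z)$:
$p = 2\,P(T_{df} > t_{obs} - \delta)$ for $t_{obs} \ge 0$ and
$2\,P(T_{df} < t_{obs} + \delta)$ otherwise, clamped to $[0,1]$ (the bound
can exceed 1; clamping keeps the contract). $t_{obs} = 0$ uses the
non-negative branch -- both branches agree there by symmetry. Two
analytic consequences are tested: $\tau = 1$ recovers the ordinary
two-sided t-test, and any gene with $|\hat M| < \log_2\tau$ is forced to
$p = 1$. This tail convention is deliberately the simple symmetric bound;
it differs from the tail formula some moderated-t implementations use, and
no reconciliation is attempted -- the classical-t variant (tTREAT) with
this bound is the package's reference method.

**tTREAT2** screens first: a $100(1-\alpha_{stage1})\%$ CI for $M$,
$\hat M \pm t_{df,1-\alpha_{stage1}/2}\, s\sqrt z$, strictly inside
$[-\log_2\theta, \log_2\theta]$ (strict at both ends) stops the gene with
$p$ reported as 1. Go genes get the tTREAT p-value at $\tau$ and are
called DE below $\alpha_{stage2}$. Defaults: $\alpha_{stage1} = 0.05$,
$\alpha_{stage2} = 0.01$; sensible margins are $\theta = \tau + 0.5$ to
$\tau + 1$. Stage 1 only removes genes, so the tTREAT2 DE set is always a
subset of the tTREAT set at matched $\tau, \alpha$.

**Multiple testing.** The composite-null bound already skews p-values
towards 1; the default pipeline applies no further adjustment, on the
view that stacking another conservative correction on a conservative bound
double-counts. Bonferroni and Benjamini--Hochberg are available behind the
`adjust` flag for users who want them.

## Running FC model

Fold-change variability is larger for lowly expressed genes, so a single
$\tau$ is either too lax at low expression or too strict at high
expression. The running FC model derives $\tau$ from the data:

1. Fold changes folded to $\ge 1$ are computed per gene, along with the
   reference-group average expression $AR_g$ (geometric mean of the
   control lanes). Genes are split into $m$ equal-count bins along AR
   (sizes differ by at most one, extras to the first bins, stable ties).
2. Per bin: the $b$-percentile of the fold changes ($bp_j$) and the median
   AR. The curve $bp = a + b/AR$ is fitted to the bin summaries by least
   squares.
3. The observed AR range is cut into $k$ application bins and the curve,
   evaluated at each bin's median AR and floored at 1, becomes that bin's
   threshold $\tau_i$, fed per gene into tTREAT (or TREAT).

Choices made where the procedure was genuinely open: the percentile uses
linear interpolation between order statistics (R's default convention --
any fixed convention works, this one is stated and tested against a
brute-force order-statistic oracle); application-bin edges are evenly
spaced in $\log_2(AR)$, because digital counts span orders of magnitude
and expression "ranges" are naturally multiplicative; the curve is
evaluated at the bin *median* AR (midpoint and edge were candidates;
median is robust to the skewed within-bin AR distribution); thresholds are
floored at 1 because a folded fold change cannot be below 1; and the curve
is fitted on informative genes only, for consistency with what is tested.
Defaults $m = k = 10$ and $b = $ P70, the midpoint of the advisable
P55--P95 range (low percentiles when many DE genes are expected, high when
few). Empty application bins are merged with their neighbours (logged).
The fitted curve is *not* itself a DE decision rule -- it only sets the
thresholds for the subsequent test.

## Simulation engine

The generator emulates a two-group digital-count experiment at the level
of the gene-wise sufficient statistics, not raw counts:

* 100 gene variances $\sigma_g^2 \sim \mathrm{InvGamma}(g_1, g_2)$;
* each $\sigma$ yields three true log2 differences $\beta$ and each
  $\beta$ three estimate/variance pairs, i.e. nine genes per $\sigma$ and
  900 genes per dataset -- so one percent of genes is exactly one
  $\sigma$'s worth, and truth-group allocation is exact by construction;
* truth groups at the $\sigma$ level: DE genes draw
  $\beta \sim N(0, (\sigma v_{start})^2)$ rejection-sampled to
  $|\beta| \ge \log_2\omega$; noisy non-DE genes the same with
  $|\beta| < \log_2\omega$; regular non-DE genes (a fixed 20% of the
  dataset) have $\beta = 0$. Rejection sampling is statistically identical
  to truncated-normal inversion and simpler to audit. A consequence of
  the truncation: the distributional centre of DE-gene estimates sits a
  little beyond $\omega$; no correction is applied.
* observed $\hat\beta \sim N(\beta, (\sigma\sqrt z)^2)$ and
  $s^2 \sim \sigma^2\chi^2_{df}/df$, with $v_{start} = 8$, $df = 10$ and
  $z = 1/3$ by default (a 6 vs 6 design; both configurable since the
  generating design is in principle free).

The packaged variance prior $(g_1, g_2) = (3, 0.5)$ -- mean
$\sigma^2 = 0.25$ on the log2 scale -- is the package's own choice of a
realistic count-data variance population; it is deliberately labelled as
such and not fitted to any published dataset. `fit_invgamma_ml()`
(numerical ML on the log-parameter scale, method-of-moments start,
checked against a grid-search oracle) closes the loop: simulations can be
seeded from real residual variances.

What the generator does *not* emulate: raw lane counts, normalization
artefacts, cartridge batch effects, or count discreteness. Passing
simulation-based tests therefore validates the testing and evaluation
machinery under the stated hierarchy, not the normalization path -- that
is exercised separately by the count-fixture generator, which writes
cartridge-like tables with known lane factors and background.

## Evaluation

DE calls are scored against truth as false discoveries (truth-negative
called) and missed genes (truth-positive not called). Ranking performance
is the midrank Mann--Whitney AUC on the percent scale, fed with
$1 - p$ as the score -- the p-value ordering is the only ranking every
method supplies, and midranks matter because threshold tests produce many
tied $p = 1$ genes by construction. Batch summaries report means with
empirical 95% prediction intervals (2.5/97.5 percentiles across
replicates; percentile intervals are distribution-free and reproducible)
and signed percent changes versus a reference method.

At 100 replicates (the suite's and acceptance script's size; the full
design uses 400, and `n_reps` is a parameter throughout) the expected
orderings are stable: the classical-t threshold test yields fewer false
discoveries than its moderated counterpart across $\omega = \tau \in
\{1.3, 1.5, 2\}$; a stringent threshold trades false discoveries for
missed genes; and the two-stage design lies between the reference and the
stringent test on both axes.

## Known limitations

* The p-value bound is conservative by design; p-values are not uniform
  under the null, so FDR procedures that assume uniformity do not apply
  cleanly (and the default applies none).
* The running FC model fits thresholds and tests on the same dataset;
  with an independent calibration dataset available, fitting there first
  is preferable.
* One fitted curve family ($a + b/AR$) is supported; it fits digital
  count data well in practice but is not checked against alternatives.
* The two-group design is first-class; arbitrary multi-factor contrasts
  beyond the general `design_spec` (full-rank $X$, single contrast) and
  weighted regression are out of scope.
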