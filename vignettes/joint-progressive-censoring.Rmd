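---
title: "Two GIED populations under joint progressive type-II censoring: methods and numerical choices"
author: "jointGIED"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two GIED populations under joint progressive type-II censoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jointGIED)
```

## The model and its assumptions

Line 1 places $m$ units and line 2 places $n$ units on a joint life test.
Lifetimes are i.i.d. within lines, independent across lines, and follow the
generalized inverted exponential distribution (GIED)

$$F(x;\theta,\lambda) = 1 - \bigl(1 - e^{-\lambda/x}\bigr)^{\theta},
\qquad x > 0,$$

with a **shared** $\lambda$ and line-specific exponents $\theta_1,
\theta_2$.  The shared-$\lambda$ assumption is what makes the two lines
comparable through their exponents alone; on real data it should be checked
first (the package provides a likelihood-ratio test, `gied_lrt`).  The GIED
hazard rises and then falls (unimodal), and larger $\theta$ means
stochastically *earlier* failure: the survival $(1-e^{-\lambda/x})^\theta$
decreases in $\theta$.  The literature is inconsistent about calling
$\theta$ or $\lambda$ the "shape"/"scale", so the package uses the symbols
only.  Under the time rescaling $x \to cx$ the model is closed with
$\lambda \to c\lambda$ and $\theta$ unchanged, which is why dividing the
jute strengths by 1000 is harmless.

Under joint progressive type-II censoring (JPC) the pooled test stops at
the $k$-th failure, and at the $i$-th failure $R_i$ surviving units are
withdrawn *uniformly at random* from the pooled risk set; the scheme must
satisfy $\sum_{i=1}^k (R_i + 1) = m + n$.  The observed record is
$(w_i, z_i, s_i, t_i)$: failure time, failing line, and the line split of
the withdrawal.  The likelihood (up to a parameter-free constant) is

$$\ell = k_1\ln\theta_1 + k_2\ln\theta_2 + k\ln\lambda
 + \sum_i \bigl[\theta_1 s_i + \theta_2 t_i + z_i\theta_1 +
 (1-z_i)\theta_2 - 1\bigr] A_i - \sum_i \Bigl[2\ln w_i +
 \frac{\lambda}{w_i}\Bigr],$$

with $A_i = \ln(1 - e^{-\lambda/w_i}) < 0$ and $k_1 = \sum z_i$,
$k_2 = k - k_1$.

## Estimation

**Profile likelihood.**  At fixed $\lambda$ the likelihood is concave in
$(\theta_1,\theta_2)$ with closed-form maximizers $\hat\theta_1(\lambda) =
-k_1/M(\lambda)$, $\hat\theta_2(\lambda) = -k_2/N(\lambda)$, where
$M = \sum (z_i + s_i) A_i$ and $N = \sum (1 - z_i + t_i) A_i$.  The profile
$p_1(\lambda)$ is unimodal, so `jgied_fit(method = "profile")` needs only a
bounded one-dimensional search; the bracket upper end is doubled until the
profile has turned down (capped at 60 doublings), which is sound *because*
of unimodality.

**EM.**  `jgied_fit(method = "em")` treats the withdrawn units' lifetimes
as missing data.  Each iteration is an expectation/conditional-maximization
cycle: (a) with the exponents fixed, the expected complete-data
log-likelihood is maximized over $\lambda$, where the censored-unit terms
$E[\ln(1-e^{-\lambda'/U}) \mid U > w_i]$ are re-integrated at every
candidate $\lambda'$ under the *current* parameters — this keeps the step a
true EM step; (b) the E-step is refreshed at the new $\lambda$ and the
exponents update in closed form, mirroring the profile formulas with the
censored expectations added to the denominators.  Both sub-steps are
preceded by an E-step at the current parameters, so the observed
log-likelihood cannot decrease (verified to $10^{-6}$ slack in the tests).
Iteration stops when all three coordinates move by at most `tol` (default
$10^{-4}$, the customary choice) or after `max_iter` (500); non-convergence
is flagged, not raised.  The default start maximizes the profile on a
coarse 20-point log grid — published simulation studies start at the
generating truth, which is unavailable in practice (the Monte Carlo driver
exposes `init_truth = TRUE` to reproduce that convention).

Profile and EM solve the same maximization; their agreement to $10^{-3}$
per coordinate across the published study schemes is an acceptance test.

**Degenerate inputs.**  When every observed failure comes from one line
($k_1 = 0$ or $k_2 = 0$), the likelihood is monotone in the unrepresented
exponent and no MLE exists; the package raises a classed error
(`"jgied_no_mle"`), and the simulation drivers redraw such replicates.  A
second, subtler degeneracy: for a $k = 2$ sample with one failure and one
withdrawal per line, $k_1/w_1 + k_2/w_2 = \sum 1/w_i$ exactly, the
$\lambda$-linear terms of the profile cancel, and $p_1(\lambda)$ grows like
$k\ln\lambda$ without a finite maximizer.  Unimodality then holds only in
the weak (monotone) sense.  Realistic sample sizes are strictly on the
bounded side of this knife edge; the test suite pins both behaviours with
deterministic fixtures.

## E-step and information integrals

All conditional expectations use the probability-integral substitution
$v = (1-e^{-\lambda/u})^{\theta}$: the survival of a GIED variate is
uniform, so given $U > w$, $v$ is uniform on $(0, (1-e^{-\lambda/w})^
{\theta})$ and every integral runs over a bounded interval with at worst a
logarithmic singularity at 0 — comfortable territory for
`stats::integrate` (`rel.tol` $10^{-9}$–$10^{-10}$).  At matching
$\lambda$'s one moment has the closed form
$E[\ln(1-e^{-\lambda/U}) \mid U > w] = \ln(1-e^{-\lambda/w}) - 1/\theta$;
the implementation always integrates and the closed form serves as an
independent oracle (agreement to $10^{-8}$ is an acceptance test).

The observed information is assembled by the missing-information principle,
$I_o = m I_1 + n I_2 - \sum_i [s_i I_{U|w_i} + t_i I_{V|w_i}]$, from
*expected* per-unit matrices: the $\theta\theta$ entries are exactly
$1/\theta^2$; the $\theta\lambda$ and $\lambda\lambda$ entries are
quadrature expectations of the analytic second derivatives (the closed-form
expectation expressions cited alongside the original derivation are not
available in the source text, so quadrature with a Monte Carlo
finite-difference cross-check replaces them — numerically equivalent and
independently verifiable).  Because the assembly uses expected rather than
realized per-unit information, it matches the numerical Hessian of the
observed log-likelihood exactly only in the $\theta\theta$ entries; the
package also exports the finite-difference Hessian (`jgied_hessian_info`)
as a clearly-labelled diagnostic.  Standard errors in `summary.jgied_fit`
are square roots of the diagonal of $I_o^{-1}$.

## Intervals

**Bootstrap-p** (`jgied_boot`, `confint.jgied_fit`): parametric — $B$
samples are simulated from the fitted model *under the same scheme* and
refitted by profile; the interval is the pair of order statistics of ranks
$\lfloor B\zeta/2 \rfloor$ and $\lfloor B(1-\zeta/2) \rfloor$.  Parametric
is the only coherent choice: censored two-line records cannot be resampled
nonparametrically while preserving the scheme.  Replicates with $k_1 = 0$
or $k_2 = 0$ are discarded and redrawn (counted in `n_discarded`).  A tiny
offset ($10^{-9}$) inside the floor guards against binary-representation
slippage (e.g. $1000 \times 0.10/2$ evaluating just below 50).

**Credible intervals** (`confint.jgied_bayes`): the estimand is sorted over
the draws (stably; ties keep draw order) with normalized weights carried
along, and all windows $(n_1, n_2)$ whose enclosed mass does not exceed the
level while adding one more draw would exceed it are enumerated; the most
tail-balanced window is returned.  With uniform weights this coincides with
the percentile rule up to one order statistic — the two conventions differ
only when a window mass lands exactly on the level, a set of measure zero
for continuous weights.

## Bayesian machinery

With independent Gamma priors $\theta_1 \sim Ga(a_1,b_1)$, $\theta_2 \sim
Ga(a_2,b_2)$, $\lambda \sim Ga(c,d)$ (shape/rate), the posterior factorizes
as $\pi(\lambda\,|\,\text{data})\,\pi(\theta_1\,|\,\lambda)\,
\pi(\theta_2\,|\,\lambda)\,d(\lambda)$ with all three factors Gamma —
$\lambda$: shape $c+k$, rate $d+\sum 1/w_i$; $\theta_j\,|\,\lambda$: shapes
$a_j + k_j$ and rates $b_j - M(\lambda)$, $b_j - N(\lambda)$, automatically
positive since $A_i < 0$ — and a weight $d(\lambda)$ free of the exponents.
`jgied_bayes` draws the triple $M$ times (default $10^4$) and normalizes
the weights by log-sum-exp; the products $\prod_i(1-e^{-\lambda/w_i})^{-1}$
overflow quickly in raw arithmetic, so *all* weight algebra is in log
space.  The effective sample size $1/\sum q_i^2$ is reported and a note is
printed below $0.05\,M$; heavy censoring with near-flat priors does drive
the ESS low, which widens Monte Carlo error but biases nothing.

Point estimates: squared-error loss gives the weighted posterior mean;
linex loss gives $-h^{-1}\ln\sum_i q_i e^{-h g_i}$ (log-sum-exp again),
with $h = 2$ the customary default and $h \to 0$ recovering the
squared-error estimate.  The default prior sets all six hyper-parameters to
$10^{-5}$, the standard near-flat choice; the informative benchmark
$a_1{=}2, b_1{=}1, a_2{=}1, b_2{=}2, c{=}3, d{=}2$ appears in the examples.
The prior keeps the posterior proper even for data where the likelihood
alone is improper in $\lambda$.

## Order restriction $\theta_1 < \theta_2$

When line 1 is known to be the stronger product, the MLE under
$\theta_1 \le \theta_2$ follows from concavity: if the unrestricted
$\hat\theta$'s already satisfy the order, nothing changes; otherwise the
maximum sits on the diagonal with the pooled closed form $\tilde\theta =
-k / \sum_i (R_i+1) A_i$ (the unique positive stationary point along
$\theta_1 = \theta_2$, confirmed against a one-dimensional grid oracle).
The restricted profile over $\lambda$ is again unimodal.  The restricted
fit always uses the profile search — a restricted EM variant is not
defined and not needed.

The restricted *Bayesian* analysis starts from the symmetrized prior
$\pi_0' \propto (\theta_1^{a_1-1}\theta_2^{a_2-1} +
\theta_1^{a_2-1}\theta_2^{a_1-1})\,\mathbb{1}\{\theta_1 < \theta_2\}\times
\cdots$, whose sampler the source derivation leaves open.  This package's
completion: the unrestricted posterior under $\pi_0'$ is a two-component
Gamma-product mixture (shapes $a_1{+}k_1/a_2{+}k_2$ and swapped
$a_2{+}k_1/a_1{+}k_2$, rates shared); draws come from that mixture with
component probabilities proportional to the components' normalizing
constants at the drawn $\lambda$, and the importance weight acquires the
factor $Z_A(\lambda) + Z_B(\lambda)$ and the indicator
$\{\theta_1 < \theta_2\}$.  The scheme is validated only against the
package's own nested-quadrature oracle (posterior probability of the order
on a small sample, within 2%), never against published numbers — none
exist.  If no draw satisfies the order the function errors with advice to
increase $M$.

## Goodness of fit and the common-$\lambda$ test

`gied_ks` offers two empirical-cdf conventions.  `positions = "mean"`
(default) measures $\max_i |i/(n{+}1) - F(x_{(i)})|$ at mean plotting
positions, the convention of reliability practice and the one under which
the published jute-fibre distances (0.121, 0.151) reproduce — the 10 mm
set to printed precision, which identifies the convention.
`positions = "ecdf"` is the classical two-sided statistic (0.142, 0.162 on
the same fits; it equals `stats::ks.test`'s D exactly, a test-suite
cross-check).  The p value uses the asymptotic Kolmogorov series at
$\sqrt n D$ and ignores both parameter estimation and the
plotting-position shift: treat it as a descriptive index, not a calibrated
test.

`gied_lrt` tests a common $\lambda$ across two complete samples: two free
fits (4 parameters) against the joint common-$\lambda$ model (3
parameters), $\chi^2_1$.  On the jute data this gives statistic 1.944,
p = 0.163.  The analysis that accompanies the original data reports
p = 0.688 for this test; that value corresponds to a statistic of 0.161
and is not recovered by this construction nor by any standard variant we
tried (Wald on $\hat\lambda_1 - \hat\lambda_2$: 0.173; common-$\lambda$ vs
fully pooled: 0.719; common-$\theta$ null: 0.425), while the MLEs printed
beside it reproduce to all digits.  The package keeps the faithful
likelihood-ratio construction.

## What the generator emulates — and what a green test establishes

`rjpc` implements the stated world exactly: GIED lifetimes per line,
failure-by-failure minimum-taking, and uniformly random withdrawal subsets
(hypergeometric line split), the natural reading of withdrawal "at random"
with no stated weighting.  Ties (probability zero in theory, possible in
rounded real data) break line-1-first then by input order, so a fixed RNG
state reproduces a sample bit-for-bit.  The generator does *not* emulate:
inspection-time rounding, dependence between lines sharing a test rig,
non-GIED misspecification, or any deterministic withdrawal rule an
experimenter might actually use.  Green simulation tests therefore
establish internal correctness of the estimators under the model, not
robustness to these departures.  Published censored-data analyses of the
jute data depend on which survivors the authors' unrecorded withdrawals
removed; those numbers are seed-dependent here and are reproduced
structurally, not numerically (`jgied_real_data` flags the section).

The simulation defaults mirror the published study design: $m = 20$,
$n = 25$, $k \in \{20, 25, 30\}$, truth $(1, 1, 0.5)$, level 0.90,
$B = 1000$ bootstrap replicates, $M = 10^4$ draws, $h = 2$.  The
acceptance-grade calibration run scales the *outer* replicates from 1000
to 200 (binomial coverage error $\approx 2$ points) to fit a CPU-minutes
budget, keeping $B = 1000$; three misprinted scheme strings in the
published design table (two in the $k{=}25$ row, one in $k{=}30$) are
corrected to the row patterns that satisfy $\sum(R_i+1) = 45$.

## Known limitations

* The expected-information assembly of $I_o$ is an approximation to the
  realized observed information under censoring; use
  `jgied_hessian_info` when the distinction matters.
* The importance sampler's ESS degrades under heavy censoring with
  near-flat priors; raise $M$ or supply a mildly informative prior.
* K-S p values are asymptotic and estimation-blind (see above).
* Exactly two populations; no type-I or hybrid censoring variants; no
  order restriction on $\lambda$.
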