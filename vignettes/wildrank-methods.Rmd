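---
title: "Rank-based tests with wild bootstrap calibration for incomplete repeated measures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based tests with wild bootstrap calibration for incomplete repeated measures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wildrank)
```

## The model

`wildrank` analyzes factorial repeated-measures designs: $a$ independent
groups of subjects, each subject measured at $d$ occasions, with subject $k$
of group $i$ contributing a random vector
$X_{ik} = (X_{i1k}, \dots, X_{idk})^\top$. Measurements may be continuous,
discrete or ordered categorical; no moments are assumed to exist. Each
marginal is described by its *normalized* distribution function
$F_{ij} = \tfrac12 (F_{ij}^+ + F_{ij}^-)$, the average of the right- and
left-continuous versions, which makes ties unproblematic and puts continuous
and ordinal data in one framework.

Missing values are tracked by indicators $\lambda_{ijk} \in \{0, 1\}$
($1$ = observed). All estimators use all available data; nothing is imputed.
The theory underlying the tests assumes the missingness is completely at
random (MCAR), and the simulation toolkit additionally provides two
missing-at-random mechanisms to probe robustness against violations of that
assumption.

Null hypotheses are linear constraints on the vector
$F = (F_{11}, \dots, F_{ad})^\top$ of distribution functions,
$H_0\colon CF = 0$, with a contrast matrix $C$ (rows summing to zero).
`contrast_matrix()` builds the three factorial standards via Kronecker
products of centering matrices $P_m = I_m - \tfrac1m J_m$:

* no group effect: $C = P_a \otimes \tfrac1d J_d$,
* no time effect: $C = \tfrac1a J_a \otimes P_d$,
* no interaction: $C = P_a \otimes P_d$.

Only the row space of $C$ matters: every representation yields the same
projection $T = C^\top (C C^\top)^+ C$ and the same test. (The group
hypothesis is often written with $1_d 1_d^\top$ instead of $\tfrac1d J_d$;
we normalize by $1/d$, which spans the same rows and keeps the conditioning
of the Wald quadratic form comparable across different $d$.)

## Effects, ranks, covariance

The scalar summary of cell $(i,j)$ is the relative marginal effect
$p_{ij} = \int H \, dF_{ij}$, where $H = N^{-1} \sum_{ijk} \lambda_{ijk}
F_{ij}$ is the observation-weighted mean distribution and $N$ the total
number of observed values. Its estimator only needs the pooled mid-ranks
$R_{ijk}$ of the observed values:
$$\hat p_{ij} = \frac{1}{\lambda_{ij\cdot}} \sum_{k} \lambda_{ijk}
  \frac{R_{ijk} - 1/2}{N},$$
with $\lambda_{ij\cdot}$ the number of observed subjects in the cell.
Mid-ranks are computed by sorting with average tie assignment; the package's
test suite holds them against the $O(N^2)$ counting-function definition,
which they must reproduce exactly. Two consequences worth noting: the
weighted mean $\sum_{ij} (\lambda_{ij\cdot}/N)\, \hat p_{ij}$ is exactly
$1/2$ on every dataset, and every statistic below is invariant under strictly
monotone transformations of the data.

The covariance of $\sqrt{n}\,\hat p$ ($n$ = total subjects) is estimated
blockwise per group with pairwise-complete sums. Writing
$\Delta_{i,jj'} = \sum_k \lambda_{ijk}\lambda_{ij'k}$:
$$\hat v_i(j,j) = \frac{n_i \sum_k \lambda_{ijk}(R_{ijk} - \bar R_{ij\cdot})^2}
  {N^2\, \lambda_{ij\cdot}(\lambda_{ij\cdot} - 1)},
  \qquad
  \hat v_i(j,j') = \frac{n_i \sum_k \lambda_{ijk}\lambda_{ij'k}
  (R_{ijk} - \bar R_{ij\cdot})(R_{ij'k} - \bar R_{ij'\cdot})}
  {N^2 \{(\lambda_{ij\cdot}-1)(\lambda_{ij'\cdot}-1) + \Delta_{i,jj'} - 1\}},$$
assembled as $\hat V_n = \bigoplus_i (n/n_i) \hat V_i$ and
$\hat D_n = \mathrm{diag}(\hat V_n)$. Estimation requires
$\lambda_{ij\cdot} \ge 2$ in every cell; `rank_test()` refuses designs that
fail this and names the offending cells. An off-diagonal denominator can be
non-positive for extremely sparse masks ($\Delta_{i,jj'} \le 1$ with tiny
cells); that entry is set to zero with a warning rather than aborting, a
choice made so that bootstrap replicates on sparse masks never crash a run.

## The three statistics

* **WTS** $T_W = n \hat p^\top C^\top (C \hat V_n C^\top)^+ C \hat p$, compared
  to $\chi^2_f$, $f = \mathrm{rank}(C)$. Asymptotically exact when the
  limiting covariance is nonsingular, but the convergence is slow and the
  asymptotic test is markedly liberal in small samples (the simulations below
  show rejection rates of 20% and more at $n = 10$).
* **ATS** $T_A = n \hat p^\top T \hat p / \mathrm{tr}(T \hat V_n)$, compared
  to $F(\hat f, \infty)$ with the Box-type estimate
  $\hat f = \mathrm{tr}(T\hat V_n)^2 / \mathrm{tr}(T\hat V_n T\hat V_n)$.
  $F(\hat f, \infty)$ is evaluated as $\chi^2_{\hat f}/\hat f$ with
  continuous degrees of freedom, which is its definition; $\hat f$ is
  generically non-integer. The approximation does not match the true limit
  law (a weighted sum of $\chi^2_1$ variables), so even asymptotically the
  test is approximate. Under sphericity, $T\hat V_n = c\,T$, the identity
  $\hat f = \mathrm{rank}(T)$ holds exactly.
* **MATS** $T_M = n \hat p^\top C^\top (C \hat D_n C^\top)^+ C \hat p$
  standardizes by the variances only, stays valid under singular covariance,
  and coincides with the WTS whenever $\hat V_n$ is diagonal. Its limit law
  has unknown weights; we deliberately report no asymptotic p-value for it —
  MATS is calibrated by the bootstrap alone. It requires all
  $\hat v_i(j,j) > 0$, which fails for, e.g., a constant cell.

Pseudoinverses and ranks are spectral with a relative eigenvalue cutoff of
$10^{-10}$ times the largest magnitude. Kronecker-built contrasts have exact
integer ranks far above that threshold, and the same tolerance is used for
$f = \mathrm{rank}(C)$ and for $(C\hat V_n C^\top)^+$ so the two cannot
disagree.

## Wild bootstrap calibration

Critical values come from a wild bootstrap on the centered rank vectors
$Z_{ik} = R_{ik} - \bar R_{i\cdot}$: each *subject* receives one i.i.d.
weight $W_{ik}$ with mean 0 and variance 1, shared across all $d$ of its
coordinates, and $Z^*_{ik} = W_{ik} Z_{ik}$. Sharing the weight within a
subject is what preserves the within-subject covariance; independent weights
per coordinate would destroy it. Unobserved entries of $Z$ are carried as
zeros and multiply $\lambda = 0$ in every sum, so a replicate never invents a
missing coordinate. From $Z^*$ the effect vector, $\hat V^*_n$ and
$\hat D^*_n$ are recomputed with the same formulas (replicate means
$\bar Z^*_{ij\cdot}$ recomputed each time), and the statistic is re-evaluated
with its own formula family. The p-value is
$B^{-1} \sum_b 1\{T^*_b \ge T\}$ — with $\ge$ and denominator $B$.

Weight schemes: Rademacher ($\pm 1$, the default and the recommended choice,
with the best type-I error control in our and the original simulations),
Mammen's two-point, standard normal, and centered Poisson. For Rademacher
weights the replicate map is sign-symmetric ($W$ and $-W$ give identical
statistics) and $W^2 = 1$ preserves the uncentered sums of squares of $Z$.

Numerical conventions, all exercised by tests:

* A replicate with $\mathrm{tr}(T\hat V^*_n) \le 0$ (possible only in
  near-degenerate designs) contributes $T_A^* = 0$ and is tallied in the
  result diagnostics; this can only enlarge the ATS p-value, never shrink it.
* Reproducibility: one root seed per call, scoped so the caller's RNG state
  is untouched. The full weight matrix is drawn from that single stream in a
  fixed replicate-major order, and weights are assigned to subjects in a
  canonical order (lexicographic by observation mask, then observed values).
  The canonical sort makes the seeded p-value invariant under permutation of
  subjects within groups and under strictly increasing transformations of the
  data. Per-replicate RNG substreams were considered and rejected: they add
  value only for parallel execution, which is out of scope here.
* The replicate loop is compiled (RcppArmadillo); the R-level reference
  implementations (`bootstrap_effects()`, `bootstrap_covariance()`) are kept
  exported and the test suite requires the two routes to agree to $10^{-10}$.

## The simulation toolkit

`generate_continuous()` draws a Gaussian copula: a multivariate normal with
correlation matrix taken from the chosen setting, mapped to uniforms and then
through the target marginal quantile function (standard normal, standard
Laplace, standard lognormal, $\chi^2_{15}$). The dependence settings are
AR(1) with $\rho = 0.6$, the identity, and the linear Toeplitz matrix
$d - |l - j|$ (normalized by its diagonal $d$ before entering the copula,
since a copula consumes a correlation and the marginals fix the scale).
Because the marginal map is strictly increasing, the ranks of a generated
dataset — and hence the null distribution of every statistic — do not depend
on the marginal at a fixed seed; the toolkit still exposes all four marginals
for fidelity of the reported scenarios and for power studies, where the
location shift `shift` is added *after* the transform, on the final scale.

`generate_ordinal()` produces four-level scores
$X = \lfloor 4(cZ_{ik} + Y_{ijk})/(c+1)\rfloor + 1$ from independent
uniforms, with the subject effect $Z_{ik}$ inducing a compound-symmetric
dependence; $c = 1$ gives a triangular latent marginal with
$P(X{=}1) = 1/8$.

Missingness mechanisms: `apply_mcar()` deletes every coordinate
independently with probability $r$ (the Bernoulli indicator convention is
resolved so that $r$ *is* the missing probability). `apply_mar1()` and
`apply_mar2()` implement missingness-at-random via (determining, target)
coordinate pairs — $(1,2), (3,4)$ for $d=4$; $(1,2), (1,3), (6,7), (6,8)$ for
$d=8$, so coordinates 4 and 5 are never missing there. MAR1 stratifies
subjects at $\pm 2\hat\sigma$ of the determining coordinate and deletes the
target with probability 0.15 (outer strata) / 0.30 (middle); MAR2 splits at
the median with probabilities 0.10 / 0.30. All three mechanisms redraw the
entire mask (up to 1000 attempts) whenever a cell would retain fewer than 2
observed subjects, because the covariance estimator is undefined otherwise;
the simulated estimand is therefore conditional on mask validity, which is
also what the estimators' assumptions require. The number of attempts is
recorded in the `"mask_tries"` attribute.

`run_type1_study()` and `run_power_study()` tie this together: per simulated
dataset they compute the asymptotic WTS and ATS p-values and the three
bootstrap p-values, and report rejection rates at level $\alpha$ (in percent)
with binomial Monte Carlo standard errors.

## What the generators do and do not emulate

The synthetic data reproduce the features the method is sensitive to:
arbitrary continuous or ordinal marginals, heavy tails and skewness, three
qualitatively different within-subject dependence patterns, unbalanced
groups, and realistic missingness rates (10–30%). They do not emulate
features of real trials such as dropout monotonicity (the fluvoxamine study
has a monotone pattern; MCAR/MAR here are non-monotone), time trends under
the null, covariate-dependent missingness beyond the two MAR mechanisms, or
cluster structure. Passing calibration checks on these generators therefore
supports the small-sample validity of the bootstrap tests under
MCAR-like conditions, but says nothing about informative missingness — the
tests' own assumptions end at MCAR, and analyses of data with suspected
missing-not-at-random mechanisms should be framed as sensitivity analyses.

## Problem sizes and defaults

Analysis default: $B = 999$ bootstrap replicates, Rademacher weights,
$\alpha = 0.05$. The packaged calibration checks run each reference scenario
at 2000 simulated datasets with $B = 499$, a size at which the binomial
3-standard-error band around a 5% rate is about $\pm 1.5$ percentage points;
that is the agreement required of the reproduced type-I error rates. The
null-uniformity check uses 1000 datasets of a complete balanced two-group
design ($n_i = 20$, $d = 4$) and a Kolmogorov–Smirnov test at $\alpha = 0.01$
on the ATS bootstrap p-values (which are discrete on $\{0, 1/B, \dots, 1\}$;
at $B = 499$ the discreteness displaces the KS statistic by at most
$1/(2B) \approx 0.001$, negligible against the 0.0515 critical value).

## Known limitations

* Hypotheses are about distribution functions, $CF = 0$ — stronger than
  hypotheses about the relative effects $Cp = 0$. Rejections speak to
  distributional differences; the package does not provide confidence
  intervals for $p$ or multiple-contrast (max-type) tests.
* Factorial structures on groups or occasions beyond one group factor and
  one time factor must be encoded by the user (flatten the labels, or supply
  a custom contrast).
* MATS has no asymptotic p-value by construction, and the asymptotic WTS
  should not be trusted below $n \approx 30$ per group; the bootstrap ATS is
  the recommended default throughout.
* Cells with a single observed subject (or none) are unanalyzable and are
  reported as errors, not worked around.

## A worked example

```{r example}
x <- demo_fixture()          # 4 subjects, 2 occasions, one missing value
print(x)
rank_test(x, "time", B = 999, seed = 1)
```

```{r simulate, eval = FALSE}
# a reduced replica of one reference calibration scenario
cfg <- scenario(a = 1, d = 4, n = 30, marginal = "normal",
                cov_setting = "AR", missing = "MCAR", r = 0.1,
                hypothesis = "time", nsim = 2000, B = 499, seed = 1)
run_type1_study(cfg)
```
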