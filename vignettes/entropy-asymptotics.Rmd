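---
title: "Asymptotic laws for plug-in entropies of multinomial counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Asymptotic laws for plug-in entropies of multinomial counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(entrotest)
```

## The statistical problem

A categorical sample over $k$ ordered categories is a single draw
$N = (N_1, \dots, N_k) \sim \mathrm{Mult}(n, p)$, and the observed
proportions $\hat p = N/n$ are the maximum-likelihood estimate of $p$.
Any scalar functional of $\hat p$ — an entropy, a diversity index, an
information measure — is therefore a random variable, and comparing two
samples through such functionals requires its sampling distribution.
`entrotest` implements closed-form large-$n$ laws for four plug-in
functionals:

* **Shannon entropy** $H_S = -\sum_\ell p_\ell \log p_\ell$,
* **Tsallis entropy of order $q \ne 1$**
  $H_T^q = \sum_\ell (p_\ell - p_\ell^q)/(q - 1)$,
* **Rényi entropy of order $q > 0$, $q \ne 1$**
  $H_R^q = \log\!\big(\sum_\ell p_\ell^q\big)/(1 - q)$,
* the **discrete Fisher information measure**
  $H_F = F_0 \sum_{\ell=1}^{k-1} (\sqrt{p_{\ell+1}} - \sqrt{p_\ell})^2$,
  which unlike the other three depends on the *ordering* of the
  categories.

The starting point is the multivariate central limit theorem for
proportions, $\sqrt n(\hat p - p) \to N(0, \Sigma_p)$ with
$\Sigma_p = D_p - p p^\top$, propagated through each functional's
per-category component functions by the multivariate delta method
(`multinomial_covariance()`, `entropy_gradient()`,
`delta_covariance()`). Shannon, Tsallis, and Fisher estimates are
asymptotically normal with mean equal to the functional at $p$ and an
$O(1/n)$ variance. The Rényi entropy is different: the *power sum*
$S = \sum_\ell \hat p_\ell^q$ is asymptotically
$N(\mu_*, \sigma_*^2)$ with $\mu_* = \sum p_\ell^q$ and
$\sigma_*^2 = (q^2/n)\big(\sum p_\ell^{2q-1} - \mu_*^2\big)$, and the
entropy $\log(S)/(1-q)$ follows the induced law of the logarithm of (the
absolute value of) a normal variable, exposed through
`renyi_limit_density()`, `law_cdf()`, and `sample_law()`.

Because the diagonal-gradient families contract to a weighted quadratic
form, the package evaluates every normal-law variance as
$\big(\sum_\ell p_\ell a_\ell^2 - (\sum_\ell p_\ell a_\ell)^2\big)/n$
with $a_\ell$ the per-category derivative ($\log p_\ell + 1$ for
Shannon, and analogously for the others). The test suite verifies this
contraction against the explicit double-sum formula and against the
entrywise closed forms of $B \Sigma_p B^\top$ to $10^{-12}$.

## The two-sample entropy z-test

`entropy_test()` compares two samples through

$$z = \frac{|H_1(\hat p_1) - H_2(\hat p_2)|}
  {\sqrt{\hat\sigma^2(n_1, \hat p_1) + \hat\sigma^2(n_2, \hat p_2)}},
  \qquad p \approx 2(1 - \Phi(z)),$$

with each variance evaluated at that sample's own plug-in proportions
and sample size — not pooled, since under the null only the *entropies*
are equal, not necessarily the underlying distributions. Normalized
entropies live on a common $[0,1]$ scale, so the two samples may have
different numbers of categories (e.g. a five-level survey item against
its three-level collapsed version, via `collapse_categories()`), and
even different functionals may be compared (with a warning that the
null then asserts equality of two different quantities). The test is
approximate, with no finite-sample correction; no multiplicity
adjustment is applied to families of pairwise tests, matching how such
pairwise survey comparisons are conventionally reported.

The `chisq_homogeneity()` baseline (Pearson $\chi^2$ on the pooled
$2 \times k$ table, no continuity correction) compares the samples
count by count. The entropy test deliberately discards information — it
compares one scalar per sample — so its p-values are systematically
larger than the $\chi^2$ test's when distributions differ in ways the
entropy does not see.

## Conventions and tunable parameters

* **Logarithms.** Natural logarithm everywhere; raw entropies are in
  nats. Normalized entropies divide by the maximum over the simplex
  ($\log k$ for Shannon/Rényi; $(1 - k^{1-q})/(q-1)$ for Tsallis) and
  are base-invariant, which the tests assert directly.
* **Zero conventions.** $0 \log 0 := 0$ and $0^q := 0$ element-wise
  before summation; these make every *mean* well defined on the closed
  simplex.
* **`f0` (default 4).** The Fisher information's renormalization
  coefficient. With `f0 = 4` the measure is 0 at the uniform
  distribution and usually below 1, but not always (an interior point
  mass on three categories gives 8); the package evaluates the defining
  formula verbatim and never clamps.
* **`q`.** Tsallis requires $q \ne 1$, Rényi $q > 0$, $q \ne 1$; both
  converge to Shannon as $q \to 1$, which the tests check at
  $q = 1 \pm 10^{-6}$.
* **`zero_floor` (default `1e-10`).** See the next section.
* **`fisher_variance` (`"delta"` default, `"paper"` alternative)** and
  **`renyi_variance` (`"power_sum"` default, `"delta"` alternative).**
  See below.

## Near-zero categories and the variance floor

Several variance terms behave badly as a cell probability approaches
zero while the corresponding mean term stays harmless. The
one-almost-zero synthetic model makes the issue concrete: one cell has
$p = \epsilon_0 \approx 2.2 \times 10^{-16}$, so that cell is *never*
observed at any realistic $n$ and contributes exactly zero sampling
fluctuation. Yet, evaluated literally at $p = \epsilon_0$:

* the Rényi $q = 1/3$ variance term $q^2 p^{2q - 1}$ is
  $\sim 10^{5}$ — formally divergent as $p \to 0$;
* the Tsallis $q = 1/2$ term is finite but tends to the *wrong*
  constant ($q^2/(q-1)^2 = 1$ per unit cell, a discontinuous limit that
  would inflate the asymptotic variance several-fold);
* the Fisher gradient component at that cell involves $1/\sqrt{p}$,
  again with a finite but spurious limiting contribution.

The package therefore applies a single uniform rule: categories with
$p$ strictly below `zero_floor` contribute **zero weight to variance
and gradient terms** (with a classed warning), while **means always
evaluate the plug-in functional directly**. Exact zeros are always
excluded from variance terms — a category that cannot occur does not
fluctuate. This choice is what makes the asymptotic laws empirically
correct for near-degenerate models: Monte-Carlo calibration and the
goodness-of-fit sweep over the one-almost-zero model agree with the
floored laws, and would not with the literal terms. Disabling the floor
(`zero_floor = NULL`) recovers the literal evaluation, and turns exact
zeros under diverging derivatives into an explicit degenerate-support
error for the gradient.

## The Fisher variance: two modes

The delta-method variance of $H_F(\hat p)$ is
$g^\top \Sigma_p\, g / n$ with $g = \nabla H_F(p)$; since $H_F$ carries
the factor $F_0$, the variance carries $F_0^2$. This is the `"delta"`
mode and the default. An alternative closed form circulating for this
quantity scales the component-function quadratic form by $F_0/n$
(not $F_0^2/n$) and uses a $(k-1, k-1)$ diagonal term
$(\sqrt{p_k} - \sqrt{p_{k-1}})^2 (1 - p_{k-1})$ that breaks the
symmetry between the last two cells; the package provides it verbatim
as `fisher_variance = "paper"` for comparison. Monte-Carlo calibration
is the arbiter: at the linear model with $k = 6$, $n = 6000$ and
$10^4$ replicates, the empirical variance of $H_F(\hat p)$ matches the
`"delta"` value within a few percent, while the alternative form is off
by roughly the renormalization scale. `variance_calibration()` lets a
user reproduce this comparison in one call.

## The Rényi variance: two conventions

For Rényi laws the `variance` field follows a convention switch:

* `"power_sum"` (default) stores $\sigma_*^2$, the asymptotic variance
  of the power sum $S$ itself. This is the quantity whose normality the
  theory actually states, and it is the convention under which the
  package's two-sample Rényi tests reproduce the published survey
  analysis it ships as a fixture.
* `"delta"` stores the first-order variance of the *entropy*,
  $\sigma_*^2 / ((1-q)^2 \mu_*^2)$ (divided by $(\log k)^2$ when
  normalized) — the statistically natural scale if one wants an
  entropy-unit standard error.

Both conventions use the same $(\mu_*, \sigma_*)$ parameters, which are
always stored in the law object; densities, CDFs, and samplers depend
only on those and are unaffected by the convention.

The limit density itself is *derived* from the normal law of $S$ by
change of variables with $s(x) = e^{(1-q)x}$, including the
(numerically negligible) negative branch of $|S|$ so that the density
integrates to one exactly. We do not transcribe any printed density
formula: deriving from the normal law keeps the raw and normalized
versions consistent by construction
($\tilde f(x) = \log k \cdot f(x \log k)$).

## Synthetic probability models and what the validation shows

Three one-parameter families generate the validation grid, chosen to
stress the laws in different ways:

* **Linear** ($p_\ell = 2\ell/(k(k+1))$): smooth, fully supported,
  no small cells — the benign case.
* **One-almost-zero** ($p_\ell = 1/k$ except $p_{k-1} = \epsilon_0$,
  $p_k = 2/k - \epsilon_0$): an effectively unobservable cell, the
  stress case for the zero-floor rule. The default $\epsilon_0$ is the
  double machine epsilon, and it is a parameter, not a constant.
* **Half-and-half** ($p_\ell = (1 \pm \epsilon)/k$): a two-level
  stairstep whose single interior jump concentrates the Fisher
  information in one adjacent pair; with small $\epsilon$ the Fisher
  estimate is strongly skewed at moderate $n$, which is exactly where
  normality fails first. Odd $k$ is refused rather than guessing an
  asymmetric split.

`validation_design()` defaults to the full factorial grid:
six functionals (Shannon, Tsallis $1/2$ and $3/2$, Rényi $1/3$ and
$2/3$, Fisher), six model configurations (linear; one-almost-zero;
half-and-half with $\epsilon \in \{0.1, 0.3, 0.5, 0.8\}$),
$k \in \{6, 24, 120, 720\}$, and $n \in \{10^2 k, 10^3 k, 10^4 k\}$ —
432 cells, 300 replicates each. These $k$ are factorials ($3!$ to
$6!$), the natural category counts when the categories are ordinal
patterns of a time series, though the package treats $k$ and $n$ as
free parameters. `normality_sweep()` applies the Anderson–Darling
composite-normality test per cell; `gof_sweep()` applies a one-sample
Kolmogorov–Smirnov test of 50 replicate entropies against the
asymptotic law **at the true generating $p$** — a fully specified
reference, which we consider the honest reading of "goodness of fit of
the asymptotic model" (testing against a per-replicate refit would
absorb part of the misfit being tested).

Within a configuration all six functionals are evaluated on the same
replicate samples, so cells co-reject in clusters; per-cell child seeds
are derived deterministically from the master seed and the cell's
position, making a sweep bit-reproducible and order-independent.

Two systematic findings from running these sweeps are worth stating
because they shape what a user should expect:

* **Anderson–Darling rejections concentrate where theory predicts** —
  the Fisher information over the half-and-half model with
  $\epsilon = 0.1$ at the smallest sample sizes, and the
  small-$n$/small-$k$ corners generally — but the *total* count of
  rejections at the 1% level fluctuates considerably from seed to seed,
  because a band of borderline cells sits near the threshold and flips
  in correlated clusters of five. Only the strongly skewed cells reject
  reproducibly.
* **The Kolmogorov–Smirnov sweep detects the plug-in bias, not just the
  shape.** The plug-in Shannon entropy has mean bias
  $\approx -(k-1)/(2n)$, which is an increasing fraction of the
  $O(n^{-1/2})$ asymptotic standard deviation as $k$ grows at a fixed
  multiplier $n/k$. Against the fixed true-$p$ law this shifts the KS
  statistic and produces rejections at $n = 10^2 k$ for larger $k$
  even though the *shape* is already near-normal. The package does not
  bias-correct (the laws are first-order by design); users comparing
  samples of similar $n$ are unaffected, since the bias largely cancels
  in the two-sample difference, but goodness-of-fit claims at small
  $n/k$ should be read with this in mind.

The generator emulates multinomial sampling exactly (sequential
binomial conditionals, no normal approximation — tail cells with
$n p_\ell \ll 1$ must behave correctly for the one-almost-zero model).
What it does **not** emulate: overdispersion, dependence between
trials, misclassification, or survey weights. Passing sweeps therefore
validate the asymptotic algebra under the multinomial ideal, not
robustness to real-survey complications.

## Numerical and design choices

* Probability vectors must be non-negative and sum to one within
  $10^{-8}$ on input; model constructors produce sums exact to
  $10^{-12}$ or better.
* Category order is authoritative everywhere: file readers preserve
  row order, no function ever sorts, and `collapse_categories()` only
  accepts contiguous order-preserving blocks — anything else would
  silently change the Fisher information.
* Degenerate inputs are explicit: a point mass yields a zero-variance
  law flagged `degenerate`; sampling such a law returns constant draws
  with a warning; a two-sample test in which *both* variances vanish is
  an error rather than a spurious $p = 0$.
* p-values below $10^{-4}$ are printed in scientific notation so that
  small values are never displayed as a row of zeros.
* Test-suite problem sizes were chosen so the whole suite runs in well
  under a minute: Monte-Carlo calibrations use $3 \times 10^3$–$10^4$
  replicates at $n = 6000$, $k = 6$ (where 5–10% agreement bands are
  comfortably stable), the type-I calibration of the two-sample test
  uses 2000 replicate pairs, and the full 432-cell sweep itself takes a
  few seconds since the sampler's cost per replicate is $O(k)$,
  independent of $n$.

## Worked example

The packaged fixture is a three-wave survey item on a five-level
agreement scale (`gss_counts()`):

```{r}
g98 <- gss_counts("1998")
g18 <- gss_counts("2018")
tidy(asymptotic_law(g98, entropy_spec("shannon")))
entropy_test(g98, g18, entropy_spec("shannon"))
```

Collapsing 1998 to three categories and comparing against the
five-category 2018 wave shows the cross-$k$ use of normalized
entropies:

```{r}
coll <- gss_counts("1998", collapsed = TRUE)
entropy_test(coll, g18, entropy_spec("renyi", q = 1/3))
```

## Known limitations

* First-order asymptotics only: no exact finite-$n$ moments, no
  second-order delta corrections, no bias-corrected (Miller–Madow,
  jackknife) estimators. The plug-in bias is visible in goodness-of-fit
  at small $n/k$, as discussed above.
* The `"paper"` Fisher variance mode is provided for comparison only;
  it does not calibrate against simulation.
* The two-sample test's null is equality of the chosen scalar
  functional, which is much weaker than equality of distributions; use
  `chisq_homogeneity()` when the count-by-count question is the one
  being asked.
* $k$ is assumed desk-scale (up to a few thousand); there is no sparse
  or streaming support.
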