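---
title: "Median-based manifold-adaptive dimension estimation: models, calibration and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Median-based manifold-adaptive dimension estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fsadim)
```

## The estimator and its assumptions

For a sample on a D-dimensional manifold with locally uniform density, the
fraction of points inside a ball of radius R around a sample point scales like
$\eta R^D$ with $\eta$ locally constant. Comparing the balls that contain k
and 2k neighbors eliminates $\eta$ and yields the local two-scale estimate

$$\delta_k(x_i) = \frac{\ln 2}{\ln\!\big(R_{2k}(x_i)/R_k(x_i)\big)},$$

where $R_k(x_i)$ is the distance to the k-th nearest neighbor. The package's
distribution layer rests on the exact law of $\delta_k$ under that local
uniformity: the normalized distance $r = R_k/R_{2k}$ satisfies a beta-type
law, and the monotone substitution $a = 2^{-D/\delta_k}$ maps $\delta_k$ onto
a Beta(k, k) variable. Two consequences drive the whole design:

* **Median exactness.** $P(\delta_k \le D) = I_{1/2}(k,k) = 1/2$ for every k,
  so the sample median of the local estimates (the mFSA aggregate) targets D
  without asymptotic bias — even at k = 1, where the *mean* of $\delta_k$
  diverges (the mean aggregate's divergence at small k is visible as the
  up-curving tail of its k-profile, $E[\delta_k] \approx D + aD/(k-1)$ with
  $a \approx 0.685$).
* **Finite-domain integrals.** Every improper integral over
  $\delta \in (0,\infty)$ — normalizations, moments of the median's sampling
  density, $E[\delta_k]$ — is computed after the $a$-substitution on (0, 1),
  which removes the heavy right tail. Quadrature uses `stats::integrate` at
  relative tolerance 1e-10 (1e-8 where the integrand is already smooth).

The k = 1 closed forms (density $D\ln 2\, 2^{-D/\delta}/\delta^2$, cdf
$2^{-D/\delta}$) are separate code paths and double as regression tests for
the general-k implementation.

What the theory does **not** cover: curvature, non-uniform density, noise.
The package's samplers include Gaussian, Cauchy-norm and sphere-surface
clouds precisely because the estimator is known to err there (under- or
over-estimation depending on regime); tests assert qualitative behavior on
those, not recovery.

## Neighbor search and boundary conventions

Radii come from exact brute-force search (compiled; `O(n^2 m)`), never from
approximate neighbor structures: $\delta_k$ consumes the *ratio* of two
consecutive order statistics, and a single rank error changes the estimate.
Two metrics are supported:

* `hard` — plain Euclidean;
* `periodic` — minimum-image Euclidean on the unit torus, for data in
  $[0,1)^m$. This removes edge effects in simulations; clouds outside
  $[0,1)$ are rejected rather than silently wrapped.

Degenerate geometry is handled at the estimator layer: $R_k = R_{2k}$ gives
$\delta = \infty$ (consistent with the divergent mean); $R_k = 0 < R_{2k}$
(coincident points) would give the meaningless $\delta = 0$, so such points
are mapped to $\infty$ as well, counted, and reported — the median stays
robust as long as fewer than half the points are degenerate. A cloud where
some $R_{2k} = 0$ is rejected outright.

Median convention for even counts: the midpoint of the two central order
statistics (the sampling theory is derived for odd n = 2l + 1 only; the even
case needs some convention and the midpoint is R's default).

## Aggregates

* `fsa_median` (default in `fsa()`): the mFSA estimate.
* `fsa_mean`: the original aggregate; infinities propagate by design.
* `ml_dimension`: maximizes the i.i.d. likelihood of the local estimates
  under the exact law. At k = 1 the root is closed-form,
  $D = n/(\ln 2 \sum 1/\delta_i)$; for k > 1 the score equation is
  transcendental and is bracketed from $[10^{-6}, 10\,\mathrm{med}(\delta)]$
  with doubling of the upper end until a sign change, then solved to
  $|\mathrm{score}| < 10^{-10}$. The score is equivariant under joint scaling
  $(\delta, D) \to (c\delta, cD)$, which the tests exploit.
* `levina_bickel`: the classical kNN maximum-likelihood baseline. Default
  averaging inverts the global mean of per-point inverse estimates
  (equivalently pools all log-ratios); the per-point mean variant is a flag.

The sampling distribution of the median is available in closed form
(`dfsa_median`), and its standard deviation both numerically
(`median_se_numeric`, quadrature of the first two moments) and through the
Laplace–Stirling approximation $\sigma \approx \kappa D/\sqrt{nk}$,
$\kappa = \sqrt{\pi}/(2\ln 2)$. The approximation is accurate to a few
percent for k > 10; at k = 1 and very small n the exact SE sits well above
it (ratio 1.5 at n = 11 falling to 1.13 at n = 1001), so the finite-n
log–log slope of SE versus n over n = 11, 101, 1001 at k = 1 is about
−0.56 rather than the asymptotic −0.5; at k = 11 the same three sample
sizes already give −0.4999. Both numbers are recomputed by the test suite;
the package reports what the quadrature yields.

## The bias correction (cmFSA)

At moderate n and large D the median estimate is biased low — a finite-sample
effect, aggravated by hard boundaries (truncated neighborhoods at the edge of
the support). The correction model assumes the *log relative error* of the
biased estimate d is polynomial in d:

$$\ln(D/d) = \sum_l \alpha_l d^{\,l} \quad\Longleftrightarrow\quad
  D \approx d\,\exp\Big(\sum_l \alpha_l d^{\,l}\Big),$$

which by construction leaves small estimates untouched
($C(d)/d \to 1$, $C'(d) \to 1$ as $d \to 0$ for exponents $\ge 1$).
Coefficients are calibrated on uniform **hard-boundary** hypercubes of
matching sample size and neighborhood — hard, because the correction exists
to absorb exactly the edge plus finite-sample bias. Two fit variants:

* `ols_all`: OLS pooling every realization-level pair; with exponent set {1}
  this reproduces the closed form
  $\alpha = \sum (\ln E_i)\, d^{(i)} / \sum (d^{(i)})^2$ exactly.
* `odr_means`: orthogonal-distance (total-least-squares) fit of the per-D
  means. Implemented as intercept-free multivariate TLS via SVD, since the
  model has no intercept beyond the chosen exponents; unweighted, as no
  error weights are specified by the protocol.

Default exponent sets: {1} for the narrow D = 2..30 hard-boundary regime;
{−1, 1, 2, 3} for wide D = 2..80 calibrations. Coefficients are n- and
k-specific; applying a model at a different n or k warns (not errors).
Extrapolation warnings compare the input against the range of *calibration
estimates* rather than true calibration dimensions, because biased estimates
sit systematically below true D — an in-regime input would otherwise warn.

Integer mode rounds halves away from zero. The ideal error rate of integer
mode under normal residuals is
$1 - [\Phi((D+0.5-\mu)/\sigma) - \Phi((D-0.5-\mu)/\sigma)]$ with $\mu,\sigma$
implied by the stored per-D residual moments of the calibration
($\mu = D e^{-\mu_e}$, $\sigma = \mu\sigma_e$ to first order in the
log-error).

Known limitations, inherited from the calibration design: the correction is
calibrated on flat, uniformly sampled supports. On curved (sphere-like) or
non-uniform (Gaussian, heavy-tailed Cauchy) data it tends to overestimate,
sometimes severely for heavy tails; no numeric contract is made there.

## Synthetic data: what it emulates and what it does not

The samplers generate the study conditions the framework was validated
under:

* `sample_hypercube` — uniform $[0,1)^D$; the periodic variant realizes the
  theory's assumptions essentially exactly, the hard variant exhibits the
  edge effect the correction targets. Calibration defaults (n matching the
  application, k = 5, D = 2..80, ≥ 15 realizations per D) follow the
  benchmark protocol; a thinned D-grid (`d_step`) trades calibration density
  for time — at every-2nd-D with 15 realizations the fitted curve is
  indistinguishable in effect from the full grid for our tests.
* `sample_gaussian`, `sample_cauchy_ball`, `sample_sphere_surface` —
  assumption-violating controls (non-uniform density, heavy tails,
  curvature). Directions for the Cauchy ball are uniform on the sphere and
  radii are |standard Cauchy| (the half-Cauchy law, i.e. the stated Cauchy
  density on positive reals normalized to integrate to one).
* `simulate_coupled_logistic` — three logistic maps (r = 3.99) with two
  independent drivers coupled into a third at strength 0.3. The driven
  update can exit [0, 1], and the state is wrapped modulo 1 each step; the
  wrapped series lives on the unit circle, so delay-embedded clouds use
  periodic distances. (Wrapping the state *and* measuring periodic distances
  is the default; the state-wrap-only reading is available by embedding with
  a hard boundary.) Transient default 1000 steps — chaotic burn-in; the
  value is unremarkable as long as it exceeds a few hundred.
* `delay_embed` — standard Takens reconstruction with E coordinates (a
  printed duplication of the last coordinate in some statements of the
  embedding map is treated as typographical; the map emits E distinct lags).

All samplers are pure functions of (parameters, seed): a non-NULL seed gives
bit-identical output and restores the caller's RNG state afterwards.

Passing tests on these generators demonstrates correctness of the machinery
under its stated assumptions; it does *not* certify performance on real
data, where curvature, noise and density gradients violate them in
combination.

## Problem sizes and numerical choices

The test and acceptance workloads run at the scale the validation needs and
no larger: distributional checks use $10^4$–$10^5$ exact-law draws; the
benchmark means use 100 realizations of n = 2500 clouds (20 in the test
suite, where a 3% band on the mean is already resolved at 20); the wide
calibration uses an every-2nd-D (acceptance) or every-4th-D (tests) grid
with 15 realizations per D. Root finding tolerances: score to 1e-10;
quadrature 1e-10 relative; translation/tie invariances asserted at 1e-12.

Open choices resolved as the package's own conventions: k = 5 (not a
k-average) for the n = 2500 benchmark means, matching the stated benchmark
setting; ties in neighbor distances resolved by the order statistic itself;
halves rounded away from zero; even-n medians by midpoint.
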