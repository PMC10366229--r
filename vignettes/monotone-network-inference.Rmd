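---
title: "Inferring signed regulatory networks under monotone ODE dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring signed regulatory networks under monotone ODE dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(monotonet)
```

## The model class and what "reproducible" means

`monotonet` asks a deliberately weak structural question of time-series
data: could the observed trajectory of a target $Y$ have been produced by
*some* ODE
$$\frac{dY}{dt} = f(X_1, \dots, X_N),$$
where $f$ is strictly monotone (increasing or decreasing) in each listed
cause? Nothing else about $f$ — rate laws, parameters, saturation — is
assumed. When a component is degraded in proportion to its own abundance,
as most molecular species are, $Y$ itself enters the list as a cause with
negative sign.

Monotonicity has an immediately testable consequence. If $f$ is increasing
in a single cause $X$, then for any two time points with
$X(t) > X(t^*)$ we must find $\dot Y(t) > \dot Y(t^*)$. Generalized to $N$
causes with sign vector $\sigma$: on the set of ordered time-point pairs
where every cause moves in its assigned direction (the
*regulation-detection region*), the product of the signed cause differences
with the target's derivative difference (the *regulation-detection
function* $I$) is positive. The *regulation-detection score*
$$S^{Y}_{\mathbf{X}^\sigma} \;=\;
\frac{\iint_R I \, dt\, dt^*}{\iint_R |I| \, dt\, dt^*} \in [-1, 1]$$
therefore equals exactly 1 when the data are reproducible by the candidate
monotone regulation. The score requires no fitting of $f$; it is a
condition on the data alone.

Two caveats shape the whole pipeline. First, the condition is *necessary*,
not sufficient: a score of 1 can occur without regulation (most famously,
appending an irrelevant component to a true regulation leaves the score at
1 with either sign). Second, the exactness of $S = 1$ holds only when the
candidate lists *all* regulators. A target with self-degradation is not
exactly reproducible by a candidate that omits the self-loop: on the
canonical driven pair ($X = \cos 2\pi t$, $dY/dt = X - Y$) the bare 1D
score evaluates to $0.9993$, not $1$, because pairs near the fold of $X$
mix in the self-regulation. With the negative self-loop appended,
$S^{Y}_{X^+Y^-} = 1$ holds to machine precision. This is why the package's
default configuration (`inference_config(self_sign = "negative")`) appends
an assumed negative self-regulation to every candidate — the standard prior
for biochemical species, and the choice under which the noiseless
exactness results in the test suite hold. Users who cannot justify the
prior set `self_sign = "none"` (or a named per-component vector); only
conclusions about targets whose true self-regulation violates the
assumption become untrustworthy.

## From scores to a network

With $N$ observed components, candidates are enumerated per target from
dimension 1 up to $N-1$ (`max_dim`): every cause subset of that size
crossed with every sign vector. Each candidate is scored on every
replicate. Aggregation and filtering use four tunables:

* **Region threshold** `r_thres` (fraction of the pair domain, default
  0.05, sensible range 0–0.1): replicates whose detection region is
  smaller are not informative for the candidate and are excluded from both
  numerator and denominator of the TRS. Smaller values help
  high-dimensional candidates, whose region size shrinks geometrically
  with dimension.
* **Score threshold** $S^{\text{thres}} = 0.9 - 0.005 \times
  \text{noise\%}$ and **TRS threshold** $\text{TRS}^{\text{thres}} = 0.9 -
  0.01 \times \text{noise\%}$: noise perturbs scores downward, so both
  criteria relax linearly with the estimated noise level (in percent; a
  10 % noise dataset uses 0.85 and 0.80). The *total regulation score* is
  the fraction of eligible replicates with $S > S^{\text{thres}}$;
  candidates with $\text{TRS} > \text{TRS}^{\text{thres}}$ survive.
* **Delta-test level** `delta_alpha` (default 0.01): for every cause of a
  surviving multi-cause candidate, the regulation-delta
  $\Delta = S(\text{cause appended } +) - S(\text{cause appended } -)$ is
  computed per replicate against the candidate's other causes. An
  ineffective cause gives $\Delta = 0$ identically; a real cause pulls
  $\Delta$ to the side of its true sign. With 25 or fewer usable
  replicates the call requires strict sign consistency; beyond that, a
  one-tailed Wilcoxon signed-rank test (normal approximation with
  continuity correction, zeros dropped) at `delta_alpha`. Causes that fail
  are removed, shrinking the candidate to its effective cause set.
* **Surrogate-test level** `surrogate_p` (default 0.001) and
  `surrogate_shuffles` (default 100): an edge whose source could reach the
  target through a chain of other surviving edges with the same sign
  product might be indirect. The suspect cause's sampled values are
  randomly permuted `surrogate_shuffles` times, the candidate rescored,
  and a one-tailed Z p-value computed per replicate for the original score
  against the shuffled-score distribution; Fisher's method combines the
  replicate p-values, and the edge is kept only if the combined statistic
  exceeds $-2k\ln(\texttt{surrogate\_p})$ for $k$ replicates. Shuffling
  destroys the suspect's temporal ordering but nothing else; since the
  suspect enters the score only through its pairwise value differences,
  no re-differentiation is needed.

Merging applies two rules. When two or more *distinct* 1D causes pass the
TRS criterion for one target, those 1D candidates are set aside: several
passing single-cause explanations mean the causes act jointly, which only
a higher-dimensional candidate can certify (a lone passing 1D edge is
reported directly). Then, per target, the surviving candidate with the
highest TRS wins. On exact TRS ties the candidate with the *larger
post-filter cause set* wins, and only then the lower dimension. The
larger-set preference departs from plain parsimony deliberately: on clean
data a true joint regulation and one of its single-cause projections can
both reach TRS = 1, and choosing the projection would silently discard a
true edge, whereas every cause in the larger set has already proven
individually effective in the delta test — the extra dimension is never
free. Parsimony is thus enforced by the delta test, not by the tie-break.

## Preprocessing

Raw replicates (CSV, irregular sampling allowed) are fitted per component
with either a Fourier series of order 1–8 or a cubic spline, resampled on
a uniform grid (default 100 points, the package's default sampling density
per period), differentiated (analytically for Fourier; central differences
with one-sided ends for the spline, which avoids amplifying fit
artifacts), and min–max normalized to $[0,1]$ per component, replicate by
replicate. Fourier order 4 is the default for noisy data; order 2 is
preferable above roughly 15 % noise, where higher orders start fitting the
noise. The Fourier fundamental frequency is not fixed by the window: it is
optimized by variable projection (linear least squares inside a coarse
grid-plus-local search over $\omega$), which tolerates windows that do not
contain an exact integer number of periods.

The noise level that drives the thresholds is estimated from the fit
residuals: per component and replicate, residual RMS relative to fitted
RMS with a degrees-of-freedom correction $\sqrt{m/(m-p)}$ for the $p$
fitted coefficients, pooled by root mean square. For multiplicative noise
$X(1+\varepsilon)$, $\varepsilon \sim N(0, s^2)$, the estimator approaches
$100\,s$; the test suite calibrates it against seeded 10 % noise (estimates
fall within 5–15 % over 20 seeds) and checks approximate linearity in $s$.
An interpolating spline leaves no residual, so the spline path reports
noise 0 and users should pass `noise_pct` explicitly when smoothing with
splines. For long recordings, utilities cut the series into period-length
windows (period from the first positive-lag autocorrelation peak, refined
by parabolic interpolation and rejected as aperiodic when the peak
autocorrelation is below 0.2), slide them with 90 % overlap, and smooth
with a centered moving average whose end windows shrink symmetrically.

## The synthetic-data generator

All tests run on data from the package's own simulator, which emulates the
in-silico protocol the method is designed for: small (2–5 node) monotone
regulatory networks, integrated with `deSolve` (lsoda, absolute and
relative tolerances $10^{-10}$), 100 replicates from initial conditions
drawn uniformly from a stated box, 100 samples per period, multiplicative
Gaussian measurement noise at a stated percent level. Driven inputs are
explicit waveforms; "random" inputs are seeded low-order Fourier series
(three harmonics, independent standard-normal coefficients rescaled to unit
amplitude). The flat harmonic spectrum is intentional: with the variance
concentrated in the fundamental the input degenerates toward a pure
cosine, every downstream component becomes a phase-shifted copy, and
score-based false positives inflate — a realistic "random signal" should
explore diverse shapes. Fixture parameters (listed in `fixtures()`) were
chosen once on dynamical grounds: feed-forward weights of 1.5–2 give the
direct paths enough strength that no single-cause projection is exactly
reproducible; the Goodwin-type oscillator uses Hill coefficient 6 and
weight 2 on all three stages, the smallest steepness at which the loop
both oscillates robustly and keeps order-one relative amplitudes on every
node (sluggish linear stages attenuate the cycle until multiplicative
noise drowns the smallest node); the repressor ring uses Hill coefficient
4 and weight 3. Oscillator windows cover one numerically measured period
(3.52 and 3.76 time units) and initial boxes cover the limit-cycle ranges,
so replicates retain genuine transient diversity rather than being
phase-shifted copies of one cycle.

For noiseless data the simulator exposes the vector field's exact
derivatives at the sample points (`fit_method = "exact"`), so the
exactness results are not blurred by differentiation error; noisy data go
through the same Fourier/spline path as real measurements. What the
generator does *not* emulate: intrinsic (demographic/molecular)
stochasticity, time delays, non-monotone or time-varying regulation,
missing samples, and non-stationary baselines. Passing tests therefore
certify the inference machinery under measurement noise on monotone ODE
dynamics — not robustness to model-class violations, which the method by
design does not claim.

## Numerical choices and degenerate inputs

* The pair domain is all ordered grid pairs $(a, b)$, $a \ne b$; integrals
  are plain sums (the grid-cell area cancels in the score ratio). With
  $T = 100$ this is $10^4$ pairs; sweeps cache the pairwise difference
  matrices per replicate.
* Region inequalities are strict, and pairs with any exact zero difference
  are excluded (ties are measure-zero for continuous data; exact
  symmetric waveforms can create them, which is why the test fixtures use
  asymmetric phases).
* $\dot Y^d$ is divided by its per-replicate maximum absolute value before
  forming $I$, so $|I| \le 1$ on normalized data; the score is provably
  unchanged.
* An empty region, or an identically zero $|I|$ (constant target
  derivative), yields an *undefined* score — `NA`, distinct from any
  numeric value — and the replicate simply does not count toward that
  candidate's TRS. Constant (degenerate) components are flagged at
  normalization and excluded from candidate sets rather than failing the
  run.
* A shuffled-score distribution with zero spread gives the conservative
  per-replicate $p = 1$; surrogate p-values are floored at $10^{-300}$
  before taking logs.
* Exact TRS ties in merging resolve as described above; remaining ties
  fall back to enumeration order, making runs fully deterministic given
  the data, configuration and seed.

## Problem sizes used by the test suite

Unit tests run on 16–50-point grids and 1–60 replicates; the double-loop
oracle cross-checks the vectorized scores on 20–24-point grids. The
end-to-end checks simulate the full study conditions — 100 replicates, 100
samples per period — for the six three-node fixtures: exact signed
recovery (F2 = 1) noiseless on all six; mean F2 across the suite at 10 %
multiplicative noise over three seeds at or above 0.8; and correct
direct-versus-indirect surrogate verdicts on the coherent versus single
feed-forward pair at 20 % noise in at least 9 of 10 seeds. These are the
quantities the acceptance checks compute; nothing beyond them is claimed.

## Known limitations

Completely synchronized systems remain out of reach: if two components
carry identical shape information (the cos/sin driven pair is an extreme
case — each input's derivative is an exact monotone function of the other
input), the score cannot distinguish them, and the package will report the
corresponding edges. High-dimensional candidates need rapidly growing
amounts of data as their detection regions shrink; the self-regulation
assumption buys one dimension back and is often decisive for small
experimental datasets. Necessary-condition testing means isolated false
positives survive all filters in noisy regimes, typically on components
(such as driven inputs) that have no true regulators; more replicates or
lower noise remove them. Regulation through fast intermediates is
reported as direct — the statistic sees shapes, not mechanisms.
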