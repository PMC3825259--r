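---
title: "Methods: the hierarchical elastic-net VAR for effective connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the hierarchical elastic-net VAR for effective connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hvarnet)
```

## The model

For subject $s$ with ROI-mean series $Y^{(s)}(t) \in \mathbb{R}^R$ and
experimental conditions indicated by $W_c^{(s)}(t) \in \{0,1\}$ (one
condition active per scan, switching at block boundaries),

$$
Y^{(s)}(t) \;=\; \sum_{k=1}^{K} \Big(\sum_{c=1}^{C} W_c^{(s)}(t)\,
\Phi^{(s)}_{c,k}\Big)\, Y^{(s)}(t-k) \;+\; e^{(s)}(t),
\qquad e^{(s)}(t) \sim N\!\big(0,\ \mathrm{diag}\{\tau_1^{-1},\dots,\tau_R^{-1}\}\big).
$$

$\Phi_{c,k}(r',r)$ is the lag-$k$ influence of source ROI $r$ on target ROI
$r'$ under condition $c$; a nonzero cross-coefficient is Granger causality
at the hemodynamic level, and network edges point $r \to r'$.  Writing all
coefficients of one subject as a vector $\phi^{(s)}$ of length
$q = R^2 K C$ (condition-major, then lag, then the column-major unrolling
of each $R \times R$ matrix), the hierarchy is

$$
\phi^{(s)} = \phi + \xi^{(s)}, \qquad
\xi^{(s)} \mid D \sim N_q(0, D), \quad D = \mathrm{diag}\{d_1^{-1},\dots,d_q^{-1}\},
$$

so $d_j^{-1}$ is the between-subject variance of coefficient $j$.  With
several groups each group has its own $\phi$ block and its own $D$;
subjects load their group's block through a selection matrix, and the noise
covariance is shared by all subjects.

The group coefficients carry the hierarchical shrinkage prior

$$
\phi \mid V_\tau, V_\Phi \sim N(0,\ V_\tau V_\Phi), \qquad
V_\tau = \mathrm{diag}\{\tau_{h(j)}^{-1}\}, \quad
V_\Phi = \mathrm{diag}\{(\alpha_j + \lambda_2)^{-1}\},
$$

where $h(j)$ is the target ROI of coefficient $j$, the latent $\alpha_j$
follow a tilted inverse-gamma mixing law, and $\lambda_2 \sim
\mathrm{Gam}(r_\lambda, h_\lambda)$, $\gamma \sim \mathrm{Gam}(r_\gamma,
h_\gamma)$ control the two penalty arms.  Integrating $\alpha_j$ out gives,
up to a constant,

$$
-\log p(\phi_j \mid \tau, \lambda_2, \gamma) \;=\;
\sqrt{\gamma\,\tau_{h(j)}}\,\lvert\phi_j\rvert \;+\;
\tfrac{1}{2}\lambda_2 \tau_{h(j)}\,\phi_j^2 \;+\; \text{const},
$$

so the conditional posterior mode of $\phi$ solves an elastic-net penalized
least-squares problem: $\gamma$ drives sparsity (L1), $\lambda_2$ drives
ridge-type grouping (L2), and both are estimated rather than tuned.  The
acceptance suite verifies this correspondence against an independent
coordinate-descent solver to $10^{-4}$.

## The Gibbs sampler and the joint it targets

All unknowns are updated by closed-form full conditionals in the fixed
order $\phi, \xi, \alpha, \tau, \lambda_2, \gamma, d$:

* $\phi$ and $\xi$: conjugate normals.  Because a design row for target
  ROI $r'$ only loads coefficients with that target, and $V_\Phi$ and $D$
  are diagonal, both conditionals factor exactly into independent
  (group $\times$ target) and (subject $\times$ target) blocks of size
  $RKC$.  Each block is drawn by Cholesky factorization of its precision
  and triangular solves; no matrix is ever inverted explicitly.
* $\alpha_j$: inverse-Gaussian with mean
  $\sqrt{\gamma / (\tau_{h(j)}\phi_j^2)}$ and shape $\gamma$.  This is the
  unique parameterization proportional to the joint density; it is locked
  in the test suite by comparison with an independent Metropolis sampler
  targeting the written conditional.  Since the mean degenerates at
  $\phi_j = 0$ (an event of measure zero but reachable at initialization),
  $\phi_j^2$ is floored at $10^{-12}$.  Draws use the Michael–Schucany–Haas
  transform in a rationalized form that is stable for extreme mean/shape
  ratios.
* $\tau_r$: Gamma with shape $(N_r + P_r)/2 + r_\tau$, where $N_r$ counts
  the usable regression rows targeting ROI $r$ (see session handling
  below) and $P_r = GCRK$ counts the prior terms tied to $\tau_r$; the
  rate adds half the residual sum of squares and half the prior quadratic
  form $\sum_j (\alpha_j + \lambda_2)\phi_j^2$ over those terms.  For two
  conditions, one group and one session this reduces to the familiar
  $((T-K)S + 2RK + 2r_\tau)/2$ count.
* $\lambda_2 \sim \mathrm{Gam}(r_\lambda + \#\phi/2,\ h_\lambda +
  \tfrac12\sum_j \tau_{h(j)}\phi_j^2)$,
  $\gamma \sim \mathrm{Gam}(r_\gamma + \#\phi,\ h_\gamma +
  \tfrac12\sum_j \alpha_j^{-1})$.
* $d_j$ (per group): $\mathrm{Gam}(S_g(r_d - \tfrac12) + 1,\
  \tfrac12\sum_{s \in g} (\xi_j^{(s)})^2 + S_g h_d)$, with $r_d > 1/2$
  required.

One point deserves an explicit statement.  The $\lambda_2$ and $d_j$
updates above are *not* the full conditionals of the naive reading of the
hierarchy in which the $\alpha$ mixing density is normalized and each
$d_j$ has a single $\mathrm{Gam}(r_d, h_d)$ prior.  They are exactly the
full conditionals of the joint density in which the $\alpha$ mixing term
is the unnormalized tilt
$\prod_j (\lambda_2 \alpha_j / (\alpha_j + \lambda_2))^{1/2}\,
\mathrm{InvGam}(\alpha_j; 1, \gamma/2)$ and the $d_j$ prior is
$\mathrm{Gam}(S(r_d - 1) + 1,\ S h_d)$.  That joint is proper, and we adopt
it as the model definition: the getting-it-right validation below draws
exact prior samples from *this* joint (by block rejection sampling) and
confirms that all seven conditionals are mutually consistent with it.  The
practical consequences are mild — the effective $\lambda_2$ prior carries
an extra $\lambda_2^{q/2}$ factor, strengthening ridge shrinkage in small
models, and the effective $d_j$ prior sharpens with the number of
subjects.

### Getting-it-right validation

On a minimal model ($R = 2$, $K = 1$, $C = 2$, $S = 2$, $T = 30$) the test
suite compares 50,000 i.i.d. draws from prior-then-data simulation against
50,000 sweeps of Gibbs-then-fresh-data simulation; if any conditional were
inconsistent with the joint, the two stationary distributions would
differ.  Fifteen test functions covering every parameter block are
compared by z-scores (batch-means variance on the autocorrelated arm), all
required to satisfy $|z| < 4$.

The validation hyperparameters are chosen so the prior keeps coefficient
scales near 0.1: a VAR prior with substantial mass on explosive regimes
makes the data-regeneration arm numerically treacherous (an explosive
series pins the coefficient conditionals near their current values, an
effectively absorbing state), which says nothing about the correctness of
the conditionals being validated.  The conditionals are identical formulas
under any hyperparameter values.

### Initialization, order, determinism

Initialization is neutral: $\phi = \xi = 0$, all precisions and latents 1.
The update order is fixed as listed; no random scan is offered.  Chains
are bitwise reproducible under a fixed seed; the retained sample is every
`thin`-th draw after `burn_in` of `iterations`, so the classic protocol
(80,000 iterations, 60,000 burn-in, thinning 5) retains 4,000 draws.
Convergence is monitored with the Geweke diagnostic (first 10% vs last
50%, spectral variance at frequency zero from an AIC-selected AR fit);
constant chains yield `NA` rather than an error.

## Design construction

Sessions are modelled as independent recording runs: lagged predictors
never cross a session boundary, so each session contributes its rows only
from scan $K+1$ onward.  The condition presented at time $t$ selects the
coefficients that predict $Y(t)$; no hemodynamic delay is applied to the
indicators (the data are assumed condition-labelled as acquired, and any
expected BOLD response is removed beforehand by the nuisance regression).
Lagged values from the previous block enter the new block's coefficients
immediately — the literal reading of the switching model.

Stationarity within a condition is certified by the spectral radius of the
$RK \times RK$ companion matrix; the stationary covariance is the series
$\sum_i M^i \Sigma (M^i)'$ truncated when a term's largest entry falls
below $10^{-10}$ (cap 10,000 terms), verified in the tests against an
exact discrete-Lyapunov solve to $10^{-8}$.

## Granger-causality networks

An edge $r \to r'$ is significant for a condition when the *lag-joint*
posterior of $[\Phi_1(r',r), \dots, \Phi_K(r',r)]$ excludes the origin.
The fixed-height "0.025 contour" of a histogram is well defined only in
the symmetric one-dimensional case, so the primary rule is the empirical
highest-density region: the smallest set of histogram bins (by descending
count) holding 95% of the draws, with the origin's bin membership giving
the decision.  The histogram uses $\lceil N^{1/(K+2)} \rceil$ bins per
dimension (capped to $[10, 50]$), a range padded 5% beyond the sample
extremes, and a grid aligned so the origin sits at a bin center — the
alignment removes the discretization bias that otherwise dominates
near-boundary decisions.  In one symmetric dimension the rule reduces to
the equal-tail interval check; the literal fixed-height contour remains
available as `method = "contour"` for comparison.  Beyond three lags the
histogram becomes unreliable and a Gaussian-approximation Mahalanobis test
at the same level is substituted and flagged.

Condition and group contrasts apply the identical rule to per-draw,
per-lag coefficient differences; subject networks use
$\phi + \xi^{(s)}$ draws.  Following common practice for this model class,
no multiple-comparison correction is applied across the $R^2$ edge tests
by default; a Bonferroni-style level adjustment is available.  Self-edges
are tested and reported like any edge but marked separately.

Agreement between the HDR rule and the analytic Mahalanobis ellipse is
validated on bivariate normal draws in stratified scenarios (clouds
clearly covering the origin, and widely spread means): at the decision
boundary itself, any finite-sample rule flips with Monte-Carlo
probability approaching one half, so boundary-straddling cases measure
noise, not correctness.

## Nuisance preprocessing

Before fitting, each ROI series can be residualized per session against:
the expected condition responses (condition indicators convolved with the
canonical double-gamma HRF — response delay 6 s, undershoot delay 16 s,
unit dispersions, ratio 1/6, 32 s support, peak-normalized; all five
parameters configurable); polynomial drift of order 0–3 built on a
$[-1,1]$-rescaled grid and orthogonalized (order 0 is the explicit
intercept); and sine/cosine pairs at configured frequencies.  Frequencies
at or above the Nyquist limit $1/(2\,\mathrm{TR})$ are dropped with a
warning — at TR = 2 s the classic cardiac/respiratory bands above 0.5 Hz
are unrepresentable, so the default is a single 0.10 Hz band and the
choice is deliberately exposed as configuration.  Sessions are detrended
independently (baselines differ) and re-concatenated with boundaries
preserved.  Detrending is idempotent and its residuals are orthogonal to
every design column; both are asserted in the tests.

## The synthetic-study generator

`make_default_truth()` builds a sparse ground truth — lag-1 self-coupling
0.3 on every condition's diagonal, `n_edges` cross-edges of magnitude
`effect_size` at random positions and signs, iteratively rescaled to
companion radius at most 0.9 — and `simulate_study()` runs the generative
model forward: deviations drawn per coefficient (diagonal $D$), resampled
(cap 100) if a subject's regime would be nonstationary, then per session a
200-step warm-up under the opening condition (discarded; at radius 0.9
this leaves initial-condition bias well under 1% of the stationary
variance) followed by the condition-switching recursion with diagonal
Gaussian noise.  The default study shape mirrors a classic block-design
acquisition: two conditions alternating in 12-scan blocks over 48-scan
sessions at TR 2 s, two groups of 13 subjects.

What the generator emulates is exactly the model's data-generating
process.  It does *not* emulate hemodynamic convolution of the switching
process, measurement drift, motion, or non-Gaussian noise, so passing
recovery tests demonstrate correctness of the inferential machinery under
the model, not robustness of the model to real fMRI violations.

## Problem sizes used in the validation suite

The suite favors a few deep checks at deliberately modest sizes: the
joint-distribution validation runs 50,000 sweeps of the minimal model; the
conditional oracles use 20,000 draws each; recovery uses a study of 12
subjects, 3 ROIs, 2 conditions and 240 scans with ±0.4 cross-effects,
deviation SD 0.1 and unit noise, fit with 5,000 iterations (2,500 burn-in,
thinning 2) — chosen as the smallest study at which group-level recovery
is decisively informative.  `scripts/acceptance.R` re-runs the same
computations from scratch under a caller-supplied seed.

## Known limitations

* Granger causality is read at the hemodynamic level; no claim about
  neuronal delays is supported at typical fMRI sampling rates.
* The noise covariance is diagonal and shared across subjects by model
  assumption; no full-covariance option is provided.
* The condition indicators are not shifted for hemodynamic lag; if the
  design warrants a shift, relabel the indicators upstream.
* Sessions must share a common block layout within a study file set, and
  all subjects share one spec.
* The sampler is a single-chain Gibbs scheme; no alternative kernels
  (HMC, variational) or marginal-likelihood machinery are included.
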