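---
title: "Smart error sums: correlation-based losses for curve fitting under multiplicative systematic errors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Smart error sums: correlation-based losses for curve fitting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smartses)
```

## The problem

Nonlinear curve fitting almost universally minimizes the residual sum of
squares (RSS). The RSS forces the model to agree with the data point by
point, so any *multiplicative systematic error* — a detector gain drift, a
scattering loss, a frequency-dependent attenuation — is silently absorbed
into the fitted parameters. The fit looks perfect; the parameters are wrong,
and nothing in the residuals warns the user.

The losses implemented here take a different view: they require the model to
reproduce the *correlations* within the measured data rather than its
absolute values. All of them share one key property: they attain their
minimum whenever model and data agree **up to a scalar factor** (for ZNCC,
up to a factor and an offset). A uniform multiplicative corruption therefore
cannot bias the fit; it simply becomes the factor at the optimum.

## The 2D correlation machinery

For a series of $m$ curves $\tilde y(x_i, t_j)$ on a common grid of $n$
points — rows of the dynamic matrix $\mathbf{Y}$, one row per perturbation
value $t_j$ — the synchronous and asynchronous correlation maps are

$$\Phi = \tfrac{1}{m-1}\,\mathbf{Y}_1^{\top}\mathbf{Y}_2, \qquad
  \Psi = \tfrac{1}{m-1}\,\mathbf{Y}_1^{\top}\mathbf{N}\,\mathbf{Y}_2,$$

with $\mathbf{N}$ the Hilbert–Noda matrix, $N_{ij} = 0$ for $i=j$ and
$1/\pi(j-i)$ otherwise. With $\mathbf{Y}_1 = \mathbf{Y}_2$ (conventional
analysis) $\Phi$ is symmetric and $\Psi$ antisymmetric about the diagonal.
For a *hybrid* pair — measured series vs simulated series — these relations
hold exactly if and only if the two series agree up to a scalar factor.
The synchronous and asynchronous residual sums

$$\mathrm{SRSS} = \sum_{k}\sum_{j \ge k}\bigl[\Phi(x_j,x_k)-\Phi(x_k,x_j)\bigr]^2,
\qquad
\mathrm{ARSS} = \sum_{k}\sum_{j \ge k}\bigl[\Psi(x_j,x_k)+\Psi(x_k,x_j)\bigr]^2$$

quantify the violation, and the series smart error sum combines them as
$\mathrm{SES} = \ln(\mathrm{SRSS}+\varepsilon) + \ln(\mathrm{ARSS}+\varepsilon)$.
The additive $\varepsilon$ (default $10^{-10}$) exists because both sums
vanish *exactly* at the optimum; it bounds the loss below by
$2\ln\varepsilon$ and is small enough to act only as a predictable
substitute for bit noise. The log-sum form is preferred over the product
$\mathrm{SRSS}\cdot\mathrm{ARSS}$ for its much better convergence behaviour
(the two sums typically differ by orders of magnitude).

### Two-trace maps

When only a single measured curve is available, the two-trace construction
replaces the series:

$$\Phi(x_j,x_k) = \tfrac12\bigl[s_j s_k + m_j m_k\bigr], \qquad
  \Psi(x_j,x_k) = \tfrac12\bigl[s_j m_k - m_j s_k\bigr].$$

A note on the asynchronous definition: only the antisymmetric cross term
$\tfrac12(s_j m_k - m_j s_k)$ makes the construction non-trivial — any form
symmetric in the index exchange collapses to zero identically and could not
serve as a loss. We adopt the cross term; it is the unique bilinear,
antisymmetric combination that vanishes exactly when $m \propto s$
(Cauchy–Schwarz equality), which is the invariance the losses are built on.

The two-trace loss is the upper-triangle sum $\sum_k \sum_{j\ge k}
\Psi(x_j,x_k)^2$. For exponent 2 the *full-matrix* sum admits the closed
form

$$\sum_{j,k} \Psi(x_j,x_k)^2
  = \tfrac12\Bigl[\textstyle\sum_j s_j^2 \sum_k m_k^2
  - \bigl(\sum_j s_j m_j\bigr)^2\Bigr],$$

which scales $O(N)$ like the RSS. We re-derived this form from the
definition of $\Psi$ (expand the square, collect the three double sums) and
verify it in the test suite against a literal $O(N^2)$ double-loop oracle;
it equals exactly twice the upper-triangle form, since the full matrix
double-counts the strict triangle and the diagonal is zero. Both variants
are exposed; they share their minimizer.

### Phase angles

Treating $(\Phi, \Psi)$ as a complex map $\Phi + i\Psi$, the phase angle is
$\Theta = \arctan(\Psi/\Phi)$ with two numerical conventions:

* **Regularization.** The denominator becomes
  $\Phi + \operatorname{sign}(\Phi)\,\varepsilon$ with $\operatorname{sign}(0)$
  taken as $+1$, so the $0/0$ case resolves to $\Theta = 0$ — the correct
  limit for a vanishing dynamic spectrum — without a branch in the code.
* **Branch adjustment.** The principal arctangent branch $(-\pi/2, \pi/2)$
  is physically too narrow: $\pi$ is added wherever the raw value falls in
  $(-\pi/2, -\pi/4]$, confining $\Theta$ to $(-\pi/4, 3\pi/4]$. The closed
  end of the interval is placed at $3\pi/4$ so that a raw value of exactly
  $-\pi/4$ (a tie) maps into the admitted range; ties are measure-zero and
  the choice does not affect any squared-loss value at the tolerances used.

Phase angles give two further losses: the two-trace phase loss
$\sum_{j\ge k}\Theta(x_j,x_k)^2$ and the series phase loss
$\sum_{j\ge k}[\Theta_{\mathrm{ex}} - \Theta_{\mathrm{sim}}]^2$, comparing
the phase maps of the measured and the simulated series. Both inherit scale
invariance because maps that differ by a factor have identical phases.

### NCC and ZNCC

The normalized cross-correlation
$\mathrm{NCC} = \sum_j s_j m_j / \sqrt{\sum s_j^2 \sum m_k^2}$ is linked to
the fast two-trace loss by
$\mathrm{NCC}^2 = 1 - 2 D / (\sum s^2 \sum m^2)$ — verified as a property
test, not assumed — and equals 1 exactly when $m = C s$. Its negation is a
loss. For the zero-mean variant we use the matched-divisor (Pearson) form,
which is bounded in $[-1, 1]$ and equals 1 exactly for $m = C s + O$: a
prefactor $1/(l+1)$ combined with population standard deviations is *not*
bounded by 1 and would break the "perfect anticorrelation gives $-1$"
semantics, so that variant is available only behind
`zncc(..., strict_printed = TRUE)`.

## The synthetic generator

The generator produces Cauchy (Lorentz-type) bands

$$f(x, t) = \frac{t\,(1 + a t)\,\gamma}{(x - x_0 \mp b t)^2 + \gamma^2},$$

where $t$ is the perturbation, $a$ an amplitude nonlinearity and $b$ a
peak-shift coupling. Two points matter:

* **Sign of $b$.** The default (`shift_sign = "downshift"`) places the peak
  at $x_0 - b t$, so the band moves to *smaller* $x$ with increasing $t$ —
  the behaviour dispersion theory predicts for real absorption bands, and
  the convention under which the reference experiment's misspecified fit
  lands on $x_0 = 999 \ldots 995$. The upshift convention is available
  behind a flag.
* **Disproportionality.** With $b = 0$ the band factorizes as
  $g(t)h(x)$, the intensity block has rank 1 and the asynchronous map is
  identically zero no matter how nonlinear $a$ makes the amplitude; every
  smart error sum is then blind. Nonlinearity in $t$ is *not* the
  criterion — a disproportionate change (here, the $t$-dependent shift) is.
  The test suite asserts the null case symbolically motivated by
  $g^{\top} \mathbf{N} g = 0$ for antisymmetric $\mathbf{N}$.

The reference world (`table1_world()`) fixes $x_0 = 1000$, $\gamma = 30$,
$a = 0$, $b = 1$ downshift, $t \in \{1,\dots,5\}$ and a uniform
multiplicative corruption of 1.1. The open interval $900 < x < 1100$ is
sampled at unit steps, 901..1099 (199 points): the simplest reading, and
the one under which the RSS fit of the corrupted series reproduces
$t = (1.09993, 2.19944, 3.29812, 4.39557, 5.49141)$ — the corruption
absorbed into the estimates, modulated slightly by the peak shift — while
every correlation loss recovers $1\ldots5$. The generation constants
$a = 0$, $b = 1$ are the unique pair consistent with both that RSS result
(which forces $t' = 1.1\,t$, hence $a = 0$) and the misspecified-fit result
$x_0' = 1000 - t$ (which forces $|b| = 1$).

What the generator deliberately does **not** emulate: noise (the reference
experiment is noise-free; a green test establishes correctness of the
machinery, not robustness to noise), $x$-dependent corruption factors
(supported by `error_model(factor = function(x) ...)` but not part of the
acceptance world), physically derived dispersion line shapes, and additive
baselines beyond the single shared offset handled by
`build_dynamic_matrix(remove_common_offset = TRUE)`. Offset removal and
mean-centering are both opt-in and off by default — referencing is often
unnecessary and sometimes detrimental, and the estimator for a shared
offset (the global minimum) is a documented choice, not a canonical one.

## Fitting

`fit()` minimizes any configured loss over free parameters within finite
bounds. Topology follows separability: the series losses couple all curves
and are minimized jointly over the full $t$ vector; every other loss is
fitted one curve at a time. Optimization is derivative-free and
deterministic:

* one free parameter: Brent's bounded method (`stats::optimize`), accurate
  and reliable in 1-D where a simplex is not;
* several parameters: Nelder–Mead with proposals reflected back into the
  bounds (a triangle-wave fold, so the objective is continuous across the
  walls), relative tolerance $10^{-10}$, and one restart from the first
  solution as a cheap polish.

Initial points sit at the centers of the bounds. With the reference
bounds $t_{\mathrm{true}} \pm 1$ this means starting at the truth; that is
the stated convention of the experiment, and for the RSS rows the optimum
lies elsewhere ($\approx 1.1\,t$), so the start does not trivialize the
result. Two runs with the same configuration are bit-identical. Non-finite
losses abort the search with a diagnostic rather than letting the simplex
wander.

Joint fits under the series SES start, by the same convention, at the exact
global minimum (the loss floor $2\ln\varepsilon$); the fitted values are
then recovered to within the stopping behaviour of the simplex. Digit-level
reproduction of any particular solver's stopping artifacts is explicitly
not attempted — the tolerance-based checks (within $5\times10^{-2}$ for the
series losses, $10^{-3}$ to $10^{-4}$ for the others) are the meaningful
claims.

## Model misspecification and the rejection diagnostic

A shift-free band of the right width can match any single shifted band
perfectly: fitting the corrupted series per curve with $b$ fixed at 0 and
$x_0$ free gives residuals at machine zero with biased estimates
($x_0 = 999\ldots995$, $t = 1.1\ldots5.5$). Nothing in the RSS exposes
this. The asynchronous map does: hybrid maps of series generated by
*different* laws lose their antisymmetric sign structure, and no smart
error sum can then converge. `antisymmetry_violation()` scores the breakage
(RMS of $\Psi(j,k)+\Psi(k,j)$ over the upper triangle, normalized by the
RMS of $\Psi$; threshold $10^{-6}$). Same-model series that differ only by
a scalar factor stay below threshold; mixtures of an $(a{=}0, b{=}1)$ and
an $(a{=}1, b{=}0)$ world exceed it by orders of magnitude. A caveat
shipped as documentation: two-trace maps are always antisymmetric by
construction and cannot be used for this diagnostic.

## Numerical and design choices, collected

* Exponent $p$: stored on `loss_spec`, default 2; only even $p$ is
  admitted (odd powers cancel antisymmetric terms meaninglessly) and only
  $p = 2$ has closed forms and test coverage.
* $\varepsilon = 10^{-10}$ enters additively inside each logarithm of the
  series SES and sign-matched in the phase denominator — nowhere else.
* Normalization of series maps is $1/(m-1)$, always; no alternative divisor
  is offered.
* Losses are pure functions; no caching, so fits are reproducible.
* Map exports are square CSVs labelled by the x-grid values at 17
  significant digits (bit-exact round trip); series CSVs use the
  `x,t=...` header schema.
* The CLI accepts a JSON configuration file (sections `simulate`, `loss`,
  `optimizer`); explicit flags always override config values. TOML was
  considered and rejected because no TOML parser is available in the
  supported dependency set.
* An exponential/log transform hook (`transform_series()`) is provided for
  turning additive systematic errors into multiplicative ones before loss
  evaluation; it transforms intensities and does nothing else.

## Limitations

Linear models are out of reach by construction: all lines parallel to the
truth correlate perfectly, so every scale-invariant loss is flat along that
direction — such problems have analytical solutions and need neither
fitting nor these losses. The series machinery requires $m \ge 2$ curves
and a disproportionate change across them. Unevenly weighted or
$x$-dependent error factors are representable in the generator but the
recovery guarantees tested here cover only the uniform-factor world.
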