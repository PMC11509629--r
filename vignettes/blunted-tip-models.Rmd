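---
title: "Contact models and modulus estimation for blunted AFM tips"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contact models and modulus estimation for blunted AFM tips}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afmblunt)
```

## The problem

AFM nanoindentation measures a force–indentation curve $F(h)$ and infers the
sample's Young's modulus $E$ from a contact-mechanics model. For pyramidal
probes the near-universal habit is Sneddon's perfect-cone law

$$F = \frac{2}{\pi}\,\frac{E}{1-\nu^2}\tan\theta\; h^2,$$

but a real probe apex is rounded: a spherical cap of radius $R$ (tens to
hundreds of nanometres) merges tangentially with the conical or pyramidal
body of half-angle $\theta$ at the transition radius $b = R\cos\theta$,
reached at the transition depth $h_T = b^2/R$. Whenever the indentation
depth is comparable to $R$ — shallow indentation of cells, thin collagen
layers probed gently to avoid substrate effects — ignoring the cap biases
$E$ substantially.

The exact blunted models fix this but are implicit: force and depth are
both parametrised by the contact radius $a$,

$$h = \frac{a}{\tan\theta}\Bigl(\frac{\pi}{2}-\arcsin\frac{b}{a}\Bigr)
      + \frac{a}{R}\Bigl(a-\sqrt{a^2-b^2}\Bigr),$$

$$F = 2E^*\Bigl[\,a h
  - \frac{a^2}{2\tan\theta}\Bigl(\frac{\pi}{2}-\arcsin\frac{b}{a}\Bigr)
  - \frac{a^3}{3R}
  + \sqrt{a^2-b^2}\Bigl(\frac{b}{2\tan\theta}
  + \frac{a^2-b^2}{3R}\Bigr)\Bigr],$$

valid for $a \ge b$, with $E^* = E/(1-\nu^2)$; below the transition
($a < b$) the contact is the Hertzian cap, $F = \tfrac43 E^*\sqrt{R}\,
h^{3/2}$ with $a = \sqrt{Rh}$. A $k$-sided blunted pyramid carries the
factor $(k/\pi)\sin(\pi/k)$ on each conical term and tends to the cone as
$k \to \infty$. Both pieces join continuously at $a=b$: the correction
terms vanish analytically there, which the test suite asserts to
$10^{-12}$ relative. The implemented forms also satisfy the contact
stiffness theorem $\mathrm{d}F/\mathrm{d}h = 2E^*a$ along the curve, a
useful independent identity that the tests verify numerically.

## The simplified estimator

The package's central tool avoids the implicit system entirely. For any
axisymmetric indenter of profile $f(r) = Br^n$,

$$F = \frac{2E^*}{\pi^{1/(2n)}B^{1/n}}\,\frac{n}{n+1}
  \left[\frac{\Gamma(n/2+1/2)}{\Gamma(n/2+1)}\right]^{1/n} h^{1+1/n},$$

a pure power law $F = c\,h^m$ with $m = 1 + 1/n$. A blunted tip is not a
power-law shape — its effective $B$ and $n$ drift with depth — but over a
finite depth window the curve is extremely close to a power law (the
noiseless fits in the tests have $R^2 > 0.999$). The estimator
interpolates the profile coefficient between its two exact anchors,
$B = 1/(2R)$ at $n=2$ (parabolic) and $B = 1/\tan\theta$ at $n=1$
(conical):

$$B^{1/n} = (2R)^{1/n-1}(\tan\theta)^{n-2}/f(n), \qquad f(n) = n^{2-n},$$

the simplest correction factor with $f(1)=f(2)=1$. Substituting gives the
closed-form prefactor implemented in `simplified_prefactor()`:

$$c = \frac{2E^*}{\pi^{1/(2n)}}\,(2R)^{1-1/n}\,(n\tan\theta)^{2-n}\,
  \frac{n}{n+1}\left[\frac{\Gamma(n/2+1/2)}{\Gamma(n/2+1)}\right]^{1/n}.$$

Both closed-form reductions (Sneddon at $n=1$, Hertz at $n=2$) hold to
machine precision; they pin the algebraic grouping uniquely, which is why
the test suite asserts them exactly. The workflow is then: fit
$F = c\,h^m$ (`fit_power_law()`, unweighted Levenberg–Marquardt on the
raw data, initialised from a log–log regression), set $n = 1/(m-1)$, and
invert $c$ — linear in $E^*$ — for the modulus
(`modulus_from_powerlaw()`). The same prefactor is applied to blunted
pyramids (equivalent-cone treatment); an effective half-angle can be
supplied when a remapping is wanted.

A guard rejects $m \le 1 + 10^{-6}$: there $n = 1/(m-1)$ blows up, and
force–indentation data that linear usually mean a flat-punch-like
(damaged or contaminated) apex rather than a fittable blunted shape —
that case should be reported, not silently inverted (see the `diagnose`
CLI command, which flags exponents outside $[1.4, 2.05]$).

## Accuracy, and how it was measured

The `x_ratio()` diagnostic quantifies the estimator on noiseless exact
curves with known $E^*$: $X = AE^*/c$, the ratio of the fitted prefactor
to the theoretical one at the fitted exponent, so $X-1$ is the relative
error of the recovered modulus. Two regimes matter, and the package's own
measurements (all recomputed in the test suite) are:

* **Fits restricted to the blunted segment** $h \in [h_T, h_\max]$
  (contact-radius windows $b < a \le 5b$, i.e. $h_\max/R$ up to 8.35):
  $|X-1| \le 0.06$, with the largest values (4–6%) for steep tips
  ($\theta = 25^\circ$) and windows reaching $h \sim 2R$. $X$ is an
  ill-conditioned diagnostic: because $c$ depends steeply on $n$,
  $\mathrm{d}X/\mathrm{d}m \approx -5$ near $m \approx 1.35$, so two
  defensible fitting protocols that differ by under 1% in $m$ (e.g.
  absolute vs. relative residual weighting, or uniform-in-$a$ vs.
  uniform-in-$h$ sampling) report $X$ values several percent apart. The
  package fixes one protocol — unweighted least squares on uniformly
  sampled raw data — and reports what it computes.
* **Fits from first contact** ($h$ from $\approx 0$ to $h_\max$), the
  practical use case: at $\theta = 35^\circ$ recovery is within about 2%
  for $h_\max \le 1.5R$ and the noisy-batch means in the tests are
  within 3% of truth. Steep tips are worse: at $\theta = 25^\circ$ with
  $h_\max = 1.5R$ the estimator is biased low by roughly 10–12%, because
  the spherical-cap segment (whose local exponent falls *below* $3/2$
  with depth) dominates a larger share of the window. For steep tips at
  depths beyond $R$, prefer `fit_classic()`.

The classic fit itself (`fit_classic()`) exploits the linearity of the
exact model in $E^*$: the one-parameter least-squares solution is the
closed-form projection $E^* = \sum F_i g_i / \sum g_i^2$ with $g_i$ the
unit-modulus prediction. It involves no iteration, is exact on
self-generated noiseless curves (asserted to $10^{-10}$), and serves as
the reference against which the simplified estimator is validated.

## Method selection

`select_method()` encodes the decision flowchart, in precedence order:

| condition | method | exponent |
|---|---|---|
| $h_\max/R < 0.1$ | `hertz` | fixed $m = 3/2$ |
| $h_\max < 3R$ | `simplified_blunt` | free $m$, prefactor inversion |
| $h_\max/R > 10$ | `sneddon_cone` | fixed $m = 2$ |
| otherwise | `large_depth` | $m = 2$ with blunt-corrected $r_c$ |

The $3R$ bound is where the simplified prefactor's interpolation error
reaches a few percent (the $b<a<5b$ window above, $h_\max = 8.35R$,
shows 4–5%). Beyond it the large-depth model takes over: integrating the
contact stiffness $S = 2E^*r_c$ of a power law gives
$F = (2/m)E^*r_c h$, and expanding the exact blunted-cone relations for
$a \gg b$ under the deep-indentation approximation $h_T \approx R$ gives
the effective contact radius

$$r_c \approx \frac{2}{\pi}\bigl[h\tan\theta + R(2-\tan\theta)\bigr].$$

With $m = 2$ this matches the exact model to 0.4% at $h = 3R$ and about
1% at $h = 10R$ for $\theta = 35^\circ$ (under 4% at $\theta=25^\circ$),
and tends to the Sneddon cone as $h/R \to \infty$ — both gated by tests.
The $m=2$ choice is forced by that limit; `fit_large_depth()` recovers a
20 kPa truth within about 1% on exact deep curves.

## Numerical choices

* **Units** are strict SI internally (m, N, Pa); nm/nN and friends are
  converted at the I/O boundary only. Half-angles are stored in radians
  and accepted in degrees at every user-facing constructor.
* **Cancellation-free kernels.** Near the transition the naive
  expressions lose all significance ($b/a$ rounds to 1, $a^2-b^2$
  cancels). The implementation uses
  $\pi/2 - \arcsin(b/a) = \operatorname{atan2}(\sqrt{d(a+b)},\,b)$ and
  $a - \sqrt{a^2-b^2} = b^2/(a+\sqrt{a^2-b^2})$ with $d = a-b$ carried
  explicitly, which stay accurate to machine precision arbitrarily close
  to $a = b$ and for $a \gg b$.
* **Depth inversion.** $h(a)$ is strictly increasing, so
  `contact_radius_from_depth()` brackets the unique root and solves with
  `uniroot`. Because $h - h_T \propto \sqrt{a-b}$ near the transition,
  the solver works in $u = \sqrt{a-b}$, in which the relation is smooth;
  the bracket grows geometrically until the residual changes sign, and
  the returned root satisfies $|h(a)-h|/h \le 10^{-10}$ (checked, with a
  hard error otherwise).
* **Power-law fitting** is unweighted nonlinear least squares
  (`minpack.lm::nlsLM`, `ftol` $10^{-15}$), initialised from the log–log
  regression. $R^2$ is $1 - SS_{res}/SS_{tot}$ on untransformed data.
  Fitted exponents are stable to sampling density (the 100- vs
  1000-point windows in the tests agree in $m$ to better than 0.1%; the
  prefactor, with its long lever arm, to about 1%).
* **Degenerate inputs**: non-positive depths, fewer than 5 points, and
  $m \to 1$ are hard errors; $h \ge R$ in the corrected sphere model and
  $h \le 3R$ in the large-depth model are warnings, since both formulas
  remain evaluable.

## The synthetic-data generator

`simulate_curves()` emulates a standard validation protocol: an elastic
half-space with $E = 20$ kPa and $\nu = 0.5$ probed by blunted conical
or pyramidal indenters (defaults $R = 200$ nm, $\theta = 35^\circ$) on a
0.1 N/m cantilever, with i.i.d. zero-mean Gaussian noise added to the
force channel. Choices worth stating:

* **Noise level.** The default is $\sigma = 2\%$ of the curve's maximum
  force. With 30 replicates this yields simplified-estimator scatter of
  a few tenths of a kPa at 20 kPa, the order of scatter such validation
  exercises exhibit; it is configurable (absolute newtons, or metres of
  deflection passed through the spring constant — off by default, since
  force-space noise is the conventional abstraction).
* **Depth grid**: uniform on $[h_{max}/n, h_{max}]$ with $n = 200$
  points; the zero-depth point is excluded so the log–log initialiser is
  defined.
* **Determinism**: a fixed seed makes output bit-reproducible, including
  written files (asserted byte-for-byte in the tests).

What the generator does *not* emulate — and hence what passing tests do
not certify about real data: contact-point mis-identification (curves
are assumed baseline-corrected; a hook is left in the reader),
cantilever calibration error, adhesion, viscoelastic rate dependence,
finite sample thickness and substrate effects, and sample heterogeneity.
On heterogeneous samples the fitted modulus is a depth-weighted average
and will drift with $h_\max$.

## Problem sizes

The shipped tests and the acceptance script use 200-point curves,
30-replicate noisy batches, and 100–1000-point density sweeps — sizes at
which every quantity reported here is stable to well inside its stated
tolerance, and the whole suite runs in seconds.

## Known limitations

* The simplified estimator assumes the tip geometry ($R$, $\theta$) is
  known; errors in $R$ propagate roughly as $(2R)^{1-1/n}$.
* Steep tips ($\theta \lesssim 25^\circ$) indented beyond $h \sim R$:
  use `fit_classic()` (see the accuracy section).
* No adhesion (JKR/DMT), viscoelasticity, or bottom-effect corrections;
  vendor file formats are out of scope — export curves to plain text.
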