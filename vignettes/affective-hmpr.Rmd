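---
title: "Modelling affective valence and arousal from skin conductance responses"
author: "hmpr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling affective valence and arousal from skin conductance responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmpr)
```

## The estimation problem

Event-related electrodermal activity carries information about the
affective state evoked by a stimulus. `hmpr` models the chain from a raw
skin conductance segment to a continuous (valence, arousal) estimate on
the 1–9 SAM scale in three stages: decompose the segment into a pure
skin conductance response (SCR), statistically enlarge the resulting
small per-stimulus feature table, and fit polynomial response surfaces
from SCR parameters to ratings. This vignette documents the models, the
tunable parameters, and the numerical and design decisions behind each
stage, together with what the synthetic test bed does and does not
establish.

## The six-parameter segment model

A pure SCR is the four-parameter sigmoid-exponential waveform
$$ f(t) = g\,\frac{e^{-(t - T_{os})/t_d}}{1 + e^{-(t - T_{os})/t_r}}, $$
where $g \ge 0$ (µS) scales the amplitude and is read as neural
activation intensity, $T_{os} \ge 0$ (s) is the onset latency after the
stimulus, $t_r > 0$ (s) shapes the sigmoid rise, and $t_d > 0$ (s) is
the exponential decay constant of the falling limb. The waveform is
non-negative and vanishes as $t \to \infty$; for a typical
parameterisation ($g = 0.8$, $T_{os} = 1.2$, $t_r = 0.7$, $t_d = 3.5$)
it peaks near $t = 2.17$ s at about $0.485$ µS.

A realistic post-stimulus segment rides on the decaying limb of the
previous response and a tonic level, giving the six-parameter model
$$ s(t) = a_0\,e^{-t/t_d} + c + f(t), $$
with $a_0 \ge 0$ the previous-response amplitude at stimulus onset and
$c \ge 0$ the tonic skin conductance level (SCL). Keeping the parameter
count at six forces the tail to share a decay constant with the SCR;
`hmpr` reuses $t_d$, the natural choice since both terms describe sweat
re-absorption through the same effector.

### Fitting: bounds, restarts, convergence

`fit_sc_segment()` minimises the residual sum of squares by
Marquardt–Levenberg iteration (through `minpack.lm`), starting from the
heuristic of `initial_guess()`: $c$ from the trace minimum, $a_0$ from
the onset value, and — after subtracting the implied tail
$a_0 e^{-t/3} + c$ — the gain from the detrended maximum and $T_{os}$
from the steepest detrended rise. The detrending step matters: when a
strong tail makes the whole segment monotone decreasing, the steepest
*raw* slope sits at the end of the segment and strands the optimizer in
a basin where the SCR escapes past the window.

Numerical choices:

* **Bounds.** Parameters are box-constrained to their meaningful ranges
  ($g, a_0, c \ge 0$; $0 \le T_{os} \le$ segment end;
  $10^{-3} \le t_r \le 10$ s; $10^{-3} \le t_d \le 20$ s) using the
  optimizer's native box constraints. Bounding beats a log
  reparameterisation here because several parameters legitimately sit
  *at* zero (a segment with no previous response has $a_0 = 0$), where a
  log transform degenerates.
* **Restarts.** The SSE surface has a second characteristic local
  minimum in which the tail absorbs the SCR. Alongside the heuristic
  start, the fit is deterministically restarted from a small fixed grid
  (onset at 10/20/30% of the segment × decay 1.5/6 s) and the lowest-SSE
  solution kept. The returned SSE therefore never exceeds that of the
  plain heuristic-start fit.
* **Convergence.** Declared when the relative SSE change drops below
  `tol` ($10^{-8}$); the iteration cap (default 20) is per start. The
  historical "20 iterations" prescription is read as *up to* 20 with
  early stopping; recovery studies in the test suite raise the cap to
  100, which matters only in the last decimals.

Across 240 noiseless synthetic traces (10 seeds × 24), this
configuration recovers all six generating parameters to better than
$10^{-3}$ relative error in every case; with 0.01 µS Gaussian noise at
the default 32 Hz sampling, the median gain error stays below 5%.

## The data-extending construction

Polynomial models of useful order need more rows than a 24-stimulus
experiment provides. For a sample $\xi_1,\dots,\xi_n$ with mean $\mu$
and variance $\sigma^2$, the extension builds one pseudo-observation per
unordered pair,
$$ \eta_{ij} = \mu + \frac{\xi_i + \xi_j - 2\mu}{\sqrt{2}}, $$
yielding $n(n-1)/2$ values. Each $\eta_{ij}$ has mean $\mu$ and variance
$\sigma^2$; two $\eta$'s sharing a source index correlate at $0.5$,
disjoint ones at $0$, and $\eta_{ij}$ correlates with its own source
$\xi_i$ at $1/\sqrt 2$. These claims hold exactly for the known-$\mu$
form, and the test suite verifies them by simulation
($\xi \sim N(5, 4)$, $n = 8$, 10{,}000 replicates, ±0.02 bands).

In application $\mu$ is unknown, so `extend_column()` defaults to the
plug-in sample mean $\bar x$. The substitution attenuates the moments by
$O(1/n)$ terms (at $n = 8$ the overlap correlation drops to ≈ 0.42 and
the variance to ≈ 0.85 σ²); the known-$\mu$ form remains available via
the `mu` argument for anyone studying the construction itself.

Two design choices in `extend_table()`:

* **Shared pair enumeration.** Within a class, every column is extended
  with the *same* (i, j) enumeration, so a simulated row combines one
  pair of source stimuli coherently across gain, decay constant and
  ratings. Independent per-column pairing would preserve marginal
  moments but destroy the joint (g, t_d, V, A) pattern that the
  regression stage consumes — an affine relation between two columns
  survives the shared-pair extension exactly, which the tests assert.
* **All pairs, lexicographic.** The construction is deterministic; no
  random subsetting. 3 classes × $\binom 8 2$ gives the 84 training
  rows.

A consequence worth noting: the extension is an affine map of each
column. A relation $y = P(x_1, x_2)$ between columns survives it exactly
when $P$ is affine, but curvature terms are attenuated, so extended rows
sit slightly off a curved generating surface. This is visible in the
closed-loop tests below.

## Higher-order multivariable polynomial regression

The $p$-th order model in $m$ variables uses every monomial
$x_1^{e_1}\cdots x_m^{e_m}$ with $\sum_v e_v \le p$ —
$\binom{m+p}{m}$ terms, enumerated in graded order. The model is linear
in its coefficients, so fitting is linear least squares on the expanded
design. Two standing numerical issues and their treatment:

* **Near-singular designs.** High-order monomials in raw units (g in
  µS, t_d in s) are nearly collinear. The solve is truncated-SVD least
  squares: singular values below `singular_criterion` (default
  $10^{-8}$) *relative to the largest* are zeroed and the minimum-norm
  solution on the retained subspace returned. The relative cutoff makes
  the solve invariant to uniform rescaling of the design. Standard
  errors use the truncated pseudoinverse with residual variance on
  $n - \mathrm{rank}$ degrees of freedom; a saturated fit flags its
  p-values as `NA` rather than failing.
* **Overparameterisation.** After the initial fit, backward elimination
  removes the single least-significant term with $p > \alpha$ (default
  $\alpha = 10^{-4}$) and refits, until all retained terms are
  significant or only the intercept remains. The intercept is exempt;
  terms with undefined p-values are never removed on that evidence.
  One-at-a-time elimination with refitting is the conservative reading
  of "fit under a significance level": correlated monomials can trade
  significance, so batch deletion is unsafe.

Inputs are *not* standardised before expansion by default (the published
model class operates on raw g and t_d); `fit_config(scale_inputs =
TRUE)` enables centring/scaling for conditioning, with predictions and
gradients mapped back automatically.

### Order selection and the Index

Models are compared by the **Index = r / MSE**. Both metrics improve the
score in their natural direction, and a perfect fit (MSE = 0) returns
`Inf` as a documented sentinel. `select_order()` fits each candidate
order on the training set (the extended rows, in the intended workflow)
and computes the Index on a designated evaluation set (the experimental
rows); the argmax wins and exact ties break toward the lower order.
Evaluating on the experimental rows rather than the training rows is
deliberate: the extension manufactures correlated rows, so training-set
metrics flatter high orders.

The 95% CI attached to the Pearson r uses the Fisher z transform
(via `cor.test`); it is descriptive only and never drives selection,
since CI constructions vary across software and the Index is the
defined criterion.

### Gradient fields

`gradient()` differentiates the fitted polynomial analytically
(exponent-weighted, degree-lowered monomials); `gradient_field()`
evaluates it on a rectangular grid for quiver plots and CSV export. In
the affective application the field answers a qualitative question:
arousal surfaces come out gain-dominated (arrows near-parallel to the
gain axis), while valence surfaces respond to both gain and decay
constant.

## The synthetic experiment

`default_affective_config()` emulates the study design the pipeline
assumes: 3 affect classes × 8 stimuli, SCR parameters drawn per class
from truncated normals (reject-and-redraw at zero), and ratings produced
by a known polynomial ground truth of (g, t_d) plus Gaussian noise
(SD 0.3 rating units), clipped to [1, 9]. Class centres place pleasant
stimuli at high gain / slow decay, neutral at low gain, unpleasant at
the highest gain / fastest decay, so pure SCR waveforms cluster by
class and a one-way ANOVA on gain separates the classes decisively —
the screening behaviour the pipeline expects. The ground-truth
coefficients are *solved* from the class-centre rating targets (valence
≈ 7 / 5 / 2.5, arousal ≈ 5.5 / 3 / 6), making arousal affine and
gain-dominated while valence carries a gain × decay interaction
(coefficient 0.5 by default) so its surface is genuinely curved. Traces
are synthesised from the six-parameter model with uniform previous-tail
amplitudes (0.1–0.6 µS), tonic levels (2–4 µS), 0.01 µS Gaussian noise,
at 32 Hz for 10 s — 32 Hz being a typical electrodermal analysis rate —
and returned with their generating truth for recovery studies.

What the generator does *not* emulate: subject-level variability and
habituation across blocks, overlapping multi-SCR segments, movement
artifacts, and measurement quantisation. Passing tests therefore
establish that the estimation stack is internally correct — each stage
recovers what the previous stage encodes — not that real skin
conductance supports any particular estimation accuracy.

### Closed-loop exactness and the interaction term

The full pipeline (extend → fit → evaluate) reproduces a noiseless
generated table with $r = 1$ to $10^{-6}$ **when the generating map is
affine**, because the extension is affine per column. With the default
interaction term the extended rows sit slightly off the generating
surface and the closed loop is merely very accurate rather than exact.
The exactness test therefore uses
`default_affective_config(valence_interaction = 0, rating_noise_sd = 0)`
— a documented configuration, not a special code path. Similarly, the
clipping of ratings to [1, 9] is a deliberate departure from
polynomial behaviour in the far parameter tails; coefficient-recovery
tests on large noiseless tables restrict to the unclipped interior.

## Problem sizes and runtime choices

The test suite and reference experiments use the study-scale sizes
throughout: 24 stimuli (3 × 8), 84 extended rows, order sweeps over
1–6 (module tests) or 1–9 (pipeline default), 10,000 replicates for the
extension moments, 24–50 traces for SCR recovery, and 20 Monte-Carlo
replicates for noisy-fit studies. These sizes keep every experiment
deterministic under a single seed and fast enough to run as ordinary
unit tests while leaving the statistical bands (3 SE, ±0.02) narrow
enough to be informative.

## Known limitations

* One SCR per segment: overlapping-event deconvolution is out of scope;
  the previous response enters only through its decaying tail.
* The extension theorem's printed correlation structure assumes the
  population mean; with the plug-in mean at $n = 8$ the attained
  correlations are attenuated (documented above), which mildly reduces
  the effective information in the 84 training rows.
* Backward elimination explores one deletion path; with strongly
  correlated monomials a different path can retain a different (equally
  predictive) term set, so retained-term identity is not a stable
  scientific conclusion — predictions and gradients are.
* Index-based selection on 24 evaluation rows is noisy; with realistic
  rating noise the sweep can prefer an order above the generating one
  when the extra flexibility happens to fit the evaluation rows better.
  The per-order report table is always written so the margin is
  inspectable.
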