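---
title: "Model-free analysis of 15N backbone relaxation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-free analysis of 15N backbone relaxation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(spinrelax)
```

## The physical model

Backbone amide ¹⁵N relaxation is driven by two interactions modulated by
molecular motion: the ¹H–¹⁵N dipolar coupling and the ¹⁵N chemical-shift
anisotropy (CSA). Under the model-free ansatz, overall tumbling and
internal motion are statistically independent, and all motional information
enters the rates through the spectral density

$$J(\omega) = \frac{2}{5}\left[\frac{S^2\tau_m}{1+(\omega\tau_m)^2} +
  \frac{(S_f^2-S^2)\,\tau'}{1+(\omega\tau')^2}\right],\qquad
  \frac{1}{\tau'}=\frac{1}{\tau_m}+\frac{1}{\tau_e},$$

with the 2/5 prefactor carried inside $J$. Here $\tau_m$ is the overall
rotational correlation time, $S^2 \in [0,1]$ the squared generalized order
parameter (1 = rigid N–H vector), $\tau_e$ the effective internal
correlation time, and $S_f^2$ the fast-motion order parameter of the
extended (two-timescale) form; the simple Lipari–Szabo form is the
$S_f^2 = 1$ special case. Total spectral power is conserved:
$\int_0^\infty J(\omega)\,d\omega = \frac{\pi}{5}S_f^2$, independent of
$\tau_m$ and $\tau_e$ — the test suite verifies this numerically to 1e-6
relative error, which pins the prefactor convention.

The observables follow the standard dipolar+CSA expressions (`predictRates()`),
with $d = \mu_0 h \gamma_H\gamma_N/(8\pi^2 r_{NH}^3)$ and
$c = \omega_N\Delta\sigma/\sqrt{3}$. Conformational exchange enters $R_2$
only, as an additive $R_{ex}$. Since $R_{ex}$ scales with the square of the
static field, records from different spectrometers are fitted per field and
only $\tau_m$ is shared across fields.

Defaults (all exposed in `spectrometerContext()` so sensitivity can be
tested): $r_{NH} = 1.02$ Å, $\Delta\sigma = -160$ ppm,
$\gamma_H/\gamma_N = -9.8656$, and a nominal "600 MHz" spectrometer read as
600.13 MHz. These are the community values of the classic model-free
software generation. The sign of $\gamma_N$ is carried only in the NOE
expression; $\omega_N$ is derived from the ratio's magnitude.

For anisotropic tumblers an axially symmetric variant is provided
(`spectralDensityAxial()`): three Lorentzians with correlation times built
from $D_\parallel$ and $D_\perp$ and orientation weights
$A_1=((3\cos^2\theta-1)/2)^2$, $A_2=3\sin^2\theta\cos^2\theta$,
$A_3=\frac{3}{4}\sin^4\theta$ (summing to 1), where $\theta$ is the angle
between the N–H vector and the unique axis. At $D_\parallel/D_\perp = 1$ it
reduces exactly to the isotropic form. The final analyses here use the
isotropic model: the anisotropy reported for small disintegrins
($D_\parallel/D_\perp \approx 1.25$) perturbs per-residue $J(\omega)$ far
less than the printed rate uncertainties, and per-residue N–H orientations
would import a structural model into an otherwise coordinate-free analysis.
Fully asymmetric (three-axis) diffusion is out of scope.

## Rate estimation from decay series

$R_1$ and $R_2$ come from nonlinear least squares of
$I(t) = I_0 e^{-Rt}$ on the *untransformed* peak heights
(Levenberg–Marquardt via `minpack.lm`), initialized from a log-linear
regression. Fitting untransformed heights is the correct error model for
intensity noise; the log-linear fit only supplies the start. No baseline
offset is fitted by default (heteronuclear ¹⁵N decays relax to zero); an
offset term sits behind a flag for nonideal data. Exactly two points
determine the exponential in closed form; fewer than three *distinct*
delays otherwise raise an error. Non-decaying series are returned flagged
(`non_decaying`) rather than dropped, and fitted rates outside
0.01–100 s⁻¹ trigger a delay-unit warning (the classic ms-vs-s mistake).

Replicates (default two independent data sets) are averaged; the reported
uncertainty is the **larger** of the propagated fit sigma and the
half-range across replicates. The convention for published tables of this
kind rarely states its error rule; taking the max is conservative and
testable. NOEs are means of saturated/reference height ratios over
experiment pairs (default three), with the pair standard deviation as the
uncertainty (zero for a single pair).

## Chi-square fitting and model selection

Each residue is fitted by minimizing
$\chi^2 = \sum_{X\in\{R_1,R_2,NOE\}}((X_{obs}-X_{pred})/\sigma_X)^2$ over
the free parameters of models m1 {S²}, m2 {S², τe}, m3 {S², Rex},
m4 {S², τe, Rex}, m5 {Sf², Ss², τe}. Uncertainties below 0.5% of the value
are raised to that floor: published tables carry ±0.01-scale errors that
would otherwise dominate the target function.

Numerical choices:

* **Multi-start bounded optimization** (L-BFGS-B): S² starts
  {0.3, 0.6, 0.9}, τe starts {10 ps, 100 ps, 1 ns}, Rex starts {0, 2} s⁻¹;
  bounds S² ∈ [0,1], τe ∈ [0, τm], Rex ∈ [0, 20] s⁻¹. The χ² surface is
  multimodal in τe, so a single start is not trustworthy. The best start is
  polished at tight tolerance so results are start-independent to ~1e-6;
  a test cross-checks model-2 fits against an exhaustive grid search
  (S² step 0.005, τe log-spaced 1 ps–10 ns).
* **Degenerate point**: at $S^2 = S_f^2 = 0$ every spectral density
  vanishes, $R_1 = 0$, and the NOE (which divides by $R_1$) is undefined;
  the objective returns a large finite penalty there so the bounded
  optimizer can pass by without crashing.
* **Boundary status**: a fit with any parameter within tolerance of a
  bound is labelled `boundary` (e.g. Rex pinned at 0), which is itself
  informative — it is how the exchange-free variant's loop residues
  present.

Selection is the standard stepwise hierarchy: accept m1 if it passes a χ²
goodness-of-fit test at the 90% level; otherwise accept m2 or m3 when they
pass their own goodness-of-fit *and* improve on m1 by an F-test at the 80%
level; otherwise consider m4/m5. Goodness-of-fit critical values are built
per record from 500 Monte Carlo simulations around the back-calculated
rates (`gof_method = "monte_carlo"`); an analytic χ² quantile path
(`"chisq"`) is provided for bulk work and τm grids. With three observables
the three-parameter models have zero residual degrees of freedom, so an
F-test (whose denominator would have zero dof) is undefined there; instead
a likelihood-ratio-style rule is used: the χ² drop relative to the best
simpler model must exceed the 80% χ² quantile for the added parameters.
Ties go to the lower model id. This reproduces the expected phenomenology:
exchange-broadened rigid residues select an Rex-containing model, while
residues with slow internal motion and no exchange select a τe-containing,
Rex-free model (m4 pins Rex at zero there and is not accepted over m2).

Parameter uncertainties are Monte Carlo: `n_draws` synthetic records drawn
Gaussian around the back-calculated rates with the record's sigmas, refitted
from the fitted parameters; the reported sigma is the standard deviation of
the refits. Reproducible under a fixed seed; seeds are explicit arguments
everywhere randomness enters.

## Overall correlation time

$\tau_m$ is fitted in two stages, mirroring the usual model-free flow:
first on a "core" subset — NOE > 0.65 and no exchange flag (R2/R1 more
than one standard deviation above the 10%-trimmed mean ratio of the
NOE-qualified set) — because flexible and exchanging residues bias the
estimate; then fixed for the final per-residue fits. The optimizer walks a
1–15 ns grid at 0.1 ns with per-residue model re-selection at each
candidate, then refines by golden-section search. The initializer
(`estimateTmR2R1()`) inverts the rigid-body R2/R1 ratio numerically from
the trimmed-mean ratio.

One subtlety is worth stating because it shapes the objective: with a free
τe, a rigid residue's triplet can be fitted *exactly* at any τm above the
true value (the τm–S²–τe degeneracy), so a naive "min over models" total
χ² is flat in τm and its minimum undefined. The per-residue re-selection
on the grid therefore carries an AIC-style parsimony penalty of 2 per
added parameter; extra parameters only win where they genuinely reduce
misfit, and the total regains a unique minimum at the generating τm. The
final per-residue fits are unaffected (they use the full stepwise rule at
fixed τm).

## The synthetic-data generator

`makeProfile()` emulates the study system: 68 residues, isotropic
τm = 6.38 ns, a disulfide-bonded core drawn from S² ~ N(0.82, 0.05)
truncated to [0.70, 0.95] with τe < 50 ps, flexible termini, and an RGD
loop (residues 48–52) set to the published per-residue values of either
variant: the wild-type-like preset carries exchange at R49/D51
(Rex = 0.91/1.42 s⁻¹, τe = 0.11/0.19 ns) and the mutant-like preset the
slow-motion signature (S² = 0.53–0.74, τe ≈ 1 ns, no Rex). Proline
positions (48 in the wild-type-like preset, 53 in both) are generated but
withheld from observable output, reproducing the missing-residue gaps of
real spectra. `simulateDecays()` emits peak heights
$I_0 e^{-Rt}(1+\varepsilon)$, $\varepsilon \sim N(0, cv)$, on the standard
ten-delay schedules (30–3000 ms for R1, 18–500 ms for R2), two replicates
per rate and three NOE pairs. Noise is multiplicative (constant CV):
peak-height scatter in well-resolved HSQCs scales with intensity. The
default CV of 2% was chosen once as the level that yields rate
uncertainties on the scale of published ± values; it is a configuration
knob, not a fitted quantity.

What the generator does **not** emulate: spectral overlap, lineshape
distortions, baseline artefacts, anisotropic tumbling, correlated noise
between replicates, and sidechain dynamics. Passing recovery tests
therefore demonstrate the estimator chain is unbiased and well-calibrated
under clean multiplicative noise — not that it is robust to pathological
spectra; real data should be inspected at the peak-height stage.

## Problem sizes and determinism

The test suite runs the full pipeline (decays → rates → τm → model-free)
on one 68-residue dataset at 2% noise, selection properties on 100 seeded
single-residue trials, the rate-estimator calibration on 1000 seeded decay
series, and recovery-degradation checks on 16-residue profiles at three
noise levels — sizes chosen to exercise every stage while keeping the suite
comfortably rerunnable during development. All stochastic steps take
explicit seeds; two runs with the same seed are bitwise identical, and
every pipeline output directory carries a JSON manifest (config snapshot,
input digests, seed, version) from which a run can be reproduced exactly.

## Known limitations

* The stepwise selector inherits the classic weaknesses of hypothesis-test
  selection: near test thresholds the chosen model can flip under noise,
  and with only three observables per field the three-parameter models fit
  exactly, so their parameters lean entirely on the selection rule. Joint
  multi-field fitting (beyond a shared τm) and Bayesian model averaging are
  out of scope.
* Rex is stored at its own field's value; cross-field comparison assumes
  quadratic field scaling where enabled.
* The wild-type comparisons assume the two variants share τm when a
  variant's own τm is not independently determined; conclusions that
  depend on that assumption are flagged as conditional in the tests.
* Composite chemical-shift perturbations use the standard amide weighting
  with a configurable nitrogen weight; published per-residue composite
  values cannot be re-derived without the underlying shift lists, so they
  are treated as reference numbers only.
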