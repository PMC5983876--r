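---
title: "Models and methods behind orkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind orkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orkin)
```

`orkin` analyzes odorant–olfactory-receptor (OR) dose-response panels
through a minimal kinetic model of GPCR activation, and propagates the
fitted statistics to perception-level quantities. This vignette explains
the model and its assumptions, the estimators and their numerical
choices, what the synthetic-data generator does and does not emulate, and
the design decisions taken where more than one reasonable choice existed.

## The kinetic model and its exact Hill form

The activation scheme has two G-protein binding branches: to the free
receptor (rate $k_{Gf}$, dissociation constant $K_G$) and to the
odorant-occupied receptor (rate $k_{OGf}$, constant $K_{OG}$), with the
odorant binding/unbinding at dissociation constant $K_O$. At steady state
the signaling output is a ratio of functions linear in the odorant
concentration $C_O$, hence exactly a Hill curve with $H = 1$ whose
parameters map to the microscopic constants:

$$K_{1/2} = K_O\,\frac{1 + C_G/K_G}{1 + C_G/K_{OG}},\qquad
E = \frac{A C_G k_{OGf}}{1 + C_G/K_{OG}},\qquad
B = \frac{A C_G k_{Gf}}{1 + C_G/K_G}.$$

Assumptions worth stating:

* **Steady state per dose.** Each concentration is an equilibrium
  measurement; no binding kinetics in time are modeled.
* **Identifiability.** Dose-response data constrain only the ratios
  $C_G/K_G$ and $C_G/K_{OG}$ and the product $A C_G k$. Internally
  concentrations are molar, EC50 is always $\log_{10}(K_{1/2}/1\,\mathrm{M})$,
  and the G-protein quantities are carried in relative units with
  $C_G = 1$, $A = 1$ by convention. Every inferred quantity exposed by
  the package (the on-rate enhancement $k_{OGf}/k_{Gf}$, $\omega$,
  $\log_{10} K_O$) is invariant to this gauge, and tests assert
  invariance under global response rescaling.
* **$H \neq 1$ is phenomenological.** Empirical curves are steeper or
  shallower than the $H = 1$ scheme; the fit treats $H$ as a free
  shape parameter and no mechanistic model (oligomerization,
  zero-order ultrasensitivity) is attached to it.
* Both $\log_{10} K_O$ and the equivalent binding free energy
  $-\ln K_O$ (in $k_BT$ units) are reported by `estimate_KO()`, since
  either convention is used for tabulating binding strengths.

The consistency inequality $1 \le K_O/K_{1/2} \le K_G/K_{OG}$
(`check_consistency()`) is an algebraic consequence of the parameter
maps whenever $K_{OG} \le K_G$ and $C_G > 0$; its violation flags
odorant-weakened G-protein binding.

## Hill fitting

`fit_hill_curve()` estimates $(B, \delta S_{max}, \log_{10} K_{1/2}, H)$
by bounded nonlinear least squares. Numerical choices:

* **Profiled multistart.** For fixed $(\log_{10} K_{1/2}, H)$ the model
  is linear in $(B, \delta S_{max})$, so each candidate on the 5×5
  multistart grid (log-EC50 spanning the dose range, $H$ log-spaced in
  $[0.3, 6]$) costs one weighted 2×2 solve. The best three candidates
  are polished by L-BFGS-B with an analytic gradient; free-$H$ Hill
  fits are multimodal and this combination is what the recovery tests
  hold to tolerance. Ties in the final sum of squares go to the
  smaller $H$.
* **Bounds.** $H \in [0.2, 10]$ (beyond the range seen in fitted
  panels), $\log_{10} K_{1/2}$ within the sampled dose range ±2
  decades, $B \ge 0$ by default (configurable, since published fits do
  not state the constraint).
* **Replicates** are averaged per concentration before fitting,
  weighted by replicate count (also configurable).
* **Degenerate data** (flat responses) pin $\delta S_{max}$ to 0 with
  status `unreliable`; optimizer failure yields a flagged record, never
  an exception mid-panel.
* **Goodness of fit** is the Pearson correlation between observed and
  fitted responses; records classify as activating/deactivating only at
  `corr >= 0.9` (configurable). Deactivating pairs use the same model
  with $\delta S_{max} < 0$ — no separate inverse-agonist form.

The collapse diagnostic maps each datum to
$\xi = H \log_{10}(C_O/K_{1/2})$, $f = (S - B)/\delta S_{max}$, on which
every reliable fit lies on $f = 10^\xi/(1 + 10^\xi)$; the RMS deviation
from that curve measures residual structure beyond measurement noise.

## Population models

* **EC50.** Gaussian by closed-form maximum likelihood, with sample
  skewness reported because screening cutoffs truncate weak-affinity
  tails in real panels.
* **Efficacy.** Two-exponential mixture by EM (weights and two
  component means), mean-ordered, 20 restarts (quantile-anchored plus
  random), converging on the log-likelihood to 1e-8. The
  single-exponential null — the maximum-entropy density at fixed mean —
  is fitted alongside and the likelihood-ratio statistic reported, so
  the two-population claim is checked rather than assumed. EM is
  written in the package: no installed package fits exponential
  mixtures, and the monotone-likelihood property is asserted in tests
  against a hand-stepped EM.
* **Differential response.** For one odorant, $\psi_\lambda$ sums the
  analytic derivative $\partial S/\partial \log_{10} C_O$ of each
  partner's fitted curve (deterministic and noise-robust, unlike
  finite differences of raw data), normalized to unit trapezoid area on
  a default grid of $-10$ to $0$ log10 M, step 0.05. Deactivating
  partners contribute absolute derivatives only behind a flag; the
  default profiles activating spectra.

## Microscopic inference

The two-step procedure mirrors how the parameter maps eliminate the
G-protein milieu: (1) fit the pooled $(B, E)$ cloud of an odorant's
activating partners to $E = rB/(1 + cB)$, giving the averaged on-rate
enhancement $r = \langle k_{OGf}/k_{Gf}\rangle$; (2) average the
per-pair $\omega = \log_{10} E - \log_{10} B - \log_{10} K_{1/2}$ and
invert $\langle\log_{10} K_O\rangle = \log_{10} r - \langle\omega\rangle$.
The identity holds row-wise in every output table by construction.

Two numerical points:

* $(r, c)$ form a flat ridge when all basal activities sit on one side
  of the hyperbola knee ($cB \approx 1$); the fit therefore multistarts
  and uses an analytic gradient with tight convergence.
* Fitted $B$ is noisiest exactly at the low-basal receptors that anchor
  the initial slope, a classic errors-in-variables attenuation. When
  fit records carry their residual sum of squares, `build_micro_table()`
  reweights iteratively with $w_i = 1/\big(\mathrm{ssr}_i\,(1 +
  (\partial m/\partial B)^2)\big)$, three passes from the unweighted
  fit. Whether the original analysis weighted receptors is unstated;
  plain least squares remains available (`irls = FALSE`), and negative
  curvature estimates are warned about, not clamped, unless the
  activating-regime constraint is switched on.

## Perception-level quantities

* `expected_active_fraction()`: the Gaussian CDF of the ensemble EC50
  model — the fraction of receptor types recruited below a given
  concentration.
* `weber_ratio_min()`: $\sqrt{2\pi}\,\ln 10\,\sigma_{EC50}/N_r$, the
  bound $\ln 10 / (N_r \psi_{ens})$ evaluated at the Gaussian peak.
  The factor is $\ln 10$, not $\log_{10}$: the detectable relative
  change $\Delta C_O/C_O$ lives on the natural-log concentration scale
  while $\psi_{ens}$ is a density per decade. With $N_r = 330$ and
  $\sigma = 1.5$ the minimum is 0.026 — a ~3% change suffices at the
  sensitivity peak. The uniform-ensemble variant uses
  $R = 2\,(2\sigma)\ln 10$; published discussions use both
  $\sigma = 1.5$ and $\sigma = 1.8$ (the activating-subset and
  all-pairs widths), give $R \approx 16$ yet $R/N_r \approx 0.042$
  (which corresponds to $\sigma = 1.5$), and the package takes
  $\sigma$ as an explicit argument rather than reconciling them.
* `orn_firing_curve()`: a neuron expressing $L$ copies of one receptor
  fires when the binomially-distributed activated fraction exceeds a
  threshold. The single-copy activation probability is the normalized
  Hill occupancy $f = (C_O/K_{1/2})^H/(1+(C_O/K_{1/2})^H)$; a basal
  floor $p_0$ is available but defaults to 0, since the mapping from
  basal signaling to copy-level activation probability is not fully
  specified. The transition width shrinks as $1/\sqrt{L}$ (binomial
  CLT), so at $L = 2.5 \times 10^4$ the response is a step for any
  practical purpose — the basis for treating the receptor code as
  binary.
* `mixture_capacity_mmax()`: solves
  $m \log_2 M - \log_2 \Gamma(m+1) = N_r$ by bisection, using the
  $M^m/m!$ approximation of the binomial coefficient as written in the
  capacity argument (the exact coefficient is available behind a
  flag and changes the root by <0.01 at $M = 10^4$). The continuous
  root at $M = 10^4$, $N_r = 330$ is 34.74 — rounding to 35 — while
  the largest integer strictly satisfying the bound is 34; both are
  returned.

## The synthetic-data generator

`generator_spec()` defaults encode the statistical structure of the
published 535-pair screening panel: 304 receptors × 89 odorants at
interaction density $535/(304 \cdot 89)$; EC50 drawn per pair from
$\mathcal N(-3.6, 1.1^2)$ log10 molar (the Gaussian reported for
activating pairs); efficacy drawn per pair from the two-exponential
mixture $(\phi, \langle E_1\rangle, \langle E_2\rangle) =
(0.79, 1.50, 10.06)$; Hill coefficients log-normal about 1 (sdlog 0.3,
truncated to the observed range $[0.3, 6.6]$); 8 doses at half-decade
spacing centered on each pair's EC50 with ±0.5-decade jitter (the real
per-pair grids are unpublished; this emulates screening practice while
keeping 4-parameter fits identifiable); additive Gaussian noise with
sd = 5% of $|\delta S_{max}|$ (error bars are shown but no noise model
stated; heteroscedastic alternatives are off by default).

Design choices that needed a decision:

* **Activation is emergent.** Basal activity is drawn once per receptor
  (log-normal, sdlog 0.8) and shared across its pairs; a pair
  deactivates when its efficacy draw falls below the receptor's basal
  level. The basal median is calibrated numerically so the expected
  deactivating fraction equals the observed 475/535 split (median
  ≈ 0.17 at the defaults). This keeps the efficacy marginal exactly on
  the stated mixture — forcing the sign by resampling would truncate
  the law and bias downstream recovery.
* **Kinetic back-solve.** In the $C_G = K_G = A = 1$ gauge, drawing
  $g = K_O/K_{1/2}$ log-uniform on $[1, g_{max}]$ fixes
  $K_{OG} = 1/(2g-1) \le K_G$, so every generated pair satisfies the
  consistency inequality by construction; $k_{Gf} = 2B$ and
  $k_{OGf} = (1 + 1/K_{OG})E$ complete a ground-truth parameter pack
  stored alongside the data.
* **Single-odorant panels** (`generate_odorant_panel()`) share one
  odorant's kinetics across receptors that differ only in $C_G$
  (log-normal, meanlog −1, sdlog 2 — wide enough that basal activities
  span both sides of the hyperbola knee, which is what makes the
  amplitude identifiable) with $K_{OG} = \min(1, \max(0.05, 1.5/r))$ so
  that $K_G/K_{OG} < r$ keeps every receptor activating.

What the generator does **not** emulate — and hence what passing
recovery tests do not show about real data: screening cutoffs (no
truncation of weak pairs, so no EC50 skew), the broader and
strong-binding-enriched EC50 distribution of deactivating pairs,
chemical structure of odorants (ids are opaque), plate effects or
luminescence normalization artifacts, and any correlation between a
receptor's basal activity and which odorants it binds. Real-panel
reliability is also far lower (59% at the 0.9 correlation threshold)
than under the generator's clean noise model.

## Problem sizes and determinism

Every stochastic stage takes an explicit seed, and identical seeds
reproduce byte-identical artifacts (asserted in tests). The test suite
and acceptance script run at the study's own scales: full-loop recovery
on a ~535-pair panel, mixture recovery on 50,000 direct draws, EC50
recovery on 5,000 draws, binarization over
$L \in \{10^2, 10^4, 10^6\}$ with 4,000 trials per concentration.

## Known limitations

* Per-pair $K_{OG}$, $K_G$, $C_G$ are not identifiable from a single
  curve; only odorant-averaged combinations are reported.
* The hyperbola amplitude is poorly conditioned for odorants whose
  partner receptors all sit in saturation; the reported estimate can
  carry 20%+ error for strongly-enhancing odorants at 25 partners even
  under the IRLS weighting.
* The EM mixture fit assumes exactly two exponential components; the
  likelihood-ratio against one component is reported, but no search
  over component counts is performed.
* H > 1 curves have no kinetic back-solve; the generator's stored
  kinetics describe the H = 1 skeleton carrying the same
  $(B, E, K_{1/2})$.
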