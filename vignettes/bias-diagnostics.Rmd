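---
title: "Separating ligand bias from system bias: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating ligand bias from system bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biasdx)
```

## The problem

A biased agonist couples a receptor more effectively to one transduction
protein (a G protein, an arrestin) than to another, and that preference is
encoded in the ligand's chemistry. But two assays of the *same*
receptor–transducer interaction rarely report proportional responses: each
signalling step and each readout applies its own nonlinear amplification.
This *system bias* can masquerade as ligand bias. `biasdx` implements nine
diagnostics that attempt the separation, plus a simulator that generates
panels in which the right answer is known — either "no ligand bias at all"
(system bias only) or "this one ligand carries exactly a 10-fold efficacy
imbalance".

## The receptor-theory backbone

All classical methods start from the stimulus chain of occupancy theory.
A ligand at concentration $[L]$ occupies receptors following the binding
isotherm $O = [L]/([L] + K_d)$; the occupied receptor produces a stimulus
$s = \varepsilon O$, where $\varepsilon$ is the ligand's intrinsic efficacy;
and the tissue converts stimulus to response through an unknown monotone
function $r = f(s)$. Taking $f$ to be a slope-$n$ hyperbola gives the
operational (Black–Leff) model

$$E([L]) \;=\; \frac{r_\mathrm{max}\,(\tau [L])^n}{([L]+K_d)^n + (\tau [L])^n},
\qquad \tau = \frac{\varepsilon}{K_E}\ \text{(transduction coefficient)},$$

with plateau $E_\mathrm{max} = r_\mathrm{max}\tau^n/(1+\tau^n)$ and midpoint
$EC_{50} = K_d/\big((2+\tau^n)^{1/n}-1\big)$, which reduces to
$K_d/(1+\tau)$ at $n=1$. Curves are fitted in log-concentration form
(`fit_logistic3`, `fit_logistic2`, `fit_operational`) by multi-start
Levenberg–Marquardt least squares; covariance and pointwise confidence
bands come from the standard asymptotic linearization. Curve means are fit
unweighted by default (replicate-averaged curves), with inverse-variance
weighting available via `bias_config(weights = "inverse_variance")`.

A *bias factor* is always the base-10 log of the cross-assay ratio of a
ligand's relative efficacy (relative to a shared reference full agonist):
$\mathrm{bias} = \log_{10}\!\big(\mathrm{RE}_A / \mathrm{RE}_B\big)$. The
reference ligand has bias 0 by construction, positive values mean bias
toward assay A, and swapping the assays negates every bias factor exactly.

### The seven classical diagnostics

1. **Fixed-$K_d$ transduction ratios** — operational fits with each
   ligand's independently measured $K_d$ held fixed;
   $\mathrm{RE} = \tau_\mathrm{lig}/\tau_\mathrm{ref}$.
2. **Free-$K_d$ composites** — $K_d$ free; only $\tau/K_d$ is carried.
   At $n = 1$ the triple $(r_\mathrm{max}, \tau, K_d)$ trades off along an
   exact ridge: *any* combination reproducing the same plateau and midpoint
   fits identically, so an unconstrained per-curve fit leaves $\tau/K_d$
   arbitrary. The package resolves this the standard way: within each
   panel the system maximum is pinned to the reference agonist's fitted
   $E_\mathrm{max}$. The residual error of that constraint,
   $\log(r_\mathrm{max}/E_m)$, is common to every ligand in the panel and
   cancels exactly in the relative values — which is why the noiseless
   null test recovers zero to $10^{-7}$ rather than wandering by half a
   log unit.
3. **$E_\mathrm{max}/EC_{50}$ ratios** — from 3-parameter logistic fits;
   identical to method 2 when all slopes equal 1 (a warning is attached
   when a fitted slope is further than `slope_warn = 0.3` from 1).
4.–6. **Equi-effective occupancy ratios** — the Stephenson–Furchgott null
   method: equal responses mean equal stimuli, so
   $\varepsilon_t/\varepsilon_r = O_r/O_t$ at equi-effective
   concentrations (obtained by inverting the fitted logistics in closed
   form). The three variants differ only in level choice, which the
   original description leaves open; the package's choices are: method 4,
   a single level at 50% of the smallest fitted maximum in the comparison;
   method 5, ten levels spanning 20–80% of that common range; method 6,
   ten levels spanning 10–90% of each reference/test pair's own overlap —
   the widest usable span per pair, which is the stated intent of an
   "optimized" range. Ratios at multiple levels are combined as geometric
   means, since the estimand is a ratio.
7. **Double-reciprocal slopes** — at equi-effective concentrations
   $1/[L_t]$ is linear in $1/[L_r]$ with slope
   $(\varepsilon/K_d)_t/(\varepsilon/K_d)_r$; the regression uses a free
   intercept and only the slope enters the bias factor. The regression is
   oriented so that the slope is the *test* ligand's relative
   $\varepsilon/K_d$, keeping the sign convention of methods 1–6.

### Significance: the parametric-bootstrap null band

Error-propagation significance tests on bias factors are known to be
anti-conservative, so the only significance machinery provided is a Monte
Carlo band (`monte_carlo_null_band`): every curve's responses are redrawn
from $\mathcal{N}(\text{fitted value}, \text{resp\_sd})$, all bias factors
are recomputed (bootstrap refits are seeded from the original estimates),
and the pooled 2.5th/97.5th percentiles across ligands and replicates form
the no-bias band. Pooling across ligands is the default; per-ligand bands
are available (`per_ligand_band = TRUE`). The procedure is deterministic
given its seed. This bootstrap is this package's construction; it plays the
role of the indeterminacy band that experimental studies of these methods
derive by Monte Carlo.

## The two model-free diagnostics

Both use only *intrinsic activities* — maximal responses as fractions of
the reference full agonist's maximum (`compute_ia`, with a delta-method SD
from the $E_\mathrm{max}$ covariance) — plus the reference agonist's two CR
curves. Because the full agonist's curve sweeps all response levels that
weaker agonists can reach, eliminating concentration between its two fitted
2-parameter logistics (EC50s $c, c'$; slopes $b, b'$) gives the *reference
trajectory*

$$Y'(Y) \;=\; \frac{1}{1 + (c'/c)^{b'}\big(\tfrac{1-Y}{Y}\big)^{b'/b}},$$

a strictly increasing curve from $(0,0)$ to $(1,1)$ on which every
unbiased ligand's IA pair must lie, *whatever* monotone amplification each
pathway applies. Observed IA pairs are projected onto the trajectory under
the anisotropic metric
$d^2(Y) = (Y-\mathrm{IA}_A)^2/\sigma_A^2 + (Y'(Y)-\mathrm{IA}_B)^2/\sigma_B^2$
(inverse-variance weighting of the two axes), by bounded one-dimensional
search over a 512-point bracket plus local refinement; an oracle test
checks the optimizer against a $10^5$-point grid.

**Method 8 (rank order).** System bias cannot reorder unbiased ligands'
IAs, so the projected points' rank pairs trace the identity line. The null
distribution of rank pairs is simulated (default 500 000 iterations;
vectorized, bit-reproducible given the seed) by perturbing the projected
coordinates with uncorrelated Gaussian noise matching each ligand's own
SDs and re-ranking. A ligand is biased when its observed rank pair falls
outside the 95% highest-density region of its position's simulated joint
distribution — cells are accumulated in descending frequency until 0.95 of
the mass is covered, the natural HDR on a discrete lattice. Ties in IA are
broken by stable ligand-id order. The method needs a reasonably large
panel of mostly unbiased ligands; below 6 test ligands it warns.

**Method 9 (trajectory distance).** Applicable to a single test ligand.
The observed point gets an axis-aligned 95% ellipse from its own SDs (the
axes are uncorrelated, matching the perturbation model of method 8); the
projected point gets one from delta-method propagation of the two
2-parameter-logistic covariances through the trajectory formula, read off
along each axis at the projection. The ellipse radius convention is the
2-df chi-square quantile $\sqrt{5.991}\,\sigma$ by default (`ellipse_df =
1` gives the marginal 1.96 convention). A ligand is biased when the two
ellipses are disjoint; disjointness is decided exactly by scaling one
ellipse to the unit circle, minimizing the scaled distance to the other's
boundary, and checking centre containment so nested ellipses count as
overlapping. The verdicts are invariant under swapping the two assays.
Neither model-free method quantifies the *size* of a bias — they are
deliberately categorical.

## The simulator: known truth for every diagnostic

`simulate_panels` generates the negative-control construct the methods must
pass: a panel of agonists with *identical* efficacies in both pathways,
viewed through two different saturating transfer functions
$f(s) = r_\mathrm{max} s^n/(K_E^n + s^n)$. Because occupancy → stimulus →
hyperbola composes to an exact operational curve with $\tau =
\varepsilon/K_E$, the classical methods are well-specified on these data; a
logarithmic transfer (`type = "log"`) is available to emulate the model
misspecification real readouts produce. Injected ligand bias is a
multiplicative efficacy perturbation in pathway B only.

Defaults (the package's canonical study conditions, fixed once):

* 12 ligands — a reference full agonist ($\varepsilon = 1$) plus 11 test
  agonists with $\varepsilon$ log-spaced over 0.05–0.8, echoing a typical
  adrenergic test panel;
* $K_d$ log-spaced over $10^{-6.5}$–$10^{-5.5}$ M; 10 log-spaced
  concentrations, $10^{-10}$–$10^{-3}$ M; 3 replicates;
* both transfers Hill slope 1 with tenfold different amplification
  ($K_E$ 0.03 vs 0.3) and different ceilings ($r_\mathrm{max}$ 1 vs 0.8) —
  pure system bias, with all seven classical methods theoretically exact
  (slope 1 keeps method 3's equivalence intact; the null method and the
  operational fits are exact at any slope);
* replicate noise SD 0.03 on the normalized response, stored truthfully as
  the SD of the mean, $0.03/\sqrt{3}$;
* the injected-bias condition multiplies the strongest test ligand's
  efficacy by 0.1 in pathway B — a 10-fold ratio, i.e. a true bias factor
  of $+1$ log10 unit, moving its IA from ~0.96 to ~0.25 while staying
  measurable.

What the generator does *not* emulate: kinetic distortions
(non-equilibrium reads), receptor internalization, correlated or
heteroscedastic replicate error, and inter-day batch effects. Passing
tests on these panels therefore demonstrate correctness of the estimators
under the theory's own assumptions, not robustness to every experimental
pathology — indeed the known fragility of the operational strategies on
weak, noisy curves (steep-slope least-squares optima with wildly wrong
$\tau/K_d$) appears here too once noise is added.

## Numerical choices

* Optimizer: `minpack.lm::nls.lm`, objective tolerance $10^{-15}$,
  ≥5 heuristic starts (plateau, half-max crossing, slope variations);
  bootstrap refits reuse the original estimates as a single start.
* Bounds: slope $n \in [0.2, 5]$, $\ln\tau \in [-12, 12]$; bound hits are
  reported as warnings, as are EC50s outside the tested range and maxima
  extrapolated beyond the top tested concentration (the poorly determined
  maximum of a low-potency agonist is a known failure mode).
* Monotone-decreasing curves are rejected (antagonist mode unsupported).
* Degenerate inputs: projection requires positive SDs on both axes;
  method 8 refuses `n_mc < 1000`; the band refuses `n_sim < 100`; a
  projection landing at a trajectory endpoint warns (the band is undefined
  there).
* Calibration experiments (false-positive rates at the 95% criterion) are
  run at noise SD 0.08, where IA uncertainty is comparable to IA spacing.
  With much smaller noise the rank lattice degenerates — essentially all
  null mass sits in the identity cell — and the discrete HDR test becomes
  trivially conservative, telling nothing about calibration; problem sizes
  are 12 ligands × 200 repeats with 20 000 rank-MC iterations per repeat.

## A worked example

```{r example, eval = FALSE}
sim <- simulate_panels(sim_config(bias = c(L11 = 0.1)), seed = 1)
rep <- run_all_methods(sim$panel_a, sim$panel_b, sim$kds,
                       bias_config(n_sim = 500, n_mc = 50000), seed = 1)
rep
subset(rep$results, ligand == "L11", c(method, bias_factor, flagged))
```

## Known limitations

* Methods 1–2 inherit the operational model's weak-curve pathology; their
  bias factors for low-IA ligands under noise can be off by log units
  (with correspondingly wide bootstrap bands). This is a property of the
  strategies, faithfully reproduced.
* The rank-order method couples ligands: one strongly biased ligand shifts
  its neighbours' observed ranks by one and can drag them over the
  contour when uncertainties are small.
* Both model-free methods lose power in high-amplification systems where
  all maxima saturate and IA carries little efficacy information.
* The trajectory band is a delta-method approximation; very wide reference
  confidence bands (poorly replicated reference curves) make method 9
  conservative.
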