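---
title: "Modelling light- and nitrogen-limited growth and EPA production of Phaeodactylum tricornutum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling light- and nitrogen-limited growth and EPA production of Phaeodactylum tricornutum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phaeosim)
```

## The model

`phaeosim` simulates photoautotrophic batch and repeated-batch cultures of
the marine diatom *Phaeodactylum tricornutum*, a production organism for
the omega-3 fatty acid EPA. Growth in a photobioreactor (PBR) is limited
by two coupled resources: light, which the culture itself attenuates as it
densifies (self-shading), and nitrogen, which the cells take up from the
medium and store internally. The state of a culture is described by three
variables:

* `X` — biomass concentration (mg DCW L⁻¹),
* `N` — dissolved nitrogen in the medium (mg N L⁻¹),
* `Q` — the intracellular nitrogen quota (mg N per mg DCW),

evolving as

$$\frac{dX}{dt} = (\mu - K_d)\,X, \qquad
  \frac{dQ}{dt} = U - \mu Q, \qquad
  \frac{dN}{dt} = -U X .$$

Growth follows a Droop (cell-quota) description: the specific growth rate
depends on the stored quota, not on the external concentration, so growth
continues for days after the medium is exhausted. The quota factor is
normalized so that it spans exactly 0 at the subsistence quota
$Q_\min$ and 1 at the storage ceiling $Q_\max$, and is multiplied by a
Monod/Hill light response in the culture-averaged intensity
$I_{av}$:

$$\mu = \mu_{\max}\,
   \frac{I_{av}^{\,n}}{K_I^{\,n} + I_{av}^{\,n}}\,
   \frac{1 - Q_\min/Q}{1 - Q_\min/Q_\max}.$$

Nitrogen uptake is Monod in `N` and down-regulated linearly as the quota
fills, $U = U_{\max}\frac{N}{K_N+N}(1 - Q/Q_\max)$, which decouples uptake
from growth (the core Droop assumption) and guarantees
$Q \in [Q_\min, Q_\max]$ whenever the inoculum quota starts inside that
interval. This boundedness, together with the nitrogen balance
$\tfrac{d}{dt}(N + QX) = -K_d Q X$, provides the two structural
invariants the test suite uses as correctness oracles.

### The radiative field

Local intensity decays along the light path by the Beer–Lambert law with
a lumped absorption–scattering coefficient $K_a$ (L mg⁻¹ m⁻¹). Two
geometries are built in:

* **Flat panel** (one illuminated face, path length $L$): the
  culture-averaged intensity has the closed form
  $I_{av} = I_o\,(1-e^{-a})/a$ with optical depth $a = K_a X L$. A series
  branch below $a < 10^{-6}$ avoids the 0/0 at clear culture.
* **Bubble column** (three light banks around a column of radius $R$):
  the average is the cross-section integral of the *sum* of three
  attenuated bank contributions, each along its chord to the illuminated
  side. At zero biomass the integrand is constant and the average equals
  exactly $3 I_o$; the additive form means the three beams superpose
  without saturation. The integral is evaluated with a tensor-product
  rule (Gauss–Legendre radially, periodic midpoint angularly) at 64×128
  nodes, with an automatic doubling check. Because the chord expressions
  lose smoothness where a chord grazes the wall, the rule converges
  algebraically, and the doubling tolerance is set to $10^{-4}$
  (relative, floored at $10^{-3}\times 3I_o$ absolutely so opaque
  cultures with $I_{av}\approx 0$ do not fail a relative test).

Pigment loss under nitrogen starvation couples the optics back to the
quota through the linear correlation $K_a = 2.74\,Q + 0.21$. During ODE
integration of the column geometry, $I_{av}$ is read from a monotone
spline cache over the optical depth $K_a X R$ (220 nodes up to depth
150, power-law tail extrapolation beyond); the cache tracks direct
quadrature to better than 0.5 %, which a test asserts. The flat-panel
geometry uses the exact closed form directly.

### Composition

Fatty acids accumulate under nitrogen starvation. The specific
total-fatty-acid content follows the reciprocal quota law
$C_{TFA} = 3.68\,Q^{-1.32} + 42.2$ (mg g⁻¹ DCW), rising from roughly
100 mg g⁻¹ at full quota to roughly 300 mg g⁻¹ when starved, while the
specific EPA content is treated as the constant 55 mg g⁻¹ DCW. The EPA
fraction of total fatty acids therefore falls from about one half to
about 17 % over a nitrogen-limited batch. No stochastic composition is
modelled (the replicate spread of the EPA measurements, s.d. about
7.7 mg g⁻¹, is not represented).

### Photoperiod and dark-phase choices

Cultures run under a daily light:dark schedule. Growth stops
instantaneously when the light goes off (the cells are assumed not to
grow on internally stored carbon). Two dark-phase behaviours are genuine
modelling choices rather than printed equations, and both default to
*active*:

* **decay** ($K_d$) continues in the dark — it is a property of the
  biomass, not of photosynthesis;
* **nitrogen uptake** continues in the dark — the Droop formulation
  explicitly decouples uptake from growth.

Both are exposed as flags (`dark_decay`, `dark_uptake`) on the
simulators. Light/dark transitions are treated as hard discontinuities:
the adaptive solver (`deSolve::lsoda`, rtol 10⁻⁸ / atol 10⁻¹⁰ by
default) is restarted at every switch instead of relying on step
rejection at the jump. The inoculum quota is taken to be $Q_\max$
(flask inocula are nutrient-replete), and the inoculum biomass is
obtained from the optical density by inverting the cuvette model
`ABS550 = 0.01 · Ka · DCW`. Nitrogen depletion is recorded as the first
crossing below 0.01 mg N L⁻¹ (the crossing is nearly vertical, so the
threshold choice is immaterial at the 10⁻³-day resolution the event is
refined to). The 3 % daily sampling withdrawal performed during the
actual experiments is *not* simulated: it is not part of the model.

## Parameters

The eight kinetic constants default to the calibrated values for the 5 L
flat-panel reference system:

| constant | value | unit | meaning |
|---|---|---|---|
| `mu_max` | 2.4 | d⁻¹ | maximum specific growth rate |
| `K_d` | 0.010 | d⁻¹ | biomass decay rate |
| `Q_min` | 0.034 | mg N mg⁻¹ | subsistence quota (growth stops) |
| `Q_max` | 0.12 | mg N mg⁻¹ | storage ceiling (uptake stops) |
| `U_max` | 0.59 | mg N mg⁻¹ d⁻¹ | maximum uptake rate |
| `K_N` | 0.010 | mg N L⁻¹ | uptake half-saturation |
| `K_I` | 50 | µmol m⁻² s⁻¹ | light half-saturation |
| `n` | 1.9 | — | light-response Hill exponent |

`initial_parameter_guess()` carries the literature-based starting values
(2, 0.01, 0.04, 0.13, 0.5, 0.01, 60, 1.9) used before calibration. The
composition coefficients live in the same container so that a
recalibrated model is a single object.

## Calibration

`fit_parameters()` minimizes a weighted root-mean-square objective over
replicated observations of `X`, `N` and `Q`,

$$\mathrm{NRMSE} = \sqrt{\tfrac{1}{pqm}
  \textstyle\sum_k \sum_j \sum_i w_{k,j} (\hat Y - Y)^2},$$

with weights that deliberately emphasize the late growth phase, where
harvesting happens: biomass residuals are weighted by the day-mean
biomass, quota residuals by the reciprocal day-mean quota, nitrogen
residuals are unweighted. Day means are taken over whichever replicates
are present. Note the weighting makes the objective scale with the
biomass magnitude — it is "normalized" only in the loose sense of the
weighting scheme, and is implemented exactly as defined.

Minimization uses the derivative-free Nelder–Mead simplex
(`stats::optim`), the same family as MATLAB's `fminsearch` used for the
original calibration. Internally the parameters are transformed so every
constraint holds by construction: all constants are fitted in log space,
$Q_\max$ is parameterized as $Q_\min + e^\theta$, and $n$ as
$1 + e^\theta$. A mask (`freeze =`) can exclude any subset — typically
`K_d`, `K_N` and `U_max`, which the sensitivity analysis shows to be
non-identifiable from batch data. The default budget is 50 simplex
iterations with a 1 % relative stopping rule, mirroring the original
procedure (where the objective moved by only 1 % after iteration 35);
serious refits should raise `max_iter` into the hundreds and tighten
`rel_tol`. Because the late-phase weighting creates long curved valleys,
`restarts` rebuilds the simplex around the incumbent with a doubled
spread after each convergence — the incumbent is a vertex, so restarts
never lose ground. With noiseless synthetic data this recovers the four
sensitivity-critical constants ($\mu_{\max}$, $K_I$, $Q_\min$,
$Q_\max$) to well under 10 % from ±30 % perturbed starts in the seeded
cases the suite runs; Nelder–Mead remains a local method, and rare
starting points exist that settle in a secondary basin with a visibly
worse objective (raising `restarts` or re-starting from a second guess
resolves these).

Trajectories are matched to observation days by exact-time dense output
(the solver lands on each sampling day exactly; a guard refuses
interpolation further than 10⁻⁶ days).

## Synthetic observations

`generate_observations()` emulates the experimental design the model was
calibrated on: about ten sampling days between Days 4 and 16, three
biological replicates, and strictly positive observables. Noise is
mean-unbiased multiplicative log-normal, parameterized by the relative
standard deviation on the natural scale; the defaults (5 % for `X` and
`N`, 10 % for `Q`) reflect a replicate spread on the order of 15–20 %
across a batch. Two quota modes mirror practice: `"direct"` perturbs the
simulated quota, `"depletion"` recomputes it from the *noisy* `N` and
`X` through the balance `Q = (N0 − N)/X`, propagating the measurement
chain — such quotas can exceed $Q_\max$ under noise and are flagged, not
clipped, because exactly that excursion is seen in real early-batch
measurements. Noisy nitrogen is capped at `N0` (the medium cannot gain
nitrogen). What the generator does **not** emulate: instrument-specific
error structure, autocorrelated drift, lag phases, contamination or
biofilm losses — so passing recovery tests demonstrate the estimator is
consistent with the model's own error structure, not that every real
data set will calibrate as cleanly.

## Harvest optimization and sensitivity

`harvest_grid_search()` scans repeated-batch strategies: an 8-day batch
(the day on which the reference batch's productivity `DCW(t)/t` peaks),
then `n_cycles = 4` cycles in which a fraction `f` of the broth is
replaced by fresh medium at interval `τ`. The default grid spans
intervals 1–7 d and fractions 10–90 %. Overall productivity is defined
as cumulative harvested biomass plus the standing-biomass gain, per
litre per elapsed day — the natural ledger over the entire run. On the
nitrogen-sufficient 5 L set-up the optimum sits at 60–80 % fractions and
3–5 day intervals, roughly 120–125 mg L⁻¹ d⁻¹, some 40–60 % above an
equal-duration single batch (whose `DCW(T)/T` declines with `T` through
self-shading), with gains beyond the fifth cycle under 2 %. Grid cells
are independent; failures are recorded per cell, never fatal.

`sensitivity_one_at_a_time()` perturbs each constant ±20 % and reports
the relative change of the final biomass and quota per scenario.
Nitrogen-replete conditions are realized as `N ≫ K_N` throughout (15×
f/2 nitrate); nitrogen-limited as the 4× f/2 reference. The reproducible
ranking: `mu_max` and `K_I` dominate everywhere; `Q_max` governs the
quota under replete nitrogen, `Q_min` under limitation; `K_N` and
`U_max` are inert (<0.4 %). One nuance: a ±20 % change of `Q_min` moves
the final biomass by ~0.7 % in our replete runs rather than strictly
<0.4 %, because the light-phase quota equilibrates slightly below
$Q_\max$, where the normalized Droop factor retains a weak $Q_\min$
dependence.

## Numerical choices, problem sizes, limitations

* Integrator `lsoda`, rtol 10⁻⁸/atol 10⁻¹⁰; halving the tolerance moves
  Day-16 biomass by far less than 0.1 % (asserted). States are clamped
  at zero and the quota at its bounds (tolerance 10⁻⁹) inside the
  right-hand side to absorb solver rounding; genuine violations raise.
* Column quadrature 64×128 with doubling check; Monte-Carlo
  cross-checks use 10⁵–10⁶ uniform area samples and a 3-standard-error
  band.
* The packaged simulations are desk-scale: 16-day batches (~800 output
  points), 63-cell harvest grids, five-start recovery experiments on a
  10-day × 3-replicate design — the full suite runs in minutes on one
  core.
* Ties in the harvest grid argmax are reported as a set (`best` holds
  every maximizing row).
* Known limitations: no temperature, pH, salinity or CO₂ effects (held
  constant experimentally and excluded by assumption); no
  photoinhibition (incident intensities stay well below the reported
  tolerance of this species); no surge nitrogen transport above
  $Q_\max$ (deliberately rejected to keep the structure minimal), so
  early-batch quota overshoots are outside the model; attenuation is
  one-dimensional (panel) or in-plane (column) — no vertical gradients,
  wall reflections or bubble optics, which are lumped into $K_a$; no
  uncertainty quantification of the fitted constants.

## Reference set-ups

Three packaged scenarios (`scenario()`, also shipped as editable config
files under `inst/extdata/`) describe the systems the model was built
against: the 5 L flat panel (0.05 m path, 350 µmol m⁻² s⁻¹, 12:12 h,
4× f/2, OD 0.05) and the 50 L three-bank bubble column (radius 0.095 m,
360 µmol m⁻² s⁻¹ per bank, 16:8 h, OD 0.08) in nitrogen-limited (5×
f/2) and nitrogen-sufficient (15× f/2 nitrate) variants. A 1× f/2
medium carries 12.32 mg N L⁻¹ (880 µM nitrate × 14 g mol⁻¹).
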