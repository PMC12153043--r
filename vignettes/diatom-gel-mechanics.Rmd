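---
title: "Gel mechanics and the proliferation of entrapped diatoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gel mechanics and the proliferation of entrapped diatoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diatomech)
library(dplyr)
```

## The problem

Diatoms are unicellular algae enclosed in a rigid silica shell (the
frustule). When a diatom is physically entrapped in an agar hydrogel, every
division cycle forces the cell to expand laterally against the gel -- once
during cytokinesis and once more when the new silica valves are exocytosed.
Whether division succeeds, how long it takes, and how large the resulting
colony grows all depend on the mechanical resistance of the gel.

`diatomech` implements the quantitative chain that connects gel mechanics to
cell proliferation:

1. **Indentation mechanics** -- extract the instantaneous modulus
   $E^*_0$, the relaxation timescales $\tau_1, \tau_2$, and the residual
   (long-time) modulus $E^*_\infty$ from spherical-indenter load-and-hold
   curves, and their power-law scaling with agar concentration $\phi$.
2. **Particle tracking velocimetry (PTV)** -- measure the displacement and
   strain fields the dividing cell imposes on the gel, from fluorescent
   tracer-bead image stacks.
3. **Growth model** -- a force balance: division proceeds when the cell's
   turgor pressure exceeds the cavitation threshold of the gel,
   $P_c \approx E^*_\infty$, plus two-regime phenomenological laws for
   division time, expansion and viability versus $\phi$.
4. **Colony statistics** -- cultivation summaries (living fraction, cells
   per colony, normalised size, histograms) and the two-regime piecewise
   regression.
5. **Synthetic data** -- generators for all three input modalities with
   exact ground truth, so the entire pipeline is testable end to end
   without any measured data.

## Indentation: Hertz loading and double-exponential relaxation

A rigid sphere of radius $R$ (default 1.565 mm) is driven into the gel at
constant rate (0.01 mm/s) to depth $d_{max}$ (1 mm), then held for 3600 s.
The loading segment follows Hertz's law,

$$F = \tfrac{4}{3}\, E^*_0\, \sqrt{R}\, d^{3/2},$$

which `fit_initial_modulus()` fits linearly in $d^{3/2}$ through the
origin. $E^*$ is reported as the effective contact modulus with no
Poisson-ratio correction -- it is what the test measures; any fixed
elastic-constant convention multiplies all moduli equally and cancels in
the pressure comparison that the growth model makes.

The hold segment relaxes as a double exponential,

$$F(t) = F_\infty + F_1 e^{-t/\tau_1} + F_2 e^{-t/\tau_2},$$

an empirical description of the gel's viscoelastic/poroelastic response
(no poroelastic constitutive model is attempted). Two-exponential fitting
is notoriously multimodal, so `fit_relaxation()` screens a $4 \times 4$
log-spaced grid of $(\tau_1, \tau_2)$ starts over $10$--$10^4$ s by
solving the amplitudes linearly (variable projection), then polishes the
best candidates with Levenberg--Marquardt; timescales are returned in
canonical order $\tau_1 < \tau_2$. The first second of the hold is
discarded to avoid the ramp-stop transient. The residual modulus inverts
Hertz at the hold depth: $E^*_\infty = 3 F_\infty / (4\sqrt{R}\,
d_{max}^{3/2})$.

```{r indentation}
crv <- sim_indentation_curve(E0_star = 100, Einf_star = 30,
                             cfg = sim_config(1, noise_sd_force = 0))
rf <- fit_relaxation(crv)
tidy(rf)
c(E0 = fit_initial_modulus(crv), Einf = residual_modulus(rf))
```

Moduli scale with agar concentration as $E = a\,\phi^b$;
`fit_power_law()` estimates $(a, b)$ by log--log OLS. Typical agarose
exponents fall in 1.5--2.2, and the printed endpoint pair
(10 kPa at 1%, 416 kPa at 7%) implies $b = \ln 41.6 / \ln 7 \approx 1.92$.

## PTV: from bead images to strain maps

`detect_particles()` finds local intensity maxima above a relative
threshold, merges candidates closer than `min_separation` (brighter one
wins), discards spots whose centroid window would clip the image border
(a truncated point-spread function biases the centroid), and refines the
survivors by intensity-weighted centroiding -- accurate to ~0.01 px on
isolated spots. `link_trajectories()` connects detections frame to frame
by exact minimum-cost assignment (a Hungarian solver run per connected
component of the distance-gated candidate graph; staying unmatched costs
`max_disp`$^2$), with a greedy fallback for very dense data. No gap
closing: a broken track terminates.

Displacement analyses follow the experiment's conventions:

* `normalized_displacement_curve()` keeps the 5% of tracks with the
  longest start-to-end displacement, normalises each by its own total and
  averages -- the "expansion clock" whose slope is the displacement rate
  (a 60-minute linear expansion reads back ~1.67 %/min).
* `displacement_vs_distance()` measures radial distance from the cell
  wall: half the initial cell height at the centre is distance zero.
* `strain_map()` fits, at every node of a regular grid, the local affine
  model $u(x) \approx c + A\,(x - x_{node})$ by weighted least squares
  over neighbours within `window_radius` (Gaussian weights,
  $\sigma =$ `window_radius`/2), and reports the deformation gradient $A$
  and the infinitesimal strain $\varepsilon = (A + A^T)/2$. Nodes with
  fewer than `min_support` neighbours or a rank-deficient neighbourhood
  are flagged invalid, never interpolated. One robustness pass drops
  neighbours with residuals beyond 4x the scaled MAD and refits, which
  suppresses occasional gross outliers without touching smooth fields
  (exactly affine fields are reproduced exactly). A Green--Lagrange
  option ($\varepsilon + A^T A/2$) is available because strains near the
  cell wall (~20--30%) strain the infinitesimal assumption.

Defaults -- grid 10 um, window 25 um, `min_support` 6 -- are reported
alongside outputs; the experimental reference does not state its gridding.

### The synthetic ground truth

The generator advects beads with an incompressible expanding-sphere
field: a material point at radius $r$ maps to
$r' = (r^3 + a_1^3 - a_0^3)^{1/3}$, so volume is conserved exactly and
the radial strain has the closed form
$\partial u_r/\partial r = r^2 (r^3 + a_1^3 - a_0^3)^{-2/3} - 1$
(compressive everywhere, with tensile hoop strain $u_r/r$). This field
was chosen precisely because it gives the whole
render-detect-link-strain chain an analytic oracle. Around an inclusion
expanding along $x$, the map shows compression along the growth axis and
tension at the poles -- the qualitative signature seen around dividing
cells.

Rendering uses a 2D Gaussian point-spread function (sd 1.2 px), 16-bit
quantisation, constant background and Gaussian read noise, on the
confocal geometry of 512 x 512 px over 500 um. Beads are seeded
uniformly outside the inclusion with a minimum separation of 8 um --
twice the detector's merge radius -- because the detection model presumes
resolvable tracers; the fidelity oracle uses a seeding density of
0.008 um^-2 ("dense" regime, ~1900 beads). The generator does not
attempt photorealism: no z-extent, no autofluorescent cell body, no
bleaching, no oscillatory ("pulsating") expansion modes. Passing the
oracle therefore demonstrates the correctness of the measurement chain
on resolvable tracers, not robustness to every imaging pathology of real
confocal data.

Strain-map accuracy is validated on nodes whose fit window lies entirely
inside the bead-populated annulus ($r \gtrsim 90$ um for the 50 to 60 um
cavity): closer to the wall the neighbourhood is one-sided and any local
affine fit is biased by field curvature; those nodes are still reported,
with their support counts, but are not oracle-graded.

## The growth model

The cavitation criterion for a pressurised hole in a soft solid says the
hole grows without bound once its pressure exceeds $P_c \approx E^*$,
with an order-unity prefactor (configurable, default 1). Applied here:
a diatom can divide at concentration $\phi$ iff its turgor pressure
exceeds $E^*_\infty(\phi)$. The residual modulus law is calibrated as
$E^*_\infty = a\,\phi^{1.9}$ with $a$ pinned so that
$E^*_\infty(10\%) = 120$ kPa -- the concentration at which division
ceases, hence 120 kPa is the inferred maximum turgor pressure. (The
experimental power-law coefficients are embedded in figures, so these
defaults are calibrated rather than transcribed.) At ~10 kPa/m of
hydrostatic gradient, a 120 kPa turgor corresponds to the ~10 m euphotic
zone depth.

The phenomenological laws are two-regime in $\phi$ with a breakpoint at
2%:

* **Division time**: 7.5 h plateau for $\phi \le 2$; linear through
  (2%, 8 h)--(7%, 20 h) above; no division at $\phi \ge 10$. Both printed
  values at the breakpoint (7.5 h plateau, 8 h anchor) are honoured,
  which leaves a small deliberate jump there.
* **Expansion** $\Delta l / l_0$: plateau 0.39 (midpoint of the observed
  40--38%); linear through (2%, 0.37)--(7%, 0.09), clamped at zero (the
  line crosses zero near 8.6%, and the model returns 0 from there on, in
  particular at 10%).
* **Viability**: cumulative fractions of the starting population
  completing the three transitions, interpolated piecewise-linearly
  through (1%: 0.89/0.44/0.29), (7%: 0.25/0/0), (10%: 0/0/0). The
  cumulative (not conditional) reading follows the way the fractions
  decline through one cohort; conditional probabilities are derivable by
  division and are what the event simulator draws sequentially.

```{r growth}
growth_model_summary(c(0.5, 2, 4.5, 7, 10))
```

## Colony simulator and its calibration

`sim_colony_series()` models each founder cell as a colony that grows by
a birth process (waiting time to the next division scales inversely with
the current cell count, lognormal with median `division_time(phi)`),
saturates at a per-colony carrying capacity, and dies as a whole with a
constant hazard. Calibrations -- stated once, used everywhere:

* **Death hazard** $\lambda(\phi) = -\ln L_{21}/21$ from the day-21
  living fractions $L_{21}$ = 0.80 (0.5%) and 0.16 (3.5%), interpolated
  linearly in $\phi$ and clamped outside the anchors.
* **Carrying capacity**: lognormal; the meanlog is solved numerically so
  that the mean realized colony size equals 18 cells (0.5%) and 6 cells
  (3.5%); the shape grows from 0.45 to 0.8 across that range, which
  reproduces both the observed histogram modes (10--20 cells in soft
  gels, 1--5 at 3.5%) and the higher relative variance in stiff gels.
* **Viability**: the founder cell fluoresces as long as the colony lives
  (the alive criterion is "at least one fluorescing cell"), and the
  remaining cells are Bernoulli with a size-dependent probability chosen
  so the aggregate viable-cell fraction is 0.78 independent of $\phi$.
* **Colony size**: $l/l_0 = n^{p(\phi)}$ with the packing exponent
  linear through (0.5%, 0.99)--(3.5%, 0.59) and clamped to $[1/3, 1]$ --
  chain-like growth in soft gels, towards the compact-sphere limit in
  stiff ones. The anchors reproduce the printed size gains (17.5x and
  2.9x).

Because the growth clock is the single-division timescale, simulated
colonies saturate within days; the simulator is faithful to the day-21
statistics it is calibrated on, not to the multi-day approach curves of
real cultivation data. Statistics are computed on the record's native
day grid over living colonies only (dead colonies freeze at their last
size and are excluded from averages -- the cultivation reference does
not state its handling, and this choice is flagged in the function
documentation).

```{r colonies}
p <- growth_params()
rec <- sim_colony_series(p, phi = 0.5, n_colonies = 2000,
                         t_grid = c(0, 7, 14, 21), cfg = sim_config(1))
c(living = living_fraction(rec, 21),
  cells = mean_cells_per_colony(rec, 21)$mean_cells,
  viable = viable_cell_fraction(rec, 21))
```

## Two-regime regression

`two_regime_fit()` splits the data at a fixed breakpoint (default 2%),
assigns the boundary point to both segments (matching the "0--2%" and
"2--7%" ranges), and fits each segment by OLS with a two-sided t-test of
zero slope on $n - 2$ degrees of freedom. An exactly flat noise-free
segment reports $p = 1$ by convention (there is no slope to test); an
exactly linear one underflows to $p = 0$. No multiple-testing correction
is applied, as none is described for the original analysis.

## Numerical choices and degenerate inputs

* All generators draw from seeded sub-streams (`sim_config(seed)` plus a
  fixed offset per generator), so a fixed seed gives byte-identical
  output and the generators do not perturb one another.
* `cavity_displacement()` rejects points inside the initial inclusion --
  they have no material image.
* A blank frame detects zero particles (not an error); an all-zero
  displacement set normalises to a zero curve (not NaN).
* `can_divide()` treats $P = P_c$ as *not* dividing, with a relative
  floating-point tolerance so that calibrated equalities (120 kPa at 10%)
  resolve deterministically.
* Problem sizes used by the test-suite fidelity checks: 20 noisy curves
  for relaxation recovery, 50 series for exponent recovery, one
  20-frame 512 x 512 stack with ~1900 beads for the PTV oracle, and
  10^4 colonies per concentration for the cultivation statistics --
  large enough that three Monte-Carlo standard errors sit well inside
  each calibration anchor's precision.

## Known limitations

* The Hertz prefactor convention is fixed but arbitrary up to the hidden
  elastic-constant convention of the reference instrument; moduli match
  external values only up to that fixed multiplicative choice.
* Strain maps are 2D in-plane; no z-resolved tracking, no drift
  correction beyond optional mean subtraction, no traction (stress)
  inversion.
* The cell-cycle laws are phenomenological interpolations of printed
  anchors, not mechanistic cell biology; between anchors they are
  exactly linear by construction.
* The colony simulator's early-time kinetics are faster than real
  colonies (see above); only day-21 statistics are calibrated.
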