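---
title: "Modelling lysis inhibition: batch, competition and plaque dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling lysis inhibition: batch, competition and plaque dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linsim)
```

## The biology being modelled

T-even-like phages respond to secondary adsorption of an already
infected host by *lysis inhibition* (LIN): lysis is postponed and the
eventual burst is larger. Rapid-lysis (*r*) mutants lack this response.
Secondary adsorptions are informative — they happen when free phage
outnumber uninfected hosts — so LIN acts as a conditional switch from
"spread fast" to "milk the current host". This package implements
deterministic population models of that switch, in well-mixed batch
culture and in a diffusion-limited soft-agar lawn, plus an exact
stochastic counterpart used for validation.

## Shared physiology

Host growth follows Monod kinetics, $g(n) = g_{\max} n/(K_n + n)$, and
one unit of nutrient makes one cell, so nutrient is counted in
cell-equivalents and $\dot n = -g(n)B$. Phage parameters degrade with
host physiology:

$$\beta(n) = \beta_0\Big(r_b + (1-r_b)\frac{g(n)}{g(n_0)}\Big),\qquad
  \tau(n) = \tau_0\Big/\Big(r_l + (1-r_l)\frac{g(n)}{g(n_0)}\Big),$$

normalized at the initial nutrient $n_0$. The latent period is an
Erlang chain: $N$ sub-states traversed at rate $N/\tau(n)$ each, giving
mean $\tau(n)$ and relative standard deviation $1/\sqrt N$.

Two conventions deserve explicit statement because the symbols are used
inconsistently in the literature:

* **$\tau_0$ is the total minimum latency** (20 min by default), never
  a per-sub-state time. Per-sub-state quantities are always derived as
  $\tau/N$. With $f_\tau = 5$ a cell infected around 2 h lyses around
  4 h, which is the behaviour a 5-fold extension of a 20-min latency
  should produce.
* **The LIN chain advances at $N/(f_\tau\,\tau(n))$ per sub-state**, so
  that its *total* latency is $f_\tau\,\tau(n)$ — the fold factor
  stretches the whole chain uniformly rather than each sub-state by
  $f_\tau N$.

All latency dependence is computed in *rate* form,
$k(n) = \frac{N}{f_\tau \tau_0}\big(r_l + (1-r_l)g(n)/g(n_0)\big)$, so
the starvation limit $r_l = 0,\ n = 0$ gives $k = 0$ exactly (arrest)
instead of a division by zero.

## Batch models

`M0` (r-mutant), `M1` (LIN phage) and `MC1` (both strains) are
mass-action ODE systems over $B$, $n$, free phage $R$ and/or $P$, the
staged infected chains $I^R_i$, $I^P_i$ and the LIN chain $L_i$. The
structural assumptions:

* infection is Lotka–Volterra: $\eta\,\Phi\,B$ with adsorption constant
  $\eta$;
* **every** cell class adsorbs free phage ($-\eta\Phi B_{tot}$): a
  phage landing on an infected or LIN-state cell is inactivated, which
  is the mechanism behind the competitive sink;
* the first infection fixes the progeny strain (superinfection
  exclusion); a single secondary adsorption moves a P-infected cell
  into $L_1$; further adsorptions change nothing;
* `trigger_mode` selects which strains trigger LIN on a P-infected
  cell: `"any_phage"` (default), `"lin_phage_only"` (some r-mutants
  cannot trigger LIN), or `"none"` (a diagnostic switch that disables
  the transition entirely, under which M1 with $f_\tau = f_\beta = 1$
  reduces exactly to M0 — used as a regression test).

Default parameters: $g_{\max} = 0.034$/min (20-min doubling),
$K_n = n_0/5$, $\eta = 5\times10^{-10}$ mL/min, $\tau_0 = 20$ min,
$\beta_0 = 150$, $r_l = 0.5$, $r_b = 0.1$, $N = 10$, $B_0 = 10^6$/mL,
phage $10^3$/mL, $n_0 = 10^9$/mL (the culture saturates at
$10^9$ cells/mL). In `MC1` the initial inoculum is split equally,
$R_0 = P_0 = 10^3$/mL. "Overnight" outcomes are read at exactly
1200 min.

Integration uses `deSolve::lsoda` (stiff-capable, adaptive) with
`rtol = 1e-8`, `atol = 1e-6` per mL, sampled every minute. Sampled
values in $[-\mathrm{atol}, 0)$ are clipped to zero. Because lsoda's
per-component error weight is $\mathrm{rtol}|y| + \mathrm{atol}$,
transient overshoot slightly beyond atol can occur near the sharp
collapse of $B$; the run is aborted only below
$-1000\cdot\mathrm{atol}$, which in these units is still $10^{-3}$ of a
single cell per mL.

Summary statistics: the final free-phage ratio $P/R$ (an
infinite-ratio marker when $R$ hits zero), the relative decline of free
$R$ from its global sampled maximum (ties broken by earliest time), and
the phage–host crossing time, found by linear interpolation of
$(R + P) - B$ between samples. Ratio sweeps over $(f_\tau, f_\beta)$
return $\log_{10}$ matrices and the ratio-one contour interpolated by
`grDevices::contourLines`.

## Plaque models

`MP0`/`MP1` are the same reaction terms on a radially symmetric domain,
with densities integrated over the soft-agar thickness
$\Delta a = 500$ µm and therefore expressed per µm². Only free phage
($D_p = 240$ µm²/min) and nutrient ($D_n = 5\times10^4$ µm²/min)
diffuse; bacteria are immobile. Unit conversions follow from
1 mL $= 10^{12}$ µm³: the per-area adsorption constant is
$\eta \cdot 10^{12}/\Delta a = 1$ µm²/min, and the per-area lawn
($B_0 = 1/400$ µm⁻², $n_0 = 0.5$ µm⁻², $k_n = n_0/5$) corresponds to
volumetric $5\times10^6$ cells/mL and $10^9$ nutrient/mL. With
$r_l = 0$ the latent period diverges as the nutrient runs out, which is
what arrests plaque expansion; $\beta(n)$ is evaluated at the moment of
lysis with the local instantaneous nutrient.

**Discretization.** A conservative finite-volume scheme on annuli with
centers at $(j-\tfrac12)\,dr$: face flux $-D\,2\pi r\,\partial_r u$,
zero flux at the origin (symmetry) and at $R_{\max}$ (reflecting). The
scheme conserves mass to machine precision and never evaluates the
$1/r$ singularity. Free spreading of a Gaussian matches the 2-D heat
kernel to better than 2% at $dr = 20$ µm.

**Grid and domain** are a package choice (they are not physical
parameters): $dr = 20$ µm resolves the phage diffusion length per stage,
$\sqrt{4 D_p \tau_0 / N} \approx 44$ µm; $R_{\max} = 10\,000$ µm
contains the arrested plaque (final fronts sit near 1.2–1.3 mm) with a
wide margin so the reflecting boundary is inert; $t_{end} = 400$ min
extends comfortably past the arrest. Halving $dr$ moves the final
plaque radius by well under 2%.

The seed is a discrete Dirac delta: stage-1 infected density $1/A_1$ in
the innermost annulus — exactly one infected bacterium in the domain.
Stochastic nucleation is deliberately out of scope; the model is
deterministic throughout.

The resulting ODE system (13 species × 500 cells for MP0, 23 × 500 for
MP1) is integrated by `deSolve::ode.1D` with the banded-Jacobian lsoda
(`rtol = 1e-6`, `atol = 1e-12` µm⁻²), sampling every 10 min.

## Front metrics

Four radii summarize a snapshot, each located as the **outermost** sign
change of its defining difference, scanned from the boundary inward and
interpolated linearly between cell centers (robust to the double-peaked
phage profile of a LIN plaque):

* $r_{PB0}$: phage density $= B_0$ (one phage per microcolony; the
  furthest reach of likely infection);
* $r_{super}$: phage $=$ total bacteria; inside it secondary
  adsorptions dominate;
* $r_{half}$: total bacteria $=$ half its value in the outermost cell —
  the visible plaque;
* $r_{ZOI}$: uninfected bacteria $=$ half its edge value — the zone of
  infection.

The half-value references come from the outermost cell of the *same*
snapshot, so lawn growth over time cancels automatically. A metric with
no crossing is reported as `NA` ("absent"), distinct from zero, and
absent cells are excluded from ratio sweeps. The 50% threshold is a
convention for "visibly clear"; `front_radii(..., half_fraction =)`
exposes it because a plate could require a deeper drop to look clear,
which would make LIN plaques appear smaller still.

## Stochastic oracle

`simulate_events()` is a direct-method Gillespie implementation of the
same reaction network with integer counts in a volume $V$: bimolecular
propensities scale as $\eta/V$, the nutrient is an integer pool of
cell-equivalents (exact conservation), and real-valued bursts are
rounded stochastically (floor + Bernoulli remainder) so the mean burst
is exact. It validates, independently of the ODE path: the Erlang
latency distribution (mean $f_\tau \tau$, SD $\tau/\sqrt N$ from
single-cell replicates), exact adsorption/release bookkeeping, and the
ODE trajectories themselves. The ODE equals the *large-volume limit* of
the stochastic process; at a few hundred individuals, demographic
correlations shift the means by $O(1/\text{size})$ (visibly so during
the early LIN influx), so the mean-agreement validation is run at
$10^3$ cells where that bias is well inside the Monte-Carlo error of a
few dozen replicates.

## What the defaults do and do not emulate

The default parameter set reproduces a standard laboratory setup: rich
batch culture saturating at $10^9$ cells/mL, a T4-like phage
($\beta_0 = 150$, 20-min latency, $\eta = 5\times10^{-10}$ mL/min), and
a plaque assay in 0.5-mm soft agar. Passing tests therefore say the
*models* behave as intended under those conditions. They do not capture
several features of real plates: discrete microcolonies and their
protective geometry, stochastic infection at low phage density (all
fronts here are deterministic), LIN collapse after prolonged
superinfection, the dependence of the delay on the number and timing of
secondary adsorptions, or pushed-wave behaviour when phage diffusion is
severely hindered. Within the deterministic treatment, absolute front
radii depend mildly on the (unreported) grid and domain conventions;
ratios between strains are the robust quantities.

## Problem sizes in the test suite

The tests run the full default batch models (1200 min), the default
plaque models to 400 min on the 500-cell grid, a 3×3 plateau sweep
reusing a single MP0 reference, grid-refinement and model-reduction
checks on smaller domains (2–3 mm, 150 min), and stochastic validation
with 400–1500 single-cell replicates and 16 trajectory replicates of a
1000-cell culture. Expensive simulations are computed once and shared
across test files.

## Known limitations

* Secondary adsorption counts are not tracked beyond the first; the
  model cannot express adsorption-number-dependent delays.
* Infected cells do not consume nutrient (only dividing cells do),
  a literal reading of the growth bookkeeping.
* The plaque model is strictly radially symmetric; plaque–plaque
  interference is out of scope.
* The final-phage-ratio statistics count free phage only; intracellular
  genomes in unlysed LIN cells are not credited to either strain.
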