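---
title: "An eco-evolutionary model of plankton cell-size diversity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An eco-evolutionary model of plankton cell-size diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(evoplankton)
```

`evoplankton` simulates the assembly and evolution of phytoplankton
cell-size diversity in a seasonally forced water column. Two competing
paradigms can be compared within the same machinery: *species sorting*
("everything is everywhere, but the environment selects"), in which a
randomly seeded pool of fixed-trait species is pruned by competition; and
*adaptive dynamics*, in which the surviving species' cell volumes evolve by
repeated mutant-invasion trials. This vignette is the package's own account
of the model, its assumptions, its numerical choices, and what its tests do
and do not establish.

## The ecological model

### Droop physiology

Phytoplankton growth follows the variable-internal-stores (Droop) model:
population growth is decoupled from the external nutrient and driven by the
internal nitrogen-to-carbon quota $Q$,

$$\frac{dQ}{dt} =
 \underbrace{V_{\max}\,\frac{Q_{\max}-Q}{Q_{\max}-Q_{\min}}\,\frac{N}{N+K_N}}_{\text{uptake}}
 \;-\;
 \underbrace{\mu_{\max}\,\gamma_T\,\gamma_I\,\frac{Q-Q_{\min}}{Q_{\max}-Q_{\min}}}_{\text{growth}}\,Q .$$

Uptake shuts down at a full quota or zero nutrient; growth shuts down at an
empty quota. $\gamma_T$ is an Eppley exponential temperature factor
(coefficient 0.0633 per degree, normalized to 1 at 10 degC) and $\gamma_I = 1 -
e^{-I/I_s}$ a saturating light factor ($I_s = 25$ W m$^{-2}$); both are
configuration data. Three nitrogen forms are resolved (NO3, NO2, NH4) with
Michaelis-Menten uptake per form, ammonium inhibition of oxidized-nitrogen
uptake ($e^{-\psi\,\mathrm{NH4}}$, $\psi = 1.5$ m$^3$ mmol$^{-1}$), and the
structural rule that Prochlorococcus cannot use nitrate at all.

### The critical nutrient concentration N\*

At the grazer-free equilibrium with mortality $m$, the quota settles at
$Q^* = (Q_{\max}-Q_{\min})\,m/\mu_{\max} + Q_{\min}$ and the nutrient at

$$N^* = \frac{K_N\,\mu_{\max}\,(Q^*-Q_{\min})\,Q^*}
             {V_{\max}(Q_{\max}-Q^*) - \mu_{\max}(Q^*-Q_{\min})\,Q^*},$$

the Droop analogue of Tilman's $R^*$: the lowest nutrient concentration at
which the species persists. `critical_nutrient()` implements the closed
form; the test suite verifies it against an independent numerical
steady-state of the 0-D Droop ODE system (deSolve) to better than $10^{-6}$
relative error for randomized admissible trait sets. $N^*$ is computed at
$\gamma_T = \gamma_I = 1$; the light and temperature limitation removed from
the calculation is assumed negligible when $N^*$ is compared with ambient
nutrient levels. Under the default allometric scalings $N^*$ increases with
cell volume in every functional type, so pure bottom-up competition selects
the smallest cells.

### Allometry and functional types

Every physiological trait is a deterministic power law of cell volume,
$\log_{10} x = a + b \log_{10} V$. The numeric $(a, b)$ pairs are *not* part
of the model structure; they are configuration data shipped in
`inst/extdata/default_params.yaml` and fully overridable. The defaults are
assembled from the published size-scaling literature (Litchman et al. 2007
for uptake, half-saturation and quota exponents; Menden-Deuer & Lessard 2000
for carbon per cell) with per-biomass exponents obtained by dividing
per-cell scalings by per-cell carbon: $V_{\max} \propto V^{-0.27}$,
$K_N \propto V^{0.33}$, $Q_{\min}, Q_{\max} \propto V^{-0.07}$. The four
functional types -- Prochlorococcus, Synechococcus, small eukaryotes,
diatoms -- differ in their volume ranges (tiling $0.1$ to $10^7$ um$^3$ with
overlaps), in the intercept of $\mu_{\max}$ (0.8, 1.0, 1.25, 1.6 d$^{-1}$ at
1 um$^3$), and in nitrate capability. No claim is made that these defaults
reproduce any particular published curve exactly; they reproduce the
qualitative structure that matters (the $N^*$ ordering and the size ordering
of the types).

### Grazing

Nine zooplankton species with log-spaced body volumes ($10^2$ to $10^{10}$
um$^3$) graze with a log-normal prey-size kernel, peak-normalized to 1 at
the optimal predator-to-prey volume ratio $\rho_{\mathrm{opt}} = 1000$ with
width $\sigma = 0.6$ (ln-volume units). The kernel peaks therefore tile the
whole phytoplankton range (optimal prey volumes $10^{-1}$ to $10^7$ um$^3$),
producing the log-periodic grazing background with *grazing refuges* (local
minima of summed, biomass-weighted grazing pressure) that drives the whole
story: evolved residents end up in refuge basins. The functional response is
Holling type 3 on palatability-weighted available biomass $A$: total
ingestion $I_{\max} Z\, A^2 / (A^2 + k_A^2)$, apportioned over prey by their
share of $A$. Zooplankton eat phytoplankton and smaller zooplankton
(intra-guild predation); their traits never evolve. Assimilated food grows
the grazer at fixed N:C quota (0.15), excess carbon is respired, excess
nitrogen excreted as ammonium, and the unassimilated fraction (30%) becomes
detritus.

Peak normalization (value 1 at the optimum) rather than integral
normalization was chosen for the kernel so that the palatability of the
optimal prey is comparable across grazers of different sizes; the grazing
half-saturation `k_A` (0.5 mmol C m$^{-3}$) is one global constant.

### Compartments and the equation count

Every plankton species -- phytoplankton *and* zooplankton -- carries a
uniform block of three tracers: carbon biomass, nitrogen biomass, and
chlorophyll (the chlorophyll slot is inert and identically zero for
grazers, a uniform tracer layout in the style of large ocean models). Eight
shared compartments complete the state: four dissolved pools (NO3, NO2,
NH4, DIC) and four detritus pools (DOC, DON, POC, PON). One location
therefore integrates $3(n_P + n_Z) + 8$ coupled equations --- 59 at 8
phytoplankton and 9 zooplankton species, 275 at 80
(`count_state_equations()`). Detritus remineralizes to NH4 (nitrogen) and
DIC (carbon) at pool-specific rates; nitrification runs NH4 to NO2 to NO3.
Chlorophyll follows a simple photoacclimation rule: it is produced with new
growth at a light-dependent target chl:C ratio (more pigment at depth) and
lost proportionally with biomass, and it feeds back on the light field
through self-shading. Both the nitrogen budget (dissolved + detrital +
biomass) and the carbon budget (DIC + detrital + biomass) are closed by
construction; the nitrogen closure is asserted to near machine precision in
the tests.

## The water column

A 3275-m column with 35 geometrically stretched levels (finest at the
surface, where the euphotic zone is; the stretch ratio 1.1 gives a ~12-m
surface layer). The seasonal forcing emulates a high-latitude (Norwegian
Sea-like) regime with annual periodicity and a 365-day calendar: surface
irradiance 2-200 W m$^{-2}$ with its minimum on January 1; surface
temperature 4-12 degC decaying to 2 degC at depth; and a mixed-layer depth
that deepens to 600 m in the December-March convection season and shoals to
30 m in summer. The mixed layer maps to a vertical diffusivity profile
($10^4$ m$^2$ d$^{-1}$ inside, 0.9 m$^2$ d$^{-1}$ background). Only the
seasonal phenomenology of the real forcing (winter mixing + winter darkness,
summer stratification, spring bloom, grazer-dominated post-bloom) is
emulated; no attempt is made to reproduce observed profiles point-for-point.

Numerics are operator-split per biological time step (`dt_bio = 0.05` d,
safely resolving the fastest default rates): forward-Euler biology, then
implicit (backward-Euler, unconditionally stable, exactly conservative)
vertical diffusion with daily re-evaluated coefficients, then first-order
upwind sinking (phytoplankton at their allometric speed, particulate
detritus at 10 m d$^{-1}$) with automatic CFL sub-stepping and a closed
bottom boundary, so the column budgets are closed. After each step the state
is repaired and every repair logged in an audit: negatives are clipped,
quotas clamped to $[Q_{\min}, Q_{\max}]$, and every actively cycling
species is floored at $10^{-15}$ mmol C m$^{-3}$ per level -- a
quasi-extinction floor that mimics immigration from surrounding waters and
keeps every strategy available for re-invasion. The floor is applied to
both guilds (grazers would otherwise decay to subnormal floating-point
values during their prey's absence). The conservation tests assert that
total nitrogen *net of the logged repairs* drifts less than $10^{-8}$
relative over a simulated decade.

## The evolutionary engine

Cell volume is the single evolving trait. Every third year, on the first
day of the model year (so that fitness integrates exactly one full seasonal
cycle), each resident spawns two mutants at $\pm 10\%$ of its cell volume
(mutants falling outside the functional type's range are not generated).
Mutants are *passive tracers*: their initial biomass, quota and chlorophyll
profiles are the resident's profiles scaled by $10^{-6}$ (the scale cancels
in the fitness ratio), they experience nutrients, light and grazer
saturation, but contribute nothing to any shared pool. The implementation
honours this contract bit-for-bit: integrating a year with or without
mutants present leaves every resident, nutrient and grazer field exactly
identical, which the test suite asserts by binary comparison.

Invasion fitness is the log annual biomass ratio
$s = \log B(t+1\,\mathrm{yr})/B(t)$, $B$ column-integrated. Because the
system is never exactly on its attractor, mutant fitnesses are compared
against the *resident's* realized annual rate rather than zero: selection is
directional when exactly one mutant beats the resident, stabilizing when
neither does, disruptive when both do. Directional winners replace their
resident by *attractor inheritance*: the new trait (and all its allometric
consequences) is written onto the old population in place, depth profiles
untouched. Two relaxation years follow before the next mutant cohort --- a
3-year cycle. Disruptive outcomes do not split lineages (branching is
deliberately out of scope); the fitter mutant wins and the event is
flagged in the log. Exact fitness ties count as stabilizing, since
replacement requires strict improvement. All residents' mutants are
evaluated simultaneously in one shared trial year; as passive tracers they
cannot interact, so simultaneous and sequential evaluation are equivalent
up to round-off, and one shared year is three times cheaper.

`classify_singularity()` runs one extra trial on the attractor: stabilizing
selection marks a CSS (continuously stable strategy, a fitness maximum
reached by convergence), disruptive marks an EBP (branching point). At the
evolutionary endpoint the trait trajectory of a CSS resident is not
constant but flip-flops by one mutation step, giving the characteristic
6-year (two-cycle) oscillation superimposed on the annual forcing --- an
artifact of the fixed step size, reproduced by the scaled protocol test.

## Diagnostics

Community structure lives on a fixed grid of 100 log-uniform cell-volume
classes spanning $0.1$ to $10^7$ um$^3$ (stored with every output so
distances are reproducible). On it:

* **Richness** counts species whose column-integrated biomass exceeds the
  quasi-extinction threshold of $10^{-3}$ mmol C m$^{-2}$.
* **Evenness** is Pielou's form $-\sum p_i \ln p_i / \ln N \in [0, 1]$,
  with $0\ln 0 = 0$. (The raw Shannon sum $\sum p_i \log p_i$ is negative;
  the sign convention here makes "high" mean "evenly spread", which is how
  the index is used.)
* **Canberra distance** $\sum_i |x_i - y_i| / (|x_i| + |y_i|)$ compares two
  binned distributions (empty-in-both classes contribute 0, so disjoint
  supports score one per occupied class). Distances default to normalized
  biomass shares so runs of different total biomass are comparable; a raw
  mode (`normalize = FALSE`) is available since either convention is
  defensible for absolute spectra.
* **MSD**, the intra-ensemble mean square Canberra distance to the
  ensemble-mean distribution, measures how conserved community structure is
  across replicate runs.
* **Grazing background and refuges**: summed biomass-times-`I_max`-weighted
  palatability over grazers along a volume axis; refuges are its local
  minima.
* **Fitness landscapes**: 200 passive probes per functional type spanning
  the type's range, co-integrated in one shared year from profiles cloned
  off the type's most abundant resident; residents plot at $s \approx 0$,
  and at the evolutionary endpoint each sits on a local maximum.

## The simulation protocol

`run_protocol()` reproduces the two-phase design: random seeding (species
allocated round-robin over the four types, volumes log-uniform within the
type range, all profiles uniformly at $6\times10^{-9}$ mmol C m$^{-3}$,
winter start), then a 100-year *ecological phase* with fixed traits
(species sorting; the attractor is typically reached within 10-20 years),
then a 250-year *eco-evolutionary phase* under the mutation-invasion
engine, with snapshots, event logs, attractor checks and final singularity
classification. `run_ensemble()` runs K = 24 independent seedings per
condition (8, 20, 40 or 80 species) and aggregates richness, evenness and
MSD. All randomness flows from one master seed through named substreams, so
`(config, seed)` reproduces a run bit-for-bit.

### Presets and problem sizes

The full protocol is `preset = "paper"` (35 levels, 3275 m, 100 + 250
years); a single such run takes on the order of an hour in this pure-R
implementation, and a four-condition, 24-member ensemble is an
overnight-scale computation. The routine testing configuration is `preset =
"desk"`: 10 levels over a 400-m column with otherwise identical structure
and forcing. The desk column is deliberately shallow enough that winter
convection ventilates it completely; this removes the centuries-long
relaxation mode of the sub-mixed-layer reservoir of a closed 3275-m column,
so the desk system lands on its annual limit cycle within a few years
(state distance at round-off after ~5 years with prescribed grazers), which
is what makes tight attractor-based checks (the zero-fitness identity at
$10^{-6}$) affordable. The test suite and the acceptance script run desk
configurations with 1-8 species over 10-70 simulated years; the paper-scale
protocol is exercised for capability, not reproduced statistically.

With *dynamic* grazers the desk system keeps a slowly damped two-year
predator-prey oscillation, so its "attractor" is only annual to about
$10^{-4}$ in relative state distance; this is the regime in which resident
fitness is "close to but not equal to zero", and it is why selection
outcomes are referenced to the resident's realized rate.

## What the synthetic conditions do and do not show

The forcing generator emulates the seasonal *phenomenology* of a
high-latitude column. Passing tests therefore demonstrate the internal
consistency of the method --- conservation, the passive-tracer contract, the
N\* theory, refuge selection, convergence and oscillation structure ---
under realistic forcing amplitudes. They do not demonstrate agreement with
observed Norwegian Sea profiles, nor robustness to multi-nutrient
limitation (P, Fe, Si are out of scope), nor anything about evolutionary
branching, which this engine detects (as flagged disruptive events) but
cannot follow. The grazing background is deliberately log-periodic; real
backgrounds are smoother, and with a smoother background the refuge
structure (and hence the evolved community) would differ.

## Numerical and degenerate-input choices

* Forward-Euler biology at `dt_bio = 0.05` d; halving the step changes a
  year on the attractor by less than 1% (asserted in the tests).
* Implicit diffusion is exactly conservative by construction (the
  h-weighted column sum is a left eigenvector of the update); no new
  extrema are created.
* Upwind sinking is positivity-preserving under its CFL sub-stepping; the
  bottom boundary is closed, so sinking matter accumulates in the deepest
  level until remineralized there.
* Grazing with all-zero palatabilities or zero prey returns exactly zero
  flux (no 0/0).
* A mutant clamped off at a range boundary simply isn't generated; with
  both mutants absent the outcome is stabilizing by convention and logged.
* Extinct mutants ($B(t+1) \le 0$) get $s = -\infty$.
* Quota invariants are enforced by clamping with audit logging, and the
  immigration floor is excluded from the conservation audit, so budget
  tests measure the physics, not the repairs.
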