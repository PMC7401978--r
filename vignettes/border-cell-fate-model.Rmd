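---
title: "A mechanistic model of the bistable JAK/STAT switch in border-cell fate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A mechanistic model of the bistable JAK/STAT switch in border-cell fate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jakstatswitch)
```

## The biology and the model

During *Drosophila* oogenesis, anterior polar cells secrete the cytokine
Unpaired (UPD). Nearby follicle cells read this signal through the
JAK/STAT pathway: UPD activates JAK, activated JAK phosphorylates STAT,
phosphorylated STAT dimerizes, and the dimer drives transcription of
*slbo* (whose product SLBO makes the cell motile), *apt* (whose product
APT keeps it stationary) and *stat* itself. APT and SLBO cross-repress:
SLBO cooperatively degrades *apt* mRNA (a `B^2` term, presumably via a
SLBO-activated miRNA), while APT represses the *slbo* gene directly and
degrades both *slbo* and *stat* mRNA through miRNAs. The cross-repression
makes the pathway a bistable switch: above a UPD threshold the
SLBO-dominated (motile) state wins, below it the APT-dominated
(stationary) state does, and in between the outcome depends on the
cell's starting composition.

`jakstatswitch` implements this system at two levels:

* the **full 15-variable model** (`full_rhs()`): mass-action kinetics
  for activated/free JAK, STAT monomer, the JAK--STAT complex, the
  activated dimer, an optional APT--dimer sequestration complex, APT,
  SLBO, three mRNAs and four gene-occupancy states;
* the **minimal three-variable model** (`three_var_rhs()`) in STAT
  (`S`), APT (`A`) and SLBO (`B`), obtained by quasi-steady-state (QSS)
  reduction.

All concentrations are nM, time is minutes, and UPD (`U`) is a
parameter, not a dynamic variable.

## The staged reduction

The gene-state binding rates (~100 min^-1^ scale) are orders of
magnitude faster than translation, transcription and degradation
(0.04--3 min^-1^), so the gene occupancies equilibrate essentially
instantaneously. Setting their derivatives to zero gives closed forms
(`gene_qss()`): with equilibrium constants written as forward/backward
ratios, the transcribing *apt* fraction is
`alphaStar = Ka*S2/(Ka*S2 + 1)`, the *slbo* states partition as
`beta = 1/(Kb*S2 + 1 + KbR*A)`, `betaR = KbR*A*beta`,
`betaStar = Kb*S2*beta` (summing to one exactly), and the inactive
*stat* fraction is `sigma = 1/(Ks*S2 + 1)`. The package uses the
forward/backward orientation because it is the one under which these
formulas solve the gene-state kinetics exactly — the test suite checks
them against a direct linear solve and against relaxation of the
integrated fast subsystem. The reversed ("printed") orientation is kept
behind `equilibrium_constants(..., orientation = "printed")` for
comparison; under it the dimer never activates *slbo* at baseline rates
and the switch is not bistable at all.

mRNA also turns over at least twice as fast as protein, so the mRNAs are
slaved next (`mrna_qss()`), producing the two-variable cross-repression
core (`two_var_rhs()`) in which APT and SLBO interact at a fixed dimer
level.

Finally STAT activation is reduced. Conservation of the JAK pool and a
saturating UPD response give `Jstar = kUJf*U*JT/(kUJb + kUJf*U)`
(`jak_qss()`), and a Michaelis--Menten treatment of the catalytic step
`Jstar + 2S -> dimer` gives

```
S2star = vmax * S^2 / (kS2star * (S^2 + km^2)),   vmax = kc1 * Jstar.
```

One subtlety deserves emphasis. Because the catalytic step binds one
JAK with **two** STAT monomers, the Michaelis constant
`(kc1b + kc1)/kc1f = 100.1` carries units of nM^2^, and the
half-saturation monomer concentration is its square root,
`km = sqrt(100.1) ≈ 10.0 nM`. Treating the 100.1 figure itself as a
concentration and squaring it (denominator `S^2 + 100.1^2`) weakens
STAT activation by two orders of magnitude; under that reading the model
fails its own calibration points — the shared initial condition
`(S, A, B) = (12, 56, 1.5)` converges to the stationary state even at
UPD = 4, and the stationary branch never folds below UPD = 60. The
package therefore fixes `km^2 = 100.1 nM^2`, under which the expected
phenomenology (fate dichotomy between UPD = 1 and 4, STAT equilibration
near 200 min, high-APT state near 44.4 nM as UPD vanishes) emerges
from the published rate constants with no further adjustment.

The resulting minimal model is

```
dS/dt = kS*(kmsigma*(1 - sigma) + msigma0)/(deltamsigma + deltaAsigma*A) - deltaS*S
dA/dt = kA*(kmalpha*alphaStar + malpha0)/(deltamalpha + deltaBalpha*B^2) - deltaA*A
dB/dt = kB*(kmbeta*betaStar  + mbeta0)/(deltambeta  + deltaAbeta*A)     - deltaB*B
```

with all occupancies evaluated at the QSS dimer level. The parameter
`deltaAsigma` (nM^-1^ min^-1^) is the APT-induced, miRNA-mediated
degradation of *stat* mRNA — the knob for the delay experiments below.

## Parameters and their provenance

`default_parameters()` returns the 33 rate constants and levels as a
named vector; `set_parameters()` produces modified copies so a scan can
never corrupt the baseline, and `read_parameters()`/`write_parameters()`
round-trip flat YAML configs bit-exactly. The values combine measured
translation/transcription rates scaled by gene lengths, measured
protein/DNA binding kinetics, and literature estimates for degradation
and miRNA action; several published unit labels are internally
inconsistent (e.g. bimolecular rates labelled min^-1^), so the numbers
are used exactly as they enter the equations, with concentrations in nM
and time in minutes throughout.

The APT--dimer sequestration complex appears in the full model's
equations but its binding rates are not part of the 33-parameter set;
`full_rhs()` exposes them as `c2_kf`/`c2_kb` defaulting to 0. The test
suite verifies algebraically that switching sequestration on leaves
every steady state of the remaining 14 variables in place (the binding
and dissociation fluxes cancel jointly at equilibrium) — sequestration
re-shapes basins of attraction, not the equilibrium structure.

## Dynamics, equilibria, bifurcation

`integrate_model()` wraps a stiff solver (`deSolve::ode`, `lsoda`,
which switches between Adams and BDF as stiffness demands) at relative
tolerance 1e-8 and absolute tolerance 1e-10. For the full model the
right-hand side is evaluated unclipped: its mass-action terms are
well-defined for the solver's tiny negative excursions and supply the
stiff restoring forces; clipping them away destabilizes the gene-state
variables. For the reduced models, where rational denominators could
vanish at large negative APT, states are clipped at zero inside the
solver callback.

`find_steady_states()` runs damped Newton iterations from a log-spaced
multistart lattice (default 8x8x8 over S up to 500, A and B up to
200 nM) and classifies roots by the eigenvalues of a central
finite-difference Jacobian (relative step 1e-6, floor 1e-9; an
independent numerical-differentiation implementation serves as the test
oracle). `continue_branch()` implements pseudo-arclength continuation
with a bordered-Newton corrector, adaptive step length (0.05 initial,
0.5 cap, halving on failure) in arclength scaled by (10, 10, 10, 1) nM
for (S, A, B, U); folds are flagged where the tangent's U-component
changes sign and refined by arclength bisection to 1e-3 nM. A single
continuation started from the U = 0 steady state traverses the entire
S-shaped curve: up the stationary branch, through the upper fold, back
along the unstable middle branch, through the lower fold, and out along
the motile branch.

With the baseline parameters the package computes a bistable UPD window
of about [0.0013, 7.87] nM: the upper limit point sits at 7.873 nM
(`max(continue_branch(...)$folds)`, confirmed by multistart root
counting), and the high-APT branch terminates at `A = 44.36` nM as UPD
approaches zero. The published account of this system reports the upper
limit point at 11.24 nM and the terminal APT level at 44.73 nM; the
second value is reproduced within 1%, the first is not (7.87 vs 11.24).
We could not find any reading of the published equations and rate
table — either Michaelis-constant convention, either equilibrium-constant
orientation, linear or bimolecular dedimerization, or the un-reduced
15-variable system, whose own stationary branch folds near 3.3 nM —
that yields 11.24 while also preserving the fate dichotomy; the
discrepancy is reported as-is rather than absorbed by adjusting any
constant.

## Fate classification and the scripted experiments

`classify_fate()` labels a trajectory by its endpoint at a deadline
(default 500 min, the experimentally reasonable horizon): within 5%
relative Euclidean distance of a stable state it is `motile`
(SLBO-dominated attractor) or `stationary` (APT-dominated); otherwise
`unresolved`, the operational signature of starting near the
separatrix. `convergence_time()` reports when a component enters and
stays within a 5% band of its final value — the package's operational
meaning of "equilibrates", applied to STAT in the delay experiments.
"Elevated" STAT means the final level exceeds the saddle's STAT value
at the same conditions.

Three experiment drivers reproduce the study designs:

* `mirna_delay_experiment()` scans `deltaAsigma` at UPD = 4 from
  (12, 56, 1.5): outcomes are `GO` (prompt elevation), `SLOW`
  (convergence delayed beyond twice the baseline time) and `STOP` (no
  elevation within the horizon). At the baseline
  `deltaAsigma = 0.05`, STAT equilibrates at 204 min. In this
  implementation the GO/STOP boundary for this initial condition lies
  at `deltaAsigma ≈ 0.202`, so the published SLOW (0.17382) and STOP
  (0.18) levels both still GO, with delays of ~80--90 min rather than
  ~600; the qualitative GO -> SLOW -> STOP progression exists but the
  critical value sits ~15% higher than published, the same direction of
  disagreement as the fold location.
* `stat_knockdown_experiment()` relaxes the system to its stationary
  state (UPD = 1 by default), then sets the STAT translation rate
  `kS = 0`: STAT decays to zero and APT falls to 44.36 nM, a ratio of
  0.49 — the experimentally observed halving. At UPD = 0.1 the
  pre-knockdown STAT level is 3.9 nM, matching the reported "about 4";
  at UPD = 1 it is 7.7 nM. The APT ratio is ~0.49 at either level, so
  the default follows the stationary-regime convention (UPD = 1) and
  the UPD level is exposed as an argument.
* `apt_sweep_experiment()` varies initial APT at UPD = 0.1 (inside the
  bistable window) with S0 = 12, B0 = 1.5: final STAT is non-increasing
  in initial APT, and sufficiently high APT lands the cell on the
  low-STAT branch — APT's feedback inhibition in action.

In the full 15-variable model the same initial condition escapes to the
motile state at UPD = 1 as well as UPD = 4. This is a real property of
the published equation set under neutral fast-variable initial
conditions (whole JAK pool unbound, genes inactive, mRNAs at
protein-conditioned QSS): the dimer pool integrates the transient of
the initial 12 nM STAT instead of tracking the decaying monomer as the
QSS reduction forces it to, and that transient activates *slbo* long
enough to commit. APT--dimer sequestration buffers the transient, but
absent published rates for it the package does not enable it by
default, and the reduced/full fate disagreement at UPD = 1 is
documented rather than hidden.

## Basins of attraction and the separatrix

`classify_grid()` integrates every node of a regular grid of initial
conditions (analysis default 21^3 over S up to 250, A up to 120, B up to
60 nM; the test suite uses 9--11 per axis, which changes basin volume
fractions by under two percentage points) and labels each node's fate
within the 500-min deadline. Grid-point integrations use slightly
relaxed tolerances (1e-6/1e-8) since fate labels are insensitive at
this resolution. `near_manifold_points()` collects the unresolved
nodes plus the midpoints of grid edges whose endpoints disagree — on a
coarse grid the unresolved set alone can be nearly empty, so the edge
midpoints supply a well-distributed boundary sample (switchable off via
`edge_midpoints = FALSE` for the strict convention).

`fit_manifold()` fits an implicit surface to the boundary cloud by
total least squares: a plane via the smallest principal direction, or a
quadratic via the smallest singular direction of the scaled degree-2
monomial matrix. "Near-planar" is operationalized as the fraction of
resolved grid points whose fate the plane's sign predicts; at UPD = 4
the plane achieves ~98% sided accuracy, its normal lies within a few
degrees of the normal to the saddle's stable eigenplane (the
separatrix's tangent plane at the saddle, computed from the left
unstable eigenvector), and the saddle itself lies within a grid cell of
the fitted surface. The motile basin's volume fraction grows strictly
with UPD (0.17, 0.78, 0.91 at UPD = 0.0133, 0.133, 4 on a 9^3 grid) as
the separatrix sweeps from low-SLBO toward high-APT territory.
`manifold_shift_report()` tabulates fits, basin fractions, and the
signed side of a probe initial condition across UPD or `deltaAsigma`
conditions; in this implementation the probe's fate flip occurs near
`deltaAsigma = 0.202` rather than between 0.17382 and 0.18.

## Robustness scanning

`is_bistable()` makes "bistable" operational in two ways, because a
UPD-dependent phase diagram admits both: existence of *some* UPD in
[0, 50] with two separated stable states (`"interval"`), or bistability
at the reference UPD = 4 (`"fixedU"`). `param_bistable_range()` moves
one parameter at a time, expanding geometrically from baseline and then
bisecting each boundary to 1% relative resolution, capped at 0 below
and 1100 above; `scan_bistable_ranges()` tabulates all 33 parameters
with per-parameter CSV caching so long scans resume, and
`sensitivity_ranking()` orders parameters by the largest tolerated
percent change.

A finding worth stating plainly: under either criterion this model's
bistability is extraordinarily robust to `deltaAsigma` increases — at
UPD = 4 the motile state keeps APT near zero, which disables the very
degradation `deltaAsigma` scales, so the bistable range runs from
~0.02 to beyond the search cap, and `deltaAsigma` ranks among the
*least* sensitive parameters (JT, deltaA and kB tolerate ~80--100%
changes; deltaAsigma tolerates orders of magnitude). The published
robustness table instead reports a razor-thin range (0.043--0.057) for
this parameter under an unstated criterion; no criterion we could
derive from the printed model reproduces that table, so the package
reports both of its criteria and the disagreement rather than a match.

## Numerical choices, in one place

* Stiff integration: `lsoda`, rtol 1e-8, atol 1e-10, 50k step cap;
  10x tighter tolerances move reported convergence times by <1%.
* Newton residual acceptance 1e-11 (steady states stored with residual
  norms, all < 1e-9); root dedup at 1e-4 relative distance.
* Finite-difference Jacobian: central, relative step 1e-6, floor 1e-9.
* Continuation: scaled pseudo-arclength, ds in [1e-6, 0.5], start 0.05;
  fold refinement to 1e-3 nM in UPD.
* Fate tolerance 5% relative; classification deadline 500 min (basins)
  and 1000 min (delay experiments), both arguments.
* Grids and lattices are deterministic; the package uses no random
  numbers anywhere, so repeated runs are bit-identical.

## What the test conditions do and do not show

All analyses run on model-generated data at the published study
conditions (initial condition (12, 56, 1.5); UPD in {0.0133, 0.133, 1,
4}; `deltaAsigma` in {0.05, 0.17382, 0.18}); there is no external data
and no fitting. Passing tests therefore certify the implementation of
the stated equations and analyses — QSS formulas exact against the fast
subsystem, conservation laws to solver precision, continuation against
multistart — and the reproduction of those published numbers that
follow from the printed constants (terminal APT 44.36 vs 44.73; STAT
equilibration 204 vs ~200 min; knockdown ratio 0.49 vs ~0.5). They do
not certify biological realism beyond the model's scope: UPD is spatially
uniform here (no gradient or diffusion), there is no cell mechanics or
collective migration, gene states are deterministic proportions rather
than stochastic switches, and the handful of quantitative disagreements
with the published analysis (fold at 7.87 vs 11.24 nM; SLOW/STOP
threshold near 0.202 vs 0.175--0.18; the full model's fate at UPD = 1;
the robustness table) are left visible in the acceptance suite with the
analysis above rather than reconciled by undocumented constants.
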