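---
title: "Modelling cellular ageing as an attractor landscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cellular ageing as an attractor landscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ageingGRN)
```

## The model

`ageingGRN` implements a 13-gene regulatory network that couples the
p53-centred DNA-damage response (p53, Mdm2, Wip1, ATM, p21, PTEN, AKT)
to Rb--E2F cell-cycle control (Myc, E2F, RB, CycE, CycD), joined
through ARF and p21. Two constant inputs drive the network: `Stress`
(DNA-damaging or oxidative stress, level 0.3), which activates ATM, and
`GS` (growth signals, level 0.2), which activates Myc and Cyclin D.

Every node $X$ obeys the same Hill-kinetics rate law,

$$\frac{dX}{dt} \;=\; a \sum_{A \in \mathrm{act}(X)}
\frac{A^n}{S^n + A^n} \;+\; b \sum_{B \in \mathrm{inh}(X)}
\frac{S^n}{S^n + B^n} \;-\; k\,X ,$$

with one global activation rate $a$, one global inhibition rate $b$, a
shared threshold $S$ and Hill coefficient $n$, and linear degradation
$k$. Note the sign convention: an "inhibition" term is a *basal
production* gated off by the inhibitor, so it is always non-negative
and bounded by $b$. Inhibitors can therefore never switch off a
self-activating node — a structural fact with consequences discussed
below. Defaults are $S = 0.5$, $n = 4$, $k = 1\ \mathrm{h^{-1}}$,
$a = 1$, $b = 0.05$; all concentrations are dimensionless and time is
in hours. $a$ is read as the accumulated level of DNA damage: it is
the ageing axis of the model and the main bifurcation parameter. $k$
may be a per-node vector for experiments with protein-specific
turnover; no alternative canonical set is shipped.

The network is compiled into incidence matrices and evaluated by a C
right-hand side through deSolve's compiled-model interface, so that
the Monte Carlo analyses below (tens of thousands of short
integrations) stay cheap. A literal hand transcription of the 13
equations is kept in the test suite as an independent oracle for the
compiled form.

## Cell fates and the fate census

Steady states are classified by their (p53, ATM) marker pair:
homeostasis (both low), cell-cycle arrest (p53 intermediate, ATM low),
senescence or apoptosis (both high), and cancer (p53 low, ATM high —
the state that evades arrest despite damage signalling). The three
p53 cuts and the ATM cut are not free constants: they are computed
once from the model itself as midpoints between the coexisting branch
levels at $a = 1$ (p53 low/intermediate/high $\approx$ 0.12 / 0.93 /
1.95, ATM low/high $\approx$ 0.12 / 1.07), giving cuts of about 0.53,
1.44 and 0.60. They are cached, overridable, and always reported next
to the raw coordinates.

A structural property of the rate law matters here: E2F activates
itself, and since inhibition terms are bounded by $b$, p21 and RB can
never extinguish the E2F-high state. The Rb--E2F module is therefore a
bistable switch in its own right, one-way driven by the p53 arm (p53
→ p21 → cell cycle, with no feedback to p53 except through the
constant-input Myc--ARF feed-forward). Consequently almost every
(p53, ATM) fate coexists in two variants — cell-cycle quiescent
(E2F off) and proliferative (E2F on) — and the 13-dimensional system
has up to twice as many stable fixed points as there are fates: six at
$a = 1$, for example. `find_attractors()` reports all distinct fixed
points honestly; `fate_census()` groups them by their marker-plane
projection, which is the census that corresponds to basins of the
two-dimensional landscape. Both numbers are meaningful and both are
tested.

`find_attractors()` relaxes seeded uniform random starts
(`[0, x_max]` per coordinate, `x_max = 3` by default — comfortably
covering the production bound $(3a + 2b)/k$ of the most-activated
node at moderate $a$ while keeping density near the attractors),
declares convergence on the derivative max-norm (step-size
independent), polishes endpoints by damped Newton iteration with the
analytic Jacobian, and clusters fixed points at max-coordinate
distance `1e-3`. One caveat from the geometry: the homeostasis basin
occupies only ~0.1% of the uniform ensemble at $a = 1$, so censuses
with fewer than a few thousand starts can miss it; the shipped checks
use 2000 starts.

## Bifurcation structure

`continue_branch()` is a natural-parameter predictor–corrector:
step the parameter, re-solve the fixed point by Newton iteration from
the previous solution, halve the step on failure, and once the step
underflows, bisect the bracket to within `1e-3` and record the fold.
Pseudo-arclength continuation is deliberately avoided: all
bifurcations of this model in the explored ranges are folds, and
branches are traced piecewise (restarting past a fold from the
coexisting attractor), which the simpler corrector handles robustly.
Stability at every accepted point comes from the Jacobian spectrum.
The fold bracket of `1e-3` matches the three-decimal reporting
precision used for thresholds; note that the near-zero eigenvalue at a
bracketed fold scales like the square root of the parameter distance,
so demonstrating the spectral collapse (gap $< 10^{-2}$) requires
bracketing to about `1e-5`.

At $b = 0.05$ the p53 readout shows the tri-stable switch that
organises the whole analysis: continuation of the homeostasis branch
upward in $a$ finds its fold at $a \approx 1.152$; the arrest branch
persists to $a \approx 1.455$; and the senescence branch, continued
downward, is lost at $a \approx 0.747$. Tri-stability thus occupies
$0.747 < a < 1.45$. Mechanistically both up-folds are ATM escapes:
on the homeostasis branch Wip1 is low, so ATM's basal term is fully
open and ATM escapes at 1.152; on the arrest branch Wip1 (raised by
p53) closes that term and postpones the escape to 1.455.

Two subtleties uncovered while validating the continuation are worth
recording.

* **Branch variants.** The proliferative (E2F-on) senescence variant
  hits its own fold at $a \approx 0.865$ — the restriction point of
  the E2F switch, where $a$ becomes too small to sustain
  self-activation. The p53 OFF threshold at 0.747 belongs to the
  quiescent (E2F-off) variant, which is the biologically senescent,
  cell-cycle-arrested state; downward continuation therefore starts
  from the fixed point reached from a p53-arm-high / cell-cycle-zero
  initial state.
* **Ramp-step sensitivity of hysteresis.** Just past the 1.152 fold
  the outcome of relaxation is a race: if p53 rises and induces Wip1
  before ATM passes its recapture threshold, the system lands in
  arrest; otherwise ATM runs away and the system goes directly to
  senescence. A quasi-static ramp with steps of 0.02 in $a$
  reproduces the two-step activation (arrest at $a = 1.16$,
  senescence at $1.46$); coarser ramps (steps $\ge 0.05$) overshoot
  the fold and show a single jump to senescence.

`scan_two_parameters()` maps multistability over an $(a, b)$ grid by
brute-force multistart counting (both fixed-point and fate counts) —
cheaper and more directly testable than two-parameter fold
continuation. `cell_cycle_bifurcation()` re-uses the continuation
machinery with the growth-signal input as the free parameter: E2F is
bistable below the fold at $GS \approx 0.40$ where the quiescent
branch dies, and the committed branch persists all the way to
$GS = 0$, i.e. the restriction point is irreversible at default $a$;
a second fold at $GS \approx 0.45$ marks the loss of the homeostasis
p53-arm as growth signals feed Myc → ARF → p53. Cyclin D increases
monotonically with growth signals along every branch.

## The quasi-potential landscape

`estimate_landscape()` integrates `n_traj` trajectories from seeded
uniform initial conditions and bins *every* sampled time point —
transients and equilibria alike — of their projection onto two
coordinate nodes (default p53 and ATM; p21 and ATM give the same
picture) on a 100 x 100 grid over `[0, x_max]`. The visit fraction
per box is $P$ and the quasi-potential is $U = -\ln P$; never-visited
boxes carry $\max U + 1$ and are flagged. Projected values beyond the
axis limit are clamped into the last box rather than dropped, so $P$
always sums to exactly 1 (the senescence fixed point sits near
p53 $\approx 3$ at $a = 1.5$ and would otherwise lose its equilibrium
mass). Time-uniform sampling (500 points over 50 h by default) is the
method's definition of the landscape: it measures where the dynamics
spends time, which weights attractor boxes heavily and also gives
weight to slow transient regions.

That last property is essential for interpreting the landscapes at
high damage. At $a = 1.5$ the arrest fixed point no longer exists
(its fold is at 1.455), yet the landscape shows a shallow basin near
(p53 1.55, ATM 0.23): the remnant ("ghost") of the just-vanished
saddle-node pair, where trajectories linger for tens of hours before
ATM completes its escape. The same mechanism produces the
homeostasis and arrest basins of the perturbed network at $a = 1.5$.
These basins are real features of the time-weighted distribution, and
they are exactly why the landscape census can exceed the fixed-point
census; conversely, minima co-locate with stable fixed points (within
one box) only at parameter values away from folds, and the test suite
checks that property at $a = 0.5$ and $a = 1$.

`locate_basins()` finds local minima of $U$ with three noise guards,
each motivated by a distinct sampling artefact:

* detection runs on a 3 x 3 boxcar-smoothed count field (then snaps
  each minimum to the most-visited raw box in its window) — the
  initial-condition scatter sprinkles single samples over the whole
  plane and local Poisson maxima of that sprinkle would otherwise
  pose as minima;
* a minimum must hold at least `max(10, 4e-6 * total samples)` counts
  in its window, the scale of a few sprinkle samples;
* its box must have been visited by at least `max(3, 5e-4 * n_traj)`
  *distinct* trajectories, because a single slow trajectory deposits
  arbitrarily many samples wherever it crawls, whatever the ensemble
  size — a basin is an ensemble feature.

Minima closer than 5 boxes merge (deepest wins), and shallow features
are removed by topographic persistence (exact union-find sweep;
threshold 1, i.e. an $e$-fold probability contrast). With these
defaults the basin census is stable from a few thousand trajectories
upward; the default `n_traj` is 100,000, while the shipped acceptance
checks use 10,000 — the counts saturate far earlier, and 10,000 keeps
the full suite within minutes. `basin_depth_rank()` orders basins by
depth and labels them from their own box coordinates when the
landscape is the (p53, ATM) plane — deliberately not via the nearest
fixed point, since ghost basins have none.

The canonical results, all recomputed by the tests at 10,000
trajectories: the intact network has one homeostasis basin at
$a = 0.5$ and two basins at $a = 1.5$ with senescence deepest;
deleting the two p53-activating edges (ATM→p53, ARF→p53) yields four
basins at $a = 1.5$ — homeostasis, arrest, senescence and a cancer
basin (p53 low, ATM high) that is markedly deeper than homeostasis —
and a single homeostasis basin at $a = 0.5$; raising $b$ to 1.2
eliminates the cancer basin ($b$ lifts the basal production floor of
p53, removing the p53-low state).

`find_saddle()` locates the saddle between two attractors by
bisecting the straight segment between them on basin membership,
following the near-boundary trajectory to its first residual dip
(the saddle approach along the stable manifold), and Newton-polishing;
`saddle_path()` then integrates out along both halves of the unstable
eigendirection, giving the heteroclinic path that appears as the
valley connecting two basins in the landscape's top view.

## Settling times

`time_to_attractor()` reports the first sampled time at which a
trajectory comes within a fraction of a target fixed point, measured
as the max-norm distance relative to the attractor's magnitude
($\max_i |x_i - x^*_i| \le 0.01 \max_i x^*_i$ for the 1% criterion).
A strictly per-coordinate relative criterion would be dominated by
nodes whose steady levels are $10^{-3}$ or smaller (AKT, ARF at high
damage) and would measure their asymptotic tail rather than the
biological settling of the state. At $a = 1.5$, the median settling
time into the senescence attractor from 500 uniform random starts is
about 6.4 h, with stragglers delayed by the arrest-ghost bottleneck;
the within-20-hours criterion holds with a wide margin.

## Reproducibility and problem sizes

Every stochastic step takes an explicit integer seed; initial
conditions are drawn in a fixed order so that enlarging an ensemble
extends it without re-randomising earlier draws. `run_grn()` writes a
provenance record (config echo, seed, versions, wall time) beside
every output, and identical config plus seed gives byte-identical CSV
output. The test suite runs the landscape analyses at 10,000
trajectories and the multistart censuses at up to 2,000 starts; the
continuation analyses are deterministic. Solver tolerances are
`rtol = 1e-8`, `atol = 1e-10`; halving them moves 50-hour endpoints
by less than $10^{-6}$, and halving the continuation step moves folds
by less than $10^{-3}$.

## Known limitations

* One global $a$ and $b$ for all edges and (by default) one $k$ for
  all proteins: per-protein turnover estimated from measured
  half-lives destroys the multistability of this parameterisation, so
  the model's conclusions are tied to the shared-rate idealisation.
* The fate census and phenotype cuts are anchored to the (p53, ATM)
  marker plane; the proliferative/quiescent distinction is invisible
  there by construction and must be read from the full attractor
  table.
* The landscape is a time-weighted occupation measure, not a Freidlin-
  Wentzell quasi-potential: no noise model is attached, barrier
  heights are not action integrals, and slow transients (fold ghosts)
  create basins without attractors. This is the intended definition,
  but it should not be over-interpreted energetically.
* Multistart census of very small basins (homeostasis at $a$ near the
  first fold) is seed-sensitive below a few thousand starts.
* The model itself is a coarse abstraction — dimensionless
  concentrations, no stochastic gene expression, no delays, and a
  hand-curated core topology — so passing its internal checks says
  nothing about fit to any particular experimental dataset.
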