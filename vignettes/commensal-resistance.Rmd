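---
title: "Modelling the costs and benefits of antibiotic resistance in commensals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the costs and benefits of antibiotic resistance in commensals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comres)
```

## The question

Antibiotic resistance in commensal bacteria is usually treated as a pure
liability: resistant commensals can pass resistance genes to pathogens by
horizontal gene transfer (HGT) and can themselves cause opportunistic
infections. But commensals also suppress pathogens ecologically, and
antibiotic treatment removes that suppression -- unless the commensal is
resistant enough to survive the treatment. `comres` implements a minimal
two-species model in which both effects can be weighed against each other,
turning resistance management into an optimisation problem rather than a
minimisation problem.

## The model

A pathogen (density $P$) and a commensal ($C$) follow Lotka-Volterra
dynamics with an added density-independent antibiotic loss term:

$$\frac{dP}{dt} = r_p P\left(1 - \frac{P + \alpha_{pc} C}{k_p}\right) - x A P,
\qquad
\frac{dC}{dt} = r_c C\left(1 - \frac{C + \alpha_{cp} P}{k_c}\right) - x f A C.$$

The parameters, all held in `lv_params()`:

| symbol | meaning | units / range | default |
|---|---|---|---|
| $r_p, r_c$ | maximal growth rates | per time, $\ge 0$ | 0.5 |
| $k_p, k_c$ | carrying capacities | scaled density, $(0, 2]$ | 1 |
| $\alpha_{pc}$ | effect of commensal on pathogen | signed, $|\alpha| < 1$ | 0.8 |
| $\alpha_{cp}$ | effect of pathogen on commensal | signed, $|\alpha| < 1$ | 0.8 |
| $x$ | maximal pathogen clearance rate | per time | 0.1 |
| $f$ | relative commensal susceptibility | $\ge 0$ | 1 |
| $A$ | antibiotic exposure | $[0, 1]$ | 0 |

Positive $\alpha$ means inhibition, negative means facilitation, so the
same equations cover competition ($+,+$), exploitation ($+,-$ / $-,+$) and
mutualism ($-,-$). The restriction $|\alpha_{ij}| < 1$ excludes strong
interference competition and with it bistability: within this regime each
parameter set has a single attractor reachable from interior initial
conditions, which is what makes the closed-form analysis below clean.
Densities are scaled so a default pathogen has unit carrying capacity, and
$x A / r_p = 0.2$ at full exposure encodes a *partially resistant*
pathogen: maximal treatment alone removes only 20% of its standing
density.

## Equilibria and stability

The model has up to four fixed points: joint extinction, the two
single-species boundary states $\big(k_p(1 - xA/r_p),\, 0\big)$ and
$\big(0,\, k_c(1 - xfA/r_c)\big)$ (collapsed to zero when the effective
growth rate is negative), and the interior coexistence point

$$P^* = \frac{r_c k_p (r_p - xA) - \alpha_{pc} r_p k_c (r_c - xfA)}
       {r_p r_c\,(1 - \alpha_{pc}\alpha_{cp})},$$

with $C^*$ by the symmetric expression. `classify_outcome()` evaluates all
candidates and returns the stable feasible one. Stability is read off the
real parts of the Jacobian eigenvalues at each fixed point, computed
analytically from the trace and determinant of the $2\times 2$ Jacobian;
the tests cross-check this against `eigen()` on a numerically
differentiated Jacobian, and against long-time ODE integration from random
interior starts.

Numerical conventions, chosen once:

* *Feasibility:* closed-form densities in $[-10^{-9}, 0)$ are snapped to
  zero; anything more negative is infeasible (never returned as an
  equilibrium).
* *Stability:* a fixed point is stable when the leading eigenvalue real
  part is below $-10^{-9}$. Points within $10^{-9}$ of zero are flagged
  `marginal` rather than silently stable -- these occur exactly on
  bifurcation lines (threshold curves in the sweeps, and the $f = 0$ edge
  of the risk profile), and `classify_outcome()` will return a marginal
  attractor, flagged, when no strictly stable one exists.
* *Degenerate collisions:* at transcritical points the interior branch
  coincides with a boundary state; coincident candidates are deduplicated,
  keeping the boundary labelling.

## Release and benefit conditions

Differentiating $P^*$ gives the two gradients the analysis revolves
around:

$$\frac{\partial P^*}{\partial A} =
  \frac{x(\alpha_{pc} r_p k_c f - r_c k_p)}{r_p r_c (1 - \alpha_{pc}\alpha_{cp})},
\qquad
\frac{\partial P^*}{\partial f} =
  \frac{\alpha_{pc} k_c x A}{r_c (1 - \alpha_{pc}\alpha_{cp})}.$$

$\partial P^*/\partial A > 0$ is **competitive release** -- more drug,
more pathogen -- and within the coexistence regime it occurs exactly above
the critical susceptibility
$f^* = r_c k_p / (r_p k_c \alpha_{pc})$ (`release_threshold_f()`; defined
only for $\alpha_{pc} > 0$). $\partial P^*/\partial f > 0$ is **beneficial
commensal resistance**; under exposure it reduces to $\alpha_{pc} > 0$:
resistance in the commensal helps exactly when the commensal inhibits the
pathogen, and it is most beneficial under reciprocal competition, weaker
when the commensal exploits the pathogen, and harmful when the commensal
facilitates pathogen growth.

```{r gradients}
dPstar_df(lv_preset("fig4"))                       # competition: benefit
release_threshold_f(lv_preset("fig3A"))            # release threshold f*
```

Both gradients are statements about the interior branch. `scan_Af()` and
`scan_alpha()` evaluate them over 2-D grids (default $201 \times 201$; the
contour increments 0.03/0.06 are carried as plot metadata); cells whose
attractor is a boundary state report that state's densities and mask the
gradients as `NA` -- no attempt is made to differentiate across
bifurcation boundaries.

## Temporal dynamics

`lv_integrate()` wraps an adaptive lsoda integration (relative tolerance
$10^{-8}$, absolute $10^{-10}$); convergence is declared when the terminal
growth rates fall below $10^{-8}$. Densities are kept non-negative:
values below zero by at most $10^{-9}$ are clipped silently (solver
overshoot), worse violations clip with a warning, and anything beyond
$-10^{-6}$ aborts. `exposure_ladder()` runs a shared initial condition --
by default the drug-free coexistence equilibrium, since the scenarios of
interest start from an established polymicrobial community -- across a
ladder of exposures (default 6 evenly spaced values in $[0, 1]$) with a
default horizon of 200 time units, long enough for all bundled presets to
converge away from bifurcation boundaries. Near those boundaries the
leading eigenvalue approaches zero and convergence slows without limit;
tests that compare ladder endpoints against closed forms therefore use
longer horizons.

One subtlety worth recording: on the susceptible-commensal ladder
($f = 2$) the attractor's pathogen density increases with $A$ only while
coexistence lasts ($A \lesssim 0.83$ at the default parameters); beyond
that the commensal is lost and the pathogen-dominance branch
$k_p(1 - 0.2A)$ declines. "Release with increasing antibiotic" is thus a
statement about the coexistence regime, and the package's tests phrase it
that way.

## Resource-explicit variant

To show that beneficial resistance is not an artefact of the
Lotka-Volterra abstraction, `resource_params()` /
`integrate_resource()` implement a one-nutrient chemostat with Monod
uptake: consumers grow at $v R/(K + R)$, pay dilution $d$ plus the same
antibiotic loss terms, and the nutrient is supplied at $d R_{in}$ and
consumed in proportion to growth over yield. Shared consumption of one
nutrient is the mechanistic analogue of mutual inhibition
($\alpha_{pc} > 0$), so resistance in the commensal remains beneficial.

Two structural caveats are deliberate. First, a single shared nutrient
admits no generically stable two-consumer coexistence (competitive
exclusion), so the treatment contrasts are finite-horizon statements,
evaluated at the default horizon of 100 time units from a symmetric
community; they are not equilibrium claims. Second, the defaults
($v = 1$, $K = 0.5$, $y = 1$, $d = 0.1$, $R_{in} = 1$, $x = 0.025$) were
fixed once so that (i) the two consumers share the nutrient equally
without drug, and (ii) the pathogen-alone steady state drops by about 20%
at full exposure, mirroring the partially-resistant-pathogen convention of
the baseline model. With these conditions the susceptible-commensal ladder
($f = 2$) shows terminal pathogen expansion with increasing $A$ and the
resistant-commensal ladder ($f = 0.5$) shows suppression below the
pathogen-alone curve. A closed variant ($d = 0$) conserves the
yield-weighted total $P/y_p + C/y_c + R$ up to antibiotic losses, which the
tests verify as a mass-balance check.

## Spatial extension

`spatial_config()` / `integrate_spatial()` extend the baseline model to a
two-dimensional reaction-diffusion system with an antibiotic gradient:

* discretisation: 5-point Laplacian on a uniform grid (default
  $64 \times 64$), method of lines with a sparse adaptive integrator;
* boundaries: no-flux (zero gradient), modelling a closed host
  compartment;
* exposure field: linear ramp from 0 to 1 along one axis by default, or
  any user matrix in $[0, 1]$;
* diffusion: $D_p = D_c = 0.005$ by default, putting the domain-crossing
  diffusion time within an order of magnitude of the demographic
  timescale.

Correctness is anchored by degeneracies rather than by quantitative
targets: with $D = 0$ and uniform exposure every cell must reproduce the
non-spatial ODE; with uniform initial fields and uniform exposure the
fields must stay uniform; with no reaction terms, no-flux diffusion must
conserve mass; and as $D \to 0$ the spatial mean of the terminal pathogen
field must approach the average of the local closed-form equilibria
$P^*(A(x, y))$. The qualitative treatment ordering (resistant commensal
suppresses the spatially averaged pathogen more than a susceptible one)
survives the extension.

## Risk optimisation

`risk_profile()` scores the attractor at each $f$ with three risk
classes: pathogen risk $w_p P^*$, opportunistic commensal risk $w_c C^*$,
and an HGT class $w_{h\beta} P^* C^*$ -- a static term proportional to the
product of the two standing populations, since transfer needs both donor
and recipient present (no transfer dynamics are modelled). The total is
their sum. With the competition ecology under full exposure and weights
$w_p = 1$, $w_c = 0.1$, the total is minimised at the smallest $f$ that
excludes the pathogen; adding $w_{h\beta} = 5$ creates an interior risk
*maximum* at intermediate resistance (both populations present, HGT risk
maximal) while leaving the minimum in the exclusion region.

```{r risk}
rp <- risk_profile(lv_preset("figS6"), risk_weights(1, 0.1, 5))
glance(rp)
```

`optimal_f()` breaks exact ties towards larger $f$ -- the least commensal
resistance achieving minimal risk, the conservative choice when resistance
itself carries unmodelled costs -- and reports the tie set. The default
$f$ grid is 301 points over $[0, 3]$, wide enough to include both the
exclusion region and the dominance plateau. Per-capita weights are
constants by default; a `weight_fn` hook accepts
susceptibility-dependent weightings, which can change the specific
optima.

## What the synthetic conditions do and do not show

Everything in this package is computed from stated parameter sets -- there
is no data input. Passing tests therefore demonstrate internal
consistency (closed forms against independent ODE and finite-difference
oracles, analytic stability against numerical eigenvalues, structural
variants against their degeneracy limits) and the logical content of the
model: which interaction structures make commensal resistance beneficial
and how the trade-off against HGT and opportunistic risk resolves. They
do not show that any particular host community has these parameters.
Real communities have more than two species, time-varying drug exposure,
resistance evolution, and HGT dynamics, all of which are outside this
model's scope; the spatial and resource variants probe robustness of the
qualitative conclusions, not realism.

Problem sizes used in the test suite were chosen to keep the full run
in the tens of seconds: sweeps up to $101 \times 101$ cells, 200 random
parameter sets for the ODE-oracle property (rejecting sets whose leading
eigenvalue is within 0.02 of zero, where fixed-horizon convergence checks
are meaningless), 100 sets for the finite-difference property (tolerance
$10^{-6}(1 + |g|)$, the absolute floor covering roundoff on near-zero
gradients), and spatial grids up to $21 \times 21$. The exported defaults
(201-point sweep axes, $64 \times 64$ spatial grids) are the
figure-quality settings.

## Known limitations

* Two species only; indirect effects in richer communities can attenuate
  or reverse pairwise conclusions.
* Antibiotic exposure is constant in time; no pharmacokinetics, dosing
  schedules, or event detection.
* HGT enters only as a static risk weight, not as transfer dynamics.
* The chemostat variant's published source equations and parameter values
  were not available to this implementation; it is a standard Monod
  chemostat documented as such, and its agreement with the baseline model
  is asserted at the level of qualitative outcomes only. The same holds
  for the exact diffusion parameterisation of the spatial variant.
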