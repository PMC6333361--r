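---
title: "Mass-balance food webs: models, impact analysis and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mass-balance food webs: models, impact analysis and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trophicweb)
```

## The mass-balance model

`trophicweb` implements the classic steady-state trophic mass balance used
throughout ecosystem-based fisheries science. A food web is a set of
functional groups — aggregations of taxa with similar diets and rates —
each carrying a biomass density $B$ (t km$^{-2}$), a production rate $P/B$
(yr$^{-1}$), a consumption rate $Q/B$ (yr$^{-1}$, consumers only; $P/Q$ may
be supplied instead), a diet composition column $DC_{\cdot j}$ summing to 1
(optionally including an *import* fraction fed outside the system), and per
fleet landings and discards (t km$^{-2}$ yr$^{-1}$). The master equation
for each living group,

$$B_i \, (P/B)_i \, EE_i \;=\; \sum_j B_j \,(Q/B)_j \, DC_{ij} \;+\; Y_i
\;+\; NM_i \;+\; BA_i,$$

states that the used fraction $EE_i$ (ecotrophic efficiency) of production
goes to predation, catch $Y$, net migration $NM$ and biomass accumulation
$BA$. The model assumes a steady state over the reference year, a closed
mass budget apart from imports/exports, and time-invariant diets.

**Solver.** Each living group contributes one equation and, normally, one
unknown (its missing $B$ or $EE$), giving a square linear system assembled
in `balance()` and solved by LU decomposition. Unknown biomasses appear on
the left through the known $EE\,(P/B)$ and inside the predation sums of
their prey's equations; unknown efficiencies appear through the known
$B\,(P/B)$. Three non-standard situations are handled explicitly:

* *Over-determined groups* (both $B$ and $EE$ supplied) contribute an
  equation but no unknown; the system becomes rectangular, is solved by QR
  least squares, and the group's residual is reported in the diagnostics
  rather than forced to zero.
* *Rank-deficient systems* fall back to the Moore–Penrose minimum-norm
  solution with a rank warning.
* $EE \notin [0,1]$ and negative respiration are *flags, not errors*:
  balancing real parameter sets is an iterative, manual exercise, and the
  diagnostics table is the instrument for it. A solved $B \le 0$ aborts.

The absolute residual tolerance is $10^{-8}$ t km$^{-2}$ yr$^{-1}$
(`balance(tol = )`); on solvable inputs residuals sit at rounding level
($\sim 10^{-14}$).

**Derived flows.** Consumption flows are $T_{ij} = B_j (Q/B)_j DC_{ij}$;
import consumption is kept separate so in-system column sums plus import
reproduce $Q_j$ exactly. Respiration is the assimilation remainder
$R_j = (1 - GS_j) Q_j - P_j$, with the unassimilated fraction $GS$
defaulting to 0.2. Producers respire nothing by convention; bacteria are
ordinary consumers (of detritus). Each detritus pool's budget sums the
fate-routed unassimilated and other-mortality losses plus discards
(inflow), detritivory (outflow), and the difference (export, flagged when
negative). By default benthic and demersal groups settle their losses to a
benthic-domain pool, pelagic groups to a suspended (non-benthic) pool, and
discards sink to the carrion pool when one exists; all three routings are
configurable tables.

## Trophic structure and system statistics

Fractional trophic levels solve $TL_j = 1 + \sum_i DC'_{ij} TL_i$ as one
linear system, with producers and detritus fixed at 1. The omnivory index
is the diet-weighted variance of prey trophic levels,
$OI_j = \sum_i DC'_{ij}\,(TL_i - (TL_j - 1))^2$, and the system omnivory
index averages consumer $OI$ with weights $\log Q_j$ (natural log; a
consumer with $Q \le 1$ would get a non-positive weight and is weighted by
$\log(1+Q)$ instead — a documented numerical guard).

**Import convention.** $DC'$ handles the import fraction in one of two
ways. The default, `"renormalise"`, excludes the import and renormalises
the in-system diet — equivalent to assuming the imported food has the
consumer's mean in-system prey TL. This is the right default for migratory
predators that feed mostly outside the modelled area on prey similar to
their in-system diet: the alternative `"tl1"` convention (import as a TL-1
prey) would drag a 70%-importing top predator most of the way down to
TL 2. The conventions are both implemented because reference software
differs between versions; results under both are one argument apart, and
the acceptance script reports the maximum TL difference between them
rather than absorbing it. A consumer whose diet is 100% import has no
in-system anchor and is assigned TL 2 with a warning.

System statistics are plain totals: production, consumption, respiration,
flow into detritus, and exports (landings + detritus export + net
migration + accumulation), with total system throughput their sum with
consumption; $PP/R$ and $PP/B$ use net primary production. A web with no
respiration reports $PP/R = \infty$ rather than an error.

## Mixed Trophic Impact

The direct net impact of component $i$ on $j$ is
$q_{ij} = d_{ji} - f_{ij}$: the fraction $i$ contributes to $j$'s intake
minus the fraction of $j$'s removal attributable to $i$. Fleets are full
components: they benefit from groups in proportion to catch composition,
harm them in proportion to their share of total removal (predation plus
catches — other mortality is excluded from the denominator so that fleet
and predator impacts are commensurate), and contribute positively to
detritus through discards. Landings leave the system and feed nothing
back. Total impacts propagate through every indirect path via
$M = (I - q)^{-1} - I$, and the overall cumulative impact exerted is the
signed off-diagonal row sum $\epsilon_i$ (the column sum is the impact
suffered). A root-sum-of-squares variant of $\epsilon$, used in parts of
the keystoneness literature, is reported alongside but the signed sum is
the default ranking.

Two numerical choices deserve emphasis:

* **Convergence.** The inversion is meaningful as a sum over impact paths
  when the spectral radius $\rho(q) < 1$. Because diet and removal shares
  each sum to one, a nearly closed web is nearly "conservative" and
  $\rho$ sits close to 1; an isolated exclusive predator–prey pair reaches
  exactly 1 while $(I-q)$ remains invertible. `mti()` therefore errors
  only when $\rho \ge 1$ strictly (non-convergent propagation), and at the
  boundary ($\rho \approx 1$) computes the inverse with a warning. The
  openness of a web — diet imports, cannibalism (whose self-loop is
  excluded from pairwise impacts but stays in the denominators), unfished
  and unpredated surpluses — is what pulls $\rho$ below 1.
* **Impacts on detritus.** The removal denominator for a detritus pool is
  its total inflow rather than its (often tiny) consumption: detritivory
  on a pool that mostly exports removes little of what the pool receives,
  so it exerts a proportionally weak negative impact. With the
  consumption-based denominator every pool would behave like a fully
  exploited prey regardless of its budget.

## Exploitation and benthic–pelagic coupling

The exploitation rate is $E_i = F_i / Z_i$ with $F_i = \sum_f Y_{if}/B_i$
and $Z_i = P/B$ (the total-mortality identity of a balanced steady state);
catches include discards. Each fleet's cumulative exploitation rate sums
its per-group contributions, $CumE_f = \sum_i (Y_{if}/B_i)/Z_i$, and is
additive: summing contributions over fleets returns each group's total
$E$. Discard intensity is reported under both common definitions
(discards/catch and discards/landings) since usage varies.

Benthic–pelagic coupling is quantified twice. By *flux*: for each group,
the consumption drawn from prey of other domains and the predation lost to
consumers of other domains, with an optional exclusion list for
lower-trophic-level compartments whose bulk fluxes would swamp the
comparison. The exclusion default is empty — a meaningful "lower trophic"
set depends on the group list, so the choice is explicit;
`sos_lower_trophic_groups()` provides the conventional set for the shipped
example model. By *impact*: the positive and negative parts of each living
group's total MTI on, and from, groups of the other domains (fleets and
detritus excluded from the domain sums).

## The synthetic web generator

`generate_web()` produces webs that are balanced by construction, with the
true $B$ and $EE$ stored alongside, and is the package's source of ground
truth: the solver must recover hidden parameters to $<10^{-9}$ relative
error, the TL solve must match fixed-point iteration, and the MTI
inversion must match the truncated Neumann series.

Construction layers consumers over producers and detritus; diets are
sampled from lower layers with connectance 0.6 and Dirichlet weights
(shape 3); rates come from standard plausible ranges (producer $P/B \in
[10, 200]$, consumer $P/B \in [0.2, 5]$ decreasing with layer, $P/Q \in
[0.1, 0.35]$); producer biomass sets the base of a pyramid whose layer
totals decrease by a factor of 4, and each layer is shrunk so no prey's
implied $EE$ exceeds 0.9; light fleet catches stay well below half of
every group's unconsumed production, so all final $EE$ lie in $(0, 1)$ and
$F < Z$ everywhere. Upper-layer consumers are partly cannibalistic (a
self-diet share scaled by $P/Q$ so that cannibalism alone implies a
self-$EE$ of 0.2–0.4), which keeps apex groups' removal denominators
positive even in unfished webs.

The generated webs are deliberately *strongly open systems*: every
consumer carries a diet import drawn from $[0.35, 0.6]$. As discussed
above, near-closed webs place the direct-impact matrix at the edge of the
convergent regime; the import leakage keeps $\rho(q)$ below 1 for most
draws, and the generator checks $\rho$ and regenerates with an incremented
sub-seed (logged) when a draw lands above. This is the main respect in
which the synthetic webs are *not* like typical shelf-sea models, which
import little: passing oracle tests on these webs validates the
arithmetic of the solver and the impact propagation, not the convergence
behaviour of any particular real parameterization. Other simplifications:
no multi-stanza age structure, no seasonal signal, diets are Dirichlet
rather than empirically clumped, and fleet catch compositions are broad.

A single integer seed drives one pseudo-random stream
(`withr::with_seed`), so every fixture is bit-reproducible across
platforms.

## The shipped example model

`inst/extdata/sos_synthetic/` is a 72-group, 18-fleet, 3-detritus model
whose *structure* — group codes, long names, domain labels, fleet
segments, a 70% diet import for the bluefin tuna group, an immigration
term for swordfish, and biomass (rather than $EE$) estimated for the
meiobenthos, euphausiid and microphytobenthos groups — mirrors a published
Mediterranean shelf–slope food-web model. All numeric values are synthetic
output of the generator (`data-raw/sos_synthetic.R`, seed 42): the
published supplementary parameter and diet tables are not redistributed in
this package, so the example model reproduces the published *shape* of
the problem (size, sparsity, mixed unknowns, import handling) but not the
published numbers, and nothing in the tests treats its outputs as
estimates of the real system.

## Problem sizes and tolerances used in validation

The test suite exercises: hand-solved 2–4 group webs (exact to machine
precision); 30-group, 3-fleet synthetic webs — 100 seeds for parameter
recovery at $10^{-9}$ relative error, 20 each for the Neumann-series
($10^{-8}$ absolute) and TL fixed-point ($10^{-10}$) oracles; recovery
fixtures at 5, 20 and 72 groups; and the 72-group example model
end-to-end, which balances in well under a second. Conservation
($Q = P + R + U$ per consumer; TST = consumption + exports + respiration +
detritus inflow) is checked to $10^{-9}$, and uniform biomass rescaling is
verified to leave $EE$, TL and MTI unchanged at $10^{-10}$.

## Known limitations

* No temporal dynamics: the package describes one balanced snapshot;
  cascades read off the MTI are comparative-statics statements, not
  simulations.
* No automatic rebalancing: inputs violating $EE \le 1$ are flagged for
  the modeller, never adjusted.
* No uncertainty propagation (no Monte Carlo over input ranges).
* Multi-stanza life stages enter as ordinary groups with their own
  parameters; the package does not derive stage-linked rates.
* The MTI warning/error policy around $\rho(q) = 1$ means nearly closed
  webs may be analysable only via the inverse, without a convergent
  path-sum interpretation.
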