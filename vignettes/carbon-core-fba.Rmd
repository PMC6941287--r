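---
title: "Constraint-based analysis of a carbon-core network: methods and design"
author: "SalinaCore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based analysis of a carbon-core network: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SalinaCore)
```

## The model

SalinaCore analyses compartmentalized stoichiometric models of
photoautotroph carbon-core metabolism, of the kind reconstructed for the
halotolerant green microalga *Dunaliella salina*: a few hundred reactions
distributed over cytosol, chloroplast and mitochondrion, with exchange
reactions moving species across the system boundary and between
compartments, a biomass pseudo-reaction draining precursors in measured
proportions, a fixed maintenance-ATP drain, and a secondary-carotenoid
branch that the organism up-regulates under stress.

Flux balance analysis treats the network as a linear program. Let $S$ be
the $m \times n$ stoichiometric matrix over the *balanced* species
(boundary species in the external compartment are excluded, so exchange
reactions appear as unbalanced columns). A flux vector
$v \in \mathbb{R}^n$, in mmol/(g dw h), is feasible when

$$S\,v = 0, \qquad lb \le v \le ub,$$

and FBA maximises a linear objective $c^\top v$ over this polytope.
Reactions without curated bounds receive the defaults
$0 \le v_j \le 100$ (irreversible) and $-100 \le v_j \le 100$
(reversible), in mmol/(g dw h). The sign convention is negative
coefficients for substrates, positive for products; exchange reactions are
written so that positive flux is uptake. The biomass flux is the specific
growth rate $\mu$ in 1/h: biomass composition coefficients are scaled to
produce 1 g dry weight per unit flux, and the importer never rescales.

## The scenario grid

Eight canonical scenarios cross two photon uptake caps (low light 320,
high light 800 mmol/(g dw h)) with two nitrate uptake caps (replete 0.19,
depleted 0.001 mmol/(g dw h)). Scenarios A–D maximise growth alone;
E–H maximise growth and then carotene. The maintenance drain is fixed at
0.92 mmol/(g dw h) in every scenario.

Two genuinely open choices are resolved as follows.

**Capped versus fixed uptakes.** The driven exchange rates are described
as *maximal* rates, so the default bound mode is `capped`
($0 \le v \le$ rate), while maintenance is always `fixed`
($lb = ub$). Under maximisation a binding cap coincides with an equality
wherever the resource actually limits the objective, so the two modes
agree on the reported optima in the limiting regimes; both modes are
implemented and selectable (`boundMode` in `makeScenario()`), since the
original computational protocol does not say which was used.

**The combined objective is lexicographic.** A combined objective
"maximise $\mu$ and Car14" could mean a weighted sum or an ordered pair.
The package implements it as lexicographic maximisation — growth first,
then carotene with growth anchored at its optimum — because the staged
scenarios are reported with *exactly* the growth rates of the
single-objective ones, which is the lexicographic signature (a weighted
sum trades growth for pigment whenever the exchange rate is favourable).
A weighted-sum mode remains available (`mode = "weighted"` in
`solveLexicographic()`) for sensitivity analysis. The anchor is an
equality constraint $c_1^\top v = z_1^\*$ held at the solver's feasibility
tolerance, not a relaxed $\ge (1-\delta) z_1^\*$: this introduces no free
parameter and reproduces stage-1 invariance to $10^{-6}$ or better.

## The LP kernel and its verification

No linear-programming package is part of this package's dependency
footprint; the kernel is a dense two-phase bounded-variable revised
simplex written for exactly this problem shape (equality rows from $S$,
finite box bounds on fluxes):

* nonbasic variables sit at a bound; the ratio test allows bound flips;
* Dantzig pricing switches to Bland's rule after a fixed iteration count,
  which guarantees termination under degeneracy (ubiquitous in FBA);
* linearly dependent rows of $S$ (conserved moieties) are dropped by QR
  rank detection, and the full system residual is re-checked on the final
  solution so an inconsistent dependent row can never yield a false
  "optimal";
* reduced-cost and ratio tolerances are $10^{-9}$ (scaled); steady-state
  acceptance is $|S v|_\infty \le 10^{-9}\max(1, \|v\|_\infty)$ and bound
  violation $\le 10^{-9}$;
* single-sided infinite bounds are supported so an uncapped improving ray
  is reported as `unbounded` together with its support; variables free on
  both sides are rejected (they do not occur in bounded flux models).

Because optimal flux vectors are generally non-unique, the *values* of
the objective stages (and the named fluxes derived from them) are the
contract; the returned vertex depends on pivoting. For reproducible flux
maps, `tieBreak = "l1"` minimises $\|v\|_1$ at the fixed stage optima,
which silences futile cycles.

The kernel is verified along two independent routes. First,
`enumerateVerticesOracle()` exhaustively enumerates basic solutions —
every choice of $\mathrm{rank}(S)$ basic columns crossed with every
assignment of nonbasic variables to their bounds — and returns the best
feasible objective; on networks of at most 12 reactions this is exact and
entirely independent of simplex logic. The test suite demands agreement
to $10^{-6}$ on over a hundred seeded random networks. Second, a panel of
fixed instances is cross-checked against an external HiGHS solver. The
oracle also cross-validates `findBlockedReactions()` (per-reaction
min/max LPs) on random networks.

Infeasibility localisation in `checkFeasibility()` uses a deletion
filter: each reaction's bound interval is relaxed in turn to
$(-10^6, 10^6)$; if the system stays infeasible the relaxation is kept,
otherwise the constraint is implicated and restored. The result is an
irreducible implicated set under this one-at-a-time scheme — a greedy
diagnostic, deliberately simpler than an exact irreducible infeasible
subsystem, which would be solver-specific.

## The synthetic generators

`makeToyPhototroph()` builds a ten-reaction, three-compartment skeleton
of the modelled biology: photon exchange `Ex01` (chloroplast), nitrate
exchange `Ex06` (cytosol), photon-to-energy conversion with yield $y_E$,
nitrate assimilation, energy transport, a mitochondrial maintenance drain
`R192` fixed at $m_{ATP}$, a biomass reaction `mu` consuming $n_N$ mmol
nitrogen and $n_E$ energy units per g dw, and a carotene branch spending
$k_{car}$ energy units per mmol pigment through the sink `Car14`. Its
optima have closed forms,

$$\mu^\* = \min\!\left(\frac{v_N^{max}}{n_N},\;
  \frac{y_E v_{light}^{max} - m_{ATP}}{n_E}\right), \qquad
  Car^\* = \max\!\left(0,\;
  \frac{y_E v_{light}^{max} - m_{ATP} - n_E \mu^\*}{k_{car}}\right),$$

valid because the internal machinery carries explicit wide capacity
($10^4$ mmol/(g dw h)) so that only the uptake caps and the maintenance
drain can bind. The defaults are chosen once as field-realistic values:
uptake caps and maintenance mirror the canonical study conditions
(320/800, 0.19/0.001, 0.92), $n_N = 5$ mmol N per g dw (about 7 %
nitrogen by weight, typical for a green microalga), $n_E = 50$ mmol
energy units per g dw, $y_E = 0.125$ energy units per photon (the order
of the photosynthetic quantum requirement), and $k_{car} = 20$ energy
units per mmol β-carotene (a C40 isoprenoid with a high reductant cost).

What the toy does and does not show: it reproduces the *sign structure*
of the published scenario analysis — zero carotene under pure growth
maximisation, maximal carotene under high light, growth collapse under
nitrate starvation, high light plus nutrient stress as the strongest
pigment inducer — and it proves the engine correct against arithmetic.
It is a stoichiometric skeleton only: no light attenuation,
photoinhibition, kinetics, or nitrogen recycling. In particular, in the
toy a higher photon cap cannot raise growth at a fixed nitrogen cap,
whereas the full network has routes that make light limiting even under
nitrogen repletion; passing toy tests therefore validates the machinery,
not the biology of any particular reconstruction.

`makeRandomNetwork()` generates sparse random networks with coefficients
in $\{\pm1, \pm2\}$ (small integers keep vertex enumeration well
conditioned), about one exchange column in five, seeded explicitly, and
always feasible because every bound interval contains zero. Orphan
metabolites are reattached so the generators never trip the structural
warnings they are not testing.

## Problem sizes and runtime choices

The verification suites are sized so the whole battery runs in minutes on
one CPU: 100 random networks of 5–9 reactions for the oracle-agreement
suite (the oracle's cost grows combinatorially, and is capped at 12
reactions by a refusal error), 200 random parameter sets for closed-form
recovery at $10^{-9}$, 100 random networks for SBML round-trip identity,
and 30 random bound-enlargement monotonicity checks. The dense simplex
comfortably handles the few-hundred-reaction scale of real carbon-core
models (about a second per solve at 221 columns).

## Import/export choices

SBML is written as Level 3 with fbc-v2 bound attributes and read in both
that form and the legacy Level 2 kineticLaw-parameter dialect
(`LOWER_BOUND`/`UPPER_BOUND`). Species with `boundaryCondition="true"`
are normalized onto the external compartment, so explicit-boundary-species
models and single-sided exchange models import identically. Compartment
identifiers map onto {cytosol, chloroplast, mitochondrion, external}
through an overridable dictionary (`defaultCompartmentMap()`); an
unmapped identifier is an error naming the id rather than a silent guess.
Stoichiometries and bounds are printed with 17 significant digits so
doubles round-trip bit-exactly, and output ordering is deterministic
(byte-identical rewrites). Ids that are not valid SBML SIds are
sanitized with the original preserved in a notes line. When a document
declares no role annotations, conventional reaction ids (`mu`/`biomass`,
`Ex01`, `Ex06`, `R192`, `Car14`) are matched case-insensitively to the
named roles, so externally produced models plug into the scenario runner
without editing; `inferRoles = FALSE` gives a strictly literal import.

Reaction tables are delimited text with a sniffed delimiter and
case-insensitive column synonyms; a missing id or equation column is a
schema error naming the missing columns, and empty annotation cells
become `NA`, never empty strings. Scenario tables are written in the
two-way printed layout (columns = scenarios) at four decimal places,
while the in-memory tables keep full precision.

## Degenerate inputs and edge policies

* A network with no balanced metabolites reduces the LP to bound
  selection; handled without equality rows.
* A reaction whose equation cancels to an empty stoichiometry is a
  validation error, not a silent zero column.
* An override with $lb > ub$ is rejected; an override with $lb < 0$ on an
  irreversible reaction flips the reversibility flag rather than creating
  an invalid object.
* Scenario solver failures are recorded per row (`status`) and the run
  continues, so one pathological scenario cannot destroy a sweep.
* The structural metabolite/reaction counts of an imported model are
  reported, never asserted: published size statements can disagree with
  each other (the carbon-core literature itself prints both 212 and 213
  metabolites for the same 221-reaction network), and the importer's job
  is to count what is in the file.

## Known limitations

Gene–protein–reaction associations are carried as opaque annotations and
never evaluated. No thermodynamic constraints, flux-variability analysis
beyond blocked-reaction detection, flux sampling, or dynamic FBA. The
deletion-filter diagnosis is greedy, not exact IIS. The simplex is dense:
adequate to a few hundred reactions, not to genome-scale
(thousands-of-reactions) models.
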