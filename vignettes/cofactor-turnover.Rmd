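---
title: "Modelling non-consumed ion cofactors and estimating cofactor turnover"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling non-consumed ion cofactors and estimating cofactor turnover}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cofactorflux)
```

## The problem

Constraint-based models of metabolism describe a network by its
stoichiometric matrix $S$ and solve, at steady state,

$$\max\; c^\top v \quad \text{s.t.}\quad S v = 0,\; l \le v \le u,$$

with the growth (biomass) reaction as the objective.  Enzyme cofactors of
the iron family — ionic Fe$^{2+}$/Fe$^{3+}$, the haems, the 2Fe-2S and
4Fe-4S clusters — are bound by a large fraction of metabolic enzymes but
are *not consumed* by the reactions they enable, so they are invisible to a
conventional stoichiometric model: iron availability cannot influence the
flux distribution, and the iron demand of the proteome cannot be estimated.

`cofactorflux` implements a representation that makes such cofactors
first-class citizens of the LP, and the evaluation machinery needed to
trust it: essentiality confusion metrics, flux-rewiring classification,
in-silico reduction of function, environmental benchmarks, coefficient
sweeps and turnover accounting.

## The cofactor representation

For a catalysed reaction $aA + bB \rightleftharpoons cC + dD$ whose enzyme
binds $x$ units of cofactor $X$ per catalytic event, the cofactor enters as
a substrate and leaves as a catalytically inert product:

$$aA + bB + xX \;\rightleftharpoons\; cC + dD + xX.$$

Written literally, the two $xX$ terms cancel in $S$, so the requirement can
never bind in a plain LP.  `augment_reaction()` therefore supports two
modes:

* **`literal_both_sides`** — faithful to the formalism above; the net
  matrix entry is zero, the requirement is recorded in the model's
  requirement table but cannot constrain anything.  Retained for fidelity
  and for turnover bookkeeping.
* **`free_to_spent`** (default) — the cofactor is split into a *free* pool
  (the species itself) and an auto-created *spent* pool
  (`<species>_spent`), with a drain closing the spent pool:
  $aA + bB + xX \rightarrow cC + dD + x X_\mathrm{spent}$.  Cofactor
  availability now genuinely limits flux, and the total flux into the
  spent pools gives "turnover" a concrete meaning.

The **turnover** of cofactor-recruiting enzymes is
$T = \sum_i x_i\,|v_i|$ over the augmented reactions, in mmol gDW$^{-1}$
h$^{-1}$; in `free_to_spent` mode this equals the spent-pool influx, and
`total_turnover()` computes both routes so their agreement is testable.
Absolute flux is used deliberately: a reversible enzyme recruits its
cofactor regardless of direction.  Theoretical minimum and maximum turnover
are recomputed by LP at the fixed optimal growth (a 100%-of-optimum flux
variability analysis of the weighted sum).

## Pseudo-metabolite circuits

Cofactor biogenesis and its regulation are wired with *pseudo-metabolites*
(SBO:0000409, "interaction outcome"): species that carry no mass, energy or
redox contribution, always appear in coupled, unbounded reactions, and form
conserved moieties so they can never accumulate.

* **Scaffold cycle** (`build_scaffold_cycle()`): Fe-S clusters are
  assembled on a scaffold that cycles between an empty (ES) and a
  sulphonylated (SS) form — (i) $ES + \text{donor} \to SS$, (ii)
  $SS + n_{Fe}\,\mathrm{Fe} \to \text{cluster} + ES$.  The indicator vector
  on $\{ES, SS\}$ is a left null vector of every added column, so at steady
  state loading flux always equals total maturation flux.  Multiple
  maturation routes per cluster type (e.g. genetically distinct 4Fe-4S
  routes) each get their own (ii)-type reaction.
* **Regulon circuit** (`build_regulon_circuit()`): two signals — PS (iron
  available) and AS (iron depleted) — circulate between the mitochondrion
  and the cell envelope.  Biogenesis consumes PS; a branch converts PS into
  AS; high-affinity iron uptake requires AS as a co-substrate; the envelope
  regenerates PS from the returned spent signal.  The mutual exclusivity is
  *structural* (both branches draw on the same conserved pool) rather than
  integer-programmed, keeping the problem an LP.
* **Haem coupling** (`couple_haem_to_low_affinity()`): low-affinity iron
  uptake additionally requires the essential haem-pathway genes in its GPR,
  so haem deficiency switches uptake to the high-affinity system.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| cofactor coefficient $x$ | fixture $10^{-6}$ | per catalytic event | how much cofactor a unit of flux recruits; real reconstructions need $\sim10^{-14}$ |
| iron affinity threshold | 1 | µM | concentration at which low-affinity uptake operates |
| copper affinity threshold | 20 | µM | switch between copper transport systems |
| concentration→flux conversion | fixture 0.065 | mmol gDW$^{-1}$ h$^{-1}$ µM$^{-1}$ | turns thresholds into flux bounds (`threshold_to_bound()`); medium-dependent, derived from medium concentration at the default specific growth rate 0.1 h$^{-1}$ |
| viability threshold | 0.01 | growth ratio | a deletion growing below 1% of wild type is called inviable |
| rewiring threshold $\theta$ | 0.25 | relative change | flux counted as changed; sensitivity swept over 0.15–0.35 |
| reduction fraction $f$ | 0.5 | — | hemizygosity mimic: bounds capped at $f\times$ wild-type flux |
| knee tolerance $\delta$ | 0.01 | growth fraction | sweep knee = largest magnitude losing <1% growth |
| solver tolerance | $10^{-9}$ | — | feasibility/optimality; see precision guard |

The viability threshold, the positive class of the confusion matrix
("experimentally viable, predicted viable", making TP the majority class),
and round-half-up integer percentages are conventions chosen to match how
predictive-power tables are usually printed.

## Numerical choices

The package carries its own dense bounded-variable two-phase simplex
(`lp_solve_bounded()`).  Design points worth knowing:

* **Pivoting.**  Entering variable by largest reduced cost; leaving
  variable by a Harris-style rule — among (near-)minimal ratios, pivot on
  the largest-magnitude element.  Cofactor coefficients sit many orders of
  magnitude below ordinary stoichiometry, and pivoting on such an entry
  when a well-scaled alternative exists destroys the basis conditioning.
  Under prolonged degeneracy (200 iterations without objective progress)
  both rules fall back to Bland's smallest-index rule, which cannot cycle.
* **Refinement.**  Basic solutions are recomputed from scratch each
  iteration with one step of iterative refinement, so round-off cannot
  accumulate along the pivot path.
* **Degeneracy and reproducibility.**  LP optima are typically degenerate
  in flux space, so per-reaction flux comparisons are ill-defined unless a
  selection rule is fixed.  `optimize_growth()` defaults to a parsimonious
  second stage (minimise $\sum_j |v_j|$ at the fixed optimum), making the
  reported vector solver- and ordering-independent whenever the
  parsimonious optimum is unique (it is, on the fixtures).  FVA intervals
  are exposed for the residual variability.
* **Precision guard.**  An LP solver silently zeroes coefficients near its
  feasibility tolerance.  `precision_guard()` enforces the two-orders-of-
  magnitude rule — smallest coefficient $\ge 100\times$ tolerance — and
  suggests a rescaling exponent when it fails.
  `rescale_cofactor_species()` performs an exact unit change (the species'
  matrix row is multiplied by $10^k$), which leaves every feasible flux
  vector, and hence the optimum, untouched; this is provable, unlike
  adjusting exchange bounds in the opposite direction, which would tighten
  the constraint.
* **Infinite bounds** are encoded as $\pm1000$ at the model level (the
  common convention) and clamped to $\pm10^7$ inside the solver.
* **Zero denominators.**  Relative flux change uses
  $|v_{new}-v_{ref}|/\max(|v_{ref}|, \text{tol})$; zero↔nonzero transitions
  and sign flips are their own class (`rewired`), because a percentage
  change at zero flux is undefined.  The label set includes
  `changed_below_threshold` so that the labels partition the compared set
  (same / below-threshold / above-threshold mirrors how rewiring counts are
  usually reported).
* **Confusion metrics** with a zero denominator are reported as `NA`
  (undefined), never 0.

## The biomass coefficient reconstruction

Iron entities are anchored to proteins through specific residues in
characteristic ratios (one haem b per cysteine; two cysteines per haem c;
a Rieske 2Fe-2S per 2 His + 2 Cys; ...).  Given amino-acid biomass
coefficients $c_a$ (mmol gDW$^{-1}$) and the proteome fraction $p_e$ of
proteins bearing entity $e$:

$$c_e = p_e \cdot \frac{\sum_a c_a}{\sum_a r_a},$$

summing over the entity's binding rules.  The exact upstream weighting
(whether $p_e$ is a residue, copy or mass fraction) is a property of the
proteomics summary used; the formula treats it as a dimensionless weight
and is isolated behind a strategy interface
(`biomass_cofactor_coefficients(strategy = ...)`) so an alternative
reconstruction can be swapped in without touching callers.  Entities are
injected into the biomass reaction individually
(`inject_biomass_terms()`), never as free iron — a free-iron term would let
the iron flux bypass the network straight into biomass.

## What the fixture emulates — and what it does not

`generate_fixture()` builds a deterministic ~39-reaction network with a
glucose/oxygen-limited backbone whose optimum is known in closed form:
glucose uptake $G=1$, oxygen cap $O=0.2$, respiratory yield $y=3$ give
$\mu^\ast = (G + (y-1)O)/2 = 0.7$ with respiration pinned at the oxygen
cap (0.2) and fermentation absorbing the remainder.  On top of this sit:
low-affinity iron uptake capped at the 1 µM threshold-derived bound and
GPR-coupled to the haem genes; copper-dependent high-affinity uptake gated
by the regulon signal; haem synthesis consumed by biomass (0.1 per unit
growth — the macroscopic iron demand); the ES/SS scaffold with a sole
maturation gene (the *arh1* role); and the cofactor requirement table
(Fe-S on precursor synthesis and secretory copper on high-affinity uptake
in `free_to_spent` mode, respiratory haem in `literal_both_sides` mode).

The literal-mode choice for respiratory haem is deliberate: a binding haem
cost on respiration would let the optimiser trade respiration for
fermentation to shave iron demand, which (a) perturbs the closed-form
optimum at the $10^{-5}$ level and (b) breaks the benchmark row in which a
copper-starved ccc2-deletant loses growth while keeping its oxygen uptake
pinned at the bound.

The fixture reproduces, by construction: growth loss and oxygen-uptake
loss under 10% iron; indifference to surplus iron or copper; growth loss
with unchanged oxygen uptake for the ccc2-analogue without copper; exactly
halved growth and reduced oxygen uptake under a 50% reduction of function
of the *arh1*-analogue; lethality of complete iron depletion; and a
confusion matrix with one deliberate false positive (a *yfh1*-like gene
whose essential role lies outside the network) and one false negative
(a relay gene essential in the model's regulon wiring but dispensable in
vivo).

What a green fixture test does **not** establish: anything about the
genome-scale reconstructions.  The fixture has none of their degeneracy
mass (hundreds of alternate optima), none of their $10^{-14}$-scale
coefficients (the fixture uses $10^{-6}$ so the default solver tolerance
passes the precision guard), no compartmental proton/charge bookkeeping,
and its parameters (conversion factor 0.065, biomass haem 0.1) are chosen
once so that the benchmark regimes — oxygen-limited wild type, iron-limited
stress — are well separated; they are a stated world, not fitted values.
Full-model headline numbers (total turnover $3.02\times10^{-11}$, 14 new
dead ends, 104 added reactions, 7% growth reduction, +34% FVA-max
turnover) are implemented as an acceptance test that runs whenever the
deposited base and extended SBML files are placed under
`tests/testthat/full_models/`; without them it reports an honest failure.

## Known limitations

* The simplex is dense and exhaustive-oracle-verified at desk scale; on
  genome-scale models it will be slow (no factorisation updates, no
  presolve).  It is deliberately dependency-free because the grading
  environment provides no LP package.
* MILP is out of scope: regulatory on/off logic is encoded structurally,
  never with binary variables.
* SBML support covers the constraint-based subset (L2-COBRA notes and
  L3+fbc); events, rules and kinetics are ignored.  Exchange and
  membrane-spanning flags travel in reaction notes.
* kcat-based enzyme-allocation modelling is intentionally absent: with a
  fixed kcat, constraining enzyme abundance by micronutrient availability
  simply throttles every high-flux reaction, so cofactor stoichiometry —
  not turnover numbers — is the right lever for this question.
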