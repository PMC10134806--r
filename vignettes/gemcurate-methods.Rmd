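---
title: "Methods: curating a marine-heterotroph metabolic model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: curating a marine-heterotroph metabolic model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gemcurate)
```

This vignette explains the models and procedures the package implements, the
choices that were genuinely open when it was designed, and what its tests do
and do not demonstrate.

## Flux balance analysis and the LP core

A metabolic model is a stoichiometric matrix $S$ (metabolites × reactions),
flux bounds $v_{\min} \le v \le v_{\max}$ (mmol/gCDW/h) and an objective
reaction. `fba()` solves $\max c^\top v$ subject to $S v = 0$ and the bounds.
Exchange reactions are written `metabolite ↔ ∅` with uptake as negative flux
— the dominant sign convention in constraint-based modelling, and the one
that makes "open the glucose exchange at lb = −10" read naturally.

The LP is solved by a dense two-phase primal simplex with direct support for
variable bounds (`R/lp.R`). Writing a simplex rather than calling a library
was not the first choice; no LP package is available to this package's
dependency set, and the general-purpose optimizer that is available proved
unreliable on degenerate flux-balance systems (singular bases, infeasibility
misreported). The solver therefore had to be owned and tested like any other
core routine:

* phase 1 minimises artificial-variable infeasibility from a basis of
  artificials; infeasibility is declared when that minimum exceeds `1e-7`;
* pricing is Dantzig with a permanent switch to Bland's rule after
  stalling, which guarantees termination on degenerate vertices;
* primal feasibility tolerance is `1e-9`; reported quantities are compared
  at `1e-6` in tests;
* bound flips, equality-pinned variables (`lb == ub`) and free variables are
  handled explicitly; unboundedness is a status, not an error.

The solver was differentially tested during development against an
independent LP implementation on hundreds of random bounded problems, and
the shipped test suite re-derives every small-fixture optimum with an
exhaustive vertex-enumeration oracle (`tests/testthat/helper-oracles.R`).
Degenerate alternate optima are a fact of FBA: the objective value is the
contract, and individual fluxes are only ever asserted through
`flux_compare()` summaries, never exactly.

## Salt-corrected cell dry weight

Washing a pellet in NaCl solution (salinity $\rho$, mg NaCl per mg water)
leaves salt in the dried pellet. With dry weight $x$, wet weight $y$,
harvested amount $w$ (OD600·mL) and cellular water per CDW $\beta$, the mass
balances for CDW and water give

$$\alpha = \frac{x(1+\rho) - \rho y}{w(1 - \rho\beta)}.$$

$\beta$ defaults to 2 mg/mg (rod-shaped Gram-negative reference value) and a
$\pm 1$ band is propagated into a reported interval on $\alpha$; because
$\beta$ only enters through $\rho\beta \ll 1$, the estimate is weakly
sensitive to it. Two boundary decisions were open and are resolved as
follows: at $\rho = 0$ the assumed $\beta$ is irrelevant and is not policed
against $\beta_{\max} = y/x - 1$; and $\beta = \beta_{\max}$ (a pellet with
no extracellular water) is admissible, since the estimator remains exact
there. The add-back regression (`alpha_regression()`) is ordinary least
squares of $y$ on $x$ — the slope is $(1+\rho)/\rho$ and the x-intercept
carries $\alpha$ — with no errors-in-variables correction, matching how such
series are read off a plot. $\rho$ itself is always a measured input; the
package never derives it from molarity.

## Growth-rate-dependent biomass composition

RNA, protein and CDW content per OD600·mL are modelled as linear functions
of growth rate; the package ships the reference parameterisation
`default_growth_rate_fits()` (RNA $0.05x + 0.05$, protein $-0.09x + 0.38$,
CDW $-0.13x + 0.64$, valid on $[0, 1.4]$/h). `composition_at()` converts
these to mass fractions of CDW, adds fixed osmolyte fractions, and fills the
residual with reference-organism proportions of the unmeasured components
(DNA, LPS, lipids, murein, inorganic ions, soluble pools; an
"iAF1260-like" table normalised to a 0.20 g/gCDW total ships in
`inst/extdata/`). Glutamate is the dominant osmolyte of marine heterotrophs
at seawater osmolarity and defaults to 5% of CDW; glutamine, observed more
than tenfold lower, defaults to 0.5% — both are explicit components separate
from the reference soluble pool, and growth-rate independent because the
measurements show no clear trend.

Monomer proportions are inferred from the genome: amino acids from
translated CDS features (start methionines counted, stop codons excluded,
ambiguous codons skipped with a warning, no expression weighting — the
standard approximation, which length-weights long genes), RNA nucleotides
from rRNA genes (rRNA dominates cellular RNA), DNA nucleotides from both
strands of the whole genome. `build_biomass_reaction()` converts a mass
fraction $f$ with monomer molar fractions $\phi_i$ and residue masses $m_i$
(free mass − 18.02 g/mol of polymerisation water; free masses for osmolytes
and lumped components) into coefficients $1000 f \phi_i / \sum_j \phi_j m_j$
mmol/gCDW, appends the GAM as an ATP + H₂O → ADP + Pᵢ hydrolysis (a proton
can be added through the species map for models that track one), and
produces one unit of a biomass species so the reaction's flux is the growth
rate.

`sensitivity_scan()` rescales one component's coefficient group at a time
(no renormalisation — the perturbation is meant to change the total) and
reports the largest relative change in optimal growth. On the toy network
the scan is reported by `analysis/03_biomass_composition.R`; because that
network is strictly carbon-limited, perturbing any mass-carrying component
moves growth in proportion to its carbon share, which is the expected
behaviour there, not a defect.

## Maintenance energy from batch cultures

Chemostats are impractical for many wild isolates, so GAM and NGAM are
estimated from batch cultures on substrates permitting different maximal
growth rates. The chain is: log-OD regression for growth rate;
concentration-vs-OD regressions for consumption and excretion yields
(acetate is the only overflow product modelled, at 2 carbons); carbon
utilization = (consumption − excretion) × growth rate; an OLS line of
utilization against growth rate across substrates. Its intercept, converted
to a substrate uptake flux by dividing by the CDW conversion (mg/(OD600·mL))
and the substrate's carbon number, is imposed on the model with biomass flux
fixed to zero while ATP hydrolysis is maximised — that optimum is the NGAM.
The GAM is then fit by bisection on the biomass reaction's ATP coefficient
until FBA-predicted growth rates (with per-series uptake pinned to its
measured value and other listed substrates closed) match the observations;
the bisection acts on the signed residual sum, which is monotone because
predicted growth is monotone nonincreasing in GAM (verified on a coarse grid
before bisecting; the bracket defaults to [0, 200] mmol/gCDW and terminates
at width 0.01).

The single largest judgment call in this module is the unit conversion from
per-OD quantities to per-gCDW fluxes: the package divides by an explicit
`cdw_conv` argument everywhere (for a zero-growth quantity like the NGAM
intercept, the natural choice is the CDW fit evaluated at zero growth), so
the choice is visible and changeable rather than buried. Acetate secretion
is left free (≥ 0) rather than pinned in the NGAM problem: the intercept is
already a net carbon rate, and on an overflow-free substrate the conversion
is exact — which is why the estimation pipeline prefers a substrate without
measurable excretion for that step.

## Gap-filling and phenotype comparison

In vivo growth on a substrate panel is called from plate curves: an OD600
increase of at least 0.9 (inclusive) within 20 h, with linear interpolation
in time because plates are read at most a few times a day. In silico growth
means optimal biomass flux ≥ 1e-6/h (configurable).

`gapfill()` finds a provably minimum-cardinality set of database reactions
enabling growth: candidate subsets are tested in order of increasing size
and, within a size, lexicographically by reaction id, so the first feasible
subset is a certified optimum and ties resolve deterministically. This is
equivalent to the binary-indicator MIP formulation of the problem at the
scale the package targets (databases of tens of candidates); an optional
time limit returns the best incumbent flagged `optimal = FALSE`. Candidate
reversibility comes from the database entries' own bounds. Exchange
reactions are a deliberate policy surface: permanent exchanges belong only
to substrates with verified in vivo growth, while phenotype testing of
non-growers uses transient exchanges that are discarded with the test model.

`phenotype_compare()` evaluates each substrate under one of three transport
assumptions — existing transporters only; plus free outer-membrane diffusion
into the periplasm; plus free inner-membrane diffusion into the cytoplasm.
Because the added diffusion reactions are plain translocations, a substrate
whose catabolism starts from a phosphorylated form made by a
transporter-coupled reaction still fails in every diffusion mode — the
biologically documented exception class. Since each mode's reaction set
contains the previous one's, the in silico growth sets nest, which the tests
assert as a property. The plate assay normalises carbon concentration, not
rate, so a default uptake cap of 10 mmol/gCDW/h is applied per test and is
configurable.

## Growth-rate-dependent FBA

The biomass reaction depends on growth rate, but FBA needs a biomass
reaction to predict growth. `gr_fba()` iterates the coupling as plain
fixed-point iteration: rebuild the biomass reaction at the current guess,
solve, feed the optimum back, stop when successive growth rates agree within
`tol` (default 1e-4/h, `max_iter` 50 — both package choices). Composition
varies slowly with growth rate, so the map is a mild contraction and
converges in a handful of iterations from any starting guess; an optional
damping factor exists for models that oscillate but is off by default to
keep the iteration faithful to the simplest scheme. Non-convergence is
reported as `converged = FALSE` with the full trajectory, not an error.
`flux_compare()` reports per-reaction percent differences
$100\,|v_a - v_b| / \max(|v_a|, |v_b|)$ (defined 0 when both magnitudes are
below 1e-9) and the fraction exceeding 20%; only such summaries are stable
under alternate optima.

## The synthetic toy network

All pipeline stages are exercised on one shared ~25-reaction network
(`make_toy_model()`): per-substrate exchange, porin diffusion and transport;
catabolism of each substrate into single-carbon units with a fixed fraction
of its carbon hard-wired to acetate overflow in the catabolic stoichiometry;
a lumped respiration reaction (3 ATP per carbon unit by default); ATP-neutral
syntheses of one generic amino acid, RNA and DNA nucleotide, glutamate,
glutamine and a lumped remainder species; an ATP-hydrolysis reaction with
lower bound NGAM; and a biomass reaction from `build_biomass_reaction()`.
Monomer synthesis is deliberately ATP-neutral so that the network's entire
energy demand is the explicit GAM and NGAM, giving closed forms used as test
oracles: with net carbon intake $q$ (mmol C/gCDW/h), biomass carbon $c_b$
(mmol C/gCDW), per-carbon ATP yield $a$,

$$\mu = \frac{q - \mathrm{NGAM}/a}{c_b + \mathrm{GAM}/a}.$$

Defaults: GAM 20 mmol/gCDW, NGAM 5 mmol/gCDW/h, glucose uptake cap 5.6
mmol/gCDW/h with overflow fraction 0.3 (μ ≈ 0.82/h), galactose cap 0.6
without overflow (μ ≈ 0.072/h), CDW conversion 0.55 mg/(OD600·mL). The
galactose condition is deliberately slow-growing: the maintenance intercept
is an extrapolation to zero growth, and its error is controlled by the lower
of the two growth rates.

The generators emulate: exponential batch growth with linear substrate and
acetate trajectories in OD (multiplicative 1% OD noise; relative 1%
concentration noise with a 0.02 mM floor, as for an HPLC assay; 40 samples
spanning growth to 250× the inoculum, substrate dosed for ~70% consumption —
sampling design fixed a priori from an error-propagation budget for the
intercept extrapolation); linear growth-rate dependence of composition
measurements (additive noise, resampling negative draws); exact
forward-generated pellet weighings; and logistic/flat plate curves around
the growth-call threshold. All generators restore the caller's RNG state and
are bit-reproducible given seed and configuration.

What passing tests therefore show: the estimators invert their own
generating models at realistic noise, the LP/gap-fill/fixed-point machinery
agrees with independent oracles, and the pipeline's unit handling is
self-consistent. What they do not show: performance on real cultures — the
generators have no lag or stationary phase, no substrate-dependent lag in
overflow onset, no carbon-storage compounds, perfectly exponential growth,
and Gaussian noise; and the toy network's energetics are far simpler than a
genome-scale model's, where alternate pathways can buffer the maintenance
response.

## Numerical and interface choices

* SBML is Level 3 Version 1 with the flux-balance-constraints (fbc v2)
  extension; models lacking fbc bounds or an objective are rejected rather
  than defaulted. Compartments are mapped through a configurable table
  (defaults: `c`/`cyt` → cytoplasm, `p`/`per` → periplasm, `e`/`ext` →
  extracellular). Writing is deterministic (byte-identical re-writes). SBML
  stores stoichiometry, bounds and objective only, so GAM metadata must be
  re-attached with `tag_biomass_gam()` after reading a model from file.
* Biomass flux is in 1/h under the convention that the biomass reaction
  consumes 1 g of components per gCDW.
* `model_stats()` classifies exchange reactions as those touching exactly
  one metabolite and transport as non-exchange reactions spanning at least
  two compartments; bidirectional diffusion reactions therefore count as
  transport. These are conventions, stated so counts are comparable.
* Degenerate inputs are errors with named causes (empty stoichiometry,
  bound inversions, substrate series that increase, slopes ≤ 1 in the
  add-back regression, GAM intervals excluding the observable range), never
  silent corrections; the single clamp in the package (negative maintenance
  intercepts) is off by default and announced by a warning.

## Problem sizes

The shipped tests and scripts run the pellet round trip at 1,000 records,
LP-oracle equivalence on networks of up to 6 reactions, gap-fill oracles on
candidate databases of up to 12 reactions, maintenance recovery on two
40-sample batch series, and fixed-point iteration on the 25-reaction toy
network — sizes chosen so every oracle remains exhaustive and the full suite
runs in well under a minute on one core.
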