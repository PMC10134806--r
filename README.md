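# gemcurate

Tools for curating a genome-scale metabolic model (GSMM) of a marine
heterotrophic bacterium grown at seawater osmolarity, exercisable end to end
on a built-in synthetic toy network.

Marine isolates pose two practical problems for constraint-based modelling
that this package addresses with tested, reusable code:

1. **Cell dry weight at high salt.** Cells grown at ~0.4 M NaCl lyse when
   washed in water, so pellets must be washed in NaCl solution — and the
   residual salt inflates the measured dry weight. `gemcurate` implements the
   corrected estimator and its add-back regression cross-check.
2. **A biomass reaction that tracks growth rate.** RNA, protein and CDW
   content per OD600·mL vary linearly with growth rate; the package turns
   those fits plus genome-derived monomer frequencies into growth-rate
   dependent biomass reactions, estimates maintenance energy (GAM/NGAM) from
   batch cultures coupled to flux balance analysis, gap-fills draft models
   against growth phenotypes, and runs FBA with the biomass reaction rebuilt
   self-consistently at the predicted growth rate.

## The core computations

**Flux balance analysis.** For a stoichiometric matrix `S`, flux vector `v`
with bounds `v_min ≤ v ≤ v_max` and objective weights `c`, FBA solves the
linear program

```
maximize  Z = cᵀ v   subject to   S v = 0,   v_min ≤ v ≤ v_max
```

with biomass production as the default objective (the biomass reaction flux
is the growth rate, 1/h). The LP is solved by a bounded-variable two-phase
simplex implemented in the package and validated against an exhaustive
vertex-enumeration oracle.

**Salt-corrected CDW.** For dry weight `x` (mg), wet weight `y` (mg),
harvested amount `w` (OD600·mL), wash salinity `ρ` (mg NaCl per mg water) and
assumed cellular water `β` (mg/mg CDW), the CDW per OD600·mL is

```
α = (x (1 + ρ) − ρ y) / (w (1 − ρ β)),     β < β_max = y/x − 1.
```

Plotting `y` against `x` across an add-back dilution series estimates `ρ`
from the slope and `α` from the x-intercept without assuming `ρ` known.

**Maintenance energy.** Per-substrate batch cultures give growth rate
(log-OD regression), consumption and excretion yields (concentration-vs-OD
regressions, mM-C/OD600). The carbon utilization rate
`(consumption − excretion) × growth rate`, regressed on growth rate across
substrates, yields an intercept (carbon burned at zero growth → NGAM via FBA
maximizing ATP hydrolysis with biomass shut off) and a slope (biomass carbon
plus GAM; the GAM is fit by bisection until FBA matches observed growth).

**Gap-filling.** A minimum-cardinality set of database reactions enabling
biomass flux is found by certified search (all smaller candidate subsets
refuted), with growth in vivo defined as an OD600 increase ≥ 0.9 within 20 h
and growth in silico as biomass flux ≥ 1e-6/h.

## Worked example

The analysis scripts run the whole pipeline on the synthetic toy network
(known truth: GAM 20 mmol/gCDW, NGAM 5 mmol/gCDW/h):

```sh
Rscript analysis/01_build_toy_model.R
Rscript analysis/04_maintenance_estimation.R
```

which prints

```
Toy network written to results/toy_model.xml
  25 reactions (11 internal / 8 transport / 6 exchange), 24 metabolites
Predicted growth rates (1/h):
 substrate uptake_cap overflow_fraction growth_rate
   glucose        5.6               0.3  0.81582813
 galactose        0.6               0.0  0.07217515
...
Per-substrate estimates:
  glucose   mu = 0.8156/h, consumption 22.72, excretion 6.77 mM-C/OD600
  galactose mu = 0.0722/h, consumption 27.51, excretion 0.00 mM-C/OD600
Maintenance line: slope 14.83 mM-C/OD600, intercept 0.915 mM-C/OD600/h
NGAM = 4.992 mmol ATP/gCDW/h (truth 5), GAM = 20.273 mmol ATP/gCDW (truth 20)
Recovery errors: NGAM 0.2%, GAM 1.4%
```

The two batch cultures are simulated with 1% measurement noise, reduced to
yields, and the maintenance parameters are recovered through the same
FBA-based procedure a real dataset would go through. The remaining scripts
(`02` CDW estimation, `03` biomass composition, `05` gap-filling and
phenotyping, `06` growth-rate-dependent FBA) follow the same pattern and
write their tables under `results/`.

In code, the same example is three calls:

```r
library(gemcurate)
spec  <- toy_network_spec()
glc   <- simulate_batch(spec, "glucose",   sim_config(1))
gal   <- simulate_batch(spec, "galactose", sim_config(1))
estimate_maintenance(make_toy_model(spec), list(glc, gal), cdw_conv = 0.55,
                     substrate_ids = c("EX_glucose", "EX_galactose"))
```

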