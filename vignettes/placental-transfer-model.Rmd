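---
title: "A maternal-fetal PBPK model of placental drug transfer: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A maternal-fetal PBPK model of placental drug transfer: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfpbpk)
```

## The problem

Most drugs given to a pregnant woman reach the fetus. How much, and how
fast, is governed by the placenta: maternal blood perfuses the intervillous
space, drug crosses the apical membrane of the syncytiotrophoblast into the
trophoblast cell, leaves through the basolateral membrane into the fetal
interstitium of the placenta, and is carried to the fetus by the umbilical
circulation. Two features of this chain are easy to get wrong in a
compartmental model and are the focus of this package:

* **Plasma protein binding differs between mother and fetus.** Fetal albumin
  is synthesised by the fetus (albumin does not cross the placenta), and at
  38 weeks its plasma concentration (about 38.6 g/L) is still below the
  non-pregnant adult level (about 46.4 g/L). Only unbound drug diffuses, so
  the fetal fraction unbound `fu_fetal` belongs in every fetal compartment
  equation, not the maternal one.
* **Influx and efflux across the trophoblast need not be symmetric.**
  Transporters such as P-gp sit in the apical membrane. The model carries
  independent dimensionless scaling factors on the influx and efflux terms
  of both the apical (`f_in`, `f_out`) and basolateral (`g_in`, `g_out`)
  membranes, all defaulting to exactly 1 (symmetric passive transfer).

The package ships parameter sets for eight drugs spanning three orders of
magnitude in protein binding and apical transfer clearance: acyclovir,
cefuroxime, diazepam, dolutegravir, emtricitabine, metronidazole,
ondansetron and raltegravir.

## Model structure

### Fetal sub-compartments and the exchange matrix

Each fetal organ compartment (the lumped fetus and the fetal placenta) is
resolved into four sub-compartments — blood cells (bc), plasma (pls),
interstitial (int) and intracellular (cell) — holding molar amounts
\(N\) (µmol). Passive, gradient-driven exchange is written as a single
4×4 matrix \(E\) acting on the concentration vector, and perfusion enters
the bc and pls rows only, split by hematocrit:

\[
\frac{d}{dt}\begin{pmatrix}N_{bc}\\ N_{pls}\\ N_{int}\\ N_{cell}\end{pmatrix}
= Q\begin{pmatrix}HCT\,(C_{bc}^{in}-C_{bc})\\ (1-HCT)\,(C_{pls}^{in}-C_{pls})\\ 0\\ 0\end{pmatrix}
+ E\begin{pmatrix}C_{bc}\\ C_{pls}\\ C_{int}\\ C_{cell}\end{pmatrix}.
\]

The entries of \(E\) carry a global `fu_fetal` prefactor and three
clearance products (permeability × surface area, converted to L/min):
plasma–blood cell exchange normalised by the blood-cell partition
coefficient \(K_{bc}\); plasma–interstitial exchange normalised by the
interstitial:plasma partition coefficient

\[
K_{int,pls}(fu) = \Bigl(f_{water,int} + \tfrac{f_{prot,int}}{f_{prot,pls}}
\bigl(\tfrac{1}{fu} - f_{water,pls}\bigr)\Bigr)\,fu ,
\]

evaluated at the *fetal* fraction unbound (water fractions 0.935/0.926 and
protein-fraction ratio 0.37, as in the adult); and
interstitial–intracellular (basolateral) exchange whose intracellular-side
coefficient is `fu_maternal / (fu_fetal * K_cell_pls)`. The last point is
subtle: the intracellular partition coefficients were predicted by methods
that carry the *maternal* fraction unbound as a discrete multiplier, so the
fetal correction multiplies by `fu_maternal/fu_fetal`, after which the
fetal fu cancels out of the intracellular term
(`k_water_cell_corrected()`). Every column of \(E\) sums to zero — passive
exchange conserves mass — and this is enforced by construction and tested
against 1,000 randomised parameter draws.

Setting `fu_fetal = fu_maternal` collapses the matrix exactly to the
single-fu formulation (`legacy_exchange_matrix()`, an independent
implementation kept as the reference for this identity).

At zero net flux the sub-compartment ratios have closed forms
(`equilibrium_concentration_ratios()`): \(C_{int}/C_{pls} =
K_{int,pls}(fu_{fetal})\) and \(C_{cell}/C_{pls} = fu_{fetal}
K_{cell,pls}/fu_{maternal}\). A corollary used throughout the tests: with a
symmetric barrier and a constant maternal concentration, the fetal:maternal
total plasma concentration ratio approaches \(fu_{maternal}/fu_{fetal}\).

### The trophoblast barrier

Apical transfer (maternal plasma ↔ trophoblast cell) is

\[
J_{ap} = f_{in}\,CL_{ap}\,fu_M\,C_{pls,M}
       - f_{out}\,CL_{ap}\,fu_M\,\frac{C_{cell,F}}{K_{apical}},
\]

with the *maternal* fraction unbound on both terms, exactly as the
equilibrium is defined for this membrane; the fetal-side binding asymmetry
enters through the basolateral coefficients instead. `K_apical` (maternal
plasma referenced) and `K_cell_pls_fetal` (fetal plasma referenced) are
stored as two distinct fields even though the shipped values are equal,
because only the apical one appears in \(J_{ap}\) — which is why doubling
`K_apical` is exactly equivalent to halving `f_out` (verified to solver
precision in the tests).

The basolateral transfer clearance is the product of the drug's organ
permeability and the trophoblast interstitial–intracellular surface area
(56,700 dm²): `basolateral_clearance(2.73e-6)` gives 0.015 L/min
(cefuroxime, below its apical 0.20 L/min — basolaterally limited) and
`basolateral_clearance(1.69e-2)` gives 96 L/min (ondansetron, far above its
apical 3.11 L/min).

`flow_limitation_diagnostic()` compares `fu_maternal * CL_apical` with the
maternal placental blood flow (0.75 L/min): metronidazole's 9.0 L/min makes
it the one flow-limited drug in the library; all others are
permeability-limited.

### Fraction unbound scaling

`estimate_fetal_fu()` scales an adult fraction unbound by the
albumin-concentration ratio under linear single-protein binding.
`scale_fu_binding_sites()` generalises to different binding-site numbers
and association constants via the capacity product \(n\,K_a\,C_{alb}\).
For diazepam, applying reported fetal/adult binding-site numbers (0.83 vs
1.02) and association constants through this linear form yields 0.0217 —
not the 0.024 sometimes quoted for that dataset (whose association constant
appears with an implausible 10⁻⁵ M⁻¹ exponent, presumably 10⁵); the
package keeps the closed form and documents the discrepancy rather than
guessing. The library's maternal and fetal fu columns are authoritative
inputs and are not recomputed, because the gestational-age-resolved albumin
values behind them are not part of the library (back-calculation implies a
term albumin nearer 43–44 g/L than the 38-week 38.6 g/L).

### The maternal core

The maternal side is a deliberately reduced whole-body core — venous and
arterial blood, lung, liver, kidney, rest-of-body, intervillous placenta,
and a gut-lumen depot — with perfusion-limited tissues (uniform Kp),
first-order oral absorption, and linear hepatic/renal clearances acting on
the unbound organ-outflow concentration (so apparent clearance is capped by
organ perfusion, the well-stirred limit). It is **not** any published
pregnancy parameterisation: its per-drug Kp/CL/ka/F defaults
(`maternal_defaults()`) are order-of-magnitude literature values chosen so
maternal half-life and peak concentration are of the right order.
Everything that depends on maternal kinetics is therefore evaluated through
properties (conservation, linearity, analytic limits, matrix-exponential
agreement), never through maternal concentration values.

Placental-flow perturbations are redistributed to rest-of-body so cardiac
output is unchanged.

## Simulation machinery

* **State in amounts.** The 23-state system is integrated in µmol with
  `deSolve::lsoda`; concentrations are derived on output. Mass conservation
  is then a literal row sum: with clearances zeroed, total amount drifts by
  less than 10⁻⁹ (relative) over 24 h at the test tolerances.
* **Tolerances.** Defaults `rtol = atol = 1e-10` (population runs use
  1e-8). Halving tolerances moves the umbilical AUC by far less than
  0.01%.
* **Dosing.** IV boluses add `dose/MW × 1000` µmol to maternal venous
  blood; oral doses to the depot with bioavailability applied at
  absorption; infusions are constant-rate windows. Repeated regimens are
  integrated interval by interval (coarse burn-in grid, interval/200) until
  the umbilical-vein AUC over one interval changes by <1% between
  consecutive intervals; the following interval is reported, re-based to
  its dose.
* **Non-negativity** is a solver-accuracy property, not enforced by
  clipping; any excursion below −10⁻⁹ µmol raises a warning flagging
  solver failure.
* **Observation windows.** The AUC to the last observation is tied to each
  drug's clinical sampling span at delivery, carried as `tlast_h` in the
  library (4 h for metronidazole and 6 h for ondansetron, whose delivery
  studies contain essentially no elimination-phase data; 8–24 h for the
  others). The sensitivity driver uses these windows by default.

### Virtual populations

`simulate_population()` draws independent lognormal parameter variability
(default CVs: 30% on clearances, absorption and apical transfer clearance;
20% on tissue partitioning; 15% on placental flow — package defaults,
documented here precisely because the real interindividual variability
structure of a pregnancy database is out of scope). Each individual draws
from a stream seeded as `(master_seed × 1000003 + i) mod (2³¹ − 1)`, so
increasing `n` never reshuffles earlier individuals. Summaries are
pointwise geometric means and empirical 5th/95th percentiles; the geometric
mean of any profile containing a zero is reported as zero. The default
population size is 500.

### Sensitivity analysis

`run_sensitivity()` follows the one-target-at-a-time protocol: placental
blood flow (factors 0.5 and 2), joint apical scaling (2, 5, 10), one-sided
apical influx or efflux (0.5, 0.75, 1.5, 2), or joint basolateral scaling
(1.5, 2, 5, 10) — never apical and basolateral together. Because large
changes in placental transfer parameters have a negligible effect on
maternal concentrations, the maternal arterial profile is computed once
from the unperturbed model and imposed as a common forcing on every sweep
member; deltas on the umbilical-vein AUC then isolate the placental-fetal
response, and maternal output is deliberately not reported. In the default
configuration a two-fold flow change moves the umbilical AUC by more than
1% only for the flow-limited metronidazole parameterisation (with
cefuroxime the runner-up), while one-sided apical scaling moves the
umbilical level roughly in proportion to the influx:efflux ratio for every
drug.

## The synthetic observed-data generator

`generate_observed_fixture()` emulates the defining nuisance of
delivery-time pharmacokinetic sampling: observation times scattered
uniformly over a window (deliveries happen when they happen), multiplicative
lognormal residual error with median 1 and a stated CV, and seed
reproducibility. Because the noise has median 1, its mean is
\(e^{\sigma^2/2}\) with \(\sigma^2 = \log(1+CV^2)\); the mean prediction
error of truth against fixture therefore converges to that known offset,
which the tests verify at n = 10,000. What the generator does **not**
emulate: between-subject kinetic variability correlated across a subject's
samples (each record is independent), censoring at the quantification
limit, and dose-time recording error. Passing metric tests on fixtures
shows the evaluation arithmetic is right, not that the model fits real
delivery data.

Evaluation metrics are the mean prediction error
\(\mathrm{MPE} = \tfrac{100}{n}\sum (C_{sim,i}-C_{obs,i})/C_{obs,i}\), the
mean squared error, and the linear trapezoidal AUC to the last observation
(from time zero, or from the last dose for repeated regimens). Linear — not
log-linear — trapezoids are used everywhere, including the decline phase;
this is the conservative default and is stated so users can compare.
Simulated profiles are interpolated linearly onto observed timepoints
before the metrics are applied. Dose normalisation
(`dose_normalize()`) scales concentrations by the dose ratio assuming
linear kinetics, as used to pool the 5/10 mg diazepam and 750/1,500 mg
cefuroxime studies.

## Parameter provenance and invented defaults

Values carried in the shipped library (fractions unbound, intracellular
partition coefficients, Caco-2 permeabilities, apical transfer clearances,
posologies, the 56,700 dm² basolateral area, 0.75 L/min placental flow,
plasma composition constants, the printed cefuroxime and ondansetron
basolateral permeabilities) are inputs taken as published. The following
are package defaults, chosen once and documented here:

* **Basolateral permeabilities for the other six drugs** (flagged
  `assumed` in `drug_library.csv`): set so the basolateral clearance is 5×
  the apical clearance, i.e. non-limiting — the neutral assumption for
  drugs whose organ permeability is unpublished.
* **Fetal geometry** (`fetal_geometry()`): a term fetus of ~3.5 L split
  bc/pls/int/cell = 0.12/0.15/0.90/2.30 L; fetal placenta 0.47 L;
  umbilical arterial/venous pools 30/50 mL; amniotic fluid 0.8 L (isolated
  — its amount never changes, and the tests assert it); umbilical flow
  0.36 L/min; fetal hematocrit 0.45. Transcapillary and blood-cell
  exchange products are set to a few L/min — fast enough never to be
  rate-limiting, as standard for small molecules — so that the trophoblast
  membrane remains the barrier.
* **Molecular weights** (not part of the published tables) are standard
  values.
* **Maternal defaults** as described above.

## Problem sizes used by the test-suite

The suite exercises the full model at sizes chosen to keep every check
sharp: conservation and equivalence runs over 24 h at 5-min output;
equilibrium-ratio runs over 30 days of constant maternal exposure at
~2.4-h output (the slowest drug, dolutegravir, settles to 0.2% of its
asymptote); the matrix-exponential oracle on the full 23-state cefuroxime
system; population determinism at n = 4–6; and the metric sampling-theory
check at n = 10,000 fixture records.

## Known limitations

* The maternal core is a stand-in with order-of-magnitude kinetics;
  absolute maternal (and hence fetal) concentration *values* are
  illustrative, and no claim of agreement with any clinical dataset is
  made or tested.
* No placental transporters (Michaelis–Menten kinetics), no placental
  metabolism, no pH/ion-trapping: asymmetric transfer is represented
  phenomenologically by the four scaling factors.
* No fetal elimination pathways; no amniotic-fluid exchange.
* Binding scaling assumes one protein, one site class, linear binding;
  drugs with substantial α1-acid-glycoprotein binding are outside the
  intended envelope.
* The apical clearance calibrator hook
  (`apical_clearance_from_calibrator()`) is a plain linear scaling and is
  never invoked silently; the richer in-vitro-to-in-vivo calibration behind
  the shipped clearances is not reproduced (and the tests document that a
  single linear factor does not recover the shipped values exactly).
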