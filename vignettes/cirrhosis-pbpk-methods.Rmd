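---
title: "A semi-PBPK model for CES1 substrates and their metabolites in liver cirrhosis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ces1pbpk)
```

This vignette is the package's account of its science: the model structure
and its assumptions, the parameters that matter and their defaults, the
conventions adopted where the problem was genuinely underdetermined, and
the limits of what the test suite demonstrates.

## Why a *semi*-PBPK model

The compounds handled here — six CES1-activated prodrugs (enalapril,
benazepril, cilazapril, perindopril, temocapril, oseltamivir) and three
CES1-inactivated drugs (flumazenil, pethidine, remimazolam) — are eliminated
almost exclusively by the liver and kidneys, and absorbed, when oral, in the
small intestine.  A whole-body PBPK model would add a dozen tissues whose
partition coefficients are poorly known and which contribute nothing but
distribution volume.  The semi-PBPK structure keeps mechanistic resolution
exactly where disease acts — gut lumen and wall, portal vein, liver,
kidney — and lumps everything else into a systemic pool of apparent volume
`V_sys` with up to two empirical peripheral compartments (`K12/K21`,
`K13/K31`).  This is the standard trade-off against overparameterisation for
drugs with organ-restricted elimination.

## Compartments and flows

Amounts are in mg, volumes in mL, times in min throughout.  The state for a
parent drug is: stomach and three intestinal lumen segments (oral dosing
only), three gut-wall segments, portal vein, liver, kidney, systemic pool,
plus peripherals.  A tracked metabolite carries the same circulation
structure minus the lumen/absorption states, and is formed inside the liver.

* **Lumen.** Gastric emptying and segmental transit are first order
  (`K_t`, per min, four values).  Each segment loses drug to its gut wall at
  `ka_i = 2 P_eff / r_i` (cylindrical surface-to-volume with segment radius
  `r_i`); drugs parameterised directly with a first-order `ka` use it
  uniformly across segments.  Ileal outflow is unabsorbed (faecal) loss.
  There is no absorption from stomach or colon.
* **Gut wall, kidney** are perfusion-limited: venous outflow concentration
  is `C_tissue · Rb / K_T:P` (tissue:plasma partition, re-expressed in blood
  via the blood:plasma ratio `Rb`).
* **Liver** is well-stirred: inflow `Q_LA · C_art + Q_PV · C_pv`, outflow
  `Q_L · C_out` with `C_out = C_liver · Rb / K_L:P`.  Each elimination
  pathway removes `CL_int · fu_b · C_out` (linear) or
  `Vmax · Cu / (Km + Cu)` with `Cu = fu_b · C_out` (saturable); biliary loss
  is `CL_bile · fu_b · C_out`, irreversible (no enterohepatic
  recirculation).
* **Kidney** removes `CL_int,K · fu_b · C_out,K`; because elimination draws
  on the emergent venous concentration, the steady-state renal clearance is
  automatically flow-limited, `Q_K fu CL_int,K / (Q_K + fu CL_int,K)`.
* **Systemic pool** closes the circulation; every node's inflows and
  outflows balance exactly, which the mass-balance ledger verifies to
  machine precision at run time.  Intravenous doses enter here, bolus as an
  initial condition, infusions as a piecewise-constant rate with an
  integrator restart at the window edge.

Plasma concentration is reported as `(A_sys / V_sys) / Rb`, i.e. `V_sys` is
treated as blood-referenced with a plasma conversion at the output.  For
twelve of the fifteen compounds `Rb = 1` and the distinction is moot.

**Why this liver/kidney formulation and not another.**  The back-calculated
intrinsic clearances in the compound table pin it down.  Remimazolam's
tabulated `CL_int` (79,212.96 mL/min) is exactly the well-stirred inversion
`Q·CL_b/(fu_b (Q − CL_b))` of its blood clearance; cilazapril's tabulated
hepatic `CL_int` (199.7 mL/min) is recovered, to the printed precision, only
if one first subtracts a *flow-limited* renal blood clearance
(77.5 mL/min) from the total 205 mL/min and then inverts.  Alternative
conventions (renal clearance as `fu·CL_int,K` without flow limitation,
elimination driven by tissue rather than venous concentration) fail this
closed-form consistency check, so the emergent-venous formulation is used
for both organs and both species.

**Unbound fraction convention.**  The tabulated binding parameter is
`fu_b`, the unbound fraction in blood, and the engine uses it against blood
concentrations — the dimensionally consistent pairing, and the one the
inversion identities above assume.  For the three compounds with `Rb ≠ 1`
(enalapril, enalaprilat, pethidine) an alternative reading — using the
unbound fraction in plasma `fu_p = fu_b·Rb` against blood
concentrations — changes predictions by up to ~35%; neither convention
reproduces every previously published prediction simultaneously, and the
package keeps the internally consistent `fu_b` form.

## Saturable metabolism

Pethidine's two hepatic routes (CES1 and CYP2B6) are Michaelis–Menten,
tabulated per mg of microsomal protein.  Whole-liver capacity is
`Vmax · MPPGL · liver mass`, with MPPGL (microsomal protein per gram of
liver) defaulting to 40 mg/g — the standard adult literature value, exposed
as a `build_system()` argument — and liver mass taken as the functional
liver volume at 1 g/mL.  `Km` (µmol/L) is converted to mass units with the
molar mass stored in the fixture.  In the linear limit this reproduces
`(Vmax/Km)·MPPGL·liver mass`, about 404 mL/min (CES1) and 1022 mL/min
(CYP2B6) for pethidine in a healthy liver, and at clinical doses the model
is only mildly nonlinear: clearance falls strictly, but by well under a
percent, between 25 and 70 mg.  Dose-linearity for every other compound
holds to 0.1%, which the test suite asserts.

## Healthy-to-cirrhosis translation

One rule per mechanism, each testable in isolation:

| quantity | rule | source of the factor |
|---|---|---|
| CES1 pathway `CL_int` | × CES1 content ratio × liver-volume ratio | hepatic CES1 mg/g: 2.45 / 2.45 / 1.715 / 0.735 (healthy/A/B/C) → factors 1, 0.7, 0.3 |
| CYP2B6 pathway | × CYP2B6 content ratio × liver-volume ratio | 17 / 17 / 15.3 / 13.6 pmol/mg |
| UGT pathway | × 0.62 × liver-volume ratio | exposure change of the UGT-cleared reference substrate metoprolol in cirrhosis; a single number applied to all grades (documented limitation) |
| biliary `CL_bile` | × MRP2 activity ratio × liver-volume ratio | MRP2 0.54 in all grades |
| `fu_b` | `1/(1 + (1−fu)(P'/P)/fu)` | albumin for all compounds except pethidine (α1-acid glycoprotein) |
| `V_sys` | × fu ratio | unbound distribution volume assumed disease-invariant |
| `CL_int,K` | × GFR ratio | 82/105 mL/min, identical for all three grades as tabulated |
| `P_eff` or `ka` | × lactulose/rhamnose ratio | intestinal permeability marker 0.037 / 0.046 / 0.052 / 0.057 |

Saturable pathways scale `Vmax` by the content factor only; the engine
rebuilds whole-liver capacity from the (already smaller) cirrhotic liver
mass, so the liver-volume ratio is not applied twice.  Translating with the
healthy physiology on both sides is the identity on every field — a
property test — which is also why the fixed UGT factor resolves to 1 when
source and target population coincide.

## Virtual population

Individuals are generated *after* cirrhosis translation by multiplying each
of: every hepatic pathway clearance (or `Vmax`), `CL_int,K`, `fu_b` (capped
at 1), `V_sys`, `P_eff` or `ka`, and the three partition coefficients, by
an independent draw from Uniform(0.8, 1.2) — parent and metabolite records
perturbed independently.  The uniform law is a choice (only the 80–120%
range is prescribed); independence across parameters is likewise assumed for
want of a published correlation structure.  Draws come from a counter-based
substream per individual, so results are reproducible from `(seed, n)` and
independent of evaluation order; a failing individual is logged and redrawn.
With symmetric multiplicative noise the population mean AUC stays within
Monte-Carlo error of the base case (asserted at n = 1000), so percentile
bands, not the mean, carry the information.

## Non-compartmental summaries

AUC uses the plain linear trapezoid (the simplest defensible default; the
convergence test verifies the expected O(h²) behaviour), with optional
log-linear tail extrapolation from the last three positive samples for
AUC(0–∞) and `CL = dose / AUC(0–∞)` for intravenous dosing.  Exposure
ratios between populations (AUCR, CmaxR) dose-normalise before dividing,
matching how multi-study comparisons are made.  The conventional acceptance
bands — 0.5–2-fold, and 0.8–1.25 as the strict bioequivalence-style
band — are provided by `fold_check()`.

## Simulation horizon, and comparability with previously published AUC0–t values

The default horizon is 48 h with a 0.1-min output grid over the first six
hours.  Published AUC0–t values for these drugs depend on each clinical
study's last sampling time, which is rarely stated alongside the model
predictions; this package deliberately uses one uniform horizon rather than
guessing per-study sampling schedules.  The consequence is visible and
systematic: for metabolites with long terminal phases (enalaprilat,
perindoprilat, oseltamivir carboxylate), AUC(0–48 h) approaches AUC(0–∞)
and therefore exceeds published AUC0–t predictions that were truncated at
~10–24 h, by factors up to ~1.6–1.9; dose-normalised *ratios* between
populations inherit a smaller bias.  Closed-form identities (dose/CL),
which are horizon-free, agree with the engine to 0.5%, so these deviations
reflect the truncation convention, not the kinetics.  `reproduce_tables()`
accepts a custom horizon for users who know a study's sampling span.

## Sensitivity analysis

The one-at-a-time scan uses the conventional fold levels (portal-vein flow,
kidney flow, transit 1/2–2×; hepatic arterial flow, hepatic `CL_int`,
permeability 1/3–3×; GFR 0.5–1.5×; unbound fractions 0.7–1.3×) and ranks
parameters by the *span* — the max/min ratio of AUC across levels — since no
standard scalar is prescribed for qualitative orderings.  With this metric,
permeability and hepatic intrinsic clearance dominate oral parent exposure
(their order can swap: for enalapril the hepatic-clearance span, 1/3–3×,
slightly exceeds the permeability span), permeability and GFR dominate the
metabolite, and hepatic arterial flow is last — the expected pattern for a
portally perfused, well-stirred liver.  The decomposition mode switches one
disease factor at a time from healthy to cirrhotic (transit, portal flow,
hepatic `CL_int`, permeability, GFR, kidney flow, binding) and confirms the
mechanistic directions: losing CES1 activity alone raises parent exposure;
losing GFR alone raises metabolite exposure; the fully translated run is, by
construction, identical to the cirrhosis base case.

## Numerical choices

* `deSolve::lsoda`, rtol 1e-8, atol 1e-10 mg; stiff-capable because liver
  uptake/partition rates and slow peripheral exchange differ by orders of
  magnitude (remimazolam couples `K31 = 0.5057` with `K21 = 0.000476` per
  min).
* The right-hand side is implemented twice: reference R and compiled C
  (the convention among PK simulators, and ~15× faster); the test suite
  asserts agreement between the two on full trajectories.
* Infusions restart the integrator at the window edge rather than relying
  on step-size control to find the discontinuity.
* Mass balance — administered = stored + eliminated + unabsorbed, and
  metabolite formed = metabolite stored + eliminated — is checked pointwise
  on every output grid; closure is at machine precision for intact systems
  and the ledger flags deliberately corrupted ones (negative-control test).
* Degenerate inputs: zero dose yields identically zero concentrations; a
  zero pathway clearance is legal; `Km = 0`, extraction ratios ≥ 1 in the
  well-stirred inversion, and negative folds are rejected with named errors.

## What the tests do and do not show

The synthetic-data side of the suite (the bundled parameter fixtures plus
the virtual-population generator) emulates the *published study
conditions*: tabulated compound parameters, four physiology columns, single
doses, 70-kg subjects, 1000-subject uniform variability.  Green tests
demonstrate internal consistency — conservation, closed-form limits,
reproducibility, monotonicity — and faithful implementation of the scaling
rules.  They do not demonstrate clinical predictivity for real patients:
etiology-, sex- and genotype-dependent CES1 variation, correlated
physiological parameters, protein-binding measurement error for the highly
bound compounds (benazepril, temocaprilat), multiple dosing, and
enterohepatic recirculation are all outside the model.  Comparisons against
previously published predicted AUC0–t values additionally carry the
truncation caveat above: part of any discrepancy is the unknown per-study
sampling horizon, not the model.

## Problem sizes used by the shipped checks

Simulations run to 48 h (24 h inside the broader property sweeps); the
population checks use the full n = 1000 with a fixed seed; the
dose-linearity and mass-balance sweeps cover all nine parent compounds
under their study routes.  These sizes match the study conditions the
package models and keep the whole suite comfortably within a coffee break.
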