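---
title: "An anatomic pulmonary model for regional lung damage and performance decrement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An anatomic pulmonary model for regional lung damage and performance decrement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulmodpm)
```

## What the model is

`pulmodpm` simulates respiratory gas exchange breath by breath in a lung
with explicit anatomy, and couples it to a whole-body control and metabolic
layer so that an injury imposed on part of the lung propagates all the way
to arterial oxygenation, ventilatory response and time to fatigue.

Three ideas organize the model:

1. **Anatomy carries heterogeneity.** The human lung is an 18-compartment
   asymmetric upper airway tree feeding 19 segments; each segment owns a
   conducting dead-space compartment, a variable-volume alveolar
   compartment and a serial capillary train. Regional ventilation and
   perfusion are gravity-dependent: per percent of lung volume they fall
   linearly with height above the lung base (slopes −0.00031 and −0.0009;
   intercepts 0.064 and 0.1). Because perfusion has the steeper slope, the
   perfusion distribution is more heterogeneous than ventilation — the
   familiar upright V/Q gradient.
2. **Damage is fluid.** Injury — chemical permeability edema, blast or
   blunt trauma — is quantified as fractional lung weight gain ΔW per
   segment. Weight gain maps to the two parameters that actually impair gas
   exchange: a per-segment fractional reduction of the oxygen diffusing
   capacity, and a global shunt (blood bypassing gas exchange), coupled
   linearly by `shunt ≈ 0.15 × D_L-reduction`.
3. **Performance is oxygen accounting.** Metabolic demand rises linearly
   with workload; delivery is cardiac output times arterial oxygen content
   (with a maximal cardiac output). Whenever demand outruns delivery an
   oxygen deficit accumulates; fatigue is declared when the deficit exceeds
   capacity, which defines the time-to-fatigue endpoint.

## Governing equations and their discretization

Airway compartments are well mixed: `V dC/dt = V̇ (C_in − C)`, with the
inlet taken from the parent on inhalation and from the flow-weighted mix of
daughters on exhalation. Wall uptake is neglected for the respiratory
gases. The alveolar balance adds volume change and membrane diffusion;
partial pressure and gas-phase concentration interconvert by `P = C·RT`
with `RT = 760·310/273 ≈ 863` mmHg per (ml STPD/ml). Each capillary tube is
discretized into `n = 10` serial divisions (a convergence check doubling
`n` until the outlet pressure moves < 0.1 mmHg supported the default);
division contents follow

```
dC_i/dt = n Q_Tot f_Q,k / (V_cap f_k) (C_{i−1} − C_i) + D_L/V_cap (P_Alv − P_i)
```

which is algebraically the same update whether written with per-division
volumes and flows or with the combined coefficients (the test suite asserts
this identity for random parameters).

**Numerics.** Airway and capillary compartments use backward Euler —
unconditionally stable, first order, and exactly mass conserving under the
flow-consistent sweep order (root-to-leaf on inhale, leaf-to-root on
exhale; capillary trains inlet-to-outlet, with safeguarded Newton iteration
on the dissociation curve in each division). Alveolar compartments use a
mass-conserving operator split per time step: advection, then membrane
diffusion (the alveolus loses exactly the gas the divisions gain), then
arterial mixing and the venous pool. The inner step is `dt = 10` ms; the
square-wave flow profile spends 35% of each cycle in inspiration. The
per-breath mass-balance residual closes to floating-point precision, and
halving `dt` moves converged arterial P_O2 by well under 0.2 mmHg.

**Blood chemistry** is not specified by the source physiology and is the
package's own plumbing: Hill oxygen saturation (P50 = 26.8 mmHg, exponent
2.7), O2 capacity 1.34 ml/g × 15 g/dl hemoglobin plus dissolved
3×10⁻⁵ ml/(ml·mmHg), and a linearized CO2 content line
(`0.2 + 0.007·P`), all exposed in configuration. A fully linear option
(`content = β·P`) exists for analytic fixtures.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `D_L_O2_ref` / `D_L_CO2` | 40 / 800 | ml/(mmHg·min) | reference membrane diffusing capacities (unscaled human) |
| D_L(P, work) quadratic | −0.0078P² + (0.3+W/833)P + 76 + W/6 | ml/(mmHg·min) | workload- and P_O2-dependent oxygen diffusing capacity |
| `k_w` | 0.25 | shunt per unit ΔW | slope linking weight gain to shunt; a reconstruction, set it explicitly in quantitative work |
| `V_capillary` | 75 | ml | total capillary volume (scaled linearly with mass) |
| `frc_ml`, dead space | 3000, 150 | ml | resting lung volume and total anatomic dead space at 70 kg |
| control gains | `G_CO2` 2, `G_hyp` 100, `G_phasic` 60, `k_ex` 0.25 | L/min per unit | tuned once to the resting sanity envelope (P_a_O2 85–105, P_a_CO2 35–45, VE 5–8) |
| `VO2_rest`, `k_O2`, RQ | 0.3, 0.0116, 0.85 | L/min, L/min/W | linear metabolic demand |
| `Q_rest`, `k_Q`, `Q_max` | 5, 5, 25 | L/min, L/L | cardiac output law with maximal ceiling |
| `D_max` | 2500 | ml O2 | oxygen-deficit capacity (fatigue threshold) |

Allometric scaling: volumes scale linearly with body mass, surfaces and
diffusing capacities with mass^(2/3); volume-like controller parameters
(resting ventilation, tidal volumes, ventilation gains) scale linearly with
mass, while per-watt terms and time constants do not. Reference masses are
70 kg (human), 40 kg (sheep) and 30 kg (goat, which reuses the sheep lobar
anatomy).

## Design choices where the design was open

- **Airway connectivity.** The morphometric tables give dimensions but not
  the parent–child map or the leaf-to-segment assignment. The package ships
  a fixed, documented adjacency map (TSV resources) built so that the left
  and right lungs are separable subtrees. An 18-node tree cannot have 19
  leaves, so the unique "feeding leaf" of each segment is its own
  conducting dead-space compartment; upper-airway leaves may feed one to
  three segments.
- **Left/right partition.** Which table segments belong to the right lung
  is not recorded; the shipped assignment (10 segments) has a right-lung
  volume fraction of exactly 0.525, consistent with the documented 0.52
  fraction and with 38.1% regional weight gain being the volume-matched
  equivalent of 20% uniform gain (20/0.525 = 38.1).
- **Dead space.** Segmental conducting regions (generations ~5–16) have no
  printed dimensions; each segment gets a single series compartment sized
  so total anatomic dead space is 150 ml at 70 kg (the upper tree itself
  contributes ~35 ml).
- **Damage slope `k_w`.** The slope of shunt against fractional weight gain
  is not printed. The default 0.25 keeps the canonical damage patterns
  (20% uniform, 38.1% regional) inside the un-clipped range of the
  coupling inversion (`D_L-reduction = k_w·ΔW/0.15 ≤ 1`); the
  regional/uniform global-shunt equivalence only holds without clipping.
  It is configuration-exposed and deliberately documented as uncertain.
- **D_L validity clamp.** The oxygen diffusing-capacity quadratic turns
  negative above ~120 mmHg alveolar P_O2 at rest. Extrapolating it there
  creates a spurious collapse feedback (hypoxemia → hypoxic drive → higher
  alveolar P_O2 → collapsed D_L). The pressure argument is clamped at
  110 mmHg, where the expression is non-negative for all workloads, with a
  floor of 1 ml/(mmHg·min) as a guard; evaluations inside the physiologic
  range are untouched.
- **Phasic hypoxic drive.** A first-order-filtered tonic drive cannot
  overshoot when its input is monotone, yet the ventilatory response to an
  isocapnic hypoxic step should overshoot and then decay. The controller
  therefore carries a phasic component — the un-adapted part of the hypoxic
  drive, fading with `tau_adapt` = 90 s — reflecting a chemoreflex that
  responds to changes in saturation more strongly than to a sustained
  level. At any steady state the phasic term is zero, so equilibria are
  unaffected.
- **Shunt plumbing.** Shunted flow is diverted before the capillary bed
  (capillary flows sum to `(1−shunt)·Q_Tot`) and recombines with
  end-capillary blood in a single flow-weighted mean; for conserved
  contents the capillary→lobar→systemic mixing order is immaterial, so
  lobar grouping affects reporting only.
- **Isocapnic clamping** is an inspired-CO2 integral controller holding
  arterial CO2 at its pre-perturbation value, mimicking the external CO2
  supply used experimentally.

## What the synthetic data emulates — and what it does not

`make_fixture_lung()` builds miniature lungs (one or two equal segments,
negligible dead space, optional linear blood chemistry) whose steady states
have closed-form or quadrature oracles; `generate_calibration_data()`
produces noisy points on a known shunt-vs-damage line standing in for
figure-read experimental calibration points. These fixtures validate the
solver and the fitters, not the biology: passing tests demonstrate internal
consistency (conservation, oracle agreement, parameter recovery,
qualitative response shapes), not agreement with any particular animal's
data. Real calibration data — individual-animal arterial oxygen against
measured lung weight change — are noisier, sparser and confounded in ways
the generator does not emulate.

## Problem sizes used by the shipped tests

Unit oracles run on fixture lungs in milliseconds. The closed-loop checks
use the full 19-segment human model (steady states converge in ~30–100
breaths at `dt` = 10 ms), the 6-lobe sheep on the ramped treadmill protocol
(runs up to ~25 simulated minutes), and the goat for the damage-parameter
recovery (three workloads per condition, bounded least squares on the unit
square). These sizes keep the complete suite at a few minutes on one CPU
while exercising every coupling path.

## Known limitations

- Ventilation/perfusion fractions are static per anatomy: no posture
  change, no hypoxic pulmonary vasoconstriction, and damage does not
  redistribute perfusion (it acts only through D_L and shunt).
- No Bohr–Haldane interaction, temperature or pH shifts of the dissociation
  curves; no nitrogen or inert-gas exchange.
- Damage is steady-state: no edema progression or recovery kinetics, and no
  prediction of weight gain from the injuring insult itself.
- The control laws are re-creations with gains tuned to resting envelopes;
  only qualitative response shapes (overshoot, plateaus, fatigue ordering)
  should be relied upon, not controller transients in detail.
- Generations 5–16 are lumped into one conducting compartment per segment;
  airway mechanics (resistance, compliance) are absent.
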