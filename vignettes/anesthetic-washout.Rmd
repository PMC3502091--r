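---
title: "Modelling anesthetic washout, emergence, and rehypnotization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling anesthetic washout, emergence, and rehypnotization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macawake)
```

## The model

`macawake` simulates the uptake and elimination of the potent volatile
anesthetics with a five-compartment mass-balance model in which every
compartment is well mixed and all exchange is flow-limited:

* the **breathing circuit** (volume `v_circuit`, default 8 L) receives
  fresh gas carrying the delivered (vaporizer) partial pressure `F_D` at
  flow `FGF` and exchanges gas with the alveoli at the alveolar minute
  ventilation `V_A`; excess gas leaves the circuit at the inspired
  pressure `F_I`;
* the **alveoli** (volume `frc`, default 2.5 L) exchange with the circuit
  through ventilation and with blood through perfusion; blood is treated
  as a volumeless carrier in instantaneous equilibrium with alveolar gas,
  so the arterial pressure equals `F_A`;
* three **perfusion-limited tissue groups** — vessel-rich (VRG), muscle
  (MG), and fat — each take up agent at a rate set by their blood flow
  `Q_i` and capacity `V_i * lambda_i`. Venous blood returns at the
  flow-weighted mixed venous pressure.

All pressures are carried as vol% of 1 atm and time in minutes. The system
is linear in the state for fixed settings, which the test suite exploits:
an eigendecomposition of the system matrix provides an independent
trajectory oracle against which the time-stepping integrator is checked.

The tissue of interest is the VRG, whose partial pressure `F_VRG` stands
in for the central nervous system. Emergence is defined as `F_VRG`
reaching **MACawake = 0.3 MAC**, and **rehypnotization** as any later
strict exceedance of 0.3 MAC (equality does not count). Both events are
read off the reported trace: the crossing by linear interpolation between
samples, the rebound by a strict comparison at every sample.

### Parameters

Packaged defaults (`inst/extdata/gasman_params.json`, loaded by
`load_params()`):

| quantity | desflurane | sevoflurane | isoflurane |
|---|---|---|---|
| MAC (vol%) | 6 | 2 | 1.2 |
| lambda blood/gas | 0.42 | 0.65 | 1.3 |
| lambda VRG | 0.54 | 1.1 | 2.1 |
| lambda muscle | 0.97 | 2.4 | 4.5 |
| lambda fat | 13 | 34 | 70 |
| overpressure `F_D` (vol%) | 18 | 5 | 3 |

Patient/circuit constants: 70 kg; circuit 8 L; FRC 2.5 L; cardiac output
5 L/min; tissue volumes 6 / 33 / 14.5 L and fractional flows 0.758 / 0.18
/ 0.06 for VRG / muscle / fat. The flow fractions sum to 0.998 and are
used **verbatim**: the perfused flow is `0.998 * Q` and venous return is
weighted by the same fractions. Renormalising to 1 would change clearances
and uptake rates by 0.2%, well below every tolerance used here, and would
break agreement with the printed parameter set the model is built from.

The solubility ladder is what drives every qualitative result: tissue
capacity `V * lambda` ranges from ~14 L (desflurane VRG) to ~1000 L
(isoflurane fat), so time constants `V * lambda / (lambda_BG * Q)` span
two minutes to nearly two days.

## The protocol engine

The study protocol (`build_protocol()`) has four phases:

1. **Wash-in**: `F_D` fixed at the agent's overpressure setting, FGF
   1 L/min, `V_A` 5 L/min, until `F_A` first reaches 1 MAC (threshold
   event). With FGF this low, the circuit balance caps how fast `F_A` can
   rise: for isoflurane at `F_D = 3` vol% exact attainment of 1.2 vol%
   takes about an hour, because the required delivered pressure exceeds
   3 vol% until mixed venous pressure has risen. If the target is not
   attained within the maintenance window an unreachable-target error is
   raised.
2. **Maintenance clamp**: from first attainment to 8 h, `F_A` is held
   exactly at 1 MAC by an algebraic controller: the tissue ODEs are
   integrated with `F_A` fixed, `F_I` is set to the value that makes the
   alveolar balance vanish, and `F_D` is back-computed from the circuit
   balance, bounded to `[0, overpressure]`. After first attainment the
   required `F_D` only falls (mixed venous pressure only rises), so the
   clamp is exact thereafter. The original procedure this reproduces was a
   human operator titrating a vaporizer; the algebraic clamp is the
   operator-free, reproducible equivalent. Because `F_I` and `F_A` are
   controller outputs rather than integrated states during this phase, the
   circuit mass ledger is only meaningful on fixed-delivery phases, and
   that is where the conservation invariant is asserted.
3. **Washout**: delivery off, FGF raised to 10 L/min, `V_A` at the
   scenario's washout level (5 = normoventilation, 10 =
   hyperventilation), until `F_VRG` falls to 0.3 MAC. A 240-min cap turns
   pathological parameter sets into errors instead of unbounded runs.
   Note that raising FGF removes agent delivery but not recirculation of
   expired gas: under this circuit model `F_I` relaxes to
   `V_A / (FGF + V_A) * F_A`, about a third of `F_A` at FGF 10 and `V_A`
   5, not to zero.
4. **Post-recovery observation**: `V_A` switched to the scenario's
   post-recovery level (0.5-10 L/min) for 120 min. The observation window
   is a package choice — long enough that every rebound peak in the
   default grid occurs well inside it (the slowest, isoflurane at
   0.5 L/min, peaks within the first hour) — and is configurable
   (`observation_min`).

Each post-recovery arm switches at its own MACawake crossing, which is how
the protocol is described operationally ("after recovery, ventilation was
reduced"); in `run_study()` the maintenance and washout segments are
integrated once per agent and washout mode and all six arms branch from
the stored crossing state, so the shared crossing is exact by
construction.

## Numerical choices

* **Integrator**: classical fixed-step RK4 at `dt = 0.25` s. The fastest
  time constant in any studied configuration is the circuit during
  washout, `V_C / (FGF + V_A) = 24` s, so the step is ~100x inside the
  stability/accuracy region; the test suite verifies that halving the
  step changes no reported pressure by more than 1e-6 vol% and that the
  trajectory matches the eigendecomposition oracle to 1e-4 vol%. An 8-h
  maintenance is 115,200 steps; the full 36-scenario grid integrates in
  about a second because the stepping core is compiled.
* **Reporting**: states are recorded every 1 s (configurable); phase
  switches happen on the internal step grid, and threshold events are
  resolved to the 0.25-s step at which they occur, then refined by linear
  interpolation when times are extracted from the trace. Reported times
  are therefore resolved finer than the 6-s granularity conventional for
  this kind of simulator display, and comparisons are made with
  tolerances, not exact seconds.
* **Mass accounting**: the cumulative agent volume delivered
  (`FGF * F_D`) and vented (`FGF * F_I`) are integrated with the same RK4
  stage weights as the state, which makes the discrete storage balance an
  algebraic identity — the conservation test asserts it to 1e-6 relative,
  and it holds to rounding error.
* **Degenerate inputs**: constructors validate positivity, flow fractions
  in (0, 1], and the fat > muscle solubility ordering at construction
  time with field-level error messages; zero-capacity compartments are
  rejected before integration. A trace that never crosses a requested
  threshold raises a typed no-crossing error rather than returning a
  sentinel.

## The scenario generator

`scenario_grid()` expands the 36-cell study design programmatically, so
the whole pipeline is testable with no external inputs. Its defaults *are*
the study conditions: 8-h maintenance, washout at 5 or 10 L/min, and
post-recovery ventilation at 0.5, 1, 1.5, 2.5, 5, or 10 L/min.

`perturbation_spec()` / `perturb_scenarios()` generate the sensitivity
scenarios the emergence question suggests: scaling muscle or fat volume
(body habitus), cardiac output, or maintenance duration. Scaling is
plainly multiplicative on one parameter with no anthropometric closure
model — in particular, **scaling a tissue volume keeps the fractional
blood flows fixed, so perfusion per unit tissue falls as the tissue
grows** (the tissue time constant stretches). This is a deliberate,
documented semantic; an alternative in which flow scales with volume
would change absolute uptake, and no principled closure is available
without a population model, which is out of scope. Random multiplier
draws, when requested, are fixed at spec construction from a seed and do
not disturb the session RNG.

What the generator does *not* emulate about real patients: inter-patient
variability in solubilities and MAC, ventilation/perfusion mismatch, dead
space, metabolism, inter-tissue diffusion, shunt, and the coupling of
hyperventilation to cerebral blood flow through CO2 (the simulated
hyperventilation is isocapnic by construction). Passing tests therefore
show internal consistency of the stated model and reproduction of its
published outputs, not clinical validity; the directional sensitivity
results (more muscle or longer anesthesia raises the rebound peak) are
properties of the simulator, asserted as such.

## Design decisions that were genuinely open

* **Venous return weighting**: printed flow fractions verbatim
  (sum 0.998), venous return weighted by the perfused flow. Chosen for
  fidelity to the printed parameter table; the alternative (renormalise)
  differs by 0.2%.
* **MACawake on `F_VRG`, not `F_A`**: the awakening threshold is applied
  to the CNS proxy trace. The alveolar pressure crosses 0.3 MAC earlier;
  using it would shift every washout time down by the VRG lag
  (~2 min for isoflurane).
* **Strict rebound inequality**: rehypnotization requires `F_VRG`
  strictly above 0.3 MAC after the crossing; touching the threshold is
  not an event. With a different convention the washout-continuation
  arms, which end exactly at the threshold, would be spuriously positive.
* **Single well-mixed circuit**: the 8-L circuit is one compartment, with
  no separate inspired-limb mixing delay. Nothing in the parameter set
  distinguishes limbs, and the washout times it produces agree with the
  published ones within a few percent.
* **Overpressure-then-clamp controller**: a bounded exact clamp rather
  than a simulated titrating operator; see above.

## Limitations

The model omits, by design: dead space and V/Q mismatch, anesthetic
metabolism, inter-tissue diffusion, intra-tissue heterogeneity (gray vs
white matter), age effects on MAC, nitrous oxide second-gas and
concentration-volume effects, and any effect of CO2 on cerebral blood
flow. Ventilation and fresh gas volumes are treated as agent-independent.
Conclusions drawn from it are therefore about the kinetics of a
perfusion-limited compartment system with the packaged parameters — a
useful and historically standard idealisation, but not a patient.

## A short tour

```{r tour, eval = FALSE}
study <- run_study()
study                      # washout times, reductions, rehypnotization matrix
tidy(study)                # one row per scenario
autoplot(study)            # vessel-rich traces, faceted by agent and washout mode

es <- simulate_scenario(paper_scenario("iso", washout_va = 10, post_recovery_va = 1))
tidy(es)
autoplot(es)

clearance_table()          # closed-form clearance across the Q x V_A grid
```
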