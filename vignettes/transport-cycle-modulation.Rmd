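---
title: "Modelling allosteric modulation of solute-carrier transport cycles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling allosteric modulation of solute-carrier transport cycles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slcmod)
```

## The model and its assumptions

A solute carrier (SLC) completes a transport cycle by stepping through a
closed loop of partial reactions: (co)-substrate binding on the outside,
translocation to the inward-facing (IF) conformation, release inside, and
the return of the empty carrier to the outward-facing (OF) state. `slcmod`
treats each partial reaction as a reversible first-order step of a
continuous-time Markov chain and asks how a ligand that binds *outside*
the substrate site (an allosteric modulator) reshapes the cycle.

Two assumptions carry all the physics:

* **Eyring kinetics.** Every unidirectional rate constant corresponds to
  an activation free energy, $k = \kappa (k_B T/h) e^{-\Delta G^\ddagger
  /RT}$. We take the transmission coefficient $\kappa = 1$ (no recrossing);
  it is kept as a field of `thermo_context()` for generality but nothing
  in the package depends on it being 1.

* **A linear free energy relationship (LFER).** Binding a ligand with
  dissociation constant $K_D$ at concentration $[M]$ lowers a ground
  state's free energy by the binding polynomial $\Delta\Delta G = -RT
  \ln(1 + [M]/K_D)$. The transition state moves linearly between the two
  ground-state shifts, $\Delta\Delta G^\ddagger = \alpha \Delta\Delta G_P
  + (1-\alpha) \Delta\Delta G_R$, where $\alpha$ locates the transition
  state on the reaction coordinate. Only the *ratio* of the two ground-state
  affinities matters for the rate changes — `lfer_apply()` gives identical
  results for a micromolar and a nanomolar ligand with the same
  $[M]/K_D$ — and the modulated rate pair satisfies detailed balance for
  every real $\alpha$, compliant with LFER or not. Values of $\alpha$
  outside $[0,1]$ are therefore computed and *flagged* (`lfer_compliant =
  FALSE`), never rejected: they are thermodynamically legal landscapes
  that happen to defy LFER.

One formulation detail deserves a note. The $\alpha$-extraction relation
used throughout is $\alpha = (\Delta\Delta G^\ddagger - \Delta\Delta
G_R)/(\Delta\Delta G_P - \Delta\Delta G_R)$, i.e. the denominator is the
*difference* of the ground-state shifts. This is the algebraic inverse of
the LFER interpolation above; a sum in the denominator would not invert
it, and `extract_alpha()` is tested to round-trip `lfer_apply()` to 1e-8
over a thousand random draws.

## The eight-state cycle

`build_positive_scheme()` and `build_negative_scheme()` construct the
two-loop network: a modulator-free front loop (To → ToNaS → TiNaS → Ti →
To) and a modulator-bound rear loop, connected by four binding edges. The
front-loop constants are the preset published rate set: lumped loading
$10^{16}[\mathrm{Na}]_{out}[S]_{out}$, translocation $10^6$ s⁻¹, internal
release $10^{12}$ s⁻¹, and the rate-limiting empty-carrier return at 2
s⁻¹. The cycle is biased forward with 0.15 M Na⁺ and 1 mM substrate
outside and nothing inside. The lumped loading constants are printed with
mixed units in the source rate set (an artifact of lumping sequential ion
and substrate binding); the package uses base constant × molar factors
directly as an effective first-order rate in s⁻¹.

For the positive modulator, the high-affinity state is To ($K_D$ 1 µM,
off-rate 1 s⁻¹, on-rate $10^6 [M]$) and every other state binds at the
low-affinity $K_D$. The rear return step carries the LFER transform of the
2 s⁻¹ step: $k_{85} = 2\,r^{\alpha}$, $k_{58} = 2\,r^{\alpha-1}$ for
selectivity $r$; the exported dial is the factor $X = 10^{\alpha-1}$, so
that at the default $r = 10$ these are exactly $20X$ and $2X$. Loop
closure forces the rear release constant to $10^{12} r$ — at $r = 10$ the
published $10^{13}$ — which is where the thermodynamic price of
stabilizing To is paid.

Three design choices here were genuinely open:

* **Which $K_D$ moves with selectivity.** We fix the high-affinity site at
  1 µM and set the low-affinity $K_D$ to $r$ µM. At $r = 10$ this
  reproduces the published off-rates (1 and 10 s⁻¹) exactly, and it is the
  convention under which the documented selectivity phenomenology emerges:
  the EC50 of the allosteric effect shifts right with selectivity, an
  over-selective ligand at 10 µM loses its gain (it dissociates from the
  IF states), and the selectivity–gain relation at fixed sub-saturating
  concentration is bell-shaped. Fixing the *low*-affinity site instead
  makes low-affinity occupancy independent of selectivity and erases all
  three effects.

* **The negative-modulator rate set** is not published; it is constructed
  by mirroring the positive preset: high affinity on ToNaS (1 µM), low
  affinity ($r$ µM) elsewhere, the 100 s⁻¹ substrate-translocation step
  LFER-transformed to $100\,r^{-\alpha}$ / $100\,r^{1-\alpha}$ in the
  bound loop, the 2 s⁻¹ return untouched, and the rear release constant
  $10^{12}/r$ completing detailed balance. Construction is verified by
  `check_detailed_balance()` and a violation is an internal error.

* **Where the 20 s⁻¹ cap goes.** `cap_second_step()` models the situation
  in which accelerating the return step makes a second reaction
  rate-limiting. The cap is applied to the lumped loading step (both
  loops, both directions scaled so every equilibrium constant is
  preserved). Capping a step *downstream* of the ToM → ToNaSM edge would
  instead let the super-stabilized ToM state hoard occupancy and turn the
  scenario into net inhibition at high selectivity; with the loading-step
  cap the simulated gains flatten across selectivities, which is the
  behavior the scenario is meant to exhibit.

A related structural property is worth knowing: because the stated $K_D$s
force an $r$-fold equilibrium penalty onto the ToM → ToNaSM edge, a very
selective positive modulator ($r \gtrsim 10^3$) at saturation traps an
appreciable fraction of the population in the ToM well, and the attainable
gain falls short of $r$ (the tests pin gain ≤ selectivity as an
invariant). This is a genuine feature of the eight-state topology, not a
numerical artifact; it disappears only in coarser lumped reductions where
the penalty lands on a flux-blocked edge.

`check_detailed_balance()` validates microscopic reversibility on a cycle
basis of the undirected reaction graph (spanning tree + fundamental
cycles, via `igraph`); balance on a basis implies balance on every cycle.
Concentration factors are evaluated at a common 1 M reference so that only
the thermodynamic consistency of the constants is tested, independent of
the applied bias.

## Numerics

* **Steady states** are computed by GTH (Grassmann–Taksar–Heyman) state
  elimination rather than a generic null-space solve. The preset rate
  matrix spans ~13 orders of magnitude; a QR or LU null-space solution
  loses roughly `eps × cond(Q)` ≈ 4 digits here, which is fatal for
  net-flux calculations that cancel 10–12 digits. GTH uses no
  subtractions, so occupancies are entrywise accurate to ~n·eps, and the
  flux-continuity invariant (identical net flux across every edge of the
  conducting loop, relative 1e-8) holds in the tests. Transient states
  (e.g. the rear loop at $[M] = 0$) receive exactly zero mass; a network
  with more than one closed communicating class has no unique stationary
  distribution and is refused with the classes listed.

* **Time integration** uses `deSolve::ode` (lsoda) with the constant
  Jacobian supplied analytically, rtol 1e-8 and atol 1e-12. Stiffness
  handling is mandatory at these rate spans. Long-time integration agrees
  with the direct steady state to 1e-6 in the tests, and a
  fixed-seed Gillespie sampler (seed 20230505) provides an independent
  stochastic cross-check with regenerative standard errors. The stochastic
  check runs on a moderate-rate scheme of the same topology: on the preset
  itself the embedded jump chain dithers ~10¹² times across the fast
  binding edge per transport cycle, so no realistic event budget mixes it.

* **Uptake** is measured as the summed net flux across the
  substrate-translocation cut (ToNaS → TiNaS plus ToNaSM → TiNaSM); by
  flux conservation any parallel cut gives the same number, which the
  tests verify, and the cut is recorded in the result object.

* **EC50/IC50** are extracted by log-linear interpolation at the
  half-effect level of the normalized response (gain normalized to
  $[0,1]$; inhibition normalized on the 1 → residual scale). A
  non-monotone dose–response yields `NA` with a warning record instead of
  an extrapolated number.

* **Composite reactions** (a two-step crossing of a short-lived occluded
  intermediate) are reduced by the quasi-steady-state formula $k_{FW} =
  ac/(b+c)$, $k_{BW} = db/(b+c)$, with a dominant-eigenvalue relaxation
  reduction available as an alternative; the two agree to better than 1%
  for a 10 µs intermediate and ~100 s⁻¹ composite rates. The apparent
  $\alpha$ of the composite is derivation-invariant (forward- and
  backward-rate readings agree to 1e-9) as detailed balance guarantees.
  The elementary rates behind the default occluded-state scenario are
  under-determined by its observable constraints, so
  `composite_from_observables()` exposes the intermediate branching ratio
  $b/(b+c)$ as an explicit knob rather than hard-coding an unverifiable
  value; sweeping it shows the apparent $\alpha$ ranges over a wide
  interval, so no single printed value is targeted by the tests.

## Parameters that matter

| Parameter | Units | Default | Rationale |
|---|---|---|---|
| `temperature` | K | 293.15 | 20 °C makes RT·ln 10 ≈ 5.6 kJ/mol, matching the barrier-shift magnitude the scenarios quote; configurable. |
| `kappa` | — | 1 | no barrier recrossing. |
| `selectivity` | fold | 10 | affinity ratio of the modulator between its high- and low-affinity states; 10 is the canonical preset. |
| `alpha` / `x_factor` | — | 1 / $10^{\alpha-1}$ | transition-state position of the modulated step. |
| bias concentrations | M | 0.15 / 1e-3 / 0 / 0 | inwardly directed Na⁺ gradient; forward-biased cycle. |
| `base_translocation` | s⁻¹ | 100 | negative-modulator target step, an order of magnitude above the 2 s⁻¹ rate-limiting return. |
| `cap` | s⁻¹ | 20 | second rate-limiting step scenario. |
| saturating $[M]$ | M | ≥ 100 × largest $K_D$ | presets use 1 mM and 1 M. |

## What the presets emulate — and what they do not

The `preset()` registry regenerates each scan scenario deterministically:
elementary-reaction landscapes (including the non-compliant $\alpha = 2$
and $\alpha = -1$ cases), positive-modulator gain surfaces over $\alpha$ ×
concentration at selectivities 10/100/1000, EC50 dose–response curves,
the selectivity bell, the capped-cycle scan, negative-modulator
inhibition surfaces with residual-uptake and IC50 summaries, and the
composite apparent-$\alpha$ scenario. Grids default to $\alpha \in \{0,
0.05, \ldots, 1\}$ and log-spaced concentrations $10^{-8}$–1 M; all scans
are deterministic given the configuration, and `run_scenario()` writes a
manifest with per-file checksums so a rerun can be verified byte-for-byte.

These scenarios are idealizations. The model is not electrogenic (no
membrane potential enters the rates, although many SLC partial reactions
are voltage-dependent); there is a single modulator species; binding
on-rates are a uniform diffusion-limited $10^6$ M⁻¹s⁻¹ so that all
affinity differences live in the off-rates; and transient (pre-steady
state) currents, exchange modes and population heterogeneity are out of
scope. Passing tests therefore demonstrate internal consistency of the
thermodynamic-kinetic framework and reproduction of its predicted
steady-state phenomenology — not agreement with any particular measured
transporter dataset, which would additionally require fitting $\alpha$,
the $K_D$s and the rate-limiting step from experiments.

## Known limitations

* LFER itself is semi-empirical; the package takes it as given and offers
  the flagged non-compliant regime rather than a deeper theory.
* The apparent $\alpha$ of a composite reaction depends on unobservable
  branching; treat `alpha_app()` as a descriptive reduction, not an
  estimate of transition-state structure.
* At selectivities ≳ 10³ the ToM-trap effect described above makes the
  positive preset's maximum gain fall below the selectivity ratio; this
  is a property of the stated eight-state topology.
* Tolerances (GTH exactness aside) were chosen for convergence of this
  model family, not to mimic any particular historical solver.
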