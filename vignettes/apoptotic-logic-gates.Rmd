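---
title: "The Bcl-2 family module as a reconfigurable apoptotic logic gate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Bcl-2 family module as a reconfigurable apoptotic logic gate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`bclgate` implements a deterministic mass-action model of the
mitochondrial apoptotic decision module. Three Bcl-2 family roles are
each collapsed into one representative: the pro-apoptotic multidomain
effector (Bax, standing in for Bax/Bak), the pro-survival restrainer
(Bcl-xL), and the BH3-only sentinel (Bad). Two further players close
the circuit: the scaffold protein 14-3-3, which sequesters
phosphorylated Bad, and a single lumped caspase species activated from
a pro-caspase pool.

Eleven ordinary differential equations track molecules per cell of Bax
mRNA, Bax, Bcl-xL, Bad (unphosphorylated and phosphorylated), the
scaffold, pro-caspase, caspase, and the three complexes Bax:Bcl-xL,
Bcl-xL:Bad_u and Bad_p:Scaffold. Two exogenous, phase-wise constant
inputs drive the system:

* `p53_killer`, the apoptosis-competent phospho-form of p53, which
  induces Bax transcription through a Hill term with cooperativity 2,
  `s1 + s2 p53^2 / (M^2 + p53^2)`;
* `Akt_u`, unphosphorylated Akt, the proxy for growth-factor
  withdrawal. The Akt pool is constant, so the anti-apoptotic kinase
  level is `Akt_p = Akt_tot - Akt_u`; `Akt_p` phosphorylates Bad (both
  free and in complex with Bcl-xL), and phosphorylated Bad is parked on
  the scaffold instead of neutralizing Bcl-xL.

Caspase activation is `(a1 Bax + a2 Casp^2) Procasp` with shared
degradation `d3`: the quadratic autocatalysis is the minimal surrogate
for the cytochrome-c/apoptosome positive feedback and is what makes the
death decision bistable and irreversible. Upstream p53/Akt dynamics and
the explicit mitochondrial permeabilization steps are deliberately out
of scope; the module is analyzed as a signal-integration device with
two analog inputs and one digital output.

Internally all rates are per second (matching the parameter table);
user-facing durations are hours, converted at the interface.

## Parameters, pools and what they mean

`default_parameters()` returns the 20 reference constants (synthesis
rates `s1`–`s4`, Hill constant `M`, degradations `d1`–`d3`, binding and
unbinding pairs `b1`–`b3`/`u1`–`u3`, phosphorylation cycle `p1`/`q1`,
caspase rates `a1`, `a2`, and the capacities `Akt_tot`,
`p53killer_max`). Two conventions deserve a note:

* `p1` is treated as bimolecular (molecules^-1 s^-1) because every
  phosphorylation term has the form `p1 * Akt_p * X`; with the printed
  numeric value this gives the dimensionless maximal phosphorylated-Bad
  fraction `m6 = p1 Akt_tot / (q1 + p1 Akt_tot) = 2/3`.
* the scaffold total is not part of the kinetic table; the package
  fixes `Scaffold_tot = 2e5`, the only value consistent with the
  resting steady state it reproduces (1.33e5 scaffold-bound Bad_p next
  to 0.67e5 free scaffold).

The biologically tunable quantities are the conserved totals
`Bad_tot` and `BclxL_tot` (plus `Scaffold_tot`), collected in
`pool_config()`. Three presets name the regimes studied throughout:
`OR` (Bad_tot = 2e5, BclxL_tot = 1e5), `AND` (0.6e5, 1e5) and
`AND_STAR` (2e5, 2.4e5).

## The caspase switch

With free Bax clamped, the caspase pair closes on itself: the total
`S = Procasp + Casp` relaxes linearly to `s3/d3 = 1e5`, and on that
invariant set the steady states solve a cubic in `Casp`. Stability is
read from the sign of the derivative of the reduced residual, which is
exact at steady state (the full 2-by-2 Jacobian is kept as a test
oracle). `caspase_steady_states()` solves the cubic by `polyroot`,
filters real roots into `[0, S]`, merges roots closer than `1e-6 * S`
(robust fold handling) and polishes with Newton steps.

`find_bifurcation()` locates the saddle-node where the low and unstable
branches coalesce through the double-root reduction
`C (S - C)^2 = d3 S / (2 a2)` on `(0, S/3)`, recovers `Bax_bif` from
the residual, and verifies the fold by a root-count change at ±1%. The
high branch extends down to `Bax = 0`, so the switch cannot revert once
taken — the structural basis of irreversibility. The unstable root at
`Bax = 0` (`commitment_threshold()`, about 2e3 molecules) is the
commitment criterion used by the transient-stimulation analyses.

## Steady-state fates and gate types

The first nine equations do not involve the caspase pair, so fate
classification never integrates it. `bcl2_steady_state()` relaxes the
nine-species subsystem from a canonical resting start (all Bad
phosphorylated and scaffold-bound up to capacity, Bcl-xL free, no Bax)
until the maximal derivative falls below 1e-6 molecules/s, checking at
a ladder of horizons (50–2000 h; non-convergence at the 2000 h cap is
an error, reported with the final residual). Relaxation, rather than
algebraic solving, is used deliberately: the subsystem is monostable,
and integration inherits the physically selected branch without
root-selection heuristics. Small integrator undershoots below zero are
tolerated up to the absolute tolerance but never clipped, so solver
trouble cannot be masked.

A steady state is apoptotic iff its free Bax reaches `Bax_bif`
(`classify_fate()`). Evaluating the four corner inputs — logic 1 being
`p53killer_max` or `Akt_tot` — yields a truth table that
`classify_gate()` maps to a label: `OR` (either maximal signal alone
commits), `AND` (only both together), `ALWAYS_SURVIVE`,
`CONSTITUTIVE`, `P53_ONLY`, and `AKT_INTERMEDIATE` for the band in
which full Akt dephosphorylation suffices but maximal p53 alone does
not. (`AKT_ONLY` names the remaining non-monotone table, apoptosis at
the Akt corner only; it is defined for totality and not expected from
this model.)

The same classification exists in closed form. Because the Bcl-xL–Bad_u
affinity `m4` far exceeds the Bax–Bcl-xL affinity `m3`, Bad_u displaces
Bax, and free Bax appears once
`Bax_tot + Bad_u > BclxL_tot + m7`, with `Bax_tot` equal to `m1`
(p53 logic 0) or `m2` (logic 1), `Bad_u` equal to `(1 - m6) Bad_tot` or
`Bad_tot`, and `m7 = Bax_bif`. One sign in the printed survival-row
conditions of the source material is inconsistent with its own worked
examples; the package uses `<` for survival throughout, which both the
ODE corners and the arithmetic confirm. The right-hand side "Bcl-xL" of
the inequality is read as the total pool. ODE and algebraic fates are
required (and tested) to agree whenever the stoichiometric margin
exceeds 10% of `BclxL_tot + m7`; inside that band finite-affinity
effects may legitimately differ.

`input_plane_scan()` maps steady-state free Bax over the full input
plane (default 81 points per axis, chosen to place the isoline to
better than 1% of the axis range at desk-scale cost);
`apoptotic_isoline()` extracts the `Bax = Bax_bif` level set by linear
interpolation along grid edges. `gate_boundary()` scans one pool total
(default step 500 molecules, matching the two-significant-figure
boundaries it resolves) and reports where each corner flips and where
the gate label changes.

## Transient stimulation and commitment

`simulate_protocol()` integrates the full 11-ODE system through a
pre/stimulus/post protocol with `deSolve::lsoda` (relative tolerance
1e-8, absolute 1e-3 molecules — caspase switching is stiff near
threshold), restarting the integrator at phase boundaries rather than
interpolating across input discontinuities. The pre-phase defaults to
analytic equilibration: the run starts at the computed resting steady
state with the caspase pair on its low branch, which removes an
arbitrary burn-in duration.

Commitment is decided by basin, not by peak: after withdrawal the
trajectory must end within 1% of a `Bax = 0` stable branch (for the
low branch, which sits at/near zero, the band is 1% of the caspase
capacity `S`); the default 500 h post-phase is extended in 500 h chunks
(cap 4000 h) until the assignment is unambiguous, and a terminal level
within 1% of the unstable threshold itself is reported as an error
rather than guessed. Transient excursions of Bax above `Bax_bif` — even
with caspase temporarily above `Casp_bif` — do not commit unless the
threshold is actually crossed in basin terms.

`minimal_stimulation_duration()` bisects the stimulus duration between
a non-committing and a committing bracket (default 0–48 h) to 0.05 h;
reported durations are rounded to 0.1 h, the precision at which such
commitment times are meaningfully comparable. Commitment is monotone in
duration (tested on a ladder around the minimum), which is what makes
bisection valid.

## Numerical choices and degenerate inputs

* Conservation of the Bcl-xL, Bad and scaffold pools is exact in the
  right-hand side (terms cancel analytically) and is monitored along
  trajectories to relative 1e-6.
* Near-double caspase roots are merged at `1e-6 * S`; the fold locator
  fails loudly when autoactivation is too weak to produce one
  (`a2 -> 0` gives a monostable subsystem).
* Negative abundances, inputs outside `[0, Akt_tot]`, unknown
  configuration keys and non-bracketing bisection inputs are rejected
  with named errors; nothing is silently clamped or guessed.
* `perturbed_parameters()` generates log-normally perturbed rate sets
  (capacities fixed) for property tests; it is deterministic per seed
  and restores the caller's RNG state.

## Problem sizes

The shipped test-suite and the reproduction script work at the sizes
the analyses were designed for: steady-state relaxations of the
9-species subsystem (milliseconds each), an 81 x 81 input-plane scan,
a 401-point pool scan at step 500, bisections of about ten stiff
11-ODE solves each, and 100 randomized root-finder cross-checks. The
complete suite runs in well under a minute on one CPU.

## Limitations

The model is a deliberately minimal caricature: one effector, one
restrainer, one BH3-only species, one lumped caspase. It is
deterministic — no intrinsic noise, no cell-to-cell variability — and
its inputs are piecewise-constant levels, not the oscillatory p53
dynamics seen in damaged cells. Passing its tests therefore
demonstrates the stoichiometric logic-gate mechanism (displacement plus
bistable readout), not quantitative agreement with any measured cell
line: absolute molecule numbers, the 2/3 phosphorylated fraction and
the hour-scale commitment times all inherit the reference parameter
table, and real Bcl-2 family networks add regulation (restrainer
cleavage, BH3-only induction by p53, direct effector activation) that
this module intentionally omits.
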