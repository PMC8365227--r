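---
title: "Methods: desk-scale hemodynamics of stented sidewall aneurysms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: desk-scale hemodynamics of stented sidewall aneurysms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(aneuflow)
```

## Scope and model

`aneuflow` studies a single question at desk scale: how does the metal
coverage rate (MCR) of an intracranial stent or flow diverter — raised by
choosing a denser device, overlapping several devices, or axially compacting
a braided device — change the hemodynamics inside an idealized sidewall
aneurysm? The reference configuration is a 4 mm parent artery carrying
pulsatile internal-carotid-like flow, with a saccular aneurysm of 5 mm
radius communicating through a 5.27 mm neck.

Three deliberate reductions make the problem tractable on one CPU:

1. **2D planar section.** The vessel is a plane channel (height = parent
   diameter), the sac a circular disc attached to the upper wall; the neck
   is the chord the sac circle cuts on the wall line. The sac center offset
   is derived from the chord relation, not free. All comparisons in the
   study are *relative* (reduction rates versus the unstented control), and
   every configuration shares the reduction, so ordering and monotonicity
   survive even though absolute magnitudes do not.
2. **Homogenized screen instead of resolved struts.** Resolving 0.03–0.09 mm
   struts in the flow grid would need micrometer cells. Instead the deployed
   device enters the solver as a porous screen on the neck chord whose local
   solidity profile comes from the stent-pattern module.
3. **Unit-depth convention.** 2D "volumes" and "flow rates" are per-meter
   quantities scaled by depth = parent diameter, so reported magnitudes are
   order-comparable with 3D values. Every output manifest records this.

Because of reductions 1–3 the package does *not* attempt to reproduce the
published absolute EL / velocity / inflow magnitudes (obtained on 30–50
million 3D elements with an unprinted inlet waveform). What it does
reproduce, and what the acceptance suite checks, is (a) all arithmetic
derivable from the published device table (reduction rates, Pearson
correlations), (b) the calibrated single-device MCRs, and (c) the
qualitative computational content of the study: inflow and neck-velocity
reductions strictly ordered by single-device solidity and monotone in
solidity.

## Stent patterns and the MCR

Patterns are unions of periodic *stripe families* on the neck rectangle
(neck width × parent circumference, unrolled). A laser-cut closed-cell
device is two strut families along the diagonals of its cell; a braided
device is two wire families at ±β from the device axis, with β the braid
angle. For crossing stripe families the covered fraction is exactly

\[ \mathrm{MCR} = 1 - \prod_k (1 - w_k / d_k), \]

with \(w_k\) the stripe width and \(d_k\) the perpendicular spacing —
the overlap fraction of two crossing families equals the product of their
fractions regardless of angle. This closed form is used to *calibrate* the
three shipped presets (`scripts/calibrate_devices.R`): wire/strut widths
are fixed at plausible published-order values (90 µm strut; 61 µm and 30 µm
wires), and pitch or braid angle is solved so the single-device MCR over
the default neck equals the study targets (7.0 %, 20.4 %, 26.8 %). Braided
compaction divides the axial pitch by the compaction factor at fixed
circumferential spacing, so \(\tan\beta' = f\,\tan\beta\); the maximum
factors are calibrated the same way against the compacted targets (35.4 %,
47.8 %). The raster MCR (center-point sampling at wire width / 8) is the
measured quantity everywhere; the closed form is its oracle.

Overlap unions shifted copies of the single-layer mask. The inter-layer
registration of real overlapped stents is unknown; the default is the
idealized "constant gap": layer \(k\) shifted axially by
\((k-1)\,p/(2L)\) for \(L\) layers of axial pitch \(p\). Composite MCRs
(double/triple devices, compacted doubles) are therefore *emergent*, not
calibrated; they land within ~2 points of the published composite values.

## Flow solver

Staggered (MAC) grid, incompressible Navier–Stokes, Chorin projection:
first-order upwind advection, explicit diffusion, time step
\(0.4\,\min(h/u_{max},\; \rho h^2/4\mu)\) recomputed every step. The
pressure Poisson equation (zero-pressure outlet, Neumann elsewhere) is
solved by conjugate gradients to relative residual \(10^{-8}\),
preconditioned by an exact banded Cholesky factorization of the
geometry-only matrix, so iteration counts stay in the single digits. The
inlet is the exact oscillatory-channel (planar Womersley) profile of the
configured waveform; walls are rigid and no-slip; there is no turbulence
model (peak Reynolds number ~600, laminar) and no randomness anywhere —
identical configurations reproduce bit-identical fields.

**Waveform.** The study's source does not print its inlet waveform. The
package default is an ICA-like shape chosen once: period 1 s, mean section
velocity 0.25 m/s, two harmonics of relative amplitude 0.4 and 0.1 with
phases 0 and π/2 (velocity stays positive; Womersley number α ≈ 2.6 in the
4 mm parent). Systole is the argmax of the inlet section-mean velocity;
all metrics are evaluated on the systolic snapshot of cycle 3 of 3.

**Screen closure.** A screened neck face imposes the standard
screen/porous-jump pressure drop
\(\Delta p = (\mu w/\kappa(s))\,u_n + \tfrac12 \rho K(s) |u_n| u_n\) with
\(K(s) = c_1 s/(1-s)^2\) (screen-drag form) and Kozeny-type permeability
\(\kappa(s) = c_2 w^2 (1-s)^3/s^2\); \(c_1 = c_2 = 1\) by default, \(w\) =
wire diameter. The drag is applied implicitly (unconditionally stable,
strictly dissipative) and the face mobility \(1/(1+\theta)\) is folded into
the projection so the corrected field stays divergence-free while the
screen resists pressure-driven flux. The same law damps the *tangential*
velocity in the sac-side cell row along the chord — the thin layer where
wires shear the entering jet. The parent-side row is deliberately left
undamped: the main stream flows inside the device lumen and never crosses
metal. (An early variant that dragged both rows dissipated the parent
stream between the measurement planes and made the energy loss *increase*
with solidity — the opposite of the physical trend.)

## Metrics

Planes A and B sit one parent diameter upstream/downstream of the neck
edges (the published figure shows the planes but not their stations; the
offsets are configurable). Plane C is the neck chord. Energy loss follows
the study's formula
\(EL = v_{in} A\,[(\tfrac12\rho v_{in}^2 + P_{in}) - (\tfrac12\rho
v_{out}^2 + P_{out})]/V_m\) with area-weighted plane averages and \(V_m\)
the inter-plane fluid volume *including the sac* ("volume of the model
between planes A and B"). The inflow rate integrates only sac-directed
normal velocity over plane C: net flux through a closed sac is ~0 by
incompressibility, so the one-sided flux is the meaningful quantity. The
average velocity is the mean speed on plane C. Reduction rates are
\(100(\mathrm{control} - \mathrm{device})/\mathrm{control}\).

Whether the published EL prefactor \(v_{in}\) is instantaneous-systolic or
cycle-averaged is not stated; the package uses the systolic value,
consistent with "calculated as systolic". Correlations (Pearson r, two-sided
t-test p) are computed over all matrix rows *including the control*; this
convention reproduces the published coefficients exactly when applied to
the published table, which resolves the ambiguity empirically.

## Synthetic data and what a green test establishes

The validation-fixtures module generates everything the tests consume:
analytic channel flows (plane Poiseuille; single-harmonic oscillatory
channel flow, the planar Womersley analogue; Taylor–Green decay as an
evaluator-only case), toy stripe lattices with closed-form coverage, the
transcribed 10-row device table (checksummed, exact printed digits), and
reduced uniform-screen study matrices. The original bench validation
against PIV measurements of a silicone phantom is replaced by these closed
forms: the experimental dataset is not distributable, and an analytic
solution is a stricter oracle for the things it covers (profile shape,
phase lag, mass conservation). What the analytic cases do *not* cover —
3D secondary flow, strut-scale wakes, wall compliance, non-Newtonian
rheology — stays uncovered; a green suite says the 2D solver solves its
2D equations correctly, not that it reproduces in-vivo hemodynamics.

Scaling choices made once and not revisited: solver-validation runs use 40
cells across the lumen (the published mesh used 0.2 mm elements on a 4 mm
vessel, the same ratio); study sweeps run at 0.2 mm spacing, 3 cardiac
cycles, on a 24 mm parent segment (≥ 5 diameters of entrance allowance on
either design); the steady-flow validation uses a 5× more viscous working
fluid so the parabolic profile develops within one period (the blood-value
establishment time, ~1 s, would triple the test cost without changing what
is verified).

## Numerical choices and degenerate inputs

* Tie-break for the time step: 0.4 × the stricter of the advective and
  diffusive limits, recomputed each step; records land exactly on their
  times by clipping the last step.
* Poisson tolerance 1e-8 relative; mass imbalance at systole is ~1e-13
  relative in practice. The initial CG guess extrapolates the pressure
  field linearly in time; this changes only iteration counts, not the
  converged field.
* Grid convergence: halving the study spacing (0.2 mm to 0.1 mm) changes
  the systolic inflow rate by 7.6% (22.60 to 21.00 mm3/s on the screened
  s = 0.204 configuration), meeting the 10% criterion
  (`scripts/grid_convergence.R`; the fine run alone needs ~10 min on one
  CPU, so this check runs standalone rather than inside the default test
  suite).
* Raster MCR uses center-point sampling; refining the raster by 2 moves
  the MCR by < 0.5 points (enforced in tests). Solidity profiles are
  clipped at 0.995 so the loss law stays finite.
* Degenerate patterns: zero families → MCR 0 and an all-zero solidity
  profile; stripe width ≥ spacing is rejected at construction but a
  "solid sheet" can be built deliberately via `stripe_pattern()` (MCR 1).
* Geometry limits: `neck_width == 2 * sac_radius` is accepted as the
  hemispherical-cap limit (offset 0); wider necks are infeasible chords and
  error. Spacing must divide the parent diameter and be ≤ diameter/20.
* The screen solidity must stay < 1; 0 is the identity (bit-for-bit equal
  to an unstented run).

## Known limitations

* Absolute EL/velocity/inflow magnitudes are not comparable to 3D values;
  only signs, orderings and monotone trends are asserted.
* The energy-loss metric in 2D is dominated more by parent-channel friction
  than in 3D, so its *relative* reductions are much smaller than published
  even when the direction agrees.
* Staircase (masked) sac boundary: wall shear at the curved sac wall is
  first-order accurate; WSS-type metrics are out of scope.
* Compacted braids in reality develop axially nonuniform coverage; the
  model compacts uniformly (noted as a limitation in the source study as
  well).
* One printed inflow-rate reduction (double laser-cut row) cannot be
  recomputed from its printed absolutes to better than 0.39 points; the
  fixture report flags it instead of asserting.
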