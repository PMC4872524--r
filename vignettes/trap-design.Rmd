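---
title: "Models and methods behind traploop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind traploop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(traploop)
```

This vignette is the package's own account of its models: what is solved,
under which assumptions, which parameters matter, and where the design was
genuinely open and a choice had to be made.

## 1. The resistance-network design model

A trapping unit offers the flow two parallel routes between junctions A and
B.  Path 1 is modelled as five rectangular-duct segments in series — a
funnel-shaped trap pocket (region i), a trapping gap (ii), the middle
chamber (iii), and their mirror images (iv, v) — and Path 2 as a single
long duct (the bypass loop).  Each straight segment uses the fully
developed laminar pressure drop

$$\Delta p = \frac{f\mathrm{Re}\; L\, \bar u\, \eta}{2 D_h^2},\qquad
D_h = \frac{4A}{P} = \frac{2WH}{W+H},$$

with the Shah–London rectangular-duct constant
$f\mathrm{Re}(\alpha) = 96\,(1 - 1.3553\alpha + 1.9467\alpha^2 -
1.7012\alpha^3 + 0.9564\alpha^4 - 0.2537\alpha^5)$,
$\alpha = \min(W,H)/\max(W,H)$, spanning 96 (parallel plates) to 56.91
(square).  Hydraulic resistance is $R = \Delta p/Q =
f\mathrm{Re}\,L\eta/(2D_h^2A)$; for tapered segments $R$ is the integral of
the local straight-duct resistance density along the length (composite
Simpson rule, 64 intervals, verified in the tests against a 400-slice
series sum).  Equal pressure drop across the parallel paths gives
$Q_1/Q_2 = R_2/R_1$, and the design criterion is $Q_2/Q_1 < 1$.

Assumptions: Newtonian fluid (water, $\eta = 10^{-3}$ Pa s,
$\rho = 10^3$ kg m$^{-3}$ by default), rigid rectangular cross-sections,
creeping flow (Re $\approx 2\times10^{-3}$ at the 100 µm/s working
velocity, so minor/junction losses are neglected in the *network* — the
next section quantifies what that neglect costs), and fully developed
profiles inside each segment.

**Open geometry choices.**  The published dimension table does not give the
pocket widths (regions i and v).  They are modelled as linear tapers from
the main-channel width $W_{13}$ down to the gap width $W_{12}$ over the
pocket length, matching the funnel shape of the published layout and
introducing no free parameter.  A `lump_pocket_gap` option instead treats
pocket+gap as a single gap-width segment, as a conservative sensitivity
bound (it raises $Q_2/Q_1$ for design 1 from 0.64 to above 1, which brackets
how much the pocket model matters).  Channel cross-sections are taken as
rectangular throughout; the real devices use a rounded (reflowed) profile
at the valve seat, which we do not model.

**Which height the headline simulation uses.**  The catalogued designs come
in 15 and 25 µm heights.  Under the network model, design 1 *fails* the
trapping criterion at H = 25 µm ($Q_2/Q_1 \approx 1.01$) and passes at
H = 15 µm ($Q_2/Q_1 = 0.639$, flux fraction $Q_1/(Q_1+Q_2) = 0.61$).  Since
the published transmission study reports the trapping path receiving the
majority of particles (62% vs 38%), and the cell-imaging work used the 5
µm-gap device at 15 µm height, the package's headline trap-unit simulation
(and the acceptance script) uses design 1 at H = 15 µm.

## 2. The depth-averaged field solver

The 3-D trap unit is reduced to a 2-D plan-view solve with the
depth-averaged Stokes–Brinkman model

$$\mu \nabla^2 \bar{\mathbf u} - \frac{12\mu}{H^2} \bar{\mathbf u} =
\nabla p, \qquad \nabla\cdot\bar{\mathbf u} = 0.$$

The drag term is the Poiseuille friction of the two plates a distance $H$
apart (the Hele-Shaw limit); the in-plane Laplacian restores no-slip at the
side walls.  Side-wall friction is what makes the 5 µm gap resistive, so a
pure Hele-Shaw (potential-flow) solve — in which the split would depend
only on channel *widths* and would route ~85% of the flow into Path 1 at
any height — is not adequate here; the Brinkman term brings the straight
channel conductance within ~5% of the exact duct series solution at aspect
0.6 and within ~12% at the gap's aspect.  The in-plane effective viscosity
is taken as $\mu$ itself (the classical Brinkman choice; a parabolic-profile
momentum factor of 6/5 exists in the literature but changes the headline
split by only a few points and is not used).

Discretization: staggered (MAC) grid on the rasterized mask, cell size
`dx`; no-slip via reflected tangential ghosts; plug inflow at the stated
mean velocity on the inlet strip; $p = 0$ on the outlet strip; the sparse
saddle system is solved directly (`Matrix`).  The mass-balance residual
(max cell divergence scaled by inlet flux) must be below $10^{-8}$ or
`solve_field()` aborts; in practice the direct solve leaves ~$10^{-14}$.
Grid convergence: the headline transmission probability changes by < 2
percentage points between dx = 1 and dx = 0.5 µm (it is identical at the
default seeds), and the straight-channel pressure drop converges
second-order.

**Valve model.**  Valve "on" removes the *entire middle chamber* from the
fluid mask, because the membrane seals the chamber completely in the real
device (partial closure is representable in the network model as a
resistance multiplier, not in the field solver).  With the chamber sealed,
the mid-gap velocity collapses to ~$4\times10^{-4}$ of the inlet mean and
the Path-1 gate flux is zero to solver precision.

**Junction losses are real in 2-D.**  The resistance network neglects
entrance/exit losses; the field solver does not.  Measured on an isolated
pocket–gap–pocket constriction, the 2-D model shows ~45–60% excess Path-1
resistance relative to the 1-D integral (converging slowly with grid
refinement towards ~45–50%; the Brinkman screening length $H/\sqrt{12}
\approx 4.3$ µm sets the size of the entrance regions).  Consequently the
gate-flux ratio $Q_2/Q_1 \approx 0.94$ sits ~48% above the network's 0.639
— outside the 25% model-consistency bound the test suite asserts, which is
therefore an expected failure, documented here rather than hidden.  The
two models bracket the published 3-D finite-element result.

## 3. Particle tracing and transmission fates

Tracers are massless (Stokes number $\ll 1$) and advected with RK4 using
per-particle CFL-limited steps and bilinear interpolation on the staggered
grid.  Finite particle size enters sterically: the seeding band and the
region a particle centre may occupy are shrunk by one radius (sub-steps
that would violate the clearance are halved), not hydrodynamically.

Fates: a tracer is **trapped** when it crosses the transverse mid-plane of
the first trapping gap, or when it wedges (stalls against the clearance
limit) inside the pocket upstream of it — the latter is how a 10 µm
particle, whose centre cannot pass the 5 µm gap, registers as trapped.  It
is **bypassed** when it crosses the bypass-leg gate at the junction.
Assigning the trap fate at the gap plane rather than at the Path-1 mouth
makes the fate robust to trajectories that merely graze the stagnant mouth
region when the valve is sealed.  Seeding is deterministic uniform spacing
(stratum midpoints) across the accessible inlet width by default;
flux-weighted seeding (inverse-CDF of the inlet profile, stratified random
quantiles) is used for the consistency property that the trapped fraction
converges to the gate-flux fraction $Q_1/(Q_1+Q_2)$ — which it does within
binomial error at $n = 10^4$.

With these choices the headline run (design 1, H = 15 µm, dx = 0.5 µm, 100
tracers of 10 µm diameter, 100 µm/s inlet) gives 52% trap / 48% bypass
with the valve off, and 100% bypass with the valve on.  The valve-off
figures sit ~10 percentage points below the published 3-D finite-element
values (62/38), consistent with the 2-D entrance-loss bias quantified
above; the valve-on figures match exactly.

## 4. Trap-array logic

Filling, release and re-trapping are routing logic on top of the flow
split: an occupied or valve-on unit has $Q_1 = 0$ (total blocking, as a
plugged pocket seals the gap), so a particle traverses units in series and
enters the first empty valve-off trap (deterministic mode, since the
criterion makes Path 1 the majority route) or enters with probability
$Q_1/(Q_1+Q_2)$ (stochastic mode, consistent with flux-weighted
streamlines).  Valve-scheduled release ejects the occupant into the main
flow, where the same routing applies downstream — hence re-trapping in
empty valve-off traps, and order-independence when the empty downstream
valves are held closed during a release (`guard_downstream`), verified
exhaustively over all 120 release orders of a 5-unit array.  The event log
is append-only with a monotone clock and replayable.

The occupancy classifier encodes the empirical size rules: gap smaller
than the particle; channel width and height above the particle size but
below twice of it for single occupancy; stacking when $H \ge 2d$,
side-by-side multiples when the entrance $\ge 2d$.  The blockage threshold
(particle $\ge$ 0.8 × the narrowest channel dimension) is a chosen
heuristic constant — the source material is qualitative — and is exposed
as an argument.

## 5. The PALM module

The generator emulates a PALM acquisition of centromere-like clusters:
cluster centres on a jittered grid with guaranteed separation, emitters
uniform within a disc of the stated diameter (default 200 nm — uniform
discs make the diameter estimator exactly calibrated), per-frame i.i.d.
Bernoulli activation, isotropic Gaussian localization error, and uniform
false localizations.  Defaults are a 5000-frame movie, 8 clusters of 40
emitters, 1% per-frame activation and σ = 12 nm.  It does **not** emulate
molecular on-time correlations, bleaching, drift, or detection
heterogeneity — so passing tests show estimator correctness under the
stated noise model, not robustness to real-microscope artefacts.

**Precision (NeNA).**  Distances from each localization to its nearest
neighbour in the *next* frame, within a 100 nm window, are fit by maximum
likelihood to a truncated Rayleigh (scale $\sqrt2\,\sigma$, the
displacement of two independent localizations of the same emitter) plus a
linearly rising false-pair background; the CI is a pair-level bootstrap.
The estimator needs the sparse single-molecule regime: with i.i.d.
activation inside a dense 40-emitter cluster, the nearest adjacent-frame
neighbour is usually a *different* emitter of the same cluster at any
activation probability (same-emitter pairs are outnumbered ~30:1), so no
estimator can recover σ there.  Parameter-recovery tests therefore run on
sparse isolated emitters — the regime the method is defined for, and the
regime real acquisitions are in while single molecules blink sparsely.
Recovery is within 10% (measured ~2%) for σ ∈ {5, 12, 20} nm at 5000
frames, with ≥ 80% bootstrap-CI coverage over 20 replicates.  The pairing
window (100 nm) keeps false-pair contamination low at the default
densities; both it and the window are arguments, and the defaults are this
package's choices, not values inherited from any published pipeline.

**Clusters.**  Exact fixed-radius connected components (union-find over
spatial bins; radius 50 nm, ≥ 10 points by default), invariant to row
order.  The diameter estimate is the Gaussian-equivalent full width
$2\sqrt{2}\,\mathrm{RMS}$ distance to the centroid with the localization
error removed in quadrature ($\mathrm{RMS}^2 - 2\sigma_{loc}^2$; two
coordinates contribute) — "~200 nm size" is not operationally defined in
the source material, so this convention is documented rather than claimed
to match it.  On the default scene the 8 planted 200 nm clusters are
recovered with ~1% mean diameter error.  Below the percolation density a
pure-background table yields zero clusters at the default `min_points`.

## 6. Problem sizes and runtime

The test suite solves fields at dx = 1 µm (≈ 25 000 fluid cells, seconds)
and the acceptance runs at dx = 0.5 µm (≈ 100 000 cells, ~15 s per solve);
tracing costs seconds for 100–10 000 tracers because fates are decided at
the junction.  PALM property tests use 2000-frame movies for the
20-replicate coverage study and the full 5000 frames for the headline
recovery checks.  These sizes were chosen so the whole suite runs in a few
minutes on one CPU while every quantitative claim above is still measured,
not extrapolated.

## 7. Known limitations

* 2-D depth-averaged flow: no vertical secondary flows, no lift or
  margination; the quantified entrance-loss bias shifts valve-off
  transmission ~10 points below the 3-D reference.
* Steric-only particle model: no particle–wall hydrodynamics, deformation
  or adhesion; occupied traps block Path 1 totally.
* Rectangular cross-sections everywhere; membrane mechanics (deflection,
  partial closure) are out of scope — the valve is binary.
* The array model neglects inter-unit main-channel resistance (not
  quantified in the source material).
* The PALM generator's photophysics is a per-frame activation probability
  only; estimator performance on strongly correlated blinking is untested.
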