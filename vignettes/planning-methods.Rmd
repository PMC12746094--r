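---
title: "Desk-scale automated planning for discrete proton arc therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Desk-scale automated planning for discrete proton arc therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

protonarc generates and compares intensity-modulated proton therapy (IMPT)
and discrete proton arc therapy (PAT) treatment plans on synthetic
phantoms, with one shared optimizer across four delivery approaches:
36-field discrete PAT with energy-layer reduction, 36-field "Utopia" IMPT
(same geometry, no layer reduction — a dosimetric best case), 4- and
6-field clinical beam-angle class solutions, and IMPT with
patient-tailored beam angles selected from 72 equiangular candidates. This
vignette documents the models, the numerical choices, and what the
synthetic test bed can and cannot show.

## The phantom and what it emulates

`generate_phantom(default_phantom_spec(), seed)` rasterizes a parametric
oropharynx-like geometry: an elliptical body, a high-dose target (CTV70,
prescribed 70 Gy_RBE), a surrounding elective target (CTV54.25,
54.25 Gy_RBE), bilateral parotid-like ellipsoids, a posterior midline
cord-like cylinder, a pharyngeal-constrictor-like shell, and two
shoulder-like blocking slabs through which pencil beams must not travel.
The seed drives a small anatomical jitter (2 mm center offsets, 5%
size factors) so seeded populations stand in for a patient cohort.

The default is quasi-2D: a single 4 mm axial slice of a 176 mm field of
view. This is a deliberate desk-scale choice — every optimization below
runs in seconds to minutes on one CPU — and it has one physical
consequence discussed under *Robustness* below. Structure volumes are
therefore cross-sections, not the tens-to-hundreds of millilitres of
clinical head-and-neck targets; the shapes and adjacencies, not the
absolute volumes, are what the algorithms exercise. Density is
piecewise-constant relative stopping power (body 1.0, air 0.0); there is
no CT-number calibration, since only radiological depth matters to the
simplified dose engine.

## The dose engine

Beams are parallel-ray (infinite source-axis distance), a simplification
that removes divergence bookkeeping. A spot with machine-side
water-equivalent range $R$ deposits, at a voxel with radiological depth
$z$ (water-equivalent mm, computed by mid-point ray marching at 2 mm
steps) and lateral distance $r$ from the spot axis:

$$ d(z, r) = A \; B(z; R_p) \; \frac{e^{-r^2 / 2\sigma^2(z)}}{2\pi\sigma^2(z)}, $$

where $B$ is a parametric Bragg curve (Gaussian-smeared peak of width
3 mm WET on a gently rising entrance plateau of relative height 0.3),
$R_p = R - 34\,$mm when a range shifter is in the beam (the shifter's
water-equivalent thickness sits upstream of the patient, pulling the
in-patient peak back by exactly its WET), and
$\sigma^2(z) = \sigma_0^2 + (kz)^2 + \sigma_{rs}^2$ with
$\sigma_0 = 3$ mm, $k = 0.03$, and $\sigma_{rs} = 4$ mm added in
quadrature when a shifter is present. The depth-growing, shifter-widened
Gaussian penumbra is the only property the downstream logic relies on:
it makes range shifters cost lateral sharpness, which is exactly the
trade-off the with/without-shifter plan pairs probe. Influence entries
below $10^{-4}$ of their column maximum are dropped to keep the matrices
sparse.

Candidate spots are laid on an isocenter-anchored lateral lattice
(integer multiples of the spacing — this guarantees an on-axis spot row
for quasi-2D slabs) covering the beam's-eye-view projection of the union
target plus a 5 mm margin, with energy layers every 6 mm of
water-equivalent depth across each ray's proximal-to-distal target span.
The spacings are configuration with no fidelity claim. The isocenter is
the center of mass of the elective target.

## Robustness scenarios

`build_scenarios(3, 3)` builds the 21-scenario error set: nominal, ±3%
range (realized as a global density scaling; undershoot = denser), ±3 mm
setup shifts along each axis, and the six shifts combined with each range
error. For parallel beams a rigid setup shift only moves the spot axes
laterally — the per-voxel depth map along a fixed direction is a property
of the density field — so scenario dose columns reuse the nominal depth
map with shifted lateral spot centers; range scenarios scale the depth
map. Whether the patient or the beam is considered shifted is
dosimetrically equivalent here; the sign convention (dose pattern moves
opposite to the patient shift) is fixed by a translation test on a slab.

One quasi-2D artifact deserves note: a ±3 mm out-of-plane shift of a
single-slice phantom loses 10–20% of dose uniformly (there is no spot
stack above or below the slice to compensate), so robust target coverage
forces roughly 110% of prescription as an attainable ceiling on the
robust maximum target dose. The shipped default wish-list therefore sets
the target maximum-dose tolerance at 115% of prescription rather than a
clinical 107%; the scenario set itself is never altered. On thicker
phantoms (`default_phantom_spec(nz = ...)`) the artifact disappears and
tighter homogeneity is attainable.

## The wish-list and the lexicographic optimizer

A wish-list is the single optimization recipe shared by all delivery
modes: hard constraints (robust target minimum/maximum dose, a robust
serial-OAR maximum, a 47 Gy cap on any single field's dose contribution
in the nominal scenario) plus prioritized objectives (nominal-scenario
mean-dose minimization for parotids, then the constrictor, then a cord
maximum, then body mean dose as an integral-dose surrogate). The shipped
goal values are illustrative configuration, not a published protocol.
`wishlist_digest()` lets a study assert that every mode ran under the
same recipe — the bias-free comparison design.

`solve_lexicographic()` runs one convex solve per priority: objective
$k$ is minimized subject to all hard constraints and to objectives
$1..k{-}1$ bounded at their achieved values times $(1+\delta)$,
$\delta = 0.03$ by default (a two-phase-style slack; $\delta = 0$ gives
strict lexicographic ordering). An objective marked `sufficient` is
bounded at its goal instead, so lower priorities may consume any slack
beyond it. Bounds are always placed at the achieved value when the goal
was not reached — clamping to an unattained goal would make the next
stage infeasible.

### Numerical realization

No LP/SOCP library is available in the target environment, so each stage
is solved as a strictly convex quadratic program (`quadprog`): the linear
stage cost plus a Tikhonov ridge of $10^{-7}$ on the weights. As the
ridge vanishes this selects the minimum-norm optimum of the underlying
LP, which doubles as the documented tie-break among equal-cost optima —
tests therefore assert objective values, never weight vectors. Voxel-wise
constraint families (robust minimum/maximum dose across scenarios,
per-field caps, max-dose epigraph rows) are handled by cutting planes:
solve, find the worst violated voxel rows (up to 40 per family per
round), add them, repeat until no violation exceeds $10^{-4}$ Gy.
Max-dose objectives use one auxiliary epigraph variable per stage.
Infeasible wish-lists are diagnosed by an elastic re-solve (one slack per
constraint) that names the violated constraints in wish-list order.

## Sparsification: SISS, ELR, BAO

All three sparsification stages run on a scalarized surrogate of the
wish-list — a weighted sum with priority $k$ weighted $10^{1-k}$ — under
all hard constraints, because one convex solve per candidate coefficient
is what keeps coefficient tuning tractable; the full lexicographic stack
then runs on the selected support.

* **SISS** (spot selection) adds an L1 term, exact for nonnegative
  weights; spots above $10^{-3}$ of the maximum weight survive.
* **ELR** (energy-layer reduction, the PAT-specific stage) adds a
  classical group lasso $\lambda \sum_g \sqrt{|g|}\,\lVert w_g\rVert_2$
  over (field, energy-layer) groups; layers above $10^{-3}$ of the
  largest group norm survive, and all spots of unselected layers are
  removed before SISS and MCO. $\lambda = 0$ reproduces the Utopia
  problem exactly; `tune_lambda()` bisects $\log\lambda$ to a target
  layer count.
* **BAO** (beam-angle optimization) applies the same group machinery with
  one group per beam over 72 equiangular candidates at coarse spot
  spacings (a runtime/fidelity knob), ranks beams by group norm, and
  keeps the top N (ties to the smaller gantry angle). "Group
  normalization" in the source literature is read as group
  regularization. For the BAO modes two full plans are generated — range
  shifters in all fields and in none — and the one with the lower summed
  NTCP (ties: lower integral dose) is kept.

The nonsmooth group penalty is minimized by an MM scheme: iteratively
reweighted quadratic majorization of the smoothed group norm
$\sqrt{\lVert w_g\rVert^2 + \varepsilon^2}$, with $\varepsilon$ annealed
from the solution scale down to $10^{-4}$ of it (the plain IRLS majorizer
freezes groups that start at zero). Because the IRLS tail is geometric,
the limits of dying group norms are recovered by Aitken $\Delta^2$
extrapolation of the last three iterates; only the *selection* uses the
extrapolated norms — every downstream stage re-solves on the selected
support, so the final weights never depend on the extrapolation.

## Finalization and evaluation

`enforce_mu_limits()` removes spots below the minimum monitor-unit
threshold and re-solves the stage-final scalarized problem once on the
reduced support with box constraints (a documented simplification of the
reference-point constraint restoration). The default box (0.02–500
MU-equivalents) reflects this engine's dose-per-MU scale; the limits are
machine configuration. `normalize_plan()` then scales all weights so the
CTV70 D98% of the voxel-wise minimum dose over the 21 scenarios equals
95% of prescription — exact by dose linearity — and re-checks the MU box,
warning rather than looping to guarantee termination. Because robust
coverage is a hard constraint, the scale factor is never above 1, so
normalization cannot break the per-field cap.

Evaluation reports nominal mean doses, D98% of the voxel-wise minimum
(robust coverage), and the near-maximum as D2% of the voxel-wise maximum
(the common convention for "near-maximum"; configurable). DVH percentiles
are computed on the voxel grid without sub-voxel interpolation
(descending sort, index $\lceil q n / 100 \rceil$). NTCP models are
logistic with identity or square-root dose transforms; the shipped
coefficients are labelled illustrative — the protocol values are data the
package does not claim. Integral dose integrates over the whole body with
nothing excluded (an `--exclude-targets` style switch is deliberately
absent from the default path and the choice is visible in every report).
Paired mode comparisons use an exact two-sided Wilcoxon signed-rank test:
zeros dropped, mid-ranks for ties, null distribution enumerated by
convolution for up to 25 pairs (all-positive differences at n = 10 give
the familiar two-sided floor p = 2/1024 ≈ 0.002).

## Problem sizes used by the tests

The test suite runs the full 21-scenario 4-field pipeline on the default
44×44×1 phantom (≈ 300 candidate spots — minutes), and the 36-field and
72-candidate studies at coarser spot spacings (10–12 mm) with the nominal
scenario only (seconds per solve). These sizes are the package's chosen
study conditions for a laptop-class machine; the algorithms themselves
are size-agnostic. Ten seeded phantoms back the ordering-law and
statistics tests, mirroring a ten-patient cohort design.

## What passing tests do and do not show

The synthetic bed exercises every algorithmic claim: scenario
composition, robust constraint satisfaction, the 34 mm shifter pullback,
lexicographic optimality against brute-force oracles, the monotone
EL-count/quality trade-off, Utopia as a quality ceiling, weak improvement
with more personalized beams, exact normalization, MU feasibility, and
exact paired statistics. It does not validate clinical dosimetry: the
engine has no nuclear halo, no heterogeneity scatter, no CT calibration,
and quasi-2D geometry; cohort-level clinical numbers (absolute NTCP
gains, clinical EL counts) are outside what synthetic phantoms can
reproduce and are not targets of this package.

## Known limitations

Parallel-ray geometry (no divergence); one global density scaling as the
range-error mechanism; surrogate-based (not lexicographic) sparsification
stages; single re-optimization instead of full constraint restoration;
per-field energy-layer caps not enforced (only the total is controlled; a
config hook exists); non-coplanar candidates limited to the printed
class-solution couch angles.
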