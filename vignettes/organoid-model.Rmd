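---
title: "The organoidsim growth model and its morphometric layer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The organoidsim growth model and its morphometric layer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`organoidsim` grows a three-dimensional tumor organoid from a single founder
cell with a center-based, off-lattice agent model.  Each cell is a sphere
described by its center $X_i$ (micrometers), current radius $R_i$, age $A_i$
(hours), an individual division age $A_{i,div}$, a cell-cycle phase and an
arrest flag.  Three ingredients drive the dynamics.

**Mechanics.**  Overlapping cells repel through linear Hookean springs with
rest length equal to the sum of their current radii,

$$ f^{rep}_{i,j} = F^{rep}\,\big((R_i+R_j) - \lVert X_i - X_j\rVert\big)\,
   \frac{X_i - X_j}{\lVert X_i - X_j\rVert},
   \qquad \lVert X_i - X_j\rVert < R_i + R_j, $$

and cells that drift into the window $(2R_{max},\, 2.25R_{max})$ are pulled
back toward the rest separation $2R_{max}$ by a weaker adhesive spring.
Motion is overdamped: the net force, divided by a damping coefficient
$\eta$, gives the velocity, and positions follow the explicit-Euler update
$X_i(t+\Delta t) = X_i(t) + \Delta t\, F_i/\eta$.  No inertia or velocity
state is kept.

**Cell cycle.**  Each lifespan is split into G1/S/G2/M at fixed fractions
45/35/15/5% of the individual division age.  The radius grows linearly from
$0.65\,R_{max}$ at birth to $R_{max}$ at the end of G2 (95% of the
lifespan); growth happens predominantly in G1 but continues through G2.
When a non-arrested cell reaches its division age, it is replaced by two
daughters placed symmetrically at $\pm 0.5\,R_{max}$ along a random axis
whose polar angle is uniform on $[0,\pi]$ and azimuth uniform on
$[0,2\pi)$.  Daughters start at age 0, radius $0.65\,R_{max}$, and receive
individual division ages $A_{div}(1+U)$, $U\sim\mathcal U(-w, w)$, which
desynchronizes the population.

**Contact inhibition.**  A cell arrests while the number of other cells
within two cell diameters exceeds the threshold $N_{neigh}$.  Arrest
freezes the cycle clock — arrest time never counts toward any phase — and
the cell resumes where it stopped once the neighborhood thins out.

One biology step of `dt` applies, in order: (1) recompute neighbor counts
and arrest flags; (2) advance the clock of non-arrested cells; (3) divide
all eligible cells simultaneously, with placements computed from the
pre-step configuration so the result cannot depend on cell order;
(4) mechanical relaxation, i.e. repeated force/relocate sub-steps until the
largest per-cell displacement falls below a tolerance (or the sub-step cap
is reached, which is logged as a warning because it indicates mis-tuned
stiffness).

## Parameters and defaults

The three biological parameters varied in morphochart studies are the
maximal radius `r_max` (5–10 um), the division age `a_div` (6–32 h) and the
inhibition threshold `n_neigh` (3–22 cells).  The remaining constants are
not biologically observable and deserve explanation:

* `f_rep/eta = 10 /h`, `f_adh/eta = 0.1 /h`.  Only the ratios to $\eta$
  matter in overdamped motion, so stiffnesses are expressed in units of
  $\eta$.  Repulsion is stiff enough that a freshly divided pair reaches
  its equilibrium separation well within one cell-cycle; adhesion is two
  orders of magnitude weaker.  Adhesion strength is the single most
  sensitive hidden constant of the model: because relaxation runs to
  quasi-equilibrium every step, any pair that wanders through the adhesion
  window is captured and consolidated at separation $2R_{max}$, and strong
  adhesion therefore acts like a surface tension that compacts the
  organoid, raises every neighbor count, and can cut the 14-day cell count
  in half.  The default keeps cohesion (detached fragments are still pulled
  back) without that artificial compaction.
* `dt = 0.1 h`, `dt_mech = 0.02 h`, `relax_tol_factor = 0.05`,
  `max_substeps = 200`.  `dt_mech * f_rep/eta = 0.2 < 1` guarantees an
  overlapping pair cannot overshoot its spring equilibrium in one sub-step.
  Relaxation stops once the largest sub-step displacement is below
  `0.05 * r_max` (0.35 um at the default radius), i.e. geometry is resolved
  to a few percent of a cell radius — finer tolerances only burn sub-steps
  re-tightening a packing whose neighbor topology no longer changes.
* `noise_frac = 0.05`.  A division-age jitter of ±5% is enough to break
  the synchronized doubling of the founder's lineage within a few
  generations while keeping the mean cycle length at `a_div`.
* `inhibition_scope = "current"`.  The text's "two cell diameters" is read
  as two diameters of the surveying cell, `4 * radius_i`; a newborn
  (radius $0.65R_{max}$) therefore surveys a ball of `18.2 um` that widens
  to `28 um` as it matures.  The alternative fixed-ball reading
  (`"r_max"`) is available; it arrests newborns in crowded crusts slightly
  more aggressively.
* `arrest_growth = "continue"`.  Arrested cells stay metabolically active:
  their radius keeps growing toward $R_{max}$ even though the cycle clock
  is frozen.  The alternative (`"freeze"`) turns out to be structurally
  degenerate: a cell arrested right after birth then stays at
  $0.65R_{max}$ indefinitely, newborn crusts remain densely packed, counts
  never fall, and whole organoids lock up permanently at a few dozen
  cells.  With growth continuing, maturing cells push their neighborhood
  apart, counts drop back below threshold, and proliferation proceeds in
  waves — which is the regime the morphochart studies describe.
* `division_axis = "polar"`.  The polar angle of the division axis is
  sampled uniformly on $[0,\pi]$, which over-weights the poles relative to
  an area-uniform direction.  This convention is kept deliberately (it
  seeds the early elongation that grows into branched morphologies at
  strict inhibition); `"area"` switches to uniform-on-sphere sampling.

## Morphometrics

* **Diameter** `D`: the mean of the maximal caliper (Feret) extents of the
  union of projected cell disks on the xy, yz and xz planes, i.e. the mean
  over planes of $\max_{i,j}(\lVert p_i-p_j\rVert + R_i + R_j)$ floored at
  the largest single-cell diameter.  The implementation prunes candidates
  with the triangle inequality but is exact (tests compare against the
  quadratic pair scan).
* **Radius of gyration** `RGYR` $= \sqrt{\sum_i \lVert X_i - X_C\rVert^2 /
  N_{cells}}$ with $X_C$ the unweighted mean of centers.  The square root
  is taken so the value carries units of micrometers; cells are
  near-uniform in size, so no mass weighting is applied.  Lower values mean
  a more compact organoid.
* **Accessible surface area** `ASA`: a Monte-Carlo estimate of the exposed
  surface of the union of cell spheres.  Each cell receives `n_points`
  (default 500) area-uniform directions on a shell inflated by a relative
  `epsilon` ($10^{-6}$ by default, a pure contact test); points falling
  inside any other (equally inflated) cell are removed, and each survivor
  stands for an equal area fraction $4\pi R_i^2 / n_{points}$.  Per-cell
  direction streams are derived from `(seed, cell id)`, so the estimate is
  independent of row order.  With the contact-test default, two cells must
  genuinely overlap before any surface is considered buried — cells at
  exactly touching distance shade nothing.  Users wanting a solvent-probe
  behavior (as in molecular surface-area codes) can raise `epsilon`, which
  acts as a probe radius in units of the cell radius.

## The calibration gate and sweep

A reference growth curve (mean ± standard deviation of diameter at days 0,
3, 7, 10 and 14) gates simulated runs: a run is accepted iff its diameter
lies within the band at every observation day **and** the coefficient of
determination against the means,
$R^2 = 1 - \sum_k (D_k - \bar D_k)^2 / \sum_k (\bar D_k - \langle \bar
D\rangle)^2$, exceeds 0.9.  A parameter triple is accepted only when all
(default 3) replicates pass individually.  The band is a hard conjunction
over days, so the sweep truncates a run as soon as its diameter exceeds
`mean + std` at an observation day — the verdict is already final, and
this is what keeps the unconstrained corners of the grid (weak inhibition,
fast division) affordable.

The package ships a clearly labeled synthetic stand-in curve
(`default_growth_curve()`), generated by `synthetic_growth_curve()` from
the reference triple `r_max = 7 um, a_div = 13 h, n_neigh = 9` over three
seeds.  Its day-0 mean is anchored at the founder diameter `2 r_max`, and
the band half-width is floored at 15% of the mean, a typical
organoid-to-organoid variability in cultured replicates (including seeding
variability at day 0).  The synthetic curve emulates the *shape* of a
measured growth trend — monotone, roughly linear after an initial lag —
but not any particular cell line; passing the gate against it demonstrates
the machinery, not agreement with a specific experiment.  The intermediate
"optimal fitting curve" some laboratory protocols interpolate through the
measured points is deliberately omitted: the gate compares at the five
observation days directly, where interpolation adds nothing.

## Morphophenotype classification

Accepted organoids are clustered in the (RGYR, ASA) plane with classical
k-medians: Lloyd-style alternation of Manhattan-distance assignment and
componentwise-median centroid updates, best of 20 seeded restarts
(alternating farthest-point and random-subset initializations), empty
clusters reseeded at the worst-fit point.  Features are RGYR in
micrometers and ASA in $10^4\,\mu m^2$; their dynamic ranges are
comparable, so no scaling is applied by default (`scale_features` enables
it).  The four classes are labeled by descending centroid RGYR —
Spherical, Compact, Elongated, Branched — matching the qualitative ladder
from large loose spheres to small branched trees.  Assignment of new
organoids is nearest-centroid in the same metric, ties toward the
lower class index; the fit itself is made permutation-invariant by sorting
the input before seeding the restarts.

## Numerical choices and degenerate inputs

* Coincident cell centers (possible only through pathological input) make
  the spring direction undefined; they are resolved with a seeded random
  unit direction and a warning.
* A neighbor at exactly the inhibition distance is *not* counted (strict
  inequality), and adhesion is active on the open window only.
* Division eligibility uses `age >= div_age - 1e-9` so an age accumulated
  in floating-point steps divides on the crossing step.
* All randomness flows from one global seed through named sub-streams
  (`simulation`, `asa`, `kmedians`, per-replicate sweep seeds) via a small
  deterministic hash, so every stage is independently reproducible and the
  full simulate–metrics–classify pipeline is byte-identical across reruns.
* Snapshots serialize with `%.17g` precision; the CSV and extended-XYZ
  dialects reconstruct identical objects.

## What the tests do and do not show

The test suite checks the mechanics against closed forms (spring laws,
two-cell equilibrium, exact population doubling with inhibition disabled),
the morphometrics against analytic oracles (sphere area, two-sphere
spherical-cap formula, cube radius of gyration, brute-force recomputations)
and the clustering against exhaustive enumeration on small inputs.
Study-scale checks simulate 14-day organoids at `r_max = 7 um` for the
handful of (a_div, n_neigh) pairs with published structural scores, three
seeds each, and a scaled-down sweep (a_div 11–21 h in 2 h steps, n_neigh
6–21 in steps of 3, three replicates against the synthetic curve) whose
accepted library is clustered into four classes; these sizes keep the
default suite to minutes on a laptop while still exercising every stage at
organoid scale.  Because the gate curve is synthetic and several of the
original model constants (stiffnesses, damping, time step, noise amplitude,
the exact neighbor-count convention, the surface-sampling offset) are not
recoverable, quantitative agreement with any particular published organoid
library is *not* something these tests can establish; reproducing the
four-class structure and the co-ordering of RGYR and ASA across classes is.

## Known limitations

* No cell death, motility, extracellular matrix, nutrient or oxygen
  gradients, or drug transport: the model covers the early, pre-hypoxic
  growth phase only (organoids under ~150 um radius).
* The Monte-Carlo ASA is an estimator of the union-of-spheres surface, not
  an exact mesh; its accuracy is set by `n_points` per cell.
* With full per-step relaxation the emergent packing sits at the spring
  rest lengths, so simulated organoids are never compressed below contact;
  published organoid libraries whose surface-area values imply deeply
  buried interiors cannot be matched by this estimator/dynamics
  combination at any parameter setting we explored.
* The synthetic default curve makes the calibration gate demonstrable but
  not biologically meaningful; supply a measured curve for real studies.
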