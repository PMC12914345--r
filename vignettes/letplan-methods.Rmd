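---
title: "Models and methods behind letplan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind letplan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`letplan` studies a specific conflict in intensity-modulated proton therapy
(IMPT) planning: managing setup and range uncertainty through robust
optimization pushes dose into the low-LET plateau of the proton depth-dose
curve, while the biologically attractive high-LET dose lives at the Bragg
peak. This vignette documents the models, the numerical choices, and what
the synthetic phantoms can and cannot tell you about real patients.

## Phantoms: the synthetic study population

Patient CT data for anatomically challenging pediatric brain tumors cannot
be shipped with a package, so `letplan` generates deterministic voxel
phantoms (3 × 3 × 3 mm³, the grid resolution typical of this planning
problem) from piecewise geometry: a spherical head with a 4 mm bone shell
(relative stopping power 1.5), a neck cylinder, soft tissue at 1.0 and air
at 0.001, a brainstem cylinder and a spinal-cord column. Three archetypes
reproduce the anatomical relationships that drive the planning trade-offs:

* `wraparound` — a C-shaped CTV around the brainstem sharing ≈22 % of the
  brainstem voxels. The overlap fraction is a step function of the C's
  inner radius and opening angle on a voxel grid, so the builder does a
  small deterministic grid search over both rather than a bisection that
  could land between steps; the achieved fraction is kept within
  19–25 %.
* `abutting` — a spherical CTV pressed against the brainstem posteriorly.
* `inferior_extension` — an elongated CTV running inferiorly past the
  brainstem and enclosing a stretch of spinal cord.

Default CTV volumes are 55.27, 56.67, and 40.88 cc; the free size
parameter of each archetype is tuned by bisection until the voxelized
volume lands within 5 % of the request. Beam arrangements (three to four
beams, including a vertex beam for the inferior-extension case) mirror the
kinds of arrangements used clinically for these anatomies.

What the phantoms deliberately do not model: realistic CT texture,
lateral tissue heterogeneity along each beam path, anatomy deformation,
and age-specific scaling. Consequences are discussed at the end.

## Beam model

The influence engine is analytical. For a spot of nominal water range $R$:

* depth dose = a gently rising plateau (entrance ≈ 23 % of peak) cut off
  smoothly at the peak, plus a Gaussian Bragg peak at $R$ with straggling
  width $\sigma_R = 0.015R + 1$ mm and a sharper distal than proximal
  shoulder (distal width $0.8\sigma_R$). A 0.1 mm sweep confirms the
  maximum sits within 2 % of $R$ and dose is below 1 % of the peak 20 mm
  beyond it.
* LET(z) rises monotonically from ≈1 keV/µm at entrance to 11 keV/µm at
  and just beyond the peak, as
  $\mathrm{LET}(z) = 0.9 + 10.1/(1 + (\rho/4)^2)$ with residual range
  $\rho = \max(R - z, 0)$ in mm. The shape concentrates high LET in the
  final ~8 mm of range, which is what makes dose-averaged LET (LETd)
  sensitive to whether a voxel is covered by a stopping beam or by the
  plateau of a deeper one. The 5–15 keV/µm peak regime matches published
  LETd maps for scanned proton beams.
* lateral spread is a single Gaussian with $\sigma(d) = 3 + 0.03 d$ mm,
  normalized as a 2-D density so the integrated depth dose is preserved.

Water-equivalent depth is computed per voxel by tracing rays against the
beam direction with 1 mm midpoint sampling of the density grid
(nearest-neighbor sampling — the phantom is piecewise constant, so this
matches trilinear interpolation up to the voxelization itself). Beams are
parallel (no divergence); a rigid patient shift therefore changes the
lateral position of each voxel relative to the spot lattice but not its
intrinsic radiological depth, and a shift purely along the beam axis is a
no-op. Spots are placed on a 5 mm lateral grid covering the CTV's
beam's-eye-view projection plus one spacing of margin; energy layers sit
on a 5 mm water-equivalent lattice restricted to depths where CTV voxels
actually are (so the gap inside a C-shaped target gets no spots), plus one
distal margin layer so range-overshoot scenarios remain coverable.
Influence entries below 10⁻⁴ of each spot's peak are dropped.

## Optimization strategies

All strategies optimize nonnegative spot weights $w$ with analytic
gradients under L-BFGS-B. Doses inside the objectives are constant-RBE
weighted (1.1 × physical). The dose objective is

$$F_D(w) = \frac{p_u}{N_T}\sum_{i \in T} \max(0, p - d_i)^2
         + \frac{p_o}{N_T}\sum_{i \in T} \max(0, d_i - p)^2
         + \sum_{O} \frac{p_O}{N_O}\sum_{i \in O} \max(0, d_i - m_O)^2,$$

with prescription $p = 54$ Gy(RBE) and maximum-dose levels
$m = 60/57$ Gy(RBE) for brainstem/spinal cord. OAR limits are enforced as
heavy penalties plus post-hoc acceptability checks (CTV D95 ≥ 51 Gy(RBE),
brainstem ≤ 60, cord ≤ 57), the same acceptability logic used clinically.
An optional linear total-fluence term (`mu_weight`) exists as an
integral-dose surrogate; the shipped configurations leave it off.

The LET strategy extends this with dose-averaged-LET terms,

$$F_L(w) = F_D(w) - \frac{\phi_T}{N_T}\sum_{i\in T} L_i^2
                  + \frac{\phi_O}{N_O}\sum_{i\in O} L_i^2,
\qquad L_i = \frac{\sum_j D_{ij} L_{ij} w_j}{\sum_j D_{ij} w_j},$$

whose gradient needs the quotient rule
$\partial L_i/\partial w_j = D_{ij}(L_{ij} - L_i)/\sum_k D_{ik} w_k$;
zero-dose voxels contribute neither value nor gradient. The OAR set of the
LET terms is the union of brainstem and spinal-cord voxels, and only the
nominal scenario is used — LET optimization here deliberately carries no
robustness component, because the package exists to compare the two pure
strategies.

The robust strategy is the objective-wise worst case: each term of $F_D$
(target underdose, target overdose, each OAR) is evaluated in all nine
scenarios and its maximum kept; gradients come from each term's active
worst scenario, ties broken toward the lowest scenario index for
determinism. The scenario set is one nominal, ±2.25 mm single-axis setup
shifts (six), and ±3.5 % range scaling (two), all equally weighted — the
standard nine-scenario uncertainty model. Setup shifts enter as an
isocenter displacement of the opposite sign; range scaling multiplies
radiological depth, which is equivalent at this fidelity to perturbing
beam energies and much simpler to verify.

### Solver and convergence policy

The worst-case composite is only piecewise smooth, and a quasi-Newton
method started far from a solution stalls at kinks. The robust solve
therefore uses continuation: the same objective evaluated on the
scenario-averaged influence matrix (a smooth surrogate) is minimized
first from the uniform start, and the exact worst-case composite is
polished from that seed with restarted L-BFGS-B rounds.

The quadratic dose objective is heavily degenerate: many weight
configurations produce nearly identical dose distributions, and once
clinical convergence is reached (coverage and OAR terms essentially
final), further iterations only redistribute weight among equivalent
solutions — empirically always toward more laterally- and depth-smeared,
more homogeneous plans. Run to numerical convergence, the "nominal" plan
converges toward an implicitly robust, plateau-dominated solution that no
clinical optimizer run produces, erasing precisely the structure
(peak-rich coverage, scenario sensitivity) that distinguishes nominal
planning in practice. The shipped configurations therefore cap the
nominal and LET solves at 150 iterations — the scale of a clinical
optimizer run, stopped at clinical convergence — while the robust
composite, whose solution is the point of the exercise, runs to full
convergence (500 iterations × 4 restart rounds). This is the package's
analog of the per-plan fine-tuning that treatment planners apply: each
strategy is run the way it would actually be run. Penalty weights
(target under/over 1000/150, OARs 5000, $\phi_T = \phi_O = 20$) are
shared across strategies and archetypes.

With these conditions, the study reproduces the qualitative clinical
signatures: the robust plan has the lowest mean target LETd (8–20 % below
nominal across archetypes) and the narrowest CTV mean-dose bandwidth
across scenarios; the LET plan has the highest target LETd and the lowest
brainstem maximum LETd; all nine plans meet the acceptability thresholds
after normalization.

## Evaluation conventions

* Every plan is normalized so its nominal-scenario constant-RBE CTV D95
  equals 54 Gy(RBE). D95 is the largest dose received by at least 95 % of
  the structure (sort-based, no interpolation). Dose is linear in $w$, so
  the normalization is exact; LETd is homogeneous of degree zero in $w$
  and unaffected.
* LETd statistics zero the LETd wherever the paired dose is at or below
  1 Gy; the threshold is applied to the constant-RBE-weighted dose
  (matching the Gy(RBE) reporting convention; configurable), and masked
  means include the zeroed voxels.
* Robustness of a metric is summarized by its worst-case minimum, maximum
  and their difference (bandwidth) across the nine scenarios.
* Biological effect uses the McNamara variable-RBE model with
  $(\alpha/\beta)_x = 10$ Gy for tumor and 2 Gy for OARs and 30 equal
  fractions; the published coefficient fit is stored as configuration
  data (`rbe_parameters()`), not scattered literals, so an alternative
  fit can be swapped in. The linear surrogate $D(1 + c\,\mathrm{LETd})$
  with $c = 0.04$ µm/keV is reported alongside; its `component`
  $c\,\mathrm{LETd}\,D$ is the LET-driven part of the biological dose.

## Numerical choices and degenerate inputs

* Voxel convention: world position of voxel $(i,j,k)$ (1-based) is
  `origin + (index − 0.5) · voxel_size`; axes are ordered left–right,
  anterior–posterior, superior–inferior.
* Zero-dose voxels have LETd defined as 0 everywhere (maps, objectives,
  statistics); empty structure masks raise errors naming the structure.
* The LETd map, gradients, and worst-case composition are each tested
  against independent oracles: dense double loops, central finite
  differences, and explicit scenario enumeration.
* Determinism: phantom construction, spot placement, scenario generation
  and the solver path are all deterministic given the configuration and
  seed; rerunning an experiment reproduces the summary CSVs bit for bit.

## Problem sizes

The default study uses ≈44 × 44 × 56 voxel grids, 2 000–2 600 beamlets
per archetype, and nine influence scenarios of roughly 2 × 10⁶ nonzeros
each; a full three-archetype, three-strategy run evaluates 27
plan-scenario combinations and completes in a few minutes per archetype on
one CPU. Unit tests use a 30 × 30 × 36 phantom with a 12 cc target so the
whole suite stays fast.

## Known limitations

* The beam model is a parametric stand-in for a commissioned beam line:
  no nuclear halo, no double-Gaussian lateral tails, no
  heterogeneity-induced lateral scattering distortions. Absolute LETd
  values are therefore calibrated only to the physically expected regime
  (entrance ≈1, peak ≈11 keV/µm); comparisons between strategies are the
  meaningful output, not absolute numbers.
* Parallel beams make along-axis setup shifts exact no-ops and decouple
  rigid shifts from radiological depth. Real divergent beams and real
  anatomy couple these weakly.
* The phantoms' lateral homogeneity means range scenarios rescale all
  depths coherently; patient-specific heterogeneity would make range
  errors spatially correlated with anatomy in ways these phantoms cannot
  show. Passing the ordering tests here demonstrates the mechanisms, not
  patient-specific magnitudes.
* No combined robust-plus-LET optimization is provided; the two pure
  strategies are the designed endpoints of the comparison.
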