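---
title: "Coverage-volume histograms and Iris aperture selection: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coverage-volume histograms and Iris aperture selection: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irisopt)
```

This vignette documents the geometric model behind `irisopt`, the design
decisions where the method left genuine freedom, and what the synthetic
cohort does and does not emulate. It is the companion to the function
reference; nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The geometric delivery model

The package evaluates tracked aperture delivery purely geometrically.
Three assumptions define the model:

* **Rigid target motion.** Tracking error displaces the aperture relative
  to an undeformed target; tumour deformation and segmentation uncertainty
  are out of scope.
* **Ball aperture.** The field of nominal diameter $d$ is a ball centred on
  the predicted target position. Beam divergence to the 800 mm reference
  distance and the non-isocentric beam arrangement are collapsed into this
  ball, so no beam-direction-resolved fluence exists in the model.
* **Target-frame accumulation.** Only the relative displacement between
  aperture and target matters for their intersection, so the CTV stays
  fixed and the aperture centre moves to $c_0 + e_t$, where $c_0$ is the
  CTV centroid and $e_t = \mathrm{pred}_t - \mathrm{true}_t$ the tracking
  error at imaging point $t$. This sidesteps the unmodelled motion of the
  surrounding anatomy; the cosine breathing path in the trace simulator
  therefore does not influence coverage, and is kept only so written traces
  look like plausible logs.

A voxel is inside the aperture iff its **centre** is within $d/2$ of the
aperture centre — no partial-volume weighting. This convention makes the
engine exactly equal to a brute-force per-voxel membership loop (a property
the test suite checks on grids up to $40^3$), at the cost of a half-voxel
boundary granularity that shrinks as the grid is refined.

Coverage and leakage possibilities are averages over all imaging points of
all fractions with equal weight; no per-fraction weighting is applied.

## Margins, axes and their conventions

`expand_margin()` implements Euclidean-ball dilation on the voxel lattice:
an output voxel is set iff its centre lies within the margin of a set input
voxel centre. On a lattice this is exact for the stated definition, but the
effective dilation radius along directions not realized by any lattice
vector of length $\le$ margin falls short by up to about half a voxel (e.g.
along the cube diagonal). All geometry tests therefore use a one-voxel
tolerance, and grids should be chosen so the margin spans at least two
voxels. The grid auto-enlarges by `ceiling(margin/spacing) + 1` voxels per
face before dilation, so expansions are never clipped.

The long axis $A_{max}$ is the maximum Feret diameter of the structure's
surface-voxel centres plus one voxel spacing (so a digitized sphere of
diameter $d$ measures $d$, not $d$ minus a spacing). The short axis
$A_{min}$ is the minimal rotating-calipers width of the surface projected
onto the plane orthogonal to the long-axis direction, plus the same
padding. This pair was chosen over bounding-box extents because it is
rotation-robust and matches the clinical reading of "length of the
long/short axis"; a single-voxel structure reports both lengths equal to
the voxel spacing, keeping the candidate interval
$[0.5 A_{min}, A_{max} + 5]$ well defined. Axis lengths are quoted in mm
throughout — the only internally consistent unit, since the Iris diameters
are defined in mm and a 56.8 cm thoracic target is impossible.

## Histogram and metric conventions

CVH/LVH curves are discretized on 1001 evenly spaced levels in $[0, 1]$,
but every scalar metric is computed from the raw voxel values, so metrics
are independent of the discretization:

* $C_{95}$/$C_{90}$ is the order statistic of the voxel values (the
  5th/10th percentile from the top), mirroring the DVH D95 convention; at
  exact ties the largest level still satisfying the volume constraint is
  reported.
* Both areas under the curves are computed as
  $\mathrm{voxel\ volume} \times \sum_v \mathrm{value}(v)$, the exact value
  of the level integral, on the **absolute** volume scale (cm³·possibility)
  for coverage and leakage alike. This makes the leakage/coverage ratio
  dimensionless and the absolute mean leakage value a possibility fraction
  in $[0, 1]$.
* The leakage support is the set of voxels that entered the aperture at
  least once while outside the CTV; an aperture that never leaves the CTV
  has zero support, and the mean leakage is then reported as 0 (and the
  leakage/coverage ratio as 0 through a zero numerator).
* PTV voxels outside the CTV are scored by aperture inclusion alone. The
  alternative — scoring them by membership in the CTV∩aperture
  intersection — would force PTV coverage to zero on the PTV rim by
  definition; aperture inclusion is the reading consistent with reporting a
  "PTV C95 coverage" at all, and the CVH builder accepts any evaluation
  structure, so either convention can be computed explicitly.

## The selection rule

Candidates are the Iris diameters within $[0.5 A_{min}, A_{max} + 5]$ mm of
the PTV axes. Feasibility prefers the strict tier ($C_{95}$ of CTV
$\ge 90\%$) and degrades explicitly to the relaxed tier ($C_{90}$ of CTV
$\ge 90\%$); if neither is attainable the result carries `tier = "none"`
and no selection, rather than silently picking something.

The cost $F(d) = w\,C_{95}^{PTV}(d) - \overline{\mathrm{leak}}(d)/V_{lung}$
is **maximized**. The rule is sometimes phrased as picking the *lowest*
cost value, but the construction — coverage entering with positive weight,
leakage with negative — only rewards coverage and penalizes leakage if the
best plan is the argmax; with the clinical default $w = 0$, maximizing $F$
is exactly minimizing the mean leakage, which is the behaviour the method
is meant to deliver ("spare the most normal tissue among feasible
apertures"). The literal minimize mode is retained behind
`direction = "minimize"` for comparison experiments. $C_{95}^{PTV}$ enters
as a fraction in $[0,1]$ so a user-chosen $w$ trades off against
$\overline{\mathrm{leak}}/V_{lung}$ on comparable scales. Cost ties break
toward the smaller diameter: at equal measured cost the smaller aperture is
the safer choice. With $w = 0$ the selection is invariant to any positive
rescaling of $V_{lung}$ (tested).

The strict-vs-relaxed "group" comparison re-runs the selection per
threshold variant. Since the per-candidate metrics do not depend on the
threshold, this is equivalent to re-filtering the same cost table, but the
code path genuinely re-executes the cascade and selection per variant.

## Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| GTV→CTV, CTV→PTV margins | 2, 4 | mm | standard microscopic-extension and delivery-uncertainty margins for this delivery technique |
| grid spacing | 1 (plans), 2 (cohort) | mm | planning-CT scale; 2 mm keeps a 37-patient × 7-candidate study in minutes while staying well below the smallest aperture |
| coverage thresholds | C95/C90 ≥ 90 | % | the two clinical target-coverage tiers of the selection rule |
| `w` | 0 | – | PTV coverage not enforced once CTV coverage is feasible |
| `v_lung` | 1500 | cm³ | typical single-lung volume; per-patient input in practice |
| imaging cadence | 1 point / 15 s, 40 points/fraction | – | x-ray imaging interval is vendor- and protocol-dependent; both are config parameters |
| histogram levels | 1001 | – | curve resolution only; metrics use raw values |

## The synthetic cohort

`cohort_spec()`/`sample_cohort()` emulate the published cohort at the
distribution level: truncated-normal PTV axes (56.80 ± 17.26 × 36.36 ±
10.44 mm, jointly resampled until $A_{max} \ge A_{min}$ and
$A_{min} \ge 14$ mm so the eroded CTV stays non-degenerate),
truncated-normal per-axis error SDs (LR 1.21 ± 0.81, AP 0.58 ± 0.31, SI
0.86 ± 0.52 mm), 3–7 fractions around 5.11 ± 1.73, lognormal $V_{lung}$
(median 1500 cm³, $\sigma = 0.25$, invented). Distribution families are
choices — only means and SDs are published. Patients are ellipsoids of
revolution about the long axis, built as a CTV ellipsoid whose 4 mm
Minkowski dilation reproduces the sampled PTV axes; the PTV volume is
therefore implied by the axes (≈ 39 cm³ at the mean axes, consistent with
the published 41.15 ± 30.17 cm³ mean) rather than sampled independently,
which would contradict the axes.

What the synthetic cohort does **not** emulate: irregular, lobulated or
concave target shapes; correlated or non-Gaussian tracking errors
(hysteresis, baseline drift); intra-patient error drift across fractions;
any relation between target size and error magnitude. Consequently,
cohort-level conclusions are checked at the **sign/ordering** level only —
the strict threshold selects larger apertures with more leakage, the
aperture-to-short-axis ratio correlates positively with relative leakage —
and per-patient absolute numbers (e.g. mean selected diameter, mean
$\Phi/A_{min}$) will differ from any real cohort. Elongated synthetic
ellipsoids in particular push selections toward the large-diameter end,
because covering 95% of a long CTV axis is the binding constraint.

## Determinism and problem sizes

Every stochastic entry point takes a `seed` and uses an isolated RNG scope
(`withr::with_seed`), so traces, manifests and whole cohort runs are
byte-reproducible. The test suite runs engine-vs-brute-force equivalence on
grids up to $40^3$, monotonicity sweeps over the full 12-diameter Iris set
on five random phantom/trace pairs, SD recovery on 10 000-point traces, and
the full default cohort (37 patients, 2 mm grids, 40 imaging points per
fraction, both threshold variants) — sizes chosen so the whole suite
completes in a few minutes on one core while leaving every assertion
scale-independent.

## Known limitations

* Geometry only: no dose, no DVH/NTCP conversion, no Monte Carlo — a
  high-leakage small aperture and a low-leakage large one may still differ
  dosimetrically in ways coverage/leakage possibilities cannot see.
* Single-aperture plans; combining two Iris diameters is not modelled.
* Isotropic grids and axis-aligned NIfTI orientations only; DICOM-RT
  structures must be rasterized externally.
* The voxel-centre membership rule makes all metrics step functions of the
  diameter at coarse spacing; refine the grid rather than interpreting
  sub-voxel differences.
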