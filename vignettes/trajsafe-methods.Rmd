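---
title: "Trajectory safety scoring and the simulated planning cohort: models, parameters, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trajectory safety scoring and the simulated planning cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(trajsafe)
```

This vignette is the package's own account of what it computes and
why: the geometric model behind the Trajectory Safety Index, the
synthetic anatomy and behavioural simulator that stand in for patient
data, every calibrated parameter with its default and rationale, the
numerical choices, and the limits of what a passing test suite shows.

## 1. Coordinate model

All geometry lives in a single world frame: millimetres, RAS axes
(+x right, +y anterior, +z superior). Voxel indices are 0-based and a
voxel's world position is its **centre**; the voxel-to-world map is an
affine 4×4 matrix. A needle trajectory is the straight segment from a
cortical entry point to the intratumoural target. The midsagittal
plane is defined by the AC and PC landmarks (both on the midline) with
the left–right axis as its normal, so it contains the AC–PC line and
the mid-commissural point.

Two representational decisions matter for every distance the package
reports:

* **Mask distances are measured to nonzero voxel centres**, not to an
  interpolated isosurface. Sub-voxel structure boundaries are not
  defined by a binary mask, and the voxel-centre convention is exactly
  checkable against a brute-force oracle. Consequently a distance can
  be 0 (the segment crosses a voxel's box) while the nearest voxel
  centre is up to half a voxel diagonal away; the scoring functions
  treat box crossing as distance 0.
* **Transgression is exact segment/voxel-box intersection**, computed
  by 3D DDA traversal in index space rather than by sampling points
  along the segment. Sampling has a step-size artefact (a segment can
  clip a voxel corner between two samples); the traversal does not.

Streamlines (CST, vessel centerlines) are polylines whose edges are
straight segments — the native semantics of TRK/TCK files — and the
segment-to-bundle distance is the exact minimum over all edges
(clamped closest-point computation between segment pairs), not a
resampling approximation.

## 2. Zones and the Trajectory Safety Index

Proximity is classified into a high-risk zone 1 and a low-risk zone 2:
within 3 mm of a vessel or of the CST, or within 20 mm of the midline,
is zone 1. All three thresholds are configurable
(`zone_thresholds()`); 3/3/20 mm are the defaults. Two boundary
conventions had to be fixed:

* A distance **exactly equal** to a threshold is zone 2. The zones are
  defined by strict inequalities on either side and the boundary is a
  measure-zero case; assigning it to the low-risk side is documented
  rather than consequential.
* "Distance from midline" is the **minimum over the whole segment**,
  not the entry or target point alone. For a straight segment against
  a plane this is 0 if the endpoints straddle the plane and otherwise
  the smaller endpoint distance. The alternative (entry-point
  distance) was rejected because the risk being flagged — paramedian
  bridging veins, interhemispheric approach — applies anywhere along
  the path.

The TSI adds one point for each of four components: sulcal
transgression, eloquent-cortex (M1) transgression, vessel zone 1,
midline zone 1. Ventricular transgression and CST zone are computed
and reported but never scored. This makes the group mean TSI exactly
the sum of the four per-group component counts divided by the group
size — an identity the test suite asserts on every scored cohort.

When vessels are available both as centerlines and as a mask, the
minimum of the two distances is used: the union of two conservative
representations of the same structure.

## 3. The synthetic scene

`generate_scene()` builds a right hemisphere as a half-ellipsoid
(semi-axes 68 × 85 × 65 mm) with:

* a spherical **tumour** (radius 10–14 mm) placed uniformly such that
  it stays inside a deep *central-core* box; the biopsy target is the
  tumour's voxel centroid;
* a **CST bundle** of 30 streamlines, each a cubic Bézier from a seed
  in the M1 band, through a corona-radiata waypoint above the tumour
  and a capsular waypoint, to the brainstem box. Points that would
  enter the tumour's clearance ball (radius + 2 mm margin) are pushed
  onto the ball with a lateral bias — a space-occupying lesion
  displaces the tract away from the midline, it never transects it.
  The waypoints are tied to the tumour position because the lesions
  being modelled are motor-eloquent *by definition*: the bundle ends
  up 2–5 mm from the tumour surface, within the 10 mm eloquence
  criterion, for every seed tested;
* 80 cortical **vessels** (great-circle arcs on the surface) plus 8
  running in sulcal depths;
* 9 **sulcal sheets**: 3 mm-thick tilted planes folded into the outer
  20% of the cortical shell, ~14 mm apart;
* an **M1 band** (y ∈ [−36, −8] mm of the shell), a deep paramedian
  **ventricle**, and the midline plane at x = 0.

Masks live on a 2 mm isotropic grid whose affine has integer
translations, so coordinates survive the float32 NIfTI round-trip
exactly. Streamlines are written as MRtrix `.tck`; the writer defaults
to Float64LE samples (valid per the format) so that world coordinates
round-trip losslessly, and also emits/reads the common Float32LE.

The four-lobe partition of the hemisphere surface (frontal / parietal
/ temporal / occipital) uses fixed landmark planes: y = −20 mm
(central region), y = −62 mm (occipital), z = 18 mm (Sylvian). These
are coarse but only need to be consistent: lobe changes are counted
against this partition both when sessions are simulated and when
entries are analysed.

## 4. The behavioural simulator

Each of 19 trainees plans one trajectory on each of 10 scenes in a
fixed alternating order (tractography-visible scenes at odd
positions). A session is simulated as follows.

1. The **trajectory-change count** c is drawn Poisson with the group's
   calibrated mean (2.89 T-nBx / 3.66 A-nBx). The Poisson choice
   matches the printed dispersion of the reference counts (SD ≈ √mean)
   and allows zero changes; a `changes_shift` parameter generalises to
   a shifted Poisson.
2. c + 1 **candidate entries** are drawn from the cortical surface
   with a Gaussian preference (τ = 30 mm) around the shortest-path
   entry. Consecutive candidates switch lobe with probability
   lobe-mean / change-mean (0.080 T, 0.180 A), so the expected number
   of lobe changes is exactly the group's calibrated mean (0.23 /
   0.66) while never exceeding the trajectory-change count.
3. The **accepted entry** minimizes a penalty over the candidates:
   weighted indicators for sulcal transgression (1), M1 transgression
   (0.2), vessel zone 1 (0.3), midline zone 1 (0.3), CST zone 1 (3),
   plus 0.5·length/100 mm and N(0, 0.2) noise. The T-nBx planner
   evaluates the CST term against the true bundle; the A-nBx planner
   against a rigidly mislocalized copy (N(0, 15 mm) in-plane shift per
   session) — anatomical guesswork about a tract displaced by the
   tumour. The 15 mm scale makes the anatomical belief effectively
   uninformative at the 3 mm zone threshold, which is the premise the
   two study arms differ on; at 6 mm the belief still overlapped the
   ~15 mm-wide bundle and both groups avoided the true CST almost
   equally well.
4. **Planning time** is lognormal: log t = μ_g + 0.06·(c − c̄_g) +
   γ_g·(order − ō_g) + N(0, 0.55²), with γ = −0.06 per exercise
   position for A-nBx only (the learning curve) and γ = 0 for T-nBx.
   μ_g is set in closed form so that E[t] equals the calibration
   target exactly: the lognormal correction σ²/2, the Poisson moment
   generating factor for the change-count term, and the mean
   exercise-order multiplier are all subtracted analytically.
   σ = 0.55 was chosen so the marginal time distribution is strongly
   right-skewed with a plausible range (roughly 25–1200 s) and a
   group SD near the reference ≈126/164 s.

Change counts are drawn *first* and the candidate mechanism fitted
around them, rather than counting emergent rejections. An emergent
rejection process cannot be calibrated to a printed mean without
tuning an acceptance threshold against the very quantity being
recovered; drawing the count keeps the calibration exact while the
candidate/penalty mechanism still produces the geometric consequences
(entry distributions, CST-awareness asymmetry) the count alone cannot.

Experience is drawn per trainee from three tiers — 5 junior
(U(0.5, 2) years), 7 intermediate (U(2.5, 5)), 7 advanced
(U(5.5, 8)) — giving a cohort mean of ≈ 4.2 years. Experience is
deliberately independent of behaviour: the reference study found no
experience effect, and independence makes the adjusted analyses a
clean null check.

### Calibration fidelity

Averaged over 20 seeds, the simulator recovers its targets: planning
times 196.2/253.2 s (targets 197.5/252.8), trajectory changes
2.91/3.68 (2.89/3.66), lobe changes 0.24/0.64 (0.23/0.66), normalized
times 0.31/0.43 (0.33/0.48). Geometric incidences were tuned once,
coarsely: vessel zone 1 ≈ 59% (target ≈ 56%), sulcal transgression ≈
47% (≈ 49%), midline zone 1 ≈ 11% (≈ 14%). Two reference quantities
are **not** reproduced and are left so deliberately:

* M1 transgression emerges at ≈ 22% against a reference ≈ 34%; pushing
  it higher would require planners to ignore eloquent cortex entirely.
* The between-group TSI difference (reference 1.37 vs 1.70, driven
  mostly by an eloquent-cortex asymmetry) has no mechanism here: both
  simulated groups see and avoid M1 identically. Modelling *why*
  anatomy-only planners transgressed eloquent cortex more often would
  be speculation, so the simulator does not claim that finding.

## 5. Statistics

* **Normalization**: per-trainee min–max over that trainee's 10 times,
  (t − min)/(max − min); a zero range maps to 0.5. The reference
  normalization formula is not public; min–max is the simplest map
  onto [0, 1] whose cohort means land near the printed 0.33/0.48, and
  it is invariant to affine rescaling of a trainee's raw times.
* **Group comparisons**: Welch's t-test for continuous outcomes.
  "Logistic regression" cannot apply to continuous outcomes, so the
  adjusted analysis is linear regression (outcome ~ group +
  experience) for continuous variables and logistic regression for
  binary flags; the adjusted p is the group coefficient's. Constant
  experience degrades gracefully to the unadjusted test with a flag.
  Under a null simulation the adjusted test keeps its nominal 5% size
  (checked at 1000 replicates).
* **Learning curve**: regression of log planning time on exercise
  order within a group. With the study's own variance (σ_log ≈ 0.55 at
  n = 95) the imposed −0.06/exercise A-nBx slope is detected in most
  but not all cohorts, and the T-nBx null is (correctly) flat. The
  power for the 55 s absolute-time group difference is ≈ 0.75 under
  the reference SDs, so tests assert direction always and significance
  in the majority of seeds rather than near-certainty — demanding more
  would fail under the study's own conditions.
* **Clustering**: the 4 features (trajectory changes, lobe changes,
  tractography availability, normalized time) are standardized; a
  k-nearest-neighbour graph (k = 15) is partitioned by Leiden
  modularity (resolution 1.0, seeded); a PCA of the standardized
  features provides the 2D display embedding. Records are canonically
  sorted before graph construction so the partition is invariant to
  record order, and the feature matrix is always assembled in a fixed
  column order. The cluster count is data-dependent and is not a
  claim: on planted well-separated archetypes the method recovers them
  with ≥ 90% purity, which is what the tests assert.

## 6. Numerical choices and degenerate inputs

* Segment–segment distance uses the clamped closest-point algorithm;
  degenerate (zero-length) trajectory segments are rejected at
  construction.
* DDA traversal clips the segment to the grid box first; segments
  entirely outside any mask return FALSE without traversal.
* The empty mask and the empty bundle raise errors rather than
  returning +Inf: silence would make a missing structure look
  maximally safe.
* All generators run under a local RNG scope (seed in, previous RNG
  state restored), so composing them never perturbs the caller's
  random stream, and every pipeline stage records its seed in a JSON
  manifest. Fixed seed in, byte-identical CSV out — asserted
  end-to-end in the suite.

## 7. Problem sizes

The shipped study sizes are the reference design: 10 scenes, 190
sessions per cohort, 20 cohorts for calibration recovery (≈ 90 s on
one core), 200-case oracle-equivalence suites for each geometric
primitive, 1000-case transgression agreement, and 1000-replicate
type-I calibration. Scene masks use a 2 mm grid — fine enough that the
half-voxel-diagonal distance quantization (≈ 1.7 mm) sits below every
zone threshold, coarse enough that a full scene builds in well under a
second.

## 8. What passing tests do and do not show

The synthetic scenes emulate the *geometry* of central-core
motor-eloquent anatomy (structure adjacency, tract displacement,
surface vasculature) but not image intensities, tractography
reconstruction error, brain shift, or inter-patient variability beyond
tumour placement. The behavioural model emulates the *statistics* of
planning behaviour — its means, dispersions, learning trend, and the
visibility asymmetry — not trainee cognition; the candidate-rejection
mechanism is an emulation device, not a cognitive claim. A green suite
therefore certifies that the geometric scoring is exact to its stated
oracles and that the statistical machinery recovers known planted
truths under the study's sample sizes. It does not certify that real
trainees behave like the simulator, and inferential p-values from the
reference cohort's raw data are not reproducible from summaries.
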