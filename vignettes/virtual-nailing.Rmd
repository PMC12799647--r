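---
title: "Virtual straight antegrade humeral nailing: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual straight antegrade humeral nailing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Straight antegrade humeral nailing (SAHN) requires an entry point at the
humeral head apex, on the extension of the medullary canal axis and at
least 5 mm medial of the supraspinatus footprint. Whether a surgeon can
reach that point without the nail striking the acromion depends on the
surgical approach and the arm position it permits: a transdeltoid split
works in neutral (0° glenohumeral extension), while an anterolateral portal
allows roughly 30° of extension, which carries the trajectory anterior to
the acromial shelf. `nailsim` reproduces this comparison in silico on
triangle surface meshes of a humerus and a scapula, and relates the
per-shoulder collision outcome to the Acromion Index (AI), the lateral
acromial overhang normalized by joint width.

## The simulation pipeline

For one shoulder the pipeline is:

1. **Medullary axis.** The labelled shaft region is sliced with planes
   perpendicular to its principal axis at 20 equally spaced stations over
   the middle 60% of its extent (the middle portion avoids the metaphyseal
   flare, where cross-sections stop being canal-like). Each cross-section
   contributes the area centroid of its inner (canal) contour — or of the
   whole section when the mesh is not hollow — and a total-least-squares
   line through the centroids is the canal axis.
2. **Entry point.** The axis, extended proximally, is intersected with the
   humerus surface restricted to the articular head patch; the most
   proximal intersection is the entry point. The minimal distance to the
   supraspinatus footprint patch is reported together with the ≥ 5 mm
   rule. The rule is advisory output: a violation is warned about, never
   silently "fixed" by relocating the entry point, because entry
   relocation is precisely the clinical compromise the analysis is meant
   to expose.
3. **Nail.** A plain closed cylinder, diameter 8 mm (the smallest
   clinically available size, chosen so that nail size does not confound
   collision risk), length 150 mm, 64 facets, collinear with the axis,
   proximal cap at the entry point. Threads, caps and locking holes are
   deliberately omitted: only the proximal cylindrical segment can ever
   reach the acromion, so they cannot change the outcome.
4. **Pose.** The centre of rotation is the least-squares sphere fitted to
   the articular head patch (algebraic Coope fit; a Gauss–Newton
   refinement is available but changes the centre by well under 0.1 mm on
   near-spherical heads). The humerus and nail rotate rigidly about the
   mediolateral axis through that centre; the scapula stays fixed.
   Positive extension moves the proximal trajectory anteriorly and the
   distal shaft posteriorly.
5. **Collision.** Contact is tested between the acromion patch of the
   scapula and the *insertion corridor*: the volume swept by the straight
   nail advanced along its own axis from first contact to seating,
   implemented as the nail cylinder extended one nail length proximal of
   the entry point. A seated nail lies entirely beneath the acromion, so
   testing only the final implant position would miss every on-the-way-in
   strike; for a straight nail advanced along its own axis the swept
   corridor is exactly a longer cylinder, which is why a single static
   test suffices. The contact predicate is exact triangle–triangle
   intersection (AABB broad phase, Möller narrow phase) plus a
   point-in-mesh parity test for full containment; the signed clearance is
   the minimal surface–surface distance, or minus the deepest vertex
   penetration under contact. `tolerance_mm = 0` means touching counts as
   collision.
6. **Morphometry.** The glenoid reference plane is the total-least-squares
   plane of the glenoid-face patch, its normal oriented laterally by the
   mesh frame. GA is the maximal signed distance of the acromion patch
   from that plane, GH the maximal signed distance of the whole humerus,
   and AI = GA/GH. Taking mesh-wide maxima is the deterministic 3D
   generalization of the planar index: it removes the ambiguity of
   choosing a single measurement slice, which the 2D protocol leaves to
   the observer. GH is measured in the neutral pose, since AI is a
   preoperative index.

All geometry is in millimetres in a right-handed patient frame with +x
lateral, +y anterior, +z superior; meshes carry this frame explicitly and
declare it in JSON sidecars on disk.

## The synthetic shoulder

No public mesh cohort accompanies the clinical question, so the package
generates parametric shoulders with analytic ground truth:

* humeral head: sphere, radius 24 mm, centred at the origin;
* shaft: hollow tube (outer 11 mm, canal 6 mm, length 120 mm) whose canal
  is collinear with the vertical axis through the head centre — the entry
  point is therefore exactly the head apex;
* neck–shaft angle (default 135°) orients the articular cap: its normal is
  tilted (180° − angle) medially from the canal axis;
* supraspinatus footprint: a vertex patch whose nearest vertex sits at an
  exact chord distance (default 7 mm) lateral of the apex — the sphere
  tessellation places a vertex ring exactly there;
* glenoid: a disc spanning the glenoid plane, 1.5 mm medial of the medial
  head surface, so GH = 2·24 + 1.5 = 49.5 mm at the defaults;
* acromion: a box shelf 8 mm above the head apex reaching
  `acromial_overhang_mm` laterally beyond the glenoid plane. The overhang
  *is* GA, so AI = overhang/GH: the AI↔overhang map is linear, strictly
  monotone, and numerically invertible.

Because every derived quantity (canal axis, apex, GA, GH, AI, and the
signed clearance of the 8-mm corridor at 0° and 30°) has a closed form,
each pipeline stage is tested against analytic truth, not against itself.

### Cohort calibration

A cohort draws AI from a truncated normal (0.668 ± 0.082 on [0.50, 0.93]),
head radii from a ±5 mm-truncated normal with SD 1.3 mm (a modest,
fixed-once choice giving adult-scale spread in GA and GH), ages from
48.3 ± 18.7 years on [18, 91], 73.7% male, 57.4% left sides.

Collision variation at fixed AI comes from two seeded geometric noises:
the anteroposterior position of the shelf's anterior edge (SD 3 mm) and
the acromial height (SD 1.5 mm). The anterior edge is placed at

y_ant = −4 + (3/1.7)·(β₀ + β₁·AI) + ε,  ε ~ N(0, 3) mm,

so that the shelf reaches the 8-mm corridor (whose anterior tangent in
neutral pose is at y = −4 mm) with probability ≈ logistic(β₀ + β₁·AI);
the 1.7 factor is the usual probit-to-logit scale. The frozen defaults
β₁ = 11.2 per AI unit and β₀ = −7.73 put the 50% point at AI = 0.69 and
correspond to an odds ratio near 3 per +0.10 AI. Setting β₁ = 0 severs the
AI–collision link entirely, which the tests exploit as a null model. These
constants are versioned in the package defaults; changing them is a
breaking change to the downstream checks.

Under this calibration a 68-shoulder cohort shows a neutral-pose collision
fraction around 45–55% and, because 30° of extension displaces the
corridor ≈ 17 mm anteriorly at shelf height — far beyond the noise SD —
an extension-pose fraction at or near zero. Extension strictly increases
every shoulder's clearance, so any 30° collision is nested inside a 0°
collision and the discordant pairs all fall on one side of the paired
table, as they must for a mechanism in which extension only ever moves the
trajectory away from the shelf.

### What the generator does *not* emulate

The shapes are idealized primitives, not statistical shape models: no
greater-tuberosity relief, no acromial curvature or os acromiale, no
cortical thickness variation, no humeral torsion (torsion rotates a
centreline-anchored trajectory about its own axis and so barely moves its
surface projection, but it is simply absent here). The 30°-condition
collision rate is effectively zero rather than the small positive rate a
real cohort shows, because the box shelf has no anterior process curving
over the displaced corridor. Passing tests therefore demonstrate that the
*pipeline* recovers known geometry and that the *statistics* recover known
parameters — not that the generator reproduces real anatomical variation.

## Statistics

The cohort analysis mirrors the standard paired-approach comparison:
collision rates with Wilson intervals (Clopper–Pearson available), the
paired McNemar test on the discordant counts — continuity-corrected by
default, χ² = (|b−c|−1)²/(b+c) clamped at zero — absolute risk reduction
and number needed to treat, Fisher-exact subgroup comparisons with Woolf
log-normal odds-ratio intervals (Haldane–Anscombe 0.5 correction on
structural zeros, flagged), logistic regression by IRLS (`glm`) reporting
the odds ratio per +0.10 AI as exp(0.1·β) with Wald intervals and
separation detection, empirical ROC with AUC equal to the normalized
Mann–Whitney statistic (ties half-counted), the Youden-optimal threshold
with ties broken toward the higher (more specific) midpoint threshold,
shoulder-level percentile bootstrap (B = 1000) for AUC, threshold,
sensitivity, specificity, PPV and NPV, Cohen's κ for binary observer
agreement, and two-way mixed single-measure ICCs from the ANOVA mean
squares (consistency ICC(3,1) by default, absolute agreement ICC(2,1)
switchable; F-based intervals, Satterthwaite for agreement).

Observer variability for the reliability workflow is emulated as seeded
Gaussian jitter of the digitized vertices; with the jitter at zero the
workflow is exactly reproducible and all ICCs equal 1.

Two conventions are worth making explicit. The two-sided Fisher p uses the
point-probability summation rule (the `fisher.test` convention); other
two-sided rules exist and can disagree in the second decimal. Proportion
intervals default to Wilson; published tables do not always say which
method they used, so these intervals are not treated as exactly
reproducible quantities. The a-priori McNemar sample-size utility
(Connor's unconditional approximation) is provided for planning only — its
answer is entirely driven by the assumed discordant probabilities, which
must be stated alongside any use.

## Numerical choices

* Degenerate fits (coplanar sphere input, collinear plane input) are
  rejected at a condition-number threshold of 1e8 on the normal equations.
* Slice contours are assembled by walking shared mesh edges; a slice with
  no crossing triangles is an error naming the slice, never silently
  skipped.
* The Youden scan evaluates midpoints between consecutive distinct scores;
  `score >= threshold` predicts positive.
* Collision tessellation: an inscribed 64-facet cylinder under-estimates
  the nail radius by 4·(1−cos(π/64)) ≈ 0.005 mm; outcomes are therefore
  resolution-stable except within a few hundredths of a millimetre of
  exact tangency (a measure-zero set under the cohort noise model).
* Bootstrap resamples that cannot support a statistic (single-class
  outcomes) are skipped and counted; more than 10% degenerate resamples
  triggers a warning in the output.
* Default mesh resolution targets 2.5 mm edges (≈ 9000 humerus triangles);
  the test suite and examples use cohorts of 2–68 shoulders, 20 axis
  slices, and B = 50–1000 bootstrap resamples depending on what the check
  needs.

## Known limitations

Real CT-derived meshes bring segmentation noise, partial scapulae and
ambiguous landmark patches that the synthetic generator cannot stand in
for; landmark patches must then be supplied by the user alongside the
meshes (JSON sidecars, indexed against PLY vertex order — STL files store
an unindexed triangle soup and cannot anchor vertex labels). The collision
endpoint is purely geometric: no deltoid or cuff soft tissue, no
retraction forces, no bone density. The 5-mm rule uses Euclidean
point-to-patch distance, not geodesic distance along the head surface.
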