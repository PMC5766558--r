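---
title: "Separating vessels and solid cores in subsolid pulmonary nodules"
author: "subsolidseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating vessels and solid cores in subsolid pulmonary nodules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Subsolid pulmonary nodules — ground-glass lesions with or without a solid
component — carry a comparatively high malignancy probability, and their
management hinges on size, mass and the presence of a solid core. Pulmonary
vessels running through a nodule share the soft-tissue attenuation of a
solid core, so naive HU thresholding inflates core and mass measurements
and can flip a nodule's type from non-solid to part-solid. `subsolidseg`
labels every voxel of a given nodule segmentation as **vessel**, **solid
core**, or **ground-glass**, using local image features plus an anatomical
constraint on vessels: a vessel inside a nodule must continue, at a
plausible calibre, the vessel that enters the nodule.

The pipeline has three stages.

### 1. Image standardization

Scans are resampled to an isotropic 0.5 mm grid by trilinear interpolation
(`resample_isotropic()`; output shape `round(dim * spacing / target)`,
origin preserved, edge-clamped sampling) and their reconstruction-kernel
appearance is harmonized by a band-energy normalization
(`kernel_normalize()`). The volume is decomposed into difference-of-
Gaussians bands at scales 0.5, 1, 2, 4 mm plus a low-pass residual — the
decomposition is exact, so unit gains reproduce the input — and each band
is rescaled by a gain estimated from reference reconstructions
(`estimate_band_profile()`). Because the bands overlap spectrally, the
gains are solved by fixed-point iteration on the energy-matching objective
(rescale by `sqrt(E_ref / E_current)`, re-normalize, repeat), which
recovers gains applied with the same band definition. The band scales are
chosen to
span the feature scales used downstream; band energies are computed over a
body mask when one is supplied, because air outside the patient otherwise
dominates the energy statistics. The estimated profile is stored inside the
trained model so that training and test scans are always standardized
identically.

### 2. Voxel classification

Each voxel in the nodule carries a 17-dimensional descriptor
(`assemble_features()`): at each scale $\sigma \in \{1, 2, 4\}$ mm the three
Hessian eigenvalues sorted by decreasing magnitude
($|\lambda_1| \ge |\lambda_2| \ge |\lambda_3|$, signs retained — a bright
tube shows $\lambda_1, \lambda_2 \ll 0$ with $|\lambda_3|$ small, a bright
blob three similar negative values) and the gradient magnitude; the raw HU
value; Gaussian-smoothed HU at the three scales; and the standard deviation
over the 26-neighbourhood including the centre (27 values; "surrounding" is
ambiguous, and including the centre is stable on one-voxel structures).
Gaussian derivative kernels are sampled at physical scale, truncated at
$4\sigma$, and corrected to exact discrete moment conditions so that ramps
and parabolas differentiate exactly.

A k-nearest-neighbour classifier (default $k = 150$) returns, for each
voxel, the class fractions among its $k$ nearest training samples
(`train_classifier()`, `predict_posteriors()`). Features are z-scored with
training statistics before the Euclidean distance is evaluated — HU and
eigenvalue magnitudes differ by orders of magnitude, and an unscaled
distance would be dominated by a single block. Training samples are
balanced by downsampling every class to the minority class size, with
water-filling quotas so each nodule contributes approximately equally
(`balance_classes()`).

The posteriors $\mathcal{P}_m$ are scaled by class weights
$w = (w_v, w_c, w_g)$, the classifier's operating point, and each voxel
receives the label

$$ y(x) = \arg\max_m \; \mathcal{L}_m(x), \qquad
   \mathcal{L}_m(x) = w_m \, \mathcal{P}_m(x). $$

The weights are optimized by exhaustive search on the simplex lattice with
step 0.01, minimizing hard-label disagreement of out-of-fold posteriors
from leave-one-patient-out cross-validation (`optimize_weights()`,
`cv_posteriors()`); ties prefer the triple nearest uniform, then
lexicographic order. Argmax ties take ground-glass over vessel over core:
ground-glass is the nodule's background class, and conservative core calls
match the method's specificity-leaning behaviour. Posteriors are computed
on the standardized grid and interpolated trilinearly back to the source
grid, then renormalized; the rare source voxel with no interpolation
support receives uniform posteriors. Finally, solitary voxels — labelled
voxels with no same-label neighbour among their masked 26-neighbours — are
replaced by the neighbourhood majority in a single pass over a snapshot
(no cascade), with majority ties resolved by the larger class likelihood
at the voxel.

### 3. Vascular continuity regularization

The initial vessel set is split into 6-connected components. For each
component the *entering vessel* is sought among the outside-vessel
components (any binary vessel segmentation can be plugged in;
`outer_vessel_mask()` provides a Hessian-tubularity + HU-threshold default)
that are (1) attached to the component, (2) at least as large as any other
attached outside vessel, and (3) part of the vascular tree. Each inside
voxel gets a local diameter $d^i_{in}(x)$ and the entering vessel a
calibre $d^i_{out}$, and the vessel likelihood is attenuated by

$$ w_{vc}(x) = \begin{cases}
  1 & d_{in} \le d_{out} \\
  0 & d_{in} \ge a \, d_{out} \\
  1 - \frac{1}{a - 1}\left(\frac{d_{in}}{d_{out}} - 1\right) &
  \text{otherwise,}
\end{cases} $$

with $a = 3$: an inside vessel three times the calibre of its entering
vessel is not a vessel. The final labels re-run the argmax with
$\mathcal{L}_v(x) = w_v \, w_{vc}(x) \, \mathcal{P}_v(x)$ (core and
ground-glass likelihoods unchanged), so the final vessel set can only
shrink, followed by the same solitary-voxel pass. Components with no
entering vessel violate the premise that an inside vessel continues an
outside one; they receive $w_{vc} = 0$ (configurable).

Design choices in this stage that the problem statement leaves open:

* **Diameter estimation** is local thickness: twice the radius of the
  largest inscribed sphere (from the Euclidean distance transform, with a
  half-voxel correction for the digital bias) covering each voxel, computed
  over the union of the inside vessel set and the outside vessel mask so a
  tube keeps its calibre across the nodule boundary. $d_{out}$ is the
  *maximum* thickness of the entering vessel within 2 mm of the nodule
  surface: the voxel-wise thickness field is artifactually small on a
  tube's one-voxel surface shell, and averaging it would overstate
  $d_{in}/d_{out}$ for thin vessels.
* **Attachment** uses a physical tolerance of 2 mm rather than strict
  voxel adjacency: partial-volume voxels at the nodule boundary are the
  hardest to classify, and a missing boundary voxel must not orphan a real
  vessel from its continuation.
* **Vascular tree membership** is approximated by component size: outside
  components with at least 10% of the largest component's voxels count as
  tree. In a whole-lung segmentation the tree is one connected component,
  but in a cropped sub-volume the entry and exit sides of a crossing vessel
  are separate components that both reconnect to the tree outside the
  crop; a largest-only rule would spuriously orphan the smaller side,
  while the size fraction still rejects segmentation-noise specks.

## The synthetic phantom generator

`generate_phantom()` renders the geometry the method is built for: lung
parenchyma at −900 HU, an ellipsoidal ground-glass nodule at −600 HU, an
optional spherical solid core and tubular vessels at +50 HU, swept along
polyline paths with linearly tapering diameter. The scene is blurred with a
0.6 mm Gaussian (partial volume) and perturbed with additive Gaussian noise
(20 HU), on an anisotropic 0.7 × 0.7 × 1 mm grid typical of low-dose
screening reconstructions. Ground-truth labels are assigned on the
*pre-blur* geometry with precedence core > vessel > ground-glass, the way a
human annotation outlines structures rather than their blur.

`generate_cohort()` samples nodule radii (5–8 mm in-plane), core radii
(2.5–4 mm — solid components below roughly 5 mm across are beneath the
clinically actionable size), vessel diameters (2–3.5 mm) and vessel counts
(1–2), stratified round-robin over the four strata used for 3D evaluation:
non-solid and part-solid, each with and without crossing vessels. A second
vessel branches off the first *outside* the nodule so each phantom's
vessels form one connected tree, as real pulmonary vessels do.
`sparse_annotations()` emulates expert training clicks: per class a capped
number of voxels, spread over the class's connected components by the same
water-filling quotas, with vessel and core clicks biased to at or above the
component's median interior depth — an annotator clicks towards the centre
of a structure and leaves its ambiguous partial-volume shell alone —
while ground-glass is annotated freely across the nodule.

What the phantoms deliberately do not emulate: airway trees, bubble-like
lucencies ("complex" nodules, which the three-class model excludes by
design), textured ground-glass, scanner-specific noise correlation, and
contact between the nodule and the chest wall. Passing the phantom study
therefore shows that the pipeline recovers the geometry it models under
realistic resolution, blur and noise — not that it handles every appearance
encountered in screening data.

## Evaluation protocol

`detect_classes()` counts, per class, 26-connected components of at least
two voxels; one such component makes the class "detected".
`pairwise_agreement()` compares detection records with accuracy,
sensitivity, specificity, precision and Cohen's kappa, with a 95% CI from
the asymptotic standard error
$\sqrt{p_o (1 - p_o) / (n (1 - p_e)^2)}$ (the CI method is a reporting
choice, flagged in the output). `voxel_scores()` computes per-nodule,
per-class sensitivity, precision and Dice, either in 3D or on the axial
slice with the largest nodule cross-section (`largest_area_slice()`, ties
to the smallest index). When exactly one of the two raters contains a
class, all three scores are zero for that nodule and class; when neither
does, the row is excluded from aggregates rather than scored.
`consensus_intersection()` builds a consensus standard as the voxel-wise
intersection of two raters, unassigned nodule voxels falling back to
ground-glass. `stratified_summary()` reports means and sample standard
deviations (n − 1) twice: over all scoreable nodules and over the stratum
with agreement on class presence.

## Study sizes and numerical conventions

The packaged phantom study (tests and the acceptance script) trains on 5
phantoms with 140 annotation clicks per class per phantom (about 2,000
clicks in total) and evaluates on 5 held-out phantoms with full 3D Dice;
the default $k = 150$ is kept, clipped with a warning only when a training
set is smaller than $k$. Weight optimization uses leave-one-phantom-out
folds. These sizes were chosen as the smallest cohort that exercises all
four strata. `generate_cohort()` also offers a vessel-rich `"training"`
composition mirroring a clinical training set for this task (nearly every
nodule contains vessels); the packaged study keeps the strata-balanced
composition on both sides so that vessel-free nodules — where false
vessel detections would matter most — are part of the training folds too.

Other fixed conventions: voxel indices are 0-based in physical mapping
(`origin + index * spacing`), column-major with x fastest; labels are
0 background / 1 vessel / 2 core / 3 ground-glass everywhere; connected
components use 26-connectivity for detection and outside vessels and
6-connectivity for splitting the inside vessel set; Gaussian kernels
truncate at $4\sigma$; band decomposition reconstructs to < 1e−4 HU;
posterior sums are enforced to 1e−6; the continuity weight is continuous
at its breakpoints to 1e−12.

## Known limitations

* **Thin vessels.** For tubes only 3–4 voxels across, roughly half of the
  geometric vessel volume lies in the partial-volume shell whose
  appearance is shared with the adjacent ground-glass ring; the
  balanced-sample operating point cannot fully separate the two, so vessel
  Dice trails the core and ground-glass classes, with errors concentrated
  in the one-voxel boundary layer. The continuity weight only removes
  implausibly *thick* vessel calls ($d_{in} \ge a\,d_{out}$), so a
  one-voxel misclassification sheath around a real vessel survives it by
  design.
* **Operating-point variability.** At five-phantom scale the
  cross-validated weight search inherits fold-level heterogeneity: each
  phantom carries vessels of a single calibre, so out-of-fold vessel
  posteriors shift from fold to fold and the selected weight triple varies
  noticeably across cohort draws. The much larger clinical training sets
  the procedure was designed for average this out.
* The default outside-vessel filter is a deliberately simple
  tubularity/HU rule adequate for phantoms; on clinical data a dedicated
  lung-vessel segmentation should be supplied via `vessel_mask`.
* Nodule segmentation itself is an input, not a product, of the package;
  errors in the supplied mask propagate.
* "Complex" bubble-containing nodules are outside the three-class model.
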