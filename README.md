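# subsolidseg

Vessels running through a subsolid pulmonary nodule share the soft-tissue
attenuation of a solid core, so they inflate core, size and mass
measurements on CT — the very quantities that drive the management of
these high-malignancy-risk lesions. `subsolidseg` takes a CT volume and a
nodule segmentation and labels every nodule voxel as **vessel**, **solid
core**, or **ground-glass**, so that vessels can be excluded from nodule
characterization. It is aimed at researchers working on quantitative
nodule assessment in lung-cancer screening who need a reproducible,
fully scriptable implementation — including a synthetic phantom generator
so the entire pipeline can be trained, exercised and evaluated without
patient data.

## Method

1. **Standardization.** The scan is resampled to an isotropic 0.5 mm grid
   (trilinear) and its reconstruction-kernel appearance is harmonized by
   rescaling difference-of-Gaussians frequency bands (σ = 0.5, 1, 2, 4 mm)
   to match a reference kernel's band energies.
2. **Voxel classification.** Each nodule voxel gets a 17-feature
   descriptor: Hessian eigenvalues (|λ₁| ≥ |λ₂| ≥ |λ₃|, signs kept) and
   gradient magnitude at σ = 1, 2, 4 mm, raw HU, Gaussian-smoothed HU at
   the three scales, and the 26-neighbourhood standard deviation. A kNN
   classifier (k = 150, z-scored Euclidean space, classes balanced to the
   minority class) yields posteriors 𝒫ᵥ, 𝒫_c, 𝒫_g, which are interpolated
   back to the source grid. Each voxel is labelled by the weighted argmax

       y(x) = argmax_m  w_m · 𝒫_m(x),

   where the operating point w = (w_v, w_c, w_g), Σw = 1, is optimized on
   a 0.01 simplex lattice by leave-one-patient-out cross-validation;
   solitary voxels are replaced by their neighbourhood majority.
3. **Vascular continuity.** Each 6-connected component of the initial
   vessel set is matched to the vessel entering the nodule (attached,
   largest, and connected to the vascular tree). With local diameters
   d_in(x) and the entering-vessel calibre d_out, the vessel likelihood is
   attenuated by

       w_vc(x) = 1                         if d_in ≤ d_out
               = 0                         if d_in ≥ a·d_out      (a = 3)
               = 1 − (d_in/d_out − 1)/(a−1) otherwise,

   and the argmax is re-run with 𝓛ᵥ(x) = w_v · w_vc(x) · 𝒫ᵥ(x) — an
   implausibly thick "vessel" loses to core or ground-glass, and vessel
   components with no entering vessel are removed. Detection and
   voxel-overlap evaluation (26-connected components of ≥ 2 voxels;
   Cohen's κ with 95% CI; sensitivity/precision/Dice with the
   presence-disagreement zero convention) mirror the protocol used to
   validate the method.

## Worked example

Train on five synthetic phantoms and segment a held-out part-solid nodule
with crossing vessels:

```r
library(subsolidseg)

coh <- generate_cohort(10, seed = 42)
cases <- lapply(1:5, function(i) {
  b <- coh$bundles[[i]]
  list(volume = b$volume,
       annotations = sparse_annotations(b$truth, per_class = 140,
                                        seed = 100 + i),
       nodule_id = coh$manifest$id[i])
})
model <- train_model(cases, k = 150, seed = 7)
model

b <- coh$bundles[[8]]   # held out: part-solid nodule with crossing vessels
res <- segment_nodule(model, b$volume, b$nodule,
                      vessel_mask = b$outer_vessels)
res$labels
detect_classes(res$labels, nodule_id = coh$manifest$id[8])
voxel_scores(res$labels, b$truth)[, c("class", "sensitivity",
                                      "precision", "dsc")]
```

```
<ssn_model> kNN k=150, 2376 training samples, weights (v=0.17, c=0.32, g=0.51)
<label_volume> 56x56x40 voxels, spacing 0.7x0.7x1 mm, origin 0, 0, 0 mm
  labels: background=122360 vessel=167 core=334 ggo=2579
   nodule_id vessel_present core_present ggo_present vessel_components
1 phantom008           TRUE         TRUE        TRUE                 3
  core_components ggo_components
1               1              1
   class sensitivity precision       dsc
1 vessel   0.7657143 0.8023952 0.7836257
2   core   0.9910714 0.6646707 0.7956989
3    ggo   0.9571056 0.9949593 0.9756654
```

The model prints its optimized operating point. The detection record says
which classes form a spatially coherent detection (a 26-connected
component of at least two voxels) — here the vessels and the solid core
are both detected. The score table compares the produced segmentation
with the phantom's geometric ground truth: each row gives the fraction of
true class voxels recovered (sensitivity), the fraction of predicted
voxels that are correct (precision), and their harmonic summary (Dice).
Ground-glass is recovered almost perfectly; vessel and core Dice sit
around 0.8, bounded by the one-voxel partial-volume shell where tube,
core and ground-glass appearances genuinely mix (see the vignette's
limitations section).

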