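---
title: "Methods: anomaly-based pathological risk scoring and multimodal event prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: anomaly-based pathological risk scoring and multimodal event prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

After carotid endarterectomy (CEA), a minority of patients go on to suffer a
cardiovascular event — stroke (including asymptomatic DWI-hyperintense
lesions) or myocardial infarction — within a year, and no single clinical
factor predicts who.  The resected plaque itself is routinely stained (H&E)
and scanned as a whole-slide image (WSI), and unstable-plaque histology
(hemorrhage, thrombus, lymphocytic infiltration, hemosiderin deposition) is a
plausible risk substrate.  `plaqrisk` implements a two-step predictor:

1. **Pathological risk score.** A reconstruction-based anomaly detector is
   trained on patches from *event-free* patients only.  At inference every
   tissue patch $x$ receives an anomaly score $A(x)$, and a patient's score
   is the mean over their pooled patch group $X$:
   $$A_p = \frac{\sum_{x \in X} A(x)}{|X|}.$$
2. **Multimodal classification.** $A_p$ is concatenated with 18 clinical
   variables into a 19-feature gradient-boosted binary classifier, evaluated
   by a repeated stratified split protocol.

The rest of this vignette records the modelling choices, defaults and
numerical details, and what the synthetic test bed does and does not show.

## Preprocessing and patching

Slides are downsampled by an integer factor (default 32), converted to HSV,
and binarized on the **saturation** channel: stained tissue is strongly
saturated while the bright background and glass are not, so saturation is
the channel that makes Otsu's threshold meaningful.  A median filter
(default 7 px window at the downsampled level) suppresses speckle before
thresholding, and a morphological closing (5 px disc) bridges small gaps.
The filter and kernel sizes and the component-area minima (tissue 512 px,
holes 256 px at downsample 32) are not canonical values — they are exposed
in `segmentation_params()` and these defaults were picked to behave well on
slide-scale inputs.

Otsu's threshold is computed on the 256-bin histogram by maximizing
between-class variance; ties take the smallest index, and the degenerate
single-populated-bin histogram returns that bin.  Connected components of
the closed binary image are filled; filled components above the tissue
minimum become tissue regions, and enclosed background regions above the
hole minimum become holes (mask = tissue minus holes, i.e. small holes are
filled).  Contours are traced per component; the representation supports
one level of hole nesting, which matches what plaque sections actually
exhibit (lumen and tears inside a section).

Patches are 256 × 256 px windows on the level-0 grid at stride 256
(non-overlapping), emitted when the area-weighted tissue fraction on the
downsampled mask reaches `min_tissue_fraction` (default 0.5 — an exposed
choice, since no canonical inclusion rule exists).  Edge windows are
discarded rather than padded: reconstruction models should only see
full-content patches.  Computing coverage on the downsampled mask (each
cell standing for `downsample²` pixels, partial cells weighted by overlap)
avoids materializing a gigapixel mask and is exact for the aligned grids
used here.

## The autoencoder

The encoder applies three 3 × 3 convolutions (stride 1, zero padding),
each followed by ReLU and 2 × 2 max pooling; the resulting feature map is
flattened and projected to the latent vector by a dense layer (no
activation on the latent).  The decoder mirrors it: a dense expansion with
ReLU back to the feature-map shape, then three stride-2 transposed
convolutions (2 × 2 kernels), the first two with ReLU and the last with a
sigmoid, so reconstructions live in $[0,1]$ and inputs are scaled to
$[0,1]$ accordingly.  Channel widths double per stage (32 → 64 → 128 at
full scale, ending in a 128-channel map before the flatten); the
3 × 3/2 × 2 kernel sizes are conventional choices recorded in the
`autoencoder_spec()` object.  Weights are He-normal initialized; biases start at zero.

The anomaly score is the per-entry mean squared reconstruction error
$$A(x) = \tfrac{1}{n}\,\lvert x - D(E(x))\rvert^2,$$
with $n$ counting every pixel–channel entry, so $A(x) \in [0,1]$ for
in-range inputs and $A(x) = 0$ iff the reconstruction is exact.

Full-scale training defaults: 300 epochs, batch 64, learning rate 0.001,
Adam.  Training is restricted to normal material; a bank containing an
anomalous-labelled patch is rejected outright (leakage guard).

**Desk-scale profile.** The architecture is size-parametric, and the test
suite and acceptance script run a 64 px / channels 8-16-32 / 128-dim-latent
profile trained for 20 epochs on 500 synthetic normal patches — a
configuration chosen so a full training run completes in about a minute on
one CPU while still separating the synthetic anomaly textures essentially
perfectly.  The network engine itself (convolution, pooling, dense and
transposed-convolution layers with exact analytic gradients, Adam and
RMSprop) is implemented in C++ via RcppArmadillo and is verified against
numerical differentiation in development.

## The f-AnoGAN variant

The optional second scoring model follows the izif scheme: a WGAN-GP
generator/critic pair is trained on normal patches (RMSprop, learning rate
5e-5, latent dimension 1024 at full scale), then an encoder is trained
against the frozen generator to map images into latent space.  The score is
$$A(x) = \tfrac{1}{n}\lvert x - G(E(x))\rvert^2 +
        \tfrac{1}{n_d}\lvert f(x) - f(G(E(x)))\rvert^2,$$
where $f(\cdot)$ is the critic's penultimate-layer activation ($n_d$ its
dimension).  The two terms carry implicit equal weighting, exactly as the
formula is stated; no weighting hyperparameter is introduced at scoring
time.  During encoder training the feature-residual weight is exposed
(`feature_weight`, default 1) because the izif loss composition admits one.

Two numerical choices deserve note:

* **Gradient penalty.** The penalty $\lambda(\lVert\nabla_x D(\hat x)\rVert - 1)^2$
  needs the derivative of an input-gradient norm with respect to the critic
  parameters (double backpropagation).  It is computed exactly to
  first order via a symmetric finite-difference Hessian–vector product: two
  additional backward passes at $\hat x \pm \epsilon v$ with $v$ the
  normalized input gradient and $\epsilon = 10^{-4}$.
* **Checkpoint selection.** Generator checkpoints are compared by a Fréchet
  distance between Gaussian summaries of embedded features of real versus
  generated patches, and the argmin checkpoint is kept.  The embedding is a
  small *fixed, seeded random-projection CNN* behind an interface: what the
  selection logic requires is a consistent feature space, and the argmin
  rule is what is tested.  Encoder training stops early once its loss has
  not improved for 30 consecutive epochs.

## Risk aggregation and heat maps

$A_p$ is the mean of the patient's patch scores after pooling patches from
*all* of the patient's slides into one group — patients commonly contribute
several WSIs, and the score definition sums over the patient's patch group,
so pooling (rather than averaging per-slide means) is the faithful reading;
it also weights every patch equally regardless of slide size.  $A_p$ is
permutation-invariant and bounded by the min and max patch score.

Heat maps paint each patch footprint at the mask resolution with the
min–max normalized score (brighter = more anomalous); non-tissue pixels are
black.  Normalization bounds default to the scored set but can be fixed
per cohort so that brightness is comparable across patients; the bounds are
always recorded in a JSON sidecar next to the PNG.

## The classifier and evaluation protocol

The 18 clinical variables (demographics, stenosis and imaging grades,
comorbidities, medications) plus $A_p$ form the 19-feature table.  Missing
cells are imputed with the column mean over observed values — for binary
indicators this is the observed prevalence, kept deliberately rather than
rounded, since tree learners handle fractional split points naturally.

Evaluation repeats, 100 times from a base seed: (i) a stratified 7:3
patient-level split (train size = round-half-up of 0.7 N, per-class sizes
likewise, adjusted in the larger class; every patient on exactly one side);
(ii) a 5-fold stratified cross-validated grid search on the training set
minimizing validation log loss, with the argmin configuration refit on the
full training set (the default grid — depth {2,3} × learning rate
{0.1,0.3}, 60 rounds — is deliberately small, sized for ~50 training
patients); (iii) a Youden-index threshold $J = \text{sens} + \text{spec} - 1$
maximized over midpoints of consecutive distinct *training-set* predictions
(ties toward the higher, more specific threshold); (iv) evaluation on the
held-out patients: rank-concordance ROC-AUC plus thresholded accuracy,
sensitivity, specificity and F1.  Computing the threshold on training
predictions avoids test leakage; which set determined it is otherwise a
free choice and is recorded here.  Aggregates are means with
normal-approximation 95% CIs, $\bar m \pm 1.96\, s/\sqrt{n}$.  Stratification
(splits and folds) is not optional at these sizes: with 21 positives an
unstratified fold can easily lose a class.  A split that fails
class-presence preconditions is redrawn under a shifted seed and the
substitution logged in the report.

The anomaly model is trained once per experiment, outside the repetition
loop, on patients disjoint from the classification cohort — the repetition
loop re-splits only the classification set.

The gradient-boosting backend is a two-function interface (fit/predict);
the shipped backend is xgboost.  No second boosting family is bundled, but
the pipeline never touches the backend beyond the interface.

## The synthetic test bed

The generator renders H&E-like slides: pink tissue (RGB ≈ 230,160,190)
with Gaussian pixel noise and sparse dark nuclei speckle on a near-white
background (245,245,245), with optional background-colored holes and three
parametric anomaly textures — dark-red clot-like fields, dense small
dark-purple dots, and brown granule blends — with exact ground-truth masks
(every anomalous pixel is a tissue pixel).  Patch banks repeat the same
textures in isolation; a cohort couples per-patient banks (event patients
receive 30% anomalous patches by default) with a clinical table drawn from
class-conditional distributions matching a real CEA cohort's summary
statistics (so features such as anticoagulant use genuinely separate the
classes), plus configurable extra effect shifts and completely-at-random
missingness.  Images are quantized to 8-bit levels, and every generator is
bit-reproducible from its seed.  Synthetic slides are single-level images;
an integer downsample parameter stands in for pyramid levels, which are an
I/O concern rather than part of the method.

The anomaly contrasts are free parameters, not calibrated to any cohort:
no quantitative visual contrast for real pathological findings is
available, so the textures are set to be clearly but not trivially distinct
from normal tissue.  Consequently the synthetic benchmark demonstrates that
the machinery is correct — scores rank anomalous material above normal,
patient aggregation and the protocol behave as specified — and says nothing
about clinical performance on real slides, which exhibit stain variation,
scanner artifacts, pen marks and far subtler pathology, none of which are
simulated.  The headline metrics of the original clinical study are
likewise not reproducible here because its cohort is private; the
acceptance script reports the synthetic-study quantities instead.

Problem sizes used by the test suite and acceptance script (chosen as the
package's standard desk-scale experiment): 500 training / 200 evaluation
patches at 64 px; a 20 vs 20 patient cohort for the rank test; a 50 vs 21
patient cohort with 20 patches per patient for the 100-repetition
protocol.

## Known limitations

* The NN engine is CPU-only, double precision, single-threaded per call;
  full-scale (256 px) training is possible but slow — the package's value
  at that scale is the pipeline structure, not raw speed.
* Hole nesting deeper than one level (islands inside holes) is not
  represented in the contour hierarchy.
* The f-AnoGAN path at desk scale uses short adversarial schedules; it
  demonstrates ordering (anomalous above normal), not GAN sample quality.
* Mean imputation ignores feature correlations; it is kept because it is
  the standard simple choice for this table size and matches the
  classifier's needs.
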