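---
title: "Methods: multi-task echo video analysis for CAD grading"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-task echo video analysis for CAD grading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its science: the model
and its assumptions, what the synthetic generator does and does not
emulate, the numerical choices, and the open design decisions we
resolved. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The clinical quantities

One subject contributes three apical views (A4C, A3C, A2C); each view
is one cardiac cycle resampled to a 20 x 256 x 256 grayscale block.
Frame 0 is end-diastole (ED), frame 10 end-systole (ES): ten frames
sample the half-open phase interval [ED, ES) uniformly and ten sample
[ES, next ED), so ES is represented exactly once. All downstream
conventions (strain/EF curve anchoring, the systolic window of the
work-efficiency computation) follow this grid.

The deterministic clinical layer implements:

* **Modified Gensini score.** Severity points per stenosis bin
  (right-closed bins: <=25% -> 1, <=50% -> 2, <=75% -> 4, <=90% -> 8,
  <=99% -> 16, 100% -> 32) times a location multiplier (left main x5;
  proximal LAD and proximal LCx x2.5; mid LAD x1.5; second diagonal and
  posterolateral branch x0.5; all other segments x1), summed over
  lesions. The published description names the classic scoring system
  without printing its tables, so the tables are explicit,
  config-overridable defaults (`gensini_config()`), not claims about
  any particular laboratory's implementation. The named "collateral
  adjustment" is likewise unspecified there; we implement it as bin
  demotion — a total or near-total (>= 99%) occlusion with collateral
  flow is scored in the 90% bin — and it can be disabled.
* **CAD labels.** Significant CAD: any left-main lesion >= 50% or any
  other lesion >= 70%. Severe CAD: Gensini >= 15 points. The four
  composite assignments are significant, severe, exclusive-or, and
  conjunction of the two.
* **Volumes and curves.** Biplane Simpson volume
  V = (pi/4)(L/n) sum a_i b_i with n = 20 disks by default (standard
  biplane practice; the source is silent on the count). EF curve
  EF_t = 100 (V_0 - V_t)/V_0 and strain curve
  eps_t = 100 (L_t - L_0)/L_0 are anchored at frame 0, so
  EF_0 = eps_0 = 0 holds by construction even for dyssynchronous
  motion; LVEF = max EF_t, GLS = min eps_t.
* **Work efficiency.** Over systolic steps (frames 0-10), shortening
  under pressure is constructive work and lengthening is wasted work;
  GWE = 100 CW / (CW + WW). A single global strain curve that shortens
  monotonically gives GWE = 100 regardless of pressure, so subject-level
  GWE aggregates segmental pressure–strain loops
  (`gwe_segments()`): regional delay or systolic stretch produces
  wasted work and GWE < 100. GWE is invariant to uniform pressure
  scaling; CW + WW = 0 (no motion) is reported as an error by
  `gwe_from_loop()` and as `NA` for a motionless phantom.

## 2. The synthetic beating-heart phantom

No clinical videos ship with the package; the generator emulates the
statistical structure the network must learn from.

The left ventricle is an elliptical cavity (semi-axes a0 in 70–90 px,
b0 in 42–56 px at ED, in the 256-px frame) inside a myocardial annulus
(thickness h0 in 12–18 px). The cycle phase is
phi(t) = sin^2(pi t / 20), so phi(0) = 0 (ED), phi(10) = 1 (ES),
monotone on each half-cycle and periodic. The local cavity radius
contracts by a fraction alpha · phi · c(theta), where alpha in
0.22–0.32 is the ejection amplitude and c(theta) is the smoothly
interpolated contractility of the three coronary territories (LAD,
LCx, RCA; von-Mises-like angular membership). Wall thickening scales
with alpha so that alpha = 0 is a truly motionless heart. These ranges
were chosen once so that healthy phantoms land near clinically typical
resting values (LVEF around 60%, GLS around -20%).

Disease enters in three coupled ways, all derived from the lesion set.
A territory's contractility falls toward a floor of 0.3 with its share
of the Gensini burden, saturating as 0.85 g / (g + 8); each lesion's
contribution is weighted by a flow-limitation factor (logistic in
stenosis, centred near the 70% hemodynamic-significance threshold),
because the Gensini severity bins alone place a moderate 60% narrowing
and a flow-limiting 70% stenosis in the same bin and would give them
identical wall-motion effects — contradicting the reported group
differences in GLS and LVEF between significant and non-significant
disease, which these choices are calibrated to mirror. Hypokinetic
territory activates late (delay up to 4 frames at the floor) and
bulges passively outward while healthy wall squeezes (systolic
stretch, 35% of the contraction amplitude at zero contractility). The
delay and stretch put lengthening steps under systolic pressure, which
is what makes GWE fall with disease; all three function metrics
(|GLS|, LVEF, GWE) are monotone non-increasing in the disease level. Ground-truth curves and
scalars are computed analytically from the generating geometry on a
fine angular grid (1,440 angles; disk summation over 80 slices for
volumes) — never from rendered pixels — so label noise is zero.

Rendering: each view is an in-plane rotation (A4C 0°, A3C +40°,
A2C -20°, each jittered ±5°) with view-specific territory visibility
weighting of the myocardial intensity, multiplicative Rayleigh speckle
(unit mean, spatially correlated by half-resolution generation and
bilinear upscale), and a transducer sector (apex top-centre,
half-angle 38°) outside which pixels are zero. Masks are rasterised
from the same geometry (0 background, 1 myocardium, 2 cavity) and are
pixel-exact by construction.

What the phantom does **not** emulate: real speckle decorrelation and
reverberation, valve and atrial anatomy, through-plane motion,
foreshortening, probe-dependent gain, and the label noise of human
annotation or speckle-tracking software. Passing tests therefore show
that the pipeline learns the geometry–function–score couplings it was
given, not that it reaches any particular clinical accuracy.

## 3. The network

`iecad_model()` builds a 3D encoder–decoder. The encoder is a stem
(3 x 7 x 7 convolution, spatial stride 2, then 2 x 2 average pooling)
followed by four residual bottleneck stages (3/4/6/3 blocks; spatial
strides 1, 2, 2, 1 with the last stage dilated), giving spatial output
stride 16 while the 20-frame axis is never strided. An atrous spatial
pyramid (rates 1, 6, 12, 18 plus an image-pooling branch) projects to
256 deep-semantic channels; a further convolution block produces the
backbone features. A 48-channel low-level tap after stage 1 feeds the
view head (after 4x average-pool downsampling) and the segmentation
decoder (at its native 1/4 grid). Four low-rank expert blocks — a
3 x 3 x 3 convolution factorised through a rank-4 channel bottleneck,
then a 1 x 1 x 1 low-rank stage, each with batch normalisation and
rectification — extract sparse task features for GLS, LVEF, GWE and
the Gensini score.

Decoders: view = global pool + 48 -> 3 linear + softmax; segmentation
= upsampled backbone concatenated with the low-level tap
(256 + 48 = 304 channels) -> 3 x 3 x 3 convolution -> 1 x 1 x 1 to
3 classes -> upsample to 256 and softmax; GLS/LVEF = spatial pooling
to a 20 x 256 sequence, bidirectional LSTM (256 per direction),
per-step 512 -> 1 linear; GWE = global pool + 256 -> 1 linear. The
score and CAD heads consume the 1,072-channel fusion: backbone plus
the Gensini expert features (added element-wise into the backbone
slot), the three metric expert features, and the downsampled low-level
features (4 x 256 + 48). The prose description of the fusion lists six
feature groups (which would give 1,328 channels); the printed layer
table fixes 1,072, and the table wins — the element-wise-add
composition is our resolution of that contradiction. Each head then
applies a 3 x 3 x 3 convolution to width 512, 8-head temporal
self-attention over the 20-step pooled sequence (with a residual
connection; no layer normalisation is printed, so none is used), a
temporal mean, and 512 -> 256 -> 1 (GELU, score) or 512 -> 256 -> 2
with softmax (ReLU, CAD).

Numerical choices: batch normalisation with running statistics
(momentum 0.1, eps 1e-5), He initialisation, forget-gate bias 1 in the
LSTMs, nearest-neighbour upsampling, average pooling in the stem
(keeps every op's adjoint exact and trivially testable). Output layers
carry fixed affine maps: regression heads predict standardised values
mapped to the target's physiologic range (GLS x10 - 8, LVEF x20 + 15,
GWE x5 + 95, Gensini x25 + 20) and classification logits a fixed gain
of 10. With a rate-bounded optimiser such as Adam, the parameter motion
available in a scheduled run is proportional to the learning rate times
the update count; the affine maps make the required motion O(1) so the
heads can converge within short schedules without touching the loss
definitions or per-task weights. The autograd
core computes exact double-precision gradients; every operator is
validated against central finite differences, and the convolution
against a brute-force direct convolution.

`width_scale` shrinks every channel width proportionally and
`input_size` the spatial grid; the full-width configuration reproduces
the published layer table exactly (verified shape-by-shape in the
acceptance suite).

## 4. Training schedule

Three phases: (1) view + segmentation (cross-entropy; segmentation
additionally soft Dice on softmax probabilities), (2) GLS/LVEF/GWE
(mean squared error), (3) Gensini (MSE) + CAD (cross-entropy) with the
encoder and all phase-1/2 heads frozen. Freezing is structural: the
frozen subgraph is evaluated once per clip in evaluation mode (running
statistics, no gradient graph) and its features cached, so frozen
parameters are bit-identical afterwards by construction — the test
suite checks identity, not closeness. Because caching removes the
input-augmentation channel, phase 3 offers feature-space augmentation
instead: Gaussian noise on the cached features
(`train_config(feature_noise = )`, relative to each tensor's spread),
which curbs the score/CAD heads' tendency to memorise small cohorts.
Each phase's final epoch trains against frozen (freshly refreshed)
normalisation statistics, so the heads converge on exactly the feature
distribution evaluation mode produces; with batch statistics
throughout, evaluation-mode accuracy lagged training accuracy
noticeably at small batch sizes. Whether phase 2 should also
carry the phase-1 losses is unstated in the source; the default is
phase-exclusive losses with a `joint_phase2` flag. Per-task loss
weights default to 1.

Defaults follow the published schedule: 30/30/90 epochs, Adam at
2e-4 with weight decay 1e-5, batch 16 with an update after every 3
gradient accumulations, cosine annealing re-warmed at each phase start
(the re-warm length is unstated; we use a linear warmup over the first
5% of each phase's updates). No early stopping: the last epoch is
canonical. Gradient accumulation is exactly equivalent to the larger
batch for mean losses; the suite verifies this on a linear model.

The subject-level split is stratified on the (significant, severe)
pair; each stratum contributes floor(n_k x 0.2) subjects to the test
set and a chi-squared screen (p > 0.1 on both labels) triggers a
bounded redraw. With a cohort composition matching the published
prevalence (122/290 significant), this rounding reproduces the
published 234/56 split sizes.

## 5. Inference and evaluation

Views are predicted independently in evaluation mode; the study's
Gensini score is the maximum over views, significance the OR, severity
the >= 15 rule on the final score. For ROC analysis the continuous
score behind each assignment is not stated in the source; we use the
maximum per-view significant-class probability (assignment 1), the
final Gensini score mapped to G/(G + 15) (assignment 2), and the
max/min of those two probability-scale scores for the XOR/AND
assignments 3/4. Metrics: Dice (empty-vs-empty defined as 1), MAE,
Pearson correlation, tie-aware AUC (Mann–Whitney normalisation;
cross-checked against pROC and exhaustive pair counting), and
confusion-matrix rates with undefined ratios reported as `NA`.
Confidence intervals are subject-level percentile bootstrap (B = 1000,
seeded), the CI method being unstated in the source.

## 6. Problem sizes used by the tests

The phantom's analytic limits are exercised at full 256-px rendering;
operator gradient checks use 3–5 element tensors. The end-to-end
training check runs a 60-subject cohort (180 clips) at 64 x 64 frames,
width scale 1/8 (attention width 64, 12 low-level channels), one block
per stage, a two-branch atrous pyramid, epochs 5/5/10, batch 8 without
accumulation at learning rate 3e-3, phase 2 in joint mode, and
feature-space noise 0.2 in phase 3 — at roughly 1/18 of the default
update count, the smaller batch and larger rate keep the number and
size of optimisation steps adequate for the reduced problem, and joint
phase 2 keeps the view head calibrated while the shared encoder
continues to train. These sizes are the package's choices for a desk-scale
demonstration; the defaults (`iecad_config()`, `train_config()`)
remain the full published configuration.

## 7. Known limitations

* The phantom is 2D-per-view with a shared in-plane geometry; real
  views are distinct 3D cross-sections.
* GWE of a healthy phantom is exactly 100% (no baseline inefficiency),
  compressing the healthy end of the GWE distribution relative to
  clinical values.
* The score/CAD heads see features frozen after phase 2, so phase-3
  capacity is limited to the expert block and the two heads — a
  faithful rendering of the staged schedule, not a recommendation.
* DICOM ingestion is an interface stub; the preprocessing contract
  starts at `raw_cycle()`.
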