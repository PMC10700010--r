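---
title: "Explainable-CNN-guided tissue sampling: models, geometry and statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Explainable-CNN-guided tissue sampling: models, geometry and statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

fruitcam implements, on fully synthetic data with planted ground truth, the
workflow in which a convolutional network predicts a fruit's post-harvest
fate from an apex-side photograph, explainable-AI maps localise the image
regions carrying that prediction, those regions guide where tissue is
sampled, and a two-criteria differential-expression analysis contrasts the
sampled regions. This vignette explains each model, the parameters that
matter, the numerical choices, and what the synthetic testbed can and cannot
establish about real data.

## The scientific setting

Rapid over-softening is a post-harvest disorder of persimmon fruit: within
roughly a week of harvest some fruits soften far beyond marketability, while
looking indistinguishable from long-shelf-life fruit at harvest, even to
experts. A binary CNN can nevertheless predict the fate from RGB photographs,
which implies the images contain *premonitory symptoms* — subtle,
spatially-localised colour signals. Relevance maps (Grad-CAM and its guided
variant) make those regions visible, so tissue can be sampled exactly where
the network looked, and the transcriptome of "featured" tissue can be
compared against control-fruit tissue (criteria i, across fruits, unpaired)
and against non-featured tissue of the same fruit (criteria ii, within
fruit, paired).

None of the original image or sequencing data is needed here: every stage
runs on synthetic inputs whose ground truth is known, which is what makes
localisation and recovery *measurable*.

## Synthetic fruit images

`scene_config()` / `render_fruit()` draw a shaded disk (radial brightness
falloff) on a near-black background — the geometry that matters for the
contour-distance analysis — rather than a photorealistic persimmon. The
class signal is carried **only** by blemishes: smooth, low-amplitude colour
bumps planted at controlled normalized contour distances `d` (0 at the
outline, 1 at the centre). Negatives never receive blemishes, so at
`blemish_amplitude = 0` the two classes are exchangeable by construction;
this is the null the classifier tests lean on.

Parameters that matter:

* `blemish_amplitude` (default 0.05 in [0,1] pixel units) — the default is
  deliberately subtle, mirroring a disorder that is "hard to see"; tests
  that need a learnable cohort raise it to 0.2–0.3, which is still well
  below full contrast but clearly above the sensor noise (`noise_sd`,
  default 0.02).
* `blemish_placement` — a band mixture over `d`; the default puts half the
  mass at the apex (`d` in [0.75, 1]) and half at the periphery
  (`d` in [0, 0.1]), the two bands where relevance accumulated in the
  motivating study. Blemishes placed near the rim are clipped by the fruit
  outline rather than pushed inboard: a "peripheral" feature must actually
  hug the contour, otherwise its distance signature is silently shifted
  into the mid band (blemish radius / fruit radius is about 0.2 here, so
  the shift would be large).
* `color_jitter_sd` — per-fruit colour jitter makes the *global* mean
  colour an unreliable class cue, forcing a classifier to localise.
* `camera_profiles` — per-channel affine gains applied after the scene
  (including noise) is rendered; the same fruit seed under two cameras
  therefore differs exactly by that transform, which is tested literally.

Images default to 224 x 224 (the size a VGG-style classifier consumes).
Tests and the acceptance script render at 48 x 48: the geometry is scale
free and the CPU budget is then minutes, not hours; the vignette's numbers
all refer to those desk-scale sizes.

## The classifier and its training protocol

`model_spec()` defines a small VGG-style network: per block one 3 x 3
convolution (zero padding 1), ReLU, and 2 x 2 max-pooling; then a flatten
and a two-way softmax head. The default is four blocks of 8–32 channels;
the end-to-end tests use three blocks of 6–24 channels at 48 px. Two
properties are required of any spec: at least two *named* convolutional
layers at different depths (`conv_last`, `conv_shallow`), because the
relevance analysis contrasts a coarse deep layer with a finer shallow one;
and output probabilities that sum to one.

Training follows the reference protocol: stochastic gradient descent at
learning rate 0.001, categorical cross-entropy, class weights
`n / (2 n_class)`, a stratified 3:1 train:validation split, and 20–100
epochs. Free choices the protocol leaves open, fixed here once: momentum
0.9 (0.95 in the end-to-end tests — from-scratch training at learning rate
0.001 needs the extra effective step size that a pretrained model does
not), minibatch size 16 (8 at desk scale), and augmentation limited to
horizontal/vertical flips plus shifts of at most 2 px. A confidence of
exactly 0.5 is called positive — the protocol fixes the threshold but not
the boundary rule, and a deterministic rule is needed for reproducibility.
The whole network is implemented in R (im2col convolutions, cached index
scatter for the backward pass): the explainability stage needs raw access
to layer activations and to the ReLU backward rule, which an in-package
network provides directly; the backward pass is verified against finite
differences in the test suite.

## Relevance maps

`grad_cam()` implements gradient-weighted class activation mapping at any
named layer: channel weights are spatial means of the class-score gradient
on the rectified feature map, the map is the ReLU of the weighted channel
sum, bilinearly upsampled to image size (nearest-neighbour would imprint
block edges on the distance histogram) and max-normalised per image to
[0, 1]. `guided_backprop()` zeroes every ReLU's backward gradient where the
forward activation or the incoming gradient is negative and reduces the
signed channel gradients to a per-pixel magnitude (max of absolute values —
the channel reduction is otherwise unspecified in the literature this
follows). `guided_grad_cam()` is their elementwise product, renormalised.
The visualisation target is always the positive (rapid-softening) class,
whatever the predicted label, since the question is "where would softening
evidence be".

Per-image max normalisation (rather than cohort-level scaling) is a
deliberate choice: it makes every fruit contribute comparable relevance
weight to the pooled histogram regardless of its absolute confidence. The
alternative — pooling raw magnitudes — would let a few high-confidence
fruits dominate the geometry.

All three maps are verified, to 1e-5, against closed forms evaluated by
independent loop-based oracles on one- and two-conv-layer toy networks with
hand-settable weights.

## Relevance geometry

`segment_fruit()` thresholds luminance (Otsu), keeps the largest connected
component, closes and hole-fills — trivial on a black background, which is
why the scene is specified that way. `normalized_contour_distance()` is the
exact Euclidean distance transform divided by its per-fruit maximum, so a
disk's centre maps to exactly 1; contour pixels sit at `1/normalization`
(about 0.05 at 48 px), not exactly 0 — the convention the histogram tests
encode. The transform is checked against brute-force all-pairs distances.

`relevance_histogram()` pools every fruit pixel of a cohort into a 20 x 20
histogram `H(r, d)` (left-closed bins, right-inclusive final bin so
`r = 1`, `d = 1` count). `band_relevance_summary()` reduces the high-`r`
rows (`r >= 0.8`) to the periphery / mid / apex bands. Because those bands
cover wildly different areas of a disk (roughly 19% / 75% / 6% of pixels),
the summary reports, besides raw mass, the **enrichment** — band share of
high-relevance mass divided by band share of all pixels — and the modal
band is read from enrichment. Raw mass comparisons would call almost any
diffuse map "mid-dominated".

`extract_featured_region()` scans every window position fully inside the
mask via integral images and returns the square window (default 32 px at
224 px, roughly the 10 mm x 10 mm tissue sample on a ~7 cm fruit face)
maximising mean relevance; ties resolve to the smallest row, then column,
within a 1e-9 relative tolerance so that float accumulation cannot scramble
the deterministic choice on flat maps. `extract_nonfeatured_region()`
minimises mean relevance subject to a centre separation of at least twice
the window side from the featured window — "no relevance" has no
quantitative definition in the motivating work, so the package defines the
non-featured sample as "least relevant, and not overlapping the featured
sample". Both scans are verified against brute force.

## The ensemble stage

Two models trained on different cameras see slightly different features;
combining them raises positive precision. `threshold_search()` uses the AND
rule — a fruit is positive when both confidences clear per-model thresholds
at or above the default 0.5 — and exhausts the grid of observed confidence
values (the accuracy surface is piecewise constant between them), returning
the accuracy maximiser subject to a positive-precision floor, with ties
broken by precision then lower thresholds. `select_extreme_samples()`
operationalises "most confidently positive by both models" as ranking by
`min(conf_A, conf_B)` and "confidently negative under both" as
`max(conf_A, conf_B)`, with `fruit_id` as the deterministic tie-break.
Whether the original study combined its two models by an AND rule is not
recorded; the AND rule is assumed because it nests the single-model case
and matches "filtering" semantics.

## Synthetic transcriptomes

`simulate_counts()` reproduces the study's sampling structure: 10 RS-F
samples (featured region, predicted rapid-softening fruit), of which 4
fruits also contribute an RS-NF sample, and 10 C-F samples. Counts are
negative binomial with length-aware expected expression, per-gene
gamma-distributed dispersion, target library sizes of 5–15 million reads,
and a per-gene, per-fruit Gaussian random effect (log2 sd 0.5) shared by
both samples of a fruit — the ingredient that makes the paired contrast
strictly more powerful than the unpaired one, and the reason the original
analysis used a paired test. Library sizes and dispersions were never
reported for the real data; these defaults are assumptions, fixed once.

Heterogeneity mirrors the study's observations: only a fraction of RS
fruits (default half) are "responders" expressing the fruit-level
(criteria i) effect, and one control fruit is mislabelled, carrying the
full RS effect — the analogue of the control sample that clustered with
the RS group. Two design choices deserve justification:

* Criteria-(i) effects are applied at *fruit* level — both the RS-F and
  RS-NF samples of a responder fruit carry them — so they cancel exactly in
  the within-fruit contrast. This keeps the two planted truth sets
  disjoint, making sensitivity and false-discovery proportions
  unambiguous. The alternative (featured-region-only effects) would make
  every criteria-(i) gene a partial criteria-(ii) positive and poison the
  recovery metrics.
* Criteria-(ii) effects are applied to the featured (RS-F) sample only, in
  all paired fruits: they model what is different about the premonitory
  region itself.

## Differential expression

`rpkm()` and `filter_expressed()` implement the expression unit and the
strict `RPKM > 1` group-mean filter of the original analysis. The two
contrasts use exactly the tools the original analysis names: criteria (i)
is a DESeq2 Wald test (RS-F vs C-F, significance convention raw
`P < 0.05`), with independent filtering and Cook's screening disabled so
every tested gene reports a p-value; criteria (ii) is edgeR with fruit as a
blocking factor (`~ fruit + group`), quasi-likelihood F-test, significance
`FDR < 0.1` after Benjamini–Hochberg. The QL flavour was chosen over the
likelihood-ratio flavour after measuring both on null simulations at the
study's size (4 pairs): QL's empirical type-I error is ~0.046 at
`P < 0.05` with a clean far tail, while the LRT's chi-square approximation
inflates the far tail about 2.3-fold at 3 residual degrees of freedom,
which propagates into inflated false-discovery proportions at `FDR < 0.1`.

A consequence worth stating plainly: at 4 pairs, a log2 fold change of 2,
and dispersions in the assumed 0.05–0.5 range, genes in the upper part of
that dispersion range are not detectable by *any* calibrated test — the
measured sensitivity of the calibrated QL test is about 0.7, and a
perfectly calibrated moderated alternative reaches about 0.78. The package
reports what the test actually achieves rather than tuning the simulation
to flatter it.

`overlap_and_concordance()` intersects the two DEG sets per direction and
correlates log2 fold changes over their union; `pca_expression()` runs PCA
on gene-centred `log2(RPKM + 1)` (the transform is unstated in the original
analysis; the pseudocount-1 log is the conventional choice) with pairwise
two-sided t-tests per component; `enrichment_hypergeometric()` is the
upper-tail hypergeometric test with BH adjustment across sets, verified
against exact combinatorial enumeration.

## Orchestration and reproducibility

`run_pipeline()` chains the seven stages — image simulation, two-model
training, prediction + ensemble, explanation, region extraction, count
simulation conditioned on the selected fruits, differential expression —
writing TSV artifacts and a JSON manifest with per-stage seeds and MD5
hashes. A single global seed fans out deterministically to stage seeds
(multiplicative hash, kept below 2^31), so one integer reproduces the whole
run bit-exactly; the test suite asserts this by hashing artifacts across
reruns. `report()` renders the figure set (ROC curves, confidence scatter,
`H(r, d)` heat map, DEG heat map, concordance scatter) from a completed
run. The package's interface is its functions; the pipeline is a function
call rather than a shell tool, which is the natural shape for an R
analysis package.

## Problem sizes used in the checks

The test suite and acceptance script run at sizes chosen to exercise every
claim in minutes on one CPU: images 48 x 48 (32 x 32 for the orchestration
checks), 100 fruits per class for training with an 3:1 split, 80 epochs,
30–50 positives per relevance cohort, and count simulations of 2,000–10,000
genes under the study's 10 + 4 + 10 sample layout. Null calibration uses
10,000 genes. These are the package's reference problem sizes; all scale up
by configuration.

## What passing tests do and do not show

The synthetic scene demonstrates that the pipeline *recovers what was
planted*: a classifier trained at protocol settings reaches held-out AUC
at or above 0.9 on learnable cohorts, guided Grad-CAM's argmax falls inside
the dilated truth mask in at least 70% of confidently predicted positives,
the high-relevance mass of `H(r, d)` is enriched in the band where
blemishes were planted, and flipping the planting flips the modal band.
None of this certifies behaviour on real fruit: real premonitory symptoms
have unknown visual structure (the blemish model is an assumption, not a
reconstruction), real cameras differ by more than affine gains, real
transcriptomes have correlation structure, batch effects and composition
biases absent here, and the real data's headline numbers (AUC, DEG counts,
correlations) depend on those specifics. What the testbed certifies is the
machinery: exact geometry, exact search, calibrated statistics, faithful
localisation when a localisable signal exists.

## Known limitations

* Fruit are disks; no calyx, no 3-D shading, no specularity. Segmentation
  is therefore near-trivial and untested against hard scenes.
* The classifier is trained from scratch; transfer learning, the usual
  practice on real images, is out of scope.
* tSNE of embeddings, read alignment, and annotation-based GO analysis are
  out of scope; enrichment operates on caller-supplied gene sets.
* The paired-design power ceiling discussed above means criteria-(ii)
  sensitivity targets above ~0.8 are unreachable at 4 pairs under the
  assumed dispersion range, whatever the test.
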