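---
title: "Methods: nucleus classification with a recall-ranked voting ensemble"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nucleus classification with a recall-ranked voting ensemble}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its method: the model and
its assumptions, the parameters that matter, the numerical and design
choices that were genuinely open, and what the synthetic tests do and do
not demonstrate.

## Problem and assumptions

The input is a collection of microscope field images of Pap-smear slides
together with a *marks table*: one row per annotated cell nucleus, giving
the image, the nucleus position `(x, y)` (0-based pixels, `x` = column),
and a Bethesda System label (NILM, ASC-US, LSIL, ASC-H, HSIL, SCC). The
pipeline assumes the marks are trustworthy and that the nucleus — not the
surrounding cytoplasm — carries the information needed to grade the
lesion; classification therefore operates on a square patch centred on
each mark. It also assumes that nuclei annotated on the same field image
are far enough apart that a patch contains a single graded nucleus; the
crop size is chosen with that in mind, and the synthetic generator
enforces it by construction.

## Pipeline stages and their parameters

**Cropping** (`crop_patch`). Patch side `m = 90` px by default: large
enough to contain a whole nucleus at 40x magnification, small enough to
exclude neighbours. Because an even `m` has no centre pixel, the window
is the half-open range `[x - m/2, x + m/2)` per axis, putting the mark at
patch index `(45, 45)`; any `m >= 1` works, odd `m` centring exactly.
Windows that overrun the image are completed by symmetric reflection
(border pixel included). Reflection was chosen over constant padding
because constant borders would be a trivially learnable artefact
correlated with mark position — on synthetic data this can leak label
information outright.

**Class schemes** (`class_scheme`). The 2-way scheme (normal | altered)
matches the screening question; the 3-way scheme (normal | low-grade
{ASC-US, LSIL} | high-grade {ASC-H, HSIL, SCC}) matches the follow-up
pathways; the 6-way scheme is the native nomenclature. The groupings are
nested, and the display order is fixed so confusion matrices are
comparable across runs.

**Test split** (`split_test`). Stratified per six-class label:
`ceiling(0.2 * n)` marks per class. The ceiling rule is the only rounding
convention consistent with the reference per-class test counts the
package reproduces (e.g. 175 of 874, 16 of 77), so it is fixed rather
than configurable. Counts are a deterministic function of class sizes;
the seed decides membership only.

**Balancing** (`plan_balance`, `expand_pool`). Ten label-preserving
transforms are available: rotations by 90/180/270 degrees, the mirrored
versions of all four rotations, and three photometric variants. The
mirror axis is left-right (the choice is immaterial up to relabeling of
the dihedral group elements). The photometric parameters, all exposed in
`aug_params()`:

* `noise_sigma = 0.01` — additive Gaussian noise SD as a fraction of the
  value range; mild enough that no plausible grading cue is destroyed;
* `tv_weight = 0.1` — total-variation smoothing weight (Chambolle's dual
  projection, 50 iterations max, relative energy tolerance `2e-4`);
* `bilateral_sigma_color = 0.05` (fraction of range) and
  `bilateral_sigma_spatial = 3` px, window radius `2 * sigma_spatial` —
  edge-preserving smoothing.

The last two are *smoothers*, not noise injections: the common phrasing
"adding total-variation noise / bilateral-filter noise" is contradictory,
and this package implements the filtered-copy interpretation while
exposing every parameter so either reading can be configured.

Two planning modes ship. `general` computes, for any pool profile, the
reference target `T` (largest six-class count inside the group with the
most member classes), sizes every group to `k_max * T` split as evenly as
possible over its members, and schedules each deficient class by the
integer rule `q = floor(e / n)`, `r = e mod n` (with `e` the deficit and
`n` the sources): `r` randomly chosen sources get `q + 1` transforms, the
rest `q`. This reaches every target exactly — a property the test suite
checks on 500 random profiles. `paper` reproduces a set of published
hand-made schedules verbatim for the reference pool profile
(689/228/478/428/699/61), including their quirks: two classes stop at 698
instead of 699, the three-class low-grade plans overshoot their half
group (1042 + 1056 > 2068), and the printed altered-group total (3452)
disagrees with its own per-class plans (3450); the package follows the
per-class plans. Literal mode exists so the package's arithmetic can be
audited against the published tables; `general` is the default.

Tags are drawn without replacement per source, so a source never repeats
a transform; if a plan demands more than ten transforms per source (the
general-mode SCC schedule does: 61 sources to target 699 needs up to 11)
the tag deck is reshuffled and reused, with a warning. The test set is
never augmented.

**Validation re-split** (`split_validation`). Validation is carved out of
the *balanced* pool — `ceiling(0.2 * p)` per six-class label — because
the reference validation counts (135 of 671, 137 of 684, ...) only arise
from balanced pools. Stratification is by the six Bethesda labels under
every scheme: the published per-class validation counts are per-class
ceilings even in the grouped schemes, which a coarser target-class
stratification would not reproduce. Consequence of re-splitting after
augmentation: transformed copies of one source image can land in both
train and validation, which makes validation metrics optimistic. This
fidelity-versus-hygiene tradeoff is deliberate and documented;
`group_by_source = TRUE` keeps all copies of a source on one side at the
cost of the exact published counts.

**Classifier** (`build_model`, `train_model`). The model is a frozen
convolutional feature extractor plus a trained head. The built-in `tiny`
backbone is three blocks of 3x3 convolution (8 channels), ReLU, and 2x2
average pooling, with He-initialized filters fixed at construction from
the model seed; crops are bilinearly resized from 90x90 to the backbone
input (default 32x32, configurable, must be divisible by 8). The head is
flatten → dropout (rate 0.2) → dense softmax, fitted with minibatch Adam
(defaults: 30 epochs, batch 32, learning rate 1e-3, early stopping on
validation macro recall with patience 5) under categorical cross-entropy;
features are standardized with training-set statistics. Freezing random
convolutional features and training only the head mirrors the standard
frozen-pretrained-backbone transfer setup while keeping training
CPU-tractable and exactly reproducible; different member seeds give
decorrelated feature spaces, which is what the voting ensemble needs.
Epochs, batch size and learning rate are package defaults chosen for the
synthetic workloads, not claims about any external study; the resize
policy is likewise a package choice. Degenerate cases are pinned down:
zero epochs is a no-op with empty history; a class absent from training
is an error; argmax ties break to the lowest class index in display
order; the head weights start at zero, so an untrained model predicts the
uniform distribution.

**Metrics** (`classification_report`). All five metrics — precision,
recall, F1, accuracy, specificity — are computed per class from
one-vs-rest counts and aggregated three ways. Macro (unweighted mean) is
the headline: with one-vs-rest accuracy, a multi-class problem can show
high accuracy alongside much lower precision/recall, and macro keeps
those distinctions visible (micro would force precision = recall =
overall accuracy). A metric with a zero denominator is defined as 0 with
a warning, so a never-predicted class damages its average rather than
producing NaN.

**Ensemble** (`select_members`, `ensemble_vote`). The three models with
the best recall vote; majority wins, and when all three disagree the
best-recall member decides. Ties in recall at the selection cut are
broken by a seeded uniform draw, including ties for rank 1 (and hence for
the tiebreaker role). With more than three members the rule generalizes
to plurality with ties resolved by the highest-ranked member voting for a
leading class. Member selection uses *validation* recall by default:
ranking on test recall — as the original ensemble construction did —
leaks test information into model selection; `select_on = "test"`
reproduces that behaviour for comparison.

**Repetition** (`run_experiment`). The whole pipeline is repeated as
shuffle–split cross-validation (reference protocol: 10 repetitions;
package default 1) with per-repetition seeds derived from the experiment
seed, and metrics averaged. Every artefact (manifest, plan, predictions,
reports) is written with the seeds that produced it, so a run is
replayable from its config alone.

## The synthetic generator

`generate_synthetic` renders grayscale fields (default 255 x 344, a
quarter-scale field) with soft-edged elliptical nuclei on a smoothly
varying pale background with a faint cytoplasm halo. Severity `s = 0..5`
(NILM → SCC) controls the appearance monotonically: mean radius
`7 + 3 s` px (SD 1), interior intensity `0.38 - 0.04 s`, chromatin
texture amplitude `0.02 + 0.025 s`; all in `synth_params()`. Nuclei sit
on a jittered grid with centres at least `m` pixels apart, so each crop
contains exactly one marked centroid; placement that cannot respect the
separation is an error. Generation is fully seeded and byte-reproducible.

What this emulates: the size/chromatin/staining gradient that grading
uses, class imbalance, multiple nuclei per field, and the bookkeeping
shape of the real collection. What it does not: overlapping and clumped
cells, inflammation and debris, staining and illumination variability
across slides, the genuine boundary ambiguity between adjacent grades,
and colour. Passing the synthetic end-to-end test therefore demonstrates
that the *mechanics* — counts, splits, plans, training, voting, scoring —
are correct and that the classifier can learn a real separable signal; it
says nothing about clinical performance on stained cytology, which would
require the real images and full-scale fine-tuned backbones.

## Problem sizes used by the tests

The acceptance suite runs the count arithmetic on the full reference
profile (3233 marks), the vote oracle on all 216 + 8 three-voter
combinations, the metric oracle on 1000 random instances, the balancing
exactness property on 500 random profiles, and one end-to-end two-class
experiment on a full synthetic reference dataset with three `tiny`
members and 6 epochs. Unit tests use profiles of tens of marks. These
sizes were chosen so the suite exercises every stage at full accounting
fidelity while training only small heads.

## Known limitations

* The ten named large-scale backbones (EfficientNets, MobileNet,
  XceptionNet, InceptionNetV3) are not bundled: they require external
  pretrained weights. The registry accepts only `tiny`; the head,
  training loop, metrics and ensemble are backbone-agnostic.
* Images are processed as grayscale; colour (hematoxylin/eosin hue) is a
  real cue the package currently ignores.
* The re-split-after-balancing leak described above is the default
  because it reproduces the reference counts; use `group_by_source` for
  honest validation estimates.
* Slide-level aggregation (combining many nuclei into one diagnosis) is
  out of scope; the unit of classification is the single nucleus.
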