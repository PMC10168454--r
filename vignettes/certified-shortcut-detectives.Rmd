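---
title: "Certified shortcut detectives for contrast and sharpness bias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Certified shortcut detectives for contrast and sharpness bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adadetect)
```

## The problem

A binary image classifier trained on a curated medical-imaging dataset can
reach excellent internal test performance while having learned nothing about
the disease. If the positive and negative cohorts were collected on
different scanners, with different post-processing, or at different sites,
then *acquisition-dependent attributes* (ADAs) — above all the global image
contrast and sharpness imprinted by the hardware and vendor pipelines —
can differ systematically between the classes. A network will exploit such a
correlation as a shortcut, and the model then fails on external data where
the correlation is absent.

Contrast and sharpness shortcuts are *intrinsic*: unlike laterality markers
or burned-in text they cannot be segmented away, because genuine disease
features are themselves expressed as local contrast and spatial correlation.
The only practical defence is to detect their presence in a curated dataset
*before* training a clinical model on it. `adadetect` implements a complete
framework for doing that:

1. **Forge** a training set in which the shortcut is the *only* signal:
   take a pool of finding-free images, split it 50/50 at random, perturb
   one half's contrast or sharpness, and label the halves 1 and 0
   (`build_detective_trainset()`). Since no findings are present, a
   classifier that separates these classes has learned the attribute.
2. **Train** an ensemble of small binary CNNs on that set
   (`train_detective()`); the ensemble score is the member mean.
3. **Certify** the ensemble with a two-exam protocol (`certify()`): it must
   be at chance on a dataset known to be shortcut-free (Exam 1,
   AUC within `delta_chance` of 0.5), and near-perfect when its own
   perturbation is injected into the positive (Exam 2a, AUC at least
   `1 - delta_perfect`) or negative class (Exam 2b, AUC at most
   `delta_perfect` — the label-flip mirror of 2a).
4. **Deploy** certified detectives on a dataset under audit
   (`detect_shortcut()`, `audit_dataset()`): an AUC deviating from 0.5
   by at least the detection margin, with a bootstrap CI excluding 0.5,
   flags a shortcut.

## The perturbation operators

"Adjust the contrast" and "adjust the sharpness" each have several possible
realisations; this package commits to the two standard operators of those
attributes, chosen and documented as its own design:

* **Contrast** is a gamma mapping, `v -> 255 (v/255)^gamma`. It is a
  monotone remap of the global intensity scale (rank-preserving, with 0 and
  255 fixed), exactly the kind of transfer-curve difference that different
  vendor post-processing produces.
* **Sharpness** is an unsharp mask, `I + amount * (I - G_sigma(I))` with a
  Gaussian blur `G` (reflect padding, kernel truncated at three sigma).
  Positive `amount` boosts the high-frequency detail band the way
  edge-enhancement firmware does; negative `amount` softens. `amount = -1`
  degenerates to pure blur, and lower values would invert detail, so they
  are rejected.

Strengths are **drawn per image**, uniformly from a configurable range,
rather than fixed: a single fixed transform would let a network memorise
one lookup table instead of learning the attribute, and real acquisition
variation is itself a distribution, not a constant. Each image's draw is
keyed by `(spec seed, image id)`, so results never depend on processing
order. The default ranges — gamma in [1.15, 1.5] (or its reciprocal for the
decrease direction), unsharp amount in [0.5, 1.5] at sigma 1.5 px (or
[-0.7, -0.3] for softening) — were chosen once as perturbations that are
visually subtle at radiograph working resolution yet reliably learnable;
all are configurable through `ada_spec()`.

## The phantom generator

`generate_phantom()` renders chest-radiograph-like phantoms: a bright
mediastinum band, two darker elliptical lung fields with rib-like
sinusoidal bands, Gaussian smoothing, and additive Gaussian noise, with
per-image jitter of the geometry (ellipse centres and radii, rib phase).
The defaults (64 px, lung contrast 0.45, 5 ribs, noise sigma 6, blur
0.8 px) give images whose intensity histogram and edge content are rich
enough for both operators to act on, while two independently seeded pools
remain statistically indistinguishable — verified by the chance-level
separability tests.

What the phantoms deliberately do **not** model: anatomy beyond the gross
intensity layout, pathology, scanner-specific noise spectra, scatter, or
positioning variation. Passing the phantom-scale pipeline therefore shows
that the *framework* — forging, training, certification, the decision rule
— behaves as specified; it does not show that a particular real dataset is
clean, which always requires running the detectives on that dataset.

## Study conditions and problem sizes

The package's working-scale study (`phantom_certification_study()`) uses a
1200-phantom pool at 64 px, a 3-member `small-cnn` ensemble trained for 5
epochs (batch 32, Adam at 1e-3), and a 300+300 shortcut-free exam cohort
with 2000 bootstrap replicates. These sizes run a full two-kind
certification in minutes on one CPU core while leaving the statistical
conclusions unambiguous: at 300 per class the null standard deviation of
the AUC is about 0.024, so the chance band and the near-perfect exam
thresholds sit many standard deviations apart. The full-resolution analog
(224 px inputs, five-member ensembles of ImageNet-scale networks) is
reachable through the same interfaces — the architecture registry declares
those entries — but is not the scale this package's tests exercise.

## Statistical choices

* **AUC estimator.** The Mann–Whitney form with midrank tie handling,
  identical to the trapezoidal area under the empirical ROC curve. It is
  invariant under strictly monotone rescaling of scores, which is why the
  ensemble-mean score needs no calibration before auditing.
* **Confidence intervals.** Stratified percentile bootstrap: positives and
  negatives are resampled separately so every replicate keeps the class
  counts (and no replicate is degenerate), 2000 replicates, percentile
  endpoints at (1-level)/2 and 1-(1-level)/2 with the default quantile
  definition. Stratification matches the default behaviour of the standard
  ROC tooling this readout is meant to be comparable with.
* **Label-flip equivalence.** An AUC of `a` under one label assignment is
  `1 - a` under the other; `auc_flip()` maps results accordingly, and the
  certification protocol uses it implicitly by requiring Exam 2b to be near
  0 rather than near 1.

## Decision thresholds

"Close to 0.5", "close to 1" and "significantly deviates" must be made
operational. The package defaults are:

* certification: `delta_chance = 0.10` (Exam 1 AUC in [0.40, 0.60]) and
  `delta_perfect = 0.05` (Exam 2a >= 0.95, Exam 2b <= 0.05);
* deployment: flag when `|AUC - 0.5| >= 0.10` **and** the 95% CI excludes
  0.5.

These are the simplest thresholds consistent with the published verdicts
this framework reproduces: certified detectives there scored up to 0.56 on
the shortcut-free exam (so the chance band must reach at least that far),
and a deployment AUC of 0.56 with a CI excluding 0.5 was *not* called a
shortcut while 0.37 and 0.84 were (so significance alone cannot flag; a
margin of 0.10 separates the two groups cleanly). The margin applies
two-sidedly, honouring the label-flip equivalence — an audit AUC of 0.05 is
as strong a flag as one of 0.95. All thresholds are arguments, not
constants.

## Numerical conventions and degenerate inputs

* All intensity quantisation rounds half away from zero
  (`round_half_away()`); base R's half-to-even would not port across
  implementations of the same pipeline.
* Resizing is bilinear with half-pixel-centre alignment and edge clamping;
  resizing a square image to its own side is exactly the identity.
* Display windowing clamps to the window edges; windowless acquisitions
  fall back to the full dynamic range (level = midrange, width = range),
  and constant inputs get width 1 so the map stays defined.
* Zero-strength perturbations, gamma 1, sigma 0 and amount 0 are bit-exact
  identities; certification of an identity-perturbation detective fails at
  Exam 2a, by design.
* Odd pools drop one random image (with a warning) rather than erroring;
  train/validation splits retry a bounded number of times and then error if
  both labels cannot appear on both sides (e.g. one patient holding every
  positive image).
* Every stochastic step — pool generation, the 50/50 split, per-image
  strength draws, member splits, weight initialisation, shuffling,
  bootstrap resampling — is seeded by a fan-out hash of one master seed
  plus a stream label, so a study is reproducible from `(kind, seed)` and
  results are independent of evaluation order. Training itself is
  single-threaded C++ and bit-reproducible for a given build.

## Design choices that were genuinely open

* **Ensembling rule**: the member mean of probabilities; simple,
  rank-stable, and sufficient at this scale. Member disagreement is
  visible in `tidy(ensemble)` rather than folded into the score.
* **Patient grouping**: the detective trainset split ignores patient ids
  (a finding-free pool is randomised into artificial classes, so leakage
  has no meaning there), but `split_train_val()` honours them whenever
  present, because validation leakage would inflate member checkpoint
  selection.
* **Uncertified detectives** can score datasets but never flag them:
  `detect_shortcut()` marks such reports advisory (`certified = FALSE`,
  `flagged = FALSE`) and `audit_dataset()` excludes them with a warning.
  A detective that fails Exam 1 sees the original task, and its deployment
  AUC would conflate disease signal with attribute signal.
* **small-cnn**: three 3x3 convolution blocks (8/16/32 channels, ReLU,
  2x2 average pooling), global average pooling and a sigmoid head — about
  6k parameters. Global attributes like a transfer-curve shift or a
  detail-band gain are low-dimensional, global statistics; a compact
  network with global pooling represents them naturally and trains in
  seconds on a CPU. The certification protocol, not the architecture, is
  what qualifies a detective, and the registry keeps heavier architectures
  nameable for full-scale work.

## Limitations

* Only contrast and sharpness operators ship; other intrinsic attributes
  (noise texture, grid artefacts) would need their own operators, though
  the forge/certify/deploy scaffolding is attribute-agnostic.
* Phantom-scale certification bounds what the tests can claim about real
  radiographs (see above).
* The deployment decision rule is a point-estimate-plus-CI heuristic; it
  inherits the arbitrariness of any threshold on a continuous deviation,
  and borderline audits deserve a look at `plot_score_distributions()`
  rather than a binary verdict.
* DICOM ingestion covers windowing of already-decoded pixel matrices
  (`window_to_8bit()`, `window_from_range()`); reading DICOM containers is
  out of scope.
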