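---
title: "Methods: dual-handed fingerspelling recognition from hand landmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-handed fingerspelling recognition from hand landmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fingerspell)
```

## The recognition problem

New Zealand Sign Language fingerspells with *two* hands. The
non-dominant hand presents a handshape; the dominant hand points at or
touches it. This has two consequences for a tabular recogniser. First,
features must describe both hands jointly. Second, handshape alone is
not sufficient: the five vowels A, E, I, O, U are signed with the same
open non-dominant hand and are distinguished only by which digit —
thumb through little finger — the dominant index fingertip touches.
`fingerspell` therefore extracts, per frame, a geometric feature block
*plus* an explicit touch code per hand.

The package deliberately starts downstream of any camera or
hand-tracking model. Its input is the tracker's output format: 21
landmarks per hand in normalised image coordinates (index 0 wrist, 1–4
thumb, then four fingers at 4 landmarks each), with the pixel dimensions
of the frame. On disk this is a line-delimited JSON stream; in code it
is a `frame_observation`.

## Feature model

Every hand contributes 28 pairwise distances between named anatomical
points: the wrist, the base (MCP knuckle) and tip of each finger, plus
three derived points — the palm base (centroid of wrist and index/little
knuckles) and the midpoints of the thumb–little and index–little tip
segments. "Thumb base" is taken as the thumb MCP, consistent with the
knuckle meaning used for the other fingers; the CMC landmark is unused.
The pair list is fixed and versioned (`distance_schema()`), beginning
with wrist–thumb-base and ending with palm-base–index-little-midpoint.

Each distance is divided by the hand's *standard length*, the
wrist-to-thumb-base distance. The ratio cancels translation, rotation
and uniform scale, so hand size and camera distance drop out; `unit-0`,
the reference pair divided by itself, is exactly 1 for every present
hand and acts as a built-in sanity flag. The invariance is asserted in
the test suite to 1e-9 relative error over 1,000 random similarity
transforms. A standard length below 1e-9 raises a degeneracy error
rather than letting the ratios blow up; real trackers do not emit such
hands, but corrupted files can.

Touch detection happens in pixel space, where the threshold has its
physical meaning: two tips touch when their pixel distance is *strictly*
less than 30 px (the default `touch_config()`). Each hand's tip code is
the digit index (1–5) of its fingertip touched by the *other* hand's
index tip — the pointer in dual-handed fingerspelling — with 0 for no
touch or no other hand; if several tips fall inside the threshold the
nearest wins, ties to the lowest digit. Records store the two codes as
`tip-1`, `tip-2` beside the 56 units.

Hands are assigned to slots by handedness: hand 1 is the left hand,
hand 2 the right, with input order as the fallback for unknown
handedness. An absent hand contributes 28 zeros and tip code 0 — a dense
encoding outside the attainable range of genuine relative distances,
which downstream classifiers handle without missing-value machinery.

## Dataset format and cleaning

A dataset is a data frame with the fixed 59-column header `letter,
unit-0…unit-55, tip-1, tip-2`, written as plain comma-separated UTF-8.
Numeric fields are serialised with 15 significant digits, so a round
trip is lossless well past the 10 digits the format guarantees. Every
transform appends to a provenance log carried on the object.

Cleaning runs in a fixed order, each step idempotent:

1. **`drop_empty`** removes records whose 56 units are all zero — frames
   where the tracker saw no hand. Single-hand records (one zero block)
   are legitimate: letter C is signed with one hand.
2. **`drop_duplicates`** removes exact repeats (label plus all 58
   numbers), keeping first occurrences; repeated captures of a held pose
   otherwise overweight it.
3. **`zscore_filter`** standardises each unit column against its mean
   and *population* standard deviation and drops any record with
   |Z| > 3 in any column. Zero-variance columns are skipped. Structural
   zeros from an absent hand are masked out of both the column
   statistics and the violation test. This masking is a deliberate
   design choice: the hand-2 reference column `unit-28` is exactly 1 for
   every two-hand record, so without masking the single-hand letter-C
   records would sit six-plus standard deviations out in that column and
   the filter would silently delete the entire class. The filter targets
   capture anomalies, not structurally absent hands.

**Augmentation** (`swap_hands`) appends a copy of each record with the
two hand blocks and tip codes exchanged, covering left- and
right-dominant signers; it is an involution, so swapping the copies
recovers the originals bit for bit. When applied before splitting it
places mirrored twins of training records in the test split; the CLI
help states this leakage risk, and the recommended order for honest
generalisation estimates is to augment the training split only.

**Splitting** (`split_gestures`) holds out 20% by default, stratified
per class with rounding, so every class lands within one record of the
target fraction; the seed makes splits reproducible, and a class with a
single record is a hard error rather than a silent empty stratum.

**Normalisation** (`minmax_fit` / `minmax_apply`) rescales each unit
column by its training-split min and max into [0, 1]; zero-range columns
map to 0, and test or live values outside the fitted range extrapolate
linearly without clipping. Fitting on the training split only avoids
test-set leakage. Tip codes are categorical and are never rescaled.
Trained models store their fitted parameters so the live prediction path
applies exactly the training-time scaling.

## Synthetic data: what it emulates, what it does not

No public landmark dataset exists for dual-handed NZSL fingerspelling,
so the package ships a generator rather than fixtures. Each of the 36
classes is a `pose_template`: per-finger flexion in [0, 1] per hand,
thumb abduction, a hands-present flag, and an optional touch
specification. Poses are rendered from a planar kinematic skeleton —
wrist at the origin, five finger chains with fixed canonical segment
lengths, curls folding each chain joint by joint — which is 2-D by
design, since every quantity in the feature model is 2-D.

The structure mirrors the study conditions the pipeline must survive:

* **Vowels** share one template (open hand 1, pointing hand 2) and
  differ only in `touch_spec`: thumb through little for A, E, I, O, U.
  Their unit blocks are exchangeable by construction — a location test
  per column cannot separate A from E — while `tip-1` separates them
  perfectly. A classifier denied the tip columns collapses to chance
  (~1/5) on the vowels; with them it reaches ceiling. This
  operationalises the reason the format stores fingertip information.
* **Letter C** is hand-1-only, exercising the zero-block path end to
  end.
* **Other classes** draw flexion/abduction procedurally under a minimum
  between-class margin (0.25 in max-absolute flexion difference), so
  classes are distinct but not trivially far apart.

Intra-class variation is per-landmark Gaussian jitter followed by an
independent similarity transform per hand. The defaults — `jitter_sd`
0.008 (≈ 4–5 px at 640 px width), rotation ±15°, scale 0.85–1.15,
translation ±0.04 — model a cooperative signer varying wrist angle and
camera distance, the variation deliberately included when such datasets
are collected. Because the features are similarity-invariant, only
jitter (and the discrete tip codes) carries class-relevant noise; the
transform noise validates the invariance rather than stressing the
classifier. Touch placement translates hand 2 rigidly so its index tip
lands at a fixed sub-threshold offset from the target digit — rigid
translation changes no relative distance, so touch enforcement never
leaks vowel identity into the unit block. Templates without a touch spec
get the hands pushed apart past 1.5× the threshold so no accidental
touch registers.

Everything is seeded: the same seed and parameters give byte-identical
CSVs, and each draw is independently reproducible from (seed, draw
index). What the generator does *not* emulate: real NZSL handshape
geometry (templates are procedural, not digitised signs), tracker error
structure (occlusion, swapped fingers, dropped frames), depth effects,
and inter-signer anatomy. Passing tests therefore demonstrate the
pipeline's mechanics — invariances, formats, cleaning rules, separability
under controlled noise — not field accuracy on human signers.

## Classifiers and evaluation

Seven families are benchmarked on the 58 feature columns: random forest
(200 trees), k-nearest neighbours (k = 5, Euclidean), Gaussian naive
Bayes, a decision tree grown without complexity pruning (`cp = 0`),
multinomial logistic regression (1,000-iteration cap), a radial-kernel
SVM (C = 1), and multiclass AdaBoost — the SAMME scheme on 50 depth-1
trees, implemented in the package since no installed library provides a
multiclass booster. Hyperparameters are exposed on `classifier_spec()`;
stochastic fits derive their RNG state from the suite seed, so identical
seeds give identical metrics.

Evaluation builds the actual-by-predicted confusion matrix and derives
per-class one-vs-rest precision, recall and F1, with 0 (and a warning)
when a denominator is zero. Headline figures are support-weighted
averages — weighted recall is then algebraically identical to accuracy,
an invariant asserted to 1e-12 on every report — with macro averages
alongside. The per-class F1 table supports letter-level error analysis;
the `analyze` subcommand writes it plus the comparison table and one
confusion matrix per model.

`predict_letter()` closes the live loop: a frame is featurised, the
model's stored min-max parameters are applied, and one label from the
model's class inventory is returned. A record with the wrong number of
features is a schema error, not a silent misprediction.

## Numerical and design choices

* Degeneracy epsilon 1e-9 on the standard length; strict `<` at the
  30 px touch threshold; nearest-tip rule with lowest-digit ties.
* Population (not sample) standard deviation in the outlier filter, as
  the statistic is computed over the whole dataset, and the any-column
  violation rule — one anomalous distance is enough to distrust a frame.
* Off-frame landmarks (coordinates outside [0, 1]) warn but are
  accepted; fingertips do leave the frame in practice.
* Zero-noise generation produces exact duplicates by design (the touch
  offset is deterministic per template), which is what makes the
  duplicate-removal contract testable bit for bit.
* `class::knn` resolves distance ties at the k-th neighbour by voting
  over the whole tie set; on data with exact duplicates this matters,
  and the package keeps k = 5 as a documented default rather than
  special-casing ties.

The test suite runs the full pipeline at reduced problem sizes (typically
12–50 draws per class) and one reference-scale check at 36 × 200 with
seed 42 — the same configuration `scripts/acceptance.R` recomputes — where
the held-out random forest exceeds 90% accuracy and tip-blinded vowel
accuracy stays at chance.

## Known limitations

Static poses only: the motion letters are treated as their static
handshapes, and no temporal smoothing or sequence modelling is included.
Touch coding covers cross-hand contacts only, not within-hand
thumb-to-finger contacts. The generator's realism limits are listed
above; results on it bound nothing about human-signer accuracy. Larger
than-memory datasets and database backends are out of scope.
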