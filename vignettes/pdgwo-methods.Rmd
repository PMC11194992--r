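---
title: "Methods: grey wolf optimization and the PD imaging pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: grey wolf optimization and the PD imaging pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdgwo)
```

This vignette is the package's own account of its methods: the optimizer
and its update equations, the hyperparameter search built on it, the
architecture contracts, the preprocessing pipeline, and — importantly —
the decisions taken where the published description of this family of
methods is ambiguous, plus what the synthetic tests do and do not
establish.

## The grey wolf optimizer

GWO is a population metaheuristic for bounded continuous minimization.
A pack of `n_wolves` positions is ranked each iteration; the three best
(alpha, beta, delta) act as leaders. Every wolf takes one *encircling
step* toward each leader

$$V_k = |S_k \cdot T_k - T|, \qquad
  \text{candidate}_k = T_k - U_k \cdot V_k, \quad k \in \{\alpha,\beta,\delta\}$$

and moves to the arithmetic mean of its three candidates, projected back
into the box. The stochastic coefficients are drawn per dimension as
$U = 2pq_1 - p$ and $S = 2q_2$ with $q_1, q_2 \sim \mathrm{Uniform}[0,1]$,
so $U \in [-p, p]$ and $S \in [0, 2]$. The scalar $p$ decays linearly
from 2 to 0 over the run: early on $|U| > 1$ is common and wolves
overshoot their leaders (exploration); late in the run $|U| < 1$ and the
pack contracts onto them (exploitation).

Design choices the equations leave open, and how this package resolves
them:

* **Per-dimension, per-leader draws.** $q_1, q_2$ are vectors drawn
  independently for every wolf, every leader, and every dimension — the
  reading that maximizes exploration and matches the method's original
  formulation. The draw order (q1-vector then q2-vector, leaders
  best-to-third, wolves in index order) is fixed and is part of the
  package's reproducibility contract; the test suite holds a
  straight-line transcription of the equations against the engine on a
  shared random stream.
* **Minimization.** Fitness is minimized; callers maximize by negation.
* **Stable tie-break.** Ranking uses a stable sort, so equal-fitness
  wolves are ordered by index. This makes runs reproducible and gives the
  documented behaviour on constant objectives (the first-evaluated wolf
  is returned).
* **Shared schedule, private noise.** $p$ is one scalar per iteration for
  the whole pack; all randomness beyond that is private to each
  wolf/leader/dimension.
* **Hard clamping.** Out-of-box coordinates are projected to the nearest
  bound, not reflected. Projection composes with the mean update without
  changing in-bounds coordinates.
* **Monotone result.** The global best is tracked separately from the
  current alpha, so the reported optimum never regresses even when the
  whole pack moves away from it. The recorded history of global best
  fitness is therefore non-increasing by construction.
* **Decay inside the loop.** Update $t$ (1-based) uses
  $p = 2(1 - t/t_{\max})$, so the final update runs at exactly $p = 0$
  (pure exploitation) and the first at $p$ just under 2. The schedule
  function itself spans $[0, 2]$ inclusive and is tested at both
  endpoints.
* **Early stop.** An optional absolute fitness threshold ends the run
  early; the default termination is the iteration count alone.
* **RNG hygiene.** `gwo()` seeds R's generator itself and restores the
  caller's RNG state on exit, so package internals never perturb
  user-level draws.

One ambiguity in the method's prose description deserves a note: the
"attacking" discussion elsewhere describes $U$ as ranging over
$[-2r, 2r]$ with an undefined $r$ and a second symbol $r_2 \in [-1, 1]$
that appears nowhere else. These conflict with the defining equation
$U = 2pq_1 - p$, whose range is $[-p, p]$; the package implements the
defining equation and leaves the stray symbols unhoused.

## Hyperparameter search

`hp_search()` turns a trainer callback into the GWO objective. The
default five-dimensional space is learning rate $[0.001, 0.01]$
(continuous), batch size $[32, 128]$ (integer), momentum $[0.9, 0.99]$
(continuous), dense units $[128, 512]$ (integer), epochs $[10, 50]$
(integer).

* **Fitness is 1 − validation accuracy.** The selection signal in this
  line of work is accuracy-driven, so the objective is exactly that;
  validation loss is recorded in the log and used only to break exact
  accuracy ties when the final best assignment is reported.
* **Continuous dynamics, integer decode.** The optimizer moves in a
  continuous box; integer dimensions are rounded to the nearest integer
  (then clamped) only when a position is decoded into an assignment.
  Decoding is idempotent. This keeps the pack dynamics exactly those of
  the update equations.
* **Fitness cache.** Decoded assignments are cached by value, so the
  trainer runs at most once per distinct assignment. The trainer-call
  budget is therefore at most `n_wolves * (n_iterations + 1)` (the
  initial pack evaluation counts) and usually much less once the pack
  contracts.
* **Dense units come as a pair.** The published head uses two hidden
  layers of 256 and 128 units while the tuning table lists a single
  dense-units range; the package exposes one integer dimension for the
  first head layer and fixes the second at half of it, reproducing
  256/128 at the default.
* **Momentum under Adam.** The training recipe names the Adam optimizer
  *and* a momentum range — classical momentum is not an Adam parameter.
  The package maps the momentum dimension onto the first-moment decay of
  whatever trainer consumes it; the built-in `tiny_trainer()` applies it
  as classical momentum on SGD. The search space keeps the dimension
  (its range $[0.9, 0.99]$ is exactly the usual first-moment decay
  range), and the mapping is the trainer's business, recorded in its
  documentation.
* **Degenerate spaces.** A pinned dimension (lower = upper) is widened
  by an epsilon for the engine and clamped back at decode time, so a
  single-point space costs exactly one trainer call.

`tiny_trainer()` exists so the search loop has a real, deterministic,
non-degenerate response surface at desk scale: logistic regression by
minibatch gradient descent with momentum on block-mean image features,
standardized with training-set statistics. Too few epochs or too small a
learning rate underfit, so accuracy genuinely varies across the box. It
is not a stand-in for a deep network's response surface — it is the
cheapest trainer that makes the search dynamics observable and testable.

## Architecture contracts

Models are declarative layer graphs; `infer_shapes()` applies the
standard output-size arithmetic (valid: $\lfloor (n-k)/s \rfloor + 1$;
same: $\lceil n/s \rceil$ per axis; concatenation sums channels and
requires equal spatial dimensions). The hybrid design carries hard
contracts at its block boundaries — 7×7×512 after the 13-convolution
VGG16 backbone, 7×7×640 after the first inception-reduction block,
3×3×832 after the second, then a 1024-long pooled vector, a 1024-unit
fully connected layer, and one sigmoid unit — and the test suite asserts
the full trace exactly.

Where the published description fixes layer-type counts and concatenated
totals but not per-branch widths, this package chose allocations meeting
both constraints; they live in one constants table
(`hybrid_block_channels`) so they are auditable and changeable in one
place. Three related decisions:

* **Block-2 runs entirely at stride 1 / same padding** (its output is
  printed as 7×7), while **Block-3's reduction stage runs stride 2 /
  valid** to produce the printed 3×3.
* **Block-3's reduction** has a budget of two 1×1 convolutions, both
  consumed by its convolutional branches, so its max-pool branch passes
  channels through unprojected; the inception concat was sized 512 so
  that 128 + 192 + 512 = 832.
* **Channel projection before pooling.** The block trace ends at 832
  channels but the pooled vector is specified as 1024; a 1×1 convolution
  (832 → 1024) before global average pooling is the minimal insertion
  reconciling the two printed numbers.

The classifier head is dense(256)–BN–dropout(0.2) →
dense(128)–BN–dropout(0.2) → dense(1, sigmoid). The source description
says in one place that the "output layer" has 128 neurons and elsewhere
that the output is a sigmoid probability for a binary task trained with
binary cross-entropy; only a 1-unit sigmoid is consistent with the loss,
so 128 is read as the last hidden width. Batch normalization is placed
after each head dense layer. The VGG16 prose also contains a stray
"6 × 6 filters with stride 2" sentence that contradicts both standard
VGG16 and its own 3×3 statement; the backbone implements standard 3×3
throughout (the inconsistency is flagged here, not guessed into the
code).

DenseNet-121 and the InceptionV3 stem are treated as standard,
configurable backbones: the DenseNet emitter reproduces the standard
block/growth arithmetic (ending 7×7×1024 on a 224 input) and the
inception stem follows the published 32/32/64-filter facts, but the
inception module body is a representative stand-in, not a re-derivation —
re-deriving those topologies is explicitly out of scope. For the
DenseNet–LSTM variant the spatial-to-sequence mapping is unspecified;
the simplest one is used: the final 7×7 feature map's rows become 7
timesteps of 7·C features feeding a single LSTM sized like the second
head layer.

`materialize()` hands a spec to a user-supplied framework adapter (e.g.
keras/tensorflow, trained with Adam and binary cross-entropy) and
cross-checks the adapter's reported shapes against `infer_shapes()`. No
framework ships with this package, so without an adapter it raises a
typed optional-dependency error; the shape cross-check itself is
exercised in the tests with a reference-arithmetic probe adapter.

## Preprocessing

* **Windowing.** DICOM pixels are mapped to 8 bits linearly through the
  file's display window (centre/width) when present, else min–max. The
  synthetic generator writes 16-bit data as 8-bit values × 257 under a
  full-range window, which makes the round trip exact and keeps the
  window path exercised.
* **Empty slices.** "Empty tuples" — slices whose arrays carry no
  anatomy — are defined here as mean 8-bit intensity below 30. The rule
  is deliberately simple, logged per file, and the threshold is a
  config parameter.
* **Skull stripping** is a transparent stand-in for a full brain
  extraction tool: Otsu threshold, largest 4-connected component,
  3×3 morphological closing (2 iterations), interior hole fill. On
  phantoms it recovers the true head mask with Dice ≥ 0.95 (asserted in
  tests); on real MRI it is a baseline, not a validated clinical
  stripper. Stripping precedes cropping: the mask defines the crop box.
* **Crop and resize.** Crop to the mask bounding box, zero-pad to a
  square (preserving aspect ratio), bilinear resample with aligned pixel
  centres to 224×224, replicate to 3 channels. Resampling an image to
  its own size is the identity.
* **Output format.** Converted images are written as lossless PNG by
  default (JPEG optional) — medical-imaging practice prefers lossless,
  and it makes the byte-identity determinism tests meaningful.
* **Splits.** Test = $\lfloor 0.2n \rfloor$, then validation =
  $\lfloor 0.2(n - n_{test}) \rfloor$ of the remainder; this floor
  convention reproduces the published totals at every level for both
  dataset sizes used in this line of work (9070 → 7256/1814 →
  5805/1451; 20096 → 16077/4019 → 12862/3215). Published per-class
  counts are internally inconsistent with those totals, so totals
  govern and stratification is best-effort largest-remainder. Default
  splitting is slice-level (which is what reproduces the printed
  totals); a subject-level mode assigns whole subjects to one split for
  leakage-safe use, at the cost of exact totals.

## The phantom generator

The generator emulates the image *structure* the pipeline depends on,
not MRI physics: a bright elliptical skull ring (intensity ≈ 230) with a
textured interior (mean 120, sd 10) on a near-black background; two
striatal foci left and right of midline whose mean intensity is
`tissue_mean + 60` for the disease class and `tissue_mean + 60 +
separation` (default separation 40) with doubled eccentricity for
controls — a low-fidelity rendering of the comma-versus-dot uptake
pattern; and a configurable fraction of near-blank slices (uniform noise
in [0, 8], guaranteed below the empty threshold). Default frame size is
256×256, the native acquisition matrix the pipeline expects to resize
from. Defaults were chosen once so that the class signal is strong but
not trivial (a closed-form intensity threshold classifies ~90%+, and the
tiny trainer's accuracy varies across the tuning box) and are not tuned
against test outcomes.

What a green test establishes: the pipeline's mechanics — filtering,
stripping, geometry, determinism, split arithmetic — and the search
dynamics on a real response surface. What it does not establish:
diagnostic performance on clinical images, robustness to scanner
artefacts, 3-D context, or anything about transfer-learned weights. The
published headline accuracies for this method family require restricted
clinical data and large-scale GPU training and are deliberately not
reproduced here.

## Numerical and degenerate-input conventions

* Zero-denominator metrics (e.g. precision with no positive calls)
  return 0 and are named in the report's `degenerate` field instead of
  raising, so batch evaluation always completes.
* The default decision threshold on sigmoid scores is 0.5.
* AUC uses trapezoidal integration over distinct-score thresholds, which
  equals pair-counting with ties at half; the equivalence is asserted to
  1e-12 in the tests.
* The engine evaluates leaders' mean as the literal three-term sum
  divided by 3 so that an independent transcription of the equations is
  bit-identical on a shared random stream.
* Non-finite objective values abort the run naming the offending
  position; fewer than 3 wolves, invalid schedules, mismatched vector
  lengths and single-class metric inputs raise immediately.
* All entry points that consume randomness take an explicit seed and
  leave the global RNG state untouched.

## Known limitations

* The DICOM codec reads only what the package writes (Explicit VR Little
  Endian, single-frame monochrome); compressed or implicit-VR archives
  need external conversion first.
* The skull stripper is intensity-based and will fail on images whose
  background is brighter than tissue.
* `tiny_trainer()` ignores `dense_units` (a single-layer model has no
  hidden width); the dimension still participates in the search space.
* Subject-level splitting trades exact split totals for leakage safety.
* The InceptionV3 module body is a stand-in; only its stem facts are
  contractual.
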