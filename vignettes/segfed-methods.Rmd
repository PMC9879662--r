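---
title: "Methods: simulated secure federated segmentation with segfed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated secure federated segmentation with segfed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(segfed)
```

## What the package models

`segfed` simulates a secured federated workflow for binary medical-style
image segmentation. Data-holding sites each train a small encoder-decoder
network locally; a genetic algorithm chooses each network's learning rate,
epoch count and batch size; the sites' predictions are fused per pixel by
plurality voting; and every model update is committed to a SHA-512 hash-chain
ledger whose verification detects tampering with the recorded training
provenance. Nothing here talks to a network or a GPU: the point is to make
the *mechanisms* — vote fusion, evolutionary tuning, hash-chain auditing —
concrete, deterministic and testable at desk scale.

## The synthetic task

Real ultrasound / MRI / radiography segmentation corpora are large,
license-bound downloads. The generator stands in for them with the minimal
structure those tasks share: a single bright foreground structure on a noisy
background.

* Masks are drawn first: one random ellipse, one thick random segment
  ("tube"), or a union of 2–4 blobs, rejection-sampled (with a morphological
  erode/dilate fallback, capped at 100 draws) until the foreground fraction
  falls inside the configured range. Every mask is guaranteed non-trivial
  (at least one pixel of each class).
* Images derive from masks: foreground intensity 0.7, background 0.3,
  Gaussian blur (`blur_sigma`, default 0.7 px, applied as a normalised
  convolution so borders are not darkened), then additive Gaussian noise
  (`noise_sigma`, default 0.05 on the `[0, 1]` scale), clamped to `[0, 1]`.
  A 0.4 intensity contrast against `sigma = 0.05` noise makes the task
  learnable by a depth-3 network in CPU minutes while still requiring the
  model to denoise and localise.
* Defaults (`32 x 32` px, foreground fraction in `[0.10, 0.35]`) mirror the
  scale of a cropped single-structure region of interest.
* Determinism: each sample derives its own RNG stream from the config seed
  and sample index, so datasets are bit-identical across runs and platforms
  and insensitive to how many samples you draw.

What the generator deliberately does **not** emulate: speckle and attenuation
artefacts, multi-structure scenes, class imbalance across images, annotation
noise, or domain shift between sites. Tests passing on this task show the
machinery is correct, not that the networks would segment clinical data well.

`make_buckets()` reproduces the nested training-fraction design used for
data-efficiency sweeps: after holding out validation and test fractions
(sizes rounded down), the shuffled training ids are sliced into five nested
buckets at 20/40/60/80/100% (sizes rounded down, minimum 1, the last bucket
being the full training set).

## The four architectures

All four families share one set of conventions, chosen so that parameter
accounting is exact and reproducible:

* blocks are `[3x3 conv -> ReLU] x 2`, same-padding, no batch normalisation;
* downsampling is 2x2 max-pooling; upsampling is either a 2x2 stride-2
  transposed convolution (default) or bilinear upsampling followed by a 3x3
  convolution;
* channel widths double per level from `base_width`; the final layer is a
  1x1 convolution with a sigmoid, so every pixel gets a probability;
* weights are He-style fan-in uniform, drawn from a seeded stream, so
  identical spec + seed give bit-identical models (`weights_digest()`
  hashes the canonical little-endian serialization).

Under these conventions the classic depth-5, widths-32–512, 1-in/1-out
U-Net counts exactly 7,759,521 trainable scalars (7.8 M at one decimal) and
the nested-skip variant 9,041,601 (9.0 M) — the widely quoted sizes for the
two designs — and `count_parameters()` computes both closed-form without
allocating weights. A test walks the instantiated models and checks exact
agreement, for every family and both upsampling modes.

The variants differ only in their skip topology:

* **unet** — long skips: each decoder level concatenates the same-scale
  encoder features.
* **unetpp** — nested dense skips: intermediate nodes `X[i, j]` concatenate
  all previous same-scale nodes plus an upsampled deeper node. At depth 2
  the nesting degenerates to the plain U-Net; from depth 3 it strictly adds
  parameters.
* **unet3p** — full-scale skips: each decoder level fuses *all* encoder
  scales (max-pooled down) and all deeper decoder levels (bilinearly
  upsampled), every source first reduced to `base_width` channels by a 3x3
  convolution; the fused decoder width is `depth * base_width` at every
  level.
* **nasunet** — fixed cells: a stride-2 convolution entry (DownSC) or an
  upsampling entry plus skip fusion (UpSC), followed by an ordered stack of
  primitives (`sep_conv_3x3`, `dil_conv_3x3`, `max_pool_3x3`, `identity`)
  closed by a residual connection. The cell composition is part of the
  declared spec; this package performs no architecture search — searching
  the cells is a different problem with its own literature, and the fixed
  cell preserves what matters here: a fourth, structurally distinct voter.

## Training

`train_segnet()` is deliberately plain stochastic gradient descent at
exactly the configured learning rate — no momentum, no adaptive scaling, no
schedules — because the tuner's learning-rate gene must be the *only*
step-size control; anything adaptive would mask the quantity being searched.
The loss is pixel-wise binary cross-entropy computed stably on logits, with
an optional soft-Dice term (`dice_weight`, default 0; useful when foreground
fractions are very small). Minibatch composition is reshuffled every epoch
from the run seed; the shuffle stream is part of the determinism contract,
so identical inputs + seed reproduce the weights digest bit for bit on a
platform. Binarisation is strict (`probability > threshold`, ties to
background) so thresholding is deterministic.

Divergence is real: at the top of a generous learning-rate range plain SGD
on this loss can collapse a model to all-background predictions. The
pipeline's default search space caps the learning rate at 0.3 for this
reason, and the ensemble vote absorbs an occasional dead voter.

## The genetic tuner

Individuals carry three genes: learning rate (sampled and binary-encoded on
a log scale, because plausible values span orders of magnitude), epochs and
batch size (integers, round-to-nearest with ties up after decoding).
Fitness is `1 / (1 + loss)` on the validation loss: any strictly decreasing
map would order individuals identically; the bounded form avoids sign and
overflow conventions. Selection is a size-`k` tournament drawn without
replacement — the winner is the best already-evaluated contestant, never
re-tested — which gives the well-known exclusion property: with distinct
fitnesses exactly `k - 1` individuals can never be selected
(`tournament_win_probability()` computes the analytic win distribution).
Crossover is one-point, either on the 3-gene vector or on the concatenated
48-bit fixed-point encoding (16 bits per gene, decoded with clipping so the
operator is closed over the space). Mutation re-randomises each gene
independently with probability `mutation_rate`, resetting fitness whenever
anything changes.

Choices the search literature leaves open were fixed as follows: one elite
is carried unchanged per generation, which makes "the search converges"
testable as a monotone best-so-far sequence; crossover rate defaults to 0.9
and per-gene mutation to 0.15, values that recover a known quadratic
optimum within 10% (per normalised gene) in at least 9 of 10 seeds at the
population-20 / 10-generation setting the experiments use. Whether fitness
should use training or validation loss is also open; validation loss is
used, since the genes being tuned (epochs especially) directly control
overfitting.

## Plurality fusion

With two labels, plurality voting is majority voting: a pixel is foreground
iff strictly more than half the models vote foreground. An even ensemble
(the default has four voters) can tie 2–2; the tie rule is foreground iff
the *mean predicted probability* across models strictly exceeds 0.5. Using
the available confidence rather than a fixed label keeps the rule
deterministic, symmetric under model permutation, and unanimity-preserving;
tests check equivalence against an exhaustive per-pixel tally oracle,
permutation symmetry, and monotonicity (a single vote flipped to foreground
never flips a fused pixel to background).

## The audit ledger

Each training round commits a block carrying: the site id, the round, the
SHA-512 digest of the training-data manifest, the hyperparameters used, the
digest of the delivered weights, and a timestamp. Serialization is
canonical — fixed key order, pinned number formats, UTF-8 — so digests are
bit-exact across platforms. Block `i + 1` stores the SHA-512 of block `i`'s
canonical serialization; that predecessor linkage is the security-bearing
integrity mechanism. SHA-512 itself is implemented in compiled code from
the standard specification (64-bit words, messages padded to a multiple of
1,024 bits — `sha512_padded_length()` exposes the padding arithmetic) and is
verified against the published test vectors.

The chain additionally carries a running checksum with the recurrence

    H_i = ( H_{i-1} + ( C(H_{i-1} || payload_digest_i) mod 64 ) ) mod 2^512

with `C` = SHA-512 and digests read as big-endian 512-bit integers, starting
from a configurable `H0` (all zeros by default). Two choices here were
genuinely open and are package decisions: the modulo binds to the
compression output (so successive checksums differ by at most 63), and `C`
is fed the previous checksum concatenated with the block's payload digest so
the checksum is content-sensitive rather than a function of `H0` alone. The
checksum is auxiliary — tamper detection never relies on it alone.

The "smart contract" layer is reduced to its testable essence: a registry
mapping site ids to signing keys with `authorized` and `blacklisted` flags
(blacklisting atomically revokes authorization). Appends are authenticated
with HMAC-SHA-512 over the payload digest under the site's registered key;
full public-key certificate machinery would add no behaviour the tests could
distinguish. `verify_chain()` recomputes every digest, linkage, checksum and
signature and *reports* offending indices rather than throwing — a verifier
that crashes on tampered data cannot audit it.

## The attack experiment

No published attack generator exists for this setting, so the experiment's
attack model is defined by this package: each simulated update is attacked
with probability `attack_rate`, the type drawn from payload tampering (an
ASCII-safe bit flip in a stored field), stale links (corrupted predecessor
hash), unauthorized appends (an unregistered intruder identity), and weight
poisoning (a bit flip in the delivered weight bytes after their digest was
committed). The audited condition detects via chain verification, registry
rejection and recomputation of delivered-weight digests; the unaudited
baseline applies only schema validation (field presence, types, ranges), a
weak detector that still catches tampering that pushes values out of range.
By construction the audited checks subsume the baseline, so its detection
rate dominates for every bucket; the experiment reproduces that *structure*
(bucket percentages x with/without auditing), not any particular printed
percentages. Weight poisoning is detectable only because the evaluator
re-hashes the delivered checkpoint; a semantically poisoned model with an
honestly recomputed digest would pass, which is a documented limitation of
digest-based auditing.

## Problem sizes and numerical choices

The shipped experiments are sized for a single CPU: 200 synthetic 32x32
images, depth-3 networks at `base_width` 8, a GA budget of about 17
evaluations (population 5, 3 generations) over learning rate in
`[5e-3, 0.3]`, epochs in `[2, 8]`, batch in `[2, 16]`, with GA fitness
evaluations trained on a 24-sample subset. Under those conditions each
architecture trains to a validation IoU around 0.9–0.99 and the four-model
ensemble reaches IoU >= 0.7 in the large majority of seeds, with a clean,
verifying four-block chain. The IoU of two empty masks is defined as 1
(the 0/0 case must be pinned for tests; two empty segmentations agree).
Probabilities are computed via a numerically stable log1p-based
cross-entropy on logits; gradients were validated against central finite
differences on every operator.

## Known limitations

* The synthetic task is far easier than clinical segmentation; absolute IoU
  values here say nothing about real datasets.
* Sites share predictions, not gradients: this simulates prediction-level
  federation with provenance auditing, not federated averaging.
* The ledger is single-writer-per-append and has no consensus, mining or
  networking; it models integrity auditing, not distribution.
* HMAC signatures assume the registry's key store is trusted; there is no
  certificate authority or key rotation.
* Plain SGD diverges at high learning rates; the tuner's bounds, not the
  optimiser, are the guard rail.
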