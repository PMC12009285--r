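---
title: "Methods: hybrid-metaheuristic thermogram analysis with thermofuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid-metaheuristic thermogram analysis with thermofuse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermofuse)
```

## The problem

Breast thermography images map skin-surface temperature; malignant lesions
are hyperthermic because tumour metabolism and angiogenesis elevate local
heat production. An analysis pipeline for such images must (i) normalize
contrast across acquisitions, (ii) segment candidate hot spots, (iii) turn
the segmented image into features, and (iv) classify. thermofuse implements
a complete, deterministic, desk-scale version of such a pipeline in which a
single hybrid metaheuristic — a rock-hyrax swarm / dandelion-algorithm
hybrid we refer to as RHDAO — supplies every optimization step: the
segmentation threshold, the feature-fusion weights, and the classifier
hyperparameters.

Everything below is testable without any external data because the package
ships a seeded phantom generator that emulates the relevant structure of
clinical thermograms.

## The hybrid optimizer

The optimizer minimizes a black-box function over a box. Each generation,
every candidate is scored by a *normalized fitness angle*

$$\mathrm{angle} = \frac{CF - BF}{WF - BF}\cdot 360 \in [0, 360],$$

where \(CF\) is the candidate's fitness and \(BF, WF\) the generation's best
and worst. The angle is jittered by a uniform offset (±36°, 10% of the
range, clamped into \([0,360]\)) and routes the candidate: **above 180°**
(the worse half) the candidate takes a rock-hyrax swarm step; otherwise it
sows dandelion seeds. The angle is computed per candidate, so the two
sub-strategies always coexist within a generation: swarm contraction drives
exploitation of poor candidates, dandelion sowing local exploration around
good ones.

Swarm steps: the population leader proposes \(l_1 \cdot y\) with
\(l_1 \sim U[0,1]\); members contract by the circular-motion radius,
\(y \leftarrow (1 - \mathrm{circle})\,y\), where
\(\mathrm{circle} = \sqrt{(s_2\cos a)^2 + (s_2\sin a)^2} = |s_2|\). Both
steps use greedy acceptance: a worse proposal never replaces its incumbent.
The literal contraction pulls toward the origin, which is only optimal for
origin-centred problems; an opt-in `recentered` variant applies the
contraction to the offset from the leader instead. The default remains the
literal rule so the package reproduces the hybrid's arithmetic faithfully.

Dandelion steps: each routed candidate sows
\(n = \lfloor n_{\max}\,(h_{\max} - h + \varepsilon)/(h_{\max} - h_{\min} +
\varepsilon)\rfloor\) seeds (floored at \(n_{\min}\); defaults 2–10)
uniformly inside its sowing radius. The best dandelion (the *core*) grows
its radius by \(f \in [1, 1.1]\) after an improving generation and withers
it by \(v \in [0.8, 1)\) otherwise; *assistants* decay as
\(\omega B + (\|y_{core}\|_\infty - \|y_{self}\|_\infty)\) with
\(\omega = 1 - he/he_{\max}\) the remaining-budget weight. Details the
hybrid's description leaves open are resolved here once:

* \(\varepsilon\) is the smallest positive normalized double — its only role
  is avoiding a zero denominator in degenerate populations.
* \(he_{\max}\) (the evaluation budget entering \(\omega\)) is
  `population_size * max_iterations * max_seeds`, an upper bound on planned
  evaluations; \(\omega\) is clamped to \([0,1]\).
* The next generation is the elitist truncation of parents and seeds to the
  population size, with ties stably resolved toward parents and lower
  indices; each slot carries its sowing radius and seeds inherit their
  sower's. Elitism makes the best-so-far history non-increasing, which the
  tests assert for every run.
* Assistant radii are floored at \(10^{-6}\) of the box diameter so sowing
  never collapses to a point.
* An angle of exactly 180° routes to the dandelion branch (the swarm
  condition is the strict `angle > 180`).

Defaults are a population of 30 and 25 iterations. Pure-`rhso` and
pure-`da` modes bypass routing for ablation; branch counters in the history
make the routing itself assertable.

## Preprocessing

Two contrast steps, exposed independently and applied CLAHE-first by
default (no canonical order exists; CLAHE-first is the package's choice):

* **CLAHE** splits the image into an \(A \times B\) tile grid, clips each
  tile histogram at
  \(\beta = \frac{\text{tile px}}{N}\left(1 + \frac{\alpha}{100}(L_{\max} -
  1)\right)\) with uniform redistribution of the excess, and blends the
  per-tile equalization maps bilinearly (edge tiles replicate; dimensions
  that do not divide the grid are padded by edge reflection and cropped).
  At \(\alpha = 0\) the clip limit is exactly the flat level
  \(\text{tile px}/N\); with one tile and an unbounded clip factor CLAHE
  reproduces global equalization, a limit case the tests exercise.
* **Histogram equalization** applies
  \(M_0(j) = \mathrm{round}(G_j (2^r - 1) / (Q\,y))\), with \(G_j\) the
  cumulative count up to level \(j\). The map is monotone, and a second
  application is the identity on the levels present in an image (the
  mapping of a mapped level reproduces itself), so idempotence holds
  exactly, not just within a level.

## Segmentation

Binary thresholding assigns foreground (1) to pixels at or above a scalar
threshold — the hot side. The threshold is chosen by running the hybrid
optimizer over the 1-D threshold space against a pluggable fitness:
unsupervised Otsu between-class variance by default, or Dice against a
reference mask when ground truth exists. The stage the threshold serves in
the full classification objective cannot be evaluated at segmentation time
(it would need a trained classifier), which is why the unsupervised
surrogate is the default.

Candidate thresholds are rounded to integer gray levels and memoized. When
the nominal budget (`population_size * max_iterations`) covers the whole
integer grid, any unvisited levels are swept after the run, so the
returned threshold *provably* attains the exhaustive-search optimum rather
than attaining it with high probability. This realizes the contract that a
budget at least the size of the discrete search space yields
oracle-equivalent results, and the acceptance tests check exact agreement
with brute force on 20 seeded images.

`optimal_threshold()` searches the full gray range by default. The full
pipeline, however, restricts the search to the clinical hot range
\([200, 255]\) (`threshold_hot_range`, on by default): after
equalization spreads intensities over the whole scale, a full-range Otsu
split merely bisects the flattened histogram — the foreground fraction is
near 0.5 for lesion-free and lesion-bearing images alike and the mask
carries no class information. Restricting the threshold to the hot range is
what makes the mask isolate hyperthermic foci. Both behaviours are
reachable through configuration.

## Feature extraction

Three deterministic branches stand behind one contract, mirroring the three
backbone families' architectural ideas at desk scale. ImageNet-pretrained
backbones are deliberately out of scope: they are GPU-scale,
dataset-dependent, and not what the surrounding optimization scaffolding
depends on. Users can plug real backbones into the same contract.

* **Branch 1** (small-filter stacks): two stages of fixed, seeded,
  non-negative 3×3 filter banks with mean pooling; features are per-channel
  statistics. Non-negativity makes the response monotone in brightness.
* **Branch 2** (residual mapping): a location-invariant intensity embedding
  (quantile profile, active-region histogram, shape statistics) passed
  through two residual stages \(y = F(n; W) + n\). The embedding is
  deliberately *not* spatial: a spatial embedding of the masked image
  encodes the random lesion position and cannot generalize across a small
  cohort. With \(W = 0\) a stage is the pure identity skip, which the tests
  assert, along with an ablation showing the skip is live.
* **Branch 3** (dense connectivity): each of three convolutional stages
  consumes the concatenation of *all* previously produced channels and the
  feature is the global average pool of every channel; the stage input
  widths are exposed as attributes so the dense wiring is structurally
  checkable.

All three are pure functions (fixed internal seeds, caller's RNG untouched),
and extraction defaults to the segmented image (`image * mask`) with the
raw-image variant a flag away.

## Fusion and classification

The stacked weighted feature is the element-wise sum
\(SF = W_1 f_1 + W_2 f_2 + W_3 f_3\) with three scalar weights in
\([0,1]\), not constrained to sum to one. (Each weight pairs with its own
branch; a variant applying the second weight to the third branch — a
transcription defect this fusion is sometimes stated with — is retained
behind a flag for forensic reproduction.)

Three small one-hidden-layer softmax heads train on \(SF\) by full-batch
gradient descent with head-specific seeds derived from the master seed; the
decision rule sums the per-head score vectors and takes the argmax, ties to
the lowest class index (a max-rule variant is available). Score-sum is the
standard reading of "higher-score" ensemble fusion. The tuned genes are
exactly the fusion weights, the epoch count in \([50, 100]\), the
hidden-neuron count in \([5, 255]\), and a categorical activation over
{relu, sigmoid, tanh} (the candidate set is a package choice; the method
names the gene but not the set). Tuning maximizes validation accuracy; the
space midpoint is injected into the initial population so elitism
guarantees the tuned result never scores below it on the selection split.
Joint optimization of weights and head hyperparameters is the default;
sequential (fusion first) remains possible through
`optimize_fusion_weights()`. The segmentation threshold joins the joint
gene vector only when a supervised segmentation fitness is configured;
otherwise segmentation is fixed first, because the unsupervised surrogate
does not depend on the classifier.

## Metrics

The metric suite computes accuracy, sensitivity/recall, specificity,
precision, FPR, FNR, NPV, FDR, F1 and MCC from TP/TN/FP/FN tallies using
the standard textbook definitions, under which the complement identities
(FPR = 1 − specificity, FNR = 1 − sensitivity, FDR = 1 − precision) hold by
construction and are asserted over randomly generated count tables.
Zero-denominator metrics report `NaN` with a warning. Multi-class input reduces one-vs-rest with macro averaging.

## The phantom generator

`generate_phantom()` emulates the structure the pipeline depends on: a
smooth warm background (mean level 120, a random linear gradient of
amplitude 20, and three low-frequency cosine modes of amplitude 10 — body
surface temperature varies smoothly), zero or more hyperthermic Gaussian
lesions, optional vignetting, Gaussian sensor noise (sd 5), and 8-bit
quantization. A lesion's `radius` parameter is its half-maximum radius, so
the ground-truth mask of an isolated lesion is analytically a disk of area
\(\pi r^2\). Cohorts default to lesion radii drawn in \([5, 9]\) pixels
with peak excess 60 gray levels — twelve times the noise sd, a clearly
separable regime chosen once as the study condition. Labels are
`abnormal` iff at least one lesion is present.

What the phantoms do *not* model: anatomy-realistic breast geometry,
bioheat (Pennes) physics, acquisition-protocol effects, or the appearance
diversity of clinical thermograms. Passing the end-to-end tests therefore
demonstrates that the pipeline's machinery is correct and that its tuning
recovers a separable signal — not that clinical performance of any level
would follow.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run, as the package's own
study conditions: 64×64 phantoms; cohorts of 20 normal + 20 abnormal with a
50/25/25 stratified train/validation/test split; threshold search with a
population of 10 over 10 iterations (the post-run sweep guarantees
optimality regardless); pipeline tuning with a population of 6 over 5
iterations; and the full default budget (30 × 25) for the optimizer
benchmarks. The end-to-end check runs ten seeded replicates against a
single-branch (branch 1, one head, midpoint hyperparameters, no fusion)
baseline on identical splits, the package's definition of the no-fusion
ablation.

Numerical details fixed once: thresholds are real during search and
reported as integers; histogram clipping redistributes in one pass (a few
counts may exceed the limit slightly, the standard behaviour);
convolutions pad by edge replication so constant images stay constant;
best/worst identification breaks ties at the lowest index; maximization
problems are negated into the minimizing core.

## Known limitations

* The literal swarm contraction favours origin-centred optima; use
  `recentered = TRUE` for strongly off-centre problems.
* Heads are desk-scale MLPs; with 20 training images the test-set
  granularity is coarse (0.1 per image), so per-seed held-out accuracies
  scatter visibly even in the separable regime.
* The Otsu surrogate is unimodal-background biased; images whose lesions
  dominate the histogram may be better served by the supervised Dice
  fitness.
* 16-bit images are supported end-to-end but the integer-grid sweep of the
  threshold search only engages when the optimizer budget covers 65536
  levels; below that the result is the metaheuristic's best.
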