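---
title: "Multi-scale graph representation learning for functional connectivity networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale graph representation learning for functional connectivity networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgrl)
```

## The problem

Resting-state fMRI yields, for each subject, one mean BOLD time series per
brain region of interest (ROI). The pairwise statistical dependence between
ROI series defines a functional connectivity network (FCN): a weighted graph
with ROIs as nodes. The number of nodes depends entirely on which atlas is
used to parcellate the brain — a coarse anatomical atlas gives ~116 regions,
a finer functional one ~200 — and the topology of the resulting network
differs across these spatial scales. Classifying subjects (e.g. autism
spectrum disorder cases versus controls) from a single-scale FCN discards
whatever complementary structure the other scale carries. This package
implements a multi-scale graph representation learning pipeline that learns
a graph-level representation per scale with a spectral graph convolutional
network (GCN), fuses the per-scale representations, and classifies; it also
implements the classical handcrafted-feature baselines and the evaluation
protocol needed to compare them fairly.

## The model

**Graph construction.** For a subject's time-series matrix $S \in
\mathbb{R}^{t \times n}$ (columns $s_i$), edge weights are Pearson
correlations

$$e_{ij} = \frac{(s_i-\bar s_i)^\top (s_j-\bar s_j)}
{\sqrt{(s_i-\bar s_i)^\top (s_i-\bar s_i)}\sqrt{(s_j-\bar s_j)^\top (s_j-\bar s_j)}}.$$

Node $i$'s feature vector is its *signed* connectivity profile
$(e_{i1},\dots,e_{in})$, so the feature matrix is $X = (e_{ij})$; the
adjacency takes magnitudes, $A = (|e_{ij}|)$, reading both positive
(facilitating) and negative (inhibiting) correlations as connection
strength. An alternative estimator is available via L1-penalised sparse
representation (each ROI regressed on all others, coefficients symmetrised
as $(|W|+|W^\top|)/2$), which produces much sparser networks. Either
estimator can be further sparsified by proportional thresholding: keep the
top $\lceil f \cdot n(n-1)/2 \rceil$ edges by magnitude, zero the rest.

**Graph convolution.** Each scale gets an independent two-layer GCN using
the first-order propagation rule with self-loops,
$\hat A = \tilde D^{-1/2}(A + I)\tilde D^{-1/2}$:

$$f(X, A) = \mathrm{ReLU}\!\left[\hat A\, \mathrm{ReLU}(\hat A X W^{(0)})\, W^{(1)}\right] \in \mathbb{R}^{n \times 32},$$

with 32 channels in both layers. (The forward formula is sometimes written
with the un-normalised self-looped adjacency; we use the normalised
operator throughout — that is the form under which the one-layer rule is
derived, and the un-normalised variant diverges numerically for dense
weighted graphs.)

**Readout and fusion.** Node embeddings are aggregated order-invariantly by
concatenating the column mean and the column maximum, giving a 64-length
graph representation per scale. The per-scale representations are
concatenated (128 for two scales) and passed through three fully-connected
layers (widths 128, 32, 16, first width equal to the fused length) and a
final two-neuron softmax layer. A fusion ratio $\alpha$ generalises the
equal treatment: block $k$ is rescaled by $K\alpha_k$ before concatenation,
which is differentiable and reduces to plain concatenation at
$\alpha_k = 1/K$.

**Baselines.** Single-scale variants reuse the same convolution and readout
with a narrower head (64, 16, 8). The handcrafted baselines replace
representation learning with per-node network statistics — weighted degree
(strength), Onnela geometric-mean local clustering, and closeness
centrality with reciprocal-weight edge lengths — concatenated across scales
(116 + 200 = 316 features) into the same style of head (316, 32, 16,
dropout 0.2).

## Training and evaluation protocol

All models train with Adam (learning rate 0.01, L2 regularisation
$10^{-5}$), cross-entropy loss, 50 epochs, dropout on the fully-connected
hidden layers only (0.5 for graph models, 0.2 for baselines). The paper
this architecture follows does not state a batch size; we use shuffled
mini-batches of 16, the conventional small-cohort recipe (`batch_size =
NULL` restores full-batch steps). Convolution layers carry no biases; the
head layers do.

Model selection: within the 50 epochs we keep the parameter snapshot with
the highest validation accuracy, resolving ties toward the later epoch.
Nothing else about training is adaptive.

Evaluation repeats an unstratified random 80/10/10 split (sizes
$\lfloor 0.8n \rfloor / \lfloor 0.1n \rfloor /$ remainder); a repetition
whose train, validation, or test part lacks a class is redrawn and logged.
The identical split index sets — and identical per-repetition training
seeds — are consumed by every method under comparison. Metrics per
repetition: accuracy, recall, precision, F1 (case class = label 1
positive), and AUC by the midrank statistic (ties count one half); a
single-class test set yields a missing AUC that is excluded from the mean
and counted. Two ablation sweeps rebuild this protocol across edge
retention fractions $\{1.0, 0.9, 0.8, 0.7, 0.6\}$ and across fusion ratios
$\{0.1, \dots, 0.9\}$. Performance need not be monotone in retention.

## The synthetic cohort generator

Real multi-site rs-fMRI cohorts are access-restricted, so the package ships
a generator whose cohorts exercise every pipeline stage:

- **Fine scale.** Each subject's $175 \times 200$ series is drawn from a
  zero-mean multivariate normal. Controls use a block-modular base
  covariance (unit variances, within-module covariance 0.3, ~20 ROIs per
  module — a crude stand-in for functional communities); cases add a signed
  perturbation of magnitude `effect_size` (default 0.6) to a seeded random
  `effect_edge_fraction` (default 0.1) of off-diagonal entries. Perturbed
  matrices are projected back to positive-definiteness by eigenvalue
  clipping at $10^{-4}$. I.i.d. Gaussian observation noise (`noise_sd`,
  default 0.5) is added; since Pearson correlation is scale-invariant,
  amplitude heterogeneity is deliberately not modelled.
- **Coarse scale.** The 116 coarse ROIs are exact means of disjoint
  contiguous blocks of the observed fine series (block boundaries seeded
  per cohort). Both scales therefore view the same underlying activity —
  the redundancy-plus-complementarity structure that makes multi-scale
  fusion meaningful — rather than being independent simulations.
- **Determinism.** Every random stage (modules, effect edges, labels,
  grouping, subject noise, splits, initialisation, dropout, batching) draws
  from a named substream derived from one root seed, so cohorts and whole
  protocol runs are bit-reproducible.

What the generator does **not** emulate: hemodynamic response dynamics,
temporal autocorrelation, site and scanner effects, realistic atlas
geometry, or head-motion artefacts. Tests passing on these cohorts
demonstrate that the pipeline recovers planted covariance differences under
Gaussian assumptions — not that any particular accuracy is attainable on
real clinical data.

## Numerical choices

- Proportional-threshold ties at the retention boundary break by
  (|weight| descending, row, column), making sparsification deterministic.
  Thresholding is applied to the connectivity before both $X$ and $A$ are
  formed, so removed edges vanish from features and adjacency alike, and it
  operates per subject on magnitudes.
- Sparse representation solves $\tfrac{1}{2t}\|s_i - S_{-i}w\|^2 +
  \lambda\|w\|_1$ on z-scored columns by cyclic coordinate descent
  (convergence tolerance $10^{-10}$); sparsity is monotone in $\lambda$.
- Closeness on disconnected graphs uses the component-scaled
  (Wasserman–Faust) form, $\frac{n_i-1}{n-1}\cdot\frac{n_i-1}{\sum d}$,
  with isolated nodes at 0 — no infinities after aggressive thresholding.
- Weights initialise Glorot-uniform from a seeded stream. Softmax is
  computed with row-max shifting; cross-entropy clamps probabilities at
  $10^{-12}$.
- AUC uses midranks, identical to the all-pairs probability of correct
  ranking.
- Handcrafted features are z-scored with training-split statistics before
  entering the baseline head (the transform is stored in the fit and
  re-applied at prediction). Node strength sums hundreds of edge weights
  and its raw scale saturates a freshly initialised softmax head;
  correlation-valued GCN inputs already live in $[-1, 1]$ and are left
  unscaled.

## Problem sizes used by the test-suite

Unit and property tests run on small cohorts (8–40 subjects, 10–30 ROIs).
The parameter-recovery check runs the full study-scale condition — 200
subjects, 175 time points, 200/116 ROIs, covariance effect 0.6 on 10% of
fine-scale edges, 20 protocol repetitions — once for the planted-effect
cohort (expected mean test accuracy at least 0.85) and once for a null
cohort (expected pooled accuracy inside the central 99% binomial band
around 0.5). Oracle comparisons use 20–50 random instances per estimator;
algebraic GCN properties are checked on 100 random instances.

## A worked example

```{r example, eval = FALSE}
library(mgrl)

cohort <- generate_cohort(cohort_spec(n_subjects = 60, seed = 1))
graphs <- cohort_graphs(cohort, method = "pearson")

result <- run_protocol(
  graphs,
  methods = c("mgrl", "gcn_coarse", "gcn_fine", "dcf"),
  reps    = 10,
  seed    = 1
)
glance(result)       # mean +/- SD of the five metrics per method
autoplot(result)     # pooled ROC curves

sweep <- sparsity_sweep(cohort, retain = c(1, 0.8, 0.6), reps = 5, seed = 1)
autoplot(sweep)
```

## Known limitations

- The trainer is plain R matrix algebra: fast enough for hundreds of
  subjects at atlas scale on one core, but not for thousands of subjects or
  voxel-level graphs.
- Graphs within one scale must share a node count; batching across
  variable-size graphs at a single scale is unsupported.
- Fusion is concatenation with fixed ratio weights; attention-style
  adaptive fusion is out of scope.
- The spectral background (explicit Laplacian eigendecomposition, Fourier
  form of the convolution) is intentionally never computed — only the
  first-order propagation rule is used.
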