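# mgrl — multi-scale graph representation learning for functional connectivity networks

Functional MRI studies represent each subject as a functional connectivity
network (FCN): brain regions of interest (ROIs) are nodes, and the Pearson
correlation between two ROIs' BOLD time series is the edge weight. How many
nodes that graph has depends on the parcellation atlas — a coarse anatomical
atlas yields ~116 ROIs, a finer functional one ~200 — and networks built at
different spatial scales carry complementary topology. This package is for
researchers who want to classify subjects (e.g. autism spectrum disorder
cases versus controls) from FCNs at **multiple scales jointly**, and to
compare that against single-scale and handcrafted-feature baselines under a
rigorous repeated-split protocol — all runnable end-to-end on a built-in
synthetic cohort generator with planted class effects.

## The model

For a subject with time-series matrix `S ∈ R^(t×n)` (columns `s_i`), edge
weights are

    e_ij = (s_i − s̄_i)ᵀ(s_j − s̄_j) / ( ‖s_i − s̄_i‖ · ‖s_j − s̄_j‖ )

Node features keep the signed profile, `X = (e_ij)`; the adjacency takes
magnitudes, `A = (|e_ij|)`. Each scale gets an independent two-layer
spectral graph convolution with the normalised self-looped propagation
`Â = D̃^(−1/2)(A+I)D̃^(−1/2)`:

    f(X, A) = ReLU( Â · ReLU( Â X W⁽⁰⁾ ) · W⁽¹⁾ )   ∈ R^(n×32)

A mean-and-max readout concatenates column means and maxima into a
64-length graph representation per scale; per-scale representations are
concatenated (128 for two scales, optionally ratio-weighted) and classified
by three fully-connected layers (128, 32, 16; ReLU, dropout 0.5) and a
softmax layer. Training: Adam, learning rate 0.01, L2 regularisation 1e-5,
cross-entropy, 50 epochs, best-validation-accuracy checkpoint.

Baselines implemented under the identical protocol: single-scale GCNs
(head 64, 16, 8) and handcrafted node statistics — weighted degree
(strength), Onnela local clustering, closeness centrality with
reciprocal-weight distances — fused across scales (116 + 200 = 316
features) into a 316/32/16 head with dropout 0.2. Ablations: proportional
edge-retention sweep (100%…60%) and fusion-ratio sweep (0.1…0.9).

## Worked example

```r
library(mgrl)

# 60 subjects, 175 time points, 200 fine / 116 coarse ROIs, covariance
# perturbation 0.6 on 10% of fine-scale edges in the case class
cohort <- generate_cohort(cohort_spec(n_subjects = 60, seed = 1))
graphs <- cohort_graphs(cohort, method = "pearson")

result <- run_protocol(
  graphs,
  methods = c("mgrl", "gcn_coarse", "gcn_fine", "dcf"),
  reps    = 10,
  seed    = 1
)
as.data.frame(glance(result))[, c("method", "accuracy_mean", "accuracy_sd",
                                  "auc_mean", "auc_sd", "f1_mean")]
```

```
      method accuracy_mean accuracy_sd auc_mean auc_sd f1_mean
1        dcf         1.000      0.0000        1      0   1.000
2 gcn_coarse         0.983      0.0527        1      0   0.989
3   gcn_fine         1.000      0.0000        1      0   1.000
4       mgrl         1.000      0.0000        1      0   1.000
```

Each row summarises 10 repetitions of an 80/10/10 random split shared by
every method: mean and SD of test accuracy, area under the ROC curve, and
F1. The planted effect here is strong, so the multi-scale model, both
single-scale variants, and even the degree-strength baseline separate the
classes essentially perfectly; weaker `effect_size` settings pull the
methods apart. `tidy(result)` exposes per-repetition metrics and confusion
counts, `autoplot(result)` draws the pooled ROC curves, and
`sparsity_sweep()` / `fusion_ratio_sweep()` produce the ablation tables
(`autoplot()` plots them).

A thin command-line wrapper with the same functionality ships at
`inst/cli/mgrl` (subcommands `simulate`, `build-graphs`, `baseline`,
`compare`, `sweep`).

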