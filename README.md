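# sitecollapse

Per-residue prediction of protein–protein interaction sites (PPIS) with an
E(n)-equivariant graph neural network, adaptive structure-aware pooling, and
four-stage graph collapse/unpooling — plus a six-model feature-group ensemble
stacked under a logistic meta-model.

## Who this is for

Structural bioinformaticians who want a fully tested, pure-R reference
implementation of the equivariant collapse-pooling architecture for
residue-level interface prediction: every stage (contact graph, equivariant
layer, pooling, collapse routing, training schedule, ensemble) is exposed as
a documented function with loop-based oracle tests, and a synthetic protein
generator makes the whole pipeline runnable without external structure or
profile data.

## The model in brief

Residues are nodes of a contact graph: `A[i,j] = 1` iff the Cα distance is
at most *t* = 14 Å. An equivariant layer updates scalars and coordinates
jointly,

    m_ij  = phi_e(h_i, h_j, |x_i - x_j|^2)
    x_j' = x_j + C_j * sum_i (x_j - x_i) * phi_x(m_ij)
    h_j' = h_j + phi_h(h_j, C_j * sum_i m_ij),        C_j = 1/(N_j - 1)

so probabilities are invariant and coordinates equivariant under rigid
transforms. Adaptive structure-aware pooling scores each node through soft
hop-1 clusters, master-to-token additive attention and local-extreme
convolution, keeping the top 30%. Each of 8 blocks then routes messages in
four stages — full graph, neighbourhoods→hubs, hubs↔hubs, hubs→neighbourhoods
(the exact transpose) — so distant residues communicate through sampled hubs
in a single block. Training is Adam + cross-entropy with a plateau learning-
rate schedule (×0.6 after 10 stagnant epochs of validation AUPRC, floor
1e-6). Six base models (handcrafted 62-d, four 320-d language-model chunks,
all 1342-d) are stacked residue-wise into a logistic meta-model.

There is no deep-learning framework underneath: the package carries its own
small reverse-mode autodiff tape over dense matrices, with every gradient
tested against finite differences.

## A worked example

```r
library(sitecollapse)

# six synthetic proteins with density-linked interface labels and
# learnable feature signal
ds  <- generate_dataset(6, c(25, 40), seed = 11, signal_strength = 0.9)
cfg <- model_config(n_layers = 2, hidden_dim = 16, epochs = 20,
                    learning_rate = 2e-3, seed = 1)
fit <- train(ds[1:5], cfg, val_dataset = ds[6])
fit
#> <sc_model: handcrafted features (62-d), 2 blocks x 16 hidden;
#>   20 epochs, final loss 0.0005, val AUPRC 1.000>

pred <- predict(fit, ds[6])
evaluate(ds[[6]]$labels, pred$prob)
#> # A tibble: 1 × 11
#>     ACC Precision Recall    F1   MCC AUROC AUPRC    TP    TN    FP    FN
#>   <dbl>     <dbl>  <dbl> <dbl> <dbl> <dbl> <dbl> <int> <int> <int> <int>
#> 1  0.88         1   0.25   0.4 0.468     1     1     1    21     0     3
```

The held-out protein has 25 residues, 4 of them interface sites. After 20
epochs on five training proteins the ranking is perfect (AUROC = AUPRC = 1:
every interface residue scores above every non-interface residue), while the
hard 0.5 threshold is conservative — 1 of the 4 sites called, none falsely.
That gap between ranking and thresholded calls is exactly why AUPRC, not
accuracy, is the headline metric for this class balance. `tidy(fit)` returns the
per-epoch log, `autoplot(fit)` draws it, and `ensemble_train()` /
`predict()` run the six-model stacked ensemble the same way.

A thin CLI over the same functions lives at `inst/cli/sitecollapse.R`
(`simulate`, `build-graph`, `train`, `predict`, `evaluate`).

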