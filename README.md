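# mvgdecode

Zero-shot neural decoding asks which image category a person was viewing
from fMRI activity evoked by categories that were **never part of the
paired training data**. Because fMRI is expensive, paired training sets are
small and cover a biased slice of all categories, so mappings learned from
brain activity into visual/semantic embedding spaces misplace novel target
categories — the *projection domain shift* problem. `mvgdecode` implements
a semi-supervised multi-view generative model that counters this by folding
in additional visual and semantic features of target-related images for
which no brain activity exists, treating the unobserved brain responses as
missing data.

The package is aimed at computational neuroscientists who want a fully
probabilistic, reproducible reference implementation of this model family
(Bayesian CCA and its multi-view, semi-supervised extensions) together with
the decoding metrics of that literature, plus a synthetic benchmark
generator for method development when no fMRI dataset is at hand.

## Model

Three views — brain activity `x^(f)` (D_f voxels), visual features `x^(v)`
and semantic features `x^(s)` — are generated from a shared latent variable
`z ∈ R^{D_z}`:

    x_n^(k) | W^(k), z_n  ~  N(W^(k) z_n,  β_k⁻¹ I),      k ∈ {f, v, s}
    z_n ~ N(0, I),   W_ij^(k) ~ N(0, α_ij^(k)⁻¹),   α_ij^(k) ~ Gamma

The element-wise Gamma hyperpriors implement automatic relevance
determination (ARD), shrinking loadings that the data do not support. For
`M` additional samples only `x^(v)` and `x^(s)` are observed; the missing
brain columns `X_miss^(f)` are treated as latent and imputed as posterior
means. All factors — `q(W^(k))`, `q(Z)`, `q(X_miss^(f))`, `q(α^(k))`,
`q(β_k)` — are updated by mean-field coordinate ascent (10 sweeps by
default, matching the protocol the model family is reported with).

At test time the latent posterior is inferred from brain activity alone,

    Σ_z,test = β_f (W̄^(f)ᵀ W̄^(f) + V^(f)) + I,
    z̄_test  = β_f Σ_z,test⁻¹ W̄^(f)ᵀ x_test^(f),

pushed through each feature view (`x̄^(i) = W̄^(i) z̄_test`), optionally
averaged over an ensemble of `T` random restarts, and scored against every
candidate category by Pearson correlation, blended across views as

    r^(v+s) = η · r^(v) + (1 − η) · r^(s),      η ∈ [0, 1].

The decoded category is the argmax; reported metrics are pairwise
(two-alternative) identification accuracy (chance 50%) and rank-n accuracy
over C candidates (chance n/C).

## Worked example

```r
library(mvgdecode)

truth <- sample_ground_truth(seed = 1)            # true loadings, prototypes
bench <- sample_dataset(truth, seed = 2)          # zero-shot split benchmark
std   <- standardize_bundle(bench$dataset, bench$test, bench$candidates)

fit   <- mvg_fit(std$dataset, model_config(latent_dim = 5, seed = 3))
print(fit)
#> Variational state: views {brain, visual, semantic}, Dz=5, N=160, M=40, 10 sweep(s) logged
#>   noise precision means: brain=1.371, visual=1.101, semantic=1.075

preds <- predict_views(fit, std$test$brain)
grid  <- evaluate_decoding(preds$visual$mean, preds$semantic$mean,
                           std$test, std$candidates, rank_cutoffs = c(1, 10))
head(grid, 3)
#>   eta pairwise_accuracy mean_rank rank1_accuracy rank10_accuracy
#> 1 0.0             0.967      3.56          0.188               1
#> 2 0.1             0.965      3.69          0.188               1
#> 3 0.2             0.965      3.69          0.188               1
```

The benchmark has 160 paired samples from 20 source categories, 40 unpaired
visual/semantic samples from the 8 zero-shot target categories, and 78
candidate categories. `evaluate_decoding` reports the whole η grid: at
η = 0.8 the fitted model identifies the true target category in 96.9% of
(truth, opponent) pairs and ranks it on average 3.4 of 78. Refitting
without the unpaired block (`fit_mgm`, the supervised-only configuration)
drops the best pairwise accuracy to 92.1% on the same data — the
semi-supervised block is what rectifies the shifted projections:

```r
mgm <- fit_mgm(std$dataset, model_config(latent_dim = 5, seed = 3))
```

A command-line pipeline wrapping the same functions ships in
`inst/scripts/mvgdecode`:

```sh
Rscript inst/scripts/mvgdecode simulate --out runs --seed 5
Rscript inst/scripts/mvgdecode fit --data runs/simulate-<hash>/dataset.json --out runs --seed 11
Rscript inst/scripts/mvgdecode predict --checkpoint runs/fit-<hash> --test runs/simulate-<hash>/test.json --out runs
Rscript inst/scripts/mvgdecode evaluate --pred runs/predict-<hash> --candidates runs/simulate-<hash>/candidates.json --test runs/simulate-<hash>/test.json --out runs --metrics pairwise,rank:5
```

Every run directory is named by a hash of its configuration and carries the
seed and configuration echoed into its JSON outputs.

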