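# rpemhc

Pan-specific prediction of MHC–peptide binding affinity from a
residue–residue pair encoding.

## What this is for

Whether a peptide binds a given MHC molecule gates antigen presentation
to T cells, and predicting that binding from sequence is a daily task in
epitope discovery and vaccine design. `rpemhc` is for computational
immunologists who need a *pan-specific* class II (and class I) affinity
predictor they can train, evaluate and dissect on their own data: a
single model covers all alleles — including unmeasured ones — by
conditioning on each allele's 34-residue binding-groove pseudo-sequence.

The core idea is the input encoding. Instead of feeding the MHC and the
peptide to the network separately, every (MHC residue, peptide residue)
pair is mapped to its own integer code over the 21-symbol alphabet (20
amino acids + `X`),

    code(a_i, b_j) = (i − 1)·21 + j   ∈ {1, …, 441},

so one MHC–peptide pair becomes a 34 × 20 integer interaction matrix
(rows: pseudo-sequence positions; columns: peptide positions padded or
truncated to 20; ordered pairs ⟨a,b⟩ and ⟨b,a⟩ get different codes). An
embedding layer, a (34, 1) convolution fusing the whole MHC axis onto
each peptide position, multi-scale CNN stages (kernels 1/3/5 with
32/64/128 filters, then 1/3/5/7 with 128/256/512/1024), two parallel
LSTM blocks, and a final kernel-9 convolution — the binding-core
width — feed a sigmoid head predicting the transformed affinity

    y = 1 − log(IC50)/log(50000)  ∈ [0, 1],

trained by mean squared error, with the conventional 500 nM binder
threshold (y ≈ 0.4256) for classification metrics. The network's
forward and backward passes are implemented in RcppArmadillo; no deep
learning framework is required.

Around the model the package provides the full working apparatus:
affinity-table / pseudo-sequence / FASTA ingestion, allele-stratified
cross-validation and leave-one-molecule-out (LOMO) protocols, 20-model
ensembling, a metric suite (AUC, PRC, PCC, PPV, F1, sensitivity,
per-molecule reports, the Frank epitope-ranking value), sliding-window
binding-core localisation, motif frequency-matrix extraction from random
peptides, a planted-motif synthetic data generator with known ground
truth, and a CLI (`simulate`, `train`, `crossval`, `lomo`, `predict`,
`evaluate`, `core`, `motif`).

## Worked example

Simulate a two-allele world with planted 9-mer core motifs, train a
small model, evaluate held-out records and localise a binding core
(about 90 seconds on one core):

```r
library(rpemhc)

world   <- make_world(n_alleles = 2, seed = 42)
dataset <- sample_dataset(world, n_per_allele = 1000, seed = 43)

set.seed(44)
test_idx <- sample(nrow(dataset), 400)
fit <- fit_affinity_model(dataset[-test_idx, ], world$alleles,
                          model_config(scale_factor = 0.1),
                          train_spec(epochs = 15, seed = 45))
glance(fit)
#> # A tibble: 1 × 6
#>   n_params n_alleles epochs_trained train_loss best_val_loss  seed
#>      <int>     <int>          <int>      <dbl>         <dbl> <int>
#> 1    57958         2             15     0.0194        0.0278    45

pred <- predict(fit, dataset[test_idx, ])
compute_metrics(dplyr::mutate(pred, y_true = y))
#> # A tibble: 1 × 9
#>       n n_binders   auc   prc   pcc   ppv    f1 sensitivity reason
#>   <int>     <int> <dbl> <dbl> <dbl> <dbl> <dbl>       <dbl> <chr>
#> 1   400       261 0.878 0.932 0.720 0.861 0.844       0.828 <NA>

strong <- pred[which.max(pred$.pred), ]
predict_core(fit, strong$allele, strong$peptide)
#> <core_prediction> SYN-02 PQTASHYWNLFGWYISAGQE
#>   core SHYWNLFGW at offset 4 (12 windows)
```

Reading the output: the held-out AUC (0.878) says the model ranks
binders above non-binders under the 500 nM threshold; the PCC (0.720)
measures agreement with the continuous transformed affinity; and the
core prediction marks the 9-mer window whose standalone score is
highest — here offset 4 of a 20-mer, scanned over all 12 windows. At the
full study conditions used by the acceptance pipeline (3 alleles × 2000
records, quarter-scale model, 15 epochs) the same numbers reach about
0.95 AUC / 0.89 PCC, with ~64% of held-out binders' planted core offsets
recovered exactly and the motif's four highest-information positions
landing on the planted anchors 1, 4, 6, 9.

The same pipeline from a shell:

```sh
inst/cli/rpemhc simulate --out sim --n-alleles 2 --n-per-allele 1000 --seed 42
inst/cli/rpemhc train --affinities sim/affinities.tsv \
    --pseudo sim/pseudosequences.tsv --out run --scale 0.1 --epochs 15
inst/cli/rpemhc predict --checkpoint run/checkpoint.rds \
    --input sim/affinities.tsv --out pred
inst/cli/rpemhc evaluate --predictions pred/predictions.tsv --out eval
```

Every run writes a `manifest.json` sufficient to re-run it.

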