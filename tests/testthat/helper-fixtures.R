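# Shared fixtures. Training runs are cached in this environment so that
# expensive fits are performed once per test session and reused across
# test files.
.fixtures <- new.env(parent = emptyenv())

std_residues <- function() amino_alphabet()[1:20]

random_pseudo <- function(n = 1L) {
  replicate(n, paste(sample(std_residues(), 34L, replace = TRUE), collapse = ""))
}

random_peptide <- function(len) {
  paste(sample(std_residues(), len, replace = TRUE), collapse = "")
}

# two-allele map for encoder/model unit tests
tiny_pseudo_map <- function(seed = 42L) {
  set.seed(seed)
  tibble::tibble(allele = c("A1", "A2"), pseudo = random_pseudo(2))
}

# deliberately small topology for fast structural tests
tiny_config <- function(...) {
  model_config(scale_factor = 0.05, embedding_dim = 8L, ...)
}

# single fit at the synthetic-world study conditions (3 alleles x 2000
# records, noise sd 0.05, quarter-scale model, one member), shared by the
# learnability, core-recovery and motif checks
trained_world_fixture <- function() {
  if (!is.null(.fixtures$world_fit)) return(.fixtures$world_fit)
  world <- make_world(seed = 101L)
  dataset <- sample_dataset(world, n_per_allele = 2000L, seed = 102L)
  set.seed(103L)
  test_idx <- sample(nrow(dataset), floor(0.2 * nrow(dataset)))
  fit <- fit_affinity_model(
    dataset[-test_idx, ], world$alleles,
    model_config(scale_factor = 0.25),
    train_spec(epochs = 15L, seed = 104L))
  .fixtures$world_fit <- list(world = world, dataset = dataset,
                              test_idx = test_idx, fit = fit)
  .fixtures$world_fit
}

# brute-force AUC: all positive/negative pairs, ties count one half
oracle_auc <- function(score, label) {
  pos <- score[label == 1L]
  neg <- score[label == 0L]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# brute-force average precision by descending-threshold enumeration
oracle_average_precision <- function(score, label) {
  thresholds <- sort(unique(score), decreasing = TRUE)
  n_pos <- sum(label == 1L)
  ap <- 0
  prev_tp <- 0
  for (th in thresholds) {
    keep <- score >= th
    tp <- sum(label[keep] == 1L)
    precision <- tp / sum(keep)
    ap <- ap + precision * (tp - prev_tp)
    prev_tp <- tp
  }
  ap / n_pos
}
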