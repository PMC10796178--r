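test_that("channel counts and shapes follow the stated topology", {
  cfg <- model_config()  # full scale
  expect_equal(cfg$conv1_c, c(32L, 64L, 128L))
  expect_equal(sum(cfg$conv1_c), 32L + 64L + 128L)
  expect_equal(cfg$conv2_c, c(128L, 256L, 512L, 1024L))
  expect_equal(sum(cfg$conv2_c), 128L + 256L + 512L + 1024L)
  expect_equal(cfg$final_k, 9L)
  # valid kernel-9 convolution over the length-20 axis leaves 12 positions
  n_out_pos <- cfg$peptide_len - cfg$final_k + 1L
  expect_equal(n_out_pos, 12L)
  shapes <- rpemhc:::param_shapes(cfg)
  expect_equal(shapes$emb, c(442L, 16L))                    # 441 pairs + pad
  expect_equal(shapes$fuse_W[1], 34L * 16L)                 # full MHC-axis contraction
  expect_equal(shapes$c2_W_4, c(1024L, (32L + 64L + 128L) * 7L))
  expect_equal(shapes$fc_W[2], cfg$final_c * 12L)
})

test_that("parameter count is a deterministic function of the config", {
  cfg <- model_config()
  n <- n_params(cfg)
  # frozen value for the default configuration
  expect_equal(n, 3822593L)
  params <- rpemhc:::init_params(cfg, 1)
  realized <- sum(vapply(params, length, numeric(1))) -
    cfg$embedding_dim  # frozen pad row
  expect_equal(realized, n)
  expect_identical(n_params(model_config()), n)
  # scaling changes counts monotonically
  expect_lt(n_params(model_config(scale_factor = 0.25)), n)
})

test_that("predictions lie strictly inside (0, 1) for arbitrary inputs", {
  set.seed(11)
  pm <- tiny_pseudo_map()
  mod <- new_affinity_predictor(tiny_config(), pm, seed = 3)
  nd <- tibble::tibble(
    allele = sample(pm$allele, 40, replace = TRUE),
    peptide = vapply(sample(9:25, 40, replace = TRUE), random_peptide, character(1)))
  p <- predict(mod, nd)$.pred
  expect_length(p, 40)
  expect_true(all(p > 0 & p < 1))
})

test_that("batch composition does not change predictions", {
  set.seed(12)
  pm <- tiny_pseudo_map()
  mod <- new_affinity_predictor(tiny_config(), pm, seed = 5)
  nd <- tibble::tibble(
    allele = sample(pm$allele, 32, replace = TRUE),
    peptide = vapply(sample(13:25, 32, replace = TRUE), random_peptide, character(1)))
  whole <- predict(mod, nd)$.pred
  singly <- vapply(seq_len(32), function(i) predict(mod, nd[i, ])$.pred, numeric(1))
  expect_lt(max(abs(whole - singly)), 1e-6)
  # order preserved, duplicates identical
  dup <- predict(mod, nd[c(1, 1, 2), ])$.pred
  expect_equal(dup[1], dup[2])
})

test_that("the model is sensitive to the MHC pseudo-sequence", {
  set.seed(13)
  pm <- tiny_pseudo_map()
  mod <- new_affinity_predictor(tiny_config(), pm, seed = 7)
  pep <- random_peptide(15)
  p <- predict(mod, tibble::tibble(allele = c("A1", "A2"), peptide = pep))$.pred
  expect_gt(abs(p[1] - p[2]), 0)
})

test_that("unknown alleles are reported by name", {
  pm <- tiny_pseudo_map()
  mod <- new_affinity_predictor(tiny_config(), pm)
  expect_error(predict(mod, tibble::tibble(allele = "NOPE", peptide = "ACDEFGHIK")),
               "NOPE")
})

test_that("analytic gradients match finite differences", {
  set.seed(14)
  pm <- tiny_pseudo_map()
  cfg <- model_config(scale_factor = 0.03, embedding_dim = 4L, dropout = 0)
  nd <- tibble::tibble(allele = sample(pm$allele, 4, replace = TRUE),
                       peptide = replicate(4, random_peptide(20)))
  y <- runif(4)
  codes <- rpemhc:::encode_dataset(nd, pm)
  ccfg <- rpemhc:::as_cpp_config(cfg)
  params <- rpemhc:::init_params(cfg, 3)
  lossfn <- function(p) rpemhc:::rpe_net_run(p, codes, ccfg, y, TRUE, 1L)$loss
  res <- rpemhc:::rpe_net_run(params, codes, ccfg, y, TRUE, 1L)
  eps <- 1e-5
  for (nm in names(params)) {
    g <- res$grads[[nm]]
    live <- which(abs(g) > 1e-12)
    if (length(live) == 0) next
    for (i in sample(live, min(2, length(live)))) {
      p_hi <- params; p_hi[[nm]][i] <- p_hi[[nm]][i] + eps
      p_lo <- params; p_lo[[nm]][i] <- p_lo[[nm]][i] - eps
      num <- (lossfn(p_hi) - lossfn(p_lo)) / (2 * eps)
      expect_lt(abs(num - g[i]) / max(1e-8, abs(num) + abs(g[i])), 1e-4,
                label = sprintf("gradient of %s", nm))
    }
  }
})

test_that("the pad embedding row stays frozen at zero through training", {
  set.seed(15)
  world <- make_world(n_alleles = 2, seed = 21)
  ds <- sample_dataset(world, n_per_allele = 20, seed = 22)
  fit <- fit_affinity_model(ds, world$alleles, tiny_config(),
                            train_spec(epochs = 2, batch_size = 16, seed = 23,
                                       validation_fraction = 0))
  expect_true(all(fit$params$emb[1, ] == 0))
})

test_that("checkpoints round-trip and refuse a vocabulary mismatch", {
  pm <- tiny_pseudo_map()
  mod <- new_affinity_predictor(tiny_config(), pm, seed = 9)
  tmp <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(mod, tmp)
  back <- load_checkpoint(tmp)
  nd <- tibble::tibble(allele = "A1", peptide = "ACDEFGHIKLMNP")
  expect_equal(predict(back, nd)$.pred, predict(mod, nd)$.pred)

  mod_bad <- mod
  mod_bad$vocab_version <- "other-formula-v9"
  saveRDS(mod_bad, tmp)
  expect_error(load_checkpoint(tmp), "vocabulary version")
})

test_that("padding is distinguishable from unknown residues", {
  # an X asserts a residue is present; padding asserts absence - the two
  # must encode (and therefore score) differently
  set.seed(16)
  pm <- tiny_pseudo_map()
  mod <- new_affinity_predictor(tiny_config(), pm, seed = 18)
  core <- random_peptide(9)
  p_pad <- predict(mod, tibble::tibble(allele = "A1", peptide = core))$.pred
  p_x <- predict(mod, tibble::tibble(allele = "A1",
                                     peptide = paste0(core, strrep("X", 11))))$.pred
  expect_gt(abs(p_pad - p_x), 0)
})
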