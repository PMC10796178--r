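test_that("core prediction slides a 9-mer window with first-max tie-breaking", {
  set.seed(91)
  pm <- tiny_pseudo_map()
  mod <- new_affinity_predictor(tiny_config(), pm, seed = 4)

  # a 9-mer has a single window: the peptide itself
  pep9 <- random_peptide(9)
  cp9 <- predict_core(mod, "A1", pep9)
  expect_equal(cp9$offset, 0L)
  expect_equal(cp9$core, pep9)
  expect_length(cp9$window_scores, 1L)

  # a 15-mer has 7 windows
  pep15 <- random_peptide(15)
  cp15 <- predict_core(mod, "A1", pep15)
  expect_length(cp15$window_scores, 15 - 9 + 1)
  expect_equal(cp15$core,
               substr(pep15, cp15$offset + 1, cp15$offset + 9))
  expect_equal(cp15$offset, which.max(cp15$window_scores) - 1L)

  expect_error(predict_core(mod, "A1", "ACDEFGH"), "shorter")
})

test_that("the core window's standalone score equals its window score", {
  set.seed(92)
  pm <- tiny_pseudo_map()
  mod <- new_affinity_predictor(tiny_config(), pm, seed = 6)
  pep <- random_peptide(18)
  cp <- predict_core(mod, "A2", pep)
  standalone <- predict(mod, tibble::tibble(allele = "A2", peptide = cp$core))$.pred
  expect_equal(standalone, cp$window_scores[cp$offset + 1], tolerance = 1e-9)
})

test_that("masked-context scoring keeps the window in place", {
  set.seed(93)
  pm <- tiny_pseudo_map()
  mod <- new_affinity_predictor(tiny_config(), pm, seed = 8)
  pep <- random_peptide(14)
  cp <- predict_core(mod, "A1", pep, context = "masked")
  expect_length(cp$window_scores, 6L)
  expect_equal(cp$core, substr(pep, cp$offset + 1, cp$offset + 9))
})

test_that("motif construction counts the requested top fraction", {
  set.seed(94)
  pm <- tiny_pseudo_map()
  mod <- new_affinity_predictor(tiny_config(), pm, seed = 10)
  motif <- build_motif(mod, "A1", n_peptides = 1000, peptide_len = 15,
                       top_frac = 0.01, seed = 95)
  expect_equal(motif$n_contributing, 10L)  # floor(1000 * 0.01)
  expect_equal(rowSums(motif$counts), rep(10, 9), ignore_attr = TRUE)
  expect_equal(rowSums(motif$frequencies), rep(1, 9), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(build_motif(mod, "A1", n_peptides = 50, top_frac = 0.01),
               "at least")
})

test_that("motif building is seed-reproducible", {
  set.seed(96)
  pm <- tiny_pseudo_map()
  mod <- new_affinity_predictor(tiny_config(), pm, seed = 12)
  m1 <- build_motif(mod, "A1", n_peptides = 400, top_frac = 0.05, seed = 97)
  m2 <- build_motif(mod, "A1", n_peptides = 400, top_frac = 0.05, seed = 97)
  expect_identical(m1$counts, m2$counts)
})

test_that("with top_frac = 1 a uniform background stays near-uniform", {
  set.seed(98)
  pm <- tiny_pseudo_map()
  mod <- new_affinity_predictor(tiny_config(), pm, seed = 14)
  motif <- build_motif(mod, "A1", n_peptides = 600, peptide_len = 9,
                       top_frac = 1, seed = 99)
  # 9-mers have one window, so cores are the raw background sample;
  # chi-square statistic against uniform should not be extreme
  for (p in 1:9) {
    counts <- motif$counts[p, 1:20]
    chisq <- sum((counts - 30)^2 / 30)
    expect_lt(chisq, 60)  # ~3x the df, far below any plausible planted signal
  }
})

test_that("background peptides can be drawn from FASTA substrings", {
  set.seed(100)
  prot <- random_peptide(60)
  bg <- tibble::tibble(id = "p1", seq = prot)
  peps <- rpemhc:::sample_background_peptides(25, 15, bg)
  expect_true(all(nchar(peps) == 15))
  expect_true(all(vapply(peps, function(p) grepl(p, prot, fixed = TRUE),
                         logical(1))))
  expect_error(rpemhc:::sample_background_peptides(5, 80, bg), "at least 80")
})

test_that("information content follows the entropy arithmetic", {
  mk_motif <- function(freq_row) {
    counts <- matrix(0L, 9, 21, dimnames = list(paste0("p", 1:9),
                                                amino_alphabet()))
    counts[, 1:20] <- matrix(rep(freq_row, each = 9), nrow = 9)
    structure(list(allele = "T", counts = counts,
                   frequencies = counts / rowSums(counts),
                   n_contributing = sum(freq_row)),
              class = "motif_matrix")
  }
  expect_equal(information_content(mk_motif(rep(5L, 20))), rep(0, 9),
               ignore_attr = TRUE)
  single <- c(100L, rep(0L, 19))
  expect_equal(information_content(mk_motif(single)), rep(log2(20), 9),
               ignore_attr = TRUE)
  half <- c(50L, 50L, rep(0L, 18))
  expect_equal(information_content(mk_motif(half)), rep(log2(20) - 1, 9),
               ignore_attr = TRUE)
})

test_that("motif export writes a self-describing frequency matrix", {
  set.seed(101)
  pm <- tiny_pseudo_map()
  mod <- new_affinity_predictor(tiny_config(), pm, seed = 16)
  motif <- build_motif(mod, "A1", n_peptides = 200, top_frac = 0.05, seed = 102)
  tmp <- withr::local_tempfile(fileext = ".pfm")
  write_motif(motif, tmp)
  lines <- readLines(tmp)
  expect_match(lines[2], "allele: A1")
  expect_match(lines[4], "columns: A C D")
  body <- read.table(text = lines[-(1:4)], row.names = 1)
  expect_equal(unname(as.matrix(body)), unname(motif$frequencies),
               tolerance = 1e-5)
})

test_that("core comparator reports exact matches and offset errors", {
  cp <- function(off) structure(list(offset = off), class = "core_prediction")
  res <- compare_core_offsets(list(cp(2L), cp(3L), cp(5L)), c(2L, 2L, 2L))
  expect_equal(res$n_exact, 1L)
  expect_equal(res$n_total, 3L)
  expect_equal(res$offset_error$count[res$offset_error$error == 1L], 1L)
})
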