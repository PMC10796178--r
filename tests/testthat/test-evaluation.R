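test_that("metrics hit their anchor values on clean inputs", {
  # perfectly separating scores
  t1 <- tibble::tibble(.pred = c(0.9, 0.8, 0.2, 0.1),
                       binary_true = c(1L, 1L, 0L, 0L))
  expect_equal(compute_metrics(t1)$auc, 1)
  # predictions equal to labels: PCC and F1 are exact
  set.seed(61)
  y <- runif(30)
  t2 <- tibble::tibble(.pred = y, y_true = y)
  m2 <- compute_metrics(t2)
  expect_equal(m2$pcc, 1)
  expect_equal(m2$f1, 1)
  expect_equal(m2$sensitivity, 1)
  expect_equal(m2$ppv, 1)
})

test_that("AUC and PRC match brute-force oracles, including ties", {
  set.seed(62)
  for (rep in 1:5) {
    n <- sample(50:200, 1)
    # coarse scores force plenty of ties
    score <- round(runif(n), 2)
    label <- rbinom(n, 1, 0.4)
    if (length(unique(label)) < 2) next
    tab <- tibble::tibble(.pred = score, binary_true = label)
    m <- compute_metrics(tab)
    expect_equal(m$auc, oracle_auc(score, label), tolerance = 1e-12)
    expect_equal(m$prc, oracle_average_precision(score, label), tolerance = 1e-12)
  }
})

test_that("rank metrics are invariant to strictly monotone score transforms", {
  set.seed(63)
  score <- runif(80)
  label <- rbinom(80, 1, 0.5)
  t1 <- tibble::tibble(.pred = score, binary_true = label)
  t2 <- tibble::tibble(.pred = plogis(5 * score - 2), binary_true = label)
  expect_equal(compute_metrics(t1)$auc, compute_metrics(t2)$auc)
  expect_equal(compute_metrics(t1)$prc, compute_metrics(t2)$prc)
})

test_that("undefined metrics are absent with a reason, not zero", {
  t1 <- tibble::tibble(.pred = c(0.6, 0.7), binary_true = c(1L, 1L))
  m <- compute_metrics(t1)
  expect_true(is.na(m$auc))
  expect_true(is.na(m$prc))
  expect_match(m$reason, "single_class")
  expect_equal(m$sensitivity, 1)  # confusion metrics still computed
})

test_that("confusion metrics agree with direct counting at the threshold", {
  set.seed(64)
  y <- runif(100)
  pred <- pmin(pmax(y + rnorm(100, sd = 0.2), 0.001), 0.999)
  tab <- tibble::tibble(.pred = pred, y_true = y)
  m <- compute_metrics(tab)
  thr <- affinity_threshold()
  lab <- as.integer(y >= thr)
  ph <- as.integer(pred >= thr)
  tp <- sum(ph & lab); fp <- sum(ph & !lab); fn <- sum(!ph & lab)
  expect_equal(m$ppv, tp / (tp + fp))
  expect_equal(m$sensitivity, tp / (tp + fn))
  expect_equal(m$f1, 2 * tp / (2 * tp + fp + fn))
})

test_that("per-molecule reports apply the strict more-than filter", {
  set.seed(65)
  mk <- function(allele, n, n_bind) {
    y <- c(runif(n_bind, 0.6, 1), runif(n - n_bind, 0, 0.3))
    tibble::tibble(allele = allele, y_true = y,
                   .pred = pmin(pmax(y + rnorm(n, sd = 0.1), 0.001), 0.999))
  }
  tab <- dplyr::bind_rows(mk("A41", 41, 3), mk("A40", 40, 10), mk("A10", 10, 2))
  rep <- per_molecule_report(tab, min_peptides = 40, min_binders = 3)
  inc <- setNames(rep$molecules$included_in_average, rep$molecules$allele)
  expect_true(inc[["A41"]])    # 41 > 40 and 3 binders
  expect_false(inc[["A40"]])   # exactly 40 peptides: excluded
  expect_false(inc[["A10"]])   # too few binders
  # macro-average equals the hand mean over included molecules
  aucs <- rep$molecules$auc[rep$molecules$included_in_average]
  expect_equal(rep$average$mean[rep$average$metric == "auc"], mean(aucs))
  # pooled-All metrics computed on the whole table
  expect_equal(rep$all$n, nrow(tab))
})

test_that("per-molecule macro-average ignores row order", {
  set.seed(66)
  tab <- tibble::tibble(
    allele = rep(c("X", "Y"), each = 50),
    y_true = runif(100),
    .pred = runif(100))
  r1 <- per_molecule_report(tab, min_peptides = 10, min_binders = 1)
  r2 <- per_molecule_report(tab[sample(100), ], min_peptides = 10, min_binders = 1)
  expect_equal(r1$average, r2$average)
})

test_that("epitope cases enumerate all overlapping same-length windows", {
  case <- annotate_epitope_case("ACDEF", "AAAACDEFAAA", "AL1")
  expect_equal(nrow(case), 11 - 5 + 1)
  expect_equal(sum(case$binary_true), 1L)
  expect_equal(case$peptide[case$binary_true == 1L], "ACDEF")

  # protein length 100, epitope length 15 -> 86 candidates
  set.seed(67)
  prot <- random_peptide(100)
  epi <- substr(prot, 30, 44)
  case2 <- annotate_epitope_case(epi, prot, "AL1")
  expect_equal(nrow(case2), 86L)

  # an epitope occurring twice yields two positives
  case3 <- annotate_epitope_case("ACA", "ACACA", "AL1")
  expect_equal(sum(case3$binary_true), 2L)

  expect_error(annotate_epitope_case("ACDEFGHIK", "ACD", "AL1"), "longer")
})

test_that("Frank counts strictly-above negatives over n - 1", {
  mk <- function(scores, pos_at) {
    tibble::tibble(.pred = scores,
                   binary_true = as.integer(seq_along(scores) == pos_at))
  }
  # positive on top: perfect
  expect_equal(frank(mk(c(0.9, 0.5, 0.4), 1)), 0)
  # equal numbers above and below
  expect_equal(frank(mk(c(0.9, 0.8, 0.5, 0.3, 0.1), 3)), 0.5)
  # 10 candidates, positive ranked 4th: 3 / 9
  scores <- seq(0.95, 0.05, length.out = 10)
  expect_equal(frank(mk(scores, 4)), 3 / 9)
  # ties with the positive do not count against it
  expect_equal(frank(mk(c(0.5, 0.5, 0.4), 1)), 0)
  # multi-occurrence: best-scoring positive is the reference
  t_multi <- tibble::tibble(.pred = c(0.9, 0.3, 0.7, 0.2),
                            binary_true = c(1L, 1L, 0L, 0L))
  expect_equal(frank(t_multi), 0)
  expect_error(frank(mk(c(0.5, 0.4), NA)), "no positive")
})

test_that("Frank partitions candidates into above, below and ties", {
  set.seed(68)
  scores <- round(runif(40), 1)
  tab <- tibble::tibble(.pred = scores,
                        binary_true = as.integer(seq_along(scores) == 7))
  ref <- scores[7]
  neg <- scores[-7]
  expect_equal(sum(neg > ref) + sum(neg < ref) + sum(neg == ref), 39)
  expect_equal(frank(tab), sum(neg > ref) / 39)
})

test_that("AUC agrees with an independent implementation when available", {
  skip_if_not_installed("pROC")
  set.seed(69)
  score <- runif(150)
  label <- rbinom(150, 1, 0.5)
  tab <- tibble::tibble(.pred = score, binary_true = label)
  ref <- as.numeric(pROC::auc(pROC::roc(label, score, quiet = TRUE,
                                        direction = "<")))
  expect_equal(compute_metrics(tab)$auc, ref, tolerance = 1e-12)
})
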