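test_that("transform_ic50 hits its fixed points and known values", {
  expect_equal(transform_ic50(50000), 0)
  expect_equal(transform_ic50(1), 1)
  # 1 - log(500)/log(50000), evaluated independently at high precision
  expect_equal(transform_ic50(500), 0.425625189808507, tolerance = 1e-12)
  expect_equal(transform_ic50(500), affinity_threshold())
})

test_that("transform_ic50 is monotone decreasing and clamped to [0, 1]", {
  grid <- exp(seq(log(0.1), log(5e6), length.out = 1000))
  y <- transform_ic50(grid)
  expect_true(all(diff(y) <= 0))
  expect_true(all(y >= 0 & y <= 1))
  inner <- grid > 1 & grid < 50000
  expect_true(all(diff(y[inner]) < 0))
})

test_that("transform_ic50 rejects invalid input", {
  expect_error(transform_ic50(0), "positive")
  expect_error(transform_ic50(-5), "positive")
  expect_error(transform_ic50(NaN), "positive")
})

test_that("binarize_label applies the 500 nM threshold with equality as binder", {
  expect_identical(binarize_label(0.9), 1L)
  expect_identical(binarize_label(0.1), 0L)
  expect_identical(binarize_label(transform_ic50(499)), 1L)
  expect_identical(binarize_label(transform_ic50(501)), 0L)
  expect_identical(binarize_label(transform_ic50(500)), 1L)
  expect_error(binarize_label(1.2), "0, 1")
})

test_that("binarization agrees with the raw-scale rule IC50 <= 500", {
  ic50 <- exp(seq(log(2), log(40000), length.out = 200))
  expect_identical(binarize_label(transform_ic50(ic50)),
                   as.integer(ic50 <= 500))
})

test_that("normalize_peptide pads short and truncates long peptides", {
  out <- normalize_peptide(c("AAAAAAAAA", strrep("C", 20), strrep("D", 25)))
  expect_equal(nchar(out$peptide), rep(20L, 3))
  expect_equal(out$peptide[1], paste0("AAAAAAAAA", strrep(pad_char(), 11)))
  expect_equal(out$peptide[2], strrep("C", 20))
  expect_equal(out$peptide[3], strrep("D", 20))
  expect_equal(out$raw_length, c(9L, 20L, 20L))
})

test_that("truncation keeps the requested end", {
  pep <- paste0(strrep("A", 20), "CDEFG")
  expect_equal(normalize_peptide(pep, keep = "n")$peptide, strrep("A", 20))
  expect_equal(normalize_peptide(pep, keep = "c")$peptide,
               paste0(strrep("A", 15), "CDEFG"))
})

test_that("normalize_peptide is idempotent and rejects bad input", {
  once <- normalize_peptide("ACDEFGHIK")
  twice <- normalize_peptide(once$peptide)
  expect_equal(twice$peptide, once$peptide)
  expect_equal(twice$raw_length, once$raw_length)
  expect_error(normalize_peptide(""), "non-empty")
  expect_error(normalize_peptide("ACDB"), "outside the alphabet")
})

test_that("affinity tables round-trip and auto-compute y from ic50", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  ds <- tibble::tibble(
    allele = c("DRB1_0101", "DRB1_0101", "DRB1_0701"),
    peptide = c("ACDEFGHIKLMNP", "WYWYWYWYWYWYW", "ACACACACACACA"),
    ic50_nM = c(12.5, 480, 20000))
  ds$y <- transform_ic50(ds$ic50_nM)
  write_affinity_table(ds, tmp)
  back <- read_affinity_table(tmp)
  expect_equal(back$allele, ds$allele)
  expect_equal(back$peptide, ds$peptide)
  expect_equal(back$y, ds$y)
  expect_equal(back$binary_label, c(1L, 1L, 0L))

  # file with only an ic50 column: y computed row by row
  writeLines(c("allele\tpeptide\tic50",
               "X1\tACDEFGHIK\t250",
               "X1\tKIHGFEDCA\t5000"), tmp)
  back2 <- read_affinity_table(tmp)
  expect_equal(back2$y, transform_ic50(c(250, 5000)))
})

test_that("reading maps foreign residues to X and counts them", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("allele,peptide,y", "X1,ACDB,0.5"), tmp)
  expect_warning(tab <- read_affinity_table(tmp), "1 residue")
  expect_equal(tab$peptide, "ACDX")
  expect_equal(attr(tab, "n_sanitized"), 1L)
})

test_that("affinity reader rejects malformed tables", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("foo\tbar", "1\t2"), tmp)
  expect_error(read_affinity_table(tmp), "must name")
  expect_error(read_affinity_table(file.path(tempdir(), "nope.tsv")), "Cannot read")
})

test_that("pseudo-sequence tables validate and round-trip", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  set.seed(7)
  tab <- tibble::tibble(allele = sprintf("AL%02d", 1:80), pseudo = random_pseudo(80))
  write_pseudosequence_table(tab, tmp)
  back <- read_pseudosequence_table(tmp)
  expect_equal(back, tab)

  writeLines(c("allele\tpseudo",
               paste0("SHORTY\t", strrep("A", 33))), tmp)
  expect_error(read_pseudosequence_table(tmp), "SHORTY")

  writeLines(c("allele\tpseudo",
               paste0("DUP\t", strrep("A", 34)),
               paste0("DUP\t", strrep("C", 34))), tmp)
  expect_error(read_pseudosequence_table(tmp), "Duplicate.*DUP")
})

test_that("FASTA reading preserves order, uppercases, and maps U to X", {
  tmp <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">prot1 some description", "acdefg", "hik",
               ">prot2", "MUM"), tmp)
  fa <- read_fasta(tmp)
  expect_equal(fa$id, c("prot1", "prot2"))
  expect_equal(fa$seq, c("ACDEFGHIK", "MXM"))

  writeLines(character(0), tmp)
  expect_error(read_fasta(tmp), "FASTA")
})
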