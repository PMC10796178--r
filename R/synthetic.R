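#' Create a synthetic world of alleles with planted binding motifs
#'
#' Each synthetic allele is a random 34-residue pseudo-sequence tied to a
#' planted 9 x 20 position-weight matrix that defines its ground-truth
#' binding preference. Four anchor rows (core positions 1, 4, 6 and 9 by
#' default, mirroring the primary anchors of class II binding) are
#' high-contrast — two preferred residues carry weight 1, the rest 0.05 —
#' while the remaining rows are near-flat, so anchor positions dominate
#' the affinity and are recoverable from a trained model's motif.
#'
#' With `related = TRUE`, alleles after the first are perturbations of the
#' first: their pseudo-sequences differ by `n_edits` random substitutions
#' and their weight matrices get small jitter. This makes generalisation
#' to a held-out allele learnable in principle through pseudo-sequence
#' similarity, which is what leave-one-molecule-out protocols probe.
#'
#' @param n_alleles Number of alleles (>= 1).
#' @param length_range Min/max peptide length, within \[8, 25\]. The
#'   default 13--25 emulates class II length spread; use c(8, 11) for a
#'   class I-like world.
#' @param noise_sd Gaussian noise added to affinities at sampling time.
#' @param seed World seed.
#' @param anchor_positions Core positions given high-contrast weight rows.
#' @param related Derive alleles 2..n from allele 1 (see above)?
#' @param n_edits Pseudo-sequence substitutions per related allele.
#' @param pwm_jitter SD of weight jitter for related alleles.
#' @return An object of class `synthetic_world`: list with `alleles`
#'   (tibble `allele`, `pseudo`), `pwm` (named list of 9 x 20 matrices),
#'   and the generation settings.
#' @export
make_world <- function(n_alleles = 3L, length_range = c(13L, 25L),
                       noise_sd = 0.05, seed = 1L,
                       anchor_positions = c(1L, 4L, 6L, 9L),
                       related = FALSE, n_edits = 3L, pwm_jitter = 0.05) {
  stopifnot(n_alleles >= 1, noise_sd >= 0)
  if (length(length_range) != 2L || length_range[1] > length_range[2] ||
      length_range[1] < 8L || length_range[2] > 25L) {
    stop("`length_range` must be (min, max) within [8, 25].", call. = FALSE)
  }
  set.seed(seed)
  std <- amino_alphabet()[1:20]
  make_pseudo <- function() paste(sample(std, 34L, replace = TRUE), collapse = "")
  make_pwm <- function() {
    w <- matrix(stats::runif(9 * 20, 0.45, 0.55), nrow = 9,
                dimnames = list(paste0("p", 1:9), std))
    for (p in anchor_positions) {
      w[p, ] <- 0.05
      w[p, sample.int(20L, 2L)] <- 1
    }
    w
  }
  alleles <- paste0("SYN-", sprintf("%02d", seq_len(n_alleles)))
  pseudos <- character(n_alleles)
  pwms <- vector("list", n_alleles)
  for (i in seq_len(n_alleles)) {
    if (related && i > 1L) {
      base <- strsplit(pseudos[1], "")[[1]]
      pos <- sample.int(34L, n_edits)
      base[pos] <- sample(std, n_edits, replace = TRUE)
      pseudos[i] <- paste(base, collapse = "")
      w <- pwms[[1]] + matrix(stats::rnorm(180, sd = pwm_jitter), nrow = 9)
      pwms[[i]] <- pmin(pmax(w, 0), 1)
    } else {
      pseudos[i] <- make_pseudo()
      pwms[[i]] <- make_pwm()
    }
  }
  while (anyDuplicated(pseudos)) {  # astronomically unlikely, but guaranteed
    pseudos[duplicated(pseudos)] <- replicate(sum(duplicated(pseudos)), make_pseudo())
  }
  names(pwms) <- alleles
  structure(
    list(alleles = tibble::tibble(allele = alleles, pseudo = pseudos),
         pwm = pwms, noise_sd = noise_sd,
         length_range = as.integer(length_range),
         anchor_positions = as.integer(anchor_positions),
         related = related, n_edits = as.integer(n_edits),
         pwm_jitter = pwm_jitter, seed = as.integer(seed)),
    class = "synthetic_world"
  )
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("<synthetic_world> ", nrow(x$alleles), " allele(s), peptide lengths ",
      x$length_range[1], "-", x$length_range[2], ", noise sd ", x$noise_sd,
      ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# per-window planted-matrix scores of one peptide, min-max normalised over
# the matrix's attainable score range
planted_window_scores <- function(pwm, peptide) {
  idx <- aa_index(peptide)
  len <- length(idx)
  smin <- sum(apply(pwm, 1, min))
  smax <- sum(apply(pwm, 1, max))
  offsets <- 0:(len - 9L)
  vapply(offsets, function(o) {
    res <- idx[(o + 1):(o + 9)]
    # X scores the row minimum: an unknown residue cannot help binding
    s <- sum(ifelse(res <= 20L, pwm[cbind(1:9, pmin(res, 20L))], apply(pwm, 1, min)))
    (s - smin) / (smax - smin)
  }, numeric(1))
}

#' Ground-truth affinity of peptides in a synthetic world
#'
#' The clean affinity is the maximum over all 9-mer windows of the
#' min-max-normalised planted-matrix score; the true core offset is the
#' argmax window (first, on ties).
#'
#' @param world A `synthetic_world`.
#' @param allele Allele name in the world.
#' @param peptide Peptide of length >= 9.
#' @return A list with `clean_y` and `true_core_offset` (0-based).
#' @export
true_affinity <- function(world, allele, peptide) {
  pwm <- world$pwm[[allele]]
  if (is.null(pwm)) stop("Allele '", allele, "' not in this world.", call. = FALSE)
  ws <- planted_window_scores(pwm, peptide)
  list(clean_y = max(ws), true_core_offset = which.max(ws) - 1L)
}

#' Sample a synthetic affinity dataset
#'
#' Draws `n_per_allele` peptides per allele with lengths uniform over the
#' world's length range. A fraction of the peptides (default one half)
#' carry an implanted core sampled from the allele's planted weight matrix
#' at a random offset, so datasets contain strong binders at realistic
#' proportions alongside background peptides; all labels, implanted or
#' not, come from the same ground-truth scoring. Observed `y` adds
#' Gaussian noise (`world$noise_sd`) to `clean_y`, clamped to \[0, 1\].
#'
#' @param world A `synthetic_world`.
#' @param n_per_allele Records per allele (>= 1).
#' @param seed Sampling seed.
#' @param implant_fraction Fraction of peptides with an implanted core.
#' @return A tibble with `allele`, `peptide`, `y`, `clean_y`,
#'   `true_core_offset`, plus sampling settings as attributes.
#' @export
sample_dataset <- function(world, n_per_allele = 2000L, seed = 1L,
                           implant_fraction = 0.5) {
  stopifnot(inherits(world, "synthetic_world"), n_per_allele >= 1,
            implant_fraction >= 0, implant_fraction <= 1)
  set.seed(seed)
  std <- amino_alphabet()[1:20]
  rows <- vector("list", nrow(world$alleles))
  for (ai in seq_len(nrow(world$alleles))) {
    allele <- world$alleles$allele[ai]
    pwm <- world$pwm[[allele]]
    lens <- sample(world$length_range[1]:world$length_range[2],
                   n_per_allele, replace = TRUE)
    implant <- stats::runif(n_per_allele) < implant_fraction
    peptides <- vapply(seq_len(n_per_allele), function(i) {
      chars <- sample(std, lens[i], replace = TRUE)
      if (implant[i]) {
        off <- sample.int(lens[i] - 9L + 1L, 1L) - 1L
        core <- vapply(1:9, function(p) {
          sample(std, 1L, prob = pwm[p, ] / sum(pwm[p, ]))
        }, character(1))
        chars[(off + 1):(off + 9)] <- core
      }
      paste(chars, collapse = "")
    }, character(1))
    truth <- lapply(peptides, function(p) true_affinity(world, allele, p))
    clean_y <- vapply(truth, `[[`, numeric(1), "clean_y")
    y <- pmin(pmax(clean_y + stats::rnorm(n_per_allele, sd = world$noise_sd), 0), 1)
    rows[[ai]] <- tibble::tibble(
      allele = allele, peptide = peptides, y = y, clean_y = clean_y,
      true_core_offset = vapply(truth, `[[`, integer(1), "true_core_offset"),
      implanted = implant
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "sample_seed") <- as.integer(seed)
  attr(out, "n_per_allele") <- as.integer(n_per_allele)
  attr(out, "implant_fraction") <- implant_fraction
  out
}

#' Write a synthetic fixture bundle to a directory
#'
#' Writes the pseudo-sequence table, the affinity table, a truth table
#' (clean affinities and core offsets) and a JSON manifest holding every
#' generation setting, so the bundle can be regenerated byte-identically
#' from the manifest alone (see [regenerate_bundle()]).
#'
#' @param world A `synthetic_world`.
#' @param dataset A tibble from [sample_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_bundle <- function(world, dataset, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("Cannot create directory: ", dir, call. = FALSE)
  }
  write_pseudosequence_table(world$alleles, file.path(dir, "pseudosequences.tsv"))
  write_affinity_table(dataset, file.path(dir, "affinities.tsv"))
  readr::write_delim(
    dataset[c("allele", "peptide", "clean_y", "true_core_offset", "implanted")],
    file.path(dir, "truth.tsv"), delim = "\t")
  manifest <- list(
    kind = "rpemhc_synthetic_bundle_v1",
    world = list(
      n_alleles = nrow(world$alleles), length_range = world$length_range,
      noise_sd = world$noise_sd, seed = world$seed,
      anchor_positions = world$anchor_positions, related = world$related,
      n_edits = world$n_edits, pwm_jitter = world$pwm_jitter
    ),
    dataset = list(
      n_per_allele = attr(dataset, "n_per_allele"),
      seed = attr(dataset, "sample_seed"),
      implant_fraction = attr(dataset, "implant_fraction")
    ),
    vocabulary = vocabulary_version()
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a synthetic fixture bundle
#' @param dir Directory written by [write_fixture_bundle()].
#' @return A list with `pseudo_map`, `dataset` (affinities joined with
#'   truth columns) and `manifest`.
#' @export
read_fixture_bundle <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  pseudo_map <- read_pseudosequence_table(file.path(dir, "pseudosequences.tsv"))
  affin <- read_affinity_table(file.path(dir, "affinities.tsv"))
  truth <- readr::read_tsv(file.path(dir, "truth.tsv"), show_col_types = FALSE,
                           progress = FALSE)
  dataset <- dplyr::left_join(
    affin, truth, by = c("allele", "peptide"),
    relationship = "many-to-many", multiple = "first")
  list(pseudo_map = pseudo_map, dataset = dataset, manifest = manifest)
}

#' Regenerate a fixture bundle from its manifest
#'
#' Rebuilds the world and dataset from the recorded seeds and settings and
#' writes them to `dir`; the result is byte-identical to the original
#' bundle.
#'
#' @param manifest Manifest list (from [read_fixture_bundle()]).
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
regenerate_bundle <- function(manifest, dir) {
  w <- manifest$world
  world <- make_world(n_alleles = w$n_alleles, length_range = w$length_range,
                      noise_sd = w$noise_sd, seed = w$seed,
                      anchor_positions = w$anchor_positions,
                      related = isTRUE(w$related), n_edits = w$n_edits,
                      pwm_jitter = w$pwm_jitter)
  d <- manifest$dataset
  dataset <- sample_dataset(world, n_per_allele = d$n_per_allele,
                            seed = d$seed,
                            implant_fraction = d$implant_fraction)
  write_fixture_bundle(world, dataset, dir)
}
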