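---
title: "Methods: residue-pair encoding for MHC-peptide affinity prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: residue-pair encoding for MHC-peptide affinity prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

MHC molecules present short peptide fragments to T cells; whether a given
peptide binds a given MHC allele is the gating step of antigen
presentation, and predicting the binding affinity from sequence is a core
task of computational vaccinology. Class II molecules are the harder
case: their open binding groove accepts peptides of widely varying length
(mostly 13-25 residues), of which a 9-residue *binding core* seated in
the groove dominates the interaction. A *pan-specific* predictor covers
all alleles - including ones never measured - by conditioning on a
34-residue *pseudo-sequence*, the fixed selection of binding-groove
residues (15 from the alpha chain, 19 from the beta chain) that
summarises an allele.

Affinity labels are IC50 values in nM, mapped to the unit interval by

$$y = 1 - \log(\mathrm{IC50}) / \log(50000),$$

so 1 nM maps to 1, 50 000 nM to 0, and the conventional 500 nM binder
cut-off to a threshold of about 0.4256. The transform is base-invariant;
we use natural logarithms and clamp to $[0,1]$ at ingestion (raw values
outside 1-50 000 nM would otherwise leave the interval; whether the
original assays excluded or clamped such values is not decidable from
published tables, and clamping keeps every record usable). Equality at
the threshold counts as binding, matching the "IC50 $\le$ 500 nM binder"
rule; the strict-inequality formulation leaves the boundary case
undefined, so a convention had to be chosen.

## Residue-pair encoding

Most sequence-based predictors encode the MHC molecule and the peptide
separately and let the network discover their interaction. This package
instead encodes the *pair* directly: over the 21-symbol alphabet (20
standard residues in alphabetical order, then `X` for unknown residues)
every ordered pair of symbols receives its own integer code,

$$\mathrm{code}(a_i, b_j) = (i - 1)\cdot 21 + j \in \{1, \dots, 441\},$$

and an MHC-peptide pair becomes a $34 \times 20$ integer matrix whose
entry $(i, j)$ codes (pseudo-sequence residue $i$, peptide residue $j$).
Order sensitivity matters: $\langle a,b\rangle$ and $\langle
b,a\rangle$ get different codes, so the matrix distinguishes which side
contributes which residue. Any fixed bijection would serve; the row-major
formula above is frozen (and version-tagged in checkpoints and exported
encodings) so that stored artifacts remain portable. Because the
assignment of codes to pairs is a free choice, trained weights from other
implementations of the same idea are not transferable - a consequence of
the encoding's arbitrariness, not a defect.

Peptides are padded or truncated to 20 positions. Padding uses a
dedicated symbol mapped to code 0 and a frozen all-zero embedding vector,
*not* `X`: an absent position carries no information, whereas `X` asserts
an unidentified residue is present, and conflating them would inject fake
"unknown residue" signal into every short peptide. Truncation keeps the
N-terminal 20 residues by default (deterministic and reading-order
consistent; a flag selects the C-terminal end instead). How the original
instrument handled either case is unstated in the literature this design
follows, so both are explicit, documented choices here.

## Network

The code matrix is embedded (dimension 16 by default; the dimension is a
free hyperparameter) into a $34 \times 20 \times E$ array, then a
convolution with kernel $(34, 1)$ contracts the whole MHC axis onto each
peptide position. We keep this fusion layer linear - it is an
allele-conditioned projection of the embedding, part of input processing
rather than feature extraction; every later convolution is followed by a
ReLU.

Feature extraction over the length-20 peptide axis then applies, in
order: three parallel same-padded convolutions with kernels 1/3/5 and
32/64/128 filters, concatenated; a width-2 max pool; four parallel
convolutions with kernels 1/3/5/7 and 128/256/512/1024 filters,
concatenated; a width-3 max pool; a kernel-1 convolution; two parallel
LSTM blocks (one- and two-layer, unidirectional, hidden size 128, both
reading the same input and returning full hidden sequences) concatenated
on channels; and a final *valid* convolution of kernel 9 - the binding
core width. A fully connected layer and a logistic output produce
$\hat y \in (0,1)$.

**The pooling regime is a deliberate resolution of an inconsistency.**
Stated literally, strided pools of widths 2 and 3 over a length-20 axis
would leave at most 3 positions, on which a kernel-9 convolution is
impossible. We therefore run both pools with stride 1 over clipped
windows (local max smoothing, no downsampling), keeping the axis at 20
positions until the final kernel-9 convolution reduces it to
$20 - 9 + 1 = 12$ - exactly one output frame per candidate binding-core
window. This preserves every stated kernel size and gives the final
layer its intended role of reading core-width context; it is documented
as this package's regime, not claimed as anyone else's. (A strided
variant could be configured but cannot satisfy the kernel-9 layer, so it
is not exposed.)

Unspecified details fixed here: ReLU activations after feature-extraction
convolutions, none after the LSTMs or before the sigmoid; dropout 0.1
after each pooling stage; He initialisation for convolution/FC weights,
uniform $\pm 1/\sqrt{H}$ for LSTM weights with forget-gate bias 1,
$N(0, 0.1)$ embeddings. A `scale_factor` multiplies every channel count
(kernel sizes and the sequence axis untouched) so the identical topology
runs at desk scale; the tests and the acceptance script use scales
0.05-0.25.

The forward and backward passes are implemented from scratch in
RcppArmadillo; correctness is enforced by a finite-difference gradient
check in the test suite (worst relative error around $10^{-6}$ away from
max-pool tie points; exactly tied pool windows - which arise when pad
columns carry identical values - are non-differentiable points where a
subgradient is used).

## Training and ensembling

Training minimises mean squared error with Adam (learning rate $10^{-3}$,
batch 128, up to 100 epochs, patience-10 early stopping on a 10%
validation split; all configurable, none prescribed by the method
itself). Every random draw - initialisation, shuffling, dropout,
splits - derives from one seed, so (data, config, spec, seed) determine
every reported number exactly. The conventional remedy for run-to-run
variance is to train 20 such models and average their predictions;
`train_ensemble()` implements this with consecutive member seeds. The
mean-of-members prediction can never have larger MSE than the mean of the
members' MSEs (convexity of the square), which the suite asserts across
seeds.

Evaluation protocols: allele-stratified k-fold cross-validation (records
dealt round-robin within shuffled alleles, so fold sizes differ by at
most one globally and per allele) and leave-one-molecule-out (LOMO),
where each round's training portion excludes *every* record of the
held-out allele and the test portion is that allele's slice of the test
fold; out-of-fold predictions combine into one per-allele result. LOMO is
the honest probe of pan-specificity: the model can only generalise to the
held-out allele through its pseudo-sequence. Published per-fold numbers
on public benchmarks are not reproducible without the original fold
assignments, so `crossval_predict()` accepts externally supplied plans.

## Metrics

`compute_metrics()` reports AUC (Mann-Whitney rank statistic, midranks
for ties), PRC (average precision with tied blocks treated as one cut),
PCC, and PPV/F1/sensitivity from the confusion matrix after binarizing
scores at the same transformed-scale threshold used for labels (scores
live on the calibrated scale, so reusing the label threshold is the
natural choice; it is configurable). Metrics whose preconditions fail
(single-class AUC, zero-variance PCC) are reported absent with a reason
code, never as zero. Per-molecule reports follow the customary filter -
strictly more than `min_peptides` peptides and at least three binders -
and give the macro-average with *sample* standard deviation (population
vs sample is ambiguous in most published tables; sample SD is labelled
as such) alongside pooled-"All" metrics.

For epitope benchmarks, a case is the set of all overlapping
same-length windows of the source protein, positives being windows
identical to the epitope. The *Frank* value is the fraction of
candidates scored strictly above the epitope, out of all candidates
except the epitope itself (ties do not count against it; with multiple
occurrences the best-scoring positive is the reference): 0 is a perfect
ranking, 0.5 is chance.

## Binding cores and motifs

`predict_core()` scores every 9-mer window and takes the argmax (first
window on ties). Windows are scored as standalone peptides by default -
each window padded to 20 - because the encoder gives a short peptide and
a window identical representations; a `context = "masked"` mode instead
keeps the window in place and masks the flanks with `X`, for users who
want positional context retained. `build_motif()` draws 100 000 random
15-mers (uniform over the 20 standard residues by default, or substrings
of user-supplied FASTA proteins - a stand-in for drawing from a real
proteome, which would require external downloads), keeps the top 1% by
predicted affinity, localises each survivor's core, and accumulates a
9 x 21 position-frequency matrix. Information content per position is
$\log_2 20 + \sum_r p_r \log_2 p_r$ over the 20 standard residues after
renormalising `X` away, as logo alphabets exclude it.

## The synthetic world

Everything above is exercised end to end on generated data with known
ground truth. A synthetic allele is a random pseudo-sequence tied to a
planted 9 x 20 weight matrix: rows at the four canonical anchor
positions (1, 4, 6, 9) are high-contrast (two preferred residues at
weight 1, the rest at 0.05), the other five rows near-flat
(uniform 0.45-0.55), echoing the anchor-dominated specificity of real
class II binding. A peptide's clean affinity is the maximum over its
9-mer windows of the min-max-normalised matrix score - the same "one
core dominates" assumption the predictor itself embodies - and observed
labels add Gaussian noise (sd 0.05 by default) clamped to $[0,1]$.
`X` residues score the row minimum, since an unknown residue cannot be
credited with anchor affinity.

Half of the sampled peptides carry a core drawn from the matrix's
per-position weights implanted at a random offset; the rest are pure
background. Real affinity datasets are assay panels enriched for
binders, not uniform random peptides, and without implantation random
20-residue strings essentially never hit two weight-1 anchors at once,
leaving a one-class dataset. The defaults (3 alleles, 2000 records per
allele, lengths 13-25, noise 0.05, implant fraction 0.5) are the study
conditions used by the test suite and the acceptance script; they yield
roughly two-thirds binders under the 500 nM threshold. The `related`
mode derives later alleles from the first by a few pseudo-sequence edits
plus weight jitter, making LOMO transfer learnable in principle - which
is precisely what the pan-specific pathway through the pseudo-sequence
must demonstrate.

What the generator does *not* emulate: assay noise structure
(heteroscedastic, censored at assay limits), eluted-ligand data,
antigen-processing signals, length-dependent affinity biases, or real
allele sequence families. A model passing the synthetic suites is shown
to learn allele-conditioned core-driven affinity from pair-encoded
input - no more; benchmark-grade performance claims on real data would
require the real datasets and full-scale ensembles (20 members at scale
1), which are outside this package's test envelope.

## Problem sizes and numerical choices

The test suite and acceptance script train a single quarter-scale member
for 15 epochs on 4800 records (80% of the default world), which reaches
held-out AUC about 0.95 and PCC about 0.90 in a few minutes on one CPU
core; the loss curve is flat from roughly epoch 12 onward, so further
epochs buy nothing at these problem sizes. Core recovery is measured on
150 held-out binders, motifs built from 20 000 random 15-mers (the
canonical 100 000 changes nothing but runtime at this scale), LOMO
transfer on a related world of 3 alleles x 500 records at scale 0.1.
Structural suites (encoding bijectivity, gradient checks, metric oracles,
fold algebra) run at full precision in seconds.

Tie-breaks are everywhere deterministic: first maximum for pooling
argmax, core windows and fold assignment; midranks only where the metric
definition demands them. Degenerate inputs fail loudly with typed errors
(usage/validation/IO/numeric in the CLI) rather than silently: empty
datasets, unknown alleles (listed by name), non-34-mer pseudo-sequences
(named by allele), non-positive IC50, matrices with conflicting residue
implications.

## Known limitations

* Published benchmark figures (cross-validation and LOMO AUC/PCC on real
  class II panels, epitope Frank averages, structural core matches) are
  not reproducible here: they need the original datasets, fold
  assignments and 20-member full-scale ensembles.
* The pair-code embedding is the only residue representation; no
  physicochemical priors are injected, so data efficiency on tiny
  per-allele panels is limited.
* Allele names are matched exactly against the pseudo-sequence table;
  nomenclature normalisation across revisions is a documented hook, not
  implemented.
* The structural-core comparator takes reference offsets as given and
  does not attempt groove-register alignment against structures.
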