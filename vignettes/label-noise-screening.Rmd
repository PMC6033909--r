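---
title: "Screening protein sequence collections for label noise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening protein sequence collections for label noise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(labelsieve)
```

## The problem

Curated sequence databases assign each protein a class label — for
example, a G protein-coupled receptor (GPCR) of the glutamate family is
labeled as metabotropic glutamate (mG), calcium sensing (CS), GABA~B~
(GB) or Taste 1 (Ta). Those labels are usually treated as ground truth,
but some of them are wrong: inferred by homology, carried over from an
earlier release, or simply mistyped. `labelsieve` screens a labeled
collection of *unaligned* amino-acid sequences for entries whose label
is at odds with what a classifier can learn from the rest of the
collection, and hands a ranked shortlist to a human curator. It never
relabels anything itself: a consistently misclassified sequence may be
mislabeled, may be an atypical but correct member of its class, or may
sit genuinely between classes, and distinguishing those cases is
curator work.

## Alignment-free representations

Classification needs fixed-length numeric vectors, while sequences have
variable length and no alignment is assumed. Four transforms are
provided:

* **AAC** (`aac()`): the frequency of each of the 20 residues, d = 20.
* **Digram** (`digram()`): the frequency of each ordered residue pair
  over the overlapping length-2 windows, d = 400.
* **ACC** (`acc_transform()`): each residue is replaced by its five
  z-scale physicochemical descriptors (`zscale_table()`, the Sandberg
  et al. 1998 scales; the table is an argument, so alternative
  descriptor sets can be injected). Each of the five descriptor traces
  is mean-centered *within the sequence* and, for every descriptor pair
  (j, k) and every lag l up to L, the lagged product average
  $\frac{1}{n-l}\sum_{t=1}^{n-l}\tilde z_{j,t}\tilde z_{k,t+l}$ is
  recorded. Auto-covariance terms (j = k) and cross-covariance terms
  (j ≠ k) give 25 values per lag, so d = 25·L; the conventional L = 13
  gives d = 325. The output order is lag-major, pair-lexicographic —
  any fixed order would do for the classifiers; this one is documented
  for reproducibility. Per-sequence centering (rather than corpus-wide)
  makes each vector self-contained; the ACC of a homopolymer is exactly
  zero.
* **Prot2Vec** (`train_embeddings()` + `prot2vec_embed()`): sequences
  are treated as sentences of 3-gram words. The training corpus splits
  every sequence into its three non-overlapping 3-gram tokenizations
  (offsets 0–2), and a skip-gram model with negative sampling learns a
  vector per 3-gram (defaults: window 25, dimension 100, 5 epochs, 5
  negative samples, minimum count 1; the dimension follows the original
  protein-embedding convention). The working representation of a
  sequence is the *sum* of the vectors of all its overlapping 3-grams.
  Whether that sum should run over the overlapping multiset or only the
  offset-split tokens is genuinely open; the two differ only in up to
  two trailing tokens per offset, both are implemented
  (`grams = "overlapping"` / `"offset"`), and overlapping is the
  default. Out-of-vocabulary 3-grams contribute zero and are reported
  as a coverage statistic, keeping the embedding total and
  deterministic. The trainer is written in C++ with a private seeded
  RNG, single-threaded, so identical corpus + parameters + seed give
  bit-identical tables.

## Classifiers and evaluation

`classifier_spec()` selects the family. The workhorse is the
**one-vs-one RBF SVM**: one binary margin classifier per class pair
(libsvm via e1071), prediction by vote. Votes are tallied from the
signed pairwise decision values, whose orientation is fixed — positive
toward the first class of the pair in class order — so downstream
statistics are reproducible. Vote ties are broken by the summed
oriented decision values over the tied classes, then by class order.
Features are standardized to training-fold mean and unit variance for
the SVM family only: RBF kernels need comparable scales across, say,
ACC and embedding dimensions, whereas trees and naive Bayes do not.
Gaussian **naive Bayes** (MAP rule) and a **random forest** (default
500 trees) serve as baselines. Optional hyperparameter search
(`svm_default_grid()`: C over 2^−5^…2^15^, γ over 2^−15^…2^3^) runs as
an inner 3-fold cross-validation inside the training portion only;
fixed hyperparameters (C = 1, γ = 1/d) are the default because a
100-iteration consistency run would otherwise repeat the search 500
times.

`evaluate_cv()` reports accuracy, the multi-class Matthews correlation
coefficient (the R~K~ statistic computed from the full confusion
matrix, which reduces exactly to the binary MCC at m = 2) and the macro
F-measure as means over the k test folds; per-class precision, recall,
MCC and F come from the confusion matrix pooled over folds, which is
the more stable choice for small classes. Whether per-class tables in
comparable studies pool folds or average per fold is generally
unstated; the package documents its choice rather than guessing.

## The consistency analysis

The screening statistic is not a single CV error but the *consistency*
of misclassification under resampling. `repeated_cv()` runs
`iterations` rounds (default 100) of stratified 5-fold CV, re-drawing
the folds each round from a per-iteration seed, so every sequence is
tested exactly once per round. Three per-sequence statistics follow
(`shortlist()`, or the one-stop `noise_scan()`):

1. **Error rate** ER~s~: the percentage of rounds in which the
   sequence was misclassified in its test fold. Sequences with
   ER~s~ ≥ θ~ER~ = 75% are *selected*.
2. **Voting ratio** R~s~ = VT~s~/VP~s~: total one-vs-one votes for the
   true class over total votes for the modal predicted class, summed
   over all binary classifiers in all rounds (not only the
   misclassified ones — the statistic should reflect the classifiers'
   overall view of the sequence). R~s~ ≤ θ~R~ = 0.5 flags a
   *consistent* error. The modal class is the most frequent predicted
   label; ties go to the tied class with more total votes, then class
   order.
3. **Cumulative decision value** CDV~s~: the sum over rounds of the
   decision value of the single binary classifier confronting the true
   class with the modal predicted class, recorded in every round
   regardless of how that pair fared in the vote. CDV is signed
   (positive toward the true class) and the error is deemed *large*
   when |CDV~s~| ≥ θ~CDV~ = 60 — with 100 rounds that is an average
   margin of 0.6 against the true class.

R and CDV are computed for every sequence (CDV is undefined, NA, when
the modal prediction is correct) but are meant to be interpreted for
selected sequences. A sequence with ER = 100, small R and a large
negative CDV is the archetype of suspected label noise. Because the
statistics depend on the pairwise machinery, they require the SVM
family; ER alone is available for any classifier.

`cross_transform_consensus()` strengthens the evidence: a sequence
shortlisted under several independent representations (composition,
physicochemical, distributed) is a much stronger suspect than one
flagged by a single feature space. `run_pipeline()` therefore shares
the per-iteration fold plans across transforms, so consensus compares
like with like.

## Synthetic validation data

`generate_sequences()` creates collections where the truth is known.
Class residue profiles are a log-linear tilt of a common Dirichlet
base composition, $p_c \propto p_0\exp(\text{separation}\cdot g_c)$
with independent standard-normal tilts $g_c$; `separation` is the
single knob between indistinguishable classes (0: accuracy converges
to 1/m) and cleanly separated ones. We take separation = 3 as the
"strong separation" regime: there the 4-class AAC + SVM accuracy is at
ceiling, so any consistently misclassified sequence is informative.
Sequence lengths are uniform on 120–360 residues by default — short
enough to be cheap, long enough that composition estimates are stable
and any ACC lag up to 13 is well defined. Label noise is injected by
flipping `round(flip_fraction · n)` uniformly chosen records to a
uniformly chosen *different* label; no class-conditional noise model is
attempted because none is established for curated databases.

The default residue model is order-0 (i.i.d. draws from the class
profile): it is the cheapest testbed in which AAC alone separates
classes, while digram/ACC/embedding stages are still exercised
dimensionally and against oracles. `markov = TRUE` switches to a
class-specific first-order chain so digram features also carry class
signal. What the generator deliberately does *not* emulate: domain
architecture, seven-transmembrane topology, phylogenetic correlation
between sequences, alignment-visible motifs, or class-conditional
label noise. Passing the recovery experiment therefore shows the
*screening machinery* is sound — that genuinely mislabeled,
learnably-different sequences are found with high precision and recall
— not that any particular real database has a given noise level.

## Numerical and design choices

* Thresholds θ~ER~ = 75, θ~R~ = 0.5, θ~CDV~ = 60 are defaults of
  `noise_thresholds()`, not constants.
* AAC/digram rows sum to 1 within 1e−9; ACC agrees with a brute-force
  double-loop oracle to 1e−12.
* Binary MCC returns 0 on a degenerate (zero-marginal) denominator;
  the multi-class statistic likewise.
* All randomness (fold draws, tree bootstraps, embedding SGD,
  generation) descends from explicit integer seeds; two runs of the
  pipeline with the same configuration produce byte-identical numeric
  reports.
* Ingest drops whole records containing ambiguity codes (B, J, O, U,
  X, Z) by default rather than stripping residues, because stripping
  biases composition statistics; both policies are available and
  counted.
* The minimum ingest length defaults to 15 = max ACC lag + 2, so every
  lag term has at least two summands.

The test suite and the bundled acceptance script run the recovery
experiment at 4 balanced classes × 100 sequences, 5% flips, 20
repeated-CV iterations, and the chance-level control at 800 sequences —
sizes chosen to make the statistical claims testable in seconds on a
laptop; the statistics themselves are O(iterations · n) and scale to
the hundreds of iterations and ~10^3^ sequences typical of a real
screening run.

## Worked example

```{r example}
gen <- generate_sequences(m = 4, n_per_class = 50, separation = 3,
                          flip_fraction = 0.05, seed = 42)
scan <- noise_scan(gen$sequences, transform = "aac",
                   iterations = 20, seed = 42)
summary(scan)
score_recovery(scan, gen$truth)
```

## Limitations

Screening power comes entirely from class-discriminative signal in the
chosen representation: a mislabeled sequence whose composition happens
to match its (wrong) class is invisible, and a correct but atypical
sequence can be flagged. Small classes are fragile — with fewer than k
members a class cannot even be stratified, and per-class metrics from
pooled confusions remain noisy. The voting ratio is undefined in the
(guarded) degenerate case of a modal class with zero votes, and CDV
requires the pairwise SVM machinery. None of the statistics is a
hypothesis test; the thresholds are screening conventions, not error
rates.
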