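---
title: "Refining contig taxonomy from composition and abundance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Refining contig taxonomy from composition and abundance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxrefiner)
```

## The problem

Taxonomic classifiers annotate assembled metagenomic contigs by sequence
search against a reference database. Their output is imperfect in two ways:
many contigs receive no label, or a label truncated at a shallow rank, and a
minority receive a wrong label. Yet the same dataset carries strong
label-free signal that classifiers ignore: contigs from one genome share a
characteristic tetranucleotide composition, and — in a multi-sample
experiment — a common co-abundance profile across samples. `taxrefiner`
trains a small neural network, per dataset, to predict the classifier's own
labels from these features, then applies it to every contig. Where the
classifier's label is supported by composition and abundance the network
reproduces it with a high score; where it is missing or inconsistent the
network completes or overrides it. No model is transferred across datasets:
the network is a dataset-specific smoother of the classifier's annotation
over the feature space.

## Features

For every contig of at least `min_contig_length` bp (default 2000) we count
all 256 overlapping tetramers over unambiguous bases. Tetramer frequencies
of double-stranded DNA carry linear redundancies: counting is
strand-symmetric, frequencies sum to one, and each trimer occurs as a
prefix of some tetramer exactly as often as it occurs as a suffix (up to
edge effects). The frequency deviation vector therefore lives in the null
space of a stacked linear constraint system — reverse-complement pairing
(120 independent rows), the all-ones row, and 64 trimer-continuity rows —
which has dimension exactly 103. `tnf_kernel()` materializes an orthonormal
basis of that null space by singular value decomposition; projecting the
centered frequency vector onto it yields a 103-dimensional composition
signature that is invariant to strand choice. The projected block is then
z-scaled per dimension across the contigs of the dataset (population
standard deviation; zero-variance dimensions are set to 0, which also
covers the single-contig corner case).

Abundances come in as a contigs × samples mean-depth table computed by
upstream coverage tooling from sorted alignments. Each sample column is
divided by the sample's total mapped reads when supplied — when not, by the
column sum of depths, which preserves the relative scaling and is the only
quantity observable from the table itself. The contig's total abundance is
the row sum taken at this point; the row is then normalized to sum to one,
giving a composition-like profile over samples. A dataset with a single
sample degenerates gracefully: the profile is the constant 1 and all
discriminative abundance information sits in the total. The final feature
table is the concatenation `[z-scaled TNF | per-sample profile | total]`,
of width 103 + Ns + 1. The total-abundance column is passed through
untransformed.

## The taxonomy tree and the hierarchical loss

The output space is the tree of taxa actually observed in the classifier's
annotations — a subgraph of the full taxonomy. Lineages are contiguous
prefixes of the seven-rank ladder (domain … species); nodes are keyed by
full path, so homonymous names under different parents remain distinct
taxa. Leaves are the childless nodes and are indexed in lexicographic
full-path order, which makes the output-unit assignment reproducible.

The network emits one logit per leaf. A softmax turns the logits into leaf
likelihoods; the likelihood of an internal node is the sum over its
descendant leaves, computed through a sparse 0/1 leaf-to-node incidence
matrix so gradients flow only through the softmax. A contig annotated to
node `t` contributes the summed negative log-likelihood along the ancestor
path of `t`, the node itself included. This is what lets annotations of
*every* depth train the same model: a genus-level annotation constrains the
sum of its species' likelihoods without asserting any particular species.
Likelihoods are clamped at 1e-12 before the log so that an (empirically
rare) all-mass-elsewhere batch cannot produce an infinite loss.

Decoding is greedy and top-down: starting at the root, the child of the
current node with the highest likelihood is selected; it is emitted with
its likelihood as the score if that likelihood is strictly greater than
0.5, otherwise decoding stops and this rank and all deeper ranks stay
unannotated. Since sibling likelihoods sum to at most the parent's, at most
one child can exceed 0.5, the greedy choice is unambiguous wherever
anything is emitted, and scores are non-increasing with depth — every
emitted prefix is contiguous and every score lies in (0.5, 1]. Ties (a
measure-zero event) resolve to the first child in path order. Whether the
boundary case of exactly 0.5 should emit is unobservable in practice; we
use the strict inequality. Greedy selection is among children of the
current node rather than among all nodes of a rank; the two differ only
when likelihood mass splits across non-sibling subtrees, where the 0.5
threshold suppresses output anyway.

## Network and training

Four fully connected hidden layers of 512 units, each followed by batch
normalization (epsilon 1e-5, momentum 0.1), leaky ReLU (negative slope
0.01) and dropout (p = 0.2); a linear output layer of width equal to the
leaf count. Training runs 100 epochs at batch size 1024 by default with
Adam at a fixed learning rate of 1e-3 — a deliberately plain optimizer
choice; adaptive learning-rate schemes are an orthogonal refinement and a
fixed rate converges comfortably at these problem sizes. The batch size is
reduced automatically when the training set is smaller than the configured
batch. There is no early stopping and no held-out validation split in a
standard refinement run: the full annotated set trains for exactly the
configured epochs, and the k-fold protocol below is the only splitting
mechanism. All randomness — weight initialization, epoch shuffling, dropout
masks — derives from the single configured seed, so a rerun with the same
seed and configuration reproduces the predictions byte for byte on a fixed
BLAS thread count.

The engine is written directly on R's BLAS-backed matrix algebra, with
activations stored units × batch so per-unit operations recycle without
copies. Two numerical conventions to note: batch normalization uses the
population (1/N) variance both for normalization and for the running
inference statistics, and a size-one batch falls back to variance zero
(the epsilon keeps it finite). Initialization is uniform in
±1/sqrt(fan-in).

## K-fold self-consistency

When ground truth is unavailable, classifiers can still be ranked by how
*reproducible* their labels are from the features alone. The annotated
contigs are split into five balanced folds; for each fold the refiner is
trained on the other four — with the tree rebuilt from the training
annotations only, so held-out label identities cannot leak into the output
space — and predicts the held-out fold at score threshold 0.5. The
concatenated held-out predictions are scored against the classifier's own
annotations with `precision = TP/(TP+FP)` and `recall = TP/(TP+FP+FN)`;
note the benchmark convention of counting FP in the recall denominator,
which makes this recall a lower bound on the textbook one. A held-out
annotation absent from the training-fold tree is counted as a false
negative: the model cannot emit a label it has never seen, and penalizing
its replacement as an FP would double-count the same unreachability.
Against ground truth, the default operating point for filtering
predictions is a score threshold of 0.95; `ground_truth_report()` sweeps
the threshold grid to produce the full precision–recall table.

## The synthetic community

All tests run on generated data, so the generator is a first-class module.
Its default community — 8 species in 2 genera and 2 families under one
order, 3 samples, 50 contigs per species of 2–6 kb — is the smallest
configuration that exercises every moving part: multi-level tree, sibling
species for confusion structure, a multi-sample abundance block, and
enough contigs per species for the network to generalize past label noise.
Base compositions are drawn hierarchically (family from a Dirichlet with
concentration 8 around uniform, genus around family and species around
genus with concentration 150), so sibling species are compositionally
closer than distant ones, mirroring real genomes; sequences are i.i.d.
draws from the species composition. Species abundances are log-normal
(sigma 1) per sample around a log-normal species baseline, with log-normal
per-contig noise (sigma 0.25). The label corrupter emulates classifier
failure modes: dropped lineages, rank-truncated lineages, and species
mislabels that prefer a same-genus sibling with probability 0.5.

What the generator does *not* emulate — and hence what passing tests do not
establish about real data: within-genome compositional heterogeneity,
assembly artifacts and chimeras, shared k-mer content between unrelated
taxa, uneven genome sizes, and read-mapping biases in the depth table.
Fixture-scale results demonstrate the mechanics of the method, not its
field accuracy.

At fixture scale the training regime is 50 epochs at batch size 256 —
about half a minute per fit on one CPU — which reaches training losses
below 0.02 on the default community; the k-fold and recovery experiments
in the test suite use exactly these conditions. Two properties measured
there: refined labels at threshold 0.5 agree with the uncorrupted truth on
more contigs than a 20%-corrupted, 20%-truncated input does, and five-fold
consistency precision cleanly separates a 5% from a 40% corruption level
(about 0.80 versus 0.41 species-level precision in a representative run).

## Novel taxa

A species present in the data but absent from the reference database can at
best be recovered at genus level. `species_deletion_experiment()` emulates
this: the annotations of all contigs of the named species are truncated to
genus, the model is retrained (the species leaves the output space), and
the affected contigs are re-predicted. The report gives the fraction
recovering the correct genus, the fraction incorrectly assigned some other
species (the false-positive share; its complement is the share of correctly
missing labels), the most frequently assigned species, and the Pearson
correlation of mean feature vectors between the deleted and the assigned
species — the diagnostic for *why* absorption happens: it is driven by a
prevalent or feature-correlated sibling in the training set.

## Known limitations

* Contigs shorter than the minimum length are excluded outright rather
  than down-weighted; very short contigs have too noisy a tetramer
  signature for the projection to be informative.
* Lineages with missing intermediate ranks (species known, family absent)
  are rejected rather than patched; reconciling them is the job of the
  upstream label converter.
* The refiner smooths toward the majority annotation per feature-space
  region; a classifier that is consistently wrong about a clade will be
  confidently reproduced, not corrected — consistency is not correctness.
* Single-sample datasets lose the abundance-profile block's discriminative
  power and lean almost entirely on composition.
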