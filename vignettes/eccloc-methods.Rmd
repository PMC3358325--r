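---
title: "Multi-label protein localization with eccloc: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-label protein localization with eccloc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eccloc)
```

## The problem

Eukaryotic proteins can occupy several subcellular locations at once. A
localization dataset is therefore a binary matrix over N proteins and L
locations rather than a single class column, and two bookkeeping quantities
recur everywhere: N(seq), the number of distinct proteins, and N(loc), the
number of *locative proteins* — (protein, location) pairs, so a protein with
multiplicity k contributes k of them. The widely used 22-location eukaryotic
benchmark this package's protocol is modelled on has N(seq) = 7,766 and
N(loc) = 8,897 (multiplicities 1–4); `euk22_locations()` and
`euk22_multiplicity()` carry that breakdown, and the package's accounting
identities (N(loc) equals both the sum of per-location counts and the
multiplicity-weighted sum) are exercised in the test suite.

## Feature extraction

### GO homology transfer

The primary representation of a query protein P is built from the GO
annotations of its homologs:

1. all GO ids appearing in the annotation corpus are renumbered into a
   compact index `1..K` (`build_go_index()`);
2. a hit table in tabular-BLAST form is filtered to hits with E-value
   ≤ `evalue_max` and percent identity ≥ `identity_min`, with P's own
   accession excluded (`filter_homologs()`); the survivors are P's
   *homology set* of size M;
3. component u of the feature vector is the fraction of the M
   representatives annotated with term u (`go_feature_vector()`).

Each component is an average of 0/1 indicators, hence lies in [0,1] and
equals 1 exactly when every representative carries the term. When M = 0, or
no representative carries any indexed term, the vector is undefined
("naught or meaningless") and the protein is routed to the backup
representation.

Two filter parameters matter:

* `identity_min` (percent, default **60**, inclusive `≥`): homology-transfer
  practice treats the stated identity level as a lower bound, and the
  inclusive comparator keeps a hit at exactly 60%.
* `evalue_max` (default **1e-3**): a conventional cutoff for confident
  BLAST homology transfer; exposed as a flag because corpora differ.

The GO index is ordered lexicographically by GO id. Only the bijection
matters downstream — any deterministic, corpus-independent ordering yields
the same model up to column permutation — and lexicographic is reproducible
without reference to any particular GO release.

### Dipeptide composition backup

`dipeptide_composition()` maps a sequence to 420 components: the 20
amino-acid composition fractions (alphabetical A..Y) followed by the 400
dipeptide fractions in the enumeration AA, AC, …, YY, counted over adjacent
pairs (N−1 windows). Each block sums to 1 for pure-standard sequences.
Ambiguity codes (B, J, O, U, X, Z) are legal in input sequences but excluded
from numerators and denominators, and any window containing one is dropped;
remapping them to standard residues would invent equivalences the data does
not support. A sequence with no standard residue, or no standard adjacent
pair, has no defined composition and is an error.

`select_representation()` implements the routing. The default `fallback`
mode uses GO when defined and dipeptide composition otherwise, which is the
reading of the method's description; a `concat` mode (single K + 420 vector,
GO part zero-filled when undefined) is also provided since the hybrid
variant is a natural alternative. Both are first-class; `fallback` is the
default.

## Multi-label classification

The base learner is a linear L2 max-margin classifier (a linear-kernel SVM,
`C = 1` by default), collapsed after fitting to its affine decision
`f(x) = x·w + b`; this makes models exactly serializable as text and keeps
prediction trivially deterministic. A label column with a single class in
its (sub)training set yields a constant learner of that class — common and
harmless when locations with ten proteins meet subsampling. A
nearest-centroid learner satisfying the same contract is included for
hand-checkable fixtures.

* **Binary Relevance** (`train_br()`): one classifier per location,
  positives = proteins in that location, negatives = all others; predicted
  sets are unions of firing classifiers.
* **Classifier Chain** (`train_cc()`): classifiers along a permutation of
  the labels, each consuming the 0/1 associations of all previous chain
  positions — ground-truth bits at training time, the chain's own predicted
  bits at prediction time (standard CC semantics).
* **ECC** (`train_ecc()`): `m` chains, each with a random permutation and a
  random row subset; per-label votes averaged into W ∈ [0,1]^L (entries are
  multiples of 1/m) and thresholded.

Parameters and their defaults:

| parameter         | default | why |
|-------------------|---------|-----|
| `m`               | 10      | the customary ensemble size in the classifier-chains literature; gains flatten quickly beyond it |
| `threshold`       | 0.5     | ensemble majority; the decision is inclusive (`W ≥ t`) so a tie at the threshold counts as evidence for the label |
| `subset_fraction` | 0.67    | without-replacement sampling at two-thirds, matching the sampling scheme of the ensemble-of-chains literature |
| `C`               | 1       | the standard linear-SVM default; features are already on [0,1] scales |

Every empty predicted set falls back to the top-scoring label (ties to the
lowest index): every protein in the intended datasets has at least one
location, so an empty answer is never right.

All randomness (permutations, subsets, fold assignment) derives from a
single integer seed; chain permutations and subsets are drawn before any
fitting so the draws depend only on the seed. Fixed data, configuration and
seed give byte-identical predictions, and a saved model (JSON with
17-significant-digit numbers, which round-trip IEEE doubles exactly)
reproduces them after loading.

## Evaluation protocol

`jackknife_predict()` implements leave-one-out as the reference protocol,
with a K-fold variant for desk-scale work (K = N reproduces the jackknife).
Feature routing is label-free: the GO index is built once from the
annotation corpus and each protein's own accession is excluded from its
homology set, so feature bundles are computed once and only the classifiers
are refitted per fold. Rebuilding the index per fold would change nothing
but column order.

Two scorers:

* `locative_success()`: per-location recall over that location's proteins,
  the unweighted average over locations, and the overall rate over N(loc).
  Average and overall answer different questions — the average weights a
  10-protein location as heavily as a 2,320-protein one — and the gap
  between them is itself diagnostic of how balanced a predictor is.
* `exact_match()`: a protein scores 1 only when its predicted set equals its
  true set, with no under- or over-prediction; reported by multiplicity and
  overall. Note exact match is *not* bounded by the locative rate in
  general; the two orderings can go either way.

Both overall rates are size-weighted means of their groupwise rates; the
identities are property-tested on random prediction maps.

## The synthetic world generator

`gen_multilabel_world()` emulates the statistical structure the pipeline
consumes, so every stage is testable offline:

* **labels** — independent Bernoulli(`label_prob` = 0.4) per location, an
  exact copy pair, or a noisy copy (flip probability `flip_prob` = 0.1),
  resampled until every protein has ≥ 1 location as in the real benchmarks;
* **annotation world** — `n_go_terms` = 60 terms, 5 informative per label;
  each homolog of a protein carries each informative term of the protein's
  true labels with probability `enrichment` = 0.9 plus background terms with
  probability `background` = 0.05 — a strong but noisy homology signal;
* **hit table** — 2–6 homologs per protein with identities uniform on
  [40, 95] and e-values log-uniform on [1e-50, 1], deliberately straddling
  the 60% and 1e-3 cutoffs so both filter branches are exercised and a
  realistic minority of proteins genuinely falls back to dipeptide
  composition;
* **sequences** — i.i.d. residues, lengths 50–120 (minimum 2 so the backup
  representation is always defined).

One conditioning subtlety: requiring ≥ 1 label makes nominally independent
labels negatively dependent (for two Bernoulli(0.5) labels the admissible
patterns 10/01/11 are each exactly 1/3, a correlation of −0.5). The tests
assert that conditional law rather than pretending the constraint away.

What the generator does *not* emulate: real sequence evolution (residues are
i.i.d., so dipeptide composition carries no location signal in synthetic
worlds — which is precisely what makes the GO/DC routing visible in tests),
the GO DAG and annotation propagation, shared homologs between proteins, and
redundancy structure. Passing tests therefore demonstrate the correctness of
the machinery and the claimed statistical behaviours (e.g. that chains
recover label correlations), not field performance on Swiss-Prot-scale data.

## Verification problem sizes

The test suite and the acceptance script size their simulations for a
laptop-class single core: reduction equivalences on 50 fixtures of 24
samples; the dipeptide oracle on 1,000 random sequences; the ECC-versus-BR
comparison on noisy-copy worlds of 300 proteins under 10-fold
cross-validation across 10 seeds (ties count for the ensemble, as the claim
is "at least as good"); and the noiseless-separability jackknife on 50
proteins, where enrichment 1 and background 0 make the GO vectors exactly
separable and the locative rate is 1 by construction. Published
whole-benchmark success rates are not recomputable here: they depend on
specific Swiss-Prot and GOA releases and on BLAST searches against them.

## Known limitations

* The GO vector ignores the ontology graph: no ancestor propagation or
  evidence-code filtering; terms are treated as atomic symbols.
* `concat` mode mixes a K-dimensional sparse block with a 420-dimensional
  dense block without re-weighting; with very large K the GO block can
  dominate the margin geometry.
* The jackknife refits classifiers per fold but shares feature bundles;
  if a user's hit table contains the training proteins themselves as
  subjects, self-information removal is limited to each query's own
  accession (the documented exclusion).
* Vote shares are not calibrated probabilities; `threshold` trades recall
  against precision of the predicted sets and is exposed for that purpose.
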