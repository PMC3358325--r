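# eccloc

Multi-label subcellular localization of eukaryotic proteins with Ensembles of
Classifier Chains.

Many proteins do not sit in a single compartment: they simultaneously exist
at, or move between, two or more subcellular locations, and classical
single-location predictors cannot represent that. `eccloc` is an R toolkit for
the multi-label formulation of the problem, aimed at computational biologists
who want to train, evaluate and dissect GO-homology-transfer localizers
offline, on their own data or on fully synthetic worlds.

## The method

A dataset of N proteins over L locations is a binary matrix **Y** ∈ {0,1}^(N×L)
with `y_ij = 1` when protein *i* resides in location *j*; row sums are the
protein *multiplicities*, and the sum of all entries is the number of
*locative proteins* N(loc) (a protein in k locations counts k times).

**Features.** For a query protein P, its *homology set* is the set of subject
accessions from a tabular BLAST-style hit table passing an E-value cutoff
(default 1e-3) and ≥ 60% pairwise identity, excluding P itself. With the GO
terms of a corpus renumbered into a compact index 1..K, the GO
homology-transfer vector of P has component

    a_u = (# representatives annotated with term u) / M,   u = 1..K,

where M is the homology-set size. When M = 0, or no representative carries an
indexed term, the vector is undefined and the protein falls back to its
**dipeptide composition**: a 420-dimensional vector whose first 20 components
are the amino-acid composition (A..Y) and whose remaining 400 components are
the fractions of the dipeptides AA, AC, …, YY over adjacent residue pairs.

**Classifier.** Binary Relevance (BR) trains one linear max-margin classifier
per label and unions the positive predictions. A Classifier Chain (CC) links
the L classifiers along a random label permutation, feeding each classifier
the 0/1 outputs of all previous chain positions, which lets it exploit
correlations between locations. The Ensemble of Classifier Chains (ECC)
trains m chains (default 10), each on a random permutation and a random
subset of the training rows; per-label votes are averaged into W ∈ [0,1]^L
and the predicted set is {j : W_j ≥ t} (default t = 0.5), with a non-empty
fallback to the top-voted label.

**Evaluation.** The reference protocol is the jackknife (leave-one-out),
scored two ways: *locative* success (per-location recall, its unweighted
average, and the overall rate over N(loc) pairs) and *exact match* (credit
only when the predicted set equals the true set, reported by multiplicity).

## Worked example

```r
library(eccloc)

# a synthetic world: 60 proteins, 3 locations, homologs whose GO terms are
# enriched for the informative terms of each protein's true locations
world <- gen_multilabel_world(sim_spec(n_proteins = 60, n_labels = 3, seed = 7))

model <- train_localizer(world, localizer_config(m = 10, seed = 3))
model
#> <localizer> ECC / fallback mode, 3 locations; routes: DC=3, GO=57

res <- jackknife_predict(world, localizer_config(m = 10, seed = 3), folds = 5)
glance(res$report)
#> # A tibble: 1 × 5
#>   n_seq n_loc average_rate overall_locative_rate overall_exact_match
#>   <int> <int>        <dbl>                 <dbl>               <dbl>
#> 1    60    91        0.978                 0.978                0.95
```

57 of the 60 proteins had at least one usable homolog and took the GO route;
3 fell back to dipeptide composition. Of the 91 locative proteins (some
proteins occupy two or more locations), 97.8% were recovered by the held-out
models, and 95% of proteins had their location set predicted exactly —
high because this synthetic world's homology signal is strong.
`tidy(res$report)` gives the per-location and per-multiplicity tables and
`autoplot(res$report)` plots the per-location rates.

The same pipeline is scriptable from a shell via `inst/cli/eccloc`
(subcommands `simulate`, `train`, `predict`, `evaluate`).

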