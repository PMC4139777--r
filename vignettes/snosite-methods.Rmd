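---
title: "Predicting cysteine S-nitrosylation sites: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting cysteine S-nitrosylation sites: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

S-nitrosylation (SNO) is a reversible post-translational modification in
which nitric oxide attaches covalently to the thiol group of a cysteine.
`snosite` predicts, from sequence-derived information alone, whether a given
cysteine in a protein is an SNO site. This vignette explains the model, its
tunable parameters, the numerical choices made where the procedure left room,
and what the package's synthetic-data tests do and do not establish.

## The representation

Every candidate site is a peptide window of `2ξ + 1` residues centered on a
cysteine (default `ξ = 10`, i.e. 21-mers). Positions that fall outside the
protein are padded with the dummy residue `X`. Coordinates are 1-based, the
convention of experimental site databases.

Each window is encoded as a 458-dimensional vector from three sources:

* **Evolutionary conservation (400 features).** A PSI-BLAST position-specific
  scoring matrix (PSSM) computed on the *full* protein supplies, for each
  sequence position, 20 integer log-odds substitution scores. For a window,
  the profile rows at its non-X positions are accumulated by the residue type
  at that position into a 20 × 20 matrix: entry `(i, j)` is the *sum* of the
  scores of window residues of type `i` being substituted by type `j`. The
  matrix is flattened row-major. Sums (not means) are used deliberately: the
  cell magnitude then carries how often a residue type occurs in the window
  as well as how conserved it is. Only the signed log-odds columns of the
  PSSM file are used — the trailing weighted-percentage columns are
  non-negative frequencies and do not express the favoured/disfavoured
  distinction the encoding aggregates. A fully padded position contributes
  nothing, so the encoding is linear over window positions.
* **Predicted secondary structure (9 features).** A per-residue H/E/C string
  (helix/strand/coil, e.g. from PSIPRED) is sliced to the window's non-X
  positions, and for each state the total residue count, the average maximal
  run length (0 when the state is absent, avoiding 0/0), and the composition
  (count over slice length) are computed. Statistics are window-local, not
  protein-global, and a run truncated by the window edge counts as one run
  of the slice.
* **Physicochemical properties (49 features).** For each of 49 per-residue
  property scales, the window value is the mean over non-X residues. X
  positions are excluded from both numerator and denominator; including them
  as zeros would bias windows near protein termini toward 0. The bundled
  table (`physchem_properties_synthetic.csv`) is a synthetic stand-in: seven
  standard published scales (Kyte–Doolittle hydropathy, residue mass,
  Zamyatnin volume, Grantham polarity, isoelectric point, Chou–Fasman helix
  and sheet propensities) plus 42 deterministic synthetic scales. The encoder
  contract — any valid 49 × 20 table with one-letter-code headers — is what
  the package tests; substituting a curated table changes feature values,
  not behaviour.

All matrix-valued objects share one canonical amino-acid column order
(alphabetical by one-letter code). PSSM files, which natively print
`A R N D C ...`, and user property tables in any order are re-mapped by
their header letters at parse time.

## Feature selection

Concatenating heterogeneous encoders invites redundancy and noise, so
features are filtered in two stages.

**Symmetric relative entropy ranking.** Each feature is scored by
`D(P‖Q) + D(Q‖P)`, the symmetrised Kullback–Leibler divergence between its
class-conditional distributions. The estimator is left open by the
procedure's description, so the package fixes one: both densities are
histograms over *shared* equal-width bins spanning the pooled min–max range
(default 20 bins), with an additive pseudocount of 1 per bin. Shared edges
make the estimate symmetric in its inputs; the pseudocount keeps every bin
positive so the divergence is finite even when one class never visits a bin.
Scores are reported in nats. Ties are broken by ascending original column
index, making the ranking deterministic. A feature constant across both
classes scores exactly 0.

**Incremental feature selection (IFS).** Features are added one at a time
from the top of the ranked list; for each prefix size a k-nearest-neighbour
classifier is evaluated by stratified 10-fold cross-validation and the
fold-mean MCC recorded. The optimal subset is the prefix maximising mean
MCC, smallest size among ties (the cheaper model wins a draw). Two choices
here were genuinely open:

* One fold partition is drawn once (seeded) and reused across all prefix
  sizes, so the IFS curve reflects feature-set changes only, not partition
  noise.
* Features are z-scored with training-fold statistics before computing
  distances. The three encoders live on very different scales — PSSM sums
  range over hundreds, compositions over `[0, 1]` — and unstandardised
  Euclidean distance would be dominated by the evolutionary block.

The sweep shares squared-distance accumulations across nested prefixes in a
compiled kernel, so evaluating all 458 prefixes costs a single pass over the
features per fold rather than 458 independent runs.

## Classification and evaluation

The classifier is k-nearest-neighbour with Euclidean distance and majority
vote (default `k = 9`, the selected operating configuration). The prediction
score is the fraction of positive neighbours; a query is called positive
when the score exceeds 0.5. With the odd default `k` no vote can tie; if a
user overrides `k` to an even value, an exact 0.5 vote resolves to negative,
the conservative call for a site predictor. Distance ties at the k-th rank
are broken by lower training-row index, so predictions are deterministic
across runs and platforms.

Performance is summarised by sensitivity, specificity, accuracy and the
Matthews correlation coefficient; MCC is the headline number because SNO
datasets are imbalanced. Cross-validation is stratified (plain random
splitting can starve a fold of the minority class on imbalanced data) and
aggregates by averaging per-fold metrics; pooled-confusion aggregation is
available as an option. A metric whose denominator is zero is reported as 0
with a `degenerate` flag rather than raising, which keeps IFS sweeps over
uninformative prefixes running.

## The synthetic-data generator

Real inputs require PSI-BLAST and PSIPRED runs, so the package ships a
generator making every stage testable offline, at two levels.

`generate_protein_set()` emulates the input *formats*: random proteins over
the 20-letter alphabet (cysteines at a configurable rate, at least one
forced per protein), an integer profile matrix per protein written in the
PSI-BLAST ASCII dialect, H/E/C strings with geometric-ish run lengths
written as `.ss2`, and random 0/1 labels over all cysteines. These fixtures
are format-faithful but content-free: scores are independent uniform draws
with none of the conservation structure, sequence motifs or label signal of
real data. Tests built on them establish parsing, indexing, padding and
plumbing correctness — not biological validity.

`generate_feature_dataset()` emulates the *statistics* the selection and
classification stages consume: standard-normal features with a planted
mean-shift on a random subset. `effect_size` is defined as the Euclidean
separation between the class mean vectors in within-class-sd units, split
evenly over the informative features (each gets
`effect_size / sqrt(n_informative)`). The vector reading keeps the overall
problem difficulty fixed as the number of informative features varies; a
per-feature reading would make the problem trivially separable after 3–4
features at realistic effect sizes, collapsing the IFS optimum below the
planted subset by construction. With `effect_size = 0` the construction is
an exact label-permutation null.

Defaults mirror the method's operating conditions: 731 positive and 810
negative samples (the size of a typical curated SNO training set), 458
features, `ξ = 10`, `k = 9`, 10 folds, 20 bins.

## Problem sizes used in the checks

The feature-recovery experiments (5 informative features, effect size 3)
run at 200 + 200 samples per seed over 20 seeds; at that size the accuracy
gain from the 4th to the 5th informative feature is large relative to fold
sampling noise, so the IFS optimum should contain the planted subset in at
least 90% of seeds. The null-behaviour check runs at the default 731 + 810
over 5 seeds, where the standard error of a 10-fold mean MCC under the null
is about 0.026, comfortably inside the ±0.1 band asserted. Oracle-agreement
checks compare the classifier against an exhaustive distance-sort
re-implementation on random fixtures up to 500 samples and the full
458-feature width.

## Known limitations

* The package does not run PSI-BLAST or PSIPRED; profiles and structure
  strings are inputs. Predictions on proteins without them are not possible.
* The bundled property table is a labelled synthetic stand-in (above);
  users reproducing published property-based results should supply their own
  curated 49 × 20 table.
* The symmetric-KL estimator's bin count (20) and pseudocount (1) are
  package defaults, not claims about the original procedure, which does not
  specify its density estimator; both are configurable.
* Cross-validation splits at the site level by default, so windows from one
  protein can land in different folds. `cross_validate(split = "protein")`
  keeps each protein's windows together, which is stricter against homology
  leakage at the cost of exact class stratification.
* Synthetic fixtures carry no SNO motif biology. Passing tests demonstrate
  the machinery is correct and reproducible, not that the defaults transfer
  to any particular organism or dataset.
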