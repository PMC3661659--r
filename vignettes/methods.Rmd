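---
title: "Per-term SVM prediction of GO annotations: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Per-term SVM prediction of GO annotations: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funpred)
```

## The problem

A large fraction of eukaryotic proteins has no experimentally supported
functional annotation and no close homologue of known function, so
annotation transfer by sequence similarity cannot reach them.  funpred
implements the alternative strategy of learning, for each Gene Ontology
(GO) term, a binary classifier that maps sequence-derived biophysical
features — residue composition, predicted disorder, secondary structure,
signal peptides, localization signals, post-translational modification
sites and so on — to the posterior probability that a protein carries the
term.  The unit of modelling is one GO term of the molecular function
(MF) or biological process (BP) namespace; a model library is the
collection of all per-term classifiers that survive quality control.

## Training recipe

**Eligibility.**  A term is modelled only when (i) it appears in the
supplied curated vocabulary, (ii) at least 150 proteins are annotated
with the term or any descendant (following both `is_a` and `part_of`),
and (iii) at least 500 proteins qualify as negatives: not annotated with
the term, its descendants or its ancestors, yet carrying at least two MF
and two BP annotations whose evidence is not merely curatorial or
electronic (codes IC, NAS, TAS, IEA are excluded).  The corpus itself is
first restricted to sequences of at most 1,500 residues and reduced to
representatives below 90% pairwise identity (the redundancy reducer is
an interface; the built-in k-mer containment clusterer is adequate for
fixtures, production users plug an external clusterer).

**Homology-aware partition.**  Each positive and negative set puts 30%
aside as a holdout.  The remainders are split into k equal-size groups
(sizes differing by at most one), where k is the largest value giving
every group at least 35 proteins in *both* sets.  Groups are formed by a
balanced K-medoids algorithm over pairwise alignment E-value distances
(minimum over both orderings and all reported alignments, capped at 10,
missing alignments at the cap), so cross-validation folds do not share
close homologues.  Positives and negatives are clustered separately on
their own distance submatrices with the same k — the procedure is
defined per set, and joint clustering would let one set's structure
distort the other's groups.  The balance constraint is enforced by
greedy margin-ordered assignment to the nearest non-full medoid,
alternated with medoid updates and pairwise swap refinement until
stable (at most 100 iterations); all ties break on accession order, so
partitions are byte-reproducible given the seed.

**Model selection.**  For every kernel configuration (linear with cost
C; RBF with C and gamma) a k-fold cross-validation trains on k−1 groups
and tests on the held-out group, with feature scaling fit inside each
training fold and the error weight on positives set to the ratio of
negative to positive training examples.  Performance is the Matthews
correlation coefficient (MCC) computed from the confusion counts pooled
across folds — pooling keeps the estimate stable when folds are small,
which is why it is preferred here over averaging per-fold MCCs.  Feature
groups (14 named groups; a group is kept or dropped as a whole) are
pruned by a single greedy pass in registry order: a group stays removed
only when the best grid MCC strictly improves without it, so the
returned configuration never scores below the all-groups baseline and
ties never remove information.  Grid ties break deterministically:
linear before RBF, then smaller C, then smaller gamma.

**Quality control and calibration.**  The selected configuration is
refit on all k groups and evaluated once on the 30% holdout: terms with
holdout MCC below 0.05 are discarded; surviving models are flagged
"H" (higher reliability) when MCC, sensitivity, specificity and
precision all exceed 0.3, 0.3, 0.7 and 0.3, else "L".  Surviving terms
are then refit on *all* examples (holdout included): the pooled sets are
re-partitioned into k groups, kernel parameters are re-optimised at
fixed kernel type and feature list, and the final classifier trains on
everything.  Decision values from that final k-fold run — never
resubstitution values, which would bias the fit — feed a Platt sigmoid
`P(y=1|f) = 1/(1+exp(A f + B))`, maximising the regularised likelihood
with smoothed targets `(N+ + 1)/(N+ + 2)` and `1/(N- + 2)` by damped
Newton iteration with backtracking (the numerically robust variant of
the classic procedure).  A model's reported quality is the earlier
holdout estimate: the final classifier's own error cannot be measured
without spending data, so it is estimated by the pre-refit holdout.
At prediction time a term is *displayed* when its posterior exceeds 0.5;
the full posterior list is always reported, H-tier rows first, then by
decreasing posterior.

## Assessment suite

**CAFA-style precision-recall.**  Predicted and reference term sets are
propagated to `is_a` ancestors (roots excluded), ancestors inheriting
the maximum confidence of their scored descendants.  At threshold v,
per-protein precision is averaged over the n_v proteins with at least
one prediction scored ≥ v, while per-protein recall is averaged over the
whole reference set; Fmax is the maximum F-measure over the sweep of
observed confidence values plus 0 and 1.

**Relaxed matching.**  A variant with no propagation on either side: a
prediction counts as correct when it equals, or is an `is_a` ancestor or
descendant of, a reference annotation.  Each predicted term is counted
once (set semantics) even when it matches several references; false
negatives are references matched by no sufficiently confident
prediction.  This variant credits correct-but-generic and compatible
predictions that exact matching penalises.

**simGIC and COGIC.**  Term specificity is measured by information
content, `IC(y) = -log f(y)`, where `f(y)` is the frequency of proteins
annotated with y or any descendant among proteins with at least one
annotation in y's namespace — this denominator keeps `f(root) = 1` per
namespace, hence `IC(root) = 0` exactly.  The natural logarithm is used;
simGIC is a ratio of IC sums, so the base cancels.  Terms never seen in
the reference corpus get infinite IC and are excluded from simGIC sums.
simGIC of two propagated sets is the IC mass of their intersection over
that of their union.  COGIC splits a protein's predictions into four
nested subsets at confidences ≥ 0.75, 0.50, 0.25 and 0, propagates each
subset and the reference, and combines the four simGIC scores with
positive, strictly decreasing weights summing to 1.  The default weights
are (8, 4, 2, 1)/15 — chosen to satisfy the score's contracts (range
[0,1]; 1 iff all predictions are validated at confidence ≥ 0.75; 0 iff
only the root is shared; higher credit to confident correct
predictions) and configurable, since any positive decreasing
normalised weight vector honours the same contracts.  Summaries use
lower-interpolation (inverse-ECDF) order statistics so the reported
median is always an observed score.

## Tunable parameters

| parameter | default | units / range | role |
|---|---|---|---|
| `max_length` | 1500 | residues | corpus length cap |
| `identity` | 0.90 | fraction | redundancy threshold |
| `holdout` | 0.30 | fraction | final-validation split |
| `min_group` | 35 | proteins | minimum CV group size |
| `min_pos`, `min_neg` | 150, 500 | proteins | term eligibility |
| `discard_mcc` | 0.05 | MCC | holdout discard rule |
| reliability thresholds | 0.3, 0.3, 0.7, 0.3 | MCC/sens/spec/prec | H tier |
| display threshold | 0.5 | posterior | report display rule |
| COGIC strata | 0.75, 0.50, 0.25, 0 | confidence | stratum cut-offs |
| COGIC weights | (8,4,2,1)/15 | — | stratum combination |
| grid | C ∈ 2^{−5..7}, gamma ∈ 2^{−9..1} (step 2²) | — | hyper-parameter search |
| E-value cap | 10 | E-value | distance ceiling |

## The synthetic fixture generator

The generator emulates every input the pipeline reads: a two-namespace
ontology (rooted DAGs with `is_a` and `part_of` edges and a diamond
motif), a proteome of random sequences, an annotation table with a
configurable evidence-code mix, a feature matrix, and a block-structured
homology distance matrix.  Default study conditions: two 12-term
namespaces, 700 proteins, three signal terms and one noise term with 150
positives each, signal strength 0.9, three homology blocks, 5% of
proteins electronic-only (their annotations all IEA, so they fail the
negative-example rules and the eligibility filters are genuinely
exercised), provider feature groups of dimension 4.

Signal is planted as `(1−s)·noise + s·(±1)` in one dedicated feature
group per signal term, so strength s = 1 is linearly separable by
construction and s = 0 carries no information.  Strength 0.9 is
deliberately strong: the end-to-end tests are meant to probe the
selection machinery (elimination, discard, reliability tiers), not the
capacity of the classifier.  The noise term's positives are stratified
over the joint membership cells of the signal classes, making the noise
label exactly orthogonal to every planted signal in the realised
fixture rather than only in expectation; without this, chance overlap
between planted sets injects a weak real signal into the "noise" term.

What the generator does *not* emulate: realistic GO topology statistics,
sequence evolution, correlated features within predictor groups, or
annotation incompleteness.  Passing tests therefore demonstrate that the
machinery implements its rules correctly under controlled conditions —
not that any particular accuracy level will be reached on real
proteomes.

## Numerical choices and degenerate inputs

* MCC is defined as 0 whenever a factor of its denominator vanishes, and
  0/0 performance ratios are reported as 0.
* Min-max scaling is fit on training rows only; test values are clipped
  to [0, 1]; constant columns map to 0.
* When no k ≥ 2 satisfies the group-size rule the term trains with k = 1
  (no cross-validation) under a warning — unreachable for eligible terms
  but the path exists.
* Obsolete-term mapping resolves only unique replacements (via
  `replaced_by` or a unique reverse `alt_id`); ambiguity returns absent
  and the caller discards.
* All stochastic steps derive per-term seeds by hashing the term id with
  the master seed, and every tie (grid, medoid, assignment) breaks
  deterministically, so identical inputs and seed give byte-identical
  outputs.

## Problem sizes used by the test suite

The shipped tests run the full pipeline at the default fixture scale
(700 proteins, 150/500-capacity sets) over 20 master seeds with a
reduced hyper-parameter grid (linear C ∈ {0.1, 1}; RBF C = 1,
gamma = 0.1) — a grid small enough that the planted signal's
separability, not search breadth, decides the outcome, which is the
property under test.  Oracle-equivalence checks use 1,000 random
confusion tables, random DAGs up to 50 nodes, and brute-force
precision-recall enumeration on instances of up to 5 proteins; recovery
checks use 10,000 calibration points and 100 seeded block-recovery runs.

## Known limitations

* The twelve predictor-backed feature groups are provider contracts;
  the package ships no secondary-structure, disorder or localization
  predictors, only the native composition and global sequence-feature
  groups.
* Posteriors are calibrated per term and are not hierarchically
  consistent: a child's posterior may exceed its parent's.
* The built-in redundancy reducer is a k-mer containment heuristic, not
  a replacement for a production clusterer.
* Distance matrices are dense; the partitioner targets per-term set
  sizes (hundreds to thousands), not whole proteomes.
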