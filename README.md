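# funpred

Homology-independent prediction of Gene Ontology (GO) annotations for
protein sequences, with per-term support vector machines and a full
assessment suite.

## The problem

Roughly a third of human proteins — and many more in other eukaryotes —
carry no functional annotation and no close homologue of known
function, so similarity-based annotation transfer cannot reach them.
funpred takes the feature-based route instead: for each GO term *t* of
the molecular function (MF) or biological process (BP) namespace it
learns a binary SVM mapping sequence-derived features (residue
composition, global physicochemical features, and twelve predictor-backed
groups such as disorder, secondary structure, signal peptides and
modification sites) to the posterior probability that a protein carries
*t*.  It is aimed at computational biologists who want to train,
calibrate, audit and benchmark such per-term model libraries on their
own corpora.

## The method in brief

For each term with ≥ 150 positives (annotated with *t* or a descendant)
and ≥ 500 well-annotated negatives outside *t*'s lineage:

1. **Partition** — 30 % of each set is held out; the rest is split into
   the maximal number *k* of equal-size groups of ≥ 35 proteins (shared
   *k* for both sets), clustered on pairwise alignment E-value distances
   by a balanced K-medoids algorithm so folds do not share homologues.
2. **Select** — an exhaustive grid over linear and RBF kernels, combined
   with greedy elimination of whole feature groups, maximises the
   cross-validated Matthews correlation coefficient

   MCC = (TP·TN − FP·FN) / √((TP+FP)(TP+FN)(TN+FP)(TN+FN)),

   with errors on positives weighted by the negative:positive ratio.
3. **Audit** — the selected model is scored once on the holdout: terms
   with MCC < 0.05 are discarded; survivors are tiered **H** when MCC,
   sensitivity, specificity and precision exceed 0.3/0.3/0.7/0.3, else **L**.
4. **Refit + calibrate** — survivors are refit on all examples with the
   kernel parameters re-optimised, and the decision values of the final
   k-fold run feed a Platt sigmoid P(y=1|f) = 1/(1+exp(A·f+B)).  A
   prediction is *displayed* when its posterior exceeds 0.5.

Prediction sets are assessed against reference annotations with
CAFA-style precision-recall curves and Fmax, a relaxed
ancestor/descendant matching variant, and the information-content based
simGIC and COGIC scores (COGIC combines simGIC at four confidence
strata ≥ 0.75/0.50/0.25/0 with decreasing weights).  A synthetic fixture
module generates ontologies, proteomes with planted feature signal,
annotation tables and homology block structure so the whole pipeline is
testable without downloads.

## Worked example

Train one term on a synthetic proteome with planted signal:

```r
library(funpred)
spec  <- fixture_spec(seed = 42, n_proteins = 240, n_pos = 55)
graph <- make_ontology(spec)
fx    <- make_proteome(spec, graph)

tset <- term_training_set(fx$signal_terms[1], fx$corpus, graph,
                          vocab = fx$vocab, min_pos = 45, min_neg = 120)
tset
#> fp_term_set GO:0100009: 55 positives, 177 negatives — eligible

cfg   <- fp_config(linear_C = c(0.1, 1), rbf_C = 1, rbf_gamma = 0.1,
                   min_group = 12, seed = 1)
model <- train_term(tset, fx$features, fx$distances, cfg)
model
#> fp_term_model GO:0100009 (linear kernel, C=0.1)
#>   retained groups: 14; k=3; CV MCC=1.000
#>   holdout: MCC=1.000 sens=1.000 spec=1.000 prec=1.000 -> H
```

The planted signal is strong, so the linear kernel separates the term
perfectly: cross-validated and holdout MCC are both 1, every feature
group is retained (removals must *strictly* improve the MCC), and the
model earns the H reliability tier.  Scoring proteins returns calibrated
posteriors, H-tier rows first:

```r
lib    <- train_library(list(tset), fx$features, fx$distances, cfg)
report <- predict(lib, fx$features)
head(report[report$displayed, ], 3)
#>   accession       term posterior reliability displayed
#> 2    P00002 GO:0100009 0.9842294           H      TRUE
#> 5    P00005 GO:0100009 0.9821808           H      TRUE
#> 6    P00006 GO:0100009 0.9863733           H      TRUE
```

A posterior of 0.98 means the calibrated sigmoid assigns a 98 % chance
that the protein carries the term; rows with posterior ≤ 0.5 remain in
the full dump but are not flagged for display.

The same machinery is scriptable from a shell through
`inst/cli/funpred.R` (`build-dataset`, `train`, `predict`, `evaluate`,
`make-fixtures` subcommands over a flat key = value config file).

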