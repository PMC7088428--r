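# mitocompart

Prediction of the sub-mitochondrial localization of proteins — inner
membrane, intermembrane space, matrix, or outer membrane — from the
amino-acid sequence alone.

Mitochondrial proteomes are large and mostly unannotated at the
sub-compartment level, while a protein's compartment constrains its
function and its relevance to mitochondrial disease. `mitocompart` is an
R (Bioconductor-style, S4) implementation of a sequence-based four-class
predictor aimed at researchers who want to assign compartments to
uncharacterized mitochondrial proteins, or to study which sequence
properties carry the localization signal.

## The method

Each protein sequence is encoded as a 239-dimensional feature vector in
four named blocks:

| block | size | content |
|---|---|---|
| `ccd` | 60 | per-residue **c**omposition `n_a/L`, **c**entroid (mean normalized position), and **d**istribution (spread of positions) for each of the 20 amino acids |
| `saac` | 60 | split amino-acid composition: the 20 compositions of the N-terminal, middle and C-terminal thirds |
| `fg_sse` | 88 | frequencies of 10 functional and 7 physico-chemical amino-acid groups; 5 sliding-window (10-mer) short-peptide class frequencies; helix/sheet/coil content from a Chou–Fasman assigner; the 17 group frequencies and 4 peptide-class frequencies recomputed per secondary-structure state |
| `physchem` | 31 | sequence means of 31 AAindex physicochemical scales (hydropathy, bulkiness, polarity, volume, flexibility, accessible surface area, …) |

Features are ranked by **information gain** — the mutual information
I(X;Y) = H(Y) − H(Y|X) in bits between the (equal-width-binned) feature
and the compartment label — and the top-k subset (typically the nested
top 10/50/100/150/200) feeds a **radial-basis-function SVM**
(`K(x,x') = exp(−γ‖x−x'‖²)`, libsvm one-vs-one multi-class). The
hyperparameters (C, γ) are tuned by grid search; performance is
estimated by stratified k-fold cross-validation, with feature scaling
and information-gain selection re-fit inside every training fold.
Per class (one-vs-rest) the report gives sensitivity TP/(TP+FN),
specificity TN/(TN+FP), the Matthews correlation coefficient
(TP·TN − FP·FN)/√((TP+FN)(TP+FP)(TN+FP)(TN+FN)) and the ROC AUC from
one-vs-rest decision scores.

The package also implements the upstream dataset hygiene used for
SWISS-PROT-derived training sets: removal of ambiguously annotated
("probable", "possible", "potential", "by similarity") and
multi-location entries, a minimum length of 80 residues, the standard
20-letter alphabet, and CD-HIT-style greedy redundancy reduction at 70%
global-alignment identity.

## Worked example

A seeded synthetic dataset with moderate class-specific compositional
bias, run through the full pipeline (encode → tune → stratified 5-fold
CV with per-fold top-50 information-gain selection):

```r
library(mitocompart)

sim <- generateProteins(nPerClass = 25, effectSize = 0.8, seed = 42)
res <- runPipelineCV(sim$proteins, topK = 50, folds = 5, seed = 42)
res$config
#> SVMConfig: C = 8, gamma = 0.0078125, weighting = none, seed = 42
res$metrics
#> MetricsReport: overall accuracy 90.00%
#>                class sensitivity (%) specificity (%)   mcc   auc
#>       inner_membrane              96           98.67 0.947 0.987
#>  intermembrane_space              84           96.00 0.811 0.953
#>               matrix              92           98.67 0.919 0.996
#>       outer_membrane              88           93.33 0.793 0.893
#> macro: sensitivity = 0.900, specificity = 0.967, mcc = 0.868, auc = 0.957
```

90% of the 100 sequences are assigned to their true compartment; the
per-class rows show where the remaining confusion lives (here mostly
outer membrane vs the rest), and the MCC column gives the
chance-corrected quality of each one-vs-rest split. With the generator's
default strong effect (`effectSize = 4`) the same pipeline is essentially
perfect; with `effectSize = 0` it collapses to the ~25% four-class
chance level — see below.

A command-line wrapper over the same functions ships at
`inst/scripts/mitocompart` (subcommands `simulate`, `curate`, `encode`,
`select`, `cv`, `train`, `predict`, `evaluate`).

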