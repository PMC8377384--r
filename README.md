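# ppiboost

Sequence-based prediction of protein–protein interactions (PPIs) with feature
fusion, sparse selection and gradient tree boosting.

Experimental interaction screens are noisy and incomplete, so computational
ranking of candidate protein pairs from sequence alone is a standard tool in
proteomics. `ppiboost` implements a complete prediction pipeline for labeled
pairs of amino-acid sequences:

1. **Encode** each protein with four fused descriptor families —
   pseudo amino acid composition (PseAAC, 20 + λ features), pseudo
   position-specific scoring matrix (PsePSSM, 20 + 20ξ), reduced sequence and
   index-vectors (RSIV, 120 + 77 = 197), and Moreau–Broto / Moran / Geary
   autocorrelation descriptors (AD, 3 × 7 × lag). At the defaults
   (λ = 11, ξ = 9, lag = 11) a protein maps to 31 + 200 + 197 + 231 = **659**
   features and a pair, by concatenation, to **1318**.
2. **Select** features with L1-regularized logistic regression (L1-RLR),
   minimizing ‖ω‖₁ + C Σᵢ log(1 + exp(−yᵢ ωᵀxᵢ)); the nonzero-weight support
   (C = 1 by default) defines the reduced representation.
3. **Classify** with gradient tree boosting (GTB) under binomial deviance:
   F₀ = empirical log-odds, then M stages of regression trees fitted to the
   negative gradient yᵢ − pᵢ with one-step Newton leaf values and shrinkage ν
   (defaults M = 1000, ν = 0.1, depth 3).
4. **Evaluate** with recall, precision, accuracy, Matthews correlation
   coefficient, ROC/PR curves, AUROC/AUPRC, and stratified five-fold
   cross-validation in which selection and classifier are refitted per fold.

A synthetic-data generator (random proteins with Dirichlet composition bias,
BLOSUM62-based pseudo-PSSMs, and a plantable composition-similarity
interaction signal) makes every stage testable offline, and a CLI wraps the
pipeline for shell use. Supported formats: FASTA, TSV/CSV pair tables,
PSI-BLAST `-out_ascii_pssm` profiles, feature-matrix CSV, JSON reports.

## Worked example

```r
library(ppiboost)

ds <- generate_ppi_dataset(synth_config(n_proteins = 40, n_pairs = 100,
                                        length_range = c(50, 120), seed = 42))
ds
#> <synth_dataset> 40 proteins, 100 pairs (50 positive), signal = 2, seed = 42

pf <- encode_proteins(ds$proteins, ds$pssms)   # 40 x 660 (id + 659 features)
pp <- encode_pairs(ds$pairs, pf)               # 100 x 1321 (ids, label + 1318)

sel <- fit_l1rlr(pp, C = 1, seed = 42)
sel
#> <l1rlr> C = 1: 36 of 1318 features selected

cv <- cross_validate(pp, k = 5, C = 1, M = 100, seed = 42)
cv
#> <ppi_cv> 5-fold cross-validation (seed 42)
#>   recall    0.6000 +/- 0.1581
#>   precision 0.5710 +/- 0.1078
#>   acc       0.5800 +/- 0.1151
#>   mcc       0.1612 +/- 0.2315
#>   auroc     0.6320 +/- 0.1165
#>   auprc     0.6626 +/- 0.1004
```

Reading the output: the sparse logistic step keeps 36 of 1318 pair features;
five-fold cross-validation (selection and boosting refitted inside each
training fold) then estimates held-out accuracy 0.58 and AUROC 0.63 ± 0.12 on
this small simulated study — above the 0.5 chance level, consistent with the
modest planted effect size (see the methods vignette for why the generator's
signal is deliberately hard). `autoplot(cv, "roc")` draws the per-fold ROC
curves; `tidy(cv)` and `glance(cv)` return the per-fold and summary tables.

For a one-call version that also writes artifacts (feature matrix, selection
and boosting models, predictions, JSON report, checksummed manifest):

```r
res <- run_pipeline(pipeline_config(simulate = synth_config(), M = 200,
                                    workdir = "run1", seed = 1))
```

The same pipeline is scriptable from the shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "ppiboost.R", package = "ppiboost"))')
Rscript $CLI simulate --out data --seed 4 --n-proteins 20 --n-pairs 40
Rscript $CLI encode   --fasta data/proteins.fasta --pssm-dir data/pssm \
                      --pairs data/pairs.tsv --out features.csv
Rscript $CLI select   --c 1.0 --seed 4 --in features.csv --out selected.csv \
                      --model sel.model --support support.txt
Rscript $CLI train    --iterations 1000 --seed 4 --in selected.csv --out gtb.model
Rscript $CLI predict  --model gtb.model --in selected.csv --out predictions.csv
Rscript $CLI evaluate --k 5 --seed 4 --in features.csv --out report.json
```

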