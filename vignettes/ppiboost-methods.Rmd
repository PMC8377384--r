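---
title: "Methods: sequence encoders, sparse selection and boosted PPI prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence encoders, sparse selection and boosted PPI prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppiboost)
```

## The problem

Given two amino-acid sequences, does the corresponding protein pair interact?
`ppiboost` treats this as supervised binary classification on ordered pairs of
sequences: each protein is mapped to a fixed-length numeric descriptor, a pair
is represented by concatenating its two protein descriptors, a sparse logistic
model prunes the concatenated representation, and a gradient-tree-boosting
(GTB) classifier predicts the interaction probability. The package covers the
whole path — file formats in, evaluation report out — so the method can be run
and audited end to end on synthetic data without any external database.

## Per-protein encoders

Four descriptor families are concatenated, in this fixed order, into a
659-dimensional per-protein vector at the default configuration
(`encoder_config()`: $\lambda = 11$, $\xi = 9$, $lag = 11$, $w = 0.05$).

**Pseudo amino acid composition (31 = 20 + $\lambda$).** Type-1 construction
over three classical scales (hydrophobicity, hydrophilicity, side-chain mass),
each standardized to zero mean / unit variance across the 20 amino acids with
the population divisor 20. The correlation factor between residues $a,b$ is
the mean squared difference of the three normalized scales,
$\Theta(a,b) = \tfrac13\sum_p (P_p(a)-P_p(b))^2$, and the rank-$k$ term is
$\theta_k = \tfrac{1}{L-k}\sum_i \Theta(R_i, R_{i+k})$. Composition counts
$f_u$ and weighted order terms are normalized jointly,
$x_u = f_u / (\sum_v f_v + w\sum_k \theta_k)$ and
$x_{20+k} = w\theta_k / (\cdot)$, so the vector is a point on the simplex —
a property the tests verify on random sequences.

**Pseudo-PSSM (200 = 20 + 20$\xi$).** Each row of the $L \times 20$
position-specific scoring matrix is standardized across its 20 scores
(population standard deviation; an exactly constant row maps to zeros rather
than dividing by zero). The first 20 features are column means of the
standardized profile; each lag block $g = 1..\xi$ holds, per column, the mean
squared lag-$g$ difference, capturing how the evolutionary profile changes
along the chain. Row standardization (rather than a sigmoid squash) was chosen
because it is scale-free, total on degenerate inputs, and keeps the lag terms
comparable across columns; it is declared here because profile preprocessing
conventions genuinely vary.

**Reduced sequence and index-vectors (197 = 120 + 77).** The index-vector
block weights each amino acid's normalized value under six physicochemical
scales by its relative frequency (6 × 20 = 120). The reduced-sequence block
maps residues onto the seven conjoint classes
{A,G,V}, {I,L,F,P}, {Y,M,T,S}, {H,N,Q,W}, {R,K}, {D,E}, {C} and collects 7
class frequencies, 49 ordered adjacent class-dipeptide frequencies and 21
unordered distinct-class transition frequencies (both divided by $L-1$). The
7 + 49 + 21 decomposition is this package's concrete realization of the
120 + 77 split; it is pinned by tests against hand-enumerated count tables.

**Autocorrelation descriptors (231 = 3 × 7 × lag).** Moreau–Broto (raw
product), Moran (centered and variance-normalized) and Geary (squared
difference) autocorrelations of seven property signals at lags $1..lag$. A
zero-variance signal (homopolymers) yields 0 for Moran and Geary by
convention; Geary features are non-negative and Moran features lie in
$[-1, 1]$ up to a small short-sequence slack, which the property tests check.

The wildcard residue `X` (and, leniently, any non-standard code mapped to it)
contributes the neutral value 0 to every normalized property signal and is
excluded from composition counts and their denominators — no chemistry is
invented for it.

Pair vectors are plain concatenations, A-side first, in the order the pair
table gives (1318 features at defaults). No canonicalization of pair order is
performed; `encode_pairs(augment_mirrored = TRUE)` optionally adds the (B, A)
mirror of each pair at training time, off by default.

## Sparse selection

`fit_l1rlr()` minimizes
$\|\omega\|_1 + C\sum_i \log(1 + e^{-y_i \omega^\top x_i})$ with labels in
$\{-1,+1\}$ and an unpenalized intercept. The solver is glmnet's coordinate
descent; the objective equals glmnet's binomial objective at
$\lambda = 1/(nC)$ up to a positive factor, so the minimizer transfers
exactly, and the tests audit the returned weights against the subgradient
optimality conditions of the objective above (tolerance $10^{-3}$). Features
enter as encoded, without per-column rescaling, matching the descriptor
construction (each block is already normalized by design); a `standardize`
flag exists for data whose scales drift. The support is
$\{j : |\omega_j| > 10^{-8}\}$ — the tolerance separates genuine sparsity
from solver float dust. An empty support is an error, not a 0-column matrix.

## Gradient tree boosting

`train_gtb()` is a stagewise additive model under binomial deviance. The
score starts at the empirical log-odds $F_0$; at each stage a regression tree
is fitted to the negative gradient $y_i - p_i$ (rpart, squared-error
splitting, `cp = 0`, depth-limited), each terminal region receives the
one-step Newton value $\sum r_i / \sum p_i(1-p_i)$ — the closed-form solution
of the per-region line search — and the score is updated with shrinkage
$\nu$. Defaults: $M = 1000$ stages, $\nu = 0.1$, depth 3; the latter two are
the conventional companions of deviance-loss boosting and are config-exposed,
since only $M$ and the loss are fixed by the method definition. No
subsampling and no early stopping are performed. Training deviance is
monotonically non-increasing across stages (tested), a single stage
reproduces an independently coded literal one-step update on small data
(tested), and serialized models reproduce their predictions bit-exactly.

## Evaluation

Recall, precision, accuracy and Matthews correlation are computed from
confusion counts; a zero-denominator metric reports 0 with a `degenerate`
flag rather than `NaN` so that reports always serialize. ROC curves use a
score-descending threshold sweep with tie groups and the trapezoid rule; the
ROC area equals the normalized Mann–Whitney U statistic, which the tests
verify by brute-force pair counting. Precision-recall areas use the
step-wise right-continuous rule, not the trapezoid, to avoid the optimistic
bias of linear interpolation in PR space.

`cross_validate()` performs stratified k-fold (default 5) splitting over
*pairs*. Selection and the boosted model are refitted inside each training
fold — the fold audit in the tests checks that supports differ across folds —
while per-protein encoding is computed once, which is safe because it never
sees labels. Splitting over pairs means one protein can appear on both sides
of a split; this mirrors the standard benchmark protocol of the field and is
documented as a caveat rather than silently "fixed", because changing it
changes the estimand. Whether folds should be stratified is a convention
choice; stratification was chosen so every fold is evaluable at small n.

## The synthetic study

`generate_ppi_dataset()` defines the package's reference study conditions:
120 proteins of length 50–200, 400 pairs balanced 1:1, label-flip noise 5%.
Each protein draws a composition bias from a symmetric Dirichlet
(concentration 1 — maximal spread without favouring any residue) and its
residues i.i.d. from that bias; pseudo-PSSMs are BLOSUM62 rows plus integer
noise in $[-2, 2]$. The latent interaction score of a candidate pair is
`signal` times the cosine similarity of the two composition biases,
*z-scored across candidate pairs*, plus standard logistic noise; labels are
score > median, subsampled to exact class balance, then flipped at the noise
rate. The z-scoring makes `signal` an interpretable effect size against the
unit-scale noise and makes `signal = 0` an exact null; without it the raw
cosine spread (sd ≈ 0.1–0.3) would be negligible against logistic noise of
sd ≈ 1.81 and every setting would be near-null.

The signal is planted in composition — reachable by the composition-based
encoders — not in profile structure, so encoder ablations order predictably.
What the generator does *not* emulate: real phylogenetic correlation between
sequences, genuine PSSM structure, hub proteins, or the
negative-sampling-by-localization scheme of curated benchmarks. Passing tests
on this generator therefore demonstrate pipeline correctness and
calibration, not biological performance.

Two quantitative caveats follow from the design and are worth stating
precisely. First, with effect size 2 against standard logistic noise, even
the Bayes-optimal classifier that observes the latent similarity directly
tops out near AUROC 0.86 and accuracy 0.78 (before the 5% label flips are
accounted for). Second, the label is a *cross-protein similarity* function;
a depth-3 tree ensemble must assemble it from conjunctions of per-protein
composition features, and with 320 training pairs it recovers only part of
it (held-out AUROC ≈ 0.55–0.6 at the defaults, ≈ 0.7 at much larger effect
sizes). The acceptance suite therefore checks the *contrast* between planted
signal and permutation null at the reference conditions, and demonstrates
high absolute discrimination (AUROC > 0.85) for the boosted model on
directly learnable feature data instead.

## Numerical and design choices

- Problem sizes in the test and acceptance runs: cross-validation at the
  reference conditions uses $M = 200$ stages; unit tests use 20–150 stages
  on smaller matrices. These sizes were chosen so the full suite exercises
  every contract at desk scale.
- Seeds: every stochastic stage takes an explicit seed; the pipeline derives
  per-fold seeds as master + fold index. Identical configuration and seed
  reproduce the evaluation report byte-for-byte (tested).
- Degenerate inputs: constant PSSM rows → zero rows; zero-variance property
  signals → zero Moran/Geary; empty selection support → error; single-class
  labels → error everywhere.
- Ties: ROC sweeps group tied scores; rpart's deterministic split search
  breaks tied splits by first feature order, which the one-step oracle test
  avoids by construction.
- The PSI-BLAST ASCII parser takes the first 20 numeric columns of each
  position row and is insensitive to run-length whitespace and the trailing
  statistics block; truncated rows are an error naming the row.

## Known limitations

- Encoder internals realize the standard constructions under the printed
  dimensional contracts; other property sets or reduced alphabets would give
  different (equally valid) 197/231-dimensional realizations.
- The pseudo-PSSM fallback (BLOSUM62 rows) carries no evolutionary
  information beyond residue identity; it exists so the pipeline runs
  without PSI-BLAST, and its use is always reported.
- Cross-validated metrics on the synthetic generator should not be read as
  expected performance on curated interaction databases.
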