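# kcatboost

Turnover-number prediction for enzyme-catalysed reactions.

The turnover number k<sub>cat</sub> — the maximal rate at which one active
site converts substrate into product, in s⁻¹ — is measured for only a tiny
fraction of enzymes, yet it is the key kinetic parameter for quantitative
models of metabolism. `kcatboost` predicts log₁₀ k<sub>cat</sub> for
natural reactions of wild-type enzymes from the two inputs that are always
available: the chemical reaction (substrates and products as SMILES or
InChI) and the enzyme's amino-acid sequence. It is aimed at computational
biologists who need k<sub>cat</sub> estimates at scale (for example to
parameterise enzyme-constrained genome-scale models) and at method
developers who need a tested, offline-reproducible reference pipeline.

## The model

Reactions are represented by a 2048-bit differential reaction fingerprint:
circular substructure environments of radius 0–3 are enumerated on both
sides of the reaction, and every environment present on exactly one side —
the chemistry that actually changes — sets a hashed bit. Enzymes are
represented by fixed 1280-dimensional numeric vectors (precomputed
protein-language-model embeddings, or the package's deterministic
sequence-sketch backend for offline work). Two gradient-boosted
regression-tree models are trained independently, one per representation,
with hyperparameters chosen by random-search five-fold cross-validation in
which no amino-acid sequence ever spans two folds. The final prediction is

&nbsp;&nbsp;&nbsp;&nbsp;ŷ = ½ (ŷ<sub>reaction</sub> + ŷ<sub>enzyme</sub>)

on the log₁₀ scale. Model quality is reported as R² (coefficient of
determination, 1 − SS<sub>res</sub>/SS<sub>tot</sub>), MSE and Pearson r
on log₁₀ k<sub>cat</sub>, stratified by the maximal sequence identity of
each test enzyme to the training set (<40, 40–80, 80–99, ≥99 %,
Needleman–Wunsch global alignment) and by reaction similarity — the
regime with no close homolog is where prediction is hardest and most
valuable.

Two further fingerprints are implemented for comparison: the structural
reaction fingerprint (3276 bits, per-side OR of 1638-bit molecular path
fingerprints) and the difference fingerprint (2048 signed atom-pair
counts, substrates minus products).

## Worked example

```r
library(kcatboost)

pipe <- run_kcat_pipeline(seed = 1, n_trials = 50)
pipe
#> <kcat_pipeline> seed 1
#> curated records: 1275 | train: 1019 | test: 256
#> ensemble held-out R^2 = 0.704, MSE = 0.330, r = 0.856

pipe$reports$ensemble$by_identity[, 1:4]
#> stratum   n    r2   mse
#> I99_100  36 0.840 0.183
#> I80_99  120 0.795 0.209
#> I40_80   79 0.547 0.502
#> I0_40    21 0.316 0.619
```

`run_kcat_pipeline()` simulates ~3000 measurements, curates them
(deduplication, geometric-mean aggregation per enzyme–reaction pair with
the 1 %-of-maximum exclusion, the 10× non-natural-reaction and 100×
suboptimal-measurement filters, mass-balance and outlier checks), makes a
sequence-grouped 80/20 split, optimises and fits both component models,
and evaluates on the held-out set. The printed numbers say: of the ~1300
curated enzyme–reaction pairs, the 256 held-out records are predicted with
R² = 0.70 overall (the ensemble beats the reaction-only model at 0.68 and
the enzyme-only model at 0.37), and accuracy falls monotonically from the
≥99 %-identity bucket (R² = 0.84) to the <40 % bucket (R² = 0.32) — the
same qualitative profile seen on real kinetic data, where measurement
noise and representation limits cap attainable accuracy much lower.

Individual stages are exported (`run_curation()`,
`reaction_fingerprint()`, `split_train_test()`, `fit_kcat_model()`,
`stratified_report()`, …), return tibbles, and chain with the pipe. A thin
command-line wrapper with `simulate | curate | split | train | predict |
evaluate` subcommands is installed under `inst/cli/kcatboost.R`.

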