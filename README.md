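# mirstress

Predict abiotic stress-responsive plant miRNAs from sequence alone.

Plant microRNAs are central regulators of the response to drought, cold,
heat, salinity and other abiotic stresses, and knowing which miRNAs are
stress-responsive matters for crop-improvement programmes — but testing each
candidate experimentally is slow. `mirstress` implements a sequence-only
classifier for this question: given mature miRNAs (~20–24 nt), precursor
hairpins (~80–120 nt), or matched pairs of both, it predicts for each
sequence the probability of being abiotic stress-responsive.

## Method

Each RNA sequence `s₁ s₂ … s_L` over `{A, U, G, C}` is encoded as a **pseudo
K-tuple nucleotide composition** (PseKNC) vector. For each tuple size *K*,
the block combines the `4^K` normalized K-tuple frequencies `g_m` with λ
sequence-order correlation factors

    δ_j = (1 / (L−K−j+1)) Σ_i Φ(i, i+j),      j = 1…λ,

where `Φ(i, i+j)` is the mean over R physicochemical properties of the
squared difference between the property values of the tuples starting at
positions `i` and `i+j`. The block of `4^K + λ` features is jointly
normalized,

    θ_m = g_m / (Σg + ω Σδ)          (m ≤ 4^K)
    θ_m = ω δ_{m−4^K} / (Σg + ω Σδ)  (otherwise),

so it sums to 1. With the defaults `K ∈ {2,3,4,5}`, `λ = 3`, `ω = 0.2` the
blocks have 19, 67, 259 and 1027 entries — 1372 features per sequence, 2744
for a mature + precursor pair. Dinucleotide properties default to the six
standard RNA structural parameters (rise, roll, shift, slide, tilt, twist),
z-standardized; any table can be supplied as TSV.

Classification uses an RBF-kernel support vector machine
(`K(x, x′) = exp(−γ‖x−x′‖²)`, defaults `C = 1`, `γ = 1/#features`, optional
`2^{−5..5}` log-grid search) trained on class-balanced data (random
undersampling of the majority class). Features are ranked by **SVM-RFE**
(iterative linear-SVM fits, removing the lowest-`w²` features) and the subset
size is chosen from an incremental auROC/auPRC curve. Evaluation offers
stratified 5-fold CV and LOOCV with sensitivity, specificity, balanced
accuracy `Acc = (Sen+Spe)/2`, precision, F-score, auROC (trapezoid) and
auPRC (step interpolation).

## Worked example

The package ships a first-order Markov sequence simulator with a
class-separation knob, so the whole pipeline runs without external data:

```r
library(mirstress)

dir <- tempfile(); dir.create(dir)
run_simulate(sim_spec(n_per_class = 100, seed = 7), dir)

cfg <- run_config(
  mode      = "miRNA",
  positive  = file.path(dir, "positive.fasta"),
  negative  = file.path(dir, "negative.fasta"),
  selection = TRUE, rfe_step = 25, curve_step = 100, cv_folds = 5
)
res <- run_train(cfg)

res$curve
#> <selection_curve: 14 sizes evaluated; chosen 100 features (auROC 100.00)>
res$cv
#> <cv_result: fivefold (k = 5), 200 held-out predictions>
#> # A tibble: 1 × 7
#>     Sen   Spe   Acc   Pre F_score auROC auPRC
#>   <dbl> <dbl> <dbl> <dbl>   <dbl> <dbl> <dbl>
#> 1    90    93  91.5  92.8    91.4  96.8  97.3

pred <- run_predict(res$model, file.path(dir, "positive.fasta"))
head(pred$predictions, 3)
#> # A tibble: 3 × 3
#>   id       class    prob_positive
#>   <chr>    <chr>            <dbl>
#> 1 pos_0001 positive         0.987
#> 2 pos_0002 positive         0.975
#> 3 pos_0003 positive         0.997
```

The selection curve chose 100 of the 1372 PseKNC features; five-fold
cross-validation of the selected model gives balanced accuracy 91.5% and
auROC 96.8% on this strongly separated synthetic dataset, and the training
positives are predicted stress-responsive with high probability.
`autoplot(res$curve)` and `autoplot(res$cv)` draw the selection curve and
the ROC/PR curves; `tidy()`/`glance()` methods return the underlying tables.

A command-line interface with `clean`, `encode`, `select`, `train`,
`evaluate`, `predict` and `simulate` subcommands is installed at
`system.file("scripts", "mirstress", package = "mirstress")`.

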