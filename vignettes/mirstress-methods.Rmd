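---
title: "Methods: PseKNC encoding, SVM-RFE and cross-validated SVM classification of stress-responsive miRNAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PseKNC encoding, SVM-RFE and cross-validated SVM classification of stress-responsive miRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirstress)
```

## The problem and the model

Plant miRNAs that respond to abiotic stress (drought, cold, heat, salt,
oxidative stress) are experimentally expensive to identify, and the mature
sequences are short (20–24 nt), which limits how much signal any encoding
can extract. `mirstress` treats the task as binary sequence classification:
stress-responsive ("positive") versus non-responsive ("negative"), from
sequence alone — no expression data, no secondary structure.

The model has three parts, each exposed as ordinary functions over tibbles:

1. **PseKNC encoding** turns each sequence into a fixed-length numeric
   vector combining k-mer composition with sequence-order information.
2. **SVM-RFE feature selection** ranks the (highly sparse and correlated)
   features and an incremental cross-validation curve picks how many to
   keep.
3. An **RBF-kernel SVM**, trained on class-balanced data, yields a
   calibrated probability of stress responsiveness.

## PseKNC encoding

For tuple size $K$ the encoder computes the $4^K$ overlapping-window
(step 1) tuple frequencies $g_m$, normalized to sum to 1, and $\lambda$
correlation factors

$$\delta_j = \frac{1}{L-K-j+1} \sum_{i=1}^{L-K-j+1} \Phi(i, i+j), \qquad
\Phi(i,i+j) = \frac{1}{R}\sum_{r=1}^{R}
\left[\varphi_r(t_i) - \varphi_r(t_{i+j})\right]^2,$$

where $t_i$ is the tuple starting at position $i$ and $\varphi_r$ its $r$-th
physicochemical property. The combined block
$\theta_m = g_m / (\sum g + \omega \sum \delta)$ for frequency entries and
$\theta_m = \omega\,\delta_{m-4^K} / (\sum g + \omega \sum \delta)$ for
correlation entries sums to exactly 1, a property the tests assert to
$10^{-9}$. Homopolymers are the degenerate case: all tuples are equal, every
$\delta_j = 0$, and the block collapses to a one-hot frequency vector.

Defaults: $K \in \{2,3,4,5\}$, $\lambda = 3$, $\omega = 0.2$, giving blocks
of 19/67/259/1027 features and 1372 per sequence (2744 for a mature +
precursor pair, encoded separately and concatenated with `mat_`/`pre_` name
prefixes). $\lambda$ is kept small because a 20-nt mature sequence leaves
few $(i, i+j)$ pairs per tier; the minimum encodable length is
$\max(K)+\lambda = 8$ nt, enforced as an error rather than silently
shrinking the feature space, because a dataset must have a constant column
set.

**Property tables.** For dinucleotides we use the six standard RNA
structural parameters (rise, roll, shift, slide, tilt, twist) from A-form
RNA crystallography, z-standardized across the 16 dinucleotides. No
canonical property sets exist for longer tuples, so for $K>2$ each K-tuple
receives the mean of its $K-1$ constituent dinucleotides' standardized
values, re-standardized across the $4^K$ tuples — the least surprising
extension, and every table is replaceable via a TSV
(`read_property_table()`). Standardization happens once at table
construction; it makes $\delta_j$ scale-free (scaling raw property values by
$c$ scales raw $\delta_j$ by $c^2$, which the tests verify on
unstandardized tables). Because published PseKNC web toolkits do not
document their exact RNA property sets, numeric parity with any particular
server output is not claimed; what is guaranteed — and oracle-tested term
by term — is fidelity to the defining formulas above.

Whether tuple frequencies should use overlapping windows is a genuinely
open choice; we use step 1 (overlapping), the standard reading.

## Sequence hygiene

`clean_dataset()` applies the two universal rules — collapse exact duplicate
sequences (first occurrence wins, for determinism) and drop records with
residues outside `{A,U,G,C}` — and logs counts in a `provenance()`
attribute. Input `T` is normalized to `U` on read, so DNA-alphabet FASTA
encodes identically.

`reduce_redundancy()` offers homology reduction at a configurable identity
threshold (default 0.80). It is a greedy clusterer in input order using
exact global-alignment identity with match +1, mismatch/indel 0 and free
end gaps; under that scoring the maximal match count is the longest common
subsequence, so identity = LCS / (L₁+L₂−LCS). This is deliberately *not* a
re-implementation of CD-HIT: CD-HIT's word-filter heuristics are
approximations that pay off on long sequences, while short RNAs make the
exact pairwise computation cheap. Cluster membership can therefore differ
from CD-HIT on borderline pairs. When positives and negatives both need
reduction, the pipeline reduces each class separately (reducing them
jointly would let a negative suppress a near-identical positive, changing
class sizes asymmetrically); both behaviours are reachable through the API.

## Classifier

The SVM is the standard libsvm solver behind `e1071`, used with the RBF
kernel and defaults $C = 1$, $\gamma = 1/\#\text{features}$. Two design
choices deserve explanation:

**Internal feature standardization.** Raw PseKNC features are mostly tiny
(a 20-nt sequence occupies at most 16 of the 1024 $K{=}5$ tuples), so
squared distances between vectors are of order $10^{-2}$ and
$\gamma = 1/1372$ would make the kernel nearly constant — the fitted
decision values then reflect only class imbalance, which is catastrophic
for leave-one-out CV (the held-out example's class is always the training
minority). Every fit therefore z-standardizes features on its training set;
the center/scale vectors are stored in the model and re-applied at
prediction. Zero-variance columns get scale 1, mapping to a constant 0 that
drops out of kernel distances.

**Probability calibration.** Probabilities come from a Platt-style sigmoid
$P(\text{positive}\mid f) = 1/(1+e^{-(a+bf)})$ fitted to decision values
$f$. We fit it in-package — seeded stratified internal CV (default 3 folds)
produces out-of-fold decision values, and a quasi-binomial GLM with Platt's
smoothed targets $(n_+{+}1)/(n_+{+}2)$ and $1/(n_-{+}2)$ keeps the fit
finite on separable data — rather than using libsvm's built-in probability
machinery, whose internal cross-validation draws from the C library's RNG
and is not reproducible from R's seed. The in-package route is
deterministic given the seed, monotone in $f$ (so ranking by probability
equals ranking by decision value), and serializes as two numbers. The
decision threshold is fixed at 0.5.

`grid_search_svm()` reads the conventional log-grid: exponents −5…5 in
steps of 2 on both axes ($\gamma, C \in \{2^{-5}, 2^{-3}, …, 2^{5}\}$, 36
candidates), scored by cross-validated pooled auROC of decision values
(auROC because it is threshold-free; the metric choice is configurable
territory, but auROC is the default). Ties break toward smaller $C$, then
smaller $\gamma$ — preferring the less complex model.

Model artifacts embed a format-version string and the encoder fingerprint;
prediction refuses features encoded under a different PseKNC configuration
instead of silently re-encoding.

## Feature selection

SVM-RFE is the canonical backward elimination: fit a **linear**-kernel SVM
on the surviving features, score each by $w_k^2$ where
$w = \sum_i \alpha_i y_i x_i$, remove the lowest-scoring `step` features,
repeat until none remain; the ranking is the reverse removal order. The
linear kernel is used for ranking even though classification uses RBF —
$w$ is only defined for a linear machine, and this matches the method as
originally described. The default step is 1 (the canonical procedure);
larger steps are a documented speed/fidelity trade. $w^2$ ties break by
original column order (stable sort), making the ranking deterministic and
column-order invariant.

`selection_curve()` evaluates prefixes of the ranking in increments of 10
features by stratified k-fold CV with the RBF SVM at defaults
($\gamma = 1/\text{subset size}$), always including the full set as the
last point (so "keep everything" competes fairly). The chosen size
maximizes auROC, ties broken by higher auPRC then smaller size. The
pipeline runs ranking and curve on a stratified random half of the balanced
data (`selection_fraction = 0.5`, seeded), so selection does not consume
the full training responses.

## Evaluation

`compute_metrics()` derives all seven reported metrics from the confusion
counts at threshold 0.5 and the score curves: Sen, Spe, balanced accuracy
$Acc = (Sen+Spe)/2$ (the mean of class rates, deliberately robust to
imbalanced test sets), Pre, F-score $= 2TP/(2TP+FP+FN)$, auROC and auPRC,
all as percentages. The ROC is swept over unique score thresholds with tied
blocks grouped, so the trapezoid area equals the pairwise-concordance
(rank-sum) statistic with ties counted ½ — the tests assert that identity
against an exhaustive pair-enumeration oracle. auPRC uses step
interpolation (area accrues as precision times recall increment), never
linear interpolation between PR points, which is known to overestimate.
Reported tables round to 2 decimals (round-half-even); raw values are kept
in the returned objects.

Cross-validation is stratified: each class is shuffled (seeded) and split
into k near-equal subsets, fold i uniting the i-th subset of each class, so
per-fold class ratios match the data within one example and every example
is tested exactly once. Aggregation follows a documented convention:
threshold metrics are averaged over folds, while auROC/auPRC are computed
on the pooled held-out scores — pooled curves remain well-defined for tiny
folds and for LOOCV (where per-fold curves do not exist at all). LOOCV
involves no randomness and is exactly reproducible. `k = n` is accepted as
a degenerate case that reproduces LOOCV predictions. With single-class
truth, threshold metrics are returned where their denominators exist and
curve metrics raise an explicit error.

`balance_dataset()` implements random undersampling: all minority rows are
kept and the majority class is sampled uniformly without replacement to
match, deterministically per seed. Balancing precedes selection, grid
search and CV in the pipeline.

## The simulator: what it does and does not emulate

`simulate_mirna_data()` draws sequences from a "sticky" first-order Markov
chain: the next base repeats the current one with probability
$\rho = 0.25$ and otherwise samples from the class composition. This chain
has the class composition as its *exact* stationary distribution (the
initial base is drawn from it too), which makes the compositional claim
testable, while the persistence injects dinucleotide autocorrelation so the
PseKNC correlation tiers carry real signal rather than noise. Class
separation is a single knob: class compositions are shrunk toward their
midpoint by $1-\text{effect}$, so `effect = 0` is an exact null (both
classes identically distributed) and `effect = 1` the full contrast. The
default contrast — GC-rich positives (A/C/G/U = 0.15/0.35/0.35/0.15) versus
the AU-rich mirror — reflects the broad GC-content differences reported
between stress-responsive and non-responsive plant miRNAs, at a strength
chosen to make "strong separation" clearly learnable. Mature lengths are
uniform on 20–24 nt and precursors on 80–120 nt, matching the biological
ranges; paired mode embeds each mature sequence verbatim in its precursor
at a random offset, as in real hairpins.

What the simulator does **not** emulate: hairpin secondary structure and
its thermodynamic constraints, phylogenetic relatedness between sequences
(real miRNA families are highly redundant — precisely why
`reduce_redundancy()` exists), species composition effects, and any
motif-level (as opposed to compositional) signal. Passing the synthetic
recovery tests therefore shows the pipeline is correct and well-calibrated,
not that real stress-responsive miRNAs are separable to the same degree;
published accuracies on curated plant miRNA data sit near 65–78% auROC,
far below the synthetic strong-separation regime.

## Problem sizes and numerical choices

The test suite regenerates all data programmatically at sizes chosen to
make the statistical assertions stable: encoder-vs-oracle agreement on 100
random sequences at $10^{-12}$; auROC-vs-concordance on 100 random score
sets at $10^{-10}$; planted-feature recovery with 20 informative + 180
noise features at $n = 200$; end-to-end signal recovery and the `effect = 0`
null calibration at 200 sequences per class (the null is checked across 20
seeds, each pooled CV auROC expected in [40, 60] — at this size the null
sampling SD of auROC is ≈3 points, so the band is ≈3σ); LOOCV/5-fold
agreement at 50 per class. Module tests use a reduced $K \in \{2,3\}$
encoder where dimension is not the point.

Degenerate inputs are errors, not warnings: empty post-filter datasets,
single-class training data, sequences below the minimum encodable length,
RFE steps that would eliminate everything in one iteration, thresholds
outside $(0,1]$. All randomness — balancing, fold assignment, selection
subsampling, Platt folds, simulation — flows through explicit integer
seeds, and seeded operations restore the caller's RNG state, so identical
configurations produce byte-identical persisted reports (wall-clock timings
are kept out of the persisted run log for this reason).

## Known limitations

- No numeric parity with any specific PseKNC web-server output (their RNA
  property tables are undocumented); fidelity is to the formulas.
- The greedy identity clusterer approximates, and does not reproduce,
  CD-HIT clusters.
- The "step size 2" log-grid is one reading of the conventional grid
  notation; the exponent set is an argument, not a constant.
- Balanced training plus Platt calibration targets balanced operating
  conditions; on heavily imbalanced deployment data the 0.5 threshold is
  conservative and the probability scale should be interpreted with the
  training prior in mind.
- RFE at step 1 over the full 1372-feature space costs one linear SVM fit
  per feature; the pipeline exposes `rfe_step` for the common case where a
  coarser ranking suffices.
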