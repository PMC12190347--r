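---
title: "Methods: a mechanistic digital twin of liver regeneration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a mechanistic digital twin of liver regeneration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`hepatwin` forecasts a liver donor's post-hepatectomy gene expression
trajectory from a single early blood sample by routing it through a
mechanistic model of the regenerating liver. This vignette documents the
model and the design decisions behind each stage, in the spirit of the
methods sections of mature omics packages: what is computed, under which
assumptions, with which defaults, and what the included tests do and do not
establish.

## Data model

Longitudinal expression is held as a gene × patient × time array with an
explicit observation mask and a *scale tag*. The tag starts at `raw`,
becomes `log1p` after the `log2(1 + x)` transform, and `log2fc` after
baseline subtraction. Every operation checks the tag, which makes the
pipeline order — impute, correct negatives, log-transform, fold change —
the only order the code will execute. The mask is authoritative: a masked
cell never contributes to an imputation donor pool, a correlation, a
cluster mean, a training pair, or an evaluation metric (tests verify this
by injecting absurd values under the mask).

The default sampling grid is one preoperative baseline plus 14
post-operative points: 5 and 30 minutes; 1–4 hours; 1–4 and 10 days; 3, 6
and 12 months, with one month taken as 730 h. Grids are configurable
(minimum three points) and may carry additional pre-resection samples, such
as a post-incision draw taken before the liver is resected.

## Preprocessing choices

* **Imputation** uses same-time cross-patient means only. Temporal
  interpolation was deliberately rejected: it would smooth exactly the
  dynamics the clustering stage is trying to detect. Cells observed in no
  patient stay masked and are reported, never silently filled.
* **Negative values** (noise artifacts of low-expressed genes) are replaced
  by the mean of other patients' non-negative values, falling back to 0
  with a logged warning. Zero itself is left untouched.
* **Baselines are never imputed from post-operative values.** A missing
  baseline masks the whole gene/patient series. The alternative (borrowing
  a baseline from later samples) would leak post-surgical signal into the
  reference level that fold changes are measured against.
* **Fold-change filtering** operates on differences of `log2(1 + x)`, so
  the "two-fold" rule `|Δ| ≥ 1` is exact only for expression levels well
  above 1; this approximation is accepted and documented. A gene is
  differential when the *cross-patient mean* profile exceeds the threshold
  at ≥ 2 consecutive post-operative points (a per-patient variant is
  exposed via `per_patient = TRUE`); it is excluded as a nonspecific
  surgical response when it moves ≥ 1.5-fold at any pre-resection sample
  beyond the baseline itself. On the default grid, which carries no such
  sample, the exclusion is inert by construction; it activates when the
  grid declares one.

## Co-expression network and clustering

The network is *unsigned*: adjacency `|cor|^β`. Up- and down-regulated
genes that share timing should co-cluster (observed cluster traces mix
signs), which a signed network would forbid. Correlations are Pearson over
the flattened (patient, time) samples, pairwise-complete under the mask;
per-patient correlation averaging was rejected as more fragile under block
missingness. β is the smallest power whose scale-free topology fit
(R² of log-frequency vs log-connectivity over ≥ 10 connectivity quantile
bins, negative slope required) reaches 0.8, falling back to the argmax with
a warning, or to the conventional β = 6 below 30 genes where binning is
meaningless.

Topological overlap follows the standard unsigned formula
`TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 − a_ij)`; the implementation is
matrix-multiplication based and is checked against a literal triple-loop
oracle at 1e−12. Preliminary modules come from average-linkage clustering on
`1 − TOM`, cut at a fixed height (default the 0.99 quantile of merge
heights) with undersized groups merged into their nearest group by mean
inter-group TOM. A fixed-height cut was chosen over dynamic tree-cut
variants because it is fully specifiable and therefore testable; both the
quantile and the minimum size (default 30) are arguments.

The self-organizing map then makes the final call. K units (default 15,
laid out 5 × 3) are initialized from the network groups' centroid profiles
— cycled and padded with random gene profiles when there are fewer groups
than units — and trained on each gene's mean-across-patients trajectory
with a Gaussian neighbourhood and linearly decaying learning rate (0.5 →
0.01) and radius over 100 epochs. The network thus informs the map, but
each gene's label is its best-matching unit; empty units are dropped and
the surviving count reported. SOM outcomes depend on presentation order,
so the seed is a mandatory argument, never taken from the clock.

Clusters are tagged by the peak time of the cross-patient mean |log2FC|:
≤ 24 h early, ≤ 240 h proliferation, later long-term (sustained elevation
over the last three grid points also qualifies as long-term). Peaks between
10 days and 3 months fall outside all three canonical phases; they are
assigned long-term and flagged ambiguous unless sustained. Flat clusters
default to early with an ambiguous flag.

## The mechanistic model

State: hepatocyte fractions Q (quiescent), P (primed), R (replicating),
normalized so the intact liver has Q = 1; molecular levels TNF, IL-6,
STAT3, SOCS3, immediate-early genes (IE), growth factor (GF) and
extracellular matrix (ECM), normalized to 1 at the basal steady state.
With metabolic load m = M/N (M = 1, N = Q + P + R), the equations are

    dTNF   = κ_T m − λ_T TNF
    dIL6   = κ_I TNF − λ_I IL6
    dSTAT3 = κ_S IL6 / (1 + γ SOCS3) − λ_S STAT3
    dSOCS3 = κ_C STAT3 − λ_C SOCS3
    dIE    = κ_E STAT3 − λ_E IE
    dGF    = κ_G m − λ_G GF − k_up ECM · GF
    dECM   = k_syn − k_deg TNF · ECM
    dQ     = −α₀ (IE − IE_b)₊ Q + θ_R R + θ_P ECM · P
    dP     =  α₀ (IE − IE_b)₊ Q − β₀ GF · P − θ_P ECM · P − δ_P P
    dR     =  β₀ GF · P + k_div R − θ_R R − δ_R R

One structural choice deserves emphasis: the priming term uses the
immediate-early *excess over a basal threshold* `(IE − IE_b)₊` rather than
IE itself. The cytokine cascade has a strictly positive basal level (at
m = 1, TNF* = κ_T/λ_T > 0 propagates down to IE* > 0), so a term
proportional to raw IE would drain Q even in the intact liver and no
quiescent fixed point could exist. Thresholding at the basal level `IE_b`
(default 1, the basal IE under the default rates) restores an exact,
stable quiescent steady state while preserving the intended causality:
priming responds to IE *induction*, not to its constitutive presence.

The quiescent steady state solves in closed form (sequentially: TNF, IL-6,
a quadratic for STAT3 through the SOCS3 feedback, IE, ECM, GF) and is
verified to residual < 1e−8. Resection multiplies Q by (1 − f) and zeroes
P and R, leaving molecular levels continuous; the load m jumps through N.

Default rates are **calibration artifacts**, not literature estimates. They
were fixed once against three qualitative constraints: the basal state is a
stable fixed point (all components exactly 1 under the defaults, which
makes the normalization transparent); a 60% resection recovers ≥ 95% of
volume within 12 months; and peak replication falls between 1 and 10 days,
the proliferative window of regeneration. A structural stability condition
matters here: `k_div < θ_R + δ_R`, i.e. each replicating cell produces
fewer than one net descendant per residence, so replication shuts down when
priming stops instead of growing autonomously; recovery overshoot is then
bounded by the P/R pool in flight when the load normalizes. Volume is read
out as V = Q + h_P P + h_R R with h_P = h_R = 1.5, encoding hypertrophy of
the active compartments. Time is in hours everywhere; integration uses
`deSolve::lsoda` (rtol 1e−8, atol 1e−10) with sub-tolerance negative
undershoots clipped at zero.

## Neural maps

Both maps are three-layer fully connected networks, input → 64 → 128 →
output, rectifier after each hidden layer, dropout 0.2 after each hidden
layer during training only. The forward map takes the K cluster values
plus, by default, the resected fraction as an input feature — the cleanest
way to let the mapped state depend on the extent of resection (a
configuration switch removes it). The reverse map takes the 10-component
state vector in the fixed order Q, P, R, TNF, IL6, STAT3, SOCS3, IE, GF,
ECM. Training minimizes mean squared error with Adam (learning rate 1e−3,
2000 epochs, full batch, no early stopping — small-data settings chosen
once and exposed in `net_spec()`). Inputs and targets are standardized per
feature on the training set and the standardization inverted at
prediction; without it the heterogeneous magnitudes of the state components
dominate the loss. All arithmetic is plain R matrix algebra, so a fixed
seed yields bit-identical weights and loss logs; the hand-written
backpropagation is verified against central finite differences at 1e−5.

Dropout is a regularizer for the real use case — a dozen patients — and
imposes an error floor of roughly 0.02 (standardized MSE) on tasks a
network could otherwise fit exactly. The optimizer-correctness diagnostic
(learning the identity on 500 random vectors to MSE < 0.01) therefore runs
with dropout disabled; the noisy-regression bound (held-out MSE ≤ 2σ² +
0.05 on a smooth squashed map of simulated states with σ = 0.1 noise) keeps
the full default architecture including dropout.

## The twin loop and its conventions

Forecasting patient X from starting point t₀: the forward map sends the
cluster expression observed at t₀ (plus f) to a model state, clipped at 0.
If t₀ is pre-resection, that state is interpreted as the intact-liver state;
the resection is applied and the clock starts at hour 0. If t₀ is
post-operative (5 or 30 minutes), the mapped state is used directly and
integration starts at t₀'s clock time. The simulated state at each later
grid point is reverse-mapped into predicted cluster expression. The
baseline column of a forecast is always the observed input, never a
prediction.

Evaluation is per cluster over observed post-t₀ points: MSE and Pearson
correlation. Clusters with fewer than two usable points or zero variance
have no defined correlation; they are flagged and excluded from the
correlation average (with a count reported) rather than imputed as 0,
which would silently depress averages. Note that a constant offset leaves
Pearson at 1 while moving MSE — the two metrics are deliberately
complementary.

Train/test splitting orders patients by descending availability (ties:
original order) and trains on the top two-thirds. This mirrors the natural
experiment in this kind of cohort: the patients missing late samples are
exactly the ones whose futures need predicting.

## The synthetic cohort: what it emulates, and what not

Each synthetic patient draws a resection fraction uniformly from
[0.5, 0.7] (the realistic range for living-donor hepatectomies), is
simulated through the mechanistic model over the study grid, and receives
K = 15 cluster trajectories through a fixed random *affine-plus-tanh* map
of the state vector, anchored so the intact state maps to exactly zero
fold change. The squashing matters: a linear truth map would let a linear
readout win and would not exercise the reverse network's nonlinearity. Each
of the 40 genes per cluster scatters around its cluster trajectory with a
per-gene multiplicative factor (sd 0.1) and additive Gaussian noise
(sd 0.1, the default study condition); the baseline column is forced to 0.
Missingness is block-structured: the last third of patients lose their 2–4
latest time points, reproducing the availability-sorted data layout that
motivates the train/test split. A companion raw-scale tensor (the exact
preimage of the fold changes around positive per-gene baselines) exercises
the full preprocessing path; round-tripping it recovers the fold-change
tensor to numerical precision.

What the synthetic cohort does *not* model: count-level properties of
RNA-seq (library size, overdispersion), batch effects, genes outside the
clustered set, inter-patient differences beyond the resection fraction, and
any misspecification between the data-generating dynamics and the model —
the generator uses the same ODE family the twin fits. Passing end-to-end
tests therefore demonstrates that the pipeline machinery is correct and
that the mapping/simulation loop can recover dynamics it is capable of
representing; it does not certify predictive accuracy on real donors.

## Problem sizes and numerical conventions in the test suite

The end-to-end experiments use the default cohort (12 patients, 600 genes,
15 clusters, σ = 0.1, 8/4 split) with three seeded repeats, requiring
held-out cluster-average Pearson ≥ 0.8 and MSE ≤ 0.3 × signal variance in
at least two of three; clustering purity uses three archetypes × 90 genes
over five seeds (≥ 0.9 in at least four, exactly 1 at σ = 0); the
topological-overlap oracle runs 50 random networks of up to 20 genes at
1e−12; map-training bounds use 500 training pairs. The starting-point
robustness check compares forecasts launched from the baseline, 5-minute
and 30-minute samples and requires the per-time-point MSE spread at the
last three grid points to stay below 50% of its mean; because the held-out
patients are precisely the ones missing late observations, that comparison
is scored against the generator's noise-free truth trajectories, which
exist at all points.

## Known limitations

* The ODE instantiation realizes the qualitative interaction structure of
  the regeneration cascade; its parameter values are calibrated, not
  fitted, and carry no quantitative claim about any specific dataset.
* Cluster-level forecasting only: gene-level reconstruction within a
  cluster is out of scope, as are enrichment analysis and any biological
  interpretation of the modules.
* One map is trained across all time points (pooled), not one per time
  point; with a dozen patients, per-time-point training would be badly
  underdetermined.
* The fixed-height tree cut is simpler than dynamic tree-cut algorithms and
  can split large loose modules differently; the SOM refinement largely
  absorbs this, but the cut height is exposed for tuning.
* Forecast uncertainty is not quantified; reports carry point predictions
  and residual metrics only.
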