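# hepatwin

Patient-specific digital twins of liver regeneration after partial
hepatectomy, built from longitudinal blood gene expression.

## The problem

Living liver donors undergo a partial hepatectomy (PHx) and regenerate most
of their liver mass within a year. Their blood transcriptome tracks this
recovery: thousands of genes move in coordinated temporal waves — an early
inflammatory burst within 24 h, a proliferative program between 1 and 10
days, and a long-term remodeling phase beyond 3 months. `hepatwin` connects
these molecular readouts to a mechanistic model of the regenerating liver,
so that a single early blood sample (even the preoperative one) can be
projected forward into a patient's expected expression trajectory over the
following year.

The package is aimed at computational biologists working with longitudinal
omics from surgical cohorts, and at modelers who want a fully testable,
self-contained implementation of the hybrid mechanistic/learned "digital
twin" pattern.

## What it implements

The pipeline has five stages, each an exported module:

1. **Preprocessing** (`impute_missing`, `correct_negatives`,
   `log_transform`, `to_log2fc`, `select_degs`): cross-patient imputation,
   negative-value correction, the `log2(1 + x)` transform, per-patient
   log2 fold changes against the preoperative baseline, and
   differential-expression filtering (≥ 2-fold at ≥ 2 consecutive
   post-operative points, minus genes moving ≥ 1.5-fold at pre-resection
   samples, which reflect the incision rather than the liver).
2. **Temporal clustering** (`correlation_matrix`, `pick_soft_threshold`,
   `tom_similarity`, `detect_modules`, `som_refine`, `cluster_profiles`,
   `tag_modules`): a weighted co-expression network (adjacency
   `|cor|^β` with β chosen by scale-free topology fit), topological-overlap
   similarity, average-linkage module detection, refinement by a
   self-organizing map into K clusters (default 15 on a 5 × 3 grid), and
   tagging of each cluster as early / proliferation / long-term by its peak
   time.
3. **Mechanistic model** (`ode_params`, `liver_rhs`,
   `quiescent_steady_state`, `apply_resection`, `simulate_liver`,
   `simulate_patient`): hepatocytes transition between quiescent (Q),
   primed (P) and replicating (R) states. Resection raises the metabolic
   load per hepatocyte m = M/N, which drives TNF and growth-factor
   production; TNF degrades the extracellular matrix and induces IL-6 →
   STAT3 → (SOCS3 feedback, immediate-early genes); IE excess primes Q → P,
   growth factor drives P → R, and matrix restoration reverses both. Liver
   volume is V = Q + 1.5 P + 1.5 R (hypertrophy of active cells).
4. **Neural maps** (`net_spec`, `train_map`, `apply_map`,
   `build_training_pairs`): two feed-forward networks
   (input → 64 → 128 → output, rectifier activations, dropout 0.2 during
   training, Adam on mean squared error) map cluster expression (+ resected
   fraction) to the 10-component model state and back.
5. **The twin** (`run_twin`, `evaluate_forecast`, `robustness_compare`,
   `split_cohort`, `twin_experiment`): forward-map the expression observed
   at a starting time point, simulate the mechanistic model forward, and
   reverse-map each simulated state into predicted cluster expression;
   score predictions with per-cluster MSE and Pearson correlation.

Because the original donor dataset is not deposited, the package ships a
seeded synthetic-cohort generator (`gen_cohort`, `gen_archetypes`,
`gen_deg_toy`) that emulates its structure — 12 patients, 15 time points
from 5 minutes to 12 months, genes grouped in temporal clusters, Gaussian
noise, and block missingness of late samples — with full ground truth, so
every stage is testable end to end.

## Worked example

```r
library(hepatwin)

# a seeded synthetic cohort with known truth
cohort <- gen_cohort(synth_config(seed = 42))
cohort$tensor
#> <expression_tensor> 600 genes x 12 patients x 15 time points [log2fc], 94.4% observed

split_cohort(cohort$tensor)$test      # patients lacking late samples
#> [1] "P09" "P10" "P11" "P12"

# full twin loop: train maps on 8 patients, forecast the other 4
ex <- twin_experiment(42)
ex$reports[["P09"]]
#> <eval_report> avg MSE 0.0033; avg Pearson 0.974 (0 cluster(s) undefined); 30 masked points skipped
round(c(pearson = ex$mean_pearson, mse = ex$mean_mse), 3)
#> pearson     mse
#>   0.968   0.005

# the mechanistic model alone: 60% resection, one-year grid
sim <- simulate_patient(ode_params(), f = 0.6, default_time_grid())
round(sim$volume, 3)
#> Before Surgery  5 min  30 min  1 hour ... 4 days  10 days  3 months  6 months  12 months
#>          1.000  0.400   0.400   0.400 ...  0.580    0.769     1.000     1.000      1.000
```

The eval report's Pearson averages the per-cluster correlations between
predicted and observed cluster trajectories over the held-out patient's
post-baseline samples; the volume series shows the liver dropping to 40% at
resection and recovering fully by 3 months, with the proliferative burst
peaking around day 3–4.

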