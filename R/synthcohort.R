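# Seeded synthetic cohorts with known ground truth.
#
# Each synthetic patient is a mechanistically simulated regeneration course:
# a resection fraction is drawn, the ODE model is integrated over the study
# grid, and a fixed random affine-plus-squashing "truth map" turns the state
# vector into K cluster-level log2 fold changes (anchored so the
# pre-resection state maps to exactly 0). Member genes scatter around their
# cluster trajectory with a per-gene multiplicative factor and additive
# Gaussian noise, and a block-structured missingness mask removes late time
# points for the lowest-availability third of patients, mimicking the
# real cohort's data structure.

#' Configuration of a synthetic cohort
#'
#' @param n_patients number of patients (default 12).
#' @param K number of gene clusters (default 15).
#' @param genes_per_cluster member genes per cluster (default 40).
#' @param f_range range of the uniform resection-fraction draw
#'   (default `c(0.5, 0.7)`).
#' @param noise_sd additive gene-level noise sd on the log2FC scale
#'   (default 0.1).
#' @param gene_scale_sd sd of the per-gene multiplicative factor around its
#'   cluster trajectory (default 0.1).
#' @param missing_late integer vector (length `n_patients`) of late time
#'   points dropped per patient; default removes 2--4 late points from the
#'   last third of patients and none elsewhere.
#' @param baseline_expr median raw-scale baseline expression used when
#'   emitting the companion raw tensor (default 50).
#' @param seed RNG seed; the whole cohort is a deterministic function of it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_patients = 12, K = 15, genes_per_cluster = 40,
                         f_range = c(0.5, 0.7), noise_sd = 0.1,
                         gene_scale_sd = 0.1, missing_late = NULL,
                         baseline_expr = 50, seed = 1) {
  if (n_patients < 0 || K < 1 || genes_per_cluster < 1)
    stop("counts must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (any(f_range < 0) || any(f_range >= 1)) stop("f_range must lie in [0, 1)")
  if (is.null(missing_late)) {
    missing_late <- rep(0L, n_patients)
    n_test <- ceiling(n_patients / 3)
    if (n_test > 0 && n_patients > 0) {
      tail_idx <- seq(n_patients - n_test + 1, n_patients)
      missing_late[tail_idx] <- pmin(2L + (seq_len(n_test) - 1L) %/% 2L, 4L)
    }
  }
  if (length(missing_late) != n_patients)
    stop("missing_late must have one entry per patient")
  structure(list(n_patients = n_patients, K = K,
                 genes_per_cluster = genes_per_cluster, f_range = f_range,
                 noise_sd = noise_sd, gene_scale_sd = gene_scale_sd,
                 missing_late = as.integer(missing_late),
                 baseline_expr = baseline_expr, seed = as.integer(seed)),
            class = "synth_config")
}

# draw the affine-plus-squashing truth map: K cluster values from a state
# vector, anchored at the quiescent state (maps to 0)
draw_truth_map <- function(K, state_dim, anchor) {
  W <- matrix(stats::rnorm(K * state_dim, 0, 0.4), K, state_dim)
  b <- stats::rnorm(K, 0, 0.3)
  amp <- stats::runif(K, 1.5, 3)
  offset <- amp * tanh(drop(W %*% anchor) + b)
  list(W = W, b = b, amp = amp, offset = offset)
}

# evaluate the truth map on a state vector (or time x state matrix)
truth_map_eval <- function(tm, states) {
  S <- if (is.null(dim(states))) matrix(states, 1) else as.matrix(states)
  out <- tm$amp * tanh(tm$W %*% t(S) + tm$b) - tm$offset  # K x T
  out
}

#' Generate a synthetic cohort with full ground truth
#'
#' @param cfg a [synth_config()].
#' @param params an [ode_params()] (defaults used when omitted).
#' @param grid a [time_grid()] (default [default_time_grid()]).
#' @return A list:
#'   `tensor` -- log2fc-scale [expression_tensor()] with the missingness
#'   mask applied; `raw` -- the companion raw-scale tensor (the exact
#'   preimage of the log2FC values around a positive per-gene baseline, for
#'   exercising the preprocessing pipeline); `truth` -- a `synth_truth` list
#'   with per-patient `f`, simulated trajectories `sims`, the truth-map
#'   parameters, ground-truth `labels` (gene -> cluster), per-gene scale
#'   factors `gene_scale`, noise-free cluster trajectories `cluster_true`
#'   (K x patient x time), and the `seed`.
#' @export
gen_cohort <- function(cfg, params = ode_params(), grid = default_time_grid()) {
  K <- cfg$K; G <- K * cfg$genes_per_cluster
  nP <- cfg$n_patients; nT <- length(grid$hours)
  with_seed(cfg$seed, {
    ss <- quiescent_steady_state(params)
    tm <- draw_truth_map(K, length(ss), state_vector(ss))
    f <- stats::runif(nP, cfg$f_range[1], cfg$f_range[2])
    gene_scale <- stats::rnorm(G, 0, cfg$gene_scale_sd)
    labels <- rep(seq_len(K), each = cfg$genes_per_cluster)
    gene_ids <- sprintf("g%03d_c%02d", seq_len(G), labels)
    names(labels) <- gene_ids
    base_raw <- stats::rlnorm(G, log(cfg$baseline_expr), 0.5)

    vals <- array(NA_real_, c(G, nP, nT))
    cluster_true <- array(NA_real_, c(K, nP, nT))
    sims <- list()
    for (p in seq_len(nP)) {
      sim <- simulate_patient(params, f[p], grid)
      sims[[p]] <- sim
      ct <- truth_map_eval(tm, sim$states[, STATE_ORDER])   # K x T
      cluster_true[, p, ] <- ct
      eps <- matrix(stats::rnorm(G * nT, 0, cfg$noise_sd), G, nT)
      vals[, p, ] <- ct[labels, , drop = FALSE] * (1 + gene_scale) + eps
      vals[, p, baseline_idx(grid)] <- 0
    }
    mask <- array(TRUE, c(G, nP, nT))
    for (p in seq_len(nP)) {
      k <- cfg$missing_late[p]
      if (k > 0) mask[, p, seq(nT - k + 1, nT)] <- FALSE
    }
    vals[!mask] <- NA_real_
    patient_ids <- sprintf("P%02d", seq_len(nP))
    names(sims) <- patient_ids
    tensor <- expression_tensor(vals, mask, "log2fc", gene_ids, patient_ids, grid)

    raw_vals <- (1 + base_raw) * 2^vals - 1
    raw_vals[!mask] <- NA_real_
    raw <- expression_tensor(raw_vals, mask, "raw", gene_ids, patient_ids, grid)

    truth <- structure(list(f = stats::setNames(f, patient_ids), sims = sims,
                            truth_map = tm, labels = labels,
                            gene_scale = gene_scale, base_raw = base_raw,
                            cluster_true = cluster_true, seed = cfg$seed),
                       class = "synth_truth")
    list(tensor = tensor, raw = raw, truth = truth)
  })
}

#' A 5-gene toy with a hand-enumerated differential-expression answer
#'
#' Constructs a small fold-change tensor on a grid that carries a
#' post-incision, pre-resection sample, with: two genes exceeding two-fold
#' at two consecutive post-operative points (one up-, one down-regulated),
#' one gene that passes the two-fold rule but moves more than 1.5-fold at
#' the pre-resection sample (a nonspecific surgical response), one gene with
#' a single isolated spike, and one flat gene. Exactly the two clean passers
#' should be selected.
#'
#' @param seed RNG seed for the small jitter between the two toy patients.
#' @return List: `tensor` (log2fc scale) and `expected` (the enumerated
#'   `n_twofold`, `n_presurgical_excluded`, `n_selected`, `selected`).
#' @export
gen_deg_toy <- function(seed = 1) {
  grid <- time_grid(
    labels = c("Before Surgery", "Incision", "1 hour", "4 hours", "1 day", "4 days"),
    hours = c(0, 0, 1, 4, 24, 96),
    pre_resection = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  # per-gene profiles: baseline, incision, then 4 post-op points
  profiles <- rbind(
    g_up     = c(0, 0.00, 1.2, 1.1, 0.2, 0.0),   # two-fold at two consecutive
    g_down   = c(0, 0.20, -1.3, -1.1, 0.0, 0.0), # same, down-regulated
    g_incis  = c(0, 0.70, 1.5, 1.4, 0.3, 0.0),   # passes but 2^0.7 = 1.62-fold pre-resection
    g_spike  = c(0, 0.00, 0.0, 3.0, 0.0, 0.0),   # isolated single point
    g_flat   = c(0, 0.10, 0.3, 0.2, 0.1, 0.0))
  vals <- array(NA_real_, c(5, 2, 6))
  with_seed(seed, {
    for (p in 1:2) vals[, p, ] <- profiles +
        matrix(stats::rnorm(30, 0, 0.005), 5, 6) * rep(c(0, 1, 1, 1, 1, 1), each = 5)
  })
  # symmetrize so the cross-patient mean equals the stated profile exactly
  vals[, 2, ] <- 2 * profiles - vals[, 1, ]
  tensor <- expression_tensor(vals, scale = "log2fc",
                              gene_ids = rownames(profiles),
                              patient_ids = c("P1", "P2"), grid = grid)
  list(tensor = tensor,
       expected = list(n_twofold = 3L, n_presurgical_excluded = 1L,
                       n_selected = 2L, selected = c("g_up", "g_down")))
}

#' Well-separated temporal archetypes for clustering purity checks
#'
#' Builds K archetype trajectories spread over the three regeneration
#' phases -- an early spike (peak within 24 h), a mid bump (1--10 days) and
#' a late ramp (beyond 3 months) -- assigns `n_genes` round-robin to them,
#' and adds Gaussian noise.
#'
#' @param K number of archetypes (>= 2).
#' @param n_genes total genes (>= K).
#' @param sigma additive noise sd.
#' @param seed RNG seed.
#' @param n_patients patients to replicate (default 3).
#' @param grid a [time_grid()] (default [default_time_grid()]).
#' @return List: `tensor` (log2fc scale), `labels` (gene -> archetype),
#'   `archetypes` (K x T matrix).
#' @export
gen_archetypes <- function(K, n_genes, sigma = 0, seed = 1, n_patients = 3,
                           grid = default_time_grid()) {
  if (K > n_genes) stop("K exceeds the number of genes")
  h <- grid$hours
  shape <- function(kind, peak, scale) switch(kind,
    spike = scale * (h / peak) * exp(1 - h / peak),
    bump  = scale * exp(-(log(pmax(h, 1e-6) / peak))^2 / 0.8) * (h > 0),
    ramp  = scale * pmin(h / peak, 1.5))
  kinds <- rep(c("spike", "bump", "ramp"), length.out = K)
  peaks <- rep(c(2, 96, 2920), length.out = K)
  arch <- t(vapply(seq_len(K), function(k) {
    sgn <- if (k %% 2 == 0 && K > 3) -1 else 1
    sc <- 2 * (1 + 0.25 * ((k - 1) %/% 3))
    prof <- shape(kinds[k], peaks[k], sgn * sc)
    prof[1] <- 0
    prof
  }, h))
  labels <- rep(seq_len(K), length.out = n_genes)
  labels <- sort(labels)
  vals <- array(NA_real_, c(n_genes, n_patients, length(h)))
  with_seed(seed, {
    for (p in seq_len(n_patients))
      vals[, p, ] <- arch[labels, , drop = FALSE] +
        matrix(stats::rnorm(n_genes * length(h), 0, sigma), n_genes)
  })
  vals[, , 1] <- 0
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  names(labels) <- gene_ids
  list(tensor = expression_tensor(vals, scale = "log2fc", gene_ids = gene_ids,
                                  patient_ids = paste0("P", seq_len(n_patients)),
                                  grid = grid),
       labels = labels, archetypes = arch)
}

#' Clustering purity against ground-truth labels
#'
#' Fraction of genes whose cluster's majority ground-truth label matches
#' their own: each discovered cluster is credited with its most common truth
#' label.
#'
#' @param assigned named integer vector or `cluster_assignment`.
#' @param truth named ground-truth labels.
#' @return Purity in `[0, 1]`.
#' @export
cluster_purity <- function(assigned, truth) {
  a <- if (inherits(assigned, "cluster_assignment")) assigned$labels else assigned
  truth <- truth[names(a)]
  sum(vapply(split(truth, a), function(x) max(table(x)), 0)) / length(a)
}
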