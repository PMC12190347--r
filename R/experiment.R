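#' Run a full twin experiment on a synthetic cohort
#'
#' The complete loop on generated data with known truth: generate a cohort,
#' compute cluster trajectories from the ground-truth gene memberships,
#' split patients into training and test thirds by data availability, train
#' the forward and reverse maps on the training patients' (expression,
#' simulated state) pairs, then forecast every held-out patient from the
#' chosen starting point and score the forecasts. Cluster discovery itself
#' (network + SOM) is deliberately not in this loop so the mapping and
#' simulation stages are scored against a well-defined truth; it is
#' exercised and scored separately via archetype purity.
#'
#' @param seed master seed; the cohort and both map initializations derive
#'   from it.
#' @param cfg a [synth_config()]; defaults to `synth_config(seed = seed)`.
#' @param params an [ode_params()].
#' @param grid a [time_grid()].
#' @param t0 starting label for the forecasts (default the baseline).
#' @param spec_overrides named list passed on to both [net_spec()]s
#'   (e.g. `list(epochs = 500)`).
#' @return A list: `reports` (per test patient [evaluate_forecast()]
#'   results), `mean_pearson`, `mean_mse`, `signal_var` (variance of the
#'   observed test-patient cluster values over predicted points), `split`,
#'   `fwd`, `rev`, `cohort`, `traj`.
#' @export
twin_experiment <- function(seed, cfg = synth_config(seed = seed),
                            params = ode_params(), grid = default_time_grid(),
                            t0 = "Before Surgery", spec_overrides = list()) {
  cohort <- gen_cohort(cfg, params, grid)
  traj <- cluster_profiles(cohort$tensor, cohort$truth$labels)
  split <- split_cohort(cohort$tensor)
  sub <- function(tr, ids) {
    keep <- match(ids, tr$patient_ids)
    tr$values <- tr$values[, keep, , drop = FALSE]
    tr$mask <- tr$mask[, keep, , drop = FALSE]
    tr$patient_ids <- ids
    tr
  }
  tr_traj <- sub(traj, split$train)
  pairs_f <- build_training_pairs(tr_traj, cohort$truth$sims, "forward")
  pairs_r <- build_training_pairs(tr_traj, cohort$truth$sims, "reverse")
  K <- cfg$K; S <- ncol(pairs_f$targets)
  mk_spec <- function(ind, outd, s) {
    args <- utils::modifyList(list(input_dim = ind, output_dim = outd, seed = s),
                              spec_overrides)
    do.call(net_spec, args)
  }
  fwd <- train_map(pairs_f, mk_spec(ncol(pairs_f$inputs), S, seed + 1L))
  rev <- train_map(pairs_r, mk_spec(S, K, seed + 2L))
  i0 <- match(t0, grid$labels)
  if (is.na(i0)) stop("t0 not on the grid: ", t0)
  reports <- list()
  sig <- c()
  for (pid in split$test) {
    p <- match(pid, traj$patient_ids)
    fc <- run_twin(traj$values[, p, i0], cohort$truth$f[pid], t0, grid,
                   fwd, params, rev)
    fc$patient <- pid
    reports[[pid]] <- evaluate_forecast(fc, traj, pid)
    obs <- traj$values[, p, fc$pred_idx, drop = FALSE]
    sig <- c(sig, obs[traj$mask[, p, fc$pred_idx, drop = FALSE]])
  }
  pe <- vapply(reports, function(r) r$avg_pearson, 0)
  ms <- vapply(reports, function(r) r$avg_mse, 0)
  list(reports = reports, mean_pearson = mean(pe), mean_mse = mean(ms),
       signal_var = stats::var(sig), split = split, fwd = fwd, rev = rev,
       cohort = cohort, traj = traj)
}

#' Initial-time-point robustness on a synthetic cohort
#'
#' For every held-out patient of a [twin_experiment()], re-runs the twin
#' from each starting choice and computes the mean squared error per
#' predicted grid point against the noise-free ground-truth cluster
#' trajectories (which, unlike the observations, exist at the late points
#' the block missingness removes). Returns the per-time-point MSE averaged
#' over clusters and patients, one row per starting choice.
#'
#' @param ex a [twin_experiment()] result.
#' @param t0_choices starting labels (default baseline, 5 min, 30 min).
#' @return A matrix, starting choice x grid label, of mean squared errors
#'   (`NA` where a choice does not predict that point).
#' @export
robustness_matrix <- function(ex, t0_choices = c("Before Surgery", "5 min", "30 min")) {
  grid <- ex$traj$grid
  truth <- ex$cohort$truth
  K <- dim(truth$cluster_true)[1]
  out <- matrix(NA_real_, length(t0_choices), length(grid$labels),
                dimnames = list(t0_choices, grid$labels))
  for (ti in seq_along(t0_choices)) {
    t0 <- t0_choices[ti]
    i0 <- match(t0, grid$labels)
    if (is.na(i0)) next
    acc <- matrix(0, K, length(grid$labels)); cnt <- 0
    for (pid in ex$split$test) {
      p <- match(pid, ex$traj$patient_ids)
      if (!all(ex$traj$mask[, p, i0])) next
      fc <- run_twin(ex$traj$values[, p, i0], truth$f[pid], t0, grid,
                     ex$fwd, ex$cohort$truth$sims[[pid]]$params, ex$rev)
      ptruth <- truth$cluster_true[, match(pid, names(truth$f)), ]
      err <- (fc$predicted - ptruth)^2
      acc[, fc$pred_idx] <- acc[, fc$pred_idx] + err[, fc$pred_idx]
      cnt <- cnt + 1
    }
    if (cnt > 0) {
      mseq <- colMeans(acc) / cnt
      pred_cols <- which(grid$hours > grid$hours[i0] & !grid$pre_resection)
      out[ti, pred_cols] <- mseq[pred_cols]
    }
  }
  out
}
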