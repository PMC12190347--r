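# The digital-twin loop: forward-map an early expression profile to a
# mechanistic state, simulate regeneration forward, reverse-map the simulated
# states to predicted cluster expression at future time points.

#' Split a cohort into training and test patients by data availability
#'
#' Patients are ordered by descending number of available time points (ties
#' broken by their original order); the top two-thirds train, the rest test.
#' Mirrors the design where the patients lacking late samples become the
#' forecasting test set. Explicit lists override the rule.
#'
#' @param t an [expression_tensor()] or [cluster_profiles()] result (any
#'   object with `mask` and `patient_ids`).
#' @param train,test optional explicit patient-id character vectors.
#' @return List with `train` and `test` patient-id vectors.
#' @export
split_cohort <- function(t, train = NULL, test = NULL) {
  ids <- t$patient_ids
  if (!is.null(train) || !is.null(test)) {
    train <- train %||% setdiff(ids, test)
    test <- test %||% setdiff(ids, train)
    return(list(train = train, test = test))
  }
  avail <- vapply(seq_along(ids), function(p)
    sum(apply(t$mask[, p, , drop = FALSE], 3, any)), 0L)
  ord <- order(-avail, seq_along(ids))   # stable: ties keep original order
  n_train <- floor(2 * length(ids) / 3)
  list(train = ids[sort(ord[seq_len(n_train)])],
       test = ids[sort(ord[-seq_len(n_train)])])
}

#' Run the digital twin for one patient
#'
#' Maps the expression profile at the starting time point to a mechanistic
#' state, simulates the regeneration model forward, and reverse-maps the
#' simulated state at every later grid point to predicted cluster expression.
#' Starting from the preoperative baseline, the mapped state is taken as the
#' pre-resection state and the resection (fraction `f`) is applied at hour 0;
#' starting from an early post-operative point, the mapped state is used
#' directly at that clock time.
#'
#' @param expr0 K-vector of cluster log2 fold changes observed at `t0`.
#' @param f the patient's resected fraction.
#' @param t0 label of the starting grid point (a pre-resection label means
#'   baseline initialization).
#' @param grid a [time_grid()].
#' @param fwd trained forward map (expression \[+ f\] -> state).
#' @param params an [ode_params()].
#' @param rev trained reverse map (state -> expression).
#' @return A `twin_forecast`: `patient` (NA unless set by the caller), `t0`,
#'   `f`, `predicted` (K x T matrix, columns = grid labels; `NA` at and
#'   before `t0`), `simulated` trajectory, `pred_idx` (predicted columns).
#' @export
run_twin <- function(expr0, f, t0, grid, fwd, params, rev) {
  i0 <- match(t0, grid$labels)
  if (is.na(i0)) stop("t0 not on the grid: ", t0)
  K <- rev$spec$output_dim
  x_in <- if (fwd$spec$input_dim == length(expr0) + 1) c(expr0, f)
  else if (fwd$spec$input_dim == length(expr0)) expr0
  else stop("forward map expects the resection fraction but input widths do not line up")
  state0 <- apply_map(fwd, x_in)
  if (any(!is.finite(state0))) stop("forward map produced non-finite state")
  state0 <- vector_to_state(pmax(state0, 0))
  from_baseline <- grid$pre_resection[i0]
  if (from_baseline) state0 <- apply_resection(state0, f)
  later <- which(grid$hours > grid$hours[i0] & !grid$pre_resection)
  t_start <- if (from_baseline) 0 else grid$hours[i0]
  sim <- simulate_liver(params, state0, c(t_start, grid$hours[later]))
  predicted <- matrix(NA_real_, K, length(grid$hours),
                      dimnames = list(paste0("C", seq_len(K)), grid$labels))
  if (length(later)) {
    preds <- apply_map(rev, sim$states[-1, , drop = FALSE])
    predicted[, later] <- t(as.matrix(preds))
  }
  structure(list(patient = NA_character_, t0 = t0, f = f,
                 predicted = predicted, simulated = sim,
                 pred_idx = later, grid = grid),
            class = "twin_forecast")
}

#' @export
print.twin_forecast <- function(x, ...) {
  cat(sprintf("<twin_forecast> from '%s' (f = %.2f): %d predicted time points x %d clusters\n",
              x$t0, x$f, length(x$pred_idx), nrow(x$predicted)))
  invisible(x)
}

pearson_or_na <- function(a, b) {
  if (length(a) < 2 || stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Evaluate a forecast against observed cluster trajectories
#'
#' Per cluster, over the observed post-`t0` grid points: mean squared error
#' and Pearson correlation between predicted and observed values. Clusters
#' with fewer than 2 usable points or zero variance get an undefined
#' correlation flag and are excluded from the correlation average; masked
#' observations never enter any metric.
#'
#' @param forecast a [run_twin()] result.
#' @param observed a [cluster_profiles()] result (or compatible list with
#'   `values`/`mask`), for one patient or with `patient` naming the column.
#' @param patient patient id selecting the column of `observed`
#'   (default: first).
#' @return An `eval_report`: `per_cluster` data.frame (cluster, n, mse,
#'   pearson, pearson_defined), `avg_mse`, `avg_pearson`,
#'   `n_undefined_pearson`, `per_timepoint` data.frame (timepoint, mse),
#'   `n_masked_skipped`.
#' @export
evaluate_forecast <- function(forecast, observed, patient = NULL) {
  p <- if (is.null(patient)) 1L else match(patient, observed$patient_ids)
  if (is.na(p)) stop("patient not found in observed trajectories")
  idx <- forecast$pred_idx
  K <- nrow(forecast$predicted)
  per <- data.frame(cluster = seq_len(K), n = 0L, mse = NA_real_,
                    pearson = NA_real_, pearson_defined = FALSE)
  skipped <- 0L
  for (k in seq_len(K)) {
    obs_ok <- observed$mask[k, p, idx]
    skipped <- skipped + sum(!obs_ok)
    use <- idx[obs_ok]
    if (!length(use)) next
    pr <- forecast$predicted[k, use]
    ob <- observed$values[k, p, use]
    per$n[k] <- length(use)
    per$mse[k] <- mean((pr - ob)^2)
    r <- pearson_or_na(pr, ob)
    per$pearson[k] <- r
    per$pearson_defined[k] <- !is.na(r)
  }
  ptp <- data.frame(timepoint = forecast$grid$labels[idx],
                    hours = forecast$grid$hours[idx], mse = NA_real_)
  for (j in seq_along(idx)) {
    tt <- idx[j]
    ok <- observed$mask[, p, tt]
    if (any(ok))
      ptp$mse[j] <- mean((forecast$predicted[ok, tt] -
                            observed$values[ok, p, tt])^2)
  }
  structure(list(per_cluster = per,
                 avg_mse = mean(per$mse, na.rm = TRUE),
                 avg_pearson = if (any(per$pearson_defined))
                   mean(per$pearson[per$pearson_defined]) else NA_real_,
                 n_undefined_pearson = sum(!per$pearson_defined),
                 per_timepoint = ptp,
                 n_masked_skipped = skipped),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> avg MSE %.4f; avg Pearson %s (%d cluster(s) undefined); %d masked points skipped\n",
              x$avg_mse,
              ifelse(is.na(x$avg_pearson), "NA", sprintf("%.3f", x$avg_pearson)),
              x$n_undefined_pearson, x$n_masked_skipped))
  invisible(x)
}

#' Compare forecast accuracy across alternative starting time points
#'
#' Re-runs the twin for each requested starting point (typically baseline,
#' 5 minutes and 30 minutes) and tabulates per-time-point mean squared
#' errors, the layout used to ask whether a later start improves prediction.
#' A start with no observation is skipped with a warning.
#'
#' @param observed a [cluster_profiles()] result.
#' @param patient patient id.
#' @param f resected fraction of that patient.
#' @param t0_choices starting labels (default baseline, 5 min, 30 min).
#' @param fwd,params,rev as in [run_twin()].
#' @return Named list of `eval_report`s (one per usable start), with
#'   attribute `forecasts` holding the matching `twin_forecast`s.
#' @export
robustness_compare <- function(observed, patient, f,
                               t0_choices = c("Before Surgery", "5 min", "30 min"),
                               fwd, params, rev) {
  p <- match(patient, observed$patient_ids)
  if (is.na(p)) stop("unknown patient: ", patient)
  reports <- list(); fcs <- list()
  for (t0 in t0_choices) {
    tt <- match(t0, observed$grid$labels)
    if (is.na(tt) || !all(observed$mask[, p, tt])) {
      warning(sprintf("no observation at '%s' for %s; skipped", t0, patient),
              call. = FALSE)
      next
    }
    fc <- run_twin(observed$values[, p, tt], f, t0, observed$grid,
                   fwd, params, rev)
    fc$patient <- patient
    reports[[t0]] <- evaluate_forecast(fc, observed, patient)
    fcs[[t0]] <- fc
  }
  attr(reports, "forecasts") <- fcs
  reports
}
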