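make_traj <- function(vals, mask = NULL, grid = tiny_grid(),
                      patients = paste0("P", seq_len(dim(vals)[2]))) {
  if (is.null(mask)) mask <- array(TRUE, dim(vals))
  structure(list(values = vals, spread = vals * 0, mask = mask,
                 clusters = seq_len(dim(vals)[1]), patient_ids = patients,
                 grid = grid), class = "cluster_trajectory")
}

test_that("the cohort splits two-thirds/one-third by availability with stable ties", {
  mk <- function(avail_per_patient, nT = 4) {
    nP <- length(avail_per_patient)
    mask <- array(FALSE, c(2, nP, nT))
    for (p in seq_len(nP)) mask[, p, seq_len(avail_per_patient[p])] <- TRUE
    structure(list(mask = mask, patient_ids = paste0("P", seq_len(nP))),
              class = "expression_tensor")
  }
  # 12 patients -> 8 train / 4 test, lowest availability tested
  t12 <- mk(c(4, 4, 4, 4, 4, 4, 4, 4, 3, 3, 2, 2))
  sp <- split_cohort(t12)
  expect_length(sp$train, 8); expect_length(sp$test, 4)
  expect_setequal(sp$test, c("P9", "P10", "P11", "P12"))
  # 3 patients -> 2/1
  sp3 <- split_cohort(mk(c(4, 3, 2)))
  expect_equal(sp3$train, c("P1", "P2")); expect_equal(sp3$test, "P3")
  # full tie: stable original order decides
  spt <- split_cohort(mk(c(4, 4, 4)))
  expect_equal(spt$train, c("P1", "P2")); expect_equal(spt$test, "P3")
  # explicit lists override
  spo <- split_cohort(t12, test = c("P01", "P02"))
  expect_setequal(spo$train, setdiff(t12$patient_ids, c("P01", "P02")))
})

test_that("forecast evaluation matches direct formulas and flags degenerate series", {
  grid <- tiny_grid()
  K <- 3
  obs <- array(rnorm(K * 1 * 4), c(K, 1, 4))
  obs[3, 1, ] <- 2                                   # constant cluster
  traj <- make_traj(obs, grid = grid, patients = "P1")
  pred <- matrix(rnorm(K * 4), K, 4, dimnames = list(NULL, grid$labels))
  fc <- structure(list(patient = "P1", t0 = "Before Surgery", f = 0.6,
                       predicted = pred, pred_idx = 2:4, grid = grid),
                  class = "twin_forecast")
  ev <- evaluate_forecast(fc, traj, "P1")
  for (k in 1:2) {
    expect_equal(ev$per_cluster$mse[k], mean((pred[k, 2:4] - obs[k, 1, 2:4])^2))
    expect_equal(ev$per_cluster$pearson[k], cor(pred[k, 2:4], obs[k, 1, 2:4]))
  }
  expect_false(ev$per_cluster$pearson_defined[3])    # zero variance
  expect_equal(ev$n_undefined_pearson, 1)
  expect_equal(ev$avg_pearson, mean(ev$per_cluster$pearson[1:2]))
  expect_equal(ev$per_cluster$mse[3], mean((pred[3, 2:4] - 2)^2))
  # perfect prediction and a constant shift
  fc$predicted[, 2:4] <- obs[, 1, 2:4]
  ev0 <- evaluate_forecast(fc, traj, "P1")
  expect_equal(ev0$per_cluster$mse[1:2], c(0, 0))
  expect_equal(ev0$per_cluster$pearson[1:2], c(1, 1))
  fc$predicted[, 2:4] <- obs[, 1, 2:4] + 1
  ev1 <- evaluate_forecast(fc, traj, "P1")
  expect_equal(ev1$per_cluster$mse[1:2], c(1, 1))
  expect_equal(ev1$per_cluster$pearson[1:2], c(1, 1))
})

test_that("masked observations never influence any metric", {
  grid <- tiny_grid()
  obs <- array(rnorm(2 * 1 * 4), c(2, 1, 4))
  mask <- array(TRUE, dim(obs)); mask[, 1, 3] <- FALSE
  pred <- matrix(rnorm(8), 2, 4, dimnames = list(NULL, grid$labels))
  fc <- structure(list(patient = "P1", t0 = "Before Surgery", f = 0.5,
                       predicted = pred, pred_idx = 2:4, grid = grid),
                  class = "twin_forecast")
  ev1 <- evaluate_forecast(fc, make_traj(obs, mask, grid, "P1"), "P1")
  obs2 <- obs; obs2[, 1, 3] <- 1e6                   # absurd values under the mask
  ev2 <- evaluate_forecast(fc, make_traj(obs2, mask, grid, "P1"), "P1")
  expect_equal(ev1$per_cluster, ev2$per_cluster)
  expect_equal(ev1$avg_mse, ev2$avg_mse)
  expect_equal(ev1$n_masked_skipped, 2)
})

test_that("the twin loop honors its maps: constant reverse map, empty horizons", {
  grid <- tiny_grid()
  p <- ode_params()
  ss <- quiescent_steady_state(p)
  fwd <- const_map(4, 10, state_vector(ss), direction = "forward")
  cvec <- c(0.3, -0.2, 1)
  rev <- const_map(10, 3, cvec)
  fc <- run_twin(rep(0, 3), 0.6, "Before Surgery", grid, fwd, p, rev)
  expect_equal(fc$pred_idx, 2:4)
  for (j in 2:4) expect_equal(unname(fc$predicted[, j]), cvec)
  expect_true(all(is.na(fc$predicted[, 1])))
  # starting at the last grid point leaves nothing to predict
  fc2 <- run_twin(rep(0, 3), 0.6, "4 days", grid, fwd, p, rev)
  expect_length(fc2$pred_idx, 0)
  expect_true(all(is.na(fc2$predicted)))
  # resection fraction is required when the forward spec expects it
  expect_error(run_twin(rep(0, 2), 0.6, "Before Surgery", grid, fwd, p, rev),
               "widths")
})

test_that("alternative starting points are compared and unobservable starts skipped", {
  grid <- tiny_grid()
  p <- ode_params()
  ss <- quiescent_steady_state(p)
  fwd <- const_map(4, 10, state_vector(ss), direction = "forward")
  rev <- const_map(10, 3, c(0, 0, 0))
  obs <- array(0.1, c(3, 1, 4))
  mask <- array(TRUE, dim(obs)); mask[, 1, 2] <- FALSE
  traj <- make_traj(obs, mask, grid, "P1")
  expect_warning(
    reps <- robustness_compare(traj, "P1", 0.6,
                               t0_choices = c("Before Surgery", "1 hour", "1 day"),
                               fwd = fwd, params = p, rev = rev),
    "skipped")
  expect_setequal(names(reps), c("Before Surgery", "1 day"))
  expect_s3_class(reps[["1 day"]], "eval_report")
})
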