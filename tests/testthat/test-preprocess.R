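test_that("cross-patient imputation fills means and reports unimputable cells", {
  # gene 1: patient 1 missing at t2, donors {2, 4} -> 3; gene 2: single donor 5
  m1 <- rbind(c(1, NA, 2, 3), c(1, NA, 1, 1), c(1, NA, 1, 1))
  m2 <- rbind(c(1, 2, 2, 3), c(1, 5, 1, 1), c(1, NA, 1, 1))
  m3 <- rbind(c(1, 4, 2, 3), c(1, NA, 1, 1), c(1, NA, 1, 1))
  t <- tensor_from(list(m1, m2, m3))
  out <- impute_missing(t)
  expect_equal(out$values[1, 1, 2], 3)            # mean of {2, 4}
  expect_equal(out$values[2, 2, 2], 5)            # single donor
  expect_true(out$mask[1, 1, 2] && out$mask[2, 2, 2])
  # gene 3 at t2: observed in zero patients -> stays masked, reported
  expect_false(any(out$mask[3, , 2]))
  expect_equal(attr(out, "unimputable")$gene, "g3")
  expect_true(all(attr(out, "imputed")[cbind(c(1, 2), c(1, 1), c(2, 2))]))
})

test_that("negative values are replaced by non-negative donor means, 0 untouched", {
  m1 <- rbind(c(1, -0.5, 0, 1), c(1, -1, 1, 1))
  m2 <- rbind(c(1, 2, 1, 1), c(1, NA, 1, 1))
  m3 <- rbind(c(1, 4, 1, 1), c(1, NA, 1, 1))
  t <- tensor_from(list(m1, m2, m3))
  expect_warning(out <- correct_negatives(t), "no non-negative donors")
  expect_equal(out$values[1, 1, 2], 3)            # mean of donors {2, 4}
  expect_equal(out$values[1, 1, 3], 0)            # zero is not negative
  expect_equal(out$values[2, 1, 2], 0)            # all donors missing -> 0
  log <- attr(out, "negatives_replaced")
  expect_equal(nrow(log), 2)
  expect_true(log$fallback_zero[log$gene == "g2"])
})

test_that("log transform is log2(1+x) and rejects negatives", {
  t <- tensor_from(list(rbind(c(0, 1, 7, 0)), rbind(c(0, 0, 0, 0))))
  out <- log_transform(t)
  expect_equal(unname(out$values[1, 1, 1:3]), c(0, 1, 3))
  expect_identical(out$scale, "log1p")
  neg <- tensor_from(list(rbind(c(0, -1, 0, 0)), rbind(c(0, 0, 0, 0))))
  expect_error(log_transform(neg), "negative")
})

test_that("fold change subtracts each patient's baseline; missing baseline masks the gene", {
  m1 <- rbind(c(2, 3, 2, 4), c(NA, 1, 1, 1))
  t <- tensor_from(list(m1, m1 + 1), scale = "log1p")
  out <- to_log2fc(t)
  expect_equal(unname(out$values[1, 1, ]), c(0, 1, 0, 2))
  expect_equal(unname(out$values[1, 2, ]), c(0, 1, 0, 2))   # baseline shift cancels
  expect_false(any(out$mask[2, 1, ]))                # baseline was masked
  expect_equal(unique(attr(out, "missing_baseline")$gene), "g2")
  expect_identical(out$scale, "log2fc")
})

test_that("preprocessing stages are idempotent and order is enforced by scale tags", {
  set.seed(4)
  arr <- array(abs(rnorm(2 * 3 * 4)), c(2, 3, 4))
  arr[1, 1, 2] <- NA; arr[2, 2, 3] <- -0.2
  t <- expression_tensor(arr, grid = tiny_grid())
  i1 <- impute_missing(t)
  expect_equal(impute_missing(i1)$values, i1$values)
  c1 <- correct_negatives(i1)
  expect_equal(correct_negatives(c1)$values, c1$values)
  l1 <- log_transform(c1)
  expect_equal(log_transform(l1)$values, l1$values)
  fc <- to_log2fc(l1)
  expect_error(impute_missing(fc), "raw-scale")
  expect_error(log_transform(fc), "raw-scale")
  expect_error(to_log2fc(t), "log1p")
  expect_error(select_degs(l1), "log2fc")
  expect_equal(preprocess_tensor(t)$values, fc$values)
})

test_that("the toy differential-expression fixture is selected exactly as enumerated", {
  toy <- gen_deg_toy(seed = 3)
  rep <- select_degs(toy$tensor)
  expect_equal(rep$n_twofold, toy$expected$n_twofold)
  expect_equal(rep$n_presurgical_excluded, toy$expected$n_presurgical_excluded)
  expect_equal(rep$n_selected, toy$expected$n_selected)
  expect_setequal(rep$selected, toy$expected$selected)
  expect_equal(rep$n_selected,
               rep$n_twofold - sum(rep$flags$twofold & rep$flags$presurgical))
})

test_that("raising the fold-change threshold never adds genes", {
  toy <- gen_deg_toy(seed = 5)
  sel <- lapply(c(0.25, 0.5, 1, 1.5, 3),
                function(th) select_degs(toy$tensor, twofold_log2 = th)$selected)
  for (i in seq_len(length(sel) - 1))
    expect_true(all(sel[[i + 1]] %in% sel[[i]]))
  # loosened to 1-fold (threshold 0), every non-excluded gene passes
  expect_equal(select_degs(toy$tensor, twofold_log2 = 0)$n_selected, 4)
})

test_that("noise-free archetype genes are recovered exactly by the fold-change filter", {
  ar <- gen_archetypes(K = 3, n_genes = 30, sigma = 0, seed = 2)
  flat <- array(0, c(10, 3, length(ar$tensor$grid$hours)))
  vals <- array(NA_real_, c(40, 3, dim(flat)[3]))
  vals[1:30, , ] <- ar$tensor$values
  vals[31:40, , ] <- flat
  t <- expression_tensor(vals, scale = "log2fc",
                         gene_ids = c(ar$tensor$gene_ids, paste0("flat", 1:10)),
                         patient_ids = paste0("P", 1:3), grid = ar$tensor$grid)
  rep <- select_degs(t)
  expect_setequal(rep$selected, ar$tensor$gene_ids)
})
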