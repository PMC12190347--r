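test_that("correlation matches the textbook formula and handles degenerate genes", {
  # 3 genes over 4 flattened samples (1 patient), hand-checkable sums
  g1 <- c(0, 1, 2, 3); g2 <- c(0, 2, 4, 6); g3 <- c(0, 3, 1, 2)
  t <- tensor_from(list(rbind(g1, g2, g3)), scale = "log2fc")
  net <- correlation_matrix(t)
  expect_equal(net$cor[1, 2], 1)                       # identical shape
  r13 <- sum((g1 - mean(g1)) * (g3 - mean(g3))) /
    sqrt(sum((g1 - mean(g1))^2) * sum((g3 - mean(g3))^2))
  expect_equal(net$cor[1, 3], r13)
  # negated profile
  t2 <- tensor_from(list(rbind(g1, -g1)), scale = "log2fc")
  expect_equal(correlation_matrix(t2)$cor[1, 2], -1)
  # zero-variance gene dropped with a warning
  t3 <- tensor_from(list(rbind(g1, g3, rep(1, 4))), scale = "log2fc")
  expect_warning(net3 <- correlation_matrix(t3), "zero variance")
  expect_equal(length(net3$genes), 2)
})

test_that("soft-threshold choice agrees with an independent scale-free-fit oracle", {
  ar <- gen_archetypes(K = 3, n_genes = 60, sigma = 0.6, seed = 8)
  net <- correlation_matrix(ar$tensor)
  # independent oracle: same fit definition, separate code path
  oracle_fit <- function(b) {
    a <- abs(net$cor)^b; diag(a) <- 1
    k <- colSums(a) - 1
    k <- k[k > 0]
    br <- unique(quantile(k, seq(0, 1, length.out = 11)))
    bin <- cut(k, br, include.lowest = TRUE)
    fr <- tapply(k, bin, length) / length(k)
    km <- tapply(k, bin, mean)
    ok <- !is.na(fr) & fr > 0 & km > 0
    fit <- lm(log10(fr[ok]) ~ log10(km[ok]))
    if (coef(fit)[2] >= 0) 0 else summary(fit)$r.squared
  }
  fits <- vapply(1:20, oracle_fit, 0)
  expected <- if (any(fits >= 0.8)) which(fits >= 0.8)[1] else which.max(fits)
  got <- suppressWarnings(pick_soft_threshold(net))
  expect_equal(got$beta, as.integer(expected))
  expect_equal(got$adjacency, abs(net$cor)^got$beta,
               ignore_attr = TRUE, tolerance = 1e-12)
  # fewer than 30 genes: conventional default with a warning
  small <- correlation_matrix(gen_archetypes(K = 2, n_genes = 10, sigma = 0.1,
                                             seed = 1)$tensor)
  expect_warning(got2 <- pick_soft_threshold(small), "beta = 6")
  expect_equal(got2$beta, 6L)
})

test_that("adjacency is monotone non-increasing in beta, invariant at |cor| = 1", {
  set.seed(11)
  cc <- cor(matrix(rnorm(80), 10, 8))
  cc[1, 2] <- cc[2, 1] <- 1
  for (b in 1:5) {
    a_lo <- abs(cc)^b; a_hi <- abs(cc)^(b + 1)
    expect_true(all(a_hi <= a_lo + 1e-15))
    expect_equal(a_hi[1, 2], a_lo[1, 2])
  }
})

test_that("topological overlap matches hand-derived cases and the brute-force oracle", {
  mknet <- function(a) {
    diag(a) <- 1
    structure(list(genes = paste0("g", seq_len(nrow(a))), cor = a, beta = 1L,
                   adjacency = a, tom = NULL), class = "coexpression_network")
  }
  # 2 genes, a12 = 1 -> TOM = (0+1)/(1+1-1) = 1
  t2 <- tom_similarity(mknet(matrix(c(1, 1, 1, 1), 2)))
  expect_equal(t2$tom[1, 2], 1)
  # 3 genes all connected at 1 -> (1+1)/(2+1-1) = 1
  t3 <- tom_similarity(mknet(matrix(1, 3, 3)))
  expect_equal(t3$tom[1, 2], 1)
  # no connections -> off-diagonal 0
  t0 <- tom_similarity(mknet(diag(3)))
  expect_equal(t0$tom, diag(3))
  # random networks vs the independent triple-loop oracle
  set.seed(42)
  for (i in 1:10) {
    n <- sample(3:20, 1)
    a <- abs(cor(matrix(rnorm(n * (n + 5)), n + 5, n)))^2
    net <- tom_similarity(mknet(a))
    diag(a) <- 0
    expect_lt(max(abs(net$tom - tom_bruteforce(a))), 1e-12)
  }
})

test_that("module detection separates blocks and merges undersized groups", {
  ar <- gen_archetypes(K = 2, n_genes = 40, sigma = 0.02, seed = 3)
  net <- correlation_matrix(ar$tensor)
  net$beta <- 6L; net$adjacency <- abs(net$cor)^6; diag(net$adjacency) <- 1
  net <- tom_similarity(net)
  grp <- detect_modules(net, min_size = 5)
  expect_equal(length(unique(grp)), 2)
  expect_equal(cluster_purity(grp, ar$labels), 1)
  # min_size larger than every block forces a single merged group
  expect_warning(one <- detect_modules(net, min_size = 39), "one group")
  expect_equal(length(unique(one)), 1)
})

test_that("cluster profiles aggregate means/sds under the mask and commute with relabeling", {
  vals <- array(NA_real_, c(3, 2, 4))
  vals[1, , ] <- rbind(c(0, 1, 2, 1), c(0, 2, 2, 0))
  vals[2, , ] <- rbind(c(0, 3, 2, 1), c(0, 4, 2, 0))
  vals[3, , ] <- rbind(c(0, 9, 9, 9), c(0, 1, 1, 1))
  mask <- array(TRUE, dim(vals)); mask[3, 1, ] <- FALSE
  t <- expression_tensor(vals, mask, "log2fc", grid = tiny_grid())
  assign <- c(g1 = 1L, g2 = 1L, g3 = 2L)
  tr <- cluster_profiles(t, assign)
  expect_equal(tr$values[1, 1, 2], 2)                 # mean of {1, 3}
  expect_equal(tr$spread[1, 1, 2], sqrt(2))           # sample sd of two points
  expect_equal(tr$spread[2, 2, 2], 0)                 # singleton cluster
  expect_false(tr$mask[2, 1, 2])                      # all members masked
  expect_equal(tr$values[2, 2, 2], 1)                 # singleton mean = value
  # permutation invariance
  perm <- c(3, 1, 2)
  tp <- expression_tensor(vals[perm, , ], mask[perm, , ], "log2fc",
                          gene_ids = names(assign)[perm], grid = tiny_grid())
  tr2 <- cluster_profiles(tp, assign)
  expect_equal(tr2$values, tr$values)
  expect_equal(tr2$spread, tr$spread)
})

test_that("clusters are tagged by peak timing into the three regeneration phases", {
  grid <- default_time_grid()
  mk <- function(profiles) {
    K <- nrow(profiles)
    vals <- array(NA_real_, c(K, 1, length(grid$hours)))
    vals[, 1, ] <- profiles
    structure(list(values = vals, spread = vals * 0,
                   mask = array(TRUE, dim(vals)), clusters = seq_len(K),
                   patient_ids = "P1", grid = grid),
              class = "cluster_trajectory")
  }
  h <- grid$hours
  early <- exp(-(h - 2)^2 / 8)                       # peak at 2 h
  prolif <- exp(-(log(pmax(h, 0.01) / 96))^2)        # peak at 96 h
  late <- pmin(h / 4380, 1)                          # rises to the end
  flat <- h * 0
  tags <- tag_modules(mk(rbind(early, prolif, late, flat)))
  expect_equal(tags$module, c("early", "proliferation", "long_term", "early"))
  expect_true(tags$ambiguous[4])
  expect_false(any(tags$ambiguous[1:3]))
})
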