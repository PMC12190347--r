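# Self-organizing map refinement of co-expression groups.
#
# The SOM is trained on per-gene mean temporal profiles. Codebook vectors sit
# on a small 2-d grid (5 x 3 for K = 15) and are pulled toward presented
# profiles with a Gaussian neighbourhood whose radius and learning rate decay
# linearly over the epochs. Initialization comes from the network groups'
# centroid profiles so the network analysis informs the map, but the final
# gene labels are the SOM's best-matching units.

# near-square grid dims for K units (prefers 5x3 for 15)
som_grid_dims <- function(K) {
  best <- c(K, 1L)
  for (a in seq_len(floor(sqrt(K)))) if (K %% a == 0) best <- c(K %/% a, a)
  best
}

# mean-across-patients trajectory per gene, NA-free (masked cells dropped)
gene_mean_profiles <- function(t) {
  d <- dim(t$values)
  out <- matrix(0, d[1], d[3], dimnames = list(t$gene_ids, t$grid$labels))
  for (g in seq_len(d[1])) for (tt in seq_len(d[3])) {
    obs <- t$mask[g, , tt]
    out[g, tt] <- if (any(obs)) mean(t$values[g, obs, tt]) else 0
  }
  out
}

train_som <- function(X, K, init, epochs = 100, lr0 = 0.5, lr1 = 0.01) {
  dims <- som_grid_dims(K)
  coords <- as.matrix(expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2])))
  r0 <- max(dims) / 2; r1 <- 0.5
  W <- init
  n <- nrow(X)
  steps <- epochs * n; s <- 0
  for (e in seq_len(epochs)) {
    ord <- sample.int(n)
    for (i in ord) {
      frac <- s / steps
      lr <- lr0 + (lr1 - lr0) * frac
      r <- r0 + (r1 - r0) * frac
      x <- X[i, ]
      d2 <- rowSums((W - matrix(x, K, ncol(X), byrow = TRUE))^2)
      bmu <- which.min(d2)
      g2 <- rowSums((coords - matrix(coords[bmu, ], K, 2, byrow = TRUE))^2)
      h <- exp(-g2 / (2 * r^2))
      W <- W + lr * h * (matrix(x, K, ncol(X), byrow = TRUE) - W)
      s <- s + 1
    }
  }
  W
}

#' Refine network groups into K temporal clusters with a self-organizing map
#'
#' Trains a K-unit SOM on the genes' mean-across-patients fold-change
#' trajectories. The codebook is seeded from the centroids of the supplied
#' network groups (cycled, then padded with randomly drawn gene profiles when
#' there are fewer groups than units), so the co-expression structure guides
#' the map while the SOM decides the final assignment. Empty units are
#' dropped and the surviving count reported.
#'
#' @param t a log2fc-scale [expression_tensor()].
#' @param groups named integer vector gene -> preliminary group (from
#'   [detect_modules()]); `NULL` for purely random initialization.
#' @param K number of map units (default 15, laid out 5 x 3).
#' @param seed RNG seed; SOM outcomes depend on presentation order, so the
#'   seed is a mandatory input.
#' @param epochs training epochs (default 100).
#' @return A `cluster_assignment`: `labels` (named gene -> cluster in 1..K'),
#'   `K` (surviving cluster count), `codebook`, and `module_map` (filled by
#'   [tag_modules()] downstream, `NULL` here).
#' @export
som_refine <- function(t, groups = NULL, K = 15, seed = 1, epochs = 100) {
  if (K < 2) stop("K must be at least 2")
  X <- gene_mean_profiles(t)
  if (K > nrow(X)) stop("K exceeds the number of genes")
  with_seed(seed, {
    init <- matrix(0, K, ncol(X))
    if (!is.null(groups)) {
      groups <- groups[rownames(X)]
      cents <- do.call(rbind, lapply(sort(unique(groups)), function(g)
        colMeans(X[groups == g, , drop = FALSE])))
      for (k in seq_len(K)) init[k, ] <- cents[((k - 1) %% nrow(cents)) + 1, ]
      extra <- which(seq_len(K) > nrow(cents))
      if (length(extra)) {
        pad <- X[sample.int(nrow(X), length(extra), replace = TRUE), , drop = FALSE]
        init[extra, ] <- init[extra, ] * 0.5 + pad * 0.5
      }
      # tiny jitter so duplicated centroids separate
      init <- init + matrix(stats::rnorm(length(init), 0, 1e-4), K)
    } else {
      init <- X[sample.int(nrow(X), K, replace = FALSE), , drop = FALSE]
    }
    W <- train_som(X, K, init, epochs = epochs)
    bmu <- apply(X, 1, function(x)
      which.min(colSums((t(W) - x)^2)))
    keep <- sort(unique(bmu))
    labels <- match(bmu, keep)
    names(labels) <- rownames(X)
    structure(list(labels = labels, K = length(keep),
                   codebook = W[keep, , drop = FALSE], module_map = NULL,
                   seed = seed),
              class = "cluster_assignment")
  })
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d genes in %d clusters (seed %d)\n",
              length(x$labels), x$K, x$seed))
  invisible(x)
}
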