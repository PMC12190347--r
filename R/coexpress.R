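#' Gene-gene correlation over flattened longitudinal samples
#'
#' Computes the Pearson correlation between every pair of genes over the
#' flattened (patient, time) samples, using pairwise-complete observations
#' under the mask. Genes with zero variance or fewer than 3 observed samples
#' have no defined correlation and are dropped with a warning.
#'
#' @param t a log2fc-scale [expression_tensor()].
#' @return A `coexpression_network` list with fields `genes`, `cor`
#'   (values clipped to `[-1, 1]`); `beta`, `adjacency`, `tom` are filled by
#'   [pick_soft_threshold()] and [tom_similarity()].
#' @export
correlation_matrix <- function(t) {
  if (t$scale != "log2fc") stop("correlation_matrix expects a log2fc tensor")
  d <- dim(t$values)
  flat <- matrix(t$values, nrow = d[1])          # genes x (patient*time)
  flat[!matrix(t$mask, nrow = d[1])] <- NA_real_
  nobs <- rowSums(!is.na(flat))
  v <- apply(flat, 1, stats::var, na.rm = TRUE)
  keep <- nobs >= 3 & !is.na(v) & v > 0
  if (!all(keep))
    warning(sprintf("dropping %d gene(s) with zero variance or <3 observations",
                    sum(!keep)), call. = FALSE)
  if (sum(keep) < 2) stop("fewer than 2 usable genes")
  flat <- flat[keep, , drop = FALSE]
  cc <- suppressWarnings(stats::cor(t(flat), use = "pairwise.complete.obs"))
  cc[is.na(cc)] <- 0
  cc <- pmin(pmax(cc, -1), 1)
  diag(cc) <- 1
  structure(list(genes = t$gene_ids[keep], cor = cc, beta = NULL,
                 adjacency = NULL, tom = NULL),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("<coexpression_network> %d genes; beta = %s; TOM %s\n",
              length(x$genes), x$beta %||% "unset",
              if (is.null(x$tom)) "unset" else "computed"))
  invisible(x)
}

# scale-free topology fit index for one adjacency: R^2 of the regression of
# log10 bin frequency on log10 mean connectivity, required negative slope
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(k) < n_bins) return(0)
  br <- unique(stats::quantile(k, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(br) < 4) return(0)
  bin <- cut(k, br, include.lowest = TRUE)
  freq <- tapply(k, bin, length) / length(k)
  kb <- tapply(k, bin, mean)
  ok <- !is.na(freq) & freq > 0 & kb > 0
  if (sum(ok) < 3) return(0)
  fit <- stats::lm(log10(freq[ok]) ~ log10(kb[ok]))
  r2 <- summary(fit)$r.squared
  if (stats::coef(fit)[2] >= 0) 0 else r2
}

#' Choose the soft-threshold power for a scale-free network
#'
#' For each candidate power, raises |cor| to that power and measures how
#' well the resulting connectivity distribution fits a scale-free topology
#' (R-squared of log frequency vs log connectivity over >= 10 bins, negative
#' slope required). Returns the smallest power reaching `rsq_cut`; if none
#' does, the power maximizing the fit, with a warning. With fewer than 30
#' genes the binning is unreliable and the conventional default 6 is used.
#'
#' @param net a [correlation_matrix()] result.
#' @param candidates candidate integer powers (default 1:20).
#' @param rsq_cut fit threshold (default 0.8).
#' @return The network with `beta` and `adjacency = |cor|^beta` filled, plus
#'   attribute `sft` (data.frame power/fit).
#' @export
pick_soft_threshold <- function(net, candidates = 1:20, rsq_cut = 0.8) {
  ng <- length(net$genes)
  if (ng < 30) {
    warning("fewer than 30 genes: scale-free binning unreliable, using beta = 6",
            call. = FALSE)
    net$beta <- 6L
    net$adjacency <- abs(net$cor)^6
    diag(net$adjacency) <- 1
    return(net)
  }
  fits <- vapply(candidates, function(b) {
    a <- abs(net$cor)^b
    k <- colSums(a) - 1
    scale_free_fit(k)
  }, 0)
  pass <- which(fits >= rsq_cut)
  if (length(pass)) {
    net$beta <- as.integer(candidates[pass[1]])
  } else {
    net$beta <- as.integer(candidates[which.max(fits)])
    warning(sprintf("no power reaches R^2 >= %.2f; using argmax power %d (R^2 = %.3f)",
                    rsq_cut, net$beta, max(fits)), call. = FALSE)
  }
  net$adjacency <- abs(net$cor)^net$beta
  diag(net$adjacency) <- 1
  attr(net, "sft") <- data.frame(power = candidates, fit = fits)
  net
}

#' Topological overlap similarity
#'
#' For an unsigned adjacency a, the topological overlap between genes i and j
#' is `(l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` where
#' `l_ij = sum_{u != i,j} a_iu a_uj` counts shared neighbours and
#' `k_i = sum_{u != i} a_iu` is the connectivity. Two genes overlap strongly
#' when they are connected and share the same neighbourhood. The diagonal is
#' set to 1.
#'
#' @param net a network with `adjacency` filled (see [pick_soft_threshold()]).
#' @return The network with `tom` filled (values in `[0, 1]`).
#' @export
tom_similarity <- function(net) {
  a <- net$adjacency
  if (is.null(a)) stop("adjacency not computed; run pick_soft_threshold() first")
  diag(a) <- 0
  k <- colSums(a)
  l <- a %*% a                     # l_ij = sum_u a_iu a_uj (u != i,j since diag 0)
  kmin <- outer(k, k, pmin)
  tom <- (l + a) / (kmin + 1 - a)
  diag(tom) <- 1
  net$tom <- pmin(pmax(tom, 0), 1)
  net
}

#' Detect preliminary gene groups from topological overlap
#'
#' Average-linkage hierarchical clustering on the dissimilarity `1 - TOM`,
#' cut at a fixed height (default: the `cut_quantile` quantile of the merge
#' heights). Groups smaller than `min_size` are merged into the group with
#' the highest mean inter-group TOM.
#'
#' @param net a network with `tom` filled.
#' @param min_size smallest allowed group (default 30).
#' @param cut_quantile quantile of merge heights at which to cut
#'   (default 0.99).
#' @return Integer vector of group labels (1..G), named by gene.
#' @export
detect_modules <- function(net, min_size = 30, cut_quantile = 0.99) {
  if (is.null(net$tom)) stop("TOM not computed; run tom_similarity() first")
  diss <- 1 - net$tom
  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  h <- stats::quantile(hc$height, cut_quantile)
  grp <- stats::cutree(hc, h = h)
  # merge undersized groups into their nearest group by mean inter-group TOM
  repeat {
    sizes <- table(grp)
    if (length(sizes) == 1) break
    small <- names(sizes)[sizes < min_size]
    if (!length(small)) break
    s <- small[which.min(sizes[small])]
    members <- grp == as.integer(s)
    others <- setdiff(names(sizes), s)
    sim <- vapply(others, function(o)
      mean(net$tom[members, grp == as.integer(o), drop = FALSE]), 0)
    grp[members] <- as.integer(others[which.max(sim)])
  }
  if (length(unique(grp)) == 1)
    warning("all genes in one group", call. = FALSE)
  grp <- as.integer(factor(grp))   # relabel 1..G
  names(grp) <- net$genes
  grp
}

#' Summarize clusters as per-patient mean trajectories
#'
#' For every (cluster, patient, time): the mean and sample standard deviation
#' of the member genes' log2 fold changes over observed cells; cells with no
#' observed member are masked. Singleton clusters get sd 0.
#'
#' @param t a log2fc-scale [expression_tensor()].
#' @param assign a `cluster_assignment` (see [som_refine()]) or a named
#'   integer vector gene -> cluster.
#' @return A `cluster_trajectory` list: `values` and `spread`
#'   (cluster x patient x time arrays), `mask`, `clusters`, `patient_ids`,
#'   `grid`.
#' @export
cluster_profiles <- function(t, assign) {
  labels <- if (inherits(assign, "cluster_assignment")) assign$labels else assign
  if (!all(t$gene_ids %in% names(labels)))
    stop("assignment must cover every gene in the tensor")
  labels <- labels[t$gene_ids]
  cl <- sort(unique(labels))
  d <- dim(t$values)
  vals <- array(NA_real_, c(length(cl), d[2], d[3]))
  spread <- array(NA_real_, c(length(cl), d[2], d[3]))
  msk <- array(FALSE, c(length(cl), d[2], d[3]))
  for (ci in seq_along(cl)) {
    rows <- which(labels == cl[ci])
    for (p in seq_len(d[2])) for (tt in seq_len(d[3])) {
      obs <- t$mask[rows, p, tt]
      if (!any(obs)) next
      x <- t$values[rows, p, tt][obs]
      vals[ci, p, tt] <- mean(x)
      spread[ci, p, tt] <- if (length(x) > 1) stats::sd(x) else 0
      msk[ci, p, tt] <- TRUE
    }
  }
  dimnames(vals) <- dimnames(spread) <- dimnames(msk) <-
    list(paste0("C", cl), t$patient_ids, t$grid$labels)
  structure(list(values = vals, spread = spread, mask = msk,
                 clusters = cl, patient_ids = t$patient_ids, grid = t$grid),
            class = "cluster_trajectory")
}

#' @export
print.cluster_trajectory <- function(x, ...) {
  cat(sprintf("<cluster_trajectory> %d clusters x %d patients x %d time points\n",
              dim(x$values)[1], dim(x$values)[2], dim(x$values)[3]))
  invisible(x)
}

#' Tag clusters with their temporal module
#'
#' Clusters are grouped into the three canonical regeneration phases by the
#' timing of the peak |mean log2FC| of the cross-patient average trajectory:
#' within 24 h -> `early` (inflammation, ECM degradation); 24--240 h ->
#' `proliferation` (the replicative burst); later -> `long_term` (tissue
#' remodeling), with sustained elevation over the last three grid points as
#' an alternative route to `long_term`. Flat clusters default to `early`
#' and are flagged ambiguous.
#'
#' @param traj a [cluster_profiles()] result.
#' @param sustained_frac a cluster is "sustained" when the mean |log2FC| over
#'   the last three points exceeds this fraction of its peak (default 0.5).
#' @return A data.frame: cluster, module tag, peak hour, ambiguous flag.
#' @export
tag_modules <- function(traj, sustained_frac = 0.5) {
  hours <- traj$grid$hours
  K <- dim(traj$values)[1]
  out <- data.frame(cluster = traj$clusters,
                    module = character(K), peak_hour = NA_real_,
                    ambiguous = FALSE)
  last3 <- tail(seq_along(hours), 3)
  for (ci in seq_len(K)) {
    prof <- vapply(seq_along(hours), function(tt) {
      obs <- traj$mask[ci, , tt]
      if (!any(obs)) NA_real_ else mean(traj$values[ci, obs, tt])
    }, 0)
    a <- abs(prof)
    if (all(is.na(a)) || max(a, na.rm = TRUE) < 1e-12) {
      out$module[ci] <- "early"; out$ambiguous[ci] <- TRUE
      next
    }
    pk <- which.max(a)
    out$peak_hour[ci] <- hours[pk]
    sustained <- mean(a[last3], na.rm = TRUE) >= sustained_frac * max(a, na.rm = TRUE)
    out$module[ci] <-
      if (hours[pk] <= 24) "early"
      else if (hours[pk] <= 240) "proliferation"
      else "long_term"
    if (hours[pk] > 240 && hours[pk] <= 2190 && !sustained)
      out$ambiguous[ci] <- TRUE
  }
  out
}
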