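#' Impute missing cells from other patients at the same time point
#'
#' A missing (gene, patient, time) cell is filled with the arithmetic mean of
#' the other patients' observed values at the same gene and time. Cells for
#' which no other patient was observed stay masked and are listed in the
#' `unimputable` attribute. Imputation never uses other time points, so no
#' temporal signal leaks across the grid.
#'
#' @param t a raw-scale [expression_tensor()].
#' @return The tensor with imputed cells unmasked; attributes `imputed`
#'   (logical array marking filled cells) and `unimputable` (data.frame of
#'   gene/time pairs observed in zero patients).
#' @export
impute_missing <- function(t) {
  if (t$scale != "raw") stop("impute_missing expects a raw-scale tensor")
  v <- t$values; m <- t$mask
  imputed <- array(FALSE, dim(m))
  bad <- list()
  for (g in seq_len(dim(v)[1])) for (tt in seq_len(dim(v)[3])) {
    obs <- m[g, , tt]
    if (all(obs)) next
    if (!any(obs)) {
      if (any(!obs)) bad[[length(bad) + 1L]] <- c(g, tt)
      next
    }
    fill <- mean(v[g, obs, tt])
    v[g, !obs, tt] <- fill
    imputed[g, !obs, tt] <- TRUE
    m[g, !obs, tt] <- TRUE
  }
  out <- expression_tensor(v, m, "raw", t$gene_ids, t$patient_ids, t$grid)
  attr(out, "imputed") <- imputed
  attr(out, "unimputable") <- if (length(bad))
    data.frame(gene = t$gene_ids[vapply(bad, `[`, 0, 1)],
               timepoint = t$grid$labels[vapply(bad, `[`, 0, 2)])
  else data.frame(gene = character(), timepoint = character())
  out
}

#' Replace negative expression values by cross-patient means
#'
#' Negative values arise as noise artifacts in low-expressed genes and are
#' biologically unrealistic. Each strictly negative observed cell is replaced
#' by the mean of the other patients' non-negative observed values at the
#' same gene and time; when no such value exists, the cell is set to 0 and
#' reported. Zero is not negative and is left untouched.
#'
#' @param t a raw-scale [expression_tensor()].
#' @return The corrected tensor; attribute `negatives_replaced` is a
#'   data.frame logging every replacement (with `fallback_zero` flag).
#' @export
correct_negatives <- function(t) {
  if (t$scale != "raw") stop("correct_negatives expects a raw-scale tensor")
  v <- t$values; m <- t$mask
  log <- list()
  for (g in seq_len(dim(v)[1])) for (tt in seq_len(dim(v)[3])) {
    col <- v[g, , tt]; obs <- m[g, , tt]
    neg <- which(obs & col < 0)
    if (!length(neg)) next
    for (p in neg) {
      donors <- which(obs & col >= 0)
      donors <- setdiff(donors, p)
      if (length(donors)) {
        v[g, p, tt] <- mean(col[donors])
        log[[length(log) + 1L]] <- data.frame(
          gene = t$gene_ids[g], patient = t$patient_ids[p],
          timepoint = t$grid$labels[tt], old = col[p],
          new = v[g, p, tt], fallback_zero = FALSE)
      } else {
        v[g, p, tt] <- 0
        log[[length(log) + 1L]] <- data.frame(
          gene = t$gene_ids[g], patient = t$patient_ids[p],
          timepoint = t$grid$labels[tt], old = col[p],
          new = 0, fallback_zero = TRUE)
        warning(sprintf("no non-negative donors for %s/%s/%s; set to 0",
                        t$gene_ids[g], t$patient_ids[p], t$grid$labels[tt]),
                call. = FALSE)
      }
    }
  }
  out <- expression_tensor(v, m, "raw", t$gene_ids, t$patient_ids, t$grid)
  attr(out, "negatives_replaced") <- if (length(log)) do.call(rbind, log)
  else data.frame()
  out
}

#' Variance-stabilizing log transform
#'
#' Applies `log2(1 + x)` to every observed cell and advances the scale tag to
#' `log1p`. Negative inputs are an error: [correct_negatives()] must run
#' first.
#'
#' @param t a raw-scale, non-negative [expression_tensor()].
#' @return The transformed tensor.
#' @export
log_transform <- function(t) {
  if (t$scale == "log1p") return(t)  # idempotent by tag
  if (t$scale != "raw") stop("log_transform expects a raw-scale tensor")
  if (any(t$values[t$mask] < 0, na.rm = TRUE))
    stop("negative values present; run correct_negatives() first")
  v <- t$values
  v[t$mask] <- log2(1 + v[t$mask])
  expression_tensor(v, t$mask, "log1p", t$gene_ids, t$patient_ids, t$grid)
}

#' Convert to log2 fold change relative to the preoperative baseline
#'
#' Subtracts each patient's own baseline (first grid point) from every time
#' point on the log1p scale, so the baseline column becomes exactly 0.
#' Gene/patient pairs whose baseline is still masked after imputation are
#' masked across all time points and flagged: the baseline is never
#' back-filled from post-operative values.
#'
#' @param t a log1p-scale [expression_tensor()].
#' @param grid optional [time_grid()] override (defaults to `t$grid`).
#' @return A log2fc-scale tensor; attribute `missing_baseline` lists flagged
#'   gene/patient pairs.
#' @export
to_log2fc <- function(t, grid = t$grid) {
  if (t$scale != "log1p") stop("to_log2fc expects a log1p-scale tensor")
  b <- baseline_idx(grid)
  v <- t$values; m <- t$mask
  flagged <- list()
  for (p in seq_len(dim(v)[2])) {
    base <- v[, p, b]; base_ok <- m[, p, b]
    v[, p, ] <- v[, p, ] - base
    v[, p, b] <- 0
    if (any(!base_ok)) {
      m[!base_ok, p, ] <- FALSE
      flagged[[length(flagged) + 1L]] <- data.frame(
        gene = t$gene_ids[!base_ok], patient = t$patient_ids[p])
    }
  }
  v[!m] <- NA_real_
  out <- expression_tensor(v, m, "log2fc", t$gene_ids, t$patient_ids, grid)
  attr(out, "missing_baseline") <- if (length(flagged)) do.call(rbind, flagged)
  else data.frame(gene = character(), patient = character())
  out
}

#' Select regeneration-specific differentially expressed genes
#'
#' Two rules on the cross-patient mean log2 fold-change profile:
#' a gene is *differential* iff its |log2FC| is at least `twofold_log2`
#' (default 1, i.e. two-fold) at each of `min_consecutive` (default 2)
#' consecutive post-resection time points; it is excluded as a nonspecific
#' surgical response iff its |log2FC| reaches `log2(prefold)` (default
#' 1.5-fold) at any pre-resection sample other than the baseline itself
#' (incision effects show up there before the liver is touched). The
#' selection is the set difference.
#'
#' @param t a log2fc-scale [expression_tensor()].
#' @param grid optional [time_grid()] override.
#' @param twofold_log2 differential threshold in log2 units (default 1).
#' @param prefold pre-resection exclusion threshold as a fold change
#'   (default 1.5).
#' @param min_consecutive required run length of consecutive post-op points
#'   (default 2).
#' @param per_patient if `TRUE`, the two-fold rule is applied to each
#'   patient's own profile (a gene passes if any patient passes) instead of
#'   the cross-patient mean. Default `FALSE`.
#' @return A `deg_report` list: gene counts (`n_input`, `n_twofold`,
#'   `n_presurgical_excluded`, `n_selected`), the `selected` gene ids, and a
#'   per-gene data.frame `flags` with the max consecutive-pair fold change
#'   and the max pre-resection fold change.
#' @export
select_degs <- function(t, grid = t$grid, twofold_log2 = 1, prefold = 1.5,
                        min_consecutive = 2, per_patient = FALSE) {
  if (t$scale != "log2fc") stop("select_degs expects a log2fc-scale tensor")
  post <- post_op_idx(grid)
  if (length(post) < 2) stop("grid must contain at least 2 post-resection points")
  pre_extra <- which(grid$pre_resection)[-1]  # pre-resection beyond baseline

  run_pass <- function(prof) {
    hit <- !is.na(prof) & abs(prof) >= twofold_log2
    r <- rle(hit)
    any(r$values & r$lengths >= min_consecutive)
  }
  mean_profile <- function(g) {
    vapply(post, function(tt) {
      obs <- t$mask[g, , tt]
      if (!any(obs)) NA_real_ else mean(t$values[g, obs, tt])
    }, 0)
  }

  ng <- n_genes(t)
  twofold <- logical(ng); max_consec <- numeric(ng)
  for (g in seq_len(ng)) {
    if (per_patient) {
      pass <- FALSE
      for (p in seq_len(n_patients(t))) {
        prof <- ifelse(t$mask[g, p, post], t$values[g, p, post], NA_real_)
        if (run_pass(prof)) { pass <- TRUE; break }
      }
      twofold[g] <- pass
      max_consec[g] <- NA_real_
    } else {
      prof <- mean_profile(g)
      twofold[g] <- run_pass(prof)
      # largest min-|fc| over consecutive pairs, as a diagnostic
      pairs <- vapply(seq_len(length(prof) - 1), function(i)
        min(abs(prof[i]), abs(prof[i + 1])), 0)
      max_consec[g] <- if (all(is.na(pairs))) NA_real_ else max(pairs, na.rm = TRUE)
    }
  }

  pre_fc <- numeric(ng)
  if (length(pre_extra)) {
    for (g in seq_len(ng)) {
      vals <- abs(t$values[g, , pre_extra, drop = FALSE])
      vals <- vals[t$mask[g, , pre_extra, drop = FALSE]]
      pre_fc[g] <- if (length(vals)) max(vals) else 0
    }
  }
  presurg <- pre_fc >= log2(prefold)

  selected <- twofold & !presurg
  structure(list(
    n_input = ng,
    n_twofold = sum(twofold),
    n_presurgical_excluded = sum(presurg),
    n_selected = sum(selected),
    selected = t$gene_ids[selected],
    flags = data.frame(gene = t$gene_ids, twofold = twofold,
                       presurgical = presurg,
                       max_consecutive_log2fc = max_consec,
                       max_preresection_log2fc = pre_fc)),
    class = "deg_report")
}

#' @export
print.deg_report <- function(x, ...) {
  cat(sprintf("<deg_report> %d genes in; %d two-fold; %d pre-resection excluded; %d selected\n",
              x$n_input, x$n_twofold, x$n_presurgical_excluded, x$n_selected))
  invisible(x)
}

#' Run the full preprocessing pipeline
#'
#' Convenience wrapper: impute -> correct negatives -> log2(1+x) -> log2
#' fold change. The scale tags enforce that this is the only legal order.
#'
#' @param t a raw-scale [expression_tensor()].
#' @return A log2fc-scale tensor.
#' @export
preprocess_tensor <- function(t) {
  to_log2fc(log_transform(correct_negatives(impute_missing(t))))
}
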