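#' Longitudinal expression tensor
#'
#' The package's central container: a gene x patient x time array with an
#' observation mask and a scale tag tracking the preprocessing stage. Scale
#' transitions are one-way: `raw` -> `log1p` (after `log2(1+x)`) -> `log2fc`
#' (after baseline subtraction); every operation checks the tag so steps
#' cannot run out of order.
#'
#' @param values numeric 3-d array, genes x patients x time points.
#' @param mask logical array of the same shape, `TRUE` where observed. A cell
#'   masked `FALSE` is ignored by every downstream computation.
#' @param scale one of `"raw"`, `"log1p"`, `"log2fc"`.
#' @param gene_ids,patient_ids identifier vectors matching the first two
#'   dimensions.
#' @param grid the [time_grid()] matching the third dimension.
#' @return An object of class `expression_tensor`.
#' @export
expression_tensor <- function(values, mask = NULL, scale = "raw",
                              gene_ids = NULL, patient_ids = NULL, grid) {
  if (length(dim(values)) != 3) stop("values must be a 3-d array")
  d <- dim(values)
  if (d[3] != length(grid$hours))
    stop("third dimension must match the time grid")
  if (is.null(mask)) mask <- !is.na(values)
  if (!identical(dim(mask), d)) stop("mask shape must match values")
  scale <- match.arg(scale, c("raw", "log1p", "log2fc"))
  if (scale == "log1p" && any(values[mask] < 0, na.rm = TRUE))
    stop("log1p-scale tensor cannot hold negative values")
  gene_ids <- gene_ids %||% paste0("g", seq_len(d[1]))
  patient_ids <- patient_ids %||% paste0("P", seq_len(d[2]))
  dimnames(values) <- dimnames(mask) <-
    list(gene_ids, patient_ids, grid$labels)
  structure(list(values = values, mask = mask, scale = scale,
                 gene_ids = as.character(gene_ids),
                 patient_ids = as.character(patient_ids), grid = grid),
            class = "expression_tensor")
}

#' @export
print.expression_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<expression_tensor> %d genes x %d patients x %d time points [%s], %.1f%% observed\n",
              d[1], d[2], d[3], x$scale, 100 * mean(x$mask)))
  invisible(x)
}

n_genes <- function(t) dim(t$values)[1]
n_patients <- function(t) dim(t$values)[2]
n_times <- function(t) dim(t$values)[3]

#' Read a longitudinal expression matrix and samples sheet
#'
#' Reads a genes-by-samples matrix (TSV/CSV, genes as rows, first column gene
#' ids) together with a samples sheet mapping each matrix column to a patient
#' and a time-point label, and assembles the [expression_tensor()].
#'
#' @param matrix_file path to the expression matrix (TSV; `sep` overridable).
#' @param samples_file path to the samples sheet with columns `sample`
#'   (matrix column name), `patient`, `timepoint` (a label of `grid`).
#' @param grid the [time_grid()] the `timepoint` labels refer to.
#' @param sep field separator, default tab.
#' @return An `expression_tensor` on the raw scale; matrix cells that are
#'   `NA`, or (patient, time) combinations absent from the sheet, are masked.
#' @export
read_expression_matrix <- function(matrix_file, samples_file, grid, sep = "\t") {
  mat <- utils::read.table(matrix_file, header = TRUE, sep = sep,
                           row.names = 1, check.names = FALSE)
  sheet <- utils::read.table(samples_file, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE)
  need <- c("sample", "patient", "timepoint")
  if (!all(need %in% names(sheet)))
    stop("samples sheet needs columns: ", paste(need, collapse = ", "))
  if (!all(sheet$timepoint %in% grid$labels))
    stop("samples sheet contains time points absent from the grid")
  patients <- unique(sheet$patient)
  vals <- array(NA_real_, c(nrow(mat), length(patients), length(grid$labels)))
  for (i in seq_len(nrow(sheet))) {
    cn <- sheet$sample[i]
    if (!cn %in% colnames(mat)) stop("sample column not in matrix: ", cn)
    p <- match(sheet$patient[i], patients)
    tt <- match(sheet$timepoint[i], grid$labels)
    vals[, p, tt] <- mat[[cn]]
  }
  expression_tensor(vals, gene_ids = rownames(mat), patient_ids = patients,
                    grid = grid)
}

#' Write an expression tensor as a long-format TSV
#'
#' One row per cell: gene, patient, timepoint, hours, value, observed flag.
#' Masked cells are written with an empty value. The inverse of
#' [read_expression_long()].
#'
#' @param t an [expression_tensor()].
#' @param path output path.
#' @export
write_expression_long <- function(t, path) {
  d <- dim(t$values)
  df <- data.frame(
    gene = rep(t$gene_ids, times = d[2] * d[3]),
    patient = rep(rep(t$patient_ids, each = d[1]), times = d[3]),
    timepoint = rep(t$grid$labels, each = d[1] * d[2]),
    hours = rep(t$grid$hours, each = d[1] * d[2]),
    value = ifelse(as.vector(t$mask), as.vector(t$values), NA_real_),
    observed = as.vector(t$mask))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a long-format tensor TSV written by [write_expression_long()]
#'
#' @param path input path.
#' @param grid the [time_grid()]; labels must cover the file's time points.
#' @param scale scale tag to stamp on the result.
#' @return An [expression_tensor()].
#' @export
read_expression_long <- function(path, grid, scale = "raw") {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  genes <- unique(df$gene); patients <- unique(df$patient)
  vals <- array(NA_real_, c(length(genes), length(patients), length(grid$labels)))
  idx <- cbind(match(df$gene, genes), match(df$patient, patients),
               match(df$timepoint, grid$labels))
  vals[idx] <- df$value
  msk <- array(FALSE, dim(vals)); msk[idx] <- df$observed & !is.na(df$value)
  vals[!msk] <- NA_real_
  expression_tensor(vals, msk, scale, genes, patients, grid)
}
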