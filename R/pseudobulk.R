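#' Aggregate single cells into pseudo-bulk profiles
#'
#' Sums raw UMIs over all cells of each (sample, cell type) pair to form
#' one pseudo-bulk column per pair. Pairs contributed by fewer than
#' `min_cells` cells are dropped (strictly fewer: exactly `min_cells`
#' cells are kept) and recorded in the `dropped` attribute, so for `n`
#' samples and `m` types the matrix has at most `n * m` columns.
#'
#' @param counts Raw sparse genes x cells UMI matrix.
#' @param annot Data frame with `cell_id`, `sample_id`, `group`,
#'   `cell_type`; must cover every column of `counts`.
#' @param min_cells Minimum cells per pseudo-bulk (default 10).
#' @return Object of class `pseudobulk`: list with `counts` (genes x
#'   pseudo-bulks dense integer matrix), `coldata` (data frame:
#'   sample_id, cell_type, group, n_cells), and attribute `dropped`.
#' @export
aggregate_pseudobulk <- function(counts, annot, min_cells = 10) {
  idx <- match(colnames(counts), annot$cell_id)
  if (anyNA(idx)) stop("annotation does not cover all cells")
  key <- paste(annot$sample_id[idx], annot$cell_type[idx], sep = "\r")
  keys <- sort(unique(key))
  M <- Matrix::sparseMatrix(i = seq_along(key), j = match(key, keys), x = 1,
                            dims = c(length(key), length(keys)))
  B <- as.matrix(counts %*% M)
  n_cells <- as.integer(table(factor(key, keys)))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  coldata <- data.frame(
    sample_id = vapply(parts, `[[`, "", 1),
    cell_type = vapply(parts, `[[`, "", 2),
    n_cells = n_cells, stringsAsFactors = FALSE)
  coldata$group <- annot$group[match(coldata$sample_id, annot$sample_id)]
  keep <- coldata$n_cells >= min_cells
  dropped <- coldata[!keep, , drop = FALSE]
  if (!any(keep))
    stop("no (sample, cell type) pair has at least ", min_cells, " cells")
  B <- B[, keep, drop = FALSE]
  coldata <- coldata[keep, , drop = FALSE]
  rownames(coldata) <- colnames(B) <-
    paste(coldata$sample_id, coldata$cell_type, sep = "|")
  rownames(B) <- rownames(counts)
  structure(list(counts = B, coldata = coldata),
            class = "pseudobulk", dropped = dropped)
}

#' @export
print.pseudobulk <- function(x, ...) {
  cat("Pseudo-bulk matrix: ", nrow(x$counts), " genes x ",
      ncol(x$counts), " (sample, cell type) columns\n", sep = "")
  print(table(x$coldata$cell_type))
  invisible(x)
}

#' Median-of-ratios size factors
#'
#' For each gene expressed in every column, compute its geometric mean
#' across columns; the size factor of a column is the median over those
#' genes of the column's count divided by the gene's geometric mean.
#' Factors are not rescaled afterwards (no unit-geometric-mean
#' renormalization).
#'
#' @param B Genes x columns count matrix, or a `pseudobulk` object.
#' @return Named numeric vector of positive size factors.
#' @export
estimate_size_factors <- function(B) {
  if (inherits(B, "pseudobulk")) B <- B$counts
  B <- as.matrix(B)
  all_pos <- rowSums(B > 0) == ncol(B)
  if (!any(all_pos))
    stop("no gene has positive counts in every column; ",
         "filter genes or add a pseudo-count before size-factor estimation")
  P <- B[all_pos, , drop = FALSE]
  geo <- exp(rowMeans(log(P)))
  s <- apply(P / geo, 2, stats::median)
  stats::setNames(s, colnames(B))
}

#' Size-factor-normalized counts
#'
#' @param B Genes x columns count matrix, or a `pseudobulk` object.
#' @param s Size factors from [estimate_size_factors()].
#' @return Matrix of normalized counts (entry-wise count / s).
#' @export
norm_counts <- function(B, s = estimate_size_factors(B)) {
  if (inherits(B, "pseudobulk")) B <- B$counts
  if (length(s) != ncol(B)) stop("size factors do not match columns")
  sweep(as.matrix(B), 2, as.numeric(s), "/")
}

#' Gene-set score per pseudo-bulk profile
#'
#' The per-cell module score applied to pseudo-bulk data: the mean over
#' the set's genes of log2(normalizedCount + 1) in each column.
#'
#' @param norm Genes x columns normalized-count matrix from
#'   [norm_counts()].
#' @param geneset Character vector of gene ids.
#' @return Named numeric vector of per-column scores.
#' @export
pseudobulk_geneset_score <- function(norm, geneset) {
  present <- intersect(geneset, rownames(norm))
  if (!length(present))
    stop("no gene of the set is present in the matrix")
  if (length(present) < length(unique(geneset)))
    warning(length(unique(geneset)) - length(present),
            " set gene(s) absent from the matrix were dropped")
  colMeans(log2(norm[present, , drop = FALSE] + 1))
}
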