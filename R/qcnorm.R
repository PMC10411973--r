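#' Per-cell mitochondrial UMI fraction
#'
#' @param counts Sparse genes x cells UMI matrix.
#' @param mito_genes Character vector of mitochondrial gene ids, or
#'   `NULL` to take all genes whose id starts with `mt-`
#'   (case-insensitive, the mouse symbol convention).
#' @return Data frame with `cell_id`, `total_umi`, `mito_fraction`, and
#'   `zero_total` (flag for cells with no UMIs at all, whose fraction is
#'   reported as 0).
#' @export
mito_fraction <- function(counts, mito_genes = NULL) {
  if (is.null(mito_genes))
    mito_genes <- grep("^mt-", rownames(counts), ignore.case = TRUE,
                       value = TRUE)
  unknown <- setdiff(mito_genes, rownames(counts))
  if (length(unknown))
    stop("mitochondrial gene id(s) not in matrix: ",
         paste(unknown, collapse = ", "))
  n_c <- Matrix::colSums(counts)
  mito <- if (length(mito_genes))
    Matrix::colSums(counts[mito_genes, , drop = FALSE]) else
      numeric(ncol(counts))
  zero <- n_c == 0
  frac <- ifelse(zero, 0, mito / pmax(n_c, 1))
  cid <- colnames(counts)
  if (is.null(cid)) cid <- as.character(seq_len(ncol(counts)))
  data.frame(cell_id = cid, total_umi = as.numeric(n_c),
             mito_fraction = frac, zero_total = zero,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-cell quality filter
#'
#' Removes a cell iff its total UMI count is strictly below
#' `min_total_umi` or its mitochondrial fraction strictly exceeds
#' `max_mito`; boundary cells (exactly 1000 UMIs, exactly 10%
#' mitochondrial) are retained.
#'
#' @param counts Sparse genes x cells UMI matrix.
#' @param min_total_umi Minimum total UMIs per cell (default 1000).
#' @param max_mito Maximum mitochondrial fraction (default 0.10).
#' @param mito_genes Passed to [mito_fraction()].
#' @return List with `counts` (filtered matrix) and `report` (per-cell
#'   data frame: cell_id, total_umi, mito_fraction, kept, reason; plus a
#'   `summary` attribute counting removals by criterion and jointly).
#' @export
qc_filter <- function(counts, min_total_umi = 1000, max_mito = 0.10,
                      mito_genes = NULL) {
  stopifnot(min_total_umi >= 0, max_mito >= 0, max_mito <= 1)
  mf <- mito_fraction(counts, mito_genes)
  low <- mf$total_umi < min_total_umi
  high <- mf$mito_fraction > max_mito
  kept <- !(low | high)
  reason <- rep("", nrow(mf))
  reason[low & !high] <- "low_umi"
  reason[!low & high] <- "high_mito"
  reason[low & high] <- "low_umi;high_mito"
  report <- cbind(mf[c("cell_id", "total_umi", "mito_fraction")],
                  kept = kept, reason = reason)
  attr(report, "summary") <- c(
    n_in = nrow(mf), n_kept = sum(kept),
    removed_low_umi = sum(low), removed_high_mito = sum(high),
    removed_both = sum(low & high))
  if (nrow(mf) > 0 && !any(kept))
    warning("all cells removed by QC filter")
  list(counts = counts[, kept, drop = FALSE], report = report)
}

#' Median-ratio cell normalization factors
#'
#' The factor for cell `c` is its total UMI count divided by the median
#' total over all cells, so dividing by it rescales every cell to the
#' median library size. The median of an even number of cells is the
#' mean of the two central values.
#'
#' @param counts Sparse genes x cells UMI matrix of QC-passing cells.
#' @return Numeric vector of positive per-cell factors, named by cell;
#'   the median total is attached as attribute `median_total`.
#' @export
cell_size_factors <- function(counts) {
  if (ncol(counts) < 1) stop("need at least one cell")
  n_c <- Matrix::colSums(counts)
  if (any(n_c == 0))
    stop("normalization undefined for cells with zero total UMIs: ",
         paste(utils::head(colnames(counts)[n_c == 0], 5), collapse = ", "))
  med <- stats::median(n_c)
  f <- n_c / med
  names(f) <- colnames(counts)
  attr(f, "median_total") <- med
  f
}

#' Normalize UMIs by per-cell factors
#'
#' Divides every gene's raw UMI count in a cell by that cell's factor,
#' so all column totals equal the median pre-normalization total. The
#' sparsity pattern is preserved.
#'
#' @param counts Sparse genes x cells UMI matrix.
#' @param f Factors from [cell_size_factors()] (computed if missing).
#' @return Sparse genes x cells matrix of normalized UMIs.
#' @export
normalize_umis <- function(counts, f = cell_size_factors(counts)) {
  if (length(f) != ncol(counts) ||
      !is.null(names(f)) && !all(names(f) == colnames(counts)))
    stop("factors do not match the matrix columns")
  out <- counts %*% Matrix::Diagonal(x = 1 / as.numeric(f))
  dimnames(out) <- dimnames(counts)
  methods::as(out, "CsparseMatrix")
}
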