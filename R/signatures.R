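#' Size-factor-normalized RPKM (nRPKM) for bulk RNA-seq
#'
#' Depth- and length-normalized expression: each count is divided by
#' its column's median-of-ratios size factor, by the gene length in
#' kilobases, and by the common effective depth in millions, where the
#' effective depth D is the median across samples of the size-factor-
#' corrected column total:
#' `nRPKM[g, j] = count[g, j] / s[j] / (length[g] / 1e3) / (D / 1e6)`.
#'
#' @param counts Genes x samples integer matrix.
#' @param lengths Named numeric vector of gene lengths in bp (> 0).
#' @param s Size factors (default: [estimate_size_factors()] on counts).
#' @return Genes x samples matrix of nRPKM values, with `D` attached as
#'   attribute `effective_depth`.
#' @export
nrpkm <- function(counts, lengths, s = estimate_size_factors(counts)) {
  counts <- as.matrix(counts)
  if (is.null(names(lengths))) {
    stopifnot(length(lengths) == nrow(counts))
  } else {
    miss <- setdiff(rownames(counts), names(lengths))
    if (length(miss))
      stop("missing gene length(s): ", paste(utils::head(miss, 5),
                                             collapse = ", "))
    lengths <- lengths[rownames(counts)]
  }
  if (any(lengths <= 0)) stop("gene lengths must be positive")
  corrected <- sweep(counts, 2, as.numeric(s), "/")
  D <- stats::median(colSums(corrected))
  out <- corrected / (lengths / 1e3) / (D / 1e6)
  attr(out, "effective_depth") <- D
  out
}

#' Gene-set score per bulk sample
#'
#' Mean over the set's genes of log2(nRPKM + 1) in each sample.
#'
#' @param expr Genes x samples nRPKM matrix.
#' @param geneset Character vector of gene ids.
#' @return Named numeric vector of per-sample scores.
#' @export
bulk_geneset_score <- function(expr, geneset) {
  present <- intersect(geneset, rownames(expr))
  if (!length(present))
    stop("no gene of the set is present in the matrix")
  if (length(present) < length(unique(geneset)))
    warning(length(unique(geneset)) - length(present),
            " set gene(s) absent from the matrix were dropped")
  colMeans(log2(expr[present, , drop = FALSE] + 1))
}

#' Per-gene z-scores across samples of floored log2 expression
#'
#' Takes log2(nRPKM), floors values below `floor` (which also resolves
#' the -Inf from zero counts), then z-scores each gene across samples
#' using the sample standard deviation (ddof = 1). Genes that are
#' constant after flooring get a zero z-row and are flagged.
#'
#' @param expr Genes x samples nRPKM matrix (at least 2 samples).
#' @param floor Lower floor on log2 values (default -4).
#' @return Genes x samples z-score matrix with logical attribute
#'   `constant` per gene.
#' @export
zscore_matrix <- function(expr, floor = -4) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 2) stop("z-scoring needs at least two samples")
  x <- log2(expr)
  x[x < floor] <- floor
  mu <- rowMeans(x)
  sd <- apply(x, 1, stats::sd)
  const <- sd == 0
  z <- (x - mu) / ifelse(const, 1, sd)
  z[const, ] <- 0
  attr(z, "constant") <- stats::setNames(const, rownames(expr))
  z
}

#' Select a gene set's top genes by reference-group z-score
#'
#' Ranks the set's genes by their mean z-score within a reference group
#' of samples (e.g., the treated wild-type samples) and returns the top
#' `n` — the rule used to pick heatmap rows. Ties break by gene id.
#'
#' @param z Genes x samples z-score matrix from [zscore_matrix()].
#' @param geneset Character vector of gene ids.
#' @param reference_samples Sample (column) names forming the reference
#'   group; must be non-empty.
#' @param n Number of genes to return (default 60).
#' @return Character vector of `n` gene ids, highest reference z first.
#' @export
select_top_genes_by_zscore <- function(z, geneset, reference_samples,
                                       n = 60) {
  stopifnot(length(reference_samples) >= 1)
  if (!all(reference_samples %in% colnames(z)))
    stop("unknown reference sample(s)")
  present <- intersect(geneset, rownames(z))
  if (n > length(present))
    stop("n = ", n, " exceeds the ", length(present),
         " set genes present in the matrix")
  mz <- rowMeans(z[present, reference_samples, drop = FALSE])
  present[order(-mz, present)][seq_len(n)]
}
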