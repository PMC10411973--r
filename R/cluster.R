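# log2(x + 1) preserving sparsity
.log2p1 <- function(m) {
  out <- m
  if (length(out@x)) out@x <- log2(out@x + 1)
  out
}

.row_stats <- function(L) {
  n <- ncol(L)
  s1 <- Matrix::rowSums(L)
  s2 <- Matrix::rowSums(L^2)
  mu <- s1 / n
  v <- (s2 - n * mu^2) / (n - 1)
  list(mean = mu, var = pmax(v, 0))
}

#' Select highly variable genes
#'
#' Ranks genes by the standardized dispersion of log2(normalized UMI + 1):
#' dispersion (variance / mean) is computed per gene, genes are split
#' into `n_bins` equal-count bins of mean expression, and dispersions are
#' z-scored within each bin so that highly expressed genes do not
#' dominate. Deterministic given the input; ties break by gene id.
#'
#' @param norm Sparse genes x cells normalized-UMI matrix.
#' @param n Number of genes to return (default 3000).
#' @param n_bins Number of mean-expression bins (default 20).
#' @return Character vector of the top `n` gene ids, most variable first.
#' @export
select_hvg <- function(norm, n = 3000, n_bins = 20) {
  L <- .log2p1(norm)
  st <- .row_stats(L)
  ok <- which(st$var > 0)
  if (!length(ok)) stop("no genes with nonzero variance")
  if (n > length(ok))
    stop("requested ", n, " HVGs but only ", length(ok),
         " genes have nonzero variance")
  mu <- st$mean[ok]
  disp <- st$var[ok] / mu
  breaks <- unique(stats::quantile(mu, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(mu, breaks = breaks, include.lowest = TRUE)
  z <- disp
  for (b in levels(bin)) {
    i <- which(bin == b)
    s <- stats::sd(disp[i])
    z[i] <- if (length(i) < 2 || is.na(s) || s == 0) 0 else
      (disp[i] - mean(disp[i])) / s
  }
  ids <- rownames(norm)[ok]
  ids[order(-z, ids)][seq_len(n)]
}

#' PCA embedding of normalized expression
#'
#' Principal components of centered, unit-scaled log2(normalized UMI + 1)
#' over the selected genes. Components are ordered by decreasing
#' explained variance and each component's sign is fixed so that its
#' largest-magnitude gene loading is positive.
#'
#' @param norm Sparse genes x cells normalized-UMI matrix.
#' @param genes Gene ids to use (typically from [select_hvg()]).
#' @param n_pcs Number of components (default 30).
#' @return Cells x PCs score matrix with attributes `explained_variance`
#'   (per-PC variance) and `rotation` (gene loadings).
#' @export
pca_embed <- function(norm, genes, n_pcs = 30) {
  if (ncol(norm) < 2) stop("need at least two cells for PCA")
  genes <- intersect(genes, rownames(norm))
  if (n_pcs > min(length(genes), ncol(norm)) - 1)
    stop("n_pcs must be at most min(#genes, #cells) - 1")
  X <- t(as.matrix(.log2p1(norm[genes, , drop = FALSE])))
  X <- scale(X)
  X[, attr(X, "scaled:scale") == 0] <- 0
  pc <- stats::prcomp(X, center = FALSE, scale. = FALSE, rank. = n_pcs)
  scores <- pc$x
  rot <- pc$rotation
  for (k in seq_len(ncol(scores))) {
    j <- which.max(abs(rot[, k]))
    if (rot[j, k] < 0) {
      rot[, k] <- -rot[, k]
      scores[, k] <- -scores[, k]
    }
  }
  rownames(scores) <- colnames(norm)
  attr(scores, "explained_variance") <- pc$sdev[seq_len(ncol(scores))]^2
  attr(scores, "rotation") <- rot
  scores
}

# k nearest neighbours (excluding self) by Euclidean distance in PC space
.knn_indices <- function(scores, k) {
  D <- as.matrix(stats::dist(scores))
  n <- nrow(D)
  t(vapply(seq_len(n), function(i) order(D[i, ])[2:(k + 1)], integer(k)))
}

#' Louvain graph clustering of cells
#'
#' Builds a k-nearest-neighbour graph in PC space (Euclidean), weights
#' edges by the shared-nearest-neighbour Jaccard overlap of the two
#' cells' neighbourhoods (each including the cell itself), and runs
#' Louvain modularity optimization. A fixed seed gives identical labels
#' across runs; singleton clusters are permitted.
#'
#' @param scores Cells x PCs matrix from [pca_embed()].
#' @param k_neighbors Neighbourhood size (default 15).
#' @param resolution Louvain resolution (default 1).
#' @param seed Integer seed for the community search.
#' @return Object of class `cluster_assignment`: list with `cluster`
#'   (named integer vector of 1-based labels), `level`, and `parameters`.
#' @export
louvain_cluster <- function(scores, k_neighbors = 15, resolution = 1,
                            seed = 1L) {
  n <- nrow(scores)
  if (k_neighbors >= n)
    stop("k_neighbors (", k_neighbors, ") must be below the cell count (",
         n, ")")
  nn <- .knn_indices(scores, k_neighbors)
  A <- Matrix::sparseMatrix(
    i = rep(seq_len(n), each = k_neighbors + 1),
    j = as.vector(t(cbind(seq_len(n), nn))),
    x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(A)           # |N(i) ∩ N(j)|
  sz <- k_neighbors + 1
  jac <- shared
  jac@x <- jac@x / (2 * sz - jac@x)         # Jaccard: |∩| / |∪|
  Matrix::diag(jac) <- 0
  jac <- Matrix::drop0(jac)
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                           weighted = TRUE)
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  cl <- as.integer(igraph::membership(comm))
  names(cl) <- rownames(scores)
  structure(list(cluster = cl, level = "top",
                 parameters = list(k_neighbors = k_neighbors,
                                   resolution = resolution, seed = seed)),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("Cluster assignment (", x$level, "): ", length(x$cluster),
      " cells in ", length(unique(x$cluster)), " clusters\n", sep = "")
  print(table(cluster = x$cluster))
  invisible(x)
}

#' Per-cell gene-set module score
#'
#' The score of a cell is the mean over the set's genes of
#' log2(normalized UMI + 1). Set genes absent from the matrix are
#' dropped with a warning; if none are present this is an error.
#'
#' @param norm Sparse genes x cells normalized-UMI matrix.
#' @param geneset Character vector of gene ids.
#' @return Named numeric vector of per-cell scores.
#' @export
score_cells <- function(norm, geneset) {
  present <- intersect(geneset, rownames(norm))
  if (!length(present))
    stop("no gene of the set is present in the matrix")
  if (length(present) < length(unique(geneset)))
    warning(length(unique(geneset)) - length(present),
            " set gene(s) absent from the matrix were dropped")
  Matrix::colMeans(.log2p1(norm[present, , drop = FALSE]))
}

#' Annotate clusters with marker gene sets
#'
#' Scores every marker set in every cell, averages scores within each
#' cluster, and labels each cluster with the set whose mean score is
#' maximal. Exact ties break to the lexicographically first set name and
#' are flagged.
#'
#' @param assign A `cluster_assignment`.
#' @param norm Sparse genes x cells normalized-UMI matrix (same cells).
#' @param marker_sets Named list of gene-id vectors.
#' @return Object of class `cluster_annotation`: list with `cell_type`
#'   (named character, per cluster), `scores` (clusters x sets matrix),
#'   `tie` (logical per cluster), and `cell_type_of_cell` (per cell).
#' @export
annotate_clusters <- function(assign, norm, marker_sets) {
  stopifnot(length(marker_sets) >= 1, !is.null(names(marker_sets)))
  cl <- assign$cluster[colnames(norm)]
  if (anyNA(cl)) stop("cluster assignment does not cover all cells")
  sets <- names(marker_sets)[order(names(marker_sets))]
  per_cell <- vapply(sets, function(s) score_cells(norm, marker_sets[[s]]),
                     numeric(ncol(norm)))
  clusters <- sort(unique(cl))
  scores <- t(vapply(clusters, function(k)
    colMeans(per_cell[cl == k, , drop = FALSE]), numeric(length(sets))))
  dimnames(scores) <- list(as.character(clusters), sets)
  best <- apply(scores, 1, function(s) sets[which.max(s)])  # first max: lexicographic
  tie <- apply(scores, 1, function(s) sum(s == max(s)) > 1)
  names(best) <- names(tie) <- as.character(clusters)
  structure(list(cell_type = best, scores = scores, tie = tie,
                 cell_type_of_cell = stats::setNames(
                   best[as.character(cl)], names(cl))),
            class = "cluster_annotation")
}

#' @export
print.cluster_annotation <- function(x, ...) {
  cat("Cluster annotation:\n")
  print(data.frame(cluster = names(x$cell_type), cell_type = x$cell_type,
                   tie = x$tie, row.names = NULL))
  invisible(x)
}

#' Subcluster one cell type
#'
#' Extracts the target type's cells from the RAW counts, recomputes
#' size factors and normalization on the subset alone, then reruns HVG
#' selection, PCA and Louvain clustering within the subset (the
#' re-normalization recipe used for T-cell subtyping). `n_hvg` is capped
#' at the number of genes with nonzero variance in the subset.
#'
#' @param counts Raw sparse genes x cells UMI matrix.
#' @param cell_types Named character vector (cell id -> type), e.g.
#'   `annotation$cell_type_of_cell` from [annotate_clusters()].
#' @param target_type Cell type to subcluster.
#' @param n_hvg,n_pcs,k_neighbors,resolution,seed Clustering parameters.
#' @return A `cluster_assignment` over the target type's cells, with
#'   the subset normalized matrix attached as attribute `norm`.
#' @export
subcluster <- function(counts, cell_types, target_type, n_hvg = 3000,
                       n_pcs = 30, k_neighbors = 15, resolution = 1,
                       seed = 1L) {
  cells <- names(cell_types)[cell_types == target_type]
  cells <- intersect(colnames(counts), cells)
  if (!length(cells))
    stop("no cells of type '", target_type, "' in the matrix")
  if (length(cells) < 2 * k_neighbors)
    stop("too few cells of type '", target_type, "' to subcluster (",
         length(cells), " < ", 2 * k_neighbors, ")")
  sub <- counts[, cells, drop = FALSE]
  norm <- normalize_umis(sub, cell_size_factors(sub))
  n_var <- sum(.row_stats(.log2p1(norm))$var > 0)
  hvg <- select_hvg(norm, n = min(n_hvg, n_var))
  n_pcs <- min(n_pcs, min(length(hvg), ncol(norm)) - 1)
  scores <- pca_embed(norm, hvg, n_pcs = n_pcs)
  out <- louvain_cluster(scores, k_neighbors = k_neighbors,
                         resolution = resolution, seed = seed)
  out$level <- paste0("subcluster:", target_type)
  attr(out, "norm") <- norm
  out
}

#' One-vs-rest marker statistics per cluster
#'
#' For every (cluster, gene): the difference in mean log2(normalized
#' UMI + 1) between the cluster's cells and all other cells, and the
#' AUROC of the gene for separating the cluster from the rest (computed
#' from the rank-sum). Rows are sorted by AUROC, descending, within each
#' cluster.
#'
#' @param norm Sparse genes x cells normalized-UMI matrix.
#' @param assign A `cluster_assignment` covering the same cells.
#' @return Data frame: cluster, gene, lfc, auroc.
#' @export
find_markers <- function(norm, assign) {
  cl <- assign$cluster[colnames(norm)]
  clusters <- sort(unique(cl))
  if (length(clusters) < 2)
    stop("marker discovery needs at least two clusters")
  L <- as.matrix(.log2p1(norm))
  n <- ncol(L)
  R <- t(apply(L, 1, rank))    # average ranks handle ties
  out <- lapply(clusters, function(k) {
    inn <- cl == k
    n1 <- sum(inn); n2 <- n - n1
    auroc <- (rowSums(R[, inn, drop = FALSE]) - n1 * (n1 + 1) / 2) / (n1 * n2)
    lfc <- rowMeans(L[, inn, drop = FALSE]) -
      rowMeans(L[, !inn, drop = FALSE])
    d <- data.frame(cluster = k, gene = rownames(L), lfc = lfc,
                    auroc = auroc, row.names = NULL)
    d[order(-d$auroc, d$gene), ]
  })
  do.call(rbind, out)
}

#' Flag putative doublet clusters by marker-set co-expression
#'
#' A cluster is flagged when its second-best marker-set score comes
#' within `margin` of its best score — the signature of a cluster
#' co-expressing two disjoint cell-type programs, as doublet clusters
#' do. By default `margin` is 0.25 times the best score's excess over
#' that set's background level — its minimum across clusters — so
#' clusters with one dominant signature, or with uniformly low scores,
#' are never flagged.
#'
#' @param annotation A `cluster_annotation` (its `scores` matrix is used).
#' @param margin Absolute score gap below which a cluster is flagged;
#'   `NULL` (default) uses the adaptive 0.25 x excess rule. `Inf` flags
#'   every cluster.
#' @return Character vector of flagged cluster ids (possibly empty).
#' @export
flag_doublet_clusters <- function(annotation, margin = NULL) {
  scores <- annotation$scores
  if (ncol(scores) < 2)
    stop("doublet flagging needs at least two marker sets")
  flagged <- character(0)
  for (k in rownames(scores)) {
    s <- sort(scores[k, ], decreasing = TRUE)
    gap <- s[1] - s[2]
    thr <- if (is.null(margin)) {
      best_set <- names(s)[1]
      0.25 * max(s[1] - min(scores[, best_set]), 0)
    } else margin
    if (gap < thr) flagged <- c(flagged, k)
  }
  flagged
}

#' Mean expression profile per cluster
#'
#' @param norm Sparse genes x cells normalized-UMI matrix.
#' @param assign A `cluster_assignment`.
#' @return Genes x clusters matrix of mean log2(normalized UMI + 1).
#' @export
cluster_profiles <- function(norm, assign) {
  cl <- assign$cluster[colnames(norm)]
  L <- .log2p1(norm)
  clusters <- sort(unique(cl))
  out <- vapply(clusters, function(k)
    Matrix::rowMeans(L[, cl == k, drop = FALSE]), numeric(nrow(L)))
  dimnames(out) <- list(rownames(norm), as.character(clusters))
  out
}

#' Map a cluster profile onto a reference expression compendium
#'
#' Spearman-correlates a cluster's mean log-expression profile against
#' each reference cell type over the genes shared between the two, the
#' way immune clusters are identified against sorted-population
#' compendia. Constant reference columns yield an undefined correlation,
#' reported as `NA` and never selected as the best match.
#'
#' @param profile Named numeric vector of mean log expression per gene.
#' @param reference Genes x types numeric matrix.
#' @return List with `best` (type name) and `table` (data frame of type,
#'   spearman, ranked by correlation, `NA` last).
#' @export
map_to_reference <- function(profile, reference) {
  shared <- intersect(names(profile), rownames(reference))
  if (length(shared) < 10)
    stop("fewer than 10 genes shared with the reference (",
         length(shared), ")")
  p <- profile[shared]
  rho <- vapply(colnames(reference), function(ty) {
    r <- reference[shared, ty]
    if (stats::sd(r) == 0 || stats::sd(p) == 0) return(NA_real_)
    stats::cor(p, r, method = "spearman")
  }, numeric(1))
  tab <- data.frame(type = names(rho), spearman = rho, row.names = NULL)
  tab <- tab[order(-tab$spearman, tab$type, na.last = TRUE), ]
  best <- if (all(is.na(rho))) NA_character_ else
    tab$type[which(!is.na(tab$spearman))[1]]
  list(best = best, table = tab)
}
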