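# shared fixture builders for the test suite

# small sparse count matrix with named dims
toy_counts <- function(m) {
  if (is.null(rownames(m)))
    rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
  if (is.null(colnames(m)))
    colnames(m) <- sprintf("c%03d", seq_len(ncol(m)))
  methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
}

# a compact 4-type simulated dataset used across cluster/composition tests
small_sim <- function(seed = 11, cells = 300, de = NULL,
                      composition_effects = list(), n_groups = 2,
                      animals_per_group = 2, n_genes = 300) {
  cfg <- sim_config(
    n_groups = n_groups, animals_per_group = animals_per_group,
    cell_types = c(astrocyte = 0.30, microglia = 0.40,
                   T_cell = 0.20, dendritic = 0.10),
    composition_effects = composition_effects,
    n_genes = n_genes, marker_block_size = 15, marker_fold = 8,
    de_effects = de, mean_library_size = 1500,
    target_cells_per_sample = cells, seed = seed)
  simulate_dataset(cfg)
}

# annotation restricted to QC-surviving cells, keyed like the matrix
annot_for <- function(sim, counts) {
  i <- match(colnames(counts), sim$annotation$cell_id)
  data.frame(cell_id = colnames(counts),
             sample_id = sim$annotation$sample_id[i],
             group = sim$annotation$group[i],
             cell_type = sim$annotation$cell_type[i],
             stringsAsFactors = FALSE)
}

# direct NB pseudo-bulk simulator for DE calibration/recovery tests:
# genes x (2 groups x n_per) with optional planted log2 fold-changes
nb_pseudobulk <- function(n_genes = 2000, n_per = 6, mean_count = 50,
                          dispersion = 0.1, planted = NULL, seed = 1) {
  set.seed(seed)
  mu0 <- rgamma(n_genes, shape = 4, rate = 4 / mean_count) + 1
  lfc <- numeric(n_genes)
  if (!is.null(planted)) lfc[planted$gene] <- planted$log2fc
  mu <- cbind(matrix(mu0, n_genes, n_per),
              matrix(mu0 * 2^lfc, n_genes, n_per))
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                   n_genes, 2 * n_per)
  dimnames(counts) <- list(sprintf("g%04d", seq_len(n_genes)),
                           sprintf("s%02d", seq_len(2 * n_per)))
  list(counts = counts,
       group = rep(c("ref", "test"), each = n_per),
       lfc = lfc)
}

# adjusted Rand index between two label vectors (closed form on the
# contingency table); used to compare clusterings with planted truth
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}
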