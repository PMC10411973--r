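test_that("HVG selection ranks a planted bimodal gene first", {
  set.seed(1)
  n <- 100
  m <- matrix(rpois(50 * n, 5), nrow = 50)
  m[7, ] <- c(rep(0, n / 2), rep(40, n / 2))   # strongly bimodal gene
  m <- toy_counts(m)
  norm <- normalize_umis(m)
  hvg <- select_hvg(norm, 10)
  # oracle: raw dispersion of log2(nUMI+1)
  L <- log2(as.matrix(norm) + 1)
  disp <- apply(L, 1, var) / rowMeans(L)
  expect_equal(hvg[1], names(which.max(disp)))
  expect_equal(hvg[1], "g007")
})

test_that("HVG selection errors on degenerate input and saturates", {
  flat <- toy_counts(matrix(3, 10, 8))
  expect_error(select_hvg(normalize_umis(flat), 5), "nonzero variance")
  set.seed(2)
  m <- toy_counts(matrix(rpois(200, 6) + 1, 20, 10))
  norm <- normalize_umis(m)
  n_var <- sum(apply(as.matrix(log2(norm + 1)), 1, var) > 0)
  expect_setequal(select_hvg(norm, n_var), rownames(m)[
    apply(as.matrix(log2(norm + 1)), 1, var) > 0])
  expect_error(select_hvg(norm, n_var + 1), "HVG")
})

test_that("PCA matches a dense eigendecomposition on a toy matrix", {
  set.seed(3)
  m <- toy_counts(matrix(rpois(200 * 100, 4), 100, 200))
  norm <- normalize_umis(m)
  genes <- select_hvg(norm, 60)
  sc <- pca_embed(norm, genes, n_pcs = 30)
  X <- scale(t(as.matrix(log2(norm[genes, ] + 1))))
  ev <- eigen(cov(X), symmetric = TRUE)$values
  expect_equal(unname(attr(sc, "explained_variance")),
               ev[1:30], tolerance = 1e-8)
})

test_that("rank-1 input concentrates all variance in PC1", {
  # build values whose log2(x + 1) matrix is exactly rank 1
  u <- seq(0.2, 2, length.out = 30)    # per-gene loading
  v <- seq(0.5, 3, length.out = 10)    # per-cell score
  m <- toy_counts(2^outer(u, v) - 1)
  sc <- pca_embed(m, rownames(m), n_pcs = 2)
  var_exp <- attr(sc, "explained_variance")
  expect_gt(var_exp[1] / sum(var_exp), 1 - 1e-8)
})

test_that("duplicated cells receive identical PC scores", {
  set.seed(4)
  m <- as.matrix(small_sim(seed = 40, cells = 40)$counts)
  m <- toy_counts(cbind(m, dup = m[, 1]))
  norm <- normalize_umis(m)
  sc <- pca_embed(norm, select_hvg(norm, 50), n_pcs = 5)
  expect_equal(unname(sc[1, ]), unname(sc[ncol(m), ]), tolerance = 1e-9)
})

test_that("Louvain separates two well-separated Gaussian blobs exactly", {
  set.seed(5)
  blob <- rbind(matrix(rnorm(200 * 5), 200, 5),
                matrix(rnorm(200 * 5, mean = 50), 200, 5))
  rownames(blob) <- sprintf("c%03d", 1:400)
  # neighbourhood size commensurate with the 200-cell blobs, so each
  # blob forms one cohesive community
  cl <- louvain_cluster(blob, k_neighbors = 25, seed = 6)
  truth <- rep(1:2, each = 200)
  expect_equal(length(unique(cl$cluster)), 2)
  expect_equal(ari(cl$cluster, truth), 1)
  expect_error(louvain_cluster(blob[1:10, ], k_neighbors = 15), "below")
})

test_that("identical coordinates collapse to a single cluster", {
  pts <- matrix(1, 40, 3, dimnames = list(sprintf("c%02d", 1:40), NULL))
  cl <- louvain_cluster(pts, k_neighbors = 5, seed = 1)
  expect_equal(length(unique(cl$cluster)), 1)
})

test_that("clustering recovers planted cell types and is stable", {
  sim <- small_sim(seed = 41, cells = 200)
  norm <- normalize_umis(sim$counts)
  sc <- pca_embed(norm, select_hvg(norm, 100), n_pcs = 20)
  cl1 <- louvain_cluster(sc, seed = 7)
  cl2 <- louvain_cluster(sc, seed = 7)
  expect_identical(cl1$cluster, cl2$cluster)
  truth <- sim$annotation$cell_type[match(names(cl1$cluster),
                                          sim$annotation$cell_id)]
  expect_gte(ari(cl1$cluster, truth), 0.9)
  # permutation invariance up to label renaming
  perm <- sample(ncol(norm))
  scp <- sc[perm, ]
  clp <- louvain_cluster(scp, seed = 7)
  expect_equal(ari(cl1$cluster[rownames(scp)], clp$cluster), 1)
})

test_that("module scores follow the closed-form mean of log expression", {
  m <- toy_counts(matrix(c(1, 3, 0, 0, 0, 2), nrow = 3))
  norm <- m   # use raw values as normalized for direct arithmetic
  expect_equal(unname(score_cells(norm, c("g001", "g002"))[1]),
               (log2(2) + log2(4)) / 2)  # = 1.5
  expect_equal(unname(score_cells(norm, c("g001", "g002"))[2]), 0)
  expect_equal(unname(score_cells(norm, "g003")),
               unname(log2(as.matrix(m)[3, ] + 1)))
  expect_error(score_cells(norm, "nope"), "no gene")
  expect_warning(score_cells(norm, c("g001", "nope")), "absent")
})

test_that("marker-block annotation labels every cluster with its true type", {
  sim <- small_sim(seed = 42, cells = 200)
  norm <- normalize_umis(sim$counts)
  sc <- pca_embed(norm, select_hvg(norm, 100), n_pcs = 20)
  cl <- louvain_cluster(sc, seed = 8)
  ann <- annotate_clusters(cl, norm, sim$truth$marker_blocks)
  truth <- sim$annotation$cell_type[match(colnames(norm),
                                          sim$annotation$cell_id)]
  # every cluster's label must match the majority true type of its cells
  for (k in names(ann$cell_type)) {
    maj <- names(which.max(table(truth[cl$cluster == as.integer(k)])))
    expect_identical(unname(ann$cell_type[k]), maj)
  }
  expect_false(any(ann$tie))
})

test_that("annotation tie-breaks are lexicographic and flagged", {
  m <- toy_counts(matrix(c(4, 4, 4, 4), 2, 2))
  cl <- structure(list(cluster = c(c001 = 1L, c002 = 1L), level = "top",
                       parameters = list()), class = "cluster_assignment")
  ann <- annotate_clusters(cl, m, list(zeta = "g001", alpha = "g002"))
  expect_identical(unname(ann$cell_type), "alpha")
  expect_true(all(ann$tie))
  one <- annotate_clusters(cl, m, list(only = "g001"))
  expect_identical(unname(one$cell_type), "only")
})

test_that("subclustering re-normalizes within the subset", {
  sim <- small_sim(seed = 43, cells = 250)
  types <- with(sim$annotation, setNames(cell_type, cell_id))
  sub <- subcluster(sim$counts, types, "microglia", n_hvg = 80,
                    n_pcs = 10, k_neighbors = 10, seed = 9)
  norm <- attr(sub, "norm")
  cells <- names(types)[types == "microglia"]
  med_sub <- median(Matrix::colSums(sim$counts[, cells]))
  expect_equal(unname(Matrix::colSums(norm)),
               rep(med_sub, length(cells)), tolerance = 1e-9 * med_sub)
  expect_setequal(names(sub$cluster), cells)
  expect_error(subcluster(sim$counts, types, "neuron"), "neuron")
})

test_that("subclustering recovers two planted subtypes within one type", {
  # plant two T-cell-like subpopulations as distinct types, then ask the
  # subcluster recipe to split their union
  cfg <- sim_config(n_groups = 1, animals_per_group = 2,
                    cell_types = c(micro = 0.5, Tsub1 = 0.25, Tsub2 = 0.25),
                    n_genes = 200, marker_block_size = 15, marker_fold = 8,
                    target_cells_per_sample = 300, seed = 44)
  sim <- simulate_dataset(cfg)
  types <- with(sim$annotation, setNames(cell_type, cell_id))
  merged <- ifelse(types %in% c("Tsub1", "Tsub2"), "T_cell", types)
  names(merged) <- names(types)
  sub <- subcluster(sim$counts, merged, "T_cell", n_hvg = 100,
                    n_pcs = 10, k_neighbors = 10, seed = 10)
  truth <- types[names(sub$cluster)]
  expect_gte(ari(sub$cluster, truth), 0.9)
})

test_that("AUROC matches exhaustive pair counting on a 30-cell toy", {
  set.seed(11)
  m <- toy_counts(matrix(rpois(10 * 30, 3), 10, 30))
  cl <- structure(list(cluster = setNames(rep(c(1L, 2L), c(12, 18)),
                                          colnames(m)),
                       level = "top", parameters = list()),
                  class = "cluster_assignment")
  mk <- find_markers(m, cl)
  L <- log2(as.matrix(m) + 1)
  for (g in rownames(m)) {
    inn <- L[g, 1:12]; out <- L[g, 13:30]
    pairs <- outer(inn, out, function(a, b)
      (a > b) + 0.5 * (a == b))
    expected <- mean(pairs)
    got <- mk$auroc[mk$cluster == 1 & mk$gene == g]
    expect_equal(got, expected, tolerance = 1e-12)
  }
})

test_that("marker statistics respect separability limits", {
  m <- matrix(0, 3, 20)
  m[1, 1:10] <- 5          # expressed only in cluster 1
  m[2, ] <- 4              # flat gene: identical means
  m <- toy_counts(m)
  cl <- structure(list(cluster = setNames(rep(c(1L, 2L), each = 10),
                                          colnames(m)),
                       level = "top", parameters = list()),
                  class = "cluster_assignment")
  mk <- find_markers(m, cl)
  m1 <- mk[mk$cluster == 1, ]
  expect_identical(m1$gene[1], "g001")      # maximal AUROC
  expect_gt(m1$auroc[m1$gene == "g001"], 0.5)
  expect_equal(m1$auroc[m1$gene == "g003"], 0.5)  # never expressed
  expect_equal(m1$lfc[m1$gene == "g002"], 0)      # equal means
  single <- structure(list(cluster = setNames(rep(1L, 20), colnames(m)),
                           level = "top", parameters = list()),
                      class = "cluster_assignment")
  expect_error(find_markers(m, single), "two clusters")
})

test_that("doublet flagging targets co-expressing clusters only", {
  scores <- rbind("1" = c(micro = 2.0, T_cell = 0.2),
                  "2" = c(micro = 0.3, T_cell = 1.8),
                  "3" = c(micro = 1.9, T_cell = 1.7))  # co-expressing
  ann <- structure(list(scores = scores), class = "cluster_annotation")
  expect_identical(flag_doublet_clusters(ann), "3")
  expect_setequal(flag_doublet_clusters(ann, margin = Inf),
                  rownames(scores))
  clean <- structure(list(scores = scores[1:2, ]),
                     class = "cluster_annotation")
  expect_length(flag_doublet_clusters(clean), 0)
})

test_that("doublet-enriched cluster is flagged on simulated data", {
  cfg <- sim_config(n_groups = 1, animals_per_group = 2,
                    cell_types = c(microglia = 0.5, T_cell = 0.5),
                    n_genes = 150, marker_block_size = 20, marker_fold = 10,
                    doublet_rate = 0.05, target_cells_per_sample = 300,
                    seed = 45)
  sim <- simulate_dataset(cfg)
  norm <- normalize_umis(sim$counts)
  sc <- pca_embed(norm, select_hvg(norm, 80), n_pcs = 10)
  # neighbourhood small enough for the ~30-cell doublet population to
  # form its own community
  cl <- louvain_cluster(sc, k_neighbors = 8, seed = 12)
  ann <- annotate_clusters(cl, norm, sim$truth$marker_blocks)
  flagged <- flag_doublet_clusters(ann)
  # the flagged set must contain the cluster most enriched in true
  # cross-type doublets
  cross <- grepl("microglia\\+T_cell|T_cell\\+microglia",
                 sim$annotation$cell_type[match(names(cl$cluster),
                                                sim$annotation$cell_id)])
  enrich <- tapply(cross, cl$cluster, mean)
  expect_true(names(which.max(enrich)) %in% flagged)
  # clusters of pure cells, each with one dominant signature, stay unflagged
  expect_setequal(flagged, names(which.max(enrich)))
})

test_that("reference mapping is a Spearman argmax with NA for flat columns", {
  set.seed(13)
  ref <- matrix(rexp(50 * 3), 50, 3,
                dimnames = list(sprintf("g%03d", 1:50),
                                c("DC", "Tcell", "flat")))
  ref[, "flat"] <- 1
  profile <- setNames(ref[, "DC"] + rnorm(50, sd = 1e-3), rownames(ref))
  res <- map_to_reference(profile, ref)
  expect_identical(res$best, "DC")
  expect_true(is.na(res$table$spearman[res$table$type == "flat"]))
  # oracle: rank-then-Pearson
  expect_equal(res$table$spearman[res$table$type == "Tcell"],
               cor(rank(profile), rank(ref[, "Tcell"])), tolerance = 1e-12)
  # exact self-match ranks first with correlation 1
  self <- map_to_reference(setNames(ref[, "Tcell"], rownames(ref)), ref)
  expect_identical(self$best, "Tcell")
  expect_equal(max(self$table$spearman, na.rm = TRUE), 1)
  expect_error(map_to_reference(profile[1:5], ref), "10 genes")
})
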