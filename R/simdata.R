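#' Synthetic scRNA-seq study configuration
#'
#' Builds and validates the configuration for [simulate_dataset()]. The
#' defaults emulate a multi-genotype mouse hippocampus droplet scRNA-seq
#' design: several genotype groups with a few animals each, roughly ten
#' cell types dominated by glia, negative-binomial UMI counts, a block of
#' mitochondrial genes, and optional planted composition shifts,
#' cell-type-specific differential-expression effects and doublets.
#'
#' @param n_groups Number of genotype groups.
#' @param animals_per_group Animals (samples) per group. Either a single
#'   count or a vector of length `n_groups`.
#' @param cell_types Named numeric vector of baseline cell-type
#'   proportions; must sum to 1.
#' @param composition_effects Named list mapping `"group:cell_type"` to a
#'   fold-change applied to that type's baseline proportion in that group
#'   (proportions are renormalized afterwards).
#' @param n_genes Total number of genes, including mitochondrial genes.
#' @param marker_blocks Named list mapping cell-type name to the gene
#'   indices forming its marker block (elevated mean in that type). If
#'   `NULL`, disjoint blocks of `marker_block_size` genes are assigned
#'   automatically, one per cell type.
#' @param marker_block_size Genes per automatic marker block.
#' @param marker_fold Fold elevation of marker-block genes in their type.
#' @param de_effects A data frame with columns `group`, `cell_type`,
#'   `gene` (index or id) and `log2fc`, each row planting a
#'   log2-fold-change on that gene's mean in that (group, cell type).
#' @param mean_library_size Expected UMIs per cell.
#' @param libsize_sigma Log-scale SD of the log-normal library-size draw.
#' @param nb_dispersion Negative-binomial dispersion `alpha` in the
#'   variance function `mu + alpha * mu^2`; must be > 0.
#' @param mito_gene_count Number of mitochondrial genes (named with the
#'   `mt-` prefix, the mouse gene-symbol convention).
#' @param mito_fraction_mean Expected fraction of each cell's UMIs coming
#'   from mitochondrial genes.
#' @param target_cells_per_sample Cells drawn per sample.
#' @param composition_overdispersion If > 0, per-sample cell-type
#'   proportions are drawn Dirichlet around the planted proportions with
#'   concentration `1/composition_overdispersion` before the multinomial
#'   draw; 0 gives a plain multinomial.
#' @param doublet_rate Fraction of additional synthetic doublets (pairwise
#'   sums of cross-type cell profiles) appended per sample; 0 disables.
#' @param seed Integer seed; identical config + seed reproduce the
#'   dataset exactly.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_groups = 4,
                       animals_per_group = 3,
                       cell_types = c(
                         astrocyte = 0.18, microglia = 0.30,
                         oligodendrocyte = 0.20, OPC = 0.06,
                         neuron = 0.08, endothelial = 0.07,
                         pericyte = 0.04, T_cell = 0.02,
                         dendritic = 0.01, ependymal = 0.04),
                       composition_effects = list(),
                       n_genes = 1000,
                       marker_blocks = NULL,
                       marker_block_size = 20,
                       marker_fold = 8,
                       de_effects = NULL,
                       mean_library_size = 2000,
                       libsize_sigma = 0.3,
                       nb_dispersion = 0.1,
                       mito_gene_count = 13,
                       mito_fraction_mean = 0.05,
                       target_cells_per_sample = 10000,
                       composition_overdispersion = 0,
                       doublet_rate = 0,
                       seed = 1L) {
  stopifnot(n_groups >= 1, all(animals_per_group >= 1), n_genes >= 1,
            target_cells_per_sample >= 1)
  if (length(animals_per_group) == 1)
    animals_per_group <- rep(animals_per_group, n_groups)
  if (length(animals_per_group) != n_groups)
    stop("animals_per_group must have length 1 or n_groups")
  if (abs(sum(cell_types) - 1) > 1e-9)
    stop("baseline cell-type proportions must sum to 1 (got ",
         sum(cell_types), ")")
  if (any(cell_types < 0) || any(cell_types > 1))
    stop("baseline proportions must lie in [0, 1]")
  if (is.null(names(cell_types)) || anyDuplicated(names(cell_types)))
    stop("cell_types must be uniquely named")
  if (!is.numeric(nb_dispersion) || nb_dispersion <= 0)
    stop("nb_dispersion must be > 0")
  if (mean_library_size <= 0)
    stop("mean_library_size must be > 0")
  if (mito_fraction_mean < 0 || mito_fraction_mean > 1)
    stop("mito_fraction_mean must lie in [0, 1]")
  if (mito_gene_count < 0 || mito_gene_count >= n_genes)
    stop("mito_gene_count must be in [0, n_genes)")
  if (doublet_rate < 0 || doublet_rate > 0.5)
    stop("doublet_rate must lie in [0, 0.5]")

  types <- names(cell_types)
  if (is.null(marker_blocks)) {
    n_body <- n_genes - mito_gene_count
    need <- marker_block_size * length(types)
    if (need > n_body)
      stop("not enough non-mitochondrial genes for the marker blocks")
    marker_blocks <- stats::setNames(
      split(seq_len(need), rep(seq_along(types), each = marker_block_size)),
      types)
  } else {
    if (!all(names(marker_blocks) %in% types))
      stop("marker_blocks names must be cell types")
    if (any(unlist(marker_blocks) > n_genes))
      stop("marker gene index exceeds n_genes")
  }
  if (!is.null(de_effects)) {
    de_effects <- as.data.frame(de_effects)
    stopifnot(all(c("group", "cell_type", "gene", "log2fc") %in%
                    names(de_effects)))
    if (any(de_effects$gene < 1 | de_effects$gene > n_genes))
      stop("planted DE gene index out of range")
    if (!all(de_effects$cell_type %in% types))
      stop("planted DE cell_type unknown")
  }
  structure(list(
    n_groups = as.integer(n_groups),
    animals_per_group = as.integer(animals_per_group),
    cell_types = cell_types,
    composition_effects = composition_effects,
    n_genes = as.integer(n_genes),
    marker_blocks = marker_blocks,
    marker_fold = marker_fold,
    de_effects = de_effects,
    mean_library_size = mean_library_size,
    libsize_sigma = libsize_sigma,
    nb_dispersion = nb_dispersion,
    mito_gene_count = as.integer(mito_gene_count),
    mito_fraction_mean = mito_fraction_mean,
    target_cells_per_sample = as.integer(target_cells_per_sample),
    composition_overdispersion = composition_overdispersion,
    doublet_rate = doublet_rate,
    seed = as.integer(seed)), class = "sim_config")
}

# planted per-type proportions for one group: apply fold-changes, renormalize
.planted_proportions <- function(config, group) {
  p <- config$cell_types
  eff <- config$composition_effects
  if (length(eff)) {
    for (key in names(eff)) {
      parts <- strsplit(key, ":", fixed = TRUE)[[1]]
      if (parts[1] == group && parts[2] %in% names(p))
        p[parts[2]] <- p[parts[2]] * eff[[key]]
    }
  }
  p / sum(p)
}

# per-(type, group) relative gene means on the simplex (sum to 1)
.expression_profile <- function(config, type, group, base_weights) {
  w <- base_weights
  mb <- config$marker_blocks[[type]]
  if (length(mb)) w[mb] <- w[mb] * config$marker_fold
  de <- config$de_effects
  if (!is.null(de)) {
    hit <- de$group == group & de$cell_type == type
    if (any(hit)) w[de$gene[hit]] <- w[de$gene[hit]] * 2^de$log2fc[hit]
  }
  n_mito <- config$mito_gene_count
  if (n_mito > 0) {
    mito_idx <- seq.int(config$n_genes - n_mito + 1, config$n_genes)
    w[mito_idx] <- 0
    w <- w / sum(w) * (1 - config$mito_fraction_mean)
    w[mito_idx] <- config$mito_fraction_mean / n_mito
  } else {
    w <- w / sum(w)
  }
  w
}

#' Simulate a synthetic scRNA-seq dataset with known ground truth
#'
#' Draws, per sample, cell-type counts from a multinomial (optionally
#' Dirichlet-multinomial) around the planted group proportions; then, per
#' cell, a log-normal library size and negative-binomial gene UMIs whose
#' means combine a shared baseline profile, the cell type's marker block,
#' any planted DE effect for the cell's (group, type), and a fixed
#' mitochondrial mass split over `mt-` genes.
#'
#' @param config A [sim_config()] object.
#' @return A list with `counts` (sparse genes x cells dgCMatrix),
#'   `annotation` (data frame: cell_id, sample_id, group, cell_type — the
#'   true type; downstream clustering assigns its own), and `truth` (a
#'   list with `cell_type_of_cell`, `planted_de`, `planted_composition`,
#'   `doublet`, `marker_blocks`, and `gene_sets` — synthetic
#'   disease-associated, homeostatic, immediate-early and MHC-II-like
#'   modules drawn from the marker blocks).
#' @export
simulate_dataset <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  G <- config$n_genes
  types <- names(config$cell_types)
  gene_ids <- sprintf("g%04d", seq_len(G))
  if (config$mito_gene_count > 0) {
    mito_idx <- seq.int(G - config$mito_gene_count + 1, G)
    gene_ids[mito_idx] <- sprintf("mt-g%02d", seq_along(mito_idx))
  }
  # shared baseline expression weights (gamma-distributed, heavy-ish tail)
  base_w <- stats::rgamma(G, shape = 0.6, rate = 1) + 1e-4

  profiles <- list()
  groups <- paste0("group", seq_len(config$n_groups))
  for (gp in groups) for (ty in types)
    profiles[[paste(gp, ty, sep = ":")]] <-
      .expression_profile(config, ty, gp, base_w)

  sample_ids <- character(0)
  sample_group <- character(0)
  for (gi in seq_len(config$n_groups)) {
    ids <- sprintf("%s_s%d", groups[gi], seq_len(config$animals_per_group[gi]))
    sample_ids <- c(sample_ids, ids)
    sample_group <- c(sample_group, rep(groups[gi], length(ids)))
  }

  counts_cols <- vector("list", length(sample_ids))
  ann_list <- vector("list", length(sample_ids))
  planted_comp <- list()
  n_per <- config$target_cells_per_sample

  for (si in seq_along(sample_ids)) {
    gp <- sample_group[si]
    p <- .planted_proportions(config, gp)
    planted_comp[[sample_ids[si]]] <- p
    p_draw <- p
    if (config$composition_overdispersion > 0) {
      conc <- p / config$composition_overdispersion
      gd <- stats::rgamma(length(p), shape = conc, rate = 1)
      if (sum(gd) > 0) p_draw <- gd / sum(gd)
    }
    type_counts <- as.vector(stats::rmultinom(1, n_per, p_draw))
    cell_types_s <- rep(types, type_counts)
    libs <- stats::rlnorm(n_per,
                          meanlog = log(config$mean_library_size) -
                            config$libsize_sigma^2 / 2,
                          sdlog = config$libsize_sigma)
    m <- matrix(0L, nrow = G, ncol = n_per)
    size <- 1 / config$nb_dispersion
    for (ty in types) {
      idx <- which(cell_types_s == ty)
      if (!length(idx)) next
      prof <- profiles[[paste(gp, ty, sep = ":")]]
      mu <- outer(prof, libs[idx])
      m[, idx] <- stats::rnbinom(length(mu), mu = mu, size = size)
    }
    is_doublet <- rep(FALSE, n_per)
    if (config$doublet_rate > 0 && n_per >= 4) {
      n_db <- max(1L, round(config$doublet_rate * n_per))
      i1 <- sample.int(n_per, n_db, replace = TRUE)
      i2 <- sample.int(n_per, n_db, replace = TRUE)
      db <- m[, i1, drop = FALSE] + m[, i2, drop = FALSE]
      m <- cbind(m, db)
      cell_types_s <- c(cell_types_s,
                        paste(cell_types_s[i1], cell_types_s[i2], sep = "+"))
      is_doublet <- c(is_doublet, rep(TRUE, n_db))
    }
    cid <- sprintf("%s_c%05d", sample_ids[si], seq_len(ncol(m)))
    counts_cols[[si]] <- methods::as(Matrix::Matrix(m, sparse = TRUE),
                                     "CsparseMatrix")
    colnames(counts_cols[[si]]) <- cid
    ann_list[[si]] <- data.frame(
      cell_id = cid, sample_id = sample_ids[si], group = gp,
      cell_type = cell_types_s, doublet = is_doublet,
      stringsAsFactors = FALSE)
  }

  counts <- do.call(cbind, counts_cols)
  rownames(counts) <- gene_ids
  annotation <- do.call(rbind, ann_list)
  rownames(annotation) <- NULL

  planted_de <- config$de_effects
  if (is.null(planted_de))
    planted_de <- data.frame(group = character(0), cell_type = character(0),
                             gene = integer(0), log2fc = numeric(0))
  planted_de$gene_id <- gene_ids[planted_de$gene]

  gene_sets <- .synthetic_gene_sets(config, gene_ids)

  truth <- list(
    cell_type_of_cell = stats::setNames(annotation$cell_type,
                                        annotation$cell_id),
    planted_de = planted_de,
    planted_composition = planted_comp,
    doublet = stats::setNames(annotation$doublet, annotation$cell_id),
    marker_blocks = lapply(config$marker_blocks, function(i) gene_ids[i]),
    gene_sets = gene_sets)
  list(counts = counts, annotation = annotation, truth = truth)
}

# synthetic analogues of the study's scored modules, carved out of the
# simulated gene space so that scoring code can be exercised end-to-end
.synthetic_gene_sets <- function(config, gene_ids) {
  blocks <- config$marker_blocks
  sets <- list()
  pick <- function(ty, k) {
    if (!ty %in% names(blocks)) return(character(0))
    idx <- blocks[[ty]]
    gene_ids[idx[seq_len(min(k, length(idx)))]]
  }
  sets$DAM_like <- pick("microglia", 10)
  sets$homeostatic_like <- pick("microglia",
                                length(blocks[["microglia"]]))
  if (length(sets$homeostatic_like) > 10)
    sets$homeostatic_like <-
      utils::tail(sets$homeostatic_like, length(sets$homeostatic_like) - 10)
  sets$IEG_like <- pick("astrocyte", 8)
  sets$MHCII_like <- pick("dendritic", 8)
  sets[vapply(sets, length, 1L) > 0]
}

#' Write a simulated dataset to plain-text fixture files
#'
#' Writes the sparse counts as MatrixMarket (`matrix.mtx`, 1-based
#' coordinates) with `genes.tsv` and `barcodes.tsv`, the cell metadata as
#' `metadata.tsv` (cell_id, sample_id, group), the ground truth as
#' `truth.json`, and the planted gene sets as `gene_sets.gmt`. The files
#' round-trip losslessly through [load_counts()] and [read_gmt()].
#'
#' @param counts Sparse genes x cells count matrix.
#' @param annot Cell annotation data frame (cell_id, sample_id, group, ...).
#' @param truth Truth list from [simulate_dataset()], or `NULL` to skip.
#' @param path Output directory (created if missing).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_fixture <- function(counts, annot, truth = NULL, path) {
  if (ncol(counts) == 0 || nrow(counts) == 0)
    stop("refusing to write an empty count matrix")
  if (!all(colnames(counts) == annot$cell_id))
    stop("annotation rows must match count matrix columns")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  f <- c(mtx = file.path(path, "matrix.mtx"),
         genes = file.path(path, "genes.tsv"),
         barcodes = file.path(path, "barcodes.tsv"),
         metadata = file.path(path, "metadata.tsv"))
  Matrix::writeMM(counts, f[["mtx"]])
  writeLines(rownames(counts), f[["genes"]])
  writeLines(colnames(counts), f[["barcodes"]])
  utils::write.table(annot, f[["metadata"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(truth)) {
    f <- c(f, truth = file.path(path, "truth.json"))
    tr <- truth
    tr$cell_type_of_cell <- as.list(tr$cell_type_of_cell)
    tr$doublet <- as.list(tr$doublet)
    jsonlite::write_json(tr, f[["truth"]], auto_unbox = TRUE, digits = NA)
    if (!is.null(truth$gene_sets) && length(truth$gene_sets)) {
      f <- c(f, gmt = file.path(path, "gene_sets.gmt"))
      write_gmt(truth$gene_sets, f[["gmt"]])
    }
    if (!is.null(truth$marker_blocks) && length(truth$marker_blocks)) {
      f <- c(f, markers = file.path(path, "markers.gmt"))
      write_gmt(truth$marker_blocks, f[["markers"]])
    }
  }
  invisible(f)
}
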