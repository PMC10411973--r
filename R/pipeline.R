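#' Assemble and validate a pipeline configuration
#'
#' A configuration is a plain list (or a YAML file with the same keys):
#' either `input` (a fixture directory with `matrix.mtx`, `genes.tsv`,
#' `barcodes.tsv`, `metadata.tsv` and optionally `markers.gmt` /
#' `gene_sets.gmt`) or `sim` (arguments for [sim_config()]); `qc`
#' (`min_total_umi`, `max_mito`); `cluster` (`n_hvg`, `n_pcs`,
#' `k_neighbors`, `resolution`); `flag_doublets` (logical);
#' `exclude_clusters` (manual cluster id exclusions); `min_cells`
#' (pseudo-bulk threshold); `contrast` (`c(test, reference)` groups);
#' `fdr`, `lfc` (DEG thresholds); `seed`; `out` (optional output
#' directory).
#'
#' @param config List or path to a YAML file.
#' @return Validated configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    input = NULL, sim = NULL,
    qc = list(min_total_umi = 1000, max_mito = 0.10),
    cluster = list(n_hvg = 3000, n_pcs = 30, k_neighbors = 15,
                   resolution = 1),
    flag_doublets = FALSE,
    exclude_clusters = character(0),
    min_cells = 10,
    contrast = NULL,
    fdr = 0.01, lfc = 1.5,
    seed = 1L, out = NULL)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  for (nm in names(defaults$qc))
    if (is.null(config$qc[[nm]])) config$qc[[nm]] <- defaults$qc[[nm]]
  for (nm in names(defaults$cluster))
    if (is.null(config$cluster[[nm]]))
      config$cluster[[nm]] <- defaults$cluster[[nm]]
  if (is.null(config$input) && is.null(config$sim))
    stop("config needs either 'input' (fixture directory) or 'sim'")
  if (!is.null(config$input) && !dir.exists(config$input))
    stop("input directory does not exist: ", config$input)
  with(config$qc, stopifnot(min_total_umi >= 0, max_mito >= 0,
                            max_mito <= 1))
  stopifnot(config$min_cells >= 1, config$fdr > 0, config$fdr < 1,
            config$lfc >= 0)
  if (!is.null(config$contrast) && length(config$contrast) != 2)
    stop("contrast must name exactly two groups, c(test, reference)")
  structure(config, class = "pipeline_config")
}

#' Run the end-to-end analysis pipeline
#'
#' Sequences the stages in their analysis order: ingest (or simulate) ->
#' per-cell QC -> median-ratio normalization -> HVG/PCA/Louvain
#' clustering -> marker-set annotation (with optional doublet-cluster
#' flagging) -> cellularity and between-group Welch tests -> pseudo-bulk
#' aggregation with size factors -> moderated differential expression
#' per cell type -> pseudo-bulk gene-set scores. Identical configuration
#' and seed reproduce identical outputs.
#'
#' @param config A `pipeline_config` (or list / YAML path accepted by
#'   [pipeline_config()]).
#' @return Object of class `pipeline_run`: a list with the stage outputs
#'   (`counts`, `qc`, `norm`, `clusters`, `annotation`, `cellularity`,
#'   `composition_tests`, `pseudobulk`, `de`, `deg_counts`,
#'   `geneset_scores`, `truth` when simulated) and `report` (per-stage
#'   record of parameters and cell counts in/out). If `config$out` is
#'   set, stage tables are also written there as TSV plus a
#'   `manifest.json`.
#' @export
run_pipeline <- function(config) {
  config <- pipeline_config(unclass(config))
  report <- list()
  note <- function(stage, ...) {
    report[[stage]] <<- list(...)
  }

  # -- ingest ---------------------------------------------------------
  truth <- NULL
  marker_sets <- NULL
  gene_sets <- NULL
  if (!is.null(config$sim)) {
    sim_args <- config$sim
    if (is.null(sim_args$seed)) sim_args$seed <- config$seed
    sim <- simulate_dataset(do.call(sim_config, sim_args))
    counts <- sim$counts
    metadata <- sim$annotation
    truth <- sim$truth
    marker_sets <- truth$marker_blocks
    gene_sets <- truth$gene_sets
  } else {
    counts <- load_counts(config$input)
    metadata <- read_cell_metadata(file.path(config$input, "metadata.tsv"))
    mpath <- file.path(config$input, "markers.gmt")
    if (file.exists(mpath)) marker_sets <- read_gmt(mpath)
    gpath <- file.path(config$input, "gene_sets.gmt")
    if (file.exists(gpath)) gene_sets <- read_gmt(gpath)
  }
  if (!is.null(config$markers)) marker_sets <- read_gmt(config$markers)
  if (!is.null(config$gene_sets)) gene_sets <- read_gmt(config$gene_sets)
  if (is.null(marker_sets))
    stop("no marker sets available: supply markers.gmt or config$markers")
  metadata <- metadata[match(colnames(counts), metadata$cell_id), ]
  if (anyNA(metadata$cell_id))
    stop("metadata does not cover every cell in the count matrix")
  note("ingest", n_genes = nrow(counts), n_cells = ncol(counts),
       n_samples = length(unique(metadata$sample_id)))

  # -- QC + normalization --------------------------------------------
  qc <- qc_filter(counts, config$qc$min_total_umi, config$qc$max_mito)
  kept <- colnames(qc$counts)
  note("qc", cells_in = ncol(counts), cells_kept = length(kept),
       cells_removed = ncol(counts) - length(kept),
       summary = attr(qc$report, "summary"))
  f <- cell_size_factors(qc$counts)
  norm <- normalize_umis(qc$counts, f)
  note("normalize", median_total = attr(f, "median_total"))

  # -- clustering + annotation ---------------------------------------
  cl_par <- config$cluster
  n_var <- sum(.row_stats(.log2p1(norm))$var > 0)
  hvg <- select_hvg(norm, n = min(cl_par$n_hvg, n_var))
  n_pcs <- min(cl_par$n_pcs, min(length(hvg), ncol(norm)) - 1)
  scores <- pca_embed(norm, hvg, n_pcs = n_pcs)
  assign <- louvain_cluster(scores, k_neighbors = cl_par$k_neighbors,
                            resolution = cl_par$resolution,
                            seed = config$seed)
  annotation <- annotate_clusters(assign, norm, marker_sets)
  flagged <- character(0)
  if (isTRUE(config$flag_doublets) && length(marker_sets) >= 2)
    flagged <- flag_doublet_clusters(annotation)
  flagged <- union(flagged, as.character(config$exclude_clusters))
  note("cluster", n_hvg = length(hvg), n_pcs = n_pcs,
       n_clusters = length(unique(assign$cluster)),
       flagged_clusters = flagged)

  cell_meta <- metadata[match(kept, metadata$cell_id), ]
  cell_meta$cluster <- assign$cluster[kept]
  cell_meta$assigned_type <-
    unname(annotation$cell_type_of_cell[kept])
  cell_meta$flagged <- as.character(cell_meta$cluster) %in% flagged
  use <- cell_meta[!cell_meta$flagged, , drop = FALSE]

  # -- composition ----------------------------------------------------
  comp_annot <- data.frame(cell_id = use$cell_id,
                           sample_id = use$sample_id, group = use$group,
                           cell_type = use$assigned_type,
                           stringsAsFactors = FALSE)
  cellu <- cellularity(comp_annot)
  comp_tests <- NULL
  if (!is.null(config$contrast)) {
    comp_tests <- do.call(rbind, lapply(
      sort(unique(cellu$cell_type)), function(ty)
        tryCatch(compare_groups(cellu, config$contrast[1],
                                config$contrast[2], ty),
                 error = function(e) NULL)))
  }
  note("composition", n_samples = length(unique(cellu$sample_id)),
       n_types = length(unique(cellu$cell_type)))

  # -- pseudo-bulk + DE ----------------------------------------------
  pb <- aggregate_pseudobulk(qc$counts[, use$cell_id, drop = FALSE],
                             comp_annot, min_cells = config$min_cells)
  note("pseudobulk", n_columns = ncol(pb$counts),
       n_dropped = nrow(attr(pb, "dropped")))
  de <- NULL; degc <- NULL
  if (!is.null(config$contrast)) {
    degc <- deg_counts_by_cell_type(pb, config$contrast,
                                    fdr = config$fdr, lfc = config$lfc)
    de <- lapply(stats::setNames(nm = sort(unique(pb$coldata$cell_type))),
                 function(ty)
                   tryCatch(de_pseudobulk(pb, ty, config$contrast,
                                          fdr = config$fdr,
                                          lfc = config$lfc),
                            error = function(e) NULL))
    note("de", contrast = config$contrast,
         n_types_tested = sum(!vapply(de, is.null, TRUE)))
  }

  # -- gene-set scores ------------------------------------------------
  gs_scores <- NULL
  if (!is.null(gene_sets) && length(gene_sets)) {
    nc <- norm_counts(pb)
    gs_scores <- vapply(gene_sets, function(gs)
      suppressWarnings(pseudobulk_geneset_score(nc, gs)),
      numeric(ncol(nc)))
    note("signatures", n_sets = length(gene_sets))
  }

  run <- structure(list(
    config = unclass(config), counts = qc$counts, qc = qc$report,
    norm = norm, clusters = assign, annotation = annotation,
    cell_metadata = cell_meta, cellularity = cellu,
    composition_tests = comp_tests, pseudobulk = pb, de = de,
    deg_counts = degc, geneset_scores = gs_scores, truth = truth,
    report = report), class = "pipeline_run")
  if (!is.null(config$out)) .write_run(run, config$out)
  run
}

.write_run <- function(run, out) {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, name) {
    p <- file.path(out, name)
    utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
    name
  }
  files <- c(wt(run$qc, "qc_report.tsv"),
             wt(run$cell_metadata, "cell_clusters.tsv"),
             wt(run$cellularity, "cellularity.tsv"))
  if (!is.null(run$composition_tests))
    files <- c(files, wt(run$composition_tests, "composition_tests.tsv"))
  if (!is.null(run$deg_counts))
    files <- c(files, wt(run$deg_counts, "deg_counts.tsv"))
  if (!is.null(run$de)) {
    for (ty in names(run$de)) {
      if (is.null(run$de[[ty]])) next
      files <- c(files, wt(run$de[[ty]],
                           paste0("de_", gsub("[^A-Za-z0-9_]", "_", ty),
                                  ".tsv")))
    }
  }
  pbd <- cbind(id = rownames(run$pseudobulk$coldata),
               run$pseudobulk$coldata)
  files <- c(files, wt(pbd, "pseudobulk_columns.tsv"))
  manifest <- list(files = files, report = run$report,
                   seed = run$config$seed)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(files)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("gliastate pipeline run\n")
  for (stage in names(x$report)) {
    r <- x$report[[stage]]
    flat <- vapply(r, function(v) paste(format(unlist(v)), collapse = ","),
                   "")
    cat("  ", stage, ": ", paste(names(flat), flat, sep = "=",
                                 collapse = "; "), "\n", sep = "")
  }
  invisible(x)
}
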