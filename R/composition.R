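#' Cellularity table: per-sample cell-type composition
#'
#' Counts cells per (sample, cell type) and expresses them as a
#' percentage of all the sample's cells, the per-animal "cellularity"
#' statistic. When `parent` is given, a second percentage is computed
#' within the parent lineage's cells only (e.g., T-cell subtypes as a
#' percentage of all T-cells in that sample). Every (sample, type) pair
#' appears, including zero counts, so group comparisons see all samples.
#'
#' @param annot Data frame with `cell_id`, `sample_id`, `group`,
#'   `cell_type` per cell (cells already QC-filtered and, if desired,
#'   doublet-excluded).
#' @param parent Optional character vector of cell types forming the
#'   parent lineage for `pct_of_parent`.
#' @return Data frame: sample_id, group, cell_type, n_cells,
#'   pct_of_total, pct_of_parent (NA outside the parent lineage).
#' @export
cellularity <- function(annot, parent = NULL) {
  need <- c("cell_id", "sample_id", "group", "cell_type")
  stopifnot(all(need %in% names(annot)))
  empty <- setdiff(unique(annot$sample_id),
                   annot$sample_id[!is.na(annot$cell_type)])
  if (length(empty))
    warning("sample(s) with zero annotated cells excluded: ",
            paste(empty, collapse = ", "))
  samples <- sort(unique(annot$sample_id))
  types <- sort(unique(annot$cell_type))
  grp <- annot$group[match(samples, annot$sample_id)]
  tab <- table(factor(annot$sample_id, samples),
               factor(annot$cell_type, types))
  totals <- rowSums(tab)
  out <- data.frame(
    sample_id = rep(samples, times = length(types)),
    group = rep(grp, times = length(types)),
    cell_type = rep(types, each = length(samples)),
    n_cells = as.vector(tab),
    stringsAsFactors = FALSE)
  out$pct_of_total <- 100 * out$n_cells / totals[out$sample_id]
  out$pct_of_parent <- NA_real_
  if (!is.null(parent)) {
    ptot <- rowSums(tab[, colnames(tab) %in% parent, drop = FALSE])
    inp <- out$cell_type %in% parent
    out$pct_of_parent[inp] <-
      100 * out$n_cells[inp] / ptot[out$sample_id[inp]]
  }
  out[order(out$sample_id, out$cell_type), , drop = FALSE]
}

#' Welch t-test between two groups' composition percentages
#'
#' Two-sample Welch (unequal-variance) t-test on the per-animal
#' percentages of one cell type, the statistic behind between-genotype
#' cellularity comparisons. Significance stars use the conventional
#' bins: p < 0.05 `*`, < 0.01 `**`, < 0.001 `***`.
#'
#' @param table A [cellularity()] table.
#' @param group_a,group_b Group labels to compare.
#' @param cell_type Cell type to test.
#' @param measure `"pct_of_total"` (default) or `"pct_of_parent"`.
#' @return Data frame row: cell_type, group_a, group_b, t, df, p, stars.
#'   If both groups have zero variance: equal means give t = 0, p = 1;
#'   unequal means give an undefined t, reported as NA with
#'   `degenerate = TRUE`.
#' @export
compare_groups <- function(table, group_a, group_b, cell_type,
                           measure = "pct_of_total") {
  x <- table[table$group == group_a & table$cell_type == cell_type, measure]
  y <- table[table$group == group_b & table$cell_type == cell_type, measure]
  if (length(x) < 2 || length(y) < 2)
    stop("need at least two samples per group")
  res <- data.frame(cell_type = cell_type, group_a = group_a,
                    group_b = group_b, t = NA_real_, df = NA_real_,
                    p = NA_real_, stars = "", degenerate = FALSE,
                    stringsAsFactors = FALSE)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y)) {
      res$t <- 0; res$df <- length(x) + length(y) - 2; res$p <- 1
    } else {
      res$degenerate <- TRUE
    }
  } else {
    tt <- stats::t.test(x, y, var.equal = FALSE)
    res$t <- unname(tt$statistic)
    res$df <- unname(tt$parameter)
    res$p <- tt$p.value
  }
  res$stars <- if (is.na(res$p)) "" else
    if (res$p < 0.001) "***" else if (res$p < 0.01) "**" else
      if (res$p < 0.05) "*" else ""
  res
}

#' Boxplot summary statistics under the hinge/whisker convention
#'
#' Hinges are the first and third quartiles (type-7 quantiles); each
#' whisker extends to the most extreme data value no further than
#' 1.5 x IQR from its hinge; values beyond the whiskers are returned as
#' outliers (the points plotted individually).
#'
#' @param values Numeric vector (at least one value).
#' @return List: lower_hinge, upper_hinge, whisker_low, whisker_high,
#'   outliers.
#' @export
boxplot_stats <- function(values) {
  stopifnot(length(values) >= 1, !anyNA(values))
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  inside <- values[values >= q[1] - 1.5 * iqr & values <= q[2] + 1.5 * iqr]
  list(lower_hinge = q[1], upper_hinge = q[2],
       whisker_low = min(inside), whisker_high = max(inside),
       outliers = sort(values[values < min(inside) | values > max(inside)]))
}
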