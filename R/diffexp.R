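#' Filter genes with too little evidence of expression
#'
#' Keeps gene `g` iff it has at least `min_umi` UMIs in at least
#' `min_columns` of the analyzed columns (both comparisons inclusive).
#'
#' @param B Genes x columns count matrix, or a `pseudobulk` object.
#' @param min_umi Minimum UMIs in a qualifying column (default 10).
#' @param min_columns Minimum number of qualifying columns (default 3).
#' @return Character vector of surviving gene ids.
#' @export
filter_low_expression <- function(B, min_umi = 10, min_columns = 3) {
  if (inherits(B, "pseudobulk")) B <- B$counts
  B <- as.matrix(B)
  keep <- rowSums(B >= min_umi) >= min_columns
  if (!any(keep))
    stop("no gene passes the expression filter (>= ", min_umi,
         " UMIs in >= ", min_columns, " columns)")
  rownames(B)[keep]
}

#' Build a two-group design with an intercept
#'
#' @param group Character/factor of group per column.
#' @param contrast Character of length 2, `c(test, reference)`; the
#'   single non-intercept coefficient is the test-vs-reference log2FC.
#' @return List with `design` (matrix), `contrast` (coefficient vector),
#'   and the columns used (`use`, logical).
#' @export
design_two_group <- function(group, contrast) {
  stopifnot(length(contrast) == 2)
  use <- group %in% contrast
  g <- factor(group[use], levels = c(contrast[2], contrast[1]))
  design <- stats::model.matrix(~g)
  colnames(design) <- c("(Intercept)", paste0(contrast[1], "_vs_", contrast[2]))
  if (qr(design)$rank < ncol(design))
    stop("design is not full rank; are both groups present?")
  if (nrow(design) - ncol(design) < 1)
    stop("no residual degrees of freedom")
  list(design = design, contrast = c(0, 1), use = use)
}

#' Precision weights from the mean-variance trend
#'
#' Converts counts to log2 counts-per-million with a 0.5 pseudo-count,
#' using effective library sizes that fold in the median-of-ratios size
#' factors (rescaled so the geometric-mean library size is preserved).
#' Gene-wise linear models are fitted, a LOWESS curve of
#' sqrt(residual SD) against mean log2 count captures the mean-variance
#' trend, and each observation's weight is the predicted SD at its
#' fitted log-count raised to the power -4 — the inverse of its
#' predicted variance on the log-CPM scale.
#'
#' @param B Genes x columns count matrix (already expression-filtered).
#' @param s Size factors for the columns (default: all 1, plain library
#'   sizes).
#' @param design Design matrix (columns x covariates).
#' @param span LOWESS span (default 0.5).
#' @return Object of class `voom_fit`: list with `E` (log2-CPM),
#'   `weights`, `design`, `lib_size` (effective), and `trend` (the
#'   lowess x/y pairs).
#' @export
voom_weights <- function(B, s = NULL, design, span = 0.5) {
  B <- as.matrix(B)
  n <- ncol(B)
  if (nrow(design) != n) stop("design rows must match columns of B")
  if (n - ncol(design) < 1) stop("no residual degrees of freedom")
  lib <- colSums(B)
  # effective library size proportional to the size factors, with the
  # geometric-mean library size preserved; NULL means plain library sizes
  eff <- if (is.null(s)) lib else
    s * exp(mean(log(lib)) - mean(log(s)))
  E <- t(log2(t(B + 0.5) / (eff + 1) * 1e6))
  fit <- stats::lm.fit(design, t(E))
  beta <- fit$coefficients
  res <- fit$residuals                      # columns = genes
  df_res <- n - fit$rank
  sigma <- sqrt(colSums(res^2) / df_res)
  # mean log2-count and sqrt-SD per gene
  sx <- rowMeans(E) + mean(log2(eff + 1)) - log2(1e6)
  sy <- sqrt(sigma)
  ok <- is.finite(sx) & is.finite(sy)
  lo <- stats::lowess(sx[ok], sy[ok], f = span)
  lof <- stats::approxfun(lo$x, lo$y, rule = 2, ties = mean)
  fitted_logcpm <- t(design %*% beta)       # genes x columns
  fitted_count <- t(t(fitted_logcpm) + log2(eff + 1) - log2(1e6))
  w <- lof(fitted_count)^-4
  dim(w) <- dim(E)
  dimnames(w) <- dimnames(E)
  structure(list(E = E, weights = w, design = design, lib_size = eff,
                 trend = lo),
            class = "voom_fit")
}

# Newton inversion of the trigamma function (for prior-df estimation)
.trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif) / y < 1e-8) break
  }
  y
}

# moment-matching of log residual variances to a scaled-F prior:
# returns prior df d0 and prior variance s0^2 (d0 may be Inf)
.fit_f_dist <- function(s2, df) {
  ok <- s2 > 0 & is.finite(s2)
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.na(evar) || evar <= 0)
    return(list(d0 = Inf, s0_2 = exp(emean)))
  d0 <- 2 * .trigamma_inverse(evar)
  s0_2 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_2 = s0_2)
}

#' Moderated differential-expression fit
#'
#' Gene-wise weighted least squares on the precision-weighted log2-CPM,
#' followed by empirical-Bayes moderation of the residual variances:
#' the gene-wise variances are modeled as scaled-F draws around a prior
#' (d0, s0^2) estimated by moment-matching the log variances
#' (digamma/trigamma relations, Newton-refined); each posterior variance
#' is the df-weighted blend (d0 s0^2 + d s_g^2) / (d0 + d) and the
#' moderated t carries d0 + d degrees of freedom. Benjamini-Hochberg
#' q-values are attached via [bh_fdr()].
#'
#' @param fit A `voom_fit`.
#' @param contrast Numeric coefficient combination defining the
#'   comparison (default: the last coefficient).
#' @param prior_df `NULL` to estimate d0 (default); `0` turns moderation
#'   off, making the t ordinary WLS; `Inf` forces full shrinkage to
#'   s0^2.
#' @return Object of class `de_result`: data frame (gene, log2fc, t, p,
#'   q) with moderation parameters as attributes `d0`, `s0_2`,
#'   `df_residual`, `posterior_var`, `sigma2`.
#' @export
fit_moderated <- function(fit, contrast = NULL,
                          prior_df = NULL) {
  stopifnot(inherits(fit, "voom_fit"))
  X <- fit$design
  n <- nrow(X); p <- ncol(X)
  if (is.null(contrast)) contrast <- c(rep(0, p - 1), 1)
  G <- nrow(fit$E)
  est <- se2_unit <- s2 <- numeric(G)
  for (g in seq_len(G)) {
    w <- fit$weights[g, ]
    y <- fit$E[g, ]
    xw <- X * sqrt(w)
    yw <- y * sqrt(w)
    qx <- qr(xw)
    beta <- qr.coef(qx, yw)
    resid <- yw - xw %*% beta
    s2[g] <- sum(resid^2) / (n - p)
    xtxinv <- chol2inv(qr.R(qx))
    est[g] <- sum(contrast * beta)
    se2_unit[g] <- drop(t(contrast) %*% xtxinv %*% contrast)
  }
  d <- n - p
  if (is.null(prior_df)) {
    pr <- .fit_f_dist(s2, d)
  } else if (prior_df == 0) {
    pr <- list(d0 = 0, s0_2 = mean(s2))
  } else if (is.infinite(prior_df)) {
    pr <- list(d0 = Inf, s0_2 = .fit_f_dist(s2, d)$s0_2)
  } else {
    pr <- list(d0 = prior_df, s0_2 = .fit_f_dist(s2, d)$s0_2)
  }
  post <- if (is.infinite(pr$d0)) rep(pr$s0_2, G) else
    (pr$d0 * pr$s0_2 + d * s2) / (pr$d0 + d)
  tstat <- est / sqrt(se2_unit * post)
  df_total <- pr$d0 + d
  pval <- 2 * stats::pt(-abs(tstat), df = df_total)
  res <- data.frame(gene = rownames(fit$E), log2fc = est, t = tstat,
                    p = pval, q = bh_fdr(pval), row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(res, class = c("de_result", "data.frame"),
            d0 = pr$d0, s0_2 = pr$s0_2, df_residual = d,
            df_total = df_total, sigma2 = s2, posterior_var = post)
}

#' @export
print.de_result <- function(x, ...) {
  cat("Moderated DE result: ", nrow(x), " genes (prior df ",
      format(attr(x, "d0"), digits = 4), ", residual df ",
      attr(x, "df_residual"), ")\n", sep = "")
  print.data.frame(utils::head(x[order(x$p), ], 10))
  invisible(x)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' q for the i-th smallest p is `min over k >= i of p_(k) * m / k`,
#' capped at 1; ties and the original order are preserved in the output.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

#' Call differentially expressed genes
#'
#' A gene is a DEG iff its q-value is strictly below `fdr` and its
#' |log2 fold-change| strictly exceeds `lfc` (boundary genes with
#' q exactly at `fdr` or |log2FC| exactly at `lfc` are not called).
#'
#' @param res A `de_result` (or data frame with `log2fc` and `q`).
#' @param fdr FDR threshold (default 0.01).
#' @param lfc log2 fold-change threshold (default 1.5).
#' @return The input with a logical `deg` column added.
#' @export
call_degs <- function(res, fdr = 0.01, lfc = 1.5) {
  res$deg <- res$q < fdr & (res$log2fc > lfc | res$log2fc < -lfc)
  res
}

#' Pseudo-bulk differential expression for one cell type
#'
#' The full per-cell-type pipeline: subset the pseudo-bulk matrix to one
#' cell type and the two groups of the contrast, filter low-expressed
#' genes (at least `min_umi` UMIs in at least `min_columns` columns),
#' estimate median-of-ratios size factors on the subset, compute
#' precision weights, fit the moderated model and call DEGs.
#'
#' @param pb A `pseudobulk` object.
#' @param cell_type Cell type to analyze.
#' @param contrast Character of length 2, `c(test, reference)` groups.
#' @param min_umi,min_columns Expression-filter thresholds.
#' @param fdr,lfc DEG thresholds.
#' @return A `de_result` with a `deg` column; the analyzed columns are
#'   attached as attribute `columns`.
#' @export
de_pseudobulk <- function(pb, cell_type, contrast, min_umi = 10,
                          min_columns = 3, fdr = 0.01, lfc = 1.5) {
  stopifnot(inherits(pb, "pseudobulk"))
  sel <- pb$coldata$cell_type == cell_type &
    pb$coldata$group %in% contrast
  if (sum(sel) < 3)
    stop("fewer than 3 pseudo-bulk columns for cell type '", cell_type, "'")
  B <- pb$counts[, sel, drop = FALSE]
  grp <- pb$coldata$group[sel]
  ds <- design_two_group(grp, contrast)
  B <- B[, ds$use, drop = FALSE]
  genes <- filter_low_expression(B, min_umi, min_columns)
  B <- B[genes, , drop = FALSE]
  s <- estimate_size_factors(B)
  vf <- voom_weights(B, s = s, design = ds$design)
  res <- fit_moderated(vf, contrast = ds$contrast)
  res <- call_degs(res, fdr = fdr, lfc = lfc)
  attr(res, "columns") <- colnames(B)
  res
}

#' DEG counts per cell type for one contrast
#'
#' Runs [de_pseudobulk()] for every cell type with enough columns and
#' tabulates the number of DEGs per type — the per-cell-type DEG
#' bar-plot statistic.
#'
#' @param pb A `pseudobulk` object.
#' @param contrast Character of length 2, `c(test, reference)`.
#' @param ... Passed to [de_pseudobulk()].
#' @return Data frame: cell_type, n_genes_tested, n_deg (types whose
#'   analysis is infeasible, e.g. too few columns, are reported with NA).
#' @export
deg_counts_by_cell_type <- function(pb, contrast, ...) {
  types <- sort(unique(pb$coldata$cell_type))
  rows <- lapply(types, function(ty) {
    res <- tryCatch(de_pseudobulk(pb, ty, contrast, ...),
                    error = function(e) NULL)
    if (is.null(res))
      data.frame(cell_type = ty, n_genes_tested = NA_integer_,
                 n_deg = NA_integer_)
    else
      data.frame(cell_type = ty, n_genes_tested = nrow(res),
                 n_deg = sum(res$deg))
  })
  do.call(rbind, rows)
}
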