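#' Load a UMI count matrix from MTX or dense TSV
#'
#' Reads either a MatrixMarket triplet file (with companion `genes.tsv`
#' and `barcodes.tsv` in the same directory, 10x-style) or a dense TSV
#' with gene identifiers in the first column and cell identifiers in the
#' header. Entries must be non-negative integers. Duplicate gene symbols
#' are disambiguated deterministically with `.1`, `.2`, ... suffixes in
#' file order, with a warning.
#'
#' @param path Path to a `.mtx` file, a directory containing
#'   `matrix.mtx`/`genes.tsv`/`barcodes.tsv`, or a dense TSV.
#' @return A sparse `dgCMatrix`, genes x cells.
#' @export
load_counts <- function(path) {
  if (dir.exists(path)) {
    mtx <- file.path(path, "matrix.mtx")
    if (!file.exists(mtx)) stop("no matrix.mtx in directory ", path)
    return(load_counts(mtx))
  }
  if (grepl("\\.mtx$", path)) {
    m <- tryCatch(Matrix::readMM(path),
                  error = function(e) stop("malformed MTX file ", path, ": ",
                                           conditionMessage(e)))
    m <- methods::as(m, "CsparseMatrix")
    d <- dirname(path)
    genes <- readLines(file.path(d, "genes.tsv"))
    barcodes <- readLines(file.path(d, "barcodes.tsv"))
    # 10x genes.tsv may carry id<TAB>symbol; keep the first field
    genes <- vapply(strsplit(genes, "\t", fixed = TRUE), `[[`, "", 1)
    if (length(genes) != nrow(m) || length(barcodes) != ncol(m))
      stop("genes/barcodes do not match matrix dimensions")
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             row.names = NULL, check.names = FALSE,
                             stringsAsFactors = FALSE)
    genes <- as.character(tab[[1]])
    m <- as.matrix(tab[, -1, drop = FALSE])
    barcodes <- colnames(m)
    m <- methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
  }
  .validate_counts(m, path)
  if (anyDuplicated(genes)) {
    warning("duplicate gene identifiers disambiguated with .1, .2 suffixes")
    genes <- make.unique(genes, sep = ".")
  }
  dimnames(m) <- list(genes, barcodes)
  m
}

.validate_counts <- function(m, path = "<matrix>") {
  if (length(m@x)) {
    bad <- which(m@x < 0 | m@x != round(m@x))
    if (length(bad)) {
      i <- bad[1]
      col <- sum(m@p < i)
      stop("non-integer or negative entry in ", path, " (gene row ",
           m@i[i] + 1, ", column ", col, "): ", m@x[i])
    }
  }
  invisible(m)
}

#' Read per-cell metadata
#'
#' @param path TSV with at least `cell_id`, `sample_id`, `group` columns.
#' @return Data frame.
#' @export
read_cell_metadata <- function(path) {
  md <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("cell_id", "sample_id", "group")
  miss <- setdiff(need, names(md))
  if (length(miss))
    stop("metadata is missing required column(s): ",
         paste(miss, collapse = ", "))
  md
}

#' Read gene sets from a GMT file
#'
#' @param path GMT path (name, description, then gene ids, tab-separated).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(length(sets) > 0, !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "gliastate", sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}
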