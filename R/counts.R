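#' Sparse count-matrix container for single-cell data
#'
#' A `counts_matrix` stores a sparse n x m matrix of non-negative integer
#' counts (cells as rows, features as columns) together with unique cell and
#' feature identifiers and a modality tag. RNA data holds UMI counts; the
#' `atac_binarized` modality restricts values to presence/absence (0/1).
#'
#' @param values A matrix or sparse Matrix of non-negative integers,
#'   cells x features. Coerced to a `dgCMatrix`.
#' @param cell_ids Character vector of n unique cell identifiers. Defaults to
#'   the rownames of `values`, or `cell_1, ...` when absent.
#' @param feature_ids Character vector of m unique feature identifiers.
#' @param modality Either `"rna"` or `"atac_binarized"`.
#'
#' @return An object of class `counts_matrix` with elements `values`
#'   (a `dgCMatrix` carrying the ids as dimnames) and `modality`.
#'
#' @examples
#' x <- counts_matrix(rbind(c(0, 5), c(2, 0)))
#' dim(x)
#'
#' @export
counts_matrix <- function(values, cell_ids = NULL, feature_ids = NULL,
                          modality = c("rna", "atac_binarized")) {
  modality <- match.arg(modality)
  values <- as_dgc(values)
  n <- nrow(values)
  m <- ncol(values)
  if (is.null(cell_ids))
    cell_ids <- if (!is.null(rownames(values))) rownames(values)
                else paste0("cell_", seq_len(n))
  if (is.null(feature_ids))
    feature_ids <- if (!is.null(colnames(values))) colnames(values)
                   else paste0("feature_", seq_len(m))
  cell_ids    <- as.character(cell_ids)
  feature_ids <- as.character(feature_ids)
  if (length(cell_ids) != n)
    stop("dimension error: ", length(cell_ids), " cell ids for ", n, " rows")
  if (length(feature_ids) != m)
    stop("dimension error: ", length(feature_ids), " feature ids for ", m,
         " columns")
  if (anyDuplicated(cell_ids))
    stop("cell_ids contain duplicates")
  if (anyDuplicated(feature_ids))
    stop("feature_ids contain duplicates")
  v <- values@x
  if (length(v) > 0) {
    if (any(v < 0))
      stop("validation error: negative values in count matrix")
    if (any(abs(v - round(v)) > 1e-8))
      stop("validation error: non-integral values in count matrix")
    if (modality == "atac_binarized" && any(v != 0 & v != 1))
      stop("validation error: atac_binarized values must be 0 or 1")
  }
  dimnames(values) <- list(cell_ids, feature_ids)
  structure(list(values = values, modality = modality),
            class = "counts_matrix")
}

# Coerce any matrix-like input to a column-compressed sparse matrix.
as_dgc <- function(values) {
  if (is(values, "dgCMatrix"))
    return(values)
  if (is.matrix(values))
    return(as(as(as(Matrix::Matrix(values, sparse = TRUE), "dMatrix"),
                 "generalMatrix"), "CsparseMatrix"))
  as(as(as(values, "dMatrix"), "generalMatrix"), "CsparseMatrix")
}

#' @export
dim.counts_matrix <- function(x) dim(x$values)

#' @export
dimnames.counts_matrix <- function(x) dimnames(x$values)

#' @export
print.counts_matrix <- function(x, ...) {
  cat(sprintf("counts_matrix: %d cells x %d features (%s), %.1f%% nonzero\n",
              nrow(x$values), ncol(x$values), x$modality,
              100 * length(x$values@x) / prod(dim(x$values))))
  invisible(x)
}

#' Cell identifiers of a counts matrix
#' @param x A `counts_matrix`.
#' @return Character vector of cell ids.
#' @export
cell_ids <- function(x) rownames(x$values)

#' Feature identifiers of a counts matrix
#' @param x A `counts_matrix`.
#' @return Character vector of feature ids.
#' @export
feature_ids <- function(x) colnames(x$values)

#' Read a sparse count matrix from disk
#'
#' Reads either MatrixMarket coordinate format (with row/column name sidecar
#' files) or TSV (header row of feature names, first column of cell names).
#' MatrixMarket indices are 1-based on disk per the standard. A 10x-style
#' triplet directory (`matrix.mtx` + `barcodes.tsv` + `features.tsv` or
#' `genes.tsv`, optionally gzipped) is accepted as a dialect when `path` is a
#' directory. Otherwise, for `format = "mtx"`, the sidecars are
#' `<path>.rownames` and `<path>.colnames` (one name per line, matching the
#' matrix axes).
#'
#' @param path Path to the matrix file or 10x-style directory.
#' @param format `"mtx"` or `"tsv"`. Ignored when `path` is a directory.
#' @param transpose If `TRUE`, the file stores features x cells and is
#'   transposed after reading so the result is always cells x features.
#' @param modality Modality tag passed to [counts_matrix()].
#'
#' @return A [counts_matrix()].
#' @export
read_counts <- function(path, format = c("mtx", "tsv"), transpose = FALSE,
                        modality = "rna") {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("input path does not exist: ", path)
  if (dir.exists(path))
    return(read_counts_10x(path, transpose = transpose, modality = modality))
  if (format == "mtx") {
    values <- tryCatch(Matrix::readMM(path), error = function(e)
      stop("parse error in MatrixMarket file ", path, ": ",
           conditionMessage(e)))
    values <- as_dgc(values)
    rn <- read_name_sidecar(paste0(path, ".rownames"))
    cn <- read_name_sidecar(paste0(path, ".colnames"))
    if (length(rn) != nrow(values))
      stop("dimension error: ", length(rn), " row names for matrix with ",
           nrow(values), " rows (", path, ")")
    if (length(cn) != ncol(values))
      stop("dimension error: ", length(cn), " column names for matrix with ",
           ncol(values), " columns (", path, ")")
    dimnames(values) <- list(rn, cn)
  } else {
    dt <- data.table::fread(path, header = TRUE, sep = "\t")
    ids <- as.character(dt[[1]])
    values <- as.matrix(dt[, -1, with = FALSE])
    rownames(values) <- ids
    values <- as_dgc(values)
  }
  if (transpose)
    values <- Matrix::t(values)
  counts_matrix(values, modality = modality)
}

read_name_sidecar <- function(path) {
  if (!file.exists(path)) {
    gz <- paste0(path, ".gz")
    if (file.exists(gz)) path <- gz
    else stop("missing name sidecar file: ", path)
  }
  readLines(path)
}

# 10x-style triplet directory: matrix.mtx (genes/features x barcodes on disk,
# so the matrix is transposed to cells x features unless transpose = FALSE
# is overridden by the caller passing transpose = TRUE meaning already
# cells x rows).
read_counts_10x <- function(path, transpose = FALSE, modality = "rna") {
  pick <- function(names) {
    for (nm in names) {
      p <- file.path(path, nm)
      if (file.exists(p)) return(p)
    }
    stop("missing file in 10x-style directory ", path, ": tried ",
         paste(names, collapse = ", "))
  }
  mtx <- pick(c("matrix.mtx", "matrix.mtx.gz"))
  bc  <- pick(c("barcodes.tsv", "barcodes.tsv.gz"))
  ft  <- pick(c("features.tsv", "features.tsv.gz", "genes.tsv",
                "genes.tsv.gz"))
  values <- as_dgc(Matrix::readMM(mtx))
  barcodes <- readLines(bc)
  feats <- data.table::fread(ft, header = FALSE)[[1]]
  if (length(feats) != nrow(values) || length(barcodes) != ncol(values))
    stop("dimension error: sidecar names do not match matrix dimensions in ",
         path)
  dimnames(values) <- list(feats, barcodes)
  # 10x stores features x barcodes; normalize to cells x features.
  if (!transpose)
    values <- Matrix::t(values)
  counts_matrix(values, modality = modality)
}

#' Write a count matrix to disk
#'
#' Inverse of [read_counts()]. For `format = "mtx"` writes the matrix plus
#' `<path>.rownames` / `<path>.colnames` sidecars.
#'
#' @param x A `counts_matrix`.
#' @param path Output file path.
#' @param format `"mtx"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path, format = c("mtx", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "counts_matrix"))
  if (format == "mtx") {
    Matrix::writeMM(x$values, path)
    writeLines(cell_ids(x), paste0(path, ".rownames"))
    writeLines(feature_ids(x), paste0(path, ".colnames"))
  } else {
    dt <- data.table::data.table(cell_id = cell_ids(x))
    dense <- as.matrix(x$values)
    for (j in seq_len(ncol(dense)))
      data.table::set(dt, j = feature_ids(x)[j], value = dense[, j])
    data.table::fwrite(dt, path, sep = "\t")
  }
  invisible(path)
}

#' Binarize a count matrix
#'
#' Maps every positive count to 1, as is standard practice for single-cell
#' ATAC-seq peak matrices where read counts within a small peak are not a
#' reliable quantitative measure of accessibility. Idempotent.
#'
#' @param x A `counts_matrix`.
#' @return A `counts_matrix` with modality `"atac_binarized"`.
#' @export
binarize <- function(x) {
  stopifnot(inherits(x, "counts_matrix"))
  v <- x$values
  if (length(v@x) > 0) {
    if (any(v@x < 0))
      stop("validation error: negative values cannot be binarized")
    v@x <- as.numeric(v@x > 0)
  }
  v <- Matrix::drop0(v)
  counts_matrix(v, cell_ids(x), feature_ids(x), modality = "atac_binarized")
}

#' Drop invariant and rarely observed features
#'
#' Removes features with no variation across cells (all cells share one
#' identical value, covering all-zero and constant-nonzero columns) and,
#' additionally, features observed (nonzero) in fewer than `min_cells` cells.
#' Retained values are unchanged.
#'
#' @param x A `counts_matrix`.
#' @param min_cells Non-negative integer; a feature must be nonzero in at
#'   least this many cells to be kept (e.g. 20 for the sparse ATAC setting).
#' @param verbose Print a summary of dropped features.
#' @return A `counts_matrix` with a subset of the features.
#' @export
filter_features <- function(x, min_cells = 0, verbose = FALSE) {
  stopifnot(inherits(x, "counts_matrix"), min_cells >= 0)
  v <- x$values
  n <- nrow(v)
  nnz <- Matrix::colSums(v != 0)
  # constant column: all zero, or nonzero in every cell with a single
  # distinct value
  maxs <- apply_by_col_max(v)
  mins_nz <- apply_by_col_min_nz(v)
  const_zero <- nnz == 0
  const_nonzero <- (nnz == n) & (maxs == mins_nz) & n > 1
  if (n == 1) # a single cell makes every feature invariant-free except zeros
    const_nonzero <- rep(FALSE, ncol(v))
  novar <- const_zero | const_nonzero
  rare <- nnz < min_cells
  keep <- !(novar | rare)
  if (verbose)
    message(sprintf(
      "filter_features: dropping %d all-zero, %d constant-nonzero, %d rare (< %d cells) of %d features",
      sum(const_zero), sum(const_nonzero), sum(rare & !novar), min_cells,
      ncol(v)))
  if (!any(keep))
    stop("empty result: no features survive filtering")
  counts_matrix(v[, keep, drop = FALSE], cell_ids(x),
                feature_ids(x)[keep], modality = x$modality)
}

apply_by_col_max <- function(v) {
  out <- numeric(ncol(v))
  dp <- diff(v@p)
  splits <- rep.int(seq_len(ncol(v)), dp)
  if (length(v@x) > 0) {
    mx <- vapply(split(v@x, factor(splits, levels = seq_len(ncol(v)))),
                 function(z) if (length(z) == 0) 0 else max(z), numeric(1))
    out <- as.numeric(mx)
  }
  out
}

apply_by_col_min_nz <- function(v) {
  dp <- diff(v@p)
  splits <- rep.int(seq_len(ncol(v)), dp)
  vapply(split(v@x, factor(splits, levels = seq_len(ncol(v)))),
         function(z) if (length(z) == 0) Inf else min(z), numeric(1))
}

#' Per-cell size factors (total counts)
#'
#' The size factor of cell i is its total count, s_i = sum_j x_ij. For
#' binarized accessibility data this is the number of accessible peaks.
#' Cells with zero total count are rejected: a Poisson rate cannot be scaled
#' by a zero size factor, and silently dropping cells would desynchronize
#' the matrix from the membership matrix. Use [filter_features()] upstream or
#' drop such cells explicitly.
#'
#' @param x A `counts_matrix`.
#' @return Numeric vector of n positive size factors, named by cell id.
#' @export
compute_size_factors <- function(x) {
  stopifnot(inherits(x, "counts_matrix"))
  s <- Matrix::rowSums(x$values)
  if (any(s == 0))
    stop("all-zero cells (size factor would be 0): ",
         paste(utils::head(cell_ids(x)[s == 0], 10), collapse = ", "))
  names(s) <- cell_ids(x)
  s
}
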