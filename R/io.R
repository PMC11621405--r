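#' @useDynLib nichecov, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats prcomp sd cor predict rnorm runif rnbinom
#'   pt setNames aggregate complete.cases
#' @importFrom utils head
NULL

#' Construct a cell-by-gene count matrix
#'
#' The basic container for both modalities: a (possibly sparse) cells x genes
#' matrix of non-negative counts with unique cell and gene identifiers.
#'
#' @param values numeric or `Matrix` sparse matrix, cells in rows, genes in
#'   columns; entries must be non-negative and finite.
#' @param cell_ids,gene_ids character vectors of unique identifiers matching
#'   the matrix dimensions. If `NULL`, taken from `dimnames(values)`.
#' @return A `CountMatrix` object (the matrix with validated dimnames).
#' @export
count_matrix <- function(values, cell_ids = NULL, gene_ids = NULL) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (is.null(cell_ids)) cell_ids <- rownames(values)
  if (is.null(gene_ids)) gene_ids <- colnames(values)
  if (is.null(cell_ids) || is.null(gene_ids))
    stop("cell_ids and gene_ids are required (or set as dimnames)")
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != nrow(values))
    stop("length(cell_ids) != number of rows")
  if (length(gene_ids) != ncol(values))
    stop("length(gene_ids) != number of columns")
  if (anyDuplicated(cell_ids))
    stop("duplicate cell ids: ", paste(head(unique(
      cell_ids[duplicated(cell_ids)]), 3), collapse = ", "))
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids: ", paste(head(unique(
      gene_ids[duplicated(gene_ids)]), 3), collapse = ", "))
  if (min_value(values) < 0) stop("negative counts are not allowed")
  dimnames(values) <- list(cell_ids, gene_ids)
  # sparse inputs stay native Matrix objects (S4); dense matrices carry the
  # CountMatrix S3 tag
  if (!inherits(values, "sparseMatrix"))
    class(values) <- c("CountMatrix", class(values))
  values
}

is_count_matrix <- function(x) {
  inherits(x, "CountMatrix") || inherits(x, "sparseMatrix")
}

min_value <- function(m) {
  if (inherits(m, "sparseMatrix")) {
    x <- m@x
    if (length(x) == 0) 0 else min(min(x), 0)
  } else min(m)
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d cells x %d genes (%s)\n",
              nrow(x), ncol(x),
              if (inherits(x, "sparseMatrix")) "sparse" else "dense"))
  invisible(x)
}

strip_cm <- function(x) {
  if (inherits(x, "CountMatrix")) {
    cls <- setdiff(class(x), "CountMatrix")
    class(x) <- if (length(cls)) cls else NULL
  }
  x
}

#' Read a count matrix from MatrixMarket or delimited text
#'
#' MatrixMarket input expects genes in rows or cells in rows of the `.mtx`
#' file together with sidecar id files `<prefix>cells.tsv` and
#' `<prefix>genes.tsv` (one id per line); the orientation is resolved from the
#' id counts. Delimited input expects a header row of gene ids and a first
#' column of cell ids.
#'
#' @param path path to the matrix file.
#' @param format one of `"mtx"`, `"csv"`, `"tsv"`; default guessed from the
#'   file extension.
#' @param cells_file,genes_file id sidecar files for `mtx` input; defaults are
#'   `cells.tsv` / `genes.tsv` next to the matrix file.
#' @return A [count_matrix()]; MatrixMarket input stays sparse.
#' @export
load_counts <- function(path, format = c("auto", "mtx", "csv", "tsv"),
                        cells_file = NULL, genes_file = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     mtx = "mtx", csv = "csv", tsv = "tsv", txt = "tsv",
                     stop("cannot guess format from extension: ", path))
  }
  if (format == "mtx") {
    dir <- dirname(path)
    if (is.null(cells_file)) cells_file <- file.path(dir, "cells.tsv")
    if (is.null(genes_file)) genes_file <- file.path(dir, "genes.tsv")
    if (!file.exists(cells_file) || !file.exists(genes_file))
      stop("mtx input needs id sidecar files: ", cells_file, ", ", genes_file)
    m <- tryCatch(Matrix::readMM(path),
                  error = function(e) stop("malformed MatrixMarket file '",
                                           path, "': ", conditionMessage(e)))
    cells <- readLines(cells_file)
    genes <- readLines(genes_file)
    if (nrow(m) == length(genes) && ncol(m) == length(cells)) {
      m <- Matrix::t(m)
    } else if (!(nrow(m) == length(cells) && ncol(m) == length(genes))) {
      stop("matrix dimensions ", nrow(m), "x", ncol(m),
           " do not match id files (", length(cells), " cells, ",
           length(genes), " genes)")
    }
    m <- methods::as(methods::as(m, "dMatrix"), "CsparseMatrix")
    return(count_matrix(m, cells, genes))
  }
  sep <- if (format == "csv") "," else "\t"
  dt <- tryCatch(
    data.table::fread(path, sep = sep, header = TRUE, data.table = FALSE),
    error = function(e) stop("parse error in '", path, "': ",
                             conditionMessage(e)))
  cells <- as.character(dt[[1]])
  vals <- as.matrix(dt[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  if (anyNA(vals)) {
    bad <- which(rowSums(is.na(vals)) > 0)[1]
    stop("parse error in '", path, "': non-numeric entry near data line ", bad)
  }
  count_matrix(vals, cells, colnames(dt)[-1])
}

#' Write a count matrix
#'
#' Sparse matrices go to MatrixMarket with `cells.tsv`/`genes.tsv` sidecars;
#' dense matrices to delimited text with gene-id header and cell-id first
#' column. [load_counts()] on the result reproduces the input.
#'
#' @param cm a [count_matrix()].
#' @param path output file (`.mtx`, `.csv` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_counts <- function(cm, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "mtx") {
    Matrix::writeMM(methods::as(methods::as(strip_cm(cm), "dMatrix"),
                                "CsparseMatrix"), path)
    writeLines(rownames(cm), file.path(dirname(path), "cells.tsv"))
    writeLines(colnames(cm), file.path(dirname(path), "genes.tsv"))
  } else {
    sep <- if (ext == "csv") "," else "\t"
    df <- data.frame(cell_id = rownames(cm),
                     as.matrix(strip_cm(cm)), check.names = FALSE)
    data.table::fwrite(df, path, sep = sep)
  }
  invisible(path)
}

#' Bundle spatial counts with centroid coordinates
#'
#' @param counts a [count_matrix()].
#' @param coords data frame or matrix with one row per cell giving 2D cell
#'   centroids; either columns `(cell_id, x, y)` or a 2-column matrix in the
#'   row order of `counts`. Units are those of the input file; all distance
#'   parameters downstream are in the same units.
#' @param labels optional per-cell cell-type labels (named by cell id or in
#'   row order); the sentinel `"NM"` marks unmapped cells.
#' @return A `SpatialDataset` (list with `counts`, `coords`, `labels`).
#' @export
spatial_dataset <- function(counts, coords, labels = NULL) {
  stopifnot(is_count_matrix(counts))
  coords <- normalize_coords(coords, rownames(counts))
  if (!all(is.finite(as.matrix(coords[, c("x", "y")]))))
    stop("coordinates must be finite")
  if (nrow(coords) != nrow(counts))
    stop("coords rows (", nrow(coords), ") != cells (", nrow(counts), ")")
  labels <- normalize_labels(labels, rownames(counts))
  structure(list(counts = counts, coords = coords, labels = labels),
            class = "SpatialDataset")
}

normalize_coords <- function(coords, cell_ids) {
  if (is.matrix(coords)) {
    coords <- data.frame(cell_id = cell_ids, x = coords[, 1], y = coords[, 2])
  } else {
    coords <- as.data.frame(coords)
    if (!all(c("cell_id", "x", "y") %in% names(coords)))
      stop("coords needs columns cell_id, x, y")
    coords$cell_id <- as.character(coords$cell_id)
    idx <- match(cell_ids, coords$cell_id)
    if (anyNA(idx)) stop("coords missing cells: ",
                         paste(head(cell_ids[is.na(idx)], 3), collapse = ", "))
    coords <- coords[idx, c("cell_id", "x", "y")]
  }
  rownames(coords) <- NULL
  coords
}

normalize_labels <- function(labels, cell_ids) {
  if (is.null(labels)) return(NULL)
  if (!is.null(names(labels))) {
    idx <- match(cell_ids, names(labels))
    if (anyNA(idx)) stop("labels missing cells")
    labels <- labels[idx]
  } else if (length(labels) != length(cell_ids)) {
    stop("labels length != cell count")
  }
  setNames(as.character(labels), cell_ids)
}

#' @export
print.SpatialDataset <- function(x, ...) {
  cat(sprintf("SpatialDataset: %d cells x %d genes%s\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$labels)) "" else
                sprintf(", %d labeled (%d NM)", sum(x$labels != "NM"),
                        sum(x$labels == "NM"))))
  invisible(x)
}

#' Bundle reference counts with cluster labels
#'
#' @param counts a [count_matrix()].
#' @param cluster_labels per-cell cell-type labels (named by cell id or in row
#'   order); every cell must be labeled and at least two distinct types
#'   present.
#' @return A `ReferenceDataset` (list with `counts`, `cluster_labels`).
#' @export
reference_dataset <- function(counts, cluster_labels) {
  stopifnot(is_count_matrix(counts))
  labels <- normalize_labels(cluster_labels, rownames(counts))
  if (anyNA(labels) || any(!nzchar(labels)))
    stop("every reference cell needs a non-empty label")
  if (length(unique(labels)) < 2)
    stop("reference needs at least 2 distinct cell types")
  structure(list(counts = counts, cluster_labels = labels),
            class = "ReferenceDataset")
}

#' @export
print.ReferenceDataset <- function(x, ...) {
  cat(sprintf("ReferenceDataset: %d cells x %d genes, %d cell types\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$cluster_labels))))
  invisible(x)
}

#' Restrict both modalities to shared genes and drop low-count cells
#'
#' Genes are matched by exact, case-sensitive id; the canonical order of the
#' intersection is the reference gene order. Cells whose total transcript
#' count over the shared genes falls below `min_count` are removed (default 5,
#' the standard low-quality-cell filter for imaging-based platforms).
#'
#' @param sp a [spatial_dataset()].
#' @param ref a [reference_dataset()].
#' @param min_count minimum total transcript count per cell; cells below are
#'   dropped from either modality.
#' @return List with elements `sp` and `ref`, both restricted to the shared
#'   gene set in identical (reference) order.
#' @export
align_shared_genes <- function(sp, ref, min_count = 5) {
  stopifnot(inherits(sp, "SpatialDataset"), inherits(ref, "ReferenceDataset"),
            min_count >= 0)
  shared <- intersect(colnames(ref$counts), colnames(sp$counts))
  shared <- colnames(ref$counts)[colnames(ref$counts) %in% shared]
  if (length(shared) == 0) stop("no shared genes between modalities")
  sub_counts <- function(cm, genes) {
    out <- cm[, genes, drop = FALSE]
    keep <- rowSums2(out) >= min_count
    if (!any(keep)) stop("all cells removed by min_count = ", min_count)
    out[keep, , drop = FALSE]
  }
  spc <- sub_counts(sp$counts, shared)
  refc <- sub_counts(ref$counts, shared)
  keep_sp <- rownames(spc)
  keep_ref <- rownames(refc)
  sp_out <- spatial_dataset(
    count_matrix(spc),
    sp$coords[match(keep_sp, sp$coords$cell_id), , drop = FALSE],
    if (is.null(sp$labels)) NULL else sp$labels[keep_sp])
  ref_out <- reference_dataset(count_matrix(refc), ref$cluster_labels[keep_ref])
  list(sp = sp_out, ref = ref_out)
}

rowSums2 <- function(m) {
  if (inherits(m, "sparseMatrix")) Matrix::rowSums(m) else rowSums(m)
}
colSums2 <- function(m) {
  if (inherits(m, "sparseMatrix")) Matrix::colSums(m) else colSums(m)
}

#' Read a coordinates table (cell_id, x, y)
#' @param path CSV/TSV file with columns `cell_id`, `x`, `y`.
#' @return data frame with those columns.
#' @export
load_coords <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  if (!all(c("cell_id", "x", "y") %in% names(df)))
    stop("coordinates file needs columns cell_id, x, y")
  df$cell_id <- as.character(df$cell_id)
  df[, c("cell_id", "x", "y")]
}

#' Read a labels table (cell_id, label)
#' @param path CSV/TSV file with columns `cell_id`, `label`.
#' @return named character vector of labels.
#' @export
load_labels <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  if (!all(c("cell_id", "label") %in% names(df)))
    stop("labels file needs columns cell_id, label")
  setNames(as.character(df$label), as.character(df$cell_id))
}

#' Export a result table to delimited text
#'
#' Writes any of the package's result data frames (annotations, classifier
#' coefficients, covariation tables, LR candidates, ...) or a named numeric
#' matrix with full precision; [import_table()] reads it back with values
#' reproduced to better than 1e-12.
#'
#' @param obj data frame, or matrix with dimnames (exported long or wide).
#' @param path output path; extension selects the separator
#'   (`.csv` vs `.tsv`).
#' @return `path`, invisibly.
#' @export
export_table <- function(obj, path) {
  sep <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
  if (is.matrix(obj)) {
    obj <- data.frame(id = rownames(obj), obj, check.names = FALSE)
  }
  if (!is.data.frame(obj)) stop("export_table expects a data frame or matrix")
  ok <- tryCatch({
    data.table::fwrite(obj, path, sep = sep); TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write to: ", path)
  invisible(path)
}

#' Read back a table written by [export_table()]
#' @param path file written by [export_table()].
#' @return data frame.
#' @export
import_table <- function(path) {
  data.table::fread(path, data.table = FALSE)
}
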