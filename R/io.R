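#' Construct an expression matrix object
#'
#' Bundles a cells x genes expression matrix with gene/cell identifiers and a
#' cell metadata table. All downstream steps (SVD decorrelation, sparsity
#' z-scoring, bootstrapping) operate on this container.
#'
#' @param values numeric matrix or `Matrix` sparse matrix, cells in rows and
#'   genes in columns; entries must be finite and non-negative.
#' @param gene_ids character vector of unique gene identifiers (length = ncol).
#' @param cell_ids character vector of unique cell identifiers (length = nrow).
#' @param cell_meta data.frame with one row per cell; must contain a `cell_id`
#'   column covering every cell and a non-missing `batch_id` column (the unit
#'   resampled during bootstrapping, typically sample = individual x region).
#' @param normalized logical flag: `FALSE` for raw counts, `TRUE` after
#'   [normalize_cells()].
#' @return an object of class `scd_expr`.
#' @export
expr_matrix <- function(values, gene_ids, cell_ids, cell_meta,
                        normalized = FALSE) {
  values <- methods::as(methods::as(Matrix::Matrix(values, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  n <- nrow(values); g <- ncol(values)
  if (n < 2L || g < 2L)
    stop("need at least 2 cells and 2 genes (got ", n, " x ", g, ")")
  if (length(gene_ids) != g || length(cell_ids) != n)
    stop("id lengths do not match matrix dimensions")
  if (anyDuplicated(gene_ids)) stop("duplicate gene_ids")
  if (anyDuplicated(cell_ids)) stop("duplicate cell_ids")
  if (any(!is.finite(values@x))) stop("non-finite values in matrix")
  if (any(values@x < 0)) stop("negative values in matrix")
  cell_meta <- as.data.frame(cell_meta)
  if (!"cell_id" %in% names(cell_meta)) stop("cell_meta must have a cell_id column")
  if (!"batch_id" %in% names(cell_meta)) stop("cell_meta must have a batch_id column")
  missing_meta <- setdiff(cell_ids, cell_meta$cell_id)
  if (length(missing_meta))
    stop("cells missing from metadata: ", paste(utils::head(missing_meta, 5), collapse = ", "))
  cell_meta <- cell_meta[match(cell_ids, cell_meta$cell_id), , drop = FALSE]
  rownames(cell_meta) <- NULL
  if (any(is.na(cell_meta$batch_id))) stop("batch_id contains missing values")
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(list(values = values, gene_ids = as.character(gene_ids),
                 cell_ids = as.character(cell_ids), cell_meta = cell_meta,
                 normalized = isTRUE(normalized)),
            class = "scd_expr")
}

#' @export
print.scd_expr <- function(x, ...) {
  cat(sprintf("<scd_expr> %d cells x %d genes (%s), %d nonzeros, %d batches\n",
              nrow(x$values), ncol(x$values),
              if (x$normalized) "normalized" else "raw counts",
              length(x$values@x), length(unique(x$cell_meta$batch_id))))
  invisible(x)
}

#' @export
dim.scd_expr <- function(x) dim(x$values)

#' Read an expression matrix with cell metadata
#'
#' Supports MatrixMarket coordinate triplets with companion `features.tsv` /
#' `barcodes.tsv` files (10x-style; gene-rows or cell-rows orientation is
#' auto-detected from the companion file lengths), or a dense delimited table
#' with a header row of gene ids and a first column of cell ids.
#'
#' @param path path to the `.mtx` file or dense TSV.
#' @param format `"mtx"` or `"dense_tsv"`.
#' @param meta_path path to a cell metadata TSV (header row; `cell_id` and
#'   `batch_id` columns required).
#' @param features_path,barcodes_path companion id files for `format = "mtx"`;
#'   default to `features.tsv` / `barcodes.tsv` next to `path`.
#' @param normalized logical, whether the stored values are already normalized.
#' @return an `scd_expr` object.
#' @export
read_matrix <- function(path, format = c("mtx", "dense_tsv"), meta_path,
                        features_path = NULL, barcodes_path = NULL,
                        normalized = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("matrix file not found: ", path)
  if (!file.exists(meta_path)) stop("metadata file not found: ", meta_path)
  meta <- as.data.frame(data.table::fread(meta_path, sep = "\t",
                                          colClasses = list(character = "cell_id")))
  if (format == "mtx") {
    dir <- dirname(path)
    if (is.null(features_path)) features_path <- file.path(dir, "features.tsv")
    if (is.null(barcodes_path)) barcodes_path <- file.path(dir, "barcodes.tsv")
    for (f in c(features_path, barcodes_path))
      if (!file.exists(f)) stop("companion file not found: ", f)
    m <- Matrix::readMM(path)
    genes <- data.table::fread(features_path, header = FALSE, sep = "\t")[[1]]
    cells <- data.table::fread(barcodes_path, header = FALSE, sep = "\t")[[1]]
    if (nrow(m) == length(genes) && ncol(m) == length(cells)) {
      m <- Matrix::t(m)                      # genes-as-rows layout
    } else if (nrow(m) != length(cells) || ncol(m) != length(genes)) {
      stop(sprintf("matrix is %d x %d but features/barcodes have %d / %d entries",
                   nrow(m), ncol(m), length(genes), length(cells)))
    }
    expr_matrix(m, genes, cells, meta, normalized = normalized)
  } else {
    tab <- data.table::fread(path, sep = "\t", header = TRUE)
    cells <- as.character(tab[[1]])
    vals <- as.matrix(tab[, -1, drop = FALSE])
    expr_matrix(vals, colnames(vals), cells, meta, normalized = normalized)
  }
}

#' Write an expression matrix and metadata to disk
#'
#' Inverse of [read_matrix()]; round trips are lossless for values, ids and
#' metadata.
#'
#' @param x an `scd_expr` object.
#' @param dir output directory (created if absent).
#' @param format `"mtx"` (writes `matrix.mtx`, `features.tsv`, `barcodes.tsv`,
#'   `meta.tsv`) or `"dense_tsv"` (writes `matrix.tsv`, `meta.tsv`).
#' @return invisibly, the paths written.
#' @export
write_matrix <- function(x, dir, format = c("mtx", "dense_tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "scd_expr"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta_path <- file.path(dir, "meta.tsv")
  data.table::fwrite(x$cell_meta, meta_path, sep = "\t")
  if (format == "mtx") {
    mp <- file.path(dir, "matrix.mtx")
    Matrix::writeMM(Matrix::t(x$values), mp)  # genes-as-rows, 10x convention
    writeLines(x$gene_ids, file.path(dir, "features.tsv"))
    writeLines(x$cell_ids, file.path(dir, "barcodes.tsv"))
    invisible(c(mp, file.path(dir, c("features.tsv", "barcodes.tsv")), meta_path))
  } else {
    mp <- file.path(dir, "matrix.tsv")
    tab <- data.table::data.table(cell_id = x$cell_ids)
    tab <- cbind(tab, as.data.table_dense(x$values))
    data.table::fwrite(tab, mp, sep = "\t")
    invisible(c(mp, meta_path))
  }
}

# dense conversion helper kept separate so fwrite sees plain columns
as.data.table_dense <- function(m) {
  data.table::as.data.table(as.matrix(m))
}

#' Library-size normalize and log transform
#'
#' Scales each cell to a common total count and applies `log(1 + x)` (CP10K /
#' log1p by default). Cells with zero total count are dropped with a warning.
#'
#' @param x an `scd_expr` object holding raw counts.
#' @param target_sum per-cell total after scaling (default 10000).
#' @param force set `TRUE` to renormalize an already-normalized object.
#' @return a normalized `scd_expr`.
#' @export
normalize_cells <- function(x, target_sum = 1e4, force = FALSE) {
  stopifnot(inherits(x, "scd_expr"))
  if (x$normalized && !force)
    stop("input is already normalized; use force = TRUE to renormalize")
  totals <- Matrix::rowSums(x$values)
  keep <- totals > 0
  if (!all(keep)) {
    warning(sum(!keep), " zero-count cell(s) dropped during normalization")
    x <- subset_cells(x, which(keep))
    totals <- totals[keep]
  }
  v <- x$values
  sf <- target_sum / totals
  v@x <- v@x * sf[v@i + 1L]   # column-major storage: @i holds 0-based row index
  v@x <- log1p(v@x)
  x$values <- v
  x$normalized <- TRUE
  x
}

#' Subset cells of an expression matrix
#' @param x an `scd_expr` object.
#' @param idx integer or logical index over cells.
#' @return an `scd_expr` restricted to the selected cells.
#' @export
subset_cells <- function(x, idx) {
  expr_matrix(x$values[idx, , drop = FALSE], x$gene_ids,
              x$cell_ids[idx], x$cell_meta[idx, , drop = FALSE],
              normalized = x$normalized)
}

#' Subset genes of an expression matrix
#' @param x an `scd_expr` object.
#' @param idx integer or logical index over genes.
#' @return an `scd_expr` restricted to the selected genes.
#' @export
subset_genes <- function(x, idx) {
  expr_matrix(x$values[, idx, drop = FALSE], x$gene_ids[idx],
              x$cell_ids, x$cell_meta, normalized = x$normalized)
}

#' Per-gene sparsity (fraction of expressing cells)
#'
#' @param x an `scd_expr` object.
#' @return list with `fraction_expressed` (in `[0, 1]`) and `log10_sparsity`
#'   (`-Inf` for never-expressed genes, which must be filtered before use).
#' @export
compute_sparsity <- function(x) {
  stopifnot(inherits(x, "scd_expr"))
  frac <- Matrix::colSums(x$values > 0) / nrow(x$values)
  structure(list(fraction_expressed = unname(frac),
                 log10_sparsity = unname(log10(frac)),
                 gene_ids = x$gene_ids),
            class = "scd_sparsity")
}

#' Filter genes by expressed fraction
#'
#' Retains genes expressed in strictly more than `min_fraction` of cells
#' (default 5 percent), preserving gene order.
#'
#' @param x an `scd_expr` object.
#' @param sp sparsity from [compute_sparsity()] on `x` (computed if missing).
#' @param min_fraction retention threshold (strict `>`).
#' @return filtered `scd_expr`.
#' @export
filter_genes <- function(x, sp = compute_sparsity(x), min_fraction = 0.05) {
  stopifnot(inherits(x, "scd_expr"))
  if (length(sp$fraction_expressed) != length(x$gene_ids))
    stop("sparsity was not computed on this matrix")
  keep <- sp$fraction_expressed > min_fraction
  if (!any(keep))
    stop("no genes expressed in more than ", min_fraction * 100,
         "% of cells; lower min_fraction or check the input matrix")
  subset_genes(x, keep)
}
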