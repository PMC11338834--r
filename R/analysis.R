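#' Score modules per cell
#'
#' The score of module `m` in cell `c` is the mean normalized expression of
#' the module's member genes in that cell. A background-corrected variant
#' subtracts the mean score of a size-matched random background gene set
#' drawn from the same matrix (seeded).
#'
#' @param x a normalized `scd_expr`; module genes missing from `x` are
#'   dropped with a warning.
#' @param modules an `scd_modules` object.
#' @param background_correct subtract a size-matched random background mean.
#' @param seed seed for background gene sampling.
#' @return object of class `scd_scores`: `scores` (cells x modules matrix),
#'   `cell_ids`, `cell_meta`.
#' @export
score_modules <- function(x, modules, background_correct = FALSE, seed = 1L) {
  stopifnot(inherits(x, "scd_expr"), inherits(modules, "scd_modules"))
  if (!length(modules$modules)) stop("no reported modules to score")
  mats <- lapply(names(modules$modules), function(m) {
    gs <- modules$modules[[m]]
    present <- intersect(gs, x$gene_ids)
    if (length(present) < length(gs))
      warning(length(gs) - length(present), " gene(s) of ", m,
              " absent from the matrix; dropped")
    if (!length(present)) return(rep(NaN, nrow(x$values)))
    sc <- Matrix::rowMeans(x$values[, present, drop = FALSE])
    if (background_correct) {
      bg <- withr::with_seed(as.integer(seed) + match(m, names(modules$modules)), {
        sample(setdiff(x$gene_ids, present), min(length(present),
               length(x$gene_ids) - length(present)))
      })
      sc <- sc - Matrix::rowMeans(x$values[, bg, drop = FALSE])
    }
    as.numeric(sc)
  })
  scores <- do.call(cbind, mats)
  dimnames(scores) <- list(x$cell_ids, names(modules$modules))
  structure(list(scores = scores, cell_ids = x$cell_ids,
                 cell_meta = x$cell_meta),
            class = "scd_scores")
}

# upper-tail hypergeometric: P(X >= q) drawing n_draw from K successes in N
hyper_upper <- function(q, K, N, n_draw) {
  stats::phyper(q - 1L, K, N - K, n_draw, lower.tail = FALSE)
}

#' Covariate enrichment of module-high cells
#'
#' Cells with a module score above `mean + sd_mult * sd` (over all scored
#' cells) are the module's "high" set; for each level of the covariate a
#' hypergeometric upper-tail test asks whether high cells are enriched in
#' that level. Rows with `p < p_thresh` are flagged enriched.
#'
#' @param scores an `scd_scores` object.
#' @param covariate name of a `cell_meta` column, or a vector over cells.
#' @param sd_mult multiplier on the s.d. defining high cells (default 1).
#' @param p_thresh enrichment flag threshold (default 0.001).
#' @return data.frame with module_id, covariate level, overlap, expected,
#'   p_value, adj_p (BH across all rows), enriched flag.
#' @export
enrich_covariate <- function(scores, covariate, sd_mult = 1, p_thresh = 1e-3) {
  stopifnot(inherits(scores, "scd_scores"))
  cov_vals <- if (is.character(covariate) && length(covariate) == 1L) {
    if (!covariate %in% names(scores$cell_meta))
      stop("covariate column not found: ", covariate)
    scores$cell_meta[[covariate]]
  } else covariate
  if (length(cov_vals) != nrow(scores$scores))
    stop("covariate length does not match number of cells")
  if (anyNA(cov_vals)) stop("covariate contains missing values")
  cov_vals <- as.character(cov_vals)
  levels <- sort(unique(cov_vals))
  N <- nrow(scores$scores)
  rows <- list()
  for (m in colnames(scores$scores)) {
    sc <- scores$scores[, m]
    high <- which(sc > mean(sc) + sd_mult * stats::sd(sc))
    for (lv in levels) {
      in_lv <- which(cov_vals == lv)
      if (!length(in_lv)) next
      q <- length(intersect(high, in_lv))
      p <- hyper_upper(q, length(in_lv), N, length(high))
      rows[[length(rows) + 1L]] <- data.frame(
        module_id = m, level = lv, n_high = length(high),
        n_level = length(in_lv), overlap = q,
        expected = length(high) * length(in_lv) / N,
        p_value = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$adj_p <- stats::p.adjust(out$p_value, method = "BH")
  out$enriched <- out$p_value < p_thresh
  out
}

#' Module-module correlation network on aggregated scores
#'
#' Scores are averaged within groups defined by `group_keys` (for example
#' subtype x sample), shifted to positivity and logged
#' (`log(score - min + 1)`), and every module pair is tested for positive
#' Pearson correlation (one-sided). Edges with BH-adjusted `p < alpha` are
#' kept.
#'
#' @param scores an `scd_scores` object.
#' @param group_keys character vector of `cell_meta` columns to aggregate by.
#' @param alpha adjusted-p cutoff (default 0.01).
#' @return data.frame of edges: module_a, module_b, r, p_value, adj_p.
#'   Constant aggregated columns are excluded with a warning.
#' @export
module_module_network <- function(scores, group_keys, alpha = 0.01) {
  stopifnot(inherits(scores, "scd_scores"))
  if (!all(group_keys %in% names(scores$cell_meta)))
    stop("group_keys must name cell_meta columns")
  key <- do.call(paste, c(scores$cell_meta[group_keys], sep = "\r"))
  groups <- unique(key)
  if (length(groups) < 3L) stop("need at least 3 aggregation groups")
  agg <- rowsum(scores$scores, key)
  agg <- agg / as.integer(table(key)[rownames(agg)])
  lg <- log(agg - min(agg) + 1)
  keep <- apply(lg, 2, function(v) stats::sd(v) > 0)
  if (!all(keep))
    warning(sum(!keep), " module(s) constant after aggregation; excluded")
  lg <- lg[, keep, drop = FALSE]
  mods <- colnames(lg)
  if (length(mods) < 2L)
    return(data.frame(module_a = character(0), module_b = character(0),
                      r = numeric(0), p_value = numeric(0), adj_p = numeric(0)))
  pairs <- utils::combn(mods, 2)
  res <- apply(pairs, 2, function(pr) {
    ct <- stats::cor.test(lg[, pr[1]], lg[, pr[2]], alternative = "greater",
                          method = "pearson")
    c(r = unname(ct$estimate), p = ct$p.value)
  })
  out <- data.frame(module_a = pairs[1, ], module_b = pairs[2, ],
                    r = res["r", ], p_value = res["p", ],
                    stringsAsFactors = FALSE)
  out$adj_p <- stats::p.adjust(out$p_value, method = "BH")
  out[out$adj_p < alpha, , drop = FALSE]
}

#' Assign tested genes to their closest module and test DEG enrichment
#'
#' Each tested gene is assigned to the module whose average expression
#' profile (across cells) it correlates with most strongly; per module and
#' DEG category (up / down / ns) a hypergeometric upper-tail test compares
#' the category count among the module's assigned genes against the totals,
#' with BH correction across all module x category tests.
#'
#' @param deg_table data.frame with columns `gene_id` and
#'   `category` (values in up/down/ns); extra columns (effect sizes) pass
#'   through untouched.
#' @param x a normalized `scd_expr` containing the tested genes.
#' @param modules an `scd_modules` object.
#' @return list with `assignment` (data.frame gene_id, module_id, cor) and
#'   `enrichment` (data.frame module_id, category, counts, p_value, adj_p).
#'   Zero-variance genes are excluded from both.
#' @export
assign_degs_to_modules <- function(deg_table, x, modules) {
  stopifnot(inherits(x, "scd_expr"), inherits(modules, "scd_modules"))
  need <- c("gene_id", "category")
  if (!all(need %in% names(deg_table)))
    stop("deg_table must have columns gene_id and category")
  bad <- setdiff(unique(deg_table$category), c("up", "down", "ns"))
  if (length(bad)) stop("unknown DEG categories: ", paste(bad, collapse = ", "))
  genes <- intersect(deg_table$gene_id, x$gene_ids)
  if (!length(genes)) stop("no tested genes present in the matrix")
  # module average expression profiles over cells
  prof <- vapply(modules$modules, function(gs) {
    present <- intersect(gs, x$gene_ids)
    as.numeric(Matrix::rowMeans(x$values[, present, drop = FALSE]))
  }, numeric(nrow(x$values)))
  gx <- as.matrix(x$values[, genes, drop = FALSE])
  ok <- apply(gx, 2, function(v) stats::sd(v) > 0)
  gx <- gx[, ok, drop = FALSE]
  genes <- genes[ok]
  if (!length(genes)) stop("all tested genes have zero variance")
  cors <- stats::cor(gx, prof)
  best <- max.col(cors, ties.method = "first")
  assignment <- data.frame(gene_id = genes,
                           module_id = colnames(prof)[best],
                           cor = cors[cbind(seq_along(best), best)],
                           stringsAsFactors = FALSE)
  cat_of <- deg_table$category[match(assignment$gene_id, deg_table$gene_id)]
  N <- nrow(assignment)
  rows <- list()
  for (m in colnames(prof)) {
    in_m <- which(assignment$module_id == m)
    for (cat in c("up", "down", "ns")) {
      K <- sum(cat_of == cat)
      if (K == 0L) next
      q <- sum(cat_of[in_m] == cat)
      rows[[length(rows) + 1L]] <- data.frame(
        module_id = m, category = cat, n_module = length(in_m),
        n_category = K, overlap = q,
        expected = length(in_m) * K / N,
        p_value = hyper_upper(q, K, N, length(in_m)),
        stringsAsFactors = FALSE)
    }
  }
  enrichment <- do.call(rbind, rows)
  enrichment$adj_p <- stats::p.adjust(enrichment$p_value, method = "BH")
  list(assignment = assignment, enrichment = enrichment)
}

# separable 2D convolution with an odd square Gaussian kernel, zero padding
gauss_kernel_1d <- function(size, sigma) {
  half <- (size - 1) / 2
  k <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  k / sum(k)
}

conv2_separable <- function(mat, k1d) {
  half <- (length(k1d) - 1) / 2
  pad <- function(m) rbind(matrix(0, half, ncol(m)), m, matrix(0, half, ncol(m)))
  conv_cols <- function(m) {
    mp <- pad(m)
    out <- matrix(0, nrow(m), ncol(m))
    for (o in seq_along(k1d))
      out <- out + k1d[o] * mp[o:(o + nrow(m) - 1), , drop = FALSE]
    out
  }
  t(conv_cols(t(conv_cols(mat))))
}

#' Smooth per-cell values on a 2D embedding grid
#'
#' Values are averaged within the cells of a `grid x grid` lattice over the
#' embedding's bounding box, then convolved with a `kernel x kernel` Gaussian
#' (s.d. `sigma`, in grid-cell units; zero padding). Intended for drawing
#' module-expression contours on a UMAP.
#'
#' @param coords cells x 2 matrix of embedding coordinates.
#' @param values numeric vector per cell.
#' @param grid lattice resolution per axis (default 500).
#' @param kernel odd kernel size (default 25).
#' @param sigma Gaussian s.d. in grid units (default 1).
#' @param levels contour levels as fractions of the smoothed maximum.
#' @return list with `x`, `y` (grid center coordinates), `surface`
#'   (grid x grid matrix, rows = x bins), `levels` (absolute contour levels).
#' @export
smooth_contour <- function(coords, values, grid = 500L, kernel = 25L,
                           sigma = 1, levels = seq(0.1, 0.8, by = 0.1)) {
  coords <- as.matrix(coords)
  if (any(!is.finite(coords)) || any(!is.finite(values)))
    stop("coords and values must be finite")
  if (kernel %% 2L != 1L) stop("kernel size must be odd")
  rx <- range(coords[, 1]); ry <- range(coords[, 2])
  if (diff(rx) == 0) rx <- rx + c(-0.5, 0.5)
  if (diff(ry) == 0) ry <- ry + c(-0.5, 0.5)
  bx <- findInterval(coords[, 1], seq(rx[1], rx[2], length.out = grid + 1L),
                     rightmost.closed = TRUE, all.inside = TRUE)
  by <- findInterval(coords[, 2], seq(ry[1], ry[2], length.out = grid + 1L),
                     rightmost.closed = TRUE, all.inside = TRUE)
  idx <- (by - 1L) * grid + bx              # linear index into [x bin, y bin]
  surface <- matrix(0, grid, grid)
  sums <- rowsum(values, idx)
  cnts <- table(idx)[rownames(sums)]
  surface[as.integer(rownames(sums))] <- sums[, 1] / as.integer(cnts)
  sm <- conv2_separable(surface, gauss_kernel_1d(kernel, sigma))
  cx <- (seq(rx[1], rx[2], length.out = grid + 1L)[-1] +
           seq(rx[1], rx[2], length.out = grid + 1L)[-(grid + 1L)]) / 2
  cy <- (seq(ry[1], ry[2], length.out = grid + 1L)[-1] +
           seq(ry[1], ry[2], length.out = grid + 1L)[-(grid + 1L)]) / 2
  list(x = cx, y = cy, surface = sm, levels = levels * max(sm))
}
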