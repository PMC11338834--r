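#' Truncated non-centred SVD of an expression matrix
#'
#' Computes `X = U S V'` without centring. Centring is deliberately skipped:
#' the analytic reduction of the ZCA-whitened gene-gene covariance to
#' `g V S^p V' / n` only holds for the non-centred factorization. Small
#' problems use the dense LAPACK SVD; larger ones a seeded randomized
#' (subspace-iteration) solver.
#'
#' @param x an `scd_expr` object, or a plain numeric/sparse matrix.
#' @param k number of components to retain (`k <= min(n, g)`).
#' @param seed integer seed making the randomized path reproducible.
#' @param n_oversample extra random probe directions for the randomized solver.
#' @param n_iter power iterations for the randomized solver.
#' @return object of class `scd_svd`: list with `U` (n x k), `S` (length k,
#'   descending), `V` (g x k), `k`, `centered = FALSE`.
#' @export
compute_svd <- function(x, k, seed = 1L, n_oversample = 10L, n_iter = 3L) {
  m <- if (inherits(x, "scd_expr")) x$values else x
  n <- nrow(m); g <- ncol(m)
  if (k > min(n, g)) stop("k = ", k, " exceeds min(n, g) = ", min(n, g))
  if (k < 1L) stop("k must be >= 1")
  small <- min(n, g) <= 600L || k >= 0.5 * min(n, g)
  if (small) {
    sv <- svd(as.matrix(m), nu = k, nv = k)
    res <- list(U = sv$u[, seq_len(k), drop = FALSE],
                S = sv$d[seq_len(k)],
                V = sv$v[, seq_len(k), drop = FALSE])
  } else {
    res <- randomized_svd(m, k, seed = seed, n_oversample = n_oversample,
                          n_iter = n_iter)
  }
  # sign convention: largest-magnitude loading of each V column is positive
  for (j in seq_len(k)) {
    i <- which.max(abs(res$V[, j]))
    if (res$V[i, j] < 0) {
      res$V[, j] <- -res$V[, j]
      res$U[, j] <- -res$U[, j]
    }
  }
  structure(list(U = res$U, S = res$S, V = res$V, k = as.integer(k),
                 centered = FALSE, gene_ids = if (inherits(x, "scd_expr")) x$gene_ids else colnames(m)),
            class = "scd_svd")
}

# Halko-style randomized range finder + SVD on the projected matrix.
# Deterministic for a fixed seed; works on dense or Matrix inputs.
randomized_svd <- function(m, k, seed, n_oversample = 10L, n_iter = 3L) {
  n <- nrow(m); g <- ncol(m)
  l <- min(k + n_oversample, min(n, g))
  withr::with_seed(as.integer(seed), {
    omega <- matrix(stats::rnorm(g * l), g, l)
  })
  y <- as.matrix(m %*% omega)                       # n x l
  q <- qr.Q(qr(y))
  for (i in seq_len(n_iter)) {
    z <- as.matrix(Matrix::crossprod(m, q))         # g x l
    q <- qr.Q(qr(z))
    y <- as.matrix(m %*% q)                         # n x l
    q <- qr.Q(qr(y))
  }
  b <- as.matrix(Matrix::crossprod(q, m))           # l x g
  sv <- svd(b, nu = k, nv = k)
  list(U = q %*% sv$u[, seq_len(k), drop = FALSE],
       S = sv$d[seq_len(k)],
       V = sv$v[, seq_len(k), drop = FALSE])
}

#' @export
print.scd_svd <- function(x, ...) {
  cat(sprintf("<scd_svd> k = %d components, leading singular values: %s\n",
              x$k, paste(signif(utils::head(x$S, 4), 4), collapse = ", ")))
  invisible(x)
}

#' Decorrelated gene-gene covariance and correlation
#'
#' The ZCA whitening of the cells (rows) of `X` has non-centred covariance
#' `C_ZCA = g V V' / n` at full decorrelation. Raising the singular values to
#' a power `p` interpolates between fully whitened structure (`p = 0`) and the
#' raw non-centred covariance `g X'X / n` (`p = 2`), tuning how much the
#' dominant expression programs contribute:
#' `C = g * V diag(S^p) V' / n`.
#'
#' The covariance is rescaled to unit diagonal to give a correlation matrix;
#' genes whose diagonal falls below `eps` cannot be rescaled and are excluded.
#'
#' @param svd an `scd_svd` factorization.
#' @param p eigenvalue power, `p >= 0`.
#' @param n number of cells of the matrix that was factorized.
#' @param g number of genes.
#' @param eps diagonal floor below which a gene is excluded from `corr`.
#' @return object of class `scd_corr`: list with `p`, `cov` (g x g), `corr`
#'   (g x g, unit diagonal, clipped to `[-1, 1]`, `NA` rows/cols for excluded
#'   genes), `gene_ids`, `excluded` (integer indices).
#' @export
decorrelated_covariance <- function(svd, p, n, g = nrow(svd$V), eps = 1e-12) {
  stopifnot(inherits(svd, "scd_svd"))
  if (p < 0) stop("p must be >= 0")
  cv <- zca_cov(svd$V, svd$S, p, n, g)
  d <- diag(cv)
  excluded <- which(d < eps)
  corr <- rescale_to_corr(cv, d, excluded)
  structure(list(p = p, cov = cv, corr = corr,
                 gene_ids = svd$gene_ids, excluded = excluded),
            class = "scd_corr")
}

zca_cov <- function(V, S, p, n, g) {
  vs <- sweep(V, 2, S^p, `*`)
  cv <- g * tcrossprod(vs, V) / n
  (cv + t(cv)) / 2
}

rescale_to_corr <- function(cv, d = diag(cv), excluded = integer()) {
  inv <- 1 / sqrt(d)
  if (length(excluded)) inv[excluded] <- NA_real_
  corr <- cv * tcrossprod(inv)
  corr[corr > 1] <- 1
  corr[corr < -1] <- -1
  diag(corr) <- ifelse(seq_along(d) %in% excluded, NA_real_, 1)
  corr
}

#' Select the number of SVD components by edge-set stability
#'
#' For each candidate `k`, batches are split into two halves, the thresholded
#' decorrelated edge set is computed on each half, and the Jaccard similarity
#' of the two edge sets is recorded (averaged over `n_rep` seeded splits). The
#' `k` with the highest mean stability wins. With fewer than two batches no
#' split is possible and the method falls back to `k = min(100, min(n,g) - 1)`
#' with a warning.
#'
#' @param x a filtered, normalized `scd_expr`.
#' @param k_grid integer vector of candidate component counts.
#' @param seed integer seed.
#' @param p eigenvalue power used for the stability probe.
#' @param z_cut threshold defining the compared edge sets; the default is
#'   intentionally below the module-calling threshold so that half-split
#'   probes (with half the cells, hence weaker z) still produce populated
#'   edge sets to compare.
#' @param n_rep number of half-splits per candidate.
#' @return the selected `k` (integer).
#' @export
select_k <- function(x, k_grid, seed = 1L, p = 0, z_cut = 2, n_rep = 2L) {
  stopifnot(inherits(x, "scd_expr"))
  k_grid <- as.integer(k_grid)
  if (any(k_grid > min(dim(x$values))))
    stop("k_grid contains values exceeding min(n, g)")
  if (length(k_grid) == 1L) return(k_grid)
  batches <- unique(x$cell_meta$batch_id)
  if (length(batches) < 2L) {
    warning("fewer than 2 batches: falling back to default k")
    return(as.integer(min(100L, min(dim(x$values)) - 1L)))
  }
  stability <- vapply(k_grid, function(k) {
    js <- vapply(seq_len(n_rep), function(r) {
      withr::with_seed(as.integer(seed) + 7L * r, {
        perm <- sample(batches)
      })
      half1 <- perm[seq_len(floor(length(perm) / 2))]
      e <- lapply(list(half1, setdiff(perm, half1)), function(bs) {
        sub <- subset_cells(x, x$cell_meta$batch_id %in% bs)
        edge_set_for_stability(sub, k, p, z_cut, seed)
      })
      jaccard_sets(e[[1]], e[[2]])
    }, numeric(1))
    mean(js)
  }, numeric(1))
  k_grid[which.max(stability)]
}

edge_set_for_stability <- function(sub, k, p, z_cut, seed) {
  sp <- compute_sparsity(sub)
  ok <- sp$fraction_expressed > 0
  sub <- subset_genes(sub, ok)
  sp <- compute_sparsity(sub)
  sv <- compute_svd(sub, k = min(k, min(dim(sub$values))), seed = seed)
  co <- decorrelated_covariance(sv, p, n = nrow(sub$values))
  z <- zscore_correlations(co, fit_sparsity_bins(co, sp), sp)
  ut <- which(upper.tri(z$z) & z$z > z_cut, arr.ind = TRUE)
  paste(z$gene_ids[ut[, 1]], z$gene_ids[ut[, 2]], sep = "\r")
}

jaccard_sets <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}
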