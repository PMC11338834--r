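#' Fit the sparsity-bin calibration model
#'
#' Decorrelated correlation estimates are inflated for pairs of sparsely
#' expressed genes. To calibrate, every gene pair is assigned to a 2D bin by
#' the two genes' log10 sparsities (equal-width bins over the observed range),
#' the mean and s.d. of the correlation values are computed per bin, and both
#' statistics are smoothed with a bivariate tensor-product spline weighted by
#' `log(1 + count)` per bin. With fewer than `min_bins` populated bins per
#' axis the model falls back to constant global mean/s.d. surfaces.
#'
#' @param corr an `scd_corr` object.
#' @param sp sparsity from [compute_sparsity()] for the same genes; all
#'   fractions must be > 0.
#' @param n_bins number of bins per axis (default 20).
#' @param sd_floor lower bound applied to the smoothed s.d. surface.
#' @param min_bins minimum populated bins per axis for spline fitting.
#' @return object of class `scd_binmodel`.
#' @export
fit_sparsity_bins <- function(corr, sp, n_bins = 20L, sd_floor = 1e-4,
                              min_bins = 4L) {
  stopifnot(inherits(corr, "scd_corr"))
  s <- sp$log10_sparsity
  g <- length(s)
  if (g != nrow(corr$corr)) stop("sparsity and correlation gene sets differ")
  if (any(!is.finite(s))) stop("genes with zero expressed fraction present; filter first")
  rng <- range(s)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5) * 1e-8
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bin_of <- findInterval(s, edges, rightmost.closed = TRUE, all.inside = TRUE)

  ut <- which(upper.tri(corr$corr), arr.ind = TRUE, useNames = FALSE)
  vals <- corr$corr[ut]
  ok <- is.finite(vals)
  ut <- ut[ok, , drop = FALSE]; vals <- vals[ok]
  bi <- bin_of[ut[, 1]]; bj <- bin_of[ut[, 2]]
  lo <- pmin(bi, bj); hi <- pmax(bi, bj)
  cell <- (lo - 1L) * n_bins + hi          # canonical cell, lower triangle of bins

  cnt <- sums <- sq <- numeric(n_bins * n_bins)
  tab <- tabulate(cell, nbins = n_bins * n_bins)
  cnt <- tab
  sums[] <- unname(rowsum_fill(vals, cell, n_bins * n_bins))
  sq[] <- unname(rowsum_fill(vals^2, cell, n_bins * n_bins))
  mu <- ifelse(cnt > 0, sums / pmax(cnt, 1), NA_real_)
  va <- ifelse(cnt > 1, (sq - cnt * mu^2) / (cnt - 1), NA_real_)
  sdv <- sqrt(pmax(va, 0))

  to_mat <- function(v) {
    m <- matrix(v, n_bins, n_bins, byrow = TRUE)   # [lo, hi]
    m[lower.tri(m)] <- t(m)[lower.tri(m)]          # symmetrize
    m
  }
  bin_count <- to_mat(cnt); bin_mean <- to_mat(mu); bin_sd <- to_mat(sdv)

  centers <- (edges[-1] + edges[-length(edges)]) / 2
  pop <- which(is.finite(bin_mean) & bin_count > 0, arr.ind = TRUE)
  pop_axes <- min(length(unique(pop[, 1])), length(unique(pop[, 2])))

  grid_s <- centers
  if (pop_axes < min_bins) {
    warning("fewer than ", min_bins,
            " populated sparsity bins per axis; using constant calibration surfaces")
    gm <- stats::weighted.mean(bin_mean[pop], bin_count[pop])
    gs <- sqrt(stats::weighted.mean(bin_sd[pop]^2, bin_count[pop], na.rm = TRUE))
    if (!is.finite(gs) || gs <= 0) gs <- sd_floor
    grid_mu <- matrix(gm, n_bins, n_bins)
    grid_sd <- matrix(max(gs, sd_floor), n_bins, n_bins)
    kind <- "constant"
  } else {
    # spline fit on populated cells (both orderings present for symmetry),
    # then per-bin residuals shrunk by count: well-populated bins keep their
    # own precisely estimated statistic, sparse bins borrow the spline
    df <- data.frame(si = centers[pop[, 1]], sj = centers[pop[, 2]],
                     m = bin_mean[pop], sdv = bin_sd[pop],
                     w = log1p(bin_count[pop]))
    kb <- max(3L, min(10L, floor(sqrt(nrow(df)) / 2)))
    newd <- expand.grid(si = centers, sj = centers)
    fit_mu <- mgcv::gam(m ~ te(si, sj, k = kb), weights = w, data = df)
    grid_mu <- matrix(stats::predict(fit_mu, newd), n_bins, n_bins)
    ok_sd <- is.finite(df$sdv)
    fit_sd <- mgcv::gam(sdv ~ te(si, sj, k = kb), weights = w,
                        data = df[ok_sd, , drop = FALSE])
    grid_sd <- matrix(stats::predict(fit_sd, newd), n_bins, n_bins)
    shrink <- bin_count / (bin_count + 100)
    has <- is.finite(bin_mean)
    grid_mu[has] <- grid_mu[has] + shrink[has] * (bin_mean[has] - grid_mu[has])
    has_sd <- is.finite(bin_sd)
    grid_sd[has_sd] <- grid_sd[has_sd] +
      shrink[has_sd] * (bin_sd[has_sd] - grid_sd[has_sd])
    grid_sd <- pmax(grid_sd, sd_floor)
    # force exact symmetry of the evaluation grids
    grid_mu <- (grid_mu + t(grid_mu)) / 2
    grid_sd <- (grid_sd + t(grid_sd)) / 2
    kind <- "spline"
  }
  structure(list(bin_edges = edges, bin_mean = bin_mean, bin_sd = bin_sd,
                 bin_count = bin_count, grid_s = grid_s, grid_mu = grid_mu,
                 grid_sd = grid_sd, sd_floor = sd_floor, kind = kind,
                 gene_ids = corr$gene_ids),
            class = "scd_binmodel")
}

rowsum_fill <- function(v, idx, n) {
  out <- numeric(n)
  rs <- rowsum(v, idx)
  out[as.integer(rownames(rs))] <- rs[, 1]
  out
}

# evaluate the smoothed surface for gene pairs: each pair is scored by the
# smoothed value of its own 2D sparsity bin (out-of-range queries clamp to
# the boundary bins)
eval_surface <- function(model, si, sj, which = c("mu", "sd")) {
  which <- match.arg(which)
  m <- if (which == "mu") model$grid_mu else model$grid_sd
  bi <- findInterval(si, model$bin_edges, rightmost.closed = TRUE,
                     all.inside = TRUE)
  bj <- findInterval(sj, model$bin_edges, rightmost.closed = TRUE,
                     all.inside = TRUE)
  m[cbind(bi, bj)]
}

#' Z-score a decorrelated correlation matrix against the sparsity model
#'
#' `z[i, j] = (corr[i, j] - mu(s_i, s_j)) / max(sigma(s_i, s_j), sd_floor)`
#' where `mu` and `sigma` are the smoothed bin surfaces evaluated at the two
#' genes' log10 sparsities.
#'
#' @param corr an `scd_corr` object.
#' @param model an `scd_binmodel` fitted on the same gene set.
#' @param sp sparsity for the same genes.
#' @return object of class `scd_zmat`: `z` (symmetric g x g, diagonal `NA`),
#'   `gene_ids`, `provenance`.
#' @export
zscore_correlations <- function(corr, model, sp) {
  stopifnot(inherits(corr, "scd_corr"), inherits(model, "scd_binmodel"))
  if (!identical(model$gene_ids, corr$gene_ids))
    stop("model was fitted on a different gene set")
  g <- length(corr$gene_ids)
  s <- sp$log10_sparsity
  ut <- which(upper.tri(corr$corr), arr.ind = TRUE, useNames = FALSE)
  mu <- eval_surface(model, s[ut[, 1]], s[ut[, 2]], "mu")
  sg <- pmax(eval_surface(model, s[ut[, 1]], s[ut[, 2]], "sd"), model$sd_floor)
  zv <- (corr$corr[ut] - mu) / sg
  z <- matrix(NA_real_, g, g, dimnames = list(corr$gene_ids, corr$gene_ids))
  z[ut] <- zv
  z[ut[, c(2, 1), drop = FALSE]] <- zv
  structure(list(z = z, gene_ids = corr$gene_ids,
                 provenance = list(p = corr$p, n_boot = 1L, seed = NA_integer_)),
            class = "scd_zmat")
}

#' Bootstrap-averaged z-scores over batches, for several eigenvalue powers
#'
#' For each bootstrap, `ceil(batch_fraction * B)` of the `B` batches are drawn
#' without replacement, the truncated SVD is recomputed on those cells, and the
#' sparsity-calibrated z-scores are computed for every requested power (the
#' factorization is shared across powers; the bin model is refitted per
#' power). The per-power z matrices are averaged elementwise over bootstraps;
#' entries missing from some bootstraps (genes unexpressed in that cell
#' subset) are averaged over the contributing bootstraps only, and entries
#' missing from all bootstraps are set to 0.
#'
#' @param x a filtered, normalized `scd_expr` (gene filter already applied on
#'   the full dataset).
#' @param powers numeric vector of eigenvalue powers.
#' @param k number of SVD components.
#' @param n_boot number of bootstraps (default 10).
#' @param batch_fraction fraction of batches per bootstrap (default 0.9).
#' @param seed integer seed.
#' @param n_bins bins per sparsity axis.
#' @return named list of `scd_zmat`, one per power.
#' @export
bootstrap_zscores_multi <- function(x, powers, k, n_boot = 10L,
                                    batch_fraction = 0.9, seed = 1L,
                                    n_bins = 20L) {
  stopifnot(inherits(x, "scd_expr"))
  batches <- unique(x$cell_meta$batch_id)
  if (length(batches) < 2L) stop("bootstrapping requires at least 2 batches")
  g <- length(x$gene_ids)
  nsel <- ceiling(batch_fraction * length(batches))
  np <- length(powers)
  sumz <- lapply(seq_len(np), function(i) matrix(0, g, g))
  cntz <- lapply(seq_len(np), function(i) matrix(0L, g, g))

  for (b in seq_len(n_boot)) {
    cells <- NULL
    for (try in seq_len(10L)) {
      withr::with_seed(as.integer(seed) + 1009L * b + try - 1L, {
        sel <- sample(batches, nsel)
      })
      idx <- which(x$cell_meta$batch_id %in% sel)
      if (length(idx) >= 2L) { cells <- idx; break }
    }
    if (is.null(cells)) stop("could not draw a bootstrap with >= 2 cells")
    sub <- subset_cells(x, cells)
    spb <- compute_sparsity(sub)
    present <- which(spb$fraction_expressed > 0)
    subg <- subset_genes(sub, present)
    spg <- compute_sparsity(subg)
    kk <- min(k, min(dim(subg$values)))
    sv <- compute_svd(subg, k = kk, seed = as.integer(seed) + b)
    for (ip in seq_len(np)) {
      co <- decorrelated_covariance(sv, powers[ip], n = nrow(subg$values))
      mdl <- fit_sparsity_bins(co, spg, n_bins = n_bins)
      zb <- zscore_correlations(co, mdl, spg)
      fin <- is.finite(zb$z)
      zz <- zb$z; zz[!fin] <- 0
      sumz[[ip]][present, present] <- sumz[[ip]][present, present] + zz
      cntz[[ip]][present, present] <- cntz[[ip]][present, present] + fin
    }
  }
  out <- lapply(seq_len(np), function(ip) {
    z <- sumz[[ip]] / pmax(cntz[[ip]], 1L)
    z[cntz[[ip]] == 0L] <- 0
    diag(z) <- NA_real_
    dimnames(z) <- list(x$gene_ids, x$gene_ids)
    structure(list(z = z, gene_ids = x$gene_ids,
                   provenance = list(p = powers[ip], n_boot = n_boot,
                                     seed = as.integer(seed))),
              class = "scd_zmat")
  })
  names(out) <- paste0("p", powers)
  out
}

#' Bootstrap-averaged z-scores for a single eigenvalue power
#'
#' Convenience wrapper around [bootstrap_zscores_multi()].
#'
#' @inheritParams bootstrap_zscores_multi
#' @param p eigenvalue power.
#' @return an `scd_zmat`.
#' @export
bootstrap_zscores <- function(x, p, k, n_boot = 10L, batch_fraction = 0.9,
                              seed = 1L, n_bins = 20L) {
  bootstrap_zscores_multi(x, powers = p, k = k, n_boot = n_boot,
                          batch_fraction = batch_fraction, seed = seed,
                          n_bins = n_bins)[[1]]
}

#' Export a z-score matrix as a thresholded long-format edge list
#'
#' @param z an `scd_zmat`.
#' @param path output TSV path.
#' @param z_floor only pairs with `z > z_floor` are written (bounds file size).
#' @return invisibly, the number of rows written.
#' @export
write_edges <- function(z, path, z_floor = 2) {
  stopifnot(inherits(z, "scd_zmat"))
  ut <- which(upper.tri(z$z) & z$z > z_floor, arr.ind = TRUE, useNames = FALSE)
  tab <- data.table::data.table(gene_i = z$gene_ids[ut[, 1]],
                                gene_j = z$gene_ids[ut[, 2]],
                                z = z$z[ut])
  data.table::fwrite(tab, path, sep = "\t")
  invisible(nrow(tab))
}
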