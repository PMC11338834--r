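#' Configuration for the synthetic single-cell generator
#'
#' Defines a negative-binomial count simulation with planted co-expression
#' modules, imbalanced cell-type composition, per-batch multiplicative
#' effects, log-normal library sizes, and a gene-sparsity gradient. The
#' defaults are the package's fixed validation scenario (5,000 cells, 2,000
#' genes, 5 planted modules of 60 genes, 3 batches).
#'
#' @param n_cells,n_genes matrix dimensions.
#' @param module_sizes integer vector, genes per planted module.
#' @param type_props named cell-type proportions (sum to 1).
#' @param activity named list or matrix [type x module] of mean module
#'   activities; `NULL` uses a default layout (first module active in every
#'   type, remaining modules cycling over single types, last module shared by
#'   the first two types when 5 modules / 3 types).
#' @param loading multiplicative strength tying module genes to activity.
#' @param activity_sd cell-level Gaussian s.d. around the type mean activity.
#' @param n_batches number of batches (cells assigned at random).
#' @param batch_sd log-normal s.d. of per-batch per-gene factors.
#' @param libsize_sd log-normal s.d. of per-cell library-size factors.
#' @param nb_dispersion negative-binomial size parameter (smaller = noisier).
#' @param sparsity_range target expressed-fraction range for background genes
#'   (log-uniform); planted module genes use `module_sparsity_range` so that
#'   planted structure is not destroyed by the 5 percent expression filter.
#' @param module_sparsity_range target expressed-fraction range for module
#'   genes.
#' @param seed integer seed; the generator is bit-reproducible per seed.
#' @return a config list of class `scd_synth_config`.
#' @export
synthetic_config <- function(n_cells = 5000L, n_genes = 2000L,
                             module_sizes = rep(60L, 5L),
                             type_props = c(A = 0.6, B = 0.3, C = 0.1),
                             activity = NULL,
                             loading = 3, activity_sd = 1.5,
                             n_batches = 3L, batch_sd = 0.1,
                             libsize_sd = 0.3, nb_dispersion = 5,
                             sparsity_range = c(0.02, 0.95),
                             module_sparsity_range = c(0.10, 0.95),
                             seed = 0L) {
  stopifnot(abs(sum(type_props) - 1) < 1e-8, all(type_props > 0),
            nb_dispersion > 0, loading >= 0,
            sum(module_sizes) <= n_genes)
  nt <- length(type_props); nm <- length(module_sizes)
  if (is.null(activity)) {
    activity <- matrix(0, nt, nm)
    dimnames(activity) <- list(names(type_props),
                               if (nm) paste0("T", seq_len(nm)))
    if (nm >= 1L) activity[, 1] <- 1                  # shared program
    if (nm >= 2L) for (m in 2:nm) {
      if (m == nm && nm > nt + 1L) activity[seq_len(min(2L, nt)), m] <- 1
      else activity[((m - 2L) %% nt) + 1L, m] <- 1    # type-specific programs
    }
  }
  structure(list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
                 module_sizes = as.integer(module_sizes),
                 type_props = type_props, activity = activity,
                 loading = loading, activity_sd = activity_sd,
                 n_batches = as.integer(n_batches), batch_sd = batch_sd,
                 libsize_sd = libsize_sd, nb_dispersion = nb_dispersion,
                 sparsity_range = sparsity_range,
                 module_sparsity_range = module_sparsity_range,
                 seed = as.integer(seed)),
            class = "scd_synth_config")
}

# target expressed fraction -> NB mean, inverting P(count = 0) = f
nb_mean_for_fraction <- function(f, theta) theta * ((1 - f)^(-1 / theta) - 1)

#' Generate a synthetic expression matrix with planted modules
#'
#' Cells get a type (stated proportions), a batch, and a latent activity per
#' module (`type mean + Gaussian noise`). A module gene's NB mean is
#' `baseline * max(0, 1 + loading * activity) * batch factor * library
#' factor`; baselines are set by inverting the NB zero probability to hit a
#' log-uniform target expressed fraction, and rescaled so the planted
#' activity does not shift the marginal sparsity.
#'
#' @param config from [synthetic_config()].
#' @return list with `x` (raw-count `scd_expr`) and `truth` (class
#'   `scd_truth`: `module_assignments` named gene vector with "background"
#'   for unplanted genes, `cell_types`, `activity`, `batch_factors`,
#'   `nb_dispersion`, `seed`, `config`).
#' @export
generate_synthetic <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "scd_synth_config"))
  cfg <- config
  n <- cfg$n_cells; g <- cfg$n_genes
  nm <- length(cfg$module_sizes)
  type_counts <- round(cfg$type_props * n)
  type_counts[1] <- n - sum(type_counts[-1])
  if (any(type_counts < 1L)) stop("a cell type would receive zero cells")
  withr::with_seed(cfg$seed, {
    types <- sample(rep(names(cfg$type_props), type_counts))
    batches <- sample(rep_len(paste0("b", seq_len(cfg$n_batches)), n))
    # gene-module assignment and sparsity targets
    module_of <- rep("background", g)
    gene_perm <- sample.int(g)
    pos <- 1L
    for (m in seq_len(nm)) {
      module_of[gene_perm[pos:(pos + cfg$module_sizes[m] - 1L)]] <-
        paste0("T", m)
      pos <- pos + cfg$module_sizes[m]
    }
    is_mod <- module_of != "background"
    f_tgt <- numeric(g)
    f_tgt[!is_mod] <- exp(stats::runif(sum(!is_mod),
                                       log(cfg$sparsity_range[1]),
                                       log(cfg$sparsity_range[2])))
    f_tgt[is_mod] <- exp(stats::runif(sum(is_mod),
                                      log(cfg$module_sparsity_range[1]),
                                      log(cfg$module_sparsity_range[2])))
    base <- nb_mean_for_fraction(f_tgt, cfg$nb_dispersion)
    # latent activities: cells x modules
    amp <- cfg$activity[types, , drop = FALSE]
    act <- amp + matrix(stats::rnorm(n * nm, sd = cfg$activity_sd), n, nm)
    fac_mod <- pmax(1 + cfg$loading * act, 0)         # cells x modules
    batch_fac <- matrix(stats::rlnorm(cfg$n_batches * g, 0, cfg$batch_sd),
                        cfg$n_batches, g,
                        dimnames = list(paste0("b", seq_len(cfg$n_batches)), NULL))
    lib_fac <- stats::rlnorm(n, 0, cfg$libsize_sd)
    # NB means
    mu <- matrix(rep(base, each = n), n, g)
    for (m in seq_len(nm)) {
      cols <- which(module_of == paste0("T", m))
      fm <- fac_mod[, m] / mean(fac_mod[, m])         # preserve marginal mean
      mu[, cols] <- mu[, cols] * fm
    }
    mu <- mu * batch_fac[batches, , drop = FALSE]
    mu <- mu * lib_fac
    counts <- matrix(stats::rnbinom(n * g, size = cfg$nb_dispersion, mu = mu),
                     n, g)
  })
  gene_ids <- sprintf("g%04d", seq_len(g))
  cell_ids <- sprintf("c%05d", seq_len(n))
  meta <- data.frame(cell_id = cell_ids, batch_id = batches,
                     cell_type = types, stringsAsFactors = FALSE)
  x <- expr_matrix(counts, gene_ids, cell_ids, meta, normalized = FALSE)
  truth <- structure(list(
    module_assignments = stats::setNames(module_of, gene_ids),
    cell_types = stats::setNames(types, cell_ids),
    activity = cfg$activity,
    batch_factors = batch_fac,
    nb_dispersion = cfg$nb_dispersion,
    seed = cfg$seed, config = cfg), class = "scd_truth")
  list(x = x, truth = truth)
}

#' Load a simulation scenario from YAML
#'
#' @param path YAML file with [synthetic_config()] fields (`type_props` and
#'   `module_sizes` as named/plain lists).
#' @return an `scd_synth_config`.
#' @export
load_scenario <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (nm in c("n_cells", "n_genes", "n_batches", "seed"))
    if (!is.null(y[[nm]])) args[[nm]] <- as.integer(y[[nm]])
  for (nm in c("loading", "activity_sd", "batch_sd", "libsize_sd",
               "nb_dispersion"))
    if (!is.null(y[[nm]])) args[[nm]] <- as.numeric(y[[nm]])
  if (!is.null(y[["module_sizes"]]))
    args$module_sizes <- as.integer(unlist(y[["module_sizes"]]))
  if (!is.null(y[["type_props"]])) args$type_props <- unlist(y[["type_props"]])
  for (nm in c("sparsity_range", "module_sparsity_range"))
    if (!is.null(y[[nm]])) args[[nm]] <- as.numeric(unlist(y[[nm]]))
  if (!is.null(y[["activity"]]))
    args$activity <- do.call(rbind, lapply(y[["activity"]], unlist))
  do.call(synthetic_config, args)
}

planted_modules_list <- function(truth) {
  ma <- truth$module_assignments
  split(names(ma)[ma != "background"], ma[ma != "background"])
}

jaccard <- function(a, b) {
  length(intersect(a, b)) / length(union(a, b))
}

#' Evaluate module recovery against planted truth
#'
#' @param found an `scd_modules` object.
#' @param truth an `scd_truth` from [generate_synthetic()].
#' @param graphs optional list of `scd_graph`; when given, edge precision and
#'   recall are computed over the union of thresholded graph edges against
#'   planted co-module gene pairs, otherwise over co-membership pairs of the
#'   reported modules.
#' @return object of class `scd_recovery`: `per_module` (best-match Jaccard
#'   per planted module), `mean_jaccard`, `ari` (adjusted Rand index over
#'   genes clustered by both partitions), `edge_precision`, `edge_recall`,
#'   `no_modules` flag.
#' @export
evaluate_recovery <- function(found, truth, graphs = NULL) {
  stopifnot(inherits(found, "scd_modules"), inherits(truth, "scd_truth"))
  planted <- planted_modules_list(truth)
  if (!length(found$modules)) {
    return(structure(list(per_module = stats::setNames(rep(0, length(planted)),
                                                       names(planted)),
                          mean_jaccard = 0, ari = 0,
                          edge_precision = 0, edge_recall = 0,
                          no_modules = TRUE), class = "scd_recovery"))
  }
  per_module <- vapply(planted, function(tg) {
    max(vapply(found$modules, function(fg) jaccard(tg, fg), numeric(1)))
  }, numeric(1))
  # ARI over genes placed in a module by both partitions
  fa <- found$assignment[found$assignment %in% names(found$modules)]
  common <- intersect(names(fa),
                      names(truth$module_assignments)[truth$module_assignments != "background"])
  ari <- if (length(common) >= 2L) {
    mclust::adjustedRandIndex(truth$module_assignments[common], fa[common])
  } else 0
  true_pairs <- unlist(lapply(planted, pair_keys), use.names = FALSE)
  found_pairs <- if (!is.null(graphs)) {
    unique(unlist(lapply(graphs, function(g) {
      if (igraph::vcount(g$graph) == 0L) return(character(0))
      el <- igraph::as_edgelist(g$graph, names = TRUE)
      pair_key(el[, 1], el[, 2])
    }), use.names = FALSE))
  } else {
    unlist(lapply(found$modules, pair_keys), use.names = FALSE)
  }
  inter <- length(intersect(found_pairs, true_pairs))
  structure(list(per_module = per_module,
                 mean_jaccard = mean(per_module), ari = ari,
                 edge_precision = if (length(found_pairs)) inter / length(found_pairs) else 0,
                 edge_recall = if (length(true_pairs)) inter / length(true_pairs) else 0,
                 no_modules = FALSE),
            class = "scd_recovery")
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

pair_keys <- function(genes) {
  if (length(genes) < 2L) return(character(0))
  cb <- utils::combn(sort(genes), 2L)
  pair_key(cb[1, ], cb[2, ])
}

#' @export
print.scd_recovery <- function(x, ...) {
  cat(sprintf(paste0("<scd_recovery> mean Jaccard = %.3f, ARI = %.3f, ",
                     "edge precision = %.3f, recall = %.3f\n"),
              x$mean_jaccard, x$ari, x$edge_precision, x$edge_recall))
  invisible(x)
}

#' Raw-correlation baseline module calling
#'
#' A deliberately naive comparator for the decorrelated pipeline: the raw
#' non-centred covariance (`p = 2`), rescaled to correlations without any
#' sparsity calibration, thresholded at a matched edge count (the
#' "equivalent quantile" of the given reference edge number), pruned and
#' clustered exactly like the main pipeline.
#'
#' @param x a filtered, normalized `scd_expr`.
#' @param k SVD components.
#' @param n_edges number of top correlation pairs to keep as edges.
#' @param resolution,min_report_size,min_component as in the main pipeline.
#' @param seed integer seed.
#' @return an `scd_modules` object.
#' @export
raw_correlation_modules <- function(x, k, n_edges, resolution = 3,
                                    min_report_size = 10L, min_component = 4L,
                                    seed = 1L) {
  sv <- compute_svd(x, k = min(k, min(dim(x$values))), seed = seed)
  co <- decorrelated_covariance(sv, p = 2, n = nrow(x$values))
  r <- co$corr
  ut <- which(upper.tri(r) & is.finite(r), arr.ind = TRUE, useNames = FALSE)
  vals <- r[ut]
  n_edges <- min(n_edges, length(vals))
  if (n_edges < 1L) stop("no edges requested")
  cut <- sort(vals, decreasing = TRUE)[n_edges]
  keep <- vals >= cut
  zfake <- matrix(-Inf, nrow(r), ncol(r),
                  dimnames = dimnames(r))
  zfake[ut[keep, , drop = FALSE]] <- vals[keep] + 10   # any value above cut
  zfake[ut[keep, c(2, 1), drop = FALSE]] <- vals[keep] + 10
  zm <- structure(list(z = zfake, gene_ids = x$gene_ids,
                       provenance = list(p = 2, n_boot = 1L, seed = seed)),
                  class = "scd_zmat")
  gr <- suppressWarnings(build_graph(zm, z_cut = 0, min_component = min_component,
                                     p = 2))
  multigraph_leiden(list(gr), resolution = resolution,
                    min_report_size = min_report_size, seed = seed)
}
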