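#' Pipeline run configuration
#'
#' Collects every tunable parameter of the end-to-end module discovery run.
#' The `"published-data"` preset pins `k = 100`, `z_cut = 4.5`,
#' `resolution = 2.5` (the settings used for cross-dataset runs); the default
#' preset uses `resolution = 3`.
#'
#' @param matrix_path,meta_path,format input files for [read_matrix()]
#'   (omit when passing an in-memory matrix to [run_pipeline()]).
#' @param out_dir output directory.
#' @param k SVD components.
#' @param powers eigenvalue powers combined by the multigraph clustering.
#' @param z_cut edge threshold on averaged z-scores.
#' @param resolution Leiden RBConfiguration resolution.
#' @param n_boot,batch_fraction bootstrap settings.
#' @param min_fraction gene sparsity filter (strict `>`).
#' @param min_component,min_report_size graph/module size filters.
#' @param n_bins sparsity bins per axis.
#' @param normalized whether the input values are already log-normalized.
#' @param seed integer master seed (all stage seeds derive from it).
#' @param preset `"default"` or `"published-data"`.
#' @return a validated config list of class `scd_config`.
#' @export
run_config <- function(matrix_path = NULL, meta_path = NULL,
                       format = c("mtx", "dense_tsv"), out_dir = "scdemon_out",
                       k = 100L, powers = c(0, 0.25, 0.5, 0.75, 1),
                       z_cut = 4.5, resolution = 3, n_boot = 10L,
                       batch_fraction = 0.9, min_fraction = 0.05,
                       min_component = 4L, min_report_size = 10L,
                       n_bins = 20L, normalized = FALSE, seed = 0L,
                       preset = c("default", "published-data")) {
  preset <- match.arg(preset)
  format <- match.arg(format)
  if (preset == "published-data") {
    k <- 100L; z_cut <- 4.5; resolution <- 2.5
  }
  stopifnot(k >= 1, all(powers >= 0), z_cut > 0, resolution > 0,
            n_boot >= 1, batch_fraction > 0, batch_fraction <= 1,
            min_fraction >= 0, min_component >= 1, min_report_size >= 1)
  structure(list(matrix_path = matrix_path, meta_path = meta_path,
                 format = format, out_dir = out_dir, k = as.integer(k),
                 powers = powers, z_cut = z_cut, resolution = resolution,
                 n_boot = as.integer(n_boot), batch_fraction = batch_fraction,
                 min_fraction = min_fraction,
                 min_component = as.integer(min_component),
                 min_report_size = as.integer(min_report_size),
                 n_bins = as.integer(n_bins), normalized = isTRUE(normalized),
                 seed = as.integer(seed), preset = preset),
            class = "scd_config")
}

#' Run the full module-discovery pipeline
#'
#' Normalization, gene filtering, bootstrapped decorrelated z-scores for each
#' eigenvalue power, per-power graph construction and layout, multigraph
#' module calling, core-gene definition, and per-cell module scoring. All
#' parameters, seeds and the package version are written to
#' `manifest.json`; outputs are byte-reproducible from the manifest.
#'
#' @param config an `scd_config` from [run_config()].
#' @param x optional in-memory `scd_expr` (skips file reading).
#' @return invisibly, a list with `modules`, `graphs`, `zmats`, `scores`,
#'   `out_dir`.
#' @export
run_pipeline <- function(config, x = NULL) {
  stopifnot(inherits(config, "scd_config"))
  t0 <- Sys.time()
  if (is.null(x)) {
    if (is.null(config$matrix_path) || is.null(config$meta_path))
      stop("config must provide matrix_path and meta_path (or pass x)")
    message("[io] reading ", config$matrix_path)
    x <- read_matrix(config$matrix_path, config$format, config$meta_path,
                     normalized = config$normalized)
  }
  if (!x$normalized) {
    message("[io] normalizing to CP10K + log1p")
    x <- normalize_cells(x)
  }
  sp <- compute_sparsity(x)
  x <- filter_genes(x, sp, min_fraction = config$min_fraction)
  message("[io] ", length(x$gene_ids), " genes pass the ",
          config$min_fraction * 100, "% sparsity filter")
  message("[zscore] ", config$n_boot, " bootstraps x ",
          length(config$powers), " powers, k = ", config$k)
  zmats <- bootstrap_zscores_multi(x, powers = config$powers, k = config$k,
                                   n_boot = config$n_boot,
                                   batch_fraction = config$batch_fraction,
                                   seed = config$seed, n_bins = config$n_bins)
  graphs <- lapply(zmats, function(z) {
    suppressWarnings(build_graph(z, z_cut = config$z_cut,
                                 min_component = config$min_component))
  })
  graphs <- lapply(graphs, function(g) {
    if (igraph::vcount(g$graph) > 0L) layout_graph(g, seed = config$seed) else g
  })
  message("[graph] edges per power: ",
          paste(vapply(graphs, function(g) igraph::ecount(g$graph), numeric(1)),
                collapse = ", "))
  modules <- multigraph_leiden(graphs, resolution = config$resolution,
                               min_report_size = config$min_report_size,
                               seed = config$seed)
  modules <- define_core_genes(modules, graphs)
  message("[modules] ", length(modules$modules), " reported modules")
  scores <- if (length(modules$modules)) score_modules(x, modules) else NULL

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_modules(modules, config$out_dir, all_assignments = TRUE)
  for (i in seq_along(graphs)) {
    g <- graphs[[i]]
    if (igraph::vcount(g$graph) == 0L) next
    tag <- gsub("[^0-9p.]", "", names(graphs)[i])
    el <- igraph::as_edgelist(g$graph, names = TRUE)
    data.table::fwrite(data.table::data.table(gene_i = el[, 1],
                                              gene_j = el[, 2],
                                              z = igraph::E(g$graph)$weight),
                       file.path(config$out_dir, paste0("edges_", tag, ".tsv")),
                       sep = "\t")
    data.table::fwrite(data.table::data.table(gene = rownames(g$layout),
                                              x = g$layout[, 1],
                                              y = g$layout[, 2]),
                       file.path(config$out_dir, paste0("layout_", tag, ".tsv")),
                       sep = "\t")
  }
  if (!is.null(scores)) {
    sc <- data.table::data.table(cell_id = scores$cell_ids)
    sc <- cbind(sc, data.table::as.data.table(round(scores$scores, 6)))
    data.table::fwrite(sc, file.path(config$out_dir, "scores.tsv"), sep = "\t")
  }
  manifest <- config[setdiff(names(config), character(0))]
  manifest$package_version <- as.character(utils::packageVersion("scdemon"))
  manifest$n_cells <- nrow(x$values)
  manifest$n_genes_used <- ncol(x$values)
  manifest$n_modules <- length(modules$modules)
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  message(sprintf("[done] %.1f s -> %s",
                  as.numeric(difftime(Sys.time(), t0, units = "secs")),
                  config$out_dir))
  invisible(list(modules = modules, graphs = graphs, zmats = zmats,
                 scores = scores, out_dir = config$out_dir, x = x))
}
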