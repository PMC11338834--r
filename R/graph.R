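#' Build a thresholded gene-gene graph from averaged z-scores
#'
#' An edge connects genes `i` and `j` iff `z[i, j] > z_cut` (strict). Connected
#' components with fewer than `min_component` genes are removed, as are
#' isolated genes. An empty result is valid and returned with a warning.
#'
#' @param z an `scd_zmat`.
#' @param z_cut z-score threshold (default 4.5).
#' @param min_component minimum component size kept (default 4).
#' @param p eigenvalue power label attached to the graph (taken from the
#'   z matrix provenance when `NULL`).
#' @return object of class `scd_graph` wrapping an igraph graph whose edges
#'   carry the averaged z as `weight`.
#' @export
build_graph <- function(z, z_cut = 4.5, min_component = 4L, p = NULL) {
  stopifnot(inherits(z, "scd_zmat"))
  if (is.null(p)) p <- z$provenance$p
  ut <- which(upper.tri(z$z) & is.finite(z$z) & z$z > z_cut,
              arr.ind = TRUE, useNames = FALSE)
  if (nrow(ut) == 0L) {
    warning("no gene pairs above z = ", z_cut, "; empty graph")
    g <- igraph::make_empty_graph(0, directed = FALSE)
    return(structure(list(graph = g, p = p, z_cut = z_cut, layout = NULL),
                     class = "scd_graph"))
  }
  el <- cbind(z$gene_ids[ut[, 1]], z$gene_ids[ut[, 2]])
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::E(g)$weight <- z$z[ut]
  comp <- igraph::components(g)
  keep <- which(comp$csize[comp$membership] >= min_component)
  g <- igraph::induced_subgraph(g, keep)
  if (igraph::vcount(g) == 0L)
    warning("all components below ", min_component, " genes; empty graph")
  structure(list(graph = g, p = p, z_cut = z_cut, layout = NULL),
            class = "scd_graph")
}

#' @export
print.scd_graph <- function(x, ...) {
  cat(sprintf("<scd_graph> p = %s: %d genes, %d edges (z > %s)\n",
              format(x$p), igraph::vcount(x$graph), igraph::ecount(x$graph),
              format(x$z_cut)))
  invisible(x)
}

#' Lay out a gene graph with the Fruchterman-Reingold algorithm
#'
#' @param graph an `scd_graph` (non-empty).
#' @param seed integer seed; the same seed reproduces identical coordinates.
#' @return the graph with a `layout` matrix (genes x 2, rownames = gene ids).
#' @export
layout_graph <- function(graph, seed = 1L) {
  stopifnot(inherits(graph, "scd_graph"))
  if (igraph::vcount(graph$graph) == 0L) stop("cannot lay out an empty graph")
  coords <- withr::with_seed(as.integer(seed), {
    igraph::layout_with_fr(graph$graph)
  })
  rownames(coords) <- igraph::V(graph$graph)$name
  colnames(coords) <- c("x", "y")
  graph$layout <- coords
  graph
}

# ---- multiplex community detection ----------------------------------------

# Per-layer RBConfiguration quality, summed over layers with equal weights:
#   Q = sum_l sum_{ij} (A^l_ij - gamma * k^l_i k^l_j / (2 m^l)) delta(c_i, c_j)
# counting ordered pairs. Optimized by seeded multilevel local moving
# (Louvain/Leiden scheme: move phase, then aggregation, repeated).

# layers: list of list(edges = matrix[i, j] 1-based ints, w = weights)
# over n union vertices. Returns integer membership.
multiplex_louvain <- function(layers, n, gamma = 1, seed = 1L,
                              max_outer = 10L) {
  # current partition of original nodes
  node2comm <- seq_len(n)
  # current aggregated layers (start = input with unit structure)
  agg <- lapply(layers, function(l) list(edges = l$edges, w = l$w,
                                         self = numeric(n)))
  n_cur <- n
  map_total <- seq_len(n)                 # original node -> current super node
  for (outer in seq_len(max_outer)) {
    mem <- local_moving(agg, n_cur, gamma, seed = as.integer(seed) + outer)
    mem <- match(mem, sort(unique(mem)))  # relabel 1..C deterministically
    map_total <- mem[map_total]
    if (length(unique(mem)) == n_cur) break
    # aggregate each layer
    n_cur <- max(mem)
    agg <- lapply(agg, function(l) aggregate_layer(l, mem, n_cur))
  }
  match(map_total, unique(map_total))
}

local_moving <- function(agg, n, gamma, seed) {
  nl <- length(agg)
  # adjacency lists and degrees per layer
  adj <- vector("list", nl); deg <- vector("list", nl); m2 <- numeric(nl)
  selfw <- vector("list", nl)
  for (l in seq_len(nl)) {
    e <- agg[[l]]$edges; w <- agg[[l]]$w
    d <- numeric(n)
    if (nrow(e)) {
      d <- d + rowsum_fill(w, e[, 1], n) + rowsum_fill(w, e[, 2], n)
    }
    d <- d + 2 * agg[[l]]$self
    deg[[l]] <- d
    m2[l] <- sum(d)                      # 2m for the layer
    nb_i <- c(e[, 1], e[, 2]); nb_j <- c(e[, 2], e[, 1]); nb_w <- c(w, w)
    o <- order(nb_i)
    adj[[l]] <- list(start = c(0L, cumsum(tabulate(nb_i[o], n))),
                     j = nb_j[o], w = nb_w[o])
    selfw[[l]] <- agg[[l]]$self
  }
  mem <- seq_len(n)
  ctot <- lapply(deg, function(d) d)      # per-layer community degree sums
  improved <- TRUE; pass <- 0L
  order_nodes <- withr::with_seed(seed, sample.int(n))
  while (improved && pass < 20L) {
    improved <- FALSE; pass <- pass + 1L
    for (v in order_nodes) {
      cv <- mem[v]
      # candidate communities: those of neighbors in any layer
      cand <- integer(0)
      wlinks <- vector("list", nl)
      for (l in seq_len(nl)) {
        a <- adj[[l]]
        idx <- if (a$start[v] < a$start[v + 1L]) (a$start[v] + 1L):a$start[v + 1L] else integer(0)
        nbc <- mem[a$j[idx]]
        wlinks[[l]] <- list(comm = nbc, w = a$w[idx])
        cand <- c(cand, nbc)
      }
      cand <- sort(unique(c(cand, cv)))
      if (length(cand) == 1L) next
      # gain of placing v in community d (relative to singleton), per layer
      gain <- numeric(length(cand))
      for (l in seq_len(nl)) {
        if (m2[l] == 0) next
        wl <- numeric(length(cand))
        if (length(wlinks[[l]]$comm)) {
          agg_w <- rowsum(wlinks[[l]]$w, match(wlinks[[l]]$comm, cand))
          wl[as.integer(rownames(agg_w))] <- agg_w[, 1]
        }
        kd <- deg[[l]][v]
        ct <- ctot[[l]][cand]
        ct[cand == cv] <- ct[cand == cv] - kd   # community totals without v
        gain <- gain + 2 * wl - gamma * 2 * kd * ct / m2[l]
      }
      best <- which(gain == max(gain))
      d <- cand[best[1L]]                 # ties: smallest community id
      if (d != cv) {
        for (l in seq_len(nl)) {
          ctot[[l]][cv] <- ctot[[l]][cv] - deg[[l]][v]
          ctot[[l]][d] <- ctot[[l]][d] + deg[[l]][v]
        }
        mem[v] <- d
        improved <- TRUE
      }
    }
  }
  mem
}

aggregate_layer <- function(l, mem, n_new) {
  e <- l$edges; w <- l$w
  self_new <- numeric(n_new)
  if (length(l$self)) self_new <- self_new + rowsum_fill(l$self, mem[seq_along(l$self)], n_new)
  if (nrow(e)) {
    ci <- mem[e[, 1]]; cj <- mem[e[, 2]]
    internal <- ci == cj
    if (any(internal))
      self_new <- self_new + rowsum_fill(w[internal], ci[internal], n_new)
    lo <- pmin(ci[!internal], cj[!internal]); hi <- pmax(ci[!internal], cj[!internal])
    if (length(lo)) {
      key <- (lo - 1) * n_new + hi
      uw <- rowsum(w[!internal], key)
      k <- as.numeric(rownames(uw))
      e_new <- cbind(as.integer((k - 1) %/% n_new) + 1L,
                     as.integer((k - 1) %% n_new) + 1L)
      return(list(edges = e_new, w = uw[, 1], self = self_new))
    }
  }
  list(edges = matrix(integer(0), 0, 2), w = numeric(0), self = self_new)
}

# Multiplex RBConfiguration quality for a membership vector (ordered pairs,
# i = j null terms included; they are partition-independent). Used by tests.
multiplex_quality <- function(layers, n, membership, gamma = 1) {
  q <- 0
  for (l in layers) {
    e <- l$edges; w <- l$w
    d <- rowsum_fill(w, e[, 1], n) + rowsum_fill(w, e[, 2], n)
    m2 <- sum(d)
    if (m2 == 0) next
    internal <- membership[e[, 1]] == membership[e[, 2]]
    ctot <- rowsum_fill(d, membership, max(membership))
    q <- q + 2 * sum(w[internal]) - gamma * sum(ctot^2) / m2
  }
  q
}

#' Call gene modules by multigraph community detection
#'
#' Combines the thresholded graphs computed at several eigenvalue powers into
#' one multiplex clustering problem over the union gene set: the
#' RBConfiguration quality (configuration null with resolution parameter) is
#' summed across layers with equal weights and optimized by seeded multilevel
#' local moving (Leiden/Louvain scheme). Genes absent from a layer contribute
#' no edges there. Modules with fewer than `min_report_size` genes are kept in
#' the assignment with a sub-threshold flag but excluded from the reported set.
#'
#' @param graphs list of `scd_graph` (one per power).
#' @param resolution RBConfiguration resolution parameter (default 3).
#' @param min_report_size minimum reported module size (default 10).
#' @param seed integer seed; clustering is deterministic given the seed.
#' @return object of class `scd_modules`: `modules` (named list of gene
#'   vectors, reported only), `assignment` (named module id per gene over the
#'   union set), `sub_threshold` (logical per module id), `resolution`,
#'   `powers_used`, `min_report_size`, `core_genes` (empty until
#'   [define_core_genes()]).
#' @export
multigraph_leiden <- function(graphs, resolution = 3, min_report_size = 10L,
                              seed = 1L) {
  stopifnot(length(graphs) >= 1L)
  graphs <- Filter(function(g) igraph::vcount(g$graph) > 0L, graphs)
  if (!length(graphs)) {
    return(structure(list(modules = list(), assignment = character(0),
                          sub_threshold = logical(0), resolution = resolution,
                          powers_used = numeric(0),
                          min_report_size = as.integer(min_report_size),
                          core_genes = list()),
                     class = "scd_modules"))
  }
  nodes <- sort(unique(unlist(lapply(graphs, function(g) igraph::V(g$graph)$name))))
  n <- length(nodes)
  layers <- lapply(graphs, function(g) {
    el <- igraph::as_edgelist(g$graph, names = TRUE)
    edges <- cbind(match(el[, 1], nodes), match(el[, 2], nodes))
    list(edges = edges, w = rep(1, nrow(edges)))   # binary adjacency layers
  })
  mem <- multiplex_louvain(layers, n, gamma = resolution, seed = seed)
  # order modules by decreasing size, ties by smallest member gene id
  sizes <- tabulate(mem)
  first_gene <- vapply(seq_len(max(mem)),
                       function(c) min(nodes[mem == c]), character(1))
  ord <- order(-sizes, first_gene)
  relab <- match(mem, ord)
  ids <- paste0("M", seq_along(ord))
  assignment <- stats::setNames(ids[relab], nodes)
  modules_all <- split(nodes, assignment)
  modules_all <- modules_all[order(as.integer(sub("^M", "", names(modules_all))))]
  sub_thr <- vapply(modules_all, function(gs) length(gs) < min_report_size,
                    logical(1))
  structure(list(modules = modules_all[!sub_thr],
                 assignment = assignment,
                 sub_threshold = sub_thr,
                 resolution = resolution,
                 powers_used = vapply(graphs, function(g) as.numeric(g$p), numeric(1)),
                 min_report_size = as.integer(min_report_size),
                 core_genes = list()),
            class = "scd_modules")
}

#' @export
print.scd_modules <- function(x, ...) {
  cat(sprintf("<scd_modules> %d reported modules (>= %d genes) over %d genes; resolution = %s\n",
              length(x$modules), x$min_report_size, length(x$assignment),
              format(x$resolution)))
  invisible(x)
}

#' Identify core genes per module by within-module weighted degree
#'
#' Members of each reported module are ranked by their summed within-module
#' edge weight (averaged z) across all layers; the top
#' `ceil(top_fraction * size)` genes (at least `min_core`, ties broken
#' lexicographically by gene id) form the module core.
#'
#' @param modules an `scd_modules` object.
#' @param graphs the `scd_graph` list the modules were called on.
#' @param top_fraction fraction of members kept as core (default 0.5).
#' @param min_core minimum core size (default 5, capped at module size).
#' @return `modules` with `core_genes` filled in.
#' @export
define_core_genes <- function(modules, graphs, top_fraction = 0.5,
                              min_core = 5L) {
  stopifnot(inherits(modules, "scd_modules"))
  wdeg_tabs <- lapply(graphs, function(g) {
    if (igraph::vcount(g$graph) == 0L) return(NULL)
    el <- igraph::as_edgelist(g$graph, names = TRUE)
    data.table::data.table(i = el[, 1], j = el[, 2],
                           w = igraph::E(g$graph)$weight)
  })
  edges <- data.table::rbindlist(Filter(Negate(is.null), wdeg_tabs))
  modules$core_genes <- lapply(modules$modules, function(gs) {
    wd <- stats::setNames(numeric(length(gs)), gs)
    if (nrow(edges)) {
      within <- edges[edges$i %in% gs & edges$j %in% gs, ]
      if (nrow(within)) {
        add <- rowsum(c(within$w, within$w), c(within$i, within$j))
        wd[rownames(add)] <- wd[rownames(add)] + add[, 1]
      }
    }
    ord <- order(-wd, names(wd))
    n_core <- min(length(gs), max(as.integer(min_core),
                                  ceiling(top_fraction * length(gs))))
    sort(names(wd)[ord[seq_len(n_core)]])
  })
  modules
}

#' Write modules to disk
#'
#' Writes a GMT file (module id, description, member genes) and a long TSV
#' (gene, module, is_core, sub_threshold).
#'
#' @param modules an `scd_modules` object.
#' @param dir output directory.
#' @param all_assignments include sub-threshold modules in the TSV.
#' @return invisibly, the file paths.
#' @export
write_modules <- function(modules, dir, all_assignments = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gmt <- file.path(dir, "modules.gmt")
  lines <- vapply(names(modules$modules), function(m) {
    paste(c(m, sprintf("module_%d_genes", length(modules$modules[[m]])),
            modules$modules[[m]]), collapse = "\t")
  }, character(1))
  writeLines(lines, gmt)
  ids <- names(modules$assignment)
  mod <- unname(modules$assignment)
  keep <- if (all_assignments) rep(TRUE, length(ids)) else mod %in% names(modules$modules)
  core <- unlist(modules$core_genes, use.names = FALSE)
  tab <- data.table::data.table(gene = as.character(ids[keep]),
                                module = as.character(mod[keep]),
                                is_core = ids[keep] %in% core,
                                sub_threshold = as.logical(modules$sub_threshold[mod[keep]]))
  if (nrow(tab)) data.table::setorder(tab, module, gene)
  tsv <- file.path(dir, "modules.tsv")
  data.table::fwrite(tab, tsv, sep = "\t")
  invisible(c(gmt, tsv))
}
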