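test_that("graph construction thresholds strictly and prunes components", {
  # 5-clique plus an isolated 2-gene pair: the pair is below min_component
  z <- clique_z(c(5, 2), z_in = 5)
  z$z[6, 7] <- z$z[7, 6] <- 6
  g <- build_graph(z, z_cut = 4.5, min_component = 4)
  expect_setequal(igraph::V(g$graph)$name, z$gene_ids[1:5])
  expect_equal(igraph::ecount(g$graph), 10)
  # z_cut above every entry gives a valid empty graph
  expect_warning(ge <- build_graph(z, z_cut = Inf), "empty")
  expect_equal(igraph::vcount(ge$graph), 0)
  # edges equal the brute-force double loop over the upper triangle
  withr::with_seed(44, {
    m <- matrix(rnorm(20 * 20, sd = 3), 20, 20)
  })
  m <- (m + t(m)) / 2
  zr <- zmat_from(m, sprintf("r%02d", 1:20))
  gr <- suppressWarnings(build_graph(zr, z_cut = 3, min_component = 1))
  got <- apply(igraph::as_edgelist(gr$graph), 1,
               function(e) paste(sort(e), collapse = "|"))
  want <- character(0)
  for (i in 1:19) for (j in (i + 1):20) {
    if (m[i, j] > 3) want <- c(want, paste(zr$gene_ids[i], zr$gene_ids[j],
                                           sep = "|"))
  }
  expect_setequal(got, want)
})

test_that("raising the threshold never adds edges or modules", {
  withr::with_seed(45, {
    m <- matrix(rnorm(30 * 30, mean = 2, sd = 2), 30, 30)
  })
  m <- (m + t(m)) / 2
  z <- zmat_from(m, sprintf("m%02d", 1:30))
  g_lo <- suppressWarnings(build_graph(z, z_cut = 4.5, min_component = 1))
  g_hi <- suppressWarnings(build_graph(z, z_cut = 6, min_component = 1))
  e_lo <- apply(igraph::as_edgelist(g_lo$graph), 1,
                function(e) paste(sort(e), collapse = "|"))
  e_hi <- apply(igraph::as_edgelist(g_hi$graph), 1,
                function(e) paste(sort(e), collapse = "|"))
  expect_true(all(e_hi %in% e_lo))
  m_lo <- suppressWarnings(multigraph_leiden(list(build_graph(z, 4.5)),
                                             resolution = 1, seed = 1))
  m_hi <- suppressWarnings(multigraph_leiden(list(build_graph(z, 6)),
                                             resolution = 1, seed = 1))
  expect_lte(length(m_hi$modules), length(m_lo$modules))
})

test_that("layout is deterministic and respects graph distances", {
  z <- clique_z(c(6, 6), z_in = 6)
  g <- build_graph(z)
  g1 <- layout_graph(g, seed = 3)
  g2 <- layout_graph(g, seed = 3)
  expect_identical(g1$layout, g2$layout)
  expect_true(all(is.finite(g1$layout)))
  expect_equal(nrow(g1$layout), 12)
  # connected pairs sit closer than disconnected pairs on a 2-clique graph
  d <- as.matrix(dist(g1$layout))
  names_ <- rownames(g1$layout)
  in1 <- names_ %in% z$gene_ids[1:6]
  within <- c(d[in1, in1][upper.tri(d[in1, in1])],
              d[!in1, !in1][upper.tri(d[!in1, !in1])])
  across <- d[in1, !in1]
  expect_lt(mean(within), mean(across))
})

test_that("multigraph clustering recovers disconnected cliques", {
  z <- clique_z(c(12, 12), z_in = 6)
  g <- build_graph(z)
  m <- multigraph_leiden(list(g), resolution = 1, min_report_size = 10, seed = 2)
  expect_equal(sort(unname(lengths(m$modules))), c(12, 12))
  expect_setequal(m$modules[[1]], z$gene_ids[1:12])
  # partition property: every gene appears exactly once
  expect_equal(sort(names(m$assignment)), sort(z$gene_ids))
  expect_false(any(duplicated(names(m$assignment))))
  # agreement with the igraph Leiden reference on the same quality function
  ref <- igraph::cluster_leiden(g$graph, objective_function = "modularity",
                                resolution = 1)
  expect_equal(mclust::adjustedRandIndex(
    m$assignment[igraph::V(g$graph)$name],
    igraph::membership(ref)), 1)
})

test_that("duplicated layers give the same partition as a single layer", {
  z <- clique_z(c(11, 13, 10), z_in = 6)
  g <- build_graph(z)
  m1 <- multigraph_leiden(list(g), resolution = 1, seed = 4)
  m2 <- multigraph_leiden(list(g, g), resolution = 1, seed = 4)
  expect_identical(m1$assignment[sort(names(m1$assignment))],
                   m2$assignment[sort(names(m2$assignment))])
})

test_that("small communities are retained with a sub-threshold flag", {
  z <- clique_z(c(15, 6), z_in = 6)
  g <- build_graph(z)
  m <- multigraph_leiden(list(g), resolution = 1, min_report_size = 10, seed = 1)
  expect_equal(length(m$modules), 1L)       # only the 15-clique is reported
  expect_equal(sum(m$sub_threshold), 1L)    # the 6-clique is kept, flagged
  expect_equal(length(m$assignment), 21L)
  # empty input gives an empty module set
  me <- multigraph_leiden(list(suppressWarnings(build_graph(z, z_cut = Inf))))
  expect_equal(length(me$modules), 0L)
})

test_that("core genes rank by within-module weighted degree", {
  # 10-clique: all tied, lexicographic tie-break keeps the first five ids
  z <- clique_z(c(10), z_in = 6)
  g <- build_graph(z)
  m <- multigraph_leiden(list(g), resolution = 1, min_report_size = 10, seed = 1)
  m <- define_core_genes(m, list(g), top_fraction = 0.5)
  expect_identical(m$core_genes[[1]], sort(z$gene_ids)[1:5])
  # hub-and-spoke: hub has the highest weighted degree and is always in core
  ids <- sprintf("h%02d", 1:7)
  zm <- matrix(0, 7, 7)
  zm[1, 2:7] <- zm[2:7, 1] <- 6
  zm[2, 3] <- zm[3, 2] <- 5
  zh <- zmat_from(zm, ids)
  gh <- build_graph(zh, min_component = 4)
  mh <- multigraph_leiden(list(gh), resolution = 0.5, min_report_size = 5,
                          seed = 1)
  mh <- define_core_genes(mh, list(gh), top_fraction = 0.5)
  expect_true("h01" %in% mh$core_genes[[1]])
  # ranking equals the brute-force weighted degree
  wd <- sapply(ids, function(v) sum(zm[v == ids, ]))
  genes <- mh$modules[[1]]
  ord <- order(-wd[genes], genes)
  n_core <- max(5L, ceiling(0.5 * length(genes)))
  expect_setequal(mh$core_genes[[1]], genes[ord][seq_len(min(n_core, length(genes)))])
})

test_that("module outputs round-trip through the TSV writer", {
  z <- clique_z(c(12, 11), z_in = 6)
  g <- build_graph(z)
  m <- multigraph_leiden(list(g), resolution = 1, seed = 1)
  m <- define_core_genes(m, list(g))
  dir <- withr::local_tempdir()
  write_modules(m, dir)
  tab <- read.delim(file.path(dir, "modules.tsv"))
  expect_setequal(tab$gene, unlist(m$modules, use.names = FALSE))
  expect_equal(sum(tab$is_core), sum(lengths(m$core_genes)))
  gmt <- readLines(file.path(dir, "modules.gmt"))
  expect_equal(length(gmt), 2L)
})
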