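scored_fixture <- function(n = 60, seed = 51) {
  withr::with_seed(seed, {
    counts <- matrix(rpois(n * 12, 3), n, 12)
  })
  counts[1, ] <- 0
  x <- expr_matrix(counts, sprintf("g%02d", 1:12), sprintf("c%02d", 1:n),
                   data.frame(cell_id = sprintf("c%02d", 1:n),
                              batch_id = rep(c("b1", "b2", "b3"),
                                             length.out = n),
                              subtype = rep(c("s1", "s2"), length.out = n)))
  suppressWarnings(normalize_cells(x))
}

test_that("module scores equal per-cell means of member genes", {
  x <- scored_fixture()
  mods <- modules_from_list(list(M1 = c("g01", "g02", "g03"), M2 = "g07"))
  sc <- score_modules(x, mods)
  dense <- as.matrix(x$values)
  expect_equal(unname(sc$scores[, "M1"]),
               unname(rowMeans(dense[, c("g01", "g02", "g03")])))
  # one-gene module scores are that gene's normalized values
  expect_equal(unname(sc$scores[, "M2"]), unname(dense[, "g07"]))
  # genes absent from the matrix are dropped with a warning
  mods2 <- modules_from_list(list(M1 = c("g01", "zz")))
  expect_warning(sc2 <- score_modules(x, mods2), "absent")
  expect_equal(unname(sc2$scores[, 1]), unname(dense[, "g01"]))
})

test_that("hypergeometric enrichment matches exact tail summation", {
  # all instances on a toy population of 50
  for (case in list(c(3, 10, 50, 8), c(0, 10, 50, 8), c(8, 20, 50, 12))) {
    expect_equal(scdemon:::hyper_upper(case[1], case[2], case[3], case[4]),
                 hyper_tail_sum(case[1], case[2], case[3], case[4]),
                 tolerance = 1e-12)
  }
  # exhaustive over a small grid (populations <= 60)
  for (N in c(20, 60)) for (K in c(5, 11)) for (nd in c(4, 9)) {
    for (q in 0:min(K, nd)) {
      expect_equal(scdemon:::hyper_upper(q, K, N, nd),
                   hyper_tail_sum(q, K, N, nd), tolerance = 1e-10)
    }
  }
})

test_that("covariate enrichment flags an exclusively expressed module", {
  n <- 200; g <- 20
  withr::with_seed(52, {
    counts <- matrix(rpois(n * g, 2), n, g)
  })
  lv <- rep(c("A", "B"), times = c(40, 160))   # minority level carries the module
  counts[lv == "A", 1:3] <- counts[lv == "A", 1:3] + 30
  x <- expr_matrix(counts, sprintf("g%02d", 1:g), sprintf("c%03d", 1:n),
                   data.frame(cell_id = sprintf("c%03d", 1:n), batch_id = "b1",
                              region = lv))
  x <- normalize_cells(x)
  sc <- score_modules(x, modules_from_list(list(M1 = c("g01", "g02", "g03"))))
  tab <- enrich_covariate(sc, "region")
  pa <- tab$p_value[tab$level == "A"]
  expect_lt(pa, 1e-10)
  expect_true(tab$enriched[tab$level == "A"])
  expect_false(tab$enriched[tab$level == "B"])
})

test_that("covariate enrichment controls the null flag rate", {
  n <- 4000
  withr::with_seed(53, {
    scores <- matrix(rnorm(n * 60), n, 60,
                     dimnames = list(sprintf("c%04d", 1:n),
                                     sprintf("M%02d", 1:60)))
    lv <- sample(rep(c("A", "B"), each = n / 2))
  })
  sc <- structure(list(scores = scores, cell_ids = rownames(scores),
                       cell_meta = data.frame(cell_id = rownames(scores),
                                              batch_id = "b1", grp = lv)),
                  class = "scd_scores")
  tab <- enrich_covariate(sc, "grp", p_thresh = 1e-3)
  expect_lte(mean(tab$enriched), 0.01)
})

test_that("module network keeps real correlations and rejects noise", {
  # duplicated module: r = 1 edge survives
  n <- 300
  withr::with_seed(54, {
    base_score <- rnorm(n)
    noise <- matrix(rnorm(n * 2), n, 2)
  })
  scores <- cbind(M1 = base_score, M2 = base_score, M3 = noise[, 1],
                  M4 = noise[, 2])
  rownames(scores) <- sprintf("c%03d", 1:n)
  meta <- data.frame(cell_id = rownames(scores), batch_id = "b1",
                     sample = rep(sprintf("s%02d", 1:30), each = 10))
  sc <- structure(list(scores = scores, cell_ids = rownames(scores),
                       cell_meta = meta), class = "scd_scores")
  net <- module_module_network(sc, "sample", alpha = 0.01)
  expect_true(any(net$module_a == "M1" & net$module_b == "M2"))
  expect_equal(net$r[net$module_a == "M1" & net$module_b == "M2"], 1,
               tolerance = 1e-10)
  expect_false(any(net$module_a == "M3" & net$module_b == "M4"))
})

test_that("aggregated correlations equal the textbook Pearson formula", {
  # 5 groups, computed by hand on the aggregated, logged table
  scores <- cbind(M1 = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10),
                  M2 = c(2, 1, 4, 3, 7, 6, 9, 8, 12, 11))
  rownames(scores) <- sprintf("c%02d", 1:10)
  meta <- data.frame(cell_id = rownames(scores), batch_id = "b1",
                     grp = rep(sprintf("g%d", 1:5), each = 2))
  sc <- structure(list(scores = scores, cell_ids = rownames(scores),
                       cell_meta = meta), class = "scd_scores")
  net <- module_module_network(sc, "grp", alpha = 1)
  agg <- apply(scores, 2, function(v) tapply(v, meta$grp, mean))
  lg <- log(agg - min(agg) + 1)
  r_hand <- sum((lg[, 1] - mean(lg[, 1])) * (lg[, 2] - mean(lg[, 2]))) /
    sqrt(sum((lg[, 1] - mean(lg[, 1]))^2) * sum((lg[, 2] - mean(lg[, 2]))^2))
  expect_equal(net$r[1], r_hand, tolerance = 1e-12)
})

test_that("null module pairs rarely form network edges", {
  hits <- vapply(1:20, function(s) {
    withr::with_seed(500 + s, {
      scores <- matrix(rnorm(400 * 2), 400, 2,
                       dimnames = list(sprintf("c%03d", 1:400), c("M1", "M2")))
    })
    meta <- data.frame(cell_id = rownames(scores), batch_id = "b1",
                       grp = rep(sprintf("s%03d", 1:200), each = 2))
    sc <- structure(list(scores = scores, cell_ids = rownames(scores),
                         cell_meta = meta), class = "scd_scores")
    nrow(module_module_network(sc, "grp", alpha = 0.01))
  }, numeric(1))
  expect_gte(mean(hits == 0), 0.95)
})

test_that("DEG assignment finds the home module and matches brute force", {
  cfg <- synthetic_config(n_cells = 500, n_genes = 80,
                          module_sizes = c(15L, 15L), n_batches = 2L,
                          seed = 61)
  sim <- generate_synthetic(cfg)
  x <- normalize_cells(sim$x)
  ma <- sim$truth$module_assignments
  mods <- modules_from_list(split(names(ma)[ma != "background"],
                                  ma[ma != "background"]))
  deg <- data.frame(gene_id = x$gene_ids,
                    category = rep("ns", length(x$gene_ids)))
  deg$category[match(mods$modules[[1]][1:8], deg$gene_id)] <- "up"
  res <- assign_degs_to_modules(deg, x, mods)
  # module members land in their own module
  members <- res$assignment[res$assignment$gene_id %in% mods$modules[[1]], ]
  expect_gte(mean(members$module_id == names(mods$modules)[1]), 0.9)
  # assignment equals the brute-force correlation argmax
  dense <- as.matrix(x$values)
  prof <- sapply(mods$modules, function(gs) rowMeans(dense[, gs]))
  for (gi in sample(res$assignment$gene_id, 10)) {
    cors <- cor(dense[, gi], prof)
    expect_identical(res$assignment$module_id[res$assignment$gene_id == gi],
                     colnames(prof)[which.max(cors)])
  }
  # "up" genes enrich their module
  en <- res$enrichment
  row_up <- en[en$module_id == names(mods$modules)[1] & en$category == "up", ]
  expect_lt(row_up$adj_p, 0.01)
})

test_that("shuffled DEG labels control the enrichment rate", {
  cfg <- synthetic_config(n_cells = 300, n_genes = 60,
                          module_sizes = c(12L, 12L), n_batches = 2L,
                          seed = 62)
  sim <- generate_synthetic(cfg)
  x <- normalize_cells(sim$x)
  ma <- sim$truth$module_assignments
  mods <- modules_from_list(split(names(ma)[ma != "background"],
                                  ma[ma != "background"]))
  rates <- vapply(1:25, function(s) {
    withr::with_seed(700 + s, {
      cat_ <- sample(rep(c("up", "down", "ns"), length.out = length(x$gene_ids)))
    })
    deg <- data.frame(gene_id = x$gene_ids, category = cat_)
    en <- assign_degs_to_modules(deg, x, mods)$enrichment
    mean(en$adj_p < 0.05)
  }, numeric(1))
  expect_lte(mean(rates), 0.05 + 0.02)
})

test_that("BH adjustment is monotone in the raw p-value rank", {
  withr::with_seed(63, {
    p <- runif(40)^2
  })
  adj <- p.adjust(p, method = "BH")
  ord <- order(p)
  expect_true(all(diff(adj[ord]) >= -1e-15))
})

test_that("contour smoothing matches a direct convolution", {
  withr::with_seed(64, {
    coords <- matrix(runif(80 * 2), 80, 2)
    vals <- runif(80)
  })
  out <- smooth_contour(coords, vals, grid = 20, kernel = 5, sigma = 1)
  # direct double-loop convolution of the binned surface
  binned <- matrix(0, 20, 20)
  bx <- findInterval(coords[, 1], seq(min(coords[, 1]), max(coords[, 1]),
                                      length.out = 21),
                     rightmost.closed = TRUE, all.inside = TRUE)
  by <- findInterval(coords[, 2], seq(min(coords[, 2]), max(coords[, 2]),
                                      length.out = 21),
                     rightmost.closed = TRUE, all.inside = TRUE)
  for (cell in unique(paste(bx, by))) {
    sel <- paste(bx, by) == cell
    ij <- as.integer(strsplit(cell, " ")[[1]])
    binned[ij[1], ij[2]] <- mean(vals[sel])
  }
  k1 <- exp(-(-2:2)^2 / 2); k1 <- k1 / sum(k1)
  kern <- outer(k1, k1)
  direct <- matrix(0, 20, 20)
  for (i in 1:20) for (j in 1:20) {
    acc <- 0
    for (a in -2:2) for (b in -2:2) {
      ii <- i + a; jj <- j + b
      if (ii >= 1 && ii <= 20 && jj >= 1 && jj <= 20)
        acc <- acc + kern[a + 3, b + 3] * binned[ii, jj]
    }
    direct[i, j] <- acc
  }
  expect_equal(out$surface, direct, tolerance = 1e-12)
})

test_that("contour smoothing handles degenerate inputs", {
  # a single occupied bin produces a Gaussian bump peaking there
  coords <- rbind(c(0.5, 0.5), c(0.5, 0.5))
  out <- smooth_contour(coords, c(1, 1), grid = 21, kernel = 5, sigma = 1)
  peak <- which(out$surface == max(out$surface), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(11, 11))
  # constant values over a fully occupied region give a constant interior
  coords2 <- as.matrix(expand.grid(x = seq(0.05, 0.95, length.out = 10),
                                   y = seq(0.05, 0.95, length.out = 10)))
  out2 <- smooth_contour(coords2, rep(2, nrow(coords2)), grid = 10,
                         kernel = 3, sigma = 1)
  interior <- out2$surface[3:8, 3:8]
  expect_equal(max(interior) - min(interior), 0, tolerance = 1e-6)
})
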