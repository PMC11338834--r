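# Small in-code fixtures shared across test files.

# tiny raw-count expression object with b batches
tiny_expr <- function(n = 20, g = 10, seed = 1, n_batches = 2,
                      normalized = FALSE) {
  withr::with_seed(seed, {
    counts <- matrix(rpois(n * g, lambda = 2), n, g)
  })
  expr_matrix(counts,
              gene_ids = sprintf("g%02d", seq_len(g)),
              cell_ids = sprintf("c%02d", seq_len(n)),
              cell_meta = data.frame(
                cell_id = sprintf("c%02d", seq_len(n)),
                batch_id = rep_len(paste0("b", seq_len(n_batches)), n),
                cell_type = rep_len(c("A", "B"), n)),
              normalized = normalized)
}

# z matrix object from a dense symmetric matrix
zmat_from <- function(m, ids = sprintf("g%02d", seq_len(nrow(m))), p = 0) {
  dimnames(m) <- list(ids, ids)
  diag(m) <- NA_real_
  structure(list(z = m, gene_ids = ids,
                 provenance = list(p = p, n_boot = 1L, seed = 1L)),
            class = "scd_zmat")
}

# block-diagonal z matrix: cliques of given sizes at z_in, background z_out
clique_z <- function(sizes, z_in = 6, z_out = 0, prefix = "g") {
  n <- sum(sizes)
  ids <- sprintf("%s%03d", prefix, seq_len(n))
  m <- matrix(z_out, n, n)
  at <- 0
  for (s in sizes) {
    idx <- at + seq_len(s)
    m[idx, idx] <- z_in
    at <- at + s
  }
  zmat_from(m, ids)
}

# upper-tail hypergeometric by direct summation (oracle)
hyper_tail_sum <- function(q, K, N, n_draw) {
  ks <- q:min(K, n_draw)
  sum(choose(K, ks) * choose(N - K, n_draw - ks)) / choose(N, n_draw)
}

# minimal scd_modules object from a named list of gene vectors
modules_from_list <- function(lst) {
  assignment <- stats::setNames(rep(names(lst), lengths(lst)),
                                unlist(lst, use.names = FALSE))
  structure(list(modules = lst, assignment = assignment,
                 sub_threshold = stats::setNames(rep(FALSE, length(lst)),
                                                 names(lst)),
                 resolution = 1, powers_used = 0,
                 min_report_size = 1L, core_genes = list()),
            class = "scd_modules")
}

# run the installed CLI script in a child process that inherits this
# session's library paths; returns captured output (capture = TRUE) or the
# exit status (capture = FALSE)
run_cli <- function(args, capture = TRUE) {
  script <- system.file("cli", "scdemon.R", package = "scdemon")
  withr::with_envvar(
    c(R_LIBS = paste(.libPaths(), collapse = .Platform$path.sep)), {
      if (capture) {
        suppressWarnings(system2("Rscript", c(script, args), stdout = TRUE,
                                 stderr = TRUE))
      } else {
        suppressWarnings(system2("Rscript", c(script, args), stdout = FALSE,
                                 stderr = FALSE))
      }
    })
}

# minimal truth object from a named gene -> module vector
truth_from_assignments <- function(ma) {
  structure(list(module_assignments = ma, cell_types = character(0),
                 activity = NULL, batch_factors = NULL,
                 nb_dispersion = 1, seed = 0L, config = NULL),
            class = "scd_truth")
}
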