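# Shared fixtures, memoized so expensive objects are built once per run.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

tiny_cfg <- function(seed = 42L) {
  synth_config(n_drugs = 10L, n_cell_lines = 8L, n_combinations = 160L,
               n_genes = 24L, n_proteins = 48L, n_clusters = 2L,
               signature_size = 12L, gene_signature_size = 6L, seed = seed)
}

tiny_dataset <- function() memo("tiny_dataset", gen_dataset(tiny_cfg()))

tiny_bundle <- function() {
  memo("tiny_bundle", dataset_to_bundle(tiny_dataset(), fp_bits = 256L))
}

tiny_model_config <- function(...) {
  args <- list(variant = "gatfp", task = "classification",
               graph_dim = 8L, graph_layers = 2L, gat_heads = 2L,
               fp_dim = 8L, fp_bits = 256L, omics_dim = 8L,
               head_dims = c(16L, 8L), dropout = 0.1, lr = 5e-3,
               max_epochs = 25L, seed = 11L)
  do.call(synergraph_config, utils::modifyList(args, list(...)))
}

tiny_trained <- function() {
  memo("tiny_trained", {
    b <- tiny_bundle()
    plan <- make_split(b$records, "random", seed = 7L)
    list(fit = train_model(b, plan, tiny_model_config()), plan = plan)
  })
}

# One full-scale planted-signal experiment shared by the acceptance blocks.
acceptance_experiment <- function() {
  memo("acceptance_experiment", planted_signal_experiment(seed = 1L))
}

# Random undirected graph with no isolated guarantees beyond >= 1 node.
random_graph <- function(n, d_feat = 3L, p_edge = 0.5) {
  A <- matrix(0, n, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (stats::runif(1) < p_edge) A[i, j] <- A[j, i] <- 1
    }
  }
  ed <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
  list(H = matrix(stats::rnorm(n * d_feat), n, d_feat), A = A,
       edges = ed[, c(1, 2), drop = FALSE], n = n)
}

# Independent dense GAT oracle: explicit double loop over nodes/neighbors.
gat_oracle <- function(H, edges, W, a, slope = 0.2, act = identity) {
  n <- nrow(H)
  d <- ncol(W)
  nbr <- lapply(seq_len(n), function(u) u)  # self-loops
  for (k in seq_len(nrow(edges))) {
    u <- edges[k, 1]; w <- edges[k, 2]
    nbr[[u]] <- c(nbr[[u]], w)
    nbr[[w]] <- c(nbr[[w]], u)
  }
  Wh <- H %*% W
  out <- matrix(0, n, d)
  for (u in seq_len(n)) {
    e <- sapply(nbr[[u]], function(w) {
      v <- sum(a[1:d] * Wh[u, ]) + sum(a[(d + 1):(2 * d)] * Wh[w, ])
      if (v > 0) v else slope * v
    })
    al <- exp(e - max(e)); al <- al / sum(al)
    for (k in seq_along(nbr[[u]])) {
      out[u, ] <- out[u, ] + al[k] * Wh[nbr[[u]][k], ]
    }
  }
  act(out)
}
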