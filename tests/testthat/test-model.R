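# Model assembly: per-drug encoding, omics embedding, fusion head,
# batched forward pass, ablation semantics, checkpointing.

micro_config <- function(...) {
  args <- list(variant = "gatfp", graph_dim = 8L, graph_layers = 2L,
               gat_heads = 2L, fp_dim = 4L, fp_bits = 64L,
               omics_dim = 4L, head_dims = c(6L, 3L), dropout = 0,
               seed = 3L)
  do.call(synergraph_config, utils::modifyList(args, list(...)))
}

micro_params <- function(cfg = micro_config(), n_genes = 5L,
                         n_proteins = 7L) {
  init_synergraph_params(cfg, n_genes = n_genes, n_proteins = n_proteins)
}

test_that("variant/fingerprint mismatches raise a config error", {
  expect_error(synergraph_config(variant = "gat", use_fingerprint = TRUE),
               "config error")
  expect_error(synergraph_config(variant = "gatfp", graph_dim = 30L,
                                 gat_heads = 4L),
               "config error")
  expect_s3_class(synergraph_config(variant = "gat"), "synergraph_config")
})

test_that("per-drug embeddings have the width implied by the variant", {
  g <- smiles_to_graph("CCO")
  f <- smiles_to_fingerprint("CCO", d = 64L)
  cfg <- micro_config()
  p <- micro_params(cfg)
  h <- encode_drug(g, f, p, cfg)
  expect_equal(dim(h), c(1L, 8L + 4L))  # graph + fingerprint widths

  cfg_gat <- synergraph_config(variant = "gat", graph_dim = 8L,
                               graph_layers = 2L, gat_heads = 2L,
                               omics_dim = 4L, head_dims = c(6L, 3L),
                               seed = 3L)
  p_gat <- init_synergraph_params(cfg_gat, 5L, 7L)
  expect_equal(dim(encode_drug(g, NULL, p_gat, cfg_gat)), c(1L, 8L))

  expect_error(encode_drug(g, NULL, p, cfg), "config error")
})

test_that("a zero fingerprint map leaves only its bias in the segment", {
  g <- smiles_to_graph("CCO")
  f <- smiles_to_fingerprint("CCO", d = 64L)
  cfg <- micro_config()
  p <- micro_params(cfg)
  p$fp$W[] <- 0
  p$fp$b[] <- 4.5
  h <- encode_drug(g, f, p, cfg)
  expect_equal(unname(h[1, 9:12]), rep(4.5, 4))
})

test_that("omics embeddings are the stated linear maps", {
  cfg <- micro_config(omics_dim = 3L)
  p <- micro_params(cfg, n_genes = 3L, n_proteins = 3L)
  p$gene$W <- diag(3)
  p$gene$b[] <- 0
  G <- c(0.2, -1, 4)
  om <- encode_omics(G, c(1, 1, 1), p, cfg)
  expect_equal(om$g_exp, matrix(G, 1))

  set.seed(9)
  W <- matrix(rnorm(9), 3, 3)
  b <- matrix(rnorm(3), 1)
  p$protein$W <- W
  p$protein$b <- b
  P <- c(2, 0.5, -1)
  om2 <- encode_omics(G, P, p, cfg)
  expect_equal(om2$p_exp, matrix(P, 1) %*% W + b)

  expect_error(encode_omics(c(1, 2), P, p, cfg), "dimension error")

  cfg_np <- micro_config(omics_dim = 3L, use_protein = FALSE)
  p_np <- micro_params(cfg_np, 3L, 3L)
  expect_equal(ncol(encode_omics(G, P, p_np, cfg_np)$p_exp), 0L)
})

test_that("the fusion head reproduces hand-computed forward passes", {
  cfg <- synergraph_config(variant = "gat", task = "classification",
                           use_gene = FALSE, use_protein = FALSE,
                           graph_dim = 2L, graph_layers = 1L,
                           head_dims = c(2L, 2L), dropout = 0, seed = 1L)
  p <- init_synergraph_params(cfg, 1L, 1L)
  # bias-only network: all weights zero, b3 = 0 -> p = 0.5
  p$head$W1[] <- 0; p$head$W2[] <- 0; p$head$W3[] <- 0
  p$head$b1[] <- 0; p$head$b2[] <- 0; p$head$b3[] <- 0
  out <- fuse_and_predict(matrix(c(1, 2), 1), matrix(c(3, 4), 1),
                          matrix(0, 1, 0), matrix(0, 1, 0), p, cfg)
  expect_equal(out$p[1, 1], 0.5)

  # tiny hand-set head on a 4-vector (h_A, h_B concatenated)
  p$head$W1 <- matrix(c(1, 0, 0, 1, -1, 0, 0, 0), 4, 2)
  p$head$b1 <- matrix(c(0.5, -0.5), 1)
  p$head$W2 <- matrix(c(1, 1, 0, 1), 2, 2)
  p$head$b2 <- matrix(0, 1, 2)
  p$head$W3 <- matrix(c(2, -1), 2, 1)
  p$head$b3 <- matrix(0.1, 1, 1)
  hAB <- c(1, 2, 3, 4)
  a1 <- pmax(c(sum(hAB * p$head$W1[, 1]) + 0.5,
               sum(hAB * p$head$W1[, 2]) - 0.5), 0)
  a2 <- pmax(c(a1 %*% p$head$W2[, 1], a1 %*% p$head$W2[, 2]), 0)
  z <- sum(a2 * c(2, -1)) + 0.1
  out2 <- fuse_and_predict(matrix(c(1, 2), 1), matrix(c(3, 4), 1),
                           matrix(0, 1, 0), matrix(0, 1, 0), p, cfg)
  expect_equal(out2$p[1, 1], 1 / (1 + exp(-z)), tolerance = 1e-12)

  # regression shares the trunk and drops the sigmoid
  cfg_r <- cfg; cfg_r$task <- "regression"
  out3 <- fuse_and_predict(matrix(c(1, 2), 1), matrix(c(3, 4), 1),
                           matrix(0, 1, 0), matrix(0, 1, 0), p, cfg_r)
  expect_equal(out3$y[1, 1], z, tolerance = 1e-12)
})

test_that("classification outputs stay in [0, 1] on random inputs", {
  cfg <- synergraph_config(variant = "gat", task = "classification",
                           use_gene = FALSE, use_protein = FALSE,
                           graph_dim = 3L, graph_layers = 1L,
                           head_dims = c(4L, 2L), dropout = 0, seed = 2L)
  p <- init_synergraph_params(cfg, 1L, 1L)
  set.seed(1)
  probs <- vapply(seq_len(1000), function(i) {
    fuse_and_predict(matrix(rnorm(3) * 10, 1), matrix(rnorm(3) * 10, 1),
                     matrix(0, 1, 0), matrix(0, 1, 0), p, cfg)$p[1, 1]
  }, numeric(1))
  expect_true(all(probs >= 0 & probs <= 1))
})

test_that("batched forward agrees with single-record composition", {
  tr <- tiny_trained()
  b <- synergraph:::apply_scaler(tiny_bundle(), tr$fit$scaler)
  cfg <- tr$fit$config
  p <- tr$fit$params
  idx <- 1:6
  batch <- forward_batch(b, p, cfg, idx)
  single <- vapply(idx, function(i) forward_batch(b, p, cfg, i), numeric(1))
  expect_equal(batch, single, tolerance = 1e-12)

  perm <- c(4, 2, 6, 1, 3, 5)
  expect_equal(forward_batch(b, p, cfg, idx[perm]), batch[perm],
               tolerance = 1e-12)
  dup <- forward_batch(b, p, cfg, c(3, 3))
  expect_equal(dup[1], dup[2])
})

test_that("the batched forward equals composing the numeric ops", {
  tr <- tiny_trained()
  b <- synergraph:::apply_scaler(tiny_bundle(), tr$fit$scaler)
  cfg <- tr$fit$config
  p <- tr$fit$params
  composed <- vapply(1:4, function(i) {
    r <- b$records[i, ]
    hA <- encode_drug(b$graphs[[r$drug_a]], b$fingerprints[[r$drug_a]], p, cfg)
    hB <- encode_drug(b$graphs[[r$drug_b]], b$fingerprints[[r$drug_b]], p, cfg)
    om <- encode_omics(b$gene_matrix[r$cell_line, ],
                       b$protein_matrix[r$cell_line, ], p, cfg)
    fuse_and_predict(hA, hB, om$g_exp, om$p_exp, p, cfg)$p[1, 1]
  }, numeric(1))
  expect_equal(forward_batch(b, p, cfg, 1:4), composed, tolerance = 1e-10)
})

test_that("forward errors name unresolvable identifiers", {
  tr <- tiny_trained()
  b <- synergraph:::apply_scaler(tiny_bundle(), tr$fit$scaler)
  b$graphs[[b$records$drug_a[1]]] <- NULL
  expect_error(forward_batch(b, tr$fit$params, tr$fit$config, 1L),
               "lookup error")
})

test_that("disabling a branch equals deleting its fusion segment", {
  cfg <- micro_config(fp_bits = 256L)  # the tiny bundle's fingerprint width
  b <- tiny_bundle()
  b <- synergraph:::apply_scaler(
    b, standardize_omics(b, rownames(b$gene_matrix))$scaler)
  p <- init_synergraph_params(cfg, ncol(b$gene_matrix),
                              ncol(b$protein_matrix))
  cfg_wo <- cfg
  cfg_wo$use_protein <- FALSE
  p_wo <- p
  p_wo$protein <- NULL
  # fusion order is (h_A, h_B, g_exp, p_exp): protein rows sit at the end
  keep <- seq_len(nrow(p$head$W1) - cfg$omics_dim)
  p_wo$head$W1 <- p$head$W1[keep, , drop = FALSE]
  full_with_zero_prot <- p
  full_with_zero_prot$protein$W[] <- 0
  full_with_zero_prot$protein$b[] <- 0
  full_with_zero_prot$head$W1[-keep, ] <- 0
  expect_equal(forward_batch(b, p_wo, cfg_wo, 1:5),
               forward_batch(b, full_with_zero_prot, cfg, 1:5),
               tolerance = 1e-10)
})

test_that("symmetrization makes predictions invariant to drug order", {
  tr <- tiny_trained()
  b <- synergraph:::apply_scaler(tiny_bundle(), tr$fit$scaler)
  cfg <- tr$fit$config
  cfg$symmetrize <- TRUE
  swapped <- b
  swapped$records[, c("drug_a", "drug_b")] <- b$records[, c("drug_b",
                                                            "drug_a")]
  swapped$records[, c("smiles_a", "smiles_b")] <- b$records[, c("smiles_b",
                                                                "smiles_a")]
  p1 <- forward_batch(b, tr$fit$params, cfg, 1:6)
  p2 <- forward_batch(swapped, tr$fit$params, cfg, 1:6)
  expect_equal(p1, p2, tolerance = 1e-6)
  # without symmetrization order sensitivity is a documented property
  cfg$symmetrize <- FALSE
  q1 <- forward_batch(b, tr$fit$params, cfg, 1:6)
  q2 <- forward_batch(swapped, tr$fit$params, cfg, 1:6)
  expect_false(isTRUE(all.equal(q1, q2, tolerance = 1e-12)))
})

test_that("checkpoints round-trip through the JSON archive", {
  tr <- tiny_trained()
  path <- withr::local_tempfile(fileext = ".json")
  save_model(tr$fit, path)
  back <- load_model(path)
  b <- tiny_bundle()
  expect_equal(predict(back, b, 1:8), predict(tr$fit, b, 1:8),
               tolerance = 1e-9)
  expect_error(load_model(file.path(tempdir(), "nope.json")),
               "config error")
})
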