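# Model variants: a graph encoder (GAT, GCN, or attentive fingerprint) per
# drug, optional fingerprint and omics linear branches, and a three-layer
# fusion head emitting either a synergy score (regression) or a synergism
# probability (classification).
#
#   h_A  = [z_A, f_A]              graph embedding (+ fingerprint for GATFP)
#   h_AB = [h_A, h_B, g_exp, p_exp]
#   out  = W3 act(W2 act(W1 h_AB + b1) + b2) + b3   (sigmoid for classification)

#' Model configuration
#'
#' Collects every architectural and training choice of a synergy model. The
#' defaults follow the reference architecture: 128-wide graph and fingerprint
#' embeddings, 256-wide omics embeddings, a 1024-512 fusion head with ReLU
#' and 0.2 dropout, 4 attention heads on hidden layers and 1 on the final
#' layer, mean pooling.
#'
#' @param variant `"gatfp"`, `"gat"`, `"gcn"`, or `"attfp"`. Only the GATFP
#'   variant consumes molecular fingerprints.
#' @param task `"regression"` (Loewe score) or `"classification"`
#'   (synergism probability).
#' @param graph_dim Graph embedding width.
#' @param graph_layers Number of encoder layers (GAT/GCN).
#' @param gat_heads Attention heads on hidden GAT layers (outputs are
#'   concatenated; the final layer uses a single head).
#' @param attfp_steps Message-passing rounds of the attentive-fingerprint
#'   encoder.
#' @param fp_dim Fingerprint embedding width; `fp_bits`, `fp_radius` control
#'   the fingerprint itself.
#' @param omics_dim Width of each omics embedding.
#' @param head_dims Widths of the two hidden fusion layers.
#' @param dropout Dropout rate after each hidden fusion layer (training
#'   only).
#' @param input_dropout Dropout rate on the raw omics input features during
#'   training; encourages reliance on redundant signal-carrying feature
#'   sets rather than individual sample-identifying features (default 0).
#' @param activation Hidden nonlinearity (default `"relu"`).
#' @param negative_slope LeakyReLU slope inside attention logits.
#' @param pooling Graph readout for GAT/GCN: `"mean"`, `"sum"`, `"max"`.
#' @param use_protein,use_gene,use_fingerprint Ablation switches; a disabled
#'   branch contributes nothing to the fusion vector.
#' @param symmetrize If `TRUE`, predictions average the (A,B) and (B,A)
#'   orders, making the model exactly invariant to drug order.
#' @param augment_swap If `TRUE`, training sees each record in both drug
#'   orders.
#' @param weight_decay Decoupled L2 penalty applied to weight matrices
#'   (not biases) at each optimizer step; regularizes the wide omics
#'   branches so that generalizable signal directions are preferred over
#'   sample-fingerprint directions (default 1e-4).
#' @param lr,max_epochs,patience,rise_limit,tol,val_fraction Optimizer and
#'   early-stopping settings: training stops when the validation loss has
#'   not improved by at least `tol` for `patience` consecutive epochs, or
#'   has strictly increased for `rise_limit` consecutive epochs.
#' @param min_epochs Burn-in epochs before early stopping and best-weight
#'   tracking engage (default 0); useful when weight decay reshapes the
#'   solution long after the validation loss has flattened.
#' @param seed Seed for weight initialization and dropout.
#' @return A `synergraph_config` list.
#' @export
synergraph_config <- function(variant = c("gatfp", "gat", "gcn", "attfp"),
                              task = c("classification", "regression"),
                              graph_dim = 128L, graph_layers = 2L,
                              gat_heads = 4L, attfp_steps = 2L,
                              fp_dim = 128L, fp_bits = 2048L, fp_radius = 3L,
                              omics_dim = 256L, head_dims = c(1024L, 512L),
                              dropout = 0.2, input_dropout = 0,
                              activation = "relu",
                              negative_slope = 0.2,
                              pooling = c("mean", "sum", "max"),
                              use_protein = TRUE, use_gene = TRUE,
                              use_fingerprint = NULL,
                              symmetrize = FALSE, augment_swap = FALSE,
                              weight_decay = 1e-4,
                              lr = 1e-3, max_epochs = 300L, min_epochs = 0L,
                              patience = 30L,
                              rise_limit = 10L, tol = 1e-4,
                              val_fraction = 0.1, seed = 1L) {
  variant <- match.arg(variant)
  task <- match.arg(task)
  pooling <- match.arg(pooling)
  if (is.null(use_fingerprint)) use_fingerprint <- variant == "gatfp"
  if (use_fingerprint && variant != "gatfp") {
    stop("config error: variant '", variant,
         "' has no fingerprint branch (only gatfp does)")
  }
  if (variant %in% c("gat", "gatfp") && graph_layers > 1L &&
      graph_dim %% gat_heads != 0L) {
    stop("config error: graph_dim must be divisible by gat_heads")
  }
  structure(list(
    variant = variant, task = task,
    graph_dim = as.integer(graph_dim), graph_layers = as.integer(graph_layers),
    gat_heads = as.integer(gat_heads), attfp_steps = as.integer(attfp_steps),
    fp_dim = as.integer(fp_dim), fp_bits = as.integer(fp_bits),
    fp_radius = as.integer(fp_radius),
    omics_dim = as.integer(omics_dim), head_dims = as.integer(head_dims),
    dropout = dropout, input_dropout = input_dropout,
    activation = activation,
    negative_slope = negative_slope, pooling = pooling,
    use_protein = isTRUE(use_protein), use_gene = isTRUE(use_gene),
    use_fingerprint = isTRUE(use_fingerprint),
    symmetrize = isTRUE(symmetrize), augment_swap = isTRUE(augment_swap),
    weight_decay = weight_decay,
    lr = lr, max_epochs = as.integer(max_epochs),
    min_epochs = as.integer(min_epochs),
    patience = as.integer(patience), rise_limit = as.integer(rise_limit),
    tol = tol, val_fraction = val_fraction, seed = as.integer(seed)
  ), class = "synergraph_config")
}

glorot <- function(fan_in, fan_out) {
  l <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -l, l), fan_in, fan_out)
}

gru_init <- function(d) {
  list(Wz = glorot(d, d), Uz = glorot(d, d), bz = matrix(0, 1L, d),
       Wr = glorot(d, d), Ur = glorot(d, d), br = matrix(0, 1L, d),
       Wh = glorot(d, d), Uh = glorot(d, d), bh = matrix(0, 1L, d))
}

#' Initialize model parameters
#'
#' Draws all learnable weights with fan-based uniform (Glorot) initialization
#' under the configuration's seed; biases start at zero.
#'
#' @param config A [synergraph_config()].
#' @param n_genes,n_proteins Omics input widths.
#' @param n_atom_features Atom feature width (75 for the built-in scheme).
#' @return A nested list of parameter matrices (class `synergraph_params`).
#' @export
init_synergraph_params <- function(config, n_genes, n_proteins,
                                   n_atom_features = 75L) {
  set.seed(config$seed)
  d <- config$graph_dim
  enc <- switch(config$variant,
    gcn = {
      dims <- c(n_atom_features, rep(d, config$graph_layers))
      list(layers = lapply(seq_len(config$graph_layers), function(l) {
        list(W = glorot(dims[l], dims[l + 1L]))
      }))
    },
    gat = ,
    gatfp = {
      L <- config$graph_layers
      layers <- vector("list", L)
      d_in <- n_atom_features
      for (l in seq_len(L)) {
        if (l < L) {
          hd <- d %/% config$gat_heads
          layers[[l]] <- list(
            heads = lapply(seq_len(config$gat_heads), function(h) {
              list(W = glorot(d_in, hd), a = stats::runif(2L * hd, -0.1, 0.1))
            }),
            combine = "concat"
          )
          d_in <- d
        } else {
          layers[[l]] <- list(
            heads = list(list(W = glorot(d_in, d),
                              a = stats::runif(2L * d, -0.1, 0.1))),
            combine = "mean"
          )
        }
      }
      list(layers = layers)
    },
    attfp = {
      list(
        W_in = glorot(n_atom_features, d), b_in = matrix(0, 1L, d),
        steps = lapply(seq_len(config$attfp_steps), function(k) {
          list(W = glorot(d, d), a = stats::runif(2L * d, -0.1, 0.1),
               gru = gru_init(d))
        })
      )
    }
  )

  drug_dim <- d + if (config$use_fingerprint) config$fp_dim else 0L
  fusion_dim <- 2L * drug_dim +
    (if (config$use_gene) config$omics_dim else 0L) +
    (if (config$use_protein) config$omics_dim else 0L)
  h1 <- config$head_dims[1L]; h2 <- config$head_dims[2L]

  params <- list(
    encoder = enc,
    fp = if (config$use_fingerprint) {
      list(W = glorot(config$fp_bits, config$fp_dim),
           b = matrix(0, 1L, config$fp_dim))
    },
    gene = if (config$use_gene) {
      list(W = glorot(n_genes, config$omics_dim),
           b = matrix(0, 1L, config$omics_dim))
    },
    protein = if (config$use_protein) {
      list(W = glorot(n_proteins, config$omics_dim),
           b = matrix(0, 1L, config$omics_dim))
    },
    head = list(W1 = glorot(fusion_dim, h1), b1 = matrix(0, 1L, h1),
                W2 = glorot(h1, h2), b2 = matrix(0, 1L, h2),
                W3 = glorot(h2, 1L), b3 = matrix(0, 1L, 1L))
  )
  structure(params, class = "synergraph_params",
            n_genes = n_genes, n_proteins = n_proteins,
            n_atom_features = n_atom_features)
}

# ---- parameter flattening (shared by the optimizer and the tape) ----------

param_leaves <- function(params, prefix = character(0)) {
  out <- list()
  for (nm in names(params)) {
    x <- params[[nm]]
    if (is.null(x)) next
    path <- c(prefix, nm)
    if (is.list(x)) {
      out <- c(out, param_leaves(x, path))
    } else if (is.numeric(x)) {
      out[[paste(path, collapse = ".")]] <- as.matrix(x)
    }
  }
  out
}

set_param_leaves <- function(params, leaves) {
  for (nm in names(leaves)) {
    path <- strsplit(nm, ".", fixed = TRUE)[[1]]
    params[[path]] <- leaves[[nm]]
  }
  params
}

# Unnamed list elements (layers, heads, steps) get numeric names so the
# flatten paths are stable.
name_unnamed <- function(x) {
  if (!is.list(x)) return(x)
  if (is.null(names(x))) names(x) <- as.character(seq_along(x))
  names(x)[names(x) == ""] <- as.character(which(names(x) == ""))
  for (i in seq_along(x)) if (is.list(x[[i]])) x[[i]] <- name_unnamed(x[[i]])
  x
}

# ---- numeric (reference) forward ops --------------------------------------

#' Encode one drug into its fused embedding
#'
#' Runs the configured graph encoder over the molecular graph and, for the
#' GATFP variant, concatenates the linear fingerprint embedding:
#' `h = [z, W_f F + b_f]`.
#'
#' @param graph A `molecular_graph`.
#' @param fingerprint A `fingerprint` (required for GATFP; ignored
#'   otherwise).
#' @param params A `synergraph_params` object.
#' @param config The matching [synergraph_config()].
#' @return A `1 x d` embedding row.
#' @export
encode_drug <- function(graph, fingerprint, params, config) {
  z <- switch(config$variant,
    gcn = {
      H <- graph$features
      for (ly in params$encoder$layers) {
        H <- gcn_layer(H, graph$adjacency,
                       list(W = ly$W, activation = config$activation))
      }
      global_pool(H, config$pooling)
    },
    gat = ,
    gatfp = {
      H <- graph$features
      for (ly in params$encoder$layers) {
        H <- gat_layer(H, graph$edges,
                       list(heads = ly$heads, combine = ly$combine,
                            activation = config$activation,
                            negative_slope = config$negative_slope))
      }
      global_pool(H, config$pooling)
    },
    attfp = attfp_encode(graph, params$encoder)$h_G
  )
  if (config$use_fingerprint) {
    if (is.null(fingerprint)) {
      stop("config error: GATFP variant requires a fingerprint")
    }
    f <- matrix(fingerprint$bits, 1L) %*% params$fp$W + params$fp$b
    cbind(z, f)
  } else {
    z
  }
}

#' Embed cell-line omics vectors
#'
#' Linear embeddings `g_exp = W_g G_exp + b_g` and `p_exp = W_p P_exp + b_p`;
#' a disabled branch returns an empty (zero-width) segment.
#'
#' @param G_exp Gene-expression vector.
#' @param P_exp Protein-expression vector.
#' @param params,config Model parameters and configuration.
#' @return List with `g_exp` and `p_exp` (`1 x omics_dim` or `1 x 0`).
#' @export
encode_omics <- function(G_exp, P_exp, params, config) {
  g <- if (config$use_gene) {
    if (length(G_exp) != nrow(params$gene$W)) {
      stop("dimension error: gene vector length ", length(G_exp),
           ", expected ", nrow(params$gene$W))
    }
    matrix(G_exp, 1L) %*% params$gene$W + params$gene$b
  } else {
    matrix(0, 1L, 0L)
  }
  p <- if (config$use_protein) {
    if (length(P_exp) != nrow(params$protein$W)) {
      stop("dimension error: protein vector length ", length(P_exp),
           ", expected ", nrow(params$protein$W))
    }
    matrix(P_exp, 1L) %*% params$protein$W + params$protein$b
  } else {
    matrix(0, 1L, 0L)
  }
  list(g_exp = g, p_exp = p)
}

#' Fuse drug and omics embeddings and predict
#'
#' Concatenates `h_AB = [h_A, h_B, g_exp, p_exp]` and applies the
#' three-layer fusion network. Regression emits the raw score; the
#' classification head is identical except for a final sigmoid.
#'
#' @param h_A,h_B Per-drug embeddings (`1 x d` rows).
#' @param g_exp,p_exp Omics embeddings (possibly zero-width).
#' @param params,config Model parameters and configuration.
#' @return List with `y` (regression score) or `p` (probability), plus
#'   `h_AB`.
#' @export
fuse_and_predict <- function(h_A, h_B, g_exp, p_exp, params, config) {
  sigma <- act_fun(config$activation)
  h_AB <- cbind(h_A, h_B, g_exp, p_exp)
  hd <- params$head
  a1 <- sigma(h_AB %*% hd$W1 + matrix(hd$b1, nrow(h_AB), ncol(hd$b1),
                                      byrow = TRUE))
  if (any(!is.finite(a1))) stop("numeric error: non-finite values at layer 1")
  a2 <- sigma(a1 %*% hd$W2 + matrix(hd$b2, nrow(a1), ncol(hd$b2),
                                    byrow = TRUE))
  if (any(!is.finite(a2))) stop("numeric error: non-finite values at layer 2")
  out <- a2 %*% hd$W3 + hd$b3[1L, 1L]
  if (any(!is.finite(out))) stop("numeric error: non-finite values at layer 3")
  if (config$task == "classification") {
    list(p = 1 / (1 + exp(-out)), h_AB = h_AB)
  } else {
    list(y = out, h_AB = h_AB)
  }
}

# ---- tape (training/attribution) forward ----------------------------------

# Precompute per-graph constants: node features, directed edge list with
# self-loops, and the grouping of directed edges by source node.
prep_graph <- function(graph) {
  ed <- add_self_loops(graph$edges, graph$n_atoms)
  list(X = graph$features, src = ed[, 1L], dst = ed[, 2L], n = graph$n_atoms)
}

tape_gat_head <- function(tape, Hid, g, W_id, a_id, hd, slope) {
  Wh <- tp_matmul(tape, Hid, W_id)
  a1 <- tp_rows(tape, a_id, seq_len(hd))
  a2 <- tp_rows(tape, a_id, hd + seq_len(hd))
  e <- tp_leaky_relu(tape, tp_add(tape,
    tp_matmul(tape, tp_rows(tape, Wh, g$src), a1),
    tp_matmul(tape, tp_rows(tape, Wh, g$dst), a2)), slope)
  alpha <- tp_segment_softmax(tape, e, g$src)
  tp_segment_sum(tape, tp_colmul(tape, alpha, tp_rows(tape, Wh, g$dst)),
                 g$src, g$n)
}

tape_encode_graph <- function(tape, g, enc_ids, config) {
  Hid <- tp_leaf(tape, g$X)
  slope <- config$negative_slope
  if (config$variant %in% c("gat", "gatfp")) {
    for (ly in enc_ids$layers) {
      outs <- lapply(ly$heads, function(hp) {
        hd <- ncol(tp_value(tape, hp$W))
        tape_gat_head(tape, Hid, g, hp$W, hp$a, hd, slope)
      })
      comb <- if (identical(ly$combine, "mean")) {
        acc <- outs[[1L]]
        if (length(outs) > 1L) {
          for (o in outs[-1L]) acc <- tp_add(tape, acc, o)
        }
        tp_scale(tape, acc, 1 / length(outs))
      } else if (length(outs) == 1L) outs[[1L]] else tp_cbind(tape, outs)
      Hid <- tp_activation(tape, comb, config$activation)
    }
    pool_node(tape, Hid, config$pooling)
  } else if (config$variant == "gcn") {
    Ahat <- diag(g$n)
    if (length(g$src)) Ahat[cbind(g$src, g$dst)] <- 1
    dinv <- 1 / sqrt(rowSums(Ahat))
    Anorm_id <- tp_leaf(tape, Ahat * outer(dinv, dinv))
    for (ly in enc_ids$layers) {
      Hid <- tp_activation(tape,
        tp_matmul(tape, Anorm_id, tp_matmul(tape, Hid, ly$W)),
        config$activation)
    }
    pool_node(tape, Hid, config$pooling)
  } else {  # attfp
    Hid <- tp_leaky_relu(tape, tp_add(tape,
      tp_matmul(tape, Hid, enc_ids$W_in), enc_ids$b_in), 0.2)
    for (sp in enc_ids$steps) {
      d <- ncol(tp_value(tape, sp$W))
      m <- tape_gat_head(tape, Hid, g, sp$W, sp$a, d, slope)
      Hid <- tp_gru(tape, m, Hid, sp$gru)
    }
    tp_sum_rows(tape, Hid)
  }
}

pool_node <- function(tape, Hid, mode) {
  switch(mode,
    mean = tp_mean_rows(tape, Hid),
    sum = tp_sum_rows(tape, Hid),
    max = stop("max pooling is not differentiable on the training path; ",
               "use mean or sum")
  )
}

# Build the full forward computation on a fresh tape. `data` holds prepared
# graphs, the fingerprint matrix, standardized omics matrices and record
# index vectors. Returns node ids for predictions, parameters and (when
# requested) the omics leaves.
tape_forward <- function(params, config, data, train = FALSE,
                         loss_y = NULL) {
  tape <- tape_new()
  params <- name_unnamed(unclass(params))
  leaves <- param_leaves(params)
  leaf_ids <- lapply(leaves, function(v) tp_leaf(tape, v))
  ids <- set_param_leaves(params, leaf_ids)

  # per-drug graph embeddings, stacked into a drug matrix
  z_ids <- lapply(data$graphs, function(g) {
    tape_encode_graph(tape, g, ids$encoder, config)
  })
  Dz <- tp_rbind(tape, z_ids)
  if (config$use_fingerprint) {
    Femb <- tp_add(tape, tp_matmul(tape, tp_leaf(tape, data$fp_matrix),
                                   ids$fp$W), ids$fp$b)
    Dz <- tp_cbind(tape, list(Dz, Femb))
  }

  Gid <- Pid <- NULL
  in_drop <- if (train) config$input_dropout %||% 0 else 0
  hA <- tp_rows(tape, Dz, data$idx_a)
  hB <- tp_rows(tape, Dz, data$idx_b)
  seg <- list(hA, hB)
  if (config$use_gene) {
    Gid <- tp_leaf(tape, data$G)
    Gin <- if (in_drop > 0) tp_dropout(tape, Gid, in_drop) else Gid
    Gemb <- tp_add(tape, tp_matmul(tape, Gin, ids$gene$W), ids$gene$b)
    seg <- c(seg, tp_rows(tape, Gemb, data$idx_line))
  }
  if (config$use_protein) {
    Pid <- tp_leaf(tape, data$P)
    Pin <- if (in_drop > 0) tp_dropout(tape, Pid, in_drop) else Pid
    Pemb <- tp_add(tape, tp_matmul(tape, Pin, ids$protein$W), ids$protein$b)
    seg <- c(seg, tp_rows(tape, Pemb, data$idx_line))
  }
  hAB <- tp_cbind(tape, seg)

  a1 <- tp_activation(tape, tp_add(tape, tp_matmul(tape, hAB, ids$head$W1),
                                   ids$head$b1), config$activation)
  if (train && config$dropout > 0) a1 <- tp_dropout(tape, a1, config$dropout)
  a2 <- tp_activation(tape, tp_add(tape, tp_matmul(tape, a1, ids$head$W2),
                                   ids$head$b2), config$activation)
  if (train && config$dropout > 0) a2 <- tp_dropout(tape, a2, config$dropout)
  out <- tp_add(tape, tp_matmul(tape, a2, ids$head$W3), ids$head$b3)

  loss_id <- NULL
  if (!is.null(loss_y)) {
    loss_id <- if (config$task == "classification") {
      tp_bce_logits_loss(tape, out, loss_y)
    } else {
      tp_mse_loss(tape, out, loss_y)
    }
  }
  list(tape = tape, out = out, loss = loss_id, leaf_ids = leaf_ids,
       G = Gid, P = Pid)
}

# Assemble the constant tensors the tape forward consumes from a featurized,
# standardized bundle plus record indices.
prepare_model_data <- function(bundle, config, indices) {
  recs <- bundle$records[indices, , drop = FALSE]
  drug_ids <- unique(c(recs$drug_a, recs$drug_b))
  bad_drug <- setdiff(drug_ids, names(bundle$graphs))
  if (length(bad_drug)) {
    stop("lookup error: no featurization for drug(s) ",
         paste(bad_drug, collapse = ", "))
  }
  line_ids <- rownames(bundle$gene_matrix)
  missing <- setdiff(recs$cell_line, line_ids)
  if (length(missing)) {
    stop("lookup error: no omics profile for cell line(s) ",
         paste(missing, collapse = ", "))
  }
  graphs <- lapply(bundle$graphs[drug_ids], prep_graph)
  fp_matrix <- if (config$use_fingerprint) {
    do.call(rbind, lapply(bundle$fingerprints[drug_ids],
                          function(f) f$bits))
  }
  list(
    graphs = graphs,
    fp_matrix = fp_matrix,
    G = bundle$gene_matrix,
    P = bundle$protein_matrix,
    idx_a = match(recs$drug_a, drug_ids),
    idx_b = match(recs$drug_b, drug_ids),
    idx_line = match(recs$cell_line, line_ids),
    y = if (config$task == "classification") recs$label else recs$loewe
  )
}

#' Forward pass over a batch of records
#'
#' Vectorized application of [encode_drug()], [encode_omics()] and
#' [fuse_and_predict()] over a slice of a featurized dataset bundle.
#' Deterministic given fixed parameters and inputs. With
#' `config$symmetrize = TRUE` the two drug orders are averaged.
#'
#' @param bundle A featurized (and standardized) `dataset_bundle`.
#' @param params,config Model parameters and configuration.
#' @param indices Record indices to score (default: all).
#' @return Numeric vector: synergy scores (regression) or probabilities
#'   (classification).
#' @export
forward_batch <- function(bundle, params, config, indices = NULL) {
  if (is.null(indices)) indices <- seq_len(nrow(bundle$records))
  data <- prepare_model_data(bundle, config, indices)
  fw <- tape_forward(params, config, data)
  out <- unname(tp_value(fw$tape, fw$out)[, 1L])
  if (config$symmetrize) {
    data2 <- data
    data2$idx_a <- data$idx_b
    data2$idx_b <- data$idx_a
    fw2 <- tape_forward(params, config, data2)
    out <- (out + unname(tp_value(fw2$tape, fw2$out)[, 1L])) / 2
  }
  if (any(!is.finite(out))) stop("numeric error: non-finite model output")
  if (config$task == "classification") 1 / (1 + exp(-out)) else out
}

# ---- checkpoint serialization ---------------------------------------------

#' Save model parameters as a portable JSON archive
#'
#' Writes every weight matrix flattened column-major together with a shape
#' manifest, so checkpoints survive across platforms as plain text.
#'
#' @param model A `synergraph_model` (from [train_model()]).
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  leaves <- param_leaves(name_unnamed(unclass(model$params)))
  jsonlite::write_json(list(
    config = unclass(model$config),
    shapes = lapply(leaves, dim),
    values = lapply(leaves, as.vector),
    scaler = model$scaler,
    history = model$history
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint written by [save_model()]
#'
#' @param path Checkpoint path.
#' @return A `synergraph_model` list with `params`, `config`, `scaler`,
#'   `history`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("config error: checkpoint not found: ", path)
  ck <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(synergraph_config, ck$config[setdiff(names(ck$config),
                                                      character(0))])
  leaves <- Map(function(v, d) matrix(v, d[1L], d[2L]), ck$values, ck$shapes)
  assign_path <- function(lst, path, value) {
    if (length(path) == 1L) {
      lst[[path]] <- value
    } else {
      if (is.null(lst[[path[1L]]])) lst[[path[1L]]] <- list()
      lst[[path[1L]]] <- assign_path(lst[[path[1L]]], path[-1L], value)
    }
    lst
  }
  params <- list()
  for (nm in names(leaves)) {
    params <- assign_path(params, strsplit(nm, ".", fixed = TRUE)[[1]],
                          leaves[[nm]])
  }
  structure(list(params = params, config = cfg, scaler = ck$scaler,
                 history = ck$history), class = "synergraph_model")
}
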