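# Integrated-gradients attribution over omics inputs, top-k feature
# ranking, and attention-based atomic analysis (feature-similarity matrix
# and per-atom attention weights).

#' Integrated gradients for a scalar-valued function
#'
#' Approximates
#' `AttributionScore_i(x) = (x_i - x0_i) * Int_0^1 dF/dx_i(x0 + a (x - x0)) da`
#' with a midpoint Riemann sum over `steps` points on the straight line from
#' the baseline to the input. The completeness residual
#' `|sum_i score_i - (F(x) - F(x0))|` is computed and reported.
#'
#' @param f Function taking a numeric vector and returning a scalar.
#' @param x Input vector.
#' @param baseline Baseline vector (default: all zeros).
#' @param steps Riemann resolution (default 128).
#' @param grad_fn Optional gradient function (vector in, vector out). When
#'   omitted, central finite differences with step `fd_eps` are used.
#' @param fd_eps Finite-difference step (default 1e-5).
#' @return An `attribution_result`: list with `scores`, `baseline`, `steps`,
#'   `f_x`, `f_baseline`, `residual`.
#' @export
integrated_gradients <- function(f, x, baseline = NULL, steps = 128L,
                                 grad_fn = NULL, fd_eps = 1e-5) {
  stopifnot(steps >= 1L)
  x <- as.numeric(x)
  if (is.null(baseline)) baseline <- numeric(length(x))
  baseline <- as.numeric(baseline)
  stopifnot(length(baseline) == length(x))
  if (is.null(grad_fn)) {
    grad_fn <- function(z) {
      vapply(seq_along(z), function(i) {
        zp <- z; zm <- z
        zp[i] <- zp[i] + fd_eps
        zm[i] <- zm[i] - fd_eps
        (f(zp) - f(zm)) / (2 * fd_eps)
      }, numeric(1))
    }
  }
  diff <- x - baseline
  alphas <- (seq_len(steps) - 0.5) / steps  # midpoint rule
  acc <- numeric(length(x))
  for (a in alphas) {
    g <- grad_fn(baseline + a * diff)
    if (any(!is.finite(g))) {
      stop("attribution error: non-finite gradient at path point alpha = ", a)
    }
    acc <- acc + g
  }
  scores <- diff * acc / steps
  f_x <- f(x)
  f_b <- f(baseline)
  structure(list(scores = scores, baseline = baseline,
                 steps = as.integer(steps), f_x = f_x, f_baseline = f_b,
                 residual = abs(sum(scores) - (f_x - f_b))),
            class = "attribution_result")
}

# Gradient of the model output with respect to the gene and protein input
# vectors of one record, evaluated on a batch of interpolated omics rows.
# The drug-pair embedding is constant along the path, so it is precomputed
# once and only the omics branches and the head run on the tape.
omics_path_gradients <- function(model, bundle, record_idx, omics_rows_g,
                                 omics_rows_p) {
  cfg <- model$config
  params <- model$params
  rec <- bundle$records[record_idx, , drop = FALSE]
  sigma <- cfg$activation
  hA <- encode_drug(bundle$graphs[[rec$drug_a]],
                    bundle$fingerprints[[rec$drug_a]], params, cfg)
  hB <- encode_drug(bundle$graphs[[rec$drug_b]],
                    bundle$fingerprints[[rec$drug_b]], params, cfg)
  nr <- max(nrow(omics_rows_g %||% omics_rows_p), 1L)

  tape <- tape_new()
  seg <- list(tp_leaf(tape, matrix(rep(hA, each = nr), nr)),
              tp_leaf(tape, matrix(rep(hB, each = nr), nr)))
  Gid <- Pid <- NULL
  if (cfg$use_gene) {
    Gid <- tp_leaf(tape, omics_rows_g)
    seg <- c(seg, tp_add(tape, tp_matmul(tape, Gid,
                                         tp_leaf(tape, params$gene$W)),
                         tp_leaf(tape, params$gene$b)))
  }
  if (cfg$use_protein) {
    Pid <- tp_leaf(tape, omics_rows_p)
    seg <- c(seg, tp_add(tape, tp_matmul(tape, Pid,
                                         tp_leaf(tape, params$protein$W)),
                         tp_leaf(tape, params$protein$b)))
  }
  hAB <- tp_cbind(tape, seg)
  hd <- params$head
  a1 <- tp_activation(tape, tp_add(tape, tp_matmul(tape, hAB,
                                                   tp_leaf(tape, hd$W1)),
                                   tp_leaf(tape, hd$b1)), sigma)
  a2 <- tp_activation(tape, tp_add(tape, tp_matmul(tape, a1,
                                                   tp_leaf(tape, hd$W2)),
                                   tp_leaf(tape, hd$b2)), sigma)
  out <- tp_add(tape, tp_matmul(tape, a2, tp_leaf(tape, hd$W3)),
                tp_leaf(tape, hd$b3))
  if (cfg$task == "classification") out <- tp_sigmoid(tape, out)
  total <- tp_sum_all(tape, out)
  grads <- tp_backward(tape, total)
  list(out = tp_value(tape, out)[, 1L],
       grad_g = if (!is.null(Gid)) grads[[Gid]],
       grad_p = if (!is.null(Pid)) grads[[Pid]])
}

#' Integrated gradients over a model's omics inputs
#'
#' Attributes the model output (synergy score or synergism probability) to
#' the standardized gene- and protein-expression features, record by
#' record, with a zero baseline (the training mean after z-scoring). Exact
#' tape gradients are used; each record costs one forward/backward pass
#' over the `steps` interpolated inputs.
#'
#' @param model A trained `synergraph_model`.
#' @param bundle The featurized bundle (raw omics scale).
#' @param record_idx Record indices to attribute (e.g., the test split).
#' @param steps Midpoint-rule resolution (default 128).
#' @return An `omics_attribution`: list with `gene` and `protein` score
#'   matrices (records x features), `residual` per record, and feature
#'   names.
#' @export
omics_integrated_gradients <- function(model, bundle, record_idx,
                                       steps = 128L) {
  cfg <- model$config
  if (is.null(bundle$graphs)) {
    bundle <- featurize_bundle(bundle, cfg$fp_bits, cfg$fp_radius,
                               fingerprints = cfg$use_fingerprint)
  }
  bundle <- apply_scaler(bundle, model$scaler)
  alphas <- (seq_len(steps) - 0.5) / steps
  gene_names <- colnames(bundle$gene_matrix)
  prot_names <- colnames(bundle$protein_matrix)
  SG <- if (cfg$use_gene) {
    matrix(0, length(record_idx), ncol(bundle$gene_matrix),
           dimnames = list(NULL, gene_names))
  }
  SP <- if (cfg$use_protein) {
    matrix(0, length(record_idx), ncol(bundle$protein_matrix),
           dimnames = list(NULL, prot_names))
  }
  residual <- numeric(length(record_idx))
  for (i in seq_along(record_idx)) {
    ri <- record_idx[i]
    line <- bundle$records$cell_line[ri]
    g_x <- if (cfg$use_gene) bundle$gene_matrix[line, ]
    p_x <- if (cfg$use_protein) bundle$protein_matrix[line, ]
    rows_g <- if (cfg$use_gene) outer(alphas, g_x)
    rows_p <- if (cfg$use_protein) outer(alphas, p_x)
    pg <- omics_path_gradients(model, bundle, ri, rows_g, rows_p)
    f_parts <- omics_path_gradients(model, bundle, ri,
      if (cfg$use_gene) rbind(g_x, 0 * g_x),
      if (cfg$use_protein) rbind(p_x, 0 * p_x))
    total <- 0
    if (cfg$use_gene) {
      SG[i, ] <- g_x * colMeans(pg$grad_g)
      total <- total + sum(SG[i, ])
    }
    if (cfg$use_protein) {
      SP[i, ] <- p_x * colMeans(pg$grad_p)
      total <- total + sum(SP[i, ])
    }
    residual[i] <- abs(total - (f_parts$out[1L] - f_parts$out[2L]))
  }
  structure(list(gene = SG, protein = SP, residual = residual,
                 steps = as.integer(steps), record_idx = record_idx),
            class = "omics_attribution")
}

#' Rank features by mean absolute attribution
#'
#' Features are ordered by the mean of `|score|` across the attributed
#' records, descending, with stable name tie-breaks. The reported score is
#' `log10(mean |score| + eps)`. Features whose mean attribution is exactly
#' zero (e.g., through ReLU-induced gradient sparsity) are kept at the
#' bottom and flagged rather than dropped.
#'
#' @param attr An `omics_attribution`, or a numeric matrix/vector of scores
#'   (columns = features).
#' @param k Number of top features to return (default 50; capped at the
#'   feature count).
#' @param class_label Label stored in the output (`"protein"`, `"gene"`);
#'   chosen automatically for `omics_attribution` input via `which`.
#' @param which For `omics_attribution` input: `"protein"` or `"gene"`.
#' @param eps Offset inside the log transform (default 1e-12).
#' @return Data.frame with `feature`, `class`, `mean_abs_score`,
#'   `log10_score`, `zero_flag`, ordered by rank.
#' @export
rank_features <- function(attr, k = 50L, which = c("protein", "gene"),
                          class_label = NULL, eps = 1e-12) {
  stopifnot(k >= 1L)
  if (inherits(attr, "omics_attribution")) {
    which <- match.arg(which)
    scores <- attr[[which]]
    if (is.null(scores)) stop("no ", which, " attributions present")
    if (is.null(class_label)) class_label <- which
  } else {
    scores <- attr
    if (is.null(class_label)) class_label <- "feature"
  }
  if (is.null(dim(scores))) scores <- matrix(scores, 1L,
                                             dimnames = list(NULL,
                                                             names(scores)))
  m <- colMeans(abs(scores))
  nms <- colnames(scores) %||% paste0("f", seq_along(m))
  o <- order(-m, nms)  # stable: ties broken by feature name
  k <- min(k, length(m))
  sel <- o[seq_len(k)]
  data.frame(
    feature = nms[sel],
    class = class_label,
    mean_abs_score = m[sel],
    log10_score = log10(m[sel] + eps),
    zero_flag = m[sel] == 0,
    row.names = NULL
  )
}

#' Atomic feature similarity matrix between two drugs
#'
#' `S_uw = sim(f_u, f_w)` over all atom pairs of two molecules, where `f`
#' are per-atom feature (or embedding) vectors. Cosine similarity is the
#' default; the negated Euclidean distance is available as an alternative.
#' Zero vectors have undefined cosine; those entries are set to 0.
#'
#' @param F_A,F_B Atom feature matrices (`n_A x d`, `n_B x d`), or
#'   `molecular_graph` objects (their 75-dim feature rows are used).
#' @param sim `"cosine"` or `"euclidean"`.
#' @return `n_A x n_B` similarity matrix.
#' @export
atom_similarity <- function(F_A, F_B, sim = c("cosine", "euclidean")) {
  sim <- match.arg(sim)
  if (inherits(F_A, "molecular_graph")) F_A <- F_A$features
  if (inherits(F_B, "molecular_graph")) F_B <- F_B$features
  F_A <- as.matrix(F_A); F_B <- as.matrix(F_B)
  if (ncol(F_A) != ncol(F_B)) {
    stop("dimension error: feature widths differ (", ncol(F_A), " vs ",
         ncol(F_B), ")")
  }
  if (sim == "cosine") {
    na <- sqrt(rowSums(F_A^2))
    nb <- sqrt(rowSums(F_B^2))
    S <- (F_A %*% t(F_B)) / outer(na, nb)
    S[!is.finite(S)] <- 0
    S
  } else {
    d2 <- outer(rowSums(F_A^2), rowSums(F_B^2), "+") - 2 * F_A %*% t(F_B)
    -sqrt(pmax(d2, 0))
  }
}

#' Per-atom attention weights of a trained model
#'
#' Runs the attention-based encoder over one molecular graph and summarizes,
#' for every atom, the mean incoming attention mass across all layers (or
#' message-passing steps) and heads, normalized to sum to 1 over the
#' molecule. Available for the attention variants (GAT, GATFP, AttFP);
#' the GCN encoder has no attention coefficients.
#'
#' @param model A trained `synergraph_model` (or a list with `params` and
#'   `config`).
#' @param graph A `molecular_graph`.
#' @return Named numeric vector of per-atom weights (sums to 1).
#' @export
substructure_weights <- function(model, graph) {
  cfg <- model$config
  params <- model$params
  if (cfg$variant == "gcn") {
    stop("capability error: the GCN variant has no attention weights")
  }
  mass <- numeric(graph$n_atoms)
  n_mats <- 0L
  if (cfg$variant %in% c("gat", "gatfp")) {
    H <- graph$features
    for (ly in params$encoder$layers) {
      for (hp in ly$heads) {
        alpha <- gat_attention(H, graph$edges,
                               list(W = hp$W, a = hp$a,
                                    negative_slope = cfg$negative_slope))
        mass <- mass + colSums(alpha)
        n_mats <- n_mats + 1L
      }
      H <- gat_layer(H, graph$edges,
                     list(heads = ly$heads, combine = ly$combine,
                          activation = cfg$activation,
                          negative_slope = cfg$negative_slope))
    }
  } else {
    enc <- attfp_encode(graph, params$encoder)
    for (alpha in enc$alpha) {
      mass <- mass + colSums(alpha)
      n_mats <- n_mats + 1L
    }
  }
  w <- mass / n_mats
  w <- w / sum(w)
  stats::setNames(w, graph$elements)
}

#' Export an attribution report to CSV
#'
#' @param ranked Output of [rank_features()] (possibly several classes
#'   row-bound together).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_attribution_csv <- function(ranked, path) {
  utils::write.csv(ranked, path, row.names = FALSE)
  invisible(path)
}
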