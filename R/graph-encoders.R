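# Graph encoder layers: graph convolution (symmetric degree-normalized
# aggregation), graph attention (softmax-normalized neighbor weighting), and
# the attentive-fingerprint encoder (attention-gated message passing with GRU
# state updates and a sum readout). These are the plain-matrix reference
# implementations; training runs the same math on the autodiff tape and a
# test pins the two together.

act_fun <- function(name, slope = 0.2) {
  switch(name,
    relu = function(x) pmax(x, 0),
    leaky_relu = function(x) ifelse(x > 0, x, slope * x),
    sigmoid = function(x) 1 / (1 + exp(-x)),
    tanh = tanh,
    identity = identity,
    stop("unknown activation: ", name)
  )
}

add_self_loops <- function(edges, n) {
  di <- rbind(edges, edges[, 2:1, drop = FALSE], cbind(seq_len(n), seq_len(n)))
  di[order(di[, 1L], di[, 2L]), , drop = FALSE]
}

#' Graph convolution layer
#'
#' One propagation step of a graph convolutional network:
#' `H' = sigma(D^-1/2 (A + I) D^-1/2 H W)`, where `D` is the degree matrix of
#' the self-loop-augmented adjacency. Self-connections keep each node's own
#' features in the aggregate; the symmetric normalization makes the operator
#' independent of absolute node degree.
#'
#' @param H Node feature matrix (`n` x `d_in`).
#' @param A Symmetric binary adjacency matrix with zero diagonal.
#' @param params List with `W` (`d_in` x `d_out`) and optional `activation`
#'   (name, default `"relu"`).
#' @return Updated node embedding matrix (`n` x `d_out`).
#' @export
gcn_layer <- function(H, A, params) {
  H <- as.matrix(H); A <- as.matrix(A)
  if (nrow(H) != nrow(A) || ncol(A) != nrow(A)) {
    stop("dimension error: H has ", nrow(H), " rows but A is ",
         nrow(A), "x", ncol(A))
  }
  if (nrow(params$W) != ncol(H)) {
    stop("dimension error: W expects input width ", nrow(params$W),
         ", got ", ncol(H))
  }
  sigma <- act_fun(params$activation %||% "relu")
  Ahat <- A + diag(nrow(A))
  dinv <- 1 / sqrt(rowSums(Ahat))
  Anorm <- Ahat * outer(dinv, dinv)
  sigma(Anorm %*% H %*% params$W)
}

# Raw attention logits for the directed edge list (u attends over w).
gat_logits <- function(H, edges_dir, params) {
  Wh <- H %*% params$W
  d <- ncol(Wh)
  a1 <- params$a[seq_len(d)]
  a2 <- params$a[d + seq_len(d)]
  slope <- params$negative_slope %||% 0.2
  e <- Wh[edges_dir[, 1L], , drop = FALSE] %*% a1 +
    Wh[edges_dir[, 2L], , drop = FALSE] %*% a2
  ifelse(e > 0, e, slope * e)
}

#' Graph attention coefficients
#'
#' Computes the softmax-normalized attention matrix of a single graph
#' attention head. The logit for edge (u, w) is
#' `LeakyReLU(a^T [W h_u || W h_w])`; normalization runs over each node's
#' neighborhood (self-loops included, so isolated nodes are well defined).
#'
#' @param H Node feature matrix (`n` x `d_in`).
#' @param edges Two-column matrix of undirected edges (1-based indices).
#' @param params List with `W` (`d_in` x `d_out`), attention vector `a`
#'   (length `2 * d_out`), and optional `negative_slope` (default 0.2).
#' @return An `n` x `n` matrix whose row `u` holds `alpha_uw` over the
#'   neighborhood of `u` (zero elsewhere); every row sums to 1.
#' @export
gat_attention <- function(H, edges, params) {
  H <- as.matrix(H)
  n <- nrow(H)
  ed <- add_self_loops(edges, n)
  e <- gat_logits(H, ed, params)[, 1L]
  alpha <- matrix(0, n, n)
  for (u in unique(ed[, 1L])) {
    sel <- ed[, 1L] == u
    x <- e[sel]
    x <- exp(x - max(x))
    alpha[u, ed[sel, 2L]] <- x / sum(x)
  }
  alpha
}

#' Graph attention layer
#'
#' One propagation step of a graph attention network:
#' `h'_u = sigma(sum_w alpha_uw W h_w)` with attention coefficients from
#' [gat_attention()]. With several heads, head outputs are concatenated
#' (hidden layers) or averaged (final layer).
#'
#' @param H Node feature matrix.
#' @param edges Two-column undirected edge matrix.
#' @param params List with `heads`: a list of per-head parameter lists (each
#'   as in [gat_attention()]); `combine`: `"concat"` or `"mean"`; optional
#'   `activation` (default `"relu"`) and `negative_slope`.
#' @return Updated node embedding matrix.
#' @export
gat_layer <- function(H, edges, params) {
  H <- as.matrix(H)
  heads <- params$heads
  if (is.null(heads)) heads <- list(params)  # single-head shorthand
  sigma <- act_fun(params$activation %||% "relu")
  outs <- lapply(heads, function(hp) {
    if (nrow(hp$W) != ncol(H)) {
      stop("dimension error: head W expects input width ", nrow(hp$W),
           ", got ", ncol(H))
    }
    hp$negative_slope <- hp$negative_slope %||% params$negative_slope %||% 0.2
    alpha <- gat_attention(H, edges, hp)
    alpha %*% (H %*% hp$W)
  })
  combined <- if (identical(params$combine %||% "concat", "mean")) {
    Reduce(`+`, outs) / length(outs)
  } else {
    do.call(cbind, outs)
  }
  sigma(combined)
}

#' Attentive-fingerprint graph encoder
#'
#' Runs `K` rounds of attention-weighted neighbor aggregation, each followed
#' by a gated-recurrent-unit state update, then reads out the graph embedding
#' as the sum of final node states:
#' `m_u = sum_w alpha_uw W h_w`, `h_u <- GRU(m_u, h_u)`,
#' `h_G = sum_u h_u^(K)`.
#'
#' @param graph A `molecular_graph`, or a list with `features` and `edges`.
#' @param params List with `W_in`, `b_in` (input projection of atom features)
#'   and `steps`: a list of `K` per-step parameter lists, each holding
#'   attention parameters (`W`, `a`, optional `negative_slope`) and GRU
#'   parameters (`gru`: `Wz, Uz, bz, Wr, Ur, br, Wh, Uh, bh`).
#' @return A list with `h_G` (1 x d graph embedding), `H` (final node
#'   states), and `alpha` (list of per-step attention matrices).
#' @export
attfp_encode <- function(graph, params) {
  X <- as.matrix(graph$features)
  edges <- graph$edges
  n <- nrow(X)
  stopifnot(length(params$steps) >= 1L)
  H <- act_fun("leaky_relu")(sweep(X %*% params$W_in, 2L, params$b_in, "+"))
  alphas <- vector("list", length(params$steps))
  for (k in seq_along(params$steps)) {
    sp <- params$steps[[k]]
    alpha <- gat_attention(H, edges, sp)
    m <- alpha %*% (H %*% sp$W)
    H <- gru_update(m, H, sp$gru)
    alphas[[k]] <- alpha
  }
  list(h_G = matrix(colSums(H), 1L), H = H, alpha = alphas)
}

# Plain-matrix GRU update mirroring tp_gru().
gru_update <- function(m, h, p) {
  zt <- 1 / (1 + exp(-(sweep(m %*% p$Wz + h %*% p$Uz, 2L, p$bz, "+"))))
  rt <- 1 / (1 + exp(-(sweep(m %*% p$Wr + h %*% p$Ur, 2L, p$br, "+"))))
  ht <- tanh(sweep(m %*% p$Wh + (rt * h) %*% p$Uh, 2L, p$bh, "+"))
  (1 - zt) * h + zt * ht
}

#' Pool node embeddings into a graph-level vector
#'
#' @param H Node embedding matrix (`n` x `d`, `n >= 1`).
#' @param mode `"mean"` (default), `"sum"`, or `"max"`.
#' @return A `1 x d` matrix.
#' @export
global_pool <- function(H, mode = c("mean", "sum", "max")) {
  mode <- match.arg(mode)
  H <- as.matrix(H)
  if (nrow(H) == 0L) stop("empty graph: cannot pool zero nodes")
  v <- switch(mode,
    mean = colMeans(H),
    sum = colSums(H),
    max = apply(H, 2L, max)
  )
  matrix(v, 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
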