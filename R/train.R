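# Full-batch training with adaptive-moment gradient descent and the
# early-stopping policy. Deterministic given the configuration seed.

adam_state <- function(leaves) {
  list(m = lapply(leaves, function(x) x * 0),
       v = lapply(leaves, function(x) x * 0),
       t = 0L)
}

adam_step <- function(leaves, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  st$t <- st$t + 1L
  for (nm in names(leaves)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    # L2 penalty enters the gradient (biases exempt), so the adaptive
    # normalization gives it traction within the few hundred full-batch
    # steps a run takes
    if (weight_decay > 0 && !grepl("\\.b[a-z0-9]*$", nm)) {
      g <- g + weight_decay * leaves[[nm]]
    }
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g^2
    mhat <- st$m[[nm]] / (1 - beta1^st$t)
    vhat <- st$v[[nm]] / (1 - beta2^st$t)
    leaves[[nm]] <- leaves[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(leaves = leaves, state = st)
}

#' Train a synergy model
#'
#' Minimizes mean-squared error (regression) or binary cross-entropy
#' (classification) on the training records with full-batch Adam, monitors
#' the validation loss each epoch, and stops per [early_stop_check()] or at
#' `max_epochs`. Omics matrices are z-scored against the training cell
#' lines inside this function, so no test information leaks into the
#' scaling. The run is fully deterministic given `config$seed`.
#'
#' @param bundle A featurized `dataset_bundle` (see [featurize_bundle()]).
#' @param plan A `split_plan` from [make_split()].
#' @param config A [synergraph_config()].
#' @return A `synergraph_model`: list with `params` (best-validation
#'   weights), `config`, `history` (per-epoch data.frame plus
#'   `stop_reason`), `scaler`, `plan`.
#' @export
train_model <- function(bundle, plan, config) {
  if (is.null(bundle$graphs)) {
    bundle <- featurize_bundle(bundle, config$fp_bits, config$fp_radius,
                               fingerprints = config$use_fingerprint)
  }
  set.seed(config$seed)
  train_lines <- unique(bundle$records$cell_line[plan$train])
  bundle <- standardize_omics(bundle, train_lines)

  params <- init_synergraph_params(
    config,
    n_genes = ncol(bundle$gene_matrix),
    n_proteins = ncol(bundle$protein_matrix)
  )
  leaves <- param_leaves(name_unnamed(unclass(params)))

  train_idx <- plan$train
  data_tr <- prepare_model_data(bundle, config, train_idx)
  if (config$augment_swap) {
    ia <- data_tr$idx_a
    ib <- data_tr$idx_b
    data_tr$idx_a <- c(ia, ib)
    data_tr$idx_b <- c(ib, ia)
    data_tr$idx_line <- rep(data_tr$idx_line, 2L)
    data_tr$y <- rep(data_tr$y, 2L)
  }
  data_val <- prepare_model_data(bundle, config, plan$val)

  st <- adam_state(leaves)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  best_val <- Inf
  best_leaves <- leaves
  stop_reason <- "max_epochs"

  for (epoch in seq_len(config$max_epochs)) {
    p <- set_param_leaves(name_unnamed(unclass(params)), leaves)
    fw <- tape_forward(p, config, data_tr, train = TRUE, loss_y = data_tr$y)
    train_loss <- tp_value(fw$tape, fw$loss)[1L, 1L]
    if (!is.finite(train_loss)) {
      stop("training error: non-finite loss at epoch ", epoch)
    }
    grads_all <- tp_backward(fw$tape, fw$loss)
    grads <- lapply(fw$leaf_ids, function(id) grads_all[[id]])

    stepped <- adam_step(leaves, grads, st, config$lr,
                         weight_decay = config$weight_decay %||% 0)
    leaves <- stepped$leaves
    st <- stepped$state

    p <- set_param_leaves(name_unnamed(unclass(params)), leaves)
    fv <- tape_forward(p, config, data_val, train = FALSE,
                       loss_y = data_val$y)
    val_loss <- tp_value(fv$tape, fv$loss)[1L, 1L]
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = train_loss,
                                         val_loss = val_loss))
    burn_in <- min(config$min_epochs %||% 0L, config$max_epochs - 1L)
    if (epoch > burn_in && val_loss < best_val - config$tol) {
      best_val <- val_loss
      best_leaves <- leaves
    }
    if (epoch == burn_in) best_leaves <- leaves
    if (epoch > burn_in) {
      es <- early_stop_check(history$val_loss[history$epoch > burn_in],
                             patience = config$patience,
                             rise_limit = config$rise_limit, tol = config$tol)
      if (es$stop) {
        stop_reason <- es$reason
        break
      }
    }
  }

  final_params <- set_param_leaves(name_unnamed(unclass(params)),
                                   best_leaves)
  attr(history, "stop_reason") <- stop_reason
  structure(list(params = final_params, config = config, history = history,
                 scaler = bundle$scaler, plan = plan,
                 stop_reason = stop_reason),
            class = "synergraph_model")
}

#' @export
print.synergraph_model <- function(x, ...) {
  cat("<synergraph_model>", x$config$variant, x$config$task, "-",
      nrow(x$history), "epochs, stopped:", x$stop_reason,
      sprintf("(best val loss %.4f)\n", min(x$history$val_loss)))
  invisible(x)
}

# Re-apply a trained model's standardization to a bundle.
apply_scaler <- function(bundle, scaler) {
  rescale <- function(m, mu, sdv) {
    for (j in seq_len(ncol(m))) {
      mj <- m[, j]
      mj[!is.finite(mj)] <- mu[j]
      m[, j] <- if (sdv[j] > 0) (mj - mu[j]) / sdv[j] else 0
    }
    m
  }
  bundle$gene_matrix <- rescale(bundle$gene_matrix, scaler$gene_mean,
                                scaler$gene_sd)
  bundle$protein_matrix <- rescale(bundle$protein_matrix,
                                   scaler$protein_mean, scaler$protein_sd)
  bundle$scaler <- scaler
  bundle
}

#' Predict with a trained model
#'
#' @param object A `synergraph_model`.
#' @param bundle A featurized `dataset_bundle` (raw omics scale; the
#'   model's stored scaler is applied).
#' @param indices Record indices (default: all).
#' @param ... Unused.
#' @return Numeric vector of scores or probabilities.
#' @export
predict.synergraph_model <- function(object, bundle, indices = NULL, ...) {
  if (is.null(bundle$graphs)) {
    bundle <- featurize_bundle(bundle, object$config$fp_bits,
                               object$config$fp_radius,
                               fingerprints = object$config$use_fingerprint)
  }
  bundle <- apply_scaler(bundle, object$scaler)
  forward_batch(bundle, object$params, object$config, indices)
}

#' Evaluate a trained model on a record subset
#'
#' @param model A `synergraph_model`.
#' @param bundle The featurized bundle the model was trained on (raw omics
#'   scale).
#' @param indices Record indices (typically `plan$test`).
#' @return A `metrics_report`.
#' @export
evaluate_model <- function(model, bundle, indices) {
  preds <- predict(model, bundle, indices)
  if (model$config$task == "classification") {
    compute_metrics(bundle$records$label[indices], preds, "classification")
  } else {
    compute_metrics(bundle$records$loewe[indices], preds, "regression")
  }
}
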