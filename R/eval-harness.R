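# Dataset splitting (random, k-fold, and the three cold-start modes),
# early-stopping policy, the metric suite, repeated-seed evaluation and a
# light hyperparameter-search hook.

unordered_pair <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' Create a train/validation/test split plan
#'
#' Modes: `"random"` shuffles records and holds out `1 - ratio` for test;
#' `"kfold"` additionally partitions the training portion into `k`
#' equal-as-possible validation folds; the cold-start modes hold out 20% of
#' drug pairs (`"leave_combination_out"`), drugs (`"leave_drug_out"`) or
#' cell lines (`"leave_cell_line_out"`): every record involving a held-out
#' entity goes to the test set, so held-out entities never appear in
#' training. A validation subset for early stopping is carved from the
#' training portion.
#'
#' @param records Combination records (data.frame).
#' @param mode Split mode.
#' @param ratio Training fraction for the random/k-fold modes (default 0.8).
#' @param k Number of folds (k-fold mode, default 5).
#' @param holdout_fraction Fraction of entities held out in cold-start modes
#'   (default 0.2).
#' @param val_fraction Fraction of training records used for validation.
#' @param seed RNG seed.
#' @param holdout Optional explicit character vector of held-out entities
#'   (drug ids, pair keys `"a\rb"`, or cell-line ids) overriding the sampled
#'   holdout in cold-start modes.
#' @return A `split_plan`: list with `mode`, `seed`, `train`, `val`, `test`
#'   (record indices), `folds` (k-fold mode), `holdout` (cold-start modes).
#' @export
make_split <- function(records,
                       mode = c("random", "kfold", "leave_combination_out",
                                "leave_drug_out", "leave_cell_line_out"),
                       ratio = 0.8, k = 5L, holdout_fraction = 0.2,
                       val_fraction = 0.1, seed = 1L, holdout = NULL) {
  mode <- match.arg(mode)
  n <- nrow(records)
  if (is.null(n) || n == 0L) stop("split error: no records to split")
  set.seed(seed)
  plan <- list(mode = mode, seed = as.integer(seed), ratio = ratio,
               k = as.integer(k), folds = NULL, holdout = NULL)

  carve_val <- function(train_idx) {
    n_val <- max(1L, round(length(train_idx) * val_fraction))
    val <- sort(sample(train_idx, n_val))
    list(train = setdiff(train_idx, val), val = val)
  }

  if (mode %in% c("random", "kfold")) {
    perm <- sample.int(n)
    n_train <- round(n * ratio)
    if (n_train < 2L || n_train >= n) {
      stop("split error: ratio ", ratio, " leaves no usable train/test split")
    }
    train_all <- sort(perm[seq_len(n_train)])
    plan$test <- sort(perm[(n_train + 1L):n])
    if (mode == "kfold") {
      if (k < 2L) stop("split error: k must be >= 2")
      fold_of <- rep(seq_len(k), length.out = length(train_all))
      fold_of <- sample(fold_of)
      plan$folds <- lapply(seq_len(k), function(f) train_all[fold_of == f])
      plan$val <- plan$folds[[1L]]
      plan$train <- setdiff(train_all, plan$val)
    } else {
      cv <- carve_val(train_all)
      plan$train <- cv$train
      plan$val <- cv$val
    }
  } else {
    entity_of <- switch(mode,
      leave_combination_out = unordered_pair(records$drug_a, records$drug_b),
      leave_drug_out = NULL,  # special: records touch two entities
      leave_cell_line_out = as.character(records$cell_line)
    )
    if (mode == "leave_drug_out") {
      drugs <- unique(c(records$drug_a, records$drug_b))
      if (length(drugs) < 2L) {
        stop("split error: need at least 2 drugs for leave_drug_out")
      }
      held <- holdout %||% sample(drugs, max(1L, round(length(drugs) *
                                                         holdout_fraction)))
      in_test <- records$drug_a %in% held | records$drug_b %in% held
    } else {
      entities <- unique(entity_of)
      if (length(entities) < 2L) {
        stop("split error: need at least 2 distinct entities for ", mode)
      }
      held <- holdout %||% sample(entities,
                                  max(1L, round(length(entities) *
                                                  holdout_fraction)))
      in_test <- entity_of %in% held
    }
    if (all(in_test) || !any(in_test)) {
      stop("split error: ", mode, " holdout yields an empty train or test set")
    }
    plan$holdout <- held
    plan$test <- which(in_test)
    cv <- carve_val(which(!in_test))
    plan$train <- cv$train
    plan$val <- cv$val
  }
  structure(plan, class = "split_plan")
}

#' Audit a split plan for cold-start leakage
#'
#' Verifies the defining property of the mode: held-out drug pairs, drugs or
#' cell lines must not occur in any training (or validation) record, and
#' every test record must involve a held-out entity. Random/k-fold plans are
#' checked for disjointness and coverage.
#'
#' @param plan A `split_plan`.
#' @param records The records the plan was built from.
#' @return `TRUE` invisibly; stops with a description on any leak.
#' @export
leakage_audit <- function(plan, records) {
  tr <- c(plan$train, plan$val)
  if (length(intersect(tr, plan$test))) {
    stop("leakage: train/validation and test overlap")
  }
  if (plan$mode == "leave_cell_line_out") {
    if (length(intersect(records$cell_line[tr], plan$holdout))) {
      stop("leakage: held-out cell line appears in training")
    }
    if (!all(records$cell_line[plan$test] %in% plan$holdout)) {
      stop("leakage: test record on a non-held-out cell line")
    }
  } else if (plan$mode == "leave_drug_out") {
    train_drugs <- unique(c(records$drug_a[tr], records$drug_b[tr]))
    if (length(intersect(train_drugs, plan$holdout))) {
      stop("leakage: held-out drug appears in a training pair")
    }
    touches <- records$drug_a[plan$test] %in% plan$holdout |
      records$drug_b[plan$test] %in% plan$holdout
    if (!all(touches)) stop("leakage: test record without a held-out drug")
  } else if (plan$mode == "leave_combination_out") {
    train_pairs <- unordered_pair(records$drug_a[tr], records$drug_b[tr])
    test_pairs <- unordered_pair(records$drug_a[plan$test],
                                 records$drug_b[plan$test])
    if (length(intersect(train_pairs, test_pairs))) {
      stop("leakage: drug pair shared between train and test")
    }
  } else {
    if (length(unique(c(tr, plan$test))) != nrow(records)) {
      stop("leakage audit: split does not cover all records")
    }
  }
  invisible(TRUE)
}

#' Early-stopping decision
#'
#' Training stops when the validation loss has not improved on the running
#' best by at least `tol` for `patience` consecutive epochs
#' (`patience_no_improve`), or has strictly increased relative to the
#' previous epoch for `rise_limit` consecutive epochs
#' (`consecutive_increase`).
#'
#' @param val_loss Numeric vector of per-epoch validation losses (or a
#'   `training_history` data.frame with a `val_loss` column).
#' @param patience No-improvement budget (default 30 epochs).
#' @param rise_limit Consecutive-increase budget (default 10 epochs).
#' @param tol Minimum decrease that counts as improvement (default 1e-4).
#' @return List with `stop` (logical) and `reason` (`"continue"`,
#'   `"patience_no_improve"`, or `"consecutive_increase"`).
#' @export
early_stop_check <- function(val_loss, patience = 30L, rise_limit = 10L,
                             tol = 1e-4) {
  if (is.data.frame(val_loss)) val_loss <- val_loss$val_loss
  if (length(val_loss) == 0L) stop("early_stop_check: empty history")
  best <- val_loss[1L]
  since_best <- 0L
  rise <- 0L
  for (t in seq_along(val_loss)[-1L]) {
    if (val_loss[t] < best - tol) {
      best <- val_loss[t]
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
    }
    rise <- if (val_loss[t] > val_loss[t - 1L]) rise + 1L else 0L
    if (rise >= rise_limit) {
      return(list(stop = TRUE, reason = "consecutive_increase"))
    }
    if (since_best >= patience) {
      return(list(stop = TRUE, reason = "patience_no_improve"))
    }
  }
  list(stop = FALSE, reason = "continue")
}

#' Classification and regression metric suite
#'
#' Classification (scores in `[0, 1]`, threshold 0.5): AUROC, AUCPR (average
#' precision), accuracy, balanced accuracy, F1, Cohen's kappa. Regression:
#' RMSE, MAE, Pearson and Spearman correlation, R^2. With a single-class
#' truth vector the ranking metrics are returned as `NA` with the
#' `undefined` field set instead of failing.
#'
#' @param y_true Observed labels (0/1) or scores.
#' @param y_pred Predicted probabilities (classification) or scores
#'   (regression).
#' @param task `"classification"` or `"regression"`.
#' @return A `metrics_report` list.
#' @export
compute_metrics <- function(y_true, y_pred,
                            task = c("classification", "regression")) {
  task <- match.arg(task)
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 2L)
  n <- length(y_true)
  if (task == "classification") {
    if (any(y_pred < 0 | y_pred > 1)) {
      stop("classification scores must lie in [0, 1]")
    }
    y <- as.integer(y_true)
    undefined <- character(0)
    if (length(unique(y)) < 2L) {
      auroc <- aucpr <- NA_real_
      undefined <- c("AUROC", "AUCPR")
    } else {
      auroc <- as.numeric(pROC::auc(pROC::roc(
        response = y, predictor = y_pred, levels = c(0, 1),
        direction = "<", quiet = TRUE)))
      aucpr <- average_precision(y, y_pred)
    }
    pred <- as.integer(y_pred >= 0.5)
    tp <- sum(pred == 1L & y == 1L); tn <- sum(pred == 0L & y == 0L)
    fp <- sum(pred == 1L & y == 0L); fn <- sum(pred == 0L & y == 1L)
    acc <- (tp + tn) / n
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    bacc <- mean(c(sens, spec), na.rm = TRUE)
    f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
    tab <- table(factor(y, levels = c(0, 1)), factor(pred, levels = c(0, 1)))
    kappa <- e1071::classAgreement(tab)$kappa
    structure(list(task = task, n = n, AUROC = auroc, AUCPR = aucpr,
                   ACC = acc, BACC = bacc, F1 = f1, kappa = kappa,
                   undefined = undefined),
              class = "metrics_report")
  } else {
    err <- y_pred - y_true
    pcc <- suppressWarnings(stats::cor(y_true, y_pred))
    scc <- suppressWarnings(stats::cor(y_true, y_pred, method = "spearman"))
    ss_tot <- sum((y_true - mean(y_true))^2)
    r2 <- if (ss_tot > 0) 1 - sum(err^2) / ss_tot else NA_real_
    structure(list(task = task, n = n,
                   RMSE = sqrt(mean(err^2)), MAE = mean(abs(err)),
                   PCC = pcc, SCC = scc, R2 = r2,
                   undefined = character(0)),
              class = "metrics_report")
  }
}

# Average precision: mean of precision@k over the positions of positives in
# the score-descending ranking (step-function area under the PR curve).
average_precision <- function(y, score) {
  o <- order(score, decreasing = TRUE)
  y <- y[o]
  cum_tp <- cumsum(y)
  prec <- cum_tp / seq_along(y)
  sum(prec[y == 1L]) / sum(y)
}

#' @export
print.metrics_report <- function(x, ...) {
  nums <- x[setdiff(names(x), c("task", "n", "undefined"))]
  cat("<metrics_report>", x$task, "on n =", x$n, "\n")
  for (nm in names(nums)) cat(sprintf("  %-6s %s\n", nm,
                                      formatC(nums[[nm]], digits = 4,
                                              format = "f")))
  invisible(x)
}

#' Repeated-seed evaluation
#'
#' Repeats the full split-train-test cycle with independent seeds and
#' reports, for every metric, the mean and a Student-t confidence interval
#' on the mean (alpha = 0.05 by default, n - 1 degrees of freedom).
#'
#' @param bundle A featurized `dataset_bundle`.
#' @param config A [synergraph_config()].
#' @param n_repeats Number of repeats (default 15).
#' @param mode Split mode passed to [make_split()].
#' @param alpha CI significance level.
#' @param seed Base seed; repeat `r` uses `seed + r`.
#' @param ... Further arguments to [make_split()].
#' @return List with `per_repeat` (data.frame of metrics by repeat) and
#'   `summary` (mean, sd, ci_lower, ci_upper per metric), plus the run
#'   manifest (`n_repeats`, `mode`, `seed`).
#' @export
repeat_evaluate <- function(bundle, config, n_repeats = 15L, mode = "random",
                            alpha = 0.05, seed = 1L, ...) {
  stopifnot(n_repeats >= 2L)
  rows <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    sr <- as.integer(seed) + r
    plan <- make_split(bundle$records, mode = mode, seed = sr, ...)
    cfg <- config
    cfg$seed <- sr
    fit <- train_model(bundle, plan, cfg)
    m <- evaluate_model(fit, bundle, plan$test)
    rows[[r]] <- data.frame(repeat_id = r, seed = sr,
                            t(unlist(m[setdiff(names(m),
                                               c("task", "n", "undefined"))])))
  }
  per_repeat <- do.call(rbind, rows)
  metric_cols <- setdiff(names(per_repeat), c("repeat_id", "seed"))
  summ <- summarize_repeats(per_repeat[metric_cols], alpha)
  list(per_repeat = per_repeat, summary = summ,
       manifest = list(n_repeats = n_repeats, mode = mode, seed = seed,
                       alpha = alpha))
}

summarize_repeats <- function(df, alpha = 0.05) {
  n <- nrow(df)
  tq <- stats::qt(1 - alpha / 2, df = n - 1L)
  do.call(rbind, lapply(names(df), function(nm) {
    x <- df[[nm]]
    m <- mean(x, na.rm = TRUE)
    s <- stats::sd(x, na.rm = TRUE)
    half <- tq * s / sqrt(n)
    data.frame(metric = nm, mean = m, sd = s,
               ci_lower = m - half, ci_upper = m + half)
  }))
}

#' Hyperparameter search hook
#'
#' Evaluates `n_trials` configurations drawn from a discrete search space
#' and returns the one with the lowest validation loss. The search is
#' random (seeded); when the full grid is no larger than the trial budget it
#' is enumerated exhaustively. A pluggable `sampler` can replace the default
#' draw (e.g., an external Bayesian optimizer).
#'
#' @param bundle A featurized `dataset_bundle`.
#' @param plan A `split_plan`.
#' @param base_config Configuration whose fields the sampled values
#'   override.
#' @param search_space Named list; each element is a vector of candidate
#'   values for one configuration field.
#' @param n_trials Trial budget (default 30).
#' @param seed RNG seed.
#' @param sampler Optional `function(search_space, n_trials, seed)` that
#'   returns a list of named value sets.
#' @return List with `best_config`, `best_val_loss`, and `trials`
#'   (data.frame of sampled values and validation losses; one row per
#'   trial).
#' @export
tune_hyperparameters <- function(bundle, plan, base_config, search_space,
                                 n_trials = 30L, seed = 1L, sampler = NULL) {
  stopifnot(length(search_space) >= 1L)
  grid_size <- prod(vapply(search_space, length, numeric(1)))
  candidates <- if (!is.null(sampler)) {
    sampler(search_space, n_trials, seed)
  } else if (grid_size <= n_trials) {
    g <- expand.grid(search_space, stringsAsFactors = FALSE)
    lapply(seq_len(nrow(g)), function(i) as.list(g[i, , drop = FALSE]))
  } else {
    set.seed(seed)
    lapply(seq_len(n_trials), function(i) {
      lapply(search_space, function(v) sample(v, 1L))
    })
  }
  losses <- numeric(length(candidates))
  for (i in seq_along(candidates)) {
    cfg <- utils::modifyList(base_config, candidates[[i]])
    class(cfg) <- "synergraph_config"
    fit <- train_model(bundle, plan, cfg)
    losses[i] <- min(fit$history$val_loss)
  }
  best <- which.min(losses)
  trials <- cbind(do.call(rbind, lapply(candidates, as.data.frame)),
                  val_loss = losses)
  best_config <- utils::modifyList(base_config, candidates[[best]])
  class(best_config) <- "synergraph_config"
  list(best_config = best_config, best_val_loss = losses[best],
       trials = trials, n_trials = length(candidates))
}
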