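# Splitting (including cold-start modes), early stopping, metrics,
# repeated evaluation and the tuning hook.

fake_records <- function(n = 100L, n_drugs = 10L, n_lines = 6L,
                         seed = 1L) {
  set.seed(seed)
  drugs <- sprintf("D%02d", seq_len(n_drugs))
  pairs <- t(replicate(n, sample(drugs, 2L)))
  data.frame(drug_a = pairs[, 1], drug_b = pairs[, 2],
             cell_line = sample(sprintf("CL%d", seq_len(n_lines)), n, TRUE),
             loewe = rnorm(n, sd = 10), stringsAsFactors = FALSE)
}

test_that("random splits honor the 80:20 ratio", {
  recs <- fake_records(100L)
  plan <- make_split(recs, "random", ratio = 0.8, seed = 3L)
  expect_length(plan$test, 20L)
  expect_length(c(plan$train, plan$val), 80L)
  expect_length(intersect(c(plan$train, plan$val), plan$test), 0L)
  expect_setequal(c(plan$train, plan$val, plan$test), seq_len(100L))
})

test_that("k-fold folds are disjoint, covering, and balanced", {
  recs <- fake_records(103L)
  plan <- make_split(recs, "kfold", ratio = 0.8, k = 5L, seed = 5L)
  folds <- plan$folds
  expect_length(folds, 5L)
  all_idx <- sort(unlist(folds))
  expect_length(all_idx, length(unique(all_idx)))  # disjoint
  expect_setequal(c(all_idx, plan$test), seq_len(103L))  # cover
  sizes <- lengths(folds)
  expect_lte(diff(range(sizes)), 1L)
})

test_that("leave-drug-out puts exactly the held-out drug's records in test", {
  recs <- data.frame(
    drug_a = c("a", "a", "b", "c", "c", "b"),
    drug_b = c("b", "c", "c", "a", "b", "a"),
    cell_line = "CL1", loewe = 1:6, stringsAsFactors = FALSE)
  plan <- make_split(recs, "leave_drug_out", holdout = "c",
                     val_fraction = 0.34, seed = 1L)
  expect_setequal(plan$test, which(recs$drug_a == "c" | recs$drug_b == "c"))
  train_drugs <- unique(c(recs$drug_a[c(plan$train, plan$val)],
                          recs$drug_b[c(plan$train, plan$val)]))
  expect_length(intersect(train_drugs, "c"), 0L)
  expect_silent(leakage_audit(plan, recs))
})

test_that("cold-start plans pass the leakage audit over many seeds", {
  recs <- fake_records(200L, n_drugs = 12L, n_lines = 8L)
  for (mode in c("leave_combination_out", "leave_drug_out",
                 "leave_cell_line_out")) {
    for (s in 1:10) {
      plan <- make_split(recs, mode, seed = s)
      expect_silent(leakage_audit(plan, recs))
    }
  }
})

test_that("unsatisfiable split requests fail loudly", {
  one_drug <- data.frame(drug_a = "a", drug_b = "a", cell_line = "CL1",
                         loewe = 1)
  expect_error(make_split(one_drug, "leave_drug_out"), "split error")
  expect_error(make_split(fake_records(10L), "random", ratio = 1),
               "split error")
  empty <- data.frame(drug_a = character(0), drug_b = character(0),
                      cell_line = character(0), loewe = numeric(0))
  expect_error(make_split(empty, "random"), "split error")
})

test_that("early stopping fires at the documented budgets", {
  # best at epoch 1, then 30 epochs without improvement
  flat <- c(1, rep(1, 30))
  expect_equal(early_stop_check(flat)$reason, "patience_no_improve")
  expect_equal(early_stop_check(c(1, rep(1, 29)))$reason, "continue")

  # 10 consecutive increases
  rising <- cumsum(c(1, rep(0.1, 10)))
  expect_equal(early_stop_check(rising)$reason, "consecutive_increase")
  expect_equal(early_stop_check(cumsum(c(1, rep(0.1, 9))))$reason,
               "continue")

  # monotone decrease never stops
  expect_equal(early_stop_check(seq(1, 0.5, length.out = 50))$reason,
               "continue")

  # improvements below tol do not reset the patience counter
  creeping <- 1 - cumsum(rep(1e-6, 32))
  expect_equal(early_stop_check(creeping, tol = 1e-4)$reason,
               "patience_no_improve")
})

test_that("classification metrics match their definitions", {
  m <- compute_metrics(c(1, 0, 1, 0), c(0.9, 0.1, 0.8, 0.2),
                       "classification")
  expect_equal(m$AUROC, 1)
  expect_equal(m$F1, 1)
  expect_equal(m$kappa, 1)
  expect_equal(m$ACC, 1)

  m2 <- compute_metrics(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1),
                        "classification")
  expect_equal(m2$AUROC, 0.75)

  m3 <- compute_metrics(c(1, 1, 1), c(0.9, 0.2, 0.6), "classification")
  expect_true(is.na(m3$AUROC))
  expect_true("AUROC" %in% m3$undefined)
  expect_error(compute_metrics(c(1, 0), c(1.2, 0.1), "classification"),
               "\\[0, 1\\]")
})

test_that("regression metrics match their definitions", {
  y <- c(1, 2, 3, 4)
  m <- compute_metrics(y, y, "regression")
  expect_equal(m$RMSE, 0)
  expect_equal(m$PCC, 1)
  expect_equal(m$R2, 1)
  yhat <- c(1.5, 2.5, 2.5, 4.5)
  m2 <- compute_metrics(y, yhat, "regression")
  expect_equal(m2$RMSE, sqrt(mean((yhat - y)^2)))
  expect_equal(m2$MAE, 0.5)
  expect_equal(m2$SCC, cor(y, yhat, method = "spearman"))
  expect_equal(m2$R2, 1 - sum((yhat - y)^2) / sum((y - mean(y))^2))
})

test_that("metrics agree with brute-force oracles on random vectors", {
  set.seed(404)
  for (i in 1:50) {
    n <- sample(6:20, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    s <- runif(n)
    m <- compute_metrics(y, s, "classification")

    # AUROC by enumerating positive-negative pairs (ties count 1/2)
    pos <- s[y == 1]; neg <- s[y == 0]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(m$AUROC, mean(cmp), tolerance = 1e-9)

    # average precision by its sum definition
    o <- order(s, decreasing = TRUE)
    yo <- y[o]
    ap <- sum((cumsum(yo) / seq_along(yo))[yo == 1]) / sum(yo)
    expect_equal(m$AUCPR, ap, tolerance = 1e-9)

    # kappa from the confusion matrix
    pred <- as.integer(s >= 0.5)
    po <- mean(pred == y)
    pe <- mean(y) * mean(pred) + (1 - mean(y)) * (1 - mean(pred))
    kap <- if (pe == 1) 0 else (po - pe) / (1 - pe)
    expect_equal(m$kappa, kap, tolerance = 1e-9)
  }
})

test_that("repeat aggregation applies the Student-t interval", {
  summ <- synergraph:::summarize_repeats(data.frame(AUROC = c(0.7, 0.8, 0.9)))
  expect_equal(summ$mean, 0.8)
  half <- qt(0.975, df = 2) * sd(c(0.7, 0.8, 0.9)) / sqrt(3)
  expect_equal(summ$ci_upper - summ$mean, half, tolerance = 1e-12)
  # identical values collapse the interval
  s0 <- synergraph:::summarize_repeats(data.frame(x = rep(0.5, 4)))
  expect_equal(s0$ci_upper - s0$ci_lower, 0)
})

test_that("repeated evaluation runs end to end with a manifest", {
  b <- tiny_bundle()
  cfg <- tiny_model_config(max_epochs = 4L)
  res <- repeat_evaluate(b, cfg, n_repeats = 2L, seed = 21L)
  expect_equal(nrow(res$per_repeat), 2L)
  expect_true("AUROC" %in% res$summary$metric)
  expect_equal(res$manifest$n_repeats, 2L)
})

test_that("the tuning hook selects the stronger configuration", {
  b <- tiny_bundle()
  plan <- make_split(b$records, "random", seed = 31L)
  base <- tiny_model_config(max_epochs = 8L)
  # single-point space returns that point
  one <- tune_hyperparameters(b, plan, base,
                              list(omics_dim = 8L), n_trials = 5L)
  expect_equal(one$best_config$omics_dim, 8L)
  expect_equal(one$n_trials, 1L)

  # a healthy width beats a crippled width-1 network
  two <- tune_hyperparameters(b, plan, base,
                              list(omics_dim = c(1L, 8L)),
                              n_trials = 4L, seed = 2L)
  expect_equal(nrow(two$trials), 2L)
  expect_equal(two$best_config$omics_dim, 8L)
})
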