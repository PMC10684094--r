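test_that("sparsity and correlation penalties match their definitions", {
  net <- tiny_network(seed = 2, K = 3)
  p <- network_params(net)
  # independent summation oracle over the constrained entries
  expect_equal(sparsity_loss(net), sum(abs(p$A)) + sum(abs(p$M)),
               tolerance = 1e-12)
  # zero parameters give zero penalty
  net0 <- net
  net0$raw$A[] <- -40; net0$raw$M[] <- -40
  expect_equal(sparsity_loss(net0), 0, tolerance = 1e-10)
  # single rule: empty pair sum
  sc <- tiny_schema()
  net1 <- fz_network(sc, K = 1, C = 2, seed = 1)
  expect_identical(correlation_loss(net1), 0)
  # two identical all-ones rules over N features x usable concepts
  net2 <- fz_network(sc, K = 2, C = 2, seed = 1)
  net2$raw$A[] <- 40; net2$raw$M[] <- 40
  usable <- sum(fuzznet:::concept_mask(sc))
  expect_equal(correlation_loss(net2), usable, tolerance = 1e-6)
  # random instance vs brute-force double loop over rule pairs
  net3 <- tiny_network(seed = 14, K = 3)
  S <- contribution_matrix(net3)
  acc <- 0
  for (i in 1:2) for (j in (i + 1):3) {
    acc <- acc + sum(as.vector(S[, , i]) * as.vector(S[, , j]))
  }
  expect_equal(correlation_loss(net3), acc, tolerance = 1e-12)
})

test_that("total loss decomposes into weighted CE plus penalties", {
  net <- tiny_network(seed = 4)
  b <- tiny_batch(8, seed = 7)
  cfg0 <- train_config(lambda_sparse = 0, lambda_corr = 0,
                       class_weights = c(1, 1))
  pr <- predict(net, b$X, type = "prob")
  ce <- -mean(log(pr[cbind(1:8, b$y)]))
  expect_equal(as.numeric(total_loss(net, b$X, b$y, cfg0)), ce,
               tolerance = 1e-10)
  # uniform predictions, equal weights: ln 2 per sample
  net$raw$W[, 2] <- net$raw$W[, 1]
  expect_equal(as.numeric(total_loss(net, b$X, b$y, cfg0)), log(2),
               tolerance = 1e-12)
  # fixed tiny batch with penalties: matches the composed oracles
  cfg <- train_config(lambda_sparse = 0.1, lambda_corr = 0.1,
                      class_weights = c(1, 2))
  net <- tiny_network(seed = 4)
  pr <- predict(net, b$X[1:4, ], type = "prob")
  w <- c(1, 2)[b$y[1:4]]
  ce <- -sum(w * log(pr[cbind(1:4, b$y[1:4])])) / sum(w)
  expect_equal(as.numeric(total_loss(net, b$X[1:4, ], b$y[1:4], cfg)),
               ce + 0.1 * sparsity_loss(net) + 0.1 * correlation_loss(net),
               tolerance = 1e-12)
})

test_that("analytic gradients agree with central finite differences", {
  # seeded instance: 5 features, 3 rules, 2 classes, batch of 8
  net <- tiny_network(seed = 7, eps = 0.35, K = 3)
  b <- tiny_batch(8, seed = 1)
  cfg <- train_config(lambda_sparse = 0.1, lambda_corr = 0.1)
  Xm <- fuzznet:::as_feature_matrix(net, b$X)
  lg <- fuzznet:::fz_loss_grad(net, Xm, b$y, cfg)
  th <- fuzznet:::flatten_raw(net)
  g <- fuzznet:::flatten_grads(lg$grads)
  h <- 1e-5
  fd <- vapply(seq_along(th), function(j) {
    tp <- th; tp[j] <- tp[j] + h
    tm <- th; tm[j] <- tm[j] - h
    (fuzznet:::fz_loss_grad(fuzznet:::unflatten_raw(net, tp), Xm, b$y,
                            cfg)$loss -
       fuzznet:::fz_loss_grad(fuzznet:::unflatten_raw(net, tm), Xm, b$y,
                              cfg)$loss) / (2 * h)
  }, numeric(1))
  # per parameter group: attention, connection, inference, cutoffs
  nA <- length(net$raw$A); nM <- length(net$raw$M); nW <- length(net$raw$W)
  groups <- list(A = seq_len(nA), M = nA + seq_len(nM),
                 W = nA + nM + seq_len(nW),
                 cut = nA + nM + nW + seq_len(length(net$raw$cut)))
  for (gn in names(groups)) {
    idx <- groups[[gn]]
    rel <- abs(g[idx] - fd[idx]) / pmax(abs(fd[idx]), 1e-8)
    expect_lt(max(rel), 1e-4)
  }
})

test_that("fitting is deterministic and honors the zero-epoch contract", {
  set.seed(99)
  X <- matrix(rnorm(60 * 2), 60, 2)
  y <- as.integer(X[, 1] + X[, 2] > 0)
  sc <- feature_schema(c("a", "b"), rep("continuous", 2))
  cfg <- train_config(n_epochs = 5, n_rules = 3, seed = 11, batch_size = 16)
  n1 <- fit_network(X, y, sc, cfg)
  n2 <- fit_network(X, y, sc, cfg)
  expect_identical(n1$raw, n2$raw)
  expect_identical(attr(n1, "log"), attr(n2, "log"))
  # zero epochs: initialization returned unchanged
  cfg0 <- train_config(n_epochs = 0, n_rules = 3, seed = 11)
  ninit <- fz_network(sc, K = 3, C = 2, seed = 11,
                      smooth = smoothness_state(),
                      cutoff_quantiles = fuzznet:::data_cutoff_quantiles(X, sc))
  n0 <- fit_network(X, y, sc, cfg0)
  expect_identical(n0$raw, ninit$raw)
})

test_that("training learns a separable problem and the loss trends down", {
  set.seed(123)
  n <- 200
  X <- matrix(rnorm(n * 2), n, 2)
  y <- as.integer(X[, 1] - X[, 2] > 0)
  sc <- feature_schema(c("a", "b"), rep("continuous", 2))
  cfg <- train_config(n_epochs = 60, n_rules = 4, seed = 1,
                      batch_size = n, learning_rate = 0.05,
                      lambda_sparse = 0, lambda_corr = 0)
  net <- fit_network(X, y, sc, cfg)
  lg <- attr(net, "log")
  expect_true(all(diff(lg$loss[1:10]) < 0))
  pr <- predict(net, X, type = "prob")[, 2]
  auc <- fuzznet:::auc_trapezoid(y, pr)
  expect_gt(auc, 0.95)
})

test_that("stronger sparsity pressure does not increase the sparsity term", {
  set.seed(5)
  X <- matrix(rnorm(120 * 3), 120, 3)
  y <- as.integer(X[, 1] > 0)
  sc <- feature_schema(c("a", "b", "c"), rep("continuous", 3))
  base <- train_config(n_epochs = 30, n_rules = 4, seed = 2,
                       lambda_sparse = 1e-3)
  strong <- base; strong$lambda_sparse <- 1e-2
  n1 <- fit_network(X, y, sc, base)
  n2 <- fit_network(X, y, sc, strong)
  expect_lte(sparsity_loss(n2), sparsity_loss(n1) + 1e-8)
})

test_that("random search is reproducible and avoids sabotaged configurations", {
  set.seed(31)
  X <- matrix(rnorm(80 * 2), 80, 2)
  y <- as.integer(X[, 1] > 0)
  pid <- rep(sprintf("P%02d", 1:20), each = 4)
  sc <- feature_schema(c("a", "b"), rep("continuous", 2))
  base <- train_config(n_epochs = 8, n_rules = 2, batch_size = 40)
  # single trial returns that configuration
  sp1 <- list(learning_rate = list(min = 0.01, max = 0.1, log = TRUE))
  r1 <- random_search(X, y, sc, pid, sp1, n_trials = 1, seed = 3, k = 2,
                      base_config = base)
  expect_equal(nrow(r1$results), 1)
  expect_equal(r1$best_config$learning_rate, r1$results$learning_rate[1])
  # degenerate space returns the unique configuration
  sp2 <- list(lambda_sparse = list(min = 1e-3, max = 1e-3, log = TRUE))
  r2 <- random_search(X, y, sc, pid, sp2, n_trials = 3, seed = 3, k = 2,
                      base_config = base)
  expect_equal(r2$results$lambda_sparse, rep(1e-3, 3), tolerance = 1e-12)
  # a two-point space with a sabotaged learning rate selects the live one
  sp3 <- list(learning_rate = list(values = c(0, 0.05)))
  r3 <- random_search(X, y, sc, pid, sp3, n_trials = 6, seed = 4, k = 2,
                      base_config = base)
  expect_true(0 %in% r3$results$learning_rate)   # the sabotage was sampled
  expect_gt(r3$best_config$learning_rate, 0)
  # reproducibility
  r3b <- random_search(X, y, sc, pid, sp3, n_trials = 6, seed = 4, k = 2,
                       base_config = base)
  expect_identical(r3$results, r3b$results)
})

test_that("train configurations round-trip through YAML", {
  cfg <- train_config(lambda_sparse = 0.02, n_epochs = 17, seed = 5)
  path <- tempfile(fileext = ".yaml")
  write_train_config(cfg, path)
  cfg2 <- read_train_config(path)
  expect_equal(cfg2[setdiff(names(cfg2), "patience")],
               cfg[setdiff(names(cfg), "patience")])
})
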