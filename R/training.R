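# Loss assembly and gradient-based fitting. Gradients are analytic,
# hand-derived through the whole network (memberships, T-norm, T-conorm,
# softmax cross-entropy, regularizers and the sigmoid/softplus/ordered-gap
# reparameterizations) and are verified against central finite differences
# in the test suite.

#' Training configuration
#'
#' @param lambda_sparse weight of the attention/connection L1 sparsity
#'   penalty (default 1e-3).
#' @param lambda_corr weight of the rule-decorrelation penalty
#'   (default 1e-3).
#' @param class_weights per-class loss weights; NULL for inverse class
#'   frequency (upweights the rarer, positive, class).
#' @param learning_rate Adam step size (default 0.01).
#' @param n_epochs number of passes over the training data (default 200).
#' @param batch_size minibatch size (default 64).
#' @param gamma smoothness decay rate per optimizer step (default 0.999).
#' @param eps_min smoothness floor (default 0.01).
#' @param n_rules number of rules K (default 10).
#' @param seed RNG seed controlling initialization and minibatch order.
#' @param patience early-stopping patience in epochs on the training loss;
#'   \code{Inf} (default) disables early stopping.
#' @return a list of class \code{train_config}.
#' @export
train_config <- function(lambda_sparse = 1e-3, lambda_corr = 1e-3,
                         class_weights = NULL, learning_rate = 0.01,
                         n_epochs = 200L, batch_size = 64L,
                         gamma = 0.999, eps_min = 0.01,
                         n_rules = 10L, seed = 1L, patience = Inf) {
  stopifnot(lambda_sparse >= 0, lambda_corr >= 0, learning_rate > 0,
            n_epochs >= 0, batch_size >= 1, gamma > 0, gamma <= 1,
            eps_min > 0, n_rules >= 1)
  structure(list(lambda_sparse = lambda_sparse, lambda_corr = lambda_corr,
                 class_weights = class_weights,
                 learning_rate = learning_rate,
                 n_epochs = as.integer(n_epochs),
                 batch_size = as.integer(batch_size),
                 gamma = gamma, eps_min = eps_min,
                 n_rules = as.integer(n_rules), seed = as.integer(seed),
                 patience = patience),
            class = "train_config")
}

#' Sparsity penalty
#'
#' L1 norm of the constrained attention and connection entries,
#' \eqn{\|vec(A)\|_1 + \|vec(M)\|_1}; since both live in \eqn{[0,1]} this is
#' their plain sum. Structurally invalid concept slots of categorical
#' features are excluded.
#'
#' @param net an [fz_network()].
#' @return scalar \eqn{\ge 0}.
#' @export
sparsity_loss <- function(net) {
  p <- network_params(net)
  sum(p$A) + sum(p$M)
}

#' Rule decorrelation penalty
#'
#' Sum over rule pairs of the inner products of vectorized contribution
#' columns, \eqn{\sum_{k < k'} \langle vec(S_{:,:,k}),
#' vec(S_{:,:,k'})\rangle} with \eqn{S_{i,d,k} = A_{i,d,k} M_{i,k}};
#' penalizes rules that attend to the same feature concepts.
#'
#' @param net an [fz_network()].
#' @return scalar \eqn{\ge 0}.
#' @export
correlation_loss <- function(net) {
  S <- contribution_matrix(net)
  K <- net$K
  if (K == 1L) return(0)
  V <- matrix(S, ncol = K)           # vec(S_k) as columns
  tot <- rowSums(V)
  (sum(tot^2) - sum(V^2)) / 2
}

# Weighted cross-entropy of softmax probabilities.
# y: integer classes in 1..C; w: per-class weights.
weighted_ce <- function(prob, y, w) {
  wb <- w[y]
  -sum(wb * log(pmax(prob[cbind(seq_along(y), y)], 1e-300))) / sum(wb)
}

#' Total training loss
#'
#' Weighted cross-entropy plus \code{lambda_sparse} times the sparsity
#' penalty plus \code{lambda_corr} times the rule decorrelation penalty.
#'
#' @param net an [fz_network()].
#' @param X model-ready feature matrix.
#' @param y integer class labels in 1..C.
#' @param config a [train_config()].
#' @return scalar loss with attribute \code{"components"}.
#' @export
total_loss <- function(net, X, y, config = train_config()) {
  w <- resolve_class_weights(config$class_weights, y, net$C)
  fw <- fz_forward(net, X)
  ce <- weighted_ce(fw$prob, y, w)
  sp <- sparsity_loss(net)
  co <- correlation_loss(net)
  out <- ce + config$lambda_sparse * sp + config$lambda_corr * co
  attr(out, "components") <- c(ce = ce, sparsity = sp, correlation = co)
  out
}

resolve_class_weights <- function(class_weights, y, C) {
  if (!is.null(class_weights)) {
    stopifnot(length(class_weights) == C, all(class_weights > 0))
    return(class_weights)
  }
  tab <- tabulate(y, nbins = C)
  tab[tab == 0] <- 1
  length(y) / (C * tab)
}

# Loss and analytic gradients with respect to the raw parameters.
fz_loss_grad <- function(net, X, y, config) {
  w <- resolve_class_weights(config$class_weights, y, net$C)
  fw <- fz_forward(net, X)
  ca <- fw$cache; p <- fw$params
  B <- nrow(fw$prob); N <- net$schema$n_features
  D <- net$schema$max_concepts; K <- net$K; C <- net$C
  eps1 <- eps_role(net, "eps1")

  ce <- weighted_ce(fw$prob, y, w)
  sp <- sum(p$A) + sum(p$M)
  S <- p$A
  for (k in seq_len(K)) S[, , k] <- p$A[, , k] * p$M[, k]
  V <- matrix(S, ncol = K)
  co <- if (K > 1L) (sum(rowSums(V)^2) - sum(V^2)) / 2 else 0
  loss <- ce + config$lambda_sparse * sp + config$lambda_corr * co

  # --- backward: cross entropy -> O
  wb <- w[y]; sw <- sum(wb)
  Y <- matrix(0, B, C); Y[cbind(seq_len(B), y)] <- 1
  dO <- (fw$prob - Y) * wb / sw

  # --- inference layer -> r, W
  dr <- matrix(0, B, K)
  dlogW <- matrix(0, K, C)
  for (cc in seq_len(C)) {
    g <- dO[, cc] * fw$O[, cc]              # d loss / d logO_c
    smc <- matrix(ca$sm[, , cc], B, K)
    dlr_c <- smc * g                        # B x K
    dr <- dr + dlr_c / fw$r
    dlogW[, cc] <- colSums(dlr_c)
  }
  dW <- dlogW / p$W

  # --- T-norm -> xt, M
  dlog_base <- dr * fw$r * ca$pw                   # B x K
  LB <- aperm(array(matrix(ca$log_base, B, K), dim = c(B, K, N)), c(1, 3, 2))
  wgt <- exp(ca$lu - LB)                           # u_i / base, in [0, 1]
  dlu <- wgt * aperm(array(dlog_base, dim = c(B, K, N)), c(1, 3, 2))
  # dE[i,k] = sum_b dlu * lxc ; dlxc = dlu * E
  dE <- apply(dlu * ca$lxc, c(2, 3), sum)
  dM_t <- dE * ca$c2
  dlxc <- dlu * rep(ca$E, each = B)
  dxc <- dlxc / ca$xc
  interior <- ca$xt > TNORM_CLAMP & ca$xt < 1
  dxt <- dxc * interior

  # --- attention layer -> A, Z
  dA <- array(0, dim = c(N, D, K))
  dZ <- array(0, dim = dim(ca$Z))
  for (i in seq_len(N)) {
    Zi <- matrix(ca$Z[, i, ], nrow = B)
    dxti <- matrix(dxt[, i, ], nrow = B)
    dA[i, , ] <- crossprod(Zi, dxti)
    dZ[, i, ] <- dxti %*% t(matrix(p$A[i, , ], nrow = D))
  }

  # --- regularizers -> A, M
  dA_reg <- array(config$lambda_sparse, dim = c(N, D, K)) *
    array(net$mask, dim = c(N, D, K))
  dM_reg <- matrix(config$lambda_sparse, N, K)
  if (K > 1L && config$lambda_corr > 0) {
    tot <- rowSums(V)
    gS <- array(tot, dim = c(N, D, K)) - S       # d co / d S
    for (k in seq_len(K)) {
      dA_reg[, , k] <- dA_reg[, , k] + config$lambda_corr * gS[, , k] * p$M[, k]
      dM_reg[, k] <- dM_reg[, k] +
        config$lambda_corr * rowSums(matrix(gS[, , k] * p$A[, , k], nrow = N))
    }
  }
  dA <- dA + dA_reg
  dM_t <- dM_t + dM_reg

  # --- encoding layer -> cutoffs (continuous features only)
  X <- as_feature_matrix(net, ca$X)
  n_cont <- length(net$cont_idx)
  dcut <- matrix(0, n_cont, 4)
  for (ci in seq_len(n_cont)) {
    i <- net$cont_idx[ci]
    mg <- membership_grads(X[, i], p$cutoffs[ci, ], eps1)
    for (d in 1:3) {
      g <- mg[[d]]                                # B x (x, a1..a4)
      dcut[ci, ] <- dcut[ci, ] + colSums(dZ[, i, d] * g[, 2:5, drop = FALSE])
    }
  }

  # --- reparameterization chain to raw space
  As <- sigmoid(net$raw$A)
  dA_raw <- dA * As * (1 - As) * array(net$mask, dim = c(N, D, K))
  Ms <- sigmoid(net$raw$M)
  dM_raw <- dM_t * Ms * (1 - Ms)
  dW_raw <- dW * sigmoid(net$raw$W)
  dcut_raw <- matrix(0, n_cont, 4)
  for (ci in seq_len(n_cont)) {
    da <- dcut[ci, ]
    th <- net$raw$cut[ci, ]
    csum <- rev(cumsum(rev(da)))                  # sum of da_j for j >= index
    dcut_raw[ci, 1] <- csum[1]
    dcut_raw[ci, 2:4] <- csum[2:4] * sigmoid(th[2:4])
  }

  list(loss = loss,
       components = c(ce = ce, sparsity = sp, correlation = co),
       grads = list(A = dA_raw, M = dM_raw, W = dW_raw, cut = dcut_raw),
       prob = fw$prob)
}

# Flatten raw parameters to a vector and back (used by Adam and the
# finite-difference checks).
flatten_raw <- function(net) {
  c(as.vector(net$raw$A), as.vector(net$raw$M),
    as.vector(net$raw$W), as.vector(net$raw$cut))
}
unflatten_raw <- function(net, v) {
  nA <- length(net$raw$A); nM <- length(net$raw$M)
  nW <- length(net$raw$W); nC <- length(net$raw$cut)
  stopifnot(length(v) == nA + nM + nW + nC)
  net$raw$A <- array(v[seq_len(nA)], dim = dim(net$raw$A))
  net$raw$M <- matrix(v[nA + seq_len(nM)], nrow = nrow(net$raw$M))
  net$raw$W <- matrix(v[nA + nM + seq_len(nW)], nrow = nrow(net$raw$W))
  net$raw$cut <- matrix(v[nA + nM + nW + seq_len(nC)],
                        nrow = nrow(net$raw$cut))
  net
}
flatten_grads <- function(g) {
  c(as.vector(g$A), as.vector(g$M), as.vector(g$W), as.vector(g$cut))
}

#' Fit a fuzzy rule network
#'
#' Minimizes the total loss (weighted cross-entropy + sparsity +
#' decorrelation) with Adam over minibatches; the shared smoothness
#' \eqn{\epsilon} is annealed once per optimizer step (it is scheduled, not
#' trained). Optionally starts from a clinical-knowledge initialization.
#'
#' @param X model-ready feature matrix or data.frame (continuous columns
#'   standardized, categorical columns level codes or 0/1).
#' @param y class labels: integer in 1..C, a factor, or 0/1.
#' @param schema a [feature_schema()].
#' @param config a [train_config()].
#' @param init optional [ruleset()] used for knowledge-based initialization
#'   (see [init_from_rules()]).
#' @param net optional pre-built [fz_network()] to continue training; when
#'   given, \code{schema} and \code{init} are ignored.
#' @return the trained network, with a \code{log} attribute: a data.frame
#'   with one row per epoch (total loss, cross-entropy, sparsity and
#'   correlation terms, epsilon).
#' @export
fit_network <- function(X, y, schema, config = train_config(), init = NULL,
                        net = NULL) {
  X <- if (is.data.frame(X)) X else as.matrix(X)
  y <- as_class_index(y)
  C <- max(2L, max(y))
  if (is.null(net)) {
    cq <- NULL
    if (!is.null(schema)) {
      cq <- data_cutoff_quantiles(X, schema)
    }
    net <- if (!is.null(init) && length(init$rules) > 0) {
      init_from_rules(init, schema, K = config$n_rules, seed = config$seed,
                      C = C, cutoff_quantiles = cq)
    } else {
      fz_network(schema, K = config$n_rules, C = C, seed = config$seed,
                 smooth = smoothness_state(eps_min = config$eps_min,
                                           gamma = config$gamma),
                 cutoff_quantiles = cq)
    }
  }
  net$smooth$gamma <- config$gamma
  net$smooth$eps_min <- config$eps_min
  B <- if (is.data.frame(X)) nrow(X) else nrow(as.matrix(X))
  if (config$n_epochs == 0L) {
    attr(net, "log") <- empty_train_log()
    return(net)
  }
  Xm <- as_feature_matrix(net, X)
  theta <- flatten_raw(net)
  m <- v <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8; t <- 0L
  log_rows <- vector("list", config$n_epochs)
  set.seed(config$seed + 1L)
  best <- Inf; wait <- 0L
  for (epoch in seq_len(config$n_epochs)) {
    idx <- sample.int(B)
    splits <- split(idx, ceiling(seq_along(idx) / config$batch_size))
    ep_loss <- ep_comp <- NULL
    for (bi in splits) {
      net <- unflatten_raw(net, theta)
      lg <- fz_loss_grad(net, Xm[bi, , drop = FALSE], y[bi], config)
      if (!is.finite(lg$loss)) {
        stop("non-finite loss at epoch ", epoch, ", step ", t,
             " (eps = ", signif(net$smooth$eps, 4),
             "; |theta| max = ", signif(max(abs(theta)), 4), ")")
      }
      g <- flatten_grads(lg$grads)
      t <- t + 1L
      m <- b1 * m + (1 - b1) * g
      v <- b2 * v + (1 - b2) * g^2
      mh <- m / (1 - b1^t); vh <- v / (1 - b2^t)
      theta <- theta - config$learning_rate * mh / (sqrt(vh) + adam_eps)
      net$smooth <- anneal_eps(net$smooth)
      ep_loss <- c(ep_loss, lg$loss)
      ep_comp <- rbind(ep_comp, lg$components)
    }
    log_rows[[epoch]] <- data.frame(
      epoch = epoch, loss = mean(ep_loss),
      ce = mean(ep_comp[, "ce"]), sparsity = mean(ep_comp[, "sparsity"]),
      correlation = mean(ep_comp[, "correlation"]), eps = net$smooth$eps)
    if (is.finite(config$patience)) {
      if (mean(ep_loss) < best - 1e-8) { best <- mean(ep_loss); wait <- 0L }
      else { wait <- wait + 1L; if (wait >= config$patience) break }
    }
  }
  net <- unflatten_raw(net, theta)
  attr(net, "log") <- do.call(rbind, log_rows[!vapply(log_rows, is.null,
                                                      logical(1))])
  net
}

empty_train_log <- function() {
  data.frame(epoch = integer(), loss = numeric(), ce = numeric(),
             sparsity = numeric(), correlation = numeric(), eps = numeric())
}

as_class_index <- function(y) {
  if (is.factor(y)) return(as.integer(y))
  y <- as.integer(y)
  if (all(y %in% c(0L, 1L))) y <- y + 1L
  stopifnot(all(y >= 1L))
  y
}

# Cutoff initialization at marginal quantiles of the training data.
data_cutoff_quantiles <- function(X, schema) {
  cont <- which(schema$features$kind == "continuous")
  if (length(cont) == 0L) return(NULL)
  if (is.data.frame(X)) X <- as.matrix(X[, schema$features$name, drop = FALSE])
  q <- t(vapply(cont, function(i) {
    stats::quantile(X[, i], c(0.1, 0.35, 0.65, 0.9), na.rm = TRUE,
                    names = FALSE)
  }, numeric(4)))
  # enforce usable gaps
  for (r in seq_len(nrow(q))) {
    for (j in 2:4) q[r, j] <- max(q[r, j], q[r, j - 1] + 2 * CUT_FLOOR)
  }
  q
}

#' Random hyperparameter search
#'
#' Samples \code{n_trials} configurations uniformly (log-uniformly for
#' rates and penalty weights), scores each by patient-wise cross-validated
#' mean AUC, and returns the best.
#'
#' @param X model-ready feature matrix.
#' @param y labels (see [fit_network()]).
#' @param schema a [feature_schema()].
#' @param patient_ids patient identifier per row (folds never split a
#'   patient).
#' @param search_space named list; each element is
#'   \code{list(min =, max =, log = TRUE/FALSE, integer = TRUE/FALSE)} or
#'   \code{list(values =)} (a discrete set) for a [train_config()] argument.
#' @param n_trials number of sampled configurations.
#' @param seed RNG seed (sampling, folds and fits all derive from it).
#' @param k number of CV folds (default 3).
#' @param base_config configuration supplying the unsearched arguments.
#' @return list with \code{best_config}, \code{best_score} and a
#'   \code{results} data.frame (one row per trial).
#' @export
random_search <- function(X, y, schema, patient_ids, search_space,
                          n_trials = 10L, seed = 1L, k = 3L,
                          base_config = train_config()) {
  stopifnot(n_trials >= 1L, length(search_space) >= 1L)
  y <- as_class_index(y)
  set.seed(seed)
  draws <- lapply(seq_len(n_trials), function(t) {
    vals <- lapply(search_space, function(sp) {
      if (!is.null(sp$values)) {
        stopifnot(all(is.finite(sp$values)))
        return(sample(sp$values, 1))
      }
      stopifnot(is.finite(sp$min), is.finite(sp$max), sp$min <= sp$max)
      v <- if (isTRUE(sp$log)) {
        exp(stats::runif(1, log(sp$min), log(sp$max)))
      } else {
        stats::runif(1, sp$min, sp$max)
      }
      if (isTRUE(sp$integer)) v <- as.integer(round(v))
      v
    })
    names(vals) <- names(search_space)
    vals
  })
  fold_of <- patient_fold_ids(patient_ids, y, k, seed = seed + 1L)
  score_trial <- function(vals) {
    cfg <- base_config
    for (nmx in names(vals)) cfg[[nmx]] <- vals[[nmx]]
    aucs <- vapply(seq_len(k), function(f) {
      tr <- fold_of != f; va <- !tr
      if (cfg$learning_rate <= 0) return(0.5)
      net <- fit_network(X[tr, , drop = FALSE], y[tr], schema, cfg)
      pr <- predict(net, X[va, , drop = FALSE], type = "prob")
      auc_trapezoid(as.integer(y[va] == net$C), pr[, net$C])
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  }
  scores <- vapply(draws, score_trial, numeric(1))
  res <- cbind(do.call(rbind, lapply(draws, as.data.frame)),
               cv_mean_auc = scores)
  best <- which.max(scores)
  cfg <- base_config
  for (nmx in names(draws[[best]])) cfg[[nmx]] <- draws[[best]][[nmx]]
  list(best_config = cfg, best_score = scores[best], results = res)
}

# Patient-wise stratified fold ids (no holdout; used by random_search).
patient_fold_ids <- function(patient_ids, y, k, seed) {
  pats <- unique(patient_ids)
  pos_pat <- vapply(pats, function(p) any(y[patient_ids == p] == max(y)),
                    logical(1))
  set.seed(seed)
  fold_pat <- integer(length(pats)); names(fold_pat) <- pats
  for (grp in list(pats[pos_pat], pats[!pos_pat])) {
    if (length(grp) == 0) next
    fold_pat[sample(as.character(grp))] <-
      rep_len(seq_len(k), length(grp))
  }
  unname(fold_pat[as.character(patient_ids)])
}

#' Write a training configuration to YAML
#' @param config a [train_config()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_train_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a training configuration from YAML
#' @param path a YAML file written by [write_train_config()].
#' @return a [train_config()].
#' @export
read_train_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (length(vals) == 0) return(train_config())
  vals <- vals[!vapply(vals, is.null, logical(1))]
  vals <- vals[names(vals) %in% names(formals(train_config))]
  do.call(train_config, vals)
}
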