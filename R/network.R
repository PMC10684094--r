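# Fuzzy rule network: encoding layer (fuzzy concepts / one-hot levels),
# rule layer (attention + connection matrices feeding the parameterized
# T-norm) and inference layer (inference matrix feeding the parameterized
# T-conorm), with sigmoid/softplus reparameterizations keeping every
# constrained parameter in its admissible set.

CUT_FLOOR <- 1e-3   # minimum cutoff gap; membership denominators never vanish
TNORM_CLAMP <- 1e-6 # lower clamp on conjunction inputs

#' Create a fuzzy rule network
#'
#' Builds an untrained network with \code{K} rules and \code{C} classes over
#' the given feature schema. Attention entries \eqn{A_{i,d,k}} (importance of
#' concept \eqn{d} of feature \eqn{i} to rule \eqn{k}) and connection entries
#' \eqn{M_{i,k}} (relevance of feature \eqn{i} to rule \eqn{k}) are kept in
#' \eqn{[0,1]} by a sigmoid reparameterization; inference entries
#' \eqn{W_{k,c}} (contribution of rule \eqn{k} to class \eqn{c}) are kept
#' nonnegative by a softplus reparameterization. Membership cutoffs are
#' parameterized as a free \eqn{a_1} plus three softplus gaps floored at
#' \code{1e-3}, so the ordering \eqn{a_1 < a_2 \le a_3 < a_4} always holds.
#'
#' @param schema a [feature_schema()].
#' @param K number of rules (default 10).
#' @param C number of classes (default 2).
#' @param seed RNG seed for the random initialization.
#' @param smooth a [smoothness_state()] (defaults to the standard schedule).
#' @param class_labels labels for the classes; the last one is treated as
#'   the positive class in binary problems.
#' @param cutoff_quantiles matrix (n continuous features x 4) of initial
#'   cutoffs in standardized units, or NULL for standard-normal quantiles at
#'   probabilities (0.1, 0.35, 0.65, 0.9).
#' @return an object of class \code{fz_network}.
#' @export
fz_network <- function(schema, K = 10L, C = 2L, seed = 1L,
                       smooth = smoothness_state(),
                       class_labels = NULL,
                       cutoff_quantiles = NULL) {
  stopifnot(inherits(schema, "fz_schema"), K >= 1L, C >= 2L)
  if (is.null(class_labels)) {
    class_labels <- if (C == 2L) c("negative", "positive")
                    else paste0("class", seq_len(C))
  }
  stopifnot(length(class_labels) == C)
  N <- schema$n_features; D <- schema$max_concepts
  cont <- which(schema$features$kind == "continuous")
  set.seed(seed)
  # small random constrained magnitudes, mapped back through the sigmoid
  rawA <- array(logit(stats::runif(N * D * K, 0.05, 0.30)), dim = c(N, D, K))
  rawM <- matrix(logit(stats::runif(N * K, 0.05, 0.30)), N, K)
  rawW <- matrix(softplus_inv(stats::runif(K * C, 0.05, 0.30)), K, C)
  if (is.null(cutoff_quantiles)) {
    cutoff_quantiles <- matrix(rep(stats::qnorm(c(0.1, 0.35, 0.65, 0.9)),
                                   each = length(cont)),
                               nrow = length(cont))
  }
  stopifnot(nrow(cutoff_quantiles) == length(cont),
            ncol(cutoff_quantiles) == 4L)
  rawCut <- t(apply(cutoff_quantiles, 1, cutoffs_to_theta))
  if (length(cont) == 1L) rawCut <- matrix(rawCut, nrow = 1L)
  net <- structure(list(
    schema = schema, K = as.integer(K), C = as.integer(C),
    class_labels = class_labels,
    raw = list(A = rawA, M = rawM, W = rawW, cut = rawCut),
    mask = concept_mask(schema),
    cont_idx = cont,
    smooth = smooth,
    eps_override = list(eps1 = NULL, eps2 = NULL, eps3 = NULL),
    stats = NULL
  ), class = "fz_network")
  net
}

# cutoff vector (a1..a4) <-> unconstrained theta (a1 free, softplus gaps)
theta_to_cutoffs <- function(theta) {
  g <- CUT_FLOOR + softplus(theta[-1])
  cumsum(c(theta[1], g))
}
cutoffs_to_theta <- function(cutoffs) {
  g <- pmax(diff(cutoffs) - CUT_FLOOR, CUT_FLOOR / 2)
  c(cutoffs[1], softplus_inv(g))
}

eps_role <- function(net, role) {
  ov <- net$eps_override[[role]]
  if (is.null(ov)) net$smooth$eps else ov
}

#' Constrained network parameters
#'
#' Applies the reparameterization map to the raw (unconstrained) parameters:
#' attention and connection entries through the sigmoid into \eqn{[0,1]}
#' (structurally invalid concept slots of categorical features are zeroed),
#' inference entries through the softplus into \eqn{[0,\infty)}, and cutoff
#' parameters through the ordered-gap map so \eqn{a_1 < a_2 \le a_3 < a_4}.
#'
#' @param net an [fz_network()].
#' @return list with elements \code{A} (N x D x K), \code{M} (N x K),
#'   \code{W} (K x C), \code{cutoffs} (continuous features x 4, rownames =
#'   feature names) and the current \code{eps} values.
#' @export
network_params <- function(net) {
  stopifnot(inherits(net, "fz_network"))
  N <- net$schema$n_features; D <- net$schema$max_concepts; K <- net$K
  A <- sigmoid(net$raw$A) * array(net$mask, dim = c(N, D, K))
  M <- sigmoid(net$raw$M)
  W <- softplus(net$raw$W)
  cutoffs <- t(apply(net$raw$cut, 1, theta_to_cutoffs))
  if (length(net$cont_idx) == 1L) cutoffs <- matrix(cutoffs, nrow = 1L)
  rownames(cutoffs) <- net$schema$features$name[net$cont_idx]
  list(A = A, M = M, W = W, cutoffs = cutoffs,
       eps = c(eps1 = eps_role(net, "eps1"), eps2 = eps_role(net, "eps2"),
               eps3 = eps_role(net, "eps3")))
}

#' Contribution matrix
#'
#' \eqn{S_{i,d,k} = A_{i,d,k} M_{i,k}}: the contribution of concept \eqn{d}
#' of feature \eqn{i} to rule \eqn{k}. Used for rule rendering, rule
#' correlation penalties and rule-similarity pruning.
#'
#' @param net an [fz_network()].
#' @return an N x D x K array.
#' @export
contribution_matrix <- function(net) {
  p <- network_params(net)
  S <- p$A
  for (k in seq_len(net$K)) S[, , k] <- p$A[, , k] * p$M[, k]
  S
}

#' Encode feature rows into concept activations
#'
#' Continuous features are mapped to their (low, medium, high) membership
#' degrees at the current smoothness; categorical features to one-hot level
#' indicators occupying the leading concept slots. Missing values are
#' rejected: imputation belongs to the preprocessing pipeline, keeping the
#' network deterministic.
#'
#' @param net an [fz_network()].
#' @param X numeric matrix (rows = samples, columns = features in schema
#'   order); continuous columns standardized, categorical columns integer
#'   level codes starting at 1 (a 0/1 binary column may be passed and is
#'   shifted to codes 1/2).
#' @return array B x N x D of concept activations.
#' @export
encode_concepts <- function(net, X) {
  X <- as_feature_matrix(net, X)
  if (anyNA(X)) stop("encode_concepts: missing values must be imputed first")
  B <- nrow(X); N <- net$schema$n_features; D <- net$schema$max_concepts
  p <- network_params(net)
  eps1 <- eps_role(net, "eps1")
  Z <- array(0, dim = c(B, N, D))
  ci <- 0L
  for (i in seq_len(N)) {
    if (net$schema$features$kind[i] == "continuous") {
      ci <- ci + 1L
      Z[, i, 1:3] <- membership_all(X[, i], p$cutoffs[ci, ], eps1)
    } else {
      lev <- X[, i]
      nl <- net$schema$features$n_levels[i]
      if (any(lev != round(lev)) || any(lev < 1) || any(lev > nl)) {
        stop("categorical feature '", net$schema$features$name[i],
             "' has level codes outside 1..", nl)
      }
      Z[cbind(seq_len(B), i, lev)] <- 1
    }
  }
  Z
}

# Accept data.frames / vectors; shift 0/1 binary columns to level codes 1/2.
as_feature_matrix <- function(net, X) {
  if (is.data.frame(X)) {
    nm <- net$schema$features$name
    if (!all(nm %in% names(X))) {
      stop("missing feature column(s): ",
           paste(setdiff(nm, names(X)), collapse = ", "))
    }
    X <- as.matrix(X[, nm, drop = FALSE])
  }
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  stopifnot(ncol(X) == net$schema$n_features)
  for (i in seq_len(ncol(X))) {
    if (net$schema$features$kind[i] == "categorical") {
      v <- X[, i]
      if (all(v %in% c(0, 1, NA))) X[, i] <- v + 1
    }
  }
  X
}

# Full forward pass with caches for backpropagation.
# Returns prob (B x C) plus intermediates.
fz_forward <- function(net, X, Z = NULL) {
  p <- network_params(net)
  if (is.null(Z)) Z <- encode_concepts(net, X)
  B <- dim(Z)[1]; N <- dim(Z)[2]; K <- net$K; C <- net$C
  eps2 <- eps_role(net, "eps2"); eps3 <- eps_role(net, "eps3")

  # rule layer: xt[b,i,k] = sum_d A[i,d,k] Z[b,i,d]
  xt <- array(0, dim = c(B, N, K))
  for (i in seq_len(N)) {
    Zi <- matrix(Z[, i, ], nrow = B)
    xt[, i, ] <- Zi %*% matrix(p$A[i, , ], nrow = dim(Z)[3])
  }
  xc <- pmin(pmax(xt, TNORM_CLAMP), 1)
  c2 <- (eps2 - 1) / eps2
  E <- p$M * c2                                   # N x K, <= 0
  lxc <- log(xc)
  lu <- lxc * rep(E, each = B)                    # B x N x K, >= 0
  # log-sum-exp over features
  mu <- aperm(lu, c(2, 1, 3)); dim(mu) <- c(N, B * K)
  Lmax <- mu[1, ]
  if (N > 1L) for (i in 2:N) Lmax <- pmax(Lmax, mu[i, ])
  esh <- exp(mu - rep(Lmax, each = N))
  base_scaled <- .colSums(esh, N, B * K) - (N - 1) * exp(-Lmax)
  base_scaled <- pmax(base_scaled, TNORM_CLAMP * exp(-Lmax))
  log_base <- Lmax + log(base_scaled)             # length B*K
  pw <- eps2 / (eps2 - 1)                         # < 0
  r <- matrix(exp(pw * log_base), B, K)           # firing strengths in (0,1]

  # inference layer: O[b,c] = (sum_k (W[k,c] r[b,k])^{1/eps3})^{eps3}
  lr <- log(r)
  logW <- log(p$W)
  logO <- matrix(0, B, C)
  sm <- array(0, dim = c(B, K, C))                # softmax weights in the LSE
  for (cc in seq_len(C)) {
    lt <- (lr + matrix(logW[, cc], B, K, byrow = TRUE)) / eps3
    Lm <- lt[, 1]
    if (K > 1L) for (k in 2:K) Lm <- pmax(Lm, lt[, k])
    ex <- exp(lt - Lm)
    lse <- Lm + log(.rowSums(ex, B, K))
    logO[, cc] <- eps3 * lse
    sm[, , cc] <- exp(lt - lse)
  }
  O <- exp(logO)
  # softmax class probabilities
  Om <- O - apply(O, 1, max)
  eo <- exp(Om)
  prob <- eo / .rowSums(eo, B, C)
  colnames(prob) <- net$class_labels
  list(prob = prob, O = O, r = r, params = p,
       cache = list(Z = Z, X = X, xt = xt, xc = xc, lxc = lxc, E = E, c2 = c2,
                    pw = pw, log_base = log_base, lu = lu, sm = sm,
                    eps2 = eps2, eps3 = eps3))
}

#' Rule firing strengths
#'
#' For each sample, computes \eqn{\tilde x_{i,k} = \sum_d A_{i,d,k}
#' z_{i,d}} and the firing strength \eqn{r_k} of every rule as the
#' parameterized T-norm of the \eqn{\tilde x_{i,k}} with exponents
#' \eqn{M_{i,k}}.
#'
#' @param net an [fz_network()].
#' @param X feature matrix or data.frame (see [encode_concepts()]).
#' @return B x K matrix of firing strengths in \eqn{(0, 1]}.
#' @export
rule_strengths <- function(net, X) {
  fz_forward(net, X)$r
}

#' Class scores from firing strengths
#'
#' \eqn{O_c} is the parameterized T-conorm of \eqn{W_{k,c} r_k} over rules.
#'
#' @param net an [fz_network()].
#' @param r matrix (or vector) of firing strengths, B x K.
#' @return B x C matrix of class scores.
#' @export
infer_scores <- function(net, r) {
  if (is.null(dim(r))) r <- matrix(r, nrow = 1L)
  stopifnot(ncol(r) == net$K, all(r >= 0))
  p <- network_params(net)
  eps3 <- eps_role(net, "eps3")
  B <- nrow(r)
  O <- matrix(0, B, net$C)
  for (cc in seq_len(net$C)) {
    O[, cc] <- apply(r, 1, function(rb) tconorm(p$W[, cc] * rb, eps3))
  }
  colnames(O) <- net$class_labels
  O
}

#' Predict from a fuzzy rule network
#'
#' @param object an [fz_network()].
#' @param newdata feature matrix or data.frame.
#' @param type \code{"prob"} for softmax class probabilities,
#'   \code{"score"} for raw class scores \eqn{O_c}, \code{"strength"} for
#'   rule firing strengths, \code{"class"} for the argmax label.
#' @param ... unused.
#' @return matrix (or character vector for \code{type = "class"}).
#' @export
predict.fz_network <- function(object, newdata,
                               type = c("prob", "score", "strength", "class"),
                               ...) {
  type <- match.arg(type)
  fw <- fz_forward(object, newdata)
  switch(type,
         prob = fw$prob,
         score = fw$O,
         strength = fw$r,
         class = object$class_labels[max.col(fw$prob, ties.method = "first")])
}

#' @export
print.fz_network <- function(x, ...) {
  cat("Fuzzy rule network:", x$schema$n_features, "features,",
      x$K, "rules,", x$C, "classes; eps =",
      formatC(x$smooth$eps, digits = 4, format = "g"),
      "(step", x$smooth$step, ")\n")
  invisible(x)
}

#' Save a network checkpoint
#'
#' Writes a single JSON document holding the schema, all raw parameters,
#' the smoothness state and any attached standardization statistics, at full
#' double precision so that save -> load -> predict is bit-identical.
#'
#' @param net an [fz_network()].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_checkpoint <- function(net, path) {
  doc <- list(
    format = "fuzznet-checkpoint", version = 1L,
    schema = net$schema$features,
    K = net$K, C = net$C, class_labels = net$class_labels,
    raw = list(A = as.vector(net$raw$A), dimA = dim(net$raw$A),
               M = as.vector(net$raw$M), dimM = dim(net$raw$M),
               W = as.vector(net$raw$W), dimW = dim(net$raw$W),
               cut = as.vector(net$raw$cut), dimCut = dim(net$raw$cut)),
    smooth = unclass(net$smooth),
    eps_override = net$eps_override,
    # named vectors must survive as JSON objects, not bare arrays
    stats = if (is.null(net$stats)) NULL else
      list(mean = as.list(net$stats$mean), sd = as.list(net$stats$sd))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Load a network checkpoint
#'
#' @param path a file written by [write_checkpoint()].
#' @return the restored [fz_network()].
#' @export
read_checkpoint <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "fuzznet-checkpoint")) {
    stop("not a fuzznet checkpoint: ", path)
  }
  sc <- feature_schema(doc$schema$name, doc$schema$kind,
                       n_levels = doc$schema$n_levels,
                       units = doc$schema$unit)
  net <- fz_network(sc, K = doc$K, C = doc$C, seed = 1L,
                    class_labels = doc$class_labels)
  net$raw$A <- array(doc$raw$A, dim = doc$raw$dimA)
  net$raw$M <- matrix(doc$raw$M, doc$raw$dimM[1], doc$raw$dimM[2])
  net$raw$W <- matrix(doc$raw$W, doc$raw$dimW[1], doc$raw$dimW[2])
  net$raw$cut <- matrix(doc$raw$cut, doc$raw$dimCut[1], doc$raw$dimCut[2])
  sm <- smoothness_state()
  sm$eps <- doc$smooth$eps; sm$eps_min <- doc$smooth$eps_min
  sm$gamma <- doc$smooth$gamma; sm$step <- as.integer(doc$smooth$step)
  net$smooth <- sm
  if (!is.null(doc$eps_override)) {
    for (nmx in names(net$eps_override)) {
      v <- doc$eps_override[[nmx]]
      net$eps_override[[nmx]] <- if (is.null(v)) NULL else as.numeric(v)
    }
  }
  if (!is.null(doc$stats)) {
    mn <- unlist(doc$stats$mean); sdv <- unlist(doc$stats$sd)
    storage.mode(mn) <- "double"; storage.mode(sdv) <- "double"
    net$stats <- list(mean = mn, sd = sdv)
  }
  net
}
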