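# Independent oracles used across the suite. These deliberately use naive
# direct formulas and explicit loops, never the package's vectorized
# log-space code paths.

# Direct evaluation of the weighted N-input parameterized T-norm.
naive_tnorm <- function(values, exponents, eps) {
  n <- length(values)
  (sum(values^(exponents * (eps - 1) / eps)) - n + 1)^(eps / (eps - 1))
}

naive_tconorm <- function(values, eps) {
  (sum(values^(1 / eps)))^eps
}

# Crisp-limit piecewise-linear membership shapes.
trap_low <- function(x, a) {
  pmin(pmax((a[2] - x) / (a[2] - a[1]), 0), 1)
}
trap_high <- function(x, a) {
  pmin(pmax((x - a[3]) / (a[4] - a[3]), 0), 1)
}
trap_medium <- function(x, a) {
  pmin(pmax((x - a[1]) / (a[2] - a[1]), 0),
       pmax(1 - trap_high(x, a) - 0, 0),
       pmax((a[4] - x) / (a[4] - a[3]), 0), 1)
}

# Confusion-count metric oracle built directly from the definitions, with
# O(n^2) pairwise AUC and an explicit per-threshold AUPRC loop.
oracle_metrics <- function(labels, scores, threshold = 0.5) {
  n <- length(labels)
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_len(n)) {
    pred <- if (scores[i] >= threshold) 1L else 0L
    if (pred == 1L && labels[i] == 1L) tp <- tp + 1L
    if (pred == 1L && labels[i] == 0L) fp <- fp + 1L
    if (pred == 0L && labels[i] == 0L) tn <- tn + 1L
    if (pred == 0L && labels[i] == 1L) fn <- fn + 1L
  }
  acc <- (tp + tn) / n
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  spec <- if (tn + fp > 0) tn / (tn + fp) else 0
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den > 0) (tp * tn - fp * fn) / den else 0
  # pairwise AUC
  pos <- which(labels == 1); neg <- which(labels == 0)
  auc <- NA_real_
  if (length(pos) > 0 && length(neg) > 0) {
    s <- 0
    for (i in pos) for (j in neg) {
      s <- s + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
    }
    auc <- s / (length(pos) * length(neg))
  }
  # per-threshold AUPRC (step function / average precision)
  auprc <- NA_real_
  if (length(pos) > 0 && length(neg) > 0) {
    th <- sort(unique(scores), decreasing = TRUE)
    prev_r <- 0; ap <- 0
    for (t in th) {
      tpt <- sum(scores >= t & labels == 1)
      fpt <- sum(scores >= t & labels == 0)
      p_t <- tpt / (tpt + fpt)
      r_t <- tpt / length(pos)
      ap <- ap + (r_t - prev_r) * p_t
      prev_r <- r_t
    }
    auprc <- ap
  }
  list(accuracy = acc, recall = rec, specificity = spec, precision = prec,
       f1 = f1, auc = auc, auprc = auprc, mcc = mcc,
       tp = tp, fp = fp, tn = tn, fn = fn)
}

# A small mixed schema + network used by several files.
tiny_schema <- function() {
  feature_schema(c("x1", "x2", "x3", "x4", "cm"),
                 c(rep("continuous", 4), "categorical"),
                 n_levels = c(NA, NA, NA, NA, 2))
}
tiny_network <- function(seed = 7, eps = 0.35, K = 3) {
  net <- fz_network(tiny_schema(), K = K, C = 2, seed = seed)
  net$smooth$eps <- eps
  net
}
tiny_batch <- function(n = 8, seed = 1) {
  set.seed(seed)
  X <- cbind(matrix(rnorm(n * 4), n, 4), sample(0:1, n, replace = TRUE))
  y <- rep_len(c(1L, 2L), n)
  list(X = X, y = y)
}
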