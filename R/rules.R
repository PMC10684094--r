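# Symbolic clinical rules and their bridge to network parameters:
# knowledge-based initialization, post-training extraction with firing
# strength / correlation / importance filtering, cross-fold ensembling, and
# human-readable rendering.

#' Construct a symbolic rule
#'
#' A rule is a conjunction of (feature, concept) terms with importances in
#' \eqn{[0,1]}, plus per-class contribution weights and an optional firing
#' strength summary.
#'
#' @param terms data.frame with columns \code{feature}, \code{concept} and
#'   optionally \code{importance} (default 0.9), or a list of
#'   \code{c(feature, concept)} pairs.
#' @param class_weights nonnegative per-class weights (default: 0.05 for
#'   every class except 0.9 for the last, positive, class).
#' @param strength optional scalar firing-strength summary.
#' @param n_classes number of classes (default 2).
#' @return a list of class \code{fz_rule}.
#' @export
fz_rule <- function(terms, class_weights = NULL, strength = NA_real_,
                    n_classes = 2L) {
  if (!is.data.frame(terms)) {
    terms <- do.call(rbind, lapply(terms, function(t) {
      data.frame(feature = t[[1]], concept = t[[2]],
                 importance = if (length(t) >= 3) as.numeric(t[[3]]) else 0.9,
                 stringsAsFactors = FALSE)
    }))
  }
  if (is.null(terms$importance)) terms$importance <- 0.9
  stopifnot(nrow(terms) >= 1L,
            all(terms$importance >= 0), all(terms$importance <= 1))
  if (anyDuplicated(terms$feature)) {
    stop("a feature may appear at most once per rule")
  }
  if (is.null(class_weights)) {
    class_weights <- c(rep(0.05, n_classes - 1L), 0.9)
  }
  stopifnot(all(class_weights >= 0))
  structure(list(terms = terms, class_weights = class_weights,
                 strength = strength), class = "fz_rule")
}

#' Construct a rule set
#'
#' @param rules list of [fz_rule()] objects.
#' @param outcome_label human-readable consequent used when rendering
#'   (e.g. "refer for heart transplantation/ LVAD").
#' @return a list of class \code{fz_ruleset}.
#' @export
ruleset <- function(rules = list(), outcome_label = "positive outcome") {
  stopifnot(all(vapply(rules, inherits, logical(1), "fz_rule")))
  structure(list(rules = rules, outcome_label = outcome_label),
            class = "fz_ruleset")
}

#' @export
length.fz_ruleset <- function(x) length(x$rules)

#' @export
print.fz_ruleset <- function(x, ...) {
  cat("Rule set with", length(x$rules), "rule(s)\n")
  if (length(x$rules) > 0) cat(render_rules(x)$text, sep = "\n")
  invisible(x)
}

#' Clinical referral rules for advanced heart-failure therapies
#'
#' The four simplified expert rules used to seed the network with clinical
#' knowledge: a low ejection fraction combined with low systolic blood
#' pressure, severe mitral regurgitation, a rising BNP over the
#' hospitalization, or hyponatremia each suggests referral for heart
#' transplantation or LVAD.
#'
#' @param features optional named character vector remapping the canonical
#'   feature names (\code{lvef}, \code{sbp}, \code{mitral_regurg},
#'   \code{bnp_delta}, \code{sodium}) onto schema names.
#' @return an [ruleset()] with four rules.
#' @export
hf_referral_rules <- function(features = NULL) {
  nm <- c(lvef = "lvef", sbp = "sbp", mitral_regurg = "mitral_regurg",
          bnp_delta = "bnp_delta", sodium = "sodium")
  if (!is.null(features)) nm[names(features)] <- features
  mk <- function(f2, c2) {
    fz_rule(data.frame(feature = c(nm[["lvef"]], nm[[f2]]),
                       concept = c("low", c2), importance = 0.9,
                       stringsAsFactors = FALSE))
  }
  ruleset(list(mk("sbp", "low"),
               mk("mitral_regurg", "high"),
               mk("bnp_delta", "high"),
               mk("sodium", "low")),
          outcome_label = "refer for heart transplantation/ LVAD")
}

#' Initialize a network from symbolic rules
#'
#' Builds a network whose first \code{length(ruleset)} rule columns encode
#' the given rules: attention entries at the rules' (feature, concept) slots
#' are set to the term importances (default 0.9), connection entries of the
#' rules' features to 0.9, and the positive-class inference weights to the
#' rules' class weights; everything else is set low (0.05). The remaining
#' \code{K - length(ruleset)} rule columns keep the small random (seeded)
#' initialization, and membership cutoffs start at standardized-data
#' quantiles. The injected values bias training without pinning it.
#'
#' @param rs an [ruleset()] (may be empty, yielding the default random
#'   initialization).
#' @param schema a [feature_schema()].
#' @param K total number of rules; must be >= \code{length(rs)}.
#' @param seed RNG seed for the random rule columns.
#' @param C number of classes.
#' @param cutoff_quantiles optional cutoff initialization (see
#'   [fz_network()]).
#' @param high,low injected high/low constrained values.
#' @return an [fz_network()].
#' @export
init_from_rules <- function(rs, schema, K, seed = 1L, C = 2L,
                            cutoff_quantiles = NULL,
                            high = 0.9, low = 0.05) {
  stopifnot(inherits(rs, "fz_ruleset"), K >= length(rs$rules))
  net <- fz_network(schema, K = K, C = C, seed = seed,
                    cutoff_quantiles = cutoff_quantiles)
  nr <- length(rs$rules)
  if (nr == 0L) return(net)
  clipc <- function(p) pmin(pmax(p, 0.01), 0.99)
  for (k in seq_len(nr)) {
    rule <- rs$rules[[k]]
    i <- schema_index(schema, rule$terms$feature)
    net$raw$A[, , k] <- logit(low)
    net$raw$M[, k] <- logit(low)
    for (t in seq_len(nrow(rule$terms))) {
      d <- concept_slot(schema, i[t], rule$terms$concept[t])
      imp <- rule$terms$importance[t]
      if (!is.finite(imp) || imp <= 0) imp <- high
      net$raw$A[i[t], d, k] <- logit(clipc(imp))
      net$raw$M[i[t], k] <- logit(clipc(high))
    }
    cw <- rule$class_weights
    if (length(cw) != C || !all(is.finite(cw))) {
      cw <- c(rep(low, C - 1L), high)
    }
    net$raw$W[k, ] <- softplus_inv(pmax(cw, low))
  }
  net
}

#' Extract symbolic rules from a trained network
#'
#' Rule strength is the mean firing strength over \code{X}. Rules whose
#' dominant inference weight does not point at one of \code{target_classes}
#' (by default, the positive class: a clinical referral rule set contains
#' referral rules) or whose strength falls below \code{strength_threshold}
#' are discarded; among survivors, for any pair whose vectorized
#' contribution columns have cosine similarity above \code{corr_threshold}
#' the lower-strength member is greedily discarded. Each surviving rule
#' keeps the (feature, concept) terms whose contribution \eqn{S_{i,d,k}}
#' reaches \code{importance_threshold} (at most one concept, the strongest,
#' per feature); rules left with no terms are dropped. The result is sorted
#' by strength, descending.
#'
#' @param net a trained [fz_network()].
#' @param X reference feature matrix (typically the training rows) on which
#'   firing strengths are measured.
#' @param strength_threshold minimum mean firing strength (default 0.1).
#' @param corr_threshold cosine-similarity pruning threshold (default 0.9).
#' @param importance_threshold minimum term contribution (default 0.2).
#' @param target_classes integer class indices a rule's dominant inference
#'   weight may point at (default: the last, positive, class); NULL keeps
#'   rules for every class.
#' @param outcome_label consequent label for the returned rule set.
#' @return an [ruleset()]; empty (with a warning) if every rule is filtered
#'   out.
#' @export
extract_rules <- function(net, X, strength_threshold = 0.1,
                          corr_threshold = 0.9, importance_threshold = 0.2,
                          target_classes = net$C,
                          outcome_label = "positive outcome") {
  stopifnot(inherits(net, "fz_network"))
  r <- rule_strengths(net, X)
  strength <- colMeans(r)
  S <- contribution_matrix(net)
  V <- matrix(S, ncol = net$K)
  p <- network_params(net)
  dom <- max.col(p$W, ties.method = "last")
  class_ok <- if (is.null(target_classes)) rep(TRUE, net$K)
              else dom %in% target_classes
  keep <- which(strength >= strength_threshold & class_ok)
  if (length(keep) == 0L) {
    warning("no rule passed the class and firing-strength filters")
    return(ruleset(outcome_label = outcome_label))
  }
  keep <- keep[order(strength[keep], decreasing = TRUE)]
  kept <- integer(0)
  for (k in keep) {
    ok <- all(vapply(kept, function(j) {
      cosine_sim(V[, k], V[, j]) <= corr_threshold
    }, logical(1)))
    if (ok) kept <- c(kept, k)
  }
  rules <- list()
  for (k in kept) {
    Sk <- matrix(S[, , k], nrow = net$schema$n_features)
    terms <- NULL
    for (i in seq_len(net$schema$n_features)) {
      d <- which.max(Sk[i, ])
      if (Sk[i, d] >= importance_threshold) {
        terms <- rbind(terms, data.frame(
          feature = net$schema$features$name[i],
          concept = concept_labels(net$schema, i)[d],
          importance = Sk[i, d], stringsAsFactors = FALSE))
      }
    }
    if (is.null(terms)) next
    terms <- terms[order(terms$importance, decreasing = TRUE), , drop = FALSE]
    rules[[length(rules) + 1L]] <-
      fz_rule(terms, class_weights = p$W[k, ], strength = strength[k],
              n_classes = net$C)
  }
  if (length(rules) == 0L) {
    warning("no rule retained any term above the importance threshold")
  }
  ruleset(rules, outcome_label = outcome_label)
}

cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

# (feature, concept) term vector of a rule over a shared key space.
rule_term_vector <- function(rule, keys) {
  v <- numeric(length(keys))
  idx <- match(paste(rule$terms$feature, rule$terms$concept, sep = ":"), keys)
  v[idx] <- rule$terms$importance
  v
}

#' Ensemble rules across cross-validation folds
#'
#' Pools the rules of all folds, sorts them by strength, and greedily keeps
#' up to \code{max_rules} rules whose pairwise term-vector cosine similarity
#' stays at or below \code{corr_threshold} — the highest-weighted,
#' least-correlated rules. The result is suitable for network
#' re-initialization via [init_from_rules()]. Applying the operation twice
#' gives the same result as applying it once.
#'
#' @param fold_rulesets list of [ruleset()] objects (one per fold).
#' @param corr_threshold cosine-similarity threshold (default 0.9).
#' @param max_rules maximum number of pooled rules (default 10).
#' @return an [ruleset()].
#' @export
ensemble_rules <- function(fold_rulesets, corr_threshold = 0.9,
                           max_rules = 10L) {
  stopifnot(length(fold_rulesets) >= 1L,
            all(vapply(fold_rulesets, inherits, logical(1), "fz_ruleset")))
  pool <- unlist(lapply(fold_rulesets, function(rs) rs$rules),
                 recursive = FALSE)
  outcome_label <- fold_rulesets[[1]]$outcome_label
  if (length(pool) == 0L) return(ruleset(outcome_label = outcome_label))
  strength <- vapply(pool, function(r) {
    if (is.finite(r$strength)) r$strength else 0
  }, numeric(1))
  pool <- pool[order(strength, decreasing = TRUE)]
  keys <- unique(unlist(lapply(pool, function(r) {
    paste(r$terms$feature, r$terms$concept, sep = ":")
  })))
  kept <- list()
  for (rule in pool) {
    if (length(kept) >= max_rules) break
    v <- rule_term_vector(rule, keys)
    ok <- all(vapply(kept, function(kr) {
      cosine_sim(v, rule_term_vector(kr, keys)) <= corr_threshold
    }, logical(1)))
    if (ok) kept[[length(kept) + 1L]] <- rule
  }
  ruleset(kept, outcome_label = outcome_label)
}

#' Render rules as IF/AND/THEN sentences and a concept-by-rule heatmap
#'
#' @param rs an [ruleset()].
#' @param stats optional standardization statistics (list with named
#'   \code{mean} and \code{sd}); currently recorded alongside, cutpoint
#'   translation is handled by [critical_values()].
#' @return list with \code{text} (one sentence per rule), \code{heatmap}
#'   (matrix, rows = feature:concept, columns = rules, entries = term
#'   importances) and \code{contributions} (data.frame with per-rule firing
#'   strength and positive-class weight).
#' @export
render_rules <- function(rs, stats = NULL) {
  stopifnot(inherits(rs, "fz_ruleset"))
  n <- length(rs$rules)
  if (n == 0L) {
    return(list(text = character(0),
                heatmap = matrix(numeric(0), 0, 0),
                contributions = data.frame(rule = integer(0),
                                           strength = numeric(0),
                                           positive_weight = numeric(0))))
  }
  text <- vapply(rs$rules, function(r) {
    consequent <- if (which.max(r$class_weights) == length(r$class_weights))
      rs$outcome_label else paste0("NOT: ", rs$outcome_label)
    paste0("IF ",
           paste(paste(r$terms$feature, "is", r$terms$concept),
                 collapse = " AND "),
           ", THEN ", consequent)
  }, character(1))
  keys <- unique(unlist(lapply(rs$rules, function(r) {
    paste(r$terms$feature, r$terms$concept, sep = ":")
  })))
  heat <- vapply(rs$rules, rule_term_vector, numeric(length(keys)),
                 keys = keys)
  heat <- matrix(heat, nrow = length(keys),
                 dimnames = list(keys, paste0("rule", seq_len(n))))
  contributions <- data.frame(
    rule = seq_len(n),
    strength = vapply(rs$rules, function(r) r$strength, numeric(1)),
    positive_weight = vapply(rs$rules, function(r) {
      utils::tail(r$class_weights, 1)
    }, numeric(1)))
  list(text = text, heatmap = heat, contributions = contributions)
}

#' Write a rule report (markdown + heatmap CSV)
#'
#' @param rs an [ruleset()].
#' @param path output path of the markdown report; the heatmap matrix is
#'   written next to it as \code{<path>.heatmap.csv}.
#' @return \code{path}, invisibly.
#' @export
write_rule_report <- function(rs, path) {
  rr <- render_rules(rs)
  lines <- c("# Extracted rules", "")
  if (length(rr$text) == 0) {
    lines <- c(lines, "(no rules survived filtering)")
  } else {
    lines <- c(lines,
               paste0("- **Rule ", seq_along(rr$text), "** (strength ",
                      formatC(rr$contributions$strength, digits = 3,
                              format = "f"),
                      ", positive-class weight ",
                      formatC(rr$contributions$positive_weight, digits = 3,
                              format = "f"), "): ", rr$text))
  }
  writeLines(lines, path)
  hp <- paste0(path, ".heatmap.csv")
  hm <- as.data.frame(rr$heatmap)
  hm <- cbind(term = rownames(rr$heatmap), hm)
  utils::write.csv(hm, hp, row.names = FALSE)
  invisible(path)
}

#' Serialize a rule set to JSON
#' @param rs an [ruleset()].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_ruleset <- function(rs, path) {
  doc <- list(format = "fuzznet-ruleset", version = 1L,
              outcome_label = rs$outcome_label,
              rules = lapply(rs$rules, function(r) {
                list(terms = r$terms, class_weights = r$class_weights,
                     strength = r$strength)
              }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a rule set from JSON
#' @param path a file written by [write_ruleset()].
#' @return an [ruleset()].
#' @export
read_ruleset <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$format, "fuzznet-ruleset")) {
    stop("not a fuzznet ruleset: ", path)
  }
  rules <- lapply(doc$rules, function(rj) {
    terms <- do.call(rbind, lapply(rj$terms, function(t) {
      data.frame(feature = t$feature, concept = t$concept,
                 importance = as.numeric(t$importance),
                 stringsAsFactors = FALSE)
    }))
    cw <- as.numeric(unlist(rj$class_weights))
    fz_rule(terms, class_weights = cw,
            strength = if (is.null(rj$strength)) NA_real_
                       else as.numeric(rj$strength),
            n_classes = length(cw))
  })
  ruleset(rules, outcome_label = doc$outcome_label)
}
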