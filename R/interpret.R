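# Post-hoc interpretability: membership curves, concept transition
# boundaries in clinical units, and per-sample fired-rule explanations.

#' Concept transition boundaries (range inference)
#'
#' For every continuous feature, solves by bisection for the points where
#' each membership ramp crosses 0.5: the descending low ramp
#' (\code{low}), the ascending and descending medium ramps
#' (\code{medium_left}, \code{medium_right}) and the ascending high ramp
#' (\code{high}). With near-crisp memberships these coincide with the
#' intersections of adjacent membership curves; the 0.5-crossing convention
#' stays well defined even when the curves do not intersect cleanly, and is
#' recorded in the output metadata. Results are mapped back to clinical
#' units via the standardization statistics.
#'
#' @param net a trained [fz_network()].
#' @param stats list with named numeric vectors \code{mean} and \code{sd}
#'   (per continuous feature, in clinical units); defaults to
#'   \code{net$stats}, or the identity map if neither is available.
#' @param tol bisection tolerance in standardized units (default 1e-6).
#' @return data.frame of class \code{fz_range_table} with columns
#'   \code{feature}, \code{low}, \code{medium_left}, \code{medium_right},
#'   \code{high}, \code{unit}; features with degenerate (non-bracketed)
#'   ramps are omitted with a warning. Attribute \code{"convention"} records
#'   the boundary definition.
#' @export
critical_values <- function(net, stats = NULL, tol = 1e-6) {
  stopifnot(inherits(net, "fz_network"))
  if (is.null(stats)) stats <- net$stats
  p <- network_params(net)
  eps1 <- eps_role(net, "eps1")
  rows <- list(); dropped <- character(0)
  for (ci in seq_along(net$cont_idx)) {
    i <- net$cont_idx[ci]
    nm <- net$schema$features$name[i]
    cuts <- p$cutoffs[ci, ]
    span <- max(cuts[4] - cuts[1], 1e-3)
    lo <- cuts[1] - 0.5 * span; hi <- cuts[4] + 0.5 * span
    mem <- function(x, concept) membership(x, cuts, eps1, concept)
    b <- c(
      low = bisect_half(function(x) mem(x, "low"), lo, hi,
                        decreasing = TRUE, tol = tol),
      medium_left = bisect_half(function(x) mem(x, "medium"),
                                lo, mean(cuts[2:3]),
                                decreasing = FALSE, tol = tol),
      medium_right = bisect_half(function(x) mem(x, "medium"),
                                 mean(cuts[2:3]), hi,
                                 decreasing = TRUE, tol = tol),
      high = bisect_half(function(x) mem(x, "high"), lo, hi,
                         decreasing = FALSE, tol = tol))
    if (anyNA(b)) { dropped <- c(dropped, nm); next }
    if (!is.null(stats)) {
      mu <- stats$mean[[nm]]; sdv <- stats$sd[[nm]]
      if (!is.null(mu) && !is.null(sdv) && is.finite(mu) && is.finite(sdv)) {
        b <- mu + sdv * b
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      feature = nm, low = b[["low"]], medium_left = b[["medium_left"]],
      medium_right = b[["medium_right"]], high = b[["high"]],
      unit = net$schema$features$unit[i], stringsAsFactors = FALSE)
  }
  if (length(dropped) > 0) {
    warning("degenerate membership ramps; omitted feature(s): ",
            paste(dropped, collapse = ", "))
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(feature = character(0), low = numeric(0),
               medium_left = numeric(0), medium_right = numeric(0),
               high = numeric(0), unit = character(0))
  class(out) <- c("fz_range_table", "data.frame")
  attr(out, "convention") <- "0.5-crossing of each membership ramp"
  out
}

# Root of f(x) = 0.5 on a monotone ramp inside [lo, hi]; NA if 0.5 is not
# bracketed (degenerate membership).
bisect_half <- function(f, lo, hi, decreasing, tol = 1e-6) {
  g <- function(x) f(x) - 0.5
  glo <- g(lo); ghi <- g(hi)
  if (is.na(glo) || is.na(ghi) || glo * ghi > 0) return(NA_real_)
  tryCatch(stats::uniroot(g, c(lo, hi), tol = tol)$root,
           error = function(e) NA_real_)
}

#' Write a range table as CSV
#'
#' @param ranges an output of [critical_values()].
#' @param path output file; a schema-version comment line and the boundary
#'   convention are written first.
#' @return \code{path}, invisibly.
#' @export
write_range_table <- function(ranges, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0("# fuzznet-ranges v1; convention: ",
                    attr(ranges, "convention")), con)
  utils::write.csv(as.data.frame(ranges), con, row.names = FALSE)
  invisible(path)
}

#' Membership curves for one feature
#'
#' Dense evaluation of the three membership functions, e.g. for plotting.
#'
#' @param net an [fz_network()].
#' @param feature feature name (must be continuous).
#' @param grid numeric vector of standardized evaluation points; defaults
#'   to 201 points spanning the cutoff range plus half a span on each side.
#' @return data.frame with columns \code{x}, \code{low}, \code{medium},
#'   \code{high}.
#' @export
membership_curves <- function(net, feature, grid = NULL) {
  i <- schema_index(net$schema, feature)
  if (net$schema$features$kind[i] != "continuous") {
    stop("feature '", feature, "' is categorical; memberships are defined ",
         "for continuous features only")
  }
  ci <- match(i, net$cont_idx)
  p <- network_params(net)
  cuts <- p$cutoffs[ci, ]
  if (is.null(grid)) {
    span <- max(cuts[4] - cuts[1], 1e-3)
    grid <- seq(cuts[1] - 0.5 * span, cuts[4] + 0.5 * span, length.out = 201)
  }
  m <- membership_all(grid, cuts, eps_role(net, "eps1"))
  data.frame(x = grid, low = m[, "low"], medium = m[, "medium"],
             high = m[, "high"])
}

#' Explain a single prediction by its fired rules
#'
#' Returns the class probabilities together with the top rules by firing
#' strength on this sample, each with its rendered sentence and the
#' per-term membership degrees that drove it. Strengths are exactly the
#' [rule_strengths()] output for the same row.
#'
#' @param net a trained [fz_network()].
#' @param row a single preprocessed feature row (vector, 1-row matrix or
#'   1-row data.frame).
#' @param rs optional [ruleset()] supplying the rendered consequent
#'   (outcome label); the antecedent terms are read off the network's own
#'   contribution matrix so strengths and sentences always describe the
#'   same rule columns.
#' @param top_n number of rules to report (default 3; 0 gives the
#'   prediction only).
#' @return a list of class \code{fz_explanation} with \code{prediction}
#'   (named probabilities) and \code{fired_rules} (list sorted by strength,
#'   descending).
#' @export
explain_sample <- function(net, row, rs = NULL, top_n = 3L) {
  X <- as_feature_matrix(net, row)
  stopifnot(nrow(X) == 1L)
  fw <- fz_forward(net, X)
  r <- drop(fw$r)
  Z <- fw$cache$Z
  out <- list(prediction = stats::setNames(drop(fw$prob), net$class_labels),
              fired_rules = list())
  if (top_n > 0L) {
    ord <- order(r, decreasing = TRUE)[seq_len(min(top_n, net$K))]
    S <- contribution_matrix(net)
    pW <- network_params(net)$W
    for (k in ord) {
      terms <- rule_terms_for_column(net, S, k)
      degrees <- vapply(seq_len(nrow(terms)), function(t) {
        i <- schema_index(net$schema, terms$feature[t])
        d <- concept_slot(net$schema, i, terms$concept[t])
        Z[1, i, d]
      }, numeric(1))
      lab <- if (!is.null(rs)) rs$outcome_label else "positive outcome"
      if (which.max(pW[k, ]) != net$C) lab <- paste0("NOT: ", lab)
      sentence <- paste0(
        "IF ", paste(paste(terms$feature, "is", terms$concept),
                     collapse = " AND "),
        ", THEN ", lab)
      out$fired_rules[[length(out$fired_rules) + 1L]] <- list(
        rule = k, strength = r[k], sentence = sentence,
        terms = cbind(terms, degree = degrees))
    }
  }
  class(out) <- "fz_explanation"
  out
}

# Terms of network rule column k (top contribution concept per feature,
# above a light display threshold).
rule_terms_for_column <- function(net, S, k, display_threshold = 0.2) {
  terms <- NULL
  Sk <- matrix(S[, , k], nrow = net$schema$n_features)
  for (i in seq_len(net$schema$n_features)) {
    d <- which.max(Sk[i, ])
    if (Sk[i, d] >= display_threshold) {
      terms <- rbind(terms, data.frame(
        feature = net$schema$features$name[i],
        concept = concept_labels(net$schema, i)[d],
        importance = Sk[i, d], stringsAsFactors = FALSE))
    }
  }
  if (is.null(terms)) {
    # fall back to the single strongest slot
    idx <- arrayInd(which.max(Sk), dim(Sk))
    terms <- data.frame(
      feature = net$schema$features$name[idx[1]],
      concept = concept_labels(net$schema, idx[1])[idx[2]],
      importance = Sk[idx], stringsAsFactors = FALSE)
  }
  terms[order(terms$importance, decreasing = TRUE), , drop = FALSE]
}

#' @export
print.fz_explanation <- function(x, ...) {
  cat("Prediction:\n")
  print(round(x$prediction, 4))
  if (length(x$fired_rules) > 0) {
    cat("Fired rules (by strength):\n")
    for (fr in x$fired_rules) {
      cat(sprintf("  [%.3f] %s\n", fr$strength, fr$sentence))
    }
  }
  invisible(x)
}

#' Write a sample explanation (JSON + bedside text report)
#'
#' @param expl an [explain_sample()] result.
#' @param path output JSON path; a plain-text report is written next to it
#'   as \code{<path>.txt}.
#' @return \code{path}, invisibly.
#' @export
write_explanation <- function(expl, path) {
  doc <- list(format = "fuzznet-explanation", version = 1L,
              prediction = as.list(expl$prediction),
              fired_rules = lapply(expl$fired_rules, function(fr) {
                list(rule = fr$rule, strength = fr$strength,
                     sentence = fr$sentence, terms = fr$terms)
              }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  txt <- c("Prediction:",
           paste0("  ", names(expl$prediction), ": ",
                  formatC(expl$prediction, digits = 4, format = "f")),
           "", "Fired rules (by strength):",
           vapply(expl$fired_rules, function(fr) {
             sprintf("  [%.3f] %s", fr$strength, fr$sentence)
           }, character(1)))
  writeLines(txt, paste0(path, ".txt"))
  invisible(path)
}
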