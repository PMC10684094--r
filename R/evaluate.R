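# Metric panel and the cross-validated experiment driver: per-fold training
# with knowledge initialization, rule extraction, cross-fold ensembling,
# re-initialized retraining and holdout evaluation.

# Trapezoidal area under the ROC curve; NA when only one class is present.
auc_trapezoid <- function(labels, scores) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  grp <- cumsum(!duplicated(sc))               # distinct-threshold groups
  tp <- tapply(lab == 1, grp, sum); fp <- tapply(lab == 0, grp, sum)
  tpr <- c(0, cumsum(tp) / n1); fpr <- c(0, cumsum(fp) / n0)
  sum((fpr[-1] - fpr[-length(fpr)]) *
        (tpr[-1] + tpr[-length(tpr)]) / 2)
}

# Step-function (average-precision style) area under the PR curve.
auprc_step <- function(labels, scores) {
  n1 <- sum(labels == 1)
  if (n1 == 0 || all(labels == 1)) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  grp <- cumsum(!duplicated(sc))
  tp <- cumsum(tapply(lab == 1, grp, sum))
  fp <- cumsum(tapply(lab == 0, grp, sum))
  prec <- tp / (tp + fp); rec <- tp / n1
  sum(diff(c(0, rec)) * prec)
}

#' Confusion and threshold-free classification metrics
#'
#' Computes accuracy, recall (sensitivity), specificity, precision, F1
#' (harmonic mean of precision and recall), MCC at the given probability
#' cutoff, plus threshold-free AUC (trapezoidal over the ROC curve) and
#' AUPRC (step-function area, average-precision style). Ratios with a zero
#' denominator are reported as 0 and flagged; with a single-class label
#' vector AUC/AUPRC are NA and flagged undefined.
#'
#' @param labels 0/1 vector.
#' @param scores positive-class probabilities in \eqn{[0,1]}.
#' @param threshold decision cutoff (default 0.5).
#' @return one-row data.frame with the eight metrics, the confusion counts
#'   \code{tp}/\code{fp}/\code{tn}/\code{fn}, \code{threshold} and a
#'   semicolon-separated \code{flags} column naming any undefined
#'   quantities.
#' @export
compute_metrics <- function(labels, scores, threshold = 0.5) {
  labels <- as.integer(labels)
  stopifnot(length(labels) == length(scores), length(labels) >= 1L,
            all(labels %in% c(0L, 1L)), all(scores >= 0), all(scores <= 1))
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  flags <- character(0)
  safe_div <- function(num, den, name) {
    if (den == 0) { flags <<- c(flags, name); return(0) }
    num / den
  }
  accuracy <- (tp + tn) / length(labels)
  recall <- safe_div(tp, tp + fn, "recall")
  specificity <- safe_div(tn, tn + fp, "specificity")
  precision <- safe_div(tp, tp + fp, "precision")
  f1 <- if (precision + recall == 0) { flags <- c(flags, "f1"); 0 }
        else 2 * precision * recall / (precision + recall)
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den == 0) { flags <- c(flags, "mcc"); 0 }
         else (tp * tn - fp * fn) / mcc_den
  auc <- auc_trapezoid(labels, scores)
  auprc <- auprc_step(labels, scores)
  if (is.na(auc)) flags <- c(flags, "auc")
  if (is.na(auprc)) flags <- c(flags, "auprc")
  data.frame(accuracy = accuracy, recall = recall,
             specificity = specificity, precision = precision, f1 = f1,
             auc = auc, auprc = auprc, mcc = mcc,
             tp = tp, fp = fp, tn = tn, fn = fn,
             threshold = threshold,
             flags = paste(flags, collapse = ";"),
             stringsAsFactors = FALSE)
}

# Preprocess a pair subset: impute and standardize with models fit on
# fit_rows only, asserting the no-leakage contract.
preprocess_pairs <- function(pairs, schema, fit_rows, seed) {
  imp <- impute_cohort(pairs, schema, fit_rows = fit_rows, seed = seed)
  assert_fit_rows(attr(imp, "fit_rows"), fit_rows, "imputation")
  se <- standardize_and_encode(imp$pairs, schema, fit_rows = fit_rows)
  assert_fit_rows(attr(se, "fit_rows"), fit_rows, "standardization")
  se
}

assert_fit_rows <- function(used, allowed, what) {
  if (!all(used %in% allowed)) {
    stop("leakage guard: ", what, " models were fit on non-training rows")
  }
}

#' Patient-wise cross-validation with rule extraction
#'
#' For each fold: fits imputation and standardization on the fold's
#' training rows only, trains a (knowledge-initialized) network, evaluates
#' on the fold's validation rows, and extracts a rule set.
#'
#' @param pairs the filtered pair table.
#' @param schema an [feature_schema()].
#' @param config a [train_config()].
#' @param init_ruleset optional [ruleset()] for knowledge initialization of
#'   every fold.
#' @param manifest a [patient_folds()] manifest; rows with role
#'   \code{"test"} are ignored here.
#' @param strength_threshold,corr_threshold,importance_threshold rule
#'   extraction thresholds (see [extract_rules()]).
#' @param extract_target_classes class filter for the per-fold rule
#'   extraction; NULL (default) keeps rules of every class so that
#'   re-initialization preserves both positive and negative decision
#'   structure.
#' @return list with \code{report} (per-fold metric rows plus mean and SD
#'   rows), \code{fold_rulesets}, and \code{models}.
#' @export
run_cv <- function(pairs, schema, config = train_config(),
                   init_ruleset = NULL, manifest = NULL,
                   strength_threshold = 0.1, corr_threshold = 0.9,
                   importance_threshold = 0.2,
                   extract_target_classes = NULL) {
  if (is.null(manifest)) {
    manifest <- patient_folds(pairs, k = 5L, seed = config$seed,
                              holdout_fraction = 0)
  }
  train_man <- manifest[manifest$role == "train", ]
  folds <- sort(unique(train_man$fold))
  rows <- list(); rulesets <- list(); models <- list()
  for (f in folds) {
    va_pats <- train_man$patient_id[train_man$fold == f]
    tr_pats <- train_man$patient_id[train_man$fold != f]
    sub <- pairs[pairs$patient_id %in% c(tr_pats, va_pats), , drop = FALSE]
    rownames(sub) <- NULL
    tr_idx <- which(sub$patient_id %in% tr_pats)
    va_idx <- which(sub$patient_id %in% va_pats)
    se <- preprocess_pairs(sub, schema, fit_rows = tr_idx,
                           seed = config$seed + f)
    cfg <- config; cfg$seed <- config$seed + 100L * f
    net <- tryCatch(
      fit_network(se$X[tr_idx, , drop = FALSE], se$y[tr_idx], schema, cfg,
                  init = init_ruleset),
      error = function(e) stop("fold ", f, " training failed: ",
                               conditionMessage(e)))
    net$stats <- se$stats
    pr <- predict(net, se$X[va_idx, , drop = FALSE], type = "prob")
    met <- compute_metrics(se$y[va_idx], pr[, net$C])
    met <- cbind(fold = f, met)
    rows[[length(rows) + 1L]] <- met
    rulesets[[length(rulesets) + 1L]] <-
      extract_rules(net, se$X[tr_idx, , drop = FALSE],
                    strength_threshold = strength_threshold,
                    corr_threshold = corr_threshold,
                    importance_threshold = importance_threshold,
                    target_classes = extract_target_classes,
                    outcome_label = if (!is.null(init_ruleset))
                      init_ruleset$outcome_label else "positive outcome")
    models[[length(models) + 1L]] <- net
  }
  rep_df <- do.call(rbind, rows)
  num_cols <- c("accuracy", "recall", "specificity", "precision", "f1",
                "auc", "auprc", "mcc")
  mean_row <- sd_row <- rep_df[1, ]
  mean_row$fold <- NA; sd_row$fold <- NA
  for (cc in num_cols) {
    mean_row[[cc]] <- mean(rep_df[[cc]], na.rm = TRUE)
    sd_row[[cc]] <- stats::sd(rep_df[[cc]], na.rm = TRUE)
  }
  mean_row[c("tp", "fp", "tn", "fn")] <- NA
  sd_row[c("tp", "fp", "tn", "fn")] <- NA
  mean_row$flags <- "mean"; sd_row$flags <- "sd"
  report <- rbind(cbind(row = paste0("fold", rep_df$fold),
                        rep_df[, -1, drop = FALSE]),
                  cbind(row = "mean", mean_row[, -1, drop = FALSE]),
                  cbind(row = "sd", sd_row[, -1, drop = FALSE]))
  rownames(report) <- NULL
  list(report = report, fold_rulesets = rulesets, models = models)
}

#' Full training and evaluation protocol
#'
#' The end-to-end workflow: patient-wise split into training and holdout
#' test patients; k-fold cross-validation on the training patients with
#' knowledge initialization; ensembling of the per-fold extracted rules;
#' re-initialization of the network from the ensembled rules; retraining on
#' all training patients; and a single evaluation on the holdout patients.
#' Optionally persists the model checkpoint, the final rule set and report,
#' the concept range table and a per-sample explanation.
#'
#' @param pairs the filtered pair table.
#' @param schema an [feature_schema()].
#' @param config a [train_config()].
#' @param init_ruleset optional clinical-knowledge [ruleset()].
#' @param k number of CV folds (default 5).
#' @param holdout_fraction patient fraction held out (default 0.2).
#' @param out_dir optional output directory for artifacts.
#' @param strength_threshold,corr_threshold,importance_threshold rule
#'   extraction thresholds.
#' @return list with \code{model} (final network), \code{cv} (the
#'   [run_cv()] result), \code{ensembled_rules}, \code{final_rules},
#'   \code{holdout} (metric row), \code{ranges} (range table),
#'   \code{manifest}, \code{explanation} (for the first holdout row) and
#'   \code{artifacts} (paths, when \code{out_dir} is given).
#' @export
run_full_protocol <- function(pairs, schema, config = train_config(),
                              init_ruleset = NULL, k = 5L,
                              holdout_fraction = 0.2, out_dir = NULL,
                              strength_threshold = 0.1,
                              corr_threshold = 0.9,
                              importance_threshold = 0.2) {
  manifest <- patient_folds(pairs, k = k, seed = config$seed,
                            holdout_fraction = holdout_fraction)
  cv <- run_cv(pairs, schema, config, init_ruleset = init_ruleset,
               manifest = manifest,
               strength_threshold = strength_threshold,
               corr_threshold = corr_threshold,
               importance_threshold = importance_threshold)
  ens <- ensemble_rules(cv$fold_rulesets, corr_threshold = corr_threshold,
                        max_rules = config$n_rules)
  if (length(ens) == 0L && !is.null(init_ruleset)) ens <- init_ruleset
  tr_pats <- manifest$patient_id[manifest$role == "train"]
  te_pats <- manifest$patient_id[manifest$role == "test"]
  tr_idx <- which(pairs$patient_id %in% tr_pats)
  te_idx <- which(pairs$patient_id %in% te_pats)
  se <- preprocess_pairs(pairs, schema, fit_rows = tr_idx,
                         seed = config$seed + 999L)
  cfg <- config; cfg$seed <- config$seed + 7777L
  net <- fit_network(se$X[tr_idx, , drop = FALSE], se$y[tr_idx], schema, cfg,
                     init = if (length(ens) > 0) ens else NULL)
  net$stats <- se$stats
  final_rules <- extract_rules(net, se$X[tr_idx, , drop = FALSE],
                               strength_threshold = strength_threshold,
                               corr_threshold = corr_threshold,
                               importance_threshold = importance_threshold,
                               outcome_label = ens$outcome_label)
  holdout <- NULL; expl <- NULL
  if (length(te_idx) > 0) {
    pr <- predict(net, se$X[te_idx, , drop = FALSE], type = "prob")
    holdout <- compute_metrics(se$y[te_idx], pr[, net$C])
    expl <- explain_sample(net, se$X[te_idx[1], , drop = FALSE],
                           rs = final_rules, top_n = 3L)
  }
  ranges <- critical_values(net)
  out <- list(model = net, cv = cv, ensembled_rules = ens,
              final_rules = final_rules, holdout = holdout,
              ranges = ranges, manifest = manifest, explanation = expl)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      checkpoint = file.path(out_dir, "checkpoint.json"),
      rules = file.path(out_dir, "rules.json"),
      rule_report = file.path(out_dir, "rules.md"),
      ranges = file.path(out_dir, "ranges.csv"),
      explanation = file.path(out_dir, "explanation.json"),
      eval_report = file.path(out_dir, "eval_report.csv"),
      cv_report = file.path(out_dir, "cv_report.csv"),
      split_manifest = file.path(out_dir, "split_manifest.csv"),
      config = file.path(out_dir, "config.yaml"),
      run_manifest = file.path(out_dir, "manifest.json"))
    write_checkpoint(net, paths$checkpoint)
    write_ruleset(final_rules, paths$rules)
    write_rule_report(final_rules, paths$rule_report)
    write_range_table(ranges, paths$ranges)
    if (!is.null(expl)) write_explanation(expl, paths$explanation)
    if (!is.null(holdout)) {
      utils::write.csv(holdout, paths$eval_report, row.names = FALSE)
    }
    utils::write.csv(cv$report, paths$cv_report, row.names = FALSE)
    utils::write.csv(manifest, paths$split_manifest, row.names = FALSE)
    write_train_config(config, paths$config)
    jsonlite::write_json(
      list(format = "fuzznet-run", version = 1L,
           files = lapply(paths, basename)),
      paths$run_manifest, auto_unbox = TRUE, pretty = TRUE)
    out$artifacts <- paths
  }
  out
}
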