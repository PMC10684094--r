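# Longitudinal EHR-style preprocessing: encounter pairing and labeling,
# derived features, missingness handling, filters, standardization,
# patient-wise splitting, and a synthetic cohort generator with planted
# conjunctive rules for validation experiments.

#' Default synthetic cohort specification
#'
#' Describes an advanced-heart-failure cohort at realistic scale: ~300
#' patients with 2-5 hospitalizations each (~550 consecutive-encounter
#' pairs), mixed continuous vitals/labs/echo measures and binary
#' comorbidities, within-patient correlation, missingness (heavier on echo
#' measures), and two planted conjunctive risk rules - low systolic blood
#' pressure with low ejection fraction, and low ejection fraction with
#' hyponatremia - whose disjunction drives the label, flipped with 10%
#' noise. Thresholds are calibrated so the post-noise positive rate is
#' about 35%. Inclusion-criteria variables (age 18-80, LVEF <= 35,
#' BMI <= 50) are drawn truncated to the eligible ranges, as a cohort
#' selected on those criteria would be.
#'
#' @param n_patients number of patients (default 300).
#' @param noise label flip probability (default 0.10; must be < 0.5).
#' @param negative_regime \code{"all"} keeps every negative pair;
#'   \code{"too_well_only"} keeps only negatives from patients flagged as
#'   too well for advanced therapies.
#' @return a list of class \code{cohort_spec}.
#' @export
default_cohort_spec <- function(n_patients = 300L, noise = 0.10,
                                negative_regime = c("all", "too_well_only")) {
  negative_regime <- match.arg(negative_regime)
  features <- data.frame(
    name = c("age", "sbp", "dbp", "lvef", "sodium", "potassium", "hgb",
             "bmi", "lvidd", "mitral_regurg"),
    mean = c(56, 115, 70, 20, 138, 4.24, 11.5, 29, 67, 1.5),
    sd   = c(14, 22, 13, 8.4, 4.1, 0.54, 2, 6, 11, 1.2),
    lower = c(18, 60, 30, 3, 120, 2.5, 5, 14, 35, 0),
    upper = c(80, 220, 130, 35, 155, 7, 19, 50, 110, 4),
    missing_rate = c(0, 0.05, 0.05, 0.20, 0.05, 0.05, 0.05, 0.05, 0.30, 0.30),
    unit = c("years", "mmHg", "mmHg", "%", "mmol/L", "mmol/L", "g/dL",
             "kg/m2", "mm", "grade"),
    stringsAsFactors = FALSE)
  comorbidities <- data.frame(
    name = c("renal_failure", "liver_disease", "copd", "diabetes"),
    prevalence = c(0.65, 0.31, 0.79, 0.40),
    stringsAsFactors = FALSE)
  planted_rules <- list(
    list(terms = data.frame(feature = c("sbp", "lvef"),
                            concept = c("low", "low"),
                            threshold = c(100, 23),
                            stringsAsFactors = FALSE)),
    list(terms = data.frame(feature = c("lvef", "sodium"),
                            concept = c("low", "low"),
                            threshold = c(23, 136),
                            stringsAsFactors = FALSE)))
  structure(list(
    n_patients = as.integer(n_patients),
    encounter_probs = c(`2` = 0.52, `3` = 0.22, `4` = 0.16, `5` = 0.10),
    features = features,
    comorbidities = comorbidities,
    within_patient_cor = 0.5,
    bnp = list(first_mean = 800, first_sd = 500, first_min = 50,
               delta_mean = 15.7, delta_sd = 91.5, delta_min = -95),
    creatinine = list(first_mean = 1.4, first_sd = 0.5, first_min = 0.4,
                      delta_mean = 1.2, delta_sd = 18.8, delta_min = -80),
    planted_rules = planted_rules,
    noise = noise,
    too_well_rate = 0.9,
    negative_regime = negative_regime
  ), class = "cohort_spec")
}

rtruncnorm1 <- function(n, mean, sd, lower, upper) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower | x[bad] > upper]
  }
  x
}

#' Simulate a longitudinal synthetic cohort
#'
#' Generates patients and consecutive hospitalizations according to a
#' [default_cohort_spec()]-style specification, builds the labeled
#' encounter pairs (features from the first encounter of each pair, label
#' from the second), derives the composite features, and returns the
#' generating rules for recovery experiments. Fully deterministic given
#' \code{seed}.
#'
#' @param spec a \code{cohort_spec}.
#' @param seed RNG seed.
#' @return list with \code{encounters} (per-encounter table, missingness as
#'   NA), \code{pairs} (labeled pair table after [build_pairs()] and
#'   [derive_features()]), \code{truth} (the planted rules as an
#'   [ruleset()]), and \code{spec}.
#' @export
simulate_cohort <- function(spec = default_cohort_spec(), seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$noise >= 0.5) stop("label noise must be below 0.5")
  set.seed(seed)
  np <- spec$n_patients
  n_enc <- sample(as.integer(names(spec$encounter_probs)), np, replace = TRUE,
                  prob = spec$encounter_probs)
  rho <- spec$within_patient_cor
  fdf <- spec$features
  rows <- vector("list", np)
  for (p in seq_len(np)) {
    ne <- n_enc[p]
    # per-patient random effect per feature, shared across encounters
    b <- stats::rnorm(nrow(fdf))
    cont <- sapply(seq_len(nrow(fdf)), function(j) {
      e <- stats::rnorm(ne)
      x <- fdf$mean[j] + fdf$sd[j] * (sqrt(rho) * b[j] + sqrt(1 - rho) * e)
      pmin(pmax(x, fdf$lower[j]), fdf$upper[j])
    })
    cont <- matrix(cont, nrow = ne, dimnames = list(NULL, fdf$name))
    bnp_first <- pmax(spec$bnp$first_min,
                      stats::rnorm(ne, spec$bnp$first_mean, spec$bnp$first_sd))
    bnp_delta <- pmax(spec$bnp$delta_min,
                      stats::rnorm(ne, spec$bnp$delta_mean, spec$bnp$delta_sd))
    creat_first <- pmax(spec$creatinine$first_min,
                        stats::rnorm(ne, spec$creatinine$first_mean,
                                     spec$creatinine$first_sd))
    creat_delta <- pmax(spec$creatinine$delta_min,
                        stats::rnorm(ne, spec$creatinine$delta_mean,
                                     spec$creatinine$delta_sd))
    com <- stats::setNames(
      as.integer(stats::runif(nrow(spec$comorbidities)) <
                   spec$comorbidities$prevalence),
      spec$comorbidities$name)
    df <- data.frame(patient_id = sprintf("P%03d", p),
                     encounter = seq_len(ne), cont,
                     bnp_first = bnp_first,
                     bnp_last = bnp_first * (1 + bnp_delta / 100),
                     creat_first = creat_first,
                     creat_last = creat_first * (1 + creat_delta / 100),
                     stringsAsFactors = FALSE)
    for (cm in names(com)) df[[cm]] <- com[[cm]]
    rows[[p]] <- df
  }
  enc <- do.call(rbind, rows)
  # outcome flag at encounter j+1 = planted rules on encounter j, plus noise
  enc$outcome <- 0L
  rule_true <- function(row) {
    any(vapply(spec$planted_rules, function(r) {
      all(vapply(seq_len(nrow(r$terms)), function(t) {
        v <- row[[r$terms$feature[t]]]
        if (r$terms$concept[t] == "low") v < r$terms$threshold[t]
        else v > r$terms$threshold[t]
      }, logical(1)))
    }, logical(1)))
  }
  for (idx in seq_len(nrow(enc))) {
    if (enc$encounter[idx] == 1L) next
    prev <- enc[idx - 1L, ]
    tru <- rule_true(prev)
    flip <- stats::runif(1) < spec$noise
    enc$outcome[idx] <- as.integer(xor(tru, flip))
  }
  # too-well flag: patient-level, mostly true among never-positive patients
  pos_pat <- tapply(enc$outcome, enc$patient_id, function(o) any(o == 1L))
  tw_pat <- stats::setNames(as.integer(stats::runif(length(pos_pat)) <
                                         spec$too_well_rate), names(pos_pat))
  enc$too_well <- ifelse(pos_pat[enc$patient_id], 0L, tw_pat[enc$patient_id])
  # missingness (MCAR) on continuous measures, after labels are computed
  for (j in seq_len(nrow(fdf))) {
    mr <- fdf$missing_rate[j]
    if (mr > 0) {
      miss <- stats::runif(nrow(enc)) < mr
      enc[miss, fdf$name[j]] <- NA_real_
    }
  }
  truth <- ruleset(lapply(spec$planted_rules, function(r) {
    fz_rule(data.frame(feature = r$terms$feature, concept = r$terms$concept,
                       importance = 0.9, stringsAsFactors = FALSE))
  }), outcome_label = "refer for heart transplantation/ LVAD")
  pairs <- derive_features(build_pairs(enc, regime = spec$negative_regime))
  list(encounters = enc, pairs = pairs, truth = truth, spec = spec)
}

#' Build labeled consecutive-encounter pairs
#'
#' One sample per consecutive pair of a patient's encounters: features from
#' the first encounter, label from the \code{outcome} flag of the second.
#' Patients with a single encounter contribute no samples (their count is
#' recorded in the \code{"n_dropped_patients"} attribute). Under the
#' \code{"too_well_only"} regime, negative pairs are kept only when the
#' patient carries the too-well flag.
#'
#' @param encounters per-encounter table with \code{patient_id},
#'   \code{encounter}, feature columns, an \code{outcome} 0/1 flag, and
#'   (for the restricted regime) a \code{too_well} flag.
#' @param regime negative-pair regime, \code{"all"} (default) or
#'   \code{"too_well_only"}.
#' @return pair-level data.frame with \code{patient_id},
#'   \code{encounter_first}, \code{label} and the first encounter's feature
#'   columns.
#' @export
build_pairs <- function(encounters, regime = c("all", "too_well_only")) {
  regime <- match.arg(regime)
  stopifnot(all(c("patient_id", "encounter", "outcome") %in%
                  names(encounters)))
  feat_cols <- setdiff(names(encounters),
                       c("encounter", "outcome", "too_well"))
  out <- list(); dropped <- 0L
  for (pid in unique(encounters$patient_id)) {
    pe <- encounters[encounters$patient_id == pid, ]
    pe <- pe[order(pe$encounter), ]
    if (any(duplicated(pe$encounter))) {
      stop("duplicated encounter index for patient ", pid)
    }
    if (nrow(pe) < 2L) { dropped <- dropped + 1L; next }
    for (j in seq_len(nrow(pe) - 1L)) {
      row <- pe[j, feat_cols, drop = FALSE]
      row$encounter_first <- pe$encounter[j]
      row$label <- pe$outcome[j + 1L]
      if (regime == "too_well_only" && row$label == 0L &&
          (is.null(pe$too_well) || pe$too_well[j] != 1L)) next
      out[[length(out) + 1L]] <- row
    }
  }
  pairs <- do.call(rbind, out)
  rownames(pairs) <- NULL
  attr(pairs, "n_dropped_patients") <- dropped
  pairs
}

#' Derive composite clinical features
#'
#' Mean arterial pressure \code{map = dbp + (sbp - dbp) / 3}, pulse
#' pressure \code{pulse_pressure = sbp - dbp}, and percent changes over the
#' hospitalization \code{bnp_delta} and \code{creat_delta} =
#' \code{100 * (last - first) / first} (masked as missing when the first
#' measurement is 0, never infinite). The first creatinine is kept as the
#' \code{creatinine} feature; raw first/last BNP and creatinine columns are
#' consumed.
#'
#' @param pairs a pair-level table (see [build_pairs()]).
#' @return the augmented table.
#' @export
derive_features <- function(pairs) {
  if (all(c("sbp", "dbp") %in% names(pairs))) {
    pairs$map <- pairs$dbp + (pairs$sbp - pairs$dbp) / 3
    pairs$pulse_pressure <- pairs$sbp - pairs$dbp
  }
  pct <- function(first, last) {
    out <- 100 * (last - first) / first
    out[!is.na(first) & first == 0] <- NA_real_
    out
  }
  if (all(c("bnp_first", "bnp_last") %in% names(pairs))) {
    pairs$bnp_delta <- pct(pairs$bnp_first, pairs$bnp_last)
    pairs$bnp_first <- pairs$bnp_last <- NULL
  }
  if (all(c("creat_first", "creat_last") %in% names(pairs))) {
    pairs$creat_delta <- pct(pairs$creat_first, pairs$creat_last)
    pairs$creatinine <- pairs$creat_first
    pairs$creat_first <- pairs$creat_last <- NULL
  }
  pairs
}

#' Feature schema of a cohort pair table
#'
#' Builds the model schema from a pair table: named continuous columns plus
#' 0/1 comorbidity columns as binary categorical features.
#'
#' @param pairs the pair table.
#' @param continuous,categorical character vectors of column names; by
#'   default every numeric non-0/1 feature column is continuous and every
#'   0/1 column categorical (bookkeeping columns are excluded).
#' @param units optional named character vector of unit labels.
#' @return an [feature_schema()].
#' @export
cohort_schema <- function(pairs, continuous = NULL, categorical = NULL,
                          units = NULL) {
  book <- c("patient_id", "encounter_first", "label", "pair_id")
  cand <- setdiff(names(pairs), book)
  if (is.null(continuous) || is.null(categorical)) {
    is_bin <- vapply(cand, function(cn) {
      v <- pairs[[cn]]
      is.numeric(v) && all(v %in% c(0, 1, NA))
    }, logical(1))
    if (is.null(categorical)) categorical <- cand[is_bin]
    if (is.null(continuous)) {
      continuous <- cand[!is_bin &
                           vapply(cand, function(cn) is.numeric(pairs[[cn]]),
                                  logical(1))]
    }
  }
  nm <- c(continuous, categorical)
  un <- rep("", length(nm))
  if (!is.null(units)) un[match(names(units), nm)] <- units
  feature_schema(nm,
                 c(rep("continuous", length(continuous)),
                   rep("categorical", length(categorical))),
                 n_levels = c(rep(NA, length(continuous)),
                              rep(2L, length(categorical))),
                 units = un)
}

#' Missingness filters
#'
#' Removes (1) continuous features whose missing rate exceeds
#' \code{feature_missing_max} unless exempted (echo measures are exempt by
#' default, reflecting their clinical importance), then (2) patients with
#' more than \code{patient_missing_max} missing cells across their rows.
#' Optional eligibility filters (age 18-80, LVEF <= 35, BMI <= 50) are
#' applied to rows when the corresponding columns exist. Re-running the
#' filtered output is a no-op.
#'
#' @param pairs the pair table.
#' @param schema an [feature_schema()]; filtered features are also removed
#'   from the returned schema.
#' @param feature_missing_max maximum feature missing rate (default 0.6).
#' @param patient_missing_max maximum missing cells per patient
#'   (default 10).
#' @param exempt features never removed (default the echo measures
#'   \code{lvef}, \code{lvidd}, \code{mitral_regurg}).
#' @param eligibility apply the range filters (default TRUE).
#' @return list with \code{pairs}, \code{schema} and \code{log} (a list of
#'   removed features / excluded patients / dropped rows).
#' @export
apply_filters <- function(pairs, schema, feature_missing_max = 0.6,
                          patient_missing_max = 10,
                          exempt = c("lvef", "lvidd", "mitral_regurg"),
                          eligibility = TRUE) {
  feat <- intersect(schema$features$name, names(pairs))
  miss_rate <- vapply(feat, function(cn) mean(is.na(pairs[[cn]])), numeric(1))
  drop_feat <- feat[miss_rate > feature_missing_max & !(feat %in% exempt)]
  pairs <- pairs[, setdiff(names(pairs), drop_feat), drop = FALSE]
  keep_feat <- setdiff(schema$features$name, drop_feat)
  fi <- schema$features[match(keep_feat, schema$features$name), ]
  schema <- feature_schema(fi$name, fi$kind, n_levels = fi$n_levels,
                           units = fi$unit)
  n_miss <- tapply(
    rowSums(is.na(pairs[, intersect(keep_feat, names(pairs)),
                        drop = FALSE])),
    pairs$patient_id, sum)
  drop_pat <- names(n_miss)[n_miss > patient_missing_max]
  pairs2 <- pairs[!(pairs$patient_id %in% drop_pat), , drop = FALSE]
  dropped_rows <- 0L
  if (eligibility) {
    ok <- rep(TRUE, nrow(pairs2))
    if ("age" %in% names(pairs2)) {
      ok <- ok & (is.na(pairs2$age) | (pairs2$age >= 18 & pairs2$age <= 80))
    }
    if ("lvef" %in% names(pairs2)) {
      ok <- ok & (is.na(pairs2$lvef) | pairs2$lvef <= 35)
    }
    if ("bmi" %in% names(pairs2)) {
      ok <- ok & (is.na(pairs2$bmi) | pairs2$bmi <= 50)
    }
    dropped_rows <- sum(!ok)
    pairs2 <- pairs2[ok, , drop = FALSE]
  }
  if (nrow(pairs2) == 0L) stop("no samples remain after filtering")
  rownames(pairs2) <- NULL
  list(pairs = pairs2, schema = schema,
       log = list(removed_features = drop_feat,
                  excluded_patients = drop_pat,
                  dropped_rows = dropped_rows))
}

#' Impute missing values (carry-forward then chained stochastic completion)
#'
#' Step 1: within each patient, missing continuous values are filled
#' forward from earlier encounters (carry-forward; leakage-free by
#' construction since it never crosses patients). Step 2: remaining gaps
#' are filled by a seeded chained-equations-style completion: columns are
#' initialized at the means of the fitting rows, then for several sweeps
#' each incomplete feature is regressed (on the fitting rows where it was
#' observed) on all other features and missing entries are replaced by the
#' prediction plus Gaussian residual noise. All models and statistics use
#' only \code{fit_rows}, so validation/test rows never influence the
#' imputation model.
#'
#' @param pairs the pair table (with \code{patient_id} and
#'   \code{encounter_first} for carry-forward ordering).
#' @param schema an [feature_schema()].
#' @param fit_rows integer row indices on which imputation models are fit
#'   (default: all rows).
#' @param seed RNG seed (same seed, same completion).
#' @param sweeps number of chained sweeps (default 3).
#' @return list with \code{pairs} (no missing values), \code{log} (counts
#'   of fills by source), and attribute-carried \code{fit_rows} for
#'   leakage assertions.
#' @export
impute_cohort <- function(pairs, schema, fit_rows = seq_len(nrow(pairs)),
                          seed = 1L, sweeps = 3L) {
  cont <- intersect(schema$features$name[schema$features$kind == "continuous"],
                    names(pairs))
  cats <- intersect(schema$features$name[schema$features$kind == "categorical"],
                    names(pairs))
  n_cf <- 0L
  # carry-forward within patient
  if (all(c("patient_id", "encounter_first") %in% names(pairs))) {
    ord <- order(pairs$patient_id, pairs$encounter_first)
    for (cn in cont) {
      v <- pairs[[cn]][ord]
      pid <- pairs$patient_id[ord]
      for (j in seq_along(v)[-1]) {
        if (is.na(v[j]) && pid[j] == pid[j - 1] && !is.na(v[j - 1])) {
          v[j] <- v[j - 1]; n_cf <- n_cf + 1L
        }
      }
      pairs[[cn]][ord] <- v
    }
  }
  miss_mask <- lapply(pairs[cont], is.na)
  n_model <- sum(vapply(miss_mask, sum, integer(1)))
  if (n_model > 0) {
    set.seed(seed)
    preds <- c(cont, cats)
    # mean initialization from fitting rows
    for (cn in cont) {
      mu <- mean(pairs[[cn]][fit_rows], na.rm = TRUE)
      if (!is.finite(mu)) mu <- mean(pairs[[cn]], na.rm = TRUE)
      pairs[[cn]][miss_mask[[cn]]] <- mu
    }
    for (s in seq_len(sweeps)) {
      for (cn in cont) {
        mi <- miss_mask[[cn]]
        if (!any(mi)) next
        obs_fit <- intersect(fit_rows, which(!mi))
        if (length(obs_fit) < length(preds) + 2L) next
        rhs <- setdiff(preds, cn)
        dd <- pairs[, c(cn, rhs), drop = FALSE]
        fml <- stats::as.formula(paste0("`", cn, "` ~ ."))
        fit <- stats::lm(fml, data = dd[obs_fit, , drop = FALSE])
        # derived features make the design collinear by construction; the
        # rank-deficient fit is fine for prediction
        sig <- suppressWarnings(summary(fit)$sigma)
        if (!is.finite(sig)) sig <- 0
        mu <- suppressWarnings(
          stats::predict(fit, newdata = dd[mi, , drop = FALSE]))
        pairs[[cn]][mi] <- mu + stats::rnorm(sum(mi), 0, sig)
      }
    }
  }
  out <- list(pairs = pairs,
              log = list(carry_forward = n_cf, model_filled = n_model))
  attr(out, "fit_rows") <- fit_rows
  out
}

#' Standardize continuous features and encode categoricals
#'
#' Z-scores every continuous feature using mean/SD estimated from
#' \code{fit_rows} only (the leakage guard: applying to held-out rows uses
#' exclusively the fitting rows' statistics), and recodes binary 0/1
#' columns to level codes. Zero-variance columns are centered, given SD 1,
#' and flagged.
#'
#' @param pairs a complete (imputed) pair table.
#' @param schema an [feature_schema()].
#' @param fit_rows rows used to estimate the statistics (default: all).
#' @return list with \code{X} (model-ready numeric matrix in schema column
#'   order), \code{y} (labels if a \code{label} column exists),
#'   \code{patient_id}, \code{stats} (named \code{mean}/\code{sd} vectors in
#'   clinical units) and \code{zero_variance} (character vector of flagged
#'   features). Attribute \code{"fit_rows"} records the fitting rows.
#' @export
standardize_and_encode <- function(pairs, schema,
                                   fit_rows = seq_len(nrow(pairs))) {
  nm <- schema$features$name
  stopifnot(all(nm %in% names(pairs)))
  X <- matrix(0, nrow(pairs), length(nm), dimnames = list(NULL, nm))
  mu <- sdv <- stats::setNames(rep(NA_real_, length(nm)), nm)
  zv <- character(0)
  for (j in seq_along(nm)) {
    v <- pairs[[nm[j]]]
    if (schema$features$kind[j] == "continuous") {
      m <- mean(v[fit_rows]); s <- stats::sd(v[fit_rows])
      if (!is.finite(s) || s == 0) { s <- 1; zv <- c(zv, nm[j]) }
      mu[j] <- m; sdv[j] <- s
      X[, j] <- (v - m) / s
    } else {
      X[, j] <- if (all(v %in% c(0, 1, NA))) v + 1 else v
    }
  }
  out <- list(X = X,
              y = if ("label" %in% names(pairs)) pairs$label else NULL,
              patient_id = pairs$patient_id,
              stats = list(mean = mu[schema$features$kind == "continuous"],
                           sd = sdv[schema$features$kind == "continuous"]),
              zero_variance = zv)
  attr(out, "fit_rows") <- fit_rows
  out
}

#' Patient-wise train/test split and cross-validation folds
#'
#' Patients (never rows) are first split into a training set and a holdout
#' test set, then training patients are assigned to \code{k} folds,
#' stratified by the patient-level label (a patient is positive if any of
#' their pairs is positive). Every pair follows its patient.
#'
#' @param pairs the pair table (needs \code{patient_id} and \code{label}).
#' @param k number of folds (>= 2).
#' @param seed RNG seed.
#' @param holdout_fraction fraction of patients held out as the test set
#'   (default 0.2; 0 disables the holdout).
#' @return a \code{data.frame} manifest with columns \code{patient_id},
#'   \code{role} (\code{"train"}/\code{"test"}) and \code{fold} (NA for
#'   test patients).
#' @export
patient_folds <- function(pairs, k = 5L, seed = 1L, holdout_fraction = 0.2) {
  stopifnot(k >= 2L, holdout_fraction >= 0, holdout_fraction < 1)
  pats <- unique(pairs$patient_id)
  pos <- vapply(pats, function(p) {
    any(pairs$label[pairs$patient_id == p] == 1L)
  }, logical(1))
  set.seed(seed)
  role <- stats::setNames(rep("train", length(pats)), pats)
  for (grp in list(pats[pos], pats[!pos])) {
    n_test <- round(holdout_fraction * length(grp))
    if (n_test > 0) role[sample(as.character(grp), n_test)] <- "test"
  }
  train_pats <- pats[role[as.character(pats)] == "train"]
  if (length(train_pats) < k) stop("fewer training patients than folds")
  fold <- stats::setNames(rep(NA_integer_, length(pats)), pats)
  for (grp in list(train_pats[pos[match(train_pats, pats)]],
                   train_pats[!pos[match(train_pats, pats)]])) {
    if (length(grp) == 0) next
    fold[sample(as.character(grp))] <- rep_len(seq_len(k), length(grp))
  }
  data.frame(patient_id = pats,
             role = unname(role[as.character(pats)]),
             fold = unname(fold[as.character(pats)]),
             stringsAsFactors = FALSE)
}

#' Write / read a cohort table as CSV
#'
#' Missing values are written as empty fields; a schema-version comment
#' line is emitted first.
#'
#' @param pairs the table.
#' @param path file path.
#' @return \code{path} (writer, invisibly) or the table (reader).
#' @export
write_cohort <- function(pairs, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# fuzznet-cohort v1", con)
  utils::write.csv(pairs, con, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  utils::read.csv(path, comment.char = "#", na.strings = "",
                  stringsAsFactors = FALSE)
}

#' Write / read a cohort specification as YAML
#' @param spec a \code{cohort_spec}.
#' @param path file path.
#' @return \code{path} (writer, invisibly) or the spec (reader).
#' @export
write_cohort_spec <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  spec <- default_cohort_spec()
  for (nmx in names(raw)) {
    v <- raw[[nmx]]
    if (nmx %in% c("features", "comorbidities")) v <- as.data.frame(v)
    if (nmx == "planted_rules") {
      v <- lapply(v, function(r) list(terms = as.data.frame(r$terms)))
    }
    if (nmx == "encounter_probs") v <- unlist(v)
    spec[[nmx]] <- v
  }
  spec
}
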