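cohort_like_schema <- function() {
  feature_schema(
    c("sbp", "lvef", "sodium", "bnp_delta", "mitral_regurg", "diabetes"),
    c(rep("continuous", 5), "categorical"),
    n_levels = c(rep(NA, 5), 2))
}

test_that("rule construction enforces the invariants", {
  expect_error(fz_rule(data.frame(feature = c("a", "a"),
                                  concept = c("low", "high"))),
               "at most once")
  expect_error(fz_rule(data.frame(feature = "a", concept = "low",
                                  importance = 1.2)))
  r <- fz_rule(list(c("sbp", "low"), c("lvef", "low")))
  expect_equal(nrow(r$terms), 2)
  expect_equal(r$class_weights, c(0.05, 0.9))
  rs <- hf_referral_rules()
  expect_length(rs, 4)
  expect_true(all(vapply(rs$rules, function(r) r$terms$feature[1] == "lvef",
                         logical(1))))
})

test_that("knowledge initialization concentrates attention on the rule terms", {
  sc <- cohort_like_schema()
  rs <- hf_referral_rules()
  net <- init_from_rules(rs, sc, K = 6, seed = 3)
  p <- network_params(net)
  want <- list(c("lvef:low", "sbp:low"), c("lvef:low", "mitral_regurg:high"),
               c("lvef:low", "bnp_delta:high"), c("lvef:low", "sodium:low"))
  for (k in 1:4) {
    Ak <- p$A[, , k]
    # argmax slots are exactly the rule's (feature, concept) pairs
    got <- c()
    for (i in seq_len(nrow(Ak))) {
      if (max(Ak[i, ]) > 0.5) {
        d <- which.max(Ak[i, ])
        got <- c(got, paste0(sc$features$name[i], ":",
                             fuzznet:::concept_labels(sc, i)[d]))
      }
    }
    expect_setequal(got, want[[k]])
    # connection high only on the rule's features
    expect_true(all(p$M[sc$features$name %in%
                          c("lvef", rs$rules[[k]]$terms$feature), k] > 0.8))
    expect_gt(p$W[k, 2], 0.8)  # positive-class inference weight
  }
  # empty ruleset reproduces the plain seeded initialization exactly
  net0 <- init_from_rules(ruleset(), sc, K = 6, seed = 3)
  netref <- fz_network(sc, K = 6, C = 2, seed = 3)
  expect_identical(net0$raw, netref$raw)
  # one rule, one term, K = 1: attention concentrates on one slot
  one <- ruleset(list(fz_rule(data.frame(feature = "sbp", concept = "low"))))
  net1 <- init_from_rules(one, sc, K = 1, seed = 1)
  A1 <- network_params(net1)$A[, , 1]
  expect_equal(arrayInd(which.max(A1), dim(A1))[1, ], c(1L, 1L),
               ignore_attr = TRUE)
  expect_error(init_from_rules(
    ruleset(list(fz_rule(data.frame(feature = "nope", concept = "low")))),
    sc, K = 2), "unknown feature")
})

test_that("rule extraction filters by strength, class and correlation", {
  sc <- feature_schema(c("u", "v"), rep("continuous", 2))
  # hand-built columns: rule 1 attends u:low, rule 2 attends v:high; both
  # positive-class. Rows sit on the low plateaus of u and v, so rule 1
  # fires near 1 and rule 2 near 0.
  rs <- ruleset(list(fz_rule(data.frame(feature = "u", concept = "low")),
                     fz_rule(data.frame(feature = "v", concept = "high"))))
  net <- init_from_rules(rs, sc, K = 2, seed = 2)
  net$smooth$eps <- 0.05
  p <- network_params(net)
  set.seed(2)
  X <- cbind(rep(p$cutoffs[1, 1] - 2, 10),
             p$cutoffs[2, 1] - 2 + rnorm(10, 0, 0.1))
  r <- rule_strengths(net, X)
  expect_gt(mean(r[, 1]), 0.8)
  got <- extract_rules(net, X, strength_threshold = 0.1,
                       importance_threshold = 0.2)
  expect_length(got, 1)
  expect_equal(got$rules[[1]]$terms$feature, "u")
  expect_equal(got$rules[[1]]$terms$concept, "low")
  # two identical strong columns: correlation pruning keeps exactly one
  net$raw$A[, , 2] <- net$raw$A[, , 1]
  net$raw$M[, 2] <- net$raw$M[, 1]
  net$raw$W[2, ] <- net$raw$W[1, ]
  got2 <- extract_rules(net, X, strength_threshold = 0.1)
  expect_length(got2, 1)
  # everything filtered out: empty set with a warning, not an error
  expect_warning(
    empty <- extract_rules(net, X, strength_threshold = 2),
    "no rule passed")
  expect_length(empty, 0)
})

test_that("init -> extract round trip recovers the injected terms on top", {
  sc <- cohort_like_schema()
  rs <- hf_referral_rules()
  net <- init_from_rules(rs, sc, K = 4, seed = 5)
  net$smooth$eps <- 0.5
  set.seed(8)
  X <- cbind(matrix(rnorm(30 * 5), 30, 5), sample(0:1, 30, TRUE))
  got <- extract_rules(net, X, strength_threshold = 0,
                       corr_threshold = 0.999, importance_threshold = 0,
                       target_classes = NULL)
  expect_length(got, 4)
  for (rule in rs$rules) {
    match_found <- any(vapply(got$rules, function(gr) {
      top <- gr$terms[seq_len(min(2, nrow(gr$terms))), ]
      setequal(paste(top$feature, top$concept),
               paste(rule$terms$feature, rule$terms$concept))
    }, logical(1)))
    expect_true(match_found)
  }
})

test_that("rule ensembling keeps the strongest least-correlated rules", {
  mk <- function(f, cpt, strength, imp = 0.9) {
    fz_rule(data.frame(feature = f, concept = cpt, importance = imp),
            strength = strength)
  }
  rs1 <- ruleset(list(mk(c("a", "b"), c("low", "low"), 0.8),
                      mk(c("c", "d"), c("high", "low"), 0.5)))
  # single fold: top max_rules subset of that fold
  e1 <- ensemble_rules(list(rs1), max_rules = 1)
  expect_length(e1, 1)
  expect_equal(e1$rules[[1]]$strength, 0.8)
  # five identical folds collapse to one fold's rules
  e5 <- ensemble_rules(rep(list(rs1), 5), max_rules = 10)
  expect_length(e5, 2)
  # idempotence
  e5b <- ensemble_rules(list(e5), max_rules = 10)
  expect_equal(e5b, e5)
  # disjoint strong rules from two folds: union ordered by strength,
  # cross-checked against brute-force enumeration of admissible selections
  rs2 <- ruleset(list(mk(c("e", "f"), c("low", "high"), 0.9),
                      mk(c("g", "h"), c("low", "low"), 0.3)))
  e <- ensemble_rules(list(rs1, rs2), max_rules = 4)
  strengths <- vapply(e$rules, function(r) r$strength, numeric(1))
  expect_equal(strengths, c(0.9, 0.8, 0.5, 0.3))
  # pruning soundness: no surviving pair above the similarity threshold
  keys <- unique(unlist(lapply(e$rules, function(r) {
    paste(r$terms$feature, r$terms$concept, sep = ":")
  })))
  for (i in seq_along(e$rules)) {
    for (j in seq_len(i - 1)) {
      sim <- fuzznet:::cosine_sim(
        fuzznet:::rule_term_vector(e$rules[[i]], keys),
        fuzznet:::rule_term_vector(e$rules[[j]], keys))
      expect_lte(sim, 0.9)
    }
  }
})

test_that("rendering produces the clinical sentence form and heatmap", {
  rs <- ruleset(list(fz_rule(data.frame(
    feature = c("Systolic Blood Pressure",
                "Left Ventricular Ejection Fraction"),
    concept = c("low", "low"), importance = 0.9))),
    outcome_label = "refer for heart transplantation/ LVAD")
  rr <- render_rules(rs)
  expect_identical(
    rr$text,
    paste("IF Systolic Blood Pressure is low AND Left Ventricular",
          "Ejection Fraction is low, THEN refer for heart",
          "transplantation/ LVAD"))
  # empty ruleset renders an empty report without error
  rr0 <- render_rules(ruleset())
  expect_length(rr0$text, 0)
  # 7 rules over distinct concepts: one heatmap column per rule, one row
  # per used feature:concept
  rules7 <- lapply(1:7, function(k) {
    fz_rule(data.frame(feature = paste0("f", k), concept = "low",
                       importance = 0.5), strength = k / 10)
  })
  rr7 <- render_rules(ruleset(rules7))
  expect_equal(dim(rr7$heatmap), c(7, 7))
  # a negative-class rule gets a negated consequent
  neg <- ruleset(list(fz_rule(data.frame(feature = "sbp", concept = "high"),
                              class_weights = c(0.9, 0.05))),
                 outcome_label = "refer")
  expect_match(render_rules(neg)$text, "NOT: refer")
})

test_that("rulesets round-trip through JSON", {
  rs <- hf_referral_rules()
  rs$rules[[1]]$strength <- 0.42
  path <- tempfile(fileext = ".json")
  write_ruleset(rs, path)
  rs2 <- read_ruleset(path)
  expect_equal(length(rs2), length(rs))
  expect_identical(rs2$outcome_label, rs$outcome_label)
  for (k in seq_along(rs$rules)) {
    expect_equal(rs2$rules[[k]]$terms, rs$rules[[k]]$terms)
    expect_equal(rs2$rules[[k]]$class_weights, rs$rules[[k]]$class_weights)
  }
  expect_equal(rs2$rules[[1]]$strength, 0.42)
})
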