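test_that("importance filter keeps strictly-exceeding rules only", {
  rs <- ruleset(list(parse_rule("x <= 1", id = "a"),
                     parse_rule("x > 1", id = "b"),
                     parse_rule("x <= 0", id = "c")))
  m <- structure(list(importances = c(a = 0.05, b = 0.3, c = 0.1),
                      weights = c(a = 1, b = 1, c = 1)),
                 class = "sparse_linear_model")
  tr <- importance_filter(rs, m, thr = 0.1)
  expect_equal(tr$rules_out, "b")          # 0.1 exactly is dropped
})

test_that("phi filter matches the contingency-table formula", {
  # 2x2 table (a,b,c,d) = (30,20,20,30): phi = (ad-bc)/sqrt(row*col products)
  ind <- cbind(r = rep(c(1, 1, 0, 0), c(30, 20, 20, 30)))
  y <- rep(c(1, 0, 1, 0), c(30, 20, 20, 30))
  tr <- outcome_correlation_filter(ind, y, thr = 0.4)
  expect_equal(unname(tr$statistic[["r"]]), 0.2, tolerance = 1e-12)
  expect_length(tr$rules_out, 0)           # 0.2 < 0.4 -> dropped

  perfect <- cbind(p = y, q = 1 - y)
  tr2 <- outcome_correlation_filter(perfect, y, thr = 0.4)
  expect_setequal(tr2$rules_out, c("p", "q"))   # |phi| = 1 both ways
  expect_equal(unname(tr2$statistic[["q"]]), -1)

  const <- cbind(k = rep(1, length(y)))
  expect_message(tr3 <- outcome_correlation_filter(const, y), "constant")
  expect_equal(unname(tr3$statistic[["k"]]), 0)
})

test_that("merging concatenates datasets and unions shared-rule provenance", {
  tab <- feature_table(data.frame(x = c(0, 1, 2), f = c(1, 0, 1)))
  rs1 <- ruleset(list(parse_rule("x <= 1", id = "g1", source = "gradient_boosting"),
                      parse_rule("f", id = "g2", source = "gradient_boosting")))
  rs2 <- ruleset(list(parse_rule("f", id = "r1", source = "random_forest"),
                      parse_rule("x > 1", id = "r2", source = "random_forest")))
  i1 <- rules_to_dataset(rs1, tab); i2 <- rules_to_dataset(rs2, tab)
  mg <- merge_rule_datasets(list(rs1, rs2), list(i1, i2))
  expect_length(mg$ruleset$rules, 3)       # shared flag rule collapsed
  shared <- mg$ruleset$rules[[2]]
  expect_setequal(shared$source, c("gradient_boosting", "random_forest"))
  expect_equal(ncol(mg$indicators), 3)

  # empty dataset is the identity
  mg2 <- merge_rule_datasets(list(rs1, ruleset(list(), "x")),
                             list(i1, matrix(integer(0), 3, 0)))
  expect_length(mg2$ruleset$rules, 2)

  expect_error(merge_rule_datasets(list(rs1, rs2),
                                   list(i1, i2[1:2, , drop = FALSE])),
               "sample mismatch")
})

test_that("identical-indicator collapse keeps the simplest representative", {
  tab <- feature_table(data.frame(x = c(0, 1, 2, 3), z = c(9, 9, 9, 9)))
  rs <- ruleset(list(parse_rule("x <= 1", id = "short"),
                     parse_rule("x <= 1 & z <= 10", id = "long"),
                     parse_rule("x > 1", id = "other")))
  ind <- rules_to_dataset(rs, tab)
  cl <- collapse_identical_indicators(rs, ind)
  ids <- vapply(cl$ruleset$rules, `[[`, character(1), "id")
  expect_setequal(ids, c("short", "other"))
})

test_that("merged LASSO keeps predictive rules and respects forced lambda", {
  set.seed(12)
  y <- rbinom(300, 1, 0.45)
  good <- as.integer(runif(300) < ifelse(y == 1, 0.9, 0.1))
  noise <- matrix(rbinom(300 * 10, 1, 0.3), 300, 10)
  ind <- cbind(good = good, noise)
  colnames(ind) <- c("good", paste0("n", 1:10))
  out <- lasso_select_rules(ind, y, seed = 12)
  expect_true("good" %in% out$trace$rules_out)
  # pure-noise designs keep only a small fraction at the CV penalty
  out_noise <- lasso_select_rules(ind[, -1], y, seed = 12)
  expect_lte(length(out_noise$trace$rules_out), 5)
  # lambda forced very large: empty selection
  out_big <- lasso_select_rules(ind, y, lambda = 1e6)
  expect_length(out_big$trace$rules_out, 0)
})

test_that("linear SHAP equals exact permutation Shapley and is additive", {
  set.seed(13)
  for (p in c(2, 4, 6)) {
    x <- matrix(rbinom(40 * p, 1, 0.5), 40, p,
                dimnames = list(NULL, paste0("r", 1:p)))
    w <- stats::setNames(rnorm(p), colnames(x))
    phi <- linear_shap(w, x)
    brute <- shapley_permutation(w, x)
    expect_equal(unname(phi), unname(brute), tolerance = 1e-10)
    # additivity: rows sum to f(x) - mean f(x)
    f <- as.vector(x %*% w)
    expect_equal(unname(rowSums(phi)), f - mean(f), tolerance = 1e-8)
  }
})

test_that("SHAP filter drops zero-weight and constant-indicator rules", {
  x <- cbind(a = c(1, 0, 1, 0), b = c(1, 1, 1, 1), c = c(1, 0, 0, 0))
  m <- structure(list(weights = c(a = 0, b = 2, c = 1)),
                 class = "sparse_linear_model")
  tr <- shap_filter(m, x, thr = 0.5)
  expect_equal(unname(tr$raw[["a"]]), 0)   # zero weight -> zero contribution
  expect_equal(unname(tr$raw[["b"]]), 0)   # constant indicator -> zero
  expect_false(any(c("a", "b") %in% tr$rules_out))
  expect_true("c" %in% tr$rules_out)
})

test_that("cascade stages replay bit-identically under a fixed seed", {
  tab <- generate_cohort(150, "published_model", seed = 21)
  cfg <- ensemble_config(gbdt = list(n_trees = 5), rf = list(n_trees = 5),
                         ada = list(n_trees = 3))
  ens <- fit_ensembles(tab, cfg, seed = 21)
  c1 <- suppressWarnings(suppressMessages(fuse_and_select(ens, tab, seed = 21)))
  c2 <- suppressWarnings(suppressMessages(fuse_and_select(ens, tab, seed = 21)))
  expect_identical(rulefusion:::rule_ids(c1$ruleset),
                   rulefusion:::rule_ids(c2$ruleset))
  expect_identical(c1$indicators, c2$indicators)
  expect_identical(lapply(c1$traces, `[[`, "rules_out"),
                   lapply(c2$traces, `[[`, "rules_out"))
  tt <- cascade_trace_table(c1)
  expect_true(all(c("stage", "rule", "statistic", "kept") %in% names(tt)))
})
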