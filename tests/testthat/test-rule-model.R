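test_that("parser handles flags, prefixes, intervals and printed number quirks", {
  r5 <- parse_rule("spiculated margin", id = "Rule5")
  expect_length(r5$conditions, 1)
  expect_equal(r5$conditions[[1]]$op, "FLAG_EQ")
  expect_equal(r5$conditions[[1]]$value, 1L)

  r15 <- parse_rule("rf_original_glcm_JointEntropy > 8.48 & pleural indentation = 1",
                    id = "Rule15")
  expect_length(r15$conditions, 2)
  expect_equal(r15$source, "random_forest")
  expect_equal(vapply(r15$conditions, `[[`, character(1), "feature"),
               c("original_glcm_JointEntropy", "pleural indentation"))

  # spaced "<  =", thousands separator, unicode minus
  r <- parse_rule("a_feature <  = 45,043.45 & b_feature <  =  \u2212768.75")
  expect_equal(r$conditions[[1]]$threshold, 45043.45)
  expect_equal(r$conditions[[2]]$threshold, -768.75)

  ri <- parse_rule("x \u2208 (122.71,525.63]")
  expect_equal(ri$conditions[[1]][c("op", "lower", "upper")],
               list(op = "INTERVAL", lower = 122.71, upper = 525.63))

  r0 <- parse_rule("some flag = 0")
  expect_equal(r0$conditions[[1]]$value, 0L)

  expect_error(parse_rule("x <= 3 & x \u2208 (5, 2]"), "lower >= upper")
  expect_error(parse_rule("x >= 3"), ">=")
  expect_error(parse_rule("x < 3"), "malformed")
})

test_that("canonicalization intersects bounds, forms intervals, rejects empties", {
  r <- parse_rule("x <= 5 & x <= 3")
  expect_equal(r$conditions[[1]]$threshold, 3)

  r <- parse_rule("x > 2 & x <= 9")
  expect_equal(r$conditions[[1]][c("op", "lower", "upper")],
               list(op = "INTERVAL", lower = 2, upper = 9))

  expect_error(parse_rule("x > 7 & x <= 3"), "empty rule")
  expect_error(parse_rule("f = 1 & f = 0"), "contradictory")

  # conditions sorted by feature name
  r <- parse_rule("zeta > 1 & alpha <= 2")
  expect_equal(vapply(r$conditions, `[[`, character(1), "feature"),
               c("alpha", "zeta"))
})

test_that("evaluation uses inclusive <=, strict >, left-open intervals", {
  tab <- feature_table(data.frame(
    "original_shape_MajorAxisLength" = c(10.0, 12.47),
    "original_firstorder_10Percentile" = c(-800, -800),
    "wavelet-LLH_glszm_LargeAreaHighGrayLevelEmphasis" = c(1000, 1000),
    "wavelet-LLH_firstorder_Maximum" = c(400, 400),
    check.names = FALSE))
  rule1 <- published_ruleset()$rules[[1]]
  expect_equal(evaluate_rule(rule1, tab), c(1L, 0L))

  # boundary: <= includes the threshold, interval excludes its lower bound
  tb <- feature_table(data.frame(x = c(12.46, 122.71, 122.72, 525.63, 525.64)))
  expect_equal(evaluate_rule(parse_rule("x <= 12.46"), tb),
               c(1L, 0L, 0L, 0L, 0L))
  expect_equal(evaluate_rule(parse_rule("x \u2208 (122.71,525.63]"), tb),
               c(0L, 0L, 1L, 1L, 0L))
})

test_that("missing feature values make the rule not fire, with a warning", {
  tab <- feature_table(data.frame(x = c(0, NA, 2)))
  r <- parse_rule("x <= 1")
  expect_warning(ind <- evaluate_rule(r, tab), "missing")
  expect_equal(ind, c(1L, 0L, 0L))
  expect_error(evaluate_rule(r, tab, na_action = "error"), "missing value")
  expect_error(evaluate_rule(parse_rule("zz <= 1"), tab), "absent")
})

test_that("indicator matrices stack rule evaluations in order", {
  tab <- feature_table(data.frame(x = c(0, 2, 1)))
  rs <- ruleset(list(parse_rule("x <= 1", id = "a"),
                     parse_rule("x > 1", id = "b")))
  m <- rules_to_dataset(rs, tab)
  expect_equal(colnames(m), c("a", "b"))
  expect_true(all(m %in% c(0L, 1L)))
  # complementary rules partition every sample
  expect_equal(unname(rowSums(m)), rep(1, 3))
  # duplicated rule gives identical columns
  rs2 <- ruleset(list(parse_rule("x <= 1", id = "a"),
                      parse_rule("x <= 1", id = "a2")))
  m2 <- rules_to_dataset(rs2, tab)
  expect_equal(unname(m2[, 1]), unname(m2[, 2]))
})

test_that("deduplication collapses identical condition sets and unions provenance", {
  r1 <- parse_rule("spiculated margin", id = "g1", source = "gradient_boosting")
  r2 <- parse_rule("spiculated margin", id = "r1", source = "random_forest")
  r3 <- parse_rule("x <= 1", id = "x1", source = "adaboost")
  # same conditions in different written order also collapse
  r4 <- parse_rule("y > 2 & x <= 1", id = "y1", source = "adaboost")
  r5 <- parse_rule("x <= 1 & y > 2", id = "y2", source = "random_forest")
  dd <- deduplicate_rules(ruleset(list(r1, r2, r3, r4, r5)))
  expect_length(dd$rules, 3)
  expect_setequal(dd$rules[[1]]$source, c("gradient_boosting", "random_forest"))
  expect_setequal(dd$rules[[3]]$source, c("adaboost", "random_forest"))
})

test_that("the 15 published rules round-trip through text and JSON", {
  rs <- published_ruleset()
  expect_length(rs$rules, 15)
  # Rule5 carries both sources, as printed
  expect_setequal(rs$rules[[5]]$source, c("gradient_boosting", "random_forest"))

  for (r in rs$rules) {
    back <- parse_rule(format_rule(r), id = r$id,
                       source = paste(r$source, collapse = "/"))
    expect_identical(unclass(back), unclass(r), label = r$id)
  }

  tsv <- tempfile(fileext = ".tsv")
  write_ruleset(rs, tsv)
  rs2 <- read_ruleset(tsv)
  expect_identical(lapply(rs$rules, unclass), lapply(rs2$rules, unclass))

  js <- tempfile(fileext = ".json")
  rules_to_json(rs, js)
  rs3 <- rules_from_json(js)
  # bit-exact numeric round trip
  expect_identical(lapply(rs$rules, unclass), lapply(rs3$rules, unclass))
})

test_that("canonicalization preserves rule semantics on boundary grids", {
  set.seed(42)
  for (i in 1:20) {
    nconds <- sample(2:4, 1)
    txt <- paste(sprintf("x %s %0.2f", sample(c("<=", ">"), nconds, TRUE),
                         stats::runif(nconds, -1, 1)), collapse = " & ")
    raw <- tryCatch(parse_rule(txt, canonical = FALSE), error = function(e) NULL)
    can <- tryCatch(canonicalize_rule(raw), error = function(e) NULL)
    if (is.null(can)) next        # contradictory draw
    thrs <- unlist(lapply(raw$conditions, function(cn)
      c(cn$threshold, cn$lower, cn$upper)))
    thrs <- thrs[is.finite(thrs)]
    grid <- sort(unique(c(thrs, thrs - 1e-9, thrs + 1e-9, -2, 2)))
    tb <- feature_table(data.frame(x = grid))
    expect_equal(evaluate_rule(can, tb), evaluate_rule(raw, tb), label = txt)
  }
})
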