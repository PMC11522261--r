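# a hand-built tree frame: root splits x at 5; left child splits x at 3
manual_tree <- function() {
  rulefusion:::new_tree_frame(
    id = 1:5,
    is_leaf = c(FALSE, FALSE, TRUE, TRUE, TRUE),
    feature = c("x", "x", NA, NA, NA),
    threshold = c(5, 3, NA, NA, NA),
    yes = c(2L, 4L, NA, NA, NA),
    no = c(3L, 5L, NA, NA, NA),
    pred = c(NA, NA, 1, 0, 1))
}

manual_ensemble <- function(frames, kind = c(x = "continuous")) {
  rulefusion:::new_tree_ensemble(frames, rep(1 / length(frames), length(frames)),
                                 "averaged", "random_forest", kind)
}

test_that("path extraction yields one canonical rule per non-root node", {
  ens <- manual_ensemble(list(manual_tree()))
  rs <- extract_rules(ens)
  expect_length(rs$rules, 4)              # 5 nodes minus root
  txts <- vapply(rs$rules, format_rule, character(1))
  # the depth-2 path x<=5 then x<=3 collapses to x<=3
  expect_true("x <= 3" %in% txts)
  expect_true("x <= 5" %in% txts)
  expect_true("x > 5" %in% txts)
  # the mixed path x<=5 & x>3 becomes an interval
  expect_true(any(grepl("\\(3,5\\]", txts)))
})

test_that("depth-1 and complete depth-2 trees give 2 and 6 rules", {
  stump <- rulefusion:::new_tree_frame(1:3, c(FALSE, TRUE, TRUE),
                                       c("x", NA, NA), c(1, NA, NA),
                                       c(2L, NA, NA), c(3L, NA, NA),
                                       c(NA, 0, 1))
  expect_length(extract_rules(manual_ensemble(list(stump)))$rules, 2)
  d2 <- rulefusion:::new_tree_frame(
    1:7, c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
    c("x", "y", "y", NA, NA, NA, NA), c(0, -1, 1, NA, NA, NA, NA),
    c(2L, 4L, 6L, NA, NA, NA, NA), c(3L, 5L, 7L, NA, NA, NA, NA),
    c(NA, NA, NA, 0, 1, 0, 1))
  expect_length(extract_rules(manual_ensemble(
    list(d2), kind = c(x = "continuous", y = "continuous")))$rules, 6)
})

test_that("splits on binary flags become equality conditions", {
  fr <- rulefusion:::new_tree_frame(1:3, c(FALSE, TRUE, TRUE),
                                    c("spiculated margin", NA, NA),
                                    c(0.5, NA, NA), c(2L, NA, NA),
                                    c(3L, NA, NA), c(NA, 0, 1))
  rs <- extract_rules(manual_ensemble(list(fr),
                                      kind = c("spiculated margin" = "binary")))
  txts <- sort(vapply(rs$rules, format_rule, character(1)))
  expect_equal(txts, c("spiculated margin", "spiculated margin = 0"))
})

test_that("fitted ensembles have the stated modes, weights and determinism", {
  tab <- generate_cohort(150, "published_model", seed = 2)
  cfg <- ensemble_config(gbdt = list(n_trees = 5), rf = list(n_trees = 10),
                         ada = list(n_trees = 4))
  ens <- fit_ensembles(tab, cfg, seed = 7)
  expect_equal(ens$random_forest$mode, "averaged")
  expect_equal(ens$random_forest$tree_weights, rep(0.1, 10))
  expect_equal(ens$gradient_boosting$mode, "boosted_weighted")
  expect_equal(ens$adaboost$mode, "boosted_weighted")
  expect_true(all(ens$adaboost$tree_weights > 0))

  ens2 <- fit_ensembles(tab, cfg, seed = 7)
  expect_identical(lapply(ens$gradient_boosting$trees, as.list),
                   lapply(ens2$gradient_boosting$trees, as.list))
  expect_identical(ens$random_forest$trees, ens2$random_forest$trees)
  expect_identical(ens$adaboost$trees, ens2$adaboost$trees)

  bad <- feature_table(data.frame(x = rnorm(10)), labels = rep(1L, 10))
  expect_error(fit_ensembles(bad, cfg, seed = 1), "both outcome classes")
})

test_that("boosting separates linearly separable toy data", {
  set.seed(1)
  x <- c(runif(40, -3, -1), runif(40, 1, 3))
  tab <- feature_table(data.frame(x = x, z = rnorm(80)),
                       labels = rep(c(0L, 1L), each = 40))
  ens <- fit_ensembles(tab, ensemble_config(gbdt = list(n_trees = 30),
                                            rf = list(n_trees = 20),
                                            ada = list(n_trees = 5)),
                       seed = 3)
  sc <- predict(ens$gradient_boosting, tab)
  expect_equal(as.integer(sc > 0), tab$labels)
})

test_that("support is boundary-inclusive and complementarity holds", {
  tab <- feature_table(data.frame(x = c(0, 1, 2, 3)))
  expect_equal(rule_support(parse_rule("x <= 1"), tab), 0.5)
  expect_equal(rule_support(parse_rule("x <= 99"), tab), 1.0)
  expect_equal(rule_support(parse_rule("x > 99"), tab), 0.0)
  expect_error(rule_support(parse_rule("x <= 1"),
                            feature_table(data.frame(x = numeric(0)))),
               "empty table")

  # left-support + right-support = parent-support at every internal node
  cohort <- generate_cohort(150, "published_model", seed = 5)
  ens <- fit_ensembles(cohort, ensemble_config(gbdt = list(n_trees = 3),
                                               rf = list(n_trees = 3),
                                               ada = list(n_trees = 3)),
                       seed = 5)
  for (m in names(ens)) {
    rs <- extract_rules(ens[[m]])
    ind <- rules_to_dataset(rs, cohort)
    ids <- colnames(ind)
    supp <- colMeans(ind)
    # structural check via the frames directly
    for (k in seq_along(ens[[m]]$trees)) {
      fr <- ens[[m]]$trees[[k]]
      tag <- sub("_t.*", "", ids[1])
      for (i in which(!fr$is_leaf)) {
        p_id <- sprintf("%s_t%d_n%d", tag, k, i)
        y_id <- sprintf("%s_t%d_n%d", tag, k, fr$yes[i])
        n_id <- sprintf("%s_t%d_n%d", tag, k, fr$no[i])
        if (!(y_id %in% ids && n_id %in% ids)) next
        parent <- if (i == 1L) 1.0 else supp[[p_id]]
        expect_equal(supp[[y_id]] + supp[[n_id]], parent,
                     tolerance = 1e-12)
      }
    }
    # rule count = total non-root node count
    expect_length(rs$rules,
                  sum(vapply(ens[[m]]$trees, nrow, integer(1))) -
                    length(ens[[m]]$trees))
  }
})

test_that("re-extraction from a fitted ensemble is bit-identical", {
  tab <- generate_cohort(100, "published_model", seed = 6)
  ens <- fit_ensembles(tab, ensemble_config(gbdt = list(n_trees = 3),
                                            rf = list(n_trees = 3),
                                            ada = list(n_trees = 2)),
                       seed = 6)
  a <- extract_rules(ens$adaboost)
  b <- extract_rules(ens$adaboost)
  expect_identical(lapply(a$rules, unclass), lapply(b$rules, unclass))
  expect_error(extract_rules(rulefusion:::new_tree_ensemble(
    list(), numeric(0), "averaged", "random_forest", c(x = "continuous"))),
    "empty ensemble")
})
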