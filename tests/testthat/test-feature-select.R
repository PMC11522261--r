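test_that("standardization is idempotent and flags constant columns", {
  tab <- feature_table(data.frame(x = c(1, 2, 3), k = c(5, 5, 5),
                                  f = c(0, 1, 1)))
  s1 <- scale_features(tab)
  expect_equal(mean(s1$data$x), 0)
  expect_equal(stats::sd(s1$data$x), 1)
  expect_equal(s1$data$k, c(5, 5, 5))          # constant passes through
  expect_equal(attr(s1, "constant_features"), "k")
  expect_equal(s1$data$f, c(0, 1, 1))          # binary untouched
  s2 <- scale_features(s1)
  expect_equal(s2$data, s1$data)
})

test_that("variance filter removes near-constant continuous features", {
  tab <- feature_table(data.frame(a = c(5, 5, 5), b = c(1, 2, 3)),
                       kind = c("continuous", "continuous"))
  rep <- variance_filter(tab, tol = 1e-8)
  expect_equal(rep$removed$feature, "a")
  expect_equal(rep$kept, "b")
  expect_error(variance_filter(tab, tol = Inf), "every feature")
})

test_that("Spearman pruning drops duplicates and monotone transforms", {
  set.seed(7)
  x <- rnorm(500)
  tab <- feature_table(data.frame(orig = x, copy = x, mono = exp(x),
                                  indep = rnorm(500)))
  rep <- correlation_prune(tab, cutoff = 0.9)
  # exp() is a strictly monotone transform: Spearman rho = 1 with orig
  expect_length(intersect(c("orig", "copy", "mono"), rep$kept), 1)
  expect_true("indep" %in% rep$kept)
  # two independent standard normals at n = 500 stay far below 0.9
  tab2 <- feature_table(data.frame(u = rnorm(500), v = rnorm(500)))
  expect_length(correlation_prune(tab2, 0.9)$kept, 2)
})

test_that("mRMR ranks by relevance first and penalizes redundancy", {
  set.seed(3)
  y <- rbinom(120, 1, 0.5)
  strong <- 2 * y + rnorm(120)
  weak <- 0.8 * y + rnorm(120)
  tab <- feature_table(data.frame(copy_of_label = y, strong = strong,
                                  strong_dup = strong, weak = weak,
                                  noise = rnorm(120)),
                       labels = y,
                       kind = c("binary", rep("continuous", 4)))
  rep <- mrmr_rank(tab, k = 5)
  expect_equal(rep$kept[1], "copy_of_label")
  # an exact duplicate of an already-selected feature is fully redundant
  # (score I(f;y) - I(f;f) < 0): independent informative features and even
  # noise must outrank it
  expect_lt(match("weak", rep$kept), match("strong_dup", rep$kept))
  expect_length(mrmr_rank(tab, k = 10)$kept, 5)   # k >= p returns all
  expect_error(mrmr_rank(tab, k = 0), "k must be")

  # redundancy weight 0 reduces to univariate MI ranking (brute force)
  rep0 <- mrmr_rank(tab, k = 5, redundancy_weight = 0)
  disc <- lapply(seq_len(5), function(j) {
    x <- tab$data[[j]]
    if (tab$kind[j] == "binary") as.integer(x) + 1L
    else rulefusion:::discretize_ef(x, 10)
  })
  mi <- vapply(disc, rulefusion:::mi_disc, numeric(1), b = y + 1L)
  expect_equal(rep0$kept, names(tab$data)[order(-mi)])
})

test_that("repeated LASSO stability selection tracks predictiveness", {
  set.seed(5)
  y <- rbinom(200, 1, 0.5)
  tab <- feature_table(data.frame(perfect = y,
                                  n1 = rnorm(200), n2 = rnorm(200),
                                  n3 = rnorm(200)),
                       labels = y,
                       kind = c("binary", rep("continuous", 3)))
  rep <- repeated_lasso_select(tab, n_iter = 20, seed = 1)
  expect_equal(unname(rep$scores["perfect"]), 1.0)
  expect_true(all(rep$scores[c("n1", "n2", "n3")] < 0.5))
  expect_equal(rep$kept[1], "perfect")

  # single iteration reproduces one penalized fit's support
  set.seed(9)
  r1 <- repeated_lasso_select(tab, n_iter = 1, seed = 42)
  set.seed(42)
  foldid <- rulefusion:::stratified_folds(y, 5)
  cv <- glmnet::cv.glmnet(as.matrix(tab$data), y, family = "binomial",
                          alpha = 1, foldid = foldid, standardize = TRUE)
  co <- as.matrix(stats::coef(cv, s = cv$lambda.1se))[-1, 1]
  expect_setequal(r1$kept, names(co)[co != 0])

  expect_error(repeated_lasso_select(
    feature_table(data.frame(x = rnorm(10)), labels = rep(1, 10)),
    n_iter = 1), "both outcome classes")
})

test_that("the two-phase pipeline chains reports deterministically", {
  tab <- generate_radiomics_table(n = 120, p = 80, n_blocks = 3,
                                  block_size = 3, seed = 4)
  sel1 <- select_features(tab, mrmr_k = 30, lasso_iters = 5, seed = 11)
  sel2 <- select_features(tab, mrmr_k = 30, lasso_iters = 5, seed = 11)
  expect_identical(sel1$selected, sel2$selected)
  # stages chain: each stage's input is the previous stage's kept set
  expect_true(all(sel1$correlation$kept %in% sel1$variance$kept))
  expect_true(all(sel1$mrmr$kept %in% sel1$correlation$kept))
  expect_lte(length(sel1$selected), 10)
})
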