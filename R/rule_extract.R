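#' @title Tree ensembles and rule extraction
#' @description
#' Three ensemble architectures supply candidate rules: gradient boosting
#' (weighted, sequentially correlated trees), a random forest (equal,
#' independent trees, averaged), and discrete (SAMME) AdaBoost (per-tree
#' log-odds weights). Every fitted tree is reduced to a uniform frame of
#' axis-aligned binary splits where the "yes" child satisfies
#' `feature <= threshold` and the "no" child `feature > threshold`; every
#' root-to-node path (interior and leaf) then becomes one candidate
#' conjunctive rule, canonical by construction because bounds are narrowed
#' along the path.
#' @name rule-extraction
NULL

# uniform tree frame: one row per node
# id, is_leaf, feature (chr), threshold, yes, no (row ids), pred (leaf value)
new_tree_frame <- function(id, is_leaf, feature, threshold, yes, no, pred) {
  data.frame(id = id, is_leaf = is_leaf, feature = feature,
             threshold = threshold, yes = yes, no = no, pred = pred,
             stringsAsFactors = FALSE)
}

new_tree_ensemble <- function(trees, tree_weights, mode, method_tag,
                              feature_kind, learner = NULL) {
  stopifnot(length(trees) == length(tree_weights),
            mode %in% c("boosted_weighted", "averaged"))
  if (mode == "averaged" &&
      any(abs(tree_weights - 1 / length(trees)) > 1e-12))
    stop("averaged ensembles must have uniform weights 1/M")
  structure(list(trees = trees, tree_weights = tree_weights, mode = mode,
                 M = length(trees), method_tag = method_tag,
                 feature_kind = feature_kind, learner = learner),
            class = "tree_ensemble")
}

#' @export
print.tree_ensemble <- function(x, ...) {
  cat(sprintf("tree_ensemble [%s]: %d trees, mode %s\n",
              x$method_tag, x$M, x$mode))
  invisible(x)
}

#' Ensemble hyperparameter configuration
#'
#' Defaults follow the study design: gradient boosting with 500 trees of
#' depth 5 and learning rate 0.1; a random forest with 500 trees and
#' minimum leaf size 1; discrete (SAMME) AdaBoost with 30 depth-5 trees.
#'
#' @param gbdt,rf,ada named lists overriding individual settings.
#' @return A nested list of hyperparameters.
#' @export
ensemble_config <- function(gbdt = list(), rf = list(), ada = list()) {
  d <- list(gbdt = list(n_trees = 500, max_depth = 5, learning_rate = 0.1),
            rf = list(n_trees = 500, min_node_size = 1),
            ada = list(n_trees = 30, max_depth = 5, min_leaf = 1))
  d$gbdt[names(gbdt)] <- gbdt
  d$rf[names(rf)] <- rf
  d$ada[names(ada)] <- ada
  d
}

xgb_to_frames <- function(model, feature_names) {
  dt <- as.data.frame(xgboost::xgb.model.dt.tree(model = model))
  lapply(split(dt, dt$Tree), function(tr) {
    tr <- tr[order(tr$Node), , drop = FALSE]
    idmap <- stats::setNames(seq_len(nrow(tr)), tr$ID)
    leaf <- tr$Feature == "Leaf"
    # xgboost's yes-branch is strict "x < t" evaluated in float32; shifting
    # t down by half a float32 ulp makes the "<= / >" frame route every
    # value (including ones whose float32 image equals t) identically
    ulp <- ifelse(tr$Split == 0, 1e-38, 2^(floor(log2(abs(tr$Split))) - 23))
    thr <- tr$Split - ulp / 2
    new_tree_frame(seq_len(nrow(tr)), leaf,
                   ifelse(leaf, NA_character_, tr$Feature),
                   ifelse(leaf, NA_real_, thr),
                   ifelse(leaf, NA_integer_, unname(idmap[tr$Yes])),
                   ifelse(leaf, NA_integer_, unname(idmap[tr$No])),
                   ifelse(leaf, tr$Gain, NA_real_))
  })
}

rf_to_frame <- function(rf, k, feature_names) {
  m <- randomForest::getTree(rf, k, labelVar = FALSE)
  leaf <- m[, "status"] == -1
  feats <- feature_names[pmax(m[, "split var"], 1L)]  # leaves carry index 0
  new_tree_frame(seq_len(nrow(m)), leaf,
                 ifelse(leaf, NA_character_, feats),
                 ifelse(leaf, NA_real_, m[, "split point"]),
                 ifelse(leaf, NA_integer_, m[, "left daughter"]),
                 ifelse(leaf, NA_integer_, m[, "right daughter"]),
                 # prediction codes are 1/2 for factor levels "0"/"1"
                 ifelse(leaf, m[, "prediction"] - 1, NA_real_))
}

rpart_to_frame <- function(fit) {
  fr <- fit$frame
  nn <- as.integer(rownames(fr))
  idmap <- stats::setNames(seq_along(nn), nn)
  internal <- fr$var != "<leaf>"
  # with maxcompete = 0 and maxsurrogate = 0 the splits matrix holds exactly
  # one row per internal node, in frame order
  sp <- fit$splits
  thr <- rep(NA_real_, nrow(fr)); yes <- no <- rep(NA_integer_, nrow(fr))
  si <- 1L
  for (i in which(internal)) {
    cut <- sp[si, "index"]; ncat <- sp[si, "ncat"]; si <- si + 1L
    left <- idmap[as.character(2L * nn[i])]
    right <- idmap[as.character(2L * nn[i] + 1L)]
    thr[i] <- cut
    if (ncat < 0) {         # left child: x < cut  (cut is a data midpoint)
      yes[i] <- left; no[i] <- right
    } else {                # left child: x >= cut
      yes[i] <- right; no[i] <- left
    }
  }
  pred <- ifelse(internal, NA_real_, fr$yval - 1)  # class codes 1/2 -> 0/1
  new_tree_frame(seq_len(nrow(fr)), !internal, ifelse(internal, as.character(fr$var), NA),
                 thr, yes, no, pred)
}

fit_gbdt_ensemble <- function(table, cfg, seed) {
  x <- as.matrix(table$data)
  dm <- xgboost::xgb.DMatrix(x, label = table$labels)
  params <- list(objective = "binary:logistic", max_depth = cfg$max_depth,
                 eta = cfg$learning_rate, nthread = 1, seed = seed)
  bst <- xgboost::xgb.train(params = params, data = dm,
                            nrounds = cfg$n_trees, verbose = 0)
  trees <- xgb_to_frames(bst, colnames(x))
  new_tree_ensemble(trees, rep(cfg$learning_rate, length(trees)),
                    "boosted_weighted", "gradient_boosting",
                    table$kind, learner = bst)
}

fit_rf_ensemble <- function(table, cfg, seed) {
  set.seed(seed)
  x <- table$data
  names(x) <- paste0("f", seq_along(x))      # randomForest mangles raw names
  y <- factor(table$labels, levels = c(0, 1))
  rf <- randomForest::randomForest(x = x, y = y, ntree = cfg$n_trees,
                                   nodesize = cfg$min_node_size)
  trees <- lapply(seq_len(cfg$n_trees), rf_to_frame, rf = rf,
                  feature_names = names(table$data))
  new_tree_ensemble(trees, rep(1 / cfg$n_trees, cfg$n_trees), "averaged",
                    "random_forest", table$kind, learner = rf)
}

fit_ada_ensemble <- function(table, cfg, seed) {
  set.seed(seed)
  df <- table$data
  names(df) <- make.names(names(df))          # rpart needs syntactic names
  name_map <- stats::setNames(names(table$data), names(df))
  df$.y <- factor(table$labels, levels = c(0, 1))
  n <- nrow(df)
  w <- rep(1 / n, n)
  trees <- list(); alphas <- numeric(0)
  ctrl <- rpart::rpart.control(maxdepth = cfg$max_depth, cp = 0,
                               minsplit = 2 * cfg$min_leaf,
                               minbucket = cfg$min_leaf, xval = 0,
                               maxcompete = 0, maxsurrogate = 0,
                               usesurrogate = 0)
  for (m in seq_len(cfg$n_trees)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                        control = ctrl)
    pred <- stats::predict(fit, type = "class")
    miss <- pred != df$.y
    err <- sum(w[miss]) / sum(w)
    err <- min(max(err, 1e-10), 1 - 1e-10)
    alpha <- log((1 - err) / err)              # SAMME with K = 2 classes
    if (alpha <= 0 && m > 1) break
    fr <- rpart_to_frame(fit)
    fr$feature <- unname(name_map[fr$feature])
    trees[[length(trees) + 1L]] <- fr
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * as.numeric(miss))
    w <- w / sum(w)
  }
  new_tree_ensemble(trees, alphas, "boosted_weighted", "adaboost", table$kind)
}

#' Fit the three rule-generating ensembles
#'
#' @param table a labeled [feature_table()] (both classes present).
#' @param config an [ensemble_config()].
#' @param seed RNG seed; the same seed reproduces identical tree structures.
#' @return Named list of `tree_ensemble` objects: `gradient_boosting`
#'   (boosted, per-tree weight = learning rate), `random_forest` (averaged,
#'   uniform weights 1/M), `adaboost` (boosted, SAMME log-odds weights).
#' @export
fit_ensembles <- function(table, config = ensemble_config(), seed = 1) {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(table$labels) || length(unique(table$labels)) < 2)
    stop("ensemble fitting requires both outcome classes")
  list(gradient_boosting = fit_gbdt_ensemble(table, config$gbdt, seed),
       random_forest = fit_rf_ensemble(table, config$rf, seed),
       adaboost = fit_ada_ensemble(table, config$ada, seed))
}

# turn accumulated path bounds into a canonical condition list
bounds_to_conditions <- function(lo, up, feature_kind) {
  lo <- unlist(lo) %||% numeric(0)
  up <- unlist(up) %||% numeric(0)
  feats <- sort(union(names(lo)[is.finite(lo)], names(up)[is.finite(up)]))
  lapply(feats, function(f) {
    l <- if (f %in% names(lo)) lo[[f]] else -Inf
    u <- if (f %in% names(up)) up[[f]] else Inf
    if (identical(unname(feature_kind[f]), "binary")) {
      # a split on a 0/1 flag means equality on one side
      if (is.finite(u) && u < 1 && !is.finite(l)) return(new_condition(f, "FLAG_EQ", value = 0L))
      if (is.finite(l) && l >= 0 && !is.finite(u)) return(new_condition(f, "FLAG_EQ", value = 1L))
    }
    if (is.finite(l) && is.finite(u)) new_condition(f, "INTERVAL", lower = l, upper = u)
    else if (is.finite(u)) new_condition(f, "LE", threshold = u)
    else new_condition(f, "GT", threshold = l)
  })
}

extract_tree_rules <- function(frame, feature_kind, tag, tree_idx, weight,
                               min_depth = 1) {
  rules <- list()
  walk <- function(node, lo, up, depth) {
    row <- frame[node, ]
    if (node != 1L && depth >= min_depth) {
      conds <- bounds_to_conditions(lo, up, feature_kind)
      r <- new_rule(sprintf("%s_t%d_n%d", tag, tree_idx, node), conds,
                    source = tag, weight = weight, tree = tree_idx)
      attr(r, "canonical") <- TRUE
      rules[[length(rules) + 1L]] <<- r
    }
    if (!row$is_leaf) {
      f <- row$feature; t <- row$threshold
      lo_y <- lo; up_y <- up
      up_y[[f]] <- min(t, if (f %in% names(up)) up[[f]] else Inf)
      walk(row$yes, lo_y, up_y, depth + 1L)
      lo_n <- lo; up_n <- up
      lo_n[[f]] <- max(t, if (f %in% names(lo)) lo[[f]] else -Inf)
      walk(row$no, lo_n, up_n, depth + 1L)
    }
  }
  walk(1L, list(), list(), 0L)
  rules
}

#' Extract candidate rules from a fitted ensemble
#'
#' One candidate rule per non-root node (interior nodes included, as in
#' standard RuleFit practice): its conditions are the split decisions along
#' the path from the root, already canonical (repeated splits on one
#' feature collapse into a single bound or interval; splits on binary flags
#' become equality conditions). Each rule carries the owning tree's weight
#' and the ensemble's method tag as provenance.
#'
#' @param ensemble a fitted `tree_ensemble`.
#' @param min_depth minimum path length for a candidate rule (default 1 =
#'   every non-root node).
#' @return A [ruleset()].
#' @export
extract_rules <- function(ensemble, min_depth = 1) {
  stopifnot(inherits(ensemble, "tree_ensemble"))
  if (ensemble$M == 0) stop("empty ensemble")
  tag <- switch(ensemble$method_tag, gradient_boosting = "gb",
                random_forest = "rf", adaboost = "ada", ensemble$method_tag)
  rules <- list()
  for (k in seq_len(ensemble$M)) {
    rules <- c(rules, extract_tree_rules(ensemble$trees[[k]],
                                         ensemble$feature_kind,
                                         ensemble$method_tag, k,
                                         ensemble$tree_weights[k],
                                         min_depth = min_depth))
  }
  if (!length(rules)) stop("ensemble produced no rules (all trees are stumps?)")
  # method tag is the source; ids get a compact prefix
  for (i in seq_along(rules)) rules[[i]]$id <- sub(ensemble$method_tag, tag, rules[[i]]$id, fixed = TRUE)
  ruleset(rules, feature_vocabulary = names(ensemble$feature_kind))
}

# route samples through one tree frame, returning leaf predictions
predict_tree_frame <- function(frame, data) {
  node <- rep(1L, nrow(data))
  repeat {
    leaf <- frame$is_leaf[node]
    if (all(leaf)) break
    act <- which(!leaf)
    rows <- node[act]
    f <- frame$feature[rows]; t <- frame$threshold[rows]
    xv <- vapply(seq_along(act), function(i) data[[f[i]]][act[i]], numeric(1))
    node[act] <- ifelse(xv <= t, frame$yes[rows], frame$no[rows])
  }
  frame$pred[node]
}

#' Predict from a fitted tree ensemble
#'
#' @param object a `tree_ensemble`.
#' @param table a [feature_table()].
#' @param ... unused.
#' @return Numeric score per sample: boosted margin (gradient boosting),
#'   mean vote (random forest), or sign-vote margin (AdaBoost).
#' @export
predict.tree_ensemble <- function(object, table, ...) {
  preds <- vapply(object$trees, predict_tree_frame, numeric(nrow(table$data)),
                  data = table$data)
  preds <- matrix(preds, nrow = nrow(table$data))
  switch(object$method_tag,
         gradient_boosting = rowSums(preds),                 # logit margin
         random_forest = rowMeans(preds),                    # vote fraction
         adaboost = as.vector(preds %*% object$tree_weights) /
           sum(object$tree_weights))
}
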