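#' @title Rule fusion and selection cascade
#' @description
#' The cascade that reduces the raw candidate rules to the final diagnostic
#' set: (1) per-method filtering — RuleFit importance > 0.1 for the
#' gradient-boosting and random-forest rules, absolute phi correlation with
#' the outcome > 0.4 for the AdaBoost rules; (2) merging the three
#' rule-indicator datasets with duplicate rules collapsed; (3) an
#' L1-penalized logistic fit on the merged indicators keeping rules with
#' nonzero weight; (4) an exact-Shapley contribution filter on that model,
#' keeping rules whose mean-normalized mean absolute SHAP value is at
#' least 0.5. Every stage emits a trace recording the statistic for every input
#' rule.
#' @name rule-selection
NULL

new_selection_trace <- function(stage, rules_in, rules_out, statistic, threshold) {
  stopifnot(all(rules_out %in% rules_in))
  structure(list(stage = stage, rules_in = rules_in, rules_out = rules_out,
                 statistic = statistic, threshold = threshold),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf("selection_trace [%s]: %d -> %d rules (threshold %g)\n",
              x$stage, length(x$rules_in), length(x$rules_out), x$threshold))
  invisible(x)
}

#' Importance filter
#'
#' Keeps rules whose RuleFit importance strictly exceeds `thr`.
#'
#' @param rs the [ruleset()] the model was fitted over.
#' @param model the `sparse_linear_model` from [fit_sparse()].
#' @param thr importance threshold (default 0.1).
#' @return A `selection_trace`.
#' @export
importance_filter <- function(rs, model, thr = 0.1) {
  stopifnot(inherits(rs, "ruleset"), inherits(model, "sparse_linear_model"))
  ids <- rule_ids(rs)
  imp <- model$importances[ids]
  if (anyNA(imp)) stop("model does not cover every rule in the set")
  new_selection_trace("importance_filter", ids, ids[imp > thr], imp, thr)
}

# phi coefficient: Pearson correlation of two 0/1 vectors
phi_coefficient <- function(ind, labels) {
  if (stats::sd(ind) == 0 || stats::sd(labels) == 0) return(0)
  stats::cor(ind, labels)
}

#' Outcome-correlation (phi) filter
#'
#' Keeps rules whose absolute phi coefficient (Pearson correlation between
#' the 0/1 rule indicator and the 0/1 outcome) strictly exceeds `thr`.
#' Constant indicator columns get correlation 0 (with a message).
#'
#' @param indicators samples x rules 0/1 matrix.
#' @param labels 0/1 outcome.
#' @param thr correlation threshold (default 0.4).
#' @return A `selection_trace`.
#' @export
outcome_correlation_filter <- function(indicators, labels, thr = 0.4) {
  stopifnot(is.matrix(indicators), nrow(indicators) == length(labels))
  const <- apply(indicators, 2, function(v) stats::sd(v) == 0)
  if (any(const))
    message(sum(const), " constant rule indicator(s); correlation set to 0")
  phi <- vapply(seq_len(ncol(indicators)),
                function(j) phi_coefficient(indicators[, j], labels), numeric(1))
  names(phi) <- colnames(indicators)
  new_selection_trace("outcome_correlation_filter", colnames(indicators),
                      colnames(indicators)[abs(phi) > thr], phi, thr)
}

#' Merge rule-indicator datasets
#'
#' Column-concatenates per-method indicator matrices over the same samples
#' and collapses duplicate rules (identical canonical condition sets) into
#' one column, with provenance as the union of sources.
#'
#' @param rulesets list of [ruleset()]s.
#' @param indicator_list list of matching indicator matrices (same sample
#'   order and count).
#' @return List with `ruleset` (deduplicated) and `indicators`.
#' @export
merge_rule_datasets <- function(rulesets, indicator_list) {
  stopifnot(length(rulesets) == length(indicator_list))
  keep <- lengths(lapply(rulesets, `[[`, "rules")) > 0
  rulesets <- rulesets[keep]; indicator_list <- indicator_list[keep]
  if (!length(rulesets)) stop("nothing to merge")
  ns <- vapply(indicator_list, nrow, integer(1))
  if (length(unique(ns)) != 1) stop("sample mismatch between rule datasets")
  rn <- lapply(indicator_list, rownames)
  if (length(unique(rn)) != 1) stop("sample mismatch between rule datasets")
  all_rules <- do.call(c, lapply(rulesets, `[[`, "rules"))
  ind <- do.call(cbind, indicator_list)
  colnames(ind) <- vapply(all_rules, `[[`, character(1), "id")
  sig <- vapply(all_rules, rule_signature, character(1))
  first <- !duplicated(sig)
  merged_rules <- all_rules[first]
  names(merged_rules) <- sig[first]
  for (i in which(!first)) {
    merged_rules[[sig[i]]]$source <-
      unique(c(merged_rules[[sig[i]]]$source, all_rules[[i]]$source))
  }
  merged_rules <- unname(merged_rules)
  vocab <- sort(unique(unlist(lapply(rulesets, `[[`, "feature_vocabulary"))))
  rs <- ruleset(merged_rules, feature_vocabulary = vocab)
  list(ruleset = rs, indicators = ind[, rule_ids(rs), drop = FALSE])
}

#' Collapse rules with identical training indicators
#'
#' Rules whose 0/1 indicator columns agree on every training sample are
#' indistinguishable for all downstream fitting; each such group is
#' represented by its simplest member (fewest conditions, ties broken by
#' id), with provenance as the union of the group's sources. Typically this
#' absorbs deep tree-path rules whose extra conditions cut nothing.
#'
#' @param rs a [ruleset()].
#' @param indicators matching indicator matrix (samples x rules).
#' @return List with the collapsed `ruleset` and `indicators`.
#' @export
collapse_identical_indicators <- function(rs, indicators) {
  stopifnot(inherits(rs, "ruleset"), ncol(indicators) == length(rs$rules))
  key <- apply(indicators, 2, paste, collapse = "")
  nconds <- lengths(lapply(rs$rules, `[[`, "conditions"))
  ids <- rule_ids(rs)
  keep <- unlist(lapply(split(seq_along(key), key), function(g) {
    g[order(nconds[g], ids[g])][1]
  }), use.names = FALSE)
  keep <- sort(keep)
  rules <- rs$rules[keep]
  for (j in seq_along(keep)) {
    grp <- which(key == key[keep[j]])
    rules[[j]]$source <- unique(unlist(lapply(rs$rules[grp], `[[`, "source")))
  }
  list(ruleset = ruleset(rules, feature_vocabulary = rs$feature_vocabulary),
       indicators = indicators[, keep, drop = FALSE])
}

#' Merged-LASSO rule subset
#'
#' L1-penalized logistic fit on the merged rule indicators only; rules with
#' a nonzero weight at the cross-validated penalty survive.
#'
#' @param indicators samples x rules 0/1 matrix.
#' @param labels 0/1 outcome (both classes present).
#' @param lambda_rule,nfolds,seed,lambda passed to [fit_sparse()].
#' @return List with `trace` (statistic = |weight|) and `model` (the
#'   `sparse_linear_model`).
#' @export
lasso_select_rules <- function(indicators, labels, lambda_rule = "min",
                               nfolds = 5, seed = NULL, lambda = NULL) {
  design <- indicators
  attr(design, "term_kind") <- rep("rule", ncol(indicators))
  attr(design, "supports") <- colMeans(indicators)
  attr(design, "term_sd") <- apply(indicators, 2, stats::sd)
  model <- fit_sparse(design, labels, lambda_rule = lambda_rule,
                      nfolds = nfolds, seed = seed, lambda = lambda)
  w <- model$weights
  trace <- new_selection_trace("lasso_select", colnames(indicators),
                               names(w)[w != 0], abs(w), 0)
  list(trace = trace, model = model)
}

#' Exact Shapley values of an additive (linear-in-indicators) model
#'
#' For a linear model the Shapley value of term `j` on sample `i` is
#' closed-form: \eqn{\phi_{ij} = w_j (x_{ij} - \bar x_j)}, and the
#' per-sample attributions satisfy
#' \eqn{\sum_j \phi_{ij} = f(x_i) - \overline{f(x)}}.
#'
#' @param weights named coefficient vector (no intercept).
#' @param x matrix whose columns match `names(weights)`.
#' @return samples x terms matrix of Shapley values on the linear-predictor
#'   scale.
#' @export
linear_shap <- function(weights, x) {
  x <- as.matrix(x)[, names(weights), drop = FALSE]
  phi <- sweep(sweep(x, 2, colMeans(x)), 2, weights, `*`)
  colnames(phi) <- names(weights)
  phi
}

#' SHAP contribution filter
#'
#' Computes each rule's mean absolute Shapley value in the fitted sparse
#' model (exact, additive-model formula), rescales the contributions to a
#' dimensionless scale by dividing by their mean, and keeps rules with
#' normalized contribution at least `thr` (so the threshold reads "at
#' least half the average contribution"). Both raw and normalized values
#' are recorded.
#'
#' @param model a fitted `sparse_linear_model` (e.g. from
#'   [lasso_select_rules()]).
#' @param indicators the matrix the model was fitted on.
#' @param thr threshold on the normalized contribution (default 0.5,
#'   inclusive).
#' @return A `selection_trace` (statistic = normalized contribution; raw
#'   contributions in the `raw` element).
#' @export
shap_filter <- function(model, indicators, thr = 0.5) {
  stopifnot(inherits(model, "sparse_linear_model"))
  if (is.null(model$weights)) stop("unfitted model")
  phi <- linear_shap(model$weights, indicators)
  raw <- colMeans(abs(phi))
  m <- mean(raw)
  norm <- if (m > 0) raw / m else raw
  tr <- new_selection_trace("shap_filter", colnames(indicators),
                            colnames(indicators)[norm >= thr], norm, thr)
  tr$raw <- raw
  tr
}

#' The full fusion-and-selection cascade
#'
#' Runs per-method filtering, dataset merge, merged LASSO, and the SHAP
#' filter over the three fitted ensembles, returning the final rule set and
#' a full audit trail.
#'
#' @param ensembles list from [fit_ensembles()].
#' @param table the labeled training [feature_table()].
#' @param importance_thr,phi_thr,shap_thr stage thresholds (defaults 0.1,
#'   0.4, 0.5).
#' @param max_rules RuleFit rule budget per method (default 80).
#' @param apply_both_filters apply both the importance and phi filters to
#'   every source (default `FALSE`: importance for gradient boosting and
#'   random forest, phi for AdaBoost).
#' @param lambda_rule,nfolds,seed passed to the penalized fits.
#' @return A `rule_cascade` object: `ruleset` (final rules), `indicators`
#'   (their training indicators), `traces` (per-stage), `counts`
#'   (per-stage rule counts), and the intermediate models.
#' @export
fuse_and_select <- function(ensembles, table, importance_thr = 0.1,
                            phi_thr = 0.4, shap_thr = 0.5, max_rules = 80,
                            apply_both_filters = FALSE,
                            lambda_rule = "min", nfolds = 5, seed = NULL) {
  stopifnot(inherits(table, "feature_table"))
  traces <- list()
  counts <- list()
  per_method <- list()
  for (method in c("gradient_boosting", "random_forest")) {
    fu <- rulefit_fuse(ensembles[[method]], table, max_rules = max_rules,
                       lambda_rule = lambda_rule, nfolds = nfolds, seed = seed)
    tr <- importance_filter(fu$ruleset, fu$model, importance_thr)
    kept <- fu$ruleset$rules[rule_ids(fu$ruleset) %in% tr$rules_out]
    rs <- if (length(kept)) ruleset(kept, fu$ruleset$feature_vocabulary) else
      ruleset(list(), fu$ruleset$feature_vocabulary)
    ind <- fu$design[, tr$rules_out, drop = FALSE]
    if (apply_both_filters && length(tr$rules_out)) {
      tr2 <- outcome_correlation_filter(ind, table$labels, phi_thr)
      traces[[paste0(method, "_phi")]] <- tr2
      rs <- ruleset(rs$rules[rule_ids(rs) %in% tr2$rules_out],
                    rs$feature_vocabulary)
      ind <- ind[, tr2$rules_out, drop = FALSE]
    }
    traces[[paste0(method, "_importance")]] <- tr
    counts[[method]] <- c(raw = length(fu$ruleset), kept = length(rs$rules))
    rownames(ind) <- table$sample_ids
    per_method[[method]] <- list(ruleset = rs, indicators = ind, fuse = fu)
  }
  # AdaBoost rules: no sparse pre-fit, outcome-correlation filter instead
  rs_ada <- deduplicate_rules(extract_rules(ensembles$adaboost))
  ind_ada <- rules_to_dataset(rs_ada, table)
  tr_ada <- outcome_correlation_filter(ind_ada, table$labels, phi_thr)
  if (apply_both_filters) {
    # importance needs a sparse fit over the AdaBoost rules
    fu_ada <- local({
      design <- ind_ada
      attr(design, "term_kind") <- rep("rule", ncol(ind_ada))
      attr(design, "supports") <- colMeans(ind_ada)
      attr(design, "term_sd") <- apply(ind_ada, 2, stats::sd)
      fit_sparse(design, table$labels, lambda_rule = lambda_rule,
                 nfolds = nfolds, seed = seed)
    })
    tr_imp <- importance_filter(rs_ada, fu_ada, importance_thr)
    traces$adaboost_importance <- tr_imp
    keep_ids <- intersect(tr_ada$rules_out, tr_imp$rules_out)
  } else {
    keep_ids <- tr_ada$rules_out
  }
  traces$adaboost_phi <- tr_ada
  rs_ada_kept <- ruleset(rs_ada$rules[rule_ids(rs_ada) %in% keep_ids],
                         rs_ada$feature_vocabulary)
  counts$adaboost <- c(raw = length(rs_ada), kept = length(rs_ada_kept$rules))

  merged <- merge_rule_datasets(
    list(per_method$gradient_boosting$ruleset, per_method$random_forest$ruleset,
         rs_ada_kept),
    list(per_method$gradient_boosting$indicators,
         per_method$random_forest$indicators,
         ind_ada[, keep_ids, drop = FALSE]))
  merged <- collapse_identical_indicators(merged$ruleset, merged$indicators)
  counts$merged <- c(rules = length(merged$ruleset))

  las <- lasso_select_rules(merged$indicators, table$labels,
                            lambda_rule = lambda_rule, nfolds = nfolds,
                            seed = seed)
  traces$lasso <- las$trace
  if (!length(las$trace$rules_out))
    stop("merged LASSO selected no rules; inspect the traces")
  ind_l <- merged$indicators[, las$trace$rules_out, drop = FALSE]
  counts$lasso <- c(kept = ncol(ind_l))

  shap_model <- las$model
  shap_model$weights <- shap_model$weights[las$trace$rules_out]
  tr_shap <- shap_filter(shap_model, ind_l, shap_thr)
  traces$shap <- tr_shap
  counts$shap <- c(kept = length(tr_shap$rules_out))

  final <- ruleset(merged$ruleset$rules[rule_ids(merged$ruleset) %in% tr_shap$rules_out],
                   merged$ruleset$feature_vocabulary)
  structure(list(ruleset = final,
                 indicators = merged$indicators[, rule_ids(final), drop = FALSE],
                 traces = traces, counts = counts,
                 merged = merged, lasso_model = las$model),
            class = "rule_cascade")
}

#' @export
print.rule_cascade <- function(x, ...) {
  cat("rule fusion cascade\n")
  for (nm in names(x$counts))
    cat(sprintf("  %-18s %s\n", nm,
                paste(names(x$counts[[nm]]), x$counts[[nm]],
                      sep = "=", collapse = ", ")))
  cat(sprintf("final: %d rules\n", length(x$ruleset$rules)))
  invisible(x)
}

#' Flatten cascade traces to a data.frame
#'
#' One row per rule per stage, for audit files.
#'
#' @param cascade a `rule_cascade`.
#' @return data.frame with stage, rule id, statistic, threshold, kept flag.
#' @export
cascade_trace_table <- function(cascade) {
  do.call(rbind, lapply(names(cascade$traces), function(nm) {
    tr <- cascade$traces[[nm]]
    data.frame(stage = nm, rule = tr$rules_in,
               statistic = unname(tr$statistic[tr$rules_in]),
               threshold = tr$threshold,
               kept = tr$rules_in %in% tr$rules_out)
  }))
}
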