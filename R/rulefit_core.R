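#' @title RuleFit sparse linear fusion
#' @description
#' Rule indicators and (winsorized, standardized) linear feature terms are
#' jointly entered into an L1-penalized logistic model
#' \deqn{\hat f(x) = \hat\beta_0 + \sum_k \hat\alpha_k r_k(x) +
#'   \sum_j \hat\beta_j l_j(x_j),}
#' with the penalty \eqn{\lambda (\sum_k |\alpha_k| + \sum_j |\beta_j|)}
#' driving most weights to exactly zero. Term importance follows the
#' original RuleFit definition: coefficient magnitude times the term's
#' standard deviation, which for a 0/1 rule with support \eqn{s_k} is
#' \eqn{I_k = |\hat\alpha_k| \sqrt{s_k (1 - s_k)}}.
#' @name rulefit
NULL

#' Assemble the RuleFit design matrix
#'
#' Columns are the rule indicators followed by one linear term per
#' feature: continuous features are winsorized at the `winsor` quantiles
#' and standardized; binary flags pass through as 0/1.
#'
#' @param rs a [ruleset()] (may be empty via `NULL` to use linear terms only).
#' @param table a [feature_table()].
#' @param winsor two quantiles for linear-term trimming (default
#'   `c(0.025, 0.975)`).
#' @param linear_features features to enter linearly; default all table
#'   columns.
#' @return A numeric matrix with attributes `term_kind`
#'   (`"rule"`/`"linear"`), `supports` (rule supports, NA for linear terms)
#'   and `term_sd` (standard deviation of each column).
#' @export
assemble_design <- function(rs, table, winsor = c(0.025, 0.975),
                            linear_features = names(table$data)) {
  stopifnot(inherits(table, "feature_table"), winsor[1] < winsor[2])
  blocks <- list()
  kind <- character(0)
  if (!is.null(rs) && length(rs$rules)) {
    ind <- rules_to_dataset(rs, table)
    blocks$rules <- ind
    kind <- c(kind, rep("rule", ncol(ind)))
  }
  if (length(linear_features)) {
    lin <- vapply(linear_features, function(nm) {
      x <- table$data[[nm]]
      if (table$kind[nm] == "binary") return(as.numeric(x))
      q <- stats::quantile(x, winsor, names = FALSE, na.rm = TRUE)
      x <- pmin(pmax(x, q[1]), q[2])
      s <- stats::sd(x)
      if (is.na(s) || s == 0) x - mean(x) else (x - mean(x)) / s
    }, numeric(nrow(table$data)))
    colnames(lin) <- linear_features
    blocks$linear <- lin
    kind <- c(kind, rep("linear", length(linear_features)))
  }
  design <- do.call(cbind, blocks)
  if (is.null(design) || ncol(design) == 0) stop("empty design")
  sds <- apply(design, 2, stats::sd)
  if (all(sds == 0)) stop("degenerate design: every column is constant")
  attr(design, "term_kind") <- kind
  attr(design, "supports") <- ifelse(kind == "rule", colMeans(design), NA_real_)
  attr(design, "term_sd") <- sds
  design
}

#' Fit the sparse (L1-penalized logistic) linear model
#'
#' Fits the whole lambda path with `glmnet`, selects lambda by stratified
#' cross-validated binomial deviance, and stores the
#' coefficients at the selected penalty. The intercept is unpenalized, so
#' at very large lambda the model collapses to the log-odds of the
#' prevalence.
#'
#' @param design matrix from [assemble_design()] (or any numeric matrix).
#' @param labels 0/1 outcome.
#' @param lambda_rule `"min"` (default, the cross-validation minimum, as in
#'   the reference RuleFit implementation) or `"1se"`.
#' @param nfolds cross-validation folds.
#' @param seed optional RNG seed for the fold assignment.
#' @param lambda optional fixed lambda (skips cross-validation).
#' @return A `sparse_linear_model`: intercept, per-term `weights`, selected
#'   `lambda`, term `kind`, `supports`, `term_sd`, `importances`, and the
#'   underlying `glmnet` path fit.
#' @export
fit_sparse <- function(design, labels, lambda_rule = c("min", "1se"),
                       nfolds = 5, seed = NULL, lambda = NULL) {
  lambda_rule <- match.arg(lambda_rule)
  y <- as.integer(labels)
  if (length(unique(y)) < 2) stop("labels must contain both classes")
  if (!is.null(seed)) set.seed(seed)
  kind <- attr(design, "term_kind") %||% rep("rule", ncol(design))
  supports <- attr(design, "supports") %||%
    ifelse(kind == "rule", colMeans(design), NA_real_)
  sds <- attr(design, "term_sd") %||% apply(design, 2, stats::sd)
  x <- as.matrix(design)
  pad <- ncol(x) == 1                     # glmnet requires >= 2 columns
  if (pad) x <- cbind(x, `..pad` = 0)
  if (is.null(lambda)) {
    foldid <- stratified_folds(y, nfolds)
    cv <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = 1,
                            foldid = foldid, standardize = FALSE,
                            type.measure = "deviance")
    lam <- if (lambda_rule == "1se") cv$lambda.1se else cv$lambda.min
    path <- cv$glmnet.fit
  } else {
    path <- glmnet::glmnet(x, y, family = "binomial", alpha = 1,
                           standardize = FALSE)
    lam <- lambda
    cv <- NULL
  }
  co <- as.matrix(stats::coef(path, s = lam, exact = FALSE))
  if (pad) co <- co[rownames(co) != "..pad", , drop = FALSE]
  model <- structure(
    list(intercept = co[1, 1],
         weights = stats::setNames(co[-1, 1], setdiff(colnames(x), "..pad")),
         lambda = lam, kind = kind, supports = supports, term_sd = sds,
         loss = "binomial_deviance", path = path, cv = cv),
    class = "sparse_linear_model")
  model$importances <- rule_importance(model)
  model
}

#' @export
print.sparse_linear_model <- function(x, ...) {
  nz <- sum(x$weights != 0)
  cat(sprintf("sparse_linear_model: %d/%d nonzero terms at lambda = %.5g\n",
              nz, length(x$weights), x$lambda))
  invisible(x)
}

#' RuleFit term importances
#'
#' Rule terms: \eqn{I_k = |\hat\alpha_k| \sqrt{s_k (1-s_k)}} where
#' \eqn{s_k} is the rule support; linear terms:
#' \eqn{I_j = |\hat\beta_j| \, sd(l_j)}.
#'
#' @param model a fitted `sparse_linear_model` with supports.
#' @return Named numeric vector of importances, invariant to term order
#'   and renaming.
#' @export
rule_importance <- function(model) {
  stopifnot(inherits(model, "sparse_linear_model"))
  if (is.null(model$supports)) stop("model lacks rule supports")
  stats::setNames(
    ifelse(model$kind == "rule",
           abs(model$weights) * sqrt(pmax(model$supports * (1 - model$supports), 0)),
           abs(model$weights) * model$term_sd),
    names(model$weights))
}

#' Truncate a candidate rule set to a budget
#'
#' RuleFit-style: trees are consumed in training order and all rules of a
#' tree are taken until the budget is filled, so for boosted ensembles the
#' earliest (largest-step) trees contribute first.
#'
#' @param rs a [ruleset()] whose rules carry tree indices.
#' @param max_rules rule budget (default 80).
#' @return A [ruleset()] with at most `max_rules` rules.
#' @export
truncate_rules <- function(rs, max_rules = 80) {
  stopifnot(inherits(rs, "ruleset"))
  if (length(rs$rules) <= max_rules) return(rs)
  trees <- vapply(rs$rules, function(r) r$tree %||% NA_integer_, integer(1))
  ord <- order(trees, na.last = TRUE)
  ruleset(rs$rules[ord[seq_len(max_rules)]],
          feature_vocabulary = rs$feature_vocabulary)
}

#' RuleFit fusion for one ensemble
#'
#' Extracts rules, deduplicates, truncates to `max_rules`, assembles the
#' joint rule + linear design, and fits the sparse model.
#'
#' @param ensemble a fitted `tree_ensemble`.
#' @param table a labeled [feature_table()].
#' @param max_rules rule budget before fitting (default 80).
#' @param winsor linear-term winsorization quantiles.
#' @param lambda_rule,nfolds,seed passed to [fit_sparse()].
#' @return List with `ruleset` (the fitted candidate rules), `design` and
#'   `model`.
#' @export
rulefit_fuse <- function(ensemble, table, max_rules = 80,
                         winsor = c(0.025, 0.975),
                         lambda_rule = "min", nfolds = 5, seed = NULL) {
  rs <- extract_rules(ensemble)
  rs <- deduplicate_rules(rs)
  rs <- truncate_rules(rs, max_rules)
  design <- assemble_design(rs, table, winsor = winsor)
  model <- fit_sparse(design, table$labels, lambda_rule = lambda_rule,
                      nfolds = nfolds, seed = seed)
  list(ruleset = rs, design = design, model = model)
}
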