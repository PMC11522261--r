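#' @title Rule-based diagnostic model
#' @description
#' The final model is an ordinary multivariate logistic regression over the
#' selected rule indicators,
#' \deqn{Y_i = \beta_0 + \sum_k \beta_k r_k(x_i), \qquad
#'   P(\mathrm{IAC}) = \mathrm{logit}^{-1}(Y_i),}
#' evaluated by ROC/AUC (Mann-Whitney rank statistic with tie correction,
#' DeLong or bootstrap confidence interval) and threshold metrics
#' (accuracy, precision, recall, F1) at a probability cutoff.
#' @name diagnostic-model
NULL

#' Construct a diagnostic model
#'
#' @param intercept scalar intercept.
#' @param coefficients named numeric vector, one entry per rule id.
#' @param rs optional [ruleset()]; when given, its ids must match the
#'   coefficient names exactly.
#' @param threshold probability decision cutoff (default 0.5).
#' @return A `diagnostic_model`.
#' @export
diagnostic_model <- function(intercept, coefficients, rs = NULL,
                             threshold = 0.5) {
  stopifnot(is.numeric(intercept), length(intercept) == 1,
            !is.null(names(coefficients)))
  if (!is.null(rs)) {
    stopifnot(inherits(rs, "ruleset"))
    if (!setequal(rule_ids(rs), names(coefficients)))
      stop("coefficient names do not match rule ids")
  }
  structure(list(intercept = unname(intercept), coefficients = coefficients,
                 ruleset = rs, threshold = threshold),
            class = "diagnostic_model")
}

#' Fit the multivariate logistic rule model
#'
#' Maximum-likelihood logistic regression of the outcome on the rule
#' indicators. Constant (all-equal) columns get coefficient 0. If the fit
#' shows quasi-separation (infinite drift of coefficients), the model is
#' refitted with a tiny ridge penalty and a warning — binary-indicator
#' designs separate easily at small n.
#'
#' @param indicators samples x rules 0/1 matrix with column names.
#' @param labels 0/1 outcome.
#' @param rs optional [ruleset()] to attach.
#' @param threshold probability decision cutoff (default 0.5).
#' @param ridge ridge penalty used by the separation fallback (default 1e-6).
#' @return A `diagnostic_model` with convergence diagnostics in
#'   `$diagnostics`.
#' @export
fit_logistic <- function(indicators, labels, rs = NULL, threshold = 0.5,
                         ridge = 1e-6) {
  stopifnot(is.matrix(indicators) || is.data.frame(indicators))
  x <- as.matrix(indicators)
  y <- as.integer(labels)
  df <- data.frame(.y = y, x, check.names = FALSE)
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("did not converge", conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  co <- stats::coef(fit)
  if (sep || any(abs(co[-1]) > 15, na.rm = TRUE)) {
    warning("quasi-separation in logistic fit; refitting with ridge penalty ",
            ridge)
    xr <- if (ncol(x) == 1) cbind(x, `..pad` = 0) else x  # glmnet wants >= 2 cols
    rfit <- glmnet::glmnet(xr, y, family = "binomial", alpha = 0,
                           lambda = ridge, standardize = FALSE,
                           thresh = 1e-12)
    co <- as.matrix(stats::coef(rfit))[, 1]
    co <- co[names(co) != "..pad"]
    diag_info <- list(converged = TRUE, separation = TRUE, ridge = ridge)
  } else {
    diag_info <- list(converged = fit$converged, separation = FALSE, ridge = 0)
  }
  co[is.na(co)] <- 0            # aliased/constant columns
  m <- diagnostic_model(co[1], stats::setNames(co[-1], colnames(x)),
                        rs = rs, threshold = threshold)
  m$diagnostics <- diag_info
  m
}

#' Linear predictor and probabilities of a diagnostic model
#'
#' `Y_i = intercept + sum_k coef_k * r_k(x_i)`.
#'
#' @param model a `diagnostic_model`.
#' @param indicators matrix whose columns cover the model's rule ids.
#' @return `linear_predictor` returns Y per sample; the fitted probability
#'   is `plogis(Y)`.
#' @export
linear_predictor <- function(model, indicators) {
  stopifnot(inherits(model, "diagnostic_model"))
  x <- as.matrix(indicators)
  missing <- setdiff(names(model$coefficients), colnames(x))
  if (length(missing))
    stop("indicator matrix lacks rule columns: ", paste(missing, collapse = ", "))
  x <- x[, names(model$coefficients), drop = FALSE]
  as.vector(model$intercept + x %*% model$coefficients)
}

#' @param object a `diagnostic_model`.
#' @param newdata a [feature_table()] (the model's rule set is evaluated on
#'   it) or an indicator matrix.
#' @param type `"prob"` (default), `"link"`, or `"class"`.
#' @param ... unused.
#' @rdname linear_predictor
#' @export
predict.diagnostic_model <- function(object, newdata,
                                     type = c("prob", "link", "class"), ...) {
  type <- match.arg(type)
  ind <- if (inherits(newdata, "feature_table")) {
    if (is.null(object$ruleset)) stop("model carries no ruleset; pass indicators")
    rules_to_dataset(object$ruleset, newdata)
  } else as.matrix(newdata)
  y <- linear_predictor(object, ind)
  switch(type, link = y, prob = stats::plogis(y),
         class = as.integer(stats::plogis(y) >= object$threshold))
}

#' AUC by the Mann-Whitney rank statistic
#'
#' Tie-corrected: equals the proportion of positive-negative pairs where
#' the positive outscores the negative, ties counted 1/2.
#'
#' @param scores numeric scores.
#' @param labels 0/1 outcome with both classes present.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, labels) {
  y <- as.integer(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("AUC needs both classes")
  r <- rank(scores)                      # midranks handle ties
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

roc_curve_points <- function(scores, labels) {
  y <- as.integer(labels)
  cuts <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tp <- vapply(cuts, function(ct) sum(scores >= ct & y == 1), numeric(1))
  fp <- vapply(cuts, function(ct) sum(scores >= ct & y == 0), numeric(1))
  data.frame(cutoff = cuts, fpr = fp / sum(y == 0), tpr = tp / sum(y == 1))
}

#' Evaluate a diagnostic model
#'
#' @param model a `diagnostic_model`.
#' @param indicators indicator matrix covering the model's rules.
#' @param labels 0/1 outcome (both classes present).
#' @param ci_method `"delong"` (default, deterministic) or `"bootstrap"`
#'   for the AUC confidence interval.
#' @param threshold probability cutoff for the confusion-matrix metrics;
#'   `NULL` uses the model's own, `"youden"` picks the cutoff maximizing
#'   sensitivity + specificity - 1.
#' @param conf_level confidence level (default 0.95).
#' @param boot_n bootstrap replicates when `ci_method = "bootstrap"`.
#' @return An `evaluation_report`: `auc`, `auc_ci`, `accuracy`, `precision`,
#'   `recall`, `f1`, `threshold`, `confusion` (tp/fp/fn/tn), `roc` points.
#' @export
evaluate_model <- function(model, indicators, labels,
                           ci_method = c("delong", "bootstrap"),
                           threshold = NULL, conf_level = 0.95, boot_n = 2000) {
  ci_method <- match.arg(ci_method)
  y <- as.integer(labels)
  if (length(unique(y)) < 2) stop("evaluation needs both classes")
  yhat <- linear_predictor(model, indicators)
  prob <- stats::plogis(yhat)
  auc <- auc_rank(yhat, y)
  roc_obj <- suppressMessages(pROC::roc(response = y, predictor = yhat,
                                        levels = c(0, 1), direction = "<",
                                        quiet = TRUE))
  ci <- if (ci_method == "delong")
    as.numeric(pROC::ci.auc(roc_obj, conf.level = conf_level, method = "delong"))
  else
    as.numeric(pROC::ci.auc(roc_obj, conf.level = conf_level,
                            method = "bootstrap", boot.n = boot_n,
                            progress = "none"))
  thr <- threshold %||% model$threshold
  if (identical(thr, "youden")) {
    pts <- roc_curve_points(prob, y)
    thr <- pts$cutoff[which.max(pts$tpr - pts$fpr)]
    if (!is.finite(thr)) thr <- 0.5
  }
  pred <- as.integer(prob >= thr)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1); tn <- sum(pred == 0 & y == 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  structure(list(auc = auc, auc_ci = c(lower = ci[1], upper = ci[3]),
                 ci_method = ci_method,
                 accuracy = (tp + tn) / length(y),
                 precision = precision, recall = recall, f1 = f1,
                 threshold = thr,
                 confusion = c(tp = tp, fp = fp, fn = fn, tn = tn),
                 roc = roc_curve_points(yhat, y)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("AUC %.4f (%d%% CI %.4f-%.4f, %s)\n", x$auc,
              95, x$auc_ci[1], x$auc_ci[2], x$ci_method))
  cat(sprintf("accuracy %.4f  precision %.4f  recall %.4f  F1 %.4f @ p>=%.3g\n",
              x$accuracy, x$precision, x$recall, x$f1, x$threshold))
  invisible(x)
}

#' @export
print.diagnostic_model <- function(x, ...) {
  cat(format_equation(x), "\n")
  invisible(x)
}

format_equation <- function(model) {
  terms <- vapply(seq_along(model$coefficients), function(k) {
    b <- model$coefficients[k]
    sprintf("%s %s*%s", if (b < 0) "-" else "+", fmt_num(abs(b)),
            names(model$coefficients)[k])
  }, character(1))
  paste(c(sprintf("Y = %s", fmt_num(model$intercept)), terms), collapse = " ")
}

#' Export / import a model card
#'
#' A single plain-text document rendering the model as an equation plus a
#' rule table in the textual dialect; the card parses back to the identical
#' model (coefficients are written in shortest round-trip form).
#'
#' @param model a `diagnostic_model`.
#' @param path optional output file; `NULL` returns the card as a character
#'   vector of lines.
#' @return `export_model_card`: the lines (invisibly when written);
#'   `read_model_card`: the reconstructed `diagnostic_model`.
#' @export
export_model_card <- function(model, path = NULL) {
  stopifnot(inherits(model, "diagnostic_model"))
  rules <- if (!is.null(model$ruleset)) {
    stats::setNames(model$ruleset$rules, rule_ids(model$ruleset))
  } else NULL
  header <- c("# rulefusion diagnostic model card",
              paste0("# intercept: ", fmt_num(model$intercept)),
              paste0("# threshold: ", fmt_num(model$threshold)),
              paste0("# equation: ", format_equation(model)),
              "id\tcoefficient\tsource\trule")
  body <- vapply(names(model$coefficients), function(id) {
    r <- rules[[id]]
    paste(id, fmt_num(model$coefficients[[id]]),
          if (!is.null(r) && length(r$source)) paste(r$source, collapse = "/") else "unknown",
          if (!is.null(r)) format_rule(r) else "", sep = "\t")
  }, character(1))
  lines <- c(header, body)
  if (is.null(path)) return(lines)
  writeLines(lines, path, useBytes = FALSE)
  invisible(lines)
}

#' @param path path to a card written by `export_model_card`.
#' @rdname export_model_card
#' @export
read_model_card <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  grab <- function(key) {
    ln <- grep(paste0("^# ", key, ": "), lines, value = TRUE)[1]
    as.numeric(sub(paste0("^# ", key, ": "), "", ln))
  }
  body <- lines[!startsWith(lines, "#")]
  body <- body[-1]                      # header row
  body <- body[nzchar(body)]
  coefs <- numeric(0); rules <- list()
  for (ln in body) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    coefs[parts[1]] <- as.numeric(parts[2])
    if (length(parts) >= 4 && nzchar(parts[4]))
      rules[[length(rules) + 1L]] <- parse_rule(parts[4], id = parts[1],
                                                source = parts[3])
  }
  rs <- if (length(rules) == length(coefs)) ruleset(rules) else NULL
  diagnostic_model(grab("intercept"), coefs, rs = rs, threshold = grab("threshold"))
}
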