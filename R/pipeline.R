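#' @title End-to-end pipeline
#' @description
#' Binds the stages into the complete workflow: feature selection, fitting
#' of the three rule-generating ensembles, the fusion-and-selection
#' cascade, the final logistic model, and evaluation — with every artifact
#' written as delimited text plus a manifest (configuration hash, seed,
#' versions) so a run is reproducible from its manifest and inputs.
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' Defaults are the study's stated settings: Spearman cutoff 0.9, mRMR
#' top-100, 500 LASSO iterations, importance threshold 0.1, outcome
#' correlation threshold 0.4, SHAP threshold 0.5, rule budget 80, and the
#' ensemble settings of [ensemble_config()].
#'
#' @param ... overrides for individual entries.
#' @return Named list of stage parameters.
#' @export
pipeline_config <- function(...) {
  cfg <- list(select = TRUE, variance_tol = 1e-8, rho_cutoff = 0.9,
              mrmr_k = 100, lasso_iters = 500, stability_threshold = 0.5,
              max_features = 10, importance_thr = 0.1, phi_thr = 0.4,
              shap_thr = 0.5, max_rules = 80, winsor = c(0.025, 0.975),
              lambda_rule = "min", nfolds = 5, threshold = 0.5,
              ci_method = "delong", ensembles = ensemble_config())
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config entries: ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  cfg
}

#' Run the full rule-fusion pipeline
#'
#' Executes feature selection (optional), `fit_ensembles`, the
#' `fuse_and_select` cascade, `fit_logistic` and `evaluate_model` on a
#' training table, optionally evaluating on a held-out test table, and
#' optionally writing all artifacts (selected features, final rules,
#' per-stage trace, model card, evaluation report, manifest) to a
#' directory.
#'
#' @param train labeled training [feature_table()].
#' @param test optional labeled test [feature_table()].
#' @param config a [pipeline_config()].
#' @param seed RNG seed driving every stochastic stage.
#' @param out_dir optional output directory (created if needed).
#' @return A `pipeline_run`: `selection`, `ensembles`, `cascade`, `model`,
#'   `evaluation` (train and optional test reports), `artifacts` (paths).
#' @export
run_pipeline <- function(train, test = NULL, config = pipeline_config(),
                         seed = 1, out_dir = NULL) {
  stopifnot(inherits(train, "feature_table"))
  if (is.null(train$labels))
    stop("pipeline stage 'input': training table has no outcome labels")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  selection <- NULL
  work <- train
  if (isTRUE(config$select) && ncol(train$data) > config$max_features) {
    selection <- stage("select_features",
      select_features(train, variance_tol = config$variance_tol,
                      rho_cutoff = config$rho_cutoff, mrmr_k = config$mrmr_k,
                      lasso_iters = config$lasso_iters,
                      stability_threshold = config$stability_threshold,
                      max_features = config$max_features, seed = seed))
    work <- ft_select(train, selection$selected)
  }
  ensembles <- stage("fit_ensembles",
                     fit_ensembles(work, config$ensembles, seed = seed))
  cascade <- stage("fuse_and_select",
    fuse_and_select(ensembles, work, importance_thr = config$importance_thr,
                    phi_thr = config$phi_thr, shap_thr = config$shap_thr,
                    max_rules = config$max_rules,
                    lambda_rule = config$lambda_rule, nfolds = config$nfolds,
                    seed = seed))
  model <- stage("fit_logistic",
                 fit_logistic(cascade$indicators, work$labels,
                              rs = cascade$ruleset,
                              threshold = config$threshold))
  evaluation <- list(train = stage("evaluate",
    evaluate_model(model, cascade$indicators, work$labels,
                   ci_method = config$ci_method)))
  if (!is.null(test)) {
    stopifnot(inherits(test, "feature_table"))
    if (is.null(test$labels))
      stop("pipeline stage 'evaluate': test table has no outcome labels")
    ind_test <- stage("evaluate", rules_to_dataset(cascade$ruleset, test))
    evaluation$test <- stage("evaluate",
      evaluate_model(model, ind_test, test$labels,
                     ci_method = config$ci_method))
  }
  run <- structure(list(selection = selection, ensembles = ensembles,
                        cascade = cascade, model = model,
                        evaluation = evaluation, config = config,
                        seed = seed, artifacts = NULL),
                   class = "pipeline_run")
  if (!is.null(out_dir)) run$artifacts <- write_artifacts(run, out_dir)
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("pipeline_run (seed", x$seed, ")\n")
  print(x$cascade)
  cat("train: "); print(x$evaluation$train)
  if (!is.null(x$evaluation$test)) { cat("test:  "); print(x$evaluation$test) }
  invisible(x)
}

evaluation_table <- function(evaluation) {
  do.call(rbind, lapply(names(evaluation), function(nm) {
    e <- evaluation[[nm]]
    data.frame(cohort = nm, auc = e$auc, auc_lower = e$auc_ci[["lower"]],
               auc_upper = e$auc_ci[["upper"]], accuracy = e$accuracy,
               precision = e$precision, recall = e$recall, f1 = e$f1,
               threshold = e$threshold)
  }))
}

write_artifacts <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  sel <- if (!is.null(run$selection)) run$selection$selected
    else names(run$cascade$ruleset$feature_vocabulary) %||%
      run$cascade$ruleset$feature_vocabulary
  utils::write.csv(data.frame(feature = sel), p("selected_features.csv"),
                   row.names = FALSE)
  write_ruleset(run$cascade$ruleset, p("final_rules.tsv"))
  utils::write.table(cascade_trace_table(run$cascade), p("selection_trace.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  export_model_card(run$model, p("model_card.txt"))
  utils::write.csv(evaluation_table(run$evaluation), p("evaluation.csv"),
                   row.names = FALSE)
  cfg_json <- jsonlite::toJSON(run$config, auto_unbox = TRUE, digits = NA,
                               pretty = TRUE)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  manifest <- list(package = "rulefusion",
                   version = as.character(utils::packageVersion("rulefusion")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   seed = run$seed,
                   config_md5 = unname(tools::md5sum(tmp)),
                   config = jsonlite::fromJSON(cfg_json, simplifyVector = TRUE))
  unlink(tmp)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), p("manifest.json"))
  stats::setNames(p(c("selected_features.csv", "final_rules.tsv",
                      "selection_trace.tsv", "model_card.txt",
                      "evaluation.csv", "manifest.json")),
                  c("selected_features", "final_rules", "selection_trace",
                    "model_card", "evaluation", "manifest"))
}
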