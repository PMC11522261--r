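#' @title Two-phase radiomics feature selection
#' @description
#' Reduces a high-dimensional radiomics table (~1600 signatures plus a
#' handful of radiological flags) to a small set of key features in two
#' phases. Phase 1 acts on the continuous signatures: scaling
#' normalization, removal of near-zero-variance columns, greedy pruning of
#' feature pairs with absolute Spearman correlation above a cutoff, then
#' mRMR ranking to a top-k list. Phase 2 merges the radiological flags back
#' in and runs repeated L1-penalized logistic selection (stability
#' selection), keeping features selected in at least a configurable
#' fraction of iterations.
#' @name feature-selection
NULL

new_selection_report <- function(stage, kept, removed, scores) {
  structure(list(stage = stage, kept = kept,
                 removed = removed, scores = scores),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("selection_report [%s]: kept %d, removed %d\n",
              x$stage, length(x$kept), nrow(x$removed)))
  invisible(x)
}

#' Standardize continuous features
#'
#' Centers and scales every continuous column to mean 0, sd 1. Columns with
#' zero variance are passed through unchanged and reported in the
#' `"constant_features"` attribute; binary columns are untouched. The
#' operation is idempotent.
#'
#' @param table a [feature_table()] with at least two samples.
#' @return A `feature_table` with standardized continuous columns.
#' @export
scale_features <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (nrow(table$data) < 2) stop("need at least 2 samples to standardize")
  constant <- character(0)
  data <- table$data
  for (nm in names(data)[table$kind == "continuous"]) {
    s <- stats::sd(data[[nm]])
    if (is.na(s) || s == 0) {
      constant <- c(constant, nm)
    } else {
      data[[nm]] <- (data[[nm]] - mean(data[[nm]])) / s
    }
  }
  out <- feature_table(data, labels = table$labels, kind = unname(table$kind),
                       sample_ids = table$sample_ids)
  attr(out, "constant_features") <- constant
  out
}

#' Near-zero-variance filter
#'
#' Removes continuous features whose (pre-scaling) variance is at most
#' `tol`; binary flags are never removed here.
#'
#' @param table a [feature_table()].
#' @param tol non-negative variance tolerance.
#' @return A [selection_report] with per-feature variances as scores.
#' @export
variance_filter <- function(table, tol = 1e-8) {
  stopifnot(inherits(table, "feature_table"), tol >= 0)
  v <- vapply(table$data, stats::var, numeric(1))
  drop <- names(v)[table$kind == "continuous" & v <= tol]
  kept <- setdiff(names(v), drop)
  if (!length(kept)) stop("variance filter removed every feature (tol = ", tol, ")")
  new_selection_report("variance_filter", kept,
                       data.frame(feature = drop,
                                  reason = rep(sprintf("variance <= %g", tol),
                                               length(drop))),
                       v)
}

#' Greedy Spearman correlation pruning
#'
#' Repeatedly finds the feature pair with the largest absolute pairwise
#' Spearman correlation above `cutoff` and drops, within that pair, the
#' feature with the larger mean absolute correlation to all remaining
#' features (ties broken by dropping the lexicographically later name),
#' until no pair exceeds the cutoff.
#'
#' @param table a [feature_table()].
#' @param cutoff correlation cutoff in (0, 1].
#' @return A [selection_report]; scores give each kept feature's maximum
#'   absolute correlation to the other kept features.
#' @export
correlation_prune <- function(table, cutoff = 0.9) {
  stopifnot(inherits(table, "feature_table"), cutoff > 0, cutoff <= 1)
  x <- as.matrix(table$data)
  if (ncol(x) < 2) {
    return(new_selection_report("correlation_prune", colnames(x),
                                data.frame(feature = character(0), reason = character(0)),
                                stats::setNames(numeric(ncol(x)), colnames(x))))
  }
  C <- abs(stats::cor(x, method = "spearman"))
  C[!is.finite(C)] <- 0          # constant columns have undefined correlation
  diag(C) <- 0
  removed <- character(0)
  repeat {
    mx <- max(C)
    if (mx <= cutoff) break
    idx <- which(C == mx, arr.ind = TRUE)[1, ]
    pair <- colnames(C)[idx]
    means <- rowMeans(C)[pair]
    drop <- if (means[1] > means[2]) pair[1]
      else if (means[2] > means[1]) pair[2]
      else sort(pair)[2]          # tie: lexicographically later name
    removed <- c(removed, drop)
    keep <- setdiff(colnames(C), drop)
    C <- C[keep, keep, drop = FALSE]
  }
  kept <- setdiff(colnames(x), removed)
  scores <- if (ncol(C) >= 2) apply(C, 1, max) else stats::setNames(numeric(length(kept)), kept)
  new_selection_report("correlation_prune", kept,
                       data.frame(feature = removed,
                                  reason = rep(sprintf("|spearman rho| > %g", cutoff),
                                               length(removed))),
                       scores)
}

# equal-frequency discretization into at most `bins` levels (integer codes)
discretize_ef <- function(x, bins = 10) {
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                               na.rm = TRUE, names = FALSE, type = 7))
  if (length(br) < 2) return(rep(1L, length(x)))
  as.integer(cut(x, breaks = br, include.lowest = TRUE))
}

# mutual information (nats) between two integer-coded vectors
mi_disc <- function(a, b) {
  na <- max(a); nb <- max(b)
  counts <- tabulate((b - 1L) * na + a, nbins = na * nb)
  p <- counts / sum(counts)
  pm <- matrix(p, na, nb)
  pa <- rowSums(pm); pb <- colSums(pm)
  nz <- pm > 0
  sum(pm[nz] * log(pm[nz] / outer(pa, pb)[nz]))
}

#' mRMR feature ranking
#'
#' Greedy minimum-redundancy maximum-relevance ranking (difference form):
#' the first feature maximizes mutual information with the outcome; each
#' subsequent feature maximizes relevance minus `redundancy_weight` times
#' its mean mutual information with the already-selected features. Mutual
#' information of continuous features is computed after equal-frequency
#' discretization.
#'
#' @param table a labeled [feature_table()].
#' @param k number of features to rank (at least 1; capped at the number of
#'   features).
#' @param redundancy_weight weight of the redundancy term (default 1; 0
#'   reduces the ranking to univariate mutual information).
#' @param bins number of equal-frequency bins for continuous features.
#' @return A [selection_report]; `kept` is in selection order and `scores`
#'   holds each feature's mRMR score at the step it was selected.
#' @export
mrmr_rank <- function(table, k, redundancy_weight = 1, bins = 10) {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(table$labels)) stop("mRMR requires a labeled table")
  if (k < 1) stop("k must be >= 1")
  p <- ncol(table$data)
  k <- min(k, p)
  disc <- lapply(seq_len(p), function(j) {
    x <- table$data[[j]]
    if (table$kind[j] == "binary") as.integer(x) + 1L else discretize_ef(x, bins)
  })
  y <- as.integer(table$labels) + 1L
  rel <- vapply(disc, mi_disc, numeric(1), b = y)
  names(rel) <- names(table$data)
  selected <- integer(0)
  red_sum <- numeric(p)
  scores <- numeric(0)
  remaining <- seq_len(p)
  for (step in seq_len(k)) {
    sc <- rel[remaining] -
      if (length(selected)) redundancy_weight * red_sum[remaining] / length(selected) else 0
    best <- remaining[which.max(sc)]
    scores <- c(scores, stats::setNames(max(sc), names(table$data)[best]))
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
    if (length(remaining) && redundancy_weight != 0) {
      red_sum[remaining] <- red_sum[remaining] +
        vapply(disc[remaining], mi_disc, numeric(1), b = disc[[best]])
    }
  }
  kept <- names(table$data)[selected]
  new_selection_report("mrmr", kept,
                       data.frame(feature = setdiff(names(table$data), kept),
                                  reason = rep(sprintf("below mRMR top %d", k),
                                               ncol(table$data) - length(kept))),
                       scores)
}

#' Repeated LASSO stability selection
#'
#' Runs `n_iter` L1-penalized logistic fits, each with freshly randomized
#' stratified cross-validation folds, and records how often each feature
#' receives a nonzero coefficient at the cross-validated penalty. Features
#' selected in at least `threshold` of the iterations are kept, ordered by
#' selection frequency.
#'
#' @param table a labeled [feature_table()] with both classes present.
#' @param n_iter number of iterations (>= 1).
#' @param threshold stability threshold on the selection frequency.
#' @param nfolds cross-validation folds per iteration.
#' @param lambda_rule `"1se"` (default) or `"min"`.
#' @param seed optional RNG seed.
#' @return A [selection_report]; `scores` are selection frequencies for all
#'   features.
#' @export
repeated_lasso_select <- function(table, n_iter = 500, threshold = 0.5,
                                  nfolds = 5, lambda_rule = c("1se", "min"),
                                  seed = NULL) {
  stopifnot(inherits(table, "feature_table"), n_iter >= 1)
  lambda_rule <- match.arg(lambda_rule)
  y <- table$labels
  if (is.null(y) || length(unique(y)) < 2)
    stop("repeated LASSO requires both outcome classes")
  if (!is.null(seed)) set.seed(seed)
  x <- as.matrix(table$data)
  hits <- numeric(ncol(x))
  for (i in seq_len(n_iter)) {
    foldid <- stratified_folds(y, nfolds)
    cv <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = 1,
                            foldid = foldid, standardize = TRUE)
    lam <- if (lambda_rule == "1se") cv$lambda.1se else cv$lambda.min
    co <- as.matrix(stats::coef(cv, s = lam))[-1, 1]
    hits <- hits + (co != 0)
  }
  freq <- stats::setNames(hits / n_iter, colnames(x))
  ord <- order(-freq, names(freq), method = "radix")
  freq <- freq[ord]
  kept <- names(freq)[freq >= threshold]
  new_selection_report("repeated_lasso", kept,
                       data.frame(feature = names(freq)[freq < threshold],
                                  reason = rep(sprintf("selection frequency < %g", threshold),
                                               sum(freq < threshold))),
                       freq)
}

#' Full two-phase feature-selection pipeline
#'
#' Phase 1 (continuous signatures only): [variance_filter()],
#' [scale_features()], [correlation_prune()], [mrmr_rank()]. Phase 2: the
#' radiological flag features in `bypass` (which skip phase 1) are merged
#' with the mRMR survivors, and [repeated_lasso_select()] picks the stable
#' subset, truncated to at most `max_features` by selection frequency.
#'
#' @param table a labeled [feature_table()].
#' @param variance_tol,rho_cutoff,mrmr_k,lasso_iters,stability_threshold
#'   stage parameters (defaults 1e-8, 0.9, 100, 500, 0.5).
#' @param max_features cap on the final feature count (default 10).
#' @param bypass feature names that skip phase 1 and join before the LASSO
#'   stage; defaults to the table's binary flag columns.
#' @param seed optional RNG seed (drives the repeated-LASSO folds).
#' @return A `feature_selection` object: list of stage reports plus
#'   `selected`, the final ordered feature names.
#' @examples
#' \donttest{
#' tab <- generate_radiomics_table(n = 120, p = 60, seed = 1)
#' sel <- select_features(tab, mrmr_k = 20, lasso_iters = 10, seed = 1)
#' sel$selected
#' }
#' @export
select_features <- function(table, variance_tol = 1e-8, rho_cutoff = 0.9,
                            mrmr_k = 100, lasso_iters = 500,
                            stability_threshold = 0.5, max_features = 10,
                            bypass = NULL, seed = NULL) {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(table$labels)) stop("feature selection requires a labeled table")
  bypass <- bypass %||% names(table$data)[table$kind == "binary"]
  phase1_feats <- setdiff(names(table$data), bypass)
  t1 <- ft_select(table, phase1_feats)

  rep_var <- variance_filter(t1, variance_tol)
  t1 <- ft_select(t1, rep_var$kept)
  t1 <- scale_features(t1)
  rep_cor <- correlation_prune(t1, rho_cutoff)
  t1 <- ft_select(t1, rep_cor$kept)
  rep_mrmr <- mrmr_rank(t1, mrmr_k)

  phase2_feats <- c(rep_mrmr$kept, intersect(names(table$data), bypass))
  t2 <- ft_select(table, intersect(names(table$data), phase2_feats))
  t2s <- scale_features(t2)
  rep_lasso <- repeated_lasso_select(t2s, n_iter = lasso_iters,
                                     threshold = stability_threshold, seed = seed)
  selected <- utils::head(rep_lasso$kept, max_features)

  structure(list(variance = rep_var, correlation = rep_cor, mrmr = rep_mrmr,
                 lasso = rep_lasso, selected = selected),
            class = "feature_selection")
}

#' @export
print.feature_selection <- function(x, ...) {
  cat("two-phase feature selection\n")
  for (st in c("variance", "correlation", "mrmr", "lasso")) print(x[[st]])
  cat("final:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}
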