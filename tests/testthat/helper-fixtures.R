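# small builders shared across test files

toy_table <- function(...) {
  df <- data.frame(..., check.names = FALSE)
  labels <- df[["outcome"]]
  df[["outcome"]] <- NULL
  feature_table(df, labels = labels)
}

# brute-force AUC: mean over all positive-negative pairs, ties counted 1/2
auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# exact Shapley by averaging marginal contributions over all orderings,
# for an additive model f(x) = sum w_j x_j + b with "absent" = column mean
shapley_permutation <- function(weights, x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  p <- length(weights)
  perms <- gtools_permutations(p)
  phi <- matrix(0, nrow(x), p)
  fval <- function(mask, xi) sum(weights * ifelse(mask, xi, mu))
  for (i in seq_len(nrow(x))) {
    for (r in seq_len(nrow(perms))) {
      mask <- rep(FALSE, p)
      for (j in perms[r, ]) {
        before <- fval(mask, x[i, ])
        mask[j] <- TRUE
        phi[i, j] <- phi[i, j] + (fval(mask, x[i, ]) - before)
      }
    }
  }
  phi / nrow(perms)
}

# all permutations of 1..n (tiny n only)
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- gtools_permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub), n - 1)))
  }
  unname(out)
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)
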