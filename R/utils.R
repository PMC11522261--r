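# shared internal helpers

# shortest decimal string that parses back to exactly x
fmt_num <- function(x) {
  vapply(x, function(v) {
    if (!is.finite(v)) return(as.character(v))
    for (d in 1:17) {
      s <- sprintf(paste0("%.", d, "g"), v)
      if (as.numeric(s) == v) return(s)
    }
    sprintf("%.17g", v)
  }, character(1))
}

# parse a printed number: unicode minus, thousands separators, stray spaces
parse_num <- function(s) {
  s <- gsub("\u2212", "-", trimws(s))
  s <- gsub("(?<=\\d),(?=\\d)", "", s, perl = TRUE)
  s <- gsub("\\s+", "", s)
  suppressWarnings(as.numeric(s))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stratified cross-validation fold ids, reproducible under the current RNG state
stratified_folds <- function(y, nfolds) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
  }
  fold
}

is_binary01 <- function(x) {
  v <- x[!is.na(x)]
  length(v) > 0 && all(v %in% c(0, 1))
}
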