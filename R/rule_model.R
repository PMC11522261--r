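#' @title The conjunctive rule language
#' @description
#' A decision rule is a conjunction of axis-aligned conditions on named
#' features, written in a compact textual dialect:
#'
#' ```
#' original_shape_MajorAxisLength <= 12.46 & original_firstorder_10Percentile <= -768.75
#' wavelet-LLH_firstorder_Maximum ∈ (122.71,525.63]
#' spiculated margin            # bare name: binary flag equals 1
#' pleural indentation = 1
#' ```
#'
#' Semantics follow binary-tree splits: `<=` is inclusive, `>` strict, and
#' an interval `(l,u]` is left-open right-closed. A rule fires (indicator 1)
#' on a sample iff every condition holds. Feature tokens may carry a source
#' prefix (`gbc_`, `rf_`, `ada_`) which is stripped and recorded as
#' provenance, never as part of the feature name. Thousands separators and
#' the unicode minus sign in printed thresholds are accepted.
#' @name rule-language
NULL

RULE_SOURCES <- c("gradient_boosting", "random_forest", "adaboost", "original_feature")
SOURCE_PREFIXES <- c(gbc_ = "gradient_boosting", rf_ = "random_forest", ada_ = "adaboost")

new_condition <- function(feature, op, threshold = NA_real_,
                          lower = NA_real_, upper = NA_real_,
                          value = NA_integer_) {
  if (!op %in% c("LE", "GT", "INTERVAL", "FLAG_EQ")) stop("unknown operator: ", op)
  if (op == "INTERVAL" && !(is.finite(lower) && is.finite(upper) && lower < upper))
    stop("empty interval for '", feature, "': (", lower, ",", upper, "]")
  if (op %in% c("LE", "GT") && !is.finite(threshold))
    stop("missing threshold for '", feature, "'")
  if (op == "FLAG_EQ" && !value %in% c(0L, 1L))
    stop("flag value for '", feature, "' must be 0 or 1")
  list(feature = feature, op = op, threshold = threshold,
       lower = lower, upper = upper, value = value)
}

new_rule <- function(id, conditions, source = character(0), weight = NA_real_,
                     tree = NA_integer_) {
  if (!length(conditions)) stop("a rule needs at least one condition")
  bad <- setdiff(source, RULE_SOURCES)
  if (length(bad)) stop("unknown rule source: ", paste(bad, collapse = ", "))
  structure(list(id = as.character(id), source = source,
                 conditions = conditions, weight = weight,
                 tree = as.integer(tree)),
            class = "rule")
}

normalize_source <- function(s) {
  s <- unlist(strsplit(tolower(trimws(s)), "/", fixed = TRUE))
  s <- gsub("[ -]+", "_", trimws(s))
  s[s == "gbdt"] <- "gradient_boosting"
  s[s == "adaboosting"] <- "adaboost"
  bad <- setdiff(s, RULE_SOURCES)
  if (length(bad)) stop("unknown rule source: ", paste(bad, collapse = ", "))
  unique(s)
}

parse_condition <- function(token) {
  tok <- gsub("\u2212", "-", trimws(token))
  strip_prefix <- function(nm) {
    nm <- trimws(nm)
    for (p in names(SOURCE_PREFIXES)) {
      if (startsWith(nm, p))
        return(list(feature = substring(nm, nchar(p) + 1L),
                    source = unname(SOURCE_PREFIXES[[p]])))
    }
    list(feature = nm, source = NULL)
  }
  num <- function(s) {
    v <- parse_num(s)
    if (is.na(v)) stop("cannot parse number '", s, "' in condition '", token, "'")
    v
  }
  # interval condition: (l, u]
  m <- regmatches(tok, regexec("^(.*?)\\s*\u2208\\s*\\(\\s*(.+?)\\s*,\\s*(.+?)\\s*\\]\\s*$", tok))[[1]]
  if (length(m)) {
    f <- strip_prefix(m[2]); lo <- num(m[3]); up <- num(m[4])
    if (!(lo < up)) stop("empty interval in '", token, "': lower >= upper")
    return(list(cond = new_condition(f$feature, "INTERVAL", lower = lo, upper = up),
                source = f$source))
  }
  # less-or-equal, tolerating spaced variants "<  ="
  m <- regmatches(tok, regexec("^(.*?)\\s*<\\s*=\\s*(.+)$", tok))[[1]]
  if (length(m)) {
    f <- strip_prefix(m[2])
    return(list(cond = new_condition(f$feature, "LE", threshold = num(m[3])),
                source = f$source))
  }
  if (grepl(">\\s*=", tok)) stop("unknown operator '>=' in '", token, "'")
  m <- regmatches(tok, regexec("^(.*?)\\s*>\\s*(.+)$", tok))[[1]]
  if (length(m)) {
    f <- strip_prefix(m[2])
    return(list(cond = new_condition(f$feature, "GT", threshold = num(m[3])),
                source = f$source))
  }
  m <- regmatches(tok, regexec("^(.*?)\\s*=\\s*([01])\\s*$", tok))[[1]]
  if (length(m)) {
    f <- strip_prefix(m[2])
    return(list(cond = new_condition(f$feature, "FLAG_EQ", value = as.integer(m[3])),
                source = f$source))
  }
  if (grepl("[][<>=()\u2208]", tok))
    stop("malformed condition: '", token, "'")
  f <- strip_prefix(tok)
  if (!nzchar(f$feature)) stop("malformed condition: '", token, "'")
  list(cond = new_condition(f$feature, "FLAG_EQ", value = 1L), source = f$source)
}

#' Parse a rule from its textual form
#'
#' @param text `&`-separated conditions in the rule dialect (see
#'   [rule-language]). A bare feature name denotes a binary flag equal to 1.
#' @param id rule identifier.
#' @param source optional provenance (`"gradient_boosting"`,
#'   `"random_forest"`, `"adaboost"`, `"original_feature"`, or several,
#'   `/`-separated); prefixes found on feature tokens are added to it.
#' @param canonical canonicalize the parsed rule (default `TRUE`).
#' @return A `rule` object.
#' @examples
#' parse_rule("spiculated margin", id = "Rule5")
#' parse_rule("rf_original_glcm_JointEntropy > 8.48 & pleural indentation = 1",
#'            id = "Rule15")
#' @export
parse_rule <- function(text, id = "rule", source = NULL, canonical = TRUE) {
  tokens <- strsplit(text, "&", fixed = TRUE)[[1]]
  tokens <- tokens[nzchar(trimws(tokens))]
  if (!length(tokens)) stop("empty rule text")
  parsed <- lapply(tokens, parse_condition)
  src <- unique(c(if (!is.null(source)) normalize_source(source),
                  unlist(lapply(parsed, `[[`, "source"))))
  r <- new_rule(id, lapply(parsed, `[[`, "cond"), source = src)
  if (canonical) canonicalize_rule(r) else r
}

#' Canonicalize a rule
#'
#' Collapses repeated conditions on one feature (as arise from root-to-node
#' tree paths that split the same feature several times): `<=` thresholds
#' intersect to the minimum, `>` to the maximum, and a coexisting lower and
#' upper bound becomes a left-open right-closed interval. Conditions are
#' sorted by feature name. A logically empty rule (e.g. `x > 7 & x <= 3`)
#' is an error.
#'
#' @param rule a `rule`.
#' @return The canonical `rule`, with at most one condition per feature.
#' @export
canonicalize_rule <- function(rule) {
  stopifnot(inherits(rule, "rule"))
  feats <- vapply(rule$conditions, `[[`, character(1), "feature")
  out <- list()
  for (f in unique(feats)) {
    conds <- rule$conditions[feats == f]
    ops <- vapply(conds, `[[`, character(1), "op")
    if (any(ops == "FLAG_EQ")) {
      if (!all(ops == "FLAG_EQ"))
        stop("feature '", f, "' mixes flag and threshold conditions")
      vals <- unique(vapply(conds, `[[`, integer(1), "value"))
      if (length(vals) > 1)
        stop("empty rule: contradictory flag values for '", f, "'")
      out[[f]] <- new_condition(f, "FLAG_EQ", value = vals)
      next
    }
    lo <- -Inf; up <- Inf
    for (cn in conds) {
      switch(cn$op,
             LE = { up <- min(up, cn$threshold) },
             GT = { lo <- max(lo, cn$threshold) },
             INTERVAL = { lo <- max(lo, cn$lower); up <- min(up, cn$upper) })
    }
    if (lo >= up)
      stop("empty rule: contradictory bounds for '", f, "' (", lo, ", ", up, "]")
    out[[f]] <- if (is.infinite(lo)) new_condition(f, "LE", threshold = up)
      else if (is.infinite(up)) new_condition(f, "GT", threshold = lo)
      else new_condition(f, "INTERVAL", lower = lo, upper = up)
  }
  ord <- order(names(out), method = "radix")
  r <- new_rule(rule$id, unname(out[ord]), source = rule$source,
                weight = rule$weight, tree = rule$tree)
  attr(r, "canonical") <- TRUE
  r
}

format_condition <- function(cond) {
  switch(cond$op,
         LE = paste0(cond$feature, " <= ", fmt_num(cond$threshold)),
         GT = paste0(cond$feature, " > ", fmt_num(cond$threshold)),
         INTERVAL = paste0(cond$feature, " \u2208 (", fmt_num(cond$lower),
                           ",", fmt_num(cond$upper), "]"),
         FLAG_EQ = if (cond$value == 1L) cond$feature
                   else paste0(cond$feature, " = 0"))
}

#' Serialize a rule to the textual dialect
#'
#' Inverse of [parse_rule()] up to canonical form: parsing the returned
#' string yields a structurally identical canonical rule.
#'
#' @param rule a `rule`.
#' @return A single string.
#' @export
format_rule <- function(rule) {
  paste(vapply(rule$conditions, format_condition, character(1)), collapse = " & ")
}

#' @export
print.rule <- function(x, ...) {
  cat(sprintf("%s [%s]: %s\n", x$id,
              if (length(x$source)) paste(x$source, collapse = "/") else "?",
              format_rule(x)))
  invisible(x)
}

# order-independent structural signature of the condition set
rule_signature <- function(rule) {
  if (!isTRUE(attr(rule, "canonical"))) rule <- canonicalize_rule(rule)
  paste(vapply(rule$conditions, function(cn) {
    paste(cn$feature, cn$op, fmt_num(cn$threshold), fmt_num(cn$lower),
          fmt_num(cn$upper), cn$value, sep = "\r")
  }, character(1)), collapse = "\n")
}

#' Construct a rule set
#'
#' @param rules list of `rule` objects with unique ids.
#' @param feature_vocabulary optional character vector; defaults to the
#'   union of features used by the rules. Every condition's feature must be
#'   in the vocabulary.
#' @return A `ruleset` object (list with `rules` and `feature_vocabulary`).
#' @export
ruleset <- function(rules, feature_vocabulary = NULL) {
  stopifnot(all(vapply(rules, inherits, logical(1), "rule")))
  ids <- vapply(rules, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop("duplicate rule ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  used <- unique(unlist(lapply(rules, function(r)
    vapply(r$conditions, `[[`, character(1), "feature"))))
  feature_vocabulary <- feature_vocabulary %||% sort(used)
  extra <- setdiff(used, feature_vocabulary)
  if (length(extra))
    stop("rule features outside vocabulary: ", paste(extra, collapse = ", "))
  structure(list(rules = rules, feature_vocabulary = feature_vocabulary),
            class = "ruleset")
}

#' @export
print.ruleset <- function(x, ...) {
  cat(sprintf("ruleset: %d rules over %d features\n",
              length(x$rules), length(x$feature_vocabulary)))
  for (r in utils::head(x$rules, 10)) print(r)
  if (length(x$rules) > 10) cat("...\n")
  invisible(x)
}

#' @export
length.ruleset <- function(x) length(x$rules)

rule_ids <- function(rs) vapply(rs$rules, `[[`, character(1), "id")

#' Evaluate a rule on a feature table
#'
#' @param rule a `rule`.
#' @param table a [feature_table] containing every feature the rule uses.
#' @param na_action `"zero"` (default): a missing value in a required
#'   feature makes the rule evaluate to 0 for that sample, with a warning;
#'   `"error"`: stop instead.
#' @return Integer 0/1 vector, one entry per sample; 1 iff all conditions
#'   hold (`<=` inclusive, `>` strict, interval `(l,u]`, flags by exact
#'   equality).
#' @export
evaluate_rule <- function(rule, table, na_action = c("zero", "error")) {
  na_action <- match.arg(na_action)
  stopifnot(inherits(rule, "rule"), inherits(table, "feature_table"))
  feats <- vapply(rule$conditions, `[[`, character(1), "feature")
  missing <- setdiff(feats, names(table$data))
  if (length(missing))
    stop("rule '", rule$id, "' uses features absent from table: ",
         paste(missing, collapse = ", "))
  ind <- rep(TRUE, nrow(table$data))
  saw_na <- FALSE
  for (cn in rule$conditions) {
    x <- table$data[[cn$feature]]
    ok <- switch(cn$op,
                 LE = x <= cn$threshold,
                 GT = x > cn$threshold,
                 INTERVAL = x > cn$lower & x <= cn$upper,
                 FLAG_EQ = x == cn$value)
    if (anyNA(ok)) {
      if (na_action == "error")
        stop("missing value in feature '", cn$feature, "' while evaluating rule '",
             rule$id, "'")
      saw_na <- TRUE
      ok[is.na(ok)] <- FALSE
    }
    ind <- ind & ok
  }
  if (saw_na)
    warning("rule '", rule$id,
            "' hit missing feature values; affected samples evaluate to 0")
  as.integer(ind)
}

#' Rule indicator matrix
#'
#' Evaluates every rule of a rule set on a table, column-stacking the 0/1
#' indicators in rule-set order.
#'
#' @param rs a [ruleset()].
#' @inheritParams evaluate_rule
#' @return Integer matrix, samples x rules, with rule ids as column names
#'   and sample ids as row names.
#' @export
rules_to_dataset <- function(rs, table, na_action = c("zero", "error")) {
  na_action <- match.arg(na_action)
  stopifnot(inherits(rs, "ruleset"))
  if (!length(rs$rules)) stop("empty ruleset")
  m <- vapply(rs$rules, evaluate_rule, integer(nrow(table$data)),
              table = table, na_action = na_action)
  m <- matrix(m, nrow = nrow(table$data),
              dimnames = list(table$sample_ids, rule_ids(rs)))
  m
}

#' Fraction of samples on which a rule fires
#'
#' @inheritParams evaluate_rule
#' @return Support in `[0, 1]`.
#' @export
rule_support <- function(rule, table, na_action = c("zero", "error")) {
  if (nrow(table$data) == 0) stop("empty table")
  mean(evaluate_rule(rule, table, na_action))
}

#' Collapse duplicate rules
#'
#' Rules whose canonical condition sets are identical collapse to one rule;
#' the survivor keeps the first id and the union of sources (provenance).
#'
#' @param rs a [ruleset()] of canonical rules.
#' @return A deduplicated `ruleset`.
#' @export
deduplicate_rules <- function(rs) {
  stopifnot(inherits(rs, "ruleset"))
  sig <- vapply(rs$rules, rule_signature, character(1))
  keep <- !duplicated(sig)
  out <- rs$rules[keep]
  names(out) <- sig[keep]
  for (i in which(!keep)) {
    s <- sig[i]
    out[[s]]$source <- unique(c(out[[s]]$source, rs$rules[[i]]$source))
  }
  ruleset(unname(out), feature_vocabulary = rs$feature_vocabulary)
}

#' Read / write rule sets as tab-separated text
#'
#' One rule per line: `id<TAB>source<TAB>rule-text` in the dialect of
#' [rule-language]; multiple sources join with `/`.
#'
#' @param path file path.
#' @param canonical canonicalize on read (default `TRUE`).
#' @return `read_ruleset` returns a [ruleset()]; `write_ruleset` returns
#'   `path` invisibly.
#' @export
read_ruleset <- function(path, canonical = TRUE) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  rules <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) != 3)
      stop("malformed rule line (need id<TAB>source<TAB>text): ", ln)
    parse_rule(parts[3], id = trimws(parts[1]), source = parts[2],
               canonical = canonical)
  })
  ruleset(rules)
}

#' @param rs a [ruleset()].
#' @rdname read_ruleset
#' @export
write_ruleset <- function(rs, path) {
  stopifnot(inherits(rs, "ruleset"))
  lines <- vapply(rs$rules, function(r) {
    paste(r$id,
          if (length(r$source)) paste(r$source, collapse = "/") else "unknown",
          format_rule(r), sep = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}

#' Structured (JSON) rule serialization
#'
#' A key-value document whose numeric thresholds are stored as
#' shortest-round-trip decimal strings, so that
#' `rules_from_json(rules_to_json(rs))` reproduces every threshold
#' bit-exactly.
#'
#' @param rs a [ruleset()].
#' @param path optional file; when `NULL` the JSON string is returned.
#' @return JSON string (or `path`, invisibly).
#' @export
rules_to_json <- function(rs, path = NULL) {
  stopifnot(inherits(rs, "ruleset"))
  doc <- list(feature_vocabulary = rs$feature_vocabulary,
              rules = lapply(rs$rules, function(r) {
                out <- list(id = r$id, source = as.list(r$source))
                if (!is.na(r$weight)) out$weight <- fmt_num(r$weight)
                if (!is.na(r$tree)) out$tree <- r$tree
                out$conditions <- lapply(r$conditions, function(cn) {
                       out <- list(feature = cn$feature, op = cn$op)
                       if (cn$op %in% c("LE", "GT")) out$threshold <- fmt_num(cn$threshold)
                       if (cn$op == "INTERVAL") {
                         out$lower <- fmt_num(cn$lower); out$upper <- fmt_num(cn$upper)
                       }
                       if (cn$op == "FLAG_EQ") out$value <- cn$value
                       out
                     })
                out
              }))
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path, useBytes = TRUE)
  invisible(path)
}

#' @param json JSON string or path to a JSON file.
#' @rdname rules_to_json
#' @export
rules_from_json <- function(json) {
  if (length(json) == 1 && !grepl("\\{", json)) json <- paste(readLines(json, encoding = "UTF-8"), collapse = "\n")
  doc <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  rules <- lapply(doc$rules, function(r) {
    conds <- lapply(r$conditions, function(cn) {
      new_condition(cn$feature, cn$op,
                    threshold = if (!is.null(cn$threshold)) as.numeric(cn$threshold) else NA_real_,
                    lower = if (!is.null(cn$lower)) as.numeric(cn$lower) else NA_real_,
                    upper = if (!is.null(cn$upper)) as.numeric(cn$upper) else NA_real_,
                    value = if (!is.null(cn$value)) as.integer(cn$value) else NA_integer_)
    })
    out <- new_rule(r$id, conds, source = unlist(r$source) %||% character(0),
                    weight = if (!is.null(r$weight)) as.numeric(r$weight) else NA_real_,
                    tree = if (!is.null(r$tree)) as.integer(r$tree) else NA_integer_)
    attr(out, "canonical") <- TRUE
    out
  })
  ruleset(rules, feature_vocabulary = unlist(doc$feature_vocabulary))
}
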