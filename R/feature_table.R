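#' Construct a feature table
#'
#' The basic data container of the package: a samples x features numeric
#' matrix with named columns, a per-column kind (`"continuous"` or
#' `"binary"`), and an optional binary outcome vector (1 = invasive
#' adenocarcinoma, 0 = pre-invasive).
#'
#' @param data data.frame or matrix of numeric feature columns with unique
#'   column names.
#' @param labels optional 0/1 outcome vector, one per row.
#' @param kind optional character vector (`"continuous"`/`"binary"`) per
#'   column; inferred from the data when `NULL` (a column whose non-missing
#'   values are all 0/1 is binary).
#' @param sample_ids optional sample identifiers; default row names or
#'   `s1..sn`.
#' @return An object of class `feature_table` with elements `data`
#'   (data.frame), `labels`, `kind`, `sample_ids`.
#' @examples
#' ft <- feature_table(data.frame(x = c(1, 2, 3), flag = c(0, 1, 1)),
#'                     labels = c(0, 1, 1))
#' ft$kind
#' @export
feature_table <- function(data, labels = NULL, kind = NULL, sample_ids = NULL) {
  data <- as.data.frame(data, check.names = FALSE)
  if (anyDuplicated(names(data)))
    stop("duplicate feature names: ",
         paste(unique(names(data)[duplicated(names(data))]), collapse = ", "))
  if (!all(vapply(data, is.numeric, logical(1))))
    stop("all feature columns must be numeric")
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != nrow(data))
      stop("labels length does not match sample count")
    if (!all(labels %in% c(0L, 1L)))
      stop("labels must be binary 0/1")
  }
  if (is.null(kind)) {
    kind <- ifelse(vapply(data, is_binary01, logical(1)), "binary", "continuous")
  } else {
    if (length(kind) != ncol(data)) stop("kind must have one entry per column")
    if (!all(kind %in% c("continuous", "binary"))) stop("invalid feature kind")
  }
  names(kind) <- names(data)
  for (nm in names(data)[kind == "binary"]) {
    if (!is_binary01(data[[nm]]))
      stop("binary feature '", nm, "' contains values outside {0,1}")
  }
  sample_ids <- sample_ids %||% rownames(data) %||% paste0("s", seq_len(nrow(data)))
  structure(list(data = data, labels = labels, kind = kind,
                 sample_ids = as.character(sample_ids)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d samples x %d features (%d continuous, %d binary)%s\n",
              nrow(x$data), ncol(x$data),
              sum(x$kind == "continuous"), sum(x$kind == "binary"),
              if (is.null(x$labels)) ", unlabeled"
              else sprintf(", prevalence %.3f", mean(x$labels))))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$data)

#' Read / write feature tables as delimited text
#'
#' Plain delimited text with a header row is the interchange format; the
#' outcome travels as an ordinary 0/1 column named by `label_col`.
#'
#' @param path file path.
#' @param label_col name of the outcome column (`NULL` for unlabeled tables).
#' @param sep field separator (comma default).
#' @return `read_feature_table` returns a [feature_table]; `write_feature_table`
#'   returns `path` invisibly.
#' @export
read_feature_table <- function(path, label_col = "outcome", sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "", fileEncoding = "UTF-8")
  labels <- NULL
  if (!is.null(label_col)) {
    if (!label_col %in% names(df))
      stop("label column '", label_col, "' not found in ", path)
    labels <- df[[label_col]]
    df[[label_col]] <- NULL
  }
  feature_table(df, labels = labels)
}

#' @param table a [feature_table].
#' @rdname read_feature_table
#' @export
write_feature_table <- function(table, path, label_col = "outcome", sep = ",") {
  stopifnot(inherits(table, "feature_table"))
  df <- table$data
  if (!is.null(table$labels)) df[[label_col]] <- table$labels
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

# subset rows of a feature table
ft_subset <- function(table, idx) {
  feature_table(table$data[idx, , drop = FALSE],
                labels = if (is.null(table$labels)) NULL else table$labels[idx],
                kind = unname(table$kind),
                sample_ids = table$sample_ids[idx])
}

# subset/reorder columns
ft_select <- function(table, features) {
  missing <- setdiff(features, names(table$data))
  if (length(missing))
    stop("features not in table: ", paste(missing, collapse = ", "))
  feature_table(table$data[, features, drop = FALSE],
                labels = table$labels,
                kind = unname(table$kind[features]),
                sample_ids = table$sample_ids)
}
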