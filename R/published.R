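#' The published 15-rule diagnostic model
#'
#' The package ships, as plain-text fixtures, the 15 decision rules of the
#' published invasive-adenocarcinoma diagnostic model (in the textual rule
#' dialect, with their method provenance) and the coefficients of the
#' published multivariate logistic equation over them (intercept -0.3265).
#'
#' @return `published_ruleset()`: the 15 rules as a [ruleset()];
#'   `published_model()`: the corresponding [diagnostic_model()] with the
#'   rule set attached.
#' @examples
#' m <- published_model()
#' m$intercept
#' ind <- matrix(0, 1, 15, dimnames = list(NULL, names(m$coefficients)))
#' linear_predictor(m, ind)   # all rules off: the bare intercept
#' @export
published_ruleset <- function() {
  path <- system.file("extdata", "published_rules.tsv", package = "rulefusion",
                      mustWork = TRUE)
  read_ruleset(path)
}

#' @rdname published_ruleset
#' @export
published_model <- function() {
  path <- system.file("extdata", "published_coefficients.tsv",
                      package = "rulefusion", mustWork = TRUE)
  co <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  vals <- stats::setNames(co$coefficient, co$term)
  diagnostic_model(vals[["(Intercept)"]],
                   vals[names(vals) != "(Intercept)"],
                   rs = published_ruleset())
}
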