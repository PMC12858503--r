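#' Categorisation rules for stratum construction
#'
#' A coding scheme is an ordered list of rules, one per stratum-defining
#' variable.  Rule order defines the digit order of the stratum code
#' (first rule = first digit).  Four rule kinds are supported:
#'
#' * `rule_fixed_props()` — split a continuous variable into ordered
#'   categories of fixed proportions (e.g. 20/60/20), categories labelled
#'   `1..k` from low to high value;
#' * `rule_quantiles()` — equal-count quantile split into `k` categories
#'   labelled `1..k` (tertiles with `k = 3`);
#' * `rule_threshold()` — binary split at a fixed cut, labelled `0`
#'   (below) / `1` (at or above);
#' * `rule_binary()` — pass-through of an existing 0/1 indicator.
#'
#' Cut points for the proportion/quantile rules are nearest-rank
#' empirical quantiles; values tied exactly at a cut point are assigned
#' to the lower category, so category sizes are reproducible.
#'
#' @param variable Column name in the area table the rule applies to.
#' @param props Numeric vector of category proportions summing to 1,
#'   ordered low to high value of the underlying variable.
#' @param k Number of equal-count categories.
#' @param cut Threshold; values `>= cut` are coded 1.
#' @param labels Optional human-readable category labels (length = number
#'   of categories), used in descriptor tables.
#' @return A rule object (list with class `eimm_rule`).
#' @examples
#' rule_fixed_props("imd_score", c(0.2, 0.6, 0.2),
#'                  labels = c("least deprived", "mid deprived", "most deprived"))
#' rule_quantiles("pct_minority", 3)
#' @name coding-rules
NULL

new_rule <- function(kind, variable, n_categories, categories, labels, params) {
  if (!is.character(variable) || length(variable) != 1L || !nzchar(variable))
    stop_config("rule requires a single non-empty variable name")
  if (is.null(labels)) labels <- as.character(categories)
  if (length(labels) != n_categories)
    stop_config(sprintf("rule for '%s': %d labels supplied for %d categories",
                        variable, length(labels), n_categories))
  structure(
    list(kind = kind, variable = variable, n_categories = n_categories,
         categories = categories, labels = labels, params = params),
    class = "eimm_rule")
}

#' @rdname coding-rules
#' @export
rule_fixed_props <- function(variable, props, labels = NULL) {
  props <- as.numeric(props)
  if (length(props) < 2L || any(props <= 0) || abs(sum(props) - 1) > 1e-8)
    stop_config("props must be >= 2 positive proportions summing to 1")
  k <- length(props)
  new_rule("fixed_props", variable, k, seq_len(k), labels, list(props = props))
}

#' @rdname coding-rules
#' @export
rule_quantiles <- function(variable, k, labels = NULL) {
  k <- as.integer(k)
  if (is.na(k) || k < 2L) stop_config("k must be an integer >= 2")
  new_rule("quantiles", variable, k, seq_len(k), labels,
           list(props = rep(1 / k, k)))
}

#' @rdname coding-rules
#' @export
rule_threshold <- function(variable, cut, labels = NULL) {
  cut <- as.numeric(cut)
  if (length(cut) != 1L || !is.finite(cut)) stop_config("cut must be a finite number")
  new_rule("threshold", variable, 2L, c(0L, 1L), labels, list(cut = cut))
}

#' @rdname coding-rules
#' @export
rule_binary <- function(variable, labels = NULL) {
  new_rule("binary", variable, 2L, c(0L, 1L), labels, list())
}

#' Assemble a coding scheme
#'
#' @param ... Rules created by [rule_fixed_props()], [rule_quantiles()],
#'   [rule_threshold()] or [rule_binary()], in stratum-code digit order.
#' @return An object of class `eimm_scheme`.
#' @seealso [default_scheme()] for the study's five-variable scheme.
#' @export
coding_scheme <- function(...) {
  rules <- list(...)
  if (length(rules) == 1L && is.list(rules[[1L]]) &&
      !inherits(rules[[1L]], "eimm_rule"))
    rules <- rules[[1L]]
  if (length(rules) == 0L) stop_config("a coding scheme needs at least one rule")
  ok <- vapply(rules, inherits, logical(1L), what = "eimm_rule")
  if (!all(ok)) stop_config("all arguments must be rule objects")
  vars <- vapply(rules, `[[`, character(1L), "variable")
  if (anyDuplicated(vars))
    stop_config("each variable may appear in at most one rule")
  names(rules) <- vars
  structure(list(rules = rules), class = "eimm_scheme")
}

#' Default coding scheme of the national NOx study
#'
#' Digit order (left to right): deprivation (IMD score split 20/60/20,
#' 1 = least deprived fifth, 3 = most deprived fifth), % minority ethnic
#' (tertiles 1–3), % degree-educated (tertiles 1–3), rural/urban
#' indicator (0 rural, 1 urban; only when `include_urban = TRUE`), and an
#' ageing flag (1 when 25% or more of residents are aged 65+).  Higher
#' IMD score means more deprived, so the most deprived fifth is the top
#' quintile of the score.
#'
#' @param include_urban Include the rural/urban digit (the five-variable
#'   scheme, 108 possible strata).  With `FALSE` the four-variable scheme
#'   (54 possible strata) is returned.
#' @return An `eimm_scheme`.
#' @export
default_scheme <- function(include_urban = TRUE) {
  rules <- list(
    rule_fixed_props("imd_score", c(0.2, 0.6, 0.2),
                     labels = c("least deprived", "mid deprived", "most deprived")),
    rule_quantiles("pct_minority", 3,
                   labels = c("low % minority ethnic", "medium % minority ethnic",
                              "high % minority ethnic")),
    rule_quantiles("pct_degree", 3,
                   labels = c("low education", "medium education", "high education")))
  if (include_urban)
    rules <- c(rules, list(rule_binary("urban", labels = c("rural", "urban"))))
  rules <- c(rules, list(rule_threshold("pct_65plus", 25,
                                        labels = c("not ageing", "ageing"))))
  coding_scheme(rules)
}

#' @export
print.eimm_scheme <- function(x, ...) {
  cat("Coding scheme:", length(x$rules), "rules,",
      count_possible_strata(x), "possible strata\n")
  for (i in seq_along(x$rules)) {
    r <- x$rules[[i]]
    cat(sprintf("  digit %d: %s [%s, %d categories]\n",
                i, r$variable, r$kind, r$n_categories))
  }
  invisible(x)
}

#' Number of structurally possible strata under a scheme
#'
#' The product of the category counts across the scheme's rules.
#'
#' @param scheme An `eimm_scheme`.
#' @return Integer count of possible stratum codes.
#' @examples
#' count_possible_strata(default_scheme(TRUE))   # 108
#' count_possible_strata(default_scheme(FALSE))  # 54
#' @export
count_possible_strata <- function(scheme) {
  stopifnot(inherits(scheme, "eimm_scheme"))
  prod(vapply(scheme$rules, `[[`, integer(1L), "n_categories"))
}

# Apply one rule to a numeric vector, returning integer category labels.
apply_rule <- function(rule, x, area_id) {
  bad <- !is.finite(x)
  if (any(bad))
    stop_data(sprintf("non-numeric or missing value in '%s' for area(s): %s",
                      rule$variable,
                      paste(utils::head(area_id[bad], 5L), collapse = ", ")))
  switch(rule$kind,
    binary = {
      if (!all(x %in% c(0, 1)))
        stop_data(sprintf("'%s' must be 0/1 for a binary rule", rule$variable))
      as.integer(x)
    },
    threshold = as.integer(x >= rule$params$cut),
    fixed_props = ,
    quantiles = {
      k <- rule$n_categories
      if (length(unique(x)) < k)
        stop_data(sprintf("'%s' has fewer than %d distinct values", rule$variable, k))
      cuts <- nearest_rank_cuts(x, cumsum(rule$params$props)[-k])
      # ties at a cut point fall in the lower category
      1L + vapply(x, function(v) sum(v > cuts), integer(1L))
    },
    stop_config(sprintf("unknown rule kind '%s'", rule$kind)))
}

# Nearest-rank empirical quantiles: the value at rank ceiling(p * n).
nearest_rank_cuts <- function(x, probs) {
  xs <- sort(x)
  xs[pmin(length(xs), pmax(1L, ceiling(probs * length(xs))))]
}
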