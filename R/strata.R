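#' Assign every area to an intersectional stratum
#'
#' Applies each rule of the coding scheme to its covariate and
#' concatenates the resulting category labels, in rule order, into a
#' stratum code — one digit per rule.  For the default five-variable
#' scheme, code `21301` reads: mid deprivation (2), low % minority
#' ethnic (1), high education (3), rural (0), ageing (1).
#'
#' @param table An area table (see [as_area_table()]).
#' @param scheme An `eimm_scheme`.
#' @return An object of class `eimm_strata` with components:
#'   \describe{
#'     \item{assignment}{data frame `(area_id, code)`, one row per area,
#'       in the row order of `table`.}
#'     \item{registry}{data frame of occupied strata: `code`, index `j`,
#'       member count `n_j`, and one integer category column per rule
#'       variable.}
#'     \item{empty_codes}{character vector of structurally possible but
#'       unoccupied codes.}
#'     \item{scheme}{the scheme used.}
#'   }
#' @export
categorize <- function(table, scheme) {
  stopifnot(inherits(scheme, "eimm_scheme"))
  if (!inherits(table, "eimm_area_table"))
    table <- as_area_table(table, require = "area_id")
  vars <- vapply(scheme$rules, `[[`, character(1L), "variable")
  miss <- setdiff(vars, names(table))
  if (length(miss))
    stop_config(paste0("scheme references column(s) absent from the table: ",
                       paste(miss, collapse = ", ")))

  cats <- lapply(scheme$rules, function(r)
    apply_rule(r, as.numeric(table[[r$variable]]), table$area_id))
  cat_mat <- do.call(cbind, cats)
  colnames(cat_mat) <- vars
  codes <- apply(cat_mat, 1L, paste, collapse = "")

  possible <- possible_codes(scheme)
  occ <- sort(unique(codes))
  registry <- data.frame(code = occ,
                         j = seq_along(occ),
                         n_j = as.integer(table(factor(codes, levels = occ))),
                         stringsAsFactors = FALSE)
  digit_cols <- decode_codes(occ, scheme)
  registry <- cbind(registry, digit_cols)
  rownames(registry) <- NULL

  structure(
    list(assignment = data.frame(area_id = table$area_id, code = codes,
                                 stringsAsFactors = FALSE),
         registry = registry,
         empty_codes = setdiff(possible, occ),
         scheme = scheme),
    class = "eimm_strata")
}

#' @export
print.eimm_strata <- function(x, ...) {
  cat(sprintf("Stratum assignment: %d areas in %d occupied strata (%d possible, %d empty)\n",
              nrow(x$assignment), nrow(x$registry),
              count_possible_strata(x$scheme), length(x$empty_codes)))
  invisible(x)
}

# All structurally possible codes, in lexicographic digit order.
possible_codes <- function(scheme) {
  cats <- lapply(scheme$rules, `[[`, "categories")
  grid <- expand.grid(rev(cats), KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, rev(seq_along(cats)), drop = FALSE]
  sort(apply(grid, 1L, paste, collapse = ""))
}

# Split codes back into one integer category column per rule variable.
decode_codes <- function(codes, scheme) {
  vars <- vapply(scheme$rules, `[[`, character(1L), "variable")
  out <- as.data.frame(matrix(NA_integer_, nrow = length(codes),
                              ncol = length(vars)))
  names(out) <- vars
  for (i in seq_along(vars))
    out[[i]] <- as.integer(substr(codes, i, i))
  out
}

# Human-readable label for one stratum code under a scheme.
describe_code <- function(code, scheme) {
  vars <- vapply(scheme$rules, `[[`, character(1L), "variable")
  parts <- character(length(vars))
  for (i in seq_along(vars)) {
    r <- scheme$rules[[i]]
    d <- as.integer(substr(code, i, i))
    parts[i] <- r$labels[match(d, r$categories)]
  }
  paste(parts, collapse = ", ")
}

#' Write stratum assignment and registry to CSV
#'
#' @param strata An `eimm_strata`.
#' @param assignment_path,registry_path Output CSV paths.
#' @return Invisibly, the paths written.
#' @export
write_strata <- function(strata, assignment_path, registry_path) {
  stopifnot(inherits(strata, "eimm_strata"))
  utils::write.csv(strata$assignment, assignment_path, row.names = FALSE)
  utils::write.csv(strata$registry[, c("code", "n_j")], registry_path,
                   row.names = FALSE)
  invisible(c(assignment_path, registry_path))
}
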