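#' Validate an area-level table
#'
#' The analysis operates on one row per geographic area with a continuous
#' outcome (annual mean pollutant concentration, µg m⁻³) and the
#' stratum-defining covariates.  `as_area_table()` checks structure and
#' invariants and returns the table with class `eimm_area_table`.
#'
#' Required columns (renameable via `columns`): `area_id`, `outcome`,
#' plus whatever columns the coding scheme in use references (the default
#' scheme needs `imd_score`, `pct_minority`, `pct_degree`, `urban`,
#' `pct_65plus`).
#'
#' @param x A data frame.
#' @param columns Optional named character vector mapping canonical names
#'   to the column names present in `x`, e.g.
#'   `c(outcome = "nox", area_id = "lsoa")`.
#' @param require Character vector of canonical columns that must exist;
#'   defaults to `area_id` and `outcome`.
#' @return `x` (renamed to canonical columns) with class `eimm_area_table`.
#' @export
as_area_table <- function(x, columns = NULL,
                          require = c("area_id", "outcome")) {
  if (!is.data.frame(x)) stop_config("area table must be a data frame")
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (!is.null(columns)) {
    for (canon in names(columns)) {
      src <- columns[[canon]]
      if (!src %in% names(x))
        stop_config(sprintf("mapped column '%s' (for '%s') not found", src, canon))
      names(x)[names(x) == src] <- canon
    }
  }
  miss <- setdiff(require, names(x))
  if (length(miss))
    stop_config(paste0("missing required column(s): ",
                       paste(miss, collapse = ", ")))
  x$area_id <- as.character(x$area_id)
  if (anyDuplicated(x$area_id))
    stop_data("area_id values must be unique")
  if ("outcome" %in% names(x) && !is.numeric(x$outcome))
    stop_data("outcome must be numeric")
  for (pc in intersect(c("pct_minority", "pct_degree", "pct_65plus"), names(x))) {
    v <- x[[pc]]
    if (any(is.finite(v) & (v < 0 | v > 100)))
      stop_data(sprintf("'%s' must lie in [0, 100]", pc))
  }
  if ("urban" %in% names(x) && !all(x$urban %in% c(0, 1, NA)))
    stop_data("'urban' must be a 0/1 indicator")
  class(x) <- unique(c("eimm_area_table", class(x)))
  x
}

#' Read an area table from CSV
#'
#' @param path CSV file with a header row.
#' @inheritParams as_area_table
#' @return An `eimm_area_table`.
#' @export
read_area_table <- function(path, columns = NULL,
                            require = c("area_id", "outcome")) {
  if (!file.exists(path)) stop_config(sprintf("input file not found: %s", path))
  as_area_table(utils::read.csv(path, stringsAsFactors = FALSE),
                columns = columns, require = require)
}

# ---- condition helpers ----------------------------------------------------

stop_config <- function(msg) {
  stop(structure(class = c("eimm_config_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

stop_data <- function(msg) {
  stop(structure(class = c("eimm_data_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

stop_fit <- function(msg) {
  stop(structure(class = c("eimm_fit_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
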