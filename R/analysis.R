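#' Variance partition coefficient
#'
#' Share of total outcome variance attributable to between-stratum
#' differences: \eqn{VPC = \sigma_u^2 / (\sigma_u^2 + \sigma_e^2)}.
#' From a null model it measures total intersectional clustering; from a
#' main-effects model it measures residual clustering attributed to
#' interaction effects.
#'
#' @param sigma2_u Between-stratum variance (`>= 0`).
#' @param sigma2_e Within-stratum variance (`> 0`).
#' @return The VPC as a proportion in `[0, 1]`.
#' @examples
#' vpc(42.06, 51.67)  # 0.4487...
#' @export
vpc <- function(sigma2_u, sigma2_e) {
  if (any(sigma2_u < 0)) stop_config("sigma2_u must be >= 0")
  if (any(sigma2_u + sigma2_e <= 0))
    stop_config("VPC undefined when both variances are zero")
  if (any(sigma2_e < 0)) stop_config("sigma2_e must be >= 0")
  sigma2_u / (sigma2_u + sigma2_e)
}

#' Proportional change in variance
#'
#' Fraction of the null model's between-stratum variance accounted for
#' by additive fixed effects:
#' \eqn{PCV = (\sigma_{u,null}^2 - \sigma_{u,adj}^2) / \sigma_{u,null}^2}.
#' May be negative (adjusted variance larger than the null's); negative
#' values are reported as-is, never clipped.
#'
#' @param sigma2_u_null Between-stratum variance of the null model (`> 0`).
#' @param sigma2_u_adjusted Between-stratum variance of the adjusted model.
#' @return The PCV as a proportion (`<= 1`).
#' @examples
#' pcv(42.06, 9.37)  # 0.7772...
#' @export
pcv <- function(sigma2_u_null, sigma2_u_adjusted) {
  if (any(sigma2_u_null <= 0))
    stop_config("PCV requires a positive null between-stratum variance")
  (sigma2_u_null - sigma2_u_adjusted) / sigma2_u_null
}

#' Round half-up and format a proportion as a percentage
#'
#' @param x Proportion(s).
#' @param digits Decimal places (default 2, half-up).
#' @return Numeric percentage(s).
#' @export
as_percent <- function(x, digits = 2L) {
  p <- x * 100
  floor(abs(p) * 10^digits + 0.5) / 10^digits * sign(p)
}

#' Ranked stratum prediction table
#'
#' Predicted mean for stratum j = fixed part at the stratum's covariate
#' pattern + its shrunken residual \eqn{\hat u_j}.  The 95% interval uses
#' the EB posterior (comparative) SD only; fixed-part uncertainty is not
#' propagated.  Sorted descending by prediction; rank ties broken by
#' stratum code (lexicographic).
#'
#' @param fit An `eimm_fit`.
#' @param effects The matching [eb_residuals()] table.
#' @return Data frame `(code, n_j, fixed_part, u_hat, predicted, lower,
#'   upper, rank)` sorted by rank.
#' @export
predict_strata <- function(fit, effects = eb_residuals(fit)) {
  stopifnot(inherits(fit, "eimm_fit"))
  if (!identical(effects$code, fit$stratum$code))
    stop_config("effects table does not match the fit's stratum registry")
  fixed <- drop(fit$stratum$X %*% fit$beta)
  pred <- fixed + effects$u_hat
  out <- data.frame(code = fit$stratum$code, n_j = fit$stratum$n,
                    fixed_part = fixed, u_hat = effects$u_hat,
                    predicted = pred,
                    lower = pred - 1.96 * effects$se_u,
                    upper = pred + 1.96 * effects$se_u,
                    stringsAsFactors = FALSE)
  ord <- order(-out$predicted, out$code)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Strata with statistically significant interaction effects
#'
#' A stratum is flagged when the 95% interval of its shrunken residual
#' excludes zero (the 1.96 rule; no multiplicity correction).
#'
#' @param effects An `eimm_effects` table.
#' @return The flagged subset, ordered by `u_hat` (descending), with a
#'   `sign` column.
#' @export
flag_interactions <- function(effects) {
  stopifnot(is.data.frame(effects))
  out <- effects[effects$lower > 0 | effects$upper < 0, , drop = FALSE]
  out$sign <- ifelse(out$u_hat > 0, "positive", "negative")
  out <- out[order(-out$u_hat, out$code), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full EIM model sequence
#'
#' Fits, in order: 1a (null, four-variable strata), 1b (main effects),
#' 2a (null, five-variable strata including the rural/urban digit),
#' 2b (main effects), and optionally 3 (2b plus a two-way interaction,
#' by default % minority ethnic × urban).  PCVs are computed for 1b vs
#' 1a, 2b vs 2a and 3 vs 2a — only between models sharing a stratum
#' structure.
#'
#' @param table Area table with outcome and the five default covariates.
#' @param scheme_without_urban,scheme_with_urban Coding schemes; default
#'   to [default_scheme()].
#' @param interaction Length-2 character vector naming the Model 3
#'   interaction pair, or `NULL` to skip Model 3.
#' @param top_k Rows in the top/bottom descriptor tables.
#' @return An object of class `eimm_sequence`: a named list of per-model
#'   results (`fit`, `effects`, `predictions`, `summary`) plus a
#'   `comparison` data frame across models.
#' @export
run_model_sequence <- function(table,
                               scheme_without_urban = default_scheme(FALSE),
                               scheme_with_urban = default_scheme(TRUE),
                               interaction = c("pct_minority", "urban"),
                               top_k = 10L) {
  if (!inherits(table, "eimm_area_table"))
    table <- as_area_table(table, require = c("area_id", "outcome"))
  strata4 <- categorize(table, scheme_without_urban)
  strata5 <- categorize(table, scheme_with_urban)
  vars4 <- vapply(scheme_without_urban$rules, `[[`, character(1L), "variable")
  vars5 <- vapply(scheme_with_urban$rules, `[[`, character(1L), "variable")

  specs <- list(
    "1a" = list(strata = strata4, model = model_spec(label = "1a")),
    "1b" = list(strata = strata4, model = model_spec(vars4, label = "1b")),
    "2a" = list(strata = strata5, model = model_spec(label = "2a")),
    "2b" = list(strata = strata5, model = model_spec(vars5, label = "2b")))
  if (!is.null(interaction))
    specs[["3"]] <- list(strata = strata5,
                         model = model_spec(vars5, list(interaction), label = "3"))
  null_of <- c("1a" = NA, "1b" = "1a", "2a" = NA, "2b" = "2a", "3" = "2a")

  models <- list()
  for (lab in names(specs)) {
    sp <- specs[[lab]]
    fit <- tryCatch(fit_eim(table, sp$strata, sp$model),
                    error = function(e) stop_fit(
                      sprintf("model %s: %s", lab, conditionMessage(e))))
    eff <- eb_residuals(fit)
    preds <- predict_strata(fit, eff)
    nl <- null_of[[lab]]
    pcv_val <- if (!is.na(nl)) pcv(models[[nl]]$fit$sigma2_u, fit$sigma2_u)
               else NA_real_
    models[[lab]] <- list(
      fit = fit, effects = eff, predictions = preds,
      summary = eim_summary(lab, fit, eff, preds, pcv_val,
                            sp$strata$scheme, top_k))
  }

  comparison <- do.call(rbind, lapply(names(models), function(lab) {
    s <- models[[lab]]$summary
    f <- models[[lab]]$fit
    data.frame(model = lab,
               n_areas = f$n_areas, n_strata = f$n_strata_occupied,
               sigma2_u = f$sigma2_u, sigma2_e = f$sigma2_e,
               loglik = f$loglik, aic = f$aic,
               vpc_pct = s$vpc_pct, pcv_pct = s$pcv_pct,
               n_significant = nrow(s$significant),
               stringsAsFactors = FALSE)
  }))
  structure(list(models = models, comparison = comparison),
            class = "eimm_sequence")
}

# Per-model intersectional summary: VPC, PCV, ranked predictions,
# significant strata, top/bottom descriptor tables.
eim_summary <- function(label, fit, effects, predictions, pcv_val,
                        scheme, top_k) {
  describe <- function(tab) {
    tab$description <- vapply(tab$code, describe_code, character(1L),
                              scheme = scheme)
    tab
  }
  k <- min(top_k, nrow(predictions))
  list(label = label,
       vpc = vpc(fit$sigma2_u, fit$sigma2_e),
       vpc_pct = as_percent(vpc(fit$sigma2_u, fit$sigma2_e)),
       pcv = pcv_val,
       pcv_pct = if (is.na(pcv_val)) NA_real_ else as_percent(pcv_val),
       significant = flag_interactions(effects),
       top = describe(utils::head(predictions, k)),
       bottom = describe(utils::tail(predictions, k)))
}

#' @export
print.eimm_sequence <- function(x, ...) {
  cat("EIM model sequence\n")
  cmp <- x$comparison
  cmp$sigma2_u <- round(cmp$sigma2_u, 2); cmp$sigma2_e <- round(cmp$sigma2_e, 2)
  cmp$loglik <- round(cmp$loglik, 1); cmp$aic <- round(cmp$aic, 1)
  print(cmp, row.names = FALSE)
  invisible(x)
}
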