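#' Fixed-effect specification for an EIM model
#'
#' The fixed part always contains an intercept.  `effects` names
#' stratum-defining variables whose categories enter as dummy variables
#' against the reference category (the lowest category label: least
#' deprived, low % minority ethnic, low education, rural, not ageing
#' under the default scheme).  `interactions` lists pairs of effect
#' variables whose non-reference dummy products are added (e.g. the
#' % minority ethnic × urban interaction).
#'
#' @param effects Character vector of variable names, or `NULL` for the
#'   null (intercept-only) model.
#' @param interactions Optional list of length-2 character vectors.
#' @param label Optional model label used in reports (e.g. "2b").
#' @return An object of class `eimm_model_spec`.
#' @export
model_spec <- function(effects = NULL, interactions = NULL, label = NULL) {
  if (!is.null(effects)) effects <- as.character(effects)
  if (!is.null(interactions)) {
    if (!is.list(interactions)) interactions <- list(interactions)
    for (pr in interactions) {
      if (length(pr) != 2L)
        stop_config("each interaction must name exactly two variables")
      if (!all(pr %in% effects))
        stop_config(sprintf("interaction %s * %s requires both main effects",
                            pr[1L], pr[2L]))
    }
  }
  structure(list(effects = effects, interactions = interactions, label = label),
            class = "eimm_model_spec")
}

# Design matrix with one row per occupied stratum (stratum-defining
# covariates are constant within a stratum, so this is the full fixed
# design up to row multiplicity n_j).
build_design <- function(registry, scheme, spec) {
  J <- nrow(registry)
  X <- matrix(1, nrow = J, ncol = 1L, dimnames = list(NULL, "(Intercept)"))
  dummy_cols <- list()  # variable -> named matrix of non-reference dummies
  for (v in spec$effects) {
    r <- scheme$rules[[v]]
    if (is.null(r))
      stop_config(sprintf("effect '%s' is not a scheme variable", v))
    ref <- r$categories[1L]
    dm <- NULL
    for (cat in r$categories[-1L]) {
      col <- as.numeric(registry[[v]] == cat)
      dm <- cbind(dm, col)
      colnames(dm)[ncol(dm)] <- paste0(v, cat)
    }
    dummy_cols[[v]] <- dm
    X <- cbind(X, dm)
  }
  for (pr in spec$interactions) {
    a <- dummy_cols[[pr[1L]]]; b <- dummy_cols[[pr[2L]]]
    for (i in seq_len(ncol(a))) for (k in seq_len(ncol(b))) {
      X <- cbind(X, a[, i] * b[, k])
      colnames(X)[ncol(X)] <- paste0(colnames(a)[i], ":", colnames(b)[k])
    }
  }
  X
}

# Per-stratum sufficient statistics aligned with the registry row order:
# n_j, stratum mean of y, within-stratum sum of squares.
stratum_stats <- function(table, strata) {
  idx <- match(table$area_id, strata$assignment$area_id)
  if (anyNA(idx))
    stop_data("area(s) in the table are missing from the stratum assignment")
  code <- strata$assignment$code[idx]
  y <- table$outcome
  if (anyNA(y))
    stop_data(sprintf("missing outcome for area(s): %s",
                      paste(utils::head(table$area_id[is.na(y)], 5L),
                            collapse = ", ")))
  f <- factor(code, levels = strata$registry$code)
  if (anyNA(f))
    stop_data("assignment contains codes absent from the registry")
  n <- as.integer(table(f))
  sum_y <- as.numeric(rowsum(y, f))
  ybar <- sum_y / n
  ssw <- as.numeric(rowsum(y^2, f)) - n * ybar^2
  list(n = n, ybar = ybar, ssw = pmax(ssw, 0), N = length(y))
}

# Profiled marginal log-likelihood under compound symmetry, evaluated
# from sufficient statistics.  beta is profiled out by GLS.  Returns the
# log-likelihood with beta, stratum-mean residuals and GLS pieces as
# attributes.
profiled_loglik <- function(s2u, s2e, st, X) {
  lam <- s2e + st$n * s2u            # Var of a stratum total's mean * n
  w <- st$n / lam
  XtW <- t(X * w)
  M <- XtW %*% X
  beta <- tryCatch(solve(M, XtW %*% st$ybar),
                   error = function(e) stop_fit(
                     "singular generalised-least-squares system"))
  rbar <- st$ybar - drop(X %*% beta)
  ll <- -0.5 * (st$N * log(2 * pi) +
                (st$N - length(st$n)) * log(s2e) +
                sum(log(lam)) +
                sum(st$ssw) / s2e +
                sum(st$n * rbar^2 / lam))
  attr(ll, "beta") <- drop(beta)
  attr(ll, "rbar") <- rbar
  attr(ll, "XtWX") <- M
  ll
}

#' Evaluate the profiled marginal log-likelihood at given variances
#'
#' Exposes the exact two-level Gaussian marginal log-likelihood (fixed
#' effects profiled out by generalised least squares) as a function of
#' the between-stratum variance `sigma2_u` and within-stratum variance
#' `sigma2_e`.  [fit_eim()] maximises this same surface; at the fitted
#' variances the two agree to numerical precision.
#'
#' @param sigma2_u Between-stratum variance, `>= 0`.
#' @param sigma2_e Within-stratum variance, `> 0`.
#' @param table Area table with outcomes.
#' @param strata An `eimm_strata` for the same areas.
#' @param model An `eimm_model_spec`.
#' @return The log-likelihood (numeric scalar).
#' @export
loglik_at <- function(sigma2_u, sigma2_e, table, strata, model = model_spec()) {
  if (!is.finite(sigma2_u) || sigma2_u < 0)
    stop_config("sigma2_u must be >= 0")
  if (!is.finite(sigma2_e) || sigma2_e <= 0)
    stop_config("sigma2_e must be > 0")
  st <- stratum_stats(table, strata)
  X <- build_design(strata$registry, strata$scheme, model)
  as.numeric(profiled_loglik(sigma2_u, sigma2_e, st, X))
}

#' Fit a two-level random-intercept model by maximum likelihood
#'
#' Areas (level 1) are nested in intersectional strata (level 2):
#' \deqn{y_{ij} = x_j'\beta + u_j + e_{ij}, \quad
#'       u_j \sim N(0, \sigma_u^2), \quad e_{ij} \sim N(0, \sigma_e^2)}
#' The marginal likelihood is evaluated per stratum in closed form from
#' sufficient statistics (stratum size, stratum mean, within-stratum sum
#' of squares) under the compound-symmetry covariance; \eqn{\beta} is
#' profiled out by GLS at each variance evaluation and the two variances
#' are maximised numerically on the log scale, with the
#' \eqn{\sigma_u^2 = 0} boundary handled explicitly (closed-form
#' profile).  Estimation is ML, not REML, so variance components are
#' comparable across fixed-effect specifications (as required by the
#' PCV).
#'
#' @inheritParams loglik_at
#' @param max_iter Maximum optimiser iterations.
#' @param reltol Relative convergence tolerance on the log-likelihood.
#' @return An object of class `eimm_fit` with elements `beta`, `se_beta`,
#'   `ci95_beta`, `p_beta`, `sigma2_u`, `sigma2_e`, `loglik`, `aic`,
#'   `n_areas`, `n_strata_occupied`, boundary flags, convergence info,
#'   and internal per-stratum statistics reused by [eb_residuals()].
#' @export
fit_eim <- function(table, strata, model = model_spec(),
                    max_iter = 2000L, reltol = 1e-12) {
  stopifnot(inherits(strata, "eimm_strata"), inherits(model, "eimm_model_spec"))
  if (!inherits(table, "eimm_area_table")) table <- as_area_table(table)
  st <- stratum_stats(table, strata)
  J <- length(st$n)
  if (J < 2L) stop_fit("at least 2 occupied strata are required")
  X <- build_design(strata$registry, strata$scheme, model)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop_fit(paste0("design matrix is singular; collinear term(s): ",
                    paste(dropped, collapse = ", ")))
  }
  p <- ncol(X)

  # Degenerate zero-variance input: every residual is exactly zero.
  ols_beta <- qr.coef(qrX, st$ybar)  # unweighted start (pattern-level)
  tot_var <- sum(st$ssw) + sum(st$n * (st$ybar - drop(X %*% ols_beta))^2)
  if (tot_var < 1e-12 * max(1, mean(abs(st$ybar)))^2) {
    beta <- ols_beta
    se <- rep(0, p)
    return(new_fit(beta, se, 0, 0, loglik = Inf, p = p, st = st, X = X,
                   strata = strata, model = model, rbar = rep(0, J),
                   boundary_u = TRUE, boundary_e = TRUE,
                   convergence = list(converged = TRUE, iterations = 0L,
                                      message = "degenerate zero-variance input")))
  }

  # Moment-based start: within MS and between-stratum mean variance.
  s2e0 <- if (st$N > J) sum(st$ssw) / (st$N - J) else stats::var(st$ybar)
  s2e0 <- max(s2e0, 1e-8)
  rbar0 <- st$ybar - drop(X %*% ols_beta)
  s2u0 <- max(stats::var(rbar0) - s2e0 * mean(1 / st$n), s2e0 * 0.01, 1e-8)

  negll <- function(par) {
    val <- profiled_loglik(exp(par[1L]), exp(par[2L]), st, X)
    if (!is.finite(val)) return(1e300)
    -as.numeric(val)
  }
  opt <- stats::optim(c(log(s2u0), log(s2e0)), negll, method = "Nelder-Mead",
                      control = list(maxit = max_iter, reltol = reltol))
  # polish with a second start to guard against premature simplex collapse
  opt2 <- stats::optim(opt$par, negll, method = "Nelder-Mead",
                       control = list(maxit = max_iter, reltol = reltol))
  if (opt2$value < opt$value) opt <- opt2
  s2u <- exp(opt$par[1L]); s2e <- exp(opt$par[2L])
  ll_int <- -opt$value

  # Explicit sigma2_u = 0 boundary candidate: beta is then the n-weighted
  # OLS (independent of sigma2_e) and sigma2_e has a closed-form ML.
  w0 <- st$n
  M0 <- t(X * w0) %*% X
  beta0 <- drop(solve(M0, t(X * w0) %*% st$ybar))
  rbar_b <- st$ybar - drop(X %*% beta0)
  s2e_b <- (sum(st$ssw) + sum(st$n * rbar_b^2)) / st$N
  ll_b <- as.numeric(profiled_loglik(0, s2e_b, st, X))

  boundary_u <- FALSE
  if (ll_b >= ll_int - 1e-8 || s2u < 1e-10 * s2e) {
    s2u <- 0; s2e <- s2e_b
    ll <- profiled_loglik(0, s2e, st, X)
    boundary_u <- TRUE
  } else {
    ll <- profiled_loglik(s2u, s2e, st, X)
  }

  beta <- attr(ll, "beta")
  se <- sqrt(diag(solve(attr(ll, "XtWX"))))
  if (opt$convergence != 0L && !boundary_u)
    stop_fit(sprintf(
      "ML optimisation did not converge after %d iterations (last sigma2_u=%.6g, sigma2_e=%.6g, loglik=%.6g)",
      max_iter, s2u, s2e, as.numeric(ll)))

  new_fit(beta, se, s2u, s2e, loglik = as.numeric(ll), p = p, st = st, X = X,
          strata = strata, model = model, rbar = attr(ll, "rbar"),
          boundary_u = boundary_u, boundary_e = FALSE,
          convergence = list(converged = TRUE,
                             iterations = unname(opt$counts[1L]),
                             message = "converged"))
}

new_fit <- function(beta, se, s2u, s2e, loglik, p, st, X, strata, model,
                    rbar, boundary_u, boundary_e, convergence) {
  beta <- stats::setNames(as.numeric(beta), colnames(X))
  se <- stats::setNames(as.numeric(se), colnames(X))
  z <- ifelse(se > 0, beta / se, NA_real_)
  ci <- cbind(lower = beta - 1.96 * se, upper = beta + 1.96 * se)
  rownames(ci) <- colnames(X)
  structure(
    list(beta = beta, se_beta = se,
         ci95_beta = ci,
         p_beta = 2 * stats::pnorm(-abs(z)),
         sigma2_u = s2u, sigma2_e = s2e,
         loglik = loglik,
         aic = -2 * loglik + 2 * (p + 2),
         n_areas = st$N, n_strata_occupied = length(st$n),
         boundary_u = boundary_u, boundary_e = boundary_e,
         convergence = convergence,
         model = model,
         stratum = list(code = strata$registry$code, n = st$n,
                        ybar = st$ybar, ssw = st$ssw, rbar = rbar, X = X)),
    class = "eimm_fit")
}

#' @export
print.eimm_fit <- function(x, ...) {
  lab <- if (!is.null(x$model$label)) paste0(" [", x$model$label, "]") else ""
  cat(sprintf("Two-level random-intercept fit (ML)%s\n", lab))
  cat(sprintf("  areas: %d   occupied strata: %d\n", x$n_areas, x$n_strata_occupied))
  cat(sprintf("  sigma2_u = %.4f%s   sigma2_e = %.4f%s\n",
              x$sigma2_u, if (x$boundary_u) " (boundary)" else "",
              x$sigma2_e, if (x$boundary_e) " (boundary)" else ""))
  cat(sprintf("  loglik = %.4f   AIC = %.4f\n", x$loglik, x$aic))
  ce <- cbind(estimate = x$beta, se = x$se_beta, x$ci95_beta, p = x$p_beta)
  print(round(ce, 4))
  invisible(x)
}

#' Empirical-Bayes shrinkage of a raw stratum mean residual
#'
#' The posterior-mean stratum effect is the raw mean residual scaled by
#' the reliability \eqn{R_j = \sigma_u^2 / (\sigma_u^2 + \sigma_e^2/n_j)},
#' with comparative standard error \eqn{\sqrt{\sigma_u^2 (1 - R_j)}}.
#'
#' @param raw_mean Raw (unshrunken) stratum mean residual(s).
#' @param n_j Stratum size(s).
#' @param sigma2_u,sigma2_e Variance components.
#' @return Data frame with columns `raw_mean_resid`, `n_j`, `shrinkage`,
#'   `u_hat`, `se_u`, `lower`, `upper`.
#' @export
eb_shrinkage <- function(raw_mean, n_j, sigma2_u, sigma2_e) {
  if (sigma2_u < 0 || sigma2_e < 0) stop_config("variances must be non-negative")
  R <- if (sigma2_u == 0) rep(0, length(raw_mean))
       else sigma2_u / (sigma2_u + sigma2_e / n_j)
  u <- R * raw_mean
  se <- sqrt(sigma2_u * (1 - R))
  data.frame(raw_mean_resid = raw_mean, n_j = n_j, shrinkage = R,
             u_hat = u, se_u = se,
             lower = u - 1.96 * se, upper = u + 1.96 * se)
}

#' Empirical-Bayes stratum residuals ("interaction effects")
#'
#' For a main-effects model the shrunken stratum residual \eqn{\hat u_j}
#' is the model's estimate of the stratum's departure from its additively
#' predicted mean — the EIM/MAIHDA notion of an intersectional
#' interaction effect.  Residuals are shrunk towards zero in proportion
#' to their unreliability, so small strata are pulled in more.
#'
#' @param fit An `eimm_fit`.
#' @return An object of class `eimm_effects`: a data frame with one row
#'   per occupied stratum (`code`, `n_j`, `raw_mean_resid`, `shrinkage`,
#'   `u_hat`, `se_u`, `lower`, `upper`, `significant`), ordered as the
#'   stratum registry.
#' @export
eb_residuals <- function(fit) {
  stopifnot(inherits(fit, "eimm_fit"))
  tab <- eb_shrinkage(fit$stratum$rbar, fit$stratum$n,
                      fit$sigma2_u, fit$sigma2_e)
  out <- cbind(data.frame(code = fit$stratum$code, stringsAsFactors = FALSE),
               tab[, c("n_j", "raw_mean_resid", "shrinkage", "u_hat",
                       "se_u", "lower", "upper")])
  out$significant <- out$lower > 0 | out$upper < 0
  class(out) <- c("eimm_effects", "data.frame")
  out
}
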