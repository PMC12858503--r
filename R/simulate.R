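#' Configuration for the synthetic area-level generator
#'
#' The generator emulates the statistical structure of a national
#' small-area pollution dataset: one row per area with a continuous
#' outcome (µg m⁻³) and the five stratum-defining covariates.  The four
#' continuous covariates are drawn through a Gaussian copula with the
#' given latent correlation matrix; marginals are a right-skewed
#' lognormal for the deprivation score (mean above median, as in
#' published deprivation distributions) and Beta distributions (scaled
#' to 0–100) for the three percentage variables.  Urbanicity is a binary
#' indicator cut from its own latent normal at the configured
#' prevalence.
#'
#' The outcome for area i in stratum j is
#' `intercept + additive category effects + injected interaction effect
#' + u_j + e_ij` with `u_j ~ N(0, sigma2_u)` drawn once per structurally
#' possible stratum code and `e_ij ~ N(0, sigma2_e)`.
#'
#' @param n_areas Number of areas.
#' @param seed Integer seed; fully determines the output.
#' @param urban_prev Urban prevalence in (0, 1).
#' @param marginals Named list of marginal parameter lists; see defaults.
#' @param latent_cor Latent correlation matrix (5x5, order: imd_score,
#'   pct_minority, pct_degree, pct_65plus, urban).
#' @param intercept Fixed intercept (µg m⁻³).
#' @param effects Named list of per-category additive effects (first
#'   element of each vector is the reference category, effect 0).
#' @param sigma2_u Between-stratum variance (µg² m⁻⁶).
#' @param sigma2_e Within-stratum variance (µg² m⁻⁶).
#' @param interaction_effects Named numeric vector: stratum code ->
#'   injected interaction effect (µg m⁻³); `NULL` for none.
#' @param scheme Coding scheme used to derive stratum codes (and to key
#'   `interaction_effects` and the stratum draws).
#' @return An object of class `eimm_sim_config`.
#' @export
sim_config <- function(n_areas = 33755L,
                       seed = 1L,
                       urban_prev = 0.8294,
                       marginals = default_marginals(),
                       latent_cor = default_latent_cor(),
                       intercept = 10.75,
                       effects = default_effects(),
                       sigma2_u = 35,
                       sigma2_e = 50,
                       interaction_effects = NULL,
                       scheme = default_scheme(TRUE)) {
  n_areas <- as.integer(n_areas)
  if (is.na(n_areas) || n_areas < 1L) stop_config("n_areas must be >= 1")
  if (urban_prev <= 0 || urban_prev >= 1)
    stop_config("urban_prev must lie strictly in (0, 1)")
  if (sigma2_u < 0 || sigma2_e <= 0)
    stop_config("sigma2_u must be >= 0 and sigma2_e > 0")
  if (!is.null(interaction_effects) &&
      (is.null(names(interaction_effects)) || any(!nzchar(names(interaction_effects)))))
    stop_config("interaction_effects must be a named numeric vector keyed by stratum code")
  structure(list(n_areas = n_areas, seed = as.integer(seed),
                 urban_prev = urban_prev, marginals = marginals,
                 latent_cor = latent_cor, intercept = intercept,
                 effects = effects, sigma2_u = sigma2_u, sigma2_e = sigma2_e,
                 interaction_effects = interaction_effects, scheme = scheme),
            class = "eimm_sim_config")
}

#' @rdname sim_config
#' @export
default_marginals <- function() {
  list(
    # lognormal matched to mean 21.66, SD 15.27 (median ~17.7)
    imd_score  = list(dist = "lnorm", meanlog = 2.874, sdlog = 0.635),
    # Beta scaled to [0,100], moment-matched to published descriptives
    pct_minority = list(dist = "beta100", shape1 = 0.445, shape2 = 2.050),
    pct_degree   = list(dist = "beta100", shape1 = 4.295, shape2 = 8.480),
    pct_65plus   = list(dist = "beta100", shape1 = 3.780, shape2 = 16.20))
}

#' @rdname sim_config
#' @export
default_effects <- function() {
  list(imd_score  = c(0, 0.49, 1.65),
       pct_minority = c(0, 3.67, 10.68),
       pct_degree = c(0, -0.01, 0.37),
       urban      = c(0, 3.80),
       pct_65plus = c(0, -1.84))
}

#' @rdname sim_config
#' @export
default_latent_cor <- function() {
  v <- c("imd_score", "pct_minority", "pct_degree", "pct_65plus", "urban")
  R <- diag(5)
  dimnames(R) <- list(v, v)
  set_cor <- function(a, b, r) { R[a, b] <<- r; R[b, a] <<- r }
  set_cor("pct_minority", "urban",       0.50)
  set_cor("pct_minority", "pct_degree",  0.40)
  set_cor("pct_degree",   "urban",       0.20)
  set_cor("pct_65plus",   "urban",      -0.50)
  set_cor("pct_65plus",   "pct_minority", -0.40)
  set_cor("imd_score",    "pct_degree", -0.40)
  set_cor("imd_score",    "pct_minority", 0.30)
  set_cor("imd_score",    "pct_65plus", -0.20)
  set_cor("imd_score",    "urban",       0.15)
  set_cor("pct_degree",   "pct_65plus", -0.10)
  R
}

#' Study-like preset configuration
#'
#' Returns the generator configuration whose marginals, urban prevalence
#' (0.8294), additive effect sizes, intercept and variance components
#' (`sigma2_u = 35`, `sigma2_e = 50`) emulate the scale of the national
#' NOx study: ~33,755 areas, outcome mean ≈ 21 µg m⁻³ and SD ≈ 11,
#' most of the 108 possible strata occupied (unevenly, with some empty).
#'
#' @param n_areas Number of areas (default the study's 33,755).
#' @param seed Integer seed.
#' @param ... Overrides passed to [sim_config()].
#' @return An `eimm_sim_config`.
#' @export
preset_study_like <- function(n_areas = 33755L, seed = 1L, ...) {
  sim_config(n_areas = n_areas, seed = seed, ...)
}

#' Simulate an area-level dataset
#'
#' Draws covariates through the configured Gaussian copula, derives
#' stratum codes with the configured coding scheme, then builds the
#' outcome from the configured truth.  Stratum effects `u_j` are drawn
#' for every structurally possible code (in fixed code order), so the
#' realisation for a given code does not depend on which codes happen to
#' be occupied.  The RNG state of the caller is preserved.
#'
#' @param config An `eimm_sim_config`.
#' @return A list with components `table` (an [as_area_table()] data
#'   frame) and `truth` (the generating parameters and per-code stratum
#'   effects — kept on a separate channel so fitting code never sees it).
#' @export
simulate_areas <- function(config) {
  stopifnot(inherits(config, "eimm_sim_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())),
          add = TRUE)
  set.seed(config$seed)

  n <- config$n_areas
  vars <- c("imd_score", "pct_minority", "pct_degree", "pct_65plus", "urban")
  R <- config$latent_cor[vars, vars]
  L <- tryCatch(chol(R), error = function(e)
    stop_config("latent correlation matrix is not positive definite"))
  Z <- matrix(stats::rnorm(n * 5L), n, 5L) %*% L
  colnames(Z) <- vars
  U <- stats::pnorm(Z)

  qmarg <- function(u, m) {
    switch(m$dist,
      lnorm = stats::qlnorm(u, m$meanlog, m$sdlog),
      beta100 = 100 * stats::qbeta(u, m$shape1, m$shape2),
      stop_config(sprintf("unknown marginal distribution '%s'", m$dist)))
  }
  tab <- data.frame(
    area_id = sprintf("A%06d", seq_len(n)),
    imd_score = qmarg(U[, "imd_score"], config$marginals$imd_score),
    pct_minority = qmarg(U[, "pct_minority"], config$marginals$pct_minority),
    pct_degree = qmarg(U[, "pct_degree"], config$marginals$pct_degree),
    urban = as.integer(U[, "urban"] < config$urban_prev),
    pct_65plus = qmarg(U[, "pct_65plus"], config$marginals$pct_65plus),
    stringsAsFactors = FALSE)

  strata <- categorize(as_area_table(tab, require = "area_id"), config$scheme)
  codes <- strata$assignment$code

  all_codes <- possible_codes(config$scheme)
  u_all <- stats::rnorm(length(all_codes), 0, sqrt(config$sigma2_u))
  names(u_all) <- all_codes

  inter <- config$interaction_effects
  if (!is.null(inter)) {
    unreachable <- setdiff(names(inter), all_codes)
    if (length(unreachable))
      warning(sprintf("interaction effect(s) on structurally impossible code(s): %s",
                      paste(unreachable, collapse = ", ")))
    unocc <- setdiff(intersect(names(inter), all_codes), codes)
    if (length(unocc))
      warning(sprintf("interaction effect(s) on unoccupied code(s): %s",
                      paste(unocc, collapse = ", ")))
  }

  additive <- additive_effects(strata, config)[match(codes, strata$registry$code)]
  inter_term <- if (is.null(inter)) 0 else {
    v <- inter[codes]; v[is.na(v)] <- 0; as.numeric(v)
  }
  tab$outcome <- config$intercept + additive + inter_term +
    u_all[codes] + stats::rnorm(n, 0, sqrt(config$sigma2_e))

  tab <- tab[, c("area_id", "outcome", "imd_score", "pct_minority",
                 "pct_degree", "urban", "pct_65plus")]
  list(table = as_area_table(tab),
       truth = list(intercept = config$intercept,
                    effects = config$effects,
                    sigma2_u = config$sigma2_u,
                    sigma2_e = config$sigma2_e,
                    u = u_all,
                    interaction_effects = inter,
                    config = config))
}

# Additive fixed-part contribution per occupied stratum (registry order),
# from the config's per-category effect vectors.
additive_effects <- function(strata, config) {
  reg <- strata$registry
  out <- numeric(nrow(reg))
  for (v in names(config$effects)) {
    if (!v %in% names(reg)) next  # variable not in this scheme
    r <- config$scheme$rules[[v]]
    idx <- match(reg[[v]], r$categories)
    out <- out + config$effects[[v]][idx]
  }
  out
}
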