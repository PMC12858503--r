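test_that("zero-variance input returns the constant with flagged boundaries", {
  tab <- as_area_table(
    data.frame(area_id = paste0("Z", 1:9), outcome = 7.5,
               xvar = rep(c(1, 5, 9), 3), stringsAsFactors = FALSE),
    require = c("area_id", "outcome"))
  st <- categorize(tab, coding_scheme(rule_quantiles("xvar", 3)))
  f <- fit_eim(tab, st)
  expect_equal(unname(f$beta["(Intercept)"]), 7.5)
  expect_identical(f$sigma2_u, 0)
  expect_true(f$boundary_u)
  expect_true(f$boundary_e)
})

test_that("ML solution matches the dense grid-search oracle on the 3x4 fixture", {
  fx <- make_3x4_fixture()
  f <- fit_eim(fx$table, fx$strata)
  Xarea <- expand_design(f, fx$strata$assignment$code, fx$strata$registry$code)
  orc <- oracle_ml(fx$table$outcome, fx$strata$assignment$code, Xarea)
  expect_equal(f$loglik, orc$loglik, tolerance = 1e-6)
  expect_equal(f$sigma2_u, orc$s2u, tolerance = 1e-4)
  expect_equal(f$sigma2_e, orc$s2e, tolerance = 1e-4)
  # and the dense oracle evaluates the same surface as loglik_at
  expect_equal(
    loglik_at(2.5, 4.0, fx$table, fx$strata),
    oracle_loglik(fx$table$outcome, fx$strata$assignment$code, Xarea, 2.5, 4.0),
    tolerance = 1e-9)
})

test_that("loglik_at is self-consistent and locally optimal at the fit", {
  fx <- make_3x4_fixture()
  f <- fit_eim(fx$table, fx$strata)
  ll_hat <- loglik_at(f$sigma2_u, f$sigma2_e, fx$table, fx$strata)
  expect_equal(ll_hat, f$loglik, tolerance = 1e-8)
  for (mult in c(0.9, 1.1)) {
    expect_lt(loglik_at(f$sigma2_u * mult, f$sigma2_e, fx$table, fx$strata), ll_hat)
    expect_lt(loglik_at(f$sigma2_u, f$sigma2_e * mult, fx$table, fx$strata), ll_hat)
  }
  expect_error(loglik_at(1, 0, fx$table, fx$strata), class = "eimm_config_error")
  expect_error(loglik_at(-1, 1, fx$table, fx$strata), class = "eimm_config_error")
})

test_that("two singleton strata match the hand-computed closed form", {
  # J = 2, n_j = 1: only the total lambda = s2u + s2e is identified;
  # profiling beta gives mu = (a+b)/2 and
  # ll = -log(2*pi) - log(lambda) - (a-b)^2/(4*lambda)
  a <- 3.7; b <- 9.1
  tab <- as_area_table(
    data.frame(area_id = c("p", "q"), outcome = c(a, b), urban = c(0, 1),
               stringsAsFactors = FALSE),
    require = c("area_id", "outcome"))
  st <- categorize(tab, coding_scheme(rule_binary("urban")))
  for (th in list(c(1, 2), c(0.5, 0.25), c(0, 3))) {
    lam <- sum(th)
    expect_equal(loglik_at(th[1], th[2], tab, st),
                 -log(2 * pi) - log(lam) - (a - b)^2 / (4 * lam),
                 tolerance = 1e-10)
  }
})

test_that("balanced intercept-only ML matches the closed-form solution", {
  # balanced one-way layout: the likelihood factorises into a within part
  # ((N-J) df) and a stratum-means part, giving
  #   s2e = SSW/(N-J),  s2e + m*s2u = SSB/J  (when above the boundary)
  set.seed(21)
  J <- 8; m <- 6
  u <- stats::rnorm(J, 0, 3)
  y <- 15 + rep(u, each = m) + stats::rnorm(J * m, 0, 2)
  tab <- as_area_table(
    data.frame(area_id = sprintf("B%02d", 1:(J * m)), outcome = y,
               g = rep(seq_len(J) * 10, each = m), stringsAsFactors = FALSE),
    require = c("area_id", "outcome"))
  st <- categorize(tab, coding_scheme(rule_quantiles("g", J)))
  f <- fit_eim(tab, st)
  ybar_j <- tapply(y, rep(seq_len(J), each = m), mean)
  SSW <- sum((y - rep(ybar_j, each = m))^2)
  SSB <- m * sum((ybar_j - mean(y))^2)
  # the likelihood is quadratically flat at its optimum, so parameter
  # agreement is ~sqrt(reltol); the sharp check is the log-likelihood
  expect_equal(f$sigma2_e, SSW / (J * m - J), tolerance = 1e-5)
  expect_equal(f$sigma2_u, (SSB / J - SSW / (J * m - J)) / m, tolerance = 1e-5)
  expect_equal(f$loglik,
               loglik_at((SSB / J - SSW / (J * m - J)) / m, SSW / (J * m - J),
                         tab, st),
               tolerance = 1e-9)
  expect_equal(unname(f$beta["(Intercept)"]), mean(y), tolerance = 1e-8)
})

test_that("fit agrees with lme4 maximum likelihood on a simulated dataset", {
  skip_if_not_installed("lme4")
  sim <- simulate_areas(preset_study_like(n_areas = 2500, seed = 303))
  st <- categorize(sim$table, default_scheme(TRUE))
  vars <- names(st$scheme$rules)
  f <- fit_eim(sim$table, st, model_spec(vars))
  d <- data.frame(y = sim$table$outcome, code = st$assignment$code)
  for (v in vars)
    d[[v]] <- factor(st$registry[[v]][match(d$code, st$registry$code)])
  m <- lme4::lmer(y ~ imd_score + pct_minority + pct_degree + urban +
                    pct_65plus + (1 | code), data = d, REML = FALSE)
  vc <- as.data.frame(lme4::VarCorr(m))
  expect_equal(f$loglik, as.numeric(stats::logLik(m)), tolerance = 1e-7)
  expect_equal(f$sigma2_u, vc$vcov[1], tolerance = 1e-4)
  expect_equal(f$sigma2_e, vc$vcov[2], tolerance = 1e-5)
  expect_equal(unname(f$beta), unname(lme4::fixef(m)), tolerance = 1e-4)
})

test_that("adding a constant shifts the intercept and nothing else", {
  fx <- make_3x4_fixture()
  f0 <- fit_eim(fx$table, fx$strata)
  tab2 <- fx$table
  tab2$outcome <- tab2$outcome + 100
  f1 <- fit_eim(tab2, fx$strata)
  expect_equal(unname(f1$beta["(Intercept)"] - f0$beta["(Intercept)"]), 100,
               tolerance = 1e-6)
  expect_equal(f1$sigma2_u, f0$sigma2_u, tolerance = 1e-6)
  expect_equal(f1$sigma2_e, f0$sigma2_e, tolerance = 1e-6)
  expect_equal(eb_residuals(f1)$u_hat, eb_residuals(f0)$u_hat, tolerance = 1e-6)
})

test_that("singular designs are rejected with the collinear terms named", {
  tab <- make_small_table(n = 24, seed = 5)
  tab$pct_65plus <- ifelse(tab$urban == 1, 30, 10)  # ageing duplicates urban
  at <- as_area_table(tab)
  st <- categorize(at, default_scheme(TRUE))
  expect_error(fit_eim(at, st, model_spec(c("urban", "pct_65plus"))),
               "pct_65plus", class = "eimm_fit_error")
})

test_that("aic and Wald intervals follow their definitions", {
  fx <- make_3x4_fixture()
  f <- fit_eim(fx$table, fx$strata)
  expect_equal(f$aic, -2 * f$loglik + 2 * (length(f$beta) + 2))
  expect_equal(unname(f$ci95_beta[, "lower"]), unname(f$beta - 1.96 * f$se_beta))
  expect_equal(unname(f$ci95_beta[, "upper"]), unname(f$beta + 1.96 * f$se_beta))
})

test_that("EB shrinkage follows the closed form and its limits", {
  # hand-checked case: R = 4/(4 + 16/4) = 0.5, u = 1, se = sqrt(4*0.5)
  tb <- eb_shrinkage(raw_mean = 2, n_j = 4, sigma2_u = 4, sigma2_e = 16)
  expect_equal(tb$shrinkage, 0.5)
  expect_equal(tb$u_hat, 1.0)
  expect_equal(tb$se_u, sqrt(2))
  # shrinkage limit: huge stratum keeps its raw mean
  big <- eb_shrinkage(2, 1e6, 4, 16)
  expect_equal(big$u_hat, 2, tolerance = 1e-3)
  # zero stratum variance kills every residual
  z <- eb_shrinkage(c(-3, 0, 5), c(2, 8, 30), 0, 16)
  expect_identical(z$u_hat, c(0, 0, 0))
  expect_identical(z$shrinkage, c(0, 0, 0))
  # monotone shrinkage: equal raw residual, smaller n_j => smaller |u_hat|
  mono <- eb_shrinkage(rep(2, 5), c(1, 3, 10, 40, 200), 4, 16)
  expect_true(all(diff(abs(mono$u_hat)) > 0))
  expect_true(all(abs(mono$u_hat) <= 2))
})

test_that("eb_residuals shrinks toward zero and roughly centres", {
  sim <- simulate_areas(preset_study_like(n_areas = 2000, seed = 77))
  st <- categorize(sim$table, default_scheme(TRUE))
  f <- fit_eim(sim$table, st, model_spec(names(st$scheme$rules)))
  eff <- eb_residuals(f)
  expect_identical(eff$code, f$stratum$code)
  expect_true(all(abs(eff$u_hat) <= abs(eff$raw_mean_resid) + 1e-12))
  expect_lt(abs(stats::weighted.mean(eff$u_hat, eff$n_j)), 0.5)
  expect_equal(eff$u_hat, eff$shrinkage * eff$raw_mean_resid)
})
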