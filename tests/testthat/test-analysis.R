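test_that("vpc and pcv implement their definitions and guard their domains", {
  expect_equal(vpc(42.06, 51.67), 42.06 / (42.06 + 51.67))
  expect_equal(vpc(0, 3), 0)
  expect_equal(pcv(5, 5), 0)
  # negative PCV is reported, never clipped
  expect_equal(pcv(5, 8), -0.6)
  expect_error(vpc(0, 0), class = "eimm_config_error")
  expect_error(vpc(-1, 2), class = "eimm_config_error")
  expect_error(pcv(0, 1), class = "eimm_config_error")
})

test_that("as_percent rounds half-up at two decimals", {
  expect_identical(as_percent(0.448736), 44.87)
  expect_identical(as_percent(0.792485), 79.25)  # exactly-half case goes up
  expect_identical(as_percent(0.05), 5)
  expect_identical(as_percent(-0.012345), -1.23)
})

test_that("stratum predictions combine fixed part and shrunken residual", {
  sim <- simulate_areas(preset_study_like(n_areas = 2000, seed = 15))
  st <- categorize(sim$table, default_scheme(TRUE))
  f <- fit_eim(sim$table, st)  # null model: fixed part is the intercept
  eff <- eb_residuals(f)
  pr <- predict_strata(f, eff)
  m <- match(pr$code, eff$code)
  expect_equal(pr$predicted,
               unname(f$beta["(Intercept)"]) + eff$u_hat[m])
  expect_identical(pr$rank, seq_len(nrow(pr)))
  expect_true(all(diff(pr$predicted) <= 1e-12))
  expect_equal(pr$lower, pr$predicted - 1.96 * eff$se_u[m])

  # permuting input rows leaves the table identical
  set.seed(31)
  perm <- sample(nrow(sim$table))
  st2 <- categorize(sim$table[perm, ], default_scheme(TRUE))
  f2 <- fit_eim(sim$table[perm, ], st2)
  pr2 <- predict_strata(f2, eb_residuals(f2))
  expect_equal(pr, pr2, tolerance = 1e-9)
})

test_that("flag_interactions applies the 1.96 rule", {
  u <- c(0, 3, -4, 0.5)
  se <- c(1, 1, 1, 1)
  eff <- data.frame(code = c("a", "b", "c", "d"), u_hat = u, se_u = se,
                    lower = u - 1.96 * se, upper = u + 1.96 * se,
                    stringsAsFactors = FALSE)
  fl <- flag_interactions(eff)
  expect_setequal(fl$code, c("b", "c"))
  expect_equal(fl$lower[fl$code == "b"], 1.04)
  expect_equal(fl$upper[fl$code == "b"], 4.96)
  expect_identical(fl$sign[fl$code == "b"], "positive")
  expect_identical(fl$sign[fl$code == "c"], "negative")
  # u = 0 with positive se is never flagged
  expect_false("a" %in% fl$code)
  # ordered by u_hat descending
  expect_identical(fl$code, c("b", "c"))
})

test_that("the model sequence fits 1a/1b/2a/2b/3 with matched PCV pairs", {
  sim <- simulate_areas(preset_study_like(n_areas = 4000, seed = 101))
  res <- run_model_sequence(sim$table)
  expect_named(res$models, c("1a", "1b", "2a", "2b", "3"))
  cmp <- res$comparison
  expect_identical(cmp$model, c("1a", "1b", "2a", "2b", "3"))
  expect_true(all(is.na(cmp$pcv_pct[cmp$model %in% c("1a", "2a")])))
  expect_true(all(!is.na(cmp$pcv_pct[cmp$model %in% c("1b", "2b", "3")])))
  expect_true(all(cmp$vpc_pct >= 0 & cmp$vpc_pct <= 100))
  # PCV pairs share a stratum structure
  expect_equal(cmp$pcv_pct[cmp$model == "2b"],
               as_percent(pcv(cmp$sigma2_u[cmp$model == "2a"],
                              cmp$sigma2_u[cmp$model == "2b"])))
  expect_equal(cmp$pcv_pct[cmp$model == "3"],
               as_percent(pcv(cmp$sigma2_u[cmp$model == "2a"],
                              cmp$sigma2_u[cmp$model == "3"])))
  # additive structure exists here, so main effects must explain variance
  expect_gt(cmp$pcv_pct[cmp$model == "2b"], 0)
  expect_lt(cmp$sigma2_u[cmp$model == "2b"], cmp$sigma2_u[cmp$model == "2a"])
  # the interaction model never fits worse in likelihood than 2b
  expect_gte(cmp$loglik[cmp$model == "3"], cmp$loglik[cmp$model == "2b"] - 1e-6)
  # top/bottom descriptor tables carry readable labels
  s2b <- res$models[["2b"]]$summary
  expect_identical(nrow(s2b$top), 10L)
  expect_match(s2b$top$description[1], "deprived")
})

test_that("with no additive structure the main-effects model explains nothing", {
  zero_eff <- lapply(default_effects(), function(e) e * 0)
  cfg <- preset_study_like(n_areas = 4000, seed = 55, effects = zero_eff)
  sim <- simulate_areas(cfg)
  res <- run_model_sequence(sim$table, interaction = NULL)
  cmp <- res$comparison
  # PCV near zero up to sampling noise and the small ML degrees-of-freedom
  # effect of the 9 useless fixed parameters (~p/J ~ +10%)
  expect_gt(cmp$pcv_pct[cmp$model == "2b"], -5)
  expect_lt(cmp$pcv_pct[cmp$model == "2b"], 25)
  expect_equal(cmp$vpc_pct[cmp$model == "2a"], cmp$vpc_pct[cmp$model == "2b"],
               tolerance = 6)
})

test_that("AIC prefers the model containing the true interaction", {
  # direction-only check: with a real single-stratum deviation injected,
  # 2b + minority x urban interaction is not required, but injecting a
  # systematic minority x urban effect must lower AIC for model 3
  grid <- expand.grid(imd = 1:3, eth = 1:3, edu = 1:3, urb = 0:1, age = 0:1)
  codes <- do.call(paste0, grid)
  target <- codes[grid$eth == 3 & grid$urb == 1]  # all high-minority urban strata
  inter <- stats::setNames(rep(6, length(target)), target)
  wins <- 0L
  for (r in 1:10) {
    cfg <- preset_study_like(n_areas = 3000, seed = 400 + r, sigma2_u = 5,
                             interaction_effects = inter)
    sim <- suppressWarnings(simulate_areas(cfg))
    res <- run_model_sequence(sim$table)
    cmp <- res$comparison
    if (cmp$aic[cmp$model == "3"] < cmp$aic[cmp$model == "2b"]) wins <- wins + 1L
  }
  expect_gte(wins, 8L)
})
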