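# Small deterministic fixtures built in code.

# A minimal table exercising every default-scheme variable.  Values are
# chosen so nearest-rank category boundaries are easy to reason about.
make_small_table <- function(n = 12, seed = 11) {
  set.seed(seed)
  data.frame(
    area_id = sprintf("S%03d", seq_len(n)),
    outcome = round(stats::rnorm(n, 20, 5), 3),
    imd_score = seq(5, 5 + 4 * (n - 1), by = 4),
    pct_minority = seq(2, 2 + 7 * (n - 1), by = 7) %% 100,
    pct_degree = rev(seq(10, 10 + 5 * (n - 1), by = 5)) %% 100,
    urban = rep(c(0, 1), length.out = n),
    pct_65plus = rep(c(10, 30), each = n / 2),
    stringsAsFactors = FALSE)
}

# Random small instance for oracle-equivalence checks: a handful of
# strata via a single quantile rule, unbalanced sizes.
make_random_instance <- function(seed) {
  set.seed(seed)
  J <- sample(2:6, 1)
  n <- sample(J:50, 1)
  x <- stats::runif(n, 0, 100)
  scheme <- coding_scheme(rule_quantiles("xvar", J))
  tab <- as_area_table(
    data.frame(area_id = sprintf("R%03d", seq_len(n)),
               outcome = stats::rnorm(n, 10, 3) +
                 stats::rnorm(J, 0, 2)[ceiling(J * rank(x) / n)],
               xvar = x, stringsAsFactors = FALSE),
    require = c("area_id", "outcome"))
  strata <- categorize(tab, scheme)
  list(table = tab, strata = strata)
}

# The 3 strata x 4 areas fixture from the engine's contract examples.
make_3x4_fixture <- function() {
  y <- c(18.2, 21.4, 19.9, 20.7,   # stratum A
         27.1, 24.6, 26.3, 25.8,   # stratum B
         14.9, 16.2, 13.8, 15.5)   # stratum C
  g <- rep(c(10, 50, 90), each = 4)
  tab <- as_area_table(
    data.frame(area_id = sprintf("F%02d", 1:12), outcome = y, xvar = g,
               stringsAsFactors = FALSE),
    require = c("area_id", "outcome"))
  strata <- categorize(tab, coding_scheme(rule_quantiles("xvar", 3)))
  list(table = tab, strata = strata)
}

# GLS leverage of each stratum in the pattern-level weighted regression.
stratum_leverage <- function(fit) {
  w <- fit$stratum$n / (fit$sigma2_e + fit$stratum$n * fit$sigma2_u)
  X <- fit$stratum$X
  M <- solve(t(X * w) %*% X)
  rowSums((X %*% M) * X) * w
}
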