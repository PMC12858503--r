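# Independent dense-matrix oracle for the two-level marginal likelihood.
# Deliberately avoids the package's per-stratum closed form: builds the
# full N x N covariance V = s2e*I + s2u*Z Z', profiles beta by GLS with
# explicit solves, and evaluates the Gaussian log-density directly.

oracle_loglik <- function(y, code, Xarea, s2u, s2e) {
  N <- length(y)
  Z <- outer(code, sort(unique(code)), `==`) * 1
  V <- s2e * diag(N) + s2u * Z %*% t(Z)
  Vi <- solve(V)
  beta <- solve(t(Xarea) %*% Vi %*% Xarea, t(Xarea) %*% Vi %*% y)
  r <- y - Xarea %*% beta
  ld <- determinant(V, logarithm = TRUE)$modulus
  as.numeric(-0.5 * (N * log(2 * pi) + ld + t(r) %*% Vi %*% r))
}

# Dense grid search over (s2u, s2e) followed by Nelder-Mead refinement of
# the oracle likelihood itself.
oracle_ml <- function(y, code, Xarea, grid_n = 25) {
  vy <- stats::var(y)
  s2u_grid <- seq(0, 3 * vy, length.out = grid_n)
  s2e_grid <- seq(0.05 * vy, 3 * vy, length.out = grid_n)
  best <- c(NA, NA); best_ll <- -Inf
  for (a in s2u_grid) for (b in s2e_grid) {
    ll <- oracle_loglik(y, code, Xarea, a, b)
    if (ll > best_ll) { best_ll <- ll; best <- c(a, b) }
  }
  f <- function(par) -oracle_loglik(y, code, Xarea, exp(par[1]), exp(par[2]))
  opt <- stats::optim(log(pmax(best, 1e-4 * vy)), f, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-13))
  # raw-scale polish with box constraints so the s2u = 0 boundary is
  # reachable exactly
  g <- function(par) -oracle_loglik(y, code, Xarea, par[1], par[2])
  opt2 <- stats::optim(exp(opt$par), g, method = "L-BFGS-B",
                       lower = c(0, 1e-8 * vy),
                       control = list(maxit = 500, factr = 10,
                                      parscale = c(vy, vy)))
  if (opt2$value <= opt$value)
    list(s2u = opt2$par[1], s2e = opt2$par[2], loglik = -opt2$value,
         grid_loglik = best_ll)
  else
    list(s2u = exp(opt$par[1]), s2e = exp(opt$par[2]), loglik = -opt$value,
         grid_loglik = best_ll)
}

# Per-area design matrix matching the package's pattern-level design.
expand_design <- function(fit_or_X, code, registry_codes) {
  X <- if (inherits(fit_or_X, "eimm_fit")) fit_or_X$stratum$X else fit_or_X
  X[match(code, registry_codes), , drop = FALSE]
}
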