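# Independent oracles, kept free of the package's own fitting code paths.

# Brute-force maximiser of the Bernoulli/binomial probit log-likelihood over
# a (mu, beta) grid, coarse scan then local refinement down to steps of
# 1e-4 (mu) and 1e-3 (beta).
grid_probit_oracle <- function(dose, n, protected,
                               mu_range = log10(range(dose)) + c(-0.5, 0.5),
                               beta_range = c(0.1, 20)) {
  loglik <- function(mu, beta) {
    # vectorised over a mu grid for one beta; rows = doses, cols = mu values
    p <- stats::pnorm(beta * outer(log10(dose), mu, `-`))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    colSums(protected * log(p) + (n - protected) * log(1 - p))
  }
  scan <- function(mus, betas) {
    best <- c(-Inf, NA, NA)
    for (b in betas) {
      ll <- loglik(mus, b)
      i <- which.max(ll)
      if (ll[i] > best[1]) best <- c(ll[i], mus[i], b)
    }
    best
  }
  b1 <- scan(seq(mu_range[1], mu_range[2], by = 2e-3),
             seq(beta_range[1], beta_range[2], by = 0.05))
  b2 <- scan(seq(b1[2] - 4e-3, b1[2] + 4e-3, by = 1e-4),
             seq(max(beta_range[1], b1[3] - 0.1), b1[3] + 0.1, by = 1e-3))
  list(mu = b2[2], beta = b2[3], ed50 = 10^b2[2], loglik = b2[1])
}

# Monte-Carlo null distribution of the studentized range statistic for k
# balanced groups with error df nu: q = range(Z_1..Z_k) / sqrt(W), W ~
# chi^2_nu / nu. Returns P(q > q_obs).
mc_tukey_p <- function(q_obs, k, nu, nsim = 1e5, seed = 1234) {
  set.seed(seed)
  z <- matrix(stats::rnorm(nsim * k), nsim, k)
  s <- sqrt(stats::rchisq(nsim, nu) / nu)
  q <- (apply(z, 1, max) - apply(z, 1, min)) / s
  mean(q > q_obs)
}

# Monte-Carlo two-sided Dunnett adjusted p for k balanced treatments vs a
# control of the same size: T_i = (Zbar_i - Zbar_0) standardised with a
# pooled chi^2 variance estimate; returns P(max_i |T_i| > t_obs).
mc_dunnett_p <- function(t_obs, k, n_each, nsim = 1e5, seed = 4321) {
  set.seed(seed)
  nu <- (k + 1) * (n_each - 1)
  z0 <- stats::rnorm(nsim, 0, 1 / sqrt(n_each))
  zi <- matrix(stats::rnorm(nsim * k, 0, 1 / sqrt(n_each)), nsim, k)
  s <- sqrt(stats::rchisq(nsim, nu) / nu)
  tmax <- apply(abs(zi - z0), 1, max) / (s * sqrt(2 / n_each))
  mean(tmax > t_obs)
}

# Finite-difference gradient of a scalar function, for delta-method checks.
fd_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + h; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, 0)
}
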