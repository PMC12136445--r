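# Independent oracle implementations used to cross-check the package.
# These deliberately share no code with R/: textbook formulas, brute force
# and grid searches only.

# Textbook IRLS logistic regression via normal equations.
oracle_irls_logistic <- function(X, y, max_iter = 100, tol = 1e-12) {
  beta <- numeric(ncol(X))
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    delta <- solve(t(X) %*% (W * X), t(X) %*% (y - mu))
    beta <- beta + drop(delta)
    if (max(abs(delta)) < tol) break
  }
  eta <- drop(X %*% beta)
  mu <- 1 / (1 + exp(-eta))
  list(coef = beta, mu = mu, W = mu * (1 - mu))
}

# Textbook Rao score test for adding genotype g to a logistic model.
oracle_logistic_score <- function(X, y, g) {
  f <- oracle_irls_logistic(X, y)
  W <- f$W
  S <- sum(g * (y - f$mu))
  XtWX <- t(X) %*% (W * X)
  gWX <- t(X) %*% (W * g)
  v <- sum(g^2 * W) - drop(t(gWX) %*% solve(XtWX, gWX))
  z <- S / sqrt(v)
  list(score = S, var = v, z = z, p = 2 * pnorm(-abs(z)))
}

# Exact restricted log-likelihood for y = X a + b + e, b ~ N(0, tau Psi),
# e ~ N(0, sigma2 I).
oracle_reml_loglik <- function(y, X, Psi, tau, sigma2) {
  n <- length(y)
  V <- sigma2 * diag(n) + tau * Psi
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) return(-Inf)
  Vi <- chol2inv(R)
  XtViX <- t(X) %*% Vi %*% X
  a <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% a
  -0.5 * (2 * sum(log(diag(R))) + determinant(XtViX)$modulus[1] +
            drop(t(r) %*% Vi %*% r))
}

# Grid-search REML oracle over (tau, sigma2).
oracle_reml_grid <- function(y, X, Psi, tau_grid, sigma2_grid) {
  ll <- outer(tau_grid, sigma2_grid,
              Vectorize(function(t, s) oracle_reml_loglik(y, X, Psi, t, s)))
  ij <- which(ll == max(ll), arr.ind = TRUE)[1, ]
  list(tau = tau_grid[ij[1]], sigma2 = sigma2_grid[ij[2]], loglik = max(ll))
}

# Exhaustive tail probability P(S >= q) (and <= q) for S = sum g_i (Y_i - mu_i)
# with independent Y_i ~ Bernoulli(mu_i). Only feasible for small n.
oracle_exact_score_tail <- function(g, mu, q) {
  n <- length(g)
  stopifnot(n <= 16)
  outcomes <- as.matrix(expand.grid(rep(list(0:1), n)))
  pr <- apply(outcomes, 1, function(yy) prod(mu^yy * (1 - mu)^(1 - yy)))
  s <- drop(outcomes %*% g) - sum(g * mu)
  list(upper = sum(pr[s >= q - 1e-12]), lower = sum(pr[s <= q + 1e-12]))
}

# Two-clan block relatedness matrix: within-clan relatedness rho, across 0.
make_two_clan_grm <- function(n, rho = 0.9) {
  half <- n %/% 2
  clan <- rep(c(0, 1), c(half, n - half))
  Psi <- outer(clan, clan, function(a, b) ifelse(a == b, rho, 0))
  diag(Psi) <- 1
  rownames(Psi) <- colnames(Psi) <- sprintf("s%04d", seq_len(n))
  structure(Psi, class = c("relatedness_matrix", "matrix", "array"))
}

# Draw a multivariate normal with covariance tau * Psi + sigma2 * I.
draw_lmm_y <- function(X, alpha, Psi, tau, sigma2) {
  n <- nrow(Psi)
  ev <- eigen(Psi, symmetric = TRUE)
  b <- drop(ev$vectors %*% (sqrt(pmax(ev$values, 0) * tau) * rnorm(n)))
  drop(X %*% alpha) + b + rnorm(n, sd = sqrt(sigma2))
}

# Small helper: random binary matrix with given presence probability.
random_pangenome <- function(n, p, prob = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rbinom(n * p, 1, prob), n, p,
              dimnames = list(sprintf("s%03d", seq_len(n)),
                              sprintf("g%04d", seq_len(p))))
  pangenome_matrix(m)
}
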