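test_that("at tau = 0 the score test matches an independently coded logistic score test", {
  set.seed(51)
  for (rep in 1:10) {
    n <- 70
    Psi <- make_two_clan_grm(n)
    age <- rnorm(n, 45, 15)
    y <- rbinom(n, 1, plogis(-0.2 + 0.005 * age))
    g <- rbinom(n, 1, 0.4)
    if (length(unique(g)) == 1L || length(unique(y)) == 1L) next
    tt <- trait_table(rownames(Psi), y, covariates = data.frame(age = age))
    fit <- fit_null_model(tt, Psi, fix_tau = 0)
    res <- score_test_gene(fit, g, spa = FALSE)
    oracle <- oracle_logistic_score(tt$X, y, g)
    expect_equal(res$score, oracle$score, tolerance = 1e-6)
    expect_equal(res$var_score, oracle$var, tolerance = 1e-6)
    expect_equal(res$p_value, oracle$p, tolerance = 1e-6)
  }
})

test_that("a genotype collinear with a covariate is annihilated by the adjustment", {
  set.seed(52)
  n <- 80
  Psi <- make_two_clan_grm(n)
  g <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, 0.5)
  tt <- trait_table(rownames(Psi), y, covariates = data.frame(gcov = g))
  fit <- suppressWarnings(fit_null_model(tt, Psi))
  res <- score_test_gene(fit, g)
  expect_lt(abs(res$score), 1e-8)
  expect_true(res$untestable || res$p_value > 0.99)
})

test_that("constant genes are flagged untestable without aborting the batch", {
  set.seed(53)
  ds <- simulate_tau_dataset(n = 50, theta = 0.5, seed = 53)
  Psi <- compute_grm(ds$G)
  fit <- suppressWarnings(fit_null_model(ds$traits, Psi))
  G <- cbind(ones = rep(1, 50), real = rbinom(50, 1, 0.5),
             zeros = rep(0, 50))
  rownames(G) <- ds$traits$sample_ids
  res <- run_beta_tests(fit, G)
  expect_equal(res$untestable, c(TRUE, FALSE, TRUE))
  expect_equal(res$p_value[c(1, 3)], c(1, 1))
  # identical gene columns give identical results
  G2 <- cbind(a = G[, "real"], b = G[, "real"])
  res2 <- run_beta_tests(fit, G2)
  expect_equal(res2$p_value[1], res2$p_value[2])
  expect_equal(res2$score[1], res2$score[2])
})

test_that("SPA tails match exact enumeration within 10% on enumerable configurations", {
  # n = 12 is exhaustively enumerable (2^12 outcomes). The score distribution
  # is discrete, so comparisons are made at off-atom thresholds in the
  # moderate-tail regime where a continuous tail approximation is meaningful;
  # exact-atom thresholds and extreme lattice tails are a known limitation.
  n <- 12
  mu <- rep(0.5, n)
  g <- c(rep(1, 6), rep(0, 6))  # six carriers, even probabilities
  v <- sum(g^2 * mu * (1 - mu))
  for (q in c(0.5, 1.5)) {      # halfway between score atoms
    sp <- spa_pvalue(g, mu, q, v)
    expect_true(sp$converged)
    exact <- oracle_exact_score_tail(g, mu, q)$upper +
      oracle_exact_score_tail(g, mu, -q)$lower
    expect_lt(abs(sp$p_value - exact) / exact, 0.10)
  }
  # heterogeneous (non-lattice) adjusted genotypes, as produced by covariate
  # adjustment in practice
  set.seed(54)
  for (rep in 1:10) {
    g2 <- runif(n, -1, 1)
    mu2 <- runif(n, 0.1, 0.9)
    v2 <- sum(g2^2 * mu2 * (1 - mu2))
    for (qf in c(0.7, 1.3)) {
      q <- qf * sqrt(v2)
      sp <- spa_pvalue(g2, mu2, q, v2)
      exact <- oracle_exact_score_tail(g2, mu2, q)$upper +
        oracle_exact_score_tail(g2, mu2, -q)$lower
      expect_lt(abs(sp$p_value - exact) / exact, 0.10)
    }
  }
  expect_equal(spa_pvalue(g, mu, 0, v)$p_value, 1)
})

test_that("SPA approaches the normal approximation for balanced data at large n", {
  set.seed(55)
  n <- 5000
  mu <- rep(0.5, n)
  g <- rbinom(n, 1, 0.5)
  g_adj <- g - mean(g)
  v <- sum(g_adj^2 * mu * (1 - mu))
  q <- 2.5 * sqrt(v)
  sp <- spa_pvalue(g_adj, mu, q, v)
  p_norm <- 2 * pnorm(-abs(q) / sqrt(v))
  expect_lt(abs(sp$p_value - p_norm) / p_norm, 0.01)
})

test_that("SPA is larger (more accurate) than the normal p under severe imbalance", {
  set.seed(56)
  n <- 500
  mu <- rep(0.1, n)     # 50 expected cases in 500
  g <- c(rep(1, 25), rep(0, n - 25))  # rare gene
  g_adj <- g - mean(g)
  v <- sum(g_adj^2 * mu * (1 - mu))
  q <- 3 * sqrt(v)
  sp <- spa_pvalue(g_adj, mu, q, v)
  p_norm <- 2 * pnorm(-3)
  expect_gt(sp$p_value, p_norm)
})

test_that("glm baseline recovers the closed-form odds ratio of a 2x2 table", {
  # y x g table [[30,10],[10,30]] -> log OR = log(9)
  y <- c(rep(0, 40), rep(1, 40))
  g <- c(rep(0, 30), rep(1, 10), rep(0, 10), rep(1, 30))
  tt <- trait_table(sprintf("s%02d", 1:80), y)
  res <- glm_baseline_gene(tt, g)
  expect_equal(res$beta_hat, log(9), tolerance = 1e-6)
  expect_false(res$separation)
  # constant gene
  expect_true(glm_baseline_gene(tt, rep(1, 80))$untestable)
})

test_that("mixed-model and glm p-values agree on balanced unstructured data", {
  set.seed(57)
  n <- 300
  Psi <- structure(diag(n) * 0.0001 + outer(rep(1, n), rep(1, n)) * 0,
                   dimnames = list(sprintf("s%03d", 1:n), sprintf("s%03d", 1:n)),
                   class = c("relatedness_matrix", "matrix", "array"))
  diag(Psi) <- 1
  g <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, plogis(-0.1 + 0.4 * g))
  tt <- trait_table(sprintf("s%03d", 1:n), y)
  fit <- suppressWarnings(fit_null_model(tt, Psi))
  res <- run_beta_tests(fit, matrix(g, ncol = 1))
  glmb <- glm_baseline_gene(tt, g)
  expect_equal(res$p_value, glmb$p_value, tolerance = 0.25)
  expect_equal(sign(res$beta_hat), sign(glmb$beta_hat))
})

test_that("score-test p-values are uniform under permuted-genotype nulls on structured data", {
  set.seed(58)
  ds <- simulate_tau_dataset(n = 100, theta = 0.714, seed = 58)
  Psi <- compute_grm(ds$G)
  fit <- suppressWarnings(fit_null_model(ds$traits, Psi))
  g0 <- rbinom(100, 1, 0.3)
  P <- 400
  G <- sapply(seq_len(P), function(i) sample(g0))
  rownames(G) <- ds$traits$sample_ids
  res <- run_beta_tests(fit, G)
  ks <- ks.test(res$p_value[!res$untestable], "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("quantitative-trait score test matches the linear-model score at tau = 0", {
  set.seed(59)
  n <- 90
  Psi <- make_two_clan_grm(n)
  g <- rbinom(n, 1, 0.4)
  y <- rnorm(n) + 0.1 * g
  tt <- trait_table(rownames(Psi), y)
  fit <- suppressWarnings(fit_null_model(tt, Psi, link = "identity", fix_tau = 0))
  res <- score_test_gene(fit, g)
  lmf <- glm_baseline_gene(tt, g)
  # score z and Wald t agree closely for a single added regressor
  expect_equal(res$z_raw, lmf$z, tolerance = 0.05)
  expect_equal(sign(res$beta_hat), sign(lmf$beta_hat))
})
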