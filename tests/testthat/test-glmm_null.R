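test_that("with tau fixed at 0 the logit fit coincides with textbook IRLS", {
  set.seed(31)
  for (rep in 1:5) {
    n <- 80
    X <- cbind(1, rnorm(n, 45, 15))
    colnames(X) <- c("(Intercept)", "age")
    y <- rbinom(n, 1, plogis(-0.3 + 0.01 * X[, 2]))
    Psi <- make_two_clan_grm(n)
    tt <- trait_table(rownames(Psi), y,
                      covariates = data.frame(age = X[, 2]))
    fit <- fit_null_model(tt, Psi, fix_tau = 0)
    oracle <- oracle_irls_logistic(X, y)
    expect_equal(unname(fit$alpha), unname(oracle$coef), tolerance = 1e-6)
    expect_equal(fit$b, rep(0, n), tolerance = 1e-8)
  }
})

test_that("tau is estimated near zero when the trait is independent of the GRM", {
  set.seed(32)
  taus <- replicate(10, {
    ds <- simulate_tau_dataset(n = 100, theta = 0.5)
    Psi <- compute_grm(ds$G)
    fit <- suppressWarnings(fit_null_model(ds$traits, Psi))
    # alpha should stay close to the plain logistic fit
    oracle <- oracle_irls_logistic(ds$traits$X, ds$traits$y)
    expect_equal(unname(fit$alpha), unname(oracle$coef), tolerance = 0.2)
    fit$tau
  })
  expect_lt(median(taus), 0.1)
})

test_that("identity-link AI-REML recovers variance components against a grid REML oracle", {
  set.seed(33)
  n <- 120
  Psi <- make_two_clan_grm(n, rho = 0.8)
  X <- cbind(1, rnorm(n))
  colnames(X) <- c("(Intercept)", "x")
  tau_true <- 2
  sigma2_true <- 1
  tau_hats <- c()
  for (rep in 1:5) {
    y <- draw_lmm_y(X, c(1, 0.5), unclass(Psi), tau_true, sigma2_true)
    tt <- trait_table(rownames(Psi), y, covariates = data.frame(x = X[, 2]))
    fit <- suppressWarnings(fit_null_model(tt, Psi, link = "identity"))
    or <- oracle_reml_grid(y, X, unclass(Psi) + diag(1e-6, n),
                           tau_grid = seq(0, 10, by = 0.05),
                           sigma2_grid = seq(0.05, 3, by = 0.05))
    ll_fit <- oracle_reml_loglik(y, X, unclass(Psi) + diag(1e-6, n),
                                 fit$tau, fit$sigma2)
    # the AI-REML optimum must be at least as good as the grid optimum ...
    expect_gte(ll_fit, or$loglik - 1e-3)
    # ... and agree with it to within the grid resolution when interior
    if (fit$tau > 0.1 && fit$tau < 9.9) {
      expect_lt(abs(fit$tau - or$tau), 0.11)
      expect_lt(abs(fit$sigma2 - or$sigma2), 0.11)
    }
    tau_hats <- c(tau_hats, fit$tau)
  }
  # estimates scatter around the truth (loose Monte-Carlo check at 5 reps)
  expect_lt(abs(mean(tau_hats) - tau_true), 2)
})

test_that("AI-REML score is ~0 at an interior optimum of the identity-link REML surface", {
  set.seed(34)
  n <- 100
  Psi <- make_two_clan_grm(n)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  y <- draw_lmm_y(X, 0.5, unclass(Psi), 1.5, 1)
  tt <- trait_table(rownames(Psi), y)
  fit <- suppressWarnings(fit_null_model(tt, Psi, link = "identity"))
  if (fit$tau > 0) {
    h <- 1e-3
    ll <- function(t) oracle_reml_loglik(y, X, unclass(Psi) + diag(1e-6, n),
                                         t, fit$sigma2)
    deriv <- (ll(fit$tau + h) - ll(fit$tau - h)) / (2 * h)
    expect_lt(abs(deriv), 0.5)
  } else {
    succeed("boundary estimate")
  }
})

test_that("fit is invariant to simultaneous permutation of samples", {
  set.seed(35)
  ds <- simulate_tau_dataset(n = 60, theta = 0.7)
  Psi <- compute_grm(ds$G)
  fit <- suppressWarnings(fit_null_model(ds$traits, Psi))
  perm <- sample(60)
  tt_p <- trait_table(ds$traits$sample_ids[perm], ds$traits$y[perm],
                      covariates = data.frame(age = ds$traits$X[perm, 2]))
  Psi_p <- structure(unclass(Psi)[perm, perm],
                     class = class(Psi))
  fit_p <- suppressWarnings(fit_null_model(tt_p, Psi_p))
  expect_equal(fit_p$tau, fit$tau, tolerance = 1e-6)
  expect_equal(fit_p$b, fit$b[perm], tolerance = 1e-5)
})

test_that("Psi = I makes tau and sigma2 jointly unidentifiable and the fit flags it", {
  set.seed(36)
  n <- 60
  Psi <- structure(diag(n) + 0,
                   class = c("relatedness_matrix", "matrix", "array"),
                   dimnames = list(sprintf("s%02d", 1:n), sprintf("s%02d", 1:n)))
  y <- rnorm(n, sd = sqrt(3))
  tt <- trait_table(rownames(Psi), y)
  fit <- suppressWarnings(fit_null_model(tt, Psi, link = "identity"))
  # only the sum tau + sigma2 is identified
  expect_equal(fit$tau + fit$sigma2, var(y), tolerance = 0.5)
  expect_true("ai_matrix_singular" %in% fit$diagnostics || fit$converged)
})

test_that("training AUC handles perfect, anti-perfect and uninformative predictors", {
  set.seed(37)
  n <- 200
  y <- rep(c(0, 1), each = n / 2)
  fake_fit <- structure(list(eta = y * 2 - 1 + 0.1 * runif(n), y = y,
                             link = "logit"), class = "null_model_fit")
  expect_equal(training_auc(fake_fit), 1.0)
  fake_fit$eta <- -fake_fit$eta
  expect_equal(training_auc(fake_fit), 0.0)
  fake_fit$eta <- rnorm(n)
  expect_lt(abs(training_auc(fake_fit) - 0.5), 0.15)
  # independent cross-check of the midrank formula
  skip_if_not_installed("pROC")
  expect_equal(training_auc(fake_fit),
               as.numeric(suppressMessages(
                 pROC::auc(fake_fit$y, fake_fit$eta, direction = "<"))),
               tolerance = 1e-10)
  fake_fit$y <- rep(1, n)
  expect_error(training_auc(fake_fit), "one class")
})
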