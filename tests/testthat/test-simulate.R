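test_that("tau simulation reproduces its block structure and stated probabilities", {
  ds <- simulate_tau_dataset(n = 5000, seed = 71)
  G <- unclass(ds$G)
  expect_equal(dim(G), c(5000, 1000))
  core_mean <- mean(G[, ds$labels == "core"])
  acc_mean <- mean(G[, ds$labels == "accessory"])
  expect_lt(abs(core_mean - 0.8), 0.01)
  expect_lt(abs(acc_mean - 0.2), 0.01)
  # strain-linked genes are absent whenever the strain is absent
  strain_cols <- G[, ds$labels == "strain1"]
  expect_true(all(strain_cols[ds$strain[, 1] == 0, ] == 0))
  # presence probability among carriers centers near OR 1.8 / (1 + 1.8)
  carrier_mean <- mean(strain_cols[ds$strain[, 1] == 1, ])
  expect_lt(abs(carrier_mean - 1.8 / 2.8), 0.03)
  # age covariate
  expect_lt(abs(mean(ds$traits$X[, "age"]) - 45), 1)
  expect_lt(abs(sd(ds$traits$X[, "age"]) - 15), 1)
})

test_that("generators are bit-reproducible given a seed", {
  a <- simulate_tau_dataset(n = 50, seed = 72)
  b <- simulate_tau_dataset(n = 50, seed = 72)
  expect_identical(unclass(a$G), unclass(b$G))
  expect_identical(a$traits$y, b$traits$y)
  Psi <- compute_grm(a$G)
  x <- simulate_beta_dataset(Psi, seed = 73)
  y <- simulate_beta_dataset(Psi, seed = 73)
  expect_identical(unclass(x$G), unclass(y$G))
})

test_that("trait follows the strain at the stated conditional probabilities", {
  theta <- 0.714  # OR 2.5
  ds <- simulate_tau_dataset(n = 20000, theta = theta, seed = 74)
  y <- ds$traits$y
  s <- ds$strain[, 1]
  expect_lt(abs(mean(y[s == 1]) - theta), 0.02)
  expect_lt(abs(mean(y[s == 0]) - (1 - theta)), 0.02)
  # null: trait independent of strain
  ds0 <- simulate_tau_dataset(n = 20000, theta = 0.5, seed = 75)
  expect_lt(abs(cor(ds0$traits$y, ds0$strain[, 1])), 0.02)
})

test_that("gene-level simulation matches its design counts and causal probabilities", {
  base <- simulate_tau_dataset(n = 300, n_strains = 2, seed = 76)
  Psi <- compute_grm(base$G)
  ds <- simulate_beta_dataset(Psi, theta = 0.78, seed = 77)
  expect_equal(ncol(ds$G), 10 * 90 + 100 + 100)
  # FPR denominator: everything but PC1/PC2-derived and causal genes
  expect_equal(sum(ds$negatives), 820)
  y <- ds$traits$y
  causal <- unclass(ds$G)[, ds$labels == "causal"]
  expect_lt(abs(mean(causal[y == 1, ]) - 0.78), 0.03)
  expect_lt(abs(mean(causal[y == 0, ]) - 0.22), 0.03)
  # trait is the PC1/PC2 opposite-sign rule
  expect_equal(ds$traits$y,
               as.integer(sign(ds$pcs[, 1]) * sign(ds$pcs[, 2]) < 0))
  # theta = 0.5 appends no causal genes and they would be independent anyway
  ds0 <- simulate_beta_dataset(Psi, theta = 0.5, seed = 78)
  expect_equal(ncol(ds0$G), 1000)
})

test_that("realized causal-gene odds ratios deviate less than 0.1 from target", {
  base <- simulate_tau_dataset(n = 400, n_strains = 2, seed = 79)
  Psi <- compute_grm(base$G)
  for (theta in c(0.6, 0.7)) {
    ds <- simulate_beta_dataset(Psi, theta = theta, seed = 80)
    y <- ds$traits$y
    causal <- unclass(ds$G)[, ds$labels == "causal"]
    p1 <- mean(causal[y == 1, ])
    p0 <- mean(causal[y == 0, ])
    # realized theta averages the case presence rate and the control absence
    # rate; its odds must track the design odds ratio theta / (1 - theta)
    theta_hat <- (p1 + (1 - p0)) / 2
    realized_or <- theta_hat / (1 - theta_hat)
    expect_lt(abs(realized_or - theta / (1 - theta)), 0.1)
  }
})
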