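test_that("relatedness is 1 minus per-gene-normalized Manhattan distance", {
  m <- rbind(a = c(1, 1, 1, 1), b = c(1, 1, 1, 1), c = c(0, 0, 0, 0))
  colnames(m) <- paste0("g", 1:4)
  Psi <- compute_grm(pangenome_matrix(m))
  expect_equal(Psi["a", "b"], 1)        # identical profiles
  expect_equal(Psi["a", "c"], 0)        # fully complementary
  expect_equal(unname(diag(Psi)), rep(1, 3))

  # profiles differing at exactly half of p = 10 genes -> 0.5
  m2 <- rbind(x = c(rep(1, 5), rep(0, 5)), y = rep(1, 10), z = rep(1, 10))
  colnames(m2) <- paste0("g", 1:10)
  Psi2 <- compute_grm(pangenome_matrix(m2))
  expect_equal(Psi2["x", "y"], 0.5)
})

test_that("GRM is gene-order invariant and sample-permutation equivariant", {
  set.seed(21)
  G <- random_pangenome(20, 60)
  Psi <- compute_grm(G)
  perm_g <- sample(ncol(G))
  expect_equal(unclass(compute_grm(pangenome_matrix(unclass(G)[, perm_g]))),
               unclass(Psi))
  perm_s <- sample(nrow(G))
  Psi_p <- compute_grm(pangenome_matrix(unclass(G)[perm_s, ]))
  expect_equal(unclass(Psi_p), unclass(Psi)[perm_s, perm_s])
})

test_that("ridge adjustment yields a positive semidefinite matrix with recorded delta", {
  # 1 - Manhattan relatedness can be indefinite; build such a case
  m <- rbind(a = c(1, 0, 0), b = c(0, 1, 0), c = c(0, 0, 1), d = c(1, 1, 1))
  colnames(m) <- paste0("g", 1:3)
  Psi <- compute_grm(pangenome_matrix(m))
  Psir <- grm_ridge(Psi)
  expect_true(is.numeric(attr(Psir, "ridge")))
  ev <- eigen(unclass(Psir), symmetric = TRUE, only.values = TRUE)$values
  expect_true(min(ev) >= -1e-10)
  # idempotent: already-ridged input is returned unchanged
  expect_identical(grm_ridge(Psir), Psir)
})

test_that("principal components separate a two-clan GRM and match a brute-force eigensolver", {
  n <- 30
  Psi <- make_two_clan_grm(n, rho = 0.9)
  pcs <- grm_pcs(Psi, 2)
  clan <- rep(c(0, 1), c(n %/% 2, n - n %/% 2))
  expect_true(all(sign(pcs[clan == 0, 1]) == sign(pcs[1, 1])))
  expect_true(all(sign(pcs[clan == 1, 1]) == -sign(pcs[1, 1])))

  # oracle: raw eigendecomposition of the double-centered matrix
  C <- diag(n) - matrix(1 / n, n, n)
  B <- C %*% unclass(Psi) %*% C
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  expect_equal(unname(abs(pcs[, 1])), abs(e$vectors[, 1] * sqrt(e$values[1])),
               tolerance = 1e-8)

  # deterministic sign convention: largest-magnitude loading positive
  expect_gt(pcs[which.max(abs(pcs[, 1])), 1], 0)
})

test_that("full-rank PC decomposition reconstructs the double-centered GRM", {
  set.seed(5)
  G <- random_pangenome(15, 40)
  Psi <- compute_grm(G)
  n <- nrow(Psi)
  pcs <- grm_pcs(Psi, n)
  C <- diag(n) - matrix(1 / n, n, n)
  B <- C %*% unclass(Psi) %*% C
  vals <- attr(pcs, "values")
  pos <- vals > 1e-10
  recomposed <- pcs[, pos, drop = FALSE] %*% t(pcs[, pos, drop = FALSE])
  neg_part <- if (any(!pos)) {
    e <- eigen((B + t(B)) / 2, symmetric = TRUE)
    keep <- e$values < -1e-10
    if (any(keep)) e$vectors[, keep, drop = FALSE] %*%
      (e$values[keep] * t(e$vectors[, keep, drop = FALSE])) else 0
  } else 0
  expect_equal(unname(recomposed + neg_part), (B + t(B)) / 2, tolerance = 1e-6)
})

test_that("GRM TSV round-trips with sample ids in header and first column", {
  G <- random_pangenome(12, 30, seed = 9)
  Psi <- compute_grm(G)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_grm(Psi, f)
  Psi2 <- read_grm(f)
  expect_equal(unclass(Psi2), unclass(Psi), tolerance = 1e-12)
  expect_identical(rownames(Psi2), rownames(G))
})
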