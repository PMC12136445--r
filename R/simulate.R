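#' Simulate a strain-structured pangenome and trait
#'
#' Generates the synthetic study conditions used to calibrate the
#' population-structure test: `n_core` core genes present with probability
#' `p_core`, `n_acc` accessory genes present with probability `p_acc`, and
#' `n_strain_genes` strain-linked genes per strain. Each strain is carried by
#' a sample with probability `strain_prev`; a strain-linked gene is always
#' absent when its strain is absent and otherwise present with a per-gene
#' probability `p_g` drawn uniformly on an interval centered so the mean
#' presence odds against an even-odds reference equal `strain_gene_or`. A
#' host age covariate is drawn `N(covariate_mean, covariate_sd^2)`.
#'
#' The binary trait is `Bernoulli(0.5)` independent of the genes when
#' `theta = 0.5` (the null), and otherwise follows the first strain:
#' `y ~ Bernoulli((1 - strain) (1 - theta) + strain * theta)`, giving a
#' strain-trait odds ratio of `theta / (1 - theta)`.
#'
#' `n_strains > 1` adds additional independent strain blocks (each with its
#' own `n_strain_genes` genes); this is used to build base pangenomes whose
#' relatedness matrix has several meaningful structure dimensions for the
#' gene-level simulations.
#'
#' @param n number of samples.
#' @param n_core,p_core core gene count and presence probability.
#' @param n_acc,p_acc accessory gene count and presence probability.
#' @param n_strain_genes strain-linked genes per strain.
#' @param strain_prev probability a sample carries a strain.
#' @param strain_gene_or mean presence odds of a strain-linked gene when the
#'   strain is present.
#' @param or_halfwidth half-width of the uniform interval for `p_g`.
#' @param theta strain-trait probability; 0.5 is the null.
#' @param covariate_mean,covariate_sd age covariate parameters.
#' @param n_strains number of independent strain blocks.
#' @param seed optional integer seed.
#' @return list with `G` ([pangenome_matrix]), `traits` ([trait_table] with
#'   intercept + age), `strain` (n x n_strains 0/1 matrix, first column is
#'   the trait-linked strain), `labels` (per-gene block labels) and `config`.
#' @export
simulate_tau_dataset <- function(n = 100, n_core = 400, p_core = 0.8,
                                 n_acc = 400, p_acc = 0.2,
                                 n_strain_genes = 200, strain_prev = 0.5,
                                 strain_gene_or = 1.8, or_halfwidth = 0.15,
                                 theta = 0.5, covariate_mean = 45,
                                 covariate_sd = 15, n_strains = 1,
                                 seed = NULL) {
  stopifnot(theta >= 0.5, theta < 1, p_core > 0, p_core < 1,
            p_acc > 0, p_acc < 1, strain_prev > 0, strain_prev < 1)
  if (!is.null(seed)) set.seed(seed)
  p_center <- strain_gene_or / (1 + strain_gene_or)  # odds p/(1-p) = OR
  stopifnot(p_center - or_halfwidth > 0, p_center + or_halfwidth < 1)

  core <- matrix(stats::rbinom(n * n_core, 1, p_core), n, n_core)
  acc <- matrix(stats::rbinom(n * n_acc, 1, p_acc), n, n_acc)
  strain <- matrix(stats::rbinom(n * n_strains, 1, strain_prev), n, n_strains)
  colnames(strain) <- paste0("strain_", seq_len(n_strains))
  strain_blocks <- lapply(seq_len(n_strains), function(s) {
    p_g <- stats::runif(n_strain_genes, p_center - or_halfwidth,
                        p_center + or_halfwidth)
    sapply(p_g, function(pg) strain[, s] * stats::rbinom(n, 1, pg))
  })
  G <- cbind(core, acc, do.call(cbind, strain_blocks))
  labels <- c(rep("core", n_core), rep("accessory", n_acc),
              rep(paste0("strain", seq_len(n_strains)), each = n_strain_genes))
  colnames(G) <- paste0(labels, "_", unlist(lapply(table(labels)[unique(labels)],
                                                   seq_len)))
  rownames(G) <- sprintf("s%04d", seq_len(n))

  age <- stats::rnorm(n, covariate_mean, covariate_sd)
  if (theta == 0.5) {
    y <- stats::rbinom(n, 1, 0.5)
  } else {
    strain_delta <- (1 - strain[, 1]) * (1 - theta) + strain[, 1] * theta
    y <- stats::rbinom(n, 1, strain_delta)
  }
  traits <- trait_table(rownames(G), y, covariates = data.frame(age = age),
                        trait_kind = "binary")
  list(G = pangenome_matrix(G), traits = traits, strain = strain,
       labels = labels,
       config = list(n = n, n_core = n_core, p_core = p_core, n_acc = n_acc,
                     p_acc = p_acc, n_strain_genes = n_strain_genes,
                     strain_prev = strain_prev, strain_gene_or = strain_gene_or,
                     or_halfwidth = or_halfwidth, theta = theta,
                     covariate_mean = covariate_mean,
                     covariate_sd = covariate_sd, n_strains = n_strains,
                     seed = seed))
}

#' Type-I error experiment for the population-structure test
#'
#' Repeats the null simulation (trait independent of the gene matrix),
#' computes the relatedness matrix, runs the permutation test with `B`
#' permutations, and reports the fraction of iterations with p below `alpha`.
#'
#' @param iters number of simulation iterations.
#' @param n samples per iteration.
#' @param B permutations per iteration.
#' @param alpha nominal level.
#' @param seed integer seed.
#' @param ... passed to [simulate_tau_dataset()].
#' @return list with `fpr`, `p_values`, `tau_hats`, `iters`.
#' @export
tau_fpr_experiment <- function(iters = 1000, n = 100, B = 100, alpha = 0.05,
                               seed = 1, ...) {
  p_values <- numeric(iters)
  tau_hats <- numeric(iters)
  for (i in seq_len(iters)) {
    ds <- simulate_tau_dataset(n = n, theta = 0.5, seed = seed + i, ...)
    Psi <- compute_grm(ds$G)
    res <- suppressWarnings(tau_test(ds$traits, Psi, B = B, seed = seed + i))
    p_values[i] <- res$p_value
    tau_hats[i] <- res$tau_hat
  }
  list(fpr = mean(p_values < alpha), p_values = p_values,
       tau_hats = tau_hats, iters = iters)
}

#' Power experiment for the population-structure test
#'
#' For each sample size and strain-trait odds ratio, simulates the trait from
#' strain presence and measures the proportion of iterations with a
#' significant permutation test.
#'
#' @param n_values sample sizes to explore.
#' @param odds_ratios strain-trait odds ratios (`theta = OR / (1 + OR)`).
#' @param iters iterations per (n, OR) cell.
#' @param B permutations per iteration.
#' @param alpha nominal level.
#' @param seed integer seed.
#' @return data.frame with columns `n`, `odds_ratio`, `theta`, `power`,
#'   `iters`.
#' @export
tau_power_experiment <- function(n_values = c(60, 100, 250),
                                 odds_ratios = c(1, 1.5, 2, 2.5),
                                 iters = 125, B = 100, alpha = 0.05,
                                 seed = 1) {
  grid <- expand.grid(n = n_values, odds_ratio = odds_ratios)
  grid$theta <- grid$odds_ratio / (1 + grid$odds_ratio)
  grid$power <- NA_real_
  grid$iters <- iters
  for (k in seq_len(nrow(grid))) {
    hits <- 0L
    for (i in seq_len(iters)) {
      ds <- simulate_tau_dataset(n = grid$n[k], theta = grid$theta[k],
                                 seed = seed + 10000 * k + i)
      Psi <- compute_grm(ds$G)
      res <- suppressWarnings(tau_test(ds$traits, Psi, B = B,
                                       seed = seed + 10000 * k + i))
      if (res$p_value < alpha) hits <- hits + 1L
    }
    grid$power[k] <- hits / iters
  }
  grid
}

#' Simulate structured genes and a trait from a relatedness matrix
#'
#' Emulates realistic population structure by propagating an existing
#' relatedness matrix into simulated genes: the matrix is decomposed into its
#' first `k_pcs` principal components, each component is standardized and
#' mapped through the standard normal CDF to per-sample presence
#' probabilities, and `genes_per_pc` genes are drawn per component. A further
#' `n_random` unstructured genes use a constant presence probability drawn
#' uniformly from `random_p_range`. The binary trait is 1 when a sample's
#' loadings on the first two components have opposite signs — a nonlinear
#' function of the structure, so structured genes associate with the trait
#' only through the population structure.
#'
#' When `theta > 0.5`, `n_causal` truly trait-associated genes are appended
#' with presence probability `(1 - y)(1 - theta) + y * theta` (trait odds
#' ratio `theta / (1 - theta)`).
#'
#' @param Psi a `relatedness_matrix` providing the base structure.
#' @param k_pcs number of components used.
#' @param genes_per_pc structured genes per component.
#' @param n_random unstructured genes.
#' @param random_p_range range of presence probabilities for random genes.
#' @param n_causal trait-associated genes appended when `theta > 0.5`.
#' @param theta causal-gene presence probability given the trait.
#' @param covariate_mean,covariate_sd age covariate parameters.
#' @param seed optional integer seed.
#' @return list with `G`, `traits`, `labels` (per-gene:
#'   `"pc1"`...`"pc10"`, `"random"`, `"causal"`), `negatives` (logical mask
#'   of genes counted as true negatives: everything not from PC1/PC2 and not
#'   causal), `pcs` and `config`.
#' @export
simulate_beta_dataset <- function(Psi, k_pcs = 10, genes_per_pc = 90,
                                  n_random = 100,
                                  random_p_range = c(0.2, 0.8),
                                  n_causal = 100, theta = 0.5,
                                  covariate_mean = 45, covariate_sd = 15,
                                  seed = NULL) {
  n <- nrow(Psi)
  if (n < k_pcs) stop("need at least k_pcs samples", call. = FALSE)
  stopifnot(theta >= 0.5, theta < 1)
  if (!is.null(seed)) set.seed(seed)
  pcs <- grm_pcs(Psi, k_pcs)
  prob <- stats::pnorm(scale(pcs, center = FALSE,
                             scale = apply(pcs, 2, stats::sd)))
  pc_genes <- lapply(seq_len(k_pcs), function(j) {
    matrix(stats::rbinom(n * genes_per_pc, 1, rep(prob[, j], genes_per_pc)),
           n, genes_per_pc)
  })
  p_rand <- stats::runif(n_random, random_p_range[1], random_p_range[2])
  rand_genes <- sapply(p_rand, function(pg) stats::rbinom(n, 1, pg))
  G <- cbind(do.call(cbind, pc_genes), rand_genes)
  labels <- c(rep(paste0("pc", seq_len(k_pcs)), each = genes_per_pc),
              rep("random", n_random))

  y <- as.integer((pcs[, 1] > 0 & pcs[, 2] < 0) |
                    (pcs[, 1] < 0 & pcs[, 2] > 0))
  if (theta > 0.5) {
    ydelta <- (1 - y) * (1 - theta) + y * theta
    causal <- matrix(stats::rbinom(n * n_causal, 1, rep(ydelta, n_causal)),
                     n, n_causal)
    G <- cbind(G, causal)
    labels <- c(labels, rep("causal", n_causal))
  }
  colnames(G) <- paste0(labels, "_", unlist(lapply(rle(labels)$lengths, seq_len)))
  rownames(G) <- if (!is.null(rownames(Psi))) rownames(Psi) else
    sprintf("s%04d", seq_len(n))
  age <- stats::rnorm(n, covariate_mean, covariate_sd)
  traits <- trait_table(rownames(G), y, covariates = data.frame(age = age),
                        trait_kind = "binary")
  negatives <- !(labels %in% c("pc1", "pc2", "causal"))
  list(G = pangenome_matrix(G), traits = traits, labels = labels,
       negatives = negatives, pcs = pcs,
       config = list(k_pcs = k_pcs, genes_per_pc = genes_per_pc,
                     n_random = n_random, random_p_range = random_p_range,
                     n_causal = n_causal, theta = theta, seed = seed))
}

#' False-positive-rate and power experiment for the gene-level tests
#'
#' Runs the gene-level simulation over a grid of trait-gene odds ratios on
#' identical data for the mixed-model score test and the plain-regression
#' baseline. For each replicate a fresh base pangenome (two independent
#' strain blocks) supplies the base relatedness matrix; structured and
#' (optionally) causal genes are simulated from it; both methods are run on
#' every gene. The false positive rate is the fraction of true-negative
#' genes (everything not simulated from PC1/PC2 and not causal) with
#' p < `alpha`. Power is measured at a matched empirical false positive
#' rate: the per-method threshold is the `alpha` quantile of the negative
#' genes' p-values, and power is the fraction of causal genes below it.
#'
#' @param thetas trait-gene probabilities (0.5 = pure null, no causal genes).
#' @param n samples per replicate.
#' @param replicates replicates per theta.
#' @param alpha nominal level for FPR and the empirical threshold.
#' @param seed integer seed.
#' @return data.frame with one row per (theta, replicate): `theta`,
#'   `odds_ratio`, `replicate`, `n`, `tau_hat`, `fpr_mixed`, `fpr_glm`,
#'   `power_mixed`, `power_glm` (power is NA for theta = 0.5).
#' @export
beta_fpr_power_experiment <- function(thetas = c(0.5, 0.6, 0.7, 0.78),
                                      n = 100, replicates = 3, alpha = 0.05,
                                      seed = 1) {
  rows <- list()
  for (ti in seq_along(thetas)) {
    theta <- thetas[ti]
    for (r in seq_len(replicates)) {
      s <- seed + 1000 * ti + r
      base <- simulate_tau_dataset(n = n, n_strains = 2, theta = 0.5, seed = s)
      Psi0 <- compute_grm(base$G)
      ds <- simulate_beta_dataset(Psi0, theta = theta, seed = s + 500000)
      keep <- apply(unclass(ds$G), 2, function(col) length(unique(col)) > 1L)
      G <- pangenome_matrix(unclass(ds$G)[, keep, drop = FALSE])
      labels <- ds$labels[keep]
      negatives <- ds$negatives[keep]
      Psi <- compute_grm(G)
      fit <- suppressWarnings(fit_null_model(ds$traits, Psi))
      mixed <- run_beta_tests(fit, G)
      glmb <- run_glm_baseline(ds$traits, G)
      p_mixed <- mixed$p_value
      p_glm <- glmb$p_value
      fpr_mixed <- mean(p_mixed[negatives] < alpha)
      fpr_glm <- mean(p_glm[negatives] < alpha)
      if (theta > 0.5) {
        causal <- labels == "causal"
        thr_mixed <- stats::quantile(p_mixed[negatives], alpha, names = FALSE)
        thr_glm <- stats::quantile(p_glm[negatives], alpha, names = FALSE)
        power_mixed <- mean(p_mixed[causal] <= thr_mixed)
        power_glm <- mean(p_glm[causal] <= thr_glm)
      } else {
        power_mixed <- NA_real_
        power_glm <- NA_real_
      }
      rows[[length(rows) + 1]] <- data.frame(
        theta = theta, odds_ratio = theta / (1 - theta), replicate = r, n = n,
        tau_hat = fit$tau, fpr_mixed = fpr_mixed, fpr_glm = fpr_glm,
        power_mixed = power_mixed, power_glm = power_glm)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
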