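#' Population-structure test statistic
#'
#' The statistic `T = sum(b_i^2) / n` summarizes how strongly the fitted
#' random effects — the per-sample strain-structure component — deviate from
#' zero. Under no structure-trait association the random effects shrink
#' toward zero and T is small.
#'
#' @param fit a `null_model_fit`.
#' @return Nonnegative scalar T.
#' @export
tau_statistic <- function(fit) {
  sum(fit$b^2) / length(fit$b)
}

#' Permutation test for strain-level population structure
#'
#' Tests whether the species' population structure (encoded in the
#' relatedness matrix) is associated with the host trait. The null model is
#' fit on the observed data to obtain `T_obs = sum(b^2)/n`; the trait vector
#' is then permuted `B` times (covariates and `Psi` stay attached to their
#' samples), the model refit, and the permutation p-value computed with the
#' add-one correction `p = (1 + #\{T_perm > T_obs\}) / (B + 1)`: permuted
#' statistics must strictly exceed the observed one (variance-component
#' estimates sit on the `tau = 0` boundary in a sizeable fraction of null
#' fits, so `T` has an atom at zero and the tie-handling rule matters). The
#' add-one correction keeps `p` strictly positive.
#'
#' @param traits a [trait_table].
#' @param Psi a `relatedness_matrix` aligned to `traits`.
#' @param B number of permutations (default 1000; values below 20 give a
#'   very coarse p-value resolution and trigger a warning).
#' @param seed optional integer seed recorded in the result for exact
#'   reproducibility.
#' @param ... passed to [fit_null_model()].
#' @return An object of class `tau_result`: list with `tau_hat`, `T_obs`,
#'   `T_perm`, `p_value`, `B`, `auc` (binary traits), `b`, `fit`, `seed`.
#' @export
tau_test <- function(traits, Psi, B = 1000, seed = NULL, ...) {
  if (B < 20) {
    warning("B < 20 permutations gives very coarse p-value resolution",
            call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  Psi <- grm_ridge(Psi)  # ridge once; permutation refits reuse it
  fit <- fit_null_model(traits, Psi, ...)
  T_obs <- tau_statistic(fit)
  n <- length(traits$y)
  T_perm <- rep(NA_real_, B)
  for (i in seq_len(B)) {
    yp <- traits$y[sample.int(n)]
    tp <- traits
    tp$y <- yp
    fp <- tryCatch(
      suppressWarnings(fit_null_model(tp, Psi, ...)),
      error = function(e) NULL)
    if (!is.null(fp)) T_perm[i] <- tau_statistic(fp)
  }
  failed <- sum(is.na(T_perm))
  if (failed > 0) {
    warning(sprintf("%d of %d permutation refits failed and were dropped",
                    failed, B), call. = FALSE)
  }
  B_eff <- B - failed
  p <- (1 + sum(T_perm > T_obs, na.rm = TRUE)) / (B_eff + 1)
  auc <- if (fit$link == "logit") training_auc(fit) else NA_real_
  structure(list(tau_hat = fit$tau, T_obs = T_obs, T_perm = T_perm,
                 p_value = p, B = B, n_failed = failed, auc = auc,
                 b = fit$b, fit = fit, seed = seed),
            class = "tau_result")
}

#' @export
print.tau_result <- function(x, ...) {
  cat(sprintf("tau test: tau_hat = %.4g, T_obs = %.4g, p = %.4g (B = %d)",
              x$tau_hat, x$T_obs, x$p_value, x$B))
  if (!is.na(x$auc)) cat(sprintf(", training AUC = %.3f", x$auc))
  cat("\n")
  invisible(x)
}

#' Write per-species tau test results to TSV
#'
#' @param results named list of `tau_result` objects (names = species ids),
#'   or a single `tau_result` (species id `"species"`).
#' @param path output TSV path.
#' @export
write_tau_results <- function(results, path) {
  if (inherits(results, "tau_result")) results <- list(species = results)
  dt <- data.table::rbindlist(lapply(names(results), function(sp) {
    r <- results[[sp]]
    data.table::data.table(species_id = sp, n = length(r$b),
                           tau_hat = r$tau_hat, T_obs = r$T_obs,
                           p_value = r$p_value, B = r$B, auc = r$auc)
  }))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
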