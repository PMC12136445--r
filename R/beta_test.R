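#' Score test for one gene family given the null fit
#'
#' Tests whether a gene's presence/absence associates with the trait beyond
#' what population structure and covariates explain, without re-estimating
#' the null model (the SAIGE-style strategy: the null fit is reused across
#' all genes). The genotype is covariate-adjusted with the working weights,
#' `g_adj = g - X (X'WX)^-1 X'W g`; the score is `S = g_adj' (y - mu)`
#' (divided by `sigma2` for quantitative traits) and its exact variance is
#' `g' P g` with the projection `P` from the null fit. For binary traits,
#' p-values with `|z| >` `spa_z_threshold` are refined by a saddlepoint
#' approximation of the score distribution, which corrects the
#' normal-approximation inflation seen with unbalanced case/control ratios.
#'
#' @param fit a `null_model_fit`.
#' @param g numeric 0/1 genotype vector aligned to the fit's samples.
#' @param gene_id identifier recorded in the output.
#' @param spa apply the saddlepoint correction (binary traits only).
#' @param spa_z_threshold trigger: SPA is used when `|z_raw|` exceeds this.
#' @return One-row data.frame (a `gene_association` record) with columns
#'   `gene_id`, `score`, `var_score`, `beta_hat`, `z_raw`, `p_value`,
#'   `spa_used`, `spa_converged`, `untestable`, `z_signed`.
#' @export
score_test_gene <- function(fit, g, gene_id = "gene", spa = TRUE,
                            spa_z_threshold = 2) {
  G <- matrix(as.numeric(g), ncol = 1, dimnames = list(NULL, gene_id))
  run_beta_tests(fit, G, spa = spa, spa_z_threshold = spa_z_threshold)
}

#' Score tests for every gene in a pangenome matrix
#'
#' Runs [score_test_gene()] across all gene families, reusing the null model
#' fit (fit once per species). Constant genes and genes whose score variance
#' degenerates are flagged `untestable` with `p_value = 1` rather than
#' aborting the batch. The signed z-value used by the localFDR stage is
#' attached as `z_signed`.
#'
#' @param fit a `null_model_fit`.
#' @param G a [pangenome_matrix] (or plain 0/1 matrix) aligned to the fit's
#'   samples, typically pre-filtered with [filter_variable_genes()].
#' @inheritParams score_test_gene
#' @return data.frame with one `gene_association` row per gene.
#' @export
run_beta_tests <- function(fit, G, spa = TRUE, spa_z_threshold = 2) {
  Gm <- unclass(G)
  storage.mode(Gm) <- "numeric"
  if (is.null(dim(Gm))) Gm <- matrix(Gm, ncol = 1)
  if (nrow(Gm) != length(fit$y)) {
    stop("gene matrix rows do not match the null fit's samples", call. = FALSE)
  }
  if (!is.null(rownames(Gm)) && !is.null(fit$sample_ids) &&
      !identical(rownames(Gm), fit$sample_ids)) {
    stop("gene matrix sample order differs from the null fit", call. = FALSE)
  }
  p <- ncol(Gm)
  gene_ids <- colnames(Gm)
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(p))

  X <- fit$X
  W <- fit$W
  y <- fit$y
  mu <- fit$mu
  XtWX <- crossprod(X, W * X)
  cW <- chol((XtWX + t(XtWX)) / 2)
  H <- .spd_solve(cW, crossprod(X, W * Gm))        # q x p
  G_adj <- Gm - X %*% H
  resid_scale <- if (fit$link == "identity") 1 / fit$sigma2 else 1
  S <- drop(crossprod(G_adj, (y - mu))) * resid_scale
  PG <- .apply_P(fit$sol, Gm)
  var_S <- colSums(Gm * PG)

  constant <- apply(Gm, 2, function(col) length(unique(col)) == 1L)
  untestable <- constant | !(var_S > 1e-12)

  z_raw <- rep(NA_real_, p)
  z_raw[!untestable] <- S[!untestable] / sqrt(var_S[!untestable])
  beta_hat <- rep(NA_real_, p)
  beta_hat[!untestable] <- S[!untestable] / var_S[!untestable]
  p_value <- rep(1, p)
  p_value[!untestable] <- 2 * stats::pnorm(-abs(z_raw[!untestable]))
  spa_used <- rep(FALSE, p)
  spa_converged <- rep(NA, p)

  if (spa && fit$link == "logit") {
    idx <- which(!untestable & abs(z_raw) > spa_z_threshold)
    for (j in idx) {
      sp <- spa_pvalue(G_adj[, j], mu, S[j], var_S[j])
      spa_used[j] <- TRUE
      spa_converged[j] <- sp$converged
      if (sp$converged) p_value[j] <- sp$p_value
    }
  }
  p_value <- pmin(pmax(p_value, .Machine$double.xmin), 1)
  z_signed <- p_to_signed_z(p_value, sign(ifelse(is.na(beta_hat), 0, beta_hat)))
  data.frame(gene_id = gene_ids, score = S, var_score = var_S,
             beta_hat = beta_hat, z_raw = z_raw, p_value = p_value,
             spa_used = spa_used, spa_converged = spa_converged,
             untestable = untestable, z_signed = z_signed,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Saddlepoint tail approximation for the gene score statistic
#'
#' Under the null, the score `S = sum_i g_adj_i (y_i - mu_i)` for a binary
#' trait is a weighted sum of centered Bernoulli variables with cumulant
#' generating function
#' `K(t) = sum log(1 - mu_i + mu_i exp(g_i t)) - t sum g_i mu_i`.
#' The adjusted genotype is rescaled so that `K''(0)` equals the exact score
#' variance, the saddlepoint `K'(zeta) = s` is found by safeguarded Newton,
#' and each tail is approximated with the Barndorff-Nielsen formula
#' `w = sign(zeta) sqrt(2 (zeta s - K(zeta)))`, `v = zeta sqrt(K''(zeta))`,
#' `tail = 1 - Phi(w + log(v/w)/w)`. The two-sided p-value adds the upper
#' tail at `|s|` and the lower tail at `-|s|` (the SAIGE convention, which
#' under a skewed null correctly inflates the anti-conservative normal
#' p-value); `s = 0` returns `p = 1` exactly. A tail lying beyond the
#' support of `S` has probability 0.
#'
#' @param g_adj covariate-adjusted genotype vector.
#' @param mu fitted null means (Bernoulli probabilities).
#' @param s_obs observed score.
#' @param var_exact exact score variance `g' P g`.
#' @return list with `p_value` and `converged` (FALSE means the caller should
#'   keep the normal approximation).
#' @export
spa_pvalue <- function(g_adj, mu, s_obs, var_exact) {
  if (s_obs == 0) return(list(p_value = 1, converged = TRUE))
  v0 <- sum(g_adj^2 * mu * (1 - mu))
  if (!(v0 > 0) || !(var_exact > 0)) {
    return(list(p_value = NA_real_, converged = FALSE))
  }
  g <- g_adj * sqrt(var_exact / v0)
  gmu <- sum(g * mu)
  # support of S = sum g_i (Y_i - mu_i) over Y in {0,1}^n
  s_min <- sum(pmin(-g * mu, g * (1 - mu)))
  s_max <- sum(pmax(-g * mu, g * (1 - mu)))

  K <- function(t) sum(log1p(mu * (exp(g * t) - 1))) - t * gmu
  Kp <- function(t) {
    e <- exp(g * t)
    sum(mu * g * e / (1 - mu + mu * e)) - gmu
  }
  Kpp <- function(t) {
    e <- exp(g * t)
    sum(mu * (1 - mu) * g^2 * e / (1 - mu + mu * e)^2)
  }

  tail_p <- function(q) {
    # q > 0 requests the upper tail P(S >= q), q < 0 the lower tail P(S <= q)
    if (q > 0 && q > s_max) return(0)
    if (q < 0 && q < s_min) return(0)
    zeta <- .spa_root(q, Kp, Kpp, var_exact)
    if (is.na(zeta)) return(NA_real_)
    arg <- zeta * q - K(zeta)
    if (!(arg > 0)) return(NA_real_)
    w <- sign(zeta) * sqrt(2 * arg)
    v <- zeta * sqrt(Kpp(zeta))
    if (!(is.finite(w)) || w == 0 || !(v / w > 0)) return(NA_real_)
    u <- w + log(v / w) / w
    if (q > 0) stats::pnorm(u, lower.tail = FALSE) else stats::pnorm(u)
  }

  s <- abs(s_obs)
  upper <- tail_p(s)
  lower <- tail_p(-s)
  if (is.na(upper) || is.na(lower)) {
    return(list(p_value = NA_real_, converged = FALSE))
  }
  list(p_value = min(1, upper + lower), converged = TRUE)
}

# Safeguarded Newton solve of K'(zeta) = q, with bracket expansion and
# bisection fallback. Returns NA when q is outside the attainable range.
.spa_root <- function(q, Kp, Kpp, var0, tol = 1e-10, max_iter = 100) {
  zeta <- q / var0  # normal-approximation start
  lo <- NA_real_
  hi <- NA_real_
  # bracket: Kp is increasing, Kp(0) = 0
  step <- max(abs(zeta), 1)
  if (q > 0) {
    lo <- 0
    hi <- step
    it <- 0L
    while (Kp(hi) < q) {
      hi <- hi * 2
      it <- it + 1L
      if (it > 200L || !is.finite(Kp(hi))) return(NA_real_)
    }
  } else {
    hi <- 0
    lo <- -step
    it <- 0L
    while (Kp(lo) > q) {
      lo <- lo * 2
      it <- it + 1L
      if (it > 200L || !is.finite(Kp(lo))) return(NA_real_)
    }
  }
  zeta <- .clip(zeta, lo, hi)
  for (i in seq_len(max_iter)) {
    f <- Kp(zeta) - q
    if (abs(f) < tol * max(1, abs(q))) return(zeta)
    if (f > 0) hi <- zeta else lo <- zeta
    d <- Kpp(zeta)
    zeta_new <- if (d > 0) zeta - f / d else NA_real_
    if (is.na(zeta_new) || zeta_new <= lo || zeta_new >= hi) {
      zeta_new <- (lo + hi) / 2  # bisection safeguard
    }
    if (abs(zeta_new - zeta) < 1e-14 * max(1, abs(zeta))) return(zeta_new)
    zeta <- zeta_new
  }
  zeta
}

#' Plain logistic/linear regression baseline for one gene
#'
#' Fits the same fixed effects as the mixed model but with no random effect —
#' the standard single-gene regression used in the literature — and reports
#' the Wald p-value for the gene coefficient. Used as the comparison baseline
#' in simulations. Separation is handled by a ridge-penalized refit and
#' flagged.
#'
#' @param traits a [trait_table].
#' @param g numeric 0/1 genotype vector aligned to `traits`.
#' @param gene_id identifier recorded in the output.
#' @return One-row data.frame: `gene_id`, `beta_hat`, `se`, `z`, `p_value`,
#'   `separation`, `untestable`.
#' @export
glm_baseline_gene <- function(traits, g, gene_id = "gene") {
  run_glm_baseline(traits, matrix(as.numeric(g), ncol = 1,
                                  dimnames = list(NULL, gene_id)))
}

#' Plain-regression baseline over all genes
#'
#' @param traits a [trait_table].
#' @param G a [pangenome_matrix] (or 0/1 matrix) aligned to `traits`.
#' @return data.frame with one row per gene (see [glm_baseline_gene()]).
#' @export
run_glm_baseline <- function(traits, G) {
  Gm <- unclass(G)
  storage.mode(Gm) <- "numeric"
  if (is.null(dim(Gm))) Gm <- matrix(Gm, ncol = 1)
  gene_ids <- colnames(Gm)
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(ncol(Gm)))
  X <- traits$X
  y <- traits$y
  binary <- traits$trait_kind == "binary"
  q <- ncol(X)
  out <- lapply(seq_len(ncol(Gm)), function(j) {
    g <- Gm[, j]
    if (length(unique(g)) == 1L) {
      return(data.frame(gene_id = gene_ids[j], beta_hat = NA_real_,
                        se = NA_real_, z = NA_real_, p_value = 1,
                        separation = FALSE, untestable = TRUE))
    }
    Xg <- cbind(X, gene = g)
    separation <- FALSE
    if (binary) {
      f <- suppressWarnings(stats::glm.fit(Xg, y, family = stats::binomial()))
      coefs <- f$coefficients
      if (!f$converged || max(abs(coefs)) > 15) {
        separation <- TRUE
        coefs <- .ridge_irls(Xg, y, lambda = 1e-3)
        eta <- drop(Xg %*% coefs)
        mu <- .clip(stats::plogis(eta), 1e-9, 1 - 1e-9)
        Wd <- mu * (1 - mu)
      } else {
        Wd <- f$weights
      }
      cov <- tryCatch(chol2inv(chol(crossprod(Xg, Wd * Xg))),
                      error = function(e) NULL)
      if (is.null(cov)) {
        return(data.frame(gene_id = gene_ids[j], beta_hat = NA_real_,
                          se = NA_real_, z = NA_real_, p_value = 1,
                          separation = separation, untestable = TRUE))
      }
      se <- sqrt(cov[q + 1, q + 1])
      z <- coefs[q + 1] / se
      data.frame(gene_id = gene_ids[j], beta_hat = coefs[q + 1], se = se,
                 z = z, p_value = 2 * stats::pnorm(-abs(z)),
                 separation = separation, untestable = FALSE)
    } else {
      f <- stats::lm.fit(Xg, y)
      rdf <- length(y) - ncol(Xg)
      s2 <- sum(f$residuals^2) / rdf
      cov <- chol2inv(chol(crossprod(Xg))) * s2
      se <- sqrt(cov[q + 1, q + 1])
      tval <- f$coefficients[q + 1] / se
      data.frame(gene_id = gene_ids[j], beta_hat = f$coefficients[q + 1],
                 se = se, z = tval,
                 p_value = 2 * stats::pt(-abs(tval), df = rdf),
                 separation = FALSE, untestable = FALSE)
    }
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
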