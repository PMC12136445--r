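#' Fit the trait-on-structure null model
#'
#' Fits the generalized linear mixed model
#' `f(E[y]) = X alpha + b`, `b ~ N(0, tau * Psi)`, where `Psi` is the
#' species genetic relatedness matrix, by penalized quasi-likelihood with
#' AI-REML variance-component updates. For binary traits the link is logit
#' and the residual variance is absorbed into the PQL working weights; for
#' quantitative traits the link is identity and a free residual variance
#' `sigma2` is estimated jointly with `tau`.
#'
#' The fitted object caches the Cholesky factor of the working covariance
#' `V = W^-1 + tau * Psi` and the projection pieces needed to apply
#' `P = V^-1 - V^-1 X (X'V^-1X)^-1 X'V^-1` to new vectors, so that per-gene
#' score tests reuse the null fit without refitting.
#'
#' @param traits a [trait_table].
#' @param Psi a `relatedness_matrix` aligned to `traits` (same samples, same
#'   order). A minimal diagonal ridge is added internally if `Psi` is not
#'   positive semidefinite (see [grm_ridge()]).
#' @param link `"auto"` (logit for binary traits, identity otherwise),
#'   `"logit"` or `"identity"`.
#' @param tol convergence tolerance on the maximum relative change of
#'   `(alpha, tau, sigma2)`.
#' @param max_iter maximum outer iterations.
#' @param fix_tau optionally fix `tau` at a value (e.g. 0 to recover an
#'   ordinary GLM fit) instead of estimating it.
#' @return An object of class `null_model_fit` with elements `alpha`, `b`,
#'   `tau`, `sigma2`, `mu`, `W`, `eta`, `link`, `converged`, `n_iter`,
#'   `ridge`, `diagnostics`, plus cached factors used by the score tests.
#' @export
fit_null_model <- function(traits, Psi, link = c("auto", "logit", "identity"),
                           tol = 1e-4, max_iter = 50, fix_tau = NULL) {
  link <- match.arg(link)
  if (link == "auto") {
    link <- if (traits$trait_kind == "binary") "logit" else "identity"
  }
  if (link == "logit" && traits$trait_kind != "binary") {
    stop("logit link requires a binary trait", call. = FALSE)
  }
  y <- traits$y
  X <- traits$X
  n <- length(y)
  if (nrow(Psi) != n) stop("Psi dimension does not match sample count", call. = FALSE)
  ids_psi <- rownames(Psi)
  if (!is.null(ids_psi) && !identical(ids_psi, traits$sample_ids)) {
    if (!setequal(ids_psi, traits$sample_ids)) {
      stop("Psi and trait table sample ids differ", call. = FALSE)
    }
    Psi <- Psi[traits$sample_ids, traits$sample_ids]
  }
  Psi <- grm_ridge(Psi)
  ridge <- attr(Psi, "ridge")
  Psi <- unclass(Psi)
  attr(Psi, "ridge") <- NULL

  if (link == "logit") {
    .fit_null_logit(y, X, Psi, traits, tol, max_iter, fix_tau, ridge)
  } else {
    .fit_null_identity(y, X, Psi, traits, tol, max_iter, fix_tau, ridge)
  }
}

# One iteration's worth of mixed-model solves shared by both links.
# V^-1 is formed explicitly (n is at most a few thousand here), which makes
# every subsequent projection and trace O(n^2).
.mm_solve <- function(X, Psi, Yt, Vdiag, tau) {
  V <- tau * Psi
  diag(V) <- diag(V) + Vdiag
  R <- chol(V)
  Vinv <- chol2inv(R)
  ViX <- Vinv %*% X
  XtViX <- crossprod(X, ViX)
  cX <- chol((XtViX + t(XtViX)) / 2)
  alpha <- drop(.spd_solve(cX, crossprod(ViX, Yt)))
  PY <- as.vector(Vinv %*% Yt - ViX %*% alpha)  # = V^-1 (Yt - X alpha) = P Yt
  b <- tau * as.vector(Psi %*% PY)
  list(alpha = alpha, b = b, PY = PY, Vinv = Vinv, ViX = ViX, cX = cX)
}

# Apply P = V^-1 - V^-1 X (X'V^-1 X)^-1 X' V^-1 to columns of M.
.apply_P <- function(sol, M) {
  sol$Vinv %*% M - sol$ViX %*% .spd_solve(sol$cX, crossprod(sol$ViX, M))
}

# tr(P A) for symmetric A, using cached factors.
.trace_PA <- function(sol, A) {
  t1 <- sum(sol$Vinv * A)  # tr(V^-1 A), both symmetric
  M <- crossprod(sol$ViX, A %*% sol$ViX)  # X' V^-1 A V^-1 X, q x q
  t1 - sum(diag(.spd_solve(sol$cX, M)))
}

.fit_null_logit <- function(y, X, Psi, traits, tol, max_iter, fix_tau, ridge) {
  n <- length(y)
  diagnostics <- character(0)
  fit0 <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
  alpha <- fit0$coefficients
  if (!fit0$converged || max(abs(alpha)) > 15) {
    warning("possible separation in the initial logistic fit; ",
            "continuing from a penalized start", call. = FALSE)
    diagnostics <- c(diagnostics, "separation_initial_glm")
    alpha <- .ridge_irls(X, y, lambda = 1e-2)
  }
  b <- numeric(n)
  eta <- drop(X %*% alpha) + b
  mu <- .clip(stats::plogis(eta), 1e-5, 1 - 1e-5)
  W <- mu * (1 - mu)
  wres <- (y - mu) / W
  tau <- if (!is.null(fix_tau)) fix_tau else
    max(0.5 * stats::var(wres) / mean(diag(Psi)), 1e-4)

  converged <- FALSE
  iter <- 0L
  sol <- NULL
  repeat {
    iter <- iter + 1L
    eta <- drop(X %*% alpha) + b
    mu <- .clip(stats::plogis(eta), 1e-5, 1 - 1e-5)
    W <- mu * (1 - mu)
    Yt <- eta + (y - mu) / W
    sol <- .mm_solve(X, Psi, Yt, 1 / W, tau)
    alpha_new <- sol$alpha
    b_new <- sol$b
    tau_new <- tau
    if (is.null(fix_tau)) {
      APY <- drop(Psi %*% sol$PY)
      score <- 0.5 * (sum(sol$PY * APY) - .trace_PA(sol, Psi))
      PAPY <- drop(.apply_P(sol, APY))
      AI <- 0.5 * sum(APY * PAPY)
      step <- score / max(AI, 1e-10)
      tau_new <- tau + step
      halvings <- 0L
      while (tau_new < 0 && halvings < 30L) {  # step-halve toward the boundary
        step <- step / 2
        tau_new <- tau + step
        halvings <- halvings + 1L
      }
      if (tau_new < 0) tau_new <- tau / 2
      if (tau_new < 1e-6 && score < 0) tau_new <- 0
    }
    par_old <- c(alpha, tau)
    par_new <- c(alpha_new, tau_new)
    rel <- max(abs(par_new - par_old) / (abs(par_old) + tol))
    alpha <- alpha_new
    b <- b_new
    tau <- tau_new
    if (iter >= 2L && rel < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
  }
  if (!converged) {
    warning(sprintf("null model did not converge in %d iterations", max_iter),
            call. = FALSE)
  }
  # refresh cached quantities at the final parameters
  eta <- drop(X %*% alpha) + b
  mu <- .clip(stats::plogis(eta), 1e-5, 1 - 1e-5)
  W <- mu * (1 - mu)
  Yt <- eta + (y - mu) / W
  sol <- .mm_solve(X, Psi, Yt, 1 / W, tau)
  names(alpha) <- colnames(X)
  structure(list(alpha = alpha, b = b, tau = tau, sigma2 = 1,
                 mu = mu, W = W, eta = eta, link = "logit",
                 converged = converged, n_iter = iter, ridge = ridge,
                 diagnostics = diagnostics,
                 y = y, X = X, Psi = Psi, Yt = Yt,
                 sample_ids = traits$sample_ids,
                 trait_kind = traits$trait_kind,
                 sol = sol),
            class = "null_model_fit")
}

.fit_null_identity <- function(y, X, Psi, traits, tol, max_iter, fix_tau, ridge) {
  n <- length(y)
  diagnostics <- character(0)
  fit0 <- stats::lm.fit(X, y)
  alpha <- fit0$coefficients
  res <- fit0$residuals
  sigma2 <- max(stats::var(res), 1e-8)
  tau <- if (!is.null(fix_tau)) fix_tau else
    max(0.5 * stats::var(res) / mean(diag(Psi)), 1e-4)
  b <- numeric(n)

  converged <- FALSE
  iter <- 0L
  sol <- NULL
  repeat {
    iter <- iter + 1L
    sol <- .mm_solve(X, Psi, y, rep(sigma2, n), tau)
    alpha_new <- sol$alpha
    b_new <- sol$b
    PY <- sol$PY
    IPY <- PY
    APY <- drop(Psi %*% PY)
    score <- 0.5 * c(sum(PY * IPY) - .trace_PA(sol, diag(n)),
                     sum(PY * APY) - .trace_PA(sol, Psi))
    P_IPY <- drop(.apply_P(sol, IPY))
    P_APY <- drop(.apply_P(sol, APY))
    AI <- 0.5 * matrix(c(sum(IPY * P_IPY), sum(IPY * P_APY),
                         sum(APY * P_IPY), sum(APY * P_APY)), 2, 2)
    if (is.null(fix_tau)) {
      sv <- .safe_solve(AI, score)
      if (sv$singular) diagnostics <- unique(c(diagnostics, "ai_matrix_singular"))
      step <- sv$x
    } else {
      step <- c(score[1] / max(AI[1, 1], 1e-10), 0)
    }
    theta <- c(sigma2, tau)
    floor1 <- 1e-8 * stats::var(y)
    theta_new <- theta + step
    # boundary projection: if the joint AI step leaves the parameter space,
    # clamp the offending component and take a 1-D (step-halved) AI step in
    # the other, so the free component keeps improving
    if (theta_new[2] < 0) {
      s1 <- score[1] / max(AI[1, 1], 1e-10)
      halvings <- 0L
      while (theta[1] + s1 < floor1 && halvings < 30L) {
        s1 <- s1 / 2
        halvings <- halvings + 1L
      }
      theta_new <- c(max(theta[1] + s1, floor1), 0)
    } else if (theta_new[1] < floor1) {
      s2 <- score[2] / max(AI[2, 2], 1e-10)
      halvings <- 0L
      while (theta[2] + s2 < 0 && halvings < 30L) {
        s2 <- s2 / 2
        halvings <- halvings + 1L
      }
      theta_new <- c(floor1, max(theta[2] + s2, 0))
    }
    if (is.null(fix_tau) && theta_new[2] < 1e-6 && score[2] < 0) theta_new[2] <- 0
    par_old <- c(alpha, theta)
    par_new <- c(alpha_new, theta_new)
    rel <- max(abs(par_new - par_old) / (abs(par_old) + tol))
    alpha <- alpha_new
    b <- b_new
    sigma2 <- theta_new[1]
    tau <- if (is.null(fix_tau)) theta_new[2] else fix_tau
    if (iter >= 2L && rel < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
  }
  if (!converged) {
    warning(sprintf("null model did not converge in %d iterations", max_iter),
            call. = FALSE)
  }
  sol <- .mm_solve(X, Psi, y, rep(sigma2, n), tau)
  alpha <- sol$alpha
  b <- sol$b
  eta <- drop(X %*% alpha) + b
  names(alpha) <- colnames(X)
  structure(list(alpha = alpha, b = b, tau = tau, sigma2 = sigma2,
                 mu = eta, W = rep(1 / sigma2, n), eta = eta, link = "identity",
                 converged = converged, n_iter = iter, ridge = ridge,
                 diagnostics = diagnostics,
                 y = y, X = X, Psi = Psi, Yt = y,
                 sample_ids = traits$sample_ids,
                 trait_kind = traits$trait_kind,
                 sol = sol),
            class = "null_model_fit")
}

# Small ridge-penalized IRLS used as a penalized start under separation.
.ridge_irls <- function(X, y, lambda = 1e-2, max_iter = 50, tol = 1e-8) {
  beta <- numeric(ncol(X))
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- .clip(stats::plogis(eta), 1e-9, 1 - 1e-9)
    W <- mu * (1 - mu)
    H <- crossprod(X, W * X) + diag(lambda, ncol(X))
    g <- crossprod(X, y - mu) - lambda * beta
    delta <- solve(H, g)
    beta <- beta + drop(delta)
    if (max(abs(delta)) < tol) break
  }
  beta
}

#' @export
print.null_model_fit <- function(x, ...) {
  cat(sprintf("null_model_fit (%s link): n = %d, tau = %.4g, sigma2 = %.4g, %s in %d iters\n",
              x$link, length(x$y), x$tau, x$sigma2,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  cat("fixed effects:\n")
  print(x$alpha)
  invisible(x)
}

#' Training-set AUC of the fitted null model
#'
#' Area under the ROC curve of the fitted linear predictor `X alpha + b`
#' against the observed binary trait, with midrank handling of ties. Because
#' the random effects are per-sample parameters, this is an in-sample
#' (training) AUC: it measures how well the population-structure component
#' separates cases from controls, not out-of-sample prediction.
#'
#' @param fit a `null_model_fit` for a binary trait.
#' @param y trait vector; defaults to the one used in the fit.
#' @return AUC in \[0, 1\].
#' @export
training_auc <- function(fit, y = fit$y) {
  if (fit$link != "logit") stop("training AUC requires a binary trait", call. = FALSE)
  .rank_auc(fit$eta, y)
}
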