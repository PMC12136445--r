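#' Convert a two-sided p-value and effect sign to a signed z-value
#'
#' The standard signed transform feeding the empirical-null fit:
#' `z = qnorm(1 - p/2)` for positive effects, `z = qnorm(p/2)` for negative
#' effects, and `z = 0` when the sign is zero. Under the null the z-values
#' are standard normal, which is the reference the empirical-null maximum
#' likelihood fit requires.
#'
#' @param p two-sided p-values in (0, 1\]; exact zeros are clamped to the
#'   smallest positive double with a warning.
#' @param sign effect signs in \{-1, 0, +1\} (recycled if scalar).
#' @return numeric z-values.
#' @export
p_to_signed_z <- function(p, sign) {
  if (length(sign) == 1L) sign <- rep(sign, length(p))
  stopifnot(length(sign) == length(p))
  if (any(p == 0, na.rm = TRUE)) {
    warning("p-values of exactly 0 clamped to the smallest positive double",
            call. = FALSE)
    p[p == 0] <- .Machine$double.xmin
  }
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in (0, 1]", call. = FALSE)
  z <- stats::qnorm(p / 2, lower.tail = FALSE)
  out <- ifelse(sign > 0, z, ifelse(sign < 0, -z, 0))
  out[p == 1] <- 0
  out
}

#' Fit an empirical-null local false discovery rate model
#'
#' Models the marginal density of z-values with a Poisson regression of
#' histogram counts on a natural-spline basis (120 equal-width bins, 7
#' degrees of freedom — the canonical locfdr defaults), and fits an empirical
#' null `N(mean, sd)` by truncated-normal maximum likelihood restricted to
#' z-values between the `lo_pct` and `hi_pct` percentiles, where true signal
#' is assumed absent. The null proportion `pi0` is the fraction of z-values
#' in the central window divided by the null mass of that window, capped at
#' 1. The local false discovery rate is the posterior null probability
#' `fdr(z) = pi0 * dnorm(z; mean, sd) / f(z)`, clipped to \[0, 1\].
#'
#' @param z vector of at least 200 z-values (pooled across species).
#' @param lo_pct,hi_pct percentile bounds of the central null-fitting window.
#' @param n_bins number of histogram bins.
#' @param df spline degrees of freedom for the marginal density.
#' @return An object of class `local_fdr_fit` with elements `null_mean`,
#'   `null_sd`, `pi0`, `central_range`, `breaks`, `mids`, `counts`,
#'   `f_hat` (marginal density at bin centers) and the fitted spline
#'   coefficients. Use [local_fdr()] to evaluate it.
#' @export
fit_local_fdr <- function(z, lo_pct = 10, hi_pct = 90, n_bins = 120, df = 7) {
  z <- z[is.finite(z)]
  if (length(z) < 200) {
    stop("need at least 200 z-values for a stable empirical-null fit", call. = FALSE)
  }
  if (stats::sd(z) == 0) stop("degenerate z-values (all equal)", call. = FALSE)
  N <- length(z)
  rng <- range(z)
  pad <- 1e-8 * max(1, diff(rng))
  breaks <- seq(rng[1] - pad, rng[2] + pad, length.out = n_bins + 1)
  width <- diff(breaks)[1]
  h <- graphics::hist(z, breaks = breaks, plot = FALSE)
  mids <- h$mids
  counts <- h$counts
  basis <- splines::ns(mids, df = df)
  pois <- stats::glm.fit(cbind(1, basis), counts, family = stats::poisson())
  coefs <- pois$coefficients
  f_hat <- exp(drop(cbind(1, basis) %*% coefs)) / (N * width)

  qs <- stats::quantile(z, c(lo_pct, hi_pct) / 100, names = FALSE)
  z0 <- z[z >= qs[1] & z <= qs[2]]
  nll <- function(par) {
    d <- par[1]
    s <- exp(par[2])
    mass <- stats::pnorm(qs[2], d, s) - stats::pnorm(qs[1], d, s)
    if (!(mass > 0)) return(1e10)
    -sum(stats::dnorm(z0, d, s, log = TRUE)) + length(z0) * log(mass)
  }
  opt <- stats::optim(c(stats::median(z0), log(stats::sd(z0))), nll,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  null_mean <- opt$par[1]
  null_sd <- exp(opt$par[2])
  mass0 <- stats::pnorm(qs[2], null_mean, null_sd) -
    stats::pnorm(qs[1], null_mean, null_sd)
  pi0 <- min(1, (length(z0) / N) / mass0)

  structure(list(null_mean = null_mean, null_sd = null_sd, pi0 = pi0,
                 central_range = qs, breaks = breaks, mids = mids,
                 counts = counts, f_hat = f_hat, basis = basis,
                 coefs = coefs, n = N, bin_width = width),
            class = "local_fdr_fit")
}

#' Evaluate local false discovery rates
#'
#' @param model a `local_fdr_fit`.
#' @param z z-values at which to evaluate the localFDR.
#' @return localFDR values in \[0, 1\].
#' @export
local_fdr <- function(model, z) {
  bz <- stats::predict(model$basis, .clip(z, model$mids[1],
                                          model$mids[length(model$mids)]))
  f <- exp(drop(cbind(1, bz) %*% model$coefs)) / (model$n * model$bin_width)
  f0 <- stats::dnorm(z, model$null_mean, model$null_sd)
  .clip(model$pi0 * f0 / pmax(f, 1e-300), 0, 1)
}

#' @export
print.local_fdr_fit <- function(x, ...) {
  cat(sprintf("local_fdr_fit: null N(%.3f, %.3f^2), pi0 = %.3f, %d z-values\n",
              x$null_mean, x$null_sd, x$pi0, x$n))
  invisible(x)
}

#' Flag significant associations at a localFDR threshold
#'
#' Appends `local_fdr` and `significant` columns to a table of gene (or
#' species) associations, using a strict `<` comparison at the threshold.
#' Conventional thresholds: 0.2 for per-gene tests, 0.1 for the
#' population-structure and abundance tests.
#'
#' @param assocs data.frame with a `z_signed` column (e.g. from
#'   [run_beta_tests()]).
#' @param model a `local_fdr_fit`.
#' @param threshold localFDR significance cutoff.
#' @return `assocs` with `local_fdr` and `significant` columns.
#' @export
call_significant <- function(assocs, model, threshold = 0.2) {
  if (nrow(assocs) == 0L) {
    assocs$local_fdr <- numeric(0)
    assocs$significant <- logical(0)
    return(assocs)
  }
  assocs$local_fdr <- local_fdr(model, assocs$z_signed)
  assocs$significant <- assocs$local_fdr < threshold
  assocs
}

#' Serialize an empirical-null fit to JSON
#'
#' @param model a `local_fdr_fit`.
#' @param path output JSON path.
#' @export
write_fdr_model <- function(model, path) {
  jsonlite::write_json(
    list(null_mean = model$null_mean, null_sd = model$null_sd,
         pi0 = model$pi0, central_range = as.numeric(model$central_range),
         n = model$n, bin_width = model$bin_width),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
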