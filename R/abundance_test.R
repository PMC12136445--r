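#' Construct a relative-abundance table
#'
#' @param values n-by-s matrix of nonnegative per-sample relative abundances
#'   (each row sums to at most 1).
#' @param sample_ids,species_ids identifiers; default to dimnames.
#' @return An `abundance_table` (numeric matrix with dimnames).
#' @export
abundance_table <- function(values, sample_ids = rownames(values),
                            species_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "numeric"
  if (any(values < 0, na.rm = TRUE)) {
    stop("relative abundances must be nonnegative", call. = FALSE)
  }
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(nrow(values)))
  if (is.null(species_ids)) species_ids <- paste0("species_", seq_len(ncol(values)))
  dimnames(values) <- list(as.character(sample_ids), as.character(species_ids))
  structure(values, class = c("abundance_table", "matrix", "array"))
}

#' Read a sample-by-species relative abundance TSV
#'
#' @param path TSV with a sample-identifier first column and one column per
#'   species.
#' @return An `abundance_table`.
#' @export
read_abundance <- function(path) {
  dt <- .fread_tsv(path, colClasses = list(character = 1))
  m <- as.matrix(dt[, -1, drop = FALSE])
  rownames(m) <- dt[[1]]
  abundance_table(m)
}

#' Species-level trait association from relative abundance
#'
#' The standard species-level baseline: for each species whose mean relative
#' abundance clears `min_rel_abund` (default 0.05%), regress the trait on the
#' species' relative abundance plus the trait table's covariates (logistic
#' regression for binary traits, linear otherwise) and report the abundance
#' coefficient, its Wald p-value, and the signed z-value for localFDR
#' adjustment. Abundance is used untransformed by default; set
#' `log_transform = TRUE` for `log10(x + pseudocount)`.
#'
#' @param A an `abundance_table`.
#' @param traits a [trait_table] (samples are matched by id; the intersection
#'   is used).
#' @param min_rel_abund abundance floor; species below it are removed.
#' @param log_transform transform abundance before regression.
#' @param pseudocount added inside the log when `log_transform = TRUE`.
#' @return data.frame with one row per retained species: `species_id`, `n`,
#'   `beta_hat`, `se`, `z`, `p_value`, `separation`, `untestable`,
#'   `z_signed`.
#' @export
run_abundance_tests <- function(A, traits, min_rel_abund = 5e-4,
                                log_transform = FALSE, pseudocount = 1e-6) {
  shared <- intersect(rownames(A), traits$sample_ids)
  if (length(shared) == 0L) stop("no shared samples", call. = FALSE)
  idx <- match(shared, traits$sample_ids)
  tt <- structure(list(sample_ids = shared, y = traits$y[idx],
                       trait_kind = traits$trait_kind,
                       X = traits$X[idx, , drop = FALSE],
                       covariate_names = traits$covariate_names),
                  class = "trait_table")
  Am <- unclass(A)[shared, , drop = FALSE]
  keep <- colMeans(Am) >= min_rel_abund
  if (!any(keep)) stop("all species below the abundance floor", call. = FALSE)
  Am <- Am[, keep, drop = FALSE]
  vals <- if (log_transform) log10(Am + pseudocount) else Am
  rows <- lapply(colnames(Am), function(sp) {
    x <- vals[, sp]
    if (length(unique(x)) < 2L) {
      return(data.frame(species_id = sp, n = length(x), beta_hat = NA_real_,
                        se = NA_real_, z = NA_real_, p_value = 1,
                        separation = FALSE, untestable = TRUE))
    }
    r <- run_glm_baseline(tt, matrix(x, ncol = 1, dimnames = list(NULL, sp)))
    data.frame(species_id = sp, n = length(x), beta_hat = r$beta_hat,
               se = r$se, z = r$z, p_value = r$p_value,
               separation = r$separation, untestable = r$untestable)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$z_signed <- p_to_signed_z(pmax(out$p_value, .Machine$double.xmin),
                                sign(ifelse(is.na(out$beta_hat), 0, out$beta_hat)))
  out
}
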