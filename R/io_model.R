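#' Construct a pangenome presence/absence matrix
#'
#' A `pangenome_matrix` holds a binary sample-by-gene matrix for one microbiome
#' species: rows are metagenomic samples, columns are gene families, and each
#' entry records whether the gene family was called present (1) or absent (0)
#' in that sample, typically by an upstream pangenome profiler.
#'
#' @param values numeric matrix of 0/1 entries, samples in rows.
#' @param sample_ids character vector of unique sample identifiers; defaults to
#'   the matrix rownames.
#' @param gene_ids character vector of unique gene family identifiers; defaults
#'   to the matrix colnames.
#' @return An object of class `pangenome_matrix`: the validated integer matrix
#'   with sample ids as rownames and gene ids as colnames.
#' @export
pangenome_matrix <- function(values, sample_ids = rownames(values),
                             gene_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(nrow(values)))
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(ncol(values)))
  sample_ids <- as.character(sample_ids)
  gene_ids <- as.character(gene_ids)
  if (nrow(values) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (ncol(values) < 1L) stop("need at least 1 gene", call. = FALSE)
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!(values %in% c(0, 1)) | is.na(values))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(values)) + 1
    j <- ((bad[1] - 1) %/% nrow(values)) + 1
    stop(sprintf(
      "non-binary entry '%s' at sample '%s', gene '%s' (entries must be 0 or 1)",
      as.character(values[i, j]), sample_ids[i], gene_ids[j]), call. = FALSE)
  }
  storage.mode(values) <- "integer"
  dimnames(values) <- list(sample_ids, gene_ids)
  structure(values, class = c("pangenome_matrix", "matrix", "array"))
}

#' @export
print.pangenome_matrix <- function(x, ...) {
  cat(sprintf("pangenome_matrix: %d samples x %d gene families (mean presence %.3f)\n",
              nrow(x), ncol(x), mean(x)))
  invisible(x)
}

#' Read a pangenome presence/absence matrix from TSV
#'
#' The file must be tab-separated with a header row; the first column holds
#' identifiers. Gzip-compressed files are read transparently. Profiler merge
#' outputs commonly put gene families in rows; pass
#' `orientation = "genes_in_rows"` to transpose on read. Entries must be
#' exactly 0 or 1 — missing or non-binary values raise an error naming the
#' offending row and column rather than being silently imputed.
#'
#' @param path TSV (optionally .gz) file path.
#' @param orientation `"samples_in_rows"` (default) or `"genes_in_rows"`.
#' @return A [pangenome_matrix] with samples in rows.
#' @export
read_pangenome <- function(path,
                           orientation = c("samples_in_rows", "genes_in_rows")) {
  orientation <- match.arg(orientation)
  dt <- .fread_tsv(path, colClasses = list(character = 1))
  ids <- dt[[1]]
  m <- as.matrix(dt[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    raw <- m
    suppressWarnings(storage.mode(m) <- "numeric")
    bad <- which(is.na(m) & !is.na(raw))
    if (length(bad)) {
      i <- ((bad[1] - 1) %% nrow(m)) + 1
      j <- ((bad[1] - 1) %/% nrow(m)) + 1
      stop(sprintf("non-numeric entry '%s' at row %d, column '%s' of %s",
                   raw[bad[1]], i, colnames(m)[j], path), call. = FALSE)
    }
  }
  if (orientation == "genes_in_rows") {
    m <- t(m)
    pangenome_matrix(m, sample_ids = rownames(m), gene_ids = ids)
  } else {
    pangenome_matrix(m, sample_ids = ids, gene_ids = colnames(m))
  }
}

#' Write a pangenome matrix to TSV
#'
#' Round-trips bitwise with [read_pangenome()]. The first column is named
#' `sample_name` and holds sample identifiers.
#'
#' @param G a [pangenome_matrix].
#' @param path output path (`.gz` suffix compresses).
#' @export
write_pangenome <- function(G, path) {
  dt <- data.table::data.table(sample_name = rownames(G))
  dt <- cbind(dt, data.table::as.data.table(unclass(G)))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Construct a trait table
#'
#' Bundles the per-sample trait with a fixed-effect design matrix. An
#' intercept column is always included; covariates (e.g. host age, marker
#' depth) are appended. Binary traits must be coded 0/1; any other numeric
#' trait is treated as quantitative.
#'
#' @param sample_ids character vector of unique sample identifiers.
#' @param y numeric trait vector (binary 0/1 or quantitative).
#' @param covariates optional data.frame or matrix of numeric covariates
#'   (no intercept; one row per sample).
#' @param trait_kind `"auto"` (default), `"binary"` or `"quantitative"`.
#' @return An object of class `trait_table` with elements `sample_ids`, `y`,
#'   `trait_kind`, `X` (design matrix with intercept) and `covariate_names`.
#' @export
trait_table <- function(sample_ids, y, covariates = NULL,
                        trait_kind = c("auto", "binary", "quantitative")) {
  trait_kind <- match.arg(trait_kind)
  sample_ids <- as.character(sample_ids)
  n <- length(sample_ids)
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids", call. = FALSE)
  if (length(y) != n) stop("y and sample_ids lengths differ", call. = FALSE)
  y <- as.numeric(y)
  if (trait_kind == "auto") {
    trait_kind <- if (.is_binary(y[!is.na(y)])) "binary" else "quantitative"
  }
  if (trait_kind == "binary" && !.is_binary(y[!is.na(y)])) {
    stop("binary trait must contain only 0/1 values", call. = FALSE)
  }
  X <- matrix(1, n, 1, dimnames = list(sample_ids, "(Intercept)"))
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)
    if (nrow(cv) != n) stop("covariates must have one row per sample", call. = FALSE)
    if (is.null(colnames(cv))) colnames(cv) <- paste0("covar_", seq_len(ncol(cv)))
    storage.mode(cv) <- "numeric"
    X <- cbind(X, cv)
  }
  # drop samples with missing trait or covariates (documented choice: no imputation)
  keep <- stats::complete.cases(cbind(y, X))
  if (!all(keep)) {
    warning(sprintf("dropping %d sample(s) with missing trait/covariate values: %s",
                    sum(!keep), paste(sample_ids[!keep], collapse = ", ")),
            call. = FALSE)
    sample_ids <- sample_ids[keep]
    y <- y[keep]
    X <- X[keep, , drop = FALSE]
  }
  if (qr(X)$rank < ncol(X)) {
    stop("covariate design matrix is rank deficient", call. = FALSE)
  }
  structure(list(sample_ids = sample_ids, y = y, trait_kind = trait_kind,
                 X = X, covariate_names = colnames(X)),
            class = "trait_table")
}

#' @export
print.trait_table <- function(x, ...) {
  cat(sprintf("trait_table: %d samples, %s trait, covariates: %s\n",
              length(x$sample_ids), x$trait_kind,
              paste(x$covariate_names, collapse = ", ")))
  invisible(x)
}

#' Read a sample metadata table and build a trait table
#'
#' The metadata TSV must have a sample-identifier first column (conventionally
#' `sample_name`), a trait column, and optional covariate columns.
#'
#' @param path metadata TSV path.
#' @param trait name of the trait column.
#' @param covariates character vector of covariate column names (may be NULL).
#' @inheritParams trait_table
#' @return A [trait_table].
#' @export
read_trait_table <- function(path, trait, covariates = NULL,
                             trait_kind = c("auto", "binary", "quantitative")) {
  trait_kind <- match.arg(trait_kind)
  dt <- .fread_tsv(path, colClasses = list(character = 1))
  if (!trait %in% names(dt)) {
    stop(sprintf("trait column '%s' not found in %s", trait, path), call. = FALSE)
  }
  missing_cov <- setdiff(covariates, names(dt))
  if (length(missing_cov)) {
    stop("covariate column(s) not found: ", paste(missing_cov, collapse = ", "),
         call. = FALSE)
  }
  cv <- if (length(covariates)) dt[, covariates, drop = FALSE] else NULL
  trait_table(dt[[1]], dt[[trait]], covariates = cv, trait_kind = trait_kind)
}

#' Align a pangenome matrix and trait table on shared samples
#'
#' Restricts both inputs to the intersection of their sample identifiers, in
#' the order they appear in the pangenome matrix, and warns about dropped
#' samples. The operation is idempotent.
#'
#' @param G a [pangenome_matrix].
#' @param traits a [trait_table].
#' @return list with elements `G` and `traits`, sample-aligned.
#' @export
align_samples <- function(G, traits) {
  shared <- intersect(rownames(G), traits$sample_ids)
  if (length(shared) == 0L) {
    stop("no samples shared between pangenome matrix and trait table", call. = FALSE)
  }
  dropped <- c(setdiff(rownames(G), shared), setdiff(traits$sample_ids, shared))
  if (length(dropped)) {
    warning("dropping unmatched sample(s): ", paste(dropped, collapse = ", "),
            call. = FALSE)
  }
  Gs <- pangenome_matrix(unclass(G)[shared, , drop = FALSE])
  idx <- match(shared, traits$sample_ids)
  ts <- structure(list(sample_ids = shared,
                       y = traits$y[idx],
                       trait_kind = traits$trait_kind,
                       X = traits$X[idx, , drop = FALSE],
                       covariate_names = traits$covariate_names),
                  class = "trait_table")
  list(G = Gs, traits = ts)
}

#' Drop near-core and near-rare gene families
#'
#' Gene families with too little presence/absence variation carry no
#' association signal and are removed before modeling: core genes absent in
#' fewer than `min_absent` samples, and rare genes present in fewer than
#' `min_present` samples. The defaults (10/30) follow common pangenome MWAS
#' practice. The counts removed in each category are attached as the
#' `"removed"` attribute.
#'
#' @param G a [pangenome_matrix].
#' @param min_absent minimum number of samples a gene must be absent from.
#' @param min_present minimum number of samples a gene must be present in.
#' @return Filtered [pangenome_matrix] with attribute `removed`
#'   (named vector: `core`, `rare`).
#' @export
filter_variable_genes <- function(G, min_absent = 10, min_present = 30) {
  stopifnot(min_absent >= 0, min_present >= 0)
  present <- colSums(G)
  absent <- nrow(G) - present
  is_core <- absent < min_absent
  is_rare <- present < min_present
  keep <- !is_core & !is_rare
  if (!any(keep)) {
    stop("all gene families removed by the variability filter; ",
         "lower min_absent/min_present", call. = FALSE)
  }
  out <- pangenome_matrix(unclass(G)[, keep, drop = FALSE])
  # a gene can fail both cuts; report disjoint categories (core first)
  attr(out, "removed") <- c(core = sum(is_core), rare = sum(is_rare & !is_core))
  out
}
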