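#' Compute the species-level genetic relatedness matrix
#'
#' Relatedness between two samples is one minus the Manhattan distance of
#' their binary gene presence/absence profiles, normalized by the number of
#' gene families so that values lie in \[0, 1\]: identical gene repertoires
#' score 1, fully complementary repertoires score 0. The result is symmetric
#' with a unit diagonal.
#'
#' @param G a [pangenome_matrix].
#' @return An n-by-n `relatedness_matrix` (symmetric numeric matrix with
#'   sample ids as dimnames).
#' @export
compute_grm <- function(G) {
  if (ncol(G) < 1L) stop("pangenome matrix has no genes", call. = FALSE)
  m <- unclass(G)
  storage.mode(m) <- "numeric"
  D <- as.matrix(stats::dist(m, method = "manhattan")) / ncol(m)
  Psi <- 1 - D
  dimnames(Psi) <- list(rownames(G), rownames(G))
  structure(Psi, class = c("relatedness_matrix", "matrix", "array"))
}

#' @export
print.relatedness_matrix <- function(x, ...) {
  off <- x[upper.tri(x)]
  cat(sprintf("relatedness_matrix: %d samples, off-diagonal range [%.3f, %.3f]\n",
              nrow(x), min(off), max(off)))
  invisible(x)
}

#' Ridge-adjust a relatedness matrix to positive semidefiniteness
#'
#' One-minus-Manhattan relatedness is not guaranteed positive semidefinite;
#' the mixed model requires a valid covariance. Adds the minimal diagonal
#' ridge `delta = max(0, -lambda_min) + 1e-6` and records it.
#'
#' @param Psi a `relatedness_matrix` (or symmetric matrix).
#' @return The adjusted matrix with attribute `ridge` holding delta.
#' @export
grm_ridge <- function(Psi) {
  if (!is.null(attr(Psi, "ridge"))) return(Psi)
  # cheap path: if Psi + 1e-6 I is already positive definite, that is the
  # minimal ridge; otherwise compute lambda_min
  delta <- 1e-6
  ok <- tryCatch({chol(unclass(Psi) + diag(delta, nrow(Psi))); TRUE},
                 error = function(e) FALSE)
  if (!ok) {
    ev <- eigen(Psi, symmetric = TRUE, only.values = TRUE)$values
    delta <- max(0, -min(ev)) + 1e-6
  }
  out <- unclass(Psi) + diag(delta, nrow(Psi))
  dimnames(out) <- dimnames(Psi)
  attr(out, "ridge") <- delta
  class(out) <- class(Psi)
  out
}

#' Principal components of a relatedness matrix
#'
#' Double-centers the relatedness matrix (principal-coordinates convention)
#' and returns the leading eigenvectors scaled by the square root of their
#' eigenvalues, columns ordered by decreasing eigenvalue. Signs are fixed
#' deterministically: the largest-magnitude loading of each component is
#' positive.
#'
#' @param Psi a `relatedness_matrix`.
#' @param k number of components (k <= n).
#' @return n-by-k matrix of sample coordinates; attribute `values` holds the
#'   eigenvalues.
#' @export
grm_pcs <- function(Psi, k) {
  n <- nrow(Psi)
  if (k > n) stop("k must not exceed the number of samples", call. = FALSE)
  if (!all(is.finite(Psi))) stop("relatedness matrix has non-finite entries", call. = FALSE)
  C <- diag(n) - matrix(1 / n, n, n)
  B <- C %*% Psi %*% C
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  vec <- e$vectors[, seq_len(k), drop = FALSE]
  val <- e$values[seq_len(k)]
  for (j in seq_len(k)) {
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  pcs <- vec %*% diag(sqrt(pmax(val, 0)), k)
  rownames(pcs) <- rownames(Psi)
  colnames(pcs) <- paste0("PC", seq_len(k))
  attr(pcs, "values") <- val
  pcs
}

#' Write a relatedness matrix as square TSV
#'
#' Sample ids appear both as the header row and the first column.
#'
#' @param Psi a `relatedness_matrix`.
#' @param path output path.
#' @export
write_grm <- function(Psi, path) {
  dt <- data.table::data.table(sample_name = rownames(Psi))
  dt <- cbind(dt, data.table::as.data.table(unclass(Psi)))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read a relatedness matrix from square TSV
#'
#' @param path TSV written by [write_grm()].
#' @return A `relatedness_matrix`.
#' @export
read_grm <- function(path) {
  dt <- .fread_tsv(path, colClasses = list(character = 1))
  m <- as.matrix(dt[, -1, drop = FALSE])
  rownames(m) <- dt[[1]]
  if (!identical(rownames(m), colnames(m))) {
    stop("GRM row and column sample ids differ", call. = FALSE)
  }
  structure(m, class = c("relatedness_matrix", "matrix", "array"))
}
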