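# Internal numerical helpers shared across modules.

# Solve V x = B given the upper-triangular Cholesky factor R (V = R'R).
.chol_solve <- function(R, B) {
  backsolve(R, backsolve(R, B, transpose = TRUE))
}

# Solve A x = b for symmetric positive-definite A via its Cholesky factor.
.spd_solve <- function(Rchol, b) {
  backsolve(Rchol, backsolve(Rchol, b, transpose = TRUE))
}

# Solve A x = b, falling back to an SVD pseudo-inverse when A is singular
# (e.g. the AI matrix under tau/sigma^2 aliasing).
.safe_solve <- function(A, b, tol = 1e-10) {
  out <- tryCatch(solve(A, b), error = function(e) NULL)
  if (!is.null(out) && all(is.finite(out))) {
    return(list(x = out, singular = FALSE))
  }
  sv <- svd(A)
  keep <- sv$d > tol * max(sv$d)
  x <- sv$v[, keep, drop = FALSE] %*%
    ((crossprod(sv$u[, keep, drop = FALSE], b)) / sv$d[keep])
  list(x = drop(x), singular = TRUE)
}

.clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Midrank (Mann-Whitney) AUC of a score vector against binary labels.
.rank_auc <- function(score, y) {
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC is undefined when all samples belong to one class", call. = FALSE)
  }
  r <- rank(score)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.is_binary <- function(x) all(x %in% c(0, 1))

# fread with transparent gzip support that does not require extra packages:
# .gz files are decompressed through a base connection first.
.fread_tsv <- function(path, ...) {
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "rt")
    on.exit(close(con))
    data.table::fread(text = readLines(con), sep = "\t", header = TRUE,
                      data.table = FALSE, ...)
  } else {
    data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE, ...)
  }
}
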