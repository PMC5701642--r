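# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG state
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators never leak into (or depend on) global state.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Row-wise Euclidean norms
#' @noRd
row_norms <- function(m) sqrt(rowSums(m^2))

#' Normalize a vector to unit length
#' @noRd
unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("cannot normalize a zero vector", call. = FALSE)
  v / n
}

#' Deterministic sign convention for direction vectors
#'
#' Flips `v` so that its largest-magnitude component is positive. Makes
#' eigenvector-derived orientations reproducible across LAPACK builds.
#' @noRd
canonical_sign <- function(v) {
  i <- which.max(abs(v))
  if (v[i] < 0) -v else v
}

#' Quasi-uniform directions on the unit sphere (Fibonacci lattice)
#'
#' @param n number of directions
#' @param zmin,zmax band of z values covered (full sphere by default); a cap
#'   or band is produced by restricting the z range.
#' @param phase golden-angle phase offset, used to decorrelate lattices.
#' @noRd
fibonacci_directions <- function(n, zmin = -1, zmax = 1, phase = 0) {
  stopifnot(n >= 1, zmin < zmax)
  i <- seq_len(n) - 0.5
  z <- zmax - (zmax - zmin) * i / n
  golden <- pi * (3 - sqrt(5))
  phi <- golden * (seq_len(n) - 1) + phase
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Random 3D rotation matrix (uniform over SO(3))
#' @noRd
random_rotation <- function() {
  # QR of a Gaussian matrix with determinant fixed to +1
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Symmetric generalized eigendecomposition A v = lambda B v
#'
#' B must be symmetric positive definite; A symmetric. Returns eigenvalues in
#' decreasing order with B-orthonormal eigenvectors.
#' @noRd
sym_geigen <- function(A, B) {
  A <- (A + t(A)) / 2
  B <- (B + t(B)) / 2
  R <- tryCatch(chol(B), error = function(e) NULL)
  if (is.null(R)) {
    # fall back to an eigendecomposition-based inverse square root
    eb <- eigen(B, symmetric = TRUE)
    tol <- max(eb$values) * 1e-12
    if (max(eb$values) <= 0) stop("degenerate pencil: B is not positive semidefinite", call. = FALSE)
    keep <- eb$values > tol
    Bi2 <- eb$vectors[, keep, drop = FALSE] %*%
      diag(1 / sqrt(eb$values[keep]), sum(keep))
    M <- t(Bi2) %*% A %*% Bi2
    e <- eigen((M + t(M)) / 2, symmetric = TRUE)
    return(list(values = e$values, vectors = Bi2 %*% e$vectors))
  }
  Ri <- backsolve(R, diag(nrow(B)))
  M <- t(Ri) %*% A %*% Ri
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  list(values = e$values, vectors = Ri %*% e$vectors)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
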