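# Scalar LCMV beamformer core: sample covariance, the three constrained
# filters, data-driven orientation, and variance / excess-kurtosis outputs.
#
# For a forward solution L (N x 1, the gain along the source orientation) and
# sample covariance C, the constrained minimum-variance weights are
#
#   unit gain        W'L = 1        W = C^-1 L / (L' C^-1 L)
#   unit array gain  W'L = ||L||    W = ||L|| C^-1 L / (L' C^-1 L)
#   unit noise gain  W'W = 1, W'L>0 W = C^-1 L / sqrt(L' C^-2 L)
#
# so the array-gain and noise-gain filters are scaled versions of the
# unit-gain filter for the same L. The source orientation is chosen to
# maximize the constraint's output variance, which reduces to a 3x3
# (generalized) eigenvalue problem in the dipole moment direction.

.constraints <- c("unit_gain", "unit_array_gain", "unit_noise_gain")

#' Sample covariance of a measurement
#'
#' The 1/T outer-product average `C = (1/T) sum_t B(t) B(t)'` (not the
#' 1/(T-1) estimator). The measurement should be channel-demeaned first.
#'
#' @param B a `measurement` or a numeric channels-by-samples matrix.
#' @param loading optional diagonal-loading factor `lambda`: the regularized
#'   covariance `C + lambda * trace(C)/N * I` is used for inversions. Default
#'   0 (off); sensor noise in the simulations plays the regularizing role.
#' @return An object of class `bf_covariance`.
#' @export
sample_covariance <- function(B, loading = 0) {
  data <- if (inherits(B, "measurement")) B$data else as.matrix(B)
  T_ <- ncol(data)
  if (T_ < 2) stop("at least two time samples are required", call. = FALSE)
  C <- tcrossprod(data) / T_
  C <- (C + t(C)) / 2
  structure(
    list(matrix = C, n_samples = T_, loading = loading,
         cache = new.env(parent = emptyenv())),
    class = "bf_covariance"
  )
}

#' @export
print.bf_covariance <- function(x, ...) {
  cat("<bf_covariance>", nrow(x$matrix), "x", ncol(x$matrix), "from",
      x$n_samples, "samples; loading =", x$loading, "\n")
  invisible(x)
}

# Inverse and squared inverse of the (possibly loaded) covariance, cached.
# Common-average-referenced EEG data have exactly one structural null
# direction (the channel mean), which is deflated; any deeper rank deficiency
# is an error unless diagonal loading is enabled.
cov_inverses <- function(C) {
  stopifnot(inherits(C, "bf_covariance"))
  if (!is.null(C$cache$Ci)) return(C$cache)
  M <- C$matrix
  N <- nrow(M)
  if (C$loading > 0) M <- M + diag(C$loading * sum(diag(M)) / N, N)
  e <- eigen(M, symmetric = TRUE)
  keep <- e$values > max(e$values) * 1e-12
  if (sum(!keep) > 1) {
    stop("covariance matrix is numerically singular (rank ", sum(keep), " of ", N,
         "); enable diagonal loading (`loading > 0`) or add sensor noise",
         call. = FALSE)
  }
  V <- e$vectors[, keep, drop = FALSE]
  C$cache$Ci <- V %*% (t(V) / e$values[keep])
  C$cache$Ci2 <- V %*% (t(V) / e$values[keep]^2)
  C$cache
}

#' Frobenius-normalize a three-column gain matrix
#'
#' Divides the N x 3 gain by its Frobenius norm. Used by the unit-gain filter
#' variant to counter its noise-induced depth bias; it does not change the
#' orientation computation.
#'
#' @param gain numeric matrix `[N x 3]`, not all zero.
#' @return The normalized gain (unit Frobenius norm).
#' @export
frobenius_normalize <- function(gain) {
  gain <- as.matrix(gain)
  f <- sqrt(sum(gain^2))
  if (f == 0) stop("degenerate input: all-zero gain", call. = FALSE)
  gain / f
}

#' Variance-optimal dipole orientation for a constrained beamformer
#'
#' Returns the unit moment direction maximizing the constraint's output
#' variance, obtained from a 3x3 (generalized) eigenvalue problem:
#' unit gain minimizes `u' K u` with `K = gain' C^-1 gain`; unit array gain
#' takes the leading generalized eigenvector of the pencil
#' `(gain' gain, K)`; unit noise gain that of `(K, gain' C^-2 gain)`.
#' Rank-deficient gains (e.g. the magnetically silent radial direction of a
#' spherical MEG model) are handled by restricting the problem to the gain's
#' numerical row space. When the pencil is degenerate (all directions
#' equivalent, e.g. unit noise gain with identity covariance) the leading
#' right singular vector of the gain is returned as the documented tie-break.
#'
#' @param gain numeric matrix `[N x 3]`.
#' @param C a `bf_covariance`.
#' @param constraint one of `"unit_gain"`, `"unit_array_gain"`,
#'   `"unit_noise_gain"`.
#' @return A unit 3-vector with a deterministic sign convention.
#' @export
optimal_orientation <- function(gain, C, constraint = .constraints) {
  constraint <- match.arg(constraint)
  gain <- as.matrix(gain)
  inv <- cov_inverses(C)
  sv <- svd(gain)
  if (sv$d[1] == 0) stop("degenerate orientation: all-zero gain", call. = FALSE)
  keep <- sv$d > sv$d[1] * 1e-10
  Vr <- sv$v[, keep, drop = FALSE] # numerical row-space basis
  Gr <- gain %*% Vr
  K <- crossprod(Gr, inv$Ci %*% Gr)
  K <- (K + t(K)) / 2
  u_r <- switch(constraint,
    unit_gain = {
      e <- eigen(K, symmetric = TRUE)
      e$vectors[, ncol(K)] # smallest eigenvalue
    },
    unit_array_gain = {
      G <- crossprod(Gr)
      ge <- sym_geigen(G, K)
      pencil_vector(ge)
    },
    unit_noise_gain = {
      K2 <- crossprod(Gr, inv$Ci2 %*% Gr)
      ge <- sym_geigen(K, (K2 + t(K2)) / 2)
      pencil_vector(ge)
    }
  )
  if (is.null(u_r)) return(canonical_sign(sv$v[, 1])) # degenerate pencil tie-break
  canonical_sign(unit(as.numeric(Vr %*% u_r)))
}

# Leading generalized eigenvector, or NULL when the pencil is degenerate
# (all generalized eigenvalues numerically equal).
pencil_vector <- function(ge) {
  vals <- ge$values
  if ((vals[1] - vals[length(vals)]) <= abs(vals[1]) * 1e-9) return(NULL)
  ge$vectors[, 1]
}

#' LCMV weights for a fixed oriented forward solution
#'
#' Low-level closed forms for the three constraints, for a given N x 1
#' leadfield `L`. The emitted weights satisfy the constraint identities
#' `W'L = 1` (unit gain), `W'L = ||L||` (unit array gain) and `W'W = 1` with
#' `W'L > 0` (unit noise gain).
#'
#' @param L numeric vector: oriented leadfield.
#' @param C a `bf_covariance`.
#' @param constraint constraint name.
#' @return numeric weight vector of length N.
#' @export
lcmv_weights <- function(L, C, constraint = .constraints) {
  constraint <- match.arg(constraint)
  L <- as.numeric(L)
  inv <- cov_inverses(C)
  CiL <- as.numeric(inv$Ci %*% L)
  denom <- sum(L * CiL)
  if (denom <= 0 || !is.finite(denom)) {
    stop("degenerate filter: L' C^-1 L is not positive", call. = FALSE)
  }
  switch(constraint,
    unit_gain = CiL / denom,
    unit_array_gain = sqrt(sum(L^2)) * CiL / denom,
    unit_noise_gain = {
      d2 <- sum(L * as.numeric(inv$Ci2 %*% L))
      CiL / sqrt(d2)
    }
  )
}

#' Construct a constrained beamformer filter for one source-space node
#'
#' Determines the variance-optimal orientation for the requested constraint,
#' then builds the closed-form weights. The unit-gain variant applies
#' Frobenius normalization to the gain before weight computation (the
#' orientation is computed from the unnormalized gain; normalization does not
#' affect the orientation problem).
#'
#' @param gain numeric matrix `[N x 3]` for the node.
#' @param C a `bf_covariance`.
#' @param constraint constraint name.
#' @param node optional node index recorded in the result.
#' @return An object of class `bf_filter` with fields `weights`,
#'   `orientation`, `constraint`, `node`.
#' @export
make_filter <- function(gain, C, constraint = .constraints, node = NA_integer_) {
  constraint <- match.arg(constraint)
  gain <- as.matrix(gain)
  D <- optimal_orientation(gain, C, constraint)
  gain_used <- if (constraint == "unit_gain") frobenius_normalize(gain) else gain
  L <- as.numeric(gain_used %*% D)
  if (sqrt(sum(L^2)) == 0) stop("oriented leadfield is zero at this node", call. = FALSE)
  W <- lcmv_weights(L, C, constraint)
  structure(
    list(weights = W, orientation = D, constraint = constraint, node = node),
    class = "bf_filter"
  )
}

#' @export
print.bf_filter <- function(x, ...) {
  cat("<bf_filter>", x$constraint, "| node", x$node,
      sprintf("| orientation (%.3f, %.3f, %.3f)\n",
              x$orientation[1], x$orientation[2], x$orientation[3]))
  invisible(x)
}

#' Beamformer output variance
#'
#' `Var(W'B) = W' C W` with the sample covariance of the same measurement.
#'
#' @param W a `bf_filter` or numeric weight vector.
#' @param B a `measurement`, numeric matrix, or a precomputed
#'   `bf_covariance`.
#' @return scalar variance (>= 0).
#' @export
variance_output <- function(W, B) {
  w <- if (inherits(W, "bf_filter")) W$weights else as.numeric(W)
  C <- if (inherits(B, "bf_covariance")) B else sample_covariance(B)
  as.numeric(t(w) %*% C$matrix %*% w)
}

#' Sample excess kurtosis g2
#'
#' The biased moment-ratio estimator
#' `g2(X) = m4 / m2^2 - 3` with `m_k = (1/T) sum (X_t - mean(X))^k`.
#' Positive for heavy-tailed (spike-containing) waveforms, 0 for Gaussian
#' data, and never below -2.
#'
#' @param x numeric sample vector, length >= 4, non-constant.
#' @return scalar excess kurtosis.
#' @export
#' @examples
#' excess_kurtosis(c(1, 2, 3, 4, 5)) # -1.3
excess_kurtosis <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 4) stop("at least 4 samples are required", call. = FALSE)
  xc <- x - mean(x)
  m2 <- mean(xc^2)
  if (m2 == 0) stop("degenerate input: zero sample variance", call. = FALSE)
  mean(xc^4) / m2^2 - 3
}

#' Scan a source space with a constrained beamformer
#'
#' For every node: the variance-optimal orientation, the constrained filter,
#' the output variance `W'CW`, and (optionally) the excess kurtosis of the
#' filtered waveform `W'B`. Kurtosis is invariant to filter scale, so it is
#' evaluated on the unscaled spatially filtered time series. Nodes where the
#' filter is degenerate are recorded as skipped (outputs `NA`) with a warning,
#' never silently zeroed.
#'
#' @param source_space a `source_space` (or anything with node positions
#'   matching the leadfield stack).
#' @param leadfields a `leadfield` stack covering every node.
#' @param B a demeaned `measurement`.
#' @param constraint constraint name.
#' @param compute_kurtosis if `FALSE`, skip the filtered-waveform kurtosis
#'   (the variance map alone is much cheaper).
#' @param loading diagonal-loading factor passed to [sample_covariance()].
#' @param C optional precomputed `bf_covariance` of `B` (reused across
#'   constraints scanning the same measurement).
#' @return A `data.frame` of class `bf_scan` with one row per node:
#'   `node_id, x, y, z, constraint, variance_output, kurtosis_output,
#'   ori_x, ori_y, ori_z, skipped`.
#' @export
beamformer_scan <- function(source_space, leadfields, B,
                            constraint = .constraints,
                            compute_kurtosis = TRUE, loading = 0, C = NULL) {
  constraint <- match.arg(constraint)
  stopifnot(inherits(leadfields, "leadfield"))
  pos <- if (inherits(source_space, "source_space")) source_space$node_positions else rbind(source_space)
  n <- nrow(pos)
  if (leadfields$n_nodes != n) {
    stop("leadfield stack does not cover the source space", call. = FALSE)
  }
  if (is.null(C)) C <- sample_covariance(B, loading = loading)
  stopifnot(inherits(C, "bf_covariance"))
  inv <- cov_inverses(C)
  N <- nrow(leadfields$gain)
  CiLs <- inv$Ci %*% leadfields$gain # N x 3n
  Ci2Ls <- inv$Ci %*% CiLs
  Wt <- matrix(0, n, N) # unscaled weights (rows), for the filtered waveforms
  variance <- rep(NA_real_, n)
  ori <- matrix(NA_real_, n, 3)
  skipped <- logical(n)
  for (i in seq_len(n)) {
    cols <- (3 * i - 2):(3 * i)
    Li <- leadfields$gain[, cols, drop = FALSE]
    res <- tryCatch({
      u <- optimal_orientation_cached(Li, CiLs[, cols, drop = FALSE],
                                      Ci2Ls[, cols, drop = FALSE], constraint)
      L <- as.numeric(Li %*% u)
      CiL <- as.numeric(CiLs[, cols, drop = FALSE] %*% u)
      q_k <- sum(L * CiL) # L' C^-1 L
      if (q_k <= 0 || !is.finite(q_k)) stop("nonpositive L' C^-1 L")
      v <- switch(constraint,
        unit_gain = sum(Li^2) / q_k, # Frobenius-normalized unit gain
        unit_array_gain = sum(L^2) / q_k,
        unit_noise_gain = q_k / sum(L * as.numeric(Ci2Ls[, cols, drop = FALSE] %*% u))
      )
      list(u = u, w = CiL, v = v)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped[i] <- TRUE
      next
    }
    ori[i, ] <- res$u
    variance[i] <- res$v
    Wt[i, ] <- res$w
  }
  if (any(skipped)) {
    warning(sprintf("%d of %d nodes skipped as degenerate (e.g. node %d)",
                    sum(skipped), n, which(skipped)[1]), call. = FALSE)
  }
  kurt <- rep(NA_real_, n)
  if (compute_kurtosis) {
    data <- if (inherits(B, "measurement")) B$data else as.matrix(B)
    Y <- Wt %*% data
    Yc <- Y - rowMeans(Y)
    m2 <- rowMeans(Yc^2)
    m4 <- rowMeans(Yc^4)
    ok <- !skipped & m2 > 0
    kurt[ok] <- m4[ok] / m2[ok]^2 - 3
    skipped <- skipped | (!ok)
  }
  out <- data.frame(
    node_id = seq_len(n), x = pos[, 1], y = pos[, 2], z = pos[, 3],
    constraint = constraint, variance_output = variance,
    kurtosis_output = kurt,
    ori_x = ori[, 1], ori_y = ori[, 2], ori_z = ori[, 3],
    skipped = skipped
  )
  class(out) <- c("bf_scan", class(out))
  out
}

# Orientation from precomputed C^-1 L and C^-2 L blocks (avoids refactoring
# the covariance solve out of the per-node loop).
optimal_orientation_cached <- function(Li, CiLi, Ci2Li, constraint) {
  sv <- svd(Li)
  if (sv$d[1] == 0) stop("all-zero gain")
  keep <- sv$d > sv$d[1] * 1e-10
  Vr <- sv$v[, keep, drop = FALSE]
  K <- crossprod(Li %*% Vr, CiLi %*% Vr)
  K <- (K + t(K)) / 2
  u_r <- switch(constraint,
    unit_gain = {
      e <- eigen(K, symmetric = TRUE)
      e$vectors[, ncol(K)]
    },
    unit_array_gain = {
      G <- crossprod(Li %*% Vr)
      ge <- sym_geigen(G, K)
      pencil_vector(ge)
    },
    unit_noise_gain = {
      K2 <- crossprod(Li %*% Vr, Ci2Li %*% Vr)
      ge <- sym_geigen(K, (K2 + t(K2)) / 2)
      pencil_vector(ge)
    }
  )
  if (is.null(u_r)) return(canonical_sign(sv$v[, 1]))
  canonical_sign(unit(as.numeric(Vr %*% u_r)))
}
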