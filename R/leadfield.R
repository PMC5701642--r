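# Leadfield stacks over a set of source positions, model perturbation, and
# data-driven source orientations.

new_leadfield <- function(gain, positions, modality, units, model_label, sensors) {
  structure(
    list(
      gain = gain, # N x (3 * n_nodes), node-major column triples
      positions = positions,
      n_nodes = nrow(positions),
      modality = modality,
      units = units,
      model_label = model_label,
      sensors = sensors
    ),
    class = "leadfield"
  )
}

#' @export
print.leadfield <- function(x, ...) {
  cat("<leadfield>", x$model_label, "\n ", nrow(x$gain), toupper(x$modality),
      "channels x", x$n_nodes, "nodes x 3 axes;", x$units, "\n")
  invisible(x)
}

#' Extract one node's gain matrix from a leadfield stack
#'
#' @param lf a `leadfield`.
#' @param i node index.
#' @return numeric matrix `[n_sensors x 3]`.
#' @export
lf_gain <- function(lf, i) {
  stopifnot(inherits(lf, "leadfield"), i >= 1, i <= lf$n_nodes)
  lf$gain[, (3 * (i - 1) + 1):(3 * i), drop = FALSE]
}

#' Compute a leadfield stack over many source positions
#'
#' Evaluates the modality's analytic spherical forward solution at every
#' position. EEG gains are common-average referenced; EEG series coefficients
#' are computed once per shell model and reused across nodes.
#'
#' @param positions numeric matrix `[n x 3]` (mm) or a `source_space`.
#' @param sensors a `sensor_array`.
#' @param shells a [shell_model()] (used by EEG; MEG is conductivity-blind).
#' @param n_terms EEG series truncation order.
#' @return A `leadfield`.
#' @export
compute_leadfields <- function(positions, sensors, shells = make_shell_model("reference"),
                               n_terms = 60) {
  if (inherits(positions, "source_space")) positions <- positions$node_positions
  positions <- rbind(positions)
  stopifnot(ncol(positions) == 3, inherits(sensors, "sensor_array"))
  n <- nrow(positions)
  N <- sensors$n
  gain <- matrix(0, N, 3 * n)
  if (sensors$modality == "eeg") {
    s <- shell_response_coefficients(shells, n_terms)
    E <- sensors$positions / max(shells$radii)
    for (i in seq_len(n)) {
      k <- eeg_series_weights(shells, sqrt(sum(positions[i, ]^2)), n_terms, s = s)
      g <- eeg_gain_from_weights(E, positions[i, ], k)
      if (sensors$reference == "common_average") g <- sweep(g, 2, colMeans(g))
      gain[, (3 * i - 2):(3 * i)] <- g
    }
    units <- "V/(A*m)"
  } else {
    for (i in seq_len(n)) {
      gain[, (3 * i - 2):(3 * i)] <- meg_sphere_leadfield(sensors, positions[i, ])
    }
    units <- "T/(A*m)"
  }
  new_leadfield(gain, positions, sensors$modality, units, shells$label, sensors)
}

#' Quasi-radial and quasi-tangential source orientations from a gain matrix
#'
#' Unit eigenvectors of the 3x3 Gram matrix `t(gain) %*% gain` for the
#' smallest and largest eigenvalue. For an MEG gain in a spherical conductor
#' the smallest-eigenvalue direction is the (magnetically silent) radial
#' direction, hence "quasi-radial"; the largest is quasi-tangential. The two
#' are orthogonal.
#'
#' @param gain numeric matrix `[n_sensors x 3]`.
#' @return list with unit vectors `quasi_radial` and `quasi_tangential`.
#' @export
reference_orientations <- function(gain) {
  gain <- as.matrix(gain)
  stopifnot(ncol(gain) == 3)
  if (!all(is.finite(gain))) stop("gain contains non-finite entries", call. = FALSE)
  if (all(gain == 0)) stop("degenerate input: all-zero gain", call. = FALSE)
  e <- eigen(crossprod(gain), symmetric = TRUE)
  list(
    quasi_radial = canonical_sign(e$vectors[, 3]),
    quasi_tangential = canonical_sign(e$vectors[, 1])
  )
}

#' Perturb a leadfield by a smooth spatially correlated random field
#'
#' Adds a random perturbation that is smooth across source positions (a sum of
#' Gaussian radial-basis bumps with random sensor patterns, scaled per node by
#' the node's gain magnitude) and whose relative Frobenius norm over the whole
#' stack equals `level` exactly. This provides a modality-agnostic, controlled
#' surrogate for the forward-solution divergence between head models of
#' different detail. EEG perturbations are common-average referenced before
#' scaling, so the reference property is preserved.
#'
#' @param lf a `leadfield`.
#' @param level relative Frobenius magnitude of the perturbation (>= 0).
#' @param seed integer seed; the same seed reproduces the same perturbation.
#' @param length_scale spatial correlation length of the field (mm).
#' @param n_centers number of radial-basis centers.
#' @return A `leadfield` with perturbed gain and an updated `model_label`.
#' @export
perturb_leadfield <- function(lf, level, seed, length_scale = 30, n_centers = 24) {
  stopifnot(inherits(lf, "leadfield"))
  if (!is.numeric(level) || length(level) != 1 || level < 0) {
    stop("`level` must be a single number >= 0", call. = FALSE)
  }
  if (level == 0) return(lf)
  N <- nrow(lf$gain)
  n <- lf$n_nodes
  delta <- with_seed(seed, {
    r_max <- max(row_norms(lf$positions))
    centers <- matrix(stats::runif(n_centers * 3, -r_max, r_max), n_centers, 3)
    d2 <- outer(rowSums(lf$positions^2), rowSums(centers^2), "+") -
      2 * lf$positions %*% t(centers)
    W <- exp(-pmax(d2, 0) / (2 * length_scale^2)) # n x J bump weights
    acc <- array(0, c(N, 3, n))
    for (j in seq_len(n_centers)) {
      Ej <- matrix(stats::rnorm(N * 3), N, 3)
      acc <- acc + outer(Ej, W[, j])
    }
    acc
  })
  delta <- matrix(delta, N, 3 * n) # N x 3 x n flattens to node-major triples
  # per-node scaling by gain magnitude keeps the perturbation relative in depth
  node_norm <- sqrt(colSums(matrix(colSums(lf$gain^2), nrow = 3)))
  delta <- sweep(delta, 2, rep(node_norm, each = 3), `*`)
  if (lf$modality == "eeg" && lf$sensors$reference == "common_average") {
    delta <- sweep(delta, 2, colMeans(delta))
  }
  dn <- sqrt(sum(delta^2))
  if (dn == 0) stop("degenerate perturbation field (all zero)", call. = FALSE)
  scale <- level * sqrt(sum(lf$gain^2)) / dn
  out <- lf
  out$gain <- lf$gain + scale * delta
  out$model_label <- sprintf("%s + perturbation %.3g", lf$model_label, level)
  out
}
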