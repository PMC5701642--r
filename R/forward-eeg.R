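# Analytic EEG forward solution for concentric-shell spherical conductors.
#
# The potential of a current dipole inside a layered sphere is expanded in
# spherical harmonics. Per degree n the radial profile in each shell is
# A r^n + B r^-(n+1); matching potential and radial current density at every
# interface and imposing zero current through the scalp yields a small linear
# system whose solution gives the surface response coefficient s_n per unit
# primary (infinite-medium) coefficient. The surface potential of a dipole at
# radius b with moment m = m_r b^ + m_t t^ is then
#
#   V(e) = sum_n  s_n b^(n-1) / (4 pi sigma_1 R^(n+1)) *
#          [ m_r * n * P_n(cos g)  +  (e^ . tau) * P_n'(cos g) ]
#
# with cos g the angle between electrode direction e^ and b^, and tau the
# tangential moment component. Radii are normalized by the outer radius R so
# the interface system stays well conditioned at high degree.

#' Surface response coefficients of a layered sphere
#'
#' Solves, for each spherical-harmonic degree `n`, the interface-matching
#' system of the layered conductor and returns the scalp response per unit
#' primary dipole coefficient. The homogeneous sphere gives the closed value
#' (2n+1)/n.
#'
#' @param shells a [shell_model()].
#' @param n_terms highest degree computed.
#' @return numeric vector of length `n_terms`.
#' @keywords internal
shell_response_coefficients <- function(shells, n_terms) {
  M <- length(shells$radii)
  R <- max(shells$radii)
  rho <- shells$radii / R
  sig <- shells$conductivities
  s <- numeric(n_terms)
  for (n in seq_len(n_terms)) {
    if (M == 1L) {
      # insulated homogeneous sphere: alpha_1 = (n+1)/n, surface = 1 + alpha_1
      s[n] <- (2 * n + 1) / n
      next
    }
    p <- 2L * M - 1L # unknowns: alpha_1, (alpha_k, beta_k) k = 2..M
    A <- matrix(0, p, p)
    rhs <- numeric(p)
    a_idx <- function(k) if (k == 1L) 1L else 2L * (k - 1L)
    b_idx <- function(k) 2L * k - 1L # k >= 2
    row <- 0L
    for (k in seq_len(M - 1L)) {
      r <- rho[k]
      rn <- r^n; rm <- r^(-(n + 1)) # regular / irregular radial terms
      # potential continuity
      row <- row + 1L
      A[row, a_idx(k)] <- rn
      if (k > 1L) A[row, b_idx(k)] <- rm
      A[row, a_idx(k + 1L)] <- -rn
      A[row, b_idx(k + 1L)] <- -rm
      if (k == 1L) rhs[row] <- -rm # primary term lives in shell 1
      # radial current continuity: sigma * dV/dr
      row <- row + 1L
      dn <- n * r^(n - 1); dm <- -(n + 1) * r^(-(n + 2))
      A[row, a_idx(k)] <- sig[k] * dn
      if (k > 1L) A[row, b_idx(k)] <- sig[k] * dm
      A[row, a_idx(k + 1L)] <- -sig[k + 1L] * dn
      A[row, b_idx(k + 1L)] <- -sig[k + 1L] * dm
      if (k == 1L) rhs[row] <- -sig[k] * dm
    }
    # insulating scalp: dV/dr = 0 at rho = 1
    row <- row + 1L
    A[row, a_idx(M)] <- n
    A[row, b_idx(M)] <- -(n + 1)
    x <- solve(A, rhs)
    s[n] <- x[a_idx(M)] + x[b_idx(M)]
  }
  s
}

# Legendre polynomials and derivatives at x (vector), degrees 1..n_max,
# accumulated into the two radial sums used by the dipole expansion.
# Returns list(Sa = sum_n k_n * n * P_n, Sb = sum_n k_n * P_n').
legendre_sums <- function(x, k) {
  n_max <- length(k)
  Pm1 <- rep(1, length(x)) # P_0
  P <- x # P_1
  dPm1 <- rep(0, length(x)) # P_0'
  dP <- rep(1, length(x)) # P_1'
  Sa <- k[1] * 1 * P
  Sb <- k[1] * dP
  if (n_max >= 2) {
    for (n in 2:n_max) {
      Pn <- ((2 * n - 1) * x * P - (n - 1) * Pm1) / n
      dPn <- dPm1 + (2 * n - 1) * P # P_n' = P_{n-2}' + (2n-1) P_{n-1}
      Sa <- Sa + k[n] * n * Pn
      Sb <- Sb + k[n] * dPn
      Pm1 <- P; P <- Pn
      dPm1 <- dP; dP <- dPn
    }
  }
  list(Sa = Sa, Sb = Sb)
}

#' EEG leadfield of a layered spherical conductor
#'
#' Potential gain at the electrodes for unit dipoles along the three Cartesian
#' axes at one source position, by truncated spherical-harmonic expansion.
#' Units are V/(A*m) with positions in mm. Columns are re-referenced to the
#' common average when the electrode array declares it.
#'
#' @param shells a [shell_model()].
#' @param electrodes a `sensor_array` with `modality = "eeg"` whose positions
#'   lie on the outermost shell.
#' @param node source position (length-3, mm), strictly inside the innermost
#'   shell.
#' @param n_terms series truncation order (default 60).
#' @return numeric matrix `[n_electrodes x 3]`.
#' @export
eeg_sphere_leadfield <- function(shells, electrodes, node, n_terms = 60) {
  stopifnot(inherits(shells, "shell_model"), inherits(electrodes, "sensor_array"))
  if (electrodes$modality != "eeg") stop("`electrodes` must be an EEG array", call. = FALSE)
  node <- as.numeric(node)
  stopifnot(length(node) == 3)
  k <- eeg_series_weights(shells, sqrt(sum(node^2)), n_terms)
  E <- electrodes$positions / max(shells$radii) # unit directions
  g <- eeg_gain_from_weights(E, node, k)
  if (electrodes$reference == "common_average") {
    g <- sweep(g, 2, colMeans(g))
  }
  g
}

# Per-degree weights k_n = s_n q^(n-1) / (4 pi sigma_1 R_m^2) for a dipole at
# radius b (mm). Warns when the truncated tail is not numerically negligible.
eeg_series_weights <- function(shells, b, n_terms,
                               s = NULL, warn_tol = 1e-4) {
  r_inner <- shells$radii[1]
  if (b >= r_inner) {
    stop(sprintf("source at radius %.2f mm is not strictly inside the innermost shell (%.2f mm)",
                 b, r_inner), call. = FALSE)
  }
  if (is.null(s)) s <- shell_response_coefficients(shells, n_terms)
  R <- max(shells$radii)
  q <- b / R
  R_m <- R / 1000
  k <- s * q^(seq_len(n_terms) - 1) / (4 * pi * shells$conductivities[1] * R_m^2)
  tail_rel <- abs(k[n_terms]) * n_terms / max(sum(abs(k) * seq_len(n_terms)), .Machine$double.xmin)
  if (tail_rel > warn_tol) {
    warning(sprintf("spherical-harmonic series may not have converged at order %d (tail ratio %.2e)",
                    n_terms, tail_rel), call. = FALSE)
  }
  k
}

# Gain at unit electrode directions E (N x 3) for a dipole at `node` with
# per-degree weights k. Returns the unreferenced N x 3 gain.
eeg_gain_from_weights <- function(E, node, k) {
  b <- sqrt(sum(node^2))
  bhat <- if (b > 0) node / b else c(0, 0, 1) # direction immaterial at b = 0
  x <- as.numeric(E %*% bhat)
  sums <- legendre_sums(x, k)
  # V[, i] = bhat_i * (Sa - Sb * x) + Sb * E[, i]
  g <- outer(sums$Sa - sums$Sb * x, bhat) + sums$Sb * E
  dimnames(g) <- list(NULL, c("x", "y", "z"))
  g
}
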