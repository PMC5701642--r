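# MEG forward solution for a spherically symmetric conductor.
#
# Outside a spherically symmetric conductor the magnetic field of a current
# dipole q at position r0 has the closed form (Sarvas)
#
#   B(r) = mu0 / (4 pi F^2) * ( F (q x r0) - ((q x r0) . r) grad F ),
#   F = a (r a + r^2 - r0 . r),   a = |r - r0|,
#   grad F = (a^2/r + (a . r)/a + 2 a + 2 r) r - (a + 2 r + (a . r)/a) r0.
#
# The field is independent of the conductivity profile and vanishes exactly
# for radial dipole moments, which is why quasi-radial sources are (nearly)
# silent for MEG.

# Field of unit dipoles along the three Cartesian axes at points `pts`
# (n x 3, metres, relative to the conductor centre) for a dipole at r0
# (metres). Returns a list of three n x 3 matrices (one per moment axis).
sarvas_field <- function(pts, r0) {
  mu0 <- 4e-7 * pi
  rr <- row_norms(pts)
  av <- sweep(pts, 2, r0) # a = r - r0
  a <- row_norms(av)
  if (any(a < 1e-12)) stop("field point coincides with the dipole", call. = FALSE)
  adotr <- rowSums(av * pts)
  r0dotr <- as.numeric(pts %*% r0)
  F <- a * (rr * a + rr^2 - r0dotr)
  c1 <- a^2 / rr + adotr / a + 2 * a + 2 * rr
  c2 <- a + 2 * rr + adotr / a
  gradF <- c1 * pts - outer(c2, r0)
  axes <- diag(3)
  out <- vector("list", 3)
  for (i in 1:3) {
    Q <- cross3(axes[i, ], r0) # q x r0, constant over field points
    Qdotr <- as.numeric(pts %*% Q)
    out[[i]] <- (mu0 / (4 * pi)) * (outer(F, Q) - Qdotr * gradF) / F^2
  }
  out
}

# 3-vector cross product (kept local; no dependency needed for one primitive)
cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' MEG leadfield of a spherically symmetric conductor
#'
#' Magnetic gain at an axial-gradiometer array for unit dipoles along the
#' three Cartesian axes at one source position. Each channel reads the field
#' component along its coil normal at the first coil minus the same component
#' at the second coil (`baseline` mm further out along the normal). The gain
#' is independent of the conductivity profile and exactly zero for dipole
#' moments parallel to `node - center`.
#'
#' @param sensors a `sensor_array` with `modality = "meg"`.
#' @param node source position (length-3, mm).
#' @param center conductor centre (length-3, mm, default origin).
#' @return numeric matrix `[n_channels x 3]` in T/(A*m).
#' @export
meg_sphere_leadfield <- function(sensors, node, center = c(0, 0, 0)) {
  stopifnot(inherits(sensors, "sensor_array"))
  if (sensors$modality != "meg") stop("`sensors` must be an MEG array", call. = FALSE)
  node <- as.numeric(node); center <- as.numeric(center)
  r0 <- (node - center) / 1000
  if (sqrt(sum(r0^2)) < 1e-12) {
    stop("source at the conductor centre is magnetically silent and ill-posed", call. = FALSE)
  }
  pos1 <- sweep(sensors$positions, 2, center) / 1000
  pos2 <- pos1 + sensors$orientations * (sensors$gradiometer_baseline / 1000)
  B1 <- sarvas_field(pos1, r0)
  B2 <- sarvas_field(pos2, r0)
  g <- sapply(1:3, function(i) {
    rowSums(B1[[i]] * sensors$orientations) - rowSums(B2[[i]] * sensors$orientations)
  })
  dimnames(g) <- list(NULL, c("x", "y", "z"))
  g
}
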