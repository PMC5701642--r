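# Independent oracles used by the tests. These deliberately take different
# computational routes from the package implementation.

# Closed-form surface potential of a dipole in a homogeneous conducting
# sphere with insulating boundary (image/generating-function solution):
#   V(r) = (1/4 pi sigma) [ 2 m.d / d^3 + m.(d^ + r^) / (R^2 - r0.r + d R) ]
# with d = r - r0 on the surface |r| = R. Inputs in mm, moment in A*m.
oracle_homogeneous_potential <- function(elec_mm, pos_mm, m_vec, sigma, R_mm) {
  elec <- elec_mm / 1000; pos <- pos_mm / 1000; R <- R_mm / 1000
  apply(elec, 1, function(r) {
    d <- r - pos
    dn <- sqrt(sum(d^2)); rn <- sqrt(sum(r^2))
    denom <- R^2 - sum(pos * r) + dn * R
    (2 * sum(m_vec * d) / dn^3 + sum(m_vec * (d / dn + r / rn)) / denom) / (4 * pi * sigma)
  })
}

# Finite-dipole oracle: two opposite monopoles and the monopole surface
# series V = I/(4 pi sigma R) sum (b/R)^n (2n+1)/n P_n(cos theta).
oracle_monopole_pair_potential <- function(elec_mm, pos_mm, m_vec, sigma, R_mm,
                                           delta = 1e-4, nmax = 400) {
  mono <- function(elec, pos, R, I) {
    b <- sqrt(sum(pos^2))
    bhat <- if (b > 0) pos / b else c(0, 0, 1)
    x <- as.numeric((elec / sqrt(rowSums(elec^2))) %*% bhat)
    Pm1 <- rep(1, length(x)); P <- x
    V <- (b / R) * 3 * P
    for (n in 2:nmax) {
      Pn <- ((2 * n - 1) * x * P - (n - 1) * Pm1) / n
      V <- V + (b / R)^n * (2 * n + 1) / n * Pn
      Pm1 <- P; P <- Pn
    }
    I / (4 * pi * sigma * R) * V
  }
  elec <- elec_mm / 1000; pos <- pos_mm / 1000; R <- R_mm / 1000
  mhat <- m_vec / sqrt(sum(m_vec^2))
  I <- sqrt(sum(m_vec^2)) / delta
  mono(elec, pos + mhat * delta / 2, R, I) - mono(elec, pos - mhat * delta / 2, R, I)
}

# Gauss-Legendre nodes/weights on [-1, 1] (Golub-Welsch).
oracle_gauss_legendre <- function(n) {
  i <- 1:(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = 2 * e$vectors[1, ]^2)
}

# MEG gain oracle by the Geselowitz surface-integral formulation for a
# homogeneous sphere: total field = primary dipole field plus the secondary
# field of the volume currents, expressed as a surface integral over the
# boundary potential (computed with the closed-form EEG oracle) and evaluated
# by spectrally accurate product quadrature.
oracle_geselowitz_gain <- function(sensors, node_mm, R_mm, sigma,
                                   ntheta = 80, nphi = 160) {
  gl <- oracle_gauss_legendre(ntheta)
  phi <- (seq_len(nphi) - 0.5) * 2 * pi / nphi
  ct <- gl$x; st <- sqrt(1 - ct^2)
  R <- R_mm / 1000
  pts <- cbind(rep(st, each = nphi) * cos(phi),
               rep(st, each = nphi) * sin(phi),
               rep(ct, each = nphi)) * R
  w <- rep(gl$w, each = nphi) * (2 * pi / nphi) * R^2
  nhat <- pts / R
  mu0 <- 4e-7 * pi
  r0 <- node_mm / 1000
  cross3 <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                             u[3] * v[1] - u[1] * v[3],
                             u[1] * v[2] - u[2] * v[1])
  gain <- matrix(0, sensors$n, 3)
  for (i in 1:3) {
    m <- diag(3)[i, ]
    V <- oracle_homogeneous_potential(pts * 1000, node_mm, m, sigma, R_mm)
    for (ch in seq_len(sensors$n)) {
      for (coil in 1:2) {
        p <- sensors$positions[ch, ] / 1000 +
          (coil - 1) * sensors$orientations[ch, ] * sensors$gradiometer_baseline / 1000
        a <- p - r0
        Bprim <- mu0 / (4 * pi) * cross3(m, a) / sqrt(sum(a^2))^3
        diffs <- sweep(pts, 2, p, "-") # r' - p
        dn3 <- sqrt(rowSums(diffs^2))^3
        cr <- cbind(nhat[, 2] * (-diffs[, 3]) - nhat[, 3] * (-diffs[, 2]),
                    nhat[, 3] * (-diffs[, 1]) - nhat[, 1] * (-diffs[, 3]),
                    nhat[, 1] * (-diffs[, 2]) - nhat[, 2] * (-diffs[, 1]))
        Bsec <- -mu0 / (4 * pi) * sigma * colSums(V * w * cr / dn3)
        sgn <- if (coil == 1) 1 else -1
        gain[ch, i] <- gain[ch, i] + sgn * sum((Bprim + Bsec) * sensors$orientations[ch, ])
      }
    }
  }
  gain
}

# Naive double-loop sample covariance (1/T convention).
oracle_covariance <- function(B) {
  N <- nrow(B); T_ <- ncol(B)
  C <- matrix(0, N, N)
  for (t in seq_len(T_)) C <- C + B[, t] %*% t(B[, t])
  C / T_
}

# Direct evaluation of the excess-kurtosis moment ratio with explicit loops.
oracle_kurtosis <- function(x) {
  T_ <- length(x)
  xb <- sum(x) / T_
  m2 <- sum((x - xb)^2) / T_
  m4 <- sum((x - xb)^4) / T_
  m4 / m2^2 - 3
}

# Dense quasi-uniform direction grid (golden-angle spiral), written
# independently of the package geometry helpers.
oracle_direction_grid <- function(n) {
  i <- seq_len(n)
  z <- 1 - (2 * i - 1) / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# Output variance of each constraint as a direct Rayleigh quotient in the
# moment direction, computed with base solve() on the covariance matrix.
oracle_constraint_variance <- function(gain, Cmat, U, constraint) {
  Ci <- solve(Cmat)
  K <- t(gain) %*% Ci %*% gain
  switch(constraint,
    unit_gain = 1 / rowSums((U %*% K) * U),
    unit_array_gain = {
      G <- t(gain) %*% gain
      rowSums((U %*% G) * U) / rowSums((U %*% K) * U)
    },
    unit_noise_gain = {
      K2 <- t(gain) %*% Ci %*% Ci %*% gain
      rowSums((U %*% K) * U) / rowSums((U %*% K2) * U)
    }
  )
}
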