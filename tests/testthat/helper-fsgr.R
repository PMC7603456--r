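# shared test helpers: independent oracles and small fixtures

# adaptive-quadrature oracle for the collagen ensemble dPsi/dI4bar:
# differentiate the recruitment integral directly (Leibniz), integrating
# (1/s^2 - 1/(s lam4)) rho(s) over the recruited part of the distribution
quad_dpsi_dI4 <- function(lam4, dist, K_c = 1, m_c = 1) {
  if (lam4 <= dist$min) return(0)
  f <- function(s) (1 / s^2 - 1 / (s * lam4)) * triangular_pdf(s, dist)
  m_c * (K_c / 2) *
    stats::integrate(f, dist$min, min(lam4, dist$max),
                     rel.tol = 1e-12, abs.tol = 1e-14)$value
}

# quadrature oracle for the ensemble energy itself
quad_energy <- function(lam4, dist, K_c = 1, m_c = 1) {
  if (lam4 <= dist$min) return(0)
  f <- function(s) (lam4 / s - 1)^2 * triangular_pdf(s, dist)
  m_c * (K_c / 2) *
    stats::integrate(f, dist$min, min(lam4, dist$max),
                     rel.tol = 1e-12, abs.tol = 1e-14)$value
}

# random rotation matrix (uniform via QR of a Gaussian matrix)
random_rotation <- function() {
  qr_d <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# random deformation gradient with prescribed determinant
random_F <- function(J = 1, spread = 0.15) {
  F <- diag(3) + spread * matrix(stats::rnorm(9), 3, 3)
  F * (J / det(F))^(1 / 3)
}

# small, fast configuration for pipeline tests
small_config <- function(n_points = 61, n_steps = 10, degradation = 6) {
  cfg <- default_config()
  cfg$geometry$n_points <- n_points
  cfg$schedule$n_steps <- n_steps
  cfg$schedule$degradation_steps <- degradation
  cfg$schedule$stabilization_steps <- n_steps - degradation
  cfg$schedule$wss_cadence <- 4
  cfg
}

# total strain energy of a material point, for finite-difference stress
# oracles (assembled from the exported energy pieces)
point_energy <- function(C, layer, fibers) {
  I3 <- det(C)
  I1 <- sum(diag(C))
  Jm23 <- I3^(-1 / 3)
  e <- (layer$m_e * layer$K_e + layer$m_sm * layer$K_sm) * (Jm23 * I1 - 3)
  for (f in fibers) {
    l4 <- sqrt(Jm23 * drop(f$direction %*% C %*% f$direction))
    e <- e + collagen_strain_energy(l4, f$recruitment, layer$K_c, layer$m_c)
  }
  e + volumetric_energy(I3, layer$kappa)
}
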