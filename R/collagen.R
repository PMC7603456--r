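# Closed-form collagen ensemble energy and its I4-derivative.
#
# Each fiber has a linear 1st Piola-Kirchhoff stress/stretch law, i.e. energy
# K_c/2 (lambda_c - 1)^2 with lambda_c = lambda4 / lambda_r, and the family
# energy is the integral of the single-fiber energy over the triangular
# recruitment density rho(lambda_r) for recruited fibers
# (lambda_r <= lambda4):
#
#   Psi(lambda4) = K/2 * Int_a^{min(lambda4, c)} (lambda4/s - 1)^2 rho(s) ds.
#
# Expanding the square gives moments of rho against 1/s^2, 1/s and 1, so
#
#   Psi            = K/2 * (lambda4^2 A(u) - 2 lambda4 B(u) + M(u))
#   dPsi/dI4bar    = K/2 * (A(u) - B(u)/lambda4)         (I4bar = lambda4^2)
#
# with u = min(max(lambda4, a), c) and
#   A(x) = Int_a^x rho(s)/s^2 ds,  B(x) = Int_a^x rho(s)/s ds,
#   M(x) = Int_a^x rho(s) ds (the CDF).
# On the rising branch rho = a1 (s - a), on the falling branch
# rho = a2 (c - s); the antiderivatives are elementary (log/rational), which
# is the closed "h1/h2/h3" form: for lambda4 beyond the support the ensemble
# 1st PK stress K (A_tot lambda4 - B_tot) is affine in lambda4.

tri_moments <- function(x, dist) {
  a <- dist$min; b <- dist$mode; c <- dist$max
  if (is_degenerate_dist(dist)) {
    # point mass at a
    rec <- x >= a
    return(list(A = ifelse(rec, 1 / a^2, 0),
                B = ifelse(rec, 1 / a, 0),
                M = as.numeric(rec)))
  }
  a1 <- if (b > a) 2 / ((c - a) * (b - a)) else 0
  a2 <- if (c > b) 2 / ((c - a) * (c - b)) else 0
  x <- pmin(pmax(x, a), c)
  x1 <- pmin(x, b)                       # upper limit within rising branch
  A <- a1 * (log(x1 / a) + a / x1 - 1)
  B <- a1 * ((x1 - a) - a * log(x1 / a))
  M <- a1 * (x1 - a)^2 / 2
  if (c > b) {
    x2 <- pmax(x, b)                     # upper limit within falling branch
    A <- A + a2 * (c * (1 / b - 1 / x2) - log(x2 / b))
    B <- B + a2 * (c * log(x2 / b) - (x2 - b))
    M <- M + a2 * (c * (x2 - b) - (x2^2 - b^2) / 2)
  }
  if (b == a) {
    # rising branch empty: drop its (0 * Inf) contributions
    A <- a2 * (c * (1 / b - 1 / pmax(x, b)) - log(pmax(x, b) / b))
    B <- a2 * (c * log(pmax(x, b) / b) - (pmax(x, b) - b))
    M <- a2 * (c * (pmax(x, b) - b) - (pmax(x, b)^2 - b^2) / 2)
  }
  list(A = A, B = B, M = M)
}

#' Collagen ensemble energy derivative with respect to the fiber invariant
#'
#' Returns `m_c * dPsi/dI4bar` for a collagen fiber family with a linear
#' single-fiber stress law of stiffness `K_c` and a triangular recruitment
#' distribution, using the analytic (closed-form) integrals of the
#' recruitment-averaged energy. Zero below the recruitment minimum; once all
#' fibers are recruited (`lambda4 > dist$max`) the ensemble 1st
#' Piola-Kirchhoff stress is affine in `lambda4`.
#'
#' @param lambda4 Tissue stretch(es) in the fiber direction (isochoric),
#'   `>= 0`.
#' @param dist A [recruitment_distribution()].
#' @param K_c Fiber stiffness-like constant (MPa, default 1).
#' @param m_c Normalized collagen mass density (dimensionless, 1 at
#'   reference).
#' @return `m_c * dPsi/dI4bar` (MPa), vectorized over `lambda4`.
#' @export
collagen_dpsi_dI4 <- function(lambda4, dist, K_c = 1, m_c = 1) {
  stopifnot(inherits(dist, "recruitment_distribution"), all(lambda4 >= 0))
  out <- numeric(length(lambda4))
  rec <- lambda4 > dist$min
  if (any(rec)) {
    lam <- lambda4[rec]
    mo <- tri_moments(lam, dist)
    out[rec] <- m_c * (K_c / 2) * (mo$A - mo$B / lam)
  }
  out
}

#' Collagen ensemble strain energy
#'
#' Recruitment-averaged strain energy of a collagen fiber family (per unit
#' reference volume, scaled by the normalized mass), the closed-form integral
#' of the linear single-fiber law over the triangular recruitment density.
#'
#' @inheritParams collagen_dpsi_dI4
#' @return Energy (MPa), vectorized over `lambda4`.
#' @export
collagen_strain_energy <- function(lambda4, dist, K_c = 1, m_c = 1) {
  stopifnot(inherits(dist, "recruitment_distribution"), all(lambda4 >= 0))
  out <- numeric(length(lambda4))
  rec <- lambda4 > dist$min
  if (any(rec)) {
    lam <- lambda4[rec]
    mo <- tri_moments(lam, dist)
    out[rec] <- m_c * (K_c / 2) * (lam^2 * mo$A - 2 * lam * mo$B + mo$M)
  }
  out
}
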