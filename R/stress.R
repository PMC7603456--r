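#' Layer composition and stiffness constants
#'
#' Normalized constituent masses and stiffness-like constants for one wall
#' layer. Masses are dimensionless (1 at the reference composition);
#' stiffnesses and the bulk modulus are in MPa. The isotropic (neo-Hookean)
#' part of the layer energy is `(m_e K_e + m_sm K_sm)(I1bar - 3)`; collagen is
#' handled per fiber family through the recruitment-distribution model.
#'
#' @param m_e,m_c,m_sm Normalized masses of elastin, collagen and smooth
#'   muscle (each `>= 0`).
#' @param K_e,K_c,K_sm Stiffness-like constants (MPa, `> 0`).
#' @param kappa Bulk modulus (MPa). Default `100 * K_c`, which keeps
#'   volumetric changes of equilibrium states within about 2 percent for the
#'   constant-stiffness fiber law.
#' @param layer_tag `"media"` or `"adventitia"`.
#' @return An object of class `layer_composition`.
#' @export
layer_composition <- function(m_e = 1, m_c = 1, m_sm = 0,
                              K_e = 0.1, K_c = 1, K_sm = 0.1,
                              kappa = NULL, layer_tag = "media") {
  if (any(c(m_e, m_c, m_sm) < 0)) stop("normalized masses must be >= 0")
  if (any(c(K_e, K_c, K_sm) <= 0)) stop("stiffness constants must be > 0")
  if (is.null(kappa)) kappa <- 100 * K_c
  if (kappa <= 0) stop("bulk modulus must be > 0")
  layer_tag <- match.arg(layer_tag, c("media", "adventitia"))
  structure(list(m_e = m_e, m_c = m_c, m_sm = m_sm,
                 K_e = K_e, K_c = K_c, K_sm = K_sm,
                 kappa = kappa, layer_tag = layer_tag),
            class = "layer_composition")
}

#' Volumetric strain energy
#'
#' Dilatational energy `kappa/4 * (I3 - 1 - 2 log sqrt(I3))`, convex in J
#' near 1 with zero energy and zero derivative at `I3 = 1`.
#'
#' @param I3 Third invariant `det(C) = J^2`, `> 0`.
#' @param kappa Bulk modulus (MPa).
#' @param deriv If `TRUE`, also return the derivative with respect to `I3`.
#' @return Energy (MPa), or a list `(value, dI3)` when `deriv = TRUE`.
#' @export
volumetric_energy <- function(I3, kappa, deriv = FALSE) {
  stopifnot(all(I3 > 0))
  val <- kappa / 4 * (I3 - 1 - log(I3))
  if (!deriv) return(val)
  list(value = val, dI3 = kappa / 4 * (1 - 1 / I3))
}

#' Second Piola-Kirchhoff stress of a layered fiber-reinforced wall
#'
#' Assembles `S = 2 dPsi/dC` from the isotropic neo-Hookean part, the
#' anisotropic recruitment-distribution collagen part and the volumetric
#' penalty, using the standard isochoric-split chain rule. The deviatoric
#' projector is `Dev(X) = J^(-2/3) (X - (X : C)/3 C^-1)` applied to the
#' referential derivative of each modified invariant, i.e.
#' `d(I1bar)/dC = J^(-2/3)(I - I1/3 C^-1)` and
#' `d(I4bar_i)/dC = J^(-2/3)(m_i x m_i - I4_i/3 C^-1)`.
#'
#' @param state A `deformation_state` from [compute_invariants()], built with
#'   the same `fibers`.
#' @param layer A [layer_composition()].
#' @param fibers List of [fiber_family()] objects.
#' @return Symmetric 3x3 second Piola-Kirchhoff stress (MPa).
#' @export
second_pk_stress <- function(state, layer, fibers = list()) {
  stopifnot(inherits(state, "deformation_state"),
            inherits(layer, "layer_composition"))
  C <- state$C
  J <- state$jacobian
  Cinv <- solve(C)
  I1 <- sum(diag(C))
  Jm23 <- J^(-2 / 3)
  psi1 <- layer$m_e * layer$K_e + layer$m_sm * layer$K_sm
  S <- 2 * psi1 * Jm23 * (diag(3) - (I1 / 3) * Cinv)
  if (length(fibers)) {
    for (k in seq_along(fibers)) {
      f <- fibers[[k]]
      lam4 <- state$lambda4bar[k]
      psi4 <- collagen_dpsi_dI4(lam4, f$recruitment, layer$K_c, layer$m_c)
      if (psi4 != 0) {
        m <- f$direction
        I4raw <- drop(m %*% C %*% m)
        S <- S + 2 * psi4 * Jm23 * (tcrossprod(m) - (I4raw / 3) * Cinv)
      }
    }
  }
  psi3 <- layer$kappa / 4 * (1 - 1 / state$I3)
  S <- S + 2 * psi3 * state$I3 * Cinv
  (S + t(S)) / 2
}

#' Cauchy stress by push-forward
#'
#' @param state A `deformation_state`.
#' @param S Second Piola-Kirchhoff stress (3x3, MPa).
#' @return Cauchy stress `F S F^T / J` (MPa).
#' @export
cauchy_stress <- function(state, S) {
  F <- state$F
  (F %*% S %*% t(F)) / state$jacobian
}

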