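#' Collagen fiber family at a material point
#'
#' Bundles a reference fiber direction with the recruitment distribution that
#' governs its waviness and the attachment distribution that defines its
#' homeostatic target.
#'
#' @param direction Reference unit 3-vector (normalized internally; zero
#'   vectors are rejected).
#' @param recruitment A [recruitment_distribution()].
#' @param attachment An [attachment_distribution()] (optional; needed by the
#'   remodelling laws, not by the stress evaluation).
#' @return An object of class `fiber_family`.
#' @export
fiber_family <- function(direction, recruitment, attachment = NULL) {
  stopifnot(is.numeric(direction), length(direction) == 3)
  n <- sqrt(sum(direction^2))
  if (n < 1e-12) stop("fiber direction must be a nonzero vector")
  if (!inherits(recruitment, "recruitment_distribution")) {
    stop("recruitment must be a recruitment_distribution")
  }
  if (!is.null(attachment) && !inherits(attachment, "attachment_distribution")) {
    stop("attachment must be an attachment_distribution")
  }
  structure(list(direction = direction / n, recruitment = recruitment,
                 attachment = attachment),
            class = "fiber_family")
}

#' Kinematic invariants of a deformation gradient
#'
#' Applies the multiplicative isochoric/volumetric split `F = J^(1/3) Fbar`
#' and returns the modified invariants of the right Cauchy-Green tensor
#' together with the modified fiber stretch of each family,
#' `lambda4bar_i = sqrt(m_i . Cbar m_i)`.
#'
#' @param F 3x3 deformation gradient with positive determinant.
#' @param fibers List of [fiber_family()] objects (may be empty).
#' @return An object of class `deformation_state`: list with
#'   `F`, `jacobian` (J), `I1bar`, `I2bar`, `I3` (= J^2), `Cbar`, `C`,
#'   and `lambda4bar` (numeric vector, one per family).
#' @export
compute_invariants <- function(F, fibers = list()) {
  stopifnot(is.matrix(F), all(dim(F) == c(3, 3)))
  J <- det(F)
  if (!is.finite(J) || J <= 0) {
    stop("invalid deformation: det(F) must be positive")
  }
  C <- crossprod(F)                 # F^T F
  Cbar <- J^(-2 / 3) * C
  I1b <- sum(diag(Cbar))
  I2b <- (I1b^2 - sum(Cbar * Cbar)) / 2
  lam4 <- vapply(fibers, function(f) {
    m <- f$direction
    sqrt(drop(m %*% Cbar %*% m))
  }, numeric(1))
  structure(list(F = F, jacobian = J, I1bar = I1b, I2bar = I2b,
                 I3 = J^2, C = C, Cbar = Cbar, lambda4bar = lam4),
            class = "deformation_state")
}

#' @export
print.deformation_state <- function(x, ...) {
  cat(sprintf("deformation state: J = %.6g, I1bar = %.6g, I3 = %.6g\n",
              x$jacobian, x$I1bar, x$I3))
  if (length(x$lambda4bar)) {
    cat("  fiber stretches:", paste(signif(x$lambda4bar, 6), collapse = ", "),
        "\n")
  }
  invisible(x)
}
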