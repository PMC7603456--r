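#' Triangular collagen recruitment-stretch distribution
#'
#' Collagen fibers in the unloaded wall are wavy: each fiber straightens and
#' begins to bear load only once the tissue stretch in its direction reaches
#' the fiber's *recruitment stretch*. Across a fiber family the recruitment
#' stretches follow a triangular probability density with support
#' `[min, max]` and mode `mode`.
#'
#' @param min,mode,max Recruitment stretches (dimensionless), with
#'   `1 <= min <= mode <= max`. Equal values are permitted; `min == max`
#'   degenerates to a single-recruitment (Heaviside) family.
#' @return An object of class `recruitment_distribution`.
#' @export
recruitment_distribution <- function(min, mode, max) {
  stopifnot(is.numeric(min), is.numeric(mode), is.numeric(max))
  if (!(min >= 1 - 1e-12)) stop("recruitment stretches must be >= 1")
  if (!(min <= mode && mode <= max)) {
    stop("recruitment distribution must satisfy min <= mode <= max")
  }
  structure(list(min = min, mode = mode, max = max),
            class = "recruitment_distribution")
}

#' Homeostatic attachment-stretch distribution
#'
#' The *attachment stretch* is the stretch at which a newly deposited collagen
#' fiber is configured to the matrix in the loaded state. The triple
#' (min, mode, max) is the homeostatic target for the corresponding triple of
#' collagen fiber stretches; "mode" is the modal value of the distribution
#' (tabulated parameter sets often label it "mean").
#'
#' Values below 1 are admissible: they describe a protective fiber fabric
#' (e.g. the healthy adventitia) that is slack at physiological load and is
#' only recruited at supraphysiological pressures.
#'
#' @param min,mode,max Attachment stretches, `min <= mode <= max`.
#' @return An object of class `attachment_distribution`.
#' @export
attachment_distribution <- function(min, mode, max) {
  stopifnot(is.numeric(min), is.numeric(mode), is.numeric(max))
  if (!(min <= mode && mode <= max)) {
    stop("attachment distribution must satisfy min <= mode <= max")
  }
  structure(list(min = min, mode = mode, max = max),
            class = "attachment_distribution")
}

#' @export
print.recruitment_distribution <- function(x, ...) {
  cat(sprintf("recruitment distribution: min %.6g  mode %.6g  max %.6g\n",
              x$min, x$mode, x$max))
  invisible(x)
}

#' @export
print.attachment_distribution <- function(x, ...) {
  cat(sprintf("attachment distribution: min %.6g  mode %.6g  max %.6g\n",
              x$min, x$mode, x$max))
  invisible(x)
}

is_degenerate_dist <- function(dist, tol = 1e-12) {
  (dist$max - dist$min) < tol
}

#' Triangular recruitment probability density
#'
#' Evaluates the four-branch triangular density: zero outside `[min, max]`,
#' rising linearly on `[min, mode]` and falling linearly on `[mode, max]`.
#'
#' @param lambda_r Recruitment stretch(es) at which to evaluate the density.
#' @param dist A [recruitment_distribution()].
#' @return Density value(s). For a degenerate distribution (`min == max`) the
#'   density is a point mass; the return is `Inf` at the atom and 0 elsewhere,
#'   with attribute `point_mass = TRUE`.
#' @export
triangular_pdf <- function(lambda_r, dist) {
  stopifnot(inherits(dist, "recruitment_distribution"))
  a <- dist$min; b <- dist$mode; c <- dist$max
  if (is_degenerate_dist(dist)) {
    out <- ifelse(abs(lambda_r - a) < 1e-12, Inf, 0)
    attr(out, "point_mass") <- TRUE
    return(out)
  }
  out <- numeric(length(lambda_r))
  up <- lambda_r > a & lambda_r <= b
  dn <- lambda_r > b & lambda_r <= c
  if (b > a) {
    out[up] <- 2 * (lambda_r[up] - a) / ((c - a) * (b - a))
  }
  if (c > b) {
    out[dn] <- 2 * (c - lambda_r[dn]) / ((c - a) * (c - b))
  }
  # if b == a the density starts at its apex: include the left endpoint limit
  if (b == a) out[lambda_r == a] <- 2 / (c - a)
  out
}

#' Collagen fiber stretch statistics from the tissue stretch
#'
#' The fiber stretch is the tissue stretch along the fiber direction divided
#' by the fiber's recruitment stretch. Fibers recruited first (at `dist$min`)
#' experience the largest fiber stretch, so the pairing is crossed:
#' `max = lambda4 / dist$min`, `mode = lambda4 / dist$mode`,
#' `min = lambda4 / dist$max`.
#'
#' @param lambda4 Tissue stretch in the fiber direction (modified/isochoric).
#' @param dist A [recruitment_distribution()].
#' @param clamp If `TRUE` (the constitutive convention) fiber stretches are
#'   clamped below at 1: a fiber that is not yet recruited is slack and
#'   carries no load. Remodelling laws use the raw ratio (`clamp = FALSE`).
#' @return Named numeric vector `c(min, mode, max)` of fiber stretches.
#' @export
collagen_fiber_stretch <- function(lambda4, dist, clamp = TRUE) {
  stopifnot(inherits(dist, "recruitment_distribution"), lambda4 >= 0)
  out <- c(min  = lambda4 / dist$max,
           mode = lambda4 / dist$mode,
           max  = lambda4 / dist$min)
  if (clamp) out <- pmax(out, 1)
  out
}
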