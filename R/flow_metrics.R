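#' Wall-shear-stress time series at a surface point
#'
#' @param times Strictly increasing sample times (s) over one analysis window.
#' @param vectors Numeric matrix, one row per sample, columns are the WSS
#'   vector components (Pa). Vectors must lie in the tangent plane of
#'   `normal` (they are checked, not projected).
#' @param normal Outward unit normal 3-vector.
#' @return An object of class `wss_series`.
#' @export
wss_series <- function(times, vectors, normal) {
  stopifnot(is.numeric(times), length(times) >= 2, all(diff(times) > 0))
  vectors <- as.matrix(vectors)
  stopifnot(ncol(vectors) == 3, nrow(vectors) == length(times))
  nn <- sqrt(sum(normal^2))
  if (abs(nn - 1) > 1e-8) stop("normal must be a unit vector")
  mags <- sqrt(rowSums(vectors^2))
  ortho <- abs(vectors %*% normal)
  tol <- 1e-6 * pmax(mags, max(mags), 1e-300)
  if (any(ortho > tol + 1e-12)) {
    stop("WSS vectors must be orthogonal to the surface normal")
  }
  structure(list(times = times, vectors = vectors, normal = normal),
            class = "wss_series")
}

#' Wall shear stress vector from a fluid stress tensor
#'
#' Removes the normal component of the traction: `tau = s n - ((s n).n) n`,
#' the shearing part of the fluid traction on the wall.
#'
#' @param sigma 3x3 fluid Cauchy stress tensor (Pa).
#' @param normal Outward unit normal.
#' @return WSS 3-vector (Pa), orthogonal to `normal`.
#' @export
wss_vector <- function(sigma, normal) {
  stopifnot(is.matrix(sigma), all(dim(sigma) == c(3, 3)))
  if (abs(sqrt(sum(normal^2)) - 1) > 1e-8) stop("normal must be a unit vector")
  trac <- drop(sigma %*% normal)
  trac - drop(trac %*% normal) * normal
}

# orthonormal in-plane basis for a unit normal
tangent_basis <- function(normal) {
  a <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - drop(a %*% normal) * normal
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(normal[2] * e1[3] - normal[3] * e1[2],
          normal[3] * e1[1] - normal[1] * e1[3],
          normal[1] * e1[2] - normal[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)

#' Principal wall-shear directions of a pulsatile series
#'
#' Sweeps the in-plane angle over `[0, pi)` and picks the direction whose
#' time-integrated (trapezoid) projected WSS is extremal. The first principal
#' direction maximizes the signed integral (or the integral of the absolute
#' projection when `method = "absolute"`); the second is its in-plane
#' orthogonal complement. When the signed integral is negligible for every
#' angle (e.g. a symmetric rotating series) the direction of maximal
#' projection range is used instead and the result is flagged
#' `isotropic = TRUE`; an all-zero series is flagged `degenerate = TRUE`.
#'
#' @param series A [wss_series()].
#' @param resolution_deg Angular sweep resolution in degrees (default 0.5).
#' @param method `"signed"` (default) or `"absolute"` projection integral.
#' @return List with unit vectors `eta1`, `eta2` and logical flags
#'   `isotropic`, `degenerate`.
#' @export
principal_directions <- function(series, resolution_deg = 0.5,
                                 method = c("signed", "absolute")) {
  stopifnot(inherits(series, "wss_series"))
  method <- match.arg(method)
  bas <- tangent_basis(series$normal)
  px <- drop(series$vectors %*% bas$e1)
  py <- drop(series$vectors %*% bas$e2)
  scale <- max(sqrt(px^2 + py^2))
  if (scale == 0) {
    return(list(eta1 = bas$e1, eta2 = bas$e2,
                isotropic = TRUE, degenerate = TRUE))
  }
  th <- seq(0, pi, by = resolution_deg * pi / 180)
  th <- th[th < pi]
  proj <- outer(px, cos(th)) + outer(py, sin(th))  # samples x angles
  t <- series$times
  isotropic <- FALSE
  if (method == "signed") {
    w <- c(diff(t)[1] / 2,
           (head(diff(t), -1) + diff(t)[-1]) / 2,
           diff(t)[length(t) - 1] / 2)
    ints <- drop(w %*% proj)
    # a signed integral below a few trapezoid panels is indistinguishable
    # from the discretization noise of a symmetric (rotating) series
    span <- diff(range(t)) * scale
    if (max(abs(ints)) < 10 * span / length(t)) {
      # signed integral vanishes for every direction: fall back to the
      # direction of maximal projection range
      isotropic <- TRUE
      rng <- apply(proj, 2, function(v) diff(range(v)))
      k <- which.max(rng)
    } else {
      k <- which.max(abs(ints))
      if (ints[k] < 0) {
        th[k] <- th[k] + pi  # orient eta1 with the positive mean shear
      }
    }
  } else {
    w <- c(diff(t)[1] / 2,
           (head(diff(t), -1) + diff(t)[-1]) / 2,
           diff(t)[length(t) - 1] / 2)
    ints <- drop(w %*% abs(proj))
    k <- which.max(ints)
  }
  eta1 <- cos(th[k]) * bas$e1 + sin(th[k]) * bas$e2
  n <- series$normal
  eta2 <- c(n[2] * eta1[3] - n[3] * eta1[2],
            n[3] * eta1[1] - n[1] * eta1[3],
            n[1] * eta1[2] - n[2] * eta1[1])
  list(eta1 = eta1, eta2 = eta2, isotropic = isotropic, degenerate = FALSE)
}

#' Wall shear stress aspect ratio (WSSAR)
#'
#' Bidirectionality of the WSS over the sampled window: the ranges of the WSS
#' projections onto the two principal tangent directions are compared, and
#' WSSAR is the smaller range divided by the larger. It is 0 for
#' uni-directional flow (fixed direction, any pulsatile magnitude) and 1 for
#' fully bi-directional flow; it is invariant to rigid rotation of the frame
#' and to uniform scaling of the WSS.
#'
#' @inheritParams principal_directions
#' @return WSSAR in `[0, 1]`. A no-flow series returns 0 with attribute
#'   `degenerate = TRUE`.
#' @export
wssar <- function(series, resolution_deg = 0.5,
                  method = c("signed", "absolute")) {
  stopifnot(inherits(series, "wss_series"))
  pd <- principal_directions(series, resolution_deg, method)
  if (pd$degenerate) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  p1 <- drop(series$vectors %*% pd$eta1)
  p2 <- drop(series$vectors %*% pd$eta2)
  r1 <- diff(range(p1))
  r2 <- diff(range(p2))
  tmax <- max(r1, r2)
  if (tmax == 0) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  min(r1, r2) / tmax
}

#' Degradation thresholds
#'
#' Thresholds of the two flow-driven degradation stimulus functions: the
#' low-WSS law switches on below `tau_C` (Pa) and saturates below `tau_L`;
#' the oscillatory-flow law switches on above the WSSAR value `tau_C_AR`
#' (dimensionless; WSSAR is a ratio) and saturates above `tau_H_AR`.
#'
#' @param tau_L,tau_C Low-WSS thresholds (Pa), `tau_L < tau_C`.
#' @param tau_C_AR,tau_H_AR WSSAR thresholds (dimensionless),
#'   `tau_C_AR < tau_H_AR`.
#' @param D_max Maximum degradation rate (1/year), `>= 0`.
#' @return An object of class `degradation_thresholds`.
#' @export
degradation_thresholds <- function(tau_L = 0.5, tau_C = 1,
                                   tau_C_AR = 0.7, tau_H_AR = 0.8,
                                   D_max = 1.5) {
  if (!(tau_L < tau_C)) stop("tau_L must be < tau_C")
  if (!(tau_C_AR < tau_H_AR)) stop("tau_C_AR must be < tau_H_AR")
  if (D_max < 0) stop("D_max must be >= 0")
  structure(list(tau_L = tau_L, tau_C = tau_C, tau_C_AR = tau_C_AR,
                 tau_H_AR = tau_H_AR, D_max = D_max),
            class = "degradation_thresholds")
}

#' Low-WSS degradation stimulus
#'
#' 1 (maximal degradation) at or below `tau_L`, 0 at or above `tau_C`, and
#' the quadratic `((tau_C - |tau|)/(tau_C - tau_L))^2` in between; continuous
#' and monotone non-increasing in the WSS magnitude.
#'
#' @param tau_mag WSS magnitude(s) (Pa), `>= 0`.
#' @param thresholds A [degradation_thresholds()].
#' @return Stimulus in `[0, 1]`, vectorized.
#' @export
f_wss <- function(tau_mag, thresholds = degradation_thresholds()) {
  stopifnot(all(tau_mag >= 0))
  tl <- thresholds$tau_L; tc <- thresholds$tau_C
  out <- ifelse(tau_mag <= tl, 1,
         ifelse(tau_mag >= tc, 0, ((tc - tau_mag) / (tc - tl))^2))
  out
}

#' High-WSSAR degradation stimulus
#'
#' 0 below `tau_C_AR`, 1 at or above `tau_H_AR`, quadratic in between;
#' continuous and monotone non-decreasing in WSSAR.
#'
#' @param tau_ar WSSAR value(s) in `[0, 1]`.
#' @param thresholds A [degradation_thresholds()].
#' @return Stimulus in `[0, 1]`, vectorized.
#' @export
f_ar <- function(tau_ar, thresholds = degradation_thresholds()) {
  stopifnot(all(tau_ar >= -1e-12), all(tau_ar <= 1 + 1e-12))
  tc <- thresholds$tau_C_AR; th <- thresholds$tau_H_AR
  ifelse(tau_ar < tc, 0,
  ifelse(tau_ar >= th, 1, ((tau_ar - tc) / (th - tc))^2))
}

#' Read / write WSS time series as CSV
#'
#' The CSV layout is one row per (point, time) with columns
#' `point_id, time, taux, tauy, tauz, nx, ny, nz`.
#'
#' @param path File path.
#' @return `read_wss_csv` returns a named list of [wss_series()], one per
#'   point id.
#' @export
read_wss_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("point_id", "time", "taux", "tauy", "tauz", "nx", "ny", "nz")
  if (!all(need %in% names(d))) {
    stop("WSS CSV must have columns: ", paste(need, collapse = ", "))
  }
  out <- lapply(split(d, d$point_id), function(g) {
    g <- g[order(g$time), ]
    wss_series(g$time, as.matrix(g[, c("taux", "tauy", "tauz")]),
               as.numeric(g[1, c("nx", "ny", "nz")]))
  })
  out
}

#' @rdname read_wss_csv
#' @param series_list Named list of [wss_series()].
#' @export
write_wss_csv <- function(series_list, path) {
  rows <- lapply(names(series_list), function(id) {
    s <- series_list[[id]]
    data.frame(point_id = id, time = s$times,
               taux = s$vectors[, 1], tauy = s$vectors[, 2],
               tauz = s$vectors[, 3],
               nx = s$normal[1], ny = s$normal[2], nz = s$normal[3])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
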