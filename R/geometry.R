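# Idealized axisymmetric vessel + sac geometry.
#
# The reference surface is a surface of revolution r(z) around the z axis:
# a parent cylinder of radius R0 carrying a Gaussian bulge of height H and
# width w (standard deviation), r(z) = R0 + H exp(-z^2 / (2 w^2)).
# All internal lengths are mm; the configuration interface is SI (m).

MM_PER_M <- 1000

#' Build the idealized axisymmetric geometry
#'
#' Discretizes the meridian of the parent-vessel-plus-sac surface, computes
#' the analytic principal curvatures, and labels each point as `parent`,
#' `neck` or `dome` from the local bulge fraction, with a linear blending
#' coordinate `u` (0 = parent, 1 = dome) across the neck band. A zero sac
#' height yields a plain cylinder labeled parent everywhere; a zero neck band
#' degenerates to a hard parameter jump (with a warning).
#'
#' @param config An `fsg_config` (only the `geometry` block is used), or the
#'   `geometry` block itself.
#' @return An object of class `ideal_geometry`: list with `points` (data
#'   frame: `z`, `r_ref` in mm, meridional curvature `k1` and hoop curvature
#'   radius `r2` in 1/mm and mm, `region`, blend `u`), layer thicknesses
#'   `h_media`, `h_adv` (mm) and the profile parameters.
#' @export
build_geometry <- function(config = default_config()) {
  g <- if (inherits(config, "fsg_config")) config$geometry else config
  R0 <- g$parent_radius * MM_PER_M
  H <- g$sac_height * MM_PER_M
  w <- g$sac_width * MM_PER_M
  L <- g$length * MM_PER_M
  n <- g$n_points
  if (R0 <= 0 || w <= 0 || L <= 0 || n < 3) stop("invalid geometry block")
  z <- seq(-L / 2, L / 2, length.out = n)
  bump <- exp(-z^2 / (2 * w^2))
  r <- R0 + H * bump
  rp <- -H * z / w^2 * bump              # dr/dz
  rpp <- H * bump * (z^2 / w^4 - 1 / w^2)
  s <- sqrt(1 + rp^2)
  k1 <- -rpp / s^3                        # meridional curvature (1/mm)
  r2 <- r * s                             # hoop curvature radius (mm)
  frac <- if (H > 0) bump else rep(0, n)
  nb <- g$neck_band
  lo <- 0.5 - nb / 2
  hi <- 0.5 + nb / 2
  if (nb == 0) {
    warning("neck band fraction 0: hard parameter jump between regions")
    u <- as.numeric(frac > 0.5)
  } else {
    u <- pmin(pmax((frac - lo) / (hi - lo), 0), 1)
  }
  region <- ifelse(u <= 0, "parent", ifelse(u >= 1, "dome", "neck"))
  h <- g$thickness * MM_PER_M
  structure(list(
    points = data.frame(z = z, r_ref = r, drdz = rp, k1 = k1, r2 = r2,
                        region = region, u = u),
    h_media = h * g$media_fraction,
    h_adv = h * (1 - g$media_fraction),
    R0 = R0, H = H, w = w
  ), class = "ideal_geometry")
}

#' @export
print.ideal_geometry <- function(x, ...) {
  cat(sprintf(
    "idealized geometry: %d points, parent radius %.3g mm, sac height %.3g mm\n",
    nrow(x$points), x$R0, x$H))
  cat("  regions:", paste(names(table(x$points$region)),
                          table(x$points$region), collapse = ", "), "\n")
  invisible(x)
}

#' Blend material parameters across the neck region
#'
#' Componentwise linear interpolation between the parent-artery and dome
#' parameter blocks: `position = 0` returns the parent values exactly,
#' `position = 1` the dome values. Works recursively over nested lists of
#' numeric values (stiffnesses, masses, rates and the attachment and
#' recruitment triples).
#'
#' @param parent_params,dome_params Nested lists with identical structure.
#' @param position Blend coordinate in `[0, 1]`.
#' @return Interpolated parameter list.
#' @export
blend_region_params <- function(parent_params, dome_params, position) {
  stopifnot(position >= 0, position <= 1)
  blend <- function(p, d) {
    if (is.list(p)) {
      out <- p
      for (k in names(p)) {
        out[k] <- list(blend(p[[k]], d[[k]]))  # keeps NULL entries
      }
      return(out)
    }
    if (is.numeric(p)) return((1 - position) * p + position * d)
    p
  }
  blend(parent_params, dome_params)
}

#' Assign collagen fiber orientations over the geometry
#'
#' In the parent artery the two fiber families are rotated by plus/minus the
#' layer angle about the circumferential direction (30 degrees in the media,
#' 60 in the adventitia by default). On the dome, fibers follow the principal
#' curvature directions of the surface, which for a surface of revolution are
#' the circumferential and meridional directions (angles 0 and 90); points
#' where the two principal curvatures coincide (umbilic, e.g. a sphere-like
#' apex) are flagged and fall back to the same circumferential/meridional
#' pair. Across the neck the angles are interpolated linearly in the blend
#' coordinate to keep the fiber field continuous.
#'
#' @param geometry An [build_geometry()] result.
#' @param angles List with per-layer parent angles in degrees,
#'   e.g. `list(media = 30, adventitia = 60)`.
#' @return Data frame with one row per (point, layer): angles of the two
#'   families in radians (`ang1`, `ang2`, measured from the circumferential
#'   direction) and an `umbilic` flag.
#' @export
assign_fiber_orientations <- function(geometry,
                                      angles = list(media = 30,
                                                    adventitia = 60)) {
  stopifnot(inherits(geometry, "ideal_geometry"))
  pts <- geometry$points
  k2 <- 1 / pts$r2
  umb <- abs(pts$k1 - k2) < 1e-6 * pmax(abs(pts$k1), abs(k2), 1e-12)
  out <- do.call(rbind, lapply(c("media", "adventitia"), function(ly) {
    a <- angles[[ly]] * pi / 180
    # parent: +/- a; dome: principal curvature directions (0 and -90 degrees,
    # i.e. circumferential and meridional); neck: linear in u
    ang1 <- (1 - pts$u) * a
    ang2 <- (1 - pts$u) * (-a) + pts$u * (-pi / 2)
    data.frame(point = seq_len(nrow(pts)), layer = ly,
               ang1 = ang1, ang2 = ang2, umbilic = umb & pts$u >= 1)
  }))
  rownames(out) <- NULL
  out
}

#' Principal curvatures of the idealized surface
#'
#' Returns the analytic meridional and circumferential principal curvatures
#' at each discretization point (1/mm). For the parent cylinder these are
#' `(0, 1/R0)`; the corresponding principal directions of any surface of
#' revolution are the meridional and circumferential tangents.
#'
#' @param geometry An [build_geometry()] result.
#' @return Data frame with columns `k_meridional`, `k_circumferential`.
#' @export
surface_curvatures <- function(geometry) {
  stopifnot(inherits(geometry, "ideal_geometry"))
  data.frame(k_meridional = geometry$points$k1,
             k_circumferential = 1 / geometry$points$r2)
}
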