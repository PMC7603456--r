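# Deterministic generators of synthetic test inputs: WSS rosettes and
# material-point deformation protocols. Pure functions of (spec, seed).

#' Synthetic wall-shear-stress rosette
#'
#' Generates a WSS time series at a single surface point whose analytic WSSAR
#' equals `ratio` when `noise = 0`. The base direction lies in the tangent
#' plane of `normal` at `base_angle` degrees; modes:
#' * `"fixed"`: direction fixed, magnitude `mean (1 + amp sin)` pulses, plus a
#'   cross-component of relative range `ratio`;
#' * `"alternating"`: magnitude `mean (bias + sin)` changes sign each half
#'   cycle with a positive time-mean;
#' * `"rotating"`: elliptical sweep `mean (cos, ratio sin)`; `ratio = 1` is a
#'   rotating constant-magnitude (fully bi-directional) series.
#'
#' @param ratio Cross-direction amplitude ratio in `[0, 1]`; the analytic
#'   WSSAR of the noise-free series.
#' @param mean Magnitude scale (Pa).
#' @param amp Relative pulsation amplitude (fixed mode).
#' @param base_angle In-plane angle of the primary direction (degrees).
#' @param mode `"fixed"`, `"alternating"` or `"rotating"`.
#' @param bias Positive mean offset for the alternating mode.
#' @param n Samples per period.
#' @param period Period (s).
#' @param normal Outward unit normal.
#' @param noise Additive Gaussian sd on components (Pa), applied before
#'   projection back onto the tangent plane.
#' @param seed RNG seed (noise only).
#' @return A [wss_series()].
#' @export
make_rosette <- function(ratio = 0, mean = 1, amp = 0.5, base_angle = 0,
                         mode = c("fixed", "alternating", "rotating"),
                         bias = 0.2, n = 200, period = 0.8,
                         normal = c(0, 0, 1), noise = 0, seed = 1L) {
  stopifnot(ratio >= 0, ratio <= 1, n >= 4)
  mode <- match.arg(mode)
  bas <- tangent_basis(normal / sqrt(sum(normal^2)))
  a <- base_angle * pi / 180
  d1 <- cos(a) * bas$e1 + sin(a) * bas$e2
  d2 <- -sin(a) * bas$e1 + cos(a) * bas$e2
  tt <- (seq_len(n) - 1) * period / n
  w <- 2 * pi * tt / period
  comp <- switch(mode,
    fixed = cbind(mean * (1 + amp * sin(w)), ratio * mean * amp * cos(w)),
    alternating = cbind(mean * (bias + sin(w)), ratio * mean * cos(w)),
    rotating = cbind(mean * cos(w), ratio * mean * sin(w)))
  vec <- comp[, 1] %o% d1 + comp[, 2] %o% d2
  if (noise > 0) {
    set.seed(seed)
    vec <- vec + matrix(stats::rnorm(3 * n, sd = noise), ncol = 3)
    nrm <- normal / sqrt(sum(normal^2))
    vec <- vec - (vec %*% nrm) %*% t(nrm)  # back onto the tangent plane
  }
  wss_series(tt, vec, normal / sqrt(sum(normal^2)))
}

#' Isochoric uniaxial deformation protocol
#'
#' Sequence of volume-preserving uniaxial deformation gradients
#' `diag(lambda, 1/sqrt(lambda), 1/sqrt(lambda))` for material-point testing
#' (e.g. tracing the toe-then-linear fiber ensemble stress response).
#'
#' @param range Stretch range `c(from, to)`, `from >= some admissible value`.
#' @param steps Number of gradients (a single identity if the range is
#'   degenerate with `steps = 1`).
#' @return List of 3x3 matrices.
#' @export
make_uniaxial_protocol <- function(range = c(1, 1.5), steps = 20) {
  stopifnot(length(range) == 2, all(range > 0), steps >= 1)
  lams <- if (steps == 1) range[1] else seq(range[1], range[2],
                                            length.out = steps)
  lapply(lams, function(l) diag(c(l, 1 / sqrt(l), 1 / sqrt(l))))
}

#' Write the canonical synthetic fixtures to a directory
#'
#' Emits the standard rosette series (uni-directional, bi-directional,
#' elliptical) as WSS CSV files and the default waveform as a two-column CSV,
#' for use outside R.
#'
#' @param dir Output directory (created if needed).
#' @param seed RNG seed.
#' @return The directory path, invisibly.
#' @export
write_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ros <- list(unidirectional = make_rosette(ratio = 0, mode = "fixed"),
              bidirectional = make_rosette(ratio = 1, mode = "rotating"),
              elliptical = make_rosette(ratio = 0.3, mode = "rotating"))
  write_wss_csv(ros, file.path(dir, "rosettes.csv"))
  wf <- synthesize_waveform()
  utils::write.csv(data.frame(time = wf$times, flow = wf$q),
                   file.path(dir, "inflow_waveform.csv"), row.names = FALSE)
  utils::write.csv(data.frame(time = wf$times, pressure = wf$p),
                   file.path(dir, "pressure_waveform.csv"), row.names = FALSE)
  invisible(dir)
}
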