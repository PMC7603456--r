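# Reduced-order hemodynamic surrogate.
#
# The growth-and-remodelling laws only consume wall-shear-stress fields, so a
# full Navier-Stokes solution is replaced by (a) Poiseuille scaling of the
# parent-vessel WSS with the local lumen radius, which encodes the observed
# feedback that an enlarging sac sees ever lower WSS, and (b) a synthetic
# oscillatory cross-component that deepens with the sac, to exercise the
# WSSAR pathway. File-based WSS ingestion (read_wss_csv) is the alternative
# source.

#' Poiseuille wall shear stress
#'
#' Fully developed laminar tube flow: `tau = 4 mu Q / (pi r^3)`.
#'
#' @param Q Flow rate (m^3/s).
#' @param radius Lumen radius (m, `> 0`).
#' @param mu Dynamic viscosity (Pa s).
#' @return WSS magnitude (Pa).
#' @export
poiseuille_wss <- function(Q, radius, mu = 3.5e-3) {
  stopifnot(all(radius > 0))
  4 * mu * Q / (pi * radius^3)
}

#' Synthesize a cardiac waveform
#'
#' Smooth periodic inlet flow-rate and outlet pressure waveforms
#' parameterized by mean, relative amplitude and systolic peak timing:
#' `Q(t) = q_mean (1 + q_amp cos(2 pi (t - peak)/T))` and likewise for the
#' pressure. Zero amplitude gives the steady (mean) waveform. The time-mean
#' equals the configured mean by construction.
#'
#' @param wave Waveform block of the configuration (see [default_config()]):
#'   `period` (s), `n_samples` per cycle, `q_mean` (m^3/s), `q_amp`,
#'   `p_mean` (Pa), `p_amp`, `peak_time` (s).
#' @return Object of class `waveform`: sample times over one period, flow and
#'   pressure samples, and the diastolic/systolic pressure extrema.
#' @export
synthesize_waveform <- function(wave = default_config()$fluid$waveform) {
  T <- wave$period
  n <- wave$n_samples
  stopifnot(T > 0, n >= 2)
  t <- (seq_len(n) - 1) * T / n
  ph <- cos(2 * pi * (t - wave$peak_time) / T)
  q <- wave$q_mean * (1 + wave$q_amp * ph)
  p <- wave$p_mean * (1 + wave$p_amp * ph)
  structure(list(period = T, n_samples = n, dt = T / n, times = t,
                 q = q, p = p, q_mean = wave$q_mean, p_mean = wave$p_mean,
                 p_dias = wave$p_mean * (1 - wave$p_amp),
                 p_sys = wave$p_mean * (1 + wave$p_amp)),
            class = "waveform")
}

#' Number of transient samples over a simulation window
#'
#' @param waveform A [synthesize_waveform()] result.
#' @param n_cycles Number of cardiac cycles.
#' @return Total sample count (`n_samples` per cycle times `n_cycles`).
#' @export
waveform_sample_count <- function(waveform, n_cycles = 3) {
  stopifnot(inherits(waveform, "waveform"))
  waveform$n_samples * n_cycles
}

#' Surrogate wall-shear-stress field over the idealized sac
#'
#' Per-point WSS over one cardiac cycle. The magnitude follows Poiseuille
#' scaling with the *current* local lumen radius, so sac enlargement lowers
#' the sac WSS (the geometric feedback loop); the direction is meridional
#' (along the flow), with an oscillatory circumferential cross-component
#' whose relative amplitude grows with local sac depth to emulate the
#' oscillatory secondary flow of a deep sac. Deterministic given a seed.
#'
#' @param geometry An [build_geometry()] result.
#' @param r_current Current lumen radii at the meridian points (mm), e.g.
#'   `eq$r_cur` from [solve_equilibrium()]; defaults to the reference radii.
#' @param waveform A [synthesize_waveform()] result.
#' @param config An `fsg_config` (uses the `fluid` and `flow` blocks).
#' @param noise Additive Gaussian noise sd on the WSS components (Pa).
#' @param seed RNG seed for the noise.
#' @return List with per-point steady WSS magnitude `tau_steady` (Pa, from
#'   the mean flow), `tau_ar` (WSSAR of the synthesized series), `cross_ratio`
#'   and the sample `times`; `series(i)` returns the [wss_series()] at point
#'   i (local frame: e1 circumferential, e2 meridional, normal e3).
#' @export
sac_wss_model <- function(geometry, r_current = NULL,
                          waveform = synthesize_waveform(),
                          config = default_config(),
                          noise = 0, seed = 1L) {
  stopifnot(inherits(geometry, "ideal_geometry"))
  pts <- geometry$points
  if (is.null(r_current)) r_current <- pts$r_ref
  stopifnot(length(r_current) == nrow(pts))
  mu <- config$fluid$mu
  # local sac depth in units of the reference sac height, from the current
  # radii relative to the current parent radius
  par_idx <- pts$region == "parent"
  r_par <- if (any(par_idx)) mean(r_current[par_idx]) else min(r_current)
  depth <- if (geometry$H > 0) {
    pmax(0, (r_current - r_par) / geometry$H)
  } else {
    rep(0, nrow(pts))
  }
  # parent WSS from Poiseuille at the current parent radius, attenuated
  # exponentially with sac depth (recirculating near-wall flow in the dome);
  # enlargement deepens the sac, so the low-WSS region spreads as the
  # aneurysm grows
  tau_par <- poiseuille_wss(waveform$q_mean, r_par / MM_PER_M, mu)
  atten <- exp(-config$flow$decay_rate * depth)
  tau_steady <- tau_par * atten
  cross_ratio <- pmin(1, config$flow$cross_ratio_max * depth)
  amp <- config$flow$oscillation_amp
  n <- length(waveform$times)
  ph <- 2 * pi * (waveform$times - config$fluid$waveform$peak_time) /
    waveform$period
  # analytic WSSAR of the noise-free rosette: ratio of the circumferential
  # to meridional projection ranges
  r_mer <- config$fluid$waveform$q_amp
  r_circ <- amp * cross_ratio
  hi <- pmax(r_mer, r_circ)
  tau_ar <- ifelse(hi > 0, pmin(r_mer, r_circ) / hi, 0)
  make_series <- function(i) {
    mag <- tau_steady[i] * waveform$q / waveform$q_mean    # meridional
    crs <- cross_ratio[i] * tau_steady[i] * amp * sin(ph)  # circumferential
    vec <- cbind(crs, mag, rep(0, n))
    if (noise > 0) {
      set.seed(seed + i)
      vec <- vec + matrix(stats::rnorm(3 * n, sd = noise), ncol = 3)
      vec[, 3] <- 0  # project back to the tangent plane
    }
    wss_series(waveform$times, vec, c(0, 0, 1))
  }
  list(tau_steady = tau_steady, tau_ar = tau_ar, cross_ratio = cross_ratio,
       depth = depth, times = waveform$times, series = make_series)
}
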