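#' Default run configuration
#'
#' Returns the full configuration with every setting at its default. Material
#' defaults are the published parameter sets for the healthy parent artery and
#' the aneurysm dome (stiffnesses in MPa, stretches dimensionless); geometry
#' is in meters and pressures in Pa (SI at the interface; internally the
#' mechanics uses mm and MPa). Normalized masses and wall thickness are
#' package defaults chosen to represent medial atrophy in the dome; see the
#' methods vignette.
#'
#' @return Nested list of class `fsg_config`.
#' @export
default_config <- function() {
  region <- function(att_m, rec_m, att_a, rec_a, masses_m, masses_a) {
    list(
      media = list(K_e = 0.1, K_c = 1.0, K_sm = 0.1, kappa = NULL,
                   alpha0 = 10.0, epsilon = 0.0,
                   m_e = masses_m[1], m_c = masses_m[2], m_sm = masses_m[3],
                   att = att_m, rec = rec_m),
      adventitia = list(K_e = 0.1, K_c = 1.0, K_sm = 0.1, kappa = NULL,
                        alpha0 = 10.0, epsilon = 0.0,
                        m_e = masses_a[1], m_c = masses_a[2],
                        m_sm = masses_a[3],
                        att = att_a, rec = rec_a))
  }
  structure(list(
    geometry = list(
      parent_radius = 0.002,    # m
      sac_height = 0.002,       # m
      sac_width = 0.00283,      # m (Gaussian std dev of the bulge profile;
                                # w^2 = H (R0 + H) makes the apex spherical)
      length = 0.016,           # m (axial extent of the modeled segment)
      n_points = 200,
      thickness = 0.00035,      # m, uniform total wall thickness
      media_fraction = 2 / 3,   # media share of the wall thickness
      neck_band = 0.9           # width of the neck blending band in [0, 1]
    ),
    material = list(
      parent = region(att_m = c(0.95, 1.0, 1.05), rec_m = c(1.01, 1.05, 1.1),
                      att_a = c(0.8, 0.9, 1.0),  rec_a = c(1.2, 1.25, 1.3),
                      masses_m = c(1, 1, 1), masses_a = c(1, 1, 0)),
      dome   = region(att_m = c(0.8, 0.9, 1.0),  rec_m = c(1.2, 1.25, 1.3),
                      att_a = c(1.0, 1.05, 1.1), rec_a = c(1.01, 1.05, 1.1),
                      masses_m = c(0.1, 0.5, 0.1), masses_a = c(1, 1, 0))
    ),
    fiber_angles = list(media = 30, adventitia = 60),   # degrees
    thresholds = list(tau_L = 0.5, tau_C = 1.0,
                      tau_C_AR = 0.7, tau_H_AR = 0.8, D_max = 1.5),
    gnr = list(alpha_att = 0.5),
    schedule = list(dt = 0.02, n_steps = 150,
                    degradation_steps = 100, stabilization_steps = 50,
                    wss_cadence = 20),
    fluid = list(rho = 1066, mu = 3.5e-3,
                 waveform = list(period = 0.8, n_samples = 200,
                                 q_mean = 2.54e-6, q_amp = 0.4,
                                 # diastolic/systolic extrema 9671.38 and
                                 # 9833.19 Pa (the steady outlet pressures of
                                 # the diastolic and systolic analyses)
                                 p_mean = 9752.285, p_amp = 0.008296,
                                 peak_time = 0.2)),
    flow = list(scenario = "low_wss", cross_ratio_max = 0.9,
                decay_rate = 0.19, angle_resolution_deg = 0.5,
                principal_method = "signed", oscillation_amp = 0.4),
    solver = list(tol = 1e-8, max_iter = 200, variant = "thick",
                  bending_scale = 1),
    homeostasis = list(max_iters = 100, tol = 1e-3),
    seed = 1L
  ), class = "fsg_config")
}

# recursive full-default template used for key validation
merge_config <- function(base, override, path = "") {
  for (k in names(override)) {
    key <- if (nzchar(path)) paste0(path, "$", k) else k
    if (!k %in% names(base)) stop("unknown configuration key: ", key)
    if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      if (!is.list(override[[k]])) stop("expected a block at key: ", key)
      base[[k]] <- merge_config(base[[k]], override[[k]], key)
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

validate_config <- function(cfg) {
  g <- cfg$geometry
  if (g$parent_radius <= 0) stop("geometry$parent_radius must be > 0")
  if (g$sac_height < 0) stop("geometry$sac_height must be >= 0")
  if (g$sac_width <= 0) stop("geometry$sac_width must be > 0")
  if (g$thickness <= 0) stop("geometry$thickness must be > 0")
  if (g$media_fraction <= 0 || g$media_fraction >= 1) {
    stop("geometry$media_fraction must be in (0, 1)")
  }
  if (g$neck_band < 0 || g$neck_band > 1) {
    stop("geometry$neck_band must be in [0, 1]")
  }
  th <- cfg$thresholds
  if (!(th$tau_L < th$tau_C)) stop("thresholds$tau_L must be < tau_C")
  if (!(th$tau_C_AR < th$tau_H_AR)) stop("thresholds$tau_C_AR must be < tau_H_AR")
  if (th$D_max < 0) stop("thresholds$D_max must be >= 0")
  s <- cfg$schedule
  if (s$dt <= 0) stop("schedule$dt must be > 0")
  if (th$D_max * s$dt >= 1) stop("D_max * dt must be < 1")
  if (s$degradation_steps + s$stabilization_steps != s$n_steps) {
    stop("degradation and stabilization windows must partition n_steps")
  }
  if (s$wss_cadence < 1) stop("schedule$wss_cadence must be >= 1")
  for (rg in names(cfg$material)) {
    for (ly in names(cfg$material[[rg]])) {
      p <- cfg$material[[rg]][[ly]]
      if (any(diff(p$att) < 0)) stop("attachment triple must be ordered: ",
                                     rg, "/", ly)
      if (any(diff(p$rec) < 0) || p$rec[1] < 1) {
        stop("recruitment triple must be ordered and >= 1: ", rg, "/", ly)
      }
      if (any(c(p$m_e, p$m_c, p$m_sm) < 0)) stop("masses must be >= 0")
      if (any(c(p$K_e, p$K_c, p$K_sm) <= 0)) stop("stiffnesses must be > 0")
    }
  }
  if (!cfg$flow$scenario %in% c("low_wss", "wssar")) {
    stop("flow$scenario must be 'low_wss' or 'wssar'")
  }
  invisible(cfg)
}

#' Load a run configuration from YAML
#'
#' Reads a (possibly partial) YAML file, merges it onto [default_config()],
#' rejects unknown keys, validates all invariants and returns the resolved
#' configuration. An empty file yields the full default configuration.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @param quiet If `FALSE`, echo the resolved top-level blocks.
#' @return A validated `fsg_config`.
#' @export
load_config <- function(path = NULL, quiet = TRUE) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (!is.null(user)) cfg <- merge_config(cfg, user)
  }
  class(cfg) <- "fsg_config"
  validate_config(cfg)
  if (!quiet) {
    message("resolved configuration blocks: ",
            paste(names(cfg), collapse = ", "))
  }
  cfg
}

#' Save a configuration to YAML
#'
#' @param cfg An `fsg_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "fsg_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
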