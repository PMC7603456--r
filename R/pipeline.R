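# Orchestration of the three simulation phases: initial homeostasis search,
# flow-driven degradation, and attachment-stretch stabilization.

#' Initialize a simulation state
#'
#' Builds the geometry and spatial wall state from a configuration and
#' synthesizes the cardiac waveform that supplies the diastolic and systolic
#' pressures.
#'
#' @param config An `fsg_config` from [load_config()] / [default_config()].
#' @return Object of class `fsg_state`: list with `config`, `geometry`,
#'   `wall`, `waveform`, and slots for the current equilibrium fields
#'   (`eq_dias`, `eq_sys`) and flow metrics (`flow`).
#' @export
init_state <- function(config = default_config()) {
  validate_config(config)
  geometry <- build_geometry(config)
  wall <- build_wall_state(geometry, config)
  structure(list(config = config, geometry = geometry, wall = wall,
                 waveform = synthesize_waveform(config$fluid$waveform),
                 eq_dias = NULL, eq_sys = NULL, flow = NULL, step = 0L),
            class = "fsg_state")
}

# fiber stretch at the configuration (dias/sys) maximizing it, per wall row
# and family; returns a list with matrices lam4 (rows x 2 families)
max_config_lam4 <- function(wall, eq_dias, eq_sys) {
  n <- max(wall$point)
  cols <- function(eq, layer) {
    pre <- if (layer == "media") "m" else "a"
    cbind(eq[[paste0("lam4_", pre, "1")]], eq[[paste0("lam4_", pre, "2")]])
  }
  lam4 <- matrix(NA_real_, nrow(wall), 2)
  for (ly in c("media", "adventitia")) {
    idx <- which(wall$layer == ly)
    pt <- wall$point[idx]
    d <- cols(eq_dias, ly)[pt, , drop = FALSE]
    s <- cols(eq_sys, ly)[pt, , drop = FALSE]
    lam4[idx, ] <- pmax(d, s)
  }
  lam4
}

# systolic fiber stretch per wall row and family
sys_lam4 <- function(wall, eq_sys) {
  lam4 <- matrix(NA_real_, nrow(wall), 2)
  for (ly in c("media", "adventitia")) {
    idx <- which(wall$layer == ly)
    pt <- wall$point[idx]
    pre <- if (ly == "media") "m" else "a"
    lam4[idx, ] <- cbind(eq_sys[[paste0("lam4_", pre, "1")]][pt],
                         eq_sys[[paste0("lam4_", pre, "2")]][pt])
  }
  lam4
}

# vectorized recruitment remodelling over all wall rows (one Euler step);
# returns list(wall, max_rate) where max_rate is the largest remodelling
# rate magnitude (1/year) before the step
remodel_wall <- function(wall, lam4, dt) {
  max_rate <- 0
  for (fam in 1:2) {
    rmin <- wall[[paste0("rec", fam, "_min")]]
    rmod <- wall[[paste0("rec", fam, "_mode")]]
    rmax <- wall[[paste0("rec", fam, "_max")]]
    amin <- wall[[paste0("att", fam, "_min")]]
    amod <- wall[[paste0("att", fam, "_mode")]]
    amax <- wall[[paste0("att", fam, "_max")]]
    l4 <- lam4[, fam]
    rate_min  <- wall$alpha0 * (l4 / rmin - amax) / amax
    rate_mode <- wall$alpha0 * (l4 / rmod - amod) / amod
    rate_max  <- wall$alpha0 * (l4 / rmax - amin) / amin
    max_rate <- max(max_rate, abs(rate_min), abs(rate_mode), abs(rate_max))
    nmin <- rmin + dt * rate_min
    nmod <- rmod + dt * rate_mode
    nmax <- rmax + dt * rate_max
    if (any(c(nmin, nmod, nmax) < 1)) {
      warning("recruitment stretch clamped at 1 during remodelling")
      nmin <- pmax(nmin, 1); nmod <- pmax(nmod, 1); nmax <- pmax(nmax, 1)
    }
    # re-enforce ordering rowwise
    lo <- pmin(nmin, nmod, nmax)
    hi <- pmax(nmin, nmod, nmax)
    md <- nmin + nmod + nmax - lo - hi
    wall[[paste0("rec", fam, "_min")]] <- lo
    wall[[paste0("rec", fam, "_mode")]] <- md
    wall[[paste0("rec", fam, "_max")]] <- hi
  }
  list(wall = wall, max_rate = max_rate)
}

# largest relative deviation of the fiber-stretch triple from the attachment
# triple over all rows and families. Quantiles whose fixed-point recruitment
# stretch lam4/att would fall below 1 are excluded: the recruitment clamp
# makes them inert (zero achievable remodelling rate), so mechanobiological
# equilibrium is defined over the remodelling-capable quantiles.
homeo_residual <- function(wall, lam4) {
  res <- 0
  for (fam in 1:2) {
    for (q in c("min", "mode", "max")) {
      rq <- switch(q, min = "max", mode = "mode", max = "min")
      lc <- lam4[, fam] / wall[[paste0("rec", fam, "_", rq)]]
      at <- wall[[paste0("att", fam, "_", q)]]
      active <- lam4[, fam] / at >= 1
      if (any(active)) {
        res <- max(res, abs(lc[active] - at[active]) / at[active])
      }
    }
  }
  res
}

#' Search for the initial homeostatic state
#'
#' Fixed-point iteration alternating quasi-static equilibrium (at diastolic
#' and systolic pressure) with one explicit Euler step of the
#' recruitment-distribution remodelling law, until the collagen fiber-stretch
#' statistics match the attachment-stretch triple everywhere to within `tol`
#' (relative). Fails with the residual history if `max_iters` is exceeded.
#'
#' @param state An [init_state()] result.
#' @param max_iters Iteration cap.
#' @param tol Relative convergence tolerance (default 1e-3).
#' @param quiet Suppress progress messages.
#' @return The state at homeostasis, with `iterations` (number of remodelling
#'   sweeps applied) and `residual_history` attached.
#' @export
run_homeostasis <- function(state, max_iters = NULL, tol = NULL,
                            quiet = TRUE) {
  stopifnot(inherits(state, "fsg_state"))
  cfg <- state$config
  if (is.null(max_iters)) max_iters <- cfg$homeostasis$max_iters
  if (is.null(tol)) tol <- cfg$homeostasis$tol
  dt <- cfg$schedule$dt
  variant <- cfg$solver$variant
  p_d <- state$waveform$p_dias
  p_s <- state$waveform$p_sys
  hist <- numeric(0)
  iters <- 0L
  repeat {
    state$eq_dias <- solve_equilibrium(state$geometry, state$wall, p_d,
                                       init = state$eq_dias,
                                       variant = variant,
                                       tol = cfg$solver$tol,
                                       max_iter = cfg$solver$max_iter,
                                       bending_scale = cfg$solver$bending_scale)
    state$eq_sys <- solve_equilibrium(state$geometry, state$wall, p_s,
                                      init = state$eq_sys, variant = variant,
                                      tol = cfg$solver$tol,
                                      max_iter = cfg$solver$max_iter,
                                      bending_scale = cfg$solver$bending_scale)
    lam4 <- max_config_lam4(state$wall, state$eq_dias, state$eq_sys)
    res <- homeo_residual(state$wall, lam4)
    hist <- c(hist, res)
    if (!quiet) message(sprintf("homeostasis iter %d: residual %.3g",
                                iters, res))
    if (res < tol) break
    if (iters >= max_iters) {
      stop(sprintf(paste0("homeostasis did not converge in %d iterations ",
                          "(residual %.3g); history: %s"),
                   max_iters, res,
                   paste(signif(hist, 3), collapse = ", ")))
    }
    state$wall <- remodel_wall(state$wall, lam4, dt)$wall
    iters <- iters + 1L
  }
  attr(state, "iterations") <- iters
  attr(state, "residual_history") <- hist
  state
}

# evaluate the per-point degradation stimulus for the active scenario
eval_stimulus <- function(flow, scenario, thresholds) {
  if (scenario == "low_wss") {
    f_wss(flow$tau_steady, thresholds)
  } else {
    f_ar(flow$tau_ar, thresholds)
  }
}

#' Run the growth-and-remodelling evolution
#'
#' Marches the wall state through the degradation and stabilization windows
#' of the schedule. Each step: refresh the surrogate WSS field at the
#' configured cadence (from the current systolic geometry), evaluate the
#' degradation stimulus (low-WSS or WSSAR scenario, exclusive per run),
#' degrade the constituent masses (degradation window only), solve
#' equilibrium at both pressures, remodel the recruitment distributions at
#' the configuration maximizing the fiber stretch, grow collagen mass
#' (systolic), and - during the stabilization window - adapt the attachment
#' distributions towards the current fiber stretches.
#'
#' @param state A homeostatic `fsg_state` (from [run_homeostasis()]).
#' @param scenario `"low_wss"` or `"wssar"`; defaults to the configuration.
#' @param start_step First step index (for checkpoint restarts).
#' @param n_steps Number of steps to run (default: the rest of the schedule).
#' @param quiet Suppress progress messages.
#' @return Object of class `fsg_trajectory`: list with the per-step summary
#'   data frame `steps`, the final `state`, and `max_J_dev` (largest
#'   |J - 1| over all points, layers, steps and the two pressures).
#' @export
run_evolution <- function(state, scenario = NULL, start_step = 1L,
                          n_steps = NULL, quiet = TRUE) {
  stopifnot(inherits(state, "fsg_state"))
  cfg <- state$config
  sch <- cfg$schedule
  if (is.null(scenario)) scenario <- cfg$flow$scenario
  scenario <- match.arg(scenario, c("low_wss", "wssar"))
  if (is.null(n_steps)) n_steps <- sch$n_steps - (start_step - 1L)
  last <- start_step + n_steps - 1L
  if (last > sch$n_steps) stop("schedule window exceeded")
  thr <- degradation_thresholds(cfg$thresholds$tau_L, cfg$thresholds$tau_C,
                                cfg$thresholds$tau_C_AR,
                                cfg$thresholds$tau_H_AR,
                                cfg$thresholds$D_max)
  params <- gnr_params(alpha0 = 1, epsilon = 1,  # rates live in the wall state
                       alpha_att = cfg$gnr$alpha_att,
                       D_max = cfg$thresholds$D_max, dt = sch$dt)
  variant <- cfg$solver$variant
  p_d <- state$waveform$p_dias
  p_s <- state$waveform$p_sys
  if (is.null(state$eq_sys)) {
    state$eq_dias <- solve_equilibrium(state$geometry, state$wall, p_d,
                                       variant = variant,
                                       bending_scale = cfg$solver$bending_scale)
    state$eq_sys <- solve_equilibrium(state$geometry, state$wall, p_s,
                                      variant = variant,
                                      bending_scale = cfg$solver$bending_scale)
  }
  dome_rows <- state$wall$region == "dome"
  apex <- which.max(state$geometry$points$r_ref)
  steps <- vector("list", n_steps)
  max_J_dev <- 0
  for (k in seq_len(n_steps)) {
    step <- start_step + k - 1L
    phase <- if (step <= sch$degradation_steps) "degradation" else
      "stabilization"
    if (is.null(state$flow) || (step - 1L) %% sch$wss_cadence == 0L) {
      state$flow <- sac_wss_model(state$geometry, state$eq_sys$r_cur,
                                  state$waveform, cfg,
                                  seed = cfg$seed + step)
    }
    stim <- eval_stimulus(state$flow, scenario, thr)
    if (phase == "degradation" && thr$D_max > 0) {
      srow <- stim[state$wall$point]
      fac <- 1 - srow * thr$D_max * sch$dt
      state$wall$m_e <- state$wall$m_e * fac
      state$wall$m_c <- state$wall$m_c * fac
      state$wall$m_sm <- state$wall$m_sm * fac
    }
    eq_try <- tryCatch({
      ed <- solve_equilibrium(state$geometry, state$wall, p_d,
                              init = state$eq_dias,
                              variant = variant,
                              tol = cfg$solver$tol,
                              max_iter = cfg$solver$max_iter,
                              bending_scale = cfg$solver$bending_scale)
      es <- solve_equilibrium(state$geometry, state$wall, p_s,
                              init = state$eq_sys, variant = variant,
                              tol = cfg$solver$tol,
                              max_iter = cfg$solver$max_iter,
                              bending_scale = cfg$solver$bending_scale)
      list(ed = ed, es = es)
    }, error = function(e) e)
    if (inherits(eq_try, "error")) {
      # abort with the trajectory computed so far
      warning(sprintf("equilibrium failure at step %d: %s", step,
                      conditionMessage(eq_try)))
      out <- structure(list(steps = do.call(rbind, steps[seq_len(k - 1)]),
                            state = state, max_J_dev = max_J_dev,
                            scenario = scenario, aborted_at = step),
                       class = "fsg_trajectory")
      return(out)
    }
    state$eq_dias <- eq_try$ed
    state$eq_sys <- eq_try$es
    lam4 <- max_config_lam4(state$wall, state$eq_dias, state$eq_sys)
    rem <- remodel_wall(state$wall, lam4, sch$dt)
    state$wall <- rem$wall
    # collagen growth at systole (fibroblast stretch = max fiber stretch)
    l4s <- sys_lam4(state$wall, state$eq_sys)
    for (fam in 1:2) {
      l4f <- l4s[, fam] / state$wall[[paste0("rec", fam, "_min")]]
      attf <- state$wall[[paste0("att", fam, "_max")]]
      state$wall$m_c <- state$wall$m_c *
        (1 + state$wall$epsilon * sch$dt * (l4f - attf) / attf)
    }
    if (phase == "stabilization") {
      aatt <- cfg$gnr$alpha_att
      for (fam in 1:2) {
        for (q in c("min", "mode", "max")) {
          rq <- switch(q, min = "max", mode = "mode", max = "min")
          lc <- lam4[, fam] / state$wall[[paste0("rec", fam, "_", rq)]]
          ac <- paste0("att", fam, "_", q)
          state$wall[[ac]] <- state$wall[[ac]] +
            aatt * (lc - state$wall[[ac]])
        }
      }
    }
    Jdev <- max(abs(c(state$eq_dias$J_m, state$eq_dias$J_a,
                      state$eq_sys$J_m, state$eq_sys$J_a) - 1))
    max_J_dev <- max(max_J_dev, Jdev)
    steps[[k]] <- data.frame(
      step = step, time = step * sch$dt, phase = phase,
      apex_radius = state$eq_sys$r_cur[apex],
      wss_min = min(state$flow$tau_steady),
      wss_mean = mean(state$flow$tau_steady),
      wssar_max = max(state$flow$tau_ar),
      stim_max = max(stim),
      m_c_dome = if (any(dome_rows)) mean(state$wall$m_c[dome_rows]) else NA,
      m_e_dome = if (any(dome_rows)) mean(state$wall$m_e[dome_rows]) else NA,
      att_mode_max = max(state$wall$att1_mode, state$wall$att2_mode),
      rate_norm = rem$max_rate,
      max_J_dev = Jdev)
    state$step <- step
    if (!quiet) message(sprintf(
      "step %3d (%s): apex radius %.3f mm, rate norm %.3g /yr",
      step, phase, steps[[k]]$apex_radius, rem$max_rate))
  }
  structure(list(steps = do.call(rbind, steps), state = state,
                 max_J_dev = max_J_dev, scenario = scenario),
            class = "fsg_trajectory")
}

#' Summarize a growth-and-remodelling trajectory
#'
#' @param trajectory An [run_evolution()] result.
#' @return List with the step count, time range, the per-step series (sac
#'   size, WSS extrema, WSSAR extrema, mass means, attachment range,
#'   remodelling-rate norm) and the overall incompressibility deviation.
#' @export
summarize_trajectory <- function(trajectory) {
  stopifnot(inherits(trajectory, "fsg_trajectory"))
  s <- trajectory$steps
  if (!nrow(s)) stop("empty trajectory")
  list(n_steps = nrow(s),
       years = range(s$time),
       scenario = trajectory$scenario,
       series = s,
       apex_radius_change_mm = s$apex_radius[nrow(s)] - s$apex_radius[1],
       final_rate_norm = s$rate_norm[nrow(s)],
       max_J_dev = trajectory$max_J_dev)
}

#' @export
print.fsg_trajectory <- function(x, ...) {
  s <- x$steps
  cat(sprintf(
    "G&R trajectory (%s): %d steps over %.2f years\n", x$scenario, nrow(s),
    max(s$time) - min(s$time) + s$time[1]))
  cat(sprintf("  apex radius %.3f -> %.3f mm; final rate norm %.3g /yr\n",
              s$apex_radius[1], s$apex_radius[nrow(s)],
              s$rate_norm[nrow(s)]))
  cat(sprintf("  max |J - 1| = %.4f\n", x$max_J_dev))
  invisible(x)
}

# --- checkpointing (plain-text CSV, full double precision) -----------------

fmt_df <- function(d) {
  for (j in seq_along(d)) {
    if (is.numeric(d[[j]])) d[[j]] <- sprintf("%.17g", d[[j]])
  }
  d
}

#' Save / load a simulation checkpoint
#'
#' Writes the evolving wall state, the current equilibrium stretches (used as
#' warm starts) and step metadata as plain CSV/YAML under a path prefix, at
#' full double precision so a restarted run reproduces the remaining
#' trajectory exactly.
#'
#' @param state An `fsg_state`.
#' @param prefix Path prefix; files `<prefix>_wall.csv`,
#'   `<prefix>_eq.csv` and `<prefix>_meta.yaml` are created.
#' @return `prefix`, invisibly.
#' @export
save_checkpoint <- function(state, prefix) {
  stopifnot(inherits(state, "fsg_state"))
  utils::write.csv(fmt_df(state$wall), paste0(prefix, "_wall.csv"),
                   row.names = FALSE)
  eq <- rbind(cbind(which = "dias", state$eq_dias),
              cbind(which = "sys", state$eq_sys))
  utils::write.csv(fmt_df(eq), paste0(prefix, "_eq.csv"), row.names = FALSE)
  if (!is.null(state$flow)) {
    fl <- data.frame(tau_steady = state$flow$tau_steady,
                     tau_ar = state$flow$tau_ar,
                     cross_ratio = state$flow$cross_ratio,
                     depth = state$flow$depth)
    utils::write.csv(fmt_df(fl), paste0(prefix, "_flow.csv"),
                     row.names = FALSE)
  }
  yaml::write_yaml(list(step = state$step, config = unclass(state$config)),
                   paste0(prefix, "_meta.yaml"))
  invisible(prefix)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(prefix) {
  meta <- yaml::read_yaml(paste0(prefix, "_meta.yaml"))
  cfg <- merge_config(default_config(), meta$config)
  class(cfg) <- "fsg_config"
  state <- init_state(cfg)
  wall <- utils::read.csv(paste0(prefix, "_wall.csv"),
                          stringsAsFactors = FALSE)
  class(wall) <- c("wall_state", "data.frame")
  state$wall <- wall
  eq <- utils::read.csv(paste0(prefix, "_eq.csv"), stringsAsFactors = FALSE)
  split_eq <- function(w) {
    d <- eq[eq$which == w, names(eq) != "which"]
    rownames(d) <- NULL
    class(d) <- c("equilibrium_field", "data.frame")
    d
  }
  state$eq_dias <- split_eq("dias")
  state$eq_sys <- split_eq("sys")
  flow_path <- paste0(prefix, "_flow.csv")
  if (file.exists(flow_path)) {
    fl <- utils::read.csv(flow_path)
    state$flow <- list(tau_steady = fl$tau_steady, tau_ar = fl$tau_ar,
                       cross_ratio = fl$cross_ratio, depth = fl$depth)
  }
  state$step <- as.integer(meta$step)
  state
}
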