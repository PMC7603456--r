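#' Growth and remodelling rate parameters
#'
#' @param alpha0 Recruitment remodelling rate (1/year, `>= 0`).
#' @param epsilon Collagen mass growth rate (1/year, `>= 0`).
#' @param alpha_att Attachment adaptation rate per step (dimensionless,
#'   in `[0, 1]`; `alpha_att = 1` relaxes the attachment stretch to the
#'   current fiber stretch in one step).
#' @param D_max Maximum degradation rate (1/year, `>= 0`).
#' @param dt Time step (years, `> 0`); `D_max * dt < 1` is required so that
#'   explicit Euler keeps masses positive.
#' @return An object of class `gnr_params`.
#' @export
gnr_params <- function(alpha0 = 10, epsilon = 0, alpha_att = 0.5,
                       D_max = 1.5, dt = 0.02) {
  if (any(c(alpha0, epsilon, D_max) < 0)) stop("rates must be >= 0")
  if (alpha_att < 0 || alpha_att > 1) stop("alpha_att must be in [0, 1]")
  if (dt <= 0) stop("dt must be > 0")
  if (D_max * dt >= 1) stop("D_max * dt must be < 1 for explicit Euler")
  structure(list(alpha0 = alpha0, epsilon = epsilon, alpha_att = alpha_att,
                 D_max = D_max, dt = dt),
            class = "gnr_params")
}

#' Flow-driven mass degradation (one explicit Euler step)
#'
#' Integrates `dm/dt = -F_X * D_max * m` for one step `dt`. The same law is
#' applied to the elastin, collagen and smooth muscle normalized masses.
#'
#' @param m Normalized mass(es), `>= 0`.
#' @param stimulus Degradation stimulus `F_X` in `[0, 1]` (from [f_wss()] or
#'   [f_ar()]), recycled against `m`.
#' @param params A [gnr_params()].
#' @return Updated mass(es).
#' @export
degrade_mass <- function(m, stimulus, params) {
  stopifnot(inherits(params, "gnr_params"), all(m >= 0),
            all(stimulus >= 0), all(stimulus <= 1))
  m * (1 - stimulus * params$D_max * params$dt)
}

#' Recruitment-distribution remodelling (one explicit Euler step)
#'
#' Evolves the recruitment triple so that the collagen fiber stretch
#' distribution remodels towards the attachment distribution. The pairing is
#' crossed: fibers recruited first (`dist$min`) carry the largest stretch and
#' are compared against `att$max`, and so on. Each quantile is updated by
#' `d(rec^q)/dt = alpha0 * (lambda4c^p - att^p) / att^p` where `(q, p)` runs
#' over (min, max), (mode, mode), (max, min), evaluated at the loaded
#' configuration (systolic or diastolic) that maximizes the fiber stretch.
#'
#' The raw (unclamped) fiber stretch ratio drives remodelling, so protective
#' fabrics with attachment targets below 1 remodel consistently. Updates that
#' would drive a recruitment stretch below 1 are clamped at 1 with a warning;
#' ordering of the triple is re-enforced after the update.
#'
#' @param dist A [recruitment_distribution()].
#' @param lambda4 Tissue fiber stretch at the configuration maximizing the
#'   fiber stretch over the cardiac cycle.
#' @param att An [attachment_distribution()].
#' @param params A [gnr_params()].
#' @return Updated [recruitment_distribution()].
#' @export
remodel_recruitment <- function(dist, lambda4, att, params) {
  stopifnot(inherits(dist, "recruitment_distribution"),
            inherits(att, "attachment_distribution"),
            inherits(params, "gnr_params"))
  lc <- collagen_fiber_stretch(lambda4, dist, clamp = FALSE)
  step <- params$alpha0 * params$dt
  new_min  <- dist$min  + step * (lc[["max"]]  - att$max)  / att$max
  new_mode <- dist$mode + step * (lc[["mode"]] - att$mode) / att$mode
  new_max  <- dist$max  + step * (lc[["min"]]  - att$min)  / att$min
  v <- c(new_min, new_mode, new_max)
  if (any(v < 1)) {
    warning("recruitment stretch clamped at 1 during remodelling")
    v <- pmax(v, 1)
  }
  v <- sort(v)  # re-enforce ordering
  recruitment_distribution(v[1], v[2], v[3])
}

#' Collagen mass growth (one explicit Euler step)
#'
#' Fibroblast-mediated growth `dm/dt = epsilon * m * (l4f - l4f_att)/l4f_att`
#' evaluated at systole. The fibroblast natural configuration is identified
#' with that of the collagen fibers of maximal stretch, so `l4f` is the
#' maximum of the collagen fiber stretch distribution and `l4f_att` the
#' maximal attachment stretch.
#'
#' @param m_c Normalized collagen mass(es), `>= 0`.
#' @param lambda4f Fibroblast (= max collagen) fiber stretch at systole.
#' @param att_f Homeostatic fibroblast attachment stretch (`att$max`).
#' @param params A [gnr_params()].
#' @return Updated mass(es).
#' @export
grow_collagen_mass <- function(m_c, lambda4f, att_f, params) {
  stopifnot(inherits(params, "gnr_params"), all(m_c >= 0), att_f > 0)
  m_c * (1 + params$epsilon * params$dt * (lambda4f - att_f) / att_f)
}

#' Attachment-stretch adaptation (discrete stabilization map)
#'
#' Shifts the attachment distribution towards the current collagen fiber
#' stretch statistics: `att^q <- att^q + alpha_att (lambda4c^q - att^q)` for
#' each quantile q. Applied once per growth-and-remodelling step during the
#' stabilization phase; with `alpha_att = 1` the attachment jumps to the
#' current stretches exactly.
#'
#' @param att An [attachment_distribution()].
#' @param fiber_stats Named numeric `c(min, mode, max)` of current collagen
#'   fiber stretches (unclamped), e.g. from [collagen_fiber_stretch()].
#' @param alpha_att Adaptation rate in `[0, 1]`.
#' @return Updated [attachment_distribution()].
#' @export
adapt_attachment <- function(att, fiber_stats, alpha_att = 0.5) {
  stopifnot(inherits(att, "attachment_distribution"),
            alpha_att >= 0, alpha_att <= 1,
            all(c("min", "mode", "max") %in% names(fiber_stats)))
  v <- c(att$min  + alpha_att * (fiber_stats[["min"]]  - att$min),
         att$mode + alpha_att * (fiber_stats[["mode"]] - att$mode),
         att$max  + alpha_att * (fiber_stats[["max"]]  - att$max))
  v <- sort(v)
  attachment_distribution(v[1], v[2], v[3])
}
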