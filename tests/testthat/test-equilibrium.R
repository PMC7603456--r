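# equilibrium tests run on a coarser meridian for speed
eq_cfg <- function(n = 81, H = NULL) {
  cfg <- default_config()
  cfg$geometry$n_points <- n
  if (!is.null(H)) cfg$geometry$sac_height <- H
  cfg
}

test_that("zero pressure leaves the reference configuration unloaded", {
  cfg <- eq_cfg(41)
  st <- init_state(cfg)
  eq <- solve_equilibrium(st$geometry, st$wall, 0)
  expect_equal(eq$lam_t, rep(1, 41), tolerance = 1e-9)
  expect_equal(eq$lam_p, rep(1, 41), tolerance = 1e-9)
  expect_equal(eq$J_m, rep(1, 41), tolerance = 1e-9)
})

test_that("inflated cylinder satisfies the Laplace law with current radius", {
  cfg <- eq_cfg(81, H = 0)
  st <- init_state(cfg)
  P <- 8000
  eq <- solve_equilibrium(st$geometry, st$wall, P)
  i <- 41  # mid-cylinder, away from the ends
  sig_h <- 0
  for (ly in c("media", "adventitia")) {
    w <- st$wall[st$wall$layer == ly & st$wall$point == i, ]
    lr <- if (ly == "media") eq$lamr_m[i] else eq$lamr_a[i]
    lay <- layer_composition(w$m_e, w$m_c, w$m_sm, w$K_e, w$K_c, w$K_sm,
                             w$kappa, layer_tag = ly)
    fibs <- list(
      fiber_family(c(cos(w$ang1), sin(w$ang1), 0),
                   recruitment_distribution(w$rec1_min, w$rec1_mode,
                                            w$rec1_max)),
      fiber_family(c(cos(w$ang2), sin(w$ang2), 0),
                   recruitment_distribution(w$rec2_min, w$rec2_mode,
                                            w$rec2_max)))
    F <- diag(c(eq$lam_t[i], eq$lam_p[i], lr))
    dst <- compute_invariants(F, fibs)
    sig <- cauchy_stress(dst, second_pk_stress(dst, lay, fibs))
    sig_h <- sig_h + sig[1, 1] * lr * w$h
  }
  # hoop stress resultant balances P * r in the current configuration
  expect_equal(sig_h, P / 1e6 * eq$r_cur[i], tolerance = 5e-3)
})

test_that("sphere-like apex satisfies the general curvature Laplace balance", {
  cfg <- eq_cfg(121)
  st <- init_state(cfg)
  P <- 9000
  eq <- solve_equilibrium(st$geometry, st$wall, P)
  ia <- which.max(st$geometry$points$r_ref)
  # current curvatures from the deformed meridian
  R <- eq$r_cur; Z <- eq$z_cur
  h1 <- Z[ia] - Z[ia - 1]; h2 <- Z[ia + 1] - Z[ia]
  rp <- (R[ia + 1] * h1^2 - R[ia - 1] * h2^2 + R[ia] * (h2^2 - h1^2)) /
    (h1 * h2 * (h1 + h2))
  rpp <- 2 * (R[ia - 1] * h2 + R[ia + 1] * h1 - R[ia] * (h1 + h2)) /
    (h1 * h2 * (h1 + h2))
  k1 <- -rpp / (1 + rp^2)^1.5
  k2 <- 1 / (R[ia] * sqrt(1 + rp^2))
  # through-thickness-integrated stresses
  n_t <- 0; n_p <- 0
  for (ly in c("media", "adventitia")) {
    w <- st$wall[st$wall$layer == ly & st$wall$point == ia, ]
    lr <- if (ly == "media") eq$lamr_m[ia] else eq$lamr_a[ia]
    mat <- list(m_e = w$m_e, m_c = w$m_c, m_sm = w$m_sm, K_e = w$K_e,
                K_c = w$K_c, K_sm = w$K_sm, kappa = w$kappa,
                cs1 = cos(w$ang1)^2, cs2 = cos(w$ang2)^2,
                rec1 = matrix(c(w$rec1_min, w$rec1_mode, w$rec1_max), 1),
                rec2 = matrix(c(w$rec2_min, w$rec2_mode, w$rec2_max), 1))
    sig <- fsgr:::vec_cauchy(eq$lam_t[ia], eq$lam_p[ia], lr, mat)
    n_t <- n_t + sig$s1 * lr * w$h
    n_p <- n_p + sig$s2 * lr * w$h
  }
  # sigma_theta kappa_theta + sigma_phi kappa_phi = P / h  (resultant form)
  expect_equal(n_t * k2 + n_p * k1, P / 1e6, tolerance = 0.02)
})

test_that("equilibrium stretches increase monotonically with pressure", {
  cfg <- eq_cfg(61)
  st <- init_state(cfg)
  prev <- NULL
  eq <- NULL
  for (P in c(3000, 6000, 9000)) {
    eq <- solve_equilibrium(st$geometry, st$wall, P, init = eq)
    mid <- eq$lam_t[31]
    if (!is.null(prev)) expect_gt(mid, prev)
    prev <- mid
  }
})

test_that("thick variant keeps |J - 1| within 2 percent; membrane variant is exactly isochoric", {
  cfg <- eq_cfg(61)
  st <- init_state(cfg)
  P <- st$waveform$p_sys
  eq <- solve_equilibrium(st$geometry, st$wall, P, variant = "thick")
  expect_lt(max(abs(c(eq$J_m, eq$J_a) - 1)), 0.02)
  eqm <- solve_equilibrium(st$geometry, st$wall, P, variant = "membrane")
  expect_equal(max(abs(c(eqm$J_m, eqm$J_a) - 1)), 0, tolerance = 1e-12)
})

test_that("protective parent adventitia bears no collagen load at physiological pressure while dome collagen does", {
  cfg <- eq_cfg(81)
  st <- init_state(cfg)
  eq <- solve_equilibrium(st$geometry, st$wall, st$waveform$p_dias)
  i_par <- 8
  w <- st$wall[st$wall$layer == "adventitia" & st$wall$point == i_par, ]
  # parent adventitia: fibers only recruited at supraphysiological pressure
  expect_lt(eq$lam4_a1[i_par], w$rec1_min)
  expect_equal(collagen_dpsi_dI4(
    eq$lam4_a1[i_par],
    recruitment_distribution(w$rec1_min, w$rec1_mode, w$rec1_max),
    w$K_c, w$m_c), 0)
  # dome adventitia: collagen is load-bearing at diastole
  ia <- which.max(st$geometry$points$r_ref)
  wd <- st$wall[st$wall$layer == "adventitia" & st$wall$point == ia, ]
  expect_gt(collagen_dpsi_dI4(
    eq$lam4_a1[ia],
    recruitment_distribution(wd$rec1_min, wd$rec1_mode, wd$rec1_max),
    wd$K_c, wd$m_c), 0)
})

test_that("warm-started solves reproduce the converged field", {
  cfg <- eq_cfg(41)
  st <- init_state(cfg)
  eq1 <- solve_equilibrium(st$geometry, st$wall, 8000)
  eq2 <- solve_equilibrium(st$geometry, st$wall, 8000, init = eq1)
  expect_equal(eq2$lam_t, eq1$lam_t, tolerance = 1e-9)
})
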