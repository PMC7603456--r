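# Axisymmetric membrane equilibrium of the layered wall by total potential
# energy minimization.
#
# The deformed meridian is described by nodal positions (R_i, Z_i) of the
# discretized reference meridian (r_i, z_i). Circumferential stretch at a
# node is lam_t = R/r; meridional stretch is the length ratio of adjacent
# meridian segments (averaged at nodes). The through-thickness stretch of
# each layer follows from a plane-stress condition sigma_rr = 0 under the
# compressible volumetric law ("thick" variant; J deviates slightly from 1)
# or from exact incompressibility ("membrane" variant, J = 1). Equilibrium
# minimizes
#
#   Pi(R, Z) = sum_i W_wall(lam_t_i, lam_p_i) A_i  -  P V(R, Z)
#
# where W_wall is the through-thickness-integrated strain energy per unit
# reference area (sum over layers of W_L h_L), A_i the reference midsurface
# area attached to node i, and V the enclosed volume (pressure follower
# load). The ends of the meridian are pinned (the cut parent artery is held
# at its reference radius). The stationarity conditions reproduce the
# membrane Laplace balance: for a uniform cylinder sigma_theta h = P r, for
# a spherical cap sigma h = P r / 2.
#
# Because sigma_rr = 0 at the plane-stress solution, the envelope theorem
# gives the in-plane nodal forces directly from the Cauchy stresses:
# dW/dlam_t = J sigma_theta / lam_t and dW/dlam_p = J sigma_phi / lam_p
# (1st Piola-Kirchhoff stresses). The same expressions hold for the
# incompressible variant with sigma replaced by its deviator relative to
# sigma_rr.

# scalar fast path of collagen_dpsi_dI4 (no class checks) ------------------
dpsi4_scalar <- function(lam4, a, b, cc, K, m) {
  if (lam4 <= a || m == 0) return(0)
  if ((cc - a) < 1e-12) {            # degenerate: single recruitment stretch
    return(m * (K / 2) * (1 / a^2 - 1 / (a * lam4)))
  }
  x <- min(lam4, cc)
  if (b > a) {
    a1 <- 2 / ((cc - a) * (b - a))
    x1 <- min(x, b)
    A <- a1 * (log(x1 / a) + a / x1 - 1)
    B <- a1 * ((x1 - a) - a * log(x1 / a))
  } else {
    A <- 0; B <- 0
  }
  if (cc > b && x > b) {
    a2 <- 2 / ((cc - a) * (cc - b))
    A <- A + a2 * (cc * (1 / b - 1 / x) - log(x / b))
    B <- B + a2 * (cc * log(x / b) - (x - b))
  }
  m * (K / 2) * (A - B / lam4)
}

# scalar fast path of the collagen ensemble energy
cenergy_scalar <- function(lam4, a, b, cc, K, m) {
  if (lam4 <= a || m == 0) return(0)
  if ((cc - a) < 1e-12) {
    lc <- lam4 / a
    return(m * (K / 2) * (lc - 1)^2)
  }
  x <- min(lam4, cc)
  A <- 0; B <- 0; M <- 0
  if (b > a) {
    a1 <- 2 / ((cc - a) * (b - a))
    x1 <- min(x, b)
    A <- a1 * (log(x1 / a) + a / x1 - 1)
    B <- a1 * ((x1 - a) - a * log(x1 / a))
    M <- a1 * (x1 - a)^2 / 2
  }
  if (cc > b && x > b) {
    a2 <- 2 / ((cc - a) * (cc - b))
    A <- A + a2 * (cc * (1 / b - 1 / x) - log(x / b))
    B <- B + a2 * (cc * log(x / b) - (x - b))
    M <- M + a2 * (cc * (x - b) - (x^2 - b^2) / 2)
  }
  m * (K / 2) * (lam4^2 * A - 2 * lam4 * B + M)
}

# diagonal Cauchy stress in the local frame, plain-numeric hot path --------
# lay: list(m_e, m_c, m_sm, K_e, K_c, K_sm, kappa)
# ang: angles of the two families (rad); rec: 2x3 matrix (min, mode, max)
cauchy_local_fast <- function(lam_t, lam_p, lam_r, lay, ang, rec) {
  C1 <- lam_t * lam_t; C2 <- lam_p * lam_p; C3 <- lam_r * lam_r
  I3 <- C1 * C2 * C3
  J <- sqrt(I3)
  I1 <- C1 + C2 + C3
  Jm23 <- I3^(-1 / 3)
  psi1 <- lay$m_e * lay$K_e + lay$m_sm * lay$K_sm
  d1 <- psi1 * Jm23 * (C1 - I1 / 3)
  d2 <- psi1 * Jm23 * (C2 - I1 / 3)
  d3 <- psi1 * Jm23 * (C3 - I1 / 3)
  for (k in 1:2) {
    cs <- cos(ang[k])^2; sn <- 1 - cs
    I4raw <- C1 * cs + C2 * sn
    lam4 <- sqrt(Jm23 * I4raw)
    psi4 <- dpsi4_scalar(lam4, rec[k, 1], rec[k, 2], rec[k, 3],
                         lay$K_c, lay$m_c)
    if (psi4 != 0) {
      d1 <- d1 + psi4 * Jm23 * (C1 * cs - I4raw / 3)
      d2 <- d2 + psi4 * Jm23 * (C2 * sn - I4raw / 3)
      d3 <- d3 + psi4 * Jm23 * (-I4raw / 3)
    }
  }
  pvol <- lay$kappa / 4 * (1 - 1 / I3) * I3
  (2 / J) * c(d1 + pvol, d2 + pvol, d3 + pvol)
}

# --- vectorized layer response over all meridian nodes -------------------
# mat: list of per-node parameter vectors for one layer: m_e, m_c, m_sm,
# K_e, K_c, K_sm, kappa, h, cs1, cs2 (squared cosines of the two family
# angles) and rec1, rec2 (n x 3 recruitment matrices)

vec_dpsi4 <- function(lam4, rec, K, m) {
  a <- rec[, 1]; b <- rec[, 2]; cc <- rec[, 3]
  out <- numeric(length(lam4))
  act <- lam4 > a & m > 0
  if (!any(act)) return(out)
  deg <- act & (cc - a) < 1e-12
  gen <- act & !deg
  if (any(deg)) {
    out[deg] <- m[deg] * (K[deg] / 2) *
      (1 / a[deg]^2 - 1 / (a[deg] * lam4[deg]))
  }
  if (any(gen)) {
    ag <- a[gen]; bg <- b[gen]; cg <- cc[gen]; lg <- lam4[gen]
    x <- pmin(lg, cg)
    d1 <- (cg - ag) * (bg - ag)
    a1 <- ifelse(d1 > 0, 2 / d1, 0)
    x1 <- pmin(x, bg)
    A <- a1 * (log(x1 / ag) + ag / x1 - 1)
    B <- a1 * ((x1 - ag) - ag * log(x1 / ag))
    fall <- cg > bg & x > bg
    if (any(fall)) {
      a2 <- 2 / ((cg[fall] - ag[fall]) * (cg[fall] - bg[fall]))
      xf <- x[fall]; bf <- bg[fall]; cf <- cg[fall]
      A[fall] <- A[fall] + a2 * (cf * (1 / bf - 1 / xf) - log(xf / bf))
      B[fall] <- B[fall] + a2 * (cf * log(xf / bf) - (xf - bf))
    }
    out[gen] <- m[gen] * (K[gen] / 2) * (A - B / lg)
  }
  out
}

vec_cenergy <- function(lam4, rec, K, m) {
  a <- rec[, 1]; b <- rec[, 2]; cc <- rec[, 3]
  out <- numeric(length(lam4))
  act <- lam4 > a & m > 0
  if (!any(act)) return(out)
  deg <- act & (cc - a) < 1e-12
  gen <- act & !deg
  if (any(deg)) {
    lc <- lam4[deg] / a[deg]
    out[deg] <- m[deg] * (K[deg] / 2) * (lc - 1)^2
  }
  if (any(gen)) {
    ag <- a[gen]; bg <- b[gen]; cg <- cc[gen]; lg <- lam4[gen]
    x <- pmin(lg, cg)
    d1 <- (cg - ag) * (bg - ag)
    a1 <- ifelse(d1 > 0, 2 / d1, 0)
    x1 <- pmin(x, bg)
    A <- a1 * (log(x1 / ag) + ag / x1 - 1)
    B <- a1 * ((x1 - ag) - ag * log(x1 / ag))
    M <- a1 * (x1 - ag)^2 / 2
    fall <- cg > bg & x > bg
    if (any(fall)) {
      a2 <- 2 / ((cg[fall] - ag[fall]) * (cg[fall] - bg[fall]))
      xf <- x[fall]; bf <- bg[fall]; cf <- cg[fall]
      A[fall] <- A[fall] + a2 * (cf * (1 / bf - 1 / xf) - log(xf / bf))
      B[fall] <- B[fall] + a2 * (cf * log(xf / bf) - (xf - bf))
      M[fall] <- M[fall] + a2 * (cf * (xf - bf) - (xf^2 - bf^2) / 2)
    }
    out[gen] <- m[gen] * (K[gen] / 2) * (lg^2 * A - 2 * lg * B + M)
  }
  out
}

vec_cauchy <- function(lam_t, lam_p, lam_r, mat) {
  C1 <- lam_t^2; C2 <- lam_p^2; C3 <- lam_r^2
  I3 <- C1 * C2 * C3
  J <- sqrt(I3)
  I1 <- C1 + C2 + C3
  Jm23 <- I3^(-1 / 3)
  psi1 <- mat$m_e * mat$K_e + mat$m_sm * mat$K_sm
  d1 <- psi1 * Jm23 * (C1 - I1 / 3)
  d2 <- psi1 * Jm23 * (C2 - I1 / 3)
  d3 <- psi1 * Jm23 * (C3 - I1 / 3)
  for (k in 1:2) {
    cs <- mat[[paste0("cs", k)]]
    I4raw <- C1 * cs + C2 * (1 - cs)
    lam4 <- sqrt(Jm23 * I4raw)
    psi4 <- vec_dpsi4(lam4, mat[[paste0("rec", k)]], mat$K_c, mat$m_c)
    d1 <- d1 + psi4 * Jm23 * (C1 * cs - I4raw / 3)
    d2 <- d2 + psi4 * Jm23 * (C2 * (1 - cs) - I4raw / 3)
    d3 <- d3 + psi4 * Jm23 * (-I4raw / 3)
  }
  pvol <- mat$kappa / 4 * (1 - 1 / I3) * I3
  list(s1 = (2 / J) * (d1 + pvol), s2 = (2 / J) * (d2 + pvol),
       s3 = (2 / J) * (d3 + pvol), J = J)
}

vec_energy <- function(lam_t, lam_p, lam_r, mat) {
  C1 <- lam_t^2; C2 <- lam_p^2; C3 <- lam_r^2
  I3 <- C1 * C2 * C3
  Jm23 <- I3^(-1 / 3)
  psi1 <- mat$m_e * mat$K_e + mat$m_sm * mat$K_sm
  w <- psi1 * (Jm23 * (C1 + C2 + C3) - 3)
  for (k in 1:2) {
    cs <- mat[[paste0("cs", k)]]
    lam4 <- sqrt(Jm23 * (C1 * cs + C2 * (1 - cs)))
    w <- w + vec_cenergy(lam4, mat[[paste0("rec", k)]], mat$K_c, mat$m_c)
  }
  w + mat$kappa / 4 * (I3 - 1 - log(I3))
}

# vectorized plane-stress solve: sigma_rr = 0 for lam_r at every node
vec_solve_lamr <- function(lam_t, lam_p, mat, start) {
  lr <- start
  for (it in 1:60) {
    f <- vec_cauchy(lam_t, lam_p, lr, mat)$s3
    if (all(abs(f) < 1e-11 * mat$kappa)) return(lr)
    h <- 1e-6 * lr
    fp <- vec_cauchy(lam_t, lam_p, lr + h, mat)$s3
    df <- (fp - f) / h
    lr <- pmax(lr - f / df, 0.2 * lr)
  }
  stop("through-thickness plane-stress iteration failed to converge")
}

#' Build the spatial wall state from geometry and configuration
#'
#' Assembles the per-point, per-layer material description: parent and dome
#' parameter sets blended linearly across the neck, fiber family angles, and
#' the initial recruitment and attachment triples for both families.
#'
#' @param geometry An [build_geometry()] result.
#' @param config An `fsg_config`.
#' @return Data frame of class `wall_state`, one row per (point, layer).
#' @export
build_wall_state <- function(geometry, config = default_config()) {
  stopifnot(inherits(geometry, "ideal_geometry"))
  pts <- geometry$points
  ang <- assign_fiber_orientations(geometry, config$fiber_angles)
  rows <- lapply(c("media", "adventitia"), function(ly) {
    pp <- config$material$parent[[ly]]
    dp <- config$material$dome[[ly]]
    u <- pts$u
    lin <- function(field, j = NULL) {
      a <- if (is.null(j)) pp[[field]] else pp[[field]][j]
      b <- if (is.null(j)) dp[[field]] else dp[[field]][j]
      (1 - u) * a + u * b
    }
    K_c <- lin("K_c")
    kap_p <- if (is.null(pp$kappa)) 100 * pp$K_c else pp$kappa
    kap_d <- if (is.null(dp$kappa)) 100 * dp$K_c else dp$kappa
    aa <- ang[ang$layer == ly, ]
    df <- data.frame(
      point = seq_len(nrow(pts)), layer = ly, region = pts$region, u = u,
      m_e = lin("m_e"), m_c = lin("m_c"), m_sm = lin("m_sm"),
      K_e = lin("K_e"), K_c = K_c, K_sm = lin("K_sm"),
      kappa = (1 - u) * kap_p + u * kap_d,
      alpha0 = lin("alpha0"), epsilon = lin("epsilon"),
      h = if (ly == "media") geometry$h_media else geometry$h_adv,
      ang1 = aa$ang1, ang2 = aa$ang2)
    for (fam in 1:2) {
      for (j in 1:3) {
        q <- c("min", "mode", "max")[j]
        df[[paste0("rec", fam, "_", q)]] <- lin("rec", j)
        df[[paste0("att", fam, "_", q)]] <- lin("att", j)
      }
    }
    df
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("wall_state", "data.frame")
  out
}

# per-layer node-parameter tables for the vectorized response
layer_table <- function(wall, layer) {
  d <- wall[wall$layer == layer, ]
  d <- d[order(d$point), ]
  list(m_e = d$m_e, m_c = d$m_c, m_sm = d$m_sm,
       K_e = d$K_e, K_c = d$K_c, K_sm = d$K_sm, kappa = d$kappa,
       h = d$h, cs1 = cos(d$ang1)^2, cs2 = cos(d$ang2)^2,
       rec1 = cbind(d$rec1_min, d$rec1_mode, d$rec1_max),
       rec2 = cbind(d$rec2_min, d$rec2_mode, d$rec2_max))
}

# membrane model context: everything fixed during one equilibrium solve
membrane_model <- function(geometry, wall, variant, bending_scale = 1) {
  pts <- geometry$points
  n <- nrow(pts)
  dz <- diff(pts$z); dr <- diff(pts$r_ref)
  L_ref <- sqrt(dz^2 + dr^2)
  # reference midsurface area attached to each node (trapezoidal lumping)
  ell <- c(L_ref[1] / 2, (L_ref[-1] + L_ref[-(n - 1)]) / 2,
           L_ref[n - 1] / 2)
  A <- 2 * pi * pts$r_ref * ell
  mats <- list(layer_table(wall, "media"), layer_table(wall, "adventitia"))
  # meridional bending rigidity per layer, D = E_eff h^3 / 12, with the
  # small-strain effective modulus of the composite (neo-Hookean part
  # E = 6 c; collagen tangent taken at order K_c). The wall is thick
  # relative to its radius, so the shell carries a bending boundary layer
  # that a pure membrane lacks; this term regularizes locally degraded
  # zones exactly as the physical wall does.
  D <- numeric(n)
  for (mat in mats) {
    E_eff <- 6 * (mat$m_e * mat$K_e + mat$m_sm * mat$K_sm) +
      mat$m_c * mat$K_c
    D <- D + bending_scale * E_eff * mat$h^3 / 12
  }
  phi_ref <- atan2(dr, dz)
  cache <- new.env(parent = emptyenv())
  cache$lamr <- matrix(1, n, 2)
  list(n = n, r_ref = pts$r_ref, z_ref = pts$z, L_ref = L_ref, A = A,
       ell = ell, D = D, phi_ref = phi_ref,
       mats = mats, variant = variant, cache = cache)
}

# discrete meridional bending energy and its gradient: curvature change is
# the turning-angle increment between adjacent segments relative to the
# reference profile, per unit reference arc length
bending_energy_grad <- function(mod, dR, dZ, L_cur, gradient = TRUE) {
  n <- mod$n
  phi <- atan2(dR, dZ)                 # segment angles, length n - 1
  dphi <- diff(phi) - diff(mod$phi_ref)
  dphi <- atan2(sin(dphi), cos(dphi))  # wrap to (-pi, pi]
  kap <- dphi / mod$ell[2:(n - 1)]     # curvature change at interior nodes
  Dv <- mod$D[2:(n - 1)]
  Av <- mod$A[2:(n - 1)]
  val <- sum(Dv * kap^2 * Av) / 2
  if (!gradient) return(list(value = val))
  gk <- c(0, Dv * kap * Av / mod$ell[2:(n - 1)], 0)  # per node, length n
  cb <- gk[1:(n - 1)] - gk[2:n]        # per segment: dE/dphi_j
  wR <- cb * dZ / L_cur^2
  wZ <- cb * dR / L_cur^2
  gR <- c(0, wR) - c(wR, 0)            # node i: +wR_{i-1} - wR_i
  gZ <- c(wZ, 0) - c(0, wZ)            # node i: -wZ_{i-1} + wZ_i
  list(value = val, gR = gR, gZ = gZ)
}

# nodal stretches from nodal positions
nodal_stretches <- function(mod, R, Z) {
  n <- mod$n
  dR <- diff(R); dZ <- diff(Z)
  L_cur <- sqrt(dR^2 + dZ^2)
  lam_el <- L_cur / mod$L_ref
  lam_p <- c(lam_el[1], (lam_el[-1] + lam_el[-(n - 1)]) / 2,
             lam_el[n - 1])
  list(lam_t = R / mod$r_ref, lam_p = lam_p, lam_el = lam_el,
       L_cur = L_cur, dR = dR, dZ = dZ)
}

# per-node wall quantities at given stretches: energy density (per reference
# area), 1st PK nodal forces dW/dlam_t, dW/dlam_p, and per-layer lam_r / J;
# fully vectorized over nodes. The lam_r warm-start cache lives in
# mod$cache.
wall_response <- function(mod, lam_t, lam_p, need_energy = TRUE) {
  n <- mod$n
  W <- numeric(n); Ft <- numeric(n); Fp <- numeric(n)
  lamr <- mod$cache$lamr
  J <- matrix(0, n, 2)
  for (j in 1:2) {
    mat <- mod$mats[[j]]
    if (mod$variant == "thick") {
      lr <- vec_solve_lamr(lam_t, lam_p, mat, lamr[, j])
    } else {
      lr <- 1 / (lam_t * lam_p)
    }
    lamr[, j] <- lr
    Jl <- lam_t * lam_p * lr
    J[, j] <- Jl
    sig <- vec_cauchy(lam_t, lam_p, lr, mat)
    if (mod$variant == "thick") {
      # plane stress: sigma_rr = 0, envelope theorem
      Ft <- Ft + mat$h * Jl * sig$s1 / lam_t
      Fp <- Fp + mat$h * Jl * sig$s2 / lam_p
    } else {
      # incompressible: constrained derivative removes sigma_rr
      Ft <- Ft + mat$h * (sig$s1 - sig$s3) / lam_t
      Fp <- Fp + mat$h * (sig$s2 - sig$s3) / lam_p
    }
    if (need_energy) {
      W <- W + mat$h * vec_energy(lam_t, lam_p, lr, mat)
    }
  }
  mod$cache$lamr <- lamr
  list(W = W, Ft = Ft, Fp = Fp, lamr = lamr, J = J)
}

# circumferential stretch of a free axially-tethered uniform cylinder with
# the composition of node i: solves sigma_theta h_cur = P lam R for lam
cylinder_stretch <- function(mod, i, P) {
  if (P <= 0) return(1)
  mats_i <- lapply(mod$mats, function(mat) {
    lapply(mat, function(v) if (is.matrix(v)) v[i, , drop = FALSE] else v[i])
  })
  f <- function(lam) {
    nth <- 0
    for (mat in mats_i) {
      lr <- if (mod$variant == "thick") {
        vec_solve_lamr(lam, 1, mat, 1 / lam)
      } else {
        1 / lam
      }
      sig <- vec_cauchy(lam, 1, lr, mat)
      nth <- nth + (sig$s1 - sig$s3) * lr * mat$h
    }
    nth - P * lam * mod$r_ref[i]
  }
  stats::uniroot(f, c(1, 3), extendInt = "upX", tol = 1e-12)$root
}

# enclosed volume of the solid of revolution bounded by the meridian
enclosed_volume <- function(R, Z) {
  n <- length(R)
  Rm <- (R[-1] + R[-n]) / 2
  sum(pi * Rm^2 * diff(Z))
}

# total potential energy and its gradient wrt the free nodal dofs
membrane_energy_grad <- function(mod, x, P, free_idx, R0, Z0,
                                 gradient = TRUE) {
  n <- mod$n
  R <- R0; Z <- Z0
  R[free_idx] <- x[seq_along(free_idx)]
  Z[free_idx] <- x[seq_along(free_idx) + length(free_idx)]
  st <- nodal_stretches(mod, R, Z)
  if (any(!is.finite(st$lam_t)) || any(st$lam_t <= 0) ||
      any(st$lam_el <= 0)) {
    return(list(value = Inf))
  }
  wr <- wall_response(mod, st$lam_t, st$lam_p, need_energy = TRUE)
  V <- enclosed_volume(R, Z)
  bend <- bending_energy_grad(mod, st$dR, st$dZ, st$L_cur, gradient)
  val <- sum(wr$W * mod$A) - P * V + bend$value
  if (!gradient) return(list(value = val, st = st, wr = wr))
  # strain-energy part
  gR <- wr$Ft * mod$A / mod$r_ref
  gZ <- numeric(n)
  # meridional part: element stretch lam_el_j feeds nodes j and j+1
  FpA <- wr$Fp * mod$A
  Gel <- numeric(n - 1)
  Gel[1] <- FpA[1] + FpA[2] / 2
  if (n > 3) {
    Gel[2:(n - 2)] <- (FpA[2:(n - 2)] + FpA[3:(n - 1)]) / 2
  }
  Gel[n - 1] <- FpA[n - 1] / 2 + FpA[n]
  dldR <- st$dR / (st$L_cur * mod$L_ref)   # dlam_el/dR_{j+1} = +, dR_j = -
  dldZ <- st$dZ / (st$L_cur * mod$L_ref)
  gR <- gR + c(0, Gel * dldR) - c(Gel * dldR, 0)
  gZ <- gZ + c(0, Gel * dldZ) - c(Gel * dldZ, 0)
  # pressure-volume part
  Rm <- (R[-1] + R[-n]) / 2
  dZel <- diff(Z)
  dVdR <- pi * (c(0, Rm * dZel) + c(Rm * dZel, 0))
  dVdZ <- pi * (c(0, Rm^2) - c(Rm^2, 0))
  gR <- gR - P * dVdR + bend$gR
  gZ <- gZ - P * dVdZ + bend$gZ
  list(value = val,
       grad = c(gR[free_idx], gZ[free_idx]),
       st = st, wr = wr)
}

#' Quasi-static equilibrium of the idealized wall at a given pressure
#'
#' Solves the axisymmetric membrane boundary-value problem by minimizing the
#' total potential energy (through-thickness-integrated strain energy of both
#' layers minus the pressure-volume work of the follower load) over the nodal
#' positions of the deformed meridian, using a damped Newton iteration with
#' an analytic gradient and a colored finite-difference Hessian. The meridian
#' ends (cut parent artery) are pinned at their reference position. The
#' stationarity conditions are the membrane (Laplace) equilibrium equations:
#' a uniform cylinder satisfies `sigma_theta h = P r` and a spherical cap
#' `sigma h = P r / 2` in the current configuration.
#'
#' @param geometry An [build_geometry()] result.
#' @param wall A [build_wall_state()] data frame (possibly evolved).
#' @param pressure Transmural pressure in Pa (`>= 0`).
#' @param init Optional previous `equilibrium_field` for a warm start.
#' @param variant `"thick"` (plane-stress compressible through-thickness
#'   response; J deviates slightly from 1) or `"membrane"` (exact
#'   incompressibility, J = 1).
#' @param tol Relative out-of-balance force tolerance (default 1e-8).
#' @param max_iter Newton iteration cap.
#' @return Data frame of class `equilibrium_field`, one row per point:
#'   stretches `lam_t`, `lam_p`, per-layer through-thickness stretches and
#'   Jacobians, current radius `r_cur` and axial position `z_cur` (mm),
#'   modified fiber stretches per layer and family (`lam4_m1`, `lam4_m2`,
#'   `lam4_a1`, `lam4_a2`), the relative residual and the pressure.
#' @export
solve_equilibrium <- function(geometry, wall, pressure, init = NULL,
                              variant = c("thick", "membrane"),
                              tol = 1e-8, max_iter = 200,
                              bending_scale = 1) {
  stopifnot(inherits(geometry, "ideal_geometry"), pressure >= 0)
  variant <- match.arg(variant)
  P <- pressure / 1e6            # Pa -> MPa; lengths in mm
  mod <- membrane_model(geometry, wall, variant, bending_scale)
  n <- mod$n
  free_idx <- 2:(n - 1)
  R0 <- mod$r_ref; Z0 <- mod$z_ref
  # far-field boundary condition: the cut parent artery is held at the
  # radius of the free axially-tethered cylinder (lam_p = 1) under the same
  # pressure, so the artificial clamp carries no boundary layer
  for (iend in c(1, n)) {
    lam_end <- cylinder_stretch(mod, iend, P)
    R0[iend] <- lam_end * mod$r_ref[iend]
  }
  x <- if (!is.null(init)) {
    c(init$r_cur[free_idx], init$z_cur[free_idx])
  } else {
    c(R0[free_idx], Z0[free_idx])
  }
  # force scale for the relative convergence test: applied load per node,
  # floored at a material scale so the unloaded problem is well-posed
  P_flr <- max(P, 1e-4)
  fscale <- P_flr * mod$A[free_idx]
  fscale <- c(fscale, fscale)
  newton <- function(x, P, max_iter) {
    eg <- membrane_energy_grad(mod, x, P, free_idx, R0, Z0)
    if (!is.finite(eg$value)) stop("invalid starting configuration")
    for (it in seq_len(max_iter)) {
      res <- max(abs(eg$grad) / fscale)
      if (res < tol) return(list(x = x, res = res, converged = TRUE,
                                 eg = eg))
      H <- matrix(0, length(x), length(x))
      m <- length(free_idx)
      hstep <- 1e-6 * max(mean(abs(x)), 1)
      for (coord in 0:1) {
        for (col in 1:5) {
          dofs <- seq(col, m, by = 5) + coord * m
          xp <- x; xp[dofs] <- xp[dofs] + hstep
          egp <- membrane_energy_grad(mod, xp, P, free_idx, R0, Z0)
          dg <- (egp$grad - eg$grad) / hstep
          for (d in dofs) {
            node <- ((d - 1) %% m) + 1
            rows <- outer(max(1, node - 2):min(m, node + 2), c(0, m), "+")
            H[rows, d] <- dg[rows]
          }
        }
      }
      dx <- tryCatch(solve(H, -eg$grad), error = function(e) NULL)
      if (is.null(dx) || any(!is.finite(dx))) {
        dx <- -eg$grad / max(abs(eg$grad)) * 0.01 * max(abs(x))
      }
      # damped line search on the energy (fall back to gradient-norm
      # decrease, since the saddle-free path may pass energy plateaus)
      lam <- 1
      repeat {
        xn <- x + lam * dx
        egn <- membrane_energy_grad(mod, xn, P, free_idx, R0, Z0)
        ok <- is.finite(egn$value) &&
          (egn$value <= eg$value + 1e-12 * abs(eg$value) ||
           max(abs(egn$grad) / fscale) < res)
        if (ok || lam < 1 / 1024) break
        lam <- lam / 2
      }
      if (!is.finite(egn$value)) {
        return(list(x = x, res = res, converged = FALSE, eg = eg))
      }
      x <- xn; eg <- egn
    }
    list(x = x, res = max(abs(eg$grad) / fscale), converged = FALSE,
         eg = eg)
  }
  sol <- newton(x, P, max_iter)
  if (!sol$converged) {
    # pressure continuation from the reference configuration
    x <- c(R0[free_idx], Z0[free_idx])
    mod$cache$lamr <- matrix(1, n, 2)
    for (fr in seq(0.1, 1, by = 0.1)) {
      sol <- newton(x, P * fr, max_iter)
      if (!sol$converged) break
      x <- sol$x
    }
  }
  if (!sol$converged) {
    stop(sprintf(paste0("no membrane equilibrium found at pressure %.1f Pa ",
                        "(possible limit point); residual %.3g"),
                 pressure, sol$res))
  }
  R <- R0; Z <- Z0
  m <- length(free_idx)
  R[free_idx] <- sol$x[1:m]
  Z[free_idx] <- sol$x[(m + 1):(2 * m)]
  st <- sol$eg$st
  wr <- sol$eg$wr
  out <- data.frame(point = seq_len(n), lam_t = st$lam_t, lam_p = st$lam_p,
                    lamr_m = wr$lamr[, 1], lamr_a = wr$lamr[, 2],
                    J_m = wr$J[, 1], J_a = wr$J[, 2],
                    r_cur = R, z_cur = Z,
                    lam4_m1 = NA_real_, lam4_m2 = NA_real_,
                    lam4_a1 = NA_real_, lam4_a2 = NA_real_,
                    residual = sol$res)
  for (j in 1:2) {
    mat <- mod$mats[[j]]
    for (k in 1:2) {
      cs <- mat[[paste0("cs", k)]]
      lam4raw <- sqrt(st$lam_t^2 * cs + st$lam_p^2 * (1 - cs))
      col <- paste0("lam4_", c("m", "a")[j], k)
      out[[col]] <- wr$J[, j]^(-1 / 3) * lam4raw
    }
  }
  out$pressure <- pressure
  attr(out, "variant") <- variant
  class(out) <- c("equilibrium_field", "data.frame")
  out
}
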