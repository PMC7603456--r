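dist <- recruitment_distribution(1.18, 1.24, 1.3)

test_that("triangular density has the right shape and normalization", {
  expect_equal(triangular_pdf(dist$min, dist), 0)
  expect_equal(triangular_pdf(dist$max, dist), 0)
  expect_equal(triangular_pdf(1.1, dist), 0)
  expect_equal(triangular_pdf(1.4, dist), 0)
  expect_equal(triangular_pdf(dist$mode, dist), 2 / (dist$max - dist$min))
  total <- stats::integrate(function(s) triangular_pdf(s, dist),
                            dist$min, dist$max)$value
  expect_equal(total, 1, tolerance = 1e-8)
})

test_that("degenerate distribution is flagged as a point mass", {
  d0 <- recruitment_distribution(1.2, 1.2, 1.2)
  val <- triangular_pdf(c(1.2, 1.3), d0)
  expect_true(attr(val, "point_mass"))
  expect_equal(as.numeric(val), c(Inf, 0))
})

test_that("ordering violations are rejected", {
  expect_error(recruitment_distribution(1.3, 1.2, 1.4), "min <= mode")
  expect_error(recruitment_distribution(0.9, 1.0, 1.1), ">= 1")
  expect_error(attachment_distribution(1.1, 1.0, 1.2), "min <= mode")
})

test_that("analytic dPsi/dI4 matches adaptive quadrature on all branches", {
  dists <- list(dist,
                recruitment_distribution(1.01, 1.05, 1.1),
                recruitment_distribution(1.0, 1.0, 1.2),   # mode at min
                recruitment_distribution(1.1, 1.3, 1.3))   # mode at max
  for (d in dists) {
    grid <- c(d$min - 0.05, d$min + 1e-4,
              (d$min + d$mode) / 2, d$mode,
              (d$mode + d$max) / 2, d$max, d$max + 0.1, 2.0)
    grid <- grid[grid > 0]
    for (l4 in grid) {
      got <- collagen_dpsi_dI4(l4, d, K_c = 1.0, m_c = 0.7)
      want <- quad_dpsi_dI4(l4, d, K_c = 1.0, m_c = 0.7)
      # relative 1e-8, floored by the quadrature's absolute accuracy
      expect_lt(abs(got - want), 1e-8 * abs(want) + 1e-12)
    }
  }
})

test_that("ensemble energy matches quadrature and is C1 across branches", {
  for (l4 in c(1.2, 1.27, 1.5)) {
    got <- collagen_strain_energy(l4, dist)
    want <- quad_energy(l4, dist)
    expect_lt(abs(got - want), 1e-8 * abs(want) + 1e-12)
  }
  # C1 continuity at the three branch boundaries (finite differences)
  h <- 1e-7
  for (b in c(dist$min, dist$mode, dist$max)) {
    below <- (collagen_strain_energy(b, dist) -
              collagen_strain_energy(b - h, dist)) / h
    above <- (collagen_strain_energy(b + h, dist) -
              collagen_strain_energy(b, dist)) / h
    # one-sided differences carry O(h) truncation error; a derivative jump
    # would show up at O(1)
    expect_equal(below, above, tolerance = 1e-3)
  }
})

test_that("ensemble first PK stress is zero below recruitment, affine beyond full recruitment, and monotone", {
  expect_equal(collagen_dpsi_dI4(1.0, dist), 0)
  expect_equal(collagen_dpsi_dI4(dist$min, dist), 0)
  # 1st PK of the ensemble: P(lam4) = 2 lam4 dPsi/dI4
  pk <- function(l4) 2 * l4 * collagen_dpsi_dI4(l4, dist)
  lams <- seq(dist$max + 0.01, 2, length.out = 9)
  p <- vapply(lams, pk, numeric(1))
  expect_lt(max(abs(diff(diff(p)))), 1e-10)   # affine: zero second difference
  lams_all <- seq(1, 2, length.out = 200)
  p_all <- vapply(lams_all, pk, numeric(1))
  expect_true(all(diff(p_all) >= -1e-12))     # monotone non-decreasing
})

test_that("degenerate recruitment uses the single-fiber analytic branch", {
  d0 <- recruitment_distribution(1.2, 1.2, 1.2)
  l4 <- 1.4
  # Heaviside recruitment: dPsi/dI4 = K/2 (1/a^2 - 1/(a lam4))
  expect_equal(collagen_dpsi_dI4(l4, d0, K_c = 2),
               (2 / 2) * (1 / 1.2^2 - 1 / (1.2 * 1.4)))
  expect_equal(collagen_dpsi_dI4(1.1, d0), 0)
})

test_that("fiber stretch statistics pair crosswise and clamp at one", {
  expect_equal(collagen_fiber_stretch(dist$mode, dist)[["mode"]], 1)
  expect_equal(unname(collagen_fiber_stretch(1.1, dist)), c(1, 1, 1))
  got <- collagen_fiber_stretch(1.3, recruitment_distribution(1.18, 1.24, 1.3))
  expect_equal(unname(got), c(1.0, 1.3 / 1.24, 1.3 / 1.18), tolerance = 1e-4)
  raw <- collagen_fiber_stretch(1.1, dist, clamp = FALSE)
  expect_equal(unname(raw), 1.1 / c(1.3, 1.24, 1.18))
})
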