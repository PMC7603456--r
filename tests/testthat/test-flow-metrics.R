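test_that("wss_vector removes the normal traction component", {
  # pure pressure: no shear
  expect_equal(wss_vector(-3 * diag(3), c(0, 0, 1)), c(0, 0, 0))
  # single shear entry sigma_13 = s with normal e3 -> s e1
  sig <- matrix(0, 3, 3); sig[1, 3] <- 5; sig[3, 1] <- 5
  expect_equal(wss_vector(sig, c(0, 0, 1)), c(5, 0, 0))
  # projection identity for random tensors
  set.seed(4)
  for (rep in 1:5) {
    sig <- matrix(rnorm(9), 3, 3)
    nrm <- rnorm(3); nrm <- nrm / sqrt(sum(nrm^2))
    expect_equal(drop(wss_vector(sig, nrm) %*% nrm), 0, tolerance = 1e-12)
  }
  expect_error(wss_vector(diag(3), c(1, 1, 0)), "unit")
})

test_that("principal directions recover the dominant shear axis", {
  s <- make_rosette(ratio = 0, mode = "fixed", base_angle = 0)
  pd <- principal_directions(s)
  expect_equal(abs(drop(pd$eta1 %*% c(1, 0, 0))), 1, tolerance = 1e-6)
  # alternating direction with positive mean
  s2 <- make_rosette(ratio = 0, mode = "alternating", bias = 0.2)
  pd2 <- principal_directions(s2)
  expect_equal(drop(pd2$eta1 %*% c(1, 0, 0)), 1, tolerance = 1e-2)
  # rotating constant magnitude: integral vanishes for every angle
  s3 <- make_rosette(ratio = 1, mode = "rotating")
  expect_true(principal_directions(s3)$isotropic)
  # all-zero series
  s0 <- wss_series(c(0, 1), matrix(0, 2, 3), c(0, 0, 1))
  expect_true(principal_directions(s0)$degenerate)
})

test_that("coarse angle sweep agrees with a 10x finer sweep", {
  s <- make_rosette(ratio = 0.4, mode = "fixed", base_angle = 37.3)
  c1 <- principal_directions(s, resolution_deg = 0.5)
  c2 <- principal_directions(s, resolution_deg = 0.05)
  ang <- acos(pmin(1, abs(drop(c1$eta1 %*% c2$eta1))))
  expect_lt(ang, 0.5 * pi / 180)
})

test_that("WSSAR limit cases are exact", {
  expect_equal(as.numeric(wssar(make_rosette(ratio = 0, mode = "fixed"))), 0)
  expect_equal(as.numeric(wssar(make_rosette(ratio = 1, mode = "rotating"))),
               1)
})

test_that("WSSAR of an elliptical rosette equals the semi-axis ratio", {
  s <- make_rosette(ratio = 0.3, mode = "rotating", mean = 1)
  expect_equal(as.numeric(wssar(s)), 0.3, tolerance = 1e-6)
})

test_that("WSSAR is bounded, rotation and scale invariant, and label symmetric", {
  set.seed(7)
  for (rep in 1:8) {
    ratio <- runif(1)
    ang <- runif(1, 0, 180)
    s <- make_rosette(ratio = ratio, mode = "fixed", base_angle = ang,
                      amp = runif(1, 0.2, 1.5), noise = 0.05, seed = rep)
    v <- as.numeric(wssar(s))
    expect_gte(v, 0); expect_lte(v, 1)
    # rigid rotation of the frame
    Q <- random_rotation()
    sr <- wss_series(s$times, s$vectors %*% t(Q), drop(Q %*% s$normal))
    # invariance holds up to the finite angular sweep resolution (the
    # rotated frame shifts the sweep grid; noise amplifies the sensitivity)
    expect_equal(as.numeric(wssar(sr)), v, tolerance = 5e-3)
    # uniform scaling
    ss <- wss_series(s$times, 3.7 * s$vectors, s$normal)
    expect_equal(as.numeric(wssar(ss)), v, tolerance = 1e-12)
  }
  # swapping the roles of the two axes leaves the ratio unchanged
  a <- as.numeric(wssar(make_rosette(ratio = 0.4, mode = "rotating")))
  b <- as.numeric(wssar(make_rosette(ratio = 0.4, mode = "rotating",
                                     base_angle = 90)))
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("zero-flow series yields WSSAR 0 with a degenerate flag", {
  s0 <- wss_series(c(0, 0.5, 1), matrix(0, 3, 3), c(0, 0, 1))
  v <- wssar(s0)
  expect_equal(as.numeric(v), 0)
  expect_true(attr(v, "degenerate"))
})

test_that("low-WSS stimulus follows the quadratic ramp", {
  th <- degradation_thresholds(tau_L = 0.5, tau_C = 1)
  expect_equal(f_wss(0.4, th), 1)
  expect_equal(f_wss(1.2, th), 0)
  expect_equal(f_wss(0.75, th), 0.25)
  # monotone non-increasing and continuous at the thresholds
  x <- seq(0, 1.5, by = 1e-3)
  y <- f_wss(x, th)
  expect_true(all(diff(y) <= 1e-12))
  expect_equal(f_wss(0.5 + 1e-9, th), 1, tolerance = 1e-6)
  expect_equal(f_wss(1 - 1e-9, th), 0, tolerance = 1e-6)
})

test_that("WSSAR stimulus follows the quadratic ramp", {
  th <- degradation_thresholds(tau_C_AR = 0.7, tau_H_AR = 0.8)
  expect_equal(f_ar(0.6, th), 0)
  expect_equal(f_ar(0.9, th), 1)
  expect_equal(f_ar(0.75, th), 0.25)
  x <- seq(0, 1, by = 1e-3)
  y <- f_ar(x, th)
  expect_true(all(diff(y) >= -1e-12))
  expect_equal(f_ar(0.7 + 1e-9, th), 0, tolerance = 1e-6)
  expect_equal(f_ar(0.8 - 1e-9, th), 1, tolerance = 1e-6)
})

test_that("threshold container validates orderings", {
  expect_error(degradation_thresholds(tau_L = 1, tau_C = 0.5), "tau_L")
  expect_error(degradation_thresholds(tau_C_AR = 0.9, tau_H_AR = 0.8),
               "tau_C_AR")
  expect_error(degradation_thresholds(D_max = -1), "D_max")
})

test_that("WSS series round-trip through CSV", {
  sl <- list(p1 = make_rosette(ratio = 0.3, mode = "rotating"),
             p2 = make_rosette(ratio = 0, mode = "fixed", base_angle = 45))
  path <- tempfile(fileext = ".csv")
  write_wss_csv(sl, path)
  back <- read_wss_csv(path)
  expect_equal(unname(back$p1$vectors), unname(sl$p1$vectors),
               tolerance = 1e-12)
  expect_equal(back$p2$times, sl$p2$times)
  expect_equal(as.numeric(wssar(back$p1)), 0.3, tolerance = 1e-6)
})

test_that("series constructor enforces tangency and monotone times", {
  expect_error(wss_series(c(0, 0), matrix(0, 2, 3), c(0, 0, 1)))
  v <- matrix(c(1, 0, 0.5, 1, 0, 0.5), 2, 3, byrow = TRUE)
  expect_error(wss_series(c(0, 1), v, c(0, 0, 1)), "orthogonal")
})
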