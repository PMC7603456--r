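test_that("zero sac height degenerates to a plain parent cylinder", {
  cfg <- default_config()
  cfg$geometry$sac_height <- 0
  g <- build_geometry(cfg)
  expect_true(all(g$points$region == "parent"))
  expect_equal(g$points$r_ref, rep(2, nrow(g$points)))
  expect_equal(g$points$k1, rep(0, nrow(g$points)))
  expect_equal(g$points$r2, rep(2, nrow(g$points)))
})

test_that("default profile rises monotonically from parent to apex", {
  g <- build_geometry(default_config())
  half <- g$points$r_ref[g$points$z <= 0]
  expect_true(all(diff(half) >= 0))
  # even grid has no node exactly at the apex
  expect_equal(max(g$points$r_ref), g$R0 + g$H, tolerance = 1e-4)
})

test_that("analytic curvatures match a finite-difference oracle on the profile", {
  g <- build_geometry(default_config())
  pts <- g$points
  i <- seq(5, nrow(pts) - 5, by = 13)
  h <- diff(pts$z)[1]
  rp <- (pts$r_ref[i + 1] - pts$r_ref[i - 1]) / (2 * h)
  rpp <- (pts$r_ref[i + 1] - 2 * pts$r_ref[i] + pts$r_ref[i - 1]) / h^2
  k1_fd <- -rpp / (1 + rp^2)^1.5
  r2_fd <- pts$r_ref[i] * sqrt(1 + rp^2)
  expect_equal(pts$k1[i], k1_fd, tolerance = 1e-3)
  expect_equal(pts$r2[i], r2_fd, tolerance = 1e-4)
  sc <- surface_curvatures(g)
  expect_equal(sc$k_meridional, pts$k1)
  expect_equal(sc$k_circumferential, 1 / pts$r2)
})

test_that("zero neck band produces a hard jump with a warning", {
  cfg <- default_config()
  cfg$geometry$neck_band <- 0
  expect_warning(g <- build_geometry(cfg), "hard parameter jump")
  expect_true(all(g$points$u %in% c(0, 1)))
})

test_that("region parameters interpolate linearly across the neck", {
  cfg <- default_config()
  p <- cfg$material$parent
  d <- cfg$material$dome
  expect_equal(blend_region_params(p, d, 0), p)
  expect_equal(blend_region_params(p, d, 1), d)
  mid <- blend_region_params(p, d, 0.5)
  # adventitial attachment max: parent 1.0, dome 1.1 -> 1.05 at midpoint
  expect_equal(mid$adventitia$att[3], 1.05)
  expect_equal(mid$media$m_e, (1 + 0.1) / 2)
})

test_that("fiber orientations follow region conventions", {
  cfg <- default_config()
  g <- build_geometry(cfg)
  ang <- assign_fiber_orientations(g, cfg$fiber_angles)
  par_med <- ang[ang$layer == "media" &
                 g$points$region[ang$point] == "parent", ]
  expect_equal(unique(par_med$ang1), 30 * pi / 180, tolerance = 1e-12)
  expect_equal(unique(par_med$ang2), -30 * pi / 180, tolerance = 1e-12)
  par_adv <- ang[ang$layer == "adventitia" &
                 g$points$region[ang$point] == "parent", ]
  expect_equal(unique(par_adv$ang1), 60 * pi / 180, tolerance = 1e-12)
  dome <- ang[g$points$region[ang$point] == "dome", ]
  expect_true(all(abs(dome$ang1) < 1e-12))          # circumferential
  expect_true(all(abs(dome$ang2 + pi / 2) < 1e-12)) # meridional
  # zero parent angle keeps fibers circumferential
  ang0 <- assign_fiber_orientations(g, list(media = 0, adventitia = 0))
  expect_true(all(ang0$ang1[g$points$region[ang0$point] == "parent"] == 0))
})

test_that("a spherical apex triggers the umbilic fallback flag", {
  cfg <- default_config()
  H <- cfg$geometry$sac_height
  R0 <- cfg$geometry$parent_radius
  cfg$geometry$sac_width <- sqrt(H * (R0 + H))  # exact umbilic apex
  cfg$geometry$n_points <- 101                  # odd: node exactly at z = 0
  g <- build_geometry(cfg)
  ang <- assign_fiber_orientations(g, cfg$fiber_angles)
  apex <- which.max(g$points$r_ref)
  expect_true(any(ang$umbilic[ang$point == apex]))
  # fallback directions remain circumferential / meridional
  row <- ang[ang$point == apex & ang$layer == "media", ]
  expect_equal(row$ang1, 0)
  expect_equal(row$ang2, -pi / 2)
})

test_that("cylinder principal curvature directions are circumferential and axial", {
  cfg <- default_config()
  cfg$geometry$sac_height <- 0
  g <- build_geometry(cfg)
  sc <- surface_curvatures(g)
  # k_meridional = 0 (axial direction is flat), k_circumferential = 1/R
  expect_equal(sc$k_meridional, rep(0, nrow(g$points)))
  expect_equal(sc$k_circumferential, rep(1 / 2, nrow(g$points)))
})

test_that("overlapping or invalid geometry is rejected", {
  cfg <- default_config()
  cfg$geometry$parent_radius <- -1
  expect_error(build_geometry(cfg))
  cfg <- default_config()
  cfg$geometry$neck_band <- 2
  expect_error(validate_config(cfg), "neck_band")
})
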