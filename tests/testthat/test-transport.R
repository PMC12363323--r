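test_that("cone injection: speeds exact, directions within the cone, reproducible", {
  aw <- default_model()
  inj <- spray_injection(iu_axis(aw), diameter_um = 10, n_droplets = 500,
                         seed = 7)
  st <- cone_injection(inj, aw)
  expect_equal(nrow(st$velocity), 500)
  speeds <- sqrt(rowSums(st$velocity^2))
  expect_equal(speeds, rep(10, 500), tolerance = 1e-12)
  cosang <- st$velocity %*% inj$axis$direction / speeds
  expect_true(all(cosang >= cos(27.93 * pi / 180) - 1e-12))
  # solid-angle-uniform sampling actually fills the cone rim
  expect_gt(max(acos(pmin(cosang, 1))) * 180 / pi, 25)
  st2 <- cone_injection(spray_injection(iu_axis(aw), 10, n_droplets = 500,
                                        seed = 7), aw)
  expect_identical(st$velocity, st2$velocity)
})

test_that("degenerate cone collapses onto the axis", {
  aw <- default_model()
  inj <- spray_injection(iu_axis(aw), 10, cone_half_angle = 1e-9,
                         n_droplets = 50, seed = 1)
  st <- cone_injection(inj)
  dirs <- st$velocity / 10
  expect_equal(dirs, matrix(rep(inj$axis$direction, each = 50), 50, 3),
               tolerance = 1e-7)
})

test_that("injection outside the lumen is a placement error", {
  aw <- default_model()
  # nozzle tip 8 mm laterally: outside the 7-mm inlet radius
  ax <- spray_axis("IU", c(0, 0, 0), c(0, -1, 0), insertion_mm = 8)
  expect_error(cone_injection(spray_injection(ax, 10), aw), "outside")
})

test_that("slip-corrected relaxation time matches direct arithmetic", {
  # tau = rho_D D^2 Cc / (18 mu), D = 10 um, Cc = 1
  expect_equal(relaxation_time(10, 1500, AIR_MU, Cc = 1), 4.566e-4,
               tolerance = 1e-3)
  # doubling D quadruples tau
  expect_equal(relaxation_time(20, 1500, AIR_MU, Cc = 1) /
                 relaxation_time(10, 1500, AIR_MU, Cc = 1), 4,
               tolerance = 1e-12)
  expect_gt(cunningham_slip(0.1), cunningham_slip(1))
  expect_true(all(cunningham_slip(c(0.5, 1, 5, 20)) > 1))
})

test_that("drag acceleration is linear in slip velocity and vanishes at no slip", {
  aw <- default_model()
  fl <- flow_field(15)
  geom <- nasodose:::geometry_params(aw)
  p <- centerline_point(aw, 0.5)
  u <- velocity_at(aw, fl, p)
  parts0 <- nasodose:::.accel_parts_cpp(p, u, 10e-6, 1500, 1, geom,
                                        fl$Q_m3s, AIR_RHO, AIR_MU,
                                        c(0, 0, 0))
  expect_equal(parts0$drag, c(0, 0, 0), tolerance = 1e-12)
  v1 <- u + c(0.1, 0, 0)
  v2 <- u + c(0.3, 0, 0)
  p1 <- nasodose:::.accel_parts_cpp(p, v1, 10e-6, 1500, 1, geom, fl$Q_m3s,
                                    AIR_RHO, AIR_MU, c(0, 0, 0))
  p2 <- nasodose:::.accel_parts_cpp(p, v2, 10e-6, 1500, 1, geom, fl$Q_m3s,
                                    AIR_RHO, AIR_MU, c(0, 0, 0))
  expect_equal(p2$drag, 3 * p1$drag, tolerance = 1e-9)
  expect_equal(p1$tau, relaxation_time(10, 1500, AIR_MU, Cc = 1),
               tolerance = 1e-12)
})

test_that("Saffman lift matches an independent evaluation of the generalized formula", {
  # constant-radius tube: the analytic radial shear is the whole velocity
  # gradient up to the (small) curvature terms the oracle also captures
  aw <- airway_model(radius_profile = cbind(c(0, 1), c(6, 6)))
  fl <- flow_field(15)
  geom <- nasodose:::geometry_params(aw)
  s <- 0.5
  r <- airway_radius(aw, s)
  p <- centerline_point(aw, s) + c(0, 0.5 * r, 0) # off-centre: non-zero shear
  v <- velocity_at(aw, fl, p) * 0.4 # lagging droplet
  D <- 15e-6; rho_d <- 1500
  got <- nasodose:::.accel_parts_cpp(p, v, D, rho_d, 1, geom, fl$Q_m3s,
                                     AIR_RHO, AIR_MU, c(0, 0, 0))

  # independent oracle: numerical deformation tensor of the analytic field,
  # then F/m = 2 K nu^0.5 rho d_ij v_slip_j / (rho_p D (d_lk d_kl)^0.25)
  h <- 1e-6
  J <- matrix(0, 3, 3)
  for (j in 1:3) {
    dp <- c(0, 0, 0); dp[j] <- h
    J[, j] <- (velocity_at(aw, fl, p + dp) -
                 velocity_at(aw, fl, p - dp)) / (2 * h)
  }
  d <- (J + t(J)) / 2
  slip <- velocity_at(aw, fl, p) - v
  K <- 2.594
  nu <- AIR_MU / AIR_RHO
  oracle <- 2 * K * sqrt(nu) * AIR_RHO * (d %*% slip) /
    (rho_d * D * (sum(d * d))^0.25)
  expect_equal(got$saffman, as.numeric(oracle), tolerance = 2e-2)
  expect_gt(sqrt(sum(got$saffman^2)), 0) # the worked case has real lift

  # zero shear (still air) and zero slip both kill the lift
  still <- nasodose:::.accel_parts_cpp(p, c(0, 0, 0), D, rho_d, 1, geom,
                                       0, AIR_RHO, AIR_MU, c(0, 0, 0))
  expect_equal(still$saffman, c(0, 0, 0))
  noslip <- nasodose:::.accel_parts_cpp(p, velocity_at(aw, fl, p), D, rho_d,
                                        1, geom, fl$Q_m3s, AIR_RHO, AIR_MU,
                                        c(0, 0, 0))
  expect_equal(noslip$saffman, c(0, 0, 0), tolerance = 1e-12)
})

test_that("in still air droplet speed decays monotonically without gravity", {
  aw <- default_model()
  still <- flow_field(1e-9) # negligible flow
  ct0 <- physical_constants(aw, g_magnitude = 0)
  p0 <- centerline_point(aw, 0.5)
  inj <- point_injection(p0, diameter_um = 10, speed = 1)
  speeds <- vapply(c(2e-4, 1e-3, 3e-3), function(tm) {
    tr <- track_droplets(aw, still, inj, ct0, dt = 1e-4, t_max = tm)
    sqrt(tr$vx^2 + tr$vy^2 + tr$vz^2)
  }, numeric(1))
  expect_true(all(diff(speeds) < 0))
  expect_lt(speeds[3], 0.01) # essentially stopped after many relaxation times
})

test_that("still-air settling reaches the closed-form terminal velocity within 1%", {
  aw <- default_model()
  still <- flow_field(1e-9)
  ct <- physical_constants(aw)
  p0 <- centerline_point(aw, 0.5)
  for (D in c(1, 5, 10, 24)) {
    inj <- point_injection(p0, diameter_um = D)
    tr <- track_droplets(aw, still, inj, ct, dt = 1e-4, t_max = 0.05)
    expect_equal(tr$status, "airborne")
    v_sim <- sqrt(tr$vx^2 + tr$vy^2 + tr$vz^2)
    expect_equal(v_sim, terminal_velocity(D), tolerance = 0.01)
  }
})

test_that("droplet started outside the lumen is trapped immediately", {
  aw <- default_model()
  fl <- flow_field(15)
  ax <- spray_axis("IU", c(0, 0, 0), c(1, 0, 0.2))
  inj <- spray_injection(ax, 10, n_droplets = 3, seed = 1)
  # bypass the placement check by tracking a hand-built state far outside
  init <- cone_injection(inj)
  init$position[] <- rep(c(0, 0.5, 0), each = 3)
  res <- nasodose:::.track_cloud_cpp(init$position, init$velocity, 10e-6,
                                     1500, 1, nasodose:::geometry_params(aw),
                                     fl$Q_m3s, AIR_RHO, AIR_MU,
                                     physical_constants(aw)$g, 1e-4, 0.01)
  expect_true(all(res$status == 1L))
})

test_that("deposition curves conserve droplets and are seed-reproducible", {
  aw <- default_model()
  fl <- flow_field(15)
  dg <- c(2, 8, 16, 24)
  cv <- deposition_curve(aw, fl, iu_axis(aw), diameters_um = dg,
                         n_droplets = 150, seed = 11)
  expect_true(all(cv$n_trapped + cv$n_escaped_outlet +
                    cv$n_escaped_nostril + cv$n_airborne == 150))
  expect_true(all(cv$efficiency >= 0 & cv$efficiency <= 1))
  cv2 <- deposition_curve(aw, fl, iu_axis(aw), diameters_um = dg,
                          n_droplets = 150, seed = 11)
  expect_identical(cv$efficiency, cv2$efficiency)
  expect_identical(cv$mean_final_s, cv2$mean_final_s)
})

test_that("deposition curve CSV round-trips", {
  cv <- curve_from(c(0.1, 0.5, 0.2), protocol = "CU", flow = 30)
  path <- tempfile(fileext = ".csv")
  write_deposition_curve(cv, path)
  back <- read_deposition_curve(path)
  expect_equal(back$efficiency, cv$efficiency)
  expect_equal(attr(back, "protocol"), "CU")
  expect_equal(attr(back, "flow_lpm"), 30)
  header <- readLines(path, n = 1)
  expect_match(header, "protocol,flow_lpm,side,diameter_um,efficiency")
})
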