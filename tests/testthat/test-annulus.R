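cfg <- annulus_config()

test_that("velocity profile satisfies no-slip and carries the set flow rate", {
  v_in <- annulus_velocity(cfg$r_inner, cfg)
  expect_equal(v_in$u_theta, cfg$omega * cfg$r_inner)
  expect_equal(v_in$u_z, 0, tolerance = 1e-12)
  v_out <- annulus_velocity(cfg$r_outer, cfg)
  expect_equal(v_out$u_theta, 0, tolerance = 1e-12)
  expect_equal(v_out$u_z, 0, tolerance = 1e-12)
  expect_error(annulus_velocity(0.01, cfg), class = "dte_validation_error")
  # 2 pi int u_z r dr == q, by independent numerical quadrature
  f <- function(r) vapply(r, function(ri) {
    2 * pi * ri * annulus_velocity(ri, cfg)$u_z
  }, numeric(1))
  q_num <- integrate(f, cfg$r_inner, cfg$r_outer, rel.tol = 1e-10)$value
  expect_equal(q_num, cfg$q / 60000, tolerance = 1e-6)
})

test_that("analytic stress matches finite differences of the velocity field", {
  h <- 1e-9
  for (r in c(0.0035, 0.0045, 0.0055)) {
    vp <- annulus_velocity(r + h, cfg)
    vm <- annulus_velocity(r - h, cfg)
    v0 <- annulus_velocity(r, cfg)
    # tau_rtheta = mu * r * d(u_theta / r)/dr, tau_rz = mu * du_z/dr
    d_uth_over_r <- (vp$u_theta / (r + h) - vm$u_theta / (r - h)) / (2 * h)
    tau_rtheta_fd <- cfg$mu * r * d_uth_over_r
    tau_rz_fd <- cfg$mu * (vp$u_z - vm$u_z) / (2 * h)
    tau <- annulus_stress(r, 0, cfg)
    # at theta = 0 the Cartesian tau12 and tau13 are the cylindrical shears
    expect_equal(tau$tau12, tau_rtheta_fd, tolerance = 1e-6)
    expect_equal(tau$tau13, tau_rz_fd, tolerance = 1e-6)
  }
})

test_that("scalar stress of the annulus tensor is rotation invariant", {
  set.seed(3)
  thetas <- runif(200, -2 * pi, 4 * pi)
  for (r in c(0.0032, 0.0045, 0.0058)) {
    tau <- annulus_stress(rep(r, 200), thetas, cfg)
    sig <- scalar_stress(tau$tau11, tau$tau22, tau$tau33,
                         tau$tau12, tau$tau13, tau$tau23)
    expect_lt(diff(range(sig)) / mean(sig), 1e-12)
  }
})

test_that("Cartesian rotation agrees with an explicit tensor rotation", {
  # independent oracle: Q T_cyl Q^T with basis-vector rotation matrix
  for (theta in c(0, 0.7, 2.2, -1.3)) {
    r <- 0.004
    cyl <- list(a = -2 * cfg$mu * cfg$B / r^2,
                b = cfg$mu * cfg$uz_scale * (-2 * r + cfg$Lambda / r))
    T_cyl <- matrix(c(0, cyl$a, cyl$b,
                      cyl$a, 0, 0,
                      cyl$b, 0, 0), 3, 3)
    Q <- cbind(c(cos(theta), sin(theta), 0),
               c(-sin(theta), cos(theta), 0),
               c(0, 0, 1))
    T_cart <- Q %*% T_cyl %*% t(Q)
    tau <- annulus_stress(r, theta, cfg)
    expect_equal(tau$tau11, T_cart[1, 1], tolerance = 1e-12)
    expect_equal(tau$tau22, T_cart[2, 2], tolerance = 1e-12)
    expect_equal(tau$tau33, T_cart[3, 3], tolerance = 1e-12)
    expect_equal(tau$tau12, T_cart[1, 2], tolerance = 1e-12)
    expect_equal(tau$tau13, T_cart[1, 3], tolerance = 1e-12)
    expect_equal(tau$tau23, T_cart[2, 3], tolerance = 1e-12)
  }
  # no rotation -> no swirl stress, exactly
  still <- annulus_config(omega = 0)
  tau0 <- annulus_stress(0.004, 1.1, still)
  expect_equal(tau0$tau12, 0)
  expect_equal(tau0$tau11, 0)
  expect_equal(still$B, 0)
})

test_that("seeding is deterministic, in-support and area-uniform", {
  sc <- seed_config(n_particles = 9800, seed = 123)
  s1 <- seed_particles(cfg, sc)
  s2 <- seed_particles(cfg, sc)
  expect_identical(s1, s2)
  r <- sqrt(s1$x^2 + s1$y^2)
  expect_true(all(r >= cfg$r_inner & r <= cfg$r_outer))
  expect_true(all(s1$z == 0))
  # r^2 uniform on [r_inner^2, r_outer^2]
  u <- (r^2 - cfg$r_inner^2) / (cfg$r_outer^2 - cfg$r_inner^2)
  expect_gt(suppressWarnings(ks.test(u, "punif"))$p.value, 0.01)
})

test_that("advection conserves radius and flags exits exactly at the outlet", {
  sc <- seed_config(n_particles = 40, seed = 7)
  seeds <- seed_particles(cfg, sc)
  e <- advect(cfg, seeds, sc)
  s <- e$samples
  rad_dev <- s[, {
    r <- sqrt(x^2 + y^2); (max(r) - min(r)) / mean(r)
  }, by = particle_id]$V1
  expect_lt(max(rad_dev), 1e-9)
  last <- s[, .(z_last = z[.N]), by = particle_id]
  exited <- e$exited[last$particle_id]
  expect_identical(unname(exited), unname(last$z_last >= cfg$length - 1e-12))
})

test_that("advected SA matches the closed-form oracle at the default step", {
  sc <- seed_config(n_particles = 150, seed = 9, max_duration = 0.5)
  seeds <- seed_particles(cfg, sc)
  e <- advect(cfg, seeds, sc)
  sa <- sa_ensemble(e, completed_only = TRUE)
  r <- setNames(sqrt(seeds$x^2 + seeds$y^2), seeds$particle_id)
  oracle <- analytic_sa(r[names(sa$values)], cfg)
  rel <- abs(sa$values - oracle) / oracle
  expect_lt(max(rel), 1e-3)
})

test_that("analytic SA is linear in length and viscosity, and walls error", {
  r <- 0.004
  base <- analytic_sa(r, cfg)
  cfg2L <- annulus_config(length = 2 * cfg$length)
  expect_equal(analytic_sa(r, cfg2L), 2 * base)
  cfg2mu <- annulus_config(mu = 2 * cfg$mu)
  expect_equal(analytic_sa(r, cfg2mu), 2 * base)
  expect_error(analytic_sa(cfg$r_outer, cfg), "wall",
               class = "dte_validation_error")
  # midgap value vs dense-sampling rectangle quadrature of sigma dt
  vel <- annulus_velocity(r, cfg)
  transit <- cfg$length / vel$u_z
  tt <- seq(0, transit, length.out = 2e5 + 1)
  theta <- vel$u_theta / r * tt
  tau <- annulus_stress(rep(r, length(tt)), theta, cfg)
  sig <- scalar_stress(tau$tau11, tau$tau22, tau$tau33,
                       tau$tau12, tau$tau13, tau$tau23)
  sa_num <- sum(head(sig, -1) * diff(tt)) * 10   # Pa.s -> dyne.s/cm2
  expect_equal(sa_num, base, tolerance = 1e-8)
})

test_that("rpm calibration: closed form, bisection agreement, degenerate cases", {
  expect_equal(calibrate_rpm(pump_curve(1), 5.3, 10000), 100, tolerance = 1e-8)
  expect_equal(calibrate_rpm(pump_curve(1), 0.001, 0), 0, tolerance = 1e-8)
  set.seed(14)
  for (i in 1:20) {
    a <- runif(1, 1e-5, 1); b <- runif(1, 0, 10); q <- runif(1, 0.5, 8)
    H <- runif(1, 100, 2e4)
    expect_equal(calibrate_rpm(pump_curve(a, b), q, H),
                 sqrt((H + b * q^2) / a), tolerance = 1e-8)
  }
  expect_error(calibrate_rpm(pump_curve(1, 0), 5, -10), "unachievable")
  expect_error(pump_curve(-1), "head_coefficient")
})

test_that("rotations and mass-flow arithmetic", {
  expect_equal(rotations(10600, 0.105), 18.55)
  expect_equal(rotations(11600, 0.105), 20.3)
  expect_equal(rotations(5000, 0), 0)
  expect_equal(mass_flow(60, 1000), 1)
  expect_equal(mass_flow(5.3, 1080), 9.548e-2, tolerance = 1e-3)
  expect_equal(mass_flow(2 * 5.3, 1080), 2 * mass_flow(5.3, 1080))
  expect_equal(mass_flow(5.3, 3 * 1080), 3 * mass_flow(5.3, 1080))
})

test_that("duration choice hits the exit target and is monotone", {
  sc <- seed_config(n_particles = 500, seed = 4, max_duration = 10)
  d50 <- choose_duration(cfg, sc, 0.5)
  d90 <- choose_duration(cfg, sc, 0.9)
  d99 <- choose_duration(cfg, sc, 0.99)
  expect_true(d50 <= d90 && d90 <= d99)
  expect_equal(round(d90 / sc$dt), d90 / sc$dt)  # a whole number of steps
  # advecting for the chosen duration reaches the target
  sc_run <- seed_config(n_particles = 500, seed = 4, max_duration = d90)
  e <- advect(cfg, seed_particles(cfg, sc_run), sc_run)
  expect_gte(exit_fraction(e), 0.9)
  # a target of 1 cannot be reached before the cap (near-wall particles)
  sc_cap <- seed_config(n_particles = 500, seed = 4, max_duration = 0.2)
  expect_warning(dcap <- choose_duration(cfg, sc_cap, 1), "cap")
  expect_equal(dcap, 0.2)
})

test_that("default study conditions: ~90% of platelets exit within 0.105 s", {
  sc <- seed_config(n_particles = 2000, seed = 2)
  e <- advect(cfg, seed_particles(cfg, sc), sc)
  expect_gte(exit_fraction(e), 0.85)
  expect_equal(e$meta$dt, 7.53e-5)
})

test_that("two-device generator builds a known high-SA tail into MAX", {
  sc <- seed_config(n_particles = 400, seed = 11, max_duration = 0.3)
  pair <- two_device_ensembles(cfg, sc)
  sa_min <- sa_ensemble(pair$min)
  sa_max <- sa_ensemble(pair$max)
  expect_gt(tail_mass(sa_max, 50), tail_mass(sa_min, 50))
  # zero recirculation: statistically identical devices
  null_pair <- two_device_ensembles(cfg, sc, recirc_fraction = 0)
  ks <- suppressWarnings(ks.test(sa_ensemble(null_pair$min)$values,
                                 sa_ensemble(null_pair$max)$values))
  expect_gt(ks$p.value, 0.001)
})
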