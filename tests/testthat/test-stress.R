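test_that("scalar stress: closed-form special cases", {
  expect_identical(scalar_stress(0, 0, 0, 0, 0, 0), 0)
  # hydrostatic tensors give zero for any pressure
  for (p in c(-1e4, -1, 0.5, 3, 1e6)) {
    expect_equal(scalar_stress(p, p, p, 0, 0, 0), 0)
  }
  # pure shear: sigma equals the shear component, on any off-diagonal
  expect_equal(scalar_stress(0, 0, 0, 5, 0, 0), 5)
  expect_equal(scalar_stress(0, 0, 0, 0, -7, 0), 7)
  expect_equal(scalar_stress(0, 0, 0, 0, 0, 2.5), 2.5)
  # uniaxial: 3/sqrt(3) = sqrt(3)
  expect_equal(scalar_stress(3, 0, 0, 0, 0, 0), sqrt(3))
  expect_error(scalar_stress(NaN, 0, 0, 0, 0, 0),
               class = "dte_validation_error")
})

test_that("scalar stress is hydrostatic-invariant and positively homogeneous", {
  tens <- random_tensors(1000, seed = 42)
  sig <- scalar_stress(tens[, 1], tens[, 2], tens[, 3],
                       tens[, 4], tens[, 5], tens[, 6])
  set.seed(43)
  p <- runif(1000, -100, 100)
  sig_p <- scalar_stress(tens[, 1] + p, tens[, 2] + p, tens[, 3] + p,
                         tens[, 4], tens[, 5], tens[, 6])
  expect_lt(max(abs(sig_p - sig) / pmax(sig, .Machine$double.eps)), 1e-12)
  for (cc in c(-3, 0.25, 7)) {
    sig_c <- scalar_stress(cc * tens[, 1], cc * tens[, 2], cc * tens[, 3],
                           cc * tens[, 4], cc * tens[, 5], cc * tens[, 6])
    expect_equal(sig_c, abs(cc) * sig, tolerance = 1e-13)
  }
})

test_that("SA: constant stress and hand-computed left-rectangle sums", {
  # constant sigma = 10 dyne/cm2 over 10 uniform steps spanning 1 s -> 10
  tr <- const_shear_trajectory(tau = 10, n_steps = 10, total_time = 1)
  expect_equal(stress_accumulation(tr), 10)
  # sigma_i = i dyne/cm2 at t_i = i * 0.1, i = 0..4 -> (0+1+2+3)*0.1 = 0.6
  tr2 <- const_shear_trajectory(n_steps = 4, total_time = 0.4)
  tr2$samples$tau12 <- 0:4
  expect_equal(stress_accumulation(tr2), 0.6)
  # stored in Pa: result still reported in dyne.s/cm2
  tr3 <- const_shear_trajectory(tau = 1, n_steps = 10, total_time = 1,
                                unit = "Pa")
  expect_equal(stress_accumulation(tr3), 10)
})

test_that("SA is additive over concatenation and linear under time dilation", {
  tr <- const_shear_trajectory(n_steps = 9, total_time = 0.9)
  set.seed(7)
  tr$samples$tau12 <- runif(10, 1, 5)
  whole <- stress_accumulation(tr)
  for (cut in c(2, 5, 9)) {
    p1 <- tr; p1$samples <- tr$samples[1:cut, ]
    p2 <- tr; p2$samples <- tr$samples[cut:10, ]
    expect_equal(stress_accumulation(p1) + stress_accumulation(p2), whole)
  }
  dilated <- tr
  dilated$samples$t <- tr$samples$t * 3.7
  expect_equal(stress_accumulation(dilated), whole * 3.7)
})

test_that("SA rejects degenerate trajectories", {
  tr <- const_shear_trajectory(n_steps = 4)
  short <- tr; short$samples <- tr$samples[1, ]
  expect_error(stress_accumulation(short), "2 samples",
               class = "dte_validation_error")
  bad <- tr; bad$samples$t <- c(0, 0.1, 0.1, 0.3, 0.4)
  expect_error(stress_accumulation(bad), "increasing",
               class = "dte_validation_error")
})

test_that("SA on exact Couette samples equals sigma times residence time", {
  cfg <- annulus_config()
  r <- 0.0045
  vel <- annulus_velocity(r, cfg)
  transit <- cfg$length / vel$u_z
  tt <- seq(0, transit, length.out = 401)
  theta <- vel$u_theta / r * tt
  tau <- annulus_stress(rep(r, 401), theta, cfg)
  tr <- structure(list(
    particle_id = "c1",
    samples = cbind(data.frame(particle_id = "c1", t = tt,
                               x = r * cos(theta), y = r * sin(theta),
                               z = vel$u_z * tt), tau,
                    zone = NA_character_),
    exited = TRUE, stress_unit = "Pa"), class = "dte_trajectory")
  expect_equal(stress_accumulation(tr), analytic_sa(r, cfg),
               tolerance = 1e-10)
})

test_that("sa_ensemble scores each trajectory and honours completed_only", {
  rows <- do.call(rbind, lapply(c("a", "b", "c"), function(id) {
    d <- const_shear_trajectory(tau = 10, n_steps = 5, total_time = 0.5,
                                id = id)$samples
    d
  }))
  e <- trajectory_ensemble(rows, exited = c(a = TRUE, b = FALSE, c = FALSE),
                           stress_unit = "dyne/cm2")
  sa <- sa_ensemble(e)
  expect_equal(sa$n_scored, 3)
  expect_equal(sa$n_seeded, 3)
  expect_true(all(sa$values == 5))
  only <- sa_ensemble(e, completed_only = TRUE)
  expect_equal(only$n_scored, 1)
  expect_equal(names(only$values), "a")
  e$exited[] <- FALSE
  expect_error(sa_ensemble(e, completed_only = TRUE), "exited",
               class = "dte_validation_error")
})

test_that("single-sample particles stay seeded but are not scored", {
  rows <- const_shear_trajectory(tau = 2, n_steps = 4, id = "long")$samples
  rows <- rbind(rows, within(rows[1, ], particle_id <- "stub"))
  e <- trajectory_ensemble(rows, stress_unit = "dyne/cm2")
  expect_warning(sa <- sa_ensemble(e), "< 2 samples")
  expect_equal(sa$n_seeded, 2)
  expect_equal(sa$n_scored, 1)
})

test_that("exit_fraction counts exits over seeded particles", {
  e <- random_ensemble(10, 4, seed = 31)
  e$exited[] <- TRUE
  expect_equal(exit_fraction(e), 1)
  e$exited[] <- FALSE
  expect_equal(exit_fraction(e), 0)
  e$exited[1:9] <- TRUE
  expect_equal(exit_fraction(e), 0.9)
})

test_that("top_sa_trajectories sorts descending with id tie-break", {
  mk <- function(id, tau) {
    const_shear_trajectory(tau = tau, n_steps = 4, total_time = 1, id = id)$samples
  }
  e <- trajectory_ensemble(rbind(mk("z", 5), mk("a", 9), mk("m", 9), mk("b", 1)),
                           stress_unit = "dyne/cm2")
  top1 <- top_sa_trajectories(e, 1)
  expect_equal(top1$particle_id, "a")   # tie 9 vs 9 broken by id
  all4 <- top_sa_trajectories(e, 4)
  expect_equal(all4$particle_id, c("a", "m", "z", "b"))
  expect_equal(all4$sa, c(9, 9, 5, 1))
  expect_warning(topx <- top_sa_trajectories(e, 10), "exceeds")
  expect_equal(nrow(topx), 4)
})

test_that("SA ensemble CSV round trip preserves values and metadata", {
  e <- random_ensemble(6, 5, seed = 17, label = "dev1")
  sa <- sa_ensemble(e)
  f <- withr::local_tempfile(fileext = ".csv")
  write_sa_csv(sa, f)
  sa2 <- read_sa_csv(f)
  expect_identical(sa2$values[names(sa$values)], sa$values)
  expect_equal(sa2$n_seeded, sa$n_seeded)
  expect_identical(sa2$label, "dev1")
})
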