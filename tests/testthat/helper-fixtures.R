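# fixtures built in code: small ensembles with known structure

# trajectory with constant pure-shear stress (sigma == tau12) on a uniform
# time grid; unit defaults to dyne/cm2 so SA arithmetic is transparent
const_shear_trajectory <- function(tau = 10, n_steps = 10, total_time = 1,
                                   unit = "dyne/cm2", id = "p1", z = NULL) {
  tt <- seq(0, total_time, length.out = n_steps + 1)
  structure(list(
    particle_id = id,
    samples = data.frame(particle_id = id, t = tt,
                         x = 0.004, y = 0,
                         z = z %||% seq(0, 1, length.out = n_steps + 1),
                         tau11 = 0, tau22 = 0, tau33 = 0,
                         tau12 = tau, tau13 = 0, tau23 = 0,
                         zone = NA_character_),
    exited = TRUE, stress_unit = unit),
    class = "dte_trajectory")
}

# random valid ensemble (positions in a 3-6 mm annulus, arbitrary stresses)
random_ensemble <- function(n_particles = 5, n_samples = 8, seed = 1,
                            unit = "Pa", label = "rand") {
  set.seed(seed)
  rows <- do.call(rbind, lapply(seq_len(n_particles), function(i) {
    tt <- sort(runif(n_samples, 0, 0.1))
    r <- runif(1, 0.0031, 0.0059)
    th <- runif(n_samples, 0, 2 * pi)
    data.frame(particle_id = sprintf("p%02d", i), t = tt,
               x = r * cos(th), y = r * sin(th),
               z = sort(runif(n_samples, 0, 0.03)),
               tau11 = rnorm(n_samples), tau22 = rnorm(n_samples),
               tau33 = rnorm(n_samples), tau12 = rnorm(n_samples),
               tau13 = rnorm(n_samples), tau23 = rnorm(n_samples),
               zone = NA_character_)
  }))
  ex <- setNames(runif(n_particles) < 0.7, sprintf("p%02d", seq_len(n_particles)))
  trajectory_ensemble(rows, exited = ex, stress_unit = unit, label = label,
                      meta = list(seed = seed, dt = 7.53e-5))
}

range_spec <- function(fp) c(min(fp$grid), max(fp$grid), length(fp$grid))

random_tensors <- function(n, scale = 10, seed = 1) {
  set.seed(seed)
  matrix(runif(6 * n, -scale, scale), ncol = 6,
         dimnames = list(NULL, c("tau11", "tau22", "tau33",
                                 "tau12", "tau13", "tau23")))
}
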