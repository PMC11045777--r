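# Brute-force oracles and fixture builders used across the suite.

# O(n m |F|) double sum over particle pairs and features, independent of the
# package's kernel path
brute_inner <- function(mu, nu, sigma) {
  mu <- varifoldmap:::as_particles(mu)
  nu <- varifoldmap:::as_particles(nu)
  total <- 0
  for (i in seq_along(mu$w)) {
    for (j in seq_along(nu$w)) {
      k <- exp(-sum((mu$x[i, ] - nu$x[j, ])^2) / (2 * sigma^2))
      total <- total + k * sum(mu$w[i] * mu$p[i, ] * nu$w[j] * nu$p[j, ])
    }
  }
  total
}

brute_normed_diff <- function(mu, nu, sigma) {
  brute_inner(mu, mu, sigma) - 2 * brute_inner(mu, nu, sigma) +
    brute_inner(nu, nu, sigma)
}

# random particle varifold over nf features
random_varifold <- function(n, nf = 3L, spread = 100) {
  fs <- feature_space(paste0("f", seq_len(nf)))
  p <- matrix(stats::runif(n * nf), n, nf)
  p <- p / rowSums(p)
  particle_varifold(matrix(stats::runif(2 * n, 0, spread), n, 2L),
                    stats::runif(n, 0.1, 2), p, fs)
}

shoelace <- function(v) {
  x <- v[, 1L]; y <- v[, 2L]
  abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2
}

# small random velocity field with displacements bounded well below sigma_v
random_field <- function(n_ctrl = 5L, sigma_v = 100, n_steps = 10L,
                         sd = 10, spread = 300) {
  q0 <- matrix(stats::runif(2 * n_ctrl, 0, spread), n_ctrl, 2L)
  mom <- array(stats::rnorm(n_steps * n_ctrl * 2L, sd = sd),
               c(n_steps, n_ctrl, 2L))
  velocity_field(q0, mom, sigma_v, n_steps)
}

# affine map as a one-step "flow" oracle is not possible; for analytic-action
# tests we use rotation+scale rigid transforms wrapped in a zero-flow
# diffeomorphism
rigid_diffeo <- function(angle = 0, translation = c(0, 0), scale = 1,
                         center = c(0, 0)) {
  field <- velocity_field(matrix(c(0, 0), 1L, 2L), NULL, 100, 1L)
  diffeomorphism(field, rigid = rigid_scale(angle, translation, scale,
                                            center))
}

# default study scenario with a reduced-size variant for unit tests
small_scenario <- function(seed, deformation = NULL) {
  synthetic_scenario(seed = seed, domain = c(300, 225),
                     intensity = 0.15, deformation = deformation)
}
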