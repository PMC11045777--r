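# small shared fixture: 2-region atlas and a target drawn exactly from a law
fixture_mesh <- function() {
  fs <- feature_space(c("R1", "R2"))
  set.seed(33)
  pts <- data.frame(x = runif(300, 0, 200), y = runif(300, 0, 150))
  pts$feature <- ifelse(pts$x < 100, "R1", "R2")
  build_mesh_varifold(pts, fs, resolution = 50)
}

test_that("total_cost decomposes into its independently computed terms", {
  mesh <- fixture_mesh()
  gene_fs <- feature_space(c("a", "b", "c"))
  pis <- feature_law(matrix(c(2, 1, 0, 0, 1, 2), 2, 3, byrow = TRUE),
                     mesh$fs, gene_fs)
  target <- varifoldmap:::as_particles(apply_feature_law(mesh, pis))
  f0 <- velocity_field(varifoldmap:::thin_points(mesh$centers, 10), NULL,
                       100, 5L)
  cfg <- norm_config(80)
  # zero momenta and the generating law: perfect fit
  tc <- total_cost(f0, pis, mesh, target, cfg)
  expect_equal(tc$reg, 0)
  expect_lt(abs(tc$data), 1e-9 * varifold_inner(target, target, cfg))
  expect_equal(tc$total, tc$reg + tc$data)

  # random momenta: cross-check against module-level oracles
  set.seed(34)
  f <- velocity_field(f0$q0, array(rnorm(5 * nrow(f0$q0) * 2, sd = 5),
                                   c(5, nrow(f0$q0), 2)), 100, 5L)
  tc2 <- total_cost(f, pis, mesh, target, cfg, lambda_kl = 0.5)
  reg_o <- 0.5 * v_norm_sq(f)
  moved <- apply_diffeo(apply_feature_law(mesh, pis), diffeomorphism(f))
  data_o <- normed_difference(moved, target, cfg)
  kl_o <- kl_regularizer(pis)$total
  expect_equal(tc2$total, reg_o + data_o + 0.5 * kl_o, tolerance = 1e-9)
})

test_that("the internal cost engine matches total_cost and finite differences", {
  mesh <- fixture_mesh()
  gene_fs <- feature_space(c("a", "b", "c"))
  target <- varifoldmap:::as_particles(apply_feature_law(
    mesh, feature_law(matrix(runif(6, 0.5, 2), 2, 3), mesh$fs, gene_fs)))
  cfg <- registration_config(norm = norm_config(80), sigma_schedule = NULL,
                             sigma_v = 100, n_steps = 4L, data_weight = 1,
                             seed = 1)
  q0 <- varifoldmap:::thin_points(mesh$centers, 8)
  engine <- varifoldmap:::make_engine(mesh, target, cfg, q0)
  set.seed(35)
  Pi <- matrix(runif(6, 0.2, 1.5), 2, 3)
  mom <- array(rnorm(4 * nrow(q0) * 2, sd = 4), c(4, nrow(q0), 2))

  ev <- engine(mom, Pi, lambda_kl = 0.3, want_grad = TRUE)
  law <- feature_law(Pi, mesh$fs, gene_fs)
  tc <- total_cost(velocity_field(q0, mom, 100, 4L), law, mesh, target,
                   norm_config(80), lambda_kl = 0.3)
  expect_equal(ev$cost, tc$total, tolerance = 1e-9)

  # analytic gradients against central differences
  eps <- 1e-5
  idx <- sample(length(mom), 6)
  for (k in idx) {
    mp <- mom; mp[k] <- mp[k] + eps
    mm <- mom; mm[k] <- mm[k] - eps
    fd <- (engine(mp, Pi, 0.3, FALSE)$cost -
             engine(mm, Pi, 0.3, FALSE)$cost) / (2 * eps)
    expect_equal(ev$grad_a[k], fd,
                 tolerance = 1e-6 * max(1, abs(fd)))
  }
  for (k in sample(length(Pi), 4)) {
    pp <- Pi; pp[k] <- pp[k] + eps
    pm <- Pi; pm[k] <- pm[k] - eps
    fd <- (engine(mom, pp, 0.3, FALSE)$cost -
             engine(mom, pm, 0.3, FALSE)$cost) / (2 * eps)
    expect_equal(ev$grad_pi[k], fd,
                 tolerance = 1e-5 * max(1, abs(fd)))
  }
})

small_reg_config <- function(...) {
  args <- list(norm = norm_config(c(150, 80)), sigma_schedule = NULL,
               n_steps = 5L, max_outer = 2L, inner_maxit = 30L,
               joint_maxit = 60L, mesh_resolution = 50,
               bounds_mode = "none", rigid = FALSE, seed = 1)
  override <- list(...)
  args[names(override)] <- override
  do.call(registration_config, args)
}

test_that("registering a varifold onto itself stays at the identity", {
  mesh <- fixture_mesh()
  gene_fs <- feature_space(c("a", "b", "c"))
  pis <- feature_law(matrix(c(2, 1, 0.2, 0.3, 1, 2), 2, 3, byrow = TRUE),
                     mesh$fs, gene_fs)
  target <- varifoldmap:::as_particles(apply_feature_law(mesh, pis))
  fit <- register_alternating(mesh, target, small_reg_config())
  expect_lt(max(abs(fit$diagnostics$jacobian - 1)), 1e-2)
  final <- fit$cost_trace[nrow(fit$cost_trace), ]
  expect_lt(final$data, 1e-6 * varifold_inner(target, target,
                                              fit$config$norm))
  # recovered law close to the generator
  expect_lt(max(abs(unclass(coef(fit)) - unclass(pis))), 0.05)
})

test_that("one outer iteration with zero LDDMM steps is rigid + one QP", {
  mesh <- fixture_mesh()
  gene_fs <- feature_space(c("a", "b", "c"))
  pis <- feature_law(matrix(runif(6, 0.3, 2), 2, 3), mesh$fs, gene_fs)
  target <- varifoldmap:::as_particles(apply_feature_law(mesh, pis))
  cfg <- small_reg_config()
  cfg$inner_maxit <- 0L
  cfg$max_outer <- 1L
  cfg$rigid <- FALSE
  fit <- register_alternating(mesh, target, cfg)
  expect_true(all(fit$diffeo$field$momenta == 0))
  direct <- solve_feature_qp(mesh, target, cfg$norm, target_fs = gene_fs)
  expect_equal(unclass(coef(fit)), unclass(direct), tolerance = 1e-8)
})

test_that("alternating phases never increase the cost within a stage", {
  mesh <- fixture_mesh()
  gene_fs <- feature_space(c("a", "b", "c"))
  set.seed(36)
  pis <- feature_law(matrix(runif(6, 0.3, 2), 2, 3), mesh$fs, gene_fs)
  base <- apply_feature_law(mesh, pis)
  warped <- apply_diffeo(base, diffeomorphism(random_field(sd = 5)))
  target <- varifoldmap:::as_particles(warped)
  fit <- register_alternating(mesh, target, small_reg_config(max_outer = 3L))
  tt <- fit$cost_trace
  expect_true(all(diff(tt$total) <= 1e-6 * pmax(abs(tt$total[-nrow(tt)]), 1)))
})

test_that("registration is equivariant under a common translation", {
  mesh <- fixture_mesh()
  gene_fs <- feature_space(c("a", "b", "c"))
  pis <- feature_law(matrix(c(2, 1, 0.2, 0.3, 1, 2), 2, 3, byrow = TRUE),
                     mesh$fs, gene_fs)
  target <- varifoldmap:::as_particles(apply_feature_law(mesh, pis))
  cfg <- small_reg_config(rigid = TRUE)
  fit0 <- register_alternating(mesh, target, cfg)

  sh <- c(130, -70)
  mesh_s <- mesh_varifold(sweep(mesh$vertices, 2, sh, "+"), mesh$simplices,
                          mesh$alpha, mesh$p, mesh$fs)
  target_s <- particle_varifold(sweep(target$x, 2, sh, "+"), target$w,
                                target$p, target$fs)
  fit1 <- register_alternating(mesh_s, target_s, cfg)
  t0 <- fit0$cost_trace[nrow(fit0$cost_trace), ]
  t1 <- fit1$cost_trace[nrow(fit1$cost_trace), ]
  expect_equal(t1$data, t0$data, tolerance = 1e-6)
  expect_equal(unclass(coef(fit1)), unclass(coef(fit0)), tolerance = 1e-6)
})

test_that("partial captures register with template-side down-weighting", {
  mesh <- fixture_mesh()
  gene_fs <- feature_space(c("a", "b", "c"))
  pis <- feature_law(matrix(c(2, 1, 0.2, 0.3, 1, 2), 2, 3, byrow = TRUE),
                     mesh$fs, gene_fs)
  full <- varifoldmap:::as_particles(apply_feature_law(mesh, pis))
  keep <- full$x[, 1] <= 100   # right half missing
  target <- particle_varifold(full$x[keep, ], full$w[keep],
                              full$p[keep, ], full$fs)
  # down-weight template simplices over the missing half
  mask <- as.numeric(mesh$centers[, 1] <= 100)
  cfg <- small_reg_config()
  cfg$norm$template_mask_weights <- mask
  cfg$rigid <- FALSE
  fit <- register_joint(mesh, target, cfg)
  tt <- fit$cost_trace
  expect_lt(tt$data[nrow(tt)], tt$data[1])
  expect_true(all(fit$diagnostics$jacobian > 0))
})

test_that("fit accessors expose the model components", {
  mesh <- fixture_mesh()
  gene_fs <- feature_space(c("a", "b", "c"))
  pis <- feature_law(matrix(c(2, 1, 0.2, 0.3, 1, 2), 2, 3, byrow = TRUE),
                     mesh$fs, gene_fs)
  target <- varifoldmap:::as_particles(apply_feature_law(mesh, pis))
  fit <- register_alternating(mesh, target, small_reg_config())
  expect_s3_class(coef(fit), "feature_law")
  pr <- predict(fit, rbind(c(50, 50), c(150, 100)), direction = "forward")
  expect_equal(dim(pr$points), c(2L, 2L))
  inv <- predict(fit, pr$points, direction = "inverse")
  expect_lt(max(abs(inv$points - rbind(c(50, 50), c(150, 100)))), 1)
  r <- residuals(fit)
  expect_equal(length(r), length(target$w))
  expect_output(print(fit), "registration")
  expect_output(print(summary(fit)), "entropy")
})
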