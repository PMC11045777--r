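atlas_fs <- feature_space(c("R1", "R2", "R3"))
gene_fs <- feature_space(paste0("g", 1:4))

test_that("apply_feature_law computes the mixture exactly", {
  pi <- feature_law(matrix(c(1, 0, 0, 2,
                             0, 3, 0, 0,
                             1, 1, 1, 1), 3, 4, byrow = TRUE),
                    atlas_fs, gene_fs)
  # delta atlas distribution: row copied, scaled by w
  mu <- particle_varifold(rbind(c(0, 0)), 2, rbind(c(0, 1, 0)), atlas_fs)
  out <- apply_feature_law(mu, pi)
  expect_equal(out$w, 6)                       # 2 * rowmass(R2)
  expect_equal(drop(out$p), c(g1 = 0, g2 = 1, g3 = 0, g4 = 0))

  # uniform mass m over |F| features: w' = w * m for every particle
  pim <- feature_law(matrix(0.5, 3, 4), atlas_fs, gene_fs)
  set.seed(22)
  mu2 <- particle_varifold(matrix(runif(10), 5, 2), runif(5, 0.5, 2),
                           t(replicate(5, {
                             v <- runif(3); v / sum(v)
                           })), atlas_fs)
  out2 <- apply_feature_law(mu2, pim)
  expect_equal(out2$w, mu2$w * 2, tolerance = 1e-12)

  # random mixture vs explicit double loop
  pir <- feature_law(matrix(runif(12), 3, 4), atlas_fs, gene_fs)
  out3 <- apply_feature_law(mu2, pir)
  for (i in 1:5) {
    v <- numeric(4)
    for (l in 1:3) v <- v + mu2$w[i] * mu2$p[i, l] * unclass(pir)[l, ]
    expect_equal(out3$w[i] * out3$p[i, ], v, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("apply_feature_law acts on mesh densities", {
  fs <- feature_space(c("R1", "R2"))
  tab <- data.frame(x = c(1, 9, 1, 9), y = c(1, 1, 9, 9),
                    feature = c("R1", "R1", "R2", "R2"))
  mesh <- build_mesh_varifold(tab, fs, resolution = 10)
  pi <- feature_law(matrix(c(2, 0, 1, 1), 2, 2, byrow = TRUE), fs, gene_fs2 <- feature_space(c("a", "b")))
  out <- apply_feature_law(mesh, pi)
  expect_s3_class(out, "mesh_varifold")
  expect_equal(sum(varifold_weights(out)),
               sum((mesh$p %*% unclass(pi)) * (mesh$alpha * mesh$areas)),
               tolerance = 1e-12)
})

test_that("default_bounds follows the nearest-rank percentile convention", {
  fs <- feature_space("a")
  mk <- function(w) particle_varifold(cbind(seq_along(w), 0), w,
                                      matrix(1, length(w), 1), fs)
  b1 <- default_bounds(mk(rep(3, 10)))
  expect_equal(b1$w_min, 3); expect_equal(b1$w_max, 3)
  b2 <- default_bounds(mk(1:100))
  expect_equal(b2$w_min, 5); expect_equal(b2$w_max, 100)
  b3 <- default_bounds(mk(1:100), constant_density = TRUE)
  expect_equal(b3$w_min, 1); expect_equal(b3$w_max, 1)
  expect_error(density_bounds(2, 1), "bounds")
})

test_that("solve_feature_qp matches the scalar closed form", {
  fs1 <- feature_space("R"); gf1 <- feature_space("g")
  set.seed(23)
  xa <- matrix(runif(10, 0, 60), 5, 2)
  wa <- runif(5, 0.5, 2)
  xt <- matrix(runif(8, 0, 60), 4, 2)
  wt <- runif(4, 0.5, 3)
  mu <- particle_varifold(xa, wa, matrix(1, 5, 1), fs1)
  tg <- particle_varifold(xt, wt, matrix(1, 4, 1), gf1)
  s <- 40
  law <- solve_feature_qp(mu, tg, norm_config(s), target_fs = gf1)
  Kaa <- exp(-as.matrix(dist(xa))^2 / (2 * s^2))
  Kat <- outer(seq_len(5), seq_len(4), Vectorize(function(i, j)
    exp(-sum((xa[i, ] - xt[j, ])^2) / (2 * s^2))))
  expect_equal(as.numeric(law),
               sum(Kat * outer(wa, wt)) / sum(Kaa * outer(wa, wa)),
               tolerance = 1e-10)
})

test_that("solve_feature_qp recovers a generative law exactly (noise-free)", {
  set.seed(24)
  n <- 40
  P <- matrix(runif(n * 3), n, 3); P <- P / rowSums(P)
  mu <- particle_varifold(matrix(runif(2 * n, 0, 200), n, 2),
                          runif(n, 0.5, 2), P, atlas_fs)
  pis <- feature_law(matrix(runif(12, 0.1, 2), 3, 4), atlas_fs, gene_fs)
  target <- apply_feature_law(mu, pis)
  law <- solve_feature_qp(mu, target, norm_config(60), target_fs = gene_fs)
  expect_lt(max(abs(unclass(law) - unclass(pis))), 1e-4)
  expect_equal(attr(law, "objective"),
               normed_difference(apply_feature_law(mu, law), target,
                                 norm_config(60)),
               tolerance = 1e-8)
})

test_that("the QP objective is convex along feasible segments", {
  set.seed(25)
  n <- 20
  P <- matrix(runif(n * 3), n, 3); P <- P / rowSums(P)
  mu <- particle_varifold(matrix(runif(2 * n, 0, 150), n, 2),
                          runif(n, 0.5, 2), P, atlas_fs)
  tg <- random_varifold(15, 4, spread = 150)
  tg <- particle_varifold(tg$x, tg$w, tg$p, gene_fs)
  obj <- function(Pi) normed_difference(
    apply_feature_law(mu, feature_law(Pi, atlas_fs, gene_fs)), tg,
    norm_config(70))
  for (i in 1:5) {
    P1 <- matrix(runif(12), 3, 4); P2 <- matrix(runif(12), 3, 4)
    lam <- runif(1)
    expect_lte(obj(lam * P1 + (1 - lam) * P2),
               lam * obj(P1) + (1 - lam) * obj(P2) + 1e-9)
  }
})

test_that("density bounds are honored or reported infeasible", {
  fs1 <- feature_space("R"); gf1 <- feature_space("g")
  # two atlas particles with proportional coefficient rows: w'_2 = 2 w'_1,
  # so w_min <= w'_1 and w'_2 <= w_max force 2 w_min <= w_max
  mu <- particle_varifold(rbind(c(0, 0), c(5, 0)), c(1, 2),
                          matrix(1, 2, 1), fs1)
  tg <- particle_varifold(rbind(c(1, 0)), 1.2, matrix(1, 1, 1), gf1)
  law <- solve_feature_qp(mu, tg, norm_config(50),
                          bounds = density_bounds(0.5, 4), target_fs = gf1)
  wprime <- drop((mu$p * mu$w) %*% rowSums(unclass(law)))
  expect_true(all(wprime >= 0.5 - 1e-7 & wprime <= 4 + 1e-7))

  expect_error(solve_feature_qp(mu, tg, norm_config(50),
                                bounds = density_bounds(1, 1.5),
                                target_fs = gf1),
               "infeasible")
})

test_that("active density bounds produce the constrained optimum", {
  # one atlas particle, one feature: optimum = projection of the
  # unconstrained solution onto [w_min, w_max]
  fs1 <- feature_space("R"); gf1 <- feature_space("g")
  mu <- particle_varifold(rbind(c(0, 0)), 1, matrix(1, 1, 1), fs1)
  tg <- particle_varifold(rbind(c(0, 0)), 5, matrix(1, 1, 1), gf1)
  law <- solve_feature_qp(mu, tg, norm_config(50),
                          bounds = density_bounds(1, 3), target_fs = gf1)
  expect_equal(as.numeric(law), 3, tolerance = 1e-7)
})

test_that("greedy assembly equals the full assembly for delta atlases", {
  set.seed(26)
  n <- 25
  lab <- sample(1:3, n, replace = TRUE)
  P <- matrix(0, n, 3); P[cbind(1:n, lab)] <- 1
  mu <- particle_varifold(matrix(runif(2 * n, 0, 150), n, 2),
                          runif(n, 0.5, 2), P, atlas_fs)
  tg <- random_varifold(20, 4, spread = 150)
  tg <- particle_varifold(tg$x, tg$w, tg$p, gene_fs)
  full <- solve_feature_qp(mu, tg, norm_config(60), target_fs = gene_fs)
  greedy <- solve_feature_qp(mu, tg, norm_config(60), use_greedy = TRUE,
                             target_fs = gene_fs)
  expect_lt(max(abs(unclass(full) - unclass(greedy))), 1e-8)
})

test_that("the optimal law scales linearly with the target mass", {
  set.seed(27)
  n <- 15
  P <- matrix(runif(n * 3), n, 3); P <- P / rowSums(P)
  mu <- particle_varifold(matrix(runif(2 * n, 0, 100), n, 2),
                          runif(n, 0.5, 2), P, atlas_fs)
  tg <- random_varifold(10, 4, spread = 100)
  tg <- particle_varifold(tg$x, tg$w, tg$p, gene_fs)
  l1 <- solve_feature_qp(mu, tg, norm_config(80), target_fs = gene_fs)
  tg3 <- particle_varifold(tg$x, 3 * tg$w, tg$p, gene_fs)
  l3 <- solve_feature_qp(mu, tg3, norm_config(80), target_fs = gene_fs)
  expect_equal(as.numeric(l3), 3 * as.numeric(l1), tolerance = 1e-6)
})

test_that("kl_regularizer matches hand computations", {
  pu <- feature_law(matrix(1 / 4, 2, 4), feature_space(c("A", "B")),
                    feature_space(paste0("g", 1:4)))
  kl <- kl_regularizer(pu)
  expect_equal(unname(kl$per_label), c(0, 0))
  expect_equal(kl$total, 0)

  pd <- matrix(0, 1, 8); pd[1, 3] <- 1
  kld <- kl_regularizer(pd)
  expect_equal(kld$total, log(8), tolerance = 1e-12)

  set.seed(28)
  pr <- matrix(runif(16, 0.01, 2), 2, 8)
  klr <- kl_regularizer(pr)
  manual <- sum(apply(pr, 1, function(r) {
    q <- r / sum(r); sum(q * log(q * 8))
  }))
  expect_equal(klr$total, manual, tolerance = 1e-12)

  pz <- rbind(c(1, 1), c(0, 0))
  expect_warning(klz <- kl_regularizer(pz), "zero-mass")
  expect_equal(unname(klz$per_label[2]), 0)
})

test_that("the operator-splitting solver agrees with active-set NNLS", {
  set.seed(29)
  L <- 6
  X <- matrix(rnorm(L * 12), 12, L)
  G <- crossprod(X) / 12
  b <- rnorm(L)
  x_nn <- varifoldmap:::nnls_active_set(G, b)
  sol <- varifoldmap:::admm_qp(2 * G, -2 * b, diag(L), rep(0, L),
                               rep(Inf, L))
  expect_equal(sol$status, "solved")
  expect_equal(sol$x, x_nn, tolerance = 1e-6)
  # KKT optimality of the NNLS solution
  grad <- 2 * (G %*% x_nn - b)
  expect_true(all(grad[x_nn < 1e-10] >= -1e-8))
  expect_lt(max(abs(grad[x_nn > 1e-10])), 1e-8)
})
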