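#' Registration configuration
#'
#' Settings for the joint estimation of a diffeomorphism and a feature law.
#' Defaults follow the kernel scale at which tissue sections are matched
#' (about 100 um), with the varifold norm summed over a coarse-to-fine set of
#' bandwidths so that both global placement and local boundaries contribute.
#'
#' @param norm a [norm_config()]; the default sums bandwidths 400, 200 and
#'   100 um.
#' @param sigma_schedule optional coarse-to-fine schedule: a list of
#'   `sigma_w` vectors, each stage warm-starting the next (mask weights are
#'   carried over).  The default runs the `norm` bandwidths first and then a
#'   100/50 um refinement stage.  Set to `NULL` for a single stage at
#'   `norm`.
#' @param outer_schedule outer alternations per schedule stage (recycled);
#'   defaults to `max_outer` for every stage.
#' @param sigma_v RKHS bandwidth of the velocity field (um).
#' @param n_steps number of forward-Euler timesteps of the flow.
#' @param n_ctrl cap on the number of control points (grid thinning of the
#'   template simplex centers).
#' @param mesh_resolution grid edge (um) used when a particle template must
#'   be meshed.
#' @param max_outer outer alternations (alternating scheme).
#' @param inner_maxit L-BFGS iterations per LDDMM phase.
#' @param joint_maxit total L-BFGS iterations for the joint scheme.
#' @param rel_tol relative cost-improvement stopping tolerance.
#' @param lambda_kl weight of the KL regularizer on the feature law (used by
#'   the joint scheme; the alternating scheme uses density bounds instead).
#' @param bounds_mode density prior for the alternating scheme's quadratic
#'   program: `"density"` (5th-percentile-to-maximum target density, scaled
#'   by simplex area), `"target"` (literal bounds on `w'` from the target
#'   weights), `"constant"` (`w_min = w_max = 1`), or `"none"`.
#' @param use_greedy collapse atlas label distributions to their dominant
#'   label in the quadratic program.
#' @param data_weight multiplier on the data-attachment term relative to the
#'   kinetic-energy regularizer.  The default `"auto"` sets
#'   `100 / mean(w_T)^2` (target masses measured in units of a tenth of the
#'   mean per-particle mass), which balances the two terms across target
#'   mass scales; any positive number overrides it.
#' @param rigid estimate a rigid+scale pre-alignment first.
#' @param rigid_angles starting angles for the rigid fit restarts.
#' @param seed integer seed recorded in the result and used for any
#'   stochastic choice.
#' @return An object of class `registration_config`.
#' @export
registration_config <- function(norm = norm_config(c(400, 200, 100)),
                                sigma_schedule = list(norm$sigma_w,
                                                      c(100, 50)),
                                outer_schedule = NULL,
                                sigma_v = 100, n_steps = 10L, n_ctrl = 2000L,
                                mesh_resolution = 50,
                                max_outer = 5L, inner_maxit = 100L,
                                joint_maxit = 200L, rel_tol = 1e-6,
                                lambda_kl = 1, bounds_mode = "density",
                                use_greedy = FALSE, data_weight = "auto",
                                rigid = TRUE, rigid_angles = 0, seed = 1L) {
  bounds_mode <- match.arg(bounds_mode,
                           c("density", "target", "constant", "none"))
  stopifnot(sigma_v > 0, n_steps >= 1L, max_outer >= 1L,
            identical(data_weight, "auto") || data_weight > 0)
  if (is.null(sigma_schedule)) sigma_schedule <- list(norm$sigma_w)
  if (is.null(outer_schedule)) outer_schedule <- max_outer
  outer_schedule <- rep_len(as.integer(outer_schedule),
                            length(sigma_schedule))
  structure(list(norm = norm, sigma_schedule = sigma_schedule,
                 outer_schedule = outer_schedule,
                 sigma_v = sigma_v, n_steps = as.integer(n_steps),
                 n_ctrl = as.integer(n_ctrl),
                 mesh_resolution = mesh_resolution,
                 max_outer = as.integer(max_outer),
                 inner_maxit = as.integer(inner_maxit),
                 joint_maxit = as.integer(joint_maxit),
                 rel_tol = rel_tol, lambda_kl = lambda_kl,
                 bounds_mode = bounds_mode, use_greedy = use_greedy,
                 data_weight = data_weight, rigid = rigid,
                 rigid_angles = rigid_angles, seed = as.integer(seed)),
            class = "registration_config")
}

#' Total registration cost
#'
#' The variational objective: kinetic energy of the flow plus the varifold
#' normed difference between the feature-transformed, deformed atlas and the
#' target, `1/2 int ||v_t||_V^2 dt + ||phi . mu_A^pi - mu_T||^2`, optionally
#' plus `lambda_kl` times the KL regularizer of the feature law.
#'
#' @param field a [velocity_field()].
#' @param pi a [feature_law()].
#' @param mu_A atlas varifold over the law's atlas labels.
#' @param mu_T target varifold.
#' @param cfg a [norm_config()].
#' @param lambda_kl KL regularizer weight (default 0).
#' @param data_weight multiplier on the data term.
#' @return list with `total`, `reg`, `data` and `kl`.
#' @export
total_cost <- function(field, pi, mu_A, mu_T, cfg = norm_config(),
                       lambda_kl = 0, data_weight = 1) {
  reg <- 0.5 * v_norm_sq(field)
  moved <- apply_diffeo(apply_feature_law(mu_A, pi),
                        diffeomorphism(field), direction = "forward")
  data <- normed_difference(moved, mu_T, cfg)
  kl <- if (lambda_kl > 0) kl_regularizer(pi)$total else 0
  list(total = reg + data_weight * data + lambda_kl * kl,
       reg = reg, data = data, kl = kl)
}

# --- internal cost/gradient engine on a mesh template ----------------------

# grid-thin a point set to at most n_max representatives (occupied-cell
# centroids); deterministic
thin_points <- function(x, n_max) {
  if (nrow(x) <= n_max) return(x)
  bb <- apply(x, 2L, range)
  h <- sqrt(prod(bb[2L, ] - bb[1L, ]) / n_max)
  repeat {
    key <- paste(floor(x[, 1L] / h), floor(x[, 2L] / h))
    if (length(unique(key)) <= n_max) break
    h <- h * 1.2
  }
  key <- factor(key, levels = unique(key))
  cbind(rowsum(x[, 1L], key, reorder = FALSE)[, 1L],
        rowsum(x[, 2L], key, reorder = FALSE)[, 1L]) / as.vector(table(key))
}

# cost/gradient engine for a (rigid-aligned) mesh template against a particle
# target; backpropagates through the Euler flow analytically
make_engine <- function(mesh, mu_T, config, q0) {
  V0 <- mesh$vertices
  S <- mesh$simplices
  alpha <- mesh$alpha
  P <- mesh$p
  tmask <- check_mask(config$norm$template_mask_weights, nrow(S), "template")
  if (is.null(tmask)) tmask <- rep(1, nrow(S))
  Tg <- as_particles(mu_T)
  wT <- Tg$w
  mt <- check_mask(config$norm$target_mask_weights, length(wT), "target")
  if (!is.null(mt)) wT <- wT * mt
  y <- Tg$x
  N <- Tg$p * wT
  sigmas <- config$norm$sigma_w
  const_T <- 0
  for (s in sigmas)
    const_T <- const_T + sum(cpp_gauss_mat(y, y, s) * tcrossprod(N))
  sv <- config$sigma_v
  Tn <- config$n_steps
  dt <- 1 / Tn
  dw <- config$data_weight
  if (identical(dw, "auto")) dw <- 100 / mean(wT)^2
  nV <- nrow(V0); nq <- nrow(q0); J <- nrow(S)
  i1 <- S[, 1L]; i2 <- S[, 2L]; i3 <- S[, 3L]

  accum <- function(idx, vals) {
    out <- matrix(0, nV, 2L)
    sm <- rowsum(vals, idx)
    out[as.integer(rownames(sm)), ] <- sm
    out
  }

  function(momenta, Pi, lambda_kl = 0, want_grad = TRUE) {
    xs <- vector("list", Tn); qs <- vector("list", Tn)
    Kxqs <- vector("list", Tn); Kqqs <- vector("list", Tn)
    x <- V0; q <- q0
    reg <- 0
    for (t in seq_len(Tn)) {
      a <- matrix(momenta[t, , ], ncol = 2L)
      xs[[t]] <- x; qs[[t]] <- q
      Kqq <- cpp_gauss_mat(q, q, sv)
      Kxq <- cpp_gauss_mat(x, q, sv)
      if (want_grad) { Kqqs[[t]] <- Kqq; Kxqs[[t]] <- Kxq }
      Ka <- Kqq %*% a
      reg <- reg + dt * sum(a * Ka)
      x <- x + dt * Kxq %*% a
      q <- q + dt * Ka
    }
    areas <- signed_areas(x, S)
    if (any(areas <= 0)) {
      return(list(cost = 1e12 * (1 + sum(pmax(-areas, 0))), reg = NA,
                  data = NA, kl = NA, folded = TRUE,
                  grad_a = if (want_grad) array(0, dim(momenta)),
                  grad_pi = if (want_grad) matrix(0, nrow(Pi), ncol(Pi))))
    }
    m <- simplex_centers(x, S)
    u <- alpha * areas * tmask
    R <- P %*% Pi
    M <- u * R
    data <- const_T
    Gm <- matrix(0, J, ncol(Pi))
    mbar <- matrix(0, J, 2L)
    CT <- tcrossprod(M)
    MN <- tcrossprod(M, N)
    for (s in sigmas) {
      K_AA <- cpp_gauss_mat(m, m, s)
      K_AT <- cpp_gauss_mat(m, y, s)
      data <- data + sum(K_AA * CT) - 2 * sum(K_AT * MN)
      if (want_grad) {
        Gm <- Gm + 2 * (K_AA %*% M - K_AT %*% N)
        mbar <- mbar + 2 * cpp_gauss_grad_xK(m, m, K_AA, CT, s) -
          2 * cpp_gauss_grad_xK(m, y, K_AT, MN, s)
      }
    }
    # the KL penalty rides on the data term's scale so that lambda_kl keeps
    # the same meaning whatever the target's mass units
    kl <- if (lambda_kl > 0) suppressWarnings(kl_regularizer(Pi)$total)
          else 0
    cost <- 0.5 * reg + dw * (data + lambda_kl * kl)
    if (!want_grad)
      return(list(cost = cost, reg = 0.5 * reg, data = data, kl = kl,
                  folded = FALSE))

    Gm <- dw * Gm
    mbar <- dw * mbar
    grad_pi <- crossprod(P, u * Gm)
    if (lambda_kl > 0) grad_pi <- grad_pi + dw * lambda_kl * kl_gradient(Pi)
    ubar <- rowSums(Gm * R)
    # vertex gradient: centers contribute mbar/3; areas contribute through
    # the signed-area derivative times ubar * alpha * mask
    co <- ubar * alpha * tmask
    x1 <- x[i1, , drop = FALSE]; x2 <- x[i2, , drop = FALSE]
    x3 <- x[i3, , drop = FALSE]
    Vbar <- accum(i1, mbar / 3 + 0.5 * co * cbind(x2[, 2L] - x3[, 2L],
                                                  x3[, 1L] - x2[, 1L])) +
      accum(i2, mbar / 3 + 0.5 * co * cbind(x3[, 2L] - x1[, 2L],
                                            x1[, 1L] - x3[, 1L])) +
      accum(i3, mbar / 3 + 0.5 * co * cbind(x1[, 2L] - x2[, 2L],
                                            x2[, 1L] - x1[, 1L]))

    xb <- Vbar
    qb <- matrix(0, nq, 2L)
    grad_a <- array(0, dim(momenta))
    for (t in rev(seq_len(Tn))) {
      xt <- xs[[t]]; qt <- qs[[t]]
      a <- matrix(momenta[t, , ], ncol = 2L)
      Kxq <- Kxqs[[t]]
      Kqq <- Kqqs[[t]]
      ga <- dt * (crossprod(Kxq, xb) + crossprod(Kqq, qb)) + dt * (Kqq %*% a)
      qb_new <- qb +
        dt * cpp_gauss_grad_xK(qt, xt, t(Kxq), a %*% t(xb), sv) +
        dt * cpp_gauss_grad_xK(qt, qt, Kqq,
                               qb %*% t(a) + a %*% t(qb) + tcrossprod(a), sv)
      xb <- xb + dt * cpp_gauss_grad_xK(xt, qt, Kxq, xb %*% t(a), sv)
      qb <- qb_new
      grad_a[t, , ] <- ga
    }
    list(cost = cost, reg = 0.5 * reg, data = data, kl = kl, folded = FALSE,
         grad_a = grad_a, grad_pi = grad_pi)
  }
}

# gradient of the total KL regularizer with respect to the (positive) law
kl_gradient <- function(Pi) {
  nF <- ncol(Pi)
  out <- matrix(0, nrow(Pi), nF)
  mass <- rowSums(Pi)
  for (l in which(mass > 0)) {
    pb <- Pi[l, ] / mass[l]
    nz <- pb > 0
    kl <- sum(pb[nz] * log(pb[nz] * nF))
    g <- numeric(nF)
    g[nz] <- (log(pb[nz] * nF) - kl) / mass[l]
    out[l, ] <- g
  }
  out
}

# mesh a particle template: expand each particle into per-feature point rows
mesh_template <- function(mu, resolution) {
  if (inherits(mu, "mesh_varifold")) return(mu)
  mu <- as_particles(mu)
  mass <- mu$p * mu$w
  nz <- which(mass > 0, arr.ind = TRUE)
  tab <- data.frame(x = mu$x[nz[, 1L], 1L], y = mu$x[nz[, 1L], 2L],
                    feature = mu$fs$labels[nz[, 2L]], count = mass[nz])
  build_mesh_varifold(tab, mu$fs, resolution)
}

# density bounds for the alternating scheme, per deformed-simplex area
make_qp_bounds <- function(config, mu_T, areas) {
  switch(config$bounds_mode,
    none = NULL,
    constant = density_bounds(1, 1),
    target = default_bounds(mu_T),
    density = {
      wT <- varifold_weights(mu_T)
      share <- support_area(mu_T) / length(wT)
      q5 <- sort(wT)[max(1L, ceiling(0.05 * length(wT)))] / share
      mx <- max(wT) / share
      density_bounds(q5 * areas, mx * areas)
    })
}

#' Register an atlas varifold onto a molecular target
#'
#' Fits the cross-modality mapping model: a rigid+scale pre-alignment, a
#' geodesic diffeomorphism of coordinates parameterized by an RKHS velocity
#' field, and a latent feature law carrying atlas labels into the target
#' feature space, minimizing [total_cost()].  The template is represented as
#' a mesh varifold (particle templates are meshed at
#' `config$mesh_resolution`) and deforms by the deformed-area action.
#'
#' Two optimization schemes are available.  `"alternating"` initializes the
#' law uniform and alternates LDDMM descent over the momenta (phase A) with
#' an exact constrained quadratic program over the law (phase B); each phase
#' cannot increase the cost.  `"joint"` optimizes momenta and law together by
#' quasi-Newton descent, with positivity of the law enforced by a softplus
#' reparameterization and a KL-to-uniform penalty of weight
#' `config$lambda_kl`.
#'
#' @param mu_A atlas varifold (mesh or particle) over the atlas label space.
#' @param mu_T target varifold over the target feature space.
#' @param scheme `"alternating"` or `"joint"`.
#' @param config a [registration_config()].
#' @return An object of class `xiv_lddmm`; see [coef.xiv_lddmm()],
#'   [predict.xiv_lddmm()], [summary.xiv_lddmm()].
#' @export
xiv_register <- function(mu_A, mu_T, scheme = c("alternating", "joint"),
                         config = registration_config()) {
  scheme <- match.arg(scheme)
  set.seed(config$seed)
  if (identical(config$data_weight, "auto"))
    config$data_weight <- 100 / mean(varifold_weights(mu_T))^2
  mesh0 <- mesh_template(mu_A, config$mesh_resolution)

  rs <- if (config$rigid) {
    fit_rigid_scale(mesh0, mu_T, config$norm, angles = config$rigid_angles)
  } else rigid_scale()
  mesh <- mesh_varifold(apply_rigid_scale(rs, mesh0$vertices), mesh0$simplices,
                        mesh0$alpha / rs$scale^2, mesh0$p, mesh0$fs)

  q0 <- thin_points(mesh$centers, config$n_ctrl)
  target_fs <- mu_T$fs
  # uniform initialization on the target's mass scale: pi_l(f) = m / |F|
  # with m the target/template total-mass ratio (m = 1, i.e. exactly 1/|F|,
  # when both are constant-density), so the first LDDMM phase matches
  # geometry rather than compensating a global mass imbalance
  mass_ratio <- sum(varifold_weights(mu_T)) / sum(varifold_weights(mesh))
  Pi <- unclass(uniform_feature_law(mesh$fs, target_fs)) * mass_ratio
  momenta <- array(0, dim = c(config$n_steps, nrow(q0), 2L))

  trace <- list()
  push <- function(phase, ev) {
    trace[[length(trace) + 1L]] <<- data.frame(
      phase = phase, reg = ev$reg, data = ev$data, kl = ev$kl,
      total = ev$cost, stringsAsFactors = FALSE)
  }

  converged <- FALSE
  for (k in seq_along(config$sigma_schedule)) {
    cfg_k <- config
    cfg_k$norm$sigma_w <- config$sigma_schedule[[k]]
    cfg_k$max_outer <- config$outer_schedule[k]
    engine <- make_engine(mesh, mu_T, cfg_k, q0)
    pre <- if (length(config$sigma_schedule) > 1L) paste0("s", k, ".") else ""
    push_k <- function(phase, ev) push(paste0(pre, phase), ev)
    if (scheme == "alternating") {
      res <- run_alternating(engine, mesh, mu_T, cfg_k, momenta, Pi, push_k,
                             q0)
    } else {
      if (k == 1L)
        push_k("init", engine(momenta, Pi, lambda_kl = cfg_k$lambda_kl,
                              want_grad = FALSE))
      # warm-start the law at the current geometry (one exact solve), then
      # descend jointly over momenta and law
      Pi <- tryCatch(qp_phase(engine, mesh, mu_T, cfg_k, momenta, Pi, q0)$pi,
                     error = function(e) Pi)
      res <- run_joint(engine, cfg_k, momenta, Pi, push_k)
    }
    momenta <- res$momenta; Pi <- res$pi
    converged <- res$converged
  }

  field <- velocity_field(q0, momenta, config$sigma_v, config$n_steps)
  phi <- diffeomorphism(field, rigid = rs)
  law <- feature_law(Pi, mesh$fs, target_fs)
  fl <- flow(field, mesh$vertices, "forward", jacobian = FALSE)
  def_areas <- signed_areas(fl$points, mesh$simplices)
  pibar <- unclass(law)
  rmass <- rowSums(pibar)
  ent <- ifelse(rmass > 0, entropy_map(pibar), 0)
  names(ent) <- mesh$fs$labels

  ct <- do.call(rbind, trace)
  structure(list(
    rigid = rs, diffeo = phi, feature_law = law,
    cost_trace = ct, scheme = scheme, config = config, seed = config$seed,
    template_mesh = mesh0, aligned_mesh = mesh,
    target = mu_T,
    diagnostics = list(jacobian = def_areas / mesh$areas * rs$scale^2,
                       entropy = ent),
    converged = converged),
    class = "xiv_lddmm")
}

# one quadratic-program phase at fixed momenta; returns the new law and
# whether the descent assertion applies (incoming law feasible)
qp_phase <- function(engine, mesh, mu_T, config, momenta, Pi, q0) {
  fl <- flow(velocity_field(q0, momenta, config$sigma_v, config$n_steps),
             mesh$vertices, "forward", jacobian = FALSE)
  deformed <- mesh_varifold(fl$points, mesh$simplices, mesh$alpha, mesh$p,
                            mesh$fs)
  bounds <- make_qp_bounds(config, mu_T, deformed$areas)
  feasible_in <- qp_feasible(deformed, Pi, bounds)
  law <- solve_feature_qp(deformed, mu_T, config$norm, bounds = bounds,
                          use_greedy = config$use_greedy,
                          target_fs = mu_T$fs)
  list(pi = unclass(law), feasible_in = feasible_in)
}

run_alternating <- function(engine, mesh, mu_T, config, momenta, Pi, push,
                            q0) {
  ev <- engine(momenta, Pi, want_grad = FALSE)
  push("init", ev)
  # initial law solve at the pre-aligned geometry, so the first LDDMM phase
  # already sees the region-to-feature structure
  b0 <- qp_phase(engine, mesh, mu_T, config, momenta, Pi, q0)
  ev_b0 <- engine(momenta, b0$pi, want_grad = FALSE)
  if (b0$feasible_in) stopifnot(ev_b0$cost <= ev$cost * (1 + 1e-6) + 1e-6)
  Pi <- b0$pi
  push("B0", ev_b0)
  last_total <- ev_b0$cost
  converged <- FALSE
  for (outer in seq_len(config$max_outer)) {
    # phase A: LDDMM over momenta at fixed law
    before <- engine(momenta, Pi, want_grad = FALSE)$cost
    opt <- optim_momenta(engine, momenta, Pi, config$inner_maxit)
    stopifnot(opt$value <= before * (1 + 1e-6) + 1e-6)
    momenta <- opt$momenta
    push(paste0("A", outer), engine(momenta, Pi, want_grad = FALSE))

    # phase B: quadratic program over the law at fixed flow
    bph <- qp_phase(engine, mesh, mu_T, config, momenta, Pi, q0)
    ev_new <- engine(momenta, bph$pi, want_grad = FALSE)
    ev_old <- engine(momenta, Pi, want_grad = FALSE)
    if (bph$feasible_in)
      stopifnot(ev_new$cost <= ev_old$cost * (1 + 1e-6) + 1e-6)
    Pi <- bph$pi
    push(paste0("B", outer), ev_new)

    if (last_total - ev_new$cost < config$rel_tol * max(abs(last_total), 1)) {
      converged <- TRUE
      last_total <- ev_new$cost
      break
    }
    last_total <- ev_new$cost
  }
  list(momenta = momenta, pi = Pi, converged = converged)
}

# does the current law satisfy the bound rows (used to decide whether the
# B-phase descent assertion applies)?
qp_feasible <- function(deformed, Pi, bounds) {
  if (is.null(bounds)) return(TRUE)
  u <- varifold_weights(deformed)
  wprime <- drop((deformed$p * u) %*% rowSums(Pi))
  w_min <- rep_len(bounds$w_min, length(wprime))
  w_max <- rep_len(bounds$w_max, length(wprime))
  tol <- 1e-9 * max(1, max(w_max))
  all(wprime >= w_min - tol & wprime <= w_max + tol)
}

optim_momenta <- function(engine, momenta, Pi, maxit) {
  dm <- dim(momenta)
  if (maxit <= 0L)
    return(list(momenta = momenta,
                value = engine(momenta, Pi, want_grad = FALSE)$cost))
  cache <- new.env(parent = emptyenv())
  evaluate <- function(par) {
    key <- paste0(format(sum(par * seq_along(par)), digits = 17),
                  format(sum(par^2), digits = 17))
    if (!identical(cache$key, key)) {
      cache$res <- engine(array(par, dm), Pi, want_grad = TRUE)
      cache$key <- key
    }
    cache$res
  }
  fn <- function(par) evaluate(par)$cost
  gr <- function(par) as.numeric(evaluate(par)$grad_a)
  fit <- stats::optim(as.numeric(momenta), fn, gr, method = "L-BFGS-B",
                      control = list(maxit = maxit, factr = 1e7))
  list(momenta = array(fit$par, dm), value = fit$value)
}

run_joint <- function(engine, config, momenta, Pi, push) {
  dm <- dim(momenta)
  np <- length(Pi)
  softplus <- function(t) ifelse(t > 30, t, log1p(exp(t)))
  inv_softplus <- function(p) ifelse(p > 30, p, log(expm1(p)))
  theta <- inv_softplus(pmax(Pi, 1e-8))
  par <- c(as.numeric(momenta), as.numeric(theta))
  lam <- config$lambda_kl
  cache <- new.env(parent = emptyenv())
  evaluate <- function(p) {
    key <- paste0(format(sum(p * seq_along(p)), digits = 17),
                  format(sum(p^2), digits = 17))
    if (!identical(cache$key, key)) {
      a <- array(p[seq_len(prod(dm))], dm)
      th <- matrix(p[prod(dm) + seq_len(np)], nrow(Pi), ncol(Pi))
      pim <- matrix(softplus(as.numeric(th)), nrow(Pi), ncol(Pi))
      res <- engine(a, pim, lambda_kl = lam, want_grad = TRUE)
      res$grad_theta <- res$grad_pi * stats::plogis(th)
      cache$res <- res
      cache$key <- key
    }
    cache$res
  }
  fn <- function(p) evaluate(p)$cost
  gr <- function(p) c(as.numeric(evaluate(p)$grad_a),
                      as.numeric(evaluate(p)$grad_theta))
  push("warm", engine(momenta, Pi, lambda_kl = lam, want_grad = FALSE))
  done <- 0L
  converged <- FALSE
  last <- Inf
  while (done < config$joint_maxit) {
    step <- min(25L, config$joint_maxit - done)
    fit <- stats::optim(par, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = step, factr = 1e7))
    par <- fit$par
    done <- done + step
    a <- array(par[seq_len(prod(dm))], dm)
    pim <- matrix(softplus(par[prod(dm) + seq_len(np)]), nrow(Pi), ncol(Pi))
    ev <- engine(a, pim, lambda_kl = lam, want_grad = FALSE)
    push(paste0("iter", done), ev)
    if (last - ev$cost < config$rel_tol * max(abs(last), 1)) {
      converged <- TRUE
      break
    }
    last <- ev$cost
    if (fit$convergence == 0) { converged <- TRUE; break }
  }
  a <- array(par[seq_len(prod(dm))], dm)
  pim <- matrix(softplus(par[prod(dm) + seq_len(np)]), nrow(Pi), ncol(Pi))
  list(momenta = a, pi = pim, converged = converged)
}

#' @export
print.xiv_lddmm <- function(x, ...) {
  tt <- x$cost_trace
  cat("Cross-modality image-varifold registration (", x$scheme,
      " scheme)\n", sep = "")
  cat("  template: ", nrow(x$aligned_mesh$simplices), " simplices over ",
      x$aligned_mesh$fs$size, " atlas labels\n", sep = "")
  cat("  target:   ", length(varifold_weights(x$target)), " particles over ",
      x$target$fs$size, " features\n", sep = "")
  cat("  rigid+scale: angle ", format(x$rigid$angle, digits = 4),
      " rad, scale ", format(x$rigid$scale, digits = 4), "\n", sep = "")
  cat("  cost: ", format(tt$total[1L]), " -> ",
      format(tt$total[nrow(tt)]), " in ", nrow(tt) - 1L, " phases\n",
      sep = "")
  invisible(x)
}

#' Extract the fitted feature law
#'
#' @param object an `xiv_lddmm` fit.
#' @param ... unused.
#' @return The fitted [feature_law()] matrix.
#' @method coef xiv_lddmm
#' @export
coef.xiv_lddmm <- function(object, ...) object$feature_law

#' Map new points through a fitted registration
#'
#' @param object an `xiv_lddmm` fit.
#' @param newdata n x 2 matrix or data frame with columns `x`, `y`.
#' @param direction `"forward"` (atlas to target coordinates) or
#'   `"inverse"`.
#' @param ... unused.
#' @return list with mapped `points` and Jacobian determinants `jac`.
#' @method predict xiv_lddmm
#' @export
predict.xiv_lddmm <- function(object, newdata,
                              direction = c("forward", "inverse"), ...) {
  direction <- match.arg(direction)
  if (is.data.frame(newdata)) newdata <- cbind(newdata$x, newdata$y)
  map_points(object$diffeo, newdata, direction)
}

#' @export
summary.xiv_lddmm <- function(object, ...) {
  tt <- object$cost_trace
  jac <- object$diagnostics$jacobian
  out <- list(scheme = object$scheme,
              phases = nrow(tt) - 1L,
              cost_initial = tt$total[1L],
              cost_final = tt$total[nrow(tt)],
              data_final = tt$data[nrow(tt)],
              reg_final = tt$reg[nrow(tt)],
              jacobian_range = range(jac),
              entropy = object$diagnostics$entropy,
              row_mass = rowSums(unclass(object$feature_law)),
              converged = object$converged)
  class(out) <- "summary.xiv_lddmm"
  out
}

#' @export
print.summary.xiv_lddmm <- function(x, ...) {
  cat("xIV-LDDMM registration summary (", x$scheme, ")\n", sep = "")
  cat("  cost ", format(x$cost_initial), " -> ", format(x$cost_final),
      " over ", x$phases, " phases; converged: ", x$converged, "\n", sep = "")
  cat("  final data term ", format(x$data_final), ", kinetic energy ",
      format(x$reg_final), "\n", sep = "")
  cat("  |Dphi| range [", format(x$jacobian_range[1L], digits = 4), ", ",
      format(x$jacobian_range[2L], digits = 4), "]\n", sep = "")
  cat("  per-label predicted mass and feature entropy:\n")
  print(round(cbind(mass = x$row_mass, entropy = x$entropy), 4))
  invisible(x)
}

#' Plot a fitted registration
#'
#' `type = "trace"` shows the cost components across optimization phases;
#' `type = "jacobian"` shows per-simplex area change at the deformed simplex
#' centers; `type = "mesh"` overlays the deformed template centers on the
#' target particles.
#'
#' @param x an `xiv_lddmm` fit.
#' @param type one of `"trace"`, `"jacobian"`, `"mesh"`.
#' @param ... passed to the underlying plotting call.
#' @method plot xiv_lddmm
#' @export
plot.xiv_lddmm <- function(x, type = c("trace", "jacobian", "mesh"), ...) {
  type <- match.arg(type)
  if (type == "trace") {
    tt <- x$cost_trace
    graphics::plot(seq_len(nrow(tt)) - 1L, tt$total, type = "b",
                   xlab = "phase", ylab = "cost", log = "y",
                   main = "registration cost", ...)
    graphics::lines(seq_len(nrow(tt)) - 1L, tt$data, col = 2, type = "b")
    graphics::legend("topright", c("total", "data term"), col = c(1, 2),
                     lty = 1, bty = "n")
  } else {
    fl <- flow(x$diffeo$field, x$aligned_mesh$vertices, "forward",
               jacobian = FALSE)
    ctr <- simplex_centers(fl$points, x$aligned_mesh$simplices)
    if (type == "jacobian") {
      jac <- x$diagnostics$jacobian
      cols <- grDevices::hcl.colors(64, "Blue-Red 2")
      idx <- pmin(64L, pmax(1L, findInterval(jac, seq(min(jac), max(jac),
                                                      length.out = 65L),
                                             all.inside = TRUE)))
      graphics::plot(ctr, col = cols[idx], pch = 15,
                     xlab = "x (um)", ylab = "y (um)",
                     main = "|Dphi| (blue contraction, red expansion)", ...)
    } else {
      ty <- varifold_positions(x$target)
      graphics::plot(ty, pch = ".", col = "grey50", xlab = "x (um)",
                     ylab = "y (um)", main = "deformed template vs target",
                     ...)
      graphics::points(ctr, pch = 3, col = 2, cex = 0.5)
    }
  }
  invisible(x)
}

#' Kernel-space residuals of a fitted registration
#'
#' Evaluates the witness function of the kernel embedding of the fitted
#' minus the target measure at the target locations: large values flag
#' regions where predicted and observed feature mass disagree at the norm's
#' scale.
#'
#' @param object an `xiv_lddmm` fit.
#' @param ... unused.
#' @return numeric vector, one residual per target location (signed total
#'   mass discrepancy smoothed at the finest configured bandwidth).
#' @export
residuals.xiv_lddmm <- function(object, ...) {
  moved <- apply_diffeo(apply_feature_law(object$aligned_mesh,
                                          object$feature_law),
                        diffeomorphism(object$diffeo$field))
  s <- min(object$config$norm$sigma_w)
  Tg <- as_particles(object$target)
  mv <- as_particles(moved)
  drop(cpp_gauss_mat(Tg$x, mv$x, s) %*% mv$w) -
    drop(cpp_gauss_mat(Tg$x, Tg$x, s) %*% Tg$w)
}

#' Registration drivers by scheme
#'
#' Convenience wrappers around [xiv_register()] fixing the optimization
#' scheme: `register_alternating()` runs the alternating LDDMM /
#' quadratic-program algorithm, `register_joint()` the simultaneous
#' quasi-Newton scheme.
#'
#' @inheritParams xiv_register
#' @return An `xiv_lddmm` fit.
#' @export
register_alternating <- function(mu_A, mu_T, config = registration_config()) {
  xiv_register(mu_A, mu_T, scheme = "alternating", config = config)
}

#' @rdname register_alternating
#' @export
register_joint <- function(mu_A, mu_T, config = registration_config()) {
  xiv_register(mu_A, mu_T, scheme = "joint", config = config)
}
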