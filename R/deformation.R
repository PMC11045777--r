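#' Time-discretized RKHS velocity field
#'
#' Parameterizes a flow of diffeomorphisms by momenta attached to control
#' points: at timestep t the velocity is the kernel expansion
#' `v_t(x) = sum_k K_V(x, q_k(t)) a_k(t)` with a Gaussian kernel of bandwidth
#' `sigma_v`.  Control points are advected by their own field, so `q_k(t)` is
#' the forward-flowed position of `control_points`.
#'
#' @param control_points n x 2 matrix of control point positions at t = 0.
#' @param momenta T x n x 2 array of per-timestep momentum vectors (or NULL
#'   for all-zero momenta).
#' @param sigma_v kernel bandwidth in micrometres (> 0).
#' @param n_steps number of forward-Euler timesteps T (>= 1).
#' @return An object of class `velocity_field`.
#' @export
velocity_field <- function(control_points, momenta = NULL, sigma_v = 100,
                           n_steps = 10L) {
  q0 <- as_xy_matrix(control_points)
  n_steps <- as.integer(n_steps)
  if (n_steps < 1L) stop("n_steps must be >= 1")
  if (sigma_v <= 0) stop("sigma_v must be positive")
  if (is.null(momenta)) momenta <- array(0, dim = c(n_steps, nrow(q0), 2L))
  momenta <- array(as.numeric(momenta), dim = c(n_steps, nrow(q0), 2L))
  structure(list(q0 = q0, momenta = momenta, sigma_v = sigma_v,
                 n_steps = n_steps),
            class = "velocity_field")
}

momenta_at <- function(field, t) {
  matrix(field$momenta[t, , ], ncol = 2L)
}

# control point positions at the start of each timestep (list of length T+1;
# entry t is q at time (t-1)/T, entry T+1 the endpoint)
control_trajectory <- function(field) {
  dt <- 1 / field$n_steps
  q <- field$q0
  traj <- vector("list", field$n_steps + 1L)
  traj[[1L]] <- q
  for (t in seq_len(field$n_steps)) {
    q <- q + dt * cpp_gauss_mv(q, q, field$sigma_v, momenta_at(field, t))
    traj[[t + 1L]] <- q
  }
  traj
}

#' Evaluate the velocity field at a timestep
#'
#' Kernel-weighted sum of the momenta against the current (advected) control
#' point positions.
#'
#' @param field a [velocity_field()].
#' @param t timestep index in `1..n_steps`.
#' @param points query points (n x 2).
#' @return n x 2 matrix of velocity vectors.
#' @export
velocity_at <- function(field, t, points) {
  t <- as.integer(t)
  if (t < 1L || t > field$n_steps) stop("timestep out of range")
  q <- control_trajectory(field)[[t]]
  cpp_gauss_mv(as_xy_matrix(points), q, field$sigma_v, momenta_at(field, t))
}

#' Integrated squared RKHS norm of a velocity field
#'
#' The LDDMM kinetic energy `int_0^1 ||v_t||_V^2 dt`, discretized as
#' `sum_t (1/T) a_t' K_V(q_t, q_t) a_t`; zero iff all momenta vanish.
#'
#' @param field a [velocity_field()].
#' @return nonnegative scalar.
#' @export
v_norm_sq <- function(field) {
  dt <- 1 / field$n_steps
  traj <- control_trajectory(field)
  total <- 0
  for (t in seq_len(field$n_steps)) {
    a <- momenta_at(field, t)
    Ka <- cpp_gauss_mv(traj[[t]], traj[[t]], field$sigma_v, a)
    total <- total + dt * sum(a * Ka)
  }
  total
}

#' Flow points through a velocity field
#'
#' Forward: Euler integration `x <- x + dt * v_t(x)` for t = 1..T, with the
#' Jacobian co-integrated analytically from kernel derivatives as
#' `D <- (I + dt * Dv_t(x)) D`.  Inverse: integration with negated velocities
#' in reversed time order, anchored at the forward control-point trajectory
#' (the discrete approximate inverse, exact as T grows).
#'
#' @param field a [velocity_field()].
#' @param points n x 2 matrix of points to map.
#' @param direction `"forward"` or `"inverse"`.
#' @param jacobian if TRUE (default) also return the Jacobian determinant of
#'   the map at each input point.
#' @return list with `points` (mapped n x 2) and `jac` (length-n vector of
#'   `|Dphi|`, or NULL when `jacobian = FALSE`).
#' @export
flow <- function(field, points, direction = c("forward", "inverse"),
                 jacobian = TRUE) {
  direction <- match.arg(direction)
  x <- as_xy_matrix(points)
  n <- nrow(x)
  dt <- 1 / field$n_steps
  traj <- control_trajectory(field)
  # Jacobian accumulated per point as flattened 2x2 (d11, d12, d21, d22)
  D <- if (jacobian) cbind(rep(1, n), 0, 0, rep(1, n)) else NULL
  steps <- if (direction == "forward") seq_len(field$n_steps)
           else rev(seq_len(field$n_steps))
  sgn <- if (direction == "forward") 1 else -1
  for (t in steps) {
    q <- traj[[t]]
    a <- momenta_at(field, t)
    v <- cpp_gauss_mv(x, q, field$sigma_v, a)
    if (jacobian) {
      Dv <- cpp_velocity_jac(x, q, field$sigma_v, a)
      # (I + sgn*dt*Dv) %*% D, componentwise over points
      s11 <- 1 + sgn * dt * Dv[, 1L]; s12 <- sgn * dt * Dv[, 2L]
      s21 <- sgn * dt * Dv[, 3L];     s22 <- 1 + sgn * dt * Dv[, 4L]
      D <- cbind(s11 * D[, 1L] + s12 * D[, 3L],
                 s11 * D[, 2L] + s12 * D[, 4L],
                 s21 * D[, 1L] + s22 * D[, 3L],
                 s21 * D[, 2L] + s22 * D[, 4L])
    }
    x <- x + sgn * dt * v
  }
  jac <- NULL
  if (jacobian) {
    jac <- D[, 1L] * D[, 4L] - D[, 2L] * D[, 3L]
    if (any(jac <= 0))
      stop("flow not diffeomorphic at this resolution (|Dphi| <= 0)")
  }
  list(points = x, jac = jac)
}

#' Diffeomorphism of the plane
#'
#' Bundles a velocity field with an optional rigid+scale pre-transform into a
#' re-appliable coordinate mapping.  The forward map is
#' `phi(x) = flow(rigid(x))`; the inverse undoes the flow then the rigid
#' part.  The Jacobian determinant combines the flow Jacobian with the
#' squared rigid scale factor.
#'
#' @param field a [velocity_field()].
#' @param rigid optional [rigid_scale()] pre-transform applied before the
#'   flow.
#' @param direction default mapping direction, `"forward"` or `"inverse"`.
#' @return An object of class `diffeomorphism`.
#' @export
diffeomorphism <- function(field, rigid = NULL,
                           direction = c("forward", "inverse")) {
  direction <- match.arg(direction)
  stopifnot(inherits(field, "velocity_field"))
  if (!is.null(rigid)) stopifnot(inherits(rigid, "rigid_scale"))
  structure(list(field = field, rigid = rigid, direction = direction,
                 trajectory = control_trajectory(field)),
            class = "diffeomorphism")
}

#' @export
print.diffeomorphism <- function(x, ...) {
  cat("<diffeomorphism> ", nrow(x$field$q0), " control points, T = ",
      x$field$n_steps, ", sigma_v = ", x$field$sigma_v, " um",
      if (!is.null(x$rigid)) ", with rigid+scale pre-transform" else "",
      "\n", sep = "")
  invisible(x)
}

#' Map points through a diffeomorphism
#'
#' @param phi a [diffeomorphism()].
#' @param points n x 2 matrix.
#' @param direction `"forward"` (atlas to target) or `"inverse"`; defaults to
#'   the direction stored in `phi`.
#' @param jacobian also return `|Dphi|` at the input points.
#' @return list with `points` and `jac` (NULL when `jacobian = FALSE`).
#' @export
map_points <- function(phi, points, direction = NULL, jacobian = TRUE) {
  if (is.null(direction)) direction <- phi$direction
  direction <- match.arg(direction, c("forward", "inverse"))
  x <- as_xy_matrix(points)
  if (direction == "forward") {
    if (!is.null(phi$rigid)) x <- apply_rigid_scale(phi$rigid, x)
    fl <- flow(phi$field, x, "forward", jacobian)
    jac <- fl$jac
    if (jacobian && !is.null(phi$rigid)) jac <- jac * phi$rigid$scale^2
    list(points = fl$points, jac = jac)
  } else {
    fl <- flow(phi$field, x, "inverse", jacobian)
    y <- fl$points
    jac <- fl$jac
    if (!is.null(phi$rigid)) {
      y <- apply_rigid_scale(phi$rigid, y, inverse = TRUE)
      if (jacobian) jac <- jac / phi$rigid$scale^2
    }
    list(points = y, jac = jac)
  }
}

#' Apply a diffeomorphism to an image varifold
#'
#' Particle varifolds transform as
#' `phi . mu = sum_i |Dphi|_{x_i} w_i delta_{phi(x_i)} (x) p_i`: positions are
#' mapped, weights are multiplied by the Jacobian determinant so spatial
#' density is preserved, and feature distributions are unchanged.  Mesh
#' varifolds transform by mapping the vertices and recomputing centers;
#' densities `alpha_j` are unchanged and the effective weight of a simplex
#' becomes `alpha_j * |deformed area|` (the deformed-area approximation of
#' `|Dphi|_{m_j} |gamma_j|`).
#'
#' @param mu an image varifold.
#' @param phi a [diffeomorphism()].
#' @param direction mapping direction; defaults to the direction in `phi`.
#' @return A transformed varifold of the same class as `mu`.
#' @export
apply_diffeo <- function(mu, phi, direction = NULL) {
  UseMethod("apply_diffeo")
}

#' @export
apply_diffeo.particle_varifold <- function(mu, phi, direction = NULL) {
  if (inherits(phi, "affine_map"))
    return(apply_diffeo_affine(mu, phi, direction %||% "forward"))
  mp <- map_points(phi, mu$x, direction, jacobian = TRUE)
  particle_varifold(mp$points, mu$w * mp$jac, mu$p, mu$fs)
}

#' @export
apply_diffeo.mesh_varifold <- function(mu, phi, direction = NULL) {
  if (inherits(phi, "affine_map"))
    return(apply_diffeo_affine(mu, phi, direction %||% "forward"))
  mp <- map_points(phi, mu$vertices, direction, jacobian = FALSE)
  v <- mp$points
  if (any(signed_areas(v, mu$simplices) <= 0))
    stop("mesh fold-over: deformation too large for this kernel scale")
  mesh_varifold(v, mu$simplices, mu$alpha, mu$p, mu$fs)
}

#' Affine map of the plane
#'
#' `x -> A x + b` with `det(A) > 0`: the simplest family of diffeomorphisms,
#' with exact constant Jacobian determinant, useful for validating the
#' varifold actions analytically.  Supports [apply_diffeo()] like a flow.
#'
#' @param A 2 x 2 matrix with positive determinant.
#' @param b length-2 translation.
#' @return An object of class `affine_map`.
#' @export
affine_map <- function(A, b = c(0, 0)) {
  A <- matrix(as.numeric(A), 2L, 2L)
  if (det(A) <= 0) stop("affine map must be orientation-preserving")
  structure(list(A = A, b = as.numeric(b)), class = "affine_map")
}

#' @export
apply_diffeo.default <- function(mu, phi, direction = NULL) {
  stop("cannot apply a diffeomorphism to an object of class ",
       paste(class(mu), collapse = "/"))
}

apply_affine_points <- function(phi, x, inverse = FALSE) {
  if (inverse) sweep(x, 2L, phi$b) %*% t(solve(phi$A))
  else sweep(x %*% t(phi$A), 2L, phi$b, "+")
}

apply_diffeo_affine <- function(mu, phi, direction = "forward") {
  inv <- identical(direction, "inverse")
  jac <- if (inv) 1 / det(phi$A) else det(phi$A)
  if (inherits(mu, "mesh_varifold")) {
    v <- apply_affine_points(phi, mu$vertices, inv)
    if (any(signed_areas(v, mu$simplices) <= 0))
      stop("mesh fold-over: deformation too large for this kernel scale")
    return(mesh_varifold(v, mu$simplices, mu$alpha, mu$p, mu$fs))
  }
  mu <- as_particles(mu)
  particle_varifold(apply_affine_points(phi, mu$x, inv), mu$w * jac, mu$p,
                    mu$fs)
}

#' Rigid + isotropic scale transform
#'
#' `x -> R(angle) (scale * (x - center)) + center + translation`, the
#' pre-alignment applied to the template before diffeomorphic matching.
#'
#' @param angle rotation angle in radians.
#' @param translation length-2 translation in micrometres.
#' @param scale isotropic scale factor (> 0).
#' @param center length-2 center of rotation/scaling (the template centroid).
#' @return An object of class `rigid_scale`.
#' @export
rigid_scale <- function(angle = 0, translation = c(0, 0), scale = 1,
                        center = c(0, 0)) {
  if (scale <= 0) stop("scale must be positive")
  structure(list(angle = as.numeric(angle),
                 translation = as.numeric(translation),
                 scale = as.numeric(scale), center = as.numeric(center)),
            class = "rigid_scale")
}

#' Apply (or invert) a rigid+scale transform to points
#'
#' @param rs a [rigid_scale()].
#' @param points n x 2 matrix.
#' @param inverse apply the inverse transform.
#' @return n x 2 matrix of transformed points.
#' @export
apply_rigid_scale <- function(rs, points, inverse = FALSE) {
  x <- as_xy_matrix(points)
  R <- matrix(c(cos(rs$angle), sin(rs$angle),
                -sin(rs$angle), cos(rs$angle)), 2L, 2L)
  if (!inverse) {
    sweep(rs$scale * sweep(x, 2L, rs$center) %*% t(R), 2L,
          rs$center + rs$translation, "+")
  } else {
    sweep(sweep(x, 2L, rs$center + rs$translation) %*% R / rs$scale, 2L,
          rs$center, "+")
  }
}

# weighted centroid of a varifold
varifold_centroid <- function(mu) {
  w <- varifold_weights(mu)
  drop(crossprod(varifold_positions(mu), w)) / sum(w)
}

# total physical area of the support: mesh area, or convex hull area for
# particle varifolds
support_area <- function(mu) {
  if (inherits(mu, "mesh_varifold")) return(sum(mu$areas))
  x <- varifold_positions(mu)
  if (nrow(x) < 3L) return(0)
  hull <- grDevices::chull(x)
  hx <- x[hull, 1L]; hy <- x[hull, 2L]
  abs(sum(hx * c(hy[-1L], hy[1L]) - c(hx[-1L], hx[1L]) * hy)) / 2
}

#' Estimate a rigid + isotropic scale pre-alignment
#'
#' The scale brings the total support area of the template to equal that of
#' the target (mesh area, or convex-hull area for particle varifolds),
#' applied about the template's weighted centroid.  Rotation and translation
#' then minimize the varifold normed difference by quasi-Newton optimization
#' starting from angle 0, optionally restarted over a grid of starting
#' angles.  When the two varifolds live on different feature spaces the
#' matching is performed on their total-mass (feature-collapsed) measures.
#'
#' @param mu_A template varifold.
#' @param mu_T target varifold.
#' @param cfg a [norm_config()].
#' @param angles starting angles (radians) for restarts; the best final cost
#'   wins.
#' @param maxit maximum optimizer iterations per restart.
#' @return A [rigid_scale()].
#' @export
fit_rigid_scale <- function(mu_A, mu_T, cfg = norm_config(), angles = 0,
                            maxit = 200L) {
  area_A <- support_area(mu_A)
  area_T <- support_area(mu_T)
  if (area_A <= 0) stop("degenerate (zero-area) template")
  if (area_T <= 0) stop("degenerate (zero-area) target")
  s <- sqrt(area_T / area_A)
  ctr <- varifold_centroid(mu_A)

  A <- as_particles(mu_A); Tg <- as_particles(mu_T)
  if (!same_feature_space(A$fs, Tg$fs)) {
    A <- mass_only(A); Tg <- mass_only(Tg)
  }
  obj <- function(par) {
    rs <- rigid_scale(par[1L], par[2:3], s, ctr)
    moved <- particle_varifold(apply_rigid_scale(rs, A$x), A$w, A$p, A$fs)
    normed_difference(moved, Tg, cfg)
  }
  # start translation at the centroid offset; scale the angle coordinate so
  # quasi-Newton steps are commensurate with the translation coordinates
  t0 <- varifold_centroid(Tg) - ctr
  best <- NULL
  for (a0 in angles) {
    fit <- stats::optim(c(a0, t0), obj, method = "BFGS",
                        control = list(maxit = maxit, reltol = 1e-8,
                                       parscale = c(0.05, 20, 20)))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  rigid_scale(best$par[1L], best$par[2:3], s, ctr)
}

# collapse a particle varifold to a single "mass" feature
mass_only <- function(mu) {
  mu <- as_particles(mu)
  fs <- feature_space("mass")
  particle_varifold(mu$x, mu$w, matrix(1, length(mu$w), 1L), fs)
}
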