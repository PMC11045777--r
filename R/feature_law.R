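#' Latent per-region feature law
#'
#' A nonnegative matrix `pi` with one row per atlas label and one column per
#' target feature.  Row `l` is the unnormalized distribution `pi_l` over
#' target features assigned to atlas region `l` under the spatial-homogeneity
#' assumption; its row mass carries the predicted target density (mRNA or
#' cells per unit atlas mass).
#'
#' @param pi numeric |L| x |F| matrix, entries >= 0.
#' @param atlas_fs [feature_space()] of atlas labels (rows).
#' @param target_fs [feature_space()] of target features (columns).
#' @return An object of class `feature_law` (a matrix with dimnames and
#'   feature-space attributes).
#' @export
feature_law <- function(pi, atlas_fs, target_fs) {
  pi <- as.matrix(pi)
  stopifnot(inherits(atlas_fs, "feature_space"),
            inherits(target_fs, "feature_space"))
  if (nrow(pi) != atlas_fs$size || ncol(pi) != target_fs$size)
    stop("feature law must be |L| x |F|")
  if (any(!is.finite(pi))) stop("feature law entries must be finite")
  dimnames(pi) <- list(atlas_fs$labels, target_fs$labels)
  structure(pi, class = c("feature_law", "matrix"),
            atlas_fs = atlas_fs, target_fs = target_fs)
}

#' @export
print.feature_law <- function(x, ...) {
  cat("<feature_law> ", nrow(x), " atlas labels -> ", ncol(x),
      " target features; row masses: ",
      paste(format(rowSums(x), digits = 4), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# uniform initialization pi_l(f) = 1/|F|
uniform_feature_law <- function(atlas_fs, target_fs) {
  feature_law(matrix(1 / target_fs$size, atlas_fs$size, target_fs$size),
              atlas_fs, target_fs)
}

#' Apply a feature law to an atlas varifold
#'
#' Carries a varifold over atlas labels into the target feature space by the
#' mixture `w'_i p'_i = w_i sum_l p_i(l) pi_l`.  The returned weight is the
#' total mixture mass and the returned distribution its normalization
#' (uniform at locations of zero mass).  For mesh varifolds the mixture acts
#' on the per-simplex densities.
#'
#' @param mu atlas varifold whose feature space matches the rows of `pi`.
#' @param pi a [feature_law()].
#' @return A varifold of the same class as `mu` over the target feature
#'   space.
#' @export
apply_feature_law <- function(mu, pi) {
  stopifnot(inherits(pi, "feature_law"))
  target_fs <- attr(pi, "target_fs")
  if (!same_feature_space(mu$fs, attr(pi, "atlas_fs")))
    stop("atlas feature space does not match the feature law rows")
  if (inherits(mu, "mesh_varifold")) {
    mix <- (mu$p * mu$alpha) %*% unclass(pi)
    a2 <- rowSums(mix)
    p2 <- mix
    p2[a2 > 0, ] <- p2[a2 > 0, , drop = FALSE] / a2[a2 > 0]
    p2[a2 == 0, ] <- 1 / target_fs$size
    return(mesh_varifold(mu$vertices, mu$simplices, a2, p2, target_fs))
  }
  mu <- as_particles(mu)
  mix <- (mu$p * mu$w) %*% unclass(pi)
  w2 <- rowSums(mix)
  p2 <- mix
  p2[w2 > 0, ] <- p2[w2 > 0, , drop = FALSE] / w2[w2 > 0]
  p2[w2 == 0, ] <- 1 / target_fs$size
  particle_varifold(mu$x, w2, p2, target_fs)
}

#' Density bounds for the feature-law quadratic program
#'
#' The default prior on the predicted per-location density `w'_i`: the lower
#' bound is the 5th percentile (nearest-rank) of the target varifold's
#' weights and the upper bound their maximum.  In constant-density mode
#' (atlas-to-atlas mapping) both bounds are 1.
#'
#' @param mu_T the target varifold.
#' @param constant_density use the constant-density convention
#'   `w_min = w_max = 1`.
#' @return An object of class `density_bounds` with fields `w_min`, `w_max`
#'   (scalars or per-location vectors).
#' @export
default_bounds <- function(mu_T, constant_density = FALSE) {
  if (constant_density) return(density_bounds(1, 1))
  w <- varifold_weights(mu_T)
  if (length(w) == 0L) stop("target varifold is empty")
  ws <- sort(w)
  w_min <- ws[max(1L, ceiling(0.05 * length(ws)))]
  density_bounds(w_min, max(w))
}

#' @rdname default_bounds
#' @param w_min,w_max scalars or per-location vectors, `0 <= w_min <= w_max`.
#' @export
density_bounds <- function(w_min, w_max) {
  if (any(w_min < 0) || any(w_max < w_min))
    stop("bounds must satisfy 0 <= w_min <= w_max")
  structure(list(w_min = as.numeric(w_min), w_max = as.numeric(w_max)),
            class = "density_bounds")
}

#' Solve the feature-law quadratic program
#'
#' At a fixed diffeomorphism, the varifold normed difference is a convex
#' quadratic in the feature-law entries.  With the discrete feature kernel
#' the Hessian is block diagonal across target features with the common
#' block `G = B' K1 B` where `B[i, l] = w_i p_i(l)` collects the deformed
#' atlas weights (Jacobian factors included) against atlas labels.  The
#' program is solved under nonnegativity and optional density-bound rows
#' `w_min <= w'_i <= w_max` (linear in `pi`).  With `use_greedy`, each atlas
#' distribution is collapsed to its dominant label before assembly (exact
#' whenever all atlas distributions are deltas).
#'
#' The interior solution (nonnegativity slack, no bounds) is obtained in
#' closed form; otherwise an interior-point solve is refined by an
#' active-set KKT polish to tight accuracy.
#'
#' @param deformed_atlas the atlas varifold after [apply_diffeo()] (weights
#'   carry `|Dphi|`), over the atlas label space.
#' @param mu_T target varifold over the target feature space.
#' @param cfg a [norm_config()].
#' @param bounds optional [density_bounds()]; scalars are recycled over
#'   atlas locations.
#' @param use_greedy collapse atlas distributions to their dominant label.
#' @param target_fs feature space for the law columns; defaults to the
#'   target's.
#' @return A [feature_law()] with attributes `objective` (the attained
#'   normed difference) and `status`.
#' @export
solve_feature_qp <- function(deformed_atlas, mu_T, cfg = norm_config(),
                             bounds = NULL, use_greedy = FALSE,
                             target_fs = NULL) {
  A <- as_particles(deformed_atlas)
  Tg <- as_particles(mu_T)
  if (is.null(target_fs)) target_fs <- Tg$fs
  atlas_fs <- A$fs
  u <- A$w
  wT <- Tg$w
  mm <- check_mask(cfg$template_mask_weights, length(u), "template")
  mt <- check_mask(cfg$target_mask_weights, length(wT), "target")
  if (!is.null(mm)) u <- u * mm
  if (!is.null(mt)) wT <- wT * mt
  P <- A$p
  if (use_greedy) {
    amax <- max.col(P, ties.method = "first")
    Pg <- matrix(0, nrow(P), ncol(P))
    Pg[cbind(seq_len(nrow(P)), amax)] <- P[cbind(seq_len(nrow(P)), amax)]
    P <- Pg
  }
  B <- P * u                      # n x L mixture coefficients
  N <- Tg$p * wT                  # m x F target masses
  L <- atlas_fs$size; Fn <- target_fs$size

  G <- matrix(0, L, L)
  b <- matrix(0, L, Fn)
  const_T <- 0
  for (s in cfg$sigma_w) {
    K_AA <- cpp_gauss_mat(A$x, A$x, s)
    K_AT <- cpp_gauss_mat(A$x, Tg$x, s)
    G <- G + crossprod(B, K_AA %*% B)
    b <- b + crossprod(B, K_AT %*% N)
    const_T <- const_T + sum(cpp_gauss_mat(Tg$x, Tg$x, s) * tcrossprod(N))
  }
  G <- (G + t(G)) / 2
  objective <- function(pi) {
    sum(pi * (G %*% pi)) - 2 * sum(b * pi) + const_T
  }

  # nonnegativity-only solution, exact per feature by active-set NNLS
  # (the Hessian block is shared by all features)
  pi_nn <- matrix(apply(b, 2L, function(bf) nnls_active_set(G, bf)), L, Fn)
  if (is.null(bounds)) {
    return(structure(feature_law(pi_nn, atlas_fs, target_fs),
                     objective = objective(pi_nn), status = "interior"))
  }

  n <- length(u)
  row_mass <- rowSums(B)
  w_min <- rep_len(bounds$w_min, n)
  w_max <- rep_len(bounds$w_max, n)
  dead <- which(row_mass <= 1e-12 & w_min > 0)
  if (length(dead))
    stop("density bounds infeasible: zero-mass atlas rows ",
         paste(utils::head(dead, 10L), collapse = ", "),
         " cannot reach w_min > 0")
  wprime <- drop(B %*% rowSums(pi_nn))
  btol <- 1e-9 * max(1, max(w_max[is.finite(w_max)], 0))
  if (all(wprime >= w_min - btol) && all(wprime <= w_max + btol)) {
    # bounds slack at the nonnegativity-only optimum: it solves the full QP
    return(structure(feature_law(pi_nn, atlas_fs, target_fs),
                     objective = objective(pi_nn), status = "interior"))
  }

  # bound rows active: operator-splitting solve on vec(pi), then KKT polish
  H <- kronecker(diag(Fn), G)
  cvec <- -2 * as.numeric(b)
  Acon <- matrix(rep(B, Fn), n, L * Fn)
  bcon <- w_min
  rcon <- w_max - w_min
  Astack <- rbind(diag(L * Fn), Acon)
  lo <- c(rep(0, L * Fn), w_min)
  hi <- c(rep(Inf, L * Fn), w_max)
  sol <- admm_qp(2 * H, cvec, Astack, lo, hi, x0 = as.numeric(pi_nn))
  x <- sol$x
  status <- sol$status
  x[x < 0] <- 0
  x <- polish_qp(x, H, cvec, Acon, bcon, rcon, FALSE)
  pi_hat <- matrix(x, L, Fn)

  wprime <- drop(Acon %*% x)
  tol <- 1e-6 * max(1, max(rcon + bcon))
  viol <- which(wprime < bcon - tol | wprime > bcon + rcon + tol)
  if (length(viol))
    stop("density bounds infeasible at rows ",
         paste(utils::head(viol, 10L), collapse = ", "),
         " (solver status: ", status, ")")
  structure(feature_law(pi_hat, atlas_fs, target_fs),
            objective = objective(pi_hat), status = status)
}

# operator-splitting (ADMM) solver for min 1/2 x'Px + q'x s.t. lo <= Ax <= hi,
# with over-relaxation and periodic step-size rebalancing; absolute/relative
# tolerances 1e-8
admm_qp <- function(P, q, A, lo, hi, x0 = NULL, rho = 1, sigma = 1e-6,
                    alpha = 1.6, eps = 1e-8, max_iter = 50000L) {
  # diagonal equilibration: variables by the Hessian diagonal, constraint
  # rows by their norms
  dcol <- 1 / sqrt(pmax(diag(P), 1e-10 * max(diag(P), 1)))
  P <- P * tcrossprod(dcol)
  q <- q * dcol
  A <- sweep(A, 2L, dcol, "*")
  drow <- 1 / pmax(sqrt(rowSums(A^2)), 1e-12)
  A <- A * drow
  lo <- lo * drow
  hi <- hi * drow
  if (!is.null(x0)) x0 <- x0 / dcol
  nv <- ncol(A); m <- nrow(A)
  x <- if (is.null(x0)) numeric(nv) else x0
  z <- pmin(pmax(drop(A %*% x), lo), hi)
  y <- numeric(m)
  AtA <- crossprod(A)
  fac <- chol(P + sigma * diag(nv) + rho * AtA)
  status <- "max_iter"
  for (k in seq_len(max_iter)) {
    rhs <- sigma * x - q + drop(crossprod(A, rho * z - y))
    xt <- backsolve(fac, backsolve(fac, rhs, transpose = TRUE))
    zt <- drop(A %*% xt)
    x_new <- alpha * xt + (1 - alpha) * x
    z_prev <- z
    z <- pmin(pmax(alpha * zt + (1 - alpha) * z_prev + y / rho, lo), hi)
    y <- y + rho * (alpha * zt + (1 - alpha) * z_prev - z)
    x <- x_new
    if (k %% 25L == 0L) {
      Ax <- drop(A %*% x)
      r_prim <- max(abs(Ax - z))
      r_dual <- max(abs(drop(P %*% x) + q + drop(crossprod(A, y))))
      e_prim <- eps + eps * max(abs(Ax), abs(z))
      e_dual <- eps + eps * max(abs(P %*% x), abs(q), abs(crossprod(A, y)))
      if (r_prim < e_prim && r_dual < e_dual) { status <- "solved"; break }
      if (k %% 500L == 0L) {
        ratio <- sqrt((r_prim / max(e_prim, 1e-300)) /
                        max(r_dual / max(e_dual, 1e-300), 1e-300))
        ratio <- min(max(ratio, 0.1), 10)
        if (abs(log(ratio)) > log(2)) {
          rho <- rho * ratio
          fac <- chol(P + sigma * diag(nv) + rho * AtA)
        }
      }
    }
  }
  list(x = x * dcol, status = status)
}

# Lawson-Hanson active-set nonnegative solve of min x'Gx - 2 b'x, x >= 0
nnls_active_set <- function(G, b, tol = NULL) {
  L <- length(b)
  if (is.null(tol)) tol <- 1e-12 * max(abs(b), 1)
  x <- numeric(L)
  passive <- logical(L)
  solve_p <- function(p) {
    z <- tryCatch(solve(G[p, p, drop = FALSE], b[p]),
                  error = function(e)
                    drop(MASS::ginv(G[p, p, drop = FALSE]) %*% b[p]))
    z
  }
  for (iter in seq_len(10L * L)) {
    w <- b - drop(G %*% x)           # negative half-gradient
    w[passive] <- -Inf
    j <- which.max(w)
    if (w[j] <= tol) break
    passive[j] <- TRUE
    repeat {
      z <- numeric(L)
      z[passive] <- solve_p(passive)
      if (all(z[passive] > 0)) { x <- z; break }
      neg <- passive & z <= 0
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive[passive & x <= tol] <- FALSE
      x[!passive] <- 0
    }
  }
  x
}

# one-shot active-set KKT refinement of an approximate QP solution:
# min c'x + x'Hx s.t. x >= 0, bcon <= Acon x <= bcon + rcon
polish_qp <- function(x, H, cvec, Acon, bcon, rcon, unconstrained_rows) {
  nv <- length(x)
  scale <- max(abs(x), 1e-10)
  free <- x > 1e-7 * scale
  if (!any(free)) return(x)
  act_lo <- act_hi <- integer(0)
  if (!unconstrained_rows) {
    wp <- drop(Acon %*% x)
    span <- max(rcon + abs(bcon), 1e-10)
    act_lo <- which(abs(wp - bcon) < 1e-5 * span)
    act_hi <- which(abs(wp - (bcon + rcon)) < 1e-5 * span & rcon > 1e-12)
    act_hi <- setdiff(act_hi, act_lo)
  }
  Aact <- rbind(Acon[act_lo, free, drop = FALSE],
                Acon[act_hi, free, drop = FALSE])
  bact <- c(rep_len(bcon, nrow(Acon))[act_lo],
            (rep_len(bcon, nrow(Acon)) + rep_len(rcon, nrow(Acon)))[act_hi])
  nf <- sum(free); na <- nrow(Aact)
  # KKT system for min c_f'x_f + x_f' H_ff x_f s.t. Aact x_f = bact
  KKT <- rbind(cbind(2 * H[free, free, drop = FALSE], t(Aact)),
               cbind(Aact, matrix(0, na, na)))
  rhs <- c(-cvec[free], bact)
  sol <- tryCatch(solve(KKT, rhs), error = function(e) NULL)
  if (is.null(sol)) return(x)
  xf <- sol[seq_len(nf)]
  cand <- numeric(nv)
  cand[free] <- xf
  if (any(cand < -1e-9 * scale)) return(x)
  cand[cand < 0] <- 0
  if (!unconstrained_rows) {
    wp <- drop(Acon %*% cand)
    span <- max(rcon + abs(bcon), 1e-10)
    if (any(wp < rep_len(bcon, length(wp)) - 1e-7 * span) ||
        any(wp > rep_len(bcon, length(wp)) + rep_len(rcon, length(wp)) +
              1e-7 * span)) return(x)
  }
  obj <- function(z) sum(cvec * z) + sum(z * (H %*% z))
  if (obj(cand) <= obj(x) + 1e-12) cand else x
}

#' Kullback-Leibler regularizer of a feature law
#'
#' Per atlas label, the KL divergence of the row-normalized law from the
#' uniform distribution over target features:
#' `sum_f pibar_l(f) ln(pibar_l(f) |F|)`, with `0 ln 0 = 0` and natural
#' logarithms.  Zero-mass rows contribute 0 with a warning.
#'
#' @param pi a [feature_law()] (or plain nonnegative matrix).
#' @return list with `per_label` (named vector) and `total`.
#' @export
kl_regularizer <- function(pi) {
  pi <- unclass(as.matrix(pi))
  nF <- ncol(pi)
  mass <- rowSums(pi)
  per <- numeric(nrow(pi))
  if (any(mass <= 0)) warning("zero-mass feature-law row(s) contribute 0")
  pos <- which(mass > 0)
  for (l in pos) {
    pb <- pi[l, ] / mass[l]
    nz <- pb > 0
    per[l] <- sum(pb[nz] * log(pb[nz] * nF))
  }
  names(per) <- rownames(pi)
  list(per_label = per, total = sum(per))
}
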