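#' Set distance from cells to an atlas region
#'
#' The cross-modality accuracy metric: for each cell of a type matched to an
#' atlas region, the minimum squared Euclidean distance
#' `d_c = min_{a in A_R} ||x_a - y_c||^2` to the set of atlas particles
#' carrying full mass on that region.  Both the squared distance (um^2) and
#' its square root (um) are returned, since accuracy histograms are usually
#' discussed in micrometres.
#'
#' @param cells n x 2 matrix (or data frame with `x`, `y`) of cell positions
#'   of the matched type, in atlas coordinates.
#' @param atlas a `particle_varifold` over the atlas label space.
#' @param region atlas label whose particle set defines the target set.
#' @return data frame with columns `d2` (um^2) and `d` (um), one row per
#'   cell.
#' @export
set_distance <- function(cells, atlas, region) {
  if (is.data.frame(cells)) cells <- cbind(cells$x, cells$y)
  cells <- as_xy_matrix(cells)
  atlas <- as_particles(atlas)
  li <- feature_index(atlas$fs, region)
  sel <- atlas$p[, li] >= 1 - 1e-12
  if (!any(sel)) stop("no atlas particles with full mass on region ", region)
  d2 <- cpp_min_sq_dist(cells, atlas$x[sel, , drop = FALSE])
  data.frame(d2 = d2, d = sqrt(d2))
}

#' Entropy of per-location feature distributions
#'
#' `-sum_f p(f) ln p(f)` with `0 ln 0 = 0`, after row normalization.  Used
#' to compare atlas ontologies: entropy near 0 means a location (or region)
#' maps onto a single target feature, larger values mean its mass is spread
#' over several.
#'
#' @param dists numeric matrix of nonnegative rows (or a single vector).
#' @return numeric vector of entropies (nats), one per row; zero-mass rows
#'   give 0.
#' @export
entropy_map <- function(dists) {
  if (is.null(dim(dists))) dists <- matrix(dists, 1L)
  dists <- as.matrix(dists)
  if (any(dists < -1e-9)) stop("distributions must be nonnegative")
  dists[dists < 0] <- 0
  mass <- rowSums(dists)
  out <- numeric(nrow(dists))
  for (i in which(mass > 0)) {
    p <- dists[i, ] / mass[i]
    nz <- p > 0
    out[i] <- -sum(p[nz] * log(p[nz]))
  }
  out
}

#' Scaffold atlas of empirical feature distributions
#'
#' A particle rendering of an atlas section at a stated resolution, carrying
#' for each scaffold particle one empirical target-feature mass vector per
#' replicate (cells pulled back into atlas coordinates).
#'
#' @param scaffold a `particle_varifold` over the atlas label space (the
#'   scaffold geometry).
#' @param target_fs [feature_space()] of the target features.
#' @param replicates list of n_particles x |F| nonnegative mass matrices.
#' @return An object of class `scaffold_atlas`.
#' @export
scaffold_atlas <- function(scaffold, target_fs, replicates = list()) {
  stopifnot(inherits(scaffold, "particle_varifold"),
            inherits(target_fs, "feature_space"))
  for (m in replicates) {
    if (nrow(m) != length(scaffold$w) || ncol(m) != target_fs$size)
      stop("replicate mass matrices must be n_particles x |F|")
    if (any(m < 0)) stop("replicate masses must be nonnegative")
  }
  structure(list(scaffold = scaffold, target_fs = target_fs,
                 replicates = replicates),
            class = "scaffold_atlas")
}

#' @export
print.scaffold_atlas <- function(x, ...) {
  cat("<scaffold_atlas> ", length(x$scaffold$w), " scaffold particles, ",
      length(x$replicates), " replicate(s), ", x$target_fs$size,
      " target features\n", sep = "")
  invisible(x)
}

#' Build a scaffold rendering of an atlas section
#'
#' Aggregates an atlas particle varifold to the stated resolution (mass-
#' weighted centroids per grid cell, label histograms as distributions),
#' giving the fixed particle set onto which targets are pulled back.
#'
#' @param atlas a `particle_varifold` over the atlas label space.
#' @param resolution scaffold cell size in micrometres (e.g. 50).
#' @return A `particle_varifold` at scaffold resolution.
#' @export
scaffold_from_atlas <- function(atlas, resolution) {
  atlas <- as_particles(atlas)
  mass <- atlas$p * atlas$w
  nz <- which(mass > 0, arr.ind = TRUE)
  tab <- data.frame(x = atlas$x[nz[, 1L], 1L], y = atlas$x[nz[, 1L], 2L],
                    feature = atlas$fs$labels[nz[, 2L]], count = mass[nz])
  particles_from_points(tab, atlas$fs, resolution)
}

#' Pull mapped cells back onto an atlas scaffold
#'
#' Maps typed cells from target coordinates into atlas coordinates through
#' the inverse of a fitted registration, then assigns each cell to its
#' nearest scaffold particle (ties to the lowest particle index), giving one
#' replicate slot of empirical per-particle feature masses.  Cell counts are
#' conserved exactly.  In kernel mode each cell's mass is instead dispersed
#' over scaffold particles with Gaussian weights normalized to conserve
#' mass.
#'
#' @param cells data frame with columns `x`, `y`, `feature` and optional
#'   `count` (target coordinates).
#' @param mapping an `xiv_lddmm` fit (or [diffeomorphism()]) supporting
#'   inverse application.
#' @param scaffold a scaffold `particle_varifold` (see
#'   [scaffold_from_atlas()]).
#' @param target_fs [feature_space()] of the cell features.
#' @param mode `"nearest"` or `"kernel"`.
#' @param sigma kernel bandwidth (um) in kernel mode.
#' @return A [scaffold_atlas()] with a single replicate.
#' @export
pullback_to_scaffold <- function(cells, mapping, scaffold, target_fs,
                                 mode = c("nearest", "kernel"), sigma = 50) {
  mode <- match.arg(mode)
  cells <- as.data.frame(cells)
  phi <- if (inherits(mapping, "xiv_lddmm")) mapping$diffeo else mapping
  counts <- if ("count" %in% names(cells)) as.numeric(cells$count)
            else rep(1, nrow(cells))
  fidx <- feature_index(target_fs, cells$feature)
  mapped <- map_points(phi, cbind(cells$x, cells$y), direction = "inverse",
                       jacobian = FALSE)$points
  n_sc <- length(scaffold$w)
  mass <- matrix(0, n_sc, target_fs$size)
  if (mode == "nearest") {
    idx <- cpp_nearest_index(mapped, scaffold$x)
    for (r in seq_along(idx))
      mass[idx[r], fidx[r]] <- mass[idx[r], fidx[r]] + counts[r]
  } else {
    K <- cpp_gauss_mat(scaffold$x, mapped, sigma)
    K <- sweep(K, 2L, pmax(colSums(K), 1e-300), "/")
    for (f in seq_len(target_fs$size)) {
      sel <- fidx == f
      if (any(sel))
        mass[, f] <- drop(K[, sel, drop = FALSE] %*% counts[sel])
    }
  }
  scaffold_atlas(scaffold, target_fs, list(mass))
}

#' Merge replicate slots of scaffold atlases
#'
#' @param ... `scaffold_atlas` objects sharing one scaffold and feature
#'   space.
#' @return A `scaffold_atlas` with the concatenated replicate list.
#' @export
merge_replicates <- function(...) {
  xs <- list(...)
  base <- xs[[1L]]
  reps <- do.call(c, lapply(xs, function(s) s$replicates))
  scaffold_atlas(base$scaffold, base$target_fs, reps)
}

# region membership: particles with at least half their mass on the region;
# exact 0.5 ties go to the lowest label index
region_members <- function(scaffold, region) {
  fs <- scaffold$fs
  li <- feature_index(fs, region)
  p <- scaffold$p
  half <- p >= 0.5
  member <- half[, li]
  if (any(member)) {
    ties <- which(member & rowSums(half) > 1L)
    if (length(ties)) {
      first <- apply(half[ties, , drop = FALSE], 1L, which.max)
      member[ties] <- first == li
    }
  }
  which(member)
}

# normalized per-particle distributions of one replicate, NA rows for
# zero-mass particles
replicate_dists <- function(sc, replicate) {
  m <- sc$replicates[[replicate]]
  tot <- rowSums(m)
  d <- m / ifelse(tot > 0, tot, 1)
  d[tot == 0, ] <- NA_real_
  d
}

#' Mean empirical feature distribution of an atlas region
#'
#' Unweighted mean of the per-particle normalized feature distributions over
#' the particles with at least half their mass in the region (zero-count
#' particles are excluded from the mean).
#'
#' @param sc a [scaffold_atlas()].
#' @param region atlas label.
#' @param replicate replicate index (default 1).
#' @return list with `mean` (probability vector over target features) and
#'   `n` (number of contributing particles).
#' @export
region_mean_distribution <- function(sc, region, replicate = 1L) {
  idx <- region_members(sc$scaffold, region)
  if (length(idx) == 0L) stop("no scaffold particles belong to region ",
                              region)
  d <- replicate_dists(sc, replicate)[idx, , drop = FALSE]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nrow(d) == 0L) stop("region ", region, " has no observed cells in ",
                          "replicate ", replicate)
  list(mean = colMeans(d), n = nrow(d))
}

#' Spatial variance of feature probabilities within a region
#'
#' The sample variance `1/(N_l - 1) sum_{i in I_l} |p_i(c) - pbar_l(c)|^2`
#' of the empirical per-particle probabilities of one feature across the
#' particles of one region; undefined (NA) when fewer than two particles
#' contribute.
#'
#' @inheritParams region_mean_distribution
#' @param feature target feature label, or NULL for all features at once.
#' @return Named vector of per-feature variances (a scalar if one feature
#'   was requested).
#' @export
spatial_variance <- function(sc, region, feature = NULL, replicate = 1L) {
  idx <- region_members(sc$scaffold, region)
  d <- replicate_dists(sc, replicate)[idx, , drop = FALSE]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nrow(d) < 2L) {
    v <- rep(NA_real_, sc$target_fs$size)
  } else {
    v <- apply(d, 2L, stats::var)
  }
  names(v) <- sc$target_fs$labels
  if (!is.null(feature)) v <- v[feature_index(sc$target_fs, feature)]
  v
}

#' Per-region and per-feature spatial variance tables
#'
#' Per-region totals sum the per-feature variances over features; per-feature
#' totals sum over regions.  Both totals sum to the same grand total.
#'
#' @param sc a [scaffold_atlas()].
#' @param replicate replicate index.
#' @return list with `table` (region x feature matrix), `by_region` and
#'   `by_feature` totals.
#' @export
spatial_variance_table <- function(sc, replicate = 1L) {
  regions <- sc$scaffold$fs$labels
  tab <- t(vapply(regions,
                  function(r) spatial_variance(sc, r, replicate = replicate),
                  numeric(sc$target_fs$size)))
  dimnames(tab) <- list(regions, sc$target_fs$labels)
  list(table = tab,
       by_region = rowSums(tab, na.rm = TRUE),
       by_feature = colSums(tab, na.rm = TRUE))
}

#' Cross-replicate variance of region mean distributions
#'
#' Sample variance `1/(K - 1) sum_k |pbar^k_l(c) - mean_k pbar^k_l(c)|^2`
#' of the per-replicate region mean probabilities.
#'
#' @param sc a [scaffold_atlas()] with K >= 2 replicates.
#' @param region atlas label.
#' @param feature target feature, or NULL for all.
#' @return Named vector of per-feature variances (scalar for one feature).
#' @export
cross_replicate_variance <- function(sc, region, feature = NULL) {
  K <- length(sc$replicates)
  if (K < 2L) stop("need at least two replicates")
  means <- t(vapply(seq_len(K),
                    function(k) region_mean_distribution(sc, region, k)$mean,
                    numeric(sc$target_fs$size)))
  v <- apply(means, 2L, stats::var)
  names(v) <- sc$target_fs$labels
  if (!is.null(feature)) v <- v[feature_index(sc$target_fs, feature)]
  v
}

#' @rdname cross_replicate_variance
#' @export
cross_replicate_variance_table <- function(sc) {
  regions <- sc$scaffold$fs$labels
  tab <- t(vapply(regions, function(r) cross_replicate_variance(sc, r),
                  numeric(sc$target_fs$size)))
  dimnames(tab) <- list(regions, sc$target_fs$labels)
  list(table = tab,
       by_region = rowSums(tab, na.rm = TRUE),
       by_feature = colSums(tab, na.rm = TRUE))
}

#' Jacobian determinant map of a fitted registration
#'
#' `|Dphi|` of the full forward map (rigid scale factor included) at
#' arbitrary locations, flow-integrated from analytic kernel derivatives.
#'
#' @param result an `xiv_lddmm` fit or [diffeomorphism()].
#' @param locations n x 2 matrix of atlas-coordinate locations.
#' @return numeric vector of Jacobian determinants.
#' @export
jacobian_map <- function(result, locations) {
  phi <- if (inherits(result, "xiv_lddmm")) result$diffeo else result
  map_points(phi, locations, direction = "forward", jacobian = TRUE)$jac
}

#' Resample a particle varifold onto a regular grid
#'
#' Deposits each particle's per-feature mass onto grid pixels with a
#' Gaussian profile normalized over the grid, so per-feature mass is
#' conserved; useful for rendering deformed atlas particles as images.
#'
#' @param mu a `particle_varifold`.
#' @param pixel_size grid pixel edge (um).
#' @param sigma Gaussian smoothing bandwidth (um).
#' @param pad margin around the particle bounding box, in multiples of
#'   `sigma`.
#' @return list with `images` (named list of matrices, one per feature; rows
#'   index y), `pixel_size`, `origin`, and `argmax` (a [label_image()] of the
#'   dominant feature index, 0 where no mass).
#' @export
resample_to_grid <- function(mu, pixel_size, sigma, pad = 4) {
  stopifnot(pixel_size > 0, sigma > 0)
  mu <- as_particles(mu)
  xr <- range(mu$x[, 1L]) + c(-1, 1) * pad * sigma
  yr <- range(mu$x[, 2L]) + c(-1, 1) * pad * sigma
  ox <- floor(xr[1L] / pixel_size) * pixel_size
  oy <- floor(yr[1L] / pixel_size) * pixel_size
  nx <- ceiling((xr[2L] - ox) / pixel_size)
  ny <- ceiling((yr[2L] - oy) / pixel_size)
  cx <- ox + (seq_len(nx) - 0.5) * pixel_size
  cy <- oy + (seq_len(ny) - 0.5) * pixel_size
  gx <- exp(-outer(cx, mu$x[, 1L], "-")^2 / (2 * sigma^2))  # nx x n
  gy <- exp(-outer(cy, mu$x[, 2L], "-")^2 / (2 * sigma^2))  # ny x n
  # separable weights; normalize per particle over the grid
  norm <- colSums(gx) * colSums(gy)
  imgs <- vector("list", mu$fs$size)
  for (f in seq_len(mu$fs$size)) {
    coefs <- mu$w * mu$p[, f] / pmax(norm, 1e-300)
    imgs[[f]] <- gy %*% (t(gx) * coefs)  # ny x nx
  }
  names(imgs) <- mu$fs$labels
  stack <- vapply(imgs, identity, imgs[[1L]])
  tot <- Reduce(`+`, imgs)
  arg <- apply(stack, c(1L, 2L), which.max)
  arg[tot < 1e-12] <- 0L
  list(images = imgs, pixel_size = pixel_size, origin = c(ox, oy),
       argmax = label_image(arg, pixel_size, c(ox, oy), background = 0L))
}
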