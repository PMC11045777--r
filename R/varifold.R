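#' Particle image varifold
#'
#' An image varifold is a measure over position crossed with a finite feature
#' space, mu = sum_i w_i delta_{x_i} (x) p_i.  Each particle carries a 2D
#' position `x_i` (micrometres), a nonnegative mass `w_i` (mRNA count, cell
#' count, or 1 for constant-density tissue) and a probability distribution
#' `p_i` over the feature space.
#'
#' @param positions numeric n x 2 matrix of coordinates in micrometres.
#' @param weights numeric vector of nonnegative masses, length n.
#' @param feature_dists numeric n x |F| matrix; each row sums to 1.
#' @param fs a [feature_space()].
#' @return An object of class `particle_varifold` with fields `x`, `w`, `p`,
#'   `fs`.
#' @export
particle_varifold <- function(positions, weights, feature_dists, fs) {
  positions <- as_xy_matrix(positions)
  weights <- as.numeric(weights)
  feature_dists <- as.matrix(feature_dists)
  stopifnot(inherits(fs, "feature_space"))
  n <- nrow(positions)
  if (length(weights) != n || nrow(feature_dists) != n)
    stop("positions, weights and feature_dists must have matching lengths")
  if (ncol(feature_dists) != fs$size)
    stop("feature_dists must have one column per feature-space label")
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (any(feature_dists < -1e-12)) stop("feature distributions must be nonnegative")
  rs <- rowSums(feature_dists)
  if (any(abs(rs - 1) > 1e-9))
    stop("each feature distribution must sum to 1 (max deviation ",
         format(max(abs(rs - 1))), ")")
  colnames(feature_dists) <- fs$labels
  structure(list(x = positions, w = weights, p = feature_dists, fs = fs),
            class = "particle_varifold")
}

#' @export
print.particle_varifold <- function(x, ...) {
  cat("<particle_varifold> ", length(x$w), " particles, total mass ",
      format(sum(x$w)), ", ", x$fs$size, " features\n", sep = "")
  invisible(x)
}

#' Mesh image varifold
#'
#' A semi-discrete image varifold carried by a triangulated mesh: each
#' oriented triangle simplex has a constant spatial density `alpha_j`
#' (mass per square micrometre) and a feature distribution `p_j`, equivalent
#' to the particle measure sum_j w_j delta_{m_j} (x) p_j with weight
#' w_j = alpha_j * |simplex area| placed at the simplex center m_j.
#'
#' @param vertices numeric V x 2 matrix of vertex coordinates (micrometres).
#' @param simplices integer J x 3 matrix of vertex indices, positively
#'   oriented (positive signed area).
#' @param alpha numeric vector of per-simplex densities (mass per um^2).
#' @param feature_dists numeric J x |F| matrix of per-simplex feature
#'   distributions.
#' @param fs a [feature_space()].
#' @return An object of class `mesh_varifold` with fields `vertices`,
#'   `simplices`, `alpha`, `p`, `fs`, plus derived `centers` and `areas`.
#' @export
mesh_varifold <- function(vertices, simplices, alpha, feature_dists, fs) {
  vertices <- as_xy_matrix(vertices)
  simplices <- matrix(as.integer(as.matrix(simplices)), ncol = 3L)
  alpha <- as.numeric(alpha)
  feature_dists <- as.matrix(feature_dists)
  stopifnot(inherits(fs, "feature_space"))
  ns <- nrow(simplices)
  if (length(alpha) != ns || nrow(feature_dists) != ns)
    stop("simplices, alpha and feature_dists must have matching lengths")
  if (any(alpha < 0)) stop("densities alpha must be nonnegative")
  ar <- signed_areas(vertices, simplices)
  if (any(ar <= 0)) stop("every simplex must have positive oriented area")
  rs <- rowSums(feature_dists)
  if (any(abs(rs - 1) > 1e-9))
    stop("each feature distribution must sum to 1")
  colnames(feature_dists) <- fs$labels
  structure(list(vertices = vertices, simplices = simplices, alpha = alpha,
                 p = feature_dists, fs = fs,
                 centers = simplex_centers(vertices, simplices), areas = ar),
            class = "mesh_varifold")
}

#' @export
print.mesh_varifold <- function(x, ...) {
  cat("<mesh_varifold> ", nrow(x$vertices), " vertices, ",
      nrow(x$simplices), " simplices, total mass ",
      format(sum(x$alpha * x$areas)), ", ", x$fs$size, " features\n", sep = "")
  invisible(x)
}

# signed area (z-component of cross product / 2) per simplex
signed_areas <- function(vertices, simplices) {
  a <- vertices[simplices[, 1L], , drop = FALSE]
  b <- vertices[simplices[, 2L], , drop = FALSE]
  c <- vertices[simplices[, 3L], , drop = FALSE]
  0.5 * ((b[, 1L] - a[, 1L]) * (c[, 2L] - a[, 2L]) -
           (c[, 1L] - a[, 1L]) * (b[, 2L] - a[, 2L]))
}

simplex_centers <- function(vertices, simplices) {
  (vertices[simplices[, 1L], , drop = FALSE] +
     vertices[simplices[, 2L], , drop = FALSE] +
     vertices[simplices[, 3L], , drop = FALSE]) / 3
}

#' Area of a triangle simplex
#'
#' Computes half the magnitude of the cross product of two edge vectors;
#' returns 0 for degenerate (collinear) vertices, signalling degeneracy to
#' callers rather than erroring.
#'
#' @param vertices a 3 x 2 numeric matrix of triangle vertex coordinates.
#' @return The area in square micrometres (nonnegative scalar).
#' @examples
#' simplex_area(rbind(c(0, 0), c(1, 0), c(0, 1)))  # 0.5
#' @export
simplex_area <- function(vertices) {
  vertices <- as_xy_matrix(vertices)
  stopifnot(nrow(vertices) == 3L)
  abs(signed_areas(vertices, matrix(1:3, 1L)))
}

#' Weights of an image varifold
#'
#' Per-location masses: `w_i` for particle varifolds, `alpha_j * area_j` for
#' mesh varifolds.
#' @param mu a `particle_varifold` or `mesh_varifold`.
#' @return numeric vector of masses.
#' @export
varifold_weights <- function(mu) {
  if (inherits(mu, "particle_varifold")) return(mu$w)
  if (inherits(mu, "mesh_varifold")) return(mu$alpha * mu$areas)
  stop("not an image varifold")
}

#' Positions of an image varifold
#'
#' Particle positions, or simplex centers for a mesh varifold.
#' @inheritParams varifold_weights
#' @return numeric n x 2 matrix.
#' @export
varifold_positions <- function(mu) {
  if (inherits(mu, "particle_varifold")) return(mu$x)
  if (inherits(mu, "mesh_varifold")) return(mu$centers)
  stop("not an image varifold")
}

#' Per-feature mass marginal of an image varifold
#'
#' Returns sum_i w_i p_i(f) for each feature f: the total mass carried by each
#' feature.
#' @inheritParams varifold_weights
#' @return named numeric vector over the feature space.
#' @export
feature_marginal <- function(mu) {
  w <- varifold_weights(mu)
  drop(crossprod(mu$p, w))
}

# view a mesh varifold as particles at simplex centers; identity on particles
as_particles <- function(mu) {
  if (inherits(mu, "particle_varifold")) return(mu)
  if (inherits(mu, "mesh_varifold")) {
    return(particle_varifold(mu$centers, mu$alpha * mu$areas, mu$p, mu$fs))
  }
  stop("not an image varifold")
}

as_xy_matrix <- function(x) {
  if (is.null(dim(x))) {
    if (length(x) == 2L) x <- matrix(as.numeric(x), 1L, 2L)
    else stop("expected a 2-column coordinate matrix")
  }
  x <- as.matrix(x)
  if (ncol(x) != 2L) stop("expected a 2-column coordinate matrix")
  storage.mode(x) <- "double"
  unname(x)
}

#' Label image
#'
#' A rectangular grid of integer region labels with a physical pixel size and
#' origin, the carrier for rasterized atlas sections.  Pixel `[r, c]` has its
#' center at physical coordinates
#' `(origin[1] + (c - 1/2) * pixel_size, origin[2] + (r - 1/2) * pixel_size)`;
#' the row index increases with y (y increases upward).
#'
#' @param pixels integer matrix of region labels.
#' @param pixel_size pixel edge length in micrometres (> 0).
#' @param origin length-2 numeric, physical coordinates of the lower-left
#'   corner of pixel `[1, 1]`.
#' @param background integer label code treated as background (default 0).
#' @return An object of class `label_image`.
#' @export
label_image <- function(pixels, pixel_size, origin = c(0, 0), background = 0L) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "integer"
  if (pixel_size <= 0) stop("pixel_size must be positive")
  structure(list(pixels = pixels, pixel_size = as.numeric(pixel_size),
                 origin = as.numeric(origin),
                 background = as.integer(background)),
            class = "label_image")
}

#' @export
print.label_image <- function(x, ...) {
  cat("<label_image> ", nrow(x$pixels), " x ", ncol(x$pixels),
      " pixels at ", x$pixel_size, " um, ",
      sum(x$pixels != x$background), " foreground\n", sep = "")
  invisible(x)
}

# physical centers of all pixels, as a list(x = matrix of x, y = matrix of y)
pixel_centers <- function(img) {
  nr <- nrow(img$pixels); nc <- ncol(img$pixels)
  cx <- img$origin[1L] + (seq_len(nc) - 0.5) * img$pixel_size
  cy <- img$origin[2L] + (seq_len(nr) - 0.5) * img$pixel_size
  list(cx = cx, cy = cy)
}

#' Particle varifold from a table of point detections
#'
#' Converts a point table (one row per detection or per cell, with a feature
#' identity and an optional multiplicity) into a particle varifold.  At
#' `resolution = "native"` each row becomes one particle whose feature
#' distribution is a delta at its feature.  At a numeric resolution `h`, rows
#' are binned into h x h cells (anchored at the coordinate origin); each
#' occupied cell becomes a single particle at the count-weighted centroid of
#' its rows, with weight equal to the total count and feature distribution
#' equal to the count-normalized feature histogram.  Total mass is conserved
#' exactly.
#'
#' @param points data frame with columns `x`, `y`, `feature` and optionally
#'   `count` (defaults to 1 per row).
#' @param fs a [feature_space()] containing every feature present.
#' @param resolution `"native"` or a positive cell size in micrometres.
#' @return A `particle_varifold`.
#' @export
particles_from_points <- function(points, fs, resolution = "native") {
  points <- as.data.frame(points)
  if (nrow(points) == 0L) stop("no detections")
  required <- c("x", "y", "feature")
  miss <- setdiff(required, names(points))
  if (length(miss)) stop("point table missing column(s): ",
                         paste(miss, collapse = ", "))
  counts <- if ("count" %in% names(points)) as.numeric(points$count)
            else rep(1, nrow(points))
  if (any(counts < 0)) stop("counts must be nonnegative")
  fidx <- feature_index(fs, points$feature)
  xy <- cbind(as.numeric(points$x), as.numeric(points$y))

  if (identical(resolution, "native")) {
    p <- matrix(0, nrow(xy), fs$size)
    p[cbind(seq_len(nrow(xy)), fidx)] <- 1
    return(particle_varifold(xy, counts, p, fs))
  }
  h <- as.numeric(resolution)
  if (!is.finite(h) || h <= 0) stop("resolution must be 'native' or > 0")
  cell <- paste(floor(xy[, 1L] / h), floor(xy[, 2L] / h))
  cell <- factor(cell, levels = unique(cell))
  wtot <- rowsum(counts, cell, reorder = FALSE)[, 1L]
  cx <- rowsum(counts * xy[, 1L], cell, reorder = FALSE)[, 1L] / wtot
  cy <- rowsum(counts * xy[, 2L], cell, reorder = FALSE)[, 1L] / wtot
  hist <- matrix(0, nlevels(cell), fs$size)
  idx <- cbind(as.integer(cell), fidx)
  for (r in seq_len(nrow(idx))) {
    hist[idx[r, 1L], idx[r, 2L]] <- hist[idx[r, 1L], idx[r, 2L]] + counts[r]
  }
  keep <- wtot > 0
  particle_varifold(cbind(cx, cy)[keep, , drop = FALSE], wtot[keep],
                    hist[keep, , drop = FALSE] / wtot[keep], fs)
}

#' Particle varifold from a label image
#'
#' One particle per foreground pixel at the pixel's physical center, with unit
#' weight and a feature distribution concentrated on the pixel's label
#' (constant-density tissue convention for atlas sections).
#'
#' @param img a [label_image()].
#' @param fs a [feature_space()] whose labels are character renderings of the
#'   integer region codes present (e.g. `"5"`).
#' @return A `particle_varifold`.
#' @export
varifold_from_label_image <- function(img, fs) {
  stopifnot(inherits(img, "label_image"))
  fg <- which(img$pixels != img$background, arr.ind = TRUE)
  if (nrow(fg) == 0L) stop("label image has no foreground pixels")
  ctr <- pixel_centers(img)
  xy <- cbind(ctr$cx[fg[, 2L]], ctr$cy[fg[, 1L]])
  lab <- img$pixels[fg]
  fidx <- feature_index(fs, as.character(lab))
  p <- matrix(0, nrow(xy), fs$size)
  p[cbind(seq_len(nrow(xy)), fidx)] <- 1
  particle_varifold(xy, rep(1, nrow(xy)), p, fs)
}
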