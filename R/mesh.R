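#' Build a mesh image varifold from a point table
#'
#' Triangulates a regular grid (Delaunay-consistent diagonal split of each
#' grid square) spanning the bounding box of the detections, assigns every
#' data point to the single simplex containing it (points on a shared edge go
#' to the lowest simplex index), and attaches to each simplex the density
#' `alpha_j` = (mass in simplex) / area and the mass-normalized feature
#' histogram `p_j`.
#'
#' Pruning: simplices containing at least one data point form an
#' edge-adjacency graph; only the largest connected component of occupied
#' simplices is kept, plus empty simplices all of whose edge-neighbors are
#' kept occupied simplices (interior hole fill).  The retained mesh therefore
#' spans the tissue foreground without detached fragments.
#'
#' @inheritParams particles_from_points
#' @param resolution grid cell edge length in micrometres (> 0).
#' @return A `mesh_varifold`; retained total mass equals the mass of the
#'   points falling in retained simplices.
#' @export
build_mesh_varifold <- function(points, fs, resolution) {
  points <- as.data.frame(points)
  if (nrow(points) == 0L) stop("no detections")
  h <- as.numeric(resolution)
  if (!is.finite(h) || h <= 0) stop("resolution must be positive")
  counts <- if ("count" %in% names(points)) as.numeric(points$count)
            else rep(1, nrow(points))
  fidx <- feature_index(fs, points$feature)
  x <- as.numeric(points$x); y <- as.numeric(points$y)

  g <- grid_triangulation(range(x), range(y), h)
  asg <- assign_to_simplex(x, y, g)

  ns <- nrow(g$simplices)
  mass <- rowsum_safe(counts, asg, ns)
  occupied <- mass > 0
  if (!any(occupied)) stop("no retained simplices")

  adj <- simplex_edge_neighbors(g$simplices)
  keep_occ <- largest_occupied_component(adj, occupied)
  # interior hole fill: empty simplices whose every edge-neighbor is a kept
  # occupied simplex
  keep_empty <- vapply(seq_len(ns), function(j) {
    if (occupied[j]) return(FALSE)
    nb <- adj[[j]]
    length(nb) > 0L && all(keep_occ[nb])
  }, logical(1L))
  keep <- keep_occ | keep_empty
  if (!any(keep)) stop("no retained simplices")

  hist <- matrix(0, ns, fs$size)
  inpt <- which(asg > 0L)
  for (r in inpt) hist[asg[r], fidx[r]] <- hist[asg[r], fidx[r]] + counts[r]

  simp <- g$simplices[keep, , drop = FALSE]
  used <- sort(unique(as.integer(simp)))
  remap <- integer(nrow(g$vertices)); remap[used] <- seq_along(used)
  simp <- matrix(remap[simp], ncol = 3L)
  verts <- g$vertices[used, , drop = FALSE]

  areas <- signed_areas(verts, simp)
  if (any(areas <= 0)) stop("degenerate (zero-area) simplex in grid mesh")
  m <- mass[keep]
  p <- hist[keep, , drop = FALSE]
  p[m > 0, ] <- p[m > 0, , drop = FALSE] / m[m > 0]
  p[m == 0, ] <- 1 / fs$size
  mesh_varifold(verts, simp, m / areas, p, fs)
}

# regular grid triangulation over [xr] x [yr] with spacing h; grid nodes are
# placed on multiples of h so that construction is translation-deterministic
grid_triangulation <- function(xr, yr, h) {
  gx <- seq(floor(xr[1L] / h) * h, by = h,
            length.out = max(2L, ceiling(xr[2L] / h) - floor(xr[1L] / h) + 1L))
  gy <- seq(floor(yr[1L] / h) * h, by = h,
            length.out = max(2L, ceiling(yr[2L] / h) - floor(yr[1L] / h) + 1L))
  nx <- length(gx); ny <- length(gy)
  vertices <- cbind(rep(gx, times = ny), rep(gy, each = nx))
  vid <- function(ix, iy) (iy - 1L) * nx + ix
  ncx <- nx - 1L; ncy <- ny - 1L
  ix <- rep(seq_len(ncx), times = ncy)
  iy <- rep(seq_len(ncy), each = ncx)
  ll <- vid(ix, iy); lr <- vid(ix + 1L, iy)
  ul <- vid(ix, iy + 1L); ur <- vid(ix + 1L, iy + 1L)
  # per cell: lower triangle (ll, lr, ur) then upper triangle (ll, ur, ul),
  # both positively oriented; cells enumerated row-major in y
  simplices <- matrix(0L, 2L * ncx * ncy, 3L)
  simplices[seq(1L, nrow(simplices), by = 2L), ] <- cbind(ll, lr, ur)
  simplices[seq(2L, nrow(simplices), by = 2L), ] <- cbind(ll, ur, ul)
  list(vertices = vertices, simplices = simplices,
       gx = gx, gy = gy, nx = nx, ny = ny, h = h)
}

# simplex index (1-based) containing each point; points on the cell diagonal
# go to the lower triangle (the lower simplex index)
assign_to_simplex <- function(x, y, g) {
  ix <- pmin(pmax(floor((x - g$gx[1L]) / g$h) + 1L, 1L), g$nx - 1L)
  iy <- pmin(pmax(floor((y - g$gy[1L]) / g$h) + 1L, 1L), g$ny - 1L)
  u <- (x - g$gx[ix]) / g$h
  v <- (y - g$gy[iy]) / g$h
  cell <- (iy - 1L) * (g$nx - 1L) + ix
  as.integer(2L * (cell - 1L) + ifelse(v <= u, 1L, 2L))
}

rowsum_safe <- function(values, group, n) {
  out <- numeric(n)
  s <- rowsum(values, group)
  out[as.integer(rownames(s))] <- s[, 1L]
  out
}

# list of edge-neighbor simplex indices for each simplex
simplex_edge_neighbors <- function(simplices) {
  ns <- nrow(simplices)
  e1 <- simplices[, c(1L, 2L), drop = FALSE]
  e2 <- simplices[, c(2L, 3L), drop = FALSE]
  e3 <- simplices[, c(1L, 3L), drop = FALSE]
  edges <- rbind(e1, e2, e3)
  edges <- cbind(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
  owner <- rep(seq_len(ns), 3L)
  key <- paste(edges[, 1L], edges[, 2L])
  by_edge <- split(owner, key)
  adj <- vector("list", ns)
  for (os in by_edge) {
    if (length(os) == 2L) {
      adj[[os[1L]]] <- c(adj[[os[1L]]], os[2L])
      adj[[os[2L]]] <- c(adj[[os[2L]]], os[1L])
    }
  }
  adj
}

# logical mask of the largest connected component among occupied simplices,
# connectivity restricted to occupied simplices sharing an edge
largest_occupied_component <- function(adj, occupied) {
  occ <- which(occupied)
  if (length(occ) == 1L) {
    out <- logical(length(adj)); out[occ] <- TRUE
    return(out)
  }
  pairs <- do.call(rbind, lapply(occ, function(j) {
    nb <- adj[[j]]
    nb <- nb[occupied[nb] & nb > j]
    if (length(nb)) cbind(j, nb) else NULL
  }))
  gr <- igraph::make_empty_graph(n = length(adj), directed = FALSE)
  if (!is.null(pairs)) gr <- igraph::add_edges(gr, t(pairs))
  comp <- igraph::components(gr)
  sizes <- tabulate(comp$membership[occ], nbins = comp$no)
  big <- which.max(sizes)
  out <- logical(length(adj))
  out[occ] <- comp$membership[occ] == big
  out
}
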