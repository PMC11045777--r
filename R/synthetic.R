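#' Synthetic scenario with known ground truth
#'
#' Describes a polygonal multi-region "tissue section" and the generative
#' model used to sample a molecular target from it: within each region,
#' detections form a homogeneous Poisson point process whose expected count
#' is `intensity * area * rowmass(pi_star)` and whose features are drawn
#' i.i.d. from the normalized row of the ground-truth feature law, so the
#' target-mass law per unit area is `intensity_l * pi_star_l` (see
#' [ground_truth_law()]).  Optionally, sampled positions are warped by a
#' known diffeomorphism and/or cropped to a partial capture.
#'
#' Region geometry is either `list(type = "voronoi", seeds = <k x 2>)` (the
#' Voronoi cells of the seeds restricted to the rectangle — a polygonal
#' partition) or `list(type = "polygons", polys = <list of rings>)` with
#' explicit, disjoint polygon vertices.
#'
#' The default scenario is a 600 x 450 um rectangle with 5 Voronoi regions
#' and 8 features, detection intensity 0.25 per um^2 (about 1e4 or more
#' expected detections per region), and ground-truth warps of roughly 80 um
#' maximum displacement.
#'
#' @param domain c(width, height) of the rectangle in um.
#' @param regions region geometry spec (see Details).
#' @param pi_star |L| x |F| nonnegative ground-truth feature law.
#' @param intensity per-region expected detections per um^2 (recycled).
#' @param features feature labels of the target feature space.
#' @param deformation NULL, or list with `magnitude` (target maximum
#'   displacement, um), `sigma_v`, `spacing` (control grid spacing, um).
#' @param mask NULL or c(xmin, xmax, ymin, ymax) crop rectangle.
#' @param pixel_size rasterization pixel size (um).
#' @param seed integer seed recorded in all outputs.
#' @return An object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(domain = c(600, 450),
                               regions = NULL,
                               pi_star = NULL,
                               intensity = 0.25,
                               features = paste0("f", 1:8),
                               deformation = list(magnitude = 80,
                                                  sigma_v = 100,
                                                  spacing = 150),
                               mask = NULL,
                               pixel_size = 5,
                               seed = 1L) {
  if (is.null(regions)) {
    regions <- list(type = "voronoi",
                    seeds = cbind(c(110, 460, 300, 120, 480),
                                  c(100, 90, 240, 360, 350)))
  }
  n_regions <- if (regions$type == "voronoi") nrow(regions$seeds)
               else length(regions$polys)
  if (is.null(pi_star)) {
    # distinct, partially overlapping rows with row masses near 1
    base <- matrix(0.02, n_regions, length(features))
    for (l in seq_len(n_regions)) {
      main <- ((l - 1L) %% length(features)) + 1L
      side <- (l %% length(features)) + 1L
      base[l, main] <- base[l, main] + 0.55
      base[l, side] <- base[l, side] + 0.25
    }
    pi_star <- base * seq(0.8, 1.2, length.out = n_regions)
  }
  pi_star <- as.matrix(pi_star)
  if (any(pi_star < 0)) stop("pi_star must be nonnegative")
  if (nrow(pi_star) != n_regions) stop("pi_star must have one row per region")
  if (ncol(pi_star) != length(features))
    stop("pi_star must have one column per feature")
  intensity <- rep_len(as.numeric(intensity), n_regions)
  if (any(intensity < 0)) stop("intensities must be nonnegative")
  if (regions$type == "polygons") check_disjoint_polygons(regions$polys, domain)
  structure(list(domain = as.numeric(domain), regions = regions,
                 pi_star = pi_star, intensity = intensity,
                 features = as.character(features),
                 deformation = deformation, mask = mask,
                 pixel_size = pixel_size, seed = as.integer(seed)),
            class = "synthetic_scenario")
}

# region index (1..L) of each point; 0 outside all regions
region_of <- function(scenario, x, y) {
  if (scenario$regions$type == "voronoi") {
    return(as.integer(cpp_nearest_index(cbind(x, y), scenario$regions$seeds)))
  }
  out <- integer(length(x))
  for (l in seq_along(scenario$regions$polys)) {
    poly <- scenario$regions$polys[[l]]
    inside <- mgcv::in.out(rbind(poly, poly[1L, ]), cbind(x, y))
    out[inside & out == 0L] <- l
  }
  out
}

check_disjoint_polygons <- function(polys, domain) {
  # probe on a grid: no point may fall inside two polygons
  gx <- seq(0, domain[1L], length.out = 40L)
  gy <- seq(0, domain[2L], length.out = 40L)
  pts <- cbind(rep(gx, each = length(gy)), rep(gy, length(gx)))
  hits <- rowSums(vapply(polys, function(poly)
    mgcv::in.out(rbind(poly, poly[1L, ]), pts), logical(nrow(pts))))
  if (any(hits > 1L)) stop("overlapping polygons in region spec")
  invisible(TRUE)
}

region_labels <- function(scenario) {
  n <- if (scenario$regions$type == "voronoi") nrow(scenario$regions$seeds)
       else length(scenario$regions$polys)
  paste0("R", seq_len(n))
}

#' Ground-truth target mass law of a scenario
#'
#' The feature law the estimation should recover: expected target mass per
#' unit atlas area, `intensity_l * pi_star_l(f)`, as a [feature_law()] from
#' region labels to target features.
#'
#' @param scenario a [synthetic_scenario()].
#' @return A [feature_law()].
#' @export
ground_truth_law <- function(scenario) {
  feature_law(scenario$pi_star * scenario$intensity,
              feature_space(region_labels(scenario)),
              feature_space(scenario$features))
}

#' Rasterize a scenario into atlas representations
#'
#' Renders the polygonal partition as a label image at the scenario's pixel
#' size and derives the particle varifold (one unit-weight particle per
#' pixel) and a mesh varifold with unit density (`alpha = 1`, mass = area)
#' with consistent region labels.
#'
#' @param scenario a [synthetic_scenario()].
#' @param mesh_resolution mesh grid edge in um (default 50).
#' @return list with `image` ([label_image()]), `particles`
#'   (`particle_varifold`), `mesh` (`mesh_varifold`) and `fs` (the region
#'   [feature_space()]).
#' @export
make_atlas <- function(scenario, mesh_resolution = 50) {
  px <- scenario$pixel_size
  nc <- round(scenario$domain[1L] / px)
  nr <- round(scenario$domain[2L] / px)
  cx <- (seq_len(nc) - 0.5) * px
  cy <- (seq_len(nr) - 0.5) * px
  xx <- rep(cx, each = nr)
  yy <- rep(cy, nc)
  lab <- region_of(scenario, xx, yy)
  img <- label_image(matrix(lab, nr, nc), px, c(0, 0), background = 0L)
  fs <- feature_space(region_labels(scenario))
  labels_chr <- region_labels(scenario)
  # particle rendering: unit weight per foreground pixel
  keep <- lab > 0L
  p <- matrix(0, sum(keep), fs$size)
  p[cbind(seq_len(sum(keep)), lab[keep])] <- 1
  particles <- particle_varifold(cbind(xx[keep], yy[keep]), rep(1, sum(keep)),
                                 p, fs)
  # unit-density mesh: per-simplex label histogram from pixel assignment
  tab <- data.frame(x = xx[keep], y = yy[keep],
                    feature = labels_chr[lab[keep]], count = 1)
  mesh <- build_mesh_varifold(tab, fs, mesh_resolution)
  mesh <- mesh_varifold(mesh$vertices, mesh$simplices,
                        rep(1, nrow(mesh$simplices)), mesh$p, fs)
  list(image = img, particles = particles, mesh = mesh, fs = fs)
}

#' Sample a molecular target from a scenario
#'
#' Seeded realization of the generative model: per region a Poisson point
#' process of detections with intensity `intensity * rowmass(pi_star)` per
#' square micrometre of *observed* tissue, features i.i.d. from the
#' normalized feature-law row.  Without a warp the expected count per region
#' is `intensity * area * rowmass(pi_star)`.  With a ground-truth warp the
#' homogeneity assumption of the model is preserved on the warped geometry:
#' the process is sampled with atlas-space intensity proportional to
#' `|Dphi|` (exact Poisson thinning) and positions are then transported
#' through the diffeomorphism, so the observed process is homogeneous within
#' each warped region with the same density law.  If the scenario specifies
#' a mask, rows outside the crop rectangle are dropped.
#'
#' @param scenario a [synthetic_scenario()].
#' @param atlas optional result of [make_atlas()] (areas are computed from
#'   the label image when given, otherwise analytically from pixel
#'   counting).
#' @param warp optional [diffeomorphism()] overriding the scenario's
#'   ground-truth warp (e.g. from [make_ground_truth_diffeo()]).
#' @return data frame with columns `x`, `y`, `feature`.
#' @export
sample_target <- function(scenario, atlas = NULL, warp = NULL) {
  if (is.null(warp) && !is.null(scenario$deformation))
    warp <- make_ground_truth_diffeo(scenario)
  set.seed(scenario$seed)
  L <- nrow(scenario$pi_star)
  areas <- region_areas(scenario, atlas)
  jmax <- 1
  if (!is.null(warp)) {
    pg <- probe_grid(scenario$domain, 15)
    jmax <- 1.1 * max(map_points(warp, pg, "forward", jacobian = TRUE)$jac)
  }
  rows <- vector("list", L)
  for (l in seq_len(L)) {
    rowmass <- sum(scenario$pi_star[l, ])
    lambda <- scenario$intensity[l] * areas[l] * rowmass * jmax
    n <- stats::rpois(1L, lambda)
    if (n == 0L) next
    pts <- sample_in_region(scenario, l, n)
    if (!is.null(warp)) {
      # thin to intensity proportional to |Dphi| so the transported process
      # is homogeneous on the warped region
      jac <- map_points(warp, pts, "forward", jacobian = TRUE)$jac
      keep <- stats::runif(n) < pmin(jac / jmax, 1)
      pts <- pts[keep, , drop = FALSE]
      n <- nrow(pts)
      if (n == 0L) next
    }
    pf <- scenario$pi_star[l, ] / rowmass
    feat <- scenario$features[sample.int(length(pf), n, replace = TRUE,
                                         prob = pf)]
    rows[[l]] <- data.frame(x = pts[, 1L], y = pts[, 2L], feature = feat)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(x = numeric(), y = numeric(),
                                      feature = character())
  if (!is.null(warp) && nrow(out) > 0L) {
    mp <- map_points(warp, cbind(out$x, out$y), direction = "forward",
                     jacobian = FALSE)
    out$x <- mp$points[, 1L]
    out$y <- mp$points[, 2L]
  }
  if (!is.null(scenario$mask) && nrow(out) > 0L) {
    m <- scenario$mask
    out <- out[out$x >= m[1L] & out$x <= m[2L] &
                 out$y >= m[3L] & out$y <= m[4L], , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

region_areas <- function(scenario, atlas = NULL) {
  if (!is.null(atlas)) {
    counts <- tabulate(atlas$image$pixels[atlas$image$pixels > 0L],
                       nbins = nrow(scenario$pi_star))
    return(counts * atlas$image$pixel_size^2)
  }
  # pixel-counting at the scenario's pixel size
  px <- scenario$pixel_size
  nc <- round(scenario$domain[1L] / px)
  nr <- round(scenario$domain[2L] / px)
  xx <- rep((seq_len(nc) - 0.5) * px, each = nr)
  yy <- rep((seq_len(nr) - 0.5) * px, nc)
  lab <- region_of(scenario, xx, yy)
  tabulate(lab[lab > 0L], nbins = nrow(scenario$pi_star)) * px^2
}

# uniform rejection sampling of n points inside region l
sample_in_region <- function(scenario, l, n) {
  out <- matrix(0, 0L, 2L)
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 32L)
    x <- stats::runif(m, 0, scenario$domain[1L])
    y <- stats::runif(m, 0, scenario$domain[2L])
    keep <- region_of(scenario, x, y) == l
    out <- rbind(out, cbind(x[keep], y[keep]))
  }
  out[seq_len(n), , drop = FALSE]
}

#' Seeded ground-truth diffeomorphism of a scenario
#'
#' Draws random momenta on a coarse control grid, scaled so the maximum
#' displacement over a probe grid is close to the requested magnitude while
#' the flow stays diffeomorphic (`|Dphi| > 0` verified on a dense probe
#' grid); shrinks the momenta and retries if the requested magnitude folds
#' the flow.
#'
#' @param scenario a [synthetic_scenario()] with a non-NULL deformation
#'   spec.
#' @param n_steps number of flow timesteps.
#' @return A [diffeomorphism()].
#' @export
make_ground_truth_diffeo <- function(scenario, n_steps = 10L) {
  spec <- scenario$deformation
  if (is.null(spec)) {
    q0 <- cbind(scenario$domain[1L] / 2, scenario$domain[2L] / 2)
    return(diffeomorphism(velocity_field(q0, NULL, 100, n_steps)))
  }
  set.seed(scenario$seed + 7919L)
  gx <- seq(0, scenario$domain[1L], by = spec$spacing)
  gy <- seq(0, scenario$domain[2L], by = spec$spacing)
  q0 <- cbind(rep(gx, each = length(gy)), rep(gy, length(gx)))
  raw <- matrix(stats::rnorm(nrow(q0) * 2L), ncol = 2L)
  probes <- probe_grid(scenario$domain, 25)
  if (spec$magnitude <= 0)
    return(diffeomorphism(velocity_field(q0, NULL, spec$sigma_v, n_steps)))
  # one kernel application sets the displacement scale of unit momenta
  v0 <- cpp_gauss_mv(probes, q0, spec$sigma_v, raw)
  tau <- spec$magnitude / max(sqrt(rowSums(v0^2)))
  repeat {
    momenta <- array(rep(tau * raw, each = n_steps),
                     dim = c(n_steps, nrow(q0), 2L))
    field <- velocity_field(q0, momenta, spec$sigma_v, n_steps)
    ok <- tryCatch({
      fl <- flow(field, probes, "forward", jacobian = TRUE)
      all(fl$jac > 0)
    }, error = function(e) FALSE)
    if (ok) {
      disp <- max(sqrt(rowSums((flow(field, probes, "forward",
                                     jacobian = FALSE)$points - probes)^2)))
      if (disp <= 1.2 * spec$magnitude) break
    }
    tau <- 0.8 * tau
    if (tau < 1e-8) stop("requested warp magnitude folds the flow; ",
                         "reduce magnitude or increase sigma_v")
  }
  diffeomorphism(field)
}

probe_grid <- function(domain, spacing) {
  gx <- seq(spacing / 2, domain[1L] - spacing / 2, by = spacing)
  gy <- seq(spacing / 2, domain[2L] - spacing / 2, by = spacing)
  cbind(rep(gx, each = length(gy)), rep(gy, length(gx)))
}

#' Render a DAPI-like intensity image and its particle conversion
#'
#' Renders a per-region base intensity (proportional to the region's
#' expected target density) with additive Gaussian noise, discretizes the
#' image values into `n_bins` equal-width bins, keeps the later `n_fg` bins
#' as foreground, and converts non-overlapping 5 x 5 pixel blocks into one
#' particle each, carrying the count of foreground pixels as weight and the
#' bin histogram as feature distribution.
#'
#' @param scenario a [synthetic_scenario()].
#' @param n_bins number of equal-width intensity bins (default 35).
#' @param n_fg number of trailing bins treated as foreground (default 30).
#' @param noise_sd Gaussian noise standard deviation on the unit intensity
#'   scale.
#' @param block block edge in pixels (default 5).
#' @return list with `image` (matrix of intensities in `[0, 1]`),
#'   `particles` (`particle_varifold` over bin labels), `bins` (the bin
#'   [feature_space()]).
#' @export
make_dapi_like <- function(scenario, n_bins = 35L, n_fg = 30L,
                           noise_sd = 0.03, block = 5L) {
  set.seed(scenario$seed + 104729L)
  px <- scenario$pixel_size
  nc <- round(scenario$domain[1L] / px)
  nr <- round(scenario$domain[2L] / px)
  xx <- rep((seq_len(nc) - 0.5) * px, each = nr)
  yy <- rep((seq_len(nr) - 0.5) * px, nc)
  lab <- region_of(scenario, xx, yy)
  dens <- scenario$intensity * rowSums(scenario$pi_star)
  lvl <- if (max(dens) > 0) 0.25 + 0.7 * dens / max(dens) else dens
  base <- c(0, lvl)[lab + 1L]
  img <- matrix(pmin(pmax(base + stats::rnorm(length(base), 0, noise_sd), 0),
                     1), nr, nc)
  bin <- matrix(pmin(pmax(ceiling(img * n_bins), 1L), n_bins), nr, nc)
  fg_from <- n_bins - n_fg + 1L
  bins_fs <- feature_space(sprintf("bin%02d", fg_from:n_bins))
  rows <- list()
  for (br in seq_len(nr %/% block)) {
    for (bc in seq_len(nc %/% block)) {
      rs <- (br - 1L) * block + seq_len(block)
      cs <- (bc - 1L) * block + seq_len(block)
      sub <- bin[rs, cs]
      fg <- sub >= fg_from
      if (!any(fg)) next
      cnt <- tabulate(sub[fg] - fg_from + 1L, nbins = n_fg)
      # foreground-pixel centroid of the block
      idx <- which(fg, arr.ind = TRUE)
      cx <- mean((cs[idx[, 2L]] - 0.5) * px)
      cy <- mean((rs[idx[, 1L]] - 0.5) * px)
      rows[[length(rows) + 1L]] <-
        list(x = cx, y = cy, w = sum(fg), p = cnt / sum(fg))
    }
  }
  if (length(rows) == 0L) {
    particles <- NULL
  } else {
    particles <- particle_varifold(
      do.call(rbind, lapply(rows, function(r) c(r$x, r$y))),
      vapply(rows, `[[`, numeric(1L), "w"),
      do.call(rbind, lapply(rows, `[[`, "p")),
      bins_fs)
  }
  list(image = img, particles = particles, bins = bins_fs)
}
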