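#' Read and write point detection tables
#'
#' CSV or TSV (dialect chosen by file extension) with mandatory header and
#' required columns `x`, `y`, `feature`, plus optional `count`.  Reading
#' validates the columns and reports the first offending row on non-numeric
#' coordinates; writing and re-reading round-trips finite values.
#'
#' @param path file path ending in `.csv` or `.tsv`/`.txt`.
#' @return `read_point_table` returns a data frame.
#' @export
read_point_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE,
                           colClasses = NA, check.names = TRUE)
  miss <- setdiff(c("x", "y", "feature"), names(tab))
  if (length(miss))
    stop("point table ", path, " missing column(s): ",
         paste(miss, collapse = ", "))
  for (col in intersect(c("x", "y", "count"), names(tab))) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v) & !is.na(tab[[col]]))
    if (length(bad))
      stop("non-numeric value in column '", col, "' at row ", bad[1L])
    tab[[col]] <- v
  }
  tab$feature <- as.character(tab$feature)
  tab
}

#' @rdname read_point_table
#' @param table data frame with columns `x`, `y`, `feature` and optional
#'   `count`.
#' @export
write_point_table <- function(table, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(table, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".json")

#' Read and write label images
#'
#' Label images are stored as 16-bit grayscale TIFF (or PNG) with a JSON
#' sidecar (`<path>.json`) holding the pixel size, origin, background code
#' and format tag; integer labels up to 65535 round-trip exactly.
#'
#' @param img a [label_image()].
#' @param path file path ending in `.tif`/`.tiff` or `.png`.
#' @return `read_label_image` returns a [label_image()].
#' @export
write_label_image <- function(img, path) {
  stopifnot(inherits(img, "label_image"))
  m <- img$pixels
  png <- grepl("\\.png$", path, ignore.case = TRUE)
  depth <- if (png) 255L else 65535L  # PNG is written 8-bit, TIFF 16-bit
  if (any(m < 0L) || any(m > depth))
    stop("labels must be in 0..", depth, " for this format")
  # flip so row 1 (smallest y) is written at the image bottom
  norm <- m[rev(seq_len(nrow(m))), , drop = FALSE] / depth
  if (png) png::writePNG(norm, path)
  else tiff::writeTIFF(norm, path, bits.per.sample = 16L)
  meta <- list(format = "varifoldmap-label-image", version = 1L,
               pixel_size = img$pixel_size, origin = img$origin,
               background = img$background, depth = depth)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_label_image
#' @export
read_label_image <- function(path) {
  meta <- read_sidecar(path, "varifoldmap-label-image")
  norm <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    tiff::readTIFF(path)
  }
  if (length(dim(norm)) == 3L) norm <- norm[, , 1L]
  depth <- meta$depth %||% 65535L
  m <- round(norm * depth)
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  label_image(m, meta$pixel_size, unlist(meta$origin), meta$background)
}

read_sidecar <- function(path, expected_format) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) stop("missing JSON sidecar: ", sp)
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  if (!identical(meta$format, expected_format))
    stop("format mismatch in ", sp, ": expected '", expected_format,
         "', found '", meta$format %||% "<none>", "'")
  if (!identical(as.integer(meta$version), 1L))
    stop("schema version mismatch in ", sp, ": expected 1, found ",
         meta$version %||% "<none>")
  meta
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write mesh varifolds
#'
#' Legacy ASCII VTK polydata (triangle cells with `alpha` and the feature
#' distribution as cell data fields) plus a JSON sidecar naming the feature
#' space.  Numeric payloads round-trip to full double precision.
#'
#' @param mesh a `mesh_varifold`.
#' @param path file path ending in `.vtk`.
#' @return `read_mesh_varifold` returns a `mesh_varifold`.
#' @export
write_mesh_varifold <- function(mesh, path) {
  stopifnot(inherits(mesh, "mesh_varifold"))
  nV <- nrow(mesh$vertices); nS <- nrow(mesh$simplices)
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(x) format(x, digits = 17, scientific = TRUE, trim = TRUE)
  writeLines(c("# vtk DataFile Version 3.0", "varifoldmap mesh varifold",
               "ASCII", "DATASET POLYDATA",
               paste("POINTS", nV, "double")), con)
  writeLines(paste(fmt(mesh$vertices[, 1L]), fmt(mesh$vertices[, 2L]), "0"),
             con)
  writeLines(paste("POLYGONS", nS, 4L * nS), con)
  writeLines(paste(3L, mesh$simplices[, 1L] - 1L, mesh$simplices[, 2L] - 1L,
                   mesh$simplices[, 3L] - 1L), con)
  writeLines(c(paste("CELL_DATA", nS), "FIELD varifold 2",
               paste("alpha 1", nS, "double")), con)
  writeLines(fmt(mesh$alpha), con)
  writeLines(paste("p", mesh$fs$size, nS, "double"), con)
  writeLines(apply(mesh$p, 1L, function(r) paste(fmt(r), collapse = " ")),
             con)
  meta <- list(format = "varifoldmap-mesh", version = 1L,
               features = mesh$fs$labels)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_mesh_varifold
#' @export
read_mesh_varifold <- function(path) {
  meta <- read_sidecar(path, "varifoldmap-mesh")
  fs <- feature_space(unlist(meta$features))
  lines <- readLines(path)
  if (!grepl("^# vtk DataFile", lines[1L]))
    stop("format mismatch in ", path, ": expected a legacy VTK file")
  ip <- grep("^POINTS", lines)[1L]
  nV <- as.integer(strsplit(lines[ip], "\\s+")[[1L]][2L])
  pts <- do.call(rbind, strsplit(lines[ip + seq_len(nV)], "\\s+"))
  vertices <- cbind(as.numeric(pts[, 1L]), as.numeric(pts[, 2L]))
  ic <- grep("^POLYGONS", lines)[1L]
  nS <- as.integer(strsplit(lines[ic], "\\s+")[[1L]][2L])
  cells <- do.call(rbind, strsplit(lines[ic + seq_len(nS)], "\\s+"))
  simplices <- matrix(as.integer(cells[, 2:4]), ncol = 3L) + 1L
  ia <- grep("^alpha 1", lines)[1L]
  alpha <- as.numeric(lines[ia + seq_len(nS)])
  ipd <- grep("^p ", lines)[1L]
  hdr <- as.integer(strsplit(lines[ipd], "\\s+")[[1L]][2:3])
  if (hdr[1L] != fs$size)
    stop("feature count mismatch in ", path, ": expected ", fs$size,
         ", found ", hdr[1L])
  pm <- do.call(rbind, strsplit(lines[ipd + seq_len(nS)], "\\s+"))
  p <- matrix(as.numeric(pm), nS, fs$size)
  mesh_varifold(vertices, simplices, alpha, p, fs)
}

#' Read and write particle varifolds
#'
#' CSV with columns `x`, `y`, `w` and one `p_<label>` column per feature,
#' plus a JSON sidecar naming the feature space.
#'
#' @param mu a `particle_varifold`.
#' @param path file path ending in `.csv`.
#' @return `read_particle_varifold` returns a `particle_varifold`.
#' @export
write_particle_varifold <- function(mu, path) {
  stopifnot(inherits(mu, "particle_varifold"))
  tab <- data.frame(x = mu$x[, 1L], y = mu$x[, 2L], w = mu$w)
  pm <- as.data.frame(mu$p)
  names(pm) <- paste0("p_", mu$fs$labels)
  utils::write.table(cbind(tab, pm), path, sep = ",", row.names = FALSE,
                     quote = FALSE)
  meta <- list(format = "varifoldmap-particles", version = 1L,
               features = mu$fs$labels)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_particle_varifold
#' @export
read_particle_varifold <- function(path) {
  meta <- read_sidecar(path, "varifoldmap-particles")
  fs <- feature_space(unlist(meta$features))
  tab <- utils::read.csv(path)
  pc <- paste0("p_", fs$labels)
  miss <- setdiff(c("x", "y", "w", pc), names(tab))
  if (length(miss)) stop("particle file ", path, " missing column(s): ",
                         paste(miss, collapse = ", "))
  particle_varifold(cbind(tab$x, tab$y), tab$w, as.matrix(tab[pc]), fs)
}

#' Read and write diffeomorphism archives
#'
#' A single JSON archive holding the control points, per-timestep momenta,
#' kernel bandwidth, number of timesteps, and the rigid+scale pre-transform,
#' so an estimated mapping can be re-applied to any new point set.
#'
#' @param phi a [diffeomorphism()].
#' @param path file path ending in `.json`.
#' @return `read_diffeo` returns a [diffeomorphism()].
#' @export
write_diffeo <- function(phi, path) {
  stopifnot(inherits(phi, "diffeomorphism"))
  f <- phi$field
  obj <- list(format = "varifoldmap-diffeo", version = 1L,
              sigma_v = f$sigma_v, n_steps = f$n_steps,
              direction = phi$direction,
              control_points = f$q0,
              momenta = as.numeric(f$momenta),
              rigid = if (is.null(phi$rigid)) NULL else
                list(angle = phi$rigid$angle,
                     translation = phi$rigid$translation,
                     scale = phi$rigid$scale,
                     center = phi$rigid$center))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_diffeo
#' @export
read_diffeo <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "varifoldmap-diffeo"))
    stop("format mismatch in ", path, ": expected 'varifoldmap-diffeo', ",
         "found '", obj$format %||% "<none>", "'")
  q0 <- matrix(as.numeric(obj$control_points), ncol = 2L)
  field <- velocity_field(q0,
                          array(obj$momenta,
                                dim = c(obj$n_steps, nrow(q0), 2L)),
                          obj$sigma_v, obj$n_steps)
  rigid <- if (!is.null(obj$rigid))
    rigid_scale(obj$rigid$angle, unlist(obj$rigid$translation),
                obj$rigid$scale, unlist(obj$rigid$center))
  diffeomorphism(field, rigid = rigid, direction = obj$direction)
}

#' Read and write feature laws
#'
#' CSV matrix (atlas label rows, target feature columns) plus a JSON
#' metadata sidecar recording the solver status, attained objective and the
#' bounds used, when available.
#'
#' @param pi a [feature_law()].
#' @param path file path ending in `.csv`.
#' @return `read_feature_law` returns a [feature_law()].
#' @export
write_feature_law <- function(pi, path) {
  stopifnot(inherits(pi, "feature_law"))
  utils::write.csv(as.data.frame(unclass(pi)), path, row.names = TRUE)
  meta <- list(format = "varifoldmap-feature-law", version = 1L,
               atlas_labels = attr(pi, "atlas_fs")$labels,
               target_features = attr(pi, "target_fs")$labels,
               objective = attr(pi, "objective"),
               status = attr(pi, "status"))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_feature_law
#' @export
read_feature_law <- function(path) {
  meta <- read_sidecar(path, "varifoldmap-feature-law")
  tab <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  feature_law(as.matrix(tab), feature_space(unlist(meta$atlas_labels)),
              feature_space(unlist(meta$target_features)))
}

# ---- run configuration ----------------------------------------------------

config_schema <- list(
  top = c("paths", "norm", "registration", "scenario", "output",
          "verbosity", "seed"),
  norm = c("sigma_w", "template_mask", "target_mask"),
  registration = c("sigma_v", "n_steps", "n_ctrl", "mesh_resolution",
                   "max_outer", "inner_maxit", "joint_maxit", "rel_tol",
                   "lambda_kl", "bounds_mode", "use_greedy", "data_weight",
                   "rigid", "rigid_angles", "scheme"),
  scenario = c("domain", "seeds", "pi_star", "intensity", "features",
               "deformation", "mask", "pixel_size"))

#' Read and validate a run configuration
#'
#' YAML (or JSON) configuration with blocks `paths`, `norm`, `registration`,
#' `scenario`, `output`, `verbosity` and `seed`; unknown keys are rejected
#' before any computation.
#'
#' @param path YAML/JSON file path.
#' @return A validated named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  check_keys <- function(block, allowed, where) {
    extra <- setdiff(names(block), allowed)
    if (length(extra))
      stop("unknown configuration key(s) in ", where, ": ",
           paste(extra, collapse = ", "))
  }
  check_keys(cfg, config_schema$top, "top level")
  if (!is.null(cfg$norm)) check_keys(cfg$norm, config_schema$norm, "norm")
  if (!is.null(cfg$registration))
    check_keys(cfg$registration, config_schema$registration, "registration")
  if (!is.null(cfg$scenario))
    check_keys(cfg$scenario, config_schema$scenario, "scenario")
  structure(cfg, class = "run_config")
}

#' Build a registration configuration from a run configuration
#'
#' @param cfg a [read_run_config()] result.
#' @return A [registration_config()].
#' @export
config_to_registration <- function(cfg) {
  norm <- norm_config(sigma_w = cfg$norm$sigma_w %||% c(400, 200, 100))
  args <- cfg$registration %||% list()
  args$scheme <- NULL
  args$norm <- norm
  if (!is.null(cfg$seed)) args$seed <- cfg$seed
  do.call(registration_config, args)
}

#' Write a reproducibility manifest
#'
#' Records the configuration file checksum, the seed and the package version
#' next to a run's outputs.
#'
#' @param dir output directory.
#' @param config_path path of the configuration used (or NULL).
#' @param seed the seed used.
#' @return invisibly, the manifest path.
#' @export
write_manifest <- function(dir, config_path = NULL, seed = NA_integer_) {
  manifest <- list(
    package = "varifoldmap",
    version = as.character(utils::packageVersion("varifoldmap")),
    config = config_path,
    config_md5 = if (!is.null(config_path))
      unname(tools::md5sum(config_path)) else NULL,
    seed = seed,
    timestamp = format(Sys.time(), tz = "UTC"))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE)
  invisible(path)
}
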