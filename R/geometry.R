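# Cell and cluster geometry: ellipsoidal cells with a spherical nucleus,
# rectangular-grid clusters around a central target cell, and source-point
# position sampling for the two internalization scenarios.

#' Construct an ellipsoidal cell
#'
#' A cell is an ellipsoid of liquid water with a 10 nm membrane shell and a
#' concentric spherical nucleus of radius 4.65 um. The five catalog
#' geometries share a volume of about 4189 um^3.
#'
#' @param half_lengths Numeric 3-vector, half-lengths of the principal axes
#'   (um).
#' @param membrane_thickness Membrane thickness (um), default 0.01 (10 nm).
#' @param nucleus_radius Nucleus radius (um), default 4.65.
#' @return An object of class `ellipsoid_cell`.
#' @examples
#' cell <- ellipsoid_cell(c(10, 10, 10))
#' cell_volume(cell)
#' @export
ellipsoid_cell <- function(half_lengths, membrane_thickness = 0.01,
                           nucleus_radius = NUCLEUS_RADIUS_UM) {
  half_lengths <- as.numeric(half_lengths)
  if (length(half_lengths) != 3 || any(!is.finite(half_lengths)) ||
      any(half_lengths <= 0)) {
    stop("half_lengths must be three positive numbers (um)")
  }
  if (membrane_thickness <= 0 || nucleus_radius <= 0) {
    stop("membrane_thickness and nucleus_radius must be positive")
  }
  if (any(half_lengths <= nucleus_radius + membrane_thickness)) {
    stop("nucleus (plus membrane) must fit strictly inside the cell")
  }
  structure(
    list(half_lengths = half_lengths,
         membrane_thickness = membrane_thickness,
         nucleus_radius = nucleus_radius),
    class = "ellipsoid_cell"
  )
}

#' @export
print.ellipsoid_cell <- function(x, ...) {
  cat("Ellipsoidal cell: half-lengths (", paste(x$half_lengths, collapse = ", "),
      ") um, nucleus radius ", x$nucleus_radius, " um, membrane ",
      x$membrane_thickness * 1000, " nm\n", sep = "")
  invisible(x)
}

#' Cell volume
#'
#' @param cell An `ellipsoid_cell`.
#' @return Volume in um^3.
#' @export
cell_volume <- function(cell) {
  (4 / 3) * pi * prod(cell$half_lengths)
}

#' Catalog of the five equal-volume cell geometries
#'
#' Reads the packaged catalog of the five ellipsoid geometries (equal volume
#' of about 4189 um^3) and returns one of them, or the whole table.
#'
#' @param id Integer 1..5 selecting a geometry, or `NULL` for the full table.
#' @return An `ellipsoid_cell` if `id` is given, otherwise a data.frame.
#' @export
cell_geometry <- function(id = NULL) {
  path <- system.file("extdata", "cell_geometries.csv", package = "rbesim",
                      mustWork = TRUE)
  tab <- utils::read.csv(path)
  if (is.null(id)) return(tab)
  if (!id %in% tab$id) stop("unknown cell geometry id: ", id)
  row <- tab[tab$id == id, ]
  ellipsoid_cell(c(row$hlx_um, row$hly_um, row$hlz_um))
}

#' Number of cells along one cluster axis
#'
#' The cluster around the central target cell extends along each axis as far
#' as the emitted particles can travel and still reach the central nucleus:
#' n = 2 * ceiling(((particle_range + nucleus_radius) / half_length - 1) / 2) + 1,
#' clamped below at 1. The result is always odd so a central cell exists.
#'
#' @param particle_range Particle range (um).
#' @param nucleus_radius Nucleus radius (um).
#' @param half_length Cell half-length along the axis (um).
#' @return Odd positive integer count of cells along the axis.
#' @examples
#' cells_per_axis(140, 4.65, 10)   # 15
#' cells_per_axis(86.53, 4.65, 5)  # 19
#' @export
cells_per_axis <- function(particle_range, nucleus_radius, half_length) {
  if (any(c(particle_range, nucleus_radius, half_length) <= 0) ||
      any(!is.finite(c(particle_range, nucleus_radius, half_length)))) {
    stop("all arguments must be positive and finite")
  }
  n <- 2 * ceiling(((particle_range + nucleus_radius) / half_length - 1) / 2) + 1
  as.integer(max(1L, n))
}

#' Build a cell cluster around a central target cell
#'
#' Cells tile space on a rectangular grid with pitch 2*HL per axis. The
#' particle range is selected per nuclide and arrangement: Lu-177 uses
#' 280 um for planar monolayers and 140 um for 3D lattices; Ac-225 uses
#' 86.53 um for both. Planar clusters span the two axes with the largest
#' half-lengths (the reading that reproduces the published cell counts);
#' the third axis count is fixed at 1.
#'
#' @param cell An `ellipsoid_cell`.
#' @param arrangement `"planar_2d"` or `"lattice_3d"`.
#' @param radionuclide `"Lu177"` or `"Ac225"`.
#' @return An object of class `cell_cluster` with fields `cell`,
#'   `arrangement`, `radionuclide`, `particle_range`, `counts_per_axis`,
#'   `n_cells`, and `centers` (matrix of cell-center coordinates, um; the
#'   central cell is at the origin).
#' @examples
#' cl <- build_cluster(cell_geometry(1), "lattice_3d", "Lu177")
#' cl$n_cells  # 3375
#' @export
build_cluster <- function(cell, arrangement = c("planar_2d", "lattice_3d"),
                          radionuclide = c("Lu177", "Ac225")) {
  arrangement <- match.arg(arrangement)
  radionuclide <- match.arg(radionuclide)
  stopifnot(inherits(cell, "ellipsoid_cell"))
  rc <- range_catalog()
  particle_range <- if (radionuclide == "Ac225") {
    rc$ac_range
  } else if (arrangement == "planar_2d") {
    rc$lu_range_2d
  } else {
    rc$lu_range_3d
  }
  hl <- cell$half_lengths
  counts <- vapply(hl, function(h) {
    cells_per_axis(particle_range, cell$nucleus_radius, h)
  }, integer(1))
  if (arrangement == "planar_2d") {
    # monolayer spans the two axes with the largest half-lengths
    in_plane <- order(hl, decreasing = TRUE)[1:2]
    counts[setdiff(1:3, in_plane)] <- 1L
  }
  idx <- lapply(counts, function(n) seq.int(-(n - 1L) / 2L, (n - 1L) / 2L))
  grid <- as.matrix(expand.grid(ix = idx[[1]], iy = idx[[2]], iz = idx[[3]]))
  centers <- sweep(grid, 2, 2 * hl, `*`)
  colnames(centers) <- c("x", "y", "z")
  structure(
    list(cell = cell, arrangement = arrangement, radionuclide = radionuclide,
         particle_range = particle_range, counts_per_axis = counts,
         n_cells = as.integer(prod(counts)), indices = grid,
         centers = centers),
    class = "cell_cluster"
  )
}

#' @export
print.cell_cluster <- function(x, ...) {
  cat("Cell cluster (", x$radionuclide, ", ", x$arrangement, "): ",
      paste(x$counts_per_axis, collapse = " x "), " = ", x$n_cells,
      " cells, particle range ", x$particle_range, " um\n", sep = "")
  invisible(x)
}

#' Export a cluster layout as a data.frame
#'
#' @param cluster A `cell_cluster`.
#' @return data.frame with lattice indices and center coordinates (um).
#' @export
cluster_layout <- function(cluster) {
  stopifnot(inherits(cluster, "cell_cluster"))
  data.frame(ix = cluster$indices[, 1], iy = cluster$indices[, 2],
             iz = cluster$indices[, 3],
             x_um = cluster$centers[, 1], y_um = cluster$centers[, 2],
             z_um = cluster$centers[, 3])
}

#' Classify a point relative to a cell
#'
#' Regions are mutually exclusive and exhaustive: `nucleus` (inside the
#' nucleus sphere), `cytoplasm` (inside the membrane's inner surface but
#' outside the nucleus), `membrane` (within the 10 nm shell), `outside`.
#'
#' @param cell An `ellipsoid_cell`.
#' @param p Numeric 3-vector or n x 3 matrix of points (um, cell frame).
#' @return Character vector of region labels.
#' @export
point_region <- function(cell, p) {
  stopifnot(inherits(cell, "ellipsoid_cell"))
  p <- if (is.matrix(p)) p else matrix(p, ncol = 3)
  hl <- cell$half_lengths
  hin <- hl - cell$membrane_thickness
  q_out <- rowSums(sweep(p, 2, hl, `/`)^2)
  q_in <- rowSums(sweep(p, 2, hin, `/`)^2)
  r2 <- rowSums(p^2)
  region <- rep("outside", nrow(p))
  region[q_out <= 1] <- "membrane"
  region[q_in <= 1] <- "cytoplasm"
  region[q_in <= 1 & r2 <= cell$nucleus_radius^2] <- "nucleus"
  region
}

# Uniform sampling on a unit sphere, n x 3 matrix.
sample_unit_sphere <- function(n) {
  m <- matrix(stats::rnorm(3 * n), ncol = 3)
  m / sqrt(rowSums(m^2))
}

# Area-uniform points on the ellipsoid surface x = (a,b,c) * u via
# gradient-norm rejection from the unit-sphere parameterization.
sample_ellipsoid_surface <- function(half_lengths, n) {
  a <- half_lengths[1]; b <- half_lengths[2]; c <- half_lengths[3]
  gmax <- max(b * c, a * c, a * b)
  out <- matrix(numeric(0), ncol = 3)
  while (nrow(out) < n) {
    m <- max(1000L, ceiling((n - nrow(out)) * 1.6))
    u <- sample_unit_sphere(m)
    g <- sqrt((b * c * u[, 1])^2 + (a * c * u[, 2])^2 + (a * b * u[, 3])^2)
    keep <- stats::runif(m) < g / gmax
    out <- rbind(out, sweep(u[keep, , drop = FALSE], 2, half_lengths, `*`))
  }
  out[seq_len(n), , drop = FALSE]
}

# Volume-uniform points in the cytoplasm (inside the shrunk ellipsoid,
# outside the nucleus sphere) via bounding-box rejection.
sample_cytoplasm <- function(cell, n) {
  hin <- cell$half_lengths - cell$membrane_thickness
  rn2 <- cell$nucleus_radius^2
  out <- matrix(numeric(0), ncol = 3)
  # acceptance fraction = (V_inner - V_nucleus) / V_box
  acc <- ((4 / 3) * pi * prod(hin) - (4 / 3) * pi * cell$nucleus_radius^3) /
    (8 * prod(hin))
  while (nrow(out) < n) {
    m <- max(1000L, ceiling((n - nrow(out)) / acc * 1.2))
    p <- matrix(stats::runif(3 * m, -1, 1), ncol = 3)
    p <- sweep(p, 2, hin, `*`)
    keep <- rowSums(sweep(p, 2, hin, `/`)^2) <= 1 & rowSums(p^2) > rn2
    out <- rbind(out, p[keep, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

#' Sample source-point positions for an internalization scenario
#'
#' Membrane-bound sources are distributed uniformly per unit area on the
#' outer ellipsoid surface; fully internalized sources uniformly per unit
#' volume in the cytoplasm (inside the membrane's inner surface, outside
#' the nucleus).
#'
#' @param cell An `ellipsoid_cell`.
#' @param scenario `"membrane_bound"` or `"internalized"`.
#' @param n Number of points (>= 0).
#' @param rng_seed Optional integer seed for reproducibility.
#' @return n x 3 matrix of positions (um, cell frame).
#' @export
sample_source_positions <- function(cell,
                                    scenario = c("membrane_bound", "internalized"),
                                    n, rng_seed = NULL) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(cell, "ellipsoid_cell"))
  if (length(n) != 1 || !is.finite(n) || n < 0) stop("n must be >= 0")
  n <- as.integer(n)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  if (n == 0L) {
    return(matrix(numeric(0), ncol = 3,
                  dimnames = list(NULL, c("x", "y", "z"))))
  }
  pts <- switch(scenario,
    membrane_bound = sample_ellipsoid_surface(cell$half_lengths, n),
    internalized = sample_cytoplasm(cell, n)
  )
  colnames(pts) <- c("x", "y", "z")
  pts
}
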