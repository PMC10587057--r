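# Graded gyroid scaffold geometry: level-set field, porosity calibration,
# voxelisation and surface export.

.gyro_cache <- new.env(parent = emptyenv())

#' Unit-cell specification for a gyroid scaffold
#'
#' Describes the discretisation of a scaffold built from cubic gyroid
#' subunits: the physical edge length of one subunit, how many subunits make
#' up one scaffold edge, and the voxel resolution per subunit. The spatial
#' frequency constants `alpha`, `beta`, `gamma` set the number of gyroid
#' periods per subunit along each axis (one period per subunit by default,
#' so a default scaffold is 3 subunits x 2 mm = 6 mm per edge, sampled on a
#' 60 x 60 x 60 voxel grid).
#'
#' @param unit_size_mm Edge length of one gyroid subunit in millimetres.
#' @param cells_per_axis Number of subunits per scaffold edge.
#' @param voxels_per_unit Voxels per subunit edge.
#' @param alpha,beta,gamma Gyroid periods per subunit along x, y, z.
#' @return An object of class `unit_cell_spec`.
#' @export
#' @examples
#' spec <- unit_cell_spec()
#' grid_edge(spec)  # 60
unit_cell_spec <- function(unit_size_mm = 2, cells_per_axis = 3,
                           voxels_per_unit = 20,
                           alpha = 1, beta = 1, gamma = 1) {
  stopifnot(unit_size_mm > 0, cells_per_axis >= 1, voxels_per_unit >= 1,
            alpha > 0, beta > 0, gamma > 0)
  cells_per_axis <- as.integer(cells_per_axis)
  voxels_per_unit <- as.integer(voxels_per_unit)
  structure(list(unit_size_mm = unit_size_mm,
                 cells_per_axis = cells_per_axis,
                 voxels_per_unit = voxels_per_unit,
                 alpha = alpha, beta = beta, gamma = gamma),
            class = "unit_cell_spec")
}

#' @rdname unit_cell_spec
#' @param spec A `unit_cell_spec`.
#' @export
grid_edge <- function(spec) spec$cells_per_axis * spec$voxels_per_unit

#' @export
print.unit_cell_spec <- function(x, ...) {
  cat(sprintf("gyroid unit-cell spec: %d x %d x %d subunits of %g mm, %d voxels/unit (%d^3 grid)\n",
              x$cells_per_axis, x$cells_per_axis, x$cells_per_axis,
              x$unit_size_mm, x$voxels_per_unit, grid_edge(x)))
  invisible(x)
}

#' Admissible porosity ladder
#'
#' The discrete porosities a subunit may take: 20% to 90% in steps of 10%.
#'
#' @param levels Numeric vector of admissible porosities.
#' @return The validated ladder, sorted increasingly.
#' @export
porosity_ladder <- function(levels = seq(0.2, 0.9, by = 0.1)) {
  stopifnot(length(levels) >= 1, all(levels >= 0.2 - 1e-9), all(levels <= 0.9 + 1e-9))
  sort(unique(levels))
}

#' Construct and validate a porosity matrix
#'
#' A porosity matrix is the design variable: a small cubic array (2^3, 3^3 or
#' 4^3) assigning a porosity in \[0.2, 0.9\] to each gyroid subunit.
#'
#' @param values Cubic numeric array (or vector reshaped to `shape`^3).
#' @param discrete If `TRUE`, entries must sit on the 10%-step ladder.
#' @param shape Optional edge length when `values` is a plain vector.
#' @return An object of class `porosity_matrix` (a numeric 3D array).
#' @export
#' @examples
#' m <- porosity_matrix(array(0.5, c(3, 3, 3)))
porosity_matrix <- function(values, discrete = FALSE, shape = NULL) {
  if (is.null(dim(values))) {
    if (is.null(shape)) shape <- round(length(values)^(1 / 3))
    stopifnot(length(values) == shape^3)
    values <- array(values, c(shape, shape, shape))
  }
  d <- dim(values)
  if (length(d) != 3 || length(unique(d)) != 1 || !(d[1] %in% c(2L, 3L, 4L)))
    stop("porosity matrix must be a cubic array with edge 2, 3 or 4")
  if (any(!is.finite(values))) stop("porosity matrix entries must be finite")
  if (min(values) < 0.2 - 1e-9 || max(values) > 0.9 + 1e-9)
    stop("porosities must lie in [0.2, 0.9]")
  if (discrete && any(abs(values * 10 - round(values * 10)) > 1e-6))
    stop("discrete porosity matrix entries must be multiples of 0.1")
  structure(values, class = "porosity_matrix", discrete = discrete)
}

#' @export
print.porosity_matrix <- function(x, ...) {
  s <- dim(x)[1]
  cat(sprintf("porosity matrix %d x %d x %d (mean porosity %.3f)\n",
              s, s, s, mean(x)))
  print(unclass(x)[, , seq_len(s)])
  invisible(x)
}

#' Gyroid level-set field value
#'
#' Evaluates `sin(X)cos(Y) + sin(Y)cos(Z) + sin(Z)cos(X)` with
#' `X = 2*alpha*pi*x`, `Y = 2*beta*pi*y`, `Z = 2*gamma*pi*z`, for coordinates
#' in subunit (cell) units. The field is bounded by \[-1.5, 1.5\] and odd
#' under point reflection.
#'
#' @param x,y,z Coordinates in cell units (recycled to common length).
#' @param spec A [unit_cell_spec()] supplying `alpha`, `beta`, `gamma`.
#' @return Numeric vector of field values.
#' @export
gyroid_value <- function(x, y, z, spec = unit_cell_spec()) {
  X <- 2 * spec$alpha * pi * x
  Y <- 2 * spec$beta * pi * y
  Z <- 2 * spec$gamma * pi * z
  sin(X) * cos(Y) + sin(Y) * cos(Z) + sin(Z) * cos(X)
}

# gyroid field sampled at voxel centers (i + 0.5)/res of one periodic unit,
# cached per (res, alpha, beta, gamma)
.unit_phi <- function(resolution, spec) {
  key <- paste0("phi:", resolution, ":", spec$alpha, ":", spec$beta, ":", spec$gamma)
  got <- .gyro_cache[[key]]
  if (!is.null(got)) return(got)
  u <- (seq_len(resolution) - 0.5) / resolution
  phi <- gyroid_value(rep(u, times = resolution^2),
                      rep(rep(u, each = resolution), times = resolution),
                      rep(u, each = resolution^2), spec)
  .gyro_cache[[key]] <- phi
  phi
}

#' Solid volume fraction of a gyroid unit at a given isovalue
#'
#' Fraction of voxel centers in one periodic unit where the gyroid field
#' exceeds `c` (the solid phase is the strict super-level set). Monotone
#' non-increasing in `c`.
#'
#' @param c Isovalue (level-set constant); may be a vector.
#' @param resolution Voxels per unit edge used for the count (>= 8).
#' @param spec A [unit_cell_spec()].
#' @return Solid fraction(s) in \[0, 1\].
#' @export
solid_fraction <- function(c, resolution = 40, spec = unit_cell_spec()) {
  stopifnot(resolution >= 8)
  phi <- .unit_phi(resolution, spec)
  vapply(c, function(ci) mean(phi > ci), numeric(1))
}

#' Calibrate the isovalue that realises a target subunit porosity
#'
#' The porosity-to-isovalue map has no closed form, so it is solved
#' numerically: bisection on the voxel-counted solid fraction until
#' `solid_fraction(c) = 1 - p` within 1e-3. Results are cached per
#' (p, resolution).
#'
#' @param p Target porosity in \[0.2, 0.9\]; may be a vector.
#' @param resolution Voxels per unit used by the counting oracle.
#' @param spec A [unit_cell_spec()].
#' @return Isovalue(s) `c` with `1 - solid_fraction(c)` close to `p`.
#' @export
#' @examples
#' calibrate_isovalue(0.5)  # ~0 by symmetry
calibrate_isovalue <- function(p, resolution = 40, spec = unit_cell_spec()) {
  if (any(p < 0.2 - 1e-9) || any(p > 0.9 + 1e-9))
    stop("target porosity must lie in [0.2, 0.9]")
  one <- function(pi1) {
    key <- paste0("cal:", signif(pi1, 12), ":", resolution, ":",
                  spec$alpha, ":", spec$beta, ":", spec$gamma)
    got <- .gyro_cache[[key]]
    if (!is.null(got)) return(got)
    target <- 1 - pi1
    lo <- -1.5
    hi <- 1.5
    for (it in seq_len(60)) {
      mid <- (lo + hi) / 2
      f <- solid_fraction(mid, resolution, spec)
      if (abs(f - target) <= 1e-3 || (hi - lo) < 1e-9) break
      if (f > target) lo <- mid else hi <- mid
    }
    .gyro_cache[[key]] <- mid
    mid
  }
  vapply(p, one, numeric(1))
}

# piecewise-linear separable interpolation of per-block values (s^3 array)
# onto an n^3 grid whose voxel centers sit at (i + 0.5)/scale_out in cell
# units; block centers sit at k + 0.5; constant beyond the outer centers.
.interp_blocks <- function(vals, n_out, scale_out) {
  .interp_blocks_points(vals, (seq_len(n_out) - 0.5) / scale_out)
}

#' Build the spatially varying isovalue field for a graded scaffold
#'
#' Each subunit's porosity is converted to an isovalue by
#' [calibrate_isovalue()]; between neighbouring subunit centers the isovalue
#' varies linearly along each axis (separable piecewise-linear grading, the
#' three-axis generalisation of a linear `c = A x + B` profile), and is held
#' constant beyond the outermost centers.
#'
#' @param m A [porosity_matrix()].
#' @param spec A [unit_cell_spec()]; its `cells_per_axis` must match `dim(m)`.
#' @param resolution Calibration resolution passed to [calibrate_isovalue()].
#' @return A numeric 3D array of isovalues, one per voxel.
#' @export
build_isovalue_field <- function(m, spec = unit_cell_spec(), resolution = 40) {
  m <- as_porosity_matrix(m)
  s <- dim(m)[1]
  if (s != spec$cells_per_axis)
    stop(sprintf("porosity matrix edge (%d) does not match spec cells_per_axis (%d)",
                 s, spec$cells_per_axis))
  cvals <- array(calibrate_isovalue(as.vector(m), resolution, spec), dim(m))
  n <- grid_edge(spec)
  .interp_blocks(cvals, n, spec$voxels_per_unit)
}

as_porosity_matrix <- function(m) {
  if (inherits(m, "porosity_matrix")) m else porosity_matrix(m)
}

#' Voxelise a porosity matrix into a binary occupancy grid
#'
#' A voxel is solid (1) when the gyroid field at its center strictly exceeds
#' the local isovalue, void (0) otherwise. The default spec yields a
#' 60 x 60 x 60 grid for a 3 x 3 x 3 matrix.
#'
#' @inheritParams build_isovalue_field
#' @return An object of class `voxel_grid`: an integer 0/1 array with
#'   attributes `voxel_size_mm` and `spec`.
#' @export
#' @examples
#' g <- voxelize(porosity_matrix(array(0.5, c(3, 3, 3))))
#' measure_porosity(g)  # ~0.5
voxelize <- function(m, spec = unit_cell_spec(), resolution = 40) {
  m <- as_porosity_matrix(m)
  n <- grid_edge(spec)
  cf <- build_isovalue_field(m, spec, resolution)
  key <- paste0("scafphi:", n, ":", spec$voxels_per_unit, ":", spec$alpha,
                ":", spec$beta, ":", spec$gamma)
  phi <- .gyro_cache[[key]]
  if (is.null(phi)) {
    u <- (seq_len(n) - 0.5) / spec$voxels_per_unit
    phi <- array(gyroid_value(rep(u, times = n^2),
                              rep(rep(u, each = n), times = n),
                              rep(u, each = n^2), spec), c(n, n, n))
    .gyro_cache[[key]] <- phi
  }
  occ <- array(as.integer(phi > cf), c(n, n, n))
  structure(occ, class = "voxel_grid",
            voxel_size_mm = spec$unit_size_mm / spec$voxels_per_unit,
            spec = spec)
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("voxel grid %d x %d x %d (solid fraction %.3f, voxel %.3g mm)\n",
              d[1], d[2], d[3], mean(x), attr(x, "voxel_size_mm")))
  invisible(x)
}

.check_binary <- function(g) {
  if (!all(g %in% c(0L, 1L, 0, 1))) stop("voxel grid must be binary (0/1)")
}

#' Porosity and mass fraction of a voxel grid
#'
#' `measure_porosity` is the void fraction `1 - mean(occupancy)`;
#' `mass_fraction` is the solid fraction `mean(occupancy)`. They sum to one.
#'
#' @param g A binary occupancy array.
#' @return A fraction in \[0, 1\].
#' @export
measure_porosity <- function(g) {
  .check_binary(g)
  1 - mean(g)
}

#' @rdname measure_porosity
#' @export
mass_fraction <- function(g) {
  .check_binary(g)
  mean(g)
}

#' Per-subunit porosity of a voxelised scaffold
#'
#' Splits the grid into `cells^3` blocks and returns each block's void
#' fraction, for comparison against the design porosity matrix.
#'
#' @param g A `voxel_grid` (or binary array).
#' @param cells Subunits per axis; defaults to the grid's spec.
#' @return A `cells^3` numeric array of measured porosities.
#' @export
subunit_porosity <- function(g, cells = NULL) {
  .check_binary(g)
  if (is.null(cells)) {
    spec <- attr(g, "spec")
    cells <- if (!is.null(spec)) spec$cells_per_axis else stop("supply `cells`")
  }
  n <- dim(g)[1]
  stopifnot(n %% cells == 0)
  b <- n %/% cells
  idx <- rep(seq_len(cells), each = b)
  out <- array(0, c(cells, cells, cells))
  for (i in seq_len(cells)) for (j in seq_len(cells)) for (k in seq_len(cells)) {
    blk <- g[idx == i, idx == j, idx == k]
    out[i, j, k] <- 1 - mean(blk)
  }
  out
}

#' Expand a porosity matrix to the common 12^3 representation
#'
#' Replicates each subunit porosity into a contiguous block so that 2^3, 3^3
#' and 4^3 matrices all become 12 x 12 x 12 arrays (block edges 6, 4, 3).
#'
#' @param m A [porosity_matrix()] (or cubic array with edge 2, 3 or 4).
#' @return A 12 x 12 x 12 numeric array.
#' @export
expand_matrix <- function(m) {
  m <- as_porosity_matrix(m)
  s <- dim(m)[1]
  f <- 12L %/% s
  idx <- rep(seq_len(s), each = f)
  unclass(m)[idx, idx, idx]
}

#' Contract a 12^3 array back to a subunit-level porosity matrix
#'
#' Inverse of [expand_matrix()] on block-constant arrays: each block of edge
#' `12/shape` is replaced by its mean.
#'
#' @param a A 12 x 12 x 12 numeric array.
#' @param shape Target edge length (2, 3 or 4).
#' @return A `shape^3` numeric array (not validated as a porosity matrix).
#' @export
contract_matrix <- function(a, shape = 3) {
  stopifnot(all(dim(a) == c(12, 12, 12)), shape %in% c(2, 3, 4))
  f <- 12L %/% as.integer(shape)
  idx <- rep(seq_len(shape), each = f)
  out <- array(0, c(shape, shape, shape))
  for (i in seq_len(shape)) for (j in seq_len(shape)) for (k in seq_len(shape)) {
    out[i, j, k] <- mean(a[idx == i, idx == j, idx == k])
  }
  out
}

#' Export the graded gyroid surface of a design as a binary STL mesh
#'
#' Extracts the zero level set of (gyroid field - isovalue field) on the
#' scaffold grid (including the boundary planes) by marching tetrahedra and
#' writes a binary STL scaled to millimetres.
#'
#' @inheritParams build_isovalue_field
#' @param path Output STL file path.
#' @return Invisibly, the number of triangles written.
#' @export
export_surface <- function(m, spec = unit_cell_spec(), path, resolution = 40) {
  m <- as_porosity_matrix(m)
  n <- grid_edge(spec)
  # corner grid 0 .. cells (n + 1 points per axis) so the mesh spans the
  # full physical bounding box
  u <- (0:n) / spec$voxels_per_unit
  np <- n + 1L
  phi <- gyroid_value(rep(u, times = np^2),
                      rep(rep(u, each = np), times = np),
                      rep(u, each = np^2), spec)
  cvals <- array(calibrate_isovalue(as.vector(m), resolution, spec), dim(m))
  cf <- .interp_blocks_points(cvals, u)
  field <- phi - as.vector(cf)
  verts <- cpp_march_tetra(field, np, np, np,
                           spec$unit_size_mm / spec$voxels_per_unit, 0)
  if (nrow(verts) == 0) stop("no surface extracted; design is degenerate")
  tryCatch(write_stl(verts, path),
           error = function(e) stop(sprintf("STL export to '%s' failed: %s",
                                            path, conditionMessage(e))))
  invisible(nrow(verts) / 3)
}

# like .interp_blocks but for arbitrary axis positions (cell units)
.interp_blocks_points <- function(vals, pos) {
  s <- dim(vals)[1]
  t <- pmin(pmax(pos - 0.5, 0), s - 1)
  if (s == 1) {
    lo <- rep(1L, length(pos)); hi <- lo; w <- rep(0, length(pos))
  } else {
    lo <- pmin(floor(t), s - 2)
    w <- t - lo
    lo <- as.integer(lo) + 1L
    hi <- pmin(lo + 1L, s)
  }
  n <- length(pos)
  a <- (1 - w) * vals[lo, , , drop = FALSE] + w * vals[hi, , , drop = FALSE]
  wl <- array(rep(1 - w, each = n), c(n, n, s))
  a <- wl * a[, lo, , drop = FALSE] + (1 - wl) * a[, hi, , drop = FALSE]
  wl <- array(rep(1 - w, each = n * n), c(n, n, n))
  wl * a[, , lo, drop = FALSE] + (1 - wl) * a[, , hi, drop = FALSE]
}

#' Write a triangle soup as binary STL
#'
#' @param verts Numeric matrix with 3 rows per triangle (x, y, z columns).
#' @param path Output file path.
#' @return Invisibly, the number of triangles.
#' @export
write_stl <- function(verts, path) {
  stopifnot(is.matrix(verts), ncol(verts) == 3, nrow(verts) %% 3 == 0)
  ntri <- nrow(verts) / 3
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(rep(0, 80)), con)
  writeBin(as.integer(ntri), con, size = 4, endian = "little")
  for (t in seq_len(ntri)) {
    a <- verts[3 * t - 2, ]
    b <- verts[3 * t - 1, ]
    d <- verts[3 * t, ]
    nrm <- c((b[2] - a[2]) * (d[3] - a[3]) - (b[3] - a[3]) * (d[2] - a[2]),
             (b[3] - a[3]) * (d[1] - a[1]) - (b[1] - a[1]) * (d[3] - a[3]),
             (b[1] - a[1]) * (d[2] - a[2]) - (b[2] - a[2]) * (d[1] - a[1]))
    nn <- sqrt(sum(nrm^2))
    if (nn > 0) nrm <- nrm / nn
    writeBin(as.numeric(c(nrm, a, b, d)), con, size = 4, endian = "little")
    writeBin(as.integer(0), con, size = 2, endian = "little")
  }
  invisible(ntri)
}

#' Read a binary STL file into a triangle-soup matrix
#'
#' @param path STL file path.
#' @return Numeric matrix with 3 rows per triangle.
#' @export
read_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
  out <- matrix(0, 3 * ntri, 3)
  for (t in seq_len(ntri)) {
    rec <- readBin(con, "numeric", 12, size = 4, endian = "little")
    out[(3 * t - 2):(3 * t), ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
    readBin(con, "integer", 1, size = 2, endian = "little")
  }
  out
}
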