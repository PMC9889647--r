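#' Regular 3D grid specification
#'
#' Axis convention used throughout the package: index 1 = patient lateral
#' (linac X at gantry 0), index 2 = anterior-posterior (the beam axis at
#' gantry 0, anterior positive), index 3 = superior-inferior (the gantry
#' rotation axis and the MLC leaf-travel direction). The grid is centered on
#' the origin unless an explicit `origin` (mm coordinate of voxel
#' `[1, 1, 1]`'s center) is given.
#'
#' @param dim Integer vector of 3 voxel counts.
#' @param spacing Voxel spacing, mm (scalar or length 3).
#' @param origin Optional mm coordinates of the first voxel center.
#' @return A `grid_spec` object.
#' @export
grid_spec <- function(dim, spacing, origin = NULL) {
  dim <- as.integer(rep(dim, length.out = 3))
  spacing <- rep(as.numeric(spacing), length.out = 3)
  if (any(dim < 1)) stop("grid dimensions must be positive")
  if (any(spacing <= 0)) stop("grid spacing must be positive")
  if (is.null(origin)) origin <- -(dim - 1) * spacing / 2
  structure(list(dim = dim, spacing = spacing, origin = as.numeric(origin)),
            class = "grid_spec")
}

#' Volumetric dose (or mask) on a regular grid
#'
#' @param values 3D numeric array.
#' @param grid A [grid_spec()] describing voxel geometry.
#' @param beam_ref Optional identifier of the beam that produced the dose.
#' @return A `dose3d` object.
#' @export
dose3d <- function(values, grid, beam_ref = NULL) {
  stopifnot(inherits(grid, "grid_spec"), identical(dim(values), NULL) == FALSE)
  if (!all(dim(values) == grid$dim)) stop("array dimensions do not match grid")
  structure(list(values = values, grid = grid, beam_ref = beam_ref),
            class = "dose3d")
}

#' @export
print.dose3d <- function(x, ...) {
  cat(sprintf("<dose3d> %s voxels @ %s mm, range [%.4g, %.4g]%s\n",
              paste(x$grid$dim, collapse = "x"),
              paste(signif(x$grid$spacing, 4), collapse = "x"),
              min(x$values), max(x$values),
              if (is.null(x$beam_ref)) "" else paste0(", beam ", x$beam_ref)))
  invisible(x)
}

# voxel-center world coordinates along one axis
grid_coords <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$dim[axis]) - 1) * grid$spacing[axis]
}

# world (mm) -> 0-based continuous voxel index
world_to_index <- function(grid, xyz) {
  sweep(sweep(xyz, 2, grid$origin, "-"), 2, grid$spacing, "/")
}

# rotation about the superior-inferior (z) axis by `deg` degrees,
# positive from +x towards +y (so the gantry-0 beam axis +y maps correctly)
rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0,
           -sin(th), cos(th), 0,
           0, 0, 1), 3, 3)
}

# Generic world-affine pull-back resample of a dose3d onto a target grid:
# out(p) = src(R %*% (p - center) + center + shift), p in world mm.
# `center` defaults to the rotation center of the *target* grid (its middle).
resample_affine <- function(src, target_grid, R = diag(3), shift = c(0, 0, 0),
                            center = NULL) {
  g <- src$grid
  if (is.null(center)) {
    center <- target_grid$origin + (target_grid$dim - 1) * target_grid$spacing / 2
  }
  # target index -> world: p = t_origin + i * t_spacing (componentwise)
  # source world q = R (p - center) + center + shift
  # source index f = (q - s_origin) / s_spacing
  S_t <- diag(target_grid$spacing)
  A_world <- R %*% S_t
  t_world <- R %*% (target_grid$origin - center) + center + shift
  A <- diag(1 / g$spacing) %*% A_world
  tt <- (t_world - g$origin) / g$spacing
  vals <- cpp_affine_resample3d(src$values, g$dim, target_grid$dim, A, tt)
  dose3d(vals, target_grid, beam_ref = src$beam_ref)
}

# bilinear 2D resample between pixel-center rasters covering given extents
# (extent = c(min, max) of the covered physical range; pixel centers at
# min + (i - 0.5) * pitch). Implemented through the 3D kernel with nz = 1.
resample2d_extent <- function(mat, src_extent_r, src_extent_c,
                              out_nr, out_nc, out_extent_r, out_extent_c,
                              edge = c("zero", "clamp")) {
  edge <- match.arg(edge)
  nr <- nrow(mat); nc <- ncol(mat)
  pr_s <- diff(src_extent_r) / nr; pc_s <- diff(src_extent_c) / nc
  pr_o <- diff(out_extent_r) / out_nr; pc_o <- diff(out_extent_c) / out_nc
  # out pixel i (0-based) center -> src 0-based index
  a_r <- pr_o / pr_s
  b_r <- (out_extent_r[1] + pr_o / 2 - (src_extent_r[1] + pr_s / 2)) / pr_s
  a_c <- pc_o / pc_s
  b_c <- (out_extent_c[1] + pc_o / 2 - (src_extent_c[1] + pc_s / 2)) / pc_s
  A <- diag(c(a_r, a_c, 1))
  vals <- cpp_affine_resample3d(array(mat, c(nr, nc, 1L)),
                                c(nr, nc, 1L), c(out_nr, out_nc, 1L),
                                A, c(b_r, b_c, 0),
                                edge = if (edge == "clamp") 1L else 0L)
  matrix(vals, out_nr, out_nc)
}

# pixel-center coordinates of the size_r x size_c field raster spanning the
# full machine field (rows along linac X, cols along linac Y)
field_raster_centers <- function(machine, size_r, size_c = size_r) {
  px <- machine$field_x_extent / size_r
  py <- machine$field_y_extent / size_c
  list(x = -machine$field_x_extent / 2 + (seq_len(size_r) - 0.5) * px,
       y = -machine$field_y_extent / 2 + (seq_len(size_c) - 0.5) * py,
       pitch = c(px, py))
}
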