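#' Image grid
#'
#' Reconstruction voxel grid, centered on the scanner axis: the grid
#' center sits at (0, 0, 0) mm and voxel (i, j, k) (1-based) has its
#' center at `(i - (n + 1) / 2) * voxel` per axis.
#'
#' @param nx,ny,nz Voxel counts.
#' @param voxel_size Voxel pitch, mm triple. Defaults to the transaxial /
#'   axial pitch of a 2.036 x 2.036 x 2.027 mm reconstruction.
#' @return An object of class `image_grid`.
#' @export
image_grid <- function(nx, ny, nz, voxel_size = c(2.036, 2.036, 2.027)) {
  if (any(c(nx, ny, nz) < 1) || any(voxel_size <= 0))
    stop_input("grid dimensions and voxel sizes must be positive")
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 nz = as.integer(nz),
                 voxel_size = as.numeric(voxel_size)),
            class = "image_grid")
}

#' Default desk-scale grid
#' @return A 128 x 128 x 15 [image_grid()] at 2.036/2.027 mm pitch.
#' @export
default_grid <- function() image_grid(128, 128, 15)

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid> %d x %d x %d voxels at %.3f x %.3f x %.3f mm\n",
              x$nx, x$ny, x$nz, x$voxel_size[1], x$voxel_size[2],
              x$voxel_size[3]))
  invisible(x)
}

grid_dim <- function(grid) c(grid$nx, grid$ny, grid$nz)

# mm coordinates of voxel centers along one axis
axis_coords <- function(grid, axis) {
  n <- grid_dim(grid)[axis]
  (seq_len(n) - (n + 1) / 2) * grid$voxel_size[axis]
}

voxel_center_mm <- function(grid, j) {
  (j - (grid_dim(grid) + 1) / 2) * grid$voxel_size
}

check_volume <- function(values, grid, what = "volume") {
  if (!identical(dim(values), grid_dim(grid)))
    stop_input(what, " dimensions do not match the grid")
  invisible(values)
}

#' Scanner geometry
#'
#' 2D parallel-beam ring geometry per slice: LORs are indexed by radial
#' offset and azimuthal angle (uniform over 180 degrees), with one
#' independent set per axial slice. Volumes are slice stacks; the range
#' blur acts fully in 3D while projections are slice-parallel.
#'
#' @param n_radial Number of radial bins.
#' @param radial_bin_size Radial bin pitch, mm.
#' @param n_angles Number of projection angles over 180 degrees.
#' @param n_slices Number of axial slices (must match the image grid).
#' @return An object of class `scanner_geometry`.
#' @export
scanner_geometry <- function(n_radial = 128, radial_bin_size = 2,
                             n_angles = 120, n_slices = 15) {
  if (any(c(n_radial, n_angles, n_slices) < 1) || radial_bin_size <= 0)
    stop_input("scanner geometry parameters must be positive")
  structure(list(n_radial = as.integer(n_radial),
                 radial_bin_size = as.numeric(radial_bin_size),
                 n_angles = as.integer(n_angles),
                 n_slices = as.integer(n_slices)),
            class = "scanner_geometry")
}

#' Scanner geometry matched to an image grid
#'
#' Convenience constructor: radial bins matching the grid's transaxial
#' extent at the voxel pitch, and one slice per grid slice.
#'
#' @param grid An [image_grid()].
#' @param n_radial Radial bin count (default `grid$nx`).
#' @param n_angles Angles over 180 degrees.
#' @return A [scanner_geometry()].
#' @export
geom_for_grid <- function(grid, n_radial = NULL, n_angles = 120) {
  nr <- n_radial %||% grid$nx
  scanner_geometry(nr, max(grid$voxel_size[1:2]), n_angles, grid$nz)
}

geom_angles <- function(geom, subset = NULL) {
  idx <- subset %||% seq_len(geom$n_angles)
  pi * (idx - 1) / geom$n_angles
}

#' Sinogram container
#'
#' @param values Array `[radial, angle, slice]`.
#' @param geometry A [scanner_geometry()].
#' @param angles 1-based angle indices present (defaults to all).
#' @return An object of class `sinogram`.
#' @export
sinogram <- function(values, geometry, angles = NULL) {
  angles <- angles %||% seq_len(geometry$n_angles)
  d <- c(geometry$n_radial, length(angles), geometry$n_slices)
  if (!identical(dim(values), as.integer(d)))
    stop_input("sinogram dimensions inconsistent with geometry")
  structure(list(values = values, geometry = geometry, angles = angles),
            class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("<sinogram> %d radial x %d angles x %d slices, total %.4g\n",
              dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
              sum(x$values)))
  invisible(x)
}

#' Write / read a volume as NIfTI-1
#'
#' Volumes (activity images, mu-maps, kernels) are stored as NIfTI-1 with
#' the voxel pitch in the header.
#'
#' @param values 3D array.
#' @param voxel_size mm triple.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `write_volume` returns `path` invisibly; `read_volume` returns
#'   a list with `values` and `voxel_size`.
#' @export
write_volume <- function(values, voxel_size, path) {
  img <- RNifti::asNifti(structure(as.array(values), pixdim = voxel_size))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  list(values = array(as.numeric(img), dim = dim(img)),
       voxel_size = RNifti::pixdim(img))
}
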