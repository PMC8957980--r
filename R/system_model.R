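#' Forward projection
#'
#' Ray-driven projection with exact voxel-ray intersection lengths
#' (Siddon-style traversal): per LOR i the sinogram value is
#' `sum_j x_ij f_j`. Rays are slice-parallel 2D LORs over 180 degrees.
#'
#' @param image 3D activity array on `grid`.
#' @param grid An [image_grid()].
#' @param geom A [scanner_geometry()] with `n_slices == grid$nz`.
#' @param subset Optional 1-based angle indices (an OSEM angular subset);
#'   default all angles.
#' @return A [sinogram()] restricted to the subset's angles.
#' @export
forward_project <- function(image, grid, geom, subset = NULL) {
  check_volume(image, grid, "image")
  if (geom$n_slices != grid$nz)
    stop_input("geometry n_slices must match the image grid")
  th <- geom_angles(geom, subset)
  v <- .cpp_forward_project(as.numeric(image), grid$nx, grid$ny, grid$nz,
                            grid$voxel_size[1], grid$voxel_size[2],
                            geom$n_radial, geom$radial_bin_size, th)
  sinogram(array(v, c(geom$n_radial, length(th), geom$n_slices)), geom,
           subset %||% seq_len(geom$n_angles))
}

#' Back projection (exact adjoint of the forward projection)
#'
#' Applies `X^T` with the same intersection-length coefficients as
#' [forward_project()], so the randomized dot-product identity
#' `<X f, g> = <f, X^T g>` holds to floating-point accuracy.
#'
#' @param sino A [sinogram()] (possibly an angular subset).
#' @param grid An [image_grid()].
#' @return 3D image array.
#' @export
back_project <- function(sino, grid) {
  stopifnot(inherits(sino, "sinogram"))
  geom <- sino$geometry
  if (geom$n_slices != grid$nz)
    stop_input("geometry n_slices must match the image grid")
  th <- pi * (sino$angles - 1) / geom$n_angles
  v <- .cpp_back_project(as.numeric(sino$values), grid$nx, grid$ny, grid$nz,
                         grid$voxel_size[1], grid$voxel_size[2],
                         geom$n_radial, geom$radial_bin_size, th)
  array(v, grid_dim(grid))
}

#' Per-LOR attenuation factors
#'
#' `w_i = exp(-sum_j x_ij mu_j / 10)` with the mu-map in cm^-1 and
#' intersection lengths in mm, traced with the same ray tracer as the
#' projector. Geometric sensitivity variations are modeled as uniform, so
#' only attenuation varies across LORs.
#'
#' @param mumap A [mu_map()].
#' @param geom A [scanner_geometry()].
#' @return Array `[radial, angle, slice]` of factors in (0, 1], class
#'   `attenuation_factors` with the geometry attached.
#' @export
attenuation_factors <- function(mumap, geom) {
  stopifnot(inherits(mumap, "mu_map"))
  g <- mumap$grid
  if (geom$n_slices != g$nz)
    stop_input("geometry n_slices must match the mu-map grid")
  th <- geom_angles(geom)
  v <- .cpp_attenuation_factors(as.numeric(mumap$values), g$nx, g$ny, g$nz,
                                g$voxel_size[1], g$voxel_size[2],
                                geom$n_radial, geom$radial_bin_size, th)
  structure(array(v, c(geom$n_radial, geom$n_angles, geom$n_slices)),
            class = "attenuation_factors", geometry = geom)
}

provider_blur_args <- function(provider, dims) {
  mode <- switch(provider$mode, uniform_water = 0L, tissue_dependent = 1L,
                 spatially_variant = 2L)
  if (mode == 0L) {
    kern <- matrix(as.numeric(
      get_kernel(provider$kset, provider$isotope, "water")$values), ncol = 1)
    labels <- integer(1)
  } else {
    g <- provider$mmap$grid
    if (!identical(grid_dim(g), as.integer(dims)))
      stop_input("provider material map does not match the image grid")
    kern <- kset_matrix(provider$kset, provider$isotope)
    labels <- as.integer(provider$mmap$labels) - 1L
  }
  list(mode = mode, kern = kern, labels = labels,
       half = provider$kset$half_width)
}

#' Apply the positron-range blur operator H
#'
#' The annihilation image `b = H f`: every source voxel j distributes its
#' value according to the kernel the provider attaches to j (per-voxel
#' scatter). Kernel mass falling outside the image is dropped, which
#' keeps the transpose exact.
#'
#' @param image 3D array.
#' @param provider A [make_kernel_provider()].
#' @return Blurred 3D array of the same shape.
#' @export
apply_pr_blur <- function(image, provider) {
  stopifnot(inherits(provider, "kernel_provider"))
  d <- dim(image)
  a <- provider_blur_args(provider, d)
  v <- .cpp_pr_blur(as.numeric(image), d[1], d[2], d[3], a$mode, a$kern,
                    a$half, a$labels, FALSE)
  array(v, d)
}

#' Apply the exact transpose of the positron-range blur
#'
#' `(H^T g)_j = sum_j' h_j'j g_j'`: a gather over the same per-voxel
#' kernels used by [apply_pr_blur()].
#'
#' @inheritParams apply_pr_blur
#' @return 3D array of the same shape.
#' @export
apply_pr_blur_adjoint <- function(image, provider) {
  stopifnot(inherits(provider, "kernel_provider"))
  d <- dim(image)
  a <- provider_blur_args(provider, d)
  v <- .cpp_pr_blur(as.numeric(image), d[1], d[2], d[3], a$mode, a$kern,
                    a$half, a$labels, TRUE)
  array(v, d)
}
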