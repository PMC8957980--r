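#' 3D positron-range kernel
#'
#' A normalized 3D histogram of annihilation displacements: odd side
#' lengths, non-negative values summing to 1, geometric center at the
#' emission voxel. A kernel is the column of the resolution operator H
#' attached to one voxel.
#'
#' @param values Non-negative 3D array with odd side lengths.
#' @param voxel_size mm triple.
#' @param normalize Renormalize `values` to sum 1 (default TRUE).
#' @return An object of class `kernel3d`.
#' @export
kernel3d <- function(values, voxel_size, normalize = TRUE) {
  values <- as.array(values)
  d <- dim(values)
  if (length(d) != 3 || any(d %% 2 == 0))
    stop_input("kernel must be 3D with odd side lengths")
  if (any(values < 0)) stop_input("kernel values must be non-negative")
  s <- sum(values)
  if (normalize) {
    if (s <= 0) stop_input("cannot normalize an all-zero kernel")
    values <- values / s
  } else if (abs(s - 1) > 1e-12) {
    stop_input("kernel values must sum to 1")
  }
  structure(list(values = values, voxel_size = as.numeric(voxel_size),
                 center_index = (d + 1L) %/% 2L),
            class = "kernel3d")
}

#' @export
print.kernel3d <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<kernel3d> %d x %d x %d at %.3f/%.3f/%.3f mm, center mass %.3f\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2],
              x$voxel_size[3], x$values[x$center_index[1], x$center_index[2],
                                        x$center_index[3]]))
  invisible(x)
}

kernel_half <- function(kernel) (dim(kernel$values)[1] - 1L) %/% 2L

#' Delta (identity) kernel
#'
#' All mass in the center voxel; attaching it to every voxel makes the
#' resolution operator H the identity.
#'
#' @param half_width Half width in voxels (side = 2 * half_width + 1).
#' @param voxel_size mm triple.
#' @return A `kernel3d`.
#' @export
delta_kernel <- function(half_width = 0, voxel_size = c(2.036, 2.036, 2.027)) {
  s <- 2L * as.integer(half_width) + 1L
  v <- array(0, c(s, s, s))
  v[half_width + 1L, half_width + 1L, half_width + 1L] <- 1
  kernel3d(v, voxel_size, normalize = FALSE)
}

#' Kernel half width from a governing maximum range
#'
#' The kernel grid must cover the maximum positron range of the
#' radionuclide in its governing medium (lung for F18, water for Ga68 and
#' I124), so the half width is `ceiling(max_range / voxel_size)` and the
#' side length `2 * half_width + 1`.
#'
#' @param max_range Governing maximum positron range, mm.
#' @param voxel_size Voxel pitch, mm (scalar; use the transaxial pitch).
#' @return Half width in voxels.
#' @export
kernel_half_width <- function(max_range, voxel_size) {
  if (max_range <= 0 || voxel_size <= 0)
    stop_input("max_range and voxel_size must be positive")
  as.integer(ceiling(max_range / voxel_size))
}

#' Bin a point cloud into a range kernel
#'
#' Histograms the annihilation offsets (annihilation - emission) of a
#' point cloud on a `(2 * half_width + 1)^3` voxel grid centered on the
#' emission point (offsets assigned by `floor(offset / voxel + 0.5)` per
#' axis, i.e. the emission point sits at the exact center of the center
#' voxel), then normalizes to sum 1. Events falling outside the grid are
#' dropped; their count is available as attribute `"dropped"`.
#'
#' @param cloud A `point_cloud`.
#' @param voxel_size mm (scalar or triple).
#' @param half_width Kernel half width in voxels, see [kernel_half_width()].
#' @return A `kernel3d`.
#' @export
bin_point_cloud_to_kernel <- function(cloud, voxel_size, half_width) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (!nrow(cloud$records)) stop_input("empty point cloud")
  if (half_width < 0) stop_input("half_width must be >= 0")
  vs <- rep(as.numeric(voxel_size), length.out = 3)
  rec <- cloud$records
  ix <- floor((rec$xf - rec$xi) / vs[1] + 0.5)
  iy <- floor((rec$yf - rec$yi) / vs[2] + 0.5)
  iz <- floor((rec$zf - rec$zi) / vs[3] + 0.5)
  inside <- abs(ix) <= half_width & abs(iy) <= half_width &
    abs(iz) <= half_width
  s <- 2L * as.integer(half_width) + 1L
  lin <- (ix[inside] + half_width) + s * (iy[inside] + half_width) +
    s * s * (iz[inside] + half_width)
  counts <- tabulate(lin + 1, nbins = s^3)
  k <- kernel3d(array(counts, c(s, s, s)), vs, normalize = TRUE)
  attr(k, "dropped") <- sum(!inside)
  k
}

#' Uniform per-material kernel set
#'
#' Library of homogeneous-medium range kernels keyed by (isotope,
#' material); all members share shape and voxel size.
#'
#' @param kernels Nested named list `kernels[[isotope]][[material]]` of
#'   [kernel3d()] objects.
#' @return An object of class `uniform_kernel_set`.
#' @export
uniform_kernel_set <- function(kernels) {
  all_k <- unlist(kernels, recursive = FALSE)
  if (!length(all_k)) stop_input("empty kernel set")
  d0 <- dim(all_k[[1]]$values)
  v0 <- all_k[[1]]$voxel_size
  for (k in all_k) {
    if (!identical(dim(k$values), d0) || any(abs(k$voxel_size - v0) > 1e-9))
      stop_input("all kernels in a set must share shape and voxel size")
  }
  structure(list(kernels = kernels, voxel_size = v0,
                 half_width = (d0[1] - 1L) %/% 2L),
            class = "uniform_kernel_set")
}

#' Look up a kernel in a set
#' @param kset A [uniform_kernel_set()].
#' @param isotope Isotope name.
#' @param material Material label.
#' @return A `kernel3d`.
#' @export
get_kernel <- function(kset, isotope, material) {
  k <- kset$kernels[[isotope]][[material]]
  if (is.null(k)) stop_input("no kernel for (", isotope, ", ", material, ")")
  k
}

# s^3 x 3 matrix of the three material kernels of one isotope
kset_matrix <- function(kset, isotope) {
  cols <- lapply(material_labels(), function(m)
    as.numeric(get_kernel(kset, isotope, m)$values))
  do.call(cbind, cols)
}

#' Build the uniform kernel library by simulation
#'
#' Simulates a point source of the isotope in each material and bins the
#' annihilation cloud into a kernel sized by the governing maximum range.
#'
#' @param isotope Isotope name or [isotope_spec()].
#' @param n_events Events per material.
#' @param seed Base seed (per-material seeds derived deterministically).
#' @param voxel_size mm triple.
#' @param max_range Governing maximum range, mm (default 10, giving an
#'   11-voxel side at 2.036 mm pitch).
#' @param materials Materials to simulate.
#' @param config A [transport_config()].
#' @return A [uniform_kernel_set()] for the isotope.
#' @export
build_uniform_kernels <- function(isotope, n_events = 1e5, seed = 1,
                                  voxel_size = c(2.036, 2.036, 2.027),
                                  max_range = 10,
                                  materials = material_labels(),
                                  config = transport_config()) {
  iso <- isotope_spec(isotope)
  hw <- kernel_half_width(max_range, voxel_size[1])
  ks <- list()
  for (i in seq_along(materials)) {
    cloud <- simulate_point_source(iso, materials[i], n_events,
                                   seed = seed + 1000 * i, config = config)
    ks[[materials[i]]] <- bin_point_cloud_to_kernel(cloud, voxel_size, hw)
  }
  uniform_kernel_set(stats::setNames(list(ks), iso$name))
}

#' 511 keV attenuation map
#'
#' @param values 3D array of linear attenuation coefficients at 511 keV,
#'   cm^-1, on the PET image grid.
#' @param grid An [image_grid()].
#' @return An object of class `mu_map`.
#' @export
mu_map <- function(values, grid) {
  check_volume(values, grid, "mu map")
  if (any(values < 0)) stop_input("attenuation coefficients must be >= 0")
  structure(list(values = values, grid = grid), class = "mu_map")
}

#' Material map
#'
#' @param labels 3D integer array of material codes (1 = lung, 2 = water,
#'   3 = bone; see [material_labels()]).
#' @param grid An [image_grid()].
#' @return An object of class `material_map`.
#' @export
material_map <- function(labels, grid) {
  storage.mode(labels) <- "integer"
  check_volume(labels, grid, "material map")
  if (any(!labels %in% 1:3)) stop_input("material labels must be 1, 2 or 3")
  structure(list(labels = labels, grid = grid), class = "material_map")
}

#' Classify a 511 keV attenuation map into materials
#'
#' Thresholds the mu-map into the three-material model used for kernel
#' selection: mu below `thresholds[1]` is lung, between the thresholds is
#' water, at or above `thresholds[2]` is bone. Defaults 0.08 / 0.12 cm^-1.
#'
#' @param mumap A [mu_map()].
#' @param thresholds `(t_low, t_high)` in cm^-1, `t_low < t_high`.
#' @return A [material_map()] on the same grid.
#' @export
material_map_from_mumap <- function(mumap, thresholds = c(0.08, 0.12)) {
  stopifnot(inherits(mumap, "mu_map"))
  if (thresholds[1] >= thresholds[2])
    stop_input("thresholds must satisfy t_low < t_high")
  v <- mumap$values
  lab <- array(2L, dim(v))
  lab[v < thresholds[1]] <- 1L
  lab[v >= thresholds[2]] <- 3L
  material_map(lab, mumap$grid)
}

#' Compose the spatially variant kernel at a voxel
#'
#' Builds the voxel-specific kernel at voxel `j` by picking, for every
#' kernel offset u, the value of the uniform kernel of the material at the
#' destination (annihilation-side) voxel `j + u`, then renormalizing to
#' sum 1. Offsets falling outside the image use the nearest in-image
#' voxel's material (border clamp). Deep inside a homogeneous region the
#' composition degenerates to the material's uniform kernel.
#'
#' @param kset A [uniform_kernel_set()].
#' @param mmap A [material_map()].
#' @param j 1-based voxel index triple.
#' @param isotope Isotope name.
#' @return A `kernel3d`.
#' @export
compose_variant_kernel <- function(kset, mmap, j, isotope) {
  stopifnot(inherits(kset, "uniform_kernel_set"),
            inherits(mmap, "material_map"))
  g <- mmap$grid
  j <- as.integer(j)
  if (length(j) != 3 || any(j < 1) || any(j > grid_dim(g)))
    stop_input("voxel index outside the material map")
  hw <- kset$half_width
  s <- 2L * hw + 1L
  v <- .cpp_compose_kernel(kset_matrix(kset, isotope), hw,
                           as.integer(mmap$labels) - 1L,
                           g$nx, g$ny, g$nz, j[1] - 1L, j[2] - 1L, j[3] - 1L)
  kernel3d(array(v, c(s, s, s)), kset$voxel_size, normalize = FALSE)
}

#' Kernel provider
#'
#' The per-voxel kernel contract of the resolution operator H. Three
#' modes: `uniform_water` uses the water kernel everywhere (PRC-Unif);
#' `tissue_dependent` uses the uniform kernel of the voxel's own material,
#' ignoring borders (PRC-TD); `spatially_variant` composes a
#' voxel-specific kernel from the surrounding material neighborhood
#' (full PRC). Voxel kernels are computed on demand, never pre-stored for
#' all voxels.
#'
#' @param mode One of `"uniform_water"`, `"tissue_dependent"`,
#'   `"spatially_variant"`.
#' @param kset A [uniform_kernel_set()].
#' @param mmap A [material_map()]; required for the map-dependent modes.
#' @param isotope Isotope name.
#' @return An object of class `kernel_provider`.
#' @export
make_kernel_provider <- function(mode = c("uniform_water", "tissue_dependent",
                                          "spatially_variant"),
                                 kset, mmap = NULL, isotope) {
  mode <- match.arg(mode)
  stopifnot(inherits(kset, "uniform_kernel_set"))
  if (mode != "uniform_water" && is.null(mmap))
    stop_input("mode '", mode, "' requires a material map")
  if (!is.null(mmap)) stopifnot(inherits(mmap, "material_map"))
  iso_name <- if (inherits(isotope, "isotope_spec")) isotope$name
              else as.character(isotope)
  if (is.null(kset$kernels[[iso_name]]))
    stop_input("kernel set has no kernels for isotope '", iso_name, "'")
  structure(list(mode = mode, kset = kset, mmap = mmap,
                 isotope = iso_name),
            class = "kernel_provider")
}

#' Kernel attached to a voxel by a provider
#'
#' @param provider A [make_kernel_provider()].
#' @param j 1-based voxel index triple.
#' @return A `kernel3d`.
#' @export
provider_kernel <- function(provider, j) {
  stopifnot(inherits(provider, "kernel_provider"))
  switch(provider$mode,
    uniform_water = get_kernel(provider$kset, provider$isotope, "water"),
    tissue_dependent = {
      lab <- material_labels()[provider$mmap$labels[j[1], j[2], j[3]]]
      get_kernel(provider$kset, provider$isotope, lab)
    },
    spatially_variant = compose_variant_kernel(provider$kset, provider$mmap,
                                               j, provider$isotope))
}

#' A provider whose operator H is the identity
#'
#' @param voxel_size mm triple.
#' @param half_width Kernel half width (mass stays in the center voxel).
#' @return A `kernel_provider` in uniform mode with a delta kernel.
#' @export
identity_provider <- function(voxel_size = c(2.036, 2.036, 2.027),
                              half_width = 0) {
  dk <- delta_kernel(half_width, voxel_size)
  kset <- uniform_kernel_set(list(any = list(
    lung = dk, water = dk, bone = dk)))
  make_kernel_provider("uniform_water", kset, NULL, isotope = "any")
}

#' Compare two kernels
#'
#' @param a,b `kernel3d` objects of the same shape.
#' @return List with the L1 distance, maximum absolute voxel difference,
#'   and the two center-line profiles (along x through the kernel center)
#'   for plotting.
#' @export
compare_kernels <- function(a, b) {
  stopifnot(inherits(a, "kernel3d"), inherits(b, "kernel3d"))
  if (!identical(dim(a$values), dim(b$values)))
    stop_input("kernels must share a shape")
  cc <- a$center_index
  list(l1 = sum(abs(a$values - b$values)),
       max_abs = max(abs(a$values - b$values)),
       profile_a = a$values[, cc[2], cc[3]],
       profile_b = b$values[, cc[2], cc[3]])
}

#' Write / read a kernel as NIfTI-1
#' @param kernel A `kernel3d`.
#' @param path Output path.
#' @return `write_kernel` returns `path` invisibly; `read_kernel` the
#'   `kernel3d`.
#' @export
write_kernel <- function(kernel, path) {
  write_volume(kernel$values, kernel$voxel_size, path)
}

#' @rdname write_kernel
#' @export
read_kernel <- function(path) {
  v <- read_volume(path)
  kernel3d(v$values, v$voxel_size[1:3], normalize = TRUE)
}
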