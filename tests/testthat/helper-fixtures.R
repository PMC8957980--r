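# Shared fixtures, built once per test run.

.fixtures <- new.env()

# memoized builder so expensive simulations run once across test files
fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

tiny_grid <- function(n = 16, nz = 4, vox = 2) image_grid(n, n, nz, rep(vox, 3))

# Ga68-scale kernel set on 2 mm voxels (wide kernel, pronounced blur)
ga68_kset <- function() fixture("ga68_kset", function()
  build_uniform_kernels("Ga68", n_events = 5e4, seed = 42,
                        voxel_size = c(2, 2, 2), max_range = 8))

# F18-scale kernel set (narrow kernel)
f18_kset <- function() fixture("f18_kset", function()
  build_uniform_kernels("F18", n_events = 5e4, seed = 42,
                        voxel_size = c(2, 2, 2), max_range = 4))

# analytic symmetric Gaussian kernel (exactly centro-symmetric)
gaussian_kernel <- function(half = 2, sigma_vox = 0.8, vox = 2) {
  s <- 2 * half + 1
  u <- seq(-half, half)
  g1 <- exp(-u^2 / (2 * sigma_vox^2))
  k <- outer(outer(g1, g1), g1)
  kernel3d(array(k, c(s, s, s)), rep(vox, 3), normalize = TRUE)
}

kernel_provider_from <- function(kernel, label = "any") {
  kset <- uniform_kernel_set(list(iso = list(lung = kernel, water = kernel,
                                             bone = kernel)))
  make_kernel_provider("uniform_water", kset, NULL, isotope = "iso")
}

# small uniform-disk activity phantom on a single-slice grid
disk_image <- function(grid, radius_mm, value = 1) {
  cx <- (seq_len(grid$nx) - (grid$nx + 1) / 2) * grid$voxel_size[1]
  cy <- (seq_len(grid$ny) - (grid$ny + 1) / 2) * grid$voxel_size[2]
  m <- outer(cx^2, cy^2, `+`) <= radius_mm^2
  array(rep(m * value, grid$nz), c(grid$nx, grid$ny, grid$nz))
}

# brute-force per-offset composition oracle (direct loop + renormalize)
compose_oracle <- function(kset, mmap, j, isotope) {
  hw <- kset$half_width
  s <- 2L * hw + 1L
  d <- dim(mmap$labels)
  km <- sapply(material_labels(), function(m)
    as.numeric(get_kernel(kset, isotope, m)$values))
  v <- array(0, c(s, s, s))
  for (w in 1:s) for (vv in 1:s) for (u in 1:s) {
    x <- min(max(j[1] + u - 1L - hw, 1L), d[1])
    y <- min(max(j[2] + vv - 1L - hw, 1L), d[2])
    z <- min(max(j[3] + w - 1L - hw, 1L), d[3])
    lab <- mmap$labels[x, y, z]
    v[u, vv, w] <- km[u + s * (vv - 1L) + s * s * (w - 1L), lab]
  }
  v / sum(v)
}
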