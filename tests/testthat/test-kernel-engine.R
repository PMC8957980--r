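# Kernel construction, material classification and spatially variant
# composition.

test_that("kernel half width follows the ceiling rule", {
  expect_identical(kernel_half_width(10, 2.036), 5L)   # side 11
  expect_identical(kernel_half_width(2, 2), 1L)        # side 3
  expect_identical(kernel_half_width(10, 4), 3L)       # ceil(10/4)
  expect_error(kernel_half_width(0, 2), "positive")
  expect_error(kernel_half_width(10, -1), "positive")
})

test_that("binning a zero-displacement cloud yields a delta kernel", {
  rec <- data.frame(xi = 0, yi = 0, zi = 0, xf = 0, yf = 0, zf = 0, r = 0)
  cl <- petprc:::new_point_cloud(rec[rep(1, 100), ], "F18", "water", 100L, 1)
  k <- bin_point_cloud_to_kernel(cl, 2, 2)
  expect_equal(k$values[3, 3, 3], 1)
  expect_equal(sum(k$values), 1)
  expect_identical(attr(k, "dropped"), 0L)
})

test_that("binned kernels are normalized and drop out-of-grid events", {
  cl <- simulate_point_source("Ga68", "water", 2e4, seed = 2)
  k <- bin_point_cloud_to_kernel(cl, 1, 2)  # 5^3 grid at 1 mm: tails fall out
  expect_lt(abs(sum(k$values) - 1), 1e-12)
  expect_gt(attr(k, "dropped"), 0)
  # F18 in lung at reconstruction pitch: the governing 10 mm range gives side 11
  klarge <- bin_point_cloud_to_kernel(cl, 2.036, kernel_half_width(10, 2.036))
  expect_identical(dim(klarge$values), c(11L, 11L, 11L))
  expect_error(bin_point_cloud_to_kernel(
    simulate_point_source("F18", "water", 0), 2, 2), "empty")
})

test_that("mu-map thresholds classify lung, water and bone", {
  g <- image_grid(2, 2, 1, c(2, 2, 2))
  mu <- array(c(0.096, 0, 0.15, 0.08), c(2, 2, 1))
  mm <- material_map_from_mumap(mu_map(mu, g))
  expect_identical(mm$labels[1, 1, 1], 2L)  # 0.096 -> water
  expect_identical(mm$labels[2, 1, 1], 1L)  # 0 (air) -> lung
  expect_identical(mm$labels[1, 2, 1], 3L)  # 0.15 -> bone
  expect_identical(mm$labels[2, 2, 1], 2L)  # boundary t_low -> water
  expect_error(mu_map(array(-1, c(2, 2, 1)), g), ">= 0")
  expect_error(material_map_from_mumap(mu_map(mu, g), c(0.12, 0.08)),
               "t_low")
})

test_that("composition in a homogeneous map is bitwise the uniform kernel", {
  kset <- ga68_kset()
  g <- tiny_grid(24, 12)
  mm <- material_map(array(2L, c(24, 24, 12)), g)
  kc <- compose_variant_kernel(kset, mm, c(12, 12, 6), "Ga68")
  expect_identical(kc$values, get_kernel(kset, "Ga68", "water")$values)
})

test_that("composed kernels equal the brute-force per-offset oracle on random maps", {
  kset <- ga68_kset()
  g <- tiny_grid(20, 10)
  set.seed(123)
  worst <- 0
  for (rep in 1:100) {
    mm <- material_map(array(sample(1:3, 20 * 20 * 10, TRUE),
                             c(20, 20, 10)), g)
    j <- c(sample(20, 1), sample(20, 1), sample(10, 1))
    got <- compose_variant_kernel(kset, mm, j, "Ga68")$values
    want <- compose_oracle(kset, mm, j, "Ga68")
    worst <- max(worst, max(abs(got - want)))
    expect_lt(abs(sum(got) - 1), 1e-12)
  }
  expect_lt(worst, 1e-14)
})

test_that("kernel providers dispatch by mode", {
  kset <- ga68_kset()
  g <- tiny_grid(24, 12)
  lab <- array(2L, c(24, 24, 12))
  lab[1:8, , ] <- 3L          # bone slab
  lab[20:24, , ] <- 1L        # lung slab
  mm <- material_map(lab, g)
  pu <- make_kernel_provider("uniform_water", kset, NULL, "Ga68")
  expect_identical(provider_kernel(pu, c(2, 2, 2))$values,
                   provider_kernel(pu, c(20, 20, 10))$values)
  pt <- make_kernel_provider("tissue_dependent", kset, mm, "Ga68")
  expect_identical(provider_kernel(pt, c(4, 12, 6))$values,
                   get_kernel(kset, "Ga68", "bone")$values)
  pv <- make_kernel_provider("spatially_variant", kset, mm, "Ga68")
  # deep inside the water region composition degenerates to tissue-dependent
  expect_identical(provider_kernel(pv, c(14, 12, 6))$values,
                   provider_kernel(pt, c(14, 12, 6))$values)
  expect_error(make_kernel_provider("spatially_variant", kset, NULL, "Ga68"),
               "material map")
})

test_that("kernel comparison metrics match closed forms", {
  kset <- ga68_kset()
  kw <- get_kernel(kset, "Ga68", "water")
  cmp0 <- compare_kernels(kw, kw)
  expect_equal(cmp0$l1, 0)
  expect_equal(cmp0$max_abs, 0)
  s <- dim(kw$values)[1]
  n <- s^3
  dk <- delta_kernel((s - 1) / 2, kw$voxel_size)
  uk <- kernel3d(array(1, c(s, s, s)), kw$voxel_size)
  cmp <- compare_kernels(dk, uk)
  expect_equal(cmp$l1, 2 * (1 - 1 / n))  # closed form for delta vs uniform
  expect_equal(compare_kernels(uk, dk)$l1, cmp$l1)  # symmetry
  expect_error(compare_kernels(dk, delta_kernel(1)), "shape")
})

test_that("the composed profile across a water-lung border tails into lung", {
  kset <- fixture("ga68_kset_pet", function()
    build_uniform_kernels("Ga68", n_events = 1e5, seed = 7,
                          voxel_size = c(2.036, 2.036, 2.027)))
  ph <- make_kernel_validation_phantom("a", image_grid(49, 49, 49))
  kc <- compose_variant_kernel(kset, ph$material_map, ph$source_voxel,
                               "Ga68")
  cc <- kc$center_index
  prof <- kc$values[, cc[2], cc[3]]
  s <- length(prof)
  # the profile reaches farther into lung (+x) than into water (-x), and
  # the lung half-space holds more total mass than the mirrored water side
  expect_gt(sum(prof[(s - 1):s]), sum(prof[1:2]))
  hw <- kset$half_width
  expect_gt(sum(kc$values[(hw + 3):s, , ]), sum(kc$values[1:(hw - 1), , ]))
})

test_that("composition tracks heterogeneous simulation across a border", {
  kset <- fixture("ga68_kset_pet", function()
    build_uniform_kernels("Ga68", n_events = 1e5, seed = 7,
                          voxel_size = c(2.036, 2.036, 2.027)))
  ph <- make_kernel_validation_phantom("a", image_grid(49, 49, 49))
  cloud <- simulate_in_material_map("Ga68", ph$material_map,
                                    ph$source_voxel, 1e5, seed = 99)
  simulated <- bin_point_cloud_to_kernel(cloud, c(2.036, 2.036, 2.027),
                                         kset$half_width)
  composed <- compose_variant_kernel(kset, ph$material_map,
                                     ph$source_voxel, "Ga68")
  kw <- get_kernel(kset, "Ga68", "water")
  kl <- get_kernel(kset, "Ga68", "lung")
  l1_comp <- compare_kernels(composed, simulated)$l1
  # far below the spread between the two homogeneous assumptions
  expect_lt(l1_comp, compare_kernels(kw, kl)$l1)
  # and far closer than assuming lung everywhere
  expect_lt(l1_comp, compare_kernels(kl, simulated)$l1)
  # known failure mode: the composition overestimates the kernel just
  # beyond the border when the positron leaves the denser material
  cc <- composed$center_index
  border <- cc[1] + 3  # first full-lung voxel on the center line
  expect_gt(composed$values[border, cc[2], cc[3]],
            simulated$values[border, cc[2], cc[3]])
})

test_that("kernels round-trip through NIfTI", {
  k <- ga68_kset()
  kw <- get_kernel(k, "Ga68", "water")
  path <- file.path(tempdir(), "kernel.nii.gz")
  write_kernel(kw, path)
  back <- read_kernel(path)
  expect_equal(back$values, kw$values, tolerance = 1e-12)
  expect_equal(back$voxel_size[1:3], kw$voxel_size, tolerance = 1e-6)
})
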