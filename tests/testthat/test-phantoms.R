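# Digital phantom generators and the acquisition simulator.

nema_small <- function() fixture("nema_small", function()
  make_nema_iq(image_grid(96, 96, 25, c(2, 2, 2)),
               sphere_diameters = c(10, 13, 17, 22),
               body_semiaxes = c(80, 70), ring_radius = 42,
               bg_voi_diameter = 16, bg_voi_ring = 60, bg_voi_z = 10))

test_that("HU conversion anchors at air, water and reference bone", {
  expect_equal(hu_to_mu511(0), 0.096)
  expect_equal(hu_to_mu511(-1000), 0)
  expect_equal(hu_to_mu511(1000), 0.151)
  hu <- seq(-1000, 2000, by = 10)
  expect_true(all(diff(hu_to_mu511(hu)) >= 0))
  expect_error(hu_to_mu511(-1200), "physical")
})

test_that("NEMA phantom honors the configured activity ratio voxelwise", {
  ph <- fixture("nema_default", function() make_nema_iq())
  for (i in seq_len(nrow(ph$truth))) {
    v <- ph$vois$signal[[ph$truth$region[i]]]
    ctr <- round(v$center / ph$grid$voxel_size +
                   (petprc:::grid_dim(ph$grid) + 1) / 2)
    expect_equal(ph$activity[ctr[1], ctr[2], ctr[3]] /
                   ph$truth$background[i], 5)
  }
  expect_identical(length(ph$vois$background), 12L)
  # Ga68 variant: 24/3 gives ratio 8
  ph8 <- make_nema_iq(image_grid(96, 96, 25, c(2, 2, 2)),
                      sphere_diameters = c(10, 13),
                      sphere_activity = 24, bg_activity = 3,
                      body_semiaxes = c(80, 70), ring_radius = 42,
                      bg_voi_diameter = 16, bg_voi_ring = 60, bg_voi_z = 10)
  expect_equal(unique(ph8$truth$ratio), 8)
})

test_that("voxelized sphere volumes match the analytic volume", {
  ph <- fixture("nema_default", function() make_nema_iq())
  vol_vox <- prod(ph$grid$voxel_size)
  for (i in seq_len(nrow(ph$truth))) {
    d <- ph$truth$diameter[i]
    if (d < 13) next  # below ~6 voxels across, discretization dominates
    v <- ph$vois$signal[[ph$truth$region[i]]]
    ctr <- v$center
    fr <- petprc:::sphere_fraction(ph$grid, ctr, d, 3)
    expect_equal(sum(fr) * vol_vox, pi / 6 * d^3, tolerance = 0.05)
  }
})

test_that("phantom mu-maps threshold back to the intended materials", {
  ph <- fixture("nema_default", function() make_nema_iq())
  mm <- material_map_from_mumap(ph$mumap)
  expect_identical(mm$labels, ph$material_map$labels)
  body <- ph$mumap$values > 0
  expect_true(all(mm$labels[body] == 2L))   # water body
  expect_true(all(mm$labels[!body] == 1L))  # air thresholds to lung label
})

test_that("resolution phantom sources are equal, labeled and placed", {
  ph <- make_resolution_phantom(image_grid(96, 96, 5, c(2, 2, 2)))
  expect_identical(nrow(ph$truth), 16L)
  expect_identical(sum(ph$truth$group == "inner"), 4L)
  expect_identical(sum(ph$truth$group == "outer"), 4L)
  # equal integrated activity per source: total = 16 * per-source
  expect_equal(sum(ph$activity), 16 * ph$truth$activity[1],
               tolerance = 1e-12)
  one <- make_resolution_phantom(image_grid(32, 32, 3, c(2, 2, 2)),
                                 n_sources = 1)
  expect_equal(sum(one$activity), one$truth$activity[1], tolerance = 1e-12)
  expect_error(make_resolution_phantom(n_sources = 7), "1 or 16")
})

test_that("bone-lung phantom builds the three-material geometry", {
  ph <- fixture("bonelung", function() make_bone_lung_phantom())
  # cylinder centers threshold to lung, bone, bone
  g <- ph$grid
  th <- c(90, 210, 330) * pi / 180
  labs <- sapply(seq_along(th), function(i) {
    ctr <- round(c(60 * cos(th[i]), 60 * sin(th[i]), 0) / g$voxel_size +
                   (petprc:::grid_dim(g) + 1) / 2)
    # sample just off the sphere inserts
    ph$material_map$labels[ctr[1] + 4, ctr[2], 3]
  })
  expect_identical(material_labels()[labs], c("lung", "bone", "bone"))
  expect_setequal(unique(ph$truth$diameter), c(8.5, 19.4))
  expect_true(all(ph$truth$ratio == 5))
  expect_identical(length(ph$vois$background), 6L)
})

test_that("kernel-validation maps place the source in the right material", {
  g <- image_grid(49, 49, 49)
  a <- make_kernel_validation_phantom("a", g)
  expect_identical(a$material_map$labels[a$source_voxel[1],
                                         a$source_voxel[2],
                                         a$source_voxel[3]], 2L)
  d <- make_kernel_validation_phantom("d", g)
  expect_identical(d$material_map$labels[d$source_voxel[1],
                                         d$source_voxel[2],
                                         d$source_voxel[3]], 3L)
  for (case in c("a", "b", "c", "d")) {
    mm <- make_kernel_validation_phantom(case, g)$material_map
    expect_true(all(mm$labels %in% 1:3))
  }
})

test_that("acquisition simulation is Poisson at the requested count level", {
  ph <- nema_small()
  geom <- geom_for_grid(ph$grid, n_angles = 60)
  N <- 3e5
  s1 <- simulate_acquisition(ph, geom, NULL, N, seed = 2)
  s2 <- simulate_acquisition(ph, geom, NULL, N, seed = 2)
  expect_identical(s1$values, s2$values)
  tots <- vapply(1:5, function(k)
    sum(simulate_acquisition(ph, geom, NULL, N, seed = 100 + k)$values),
    numeric(1))
  expect_true(all(abs(tots - N) < 4 * sqrt(N)))
  # zero activity: zero-count sinogram
  ph0 <- ph
  ph0$activity[] <- 0
  s0 <- simulate_acquisition(ph0, geom, NULL, N, seed = 1)
  expect_true(all(s0$values == 0))
  # attenuated variant has strictly fewer expected counts through the body
  sw <- simulate_acquisition(ph, geom, NULL, N, seed = 2,
                             attenuation_precorrected = FALSE)
  expect_identical(sum(sw$values > 0) > 0, TRUE)
})
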