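# Projector, attenuation factors and the range-blur operator with their
# exact adjoints.

test_that("forward projection of a disk matches the analytic chord length", {
  g <- image_grid(128, 128, 1, c(1, 1, 1))
  geom <- scanner_geometry(128, 1, 8, 1)
  R <- 40
  img <- disk_image(g, R)
  sino <- forward_project(img, g, geom)
  s_off <- (seq_len(128) - (128 + 1) / 2) * 1
  keep <- abs(s_off) < 0.8 * R
  chord <- 2 * sqrt(R^2 - s_off[keep]^2)
  for (a in c(1, 4, 7)) {
    rel <- abs(sino$values[keep, a, 1] - chord) / chord
    expect_lt(max(rel), 0.03)
  }
  expect_true(all(forward_project(img * 0, g, geom)$values == 0))
})

test_that("a central hot voxel peaks at the central radial bin for every angle", {
  g <- image_grid(33, 33, 1, c(2, 2, 2))
  geom <- scanner_geometry(33, 2, 12, 1)
  img <- array(0, c(33, 33, 1))
  img[17, 17, 1] <- 1
  sino <- forward_project(img, g, geom)
  for (a in seq_len(12))
    expect_identical(which.max(sino$values[, a, 1]), 17L)
})

test_that("a translated point source traces a sinusoid in sinogram space", {
  g <- image_grid(64, 64, 1, c(2, 2, 2))
  geom <- scanner_geometry(64, 2, 24, 1)
  img <- array(0, c(64, 64, 1))
  pos <- c(12, 25)  # voxel indices
  img[pos[1], pos[2], 1] <- 1
  xy <- (pos - (64 + 1) / 2) * 2
  sino <- forward_project(img, g, geom)
  th <- pi * (seq_len(24) - 1) / 24
  s_pred <- xy[1] * cos(th) + xy[2] * sin(th)
  bin_pred <- s_pred / 2 + (64 + 1) / 2
  for (a in seq_len(24)) {
    peak <- which.max(sino$values[, a, 1])
    expect_lt(abs(peak - bin_pred[a]), 1.5)  # within one radial bin
  }
})

test_that("back projection is the exact adjoint of forward projection", {
  g <- image_grid(24, 24, 3, c(2.1, 2.1, 2))
  geom <- scanner_geometry(32, 2, 12, 3)
  set.seed(4)
  f <- array(runif(24 * 24 * 3), c(24, 24, 3))
  y <- array(runif(32 * 12 * 3), c(32, 12, 3))
  lhs <- sum(forward_project(f, g, geom)$values * y)
  rhs <- sum(f * back_project(sinogram(y, geom), g))
  expect_lt(abs(lhs - rhs) / abs(rhs), 1e-10)
  expect_true(all(back_project(sinogram(y * 0, geom), g) == 0))
})

test_that("uniform backprojection is symmetric under 90-degree rotation", {
  g <- image_grid(32, 32, 1, c(2, 2, 2))
  geom <- scanner_geometry(48, 2, 8, 1)
  ones <- sinogram(array(1, c(48, 8, 1)), geom)
  b <- back_project(ones, g)[, , 1]
  rot <- t(b[nrow(b):1, ])  # 90-degree rotation
  expect_lt(max(abs(b - rot)), 1e-8 * max(b))
})

test_that("attenuation factors follow the exponential line integral", {
  g <- image_grid(128, 128, 1, c(2, 2, 2))
  geom <- scanner_geometry(128, 2, 4, 1)
  mu0 <- mu_map(array(0, c(128, 128, 1)), g)
  w0 <- attenuation_factors(mu0, geom)
  expect_true(all(w0 == 1))
  # uniform water disk, diameter 200 mm: central LOR = exp(-0.096 * 20)
  mu <- mu_map(disk_image(g, 100, 0.096), g)
  w <- attenuation_factors(mu, geom)
  central <- w[64, 1, 1] # radial bin at s = -1 mm
  expect_equal(central, exp(-0.096 * 2 * sqrt(100^2 - 1) / 10),
               tolerance = 0.01)
  expect_true(all(w > 0 & w <= 1))
  # monotone: raising one voxel's mu never increases any factor
  mu2v <- mu$values
  mu2v[60, 64, 1] <- mu2v[60, 64, 1] + 0.05
  w2 <- attenuation_factors(mu_map(mu2v, g), geom)
  expect_true(all(w2 <= w + 1e-15))
  # w = 1 exactly where the line integral is zero
  expect_true(all((w == 1) == (abs(log(w)) == 0)))
})

test_that("blurring a delta image reproduces the kernel at that voxel", {
  kset <- ga68_kset()
  g <- tiny_grid(20, 12)
  lab <- array(2L, c(20, 20, 12)); lab[1:9, , ] <- 1L
  mm <- material_map(lab, g)
  pv <- make_kernel_provider("spatially_variant", kset, mm, "Ga68")
  img <- array(0, c(20, 20, 12))
  j <- c(10, 10, 6)
  img[j[1], j[2], j[3]] <- 1
  out <- apply_pr_blur(img, pv)
  kj <- provider_kernel(pv, j)$values
  hw <- kset$half_width
  sub <- out[(j[1] - hw):(j[1] + hw), (j[2] - hw):(j[2] + hw),
             (j[3] - hw):(j[3] + hw)]
  expect_identical(sub, kj)
  expect_equal(sum(out), 1, tolerance = 1e-10)  # mass conserved when inside
})

test_that("uniform blur equals direct dense convolution", {
  kset <- ga68_kset()
  pu <- make_kernel_provider("uniform_water", kset, NULL, "Ga68")
  n <- 32
  set.seed(5)
  img <- array(runif(n * n * 8), c(n, n, 8))
  got <- apply_pr_blur(img, pu)
  k <- get_kernel(kset, "Ga68", "water")$values
  hw <- (dim(k)[1] - 1) / 2
  want <- array(0, dim(img))
  for (w in -hw:hw) for (v in -hw:hw) for (u in -hw:hw) {
    kval <- k[u + hw + 1, v + hw + 1, w + hw + 1]
    if (kval == 0) next
    xs <- seq_len(n); ys <- seq_len(n); zs <- seq_len(8)
    xd <- xs + u; yd <- ys + v; zd <- zs + w
    okx <- xd >= 1 & xd <= n; oky <- yd >= 1 & yd <= n
    okz <- zd >= 1 & zd <= 8
    want[xd[okx], yd[oky], zd[okz]] <-
      want[xd[okx], yd[oky], zd[okz]] +
      kval * img[xs[okx], ys[oky], zs[okz]]
  }
  expect_lt(max(abs(got - want)), 1e-12)
})

test_that("the blur adjoint passes randomized dot-product tests", {
  kset <- ga68_kset()
  g <- tiny_grid(18, 8)
  set.seed(6)
  mm <- material_map(array(sample(1:3, 18 * 18 * 8, TRUE), c(18, 18, 8)), g)
  for (mode in c("uniform_water", "tissue_dependent", "spatially_variant")) {
    pv <- make_kernel_provider(mode, kset, mm, "Ga68")
    f <- array(runif(18 * 18 * 8), c(18, 18, 8))
    y <- array(runif(18 * 18 * 8), c(18, 18, 8))
    lhs <- sum(apply_pr_blur(f, pv) * y)
    rhs <- sum(f * apply_pr_blur_adjoint(y, pv))
    expect_lt(abs(lhs - rhs) / abs(rhs), 1e-10)
  }
})

test_that("a centro-symmetric invariant kernel is self-adjoint", {
  pk <- kernel_provider_from(gaussian_kernel())
  set.seed(8)
  img <- array(runif(16^3), c(16, 16, 16))
  expect_lt(max(abs(apply_pr_blur(img, pk) -
                    apply_pr_blur_adjoint(img, pk))), 1e-12)
})

test_that("delta kernels make H the identity, and the adjoint reads out rows", {
  pid <- identity_provider(c(2, 2, 2), half_width = 2)
  set.seed(10)
  img <- array(runif(12^3), c(12, 12, 12))
  expect_identical(apply_pr_blur(img, pid), img)
  expect_identical(apply_pr_blur_adjoint(img, pid), img)
  # row read-out: adjoint of a delta at j0 gives h_{j0 j} over j
  kset <- ga68_kset()
  pu <- make_kernel_provider("uniform_water", kset, NULL, "Ga68")
  dimg <- array(0, c(12, 12, 12)); j0 <- c(6, 6, 6); dimg[6, 6, 6] <- 1
  row <- apply_pr_blur_adjoint(dimg, pu)
  k <- get_kernel(kset, "Ga68", "water")$values
  hw <- (dim(k)[1] - 1) / 2
  # h_{j0 j} = k(j0 - j): the row is the kernel reflected about j0
  expect_equal(row[6 - 2, 6, 6], k[hw + 1 + 2, hw + 1, hw + 1])
  expect_equal(row[6, 6 + 1, 6], k[hw + 1, hw + 1 - 1, hw + 1])
})
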