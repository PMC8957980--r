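# OSEM / OSEM-PRC reconstruction properties.

small_recon_setup <- function(n = 64, counts = 2e6, blur = NULL,
                              noisy = FALSE, seed = 17) {
  g <- image_grid(n, n, 1, c(2, 2, 2))
  geom <- scanner_geometry(n, 2, 24, 1)
  f_true <- disk_image(g, 40, 1) + 4 * disk_image(g, 10, 1)
  fb <- if (is.null(blur)) f_true else apply_pr_blur(f_true, blur)
  lam <- forward_project(fb, g, geom)$values
  m <- if (noisy) {
    lam <- lam * (counts / sum(lam))
    petprc:::with_seed(seed, array(rpois(length(lam), lam) + 0, dim(lam)))
  } else lam
  list(g = g, geom = geom, f_true = f_true,
       sino = sinogram(array(as.numeric(m), dim(lam)), geom))
}

test_that("subset schemes interleave, cover and balance the angles", {
  geom <- scanner_geometry(32, 2, 24, 1)
  ss <- subset_scheme(geom, 6)
  expect_identical(ss[[1]], seq.int(1L, 24L, by = 6L))
  expect_identical(sort(unlist(ss)), 1:24)
  expect_true(all(lengths(ss) == 4))
  expect_error(subset_scheme(geom, 7), "divisible")
})

test_that("MLEM increases the Poisson likelihood monotonically", {
  st <- small_recon_setup(64, noisy = TRUE)
  cfg <- recon_config(n_iterations = 20, n_subsets = 1,
                      keep_iterations = TRUE)
  f <- osem(st$sino, st$g, NULL, cfg)
  lls <- vapply(attr(f, "iterations"), poisson_loglik, numeric(1),
                sino = st$sino, grid = st$g)
  expect_true(all(diff(lls) > -1e-6 * abs(lls[-1])))
})

test_that("MLEM with the blurred system model also increases its likelihood", {
  pk <- kernel_provider_from(gaussian_kernel(vox = 2))
  st <- small_recon_setup(48, blur = pk, noisy = TRUE)
  cfg <- recon_config(n_iterations = 12, n_subsets = 1,
                      keep_iterations = TRUE)
  f <- osem_prc(st$sino, st$g, NULL, pk, cfg)
  lls <- vapply(attr(f, "iterations"), poisson_loglik, numeric(1),
                sino = st$sino, grid = st$g, provider = pk)
  expect_true(all(diff(lls) > -1e-6 * abs(lls[-1])))
})

test_that("noiseless OSEM converges toward the true image", {
  st <- small_recon_setup(64)
  cfg <- recon_config(n_iterations = 10, n_subsets = 4,
                      keep_iterations = TRUE)
  f <- osem(st$sino, st$g, NULL, cfg)
  nrmse <- vapply(attr(f, "iterations"), function(x)
    sqrt(mean((x - st$f_true)^2)) / mean(st$f_true), numeric(1))
  expect_true(all(diff(nrmse) < 0))
  expect_true(all(f >= 0))
})

test_that("PRC with an identity provider reproduces plain OSEM bitwise", {
  st <- small_recon_setup(32, noisy = TRUE)
  pid <- identity_provider(c(2, 2, 2), half_width = 1)
  cfg <- recon_config(n_iterations = 3, n_subsets = 4)
  expect_identical(osem_prc(st$sino, st$g, NULL, pid, cfg),
                   osem(st$sino, st$g, NULL, cfg))
})

test_that("reconstruction is bitwise reproducible for a fixed configuration", {
  st <- small_recon_setup(32, noisy = TRUE, seed = 5)
  pk <- kernel_provider_from(gaussian_kernel(vox = 2))
  cfg <- recon_config(n_iterations = 2, n_subsets = 4)
  expect_identical(osem_prc(st$sino, st$g, NULL, pk, cfg),
                   osem_prc(st$sino, st$g, NULL, pk, cfg))
})

test_that("an all-zero sinogram reconstructs to zero with a warning", {
  st <- small_recon_setup(32)
  zero <- sinogram(st$sino$values * 0, st$geom)
  expect_warning(f <- osem(zero, st$g), "zero")
  expect_true(all(f == 0))
})

test_that("sensitivity images reduce to X^T 1 without attenuation or blur", {
  g <- image_grid(24, 24, 2, c(2, 2, 2))
  geom <- scanner_geometry(32, 2, 12, 2)
  s <- sensitivity_image(g, geom)
  xt1 <- back_project(sinogram(array(1, c(32, 12, 2)), geom), g)
  expect_equal(s, xt1, tolerance = 1e-14)
  # strictly positive inside the FOV (central region)
  expect_true(all(s[8:16, 8:16, ] > 0))
  # symmetric invariant kernel: sensitivity = blur of the plain sensitivity
  pk <- kernel_provider_from(gaussian_kernel(vox = 2))
  sp <- sensitivity_image(g, geom, provider = pk)
  expect_lt(max(abs(sp - apply_pr_blur(xt1, pk))), 1e-10 * max(sp))
})

test_that("noise matching returns first-reach iterations", {
  m <- noise_matched_pair(c(4, 8, 12), c(4, 8, 12), 10)
  expect_identical(m$iteration_a, m$iteration_b)
  expect_identical(m$iteration_a, 3L)
  m2 <- noise_matched_pair(c(6, 9, 11, 14), c(5, 6, 7, 8), 10)
  expect_identical(m2$iteration_a, 3L)
  expect_false(m2$reached_b)
  # a curve lying below another reaches any target no earlier
  a <- c(5, 9, 13, 17)
  b <- a - 2
  m3 <- noise_matched_pair(a, b, 12)
  expect_gte(m3$iteration_b, m3$iteration_a)
})

test_that("attenuation in the data model is self-consistent with attenuated data", {
  g <- image_grid(48, 48, 1, c(2, 2, 2))
  geom <- scanner_geometry(48, 2, 24, 1)
  f_true <- disk_image(g, 30, 1) + 3 * disk_image(g, 8, 1)
  mu <- mu_map(disk_image(g, 40, 0.096), g)
  lam <- forward_project(f_true, g, geom)$values *
    as.numeric(attenuation_factors(mu, geom))
  sino <- sinogram(lam, geom)
  cfg <- recon_config(n_iterations = 8, n_subsets = 4,
                      attenuation_in_data = TRUE, keep_iterations = TRUE)
  f <- osem(sino, g, mu, cfg)
  nrmse <- vapply(attr(f, "iterations"), function(x)
    sqrt(mean((x - f_true)^2)) / mean(f_true), numeric(1))
  expect_true(all(diff(nrmse) < 0))
  expect_lt(nrmse[length(nrmse)], 0.5 * nrmse[1])
})
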