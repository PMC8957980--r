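#' Angular subset scheme
#'
#' Fixed interleaved partition: angle index a (1-based) belongs to subset
#' `((a - 1) mod n_subsets) + 1`. Subsets are disjoint, cover all angles
#' and have equal size (n_angles must be divisible by n_subsets).
#'
#' @param geom A [scanner_geometry()].
#' @param n_subsets Number of subsets.
#' @return List of integer angle-index vectors, one per subset.
#' @export
subset_scheme <- function(geom, n_subsets) {
  if (geom$n_angles %% n_subsets != 0)
    stop_input("n_angles must be divisible by n_subsets")
  n_subsets <- as.integer(n_subsets)
  lapply(seq_len(n_subsets), function(k)
    seq.int(k, geom$n_angles, by = n_subsets))
}

#' Reconstruction configuration
#'
#' @param n_iterations Full OSEM iterations (each visits every subset
#'   once). Defaults follow the noise-matched protocol: 2 for plain OSEM,
#'   8 for range-corrected reconstructions (both with 12 subsets).
#' @param n_subsets Number of angular subsets.
#' @param epsilon Ratio guard added to the projection denominator.
#' @param initial_value Uniform value of the initial image inside the FOV.
#' @param sens_floor Voxels whose subset sensitivity is below
#'   `sens_floor * max(sensitivity)` are frozen at 0.
#' @param keep_iterations Keep the image after every full iteration
#'   (attribute `"iterations"` of the result).
#' @param attenuation_in_data Include the attenuation factors in the data
#'   model (`lambda = w * X H f`) instead of only in the sensitivity.
#'   Default `FALSE`: attenuation enters the sensitivity denominator
#'   only, the convention for attenuation-precorrected data.
#' @return An object of class `recon_config`.
#' @export
recon_config <- function(n_iterations = 2, n_subsets = 12, epsilon = 1e-10,
                         initial_value = 1, sens_floor = 1e-8,
                         keep_iterations = FALSE,
                         attenuation_in_data = FALSE) {
  if (n_iterations < 1) stop_input("n_iterations must be >= 1")
  if (epsilon <= 0) stop_input("epsilon must be > 0")
  structure(list(n_iterations = as.integer(n_iterations),
                 n_subsets = as.integer(n_subsets), epsilon = epsilon,
                 initial_value = initial_value, sens_floor = sens_floor,
                 keep_iterations = keep_iterations,
                 attenuation_in_data = attenuation_in_data),
            class = "recon_config")
}

#' Subset sensitivity image
#'
#' `H^T X_S^T w_S`: back-project the subset's attenuation factors, then
#' apply the adjoint of the range blur. Without a provider, `H^T` is the
#' identity; with a zero mu-map the result reduces to `X^T 1`.
#'
#' @param grid An [image_grid()].
#' @param geom A [scanner_geometry()].
#' @param mumap Optional [mu_map()]; `NULL` means no attenuation (w = 1).
#' @param provider Optional [make_kernel_provider()].
#' @param subset 1-based angle indices; default all angles.
#' @return 3D sensitivity image.
#' @export
sensitivity_image <- function(grid, geom, mumap = NULL, provider = NULL,
                              subset = NULL) {
  subset <- subset %||% seq_len(geom$n_angles)
  w <- if (is.null(mumap)) {
    array(1, c(geom$n_radial, geom$n_angles, geom$n_slices))
  } else {
    attenuation_factors(mumap, geom)
  }
  ws <- sinogram(array(w[, subset, , drop = FALSE],
                       c(geom$n_radial, length(subset), geom$n_slices)),
                 geom, subset)
  s <- back_project(ws, grid)
  if (!is.null(provider)) s <- apply_pr_blur_adjoint(s, provider)
  s
}

# Shared OSEM engine. With a provider, the range blur enters BOTH the
# forward step (project H f) and the back step (H^T applied to the
# back-projected correction), so the back projector stays the exact
# transpose of the forward operator W X H.
osem_engine <- function(sino, grid, mumap, provider, cfg) {
  stopifnot(inherits(sino, "sinogram"), inherits(cfg, "recon_config"))
  geom <- sino$geometry
  if (all(sino$values == 0)) {
    warning("all-zero sinogram: returning a zero image")
    return(array(0, grid_dim(grid)))
  }
  subsets <- subset_scheme(geom, cfg$n_subsets)
  att_data <- isTRUE(cfg$attenuation_in_data) && !is.null(mumap)
  w_full <- if (att_data) attenuation_factors(mumap, geom) else NULL
  sens <- lapply(subsets, function(ss)
    sensitivity_image(grid, geom, mumap, provider, ss))
  masks <- lapply(sens, function(s) s > cfg$sens_floor * max(s))
  fov <- Reduce(`|`, masks)
  f <- array(0, grid_dim(grid))
  f[fov] <- cfg$initial_value
  kept <- if (cfg$keep_iterations) vector("list", cfg$n_iterations) else NULL
  for (it in seq_len(cfg$n_iterations)) {
    for (k in seq_along(subsets)) {
      ss <- subsets[[k]]
      fb <- if (is.null(provider)) f else apply_pr_blur(f, provider)
      q <- forward_project(fb, grid, geom, ss)$values
      m <- array(sino$values[, ss, , drop = FALSE], dim(q))
      if (att_data) {
        ws <- array(w_full[, ss, , drop = FALSE], dim(q))
        ratio <- ws * m / pmax(ws * q, cfg$epsilon)
      } else {
        ratio <- m / pmax(q, cfg$epsilon)
      }
      cimg <- back_project(sinogram(ratio, geom, ss), grid)
      if (!is.null(provider)) cimg <- apply_pr_blur_adjoint(cimg, provider)
      upd <- array(0, dim(f))
      mk <- masks[[k]]
      upd[mk] <- f[mk] * cimg[mk] / sens[[k]][mk]
      f <- upd
    }
    if (cfg$keep_iterations) kept[[it]] <- f
  }
  if (cfg$keep_iterations) attr(f, "iterations") <- kept
  f
}

#' OSEM reconstruction
#'
#' Multiplicative ordered-subsets EM update without resolution modeling:
#' per subset S, `f <- f * X_S^T (m_S / X_S f) / (X_S^T w_S)`. Subsets are
#' visited in fixed interleaved order; iterates stay non-negative and
#' voxels with zero sensitivity stay 0. With one subset this is MLEM and
#' the Poisson log-likelihood is non-decreasing.
#'
#' @param sino Measured [sinogram()] (attenuation-precorrected by
#'   default convention; attenuation enters the sensitivity only).
#' @param grid An [image_grid()].
#' @param mumap Optional [mu_map()] for the attenuation factors.
#' @param cfg A [recon_config()].
#' @return Reconstructed 3D image; if `cfg$keep_iterations`, the per-
#'   iteration images are in `attr(, "iterations")`.
#' @export
osem <- function(sino, grid, mumap = NULL, cfg = recon_config()) {
  osem_engine(sino, grid, mumap, NULL, cfg)
}

#' OSEM with positron-range correction
#'
#' OSEM on the factorized system matrix `A = W X H`: per subset the
#' current estimate is range-blurred (`H f`), forward-projected, and the
#' back-projected correction is passed through the exact blur transpose
#' (`H^T`) before the multiplicative update with the blurred sensitivity.
#' With an identity provider this is bitwise-identical to [osem()].
#'
#' @inheritParams osem
#' @param provider A [make_kernel_provider()] defining H.
#' @return Reconstructed 3D image.
#' @export
osem_prc <- function(sino, grid, mumap = NULL, provider,
                     cfg = recon_config(n_iterations = 8)) {
  stopifnot(inherits(provider, "kernel_provider"))
  osem_engine(sino, grid, mumap, provider, cfg)
}

#' Poisson log-likelihood of an image under the (blurred) forward model
#'
#' `sum_i m_i log(lambda_i) - lambda_i` with `lambda = X H f` (H identity
#' without a provider). Bins with `lambda = 0, m = 0` contribute 0; a bin
#' with `lambda = 0, m > 0` yields `-Inf`.
#'
#' @param image 3D array.
#' @param sino Measured [sinogram()].
#' @param grid An [image_grid()].
#' @param provider Optional [make_kernel_provider()].
#' @return Scalar log-likelihood (additive constants dropped).
#' @export
poisson_loglik <- function(image, sino, grid, provider = NULL) {
  fb <- if (is.null(provider)) image else apply_pr_blur(image, provider)
  lam <- forward_project(fb, grid, sino$geometry, sino$angles)$values
  m <- sino$values
  ok <- lam > 0
  ll <- sum(m[ok] * log(lam[ok]) - lam[ok])
  if (any(m[!ok] > 0)) ll <- -Inf
  ll
}

#' Noise-matched iteration pair
#'
#' Given per-iteration background-noise curves of two reconstructions,
#' returns for each the first iteration whose noise reaches the target
#' (within `tol` below it). This implements the comparison protocol of
#' matching reconstructions at a common background noise level.
#'
#' @param noise_a,noise_b Numeric vectors of noise (percent) per
#'   iteration.
#' @param target Target noise, percent.
#' @param tol Tolerance band below the target that still counts as
#'   reached.
#' @return List with `iteration_a`, `iteration_b` (NA when never reached)
#'   and logical `reached_a`, `reached_b`.
#' @export
noise_matched_pair <- function(noise_a, noise_b, target, tol = 0) {
  first_reach <- function(x) {
    i <- which(x >= target - tol)
    if (length(i)) i[1] else NA_integer_
  }
  ia <- first_reach(noise_a)
  ib <- first_reach(noise_b)
  list(iteration_a = ia, iteration_b = ib,
       reached_a = !is.na(ia), reached_b = !is.na(ib))
}
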