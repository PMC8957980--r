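#' Spherical volume of interest
#'
#' Membership is by voxel-center inclusion: the mask holds exactly the
#' voxels whose centers lie within `diameter / 2` of the center.
#'
#' @param grid An [image_grid()].
#' @param center mm triple (grid-centered coordinates).
#' @param diameter mm.
#' @param name Label.
#' @return An object of class `voi` with fields `name`, `center`,
#'   `diameter` and `mask` (linear voxel indices).
#' @export
voi_sphere <- function(grid, center, diameter, name = "voi") {
  cx <- axis_coords(grid, 1); cy <- axis_coords(grid, 2)
  cz <- axis_coords(grid, 3)
  r2 <- (diameter / 2)^2
  dx2 <- (cx - center[1])^2
  dy2 <- (cy - center[2])^2
  dz2 <- (cz - center[3])^2
  d2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  mask <- which(d2 <= r2)
  if (!length(mask))
    stop_input("VOI '", name, "' contains no voxel centers")
  structure(list(name = name, center = as.numeric(center),
                 diameter = diameter, mask = mask), class = "voi")
}

voi_stats <- function(image, vois) {
  means <- vapply(vois, function(v) mean(image[v$mask]), numeric(1))
  sds <- vapply(vois, function(v) {
    if (length(v$mask) < 2) stop_input("VOI '", v$name, "' needs >= 2 voxels")
    sd(image[v$mask])
  }, numeric(1))
  list(means = means, sds = sds)
}

#' Background noise (percent)
#'
#' `100 * STD_background / Mean_background`, where `STD_background` is
#' the mean of the per-VOI sample standard deviations (n - 1 denominator)
#' and `Mean_background` the mean of the per-VOI means.
#'
#' @param image 3D array.
#' @param bg_vois List of background [voi_sphere()] objects.
#' @return Noise in percent.
#' @export
noise <- function(image, bg_vois) {
  if (!length(bg_vois)) stop_input("need at least one background VOI")
  st <- voi_stats(image, bg_vois)
  mb <- mean(st$means)
  if (mb == 0) stop_input("zero background mean")
  100 * mean(st$sds) / mb
}

#' Image contrast
#'
#' `Mean_signal / Mean_background` with the background mean taken over
#' the background VOIs.
#'
#' @param image 3D array.
#' @param signal_voi A [voi_sphere()].
#' @param bg_vois List of background VOIs.
#' @return Dimensionless contrast.
#' @export
contrast <- function(image, signal_voi, bg_vois) {
  st <- voi_stats(image, bg_vois)
  mb <- mean(st$means)
  if (mb == 0) stop_input("zero background mean")
  mean(image[signal_voi$mask]) / mb
}

#' Contrast-to-noise ratio
#'
#' `(Mean_signal - Mean_background) / STD_background` with
#' `STD_background` the mean of the per-VOI standard deviations.
#'
#' @inheritParams contrast
#' @return Dimensionless CNR (negative for cold lesions).
#' @export
cnr <- function(image, signal_voi, bg_vois) {
  st <- voi_stats(image, bg_vois)
  sb <- mean(st$sds)
  if (sb == 0) stop_input("zero background standard deviation")
  (mean(image[signal_voi$mask]) - mean(st$means)) / sb
}

#' Recovery coefficient
#'
#' Measured contrast divided by the true activity ratio; 1 for a perfect
#' reconstruction.
#'
#' @inheritParams contrast
#' @param activity_ratio True lesion-to-background activity ratio.
#' @return Dimensionless recovery coefficient.
#' @export
recovery_coefficient <- function(image, signal_voi, bg_vois, activity_ratio) {
  if (activity_ratio <= 0) stop_input("activity_ratio must be > 0")
  contrast(image, signal_voi, bg_vois) / activity_ratio
}

#' Contrast recovery (percent)
#'
#' `100 * (Mean_sphere / Mean_background - 1) / (activity_ratio - 1)`;
#' 100 percent for a perfect reconstruction.
#'
#' @inheritParams recovery_coefficient
#' @return Contrast recovery in percent.
#' @export
contrast_recovery_pct <- function(image, signal_voi, bg_vois, activity_ratio) {
  if (activity_ratio == 1)
    stop_input("contrast recovery is undefined for activity ratio 1")
  100 * (contrast(image, signal_voi, bg_vois) - 1) / (activity_ratio - 1)
}

#' Full width at half maximum of a sampled profile
#'
#' Subtracts a baseline (median of the edge samples), locates the global
#' maximum (must be unique and interior), and linearly interpolates the
#' half-maximum crossing on each side of the peak.
#'
#' @param profile Sampled 1D values.
#' @param spacing Sample spacing, mm.
#' @return FWHM in mm.
#' @export
fwhm <- function(profile, spacing) {
  n <- length(profile)
  if (n < 3) stop_input("profile too short")
  k <- max(1, round(0.05 * n))
  baseline <- median(c(head(profile, k), tail(profile, k)))
  p <- profile - baseline
  pk <- which(p == max(p))
  if (length(pk) != 1 || pk == 1 || pk == n)
    stop_input("profile needs a unique interior global maximum")
  half <- p[pk] / 2
  if (half <= 0) stop_input("flat profile: no half-maximum crossing")
  left <- NA_real_
  for (i in seq(pk - 1, 1)) {
    if (p[i] < half) {
      left <- i + (half - p[i]) / (p[i + 1] - p[i])
      break
    }
  }
  right <- NA_real_
  for (i in seq(pk + 1, n)) {
    if (p[i] < half) {
      right <- i - (half - p[i]) / (p[i - 1] - p[i])
      break
    }
  }
  if (is.na(left) || is.na(right))
    stop_input("no half-maximum crossing on one side of the peak")
  (right - left) * spacing
}

#' Convergence metric curves
#'
#' Computes, for a series of images (one per iteration), the background
#' noise and the per-sphere recovery coefficient and CNR, ready for
#' plotting or for [noise_matched_pair()].
#'
#' @param image_series List of 3D arrays (or a single array).
#' @param signal_vois List of signal [voi_sphere()] objects.
#' @param bg_vois List of background VOIs.
#' @param activity_ratio True activity ratio.
#' @return Data frame with columns `iteration`, `noise`, and `rc_<name>`
#'   / `cnr_<name>` per signal VOI.
#' @export
convergence_curves <- function(image_series, signal_vois, bg_vois,
                               activity_ratio) {
  if (is.array(image_series)) image_series <- list(image_series)
  if (!length(image_series)) stop_input("need at least one image")
  rows <- lapply(seq_along(image_series), function(it) {
    img <- image_series[[it]]
    row <- list(iteration = it, noise = noise(img, bg_vois))
    for (v in signal_vois) {
      row[[paste0("rc_", v$name)]] <-
        recovery_coefficient(img, v, bg_vois, activity_ratio)
      row[[paste0("cnr_", v$name)]] <- cnr(img, v, bg_vois)
    }
    as.data.frame(row)
  })
  do.call(rbind, rows)
}
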