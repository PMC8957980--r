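#' Convert Hounsfield units to 511 keV attenuation
#'
#' Bilinear mapping anchored at air (-1000 HU -> 0), water (0 HU ->
#' `mu_water`) and reference bone (1000 HU -> `mu_bone_ref`):
#' `mu = mu_water * (1 + HU/1000)` for HU <= 0 and
#' `mu = mu_water + HU * (mu_bone_ref - mu_water)/1000` for HU > 0.
#'
#' @param hu Hounsfield units (must be >= -1000).
#' @param mu_water Water attenuation at 511 keV, cm^-1.
#' @param mu_bone_ref Attenuation at 1000 HU, cm^-1.
#' @return Linear attenuation coefficients, cm^-1.
#' @export
hu_to_mu511 <- function(hu, mu_water = 0.096, mu_bone_ref = 0.151) {
  if (any(hu < -1000)) stop_input("HU below -1000 is not physical")
  ifelse(hu <= 0, mu_water * (1 + hu / 1000),
         mu_water + hu * (mu_bone_ref - mu_water) / 1000)
}

phantom_bundle <- function(activity, mumap, mmap, vois, truth, grid,
                           activity_ratio = NA_real_) {
  structure(list(activity = activity, mumap = mumap, material_map = mmap,
                 vois = vois, truth = truth, grid = grid,
                 activity_ratio = activity_ratio),
            class = "phantom_bundle")
}

#' @export
print.phantom_bundle <- function(x, ...) {
  cat(sprintf("<phantom_bundle> grid %d x %d x %d, total activity %.4g\n",
              x$grid$nx, x$grid$ny, x$grid$nz, sum(x$activity)))
  print(x$truth)
  invisible(x)
}

# 2D elliptical body mask replicated over slices
body_mask <- function(grid, semiaxes) {
  cx <- axis_coords(grid, 1); cy <- axis_coords(grid, 2)
  m2 <- outer(cx^2 / semiaxes[1]^2, cy^2 / semiaxes[2]^2, `+`) <= 1
  array(m2, grid_dim(grid))
}

# Voxelized sphere fill fraction (supersampled partial-volume weights)
sphere_fraction <- function(grid, center, diameter, supersample = 3) {
  cx <- axis_coords(grid, 1); cy <- axis_coords(grid, 2)
  cz <- axis_coords(grid, 3)
  r <- diameter / 2
  frac <- array(0, grid_dim(grid))
  sel <- list(which(abs(cx - center[1]) <= r + grid$voxel_size[1]),
              which(abs(cy - center[2]) <= r + grid$voxel_size[2]),
              which(abs(cz - center[3]) <= r + grid$voxel_size[3]))
  if (!all(lengths(sel) > 0)) return(frac)
  off <- function(v) ((seq_len(supersample) - 0.5) / supersample - 0.5) * v
  ox <- off(grid$voxel_size[1]); oy <- off(grid$voxel_size[2])
  oz <- off(grid$voxel_size[3])
  for (k in sel[[3]]) for (j in sel[[2]]) for (i in sel[[1]]) {
    dx2 <- (cx[i] + ox - center[1])^2
    dy2 <- (cy[j] + oy - center[2])^2
    dz2 <- (cz[k] + oz - center[3])^2
    inside <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= r^2
    frac[i, j, k] <- mean(inside)
  }
  frac
}

# Trilinear deposit of a point amount at mm position pos
deposit_point <- function(vol, grid, pos, amount) {
  d <- grid_dim(grid)
  u <- pos / grid$voxel_size + (d + 1) / 2  # fractional 1-based index
  i0 <- floor(u)
  w1 <- u - i0
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    i <- i0 + c(dx, dy, dz)
    if (any(i < 1) || any(i > d)) next
    w <- prod(ifelse(c(dx, dy, dz) == 1, w1, 1 - w1))
    vol[i[1], i[2], i[3]] <- vol[i[1], i[2], i[3]] + amount * w
  }
  vol
}

#' NEMA-like image quality phantom
#'
#' Digital analogue of the NEMA IQ phantom: an elliptical water cylinder
#' with six hot spheres on a 114.4 mm diameter ring and 12 spherical
#' background VOIs placed away from the spheres (six each in two planes
#' at +/- 18.5 mm axial offset). Default fill 30/6 kBq/ml (5:1); the
#' Ga-68 protocol uses 24/3 (8:1).
#'
#' @param grid An [image_grid()]; must be large enough for the 37 mm
#'   sphere and VOIs (default 128 x 128 x 37 at 2.036/2.027 mm pitch).
#' @param sphere_diameters mm; default `c(10, 13, 17, 22, 28, 37)`.
#' @param sphere_activity,bg_activity kBq/ml.
#' @param body_semiaxes Ellipse semi-axes of the body cross-section, mm.
#' @param ring_radius Radius of the sphere placement ring, mm.
#' @param mu_water Body attenuation at 511 keV, cm^-1.
#' @param bg_voi_diameter Background VOI diameter, mm.
#' @param bg_voi_ring Radius of the background-VOI placement ring, mm.
#' @param bg_voi_z Axial offset of the two background-VOI planes, mm.
#' @param supersample Sub-voxel sampling factor for the sphere
#'   partial-volume weights.
#' @return A `phantom_bundle` with activity, mu-map, material map,
#'   signal/background VOIs and the truth table.
#' @export
make_nema_iq <- function(grid = image_grid(128, 128, 37),
                         sphere_diameters = c(10, 13, 17, 22, 28, 37),
                         sphere_activity = 30, bg_activity = 6,
                         body_semiaxes = c(112, 87), ring_radius = 57.2,
                         mu_water = 0.096, bg_voi_diameter = 37,
                         bg_voi_ring = 75, bg_voi_z = 18.5,
                         supersample = 3) {
  nd <- length(sphere_diameters)
  # angles chosen so every background VOI stays disjoint from every sphere
  angles_deg <- if (nd == 6) {
    c(330, 150, 30, 210, 90, 270)[rank(sphere_diameters,
                                       ties.method = "first")]
  } else {
    seq(90, 90 + 360 * (nd - 1) / nd, length.out = nd) %% 360
  }
  th <- angles_deg * pi / 180
  centers <- cbind(ring_radius * cos(th), ring_radius * sin(th), 0)
  # pairwise overlap check
  if (nd > 1) {
    for (i in seq_len(nd - 1)) for (j in seq(i + 1, nd)) {
      mind <- (sphere_diameters[i] + sphere_diameters[j]) / 2
      if (sqrt(sum((centers[i, ] - centers[j, ])^2)) < mind)
        stop_input("spheres overlap; reduce diameters or enlarge the ring")
    }
  }
  half_fov <- grid_dim(grid) * grid$voxel_size / 2
  if (body_semiaxes[1] > half_fov[1] || body_semiaxes[2] > half_fov[2])
    stop_input("phantom body does not fit the grid")

  body <- body_mask(grid, body_semiaxes)
  activity <- array(0, grid_dim(grid))
  activity[body] <- bg_activity
  for (i in seq_len(nd)) {
    fr <- sphere_fraction(grid, centers[i, ], sphere_diameters[i],
                          supersample)
    activity <- activity * (1 - fr) + sphere_activity * fr
  }
  mu <- array(0, grid_dim(grid))
  mu[body] <- mu_water
  mumap <- mu_map(mu, grid)
  mmap <- material_map_from_mumap(mumap)

  signal <- lapply(seq_len(nd), function(i)
    voi_sphere(grid, centers[i, ], sphere_diameters[i],
               name = paste0(sphere_diameters[i], "mm")))
  names(signal) <- vapply(signal, `[[`, character(1), "name")
  bg_angles <- c(0, 45, 135, 180, 225, 315) * pi / 180
  bg_centers <- do.call(rbind, lapply(c(-bg_voi_z, bg_voi_z), function(z)
    cbind(bg_voi_ring * cos(bg_angles), bg_voi_ring * sin(bg_angles), z)))
  if (max(abs(bg_centers[, 3])) + bg_voi_diameter / 2 > half_fov[3])
    stop_input("background VOIs do not fit the grid axially")
  background <- lapply(seq_len(nrow(bg_centers)), function(i)
    voi_sphere(grid, bg_centers[i, ], bg_voi_diameter,
               name = paste0("bg", i)))
  # construction guard: background VOIs must be disjoint from all spheres
  for (b in background) for (i in seq_len(nd)) {
    if (sqrt(sum((b$center - centers[i, ])^2)) <
        (bg_voi_diameter + sphere_diameters[i]) / 2)
      stop_input("background VOI overlaps a sphere")
  }
  truth <- data.frame(region = names(signal),
                      diameter = sphere_diameters,
                      activity = sphere_activity,
                      background = bg_activity,
                      ratio = sphere_activity / bg_activity)
  phantom_bundle(activity, mumap, mmap,
                 list(signal = signal, background = background),
                 truth, grid, sphere_activity / bg_activity)
}

#' Resolution phantom
#'
#' Point-like sources in the water-filled NEMA housing for FWHM
#' analysis. With 16 sources they sit on a 4 x 4 transverse grid; the
#' central 2 x 2 are labeled `inner`, the corners `outer` (8 sources for
#' analysis), the rest `other`. Sources are deposited with trilinear
#' sub-voxel weights so all sources carry exactly equal activity.
#'
#' @param grid An [image_grid()].
#' @param n_sources 1 (a single central source) or 16.
#' @param source_diameter Nominal source diameter, mm (sub-voxel;
#'   recorded in the truth table).
#' @param source_activity Integrated activity per source.
#' @param spacing Grid spacing of the 4 x 4 source layout, mm.
#' @param body_semiaxes,mu_water Housing geometry as in [make_nema_iq()].
#' @return A `phantom_bundle`; `truth` lists source positions and groups.
#' @export
make_resolution_phantom <- function(grid = image_grid(128, 128, 5),
                                    n_sources = 16, source_diameter = 0.5,
                                    source_activity = 100, spacing = 30,
                                    body_semiaxes = c(110, 82),
                                    mu_water = 0.096) {
  if (!n_sources %in% c(1L, 16L))
    stop_input("n_sources must be 1 or 16")
  if (n_sources == 1) {
    pos <- matrix(0, 1, 3)
    group <- "inner"
  } else {
    u <- spacing * c(-1.5, -0.5, 0.5, 1.5)
    pos <- as.matrix(expand.grid(x = u, y = u))
    pos <- cbind(pos, z = 0)
    group <- ifelse(abs(pos[, 1]) == spacing / 2 &
                      abs(pos[, 2]) == spacing / 2, "inner",
                    ifelse(abs(pos[, 1]) == 1.5 * spacing &
                             abs(pos[, 2]) == 1.5 * spacing, "outer",
                           "other"))
  }
  half_fov <- grid_dim(grid) * grid$voxel_size / 2
  if (any(abs(pos[, 1]) >= half_fov[1]) || any(abs(pos[, 2]) >= half_fov[2]))
    stop_input("sources do not fit the grid")
  activity <- array(0, grid_dim(grid))
  for (i in seq_len(nrow(pos)))
    activity <- deposit_point(activity, grid, pos[i, ], source_activity)
  mu <- array(0, grid_dim(grid))
  mu[body_mask(grid, body_semiaxes)] <- mu_water
  mumap <- mu_map(mu, grid)
  truth <- data.frame(name = paste0("src", seq_len(nrow(pos))),
                      x = pos[, 1], y = pos[, 2], z = pos[, 3],
                      group = group, diameter = source_diameter,
                      activity = source_activity)
  phantom_bundle(activity, mumap, material_map_from_mumap(mumap),
                 list(signal = list(), background = list()),
                 truth, grid)
}

#' Bone-lung phantom
#'
#' Three 50 mm cylinders (lung at -800 HU and two bone types at 500 and
#' 1000 HU) inside the water-filled NEMA housing, each holding a hot
#' 8.5 mm and a hot 19.4 mm sphere at 30 kBq/ml over a 6 kBq/ml water
#' background (5:1); the cylinders themselves are cold. Six 37 mm
#' background VOIs sit in the water region.
#'
#' @param grid An [image_grid()].
#' @param cylinder_hu HU of the three cylinder materials.
#' @param sphere_diameters mm; default `c(8.5, 19.4)`.
#' @param sphere_activity,bg_activity kBq/ml.
#' @param body_semiaxes,mu_water As in [make_nema_iq()].
#' @param supersample Partial-volume supersampling factor.
#' @return A `phantom_bundle`.
#' @export
make_bone_lung_phantom <- function(grid = image_grid(128, 128, 37),
                                   cylinder_hu = c(-800, 500, 1000),
                                   sphere_diameters = c(8.5, 19.4),
                                   sphere_activity = 30, bg_activity = 6,
                                   body_semiaxes = c(110, 82),
                                   mu_water = 0.096, supersample = 3) {
  cyl_r <- 25
  cyl_th <- c(90, 210, 330) * pi / 180
  cyl_centers <- cbind(60 * cos(cyl_th), 60 * sin(cyl_th))
  cyl_names <- c("lung", "bone500", "bone1000")
  body <- body_mask(grid, body_semiaxes)
  cx <- axis_coords(grid, 1); cy <- axis_coords(grid, 2)

  mu <- array(0, grid_dim(grid))
  mu[body] <- mu_water
  activity <- array(0, grid_dim(grid))
  activity[body] <- bg_activity
  cyl_masks <- list()
  for (i in 1:3) {
    m2 <- outer((cx - cyl_centers[i, 1])^2, (cy - cyl_centers[i, 2])^2,
                `+`) <= cyl_r^2
    m3 <- array(m2, grid_dim(grid))
    cyl_masks[[i]] <- m3
    mu[m3] <- hu_to_mu511(cylinder_hu[i], mu_water = mu_water)
    activity[m3] <- 0
  }
  # hot fillable (water) spheres inside each cylinder
  signal <- list()
  truth <- NULL
  sphere_z <- c(12, -12)
  for (i in 1:3) for (s in seq_along(sphere_diameters)) {
    ctr <- c(cyl_centers[i, ], sphere_z[s])
    d <- sphere_diameters[s]
    fr <- sphere_fraction(grid, ctr, d, supersample)
    activity <- activity * (1 - fr) + sphere_activity * fr
    mu[fr > 0.5] <- mu_water
    nm <- paste0(cyl_names[i], "_", d, "mm")
    signal[[nm]] <- voi_sphere(grid, ctr, d, name = nm)
    truth <- rbind(truth, data.frame(
      region = nm, material = cyl_names[i], diameter = d,
      activity = sphere_activity, background = bg_activity,
      ratio = sphere_activity / bg_activity))
  }
  mumap <- mu_map(mu, grid)
  bg_xy <- rbind(c(70, 0), c(-70, 0), c(0, -45))
  bg_centers <- do.call(rbind, lapply(c(-10, 10), function(z)
    cbind(bg_xy, z)))
  background <- lapply(seq_len(nrow(bg_centers)), function(i)
    voi_sphere(grid, bg_centers[i, ], 37, name = paste0("bg", i)))
  phantom_bundle(activity, mumap, material_map_from_mumap(mumap),
                 list(signal = signal, background = background),
                 truth, grid, sphere_activity / bg_activity)
}

#' Heterogeneous kernel-validation material maps
#'
#' Four 10 x 10 x 10 cm box phantoms for validating composed spatially
#' variant kernels against direct simulation, with the point source at
#' the box center: (a) water with a lung half-space starting 4 mm
#' off-center; (b) a 0.6 x 0.6 x 10 cm water cuboid centered in lung;
#' (c) a 0.6 x 0.6 x 10 cm lung cuboid 4 mm off-center in water; (d) a
#' 0.2 x 0.2 x 10 cm bone cuboid on the source plus a 0.6 x 0.6 x 10 cm
#' lung cuboid beside it, in water.
#'
#' @param case `"a"`, `"b"`, `"c"` or `"d"`.
#' @param grid An [image_grid()] spanning about 10 cm per side.
#' @return List with the [material_map()] and the central `source_voxel`
#'   index triple.
#' @export
make_kernel_validation_phantom <- function(case = c("a", "b", "c", "d"),
                             grid = image_grid(49, 49, 49)) {
  case <- match.arg(case)
  d <- grid_dim(grid)
  cx <- axis_coords(grid, 1); cy <- axis_coords(grid, 2)
  lab <- array(2L, d)  # water
  in_x <- function(lo, hi) array(outer(cx >= lo & cx <= hi,
                                       rep(TRUE, d[2]), `&`), d)
  in_xy <- function(xlo, xhi, ylo, yhi)
    array(outer(cx >= xlo & cx <= xhi, cy >= ylo & cy <= yhi, `&`), d)
  if (case == "a") {
    lab[in_x(4, Inf)] <- 1L
  } else if (case == "b") {
    lab[] <- 1L
    lab[in_xy(-3, 3, -3, 3)] <- 2L
  } else if (case == "c") {
    lab[in_xy(1, 7, -3, 3)] <- 1L
  } else {
    lab[in_xy(2, 8, -3, 3)] <- 1L
    lab[in_xy(-1, 1, -1, 1)] <- 3L
  }
  list(material_map = material_map(lab, grid),
       source_voxel = (d + 1L) %/% 2L)
}

#' Simulate a noisy PET acquisition of a phantom
#'
#' Forms the expected sinogram `lambda = scale * X H a` (with `H` from
#' the provider; identity when `provider` is `NULL`) scaled so the total
#' expected counts match `expected_total_counts`, then draws independent
#' Poisson counts per bin. By default the data are attenuation-
#' precorrected (no attenuation in the data mean), matching a
#' reconstruction that keeps attenuation in the sensitivity only; set
#' `attenuation_precorrected = FALSE` to include the attenuation factors
#' in the mean.
#'
#' @param bundle A `phantom_bundle`.
#' @param geom A [scanner_geometry()].
#' @param provider Optional [make_kernel_provider()] — the range blur of
#'   the simulated physics (may deliberately differ from the one used in
#'   reconstruction for model-mismatch studies).
#' @param expected_total_counts Expected total counts over the sinogram.
#' @param seed Integer seed.
#' @param attenuation_precorrected Logical, see Details.
#' @return A [sinogram()] of counts.
#' @export
simulate_acquisition <- function(bundle, geom, provider = NULL,
                                 expected_total_counts = 5e6, seed = 1,
                                 attenuation_precorrected = TRUE) {
  stopifnot(inherits(bundle, "phantom_bundle"))
  if (expected_total_counts <= 0)
    stop_input("expected_total_counts must be > 0")
  a <- bundle$activity
  if (!is.null(provider)) a <- apply_pr_blur(a, provider)
  lam <- forward_project(a, bundle$grid, geom)$values
  if (!attenuation_precorrected) {
    w <- attenuation_factors(bundle$mumap, geom)
    lam <- lam * as.numeric(w)
  }
  tot <- sum(lam)
  if (tot <= 0) {
    if (all(bundle$activity == 0))  # a cold phantom measures zero counts
      return(sinogram(lam, geom))
    stop_input("zero total forward projection")
  }
  lam <- lam * (expected_total_counts / tot)
  counts <- with_seed(seed, rpois(length(lam), lam))
  sinogram(array(as.numeric(counts), dim(lam)), geom)
}
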