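#' Beta-decay branch of a positron emitter
#'
#' A single allowed beta-plus transition, described by its endpoint
#' (maximum) kinetic energy, its relative intensity among the isotope's
#' positron branches, and the atomic number of the daughter nucleus (which
#' enters the Coulomb correction of the beta spectrum).
#'
#' @param endpoint_energy Endpoint kinetic energy Q of the branch, MeV.
#' @param relative_intensity Fraction of positron decays through this
#'   branch, in (0, 1].
#' @param daughter_Z Atomic number of the daughter nucleus.
#' @return An object of class `beta_branch`.
#' @export
beta_branch <- function(endpoint_energy, relative_intensity = 1, daughter_Z = 1) {
  if (!is.numeric(endpoint_energy) || endpoint_energy <= 0)
    stop_input("endpoint_energy must be a positive energy in MeV")
  if (relative_intensity <= 0 || relative_intensity > 1)
    stop_input("relative_intensity must be in (0, 1]")
  structure(list(endpoint_energy = endpoint_energy,
                 relative_intensity = relative_intensity,
                 daughter_Z = as.integer(daughter_Z)),
            class = "beta_branch")
}

#' Positron-emitting isotope specification
#'
#' Built-in isotopes cover the three radionuclides relevant for
#' positron-range correction at clinical PET energies: `"F18"`
#' (Q = 0.63 MeV, single branch), `"Ga68"` (Q = 1.9 MeV, single branch)
#' and `"I124"` (two branches at 1.54 and 2.14 MeV with relative
#' intensities 0.52/0.48 from standard nuclear data).
#'
#' @param name Isotope name: `"F18"`, `"Ga68"` or `"I124"`, or any label
#'   when `branches` is supplied explicitly.
#' @param branches Optional list of [beta_branch()] objects overriding the
#'   built-in decay scheme.
#' @return An object of class `isotope_spec`.
#' @export
isotope_spec <- function(name, branches = NULL) {
  if (inherits(name, "isotope_spec")) return(name)
  if (is.null(branches)) {
    branches <- switch(name,
      F18  = list(beta_branch(0.63, 1, 8)),
      Ga68 = list(beta_branch(1.9, 1, 30)),
      I124 = list(beta_branch(1.54, 0.52, 52), beta_branch(2.14, 0.48, 52)),
      stop_input("unknown isotope '", name, "'; supply branches explicitly")
    )
  }
  if (!length(branches)) stop_input("an isotope needs at least one branch")
  ri <- vapply(branches, `[[`, numeric(1), "relative_intensity")
  if (abs(sum(ri) - 1) > 1e-9)
    stop_input("branch relative intensities must sum to 1")
  structure(list(name = name, branches = branches), class = "isotope_spec")
}

#' @export
print.isotope_spec <- function(x, ...) {
  cat("<isotope_spec>", x$name, "\n")
  for (b in x$branches)
    cat(sprintf("  branch: Q = %.3f MeV, intensity %.3f, daughter Z = %d\n",
                b$endpoint_energy, b$relative_intensity, b$daughter_Z))
  invisible(x)
}

#' Allowed-transition beta spectrum density
#'
#' Unnormalized density of the positron kinetic energy for an allowed
#' beta-plus transition, N(T) = p E (Q - T)^2 F(Z, E), where p and E are
#' the positron momentum and total energy and F is the nonrelativistic
#' Coulomb (Fermi) function for a positron, F = 2 pi eta / (1 - exp(-2 pi
#' eta)) with eta = -alpha Z / beta. The Coulomb repulsion between the
#' positron and the daughter nucleus suppresses the low-energy part of the
#' spectrum.
#'
#' @param T_MeV Kinetic energies, MeV (values outside (0, Q] get density 0).
#' @param Q Endpoint kinetic energy, MeV.
#' @param Z Atomic number of the daughter nucleus.
#' @return Unnormalized density values.
#' @export
beta_spectrum_density <- function(T_MeV, Q, Z) {
  me <- 0.510998950
  alpha <- 1 / 137.035999
  d <- numeric(length(T_MeV))
  ok <- T_MeV > 0 & T_MeV <= Q
  T_ok <- T_MeV[ok]
  E <- T_ok + me
  p <- sqrt(E^2 - me^2)
  beta <- p / E
  eta <- -alpha * Z / beta
  fermi <- ifelse(abs(eta) < 1e-12, 1, 2 * pi * eta / (1 - exp(-2 * pi * eta)))
  d[ok] <- p * E * (Q - T_ok)^2 * fermi
  d
}

#' Sample positron kinetic energies from a beta branch
#'
#' Draws from the allowed-transition Fermi beta spectrum of the branch by
#' rejection sampling against a uniform envelope. Uses the caller's RNG
#' state (seed with [set.seed()] or go through [simulate_point_source()]
#' for a self-seeded simulation).
#'
#' @param branch A [beta_branch()].
#' @param n Number of draws.
#' @return Kinetic energies in MeV, each in (0, Q].
#' @export
sample_beta_energy <- function(branch, n = 1) {
  if (!inherits(branch, "beta_branch")) stop_input("branch must be a beta_branch")
  Q <- branch$endpoint_energy
  if (!is.numeric(Q) || Q <= 0) stop_input("invalid branch: non-positive endpoint")
  if (n == 0) return(numeric(0))
  grid <- seq(Q / 4096, Q, length.out = 4096)
  dmax <- max(beta_spectrum_density(grid, Q, branch$daughter_Z)) * 1.001
  out <- numeric(0)
  while (length(out) < n) {
    m <- ceiling((n - length(out)) * 1.6) + 16
    cand <- runif(m, 0, Q)
    u <- runif(m, 0, dmax)
    acc <- u < beta_spectrum_density(cand, Q, branch$daughter_Z)
    out <- c(out, cand[acc])
  }
  out[seq_len(n)]
}

#' Tissue material specification
#'
#' The three canonical media for positron-range modeling. Mass densities
#' follow the standard tissue definitions (lung 0.26, water 1.00, bone
#' 1.92 g/cm^3). Electron densities relative to water are derived from the
#' mass density and the material Z/A; radiation lengths (g/cm^2) feed the
#' Highland multiple-scattering angle.
#'
#' @param label `"lung"`, `"water"` or `"bone"`.
#' @return An object of class `material_spec` with fields `label`,
#'   `mass_density`, `electron_density_rel_water`, `effective_Z`,
#'   `radiation_length`.
#' @export
material_spec <- function(label) {
  if (inherits(label, "material_spec")) return(label)
  tab <- list(
    lung  = list(mass_density = 0.26, electron_density_rel_water = 0.257,
                 effective_Z = 7.49, radiation_length = 36.5),
    water = list(mass_density = 1.00, electron_density_rel_water = 1.000,
                 effective_Z = 7.42, radiation_length = 36.08),
    bone  = list(mass_density = 1.92, electron_density_rel_water = 1.781,
                 effective_Z = 13.8, radiation_length = 28.8)
  )
  if (!label %in% names(tab)) stop_input("unknown material '", label, "'")
  structure(c(list(label = label), tab[[label]]), class = "material_spec")
}

#' Material labels in canonical order
#' @return `c("lung", "water", "bone")`; integer label codes 1, 2, 3 used
#'   by material maps follow this order.
#' @export
material_labels <- function() c("lung", "water", "bone")

#' Collision stopping power of water for positrons
#'
#' Mass collision stopping power of liquid water for positrons
#' (MeV cm^2/g), from the Berger-Seltzer closed form with the positron
#' stopping-number term (mean excitation energy 75 eV, Z/A = 0.55509,
#' density effect omitted). This is the tabulation that drives the
#' condensed-history transport; other media scale it by their electron
#' density relative to water. Clamped to the tabulated window
#' 10 keV - 3 MeV.
#'
#' @param T_MeV Kinetic energies, MeV.
#' @return Stopping power values, MeV cm^2/g.
#' @export
water_stopping_power <- function(T_MeV) {
  .cpp_sp_mass_water(as.numeric(T_MeV))
}
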