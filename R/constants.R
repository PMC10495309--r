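# Physical constants and nuclide data used throughout the package.
# All lengths are in micrometres (um), energies in MeV, doses in Gy,
# times in the unit stated by each function.

#' Particle range catalog
#'
#' CSDA-based particle ranges used to size the cell clusters: for
#' lutetium-177 the CSDA range of electrons at the average emission energy
#' (280 um, used for planar monolayers) or half of it (140 um, used for 3D
#' lattices to curb the cell count), and for actinium-225 the CSDA range of
#' an 8.5 MeV alpha particle in liquid water (86.53 um).
#'
#' @return Named list with elements `lu_range_2d`, `lu_range_3d`, `ac_range`
#'   (um).
#' @export
range_catalog <- function() {
  list(lu_range_2d = 280, lu_range_3d = 140, ac_range = 86.53)
}

#' Nuclide constants for source planning
#'
#' Physical half-lives and routine clinical activities of the two
#' radionuclides. The Lu-177 half-life defaults to 6.647 d, the value that
#' enters the activity scaling between the two therapies.
#'
#' @param nuclide `"Lu177"` or `"Ac225"`.
#' @return List with `half_life_days` and `clinical_activity_MBq`.
#' @export
nuclide_constants <- function(nuclide = c("Lu177", "Ac225")) {
  nuclide <- match.arg(nuclide)
  switch(nuclide,
    Lu177 = list(half_life_days = 6.647, clinical_activity_MBq = 7400),
    Ac225 = list(half_life_days = 9.92,  clinical_activity_MBq = 8)
  )
}

# Alpha energies (MeV) of the five alpha decays in the Ac-225 -> Bi-209 chain.
AC_ALPHA_ENERGIES <- c(5.8, 6.3, 7.1, 5.9, 8.4)

# Beta branches of Lu-177: (probability, maximum beta energy in keV).
LU_BETA_BRANCHES <- data.frame(
  prob = c(0.793, 0.1158, 0.091),
  e_max_keV = c(498, 177, 385)
)

# Gy deposited in the 4.65-um water nucleus per MeV of energy:
# 1 MeV = 1.602177e-13 J; nucleus mass = 1000 kg/m^3 * (4/3) pi (4.65e-6 m)^3.
NUCLEUS_RADIUS_UM <- 4.65
.nucleus_mass_kg <- 1000 * (4 / 3) * pi * (NUCLEUS_RADIUS_UM * 1e-6)^3
GY_PER_MEV <- 1.602177e-13 / .nucleus_mass_kg

#' Energy-to-dose conversion for the central nucleus
#'
#' Converts energy deposited in the spherical nucleus (radius 4.65 um,
#' liquid water) to absorbed dose.
#'
#' @param energy_MeV Deposited energy in MeV.
#' @return Absorbed dose in Gy.
#' @export
energy_to_dose <- function(energy_MeV) {
  stopifnot(all(energy_MeV >= 0))
  energy_MeV * GY_PER_MEV
}

# Simple deterministic seed mixer for hierarchical seed derivation
# (master -> condition -> run -> repetition). Keeps results < 2^31.
derive_seed <- function(seed, ...) {
  parts <- c(seed, unlist(lapply(list(...), function(x) {
    if (is.character(x)) sum(utf8ToInt(paste(x, collapse = ""))) else as.numeric(x)
  })))
  s <- 0
  for (p in parts) {
    s <- (s * 69069 + (as.numeric(p) %% 2147483647) + 12345) %% 2147483647
  }
  as.integer(s %% .Machine$integer.max)
}
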