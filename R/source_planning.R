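# Source planning: convert clinical (SPECT-derived) normalized activity
# concentrations to per-cell source-point numbers, scale Lu-177 numbers to
# Ac-225 via the clinical-activity ratio, and synthesize lesion cohorts.

#' Source points per cell from a normalized activity concentration
#'
#' Converts a lesion activity concentration at 24 h post-injection,
#' normalized per GBq injected, into the number of radionuclide source
#' points per cell using N = A * T_half / ln 2 (every nuclide in the cell
#' eventually decays; no excretion):
#' N_cell = (T_half / ln 2) * 1000 * conc * V_cell.
#'
#' @param norm_activity_conc Normalized activity concentration
#'   (kBq mL^-1 per GBq injected).
#' @param cell_volume Cell volume in mL (the catalog cells are about
#'   4.189e-9 mL).
#' @param half_life_s Physical half-life in seconds.
#' @return Real-valued number of source points per cell per GBq injected.
#' @examples
#' sources_per_cell(100, 4.189e-9, 6.647 * 86400)  # about 347
#' @export
sources_per_cell <- function(norm_activity_conc, cell_volume, half_life_s) {
  if (any(norm_activity_conc < 0) || any(cell_volume < 0) ||
      any(half_life_s < 0)) {
    stop("all inputs must be non-negative")
  }
  (half_life_s / log(2)) * 1000 * norm_activity_conc * cell_volume
}

#' Activity scaling factor from Lu-177 to Ac-225
#'
#' Ratio of decays per cell between the two therapies at their routine
#' clinical activities: (A_Lu * T_Lu) / (A_Ac * T_Ac) =
#' (7400 MBq * 6.647 d) / (8 MBq * 9.92 d), approximately 619.8. Per-cell
#' Ac-225 source numbers are the Lu-177 numbers divided by this factor.
#'
#' @param lu Constants for Lu-177, as from [nuclide_constants()].
#' @param ac Constants for Ac-225.
#' @return Dimensionless scaling factor.
#' @export
ac_scaling_factor <- function(lu = nuclide_constants("Lu177"),
                              ac = nuclide_constants("Ac225")) {
  denom <- ac$clinical_activity_MBq * ac$half_life_days
  if (denom == 0) stop("zero denominator in activity scaling")
  (lu$clinical_activity_MBq * lu$half_life_days) / denom
}

#' Per-cell source-count grids for the two nuclides
#'
#' The ten Lu-177 source numbers per cell spanning the clinically observed
#' range, and the corresponding Ac-225 numbers (Lu numbers divided by the
#' activity scaling factor of about 619.8, set to 1..10).
#'
#' @return List with integer vectors `lu_counts` and `ac_counts`.
#' @export
source_count_grid <- function() {
  list(
    lu_counts = c(100L, 300L, 500L, 700L, 900L, 1000L, 2000L, 3000L, 4000L, 5000L),
    ac_counts = 1:10
  )
}

#' Synthesize a SPECT-like lesion cohort
#'
#' Draws normalized lesion activity concentrations log-uniformly over a
#' range chosen so that, combined with the catalog cell volume through
#' [sources_per_cell()], the implied per-cell Lu-177 source numbers span
#' 100 to 5000. Lesion volumes are drawn log-uniformly between 1 and
#' 100 mL. A stand-in for the patient cohorts whose per-lesion values are
#' not published.
#'
#' @param n_lesions Number of lesions (>= 1).
#' @param rng_seed Optional integer seed.
#' @param conc_range Length-2 numeric, range of normalized activity
#'   concentration (kBq mL^-1 per GBq). Default spans per-cell counts
#'   100..5000 for a 4189 um^3 cell.
#' @return data.frame of class `lesion_cohort` with columns `label`,
#'   `norm_conc_kBq_per_mL_per_GBq`, `volume_mL`.
#' @export
synth_lesion_cohort <- function(n_lesions, rng_seed = NULL,
                                conc_range = default_conc_range()) {
  if (n_lesions < 1) stop("n_lesions must be >= 1")
  if (length(conc_range) != 2 || any(conc_range <= 0) ||
      conc_range[2] < conc_range[1]) {
    stop("conc_range must be a positive non-decreasing interval")
  }
  if (!is.null(rng_seed)) set.seed(rng_seed)
  conc <- exp(stats::runif(n_lesions, log(conc_range[1]), log(conc_range[2])))
  vol <- exp(stats::runif(n_lesions, log(1), log(100)))
  out <- data.frame(
    label = sprintf("lesion_%03d", seq_len(n_lesions)),
    norm_conc_kBq_per_mL_per_GBq = conc,
    volume_mL = vol
  )
  class(out) <- c("lesion_cohort", class(out))
  out
}

#' Default concentration range for synthetic cohorts
#'
#' Concentration interval whose endpoints map to per-cell Lu-177 counts of
#' exactly 100 and 5000 for the 4189 um^3 catalog cell.
#'
#' @return Length-2 numeric (kBq mL^-1 per GBq).
#' @export
default_conc_range <- function() {
  v_cell_mL <- (4 / 3) * pi * 10^3 * 1e-12  # geometry 1, um^3 -> mL
  t_s <- nuclide_constants("Lu177")$half_life_days * 86400
  per_conc <- sources_per_cell(1, v_cell_mL, t_s)
  c(100, 5000) / per_conc
}

#' Round a planned source count for simulation
#'
#' Planning values stay real; simulations need integer counts. Rounds
#' half away from zero.
#'
#' @param n Real-valued planned count(s).
#' @return Integer count(s).
#' @export
round_source_count <- function(n) {
  as.integer(sign(n) * floor(abs(n) + 0.5))
}
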