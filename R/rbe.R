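# Closed-form dose-dependent RBE of Ac-225 relative to Lu-177, isoeffect
# dose conversions, crossover dose, and delta-method uncertainty bands.
#
# With N_Lu(D) = a D^2 + b_lu D and N_Ac(D) = b_ac D (both through the
# origin), equating effects gives
#   RBE(D_Lu) = (b_ac/b_lu) / ((a/b_lu) D_Lu + 1)
#   RBE(D_Ac) = 2 b_ac / (sqrt(b_lu^2 + 4 a b_ac D_Ac) + b_lu)
# Both reduce to the constant b_ac/b_lu when a = 0 and at zero dose.

#' RBE model from fitted dose-effect parameters
#'
#' @param b_ac Linear slope of the Ac-225 dose-effect curve (DSB/Gy).
#' @param b_lu Linear coefficient of the Lu-177 curve (DSB/Gy).
#' @param a_lu Quadratic coefficient of the Lu-177 curve (DSB/Gy^2); 0 for
#'   initial-damage (linear) models.
#' @param b_ac_sd,b_lu_sd,a_lu_sd 1-sigma parameter uncertainties
#'   (optional, needed for uncertainty propagation).
#' @return Object of class `rbe_model`.
#' @examples
#' m <- rbe_model(152.99, 16.31, 1.21, 1.23, 0.81, 0.12)
#' rbe_vs_dose_lu(m, 0)    # 9.38
#' rbe_vs_dose_ac(m, 50)   # 1.46
#' crossover_dose(m)$dose  # 113 Gy
#' @export
rbe_model <- function(b_ac, b_lu, a_lu = 0,
                      b_ac_sd = NA_real_, b_lu_sd = NA_real_,
                      a_lu_sd = NA_real_) {
  stopifnot(b_ac > 0, b_lu > 0, a_lu >= 0)
  structure(list(b_ac = b_ac, b_lu = b_lu, a_lu = a_lu,
                 b_ac_sd = b_ac_sd, b_lu_sd = b_lu_sd, a_lu_sd = a_lu_sd),
            class = "rbe_model")
}

#' @export
print.rbe_model <- function(x, ...) {
  cat("RBE model: b_Ac = ", x$b_ac, ", b_Lu = ", x$b_lu, ", a_Lu = ", x$a_lu,
      "; RBE(0) = ", signif(x$b_ac / x$b_lu, 4), "\n", sep = "")
  invisible(x)
}

#' RBE as a function of the Lu-177 absorbed dose
#'
#' @param m An `rbe_model`.
#' @param d_lu Lu-177 absorbed dose to the nucleus (Gy), >= 0.
#' @return RBE value(s).
#' @export
rbe_vs_dose_lu <- function(m, d_lu) {
  stopifnot(inherits(m, "rbe_model"))
  if (any(d_lu < 0)) stop("dose must be >= 0")
  (m$b_ac / m$b_lu) / ((m$a_lu / m$b_lu) * d_lu + 1)
}

#' RBE as a function of the Ac-225 absorbed dose
#'
#' @param m An `rbe_model`.
#' @param d_ac Ac-225 absorbed dose to the nucleus (Gy), >= 0.
#' @return RBE value(s).
#' @export
rbe_vs_dose_ac <- function(m, d_ac) {
  stopifnot(inherits(m, "rbe_model"))
  if (any(d_ac < 0)) stop("dose must be >= 0")
  2 * m$b_ac / (sqrt(m$b_lu^2 + 4 * m$a_lu * m$b_ac * d_ac) + m$b_lu)
}

#' Isoeffect dose conversion between the two radiation qualities
#'
#' Maps a Lu-177 dose to the Ac-225 dose producing the same number of DSBs
#' (or vice versa):
#' lu_to_ac: (a/b_ac) d^2 + (b_lu/b_ac) d;
#' ac_to_lu: (sqrt(b_lu^2 + 4 a b_ac d) - b_lu) / (2 a), with the a -> 0
#' limit d b_ac / b_lu handled analytically.
#'
#' @param m An `rbe_model`.
#' @param dose Dose(s) to convert (Gy), >= 0.
#' @param direction `"lu_to_ac"` or `"ac_to_lu"`.
#' @return Converted dose(s) in Gy.
#' @export
dose_conversion <- function(m, dose, direction = c("lu_to_ac", "ac_to_lu")) {
  stopifnot(inherits(m, "rbe_model"))
  direction <- match.arg(direction)
  if (any(dose < 0)) stop("dose must be >= 0")
  if (direction == "lu_to_ac") {
    (m$a_lu / m$b_ac) * dose^2 + (m$b_lu / m$b_ac) * dose
  } else if (m$a_lu == 0) {
    dose * m$b_ac / m$b_lu
  } else {
    (sqrt(m$b_lu^2 + 4 * m$a_lu * m$b_ac * dose) - m$b_lu) / (2 * m$a_lu)
  }
}

#' Crossover dose at which RBE equals one
#'
#' D = (b_ac - b_lu) / a_lu, with a delta-method standard deviation under
#' independent parameter errors. Undefined (no crossover at finite dose)
#' when the Lu-177 curve is purely linear.
#'
#' @param m An `rbe_model` with `a_lu > 0` and `b_ac > b_lu`.
#' @return List with `dose` (Gy) and `sd` (Gy; NA when parameter
#'   uncertainties are absent).
#' @export
crossover_dose <- function(m) {
  stopifnot(inherits(m, "rbe_model"))
  if (m$a_lu == 0) stop("no finite crossover: the Lu-177 model is linear")
  if (m$b_ac < m$b_lu) stop("crossover requires b_ac > b_lu")
  d <- (m$b_ac - m$b_lu) / m$a_lu
  sd <- if (all(!is.na(c(m$b_ac_sd, m$b_lu_sd, m$a_lu_sd)))) {
    sqrt((m$b_ac_sd / m$a_lu)^2 + (m$b_lu_sd / m$a_lu)^2 +
           (d * m$a_lu_sd / m$a_lu)^2)
  } else NA_real_
  list(dose = d, sd = sd)
}

#' Delta-method uncertainty of RBE at a given dose
#'
#' First-order propagation of the fit-parameter uncertainties through the
#' RBE closed forms, treating the parameters as independent. At zero dose
#' this reduces to (b_ac/b_lu) sqrt((sd_ac/b_ac)^2 + (sd_lu/b_lu)^2).
#' Gradients are evaluated by central differences.
#'
#' @param m An `rbe_model` with parameter uncertainties.
#' @param dose Absorbed dose (Gy).
#' @param axis `"dose_lu"` or `"dose_ac"`: which dose scale `dose` refers
#'   to.
#' @return 1-sigma uncertainty of the RBE value.
#' @export
propagate_rbe_sigma <- function(m, dose, axis = c("dose_lu", "dose_ac")) {
  stopifnot(inherits(m, "rbe_model"))
  axis <- match.arg(axis)
  sds <- c(m$b_ac_sd, m$b_lu_sd, if (m$a_lu > 0) m$a_lu_sd else 0)
  if (any(is.na(sds))) stop("parameter uncertainties are required")
  f <- function(theta) {
    mm <- rbe_model(theta[1], theta[2], max(theta[3], 0))
    if (axis == "dose_lu") rbe_vs_dose_lu(mm, dose) else rbe_vs_dose_ac(mm, dose)
  }
  theta <- c(m$b_ac, m$b_lu, m$a_lu)
  grad <- vapply(1:3, function(i) {
    h <- max(1e-6, 1e-6 * abs(theta[i]))
    tp <- tm <- theta
    tp[i] <- tp[i] + h
    tm[i] <- max(tm[i] - h, if (i == 3) 0 else tm[i] - h)
    (f(tp) - f(tm)) / (tp[i] - tm[i])
  }, numeric(length(dose)))
  grad <- matrix(grad, nrow = length(dose))
  sqrt(as.vector(grad^2 %*% sds^2))
}

#' RBE curve on a dose grid
#'
#' Evaluates RBE (and, when parameter uncertainties are present, its
#' delta-method sigma) on a dose grid along either dose axis.
#'
#' @param m An `rbe_model`.
#' @param doses Dose grid (Gy); default 0..50 Gy in 501 points.
#' @param axis `"dose_lu"` or `"dose_ac"`.
#' @return data.frame with `dose_Gy`, `rbe`, `rbe_sigma`.
#' @export
rbe_curve <- function(m, doses = seq(0, 50, length.out = 501),
                      axis = c("dose_lu", "dose_ac")) {
  axis <- match.arg(axis)
  rbe <- if (axis == "dose_lu") rbe_vs_dose_lu(m, doses) else rbe_vs_dose_ac(m, doses)
  sig <- if (all(!is.na(c(m$b_ac_sd, m$b_lu_sd)))) {
    propagate_rbe_sigma(m, doses, axis)
  } else NA_real_
  data.frame(dose_Gy = doses, rbe = rbe, rbe_sigma = sig)
}
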