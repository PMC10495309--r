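# Dose-effect fitting: N_DSB(D) through the origin, linear or
# linear-quadratic, with parameter uncertainties and R^2.

#' Model choice per nuclide and damage stage
#'
#' High-LET Ac-225 damage is linear in dose at both stages; Lu-177 initial
#' damage is fitted linearly (the quadratic term is null or unstable),
#' while Lu-177 post-repair damage is linear-quadratic.
#'
#' @param nuclide `"Lu177"` or `"Ac225"`.
#' @param stage `"initial"` or `"post_repair"`.
#' @return `"linear"` or `"linear_quadratic"`.
#' @export
select_model <- function(nuclide = c("Lu177", "Ac225"),
                         stage = c("initial", "post_repair")) {
  nuclide <- match.arg(nuclide)
  stage <- match.arg(stage)
  if (nuclide == "Lu177" && stage == "post_repair") "linear_quadratic" else "linear"
}

#' Fit a dose-effect curve through the origin
#'
#' Unweighted least squares with no intercept: N = b D (linear) or
#' N = a D^2 + b D (linear-quadratic). Parameter standard errors come from
#' the estimator covariance. For the linear-quadratic model the quadratic
#' coefficient is bounded below by zero by default (refit with a = 0 when
#' the unconstrained estimate is negative). R^2 uses the centered total sum
#' of squares.
#'
#' @param dose Numeric vector of absorbed doses (Gy), all >= 0.
#' @param n_dsb Numeric vector of DSB counts.
#' @param model `"linear"` or `"linear_quadratic"`.
#' @param bound_a Logical; enforce a >= 0 in the linear-quadratic fit.
#' @return Object of class `dose_effect_fit` with `model`, `b`, `b_sd`,
#'   `a`, `a_sd`, `cov_ab`, `r_squared`, `n_points`.
#' @examples
#' d <- rep(1:5, each = 3)
#' fit_dose_effect(d, 160 * d, "linear")
#' @export
fit_dose_effect <- function(dose, n_dsb,
                            model = c("linear", "linear_quadratic"),
                            bound_a = TRUE) {
  model <- match.arg(model)
  stopifnot(length(dose) == length(n_dsb))
  if (length(dose) < 3) stop("need at least 3 points to fit")
  if (any(dose < 0)) stop("doses must be >= 0")
  if (length(unique(dose)) < 2) stop("degenerate design: all doses equal")

  if (model == "linear") {
    fit <- stats::lm(n_dsb ~ 0 + dose)
    b <- unname(stats::coef(fit)[1])
    b_sd <- sqrt(stats::vcov(fit)[1, 1])
    a <- 0; a_sd <- NA_real_; cov_ab <- NA_real_
    res <- stats::residuals(fit)
  } else {
    dose2 <- dose^2
    fit <- stats::lm(n_dsb ~ 0 + dose + dose2)
    cf <- stats::coef(fit)
    if (bound_a && cf["dose2"] < 0) {
      # boundary solution: quadratic term pinned at zero
      fit_l <- stats::lm(n_dsb ~ 0 + dose)
      b <- unname(stats::coef(fit_l)[1])
      b_sd <- sqrt(stats::vcov(fit_l)[1, 1])
      a <- 0
      a_sd <- sqrt(stats::vcov(fit)["dose2", "dose2"])
      cov_ab <- 0
      res <- stats::residuals(fit_l)
    } else {
      v <- stats::vcov(fit)
      b <- unname(cf["dose"]); a <- unname(cf["dose2"])
      b_sd <- sqrt(v["dose", "dose"]); a_sd <- sqrt(v["dose2", "dose2"])
      cov_ab <- v["dose", "dose2"]
      res <- stats::residuals(fit)
    }
  }
  ss_res <- sum(res^2)
  ss_tot <- sum((n_dsb - mean(n_dsb))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  structure(list(model = model, b = b, b_sd = b_sd, a = a, a_sd = a_sd,
                 cov_ab = cov_ab, r_squared = r2, n_points = length(dose)),
            class = "dose_effect_fit")
}

#' @export
print.dose_effect_fit <- function(x, ...) {
  cat("Dose-effect fit (", x$model, ", through origin, n = ", x$n_points,
      ")\n  b = ", signif(x$b, 5), " +- ", signif(x$b_sd, 3),
      " DSB/Gy\n", sep = "")
  if (x$model == "linear_quadratic") {
    cat("  a = ", signif(x$a, 5),
        if (!is.na(x$a_sd)) paste0(" +- ", signif(x$a_sd, 3)),
        " DSB/Gy^2\n", sep = "")
  }
  cat("  R^2 = ", signif(x$r_squared, 4), "\n", sep = "")
  invisible(x)
}
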