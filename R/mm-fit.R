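# Michaelis-Menten parameter estimation from initial-rate tables, by the
# classical double-reciprocal (Lineweaver-Burk) line and by direct nonlinear
# least squares on v = Vmax*S/(Km+S).

#' Pseudo-initial rate from an endpoint assay
#'
#' Product formed over a short fixed assay divided by its duration. This is
#' the usual endpoint approximation to the initial rate; it is biased low
#' when a noticeable substrate fraction is consumed within the assay.
#'
#' @param product_mM Product formed by the end of the assay, mM (vectorised).
#' @param duration_min Assay duration, minutes.
#' @return Rate in mM per minute.
#' @examples
#' initial_rate(2.0, 5) # 0.4 mM/min
#' @export
initial_rate <- function(product_mM, duration_min) {
  if (any(product_mM < 0)) abort("initial_rate(): product must be non-negative.")
  if (duration_min <= 0) abort("initial_rate(): duration must be positive.")
  product_mM / duration_min
}

#' Double-reciprocal (Lineweaver-Burk) Michaelis-Menten fit
#'
#' Unweighted least-squares line of 1/v on 1/S; `Km = slope/intercept`,
#' `Vmax = 1/intercept`. Standard errors for Km and Vmax are obtained from
#' the regression coefficients by the delta method.
#'
#' @param data Data frame with columns `S_mM` and `v_mM_per_min`, at least
#'   3 points, all rates strictly positive.
#' @param E0 Optional enzyme concentration, uM; when given, `kcat` and
#'   `kcat/Km` are derived via [kcat_from_vmax()].
#' @return An object of class `mm_fit`.
#' @examples
#' d <- data.frame(S_mM = c(1, 2, 5, 10, 20, 40))
#' d$v_mM_per_min <- 0.4335 * d$S_mM / (3.69 + d$S_mM)
#' fit_double_reciprocal(d, E0 = 1.7)
#' @export
fit_double_reciprocal <- function(data, E0 = NULL) {
  d <- check_rate_data(data)
  if (any(d$v_mM_per_min <= 0)) {
    abort("fit_double_reciprocal(): all rates must be > 0 (reciprocals undefined otherwise); use fit_mm_nonlinear() for data containing zero rates.")
  }
  x <- 1 / d$S_mM; y <- 1 / d$v_mM_per_min
  if (length(unique(x)) < 2) {
    abort("fit_double_reciprocal(): singular regression; need at least two distinct substrate concentrations.")
  }
  fit <- lm(y ~ x)
  a <- coef(fit)[["(Intercept)"]]; b <- coef(fit)[["x"]]
  if (a <= 0) {
    abort("fit_double_reciprocal(): non-positive intercept; the data are inconsistent with saturation kinetics.")
  }
  V <- suppressWarnings(vcov(fit)) # summary.lm warns on numerically perfect fits
  # Vmax = 1/a, Km = b/a; delta method
  se_Vmax <- sqrt(V[1, 1]) / a^2
  g <- c(-b / a^2, 1 / a)
  se_Km <- sqrt(drop(t(g) %*% V %*% g))
  new_mm_fit(Km = b / a, Vmax = 1 / a, se_Km = se_Km, se_Vmax = se_Vmax,
             method = "double_reciprocal", data = d, E0 = E0)
}

#' Nonlinear least-squares Michaelis-Menten fit
#'
#' Direct Levenberg-Marquardt fit of `v = Vmax * S / (Km + S)`, initialised
#' from the double-reciprocal estimate when that is available (otherwise from
#' a crude heuristic). On noiseless data the two fitters agree to numerical
#' precision; under noise the direct fit is the statistically better one.
#'
#' @inheritParams fit_double_reciprocal
#' @param start Optional list with `Km` and `Vmax` starting values.
#' @return An object of class `mm_fit`.
#' @export
fit_mm_nonlinear <- function(data, E0 = NULL, start = NULL) {
  d <- check_rate_data(data)
  if (length(unique(d$S_mM)) < 3) {
    abort("fit_mm_nonlinear(): need at least 3 distinct substrate concentrations.")
  }
  if (is.null(start)) {
    start <- tryCatch({
      dr <- fit_double_reciprocal(d)
      list(Km = dr$Km, Vmax = dr$Vmax)
    }, error = function(e) {
      list(Km = stats::median(d$S_mM), Vmax = max(d$v_mM_per_min) * 1.2)
    })
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v_mM_per_min ~ Vmax * S_mM / (Km + S_mM),
      data = d, start = start,
      lower = c(Vmax = 0, Km = 1e-12),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14, ptol = 1e-14)
    ),
    error = function(e) {
      abort(sprintf(
        "fit_mm_nonlinear(): did not converge from start Km = %g, Vmax = %g (%s).",
        start$Km, start$Vmax, conditionMessage(e)
      ))
    }
  )
  est <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(Vmax = NA_real_, Km = NA_real_))
  new_mm_fit(Km = est[["Km"]], Vmax = est[["Vmax"]],
             se_Km = unname(se["Km"]), se_Vmax = unname(se["Vmax"]),
             method = "nonlinear", data = d, E0 = E0)
}

#' Turnover number from Vmax and enzyme concentration
#'
#' `kcat = Vmax / E0` in consistent units: Vmax (mM/min) is converted to mM/s
#' and E0 (uM) to mM.
#'
#' @param Vmax Maximal rate, mM per minute.
#' @param E0 Enzyme concentration, uM.
#' @return kcat in per second.
#' @examples
#' kcat_from_vmax(0.4335, 1.7) # 4.25 /s
#' @export
kcat_from_vmax <- function(Vmax, E0) {
  if (any(Vmax < 0)) abort("kcat_from_vmax(): Vmax must be non-negative.")
  if (any(E0 <= 0)) abort("kcat_from_vmax(): E0 must be positive.")
  per_min_to_per_s(Vmax) / uM_to_mM(E0)
}

#' Specific enzyme activity
#'
#' One activity unit (U) is the amount of enzyme producing 1 umol of product
#' per minute under assay conditions; specific activity is units per mg of
#' enzyme.
#'
#' @param rate_umol_min Product formation rate, umol per minute.
#' @param mass_mg Enzyme mass in the assay, mg.
#' @return Specific activity, U per mg.
#' @examples
#' activity_units(0.5, 0.025) # 20 U/mg
#' @export
activity_units <- function(rate_umol_min, mass_mg) {
  if (any(rate_umol_min < 0)) abort("activity_units(): rate must be non-negative.")
  if (any(mass_mg <= 0)) abort("activity_units(): enzyme mass must be positive.")
  rate_umol_min / mass_mg
}

new_mm_fit <- function(Km, Vmax, se_Km, se_Vmax, method, data, E0) {
  kcat <- if (!is.null(E0)) kcat_from_vmax(Vmax, E0) else NA_real_
  pred <- Vmax * data$S_mM / (Km + data$S_mM)
  ss_tot <- sum((data$v_mM_per_min - mean(data$v_mM_per_min))^2)
  r2 <- if (ss_tot > 0) 1 - sum((data$v_mM_per_min - pred)^2) / ss_tot else NA_real_
  structure(
    list(Km = Km, Vmax = Vmax, se_Km = se_Km, se_Vmax = se_Vmax,
         kcat = kcat, kcat_over_Km = kcat / Km,
         E0 = if (is.null(E0)) NA_real_ else E0,
         method = method, r_squared = r2, data = data),
    class = "mm_fit"
  )
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("<mm_fit> method = %s, n = %d\n", x$method, nrow(x$data)))
  cat(sprintf("  Km   = %g mM (se %g)\n", x$Km, x$se_Km))
  cat(sprintf("  Vmax = %g mM/min (se %g)\n", x$Vmax, x$se_Vmax))
  if (!is.na(x$kcat)) {
    cat(sprintf("  kcat = %g /s, kcat/Km = %g /s/mM (E0 = %g uM)\n",
                x$kcat, x$kcat_over_Km, x$E0))
  }
  invisible(x)
}

check_rate_data <- function(data) {
  stopifnot(is.data.frame(data))
  missing <- setdiff(c("S_mM", "v_mM_per_min"), names(data))
  if (length(missing) > 0) {
    abort(paste0("Rate data must have columns S_mM and v_mM_per_min; missing: ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(data) < 3) abort("Rate data need at least 3 points.")
  if (any(data$S_mM <= 0)) abort("S_mM must be positive.")
  if (any(data$v_mM_per_min < 0)) abort("v_mM_per_min must be non-negative.")
  as_tibble(data[, c("S_mM", "v_mM_per_min")])
}
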