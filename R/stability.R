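# Catalytic-stability pipeline: polynomial fit of product vs time,
# differentiation to instantaneous activity, normalisation to residual
# activity, first-order decay fit, half-life and empirical TTN.

#' Fit a zero-intercept polynomial to a progress curve
#'
#' Least-squares polynomial of product (mM) against time (min) with the
#' intercept constrained to 0 (no product before the reaction starts).
#'
#' @param data Data frame with columns `time_min` and `product_mM`.
#' @param degree Polynomial degree, 2-5. The number of points with `t > 0`
#'   must exceed... must be at least `degree`.
#' @return An object of class `progress_poly`: coefficients `c1..cdegree`
#'   (so that P(t) = c1 t + c2 t^2 + ...), `r_squared` (NA when the data are
#'   all zero), `degree` and the fitted time range.
#' @examples
#' d <- data.frame(time_min = c(0, 5, 10, 20, 30), product_mM = 2 * c(0, 5, 10, 20, 30))
#' fit_progress_polynomial(d, degree = 3)
#' @export
fit_progress_polynomial <- function(data, degree = 3) {
  d <- check_progress_data(data)
  if (degree < 2 || degree > 5 || degree != round(degree)) {
    abort("degree must be an integer between 2 and 5.")
  }
  n_pos <- sum(d$time_min > 0)
  if (n_pos < degree) {
    abort(sprintf(
      "Underdetermined fit: degree %d needs at least %d points with t > 0, got %d.",
      degree, degree, n_pos
    ))
  }
  X <- outer(d$time_min, seq_len(degree), `^`)
  fit <- lm.fit(X, d$product_mM)
  coefs <- setNames(fit$coefficients, paste0("c", seq_len(degree)))
  coefs[is.na(coefs)] <- 0
  ss_tot <- sum((d$product_mM - mean(d$product_mM))^2)
  r2 <- if (all(d$product_mM == 0) || ss_tot == 0) NA_real_
        else 1 - sum(fit$residuals^2) / ss_tot
  structure(
    list(coefficients = coefs, degree = degree, r_squared = r2,
         t_max = max(d$time_min), data = d),
    class = "progress_poly"
  )
}

#' @export
print.progress_poly <- function(x, ...) {
  cat(sprintf("<progress_poly> degree %d, R^2 = %s\n", x$degree,
              format(x$r_squared, digits = 4)))
  print(x$coefficients)
  invisible(x)
}

#' Instantaneous activity from a fitted progress polynomial
#'
#' Analytic derivative of the fitted polynomial, i.e. the product-formation
#' rate at time `t`. Extrapolation beyond the fitted time range is refused:
#' polynomial derivatives are meaningless outside the data.
#'
#' @param fit A `progress_poly` from [fit_progress_polynomial()].
#' @param t Times in minutes, each within `[0, max fitted time]`.
#' @return Activity in mM per minute.
#' @export
instantaneous_activity <- function(fit, t) {
  stopifnot(inherits(fit, "progress_poly"))
  if (any(t < 0) || any(t > fit$t_max)) {
    abort(sprintf(
      "instantaneous_activity(): t must lie in [0, %g] min (the fitted range); extrapolation refused.",
      fit$t_max
    ))
  }
  co <- fit$coefficients
  k <- seq_along(co)
  vapply(t, function(tt) sum(co * k * tt^(k - 1)), numeric(1))
}

#' Residual activity series
#'
#' Instantaneous activity expressed as a percentage of the t = 0 activity,
#' which is defined as 100 %. Negative fitted derivatives (a polynomial
#' artefact at late times) are clipped to 0 with a warning.
#'
#' @param fit A `progress_poly`.
#' @param t_grid Evaluation times, minutes, within the fitted range.
#' @return Tibble with `time_min`, `activity_mM_min`, `residual_pct`.
#' @export
residual_activity <- function(fit, t_grid) {
  act <- instantaneous_activity(fit, t_grid)
  a0 <- instantaneous_activity(fit, 0)
  if (a0 <= 0) {
    abort("residual_activity(): the fitted initial activity is not positive; cannot normalise to 100 %.")
  }
  pct <- 100 * act / a0
  if (any(pct < 0)) {
    warn("Negative fitted activity clipped to 0 (polynomial artefact at late times).")
    pct <- pmax(pct, 0)
  }
  tibble(time_min = t_grid, activity_mM_min = act, residual_pct = pct)
}

#' Fit a first-order decay to a residual-activity series
#'
#' Least-squares fit of `100 * exp(-lambda * t)` to residual activity,
#' treating mechanism-based inactivation as first order in time while the
#' enzyme is substrate-saturated. The half-life is read off the fitted curve
#' as `ln(2)/lambda`.
#'
#' @param data Data frame with columns `time_min` and `residual_pct`; at
#'   least 3 points, the first being (0, 100).
#' @return A list of class `inactivation_fit`: `lambda_per_min`,
#'   `half_life_min` (`Inf` when `lambda` is 0), `kinact_per_s`
#'   (`lambda` converted to per second, for comparison with rate constants
#'   quoted in s^-1), and the sum of squared residuals `ssr`.
#' @examples
#' t <- c(0, 10, 20, 30)
#' fit_inactivation(data.frame(time_min = t, residual_pct = 100 * exp(-0.0387 * t)))
#' @export
fit_inactivation <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("time_min", "residual_pct") %in% names(data)))
  t <- data$time_min; r <- data$residual_pct
  if (length(t) < 3) abort("fit_inactivation(): need at least 3 points.")
  if (t[1] != 0 || abs(r[1] - 100) > 1e-8) {
    abort("fit_inactivation(): the first point must be (0, 100).")
  }
  if (all(r[-1] <= 0)) {
    abort("fit_inactivation(): all residuals beyond t = 0 are <= 0; the fit is degenerate. Trim the series to the informative early window.")
  }
  obj <- function(l) sum((r - 100 * exp(-l * t))^2)
  # log-linear pre-estimate fixes the scale of the decay; the golden-section
  # search needs a bracket that is not orders of magnitude too wide
  pos <- which(t > 0 & r > 0)
  lam0 <- if (length(pos) >= 2) {
    max(-coef(lm.fit(cbind(t[pos]), log(r[pos] / 100)))[1], 0)
  } else 0
  hi <- max(10 * lam0, 1e-4)
  opt <- optimize(obj, interval = c(0, hi), tol = 1e-12)
  lambda <- opt$minimum
  # snap to zero when a flat series fits (numerically) at least as well
  if (obj(0) <= opt$objective + 1e-12) lambda <- 0
  structure(
    list(
      lambda_per_min = lambda,
      half_life_min = if (lambda > 0) log(2) / lambda else Inf,
      kinact_per_s = per_min_to_per_s(lambda),
      ssr = obj(lambda),
      data = as_tibble(data)
    ),
    class = "inactivation_fit"
  )
}

#' @export
print.inactivation_fit <- function(x, ...) {
  cat(sprintf(
    "<inactivation_fit> lambda = %g /min (%g /s), half-life = %g min\n",
    x$lambda_per_min, x$kinact_per_s, x$half_life_min
  ))
  invisible(x)
}

#' Full catalytic-stability pipeline for one progress curve
#'
#' Runs the whole chain: polynomial fit of product vs time, analytic
#' differentiation to instantaneous activity, normalisation to residual
#' activity (100 % at t = 0), and a first-order decay fit giving the decay
#' constant, half-life and the inactivation rate in s^-1.
#'
#' @param data Data frame with columns `time_min`, `product_mM` and
#'   optionally `label`.
#' @param degree Polynomial degree passed to [fit_progress_polynomial()].
#' @param eval_times Times at which residual activity is evaluated before the
#'   decay fit; defaults to the observed time points. Keep the span within
#'   roughly two half-lives: polynomial differentiation degrades beyond that.
#' @return An object of class `stability_fit` bundling the polynomial fit,
#'   the residual-activity series and the decay fit. Use [tidy()]/[glance()]
#'   for tabular summaries and [autoplot()] for the stability curve.
#' @examples
#' wt <- kinetic_params(3.69, 4.25, 0.0007)
#' d <- simulate_progress(wt, reaction_conditions(1.7, 40), seq(0, 30, 5))
#' fit_stability(data.frame(time_min = d$time_min, product_mM = d$P_mM))
#' @export
fit_stability <- function(data, degree = 3, eval_times = NULL) {
  d <- check_progress_data(data)
  poly <- fit_progress_polynomial(d, degree = degree)
  if (is.null(eval_times)) eval_times <- d$time_min
  res <- residual_activity(poly, eval_times)
  dec <- fit_inactivation(res[, c("time_min", "residual_pct")])
  structure(
    list(
      label = if ("label" %in% names(data)) data$label[1] else NA_character_,
      poly = poly,
      residual = res,
      decay = dec,
      lambda_per_min = dec$lambda_per_min,
      half_life_min = dec$half_life_min,
      kinact_per_s = dec$kinact_per_s
    ),
    class = "stability_fit"
  )
}

#' @export
print.stability_fit <- function(x, ...) {
  cat("<stability_fit>", if (!is.na(x$label)) x$label else "", "\n")
  cat(sprintf("  polynomial degree %d (R^2 = %s)\n",
              x$poly$degree, format(x$poly$r_squared, digits = 4)))
  cat(sprintf("  decay constant = %g /min  (%g /s)\n",
              x$lambda_per_min, x$kinact_per_s))
  cat(sprintf("  half-life = %g min\n", x$half_life_min))
  invisible(x)
}

#' Empirical total turnover number from a plateaued conversion
#'
#' Moles of product formed per mole of enzyme once the conversion has
#' plateaued: the operational, assay-side counterpart of the model-based
#' [partition_ratio()].
#'
#' @param data Data frame with `time_min`, `product_mM`, plateaued at the end.
#' @param cond A [reaction_conditions()] object supplying E0.
#' @param plateau_tol Maximum relative change between the last two product
#'   values for the curve to count as plateaued (default 2 %).
#' @param force Set TRUE to compute from the last point even without a
#'   detected plateau.
#' @return Dimensionless turnover number.
#' @examples
#' wt <- kinetic_params(3.69, 4.25, 0.0011)
#' cond <- reaction_conditions(1.7, 40)
#' d <- simulate_progress(wt, cond, seq(0, 120, 5))
#' empirical_ttn(data.frame(time_min = d$time_min, product_mM = d$P_mM), cond)
#' @export
empirical_ttn <- function(data, cond, plateau_tol = 0.02, force = FALSE) {
  d <- check_progress_data(data)
  stopifnot(inherits(cond, "reaction_conditions"))
  n <- nrow(d)
  p_last <- d$product_mM[n]
  if (p_last <= 0) abort("empirical_ttn(): no product formed.")
  rel_change <- abs(p_last - d$product_mM[n - 1]) / p_last
  if (rel_change >= plateau_tol && !force) {
    abort(sprintf(
      "No plateau: the last two points differ by %.1f %% (tolerance %.1f %%). Extend the assay/simulation or set force = TRUE.",
      100 * rel_change, 100 * plateau_tol
    ))
  }
  # mol product / mol enzyme == (mM product)/(mM enzyme) in the same volume
  p_last / uM_to_mM(cond$E0)
}

check_progress_data <- function(data) {
  stopifnot(is.data.frame(data))
  missing <- setdiff(c("time_min", "product_mM"), names(data))
  if (length(missing) > 0) {
    abort(paste0("Progress data must have columns time_min and product_mM; missing: ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(data) < 3) abort("Progress data need at least 3 points.")
  if (any(diff(data$time_min) <= 0)) abort("time_min must be strictly increasing.")
  if (any(data$product_mM < 0)) abort("product_mM must be non-negative.")
  as_tibble(data[, intersect(c("time_min", "product_mM", "label"), names(data))])
}
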