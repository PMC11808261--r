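# broom-style tidiers and ggplot2 autoplot methods for fitted objects.

#' Tidy a Michaelis-Menten fit
#'
#' @param x An `mm_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`,
#'   `std.error`.
#' @exportS3Method generics::tidy
tidy.mm_fit <- function(x, ...) {
  tibble(
    term = c("Km", "Vmax"),
    estimate = c(x$Km, x$Vmax),
    std.error = c(x$se_Km, x$se_Vmax)
  )
}

#' One-row summary of a Michaelis-Menten fit
#'
#' @inheritParams tidy.mm_fit
#' @return A one-row tibble: `Km`, `Vmax`, `kcat`, `kcat_over_Km`,
#'   `r.squared`, `method`, `nobs`.
#' @exportS3Method generics::glance
glance.mm_fit <- function(x, ...) {
  tibble(
    Km = x$Km, Vmax = x$Vmax, kcat = x$kcat, kcat_over_Km = x$kcat_over_Km,
    r.squared = x$r_squared, method = x$method, nobs = nrow(x$data)
  )
}

#' Plot a Michaelis-Menten fit
#'
#' Rate data with the fitted saturation curve.
#'
#' @param object An `mm_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.mm_fit <- function(object, ...) {
  grid <- tibble(S_mM = seq(0, max(object$data$S_mM), length.out = 200))
  grid$v <- object$Vmax * grid$S_mM / (object$Km + grid$S_mM)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$S_mM, y = .data$v_mM_per_min)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$v), colour = "steelblue") +
    ggplot2::labs(
      x = "Substrate (mM)", y = "Initial rate (mM/min)",
      title = sprintf("Michaelis-Menten fit (%s): Km = %.2f mM, Vmax = %.3f mM/min",
                      object$method, object$Km, object$Vmax)
    )
}

#' Tidy a catalytic-stability fit
#'
#' @param x A `stability_fit` object.
#' @param ... Unused.
#' @return A tibble of the fitted quantities, one row per term (polynomial
#'   coefficients and the decay constant).
#' @exportS3Method generics::tidy
tidy.stability_fit <- function(x, ...) {
  tibble(
    term = c(names(x$poly$coefficients), "lambda"),
    estimate = c(unname(x$poly$coefficients), x$lambda_per_min),
    unit = c(paste0("mM/min^", seq_along(x$poly$coefficients)), "1/min")
  )
}

#' One-row summary of a catalytic-stability fit
#'
#' @inheritParams tidy.stability_fit
#' @return A one-row tibble: `lambda_per_min`, `half_life_min`,
#'   `kinact_per_s`, `poly_degree`, `poly_r_squared`, `label`.
#' @exportS3Method generics::glance
glance.stability_fit <- function(x, ...) {
  tibble(
    lambda_per_min = x$lambda_per_min,
    half_life_min = x$half_life_min,
    kinact_per_s = x$kinact_per_s,
    poly_degree = x$poly$degree,
    poly_r_squared = x$poly$r_squared,
    label = x$label
  )
}

#' Plot a catalytic-stability curve
#'
#' Residual-activity points with the fitted first-order decay.
#'
#' @param object A `stability_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.stability_fit <- function(object, ...) {
  res <- object$residual
  grid <- tibble(time_min = seq(0, max(res$time_min), length.out = 200))
  grid$fit <- 100 * exp(-object$lambda_per_min * grid$time_min)
  ggplot2::ggplot(res, ggplot2::aes(x = .data$time_min, y = .data$residual_pct)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fit), colour = "firebrick") +
    ggplot2::labs(
      x = "Time (min)", y = "Residual activity (%)",
      title = sprintf("Catalytic stability: half-life %.1f min",
                      object$half_life_min)
    )
}

#' Plot a hydropathy profile
#'
#' Windowed Kyte-Doolittle scores along the sequence with the hydrophilicity
#' threshold marked; optionally highlights regions of interest.
#'
#' @param profile A tibble from [kd_profile()].
#' @param regions Optional data frame with `start`, `end` (1-based) columns
#'   to shade.
#' @return A ggplot object.
#' @export
plot_hydropathy <- function(profile, regions = NULL) {
  thr <- attr(profile, "threshold") %||% -0.5
  p <- ggplot2::ggplot(profile, ggplot2::aes(x = .data$position, y = .data$score))
  if (!is.null(regions)) {
    p <- p + ggplot2::geom_rect(
      data = as_tibble(regions), inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = -Inf, ymax = Inf, fill = "grey85"
    )
  }
  p +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "Residue position", y = "Kyte-Doolittle score",
                  title = sprintf("Hydropathy profile (window %d)",
                                  attr(profile, "window") %||% NA))
}
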