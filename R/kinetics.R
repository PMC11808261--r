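# Turnover-coupled (mechanism-based) inactivation model.
#
# The enzyme follows Michaelis-Menten turnover, and a small fraction of
# catalytic cycles ends in irreversible loss of the active site (for
# pyruvoyl-dependent ADC, misprotonation of the imine intermediate converts
# the pyruvoyl cofactor to an inactive alanyl group). Because inactivation is
# a side branch of turnover, its rate carries the same saturation factor
# S/(Km+S) as product formation:
#
#   dP/dt  = +kcat * Ea * S/(Km+S)
#   dS/dt  = -kcat * Ea * S/(Km+S)
#   dEa/dt = -kinact * Ea * S/(Km+S)
#
# Two exact consequences are used as invariants throughout: S + P = S0, and
# Ea = E0 - (kinact/kcat) * P (the two rates share the saturation factor, so
# their ratio is constant).

#' Kinetic parameters of one enzyme variant
#'
#' Bundles the Michaelis constant, turnover number and mechanism-based
#' inactivation rate constant of a variant.
#'
#' @param Km Michaelis constant, mM. Must be > 0.
#' @param kcat Turnover rate constant, per second. Must be > 0.
#' @param kinact Inactivation rate constant, per second. Must be >= 0;
#'   0 means a perfectly stable catalyst.
#' @param label Optional variant name.
#' @return An object of class `kinetic_params`.
#' @examples
#' kinetic_params(Km = 3.69, kcat = 4.25, kinact = 0.0011, label = "wt")
#' @export
kinetic_params <- function(Km, kcat, kinact = 0, label = NULL) {
  check_scalar(Km, "Km", strict = TRUE)
  check_scalar(kcat, "kcat", strict = TRUE)
  check_scalar(kinact, "kinact", strict = FALSE)
  structure(
    list(Km = Km, kcat = kcat, kinact = kinact, label = label),
    class = "kinetic_params"
  )
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("<kinetic_params>", if (!is.null(x$label)) x$label else "", "\n")
  cat(sprintf("  Km = %g mM, kcat = %g /s, kinact = %g /s\n",
              x$Km, x$kcat, x$kinact))
  if (x$kinact > 0) {
    cat(sprintf("  partition ratio kcat/kinact = %g turnovers\n",
                x$kcat / x$kinact))
  }
  invisible(x)
}

#' Reaction conditions
#'
#' Initial concentrations for a batch conversion; temperature and pH are
#' carried as annotations only.
#'
#' @param E0 Total active enzyme at t = 0, uM. Must be > 0.
#' @param S0 Initial substrate, mM. Must be > 0.
#' @param temperature_C,pH Annotations; no computation depends on them.
#' @return An object of class `reaction_conditions`.
#' @examples
#' reaction_conditions(E0 = 1.7, S0 = 40)
#' @export
reaction_conditions <- function(E0, S0, temperature_C = 37, pH = 7.0) {
  check_scalar(E0, "E0", strict = TRUE)
  check_scalar(S0, "S0", strict = TRUE)
  structure(
    list(E0 = E0, S0 = S0, temperature_C = temperature_C, pH = pH),
    class = "reaction_conditions"
  )
}

#' @export
print.reaction_conditions <- function(x, ...) {
  cat(sprintf("<reaction_conditions> E0 = %g uM, S0 = %g mM (%g C, pH %g)\n",
              x$E0, x$S0, x$temperature_C, x$pH))
  invisible(x)
}

#' Michaelis-Menten velocity
#'
#' Instantaneous product-formation rate `kcat * Ea * S / (Km + S)`, with the
#' enzyme concentration converted from uM to mM so the result is in mM/s.
#'
#' @param params A [kinetic_params()] object.
#' @param Ea Active enzyme concentration, uM (vectorised).
#' @param S Substrate concentration, mM (vectorised).
#' @return Rate in mM per second.
#' @examples
#' wt <- kinetic_params(3.69, 4.25, 0.0011)
#' mm_velocity(wt, Ea = 1.7, S = 40)
#' @export
mm_velocity <- function(params, Ea, S) {
  stopifnot(inherits(params, "kinetic_params"))
  if (any(Ea < 0) || any(S < 0)) {
    abort("mm_velocity(): Ea and S must be non-negative.")
  }
  params$kcat * uM_to_mM(Ea) * S / (params$Km + S)
}

#' Simulate a progress curve under turnover-coupled inactivation
#'
#' Integrates the model ODEs with an adaptive solver (lsoda, relative
#' tolerance 1e-8). By default inactivation is coupled to turnover (rate
#' factor S/(Km+S)); `coupling = "first_order"` switches to plain
#' time-dependent first-order decay `dEa/dt = -kinact * Ea`, the description
#' some of the ADC literature uses.
#'
#' @param params A [kinetic_params()] object.
#' @param cond A [reaction_conditions()] object.
#' @param t_min Output time grid in minutes; strictly increasing, starting
#'   at 0.
#' @param coupling `"turnover"` (default) or `"first_order"`.
#' @return A tibble with columns `time_min`, `S_mM`, `P_mM`, `Ea_uM`.
#' @examples
#' wt <- kinetic_params(3.69, 4.25, 0.0011)
#' simulate_progress(wt, reaction_conditions(1.7, 40), t_min = c(0, 10, 20, 30, 60))
#' @export
simulate_progress <- function(params, cond, t_min,
                              coupling = c("turnover", "first_order")) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(cond, "reaction_conditions"))
  coupling <- match.arg(coupling)
  if (length(t_min) < 2 || any(diff(t_min) <= 0)) {
    abort("simulate_progress(): t_min must be strictly increasing with >= 2 points.")
  }
  if (t_min[1] != 0) {
    abort("simulate_progress(): the time grid must start at 0.")
  }

  Km <- params$Km; kcat <- params$kcat; kinact <- params$kinact
  deriv <- function(t, y, parms) {
    sat <- y[["S"]] / (Km + y[["S"]])
    v <- kcat * uM_to_mM(y[["Ea"]]) * sat
    dEa <- if (coupling == "turnover") -kinact * y[["Ea"]] * sat
           else -kinact * y[["Ea"]]
    list(c(S = -v, P = v, Ea = dEa))
  }
  out <- deSolve::ode(
    y = c(S = cond$S0, P = 0, Ea = cond$E0),
    times = min_to_s(t_min),
    func = deriv, parms = NULL,
    method = "lsoda", rtol = 1e-8, atol = 1e-10
  )
  tibble(
    time_min = t_min,
    S_mM = pmax(out[, "S"], 0),
    P_mM = pmin(pmax(out[, "P"], 0), cond$S0),
    Ea_uM = pmax(out[, "Ea"], 0)
  )
}

#' Partition ratio (model-based total turnover number)
#'
#' The expected number of catalytic cycles completed per enzyme molecule
#' before inactivation, `kcat / kinact`. This is the model-side quantity;
#' the empirical counterpart measured from a plateaued conversion is
#' [empirical_ttn()], and the two are reported separately because published
#' tables do not always make them agree.
#'
#' @param params A [kinetic_params()] object with `kinact > 0`.
#' @return Dimensionless number of turnovers.
#' @examples
#' partition_ratio(kinetic_params(3.69, 4.25, 0.0011))
#' @export
partition_ratio <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  if (params$kinact <= 0) {
    abort("partition_ratio(): kinact = 0 means no inactivation; the total turnover number is unbounded.")
  }
  params$kcat / params$kinact
}

#' Product plateau of a batch conversion
#'
#' Under turnover-coupled inactivation the product concentration saturates at
#' `min(S0, (kcat/kinact) * E0)`: the reaction stops when either the substrate
#' or the enzyme's catalytic lifetime is exhausted.
#'
#' @param params A [kinetic_params()] object.
#' @param cond A [reaction_conditions()] object.
#' @return Plateau product concentration, mM, with attribute
#'   `substrate_limited` (TRUE when the plateau equals `S0`). With
#'   `kinact = 0` the plateau is `S0` and a warning notes there is no
#'   inactivation-limited plateau.
#' @examples
#' final_product(kinetic_params(3.69, 4.25, 0.0011), reaction_conditions(1.7, 40))
#' @export
final_product <- function(params, cond) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(cond, "reaction_conditions"))
  if (params$kinact == 0) {
    warn("kinact = 0: no inactivation, the plateau is set by substrate alone (S0).")
    return(structure(cond$S0, substrate_limited = TRUE))
  }
  cap <- partition_ratio(params) * uM_to_mM(cond$E0)
  structure(min(cond$S0, cap), substrate_limited = cap >= cond$S0)
}

check_scalar <- function(x, name, strict) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      (strict && x <= 0) || (!strict && x < 0)) {
    abort(sprintf("%s must be a single finite number %s 0.",
                  name, if (strict) ">" else ">="))
  }
  invisible(x)
}
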