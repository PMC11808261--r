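# Seeded synthetic-data generators: noisy progress curves, initial-rate
# tables and mock 96-well screening plates. All randomness is confined to an
# explicit seed argument; the global RNG state is left untouched.

#' Generate noisy replicate progress curves
#'
#' Simulates the true trajectory once with [simulate_progress()] and adds
#' independent Gaussian measurement noise per replicate,
#' `sd = sigma_abs + sigma_rel * P`, truncating readings at 0. This emulates
#' an HPLC concentration readout; it does not emulate systematic drift,
#' sample-handling dropout or between-batch enzyme-loading error.
#'
#' @param params A [kinetic_params()] object.
#' @param cond A [reaction_conditions()] object.
#' @param t_min Sampling times, minutes (strictly increasing from 0).
#' @param sigma_abs Absolute noise sd, mM.
#' @param sigma_rel Relative noise sd (fraction of the true concentration).
#' @param n_replicates Number of noisy replicates.
#' @param seed Integer seed; identical seeds give identical output.
#' @return A tibble `replicate`, `time_min`, `product_mM` (plus `label` when
#'   the params carry one).
#' @examples
#' wt <- kinetic_params(3.69, 4.25, 7e-4, label = "wt")
#' sim_progress_curves(wt, reaction_conditions(1.7, 40), seq(0, 30, 5),
#'                     sigma_rel = 0.01, n_replicates = 3, seed = 1)
#' @export
sim_progress_curves <- function(params, cond, t_min,
                                sigma_abs = 0, sigma_rel = 0,
                                n_replicates = 1, seed = 1) {
  stopifnot(sigma_abs >= 0, sigma_rel >= 0, n_replicates >= 1)
  traj <- simulate_progress(params, cond, t_min)
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_replicates), function(r) {
      sd <- sigma_abs + sigma_rel * traj$P_mM
      p <- traj$P_mM + ifelse(sd > 0, rnorm(nrow(traj), 0, sd), 0)
      out <- tibble(replicate = r, time_min = traj$time_min,
                    product_mM = pmax(p, 0))
      if (!is.null(params$label)) out$label <- params$label
      out
    })
  })
}

#' Generate a synthetic initial-rate dataset
#'
#' For each substrate concentration, simulates an endpoint assay of the given
#' duration under the full inactivation model, converts the endpoint to a
#' pseudo-initial rate with [initial_rate()], and adds seeded Gaussian noise
#' on the endpoint product. Short assays at low enzyme load converge to the
#' true instantaneous rate; the default mirrors a 5-minute endpoint protocol.
#'
#' @param params A [kinetic_params()] object.
#' @param E0 Enzyme concentration, uM.
#' @param S_mM Substrate grid, mM.
#' @param duration_min Assay duration, minutes.
#' @param sigma_abs,sigma_rel Noise on the endpoint product, as in
#'   [sim_progress_curves()].
#' @param n_replicates Replicates per substrate level.
#' @param seed Integer seed.
#' @return A tibble `replicate`, `S_mM`, `v_mM_per_min`.
#' @export
sim_rate_data <- function(params, E0, S_mM = c(1, 2, 5, 10, 20, 40),
                          duration_min = 5, sigma_abs = 0, sigma_rel = 0,
                          n_replicates = 1, seed = 1) {
  stopifnot(all(S_mM > 0), duration_min > 0, n_replicates >= 1)
  p_end <- vapply(S_mM, function(s) {
    if (E0 == 0) return(0)
    traj <- simulate_progress(params, reaction_conditions(E0, s),
                              c(0, duration_min))
    traj$P_mM[2]
  }, numeric(1))
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_replicates), function(r) {
      sd <- sigma_abs + sigma_rel * p_end
      p <- pmax(p_end + ifelse(sd > 0, rnorm(length(p_end), 0, sd), 0), 0)
      tibble(replicate = r, S_mM = S_mM,
             v_mM_per_min = initial_rate(p, duration_min))
    })
  })
}

#' Simulate a screening plate of variant wells
#'
#' Emulates one round of high-throughput library screening: each well holds a
#' variant whose kcat is the base value times a log-normal multiplier
#' (`sdlog`, default 0.3), a `beneficial_frac` tail of wells additionally
#' gets `beneficial_boost` times higher kcat, and the recorded signal is the
#' product concentration at the sampling time - a monotone proxy for a
#' fluorescence peak. Optional Gaussian noise applies to the signal.
#'
#' @param n_variants Number of wells (default 96).
#' @param base_params A [kinetic_params()] object for the parent enzyme.
#' @param cond A [reaction_conditions()] object.
#' @param sample_time_min Time at which the signal is read, minutes.
#' @param sdlog Log-normal sd of the kcat multiplier.
#' @param beneficial_frac Fraction of wells in the improved tail.
#' @param beneficial_boost kcat multiplier applied to beneficial wells.
#' @param sigma_rel Relative Gaussian noise on the signal.
#' @param seed Integer seed.
#' @return A tibble `well`, `beneficial`, `kcat`, `kinact`, `signal`.
#' @export
sim_screen_plate <- function(n_variants = 96, base_params, cond,
                             sample_time_min = 60, sdlog = 0.3,
                             beneficial_frac = 0.05, beneficial_boost = 2,
                             sigma_rel = 0, seed = 1) {
  stopifnot(inherits(base_params, "kinetic_params"),
            inherits(cond, "reaction_conditions"),
            n_variants >= 1, sample_time_min > 0)
  withr::with_seed(seed, {
    mult <- stats::rlnorm(n_variants, meanlog = 0, sdlog = sdlog)
    beneficial <- stats::runif(n_variants) < beneficial_frac
    kcat <- base_params$kcat * mult * ifelse(beneficial, beneficial_boost, 1)
    kinact <- rep(base_params$kinact, n_variants)
    signal <- vapply(seq_len(n_variants), function(i) {
      p <- kinetic_params(base_params$Km, kcat[i], kinact[i])
      simulate_progress(p, cond, c(0, sample_time_min))$P_mM[2]
    }, numeric(1))
    if (sigma_rel > 0) {
      signal <- pmax(signal + rnorm(n_variants, 0, sigma_rel * signal), 0)
    }
    tibble(
      well = sprintf("w%03d", seq_len(n_variants)),
      beneficial = beneficial, kcat = kcat, kinact = kinact, signal = signal
    )
  })
}

#' Select the top wells of a screening plate
#'
#' Returns the labels of the `k` wells with the highest signal, in
#' descending signal order (ties broken by well label for determinism).
#'
#' @param plate A tibble from [sim_screen_plate()].
#' @param k Number of wells to retain.
#' @return Character vector of well labels, length `k`.
#' @export
select_top <- function(plate, k) {
  stopifnot(is.data.frame(plate), all(c("well", "signal") %in% names(plate)))
  if (k > nrow(plate)) {
    abort(sprintf("select_top(): k = %d exceeds the number of wells (%d).",
                  k, nrow(plate)))
  }
  ord <- order(-plate$signal, plate$well)
  plate$well[ord][seq_len(k)]
}
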