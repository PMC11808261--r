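#' Published characterization of the BsADC reference variants
#'
#' Kinetic and stability constants reported for wild-type B. subtilis
#' L-aspartate-alpha-decarboxylase (panD-wt) and the engineered combination
#' variants N3 (S7N/K63N/I88M/A99E/K113R/I126*) and Y1
#' (S7Y/K63N/I88M/A99E/K113R/I126*): Michaelis constant, turnover number,
#' catalytic efficiency, empirically determined inactivation rate, total
#' turnover number, and half-life. These serve as reference parameter sets
#' for simulations and as comparison values for fitted results. Note that
#' the published empirical TTN and inactivation-rate figures are not the
#' model-based quantities kcat/kinact and ln(2)/half-life; this package
#' reports model-based and empirical quantities separately and never forces
#' them to agree.
#'
#' @return A tibble with one row per variant: `variant`, `Km_mM`, `kcat_s`,
#'   `kcat_over_Km`, `inact_rate_s`, `ttn`, `half_life_min`.
#' @examples
#' bsadc_variants()
#' @export
bsadc_variants <- function() {
  tibble(
    variant = c("panD-wt", "N3", "Y1"),
    Km_mM = c(3.69, 3.22, 3.82),
    kcat_s = c(4.25, 8.29, 7.26),
    kcat_over_Km = c(1.15, 2.57, 1.90),
    inact_rate_s = c(0.0011, 0.0003, 0.0002),
    ttn = c(830.56, 1676.30, 1685.46),
    half_life_min = c(17.91, 38.18, 60.35)
  )
}
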