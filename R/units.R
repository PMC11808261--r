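# Unit layer. All user-facing time is minutes, rate constants are per second,
# substrate/product are mM and enzyme is uM. Every conversion between those
# scales lives here so that no factor of 60 or 1000 appears ad hoc elsewhere.

MIN_TO_S <- 60
UM_TO_MM <- 1e-3

min_to_s <- function(t_min) t_min * MIN_TO_S
s_to_min <- function(t_s) t_s / MIN_TO_S
uM_to_mM <- function(x) x * UM_TO_MM
mM_to_uM <- function(x) x / UM_TO_MM
per_min_to_per_s <- function(k) k / MIN_TO_S
per_s_to_per_min <- function(k) k * MIN_TO_S

# Average (isotope-weighted) residue masses in Da, i.e. amino-acid mass minus
# one water; standard values used by protein parameter calculators.
AA_RESIDUE_MASS <- c(
  A =  71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G =  57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P =  97.1167,
  S =  87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V =  99.1326
)
WATER_MASS <- 18.01528

#' Average molar mass of a protein sequence
#'
#' Sums average residue masses plus one water, as protein parameter
#' calculators do. Useful for converting an enzyme loading given as a mass
#' concentration into a molar concentration.
#'
#' @param sequence Character scalar of one-letter amino-acid codes
#'   (standard 20 only).
#' @return Molar mass in Da (g/mol).
#' @examples
#' protein_molar_mass("MMSGKLHRA")
#' @export
protein_molar_mass <- function(sequence) {
  res <- split_residues(sequence)
  sum(AA_RESIDUE_MASS[res]) + WATER_MASS
}

#' Enzyme molar concentration from a mass loading
#'
#' Converts an assay loading such as "25 ug of purified enzyme in 1 mL" into
#' a molar concentration, given the monomer molar mass (supply it directly or
#' compute it from the sequence with [protein_molar_mass()]).
#'
#' @param mass_ug Enzyme mass loaded, micrograms.
#' @param volume_mL Reaction volume, millilitres.
#' @param molar_mass Monomer molar mass, Da.
#' @return Concentration in uM.
#' @examples
#' enzyme_molarity(25, 1, 13800) # ~1.8 uM
#' @export
enzyme_molarity <- function(mass_ug, volume_mL = 1, molar_mass) {
  stopifnot(mass_ug >= 0, volume_mL > 0, molar_mass > 0)
  # ug / (g/mol) = umol * 1e-6; per mL -> per L is *1000; net uM = ug/(Da*mL)*1000
  (mass_ug / molar_mass) / volume_mL * 1000
}

split_residues <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(res), names(AA_RESIDUE_MASS))
  if (length(bad) > 0) {
    abort(paste0(
      "Non-standard residue code(s): ", paste(bad, collapse = ", "),
      ". Only the 20 standard one-letter codes are accepted."
    ))
  }
  res
}
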