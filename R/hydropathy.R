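# Mutation strings, sequence editing and Kyte-Doolittle hydropathy profiles.

#' Kyte-Doolittle hydropathy scale
#'
#' Named numeric vector of the 20 standard per-residue hydropathy constants
#' (range -4.5 for Arg to +4.5 for Ile). Windowed means below -0.5 are
#' conventionally read as hydrophilic stretches.
#'
#' @format Named numeric vector of length 20.
#' @export
kd_scale <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  E = -3.5, Q = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

#' Parse a slash-separated mutation string
#'
#' Accepts the common variant notation `"S7N/K63N/I88M/A99E/K113R/I126*"`:
#' each token is wild-type residue, 1-based position, replacement residue, or
#' `*` for truncation at (and including) that position. Whitespace inside
#' tokens (as sometimes typeset, "S7 N") is tolerated.
#'
#' @param text Mutation string; `""` (or `NA`) yields an empty spec, the
#'   identity edit.
#' @return A tibble with columns `wt`, `pos`, `new`, ordered by position.
#' @examples
#' parse_mutation_string("S7N/K63N/I88M/A99E/K113R/I126*")
#' @export
parse_mutation_string <- function(text) {
  empty <- tibble(wt = character(), pos = integer(), new = character())
  if (is.null(text) || is.na(text) || !nzchar(trimws(text))) return(empty)
  tokens <- strsplit(trimws(text), "/", fixed = TRUE)[[1]]
  m <- regmatches(tokens, regexec("^\\s*([A-Z])\\s*([0-9]+)\\s*([A-Z*])\\s*$", tokens))
  bad <- tokens[vapply(m, length, integer(1)) == 0]
  if (length(bad) > 0) {
    abort(paste0("Malformed mutation token(s): ", paste(bad, collapse = ", "),
                 ". Expected e.g. S7N or I126*."))
  }
  spec <- tibble(
    wt  = vapply(m, `[`, character(1), 2),
    pos = as.integer(vapply(m, `[`, character(1), 3)),
    new = vapply(m, `[`, character(1), 4)
  )
  bad_aa <- setdiff(unique(c(spec$wt, setdiff(spec$new, "*"))), names(kd_scale))
  if (length(bad_aa) > 0) {
    abort(paste0("Non-standard residue code(s) in mutation string: ",
                 paste(bad_aa, collapse = ", ")))
  }
  if (anyDuplicated(spec$pos)) {
    dup <- spec$pos[duplicated(spec$pos)]
    abort(paste0("Duplicate mutation position(s): ", paste(unique(dup), collapse = ", ")))
  }
  spec <- spec[order(spec$pos), ]
  stops <- which(spec$new == "*")
  if (length(stops) > 1) abort("At most one truncation ('*') is allowed.")
  if (length(stops) == 1 && stops != nrow(spec)) {
    abort("A truncation ('*') must be the last (highest-position) edit.")
  }
  spec
}

#' Canonical mutation-string formatting
#'
#' Inverse of [parse_mutation_string()]: no internal spaces, positions
#' ascending, truncation last.
#'
#' @param spec A mutation spec tibble (`wt`, `pos`, `new`).
#' @return A single string, `""` for an empty spec.
#' @export
format_mutation_string <- function(spec) {
  if (nrow(spec) == 0) return("")
  spec <- spec[order(spec$pos), ]
  paste0(spec$wt, spec$pos, spec$new, collapse = "/")
}

#' Apply mutations to a protein sequence
#'
#' Applies substitutions and an optional C-terminal truncation to a sequence.
#' Each edit's wild-type letter must match the sequence at that position; a
#' truncation `X<pos>*` removes residue `pos` and everything downstream,
#' leaving `pos - 1` residues.
#'
#' @param sequence Character scalar of one-letter codes.
#' @param spec A mutation spec tibble from [parse_mutation_string()], or a
#'   mutation string (parsed for you).
#' @return The edited sequence as a character scalar.
#' @examples
#' apply_mutations("MYRTMMSGKLHRA", "S7N")
#' @export
apply_mutations <- function(sequence, spec) {
  if (is.character(spec) && is.null(dim(spec))) spec <- parse_mutation_string(spec)
  res <- split_residues(sequence)
  if (nrow(spec) == 0) return(sequence)
  if (any(spec$pos > length(res))) {
    out <- spec$pos[spec$pos > length(res)]
    abort(sprintf("Mutation position(s) %s beyond sequence length %d.",
                  paste(out, collapse = ", "), length(res)))
  }
  mismatch <- spec$wt != res[spec$pos]
  if (any(mismatch)) {
    i <- which(mismatch)[1]
    abort(sprintf(
      "Wild-type mismatch at position %d: mutation says %s, sequence has %s.",
      spec$pos[i], spec$wt[i], res[spec$pos[i]]
    ))
  }
  subs <- spec[spec$new != "*", ]
  res[subs$pos] <- subs$new
  stop_row <- spec[spec$new == "*", ]
  if (nrow(stop_row) == 1) res <- res[seq_len(stop_row$pos - 1)]
  paste(res, collapse = "")
}

#' Sliding-window Kyte-Doolittle hydropathy profile
#'
#' Uniform (unweighted) mean of the Kyte-Doolittle constants over each full
#' window of odd width, assigned to the central residue. No edge padding: the
#' first and last `(window-1)/2` positions have no score (NA). Scores below
#' -0.5 are flagged hydrophilic (strict inequality).
#'
#' @param sequence Character scalar of one-letter codes (standard 20 only).
#' @param window Odd window width, `3 <= window <= nchar(sequence)`;
#'   default 9, the conventional choice for surface/hydrophilicity scans.
#' @param threshold Hydrophilicity cutoff; a residue is flagged when its
#'   score is strictly below it. Default -0.5.
#' @return A tibble with `position`, `residue`, `score`, `hydrophilic`
#'   (NA where the score is undefined), carrying the window width as an
#'   attribute.
#' @examples
#' kd_profile("MYRTMMSGKLHRA", window = 9)
#' @export
kd_profile <- function(sequence, window = 9, threshold = -0.5) {
  res <- split_residues(sequence)
  n <- length(res)
  if (window %% 2 == 0) abort("window must be odd.")
  if (window < 3 || window > n) {
    abort(sprintf("window must be between 3 and the sequence length (%d).", n))
  }
  half <- (window - 1) / 2
  vals <- kd_scale[res]
  csum <- cumsum(c(0, vals))
  score <- rep(NA_real_, n)
  centers <- (half + 1):(n - half)
  score[centers] <- (csum[centers + half + 1] - csum[centers - half]) / window
  out <- tibble(
    position = seq_len(n),
    residue = res,
    score = score,
    hydrophilic = classify_hydrophilic(score, threshold)
  )
  attr(out, "window") <- window
  attr(out, "threshold") <- threshold
  out
}

#' Hydrophilicity classification of windowed scores
#'
#' A residue is hydrophilic when its windowed score is strictly below the
#' threshold (default -0.5); a score exactly at the threshold is not.
#'
#' @param score Numeric scores (NA allowed, propagated).
#' @param threshold Cutoff, default -0.5.
#' @return Logical vector.
#' @examples
#' classify_hydrophilic(c(-0.678, -0.5, -0.378))
#' @export
classify_hydrophilic <- function(score, threshold = -0.5) {
  score < threshold
}

#' Mean hydropathy over a sequence region
#'
#' Arithmetic mean of the defined (non-NA) windowed scores in a 1-based
#' inclusive region, with a count of positions that had no score.
#'
#' @param profile A profile tibble from [kd_profile()].
#' @param start,end 1-based inclusive region bounds.
#' @return One-row tibble: `start`, `end`, `mean_score`, `n_scored`,
#'   `n_unscored`.
#' @export
region_summary <- function(profile, start, end) {
  stopifnot(is.data.frame(profile), all(c("position", "score") %in% names(profile)))
  n <- nrow(profile)
  if (!(start >= 1 && start <= end && end <= n)) {
    abort(sprintf("Region must satisfy 1 <= start <= end <= %d.", n))
  }
  s <- profile$score[start:end]
  if (all(is.na(s))) {
    abort("Region has no positions with a defined score (all within the window edge).")
  }
  tibble(
    start = start, end = end,
    mean_score = mean(s, na.rm = TRUE),
    n_scored = sum(!is.na(s)),
    n_unscored = sum(is.na(s))
  )
}
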