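# File I/O: progress curves and rate tables as CSV/TSV (delimiter chosen by
# extension), protein sequences as FASTA, results as JSON.

#' Read a progress-curve table
#'
#' CSV or TSV (by file extension) with header columns `time_min`,
#' `product_mM` and optionally `label`.
#'
#' @param path File path; `.tsv`/`.tab` are read tab-separated, anything
#'   else comma-separated.
#' @return A tibble validated as a progress curve.
#' @export
read_progress_csv <- function(path) {
  d <- read_delim_auto(path, c("time_min", "product_mM"))
  check_progress_data(d)
}

#' Read an initial-rate table
#'
#' CSV or TSV with header columns `S_mM` and `v_mM_per_min`.
#'
#' @inheritParams read_progress_csv
#' @return A validated tibble.
#' @export
read_rates_csv <- function(path) {
  d <- read_delim_auto(path, c("S_mM", "v_mM_per_min"))
  check_rate_data(d)
}

read_delim_auto <- function(path, required) {
  delim <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort(paste0(path, " is missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (nrow(raw) == 0) abort(paste0(path, " contains a header but no data rows."))
  for (col in required) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    if (anyNA(vals)) {
      abort(sprintf("Non-numeric value(s) in column %s of %s (row %s).",
                    col, path, paste(which(is.na(vals)), collapse = ", ")))
    }
    raw[[col]] <- vals
  }
  raw
}

#' Read a single-or-multi record protein FASTA
#'
#' Thin wrapper over `Biostrings::readAAStringSet()` that validates residue
#' codes and rejects duplicate record ids.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta_seq <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    abort(paste0("Duplicate FASTA id(s): ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  seqs <- as.character(set)
  names(seqs) <- ids
  for (s in seqs) split_residues(s) # validates codes
  seqs
}

#' Write an analysis result as JSON
#'
#' Serialises fitted objects (or plain lists/data frames) to JSON with
#' full-precision numbers plus, for fitted objects, a `formatted` block
#' rounded to two decimals for eyeballing against published tables.
#'
#' @param x An `mm_fit`, `stability_fit`, list or data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results_json <- function(x, path) {
  payload <- result_payload(x)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

result_payload <- function(x) {
  if (inherits(x, "mm_fit")) {
    vals <- list(Km_mM = x$Km, Vmax_mM_per_min = x$Vmax,
                 se_Km = x$se_Km, se_Vmax = x$se_Vmax,
                 kcat_per_s = x$kcat, kcat_over_Km = x$kcat_over_Km,
                 E0_uM = x$E0, r_squared = x$r_squared, method = x$method)
    c(vals, list(formatted = round2(vals)))
  } else if (inherits(x, "stability_fit")) {
    vals <- list(label = x$label,
                 poly_degree = x$poly$degree,
                 poly_coefficients = as.list(x$poly$coefficients),
                 poly_r_squared = x$poly$r_squared,
                 lambda_per_min = x$lambda_per_min,
                 half_life_min = x$half_life_min,
                 kinact_per_s = x$kinact_per_s)
    c(vals, list(formatted = round2(vals)))
  } else if (is.data.frame(x)) {
    x
  } else if (is.list(x)) {
    x
  } else {
    abort("write_results_json(): unsupported object type.")
  }
}

round2 <- function(vals) {
  lapply(vals, function(v) {
    if (is.numeric(v) && length(v) == 1 && is.finite(v)) round(v, 2) else NULL
  })
}
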