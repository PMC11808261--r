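# Combination enumeration and ddG-guided ranking of recombination candidates.
# Predicted folding free-energy changes (e.g. FoldX output) are consumed as
# data; negative ddG is taken as non-destabilising and hence favourable.

#' Enumerate mutation combinations from per-site residue menus
#'
#' Builds the full cross product of allowed replacements at each menu site,
#' merges every combination with a fixed background of edits, and returns the
#' canonical mutation strings in deterministic lexicographic order.
#'
#' @param menu Character vector of site menus, each `"S7:NCY"` style:
#'   wild-type letter, position, colon, allowed replacement letters.
#' @param background Mutation string applied to every combination, e.g.
#'   `"K63N/I88M/I126*"`; may be `""`.
#' @return A tibble with one column `mutation_string`.
#' @examples
#' enumerate_combinations(c("S7:NCY", "A99:VET", "K113:RE"),
#'                        background = "K63N/I88M/I126*")
#' @export
enumerate_combinations <- function(menu = character(), background = "") {
  bg <- parse_mutation_string(background)
  sites <- lapply(menu, parse_site_menu)
  pos <- vapply(sites, function(s) s$pos, integer(1))
  if (anyDuplicated(pos)) abort("Duplicate site position in menu.")
  if (any(pos %in% bg$pos)) {
    abort(sprintf("Menu position(s) %s collide with background edits.",
                  paste(intersect(pos, bg$pos), collapse = ", ")))
  }
  choice_list <- lapply(sites, function(s) {
    tibble(wt = s$wt, pos = s$pos, new = s$residues)
  })
  combos <-
    if (length(choice_list) == 0) list(bg)
    else {
      grid <- expand.grid(lapply(choice_list, function(x) seq_len(nrow(x))),
                          KEEP.OUT.ATTRS = FALSE)
      lapply(seq_len(nrow(grid)), function(i) {
        picked <- purrr::map2_dfr(choice_list, as.integer(grid[i, ]),
                                  function(ch, j) ch[j, ])
        dplyr::bind_rows(bg, picked)
      })
    }
  strings <- vapply(combos, format_mutation_string, character(1))
  tibble(mutation_string = sort(strings))
}

parse_site_menu <- function(token) {
  m <- regmatches(token, regexec("^\\s*([A-Z])\\s*([0-9]+)\\s*:\\s*([A-Z]+)\\s*$", token))[[1]]
  if (length(m) == 0) {
    abort(paste0("Malformed site menu '", token, "'. Expected e.g. S7:NCY."))
  }
  wt <- m[2]; pos <- as.integer(m[3])
  residues <- strsplit(m[4], "", fixed = TRUE)[[1]]
  if (any(residues == wt)) {
    abort(sprintf("Menu at %s%d lists the wild-type residue itself.", wt, pos))
  }
  bad <- setdiff(residues, names(kd_scale))
  if (length(bad) > 0) {
    abort(paste0("Non-standard residue(s) in menu '", token, "': ",
                 paste(bad, collapse = ", ")))
  }
  list(wt = wt, pos = pos, residues = residues)
}

#' Read a table of ddG-scored combination candidates
#'
#' Tab-separated file with columns `name`, `variant` (a mutation string) and
#' `ddg_kcal_mol`. Every variant string is validated by
#' [parse_mutation_string()] and every ddG must be numeric.
#'
#' @param path Path to the TSV file.
#' @return A tibble `name`, `variant`, `ddg_kcal_mol`.
#' @export
read_ddg_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  required <- c("name", "variant", "ddg_kcal_mol")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort(paste0("ddG table is missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (nrow(raw) == 0) {
    warn("ddG table is empty.")
    return(tibble(name = character(), variant = character(), ddg_kcal_mol = numeric()))
  }
  ddg <- suppressWarnings(as.numeric(raw$ddg_kcal_mol))
  if (anyNA(ddg)) {
    bad <- which(is.na(ddg))
    abort(sprintf("Non-numeric ddG value(s) in row(s) %s of %s.",
                  paste(bad, collapse = ", "), path))
  }
  for (i in seq_len(nrow(raw))) {
    tryCatch(parse_mutation_string(raw$variant[i]),
             error = function(e) abort(sprintf(
               "Row %d ('%s'): unparseable variant string (%s).",
               i, raw$name[i], conditionMessage(e))))
  }
  tibble(name = raw$name, variant = raw$variant, ddg_kcal_mol = ddg)
}

#' Rank combination candidates by ddG and flag the selection
#'
#' Sorts candidates by ascending predicted folding free-energy change (more
#' negative = more stabilising), breaking ties by name, and selects every
#' candidate strictly below the threshold (default 0, i.e. all
#' non-destabilising combinations).
#'
#' @param candidates Tibble from [read_ddg_table()] (columns `name`,
#'   `variant`, `ddg_kcal_mol`).
#' @param threshold Selection cutoff in kcal/mol; strict `<`. Default 0.
#' @return The candidates tibble, ranked, with added columns `rank` and
#'   `selected`.
#' @export
rank_and_select <- function(candidates, threshold = 0) {
  stopifnot(is.data.frame(candidates),
            all(c("name", "variant", "ddg_kcal_mol") %in% names(candidates)))
  if (nrow(candidates) == 0) abort("rank_and_select(): no candidates supplied.")
  out <- dplyr::arrange(as_tibble(candidates), .data$ddg_kcal_mol, .data$name)
  out$rank <- seq_len(nrow(out))
  out$selected <- out$ddg_kcal_mol < threshold
  out
}
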