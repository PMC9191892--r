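#' Parse sample names into condition, fraction and replicate
#'
#' The default naming convention for quantification columns is
#' `"<condition>_<fraction>_rep<k>"`, e.g. `"unstressed_F1_rep2"` or
#' `"H2O2_T_rep4"`. A user-supplied sample map (a data frame with columns
#' `column`, `condition`, `fraction`, `replicate`) overrides the convention
#' when the input files use different headers.
#'
#' @param x Character vector of sample names.
#' @return A tibble with columns `column`, `condition`, `fraction`,
#'   `replicate` (integer). Names that do not follow the convention yield
#'   `NA` fields.
#' @export
#' @examples
#' parse_sample_names(c("unstressed_F1_rep1", "3AT_T_rep4"))
parse_sample_names <- function(x) {
  m <- regmatches(x, regexec("^([A-Za-z0-9]+)_(T|F[1-5])_rep([0-9]+)$", x))
  parsed <- purrr::map(m, function(g) {
    if (length(g) == 4L && g[2] %in% CONDITIONS) {
      tibble(condition = g[2], fraction = g[3], replicate = as.integer(g[4]))
    } else {
      tibble(condition = NA_character_, fraction = NA_character_,
             replicate = NA_integer_)
    }
  })
  bind_cols(tibble(column = x), bind_rows(parsed))
}

#' Compose sample names from keys
#'
#' Inverse of [parse_sample_names()].
#'
#' @param condition,fraction Character vectors of condition / fraction levels.
#' @param replicate Integer vector of replicate indices.
#' @return Character vector `"<condition>_<fraction>_rep<k>"`.
#' @export
sample_name <- function(condition, fraction, replicate) {
  paste0(condition, "_", fraction, "_rep", replicate)
}

# Validate a sample map data frame; returns it as a tibble with the four
# canonical columns, or aborts.
check_sample_map <- function(sample_map) {
  needed <- c("column", "condition", "fraction", "replicate")
  if (!all(needed %in% names(sample_map))) {
    abort(paste0("sample_map must have columns: ",
                 paste(needed, collapse = ", ")))
  }
  sm <- as_tibble(sample_map[needed])
  sm$replicate <- as.integer(sm$replicate)
  bad_c <- setdiff(unique(sm$condition), CONDITIONS)
  bad_f <- setdiff(unique(sm$fraction), FRACTIONS)
  if (length(bad_c)) abort(paste0("unknown condition(s) in sample_map: ",
                                  paste(bad_c, collapse = ", ")))
  if (length(bad_f)) abort(paste0("unknown fraction(s) in sample_map: ",
                                  paste(bad_f, collapse = ", ")))
  if (anyNA(sm$replicate) || any(sm$replicate < 1L)) {
    abort("sample_map replicates must be positive integers")
  }
  key <- paste(sm$condition, sm$fraction, sm$replicate)
  if (anyDuplicated(key)) {
    abort("sample_map assigns the same (condition, fraction, replicate) twice")
  }
  if (anyDuplicated(sm$column)) abort("sample_map lists a column twice")
  sm
}

# Validate a long LFQ tibble: protein_id, condition, fraction, replicate,
# intensity. Values must be finite and non-negative (0 = not quantified).
check_lfq <- function(lfq, arg = "lfq") {
  needed <- c("protein_id", "condition", "fraction", "replicate", "intensity")
  if (!all(needed %in% names(lfq))) {
    abort(paste0(arg, " must be a long intensity table with columns: ",
                 paste(needed, collapse = ", ")))
  }
  if (any(!is.finite(lfq$intensity)) || any(lfq$intensity < 0)) {
    abort(paste0(arg, "$intensity must be finite and >= 0"))
  }
  bad_f <- setdiff(unique(lfq$fraction), FRACTIONS)
  if (length(bad_f)) abort(paste0("unknown fraction(s): ",
                                  paste(bad_f, collapse = ", ")))
  key <- paste(lfq$protein_id, lfq$condition, lfq$fraction, lfq$replicate)
  if (anyDuplicated(key)) {
    abort(paste0(arg, " has duplicate (protein, condition, fraction, ",
                 "replicate) entries"))
  }
  invisible(lfq)
}
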