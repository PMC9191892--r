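#' Reproducible-detection filter
#'
#' A protein counts as detected in a sample (condition x fraction) when its
#' LFQ intensity is strictly positive in at least `min_reps` replicates of
#' that exact sample. No intensity threshold beyond > 0 is applied.
#'
#' @param lfq Long intensity tibble (see [read_protein_groups()]).
#' @param min_reps Minimum replicates with a positive value (default 2).
#' @return A tibble with columns `protein_id`, `condition`, `fraction`,
#'   `n_positive`, `detected`.
#' @export
detect_proteins <- function(lfq, min_reps = 2) {
  check_lfq(lfq)
  if (min_reps < 1) abort("min_reps must be >= 1")
  n_reps <- lfq |>
    distinct(.data$condition, .data$fraction, .data$replicate) |>
    count(.data$condition, .data$fraction)
  if (min_reps > max(n_reps$n)) {
    abort("min_reps exceeds the number of replicates present")
  }
  lfq |>
    group_by(.data$protein_id, .data$condition, .data$fraction) |>
    summarise(n_positive = sum(.data$intensity > 0), .groups = "drop") |>
    mutate(detected = .data$n_positive >= min_reps)
}

#' Proteins detected across a grid of conditions and fractions
#'
#' Returns the proteins detected in *every* (condition, fraction) cell of
#' the requested grid, e.g. the set found in each of F1-F4 under all three
#' conditions. The count is antitone in grid size: adding a fraction or a
#' condition can only shrink the set.
#'
#' @param detection Output of [detect_proteins()].
#' @param fractions,conditions Non-empty character vectors selecting the
#'   grid.
#' @return A one-row tibble with `n_conditions`, `n_fractions`, `count` and
#'   a list-column `proteins` holding the member IDs.
#' @export
overlap_counts <- function(detection,
                           fractions = c("F1", "F2", "F3", "F4"),
                           conditions = CONDITIONS) {
  if (length(fractions) == 0L || length(conditions) == 0L) {
    abort("fractions and conditions must be non-empty")
  }
  present_f <- unique(detection$fraction)
  present_c <- unique(detection$condition)
  if (!all(fractions %in% present_f)) {
    abort(paste0("fraction(s) absent from detection table: ",
                 paste(setdiff(fractions, present_f), collapse = ", ")))
  }
  if (!all(conditions %in% present_c)) {
    abort(paste0("condition(s) absent from detection table: ",
                 paste(setdiff(conditions, present_c), collapse = ", ")))
  }
  n_cells <- length(fractions) * length(conditions)
  hits <- detection |>
    filter(.data$fraction %in% fractions,
           .data$condition %in% conditions,
           .data$detected) |>
    count(.data$protein_id) |>
    filter(.data$n == n_cells)
  proteins <- sort(hits$protein_id)
  tibble(n_conditions = length(conditions), n_fractions = length(fractions),
         count = length(proteins), proteins = list(proteins))
}

#' Per-region condition overlap membership
#'
#' Venn-style breakdown: for proteins detected in every requested fraction
#' of at least one condition, reports which exact subset of conditions each
#' protein satisfies, with membership lists per region.
#'
#' @inheritParams overlap_counts
#' @return A tibble with columns `region` (e.g. `"unstressed+H2O2"`),
#'   `count`, and list-column `proteins`.
#' @export
overlap_regions <- function(detection,
                            fractions = c("F1", "F2", "F3", "F4"),
                            conditions = CONDITIONS) {
  per_condition <- purrr::map(conditions, function(cond) {
    overlap_counts(detection, fractions, cond)$proteins[[1]]
  })
  names(per_condition) <- conditions
  all_ids <- sort(unique(unlist(per_condition)))
  membership <- vapply(all_ids, function(id) {
    paste(conditions[vapply(per_condition, function(s) id %in% s,
                            logical(1))], collapse = "+")
  }, character(1))
  tibble(protein_id = all_ids, region = membership) |>
    group_by(.data$region) |>
    summarise(count = n(), proteins = list(.data$protein_id),
              .groups = "drop") |>
    arrange(desc(.data$count))
}

#' Replicate agreement of log2 intensities
#'
#' Squared Pearson correlation of log2 LFQ intensities between each pair of
#' replicates of each sample, computed over the proteins quantified (> 0)
#' in both members of the pair. Pairs sharing fewer than 3 proteins get an
#' `NA` r-squared with `flag = "insufficient"` rather than an error.
#'
#' @param lfq Long intensity tibble.
#' @return A tibble with `condition`, `fraction`, `rep_a`, `rep_b`, `n`
#'   (shared quantified proteins), `r_squared`, `flag`.
#' @export
replicate_correlation <- function(lfq) {
  check_lfq(lfq)
  samples <- lfq |> distinct(.data$condition, .data$fraction)
  purrr::pmap(samples, function(condition, fraction) {
    sub <- lfq[lfq$condition == condition & lfq$fraction == fraction, ]
    reps <- sort(unique(sub$replicate))
    if (length(reps) < 2L) return(NULL)
    pairs <- utils::combn(reps, 2)
    purrr::map(seq_len(ncol(pairs)), function(j) {
      a <- sub[sub$replicate == pairs[1, j], ]
      b <- sub[sub$replicate == pairs[2, j], ]
      m <- inner_join(a, b, by = "protein_id", suffix = c("_a", "_b"))
      m <- m[m$intensity_a > 0 & m$intensity_b > 0, ]
      if (nrow(m) < 3L) {
        tibble(condition = condition, fraction = fraction,
               rep_a = pairs[1, j], rep_b = pairs[2, j],
               n = nrow(m), r_squared = NA_real_, flag = "insufficient")
      } else {
        r2 <- cor(log2(m$intensity_a), log2(m$intensity_b))^2
        tibble(condition = condition, fraction = fraction,
               rep_a = pairs[1, j], rep_b = pairs[2, j],
               n = nrow(m), r_squared = r2, flag = "ok")
      }
    }) |> bind_rows()
  }) |> bind_rows()
}
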