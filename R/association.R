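#' Fraction sums of raw LFQ intensities
#'
#' For each protein and condition, averages the strictly positive replicate
#' values within each ribosomal fraction (missing replicates excluded) and
#' sums the per-fraction means over F1-F5 to give the fraction sum FS, the
#' numerator of the FS/T ribosome-association statistic. Fractions with no
#' positive replicate contribute 0 and `n_fractions_used` records how many
#' fractions carried signal.
#'
#' @param lfq Long intensity tibble.
#' @param fractions Ribosomal fractions to sum (default F1-F5).
#' @return A tibble with `protein_id`, `condition`, `FS`,
#'   `n_fractions_used`.
#' @export
fraction_sums <- function(lfq, fractions = RIBO_FRACTIONS) {
  check_lfq(lfq)
  lfq |>
    filter(.data$fraction %in% fractions) |>
    group_by(.data$protein_id, .data$condition, .data$fraction) |>
    summarise(f_mean = if (any(.data$intensity > 0)) {
      mean(.data$intensity[.data$intensity > 0])
    } else 0, .groups = "drop_last") |>
    summarise(FS = sum(.data$f_mean),
              n_fractions_used = sum(.data$f_mean > 0), .groups = "drop")
}

#' Per-protein ribosome association (FS/T and percent ribosomal)
#'
#' Estimates overall ribosome engagement per protein and condition: the
#' fraction sum FS (see [fraction_sums()]) is divided by the mean total
#' lysate intensity T, log2-transformed (`log2_fs_t`), and converted to the
#' estimated ribosome-associated proportion
#' `pct_ribosomal = 100 * (FS / T) / loading_factor`, where the loading
#' factor (default 30) accounts for the relative amounts of fractions
#' versus totals analysed by MS.
#'
#' Records where the protein is not quantified in the totals are flagged
#' `"no_total"` (association undefined, excluded from downstream testing);
#' records with no fraction signal are flagged `"no_fraction_signal"`;
#' estimates above 100 percent are reported uncapped with
#' `pct_gt_100 = TRUE`.
#'
#' @param lfq Long intensity tibble.
#' @param loading_factor Fractions-to-totals loading ratio (default 30).
#' @param fractions Ribosomal fractions summed into FS (default F1-F5).
#' @return A tibble with `protein_id`, `condition`, `FS`, `T_mean`,
#'   `log2_fs_t`, `pct_ribosomal`, `n_fractions_used`, `pct_gt_100`,
#'   `flag`.
#' @export
ribosome_association <- function(lfq, loading_factor = 30,
                                 fractions = RIBO_FRACTIONS) {
  if (loading_factor <= 0) abort("loading_factor must be > 0")
  fs <- fraction_sums(lfq, fractions)
  t_mean <- lfq |>
    filter(.data$fraction == "T") |>
    group_by(.data$protein_id, .data$condition) |>
    summarise(T_mean = if (any(.data$intensity > 0)) {
      mean(.data$intensity[.data$intensity > 0])
    } else NA_real_, .groups = "drop")
  full_join(fs, t_mean, by = c("protein_id", "condition")) |>
    mutate(
      FS = tidyr::replace_na(.data$FS, 0),
      n_fractions_used = tidyr::replace_na(.data$n_fractions_used, 0L),
      log2_fs_t = ifelse(!is.na(.data$T_mean) & .data$FS > 0,
                         log2(.data$FS / .data$T_mean), NA_real_),
      pct_ribosomal = ifelse(!is.na(.data$T_mean),
                             100 * (.data$FS / .data$T_mean) / loading_factor,
                             NA_real_),
      pct_gt_100 = !is.na(.data$pct_ribosomal) & .data$pct_ribosomal > 100,
      flag = case_when(
        is.na(.data$T_mean) ~ "no_total",
        .data$FS == 0 ~ "no_fraction_signal",
        TRUE ~ "ok"
      )
    ) |>
    arrange(.data$protein_id, match(.data$condition, CONDITIONS))
}

#' Stress-induced change in ribosome association
#'
#' Computes delta FS/T: the difference in `log2_fs_t` between each stress
#' condition and the unstressed reference, per protein. The reference rows
#' get a delta of exactly 0; proteins lacking a defined `log2_fs_t` in the
#' reference (or in the stress condition) get `NA` with a flag.
#'
#' @param association Output of [ribosome_association()].
#' @param reference Reference condition (default `"unstressed"`).
#' @return The input with columns `delta_fs_t` and `delta_flag` added.
#' @export
delta_fs_t <- function(association, reference = "unstressed") {
  if (!reference %in% association$condition) {
    abort(paste0("reference condition '", reference, "' not present"))
  }
  ref <- association |>
    filter(.data$condition == reference) |>
    select("protein_id", ref_log2 = "log2_fs_t")
  association |>
    left_join(ref, by = "protein_id") |>
    mutate(
      delta_fs_t = case_when(
        .data$condition == reference & !is.na(.data$log2_fs_t) ~ 0,
        !is.na(.data$log2_fs_t) & !is.na(.data$ref_log2) ~
          .data$log2_fs_t - .data$ref_log2,
        TRUE ~ NA_real_
      ),
      delta_flag = ifelse(is.na(.data$delta_fs_t), "undefined", "ok")
    ) |>
    select(-"ref_log2")
}

#' Fit the ribosomal-protein null model for association changes
#'
#' Ribosomal proteins show essentially no change in overall ribosome
#' association under stress (redistribution among fractions leaves their
#' summed fraction signal constant), so their delta FS/T values define an
#' empirical null for non-changing proteins: a normal distribution with the
#' RP deltas' mean and standard deviation (n-1 denominator), fitted
#' separately for each stress condition.
#'
#' @param deltas Output of [delta_fs_t()].
#' @param annotations Annotation tibble with `protein_id`, `category`.
#' @param reference Reference condition excluded from fitting.
#' @return An object of class `"rp_null"`: a list with a per-condition
#'   tibble `params` (`condition`, `mu`, `sigma`, `n_rp`). Errors if any
#'   stress condition has fewer than 3 RPs with defined deltas, or a zero
#'   standard deviation.
#' @export
fit_rp_null <- function(deltas, annotations, reference = "unstressed") {
  rp_ids <- annotations$protein_id[annotations$category == "RP"]
  rp <- deltas |>
    filter(.data$protein_id %in% rp_ids,
           .data$condition != reference,
           !is.na(.data$delta_fs_t))
  if (nrow(rp) == 0L) abort("no RP deltas available to fit the null")
  params <- rp |>
    group_by(.data$condition) |>
    summarise(mu = mean(.data$delta_fs_t),
              sigma = stats::sd(.data$delta_fs_t),
              n_rp = n(), .groups = "drop")
  if (any(params$n_rp < 3L)) {
    abort("null not fittable: fewer than 3 RPs with defined delta FS/T")
  }
  if (any(params$sigma == 0)) {
    abort("degenerate null: RP delta FS/T standard deviation is 0")
  }
  structure(list(params = params, reference = reference), class = "rp_null")
}

#' @exportS3Method base::print
print.rp_null <- function(x, ...) {
  cat("<rp_null> delta FS/T null from ribosomal proteins\n")
  print(x$params)
  invisible(x)
}

#' @rdname fit_rp_null
#' @param x An `rp_null` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.rp_null <- function(x, ...) x$params

#' @rdname fit_rp_null
#' @exportS3Method generics::glance
glance.rp_null <- function(x, ...) {
  tibble(n_conditions = nrow(x$params),
         n_rp_total = sum(x$params$n_rp),
         reference = x$reference)
}

#' P-values for association changes under the RP null
#'
#' Two-sided tail probabilities for each protein's delta FS/T under the
#' fitted RP null: `p = 2 * pnorm(-|delta - mu| / sigma)`. The direction of
#' the change (increase / decrease relative to the null mean) is reported
#' alongside, plus a Benjamini-Hochberg adjusted column (per condition) for
#' reference; significance flags use the raw p-value, matching the
#' original analysis.
#'
#' @param deltas Output of [delta_fs_t()].
#' @param null An [fit_rp_null()] object.
#' @param alpha Significance level for the `significant` flag
#'   (default 0.05).
#' @return The input with `p_value`, `direction`, `significant`, `p_bh`
#'   columns added (reference-condition rows get `NA`).
#' @export
null_pvalues <- function(deltas, null, alpha = 0.05) {
  stopifnot(inherits(null, "rp_null"))
  out <- deltas |>
    left_join(null$params, by = "condition") |>
    mutate(
      p_value = ifelse(!is.na(.data$delta_fs_t) & !is.na(.data$sigma),
                       2 * pnorm(-abs(.data$delta_fs_t - .data$mu) /
                                   .data$sigma),
                       NA_real_),
      direction = case_when(
        is.na(.data$p_value) ~ NA_character_,
        .data$delta_fs_t >= .data$mu ~ "increase",
        TRUE ~ "decrease"
      ),
      significant = !is.na(.data$p_value) & .data$p_value < alpha
    ) |>
    group_by(.data$condition) |>
    mutate(p_bh = ifelse(is.na(.data$p_value), NA_real_,
                         p.adjust(.data$p_value, method = "BH"))) |>
    ungroup() |>
    select(-"mu", -"sigma", -"n_rp")
  out
}

#' Full ribosome-association testing stage
#'
#' Convenience wrapper chaining [ribosome_association()], [delta_fs_t()],
#' [fit_rp_null()] and [null_pvalues()].
#'
#' @inheritParams ribosome_association
#' @inheritParams null_pvalues
#' @param annotations Annotation tibble (needs the RP category).
#' @param reference Reference condition.
#' @return The per-protein, per-condition association tibble, with the
#'   fitted `rp_null` attached as attribute `"null"`.
#' @export
association_test <- function(lfq, annotations, loading_factor = 30,
                             fractions = RIBO_FRACTIONS,
                             reference = "unstressed", alpha = 0.05) {
  assoc <- ribosome_association(lfq, loading_factor, fractions) |>
    delta_fs_t(reference)
  null <- fit_rp_null(assoc, annotations, reference)
  out <- null_pvalues(assoc, null, alpha)
  attr(out, "null") <- null
  out
}
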