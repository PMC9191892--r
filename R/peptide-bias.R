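#' Eligibility filter for the peptide positional-bias test
#'
#' The positional test is only informative for well-covered proteins, so
#' eligibility requires a protein to exceed *both* dataset medians: a
#' strictly greater than median number of distinct peptides, and strictly
#' greater than median sequence coverage (proportion of residues inside at
#' least one peptide's inclusive span). Ties at a median are excluded.
#' Proteins with unknown length are dropped with a warning (coverage
#' undefined).
#'
#' @param peptides Long peptide tibble (see [read_peptides()]).
#' @param lengths Tibble `protein_id`, `length` (residues).
#' @return A tibble `protein_id`, `n_peptides`, `coverage`, `eligible`,
#'   with the two medians attached as attribute `"thresholds"`.
#' @export
peptide_eligibility <- function(peptides, lengths) {
  if (nrow(peptides) == 0L) abort("peptide table is empty")
  no_len <- setdiff(unique(peptides$protein_id), lengths$protein_id)
  if (length(no_len)) {
    warn(paste0("excluding ", length(no_len),
                " protein(s) with unknown length"))
  }
  spans <- peptides |>
    filter(.data$intensity > 0) |>
    distinct(.data$protein_id, .data$start, .data$end) |>
    inner_join(lengths, by = "protein_id")

  stats_tab <- spans |>
    group_by(.data$protein_id) |>
    summarise(n_peptides = n(),
              coverage = covered_fraction(.data$start, .data$end,
                                          .data$length[1]),
              .groups = "drop")
  med_n <- median(stats_tab$n_peptides)
  med_cov <- median(stats_tab$coverage)
  out <- stats_tab |>
    mutate(eligible = .data$n_peptides > med_n & .data$coverage > med_cov)
  attr(out, "thresholds") <- c(median_n_peptides = med_n,
                               median_coverage = med_cov)
  out
}

# Fraction of residues 1..len covered by >= 1 inclusive span.
covered_fraction <- function(start, end, len) {
  hit <- logical(len)
  for (i in seq_along(start)) {
    hit[start[i]:min(end[i], len)] <- TRUE
  }
  mean(hit)
}

#' Cumulative positional intensity curve
#'
#' Builds the N-to-C cumulative peptide-intensity distribution for one
#' protein in one sample: each peptide's intensity is spread uniformly over
#' its inclusive residue span (`intensity / (end - start + 1)` per residue;
#' or assigned wholly to its start residue with `position = "start"`),
#' per-residue contributions are summed over peptides, and the running sum
#' is normalized by the total so the curve rises from 0 to 1 along the
#' protein.
#'
#' @param start,end Integer vectors of 1-based inclusive peptide spans.
#' @param intensity Non-negative peptide intensities in the sample.
#' @param length Protein length in residues.
#' @param position `"spread"` (default) or `"start"`.
#' @return A tibble `residue` (1..length), `cdf`; `NULL` when the total
#'   intensity is zero (curve undefined).
#' @export
cumulative_curve <- function(start, end, intensity, length,
                             position = c("spread", "start")) {
  position <- match.arg(position)
  keep <- intensity > 0
  if (!any(keep)) return(NULL)
  start <- start[keep]; end <- end[keep]; intensity <- intensity[keep]
  if (any(start < 1L) || any(end > length) || any(end < start)) {
    abort("peptide spans must satisfy 1 <= start <= end <= length")
  }
  per_res <- numeric(length)
  if (position == "spread") {
    span <- end - start + 1L
    idx <- sequence(span, from = start)
    val <- rep(intensity / span, span)
  } else {
    idx <- start
    val <- intensity
  }
  acc <- tapply(val, idx, sum)
  per_res[as.integer(names(acc))] <- acc
  tibble(residue = seq_len(length), cdf = cumsum(per_res) / sum(per_res))
}

# Asymptotic two-sample Kolmogorov-Smirnov tail probability with effective
# sizes n1, n2; the standard Kolmogorov series with the small-sample
# correction to the argument.
ks_asymptotic_p <- function(D, n1, n2) {
  if (D <= 0) return(1)
  ne <- n1 * n2 / (n1 + n2)
  lambda <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * D
  j <- 1:100
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))
  min(1, max(0, p))
}

#' Kolmogorov-Smirnov comparison of two positional curves
#'
#' The KS statistic `D` is the maximum absolute difference between the
#' fraction-sample and total-sample cumulative positional curves over the
#' residue grid; `signed_D` carries the sign at the maximizing residue
#' (positive when the fraction curve leads, i.e. N-terminal bias in the
#' gradient signal). The asymptotic p-value treats the curves as two-sample
#' empirical CDFs with the peptide counts as effective sample sizes — an
#' acknowledged approximation for intensity-weighted curves that is
#' accurate when peptide intensities are of comparable magnitude and
#' anti-conservative when a few peptides dominate; the permutation p-value
#' (see [peptide_bias_test()]) is the rigorous alternative.
#'
#' @param curve_fraction,curve_total Tibbles from [cumulative_curve()] on
#'   the same residue grid.
#' @param n_fraction,n_total Peptide counts behind each curve.
#' @return A one-row tibble `D`, `signed_D`, `p_raw`.
#' @export
ks_bias_stat <- function(curve_fraction, curve_total, n_fraction, n_total) {
  if (nrow(curve_fraction) != nrow(curve_total)) {
    abort("curves must share the residue grid")
  }
  diff <- curve_fraction$cdf - curve_total$cdf
  i <- which.max(abs(diff))
  D <- abs(diff[i])
  tibble(D = D, signed_D = diff[i],
         p_raw = ks_asymptotic_p(D, n_fraction, n_total))
}

#' Peptide N-terminal bias test (nascent-chain control)
#'
#' Tests, per protein, whether the positional distribution of peptide
#' intensity in the gradient fractions differs from that in the total
#' lysate — the signature expected if nascent chains contributed to the
#' gradient signal. For each eligible protein (see [peptide_eligibility()])
#' and each condition, replicate intensities are summed, cumulative
#' positional curves are built for the total sample and for each gradient
#' fraction (or the pooled fractions), and compared with the KS statistic.
#' Raw p-values are Bonferroni-corrected by the number of comparisons
#' actually performed.
#'
#' An optional permutation p-value pools the total- and fraction-sample
#' peptide observations, randomly relabels them (preserving group sizes)
#' `n_perm` times, and reports `(1 + #{D* >= D}) / (n_perm + 1)`.
#'
#' @param peptides Long peptide tibble.
#' @param lengths Tibble `protein_id`, `length`.
#' @param compare `"per_fraction"` (each of F1-F5 vs T, the default) or
#'   `"pooled"` (all fractions pooled vs T).
#' @param alpha Significance level applied to the Bonferroni-corrected
#'   p-value (default 0.05).
#' @param n_perm Permutation iterations (0 disables, the default).
#' @param position Positional convention, see [cumulative_curve()].
#' @param apply_eligibility Apply the median-based eligibility filter
#'   (default `TRUE`).
#' @param seed Seed for the permutation draws.
#' @return A tibble with one row per (protein, condition, fraction sample)
#'   comparison: `protein_id`, `condition`, `fraction`, `n_pep_fraction`,
#'   `n_pep_total`, `D`, `signed_D`, `p_raw`, `p_perm` (NA unless
#'   requested), `p_bonferroni`, `significant`. The number of tests is
#'   attached as attribute `"n_tests"`, the eligibility thresholds as
#'   `"thresholds"`.
#' @export
peptide_bias_test <- function(peptides, lengths,
                              compare = c("per_fraction", "pooled"),
                              alpha = 0.05, n_perm = 0,
                              position = c("spread", "start"),
                              apply_eligibility = TRUE, seed = NULL) {
  compare <- match.arg(compare)
  position <- match.arg(position)
  if (!is.null(seed)) set.seed(seed)

  elig <- peptide_eligibility(peptides, lengths)
  keep <- if (apply_eligibility) elig$protein_id[elig$eligible] else
    elig$protein_id
  summed <- peptides |>
    filter(.data$protein_id %in% keep) |>
    group_by(.data$protein_id, .data$condition, .data$fraction,
             .data$start, .data$end) |>
    summarise(intensity = sum(.data$intensity), .groups = "drop") |>
    inner_join(lengths, by = "protein_id")
  if (compare == "pooled") {
    summed <- summed |>
      mutate(fraction = ifelse(.data$fraction == "T", "T", "pooled")) |>
      group_by(.data$protein_id, .data$condition, .data$fraction,
               .data$start, .data$end, .data$length) |>
      summarise(intensity = sum(.data$intensity), .groups = "drop")
  }

  groups <- summed |>
    distinct(.data$protein_id, .data$condition)
  rows <- purrr::pmap(groups, function(protein_id, condition) {
    sub <- summed[summed$protein_id == protein_id &
                    summed$condition == condition, ]
    len <- sub$length[1]
    tot <- sub[sub$fraction == "T" & sub$intensity > 0, ]
    if (nrow(tot) == 0L) return(NULL)
    curve_t <- cumulative_curve(tot$start, tot$end, tot$intensity, len,
                                position)
    frac_names <- setdiff(unique(sub$fraction), "T")
    purrr::map(frac_names, function(f) {
      fr <- sub[sub$fraction == f & sub$intensity > 0, ]
      if (nrow(fr) == 0L) return(NULL)
      curve_f <- cumulative_curve(fr$start, fr$end, fr$intensity, len,
                                  position)
      res <- ks_bias_stat(curve_f, curve_t, nrow(fr), nrow(tot))
      p_perm <- if (n_perm > 0) {
        permutation_p(fr, tot, len, position, res$D, n_perm)
      } else NA_real_
      tibble(protein_id = protein_id, condition = condition, fraction = f,
             n_pep_fraction = nrow(fr), n_pep_total = nrow(tot),
             D = res$D, signed_D = res$signed_D, p_raw = res$p_raw,
             p_perm = p_perm)
    }) |> bind_rows()
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0L) abort("no testable (protein, sample) pairs")
  n_tests <- nrow(out)
  out <- out |>
    mutate(p_bonferroni = pmin(1, .data$p_raw * n_tests),
           significant = .data$p_bonferroni < alpha)
  attr(out, "n_tests") <- n_tests
  attr(out, "thresholds") <- attr(elig, "thresholds")
  out
}

# Pooled-relabeling permutation null for the KS bias statistic.
permutation_p <- function(fr, tot, len, position, D_obs, n_perm) {
  pool_start <- c(fr$start, tot$start)
  pool_end <- c(fr$end, tot$end)
  pool_int <- c(fr$intensity, tot$intensity)
  n1 <- nrow(fr)
  n <- length(pool_int)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    pick <- sample.int(n, n1)
    c1 <- cumulative_curve(pool_start[pick], pool_end[pick],
                           pool_int[pick], len, position)
    c2 <- cumulative_curve(pool_start[-pick], pool_end[-pick],
                           pool_int[-pick], len, position)
    if (is.null(c1) || is.null(c2)) next
    if (max(abs(c1$cdf - c2$cdf)) >= D_obs - 1e-12) hits <- hits + 1L
  }
  (1 + hits) / (n_perm + 1)
}

#' Cumulative curves for plotting
#'
#' Convenience builder returning the total and per-fraction cumulative
#' positional curves of one protein in long format.
#'
#' @param peptides Long peptide tibble.
#' @param lengths Tibble `protein_id`, `length`.
#' @param protein Protein ID.
#' @param condition Condition selected.
#' @param position Positional convention, see [cumulative_curve()].
#' @return A tibble `fraction`, `residue`, `cdf`.
#' @export
cumulative_curves <- function(peptides, lengths, protein,
                              condition = "unstressed",
                              position = "spread") {
  len <- lengths$length[lengths$protein_id == protein]
  if (length(len) != 1L) abort("protein length not found")
  sub <- peptides |>
    filter(.data$protein_id == protein, .data$condition == condition) |>
    group_by(.data$fraction, .data$start, .data$end) |>
    summarise(intensity = sum(.data$intensity), .groups = "drop")
  purrr::map(unique(sub$fraction), function(f) {
    fr <- sub[sub$fraction == f & sub$intensity > 0, ]
    if (nrow(fr) == 0L) return(NULL)
    cumulative_curve(fr$start, fr$end, fr$intensity, len, position) |>
      mutate(fraction = f, .before = 1)
  }) |> bind_rows()
}
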