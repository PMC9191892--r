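#' Simulation configuration
#'
#' Builds and validates the configuration for the synthetic polysome
#' profiling experiment. The generator mirrors the structure of the real
#' design: three growth conditions, a total-lysate sample plus five gradient
#' fractions, four biological replicates, and a 30-fold difference in the
#' relative amount of material loaded for fractions versus totals.
#'
#' Each protein draws a total abundance `A` (log-normal on the log2 scale),
#' a true ribosome-engaged fraction `pi` per condition, and per-condition
#' weights over F1-F5 from its profile archetype. Expected signals are
#' `A / loading_factor` for totals and `A * pi * w(f)` for fraction `f`;
#' observed values multiply in log-normal noise and are independently set
#' to zero (not quantified) with a logistic, intensity-dependent dropout
#' probability that increases as signals get weaker (left-censored-like
#' missingness, not MCAR).
#'
#' Archetypes:
#' \describe{
#'   \item{rp_like}{polysome-weighted profile; shifts toward F1 (monosomes)
#'     under stress by `stress_runoff`, emulating ribosome run-off.}
#'   \item{polysome_retained}{heavy-polysome weighted; retains its profile
#'     under stress.}
#'   \item{even}{uniform across F1-F5, no stress shift.}
#'   \item{monosome_shifted}{roughly even profile that shifts toward F1
#'     under stress.}
#'   \item{low_association}{uniform profile with a low engaged fraction
#'     (`pi` in 0.02-0.10).}
#' }
#'
#' @param n_proteins Number of protein groups.
#' @param n_replicates Biological replicates per sample (default 4).
#' @param conditions Subset of `c("unstressed", "H2O2", "3AT")`.
#' @param loading_factor Relative amount of material analysed for fractions
#'   versus totals (default 30).
#' @param archetype_mix Named proportions over the five archetypes; must sum
#'   to 1.
#' @param pi_range Interval in `[0, 1]` for the true ribosome-engaged
#'   fraction of non-`low_association` proteins.
#' @param noise_cv Coefficient of variation of multiplicative replicate
#'   noise (0 disables noise).
#' @param dropout Logical: apply intensity-dependent missingness.
#' @param dropout_midpoint,dropout_slope Logistic dropout parameters on the
#'   log2 intensity scale: an observation at log2 intensity `x` is zeroed
#'   with probability `plogis(dropout_slope * (dropout_midpoint - x))`.
#'   Defaults give roughly 15 percent marginal missingness under the
#'   default abundance model.
#' @param stress_runoff Fraction of polysomal (F2-F5) weight moved to F1
#'   under stress for the shifting archetypes (default 0.5).
#' @param frac_pi_change Proportion of proteins whose engaged fraction
#'   changes under stress (default 0: the null experiment).
#' @param pi_change_fold Multiplicative change applied to `pi` in stress
#'   conditions for the affected proteins (e.g. 0.5 for a 2-fold drop).
#' @param mean_log2_abundance,sd_log2_abundance Log2-normal abundance model
#'   for total protein amounts `A`.
#' @param seed Integer seed; a fixed seed makes [simulate_experiment()]
#'   bit-reproducible.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_proteins = 500,
                       n_replicates = 4,
                       conditions = CONDITIONS,
                       loading_factor = 30,
                       archetype_mix = c(rp_like = 0.20,
                                         polysome_retained = 0.20,
                                         even = 0.30,
                                         monosome_shifted = 0.20,
                                         low_association = 0.10),
                       pi_range = c(0.05, 0.95),
                       noise_cv = 0.2,
                       dropout = TRUE,
                       dropout_midpoint = 12.6,
                       dropout_slope = 1,
                       stress_runoff = 0.5,
                       frac_pi_change = 0,
                       pi_change_fold = 1,
                       mean_log2_abundance = 20,
                       sd_log2_abundance = 2,
                       seed = 1L) {
  archetypes <- c("rp_like", "polysome_retained", "even",
                  "monosome_shifted", "low_association")
  mix <- setNames(rep(0, length(archetypes)), archetypes)
  if (is.null(names(archetype_mix)) ||
      !all(names(archetype_mix) %in% archetypes)) {
    abort(paste0("archetype_mix must be named with: ",
                 paste(archetypes, collapse = ", ")))
  }
  mix[names(archetype_mix)] <- archetype_mix
  if (any(mix < 0) || abs(sum(mix) - 1) > 1e-8) {
    abort("archetype_mix proportions must be >= 0 and sum to 1")
  }
  if (loading_factor <= 0) abort("loading_factor must be > 0")
  if (noise_cv < 0) abort("noise_cv must be >= 0")
  if (length(pi_range) != 2L || pi_range[1] > pi_range[2] ||
      pi_range[1] < 0 || pi_range[2] > 1) {
    abort("pi_range must be an interval within [0, 1]")
  }
  if (stress_runoff < 0 || stress_runoff > 1) {
    abort("stress_runoff must be in [0, 1]")
  }
  if (frac_pi_change < 0 || frac_pi_change > 1) {
    abort("frac_pi_change must be in [0, 1]")
  }
  bad_c <- setdiff(conditions, CONDITIONS)
  if (length(bad_c)) abort(paste0("unknown condition(s): ",
                                  paste(bad_c, collapse = ", ")))
  cfg <- list(n_proteins = as.integer(n_proteins),
              n_replicates = as.integer(n_replicates),
              conditions = conditions,
              loading_factor = loading_factor,
              archetype_mix = mix,
              pi_range = pi_range,
              noise_cv = noise_cv,
              dropout = isTRUE(dropout),
              dropout_midpoint = dropout_midpoint,
              dropout_slope = dropout_slope,
              stress_runoff = stress_runoff,
              frac_pi_change = frac_pi_change,
              pi_change_fold = pi_change_fold,
              mean_log2_abundance = mean_log2_abundance,
              sd_log2_abundance = sd_log2_abundance,
              seed = as.integer(seed))
  structure(cfg, class = "sim_config")
}

# Base fraction weights (F1..F5) per archetype, before any stress shift.
archetype_weights <- function(archetype) {
  switch(archetype,
         rp_like = c(0.10, 0.15, 0.20, 0.25, 0.30),
         polysome_retained = c(0.05, 0.10, 0.20, 0.30, 0.35),
         even = rep(0.2, 5),
         monosome_shifted = c(0.15, 0.20, 0.25, 0.20, 0.20),
         low_association = rep(0.2, 5),
         abort(paste0("unknown archetype: ", archetype)))
}

# Move `runoff` of the polysomal (F2-F5) weight into F1.
shift_to_monosome <- function(w, runoff) {
  moved <- runoff * sum(w[2:5])
  w[2:5] <- w[2:5] * (1 - runoff)
  w[1] <- w[1] + moved
  w
}

#' Simulate a polysome profiling LFQ experiment
#'
#' Generates a complete synthetic dataset: a long LFQ intensity table over
#' (condition, fraction, replicate), a functional-category annotation table
#' (archetypes map to categories: `rp_like` to RP, `monosome_shifted` to TF,
#' `polysome_retained` to RBP, `even` and `low_association` to nonRBP; the
#' first RP is flagged as the reference marker), and a ground-truth table
#' with each protein's archetype, per-condition engaged fraction `pi` and
#' fraction weights. Identical configurations (including the seed) produce
#' bit-identical output.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `"polysome_sim"` with elements `lfq`,
#'   `annotations`, `truth` (tibbles) and `config`.
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_proteins
  ids <- sprintf("P%04d", seq_len(n))

  counts <- round(config$archetype_mix * n)
  # rounding drift absorbed by the largest class
  counts[which.max(counts)] <- counts[which.max(counts)] + n - sum(counts)
  archetype <- sample(rep(names(counts), counts))

  category <- c(rp_like = "RP", monosome_shifted = "TF",
                polysome_retained = "RBP", even = "nonRBP",
                low_association = "nonRBP")[archetype]
  marker <- ids[which(category == "RP")[1]]
  annotations <- tibble(protein_id = ids, category = unname(category),
                        is_rp_marker = ids == marker & !is.na(marker))

  A <- 2^rnorm(n, config$mean_log2_abundance, config$sd_log2_abundance)
  pi_base <- runif(n, config$pi_range[1], config$pi_range[2])
  low <- archetype == "low_association"
  pi_base[low] <- runif(sum(low), 0.02, 0.10)
  # Planted stress changes are drawn among non-RP proteins: RPs are the
  # non-changing anchor that defines the null in this design.
  changed <- rep(FALSE, n)
  if (config$frac_pi_change > 0) {
    eligible <- which(archetype != "rp_like")
    n_changed <- round(config$frac_pi_change * n)
    if (n_changed > length(eligible)) {
      abort("frac_pi_change exceeds the non-RP proportion")
    }
    changed[sample(eligible, n_changed)] <- TRUE
  }

  sigma <- if (config$noise_cv > 0) sqrt(log(1 + config$noise_cv^2)) else 0

  per_condition <- purrr::map(config$conditions, function(cond) {
    stressed <- cond != "unstressed"
    w <- t(vapply(archetype, archetype_weights, numeric(5)))
    dimnames(w) <- NULL
    if (stressed && config$stress_runoff > 0) {
      shifting <- archetype %in% c("rp_like", "monosome_shifted")
      w[shifting, ] <- t(apply(w[shifting, , drop = FALSE], 1,
                               shift_to_monosome, config$stress_runoff))
    }
    pi_c <- pi_base
    if (stressed) pi_c[changed] <- pmin(1, pi_c[changed] * config$pi_change_fold)

    expected <- cbind(T = A / config$loading_factor,
                      A * pi_c * w)
    colnames(expected) <- FRACTIONS

    truth <- tibble(protein_id = ids, condition = cond,
                    archetype = archetype, pi = pi_c,
                    pi_changed = changed & stressed,
                    w_F1 = w[, 1], w_F2 = w[, 2], w_F3 = w[, 3],
                    w_F4 = w[, 4], w_F5 = w[, 5])

    reps <- purrr::map(seq_len(config$n_replicates), function(r) {
      obs <- expected
      if (sigma > 0) {
        obs <- obs * exp(matrix(rnorm(length(obs), 0, sigma), nrow = n))
      }
      if (config$dropout) {
        p_drop <- stats::plogis(config$dropout_slope *
                                  (config$dropout_midpoint - log2(obs)))
        obs[matrix(runif(length(obs)), nrow = n) < p_drop] <- 0
      }
      tibble(protein_id = rep(ids, times = 6L),
             condition = cond,
             fraction = rep(FRACTIONS, each = n),
             replicate = r,
             intensity = as.vector(obs))
    })
    list(lfq = bind_rows(reps), truth = truth)
  })

  out <- list(lfq = bind_rows(purrr::map(per_condition, "lfq")),
              annotations = annotations,
              truth = bind_rows(purrr::map(per_condition, "truth")),
              config = config)
  structure(out, class = "polysome_sim")
}

#' @exportS3Method base::print
print.polysome_sim <- function(x, ...) {
  cat("<polysome_sim> ", x$config$n_proteins, " proteins, ",
      length(x$config$conditions), " condition(s), ",
      x$config$n_replicates, " replicates; seed ", x$config$seed, "\n",
      sep = "")
  invisible(x)
}

#' Simulate positional peptide intensities
#'
#' Generates a peptide-level table for the nascent-chain control analysis:
#' peptides of length 7-25 tiled at random positions over each protein, with
#' per-sample intensities for the total lysate and each gradient fraction of
#' one condition. With `bias_strength = 0` the expected positional intensity
#' is uniform in both sample types; with `bias_strength = b > 0` the
#' fraction-sample expectation is tilted toward the N-terminus by an
#' exponential ramp `exp(-b * position / length)` while totals stay uniform,
#' emulating a nascent-chain contribution to the gradient signal.
#'
#' Each peptide draws a base (ionization-efficiency) intensity shared by all
#' of its samples when `shared_base = TRUE` (realistic: peptide flyability
#' is a property of the peptide), or independently per sample otherwise;
#' log-normal noise with coefficient of variation `noise_cv` multiplies in.
#'
#' @param config A [sim_config()] (supplies `noise_cv` and the seed).
#' @param proteins Character vector of protein IDs; default generates
#'   `config$n_proteins` fresh IDs.
#' @param bias_strength Non-negative ramp strength `b` (0 = no bias).
#' @param peptides_per_protein Mean peptides tiled per protein (default
#'   20); per-protein counts are Poisson, proportional to length.
#' @param length_range Protein length range in residues (default 200-600).
#' @param condition Condition the fraction samples belong to.
#' @param fractions Gradient fractions simulated alongside the total.
#' @param shared_base Share each peptide's base intensity across samples.
#' @param base_log2_sd Log2 standard deviation of the per-peptide base
#'   intensity (default 1; small values give near-uniform peptide weights).
#' @return A list with tibbles `peptides` (long:
#'   `protein_id, start, end, condition, fraction, replicate, intensity`),
#'   `lengths` (`protein_id, length`) and `truth`
#'   (`protein_id, biased`).
#' @export
simulate_peptides <- function(config, proteins = NULL, bias_strength = 0,
                              peptides_per_protein = 20,
                              length_range = c(200, 600),
                              condition = "unstressed",
                              fractions = RIBO_FRACTIONS,
                              shared_base = TRUE, base_log2_sd = 1) {
  stopifnot(inherits(config, "sim_config"))
  if (bias_strength < 0) abort("bias_strength must be >= 0")
  set.seed(config$seed + 104729L)  # stage-specific child seed
  proteins <- proteins %||% sprintf("P%04d", seq_len(config$n_proteins))
  n <- length(proteins)
  L <- sample(length_range[1]:length_range[2], n, replace = TRUE)
  sigma <- if (config$noise_cv > 0) sqrt(log(1 + config$noise_cv^2)) else 0
  samples <- c("T", fractions)

  # peptide counts scale with protein length (longer proteins yield more
  # tryptic peptides) with Poisson variation, so the dataset has the count
  # and coverage spread the median-based eligibility filter expects
  n_pep <- pmax(3L, stats::rpois(n, peptides_per_protein * L / mean(L)))

  total <- sum(n_pep)
  pid <- rep.int(seq_len(n), n_pep)
  len <- sample(7:25, total, replace = TRUE)
  start <- floor(runif(total) * (L[pid] - len + 1L)) + 1L
  end <- start + len - 1L
  ramp <- exp(-bias_strength * ((start + end) / 2) / L[pid])
  base <- 2^rnorm(total, 18, base_log2_sd)

  per_sample <- purrr::map(samples, function(s) {
    b <- if (shared_base) base else 2^rnorm(total, 18, base_log2_sd)
    expected <- if (s == "T") b else b * ramp
    n_obs <- total * config$n_replicates
    obs <- rep(expected, times = config$n_replicates)
    if (sigma > 0) obs <- obs * exp(rnorm(n_obs, 0, sigma))
    tibble(protein_id = rep(proteins[pid], times = config$n_replicates),
           start = rep(as.integer(start), times = config$n_replicates),
           end = rep(as.integer(end), times = config$n_replicates),
           condition = condition, fraction = s,
           replicate = rep(seq_len(config$n_replicates), each = total),
           intensity = obs)
  })

  list(peptides = bind_rows(per_sample),
       lengths = tibble(protein_id = proteins, length = L),
       truth = tibble(protein_id = proteins, biased = bias_strength > 0))
}
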