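#' Pipeline run configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]. Either
#' `simulate` (a [sim_config()]) or the three input paths must be supplied.
#' All stage parameters default to the values of the original analysis:
#' detection in at least 2 replicates, loading factor 30, 14 clusters,
#' alpha 0.05, enrichment-class threshold tau 0.5 log2 units.
#'
#' @param out_dir Output directory for result TSVs and the manifest.
#' @param simulate Optional [sim_config()]; when given, data are simulated.
#' @param protein_groups,annotations,peptides Optional input paths (used
#'   when `simulate` is `NULL`; `peptides` additionally needs `lengths`).
#' @param lengths Optional path to a protein-length TSV
#'   (`protein_id`, `length`).
#' @param sample_map Optional sample map data frame for the readers.
#' @param min_reps Detection replicate threshold.
#' @param loading_factor Fractions-to-totals loading ratio.
#' @param k Cluster count.
#' @param alpha Significance level.
#' @param tau Enrichment-class threshold (log2).
#' @param reference_fractions Centering fractions for profiles.
#' @param bias_strength Peptide-bias ramp used when simulating peptides.
#' @param n_perm Permutation iterations for the peptide test (0 = off).
#' @param seed Single integer seed governing every random draw.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(out_dir,
                       simulate = NULL,
                       protein_groups = NULL, annotations = NULL,
                       peptides = NULL, lengths = NULL,
                       sample_map = NULL,
                       min_reps = 2, loading_factor = 30, k = 14,
                       alpha = 0.05, tau = 0.5,
                       reference_fractions = c("F1", "F2", "F3", "F4"),
                       bias_strength = 0, n_perm = 0,
                       seed = 1L) {
  if (is.null(simulate) && (is.null(protein_groups) || is.null(annotations))) {
    abort("supply either a sim_config or protein_groups + annotations paths")
  }
  structure(list(out_dir = out_dir, simulate = simulate,
                 protein_groups = protein_groups, annotations = annotations,
                 peptides = peptides, lengths = lengths,
                 sample_map = sample_map,
                 min_reps = min_reps, loading_factor = loading_factor,
                 k = k, alpha = alpha, tau = tau,
                 reference_fractions = reference_fractions,
                 bias_strength = bias_strength, n_perm = n_perm,
                 seed = as.integer(seed)),
            class = "run_config")
}

# Wrap a stage so failures name the stage and abort.
run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ",
                 conditionMessage(e)))
  })
}

#' Run the full polysome-proteomics pipeline
#'
#' Executes simulate (or read) -> detect -> overlaps -> associate ->
#' profile -> cluster -> peptide-bias, writes every result table as TSV
#' with a JSON manifest (and the dendrogram in Newick format) to
#' `config$out_dir`, and returns the result bundle invisibly. With a fixed
#' seed the bundle is byte-identical between runs. Each stage failure
#' aborts with the stage named in the error message.
#'
#' @param config A [run_config()] object.
#' @return Invisibly, a named list with elements `lfq`, `annotations`,
#'   `truth` (when simulated), `detection`, `overlaps`, `replicate_qc`,
#'   `association`, `profiles`, `clusters`, `cluster_classes`,
#'   `peptide_bias` (when peptide data are available).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))

  dat <- if (!is.null(config$simulate)) {
    run_stage("simulate", {
      cfg <- config$simulate
      cfg$seed <- config$seed
      sim <- simulate_experiment(cfg)
      pep <- simulate_peptides(cfg, proteins = sim$annotations$protein_id,
                               bias_strength = config$bias_strength)
      list(lfq = sim$lfq, annotations = sim$annotations, truth = sim$truth,
           peptides = pep$peptides, lengths = pep$lengths)
    })
  } else {
    run_stage("read", {
      lfq <- read_protein_groups(config$protein_groups, config$sample_map)
      ann <- read_annotations(config$annotations)
      pep <- NULL; lens <- NULL
      if (!is.null(config$peptides)) {
        if (is.null(config$lengths)) {
          abort("peptide input requires a lengths table")
        }
        pep <- read_peptides(config$peptides, config$sample_map)
        lens <- readr::read_tsv(config$lengths, show_col_types = FALSE)
      }
      list(lfq = lfq, annotations = ann, truth = NULL,
           peptides = pep, lengths = lens)
    })
  }

  detection <- run_stage("detect",
                         detect_proteins(dat$lfq, config$min_reps))
  conds <- intersect(CONDITIONS, unique(dat$lfq$condition))
  overlaps <- run_stage("overlaps", bind_rows(
    overlap_counts(detection, c("F1", "F2", "F3", "F4"), conds),
    overlap_counts(detection, c("F1", "F2", "F3", "F4", "F5"), conds)
  ))
  replicate_qc <- run_stage("replicate_qc", replicate_correlation(dat$lfq))

  association <- run_stage("associate", {
    if (length(conds) > 1L && "unstressed" %in% conds) {
      # a degenerate RP null (e.g. exactly reproducible noiseless data)
      # falls back to association estimates without significance calls
      tryCatch(
        association_test(dat$lfq, dat$annotations,
                         loading_factor = config$loading_factor,
                         alpha = config$alpha),
        error = function(e) {
          if (!grepl("degenerate|fewer than 3", conditionMessage(e))) {
            stop(e)
          }
          warn(paste0("RP null not fittable (", conditionMessage(e),
                      "); reporting associations without p-values"))
          delta_fs_t(ribosome_association(dat$lfq, config$loading_factor))
        })
    } else {
      ribosome_association(dat$lfq, config$loading_factor)
    }
  })

  profiles <- run_stage("profile", {
    core <- overlap_counts(detection, c("F1", "F2", "F3", "F4"),
                           conds)$proteins[[1]]
    enrichment_profiles(dat$lfq, proteins = core,
                        reference_fractions = config$reference_fractions)
  })
  clusters <- run_stage("cluster", {
    k <- min(config$k, nrow(profiles))
    cluster_profiles(profiles, k = k, association = association)
  })
  classes <- run_stage("classify", classify_clusters(clusters, config$tau))

  peptide_bias <- if (!is.null(dat$peptides)) {
    run_stage("peptide-bias",
              peptide_bias_test(dat$peptides, dat$lengths,
                                alpha = config$alpha,
                                n_perm = config$n_perm,
                                seed = config$seed + 7L))
  } else NULL

  tables <- list(detection = detection,
                 overlaps = overlaps |> select(-"proteins"),
                 replicate_qc = replicate_qc,
                 association = association,
                 profiles = profiles,
                 cluster_labels = clusters$labels,
                 cluster_classes = classes)
  if (!is.null(dat$truth)) tables$truth <- dat$truth
  if (!is.null(peptide_bias)) tables$peptide_bias <- peptide_bias

  run_stage("write", {
    cfg_manifest <- config
    cfg_manifest$sample_map <- NULL
    # keep the manifest free of run-specific paths so identical analyses
    # produce identical bundles
    cfg_manifest$out_dir <- NULL
    class(cfg_manifest) <- NULL
    if (!is.null(cfg_manifest$simulate)) {
      cfg_manifest$simulate <- unclass(cfg_manifest$simulate)
    }
    write_results(tables, config$out_dir, config = cfg_manifest,
                  seed = config$seed)
    export_dendrogram(clusters, file.path(config$out_dir, "dendrogram.nwk"))
  })

  invisible(c(dat[!vapply(dat, is.null, logical(1))],
              list(detection = detection, overlaps = overlaps,
                   replicate_qc = replicate_qc, association = association,
                   profiles = profiles, clusters = clusters,
                   cluster_classes = classes,
                   peptide_bias = peptide_bias)))
}
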