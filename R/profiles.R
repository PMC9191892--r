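#' Polysome enrichment profiles
#'
#' Builds the normalized per-protein enrichment profile matrix: for each
#' protein and each requested (condition, fraction) column, the replicate
#' mean of log2 LFQ intensity (positive replicates only; a geometric mean
#' on the raw scale), centred by subtracting the protein's own mean over
#' the unstressed reference fractions. Proteins lacking a positive
#' replicate in any required cell are excluded (never imputed), with a
#' message giving the count.
#'
#' @param lfq Long intensity tibble.
#' @param conditions Conditions included as columns (default: all present).
#' @param fractions Fractions included as columns (default `T`, `F1`-`F4`,
#'   the columns displayed in the clustered heat map).
#' @param reference_condition Condition supplying the centering reference
#'   (default `"unstressed"`).
#' @param reference_fractions Fractions of the reference condition averaged
#'   for centering (default `F1`-`F4`; set to `F1`-`F5` for the
#'   all-ribosomal-fractions variant).
#' @param proteins Optional protein subset.
#' @return A wide tibble: `protein_id` plus one numeric column per
#'   `"<condition>_<fraction>"`. Attributes `"columns"` (tibble mapping
#'   column name to condition/fraction) and `"reference_columns"` record
#'   the layout.
#' @export
enrichment_profiles <- function(lfq, conditions = NULL,
                                fractions = c("T", "F1", "F2", "F3", "F4"),
                                reference_condition = "unstressed",
                                reference_fractions = c("F1", "F2", "F3", "F4"),
                                proteins = NULL) {
  check_lfq(lfq)
  conditions <- conditions %||%
    intersect(CONDITIONS, unique(lfq$condition))
  if (!reference_condition %in% conditions) {
    abort("reference_condition must be among the profiled conditions")
  }
  if (!all(reference_fractions %in% fractions)) {
    abort("reference_fractions must be a subset of fractions")
  }
  sub <- lfq |>
    filter(.data$condition %in% conditions, .data$fraction %in% fractions)
  if (!is.null(proteins)) sub <- sub |> filter(.data$protein_id %in% proteins)

  cells <- sub |>
    group_by(.data$protein_id, .data$condition, .data$fraction) |>
    summarise(log2_mean = if (any(.data$intensity > 0)) {
      mean(log2(.data$intensity[.data$intensity > 0]))
    } else NA_real_, .groups = "drop")

  n_cells <- length(conditions) * length(fractions)
  complete <- cells |>
    group_by(.data$protein_id) |>
    filter(sum(!is.na(.data$log2_mean)) == n_cells) |>
    ungroup()
  n_dropped <- n_distinct(cells$protein_id) - n_distinct(complete$protein_id)
  if (n_dropped > 0) {
    inform(paste0("excluded ", n_dropped,
                  " protein(s) not quantified in every profile cell"))
  }
  if (nrow(complete) == 0L) abort("no protein has a complete profile")

  centred <- complete |>
    group_by(.data$protein_id) |>
    mutate(value = .data$log2_mean -
             mean(.data$log2_mean[.data$condition == reference_condition &
                                    .data$fraction %in% reference_fractions])) |>
    ungroup()

  col_map <- tidyr::expand_grid(condition = conditions, fraction = fractions) |>
    mutate(column = paste0(.data$condition, "_", .data$fraction))
  wide <- centred |>
    mutate(column = paste0(.data$condition, "_", .data$fraction)) |>
    select("protein_id", "column", "value") |>
    tidyr::pivot_wider(names_from = "column", values_from = "value") |>
    select("protein_id", dplyr::all_of(col_map$column)) |>
    arrange(.data$protein_id)

  attr(wide, "columns") <- col_map
  attr(wide, "reference_columns") <-
    paste0(reference_condition, "_", reference_fractions)
  wide
}

#' Marker-relative ribosomal-protein profiles
#'
#' Normalizes each protein's replicate-mean LFQ intensity to the reference
#' ribosomal-protein marker (the Rps3/uS3 group in the original design) on
#' a fraction-by-fraction basis, and then to the protein's own
#' unstressed-F1 value:
#' `value(p, c, f) = [LFQ(p,c,f) / LFQ(m,c,f)] / [LFQ(p,u,F1) / LFQ(m,u,F1)]`.
#' The marker itself therefore maps to 1 everywhere, as does any protein
#' exactly proportional to it.
#'
#' @param lfq Long intensity tibble.
#' @param annotations Annotation tibble whose `is_rp_marker` column flags
#'   exactly one marker (ignored when `marker` is given).
#' @param marker Protein ID of the reference marker.
#' @param conditions,fractions Cells profiled (default all conditions,
#'   F1-F5).
#' @return A long tibble `protein_id`, `condition`, `fraction`,
#'   `rel_intensity` (`NA` where the protein is not quantified). Errors,
#'   naming the cell, if the marker is not quantified in any used cell.
#' @export
rp_relative_profile <- function(lfq, annotations = NULL, marker = NULL,
                                conditions = NULL,
                                fractions = RIBO_FRACTIONS) {
  check_lfq(lfq)
  marker <- marker %||% rp_marker_id(annotations)
  conditions <- conditions %||% intersect(CONDITIONS, unique(lfq$condition))

  cells <- lfq |>
    filter(.data$condition %in% conditions, .data$fraction %in% fractions) |>
    group_by(.data$protein_id, .data$condition, .data$fraction) |>
    summarise(raw_mean = if (any(.data$intensity > 0)) {
      mean(.data$intensity[.data$intensity > 0])
    } else NA_real_, .groups = "drop")

  mk <- cells |>
    filter(.data$protein_id == marker) |>
    select("condition", "fraction", marker_mean = "raw_mean")
  missing_cells <- mk |> filter(is.na(.data$marker_mean))
  grid <- tidyr::expand_grid(condition = conditions, fraction = fractions)
  absent <- anti_join(grid, mk, by = c("condition", "fraction"))
  if (nrow(missing_cells) || nrow(absent)) {
    bad <- bind_rows(missing_cells |> select("condition", "fraction"), absent)
    abort(paste0("marker '", marker, "' not quantified in cell(s): ",
                 paste(paste0(bad$condition, "/", bad$fraction),
                       collapse = ", ")))
  }

  ratios <- cells |>
    inner_join(mk, by = c("condition", "fraction")) |>
    mutate(ratio = .data$raw_mean / .data$marker_mean)
  ref <- ratios |>
    filter(.data$condition == "unstressed", .data$fraction == "F1") |>
    select("protein_id", ref_ratio = "ratio")
  ratios |>
    left_join(ref, by = "protein_id") |>
    mutate(rel_intensity = .data$ratio / .data$ref_ratio) |>
    select("protein_id", "condition", "fraction", "rel_intensity")
}

#' Cluster polysome enrichment profiles
#'
#' Hierarchical clustering of the normalized enrichment profiles with
#' Euclidean distance and complete linkage (deterministic tie-breaking, see
#' [complete_linkage()]), cut to exactly `k` clusters. Cluster labels are
#' renumbered along the ribosome-association gradient: cluster 1 has the
#' lowest mean member association, cluster `k` the highest (matching the
#' low-to-high ordering of the original 14-cluster analysis). Without an
#' association table, the cluster's mean profile value over the ribosomal
#' fraction columns is used as the ordering proxy.
#'
#' @param profiles Wide profile tibble from [enrichment_profiles()].
#' @param k Number of clusters (default 14).
#' @param association Optional output of [ribosome_association()]; member
#'   mean `log2_fs_t` (averaged over conditions) orders the labels.
#' @param include_totals Include the `T` columns in the distance
#'   computation (default `TRUE`).
#' @return An object of class `"profile_clusters"`: list with `labels`
#'   (tibble `protein_id`, `cluster`), `hclust`, `k`, `summary` (per-cluster
#'   size and mean profile), and the profile matrix used.
#' @export
cluster_profiles <- function(profiles, k = 14, association = NULL,
                             include_totals = TRUE) {
  cols <- setdiff(names(profiles), "protein_id")
  if (!include_totals) cols <- cols[!grepl("_T$", cols)]
  mat <- as.matrix(profiles[cols])
  rownames(mat) <- profiles$protein_id
  if (anyNA(mat)) abort("profiles contain missing cells")
  if (k > nrow(mat)) abort("k exceeds the number of proteins")

  hc <- complete_linkage(stats::dist(mat, method = "euclidean"))
  raw_labels <- cutree(hc, k = k)

  rank_value <- if (!is.null(association)) {
    assoc <- association |>
      group_by(.data$protein_id) |>
      summarise(value = mean(.data$log2_fs_t, na.rm = TRUE), .groups = "drop")
    setNames(assoc$value, assoc$protein_id)[rownames(mat)]
  } else {
    frac_cols <- cols[!grepl("_T$", cols)]
    rowMeans(mat[, frac_cols, drop = FALSE])
  }
  cluster_rank <- tapply(rank_value, raw_labels, mean, na.rm = TRUE)
  # ascending association: cluster 1 = least ribosome-associated
  new_label <- match(raw_labels, as.integer(names(sort(cluster_rank))))

  labels <- tibble(protein_id = rownames(mat), cluster = new_label)
  summary <- bind_cols(labels, as_tibble(mat)) |>
    group_by(.data$cluster) |>
    summarise(size = n(),
              across(dplyr::all_of(cols), mean), .groups = "drop")

  structure(list(labels = labels, hclust = hc, k = k, summary = summary,
                 profiles = profiles, columns = attr(profiles, "columns"),
                 distance_columns = cols),
            class = "profile_clusters")
}

#' @exportS3Method base::print
print.profile_clusters <- function(x, ...) {
  cat("<profile_clusters> ", nrow(x$labels), " proteins in ", x$k,
      " clusters (Euclidean, complete linkage)\n", sep = "")
  print(x$summary |> select("cluster", "size"))
  invisible(x)
}

#' @rdname cluster_profiles
#' @param x A `profile_clusters` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.profile_clusters <- function(x, ...) x$labels

#' @rdname cluster_profiles
#' @exportS3Method generics::glance
glance.profile_clusters <- function(x, ...) {
  tibble(n_proteins = nrow(x$labels), k = x$k,
         max_height = max(x$hclust$height),
         min_cluster_size = min(x$summary$size),
         max_cluster_size = max(x$summary$size))
}

#' Classify clusters by stress enrichment pattern
#'
#' Labels each cluster `Mono`, `Poly` or `Even` from its mean stress-
#' condition profile: `Mono` (monosome-enriched) when the mean F1 value
#' exceeds the mean over F2-F4 by more than `tau` log2 units, `Poly`
#' (polysome-enriched) when it falls below by more than `tau`, otherwise
#' `Even`.
#'
#' @param clusters A [cluster_profiles()] result.
#' @param tau Log2 threshold separating the classes (default 0.5).
#' @param stress_conditions Conditions averaged for the comparison.
#' @return A tibble `cluster`, `size`, `mean_f1`, `mean_f2_f4`,
#'   `enrichment_class`.
#' @export
classify_clusters <- function(clusters, tau = 0.5,
                              stress_conditions = c("H2O2", "3AT")) {
  stopifnot(inherits(clusters, "profile_clusters"))
  cols <- setdiff(names(clusters$summary), c("cluster", "size"))
  f1_cols <- cols[grepl("_F1$", cols) &
                    sub("_F1$", "", cols) %in% stress_conditions]
  f24_cols <- cols[grepl("_F[234]$", cols) &
                     sub("_F[234]$", "", cols) %in% stress_conditions]
  if (!length(f1_cols) || !length(f24_cols)) {
    abort("profiles lack the stress-condition F1-F4 columns")
  }
  clusters$summary |>
    mutate(mean_f1 = rowMeans(across(dplyr::all_of(f1_cols))),
           mean_f2_f4 = rowMeans(across(dplyr::all_of(f24_cols))),
           enrichment_class = case_when(
             .data$mean_f1 - .data$mean_f2_f4 > tau ~ "Mono",
             .data$mean_f2_f4 - .data$mean_f1 > tau ~ "Poly",
             TRUE ~ "Even"
           )) |>
    select("cluster", "size", "mean_f1", "mean_f2_f4", "enrichment_class")
}

#' Export a cluster dendrogram as Newick
#'
#' @param clusters A [cluster_profiles()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_dendrogram <- function(clusters, path) {
  stopifnot(inherits(clusters, "profile_clusters"))
  phy <- ape::as.phylo(clusters$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}
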