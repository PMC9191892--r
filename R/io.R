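#' Read a MaxQuant-style proteinGroups table
#'
#' Parses a tab-separated protein-group quantification table (the
#' `proteinGroups.txt` dialect: one row per protein group, one
#' `"LFQ intensity <sample>"` column per sample) into a long intensity
#' tibble. Rows flagged as potential contaminant, reverse decoy, or only
#' identified by site are removed at read time (MaxQuant hygiene), and an
#' LFQ value of 0 is kept as-is with the meaning "not quantified".
#'
#' @param path Path to a tab-separated file.
#' @param sample_map Optional data frame mapping column names to samples
#'   (columns `column`, `condition`, `fraction`, `replicate`). When `NULL`,
#'   the `"LFQ intensity "` suffixes are parsed with [parse_sample_names()].
#' @param id_col Name of the protein-group identifier column. When `NULL`,
#'   the first of `"Majority protein IDs"`, `"Protein IDs"`, `"protein_id"`
#'   present is used.
#' @param filter_flagged Remove contaminant / reverse / site-only rows
#'   (default `TRUE`).
#' @return A tibble with columns `protein_id`, `condition`, `fraction`,
#'   `replicate`, `intensity`, one row per protein x sample. Unmapped LFQ
#'   columns are ignored with a warning.
#' @export
read_protein_groups <- function(path, sample_map = NULL, id_col = NULL,
                                filter_flagged = TRUE) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  id_candidates <- c("Majority protein IDs", "Protein IDs", "protein_id")
  id_col <- id_col %||% id_candidates[id_candidates %in% names(tab)][1]
  if (is.na(id_col) || is.null(id_col) || !id_col %in% names(tab)) {
    abort("no protein-group ID column found (expected one of: Majority protein IDs, Protein IDs, protein_id)")
  }

  n_in <- nrow(tab)
  if (filter_flagged) {
    flag_cols <- intersect(
      c("Potential contaminant", "Reverse", "Only identified by site"),
      names(tab))
    if (length(flag_cols)) {
      flagged <- Reduce(`|`, lapply(flag_cols, function(cl) {
        v <- tab[[cl]]
        !is.na(v) & v == "+"
      }))
      tab <- tab[!flagged, , drop = FALSE]
      if (sum(flagged) > 0) {
        inform(paste0("removed ", sum(flagged),
                      " flagged row(s) (contaminant/reverse/site-only)"))
      }
    }
  }

  lfq_cols <- grep("^LFQ intensity ", names(tab), value = TRUE)
  if (is.null(sample_map)) {
    sm <- parse_sample_names(sub("^LFQ intensity ", "", lfq_cols))
    sm$column <- lfq_cols
    unmapped <- sm$column[is.na(sm$condition)]
    sm <- sm[!is.na(sm$condition), , drop = FALSE]
  } else {
    sm <- check_sample_map(sample_map)
    absent <- setdiff(sm$column, names(tab))
    if (length(absent)) {
      abort(paste0("sample_map names column(s) absent from the file: ",
                   paste(absent, collapse = ", ")))
    }
    unmapped <- setdiff(lfq_cols, sm$column)
  }
  if (length(unmapped)) {
    warn(paste0("ignoring ", length(unmapped), " unmapped LFQ column(s): ",
                paste(unmapped, collapse = ", ")))
  }
  if (nrow(sm) == 0L) abort("no LFQ sample columns mapped")

  ids <- tab[[id_col]]
  if (anyDuplicated(ids)) {
    dups <- unique(ids[duplicated(ids)])
    abort(paste0("duplicate protein IDs after filtering: ",
                 paste(dups, collapse = ", ")))
  }

  long <- purrr::pmap(sm, function(column, condition, fraction, replicate) {
    vals <- suppressWarnings(as.numeric(tab[[column]]))
    if (anyNA(vals)) abort(paste0("non-numeric LFQ values in column ", column))
    tibble(protein_id = ids, condition = condition, fraction = fraction,
           replicate = as.integer(replicate), intensity = vals)
  })
  out <- bind_rows(long)
  check_lfq(out)
  out
}

#' Write a long intensity table as a proteinGroups-style TSV
#'
#' Inverse of [read_protein_groups()]: widens the long tibble into one
#' `"LFQ intensity <condition>_<fraction>_rep<k>"` column per sample.
#' Numbers are serialized at full (round-trip) precision.
#'
#' @param lfq Long intensity tibble (see [read_protein_groups()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_protein_groups <- function(lfq, path) {
  check_lfq(lfq)
  wide <- lfq |>
    mutate(column = paste0("LFQ intensity ",
                           sample_name(.data$condition, .data$fraction,
                                       .data$replicate)),
           value = sprintf("%.17g", .data$intensity)) |>
    select("protein_id", "column", "value") |>
    tidyr::pivot_wider(names_from = "column", values_from = "value")
  wide <- wide |> rename(`Majority protein IDs` = "protein_id")
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' Read a peptide table with residue positions
#'
#' Parses a tab-separated peptide table: one row per peptide with its
#' protein group, 1-based inclusive start/end residue positions, and one
#' `"Intensity <sample>"` column per sample. Rows with `end < start` are
#' dropped with a warning giving the count.
#'
#' @inheritParams read_protein_groups
#' @return A long tibble with columns `protein_id`, `start`, `end`,
#'   `condition`, `fraction`, `replicate`, `intensity`.
#' @export
read_peptides <- function(path, sample_map = NULL) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  id_candidates <- c("Leading razor protein", "Proteins", "protein_id")
  id_col <- id_candidates[id_candidates %in% names(tab)][1]
  start_col <- c("Start position", "start")[c("Start position", "start") %in% names(tab)][1]
  end_col <- c("End position", "end")[c("End position", "end") %in% names(tab)][1]
  if (is.na(id_col) || is.na(start_col) || is.na(end_col)) {
    abort("peptide table needs a protein ID column and start/end position columns")
  }
  starts <- suppressWarnings(as.numeric(tab[[start_col]]))
  ends <- suppressWarnings(as.numeric(tab[[end_col]]))
  if (anyNA(starts) || anyNA(ends)) {
    bad <- which(is.na(starts) | is.na(ends))
    abort(paste0("non-numeric peptide positions at row(s): ",
                 paste(head(bad, 10), collapse = ", ")))
  }
  rev_span <- ends < starts
  if (any(rev_span)) {
    warn(paste0("dropped ", sum(rev_span), " peptide row(s) with end < start"))
    tab <- tab[!rev_span, , drop = FALSE]
    starts <- starts[!rev_span]
    ends <- ends[!rev_span]
  }

  int_cols <- grep("^Intensity ", names(tab), value = TRUE)
  if (is.null(sample_map)) {
    sm <- parse_sample_names(sub("^Intensity ", "", int_cols))
    sm$column <- int_cols
    sm <- sm[!is.na(sm$condition), , drop = FALSE]
  } else {
    sm <- check_sample_map(sample_map)
    absent <- setdiff(sm$column, names(tab))
    if (length(absent)) {
      abort(paste0("sample_map names column(s) absent from the file: ",
                   paste(absent, collapse = ", ")))
    }
  }
  if (nrow(sm) == 0L) abort("no peptide intensity columns mapped")

  long <- purrr::pmap(sm, function(column, condition, fraction, replicate) {
    vals <- suppressWarnings(as.numeric(tab[[column]]))
    if (anyNA(vals)) abort(paste0("non-numeric intensities in column ", column))
    tibble(protein_id = tab[[id_col]], start = as.integer(starts),
           end = as.integer(ends), condition = condition,
           fraction = fraction, replicate = as.integer(replicate),
           intensity = vals)
  })
  out <- bind_rows(long)
  if (any(out$intensity < 0)) abort("peptide intensities must be >= 0")
  out
}

#' Write a peptide table
#'
#' Inverse of [read_peptides()].
#'
#' @param peptides Long peptide tibble (see [read_peptides()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_peptides <- function(peptides, path) {
  wide <- peptides |>
    mutate(column = paste0("Intensity ",
                           sample_name(.data$condition, .data$fraction,
                                       .data$replicate)),
           value = sprintf("%.17g", .data$intensity)) |>
    select("protein_id", "start", "end", "column", "value") |>
    tidyr::pivot_wider(names_from = "column", values_from = "value")
  wide <- wide |> rename(`Leading razor protein` = "protein_id",
                         `Start position` = "start", `End position` = "end")
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' Read a protein annotation table
#'
#' Parses a tab-separated table mapping protein groups to functional
#' categories (`RP`, `TF`, `RBP`, `nonRBP`) with an optional logical
#' `is_rp_marker` column designating the reference ribosomal protein
#' (the Rps3/uS3 group in the original design) used for marker-relative
#' profiles.
#'
#' @param path Path to a tab-separated file with columns `protein_id`,
#'   `category` and optionally `is_rp_marker`.
#' @return A tibble with columns `protein_id`, `category`, `is_rp_marker`.
#' @export
read_annotations <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!all(c("protein_id", "category") %in% names(tab))) {
    abort("annotation table needs columns protein_id and category")
  }
  bad <- setdiff(unique(tab$category), CATEGORIES)
  if (length(bad)) {
    abort(paste0("unknown categor(ies): ", paste(bad, collapse = ", "),
                 " (valid: ", paste(CATEGORIES, collapse = ", "), ")"))
  }
  marker <- if ("is_rp_marker" %in% names(tab)) {
    toupper(tab$is_rp_marker) %in% c("TRUE", "T", "1", "YES")
  } else {
    rep(FALSE, nrow(tab))
  }
  tibble(protein_id = tab$protein_id, category = tab$category,
         is_rp_marker = marker)
}

# Resolve the single reference-RP marker; aborts unless exactly one.
rp_marker_id <- function(annotations) {
  ids <- annotations$protein_id[annotations$is_rp_marker]
  if (length(ids) != 1L) {
    abort(paste0("exactly one reference RP marker required, found ",
                 length(ids)))
  }
  ids
}

#' Write pipeline result tables with a run manifest
#'
#' Writes each table in a named list as `<name>.tsv` (tab-separated, header
#' row, floats at full round-trip precision) plus a `manifest.json`
#' recording the configuration, seed and software versions.
#'
#' @param tables Named list of data frames.
#' @param out_dir Output directory (created if needed).
#' @param config List of run parameters recorded in the manifest.
#' @param seed Integer seed recorded in the manifest (or `NULL`).
#' @return Character vector of the files written, invisibly.
#' @export
write_results <- function(tables, out_dir, config = list(), seed = NULL) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("cannot create output directory: ", out_dir))
  }
  if (is.null(names(tables)) || any(names(tables) == "")) {
    abort("tables must be a named list")
  }
  paths <- purrr::imap_chr(tables, function(tab, nm) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    out <- as_tibble(tab)
    num <- vapply(out, is.double, logical(1))
    out[num] <- lapply(out[num], function(x) sprintf("%.17g", x))
    readr::write_tsv(out, p, progress = FALSE)
    p
  })
  manifest <- list(
    config = config,
    seed = seed,
    package = "polysomics",
    package_version = as.character(utils::packageVersion("polysomics")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    tables = names(tables)
  )
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(c(paths, mp))
}
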