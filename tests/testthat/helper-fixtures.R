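# Shared fixture builders and independent oracles used across test files.

# Long LFQ tibble from a named list: values[[protein]][[sample_name]] = reps.
make_lfq <- function(values) {
  rows <- list()
  for (pid in names(values)) {
    for (smp in names(values[[pid]])) {
      key <- strsplit(smp, "_", fixed = TRUE)[[1]]
      reps <- values[[pid]][[smp]]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        protein_id = pid, condition = key[1], fraction = key[2],
        replicate = seq_along(reps), intensity = reps)
    }
  }
  dplyr::bind_rows(rows)
}

# A fully crossed random LFQ table (all samples for every protein).
random_lfq <- function(n_proteins, conditions = c("unstressed", "H2O2"),
                       fractions = c("T", "F1", "F2", "F3", "F4", "F5"),
                       n_reps = 4, zero_rate = 0) {
  grid <- expand.grid(protein_id = sprintf("P%03d", seq_len(n_proteins)),
                      condition = conditions, fraction = fractions,
                      replicate = seq_len(n_reps),
                      stringsAsFactors = FALSE)
  grid$intensity <- 2^stats::rnorm(nrow(grid), 20, 2)
  if (zero_rate > 0) {
    grid$intensity[stats::runif(nrow(grid)) < zero_rate] <- 0
  }
  tibble::as_tibble(grid)
}

# Independent brute-force fraction-sum: plain loops, no dplyr.
oracle_fs <- function(lfq, pid, cond, fractions = paste0("F", 1:5)) {
  total <- 0
  used <- 0L
  for (f in fractions) {
    v <- lfq$intensity[lfq$protein_id == pid & lfq$condition == cond &
                         lfq$fraction == f]
    v <- v[v > 0]
    if (length(v)) {
      total <- total + sum(v) / length(v)
      used <- used + 1L
    }
  }
  list(FS = total, n_used = used)
}

# Exhaustive O(n^3) complete-linkage reference: recomputes every cluster
# pair distance from scratch as the max over member pairs at each step.
oracle_complete_linkage <- function(x) {
  d <- as.matrix(stats::dist(x))
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(n - 1L)
  for (s in seq_len(n - 1L)) {
    best <- Inf; bi <- 0L; bj <- 0L
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        dij <- max(d[clusters[[i]], clusters[[j]]])
        if (dij < best) { best <- dij; bi <- i; bj <- j }
      }
    }
    heights[s] <- best
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

# Per-residue accumulation oracle for cumulative curves: explicit loop.
oracle_curve <- function(start, end, intensity, len) {
  per_res <- numeric(len)
  for (i in seq_along(start)) {
    if (intensity[i] <= 0) next
    span <- start[i]:end[i]
    per_res[span] <- per_res[span] + intensity[i] / length(span)
  }
  cumsum(per_res) / sum(per_res)
}
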