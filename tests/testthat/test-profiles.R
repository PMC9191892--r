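profile_fixture <- function(n = 30, seed = 61, conds = c("unstressed",
                                                         "H2O2")) {
  set.seed(seed)
  random_lfq(n, conditions = conds, zero_rate = 0)
}

test_that("profiles are centred on the unstressed reference fractions", {
  lfq <- make_lfq(list(
    P1 = list(unstressed_T = c(4, 4), unstressed_F1 = c(8, 8),
              unstressed_F2 = c(8, 8), unstressed_F3 = c(8, 8),
              unstressed_F4 = c(8, 8)),
    P2 = list(unstressed_T = c(4, 4), unstressed_F1 = c(16, 16),
              unstressed_F2 = c(8, 8), unstressed_F3 = c(8, 8),
              unstressed_F4 = c(8, 8))))
  prof <- enrichment_profiles(lfq, conditions = "unstressed")
  p1 <- unlist(prof[prof$protein_id == "P1",
                    paste0("unstressed_F", 1:4)])
  expect_equal(unname(p1), rep(0, 4))
  # P2: F1 doubled relative to the others; reference mean log2 = 3.25
  p2 <- prof[prof$protein_id == "P2", ]
  expect_equal(p2$unstressed_F1, 4 - 3.25)
  expect_equal(p2$unstressed_F2, 3 - 3.25)
})

test_that("every profile row has zero mean over reference columns", {
  lfq <- profile_fixture()
  prof <- enrichment_profiles(lfq)
  ref_cols <- attr(prof, "reference_columns")
  ref_mean <- rowMeans(as.matrix(prof[ref_cols]))
  expect_lt(max(abs(ref_mean)), 1e-9)
})

test_that("profile cells match a brute-force recomputation", {
  lfq <- profile_fixture(n = 12)
  prof <- enrichment_profiles(lfq)
  for (i in 1:5) {
    pid <- prof$protein_id[i]
    cell <- function(cond, frac) {
      v <- lfq$intensity[lfq$protein_id == pid & lfq$condition == cond &
                           lfq$fraction == frac]
      mean(log2(v[v > 0]))
    }
    ref <- mean(vapply(paste0("F", 1:4), function(f) {
      cell("unstressed", f)
    }, numeric(1)))
    expect_equal(prof$H2O2_F3[i], cell("H2O2", "F3") - ref)
    expect_equal(prof$unstressed_T[i], cell("unstressed", "T") - ref)
  }
})

test_that("proteins with incomplete cells are excluded, never imputed", {
  lfq <- profile_fixture(n = 8)
  lfq$intensity[lfq$protein_id == "P001" & lfq$fraction == "F2" &
                  lfq$condition == "H2O2"] <- 0
  expect_message(prof <- enrichment_profiles(lfq), "excluded 1")
  expect_false("P001" %in% prof$protein_id)
})

test_that("marker-relative profiles satisfy the self and proportional identities", {
  set.seed(62)
  lfq <- random_lfq(8, conditions = c("unstressed", "H2O2"), zero_rate = 0)
  # make P002 exactly 3x the marker P001 everywhere
  marker_rows <- lfq[lfq$protein_id == "P001", ]
  prop <- marker_rows
  prop$protein_id <- "P002"
  prop$intensity <- 3 * marker_rows$intensity
  lfq <- dplyr::bind_rows(lfq[lfq$protein_id != "P002", ], prop)
  rel <- rp_relative_profile(lfq, marker = "P001")
  expect_equal(rel$rel_intensity[rel$protein_id == "P001"],
               rep(1, 10))
  expect_equal(rel$rel_intensity[rel$protein_id == "P002"],
               rep(1, 10))
  # brute-force check of one arbitrary cell
  cellmean <- function(pid, cond, frac) {
    v <- lfq$intensity[lfq$protein_id == pid & lfq$condition == cond &
                         lfq$fraction == frac]
    mean(v[v > 0])
  }
  expected <- (cellmean("P003", "H2O2", "F4") / cellmean("P001", "H2O2", "F4")) /
    (cellmean("P003", "unstressed", "F1") / cellmean("P001", "unstressed", "F1"))
  expect_equal(rel$rel_intensity[rel$protein_id == "P003" &
                                   rel$condition == "H2O2" &
                                   rel$fraction == "F4"], expected)
})

test_that("a marker missing from a used cell fails loudly", {
  lfq <- profile_fixture(n = 4)
  lfq$intensity[lfq$protein_id == "P001" & lfq$condition == "H2O2" &
                  lfq$fraction == "F5"] <- 0
  expect_error(rp_relative_profile(lfq, marker = "P001"), "H2O2/F5")
})

test_that("complete linkage reproduces hclust on generic instances", {
  set.seed(63)
  for (i in 1:20) {
    n <- sample(5:20, 1)
    x <- matrix(stats::rnorm(n * 5), n)
    rownames(x) <- sprintf("P%02d", seq_len(n))
    mine <- complete_linkage(stats::dist(x))
    ref <- stats::hclust(stats::dist(x), method = "complete")
    expect_equal(sort(mine$height), sort(ref$height), tolerance = 1e-12)
    expect_equal(as.matrix(stats::cophenetic(mine))[rownames(x), rownames(x)],
                 as.matrix(stats::cophenetic(ref))[rownames(x), rownames(x)],
                 tolerance = 1e-12)
  }
})

test_that("complete linkage matches the exhaustive O(n^3) oracle heights", {
  set.seed(64)
  for (i in 1:10) {
    n <- sample(4:15, 1)
    x <- matrix(stats::rnorm(n * 4), n)
    rownames(x) <- sprintf("P%02d", seq_len(n))
    expect_equal(complete_linkage(stats::dist(x))$height,
                 oracle_complete_linkage(x), tolerance = 1e-12)
  }
})

test_that("equal-distance merges break ties by smallest member labels", {
  # b-c and b-d are tied at distance 1 from a... construct explicit ties:
  # four collinear points with pairwise-tied neighbours
  x <- matrix(c(0, 1, 10, 11), ncol = 1)
  rownames(x) <- c("d", "c", "b", "a")
  hc <- complete_linkage(stats::dist(x))
  # both (c,d) and (a,b) merge at height 1; (a,b) must merge first
  first <- sort(hc$merge[1, ])
  expect_equal(sort(hc$labels[-first]), c("a", "b"))
  expect_true(all(diff(hc$height) >= 0))
})

test_that("clustering is invariant to input row order", {
  lfq <- profile_fixture(n = 25)
  prof <- enrichment_profiles(lfq)
  shuffled <- prof[sample(nrow(prof)), ]
  attributes(shuffled)$columns <- attr(prof, "columns")
  a <- cluster_profiles(prof, k = 5)
  b <- cluster_profiles(shuffled, k = 5)
  m <- dplyr::inner_join(tidy(a), tidy(b), by = "protein_id")
  expect_equal(m$cluster.x, m$cluster.y)
})

test_that("identical profile rows always share a cluster", {
  lfq <- profile_fixture(n = 10)
  prof <- enrichment_profiles(lfq)
  dup <- prof
  dup[2, -1] <- dup[1, -1]
  cl <- cluster_profiles(dup, k = 4)
  lab <- tidy(cl)
  expect_equal(lab$cluster[1], lab$cluster[2])
})

test_that("planted archetypes are recovered perfectly at low noise", {
  mix <- c(rp_like = 1 / 3, polysome_retained = 1 / 3, even = 1 / 3)
  cfg <- sim_config(n_proteins = 150, archetype_mix = mix,
                    noise_cv = 0.05, dropout = FALSE, seed = 65)
  sim <- simulate_experiment(cfg)
  prof <- enrichment_profiles(sim$lfq)
  cl <- cluster_profiles(prof, k = 3, include_totals = FALSE)
  truth <- sim$truth[sim$truth$condition == "unstressed",
                     c("protein_id", "archetype")]
  m <- dplyr::inner_join(tidy(cl), truth, by = "protein_id")
  expect_equal(mclust::adjustedRandIndex(m$cluster, m$archetype), 1)
})

test_that("cluster labels are ordered by member ribosome association", {
  mix <- c(rp_like = 0.4, low_association = 0.6)
  cfg <- sim_config(n_proteins = 100, archetype_mix = mix,
                    noise_cv = 0.05, dropout = FALSE, seed = 66)
  sim <- simulate_experiment(cfg)
  assoc <- ribosome_association(sim$lfq)
  prof <- enrichment_profiles(sim$lfq)
  cl <- cluster_profiles(prof, k = 2, association = assoc,
                         include_totals = FALSE)
  m <- dplyr::inner_join(tidy(cl),
                         sim$truth[sim$truth$condition == "unstressed", ],
                         by = "protein_id")
  # cluster 1 must be the low-association archetype
  expect_true(all(m$archetype[m$cluster == 1] == "low_association"))
  expect_true(all(m$archetype[m$cluster == 2] == "rp_like"))
})

test_that("cluster classification separates Mono, Poly and Even patterns", {
  mk <- function(f1, f24) {
    tibble::tibble(cluster = 1L, size = 5L,
                   H2O2_F1 = f1, H2O2_F2 = f24, H2O2_F3 = f24,
                   H2O2_F4 = f24, `3AT_F1` = f1, `3AT_F2` = f24,
                   `3AT_F3` = f24, `3AT_F4` = f24)
  }
  fake <- structure(list(summary = mk(0, 0)), class = "profile_clusters")
  expect_equal(classify_clusters(fake)$enrichment_class, "Even")
  fake$summary <- mk(2, -1)
  expect_equal(classify_clusters(fake)$enrichment_class, "Mono")
  fake$summary <- mk(-1, 1)
  expect_equal(classify_clusters(fake)$enrichment_class, "Poly")
})

test_that("generator archetypes classify as their expected stress pattern", {
  mix <- c(rp_like = 0.5, polysome_retained = 0.5)
  cfg <- sim_config(n_proteins = 80, archetype_mix = mix,
                    noise_cv = 0.05, dropout = FALSE, stress_runoff = 0.6,
                    seed = 67)
  sim <- simulate_experiment(cfg)
  prof <- enrichment_profiles(sim$lfq)
  cl <- cluster_profiles(prof, k = 2, include_totals = FALSE)
  classes <- classify_clusters(cl)
  truth <- sim$truth[sim$truth$condition == "unstressed", ]
  m <- dplyr::inner_join(tidy(cl), truth, by = "protein_id")
  rp_cluster <- unique(m$cluster[m$archetype == "rp_like"])
  poly_cluster <- unique(m$cluster[m$archetype == "polysome_retained"])
  expect_equal(classes$enrichment_class[classes$cluster == rp_cluster],
               "Mono")
  expect_equal(classes$enrichment_class[classes$cluster == poly_cluster],
               "Poly")
})

test_that("dendrograms export as parseable Newick", {
  lfq <- profile_fixture(n = 10)
  cl <- cluster_profiles(enrichment_profiles(lfq), k = 3)
  path <- withr::local_tempfile(fileext = ".nwk")
  export_dendrogram(cl, path)
  phy <- ape::read.tree(path)
  expect_equal(sort(phy$tip.label), sort(tidy(cl)$protein_id))
})
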