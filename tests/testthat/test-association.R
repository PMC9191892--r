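test_that("fraction sums follow the positive-replicate-mean convention", {
  lfq <- make_lfq(list(
    P1 = list(unstressed_F1 = c(10, 10), unstressed_F2 = c(10, 10),
              unstressed_F3 = c(10, 10), unstressed_F4 = c(10, 10),
              unstressed_F5 = c(10, 10), unstressed_T = c(2, 2)),
    P2 = list(unstressed_F1 = c(10, 10), unstressed_F2 = c(10, 10),
              unstressed_F3 = c(10, 10), unstressed_F4 = c(10, 10),
              unstressed_F5 = c(0, 0), unstressed_T = c(2, 2))))
  fs <- fraction_sums(lfq)
  expect_equal(fs$FS[fs$protein_id == "P1"], 50)
  expect_equal(fs$FS[fs$protein_id == "P2"], 40)
  expect_equal(fs$n_fractions_used[fs$protein_id == "P2"], 4L)
})

test_that("fraction sums match an independent brute-force recomputation", {
  set.seed(51)
  lfq <- random_lfq(20, zero_rate = 0.25)
  fs <- fraction_sums(lfq)
  for (i in sample(nrow(fs), 12)) {
    o <- oracle_fs(lfq, fs$protein_id[i], fs$condition[i])
    expect_equal(fs$FS[i], o$FS)
    expect_equal(fs$n_fractions_used[i], o$n_used)
  }
})

test_that("percent ribosomal implements 100 * (FS/T) / loading_factor", {
  lfq <- make_lfq(list(
    P1 = list(unstressed_F1 = 1, unstressed_F2 = 1, unstressed_F3 = 0.5,
              unstressed_F4 = 0.25, unstressed_F5 = 0.25,
              unstressed_T = 1),
    P2 = list(unstressed_F1 = 10, unstressed_F2 = 8, unstressed_F3 = 6,
              unstressed_F4 = 4, unstressed_F5 = 2, unstressed_T = 1)))
  assoc <- ribosome_association(lfq)
  expect_equal(assoc$pct_ribosomal[assoc$protein_id == "P1"], 10)  # FS/T = 3
  expect_equal(assoc$pct_ribosomal[assoc$protein_id == "P2"], 100) # FS/T = 30
  expect_false(any(assoc$pct_gt_100))
  # internal consistency of the two parameterizations
  expect_equal(assoc$pct_ribosomal, 100 * 2^assoc$log2_fs_t / 30)
})

test_that("undefined totals and empty fractions are flagged not dropped", {
  lfq <- make_lfq(list(
    P1 = list(unstressed_F1 = 5, unstressed_T = 0),
    P2 = list(unstressed_F1 = 0, unstressed_T = 5)))
  assoc <- ribosome_association(lfq)
  expect_equal(assoc$flag[assoc$protein_id == "P1"], "no_total")
  expect_equal(assoc$flag[assoc$protein_id == "P2"], "no_fraction_signal")
  expect_true(is.na(assoc$log2_fs_t[assoc$protein_id == "P1"]))
})

test_that("delta FS/T is zero at reference and log2-fold elsewhere", {
  lfq <- make_lfq(list(
    P1 = list(unstressed_F1 = 8, unstressed_T = 1,
              H2O2_F1 = 8, H2O2_T = 1),
    P2 = list(unstressed_F1 = 8, unstressed_T = 1,
              H2O2_F1 = 4, H2O2_T = 1)))
  d <- delta_fs_t(ribosome_association(lfq))
  expect_identical(d$delta_fs_t[d$condition == "unstressed"], c(0, 0))
  expect_equal(d$delta_fs_t[d$protein_id == "P1" & d$condition == "H2O2"], 0)
  expect_equal(d$delta_fs_t[d$protein_id == "P2" & d$condition == "H2O2"], -1)
})

test_that("a noiseless planted 2-fold engagement drop gives delta exactly -1", {
  cfg <- sim_config(n_proteins = 60, noise_cv = 0, dropout = FALSE,
                    frac_pi_change = 0.2, pi_change_fold = 0.5,
                    pi_range = c(0.05, 0.45), seed = 52)
  sim <- simulate_experiment(cfg)
  d <- delta_fs_t(ribosome_association(sim$lfq))
  chk <- dplyr::inner_join(d, sim$truth, by = c("protein_id", "condition"))
  aff <- chk[chk$pi_changed, ]
  expect_gt(nrow(aff), 0)
  expect_equal(aff$delta_fs_t, rep(-1, nrow(aff)), tolerance = 1e-12)
})

test_that("the RP null has the closed-form mean and sd", {
  deltas <- tibble::tibble(protein_id = c("R1", "R2", "R3"),
                           condition = "H2O2",
                           delta_fs_t = c(-0.1, 0, 0.1))
  ann <- tibble::tibble(protein_id = c("R1", "R2", "R3"),
                        category = "RP", is_rp_marker = FALSE)
  null <- fit_rp_null(deltas, ann)
  expect_equal(null$params$mu, 0)
  expect_equal(null$params$sigma, 0.1)
  expect_equal(null$params$n_rp, 3L)
  expect_s3_class(tidy(null), "tbl_df")

  # degenerate guards
  deltas$delta_fs_t <- c(0.2, 0.2, 0.2)
  expect_error(fit_rp_null(deltas, ann), "degenerate")
  expect_error(fit_rp_null(deltas[1:2, ], ann), "fewer than 3")
})

test_that("null p-values follow the normal tail identities", {
  null <- structure(list(params = tibble::tibble(condition = "H2O2",
                                                 mu = 0.2, sigma = 0.3,
                                                 n_rp = 10L),
                         reference = "unstressed"), class = "rp_null")
  deltas <- tibble::tibble(protein_id = c("A", "B", "C"),
                           condition = "H2O2",
                           delta_fs_t = c(0.2, 0.2 + 1.959964 * 0.3,
                                          0.2 - 1.959964 * 0.3))
  p <- null_pvalues(deltas, null)
  expect_equal(p$p_value[1], 1)
  expect_equal(p$p_value[2], 0.05, tolerance = 1e-6)
  expect_equal(p$p_value[3], 0.05, tolerance = 1e-6)
  expect_equal(p$direction, c("increase", "increase", "decrease"))
})

test_that("the null fit recovers known normal parameters within error", {
  set.seed(53)
  n_rp <- 70
  true_sd <- 0.3
  deltas <- tibble::tibble(protein_id = sprintf("R%02d", 1:n_rp),
                           condition = "3AT",
                           delta_fs_t = stats::rnorm(n_rp, 0, true_sd))
  ann <- tibble::tibble(protein_id = deltas$protein_id, category = "RP",
                        is_rp_marker = FALSE)
  null <- fit_rp_null(deltas, ann)
  se_mu <- true_sd / sqrt(n_rp)
  expect_lt(abs(null$params$mu), 3 * se_mu)
  se_sd <- true_sd / sqrt(2 * (n_rp - 1))
  expect_lt(abs(null$params$sigma - true_sd), 3 * se_sd)
})

test_that("type-I error is nominal under the exchangeable-noise null", {
  cfg <- sim_config(n_proteins = 3000, noise_cv = 0.2, dropout = FALSE,
                    seed = 54)
  sim <- simulate_experiment(cfg)
  res <- association_test(sim$lfq, sim$annotations)
  stress <- res[res$condition != "unstressed" & !is.na(res$p_value), ]
  for (alpha in c(0.01, 0.05)) {
    frac <- mean(stress$p_value < alpha)
    se <- sqrt(alpha * (1 - alpha) / nrow(stress))
    expect_lt(abs(frac - alpha), 3 * se)
  }
})

test_that("percent ribosomal is increasing in FS at fixed T", {
  fs <- seq(1, 30, length.out = 10)
  lfq <- make_lfq(setNames(lapply(fs, function(f) {
    list(unstressed_F1 = f, unstressed_T = 1)
  }), sprintf("P%02d", 1:10)))
  assoc <- ribosome_association(lfq)
  assoc <- assoc[order(assoc$protein_id), ]
  expect_true(all(diff(assoc$pct_ribosomal) > 0))
})
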