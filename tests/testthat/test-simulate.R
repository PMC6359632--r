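test_that("simulation is deterministic in the seed", {
  cfg <- sim_config(n_proteins = 80, n_dep = 8, seed = 11)
  a <- simulate_counts(cfg)
  b <- simulate_counts(cfg)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$truth, b$truth)

  c <- simulate_counts(sim_config(n_proteins = 80, n_dep = 8, seed = 12))
  expect_false(identical(a$counts$counts, c$counts$counts))
})

test_that("per-run totals concentrate around the configured depth", {
  sim <- simulate_counts(sim_config(n_proteins = 200, n_dep = 0,
                                    depth = 20000, seed = 5))
  totals <- colSums(sim$counts$counts)
  expect_true(all(abs(totals - 20000) / 20000 < 0.05))
})

test_that("without planted effects the mean NSAF ratio is near 1", {
  sim <- simulate_counts(sim_config(n_proteins = 200, n_dep = 0,
                                    depth = 10000, seed = 21))
  dep <- call_dep_table(sim$counts, "group_ref", "group_cmp")
  t <- tidy(dep)
  r <- t$nsaf_ratio[is.finite(t$nsaf_ratio) & t$nsaf_ratio > 0]
  expect_gt(mean(r), 0.8)
  expect_lt(mean(r), 1.25)
})

test_that("truth bookkeeping and the detection floor hold", {
  cfg <- sim_config(n_proteins = 150, n_dep = 15, fold_changes = c(6, 0.2),
                    detection_floor = 2, seed = 31)
  sim <- simulate_counts(cfg)
  expect_equal(sum(sim$truth$is_dep), 15)
  expect_true(all(sim$truth$true_fold[sim$truth$is_dep] %in% c(6, 0.2)))
  expect_true(all(sim$truth$true_fold[!sim$truth$is_dep] == 1))
  counts <- sim$counts$counts
  expect_true(all(counts == 0 | counts >= 2))
  expect_true(all(sim$counts$proteins$length >= 50 &
                    sim$counts$proteins$length <= 5000))
})

test_that("recovery scoring handles perfect, empty and saturated call sets", {
  truth <- tibble::tibble(
    accession = sprintf("P%02d", 1:10),
    is_dep = c(rep(TRUE, 3), rep(FALSE, 7)),
    true_fold = c(4, 4, 0.25, rep(1, 7))
  )
  calls <- tibble::tibble(
    accession = truth$accession,
    call = factor(c("overexpressed", "unique_to_cmp", "underexpressed",
                    rep("not_significant", 7)),
                  levels = c("overexpressed", "underexpressed",
                             "unique_to_cmp", "unique_to_ref",
                             "not_significant", "absent_in_both")),
    governing_tier = factor("medium",
                            levels = c("absent", "very_low", "low",
                                       "medium", "high"), ordered = TRUE)
  )
  perfect <- evaluate_recovery(calls, truth)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$fdp, 0)

  none <- calls
  none$call[] <- "not_significant"
  zero <- evaluate_recovery(none, truth)
  expect_equal(zero$sensitivity, 0)
  expect_equal(zero$fdp, 0)

  all_called <- calls
  all_called$call[] <- "overexpressed"
  sat <- evaluate_recovery(all_called, truth)
  # the down-regulated planted protein is called in the wrong direction
  expect_equal(sat$sensitivity, 2 / 3)
  expect_equal(sat$fdp, 8 / 10)

  # direction must agree with the planted fold
  wrong_dir <- calls
  wrong_dir$call[3] <- "overexpressed"
  wd <- evaluate_recovery(wrong_dir, truth)
  expect_equal(wd$sensitivity, 2 / 3)
  expect_equal(wd$fdp, 1 / 3)
})

test_that("larger planted folds do not reduce sensitivity", {
  sens_for_fold <- function(fold) {
    out <- vapply(c(41, 42, 43), function(seed) {
      cfg <- sim_config(n_proteins = 150, n_dep = 15, fold_changes = fold,
                        depth = 20000, seed = seed)
      sim <- simulate_counts(cfg)
      dep <- call_dep_table(sim$counts, "group_ref", "group_cmp")
      evaluate_recovery(dep, sim$truth)$sensitivity
    }, numeric(1))
    mean(out)
  }
  s2 <- sens_for_fold(2)
  s5 <- sens_for_fold(5)
  s10 <- sens_for_fold(10)
  expect_gte(s5, s2 - 0.05)
  expect_gte(s10, s5 - 0.05)
  expect_gt(s10, s2)
})

test_that("flat key=value config files round trip", {
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c(
    "# simulation settings",
    "n_proteins = 40",
    "n_dep = 4",
    "fold_changes = 5,0.2",
    "depth = 5000",
    "seed = 9"
  ), path)
  cfg <- read_sim_config(path)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$n_proteins, 40L)
  expect_equal(cfg$fold_changes, c(5, 0.2))
  expect_equal(cfg$seed, 9L)

  bad <- withr::local_tempfile(fileext = ".cfg")
  writeLines("nonsense_key = 1", bad)
  expect_error(read_sim_config(bad), class = "nsafdep_input_error")
})

test_that("config validation rejects impossible settings", {
  expect_error(sim_config(10, n_dep = 11), class = "nsafdep_input_error")
  expect_error(sim_config(10, depth = -1), class = "nsafdep_input_error")
  expect_error(sim_config(10, n_dep = 2, fold_changes = -2),
               class = "nsafdep_input_error")
  expect_error(sim_config(10, dispersion = -0.1),
               class = "nsafdep_input_error")
})
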