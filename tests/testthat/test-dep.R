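test_that("expression calls follow the tiered scheme on worked cases", {
  # high tier: modest 1.61-fold suffices
  expect_equal(
    as.character(call_expression(98.7, 181.3, ratio = 1.61, p_value = 0)$call),
    "overexpressed"
  )
  # medium governs a medium-vs-very_low pair; 0.05 is far below 0.5
  r <- call_expression(34.0, 1.7, ratio = 0.05, p_value = 0)
  expect_equal(as.character(r$governing_tier), "medium")
  expect_equal(as.character(r$call), "underexpressed")
  # presence/absence beats thresholds
  expect_equal(
    as.character(call_expression(2.0, 0, ratio = 0, p_value = 0)$call),
    "unique_to_ref"
  )
  expect_equal(
    as.character(call_expression(0, 3.1, ratio = Inf, p_value = 0)$call),
    "unique_to_cmp"
  )
  expect_equal(
    as.character(call_expression(0, 0, ratio = NA, p_value = NA)$call),
    "absent_in_both"
  )
  expect_equal(
    as.character(call_expression(50, 50, ratio = 1, p_value = 1)$call),
    "not_significant"
  )
  # a significant p alone is not enough without the fold cutoff
  expect_equal(
    as.character(call_expression(50, 60, ratio = 1.2, p_value = 1e-5)$call),
    "not_significant"
  )
})

test_that("threshold comparisons are inclusive at the boundary", {
  th <- tier_thresholds()
  # medium tier: p exactly 0.05 and ratio exactly 2.0 -> overexpressed
  expect_equal(
    as.character(call_expression(30, 60, ratio = 2.0, p_value = 0.05)$call),
    "overexpressed"
  )
  expect_equal(
    as.character(call_expression(30, 60, ratio = 2.0 - 1e-9,
                                 p_value = 0.05)$call),
    "not_significant"
  )
  # high tier underexpression boundary sits at exactly 2/3
  expect_equal(
    as.character(call_expression(120, 80, ratio = 2 / 3, p_value = 0.01)$call),
    "underexpressed"
  )
})

test_that("group swap maps ratios to reciprocals and OE to UE", {
  withr::with_seed(7, {
    for (i in 1:200) {
      sc_a <- stats::runif(1, 0.5, 200)
      sc_b <- stats::runif(1, 0.5, 200)
      ratio <- stats::runif(1, 0.02, 50)
      p <- stats::runif(1)
      fwd <- call_expression(sc_a, sc_b, ratio, p)$call
      rev <- call_expression(sc_b, sc_a, 1 / ratio, p)$call
      swap <- c(overexpressed = "underexpressed",
                underexpressed = "overexpressed",
                not_significant = "not_significant")
      expect_equal(as.character(rev), unname(swap[as.character(fwd)]))
    }
  })
})

test_that("raising the ratio never demotes an overexpressed call", {
  th <- tier_thresholds()
  for (tier_sc in c(3, 10, 30, 100)) {
    prev_oe <- FALSE
    for (ratio in c(0.8, 1.2, 1.5, 2.0, 2.5, 3.5, 10)) {
      call <- as.character(
        call_expression(tier_sc, tier_sc, ratio, p_value = 0)$call
      )
      if (prev_oe) expect_equal(call, "overexpressed")
      prev_oe <- call == "overexpressed"
    }
  }
})

test_that("call_dep_table assembles calls, ratios and summary consistently", {
  x <- toy_matrix()
  dep <- call_dep_table(x, "gA", "gB")
  t <- tidy(dep)

  expect_equal(nrow(t), 3)
  # P2 absent from gA, present in gB
  expect_equal(as.character(t$call[t$accession == "P2"]), "unique_to_cmp")
  expect_identical(t$nsaf_ratio[t$accession == "P2"], Inf)
  # P3 present in gA only
  expect_equal(as.character(t$call[t$accession == "P3"]), "unique_to_ref")
  expect_equal(t$nsaf_ratio[t$accession == "P3"], 0)

  g <- glance(dep)
  expect_equal(g$n_proteins_union, 3)
  expect_equal(g$n_dep, g$n_oe + g$n_ue + g$n_unique)
  expect_equal(g$dep_fraction_percent, 100 * g$n_dep / g$n_proteins_union)

  expect_error(call_dep_table(x, "gA", "gA"), class = "nsafdep_input_error")
  expect_error(call_dep_table(x, "gA", "nope"),
               class = "nsafdep_input_error")
})

test_that("ratio overrides replace computed ratios only where named", {
  x <- toy_matrix()
  dep <- call_dep_table(x, "gA", "gB",
                        ratio_override = c(P1 = 9.99))
  t <- tidy(dep)
  expect_equal(t$nsaf_ratio[t$accession == "P1"], 9.99)
  base <- tidy(call_dep_table(x, "gA", "gB"))
  expect_equal(t$nsaf_ratio[t$accession == "P3"],
               base$nsaf_ratio[base$accession == "P3"])
  expect_error(
    call_dep_table(x, "gA", "gB", ratio_override = c(NOPE = 1)),
    class = "nsafdep_input_error"
  )
})

test_that("DEP report mirrors the published table layout", {
  dep <- fixture_dep_result(neat_fixture(), "group1", "group3")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_dep_report(dep, path)
  rep <- readr::read_tsv(path, show_col_types = FALSE)
  expect_named(rep, c("accession", "gene", "description", "SC_ref",
                      "Abun_ref", "SC_cmp", "Abun_cmp", "NSAF_ratio",
                      "p_value", "Expression"))
  expect_equal(rep$Expression[rep$gene == "ARSA"], "UE")
  expect_equal(rep$Expression[rep$gene == "PACRG"], "OE")
  expect_equal(rep$SC_ref[rep$gene == "LTF"], 2486.7)
  expect_equal(rep$NSAF_ratio[rep$gene == "ATP1A1"], 1.61)
  expect_equal(rep$Abun_cmp[rep$gene == "ARSA"], "VL")
})
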