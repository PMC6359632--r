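#' Independent two-sample t-test with degenerate-replicate rules
#'
#' Two-sided Student's t-test with pooled variance, as applied to the per-run
#' NSAF values of one protein in two groups of technical replicates. Two
#' degenerate cases arise with summary-table fixtures whose pseudo-replicates
#' carry zero variance: if both groups are exactly constant the p-value is 1
#' when the means agree and 0 when they differ (the within-run evidence is
#' noiseless, so any difference is taken at face value).
#'
#' @param values_ref,values_cmp Numeric vectors of per-replicate values, each
#'   with at least one element.
#' @return The two-sided p-value in `[0, 1]`.
#' @examples
#' ttest_independent(c(1, 2, 3), c(4, 5, 6))  # ~0.0213
#' @export
ttest_independent <- function(values_ref, values_cmp) {
  if (length(values_ref) < 1 || length(values_cmp) < 1) {
    abort_input("both groups need at least one value")
  }
  const_ref <- diff(range(values_ref)) == 0
  const_cmp <- diff(range(values_cmp)) == 0
  if (const_ref && const_cmp) {
    # zero within-group variance on both sides (summary-table pseudo-replicates)
    return(if (mean(values_ref) == mean(values_cmp)) 1 else 0)
  }
  stats::t.test(values_ref, values_cmp, var.equal = TRUE)$p.value
}

dep_call_levels <- c("overexpressed", "underexpressed", "unique_to_cmp",
                     "unique_to_ref", "not_significant", "absent_in_both")

#' Tiered differential-expression call for one or more proteins
#'
#' Presence/absence is resolved first: a protein with counts in only one
#' group is `unique_to_cmp` / `unique_to_ref`, and one with no counts at all
#' is `absent_in_both`. For proteins present in both groups, the governing
#' abundance tier (the higher of the two groups' tiers, see
#' [governing_tier()]) selects a p-value ceiling and NSAF-ratio cutoffs; the
#' protein is `overexpressed` when `p <= p_max` and `ratio >= oe_ratio_min`,
#' `underexpressed` when `p <= p_max` and `ratio <= ue_ratio_max`, and
#' `not_significant` otherwise. All threshold comparisons are inclusive.
#'
#' @param mean_sc_ref,mean_sc_cmp Group-mean spectral counts (non-negative).
#' @param ratio NSAF ratio, comparison over reference; may be `Inf`.
#' @param p_value Two-sided p-value from [ttest_independent()].
#' @param thresholds A [tier_thresholds()] tibble.
#' @return A tibble with columns `tier_ref`, `tier_cmp`, `governing_tier`,
#'   and `call` (factor with levels overexpressed, underexpressed,
#'   unique_to_cmp, unique_to_ref, not_significant, absent_in_both).
#' @examples
#' call_expression(98.7, 181.3, ratio = 1.61, p_value = 0)$call  # overexpressed
#' call_expression(34.0, 1.7, ratio = 0.05, p_value = 0)$call   # underexpressed
#' @export
call_expression <- function(mean_sc_ref, mean_sc_cmp, ratio, p_value,
                            thresholds = tier_thresholds()) {
  n <- max(length(mean_sc_ref), length(mean_sc_cmp), length(ratio),
           length(p_value))
  mean_sc_ref <- rep_len(mean_sc_ref, n)
  mean_sc_cmp <- rep_len(mean_sc_cmp, n)
  ratio <- rep_len(ratio, n)
  p_value <- rep_len(p_value, n)

  tier_ref <- classify_abundance(mean_sc_ref)
  tier_cmp <- classify_abundance(mean_sc_cmp)

  gov <- factor(rep(NA_character_, n), levels = tier_levels, ordered = TRUE)
  call <- rep(NA_character_, n)

  both_zero <- mean_sc_ref == 0 & mean_sc_cmp == 0
  uniq_cmp <- mean_sc_ref == 0 & mean_sc_cmp > 0
  uniq_ref <- mean_sc_cmp == 0 & mean_sc_ref > 0
  present <- mean_sc_ref > 0 & mean_sc_cmp > 0

  call[both_zero] <- "absent_in_both"
  call[uniq_cmp] <- "unique_to_cmp"
  call[uniq_ref] <- "unique_to_ref"

  if (any(present)) {
    g <- governing_tier(tier_ref[present], tier_cmp[present])
    gov[present] <- g
    th <- thresholds[match(as.character(g), as.character(thresholds$tier)), ]
    p <- p_value[present]
    r <- ratio[present]
    oe <- p <= th$p_max & r >= th$oe_ratio_min
    ue <- p <= th$p_max & r <= th$ue_ratio_max
    call[present] <- ifelse(oe, "overexpressed",
                            ifelse(ue, "underexpressed", "not_significant"))
  }

  tibble::tibble(
    tier_ref = tier_ref,
    tier_cmp = tier_cmp,
    governing_tier = gov,
    call = factor(call, levels = dep_call_levels)
  )
}

#' Differential-expression table for a two-group comparison
#'
#' Runs the full tiered spectral-counting comparison between a reference and
#' a comparison group: group-mean spectral counts, per-run NSAF averaged per
#' group, NSAF ratio (comparison/reference), pooled-variance t-test on the
#' per-run NSAF values, and the tiered expression call for every protein
#' detected in either group.
#'
#' @param x A [spectral_counts] object containing runs for both groups.
#' @param group_ref,group_cmp Group labels in the design; the ratio is
#'   oriented comparison over reference.
#' @param thresholds A [tier_thresholds()] tibble.
#' @param ratio_override Optional named numeric vector of externally
#'   supplied NSAF ratios (names are accessions). Published summary tables
#'   report ratios computed against full-proteome NSAF denominators that a
#'   table-sized excerpt cannot reconstruct; supplying them here lets the
#'   classifier reproduce published calls exactly. Accessions not named keep
#'   their computed ratio.
#' @return A `dep_result` object; see [tidy.dep_result()] and
#'   [glance.dep_result()].
#' @export
call_dep_table <- function(x, group_ref, group_cmp,
                           thresholds = tier_thresholds(),
                           ratio_override = NULL) {
  stopifnot(inherits(x, "spectral_counts"))
  if (identical(group_ref, group_cmp)) {
    abort_input("reference and comparison group must differ")
  }
  runs_ref <- group_runs(x, group_ref)
  runs_cmp <- group_runs(x, group_cmp)

  mean_ref <- group_mean_sc(x, group_ref)
  mean_cmp <- group_mean_sc(x, group_cmp)

  nsaf <- nsaf_matrix(x)
  nsaf_ref <- nsaf[, runs_ref, drop = FALSE]
  nsaf_cmp <- nsaf[, runs_cmp, drop = FALSE]
  mnsaf_ref <- rowMeans(nsaf_ref)
  mnsaf_cmp <- rowMeans(nsaf_cmp)

  present <- mean_ref > 0 | mean_cmp > 0
  ratio <- rep(NA_real_, nrow(x$counts))
  ratio[present] <- nsaf_ratio(mnsaf_ref[present], mnsaf_cmp[present])

  if (!is.null(ratio_override)) {
    if (is.null(names(ratio_override))) {
      abort_input("`ratio_override` must be named by accession")
    }
    unknown <- setdiff(names(ratio_override), rownames(x$counts))
    if (length(unknown) > 0) {
      abort_input("ratio_override names not in matrix: ",
                  paste(unknown, collapse = ", "))
    }
    hit <- match(names(ratio_override), rownames(x$counts))
    ratio[hit] <- unname(ratio_override)
  }

  p_value <- vapply(seq_len(nrow(x$counts)), function(i) {
    ttest_independent(nsaf_ref[i, ], nsaf_cmp[i, ])
  }, numeric(1))

  calls <- call_expression(mean_ref, mean_cmp, ratio, p_value, thresholds)

  table <- dplyr::bind_cols(
    x$proteins,
    tibble::tibble(
      mean_sc_ref = unname(mean_ref),
      mean_sc_cmp = unname(mean_cmp),
      mean_nsaf_ref = unname(mnsaf_ref),
      mean_nsaf_cmp = unname(mnsaf_cmp),
      nsaf_ratio = ratio,
      p_value = p_value
    ),
    calls
  )

  n_oe <- sum(table$call == "overexpressed", na.rm = TRUE)
  n_ue <- sum(table$call == "underexpressed", na.rm = TRUE)
  n_unique <- sum(table$call %in% c("unique_to_cmp", "unique_to_ref"),
                  na.rm = TRUE)
  n_union <- sum(present)
  n_dep <- n_oe + n_ue + n_unique

  structure(
    list(
      table = table,
      group_ref = group_ref,
      group_cmp = group_cmp,
      thresholds = thresholds,
      nsaf_runs_ref = nsaf_ref,
      summary = list(
        n_proteins_union = n_union,
        n_dep = n_dep,
        n_oe = n_oe,
        n_ue = n_ue,
        n_unique = n_unique,
        dep_fraction_percent = if (n_union > 0) 100 * n_dep / n_union else 0
      )
    ),
    class = "dep_result"
  )
}

#' @export
print.dep_result <- function(x, ...) {
  s <- x$summary
  cat("<dep_result> ", x$group_cmp, " vs ", x$group_ref,
      " (ratio = ", x$group_cmp, "/", x$group_ref, ")\n", sep = "")
  cat("  proteins in union: ", s$n_proteins_union, "\n", sep = "")
  cat("  DEPs: ", s$n_dep, " (", format(round(s$dep_fraction_percent, 2)),
      "%) — ", s$n_oe, " overexpressed, ", s$n_ue, " underexpressed, ",
      s$n_unique, " unique to one group\n", sep = "")
  invisible(x)
}

#' Per-protein differential-expression calls
#'
#' @param x A `dep_result` from [call_dep_table()].
#' @param ... Unused.
#' @return A tibble with one row per protein: metadata, group-mean spectral
#'   counts and NSAF, NSAF ratio, p-value, tiers, and the expression call.
#' @export
tidy.dep_result <- function(x, ...) {
  x$table
}

#' One-row summary of a differential-expression comparison
#'
#' @param x A `dep_result` from [call_dep_table()].
#' @param ... Unused.
#' @return A one-row tibble: `n_proteins_union`, `n_dep`, `n_oe`, `n_ue`,
#'   `n_unique`, `dep_fraction_percent`.
#' @export
glance.dep_result <- function(x, ...) {
  tibble::as_tibble(x$summary)
}

tier_abbrev <- c(absent = "-", very_low = "VL", low = "L",
                 medium = "M", high = "H")

format_call <- function(call, group_ref, group_cmp) {
  dplyr::case_match(as.character(call),
    "overexpressed" ~ "OE",
    "underexpressed" ~ "UE",
    "unique_to_cmp" ~ paste("Unique to", group_cmp),
    "unique_to_ref" ~ paste("Unique to", group_ref),
    "not_significant" ~ "NS",
    "absent_in_both" ~ "Absent"
  )
}

#' Write a differential-expression report TSV
#'
#' Columns mirror the conventional spectral-counting report layout:
#' accession, gene, description, mean SC and abundance tier per group
#' (VL/L/M/H abbreviations), NSAF ratio (2 decimals), p-value, and the
#' expression label (OE, UE, `Unique to <group>`, NS). Spectral-count means
#' are reported to 1 decimal.
#'
#' @param x A `dep_result` from [call_dep_table()].
#' @param path Output TSV path.
#' @return `x`, invisibly.
#' @export
write_dep_report <- function(x, path) {
  t <- x$table
  out <- tibble::tibble(
    accession = t$accession,
    gene = t$gene,
    description = t$description,
    SC_ref = sprintf("%.1f", t$mean_sc_ref),
    Abun_ref = tier_abbrev[as.character(t$tier_ref)],
    SC_cmp = sprintf("%.1f", t$mean_sc_cmp),
    Abun_cmp = tier_abbrev[as.character(t$tier_cmp)],
    NSAF_ratio = sprintf("%.2f", t$nsaf_ratio),
    p_value = signif(t$p_value, 4),
    Expression = format_call(t$call, x$group_ref, x$group_cmp)
  )
  readr::write_tsv(out, path)
  invisible(x)
}

#' Write the JSON comparison summary
#'
#' @param x A `dep_result` from [call_dep_table()].
#' @param path Output JSON path.
#' @return `x`, invisibly.
#' @export
write_dep_summary <- function(x, path) {
  jsonlite::write_json(x$summary, path, auto_unbox = TRUE, digits = NA)
  invisible(x)
}
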