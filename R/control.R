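#' Annotate differential proteins against a control proteome
#'
#' For each protein in a two-group comparison result, looks up its abundance
#' in a separately profiled control proteome (here, a pure leukocyte
#' culture) and classifies its status there with the same tiered scheme used
#' for the study comparison: `absent_in_control` when the control never
#' detects it, otherwise `overexpressed_in_control` /
#' `underexpressed_in_control` / `not_significant` from the NSAF ratio
#' control-over-reference and a t-test of per-run NSAF values, with the
#' governing tier taken as the higher of the reference and control tiers.
#' Proteins in the comparison that are missing entirely from the control
#' matrix are treated as zero-count in the control.
#'
#' @param dep A `dep_result` from [call_dep_table()] (study comparison;
#'   its reference group anchors the ratio orientation).
#' @param control A [spectral_counts] object holding the control runs. All
#'   its runs are used regardless of group labels.
#' @param thresholds A [tier_thresholds()] tibble; defaults to the ones used
#'   for the study comparison.
#' @param ratio_override Optional named numeric vector of published
#'   control/reference NSAF ratios, as in [call_dep_table()].
#' @param deps_only If `TRUE` (default) only proteins called differentially
#'   expressed in `dep` are annotated, mirroring the usual
#'   published-table layout; otherwise all proteins.
#' @return A `control_annotation` object. `tidy()` returns the per-protein
#'   table; `glance()` returns status counts and `n_shared_all_three`, the
#'   number of annotated proteins with nonzero mean spectral count in the
#'   reference group, the comparison group, and the control.
#' @export
annotate_with_control <- function(dep, control,
                                  thresholds = dep$thresholds,
                                  ratio_override = NULL,
                                  deps_only = TRUE) {
  stopifnot(inherits(dep, "dep_result"), inherits(control, "spectral_counts"))
  tab <- dep$table
  if (deps_only) {
    tab <- tab[tab$call %in% c("overexpressed", "underexpressed",
                               "unique_to_cmp", "unique_to_ref"), ,
               drop = FALSE]
  }

  ctl_nsaf <- nsaf_matrix(control)
  ctl_mean_sc_all <- rowMeans(control$counts)
  ctl_mean_nsaf_all <- rowMeans(ctl_nsaf)

  hit <- match(tab$accession, rownames(control$counts))
  ctl_mean_sc <- ifelse(is.na(hit), 0, ctl_mean_sc_all[hit])
  ctl_mean_nsaf <- ifelse(is.na(hit), 0, ctl_mean_nsaf_all[hit])

  n <- nrow(tab)
  ratio <- rep(NA_real_, n)
  ok <- tab$mean_nsaf_ref > 0 | ctl_mean_nsaf > 0
  ratio[ok] <- nsaf_ratio(tab$mean_nsaf_ref[ok], ctl_mean_nsaf[ok])

  if (!is.null(ratio_override)) {
    if (is.null(names(ratio_override))) {
      abort_input("`ratio_override` must be named by accession")
    }
    unknown <- setdiff(names(ratio_override), tab$accession)
    if (length(unknown) > 0) {
      abort_input("ratio_override names not in the comparison: ",
                  paste(unknown, collapse = ", "))
    }
    ratio[match(names(ratio_override), tab$accession)] <-
      unname(ratio_override)
  }

  # t-test of reference-group vs control per-run NSAF; degenerate rules apply
  # when a protein is missing from either side
  ref_hit <- match(tab$accession, rownames(dep$nsaf_runs_ref))
  p_value <- vapply(seq_len(n), function(i) {
    ctl_vals <- if (is.na(hit[i])) {
      rep(0, ncol(control$counts))
    } else {
      ctl_nsaf[hit[i], ]
    }
    ref_vals <- dep$nsaf_runs_ref[ref_hit[i], ]
    ttest_independent(ref_vals, ctl_vals)
  }, numeric(1))

  raw <- call_expression(tab$mean_sc_ref, ctl_mean_sc, ratio, p_value,
                         thresholds)
  status <- dplyr::case_match(as.character(raw$call),
    "unique_to_ref" ~ "absent_in_control",
    "absent_in_both" ~ "absent_in_control",
    "unique_to_cmp" ~ "overexpressed_in_control",
    "overexpressed" ~ "overexpressed_in_control",
    "underexpressed" ~ "underexpressed_in_control",
    "not_significant" ~ "not_significant"
  )

  out <- dplyr::bind_cols(
    tab[, c("accession", "gene", "description", "mean_sc_ref", "tier_ref",
            "mean_sc_cmp", "tier_cmp", "call")],
    tibble::tibble(
      control_mean_sc = ctl_mean_sc,
      control_tier = classify_abundance(ctl_mean_sc),
      ratio_control_over_ref = ratio,
      control_p_value = p_value,
      status = factor(status,
                      levels = c("absent_in_control",
                                 "underexpressed_in_control",
                                 "overexpressed_in_control",
                                 "not_significant"))
    )
  )

  n_shared <- sum(out$mean_sc_ref > 0 & out$mean_sc_cmp > 0 &
                    out$control_mean_sc > 0)

  structure(
    list(table = out, n_shared_all_three = n_shared,
         group_ref = dep$group_ref, group_cmp = dep$group_cmp),
    class = "control_annotation"
  )
}

#' @export
print.control_annotation <- function(x, ...) {
  cat("<control_annotation> ", nrow(x$table), " proteins vs control\n",
      sep = "")
  print(table(x$table$status))
  cat("  present in ", x$group_ref, ", ", x$group_cmp,
      " and control: ", x$n_shared_all_three, "\n", sep = "")
  invisible(x)
}

#' Per-protein control annotations
#' @param x A `control_annotation` object.
#' @param ... Unused.
#' @return The annotation tibble.
#' @export
tidy.control_annotation <- function(x, ...) {
  x$table
}

#' One-row summary of a control annotation
#' @param x A `control_annotation` object.
#' @param ... Unused.
#' @return A one-row tibble with status counts and `n_shared_all_three`.
#' @export
glance.control_annotation <- function(x, ...) {
  s <- x$table$status
  tibble::tibble(
    n_annotated = length(s),
    n_absent_in_control = sum(s == "absent_in_control"),
    n_underexpressed_in_control = sum(s == "underexpressed_in_control"),
    n_overexpressed_in_control = sum(s == "overexpressed_in_control"),
    n_not_significant = sum(s == "not_significant"),
    n_shared_all_three = x$n_shared_all_three
  )
}

#' Write the three-way control comparison report TSV
#'
#' @param x A `control_annotation` object.
#' @param path Output TSV path.
#' @return `x`, invisibly.
#' @export
write_control_report <- function(x, path) {
  t <- x$table
  out <- tibble::tibble(
    accession = t$accession,
    gene = t$gene,
    description = t$description,
    SC_ref = sprintf("%.1f", t$mean_sc_ref),
    Abun_ref = tier_abbrev[as.character(t$tier_ref)],
    SC_cmp = sprintf("%.1f", t$mean_sc_cmp),
    Abun_cmp = tier_abbrev[as.character(t$tier_cmp)],
    SC_control = sprintf("%.1f", t$control_mean_sc),
    Abun_control = tier_abbrev[as.character(t$control_tier)],
    NSAF_ratio_control = sprintf("%.2f", t$ratio_control_over_ref),
    Expression_in_control = dplyr::case_match(as.character(t$status),
      "absent_in_control" ~ "Absent in control",
      "underexpressed_in_control" ~ "UE",
      "overexpressed_in_control" ~ "OE",
      "not_significant" ~ "NS")
  )
  readr::write_tsv(out, path)
  invisible(x)
}
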