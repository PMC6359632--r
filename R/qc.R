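#' Coefficient of variation, in percent
#'
#' Intra-assay variability between technical replicates: 100 x standard
#' deviation / mean. The sample (n-1) standard deviation is the default;
#' with triplicates the choice is material, so the population (n) form is
#' available.
#'
#' @param values Numeric vector, length >= 2, with a strictly positive mean.
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return CV as a percentage.
#' @examples
#' cv_percent(c(10, 12, 14))  # sd 2 over mean 12 -> 16.67
#' @export
cv_percent <- function(values, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (length(values) < 2) abort_input("CV needs at least 2 values")
  m <- mean(values)
  if (is.na(m) || m <= 0) abort_input("CV needs a positive mean")
  s <- stats::sd(values)
  if (sd_type == "population") {
    s <- s * sqrt((length(values) - 1) / length(values))
  }
  100 * s / m
}

#' Number of detected proteins per run
#'
#' A protein counts as detected in a run when its spectral count is
#' strictly positive.
#'
#' @param x A [spectral_counts] object.
#' @return A tibble with columns `run_id`, `group`, `replicate`,
#'   `n_proteins`.
#' @export
run_protein_totals <- function(x) {
  stopifnot(inherits(x, "spectral_counts"))
  dplyr::mutate(x$design,
                n_proteins = unname(colSums(x$counts[, x$design$run_id,
                                                     drop = FALSE] > 0)))
}

#' Per-group CV of the per-run protein totals
#'
#' @inheritParams run_protein_totals
#' @inheritParams cv_percent
#' @return A tibble with columns `group` and `cv_percent`.
#' @export
group_cv <- function(x, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  totals <- run_protein_totals(x)
  # a single-run group has no within-group variability to measure
  totals |>
    dplyr::summarise(
      cv_percent = if (dplyr::n() >= 2) {
        cv_percent(.data$n_proteins, sd_type = sd_type)
      } else {
        NA_real_
      },
      .by = "group"
    )
}

#' Interference verdict: DEP fraction vs technical variability
#'
#' The central quality argument of presence/absence proteome comparison:
#' if the fraction of proteins called differentially expressed between two
#' conditions does not exceed the coefficient of variation observed between
#' technical replicates, the between-condition differences are judged to lie
#' within technical variability (here, that round-cell/leukocyte proteins do
#' not measurably interfere with the sperm proteome). The boundary is
#' inclusive: a DEP fraction exactly equal to the largest group CV is still
#' "within".
#'
#' @param dep_fraction_percent Percentage of proteins called differentially
#'   expressed (see [glance.dep_result()]).
#' @param cvs Numeric vector of per-group CV percentages (typically from
#'   [group_cv()]), or the [group_cv()] tibble itself.
#' @return `"within_technical_variability"` or
#'   `"exceeds_technical_variability"`.
#' @examples
#' interference_assessment(1.18, c(g1 = 2.01, g3 = 1.74))
#' @export
interference_assessment <- function(dep_fraction_percent, cvs) {
  if (is.data.frame(cvs)) cvs <- cvs$cv_percent
  if (length(cvs) == 0 || anyNA(cvs)) {
    abort_input("need at least one non-missing group CV")
  }
  if (dep_fraction_percent <= max(cvs)) {
    "within_technical_variability"
  } else {
    "exceeds_technical_variability"
  }
}

#' Technical-replicate QC summary for a comparison
#'
#' Combines per-run detected-protein totals, per-group CVs, the DEP fraction
#' of a comparison, and the interference verdict.
#'
#' @param x A [spectral_counts] object.
#' @param dep A `dep_result` from [call_dep_table()], or a DEP fraction
#'   percentage.
#' @inheritParams cv_percent
#' @return A `qc_summary` object with fields `per_run_totals`,
#'   `per_group_cv`, `dep_fraction_percent`, `verdict`.
#' @export
qc_summary <- function(x, dep, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  frac <- if (inherits(dep, "dep_result")) {
    dep$summary$dep_fraction_percent
  } else {
    as.numeric(dep)
  }
  totals <- run_protein_totals(x)
  cvs <- group_cv(x, sd_type = sd_type)
  usable <- cvs$cv_percent[!is.na(cvs$cv_percent)]
  structure(
    list(
      per_run_totals = totals,
      per_group_cv = cvs,
      dep_fraction_percent = frac,
      verdict = if (length(usable) > 0) {
        interference_assessment(frac, usable)
      } else {
        NA_character_
      }
    ),
    class = "qc_summary"
  )
}

#' @export
print.qc_summary <- function(x, ...) {
  cat("<qc_summary>\n")
  cat("  per-group CV of protein totals (%):\n")
  for (i in seq_len(nrow(x$per_group_cv))) {
    cat("    ", x$per_group_cv$group[i], ": ",
        format(round(x$per_group_cv$cv_percent[i], 2)), "\n", sep = "")
  }
  cat("  DEP fraction: ", format(round(x$dep_fraction_percent, 2)),
      "%\n  verdict: ", x$verdict, "\n", sep = "")
  invisible(x)
}

#' @export
glance.qc_summary <- function(x, ...) {
  tibble::tibble(
    dep_fraction_percent = x$dep_fraction_percent,
    max_cv_percent = suppressWarnings(max(x$per_group_cv$cv_percent,
                                          na.rm = TRUE)),
    verdict = x$verdict
  )
}

#' Write the QC report TSV
#'
#' One row per run (run_id, group, replicate, n_proteins) followed by the
#' per-group CV block appended as rows with `run_id = NA`.
#'
#' @param x A `qc_summary` object.
#' @param path Output TSV path.
#' @return `x`, invisibly.
#' @export
write_qc_report <- function(x, path) {
  runs <- dplyr::mutate(x$per_run_totals, cv_percent = NA_real_)
  cvs <- tibble::tibble(
    run_id = NA_character_, group = x$per_group_cv$group,
    replicate = NA_integer_, n_proteins = NA_integer_,
    cv_percent = x$per_group_cv$cv_percent
  )
  readr::write_tsv(dplyr::bind_rows(runs, cvs), path)
  invisible(x)
}
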