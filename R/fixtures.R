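#' Bundled example comparison tables
#'
#' Small published-style summary tables from a semen proteomics study of
#' round-cell interference, shipped as plain TSV. Three comparisons are
#' available: `"neat_comparison"` (leukocyte-rich neat semen, group 1, vs
#' round-cell-poor neat semen, group 3; 26 differential proteins),
#' `"processed_comparison"` (the same contrast after 65% density-gradient
#' processing, group 2 vs group 4; 6 differential proteins), and
#' `"control_comparison"` (the group 1 vs 3 proteins with their abundance
#' in a pure cultured-leukocyte control proteome). Each row carries
#' group-mean spectral counts over triplicate runs, printed abundance-tier
#' labels, the published NSAF ratio, and the published expression label.
#'
#' In `processed_comparison.tsv` the FAM210A expression label is stored as
#' `UE`, agreeing with its ratio (0.14) and with the study's running text;
#' the originally printed table label (`OE`) contradicts both.
#'
#' @param name Which table to load.
#' @return The fixture's file path (`nsafdep_example`) or its parsed tibble
#'   (`read_dep_summary`).
#' @export
nsafdep_example <- function(name = c("neat_comparison",
                                     "processed_comparison",
                                     "control_comparison")) {
  name <- match.arg(name)
  system.file("extdata", paste0(name, ".tsv"), package = "nsafdep",
              mustWork = TRUE)
}

#' @rdname nsafdep_example
#' @param path Path to a summary TSV (columns `accession`, `gene`,
#'   `description`, `sc_ref`, `abun_ref`, `sc_cmp`, `abun_cmp`,
#'   `nsaf_ratio`, `expression`, optionally `sc_control`, `abun_control`,
#'   `nsaf_ratio_control`, `expression_control`).
#' @export
read_dep_summary <- function(path) {
  tab <- read_tsv_strict(path)
  need <- c("accession", "gene", "description", "sc_ref", "sc_cmp")
  if (!all(need %in% names(tab))) {
    abort_input("summary table must have columns ",
                paste(need, collapse = ", "))
  }
  if (!any(c("nsaf_ratio", "nsaf_ratio_control") %in% names(tab))) {
    abort_input("summary table must carry an NSAF ratio column")
  }
  tab
}

#' Expand a summary table into zero-variance pseudo-replicate runs
#'
#' Published comparison tables carry only group means. To push them through
#' the run-level pipeline, each group mean is replicated unchanged into
#' `n_replicates` identical pseudo-runs; within-group variance is then
#' exactly zero and the degenerate t-test rules of [ttest_independent()]
#' apply (p = 0 wherever the means differ). Optional decoy proteins with
#' identical means in both groups emulate the non-differential bulk of the
#' proteome; their NSAF ratio is fixed at 1.
#'
#' @param summary A summary tibble from [read_dep_summary()] (uses
#'   `sc_ref`/`sc_cmp`, or `sc_control` when `use_control = TRUE`).
#' @param group_ref,group_cmp Group labels for the generated design.
#' @param n_replicates Pseudo-replicates per group.
#' @param n_decoys Number of decoy proteins to append.
#' @param decoy_means Optional numeric vector (recycled) of decoy group
#'   means; defaults to values regularly spaced over `[1, 100]` so that decoys
#'   populate the very-low through high abundance tiers.
#' @param default_length Placeholder sequence length for all proteins. The
#'   published ratios are supplied via `ratio_override` downstream, so
#'   lengths only feed the (degenerate) within-table NSAF computation.
#' @param use_control Build the matrix from the control column instead of
#'   the comparison column.
#' @return A list: `counts` (a [spectral_counts]), `ratio_override` (named
#'   vector: published ratios plus 1.0 for decoys, for [call_dep_table()]).
#' @export
pseudo_replicate_counts <- function(summary,
                                    group_ref = "group_ref",
                                    group_cmp = "group_cmp",
                                    n_replicates = 3,
                                    n_decoys = 0,
                                    decoy_means = NULL,
                                    default_length = 300L,
                                    use_control = FALSE) {
  sc_cmp_col <- if (use_control) "sc_control" else "sc_cmp"
  ratio_col <- if (use_control) "nsaf_ratio_control" else "nsaf_ratio"
  if (!sc_cmp_col %in% names(summary)) {
    abort_input("summary has no column '", sc_cmp_col, "'")
  }
  acc <- summary$accession
  sc_ref <- summary$sc_ref
  sc_cmp <- summary[[sc_cmp_col]]
  ratio <- if (ratio_col %in% names(summary)) {
    summary[[ratio_col]]
  } else {
    rep(NA_real_, length(acc))
  }

  if (n_decoys > 0) {
    if (is.null(decoy_means)) {
      decoy_means <- seq(1, 100, length.out = n_decoys)
    }
    decoy_means <- rep_len(decoy_means, n_decoys)
    dacc <- sprintf("DECOY%03d", seq_len(n_decoys))
    acc <- c(acc, dacc)
    sc_ref <- c(sc_ref, decoy_means)
    sc_cmp <- c(sc_cmp, decoy_means)
    ratio <- c(ratio, rep(1, n_decoys))
  }

  counts <- cbind(
    matrix(rep(sc_ref, n_replicates), ncol = n_replicates),
    matrix(rep(sc_cmp, n_replicates), ncol = n_replicates)
  )
  design <- tibble::tibble(
    run_id = c(paste0(group_ref, "_N", seq_len(n_replicates)),
               paste0(group_cmp, "_N", seq_len(n_replicates))),
    group = rep(c(group_ref, group_cmp), each = n_replicates),
    replicate = rep(seq_len(n_replicates), 2)
  )
  proteins <- tibble::tibble(
    accession = acc,
    gene = c(summary$gene, if (n_decoys > 0) dacc else character(0)),
    description = c(summary$description,
                    rep("decoy protein", n_decoys)),
    length = as.integer(default_length)
  )
  override <- stats::setNames(ratio, acc)
  list(
    counts = spectral_counts(counts, proteins, design),
    ratio_override = override[!is.na(override)]
  )
}

#' Control-proteome pseudo-replicate matrix from a summary table
#'
#' Builds a single-group [spectral_counts] for the control proteome from the
#' `sc_control` column of a summary table, replicating each mean into
#' `n_replicates` identical pseudo-runs, for use with
#' [annotate_with_control()]. The published control/reference ratios (column
#' `nsaf_ratio_control`) are returned alongside as an override vector.
#'
#' @inheritParams pseudo_replicate_counts
#' @param group Group label for the control runs.
#' @return A list: `counts` (control-only [spectral_counts]) and
#'   `ratio_override` (named vector of published control/reference ratios).
#' @export
control_matrix_from_summary <- function(summary,
                                        group = "control",
                                        n_replicates = 3,
                                        default_length = 300L) {
  need <- c("sc_control", "nsaf_ratio_control")
  if (!all(need %in% names(summary))) {
    abort_input("summary has no control columns (",
                paste(need, collapse = ", "), ")")
  }
  counts <- matrix(rep(summary$sc_control, n_replicates),
                   ncol = n_replicates)
  design <- tibble::tibble(
    run_id = paste0(group, "_N", seq_len(n_replicates)),
    group = group,
    replicate = seq_len(n_replicates)
  )
  proteins <- tibble::tibble(
    accession = summary$accession, gene = summary$gene,
    description = summary$description,
    length = as.integer(default_length)
  )
  list(
    counts = spectral_counts(counts, proteins, design),
    ratio_override = stats::setNames(summary$nsaf_ratio_control,
                                     summary$accession)
  )
}
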